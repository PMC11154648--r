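one_species <- function(...) {
  sp <- data.frame(species = "solo", body_weight = 1, lipid_fraction = 0.05,
                   k1 = 500, feeding_rate = 0, alpha_diet = 0.7,
                   egestion_ratio = 0, k_G = 0, k_M = 0, phi_sed = 0,
                   diet_phyto = 1, diet_zoo = 0, diet_sed = 0,
                   stringsAsFactors = FALSE)
  over <- list(...)
  for (nm in names(over)) sp[[nm]] <- over[[nm]]
  sp
}

cell <- function(c_water = 1, c_sediment = 0, f_oc = 0.03)
  list(c_water = c_water, c_sediment = c_sediment, f_oc = f_oc)

test_that("rate constants follow the lipid-partitioning relation", {
  sp <- list(k1 = 500, lipid_fraction = 0.05, feeding_rate = 0.02,
             alpha_diet = 0.7, egestion_ratio = 0.3)
  k <- rate_constants(sp, chem_params(log_kow = 6))
  expect_equal(k$k2, 0.01)
  expect_equal(k$kD, 0.014)
  expect_equal(k$kE, 0.0042)
  # log Kow outside the validity range is rejected
  expect_error(chem_params(log_kow = 0), "validity range")
  expect_error(chem_params(log_kow = 9.5), "validity range")
  # k2 strictly decreasing in log Kow, all else fixed
  grid <- seq(2, 8, by = 0.5)
  k2s <- vapply(grid, function(lk)
    rate_constants(sp, chem_params(log_kow = lk))$k2, numeric(1))
  expect_true(all(diff(k2s) < 0))
})

test_that("plankton equilibrium partitioning is linear with traced units", {
  ch <- chem_params(log_kow = 5)
  expect_equal(phytoplankton_concentration(0, ch), 0)
  expect_equal(phytoplankton_concentration(1, ch, lipid = 0.01), 1.0)
  expect_equal(phytoplankton_concentration(2, ch, lipid = 0.01),
               2 * phytoplankton_concentration(1, ch, lipid = 0.01))
})

test_that("no-diet limit reduces to the bioconcentration closed form", {
  web <- build_foodweb(one_species())
  ch <- chem_params(log_kow = 6)
  cw <- 3.7
  cc <- steady_state_concentrations(web, cell(c_water = cw), ch)
  k <- rate_constants(web$params, ch)
  expect_equal(unname(cc), 1e-3 * k$k1 / k$k2 * cw, tolerance = 1e-12)
})

test_that("a two-species chain matches the hand-derived algebra", {
  prey <- one_species(species = "prey", feeding_rate = 0.03,
                      egestion_ratio = 0.3, k_G = 0.005)
  pred <- one_species(species = "pred", feeding_rate = 0.02, k1 = 400,
                      lipid_fraction = 0.06, egestion_ratio = 0.3,
                      k_G = 0.003, diet_phyto = 0, diet_prey = 1)
  prey$diet_prey <- 0
  web <- build_foodweb(rbind(prey, pred))
  ch <- chem_params(log_kow = 6)
  cl <- cell(c_water = 2)
  cc <- steady_state_concentrations(web, cl, ch)

  # hand algebra: triangular two-equation system, solved by substitution
  k <- rate_constants(web$params, ch)
  ktot <- k$k2 + k$kE + web$params$k_G
  c_phy <- phytoplankton_concentration(cl$c_water, ch)
  c_prey <- (1e-3 * k$k1[1] * cl$c_water + k$kD[1] * c_phy) / ktot[1]
  c_pred <- (1e-3 * k$k1[2] * cl$c_water + k$kD[2] * c_prey) / ktot[2]
  expect_equal(unname(cc), c(c_prey, c_pred), tolerance = 1e-12)
})

test_that("direct solve agrees with fixed-point iteration on random 8-species webs", {
  ch <- chem_params(log_kow = 6.2)
  for (seed in 1:5) {
    set.seed(seed)
    sp <- species_presets()
    # perturb physiology and rewire diets randomly (row-normalised)
    sp$k1 <- sp$k1 * runif(8, 0.5, 1.5)
    sp$feeding_rate <- sp$feeding_rate * runif(8, 0.5, 1.2)
    raw <- matrix(runif(64) * (matrix(runif(64), 8) < 0.3), 8)
    diag(raw) <- 0
    base <- cbind(runif(8, 0.1, 1), runif(8, 0.1, 1), runif(8, 0, 0.5))
    tot <- rowSums(raw) + rowSums(base)
    raw <- raw / tot; base <- base / tot
    sp[, c("diet_phyto", "diet_zoo", "diet_sed")] <- base
    sp[, paste0("diet_", sp$species)] <- raw
    web <- build_foodweb(sp)
    cl <- cell(c_water = 0.4, c_sediment = 25)
    direct <- steady_state_concentrations(web, cl, ch)
    iter <- ref_foodweb_fixed_point(web, cl, ch)
    expect_equal(unname(direct), iter, tolerance = 1e-10)
  }
})

test_that("biota concentrations are linear in the environmental field", {
  web <- build_foodweb(species_presets())
  ch <- chem_params()
  c1 <- steady_state_concentrations(web, cell(0.3, 12), ch)
  c2 <- steady_state_concentrations(web, cell(0.3 * 7.5, 12 * 7.5), ch)
  expect_equal(c2, 7.5 * c1, tolerance = 1e-12)
  expect_equal(unname(steady_state_concentrations(web, cell(0, 0), ch)),
               rep(0, 8))
})

test_that("trophic amplification holds along a pelagic chain of presets", {
  # chain assembled from preset physiology: plankton feeder -> mid -> top,
  # kM = 0 and dietary assimilation exceeding egestion throughout
  pre <- species_presets()
  rows <- pre[match(c("pomfret", "sea_bass", "hairtail"), pre$species), ]
  rows[, grep("^diet_", names(rows))] <- 0
  rows$diet_phyto <- c(0.2, 0, 0)
  rows$diet_zoo <- c(0.8, 0, 0)
  rows$diet_pomfret <- c(0, 1, 0)
  rows$diet_sea_bass <- c(0, 0, 1)
  rows$phi_sed <- 0
  web <- build_foodweb(rows)
  cc <- steady_state_concentrations(web, cell(c_water = 1), chem_params())
  lipid_norm <- cc / rows$lipid_fraction
  expect_true(all(diff(lipid_norm) >= 0))
})

test_that("regional summaries average cells and respect structural zeros", {
  cfg <- world_config(n_provinces = 1, n_coastal = 1,
                      grid_cells_per_region = 3, conc_gsd = 1,
                      offshore_decay = 0.5, seed = 1)
  env <- generate_environment(cfg, water_median = 1, sediment_median = 10)
  web <- build_foodweb(species_presets())
  ch <- chem_params()
  tab <- regional_concentrations(web, env, ch)
  # mean over the three cells matches the hand average of per-cell solves
  per_cell <- sapply(1:3, function(i)
    steady_state_concentrations(web, env[i, ], ch))
  expect_equal(tab$mean, unname(rowMeans(per_cell)), tolerance = 1e-12)
  expect_true(all(tab$q2.5 <= tab$q50 & tab$q50 <= tab$q97.5))

  # uniform field: quantiles collapse to the mean
  envu <- env; envu$c_water <- 1; envu$c_sediment <- 10
  tabu <- regional_concentrations(web, envu, ch)
  expect_equal(tabu$q2.5, tabu$mean, tolerance = 1e-12)
  expect_equal(tabu$q97.5, tabu$mean, tolerance = 1e-12)

  # raising sediment only: clam responds, pure pelagic pomfret does not
  env_hi <- envu; env_hi$c_sediment <- 40
  tab_hi <- regional_concentrations(web, env_hi, ch)
  clam <- tab$species == "clam"; pomfret <- tab$species == "pomfret"
  expect_gt(tab_hi$mean[clam], tabu$mean[clam])
  expect_equal(tab_hi$mean[pomfret], tabu$mean[pomfret], tolerance = 1e-12)

  expect_error(regional_concentrations(web, env[0, ], ch), "empty")
})

test_that("benthic species dominate when sediment is enriched", {
  web <- build_foodweb(species_presets())
  cc <- steady_state_concentrations(web, cell(c_water = 0.05,
                                              c_sediment = 50),
                                    chem_params())
  expect_identical(names(which.max(cc)), "clam")
  expect_identical(names(which.min(cc)), "pomfret")
  benthic <- c("prawn", "clam", "oyster")
  expect_gt(min(cc[benthic]), mean(cc[setdiff(names(cc), benthic)]))
})

test_that("invalid webs are rejected with informative errors", {
  sp <- one_species()
  sp$diet_phyto <- 0.7   # diet no longer sums to 1
  expect_error(build_foodweb(sp), "sum to 1")
  sp2 <- one_species(phi_sed = 1.4)
  expect_error(build_foodweb(sp2), "phi_sed")
  # a self-loop strong enough to make the system singular is reported
  sp3 <- one_species(feeding_rate = 10, alpha_diet = 1, egestion_ratio = 0,
                     diet_phyto = 0)
  sp3$diet_solo <- 1
  sp3$k1 <- 1e-6
  web3 <- build_foodweb(sp3)
  k <- rate_constants(sp3, chem_params(log_kow = 6))
  sp3$feeding_rate <- (k$k2 + 0) / sp3$alpha_diet  # kD == ktot exactly
  web3 <- build_foodweb(sp3)
  expect_error(steady_state_concentrations(web3, cell(1, 0),
                                           chem_params(log_kow = 6)),
               "singular|residual")
})
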