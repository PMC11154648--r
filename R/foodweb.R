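#' Build a food web from a species parameter table
#'
#' Validates the species table and splits its diet columns into the
#' predator-prey matrix `P` (rows are predators, columns prey; row sums equal
#' each species' "other species" diet share) and the base-compartment matrix
#' (phytoplankton, zooplankton, sediment/detritus shares). Total diet shares
#' must sum to 1 per species. The steady-state linear system is checked for
#' solvability at build time: the dietary coupling must be a strict
#' contraction of the elimination terms (the system matrix is strictly
#' diagonally dominant whenever egestion, growth or gill elimination is
#' positive, since assimilated diet shares are < 1 of total elimination in
#' any physically sensible parameterisation); an exactly singular system is
#' rejected.
#'
#' @param species Data frame as produced by [species_presets()].
#' @return A list of class `foodweb` with elements `params` (data frame),
#'   `P` (diet matrix among species), `base` (matrix with columns
#'   `diet_phyto`, `diet_zoo`, `diet_sed`).
#' @export
build_foodweb <- function(species = species_presets()) {
  req <- c("species", "body_weight", "lipid_fraction", "k1", "feeding_rate",
           "alpha_diet", "egestion_ratio", "k_G", "k_M", "phi_sed",
           "diet_phyto", "diet_zoo", "diet_sed")
  miss <- setdiff(req, names(species))
  if (length(miss))
    stop("build_foodweb: species table lacks columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  sp <- species$species
  if (anyDuplicated(sp)) stop("build_foodweb: duplicated species names", call. = FALSE)

  prey_cols <- paste0("diet_", sp)
  present <- intersect(prey_cols, names(species))
  P <- matrix(0, length(sp), length(sp), dimnames = list(sp, sp))
  if (length(present))
    P[, sub("^diet_", "", present)] <-
      as.matrix(species[, present, drop = FALSE])
  base <- as.matrix(species[, c("diet_phyto", "diet_zoo", "diet_sed")])
  rownames(base) <- sp

  tot <- rowSums(P) + rowSums(base)
  if (any(abs(tot - 1) > 1e-12))
    stop("build_foodweb: diet fractions must sum to 1 (offending: ",
         paste(sp[abs(tot - 1) > 1e-12], collapse = ", "), ")", call. = FALSE)
  if (any(P < 0) || any(base < 0))
    stop("build_foodweb: diet fractions must be non-negative", call. = FALSE)
  with(species, {
    if (any(phi_sed < 0 | phi_sed > 1))
      stop("build_foodweb: phi_sed must lie in [0, 1]", call. = FALSE)
    if (any(c(k1, feeding_rate, alpha_diet, egestion_ratio, k_G, k_M) < 0) ||
        any(lipid_fraction <= 0) || any(body_weight <= 0))
      stop("build_foodweb: negative rate or non-positive weight/lipid",
           call. = FALSE)
  })
  structure(list(params = species, P = P, base = base), class = "foodweb")
}

#' Kinetic rate constants for one species in one environment cell
#'
#' Standard steady-state bioaccumulation kinetics: gill uptake `k1`
#' (supplied as a species parameter, L kg^-1 d^-1), gill elimination
#' `k2 = k1 / (lipid_fraction * Kow)` (d^-1, the lipid-partitioning
#' relation), dietary uptake `kD = alpha_diet * feeding_rate`
#' (kg kg^-1 d^-1) and faecal egestion `kE = egestion_ratio * kD` (d^-1).
#'
#' @param species One-row species data frame (or list) with fields
#'   `k1`, `lipid_fraction`, `feeding_rate`, `alpha_diet`, `egestion_ratio`.
#' @param chem A [chem_params()]; `log_kow` must lie in the validity range
#'   1-9.
#' @return Named list with `k1`, `k2`, `kD`, `kE` (vectorised over species
#'   rows).
#' @export
#' @examples
#' sp <- list(k1 = 500, lipid_fraction = 0.05, feeding_rate = 0.02,
#'            alpha_diet = 0.7, egestion_ratio = 0.3)
#' rate_constants(sp, chem_params(log_kow = 6))$k2  # 0.01 d^-1
rate_constants <- function(species, chem = chem_params()) {
  stopifnot(inherits(chem, "chem_params"))
  kow <- 10 ^ chem$log_kow
  k1 <- species$k1
  k2 <- k1 / (species$lipid_fraction * kow)
  kD <- species$alpha_diet * species$feeding_rate
  kE <- species$egestion_ratio * kD
  if (any(!is.finite(c(k1, k2, kD, kE))) || any(c(k1, k2) <= 0))
    stop("rate_constants: rates must be positive and finite", call. = FALSE)
  list(k1 = k1, k2 = k2, kD = kD, kE = kE)
}

#' Phytoplankton concentration by equilibrium partitioning
#'
#' The plankton base of the web is assumed at lipid-partitioning equilibrium
#' with dissolved water: `C = lipid * Kow * C_water * 1e-3` with the 1e-3
#' factor converting L to g of tissue, giving ng g^-1 wet weight from
#' ng L^-1 water. Linear in the water concentration.
#'
#' @param c_water Dissolved-water concentration, ng L^-1.
#' @param chem A [chem_params()].
#' @param lipid Lipid fraction; defaults to the phytoplankton value in
#'   `chem`.
#' @return Concentration, ng g^-1 ww.
#' @export
#' @examples
#' phytoplankton_concentration(1, chem_params(log_kow = 5), lipid = 0.01) # 1
phytoplankton_concentration <- function(c_water, chem = chem_params(),
                                        lipid = chem$lipid_phyto) {
  stopifnot(all(c_water >= 0))
  lipid * 10 ^ chem$log_kow * c_water * 1e-3
}

#' Sediment pore-water concentration by organic-carbon partitioning
#'
#' `C_pw = C_sed * 1000 / (f_oc * Koc)` with `Koc = koc_factor * Kow`
#' (L kg^-1); the factor 1000 converts ng g^-1 dry sediment to ng kg^-1.
#'
#' @param c_sediment Sediment concentration, ng g^-1 dry.
#' @param f_oc Organic-carbon fraction of sediment.
#' @param chem A [chem_params()].
#' @return Pore-water concentration, ng L^-1.
#' @export
porewater_concentration <- function(c_sediment, f_oc, chem = chem_params()) {
  stopifnot(all(c_sediment >= 0), all(f_oc > 0 & f_oc < 1))
  koc <- chem$koc_factor * 10 ^ chem$log_kow
  c_sediment * 1000 / (f_oc * koc)
}

#' Steady-state tissue concentrations in one environment cell
#'
#' Solves the coupled linear steady-state mass balance for all species
#' simultaneously:
#' \deqn{C_i (k_{2,i} + k_{E,i} + k_{G,i} + k_{M,i}) =
#'   10^{-3} k_{1,i} [(1-\phi_i) C_w + \phi_i C_{pw}]
#'   + k_{D,i} (\sum_j P_{ij} C_j + p_{phy,i} C_{phy}
#'   + p_{zoo,i} C_{zoo} + p_{sed,i} C_{sed})}
#' where the 1e-3 factor converts the gill term (L kg^-1 d^-1 times
#' ng L^-1) to ng g^-1 d^-1. The system `(diag(k_tot) - diag(kD) P) C = b`
#' is solved directly; cyclic diets are legal as long as the system is
#' nonsingular. The residual is checked to 1e-10 relative and all
#' concentrations must be non-negative.
#'
#' @param web A [build_foodweb()] object.
#' @param cell One-row data frame (or list) with `c_water`, `c_sediment`,
#'   `f_oc` (and optionally `temperature`).
#' @param chem A [chem_params()].
#' @return Named numeric vector of concentrations, ng g^-1 ww.
#' @export
steady_state_concentrations <- function(web, cell, chem = chem_params()) {
  stopifnot(inherits(web, "foodweb"))
  if (cell$c_water < 0 || cell$c_sediment < 0)
    stop("steady_state_concentrations: negative environmental concentration",
         call. = FALSE)
  par <- web$params
  k <- rate_constants(par, chem)
  ktot <- k$k2 + k$kE + par$k_G + par$k_M

  c_phy <- phytoplankton_concentration(cell$c_water, chem, chem$lipid_phyto)
  c_zoo <- phytoplankton_concentration(cell$c_water, chem, chem$lipid_zoo)
  c_pw <- porewater_concentration(cell$c_sediment, cell$f_oc, chem)
  c_resp <- (1 - par$phi_sed) * cell$c_water + par$phi_sed * c_pw

  b <- 1e-3 * k$k1 * c_resp +
    k$kD * (web$base[, "diet_phyto"] * c_phy +
            web$base[, "diet_zoo"] * c_zoo +
            web$base[, "diet_sed"] * cell$c_sediment)
  A <- diag(ktot, nrow = length(ktot)) - k$kD * web$P

  conc <- tryCatch(solve(A, b), error = function(e) {
    cyc <- par$species[rowSums(web$P) > 0]
    stop("steady_state_concentrations: singular steady-state system; ",
         "check diet cycle among: ", paste(cyc, collapse = ", "),
         call. = FALSE)
  })
  res <- max(abs(A %*% conc - b)) / max(abs(b), .Machine$double.xmin)
  if (res > 1e-10)
    stop("steady_state_concentrations: linear solve residual ", res, call. = FALSE)
  if (any(conc < 0))
    stop("steady_state_concentrations: negative concentration in solution",
         call. = FALSE)
  stats::setNames(as.numeric(conc), par$species)
}

#' Regional species concentrations over a contaminant field
#'
#' Solves the steady-state web in every grid cell of every region, then
#' summarises per (region, species): the mean across cells plus the spatial
#' 2.5, 50 and 97.5 percent quantiles.
#'
#' @param web A [build_foodweb()] object.
#' @param field An `environment_field` data frame from
#'   [generate_environment()] (columns `region`, `cell`, `c_water`,
#'   `c_sediment`, `f_oc`).
#' @param chem A [chem_params()].
#' @return A data frame of class `concentration_table` with columns
#'   `region`, `species`, `mean`, `q2.5`, `q50`, `q97.5` (ng g^-1 ww).
#' @export
regional_concentrations <- function(web, field, chem = chem_params()) {
  stopifnot(inherits(web, "foodweb"))
  if (!nrow(field)) stop("regional_concentrations: empty field", call. = FALSE)
  regions <- unique(field$region)
  sp <- web$params$species
  out <- vector("list", length(regions))
  for (r in seq_along(regions)) {
    cells <- field[field$region == regions[r], , drop = FALSE]
    if (!nrow(cells))
      stop("regional_concentrations: region without cells: ", regions[r],
           call. = FALSE)
    cc <- t(vapply(seq_len(nrow(cells)), function(i)
      steady_state_concentrations(web, cells[i, ], chem),
      numeric(length(sp))))
    q <- apply(cc, 2, stats::quantile, probs = c(0.025, 0.5, 0.975),
               names = FALSE, type = 7)
    out[[r]] <- data.frame(region = regions[r], species = sp,
                           mean = colMeans(cc),
                           q2.5 = q[1, ], q50 = q[2, ], q97.5 = q[3, ],
                           stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, out)
  rownames(tab) <- NULL
  class(tab) <- c("concentration_table", class(tab))
  tab
}

#' Concentration table as a region x species matrix
#' @param conc A `concentration_table`.
#' @param value Which column to spread (default `"mean"`).
#' @return Matrix with region rows and species columns.
#' @export
concentration_matrix <- function(conc, value = "mean") {
  regions <- unique(conc$region)
  sp <- unique(conc$species)
  m <- matrix(NA_real_, length(regions), length(sp),
              dimnames = list(regions, sp))
  m[cbind(match(conc$region, regions), match(conc$species, sp))] <-
    conc[[value]]
  m
}
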