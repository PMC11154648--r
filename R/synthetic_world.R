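#' Default marine species parameter presets
#'
#' Eight commercially important Chinese seafood taxa with the physiological
#' and dietary parameters needed by the steady-state food-web model. Prawn,
#' clam and oyster carry benthic exposure (positive `phi_sed` and a
#' sediment/detritus diet share), reflecting that bottom-dwelling species
#' contact contaminated sediment far more than pelagic fish. Diet columns
#' (`diet_phyto`, `diet_zoo`, `diet_sed` and one `diet_<prey>` column per
#' species) sum to 1 for every species.
#'
#' Columns:
#' \describe{
#'   \item{species}{Name.}
#'   \item{body_weight}{kg.}
#'   \item{lipid_fraction}{Unitless wet-weight lipid content.}
#'   \item{k1}{Gill uptake rate constant, L kg^-1 d^-1.}
#'   \item{feeding_rate}{Specific feeding rate, kg food (kg body)^-1 d^-1.}
#'   \item{alpha_diet}{Dietary chemical assimilation efficiency (unitless).}
#'   \item{egestion_ratio}{Faecal egestion rate as a fraction of the dietary
#'     uptake rate constant (unitless, < 1 so dietary uptake exceeds
#'     egestion and contaminant biomagnifies along the chain).}
#'   \item{k_G}{Growth dilution rate constant, d^-1.}
#'   \item{k_M}{Metabolic transformation rate constant, d^-1; defaults to 0
#'     because metabolism of chlorinated paraffins in marine organisms is
#'     poorly characterised.}
#'   \item{phi_sed}{Fraction of respired water drawn from sediment pore
#'     water, unitless in [0, 1].}
#'   \item{cons_weight}{Relative per-capita consumption weight used by the
#'     synthetic-world generator (clam- and oyster-heavy, matching the
#'     shellfish-dominated intake pattern of the study population).}
#' }
#'
#' @return A data frame, one row per species.
#' @export
species_presets <- function() {
  sp <- c("hairtail", "large_yellow_croaker", "small_yellow_croaker",
          "sea_bass", "pomfret", "prawn", "clam", "oyster")
  tab <- data.frame(
    species        = sp,
    body_weight    = c(1.0, 0.8, 0.15, 2.0, 0.3, 0.02, 0.01, 0.05),
    lipid_fraction = c(0.05, 0.06, 0.04, 0.04, 0.05, 0.010, 0.012, 0.015),
    k1             = c(500, 520, 800, 420, 700, 1400, 1600, 1000),
    feeding_rate   = c(0.025, 0.025, 0.035, 0.020, 0.030, 0.040, 0.050, 0.050),
    alpha_diet     = c(0.70, 0.70, 0.70, 0.70, 0.70, 0.60, 0.55, 0.55),
    egestion_ratio = c(0.30, 0.30, 0.30, 0.30, 0.30, 0.35, 0.35, 0.35),
    k_G            = c(0.004, 0.004, 0.008, 0.003, 0.005, 0.010, 0.006, 0.008),
    k_M            = 0,
    phi_sed        = c(0, 0, 0, 0, 0, 0.30, 0.50, 0.40),
    cons_weight    = c(0.12, 0.05, 0.05, 0.04, 0.04, 0.10, 0.35, 0.25),
    stringsAsFactors = FALSE)

  diet <- matrix(0, nrow = 8, ncol = 8, dimnames = list(sp, sp))
  base <- matrix(0, nrow = 8, ncol = 3,
                 dimnames = list(sp, c("diet_phyto", "diet_zoo", "diet_sed")))
  # predator rows; prey columns -------------------------------------------
  diet["hairtail", c("small_yellow_croaker", "prawn")] <- c(0.45, 0.25)
  base["hairtail", "diet_zoo"] <- 0.30
  diet["large_yellow_croaker", "prawn"] <- 0.40
  base["large_yellow_croaker", c("diet_phyto", "diet_zoo")] <- c(0.10, 0.50)
  diet["small_yellow_croaker", "prawn"] <- 0.20
  base["small_yellow_croaker", c("diet_phyto", "diet_zoo")] <- c(0.10, 0.70)
  diet["sea_bass", c("small_yellow_croaker", "prawn")] <- c(0.30, 0.40)
  base["sea_bass", "diet_zoo"] <- 0.30
  base["pomfret", c("diet_phyto", "diet_zoo")] <- c(0.20, 0.80)
  base["prawn", c("diet_phyto", "diet_zoo", "diet_sed")] <- c(0.30, 0.30, 0.40)
  base["clam", c("diet_phyto", "diet_sed")] <- c(0.50, 0.50)
  base["oyster", c("diet_phyto", "diet_sed")] <- c(0.60, 0.40)

  out <- cbind(tab, as.data.frame(base),
               stats::setNames(as.data.frame(diet), paste0("diet_", sp)))
  rownames(out) <- NULL
  out
}

#' Generate the coastal contaminant field
#'
#' Draws per-cell dissolved-water and sediment concentrations for each
#' coastal region. Cells are ranked from nearshore (rank 1) outward; cell
#' values are `median_region * GSD-lognormal noise * offshore_decay^(rank-1)`,
#' so concentrations decrease toward offshore in expectation. Region medians
#' are drawn lognormally around the configured national medians unless
#' supplied explicitly.
#'
#' @param config A [world_config()].
#' @param water_median,sediment_median Optional explicit per-region medians
#'   (length `n_coastal`), bypassing the region-level draw.
#' @return A data frame of class `environment_field` with columns `region`,
#'   `cell`, `c_water` (ng L^-1), `c_sediment` (ng g^-1 dry), `f_oc`,
#'   `temperature`.
#' @export
generate_environment <- function(config, water_median = NULL,
                                 sediment_median = NULL) {
  validate_world_config(config)
  nr <- config$n_coastal
  nc <- config$grid_cells_per_region
  regions <- province_names(config$n_provinces)[seq_len(nr)]

  set.seed(stage_seed(config$seed, "environment"))
  sdlog <- log(config$conc_gsd)
  if (is.null(water_median))
    water_median <- stats::rlnorm(nr, log(config$water_median), sdlog)
  if (is.null(sediment_median))
    sediment_median <- stats::rlnorm(nr, log(config$sediment_median), sdlog)
  stopifnot(length(water_median) == nr, length(sediment_median) == nr,
            all(water_median > 0), all(sediment_median > 0))

  decay <- config$offshore_decay ^ (seq_len(nc) - 1L)
  rows <- lapply(seq_len(nr), function(i) {
    w <- stats::rlnorm(nc, log(water_median[i]), sdlog) * decay
    s <- stats::rlnorm(nc, log(sediment_median[i]), sdlog) * decay
    data.frame(region = regions[i], cell = seq_len(nc),
               c_water = w, c_sediment = s,
               f_oc = config$f_oc, temperature = config$temperature,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("environment_field", class(out))
  out
}

province_names <- function(n) sprintf("P%02d", seq_len(n))

#' Generate the provincial table and distance matrix
#'
#' Coastal provinces sit along a synthetic coastline, inland provinces behind
#' it; interprovincial distances are Euclidean between the random 2-D
#' coordinates (only relative deterrence matters to the gravity model, so a
#' road network adds nothing at desk scale). Coastal provinces receive
#' fishery supply proportional to random weights summing to `total_supply`;
#' every province receives per-species consumption rates (coastal provinces
#' consume more, as observed for seafood), and demand is derived exactly as
#' `rate * population * 365 / 1e9` kilotons per year, rescaled so national
#' demand equals `total_demand`. Per-species supply totals are set to species
#' demand totals scaled up by the national supply/demand ratio, so each
#' species market carries the same relative surplus.
#'
#' @param config A [world_config()].
#' @param species Species parameter table; defaults to [species_presets()].
#' @return A list of class `province_table` with elements `provinces` (data
#'   frame: `name`, `coastal`, `population`, `x`, `y`, and per-species
#'   `cons_*` (g day^-1 person^-1), `dem_*`, `sup_*` (kilotons yr^-1)
#'   columns) and `distances` (symmetric km matrix, zero diagonal).
#' @export
generate_provinces <- function(config, species = species_presets()) {
  validate_world_config(config)
  n <- config$n_provinces
  ncst <- config$n_coastal
  nm <- province_names(n)
  sp <- species$species

  set.seed(stage_seed(config$seed, "provinces"))
  coastal <- c(rep(TRUE, ncst), rep(FALSE, n - ncst))
  x <- numeric(n); y <- numeric(n)
  x[coastal] <- sort(stats::runif(ncst, 0, 2500))
  y[coastal] <- stats::runif(ncst, 0, 150)
  if (n > ncst) {
    x[!coastal] <- stats::runif(n - ncst, 0, 2500)
    y[!coastal] <- stats::runif(n - ncst, 300, 1800)
  }
  d <- as.matrix(stats::dist(cbind(x, y)))
  dimnames(d) <- list(nm, nm)

  population <- stats::rlnorm(n, log(4.5e7), 0.6)

  # per-capita consumption: total rate per person, split by species weights,
  # coastal multiplier reflecting higher seafood intake on the coast
  w_sp <- species$cons_weight / sum(species$cons_weight)
  rate_tot <- stats::rlnorm(n, log(20), 0.35) *
    ifelse(coastal, stats::rlnorm(n, log(2), 0.25), 1)
  cons <- outer(rate_tot, w_sp) *
    matrix(stats::rlnorm(n * length(sp), 0, 0.20), n)
  dem <- cons * population * 365 / 1e9          # g/day -> kilotons/yr
  scale_d <- config$total_demand / sum(dem)
  cons <- cons * scale_d
  dem <- dem * scale_d

  # coastal supply: random fishery weights, per-species split with jitter,
  # species totals carry the national surplus ratio
  surplus_ratio <- config$total_supply / config$total_demand
  sup_sp_tot <- colSums(dem) * surplus_ratio
  w_prov <- stats::rgamma(ncst, shape = 2, rate = 1)
  sup <- matrix(0, n, length(sp))
  jit <- matrix(stats::rlnorm(ncst * length(sp), 0, 0.3), ncst)
  wj <- (w_prov * jit)
  wj <- sweep(wj, 2, colSums(wj), "/")
  sup[coastal, ] <- sweep(wj, 2, sup_sp_tot, "*")

  colnames(cons) <- paste0("cons_", sp)
  colnames(dem) <- paste0("dem_", sp)
  colnames(sup) <- paste0("sup_", sp)
  provinces <- cbind(
    data.frame(name = nm, coastal = coastal, population = population,
               x = x, y = y, stringsAsFactors = FALSE),
    as.data.frame(cons), as.data.frame(dem), as.data.frame(sup))

  structure(list(provinces = provinces, distances = d, species = sp),
            class = "province_table")
}

#' Species columns of a province table
#' @param provinces A `province_table`.
#' @param what One of `"sup"`, `"dem"`, `"cons"`.
#' @return Matrix provinces x species.
#' @export
province_matrix <- function(provinces, what = c("sup", "dem", "cons")) {
  what <- match.arg(what)
  p <- provinces$provinces
  m <- as.matrix(p[, paste0(what, "_", provinces$species), drop = FALSE])
  dimnames(m) <- list(p$name, provinces$species)
  m
}

#' Generate noisy observed trade flows
#'
#' Produces a synthetic "observed" interprovincial flow matrix for the total
#' seafood market: gravity-model flows at the configured true deterrence
#' exponent, perturbed by multiplicative lognormal noise (median 1) and
#' re-balanced by iterative proportional fitting to the margins of the
#' noise-free flows, so supply and demand accounting still closes. Used to
#' exercise deterrence-exponent recovery.
#'
#' @param provinces A `province_table` from [generate_provinces()].
#' @param beta_true True deterrence exponent.
#' @param noise_gsd Geometric SD of the multiplicative noise (>= 1; 1 means
#'   no noise and returns the gravity flows unchanged).
#' @param seed Integer seed.
#' @param params Gravity parameters (the exponent is overridden by
#'   `beta_true`).
#' @return A flow matrix (kilotons yr^-1) with origin rows and destination
#'   columns.
#' @export
generate_observed_flows <- function(provinces, beta_true = 1, noise_gsd = 1.1,
                                    seed = 1L, params = gravity_params()) {
  if (!is.numeric(noise_gsd) || noise_gsd < 1)
    stop("generate_observed_flows: noise_gsd must be >= 1", call. = FALSE)
  params$beta <- beta_true
  sup <- rowSums(province_matrix(provinces, "sup"))
  dem <- rowSums(province_matrix(provinces, "dem"))
  flows0 <- gravity_flows(sup, dem, provinces$distances, params)
  if (noise_gsd == 1) return(flows0)
  set.seed(stage_seed(seed, "observed_flows"))
  noise <- matrix(stats::rlnorm(length(flows0), 0, log(noise_gsd)),
                  nrow(flows0))
  perturbed <- unclass(flows0) * noise
  rebalanced <- ipf_scale(perturbed, rowSums(flows0), colSums(flows0),
                          tol = 1e-12, max_iter = params$ipf_max_iter)
  dimnames(rebalanced) <- dimnames(flows0)
  rebalanced
}

#' Generate synthetic tissue-concentration measurements
#'
#' Perturbs modelled ("true") concentrations with multiplicative lognormal
#' measurement error of median 1, yielding a paired modelled/measured table
#' for model-evaluation metrics (mean bias, normalized mean bias, factor-k
#' coverage).
#'
#' @param true_conc Numeric vector (or a `concentration_table` data frame
#'   with a `mean` column) of true concentrations, ng g^-1 ww; must be
#'   positive.
#' @param meas_gsd Geometric SD of the measurement error (>= 1).
#' @param seed Integer seed.
#' @return A data frame with columns `modeled` and `measured` (plus `region`
#'   and `species` when a concentration table is supplied).
#' @export
generate_measurements <- function(true_conc, meas_gsd = 1.5, seed = 1L) {
  if (!is.numeric(meas_gsd) || meas_gsd < 1)
    stop("generate_measurements: meas_gsd must be >= 1", call. = FALSE)
  keys <- NULL
  if (is.data.frame(true_conc)) {
    keys <- true_conc[, intersect(c("region", "species"), names(true_conc)),
                      drop = FALSE]
    true_conc <- true_conc$mean
  }
  if (any(true_conc <= 0))
    stop("generate_measurements: true concentrations must be positive",
         call. = FALSE)
  set.seed(stage_seed(seed, "measurements"))
  measured <- true_conc * stats::rlnorm(length(true_conc), 0, log(meas_gsd))
  out <- data.frame(modeled = true_conc, measured = measured)
  if (!is.null(keys) && ncol(keys)) out <- cbind(keys, out)
  out
}
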