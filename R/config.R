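#' Configuration of the synthetic coastal world
#'
#' Bundles every knob of the synthetic-world generator: the national geometry
#' (number of provinces, how many of them are coastal), the contaminant field
#' (region-median levels, within-region geometric spread, offshore decay), the
#' trade-generating gravity exponent and the national supply/demand totals.
#' The defaults describe a desk-scale system mirroring the Chinese geometry of
#' the analysis: 31 provinces of which 11 are coastal, national seafood supply
#' exceeding national demand, and a nearshore-high contaminant gradient.
#'
#' @param n_provinces Number of provinces.
#' @param n_coastal Number of coastal (seafood-producing) provinces; must not
#'   exceed `n_provinces`.
#' @param grid_cells_per_region Number of marine grid cells per coastal
#'   region, ordered from nearshore (rank 1) to offshore.
#' @param conc_gsd Geometric standard deviation (unitless, >= 1) of the
#'   multiplicative lognormal noise applied to cell concentrations around the
#'   region median.
#' @param offshore_decay Per-cell multiplicative decay (0 < decay <= 1) of
#'   concentration moving away from shore; 1 means no gradient.
#' @param beta_true Gravity deterrence exponent used when generating observed
#'   trade flows (unitless, >= 0).
#' @param total_supply National seafood supply, kilotons per year.
#' @param total_demand National seafood demand, kilotons per year; must not
#'   exceed `total_supply` (the system is supply-surplus).
#' @param water_median National-scale median dissolved-water concentration,
#'   ng L^-1; region medians are drawn around it.
#' @param sediment_median National-scale median sediment concentration,
#'   ng g^-1 dry weight.
#' @param f_oc Organic-carbon fraction of sediment (0 < f_oc < 1).
#' @param temperature Water temperature, degrees C (carried through, not used
#'   by the default kinetics).
#' @param seed Integer root seed; every stochastic stage derives its own
#'   substream from it via [stage_seed()].
#'
#' @return A validated list of class `world_config`.
#' @export
#' @examples
#' cfg <- world_config(n_provinces = 6, n_coastal = 3, seed = 42)
world_config <- function(n_provinces = 31,
                         n_coastal = 11,
                         grid_cells_per_region = 5,
                         conc_gsd = 1.5,
                         offshore_decay = 0.7,
                         beta_true = 1,
                         total_supply = 13742.9,
                         total_demand = 11000,
                         water_median = 0.05,
                         sediment_median = 10,
                         f_oc = 0.03,
                         temperature = 15,
                         seed = 1L) {
  cfg <- structure(
    list(n_provinces = as.integer(n_provinces),
         n_coastal = as.integer(n_coastal),
         grid_cells_per_region = as.integer(grid_cells_per_region),
         conc_gsd = conc_gsd,
         offshore_decay = offshore_decay,
         beta_true = beta_true,
         total_supply = total_supply,
         total_demand = total_demand,
         water_median = water_median,
         sediment_median = sediment_median,
         f_oc = f_oc,
         temperature = temperature,
         seed = as.integer(seed)),
    class = "world_config")
  validate_world_config(cfg)
  cfg
}

validate_world_config <- function(cfg) {
  stopifnot(inherits(cfg, "world_config"))
  num <- c("n_provinces", "n_coastal", "grid_cells_per_region", "conc_gsd",
           "offshore_decay", "beta_true", "total_supply", "total_demand",
           "water_median", "sediment_median", "f_oc", "temperature")
  for (f in num) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("world_config: field '", f, "' must be a finite scalar", call. = FALSE)
  }
  if (cfg$n_provinces < 1L) stop("world_config: n_provinces must be >= 1", call. = FALSE)
  if (cfg$n_coastal < 1L || cfg$n_coastal > cfg$n_provinces)
    stop("world_config: need 1 <= n_coastal <= n_provinces", call. = FALSE)
  if (cfg$grid_cells_per_region < 1L)
    stop("world_config: grid_cells_per_region must be >= 1", call. = FALSE)
  if (cfg$conc_gsd < 1) stop("world_config: conc_gsd must be >= 1", call. = FALSE)
  if (cfg$offshore_decay <= 0 || cfg$offshore_decay > 1)
    stop("world_config: offshore_decay must be in (0, 1]", call. = FALSE)
  if (cfg$beta_true < 0) stop("world_config: beta_true must be >= 0", call. = FALSE)
  if (cfg$total_supply <= 0 || cfg$total_demand <= 0)
    stop("world_config: supply and demand totals must be positive", call. = FALSE)
  if (cfg$total_demand > cfg$total_supply)
    stop("world_config: total_demand must not exceed total_supply ",
         "(the system is supply-surplus)", call. = FALSE)
  if (cfg$water_median <= 0 || cfg$sediment_median <= 0)
    stop("world_config: environmental medians must be positive", call. = FALSE)
  if (cfg$f_oc <= 0 || cfg$f_oc >= 1)
    stop("world_config: f_oc must be in (0, 1)", call. = FALSE)
  invisible(cfg)
}

#' Gravity-model parameters
#'
#' @param beta Deterrence exponent (unitless, >= 0).
#' @param deterrence_form Either `"power"` (weight `d^-beta`) or
#'   `"exponential"` (weight `exp(-beta * d)`).
#' @param d_intra_factor Intra-provincial distances are undefined when
#'   distances are measured between provincial capitals; zero diagonal entries
#'   are replaced by `d_intra_factor * min_j d_ij` (default one half the
#'   distance to the nearest other province).
#' @param ipf_tol Convergence tolerance of iterative proportional fitting,
#'   maximum relative margin error.
#' @param ipf_max_iter Maximum IPF iterations before failing.
#'
#' @return A list of class `gravity_params`.
#' @export
gravity_params <- function(beta = 1,
                           deterrence_form = c("power", "exponential"),
                           d_intra_factor = 0.5,
                           ipf_tol = 1e-10,
                           ipf_max_iter = 10000L) {
  deterrence_form <- match.arg(deterrence_form)
  if (!is.numeric(beta) || length(beta) != 1L || !is.finite(beta) || beta < 0)
    stop("gravity_params: beta must be a finite scalar >= 0", call. = FALSE)
  if (ipf_tol <= 0) stop("gravity_params: ipf_tol must be positive", call. = FALSE)
  if (d_intra_factor <= 0)
    stop("gravity_params: d_intra_factor must be positive", call. = FALSE)
  structure(list(beta = beta,
                 deterrence_form = deterrence_form,
                 d_intra_factor = d_intra_factor,
                 ipf_tol = ipf_tol,
                 ipf_max_iter = as.integer(ipf_max_iter)),
            class = "gravity_params")
}

#' Chemical parameters of the modelled contaminant
#'
#' The contaminant is treated as a single hydrophobic compound with one
#' representative octanol-water partition coefficient. The default
#' `log_kow = 6.2` sits mid-range of the span reported for commercial
#' short-chain chlorinated paraffin mixtures (log Kow roughly 4 to 8.7).
#'
#' @param log_kow log10 octanol-water partition coefficient; must lie in the
#'   validity range 1-9 of the kinetic relations.
#' @param lipid_phyto,lipid_zoo Lipid fractions of the phytoplankton and
#'   zooplankton base compartments (unitless).
#' @param koc_factor Organic-carbon partition coefficient as a fraction of
#'   Kow (`Koc = koc_factor * Kow`, L kg^-1).
#' @return A list of class `chem_params`.
#' @export
chem_params <- function(log_kow = 6.2,
                        lipid_phyto = 0.005,
                        lipid_zoo = 0.012,
                        koc_factor = 0.35) {
  if (!is.numeric(log_kow) || length(log_kow) != 1L || !is.finite(log_kow) ||
      log_kow < 1 || log_kow > 9)
    stop("chem_params: log_kow must lie in the validity range [1, 9]",
         call. = FALSE)
  if (lipid_phyto <= 0 || lipid_zoo <= 0)
    stop("chem_params: plankton lipid fractions must be positive", call. = FALSE)
  if (koc_factor <= 0) stop("chem_params: koc_factor must be positive", call. = FALSE)
  structure(list(log_kow = log_kow, lipid_phyto = lipid_phyto,
                 lipid_zoo = lipid_zoo, koc_factor = koc_factor),
            class = "chem_params")
}

#' Derive a reproducible per-stage seed from the root seed
#'
#' All randomness in the pipeline flows from one root seed through named
#' substreams, so that stages rerun individually reproduce the full-pipeline
#' draws. The derived seed is always a non-negative 32-bit integer.
#'
#' @param seed Integer root seed.
#' @param stage Character stage name.
#' @return An integer seed.
#' @export
#' @examples
#' stage_seed(1, "environment")
stage_seed <- function(seed, stage) {
  stopifnot(is.character(stage), length(stage) == 1L)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 1009 + h * 97) %% 2147483647)
}
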