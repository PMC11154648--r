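#' Destination-side consumed concentration
#'
#' Trade disconnects where seafood is produced from where it is eaten: the
#' concentration in the seafood a destination actually consumes is the
#' share-weighted convex combination of origin concentrations,
#' `Cbar_j = sum_i share[i,j] * C_i`. Destinations flagged as zero-demand in
#' the share matrix get a zero concentration.
#'
#' @param conc_origin Named numeric vector of origin concentrations
#'   (ng g^-1 ww), one per origin row of `shares`; origins without
#'   production may be `NA` provided their share is zero everywhere.
#' @param shares Share matrix from [consumption_shares()] (columns sum to 1
#'   or are flagged zero).
#' @return Numeric vector of per-destination concentrations, ng g^-1 ww.
#' @export
consumed_concentration <- function(conc_origin, shares) {
  s <- as.matrix(shares)
  if (length(conc_origin) != nrow(s))
    stop("consumed_concentration: origin set mismatch between ",
         "concentrations (", length(conc_origin), ") and shares (",
         nrow(s), " rows)", call. = FALSE)
  if (!is.null(names(conc_origin)) && !is.null(rownames(s)) &&
      !identical(names(conc_origin), rownames(s)))
    stop("consumed_concentration: origin names disagree", call. = FALSE)
  if (any(is.na(conc_origin) & rowSums(s != 0) > 0))
    stop("consumed_concentration: NA concentration for an origin with ",
         "positive share", call. = FALSE)
  c0 <- conc_origin
  c0[is.na(c0)] <- 0
  as.numeric(crossprod(s, c0))
}

#' Estimated daily intake
#'
#' `EDI = C * I / W` in ng kg^-1 day^-1, with `C` the consumed-seafood
#' concentration (ng g^-1 ww), `I` the per-capita daily consumption
#' (g day^-1) and `W` the standard adult body weight (kg, default 63).
#' Linear in both `C` and `I`.
#'
#' @param C Concentration, ng g^-1 ww.
#' @param I Daily per-capita consumption, g day^-1.
#' @param W Body weight, kg; must be positive.
#' @return EDI, ng kg^-1 day^-1.
#' @export
#' @examples
#' edi(23.7, 10, 63)  # 3.762 ng kg^-1 day^-1
edi <- function(C, I, W = 63) {
  if (any(W <= 0)) stop("edi: body weight must be positive", call. = FALSE)
  if (any(C < 0) || any(I < 0))
    stop("edi: negative concentration or intake", call. = FALSE)
  C * I / W
}

#' Provincial totals and species contributions
#'
#' Sums per-species EDIs into each province's total-seafood-consumption EDI
#' and computes each species' percentage contribution to the (optionally
#' population-weighted) national EDI. Contributions sum to 100.
#'
#' @param table Data frame with columns `province`, `species`, `edi`.
#' @param population Optional named vector of provincial populations for
#'   population weighting of the national contributions; unweighted means
#'   otherwise.
#' @return List with `province_total` (data frame `province`, `edi`) and
#'   `species_contribution` (data frame `species`, `edi`, `pct`).
#' @export
total_edi <- function(table, population = NULL) {
  stopifnot(all(c("province", "species", "edi") %in% names(table)))
  prov <- unique(table$province)
  tot <- vapply(prov, function(p) sum(table$edi[table$province == p]),
                numeric(1))
  w <- if (is.null(population)) stats::setNames(rep(1, length(prov)), prov)
       else population[prov]
  sp <- unique(table$species)
  nat <- vapply(sp, function(s) {
    sub <- table[table$species == s, ]
    sum(sub$edi * w[sub$province]) / sum(w)
  }, numeric(1))
  if (sum(nat) <= 0) stop("total_edi: zero national EDI", call. = FALSE)
  pct <- 100 * nat / sum(nat)
  list(province_total = data.frame(province = prov, edi = as.numeric(tot)),
       species_contribution = data.frame(species = sp,
                                         edi = as.numeric(nat),
                                         pct = as.numeric(pct)))
}

#' Trade / no-trade scenario differencing
#'
#' `EDI_DF = EDI_T - EDI_NT` per province, with the relative change reported
#' against the trade-scenario EDI, `EDI_DF / EDI_T * 100` (the convention
#' consistent with reporting a reduction of x% of what consumers actually
#' experience under trade).
#'
#' @param edi_t,edi_nt Named (or positionally matched) numeric vectors of
#'   per-province total EDI under the trade and no-trade scenarios.
#' @return Data frame `province`, `edi_t`, `edi_nt`, `edi_df`,
#'   `rel_change_pct` (NA where `edi_t` is 0).
#' @export
scenario_diff <- function(edi_t, edi_nt) {
  if (length(edi_t) != length(edi_nt))
    stop("scenario_diff: scenario vectors differ in length", call. = FALSE)
  if (!is.null(names(edi_t)) && !is.null(names(edi_nt))) {
    if (!setequal(names(edi_t), names(edi_nt)))
      stop("scenario_diff: provinces do not match", call. = FALSE)
    edi_nt <- edi_nt[names(edi_t)]
  }
  df <- edi_t - edi_nt
  rel <- ifelse(edi_t > 0, df / edi_t * 100, NA_real_)
  data.frame(province = if (is.null(names(edi_t)))
               seq_along(edi_t) else names(edi_t),
             edi_t = as.numeric(edi_t), edi_nt = as.numeric(edi_nt),
             edi_df = as.numeric(df), rel_change_pct = as.numeric(rel),
             stringsAsFactors = FALSE)
}

#' Origin attribution of provincial EDI
#'
#' Splits each destination's EDI over the origins of its consumed seafood:
#' `attr[i,j] = sum_s share_s[i,j] * C[i,s] * I_s[j] * coverage_s[j] / W`.
#' Columns sum exactly to the destination's total EDI.
#'
#' @param conc Origin x species concentration matrix (ng g^-1 ww); rows may
#'   cover coastal origins only, missing origins contribute zero.
#' @param shares_list Named list (by species) of origin x destination share
#'   matrices.
#' @param intake Destination x species matrix of per-capita consumption
#'   rates, g day^-1.
#' @param coverage Destination x species matrix of demand coverage (fraction
#'   of demand actually delivered, 1 under a balanced trade scenario).
#' @param W Body weight, kg.
#' @return Origin x destination matrix of attributed EDI.
#' @export
attribute_edi <- function(conc, shares_list, intake, coverage = NULL, W = 63) {
  sp <- names(shares_list)
  s1 <- shares_list[[1]]
  out <- matrix(0, nrow(s1), ncol(s1), dimnames = dimnames(s1))
  if (is.null(coverage))
    coverage <- matrix(1, ncol(s1), length(sp),
                       dimnames = list(colnames(s1), sp))
  for (s in sp) {
    cs <- numeric(nrow(s1))
    names(cs) <- rownames(s1)
    cs[rownames(conc)] <- conc[, s]
    out <- out + (shares_list[[s]] * cs) *
      rep(intake[colnames(s1), s] * coverage[colnames(s1), s] / W,
          each = nrow(s1))
  }
  out
}

#' National share of exposure embodied in trade
#'
#' Population-weighted percentage of national EDI attributable to non-local
#' origins: `100 * sum_p pop_p * sum_{i != p} attr[i,p] / sum_p pop_p *
#' EDI_p`. Zero under the no-trade counterfactual; 100 when every province
#' imports everything it eats.
#'
#' @param attribution Origin x destination attributed-EDI matrix (square,
#'   matching province order) from [attribute_edi()].
#' @param population Per-province population vector.
#' @return Percentage in [0, 100].
#' @export
trade_embodied_share <- function(attribution, population) {
  a <- as.matrix(attribution)
  if (nrow(a) != ncol(a))
    stop("trade_embodied_share: attribution matrix must be square over ",
         "provinces", call. = FALSE)
  stopifnot(length(population) == ncol(a))
  tot <- colSums(a)
  denom <- sum(population * tot)
  if (denom <= 0)
    stop("trade_embodied_share: zero national EDI, share undefined",
         call. = FALSE)
  nonlocal <- tot - diag(a)
  100 * sum(population * nonlocal) / denom
}

#' Model-evaluation metrics against measurements
#'
#' Mean bias `MB = mean(model - obs)`, normalized mean bias
#' `NMB = 100 * sum(model - obs) / sum(obs)`, the R^2 of the least-squares
#' fit of modelled on measured values, and the percentage of pairs within a
#' factor k of the measurements (inclusive bounds), for each requested k.
#'
#' @param modeled,measured Paired numeric vectors; measured values must be
#'   positive for the factor coverage, and at least 2 pairs are required for
#'   R^2.
#' @param factors Factor thresholds, default `c(2, 5)`.
#' @return List of class `eval_metrics`: `MB`, `NMB`, `R2`,
#'   `pct_within_factor` (named by factor), `n`.
#' @export
evaluate_model <- function(modeled, measured, factors = c(2, 5)) {
  if (length(modeled) != length(measured))
    stop("evaluate_model: unpaired inputs", call. = FALSE)
  if (length(modeled) < 2)
    stop("evaluate_model: need at least 2 pairs for R^2", call. = FALSE)
  if (any(measured <= 0))
    stop("evaluate_model: measured values must be positive", call. = FALSE)
  mb <- mean(modeled - measured)
  nmb <- 100 * sum(modeled - measured) / sum(measured)
  # suppressed: summary.lm warns on an essentially perfect fit
  r2 <- suppressWarnings(summary(stats::lm(modeled ~ measured))$r.squared)
  ratio <- modeled / measured
  pw <- vapply(sort(factors), function(k)
    100 * mean(ratio >= 1 / k & ratio <= k), numeric(1))
  names(pw) <- sort(factors)
  structure(list(MB = mb, NMB = nmb, R2 = r2, pct_within_factor = pw,
                 n = length(modeled)), class = "eval_metrics")
}

#' Multiplicative uncertainty interval around an EDI
#'
#' The overall uncertainty of the exposure chain (environmental fields,
#' bioaccumulation parameters, consumption rates) is summarised by a single
#' multiplicative uncertainty factor: `CI = (edi / uf, edi * uf)`. The
#' default `uf = 10` spans two orders of magnitude around the point
#' estimate, the conventional envelope for screening-level dietary exposure.
#'
#' @param edi Point estimate(s), ng kg^-1 day^-1.
#' @param uf Uncertainty factor, >= 1.
#' @return Data frame `ci_low`, `ci_high` (single row per input value).
#' @export
#' @examples
#' uncertainty_interval(16.7)  # (1.67, 167.0)
uncertainty_interval <- function(edi, uf = 10) {
  if (any(uf < 1)) stop("uncertainty_interval: uf must be >= 1", call. = FALSE)
  data.frame(ci_low = edi / uf, ci_high = edi * uf)
}

#' Margin to the no-observed-adverse-effect level
#'
#' Ratio of an EDI to the toxicological reference point for the contaminant.
#' For short-chain chlorinated paraffins the European Food Safety Authority
#' NOAEL is 10 mg kg^-1 day^-1 (1e7 ng kg^-1 day^-1); ratios far below 1
#' indicate exposure well under the benchmark.
#'
#' @param edi EDI, ng kg^-1 day^-1.
#' @param noael_mg Reference level, mg kg^-1 day^-1.
#' @return Unitless ratio `edi / noael`.
#' @export
noael_ratio <- function(edi, noael_mg = 10) {
  if (any(noael_mg <= 0)) stop("noael_ratio: NOAEL must be positive", call. = FALSE)
  edi / (noael_mg * 1e6)
}

#' Seeded lognormal Monte-Carlo uncertainty interval
#'
#' Alternative to the fixed uncertainty factor: the EDI is treated as
#' lognormal with median at the point estimate and geometric SD `gsd`; the
#' interval is the (alpha/2, 1 - alpha/2) quantile pair estimated from `n`
#' seeded draws.
#'
#' @param edi Point estimate(s).
#' @param gsd Geometric SD (> 1).
#' @param n Number of draws.
#' @param alpha Two-sided tail probability (default 0.05).
#' @param seed Integer seed.
#' @return Data frame `ci_low`, `ci_high`.
#' @export
uncertainty_interval_mc <- function(edi, gsd = 3, n = 10000L, alpha = 0.05,
                                    seed = 1L) {
  if (gsd <= 1) stop("uncertainty_interval_mc: gsd must exceed 1", call. = FALSE)
  set.seed(stage_seed(seed, "uncertainty_mc"))
  out <- t(vapply(edi, function(e) {
    draws <- e * stats::rlnorm(n, 0, log(gsd))
    stats::quantile(draws, c(alpha / 2, 1 - alpha / 2), names = FALSE)
  }, numeric(2)))
  data.frame(ci_low = out[, 1], ci_high = out[, 2])
}
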