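#' Build the multiobjective trade-routing problem for one species
#'
#' Variables are the origin-to-destination flows `T[i,j]` (kilotons yr^-1)
#' subject to `sum_j T[i,j] <= supply_i` and `sum_i T[i,j] = demand_j`.
#' Two linear objective terms are combined:
#' \itemize{
#'   \item shipping cost `sum c[i,j] T[i,j]`, with
#'     `c[i,j] = unit_cost * d_ij` (yuan, from yuan kiloton^-1 km^-1);
#'   \item population exposure `sum h[i,j] T[i,j]`, with
#'     `h[i,j] = C_i * I_j * pop_j / (demand_j * W * sum(pop))` chosen so the
#'     sum equals the population-weighted national mean EDI
#'     (ng kg^-1 day^-1) exactly, keeping the health objective linear in the
#'     flows.
#' }
#' Each term is normalised by its value at the supplied baseline (gravity)
#' flows, so at the baseline both terms equal 1 and the weights are
#' dimensionless.
#'
#' @param supply,demand Margin vectors for the species (kilotons yr^-1);
#'   total supply must cover total demand.
#' @param distance Distance matrix, km (intra rule applied internally).
#' @param conc_origin Per-origin tissue concentration, ng g^-1 ww.
#' @param intake Per-destination consumption rate of the species,
#'   g day^-1 person^-1.
#' @param population Per-destination population.
#' @param baseline Baseline flow matrix (typically [gravity_flows()]).
#' @param w_cost,w_health Non-negative scalarisation weights, not both zero.
#' @param unit_cost Transport cost, yuan kiloton^-1 km^-1.
#' @param W Body weight, kg.
#' @param params A [gravity_params()] (for the intra-distance rule only).
#' @return List of class `trade_lp`.
#' @export
build_trade_lp <- function(supply, demand, distance, conc_origin, intake,
                           population, baseline,
                           w_cost = 0.5, w_health = 0.5,
                           unit_cost = 1, W = 63,
                           params = gravity_params()) {
  supply <- as.numeric(supply); demand <- as.numeric(demand)
  if (sum(supply) < sum(demand) * (1 - 1e-12))
    stop("build_trade_lp: infeasible, total supply below total demand",
         call. = FALSE)
  if (w_cost < 0 || w_health < 0 || (w_cost == 0 && w_health == 0))
    stop("build_trade_lp: weights must be >= 0 and not both zero",
         call. = FALSE)
  if (length(conc_origin) != length(supply))
    stop("build_trade_lp: concentrations must cover every origin",
         call. = FALSE)
  if (any(!is.finite(conc_origin)) || any(conc_origin < 0))
    stop("build_trade_lp: concentrations must be finite and >= 0",
         call. = FALSE)
  d <- apply_intra_distance(distance, params)
  cost <- unit_cost * d
  hd <- ifelse(demand > 0, intake * population / (demand * W * sum(population)),
               0)
  health <- outer(conc_origin, hd)          # sum(health * T) = national mean EDI
  base <- as.matrix(baseline)
  cost0 <- sum(cost * base)
  health0 <- sum(health * base)
  if (cost0 <= 0) stop("build_trade_lp: zero baseline cost", call. = FALSE)
  obj <- w_cost * cost / cost0 +
    (if (health0 > 0) w_health * health / health0 else 0 * health)
  structure(list(supply = supply, demand = demand, cost = cost,
                 health = health, objective = obj,
                 cost0 = cost0, health0 = health0,
                 w_cost = w_cost, w_health = w_health), class = "trade_lp")
}

#' Solve the trade-routing linear program
#'
#' Minimises the scalarised objective over the transportation polytope with
#' the revised simplex method (`boot::simplex`), which is deterministic for
#' fixed inputs. The optimum never exceeds the objective of any feasible
#' starting point (in particular the gravity baseline).
#'
#' @param problem A [build_trade_lp()] object.
#' @return List of class `trade_lp_result`: `flows` (origins x
#'   destinations), `total_cost` (yuan), `national_edi` (population-weighted
#'   mean EDI, ng kg^-1 day^-1), `objective`, `status` (`"optimal"`).
#' @export
solve_trade_lp <- function(problem) {
  stopifnot(inherits(problem, "trade_lp"))
  m <- length(problem$supply); n <- length(problem$demand)
  nv <- m * n                                  # x = vec(t(T)): row-major
  A1 <- matrix(0, m, nv)
  for (i in seq_len(m)) A1[i, ((i - 1) * n + 1):(i * n)] <- 1
  A3 <- matrix(0, n, nv)
  for (j in seq_len(n)) A3[j, seq(j, nv, by = n)] <- 1
  a <- as.numeric(t(problem$objective))
  res <- boot::simplex(a = a, A1 = A1, b1 = problem$supply,
                       A3 = A3, b3 = problem$demand,
                       maxi = FALSE, n.iter = 50 * (m + n + nv))
  if (res$solved != 1)
    stop("solve_trade_lp: solver did not reach an optimum (status ",
         res$solved, ")", call. = FALSE)
  flows <- matrix(res$soln[seq_len(nv)], nrow = m, byrow = TRUE)
  dimnames(flows) <- dimnames(problem$cost)
  structure(list(flows = flows,
                 total_cost = sum(problem$cost * flows),
                 national_edi = sum(problem$health * flows),
                 objective = sum(problem$objective * flows),
                 status = "optimal"),
            class = "trade_lp_result")
}

#' Cost-health Pareto sweep
#'
#' Re-solves the routing LP across a grid of health weights (with
#' `w_cost = 1 - w_health`), tracing the weighted-sum Pareto frontier. By
#' the standard scalarisation argument the national mean EDI is
#' non-increasing and the total cost non-decreasing in `w_health`.
#'
#' @param supply,demand,distance,conc_origin,intake,population,baseline,unit_cost,W,params
#'   As in [build_trade_lp()].
#' @param w_health_grid Increasing vector of health weights in [0, 1],
#'   length >= 2.
#' @return Data frame `w_health`, `total_cost`, `national_edi`.
#' @export
pareto_sweep <- function(supply, demand, distance, conc_origin, intake,
                         population, baseline,
                         w_health_grid = seq(0, 1, by = 0.25),
                         unit_cost = 1, W = 63, params = gravity_params()) {
  if (length(w_health_grid) < 2)
    stop("pareto_sweep: need a grid of >= 2 weights", call. = FALSE)
  rows <- lapply(w_health_grid, function(w) {
    pb <- build_trade_lp(supply, demand, distance, conc_origin, intake,
                         population, baseline,
                         w_cost = 1 - w, w_health = w,
                         unit_cost = unit_cost, W = W, params = params)
    r <- solve_trade_lp(pb)
    data.frame(w_health = w, total_cost = r$total_cost,
               national_edi = r$national_edi)
  })
  do.call(rbind, rows)
}

#' Compare optimized against current flows per province
#'
#' Relative EDI difference `EDI_RD = 100 * (EDI_opt - EDI_cur) / EDI_cur`
#' and the analogous relative difference of the per-unit-trade delivery cost
#' `Cost_DF` (cost per kiloton delivered to each destination). Provinces
#' with zero current EDI (or no deliveries) are flagged `NA`.
#'
#' @param optimized,current Flow matrices (origins x destinations).
#' @param conc_origin Per-origin concentrations, ng g^-1 ww.
#' @param intake Per-destination consumption rates, g day^-1.
#' @param cost Cost matrix (yuan per kiloton on each route), e.g.
#'   `unit_cost * apply_intra_distance(distance)`.
#' @param W Body weight, kg.
#' @return Data frame `province`, `edi_current`, `edi_optimized`,
#'   `edi_rd_pct`, `cost_df_pct`.
#' @export
compare_scenarios <- function(optimized, current, conc_origin, intake, cost,
                              W = 63) {
  opt <- as.matrix(optimized); cur <- as.matrix(current)
  stopifnot(identical(dim(opt), dim(cur)))
  edi_of <- function(f) {
    sh <- consumption_shares(f)
    edi(consumed_concentration(conc_origin, sh), intake, W)
  }
  e_cur <- edi_of(cur); e_opt <- edi_of(opt)
  unit_cost_of <- function(f) {
    del <- colSums(f)
    ifelse(del > 0, colSums(cost * f) / del, NA_real_)
  }
  uc_cur <- unit_cost_of(cur); uc_opt <- unit_cost_of(opt)
  data.frame(
    province = colnames(cur) %||% seq_len(ncol(cur)),
    edi_current = e_cur, edi_optimized = e_opt,
    edi_rd_pct = ifelse(e_cur > 0, 100 * (e_opt - e_cur) / e_cur, NA_real_),
    cost_df_pct = ifelse(is.finite(uc_cur) & uc_cur > 0 & is.finite(uc_opt),
                         100 * (uc_opt - uc_cur) / uc_cur, NA_real_),
    stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
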