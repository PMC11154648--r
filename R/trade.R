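#' Distance deterrence weight
#'
#' Transfer cost enters the gravity model through a decreasing function of
#' distance: a power law `d^-beta` or an exponential `exp(-beta * d)`.
#'
#' @param d Distance(s), km, after any intra-provincial substitution.
#' @param params A [gravity_params()].
#' @return Strictly positive weights, non-increasing in `d`.
#' @export
#' @examples
#' deterrence(10, gravity_params(beta = 2))  # 0.01
deterrence <- function(d, params = gravity_params()) {
  if (any(d < 0)) stop("deterrence: negative distance", call. = FALSE)
  if (params$deterrence_form == "power") {
    if (params$beta > 0 && any(d == 0))
      stop("deterrence: d = 0 with power form; apply the intra-provincial ",
           "distance rule first", call. = FALSE)
    d ^ (-params$beta)
  } else {
    exp(-params$beta * d)
  }
}

#' Replace undefined intra-provincial distances
#'
#' Capital-to-capital distance matrices have zero entries on intra-provincial
#' routes although local trade plainly exists; each zero entry is replaced by
#' `d_intra_factor` times the distance from that origin to its nearest other
#' province. Non-zero entries are left untouched. Works for square matrices
#' and for origin-subset (rectangular) matrices alike.
#'
#' @param distance Distance matrix, km.
#' @param params A [gravity_params()].
#' @return Distance matrix with all entries positive.
#' @export
apply_intra_distance <- function(distance, params = gravity_params()) {
  d <- as.matrix(distance)
  for (i in seq_len(nrow(d))) {
    z <- d[i, ] == 0
    if (any(z)) {
      pos <- d[i, !z]
      d[i, z] <- if (length(pos)) params$d_intra_factor * min(pos) else 1
    }
  }
  d
}

ipf_scale <- function(K, row_t, col_t, tol, max_iter) {
  # alternating row/column scaling of K to the target margins
  if (any(row_t < 0) || any(col_t < 0))
    stop("ipf_scale: negative margin target", call. = FALSE)
  bad_r <- row_t > 0 & rowSums(K) <= 0
  bad_c <- col_t > 0 & colSums(K) <= 0
  if (any(bad_r) || any(bad_c))
    stop("ipf_scale: structurally infeasible margins (no positive weight ",
         "serves row(s) ", paste(which(bad_r), collapse = ","),
         " / column(s) ", paste(which(bad_c), collapse = ","), ")",
         call. = FALSE)
  M <- K
  M[row_t == 0, ] <- 0
  M[, col_t == 0] <- 0
  scale_ref <- max(row_t, col_t, 1)
  for (it in seq_len(max_iter)) {
    rs <- rowSums(M)
    rf <- ifelse(row_t > 0, row_t / pmax(rs, .Machine$double.xmin), 0)
    M <- M * rf
    cs <- colSums(M)
    cf <- ifelse(col_t > 0, col_t / pmax(cs, .Machine$double.xmin), 0)
    M <- sweep(M, 2, cf, "*")
    err <- max(abs(rowSums(M) - row_t), abs(colSums(M) - col_t)) / scale_ref
    if (err <= tol) {
      attr(M, "iterations") <- it
      attr(M, "margin_error") <- err
      return(M)
    }
  }
  stop("ipf_scale: no convergence in ", max_iter,
       " iterations; final relative margin error ", signif(err, 4),
       call. = FALSE)
}

#' Doubly-constrained gravity trade flows
#'
#' Leontief-Strout-type interregional flows: `T[i,j]` is proportional to
#' `supply_i * demand_j * f(d_ij)` with the balancing factors found by
#' iterative proportional fitting so that row sums match supply and column
#' sums match demand. When national supply exceeds national demand a virtual
#' slack destination with no distance preference absorbs the surplus (its
#' column is dropped from the returned matrix but kept in the `slack`
#' attribute, so full margins remain checkable).
#'
#' @param supply Non-negative supply vector, kilotons yr^-1 (zero for inland
#'   provinces).
#' @param demand Non-negative demand vector, kilotons yr^-1.
#' @param distance Square distance matrix, km (zero diagonal allowed; the
#'   intra-provincial rule is applied).
#' @param params A [gravity_params()].
#' @return Flow matrix `T` (origins x destinations, kilotons yr^-1) with
#'   attributes `slack` (per-origin surplus flow, zero when balanced),
#'   `iterations` and `margin_error`.
#' @export
gravity_flows <- function(supply, demand, distance, params = gravity_params()) {
  supply <- as.numeric(supply); demand <- as.numeric(demand)
  if (any(supply < 0) || any(demand < 0))
    stop("gravity_flows: negative supply or demand", call. = FALSE)
  tot_s <- sum(supply); tot_d <- sum(demand)
  if (tot_s < tot_d * (1 - 1e-12))
    stop("gravity_flows: total supply (", signif(tot_s, 6),
         ") below total demand (", signif(tot_d, 6), ")", call. = FALSE)
  d <- apply_intra_distance(distance, params)
  if (nrow(d) != length(supply) || ncol(d) != length(demand))
    stop("gravity_flows: distance matrix does not match supply/demand",
         call. = FALSE)
  f <- deterrence(d, params)
  K <- outer(supply, demand) * f
  surplus <- tot_s - tot_d
  has_slack <- surplus > 1e-12 * max(tot_s, 1)
  if (has_slack) {
    K <- cbind(K, supply)              # slack: no deterrence preference
    col_t <- c(demand, surplus)
  } else col_t <- demand
  M <- ipf_scale(K, supply, col_t, params$ipf_tol, params$ipf_max_iter)
  nI <- length(demand)
  flows <- M[, seq_len(nI), drop = FALSE]
  dimnames(flows) <- dimnames(as.matrix(distance))
  attr(flows, "slack") <- if (has_slack) M[, nI + 1L] else numeric(length(supply))
  attr(flows, "iterations") <- attr(M, "iterations")
  attr(flows, "margin_error") <- attr(M, "margin_error")
  flows
}

#' Estimate the deterrence exponent from observed flows
#'
#' Calibrates `beta` by one-dimensional bounded minimisation of the sum of
#' squared log differences between modelled and observed flows over the
#' strictly positive observed entries.
#'
#' @param observed Observed flow matrix.
#' @param supply,demand Margin vectors.
#' @param distance Distance matrix, km.
#' @param params A [gravity_params()] fixing the deterrence form and IPF
#'   settings.
#' @param beta_max Upper search bound.
#' @return List with `beta_hat` and the final `objective`.
#' @export
estimate_beta <- function(observed, supply, demand, distance,
                          params = gravity_params(), beta_max = 10) {
  obs <- as.matrix(observed)
  pos <- is.finite(obs) & obs > 0
  d <- apply_intra_distance(distance, params)
  dd <- unique(signif(d[pos], 12))
  if (sum(pos) < 3 || length(dd) < 3)
    stop("estimate_beta: need positive flows on >= 3 distinct distances ",
         "(deterrence exponent unidentifiable)", call. = FALSE)
  obj <- function(b) {
    p <- params; p$beta <- b
    m <- gravity_flows(supply, demand, distance, p)
    sum((log(m[pos]) - log(obs[pos]))^2)
  }
  o <- stats::optimize(obj, c(0, beta_max), tol = 1e-9)
  list(beta_hat = o$minimum, objective = o$objective)
}

#' Origin shares of each destination's consumption
#'
#' Normalises each destination column of a flow matrix to sum to 1. A
#' zero-total destination gets a zero column and is flagged in the
#' `zero_destinations` attribute.
#'
#' @param flows Flow matrix (origins x destinations).
#' @return Share matrix with columns summing to 1 (or flagged zero).
#' @export
consumption_shares <- function(flows) {
  f <- as.matrix(flows)
  tot <- colSums(f)
  s <- sweep(f, 2, ifelse(tot > 0, tot, 1), "/")
  attr(s, "zero_destinations") <- which(tot <= 0)
  s
}

#' No-trade counterfactual flows
#'
#' With interprovincial trade absent, every province consumes only its own
#' production: a diagonal flow matrix with `T[i,i] = min(supply_i,
#' demand_i)`. Inland provinces (zero supply) receive no seafood at all.
#'
#' @param supply,demand Margin vectors.
#' @return Diagonal flow matrix.
#' @export
no_trade_flows <- function(supply, demand) {
  stopifnot(length(supply) == length(demand))
  if (any(supply < 0) || any(demand < 0))
    stop("no_trade_flows: negative supply or demand", call. = FALSE)
  m <- diag(pmin(supply, demand), nrow = length(supply))
  dimnames(m) <- list(names(supply), names(supply))
  m
}
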