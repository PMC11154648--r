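# Independent reference implementations used as oracles. These deliberately
# use different formulations/algorithms from the package code paths.

# Doubly-constrained gravity via explicit balancing factors a_i, b_j
# (Leontief-Strout textbook form), not matrix margin scaling.
ref_gravity_balancing <- function(supply, demand, weight, tol = 1e-12,
                                  max_iter = 100000) {
  m <- length(supply); n <- length(demand)
  a <- rep(1, m); b <- rep(1, n)
  for (it in seq_len(max_iter)) {
    a_new <- vapply(seq_len(m), function(i) {
      den <- sum(b * demand * weight[i, ])
      if (den > 0) 1 / den else 0
    }, numeric(1))
    b_new <- vapply(seq_len(n), function(j) {
      den <- sum(a_new * supply * weight[, j])
      if (den > 0) 1 / den else 0
    }, numeric(1))
    flows <- outer(a_new * supply, b_new * demand) * weight
    err <- max(abs(rowSums(flows) - supply), abs(colSums(flows) - demand))
    a <- a_new; b <- b_new
    if (err < tol) return(flows)
  }
  stop("ref_gravity_balancing did not converge")
}

# Fixed-point iteration solver for the steady-state food web, independent of
# the direct linear solve.
ref_foodweb_fixed_point <- function(web, cell, chem, tol = 1e-14,
                                    max_iter = 100000) {
  par <- web$params
  k <- rate_constants(par, chem)
  ktot <- k$k2 + k$kE + par$k_G + par$k_M
  c_phy <- phytoplankton_concentration(cell$c_water, chem, chem$lipid_phyto)
  c_zoo <- phytoplankton_concentration(cell$c_water, chem, chem$lipid_zoo)
  c_pw <- porewater_concentration(cell$c_sediment, cell$f_oc, chem)
  b <- 1e-3 * k$k1 * ((1 - par$phi_sed) * cell$c_water + par$phi_sed * c_pw) +
    k$kD * (web$base[, "diet_phyto"] * c_phy +
            web$base[, "diet_zoo"] * c_zoo +
            web$base[, "diet_sed"] * cell$c_sediment)
  x <- rep(0, nrow(par))
  for (it in seq_len(max_iter)) {
    x_new <- as.numeric((b + k$kD * as.numeric(web$P %*% x)) / ktot)
    if (max(abs(x_new - x)) <= tol * max(1, max(abs(x_new)))) return(x_new)
    x <- x_new
  }
  stop("ref_foodweb_fixed_point did not converge")
}

# Exact LP oracle by brute-force vertex enumeration for the balanced
# transportation problem min sum(C*T), rowSums(T)=supply, colSums(T)=demand.
ref_transport_enum <- function(cost, supply, demand) {
  m <- length(supply); n <- length(demand)
  stopifnot(abs(sum(supply) - sum(demand)) < 1e-9)
  nv <- m * n
  A <- matrix(0, m + n, nv)
  for (i in seq_len(m)) A[i, ((i - 1) * n + 1):(i * n)] <- 1
  for (j in seq_len(n)) A[m + j, seq(j, nv, by = n)] <- 1
  bvec <- c(supply, demand)
  cvec <- as.numeric(t(cost))
  r <- m + n - 1                      # rank of the constraint system
  best <- Inf
  for (basis in utils::combn(nv, r, simplify = FALSE)) {
    B <- A[, basis, drop = FALSE]
    qrB <- qr(B)
    if (qrB$rank < r) next
    xB <- qr.coef(qrB, bvec)
    if (anyNA(xB)) next
    if (max(abs(B %*% xB - bvec)) > 1e-8) next   # inconsistent
    if (any(xB < -1e-9)) next
    val <- sum(cvec[basis] * xB)
    if (val < best) best <- val
  }
  best
}

# Transportation LP solved by scipy's HiGHS solver through the system python;
# used as an independent cross-check at sizes where enumeration is
# impractical.
ref_transport_scipy <- function(cost, supply, demand) {
  inp <- tempfile(fileext = ".json"); outp <- tempfile(fileext = ".json")
  on.exit(unlink(c(inp, outp)))
  jsonlite::write_json(list(cost = cost, supply = supply, demand = demand),
                       inp, digits = NA, matrix = "rowmajor")
  script <- paste(
    "import json, sys",
    "import numpy as np",
    "from scipy.optimize import linprog",
    sprintf("d = json.load(open(%s))", deparse(inp)),
    "C = np.array(d['cost']); s = np.array(d['supply']); t = np.array(d['demand'])",
    "m, n = C.shape",
    "Aeq = []; beq = []",
    "for i in range(m):",
    "    row = np.zeros(m*n); row[i*n:(i+1)*n] = 1; Aeq.append(row); beq.append(s[i])",
    "for j in range(n):",
    "    row = np.zeros(m*n); row[j::n] = 1; Aeq.append(row); beq.append(t[j])",
    "r = linprog(C.ravel(), A_eq=np.array(Aeq), b_eq=np.array(beq),",
    "            bounds=(0, None), method='highs')",
    sprintf("json.dump({'fun': r.fun, 'status': int(r.status)}, open(%s, 'w'))",
            deparse(outp)),
    sep = "\n")
  res <- system2("python", c("-c", shQuote(script)), stdout = TRUE,
                 stderr = TRUE)
  if (!file.exists(outp))
    stop("scipy oracle failed: ", paste(res, collapse = "\n"))
  out <- jsonlite::fromJSON(outp)
  stopifnot(out$status == 0)
  out$fun
}

# Small default worlds for tests.
small_config <- function(seed = 1, n = 8, ncst = 3, cells = 3) {
  world_config(n_provinces = n, n_coastal = ncst,
               grid_cells_per_region = cells, seed = seed)
}

small_run_config <- function(seed = 1, n = 8, ncst = 3, cells = 3,
                             pareto = FALSE) {
  cfg <- default_run_config(seed = seed)
  cfg$world$n_provinces <- n
  cfg$world$n_coastal <- ncst
  cfg$world$grid_cells_per_region <- cells
  cfg$optimizer$run_pareto <- pareto
  cfg
}

# Random balanced LP routing inputs with a feasible interior baseline.
lp_inputs <- function(m, n, seed) {
  set.seed(seed)
  d <- matrix(runif(m * n, 10, 1000), m, n)
  supply <- runif(m, 1, 5)
  demand <- runif(n, 0.2, 2)
  demand <- demand / sum(demand) * sum(supply)   # balanced
  conc <- rexp(m, 0.2)
  intake <- runif(n, 5, 40)
  pop <- runif(n, 1e6, 5e7)
  baseline <- outer(supply, demand) / sum(demand)  # feasible interior point
  list(supply = supply, demand = demand, distance = d, conc = conc,
       intake = intake, pop = pop, baseline = baseline)
}

random_margins <- function(m, n, seed) {
  set.seed(seed)
  supply <- c(runif(max(1, m %/% 2), 1, 10), rep(0, m - max(1, m %/% 2)))
  supply <- sample(supply)
  demand <- runif(n, 0.1, 5)
  demand <- demand / sum(demand) * sum(supply) * runif(1, 0.5, 1)
  dist <- as.matrix(stats::dist(cbind(runif(max(m, n), 0, 100),
                                      runif(max(m, n), 0, 100))))
  list(supply = supply, demand = demand,
       distance = dist[seq_len(m), seq_len(n), drop = FALSE])
}
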