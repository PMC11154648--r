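test_that("baseline normalisation makes both objective terms equal 1", {
  x <- lp_inputs(3, 4, seed = 1)
  for (w in list(c(1, 0), c(0, 1))) {
    pb <- build_trade_lp(x$supply, x$demand, x$distance, x$conc, x$intake,
                         x$pop, x$baseline, w_cost = w[1], w_health = w[2])
    expect_equal(sum(pb$objective * x$baseline), 1, tolerance = 1e-12)
  }
  expect_error(build_trade_lp(x$supply, x$demand * 10, x$distance, x$conc,
                              x$intake, x$pop, x$baseline), "infeasible")
  expect_error(build_trade_lp(x$supply, x$demand, x$distance, x$conc,
                              x$intake, x$pop, x$baseline,
                              w_cost = 0, w_health = 0), "weights")
})

test_that("the health term equals the population-weighted national mean EDI", {
  x <- lp_inputs(3, 3, seed = 2)
  pb <- build_trade_lp(x$supply, x$demand, x$distance, x$conc, x$intake,
                       x$pop, x$baseline)
  f <- x$baseline
  sh <- consumption_shares(f)
  e <- edi(consumed_concentration(x$conc, sh), x$intake, 63)
  expect_equal(sum(pb$health * f), sum(x$pop * e) / sum(x$pop),
               tolerance = 1e-12)
})

test_that("trivial and 2x2 routings solve to the known optimum", {
  # one origin, one destination
  x1 <- lp_inputs(1, 1, seed = 3)
  pb1 <- build_trade_lp(x1$supply, x1$demand, x1$distance, x1$conc,
                        x1$intake, x1$pop, x1$baseline)
  r1 <- solve_trade_lp(pb1)
  expect_equal(as.numeric(r1$flows), x1$demand, tolerance = 1e-9)

  # cheap diagonal with pure cost objective: all flow on the diagonal
  d <- matrix(c(1, 2, 2, 1), 2, 2, byrow = TRUE)
  base <- matrix(0.5, 2, 2)
  pb2 <- build_trade_lp(c(1, 1), c(1, 1), d, c(1, 1), c(10, 10),
                        c(1e6, 1e6), base, w_cost = 1, w_health = 0)
  r2 <- solve_trade_lp(pb2)
  expect_equal(unclass(r2$flows), diag(2), tolerance = 1e-9)
  enum <- ref_transport_enum(pb2$objective, c(1, 1), c(1, 1))
  expect_equal(r2$objective, enum, tolerance = 1e-9)
  # optimal objective never exceeds the baseline's
  expect_lte(r2$objective, sum(pb2$objective * base) + 1e-12)
})

test_that("the cost/health crossover weight matches hand algebra", {
  # two origins, one destination: origin 1 cheap but contaminated,
  # origin 2 expensive but clean
  d <- matrix(c(10, 100), 2, 1)
  conc <- c(8, 1)
  supply <- c(1, 1); demand <- 1
  base <- matrix(c(0.5, 0.5), 2, 1)
  intake <- 20; pop <- 1e6
  cost0 <- 0.5 * 10 + 0.5 * 100
  h <- conc * intake / (demand * 63)          # per-unit health coefficient
  health0 <- sum(base * h)
  # route objectives equal when (1-w)(c1-c2)/cost0 + w(h1-h2)/health0 = 0
  w_star <- ((100 - 10) / cost0) /
    ((100 - 10) / cost0 + (h[1] - h[2]) / health0)
  for (w in c(w_star - 0.1, w_star + 0.1)) {
    pb <- build_trade_lp(supply, demand, d, conc, intake, pop, base,
                         w_cost = 1 - w, w_health = w)
    r <- solve_trade_lp(pb)
    if (w < w_star) expect_equal(as.numeric(r$flows), c(1, 0),
                                 tolerance = 1e-9)
    else expect_equal(as.numeric(r$flows), c(0, 1), tolerance = 1e-9)
  }
})

test_that("solver matches brute-force vertex enumeration on small instances", {
  for (seed in 1:8) {
    set.seed(seed)
    m <- sample(2:4, 1); n <- sample(2:4, 1)
    x <- lp_inputs(m, n, seed = 400 + seed)
    w <- runif(1)
    pb <- build_trade_lp(x$supply, x$demand, x$distance, x$conc, x$intake,
                         x$pop, x$baseline, w_cost = 1 - w, w_health = w)
    r <- solve_trade_lp(pb)
    enum <- ref_transport_enum(pb$objective, x$supply, x$demand)
    expect_equal(r$objective, enum, tolerance = 1e-9)
    # feasibility at solver tolerance
    expect_equal(colSums(r$flows), x$demand, tolerance = 1e-9)
    expect_true(all(rowSums(r$flows) <= x$supply + 1e-9))
    expect_true(all(r$flows >= -1e-12))
  }
})

test_that("Pareto sweep is monotone and hits the pure endpoints", {
  x <- lp_inputs(4, 5, seed = 9)
  grid <- c(0, 0.3, 0.6, 1)
  ps <- pareto_sweep(x$supply, x$demand, x$distance, x$conc, x$intake,
                     x$pop, x$baseline, w_health_grid = grid)
  expect_true(all(diff(ps$national_edi) <= 1e-9))
  expect_true(all(diff(ps$total_cost) >= -1e-9))
  # endpoints agree with the dedicated pure-cost / pure-health solves
  pure_cost <- solve_trade_lp(build_trade_lp(x$supply, x$demand, x$distance,
                                             x$conc, x$intake, x$pop,
                                             x$baseline, w_cost = 1,
                                             w_health = 0))
  pure_health <- solve_trade_lp(build_trade_lp(x$supply, x$demand, x$distance,
                                               x$conc, x$intake, x$pop,
                                               x$baseline, w_cost = 0,
                                               w_health = 1))
  expect_equal(ps$total_cost[1], pure_cost$total_cost, tolerance = 1e-9)
  expect_equal(ps$national_edi[nrow(ps)], pure_health$national_edi,
               tolerance = 1e-9)
  expect_error(pareto_sweep(x$supply, x$demand, x$distance, x$conc,
                            x$intake, x$pop, x$baseline,
                            w_health_grid = 0.5), "grid")
})

test_that("scenario comparison reports relative differences per province", {
  x <- lp_inputs(2, 2, seed = 12)
  cur <- x$baseline
  cmp0 <- compare_scenarios(cur, cur, x$conc, x$intake,
                            x$distance)
  expect_equal(cmp0$edi_rd_pct, c(0, 0))
  expect_equal(cmp0$cost_df_pct, c(0, 0))
  # halving the consumed concentration at one destination -> -50%
  conc <- c(2, 2)
  cur2 <- matrix(c(1, 0, 0, 1), 2, 2)
  opt2 <- cur2
  conc_opt <- c(1, 2)
  e_cur <- edi(consumed_concentration(conc, consumption_shares(cur2)),
               x$intake, 63)
  cmp <- compare_scenarios(opt2, cur2, conc, x$intake, x$distance)
  expect_equal(cmp$edi_rd_pct, c(0, 0))
  cmp2 <- compare_scenarios(matrix(c(0, 1, 0, 1), 2, 2), cur2,
                            c(1, 2), x$intake, matrix(1, 2, 2))
  # destination 1 now eats origin-2 seafood at twice the concentration
  expect_equal(cmp2$edi_rd_pct[1], 100)
})
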