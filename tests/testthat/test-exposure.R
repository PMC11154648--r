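test_that("consumed concentration is the share-weighted convex combination", {
  # all-local shares: destination sees its own concentration
  s_local <- diag(2)
  expect_equal(consumed_concentration(c(4, 9), s_local), c(4, 9))
  # 50/50 split of origins at 10 and 20 -> 15
  s_half <- matrix(0.5, 2, 2)
  expect_equal(consumed_concentration(c(10, 20), s_half), c(15, 15))
  # convexity bound on random instances
  set.seed(7)
  for (rep in 1:20) {
    m <- sample(2:6, 1); n <- sample(2:6, 1)
    f <- matrix(rexp(m * n), m, n)
    s <- consumption_shares(f)
    cc <- rexp(m, 0.2)
    out <- consumed_concentration(cc, s)
    expect_true(all(out >= min(cc) - 1e-12 & out <= max(cc) + 1e-12))
  }
  expect_error(consumed_concentration(c(1, 2, 3), diag(2)), "mismatch")
})

test_that("EDI arithmetic follows C * I / W", {
  expect_equal(edi(0, 10), 0)
  expect_equal(edi(23.7, 10, 63), 23.7 * 10 / 63)  # 3.7619...
  expect_equal(edi(23.7, 20, 63), 2 * edi(23.7, 10, 63))
  expect_error(edi(1, 1, 0), "body weight")
  expect_error(edi(-1, 1), "negative")
})

test_that("provincial totals and species contributions normalise to 100%", {
  tab1 <- data.frame(province = "A", species = "clam", edi = 2.5)
  t1 <- total_edi(tab1)
  expect_equal(t1$species_contribution$pct, 100)
  # two species, two provinces, population weighting
  tab2 <- data.frame(province = rep(c("A", "B"), each = 2),
                     species = rep(c("x", "y"), 2),
                     edi = c(3, 1, 1, 1))
  pop <- c(A = 3e6, B = 1e6)
  t2 <- total_edi(tab2, pop)
  expect_equal(t2$province_total$edi, c(4, 2))
  nat_x <- (3 * 3e6 + 1 * 1e6) / 4e6
  nat_y <- 1
  expect_equal(t2$species_contribution$pct,
               100 * c(nat_x, nat_y) / (nat_x + nat_y))
  expect_equal(sum(t2$species_contribution$pct), 100, tolerance = 1e-9)
})

test_that("scenario differencing subtracts no-trade from trade", {
  same <- c(A = 2, B = 5)
  d0 <- scenario_diff(same, same)
  expect_equal(d0$edi_df, c(0, 0))
  expect_equal(d0$rel_change_pct, c(0, 0))
  d <- scenario_diff(c(A = 10, B = 0), c(A = 4, B = 1))
  expect_equal(d$edi_df, c(6, -1))
  expect_equal(d$rel_change_pct, c(60, NA))
  expect_error(scenario_diff(c(A = 1), c(B = 1)), "match")
})

test_that("trade-embodied share covers the no-trade and all-import extremes", {
  pop <- c(2e6, 8e6)
  # purely local attribution -> 0%
  expect_equal(trade_embodied_share(diag(c(1, 3)), pop), 0)
  # everything imported -> 100%
  a_imp <- matrix(c(0, 2, 3, 0), 2, 2)
  expect_equal(trade_embodied_share(a_imp, pop), 100)
  # two-province hand case: attr[i,j], column j eaten in province j
  a <- matrix(c(1, 0.5, 2, 1), 2, 2)   # col1 = (1, 0.5), col2 = (2, 1)
  hand <- 100 * (2e6 * 0.5 + 8e6 * 2) / (2e6 * 1.5 + 8e6 * 3)
  expect_equal(trade_embodied_share(a, pop), hand)
  expect_error(trade_embodied_share(matrix(0, 2, 2), pop), "undefined")
})

test_that("origin attribution conserves the total EDI", {
  set.seed(11)
  m <- 4; sp <- c("a", "b")
  conc <- matrix(rexp(m * 2, 0.1), m, 2,
                 dimnames = list(paste0("P", 1:m), sp))
  shares <- lapply(sp, function(s)
    consumption_shares(matrix(rexp(m * m), m, m,
                              dimnames = list(paste0("P", 1:m),
                                              paste0("P", 1:m)))))
  names(shares) <- sp
  intake <- matrix(runif(m * 2, 5, 30), m, 2,
                   dimnames = list(paste0("P", 1:m), sp))
  at <- attribute_edi(conc, shares, intake, W = 63)
  direct <- rowSums(vapply(sp, function(s)
    edi(consumed_concentration(conc[, s], shares[[s]]), intake[, s], 63),
    numeric(m)))
  expect_equal(colSums(at), direct, tolerance = 1e-12)
})

test_that("evaluation metrics match hand-computed values", {
  perfect <- evaluate_model(c(1, 2, 3), c(1, 2, 3))
  expect_equal(perfect$MB, 0)
  expect_equal(perfect$NMB, 0)
  expect_equal(perfect$R2, 1)
  expect_equal(unname(perfect$pct_within_factor), c(100, 100))

  # exact factor-2 overprediction sits inside the inclusive bound
  double <- evaluate_model(c(2, 4), c(1, 2))
  expect_equal(double$NMB, 100)
  expect_equal(unname(double$pct_within_factor[["2"]]), 100)

  # three-pair hand computation
  mod <- c(2, 4, 9); obs <- c(1, 5, 10)
  met <- evaluate_model(mod, obs)
  expect_equal(met$MB, mean(c(1, -1, -1)))
  expect_equal(met$NMB, 100 * (15 - 16) / 16)
  expect_equal(met$R2, stats::cor(mod, obs)^2)
  expect_equal(unname(met$pct_within_factor), c(100, 100))
  met5 <- evaluate_model(c(0.1, 1), c(1, 1))
  expect_equal(unname(met5$pct_within_factor), c(50, 50))

  expect_error(evaluate_model(1, 1), "2 pairs")
  expect_error(evaluate_model(c(1, 2), c(0, 1)), "positive")
})

test_that("the NOAEL margin is a plain unit-converted ratio", {
  expect_equal(noael_ratio(1e7, 10), 1)
  expect_equal(noael_ratio(5.8), 5.8e-7)
  expect_error(noael_ratio(1, 0), "positive")
})

test_that("uncertainty intervals are multiplicative and symmetric", {
  ci <- uncertainty_interval(16.7, 10)
  expect_equal(ci$ci_low, 1.67)
  expect_equal(ci$ci_high, 167.0)
  # degenerate factor
  ci1 <- uncertainty_interval(5, 1)
  expect_equal(ci1$ci_low, 5)
  expect_equal(ci1$ci_high, 5)
  # multiplicative symmetry: high/point == point/low
  ci2 <- uncertainty_interval(3.3, 7)
  expect_equal(ci2$ci_high / 3.3, 3.3 / ci2$ci_low)
  expect_error(uncertainty_interval(1, 0.5), "uf")
  # Monte-Carlo variant is seeded and ordered
  mc <- uncertainty_interval_mc(c(2, 4), gsd = 3, n = 2000, seed = 5)
  expect_identical(mc, uncertainty_interval_mc(c(2, 4), gsd = 3, n = 2000,
                                               seed = 5))
  expect_true(all(mc$ci_low < c(2, 4) & mc$ci_high > c(2, 4)))
})
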