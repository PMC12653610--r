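test_that("ANOVA handles identical groups and matches a frozen F value", {
  same <- one_way_anova(list(a = c(1, 2, 3), b = c(3, 2, 1)))
  expect_equal(same$f_statistic, 0)
  expect_equal(same$p_value, 1)
  # frozen oracle: F({1,2,3} vs {4,5,6}) = 13.5 from raw sums of squares
  res <- one_way_anova(list(g1 = c(1, 2, 3), g2 = c(4, 5, 6)))
  expect_equal(res$f_statistic, 13.5, tolerance = 1e-9)
  expect_equal(res$df_between, 1)
  expect_equal(res$df_within, 4)
  # degenerate: zero within-group variance, distinct means
  degen <- one_way_anova(list(a = c(5, 5), b = c(7, 7)))
  expect_identical(degen$f_statistic, Inf)
  expect_identical(degen$p_value, 0)
  expect_error(one_way_anova(list(a = 1:3)))
})

test_that("ANOVA agrees with the brute-force sums-of-squares oracle", {
  set.seed(23)
  for (i in 1:20) {
    k <- sample(2:5, 1)
    groups <- lapply(1:k, function(j) rnorm(sample(3:12, 1), mean = rnorm(1)))
    names(groups) <- paste0("g", 1:k)
    fast <- one_way_anova(groups)
    slow <- anova_brute(groups)
    expect_equal(fast$f_statistic, slow$f, tolerance = 1e-9)
    expect_equal(fast$p_value, slow$p, tolerance = 1e-9)
  }
})

test_that("ANOVA holds its nominal size under the null", {
  set.seed(29)
  p <- replicate(100, {
    one_way_anova(list(a = rnorm(10), b = rnorm(10), c = rnorm(10)))$p_value
  })
  expect_gte(mean(p > 0.05), 0.90)
})

test_that("Tukey HSD separates the five grade YI populations", {
  set.seed(31)
  groups <- lapply(rubber_grades(), function(g) {
    sample_color_vectors(g, 30, seed = 300 + match(g, rubber_grades()))$yi
  })
  names(groups) <- rubber_grades()
  tk <- tukey_hsd(groups)
  expect_equal(nrow(tk), choose(5, 2))
  expect_true(all(c("pair", "diff", "lwr", "upr", "p_adj", "significant")
                  %in% names(tk)))
  # all pairs except STR5 vs STR5L (means 62.8 vs 64.3, SD ~6) separate
  close_pair <- grepl("STR5L", tk$pair) & grepl("STR5-|-STR5$", tk$pair)
  expect_true(all(tk$significant[!close_pair]))
  expect_error(tukey_hsd(list(a = 1:3)), "at least 2")
})

test_that("Tukey HSD on two groups agrees with the pooled t-test", {
  set.seed(37)
  a <- rnorm(12, 10); b <- rnorm(12, 11)
  tk <- tukey_hsd(list(a = a, b = b))
  tt <- t.test(b, a, var.equal = TRUE)
  expect_equal(tk$diff, unname(diff(c(mean(a), mean(b)))), tolerance = 1e-9)
  expect_equal(tk$p_adj, tt$p.value, tolerance = 1e-9)
  # ptukey is evaluated to ~1e-7; looser than the exact t quantile
  expect_equal(tk$lwr, tt$conf.int[1], tolerance = 1e-6)
  expect_equal(tk$upr, tt$conf.int[2], tolerance = 1e-6)
})

test_that("precision metrics recover planted variance components", {
  # balanced design: 8 sessions x 20 replicates, sigma_r = 2, sigma_L = 3
  set.seed(41)
  n_sess <- 8; n_rep <- 200
  sess_eff <- rnorm(n_sess, 0, 3)
  values <- unlist(lapply(1:n_sess, function(s) 100 + sess_eff[s] +
                            rnorm(n_rep, 0, 2)))
  session <- rep(1:n_sess, each = n_rep)
  pm <- precision_metrics(values, session)
  expect_equal(pm$repeatability_sd, 2, tolerance = 0.15)
  expect_equal(pm$between_session_sd, 3, tolerance = 0.15 * 3 + 1.5)
  expect_equal(pm$reproducibility_sd,
               sqrt(pm$repeatability_sd^2 + pm$between_session_sd^2),
               tolerance = 1e-9)
  expect_gte(pm$reproducibility_sd, pm$repeatability_sd)
  expect_lt(pm$repeatability_cv, 0.1)
})

test_that("precision metrics flag single-session data", {
  pm <- precision_metrics(c(10, 11, 9, 10.5), rep("s1", 4))
  expect_true(pm$single_session)
  expect_true(is.na(pm$reproducibility_cv))
  expect_equal(pm$repeatability_sd, sd(c(10, 11, 9, 10.5)))
  expect_error(precision_metrics(c(1, 2, 3), c("a", "a", "b")),
               "at least 2 replicates")
})

test_that("uncertainty propagation is exact at zero SD and scales linearly", {
  rgb <- ref_rgb("STR5")
  zero <- propagate_uncertainty(rgb, c(0, 0, 0))
  expect_identical(zero$u_yi, 0)
  expect_equal(zero$yi_mean, 62.84, tolerance = 0.1)
  u1 <- propagate_uncertainty(rgb, c(1, 1, 1), n_mc = 2e5, seed = 5)
  u2 <- propagate_uncertainty(rgb, c(2, 2, 2), n_mc = 2e5, seed = 5)
  # YI is nearly linear over a few counts: doubling SD ~ doubles u
  expect_equal(u2$u_yi / u1$u_yi, 2, tolerance = 0.05)
  # identical seeds reproduce bit-identically
  expect_identical(u1, propagate_uncertainty(rgb, c(1, 1, 1), n_mc = 2e5,
                                             seed = 5))
  # convergence: two large independent runs agree to ~2%
  a <- propagate_uncertainty(rgb, c(2, 3, 2), n_mc = 2e5, seed = 11)$u_yi
  b <- propagate_uncertainty(rgb, c(2, 3, 2), n_mc = 2e5, seed = 13)$u_yi
  expect_equal(a, b, tolerance = 0.02)
})

test_that("propagated YI uncertainty matches the analytic delta method", {
  # for small SDs the MC SD should match the first-order Jacobian estimate
  rgb <- ref_rgb("RSS3"); sds <- c(0.5, 0.5, 0.5)
  yi_of <- function(v) yellowness_index(
    rgb_to_xyz(v, color_transform_config(output_scale = 1),
               path = "raw_linear"))
  grad <- vapply(1:3, function(i) {
    h <- 1e-4; e <- c(0, 0, 0); e[i] <- h
    (yi_of(rgb + e) - yi_of(rgb - e)) / (2 * h)
  }, numeric(1))
  analytic <- sqrt(sum((grad * sds)^2))
  mc <- propagate_uncertainty(rgb, sds, n_mc = 2e5, seed = 17)$u_yi
  expect_equal(mc, analytic, tolerance = 0.03)
})

test_that("calibration report counts passes against the CIE76 tolerance", {
  ref <- matrix(c(50, 0, 0,  60, 5, 10,  30, -2, 4), ncol = 3, byrow = TRUE)
  exact <- calibration_report(ref, ref)
  expect_equal(exact$mean_de, 0)
  expect_equal(exact$pass_fraction, 1)
  shifted <- ref; shifted[2, ] <- shifted[2, ] + c(3, 0, 0)   # dE = 3 > 2
  rep2 <- calibration_report(shifted, ref)
  expect_equal(rep2$pass_fraction, 2 / 3)
  expect_equal(rep2$max_de, 3)
  expect_false(rep2$table$pass[2])
  expect_error(calibration_report(ref[1:2, ], ref), "differ in length")
})

test_that("calibration report distinguishes quiet and noisy measurement regimes", {
  set.seed(43)
  ref <- cbind(runif(24, 20, 80), runif(24, -20, 20), runif(24, -20, 40))
  quiet <- ref + matrix(rnorm(72, 0, 0.3), ncol = 3)
  noisy <- ref + matrix(rnorm(72, 0, 3), ncol = 3)
  expect_gt(calibration_report(quiet, ref)$pass_fraction, 0.9)
  expect_lt(calibration_report(noisy, ref)$pass_fraction, 0.5)
})
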