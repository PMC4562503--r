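make_records <- function(on, off, subject = 1, size_px = 100) {
  data.frame(subject = subject, experiment = 1,
             trial = seq_len(length(on) + length(off)),
             task = rep(c("onset", "offset"), c(length(on), length(off))),
             size_px = size_px, delta_t_ms = c(on, off),
             n_reps = 2L, converged = TRUE, stringsAsFactors = FALSE)
}

test_that("synchrony estimates implement VP = D - E with repetition SDs", {
  rec <- make_records(rep(30, 5), rep(530, 5))
  est <- synchrony_estimates(rec, condition_cols = "size_px")
  expect_equal(est$E, 30)
  expect_equal(est$D_off, 530)
  expect_equal(est$VP, 500)
  expect_equal(est$sd_on, 0)
  expect_equal(est$sd_off, 0)
  expect_equal(est$n_on, 5L)

  # VP always equals D_off - E on a heterogeneous table
  rec2 <- rbind(make_records(stats::rnorm(5, 20, 40),
                             stats::rnorm(5, 500, 80)),
                make_records(stats::rnorm(5, -10, 40),
                             stats::rnorm(5, 700, 80), subject = 2,
                             size_px = 200))
  est2 <- synchrony_estimates(rec2, condition_cols = "size_px")
  expect_equal(est2$VP, est2$D_off - est2$E)

  # a cell lacking one task is excluded with a message
  rec3 <- rbind(make_records(rep(30, 3), numeric(0)),
                make_records(rep(10, 3), rep(400, 3), subject = 2))
  expect_message(est3 <- synchrony_estimates(rec3,
                                             condition_cols = "size_px"),
                 "lack one task")
  expect_equal(nrow(est3), 1L)
  expect_equal(est3$subject, 2)
})

test_that("grand means agree across marginalisations of a balanced table", {
  profs <- exp1_profiles(n = 3, seed = 7)
  rec <- simulate_experiment(1, profs, reps = 4, seed = 17)
  est <- synchrony_estimates(rec)
  grand_by_size <- mean(tapply(est$VP, est$size_px, mean))
  grand_by_thick <- mean(tapply(est$VP, est$thickness_px, mean))
  expect_equal(grand_by_size, grand_by_thick, tolerance = 1e-10)
})

test_that("drift screening flags monotone offset drifters only", {
  up <- make_records(numeric(0), seq(100, 900, length.out = 20))
  flat <- make_records(numeric(0), rep(500, 20), subject = 2)
  set.seed(55)
  noisy <- make_records(numeric(0), stats::rnorm(20, 500, 60), subject = 3)
  dc <- drift_check(rbind(up, flat, noisy))
  expect_true(dc$flagged[dc$subject == 1])
  expect_false(dc$flagged[dc$subject == 2])
  expect_false(dc$flagged[dc$subject == 3])
  expect_equal(dc$rho[dc$subject == 1], 1)

  # rank correlation matches a direct computation on the ranks
  r_direct <- stats::cor(rank(noisy$delta_t_ms), rank(seq_len(20)))
  expect_equal(dc$rho[dc$subject == 3], r_direct, tolerance = 1e-10)

  # too few trials: flag unavailable
  short <- make_records(numeric(0), seq(100, 500, 100), subject = 4)
  expect_true(is.na(drift_check(short)$flagged))
})

test_that("linear fits match the normal-equations oracle", {
  f <- linear_fit(1:5, 2 * (1:5) + 1)
  expect_equal(f$slope, 2)
  expect_equal(f$intercept, 1)
  expect_equal(f$r, 1)

  set.seed(66)
  x <- stats::runif(20, 0, 10)
  y <- 3 - 0.7 * x + stats::rnorm(20)
  f2 <- linear_fit(x, y)
  cf <- oracle_ols(cbind(1, x), y)
  expect_equal(f2$intercept, cf[1], tolerance = 1e-8)
  expect_equal(f2$slope, cf[2], tolerance = 1e-8)
  expect_equal(sign(f2$r), sign(f2$slope))

  expect_error(linear_fit(rep(2, 5), 1:5), "constant")
})

test_that("the filling-in regression recovers coefficients and signs", {
  geom <- display_geometry()
  annuli <- list(annulus_spec(100, 25), annulus_spec(100, 75),
                 annulus_spec(200, 25), annulus_spec(200, 75))
  feats <- lapply(annuli, fillin_features, geom = geom)
  C <- vapply(feats, `[[`, 0, "contour_len_px")
  D <- vapply(feats, `[[`, 0, "fill_dist_px")

  # noiseless recovery is exact
  vp <- 500 - 0.05 * C + 1.5 * D
  fit <- fillin_regression(vp, feats)
  expect_equal(fit$b0, 500, tolerance = 1e-8)
  expect_equal(fit$b1, -0.05, tolerance = 1e-10)
  expect_equal(fit$b2, 1.5, tolerance = 1e-10)
  expect_equal(fit$r, 1, tolerance = 1e-10)

  # coefficients match the normal-equations oracle under noise
  set.seed(77)
  vp_n <- vp + stats::rnorm(4, 0, 5)
  fit_n <- fillin_regression(vp_n, feats)
  cf <- oracle_ols(cbind(1, C, D), vp_n)
  expect_equal(c(fit_n$b0, fit_n$b1, fit_n$b2), cf, tolerance = 1e-8)

  # the published qualitative pattern (small > large, thick > thin) forces
  # a negative contour coefficient and a positive fill-distance coefficient
  vp_pattern <- c(505, 560, 450, 520)  # (s,thin) (s,thick) (l,thin) (l,thick)
  fit_p <- fillin_regression(vp_pattern, feats)
  expect_lt(fit_p$b1, 0)
  expect_gt(fit_p$b2, 0)

  # cross-prediction applies the coefficients to new shapes
  disks <- lapply(c(1.5, 3, 4.5, 6), function(dd)
    fillin_features(disk_spec(dd), geom))
  cp <- cross_predict(fit, disks, observed = 500 -
                        0.05 * vapply(disks, `[[`, 0, "contour_len_px") +
                        1.5 * vapply(disks, `[[`, 0, "fill_dist_px"))
  expect_equal(cp$r, 1, tolerance = 1e-10)

  expect_error(fillin_regression(vp[1:2], feats[1:2]), "three conditions")
  bad <- data.frame(contour_len_px = c(1, 2, 3, 4),
                    fill_dist_px = 2 * c(1, 2, 3, 4))
  expect_error(fillin_regression(vp, bad), "rank deficient")
})

test_that("slope-to-speed conversion treats fill distance as the radius", {
  expect_equal(round(speed_from_slope(70)), 7)
  expect_equal(speed_from_slope(140), 1000 / 280)
  expect_lt(speed_from_slope(1e6), 1e-3)
  expect_error(speed_from_slope(0), "positive")
  expect_error(speed_from_slope(-3), "positive")
})
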