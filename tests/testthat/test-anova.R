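test_that("repeated-measures ANOVA matches the brute-force SS oracle", {
  d <- random_vp_table(9, list(A = c("a1", "a2"), B = c("b1", "b2"),
                               C = c("c1", "c2")), seed = 101)
  an <- rm_anova(d, dv = "value", factors = c("A", "B", "C"))
  ss <- oracle_ss(d, "value", c("subject", "A", "B", "C"))
  n_levels <- c(subject = 9, A = 2, B = 2, C = 2)
  for (i in seq_len(nrow(an))) {
    eff <- strsplit(an$effect[i], ":")[[1]]
    expect_equal(an$ss[i], ss[[paste(sort(eff), collapse = ":")]],
                 tolerance = 1e-8)
    expect_equal(an$F[i], oracle_rm_F(ss, eff, "subject", n_levels),
                 tolerance = 1e-8)
  }
  # two-level effects trivially satisfy sphericity
  expect_true(all(an$epsilon == 1))
  expect_true(all(!an$gg_applied))
})

test_that("an effect with equal condition means has F = 0", {
  n <- 6
  dev <- seq(-1, 1, length.out = n) * 30  # sums to zero across subjects
  d <- data.frame(subject = rep(1:n, each = 2),
                  A = rep(c("a1", "a2"), n),
                  value = 500 + rep(dev, each = 2) * c(1, -1))
  an <- rm_anova(d, dv = "value", factors = "A")
  expect_equal(an$F, 0, tolerance = 1e-12)
})

test_that("GG epsilon and Mauchly agree with independent references", {
  # one within factor, four levels, correlated subject scores
  set.seed(202)
  n <- 12; k <- 4
  base <- stats::rnorm(n, 0, 40)
  Y <- outer(base, rep(1, k)) +
    matrix(stats::rnorm(n * k, 0, 25), n, k) %*% chol(diag(k) + 0.5)
  d <- data.frame(subject = rep(1:n, k),
                  A = rep(paste0("l", 1:k), each = n),
                  value = as.vector(Y))
  an <- rm_anova(d, dv = "value", factors = "A")
  expect_gte(an$epsilon, 1 / (k - 1))
  expect_lte(an$epsilon, 1)
  expect_equal(an$epsilon, oracle_box_epsilon(Y), tolerance = 1e-10)
  mt <- stats::mauchly.test(stats::lm(Y ~ 1), X = ~1)
  expect_equal(an$mauchly_W, unname(mt$statistic), tolerance = 1e-10)
  # p-values agree to the order of the chi-square approximation (the
  # second-order terms differ slightly between implementations)
  expect_equal(an$mauchly_p, mt$p.value, tolerance = 1e-3)
  # F itself still matches the brute-force route
  ss <- oracle_ss(d, "value", c("subject", "A"))
  expect_equal(an$F, oracle_rm_F(ss, "A", "subject",
                                 c(subject = n, A = k)), tolerance = 1e-8)
})

test_that("unbalanced designs are rejected with the missing cells named", {
  d <- random_vp_table(4, list(A = c("a1", "a2")), seed = 303)
  d <- d[-1, ]
  expect_error(rm_anova(d, dv = "value", factors = "A"), "a1")
})

test_that("within-subject CI half-width matches the Loftus-Masson formula", {
  d <- random_vp_table(8, list(A = paste0("l", 1:4)), seed = 404)
  ci <- within_subject_ci(d, dv = "value", factor_col = "A")
  # oracle: interaction mean square from a two-way additive lm fit
  fit <- stats::lm(value ~ factor(subject) + A, data = d)
  ms <- sum(stats::resid(fit)^2) / fit$df.residual
  expect_equal(ci$ms_error, ms, tolerance = 1e-8)
  expect_equal(ci$halfwidth,
               stats::qt(0.975, fit$df.residual) * sqrt(ms / 8),
               tolerance = 1e-8)

  # invariant to adding a per-subject constant
  d2 <- d
  d2$value <- d2$value + 1000 * d2$subject
  expect_equal(within_subject_ci(d2, dv = "value", factor_col = "A")$halfwidth,
               ci$halfwidth, tolerance = 1e-8)

  # purely additive data have zero interaction variance
  d3 <- expand.grid(subject = 1:5, A = c("x", "y", "z"))
  d3$value <- 10 * d3$subject + 50 * as.integer(d3$A)
  expect_equal(within_subject_ci(d3, dv = "value",
                                 factor_col = "A")$halfwidth, 0,
               tolerance = 1e-10)
  expect_error(within_subject_ci(d3[d3$subject == 1, ], dv = "value",
                                 factor_col = "A"), "two subjects")
})
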