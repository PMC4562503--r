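test_that("design builders emit the published structure", {
  d1 <- build_design(1, seed = 1)
  expect_equal(nrow(d1), 320)
  expect_true(all(d1$task[1:10] == "onset"))
  # tasks alternate in blocks of ten
  blocks <- matrix(d1$task, nrow = 10)
  expect_true(all(apply(blocks, 2, function(b) length(unique(b)) == 1)))
  expect_identical(unique(blocks[1, ]), c("onset", "offset"))
  # every condition x task cell holds exactly `reps` trials
  counts <- table(d1$size_px, d1$thickness_px, d1$modality, d1$task)
  expect_true(all(counts == 20))

  d2 <- build_design(2, seed = 2)
  expect_equal(nrow(d2), 120)
  expect_true(all(table(d2$duration_s, d2$task) == 10))
  expect_equal(sort(unique(d2$duration_s)), seq(0.2, 1.2, by = 0.2))

  d3 <- build_design(3, seed = 3)
  expect_equal(nrow(d3), 320)
  expect_true(all(table(d3$size_deg, d3$ecc_deg, d3$task) == 10))
  expect_true(all(d3$task[1:10] == "onset"))
  expect_true(all(d3$direction >= 0 & d3$direction < 2 * pi))
  expect_gt(length(unique(d3$direction)), 300)  # fresh direction per trial

  expect_equal(nrow(build_design(1, reps = 5, seed = 1)), 80)
  expect_error(build_design(4))
})

test_that("noiseless adjustment converges to the latency difference", {
  ctl <- adjustment_controls("keys")
  cond <- data.frame(trial = 1, task = "onset", size_px = 100,
                     thickness_px = 25, modality = "auditory",
                     stringsAsFactors = FALSE)
  # onset: E converges to e_T - e_R within one minimum step
  pr <- noiseless_profile(500, e_T = 50, e_R = 20)
  set.seed(11)
  rec <- simulate_trial(cond, pr, ctl, new.env(parent = emptyenv()))
  expect_lte(abs(rec$delta_t_ms - 30), 10)
  expect_true(rec$converged)

  # zero latencies: E converges to 0
  pr0 <- noiseless_profile(500, e_T = 0, e_R = 0)
  set.seed(12)
  rec0 <- simulate_trial(cond, pr0, ctl, new.env(parent = emptyenv()))
  expect_lte(abs(rec0$delta_t_ms), 10)

  # offset minus onset recovers the persistence within two minimum steps
  expect_lte(abs(recover_vp(noiseless_profile(500)) - 500), 20)
})

test_that("recovered persistence is invariant to latency shifts", {
  base <- recover_vp(noiseless_profile(500, e_T = 50, e_R = 20))
  for (shift in c(-40, 25, 90)) {
    vp_t <- recover_vp(noiseless_profile(500, e_T = 50 + shift, e_R = 20))
    vp_r <- recover_vp(noiseless_profile(500, e_T = 50, e_R = 20 + shift))
    # each recovered VP is accurate to two minimum steps, so two VPs of the
    # same true persistence may differ by up to two steps
    expect_lte(abs(vp_t - base), 20)
    expect_lte(abs(vp_r - base), 20)
  }
})

test_that("noiseless observers recover persistence across the tested range", {
  for (P in seq(200, 1200, by = 200))
    expect_lte(abs(recover_vp(noiseless_profile(P)) - P), 20)
})

test_that("noisy adjustment recovers persistence within its own 95% CI", {
  P <- 600
  pr <- observer_profile(e_T_ms = 60, e_R_ms = 40, persistence_ms = P,
                         judgment_noise_sd_ms = 30)
  ctl <- adjustment_controls("keys")
  cond <- data.frame(trial = 1, task = "onset", size_px = 100,
                     thickness_px = 25, modality = "auditory",
                     stringsAsFactors = FALSE)
  state <- new.env(parent = emptyenv())
  set.seed(31)
  ons <- replicate(20, simulate_trial(cond, pr, ctl, state)$delta_t_ms)
  cond$task <- "offset"
  offs <- replicate(20, simulate_trial(cond, pr, ctl, state)$delta_t_ms)
  vp <- mean(offs) - mean(ons)
  half <- stats::qt(0.975, 38) * sqrt(stats::var(ons) / 20 +
                                        stats::var(offs) / 20)
  expect_lt(abs(vp - P), half)
})

test_that("simulated experiments are deterministic given seed and profiles", {
  profs <- exp2_profiles(n = 2, seed = 5)
  r1 <- simulate_experiment(2, profs, reps = 3, seed = 99)
  r2 <- simulate_experiment(2, profs, reps = 3, seed = 99)
  expect_identical(r1, r2)
  r3 <- simulate_experiment(2, profs, reps = 3, seed = 100)
  expect_false(identical(r1, r3))
})

test_that("proxy-experiment offsets track physical duration; onsets do not", {
  profs <- exp2_profiles(seed = 12)
  rec <- simulate_experiment(2, profs, seed = 22)
  expect_equal(nrow(rec), 4 * 120)
  est <- synchrony_estimates(rec)
  dur_ms <- sort(unique(est$duration_s)) * 1000
  Dm <- as.numeric(tapply(est$D_off, est$duration_s, mean))
  Em <- as.numeric(tapply(est$E, est$duration_s, mean))
  f_off <- linear_fit(dur_ms, Dm)
  f_on <- linear_fit(dur_ms, Em)
  expect_lt(abs(f_off$slope - 1), 0.1)
  expect_lt(abs(f_on$slope), 0.05)
})

test_that("a simulated cohort reproduces the condition effects", {
  profs <- exp1_profiles(n = 9, seed = 11)
  rec <- simulate_experiment(1, profs, seed = 21)
  expect_equal(nrow(rec), 9 * 320)
  # every condition x task cell of every subject holds 20 repetitions
  counts <- table(rec$subject, rec$size_px, rec$thickness_px,
                  rec$modality, rec$task)
  expect_true(all(counts == 20))

  est <- synchrony_estimates(rec)
  an <- rm_anova(est, dv = "VP",
                 factors = c("size_px", "thickness_px", "modality"))
  p_of <- function(e) an$p_reported[an$effect == e]
  expect_lt(p_of("size_px"), 0.05)
  expect_lt(p_of("thickness_px"), 0.05)
  expect_lt(p_of("modality"), 0.05)
  expect_gt(p_of("size_px:thickness_px"), 0.01)
  # direction of the effects: small > large, thick > thin, auditory > visual
  expect_gt(mean(est$VP[est$size_px == 100]),
            mean(est$VP[est$size_px == 200]))
  expect_gt(mean(est$VP[est$thickness_px == 75]),
            mean(est$VP[est$thickness_px == 25]))
  expect_gt(mean(est$VP[est$modality == "auditory"]),
            mean(est$VP[est$modality == "visual"]))
  # criterion jitter makes offsets less precise than onsets
  expect_gt(mean(est$sd_off), mean(est$sd_on))
  # onset times are unaffected by the stimulus factors
  an_e <- rm_anova(est, dv = "E",
                   factors = c("size_px", "thickness_px", "modality"))
  expect_true(all(an_e$p_reported[an_e$effect %in%
                                    c("size_px", "thickness_px")] > 0.01))
})
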