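# Independent oracles used to cross-check the package implementations.
# These deliberately take different computational routes than the package.

# Brute-force sums of squares for a fully crossed balanced design, by
# inclusion-exclusion over marginal means (subject included as a factor).
# Returns a named list keyed by sorted "f1:f2" term labels.
oracle_ss <- function(d, dv, facs) {
  all_sets <- unlist(lapply(seq_along(facs), function(k)
    utils::combn(facs, k, simplify = FALSE)), recursive = FALSE)
  grand <- mean(d[[dv]])
  eff <- list()
  ss <- list()
  for (s in all_sets) {
    key <- paste(sort(s), collapse = ":")
    m <- stats::ave(d[[dv]], interaction(d[s], drop = TRUE), FUN = mean)
    e <- m - grand
    for (t in all_sets) {
      if (length(t) < length(s) && all(t %in% s))
        e <- e - eff[[paste(sort(t), collapse = ":")]]
    }
    eff[[key]] <- e
    ss[[key]] <- sum(e^2)
  }
  ss
}

# RM-ANOVA F statistic for one effect from the brute-force SS list.
oracle_rm_F <- function(ss_list, eff_factors, subject, n_levels) {
  key <- paste(sort(eff_factors), collapse = ":")
  ekey <- paste(sort(c(subject, eff_factors)), collapse = ":")
  df1 <- prod(n_levels[eff_factors] - 1)
  df2 <- df1 * (n_levels[[subject]] - 1)
  unname((ss_list[[key]] / df1) / (ss_list[[ekey]] / df2))
}

# Box's original epsilon formula on the level covariance matrix
# (algebraically equivalent to the orthonormal-contrast form, computed by
# an entirely different route).
oracle_box_epsilon <- function(Y) {
  S <- stats::cov(Y)
  k <- ncol(S)
  sbar <- mean(S)
  sdiag <- mean(diag(S))
  mi <- rowMeans(S)
  k^2 * (sdiag - sbar)^2 /
    ((k - 1) * (sum(S^2) - 2 * k * sum(mi^2) + k^2 * sbar^2))
}

# Normal-equations least squares.
oracle_ols <- function(X, y) {
  as.numeric(solve(t(X) %*% X, t(X) %*% y))
}

# First downward crossing of a calibrated decay curve through `level`,
# by dense grid scan after the peak with linear interpolation.
oracle_crossing <- function(p, level, t_max = 50, dt = 1e-4) {
  tt <- seq(p$t_peak, t_max, by = dt)
  v <- impulse_response(tt, p)
  i <- which(v < level)[1]
  stopifnot(!is.na(i), i > 1)
  t0 <- tt[i - 1]; t1 <- tt[i]
  v0 <- v[i - 1]; v1 <- v[i]
  t0 + (v0 - level) / (v0 - v1) * (t1 - t0)
}

# Noiseless observer with a fixed true persistence (ms).
noiseless_profile <- function(persistence_ms, e_T = 50, e_R = 20,
                              criterion_jitter = 0) {
  observer_profile(e_T_ms = e_T, e_R_ms = e_R,
                   persistence_ms = persistence_ms,
                   judgment_noise_sd_ms = 0,
                   criterion_jitter_sd = criterion_jitter)
}

# Recovered VP from one noiseless onset/offset trial pair under a fixed
# RNG state (the init jitter is the only random draw).
recover_vp <- function(profile, controls = adjustment_controls("keys"),
                       seed = 7) {
  cond <- data.frame(trial = 1, task = "onset", size_px = 100,
                     thickness_px = 25, modality = "auditory",
                     stringsAsFactors = FALSE)
  state <- new.env(parent = emptyenv())
  set.seed(seed)
  on <- simulate_trial(cond, profile, controls, state)
  cond$task <- "offset"
  off <- simulate_trial(cond, profile, controls, state)
  off$delta_t_ms - on$delta_t_ms
}

# Small balanced random VP table: n subjects x full factorial of `levels`.
random_vp_table <- function(n_subj, levels, seed, sd = 50) {
  set.seed(seed)
  cells <- expand.grid(levels, KEEP.OUT.ATTRS = FALSE,
                       stringsAsFactors = FALSE)
  d <- cells[rep(seq_len(nrow(cells)), n_subj), , drop = FALSE]
  d$subject <- rep(seq_len(n_subj), each = nrow(cells))
  d$value <- 500 + stats::rnorm(nrow(d), 0, sd)
  d
}
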