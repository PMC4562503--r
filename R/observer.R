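#' Synthetic observer profile
#'
#' A parametric observer for the judgment-of-synchrony task.  Latent
#' perceptual latencies `e_T` (matrix transition to percept onset) and
#' `e_R` (reference onset to percept) are unknown to the measurement
#' procedure; the analysis relies on their cancellation in `VP = D - E`.
#' The observer's internal persistence trace is a calibrated decay curve;
#' its perceived offset is where that curve falls through
#' `offset_criterion`.  Trial-to-trial wobble of the criterion
#' (`criterion_jitter_sd`, on the log10 scale) makes offset judgments less
#' precise than onset judgments.
#'
#' @param subject Subject identifier.
#' @param e_T_ms Transition-to-percept latency, ms.
#' @param e_R_ms Reference-to-percept latency, ms; either a scalar or a
#'   named vector by reference modality, e.g.
#'   `c(auditory = 70, visual = 85)`.
#' @param persistence_fun Function of one argument (a trial condition row)
#'   returning the observer's true persistence for that condition, in ms.
#'   Alternatively supply a constant via `persistence_ms`.
#' @param persistence_ms Convenience constant used when `persistence_fun`
#'   is missing.
#' @param offset_criterion Criterion in (0, 1] applied to the normalised
#'   persistence trace; default equals the trace calibration threshold, so
#'   perceived persistence equals the calibrated offset time.
#' @param judgment_noise_sd_ms SD of Gaussian noise added to each perceived
#'   asynchrony, ms.
#' @param confirm_jnd_ms The observer confirms synchrony when the absolute
#'   perceived asynchrony falls below this tolerance, ms.
#' @param criterion_jitter_sd Trial-to-trial SD of `log10(criterion)`.
#' @param trace_a,trace_threshold,trace_ratio Parameters handed to
#'   [calibrate_offset()] when building the internal persistence trace.
#' @return Object of class `observer_profile`.
#' @export
observer_profile <- function(subject = 1L, e_T_ms = 60, e_R_ms = 70,
                             persistence_fun = NULL, persistence_ms = 500,
                             offset_criterion = 0.01,
                             judgment_noise_sd_ms = 30, confirm_jnd_ms = 20,
                             criterion_jitter_sd = 0,
                             trace_a = 50, trace_threshold = 0.01,
                             trace_ratio = 1.2) {
  stopifnot(is.finite(e_T_ms), all(is.finite(e_R_ms)), confirm_jnd_ms >= 0,
            judgment_noise_sd_ms >= 0, criterion_jitter_sd >= 0,
            offset_criterion > 0, offset_criterion <= 1)
  if (is.null(persistence_fun)) {
    force(persistence_ms)
    persistence_fun <- function(cond) persistence_ms
  }
  structure(
    list(subject = subject, e_T_ms = e_T_ms, e_R_ms = e_R_ms,
         persistence_fun = persistence_fun,
         offset_criterion = offset_criterion,
         judgment_noise_sd_ms = judgment_noise_sd_ms,
         confirm_jnd_ms = confirm_jnd_ms,
         criterion_jitter_sd = criterion_jitter_sd,
         trace_a = trace_a, trace_threshold = trace_threshold,
         trace_ratio = trace_ratio),
    class = "observer_profile")
}

# Reference latency for a trial: modality-addressable when e_R is named.
get_e_R <- function(profile, cond) {
  e <- profile$e_R_ms
  if (length(e) > 1L && !is.null(cond$modality) &&
      !is.na(match(cond$modality, names(e)))) {
    unname(e[[cond$modality]])
  } else unname(e[[1L]])
}

#' Adjustment-procedure controls
#'
#' `"keys"` mode offers the four fixed steps (-100, -10, +10, +100 ms;
#' the minimum step equals the 10 ms display frame); `"knob"` mode applies
#' a continuous correction but the display rounds the presented interval to
#' the frame grid.  The semi-adaptive initialiser starts a condition's
#' first trial at a small jitter around zero (`"jitter"` policy, drawn from
#' -30..30 ms in 10 ms steps) or around the physical event time
#' (`"uniform"` policy, +-200 ms); later trials start at the running mean
#' of that condition's previous estimates plus the same jitter.
#'
#' @param mode `"keys"` or `"knob"`.
#' @param key_steps_ms Permitted step sizes in keys mode, ms.
#' @param knob_gain_ms_per_deg Knob gain (about 1000 ms per 90 deg).
#' @param frame_ms Display frame duration, ms.
#' @param init_policy `"jitter"` or `"uniform"`.
#' @param init_jitter_set_ms Jitter values for the `"jitter"` policy.
#' @param init_spread_ms Half-width of the `"uniform"` policy draw.
#' @param max_repetitions Per-trial cap on sequence repetitions; trials
#'   hitting it are kept but flagged non-converged.
#' @return Object of class `adjustment_controls`.
#' @export
adjustment_controls <- function(mode = c("keys", "knob"),
                                key_steps_ms = c(-100, -10, 10, 100),
                                knob_gain_ms_per_deg = 1000 / 90,
                                frame_ms = 10,
                                init_policy = c("jitter", "uniform"),
                                init_jitter_set_ms = seq(-30, 30, by = 10),
                                init_spread_ms = 200,
                                max_repetitions = 200) {
  mode <- match.arg(mode)
  init_policy <- match.arg(init_policy)
  if (mode == "keys" && min(abs(key_steps_ms)) < frame_ms)
    stop("minimum key step must be at least one display frame")
  structure(
    list(mode = mode, key_steps_ms = key_steps_ms,
         knob_gain_ms_per_deg = knob_gain_ms_per_deg, frame_ms = frame_ms,
         init_policy = init_policy,
         init_jitter_set_ms = init_jitter_set_ms,
         init_spread_ms = init_spread_ms,
         max_repetitions = max_repetitions),
    class = "adjustment_controls")
}

# Condition key for the semi-adaptive initialiser: the experimental cell
# and the task, excluding per-trial fields.
cond_key <- function(cond) {
  drop <- c("trial", "direction")
  keep <- setdiff(names(cond), drop)
  paste(vapply(keep, function(k) paste0(k, "=", cond[[k]]), ""),
        collapse = ";")
}

# Calibrated persistence trace for one target offset time, cached in the
# session state.
condition_trace <- function(state, t_off_ms, profile) {
  if (is.null(state$traces)) state$traces <- new.env(parent = emptyenv())
  key <- sprintf("%.6f", t_off_ms)
  tr <- state$traces[[key]]
  if (is.null(tr)) {
    tr <- calibrate_offset(a_rate = profile$trace_a, t_off = t_off_ms / 1000,
                           threshold = profile$trace_threshold,
                           rate_ratio = profile$trace_ratio)
    state$traces[[key]] <- tr
  }
  tr
}

# Persistence readout with caching for the deterministic (no-jitter) path.
trace_persistence_ms <- function(state, trace, criterion) {
  if (is.null(state$persist)) state$persist <- new.env(parent = emptyenv())
  key <- sprintf("%.6f|%.10g", trace$t_off, criterion)
  v <- state$persist[[key]]
  if (is.null(v)) {
    v <- 1000 * persistence_duration(trace, criterion)
    state$persist[[key]] <- v
  }
  v
}

#' Perceived time of the judged event
#'
#' Onset task: the percept of the transient arises at `t_T + e_T`.  Offset
#' task: the fading percept ends when the internal persistence trace falls
#' through the observer's offset criterion, i.e. at
#' `t_T + e_T + 1000 * persistence_duration(trace, criterion)`.
#'
#' @param task `"onset"` or `"offset"`.
#' @param t_T_ms Physical transition time, ms.
#' @param profile An [observer_profile()].
#' @param trace A calibrated [decay_params()] object (the observer's
#'   persistence trace for the current condition).
#' @return Perceived event time, ms.
#' @export
perceived_event_time <- function(task, t_T_ms, profile, trace = NULL) {
  stopifnot(task %in% c("onset", "offset"))
  if (task == "onset") return(t_T_ms + profile$e_T_ms)
  if (is.null(trace)) stop("offset task requires a persistence trace")
  t_T_ms + profile$e_T_ms +
    1000 * persistence_duration(trace, profile$offset_criterion)
}

#' Simulate one adjustment trial
#'
#' Runs the sequence loop: on each repetition the observer perceives the
#' asynchrony `A = (t_T + delta_t + e_R) - perceived event time` plus
#' Gaussian judgment noise, confirms when `|A| < confirm_jnd`, and
#' otherwise applies the permitted key step that most reduces the expected
#' asynchrony (keys mode) or nulls it directly (knob mode,
#' `delta_t <- delta_t - A`, presented rounded to the frame grid but
#' stored continuously).
#'
#' @param cond One trial row from [build_design()] (including `task`).
#' @param profile An [observer_profile()].
#' @param controls An [adjustment_controls()].
#' @param state Session environment holding the semi-adaptive initialiser
#'   means and trace caches; reuse one per (subject, session).
#' @param experiment Experiment id recorded with the trial.
#' @return One-row data frame: trial record with final `delta_t_ms`,
#'   `n_reps`, `converged`.
#' @export
simulate_trial <- function(cond, profile, controls,
                           state = new.env(parent = emptyenv()),
                           experiment = 1L) {
  task <- cond$task
  stopifnot(task %in% c("onset", "offset"))
  e_T <- profile$e_T_ms
  e_R <- get_e_R(profile, cond)
  trace <- NULL
  if (task == "offset") {
    t_off_ms <- profile$persistence_fun(cond)
    trace <- condition_trace(state, t_off_ms, profile)
  }

  # semi-adaptive initial delta_t
  if (is.null(state$means)) state$means <- new.env(parent = emptyenv())
  key <- cond_key(cond)
  st <- state$means[[key]]
  anchor <- if (!is.null(st)) {
    st$sum / st$n
  } else if (controls$init_policy == "uniform") {
    if (task == "offset") profile$persistence_fun(cond) else 0
  } else 0
  eps <- if (controls$init_policy == "uniform") {
    stats::runif(1, -controls$init_spread_ms, controls$init_spread_ms)
  } else {
    sample(controls$init_jitter_set_ms, 1L)
  }
  dt <- anchor + eps

  converged <- FALSE
  noise_sd <- profile$judgment_noise_sd_ms
  jit <- profile$criterion_jitter_sd
  n_rep <- 0L
  for (n_rep in seq_len(controls$max_repetitions)) {
    perceived <- if (task == "onset") {
      e_T
    } else {
      crit <- profile$offset_criterion
      if (jit > 0) {
        crit <- 10^(log10(crit) + stats::rnorm(1, 0, jit))
        crit <- min(max(crit, 1e-12), 1)
        e_T + 1000 * persistence_duration(trace, crit)
      } else {
        e_T + trace_persistence_ms(state, trace, crit)
      }
    }
    presented <- if (controls$mode == "knob") {
      round(dt / controls$frame_ms) * controls$frame_ms
    } else dt
    A <- presented + e_R - perceived +
      if (noise_sd > 0) stats::rnorm(1, 0, noise_sd) else 0
    if (abs(A) < profile$confirm_jnd_ms) {
      converged <- TRUE
      break
    }
    if (controls$mode == "keys") {
      steps <- controls$key_steps_ms
      dt <- dt + steps[which.min(abs(A + steps))]
    } else {
      dt <- dt - A
    }
  }

  if (is.null(st)) st <- list(sum = 0, n = 0L)
  state$means[[key]] <- list(sum = st$sum + dt, n = st$n + 1L)

  rec <- data.frame(subject = profile$subject, experiment = experiment,
                    trial = if (!is.null(cond$trial)) cond$trial else NA,
                    task = task, stringsAsFactors = FALSE)
  for (k in setdiff(names(cond), c("trial", "task")))
    rec[[k]] <- cond[[k]]
  rec$delta_t_ms <- dt
  rec$n_reps <- n_rep
  rec$converged <- converged
  rec
}

#' Simulate a full experiment for a set of observers
#'
#' Builds one randomised design per observer and runs every trial through
#' [simulate_trial()], with an independent RNG stream per subject, so the
#' result is deterministic given `(seed, profiles)`.
#'
#' @param experiment 1, 2 or 3.
#' @param profiles List of [observer_profile()] objects.
#' @param controls An [adjustment_controls()]; defaults to keys mode for
#'   Experiment 1 and knob mode (uniform initialiser for Experiment 2)
#'   otherwise.
#' @param reps Repetitions per condition; `NULL` uses the experiment
#'   default.
#' @param seed Integer master seed.
#' @return Data frame of trial records (one row per trial).
#' @export
simulate_experiment <- function(experiment, profiles, controls = NULL,
                                reps = NULL, seed = 1L) {
  stopifnot(length(profiles) >= 1L)
  experiment <- as.integer(experiment)
  if (is.null(controls)) {
    controls <- switch(experiment,
      adjustment_controls(mode = "keys", init_policy = "jitter"),
      adjustment_controls(mode = "knob", init_policy = "uniform"),
      adjustment_controls(mode = "knob", init_policy = "jitter"))
  }
  out <- with_seed(seed, {
    subject_seeds <- sample.int(.Machine$integer.max - 1L, length(profiles))
    lapply(seq_along(profiles), function(i) {
      set.seed(subject_seeds[i])
      design <- build_design(experiment, reps = reps, seed = NULL)
      state <- new.env(parent = emptyenv())
      recs <- lapply(seq_len(nrow(design)), function(j)
        simulate_trial(design[j, , drop = FALSE], profiles[[i]], controls,
                       state, experiment))
      tab <- do.call(rbind, recs)
      tab$seed <- subject_seeds[i]
      tab
    })
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  n_bad <- sum(!res$converged)
  if (n_bad > 0)
    warning(sprintf("%d trial(s) hit max_repetitions without converging",
                    n_bad))
  res
}

# ---- default observer populations (the study conditions) -----------------

rlnorm_trunc <- function(n, meanlog, sdlog, min) {
  pmax(stats::rlnorm(n, meanlog, sdlog), min)
}

#' Default observer populations for the three experiments
#'
#' Each builder draws a cohort of synthetic observers whose true
#' persistence follows the published condition structure:
#'
#' * `exp1_profiles()`: additive cell effects on persistence — thickness
#'   +69 ms (thick vs thin), annulus size -55.6 ms (large vs small),
#'   reference modality +102.2 ms (auditory vs visual) — around a
#'   log-normal subject baseline (median 450 ms, sdlog 0.6, matching the
#'   very large inter-individual spread of persistence durations).
#' * `exp2_profiles()`: persistence equals the proxy stimulus's calibrated
#'   decay duration; every observer's offset criterion equals the
#'   calibration threshold.
#' * `exp3_profiles()`: persistence grows by 67.78 ms per degree of disk
#'   diameter around a log-normal baseline (median 1007.95 ms,
#'   sdlog 0.3); eccentricity has no effect.
#'
#' Cell-level persistence is floored at `min_persistence_ms`.
#'
#' @param n Number of observers.
#' @param seed Integer seed for drawing the cohort.
#' @param thickness_effect,size_effect,modality_effect Exp 1 condition
#'   effects, ms.
#' @param base_meanlog,base_sdlog Log-normal baseline parameters.
#' @param size_slope_ms_per_deg Exp 3 persistence slope, ms per degree of
#'   disk diameter.
#' @param e_T_mean,e_T_sd,e_R_mean,e_R_sd Latency population parameters,
#'   ms (`e_R_mean` may be a named per-modality vector).
#' @param judgment_noise_sd_ms,criterion_jitter_sd,confirm_jnd_ms Observer
#'   noise parameters (see [observer_profile()]).
#' @param min_persistence_ms Floor on cell-level persistence, ms.
#' @return List of [observer_profile()] objects.
#' @export
exp1_profiles <- function(n = 9, seed = NULL,
                          thickness_effect = 69.0, size_effect = -55.6,
                          modality_effect = 102.2,
                          base_meanlog = log(450), base_sdlog = 0.6,
                          e_T_mean = 60, e_T_sd = 15,
                          e_R_mean = c(auditory = 70, visual = 85),
                          e_R_sd = 15,
                          judgment_noise_sd_ms = 30,
                          criterion_jitter_sd = 0.1,
                          confirm_jnd_ms = 20,
                          min_persistence_ms = 200) {
  with_seed(seed, {
    base <- rlnorm_trunc(n, base_meanlog, base_sdlog, min_persistence_ms)
    lapply(seq_len(n), function(i) {
      b <- base[i]
      pf <- function(cond) {
        p <- b +
          0.5 * thickness_effect * ifelse(cond$thickness_px == 75, 1, -1) +
          0.5 * size_effect * ifelse(cond$size_px == 200, 1, -1) +
          0.5 * modality_effect * ifelse(cond$modality == "auditory", 1, -1)
        max(p, min_persistence_ms)
      }
      e_R <- e_R_mean + stats::rnorm(length(e_R_mean), 0, e_R_sd)
      observer_profile(subject = i,
                       e_T_ms = stats::rnorm(1, e_T_mean, e_T_sd),
                       e_R_ms = e_R, persistence_fun = pf,
                       judgment_noise_sd_ms = judgment_noise_sd_ms,
                       criterion_jitter_sd = criterion_jitter_sd,
                       confirm_jnd_ms = confirm_jnd_ms)
    })
  })
}

#' @rdname exp1_profiles
#' @export
exp2_profiles <- function(n = 4, seed = NULL,
                          e_T_mean = 60, e_T_sd = 15,
                          e_R_mean = c(auditory = 70), e_R_sd = 15,
                          judgment_noise_sd_ms = 30,
                          criterion_jitter_sd = 0.1,
                          confirm_jnd_ms = 20) {
  with_seed(seed, {
    lapply(seq_len(n), function(i) {
      observer_profile(subject = i,
                       e_T_ms = stats::rnorm(1, e_T_mean, e_T_sd),
                       e_R_ms = e_R_mean + stats::rnorm(length(e_R_mean),
                                                        0, e_R_sd),
                       persistence_fun = function(cond)
                         cond$duration_s * 1000,
                       offset_criterion = 0.01,
                       judgment_noise_sd_ms = judgment_noise_sd_ms,
                       criterion_jitter_sd = criterion_jitter_sd,
                       confirm_jnd_ms = confirm_jnd_ms)
    })
  })
}

#' @rdname exp1_profiles
#' @export
exp3_profiles <- function(n = 9, seed = NULL,
                          size_slope_ms_per_deg = 67.78,
                          base_meanlog = log(1007.95), base_sdlog = 0.3,
                          e_T_mean = 60, e_T_sd = 15,
                          e_R_mean = c(auditory = 70), e_R_sd = 15,
                          judgment_noise_sd_ms = 30,
                          criterion_jitter_sd = 0.1,
                          confirm_jnd_ms = 20,
                          min_persistence_ms = 200) {
  with_seed(seed, {
    base <- rlnorm_trunc(n, base_meanlog, base_sdlog, min_persistence_ms)
    lapply(seq_len(n), function(i) {
      b <- base[i]
      pf <- function(cond)
        max(b + size_slope_ms_per_deg * cond$size_deg, min_persistence_ms)
      observer_profile(subject = i,
                       e_T_ms = stats::rnorm(1, e_T_mean, e_T_sd),
                       e_R_ms = e_R_mean + stats::rnorm(length(e_R_mean),
                                                        0, e_R_sd),
                       persistence_fun = pf,
                       judgment_noise_sd_ms = judgment_noise_sd_ms,
                       criterion_jitter_sd = criterion_jitter_sd,
                       confirm_jnd_ms = confirm_jnd_ms)
    })
  })
}
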