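#' Onset/offset synchrony estimates and visible persistence
#'
#' Per subject and condition: `E` is the mean adjusted interval over onset
#' trials, `D_off` the mean over offset trials, and `VP = D_off - E` the
#' visible-persistence duration; repetition SDs and counts are carried
#' along.  Cells missing either task are marked incomplete and excluded
#' (with a message).
#'
#' @param records Trial-record table (from [simulate_experiment()] or
#'   [read_trials()]).
#' @param condition_cols Columns defining a condition; by default every
#'   recognised condition column present in `records`.
#' @return Data frame with one row per subject x condition: `E`, `D_off`,
#'   `VP`, `sd_on`, `sd_off`, `n_on`, `n_off`.
#' @export
synchrony_estimates <- function(records, condition_cols = NULL) {
  if (is.null(condition_cols))
    condition_cols <- intersect(c("size_px", "thickness_px", "modality",
                                  "duration_s", "size_deg", "ecc_deg"),
                                names(records))
  stopifnot("subject" %in% names(records), "task" %in% names(records),
            "delta_t_ms" %in% names(records), length(condition_cols) > 0)
  grp <- records[c("subject", condition_cols)]
  key <- interaction(grp, drop = TRUE, lex.order = TRUE)
  pieces <- split(records, key)
  rows <- lapply(pieces, function(p) {
    on <- p$delta_t_ms[p$task == "onset"]
    off <- p$delta_t_ms[p$task == "offset"]
    out <- p[1L, c("subject", condition_cols), drop = FALSE]
    out$E <- if (length(on)) mean(on) else NA_real_
    out$D_off <- if (length(off)) mean(off) else NA_real_
    out$VP <- out$D_off - out$E
    out$sd_on <- if (length(on) > 1L) stats::sd(on) else
      if (length(on) == 1L) 0 else NA_real_
    out$sd_off <- if (length(off) > 1L) stats::sd(off) else
      if (length(off) == 1L) 0 else NA_real_
    out$n_on <- length(on)
    out$n_off <- length(off)
    out
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  bad <- res$n_on == 0L | res$n_off == 0L
  if (any(bad)) {
    message(sum(bad), " subject x condition cell(s) lack one task; excluded")
    res <- res[!bad, , drop = FALSE]
  }
  res
}

#' Screen subjects for offset drift
#'
#' Flags subjects whose offset settings drift upward over the course of the
#' experiment — the pattern of a subject who starts with very low offset
#' values that then increase monotonically (interpreted as a task
#' misunderstanding).  Operationalised as Spearman rank correlation between
#' the offset `delta_t_ms` and the trial index exceeding `rho_threshold`
#' with a one-sided p below `alpha`.
#'
#' @param records Trial-record table containing offset trials and a
#'   `trial` column.
#' @param rho_threshold Rank-correlation threshold (default 0.5).
#' @param alpha Significance level (default 0.05).
#' @param min_trials Minimum offset trials per subject (default 10); below
#'   it the flag is `NA`.
#' @return Data frame: `subject`, `n`, `rho`, `p`, `flagged`.
#' @export
drift_check <- function(records, rho_threshold = 0.5, alpha = 0.05,
                        min_trials = 10L) {
  off <- records[records$task == "offset", , drop = FALSE]
  rows <- lapply(split(off, off$subject), function(p) {
    p <- p[order(p$trial), , drop = FALSE]
    n <- nrow(p)
    if (n < min_trials)
      return(data.frame(subject = p$subject[1L], n = n, rho = NA_real_,
                        p = NA_real_, flagged = NA))
    if (stats::sd(p$delta_t_ms) == 0)  # constant settings cannot drift
      return(data.frame(subject = p$subject[1L], n = n, rho = 0,
                        p = 1, flagged = FALSE))
    ct <- suppressWarnings(
      stats::cor.test(p$delta_t_ms, seq_len(n), method = "spearman",
                      alternative = "greater", exact = FALSE))
    data.frame(subject = p$subject[1L], n = n,
               rho = unname(ct$estimate), p = ct$p.value,
               flagged = unname(ct$estimate) > rho_threshold &
                 ct$p.value < alpha)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Ordinary least-squares line
#'
#' @param x Predictor values (at least two distinct).
#' @param y Responses.
#' @return List with `slope`, `intercept`, `r` (Pearson correlation).
#' @export
linear_fit <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2L)
  if (length(unique(x)) < 2L) stop("x is constant; no line can be fitted")
  fit <- stats::lm(y ~ x)
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       r = stats::cor(x, y))
}

# Coerce a list of fillin_features() outputs (or a data frame) to a
# two-column data frame C / D_fill.
features_table <- function(features) {
  if (is.data.frame(features)) {
    stopifnot(all(c("contour_len_px", "fill_dist_px") %in% names(features)))
    features[c("contour_len_px", "fill_dist_px")]
  } else {
    data.frame(
      contour_len_px = vapply(features, `[[`, 0, "contour_len_px"),
      fill_dist_px = vapply(features, `[[`, 0, "fill_dist_px"))
  }
}

#' Filling-in regression of persistence on stimulus features
#'
#' Fits `VP = b0 + b1 * C + b2 * D_fill`, with `C` the summed contour
#' length and `D_fill` the filling-in distance (pixels; see
#' [fillin_features()]).  A negative `b1` is read as stronger edge signals
#' speeding up filling-in; a positive `b2` as longer fill distances
#' prolonging it.
#'
#' @param vp_means Per-condition mean persistence durations, ms (>= 3).
#' @param features List of [fillin_features()] results (or a data frame
#'   with columns `contour_len_px`, `fill_dist_px`) matching `vp_means`.
#' @return List of class `fillin_fit`: `b0`, `b1`, `b2`, `r` (correlation
#'   of fitted with observed values), `fitted`.
#' @export
fillin_regression <- function(vp_means, features) {
  ft <- features_table(features)
  stopifnot(length(vp_means) == nrow(ft))
  if (length(vp_means) < 3L)
    stop("at least three conditions needed for the three-parameter fit")
  X <- cbind(1, ft$contour_len_px, ft$fill_dist_px)
  if (qr(X)$rank < 3L)
    stop("feature matrix is rank deficient; C and D_fill are confounded")
  fit <- stats::lm(vp_means ~ ft$contour_len_px + ft$fill_dist_px)
  cf <- unname(stats::coef(fit))
  structure(list(b0 = cf[1L], b1 = cf[2L], b2 = cf[3L],
                 r = stats::cor(stats::fitted(fit), vp_means),
                 fitted = unname(stats::fitted(fit))),
            class = "fillin_fit")
}

#' @export
print.fillin_fit <- function(x, ...) {
  cat(sprintf("VP = %.2f %+.4f * C %+.4f * D_fill   (r = %.3f)\n",
              x$b0, x$b1, x$b2, x$r))
  invisible(x)
}

#' Cross-predict persistence from a filling-in fit
#'
#' Applies the coefficients of a [fillin_regression()] fit to new stimulus
#' features and, when observed values are supplied, reports the Pearson
#' correlation between observed and predicted persistence.
#'
#' @param fit A `fillin_fit`.
#' @param features Features of the new conditions (as in
#'   [fillin_regression()]).
#' @param observed Optional observed persistence means, ms.
#' @return List with `predicted` and (if `observed` given) `r`.
#' @export
cross_predict <- function(fit, features, observed = NULL) {
  stopifnot(inherits(fit, "fillin_fit"))
  ft <- features_table(features)
  pred <- fit$b0 + fit$b1 * ft$contour_len_px + fit$b2 * ft$fill_dist_px
  out <- list(predicted = pred)
  if (!is.null(observed)) out$r <- stats::cor(pred, observed)
  out
}

#' Filling-in speed from a persistence-vs-diameter slope
#'
#' A slope of `s` ms of persistence per degree of stimulus *diameter*
#' corresponds to a centripetal filling-in speed of `1000 / (2 s)` degrees
#' of *radius* per second (the fill distance is the radius, half the
#' diameter).
#'
#' @param slope_ms_per_deg Positive slope, ms per degree of diameter.
#' @return Speed in degrees of radius per second.
#' @examples
#' speed_from_slope(70)  # ~7 deg/s
#' @export
speed_from_slope <- function(slope_ms_per_deg) {
  if (!is.finite(slope_ms_per_deg) || slope_ms_per_deg <= 0)
    stop("slope must be positive")
  1000 / (2 * slope_ms_per_deg)
}
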