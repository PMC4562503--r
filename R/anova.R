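#' Repeated-measures ANOVA with Greenhouse-Geisser correction
#'
#' Full-factorial within-subject decomposition of a balanced table with one
#' observation per subject and design cell.  Each effect is tested against
#' its own subject-by-effect interaction.  For effects with more than one
#' numerator df, the Greenhouse-Geisser epsilon and Mauchly's sphericity
#' test are computed from the covariance of orthonormal within-subject
#' contrast scores; the corrected p-value is reported whenever Mauchly's
#' test rejects at `sphericity_alpha` (or whenever the contrast covariance
#' is singular, in which case the test is unavailable and the correction is
#' applied conservatively).
#'
#' @param data Long-format data frame.
#' @param dv Name of the dependent-variable column.
#' @param factors Character vector of within-subject factor columns.
#' @param subject Name of the subject column.
#' @param sphericity_alpha Alpha for Mauchly's test (default 0.05).
#' @return Data frame of class `rm_anova` with one row per effect:
#'   sums of squares, df, F, p, epsilon, Mauchly results, and the reported
#'   (possibly corrected) p-value.
#' @export
rm_anova <- function(data, dv = "value", factors, subject = "subject",
                     sphericity_alpha = 0.05) {
  stopifnot(dv %in% names(data), all(factors %in% names(data)),
            subject %in% names(data))
  d <- data
  d[[subject]] <- factor(d[[subject]])
  for (f in factors) d[[f]] <- factor(d[[f]])

  counts <- table(d[c(subject, factors)])
  if (any(counts != 1L)) {
    bad <- which(counts != 1L, arr.ind = TRUE)
    labs <- apply(bad, 1L, function(ix)
      paste(mapply(function(dn, i) dn[i], dimnames(counts), ix),
            collapse = "/"))
    stop("design not balanced (one observation per subject x cell needed); ",
         "offending cells: ", paste(unique(labs), collapse = ", "))
  }

  n_subj <- nlevels(d[[subject]])
  form <- stats::as.formula(paste(dv, "~", paste(c(subject, factors),
                                                 collapse = "*")))
  # the saturated within-subject model has zero residual df by design;
  # anova.lm warns about its own (unused) F column, so muffle that warning
  at <- withCallingHandlers(
    stats::anova(stats::lm(form, data = d)),
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  term_parts <- strsplit(rownames(at), ":", fixed = TRUE)

  find_term <- function(parts) {
    hit <- which(vapply(term_parts, function(p)
      setequal(p, parts), logical(1)))
    if (length(hit) != 1L) stop("internal: term lookup failed")
    hit
  }

  effects <- unlist(lapply(seq_along(factors), function(k)
    utils::combn(factors, k, simplify = FALSE)), recursive = FALSE)

  rows <- lapply(effects, function(eff) {
    ie <- find_term(eff)
    ierr <- find_term(c(subject, eff))
    ss <- at$`Sum Sq`[ie]; df1 <- at$Df[ie]
    ss_e <- at$`Sum Sq`[ierr]; df2 <- at$Df[ierr]
    Fv <- (ss / df1) / (ss_e / df2)
    p <- stats::pf(Fv, df1, df2, lower.tail = FALSE)

    sph <- contrast_sphericity(d, dv, eff, subject)
    gg_applied <- FALSE
    p_gg <- NA_real_
    if (sph$q > 1L) {
      p_gg <- stats::pf(Fv, sph$epsilon * df1, sph$epsilon * df2,
                        lower.tail = FALSE)
      gg_applied <- is.na(sph$mauchly_p) || sph$mauchly_p < sphericity_alpha
    }
    data.frame(effect = paste(eff, collapse = ":"),
               df1 = df1, df2 = df2, ss = ss, ss_err = ss_e,
               F = Fv, p = p, epsilon = sph$epsilon,
               mauchly_W = sph$mauchly_W, mauchly_p = sph$mauchly_p,
               gg_applied = gg_applied, p_gg = p_gg,
               p_reported = if (gg_applied) p_gg else p,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  class(res) <- c("rm_anova", "data.frame")
  attr(res, "n_subjects") <- n_subj
  res
}

# Orthonormal contrast columns for a k-level factor.
orthonorm_contrasts <- function(k) {
  cm <- stats::contr.helmert(k)
  cm %*% diag(1 / sqrt(colSums(cm^2)), ncol(cm))
}

# Subject x cell matrix for an effect (cells = combinations of the effect's
# factors, averaged over all other factors), plus GG epsilon and Mauchly's
# test on the orthonormal contrast scores.
contrast_sphericity <- function(d, dv, eff, subject) {
  n_subj <- nlevels(d[[subject]])
  arr <- tapply(d[[dv]], d[c(subject, eff)], mean)
  Y <- matrix(arr, nrow = n_subj)  # columns: first effect factor fastest
  M <- Reduce(function(A, B) kronecker(B, A),
              lapply(eff, function(f) orthonorm_contrasts(nlevels(d[[f]]))))
  q <- ncol(M)
  if (q == 1L)
    return(list(q = 1L, epsilon = 1,
                mauchly_W = NA_real_, mauchly_p = NA_real_))
  Z <- Y %*% M
  S <- stats::cov(Z)
  eps <- sum(diag(S))^2 / (q * sum(S * S))
  eps <- min(max(eps, 1 / q), 1)
  nd <- n_subj - 1L
  if (nd <= q) {
    # contrast covariance singular: Mauchly's test unavailable
    return(list(q = q, epsilon = eps,
                mauchly_W = NA_real_, mauchly_p = NA_real_))
  }
  # Mauchly's W with the standard two-term chi-square approximation
  W <- det(S) / (mean(diag(S)))^q
  rho <- 1 - (2 * q^2 + q + 2) / (6 * q * nd)
  w2 <- (q + 2) * (q - 1) * (q - 2) * (2 * q^3 + 6 * q^2 + 3 * q + 2) /
    (288 * q^2 * nd^2 * rho^2)
  z <- -nd * rho * log(W)
  f <- q * (q + 1) / 2 - 1
  p_m <- stats::pchisq(z, f, lower.tail = FALSE) +
    w2 * (stats::pchisq(z, f + 4, lower.tail = FALSE) -
            stats::pchisq(z, f, lower.tail = FALSE))
  list(q = q, epsilon = eps, mauchly_W = W, mauchly_p = p_m)
}

#' Within-subject confidence-interval half-width (Loftus-Masson)
#'
#' Half-width of the `level` confidence interval for condition means of a
#' within-subject factor: `t_{1-(1-level)/2, df} * sqrt(MS_SxC / n)`, where
#' `MS_SxC` is the subject-by-condition interaction mean square of the
#' subject x condition table (other factors averaged out) and `n` the
#' number of subjects.  The half-width is common to all conditions.
#'
#' @param data Long-format data frame.
#' @param dv Dependent-variable column name.
#' @param factor_col Within-subject factor of interest.
#' @param subject Subject column name.
#' @param level Confidence level (default 0.95).
#' @return List with `halfwidth`, `ms_error`, `df`, `n_subjects`.
#' @export
within_subject_ci <- function(data, dv = "value", factor_col,
                              subject = "subject", level = 0.95) {
  d <- data
  d[[subject]] <- factor(d[[subject]])
  d[[factor_col]] <- factor(d[[factor_col]])
  n <- nlevels(d[[subject]])
  k <- nlevels(d[[factor_col]])
  if (n < 2L) stop("at least two subjects required")
  cell <- tapply(d[[dv]], d[c(subject, factor_col)], mean)
  if (any(is.na(cell))) stop("design not balanced for ", factor_col)
  subj_m <- rowMeans(cell)
  cond_m <- colMeans(cell)
  grand <- mean(cell)
  resid <- cell - outer(subj_m, rep(1, k)) - outer(rep(1, n), cond_m) + grand
  df <- (n - 1L) * (k - 1L)
  ms <- sum(resid^2) / df
  hw <- stats::qt(1 - (1 - level) / 2, df) * sqrt(ms / n)
  list(halfwidth = hw, ms_error = ms, df = df, n_subjects = n)
}
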