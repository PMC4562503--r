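#' Build the trial list for one experiment
#'
#' * Experiment 1: 2 sizes x 2 thicknesses x 2 reference modalities,
#'   `reps` repetitions per condition and task (default 20, i.e. 320
#'   trials).  The task alternates between onset and offset judgments in
#'   blocks of 10 trials, onset first; conditions are randomised within the
#'   per-task trial pools.
#' * Experiment 2: 6 decay durations x 2 tasks, `reps` repetitions
#'   (default 10, i.e. 120 trials), fully randomised.
#' * Experiment 3: 4 disk sizes x 4 eccentricities, `reps` repetitions per
#'   condition and task (default 10, i.e. 320 trials), tasks in blocks of
#'   10 as in Experiment 1, with a fresh random displacement direction on
#'   every trial.
#'
#' @param experiment 1, 2 or 3.
#' @param reps Repetitions per condition (and task); defaults to the
#'   experiment's published count.
#' @param seed Optional integer seed for the randomisation.
#' @return Data frame with a `trial` index, `task`, and the experiment's
#'   condition columns.
#' @export
build_design <- function(experiment, reps = NULL, seed = NULL) {
  experiment <- as.integer(experiment)
  stopifnot(experiment %in% 1:3)
  if (is.null(reps)) reps <- c(20L, 10L, 10L)[experiment]
  stopifnot(reps > 0)
  with_seed(seed, switch(experiment,
                         design_exp1(reps),
                         design_exp2(reps),
                         design_exp3(reps)))
}

# Interleave per-task trial pools in alternating blocks of `block` trials,
# onset first; a pool not divisible by `block` ends with a shorter block.
interleave_task_blocks <- function(onset, offset, block = 10L) {
  n <- nrow(onset)
  stopifnot(n == nrow(offset))
  nb <- ceiling(n / block)
  out <- vector("list", 2L * nb)
  for (k in seq_len(nb)) {
    idx <- ((k - 1L) * block + 1L):min(k * block, n)
    out[[2L * k - 1L]] <- onset[idx, , drop = FALSE]
    out[[2L * k]] <- offset[idx, , drop = FALSE]
  }
  res <- do.call(rbind, out)
  res$trial <- seq_len(nrow(res))
  rownames(res) <- NULL
  res[, c("trial", setdiff(names(res), "trial"))]
}

design_exp1 <- function(reps) {
  conds <- expand.grid(size_px = c(100, 200), thickness_px = c(25, 75),
                       modality = c("auditory", "visual"),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  pool <- function(task) {
    p <- conds[rep(seq_len(nrow(conds)), each = reps), , drop = FALSE]
    p <- p[sample.int(nrow(p)), , drop = FALSE]
    p$task <- task
    p
  }
  interleave_task_blocks(pool("onset"), pool("offset"))
}

design_exp2 <- function(reps) {
  conds <- expand.grid(duration_s = seq(0.2, 1.2, by = 0.2),
                       task = c("onset", "offset"),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  d <- conds[rep(seq_len(nrow(conds)), each = reps), , drop = FALSE]
  d <- d[sample.int(nrow(d)), , drop = FALSE]
  d$trial <- seq_len(nrow(d))
  rownames(d) <- NULL
  d[, c("trial", "task", "duration_s")]
}

design_exp3 <- function(reps) {
  conds <- expand.grid(size_deg = c(1.5, 3, 4.5, 6),
                       ecc_deg = c(3, 4.5, 6, 7.5),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  pool <- function(task) {
    p <- conds[rep(seq_len(nrow(conds)), each = reps), , drop = FALSE]
    p <- p[sample.int(nrow(p)), , drop = FALSE]
    p$task <- task
    p
  }
  d <- interleave_task_blocks(pool("onset"), pool("offset"))
  d$direction <- stats::runif(nrow(d), 0, 2 * pi)
  d
}
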