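# Run an expression under a temporary RNG seed, restoring the caller's
# RNG state afterwards; seed = NULL uses (and advances) the global stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Generate a random black/white pixel matrix
#'
#' Each pixel is independently black (0) or white (1) with probability 0.5.
#'
#' @param side_px Matrix side length in pixels (positive integer).
#' @param seed Optional integer seed; the caller's RNG state is preserved.
#' @return Integer `side_px x side_px` matrix of 0/1.
#' @export
random_matrix <- function(side_px, seed = NULL) {
  stopifnot(side_px > 0)
  with_seed(seed,
    matrix(sample(c(0L, 1L), side_px * side_px, replace = TRUE),
           side_px, side_px))
}

#' Apply a single second-order transient
#'
#' Flips pixel polarity exactly on mask pixels and nowhere else; applying
#' the same mask twice restores the original matrix.
#'
#' @param m1 Binary (0/1) pixel matrix.
#' @param mask Logical or 0/1 matrix of the same dimensions.
#' @return The flipped matrix `m2` with `(m1 != m2) == mask`.
#' @export
apply_transient <- function(m1, mask) {
  if (!identical(dim(m1), dim(mask)))
    stop("m1 and mask must have identical dimensions")
  m2 <- m1
  m2[mask > 0] <- 1L - m1[mask > 0]
  m2
}

#' Build a transient pair of random-dot matrices
#'
#' Two matrices identical everywhere except inside the shape mask, where
#' all pixels reverse luminance polarity on the M1 -> M2 transition: the
#' single second-order transient that triggers the fading percept.
#'
#' @param spec An [annulus_spec()] or [disk_spec()].
#' @param geom A [display_geometry()].
#' @param seed Optional integer seed for the random matrix.
#' @return A list of class `transient_pair` with `m1`, `m2`, `mask`, `seed`.
#' @export
transient_pair <- function(spec, geom = display_geometry(), seed = NULL) {
  mask <- shape_mask(spec, geom)
  m1 <- random_matrix(geom$matrix_px, seed = seed)
  structure(list(m1 = m1, m2 = apply_transient(m1, mask), mask = mask,
                 seed = seed),
            class = "transient_pair")
}

#' Frame schedule for one stimulus sequence
#'
#' Times are in ms from sequence start.  The matrix transition happens at
#' `t_T` after a fixation interval drawn uniformly from `fixation_range`
#' (rounded to the frame grid); the reference stimulus starts at
#' `t_R_on = t_T + delta_t`.
#'
#' @param delta_t_ms Adjustable transition-to-reference interval, ms.
#' @param fixation_range Range of the randomised fixation interval, ms.
#' @param frame_ms Frame duration (default 10 ms, a 100 Hz display).
#' @param ref_duration_ms Reference-stimulus duration, ms.
#' @param tail_ms Time shown after the later of transition/reference end.
#' @return List of class `frame_schedule` with `frame_times`, `t_T`,
#'   `t_R_on`, `ref_duration_ms`, `fixation_ms`.
#' @export
frame_schedule <- function(delta_t_ms, fixation_range = c(1000, 1500),
                           frame_ms = 10, ref_duration_ms = 500,
                           tail_ms = 1500) {
  fix <- round(stats::runif(1, fixation_range[1], fixation_range[2]) /
                 frame_ms) * frame_ms
  t_T <- fix
  t_R <- t_T + delta_t_ms
  t_end <- max(t_T, t_R + ref_duration_ms) + tail_ms
  structure(list(frame_times = seq(0, t_end, by = frame_ms), t_T = t_T,
                 t_R_on = t_R, ref_duration_ms = ref_duration_ms,
                 fixation_ms = fix),
            class = "frame_schedule")
}

#' Render the contrast-decay proxy stimulus
#'
#' Inside the disk, pixel luminance at time `t` is
#' `0.5 + (pixel - 0.5) * (1 - f(t))` where `f` is the calibrated contrast
#' reduction (clamped to `[0, 1]`); a reduction of 1 yields a homogeneous
#' grey disk at the design mean of black and white pixels.  Outside the disk
#' frames equal the base matrix, so the regional mean luminance never
#' changes.  Grey levels are floats in `[0, 1]`; quantisation happens only
#' at export.
#'
#' @param base Binary (0/1) base matrix.
#' @param disk A [disk_spec()].
#' @param decay A calibrated [decay_params()] object.
#' @param frame_times_ms Frame times in ms.
#' @param t_T_ms Transition (decay onset) time in ms; `f` is 0 before it.
#' @param geom A [display_geometry()] matching `base`.
#' @return List of class `proxy_frames`: `frames` (list of matrices),
#'   `frame_times_ms`, `contrast_reduction`.
#' @export
proxy_frames <- function(base, disk, decay, frame_times_ms, t_T_ms = 0,
                         geom = display_geometry(matrix_px = nrow(base))) {
  stopifnot(inherits(disk, "disk_spec"), inherits(decay, "decay_params"))
  if (!isTRUE(decay$calibrated))
    stop("decay params must be calibrated (unit peak) before rendering")
  mask <- shape_mask(disk, geom)
  t_rel <- (frame_times_ms - t_T_ms) / 1000
  f <- ifelse(t_rel < 0, 0, impulse_response(pmax(t_rel, 0), decay))
  f <- pmin(pmax(f, 0), 1)
  g <- base + 0  # float copy
  frames <- lapply(f, function(ft) {
    fr <- g
    fr[mask] <- 0.5 + (g[mask] - 0.5) * (1 - ft)
    fr
  })
  structure(list(frames = frames, frame_times_ms = frame_times_ms,
                 contrast_reduction = f),
            class = "proxy_frames")
}
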