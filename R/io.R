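trial_schema <- c("subject", "experiment", "trial", "task", "delta_t_ms",
                  "n_reps", "converged")

#' Read and write trial-record tables
#'
#' CSV, comma-separated, UTF-8, header row, `.` decimal; times in ms.
#' `delta_t_ms` is serialised at 0.1 ms precision.  Unknown columns are
#' preserved in order; the required schema columns must be present.
#'
#' @param records Trial-record data frame.
#' @param path File path.
#' @return `read_trials()` returns the table; `write_trials()` returns
#'   `path` invisibly.
#' @export
write_trials <- function(records, path) {
  miss <- setdiff(trial_schema, names(records))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  records$delta_t_ms <- round(records$delta_t_ms, 1)
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(trial_schema, names(tab))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  tab
}

#' Run configuration
#'
#' A plain list of all pipeline defaults (geometry, annulus convention,
#' decay calibration, observer population, design repetitions, seed) that
#' round-trips losslessly through YAML.
#'
#' @param path File path for the YAML serialisation.
#' @param config A configuration list.
#' @return `default_config()`/`read_config()` return the list;
#'   `write_config()` returns `path` invisibly.
#' @export
default_config <- function() {
  list(
    geometry = list(matrix_px = 600L, matrix_deg = 19.15),
    convention = "diameter_diff",
    fill_dist = "width",
    decay = list(a_rate = 50, threshold = 0.01, rate_ratio = 1.2),
    observer = list(judgment_noise_sd_ms = 30, confirm_jnd_ms = 20,
                    criterion_jitter_sd = 0.1, offset_criterion = 0.01),
    design = list(reps_exp1 = 20L, reps_exp2 = 10L, reps_exp3 = 10L,
                  n_subjects_exp1 = 9L, n_subjects_exp2 = 4L,
                  n_subjects_exp3 = 9L),
    seed = 1L)
}

#' @rdname default_config
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname default_config
#' @export
read_config <- function(path) {
  yaml::read_yaml(path)
}

#' Export a single frame (or mask) as PNG
#'
#' Grey values in `[0, 1]` are written as 8-bit grayscale PNG; logical
#' masks are written as 0/255.
#'
#' @param frame Numeric matrix in `[0, 1]` or logical matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_frame_png <- function(frame, path) {
  png::writePNG(frame * 1.0, path)
  invisible(path)
}
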