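#' Split a signal into disjoint equal windows
#'
#' Deterministic windowing: the signal is cut into `n_windows` contiguous,
#' non-overlapping slices of `floor(L / n_windows)` samples each; the trailing
#' remainder (`L mod n_windows` samples) is dropped so all windows have equal
#' length. A 1,000,000-sample recording with the default `n_windows = 10`
#' yields ten windows of 100,000 samples.
#'
#' @param signal An [ae_signal()] or a numeric vector.
#' @param n_windows Number of slices (>= 1, <= signal length).
#' @param source_id Identifier stored with the window set.
#' @return A tibble of class `window_set` with columns `window_index` and
#'   `samples` (list of numeric vectors); attributes `window_length`,
#'   `source_id` and `fs` (when known).
#' @export
#' @examples
#' ws <- window_signal(ae_signal(rnorm(105), 100), n_windows = 10)
#' attr(ws, "window_length")
window_signal <- function(signal, n_windows = 10, source_id = "signal") {
  fs <- NA_real_
  if (inherits(signal, "ae_signal")) {
    fs <- signal$fs
    x <- signal$samples
  } else {
    x <- as.numeric(signal)
  }
  n_windows <- as.integer(n_windows)
  if (is.na(n_windows) || n_windows < 1) abort("`n_windows` must be >= 1.")
  if (n_windows > length(x)) {
    abort("`n_windows` exceeds the signal length.")
  }
  len <- length(x) %/% n_windows
  starts <- (seq_len(n_windows) - 1L) * len + 1L
  out <- tibble(
    window_index = seq_len(n_windows),
    samples = purrr::map(starts, ~ x[.x:(.x + len - 1L)])
  )
  attr(out, "window_length") <- len
  attr(out, "source_id") <- source_id
  attr(out, "fs") <- fs
  class(out) <- c("window_set", class(out))
  out
}

#' Window every recording in a dataset
#'
#' Applies [window_signal()] per recording (windowing is per file, never
#' across pooled recordings) and stacks the slices into one long tibble.
#'
#' @param dataset An `ae_dataset` from [simulate_dataset()].
#' @param n_windows Slices per recording.
#' @return A tibble with columns `signal_id`, `class`, `window_index`,
#'   `samples` (list) and `fs`.
#' @export
window_dataset <- function(dataset, n_windows = 10) {
  purrr::map2(dataset$signal, dataset$signal_id,
              ~ window_signal(.x, n_windows, source_id = .y)) |>
    purrr::map2(seq_len(nrow(dataset)), function(ws, i) {
      tibble(signal_id = dataset$signal_id[i], class = dataset$class[i],
             window_index = ws$window_index, samples = ws$samples,
             fs = attr(ws, "fs"))
    }) |>
    dplyr::bind_rows()
}
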