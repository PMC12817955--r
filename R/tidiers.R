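#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy / glance methods for differential-expression results
#'
#' `tidy()` returns the per-feature table as a plain tibble; `glance()`
#' returns a one-row model summary (feature counts and the range of size
#' factors).
#'
#' @param x A `de_result` from [de_stand_in()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.de_result <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "de_result")
  attr(out, "size_factors") <- NULL
  out
}

#' @rdname tidy.de_result
#' @export
glance.de_result <- function(x, ...) {
  sf <- attr(x, "size_factors")
  tibble::tibble(
    n_features = nrow(x),
    n_significant = sum(x$significant, na.rm = TRUE),
    n_up = sum(x$significant & x$log2fc > 0, na.rm = TRUE),
    n_down = sum(x$significant & x$log2fc < 0, na.rm = TRUE),
    min_size_factor = min(sf),
    max_size_factor = max(sf)
  )
}

#' Tidy / glance methods for the GC background test
#'
#' `tidy()` returns one row per observation (peak or background window)
#' with its GC fraction; `glance()` returns the test summary.
#'
#' @param x A `gc_bg_test` from [gc_background_test()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.gc_bg_test <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(set = "peak", gc_fraction = x$peak_gc),
    tibble::tibble(set = "background", gc_fraction = x$background_gc)
  )
}

#' @rdname tidy.gc_bg_test
#' @export
glance.gc_bg_test <- function(x, ...) {
  tibble::tibble(
    n_peaks = length(x$peak_gc),
    n_windows = length(x$background_gc),
    peak_median = x$peak_median,
    background_median = x$background_median,
    statistic = x$statistic,
    p_value = x$p_value
  )
}
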