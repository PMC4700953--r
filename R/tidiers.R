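#' Tidy and glance methods for scan results
#'
#' `tidy()` returns the candidate-region table (one row per merged region,
#' 1-based inclusive coordinates); `glance()` returns a one-row run summary.
#'
#' @param x A `fixation_scan` or `fst_scan` object.
#' @param ... Unused.
#' @return A tibble.
#' @name scan-tidiers
NULL

#' @rdname scan-tidiers
#' @export
tidy.fixation_scan <- function(x, ...) x$regions

#' @rdname scan-tidiers
#' @export
glance.fixation_scan <- function(x, ...) {
  tibble(
    n_sites = x$log$n_sites, n_windows = x$log$n_windows,
    n_flagged = x$log$n_flagged, n_regions = nrow(x$regions),
    tau = x$config$fixation_tau,
    window_size = x$config$window_size, step = x$config$step
  )
}

#' @rdname scan-tidiers
#' @export
tidy.fst_scan <- function(x, ...) x$regions

#' @rdname scan-tidiers
#' @export
glance.fst_scan <- function(x, ...) {
  tibble(
    n_sites = x$log$n_sites, n_windows = x$log$n_windows,
    n_flagged = x$log$n_flagged, n_regions = nrow(x$regions),
    threshold = x$threshold, quantile = x$config$fst_quantile,
    fst_multilocus = x$global$fst_multilocus,
    mean_site_fst = x$global$mean_site_fst,
    sd_site_fst = x$global$sd_site_fst,
    window_size = x$config$window_size, step = x$config$step
  )
}

#' Export a candidate-region table as BED6
#'
#' @param regions A region tibble from [tidy()] on a scan result.
#' @param score_col Column used for the BED score (scaled to 0-1000).
#' @return A tibble in BED6 column order (0-based half-open coordinates).
#' @export
regions_as_bed <- function(regions, score_col = c("min_af", "max_fst")) {
  score_col <- intersect(score_col, names(regions))[1]
  if (is.na(score_col)) abort("no usable score column in `regions`")
  tibble(
    chrom = regions$chrom,
    start = regions$start - 1L,
    end = regions$end,
    name = sprintf("region_%d", seq_len(nrow(regions))),
    score = as.integer(round(1000 * pmin(pmax(regions[[score_col]], 0), 1))),
    strand = "."
  )
}
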