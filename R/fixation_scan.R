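#' Across-population minimum allele frequency
#'
#' The decision statistic of the parallel-fixation screen: the same allele is
#' elevated in *all* populations exactly when the minimum of the per-population
#' frequencies clears the threshold. Any missing frequency is an error —
#' a parallel claim must rest on every population.
#'
#' @param afs Numeric vector of per-population allele frequencies
#'   (length >= 2, no missing values).
#' @return `min(afs)`.
#' @examples
#' min_af_statistic(c(0.95, 0.91, 0.89))  # 0.89
#' @export
min_af_statistic <- function(afs) {
  if (!is.numeric(afs) || length(afs) < 2L) {
    abort("`afs` must be a numeric vector over at least 2 populations")
  }
  if (anyNA(afs)) abort("missing allele frequency: statistic undefined")
  min(afs)
}

#' Flag windows with parallel elevated allele frequency
#'
#' A window is flagged when every population's window-mean alternate-allele
#' frequency is at least `tau` (inclusive, so a window sitting exactly at the
#' threshold counts). Windows with a missing mean in any population are never
#' flagged.
#'
#' @param stats Named list of [window_mean()] outputs, one per population, on
#'   one shared grid.
#' @param tau Frequency threshold (default 0.85).
#' @return The grid with one `af_<pop>` column per population, `min_af`, and
#'   logical `flagged`.
#' @export
flag_fixation_windows <- function(stats, tau = 0.85) {
  assert_scalar_number(tau, "tau", min = 0, max = 1)
  if (!is.list(stats) || length(stats) < 2L) {
    abort("`stats` must be a named list of window statistics for >= 2 populations")
  }
  if (is.null(names(stats)) || any(names(stats) == "")) {
    abort("`stats` must be named by population")
  }
  base <- stats[[1]]
  for (s in stats[-1]) {
    if (nrow(s) != nrow(base) || !all(s$start == base$start) ||
        !all(s$chrom == base$chrom)) {
      abort("window statistics do not share one grid")
    }
  }
  out <- base[, c("chrom", "start", "end")]
  vals <- vapply(stats, function(s) s$value, numeric(nrow(base)))
  vals <- matrix(vals, nrow = nrow(base),
                 dimnames = list(NULL, names(stats)))
  for (p in names(stats)) out[[paste0("af_", p)]] <- vals[, p]
  any_na <- rowSums(is.na(vals)) > 0
  out$min_af <- ifelse(any_na, NA_real_, do.call(pmin, as.data.frame(vals)))
  out$flagged <- !any_na & out$min_af >= tau
  out
}

merge_window_runs <- function(win, flagged, step, gap_tolerance = 0) {
  idx <- which(flagged)
  if (length(idx) == 0L) return(list())
  new_run <- c(TRUE,
               diff(win$start[idx]) > step * (1 + gap_tolerance) |
                 win$chrom[idx][-1] != win$chrom[idx][-length(idx)])
  split(idx, cumsum(new_run))
}

#' Merge flagged windows into candidate parallel-fixation regions
#'
#' Maximal runs of grid-adjacent flagged windows (consecutive starts on one
#' chromosome) become regions spanning the union of their members. Each
#' population's region-level frequency is the mean over member windows (the
#' per-window maximum is also reported). Coordinates are returned 1-based
#' inclusive, the convention of published candidate-region tables.
#'
#' @param flags Output of [flag_fixation_windows()].
#' @param step Grid step in bp (default: inferred from the grid).
#' @param gap_tolerance Number of unflagged grid steps allowed inside a run
#'   (default 0, strict adjacency).
#' @return A tibble of regions: chrom, start, end (1-based inclusive),
#'   n_windows, `af_<pop>` means, `max_af_<pop>`, min_af.
#' @export
merge_flagged_windows <- function(flags, step = NULL, gap_tolerance = 0) {
  if (is.null(step)) {
    step <- if (nrow(flags) >= 2L) min(diff(unique(sort(flags$start)))) else 1L
  }
  af_cols <- grep("^af_", names(flags), value = TRUE)
  runs <- merge_window_runs(flags, flags$flagged, step, gap_tolerance)
  width <- if (nrow(flags)) flags$end[1] - flags$start[1] else 0L
  out <- purrr::map_dfr(runs, function(idx) {
    r <- tibble(
      chrom = flags$chrom[idx[1]],
      start = flags$start[idx[1]] + 1L,
      end = flags$start[idx[length(idx)]] + width,
      n_windows = length(idx)
    )
    for (p in af_cols) {
      r[[p]] <- mean(flags[[p]][idx])
      r[[sub("^af_", "max_af_", p)]] <- max(flags[[p]][idx])
    }
    r$min_af <- min(vapply(af_cols, function(p) r[[p]], numeric(1)))
    r
  })
  if (nrow(out)) out <- dplyr::arrange(out, .data$chrom, .data$start)
  out
}
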