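#' Build an overlapping sliding-window grid for one chromosome
#'
#' Windows of `window_size` bp advance in steps of `step` bp, anchored at
#' coordinate 0; only full-width windows are kept, so a chromosome shorter
#' than one window yields an empty grid. The default 40 kb / 5 kb frame gives
#' each interior site membership in 8 consecutive windows, smoothing
#' locus-to-locus noise in per-site statistics.
#'
#' @param chrom_length Chromosome length in bp.
#' @param window_size Window width in bp (default 40000).
#' @param step Offset between consecutive window starts in bp (default 5000).
#' @param chrom Chromosome label carried into the output (default "chr1").
#' @return A tibble with columns `chrom`, `start`, `end` (0-based,
#'   half-open); `floor((L - W)/S) + 1` rows when `L >= W`.
#' @examples
#' nrow(make_window_grid(100000))  # 13 windows
#' @export
make_window_grid <- function(chrom_length, window_size = 40000, step = 5000,
                             chrom = "chr1") {
  assert_scalar_number(chrom_length, "chrom_length", min = 1)
  assert_scalar_number(window_size, "window_size", min = 1)
  assert_scalar_number(step, "step", min = 1)
  if (step > window_size) abort("`step` must not exceed `window_size`")
  if (chrom_length < window_size) {
    return(tibble(chrom = character(), start = integer(), end = integer()))
  }
  starts <- seq(0L, as.integer(chrom_length - window_size), by = as.integer(step))
  tibble(chrom = chrom, start = starts, end = starts + as.integer(window_size))
}

#' Build a window grid across several chromosomes
#'
#' @param chrom_lengths Named vector of chromosome lengths.
#' @inheritParams make_window_grid
#' @return Row-bound grids for every chromosome.
#' @export
make_genome_grid <- function(chrom_lengths, window_size = 40000, step = 5000) {
  purrr::map_dfr(names(chrom_lengths), function(ch) {
    make_window_grid(chrom_lengths[[ch]], window_size, step, chrom = ch)
  })
}

# windowed sum/count for one chromosome via cumulative sums; positions must
# already be sorted
window_accumulate <- function(pos, value, starts, width) {
  keep <- !is.na(value)
  pk <- pos[keep]
  cs <- c(0, cumsum(value[keep]))
  lo <- findInterval(starts - 0.5, pk)
  hi <- findInterval(starts + width - 0.5, pk)
  list(sum = cs[hi + 1L] - cs[lo + 1L], n = hi - lo)
}

#' Average a per-site track over an overlapping window grid
#'
#' Each site contributes to every window covering it, so consecutive windows
#' share most of their support. Windows with fewer than `min_snps`
#' contributing (non-missing) sites get a missing value rather than an
#' unstable mean.
#'
#' @param track A data frame with columns `pos` (0-based, sorted within
#'   chromosome), `value`, and optionally `chrom` (required when `grid` spans
#'   several chromosomes).
#' @param grid A window grid from [make_window_grid()] or
#'   [make_genome_grid()].
#' @param min_snps Minimum contributing sites per window (default 5).
#' @return The grid with `value` (window mean or `NA`) and `n_snps` columns.
#' @export
window_mean <- function(track, grid, min_snps = 5) {
  assert_scalar_number(min_snps, "min_snps", min = 0)
  if (!all(c("pos", "value") %in% names(track))) {
    abort("`track` needs `pos` and `value` columns")
  }
  chroms <- unique(grid$chrom)
  if (!"chrom" %in% names(track)) {
    if (length(chroms) > 1L) abort("`track` needs a `chrom` column for a multi-chromosome grid")
    track$chrom <- if (length(chroms)) chroms else NA_character_
  }
  assert_sorted_positions(track$pos, track$chrom)
  width <- if (nrow(grid)) grid$end[1] - grid$start[1] else 0L
  out <- purrr::map_dfr(chroms, function(ch) {
    g <- grid[grid$chrom == ch, , drop = FALSE]
    t <- track[track$chrom == ch, , drop = FALSE]
    acc <- window_accumulate(t$pos, t$value, g$start, width)
    g$value <- ifelse(acc$n >= min_snps & acc$n > 0, acc$sum / acc$n, NA_real_)
    g$n_snps <- acc$n
    g
  })
  out
}

#' Export a window statistic as a BEDGRAPH-style tibble
#'
#' @param winstat Output of [window_mean()].
#' @return Tibble with chrom, start, end (0-based half-open), value, n_snps;
#'   windows with missing values are kept with `NA` so track alignment is
#'   explicit.
#' @export
as_bedgraph <- function(winstat) {
  winstat[, c("chrom", "start", "end", "value", "n_snps")]
}
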