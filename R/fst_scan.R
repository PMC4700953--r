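# Weir & Cockerham (1984) variance components for two populations at one or
# more biallelic sites. Sample sizes arrive as haplotype-equivalent counts
# and are converted to diploid-individual counts; heterozygosity enters as
# its Hardy-Weinberg expectation 2p(1-p), the only version available when one
# side is pool-sequenced (no genotypes observed).
wc_components <- function(p1, p2, n1, n2) {
  if (any(c(n1, n2) < 2)) abort("haplotype sample sizes must be >= 2")
  ni1 <- n1 / 2
  ni2 <- n2 / 2
  r <- 2
  nbar <- (ni1 + ni2) / 2
  nsum <- ni1 + ni2
  nc <- (nsum - (ni1^2 + ni2^2) / nsum) / (r - 1)
  pbar <- (ni1 * p1 + ni2 * p2) / nsum
  s2 <- (ni1 * (p1 - pbar)^2 + ni2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (ni1 * 2 * p1 * (1 - p1) + ni2 * 2 * p2 * (1 - p2)) / nsum
  a <- nbar / nc *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  list(a = a, b = b, c = cc)
}

#' Per-site Weir-Cockerham Fst between two populations
#'
#' The Weir & Cockerham (1984) estimator `theta = a / (a + b + c)` computed
#' from the two allele frequencies and haplotype-equivalent sample sizes.
#' Small negative values are legitimate (the estimator is unbiased around
#' zero under no differentiation); sites where both populations are fixed
#' for the same allele have no variance to partition and return `NA`.
#'
#' @param p1,p2 Alternate-allele frequencies in the two populations
#'   (vectors allowed).
#' @param n1,n2 Haplotype-equivalent sample sizes (genotyped: 2 x
#'   individuals; pooled: read count, optionally capped); must be >= 2, and
#'   the combined size must exceed 4 for the variance components to exist.
#' @return Per-site theta-hat; `NA` where undefined.
#' @seealso [wc_fst_global()] for the multi-locus estimate,
#'   [hudson_fst_site()] for the cross-check estimator.
#' @examples
#' wc_fst_site(1, 0, 1000, 1000)  # near 1: fixed difference
#' @export
wc_fst_site <- function(p1, p2, n1, n2) {
  k <- wc_components(p1, p2, n1, n2)
  denom <- k$a + k$b + k$c
  out <- ifelse(denom == 0, NA_real_, k$a / denom)
  ifelse(is.nan(out), NA_real_, out)
}

#' Multi-locus Weir-Cockerham Fst
#'
#' The 1984 multi-locus estimator: variance components summed over loci
#' before the ratio is taken, `sum(a) / sum(a + b + c)`. This — not the
#' arithmetic mean of per-site ratios, which is dragged down by
#' low-information sites — is the genome-wide Fst figure, and it recovers
#' the drift parameter of the Balding-Nichols generator.
#'
#' @inheritParams wc_fst_site
#' @return A single number.
#' @export
wc_fst_global <- function(p1, p2, n1, n2) {
  k <- wc_components(p1, p2, n1, n2)
  ok <- !is.na(k$a) & !is.na(k$b) & !is.na(k$c)
  sum(k$a[ok]) / sum(k$a[ok] + k$b[ok] + k$c[ok])
}

#' Per-site Hudson Fst (cross-check estimator)
#'
#' The mismatch-based two-population estimator: between-population allele
#' sharing corrected for finite within-population sampling. Used as an
#' independent check on the Weir-Cockerham values; the two estimators agree
#' closely at balanced, moderate sample sizes and diverge in known ways when
#' sizes are unequal.
#'
#' @inheritParams wc_fst_site
#' @return Per-site estimate; `NA` where the denominator vanishes.
#' @export
hudson_fst_site <- function(p1, p2, n1, n2) {
  if (any(c(n1, n2) < 2)) abort("haplotype sample sizes must be >= 2")
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  ifelse(den == 0, NA_real_, num / den)
}

#' Empirical percentile P of a window statistic
#'
#' `P = (# windows with value >= obs) / (# windows with a defined value)`,
#' self-inclusive, so the most extreme window has `P = 1/N`, never 0.
#'
#' @param values Statistic across all windows (missing entries ignored).
#' @param obs Observed value(s) to score.
#' @return P for each element of `obs`.
#' @examples
#' empirical_p(c(1, 2, 3, 4), 3)  # 0.5
#' @export
empirical_p <- function(values, obs) {
  v <- values[!is.na(values)]
  if (length(v) == 0L) abort("`values` must contain at least one defined value")
  vapply(obs, function(o) mean(v >= o), numeric(1))
}

#' Nearest-rank top-quantile threshold
#'
#' Returns the threshold `t` such that `{v >= t}` contains exactly
#' `ceiling((1 - q) * N)` windows when values are distinct (ties at `t` are
#' flagged inclusively, which can only enlarge the set). This reproduces a
#' "top 1%" outlier rule as a set-size contract rather than an interpolated
#' quantile.
#'
#' @param values Window statistic (missing entries ignored).
#' @param q Quantile, e.g. 0.99 for the top 1% (default).
#' @return The threshold value.
#' @export
top_quantile_threshold <- function(values, q = 0.99) {
  assert_scalar_number(q, "q")
  if (q <= 0 || q >= 1) abort("`q` must lie strictly between 0 and 1")
  v <- values[!is.na(values)]
  if (length(v) == 0L) abort("`values` must contain at least one defined value")
  # epsilon guards the ceiling against float noise in (1 - q) * N
  k <- max(1L, ceiling((1 - q) * length(v) - 1e-9))
  sort(v, decreasing = TRUE)[k]
}

#' Cluster windows above a threshold into divergence regions
#'
#' Maximal runs of grid-adjacent windows with `value >= threshold` are merged
#' into regions. Each region reports the maximum member-window mean Fst, the
#' minimum member-window empirical percentile P (computed over all defined
#' windows of the scan), and its member count. Coordinates are 1-based
#' inclusive.
#'
#' @param winstat A [window_mean()] output for the Fst track.
#' @param threshold Flagging threshold, e.g. from
#'   [top_quantile_threshold()].
#' @param step Grid step (default: inferred).
#' @param gap_tolerance Unflagged steps allowed within a run (default 0).
#' @return Tibble of regions: chrom, start, end, n_windows, max_fst, min_p.
#' @export
cluster_divergent_windows <- function(winstat, threshold, step = NULL,
                                      gap_tolerance = 0) {
  if (is.null(step)) {
    step <- if (nrow(winstat) >= 2L) min(diff(unique(sort(winstat$start)))) else 1L
  }
  flagged <- !is.na(winstat$value) & winstat$value >= threshold
  pvals <- rep(NA_real_, nrow(winstat))
  defined <- !is.na(winstat$value)
  if (any(defined)) {
    pvals[defined] <- empirical_p(winstat$value, winstat$value[defined])
  }
  width <- if (nrow(winstat)) winstat$end[1] - winstat$start[1] else 0L
  runs <- merge_window_runs(winstat, flagged, step, gap_tolerance)
  out <- purrr::map_dfr(runs, function(idx) {
    tibble(
      chrom = winstat$chrom[idx[1]],
      start = winstat$start[idx[1]] + 1L,
      end = winstat$start[idx[length(idx)]] + width,
      n_windows = length(idx),
      max_fst = max(winstat$value[idx]),
      min_p = min(pvals[idx])
    )
  })
  if (nrow(out)) out <- dplyr::arrange(out, .data$chrom, .data$start)
  out
}

#' Default chicken chromosome size classes
#'
#' GGA1-5 are macrochromosomes, GGA6-10 intermediate (conventionally
#' excluded from macro/micro contrasts), GGA11 and above microchromosomes;
#' non-numeric labels (sex chromosomes, linkage groups) fall in "other".
#' Override by supplying your own map to [stratified_mean_fst()].
#'
#' @param chroms Character vector of chromosome labels (e.g. "chr1", "GGA7",
#'   "12").
#' @return Named character vector mapping each label to
#'   macro/intermediate/micro/other.
#' @export
chicken_chrom_classes <- function(chroms) {
  num <- suppressWarnings(as.integer(sub("^(chr|GGA|gga)", "", chroms)))
  cls <- dplyr::case_when(
    is.na(num) ~ "other",
    num <= 5 ~ "macro",
    num <= 10 ~ "intermediate",
    TRUE ~ "micro"
  )
  setNames(cls, chroms)
}

#' Mean windowed Fst stratified by chromosome class
#'
#' Recombination differs strongly between chicken macro- and
#' microchromosomes, which could shift the differentiation background; this
#' summary makes the contrast explicit before a genome-wide outlier
#' threshold is trusted.
#'
#' @param winstat Windowed Fst ([window_mean()] output with a `chrom`
#'   column).
#' @param chrom_classes Named character vector mapping every chromosome in
#'   `winstat` to a class (default: [chicken_chrom_classes()]).
#' @return Tibble: class, mean_fst (NA when the class has no defined
#'   window), n_windows.
#' @export
stratified_mean_fst <- function(winstat, chrom_classes = NULL) {
  chrom_classes <- chrom_classes %||% chicken_chrom_classes(unique(winstat$chrom))
  missing_cls <- setdiff(unique(winstat$chrom), names(chrom_classes))
  if (length(missing_cls)) {
    abort(sprintf("chromosome not classified: %s", missing_cls[1]))
  }
  winstat |>
    mutate(class = unname(chrom_classes[.data$chrom])) |>
    group_by(.data$class) |>
    summarise(
      mean_fst = if (any(!is.na(.data$value))) mean(.data$value, na.rm = TRUE) else NA_real_,
      n_windows = sum(!is.na(.data$value)),
      .groups = "drop"
    )
}

#' Per-site expected heterozygosity
#'
#' `2p(1-p)` from a frequency track; window-average it with [window_mean()]
#' to obtain the heterozygosity track, expected to dip where a sweep has
#' removed variation.
#'
#' @param track A frequency track tibble (chrom, pos, freq, ...).
#' @return Tibble chrom, pos, value.
#' @export
expected_heterozygosity <- function(track) {
  tibble(chrom = track$chrom, pos = track$pos,
         value = 2 * track$freq * (1 - track$freq))
}
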