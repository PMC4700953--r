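#' Per-site alternate-allele frequency from diploid genotypes
#'
#' Frequency is the dosage sum over the chosen samples divided by twice the
#' number of non-missing genotypes; sites where every chosen genotype is
#' missing get a missing frequency. The alternate (non-reference) allele is
#' counted in every population, so elevated frequencies refer to the same
#' allele everywhere — the premise of a parallel-fixation comparison.
#'
#' @param gm A `genotype_matrix` from [read_vcf()].
#' @param samples Character vector of sample ids (default: all samples).
#' @param pop_id Label stored in the `pop` column (default "pop").
#' @return A frequency track tibble: chrom, pos (0-based), freq, n_obs
#'   (haplotypes observed), pop.
#' @export
genotype_freq <- function(gm, samples = NULL, pop_id = "pop") {
  stopifnot(inherits(gm, "genotype_matrix"))
  samples <- samples %||% gm$samples
  unknown <- setdiff(samples, gm$samples)
  if (length(unknown)) abort(sprintf("unknown sample id: %s", unknown[1]))
  if (length(samples) == 0L) abort("`samples` must be non-empty")
  d <- gm$dosage[, samples, drop = FALSE]
  n_called <- rowSums(!is.na(d))
  freq <- ifelse(n_called > 0, rowSums(d, na.rm = TRUE) / (2 * n_called), NA_real_)
  tibble(chrom = gm$sites$chrom, pos = gm$sites$pos, freq = freq,
         n_obs = 2L * n_called, pop = pop_id)
}

#' Per-site alternate-allele frequency from pooled read counts
#'
#' `freq = alt / (alt + ref)`; sites masked for the pool (depth below the
#' ingestion threshold) get a missing frequency. `n_obs` is the read count,
#' the haplotype-equivalent sample size of a pooled estimate.
#'
#' @param pc A `pool_counts` table from [read_pool_counts()].
#' @param pool Pool identifier.
#' @return A frequency track tibble (chrom, pos, freq, n_obs, pop).
#' @export
pool_freq <- function(pc, pool) {
  stopifnot(inherits(pc, "pool_counts"))
  if (!pool %in% pc$pools) abort(sprintf("unknown pool: %s", pool))
  ref <- pc$ref_count[, pool]
  alt <- pc$alt_count[, pool]
  tot <- ref + alt
  freq <- ifelse(pc$masked[, pool] | tot == 0, NA_real_, alt / tot)
  tibble(chrom = pc$sites$chrom, pos = pc$sites$pos, freq = freq,
         n_obs = as.integer(tot), pop = pool)
}

#' Average frequency tracks into one group track
#'
#' Unweighted mean across tracks at each site of a shared site frame. A site
#' missing in any contributing track is missing in the group track, so a
#' group-level claim never rests on a subset of the populations. `n_obs`
#' sums the contributing observation counts.
#'
#' @param tracks List of frequency-track tibbles aligned to one site frame.
#' @param pop_id Label of the combined track (default "group").
#' @return A frequency track tibble.
#' @export
group_mean_freq <- function(tracks, pop_id = "group") {
  if (!is.list(tracks) || length(tracks) < 1L) abort("`tracks` must be a non-empty list")
  base <- tracks[[1]]
  for (t in tracks[-1]) {
    if (nrow(t) != nrow(base) ||
        !all(t$chrom == base$chrom) || !all(t$pos == base$pos)) {
      abort("tracks are not aligned to a common site frame")
    }
  }
  fmat <- vapply(tracks, function(t) t$freq, numeric(nrow(base)))
  fmat <- matrix(fmat, nrow = nrow(base))
  nmat <- matrix(vapply(tracks, function(t) as.numeric(t$n_obs), numeric(nrow(base))),
                 nrow = nrow(base))
  any_na <- rowSums(is.na(fmat)) > 0
  tibble(
    chrom = base$chrom, pos = base$pos,
    freq = ifelse(any_na, NA_real_, rowMeans(fmat)),
    n_obs = ifelse(any_na, NA_integer_, as.integer(rowSums(nmat))),
    pop = pop_id
  )
}

#' Per-site frequency of every population in a haplotype panel
#'
#' @param panel A `haplotype_panel`.
#' @return A frequency track tibble with one block per population
#'   (derived-allele frequency; `n_obs` = chromosomes).
#' @export
panel_freq <- function(panel) {
  stopifnot(inherits(panel, "haplotype_panel"))
  purrr::map_dfr(unique(panel$pop), function(p) {
    rows <- which(panel$pop == p)
    tibble(chrom = panel$chrom, pos = panel$positions,
           freq = colMeans(panel$hap[rows, , drop = FALSE]),
           n_obs = length(rows), pop = p)
  })
}
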