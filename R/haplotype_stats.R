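#' Convert a phased genotype matrix to a haplotype panel
#'
#' Haplotype statistics require known phase; an unphased matrix is a hard
#' error rather than something to guess around. Polarization follows the
#' reference allele: REF is taken as ancestral (0), ALT as derived (1), the
#' convention the synthetic fixtures are written with.
#'
#' @param gm A phased `genotype_matrix` (see [read_vcf()]).
#' @param sample_pops Named character vector mapping sample id to population
#'   label (default: everything in one population "all").
#' @return A `haplotype_panel`.
#' @export
as_haplotype_panel <- function(gm, sample_pops = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (!gm$phased || is.null(gm$haplotypes)) {
    abort("genotypes are not phased: haplotype statistics are undefined")
  }
  chroms <- unique(gm$sites$chrom)
  if (length(chroms) != 1L) {
    abort("panel construction expects a single chromosome; split the matrix first")
  }
  sample_pops <- sample_pops %||% setNames(rep("all", length(gm$samples)), gm$samples)
  pop <- rep(unname(sample_pops[gm$samples]), each = 2L)
  if (anyNA(pop)) abort("every sample needs a population label")
  structure(
    list(chrom = chroms, positions = gm$sites$pos,
         hap = t(gm$haplotypes), pop = pop),
    class = "haplotype_panel"
  )
}

# one-direction EHH walk from a core site; NA alleles are treated as a
# private allele so missing data always breaks homozygosity
ehh_walk <- function(hap, positions, core, allele, dirstep,
                     truncation = 0.05, max_gap = 2e5) {
  carriers <- which(hap[, core] == allele)
  n <- length(carriers)
  if (n < 2L) return(NULL)
  npair <- n * (n - 1)
  pos_out <- positions[core]
  ehh_out <- 1
  grp <- rep(1L, n)
  stop_reason <- "edge"
  j <- core + dirstep
  while (j >= 1L && j <= ncol(hap)) {
    if (abs(positions[j] - positions[j - dirstep]) > max_gap) {
      stop_reason <- "gap"
      break
    }
    al <- hap[carriers, j]
    al[is.na(al)] <- 2L
    key <- grp * 3L + al
    grp <- match(key, unique(key))
    tab <- tabulate(grp)
    e <- sum(tab * (tab - 1)) / npair
    pos_out <- c(pos_out, positions[j])
    ehh_out <- c(ehh_out, e)
    if (e < truncation) {
      stop_reason <- "truncated"
      break
    }
    j <- j + dirstep
  }
  list(pos = pos_out, ehh = ehh_out, stop = stop_reason, n = n)
}

#' Extended haplotype homozygosity around a core site
#'
#' EHH at distance x is the probability that two randomly drawn carrier
#' chromosomes of the core allele are identical over every site between the
#' core and x. It is 1 at the core by construction and can only decrease
#' outward. The walk stops when EHH drops below `truncation`, at a physical
#' gap larger than `max_gap`, or at the chromosome edge.
#'
#' @param panel A `haplotype_panel`.
#' @param core Site index of the core SNP.
#' @param allele `"derived"` (1) or `"ancestral"` (0) carrier class.
#' @param truncation EHH level at which the walk stops (default 0.05).
#' @param max_gap Maximum tolerated inter-site gap in bp (default 200000).
#' @return A tibble (direction, pos, offset, ehh) with per-direction stop
#'   reasons in the `stops` attribute, or `NULL` when fewer than 2
#'   chromosomes carry the allele.
#' @export
ehh <- function(panel, core, allele = c("derived", "ancestral"),
                truncation = 0.05, max_gap = 2e5) {
  stopifnot(inherits(panel, "haplotype_panel"))
  allele <- match.arg(allele)
  al <- if (allele == "derived") 1L else 0L
  up <- ehh_walk(panel$hap, panel$positions, core, al, -1L, truncation, max_gap)
  down <- ehh_walk(panel$hap, panel$positions, core, al, +1L, truncation, max_gap)
  if (is.null(up)) return(NULL)
  cpos <- panel$positions[core]
  out <- dplyr::bind_rows(
    tibble(direction = "upstream", pos = up$pos, offset = up$pos - cpos,
           ehh = up$ehh),
    tibble(direction = "downstream", pos = down$pos, offset = down$pos - cpos,
           ehh = down$ehh)
  )
  attr(out, "stops") <- c(upstream = up$stop, downstream = down$stop)
  attr(out, "n_carriers") <- up$n
  out
}

trapezoid <- function(x, y) {
  if (length(x) < 2L) return(0)
  sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
}

ihh_one <- function(hap, positions, core, al, truncation, max_gap) {
  up <- ehh_walk(hap, positions, core, al, -1L, truncation, max_gap)
  down <- ehh_walk(hap, positions, core, al, +1L, truncation, max_gap)
  if (is.null(up) || is.null(down)) return(list(ihh = NA_real_, ok = FALSE))
  # a curve that runs into the edge or a gap while still above the
  # truncation level is incomplete; the integral would be biased low
  ok <- up$stop == "truncated" && down$stop == "truncated"
  cpos <- positions[core]
  ihh <- trapezoid(abs(up$pos - cpos), up$ehh) +
    trapezoid(abs(down$pos - cpos), down$ehh)
  list(ihh = ihh, ok = ok)
}

#' Unstandardized integrated haplotype scores for a population panel
#'
#' For every core SNP with derived-allele frequency inside
#' `[maf_min, 1 - maf_min]`, integrates the EHH curve of each core-allele
#' class over physical distance (trapezoid rule, both directions) and takes
#' `ihs_raw = ln(ihh_ancestral / ihh_derived)`. Long derived haplotypes — the
#' mark of an incomplete sweep — give negative raw scores. Cores whose
#' curves run off the chromosome or into a gap larger than `max_gap` before
#' reaching the truncation level are reported with a missing score, as are
#' cores with fewer than 2 carriers of either allele.
#'
#' @param panel A `haplotype_panel` (one population; subset first if
#'   needed).
#' @param maf_min Minor-allele-frequency cutoff for usable cores
#'   (default 0.05).
#' @param truncation EHH truncation level (default 0.05).
#' @param max_gap Maximum tolerated inter-site gap in bp (default 200000).
#' @return Tibble: chrom, pos, daf, ihh_a, ihh_d, ihs_raw.
#' @seealso [standardize_ihs()], [windowed_abs_ihs()]
#' @export
ihs <- function(panel, maf_min = 0.05, truncation = 0.05, max_gap = 2e5) {
  stopifnot(inherits(panel, "haplotype_panel"))
  hap <- panel$hap
  daf <- colMeans(hap, na.rm = TRUE)
  usable <- which(daf >= maf_min & daf <= 1 - maf_min)
  rows <- purrr::map_dfr(usable, function(core) {
    anc <- ihh_one(hap, panel$positions, core, 0L, truncation, max_gap)
    der <- ihh_one(hap, panel$positions, core, 1L, truncation, max_gap)
    raw <- NA_real_
    if (anc$ok && der$ok && !is.na(anc$ihh) && !is.na(der$ihh) &&
        anc$ihh > 0 && der$ihh > 0) {
      raw <- log(anc$ihh / der$ihh)
    }
    tibble(chrom = panel$chrom, pos = panel$positions[core],
           daf = daf[core], ihh_a = anc$ihh, ihh_d = der$ihh, ihs_raw = raw)
  })
  if (nrow(rows) == 0L) {
    rows <- tibble(chrom = character(), pos = integer(), daf = numeric(),
                   ihh_a = numeric(), ihh_d = numeric(), ihs_raw = numeric())
  }
  rows
}

#' Standardize iHS within derived-allele-frequency bins
#'
#' Raw log-ratios depend systematically on the derived-allele frequency, so
#' scores are centered and scaled within equal-width frequency bins:
#' `ihs_std = (raw - bin mean) / bin SD`. Bins with fewer than 2 defined raw
#' scores, or zero spread, leave their members unstandardized (missing, with
#' a warning in the degenerate-spread case).
#'
#' @param sites Output of [ihs()].
#' @param n_bins Number of equal-width bins on (0, 1) (default 20).
#' @return `sites` with an added `ihs_std` column.
#' @export
standardize_ihs <- function(sites, n_bins = 20) {
  assert_scalar_number(n_bins, "n_bins", min = 1)
  bin <- cut(sites$daf, breaks = seq(0, 1, length.out = n_bins + 1),
             include.lowest = TRUE)
  std <- rep(NA_real_, nrow(sites))
  degenerate <- FALSE
  for (b in levels(bin)) {
    in_bin <- which(bin == b & !is.na(sites$ihs_raw))
    if (length(in_bin) < 2L) next
    s <- sd(sites$ihs_raw[in_bin])
    if (s == 0) {
      degenerate <- TRUE
      next
    }
    std[in_bin] <- (sites$ihs_raw[in_bin] - mean(sites$ihs_raw[in_bin])) / s
  }
  if (degenerate) warn("bin with zero iHS spread left unstandardized")
  sites$ihs_std <- std
  sites
}

#' Window-averaged |iHS| track
#'
#' Mean absolute standardized iHS per window — extreme scores of either sign
#' mark sweeps, so the magnitude is averaged.
#'
#' @param sites Output of [standardize_ihs()].
#' @param grid A window grid.
#' @param min_snps Minimum scored sites per window (default 5).
#' @return A [window_mean()] window statistic.
#' @export
windowed_abs_ihs <- function(sites, grid, min_snps = 5) {
  if (is.null(sites$ihs_std)) abort("run standardize_ihs() first")
  track <- tibble(chrom = sites$chrom, pos = sites$pos,
                  value = abs(sites$ihs_std))
  window_mean(track, grid, min_snps = min_snps)
}

#' Subset a haplotype panel to one population
#'
#' @param panel A `haplotype_panel`.
#' @param pop Population label.
#' @return A `haplotype_panel` holding only that population's chromosomes.
#' @export
panel_subset <- function(panel, pop) {
  stopifnot(inherits(panel, "haplotype_panel"))
  rows <- which(panel$pop == pop)
  if (length(rows) == 0L) abort(sprintf("no chromosomes for population %s", pop))
  panel$hap <- panel$hap[rows, , drop = FALSE]
  panel$pop <- panel$pop[rows]
  panel
}
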