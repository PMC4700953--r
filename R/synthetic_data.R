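#' Configuration for the synthetic chicken-panel generator
#'
#' Describes one simulated chromosome mirroring the study design: two
#' individually genotyped layer populations (White and Brown layer, 25 hens
#' each, phased), three pool-sequenced broiler populations, SNPs at ~107 bp
#' mean spacing, and drift-level differentiation generated by the
#' Balding-Nichols model with parameter `baseline_fst` (the genome-wide Fst
#' the populations should show). Hard sweeps are described by
#' [sweep_spec()] entries and implanted on top of the neutral background.
#'
#' @param seed Integer RNG seed; identical seeds give identical output.
#' @param chrom_length Chromosome length in bp (default 1e6, ~9300 SNPs at
#'   the default spacing).
#' @param mean_spacing Mean distance between adjacent SNPs in bp
#'   (default 107).
#' @param n_layers Diploid individuals per layer population (default 25).
#' @param layer_pops Labels of the individually genotyped populations
#'   (default `c("WL", "BL")`).
#' @param n_pools Number of pooled broiler populations (default 3).
#' @param pool_depth Mean sequencing depth per pool per site; per-site depth
#'   is Poisson around this (default 30).
#' @param baseline_fst Balding-Nichols drift parameter F in (0, 1)
#'   (default 0.18).
#' @param ancestral_range Range of the uniform distribution of ancestral
#'   allele frequencies (default `c(0.05, 0.95)`, avoiding monomorphic
#'   sites).
#' @param sweep_specs List of [sweep_spec()] objects.
#' @param chrom Chromosome label (default "chr1").
#' @return A `sim_config` object.
#' @export
sim_config <- function(seed = 1, chrom_length = 1e6, mean_spacing = 107,
                       n_layers = 25, layer_pops = c("WL", "BL"),
                       n_pools = 3, pool_depth = 30, baseline_fst = 0.18,
                       ancestral_range = c(0.05, 0.95),
                       sweep_specs = list(), chrom = "chr1") {
  assert_scalar_number(seed, "seed")
  assert_scalar_number(chrom_length, "chrom_length", min = 1)
  assert_scalar_number(mean_spacing, "mean_spacing", min = 1)
  assert_scalar_number(n_layers, "n_layers", min = 1)
  assert_scalar_number(n_pools, "n_pools", min = 0)
  assert_scalar_number(pool_depth, "pool_depth", min = 1)
  assert_scalar_number(baseline_fst, "baseline_fst")
  if (baseline_fst <= 0 || baseline_fst >= 1) {
    abort("`baseline_fst` must lie strictly between 0 and 1")
  }
  for (s in sweep_specs) {
    if (!inherits(s, "sweep_spec")) abort("`sweep_specs` must be a list of sweep_spec objects")
    if (s$center < 0 || s$center >= chrom_length) abort("sweep center outside chromosome")
  }
  structure(
    list(seed = seed, chrom_length = chrom_length, mean_spacing = mean_spacing,
         n_layers = n_layers, layer_pops = layer_pops, n_pools = n_pools,
         pool_depth = pool_depth, baseline_fst = baseline_fst,
         ancestral_range = ancestral_range, sweep_specs = sweep_specs,
         chrom = chrom),
    class = "sim_config"
  )
}

#' Describe one hard selective sweep to implant
#'
#' The selected allele sits at `center`; in `target_pops` the derived-allele
#' frequency at distance `d` from the center is raised toward
#' `p(d) = p_bg + (p_sweep - p_bg) * exp(-d / decay_length)`, the classic
#' hitchhiking decay of linked neutral variants. With `core_haplotype`,
#' swept chromosomes share one derived haplotype across the tract, producing
#' the long-range haplotype homozygosity that iHS detects.
#'
#' @param center Sweep center in bp.
#' @param target_pops Character vector of population labels carrying the
#'   sweep.
#' @param p_sweep Selected-allele frequency at the center (default 0.95).
#' @param decay_length Decay scale L in bp (default 1e5).
#' @param core_haplotype Should swept chromosomes share a core haplotype?
#'   (default TRUE; only affects individually genotyped populations).
#' @return A `sweep_spec` object.
#' @export
sweep_spec <- function(center, target_pops, p_sweep = 0.95,
                       decay_length = 1e5, core_haplotype = TRUE) {
  assert_scalar_number(center, "center", min = 0)
  assert_scalar_number(p_sweep, "p_sweep", min = 0, max = 1)
  assert_scalar_number(decay_length, "decay_length")
  if (decay_length <= 0) abort("`decay_length` must be positive")
  if (length(target_pops) == 0L) abort("`target_pops` must name at least one population")
  structure(
    list(center = center, target_pops = as.character(target_pops),
         p_sweep = p_sweep, decay_length = decay_length,
         core_haplotype = isTRUE(core_haplotype)),
    class = "sweep_spec"
  )
}

# Balding-Nichols draw of a population frequency around ancestral p0
bn_draw <- function(p0, f) {
  if (f < 1e-6) return(p0)
  rbeta(length(p0), p0 * (1 - f) / f, (1 - p0) * (1 - f) / f)
}

sweep_target_freq <- function(p_bg, pos, spec) {
  e <- exp(-abs(pos - spec$center) / spec$decay_length)
  p_bg + (spec$p_sweep - p_bg) * e
}

#' Simulate a genotyped + pooled chicken panel
#'
#' Draws SNP positions with exponential spacing, ancestral frequencies
#' uniform on `ancestral_range`, per-population frequencies from the
#' Balding-Nichols model, phased layer haplotypes site-independently given
#' the population frequency, and pooled read counts as
#' binomial(Poisson depth, pool frequency). Sweeps listed in
#' `cfg$sweep_specs` are implanted: at the frequency level for pools and for
#' layer populations without a core haplotype, and by forcing a nested set
#' of carrier chromosomes to the derived allele (a shared decaying core
#' haplotype) where `core_haplotype` is set.
#'
#' @param cfg A [sim_config()].
#' @return A `sweep_sim` list: `panel` (a `haplotype_panel` of the layer
#'   populations), `pools` (a `pool_counts` table), `truth` (tibble of the
#'   sampling frequencies per population) and `cfg`.
#' @seealso [simulate_neutral_panel()], [implant_sweep()], [emit_fixtures()]
#' @export
simulate_panel <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  pos <- integer(0)
  at <- 0
  repeat {
    gaps <- rexp(ceiling(cfg$chrom_length / cfg$mean_spacing * 0.3) + 100L,
                 rate = 1 / cfg$mean_spacing)
    pos <- c(pos, at + cumsum(gaps))
    at <- pos[length(pos)]
    if (at > cfg$chrom_length) break
  }
  pos <- unique(as.integer(pos))
  pos <- pos[pos >= 1 & pos < cfg$chrom_length]
  m <- length(pos)
  if (m < 2L) abort("chromosome too short for the requested SNP spacing")

  p0 <- runif(m, cfg$ancestral_range[1], cfg$ancestral_range[2])
  pools <- if (cfg$n_pools > 0) paste0("BR", seq_len(cfg$n_pools)) else character()
  pops <- c(cfg$layer_pops, pools)
  freq <- vapply(pops, function(p) bn_draw(p0, cfg$baseline_fst), numeric(m))

  # frequency-level sweep targets
  core_specs <- list()
  for (spec in cfg$sweep_specs) {
    unknown <- setdiff(spec$target_pops, pops)
    if (length(unknown)) abort(sprintf("unknown sweep target population: %s", unknown[1]))
    for (p in spec$target_pops) {
      if (spec$core_haplotype && p %in% cfg$layer_pops) {
        core_specs[[length(core_specs) + 1L]] <- list(pop = p, spec = spec)
      } else {
        freq[, p] <- sweep_target_freq(freq[, p], pos, spec)
      }
    }
  }

  n_hap <- 2L * cfg$n_layers
  hap <- matrix(NA_integer_, length(cfg$layer_pops) * n_hap, m)
  pop_labels <- rep(cfg$layer_pops, each = n_hap)
  for (k in seq_along(cfg$layer_pops)) {
    rows <- (k - 1L) * n_hap + seq_len(n_hap)
    hap[rows, ] <- matrix(
      rbinom(n_hap * m, 1L, rep(freq[, cfg$layer_pops[k]], each = n_hap)),
      nrow = n_hap
    )
  }
  panel <- structure(
    list(chrom = cfg$chrom, positions = pos, hap = hap, pop = pop_labels),
    class = "haplotype_panel"
  )
  for (cs in core_specs) {
    panel <- implant_sweep(panel, cs$spec, pops = cs$pop)
    rows <- which(pop_labels == cs$pop)
    freq[, cs$pop] <- colMeans(panel$hap[rows, , drop = FALSE])
  }

  pool_counts <- NULL
  if (cfg$n_pools > 0) {
    depth <- matrix(rpois(m * cfg$n_pools, cfg$pool_depth), m, cfg$n_pools)
    alt <- matrix(rbinom(m * cfg$n_pools, as.vector(depth),
                         as.vector(freq[, pools, drop = FALSE])), m, cfg$n_pools)
    ref <- depth - alt
    masked <- depth < 4
    colnames(ref) <- colnames(alt) <- colnames(masked) <- pools
    pool_counts <- structure(
      list(
        sites = tibble(chrom = cfg$chrom, pos = pos, ref = "A", alt = "G",
                       qual = NA_real_, depth = rowSums(depth)),
        pools = pools, ref_count = ref, alt_count = alt,
        masked = masked
      ),
      class = "pool_counts"
    )
  }

  truth <- dplyr::bind_cols(
    tibble(chrom = cfg$chrom, pos = pos, p_ancestral = p0),
    as_tibble(freq)
  )
  structure(list(panel = panel, pools = pool_counts, truth = truth, cfg = cfg),
            class = "sweep_sim")
}

#' @describeIn simulate_panel Simulate the same panel with all sweeps
#'   stripped (pure neutral drift).
#' @export
simulate_neutral_panel <- function(cfg) {
  cfg$sweep_specs <- list()
  simulate_panel(cfg)
}

#' Implant a hard sweep into a phased haplotype panel
#'
#' Raises the derived-allele frequency in the target populations toward
#' `p(d) = p_bg + (p_sweep - p_bg) * exp(-d/L)`, where `p_bg` is the panel's
#' realized background frequency at each site. With `core_haplotype`, a
#' nested set of carrier chromosomes is forced to the derived allele — the
#' carrier set shrinks with distance from the center, so near-core carriers
#' share one long haplotype while distant sites revert to background, the
#' footprint iHS is designed to detect. Without it, chromosomes are flipped
#' to the derived allele independently per site. Uses the session RNG; seed
#' before calling for reproducibility.
#'
#' @param panel A `haplotype_panel`.
#' @param spec A [sweep_spec()].
#' @param pops Restrict implanting to these populations (default: all of
#'   `spec$target_pops` present in the panel).
#' @return The modified panel.
#' @export
implant_sweep <- function(panel, spec, pops = NULL) {
  stopifnot(inherits(panel, "haplotype_panel"), inherits(spec, "sweep_spec"))
  if (length(spec$target_pops) == 0L) abort("sweep has no target populations")
  if (spec$center < 0 || spec$center > max(panel$positions)) {
    abort("sweep center outside the panel")
  }
  targets <- intersect(pops %||% spec$target_pops, unique(panel$pop))
  if (length(targets) == 0L) abort("no sweep target population present in panel")
  pos <- panel$positions
  e <- exp(-abs(pos - spec$center) / spec$decay_length)
  for (p in targets) {
    rows <- which(panel$pop == p)
    n <- length(rows)
    sub <- panel$hap[rows, , drop = FALSE]
    p_bg <- colMeans(sub)
    target <- p_bg + (spec$p_sweep - p_bg) * e
    if (spec$core_haplotype) {
      # carrier fraction solving f + (1-f)*p_bar = p_sweep at the center,
      # decaying smoothly with distance; anchoring on the population's mean
      # background (not the per-site one) keeps the forced carrier set
      # nested and contiguous, i.e. a genuine shared core haplotype
      p_bar <- mean(p_bg)
      f0 <- min(max((spec$p_sweep - p_bar) / max(1 - p_bar, 1e-12), 0), 1)
      f <- f0 * e
      perm <- sample.int(n)
      n_carrier <- round(f * n)
      for (j in which(n_carrier > 0L)) {
        sub[perm[seq_len(n_carrier[j])], j] <- 1L
      }
    } else {
      for (j in seq_along(pos)) {
        add <- round((target[j] - p_bg[j]) * n)
        if (add > 0L) {
          anc <- which(sub[, j] == 0L)
          sub[anc[sample.int(length(anc), min(add, length(anc)))], j] <- 1L
        }
      }
    }
    panel$hap[rows, ] <- sub
  }
  panel
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat(sprintf("<haplotype_panel> %s: %d chromosomes x %d sites; pops: %s\n",
              x$chrom, nrow(x$hap), length(x$positions),
              paste(unique(x$pop), collapse = ", ")))
  invisible(x)
}

#' @export
print.sweep_sim <- function(x, ...) {
  cat(sprintf("<sweep_sim> seed %s, %d sites, %d sweeps\n",
              format(x$cfg$seed), nrow(x$truth), length(x$cfg$sweep_specs)))
  invisible(x)
}

#' Write simulated data as analysis-ready fixture files
#'
#' Emits a phased VCF for the individually genotyped layer populations
#' (GT with `|` separators, ancestral allele as REF so polarization is known),
#' a pool-count TSV for the broiler pools, a sample-to-population map, and a
#' chromosome-length table. Reading the files back through [read_vcf()] /
#' [read_pool_counts()] reproduces dosages and counts exactly.
#'
#' @param sim A `sweep_sim` from [simulate_panel()].
#' @param out_dir Output directory (created if needed).
#' @return Named character vector of written paths, invisibly.
#' @export
emit_fixtures <- function(sim, out_dir) {
  stopifnot(inherits(sim, "sweep_sim"))
  panel <- sim$panel
  if (length(panel$positions) == 0L) abort("empty panel: nothing to write")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  pops <- unique(panel$pop)
  n_per <- table(panel$pop)[pops] / 2L
  samples <- unlist(lapply(pops, function(p) {
    sprintf("%s_%02d", p, seq_len(n_per[[p]]))
  }))
  pop_of_sample <- rep(pops, times = n_per[pops])

  vcf_path <- file.path(out_dir, "layers.vcf")
  m <- length(panel$positions)
  dp <- 30L * length(samples)
  gt_cols <- vapply(seq_along(samples), function(s) {
    prow <- which(panel$pop == pop_of_sample[s])
    i1 <- prow[2L * ((s - 1L) %% n_per[[pop_of_sample[s]]]) + 1L]
    paste0(panel$hap[i1, ], "|", panel$hap[i1 + 1L, ])
  }, character(m))
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", panel$chrom, sim$cfg$chrom_length),
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Total read depth\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  body <- paste(panel$chrom, panel$positions + 1L, ".", "A", "G", 60, "PASS",
                paste0("DP=", dp), "GT",
                apply(gt_cols, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), vcf_path)

  paths <- c(vcf = vcf_path)
  if (!is.null(sim$pools)) {
    pc <- sim$pools
    tab <- dplyr::bind_cols(
      tibble(chrom = pc$sites$chrom, pos = pc$sites$pos + 1L,
             ref = pc$sites$ref, alt = pc$sites$alt),
      as_tibble(setNames(as.data.frame(pc$ref_count),
                         paste0(pc$pools, "_ref"))),
      as_tibble(setNames(as.data.frame(pc$alt_count),
                         paste0(pc$pools, "_alt")))
    )
    pool_path <- file.path(out_dir, "pools.tsv")
    readr::write_tsv(tab, pool_path, progress = FALSE)
    paths <- c(paths, pools = pool_path)
  }
  map_path <- file.path(out_dir, "pops.tsv")
  readr::write_tsv(tibble(sample = samples, pop = pop_of_sample), map_path,
                   progress = FALSE)
  len_path <- file.path(out_dir, "chrom_lengths.tsv")
  readr::write_tsv(tibble(chrom = panel$chrom, length = sim$cfg$chrom_length),
                   len_path, col_names = FALSE, progress = FALSE)
  invisible(c(paths, pops_map = map_path, chrom_lengths = len_path))
}
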