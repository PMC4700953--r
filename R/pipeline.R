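#' Resolved configuration for the selection scans
#'
#' Collects every tunable of the two screens with the study's stated values
#' as defaults: 40 kb windows stepping 5 kb, parallel-fixation threshold
#' 0.85 (inclusive), divergence outliers at the empirical top 1%. The
#' resolved config travels inside every result object so a run can be
#' reproduced from its output alone.
#'
#' @param window_size,step Window frame in bp (defaults 40000 / 5000).
#' @param fixation_tau Parallel-fixation AF threshold (default 0.85).
#' @param fst_quantile Quantile defining divergence outliers (default 0.99,
#'   i.e. the top 1%).
#' @param min_snps_per_window Minimum contributing SNPs for a window mean
#'   (default 5).
#' @param maf_min iHS minor-allele-frequency cutoff (default 0.05).
#' @param ehh_truncation EHH truncation level (default 0.05).
#' @param max_gap Maximum inter-site gap tolerated by EHH walks, bp
#'   (default 200000).
#' @param layer_combine How the layer group frequency is formed for the
#'   divergence scan: `"mean"` (unweighted mean of the per-population
#'   tracks) or `"pooled"` (haplotype-weighted mean, equivalent to pooling
#'   the genotypes).
#' @param pool_size Diploid individuals per broiler pool, when known; caps
#'   the haplotype-equivalent sample size of pooled sites at `2 * pool_size`
#'   so read depth cannot overstate precision (default `NA`, no cap).
#' @param gap_tolerance Unflagged grid steps tolerated inside a merged
#'   region (default 0).
#' @param seed Optional integer echoed into provenance (the scans themselves
#'   are deterministic).
#' @return A `scan_config` object.
#' @export
scan_config <- function(window_size = 40000, step = 5000, fixation_tau = 0.85,
                        fst_quantile = 0.99, min_snps_per_window = 5,
                        maf_min = 0.05, ehh_truncation = 0.05, max_gap = 2e5,
                        layer_combine = c("mean", "pooled"), pool_size = NA,
                        gap_tolerance = 0, seed = NULL) {
  layer_combine <- match.arg(layer_combine)
  assert_scalar_number(window_size, "window_size", min = 1)
  assert_scalar_number(step, "step", min = 1)
  assert_scalar_number(fixation_tau, "fixation_tau", min = 0, max = 1)
  assert_scalar_number(fst_quantile, "fst_quantile", min = 0, max = 1)
  assert_scalar_number(min_snps_per_window, "min_snps_per_window", min = 0)
  structure(
    list(window_size = window_size, step = step, fixation_tau = fixation_tau,
         fst_quantile = fst_quantile,
         min_snps_per_window = min_snps_per_window, maf_min = maf_min,
         ehh_truncation = ehh_truncation, max_gap = max_gap,
         layer_combine = layer_combine, pool_size = pool_size,
         gap_tolerance = gap_tolerance, seed = seed),
    class = "scan_config"
  )
}

infer_sample_pops <- function(samples) {
  setNames(sub("_.*$", "", samples), samples)
}

# normalize the mix of accepted inputs (paths, parsed objects, or a whole
# simulation) into per-population layer tracks, per-pool tracks and the
# chromosome lengths the window grid needs
prepare_scan_inputs <- function(layers, pools = NULL, sample_pops = NULL,
                                filter = filter_config(),
                                chrom_lengths = NULL) {
  log <- list()
  panel <- NULL
  if (inherits(layers, "sweep_sim")) {
    sim <- layers
    panel <- sim$panel
    pools <- pools %||% sim$pools
    chrom_lengths <- chrom_lengths %||%
      setNames(sim$cfg$chrom_length, sim$cfg$chrom)
    layer_tracks <- panel_freq(panel) |> split_track_by_pop()
  } else {
    if (is.character(layers)) layers <- read_vcf(layers, filter = filter)
    if (is.character(pools)) pools <- read_pool_counts(pools, filter = filter)
    if (inherits(layers, "haplotype_panel")) {
      panel <- layers
      layer_tracks <- panel_freq(panel) |> split_track_by_pop()
    } else if (inherits(layers, "genotype_matrix")) {
      gm <- layers
      if (!is.null(pools)) {
        aligned <- intersect_sites(list(gm, pools))
        log$intersect <- attr(aligned, "intersect_log")
        gm <- aligned[[1]]
        pools <- aligned[[2]]
      }
      sample_pops <- sample_pops %||% infer_sample_pops(gm$samples)
      pop_order <- unique(unname(sample_pops[gm$samples]))
      layer_tracks <- lapply(split(names(sample_pops),
                                   unname(sample_pops))[pop_order],
                             function(ss) genotype_freq(gm, ss))
      layer_tracks <- purrr::imap(layer_tracks,
                                  function(t, p) { t$pop <- p; t })
      log$drop_log <- gm$drop_log
      if (gm$phased) {
        panel <- as_haplotype_panel(gm, sample_pops)
      }
    } else {
      abort("`layers` must be a VCF path, genotype_matrix, haplotype_panel or sweep_sim")
    }
  }
  if (is.character(pools)) pools <- read_pool_counts(pools, filter = filter)
  pool_tracks <- NULL
  if (!is.null(pools)) {
    # a simulated panel and its pools share one site frame by construction;
    # anything else is restricted to the common sites
    key_l <- site_key(layer_tracks[[1]]$chrom, layer_tracks[[1]]$pos)
    key_p <- site_key(pools$sites$chrom, pools$sites$pos)
    if (!identical(key_l, key_p)) {
      common <- intersect(key_l, key_p)
      if (length(common) == 0L) abort("no sites shared between layers and pools")
      layer_tracks <- lapply(layer_tracks,
                             function(t) t[match(common, key_l), , drop = FALSE])
      pools <- subset_variant_table(pools, match(common, key_p))
      if (!is.null(panel)) {
        keep <- match(common, site_key(panel$chrom, panel$positions))
        panel$positions <- panel$positions[keep]
        panel$hap <- panel$hap[, keep, drop = FALSE]
      }
    }
    pool_tracks <- lapply(pools$pools, function(p) pool_freq(pools, p))
    names(pool_tracks) <- pools$pools
  }
  if (is.null(chrom_lengths)) {
    pos_tab <- layer_tracks[[1]]
    chrom_lengths <- tapply(pos_tab$pos, pos_tab$chrom, function(p) max(p) + 1L)
    chrom_lengths <- setNames(as.numeric(chrom_lengths), names(chrom_lengths))
  }
  log$n_sites <- nrow(layer_tracks[[1]])
  list(layer_tracks = layer_tracks, pool_tracks = pool_tracks, panel = panel,
       chrom_lengths = chrom_lengths, log = log)
}

split_track_by_pop <- function(track) {
  out <- split(track, track$pop)
  out[unique(track$pop)]
}

cap_pool_n <- function(track, pool_size) {
  if (!is.na(pool_size)) track$n_obs <- pmin(track$n_obs, 2L * pool_size)
  track
}

#' Run the parallel-fixation screen
#'
#' The first of the two selection screens: window-mean alternate-allele
#' frequencies are computed for each layer population and for the broiler
#' group (unweighted mean over the pools), windows where every population
#' clears `fixation_tau` are flagged, and adjacent flagged windows are
#' merged into candidate parallel-fixation regions.
#'
#' @param layers Layer-population input: path to a multi-sample VCF, a
#'   `genotype_matrix`, a `haplotype_panel`, or a whole `sweep_sim`.
#' @param pools Broiler input: path to a pool-count TSV or a `pool_counts`
#'   object (taken from the simulation when `layers` is a `sweep_sim`).
#' @param sample_pops Named vector mapping VCF sample ids to populations
#'   (default: the prefix before the first underscore).
#' @param config A [scan_config()].
#' @param filter A [filter_config()] applied when reading from files.
#' @param chrom_lengths Named chromosome lengths for the window grid
#'   (default: inferred from the data, or taken from the simulation config).
#' @return A `fixation_scan` object: `regions`, per-window `windows` table,
#'   `config`, `log`. Use [tidy()] for the region table, [glance()] for the
#'   run summary and [autoplot()] for the track figure.
#' @export
run_fixation_scan <- function(layers, pools = NULL, sample_pops = NULL,
                              config = scan_config(),
                              filter = filter_config(),
                              chrom_lengths = NULL) {
  inp <- prepare_scan_inputs(layers, pools, sample_pops, filter, chrom_lengths)
  if (length(inp$layer_tracks) + as.integer(!is.null(inp$pool_tracks)) < 2L) {
    abort("the fixation screen needs at least 2 populations")
  }
  tracks <- inp$layer_tracks
  if (!is.null(inp$pool_tracks)) {
    tracks$BR <- group_mean_freq(inp$pool_tracks, pop_id = "BR")
  }
  grid <- make_genome_grid(inp$chrom_lengths, config$window_size, config$step)
  stats <- lapply(tracks, function(t) {
    window_mean(tibble(chrom = t$chrom, pos = t$pos, value = t$freq),
                grid, min_snps = config$min_snps_per_window)
  })
  flags <- flag_fixation_windows(stats, tau = config$fixation_tau)
  regions <- merge_flagged_windows(flags, step = config$step,
                                   gap_tolerance = config$gap_tolerance)
  log <- c(inp$log, list(n_windows = nrow(flags),
                         n_flagged = sum(flags$flagged),
                         n_regions = nrow(regions)))
  structure(list(regions = regions, windows = flags, tracks = tracks,
                 config = config, log = log),
            class = "fixation_scan")
}

#' Run the layer-broiler divergence screen
#'
#' The second screen: per-site Weir-Cockerham Fst between the layer group
#' and the broiler group, averaged over the window frame, thresholded at the
#' empirical top quantile, and clustered into divergence regions with
#' empirical percentile P values. Expected-heterozygosity window tracks for
#' both groups are always computed; a window-averaged |iHS| track for the
#' layer populations is added when `include_ihs = TRUE` and phased data are
#' available.
#'
#' @inheritParams run_fixation_scan
#' @param include_ihs Compute the |iHS| track (slower; needs phased layers).
#' @return An `fst_scan` object: `regions`, `windows` (Fst window track with
#'   empirical P), `threshold`, `global` (multi-locus Fst, mean/sd of
#'   per-site values, per-chromosome-class means), `tracks` (het and
#'   optional |iHS| window tracks), `config`, `log`.
#' @export
run_fst_scan <- function(layers, pools = NULL, sample_pops = NULL,
                         config = scan_config(), filter = filter_config(),
                         chrom_lengths = NULL, include_ihs = FALSE) {
  inp <- prepare_scan_inputs(layers, pools, sample_pops, filter, chrom_lengths)
  if (is.null(inp$pool_tracks)) abort("the divergence screen needs pooled data")
  layer_group <- combine_layer_tracks(inp$layer_tracks, config$layer_combine)
  pool_tracks <- lapply(inp$pool_tracks, cap_pool_n, config$pool_size)
  broiler_group <- group_mean_freq(pool_tracks, pop_id = "BR")
  if (nrow(layer_group) == 0L) abort("empty common site set")

  ok <- !is.na(layer_group$freq) & !is.na(broiler_group$freq) &
    layer_group$n_obs >= 2 & broiler_group$n_obs >= 2
  fst <- rep(NA_real_, nrow(layer_group))
  fst[ok] <- wc_fst_site(layer_group$freq[ok], broiler_group$freq[ok],
                         layer_group$n_obs[ok], broiler_group$n_obs[ok])
  fst_track <- tibble(chrom = layer_group$chrom, pos = layer_group$pos,
                      value = fst)

  grid <- make_genome_grid(inp$chrom_lengths, config$window_size, config$step)
  win <- window_mean(fst_track, grid, min_snps = config$min_snps_per_window)
  threshold <- top_quantile_threshold(win$value, q = config$fst_quantile)
  regions <- cluster_divergent_windows(win, threshold, step = config$step,
                                       gap_tolerance = config$gap_tolerance)
  win$p <- rep(NA_real_, nrow(win))
  win$p[!is.na(win$value)] <- empirical_p(win$value, win$value[!is.na(win$value)])

  tracks <- list(
    het_layer = window_mean(expected_heterozygosity(layer_group),
                            grid, min_snps = config$min_snps_per_window),
    het_broiler = window_mean(expected_heterozygosity(broiler_group),
                              grid, min_snps = config$min_snps_per_window)
  )
  if (include_ihs) {
    if (is.null(inp$panel)) abort("|iHS| track requested but no phased layer data")
    ihs_wins <- lapply(unique(inp$panel$pop), function(p) {
      scores <- ihs(panel_subset(inp$panel, p), maf_min = config$maf_min,
                    truncation = config$ehh_truncation,
                    max_gap = config$max_gap)
      windowed_abs_ihs(standardize_ihs(scores), grid,
                       min_snps = config$min_snps_per_window)
    })
    comb <- ihs_wins[[1]]
    vals <- vapply(ihs_wins, function(w) w$value, numeric(nrow(comb)))
    vals <- matrix(vals, nrow = nrow(comb))
    comb$value <- rowMeans(vals, na.rm = TRUE)
    comb$value[is.nan(comb$value)] <- NA_real_
    tracks$abs_ihs <- comb
  }

  global <- list(
    fst_multilocus = wc_fst_global(layer_group$freq[ok], broiler_group$freq[ok],
                                   layer_group$n_obs[ok],
                                   broiler_group$n_obs[ok]),
    mean_site_fst = mean(fst, na.rm = TRUE),
    sd_site_fst = sd(fst, na.rm = TRUE),
    by_chrom_class = stratified_mean_fst(win)
  )
  log <- c(inp$log, list(n_windows = nrow(win),
                         n_flagged = sum(!is.na(win$value) & win$value >= threshold),
                         n_regions = nrow(regions)))
  structure(list(regions = regions, windows = win, threshold = threshold,
                 global = global, tracks = tracks, config = config, log = log),
            class = "fst_scan")
}

combine_layer_tracks <- function(layer_tracks, how) {
  if (length(layer_tracks) == 1L) return(layer_tracks[[1]])
  if (how == "mean") {
    group_mean_freq(layer_tracks, pop_id = "L")
  } else {
    base <- layer_tracks[[1]]
    fmat <- vapply(layer_tracks, function(t) t$freq, numeric(nrow(base)))
    nmat <- vapply(layer_tracks, function(t) as.numeric(t$n_obs),
                   numeric(nrow(base)))
    any_na <- rowSums(is.na(fmat)) > 0
    tibble(chrom = base$chrom, pos = base$pos,
           freq = ifelse(any_na, NA_real_, rowSums(fmat * nmat) / rowSums(nmat)),
           n_obs = ifelse(any_na, NA_integer_, as.integer(rowSums(nmat))),
           pop = "L")
  }
}

#' @export
print.fixation_scan <- function(x, ...) {
  cat(sprintf("<fixation_scan> %d/%d windows flagged (tau=%.2f), %d regions\n",
              x$log$n_flagged, x$log$n_windows, x$config$fixation_tau,
              nrow(x$regions)))
  invisible(x)
}

#' @export
print.fst_scan <- function(x, ...) {
  cat(sprintf(
    "<fst_scan> multi-locus Fst %.3f; top-%g%% threshold %.3f; %d regions\n",
    x$global$fst_multilocus, 100 * (1 - x$config$fst_quantile), x$threshold,
    nrow(x$regions)))
  invisible(x)
}
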