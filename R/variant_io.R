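#' Site-filter settings for variant ingestion
#'
#' Bundles the quality filters applied when reading variant data: a minimum
#' Phred-scaled site quality, a read-depth band expressed in standard
#' deviations around the dataset mean (to exclude collapsed repeats and
#' low-coverage artifacts), and a minimum per-pool read depth below which a
#' pooled allele frequency is considered undefined.
#'
#' @param min_qual Minimum Phred-scaled site quality (default 20, i.e. 99%
#'   call accuracy).
#' @param depth_sigma Half-width of the accepted total-depth band in standard
#'   deviations of the dataset depth distribution (default 2).
#' @param min_pool_depth Minimum reads per pool at a site for the pooled
#'   frequency to be defined; shallower sites are masked, not dropped
#'   (default 4).
#' @return An object of class `filter_config`.
#' @examples
#' filter_config(min_qual = 30)
#' @export
filter_config <- function(min_qual = 20, depth_sigma = 2, min_pool_depth = 4) {
  assert_scalar_number(min_qual, "min_qual", min = 0)
  assert_scalar_number(depth_sigma, "depth_sigma", min = 0)
  assert_scalar_number(min_pool_depth, "min_pool_depth", min = 0)
  structure(
    list(min_qual = min_qual, depth_sigma = depth_sigma,
         min_pool_depth = min_pool_depth),
    class = "filter_config"
  )
}

is_snp_allele <- function(x) !is.na(x) & nchar(x) == 1L & x %in% c("A", "C", "G", "T")

#' Read a multi-sample VCF into a filtered genotype matrix
#'
#' Parses a VCF (plain or bgzipped), keeps only biallelic SNPs passing the
#' quality and depth filters, and returns a `genotype_matrix`: a site table
#' plus a sites-by-samples diploid dosage matrix (0/1/2 copies of the
#' alternate allele, `NA` for missing calls). Positions are converted to
#' 0-based internally; all reporting functions convert back to 1-based.
#' Haplotype columns are retained when every genotype is phased, so the same
#' object can feed haplotype statistics.
#'
#' Records are dropped (and counted in the `drop_log` attribute) when they
#' are multi-allelic, indels or other non-SNPs, below `min_qual`, or outside
#' the depth band; the depth band is `mean +/- depth_sigma * sd` computed
#' over all sites surviving the earlier filters (see [apply_depth_filter()]).
#'
#' @param path Path to a VCF file with diploid genotypes.
#' @param filter A [filter_config()].
#' @param chrom_lengths Optional named vector of chromosome lengths; sites
#'   beyond the stated length raise an error.
#' @return A `genotype_matrix` with elements `sites` (tibble: chrom, pos
#'   (0-based), ref, alt, qual, depth), `samples`, `dosage`, `phased`,
#'   `haplotypes` (0/1 matrix, two columns per sample, only when phased) and
#'   `drop_log`.
#' @seealso [read_pool_counts()], [intersect_sites()], [genotype_freq()]
#' @export
read_vcf <- function(path, filter = filter_config(), chrom_lengths = NULL) {
  if (!file.exists(path)) abort(sprintf("VCF not found: %s", path))
  vcf <- tryCatch(
    vcfR::read.vcfR(path, verbose = FALSE),
    error = function(e) abort(sprintf("malformed VCF '%s': %s", path, conditionMessage(e)))
  )
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  n_total <- nrow(fix)
  log <- new_drop_log()
  if (n_total == 0L) {
    warn(sprintf("no records in VCF '%s'", path))
  }

  chrom <- fix$CHROM
  pos1 <- suppressWarnings(as.integer(fix$POS))
  if (anyNA(pos1)) {
    abort(sprintf("malformed VCF '%s': non-numeric POS at record %d",
                  path, which(is.na(pos1))[1]))
  }
  ref <- fix$REF
  alt <- fix$ALT
  qual <- suppressWarnings(as.numeric(fix$QUAL))
  info <- paste0(";", ifelse(is.na(fix$INFO), "", fix$INFO), ";")
  m <- regexpr(";DP=[0-9.]+", info)
  depth <- rep(NA_real_, length(info))
  hit <- m > 0L
  depth[hit] <- as.numeric(substring(info[hit], m[hit] + 4L,
                                     m[hit] + attr(m, "match.length")[hit] - 1L))

  multi <- grepl(",", alt)
  nonsnp <- !multi & !(is_snp_allele(ref) & is_snp_allele(alt))
  lowq <- !multi & !nonsnp & (is.na(qual) | qual < filter$min_qual)
  keep <- !(multi | nonsnp | lowq)
  log <- add_drop(log, "multiallelic", sum(multi))
  log <- add_drop(log, "indel_or_nonsnp", sum(nonsnp))
  log <- add_drop(log, "low_qual", sum(lowq))

  sites <- tibble(
    chrom = chrom[keep], pos = pos1[keep] - 1L,
    ref = ref[keep], alt = alt[keep],
    qual = qual[keep], depth = depth[keep]
  )

  # depth band over the surviving set; skipped (with a note) when the file
  # carries no DP field at all
  if (nrow(sites) >= 2L && any(!is.na(sites$depth))) {
    nodp <- is.na(sites$depth)
    log <- add_drop(log, "missing_depth", sum(nodp))
    sites <- sites[!nodp, , drop = FALSE]
    n_before <- nrow(sites)
    sites <- apply_depth_filter(sites, sigma = filter$depth_sigma)
    log <- add_drop(log, "depth_band", n_before - nrow(sites))
  }

  if (!is.null(chrom_lengths)) {
    over <- sites$pos >= chrom_lengths[sites$chrom]
    if (any(over, na.rm = TRUE)) {
      abort(sprintf("site %s:%d beyond stated chromosome length",
                    sites$chrom[which(over)[1]], sites$pos[which(over)[1]] + 1L))
    }
  }

  gt <- vcfR::extract.gt(vcf, element = "GT")
  samples <- colnames(gt)
  key_all <- site_key(chrom, pos1 - 1L)
  gt <- gt[match(site_key(sites$chrom, sites$pos), key_all), , drop = FALSE]

  a1 <- substr(gt, 1L, 1L)
  sep <- substr(gt, 2L, 2L)
  a2 <- substr(gt, 3L, 3L)
  miss <- is.na(gt) | a1 == "." | a2 == "." | a2 == ""
  dosage <- (a1 == "1") + (a2 == "1")
  dosage[miss] <- NA_integer_
  mode(dosage) <- "integer"
  dimnames(dosage) <- list(NULL, samples)
  phased <- all(sep[!miss] == "|") && any(!miss)

  o <- order(sites$chrom, sites$pos)
  sites <- sites[o, , drop = FALSE]
  dosage <- dosage[o, , drop = FALSE]

  haplotypes <- NULL
  if (phased) {
    h <- matrix(NA_integer_, nrow(sites), 2L * length(samples))
    h[, seq(1L, ncol(h), by = 2L)] <- ifelse(miss[o, , drop = FALSE], NA_integer_,
                                             as.integer(a1[o, , drop = FALSE] == "1"))
    h[, seq(2L, ncol(h), by = 2L)] <- ifelse(miss[o, , drop = FALSE], NA_integer_,
                                             as.integer(a2[o, , drop = FALSE] == "1"))
    colnames(h) <- paste0(rep(samples, each = 2L), c("_1", "_2"))
    haplotypes <- h
  }

  if (nrow(sites) == 0L) {
    warn(sprintf("no sites retained from '%s' after filtering", path))
  }

  structure(
    list(sites = sites, samples = samples, dosage = dosage,
         phased = phased, haplotypes = haplotypes, drop_log = log),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d sites x %d samples (%s)\n",
              nrow(x$sites), length(x$samples),
              if (x$phased) "phased" else "unphased"))
  if (nrow(x$drop_log)) {
    cat("dropped:", paste(sprintf("%s=%d", x$drop_log$reason, x$drop_log$n),
                          collapse = ", "), "\n")
  }
  invisible(x)
}

#' Filter sites to a read-depth band around the dataset mean
#'
#' Retains sites whose total depth lies in `[mean - sigma*sd, mean + sigma*sd]`
#' where mean and (sample) standard deviation are computed over the input set
#' in a single pass, before any removal. Excessive depth marks collapsed
#' repetitive sequence; unusually low depth marks unreliable calls.
#'
#' @param sites A tibble with a numeric `depth` column (at least 2 rows).
#' @param sigma Half-width of the band in standard deviations.
#' @return The filtered tibble, same columns, original order.
#' @examples
#' sites <- tibble::tibble(depth = c(rep(10, 20), 100))
#' nrow(apply_depth_filter(sites, sigma = 2))  # outlier removed
#' @export
apply_depth_filter <- function(sites, sigma = 2) {
  assert_scalar_number(sigma, "sigma", min = 0)
  if (!is.data.frame(sites) || is.null(sites$depth)) {
    abort("`sites` must be a data frame with a `depth` column")
  }
  if (nrow(sites) < 2L) abort("need at least 2 sites to estimate the depth band")
  m <- mean(sites$depth)
  s <- sd(sites$depth)
  keep <- sites$depth >= m - sigma * s & sites$depth <= m + sigma * s
  sites[keep, , drop = FALSE]
}

#' Read pooled allele counts from a TSV
#'
#' Expects a tab-separated file with header columns `chrom`, `pos` (1-based),
#' `ref`, `alt`, then a `<pool>_ref` / `<pool>_alt` pair per pool. Sites where
#' a pool's total depth falls below `min_pool_depth` are masked for that pool
#' (frequency undefined there) but kept in the table so site frames stay
#' aligned across populations.
#'
#' @param path Path to the TSV.
#' @param filter A [filter_config()]; only `min_pool_depth` is used.
#' @return A `pool_counts` object: `sites` tibble (chrom, pos 0-based, ref,
#'   alt), `pools`, `ref_count` / `alt_count` matrices and a logical `masked`
#'   matrix.
#' @export
read_pool_counts <- function(path, filter = filter_config()) {
  if (!file.exists(path)) abort(sprintf("pool-count table not found: %s", path))
  tab <- suppressWarnings(readr::read_tsv(path, col_types = readr::cols(
    chrom = readr::col_character(), pos = readr::col_double(),
    ref = readr::col_character(), alt = readr::col_character(),
    .default = readr::col_double()
  ), progress = FALSE))
  prob <- readr::problems(tab)
  if (nrow(prob)) {
    abort(sprintf("parse error in '%s' at line %d: %s",
                  path, prob$row[1] + 1L, prob$expected[1]))
  }
  need <- c("chrom", "pos", "ref", "alt")
  if (!all(need %in% names(tab))) {
    abort(sprintf("pool-count table must start with columns %s",
                  paste(need, collapse = ", ")))
  }
  cnt_cols <- setdiff(names(tab), need)
  if (length(cnt_cols) == 0L || length(cnt_cols) %% 2L != 0L) {
    abort("expected one <pool>_ref / <pool>_alt column pair per pool")
  }
  ref_cols <- grep("_ref$", cnt_cols, value = TRUE)
  alt_cols <- grep("_alt$", cnt_cols, value = TRUE)
  pools <- sub("_ref$", "", ref_cols)
  if (!setequal(pools, sub("_alt$", "", alt_cols))) {
    abort("mismatched <pool>_ref / <pool>_alt column pairs")
  }
  cnt <- as.matrix(tab[, c(ref_cols, alt_cols)])
  if (anyNA(cnt) || any(cnt < 0) || any(cnt != round(cnt))) {
    abort(sprintf("non-numeric, negative or fractional count in '%s'", path))
  }
  key <- site_key(tab$chrom, tab$pos)
  if (anyDuplicated(key)) {
    abort(sprintf("duplicated site %s in '%s'", key[duplicated(key)][1], path))
  }
  o <- order(tab$chrom, tab$pos)
  tab <- tab[o, , drop = FALSE]
  ref_count <- as.matrix(tab[, paste0(pools, "_ref")])
  alt_count <- as.matrix(tab[, paste0(pools, "_alt")])
  storage.mode(ref_count) <- storage.mode(alt_count) <- "integer"
  colnames(ref_count) <- colnames(alt_count) <- pools
  total <- ref_count + alt_count
  masked <- total < filter$min_pool_depth
  sites <- tibble(chrom = tab$chrom, pos = as.integer(tab$pos) - 1L,
                  ref = tab$ref, alt = tab$alt,
                  qual = NA_real_, depth = rowSums(total))
  structure(
    list(sites = sites, pools = pools, ref_count = ref_count,
         alt_count = alt_count, masked = masked),
    class = "pool_counts"
  )
}

#' @export
print.pool_counts <- function(x, ...) {
  cat(sprintf("<pool_counts> %d sites x %d pools (%d site-pool cells masked)\n",
              nrow(x$sites), length(x$pools), sum(x$masked)))
  invisible(x)
}

subset_variant_table <- function(x, idx) {
  x$sites <- x$sites[idx, , drop = FALSE]
  if (inherits(x, "genotype_matrix")) {
    x$dosage <- x$dosage[idx, , drop = FALSE]
    if (!is.null(x$haplotypes)) x$haplotypes <- x$haplotypes[idx, , drop = FALSE]
  } else {
    x$ref_count <- x$ref_count[idx, , drop = FALSE]
    x$alt_count <- x$alt_count[idx, , drop = FALSE]
    x$masked <- x$masked[idx, , drop = FALSE]
  }
  x
}

flip_variant_rows <- function(x, flip) {
  if (!any(flip)) return(x)
  sw <- x$sites$ref[flip]
  x$sites$ref[flip] <- x$sites$alt[flip]
  x$sites$alt[flip] <- sw
  if (inherits(x, "genotype_matrix")) {
    x$dosage[flip, ] <- 2L - x$dosage[flip, , drop = FALSE]
    if (!is.null(x$haplotypes)) {
      x$haplotypes[flip, ] <- 1L - x$haplotypes[flip, , drop = FALSE]
    }
  } else {
    tmp <- x$ref_count[flip, , drop = FALSE]
    x$ref_count[flip, ] <- x$alt_count[flip, , drop = FALSE]
    x$alt_count[flip, ] <- tmp
  }
  x
}

#' Restrict variant tables to their common sites
#'
#' Takes two or more variant tables ([read_vcf()] genotype matrices and/or
#' [read_pool_counts()] tables), restricts each to the sites present in all
#' of them, in one shared order, and harmonizes allele orientation to the
#' first table's ref/alt convention. Sites whose ref/alt are swapped relative
#' to the first table are flipped (dosages complemented, counts swapped) and
#' logged; sites with irreconcilable alleles are dropped from every output
#' and counted.
#'
#' @param tables A list of `genotype_matrix` / `pool_counts` objects
#'   (length >= 2).
#' @return A list of the same objects restricted to the common sites, with an
#'   `intersect_log` attribute (tibble: table, n_flipped, n_irreconcilable).
#' @export
intersect_sites <- function(tables) {
  if (!is.list(tables) || length(tables) < 2L) {
    abort("`tables` must be a list of at least 2 variant tables")
  }
  keys <- lapply(tables, function(t) site_key(t$sites$chrom, t$sites$pos))
  common <- Reduce(intersect, keys)
  ref1 <- tables[[1]]$sites
  k1 <- keys[[1]]
  base <- ref1[match(common, k1), c("chrom", "pos", "ref", "alt")]
  o <- order(base$chrom, base$pos)
  base <- base[o, , drop = FALSE]
  common <- common[o]

  ok_all <- rep(TRUE, length(common))
  flips <- vector("list", length(tables))
  for (i in seq_along(tables)) {
    idx <- match(common, keys[[i]])
    s <- tables[[i]]$sites[idx, , drop = FALSE]
    same <- s$ref == base$ref & s$alt == base$alt
    swapped <- s$ref == base$alt & s$alt == base$ref
    flips[[i]] <- swapped
    ok_all <- ok_all & (same | swapped)
  }
  log <- tibble(
    table = seq_along(tables),
    n_flipped = vapply(flips, function(f) sum(f & ok_all), integer(1)),
    n_irreconcilable = sum(!ok_all)
  )
  out <- vector("list", length(tables))
  for (i in seq_along(tables)) {
    idx <- match(common, keys[[i]])
    x <- subset_variant_table(tables[[i]], idx)
    x <- flip_variant_rows(x, flips[[i]])
    out[[i]] <- subset_variant_table(x, which(ok_all))
  }
  names(out) <- names(tables)
  attr(out, "intersect_log") <- log
  out
}

#' @describeIn read_vcf Tidy a genotype matrix into a long tibble
#'   (chrom, pos, ref, alt, sample, dosage).
#' @param x A `genotype_matrix`.
#' @param ... Unused.
#' @export
tidy.genotype_matrix <- function(x, ...) {
  d <- as_tibble(x$dosage)
  dplyr::bind_cols(x$sites[, c("chrom", "pos", "ref", "alt")], d) |>
    tidyr::pivot_longer(-c("chrom", "pos", "ref", "alt"),
                        names_to = "sample", values_to = "dosage")
}

#' @describeIn read_pool_counts Tidy pool counts into a long tibble
#'   (chrom, pos, ref, alt, pool, ref_count, alt_count, masked).
#' @param x A `pool_counts` object.
#' @param ... Unused.
#' @export
tidy.pool_counts <- function(x, ...) {
  purrr::map_dfr(seq_along(x$pools), function(i) {
    dplyr::bind_cols(
      x$sites[, c("chrom", "pos", "ref", "alt")],
      tibble(pool = x$pools[i],
             ref_count = x$ref_count[, i],
             alt_count = x$alt_count[, i],
             masked = x$masked[, i])
    )
  })
}
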