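# Independent oracles, written directly from the definitions and kept free
# of any package internals so they can arbitrate disagreements.

# Weir & Cockerham (1984) variance components for r populations at one
# biallelic locus; scalar transcription of the published formulas.
# p: per-population allele frequencies; n_ind: diploid sample sizes;
# h: per-population heterozygote frequencies (HWE expectation by default).
oracle_wc84 <- function(p, n_ind, h = 2 * p * (1 - p)) {
  r <- length(p)
  nbar <- mean(n_ind)
  nc <- (sum(n_ind) - sum(n_ind^2) / sum(n_ind)) / (r - 1)
  pbar <- sum(n_ind * p) / sum(n_ind)
  s2 <- sum(n_ind * (p - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n_ind * h) / sum(n_ind)
  a <- (nbar / nc) *
    (s2 - (1 / (nbar - 1)) * (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - ((r - 1) / r) * s2 - ((2 * nbar - 1) / (4 * nbar)) * hbar)
  cc <- hbar / 2
  c(a = a, b = b, c = cc)
}

oracle_wc84_theta <- function(p1, p2, n1_hap, n2_hap) {
  k <- oracle_wc84(c(p1, p2), c(n1_hap, n2_hap) / 2)
  if (sum(k) == 0) return(NA_real_)
  unname(k["a"] / sum(k))
}

# brute-force window mean: literal membership test per window
oracle_window_mean <- function(pos, value, starts, width, min_snps) {
  vapply(starts, function(s) {
    v <- value[pos >= s & pos < s + width]
    v <- v[!is.na(v)]
    if (length(v) < min_snps || length(v) == 0L) NA_real_ else mean(v)
  }, numeric(1))
}

# brute-force EHH: fraction of carrier pairs identical over every site
# between the core and x (inclusive), by explicit pair enumeration
oracle_ehh_at <- function(hap, core, x, allele) {
  carriers <- which(hap[, core] == allele)
  n <- length(carriers)
  span <- seq(min(core, x), max(core, x))
  same <- 0L
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      if (all(hap[carriers[i], span] == hap[carriers[j], span])) same <- same + 1L
    }
  }
  same / (n * (n - 1) / 2)
}

# brute-force one-direction integrated EHH with truncation at `trunc`
oracle_ihh_dir <- function(hap, positions, core, allele, dirstep, trunc = 0.05) {
  xs <- 0
  ys <- 1
  j <- core + dirstep
  while (j >= 1 && j <= ncol(hap)) {
    e <- oracle_ehh_at(hap, core, j, allele)
    xs <- c(xs, abs(positions[j] - positions[core]))
    ys <- c(ys, e)
    if (e < trunc) break
    j <- j + dirstep
  }
  sum(diff(xs) * (ys[-length(ys)] + ys[-1]) / 2)
}

oracle_ihs_raw <- function(hap, positions, core, trunc = 0.05) {
  ihh_a <- oracle_ihh_dir(hap, positions, core, 0L, -1L, trunc) +
    oracle_ihh_dir(hap, positions, core, 0L, +1L, trunc)
  ihh_d <- oracle_ihh_dir(hap, positions, core, 1L, -1L, trunc) +
    oracle_ihh_dir(hap, positions, core, 1L, +1L, trunc)
  log(ihh_a / ihh_d)
}

# 4-haplotype, 6-site toy panel: every EHH walk truncates before the edge,
# so the whole score is enumerable by hand (rows = chromosomes)
toy_panel <- function() {
  hap <- rbind(
    c(0L, 0L, 1L, 1L, 1L, 1L),
    c(0L, 1L, 1L, 1L, 1L, 0L),
    c(1L, 1L, 0L, 0L, 0L, 0L),
    c(0L, 1L, 0L, 1L, 0L, 0L)
  )
  structure(
    list(chrom = "chr1", positions = c(0L, 1000L, 2000L, 3000L, 4000L, 6000L),
         hap = hap, pop = rep("P", 4)),
    class = "haplotype_panel"
  )
}

# minimal VCF writer for ingestion tests; rows as pre-formatted body lines
write_test_vcf <- function(rows, samples = c("S1", "S2"), path = tempfile(fileext = ".vcf")) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1,length=1000000>",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Total read depth\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    rows
  ), path)
  path
}

vcf_row <- function(pos, ref = "A", alt = "G", qual = 50, dp = 20,
                    gts = c("0/1", "0/0")) {
  paste(c("chr1", pos, ".", ref, alt, qual, "PASS", paste0("DP=", dp), "GT",
          gts), collapse = "\t")
}

table1_path <- function() {
  system.file("extdata", "parallel_fixation_candidates.tsv",
              package = "sweepscan", mustWork = TRUE)
}
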