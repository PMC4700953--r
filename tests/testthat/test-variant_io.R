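test_that("read_vcf keeps only biallelic SNPs passing the quality filter", {
  path <- write_test_vcf(c(
    vcf_row(100, qual = 19),                          # below Phred 20
    vcf_row(200, qual = 50),                          # clean SNP
    vcf_row(300, ref = "AT", alt = "A", qual = 50),   # indel
    vcf_row(400, alt = "G,T", qual = 50),             # multiallelic
    vcf_row(500, qual = 20)                           # boundary: retained
  ))
  gm <- read_vcf(path)
  expect_s3_class(gm, "genotype_matrix")
  expect_equal(gm$sites$pos, c(199L, 499L))  # 0-based
  log <- gm$drop_log
  expect_equal(log$n[log$reason == "low_qual"], 1L)
  expect_equal(log$n[log$reason == "indel_or_nonsnp"], 1L)
  expect_equal(log$n[log$reason == "multiallelic"], 1L)
})

test_that("read_vcf dosage, phasing and missing-call handling", {
  path <- write_test_vcf(c(
    vcf_row(100, gts = c("1|1", "0|1")),
    vcf_row(200, gts = c("0|0", ".|.")),
    vcf_row(300, gts = c("0|1", "1|1"))
  ))
  gm <- read_vcf(path)
  expect_true(gm$phased)
  expect_equal(unname(gm$dosage[, "S1"]), c(2L, 0L, 1L))
  expect_equal(unname(gm$dosage[, "S2"]), c(1L, NA_integer_, 2L))
  expect_equal(dim(gm$haplotypes), c(3L, 4L))
  # unphased separators switch the flag off
  gm2 <- read_vcf(write_test_vcf(vcf_row(100, gts = c("0/1", "0/0"))))
  expect_false(gm2$phased)
  expect_null(gm2$haplotypes)
})

test_that("zero retained sites warns rather than failing silently", {
  path <- write_test_vcf(vcf_row(100, qual = 5))
  expect_warning(gm <- read_vcf(path), "no sites retained")
  expect_equal(nrow(gm$sites), 0L)
})

test_that("depth band removes an extreme-coverage site", {
  depths <- c(rep(10, 20), 100)
  sites <- tibble::tibble(pos = seq_along(depths), depth = depths)
  kept <- apply_depth_filter(sites, sigma = 2)
  # direct arithmetic: band = mean +/- 2 sd over the full input
  band <- mean(depths) + c(-2, 2) * sd(depths)
  expect_true(100 > band[2])
  expect_equal(kept$depth, rep(10, 20))
})

test_that("depth filter edge cases: equal depths, sigma 0, tiny input", {
  eq <- tibble::tibble(depth = rep(7, 5))
  expect_equal(nrow(apply_depth_filter(eq, sigma = 2)), 5L)
  uneq <- tibble::tibble(depth = c(10, 20, 30))
  expect_equal(apply_depth_filter(uneq, sigma = 0)$depth, 20)
  expect_error(apply_depth_filter(tibble::tibble(depth = 1), 2), "at least 2")
})

test_that("filtering is deterministic and monotone in sigma", {
  set.seed(11)
  path <- write_test_vcf(vapply(1:40, function(i) {
    vcf_row(i * 100, dp = rpois(1, 30))
  }, character(1)))
  gm1 <- read_vcf(path)
  gm2 <- read_vcf(path)  # same file, same config: identical table
  expect_identical(gm1$sites, gm2$sites)
  expect_identical(gm1$dosage, gm2$dosage)
  sites <- tibble::tibble(depth = rpois(200, 30))
  kept <- vapply(c(0.5, 1, 2, 3), function(s) nrow(apply_depth_filter(sites, s)),
                 numeric(1))
  expect_true(all(diff(kept) >= 0))
  expect_equal(kept[4], 200)
})

test_that("pool-count ingestion masks shallow pools and rejects bad tables", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c(
    "chrom\tpos\tref\talt\tP1_ref\tP1_alt\tP2_ref\tP2_alt",
    "chr1\t101\tA\tG\t2\t8\t5\t5",
    "chr1\t201\tC\tT\t0\t0\t3\t9"
  ), path)
  pc <- read_pool_counts(path)
  expect_equal(pc$sites$pos, c(100L, 200L))
  expect_false(pc$masked[1, "P1"])
  expect_true(pc$masked[2, "P1"])   # 0 reads: frequency undefined
  expect_false(pc$masked[2, "P2"])

  dup <- tempfile(fileext = ".tsv")
  writeLines(c(
    "chrom\tpos\tref\talt\tP1_ref\tP1_alt",
    "chr1\t101\tA\tG\t2\t8",
    "chr1\t101\tA\tG\t1\t9"
  ), dup)
  expect_error(read_pool_counts(dup), "duplicated")

  bad <- tempfile(fileext = ".tsv")
  writeLines(c(
    "chrom\tpos\tref\talt\tP1_ref\tP1_alt",
    "chr1\t101\tA\tG\ttwo\t8"
  ), bad)
  expect_error(read_pool_counts(bad), "parse error")
})

test_that("intersect_sites matches a brute-force set oracle and flips alleles", {
  v1 <- write_test_vcf(c(
    vcf_row(100, gts = c("0/1", "0/0")),
    vcf_row(200, gts = c("1/1", "0/1")),
    vcf_row(300, gts = c("0/0", "0/1"))
  ))
  # site 100 absent; site 200 with ref/alt swapped; site 400 private
  v2 <- write_test_vcf(c(
    paste(c("chr1", 200, ".", "G", "A", 50, "PASS", "DP=20", "GT",
            "0/0", "0/1"), collapse = "\t"),
    vcf_row(300, gts = c("0/1", "0/1")),
    vcf_row(400, gts = c("0/1", "0/1"))
  ))
  t1 <- read_vcf(v1)
  t2 <- read_vcf(v2)
  out <- intersect_sites(list(t1, t2))
  brute <- intersect(paste(t1$sites$chrom, t1$sites$pos),
                     paste(t2$sites$chrom, t2$sites$pos))
  expect_setequal(paste(out[[1]]$sites$chrom, out[[1]]$sites$pos), brute)
  expect_equal(out[[1]]$sites$ref, out[[2]]$sites$ref)
  # swapped site complements dosage: "0/0" on the swapped orientation is
  # two copies of the harmonized alternate allele
  i200 <- which(out[[2]]$sites$pos == 199L)
  expect_equal(unname(out[[2]]$dosage[i200, ]), c(2L, 1L))
  log <- attr(out, "intersect_log")
  expect_equal(log$n_flipped[2], 1L)
})

test_that("identical site lists pass through intersect_sites unchanged", {
  sim <- simulate_panel(sim_config(seed = 4, chrom_length = 5e4))
  d <- tempfile()
  emit_fixtures(sim, d)
  gm <- read_vcf(file.path(d, "layers.vcf"))
  pc <- read_pool_counts(file.path(d, "pools.tsv"))
  out <- intersect_sites(list(gm, pc))
  expect_equal(out[[1]]$sites$pos, gm$sites$pos)
  expect_equal(out[[2]]$alt_count, pc$alt_count)
})
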