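test_that("EHH is definitional at the core and collapses with carrier diversity", {
  panel <- toy_panel()
  curve <- ehh(panel, core = 3, allele = "derived")
  expect_equal(curve$ehh[curve$offset == 0], c(1, 1))
  # all carriers globally identical: EHH stays 1 to the edge
  mono <- panel
  mono$hap <- rbind(c(1L, 1L, 1L, 1L, 1L, 1L),
                    c(1L, 1L, 1L, 1L, 1L, 1L),
                    c(0L, 1L, 0L, 1L, 0L, 0L),
                    c(0L, 0L, 0L, 0L, 1L, 0L))
  c2 <- ehh(mono, core = 3, allele = "derived")
  expect_true(all(c2$ehh == 1))
  expect_equal(unname(attr(c2, "stops")), c("edge", "edge"))
  # carriers pairwise distinct at the adjacent site: EHH drops to 0 there
  c3 <- ehh(mono, core = 3, allele = "ancestral")
  expect_equal(c3$ehh[c3$direction == "downstream"], c(1, 0))
  # fewer than 2 carriers: curve undefined
  solo <- panel
  solo$hap[, 3] <- c(1L, 0L, 0L, 0L)
  expect_null(ehh(solo, core = 3, allele = "derived"))
})

test_that("every computed EHH curve is monotone non-increasing outward", {
  sim <- simulate_panel(sim_config(seed = 41, chrom_length = 4e4,
    sweep_specs = list(sweep_spec(2e4, "WL", p_sweep = 0.8,
                                  decay_length = 1.5e4))))
  panel <- panel_subset(sim$panel, "WL")
  set.seed(1)
  for (core in sample(ncol(panel$hap), 40)) {
    for (al in c("derived", "ancestral")) {
      curve <- ehh(panel, core, al)
      if (is.null(curve)) next
      for (dir in unique(curve$direction)) {
        e <- curve$ehh[curve$direction == dir]
        expect_true(all(diff(e) <= 1e-12))
      }
    }
  }
})

test_that("EHH and iHS match brute-force pair enumeration on small panels", {
  panel <- toy_panel()
  # spot-check EHH against explicit pair counting
  for (x in c(2, 4, 5)) {
    walk <- ehh(panel, core = 3, allele = "derived")
    got <- walk$ehh[walk$pos == panel$positions[x]]
    if (length(got)) {
      expect_equal(got, oracle_ehh_at(panel$hap, 3, x, 1L))
    }
  }
  # frozen exhaustive value for the toy panel: ihh_a = 2000, ihh_d = 3500
  res <- ihs(panel, maf_min = 0.05)
  row <- res[res$pos == 2000L, ]
  expect_equal(row$ihh_a, 2000)
  expect_equal(row$ihh_d, 3500)
  expect_equal(row$ihs_raw, log(4 / 7))
  expect_equal(row$ihs_raw, oracle_ihs_raw(panel$hap, panel$positions, 3))
})

test_that("iHS on random panels agrees with the brute-force oracle", {
  set.seed(43)
  for (rep in 1:3) {
    n <- 12
    m <- 30
    hap <- matrix(rbinom(n * m, 1L, 0.5), n, m)
    positions <- sort(sample.int(5000, m))
    panel <- structure(list(chrom = "chr1", positions = positions, hap = hap,
                            pop = rep("P", n)), class = "haplotype_panel")
    res <- ihs(panel, maf_min = 0.2)
    defined <- res[!is.na(res$ihs_raw), ]
    skip_if(nrow(defined) == 0, "no scoreable core in this draw")
    for (i in seq_len(min(5, nrow(defined)))) {
      core <- match(defined$pos[i], positions)
      expect_equal(defined$ihs_raw[i],
                   oracle_ihs_raw(hap, positions, core))
    }
  }
})

test_that("iHS is antisymmetric under ancestral/derived relabeling", {
  sim <- simulate_panel(sim_config(seed = 44, chrom_length = 3e4))
  panel <- panel_subset(sim$panel, "BL")
  flipped <- panel
  flipped$hap <- 1L - flipped$hap
  a <- ihs(panel)
  b <- ihs(flipped)
  expect_equal(b$daf, 1 - a$daf)
  both <- !is.na(a$ihs_raw) & !is.na(b$ihs_raw)
  expect_gt(sum(both), 10)
  expect_equal(b$ihs_raw[both], -a$ihs_raw[both])
})

test_that("standardized scores have mean 0 and unit spread within bins", {
  sim <- simulate_panel(sim_config(seed = 45, chrom_length = 1e5))
  sc <- standardize_ihs(ihs(panel_subset(sim$panel, "WL")))
  bin <- cut(sc$daf, seq(0, 1, length.out = 21), include.lowest = TRUE)
  for (b in levels(bin)) {
    z <- sc$ihs_std[bin == b & !is.na(sc$ihs_std)]
    if (length(z) < 2) next
    expect_lt(abs(mean(z)), 1e-10)
    expect_equal(sd(z), 1, tolerance = 1e-10)
  }
  # single-site and zero-spread bins stay missing
  one <- tibble::tibble(chrom = "chr1", pos = c(1L, 2L, 3L),
                        daf = c(0.12, 0.52, 0.53),
                        ihh_a = 1, ihh_d = 1, ihs_raw = c(0.5, 0.7, 0.7))
  expect_warning(out <- standardize_ihs(one), "zero iHS spread")
  expect_true(is.na(out$ihs_std[1]))
  expect_true(all(is.na(out$ihs_std[2:3])))
})

test_that("swept windows carry elevated |iHS| (directional power)", {
  # paired comparison across replicates: mean |iHS| inside the swept tract
  # against the panel-wide mean; the chromosome is long enough that swept
  # cores truncate before the edge instead of being excluded
  n_rep <- 50L
  diffs <- vapply(seq_len(n_rep), function(i) {
    sim <- simulate_panel(sim_config(seed = 4600 + i, chrom_length = 8e4,
      sweep_specs = list(sweep_spec(4e4, "WL", p_sweep = 0.8,
                                    decay_length = 8e3))))
    sc <- suppressWarnings(standardize_ihs(ihs(panel_subset(sim$panel, "WL"))))
    swept <- abs(sc$pos - 4e4) < 8e3
    mean(abs(sc$ihs_std[swept]), na.rm = TRUE) -
      mean(abs(sc$ihs_std), na.rm = TRUE)
  }, numeric(1))
  expect_gt(mean(diffs), 0)
  expect_gt(mean(diffs > 0), 0.8)
})

test_that("unphased genotypes are rejected for haplotype statistics", {
  path <- write_test_vcf(vcf_row(100, gts = c("0/1", "0/0")))
  gm <- read_vcf(path)
  expect_error(as_haplotype_panel(gm), "not phased")
  phased <- read_vcf(write_test_vcf(c(vcf_row(100, gts = c("0|1", "0|0")),
                                      vcf_row(200, gts = c("1|1", "0|1")))))
  panel <- as_haplotype_panel(phased, c(S1 = "A", S2 = "B"))
  expect_equal(nrow(panel$hap), 4L)
  expect_equal(panel$pop, c("A", "A", "B", "B"))
  expect_equal(unname(panel$hap[, 1]), c(0L, 1L, 0L, 0L))
})
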