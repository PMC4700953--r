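test_that("identical seeds give identical simulations, different seeds differ", {
  cfg <- sim_config(seed = 9, chrom_length = 5e4)
  a <- simulate_panel(cfg)
  b <- simulate_panel(cfg)
  expect_identical(a$panel$hap, b$panel$hap)
  expect_identical(a$pools$alt_count, b$pools$alt_count)
  expect_identical(a$truth, b$truth)
  c <- simulate_panel(sim_config(seed = 10, chrom_length = 5e4))
  expect_false(identical(a$panel$hap, c$panel$hap))
})

test_that("SNP spacing and site frame match the configuration", {
  sim <- simulate_panel(sim_config(seed = 2, chrom_length = 5e5, mean_spacing = 107))
  gaps <- diff(sim$panel$positions)
  expect_gt(length(gaps), 3000)
  expect_lt(abs(mean(gaps) - 107), 10)
  expect_true(all(sim$panel$positions < 5e5))
  expect_identical(sim$panel$positions, sim$pools$sites$pos)
})

test_that("vanishing drift parameter gives undifferentiated populations", {
  sim <- simulate_panel(sim_config(seed = 3, chrom_length = 1e6,
                                   baseline_fst = 1e-9))
  tr <- panel_freq(sim$panel)
  wl <- tr$freq[tr$pop == "WL"]
  bl <- tr$freq[tr$pop == "BL"]
  fst <- wc_fst_global(wl, bl, 50, 50)
  expect_lt(abs(fst), 0.01)
})

test_that("Balding-Nichols drift parameter is recovered from sampled genotypes", {
  sim <- simulate_panel(sim_config(seed = 5, chrom_length = 1e6))
  tr <- panel_freq(sim$panel)
  fst <- wc_fst_global(tr$freq[tr$pop == "WL"], tr$freq[tr$pop == "BL"], 50, 50)
  expect_lt(abs(fst - 0.18), 0.02)
})

test_that("implanted sweep follows the exponential hitchhiking decay", {
  center <- 5e5
  L <- 1e5
  cfg <- sim_config(seed = 21, chrom_length = 1e6,
    sweep_specs = list(sweep_spec(center, c("BR1", "BR2", "BR3"),
                                  p_sweep = 0.95, decay_length = L)))
  sim <- simulate_panel(cfg)
  neutral <- simulate_neutral_panel(cfg)
  d <- abs(sim$truth$pos - center)
  for (pool in c("BR1", "BR2", "BR3")) {
    excess <- sim$truth[[pool]] - neutral$truth[[pool]]
    expected <- (0.95 - neutral$truth[[pool]]) * exp(-d / L)
    expect_equal(excess, expected, tolerance = 1e-10)
  }
  # non-target populations untouched
  expect_identical(sim$truth$WL, neutral$truth$WL)
  # frequency at the center approaches p_sweep; at distance L the excess
  # decays to exp(-1) of the center excess
  near <- d < 5e3
  expect_lt(abs(mean(sim$truth$BR1[near]) - 0.95), 0.05)
  at_L <- abs(d - L) < 5e3
  ratio <- mean((sim$truth$BR1 - neutral$truth$BR1)[at_L] /
                  (0.95 - neutral$truth$BR1[at_L]))
  expect_lt(abs(ratio - exp(-1)), 0.05)
})

test_that("null sweep (p_sweep at background) leaves frequencies in place", {
  cfg <- sim_config(seed = 8, chrom_length = 1e5, baseline_fst = 1e-9,
                    ancestral_range = c(0.5, 0.5))
  sim <- simulate_panel(cfg)
  set.seed(1)
  before <- colMeans(sim$panel$hap[sim$panel$pop == "WL", ])
  swept <- implant_sweep(sim$panel, sweep_spec(5e4, "WL", p_sweep = 0.5,
                                               decay_length = 2e4,
                                               core_haplotype = FALSE))
  after <- colMeans(swept$hap[swept$pop == "WL", ])
  # raising toward a target at the background level never lowers a
  # frequency, and shifts stay within binomial sampling noise of zero
  expect_true(all(after >= before - 1e-12))
  expect_lt(mean(after - before), 0.02)
})

test_that("core-haplotype sweeps share derived alleles across the tract", {
  cfg <- sim_config(seed = 13, chrom_length = 2e5,
    sweep_specs = list(sweep_spec(1e5, "WL", p_sweep = 0.9,
                                  decay_length = 5e4, core_haplotype = TRUE)))
  sim <- simulate_panel(cfg)
  wl <- sim$panel$hap[sim$panel$pop == "WL", ]
  core <- which.min(abs(sim$panel$positions - 1e5))
  carriers <- which(wl[, core] == 1L)
  expect_gt(length(carriers), 35)  # ~0.9 * 50
  # most center carriers share one haplotype over the near-core tract
  tract <- abs(sim$panel$positions - 1e5) < 5e3
  patterns <- apply(wl[carriers, tract, drop = FALSE], 1, paste, collapse = "")
  expect_gt(max(table(patterns)) / length(carriers), 0.6)
})

test_that("sweep validation rejects bad targets", {
  cfg <- sim_config(seed = 1, chrom_length = 1e5)
  sim <- simulate_panel(cfg)
  expect_error(sweep_spec(5e4, character()), "target")
  expect_error(implant_sweep(sim$panel, sweep_spec(9e9, "WL")), "outside")
  expect_error(implant_sweep(sim$panel, sweep_spec(5e4, "NOPE")), "target")
  expect_error(sim_config(baseline_fst = 0), "between 0 and 1")
})

test_that("emitted fixtures round-trip exactly through the readers", {
  sim <- simulate_panel(sim_config(seed = 6, chrom_length = 4e4))
  d <- tempfile()
  paths <- emit_fixtures(sim, d)
  gm <- read_vcf(paths[["vcf"]])
  expect_true(gm$phased)
  # dosages reconstruct the panel's per-population frequencies exactly
  for (p in c("WL", "BL")) {
    got <- genotype_freq(gm, grep(paste0("^", p), gm$samples, value = TRUE))
    want <- colMeans(sim$panel$hap[sim$panel$pop == p, ])
    expect_equal(got$freq, unname(want))
  }
  pc <- read_pool_counts(paths[["pools"]])
  expect_identical(pc$alt_count, sim$pools$alt_count)
  expect_identical(pc$ref_count, sim$pools$ref_count)
  # identical rerun produces byte-identical files
  d2 <- tempfile()
  emit_fixtures(simulate_panel(sim_config(seed = 6, chrom_length = 4e4)), d2)
  expect_identical(readLines(file.path(d, "layers.vcf")),
                   readLines(file.path(d2, "layers.vcf")))
  empty <- sim
  empty$panel$positions <- integer()
  expect_error(emit_fixtures(empty, tempfile()), "empty")
})
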