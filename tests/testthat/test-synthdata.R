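test_that("panel simulation is deterministic and respects degenerate sizes", {
  cfg <- sim_config(n_sites = 50, genome_length = 5e4, n_haplotypes = 20)
  p1 <- simulate_panel(cfg, seed = 7)
  p2 <- simulate_panel(cfg, seed = 7)
  expect_identical(p1$alleles, p2$alleles)
  expect_identical(p1$sites, p2$sites)

  tiny <- simulate_panel(sim_config(n_sites = 1, genome_length = 10,
                                    n_haplotypes = 2, cpg_proportion = 0),
                         seed = 1)
  expect_equal(dim(tiny$alleles), c(2L, 1L))
  expect_true(all(tiny$alleles %in% c(0L, 1L)))

  expect_error(simulate_panel(sim_config(n_sites = 100, genome_length = 50)),
               "genome_length")
  expect_error(sim_config(n_sites = -1), "positive")
})

test_that("panel MAF spectrum matches the configured truncated-beta mass", {
  cfg <- sim_config(n_sites = 10000, genome_length = 5e6, n_haplotypes = 200)
  panel <- simulate_panel(cfg, seed = 11)
  maf <- compute_maf(panel)

  # oracle: numeric integration of the configured truncated beta density,
  # folded about 1/2, over MAF < 0.1
  dens <- function(p) stats::dbeta(p, cfg$af_alpha, cfg$af_beta)
  min_maf <- 1 / cfg$n_haplotypes
  z <- stats::integrate(dens, min_maf, 1 - min_maf)$value
  mass_below <- (stats::integrate(dens, min_maf, 0.1)$value +
                   stats::integrate(dens, 0.9, 1 - min_maf)$value) / z

  expect_lt(abs(mean(maf < 0.1) - mass_below), 0.05)
})

test_that("sample mosaics copy panel rows and switch at the configured rate", {
  cfg <- sim_config(n_sites = 200, genome_length = 2e5, n_haplotypes = 30)
  panel <- simulate_panel(cfg, seed = 3)

  nosw <- simulate_samples(panel, 5, switch_rate = 0, seed = 4)
  for (i in 1:5) {
    expect_true(any(apply(panel$alleles, 1, identical, nosw$hap1[i, ])))
    expect_equal(length(unique(nosw$source1[i, ])), 1L)
  }

  mono <- haplotype_panel(panel$sites,
                          matrix(rep(panel$alleles[1, ], each = 4), nrow = 4))
  ms <- simulate_samples(mono, 3, switch_rate = 1e-4, seed = 5)
  expect_equal(true_genotype_matrix(ms),
               matrix(rep(2L * panel$alleles[1, ], each = 3), nrow = 3),
               ignore_attr = TRUE)

  # Poisson-count oracle: mean visible switch count over many haplotypes
  rate <- 1e-5
  cfg2 <- sim_config(n_sites = 1000, genome_length = 1e6, n_haplotypes = 50)
  panel2 <- simulate_panel(cfg2, seed = 6)
  sams <- simulate_samples(panel2, 600, switch_rate = rate, seed = 7)
  switches <- c(rowSums(sams$source1[, -1] != sams$source1[, -1000]),
                rowSums(sams$source2[, -1] != sams$source2[, -1000]))
  # expected visible switches: sum of per-gap switch probabilities, thinned
  # by the 1/H chance of re-drawing the same row
  lambda <- sum(1 - exp(-rate * diff(panel2$sites$pos))) * (1 - 1 / 50)
  se <- sqrt(lambda / length(switches))
  expect_lt(abs(mean(switches) - lambda), 3 * se)
})

test_that("read simulation hits the requested coverage with Poisson depths", {
  sc <- tiny_scenario(seed = 21, coverage = 0)
  expect_equal(nrow(sc$reads$reads), 0L)

  cfg <- sim_config(n_sites = 500, genome_length = 5e5, n_haplotypes = 40,
                    n_samples = 4)
  panel <- simulate_panel(cfg, seed = 22)
  truth <- simulate_samples(panel, 4, cfg$sample_switch_rate, seed = 23)
  reads <- simulate_reads(truth, config = cfg, coverage = 0.5, seed = 24)

  cov <- realized_coverage(reads)
  expect_true(all(abs(cov - 0.5) / 0.5 < 0.05))

  # balanced haplotype of origin
  frac1 <- mean(reads$reads$hap_origin == 1)
  se <- sqrt(0.25 / nrow(reads$reads))
  expect_lt(abs(frac1 - 0.5), 3 * se)

  # per-site depth approximately Poisson(coverage)
  pile <- build_pileup(reads, panel$sites)
  depth <- pileup_depth(pile)$depth
  expect_gt(var(depth) / mean(depth), 0.8)
  expect_lt(var(depth) / mean(depth), 1.2)
})

test_that("read errors follow e, inflated at CpG sites on the masked strand", {
  # noiseless limit: every observed base equals the originating allele
  cfg0 <- sim_config(n_sites = 100, genome_length = 1e5, n_haplotypes = 20,
                     n_samples = 2, base_error = 1e-9,
                     cpg_error_inflation = 1)
  panel0 <- simulate_panel(cfg0, seed = 31)
  truth0 <- simulate_samples(panel0, 2, 0, seed = 32)
  reads0 <- simulate_reads(truth0, config = cfg0, coverage = 5, seed = 33)
  obs <- reads0$obs
  origin <- reads0$reads$hap_origin[match(obs$read_id, reads0$reads$read_id)]
  s_idx <- match(obs$sample_id, truth0$sample_id)
  allele <- ifelse(origin == 1,
                   truth0$hap1[cbind(s_idx, obs$site)],
                   truth0$hap2[cbind(s_idx, obs$site)])
  want <- ifelse(allele == 1, panel0$sites$alt[obs$site],
                 panel0$sites$ref[obs$site])
  expect_identical(obs$base, want)

  # binomial oracle on e' = inflation * e at CpG-forward sites, forward reads
  cfg <- sim_config(n_sites = 2000, genome_length = 2e5, n_haplotypes = 20,
                    n_samples = 2, base_error = 0.03,
                    cpg_error_inflation = 10, cpg_proportion = 0.5)
  panel <- simulate_panel(cfg, seed = 34)
  truth <- simulate_samples(panel, 2, 0, seed = 35)
  reads <- simulate_reads(truth, config = cfg, coverage = 50, seed = 36)
  obs <- reads$obs
  origin <- reads$reads$hap_origin[match(obs$read_id, reads$reads$read_id)]
  s_idx <- match(obs$sample_id, truth$sample_id)
  allele <- ifelse(origin == 1,
                   truth$hap1[cbind(s_idx, obs$site)],
                   truth$hap2[cbind(s_idx, obs$site)])
  want <- ifelse(allele == 1, panel$sites$alt[obs$site],
                 panel$sites$ref[obs$site])
  cpgf_fwd <- panel$sites$cpg_forward[obs$site] & obs$strand == "+"
  n <- sum(cpgf_fwd)
  expect_gt(n, 2e4)
  mis <- mean(obs$base[cpgf_fwd] != want[cpgf_fwd])
  expect_lt(abs(mis - 0.30), 3 * sqrt(0.3 * 0.7 / n))
  # phred-derived error still encodes the baseline e
  expect_true(all(obs$e == 0.03))
})

test_that("effect simulation is sparse, Gaussian and seeded", {
  cfg <- sim_config(n_sites = 400, genome_length = 4e5,
                    prop_prediction = 0.5)
  panel <- simulate_panel(cfg, seed = 41)

  zero <- simulate_effects(panel$sites, prop_causal = 0, seed = 42)
  expect_true(all(zero$effect == 0))
  expect_equal(nrow(zero), sum(panel$sites$is_prediction_site))

  full <- simulate_effects(panel$sites, prop_causal = 1, seed = 42)
  expect_equal(sum(full$effect != 0), nrow(full))

  # binomial oracle on the causal count
  cfg2 <- sim_config(n_sites = 10000, genome_length = 2e6,
                     prop_prediction = 1)
  panel2 <- simulate_panel(cfg2, seed = 43)
  eff <- simulate_effects(panel2$sites, prop_causal = 0.1, seed = 44)
  expect_lt(abs(sum(eff$effect != 0) - 1000), 3 * sqrt(10000 * 0.1 * 0.9))

  expect_identical(simulate_effects(panel$sites, 0.5, 1, seed = 9),
                   simulate_effects(panel$sites, 0.5, 1, seed = 9))
  expect_error(simulate_effects(panel$sites, effect_sd = -1), "negative")
})
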