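column_of <- function(bases, e) {
  tibble::tibble(base = bases, e = rep_len(e, length(bases)))
}

test_that("Q-score likelihood matches the per-read product formula", {
  expect_equal(genotype_likelihood_qscore(column_of(character(0), 0.01), "A", "C"),
               c(rr = 1, ra = 1, aa = 1))

  one <- genotype_likelihood_qscore(column_of("A", 0.01), "A", "C")
  expect_equal(unname(one), c(0.99, 0.4966667, 0.0033333), tolerance = 1e-6)

  two <- genotype_likelihood_qscore(column_of(c("A", "C"), 0.01), "A", "C")
  expect_equal(unname(two),
               unname(oracle_gl(c("A", "C"), c(0.01, 0.01), "A", "C")),
               tolerance = 1e-12)
  expect_equal(unname(two), c(0.0033, 0.2466778, 0.0033), tolerance = 1e-6)
  expect_gt(two["ra"], max(two["rr"], two["aa"]))

  # third-allele bases contribute e/3 under both alleles
  third <- genotype_likelihood_qscore(column_of("G", 0.03), "A", "C")
  expect_equal(unname(third), rep(0.01, 3))

  expect_error(genotype_likelihood_qscore(column_of("A", 0.01), "A", "A"),
               "differ")
  expect_error(genotype_likelihood_qscore(column_of("A", 1.2), "A", "C"),
               "error probabilities")
})

test_that("likelihoods agree with an independent oracle on random columns", {
  set.seed(202)
  worst <- 0
  for (i in 1:1000) {
    m <- sample(0:8, 1)
    ref <- sample(c("A", "C", "G", "T"), 1)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    bases <- sample(c("A", "C", "G", "T"), m, replace = TRUE)
    errs <- runif(m, 1e-4, 0.3)
    got <- genotype_likelihood_qscore(tibble::tibble(base = bases, e = errs),
                                      ref, alt)
    want <- oracle_gl(bases, errs, ref, alt)
    worst <- max(worst, max(abs(got - want)))
  }
  expect_lt(worst, 1e-12)
})

test_that("likelihood symmetry and depth monotonicity hold", {
  set.seed(203)
  for (i in 1:50) {
    m <- sample(1:6, 1)
    bases <- sample(c("A", "C", "G"), m, replace = TRUE)
    errs <- runif(m, 0.001, 0.2)
    ab <- genotype_likelihood_qscore(tibble::tibble(base = bases, e = errs), "A", "C")
    ba <- genotype_likelihood_qscore(tibble::tibble(base = bases, e = errs), "C", "A")
    expect_equal(unname(ab[c("aa", "ra", "rr")]), unname(ba), tolerance = 1e-14)
  }
  ratios <- vapply(c(1, 2, 4, 8), function(m) {
    l <- genotype_likelihood_qscore(column_of(rep("A", m), 0.02), "A", "C")
    l["rr"] / l["ra"]
  }, 0)
  expect_true(all(diff(ratios) > 0))
})

test_that("methylation masking keeps only the non-methylated strand", {
  pile <- tibble::tibble(
    sample_id = "S1", read_id = sprintf("r%d", 1:10),
    site = rep(1:2, each = 5), pos = rep(c(10L, 20L), each = 5),
    base = "A", e = 0.01,
    strand = c("+", "+", "+", "-", "-", "+", "+", "+", "-", "-"),
    ref = "C", alt = "A",
    cpg_forward = rep(c(TRUE, FALSE), each = 5),
    cpg_reverse = FALSE
  )
  masked <- methylation_mask(pile)
  expect_equal(sum(masked$site == 1), 2L)            # reverse reads survive
  expect_true(all(masked$strand[masked$site == 1] == "-"))
  expect_equal(sum(masked$site == 2), 5L)            # non-CpG untouched

  pile$cpg_forward <- FALSE
  expect_equal(nrow(methylation_mask(pile)), 10L)

  # fully masked column proceeds with depth 0 and uniform likelihoods
  allfwd <- pile[pile$site == 1, ]
  allfwd$cpg_forward <- TRUE
  allfwd$strand <- "+"
  expect_equal(nrow(methylation_mask(allfwd)), 0L)

  # a cpg_reverse site keeps forward-strand reads and drops reverse ones
  rev_site <- tibble::tibble(
    sample_id = "S1", read_id = c("r1", "r2"), site = 1L, pos = 10L,
    base = "G", e = 0.01, strand = c("-", "+"), ref = "G", alt = "C",
    cpg_forward = FALSE, cpg_reverse = TRUE
  )
  kept <- methylation_mask(rev_site)
  expect_equal(kept$strand, "+")
})

test_that("MAC caller follows the stated decision rule", {
  r1 <- mac_rule(1, Inf, mac = 1)
  col <- tibble::tibble(base = c("A", "A", "C"), ref = "A", alt = "C")
  expect_equal(call_mac(col, r1), 1L)

  expect_equal(call_mac(col[0, ], r1), NA_integer_)

  r2 <- mac_rule(1, Inf, mac = 2)
  col10 <- tibble::tibble(base = c(rep("A", 9), "C"), ref = "A", alt = "C")
  expect_equal(call_mac(col10, r2), 0L)

  # default bins: 1-4 -> 1, 5-9 -> 2, >= 10 -> ceiling(0.15 * depth)
  rule <- default_mac_rule()
  expect_equal(skimpute:::mac_for_depth(rule, c(1, 4, 5, 9, 10, 20, 40)),
               c(1, 1, 2, 2, 2, 3, 6))
  expect_error(mac_rule(c(1, 7), c(4, 9), mac = c(1, 2)), "contiguous")
  expect_error(skimpute:::mac_for_depth(mac_rule(1, 4, 1), 5), "outside")

  # never a heterozygote at depth < 2
  for (b in list("A", "C")) {
    expect_false(isTRUE(call_mac(tibble::tibble(base = b, ref = "A", alt = "C"),
                                 rule) == 1L))
  }
})

test_that("genotype_sample produces coherent call sets on both paths", {
  sc <- tiny_scenario(seed = 81, coverage = 30, n_samples = 2,
                      base_error = 1e-4)
  tg <- true_genotype_matrix(sc$truth)

  qs <- genotype_sample(sc$reads, sc$panel$sites, method = "qscore",
                        hard_calls = TRUE)
  expect_true(all(qs$source == "qscore"))
  gt <- call_matrix(qs, value = "gt")[sc$truth$sample_id, ]
  expect_equal(unname(gt), unname(tg))  # noiseless deep limit recovers truth

  mac <- genotype_sample(sc$reads, sc$panel$sites, method = "mac")
  gtm <- call_matrix(mac, value = "gt")[sc$truth$sample_id, ]
  expect_gt(mean(gtm == tg, na.rm = TRUE), 0.99)
  expect_true(all(mac$source == "mac"))

  # 0.05x sparsity: most sites missing (MAC) or uniform likelihoods (Q-score)
  sparse <- subsample_reads(sc$reads, 0.05, seed = 82)
  mac2 <- genotype_sample(sparse, sc$panel$sites, method = "mac")
  expect_gt(mean(is.na(mac2$gt)), 0.5)
  qs2 <- genotype_sample(sparse, sc$panel$sites, method = "qscore")
  expect_gt(mean(qs2$gl_rr == 1 & qs2$gl_ra == 1 & qs2$gl_aa == 1), 0.5)

  # vectorized likelihoods equal the column-wise formula
  pile <- methylation_mask(build_pileup(sc$reads, sc$panel$sites))
  some <- dplyr::slice_sample(dplyr::distinct(pile[, c("sample_id", "site")]),
                              n = 25)
  for (i in seq_len(nrow(some))) {
    col <- pile[pile$sample_id == some$sample_id[i] & pile$site == some$site[i], ]
    want <- genotype_likelihood_qscore(col, col$ref[1], col$alt[1])
    got <- qs[qs$sample_id == some$sample_id[i] & qs$site == some$site[i], ]
    expect_equal(c(got$gl_rr, got$gl_ra, got$gl_aa), unname(want),
                 tolerance = 1e-12)
  }
})
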