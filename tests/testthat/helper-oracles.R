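# Independent oracles used across the test files. These deliberately use
# naive, direct implementations (path enumeration, per-observation loops)
# so they share no code with the package internals they check.

# Genotype-likelihood triple by direct evaluation of the per-read product:
# per read 1/2 Pr(b|A1) + 1/2 Pr(b|A2), Pr(b|A) = 1 - e if b == A else e/3.
oracle_gl <- function(bases, errs, ref, alt) {
  l <- c(rr = 1, ra = 1, aa = 1)
  for (i in seq_along(bases)) {
    pr <- function(allele) if (bases[i] == allele) 1 - errs[i] else errs[i] / 3
    l["rr"] <- l["rr"] * (0.5 * pr(ref) + 0.5 * pr(ref))
    l["ra"] <- l["ra"] * (0.5 * pr(ref) + 0.5 * pr(alt))
    l["aa"] <- l["aa"] * (0.5 * pr(alt) + 0.5 * pr(alt))
  }
  l
}

# Haploid Li-Stephens posterior by exhaustive path enumeration.
# Evidence per site: m1/m0 = products of P(obs | allele 1/0).
oracle_haploid_enum <- function(hap, pswitch, eps, m1, m0) {
  H <- nrow(hap)
  L <- ncol(hap)
  w1 <- ifelse(hap == 1, 1 - eps, eps)
  emm <- matrix(0, H, L)
  for (l in seq_len(L)) emm[, l] <- w1[, l] * m1[l] + (1 - w1[, l]) * m0[l]
  trans <- lapply(seq_len(L - 1), function(l) {
    (1 - pswitch[l]) * diag(H) + pswitch[l] / H
  })
  paths <- as.matrix(expand.grid(rep(list(seq_len(H)), L)))
  tot <- 0
  anum <- numeric(L)
  for (r in seq_len(nrow(paths))) {
    pr <- 1 / H
    for (l in seq_len(L)) {
      h <- paths[r, l]
      if (l > 1) pr <- pr * trans[[l - 1]][paths[r, l - 1], h]
      pr <- pr * emm[h, l]
    }
    tot <- tot + pr
    for (l in seq_len(L)) {
      h <- paths[r, l]
      anum[l] <- anum[l] + pr * w1[h, l] * m1[l] / emm[h, l]
    }
  }
  list(loglik = log(tot), allele_prob = anum / tot)
}

# Diploid Li-Stephens posterior over ordered haplotype pairs by exhaustive
# path enumeration, genotype-likelihood emissions with eps smoothing.
oracle_diploid_enum <- function(gl, hap, pswitch, eps) {
  H <- nrow(hap)
  L <- ncol(hap)
  w1 <- ifelse(hap == 1, 1 - eps, eps)
  jk <- expand.grid(j = seq_len(H), k = seq_len(H))
  trans <- lapply(seq_len(L - 1), function(l) {
    (1 - pswitch[l]) * diag(H) + pswitch[l] / H
  })
  em_state <- function(j, k, l) {
    a1 <- c(1 - w1[j, l], w1[j, l])
    a2 <- c(1 - w1[k, l], w1[k, l])
    pg <- c(a1[1] * a2[1] * gl[l, 1],
            (a1[1] * a2[2] + a1[2] * a2[1]) * gl[l, 2],
            a1[2] * a2[2] * gl[l, 3])
    pg
  }
  paths <- as.matrix(expand.grid(rep(list(seq_len(H * H)), L)))
  tot <- 0
  postnum <- matrix(0, L, 3)
  for (r in seq_len(nrow(paths))) {
    pr <- 1 / (H * H)
    pg_path <- vector("list", L)
    for (l in seq_len(L)) {
      s <- paths[r, l]
      if (l > 1) {
        sp <- paths[r, l - 1]
        pr <- pr * trans[[l - 1]][jk$j[sp], jk$j[s]] *
          trans[[l - 1]][jk$k[sp], jk$k[s]]
      }
      pg <- em_state(jk$j[s], jk$k[s], l)
      pg_path[[l]] <- pg
      pr <- pr * sum(pg)
    }
    tot <- tot + pr
    for (l in seq_len(L)) {
      postnum[l, ] <- postnum[l, ] + pr * pg_path[[l]] / sum(pg_path[[l]])
    }
  }
  list(loglik = log(tot), posterior = postnum / tot)
}

# A small deterministic scenario shared by several files.
tiny_scenario <- function(seed = 101, n_sites = 120, genome_length = 1.2e5,
                          n_haplotypes = 40, n_samples = 3, coverage = 1,
                          base_error = 0.01) {
  cfg <- sim_config(genome_length = genome_length, n_sites = n_sites,
                    n_haplotypes = n_haplotypes, n_samples = n_samples,
                    base_error = base_error, coverage = coverage)
  panel <- simulate_panel(cfg, seed = seed)
  truth <- simulate_samples(panel, n_samples, cfg$sample_switch_rate,
                            seed = seed + 1)
  reads <- simulate_reads(truth, config = cfg, coverage = coverage,
                          seed = seed + 2)
  list(cfg = cfg, panel = panel, truth = truth, reads = reads)
}

# call_set holding the simulated truth genotypes.
truth_call_set <- function(truth, sites) {
  tg <- true_genotype_matrix(truth)
  call_set(
    sample_id = rep(truth$sample_id, each = ncol(tg)),
    site = rep(seq_len(ncol(tg)), nrow(tg)),
    gt = as.integer(t(tg)),
    source = "truth", sites = sites
  )
}
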