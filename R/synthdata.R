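#' Simulation configuration
#'
#' Bundles the parameters of the synthetic-data generator. The defaults define
#' a desk-scale analogue of a skim-sequencing study in a livestock population:
#' a 2 Mb chromosome carrying 2,000 biallelic SNP of which 500 form the
#' prediction set, a reference panel of 200 phased haplotypes built as
#' recombinant mosaics of a founder set (so linkage disequilibrium decays with
#' distance), 20 diploid study samples mosaicked from the panel, and long reads
#' with a mean length of 1,792 bp and a per-base substitution error of about 3%
#' (phred Q15, within the 2.7-7% range typical of nanopore basecalls).
#' Cytosines of CpG dinucleotides carry a 10-fold inflated error on the
#' methylation-prone strand while their recorded base qualities still encode
#' the baseline error, emulating the methylation miscall artefact that base
#' qualities do not reveal.
#'
#' @param genome_length chromosome length in bp.
#' @param n_sites number of segregating sites.
#' @param n_haplotypes number of phased reference haplotypes (even).
#' @param n_samples number of diploid study samples.
#' @param af_alpha,af_beta shape parameters of the beta allele-frequency
#'   spectrum; frequencies are truncated to minor allele frequency at least
#'   `1/n_haplotypes`.
#' @param n_founders founder haplotypes the panel is mosaicked from.
#' @param founder_switch_rate per-bp switch rate of the panel mosaic.
#' @param sample_switch_rate per-bp switch rate of the sample mosaic.
#' @param prop_prediction fraction of sites in the prediction SNP set.
#' @param cpg_proportion fraction of sites flagged as CpG (alternating
#'   forward/reverse strand).
#' @param coverage default sequencing coverage (mean bases per reference bp).
#' @param mean_read_length mean read length in bp (geometric-like).
#' @param base_error per-base substitution error probability `e`.
#' @param cpg_error_inflation multiplicative error inflation at CpG cytosines
#'   observed on the methylation-prone strand.
#' @param prop_causal fraction of prediction sites with nonzero SNP effect.
#' @param effect_sd standard deviation of nonzero SNP effects.
#' @param seed default seed recorded in the config (individual generators also
#'   accept a `seed` argument).
#'
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(genome_length = 2e6,
                       n_sites = 2000,
                       n_haplotypes = 200,
                       n_samples = 20,
                       af_alpha = 0.5,
                       af_beta = 0.5,
                       n_founders = 32,
                       founder_switch_rate = 5e-6,
                       sample_switch_rate = 1e-6,
                       prop_prediction = 0.25,
                       cpg_proportion = 0.10,
                       coverage = 0.5,
                       mean_read_length = 1792,
                       base_error = 10^(-15 / 10),
                       cpg_error_inflation = 10,
                       prop_causal = 1,
                       effect_sd = 1,
                       seed = NULL) {
  cfg <- list(
    genome_length = as.numeric(genome_length),
    n_sites = as.integer(n_sites),
    n_haplotypes = as.integer(n_haplotypes),
    n_samples = as.integer(n_samples),
    af_alpha = af_alpha, af_beta = af_beta,
    n_founders = as.integer(n_founders),
    founder_switch_rate = founder_switch_rate,
    sample_switch_rate = sample_switch_rate,
    prop_prediction = prop_prediction,
    cpg_proportion = cpg_proportion,
    coverage = coverage,
    mean_read_length = mean_read_length,
    base_error = base_error,
    cpg_error_inflation = cpg_error_inflation,
    prop_causal = prop_causal,
    effect_sd = effect_sd,
    seed = seed
  )
  probs <- c("cpg_proportion", "prop_prediction", "prop_causal", "base_error",
             "founder_switch_rate", "sample_switch_rate")
  for (p in probs) {
    if (cfg[[p]] < 0 || cfg[[p]] > 1) abort(paste0(p, " must lie in [0, 1]"))
  }
  if (cfg$genome_length <= 0 || cfg$n_sites <= 0 || cfg$n_haplotypes <= 0 ||
      cfg$n_samples <= 0 || cfg$mean_read_length <= 0) {
    abort("counts and lengths must be positive")
  }
  if (cfg$coverage < 0) abort("coverage must be non-negative")
  if (cfg$effect_sd < 0) abort("effect_sd must be non-negative")
  if (cfg$cpg_error_inflation < 1) abort("cpg_error_inflation must be >= 1")
  structure(cfg, class = "sim_config")
}

# Run code under a local seed, restoring the caller's RNG state afterwards.
# seed = NULL uses (and advances) the current RNG stream.
with_local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

# Draw allele frequencies from the configured beta spectrum, truncated so that
# min(p, 1-p) >= 1/n_haplotypes (rejection sampling).
draw_allele_frequencies <- function(n, alpha, beta, min_maf) {
  out <- numeric(0)
  while (length(out) < n) {
    p <- stats::rbeta(2L * (n - length(out)) + 16L, alpha, beta)
    p <- p[pmin(p, 1 - p) >= min_maf]
    out <- c(out, p)
  }
  out[seq_len(n)]
}

# Copy n_out haplotypes as recombinant mosaics of the rows of `pool`.
# Switches occur between consecutive sites with probability
# 1 - exp(-rate * distance); the source after a switch is uniform over the
# pool (so a fraction 1/nrow(pool) of switches is invisible).
mosaic_haplotypes <- function(pool, n_out, pos, rate) {
  n_pool <- nrow(pool)
  L <- length(pos)
  p_gap <- if (L > 1) 1 - exp(-rate * diff(pos)) else numeric(0)
  alleles <- matrix(0L, n_out, L)
  source <- matrix(0L, n_out, L)
  for (i in seq_len(n_out)) {
    src <- integer(L)
    cur <- sample.int(n_pool, 1L)
    src[1L] <- cur
    if (L > 1) {
      switches <- which(runif(L - 1L) < p_gap)
      if (length(switches) == 0L) {
        src[] <- cur
      } else {
        bounds <- c(1L, switches + 1L, L + 1L)
        picks <- c(cur, sample.int(n_pool, length(switches), replace = TRUE))
        src <- rep(picks, diff(bounds))
      }
    }
    source[i, ] <- src
    alleles[i, ] <- pool[cbind(src, seq_len(L))]
  }
  list(alleles = alleles, source = source)
}

#' Simulate a phased haplotype reference panel
#'
#' Draws per-site allele frequencies from the configured (truncated beta)
#' spectrum, builds a founder set with those frequencies, and copies the panel
#' haplotypes as recombinant founder mosaics so that linkage disequilibrium
#' decays with distance. Site positions are uniform over the chromosome;
#' a `prop_prediction` fraction of sites is flagged as the prediction SNP set
#' and a `cpg_proportion` fraction as CpG sites, alternating between the
#' forward-strand C (ref allele C) and the reverse-strand C (ref allele G).
#'
#' @param config a [sim_config()].
#' @param seed optional integer seed; a fixed seed gives a bit-identical panel.
#'
#' @return a `haplotype_panel`: a list with elements `sites` (a [site_map()]),
#'   `alleles` (an `n_haplotypes` x `n_sites` 0/1 integer matrix) and
#'   `n_haplotypes`.
#' @export
simulate_panel <- function(config = sim_config(), seed = config$seed) {
  if (config$n_sites < 1 || config$n_haplotypes < 2) {
    abort("need n_sites >= 1 and n_haplotypes >= 2")
  }
  if (config$genome_length < config$n_sites) {
    abort("genome_length must be at least n_sites")
  }
  with_local_seed(seed, {
    L <- config$n_sites
    pos <- sort(sample.int(config$genome_length, L))

    n_cpg <- round(config$cpg_proportion * L)
    cpg_idx <- if (n_cpg > 0) sort(sample.int(L, n_cpg)) else integer(0)
    cpg_forward <- cpg_reverse <- rep(FALSE, L)
    if (n_cpg > 0) {
      fwd <- cpg_idx[seq_along(cpg_idx) %% 2L == 1L]
      rev <- setdiff(cpg_idx, fwd)
      cpg_forward[fwd] <- TRUE
      cpg_reverse[rev] <- TRUE
    }

    ref <- sample(NUCLEOTIDES, L, replace = TRUE)
    ref[cpg_forward] <- "C"
    ref[cpg_reverse] <- "G"
    alt <- vapply(ref, function(r) sample(setdiff(NUCLEOTIDES, r), 1L), "")

    n_pred <- round(config$prop_prediction * L)
    pred <- rep(FALSE, L)
    if (n_pred > 0) pred[sort(sample.int(L, n_pred))] <- TRUE

    sites <- site_map(chrom = "chr1", pos = pos, ref = ref, alt = alt,
                      is_prediction_site = pred,
                      cpg_forward = cpg_forward, cpg_reverse = cpg_reverse)

    # truncate the spectrum at the panel's resolution; capped so tiny panels
    # keep a positive acceptance region
    p <- draw_allele_frequencies(L, config$af_alpha, config$af_beta,
                                 min(1 / config$n_haplotypes, 0.25))
    founders <- matrix(
      as.integer(runif(config$n_founders * L) < rep(p, each = config$n_founders)),
      nrow = config$n_founders, ncol = L
    )
    mos <- mosaic_haplotypes(founders, config$n_haplotypes, pos,
                             config$founder_switch_rate)
    haplotype_panel(sites, mos$alleles)
  })
}

#' Construct a haplotype panel object
#'
#' @param sites a [site_map()].
#' @param alleles 0/1 integer matrix, one row per haplotype, one column per
#'   site.
#' @return a list of class `haplotype_panel`.
#' @export
haplotype_panel <- function(sites, alleles) {
  sites <- validate_site_map(sites)
  alleles <- as.matrix(alleles)
  storage.mode(alleles) <- "integer"
  if (ncol(alleles) != nrow(sites)) {
    abort("allele matrix must have one column per site")
  }
  if (nrow(alleles) > 0 && !all(alleles %in% c(0L, 1L))) {
    abort("panel alleles must be 0 or 1")
  }
  structure(list(sites = sites, alleles = alleles,
                 n_haplotypes = nrow(alleles)),
            class = "haplotype_panel")
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat(sprintf("<haplotype_panel> %d haplotypes x %d sites (%d prediction sites)\n",
              x$n_haplotypes, nrow(x$sites), sum(x$sites$is_prediction_site)))
  invisible(x)
}

#' Simulate phased diploid samples from a panel
#'
#' Each sample receives two haplotypes copied as recombinant mosaics of the
#' panel rows, with switch distances geometric at `switch_rate` per bp. The
#' phased truth (and the copied panel row at every site, for test oracles) is
#' retained; diploid genotypes are the per-site sum of the two haplotypes.
#'
#' @param panel a `haplotype_panel`.
#' @param n_samples number of diploid samples.
#' @param switch_rate per-bp mosaic switch probability.
#' @param seed optional integer seed.
#'
#' @return a list of class `true_genotypes` with elements `sites`, `hap1`,
#'   `hap2` (n x L 0/1 matrices), `source1`, `source2` (copied panel row
#'   indices) and `sample_id`.
#' @export
simulate_samples <- function(panel, n_samples, switch_rate = 1e-6, seed = NULL) {
  stopifnot(inherits(panel, "haplotype_panel"))
  if (panel$n_haplotypes < 1 || nrow(panel$sites) < 1) abort("panel is empty")
  if (n_samples <= 0) abort("n_samples must be positive")
  with_local_seed(seed, {
    h1 <- mosaic_haplotypes(panel$alleles, n_samples, panel$sites$pos, switch_rate)
    h2 <- mosaic_haplotypes(panel$alleles, n_samples, panel$sites$pos, switch_rate)
    structure(list(
      sites = panel$sites,
      hap1 = h1$alleles, hap2 = h2$alleles,
      source1 = h1$source, source2 = h2$source,
      sample_id = sprintf("S%03d", seq_len(n_samples))
    ), class = "true_genotypes")
  })
}

#' @export
print.true_genotypes <- function(x, ...) {
  cat(sprintf("<true_genotypes> %d samples x %d sites (phased)\n",
              nrow(x$hap1), ncol(x$hap1)))
  invisible(x)
}

#' Diploid genotype matrix of simulated truth
#'
#' @param truth a `true_genotypes` object.
#' @return integer matrix (samples x sites) of genotypes in \{0, 1, 2\}.
#' @export
true_genotype_matrix <- function(truth) {
  g <- truth$hap1 + truth$hap2
  rownames(g) <- truth$sample_id
  g
}

#' Simulate long-read observations at the mapped sites
#'
#' Reads are placed uniformly on the chromosome and drawn until the total
#' simulated bases first reach `coverage * genome_length` per sample, so
#' realized coverage is within one read length of the target and per-site
#' depth is approximately Poisson(coverage). Read lengths are geometric-like
#' with the configured mean; each read originates from one of the sample's two
#' haplotypes with probability 1/2 (the origin is recorded for test oracles)
#' and a uniform random strand. At every covered site the observed base equals
#' the originating haplotype's allele with probability `1 - e'` and one of the
#' other three nucleotides (uniformly) otherwise, where `e'` is the configured
#' base error `e` — except at a `cpg_forward` site read on the forward strand
#' (and symmetrically `cpg_reverse` on the reverse strand), where
#' `e' = e * cpg_error_inflation`. The phred-derived error recorded with each
#' observation encodes `e`, not `e'`: the methylation artefact is invisible to
#' base qualities, as in real data.
#'
#' @param truth a `true_genotypes` object.
#' @param sites the site map (defaults to the truth's own map).
#' @param config a [sim_config()].
#' @param coverage target coverage (defaults to `config$coverage`).
#' @param seed optional integer seed.
#'
#' @return a list of class `read_set` with tibbles `reads` (sample_id,
#'   read_id, strand, start, length, hap_origin) and `obs` (sample_id,
#'   read_id, site, pos, base, e, strand), plus the genome length.
#' @export
simulate_reads <- function(truth, sites = truth$sites, config = sim_config(),
                           coverage = config$coverage, seed = NULL) {
  stopifnot(inherits(truth, "true_genotypes"))
  sites <- validate_site_map(sites)
  if (nrow(sites) == 0) abort("site map is empty")
  if (coverage < 0) abort("coverage must be non-negative")
  G <- config$genome_length
  n_samples <- nrow(truth$hap1)
  with_local_seed(seed, {
    reads_l <- vector("list", n_samples)
    obs_l <- vector("list", n_samples)
    for (s in seq_len(n_samples)) {
      reads <- draw_reads_one_sample(coverage, G, config$mean_read_length)
      if (nrow(reads) == 0) {
        reads_l[[s]] <- reads
        next
      }
      reads$sample_id <- truth$sample_id[s]
      reads$read_id <- sprintf("%s_r%05d", truth$sample_id[s], seq_len(nrow(reads)))
      reads$hap_origin <- sample(c(1L, 2L), nrow(reads), replace = TRUE)
      reads$strand <- sample(c("+", "-"), nrow(reads), replace = TRUE)
      reads_l[[s]] <- reads
      obs_l[[s]] <- observe_sites(reads, truth, s, sites, config)
    }
    reads <- dplyr::bind_rows(reads_l)
    obs <- dplyr::bind_rows(obs_l)
    if (nrow(reads) > 0) {
      reads <- dplyr::select(reads, "sample_id", "read_id", "strand",
                             "start", "length", "hap_origin")
    } else {
      reads <- tibble::tibble(sample_id = character(), read_id = character(),
                              strand = character(), start = integer(),
                              length = integer(), hap_origin = integer())
    }
    if (nrow(obs) == 0) {
      obs <- empty_obs()
    }
    structure(list(reads = reads, obs = obs, genome_length = G),
              class = "read_set")
  })
}

empty_obs <- function() {
  tibble::tibble(sample_id = character(), read_id = character(),
                 site = integer(), pos = integer(), base = character(),
                 e = numeric(), strand = character())
}

# Draw uniformly placed reads until total bases first reach coverage * G.
draw_reads_one_sample <- function(coverage, G, mean_len) {
  target <- coverage * G
  if (target <= 0) {
    return(tibble::tibble(start = integer(), length = integer()))
  }
  starts <- integer(0)
  lens <- integer(0)
  total <- 0
  while (total < target) {
    n_new <- max(16L, ceiling(1.2 * (target - total) / mean_len))
    st <- sample.int(G, n_new, replace = TRUE)
    ln <- rgeom(n_new, 1 / mean_len) + 1L
    ln <- pmin(ln, G - st + 1L)  # truncate at the chromosome end
    starts <- c(starts, st)
    lens <- c(lens, ln)
    total <- sum(as.numeric(lens))
  }
  keep <- which(cumsum(as.numeric(lens)) >= target)[1]
  tibble::tibble(start = starts[seq_len(keep)], length = lens[seq_len(keep)])
}

# Build the per-site observation table for one sample's reads.
observe_sites <- function(reads, truth, sample_idx, sites, config) {
  pos <- sites$pos
  lo <- findInterval(reads$start - 1L, pos) + 1L
  hi <- findInterval(reads$start + reads$length - 1L, pos)
  n_cov <- pmax(hi - lo + 1L, 0L)
  covered <- n_cov > 0L
  if (!any(covered)) return(empty_obs())
  ridx <- rep(which(covered), n_cov[covered])
  site_idx <- sequence(n_cov[covered]) + rep(lo[covered] - 1L, n_cov[covered])

  origin <- reads$hap_origin[ridx]
  allele <- ifelse(origin == 1L,
                   truth$hap1[sample_idx, site_idx],
                   truth$hap2[sample_idx, site_idx])
  true_base <- ifelse(allele == 1L, sites$alt[site_idx], sites$ref[site_idx])
  strand <- reads$strand[ridx]

  inflate <- (sites$cpg_forward[site_idx] & strand == "+") |
    (sites$cpg_reverse[site_idx] & strand == "-")
  e_eff <- ifelse(inflate, pmin(config$base_error * config$cpg_error_inflation,
                                0.75),
                  config$base_error)
  err <- runif(length(site_idx)) < e_eff
  base <- true_base
  if (any(err)) {
    # substitute uniformly among the three other nucleotides
    offset <- sample.int(3L, sum(err), replace = TRUE)
    cur <- match(true_base[err], NUCLEOTIDES)
    base[err] <- NUCLEOTIDES[((cur - 1L + offset) %% 4L) + 1L]
  }
  tibble::tibble(
    sample_id = reads$sample_id[ridx],
    read_id = reads$read_id[ridx],
    site = site_idx,
    pos = pos[site_idx],
    base = base,
    e = config$base_error,
    strand = strand
  )
}

#' @export
print.read_set <- function(x, ...) {
  cat(sprintf("<read_set> %d reads, %d site observations, %d sample(s)\n",
              nrow(x$reads), nrow(x$obs),
              length(unique(x$reads$sample_id))))
  invisible(x)
}

#' Simulate SNP effects for the prediction set
#'
#' Effects are nonzero only at prediction sites; each prediction site is
#' causal with probability `prop_causal` and causal effects are drawn
#' `N(0, effect_sd^2)`.
#'
#' @param sites a [site_map()].
#' @param prop_causal fraction of prediction sites with nonzero effect.
#' @param effect_sd standard deviation of nonzero effects.
#' @param seed optional integer seed.
#'
#' @return an `effect_vector` tibble with one row per prediction site:
#'   columns `site` (index into the site map), `pos` and `effect`.
#' @export
simulate_effects <- function(sites, prop_causal = 1, effect_sd = 1, seed = NULL) {
  sites <- validate_site_map(sites)
  if (prop_causal < 0 || prop_causal > 1) abort("prop_causal must lie in [0, 1]")
  if (effect_sd < 0) abort("effect_sd must be non-negative")
  idx <- which(sites$is_prediction_site)
  with_local_seed(seed, {
    causal <- runif(length(idx)) < prop_causal
    effect <- numeric(length(idx))
    effect[causal] <- rnorm(sum(causal), 0, effect_sd)
    out <- tibble::tibble(site = idx, pos = sites$pos[idx], effect = effect)
    class(out) <- unique(c("effect_vector", class(out)))
    out
  })
}
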