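#' Imputation engine parameters
#'
#' Both engines use the Li-Stephens haplotype-copying model: between adjacent
#' panel sites a gamete switches reference haplotype with probability
#' `1 - exp(-recomb_rate_per_bp * distance * switch_scale)`, landing uniformly
#' on one of the `H` panel haplotypes (so the self-transition mass is
#' `1 - p + p/H` and every other haplotype receives `p/H`). Emissions allow an
#' `emission_mismatch` probability of copying the opposite allele, which
#' absorbs panel-copying errors independently of the base-level error already
#' captured in genotype likelihoods or read evidence.
#'
#' @param recomb_rate_per_bp per-bp switch intensity; the default matches the
#'   per-bp mosaic switch rate of the default sample simulation.
#' @param switch_scale dimensionless multiplier on the switch intensity.
#' @param emission_mismatch haplotype-copying mismatch probability in
#'   (0, 0.5).
#' @param gibbs_iterations,burn_in Gibbs sweeps for the read-aware engine and
#'   how many initial sweeps are discarded.
#' @param seed optional default seed for the read-aware engine.
#' @return a list of class `imputation_params`.
#' @export
imputation_params <- function(recomb_rate_per_bp = 1e-6,
                              switch_scale = 1,
                              emission_mismatch = 0.001,
                              gibbs_iterations = 60L,
                              burn_in = 20L,
                              seed = NULL) {
  if (emission_mismatch <= 0 || emission_mismatch >= 0.5) {
    abort("emission_mismatch must lie in (0, 0.5)")
  }
  if (burn_in >= gibbs_iterations) {
    abort("burn_in must be smaller than gibbs_iterations")
  }
  if (recomb_rate_per_bp < 0 || switch_scale < 0) {
    abort("switch intensities must be non-negative")
  }
  structure(list(recomb_rate_per_bp = recomb_rate_per_bp,
                 switch_scale = switch_scale,
                 emission_mismatch = emission_mismatch,
                 gibbs_iterations = as.integer(gibbs_iterations),
                 burn_in = as.integer(burn_in),
                 seed = seed),
            class = "imputation_params")
}

#' Li-Stephens switch probability
#'
#' `p_switch = 1 - exp(-recomb_rate_per_bp * distance * switch_scale)`. After
#' a switch the copied haplotype is uniform over the panel, so for panel size
#' `H` each haplotype's transition row puts `1 - p + p/H` on itself and `p/H`
#' on every other haplotype.
#'
#' @param distance_bp non-negative distance(s) in bp.
#' @param params an [imputation_params()].
#' @return switch probabilities in `[0, 1)`.
#' @export
ls_transition <- function(distance_bp, params = imputation_params()) {
  if (any(distance_bp < 0)) abort("distances must be non-negative")
  1 - exp(-params$recomb_rate_per_bp * params$switch_scale * distance_bp)
}

panel_pswitch <- function(panel, params) {
  ls_transition(diff(panel$sites$pos), params)
}

new_posterior_genotypes <- function(df, sites, engine) {
  attr(df, "sites") <- sites
  attr(df, "engine") <- engine
  class(df) <- unique(c("posterior_genotypes", class(df)))
  df
}

#' @export
print.posterior_genotypes <- function(x, ...) {
  cat(sprintf("<posterior_genotypes> engine=%s, %d sample(s) x %d sites\n",
              attr(x, "engine"), length(unique(x$sample_id)),
              length(unique(x$site))))
  NextMethod()
}

# Align a call set's genotype likelihoods to the panel sites (by position);
# panel sites without a call carry the uninformative triple.
gl_matrix_for_panel <- function(calls, panel) {
  call_sites <- attr(calls, "sites")
  if (is.null(call_sites)) abort("call set must carry its site map")
  out <- list()
  for (s in unique(calls$sample_id)) {
    sub <- calls[calls$sample_id == s, ]
    idx <- match(panel$sites$pos, call_sites$pos[sub$site])
    m <- matrix(1, nrow(panel$sites), 3)
    ok <- !is.na(idx)
    m[ok, 1] <- sub$gl_rr[idx[ok]]
    m[ok, 2] <- sub$gl_ra[idx[ok]]
    m[ok, 3] <- sub$gl_aa[idx[ok]]
    m[is.na(m)] <- 1
    out[[s]] <- m
  }
  out
}

#' Diploid genotype-likelihood imputation
#'
#' Runs the diploid Li-Stephens forward-backward over ordered haplotype pairs
#' (`H^2` states): per-gamete switch transitions, and emissions equal to the
#' site's genotype likelihood of the allele pair implied by the state, with
#' `emission_mismatch` smoothing per gamete. This is the engine family that
#' consumes genotype likelihoods produced by a prior calling step; it returns
#' posteriors and dosages for every panel site, including sites with no data.
#'
#' @param calls a `call_set` with likelihood columns (e.g. from
#'   [genotype_sample()] with the Q-score method), or a numeric `L x 3`
#'   likelihood matrix for a single sample aligned to the panel sites.
#' @param panel a `haplotype_panel` (at least 2 haplotypes).
#' @param params an [imputation_params()].
#' @return a `posterior_genotypes` tibble: `sample_id`, `site`, `pos`, `p0`,
#'   `p1`, `p2`, `dosage`; per-sample forward log-likelihoods are attached as
#'   attribute `loglik`.
#' @export
impute_diploid_gl <- function(calls, panel, params = imputation_params()) {
  stopifnot(inherits(panel, "haplotype_panel"))
  if (panel$n_haplotypes < 2) abort("panel must contain at least 2 haplotypes")
  if (is.matrix(calls)) {
    gls <- list(S1 = calls)
  } else {
    gls <- gl_matrix_for_panel(calls, panel)
  }
  ps <- panel_pswitch(panel, params)
  L <- nrow(panel$sites)
  res <- purrr::imap(gls, function(gl, sample_id) {
    fit <- cpp_diploid_fb(gl, panel$alleles, ps, params$emission_mismatch)
    tibble::tibble(sample_id = sample_id, site = seq_len(L),
                   pos = panel$sites$pos,
                   p0 = fit$posterior[, 1], p1 = fit$posterior[, 2],
                   p2 = fit$posterior[, 3], dosage = fit$dosage,
                   .loglik = fit$loglik)
  })
  out <- dplyr::bind_rows(res)
  loglik <- vapply(split(out$.loglik, out$sample_id), function(x) x[1], 0)
  out$.loglik <- NULL
  out <- new_posterior_genotypes(out, panel$sites, "diploid_gl")
  attr(out, "loglik") <- loglik
  out
}

# Build CSR read evidence against the panel sites for one sample.
# Returns NULL-free lists; reads with no panel-site observation get an empty
# span (they remain in the labelling with an uninformative conditional).
read_evidence <- function(reads, panel, sample_id, mask = TRUE) {
  pile <- build_pileup(reads, panel$sites)
  if (mask) pile <- methylation_mask(pile)
  pile <- pile[pile$sample_id == sample_id, ]
  ids <- reads$reads$read_id[reads$reads$sample_id == sample_id]
  ord <- order(match(pile$read_id, ids), pile$site)
  pile <- pile[ord, ]
  e <- pile$e
  p1 <- ifelse(pile$base == pile$alt, 1 - e, e / 3)
  p0 <- ifelse(pile$base == pile$ref, 1 - e, e / 3)
  n_per_read <- tabulate(match(pile$read_id, ids), nbins = length(ids))
  list(read_id = ids,
       obs_site = pile$site - 1L,
       obs_p1 = p1, obs_p0 = p0,
       read_ptr = c(0L, cumsum(n_per_read)))
}

#' Gibbs assignment of reads to parental gametes
#'
#' Long reads spanning several panel sites carry phase information: the
#' co-localization of alleles on one read ties those sites to the same
#' parental gamete. Each read carries a gamete label in \{1, 2\}; at every
#' sweep the two current read groups are imputed as haploids under the
#' Li-Stephens model and each read's label is resampled from its conditional
#' probability under the two gamete posteriors. Labels are exchangeable (the
#' gamete identities can swap globally); results are deterministic given the
#' seed.
#'
#' @param reads a `read_set` (one or more samples; labelling is per sample).
#' @param panel a `haplotype_panel`.
#' @param params an [imputation_params()].
#' @param mask apply the CpG strand mask to the read evidence (default TRUE).
#' @param seed optional integer seed.
#' @return a list of class `read_labeling`: `labels` (tibble `sample_id`,
#'   `read_id`, `label`) and `trace` (per sample, a reads x kept-iterations
#'   matrix of post-burn-in labels).
#' @export
label_reads_gibbs <- function(reads, panel, params = imputation_params(),
                              mask = TRUE, seed = params$seed) {
  stopifnot(inherits(reads, "read_set"), inherits(panel, "haplotype_panel"))
  ps <- panel_pswitch(panel, params)
  samples <- unique(reads$reads$sample_id)
  with_local_seed(seed, {
    labs <- list()
    trace <- list()
    for (s in samples) {
      ev <- read_evidence(reads, panel, s, mask = mask)
      fit <- cpp_read_aware(panel$alleles, ps, params$emission_mismatch,
                            ev$obs_site, ev$obs_p1, ev$obs_p0, ev$read_ptr,
                            params$gibbs_iterations, params$burn_in,
                            keep_trace = TRUE)
      labs[[s]] <- tibble::tibble(sample_id = s, read_id = ev$read_id,
                                  label = fit$labels)
      tr <- fit$trace
      rownames(tr) <- ev$read_id
      trace[[s]] <- tr
    }
    structure(list(labels = dplyr::bind_rows(labs), trace = trace),
              class = "read_labeling")
  })
}

#' Read-aware haploid imputation
#'
#' The read-aware engine couples [label_reads_gibbs()] with haploid
#' imputation: at each post-burn-in Gibbs sweep the reads are split by gamete
#' label, each gamete is imputed as a haploid Li-Stephens mosaic with the
#' per-site base evidence of its reads, and the genotype posterior is the
#' convolution of the two gametes' allele posteriors (gametes independent
#' given the labels). Posteriors are averaged over the kept sweeps. With no
#' reads the output reduces to the panel-frequency prior (dosage `2p` up to
#' emission-mismatch smoothing).
#'
#' @inheritParams label_reads_gibbs
#' @return a `posterior_genotypes` tibble (`sample_id`, `site`, `pos`, `p0`,
#'   `p1`, `p2`, `dosage`).
#' @export
impute_read_aware <- function(reads, panel, params = imputation_params(),
                              mask = TRUE, seed = params$seed) {
  stopifnot(inherits(reads, "read_set"), inherits(panel, "haplotype_panel"))
  if (panel$n_haplotypes < 2) abort("panel must contain at least 2 haplotypes")
  ps <- panel_pswitch(panel, params)
  L <- nrow(panel$sites)
  samples <- unique(reads$reads$sample_id)
  if (length(samples) == 0) samples <- "S1"
  with_local_seed(seed, {
    res <- purrr::map(samples, function(s) {
      ev <- read_evidence(reads, panel, s, mask = mask)
      fit <- cpp_read_aware(panel$alleles, ps, params$emission_mismatch,
                            ev$obs_site, ev$obs_p1, ev$obs_p0, ev$read_ptr,
                            params$gibbs_iterations, params$burn_in,
                            keep_trace = FALSE)
      tibble::tibble(sample_id = s, site = seq_len(L), pos = panel$sites$pos,
                     p0 = fit$posterior[, 1], p1 = fit$posterior[, 2],
                     p2 = fit$posterior[, 3], dosage = fit$dosage)
    })
    new_posterior_genotypes(dplyr::bind_rows(res), panel$sites, "read_aware")
  })
}

#' Hard calls and dosages from genotype posteriors
#'
#' The dosage is copied; the hard call is the argmax of the posterior with
#' ties resolved to the heterozygote; provenance is tagged `"imputed"`.
#'
#' @param post a `posterior_genotypes` tibble.
#' @return a `call_set`.
#' @export
posterior_to_calls <- function(post) {
  stopifnot(inherits(post, "posterior_genotypes"))
  gt <- argmax_genotype(post$p0, post$p1, post$p2)
  call_set(post$sample_id, post$site, gt = gt,
           dosage = pmin(pmax(post$dosage, 0), 2),
           source = "imputed", sites = attr(post, "sites"))
}
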