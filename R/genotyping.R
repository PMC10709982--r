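#' Genotype likelihoods from base qualities (Q-score method)
#'
#' For a biallelic site with alleles `A1` (ref) and `A2` (alt), the likelihood
#' of diploid genotype `G = {A1, A2}` given the pileup is the product over the
#' `M` covering reads of `1/2 Pr(b_i | A1) + 1/2 Pr(b_i | A2)`, with
#' `Pr(b | A) = 1 - e` when the observed base matches the allele and `e / 3`
#' otherwise (`e` the phred-derived error probability of the base). Bases that
#' match neither allele contribute `e / 3` under both alleles. An empty column
#' returns the uninformative triple `(1, 1, 1)`.
#'
#' @param column a pileup column: a data frame with columns `base` and `e`
#'   (rows are the read observations covering one site).
#' @param ref,alt the site's alleles (distinct nucleotides).
#' @return a named numeric triple `c(rr, ra, aa)` of linear-scale likelihoods
#'   for genotypes ref/ref, ref/alt and alt/alt.
#' @export
genotype_likelihood_qscore <- function(column, ref, alt) {
  if (ref == alt) abort("ref and alt alleles must differ")
  if (nrow(column) == 0) {
    return(c(rr = 1, ra = 1, aa = 1))
  }
  e <- column$e
  if (any(e <= 0 | e >= 1)) abort("error probabilities must lie in (0, 1)")
  pr_ref <- ifelse(column$base == ref, 1 - e, e / 3)
  pr_alt <- ifelse(column$base == alt, 1 - e, e / 3)
  c(rr = prod(pr_ref),
    ra = prod(0.5 * pr_ref + 0.5 * pr_alt),
    aa = prod(pr_alt))
}

# Vectorized Q-score likelihoods over a whole pileup: one row per
# sample x covered site.
gl_from_pileup <- function(pileup) {
  if (nrow(pileup) == 0) {
    return(tibble::tibble(sample_id = character(), site = integer(),
                          gl_rr = numeric(), gl_ra = numeric(),
                          gl_aa = numeric()))
  }
  e <- pileup$e
  if (any(e <= 0 | e >= 1)) abort("error probabilities must lie in (0, 1)")
  pr_ref <- ifelse(pileup$base == pileup$ref, 1 - e, e / 3)
  pr_alt <- ifelse(pileup$base == pileup$alt, 1 - e, e / 3)
  df <- tibble::tibble(sample_id = pileup$sample_id, site = pileup$site,
                       pr_ref = pr_ref, pr_alt = pr_alt)
  dplyr::summarise(
    dplyr::group_by(df, .data$sample_id, .data$site),
    gl_rr = prod(.data$pr_ref),
    gl_ra = prod(0.5 * .data$pr_ref + 0.5 * .data$pr_alt),
    gl_aa = prod(.data$pr_alt),
    .groups = "drop"
  )
}

#' Mask the methylation-prone strand at CpG sites
#'
#' Methylated cytosines are miscalled at an elevated rate in nanopore data,
#' and base qualities do not flag the artefact. The mask therefore genotypes
#' potential methylation sites from the non-methylated strand only: at a
#' `cpg_forward` site (the C of a forward-strand CpG) only reverse-strand
#' observations are kept; at a `cpg_reverse` site only forward-strand
#' observations. Non-CpG columns pass through unchanged; a fully masked column
#' proceeds downstream with depth 0.
#'
#' @param pileup a `pileup` (or any data frame with `strand`, `cpg_forward`,
#'   `cpg_reverse` columns).
#' @return the pileup with masked observations removed.
#' @export
methylation_mask <- function(pileup) {
  keep <- !((pileup$cpg_forward & pileup$strand == "+") |
              (pileup$cpg_reverse & pileup$strand == "-"))
  out <- pileup[keep, ]
  attr(out, "sites") <- attr(pileup, "sites")
  class(out) <- class(pileup)
  out
}

#' Coverage-binned minimum-allele-count rule
#'
#' A MAC rule is an ordered set of contiguous depth bins, each with a minimum
#' allele count: an allele is accepted at a site when it is seen in at least
#' `mac` reads for the bin containing the site's depth. A bin may instead
#' specify `mac_frac`, in which case the threshold is
#' `ceiling(mac_frac * depth)`.
#'
#' The default rule uses MAC 1 at depths 1-4, MAC 2 at depths 5-9 and
#' `ceiling(0.15 * depth)` at depths 10 and above.
#'
#' @param depth_lo,depth_hi inclusive depth bounds of each bin (the last bin
#'   may be unbounded with `Inf`).
#' @param mac fixed minimum allele count per bin (NA when `mac_frac` drives
#'   the bin).
#' @param mac_frac fractional threshold per bin (NA when `mac` drives it).
#' @return a tibble of class `mac_rule`.
#' @export
mac_rule <- function(depth_lo, depth_hi, mac = NA_integer_,
                     mac_frac = NA_real_) {
  out <- tibble::tibble(depth_lo = as.numeric(depth_lo),
                        depth_hi = as.numeric(depth_hi),
                        mac = as.integer(mac),
                        mac_frac = as.numeric(mac_frac))
  out <- dplyr::arrange(out, .data$depth_lo)
  if (out$depth_lo[1] != 1) abort("MAC bins must start at depth 1")
  if (nrow(out) > 1 &&
      any(out$depth_lo[-1] != out$depth_hi[-nrow(out)] + 1)) {
    abort("MAC bins must be contiguous and non-overlapping")
  }
  if (any(is.na(out$mac) & is.na(out$mac_frac))) {
    abort("each bin needs mac or mac_frac")
  }
  if (any(!is.na(out$mac) & out$mac < 1)) abort("mac must be >= 1")
  class(out) <- unique(c("mac_rule", class(out)))
  out
}

#' @rdname mac_rule
#' @export
default_mac_rule <- function() {
  mac_rule(depth_lo = c(1, 5, 10), depth_hi = c(4, 9, Inf),
           mac = c(1L, 2L, NA), mac_frac = c(NA, NA, 0.15))
}

# Effective minimum allele count for each depth (vectorized).
mac_for_depth <- function(rule, depth) {
  bin <- findInterval(depth, rule$depth_lo)
  if (any(depth >= 1 & (bin == 0 | depth > rule$depth_hi[pmax(bin, 1L)]))) {
    abort("depth outside all MAC bins")
  }
  bin[bin == 0] <- NA
  out <- rule$mac[bin]
  frac <- is.na(out)
  out[frac] <- ceiling(rule$mac_frac[bin[frac]] * depth[frac])
  out
}

#' Hard genotype call by minimum allele count
#'
#' Counts the reads supporting the ref and alt alleles (bases matching
#' neither allele are ignored in the counts, but do contribute to the depth
#' used to pick the bin). An allele passes when its count reaches the bin's
#' minimum allele count; both passing gives a heterozygote, exactly one the
#' corresponding homozygote, neither (or depth 0) a missing call.
#'
#' @param column a pileup column (data frame with `base`, `ref`, `alt`).
#' @param rule a [mac_rule()].
#' @return integer genotype 0/1/2 or NA.
#' @export
call_mac <- function(column, rule = default_mac_rule()) {
  depth <- nrow(column)
  if (depth == 0) return(NA_integer_)
  mac <- mac_for_depth(rule, depth)
  ref_n <- sum(column$base == column$ref)
  alt_n <- sum(column$base == column$alt)
  mac_decision(ref_n, alt_n, mac)
}

mac_decision <- function(ref_n, alt_n, mac) {
  ref_pass <- ref_n >= mac
  alt_pass <- alt_n >= mac
  out <- rep(NA_integer_, length(ref_pass))
  out[ref_pass & alt_pass] <- 1L
  out[ref_pass & !alt_pass] <- 0L
  out[!ref_pass & alt_pass] <- 2L
  out
}

# Q-score hard call: argmax of the triple, ties resolved to the heterozygote.
argmax_genotype <- function(gl_rr, gl_ra, gl_aa) {
  best <- pmax(gl_rr, gl_ra, gl_aa)
  out <- rep(NA_integer_, length(best))
  out[gl_aa == best] <- 2L
  out[gl_rr == best] <- 0L
  out[gl_ra == best] <- 1L  # het wins ties
  out
}

#' Genotype a sample set from reads
#'
#' Runs one of the two callers over every sample and mapped site. The Q-score
#' path applies the [methylation_mask()] before computing likelihoods and
#' returns the likelihood triples (uninformative `(1,1,1)` at uncovered
#' sites) plus, when `hard_calls = TRUE`, argmax genotypes (ties to the
#' heterozygote). The MAC path returns hard calls only. The provenance tag
#' records the method.
#'
#' @param reads a `read_set`.
#' @param sites the [site_map()] to genotype over.
#' @param method `"qscore"` or `"mac"`.
#' @param rule MAC rule for the MAC path.
#' @param mask apply the CpG strand mask on the Q-score path (default TRUE).
#' @param hard_calls also emit argmax hard calls on the Q-score path.
#' @return a `call_set` covering every sample x site.
#' @export
genotype_sample <- function(reads, sites, method = c("qscore", "mac"),
                            rule = default_mac_rule(), mask = TRUE,
                            hard_calls = FALSE) {
  method <- match.arg(method)
  sites <- validate_site_map(sites)
  pile <- build_pileup(reads, sites)
  samples <- unique(reads$reads$sample_id)
  if (length(samples) == 0) samples <- unique(pile$sample_id)
  grid <- tidyr::expand_grid(sample_id = samples, site = seq_len(nrow(sites)))

  if (method == "qscore") {
    if (mask) pile <- methylation_mask(pile)
    gls <- gl_from_pileup(pile)
    full <- dplyr::left_join(grid, gls, by = c("sample_id", "site"))
    full <- dplyr::mutate(
      full,
      gl_rr = dplyr::coalesce(.data$gl_rr, 1),
      gl_ra = dplyr::coalesce(.data$gl_ra, 1),
      gl_aa = dplyr::coalesce(.data$gl_aa, 1)
    )
    gt <- if (hard_calls) {
      argmax_genotype(full$gl_rr, full$gl_ra, full$gl_aa)
    } else NA_integer_
    call_set(full$sample_id, full$site, gt = gt,
             gl_rr = full$gl_rr, gl_ra = full$gl_ra, gl_aa = full$gl_aa,
             source = "qscore", sites = sites)
  } else {
    counts <- dplyr::summarise(
      dplyr::group_by(tibble::as_tibble(pile), .data$sample_id, .data$site),
      depth = dplyr::n(),
      ref_n = sum(.data$base == .data$ref),
      alt_n = sum(.data$base == .data$alt),
      .groups = "drop"
    )
    full <- dplyr::left_join(grid, counts, by = c("sample_id", "site"))
    full$depth[is.na(full$depth)] <- 0L
    gt <- rep(NA_integer_, nrow(full))
    covered <- full$depth > 0L
    if (any(covered)) {
      mac <- mac_for_depth(rule, full$depth[covered])
      gt[covered] <- mac_decision(full$ref_n[covered], full$alt_n[covered], mac)
    }
    call_set(full$sample_id, full$site, gt = gt, source = "mac", sites = sites)
  }
}
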