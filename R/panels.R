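#' Per-site minor allele frequency of a panel
#'
#' `MAF = min(p, 1 - p)` with `p` the alternate-allele count over the panel's
#' haplotypes.
#'
#' @param panel a `haplotype_panel`.
#' @return numeric vector in `[0, 0.5]`, one value per site.
#' @export
compute_maf <- function(panel) {
  stopifnot(inherits(panel, "haplotype_panel"))
  if (panel$n_haplotypes < 1 || nrow(panel$sites) < 1) abort("panel is empty")
  p <- colMeans(panel$alleles)
  pmin(p, 1 - p)
}

#' Alternate-allele frequency of a panel
#'
#' @param panel a `haplotype_panel`.
#' @return numeric vector in `[0, 1]`, one value per site.
#' @export
alt_frequency <- function(panel) {
  stopifnot(inherits(panel, "haplotype_panel"))
  colMeans(panel$alleles)
}

#' Specify a MAF-filtered reference panel
#'
#' A panel spec either applies a strict MAF cutoff (`MAF > cutoff`, always
#' retaining the prediction SNP set) or restricts the panel to the prediction
#' SNP set only (the HD-array analogue). Exactly one of the two drives the
#' filtering.
#'
#' @param name label for the panel (used in reports).
#' @param maf_cutoff strict lower MAF bound in `[0, 0.5)`, or `NULL` for no
#'   MAF filter.
#' @param prediction_only keep only prediction SNP (ignores `maf_cutoff`).
#' @return a list of class `panel_spec`.
#' @export
panel_spec <- function(name, maf_cutoff = NULL, prediction_only = FALSE) {
  if (prediction_only && !is.null(maf_cutoff)) {
    abort("use either maf_cutoff or prediction_only, not both")
  }
  if (!is.null(maf_cutoff) && (maf_cutoff < 0 || maf_cutoff >= 0.5)) {
    abort("maf_cutoff must lie in [0, 0.5)")
  }
  structure(list(name = name, maf_cutoff = maf_cutoff,
                 prediction_only = prediction_only),
            class = "panel_spec")
}

#' The five standard panel specifications
#'
#' The unfiltered panel, three MAF-filtered panels (`MAF > 0.1/0.2/0.3`,
#' prediction SNP always retained) and the prediction-sites-only panel.
#'
#' @return named list of [panel_spec()] objects.
#' @export
default_panel_specs <- function() {
  list(
    no_filter = panel_spec("no_filter"),
    maf_0.1 = panel_spec("maf_0.1", maf_cutoff = 0.1),
    maf_0.2 = panel_spec("maf_0.2", maf_cutoff = 0.2),
    maf_0.3 = panel_spec("maf_0.3", maf_cutoff = 0.3),
    prediction_only = panel_spec("prediction_only", prediction_only = TRUE)
  )
}

#' Filter a reference panel by minor allele frequency
#'
#' Retains the sites with `MAF > cutoff` together with every prediction site
#' (the prediction set is always a subset of the filtered panel, so the SNP
#' used for breeding values can never be filtered away). With
#' `prediction_only`, only prediction sites are kept. Site order and
#' haplotype rows are unchanged.
#'
#' @param panel a `haplotype_panel`.
#' @param spec a [panel_spec()].
#' @return the filtered `haplotype_panel`; the retained original site indices
#'   are attached as attribute `kept_sites`.
#' @export
filter_panel <- function(panel, spec) {
  stopifnot(inherits(panel, "haplotype_panel"), inherits(spec, "panel_spec"))
  keep <- if (spec$prediction_only) {
    panel$sites$is_prediction_site
  } else if (is.null(spec$maf_cutoff)) {
    rep(TRUE, nrow(panel$sites))
  } else {
    compute_maf(panel) > spec$maf_cutoff | panel$sites$is_prediction_site
  }
  idx <- which(keep)
  out <- haplotype_panel(panel$sites[idx, ], panel$alleles[, idx, drop = FALSE])
  attr(out, "kept_sites") <- idx
  out
}
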