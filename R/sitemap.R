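#' Construct and validate a site map
#'
#' A site map is the ordered set of biallelic SNP the pipeline works over. It
#' is a plain tibble with one row per site and columns:
#'
#' * `chrom` — chromosome identifier (a single chromosome per map),
#' * `pos` — 1-based base-pair coordinate, strictly increasing,
#' * `ref`, `alt` — reference and alternate nucleotide (`A/C/G/T`, distinct),
#' * `is_prediction_site` — logical; membership in the SNP set used for
#'   breeding-value prediction (the analogue of a HD-array SNP set),
#' * `cpg_forward` — logical; the site is the C of a CpG dinucleotide on the
#'   forward reference strand (methylation can corrupt forward-strand reads),
#' * `cpg_reverse` — logical; the site is the G of a forward-strand CpG, i.e.
#'   the C on the reverse strand.
#'
#' @param chrom character vector (recycled) of chromosome ids.
#' @param pos integer vector of 1-based positions, strictly increasing.
#' @param ref,alt nucleotide vectors, `ref[i] != alt[i]`.
#' @param is_prediction_site,cpg_forward,cpg_reverse logical vectors
#'   (recycled; default all `FALSE`).
#'
#' @return a tibble of class `site_map`.
#' @export
site_map <- function(chrom, pos, ref, alt,
                     is_prediction_site = FALSE,
                     cpg_forward = FALSE,
                     cpg_reverse = FALSE) {
  sites <- tibble::tibble(
    chrom = as.character(chrom),
    pos = as.integer(pos),
    ref = as.character(ref),
    alt = as.character(alt),
    is_prediction_site = rep_len(as.logical(is_prediction_site), length(pos)),
    cpg_forward = rep_len(as.logical(cpg_forward), length(pos)),
    cpg_reverse = rep_len(as.logical(cpg_reverse), length(pos))
  )
  validate_site_map(sites)
}

#' @rdname site_map
#' @param sites a data frame with the site-map columns.
#' @export
validate_site_map <- function(sites) {
  sites <- tibble::as_tibble(sites)
  needed <- c("chrom", "pos", "ref", "alt", "is_prediction_site",
              "cpg_forward", "cpg_reverse")
  missing <- setdiff(needed, names(sites))
  if (length(missing) > 0) {
    abort(paste0("site map is missing columns: ", paste(missing, collapse = ", ")))
  }
  if (length(unique(sites$chrom)) > 1) {
    abort("site map must contain a single chromosome")
  }
  if (nrow(sites) > 0 && any(diff(sites$pos) <= 0)) {
    abort("site positions must be strictly increasing")
  }
  if (any(!sites$ref %in% NUCLEOTIDES) || any(!sites$alt %in% NUCLEOTIDES)) {
    abort("ref/alt alleles must be A, C, G or T")
  }
  if (any(sites$ref == sites$alt)) {
    abort("ref and alt alleles must differ at every site")
  }
  if (any(sites$cpg_forward & sites$cpg_reverse)) {
    abort("a site cannot be both cpg_forward and cpg_reverse")
  }
  class(sites) <- unique(c("site_map", class(sites)))
  sites
}
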