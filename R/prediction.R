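#' SNP-BLUP genomic estimated breeding values
#'
#' Computes `a_hat = M g_hat`: the matrix product of an `n x m` genotype
#' dosage matrix (samples by prediction sites, entries in `[0, 2]`) with the
#' vector of `m` predicted SNP effects. No centering or scaling is applied.
#' Missing dosages are filled per `missing`: the column mean over non-missing
#' samples (default; an all-missing column falls back to 1, the heterozygote
#' dosage), zero, or an error.
#'
#' @param dosages numeric matrix samples x prediction sites, or a `call_set`
#'   (its dosage matrix at the prediction sites of its site map is used, hard
#'   genotypes standing in where the dosage is absent).
#' @param effects an `effect_vector` tibble (column `effect`) or a numeric
#'   vector of length `ncol(dosages)`.
#' @param missing `"mean"`, `"zero"` or `"error"`.
#' @return a tibble (`sample_id`, `gebv`).
#' @export
gebv <- function(dosages, effects, missing = c("mean", "zero", "error")) {
  missing <- match.arg(missing)
  if (inherits(dosages, "call_set")) {
    sites <- attr(dosages, "sites")
    if (is.null(sites)) abort("call set must carry its site map")
    pred <- which(sites$is_prediction_site)
    dosages <- call_matrix(dosages, sites = pred, value = "dosage")
  }
  dosages <- as.matrix(dosages)
  g <- if (is.data.frame(effects)) effects$effect else as.numeric(effects)
  if (ncol(dosages) != length(g)) {
    abort(sprintf("dosage matrix has %d columns but %d effects supplied",
                  ncol(dosages), length(g)))
  }
  if (anyNA(dosages)) {
    if (missing == "error") abort("missing dosages present")
    if (missing == "zero") {
      dosages[is.na(dosages)] <- 0
    } else {
      mu <- colMeans(dosages, na.rm = TRUE)
      mu[is.nan(mu)] <- 1
      na_idx <- which(is.na(dosages), arr.ind = TRUE)
      dosages[na_idx] <- mu[na_idx[, 2]]
    }
  }
  ids <- rownames(dosages) %||% sprintf("S%03d", seq_len(nrow(dosages)))
  tibble::tibble(sample_id = ids, gebv = as.numeric(dosages %*% g))
}
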