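#' Pearson correlation with Fisher-z confidence interval
#'
#' @param x,y numeric vectors of equal length `n >= 4` with nonzero variance.
#' @param level confidence level (default 0.95).
#' @return a one-row tibble (`r`, `lo`, `hi`, `n`).
#' @export
pearson_ci <- function(x, y, level = 0.95) {
  n <- length(x)
  if (n < 4 || length(y) != n) abort("need equal-length vectors with n >= 4")
  if (sd(x) == 0 || sd(y) == 0) abort("constant input: correlation undefined")
  r <- cor(x, y)
  z <- atanh(r)
  se <- 1 / sqrt(n - 3)
  q <- qnorm(1 - (1 - level) / 2)
  tibble::tibble(r = r, lo = tanh(z - q * se), hi = tanh(z + q * se), n = n)
}

#' Genomic prediction bias
#'
#' The ordinary least-squares regression coefficient of the reference GEBVs
#' on the test GEBVs, minus 1. Zero indicates an unbiased scale; the
#' intercept absorbs any constant shift.
#'
#' @param reference_gebv,test_gebv numeric vectors, `n >= 3`.
#' @return the slope minus 1 (numeric scalar).
#' @export
prediction_bias <- function(reference_gebv, test_gebv) {
  n <- length(reference_gebv)
  if (n < 3 || length(test_gebv) != n) abort("need equal-length vectors with n >= 3")
  if (var(test_gebv) == 0) abort("zero variance in test GEBVs")
  fit <- stats::lm(reference_gebv ~ test_gebv)
  unname(stats::coef(fit)[2]) - 1
}

gt_matrix_of <- function(x, sites) {
  if (inherits(x, "call_set")) call_matrix(x, sites = sites, value = "gt")
  else as.matrix(x)
}

#' Imputation accuracy against truth
#'
#' The fraction of matching hard genotypes over every evaluated sample x site
#' cell; the denominator is the full evaluated-site count, so a genotype
#' missing in either set counts as a non-match.
#'
#' @param calls,truth `call_set`s (or genotype matrices with samples in
#'   matching row order).
#' @param sites site indices to evaluate (default: the prediction sites of
#'   the calls' site map, if available, else all shared sites).
#' @param by_sample return a per-sample tibble instead of the pooled
#'   fraction.
#' @return a fraction in `[0, 1]`, or a tibble (`sample_id`, `accuracy`).
#' @export
imputation_accuracy <- function(calls, truth, sites = NULL, by_sample = FALSE) {
  if (is.null(sites) && inherits(calls, "call_set")) {
    sm <- attr(calls, "sites")
    if (!is.null(sm)) sites <- which(sm$is_prediction_site)
    if (length(sites) == 0) sites <- NULL
  }
  a <- gt_matrix_of(calls, sites)
  b <- gt_matrix_of(truth, sites)
  if (length(a) == 0) abort("no sites to evaluate")
  common <- intersect(colnames(a) %||% character(), colnames(b) %||% character())
  if (length(common) > 0) {
    a <- a[, common, drop = FALSE]
    b <- b[, common, drop = FALSE]
  }
  if (!identical(dim(a), dim(b))) abort("call sets do not share the site set")
  if (!is.null(rownames(a)) && !is.null(rownames(b))) {
    b <- b[rownames(a), , drop = FALSE]
  }
  match_m <- !is.na(a) & !is.na(b) & a == b
  if (by_sample) {
    tibble::tibble(sample_id = rownames(a) %||% as.character(seq_len(nrow(a))),
                   accuracy = rowMeans(match_m))
  } else {
    mean(match_m)
  }
}

#' Genotype concordance between two runs of the same samples
#'
#' The fraction of sites with identical hard genotypes among sites
#' non-missing in both runs (the usual stats-tool convention); the count of
#' both-nonmissing sites is reported alongside.
#'
#' @param calls_run1,calls_run2 `call_set`s for the same samples (or genotype
#'   matrices/vectors).
#' @param sites site indices to compare (default: all).
#' @return a tibble (`sample_id`, `concordance`, `n_compared`), one row per
#'   sample.
#' @export
concordance <- function(calls_run1, calls_run2, sites = NULL) {
  vec_in <- !inherits(calls_run1, "call_set") && is.null(dim(calls_run1))
  a <- if (vec_in) matrix(calls_run1, nrow = 1) else gt_matrix_of(calls_run1, sites)
  b <- if (vec_in) matrix(calls_run2, nrow = 1) else gt_matrix_of(calls_run2, sites)
  if (!identical(dim(a), dim(b))) abort("runs do not share the site set")
  if (!is.null(rownames(a)) && !is.null(rownames(b))) {
    b <- b[rownames(a), , drop = FALSE]
  }
  both <- !is.na(a) & !is.na(b)
  if (!any(both)) abort("no sites non-missing in both runs")
  ids <- rownames(a) %||% as.character(seq_len(nrow(a)))
  tibble::tibble(
    sample_id = ids,
    concordance = unname(rowSums(both & a == b) / rowSums(both)),
    n_compared = unname(rowSums(both))
  )
}

# Quartile labels (1-4) by rank; ties broken by original order; when n is not
# a multiple of 4 the earlier quartiles take the extra samples.
quartile_bins <- function(x) {
  n <- length(x)
  sizes <- rep(n %/% 4L, 4L)
  extra <- n %% 4L
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  bins <- rep(1:4, sizes)
  bins[rank(x, ties.method = "first")]
}

#' Quartile re-ranking between two GEBV vectors
#'
#' Samples are binned into quartiles by each vector (rank-based, ties by
#' sample order) and moves are counted: entry (i, j) is the number of samples
#' in reference quartile i and test quartile j. Row sums equal the
#' per-quartile sample counts regardless of the test vector.
#'
#' @param reference_gebv,test_gebv numeric vectors, `n >= 4`.
#' @return a 4 x 4 integer count matrix (rows: reference quartile).
#' @export
quartile_transitions <- function(reference_gebv, test_gebv) {
  n <- length(reference_gebv)
  if (n < 4 || length(test_gebv) != n) abort("need equal-length vectors with n >= 4")
  qr <- factor(quartile_bins(reference_gebv), levels = 1:4)
  qt <- factor(quartile_bins(test_gebv), levels = 1:4)
  m <- table(reference = qr, test = qt)
  matrix(as.integer(m), 4, 4, dimnames = list(
    reference = paste0("Q", 1:4), test = paste0("Q", 1:4)))
}

#' Subsample reads to a target coverage
#'
#' Reads are drawn without replacement, per sample, in a seeded random order
#' until the total bases first reach `target_coverage * genome_length`, so
#' the subsampled bases overshoot the target by less than one read length.
#'
#' @param reads a `read_set`.
#' @param target_coverage target mean coverage; must not exceed the source
#'   coverage of any sample.
#' @param genome_length reference length in bp (default: from the read set).
#' @param seed optional integer seed.
#' @return a `read_set` containing the sampled reads and their observations.
#' @export
subsample_reads <- function(reads, target_coverage,
                            genome_length = reads$genome_length, seed = NULL) {
  stopifnot(inherits(reads, "read_set"))
  if (target_coverage < 0) abort("target coverage must be non-negative")
  target <- target_coverage * genome_length
  with_local_seed(seed, {
    keep_ids <- character(0)
    for (s in unique(reads$reads$sample_id)) {
      sub <- reads$reads[reads$reads$sample_id == s, ]
      if (sum(sub$length) < target) {
        abort("target coverage exceeds the available reads")
      }
      if (target == 0) next
      ord <- sample.int(nrow(sub))
      n_keep <- which(cumsum(as.numeric(sub$length[ord])) >= target)[1]
      keep_ids <- c(keep_ids, sub$read_id[ord[seq_len(n_keep)]])
    }
    structure(list(
      reads = reads$reads[reads$reads$read_id %in% keep_ids, ],
      obs = reads$obs[reads$obs$read_id %in% keep_ids, ],
      genome_length = genome_length
    ), class = "read_set")
  })
}

# Restrict a read set to the given samples.
filter_reads <- function(reads, sample_ids) {
  structure(list(
    reads = reads$reads[reads$reads$sample_id %in% sample_ids, ],
    obs = reads$obs[reads$obs$sample_id %in% sample_ids, ],
    genome_length = reads$genome_length
  ), class = "read_set")
}

# Realized coverage per sample (total read bases / genome length).
realized_coverage <- function(reads) {
  df <- dplyr::summarise(dplyr::group_by(reads$reads, .data$sample_id),
                         coverage = sum(.data$length) / reads$genome_length,
                         .groups = "drop")
  setNames(df$coverage, df$sample_id)
}

#' Drop samples with outlying realized coverage
#'
#' Within a coverage group, a sample is dropped when its realized coverage
#' lies more than one sample standard deviation from the group mean. The
#' default is two-sided (`|c - mean| > sd`); `sides = "low"` drops only the
#' low-coverage tail.
#'
#' @param coverage numeric vector of per-sample realized coverages
#'   (`n >= 2`).
#' @param sides `"two"` or `"low"`.
#' @return integer indices of the kept samples.
#' @export
drop_coverage_outliers <- function(coverage, sides = c("two", "low")) {
  sides <- match.arg(sides)
  if (length(coverage) < 2) abort("need at least 2 samples")
  mu <- mean(coverage)
  s <- sd(coverage)
  if (sides == "two") {
    which(abs(coverage - mu) <= s)
  } else {
    which(coverage >= mu - s)
  }
}
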