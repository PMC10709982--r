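#' Configuration of the coverage x panel x method evaluation grid
#'
#' @param sim a [sim_config()] describing the simulated population and reads.
#' @param params an [imputation_params()].
#' @param coverages coverages (x) to subsample the read pool down to.
#' @param panels named list of [panel_spec()]s.
#' @param methods imputation engines: `"read_aware"` and/or `"diploid_gl"`.
#' @param n_seeds independent simulation replicates.
#' @param n_duplicates how many samples are "sequenced twice" (an independent
#'   read pool is simulated for them and duplicate-run concordance reported);
#'   0 disables concordance.
#' @param drop_outliers drop samples whose realized coverage is more than one
#'   SD from the per-coverage mean before computing GEBV metrics.
#' @param seed base seed; replicate r uses deterministic stage seeds derived
#'   from `seed + 7919 * (r - 1)`.
#' @return a list of class `grid_config`.
#' @export
grid_config <- function(sim = sim_config(),
                        params = imputation_params(),
                        coverages = c(0.05, 0.1, 0.5, 1, 2),
                        panels = default_panel_specs(),
                        methods = c("read_aware", "diploid_gl"),
                        n_seeds = 1L,
                        n_duplicates = 0L,
                        drop_outliers = TRUE,
                        seed = 1L) {
  methods <- match.arg(methods, c("read_aware", "diploid_gl"),
                       several.ok = TRUE)
  if (is.null(names(panels))) {
    names(panels) <- vapply(panels, function(p) p$name, "")
  }
  if (n_duplicates > sim$n_samples) abort("n_duplicates exceeds n_samples")
  structure(list(sim = sim, params = params, coverages = sort(coverages),
                 panels = panels, methods = methods,
                 n_seeds = as.integer(n_seeds),
                 n_duplicates = as.integer(n_duplicates),
                 drop_outliers = drop_outliers, seed = as.integer(seed)),
            class = "grid_config")
}

# Deterministic stage seeds for one replicate.
grid_stage_seeds <- function(base_seed, rep) {
  base <- base_seed + 7919L * (rep - 1L)
  list(panel = base + 1L, samples = base + 2L, effects = base + 3L,
       pool = base + 4L, dup_pool = base + 5L,
       subsample = function(i) base + 10L + i,
       dup_subsample = function(i) base + 40L + i,
       impute = function(i) base + 100L + i,
       dup_impute = function(i) base + 2000L + i)
}

# Impute one read set against one panel with one engine; returns hard calls
# and dosages as a call_set over the panel sites.
impute_with_method <- function(reads, panel, method, params, seed) {
  post <- if (method == "read_aware") {
    impute_read_aware(reads, panel, params, seed = seed)
  } else {
    gl_calls <- genotype_sample(reads, panel$sites, method = "qscore")
    impute_diploid_gl(gl_calls, panel, params)
  }
  posterior_to_calls(post)
}

# Dosage and hard-genotype matrices at the prediction sites of a panel,
# ordered by sample id.
prediction_matrices <- function(calls, panel) {
  pred <- which(panel$sites$is_prediction_site)
  list(
    dosage = call_matrix(calls, sites = pred, value = "dosage"),
    gt = call_matrix(calls, sites = pred, value = "gt"),
    pos = panel$sites$pos[pred]
  )
}

#' Run the coverage x panel x method evaluation grid
#'
#' For every replicate: simulate a reference panel, diploid samples, SNP
#' effects and a read pool at the largest coverage; then, for every grid
#' cell, subsample the pool to the cell's coverage, impute with the cell's
#' engine against the cell's filtered panel, compute GEBVs from the imputed
#' dosages at the prediction sites, and score everything against the
#' truth-genotype GEBVs: Pearson correlation with 95% CI, prediction bias,
#' hard-call imputation accuracy, the quartile-transition matrix, and (when
#' duplicates are configured) duplicate-run genotype concordance.
#'
#' @param config a [grid_config()].
#' @param verbose print progress to stderr.
#' @return a tibble of class `skim_eval`, one row per replicate x coverage x
#'   panel x method, with the quartile matrix in a list column; the config is
#'   attached as attribute `config`.
#' @export
run_grid <- function(config = grid_config(), verbose = FALSE) {
  stopifnot(inherits(config, "grid_config"))
  sim <- config$sim
  rows <- list()
  for (rep in seq_len(config$n_seeds)) {
    seeds <- grid_stage_seeds(config$seed, rep)
    panel_full <- simulate_panel(sim, seed = seeds$panel)
    truth <- simulate_samples(panel_full, sim$n_samples,
                              sim$sample_switch_rate, seed = seeds$samples)
    effects <- simulate_effects(panel_full$sites, sim$prop_causal,
                                sim$effect_sd, seed = seeds$effects)
    pred_idx <- which(panel_full$sites$is_prediction_site)
    truth_gt <- true_genotype_matrix(truth)
    truth_gebv <- gebv(truth_gt[, pred_idx, drop = FALSE], effects)

    max_cov <- max(config$coverages)
    pool <- simulate_reads(truth, config = sim, coverage = max_cov,
                           seed = seeds$pool)
    dup_ids <- head(truth$sample_id, config$n_duplicates)
    dup_pool <- NULL
    if (config$n_duplicates > 0) {
      dup_truth <- truth
      keep <- match(dup_ids, truth$sample_id)
      dup_truth$hap1 <- truth$hap1[keep, , drop = FALSE]
      dup_truth$hap2 <- truth$hap2[keep, , drop = FALSE]
      dup_truth$sample_id <- dup_ids
      dup_pool <- simulate_reads(dup_truth, config = sim, coverage = max_cov,
                                 seed = seeds$dup_pool)
    }

    panels <- lapply(config$panels, function(sp) filter_panel(panel_full, sp))
    cell <- 0L
    for (ci in seq_along(config$coverages)) {
      cov <- config$coverages[ci]
      sub <- subsample_reads(pool, cov, seed = seeds$subsample(ci))
      dup_sub <- if (!is.null(dup_pool)) {
        subsample_reads(dup_pool, cov, seed = seeds$dup_subsample(ci))
      }
      realized <- realized_coverage(sub)[truth$sample_id]
      kept_idx <- if (config$drop_outliers) {
        drop_coverage_outliers(realized)
      } else seq_along(realized)
      kept_ids <- truth$sample_id[kept_idx]

      for (pn in names(panels)) {
        panel <- panels[[pn]]
        for (m in config$methods) {
          cell <- cell + 1L
          if (verbose) {
            message(sprintf("rep %d cov %gx panel %s method %s",
                            rep, cov, pn, m))
          }
          calls <- impute_with_method(sub, panel, m, config$params,
                                      seed = seeds$impute(cell))
          mats <- prediction_matrices(calls, panel)
          est_gebv <- gebv(mats$dosage, effects)
          est <- est_gebv$gebv[match(truth$sample_id, est_gebv$sample_id)]
          ref <- truth_gebv$gebv

          truth_pred <- truth_gt[, pred_idx, drop = FALSE]
          colnames(truth_pred) <- as.character(pred_idx)
          acc_gt <- mats$gt
          colnames(acc_gt) <- as.character(pred_idx)
          acc_gt <- acc_gt[truth$sample_id, , drop = FALSE]
          acc <- mean(!is.na(acc_gt) & acc_gt == truth_pred)

          ci_tab <- pearson_ci(ref[kept_idx], est[kept_idx])
          bias <- prediction_bias(ref[kept_idx], est[kept_idx])
          qt <- quartile_transitions(ref[kept_idx], est[kept_idx])

          conc <- NA_real_
          if (!is.null(dup_sub)) {
            dup_calls <- impute_with_method(dup_sub, panel, m, config$params,
                                            seed = seeds$dup_impute(cell))
            run1 <- calls[calls$sample_id %in% dup_ids, ]
            attr(run1, "sites") <- attr(calls, "sites")
            class(run1) <- class(calls)
            pred_panel <- which(panel$sites$is_prediction_site)
            conc_tab <- concordance(run1, dup_calls, sites = pred_panel)
            conc <- mean(conc_tab$concordance)
          }

          n_panel_sites <- nrow(panel$sites)
          rows[[length(rows) + 1L]] <- tibble::tibble(
            rep = rep, coverage = cov, panel = pn, method = m,
            n_samples = sim$n_samples, n_kept = length(kept_idx),
            n_dropped = sim$n_samples - length(kept_idx),
            n_panel_sites = n_panel_sites,
            r = ci_tab$r, r_lo = ci_tab$lo, r_hi = ci_tab$hi,
            bias = bias, accuracy = acc, concordance = conc,
            quartile_matrix = list(qt)
          )
        }
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "config") <- config
  class(out) <- unique(c("skim_eval", class(out)))
  out
}
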