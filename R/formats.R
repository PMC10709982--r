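#' Build a per-sample pileup over a site map
#'
#' Collects every read observation covering each mapped site, preserving the
#' observed base, its phred-derived error probability, the read strand and the
#' read id — one row per observation, tagged with the site's alleles and CpG
#' flags. Sites with no observations simply have no rows (depth 0).
#'
#' Observations are matched to `sites` by position, so a pileup can be built
#' over a subset of the sites the reads were simulated on (e.g. a filtered
#' reference panel's sites).
#'
#' @param reads a `read_set`.
#' @param sites a [site_map()].
#' @return a tibble of class `pileup` with columns `sample_id`, `read_id`,
#'   `site` (index into `sites`), `pos`, `base`, `e`, `strand`, `ref`, `alt`,
#'   `cpg_forward`, `cpg_reverse`; the site map is attached as attribute
#'   `sites`.
#' @export
build_pileup <- function(reads, sites) {
  stopifnot(inherits(reads, "read_set"))
  sites <- validate_site_map(sites)
  obs <- reads$obs
  idx <- match(obs$pos, sites$pos)
  keep <- !is.na(idx)
  out <- tibble::tibble(
    sample_id = obs$sample_id[keep],
    read_id = obs$read_id[keep],
    site = idx[keep],
    pos = obs$pos[keep],
    base = obs$base[keep],
    e = cap_error(obs$e[keep]),
    strand = obs$strand[keep],
    ref = sites$ref[idx[keep]],
    alt = sites$alt[idx[keep]],
    cpg_forward = sites$cpg_forward[idx[keep]],
    cpg_reverse = sites$cpg_reverse[idx[keep]]
  )
  out <- dplyr::arrange(out, .data$sample_id, .data$site)
  attr(out, "sites") <- sites
  class(out) <- unique(c("pileup", class(out)))
  out
}

#' Per-site read depth of a pileup
#'
#' @param pileup a `pileup` from [build_pileup()].
#' @return a tibble (`sample_id`, `site`, `depth`) covering every site of the
#'   pileup's site map for every sample present (zero depths included).
#' @export
pileup_depth <- function(pileup) {
  sites <- attr(pileup, "sites")
  samples <- unique(pileup$sample_id)
  full <- tidyr::expand_grid(sample_id = samples, site = seq_len(nrow(sites)))
  counts <- dplyr::count(tibble::as_tibble(pileup), .data$sample_id, .data$site,
                         name = "depth")
  out <- dplyr::left_join(full, counts, by = c("sample_id", "site"))
  dplyr::mutate(out, depth = dplyr::coalesce(.data$depth, 0L))
}

#' Construct a call set
#'
#' A call set holds per sample x site genotype information: a hard genotype in
#' \{0, 1, 2\} (NA = missing), a dosage in `[0, 2]` (NA allowed), an optional
#' linear-scale likelihood triple, and a provenance tag (`"mac"`, `"qscore"`
#' or `"imputed"`).
#'
#' @param sample_id,site,gt,dosage,gl_rr,gl_ra,gl_aa,source column vectors;
#'   likelihood columns may be omitted (NA).
#' @param sites the [site_map()] the `site` indices refer to.
#' @return a tibble of class `call_set` with the site map attached as
#'   attribute `sites`.
#' @export
call_set <- function(sample_id, site, gt = NA_integer_, dosage = NA_real_,
                     gl_rr = NA_real_, gl_ra = NA_real_, gl_aa = NA_real_,
                     source = NA_character_, sites = NULL) {
  out <- tibble::tibble(
    sample_id = as.character(sample_id),
    site = as.integer(site),
    gt = as.integer(gt),
    dosage = as.numeric(dosage),
    gl_rr = as.numeric(gl_rr),
    gl_ra = as.numeric(gl_ra),
    gl_aa = as.numeric(gl_aa),
    source = as.character(source)
  )
  bad_gt <- !is.na(out$gt) & !out$gt %in% 0:2
  if (any(bad_gt)) abort("hard genotypes must be 0, 1, 2 or NA")
  bad_ds <- !is.na(out$dosage) & (out$dosage < 0 | out$dosage > 2)
  if (any(bad_ds)) abort("dosages must lie in [0, 2]")
  if (!is.null(sites)) attr(out, "sites") <- validate_site_map(sites)
  class(out) <- unique(c("call_set", class(out)))
  out
}

#' Dosage (or genotype) matrix of a call set
#'
#' @param calls a `call_set`.
#' @param sites restrict to these site indices (default: all sites present).
#' @param value `"dosage"` uses the dosage where present, falling back to the
#'   hard genotype; `"gt"` uses hard genotypes only.
#' @return numeric matrix samples x sites with NA for missing entries.
#' @export
call_matrix <- function(calls, sites = NULL, value = c("dosage", "gt")) {
  value <- match.arg(value)
  df <- tibble::as_tibble(calls)
  if (!is.null(sites)) df <- df[df$site %in% sites, ]
  df$value <- if (value == "dosage") {
    dplyr::coalesce(df$dosage, as.numeric(df$gt))
  } else {
    as.numeric(df$gt)
  }
  wide <- tidyr::pivot_wider(df[, c("sample_id", "site", "value")],
                             names_from = "site", values_from = "value")
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$sample_id
  m[, order(as.integer(colnames(m))), drop = FALSE]
}

vcf_connection <- function(path, open = "w") {
  if (grepl("\\.gz$", path)) gzfile(path, open) else file(path, open)
}

vcf_header <- function(sites, sample_names, format_lines, provenance = NULL) {
  c(
    "##fileformat=VCFv4.2",
    paste0("##source=skimpute ",
           as.character(utils::packageVersion("skimpute"))),
    if (!is.null(provenance)) paste0("##skimpute_", names(provenance), "=",
                                     unlist(provenance)),
    paste0("##contig=<ID=", sites$chrom[1], ">"),
    "##INFO=<ID=PRED,Number=0,Type=Flag,Description=\"Prediction SNP set member\">",
    "##INFO=<ID=CPGF,Number=0,Type=Flag,Description=\"CpG cytosine on forward strand\">",
    "##INFO=<ID=CPGR,Number=0,Type=Flag,Description=\"CpG cytosine on reverse strand\">",
    format_lines,
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_names), collapse = "\t")
  )
}

site_info_field <- function(sites) {
  info <- rep("", nrow(sites))
  add <- function(info, flag, tag) {
    ifelse(flag, ifelse(info == "", tag, paste0(info, ";", tag)), info)
  }
  info <- add(info, sites$is_prediction_site, "PRED")
  info <- add(info, sites$cpg_forward, "CPGF")
  info <- add(info, sites$cpg_reverse, "CPGR")
  ifelse(info == "", ".", info)
}

#' Write a phased haplotype panel as VCF v4.2
#'
#' Haplotype rows 2i-1 and 2i become the phased GT of sample i
#' (`"0|1"`-style). Site flags are stored as INFO flags (`PRED`, `CPGF`,
#' `CPGR`) so that [read_panel_vcf()] round-trips the site map exactly.
#'
#' @param panel a `haplotype_panel` with an even number of haplotypes.
#' @param path output path (`.gz` for gzip).
#' @param provenance optional named list written as `##skimpute_*` header
#'   lines (e.g. seed, config hash).
#' @export
write_panel_vcf <- function(panel, path, provenance = NULL) {
  stopifnot(inherits(panel, "haplotype_panel"))
  H <- panel$n_haplotypes
  if (H %% 2L != 0L) abort("panel must have an even number of haplotypes")
  sites <- panel$sites
  n_s <- H %/% 2L
  sample_names <- sprintf("HAP%03d", seq_len(n_s))
  gt <- matrix("", nrow(sites), n_s)
  for (j in seq_len(n_s)) {
    gt[, j] <- paste0(panel$alleles[2L * j - 1L, ], "|", panel$alleles[2L * j, ])
  }
  body <- paste(sites$chrom, sites$pos, ".", sites$ref, sites$alt, ".", "PASS",
                site_info_field(sites), "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  hdr <- vcf_header(sites, sample_names,
                    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
                    provenance)
  con <- vcf_connection(path)
  on.exit(close(con))
  writeLines(c(hdr, body), con)
  invisible(path)
}

parse_vcf_sites <- function(vcf) {
  fix <- vcfR::getFIX(vcf)
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  if (length(unique(fix$CHROM)) > 1) {
    abort("VCF parse error: records span multiple chromosomes")
  }
  pos <- as.integer(fix$POS)
  if (length(pos) > 1 && any(diff(pos) <= 0)) {
    abort("VCF parse error: records are not sorted by position")
  }
  info <- vcf@fix[, "INFO"]
  info <- ifelse(is.na(info), ".", info)
  toks <- strsplit(info, ";", fixed = TRUE)
  has <- function(tag) vapply(toks, function(t) tag %in% t, logical(1))
  site_map(chrom = fix$CHROM, pos = pos, ref = fix$REF, alt = fix$ALT,
           is_prediction_site = has("PRED"),
           cpg_forward = has("CPGF"), cpg_reverse = has("CPGR"))
}

#' Read a phased haplotype panel from VCF
#'
#' @param path VCF path (plain or gzipped).
#' @return a `haplotype_panel`. Unphased genotypes (`/` separator), unsorted
#'   records or mixed chromosomes raise a parse error.
#' @export
read_panel_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  sites <- parse_vcf_sites(vcf)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (any(grepl("/", gt, fixed = TRUE))) {
    abort("panel VCF must be phased ('|' genotype separator)")
  }
  if (any(is.na(gt) | gt == ".")) abort("panel VCF must have no missing genotypes")
  L <- nrow(sites)
  n_s <- ncol(gt)
  alleles <- matrix(0L, 2L * n_s, L)
  for (j in seq_len(n_s)) {
    parts <- strsplit(gt[, j], "|", fixed = TRUE)
    a <- vapply(parts, function(p) as.integer(p), integer(2))
    alleles[2L * j - 1L, ] <- a[1, ]
    alleles[2L * j, ] <- a[2, ]
  }
  haplotype_panel(sites, alleles)
}

phred_pl <- function(gl) {
  # phred-scale a linear likelihood triple, normalized so the best is 0
  pl <- -10 * log10(gl / max(gl))
  as.integer(round(pl))
}

#' Write genotype calls as VCF v4.2 with GT, DS and PL
#'
#' Missing hard calls become `./.`; DS and PL fields are `.` when absent.
#' Likelihood triples are stored phred-scaled (PL), normalized so the most
#' likely genotype has PL 0; internally likelihoods stay on the linear scale.
#'
#' @param calls a `call_set`.
#' @param sites the [site_map()] the call `site` indices refer to.
#' @param path output path.
#' @param provenance optional named list of `##skimpute_*` header values.
#' @export
write_calls_vcf <- function(calls, sites, path, provenance = NULL) {
  sites <- validate_site_map(sites)
  df <- tibble::as_tibble(calls)
  samples <- sort(unique(df$sample_id))
  used_sites <- sort(unique(df$site))
  gt_str <- function(g) {
    ifelse(is.na(g), "./.", c("0/0", "0/1", "1/1")[g + 1L])
  }
  cell <- function(row) {
    gt <- gt_str(row$gt)
    ds <- ifelse(is.na(row$dosage), ".", sprintf("%.6g", row$dosage))
    pl <- if (any(!is.na(row$gl_rr))) {
      ifelse(is.na(row$gl_rr), ".",
             paste(row$pl_rr, row$pl_ra, row$pl_aa, sep = ","))
    } else rep(".", nrow(row))
    paste(gt, ds, pl, sep = ":")
  }
  has_gl <- !is.na(df$gl_rr)
  df$pl_rr <- df$pl_ra <- df$pl_aa <- NA_integer_
  if (any(has_gl)) {
    gl <- as.matrix(df[has_gl, c("gl_rr", "gl_ra", "gl_aa")])
    pls <- t(apply(gl, 1, phred_pl))
    df$pl_rr[has_gl] <- pls[, 1]
    df$pl_ra[has_gl] <- pls[, 2]
    df$pl_aa[has_gl] <- pls[, 3]
  }
  grid <- tidyr::expand_grid(site = used_sites, sample_id = samples)
  full <- dplyr::left_join(grid, df, by = c("site", "sample_id"))
  cells <- matrix(cell(full), nrow = length(used_sites), byrow = TRUE)
  sub <- sites[used_sites, ]
  body <- paste(sub$chrom, sub$pos, ".", sub$ref, sub$alt, ".", "PASS",
                site_info_field(sub), "GT:DS:PL",
                apply(cells, 1, paste, collapse = "\t"), sep = "\t")
  fmt <- c(
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Dosage\">",
    "##FORMAT=<ID=PL,Number=G,Type=Integer,Description=\"Phred-scaled genotype likelihoods\">"
  )
  hdr <- vcf_header(sub, samples, fmt, provenance)
  con <- vcf_connection(path)
  on.exit(close(con))
  writeLines(c(hdr, body), con)
  invisible(path)
}

#' Read genotype calls written by [write_calls_vcf()]
#'
#' @param path VCF path.
#' @return a list with the `site_map` (`sites`) and a `call_set` (`calls`)
#'   whose `site` indices refer to that map; PL fields are returned both as
#'   integers (`pl_*`) and converted back to linear likelihoods normalized to
#'   max 1 (`gl_*`).
#' @export
read_calls_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  sites <- parse_vcf_sites(vcf)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  ds <- vcfR::extract.gt(vcf, element = "DS")
  pl <- vcfR::extract.gt(vcf, element = "PL")
  samples <- colnames(gt)
  L <- nrow(sites)
  to_gt <- function(x) {
    out <- rep(NA_integer_, length(x))
    out[x %in% c("0/0", "0|0")] <- 0L
    out[x %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
    out[x %in% c("1/1", "1|1")] <- 2L
    out
  }
  rows <- lapply(seq_along(samples), function(j) {
    plj <- pl[, j]
    plm <- matrix(NA_integer_, L, 3)
    okpl <- !is.na(plj) & plj != "."
    if (any(okpl)) {
      sp <- do.call(rbind, strsplit(plj[okpl], ",", fixed = TRUE))
      plm[okpl, ] <- as.integer(sp)
    }
    glm <- 10^(-plm / 10)
    tibble::tibble(
      sample_id = samples[j],
      site = seq_len(L),
      gt = to_gt(gt[, j]),
      dosage = suppressWarnings(as.numeric(ifelse(ds[, j] == ".", NA, ds[, j]))),
      gl_rr = glm[, 1], gl_ra = glm[, 2], gl_aa = glm[, 3],
      pl_rr = plm[, 1], pl_ra = plm[, 2], pl_aa = plm[, 3]
    )
  })
  calls <- dplyr::bind_rows(rows)
  cs <- call_set(calls$sample_id, calls$site, calls$gt, calls$dosage,
                 calls$gl_rr, calls$gl_ra, calls$gl_aa,
                 source = NA_character_, sites = sites)
  cs$pl_rr <- calls$pl_rr
  cs$pl_ra <- calls$pl_ra
  cs$pl_aa <- calls$pl_aa
  list(sites = sites, calls = cs)
}

#' Read/write SNP effects as TSV
#'
#' Tab-separated with a header (`site`, `pos`, `effect`).
#'
#' @param path TSV path (gzip-transparent).
#' @return `read_effects_tsv()` returns an `effect_vector` tibble.
#' @export
read_effects_tsv <- function(path) {
  out <- readr::read_tsv(path, col_types = readr::cols(
    site = readr::col_integer(), pos = readr::col_integer(),
    effect = readr::col_double()
  ))
  class(out) <- unique(c("effect_vector", class(out)))
  out
}

#' @rdname read_effects_tsv
#' @param effects an `effect_vector` tibble.
#' @export
write_effects_tsv <- function(effects, path) {
  readr::write_tsv(effects[, c("site", "pos", "effect")], path)
  invisible(path)
}
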