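# Gene-level alteration calling: binary patient-by-gene matrices from
# non-synonymous variant tables and copy-number log-R-ratio (LRR) profiles,
# recurrence filtering, NAG burden scores and their dichotomization.
#
# A gene counts as "altered" in a patient if it carries at least one somatic
# non-synonymous variant, or its copy-number state is a gain (LRR > 0.5) or
# a loss (LRR < -0.5). Gene symbols are matched case-insensitively after a
# single trim/uppercase normalization pass.

#' Call gene-level copy-number state from log-R ratio
#'
#' Gain when LRR > 0.5, loss when LRR < -0.5, neutral otherwise. The
#' inequalities are strict: LRR of exactly +/-0.5 is neutral.
#'
#' @param lrr numeric vector of per-gene log-R-ratio values (finite).
#' @return character vector in `c("loss", "neutral", "gain")`.
#' @export
call_copy_number_state <- function(lrr) {
  if (!is.numeric(lrr) || any(!is.finite(lrr)))
    stopf("LRR values must be finite numbers")
  out <- rep("neutral", length(lrr))
  out[lrr > 0.5] <- "gain"
  out[lrr < -0.5] <- "loss"
  out
}

#' @keywords internal
#' @noRd
check_variants <- function(variants) {
  need <- c("sample_id", "gene", "protein_pos", "ref_aa", "alt_aa", "vaf")
  miss <- setdiff(need, names(variants))
  if (length(miss))
    stopf("variant table missing columns: %s", paste(miss, collapse = ", "))
  if (nrow(variants)) {
    if (any(variants$protein_pos < 1)) stopf("protein_pos must be >= 1")
    if (any(variants$ref_aa == variants$alt_aa))
      stopf("synonymous records present (ref_aa == alt_aa)")
    if (any(variants$vaf < 0 | variants$vaf > 1))
      stopf("VAF must lie in [0, 1]")
  }
  invisible(TRUE)
}

#' Build the binary patient-by-gene alteration matrix
#'
#' Entry (patient, gene) is 1 when the patient carries at least one
#' non-synonymous variant in that gene, or the gene's copy-number state is
#' gain or loss; multiple events in one gene still give a single 1. Genes of
#' the universe absent from both inputs stay 0.
#'
#' @param variants data frame of variant records (`sample_id`, `gene`,
#'   `protein_pos`, `ref_aa`, `alt_aa`, `vaf`).
#' @param lrr numeric gene x sample matrix of log-R ratios (dimnames
#'   required), or NULL for mutation-only matrices.
#' @param gene_universe character vector of genes forming the columns.
#' @param samples character vector of patient ids forming the rows; defaults
#'   to the union of LRR columns and variant samples. Variants from samples
#'   outside this set are an error (guards against clinical/genomic id
#'   mismatches).
#' @return object of class `alteration_matrix`: a 0/1 integer matrix,
#'   patients in rows, genes (normalized symbols, in `gene_universe` order)
#'   in columns.
#' @export
build_alteration_matrix <- function(variants, lrr = NULL, gene_universe,
                                    samples = NULL) {
  check_variants(variants)
  if (!length(gene_universe)) stopf("gene_universe is empty")
  genes <- unique(normalize_gene(gene_universe))
  if (is.null(samples)) {
    samples <- union(colnames(lrr), unique(as.character(variants$sample_id)))
  }
  samples <- as.character(samples)
  if (!length(samples)) stopf("no samples to build the matrix over")
  unknown <- setdiff(unique(as.character(variants$sample_id)), samples)
  if (length(unknown))
    stopf("variant table contains unknown sample id(s): %s",
          paste(unknown, collapse = ", "))

  mat <- matrix(0L, nrow = length(samples), ncol = length(genes),
                dimnames = list(samples, genes))
  if (nrow(variants)) {
    vg <- normalize_gene(variants$gene)
    keep <- vg %in% genes
    if (any(keep)) {
      mat[cbind(as.character(variants$sample_id)[keep], vg[keep])] <- 1L
    }
  }
  if (!is.null(lrr)) {
    if (is.null(rownames(lrr)) || is.null(colnames(lrr)))
      stopf("LRR matrix needs gene rownames and sample colnames")
    lg <- normalize_gene(rownames(lrr))
    gsel <- which(lg %in% genes)
    ssel <- intersect(colnames(lrr), samples)
    for (s in ssel) {
      vals <- lrr[gsel, s]
      st <- call_copy_number_state(vals)
      hit <- st != "neutral"
      if (any(hit)) mat[s, lg[gsel][hit]] <- 1L
    }
  }
  class(mat) <- c("alteration_matrix", class(mat))
  mat
}

#' Drop genes altered in fewer than a minimum number of patients
#'
#' Mirrors the discovery filter that removes genes altered in only one
#' patient: retained genes have column sums >= `min_patients`.
#'
#' @param matrix an `alteration_matrix`.
#' @param min_patients minimum patient count (default 2).
#' @return filtered `alteration_matrix` (possibly zero genes).
#' @export
filter_recurrent_genes <- function(matrix, min_patients = 2) {
  if (min_patients < 1) stopf("min_patients must be >= 1")
  keep <- colSums(matrix) >= min_patients
  out <- matrix[, keep, drop = FALSE]
  class(out) <- c("alteration_matrix", "matrix", "array")
  out
}

#' Number of altered genes (NAG) within a fixed panel
#'
#' Per-patient count of panel genes that are altered. Panel genes missing
#' from the matrix's gene universe contribute 0 and are reported once via a
#' message; a panel entirely disjoint from the universe is an error.
#'
#' @param matrix an `alteration_matrix`.
#' @param panel character vector of panel gene symbols.
#' @return named integer vector of per-patient scores in `[0, |panel|]`.
#' @export
nag_score <- function(matrix, panel) {
  if (!length(panel)) stopf("panel is empty")
  panel <- unique(normalize_gene(panel))
  present <- intersect(panel, colnames(matrix))
  if (!length(present))
    stopf("panel is disjoint from the matrix gene universe")
  absent <- setdiff(panel, present)
  if (length(absent))
    message(sprintf("nag_score: %d/%d panel gene(s) absent from universe, contributing 0",
                    length(absent), length(panel)))
  scores <- rowSums(matrix[, present, drop = FALSE])
  storage.mode(scores) <- "integer"
  scores
}

#' Dichotomize burden scores into low/high groups
#'
#' With a data-driven cut (the default), the cut is the `quartile` quantile
#' of the scores (type-7 quantiles) and ties go to "low": low when score <=
#' Q1, high otherwise. With a supplied absolute `threshold` t, "high" means
#' score >= t (so a patient at exactly the published 87-gene cutoff is
#' high-burden).
#'
#' @param scores numeric scores (>= 4 values when the cut is data-driven).
#' @param quartile probability of the data-driven cut (default 0.25).
#' @param threshold optional absolute cutoff overriding the quantile rule.
#' @return factor with levels `c("low", "high")`, named like `scores`;
#'   attribute `cutoff` records the cut used.
#' @export
dichotomize_scores <- function(scores, quartile = 0.25, threshold = NULL) {
  if (!length(scores)) stopf("no scores to dichotomize")
  if (is.null(threshold)) {
    if (length(scores) < 4L)
      stopf("need >= 4 observations to compute a quartile cutoff")
    if (diff(range(scores)) == 0)
      stopf("constant scores: no quantile split possible")
    cut <- quantile7(scores, quartile)
    lab <- ifelse(scores <= cut, "low", "high")
  } else {
    cut <- threshold
    lab <- ifelse(scores >= threshold, "high", "low")
  }
  out <- factor(lab, levels = c("low", "high"))
  names(out) <- names(scores)
  attr(out, "cutoff") <- cut
  out
}
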