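# Expression proxy signature for alteration burden: differential expression
# between high/low NAG groups, per-patient expression risk scores (linear
# predictor of a penalized Cox fit on signature genes), risk-score
# thresholding at the third quartile, and the combined NAG/expression
# classifier.
#
# Scale conventions: fold changes are ratios of group means on the linear
# (RSEM-like) scale; t-tests and risk scores operate on asinh-transformed
# values, the transform used for all survival modelling of expression here.

#' Inverse-hyperbolic-sine transform of an expression matrix
#'
#' Elementwise asinh(x) = log(x + sqrt(x^2 + 1)); behaves like log(2x) for
#' large x but is defined at zero. The transform is recorded in an attribute
#' and refuses to be applied twice.
#'
#' @param expr nonnegative numeric gene x sample matrix.
#' @return transformed matrix with attribute `transformed = TRUE`.
#' @export
asinh_transform <- function(expr) {
  if (isTRUE(attr(expr, "transformed")))
    stopf("expression matrix is already asinh-transformed")
  if (any(expr < 0)) stopf("expression must be nonnegative before transform")
  out <- asinh(expr)
  attr(out, "transformed") <- TRUE
  out
}

#' Differentially expressed genes between two groups
#'
#' A gene is retained when its absolute fold change exceeds `fc_threshold`
#' and its Welch t-test p-value is below `p_threshold`. The fold change is
#' the ratio of group means on the linear scale, direction-symmetric
#' (max of ratio and its reciprocal); the t-test runs on asinh-transformed
#' values. Genes with zero variance in both groups and equal means are
#' skipped with a warning. Optionally Benjamini-Hochberg-adjusted p-values
#' replace raw ones.
#'
#' @param expr linear-scale (untransformed) gene x sample matrix.
#' @param group_labels two-level factor/character over the samples, each
#'   level with n >= 2.
#' @param fc_threshold fold-change cutoff (default 2, exclusive).
#' @param p_threshold p-value cutoff (default 0.05, exclusive).
#' @param adjust apply BH correction before thresholding (default FALSE:
#'   raw p-values).
#' @return data frame `gene`, `mean_1`, `mean_2`, `fold_change` (ratio of
#'   level-1 over level-2 means), `abs_fold_change`, `t`, `p` for retained
#'   genes.
#' @export
differential_expression <- function(expr, group_labels, fc_threshold = 2,
                                    p_threshold = 0.05, adjust = FALSE) {
  if (isTRUE(attr(expr, "transformed")))
    stopf("supply linear-scale expression; fold changes are defined on it")
  g <- factor(group_labels)
  if (nlevels(g) != 2L) stopf("exactly two groups required")
  if (any(table(g) < 2L)) stopf("each group needs n >= 2")
  if (ncol(expr) != length(g)) stopf("labels do not align with samples")
  i1 <- which(g == levels(g)[1]); i2 <- which(g == levels(g)[2])
  tr <- asinh(expr)

  m1 <- rowMeans(expr[, i1, drop = FALSE])
  m2 <- rowMeans(expr[, i2, drop = FALSE])
  fc <- m1 / m2
  afc <- pmax(fc, 1 / fc)

  v1 <- apply(tr[, i1, drop = FALSE], 1, stats::var)
  v2 <- apply(tr[, i2, drop = FALSE], 1, stats::var)
  mt1 <- rowMeans(tr[, i1, drop = FALSE])
  mt2 <- rowMeans(tr[, i2, drop = FALSE])
  degenerate <- v1 == 0 & v2 == 0 & mt1 == mt2
  if (any(degenerate))
    warnf("%d gene(s) with zero variance and equal means skipped",
          sum(degenerate))

  # Welch t statistic and Satterthwaite df, vectorized over genes
  n1 <- length(i1); n2 <- length(i2)
  sed2 <- v1 / n1 + v2 / n2
  tstat <- (mt1 - mt2) / sqrt(sed2)
  df <- sed2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(tstat), df)
  if (adjust) p <- stats::p.adjust(p, method = "BH")

  keep <- !degenerate & is.finite(afc) & afc > fc_threshold &
    is.finite(p) & p < p_threshold
  keep[is.na(keep)] <- FALSE
  data.frame(
    gene = rownames(expr)[keep],
    mean_1 = m1[keep], mean_2 = m2[keep],
    fold_change = fc[keep], abs_fold_change = afc[keep],
    t = tstat[keep], p = p[keep],
    row.names = NULL
  )
}

#' Per-patient expression risk score
#'
#' Linear predictor of a penalized Cox expression model: for each patient,
#' the sum over signature genes of coefficient times asinh-transformed
#' expression. Coefficient genes absent from the matrix contribute 0 and are
#' reported via a message.
#'
#' @param expr gene x sample matrix; transformed already (attribute set) or
#'   linear, in which case it is asinh-transformed internally.
#' @param coefficients named numeric vector, gene -> coefficient.
#' @return named numeric vector of per-patient scores.
#' @export
expression_risk_score <- function(expr, coefficients) {
  if (!length(coefficients)) stopf("empty coefficient map")
  if (is.null(names(coefficients)) || any(!nzchar(names(coefficients))))
    stopf("coefficients must be named by gene")
  if (!isTRUE(attr(expr, "transformed"))) expr <- asinh_transform(expr)
  genes <- normalize_gene(names(coefficients))
  rn <- normalize_gene(rownames(expr))
  present <- genes %in% rn
  if (any(!present))
    message(sprintf("expression_risk_score: %d/%d signature gene(s) absent, contributing 0",
                    sum(!present), length(genes)))
  if (!any(present)) return(stats::setNames(rep(0, ncol(expr)), colnames(expr)))
  idx <- match(genes[present], rn)
  scores <- drop(crossprod(expr[idx, , drop = FALSE],
                           unname(coefficients)[present]))
  stats::setNames(as.numeric(scores), colnames(expr))
}

#' Threshold expression risk scores into low/high risk labels
#'
#' Scores at or above the cutoff are labelled `high_risk_expr` (the
#' direction associated with low alteration burden), below it
#' `low_risk_expr`. The cutoff is either supplied (e.g. the published 0.17)
#' or computed as the third quartile of the scores, mirroring the first
#' quartile cut used for the burden score itself.
#'
#' @param scores numeric scores.
#' @param cutoff absolute cutoff; NULL (default) computes Q3 (type-7).
#' @return factor with levels `c("low_risk_expr", "high_risk_expr")` and
#'   attribute `cutoff`.
#' @export
threshold_risk_score <- function(scores, cutoff = NULL) {
  if (!length(scores)) stopf("no scores")
  if (is.null(cutoff)) {
    if (diff(range(scores)) == 0)
      stopf("constant scores: cannot compute a quartile cutoff")
    cutoff <- quantile7(scores, 0.75)
  }
  out <- factor(ifelse(scores >= cutoff, "high_risk_expr", "low_risk_expr"),
                levels = c("low_risk_expr", "high_risk_expr"))
  names(out) <- names(scores)
  attr(out, "cutoff") <- cutoff
  out
}

#' Combined burden/expression prognostic classifier
#'
#' A patient has the better-prognosis label when burden is high OR the
#' expression risk score is low-risk; only low-burden, high-risk patients
#' fall in the worse group.
#'
#' @param nag_labels factor/character in `c("low", "high")` per patient.
#' @param expr_labels factor/character in
#'   `c("low_risk_expr", "high_risk_expr")` per patient, aligned with
#'   `nag_labels`.
#' @return factor with levels `c("worse", "better")`.
#' @export
combined_classifier <- function(nag_labels, expr_labels) {
  if (length(nag_labels) != length(expr_labels))
    stopf("label vectors have different lengths")
  if (anyNA(nag_labels) || anyNA(expr_labels))
    stopf("missing label for at least one patient")
  better <- nag_labels == "high" | expr_labels == "low_risk_expr"
  out <- factor(ifelse(better, "better", "worse"),
                levels = c("worse", "better"))
  names(out) <- names(nag_labels)
  out
}
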