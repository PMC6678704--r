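# Pipeline orchestration: the discovery workflow (cohort -> recurrent
# alteration matrix -> elastic-net Cox panel -> NAG scores -> expression
# proxy signature -> survival reports) and the validation workflow (frozen
# panel/coefficients/cutoffs applied to a new cohort, plus neoantigen
# stratification). Every threshold and seed lands in a JSON run manifest so
# a run can be audited and reproduced.

#' @keywords internal
#' @noRd
default_thresholds <- function() {
  list(
    lrr_gain = 0.5, lrr_loss = -0.5,
    min_patients_recurrent = 2,
    alpha = 0.1,
    os_horizon_years = 5,
    nag_quartile = 0.25,
    fc_threshold = 2, p_threshold = 0.05,
    risk_score_quartile = 0.75,
    affinity_threshold_nm = 500
  )
}

#' @keywords internal
#' @noRd
build_manifest <- function(stage, seed, thresholds, extra = list()) {
  c(list(stage = stage,
         package = "nagburden",
         version = as.character(utils::packageVersion("nagburden")),
         rng = "Mersenne-Twister (R default)",
         seed = seed,
         thresholds = thresholds),
    extra)
}

#' @keywords internal
#' @noRd
write_outputs <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  jsonlite::write_json(res$manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  if (!is.null(res$panel)) {
    utils::write.table(
      data.frame(gene = names(res$panel), coefficient = fmt_num(res$panel)),
      p("panel.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(res$nag_scores)) {
    utils::write.table(
      data.frame(sample_id = names(res$nag_scores), nag = res$nag_scores,
                 nag_group = as.character(res$nag_labels)),
      p("nag_scores.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(res$de_genes)) {
    de <- res$de_genes
    for (cc in c("mean_1", "mean_2", "fold_change", "abs_fold_change",
                 "t", "p"))
      de[[cc]] <- fmt_num(de[[cc]])
    utils::write.table(de, p("de_genes.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(res$risk_scores)) {
    utils::write.table(
      data.frame(sample_id = names(res$risk_scores),
                 risk_score = fmt_num(res$risk_scores),
                 risk_group = as.character(res$risk_labels)),
      p("risk_scores.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(res$survival)) {
    jsonlite::write_json(res$survival, p("survival_reports.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(out_dir)
}

#' @keywords internal
#' @noRd
survival_report <- function(clinical, labels, label_name) {
  # keep the caller's factor order so two-level HRs read second-vs-first
  # (e.g. "high" NAG vs the "low" reference)
  lv <- if (is.factor(labels)) levels(droplevels(labels))
        else sort(unique(as.character(labels)))
  df <- data.frame(time = clinical$time, event = clinical$event,
                   group = factor(as.character(labels), levels = lv))
  if (length(lv) < 2L) {
    # degenerate stratification (e.g. a frozen cutoff beyond this cohort's
    # score range): report group sizes, no tests
    return(list(grouping = label_name, groups = as.list(table(df$group)),
                n = nrow(df), events = sum(df$event),
                hr = NA_real_, hr_lower = NA_real_, hr_upper = NA_real_,
                wald_p = NA_real_, logrank_chisq = NA_real_,
                logrank_p = NA_real_))
  }
  lr <- logrank_test(df$time, df$event, df$group)
  hr <- NA_real_
  hr_ci <- c(NA_real_, NA_real_)
  wald_p <- NA_real_
  if (length(lv) == 2L) {
    cf <- cox_fit(df, "group")
    hr <- cf$table$hr[1]
    hr_ci <- c(cf$table$lower[1], cf$table$upper[1])
    wald_p <- cf$table$p[1]
  }
  list(grouping = label_name,
       groups = as.list(table(df$group)),
       n = nrow(df), events = sum(df$event),
       hr = hr, hr_lower = hr_ci[1], hr_upper = hr_ci[2],
       wald_p = wald_p,
       logrank_chisq = lr$chisq, logrank_p = lr$p)
}

#' Discovery workflow: panel selection, burden scoring, proxy signature
#'
#' Runs the full discovery analysis on a cohort bundle: builds the binary
#' alteration matrix from variants and copy-number LRR, drops
#' non-recurrent genes, fits the elastic-net Cox model of 5-year overall
#' survival on the alteration profiles (alpha 0.1), selects the model
#' maximizing the deviance ratio, extracts the nonzero-coefficient gene
#' panel, scores each patient's NAG and dichotomizes at the first
#' quartile, derives the differential-expression signature between the
#' burden groups, fits the expression risk model on those genes by
#' cross-validated elastic-net Cox, thresholds the risk scores at their
#' third quartile, applies the combined classifier, and produces
#' Kaplan-Meier/log-rank/Cox reports for each stratification.
#'
#' @param bundle a `cohort_bundle` (from [simulate_cohort()] or
#'   [read_bundle()]).
#' @param seed integer seed for the cross-validation folds.
#' @param thresholds named list overriding entries of the default
#'   threshold registry (LRR cuts, alpha, quartiles, FC/p cutoffs...).
#' @param out_dir optional directory; when given, panel, scores, DE table,
#'   risk scores, survival reports and the JSON run manifest are written
#'   there.
#' @return list with `panel` (named coefficients), `fit` (selected `encox`
#'   path), `nag_scores`, `nag_labels`, `de_genes`, `signature`
#'   (named coefficients of the expression model), `risk_scores`,
#'   `risk_labels`, `combined`, `survival` (per-stratification reports),
#'   `manifest`.
#' @export
run_discovery <- function(bundle, seed = 1, thresholds = list(),
                          out_dir = NULL) {
  stopifnot(inherits(bundle, "cohort_bundle"))
  thr <- utils::modifyList(default_thresholds(), thresholds)
  clin <- truncate_followup(bundle$clinical, thr$os_horizon_years)

  gene_universe <- union(rownames(bundle$lrr), unique(bundle$variants$gene))
  amat <- build_alteration_matrix(bundle$variants, bundle$lrr,
                                  gene_universe = gene_universe,
                                  samples = bundle$clinical$sample_id)
  amat <- filter_recurrent_genes(amat, thr$min_patients_recurrent)
  if (!ncol(amat)) stopf("no recurrently altered genes; nothing to fit")
  amat <- amat[clin$sample_id, , drop = FALSE]

  fit <- encox(amat, clin$time, clin$event, alpha = thr$alpha)
  fit <- select_by_deviance_ratio(fit)
  panel <- extract_panel(fit)
  if (!length(panel)) stopf("selected model is empty; no panel genes")

  nag <- nag_score(amat, names(panel))
  nag_labels <- dichotomize_scores(nag, quartile = thr$nag_quartile)

  expr <- bundle$expression[, clin$sample_id, drop = FALSE]
  de <- differential_expression(expr, nag_labels,
                                fc_threshold = thr$fc_threshold,
                                p_threshold = thr$p_threshold)
  signature <- numeric(0)
  risk_scores <- NULL; risk_labels <- NULL; combined <- NULL
  if (nrow(de) >= 2) {
    sig_expr <- t(asinh_transform(expr)[de$gene, , drop = FALSE])
    cv <- cv_encox(sig_expr, clin$time, clin$event, nfolds = 5,
                   alpha = thr$alpha, seed = seed)
    signature <- coef(cv)
    signature <- signature[signature != 0]
    if (length(signature)) {
      risk_scores <- expression_risk_score(asinh_transform(expr), signature)
      risk_labels <- threshold_risk_score(risk_scores)
      combined <- combined_classifier(nag_labels, risk_labels)
    }
  }

  surv <- list(nag = survival_report(clin, nag_labels, "nag"))
  if (!is.null(risk_labels))
    surv$signature <- survival_report(clin, risk_labels, "signature")
  if (!is.null(combined))
    surv$combined <- survival_report(clin, combined, "combined")

  manifest <- build_manifest(
    "discovery", seed, thr,
    list(n_patients = nrow(clin), n_events = sum(clin$event),
         n_genes_recurrent = ncol(amat), panel_size = length(panel),
         n_de_genes = nrow(de), signature_size = length(signature),
         nag_cutoff = attr(nag_labels, "cutoff"),
         risk_cutoff = if (!is.null(risk_labels)) attr(risk_labels, "cutoff")
                       else NA_real_,
         selected_lambda = attr(fit, "selected_lambda")))
  res <- list(panel = panel, fit = fit, nag_scores = nag,
              nag_labels = nag_labels, de_genes = de, signature = signature,
              risk_scores = risk_scores, risk_labels = risk_labels,
              combined = combined, survival = surv, manifest = manifest)
  if (!is.null(out_dir)) write_outputs(res, out_dir)
  res
}

#' Validation workflow: frozen classifiers applied to a new cohort
#'
#' Applies a fixed panel, fixed signature coefficients and fixed cutoffs to
#' an independent cohort -- no refitting anywhere, mirroring external
#' validation practice. Computes NAG counts against the supplied panel
#' (dichotomized at the supplied absolute threshold, or this cohort's first
#' quartile when none is given), expression risk scores from the supplied
#' coefficients (cutoff analogous), the combined classifier, per-patient
#' neoantigen immunogenicity through the chosen affinity backend, the
#' three-group burden/immunogenicity stratification, and survival reports
#' for each.
#'
#' @param bundle a `cohort_bundle` for the validation cohort.
#' @param panel named coefficient vector (or bare gene vector) defining the
#'   burden panel.
#' @param signature named coefficient vector of the expression model.
#' @param backend affinity backend for neoantigen calls; NULL skips the
#'   immunogenicity arm.
#' @param nag_threshold absolute NAG cutoff (score >= threshold is high);
#'   NULL uses this cohort's first quartile.
#' @param risk_cutoff absolute risk-score cutoff (score >= cutoff is
#'   high-risk); NULL uses this cohort's third quartile.
#' @param thresholds named list overriding the default threshold registry.
#' @param out_dir optional output directory (see [run_discovery()]).
#' @return list with `nag_scores`, `nag_labels`, `risk_scores`,
#'   `risk_labels`, `combined`, `immunogenicity` (per-patient calls, when a
#'   backend is given), `three_group`, `survival`, `manifest`.
#' @export
run_validation <- function(bundle, panel, signature, backend = NULL,
                           nag_threshold = NULL, risk_cutoff = NULL,
                           thresholds = list(), out_dir = NULL) {
  stopifnot(inherits(bundle, "cohort_bundle"))
  thr <- utils::modifyList(default_thresholds(), thresholds)
  clin <- truncate_followup(bundle$clinical, thr$os_horizon_years)
  panel_genes <- if (is.null(names(panel))) as.character(panel)
                 else names(panel)

  gene_universe <- union(rownames(bundle$lrr), unique(bundle$variants$gene))
  amat <- build_alteration_matrix(bundle$variants, bundle$lrr,
                                  gene_universe = gene_universe,
                                  samples = bundle$clinical$sample_id)
  amat <- amat[clin$sample_id, , drop = FALSE]
  nag <- nag_score(amat, panel_genes)
  nag_labels <- dichotomize_scores(nag, quartile = thr$nag_quartile,
                                   threshold = nag_threshold)

  expr <- bundle$expression[, clin$sample_id, drop = FALSE]
  risk_scores <- expression_risk_score(asinh_transform(expr), signature)
  risk_labels <- threshold_risk_score(risk_scores, cutoff = risk_cutoff)
  combined <- combined_classifier(nag_labels, risk_labels)

  surv <- list(nag = survival_report(clin, nag_labels, "nag"),
               signature = survival_report(clin, risk_labels, "signature"),
               combined = survival_report(clin, combined, "combined"))

  immuno <- NULL; three <- NULL
  if (!is.null(backend)) {
    panel_variants <- bundle$variants[
      normalize_gene(bundle$variants$gene) %in% normalize_gene(panel_genes), ,
      drop = FALSE]
    calls <- neoantigen_calls(panel_variants, bundle$proteome, bundle$hla,
                              expr, backend,
                              threshold = thr$affinity_threshold_nm)
    immuno <- calls$patients
    flag <- immuno$is_immunogenic[match(clin$sample_id, immuno$sample_id)]
    three <- three_group_stratification(nag_labels, flag)
    surv$immunogenicity <- survival_report(
      clin, ifelse(flag, "immunogenic", "nonimmunogenic"), "immunogenicity")
    if (nlevels(droplevels(three)) >= 2)
      surv$three_group <- survival_report(clin, three, "three_group")
  }

  manifest <- build_manifest(
    "validation", NA_integer_, thr,
    list(n_patients = nrow(clin), n_events = sum(clin$event),
         panel_size = length(panel_genes),
         signature_size = length(signature),
         nag_cutoff = attr(nag_labels, "cutoff"),
         risk_cutoff = attr(risk_labels, "cutoff"),
         backend = if (is.null(backend)) "none" else class(backend)[1]))
  res <- list(nag_scores = nag, nag_labels = nag_labels,
              risk_scores = risk_scores, risk_labels = risk_labels,
              combined = combined, immunogenicity = immuno,
              three_group = three, survival = surv, manifest = manifest)
  if (!is.null(out_dir)) write_outputs(res, out_dir)
  res
}
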