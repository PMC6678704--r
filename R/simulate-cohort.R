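# Synthetic cohort generator. Emits every input the burden pipeline
# consumes -- variant table, gene-level LRR matrix, expression matrix,
# clinical/survival table, HLA-A genotypes, a toy proteome -- together with
# the ground truth planted into them, so each downstream stage can be
# validated against a known generating model.
#
# Generating model (all draws from R's default Mersenne-Twister stream,
# fully determined by `seed`):
#   * A latent patient group (fraction `prob_low_group`) alters planted
#     panel genes at a low rate, the remainder at a high rate; background
#     genes alter at a common low rate. This reproduces the clearly
#     separated high/low burden groups the quartile dichotomization
#     assumes.
#   * Survival is exponential with hazard
#       baseline_hazard * exp(beta_per_alteration * (burden - E[burden]))
#     (centring keeps the marginal event rate at the baseline regardless of
#     beta), censored by an independent exponential and administratively at
#     `followup_horizon`.
#   * Signature genes are mean-shifted on the asinh scale between the
#     burden-quartile groups; all expression is mapped back through sinh to
#     a nonnegative RSEM-like linear scale. An HLA-A expression row is
#     always included.
#   * Each altered (patient, gene) pair receives a missense variant drawn
#     inside the gene's simulated protein; a chosen subset of high-burden
#     patients gets one variant peptide planted on the surrogate affinity
#     backend's strong-binder list, with gene and HLA-A expression forced
#     above the cohort medians, so those patients are immunogenic by
#     construction.

#' Simulation configuration
#'
#' Validates and fills the parameter set of [simulate_cohort()]. Defaults
#' describe a moderate early-stage cohort with a planted protective burden
#' effect; see the package vignette for the rationale behind each value.
#'
#' @param n_patients cohort size (default 300).
#' @param n_genes total genes carrying alterations (default 120).
#' @param n_panel_genes planted prognostic genes, <= n_genes (default 40).
#' @param alteration_rate_background per-gene per-patient alteration
#'   probability outside the panel (default 0.08).
#' @param alteration_rate_panel length-2 vector: panel alteration
#'   probability in the latent low-burden and high-burden patient groups
#'   (default c(0.15, 0.60)).
#' @param prob_low_group fraction of patients in the latent low-burden
#'   group (default 0.25, matching the quartile dichotomization).
#' @param beta_per_alteration log-hazard increment per altered planted gene
#'   (negative = protective; default -0.05).
#' @param baseline_hazard events per year at the expected burden (default
#'   0.15).
#' @param censoring_rate exponential censoring hazard per year (default
#'   0.05).
#' @param followup_horizon administrative censoring time in years (default
#'   10; `Inf` disables it).
#' @param n_signature_genes planted differentially expressed genes
#'   (default 30).
#' @param signature_shift expression mean difference between burden groups
#'   on the asinh scale (default 2).
#' @param noise_sd expression noise SD on the asinh scale (default 1).
#' @param n_immunogenic_patients patients given a planted strong-binder
#'   peptide (default 8).
#' @param protein_length_range amino-acid length range of simulated
#'   proteins (default c(60, 120)).
#' @param seed integer RNG seed.
#' @return validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_patients = 300,
                              n_genes = 120,
                              n_panel_genes = 40,
                              alteration_rate_background = 0.08,
                              alteration_rate_panel = c(0.15, 0.60),
                              prob_low_group = 0.25,
                              beta_per_alteration = -0.05,
                              baseline_hazard = 0.15,
                              censoring_rate = 0.05,
                              followup_horizon = 10,
                              n_signature_genes = 30,
                              signature_shift = 2,
                              noise_sd = 1,
                              n_immunogenic_patients = 8,
                              protein_length_range = c(60, 120),
                              seed = 1) {
  followup_horizon <- as.numeric(followup_horizon) # accepts "Inf" from JSON
  cfg <- list(
    n_patients = as.integer(n_patients), n_genes = as.integer(n_genes),
    n_panel_genes = as.integer(n_panel_genes),
    alteration_rate_background = alteration_rate_background,
    alteration_rate_panel = rep_len(alteration_rate_panel, 2L),
    prob_low_group = prob_low_group,
    beta_per_alteration = beta_per_alteration,
    baseline_hazard = baseline_hazard, censoring_rate = censoring_rate,
    followup_horizon = followup_horizon,
    n_signature_genes = as.integer(n_signature_genes),
    signature_shift = signature_shift, noise_sd = noise_sd,
    n_immunogenic_patients = as.integer(n_immunogenic_patients),
    protein_length_range = as.integer(rep_len(protein_length_range, 2L)),
    seed = as.integer(seed)
  )
  probs <- c(cfg$alteration_rate_background, cfg$alteration_rate_panel,
             cfg$prob_low_group)
  if (any(probs < 0 | probs > 1)) stopf("probabilities must lie in [0, 1]")
  if (cfg$n_patients < 8 || cfg$n_genes < 1 || cfg$n_panel_genes < 1 ||
      cfg$n_signature_genes < 0)
    stopf("counts must be positive (and n_patients >= 8)")
  if (cfg$n_panel_genes > cfg$n_genes) stopf("n_panel_genes must be <= n_genes")
  if (cfg$baseline_hazard <= 0 || cfg$censoring_rate < 0 ||
      cfg$followup_horizon <= 0)
    stopf("hazards must be positive (censoring may be zero)")
  if (cfg$noise_sd <= 0) stopf("noise_sd must be positive")
  if (cfg$protein_length_range[1] < 12 ||
      cfg$protein_length_range[1] > cfg$protein_length_range[2])
    stopf("protein_length_range must be increasing and >= 12 aa")

  # reject unfittable configurations: expected events per latent group
  horizon <- min(cfg$followup_horizon, 5)
  for (grp in 1:2) {
    n_g <- cfg$n_patients * c(cfg$prob_low_group, 1 - cfg$prob_low_group)[grp]
    mean_burden <- cfg$n_panel_genes * cfg$alteration_rate_panel[grp]
    center <- cfg$n_panel_genes *
      (cfg$prob_low_group * cfg$alteration_rate_panel[1] +
         (1 - cfg$prob_low_group) * cfg$alteration_rate_panel[2])
    hz <- cfg$baseline_hazard * exp(cfg$beta_per_alteration *
                                      (mean_burden - center))
    if (n_g * (1 - exp(-hz * horizon)) < 2)
      stopf("configuration expects < 2 events in a latent group; unfittable")
  }
  class(cfg) <- "simulation_config"
  cfg
}

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

COMMON_HLA_A <- c("HLA-A*01:01", "HLA-A*02:01", "HLA-A*03:01", "HLA-A*11:01",
                  "HLA-A*24:02", "HLA-A*26:01", "HLA-A*68:01", "HLA-A*31:01")

#' Simulate a cohort with planted prognostic structure
#'
#' Draws a complete cohort from the generating model described in
#' [simulation_config()]. Identical configurations (including the seed)
#' produce bit-identical bundles.
#'
#' @param config a `simulation_config`.
#' @return object of class `cohort_bundle`: list with `variants` (variant
#'   table), `lrr` (gene x patient matrix), `expression` (gene x patient
#'   linear-scale matrix including an `HLA-A` row), `clinical` (per-patient
#'   `sample_id`, `time`, `event`, `age`, `sex`, `smoking`, `histology`,
#'   `stage`), `hla` (`sample_id`, `allele_1`, `allele_2`), `proteome`
#'   (named character vector), `truth` (planted panel genes, signature
#'   genes, latent groups, true burden, immunogenic patients and planted
#'   binder peptides), and `config`.
#' @export
simulate_cohort <- function(config = simulation_config()) {
  if (!inherits(config, "simulation_config"))
    stopf("config must come from simulation_config()")
  cfg <- config
  set.seed(cfg$seed)

  patients <- sprintf("P%03d", seq_len(cfg$n_patients))
  genes <- sprintf("GENE%04d", seq_len(cfg$n_genes))
  panel <- genes[seq_len(cfg$n_panel_genes)]

  # latent alteration-rate group
  low_group <- stats::runif(cfg$n_patients) < cfg$prob_low_group
  rate_panel <- ifelse(low_group, cfg$alteration_rate_panel[1],
                       cfg$alteration_rate_panel[2])

  altered <- matrix(0L, cfg$n_patients, cfg$n_genes,
                    dimnames = list(patients, genes))
  for (j in seq_len(cfg$n_genes)) {
    pr <- if (genes[j] %in% panel) rate_panel
          else rep(cfg$alteration_rate_background, cfg$n_patients)
    altered[, j] <- as.integer(stats::runif(cfg$n_patients) < pr)
  }
  burden <- rowSums(altered[, panel, drop = FALSE])
  storage.mode(burden) <- "integer"

  # survival: exponential event and censoring times, administrative horizon
  center <- cfg$n_panel_genes *
    (cfg$prob_low_group * cfg$alteration_rate_panel[1] +
       (1 - cfg$prob_low_group) * cfg$alteration_rate_panel[2])
  hazard <- cfg$baseline_hazard *
    exp(cfg$beta_per_alteration * (burden - center))
  t_event <- stats::rexp(cfg$n_patients, rate = hazard)
  t_cens <- if (cfg$censoring_rate > 0)
    stats::rexp(cfg$n_patients, rate = cfg$censoring_rate)
  else rep(Inf, cfg$n_patients)
  t_obs <- pmin(t_event, t_cens, cfg$followup_horizon)
  event <- as.integer(t_event <= pmin(t_cens, cfg$followup_horizon))
  t_obs <- pmax(t_obs, 1 / 365) # guard against zero times

  clinical <- data.frame(
    sample_id = patients,
    time = t_obs,
    event = event,
    age = as.integer(round(stats::rnorm(cfg$n_patients, 67, 8))),
    sex = sample(c("F", "M"), cfg$n_patients, replace = TRUE),
    smoking = sample(c("smoker", "never"), cfg$n_patients, replace = TRUE,
                     prob = c(0.8, 0.2)),
    histology = sample(c("adeno", "squamous"), cfg$n_patients, replace = TRUE,
                       prob = c(0.6, 0.4)),
    stage = "I",
    stringsAsFactors = FALSE
  )

  # proteome: uniform random sequences
  plen <- sample(seq(cfg$protein_length_range[1], cfg$protein_length_range[2]),
                 cfg$n_genes, replace = TRUE)
  proteome <- vapply(plen, function(L)
    paste(sample(AA20, L, replace = TRUE), collapse = ""), character(1))
  names(proteome) <- genes

  # alteration mechanism: altered pairs carry a variant, a CNA, or both
  var_rows <- list()
  lrr <- matrix(stats::runif(cfg$n_genes * cfg$n_patients, -0.4, 0.4),
                nrow = cfg$n_genes, dimnames = list(genes, patients))
  for (i in seq_len(cfg$n_patients)) {
    js <- which(altered[i, ] == 1L)
    if (!length(js)) next
    mech <- sample(c("snv", "cna", "both"), length(js), replace = TRUE,
                   prob = c(0.55, 0.3, 0.15))
    for (kk in seq_along(js)) {
      j <- js[kk]
      if (mech[kk] %in% c("cna", "both")) {
        sgn <- sample(c(-1, 1), 1)
        lrr[j, i] <- sgn * stats::runif(1, 0.6, 2)
      }
      if (mech[kk] %in% c("snv", "both")) {
        pos <- sample.int(plen[j], 1)
        ref <- substr(proteome[[j]], pos, pos)
        alt <- sample(setdiff(AA20, ref), 1)
        var_rows[[length(var_rows) + 1L]] <- data.frame(
          sample_id = patients[i], gene = genes[j], protein_pos = pos,
          ref_aa = ref, alt_aa = alt,
          vaf = stats::rbeta(1, 5, 5), stringsAsFactors = FALSE)
      }
    }
  }
  variants <- if (length(var_rows)) do.call(rbind, var_rows) else
    data.frame(sample_id = character(), gene = character(),
               protein_pos = integer(), ref_aa = character(),
               alt_aa = character(), vaf = numeric())

  # expression: burden-quartile group drives the signature shift
  q1 <- quantile7(burden, 0.25)
  nag_latent <- ifelse(burden <= q1, "low", "high")
  sig_genes <- if (cfg$n_signature_genes > 0)
    sprintf("SIG%03d", seq_len(cfg$n_signature_genes)) else character()
  expr_genes <- c(genes, sig_genes, "HLA-A")
  mu <- stats::runif(length(expr_genes), 1.5, 4)
  names(mu) <- expr_genes
  expr_asinh <- matrix(
    stats::rnorm(length(expr_genes) * cfg$n_patients, mean = mu,
                 sd = cfg$noise_sd),
    nrow = length(expr_genes), dimnames = list(expr_genes, patients))
  if (length(sig_genes)) {
    expr_asinh[sig_genes, nag_latent == "high"] <-
      expr_asinh[sig_genes, nag_latent == "high"] + cfg$signature_shift
  }
  expression <- pmax(sinh(expr_asinh), 0)

  # HLA-A genotypes
  hla <- data.frame(
    sample_id = patients,
    allele_1 = sample(COMMON_HLA_A, cfg$n_patients, replace = TRUE),
    allele_2 = sample(COMMON_HLA_A, cfg$n_patients, replace = TRUE),
    stringsAsFactors = FALSE
  )

  # planted immunogenic patients: one guaranteed-binder peptide each,
  # with gene and HLA-A expression forced above cohort medians
  planted <- data.frame(sample_id = character(), gene = character(),
                        peptide = character(), stringsAsFactors = FALSE)
  immuno_patients <- character()
  if (cfg$n_immunogenic_patients > 0 && nrow(variants)) {
    eligible <- intersect(patients[nag_latent == "high"],
                          unique(variants$sample_id))
    pick <- utils::head(sample(eligible), cfg$n_immunogenic_patients)
    hi_expr <- sinh(max(mu) + 3 * cfg$noise_sd)
    for (pt in pick) {
      vs <- variants[variants$sample_id == pt, , drop = FALSE]
      v <- vs[sample.int(nrow(vs), 1), ]
      mut <- apply_missense(proteome[[v$gene]], v$protein_pos, v$ref_aa,
                            v$alt_aa)
      peps <- enumerate_peptides(mut, v$protein_pos, lengths = 9)
      if (!nrow(peps)) next
      planted <- rbind(planted, data.frame(
        sample_id = pt, gene = v$gene, peptide = peps$peptide[1],
        stringsAsFactors = FALSE))
      expression[v$gene, pt] <- hi_expr
      expression["HLA-A", pt] <- hi_expr
      immuno_patients <- c(immuno_patients, pt)
    }
  }

  bundle <- list(
    variants = variants, lrr = lrr, expression = expression,
    clinical = clinical, hla = hla, proteome = proteome,
    truth = list(panel_genes = panel, signature_genes = sig_genes,
                 latent_rate_group = stats::setNames(
                   ifelse(low_group, "low", "high"), patients),
                 nag_latent_group = stats::setNames(unname(nag_latent),
                                                    patients),
                 burden = stats::setNames(unname(burden), patients),
                 immunogenic_patients = immuno_patients,
                 planted_binders = planted),
    config = cfg
  )
  class(bundle) <- "cohort_bundle"
  bundle
}

#' @export
print.cohort_bundle <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d patients, %d alteration genes (%d planted panel genes)\n",
              nrow(x$clinical), nrow(x$lrr), length(x$truth$panel_genes)))
  cat(sprintf("  %d variants, %d expression genes, %d events (%.0f%%), %d planted immunogenic patients\n",
              nrow(x$variants), nrow(x$expression), sum(x$clinical$event),
              100 * mean(x$clinical$event),
              length(x$truth$immunogenic_patients)))
  invisible(x)
}
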