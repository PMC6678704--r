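# Neoantigen calling: mutant 8-11mer peptide enumeration from missense
# variants, HLA-A supertyping, binding-affinity prediction through a
# pluggable backend, and the three-condition immunogenicity rule:
#   (1) predicted IC50 strictly below 500 nM against BOTH HLA-A alleles
#       ("antigenic");
#   (2) the mutated gene expressed strictly above its cohort median;
#   (3) the patient's HLA-A gene expressed strictly above the cohort median.
# A patient with >= 1 immunogenic peptide is classified immunogenic.
# Expression for the median filters is on the raw (linear, RSEM-like)
# scale.

#' Apply a missense substitution to a protein sequence
#'
#' @param protein_seq amino-acid string.
#' @param protein_pos 1-based residue index.
#' @param ref_aa,alt_aa single-letter amino acids; the residue at
#'   `protein_pos` must equal `ref_aa` (guards against wrong isoforms).
#' @return mutated sequence, same length.
#' @export
apply_missense <- function(protein_seq, protein_pos, ref_aa, alt_aa) {
  n <- nchar(protein_seq)
  if (protein_pos < 1 || protein_pos > n)
    stopf("protein_pos %d outside sequence of length %d", protein_pos, n)
  at <- substr(protein_seq, protein_pos, protein_pos)
  if (at != ref_aa)
    stopf("reference mismatch at position %d: sequence has '%s', variant says '%s'",
          protein_pos, at, ref_aa)
  if (ref_aa == alt_aa) stopf("not a missense change: ref equals alt")
  substr(protein_seq, protein_pos, protein_pos) <- alt_aa
  protein_seq
}

#' Enumerate mutant peptides covering an altered residue
#'
#' All windows of each requested length that lie fully inside the mutated
#' sequence and span the altered position. Windows yielding identical
#' peptide strings are collapsed to one row; `starts` keeps the provenance
#' of every contributing window.
#'
#' @param mutated_seq mutated protein sequence.
#' @param protein_pos 1-based position of the altered residue.
#' @param lengths window lengths (default 8:11).
#' @return data frame with `peptide`, `length`, `start` (1-based first
#'   window start), `mutated_offset` (0-based index of the altered residue
#'   within the peptide), `protein_pos`, `starts` (comma-separated list of
#'   all window starts producing the peptide). Zero rows for proteins
#'   shorter than the minimum length.
#' @export
enumerate_peptides <- function(mutated_seq, protein_pos, lengths = 8:11) {
  P <- nchar(mutated_seq)
  if (protein_pos < 1 || protein_pos > P) stopf("position outside sequence")
  rows <- list()
  for (L in lengths) {
    s_min <- max(1L, protein_pos - L + 1L)
    s_max <- min(protein_pos, P - L + 1L)
    if (s_max < s_min) next
    starts <- s_min:s_max
    rows[[length(rows) + 1L]] <- data.frame(
      peptide = substring(mutated_seq, starts, starts + L - 1L),
      length = L,
      start = starts,
      mutated_offset = protein_pos - starts,
      protein_pos = protein_pos
    )
  }
  if (!length(rows)) {
    return(data.frame(peptide = character(), length = integer(),
                      start = integer(), mutated_offset = integer(),
                      protein_pos = integer(), starts = character()))
  }
  out <- do.call(rbind, rows)
  prov <- vapply(split(out$start, out$peptide),
                 function(s) paste(sort(s), collapse = ","), character(1))
  first <- !duplicated(out$peptide)
  out <- out[first, , drop = FALSE]
  out$starts <- unname(prov[out$peptide])
  rownames(out) <- NULL
  out
}

#' Closed-form count of mutation-covering windows
#'
#' For protein length `P` and altered position `p`, the number of windows of
#' each length L that fit inside the protein and cover position p is
#' `max(0, min(p, P - L + 1) - max(1, p - L + 1) + 1)`; the total sums over
#' the requested lengths. Counts windows, not distinct peptide strings.
#'
#' @param P protein length.
#' @param p 1-based altered position.
#' @param lengths window lengths (default 8:11).
#' @return integer window count.
#' @export
count_peptide_windows <- function(P, p, lengths = 8:11) {
  sum(pmax(0L, pmin(p, P - lengths + 1L) - pmax(1L, p - lengths + 1L) + 1L))
}

#' Default HLA-A supertype mapping
#'
#' Minimal table covering common HLA-A alleles, grouped into the standard
#' A01/A02/A03/A24 supertype categories; shipped as an editable TSV in
#' `inst/extdata/hla_supertypes.tsv` so users can substitute their own
#' mapping.
#'
#' @return data frame with columns `allele`, `supertype`.
#' @export
default_supertype_table <- function() {
  path <- system.file("extdata", "hla_supertypes.tsv", package = "nagburden")
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Map an HLA-A allele to its supertype
#'
#' @param allele 4-digit allele string, format `"HLA-A*02:01"`.
#' @param mapping_table data frame `allele`/`supertype`; defaults to the
#'   shipped table.
#' @return supertype label; `"unclassified"` (with a warning) for alleles
#'   absent from the table. Malformed allele strings are an error.
#' @export
supertype_allele <- function(allele, mapping_table = default_supertype_table()) {
  if (!grepl("^HLA-A\\*[0-9]{2}:[0-9]{2}$", allele))
    stopf("malformed HLA-A allele string: '%s' (expected e.g. HLA-A*02:01)",
          allele)
  hit <- match(allele, mapping_table$allele)
  if (is.na(hit)) {
    warnf("allele %s not in supertype table; returning 'unclassified'", allele)
    return("unclassified")
  }
  mapping_table$supertype[hit]
}

# ---- affinity backends ------------------------------------------------------

#' Precomputed-table affinity backend
#'
#' Wraps a table of externally predicted binding affinities (e.g. from an
#' MHC-binding predictor run outside this package).
#'
#' @param table data frame with columns `peptide`, `allele`, `ic50_nm`
#'   (positive), or a path to such a TSV.
#' @return object of class `affinity_table`.
#' @export
affinity_table <- function(table) {
  if (is.character(table)) table <- utils::read.delim(table, stringsAsFactors = FALSE)
  need <- c("peptide", "allele", "ic50_nm")
  if (!all(need %in% names(table))) stopf("affinity table needs columns %s",
                                          paste(need, collapse = ", "))
  if (any(table$ic50_nm <= 0)) stopf("ic50_nm must be positive")
  structure(list(table = table), class = "affinity_table")
}

#' Deterministic surrogate affinity backend
#'
#' A pure function of (peptide, allele) for dependency-free testing: each
#' pair hashes to an IC50 log-uniform in [600, 50000] nM, except peptides on
#' the planted strong-binder list, which always score `planted_ic50`
#' (default 50 nM, i.e. below the 500 nM antigenicity cutoff for every
#' allele). The surrogate carries no binding biology; it exists so that the
#' classification logic downstream of any affinity predictor can be tested
#' against known truth.
#'
#' @param planted_binders character vector of peptide strings to plant as
#'   strong binders.
#' @param planted_ic50 IC50 assigned to planted binders (default 50 nM).
#' @return object of class `affinity_surrogate`.
#' @export
affinity_surrogate <- function(planted_binders = character(), planted_ic50 = 50) {
  if (planted_ic50 <= 0) stopf("planted_ic50 must be positive")
  structure(list(planted = unique(planted_binders), planted_ic50 = planted_ic50),
            class = "affinity_surrogate")
}

#' Predict peptide-allele binding affinities
#'
#' Evaluates every peptide x allele combination through the chosen backend.
#'
#' @param backend an `affinity_table` or `affinity_surrogate`.
#' @param peptides character vector of peptides.
#' @param alleles character vector of allele strings.
#' @return data frame `peptide`, `allele`, `ic50_nm`, one row per
#'   combination. The table backend errors (listing the missing pairs) when
#'   a required pair is absent.
#' @export
predict_affinity <- function(backend, peptides, alleles) {
  UseMethod("predict_affinity")
}

#' @export
predict_affinity.affinity_table <- function(backend, peptides, alleles) {
  grid <- expand.grid(peptide = unique(peptides), allele = unique(alleles),
                      stringsAsFactors = FALSE)
  key <- paste(grid$peptide, grid$allele, sep = "|")
  tkey <- paste(backend$table$peptide, backend$table$allele, sep = "|")
  hit <- match(key, tkey)
  if (anyNA(hit))
    stopf("affinity table missing %d pair(s): %s", sum(is.na(hit)),
          paste(utils::head(key[is.na(hit)], 5), collapse = "; "))
  data.frame(peptide = grid$peptide, allele = grid$allele,
             ic50_nm = backend$table$ic50_nm[hit])
}

#' @export
predict_affinity.affinity_surrogate <- function(backend, peptides, alleles) {
  grid <- expand.grid(peptide = unique(peptides), allele = unique(alleles),
                      stringsAsFactors = FALSE)
  u <- string_hash01(paste(grid$peptide, grid$allele, sep = "|"))
  ic50 <- 10^(log10(600) + u * (log10(50000) - log10(600)))
  planted <- grid$peptide %in% backend$planted
  ic50[planted] <- backend$planted_ic50
  data.frame(peptide = grid$peptide, allele = grid$allele, ic50_nm = ic50)
}

# ---- immunogenicity logic ---------------------------------------------------

#' Dual-allele antigenicity call
#'
#' A peptide is antigenic when its predicted IC50 is strictly below the
#' threshold against both of the patient's HLA-A alleles (a single test for
#' homozygous patients). Exactly 500 nM is NOT antigenic.
#'
#' @param ic50_allele1,ic50_allele2 predicted affinities (nM) for the two
#'   alleles; must be present and positive.
#' @param threshold nM cutoff (default 500).
#' @return logical.
#' @export
call_antigenic <- function(ic50_allele1, ic50_allele2, threshold = 500) {
  if (anyNA(ic50_allele1) || anyNA(ic50_allele2))
    stopf("missing affinity prediction for at least one allele")
  ic50_allele1 < threshold & ic50_allele2 < threshold
}

#' Three-condition immunogenicity call for a peptide
#'
#' Antigenic (dual-allele affinity) AND source-gene expression strictly
#' above its cohort median AND patient HLA-A expression strictly above the
#' cohort HLA-A median. Values exactly at a median fail.
#'
#' @param antigenic logical from [call_antigenic()].
#' @param gene_expression patient's raw-scale expression of the mutated
#'   gene.
#' @param gene_median cohort median expression of that gene.
#' @param hla_expression patient's raw-scale HLA-A expression.
#' @param hla_median cohort median HLA-A expression.
#' @return logical.
#' @export
call_immunogenic <- function(antigenic, gene_expression, gene_median,
                             hla_expression, hla_median) {
  antigenic & gene_expression > gene_median & hla_expression > hla_median
}

#' Per-patient neoantigen calls from variants to immunogenicity
#'
#' Runs the full chain for each patient: apply each missense variant to its
#' protein, enumerate 8-11mer windows covering the altered residue, predict
#' affinity for both patient alleles through the backend, call antigenicity
#' (dual-allele, strict 500 nM by default) and immunogenicity (expression
#' medians on the raw scale), and aggregate per patient. Peptides arising
#' identically from different windows are deduplicated per (patient, gene,
#' peptide). Variants in genes absent from the expression matrix yield
#' non-immunogenic peptides with a warning; variants whose gene lacks a
#' protein sequence, or whose position falls outside it, are skipped with a
#' warning (wrong-isoform guard at the cohort level).
#'
#' @param variants variant table (`sample_id`, `gene`, `protein_pos`,
#'   `ref_aa`, `alt_aa`, `vaf`).
#' @param proteome named character vector, gene -> amino-acid sequence.
#' @param hla data frame `sample_id`, `allele_1`, `allele_2`.
#' @param expression raw-scale gene x sample matrix containing the mutated
#'   genes and an `HLA-A` row.
#' @param backend affinity backend (see [affinity_table()],
#'   [affinity_surrogate()]).
#' @param threshold antigenicity IC50 cutoff in nM (default 500).
#' @param hla_gene expression row used for the MHC-I expression condition
#'   (default `"HLA-A"`).
#' @return list with `peptides` (per-peptide call table) and `patients`
#'   (per-patient data frame: `sample_id`, `n_peptides`, `n_antigenic`,
#'   `n_immunogenic`, `is_immunogenic`). Patients in `hla` with no variants
#'   appear with zero counts.
#' @export
neoantigen_calls <- function(variants, proteome, hla, expression, backend,
                             threshold = 500, hla_gene = "HLA-A") {
  check_variants(variants)
  if (!(hla_gene %in% rownames(expression)))
    stopf("expression matrix lacks the '%s' row needed for the MHC-I condition",
          hla_gene)
  if (isTRUE(attr(expression, "transformed")))
    stopf("immunogenicity medians are defined on raw-scale expression")
  gene_median <- apply(expression, 1, stats::median)
  hla_median <- gene_median[[hla_gene]]

  pep_rows <- list()
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, ]
    sid <- as.character(v$sample_id)
    gene <- normalize_gene(v$gene)
    if (!(gene %in% names(proteome))) {
      warnf("no protein sequence for gene %s; variant skipped", gene)
      next
    }
    seq <- proteome[[gene]]
    if (v$protein_pos > nchar(seq)) {
      warnf("variant position %d beyond %s length %d; skipped",
            v$protein_pos, gene, nchar(seq))
      next
    }
    mut <- apply_missense(seq, v$protein_pos, v$ref_aa, v$alt_aa)
    windows <- enumerate_peptides(mut, v$protein_pos)
    if (!nrow(windows)) next
    windows$sample_id <- sid
    windows$gene <- gene
    windows$vaf <- v$vaf
    pep_rows[[length(pep_rows) + 1L]] <- windows
  }

  hrow <- match(hla_gene, rownames(expression))
  patients_all <- as.character(hla$sample_id)

  if (!length(pep_rows)) {
    peptides <- data.frame(sample_id = character(), gene = character(),
                           peptide = character(), vaf = numeric(),
                           ic50_allele1 = numeric(), ic50_allele2 = numeric(),
                           antigenic = logical(), immunogenic = logical())
  } else {
    peptides <- do.call(rbind, pep_rows)
    # deduplicate per (patient, gene, peptide)
    peptides <- peptides[!duplicated(peptides[c("sample_id", "gene", "peptide")]), ]
    rownames(peptides) <- NULL

    miss_hla <- setdiff(unique(peptides$sample_id), patients_all)
    if (length(miss_hla))
      stopf("no HLA genotype for sample(s): %s", paste(miss_hla, collapse = ", "))

    a1 <- hla$allele_1[match(peptides$sample_id, patients_all)]
    a2 <- hla$allele_2[match(peptides$sample_id, patients_all)]
    aff <- predict_affinity(backend, peptides$peptide, unique(c(a1, a2)))
    akey <- paste(aff$peptide, aff$allele, sep = "|")
    peptides$ic50_allele1 <- aff$ic50_nm[match(paste(peptides$peptide, a1, sep = "|"), akey)]
    peptides$ic50_allele2 <- aff$ic50_nm[match(paste(peptides$peptide, a2, sep = "|"), akey)]
    peptides$antigenic <- call_antigenic(peptides$ic50_allele1,
                                         peptides$ic50_allele2, threshold)

    expr_cols <- colnames(expression)
    grow <- match(peptides$gene, rownames(expression))
    pcol <- match(peptides$sample_id, expr_cols)
    if (anyNA(pcol))
      stopf("sample(s) absent from expression matrix: %s",
            paste(unique(peptides$sample_id[is.na(pcol)]), collapse = ", "))
    gene_absent <- is.na(grow)
    if (any(gene_absent))
      warnf("%d peptide(s) from gene(s) absent in expression matrix treated as non-immunogenic",
            sum(gene_absent))
    gexpr <- rep(NA_real_, nrow(peptides))
    gmed <- rep(NA_real_, nrow(peptides))
    ok <- !gene_absent
    gexpr[ok] <- expression[cbind(grow[ok], pcol[ok])]
    gmed[ok] <- gene_median[grow[ok]]
    hexpr <- expression[hrow, ][pcol]
    peptides$immunogenic <- ifelse(
      gene_absent, FALSE,
      call_immunogenic(peptides$antigenic, gexpr, gmed, hexpr, hla_median)
    )
  }

  counts <- function(sid, col) {
    if (!nrow(peptides)) return(rep(0L, length(sid)))
    tab <- tapply(peptides[[col]], peptides$sample_id, sum)
    out <- as.integer(tab[sid])
    out[is.na(out)] <- 0L
    out
  }
  patients <- data.frame(
    sample_id = patients_all,
    n_peptides = as.integer(table(factor(peptides$sample_id,
                                         levels = patients_all))),
    n_antigenic = counts(patients_all, "antigenic"),
    n_immunogenic = counts(patients_all, "immunogenic")
  )
  patients$is_immunogenic <- classify_patient(patients$n_immunogenic)
  list(peptides = peptides, patients = patients)
}

#' Patient-level immunogenicity classification
#'
#' A patient is immunogenic when carrying at least one immunogenic peptide.
#'
#' @param n_immunogenic per-patient immunogenic peptide counts.
#' @return logical vector.
#' @export
classify_patient <- function(n_immunogenic) {
  if (any(n_immunogenic < 0)) stopf("counts must be nonnegative")
  n_immunogenic >= 1
}

#' Three-group burden/immunogenicity stratification
#'
#' Splits patients into low-burden, high-burden non-immunogenic and
#' high-burden immunogenic groups. An immunogenic low-burden patient (a
#' combination absent from the cohorts this stratification was designed on)
#' is assigned `low_nag` with a warning.
#'
#' @param nag_labels factor/character in `c("low", "high")`.
#' @param immunogenic logical, aligned with `nag_labels`.
#' @return factor with levels `c("low_nag", "high_nag_nonimmunogenic",
#'   "high_nag_immunogenic")`.
#' @export
three_group_stratification <- function(nag_labels, immunogenic) {
  if (length(nag_labels) != length(immunogenic))
    stopf("label vectors have different lengths")
  odd <- nag_labels == "low" & immunogenic
  if (any(odd))
    warnf("%d immunogenic low-burden patient(s) assigned to low_nag", sum(odd))
  out <- ifelse(nag_labels == "low", "low_nag",
                ifelse(immunogenic, "high_nag_immunogenic",
                       "high_nag_nonimmunogenic"))
  factor(out, levels = c("low_nag", "high_nag_nonimmunogenic",
                         "high_nag_immunogenic"))
}

#' Compare variant allele fractions of immunogenic vs other mutations
#'
#' Two-sided Wilcoxon rank-sum test (normal approximation with tie
#' correction) of the VAF distributions, probing whether immunogenic
#' mutations look subclonal relative to the rest.
#'
#' @param vaf_immunogenic,vaf_other nonempty numeric VAF vectors.
#' @return list with `statistic` (rank-sum U of the first group), `p`.
#' @export
compare_vaf <- function(vaf_immunogenic, vaf_other) {
  if (!length(vaf_immunogenic) || !length(vaf_other))
    stopf("both VAF groups must be nonempty")
  wt <- stats::wilcox.test(vaf_immunogenic, vaf_other,
                           exact = FALSE, correct = FALSE)
  list(statistic = unname(wt$statistic), p = wt$p.value)
}
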