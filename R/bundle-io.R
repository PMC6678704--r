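# Cohort bundle serialization: plain-text files in the schemas the pipeline
# documents (MAF-like TSV, gene x sample TSV matrices, FASTA proteome, HLA
# TSV, JSON truth/config). Numeric values are written with 17 significant
# digits so a write/read round trip reproduces doubles exactly.

#' @keywords internal
#' @noRd
fmt_num <- function(x) {
  ifelse(is.finite(x) & x == round(x) & abs(x) < 2^31,
         format(x, scientific = FALSE, trim = TRUE),
         sprintf("%.17g", x))
}

#' @keywords internal
#' @noRd
write_matrix_tsv <- function(mat, path, first_col = "gene") {
  df <- data.frame(rownames(mat),
                   apply(mat, 2, fmt_num),
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- c(first_col, colnames(mat))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' @keywords internal
#' @noRd
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- df[[1]]
  mat
}

#' Write a cohort bundle to a directory of plain-text files
#'
#' Emits `variants.maf.tsv` (MAF-like: sample_id, gene, protein_pos,
#' ref_aa, alt_aa, vaf), `lrr.tsv` and `expression.tsv` (gene rows x sample
#' columns), `clinical.tsv`, `hla.tsv`, `proteome.fasta` and `truth.json`
#' (planted ground truth plus the generating configuration). A later
#' [read_bundle()] reproduces the bundle exactly.
#'
#' @param bundle a `cohort_bundle`.
#' @param directory output directory (created if missing).
#' @return invisibly, the vector of files written.
#' @export
write_bundle <- function(bundle, directory) {
  stopifnot(inherits(bundle, "cohort_bundle"))
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(directory, f)

  v <- bundle$variants
  v$vaf <- fmt_num(v$vaf)
  utils::write.table(v, p("variants.maf.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_matrix_tsv(bundle$lrr, p("lrr.tsv"))
  write_matrix_tsv(bundle$expression, p("expression.tsv"))
  cl <- bundle$clinical
  cl$time <- fmt_num(cl$time)
  utils::write.table(cl, p("clinical.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(bundle$hla, p("hla.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  seqinr::write.fasta(as.list(bundle$proteome),
                      names = names(bundle$proteome),
                      file.out = p("proteome.fasta"), as.string = TRUE,
                      nbchar = 60)
  truth <- bundle$truth
  truth$config <- unclass(bundle$config)
  if (is.infinite(truth$config$followup_horizon))
    truth$config$followup_horizon <- "Inf" # JSON has no Inf literal
  jsonlite::write_json(truth, p("truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(c("variants.maf.tsv", "lrr.tsv", "expression.tsv",
              "clinical.tsv", "hla.tsv", "proteome.fasta", "truth.json"))
}

#' Read a cohort bundle written by [write_bundle()]
#'
#' @param directory directory containing the bundle files.
#' @return a `cohort_bundle`.
#' @export
read_bundle <- function(directory) {
  p <- function(f) file.path(directory, f)
  for (f in c("variants.maf.tsv", "lrr.tsv", "expression.tsv",
              "clinical.tsv", "hla.tsv", "proteome.fasta", "truth.json")) {
    if (!file.exists(p(f))) stopf("bundle file missing: %s", f)
  }
  variants <- utils::read.delim(p("variants.maf.tsv"),
                                stringsAsFactors = FALSE,
                                colClasses = c(sample_id = "character",
                                               gene = "character",
                                               protein_pos = "integer",
                                               ref_aa = "character",
                                               alt_aa = "character",
                                               vaf = "numeric"))
  clinical <- utils::read.delim(p("clinical.tsv"), stringsAsFactors = FALSE,
                                colClasses = c(sample_id = "character"))
  hla <- utils::read.delim(p("hla.tsv"), stringsAsFactors = FALSE)
  fa <- seqinr::read.fasta(p("proteome.fasta"), seqtype = "AA",
                           as.string = TRUE, forceDNAtolower = FALSE)
  proteome <- vapply(fa, function(s) toupper(as.character(s)[1]), character(1))
  names(proteome) <- names(fa)
  tr <- jsonlite::read_json(p("truth.json"), simplifyVector = TRUE)
  config <- tr$config
  tr$config <- NULL
  tr$panel_genes <- as.character(tr$panel_genes)
  # JSON arrays drop vector names; patient order matches the clinical table
  tr$burden <- stats::setNames(as.integer(tr$burden), clinical$sample_id)
  tr$latent_rate_group <- stats::setNames(as.character(tr$latent_rate_group),
                                          clinical$sample_id)
  tr$nag_latent_group <- stats::setNames(as.character(tr$nag_latent_group),
                                         clinical$sample_id)
  tr$signature_genes <- as.character(tr$signature_genes)
  tr$immunogenic_patients <- as.character(tr$immunogenic_patients)
  tr$planted_binders <- as.data.frame(tr$planted_binders,
                                      stringsAsFactors = FALSE)
  if (!nrow(tr$planted_binders))
    tr$planted_binders <- data.frame(sample_id = character(),
                                     gene = character(),
                                     peptide = character(),
                                     stringsAsFactors = FALSE)
  cfg <- do.call(simulation_config, config[setdiff(names(config), NULL)])
  bundle <- list(
    variants = variants,
    lrr = read_matrix_tsv(p("lrr.tsv")),
    expression = read_matrix_tsv(p("expression.tsv")),
    clinical = clinical,
    hla = hla,
    proteome = proteome,
    truth = tr,
    config = cfg
  )
  class(bundle) <- "cohort_bundle"
  bundle
}
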