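test_that("missense application substitutes exactly one residue with guards", {
  expect_equal(apply_missense("MKT", 2, "K", "R"), "MRT")
  expect_error(apply_missense("MKT", 4, "K", "R"), "outside")
  expect_error(apply_missense("MKT", 2, "Q", "R"), "mismatch")
  expect_error(apply_missense("MKT", 2, "K", "K"), "missense")
})

test_that("peptide windows match the brute-force and closed-form counts", {
  long <- paste(rep("ACDEFGHIKLMNPQRSTVWY", 3), collapse = "")
  mid <- enumerate_peptides(long, 30)
  expect_equal(sum(as.integer(vapply(
    strsplit(mid$starts, ","), length, integer(1)))), 38) # interior: 8+9+10+11
  expect_true(all(nchar(mid$peptide) == mid$length))
  expect_true(all(substr(mid$peptide, mid$mutated_offset + 1,
                         mid$mutated_offset + 1) == substr(long, 30, 30)))

  edge <- enumerate_peptides(long, 1)
  expect_equal(nrow(edge), 4L) # one window per length at position 1
  expect_equal(nrow(enumerate_peptides("ACDEFGH", 3)), 0L) # protein shorter than 8

  # property: closed form == brute force for all P <= 40 and positions
  for (P in c(5, 8, 12, 21, 40)) {
    for (p in seq_len(P)) {
      expect_equal(count_peptide_windows(P, p), brute_force_windows(P, p))
    }
  }
})

test_that("supertype lookup resolves known alleles and flags the rest", {
  expect_equal(supertype_allele("HLA-A*02:01"), "A02")
  expect_equal(supertype_allele("HLA-A*24:02"), "A24")
  expect_warning(st <- supertype_allele("HLA-A*99:99"), "unclassified")
  expect_equal(st, "unclassified")
  expect_error(supertype_allele("A2"), "malformed")
})

test_that("surrogate backend is deterministic with planted binders below 500 nM", {
  bk <- affinity_surrogate(planted_binders = "SIINFEKLM")
  peps <- c("SIINFEKLM", "ACDEFGHIK", "LLLLLLLLL")
  al <- c("HLA-A*02:01", "HLA-A*01:01")
  a1 <- predict_affinity(bk, peps, al)
  a2 <- predict_affinity(bk, peps, al)
  expect_identical(a1, a2)
  expect_true(all(a1$ic50_nm[a1$peptide == "SIINFEKLM"] < 500))
  expect_true(all(a1$ic50_nm[a1$peptide != "SIINFEKLM"] >= 500))
  expect_true(all(a1$ic50_nm > 0))
})

test_that("table backend round-trips through TSV and reports missing pairs", {
  tab <- data.frame(peptide = c("AAA", "AAA", "BBB"),
                    allele = c("HLA-A*01:01", "HLA-A*02:01", "HLA-A*01:01"),
                    ic50_nm = c(100, 600, 50))
  bk <- affinity_table(tab)
  got <- predict_affinity(bk, "AAA", c("HLA-A*01:01", "HLA-A*02:01"))
  expect_equal(got$ic50_nm, c(100, 600))

  f <- tempfile(fileext = ".tsv")
  utils::write.table(tab, f, sep = "\t", quote = FALSE, row.names = FALSE)
  got2 <- predict_affinity(affinity_table(f), "AAA",
                           c("HLA-A*01:01", "HLA-A*02:01"))
  expect_equal(got2, got)

  expect_error(predict_affinity(bk, "BBB", c("HLA-A*01:01", "HLA-A*02:01")),
               "missing")
})

test_that("antigenicity needs strict sub-500 nM affinity on both alleles", {
  expect_true(call_antigenic(100, 450))
  expect_false(call_antigenic(100, 501))
  expect_false(call_antigenic(500, 500)) # boundary: strict inequality
  expect_false(call_antigenic(499.9999, 500))
  expect_true(call_antigenic(499.9999, 499.9999))
  expect_error(call_antigenic(NA, 100), "missing")
})

test_that("immunogenicity is the strict three-condition conjunction", {
  # exhaustive truth table over the three binary conditions
  for (ant in c(TRUE, FALSE)) {
    for (gene_hi in c(TRUE, FALSE)) {
      for (hla_hi in c(TRUE, FALSE)) {
        got <- call_immunogenic(ant,
                                gene_expression = ifelse(gene_hi, 10, 2),
                                gene_median = 5,
                                hla_expression = ifelse(hla_hi, 20, 1),
                                hla_median = 8)
        expect_equal(got, ant && gene_hi && hla_hi)
      }
    }
  }
  # values exactly at the median fail (strict inequality)
  expect_false(call_immunogenic(TRUE, 5, 5, 20, 8))
  expect_false(call_immunogenic(TRUE, 10, 5, 8, 8))
})

test_that("patient classification triggers at one immunogenic peptide", {
  expect_equal(classify_patient(c(0, 1, 12)), c(FALSE, TRUE, TRUE))
  expect_error(classify_patient(-1), "nonnegative")
})

test_that("three-group stratification follows burden and immunogenicity", {
  nag <- c("high", "high", "low")
  imm <- c(TRUE, FALSE, FALSE)
  out <- three_group_stratification(nag, imm)
  expect_equal(as.character(out),
               c("high_nag_immunogenic", "high_nag_nonimmunogenic", "low_nag"))
  expect_warning(odd <- three_group_stratification("low", TRUE), "low_nag")
  expect_equal(as.character(odd), "low_nag")
})

test_that("VAF comparison is a two-sided rank-sum with symmetric labels", {
  # maximal separation: U equals n1 * n2 = 9
  res <- compare_vaf(c(0.9, 0.8, 0.85), c(0.1, 0.05, 0.12))
  expect_equal(res$statistic, 9)
  # identical sets sit at the null center with p = 1
  expect_equal(compare_vaf(c(0.2, 0.4, 0.6), c(0.2, 0.4, 0.6))$p, 1)
  # swapping groups complements the statistic, keeps p
  a <- c(0.3, 0.5, 0.7, 0.2); b <- c(0.4, 0.6, 0.1)
  r1 <- compare_vaf(a, b); r2 <- compare_vaf(b, a)
  expect_equal(r1$statistic + r2$statistic, length(a) * length(b))
  expect_equal(r1$p, r2$p)
  expect_error(compare_vaf(numeric(0), a), "nonempty")
})

test_that("cohort-level neoantigen calls respect planted truth and monotonicity", {
  b <- simulate_cohort(small_config(seed = 21))
  backend <- affinity_surrogate(b$truth$planted_binders$peptide)
  calls <- suppressWarnings(neoantigen_calls(
    b$variants, b$proteome, b$hla, b$expression, backend))
  pats <- calls$patients
  expect_true(all(pats$n_immunogenic <= pats$n_antigenic))
  planted <- b$truth$immunogenic_patients
  expect_true(all(planted %in% pats$sample_id[pats$is_immunogenic]))

  # restricting variants never increases any immunogenic count
  sub <- b$variants[b$variants$gene %in% unique(b$variants$gene)[1:10], ]
  calls_sub <- suppressWarnings(neoantigen_calls(
    sub, b$proteome, b$hla, b$expression, backend))
  m <- match(calls_sub$patients$sample_id, pats$sample_id)
  expect_true(all(calls_sub$patients$n_immunogenic <= pats$n_immunogenic[m]))

  # immunogenicity monotone nonincreasing in the affinity threshold
  strict <- suppressWarnings(neoantigen_calls(
    b$variants, b$proteome, b$hla, b$expression, backend, threshold = 100))
  expect_true(all(strict$patients$n_immunogenic <= pats$n_immunogenic))
})
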