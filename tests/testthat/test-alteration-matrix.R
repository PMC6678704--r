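test_that("copy-number states follow the strict +/-0.5 LRR cuts", {
  expect_equal(call_copy_number_state(c(0.6, 0, -0.5, 0.5, -0.9, -0.51)),
               c("gain", "neutral", "neutral", "neutral", "loss", "loss"))
  expect_error(call_copy_number_state(NaN), "finite")
  expect_error(call_copy_number_state(Inf), "finite")
})

make_variants <- function(sample_id, gene, pos = 5, ref = "A", alt = "V",
                          vaf = 0.5) {
  data.frame(sample_id = sample_id, gene = gene, protein_pos = pos,
             ref_aa = ref, alt_aa = alt, vaf = vaf,
             stringsAsFactors = FALSE)
}

test_that("alteration matrix combines variants and CNA as a binary OR", {
  lrr <- matrix(c(0, -0.9, 0.2, 0.1), nrow = 2,
                dimnames = list(c("G1", "G2"), c("P1", "P2")))
  v <- make_variants(c("P1", "P2", "P2", "P2"), c("G1", "G3", "G3", "G3"))
  m <- build_alteration_matrix(v, lrr, gene_universe = c("G1", "G2", "G3", "G4"))

  expect_equal(dim(m), c(2, 4))
  expect_equal(m["P1", "G1"], 1L) # variant, neutral LRR
  expect_equal(m["P1", "G2"], 1L) # no variant, LRR -0.9 = loss
  expect_equal(m["P2", "G3"], 1L) # three variants still binary 1
  expect_equal(m["P2", "G2"], 0L)
  expect_equal(unname(m[, "G4"]), c(0L, 0L)) # gene absent from both inputs
  expect_true(all(m %in% 0:1))
})

test_that("unknown variant samples are rejected with the offending id", {
  v <- make_variants("P9", "G1")
  expect_error(
    build_alteration_matrix(v, NULL, gene_universe = "G1",
                            samples = c("P1", "P2")),
    "P9")
})

test_that("matrix construction matches a naive double-loop oracle", {
  set.seed(11)
  samples <- sprintf("S%02d", 1:10)
  genes <- sprintf("G%02d", 1:20)
  for (rep in 1:3) {
    lrr <- matrix(rnorm(200, sd = 0.6), nrow = 20,
                  dimnames = list(genes, samples))
    nv <- 25
    v <- make_variants(sample(samples, nv, TRUE), sample(genes, nv, TRUE))
    m <- build_alteration_matrix(v, lrr, gene_universe = genes)

    oracle <- matrix(0L, 10, 20, dimnames = list(samples, genes))
    for (s in samples) {
      for (g in genes) {
        has_var <- any(v$sample_id == s & v$gene == g)
        cna <- lrr[g, s] > 0.5 || lrr[g, s] < -0.5
        oracle[s, g] <- as.integer(has_var || cna)
      }
    }
    expect_equal(unclass(m)[samples, genes], oracle)
  }
})

test_that("recurrence filter keeps genes altered in >= min_patients and is idempotent", {
  m <- build_alteration_matrix(
    make_variants(c("P1", "P1", "P2"), c("G1", "G2", "G2")), NULL,
    gene_universe = c("G1", "G2", "G3"), samples = c("P1", "P2", "P3"))
  f <- filter_recurrent_genes(m)
  expect_equal(colnames(f), "G2")          # G1 in one patient dropped
  expect_equal(colnames(filter_recurrent_genes(f)), "G2") # idempotent
  zero <- m; zero[] <- 0L
  expect_equal(ncol(filter_recurrent_genes(zero)), 0L)
})

test_that("NAG scores count altered panel genes and grow by exactly one per added alteration", {
  m <- matrix(c(1L, 0L, 1L, 1L, 0L, 0L, 1L, 0L, 1L, 0L),
              nrow = 2, dimnames = list(c("P1", "P2"), paste0("G", 1:5)))
  class(m) <- c("alteration_matrix", "matrix", "array")
  s <- nag_score(m, paste0("G", 1:5))
  expect_equal(unname(s["P1"]), sum(m["P1", ]))
  expect_error(nag_score(m, c("ZZ1", "ZZ2")), "disjoint")
  expect_message(nag_score(m, c("G1", "G2", "ZZ1")), "absent")

  # incremental oracle: flipping any single 0 in a panel gene adds 1
  set.seed(3)
  panel <- paste0("G", 1:3)
  for (k in 1:5) {
    i <- sample(1:2, 1); j <- sample(panel, 1)
    m2 <- m; m2[i, j] <- 1L
    expected <- unname(nag_score(m, panel)[i]) + as.integer(m[i, j] == 0L)
    expect_equal(unname(nag_score(m2, panel)[i]), expected)
  }
})

test_that("monotonicity: adding alterations never decreases any NAG score", {
  set.seed(5)
  m <- matrix(rbinom(60, 1, 0.3), nrow = 6,
              dimnames = list(paste0("P", 1:6), paste0("G", 1:10)))
  class(m) <- c("alteration_matrix", "matrix", "array")
  panel <- paste0("G", 1:6)
  base <- nag_score(m, panel)
  zeros <- which(m == 0L)
  for (idx in sample(zeros, 10)) {
    m2 <- m; m2[idx] <- 1L
    expect_true(all(nag_score(m2, panel) >= base))
  }
})

test_that("quartile dichotomization puts ties in 'low' and absolute cutoffs in 'high'", {
  s <- stats::setNames(1:8, paste0("P", 1:8))
  lab <- dichotomize_scores(s)
  expect_equal(attr(lab, "cutoff"), 2.75) # type-7 Q1 of 1..8
  expect_equal(sum(lab == "low"), 2L)

  # score exactly at Q1 goes low
  s2 <- c(2, 2, 2, 10, 11, 12, 13, 14)
  lab2 <- dichotomize_scores(s2)
  expect_true(all(lab2[s2 == 2] == "low"))

  # absolute threshold: >= 87 is high
  lab3 <- dichotomize_scores(c(86, 87, 88), threshold = 87)
  expect_equal(as.character(lab3), c("low", "high", "high"))

  expect_error(dichotomize_scores(rep(4, 10)), "constant")
  expect_error(dichotomize_scores(c(1, 2, 3)), ">= 4")
})
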