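test_that("asinh transform matches its closed form and refuses double application", {
  m <- matrix(c(0, 1, 10, 100), 2, 2)
  t1 <- asinh_transform(m)
  expect_equal(t1[1, 1], 0)
  expect_equal(t1[2, 2], log(100 + sqrt(100^2 + 1)))
  expect_equal(t1[1, 2], log(10 + sqrt(101)), tolerance = 1e-12)
  expect_true(all(diff(asinh(c(0, 0.5, 1, 5, 50))) > 0)) # monotone
  expect_error(asinh_transform(t1), "already")
  expect_error(asinh_transform(matrix(-1)), "nonnegative")
})

de_fixture <- function(seed = 2) {
  set.seed(seed)
  n <- 20
  g <- rep(c("A", "B"), each = n)
  # gene1: linear means 30 vs 10 (FC 3), tight noise on asinh scale
  # gene2: FC 1.5 only; gene3: null
  e <- rbind(
    gene1 = sinh(asinh(ifelse(g == "A", 30, 10)) + rnorm(2 * n, sd = 0.05)),
    gene2 = sinh(asinh(ifelse(g == "A", 15, 10)) + rnorm(2 * n, sd = 0.05)),
    gene3 = sinh(asinh(10) + rnorm(2 * n, sd = 0.05))
  )
  colnames(e) <- paste0("S", seq_len(2 * n))
  list(expr = pmax(e, 0), group = g)
}

test_that("differential expression applies the dual fold-change/p-value filter", {
  fx <- de_fixture()
  de <- differential_expression(fx$expr, fx$group)
  expect_true("gene1" %in% de$gene)          # FC = 3, clean separation
  expect_false("gene2" %in% de$gene)         # FC 1.5 below threshold
  expect_false("gene3" %in% de$gene)         # no signal
  expect_gt(de$abs_fold_change[de$gene == "gene1"], 2)

  # identical groups: nothing passes
  e0 <- fx$expr[, 1:20]
  expect_equal(nrow(differential_expression(cbind(e0, e0),
                                            rep(c("A", "B"), each = 20))), 0L)
})

test_that("DE gene list is symmetric under group-label swap", {
  fx <- de_fixture(seed = 4)
  d1 <- differential_expression(fx$expr, fx$group)
  d2 <- differential_expression(fx$expr, ifelse(fx$group == "A", "B", "A"))
  expect_setequal(d1$gene, d2$gene)
  expect_equal(d1$fold_change[order(d1$gene)],
               1 / d2$fold_change[order(d2$gene)], tolerance = 1e-12)
})

test_that("degenerate zero-variance equal-mean genes are skipped with a warning", {
  e <- rbind(flat = rep(5, 8), ok = c(1, 2, 1, 2, 30, 31, 30, 31))
  colnames(e) <- paste0("S", 1:8)
  expect_warning(de <- differential_expression(e, rep(c("A", "B"), each = 4)),
                 "zero variance")
  expect_false("flat" %in% de$gene)
})

test_that("expression risk score is the linear predictor of the signature", {
  e <- matrix(c(1, 4, 9, 16, 25, 36), nrow = 3,
              dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
  tr <- asinh_transform(e)

  one <- expression_risk_score(tr, c(g2 = 1))
  expect_equal(unname(one), unname(tr["g2", ])) # identity

  cf <- c(g1 = 0.5, g3 = -2)
  sc <- expression_risk_score(tr, cf)
  expect_equal(unname(sc), unname(0.5 * tr["g1", ] - 2 * tr["g3", ]))
  expect_equal(unname(expression_risk_score(tr, 2 * cf)), unname(2 * sc)) # linear

  expect_equal(unname(expression_risk_score(tr, c(g1 = 0, g2 = 0))),
               c(0, 0))
  # missing genes contribute zero without disturbing present ones
  expect_message(sc2 <- expression_risk_score(tr, c(cf, NOPE = 3)), "absent")
  expect_equal(unname(sc2), unname(sc))
  expect_error(expression_risk_score(tr, numeric(0)), "empty")
})

test_that("risk-score thresholding uses >= cutoff as high-risk and Q3 by default", {
  sc <- c(a = 0.16, b = 0.17, c = 0.5)
  lab <- threshold_risk_score(sc, cutoff = 0.17)
  expect_equal(as.character(lab), c("low_risk_expr", "high_risk_expr",
                                    "high_risk_expr"))
  q3 <- threshold_risk_score(c(0, 0, 0, 1))
  expect_equal(sum(q3 == "high_risk_expr"), 1L) # type-7 Q3 = 0.25
  expect_error(threshold_risk_score(rep(1, 4)), "constant")
})

test_that("combined classifier is the high-NAG OR low-risk disjunction", {
  nag <- c("high", "low", "low", "high")
  expr <- c("high_risk_expr", "low_risk_expr", "high_risk_expr",
            "low_risk_expr")
  out <- combined_classifier(nag, expr)
  expect_equal(as.character(out), c("better", "better", "worse", "better"))
  expect_error(combined_classifier(c("high", NA), rep("low_risk_expr", 2)),
               "missing")
  expect_error(combined_classifier("high", rep("low_risk_expr", 2)),
               "length")
})
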