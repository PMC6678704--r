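test_that("the path starts at the all-zero solution with a nondecreasing deviance ratio", {
  pr <- encox_problem(n = 60, p = 10, seed = 1,
                      beta = c(-1, 0.8, rep(0, 8)))
  fit <- encox(pr$x, pr$time, pr$event, alpha = 0.1)
  expect_true(all(fit$beta[, 1] == 0))
  expect_equal(fit$df[1], 0)
  expect_true(all(diff(fit$dev.ratio) > -1e-8))
  expect_true(all(diff(fit$lambda) < 0))

  # lambda above lambda_max still gives the zero solution
  hi <- encox(pr$x, pr$time, pr$event, alpha = 0.1,
              lambda = fit$lambda[1] * c(10, 2))
  expect_true(all(hi$beta == 0))
})

test_that("KKT conditions hold along the path at 1e-6", {
  for (seed in 1:2) {
    pr <- encox_problem(n = 30, p = 50, seed = seed)
    fit <- encox(pr$x, pr$time, pr$event, alpha = 0.1)
    kkt <- check_kkt(fit, pr$x, pr$time, pr$event, tol = 1e-6)
    expect_true(kkt$ok)
  }
})

test_that("a single-covariate fit at vanishing lambda matches the Newton-Raphson Cox oracle", {
  pr <- encox_problem(n = 80, p = 3, seed = 7)
  x1 <- matrix(as.numeric(pr$x[, 1] > 0), ncol = 1,
               dimnames = list(NULL, "b"))
  fit <- encox(x1, pr$time, pr$event, alpha = 0.1,
               lambda = c(1e-1, 1e-4, 1e-9))
  oracle <- cox_fit(data.frame(time = pr$time, event = pr$event,
                               b = x1[, 1]), "b")
  expect_equal(unname(fit$beta[1, 3]), oracle$table$coef, tolerance = 1e-4)
})

test_that("the solution path matches an independent penalized-Cox implementation", {
  skip_if_not_installed("glmnet")
  pr <- encox_problem(n = 60, p = 10, seed = 1,
                      beta = c(-1, 0.8, rep(0, 8)))
  fit <- encox(pr$x, pr$time, pr$event, alpha = 0.1)
  g <- glmnet::glmnet(pr$x, survival::Surv(pr$time, pr$event),
                      family = "cox", alpha = 0.1, lambda = fit$lambda,
                      standardize = TRUE, thresh = 1e-12)
  expect_lt(max(abs(fit$beta - as.matrix(g$beta))), 1e-4)
  expect_lt(max(abs(fit$dev.ratio - g$dev.ratio)), 1e-5)
})

test_that("warm-start path equals cold-start solutions at each lambda", {
  pr <- encox_problem(n = 50, p = 12, seed = 3,
                      beta = c(0.7, -0.7, rep(0, 10)))
  fit <- encox(pr$x, pr$time, pr$event, alpha = 0.1, nlambda = 30)
  for (k in c(5, 15, 30)) {
    cold <- encox(pr$x, pr$time, pr$event, alpha = 0.1,
                  lambda = fit$lambda[k])
    expect_lt(max(abs(cold$beta[, 1] - fit$beta[, k])), 1e-6)
  }
})

test_that("alpha interpolates between lasso sparsity and ridge shrinkage", {
  pr <- encox_problem(n = 60, p = 15, seed = 5,
                      beta = c(1, -1, rep(0, 13)))
  lam <- 0.05
  lasso <- encox(pr$x, pr$time, pr$event, alpha = 1, lambda = c(1, lam))
  ridge <- encox(pr$x, pr$time, pr$event, alpha = 0, lambda = c(1, lam))
  mix <- encox(pr$x, pr$time, pr$event, alpha = 0.1, lambda = c(1, lam))
  expect_true(any(lasso$beta[, 2] == 0))         # exact zeros under L1
  expect_true(all(ridge$beta[, 2] != 0))         # ridge never zeros exactly
  expect_lte(sum(lasso$beta[, 2] != 0), sum(mix$beta[, 2] != 0))

  skip_if_not_installed("glmnet")
  gl <- glmnet::glmnet(pr$x, survival::Surv(pr$time, pr$event),
                       family = "cox", alpha = 1, lambda = c(1, lam),
                       standardize = TRUE, thresh = 1e-12)
  expect_lt(max(abs(lasso$beta[, 2] - as.matrix(gl$beta)[, 2])), 1e-4)
})

test_that("standardize-then-backtransform equals a direct fit on pre-standardized data", {
  pr <- encox_problem(n = 50, p = 8, seed = 9,
                      beta = c(0.8, rep(0, 7)))
  x <- sweep(pr$x, 2, colMeans(pr$x))
  x <- sweep(x, 2, sqrt(colMeans(x^2)), "/")
  raw <- encox(pr$x, pr$time, pr$event, alpha = 0.1, nlambda = 20)
  std <- encox(x, pr$time, pr$event, alpha = 0.1, lambda = raw$lambda)
  sds <- sqrt(colMeans(sweep(pr$x, 2, colMeans(pr$x))^2))
  expect_lt(max(abs(raw$beta * sds - std$beta)), 1e-6)
})

test_that("deviance-ratio selection maximizes, breaks ties to the sparser model, and recomputes", {
  pr <- encox_problem(n = 60, p = 10, seed = 1,
                      beta = c(-1, 0.8, rep(0, 8)))
  fit <- select_by_deviance_ratio(encox(pr$x, pr$time, pr$event, alpha = 0.1))
  # monotone path: maximum sits at the smallest lambda
  expect_equal(attr(fit, "selected_index"), length(fit$lambda))

  # tie rule: equal deviance ratios resolve to the larger lambda
  flat <- fit
  flat$dev.ratio <- rep(0.3, length(fit$lambda))
  flat <- select_by_deviance_ratio(flat)
  expect_equal(attr(flat, "selected_index"), 1L)

  # stored deviance ratio equals a recomputation from the coefficients
  # through an independent Breslow partial-likelihood implementation
  k <- attr(fit, "selected_index")
  eta <- drop(pr$x %*% fit$beta[, k])
  ll <- breslow_loglik(pr$time, pr$event, eta - mean(eta))
  ll0 <- breslow_loglik(pr$time, pr$event, rep(0, length(pr$time)))
  expect_equal(1 - ll / ll0, fit$dev.ratio[k], tolerance = 1e-8)
})

test_that("a planted protective feature is selected with a negative coefficient", {
  set.seed(31)
  n <- 200; p <- 20
  x <- matrix(rbinom(n * p, 1, 0.3), n, p,
              dimnames = list(NULL, paste0("g", 1:p)))
  eta <- -1 * x[, 1]
  t_ev <- rexp(n, 0.3 * exp(eta)); t_ce <- rexp(n, 0.1)
  fit <- select_by_deviance_ratio(
    encox(x, pmin(t_ev, t_ce), as.integer(t_ev <= t_ce), alpha = 0.1))
  panel <- extract_panel(fit)
  expect_true("g1" %in% names(panel))
  expect_lt(panel[["g1"]], 0)
  expect_equal(length(panel), sum(fit$beta[, attr(fit, "selected_index")] != 0))
})

test_that("degenerate inputs are rejected and zero-variance features dropped", {
  pr <- encox_problem(n = 30, p = 4, seed = 2)
  expect_error(encox(pr$x, pr$time, rep(0, 30)), "2 events")
  xx <- pr$x; xx[1, 1] <- Inf
  expect_error(encox(xx, pr$time, pr$event), "finite")
  xc <- pr$x; xc[, 2] <- 7
  expect_warning(fit <- encox(xc, pr$time, pr$event, nlambda = 10),
                 "zero-variance")
  expect_true(all(fit$beta[2, ] == 0))

  # all-zero selected solution gives an empty panel
  f0 <- encox(pr$x, pr$time, pr$event, lambda = 10)
  expect_length(extract_panel(f0), 0)
})

test_that("predict and coef agree on the linear predictor scale", {
  pr <- encox_problem(n = 50, p = 6, seed = 4, beta = c(1, rep(0, 5)))
  fit <- select_by_deviance_ratio(encox(pr$x, pr$time, pr$event))
  cf <- coef(fit)
  eta <- predict(fit, pr$x)
  expect_equal(eta, drop(pr$x %*% cf))
  expect_equal(predict(fit, pr$x, type = "response"), exp(eta))
})
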