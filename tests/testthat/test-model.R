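test_that("penalties at or above lambda_max zero every slope coefficient", {
  sim <- logistic_sim(200, 6, beta = c(1.5, -1, 0.5), seed = 5)
  lmax <- lambda_max(sim$X, sim$y)
  for (lam in c(lmax, 1.5 * lmax)) {
    fit <- fit_lasso(sim$X, sim$y, lam)
    expect_equal(unname(fit$beta), rep(0, 6))
    expect_equal(fit$beta0, stats::qlogis(mean(sim$y)), tolerance = 1e-6)
  }
  # just below lambda_max, at least one coefficient activates
  fit2 <- fit_lasso(sim$X, sim$y, 0.95 * lmax)
  expect_gt(sum(fit2$beta != 0), 0)
})

test_that("the unpenalized fit matches the Newton-Raphson (glm) oracle", {
  sim <- logistic_sim(80, 1, beta = 1, seed = 6)
  df <- data.frame(x = sim$X[, 1], y = sim$y)
  oracle <- stats::glm(y ~ x, data = df, family = stats::binomial())
  fit <- fit_lasso(sim$X, sim$y, lambda = 0, tol = 1e-10)
  # compare on the original scale through fitted probabilities
  Xs <- scale(sim$X, center = fit$center, scale = fit$scale)
  p_mine <- stats::plogis(fit$beta0 + drop(Xs %*% fit$beta))
  expect_equal(p_mine, unname(stats::fitted(oracle)), tolerance = 1e-6)
})

test_that("the penalized objective is non-increasing across IRLS iterations", {
  sim <- logistic_sim(150, 5, beta = c(1, -1), seed = 7)
  fit <- fit_lasso(sim$X, sim$y, lambda = 0.02)
  expect_true(all(diff(fit$objective) <= 1e-8))
})

test_that("coordinate descent agrees with the glmnet oracle along the path", {
  skip_if_not_installed("glmnet")
  sim <- logistic_sim(300, 8, beta = c(1.2, -0.8, 0.6), seed = 8)
  lams <- c(0.05, 0.02, 0.005)
  gfit <- glmnet::glmnet(
    sim$X, sim$y,
    family = "binomial", lambda = lams,
    standardize = TRUE, thresh = 1e-12
  )
  for (i in seq_along(lams)) {
    mine <- fit_lasso(sim$X, sim$y, lams[i], tol = 1e-9)
    # convert standardized-scale coefficients to the original scale
    b_orig <- mine$beta / mine$scale
    b0_orig <- mine$beta0 - sum(mine$beta * mine$center / mine$scale)
    expect_equal(
      unname(b_orig), as.numeric(gfit$beta[, i]),
      tolerance = 2e-3, info = paste("lambda", lams[i])
    )
    expect_equal(b0_orig, gfit$a0[[i]], tolerance = 2e-3)
  }
})

test_that("cross-validation is deterministic, stratified and beats the null model", {
  sim <- logistic_sim(300, 6, beta = c(1.5, -1.2, 0.8), seed = 9)
  cv1 <- cross_validate(sim$X, sim$y, k_folds = 5, seed = 123)
  cv2 <- cross_validate(sim$X, sim$y, k_folds = 5, seed = 123)
  expect_identical(cv1, cv2)
  # every fold contains both classes (stratification)
  for (f in unique(cv1$folds)) {
    expect_equal(sort(unique(sim$y[cv1$folds == f])), c(0, 1))
  }
  # grid of one lambda -> one deviance entry
  one <- cross_validate(sim$X, sim$y, lambdas = 0.01, k_folds = 5, seed = 1)
  expect_length(one$cvm, 1L)
  # nested-model sanity: selected model no worse than intercept-only on
  # the same folds
  null_dev <- mean(vapply(seq_len(max(cv1$folds)), function(f) {
    p0 <- mean(sim$y[cv1$folds != f])
    splicescreen:::binomial_deviance(
      sim$y[cv1$folds == f], rep(p0, sum(cv1$folds == f))
    )
  }, numeric(1)))
  expect_lte(min(cv1$cvm), null_dev)
  expect_error(
    cross_validate(sim$X[1:3, ], c(1, 1, 1)),
    "each class"
  )
})

test_that("lambda selection takes the deviance argmin, ties to the sparser model", {
  mk <- function(cvm) {
    structure(
      list(lambda = exp(seq(0, -4, length.out = length(cvm))), cvm = cvm),
      class = "cv_lasso"
    )
  }
  dec <- mk(seq(2, 1, length.out = 10))
  expect_equal(select_lambda(dec), min(dec$lambda))
  flat <- mk(rep(1.5, 10))
  expect_equal(select_lambda(flat), max(flat$lambda))
  uni <- mk(c(2, 1.5, 1.2, 1.05, 1.0, 1.1, 1.4, 1.9))
  # brute-force scan oracle over the stored grid
  expect_equal(select_lambda(uni), uni$lambda[which.min(uni$cvm)])
})

test_that("scores are the logistic transform of the standardized predictor", {
  reg <- c("f1", "f2", "f3")
  fit <- list(
    beta0 = 0, beta = c(0, 0, 0), center = rep(0, 3), scale = rep(1, 3),
    lambda = 0.1, objective = 0, n_iter = 1
  )
  m0 <- new_splice_lasso(fit, reg, 0.5, "5ss")
  expect_equal(
    predict_score(m0, tibble::tibble(f1 = 0, f2 = 0, f3 = 0)), 0.5
  )
  fit$beta <- c(1, -2, 0.3)
  fit$beta0 <- 0.5
  m <- new_splice_lasso(fit, reg, 0.5, "5ss")
  # pocket-calculator predictor: 0.5 + 0.2 - 0.2 - 0.3 = 0.2
  expect_equal(
    predict_score(m, tibble::tibble(f1 = 0.2, f2 = 0.1, f3 = -1)),
    stats::plogis(0.2),
    tolerance = 1e-12
  )
  # extreme negative predictor drives the score toward 0
  expect_lt(
    predict_score(m, tibble::tibble(f1 = -50, f2 = 50, f3 = 0)), 1e-10
  )
  expect_error(
    predict_score(m, tibble::tibble(f1 = 1, f2 = 2)), "f3"
  )
})

test_that("cutoff selection maximizes Youden's J over score midpoints", {
  expect_equal(
    select_cutoff(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 0.5
  )
  # duplicated points leave the optimum unchanged
  expect_equal(
    select_cutoff(c(0.9, 0.8, 0.8, 0.2, 0.1), c(1, 1, 1, 0, 0)), 0.5
  )
  # perfectly inverted scores: degenerate but still returns an argmax
  inv <- select_cutoff(c(0.1, 0.2, 0.8, 0.9), c(1, 1, 0, 0))
  expect_true(is.finite(inv))
  expect_error(select_cutoff(c(0.5, 0.6), c(1, 1)), "both classes")
})

test_that("classification against shipped cutoffs is boundary-inclusive", {
  models <- default_models()
  expect_equal(classify(models[["5ss"]], 0.13), "significant")
  expect_equal(classify(models[["3ss_AG"]], 0.5), "significant")
  expect_equal(classify(models[["3ss_nonAG"]], 0.07), "not_significant")
  expect_equal(classify(models[["3ss_nonAG"]], 0.07784796), "significant")
  expect_equal(
    vapply(models, function(m) m$cutoff, numeric(1)),
    c("5ss" = 0.13, "3ss_AG" = 0.1837238, "3ss_nonAG" = 0.07784796)
  )
})

test_that("models round-trip through JSON bit-exactly", {
  sim <- logistic_sim(100, 4, beta = c(1, -1), seed = 10)
  fit <- fit_lasso(sim$X, sim$y, 0.02)
  m <- new_splice_lasso(fit, colnames(sim$X), 0.3, "3ss_AG")
  path <- withr::local_tempfile(fileext = ".json")
  save_model(m, path)
  m2 <- load_model(path)
  Xnew <- tibble::as_tibble(as.data.frame(sim$X[1:10, ]))
  expect_identical(predict_score(m, Xnew), predict_score(m2, Xnew))
  expect_equal(m2$cutoff, m$cutoff)
  # version-tag mismatch refuses to load
  bad <- jsonlite::read_json(path)
  bad$version <- "999"
  path2 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(bad, path2, auto_unbox = TRUE)
  expect_error(load_model(path2), "version")
})

test_that("the CV-selected model recovers a strong sparse support", {
  sim <- logistic_sim(500, 8, beta = c(1.5, -1.5, 1.2), seed = 20)
  cv <- cross_validate(sim$X, sim$y, k_folds = 5, seed = 20)
  fit <- fit_lasso(sim$X, sim$y, select_lambda(cv))
  expect_true(all(fit$beta[1] > 0, fit$beta[2] < 0, fit$beta[3] > 0))
  # the true signals dominate any noise coefficients in magnitude
  expect_gt(min(abs(fit$beta[1:3])), max(abs(fit$beta[4:8])))
})
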