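# L1-penalized logistic regression by cyclic coordinate descent on the
# IRLS quadratic approximation. The penalized objective is
#   f(b0, b) = -(1/n) * loglik(b0, b) + lambda * sum(|b_j|)
# with the intercept unpenalized. Features are standardized internally
# (mean 0, variance 1 with 1/n denominator); coefficients are stored on
# the standardized scale together with the transform.

soft_threshold <- function(z, g) {
  d <- abs(z) - g
  # relative dead-zone: |z| exceeding g only by float rounding is inactive
  # (keeps the KKT zero-solution exact at lambda == lambda_max)
  d[d <= g * 1e-12] <- 0
  sign(z) * pmax(d, 0)
}

standardize_X <- function(X) {
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)
  scl <- sqrt(colMeans(Xc^2))
  scl[scl == 0] <- 1 # constant columns stay centered at 0, coef 0
  list(X = sweep(Xc, 2, scl, "/"), center = ctr, scale = scl)
}

#' Largest penalty with any active coefficient
#'
#' At `lambda >= lambda_max = max_j |sum_i x_ij (y_i - ybar)| / n` (on
#' standardized features) the KKT conditions are satisfied by the
#' intercept-only model, so every slope coefficient is exactly zero.
#'
#' @param X Feature matrix (unstandardized).
#' @param y Binary labels.
#' @return `lambda_max`.
#' @export
lambda_max <- function(X, y) {
  Xs <- standardize_X(as.matrix(X))$X
  max(abs(crossprod(Xs, y - mean(y)))) / length(y)
}

#' Fit an L1-penalized logistic model
#'
#' @param X Numeric matrix or data frame, rows = instances.
#' @param y Binary 0/1 labels.
#' @param lambda Penalty `>= 0`.
#' @param standardize Standardize columns internally (default; the returned
#'   coefficients are on the standardized scale, with the transform stored).
#' @param max_iter Maximum outer IRLS iterations.
#' @param tol Convergence: maximum absolute coefficient change.
#' @return List with `beta0`, `beta` (named), `center`, `scale`, `lambda`,
#'   `objective` (penalized objective trace, one entry per outer
#'   iteration) and `n_iter`.
#' @export
fit_lasso <- function(X, y, lambda, standardize = TRUE, max_iter = 200L,
                      tol = 1e-7) {
  X <- as.matrix(X)
  stopifnot(all(is.finite(X)), all(y %in% c(0, 1)), lambda >= 0)
  n <- nrow(X)
  p <- ncol(X)
  if (standardize) {
    st <- standardize_X(X)
    Xs <- st$X
  } else {
    st <- list(center = rep(0, p), scale = rep(1, p))
    Xs <- X
  }
  beta <- rep(0, p)
  beta0 <- stats::qlogis(min(max(mean(y), 1e-10), 1 - 1e-10))
  obj_trace <- numeric()
  penalized_obj <- function(b0, b) {
    eta <- b0 + drop(Xs %*% b)
    -(sum(y * eta - log1p(exp(eta)))) / n + lambda * sum(abs(b))
  }
  for (it in seq_len(max_iter)) {
    beta_old <- beta
    beta0_old <- beta0
    eta <- beta0 + drop(Xs %*% beta)
    pr <- stats::plogis(eta)
    w <- pmax(pr * (1 - pr), 1e-5)
    z <- eta + (y - pr) / w
    # inner cyclic coordinate descent on the weighted least-squares surrogate
    r <- z - beta0 - drop(Xs %*% beta)
    for (sweep_i in 1:50) {
      delta <- 0
      for (j in seq_len(p)) {
        rj <- r + Xs[, j] * beta[j]
        num <- mean(w * Xs[, j] * rj)
        den <- mean(w * Xs[, j]^2)
        bj <- if (den > 0) soft_threshold(num, lambda) / den else 0
        if (bj != beta[j]) {
          r <- rj - Xs[, j] * bj
          delta <- max(delta, abs(bj - beta[j]))
          beta[j] <- bj
        }
      }
      b0_new <- beta0 + sum(w * r) / sum(w)
      r <- r - (b0_new - beta0)
      delta <- max(delta, abs(b0_new - beta0))
      beta0 <- b0_new
      if (delta < tol) break
    }
    obj_trace <- c(obj_trace, penalized_obj(beta0, beta))
    obj_converged <- it > 1L &&
      abs(obj_trace[it - 1L] - obj_trace[it]) <
        1e-9 * max(1, abs(obj_trace[it]))
    if (obj_converged ||
        max(abs(c(beta - beta_old, beta0 - beta0_old))) < tol) {
      names(beta) <- colnames(X)
      return(list(
        beta0 = beta0, beta = beta, center = st$center, scale = st$scale,
        lambda = lambda, objective = obj_trace, n_iter = it
      ))
    }
  }
  stop(
    "coordinate descent did not converge in ", max_iter,
    " iterations (lambda = ", signif(lambda, 4),
    ", last max change = ",
    signif(max(abs(c(beta - beta_old, beta0 - beta0_old))), 3), ")"
  )
}

# Warm-started fits along a decreasing lambda path (internal; used by CV).
fit_lasso_path <- function(Xs, y, lambdas, max_iter = 25L, tol = 1e-6) {
  n <- nrow(Xs)
  p <- ncol(Xs)
  beta <- rep(0, p)
  beta0 <- stats::qlogis(min(max(mean(y), 1e-10), 1 - 1e-10))
  out <- vector("list", length(lambdas))
  obj <- function(b0, b, lambda) {
    eta <- b0 + drop(Xs %*% b)
    -(sum(y * eta - log1p(exp(eta)))) / n + lambda * sum(abs(b))
  }
  for (li in seq_along(lambdas)) {
    lambda <- lambdas[li]
    obj_prev <- Inf
    for (it in seq_len(max_iter)) {
      beta_old <- beta
      beta0_old <- beta0
      eta <- beta0 + drop(Xs %*% beta)
      # saturated (separable) fit: further coefficient growth cannot move
      # the held-out deviance, stop refining this lambda
      if (max(abs(eta)) > 30) break
      pr <- stats::plogis(eta)
      w <- pmax(pr * (1 - pr), 1e-5)
      z <- eta + (y - pr) / w
      r <- z - beta0 - drop(Xs %*% beta)
      for (sweep_i in 1:10) {
        delta <- 0
        for (j in seq_len(p)) {
          rj <- r + Xs[, j] * beta[j]
          num <- mean(w * Xs[, j] * rj)
          den <- mean(w * Xs[, j]^2)
          bj <- if (den > 0) soft_threshold(num, lambda) / den else 0
          if (bj != beta[j]) {
            r <- rj - Xs[, j] * bj
            delta <- max(delta, abs(bj - beta[j]))
            beta[j] <- bj
          }
        }
        b0_new <- beta0 + sum(w * r) / sum(w)
        r <- r - (b0_new - beta0)
        delta <- max(delta, abs(b0_new - beta0))
        beta0 <- b0_new
        if (delta < tol) break
      }
      obj_now <- obj(beta0, beta, lambda)
      if (max(abs(c(beta - beta_old, beta0 - beta0_old))) < tol ||
          abs(obj_prev - obj_now) < 1e-8 * max(1, abs(obj_now))) {
        break
      }
      obj_prev <- obj_now
    }
    out[[li]] <- list(beta0 = beta0, beta = beta)
  }
  out
}

#' Default penalty grid
#'
#' 100 log-spaced values from `lambda_max` down to `1e-4 * lambda_max`.
#'
#' @param X,y Training data.
#' @param n_lambda Grid size.
#' @param min_ratio Smallest lambda as a fraction of `lambda_max`.
#' @return Strictly decreasing numeric vector.
#' @export
lambda_grid <- function(X, y, n_lambda = 100L, min_ratio = 1e-4) {
  lmax <- lambda_max(X, y)
  exp(seq(log(lmax), log(lmax * min_ratio), length.out = n_lambda))
}

binomial_deviance <- function(y, p) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -2 * mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Cross-validate the penalty by held-out binomial deviance
#'
#' Stratified k-fold cross-validation: fold labels are assigned within each
#' class so every fold sees both classes. For a fixed `seed` the fold
#' assignment, and hence the whole result, is deterministic.
#'
#' @param X,y Training data.
#' @param lambdas Decreasing penalty grid (default [lambda_grid()]).
#' @param k_folds Number of folds.
#' @param seed RNG seed for fold assignment (the global RNG state is left
#'   untouched).
#' @return A `cv_lasso` object: `lambda`, `cvm` (mean held-out deviance per
#'   lambda), `folds`, `seed`.
#' @export
cross_validate <- function(X, y, lambdas = NULL, k_folds = 10L,
                           seed = 20240615L) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (length(unique(y)) < 2L || min(table(y)) < 2L) {
    stop("cross-validation needs at least 2 instances of each class")
  }
  if (is.null(lambdas)) lambdas <- lambda_grid(X, y)
  stopifnot(all(diff(lambdas) < 0))
  k_folds <- min(k_folds, min(table(y)))
  folds <- integer(n)
  withr::with_seed(seed, {
    for (cls in unique(y)) {
      idx <- which(y == cls)
      folds[idx] <- sample(rep_len(seq_len(k_folds), length(idx)))
    }
  })
  dev <- matrix(NA_real_, k_folds, length(lambdas))
  for (f in seq_len(k_folds)) {
    tr <- folds != f
    st <- standardize_X(X[tr, , drop = FALSE])
    fits <- fit_lasso_path(st$X, y[tr], lambdas)
    Xte <- sweep(sweep(X[!tr, , drop = FALSE], 2, st$center), 2, st$scale, "/")
    for (li in seq_along(lambdas)) {
      eta <- fits[[li]]$beta0 + drop(Xte %*% fits[[li]]$beta)
      dev[f, li] <- binomial_deviance(y[!tr], stats::plogis(eta))
    }
  }
  structure(
    list(lambda = lambdas, cvm = colMeans(dev), fold_deviance = dev,
         folds = folds, seed = seed),
    class = "cv_lasso"
  )
}

#' Select the penalty at minimal cross-validated deviance
#'
#' Ties go to the larger lambda (the sparser model).
#'
#' @param cv A `cv_lasso` from [cross_validate()].
#' @return The selected lambda.
#' @export
select_lambda <- function(cv) {
  cv$lambda[which(cv$cvm == min(cv$cvm))[1]]
}

#' Select a classification cutoff by Youden's J
#'
#' Scans the midpoints of consecutive sorted unique scores and returns the
#' threshold maximizing `J = sensitivity + specificity - 1` under the
#' boundary-inclusive rule `score >= cutoff`. Ties take the lowest
#' threshold (favoring sensitivity).
#'
#' @param scores Numeric scores in `(0, 1)`.
#' @param labels Binary 0/1 truth.
#' @return The selected cutoff.
#' @export
select_cutoff <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  if (length(unique(labels)) < 2L) {
    stop("cutoff selection needs both classes present")
  }
  u <- sort(unique(scores))
  cand <- if (length(u) > 1L) (u[-length(u)] + u[-1]) / 2 else u
  j <- vapply(cand, function(t) {
    sens <- mean(scores[labels == 1] >= t)
    spec <- mean(scores[labels == 0] < t)
    sens + spec - 1
  }, numeric(1))
  cand[which(j == max(j))[1]]
}

#' Construct a route model
#'
#' @param fit Result of [fit_lasso()].
#' @param feature_names Registry feature names, in the column order of the
#'   training matrix.
#' @param cutoff Decision threshold in `(0, 1)`.
#' @param route_tag One of `"5ss"`, `"3ss_AG"`, `"3ss_nonAG"`.
#' @param trained Whether the coefficients come from data (placeholder
#'   models carry `FALSE`).
#' @param metadata Free-form training metadata list.
#' @return A `splice_lasso` object.
#' @export
new_splice_lasso <- function(fit, feature_names, cutoff, route_tag,
                             trained = TRUE, metadata = list()) {
  structure(
    list(
      version = "1",
      route_tag = route_tag,
      feature_names = feature_names,
      beta0 = fit$beta0,
      beta = stats::setNames(as.numeric(fit$beta), feature_names),
      center = stats::setNames(as.numeric(fit$center), feature_names),
      scale = stats::setNames(as.numeric(fit$scale), feature_names),
      lambda = fit$lambda,
      cutoff = cutoff,
      trained = trained,
      metadata = metadata
    ),
    class = "splice_lasso"
  )
}

#' Score feature vectors with a route model
#'
#' `plogis(beta0 + sum(beta_j * x_j))` on the model's stored
#' standardization. Every model feature must be present.
#'
#' @param model A `splice_lasso`.
#' @param features A data frame (or named numeric vector) of features.
#' @return Numeric scores in `(0, 1)`.
#' @export
predict_score <- function(model, features) {
  if (is.numeric(features) && !is.null(names(features))) {
    features <- tibble::as_tibble(as.list(features))
  }
  missing <- setdiff(model$feature_names, names(features))
  if (length(missing)) {
    stop("missing model feature(s): ", paste(missing, collapse = ", "))
  }
  X <- as.matrix(features[, model$feature_names, drop = FALSE])
  Xs <- sweep(sweep(X, 2, model$center), 2, model$scale, "/")
  stats::plogis(model$beta0 + drop(Xs %*% model$beta))
}

#' Classify a score against the model cutoff
#'
#' Boundary-inclusive: a score exactly at the cutoff is called significant.
#'
#' @param model A `splice_lasso`.
#' @param score Numeric scores.
#' @return `"significant"` / `"not_significant"` per score.
#' @export
classify <- function(model, score) {
  ifelse(score >= model$cutoff, "significant", "not_significant")
}

#' @export
print.splice_lasso <- function(x, ...) {
  cat(
    "<splice_lasso> route ", x$route_tag,
    if (!x$trained) " (untrained placeholder)",
    "\n  lambda ", signif(x$lambda, 4),
    ", cutoff ", x$cutoff,
    ", nonzero ", sum(x$beta != 0), "/", length(x$beta), "\n",
    sep = ""
  )
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted route model
#'
#' @param x A `splice_lasso`.
#' @param ... Unused.
#' @return Tibble of `term`/`estimate` (standardized scale), intercept
#'   included.
#' @method tidy splice_lasso
#' @export
tidy.splice_lasso <- function(x, ...) {
  tibble::tibble(
    term = c("(Intercept)", names(x$beta)),
    estimate = c(x$beta0, unname(x$beta))
  )
}

#' One-row summary of a route model
#' @param x A `splice_lasso`.
#' @param ... Unused.
#' @return Tibble: route, lambda, cutoff, number of nonzero terms, trained.
#' @method glance splice_lasso
#' @export
glance.splice_lasso <- function(x, ...) {
  tibble::tibble(
    route = x$route_tag,
    lambda = x$lambda,
    cutoff = x$cutoff,
    n_nonzero = sum(x$beta != 0),
    trained = x$trained
  )
}

#' Tidy a cross-validation result
#' @param x A `cv_lasso`.
#' @param ... Unused.
#' @return Tibble of `lambda` and mean held-out `deviance`.
#' @method tidy cv_lasso
#' @export
tidy.cv_lasso <- function(x, ...) {
  tibble::tibble(lambda = x$lambda, deviance = x$cvm)
}

#' Save a route model as versioned JSON
#' @param model A `splice_lasso`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  jsonlite::write_json(
    unclass(model), path,
    auto_unbox = TRUE, digits = I(17), pretty = TRUE
  )
  invisible(path)
}

#' Load a route model saved by [save_model()]
#' @param path JSON model file.
#' @return A `splice_lasso`.
#' @export
load_model <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(m$version, "1")) {
    stop("unsupported model file version: ", m$version %||% "<missing>")
  }
  m$beta <- stats::setNames(as.numeric(m$beta), m$feature_names)
  m$center <- stats::setNames(as.numeric(m$center), m$feature_names)
  m$scale <- stats::setNames(as.numeric(m$scale), m$feature_names)
  m$metadata <- as.list(m$metadata)
  structure(m, class = "splice_lasso")
}

#' Shipped placeholder models
#'
#' Untrained placeholder models for the three routes, carrying the
#' published decision cutoffs (0.13 for 5'ss, 0.1837238 for 3'ss novel-AG,
#' 0.07784796 for 3'ss non-AG) and zero coefficients. They exist so the
#' pipeline and the classification contract are usable out of the box;
#' retrain on your own labeled data (or the synthetic generator) for
#' meaningful scores.
#'
#' @return Named list of three `splice_lasso` objects.
#' @export
default_models <- function() {
  dir <- system.file("extdata", "models", package = "splicescreen")
  stats::setNames(
    lapply(c("5ss", "3ss_AG", "3ss_nonAG"), function(r) {
      load_model(file.path(dir, paste0(gsub("'", "", r), ".json")))
    }),
    c("5ss", "3ss_AG", "3ss_nonAG")
  )
}
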