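#' End-to-end splice-variant prediction
#'
#' Runs the full screen for a batch of variants: filter, triage into the
#' donor/acceptor windows, novel-AG routing, feature assembly, scoring
#' with the route's model and classification against the route's cutoff.
#' Every input variant appears in the output; variants outside the model
#' windows (or failing the filters) keep their basic gene/intron
#' information with an empty score and `effect = "not_evaluated"`.
#'
#' @param variants Variant tibble from [read_vcf()] (or with the same
#'   columns).
#' @param genome A `genome_model`.
#' @param introns Intron table from [extract_introns()].
#' @param models Named list of `splice_lasso` models for routes `5ss`,
#'   `3ss_AG`, `3ss_nonAG` (default: the shipped placeholder models).
#' @param track Optional `conservation_track`.
#' @param bp_store Optional `bp_store` for the branchpoint output column.
#' @param pwms Optional `pwm_store` (built from `introns` when omitted).
#' @param config A [feature_config()].
#' @return Prediction tibble: variant columns, `gene_id`, `intron_start`/
#'   `intron_end` (0-based half-open), `strand`, `model`, `distance`,
#'   `branchpoint`, `score`, `effect`, `n_introns`, plus the feature
#'   columns.
#' @export
predict_splice_variants <- function(variants, genome, introns,
                                    models = default_models(),
                                    track = NULL, bp_store = NULL,
                                    pwms = NULL,
                                    config = feature_config()) {
  stopifnot(all(c("5ss", "3ss_AG", "3ss_nonAG") %in% names(models)))
  if (is.null(pwms)) pwms <- build_pwms(genome, introns)
  triaged <- triage_all(variants, genome, introns)
  feats <- build_features(triaged, genome, track = track, pwms = pwms, config = config)
  n <- nrow(feats)
  score <- rep(NA_real_, n)
  effect <- rep("not_evaluated", n)
  for (r in c("5ss", "3ss_AG", "3ss_nonAG")) {
    idx <- which(feats$route == r & feats$feature_ok)
    if (length(idx) == 0L) next
    m <- models[[r]]
    sc <- predict_score(m, feats[idx, m$feature_names, drop = FALSE])
    score[idx] <- sc
    effect[idx] <- classify(m, sc)
  }
  bp <- rep(NA_integer_, n)
  if (!is.null(bp_store)) {
    routed <- which(!is.na(feats$intron_start))
    for (k in routed) {
      bp[k] <- annotate_branchpoint(bp_store, list(
        contig = feats$contig[k], start = feats$intron_start[k],
        end = feats$intron_end[k], strand = feats$strand[k]
      ))
    }
  }
  out <- dplyr::mutate(
    feats,
    model = dplyr::if_else(
      .data$route %in% c("5ss", "3ss_AG", "3ss_nonAG") & score_ok(score, .data$route),
      .data$route, "none"
    ),
    branchpoint = bp, score = score, effect = effect
  )
  out$model[is.na(out$score)] <- "none"
  out$effect[out$model == "none"] <- "not_evaluated"
  out
}

score_ok <- function(score, route) !is.na(score)

#' Train the three route models
#'
#' Splits labeled instances by route; for each route with at least 20
#' instances: stratified hold-out split, cross-validated penalty selection
#' on the training part, coordinate-descent fit, Youden-J cutoff on the
#' training scores, and metrics on the held-out part. Routes with too few
#' instances are skipped with a warning.
#'
#' @param X Feature data frame (registry columns).
#' @param y Binary labels (1 = significantly affects splicing).
#' @param route Character route tag per row.
#' @param registry Feature columns to use.
#' @param k_folds,seed Cross-validation parameters.
#' @param holdout Fraction of instances held out for evaluation.
#' @return A list with `models` (named list of `splice_lasso`) and
#'   `metrics` (tibble of per-route held-out metrics).
#' @export
train_route_models <- function(X, y, route,
                               registry = default_feature_registry(),
                               k_folds = 10L, seed = 20240615L,
                               holdout = 0.25) {
  X <- tibble::as_tibble(X)[, registry, drop = FALSE]
  models <- list()
  metrics <- list()
  for (r in intersect(c("5ss", "3ss_AG", "3ss_nonAG"), unique(route))) {
    idx <- which(route == r)
    if (length(idx) < 20L) {
      warning("route ", r, " has ", length(idx), " instances (< 20); skipped")
      next
    }
    Xr <- as.matrix(X[idx, , drop = FALSE])
    yr <- y[idx]
    te <- withr::with_seed(seed + match(r, c("5ss", "3ss_AG", "3ss_nonAG")), {
      unlist(lapply(split(seq_along(yr), yr), function(g) {
        sample(g, max(1L, round(holdout * length(g))))
      }), use.names = FALSE)
    })
    tr <- setdiff(seq_along(yr), te)
    if (length(unique(yr[tr])) < 2L || length(unique(yr[te])) < 2L) {
      warning("route ", r, ": a split lacks both classes; skipped")
      next
    }
    cv <- cross_validate(Xr[tr, , drop = FALSE], yr[tr], k_folds = k_folds, seed = seed)
    lam <- select_lambda(cv)
    fit <- fit_lasso(Xr[tr, , drop = FALSE], yr[tr], lam)
    sc_tr <- predict_score(
      new_splice_lasso(fit, registry, 0.5, r),
      tibble::as_tibble(as.data.frame(Xr[tr, , drop = FALSE]))
    )
    cut <- select_cutoff(sc_tr, yr[tr])
    model <- new_splice_lasso(
      fit, registry, cut, r,
      metadata = list(
        n_train = length(tr), n_holdout = length(te),
        cv_seed = seed, selected_lambda = lam
      )
    )
    sc_te <- predict_score(model, tibble::as_tibble(as.data.frame(Xr[te, , drop = FALSE])))
    cm <- confusion(yr[te], as.integer(sc_te >= cut))
    models[[r]] <- model
    metrics[[r]] <- dplyr::mutate(metric_report(cm), route = r, .before = 1)
  }
  list(models = models, metrics = dplyr::bind_rows(metrics))
}

#' Evaluate predictions against truth
#'
#' Joins predictions and truth on the variant key
#' (`contig`, `pos`, `ref`, `alt`), converts effects and labels to binary
#' calls, and reports per-route and pooled confusion-matrix metrics.
#'
#' @param predictions Prediction tibble (needs the key columns, `model`
#'   and `effect`).
#' @param truth Tibble with the key columns and a binary `label`.
#' @return Tibble of metrics with a `route` column (`"pooled"` included).
#' @export
evaluate_predictions <- function(predictions, truth) {
  keys <- c("contig", "pos", "ref", "alt")
  joined <- dplyr::inner_join(
    dplyr::filter(predictions, .data$effect != "not_evaluated"),
    dplyr::select(truth, dplyr::all_of(c(keys, "label"))),
    by = keys
  )
  if (nrow(joined) == 0L) {
    stop("predictions and truth share no evaluable variant keys")
  }
  calls <- as.integer(joined$effect == "significant")
  per_route <- joined |>
    dplyr::group_by(route = .data$model) |>
    dplyr::group_modify(function(g, key) {
      metric_report(confusion(g$label, as.integer(g$effect == "significant")))
    }) |>
    dplyr::ungroup()
  pooled <- dplyr::mutate(
    metric_report(confusion(joined$label, calls)),
    route = "pooled", .before = 1
  )
  dplyr::bind_rows(per_route, pooled)
}
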