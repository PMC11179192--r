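#' Configuration of the synthetic splicing-assay simulator
#'
#' The simulator emulates the structure of a massively parallel splicing
#' reporter assay: paired reference/alternative minigene constructs whose
#' splicing outcome is read out as spliced vs unspliced amplicon counts,
#' and whose difference is tested pair-by-pair with Fisher's exact test.
#' Defaults are a reduced-scale emulation: 2,000 pairs, mean read depth
#' 200 per construct, 20% of pairs truly splice-altering with
#' logit-scale effect sizes around 2.
#'
#' @param n_pairs Number of ref/alt construct pairs.
#' @param mean_depth Mean sequencing depth per construct (Poisson).
#' @param effect_fraction Fraction of pairs with a true splicing effect.
#' @param effect_size_mean,effect_size_sd Magnitude distribution of the
#'   logit-PSI shift for affected pairs (random sign).
#' @param psi_shape1,psi_shape2 Beta distribution of the reference PSI.
#' @param seed RNG seed; the whole simulation is deterministic given it.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_pairs = 2000L, mean_depth = 200,
                         effect_fraction = 0.2, effect_size_mean = 2,
                         effect_size_sd = 0.5, psi_shape1 = 2,
                         psi_shape2 = 2, seed = 1L) {
  stopifnot(effect_fraction >= 0, effect_fraction <= 1, mean_depth >= 1)
  structure(
    list(
      n_pairs = as.integer(n_pairs), mean_depth = mean_depth,
      effect_fraction = effect_fraction,
      effect_size_mean = effect_size_mean, effect_size_sd = effect_size_sd,
      psi_shape1 = psi_shape1, psi_shape2 = psi_shape2, seed = as.integer(seed)
    ),
    class = "synth_config"
  )
}

#' Simulate paired ref/alt splicing-assay counts
#'
#' For each pair the reference splicing efficiency (PSI) is drawn from a
#' Beta distribution; truly affected pairs shift the alternative allele's
#' logit-PSI by a random-signed effect; spliced read counts are binomial
#' draws at Poisson depths.
#'
#' @param config A [synth_config()].
#' @return Tibble with `pair_id`, `psi_ref`, `psi_alt`, `altered`
#'   (simulation truth), and the 2x2 counts `ref_spliced`,
#'   `ref_unspliced`, `alt_spliced`, `alt_unspliced`.
#' @export
simulate_pairs <- function(config = synth_config()) {
  withr::with_seed(config$seed, {
    n <- config$n_pairs
    psi_ref <- stats::rbeta(n, config$psi_shape1, config$psi_shape2)
    altered <- stats::rbinom(n, 1L, config$effect_fraction) == 1L
    shift <- ifelse(
      altered,
      sample(c(-1, 1), n, replace = TRUE) *
        stats::rnorm(n, config$effect_size_mean, config$effect_size_sd),
      0
    )
    psi_alt <- stats::plogis(stats::qlogis(pmin(pmax(psi_ref, 1e-6), 1 - 1e-6)) + shift)
    d_ref <- pmax(1L, stats::rpois(n, config$mean_depth))
    d_alt <- pmax(1L, stats::rpois(n, config$mean_depth))
    rs <- stats::rbinom(n, d_ref, psi_ref)
    as <- stats::rbinom(n, d_alt, psi_alt)
    tibble::tibble(
      pair_id = sprintf("pair%05d", seq_len(n)),
      psi_ref = psi_ref, psi_alt = psi_alt, altered = altered,
      ref_spliced = rs, ref_unspliced = d_ref - rs,
      alt_spliced = as, alt_unspliced = d_alt - as
    )
  })
}

#' Label assay pairs by Fisher's exact test
#'
#' Computes the two-sided Fisher p-value of each pair's 2x2
#' spliced/unspliced table, optionally applies Benjamini-Hochberg
#' correction across pairs, and labels pairs below the threshold as
#' splice-altering. The default (BH at 0.05) reflects that the real assay
#' runs thousands of simultaneous tests.
#'
#' @param pairs Tibble from [simulate_pairs()] (or any table with the four
#'   count columns).
#' @param alpha Significance threshold.
#' @param correction `"BH"` (step-up false-discovery-rate control) or
#'   `"none"`.
#' @return `pairs` with `p_value`, `p_adj` and `label` (0/1) appended.
#' @export
label_pairs <- function(pairs, alpha = 0.05, correction = c("BH", "none")) {
  correction <- match.arg(correction)
  p <- vapply(seq_len(nrow(pairs)), function(i) {
    fisher_exact_2x2(
      pairs$ref_spliced[i], pairs$ref_unspliced[i],
      pairs$alt_spliced[i], pairs$alt_unspliced[i]
    )
  }, numeric(1))
  padj <- if (correction == "BH") stats::p.adjust(p, method = "BH") else p
  dplyr::mutate(
    pairs,
    p_value = p, p_adj = padj, label = as.integer(padj <= alpha)
  )
}

#' Draw labels from a sparse logistic truth
#'
#' Bernoulli labels from `plogis(beta0 + Xs %*% beta)` where `Xs` is the
#' column-standardized feature matrix; `beta` names select columns of `X`.
#' Used by the synthetic training-set generator and by
#' support-recovery simulations.
#'
#' @param X Feature data frame/matrix.
#' @param beta Named true coefficient vector (standardized scale).
#' @param beta0 True intercept.
#' @param seed RNG seed.
#' @return Integer 0/1 labels.
#' @export
draw_labels <- function(X, beta, beta0 = 0, seed = 1L) {
  X <- as.matrix(X)
  b <- stats::setNames(numeric(ncol(X)), colnames(X))
  b[names(beta)] <- beta
  Xs <- standardize_X(X)$X
  eta <- beta0 + drop(Xs %*% b)
  withr::with_seed(seed, as.integer(stats::rbinom(length(eta), 1L, stats::plogis(eta))))
}

#' Generate a synthetic labeled training set
#'
#' Plants random single-nucleotide variants in the routed windows of the
#' toy locus introns, triages them, computes the full feature table, and
#' draws labels from a known sparse logistic model on the standardized
#' features — so the inferential structure (features in, LASSO-selected
#' coefficients out) can be exercised and support recovery verified
#' against the stored truth.
#'
#' @param n_variants Number of variants to plant (across both routes).
#' @param true_beta Named true coefficients on registry features. The
#'   default couples splice-site weakening (`delta_site_strength` < 0),
#'   conservation and U2-pairing loss to the altering probability.
#' @param beta0 True intercept (controls base rate).
#' @param seed RNG seed (variant placement and labels).
#' @param locus Optional pre-built toy locus (from [make_toy_locus()]);
#'   generated at `seed` when omitted.
#' @param registry Feature registry (columns of `X`).
#' @return List of class `synth_training_set`: `X` (feature tibble),
#'   `y`, `route`, `features` (full feature table), `true_beta`, `beta0`.
#' @export
synth_training_set <- function(n_variants = 120L,
                               true_beta = c(
                                 delta_site_strength = -1.5,
                                 conservation = 1.2,
                                 delta_u2_mfe = 1.0
                               ),
                               beta0 = -0.5, seed = 1L, locus = NULL,
                               registry = default_feature_registry()) {
  if (n_variants < 20L) stop("need at least 20 variants for a training set")
  if (is.null(locus)) locus <- make_toy_locus(seed = seed)
  genome <- load_genome(locus$fasta, assembly = "toy")
  introns <- extract_introns(locus$gtf)
  track <- read_conservation(locus$conservation)
  pwms <- build_pwms(genome, introns)
  uniq <- dplyr::distinct(introns, .data$contig, .data$start, .data$end, .data$strand)
  variants <- withr::with_seed(seed + 1L, {
    purrr::map_dfr(seq_len(n_variants), function(k) {
      intr <- uniq[sample.int(nrow(uniq), 1L), ]
      if (stats::runif(1) < 0.5) {
        o <- sample(seq.int(FIVE_PRIME_WINDOW[1], FIVE_PRIME_WINDOW[2]), 1L)
        g0 <- genomic_from_offset_5p(o, intr$start, intr$end, intr$strand)
      } else {
        o <- sample(seq.int(THREE_PRIME_WINDOW[1], THREE_PRIME_WINDOW[2]), 1L)
        g0 <- genomic_from_offset_3p(o, intr$start, intr$end, intr$strand)
      }
      ref <- substr(genome$contigs[[intr$contig]], g0 + 1L, g0 + 1L)
      alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1L)
      tibble::tibble(
        contig = intr$contig, pos = g0 + 1L, vid = ".",
        ref = ref, alt = alt, record = k
      )
    })
  })
  triaged <- triage_all(variants, genome, introns)
  triaged <- dplyr::distinct(triaged, .data$record, .keep_all = TRUE)
  feats <- build_features(triaged, genome, track = track, pwms = pwms)
  feats <- dplyr::filter(feats, .data$feature_ok)
  X <- feats[, registry, drop = FALSE]
  y <- draw_labels(X, true_beta, beta0, seed = seed + 2L)
  structure(
    list(
      X = X, y = y, route = feats$route, features = feats,
      true_beta = true_beta, beta0 = beta0, seed = seed
    ),
    class = "synth_training_set"
  )
}
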