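#' Feature computation configuration
#'
#' Windows are offsets in transcript orientation (see the triage
#' conventions). Defaults: branch-region window -50..-10 and
#' polypyrimidine window -25..-5 from the intron 3' end (both bracketing
#' the acceptor triage window), folding window variant +/- 35 nt, openness
#' span 11 nt, conservation window 7 nt.
#'
#' @param branch_window,py_window Integer length-2 offset ranges at the 3'
#'   intron end.
#' @param fold_flank Half-width (nt) of the transcript-strand folding
#'   window around the variant.
#' @param openness_span Width (nt) of the unpaired-probability span.
#' @param cons_window Width (nt) of the conservation mean window (odd).
#' @param u2_seq U2 snRNA branch-recognition sequence used by
#'   [u2_pairing_mfe()].
#' @param known_variant Include an indicator for a non-`"."` VCF ID column
#'   as a feature (off by default).
#' @return A named list of class `feature_config`.
#' @export
feature_config <- function(branch_window = c(-50L, -10L),
                           py_window = c(-25L, -5L),
                           fold_flank = 35L,
                           openness_span = 11L,
                           cons_window = 7L,
                           u2_seq = "GUAGUA",
                           known_variant = FALSE) {
  structure(
    list(
      branch_window = as.integer(branch_window),
      py_window = as.integer(py_window),
      fold_flank = as.integer(fold_flank),
      openness_span = as.integer(openness_span),
      cons_window = as.integer(cons_window),
      u2_seq = u2_seq,
      known_variant = known_variant
    ),
    class = "feature_config"
  )
}

#' Polypyrimidine-tract score
#'
#' Pyrimidine (C/T/U) fraction of a sequence window, with the longest
#' consecutive pyrimidine run as a secondary feature.
#'
#' @param seq Sequence of the 3'-end window on the transcript strand.
#' @return Named numeric vector: `fraction` in `[0, 1]` and `longest_run`
#'   (bases).
#' @export
py_tract_score <- function(seq) {
  b <- strsplit(chartr("U", "T", toupper(seq)), "")[[1]]
  if (length(b) == 0L) return(c(fraction = 0, longest_run = 0))
  py <- b %in% c("C", "T")
  r <- rle(py)
  run <- if (any(r$values)) max(r$lengths[r$values]) else 0L
  c(fraction = mean(py), longest_run = as.numeric(run))
}

#' Novel-AG features of a triaged variant
#'
#' @param triaged Triaged tibble (rows from [triage_all()]).
#' @return Tibble with `novel_ag_flag` (1 iff routed `3ss_AG`) and
#'   `novel_ag_to_canonical_dist` (offset gap between the created AG's G
#'   and the canonical acceptor G at offset -1; 0 off-route).
#' @export
novel_ag_features <- function(triaged) {
  tibble::tibble(
    novel_ag_flag = as.numeric(triaged$route == "3ss_AG"),
    novel_ag_to_canonical_dist = ifelse(
      triaged$route == "3ss_AG", as.numeric(triaged$novel_ag_dist), 0
    )
  )
}

#' Default model feature registry
#'
#' Names of the feature columns the route models consume, in stable order.
#' Paired sequence features enter as the reference value plus the
#' alt-minus-ref delta, so a model can weigh baseline context and the
#' perturbation separately. Users can pass any subset (or additional
#' columns they compute themselves) to the training functions.
#'
#' @param known_variant Append the optional known-variant indicator.
#' @return Character vector of feature names.
#' @export
default_feature_registry <- function(known_variant = FALSE) {
  reg <- c(
    "distance_to_site", "conservation", "cons_imputed",
    "py_tract_ref", "delta_py_tract", "py_run_ref", "delta_py_run",
    "u2_mfe_ref", "delta_u2_mfe",
    "fold_dG_ref", "delta_fold_dG",
    "openness_ref", "delta_openness",
    "site_strength_ref", "delta_site_strength",
    "novel_ag_flag", "novel_ag_to_canonical_dist"
  )
  if (known_variant) reg <- c(reg, "known_variant")
  reg
}

# Transcript-strand index of the variant inside its intron, or NA.
variant_ts_index <- function(g0, start, end, strand) {
  if (g0 < start || g0 >= end) return(NA_integer_)
  if (strand == "+") g0 - start + 1L else end - g0
}

substitute_base <- function(seq, i, base) {
  if (is.na(i) || i < 1L || i > nchar(seq)) return(seq)
  paste0(substr(seq, 1L, i - 1L), base, substr(seq, i + 1L, nchar(seq)))
}

# Extract a window of the transcript-strand intron sequence by 3'-end
# offsets, clamped to the intron.
intron_3p_window <- function(ts, w) {
  L <- nchar(ts)
  i1 <- max(1L, ts_index_from_offset_3p(w[1], L))
  i2 <- max(1L, ts_index_from_offset_3p(w[2], L))
  substr(ts, i1, i2)
}

#' Assemble the per-variant feature table
#'
#' Computes every registry feature for the reference and alternative
#' context of each routed variant: conservation around the variant, U2
#' pairing energy over the branch window, folding energy and structural
#' openness of the transcript-strand window around the variant,
#' polypyrimidine-tract content, splice-site PWM strength of the route's
#' junction, signed distance to the splice site, and the novel-AG
#' features. Alt-context features are recomputed on the substituted
#' sequence; `delta_*` columns are alt minus ref. Folding and openness are
#' batched into single engine calls across all rows.
#'
#' Rows whose route carries no model (filtered or out-of-scope variants)
#' and rows where a feature computation fails get `feature_ok = FALSE`;
#' failed feature values are imputed as 0 so downstream matrices contain
#' no missing entries, and such rows are emitted unscored by the pipeline.
#'
#' @param triaged Tibble from [triage_all()].
#' @param genome A `genome_model`.
#' @param track Optional `conservation_track`.
#' @param pwms Optional `pwm_store`; built from `introns` of the triage
#'   when omitted (pass explicitly to reuse across calls).
#' @param config A [feature_config()].
#' @return The input tibble with feature columns and `feature_ok` appended.
#' @export
build_features <- function(triaged, genome, track = NULL, pwms = NULL,
                           config = feature_config()) {
  n <- nrow(triaged)
  feat_names <- default_feature_registry(known_variant = TRUE)
  feats <- tibble::as_tibble(matrix(
    NA_real_, n, length(feat_names),
    dimnames = list(NULL, feat_names)
  ))
  routed <- which(triaged$route %in% c("5ss", "3ss_AG", "3ss_nonAG"))
  ok <- rep(FALSE, n)
  fold_ref <- fold_alt <- character(n)
  fold_center <- integer(n)
  for (k in routed) {
    row <- triaged[k, ]
    res <- try(
      {
        intron <- list(
          contig = row$contig, start = row$intron_start, end = row$intron_end,
          strand = row$strand, gene_id = row$gene_id
        )
        g0 <- row$pos - 1L
        ts <- intron_seq(genome, intron)
        i_ts <- variant_ts_index(g0, intron$start, intron$end, intron$strand)
        alt_b <- if (intron$strand == "-") comp_base(row$alt) else row$alt
        ts_alt <- substitute_base(ts, i_ts, alt_b)

        branch_ref <- intron_3p_window(ts, config$branch_window)
        branch_alt <- intron_3p_window(ts_alt, config$branch_window)
        py_ref <- py_tract_score(intron_3p_window(ts, config$py_window))
        py_alt <- py_tract_score(intron_3p_window(ts_alt, config$py_window))

        cons <- conservation_at(track, row$contig, row$pos, config$cons_window)

        end_kind <- if (row$route == "5ss") "donor" else "acceptor"
        off <- if (row$route == "5ss") row$off5 else row$off3
        ss_ref <- site_strength(genome, intron, end_kind, pwms)
        ss_alt <- site_strength(
          genome, intron, end_kind, pwms,
          allele = list(offset = off, base = alt_b)
        )

        # transcript-strand folding window around the variant
        a <- max(1L, row$pos - config$fold_flank)
        b <- min(nchar(genome$contigs[[row$contig]]), row$pos + config$fold_flank)
        wseq <- genome_seq(genome, row$contig, a, b)
        center <- if (intron$strand == "-") b - row$pos + 1L else row$pos - a + 1L
        if (intron$strand == "-") wseq <- revcomp(wseq)
        fold_ref[k] <- wseq
        fold_alt[k] <- substitute_base(wseq, center, alt_b)
        fold_center[k] <- center

        nag <- novel_ag_features(row)
        feats$distance_to_site[k] <- as.numeric(row$distance)
        feats$conservation[k] <- as.numeric(cons)
        feats$cons_imputed[k] <- as.numeric(attr(cons, "imputed"))
        feats$py_tract_ref[k] <- py_ref[["fraction"]]
        feats$delta_py_tract[k] <- py_alt[["fraction"]] - py_ref[["fraction"]]
        feats$py_run_ref[k] <- py_ref[["longest_run"]]
        feats$delta_py_run[k] <- py_alt[["longest_run"]] - py_ref[["longest_run"]]
        feats$u2_mfe_ref[k] <- u2_pairing_mfe(branch_ref, config$u2_seq)
        feats$delta_u2_mfe[k] <-
          u2_pairing_mfe(branch_alt, config$u2_seq) - feats$u2_mfe_ref[k]
        feats$site_strength_ref[k] <- ss_ref
        feats$delta_site_strength[k] <- ss_alt - ss_ref
        feats$novel_ag_flag[k] <- nag$novel_ag_flag
        feats$novel_ag_to_canonical_dist[k] <- nag$novel_ag_to_canonical_dist
        feats$known_variant[k] <- as.numeric(!is.na(row$vid) && row$vid != ".")
        TRUE
      },
      silent = TRUE
    )
    ok[k] <- isTRUE(res)
  }
  idx <- routed[ok[routed]]
  if (length(idx)) {
    dg <- fold_dG(c(fold_ref[idx], fold_alt[idx]))
    op <- openness(
      c(fold_ref[idx], fold_alt[idx]),
      rep(fold_center[idx], 2L),
      span = config$openness_span
    )
    m <- length(idx)
    feats$fold_dG_ref[idx] <- dg[seq_len(m)]
    feats$delta_fold_dG[idx] <- dg[m + seq_len(m)] - dg[seq_len(m)]
    feats$openness_ref[idx] <- op[seq_len(m)]
    feats$delta_openness[idx] <- op[m + seq_len(m)] - op[seq_len(m)]
  }
  bad <- rep(FALSE, n)
  bad[idx] <- rowSums(is.na(feats[idx, , drop = FALSE])) > 0L
  ok[bad] <- FALSE
  feats[is.na(feats)] <- 0
  out <- dplyr::bind_cols(triaged, feats)
  out$feature_ok <- ok
  out
}
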