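# Routing windows, in transcript orientation (inclusive at both ends):
#   donor (5'ss) route:     offset_5p in [-3, +30]
#   acceptor (3'ss) routes: offset_3p in [-78, -4], split on novel-AG creation
FIVE_PRIME_WINDOW <- c(-3L, 30L)
THREE_PRIME_WINDOW <- c(-78L, -4L)

route_levels <- c(
  "5ss", "3ss_AG", "3ss_nonAG", "out_of_scope", "not_snv", "intergenic",
  "ref_mismatch"
)

#' Pre-filter a variant before routing
#'
#' Applies, in order: single-nucleotide check (indels are not scored),
#' intragenic check against gene spans, and reference-allele concordance.
#'
#' @param variant One-row data frame/list with `contig`, `pos`, `ref`, `alt`.
#' @param genome A `genome_model`.
#' @param introns Intron table from [extract_introns()] (supplies gene spans).
#' @return `"pass"`, or one of `"not_snv"`, `"intergenic"`, `"ref_mismatch"`.
#' @export
filter_variant <- function(variant, genome, introns) {
  if (nchar(variant$ref) != 1L || nchar(variant$alt) != 1L) return("not_snv")
  sp <- gene_spans(introns)
  g0 <- variant$pos - 1L
  hit <- sp$contig == variant$contig & g0 >= sp$start & g0 < sp$end
  if (!any(hit)) return("intergenic")
  if (!check_reference(variant, genome)) return("ref_mismatch")
  "pass"
}

#' Nearest intron to a variant
#'
#' Among the introns of genes whose span contains the variant, returns the
#' intron whose donor or acceptor boundary is closest in genomic bp.
#' Ties prefer an intron for which the variant lands in the donor window,
#' then the lower genomic start coordinate.
#'
#' @param variant One-row variant.
#' @param introns Intron tibble.
#' @return A one-row intron tibble with `off5`, `off3` and `dist` (absolute
#'   genomic bp to the closer boundary) appended, or `NULL` when the
#'   containing gene(s) have no introns.
#' @export
nearest_intron <- function(variant, introns) {
  cand <- variant_intron_offsets(variant, introns)
  if (is.null(cand) || nrow(cand) == 0L) return(NULL)
  cand <- dplyr::arrange(
    cand, .data$dist,
    !(.data$off5 >= FIVE_PRIME_WINDOW[1] & .data$off5 <= FIVE_PRIME_WINDOW[2]),
    .data$start
  )
  cand[1, ]
}

# Offsets of one variant against all introns of its containing gene(s).
variant_intron_offsets <- function(variant, introns) {
  sp <- gene_spans(introns)
  g0 <- variant$pos - 1L
  genes <- sp$gene_id[sp$contig == variant$contig & g0 >= sp$start & g0 < sp$end]
  if (length(genes) == 0L) return(NULL)
  cand <- dplyr::filter(introns, .data$gene_id %in% genes, .data$contig == variant$contig)
  if (nrow(cand) == 0L) return(NULL)
  cand$off5 <- offset_5p(g0, cand$start, cand$end, cand$strand)
  cand$off3 <- offset_3p(g0, cand$start, cand$end, cand$strand)
  # genomic distance to the closer boundary: offsets are 1-anchored on the
  # intronic side, so |off| - 1 at intronic positions, |off| at exonic ones
  d5 <- abs(cand$off5) - as.integer(cand$off5 > 0L)
  d3 <- abs(cand$off3) - as.integer(cand$off3 < 0L)
  cand$dist <- pmin(d5, d3)
  cand
}

in_window <- function(x, w) !is.na(x) & x >= w[1] & x <= w[2]

#' Route a triaged variant to a model window
#'
#' A variant in the donor window `[-3, +30]` goes to the 5'ss model
#' (preferred on overlap); one in the acceptor window `[-78, -4]` goes to
#' the 3'ss novel-AG model when the substitution creates an AG dinucleotide
#' overlapping the variant on the transcript strand that the reference
#' lacks, otherwise to the 3'ss non-AG model.
#'
#' @param variant One-row variant (SNV).
#' @param intron One-row intron with `off5`, `off3` columns (as from
#'   [nearest_intron()]).
#' @param genome A `genome_model`.
#' @return One of `"5ss"`, `"3ss_AG"`, `"3ss_nonAG"`, `"out_of_scope"`.
#' @export
route_variant <- function(variant, intron, genome) {
  if (in_window(intron$off5, FIVE_PRIME_WINDOW)) return("5ss")
  if (in_window(intron$off3, THREE_PRIME_WINDOW)) {
    ag <- novel_ag(variant, intron, genome)
    return(if (ag$flag) "3ss_AG" else "3ss_nonAG")
  }
  "out_of_scope"
}

# Novel-AG creation test on the transcript strand. Only the two
# dinucleotides overlapping the substituted base can gain an AG from a
# single substitution. Returns the flag and the offset distance from the
# created AG's G to the canonical acceptor G at offset -1.
novel_ag <- function(variant, intron, genome) {
  none <- list(flag = FALSE, dist = 0L)
  o <- intron$off3
  if (!in_window(o, THREE_PRIME_WINDOW)) return(none)
  ts <- intron_seq(genome, intron)
  L <- nchar(ts)
  i <- ts_index_from_offset_3p(o, L)
  if (i < 2L || i >= L) return(none)
  alt_b <- if (intron$strand == "-") comp_base(variant$alt) else variant$alt
  ref_b <- substr(ts, i, i)
  prev <- substr(ts, i - 1L, i - 1L)
  nxt <- substr(ts, i + 1L, i + 1L)
  # left dinucleotide (i-1, i): gains AG iff prev == A and alt == G
  if (prev == "A" && alt_b == "G" && ref_b != "G") {
    return(list(flag = TRUE, dist = -1L - o))
  }
  # right dinucleotide (i, i+1): gains AG iff alt == A and next == G
  if (alt_b == "A" && nxt == "G" && ref_b != "A") {
    return(list(flag = TRUE, dist = -1L - (o + 1L)))
  }
  none
}

#' Triage a batch of variants
#'
#' Runs the full filter/assign/route cascade. Variants that pass the filters
#' are matched against every intron of their containing gene(s); each
#' qualifying (variant, intron) pair yields one row (identical intron
#' intervals shared by several transcripts are collapsed), with
#' `n_introns` recording the multiplicity. Variants with no qualifying
#' intron are reported once against their nearest intron as
#' `out_of_scope`; filtered variants carry their filter route and no intron.
#'
#' @param variants Variant tibble from [read_vcf()].
#' @param genome A `genome_model`.
#' @param introns Intron table from [extract_introns()].
#' @return A tibble: variant columns plus `route`, `gene_id`,
#'   `transcript_id`, `intron_start`, `intron_end`, `strand`, `off5`,
#'   `off3`, `distance` (signed, transcript orientation), `novel_ag_dist`,
#'   `n_introns`. Input order is preserved.
#' @export
triage_all <- function(variants, genome, introns) {
  if (nrow(variants) == 0L) return(empty_triage())
  rows <- purrr::map(seq_len(nrow(variants)), function(k) {
    v <- variants[k, ]
    fl <- filter_variant(v, genome, introns)
    if (fl != "pass") return(triage_row(v, NULL, fl))
    cand <- variant_intron_offsets(v, introns)
    if (is.null(cand)) return(triage_row(v, NULL, "out_of_scope"))
    cand <- dplyr::distinct(
      cand, .data$contig, .data$start, .data$end, .data$strand,
      .keep_all = TRUE
    )
    cand$route <- vapply(
      seq_len(nrow(cand)),
      function(j) route_variant(v, cand[j, ], genome),
      character(1)
    )
    qual <- cand[cand$route != "out_of_scope", ]
    if (nrow(qual) == 0L) {
      ni <- nearest_intron(v, introns)
      return(triage_row(v, ni, "out_of_scope", n_introns = 1L))
    }
    qual <- dplyr::arrange(qual, .data$route != "5ss", .data$start)
    purrr::map_dfr(seq_len(nrow(qual)), function(j) {
      nag <- if (qual$route[j] == "3ss_AG") {
        novel_ag(v, qual[j, ], genome)$dist
      } else 0L
      triage_row(v, qual[j, ], qual$route[j],
        n_introns = nrow(qual), nag_dist = nag
      )
    })
  })
  dplyr::bind_rows(rows)
}

triage_row <- function(v, intron, route, n_introns = 0L, nag_dist = 0L) {
  base <- tibble::tibble(
    contig = v$contig, pos = v$pos, vid = v$vid %||% ".",
    ref = v$ref, alt = v$alt, record = v$record %||% NA_integer_,
    route = route
  )
  if (is.null(intron)) {
    return(dplyr::mutate(
      base,
      gene_id = NA_character_, transcript_id = NA_character_,
      intron_start = NA_integer_, intron_end = NA_integer_,
      strand = NA_character_, off5 = NA_integer_, off3 = NA_integer_,
      distance = NA_integer_, novel_ag_dist = 0L, n_introns = n_introns
    ))
  }
  dist <- switch(route,
    "5ss" = intron$off5,
    "3ss_AG" = ,
    "3ss_nonAG" = intron$off3,
    if (abs(intron$off5) <= abs(intron$off3)) intron$off5 else intron$off3
  )
  dplyr::mutate(
    base,
    gene_id = intron$gene_id, transcript_id = intron$transcript_id,
    intron_start = as.integer(intron$start), intron_end = as.integer(intron$end),
    strand = intron$strand,
    off5 = as.integer(intron$off5), off3 = as.integer(intron$off3),
    distance = as.integer(dist), novel_ag_dist = as.integer(nag_dist),
    n_introns = n_introns
  )
}

empty_triage <- function() {
  tibble::tibble(
    contig = character(), pos = integer(), vid = character(),
    ref = character(), alt = character(), record = integer(),
    route = character(), gene_id = character(), transcript_id = character(),
    intron_start = integer(), intron_end = integer(), strand = character(),
    off5 = integer(), off3 = integer(), distance = integer(),
    novel_ag_dist = integer(), n_introns = integer()
  )
}
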