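# Offset conventions around an intron [start, end) (0-based half-open),
# in transcript orientation:
#   5' end (donor):  +1 = first intronic base, -1 = last base of the
#                    upstream exon (the window -3..+30 spans the junction).
#   3' end (acceptor): -1 = last intronic base (the acceptor G), -78..-4 is
#                    wholly intronic; +1 = first base of the downstream exon.
# g0 is the 0-based genomic position of the variant. All helpers recycle
# their arguments (strand may be scalar against vector offsets/positions).

pick_strand <- function(strand, plus, minus) {
  n <- max(length(plus), length(minus))
  ifelse(rep_len(strand == "+", n), rep_len(plus, n), rep_len(minus, n))
}

offset_5p <- function(g0, start, end, strand) {
  pick_strand(
    strand,
    ifelse(g0 >= start, g0 - start + 1L, g0 - start),
    ifelse(g0 < end, end - g0, end - g0 - 1L)
  )
}

offset_3p <- function(g0, start, end, strand) {
  pick_strand(
    strand,
    ifelse(g0 < end, g0 - end, g0 - end + 1L),
    ifelse(g0 >= start, start - g0 - 1L, start - g0)
  )
}

# Genomic 0-based position of a 3'-end offset (o < 0 intronic, o > 0 exonic).
genomic_from_offset_3p <- function(o, start, end, strand) {
  pick_strand(
    strand,
    ifelse(o < 0L, end + o, end + o - 1L),
    ifelse(o < 0L, start - 1L - o, start - o)
  )
}

# Genomic 0-based position of a 5'-end offset (o > 0 intronic, o < 0 exonic).
genomic_from_offset_5p <- function(o, start, end, strand) {
  pick_strand(
    strand,
    ifelse(o > 0L, start + o - 1L, start + o),
    ifelse(o > 0L, end - o, end - 1L - o)
  )
}

# Transcript-strand intron sequence; index 1 = first intronic base (offset +1).
intron_seq <- function(genome, intron) {
  s <- genome_seq(genome, intron$contig, intron$start + 1L, intron$end)
  if (intron$strand == "-") revcomp(s) else s
}

# Index into the transcript-strand intron sequence for a 3'-end offset.
ts_index_from_offset_3p <- function(o, intron_len) intron_len + o + 1L

# Complement of single bases (vectorized over characters).
comp_base <- function(b) chartr("ACGTN", "TGCAN", b)
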