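# Shared fixtures: the deterministic synthetic reference and small read
# constructors used across test files.

test_ref <- synthetic_reference()

# a read with constant quality, default fully matching
make_read <- function(start, seq, strand = "+", paired = FALSE,
                      qual = strrep("I", nchar(seq)),
                      cigar = paste0(nchar(seq), "M"), id = "r") {
  read_stack(data.frame(
    read_id = id, start = as.integer(start), strand = strand,
    paired = paired, seq = seq, qual = qual, cigar = cigar,
    stringsAsFactors = FALSE
  ))
}

bind_reads <- function(...) {
  read_stack(do.call(rbind, lapply(list(...), as.data.frame)))
}

# reference-derived read sequence over [start, start+len-1]
ref_seq <- function(start, len) {
  substr(test_ref$sequence, start, start + len - 1L)
}

# pileup columns with the given per-strand base counts at one position
one_column_pileup <- function(position, counts10) {
  cm <- matrix(0L, test_ref$length, 10L)
  cm[position, ] <- as.integer(counts10)
  mitohap:::new_pileup(cm, mitohap:::empty_insertions(), test_ref)
}

# substitution token for a position: reference base -> its transition
transition_token <- function(pos) {
  rb <- substr(test_ref$sequence, pos, pos)
  alt <- c(A = "G", G = "A", C = "T", T = "C")[[rb]]
  paste0(rb, pos, alt)
}
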