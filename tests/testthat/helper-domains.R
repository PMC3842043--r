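# Shared fixtures for the motif/classifier tests, built in code.

# A zero-mismatch consensus instance with chosen spacer lengths: every
# wildcard and spacer position is A, class tokens take K/R/I/F/V and the
# invariant residues are spelled out. With (3, 5) this is the minimal
# 44-residue instance.
make_perfect_domain <- function(s1 = 3, s2 = 5) {
  paste0("KR", strrep("A", s1), "EKAR", "AAA", "IN", "AA", "F", "AA", "L",
         "K", strrep("A", s2), "R", "AA", "K", "AA", "V", "L", "AA", "A",
         "V", "A", "Y", "I", "AA", "L")
}

PERFECT <- make_perfect_domain()

# 1-based positions of the 19 diagnostic sites of a domain that starts at
# position 1 with spacers (s1, s2).
diag_positions <- function(s1 = 3, s2 = 5) {
  c(1, 2,
    2 + s1 + c(1, 2, 4, 8, 9, 12, 15, 16),
    18 + s1 + s2 + c(1, 4, 7, 8, 11, 12, 14, 15, 18))
}

mutate_at <- function(seq, pos, to = "G") {
  chars <- strsplit(seq, "")[[1]]
  chars[pos] <- to
  paste(chars, collapse = "")
}

random_protein <- function(len) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], len,
               replace = TRUE), collapse = "")
}

write_tmp_fasta <- function(seqs, path = tempfile(fileext = ".fasta")) {
  writeLines(as.vector(rbind(paste0(">", names(seqs)), unname(seqs))), path)
  path
}
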