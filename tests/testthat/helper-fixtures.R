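# Small builders shared across test files; everything is generated in code.

make_reads <- function(seqs, q = 30) {
  if (is.null(names(seqs)))
    names(seqs) <- sprintf("r%04d", seq_along(seqs))
  qs <- Biostrings::PhredQuality(vapply(nchar(seqs), function(w)
    paste(rep(rawToChar(as.raw(q + 33L)), w), collapse = ""), character(1)))
  Biostrings::QualityScaledDNAStringSet(Biostrings::DNAStringSet(seqs), qs)
}

# One read with an explicit per-base quality vector.
make_read_q <- function(seq, qvec) {
  qs <- Biostrings::PhredQuality(paste(rawToChar(as.raw(qvec + 33L)),
                                       collapse = ""))
  Biostrings::QualityScaledDNAStringSet(Biostrings::DNAStringSet(seq), qs)
}

toy_table <- function() {
  m <- matrix(c(90L, 10L, 0L, 50L, 25L, 25L), ncol = 2,
              dimnames = list(c("u1", "u2", "u3"),
                              c("S1|rDNA", "S1|rRNA")))
  unitCountTable(m)
}

# Deterministic mutation of one sequence at given 1-based positions.
mutate_at <- function(seq, pos) {
  s <- strsplit(seq, "")[[1]]
  for (p in pos) s[p] <- setdiff(c("A", "C", "G", "T"), s[p])[1]
  paste(s, collapse = "")
}

small_scenario <- function(...) {
  args <- list(n_taxa = 12, seq_len = 250, depth_rdna = 2000,
               depth_rrna = 2000, sub_error_rate = 0, rt_error_rate = 0,
               seed = 42)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(simScenario, args)
}
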