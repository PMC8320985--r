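# Independent brute-force oracles used to cross-check the implementation.
# They deliberately share no code with the package internals.

# All 4^n words over ACGT filtered by GC weight and (optionally) the
# no-runlength rule, via direct expansion. Only sane for n <= 6.
brute_valid_words <- function(n, w, nrl = TRUE) {
  stopifnot(n <= 6)
  grids <- rep(list(c("A", "C", "G", "T")), n)
  all_words <- do.call(paste0, rev(expand.grid(grids, stringsAsFactors = FALSE)))
  keep <- vapply(all_words, function(x) {
    ch <- strsplit(x, "")[[1]]
    if (sum(ch %in% c("G", "C")) != w) return(FALSE)
    if (nrl && n > 1 && any(ch[-1] == ch[-n])) return(FALSE)
    TRUE
  }, logical(1))
  sort(all_words[keep])
}

# Position-by-position Hamming distance, independent of the package.
brute_hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# A random word over ACGT (not necessarily constraint-valid).
random_word <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
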