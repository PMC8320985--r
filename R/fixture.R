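#' Reference code set at n = 9, d = 6
#'
#' Loads the 26-codeword reference set shipped with the package (plain text
#' under `extdata`): length 9, minimum pairwise Hamming distance 6, GC
#' weight 4, no-runlength. Validation is re-run at load time, so the fixture
#' doubles as an end-to-end check of the constraint predicates.
#'
#' @return a validated [code_set()] with profile `(n = 9, d = 6, w = 4)`.
#' @examples
#' s <- load_reference_set_n9_d6()
#' length(s)                  # 26
#' min_pairwise_distance(s)   # >= 6
#' @export
load_reference_set_n9_d6 <- function() {
  path <- system.file("extdata", "code_set_n9_d6.txt", package = "eorscode",
                      mustWork = TRUE)
  code_set(read_codewords(path, format = "text"),
           constraint_profile(n = 9L, d = 6L, w = 4L, nrl = TRUE))
}
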