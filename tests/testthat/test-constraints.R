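# constraints_core: codeword predicates, set validity, fitness, coding rate.

test_that("hamming_distance matches hand-derived values and errors on mismatch", {
  expect_identical(hamming_distance("ATCTGCTCA", "ATCTGCTCA"), 0L)
  expect_identical(hamming_distance("ATCTGCTCA", "ATCGAGATG"), 6L)
  expect_identical(hamming_distance("ATCTGCTCA", "GTAGTCGAT"), 7L)
  expect_identical(hamming_distance("atctgctca", "ATCGAGATG"), 6L) # case-folded
  expect_error(hamming_distance("ACGT", "ACG"), "4.*3")
})

test_that("hamming_distance satisfies the metric axioms on random triples", {
  set.seed(42)
  for (rep in 1:50) {
    n <- sample(2:10, 1)
    a <- random_word(n); b <- random_word(n); c <- random_word(n)
    expect_identical(hamming_distance(a, b), hamming_distance(b, a))
    expect_identical(hamming_distance(a, b) == 0L, a == b)
    expect_lte(hamming_distance(a, c),
               hamming_distance(a, b) + hamming_distance(b, c))
    expect_identical(hamming_distance(a, b), brute_hamming(a, b))
  }
})

test_that("gc_count / gc_content behave and complement the A/T count", {
  expect_identical(gc_count("ATCTGCTCA"), 4L)
  expect_identical(gc_count("AAAA"), 0L)
  expect_identical(gc_count("GCGC"), 4L)
  expect_equal(gc_content("GCGC"), 1)
  expect_error(gc_count(""), "invalid")
  set.seed(7)
  for (rep in 1:25) {
    x <- random_word(sample(1:12, 1))
    at <- sum(strsplit(x, "")[[1]] %in% c("A", "T"))
    expect_identical(gc_count(x) + at, nchar(x))
  }
})

test_that("has_no_runlength flags adjacent repeats", {
  expect_false(has_no_runlength("TCCCCAC"))
  expect_true(has_no_runlength("TAGCTAGCT"))
  expect_true(has_no_runlength("A"))
  expect_identical(has_no_runlength(c("ACA", "ACC")), c(TRUE, FALSE))
})

test_that("constraint_profile enforces its ranges and defaults", {
  p <- constraint_profile(9, 6)
  expect_identical(p$w, 4L)          # floor(n/2)
  expect_true(p$nrl)
  expect_error(constraint_profile(4, 5), "d must be")
  expect_error(constraint_profile(4, 3, w = 5), "w must be")
  expect_error(constraint_profile(0, 1), "n must be")
})

test_that("is_valid_codeword combines GC weight and NRL", {
  p9 <- constraint_profile(9, 6, 4)
  expect_true(is_valid_codeword("ATCTGCTCA", p9))
  expect_false(is_valid_codeword("TCCCCAC", constraint_profile(7, 3, 3)))
  expect_false(is_valid_codeword("GGGGCGCGC", p9))    # GC weight mismatch
  expect_error(is_valid_codeword("ACGT", p9), "length mismatch")
  # NRL off: only the GC weight counts
  expect_true(is_valid_codeword("GGTATAATT",
                                constraint_profile(9, 6, 2, nrl = FALSE)))
})

test_that("codeword text/digit representations are mutually consistent", {
  expect_identical(digits_to_codewords(matrix(c(0L, 1L, 2L, 3L), nrow = 1)),
                   "TCGA")
  expect_identical(codeword_digits("TCGA")[1, ], c(TCGA = 0L, 1L, 2L, 3L),
                   ignore_attr = TRUE)
  set.seed(11)
  for (rep in 1:20) {
    x <- random_word(sample(1:10, 1))
    expect_identical(digits_to_codewords(codeword_digits(x)), x)
  }
  expect_error(as_codewords("ACGN"), "invalid")
  expect_error(as_codewords("AC-G"), "invalid")
  expect_identical(as_codewords("acgt"), "ACGT")
})

test_that("canonical order is lexicographic on digits (T < C < G < A)", {
  expect_identical(canonical_sort(c("AA", "TT", "GG", "CC", "TA", "AT")),
                   c("TT", "TA", "CC", "GG", "AT", "AA"))
})

test_that("min_pairwise_distance returns the NA sentinel below two members", {
  expect_identical(min_pairwise_distance(character(0)), NA_integer_)
  expect_identical(min_pairwise_distance("ACGT"), NA_integer_)
  expect_identical(min_pairwise_distance(c("GA", "CT")), 2L)
  expect_error(min_pairwise_distance(c("GA", "CTT")), "mixed lengths")
})

test_that("is_valid_code checks members and all pairs, and is hereditary", {
  p <- constraint_profile(2, 2, 1)
  expect_true(is_valid_code(c("GA", "CT", "AG", "TC"), p))
  expect_false(is_valid_code(c("GA", "GT"), p))   # H = 1 < 2
  expect_true(is_valid_code("GA", p))             # singleton: vacuous
  expect_true(is_valid_code(character(0), p))
  # hereditary: every subset of a valid code is valid
  s <- load_reference_set_n9_d6()
  set.seed(3)
  for (rep in 1:10) {
    sub <- sample(s$words, sample(0:length(s), 1))
    expect_true(is_valid_code(sub, s$profile))
  }
})

test_that("code_set validates, deduplicates and orders members", {
  p <- constraint_profile(2, 2, 1)
  s <- code_set(c("GA", "CT", "AG", "TC"), p)
  expect_identical(s$words, canonical_sort(s$words))
  expect_identical(length(s), 4L)
  expect_error(code_set(c("GA", "GA"), p), "duplicate")
  expect_error(code_set(c("GA", "GT"), p), "violates")
  expect_silent(code_set(c("GA", "GT"), p, validate = FALSE))
})

test_that("code_fitness is the distance sum, 0 on the empty set", {
  expect_identical(code_fitness("ACGT", character(0)), 0L)
  expect_identical(code_fitness("ATCGAGATG", "ATCTGCTCA"), 6L)
  s <- c("ATCTGCTCA", "ATCGAGATG")
  expect_identical(code_fitness("ATCTGCTCA", s),
                   hamming_distance("ATCTGCTCA", "ATCGAGATG")) # self adds 0
  expect_error(code_fitness("ACG", s), "length mismatch")
})

test_that("coding_rate matches log4(M)/n and is monotone", {
  expect_equal(round(coding_rate(110, 8), 2), 0.42)
  expect_equal(coding_rate(1, 5), 0)
  expect_equal(coding_rate(256, 4), 1)
  expect_error(coding_rate(0, 4), "requires")
  expect_true(all(diff(coding_rate(1:50, 6)) > 0))          # increasing in M
  expect_true(all(diff(coding_rate(20, 2:10)) < 0))         # decreasing in n
})
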