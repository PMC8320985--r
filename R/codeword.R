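# Canonical base order: the digit mapping T->0, C->1, G->2, A->3 used for
# all integer representations and for the canonical lexicographic order.
.BASES <- c("T", "C", "G", "A")

#' Convert DNA codewords to their integer digit form
#'
#' Codewords are stored as uppercase strings over \{A, C, G, T\}; for
#' arithmetic they are mapped to digits with T = 0, C = 1, G = 2, A = 3.
#'
#' @param x character vector of codewords (case-insensitive).
#' @return For `codeword_digits`, an integer matrix with one row per codeword
#'   and one column per position. For `digits_to_codewords`, a character
#'   vector of uppercase codewords.
#' @examples
#' codeword_digits("TCGA")
#' digits_to_codewords(matrix(0:3, nrow = 1))
#' @export
codeword_digits <- function(x) {
  x <- as_codewords(x)
  if (length(x) == 0L) return(matrix(integer(0), nrow = 0, ncol = 0))
  n <- unique(nchar(x))
  if (length(n) != 1L) {
    stop("codewords have mixed lengths: ", paste(sort(n), collapse = ", "))
  }
  m <- matrix(match(unlist(strsplit(x, "", fixed = TRUE)), .BASES) - 1L,
              ncol = n, byrow = TRUE)
  rownames(m) <- x
  m
}

#' @param digits integer matrix (rows = codewords) with entries in 0..3.
#' @rdname codeword_digits
#' @export
digits_to_codewords <- function(digits) {
  digits <- as.matrix(digits)
  if (!all(digits %in% 0:3)) stop("digits must be integers in 0..3")
  unname(apply(digits, 1L, function(d) paste(.BASES[d + 1L], collapse = "")))
}

#' Validate and canonicalize codeword strings
#'
#' Input is case-folded to uppercase; any symbol outside \{A, C, G, T\}
#' (including N, U and gap characters) is rejected, not coerced.
#'
#' @param x character vector.
#' @return uppercase character vector.
#' @export
as_codewords <- function(x) {
  if (length(x) == 0L) return(character(0))
  if (!is.character(x)) stop("codewords must be character strings")
  x <- toupper(x)
  bad <- grepl("[^ACGT]", x) | nchar(x) == 0L
  if (any(bad)) {
    stop("invalid codeword(s): ",
         paste(utils::head(x[bad], 5L), collapse = ", "),
         " (only A, C, G, T are accepted)")
  }
  x
}

# Order codewords lexicographically on their digits (T < C < G < A).
canonical_order <- function(x) order(chartr("TCGA", "0123", x), method = "radix")

#' Sort codewords into canonical order
#'
#' Canonical order is lexicographic on the integer digits (T < C < G < A),
#' used for deterministic output and set deduplication.
#'
#' @param x character vector of codewords.
#' @return sorted character vector.
#' @export
canonical_sort <- function(x) {
  x <- as_codewords(x)
  x[canonical_order(x)]
}

#' Constraint profile for a DNA storage code
#'
#' Bundles the codeword length `n`, the minimum pairwise Hamming distance
#' `d`, the exact GC weight `w` (number of G/C symbols each codeword must
#' carry) and whether the no-runlength (NRL, homopolymer-free) constraint is
#' enforced. Defaults reproduce the usual regime: `w = floor(n/2)` and NRL on.
#'
#' @param n codeword length, positive integer.
#' @param d minimum Hamming distance, integer in `[1, n]`.
#' @param w required GC count, integer in `[0, n]`; default `floor(n/2)`.
#' @param nrl logical; enforce the no-runlength constraint (default `TRUE`).
#' @return an object of class `constraint_profile`.
#' @examples
#' constraint_profile(9, 6)
#' @export
constraint_profile <- function(n, d, w = floor(n / 2), nrl = TRUE) {
  n <- as.integer(n); d <- as.integer(d); w <- as.integer(w)
  if (length(n) != 1L || is.na(n) || n < 1L) stop("n must be a positive integer")
  if (length(d) != 1L || is.na(d) || d < 1L || d > n)
    stop("d must be an integer in [1, n]; got d = ", d, ", n = ", n)
  if (length(w) != 1L || is.na(w) || w < 0L || w > n)
    stop("w must be an integer in [0, n]; got w = ", w, ", n = ", n)
  structure(list(n = n, d = d, w = w, nrl = isTRUE(nrl)),
            class = "constraint_profile")
}

#' @export
print.constraint_profile <- function(x, ...) {
  cat(sprintf("Constraint profile: n = %d, d = %d, w = %d, no-runlength %s\n",
              x$n, x$d, x$w, if (x$nrl) "on" else "off"))
  invisible(x)
}

#' Hamming distance between two codewords
#'
#' The number of positions at which the two equal-length sequences differ.
#'
#' @param a,b codeword strings of equal length.
#' @return non-negative integer.
#' @examples
#' hamming_distance("ATCTGCTCA", "ATCGAGATG")  # 6
#' @export
hamming_distance <- function(a, b) {
  a <- as_codewords(a); b <- as_codewords(b)
  if (length(a) != 1L || length(b) != 1L) stop("a and b must be single codewords")
  if (nchar(a) != nchar(b)) {
    stop("length mismatch: nchar(a) = ", nchar(a), ", nchar(b) = ", nchar(b))
  }
  sum(strsplit(a, "", fixed = TRUE)[[1L]] != strsplit(b, "", fixed = TRUE)[[1L]])
}

#' GC count and GC content of codewords
#'
#' `gc_count` returns the exact integer number of G and C symbols;
#' `gc_content` the derived ratio in `[0, 1]`. The integer count is the
#' stored quantity so validity never rests on float equality.
#'
#' @param x character vector of codewords.
#' @return integer vector (`gc_count`) or numeric vector (`gc_content`).
#' @examples
#' gc_count("ATCTGCTCA")  # 4
#' @export
gc_count <- function(x) {
  x <- as_codewords(x)
  if (length(x) == 0L) return(integer(0))
  vapply(strsplit(x, "", fixed = TRUE),
         function(s) sum(s %in% c("G", "C")), integer(1))
}

#' @rdname gc_count
#' @export
gc_content <- function(x) gc_count(x) / nchar(as_codewords(x))

#' No-runlength (homopolymer) check
#'
#' `TRUE` iff no two adjacent symbols are equal, i.e. the word contains no
#' homopolymer of length 2 or more.
#'
#' @param x character vector of codewords.
#' @return logical vector.
#' @examples
#' has_no_runlength("TCCCCAC")   # FALSE: the C run
#' has_no_runlength("TAGCTAGCT") # TRUE
#' @export
has_no_runlength <- function(x) {
  x <- as_codewords(x)
  if (length(x) == 0L) return(logical(0))
  vapply(strsplit(x, "", fixed = TRUE), function(s) {
    length(s) == 1L || all(s[-1L] != s[-length(s)])
  }, logical(1))
}

#' Per-word validity under a constraint profile
#'
#' A codeword is valid iff its GC count equals `p$w` and, when the profile
#' enforces no-runlength, it contains no adjacent repeat. The pairwise
#' distance requirement is a property of sets, not single words.
#'
#' @param x character vector of codewords of length `p$n`.
#' @param p a [constraint_profile()].
#' @return logical vector.
#' @export
is_valid_codeword <- function(x, p) {
  stopifnot(inherits(p, "constraint_profile"))
  x <- as_codewords(x)
  if (length(x) == 0L) return(logical(0))
  if (any(nchar(x) != p$n)) {
    stop("length mismatch: codeword length(s) ",
         paste(unique(nchar(x)[nchar(x) != p$n]), collapse = ", "),
         " but profile n = ", p$n)
  }
  ok <- gc_count(x) == p$w
  if (p$nrl) ok <- ok & has_no_runlength(x)
  ok
}

#' DNA code set
#'
#' A collection of distinct codewords attached to a [constraint_profile()].
#' Members are stored in canonical order (lexicographic on digits,
#' T < C < G < A). With `validate = TRUE` every member must pass per-word
#' validity and every unordered pair must be at Hamming distance `>= d`.
#'
#' @param words character vector of codewords.
#' @param profile a [constraint_profile()].
#' @param validate check full code validity at construction (default `TRUE`).
#' @return an object of class `code_set` with fields `words` and `profile`.
#' @examples
#' code_set(c("GA", "CT", "AG", "TC"), constraint_profile(2, 2, 1))
#' @export
code_set <- function(words, profile, validate = TRUE) {
  stopifnot(inherits(profile, "constraint_profile"))
  words <- as_codewords(words)
  if (anyDuplicated(words)) stop("duplicate codewords in code set")
  if (length(words) > 0 && any(nchar(words) != profile$n)) {
    stop("codeword length(s) ", paste(unique(nchar(words)), collapse = ", "),
         " do not match profile n = ", profile$n)
  }
  words <- canonical_sort(words)
  s <- structure(list(words = words, profile = profile, validated = FALSE),
                 class = "code_set")
  if (validate) {
    if (!is_valid_code(s)) stop("code set violates its constraint profile")
    s$validated <- TRUE
  }
  s
}

#' @export
print.code_set <- function(x, ...) {
  p <- x$profile
  cat(sprintf("DNA code set: %d codeword(s), n = %d, d = %d, w = %d, NRL %s%s\n",
              length(x$words), p$n, p$d, p$w, if (p$nrl) "on" else "off",
              if (isTRUE(x$validated)) " [validated]" else ""))
  if (length(x$words)) {
    show <- utils::head(x$words, 6L)
    cat("  ", paste(show, collapse = " "),
        if (length(x$words) > 6L) "..." else "", "\n")
  }
  invisible(x)
}

#' @export
length.code_set <- function(x) length(x$words)

#' Minimum pairwise Hamming distance of a set
#'
#' Returns the smallest Hamming distance over all unordered pairs. For fewer
#' than two members there are no pairs and the distinguished sentinel
#' `NA_integer_` is returned -- callers must handle the degenerate case
#' explicitly rather than compare against an artificial large number.
#'
#' @param S a `code_set` or character vector of equal-length codewords.
#' @return integer, or `NA_integer_` when `|S| < 2`.
#' @export
min_pairwise_distance <- function(S) {
  words <- if (inherits(S, "code_set")) S$words else as_codewords(S)
  if (length(words) < 2L) return(NA_integer_)
  dig <- codeword_digits(words)  # errors on mixed lengths
  m <- nrow(dig)
  dmin <- ncol(dig)
  for (i in seq_len(m - 1L)) {
    di <- dig[(i + 1L):m, , drop = FALSE]
    h <- rowSums(di != matrix(dig[i, ], nrow = nrow(di), ncol = ncol(dig),
                              byrow = TRUE))
    dmin <- min(dmin, h)
  }
  as.integer(dmin)
}

#' Full code validity
#'
#' `TRUE` iff every member passes [is_valid_codeword()] and the minimum
#' pairwise distance is at least the profile's `d` (vacuously true for sets
#' of size 0 or 1).
#'
#' @param S a `code_set`, or a character vector together with `profile`.
#' @param profile a [constraint_profile()] (ignored when `S` is a `code_set`).
#' @return logical scalar.
#' @export
is_valid_code <- function(S, profile = NULL) {
  if (inherits(S, "code_set")) {
    words <- S$words
    profile <- S$profile
  } else {
    stopifnot(inherits(profile, "constraint_profile"))
    words <- as_codewords(S)
  }
  if (length(words) == 0L) return(TRUE)
  if (any(nchar(words) != profile$n)) return(FALSE)
  if (!all(is_valid_codeword(words, profile))) return(FALSE)
  if (length(words) < 2L) return(TRUE)
  min_pairwise_distance(words) >= profile$d
}

#' Distance-sum fitness of a candidate against a code set
#'
#' The fitness used by the EORS search: the sum of Hamming distances from
#' the candidate `s` to every member of `S`. Larger values mark candidates
#' far from the current set, hence more likely insertable. Defined as 0 for
#' an empty set, so the first candidate is always accepted.
#'
#' @param s a single codeword.
#' @param S a `code_set` or character vector of codewords of equal length.
#' @return non-negative integer.
#' @export
code_fitness <- function(s, S) {
  words <- if (inherits(S, "code_set")) S$words else as_codewords(S)
  s <- as_codewords(s)
  if (length(s) != 1L) stop("s must be a single codeword")
  if (length(words) == 0L) return(0L)
  if (any(nchar(words) != nchar(s))) {
    stop("length mismatch: candidate has length ", nchar(s),
         ", set has length ", paste(unique(nchar(words)), collapse = ", "))
  }
  dig <- codeword_digits(words)
  sd <- codeword_digits(s)
  as.integer(sum(dig != matrix(sd, nrow = nrow(dig), ncol = ncol(dig),
                               byrow = TRUE)))
}

#' Coding rate of a code
#'
#' The information per base relative to the unconstrained quaternary
#' alphabet: `R = log4(M) / n` for a code of `M` words of length `n`.
#'
#' @param M code set size, `>= 1`.
#' @param n codeword length, `>= 1`.
#' @return numeric rate.
#' @examples
#' coding_rate(110, 8)  # ~0.42
#' @export
coding_rate <- function(M, n) {
  if (any(M < 1) || any(n < 1)) stop("coding_rate requires M >= 1 and n >= 1")
  log(M, base = 4) / n
}
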