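# Random-search (RS) augmentation stage: random valid candidates are tested
# against the current set; compatible ones are inserted, and a candidate
# conflicting with exactly one member replaces that member (the swap rule).

#' Random-search parameters
#'
#' @param budget total number of valid candidate draws tested (default 1e5);
#'   governs termination.
#' @param batch candidates sampled per round (default 1000).
#' @param seed optional RNG seed for a reproducible run.
#' @return an object of class `rs_params`.
#' @export
rs_params <- function(budget = 100000L, batch = 1000L, seed = NULL) {
  budget <- as.integer(budget); batch <- as.integer(batch)
  if (budget < 0L) stop("budget must be non-negative")
  if (batch < 1L) stop("batch must be positive")
  structure(list(budget = budget, batch = batch, seed = seed),
            class = "rs_params")
}

# Sample m valid codewords as a digit matrix: choose w GC positions uniformly
# among placements, assign G/C and A/T letters uniformly, and resample rows
# violating no-runlength (rejection within the GC-feasible stratum).
sample_valid_digits <- function(profile, m) {
  n <- profile$n; w <- profile$w
  out <- matrix(0L, nrow = 0L, ncol = n)
  while (nrow(out) < m) {
    need <- m - nrow(out)
    gc_mask <- matrix(FALSE, nrow = need, ncol = n)
    for (i in seq_len(need)) {
      gc_mask[i, sample.int(n, w)] <- TRUE
    }
    u <- matrix(stats::runif(need * n) > 0.5, nrow = need)
    # GC stratum: C=1 or G=2; AT stratum: T=0 or A=3
    dig <- ifelse(gc_mask, ifelse(u, 2L, 1L), ifelse(u, 3L, 0L))
    if (profile$nrl && n > 1L) {
      ok <- rowSums(dig[, -1L, drop = FALSE] ==
                    dig[, -n, drop = FALSE]) == 0L
      dig <- dig[ok, , drop = FALSE]
    }
    out <- rbind(out, dig)
  }
  out[seq_len(m), , drop = FALSE]
}

#' Sample a uniformly random valid codeword
#'
#' Constructive sampler: `w` GC positions are chosen uniformly among
#' placements, G/C and A/T letters assigned uniformly, and draws violating
#' the no-runlength constraint are rejected and resampled. Every output
#' passes [is_valid_codeword()].
#'
#' @param profile a [constraint_profile()].
#' @param m number of codewords to draw (default 1).
#' @return character vector of `m` codewords.
#' @export
sample_valid_codeword <- function(profile, m = 1L) {
  stopifnot(inherits(profile, "constraint_profile"))
  digits_to_codewords(sample_valid_digits(profile, as.integer(m)))
}

#' Conflicting members of a set for a candidate
#'
#' The members of `S` at Hamming distance `< d` from `s`. An empty result
#' means `s` is insertable; a candidate already in the set conflicts with
#' itself (distance 0).
#'
#' @param s a single codeword.
#' @param S a `code_set`, or character vector plus `profile`.
#' @param profile a [constraint_profile()] (ignored when `S` is a `code_set`).
#' @return character vector of conflicting members.
#' @export
conflicts <- function(s, S, profile = NULL) {
  if (inherits(S, "code_set")) {
    words <- S$words; profile <- S$profile
  } else {
    stopifnot(inherits(profile, "constraint_profile"))
    words <- as_codewords(S)
  }
  s <- as_codewords(s)
  if (length(s) != 1L) stop("s must be a single codeword")
  if (length(words) == 0L) return(character(0))
  if (any(nchar(words) != nchar(s))) {
    stop("length mismatch: candidate has length ", nchar(s),
         ", set member length ", paste(unique(nchar(words)), collapse = ", "))
  }
  h <- hamming_to_set(codeword_digits(s)[1L, ], codeword_digits(words))
  words[h < profile$d]
}

# One candidate application on a digit matrix: insert when conflict-free,
# swap when exactly one member conflicts, discard otherwise.
rs_step_digits <- function(set_digits, cand, d) {
  h <- hamming_to_set(cand, set_digits)
  k <- which(h < d)
  if (length(k) == 0L) {
    rbind(set_digits, cand)
  } else if (length(k) == 1L) {
    set_digits[k, ] <- cand
    set_digits
  } else {
    set_digits
  }
}

#' Apply one random-search candidate to a code set
#'
#' The elementary move of the augmentation pass: if `s` conflicts with no
#' member it is inserted; if it conflicts with exactly one member, that
#' member is deleted and `s` inserted (size-neutral swap); otherwise the set
#' is returned unchanged. Exposed so the per-step validity invariant can be
#' checked externally.
#'
#' @param S a validated `code_set`.
#' @param s a single valid codeword.
#' @return the updated `code_set`.
#' @export
rs_step <- function(S, s) {
  stopifnot(inherits(S, "code_set"))
  s <- as_codewords(s)
  dig <- rs_step_digits(codeword_digits(S$words), codeword_digits(s)[1L, ],
                        S$profile$d)
  code_set(digits_to_codewords(dig), S$profile)
}

#' Random-search augmentation of a code set
#'
#' Expands `S_EO` into the final set `S_BS`: until the draw budget is
#' exhausted, batches of uniformly random valid codewords are tested one by
#' one; a conflict-free candidate is inserted, a single-conflict candidate
#' replaces its conflicting member, and anything else is discarded. The set
#' size never decreases and the set remains a valid code after every
#' individual move.
#'
#' @param S a validated `code_set` (the EO output; may be empty).
#' @param params an [rs_params()]; `params$seed`, when set, seeds the run.
#' @return a validated `code_set` (`S_BS`) with `length >= length(S)`.
#' @export
rs_augment <- function(S, params = rs_params()) {
  stopifnot(inherits(S, "code_set"), inherits(params, "rs_params"))
  if (!is_valid_code(S)) stop("input set is not a valid code")
  if (!is.null(params$seed)) set.seed(params$seed)
  profile <- S$profile
  set_digits <- codeword_digits(S$words)
  if (length(S$words) == 0L) {
    set_digits <- matrix(integer(0), nrow = 0L, ncol = profile$n)
  }
  drawn <- 0L
  while (drawn < params$budget) {
    m <- min(params$batch, params$budget - drawn)
    cand <- sample_valid_digits(profile, m)
    for (i in seq_len(m)) {
      set_digits <- rs_step_digits(set_digits, cand[i, ], profile$d)
    }
    drawn <- drawn + m
  }
  code_set(digits_to_codewords(set_digits), profile)
}

#' Full EORS pipeline
#'
#' Runs the EO stage ([eo_search()]) and then the random-search augmentation
#' ([rs_augment()]). The two stages consume independent RNG streams derived
#' from one master seed, so each stage is reproducible in isolation.
#'
#' @param profile a [constraint_profile()].
#' @param eo an [eo_params()].
#' @param rs an [rs_params()].
#' @param seed master seed; when set, overrides the per-stage seeds.
#' @return a validated `code_set` with attributes `"size_eo"` (size after
#'   the EO stage) and `"seeds"` (the derived per-stage seeds).
#' @export
eors_search <- function(profile, eo = eo_params(), rs = rs_params(),
                        seed = NULL) {
  stopifnot(inherits(profile, "constraint_profile"))
  if (!is.null(seed)) {
    set.seed(as.integer(seed))
    derived <- sample.int(.Machine$integer.max - 1L, 2L)
    eo$seed <- derived[1L]
    rs$seed <- derived[2L]
  }
  s_eo <- eo_search(profile, eo)
  s_bs <- rs_augment(s_eo, rs)
  attr(s_bs, "size_eo") <- length(s_eo)
  attr(s_bs, "seeds") <- c(eo = eo$seed, rs = rs$seed)
  s_bs
}
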