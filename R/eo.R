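# Equilibrium-optimizer (EO) stage: a population of continuous
# "concentration" vectors in [0,3]^n relaxes toward an equilibrium pool of
# the best particles; decoded particles seed and grow the code set S_EO.

# Concentration bounds shared by the whole EO stage: one coordinate per
# codeword position, spanning the digit range T=0 .. A=3.
.C_MIN <- 0
.C_MAX <- 3

#' Equilibrium-optimizer parameters
#'
#' Defaults follow the original equilibrium-optimizer settings: exploration
#' constant `a1 = 2`, exploitation constant `a2 = 1`, generation-rate
#' probability `RP = 0.5` and unit volume `V = 1`.
#'
#' @param pop_size number of particles (default 50).
#' @param t_max iteration (sweep) budget (default 1000).
#' @param a1 exploration constant (default 2).
#' @param a2 exploitation constant (default 1).
#' @param RP generation-rate probability threshold in `[0, 1]` (default 0.5).
#' @param V volume constant (default 1).
#' @param seed optional RNG seed for a reproducible run.
#' @return an object of class `eo_params`.
#' @export
eo_params <- function(pop_size = 50L, t_max = 1000L, a1 = 2, a2 = 1,
                      RP = 0.5, V = 1, seed = NULL) {
  pop_size <- as.integer(pop_size); t_max <- as.integer(t_max)
  if (pop_size < 1L) stop("pop_size must be positive")
  if (t_max < 0L) stop("t_max must be non-negative")
  if (a1 <= 0 || a2 <= 0 || V <= 0) stop("a1, a2, V must be positive")
  if (RP < 0 || RP > 1) stop("RP must lie in [0, 1]")
  structure(list(pop_size = pop_size, t_max = t_max, a1 = a1, a2 = a2,
                 RP = RP, V = V, seed = seed),
            class = "eo_params")
}

#' Initialize the EO population
#'
#' Each of the `pop_size` particles is an n-vector with coordinates drawn
#' uniformly on `[0, 3]` from the current RNG stream.
#'
#' @param params an [eo_params()].
#' @param profile a [constraint_profile()].
#' @return numeric matrix, `pop_size` rows by `n` columns.
#' @export
initialize_population <- function(params, profile) {
  stopifnot(inherits(params, "eo_params"), inherits(profile, "constraint_profile"))
  matrix(.C_MIN + (.C_MAX - .C_MIN) * stats::runif(params$pop_size * profile$n),
         nrow = params$pop_size, ncol = profile$n)
}

#' EO time parameter
#'
#' The iteration-dependent decay `t = (1 - iter/t_max)^(a2 * iter/t_max)`,
#' equal to 1 at the start of the run and 0 at the final sweep.
#'
#' @param iter current iteration in `[0, t_max]`.
#' @param params an [eo_params()].
#' @return numeric scalar.
#' @export
time_parameter <- function(iter, params) {
  stopifnot(inherits(params, "eo_params"))
  frac <- iter / params$t_max
  (1 - frac)^(params$a2 * frac)
}

#' EO exponential balance term F
#'
#' `F = a1 * sign(r - 0.5) * (exp(-lambda * t) - 1)`, the closed form of the
#' exploration/exploitation factor: each coordinate lies in `(-a1, a1)` and
#' vanishes at `t = 0`.
#'
#' @param lambda numeric vector of turnover rates in `(0, 1)`.
#' @param t scalar time parameter from [time_parameter()].
#' @param params an [eo_params()].
#' @param r numeric vector of uniform draws in `(0, 1)`.
#' @return numeric vector F.
#' @export
exponential_term <- function(lambda, t, params, r) {
  stopifnot(inherits(params, "eo_params"))
  params$a1 * sign(r - 0.5) * (exp(-lambda * t) - 1)
}

#' EO generation rate R
#'
#' The generation-rate control `RCP` is `0.5 * r1` when `r2 > RP` and 0
#' otherwise; then `R0 = RCP * (c_eq - lambda * c)` and `R = R0 * F`.
#'
#' @param lambda numeric vector of turnover rates.
#' @param conc particle concentration vector.
#' @param c_eq equilibrium candidate concentration vector.
#' @param F balance term from [exponential_term()].
#' @param r1,r2 scalar uniform draws in `[0, 1]`.
#' @param params an [eo_params()].
#' @return numeric vector R.
#' @export
generation_rate <- function(lambda, conc, c_eq, F, r1, r2, params) {
  stopifnot(inherits(params, "eo_params"))
  rcp <- if (r2 > params$RP) 0.5 * r1 else 0
  rcp * (c_eq - lambda * conc) * F
}

# Build the equilibrium pool from the population: the four best particles by
# fitness (ties broken by particle index) plus their coordinate-wise mean.
equilibrium_pool <- function(pop, fitness) {
  k <- min(4L, nrow(pop))
  ord <- order(-fitness, seq_along(fitness))[seq_len(k)]
  best4 <- pop[ord, , drop = FALSE]
  rbind(best4, colMeans(best4))
}

#' One EO concentration update
#'
#' Draws an equilibrium candidate uniformly from the five-member pool,
#' fresh per-coordinate `lambda` and `r` vectors and scalar `r1`, `r2`, and
#' applies `c <- c_eq + (c - c_eq)*F + R/(lambda*V)*(1 - F)`, clamped to
#' `[0, 3]`. Consumes the current RNG stream.
#'
#' @param conc particle concentration vector.
#' @param pool matrix of pool candidates (rows), as built by `eo_search`.
#' @param iter current iteration.
#' @param params an [eo_params()].
#' @return updated concentration vector.
#' @export
update_concentration <- function(conc, pool, iter, params) {
  stopifnot(inherits(params, "eo_params"))
  n <- length(conc)
  c_eq <- pool[sample.int(nrow(pool), 1L), ]
  # lambda bounded away from 0: it divides the generation-rate term
  lambda <- pmax(stats::runif(n), 1e-12)
  r <- stats::runif(n)
  r1 <- stats::runif(1L)
  r2 <- stats::runif(1L)
  t <- time_parameter(iter, params)
  F <- exponential_term(lambda, t, params, r)
  R <- generation_rate(lambda, conc, c_eq, F, r1, r2, params)
  out <- c_eq + (conc - c_eq) * F + R / (lambda * params$V) * (1 - F)
  pmin(.C_MAX, pmax(.C_MIN, out))
}

#' Decode a concentration vector to a valid codeword
#'
#' Coordinates are rounded to the nearest digit in \{0,1,2,3\} (ties round
#' half up) and mapped to bases (T=0, C=1, G=2, A=3); a deterministic
#' two-phase repair then enforces per-word validity so no particle is wasted
#' on rejection:
#'
#' 1. GC weight: while the count of \{C,G\} positions differs from `w`, flip
#'    the class of the position whose coordinate sits closest to the target
#'    class on the digit line (ties toward the smaller index).
#' 2. No-runlength: scan left to right; each position keeps its rounded
#'    digit when it lies in the assigned class and differs from its left
#'    neighbour, otherwise it takes the in-class digit nearest the original
#'    coordinate that differs from the left neighbour (ties toward the
#'    smaller digit). Each class holds two digits, so a feasible choice
#'    always exists.
#'
#' The repair is the identity on already-valid words and idempotent.
#'
#' @param conc numeric vector with coordinates in `[0, 3]`.
#' @param profile a [constraint_profile()].
#' @return a single codeword string.
#' @examples
#' decode_particle(c(0.2, 1.6, 2.4, 3.7), constraint_profile(4, 1, 2))
#' @export
decode_particle <- function(conc, profile) {
  stopifnot(inherits(profile, "constraint_profile"))
  n <- profile$n
  if (length(conc) != n) {
    stop("concentration length ", length(conc), " does not match n = ", n)
  }
  dig <- pmin(3L, pmax(0L, as.integer(floor(conc + 0.5))))
  is_gc <- dig == 1L | dig == 2L
  # phase 1: fix the GC/AT class pattern at minimal coordinate perturbation
  while ((ct <- sum(is_gc)) != profile$w) {
    if (ct < profile$w) {
      from <- which(!is_gc)
      cost <- pmin(abs(conc[from] - 1), abs(conc[from] - 2))
    } else {
      from <- which(is_gc)
      cost <- pmin(abs(conc[from]), abs(conc[from] - 3))
    }
    i <- from[order(cost, from)][1L]
    is_gc[i] <- !is_gc[i]
  }
  # phase 2: assign in-class digits left to right, avoiding adjacent repeats
  for (i in seq_len(n)) {
    cls <- if (is_gc[i]) c(1L, 2L) else c(0L, 3L)
    keep <- dig[i] %in% cls &&
      (!profile$nrl || i == 1L || dig[i] != dig[i - 1L])
    if (!keep) {
      cand <- cls[order(abs(cls - conc[i]), cls)]
      if (profile$nrl && i > 1L) cand <- cand[cand != dig[i - 1L]]
      dig[i] <- cand[1L]
    }
  }
  digits_to_codewords(matrix(dig, nrow = 1L))
}

# Hamming distances from one digit vector to each row of a digit matrix.
hamming_to_set <- function(dig_row, set_digits) {
  if (nrow(set_digits) == 0L) return(integer(0))
  rowSums(set_digits != matrix(dig_row, nrow = nrow(set_digits),
                               ncol = length(dig_row), byrow = TRUE))
}

#' Equilibrium-optimizer code-set search
#'
#' Runs the EO stage: the population is initialized uniformly on `[0,3]^n`
#' and the best decoded particle seeds the set `S_EO`; each sweep evaluates
#' the distance-sum fitness of every decoded particle against the current
#' set, rebuilds the equilibrium pool from the four best, updates all
#' particles, then greedily inserts any decoded word compatible (Hamming
#' `>= d`) with every member. Insertion-only, so the set size never
#' decreases.
#'
#' @param profile a [constraint_profile()].
#' @param params an [eo_params()]; `params$seed`, when set, seeds the run.
#' @param trace logical; attach a per-sweep log (iteration, pool best
#'   fitness, set size) as attribute `"trace"`.
#' @return a validated [code_set()] (`S_EO`).
#' @export
eo_search <- function(profile, params = eo_params(), trace = FALSE) {
  stopifnot(inherits(profile, "constraint_profile"), inherits(params, "eo_params"))
  if (!is.null(params$seed)) set.seed(params$seed)
  n <- profile$n
  pop <- initialize_population(params, profile)
  decode_all <- function(pop) {
    words <- vapply(seq_len(nrow(pop)),
                    function(i) decode_particle(pop[i, ], profile),
                    character(1))
    codeword_digits(words)
  }
  dec <- decode_all(pop)
  # seed S_EO with the best initial decoded word; against an empty set all
  # fitness values are 0, so the tie goes to the first particle
  set_digits <- dec[1L, , drop = FALSE]
  log_rows <- vector("list", params$t_max)
  for (iter in seq_len(params$t_max)) {
    fit <- vapply(seq_len(params$pop_size),
                  function(i) sum(hamming_to_set(dec[i, ], set_digits)),
                  numeric(1))
    pool <- equilibrium_pool(pop, fit)
    for (i in seq_len(params$pop_size)) {
      pop[i, ] <- update_concentration(pop[i, ], pool, iter, params)
    }
    dec <- decode_all(pop)
    for (i in seq_len(params$pop_size)) {
      if (all(hamming_to_set(dec[i, ], set_digits) >= profile$d)) {
        set_digits <- rbind(set_digits, dec[i, ])
      }
    }
    if (trace) {
      log_rows[[iter]] <- data.frame(iter = iter, best_fitness = max(fit),
                                     set_size = nrow(set_digits))
    }
  }
  out <- code_set(unique(digits_to_codewords(set_digits)), profile)
  if (trace) attr(out, "trace") <- do.call(rbind, log_rows)
  out
}
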