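# Exact ground truth for small instances: exhaustive enumeration of valid
# codewords, the compatibility (conflict) graph, exact maximum clique by
# branch and bound, and a randomized-greedy baseline.

#' Enumerate all valid codewords of a profile
#'
#' Depth-first generation over digit prefixes with GC-count pruning, so only
#' feasible branches of the 4^n tree are visited. Output is in canonical
#' order (lexicographic on digits, T < C < G < A) and duplicate-free.
#'
#' @param profile a [constraint_profile()] (its `d` is ignored here).
#' @param guard maximum `n` accepted (default 12); beyond it the heuristic
#'   path should be used instead.
#' @return character vector of all valid codewords, canonically ordered.
#' @examples
#' enumerate_valid_codewords(constraint_profile(2, 1, 1))  # 8 words
#' @export
enumerate_valid_codewords <- function(profile, guard = 12L) {
  stopifnot(inherits(profile, "constraint_profile"))
  n <- profile$n; w <- profile$w
  if (n > guard) {
    stop("n = ", n, " exceeds the enumeration guard (", guard,
         "); use the heuristic search path instead")
  }
  # level-wise extension: rows are digit prefixes, tracked with GC counts
  pre <- matrix(0:3, ncol = 1L)
  gc <- as.integer(pre[, 1L] %in% 1:2)
  keep <- gc <= w & gc + (n - 1L) >= w
  pre <- pre[keep, , drop = FALSE]; gc <- gc[keep]
  if (n > 1L) {
    for (j in 2:n) {
      blocks <- vector("list", 4L)
      for (d in 0:3) {
        g <- gc + as.integer(d %in% 1:2)
        ok <- g <= w & g + (n - j) >= w
        if (profile$nrl) ok <- ok & pre[, j - 1L] != d
        blocks[[d + 1L]] <- cbind(pre[ok, , drop = FALSE], d,
                                  deparse.level = 0L)
        attr(blocks[[d + 1L]], "gc") <- g[ok]
      }
      pre <- do.call(rbind, blocks)
      gc <- unlist(lapply(blocks, attr, "gc"))
    }
  }
  words <- digits_to_codewords(pre)
  canonical_sort(words)
}

#' Compatibility (conflict) graph of all valid codewords
#'
#' Vertices are the enumerated valid codewords in canonical order; an edge
#' joins `u`, `v` iff their Hamming distance is at least `d` (the pair is
#' compatible). A code set under the profile is exactly a clique.
#'
#' @param profile a [constraint_profile()].
#' @param guard enumeration guard forwarded to [enumerate_valid_codewords()].
#' @return an object of class `conflict_graph` with fields `words`,
#'   `profile` and the logical adjacency matrix `adj`.
#' @export
build_conflict_graph <- function(profile, guard = 12L) {
  words <- enumerate_valid_codewords(profile, guard = guard)
  dig <- codeword_digits(words)
  v <- length(words)
  h <- matrix(0L, v, v)
  for (j in seq_len(profile$n)) {
    h <- h + outer(dig[, j], dig[, j], "!=")
  }
  adj <- h >= profile$d
  diag(adj) <- FALSE
  dimnames(adj) <- list(words, words)
  structure(list(words = words, profile = profile, adj = adj),
            class = "conflict_graph")
}

#' @export
print.conflict_graph <- function(x, ...) {
  cat(sprintf("Compatibility graph: %d valid codewords, %d edges (n = %d, d = %d, w = %d)\n",
              length(x$words), sum(x$adj) / 2L,
              x$profile$n, x$profile$d, x$profile$w))
  invisible(x)
}

# Greedy sequential coloring of the vertices `P` (indices into adj), in the
# given order; returns the color of each vertex. The number of colors bounds
# the clique number of the induced subgraph.
greedy_color <- function(adj, P) {
  m <- length(P)
  cols <- integer(m)
  for (i in seq_len(m)) {
    prev <- seq_len(i - 1L)
    nb <- cols[prev][adj[P[i], P[prev]]]
    col <- 1L
    while (col %in% nb) col <- col + 1L
    cols[i] <- col
  }
  cols
}

#' Exact maximum clique of a compatibility graph
#'
#' Branch-and-bound maximum-clique search with greedy-coloring upper bounds;
#' vertices are processed in canonical order with deterministic tie-breaks,
#' so the returned clique (not just its size) is reproducible. The clique
#' size is the exact optimum `A^{GC,NL}(n, d, w)` for the profile.
#'
#' @param g a `conflict_graph` from [build_conflict_graph()].
#' @param guard maximum vertex count accepted (default 2000).
#' @param force bypass the guard (exact search may then be very slow).
#' @return a validated [code_set()] realizing the maximum.
#' @export
max_clique_exact <- function(g, guard = 2000L, force = FALSE) {
  stopifnot(inherits(g, "conflict_graph"))
  v <- length(g$words)
  if (v > guard && !force) {
    stop(v, " vertices exceed the exact-search guard (", guard,
         "); use the greedy/heuristic path or force = TRUE")
  }
  if (v == 0L) return(code_set(character(0), g$profile))
  adj <- g$adj
  best <- integer(0)
  expand <- function(R, P) {
    if (length(P) == 0L) {
      if (length(R) > length(best)) best <<- R
      return(invisible())
    }
    cols <- greedy_color(adj, P)
    o <- order(cols, P)
    P <- P[o]; cols <- cols[o]
    for (k in rev(seq_along(P))) {
      if (length(R) + cols[k] <= length(best)) return(invisible())
      vk <- P[k]
      cand <- P[seq_len(k - 1L)]
      cand <- cand[adj[vk, cand]]
      expand(c(R, vk), cand)
    }
  }
  expand(integer(0), seq_len(v))
  code_set(g$words[best], g$profile)
}

#' Randomized-greedy baseline code construction
#'
#' Enumerates all valid codewords, then over `restarts` independent random
#' permutations greedily inserts each word compatible with everything chosen
#' so far, keeping the largest maximal set found. A cheap benchmark floor
#' for the EORS heuristic; its size never exceeds the exact optimum.
#'
#' @param profile a [constraint_profile()].
#' @param restarts number of random restarts (default 10).
#' @param seed optional RNG seed.
#' @param guard enumeration guard forwarded to [enumerate_valid_codewords()].
#' @return a validated `code_set`.
#' @export
greedy_random_baseline <- function(profile, restarts = 10L, seed = NULL,
                                   guard = 12L) {
  stopifnot(inherits(profile, "constraint_profile"))
  if (!is.null(seed)) set.seed(seed)
  words <- enumerate_valid_codewords(profile, guard = guard)
  dig <- codeword_digits(words)
  best <- integer(0)
  for (r in seq_len(max(1L, as.integer(restarts)))) {
    perm <- sample.int(length(words))
    chosen <- matrix(integer(0), nrow = 0L, ncol = profile$n)
    idx <- integer(0)
    for (i in perm) {
      if (all(hamming_to_set(dig[i, ], chosen) >= profile$d)) {
        chosen <- rbind(chosen, dig[i, ])
        idx <- c(idx, i)
      }
    }
    if (length(idx) > length(best)) best <- idx
  }
  code_set(words[best], profile)
}
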