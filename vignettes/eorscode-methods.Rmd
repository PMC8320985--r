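---
title: "Constructing constrained DNA storage codes with eorscode"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constructing constrained DNA storage codes with eorscode}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eorscode)
```

## The problem

DNA data storage encodes digital information in synthesized
oligonucleotides. Errors arise in synthesis and sequencing, and similar
strands cross-hybridize in solution, so the *codewords* — the fixed-length
sequences that carry addresses or payload blocks — are designed under joint
combinatorial constraints:

* **Hamming distance**: every unordered pair of codewords differs in at
  least $d$ positions, giving error-detection margin and suppressing
  non-specific hybridization;
* **GC weight**: every codeword contains exactly $w$ symbols from
  $\{G, C\}$ (here $w = \lfloor n/2 \rfloor$ by default), keeping melting
  temperature and synthesis behaviour uniform;
* **no-runlength (NRL)**: no two adjacent bases are equal, because
  homopolymers are misread as shorter or longer runs.

A set of $M$ length-$n$ words meeting all three is a code whose size lower
bounds $A^{GC,NL}(n, d, w)$, the maximum achievable size. Larger $M$ at
fixed $n$ means a higher coding rate $R = \log_4(M)/n$ — more stored
information per synthesized base.

`eorscode` constructs such codes three ways: an **exact** branch-and-bound
maximum-clique search over the compatibility graph of all valid words
(small $n$), a **randomized-greedy** baseline, and the **EORS** heuristic —
an equilibrium-optimizer population search followed by random-search
augmentation — which scales past the reach of the exact oracle.

## The EORS heuristic

### Equilibrium-optimizer stage

Each particle is a concentration vector $c \in [0,3]^n$, one coordinate per
codeword position on the digit line $T=0, C=1, G=2, A=3$. The population
(default 50) initializes uniformly at random. Each sweep $iter = 1 \dots
t_{max}$:

1. every decoded particle is scored by the distance-sum fitness
   $\sum_{s_i \in S} H(s, s_i)$ against the current set $S$ — fitness is
   *maximized*: high-sum particles sit far from the set and are the likely
   insertable ones;
2. the **equilibrium pool** is rebuilt: the four best particles plus their
   coordinate-wise mean;
3. every particle moves toward a pool candidate $c_{eq}$ drawn uniformly
   from the five:
   $c \leftarrow c_{eq} + (c - c_{eq})F + \frac{R}{\lambda V}(1 - F)$,
   with $F = a_1\,\mathrm{sign}(r - 0.5)(e^{-\lambda t} - 1)$,
   $t = (1 - iter/t_{max})^{a_2\,iter/t_{max}}$, and generation rate
   $R = 0.5\,r_1 (c_{eq} - \lambda c) F$ applied only when $r_2 > RP$;
4. after the sweep, any decoded word compatible (distance $\ge d$) with
   every member of $S$ is inserted. Insertion-only, so $|S|$ never
   decreases.

Parameters and defaults: $a_1 = 2$ (exploration), $a_2 = 1$
(exploitation), $RP = 0.5$, $V = 1$ — the standard equilibrium-optimizer
settings. $\lambda$ and $r$ are fresh per-coordinate uniform draws per
particle per sweep; $r_1, r_2$ fresh scalars. These granularities are a
design choice (the update rules do not fix them); $\lambda$ is bounded
below by $10^{-12}$ because it divides the generation-rate term.
Coordinates are clamped to $[0,3]$ after every update. Termination is a
fixed sweep budget `t_max`; there is no adaptive stop.

### Decoding and repair

The continuous-to-discrete mapping is a design decision. Rounding alone
wastes most particles on invalid words, so decoding rounds each coordinate
to the nearest digit (ties half up) and then applies a deterministic
two-phase repair:

1. **class pattern**: while the count of $\{C,G\}$ positions differs from
   $w$, flip the class of the position whose coordinate is closest to the
   target class (ties toward the smaller index);
2. **digit assignment**: left to right, keep the rounded digit when it lies
   in its assigned class and differs from its left neighbour; otherwise
   take the in-class digit nearest the coordinate that differs from the
   left neighbour (ties toward the smaller digit). Each class holds two
   digits, so a feasible digit always exists.

An earlier variant (fix NRL first, then flip single positions for GC,
re-checking NRL) can dead-end: an A/T position flanked by C and G admits no
GC-class flip at all. The two-phase order is total, keeps the repair
identity on already-valid words, and is idempotent — both properties are
tested. Example: $(0.2, 1.6, 2.4, 3.7)$ rounds to $(0,2,2,3)$ and repairs
to `TGCA`.

### Random-search augmentation

The EO output $S_{EO}$ seeds a second stage: draw batches of uniformly
random *valid* words (choose $w$ GC positions uniformly, assign G/C and A/T
letters uniformly, reject NRL violations within that stratum); for each
candidate $s$,

* no member of $S$ conflicts ($H < d$) — insert $s$;
* exactly one member conflicts — delete it and insert $s$ (the swap is
  size-neutral but relocates the set, escaping local packings);
* otherwise discard $s$.

A candidate equal to a member conflicts with itself, so duplicates are
never double-inserted. Termination is a fixed draw budget (default
$10^5$), making cost deterministic and runs seed-reproducible. The set
remains a valid code after *every* individual move, and never shrinks; both
are tested by instrumenting the elementary step (`rs_step`).

The EO and RS stages consume independent RNG streams derived from one
master seed (`eors_search(seed = )`), so each stage is testable in
isolation and a full run is reproducible end to end.

## The exact oracle

For small instances the package enumerates every valid word (guard
$n \le 12$), builds the compatibility graph — vertices are valid words,
edges join pairs at distance $\ge d$ — and finds a maximum clique by branch
and bound with greedy-coloring upper bounds (guard: 2000 vertices, both
guards overridable). A code set is exactly a clique in this graph, so the
clique size is the true optimum $A^{GC,NL}(n,d,w)$. Vertices are processed
in canonical order (lexicographic on digits, $T<C<G<A$) with deterministic
tie-breaks, so the returned witness clique itself is reproducible. In the
test suite the clique number is cross-checked against igraph on small
instances, and every heuristic result is bounded by the oracle wherever the
oracle runs.

At $(n=4, d=3, w=2)$ the oracle proves the optimum is exactly 12 over the
56 valid words — so the published lower bound 12 at that cell is tight.

## What the generators emulate — and what a green test does not establish

No external data enters: inputs are constraint parameters, and the
stochastic "data" are the optimizer's own random draws. The shipped
26-word reference set at $(n=9, d=6, w=4)$ is embedded as published, with
whitespace stripped, and is re-validated at load time. Random candidates
are uniform within the GC-feasible stratum — they emulate the combinatorial
search space itself, not sequencing noise, synthesis bias, or
thermodynamics. A green suite therefore establishes combinatorial validity
and reproducibility of the constructions; it says nothing about wet-lab
behaviour of the resulting oligos (melting temperature, secondary
structure and edit-distance effects are out of scope).

Heuristic sizes are stochastic: at $(n=6, d=3, w=3)$ with population 50,
500 sweeps and $10^5$ draws, runs across seeds comfortably clear the
altruistic-baseline floor of 44 and typically land in the mid-50s to low
60s; matching or beating any particular published heuristic value at every
cell is implementation-sensitive and is reported, not asserted.

## Numerical and degenerate-input choices

* GC content is stored as the exact integer count; the ratio is derived,
  so no float-equality tests.
* `min_pairwise_distance` on fewer than two members returns `NA_integer_`
  — a sentinel, never an artificial $n+1$ or `Inf` — forcing callers to
  treat the degenerate case explicitly; `is_valid_code` is vacuously true
  for sizes 0 and 1.
* The distance-sum fitness of a candidate against an empty set is defined
  as 0, and the first candidate is always accepted.
* `d` is a lower bound on *every* unordered pair (the standard
  $A(n,d,w)$ convention).
* Input sequences are case-folded to uppercase; symbols outside
  `A/C/G/T` (N, U, gaps) are rejected, never coerced.
* Zero-iteration EO budgets leave at most the single best initial decoded
  word; zero RS budget returns the input set unchanged.
* The generation-rate branch uses the strict comparison $r_2 > RP$; a
  non-strict reading differs only on a measure-zero event.

## Worked example

```{r example}
profile <- constraint_profile(n = 6, d = 3)   # w defaults to 3, NRL on
s <- eors_search(profile,
                 eo = eo_params(pop_size = 50, t_max = 100),
                 rs = rs_params(budget = 20000),
                 seed = 1)
s
attr(s, "size_eo")          # set size after the EO stage alone
coding_rate(length(s), 6)   # information per base
min_pairwise_distance(s)    # >= 3 by construction
```

For comparison, the exact optimum where it is computable:

```{r oracle}
mc <- max_clique_exact(build_conflict_graph(constraint_profile(4, 3)))
length(mc)
```

## Known limitations

* The exact oracle is exponential; beyond the guards only heuristic and
  greedy results (lower bounds) are available.
* Pure-R inner loops: a single full EORS run at $n \le 10$ takes seconds
  to minutes, fine for code design, slow for large parameter sweeps.
* Only substitution (Hamming) structure is modelled; insertions/deletions,
  reverse-complement distance and GC *ranges* are out of scope.
* Uniform candidate sampling treats all valid words equally; no
  thermodynamic weighting.
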