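# eorscode

Design of constrained DNA codeword sets for DNA data storage.

Codewords used to address and carry data in synthesized DNA must be
mutually dissimilar and biochemically well-behaved. `eorscode` constructs
sets of length-`n` words over `{A,C,G,T}` that jointly satisfy

* a **minimum pairwise Hamming distance** `d` (error margin, less
  cross-hybridization),
* an **exact GC weight** `w` — each word carries exactly `w` G/C symbols
  (default `floor(n/2)`, for uniform melting behaviour),
* the **no-runlength** constraint — no two adjacent bases equal (homopolymers
  are misread during synthesis and sequencing).

The size `M` of such a set lower-bounds `A^{GC,NL}(n, d, w)`; the coding
rate `R = log4(M) / n` measures information per base. The package provides:

* **EORS heuristic** (`eors_search`): an equilibrium-optimizer population
  search over continuous concentration vectors in `[0,3]^n` (digit mapping
  T=0, C=1, G=2, A=3), decoded with a deterministic repair, followed by a
  random-search augmentation pass with a single-conflict swap rule;
* **exact oracle** (`enumerate_valid_codewords`, `build_conflict_graph`,
  `max_clique_exact`): exhaustive enumeration plus branch-and-bound maximum
  clique on the compatibility graph — the true optimum at small `n`;
* **baseline** (`greedy_random_baseline`) and a benchmark harness
  (`benchmark_sweep`) against published lower bounds (`reference_bounds`);
* **I/O and CLI**: plain-text and FASTA codeword lists, flat `key: value`
  configs, JSON run summaries, and the `cli_entry()` command-line surface
  (`search`, `exact`, `enumerate`, `validate`, `rate`, `benchmark`).

## Worked example

```r
library(eorscode)

profile <- constraint_profile(n = 6, d = 3)   # w defaults to 3, NRL on
s <- eors_search(profile,
                 eo = eo_params(pop_size = 50, t_max = 100),
                 rs = rs_params(budget = 20000),
                 seed = 1)
s
#> DNA code set: 56 codeword(s), n = 6, d = 3, w = 3, NRL on [validated]
#>    TCTCGT TCTGTG TCGTGA TCGACT TCAGAC TGTCTC ...
attr(s, "size_eo")         # after the EO stage alone
#> [1] 40
coding_rate(length(s), 6)  # information per base
#> [1] 0.4839462
min_pairwise_distance(s)   # >= 3 by construction
#> [1] 3
```

56 mutually compatible words at `(n = 6, d = 3, w = 3)` beats the published
altruistic-algorithm bound of 44 at that cell. Where the exact oracle can
run, it settles the cell outright:

```r
length(max_clique_exact(build_conflict_graph(constraint_profile(4, 3))))
#> [1] 12      # provably optimal over the 56 valid length-4 words
```

Every run is reproducible from its master seed; the shipped 26-word
reference set at `(n = 9, d = 6, w = 4)` is re-validated on load
(`load_reference_set_n9_d6()`).

## Command line

```sh
Rscript inst/scripts/eorscode search --n 6 --d 3 --seed 1 --out words.txt
Rscript inst/scripts/eorscode validate --file words.txt --n 6 --d 3
Rscript inst/scripts/eorscode rate --M 110 --n 8     # prints 0.42
```

(After installation the launcher lives at
`system.file("scripts", "eorscode", package = "eorscode")`.)

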