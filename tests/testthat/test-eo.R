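# eo_optimizer: population dynamics, decoding with repair, EO set search.

test_that("time_parameter hits its boundary values and midpoint", {
  prm <- eo_params(t_max = 1000, a2 = 1)
  expect_equal(time_parameter(0, prm), 1)
  expect_equal(time_parameter(1000, prm), 0)
  expect_equal(time_parameter(500, prm), sqrt(0.5), tolerance = 1e-12)
})

test_that("exponential_term follows the closed form", {
  prm <- eo_params(a1 = 2)
  lam <- c(0.2, 0.5, 0.9)
  expect_equal(exponential_term(lam, 0, prm, c(0.1, 0.6, 0.9)), c(0, 0, 0))
  # r > 0.5, t > 0: strictly negative, magnitude below a1
  F <- exponential_term(lam, 0.7, prm, c(0.8, 0.9, 0.6))
  expect_true(all(F < 0) && all(abs(F) < prm$a1))
  expect_equal(exponential_term(log(2), 1, prm, 0.9), -1)
})

test_that("generation_rate vanishes on each zero branch", {
  prm <- eo_params(RP = 0.5)
  lam <- c(0.3, 0.7); conc <- c(1, 2); ceq <- c(2, 1); F <- c(-0.5, 0.4)
  expect_equal(generation_rate(lam, conc, ceq, F, r1 = 0.8, r2 = 0.2, prm),
               c(0, 0))                       # r2 below RP
  expect_equal(generation_rate(lam, conc, ceq, 0, r1 = 0.8, r2 = 0.9, prm),
               c(0, 0))                       # F = 0
  expect_equal(generation_rate(lam, conc, lam * conc, F, 0.8, 0.9, prm),
               c(0, 0))                       # c_eq = lambda * c cancellation
  # live branch: RCP = 0.5 r1
  expect_equal(generation_rate(lam, conc, ceq, F, 0.8, 0.9, prm),
               0.4 * (ceq - lam * conc) * F)
})

test_that("initialize_population is uniform on [0,3] and seed-reproducible", {
  prm <- eo_params(pop_size = 20, t_max = 10)
  prof <- constraint_profile(6, 3)
  set.seed(5); pop1 <- initialize_population(prm, prof)
  set.seed(5); pop2 <- initialize_population(prm, prof)
  expect_identical(pop1, pop2)
  expect_identical(dim(pop1), c(20L, 6L))
  expect_true(all(pop1 >= 0 & pop1 <= 3))
})

test_that("update_concentration stays clamped and has its fixed points", {
  prm <- eo_params(t_max = 100, RP = 1)   # RP = 1: generation rate always 0
  n <- 5
  conc <- runif(n, 0, 3)
  pool <- matrix(rep(conc, 5), nrow = 5, byrow = TRUE)  # pool collapsed on c
  set.seed(1)
  expect_equal(update_concentration(conc, pool, iter = 50, prm), conc)
  # F = 0 at the final sweep (t = 0) and R = 0: full pull to the candidate
  ceq <- runif(n, 0, 3)
  pool2 <- matrix(rep(ceq, 5), nrow = 5, byrow = TRUE)
  expect_equal(update_concentration(runif(n, 0, 3), pool2,
                                    iter = prm$t_max, prm), ceq)
  # clamping under arbitrary pools and many updates
  prm2 <- eo_params(t_max = 100)
  set.seed(2)
  x <- runif(n, 0, 3)
  pool3 <- matrix(runif(5 * n, 0, 3), nrow = 5)
  for (it in 1:100) {
    x <- update_concentration(x, pool3, iter = it %% 101, prm2)
    expect_true(all(x >= 0 & x <= 3))
  }
})

test_that("decode_particle rounds, repairs and is idempotent", {
  p <- constraint_profile(4, 1, 2)
  # worked repair example: rounds to (0,2,2,3), NRL picks 1 at position 3
  expect_identical(decode_particle(c(0.2, 1.6, 2.4, 3.7), p), "TGCA")
  # already-valid integer vector decodes to itself
  expect_identical(decode_particle(c(0, 2, 1, 3), p), "TGCA")
  # all-zero vector: TTTT repaired to a valid word (hand-derived: the two
  # cheapest class flips hit positions 1 and 2, then NRL assignment)
  expect_identical(decode_particle(c(0, 0, 0, 0), p), "CGTA")
  expect_true(is_valid_codeword(decode_particle(rep(0, 4), p), p))
  expect_error(decode_particle(c(0, 1), p), "does not match")
})

test_that("decode_particle output is always valid and repair is idempotent", {
  set.seed(9)
  for (rep in 1:60) {
    n <- sample(2:10, 1)
    p <- constraint_profile(n, 1, sample(0:n, 1))
    conc <- runif(n, 0, 3)
    word <- decode_particle(conc, p)
    expect_true(is_valid_codeword(word, p))
    # feeding the decoded digits back through the decoder changes nothing
    expect_identical(decode_particle(codeword_digits(word)[1, ], p), word)
  }
})

test_that("eo_search returns a valid, reproducible, insertion-only set", {
  prof <- constraint_profile(4, 3, 2)
  prm <- eo_params(pop_size = 20, t_max = 30, seed = 123)
  s1 <- eo_search(prof, prm, trace = TRUE)
  s2 <- eo_search(prof, prm)
  expect_true(is_valid_code(s1))
  expect_identical(s1$words, s2$words)
  tr <- attr(s1, "trace")
  expect_true(all(diff(tr$set_size) >= 0))   # set never shrinks
  # never exceeds the exact optimum
  opt <- length(max_clique_exact(build_conflict_graph(prof)))
  expect_lte(length(s1), opt)
  # zero iterations: at most the best initial decoded word
  s0 <- eo_search(prof, eo_params(pop_size = 10, t_max = 0, seed = 1))
  expect_lte(length(s0), 1L)
})
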