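test_that("chromosome encoding is a row-major round trip", {
  V <- rbind(c(1, 2), c(3, 4))
  expect_equal(encode_chromosome(V), c(1, 2, 3, 4))
  expect_equal(decode_chromosome(c(1, 2, 3, 4), 2, 2), V)
  # c=1: chromosome is the single center verbatim
  expect_equal(decode_chromosome(encode_chromosome(rbind(c(7, 8, 9))), 1, 3),
               rbind(c(7, 8, 9)))
  # c=3, p=2: genes 3..4 are center 2
  a <- as.numeric(1:6)
  expect_equal(decode_chromosome(a, 3, 2)[2, ], a[3:4])
  expect_error(decode_chromosome(1:5, 2, 3), "length")
})

test_that("initial populations respect feature ranges and the seed", {
  X <- cbind(runif(50, 0, 10), rep(4, 50))
  cfg <- miea_config(c = 2, p_n = 20)
  set.seed(1); pop1 <- init_population(cfg, X)
  set.seed(1); pop2 <- init_population(cfg, X)
  expect_identical(pop1, pop2)
  lo <- attr(pop1, "lo"); hi <- attr(pop1, "hi")
  expect_true(all(sweep(pop1, 2, lo, ">=") & sweep(pop1, 2, hi, "<=")))
  # constant feature: that gene identical across the population
  expect_true(all(pop1[, 2] == 4) && all(pop1[, 4] == 4))
  # uniformity: empirical mean of a gene near the range midpoint
  set.seed(2)
  big <- init_population(miea_config(c = 1, p_n = 10000),
                         cbind(c(0, 10), c(0, 10)))
  expect_lt(abs(mean(big[, 1]) - 5), 0.2)
})

test_that("roulette and rank selection behave like their sampling models", {
  pop <- rbind(c(1, 1), c(2, 2))
  # equal fitness: both rows drawn about equally often
  set.seed(3)
  eq <- select_parents(pop, c(0.5, 0.5), "roulette", 10000)
  expect_lt(abs(mean(eq[, 1] == 1) - 0.5), 0.02)
  # fitness (0.8, 0.2): first parent drawn about 80% of the time
  set.seed(4)
  sel <- select_parents(pop, c(0.8, 0.2), "roulette", 10000)
  expect_lt(abs(mean(sel[, 1] == 1) - 0.8), 0.02)
  # rank selection depends only on fitness order
  f <- c(0.1, 0.7, 0.3)
  pop3 <- diag(3)
  set.seed(5); r1 <- select_parents(pop3, f, "rank", 500)
  set.seed(5); r2 <- select_parents(pop3, f^3, "rank", 500)
  expect_identical(r1, r2)
  expect_error(select_parents(pop3[0, , drop = FALSE], numeric(0),
                              "roulette", 1), "empty")
})

test_that("crossover swaps complementary segments and conserves genes", {
  p1 <- c(1, 1, 1, 1); p2 <- c(2, 2, 2, 2)
  set.seed(6)
  expect_identical(crossover_chromosomes(p1, p2, p_c = 0), list(p1, p2))
  for (method in c("one_point", "two_point", "uniform")) {
    for (rep in 1:25) {
      kids <- crossover_chromosomes(p1, p2, p_c = 1, method = method)
      # per-position multiset conservation
      expect_equal(kids[[1]] + kids[[2]], rep(3, 4))
      if (method == "one_point") {
        # children are a prefix of one parent and the suffix of the other
        flips <- sum(diff(kids[[1]]) != 0)
        expect_lte(flips, 1)
        expect_equal(sum(kids[[1]] != p1) + sum(kids[[2]] != p2),
                     2 * sum(kids[[1]] == 2))
        expect_gt(sum(kids[[1]] == 2), 0)  # the cut leaves 1..l-1 genes
        expect_lt(sum(kids[[1]] == 2), 4)
      }
    }
  }
  expect_error(crossover_chromosomes(1:3, 1:4), "length")
})

test_that("reset mutation re-randomizes genes at the binomial rate within
           bounds", {
  lo <- rep(0, 100); hi <- rep(1, 100)
  a <- rep(0.5, 100)
  set.seed(7)
  expect_identical(mutate_chromosome(a, 0, lo, hi), a)
  full <- mutate_chromosome(a, 1, lo, hi)
  expect_true(all(full >= 0 & full <= 1))
  # expected mutated-gene count at p_m = 0.01, l = 100 is 1
  set.seed(8)
  counts <- replicate(10000, sum(mutate_chromosome(a, 0.01, lo, hi) != 0.5))
  expect_lt(abs(mean(counts) - 1), 0.05)
  # segment reversal permutes gene values, never invents new ones
  set.seed(9)
  b <- as.numeric(1:10)
  rev_out <- mutate_chromosome(b, 1, lo[1:10], hi[1:10],
                               method = "segment_reversal")
  expect_setequal(rev_out, b)
  expect_false(identical(rev_out, b))
})

test_that("vaccines carry elite genes and vaccination is gated by p_v", {
  elite <- c(10, 20, 30, 40, 50, 60, 70, 80)
  set.seed(10)
  # fraction 0.25 of l=8 gives exactly 2 entries
  v <- extract_vaccine(elite, elite_f = 0.9, vaccine_fraction = 0.25)
  expect_length(v$positions, 2L)
  expect_equal(v$values, elite[v$positions])
  expect_equal(v$source_fitness, 0.9)
  # fraction 1 donates every gene
  v_full <- extract_vaccine(elite, 0.9, 1)
  expect_equal(v_full$positions, 1:8)
  expect_equal(v_full$values, elite)

  a <- rep(9, 8)
  set.seed(11)
  expect_identical(vaccinate(a, v_full, p_v = 0), a)
  expect_equal(vaccinate(a, v_full, p_v = 1), elite)
  # targeted overwrite: positions {1,3} with values (1,3)
  v13 <- structure(list(positions = c(1L, 3L), values = c(1, 3),
                        source_fitness = 1), class = "miea_vaccine")
  expect_equal(vaccinate(c(9, 9, 9, 9), v13, p_v = 1), c(1, 9, 3, 9))
  expect_error(vaccinate(c(9, 9), v13, p_v = 1), "out of range")
})

test_that("immune selection returns the fitter of original and vaccinated", {
  a <- c(1, 2); b <- c(3, 4)
  expect_equal(immune_select(a, b, 0.5, 0.9)$chromosome, b)
  expect_equal(immune_select(a, b, 0.9, 0.5)$chromosome, a)
  # tie accepts the vaccinated individual
  expect_equal(immune_select(a, b, 0.7, 0.7)$chromosome, b)
  set.seed(12)
  for (rep in 1:200) {
    fo <- runif(1); fv <- runif(1)
    expect_equal(immune_select(a, b, fo, fv)$f, max(fo, fv))
  }
})

test_that("run_miea recovers a separable mixture exactly and is
           reproducible", {
  spec <- toy_mixture_spec(spreads = 0)
  ds <- generate_mixture(spec, 30, seed = 1)
  cfg <- miea_config(c = 3, p_n = 20, max_gens = 40, seed = 1)
  res <- run_miea(ds, cfg)
  expect_lt(res$J, 1e-6)
  # hard labels reproduce generating labels up to cluster permutation
  expect_equal(f_measure(contingency(ds$labels, res$hard_labels)), 1)

  res2 <- run_miea(ds, cfg)
  expect_equal(res$prototypes, res2$prototypes)
  expect_identical(res$hard_labels, res2$hard_labels)
  expect_identical(res$J_history, res2$J_history)
})

test_that("the elite objective never increases and chromosomes stay within
           bounds", {
  ds <- generate_mixture(toy_mixture_spec(spreads = 0.6), 90, seed = 2)
  for (s in 1:5) {
    res <- run_miea(ds, miea_config(c = 3, p_n = 15, max_gens = 25,
                                    seed = s))
    expect_true(all(diff(res$J_history) <= 1e-12))
    expect_true(all(res$hard_labels %in% 0:2))
    # prototypes stay inside the data's bounding box
    lo <- apply(ds$features, 2, min); hi <- apply(ds$features, 2, max)
    expect_true(all(sweep(res$prototypes, 2, lo, ">=") &
                    sweep(res$prototypes, 2, hi, "<=")))
  }
})

test_that("run_miea validates its configuration against the data", {
  ds <- generate_mixture(toy_mixture_spec(), 10, seed = 3)
  expect_error(run_miea(ds, miea_config(c = 10, seed = 1)), "c must")
  expect_error(miea_config(c = 0), "c >= 1")
  expect_error(miea_config(c = 2, m = 1), "m > 1")
  expect_error(miea_config(c = 2, p_c = 1.2), "p_c")
})
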