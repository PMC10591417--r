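test_that("hazard follows the piecewise-linear age law with hard cutoff", {
  expect_equal(death_probability(0, 0, 0.05), 0.05)
  expect_equal(death_probability(0, 1000, 0.05), 0.05)  # genetically immortal
  # alpha = 0.1: tau_max = floor(0.95 / 0.1) = 9
  expect_equal(death_probability(0.1, 9, 0.05), 0.95)
  expect_equal(death_probability(0.1, 10, 0.05), 1)
  expect_equal(death_probability(0.1, 0:3, 0.05), 0.05 + 0.1 * 0:3)
  # maximal aging rate for La = 50: tau_max = floor(0.95 / 0.5) = 1
  expect_equal(death_probability(0.5, 1, 0.05), 0.55)
  expect_equal(death_probability(0.5, 2, 0.05), 1)
  expect_error(death_probability(0.1, 5, 1.5), "delta0")
  # non-decreasing in age and in alpha, never below delta0 or above 1
  d <- death_probability(0.07, 0:40, 0.05)
  expect_true(all(diff(d) >= 0) && all(d >= 0.05) && all(d <= 1))
})

test_that("Moore neighbourhoods have (2n+1)^2 - 1 distinct wrapped sites", {
  nb <- moore_neighbors(1, 1, 1, 200)
  expect_equal(nrow(nb), 8)
  expect_true(any(nb[, 1] == 200 & nb[, 2] == 200))  # torus wrap
  expect_equal(nrow(moore_neighbors(5, 5, 2, 20)), 24)
  expect_equal(nrow(unique(moore_neighbors(3, 3, 2, 7))), 24)
  # all within Chebyshev distance n on the torus
  nb <- moore_neighbors(10, 10, 3, 50)
  d <- pmax(abs(nb[, 1] - 10), abs(nb[, 2] - 10))
  expect_true(all(d <= 3) && !any(d == 0))
})

test_that("initial lattice is full, non-aging, with uniform integer ages", {
  set.seed(101)
  p <- sim_params(N = 50, generations = 10)
  st <- initialize_lattice(p)
  expect_equal(mean(st$occ), 1)           # full occupancy
  a <- senesim:::state_alpha(st)
  expect_true(all(a == 0))                # non-aging start
  # ages ~ floor(U(0, 20)): mean about 9.5, support {0..19}
  expect_true(all(st$age >= 0 & st$age <= 19))
  expect_equal(mean(st$age), 9.5, tolerance = 0.05)
  # fecundity alleles i.i.d. fair coin
  expect_equal(mean(as.integer(st$alleles[st$layout$fec_pos, ])), 0.5,
               tolerance = 0.02)
})

test_that("death-only dynamics match the per-draw hazard exactly", {
  # a single occupant on a 3x3 torus in sexual mode can never reproduce;
  # its per-generation survival is E[(1 - delta)^k], k ~ Binomial(9, 1/9)
  set.seed(55)
  p <- sim_params(N = 3, Lf = 2, La = 2, pa = 0, pf = 0,
                  selection = "stabilizing")
  lay <- make_locus_layout(2, 2)
  tg <- init_target_stabilizing(2)
  reps <- 3000
  dead_after_1 <- 0
  for (r in 1:reps) {
    st <- manual_state(3, lay, tg, data.frame(x = 2, y = 2, age = 0),
                       matrix(0L, 1, 4))
    out <- engine_step(st, p, 1)
    dead_after_1 <- dead_after_1 + (sum(out$state$occ) == 0)
  }
  p_die <- 1 - (1 - 0.05 / 9)^9   # 0.0488
  expect_equal(dead_after_1 / reps, p_die, tolerance = 0.15)
})

test_that("parent choice is proportional to raw fecundity b^s", {
  # two candidates with s = 2 and s = 0 at b = 1.2: win probabilities
  # 1.44/2.44 and 1/2.44; measured by the tag of asexual offspring
  set.seed(77)
  p <- sim_params(N = 3, Lf = 2, La = 2, pa = 0, pf = 0, delta0 = 0.05,
                  reproduction = "asexual", selection = "stabilizing")
  lay <- make_locus_layout(2, 2)
  tg <- senesim:::new_target(c(1L, 1L), "stabilizing", 1L)
  g <- matrix(0L, 2, 4)
  g[1, lay$fec_pos] <- 1L   # parent 1 matches the target: s = 2
  wins <- c(match = 0, mismatch = 0); births <- 0
  for (r in 1:800) {
    st <- manual_state(3, lay, tg, data.frame(x = c(1, 3), y = c(1, 3),
                                              age = c(0, 0)),
                       g, tag = c(1L, 0L))
    out <- engine_step(st, p, 1)
    newb <- which(out$state$occ == 1L & out$state$age == 1L &
                    !(seq_len(9) %in% c(1, 9)))
    for (i in newb) {
      births <- births + 1
      if (out$state$tag[i] == 1L) wins["match"] <- wins["match"] + 1
      else wins["mismatch"] <- wins["mismatch"] + 1
    }
  }
  expect_gt(births, 500)
  expect_equal(unname(wins["match"] / births), 1.44 / 2.44, tolerance = 0.08)
})

test_that("sexual reproduction needs a pair; a lone neighbour leaves the site empty", {
  set.seed(88)
  p <- sim_params(N = 3, Lf = 2, La = 2, pa = 0, pf = 0, delta0 = 0.01,
                  reproduction = "sexual", selection = "stabilizing")
  lay <- make_locus_layout(2, 2)
  tg <- init_target_stabilizing(2)
  st <- manual_state(3, lay, tg, data.frame(x = 2, y = 2, age = 0),
                     matrix(0L, 1, 4))
  out <- engine_step(st, p, 3)
  # the lone occupant may die, but no birth can ever happen
  expect_lte(sum(out$state$occ), 1)
  expect_equal(sum(out$metrics$births), 0)
})

test_that("asexual offspring of a lone parent are exact copies at p = 0", {
  set.seed(99)
  p <- sim_params(N = 3, Lf = 3, La = 3, pa = 0, pf = 0, delta0 = 0.01,
                  reproduction = "asexual", selection = "stabilizing")
  lay <- make_locus_layout(3, 3)
  tg <- init_target_stabilizing(3)
  g <- matrix(c(1L, 0L, 1L, 0L, 1L, 0L), 1)
  st <- manual_state(3, lay, tg, data.frame(x = 2, y = 2, age = 0), g)
  out <- engine_step(st, p, 2)
  occ <- which(out$state$occ == 1L)
  expect_gt(length(occ), 1)  # colonised some of the torus
  for (i in occ)
    expect_identical(as.integer(out$state$alleles[, i]), as.integer(g[1, ]))
})

test_that("diffusion is calibrated to 2D site moves per generation", {
  set.seed(111)
  p0 <- sim_params(N = 20, D = 0, generations = 5)
  s0 <- run_sim(p0, seed = 4)
  expect_equal(sum(s0$metrics$swaps), 0)
  # D = 1: exactly one swap per elementary update, N^2 per generation
  p1 <- update_params(p0, D = 1)
  s1 <- run_sim(p1, generations = 5, seed = 4)
  expect_equal(s1$metrics$swaps, rep(400, 5))
  # D = 0.5: Binomial(N^2, 0.5) swaps per generation
  p5 <- update_params(p0, D = 0.5)
  s5 <- run_sim(p5, generations = 40, seed = 4)
  expect_equal(mean(s5$metrics$swaps) / 400, 0.5, tolerance = 0.05)
  # D = 2.25: floor + Bernoulli remainder
  p2 <- update_params(p0, D = 2.25)
  s2 <- run_sim(p2, generations = 20, seed = 4)
  expect_equal(mean(s2$metrics$swaps) / 400, 2.25, tolerance = 0.05)
})

test_that("a diffusion swap conserves the pair of site contents", {
  set.seed(123)
  p <- sim_params(N = 6, Lf = 3, La = 3, delta0 = 0.01, pa = 0, pf = 0,
                  D = 5, selection = "stabilizing")
  st <- initialize_lattice(p)
  genomes0 <- sort(apply(matrix(as.integer(st$alleles), nrow = 6), 2,
                         paste, collapse = ""))
  # suppress births/deaths almost entirely for one generation and compare
  out <- engine_step(st, p, 1)
  expect_gt(sum(out$metrics$swaps), 100)
  expect_equal(sum(out$state$occ) + sum(out$metrics$deaths) -
                 sum(out$metrics$births), 36)
})

test_that("runs are bit-reproducible from the seed and ages advance by 1", {
  p <- sim_params(N = 12, generations = 30)
  a <- run_sim(p, seed = 9)
  b <- run_sim(p, seed = 9)
  expect_identical(a$metrics, b$metrics)
  expect_identical(a$state$alleles, b$state$alleles)
  c <- run_sim(p, seed = 10)
  expect_false(identical(a$metrics, c$metrics))
  # survivors age by exactly one per generation: continuing a frozen
  # death-free, birth-free population shifts the age histogram
  p2 <- sim_params(N = 5, Lf = 2, La = 2, delta0 = 1e-3, pa = 0, pf = 0,
                   selection = "stabilizing")
  st <- initialize_lattice(p2)
  out <- engine_step(st, p2, 1)
  alive <- out$state$occ == 1L & st$occ == 1L & out$state$age > 0
  expect_true(all(out$state$age[alive] - st$age[alive] == 1))
})

test_that("aging cannot arise when senescence mutation is off", {
  p <- sim_params(N = 15, pa = 0, generations = 80)
  sim <- run_sim(p, seed = 21)
  expect_true(all(sim$metrics$mean_alpha == 0))
})

test_that("occupancy stays near saturation at standard parameters", {
  p <- sim_params(N = 30, generations = 150)
  sim <- run_sim(p, seed = 31)
  expect_true(all(sim$metrics$occupancy > 0.99))
  expect_true(all(sim$metrics$occupancy <= 1))
})

test_that("the pure-R generation agrees with the engine death law", {
  # same single-occupant construction as the engine oracle, via the
  # independent R path
  set.seed(66)
  p <- sim_params(N = 3, Lf = 2, La = 2, pa = 0, pf = 0,
                  selection = "stabilizing")
  lay <- make_locus_layout(2, 2)
  tg <- init_target_stabilizing(2)
  reps <- 1500
  dead <- 0
  for (r in 1:reps) {
    st <- manual_state(3, lay, tg, data.frame(x = 2, y = 2, age = 0),
                       matrix(0L, 1, 4))
    st2 <- senesim:::step_generation_r(st, p)
    dead <- dead + (sum(st2$occ) == 0)
  }
  p_die <- 1 - (1 - 0.05 / 9)^9
  expect_equal(dead / reps, p_die, tolerance = 0.2)
})
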