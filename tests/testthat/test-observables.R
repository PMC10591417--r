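test_that("lattice summaries: means over occupants, degenerate correlation flagged", {
  set.seed(201)
  p <- sim_params(N = 4, Lf = 3, La = 3, selection = "stabilizing")
  lay <- make_locus_layout(3, 3)
  tg <- senesim:::new_target(c(1L, 0L, 1L), "stabilizing", 1L)

  # all individuals identical: correlation undefined, not 0
  g <- matrix(rep(c(1L, 1L, 0L, 0L, 1L, 0L), 3), 3, byrow = TRUE)
  st <- manual_state(4, lay, tg, data.frame(x = 1:3, y = 1:3, age = c(2, 5, 7)), g)
  sm <- summarize_lattice(st, p)
  expect_true(is.na(sm$corr_alpha_fec))
  expect_equal(sm$occupancy, 3 / 16)
  expect_equal(sm$mean_age, mean(c(2, 5, 7)))

  # single occupant with a perfect match: normalised fecundity 1
  g1 <- matrix(0L, 1, 6); g1[1, lay$fec_pos] <- c(1L, 0L, 1L)
  st1 <- manual_state(4, lay, tg, data.frame(x = 2, y = 2, age = 0), g1)
  sm1 <- summarize_lattice(st1, p)
  expect_equal(sm1$mean_fecundity, 1)
  expect_equal(sm1$mean_match, 3)
  expect_equal(sm1$mean_hamming, 0)

  # empty lattice: occupancy 0, means undefined
  st0 <- manual_state(4, lay, tg, data.frame(x = integer(0), y = integer(0),
                                             age = integer(0)),
                      matrix(0L, 0, 6))
  sm0 <- summarize_lattice(st0, p)
  expect_equal(sm0$occupancy, 0)
  expect_true(is.na(sm0$mean_alpha) && is.na(sm0$mean_age))
})

test_that("summaries agree with the engine's own metrics row", {
  p <- sim_params(N = 10, generations = 12)
  sim <- run_sim(p, seed = 7)
  sm <- summarize_lattice(sim$state, p)
  last <- sim$metrics[nrow(sim$metrics), ]
  for (col in c("occupancy", "mean_alpha", "mean_age", "mean_mortality",
                "mean_fecundity", "mean_match", "mean_hamming"))
    expect_equal(sm[[col]], last[[col]], tolerance = 1e-12, label = col)
})

test_that("mean mortality predicts the realised death frequency", {
  # freeze a non-trivial evolved lattice and compare its hazard summary
  # with the death counts of many one-generation continuations
  p <- sim_params(N = 20, generations = 150)
  sim <- run_sim(p, seed = 13)
  sm <- summarize_lattice(sim$state, p)
  nocc <- sum(sim$state$occ)
  set.seed(14)
  deaths <- replicate(60, engine_step(sim$state, p, 1)$metrics$deaths)
  # each occupant is drawn Binomial(N^2, 1/N^2) ~ Poisson(1) times per
  # generation; expected deaths ~= sum over occupants of 1 - (1-d_i/N^2)^(N^2)
  a <- senesim:::state_alpha(sim$state)
  occ <- sim$state$occ == 1L
  d_i <- death_probability(a[occ], sim$state$age[occ], p$delta0)
  expected <- sum(1 - (1 - d_i / 400)^400)
  expect_equal(mean(deaths), expected, tolerance = 0.1)
  # and the summary's mean mortality is the plain average of the hazards
  expect_equal(sm$mean_mortality, mean(d_i), tolerance = 1e-12)
})

test_that("Hamming distance to target spans its range and halves at random", {
  set.seed(31)
  p <- sim_params(N = 6, Lf = 20, La = 4, selection = "stabilizing")
  lay <- make_locus_layout(20, 4)
  tg <- init_target_stabilizing(20)
  L <- 24
  # perfect matches
  g <- matrix(0L, 5, L)
  for (i in 1:5) g[i, lay$fec_pos] <- tg$phi
  st <- manual_state(6, lay, tg, data.frame(x = 1:5, y = rep(1, 5),
                                            age = rep(0, 5)), g)
  expect_equal(mean_hamming_to_target(st), 0)
  # complements
  for (i in 1:5) g[i, lay$fec_pos] <- 1L - tg$phi
  st <- manual_state(6, lay, tg, data.frame(x = 1:5, y = rep(1, 5),
                                            age = rep(0, 5)), g)
  expect_equal(mean_hamming_to_target(st), 20)
  # random genomes against a random target: about Lf / 2
  set.seed(33)
  hs <- replicate(300, {
    gi <- matrix(sample(0:1, L, replace = TRUE), 1)
    sti <- manual_state(6, lay, tg, data.frame(x = 1, y = 1, age = 0), gi)
    mean_hamming_to_target(sti)
  })
  expect_equal(mean(hs), 10, tolerance = 0.05 * 10)
})

test_that("aging gradient profile is zero for uniform lattices and exact on a split", {
  set.seed(41)
  p <- sim_params(N = 6, Lf = 2, La = 10, pa = 0, pf = 0,
                  selection = "stabilizing")
  lay <- make_locus_layout(2, 10)
  tg <- init_target_stabilizing(2)
  # uniform aging rate everywhere -> identically zero profile
  g <- matrix(0L, 36, 12)
  g[, lay$sen_pos[1]] <- 1L
  xy <- expand.grid(x = 1:6, y = 1:6)
  st <- manual_state(6, lay, tg, data.frame(xy, age = 0), g)
  prof <- aging_gradient_profile(st, d_max = 2)
  expect_equal(prof$mean_abs_dalpha, c(0, 0))

  # two homogeneous half-lattices (rows 1-3 alpha 0, rows 4-6 alpha 0.1):
  # compare with an exhaustive double loop over all site pairs
  g2 <- matrix(0L, 36, 12)
  top <- xy$x <= 3
  g2[!top, lay$sen_pos] <- 1L  # alpha = 0.1
  st2 <- manual_state(6, lay, tg, data.frame(xy, age = 0), g2)
  prof2 <- aging_gradient_profile(st2, d_max = 2)
  alpha <- ifelse(top, 0, 0.1)
  for (d in 1:2) {
    diffs <- c()
    for (i in 1:36) for (j in 1:36) {
      dx <- abs(xy$x[i] - xy$x[j]); dx <- min(dx, 6 - dx)
      dy <- abs(xy$y[i] - xy$y[j]); dy <- min(dy, 6 - dy)
      if (max(dx, dy) == d) diffs <- c(diffs, abs(alpha[i] - alpha[j]))
    }
    expect_equal(prof2$mean_abs_dalpha[d], mean(diffs), tolerance = 1e-12)
  }
  expect_gt(prof2$mean_abs_dalpha[2], prof2$mean_abs_dalpha[1])
})

test_that("age histogram counts sum to the occupant count", {
  p <- sim_params(N = 15, generations = 40)
  sim <- run_sim(p, seed = 3)
  h <- age_histogram(sim$state)
  expect_equal(sum(h$count), sum(sim$state$occ))
  expect_true(all(h$age >= 0))
})
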