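#' Per-generation death probability
#'
#' The hazard is the probability that an individual dies during one
#' generation: `delta0 + alpha * tau` up to the maximum lifespan
#' `tau_max = floor((1 - delta0) / alpha)`, and 1 beyond it.  An
#' individual with `alpha = 0` is genetically immortal and dies only from
#' the baseline hazard `delta0` at every age.
#'
#' @param alpha aging rate(s), `>= 0`.
#' @param tau age(s) in generations, `>= 0`.
#' @param delta0 baseline mortality in (0, 1).
#' @return Death probability in `[delta0, 1]` (vectorised over
#'   `alpha`/`tau`).
#' @examples
#' death_probability(0, 40, 0.05)       # baseline only
#' death_probability(0.1, 9:10, 0.05)   # 0.95 at tau_max, then 1
#' @export
death_probability <- function(alpha, tau, delta0) {
  if (any(delta0 <= 0 | delta0 >= 1)) stop("delta0 must lie in (0, 1)", call. = FALSE)
  if (any(alpha < 0)) stop("alpha must be >= 0", call. = FALSE)
  d <- delta0 + alpha * tau
  tmax <- ifelse(alpha > 0, floor((1 - delta0) / alpha), Inf)
  ifelse(tau > tmax, 1, d)
}

#' Moore neighbourhood on the torus
#'
#' The `(2n+1)^2 - 1` sites within Chebyshev distance `n` of a focal site,
#' with periodic wraparound; the focal site itself is excluded.
#'
#' @param x,y 1-based coordinates of the focal site.
#' @param n neighbourhood radius (`n = 1` gives the standard 8 sites).
#' @param N lattice side length.
#' @return A two-column integer matrix of neighbour coordinates.
#' @export
moore_neighbors <- function(x, y, n, N) {
  stopifnot(n >= 1, N >= 2 * n + 1)
  d <- seq.int(-n, n)
  g <- expand.grid(dx = d, dy = d)
  g <- g[g$dx != 0L | g$dy != 0L, ]
  cbind(x = as.integer((x - 1L + g$dx) %% N + 1L),
        y = as.integer((y - 1L + g$dy) %% N + 1L))
}

#' Initial lattice state
#'
#' Fills every site of the torus with an individual: ages are
#' `floor(U(0, 1/delta0))`, senescence alleles start in state 0 (so the
#' whole population is initially non-aging and senescence must arise by
#' mutation), and fecundity alleles are i.i.d. uniform 0/1.  The locus
#' layout and the selective target are drawn here unless supplied.
#'
#' Variant switches alter the start: `monomorphic_fertility` sets all
#' fecundity alleles (and the static target) to 0; `fixed_alpha = a` turns
#' ON the first `100 * a` senescence loci of every individual.
#'
#' @param params a [sim_params()] object.
#' @param layout optional [make_locus_layout()] to reuse across runs.
#' @param target optional `selection_target` to reuse.
#' @return An object of class `lattice_state`: list with `N`, `occ`,
#'   `age`, `tag` (integer vectors over the `N^2` sites, row-major),
#'   `alleles` (raw `L x N^2` matrix, one genome per column in chromosome
#'   order), `layout`, `target` and `t = 0`.
#' @export
initialize_lattice <- function(params, layout = NULL, target = NULL) {
  stopifnot(inherits(params, "sim_params"))
  N2 <- params$N^2
  L <- params$Lf + params$La
  if (is.null(layout)) layout <- make_locus_layout(params$Lf, params$La)
  if (is.null(target)) {
    target <-
      if (params$monomorphic_fertility)
        new_target(integer(params$Lf), "stabilizing", 1L)
      else if (params$selection == "directional")
        init_target_directional(params$Lf, params$T)
      else init_target_stabilizing(params$Lf)
  }
  alleles <- matrix(as.raw(0L), nrow = L, ncol = N2)
  if (!params$monomorphic_fertility)
    alleles[layout$fec_pos, ] <- as.raw(stats::rbinom(params$Lf * N2, 1L, 0.5))
  if (!is.na(params$fixed_alpha)) {
    k <- as.integer(round(params$fixed_alpha * 100))
    if (k > 0) alleles[layout$sen_pos[seq_len(k)], ] <- as.raw(1L)
  }
  st <- list(N = params$N,
             occ = rep(1L, N2),
             age = as.integer(floor(stats::runif(N2, 0, 1 / params$delta0))),
             tag = integer(N2),
             alleles = alleles,
             layout = layout, target = target, t = 0L)
  class(st) <- "lattice_state"
  st
}

#' @export
print.lattice_state <- function(x, ...) {
  nocc <- sum(x$occ)
  cat(sprintf("lattice_state: %d x %d torus at t = %d, %d/%d sites occupied\n",
              x$N, x$N, x$t, nocc, x$N^2))
  invisible(x)
}

# ---- slow pure-R generation, used as an independent reference in tests ----

# per-site aging rates / match counts (NA on empty sites)
state_alpha <- function(state) {
  a <- 0.01 * colSums(matrix(as.integer(state$alleles[state$layout$sen_pos, ,
                                                      drop = FALSE]),
                             nrow = state$layout$La))
  a[state$occ == 0L] <- NA_real_
  a
}

state_match <- function(state) {
  fa <- matrix(as.integer(state$alleles[state$layout$fec_pos, , drop = FALSE]),
               nrow = state$layout$Lf)
  s <- colSums(fa == state$target$phi)
  s[state$occ == 0L] <- NA_real_
  s
}

# candidate parent site indices for an empty site (normal or config-field)
candidate_parents <- function(state, idx, params) {
  N <- state$N
  if (params$config_field) {
    pool <- setdiff(seq_len(N^2), idx)
    sites <- sample(pool, 8L)
  } else {
    r <- (idx - 1L) %/% N + 1L
    c <- (idx - 1L) %% N + 1L
    nb <- moore_neighbors(r, c, params$n, N)
    sites <- (nb[, 1] - 1L) * N + nb[, 2]
  }
  sites[state$occ[sites] == 1L]
}

# one fecundity-proportional draw among candidate sites
choose_parent <- function(weights) {
  if (length(weights) == 1L) return(1L)
  sample.int(length(weights), 1L, prob = weights)
}

# attempt a birth at empty site idx; returns the updated state
fill_empty_site <- function(state, idx, params) {
  cand <- candidate_parents(state, idx, params)
  sexual <- params$reproduction == "sexual"
  if ((sexual && length(cand) < 2L) || length(cand) < 1L) return(state)
  s <- state_match(state)
  w <- fecundity(s[cand], params$b)
  g1 <- as.integer(state$alleles[, cand[i1 <- choose_parent(w)]])
  tag <- state$tag[cand[i1]]
  if (sexual) {
    rest <- cand[-i1]
    i2 <- choose_parent(w[-i1])
    g2 <- as.integer(state$alleles[, rest[i2]])
    tag <- as.integer(tag | state$tag[rest[i2]])
    child <- recombine_genomes(g1, g2, params$prec)
  } else child <- g1
  child <- mutate_genome(child, state$layout, params$pf, params$pa)
  state$alleles[, idx] <- as.raw(child)
  state$occ[idx] <- 1L
  state$age[idx] <- 0L
  state$tag[idx] <- tag
  state
}

# one full generation in plain R: N^2 elementary updates (death trial on an
# occupied focal site, then a birth attempt if the site is empty, then D
# diffusion swap trials), followed by the synchronous age update.  Mirrors
# the compiled engine; kept for oracle tests on tiny lattices.
step_generation_r <- function(state, params) {
  t <- state$t + 1L
  if (params$selection == "directional" && !params$monomorphic_fertility)
    state$target <- advance_target(state$target, t - 1L)
  N2 <- state$N^2
  for (step in seq_len(N2)) {
    idx <- sample.int(N2, 1L)
    if (state$occ[idx] == 1L) {
      alpha <- if (params$evolvable_baseline) 0 else
        0.01 * sum(as.integer(state$alleles[state$layout$sen_pos, idx]))
      dp <- if (params$evolvable_baseline)
        0.002 + 0.01 * sum(as.integer(state$alleles[state$layout$sen_pos, idx]))
      else death_probability(alpha, state$age[idx], params$delta0)
      if (stats::runif(1) < dp) state$occ[idx] <- 0L
    }
    if (state$occ[idx] == 0L)
      state <- fill_empty_site(state, idx, params)
    if (params$D > 0) {
      m <- floor(params$D) + (stats::runif(1) < params$D %% 1)
      for (q in seq_len(m)) {
        u <- sample.int(N2, 1L)
        r <- (u - 1L) %/% state$N + 1L
        c <- (u - 1L) %% state$N + 1L
        nb <- moore_neighbors(r, c, 1L, state$N)
        v <- nb[sample.int(8L, 1L), ]
        v <- (v[1] - 1L) * state$N + v[2]
        tmp_occ <- state$occ[u]; state$occ[u] <- state$occ[v]; state$occ[v] <- tmp_occ
        tmp_age <- state$age[u]; state$age[u] <- state$age[v]; state$age[v] <- tmp_age
        tmp_tag <- state$tag[u]; state$tag[u] <- state$tag[v]; state$tag[v] <- tmp_tag
        tmp_al <- state$alleles[, u]
        state$alleles[, u] <- state$alleles[, v]
        state$alleles[, v] <- tmp_al
      }
    }
  }
  state$age[state$occ == 1L] <- state$age[state$occ == 1L] + 1L
  state$t <- t
  state
}
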