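#' Lattice summary statistics
#'
#' Computes the per-generation observables from a lattice state: occupancy,
#' and over occupied sites only the means of aging rate, age, mortality
#' (hazard evaluated at each occupant's current age), normalised fecundity
#' `b^(s - Lf)`, target match `s`, Hamming distance to the target
#' `Lf - s`, the tagged-lineage frequency, and the population Pearson
#' correlation between aging rate and normalised fecundity (reported as
#' `NA` when either variance is zero, never silently 0).  Pure function of
#' the state.
#'
#' @param state a `lattice_state`.
#' @param params the matching [sim_params()].
#' @return A one-row data.frame with the same columns as the `metrics`
#'   table of [run_sim()] (counters `deaths`/`births`/`swaps` are `NA`:
#'   they are properties of a generation, not of a state).
#' @export
summarize_lattice <- function(state, params) {
  stopifnot(inherits(state, "lattice_state"))
  occ <- state$occ == 1L
  nocc <- sum(occ)
  out <- data.frame(t = state$t, occupancy = nocc / state$N^2,
                    mean_alpha = NA_real_, mean_age = NA_real_,
                    mean_mortality = NA_real_, mean_baseline = NA_real_,
                    mean_fecundity = NA_real_, corr_alpha_fec = NA_real_,
                    mean_match = NA_real_, mean_hamming = NA_real_,
                    invader_freq = NA_real_, deaths = NA_real_,
                    births = NA_real_, swaps = NA_real_)
  if (nocc == 0L) return(out)
  na_cnt <- colSums(matrix(as.integer(
    state$alleles[state$layout$sen_pos, occ, drop = FALSE]),
    nrow = state$layout$La))
  s <- state_match(state)[occ]
  alpha <- if (params$evolvable_baseline) rep(0, nocc) else 0.01 * na_cnt
  base <- if (params$evolvable_baseline) 0.002 + 0.01 * na_cnt
          else rep(params$delta0, nocc)
  mort <- if (params$evolvable_baseline) base
          else death_probability(alpha, state$age[occ], params$delta0)
  fec <- fecundity(s, params$b, params$Lf)
  out$mean_alpha <- mean(alpha)
  out$mean_age <- mean(state$age[occ])
  out$mean_mortality <- mean(mort)
  out$mean_baseline <- mean(base)
  out$mean_fecundity <- mean(fec)
  out$mean_match <- mean(s)
  out$mean_hamming <- params$Lf - mean(s)
  out$invader_freq <- mean(state$tag[occ] > 0L)
  vx <- mean(alpha^2) - mean(alpha)^2
  vy <- mean(fec^2) - mean(fec)^2
  if (vx > 1e-16 && vy > 1e-16)
    out$corr_alpha_fec <- (mean(alpha * fec) - mean(alpha) * mean(fec)) /
      sqrt(vx * vy)
  out
}

#' Mean Hamming distance to the target genotype
#'
#' Lattice mean of `Lf - s` over occupied sites, where `s` is the number
#' of fecundity alleles matching the current optimum.
#'
#' @param state a `lattice_state`.
#' @return Mean Hamming distance in `[0, Lf]` (`NA` for an empty lattice).
#' @export
mean_hamming_to_target <- function(state) {
  s <- state_match(state)
  state$layout$Lf - mean(s, na.rm = TRUE)
}

#' Spatial gradient profile of the aging rate
#'
#' For each Chebyshev distance `d = 1, ..., d_max` (torus metric, matching
#' the Moore-neighbourhood geometry), the mean and standard deviation of
#' the absolute aging-rate difference over all pairs of occupied sites
#' exactly `d` apart.  In a viscous evolved population the profile rises
#' with distance until the characteristic length of the local aging-rate
#' gradients is exceeded, then saturates.  All pairs are enumerated
#' exactly by lattice shifts.
#'
#' @param state a `lattice_state`.
#' @param d_max largest distance (must satisfy `2 * d_max < N` so distinct
#'   offsets stay distinct distances on the torus).
#' @return Data.frame with columns `d`, `mean_abs_dalpha`, `sd_abs_dalpha`,
#'   `n_pairs`.
#' @export
aging_gradient_profile <- function(state, d_max = 10L) {
  stopifnot(inherits(state, "lattice_state"), d_max >= 1L)
  N <- state$N
  if (2L * d_max >= N) stop("need 2 * d_max < N on the torus", call. = FALSE)
  a <- matrix(state_alpha(state), nrow = N, byrow = TRUE)  # row-major sites
  shift <- function(m, dx, dy) {
    ri <- ((seq_len(N) - 1L + dx) %% N) + 1L
    ci <- ((seq_len(N) - 1L + dy) %% N) + 1L
    m[ri, ci, drop = FALSE]
  }
  res <- data.frame(d = seq_len(d_max), mean_abs_dalpha = NA_real_,
                    sd_abs_dalpha = NA_real_, n_pairs = 0L)
  for (d in seq_len(d_max)) {
    offs <- expand.grid(dx = -d:d, dy = -d:d)
    offs <- offs[pmax(abs(offs$dx), abs(offs$dy)) == d, ]
    # half ring: count each unordered pair once
    offs <- offs[offs$dx > 0 | (offs$dx == 0 & offs$dy > 0), ]
    diffs <- c()
    for (i in seq_len(nrow(offs))) {
      dd <- abs(a - shift(a, offs$dx[i], offs$dy[i]))
      diffs <- c(diffs, dd[!is.na(dd)])
    }
    res$mean_abs_dalpha[d] <- mean(diffs)
    res$sd_abs_dalpha[d] <- stats::sd(diffs)
    res$n_pairs[d] <- length(diffs)
  }
  res
}

#' Age distribution of the population
#'
#' @param state a `lattice_state`.
#' @return Data.frame with columns `age` and `count`; counts sum to the
#'   number of occupied sites.
#' @export
age_histogram <- function(state) {
  ages <- state$age[state$occ == 1L]
  tab <- table(factor(ages, levels = 0:max(c(ages, 0L))))
  data.frame(age = as.integer(names(tab)), count = as.integer(tab))
}
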