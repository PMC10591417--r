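engine_par <- function(params) {
  list(N = params$N, delta0 = params$delta0, b = params$b, n = params$n,
       T = params$T, prec = params$prec,
       pf = if (params$monomorphic_fertility) 0 else params$pf,
       pa = params$pa, D = params$D,
       sexual = params$reproduction == "sexual",
       directional = params$selection == "directional" &&
         !params$monomorphic_fertility,
       config_field = params$config_field,
       evolvable_baseline = params$evolvable_baseline)
}

#' Run the senescence lattice simulation
#'
#' Seeds the RNG, initialises the lattice (unless a state to resume from is
#' given) and advances it by `generations` generations of `N^2`
#' asynchronous Monte Carlo updates each.  Every elementary update draws a
#' uniformly random site; an occupant dies with its age-dependent hazard,
#' and an empty site (whether just vacated or found empty) is contested by
#' the fecundity-weighted candidates of its neighbourhood.  Ages advance
#' synchronously at each generation's end.  Runs are bit-reproducible from
#' `(params, seed)`.
#'
#' @param params a [sim_params()] object.
#' @param generations number of generations to simulate (defaults to
#'   `params$generations`).
#' @param seed RNG seed (defaults to `params$seed`; required one way or the
#'   other).
#' @param state optional `lattice_state` to resume from instead of a fresh
#'   initialisation (used for invasions and snapshot restarts).
#' @return An object of class `senescence_sim`: list with `params`, `seed`,
#'   `metrics` (one row per generation: occupancy, mean aging rate, mean
#'   age, mean mortality, mean normalised fecundity, aging--fecundity
#'   correlation, mean target match and Hamming distance, tagged-lineage
#'   frequency, death/birth/swap counts) and `state` (final
#'   `lattice_state`).
#' @examples
#' p <- sim_params(N = 30, generations = 50)
#' sim <- run_sim(p, seed = 1)
#' summary(sim)
#' @export
run_sim <- function(params, generations = params$generations,
                    seed = params$seed, state = NULL) {
  stopifnot(inherits(params, "sim_params"))
  if (is.na(seed)) stop("a seed is required for a reproducible run", call. = FALSE)
  generations <- as.integer(generations)
  stopifnot(generations >= 1L)
  set.seed(as.integer(seed))
  if (is.null(state)) state <- initialize_lattice(params)
  out <- resume_engine(state, params, generations)
  res <- list(params = params, seed = as.integer(seed),
              generations = generations,
              metrics = out$metrics, state = out$state)
  class(res) <- "senescence_sim"
  res
}

# advance an existing state without touching the RNG seed
resume_engine <- function(state, params, generations) {
  stopifnot(inherits(state, "lattice_state"))
  if (state$N != params$N) stop("state and params disagree on N", call. = FALSE)
  eng <- engine_run(state$occ, state$age, state$tag, state$alleles,
                    state$layout$fec_pos - 1L, state$layout$sen_pos - 1L,
                    state$target$phi, state$target$phase, state$t,
                    as.integer(generations), engine_par(params))
  new_state <- state
  new_state$occ <- eng$occ
  new_state$age <- eng$age
  new_state$tag <- eng$tag
  new_state$alleles <- eng$alleles
  new_state$target$phi <- eng$target
  new_state$target$phase <- eng$phase
  new_state$t <- eng$t
  list(metrics = as.data.frame(eng$metrics), state = new_state)
}

#' Continue a finished run
#'
#' Advances the final state of `sim` by further generations, re-seeding the
#' RNG so the continuation is itself reproducible.
#'
#' @param sim a `senescence_sim`.
#' @param generations generations to append.
#' @param seed seed for the continuation.
#' @return A new `senescence_sim` whose `metrics` contain the full
#'   concatenated history.
#' @export
continue_sim <- function(sim, generations, seed) {
  stopifnot(inherits(sim, "senescence_sim"))
  set.seed(as.integer(seed))
  out <- resume_engine(sim$state, sim$params, as.integer(generations))
  sim$metrics <- rbind(sim$metrics, out$metrics)
  sim$state <- out$state
  sim$generations <- sim$generations + as.integer(generations)
  sim
}

#' Time-averaged metrics over an equilibrium window
#'
#' @param sim a `senescence_sim`.
#' @param window generation range `c(from, to)` (inclusive, absolute
#'   indices); defaults to the last 40% of the run.
#' @return Named numeric vector of window means of all metric columns.
#' @export
window_means <- function(sim, window = NULL) {
  m <- sim$metrics
  if (is.null(window)) {
    from <- m$t[1] + ceiling(0.6 * (m$t[nrow(m)] - m$t[1] + 1))
    window <- c(from, m$t[nrow(m)])
  }
  sel <- m$t >= window[1] & m$t <= window[2]
  if (!any(sel)) stop("window outside the recorded generations", call. = FALSE)
  cols <- setdiff(names(m), "t")
  vapply(m[sel, cols], mean, numeric(1), na.rm = TRUE)
}

#' @export
print.senescence_sim <- function(x, ...) {
  p <- x$params
  last <- x$metrics[nrow(x$metrics), ]
  cat(sprintf("senescence_sim: %s %s, %d x %d, %d generations (seed %d)\n",
              p$reproduction, p$selection, p$N, p$N, nrow(x$metrics), x$seed))
  cat(sprintf("  final: occupancy %.4f, mean alpha %.4f, mean age %.2f\n",
              last$occupancy, last$mean_alpha, last$mean_age))
  invisible(x)
}

#' @export
summary.senescence_sim <- function(object, window = NULL, ...) {
  wm <- window_means(object, window)
  out <- list(params = object$params, generations = nrow(object$metrics),
              window_means = wm)
  class(out) <- "summary.senescence_sim"
  out
}

#' @export
print.summary.senescence_sim <- function(x, ...) {
  cat(sprintf("senescence_sim over %d generations\n", x$generations))
  cat("equilibrium-window means:\n")
  keep <- c("occupancy", "mean_alpha", "mean_age", "mean_mortality",
            "mean_fecundity", "mean_hamming", "corr_alpha_fec")
  print(round(x$window_means[keep], 4))
  invisible(x)
}

#' Plot metric trajectories
#'
#' Base-graphics panels of the lattice means of aging rate, age, mortality
#' and normalised fecundity against time.
#'
#' @param x a `senescence_sim`.
#' @param which metric columns to draw.
#' @param ... passed to [graphics::plot.default()].
#' @export
plot.senescence_sim <- function(x, which = c("mean_alpha", "mean_age",
                                             "mean_mortality",
                                             "mean_fecundity"), ...) {
  m <- x$metrics
  labs <- c(mean_alpha = expression(bar(alpha)),
            mean_age = expression(bar(tau)),
            mean_mortality = expression(bar(delta)),
            mean_fecundity = expression(bar(phi)),
            occupancy = "occupancy",
            mean_hamming = "Hamming distance to target",
            corr_alpha_fec = expression(r(alpha, phi)),
            invader_freq = "tagged-lineage frequency")
  old <- graphics::par(mfrow = grDevices::n2mfrow(length(which)),
                       mar = c(4, 4, 1, 1))
  on.exit(graphics::par(old))
  for (w in which) {
    yl <- if (w %in% names(labs)) labs[[w]] else w
    graphics::plot(m$t, m[[w]], type = "l", xlab = "generation", ylab = yl, ...)
  }
  invisible(x)
}
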