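#' Parameter sweep with stabilizing controls
#'
#' Runs the simulator over a grid of values of one parameter, with several
#' replicate seeds per value, and reports equilibrium-window means of all
#' observables.  Unless `control = FALSE`, a matched stabilizing-selection
#' control (identical parameters except `selection = "stabilizing"`) is run
#' for every value, enabling the "directional minus stabilizing" estimator
#' of the beneficial effect of aging.  Replicate seeds are derived
#' deterministically from `base_seed`, so the whole sweep is a pure
#' function of `(spec, base_seed)`.
#'
#' @param params base [sim_params()].
#' @param param name of the swept parameter; `"p"` sweeps `pf` and `pa`
#'   jointly.
#' @param values vector of values to sweep.
#' @param replicates runs per value (>= 1).
#' @param generations run length per replicate.
#' @param window equilibrium window `c(from, to)` for time-averaging;
#'   defaults to the last 40% of the run (after the transient).
#' @param base_seed integer; replicate `r` of value `i` uses seed
#'   `base_seed + 1000 * (i - 1) + (r - 1)` (controls are offset by
#'   500000).
#' @param control run the stabilizing control alongside each value.
#' @return A data.frame of class `senescence_sweep`, one row per
#'   value x replicate x regime, holding the window means plus `param`,
#'   `value`, `regime`, `replicate`, `seed`.
#' @export
run_sweep <- function(params, param, values, replicates = 3L,
                      generations = params$generations, window = NULL,
                      base_seed = 1L, control = TRUE) {
  stopifnot(inherits(params, "sim_params"), length(values) >= 1L)
  if (replicates < 1L) stop("replicates must be >= 1", call. = FALSE)
  known <- c(names(unclass(params)), "p")
  if (!param %in% known) stop("unknown sweep parameter: ", param, call. = FALSE)
  rows <- list()
  for (i in seq_along(values)) {
    v <- values[i]
    pv <- if (param == "p") update_params(params, pf = v, pa = v)
          else do.call(update_params, stats::setNames(list(params, v),
                                                      c("object", param)))
    for (r in seq_len(replicates)) {
      seed <- base_seed + 1000L * (i - 1L) + (r - 1L)
      regimes <- list(list(p = pv, regime = pv$selection, seed = seed))
      if (control && pv$selection != "stabilizing")
        regimes <- c(regimes, list(list(
          p = update_params(pv, selection = "stabilizing"),
          regime = "stabilizing", seed = seed + 500000L)))
      for (rg in regimes) {
        sim <- run_sim(rg$p, generations = generations, seed = rg$seed)
        wm <- window_means(sim, window)
        rows[[length(rows) + 1L]] <-
          cbind(data.frame(param = param, value = v, regime = rg$regime,
                           replicate = r, seed = rg$seed),
                as.data.frame(as.list(wm)))
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "window") <- window
  attr(out, "generations") <- generations
  class(out) <- c("senescence_sweep", "data.frame")
  out
}

#' Transition point of a sweep
#'
#' The smallest (or largest) swept value at which the directional
#' equilibrium aging rate is no longer distinguishable from the
#' stabilizing control: the across-replicate mean difference falls below
#' `n_sd` across-replicate standard deviations of the control at that
#' value (a pooled control SD is used as a floor when a per-value SD
#' degenerates to 0).
#'
#' @param sweep a [run_sweep()] result containing both regimes.
#' @param metric column to compare (default `"mean_alpha"`).
#' @param n_sd separation threshold in control SD units.
#' @param from direction of the scan: `"small"` reports the smallest
#'   indistinguishable value, `"large"` the largest.
#' @return The transition value (`NA` if every value stays distinguishable).
#' @export
sweep_threshold <- function(sweep, metric = "mean_alpha", n_sd = 2,
                            from = c("small", "large")) {
  from <- match.arg(from)
  stopifnot(inherits(sweep, "senescence_sweep"))
  vals <- sort(unique(sweep$value))
  ctl <- sweep[sweep$regime == "stabilizing", ]
  dir <- sweep[sweep$regime != "stabilizing", ]
  if (!nrow(ctl) || !nrow(dir))
    stop("sweep must contain both regimes", call. = FALSE)
  pooled_sd <- stats::sd(ctl[[metric]])
  indist <- vapply(vals, function(v) {
    d <- dir[[metric]][dir$value == v]
    c0 <- ctl[[metric]][ctl$value == v]
    s0 <- stats::sd(c0)
    if (!is.finite(s0) || s0 == 0) s0 <- pooled_sd
    mean(d) - mean(c0) < n_sd * s0
  }, logical(1))
  if (!any(indist)) return(NA_real_)
  if (from == "small") vals[which(indist)[1]] else vals[max(which(indist))]
}

#' Invasibility experiment
#'
#' Equilibrates a resident population, replaces the genomes of a random
#' fraction of occupied sites with an invader genotype of fixed aging rate
#' (the residents' fecundity alleles and ages are kept, so only the aging
#' genotype is perturbed), and follows the system for a further horizon.
#'
#' Two bookkeeping devices track the invaders: a neutral descent tag
#' (inherited by any offspring with at least one tagged parent — under
#' sexual reproduction this genealogical measure grows towards 1 for any
#' sizable founding fraction regardless of selection, so it is reported
#' only as a diagnostic), and the frequency of carriers of senescence
#' alleles in state 1, which with `pa = 0` is an exact census of
#' invader-derived aging alleles and is the basis of the establishment
#' verdict.
#'
#' @param params resident [sim_params()] (typically `pa = 0` for a
#'   non-aging resident).
#' @param invader_alpha aging rate of the introduced genotype (a multiple
#'   of 0.01).
#' @param fraction fraction of occupied sites replaced, in `[0, 1)`.
#' @param equilibration resident generations before the introduction.
#' @param horizon generations after the introduction.
#' @param seed RNG seed for the whole experiment.
#' @param threshold establishment threshold on the carrier frequency.
#' @return Object of class `senescence_invasion`: list with the combined
#'   `metrics`, the pre-invasion window statistics (`mean`, `sd`, slope
#'   p-value of the trailing aging-rate trend), the final carrier
#'   frequency, and the `verdict` (`established`, and `relaxed` -- whether
#'   the final aging rate is within 2 pre-invasion SDs of the resident
#'   equilibrium).
#' @export
run_invasion <- function(params, invader_alpha, fraction, equilibration,
                         horizon, seed, threshold = 0.05) {
  stopifnot(inherits(params, "sim_params"),
            fraction >= 0, fraction < 1)
  k <- as.integer(round(invader_alpha * 100))
  if (abs(invader_alpha * 100 - k) > 1e-8 || k < 0 || k > params$La)
    stop("invader_alpha must be a multiple of 0.01 in [0, 0.01*La]",
         call. = FALSE)
  resident <- run_sim(params, generations = equilibration, seed = seed)

  m <- resident$metrics
  wsel <- m$t > equilibration * 0.75
  pre_mean <- mean(m$mean_alpha[wsel])
  pre_sd <- stats::sd(m$mean_alpha[wsel])
  slope_p <- tryCatch({
    fit <- stats::lm(mean_alpha ~ t, data = m[wsel, ])
    stats::coef(summary(fit))["t", "Pr(>|t|)"]
  }, error = function(e) NA_real_)

  state <- resident$state
  if (fraction > 0) {
    occ_sites <- which(state$occ == 1L)
    n_inv <- round(fraction * length(occ_sites))
    inv_sites <- sample(occ_sites, n_inv)
    sen <- state$layout$sen_pos
    state$alleles[sen, inv_sites] <- as.raw(0L)
    if (k > 0) state$alleles[sen[seq_len(k)], inv_sites] <- as.raw(1L)
    state$tag[inv_sites] <- 1L
  }
  post <- resume_engine(state, params, horizon)

  carriers <- carrier_frequency(post$state)
  metrics <- rbind(m, post$metrics)
  final_alpha <- mean(post$metrics$mean_alpha[
    post$metrics$t > equilibration + horizon * 0.75])
  out <- list(params = params, invader_alpha = invader_alpha,
              fraction = fraction, introduced_at = equilibration,
              metrics = metrics,
              pre = list(mean_alpha = pre_mean, sd_alpha = pre_sd,
                         slope_p = slope_p),
              carrier_freq = carriers,
              final_alpha = final_alpha,
              verdict = list(
                established = is.finite(carriers) && carriers > threshold,
                relaxed = abs(final_alpha - pre_mean) <=
                  2 * max(pre_sd, .Machine$double.eps)))
  class(out) <- "senescence_invasion"
  out
}

# frequency of occupied sites carrying at least one ON senescence allele
carrier_frequency <- function(state) {
  occ <- state$occ == 1L
  if (!any(occ)) return(NA_real_)
  na_cnt <- colSums(matrix(as.integer(
    state$alleles[state$layout$sen_pos, occ, drop = FALSE]),
    nrow = state$layout$La))
  mean(na_cnt > 0L)
}

#' @export
print.senescence_invasion <- function(x, ...) {
  cat(sprintf("invasion: alpha = %g at fraction %.2f into %s resident\n",
              x$invader_alpha, x$fraction, x$params$selection))
  cat(sprintf("  pre-invasion mean alpha %.4f (sd %.2g), carriers at end %.4f\n",
              x$pre$mean_alpha, x$pre$sd_alpha, x$carrier_freq))
  cat(sprintf("  established: %s; relaxed to resident equilibrium: %s\n",
              x$verdict$established, x$verdict$relaxed))
  invisible(x)
}

#' Run a model variant
#'
#' Convenience wrapper that switches one of the model variants on and runs
#' the simulator: `"config_field"` (parents from random lattice sites),
#' `"monomorphic_fertility"` (only senescence alleles evolve),
#' `"evolvable_baseline"` (senescence alleles encode age-independent
#' mortality `0.002 + 0.01 * sum(a)`), or `"fixed_alpha"` (constant,
#' non-evolving aging rate; pass `fixed_alpha`).  Inconsistent
#' combinations are rejected by [sim_params()] validation.
#'
#' @param name variant name.
#' @param params base [sim_params()].
#' @param fixed_alpha aging rate for the `"fixed_alpha"` variant.
#' @param ... passed to [run_sim()] (`generations`, `seed`).
#' @return A `senescence_sim`.
#' @export
run_variant <- function(name = c("config_field", "monomorphic_fertility",
                                 "evolvable_baseline", "fixed_alpha"),
                        params, fixed_alpha = NULL, ...) {
  name <- match.arg(name)
  p <- switch(name,
    config_field = update_params(params, config_field = TRUE),
    monomorphic_fertility = update_params(params, monomorphic_fertility = TRUE),
    evolvable_baseline = update_params(params, evolvable_baseline = TRUE),
    fixed_alpha = {
      if (is.null(fixed_alpha))
        stop("fixed_alpha value required", call. = FALSE)
      update_params(params, fixed_alpha = fixed_alpha)
    })
  run_sim(p, ...)
}
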