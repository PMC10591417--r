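#' Simulation parameters
#'
#' Constructs and validates the full parameter set of the lattice model of
#' evolving senescence.  Defaults are the standard values used throughout:
#' a 200 x 200 torus, 50 fecundity and 50 senescence loci, baseline
#' mortality 0.05, fitness base 1.2, Moore radius 1, one target-locus flip
#' every 10 generations, obligate single-point recombination, per-bit
#' mutation rate 0.01 for both locus classes, and no diffusive mixing.
#'
#' @param N lattice side length; the population lives on an `N x N` torus.
#' @param Lf number of fecundity loci.
#' @param La number of senescence loci.
#' @param delta0 age-independent baseline mortality per generation, in (0,1).
#' @param b base of the multiplicative fecundity function `b^s`, where `s`
#'   counts fecundity alleles matching the environmental optimum; `b > 1`.
#' @param n Moore-neighbourhood radius for reproduction: an empty site can be
#'   colonised from the `(2n+1)^2 - 1` surrounding sites.
#' @param T generations between single-locus flips of the moving optimum
#'   ("fitness period dilution").
#' @param prec probability of single-point recombination for sexual
#'   reproduction.
#' @param pf,pa per-bit mutation (flip) probabilities for fecundity and
#'   senescence alleles.
#' @param D diffusion parameter: expected number of random adjacent-pair
#'   site swaps appended to each elementary update.  `D = 0.5` corresponds
#'   to one lattice step per site per generation on average.
#' @param reproduction `"sexual"` (two distinct parents, recombination) or
#'   `"asexual"` (clonal copy of one parent).
#' @param selection `"directional"` (moving optimum) or `"stabilizing"`
#'   (static random optimum).
#' @param config_field if `TRUE`, candidate parents for an empty site are
#'   drawn from eight random lattice sites instead of the local
#'   neighbourhood, destroying relatedness (mean-field control).
#' @param monomorphic_fertility if `TRUE`, all individuals share a fixed
#'   fecundity genotype that never mutates (`pf` must be 0); only
#'   senescence alleles evolve.
#' @param evolvable_baseline if `TRUE`, the senescence alleles encode an
#'   age-independent baseline mortality `0.002 + 0.01 * sum(a)` instead of
#'   an aging rate (the age-dependent term is switched off).
#' @param fixed_alpha optional fixed aging rate: every individual starts
#'   with `round(100 * fixed_alpha)` senescence alleles ON and `pa` must be
#'   0 so the rate cannot evolve.  `NA` (default) disables the variant.
#' @param generations default run length used by [run_sim()].
#' @param seed optional default RNG seed for [run_sim()].
#'
#' @return An object of class `sim_params` (a validated named list).
#' @seealso [run_sim()], [load_config()]
#' @examples
#' p <- sim_params(N = 50, generations = 200)
#' p
#' @export
sim_params <- function(N = 200, Lf = 50, La = 50, delta0 = 0.05, b = 1.2,
                       n = 1, T = 10, prec = 1, pf = 0.01, pa = 0.01, D = 0,
                       reproduction = c("sexual", "asexual"),
                       selection = c("directional", "stabilizing"),
                       config_field = FALSE, monomorphic_fertility = FALSE,
                       evolvable_baseline = FALSE, fixed_alpha = NA,
                       generations = 10000, seed = NA) {
  reproduction <- match.arg(reproduction)
  selection <- match.arg(selection)
  p <- list(N = as.integer(N), Lf = as.integer(Lf), La = as.integer(La),
            delta0 = delta0, b = b, n = as.integer(n), T = as.integer(T),
            prec = prec, pf = pf, pa = pa, D = D,
            reproduction = reproduction, selection = selection,
            config_field = isTRUE(config_field),
            monomorphic_fertility = isTRUE(monomorphic_fertility),
            evolvable_baseline = isTRUE(evolvable_baseline),
            fixed_alpha = if (is.na(fixed_alpha)) NA_real_
                          else as.numeric(fixed_alpha),
            generations = as.integer(generations),
            seed = if (is.na(seed)) NA_integer_ else as.integer(seed))
  validate_params(p)
  class(p) <- "sim_params"
  p
}

validate_params <- function(p) {
  stopifnot(is.list(p))
  chk <- function(cond, msg) if (!cond) stop(msg, call. = FALSE)
  chk(length(p$N) == 1L && !is.na(p$N) && p$N >= 3L, "N must be an integer >= 3")
  chk(p$Lf >= 1L, "Lf must be a positive integer")
  chk(p$La >= 1L, "La must be a positive integer")
  chk(is.numeric(p$delta0) && p$delta0 > 0 && p$delta0 < 1,
      "delta0 must lie in (0, 1)")
  chk(is.numeric(p$b) && p$b > 1, "b must be > 1")
  chk(p$n >= 1L, "n must be a positive integer")
  chk(p$N >= 2L * p$n + 1L, "N must be at least 2*n + 1")
  chk(p$T >= 1L, "T must be a positive integer")
  for (key in c("prec", "pf", "pa")) {
    v <- p[[key]]
    chk(is.numeric(v) && length(v) == 1L && v >= 0 && v <= 1,
        paste0(key, " must be a probability in [0, 1]"))
  }
  chk(is.numeric(p$D) && p$D >= 0, "D must be >= 0")
  chk(p$reproduction %in% c("sexual", "asexual"), "invalid reproduction mode")
  chk(p$selection %in% c("directional", "stabilizing"), "invalid selection mode")
  chk(p$generations >= 1L, "generations must be a positive integer")
  if (!is.na(p$fixed_alpha)) {
    fa <- p$fixed_alpha
    chk(is.numeric(fa) && fa >= 0 && fa <= 0.01 * p$La + 1e-12,
        "fixed_alpha must lie in [0, 0.01 * La]")
    chk(abs(fa * 100 - round(fa * 100)) < 1e-8,
        "fixed_alpha must be a multiple of 0.01 (one senescence allele each)")
    chk(p$pa == 0, "fixed_alpha requires pa = 0 (aging rate must not mutate)")
    chk(!p$evolvable_baseline,
        "fixed_alpha and evolvable_baseline cannot be combined")
  }
  if (p$monomorphic_fertility)
    chk(p$pf == 0, "monomorphic_fertility requires pf = 0")
  invisible(p)
}

#' Modify a parameter set
#'
#' Returns a copy of `params` with the named fields replaced, re-validated.
#'
#' @param object a [sim_params()] object.
#' @param ... fields to replace, e.g. `T = 32`, `selection = "stabilizing"`.
#' @return A new `sim_params` object.
#' @export
update_params <- function(object, ...) {
  stopifnot(inherits(object, "sim_params"))
  upd <- list(...)
  bad <- setdiff(names(upd), names(unclass(object)))
  if (length(bad))
    stop("unknown parameter(s): ", paste(bad, collapse = ", "), call. = FALSE)
  p <- unclass(object)
  for (k in names(upd)) p[[k]] <- upd[[k]]
  do.call(sim_params, p)
}

#' @export
print.sim_params <- function(x, ...) {
  cat("Senescence lattice model parameters\n")
  cat(sprintf("  grid %d x %d (torus), Lf = %d, La = %d\n", x$N, x$N, x$Lf, x$La))
  cat(sprintf("  delta0 = %g, b = %g, n = %d, T = %d\n", x$delta0, x$b, x$n, x$T))
  cat(sprintf("  prec = %g, pf = %g, pa = %g, D = %g\n", x$prec, x$pf, x$pa, x$D))
  cat(sprintf("  %s reproduction, %s selection\n", x$reproduction, x$selection))
  flags <- c(if (x$config_field) "config_field",
             if (x$monomorphic_fertility) "monomorphic_fertility",
             if (x$evolvable_baseline) "evolvable_baseline",
             if (!is.na(x$fixed_alpha)) sprintf("fixed_alpha = %g", x$fixed_alpha))
  if (length(flags)) cat("  variants:", paste(flags, collapse = ", "), "\n")
  cat(sprintf("  run length %d generations%s\n", x$generations,
              if (is.na(x$seed)) "" else sprintf(", seed %d", x$seed)))
  invisible(x)
}

config_keys <- function() {
  c("N", "Lf", "La", "delta0", "b", "n", "T", "prec", "pf", "pa", "D",
    "reproduction", "selection", "config_field", "monomorphic_fertility",
    "evolvable_baseline", "fixed_alpha", "generations", "seed")
}

#' Read a simulation configuration file
#'
#' Configuration files are flat `key = value` text, one pair per line, with
#' `#` comments.  Keys are named after the model symbols (`N`, `Lf`, `La`,
#' `delta0`, `b`, `n`, `T`, `prec`, `pf`, `pa`, `D`) plus the mode switches
#' accepted by [sim_params()].  Missing keys take the standard defaults;
#' unknown keys are an error.
#'
#' @param path file to read.
#' @return A validated [sim_params()] object.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  args <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2L)
      stop("malformed config line: '", ln, "'", call. = FALSE)
    key <- trimws(kv[1]); val <- trimws(kv[2])
    if (!key %in% config_keys())
      stop("unknown config key: '", key, "'", call. = FALSE)
    args[[key]] <-
      if (key %in% c("reproduction", "selection")) val
      else if (key %in% c("config_field", "monomorphic_fertility",
                          "evolvable_baseline")) as.logical(val)
      else if (toupper(val) == "NA") NA
      else as.numeric(val)
  }
  do.call(sim_params, args)
}

#' Write a simulation configuration file
#'
#' @param params a [sim_params()] object.
#' @param path file to write.
#' @return `path`, invisibly.
#' @export
write_config <- function(params, path) {
  stopifnot(inherits(params, "sim_params"))
  p <- unclass(params)
  fmt <- vapply(config_keys(), function(k) {
    v <- p[[k]]
    paste(k, "=", if (is.character(v)) v else format(v, digits = 15))
  }, character(1))
  writeLines(fmt, path)
  invisible(path)
}
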