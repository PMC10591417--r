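#' Selective environments
#'
#' The environment is a binary optimum ("target") vector of length `Lf`
#' against which fecundity genotypes are matched.  Under directional
#' selection the target starts as the zero vector and drifts: every `T`
#' generations one randomly chosen element opposite to the current phase
#' flips, sweeping up to the all-ones state and back, so a full period
#' spans `2 * T * Lf` generations and consecutive states differ at exactly
#' one locus.  Under stabilizing selection the target is a static random
#' vector.
#'
#' @param Lf number of fecundity loci.
#' @param T generations between flips.
#' @return An object of class `selection_target`: list with `phi` (binary
#'   vector of length `Lf`), `mode` (`"directional"` or `"stabilizing"`),
#'   `T`, and `phase` (+1 ascending, -1 descending; unused when static).
#' @name selection_target
NULL

new_target <- function(phi, mode, T, phase = 1L) {
  t <- list(phi = as.integer(phi), mode = mode, T = as.integer(T),
            phase = as.integer(phase))
  class(t) <- "selection_target"
  t
}

#' @rdname selection_target
#' @export
init_target_directional <- function(Lf, T) {
  if (T < 1) stop("T must be >= 1", call. = FALSE)
  new_target(integer(Lf), "directional", T, 1L)
}

#' @rdname selection_target
#' @export
init_target_stabilizing <- function(Lf) {
  if (Lf < 1) stop("Lf must be >= 1", call. = FALSE)
  new_target(stats::rbinom(Lf, 1L, 0.5), "stabilizing", 1L, 1L)
}

#' Advance the moving optimum
#'
#' Called once per generation boundary.  A flip is due when `t > 0` and
#' `t %% T == 0`; the flipped state is then the optimum for generation
#' `t + 1` onwards.  The phase reverses on the flip that reaches
#' saturation (all ones or all zeros).  Stabilizing targets are returned
#' unchanged.
#'
#' @param target a `selection_target`.
#' @param t generation index just completed (the first flip occurs after
#'   generation `T`).
#' @return The (possibly) advanced target.
#' @export
advance_target <- function(target, t) {
  stopifnot(inherits(target, "selection_target"))
  if (target$mode != "directional") return(target)
  if (t <= 0 || t %% target$T != 0) return(target)
  phi <- target$phi
  if (target$phase > 0) {
    zeros <- which(phi == 0L)
    k <- if (length(zeros) == 1L) zeros else sample(zeros, 1L)
    phi[k] <- 1L
    if (all(phi == 1L)) target$phase <- -1L
  } else {
    ones <- which(phi == 1L)
    k <- if (length(ones) == 1L) ones else sample(ones, 1L)
    phi[k] <- 0L
    if (all(phi == 0L)) target$phase <- 1L
  }
  target$phi <- phi
  target
}

#' @export
print.selection_target <- function(x, ...) {
  cat(sprintf("%s target, Lf = %d", x$mode, length(x$phi)))
  if (x$mode == "directional")
    cat(sprintf(", T = %d, phase %s", x$T,
                if (x$phase > 0) "ascending" else "descending"))
  cat("\n ", paste(x$phi, collapse = ""), "\n")
  invisible(x)
}
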