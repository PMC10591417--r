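#' Random locus layout
#'
#' Draws the run-fixed arrangement of fecundity and senescence loci along
#' the single chromosome.  Positions are a uniformly random permutation of
#' roles, drawn once per run; a recombination cut can therefore separate
#' any mixture of the two locus classes.
#'
#' @param Lf,La numbers of fecundity and senescence loci (both >= 1).
#' @return An object of class `locus_layout`: a list with `Lf`, `La`,
#'   `roles` (integer vector over chromosome positions, 1 = fecundity,
#'   2 = senescence), `fec_pos` and `sen_pos` (chromosome positions of
#'   fecundity locus k and senescence locus j, in locus order).
#' @examples
#' set.seed(1)
#' make_locus_layout(5, 5)
#' @export
make_locus_layout <- function(Lf, La) {
  if (length(Lf) != 1L || length(La) != 1L || is.na(Lf) || is.na(La) ||
      Lf < 1 || La < 1)
    stop("Lf and La must be positive integers", call. = FALSE)
  Lf <- as.integer(Lf); La <- as.integer(La)
  roles <- sample(rep(c(1L, 2L), c(Lf, La)))
  layout <- list(Lf = Lf, La = La, roles = roles,
                 fec_pos = which(roles == 1L), sen_pos = which(roles == 2L))
  class(layout) <- "locus_layout"
  layout
}

check_genome <- function(genome, layout) {
  L <- layout$Lf + layout$La
  if (length(genome) != L)
    stop("genome length must equal Lf + La = ", L, call. = FALSE)
  if (!all(genome %in% c(0L, 1L)))
    stop("genome must be a binary (0/1) vector", call. = FALSE)
  invisible(genome)
}

#' Aging rate of a genome
#'
#' The heritable coefficient of the age-dependent mortality term:
#' `alpha = 0.01 * (number of senescence alleles in state 1)`, so the
#' maximum attainable rate is `0.01 * La`.
#'
#' @param genome binary vector of length `Lf + La` in chromosome order.
#' @param layout the run's [make_locus_layout()].
#' @return Aging rate per generation squared, in `[0, 0.01 * La]`.
#' @export
aging_rate <- function(genome, layout) {
  check_genome(genome, layout)
  0.01 * sum(genome[layout$sen_pos])
}

#' Matching fecundity alleles
#'
#' Counts the fecundity loci at which a genome agrees with the current
#' environmental optimum.
#'
#' @inheritParams aging_rate
#' @param target binary vector of length `Lf` (optimum allele per
#'   fecundity locus).
#' @return Integer `s` in `[0, Lf]`.
#' @export
match_count <- function(genome, layout, target) {
  check_genome(genome, layout)
  if (length(target) != layout$Lf)
    stop("target length must equal Lf = ", layout$Lf, call. = FALSE)
  sum(genome[layout$fec_pos] == target)
}

#' Fecundity from match count
#'
#' Multiplicative fecundity `b^s`.  When `Lf` is supplied the value is
#' normalised by the maximum attainable fecundity `b^Lf`, giving a weight
#' in `(0, 1]`.
#'
#' @param s number of matching fecundity alleles (may be a vector).
#' @param b base of fitness, `b > 1`.
#' @param Lf if given, normalise by `b^Lf`.
#' @return Raw weight `b^s`, or normalised fecundity `b^(s - Lf)`.
#' @export
fecundity <- function(s, b, Lf = NULL) {
  if (!is.numeric(b) || b <= 1) stop("b must be > 1", call. = FALSE)
  if (is.null(Lf)) b^s else b^(s - Lf)
}

#' Bit-flip mutation
#'
#' Flips each fecundity allele independently with probability `pf` and each
#' senescence allele with probability `pa`.  The input genome is not
#' modified.
#'
#' @inheritParams aging_rate
#' @param pf,pa per-bit flip probabilities in `[0, 1]`.
#' @return The mutated genome.
#' @export
mutate_genome <- function(genome, layout, pf, pa) {
  for (v in c(pf, pa))
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1)
      stop("mutation probabilities must lie in [0, 1]", call. = FALSE)
  check_genome(genome, layout)
  g <- as.integer(genome)
  fp <- layout$fec_pos; sp <- layout$sen_pos
  flip_f <- fp[stats::runif(layout$Lf) < pf]
  flip_a <- sp[stats::runif(layout$La) < pa]
  flips <- c(flip_f, flip_a)
  if (length(flips)) g[flips] <- 1L - g[flips]
  g
}

#' Single-point recombination
#'
#' With probability `p_rec`, a crossover point is drawn uniformly from the
#' `L - 1` internal inter-locus positions of the chromosome; the offspring
#' takes the positions left of the cut from one parent and the rest from
#' the other, the orientation being chosen uniformly, so at least one gene
#' comes from each parent.  With probability `1 - p_rec` the offspring is
#' an exact copy of one uniformly chosen parent.  Mutation is not applied
#' here.
#'
#' @param g1,g2 parental genomes (equal length, same layout).
#' @param p_rec crossover probability in `[0, 1]`.
#' @return The recombinant genome.
#' @export
recombine_genomes <- function(g1, g2, p_rec = 1) {
  if (length(g1) != length(g2))
    stop("parental genomes must share the same layout", call. = FALSE)
  if (!is.numeric(p_rec) || p_rec < 0 || p_rec > 1)
    stop("p_rec must lie in [0, 1]", call. = FALSE)
  L <- length(g1)
  if (stats::runif(1) < p_rec) {
    cut <- sample.int(L - 1L, 1L)
    if (stats::runif(1) < 0.5) c(g1[seq_len(cut)], g2[(cut + 1L):L])
    else c(g2[seq_len(cut)], g1[(cut + 1L):L])
  } else {
    if (stats::runif(1) < 0.5) as.integer(g1) else as.integer(g2)
  }
}
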