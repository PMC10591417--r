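# small parameter set used across tests
small_params <- function(...) {
  sim_params(N = 30, generations = 200, ...)
}

# build a lattice state by hand: `sites` is a data.frame with columns
# x, y, age, and a genome matrix `g` (one row per site, chromosome order)
manual_state <- function(N, layout, target, sites, g, tag = NULL) {
  N2 <- N^2
  L <- layout$Lf + layout$La
  st <- list(N = N, occ = integer(N2), age = integer(N2), tag = integer(N2),
             alleles = matrix(as.raw(0L), nrow = L, ncol = N2),
             layout = layout, target = target, t = 0L)
  for (i in seq_len(nrow(sites))) {
    idx <- (sites$x[i] - 1L) * N + sites$y[i]
    st$occ[idx] <- 1L
    st$age[idx] <- as.integer(sites$age[i])
    if (!is.null(tag)) st$tag[idx] <- as.integer(tag[i])
    st$alleles[, idx] <- as.raw(g[i, ])
  }
  class(st) <- "lattice_state"
  st
}

# run the compiled engine for `gens` generations from a given state
engine_step <- function(state, params, gens = 1L) {
  senesim:::resume_engine(state, params, gens)
}
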