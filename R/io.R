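#' Lattice snapshot files
#'
#' Snapshots are delimited text: header comment lines (`# key value`)
#' recording the generation index, lattice size, locus layout (one `F`/`S`
#' character per chromosome position), target vector and phase, followed
#' by one tab-separated row per occupied site: 1-based `x` (row), `y`
#' (column), `age`, `tag`, and the genome as a 0/1 string in chromosome
#' order.  `read_snapshot()` reproduces the `lattice_state` exactly.
#'
#' @param state a `lattice_state`.
#' @param path file to write/read.
#' @return `write_snapshot()` returns `path` invisibly; `read_snapshot()`
#'   returns a `lattice_state`.
#' @export
write_snapshot <- function(state, path) {
  stopifnot(inherits(state, "lattice_state"))
  roles <- paste(c("F", "S")[state$layout$roles], collapse = "")
  hdr <- c(paste("# t", state$t),
           paste("# N", state$N),
           paste("# mode", state$target$mode),
           paste("# T", state$target$T),
           paste("# phase", state$target$phase),
           paste("# roles", roles),
           paste("# target", paste(state$target$phi, collapse = "")),
           "x\ty\tage\ttag\tgenome")
  occ <- which(state$occ == 1L)
  gs <- apply(matrix(as.integer(state$alleles[, occ, drop = FALSE]),
                     nrow = nrow(state$alleles)), 2, paste, collapse = "")
  rows <- sprintf("%d\t%d\t%d\t%d\t%s",
                  (occ - 1L) %/% state$N + 1L, (occ - 1L) %% state$N + 1L,
                  state$age[occ], state$tag[occ], gs)
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' @rdname write_snapshot
#' @export
read_snapshot <- function(path) {
  lines <- readLines(path, warn = FALSE)
  is_hdr <- startsWith(lines, "# ")
  hdr <- lines[is_hdr]
  get <- function(key) {
    ln <- hdr[startsWith(hdr, paste0("# ", key, " "))]
    if (!length(ln)) stop("snapshot header misses key: ", key, call. = FALSE)
    sub(paste0("# ", key, " "), "", ln[1], fixed = TRUE)
  }
  N <- as.integer(get("N"))
  roles_chr <- strsplit(get("roles"), "")[[1]]
  roles <- ifelse(roles_chr == "F", 1L, 2L)
  layout <- list(Lf = sum(roles == 1L), La = sum(roles == 2L), roles = roles,
                 fec_pos = which(roles == 1L), sen_pos = which(roles == 2L))
  class(layout) <- "locus_layout"
  phi <- as.integer(strsplit(get("target"), "")[[1]])
  target <- new_target(phi, get("mode"), as.integer(get("T")),
                       as.integer(get("phase")))
  body <- lines[!is_hdr]
  body <- body[-1]  # column header row
  N2 <- N^2
  L <- length(roles)
  st <- list(N = N, occ = integer(N2), age = integer(N2), tag = integer(N2),
             alleles = matrix(as.raw(0L), nrow = L, ncol = N2),
             layout = layout, target = target, t = as.integer(get("t")))
  if (length(body)) {
    parts <- strsplit(body, "\t", fixed = TRUE)
    for (p in parts) {
      idx <- (as.integer(p[1]) - 1L) * N + as.integer(p[2])
      st$occ[idx] <- 1L
      st$age[idx] <- as.integer(p[3])
      st$tag[idx] <- as.integer(p[4])
      st$alleles[, idx] <- as.raw(as.integer(strsplit(p[5], "")[[1]]))
    }
  }
  class(st) <- "lattice_state"
  st
}

#' Metrics tables on disk
#'
#' Tab-delimited with a single header row, one row per generation.
#'
#' @param metrics a metrics data.frame (from [run_sim()]).
#' @param path file to write/read.
#' @export
write_metrics <- function(metrics, path) {
  utils::write.table(metrics, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_metrics
#' @export
read_metrics <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t")
}

#' Run manifest
#'
#' Writes a JSON record sufficient to reproduce a run bit-for-bit: the
#' full parameter set, seed, generation range, package version, and an
#' inventory of output files.
#'
#' @param sim a `senescence_sim`.
#' @param path file to write.
#' @param files named character vector of output files produced alongside.
#' @export
write_manifest <- function(sim, path, files = character()) {
  stopifnot(inherits(sim, "senescence_sim"))
  man <- list(package = "senesim",
              version = as.character(utils::packageVersion("senesim")),
              params = unclass(sim$params),
              seed = sim$seed,
              generations = nrow(sim$metrics),
              t_final = sim$state$t,
              files = as.list(files))
  jsonlite::write_json(man, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, na = "null")
  invisible(path)
}
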