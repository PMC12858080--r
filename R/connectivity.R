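#' Sample a connectivity matrix from a contact model
#'
#' Draws one realisation of a polymer topology in contact space: beads
#' `0..L` joined by the always-present backbone bonds `(i, i+1)`, plus
#' independent Bernoulli non-backbone bonds for every pair with
#' `|i - j| >= 2` at the model's contact probability. With the default
#' `boundary_factor = 0` non-backbone bonds form only among interior beads
#' `1..L-1`.
#'
#' Sampling is reproducible: one uniform variate is consumed per eligible
#' pair, visited in row-major order over pairs `(i < j)`, using R's global
#' generator (set a seed via `rng_seed` or [set.seed()]).
#'
#' @param model A [contact_model()].
#' @param L Domain length; the network has `L + 1` beads `0..L`.
#' @param rng_seed Optional integer seed.
#' @return An object of class `connectivity_matrix`: a list with `L` and
#'   `bonds`, a two-column 0-based integer matrix of non-backbone bonds
#'   (`i < j`). Backbone bonds are implicit.
#' @examples
#' C <- build_connectivity(contact_model("uniform", p_u = 0.01), L = 100,
#'                         rng_seed = 1)
#' count_bonds(C)
#' @export
build_connectivity <- function(model, L, rng_seed = NULL) {
  stopifnot(inherits(model, "contact_model"), L >= 2, L == round(L))
  if (!is.null(rng_seed)) set.seed(rng_seed)
  bonds <- cpp_sample_bonds(as.integer(L), pc_by_separation(model, L),
                            model$boundary_factor)
  new_connectivity(L, bonds)
}

new_connectivity <- function(L, bonds) {
  storage.mode(bonds) <- "integer"
  colnames(bonds) <- c("i", "j")
  structure(list(L = as.integer(L), bonds = bonds),
            class = "connectivity_matrix")
}

#' Redraw the non-backbone bonds of a network
#'
#' Replaces every non-backbone bond with a fresh, independent draw from the
#' model; the result retains no memory of the previous configuration. The
#' backbone is untouched. This is the elementary move of a dynamically
#' rewired ("annealed") polymer network.
#'
#' @param C A `connectivity_matrix`.
#' @inheritParams build_connectivity
#' @return A new `connectivity_matrix` of the same length.
#' @export
reshuffle_connectivity <- function(C, model, rng_seed = NULL) {
  stopifnot(inherits(C, "connectivity_matrix"))
  build_connectivity(model, C$L, rng_seed)
}

#' Count non-neighbouring bonds
#'
#' `N_b` counts the realised bonds between beads with `|i - j| >= 2`;
#' `N_b_max` is the number of distinct bead pairs that could carry one,
#' `choose(L + 1, 2) - L` for `L + 1` beads.
#'
#' @param C A `connectivity_matrix`.
#' @return A list with `N_b` and `N_b_max`.
#' @export
count_bonds <- function(C) {
  stopifnot(inherits(C, "connectivity_matrix"))
  n <- C$L + 1
  list(N_b = nrow(C$bonds), N_b_max = choose(n, 2) - (n - 1))
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat(sprintf("<connectivity_matrix> beads 0..%d, %d backbone bonds, %d non-backbone bonds\n",
              x$L, x$L, nrow(x$bonds)))
  invisible(x)
}

#' Dense adjacency matrix of a contact network
#'
#' @param x A `connectivity_matrix`.
#' @param ... Unused.
#' @return A symmetric binary `(L+1) x (L+1)` matrix with zero diagonal;
#'   rows and columns are beads `0..L`.
#' @export
as.matrix.connectivity_matrix <- function(x, ...) {
  n <- x$L + 1
  M <- matrix(0L, n, n, dimnames = list(0:x$L, 0:x$L))
  idx <- cbind(seq_len(n - 1), seq_len(n - 1) + 1L)
  M[idx] <- 1L
  M[idx[, 2:1]] <- 1L
  if (nrow(x$bonds) > 0) {
    M[x$bonds + 1L] <- 1L
    M[x$bonds[, 2:1, drop = FALSE] + 1L] <- 1L
  }
  M
}

# degree of every bead (backbone included)
bead_degree <- function(C) {
  deg <- integer(C$L + 1)
  deg[1] <- 1L
  deg[C$L + 1] <- 1L
  if (C$L >= 2) deg[2:C$L] <- 2L
  if (nrow(C$bonds) > 0) {
    tab <- tabulate(c(C$bonds[, 1], C$bonds[, 2]) + 1L, nbins = C$L + 1)
    deg <- deg + tab
  }
  deg
}

#' Read and write contact networks as edge lists
#'
#' Plain TSV with two 0-based integer columns (`i`, `j`), `i < j`, one row
#' per bond including the backbone, preceded by a header line `# L=<int>`.
#'
#' @param C A `connectivity_matrix`.
#' @param path File path.
#' @return `write_edge_list()` returns `path` invisibly; `read_edge_list()`
#'   returns a `connectivity_matrix`.
#' @export
write_edge_list <- function(C, path) {
  stopifnot(inherits(C, "connectivity_matrix"))
  backbone <- cbind(0:(C$L - 1), 1:C$L)
  edges <- rbind(backbone, C$bonds)
  edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# L=%d", C$L), con)
  utils::write.table(edges, con, sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_edge_list
#' @export
read_edge_list <- function(path) {
  header <- readLines(path, n = 1)
  if (!grepl("^# L=\\d+$", header)) stop("missing '# L=<int>' header")
  L <- as.integer(sub("^# L=", "", header))
  edges <- utils::read.table(path, sep = "\t", comment.char = "#",
                             col.names = c("i", "j"))
  if (any(edges$i >= edges$j)) stop("edge list must satisfy i < j")
  keep <- (edges$j - edges$i) >= 2
  new_connectivity(L, as.matrix(edges[keep, , drop = FALSE]))
}

#' Insulate the boundary beads of a network
#'
#' Removes every non-backbone bond touching bead 0 or bead `L`, leaving
#' the absorbing boundaries reachable only by sliding. Networks sampled
#' from a [contact_model()] with `boundary_factor = 0` are insulated by
#' construction; networks derived from 3D conformations or Hi-C maps are
#' not, and can be passed through this function when the insulated-target
#' convention is wanted.
#'
#' @param C A `connectivity_matrix`.
#' @return The insulated `connectivity_matrix`.
#' @export
insulate_boundary <- function(C) {
  stopifnot(inherits(C, "connectivity_matrix"))
  b <- C$bonds
  keep <- b[, 1] != 0L & b[, 2] != C$L
  new_connectivity(C$L, b[keep, , drop = FALSE])
}
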