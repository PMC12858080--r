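# fixture builders shared across test files

chain <- function(L) {
  build_connectivity(contact_model("uniform", p_u = 0), L)
}

# network with explicitly chosen non-backbone bonds; `bonds` is either a
# two-column matrix or a flat vector of (i, j) pairs
with_bonds <- function(L, bonds) {
  C <- chain(L)
  if (!is.matrix(bonds))
    bonds <- matrix(as.integer(bonds), ncol = 2, byrow = TRUE)
  storage.mode(bonds) <- "integer"
  dimnames(bonds) <- list(NULL, c("i", "j"))
  C$bonds <- bonds
  C
}

uniform_model <- function(p_u, bf = 0) {
  contact_model("uniform", p_u = p_u, boundary_factor = bf)
}

powerlaw_model <- function(c = 0.0214, gamma = 0.71, bf = 0) {
  contact_model("powerlaw", c = c, gamma = gamma, boundary_factor = bf)
}

tad_average_model <- function() powerlaw_model(0.0214, 0.71)

# brute-force annealed transition kernel: exact expectation of C_ij / N_i by
# enumerating every configuration of the eligible bonds (oracle; tiny L only)
brute_annealed_kernel <- function(L, model) {
  pairs <- which(upper.tri(matrix(0, L + 1, L + 1)), arr.ind = TRUE) - 1L
  elig <- pairs[pairs[, 2] - pairs[, 1] >= 2, , drop = FALSE]
  p_pair <- contact_probability(model, elig[, 2] - elig[, 1])
  bf <- model$boundary_factor
  p_pair <- p_pair * ifelse(elig[, 1] == 0 | elig[, 2] == L, bf, 1)
  ne <- nrow(elig)
  W <- matrix(0, L + 1, L + 1)
  for (mask in 0:(2^ne - 1)) {
    bits <- as.integer(intToBits(mask))[seq_len(ne)]
    prob <- prod(ifelse(bits == 1, p_pair, 1 - p_pair))
    if (prob == 0) next
    C <- with_bonds(L, elig[bits == 1, , drop = FALSE])
    M <- as.matrix(C)
    deg <- rowSums(M)
    for (i in 2:L) W[i, ] <- W[i, ] + prob * M[i, ] / deg[i]
  }
  W
}

# 1D mean first-passage time from site i on a chain 0..L (closed form)
mfpt_1d <- function(L, i) i * (L - i)
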