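#' Exact mean search times on a fixed (quenched) network
#'
#' Solves the linear system for the mean first-passage time to the
#' absorbing beads 0 and `L` from every starting bead, on one fixed
#' connectivity realisation. The unknowns are the times `T_i` for beads
#' `0..L` plus the bulk (freely diffusing) state `f`:
#' \deqn{T_i = (1 - p_{off}) \sum_j \frac{C_{ij}}{N_i}(c_{ij} + T_j)
#'       + p_{off}(\tau + T_f), \qquad
#'       T_f = \tau_f + \frac{1}{L+1}\sum_{j=0}^{L} T_j,}
#' with `T_0 = T_L = 0`, `N_i` the degree of bead `i`, and per-move cost
#' `c_ij = tau` for a slide and `t_jump` for a hop. With `t_jump = tau`
#' the right-hand side reduces to the constant `tau` on interior rows.
#'
#' The system is solved with a sparse LU factorisation
#' (dense when the network is densely connected).
#'
#' @param C A `connectivity_matrix`.
#' @param params A [walker_params()] (`t_config_switch` is ignored:
#'   quenched means static).
#' @return An object of class `fpt_solution`: `T` (times for beads `0..L`,
#'   units of `tau`), `T_free`, `T_mid` (at bead `floor(L/2)`), `L`, and
#'   the relative residual of the solve.
#' @examples
#' C <- build_connectivity(contact_model("uniform", p_u = 0), L = 4)
#' solve_quenched(C)$T_mid  # pure 1D: L^2/4 = 4
#' @export
solve_quenched <- function(C, params = walker_params()) {
  stopifnot(inherits(C, "connectivity_matrix"),
            inherits(params, "walker_params"))
  L <- C$L
  n <- L + 2                 # beads 0..L then the free state
  deg <- bead_degree(C)
  p_off <- params$p_off

  # triplets for A
  ti <- tj <- tx <- list()
  add <- function(i, j, x) {
    k <- length(ti) + 1
    ti[[k]] <<- i; tj[[k]] <<- j; tx[[k]] <<- x
  }
  add(seq_len(n), seq_len(n), rep(1, n))              # diagonal
  B <- numeric(n)

  # interior rows: couple to bonded neighbours and to the free state
  bonds <- rbind(C$bonds, C$bonds[, 2:1, drop = FALSE])   # directed
  backbone <- cbind(1:L - 1L, 1:L)                        # i -> i+1 slides
  backbone <- rbind(backbone, backbone[, 2:1])
  all_e <- rbind(backbone, bonds)
  cost <- c(rep(params$tau, nrow(backbone)), rep(params$t_jump, nrow(bonds)))
  from <- all_e[, 1]
  keep <- from >= 1 & from <= L - 1
  from <- from[keep]
  to <- all_e[keep, 2]
  cost <- cost[keep]
  w <- (1 - p_off) / deg[from + 1]
  add(from + 2 - 1, to + 1, -w)                       # rows/cols are 1-based
  interior <- 2:L
  if (p_off > 0) add(interior, rep(n, L - 1), rep(-p_off, L - 1))
  B[interior] <- p_off * params$tau
  # expected on-polymer step cost, accumulated per origin bead
  B_move <- vapply(split(w * cost, factor(from, levels = 1:(L - 1))), sum, 0)
  B[interior] <- B[interior] + unname(B_move)

  # free-state row
  add(rep(n, L + 1), 1:(L + 1), rep(-1 / (L + 1), L + 1))
  B[n] <- params$tau_f

  ii <- unlist(ti); jj <- unlist(tj); xx <- unlist(tx)
  dense <- length(xx) / n^2 > 0.05
  if (dense) {
    A <- matrix(0, n, n)
    # accumulate duplicates (diagonal + couplings can coincide only off-diag)
    for (k in seq_along(xx)) A[ii[k], jj[k]] <- A[ii[k], jj[k]] + xx[k]
    Tv <- solve(A, B)
    res <- max(abs(A %*% Tv - B)) / max(abs(B))
  } else {
    A <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n))
    Tv <- as.numeric(Matrix::solve(A, B))
    res <- max(abs(A %*% Tv - B)) / max(abs(B))
  }
  new_fpt_solution(Tv, L, res)
}

new_fpt_solution <- function(Tv, L, residual) {
  Tsites <- Tv[1:(L + 1)]
  names(Tsites) <- 0:L
  structure(list(T = Tsites, T_free = Tv[L + 2], T_mid = Tsites[[L %/% 2 + 1]],
                 L = L, residual = residual),
            class = "fpt_solution")
}

#' @export
print.fpt_solution <- function(x, ...) {
  cat(sprintf("<fpt_solution> L = %d, T_mid = %.6g tau (residual %.2g)\n",
              x$L, x$T_mid, x$residual))
  invisible(x)
}

#' Configuration-averaged quenched search time
#'
#' Averages the exact midpoint search time [solve_quenched()] over
#' `n_configs` independently sampled network realisations.
#'
#' @inheritParams ensemble_search_time
#' @return A `search_estimate` (the `sem` is across configurations;
#'   `n_walks` is `NA` since no stochastic walks are involved).
#' @export
mean_quenched <- function(model, L, params = walker_params(), n_configs = 1,
                          rng_seed = NULL) {
  stopifnot(n_configs >= 1)
  if (!is.null(rng_seed)) set.seed(rng_seed)
  t_mid <- vapply(seq_len(n_configs), function(k) {
    solve_quenched(build_connectivity(model, L), params)$T_mid
  }, 0)
  sem <- if (n_configs > 1) stats::sd(t_mid) / sqrt(n_configs) else 0
  new_search_estimate(mean(t_mid), sem, NA_integer_, n_configs, L, params)
}

#' Exact search times on a dynamically rewired (annealed) network
#'
#' When the non-backbone bonds are redrawn at every walker step, the search
#' is a Markov chain whose transition probabilities are the exact
#' expectations `E[C_ij / N_i]` under a fresh configuration draw. The
#' default `method = "exact"` computes them by conditioning on the bond
#' `(i, j)` being present and convolving the remaining degree distribution
#' (a Poisson-binomial, evaluated by dynamic programming). The
#' `"meanfield"` variant replaces the expectation of the ratio by the ratio
#' of expectations, `P_ij / E[N_i]`; it is approximate and provided for
#' comparison with closed-form treatments.
#'
#' @param model A [contact_model()].
#' @param L Domain length.
#' @param params A [walker_params()].
#' @param method `"exact"` (default) or `"meanfield"`.
#' @return An `fpt_solution`.
#' @examples
#' solve_annealed(contact_model("uniform", p_u = 0), L = 10)$T_mid  # 25
#' @export
solve_annealed <- function(model, L, params = walker_params(),
                           method = c("exact", "meanfield")) {
  method <- match.arg(method)
  stopifnot(inherits(model, "contact_model"), L >= 2)
  p_by_sep <- pc_by_separation(model, L)
  W <- if (method == "exact") {
    cpp_annealed_kernel(as.integer(L), p_by_sep, model$boundary_factor)
  } else {
    meanfield_kernel(L, p_by_sep, model$boundary_factor)
  }
  n <- L + 2
  p_off <- params$p_off
  A <- diag(n)
  B <- numeric(n)
  interior <- 2:L
  A[interior, 1:(L + 1)] <- A[interior, 1:(L + 1)] -
    (1 - p_off) * W[interior, , drop = FALSE]
  if (p_off > 0) A[interior, n] <- -p_off
  # expected per-step cost: slides cost tau, hops cost t_jump
  w_slide <- W[cbind(interior, interior - 1)] + W[cbind(interior, interior + 1)]
  w_hop <- rowSums(W[interior, , drop = FALSE]) - w_slide
  B[interior] <- (1 - p_off) * (params$tau * w_slide + params$t_jump * w_hop) +
    p_off * params$tau
  A[n, 1:(L + 1)] <- -1 / (L + 1)
  A[n, n] <- 1
  B[n] <- params$tau_f
  Tv <- solve(A, B)
  res <- max(abs(A %*% Tv - B)) / max(abs(B))
  new_fpt_solution(Tv, L, res)
}

# mean-field transition kernel P_ij / E[N_i]
meanfield_kernel <- function(L, p_by_sep, bf) {
  n <- L + 1
  W <- matrix(0, n, n)
  for (i in 1:(L - 1)) {
    p <- numeric(n)
    js <- which(abs(0:L - i) >= 2) - 1L
    p[js + 1] <- pmin(1, p_by_sep[abs(js - i)])
    p[c(1, n)] <- p[c(1, n)] * bf
    EN <- 2 + sum(p)
    W[i + 1, ] <- p / EN
    W[i + 1, c(i, i + 2)] <- 1 / EN
  }
  W
}

#' Printed low-connectivity expansion of the scaled search time
#'
#' First-order expansion of `<T>/T_d` in the uniform contact probability
#' `p_u`, valid for `p_u << 1 / L^2`:
#' \deqn{\frac{\langle T \rangle}{T_d} \approx
#'       1 - \frac{L^3 - 5L^2 - 20L + 48}{48}\, p_u.}
#'
#' @param L Domain length.
#' @param p_u Uniform contact probability.
#' @return Scaled search time `T / T_d` (dimensionless).
#' @export
low_pu_approx <- function(L, p_u) {
  if (any(p_u * L^2 > 0.1))
    warning("low_pu_approx outside its validity regime (p_u * L^2 > 0.1)")
  1 - (L^3 - 5 * L^2 - 20 * L + 48) / 48 * p_u
}

#' Printed high-connectivity closed form of the search time
#'
#' Closed-form search time (units of `tau`) from the simplified governing
#' equation in which all interior beads are treated as equivalent, accurate
#' as `p_u` approaches 1:
#' \deqn{\langle T \rangle = \frac{2 + (L-3)p_u + (2 + (L-4)p_u)^2}{2 p_u}.}
#'
#' @inheritParams low_pu_approx
#' @return Search time in units of `tau`.
#' @export
high_pu_approx <- function(L, p_u) {
  if (any(p_u == 0)) stop("high_pu_approx is undefined at p_u = 0")
  (2 + (L - 3) * p_u + (2 + (L - 4) * p_u)^2) / (2 * p_u)
}
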