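#' Parameters of the searching random walker
#'
#' The walker starts at an interior bead and is absorbed at beads 0 and `L`
#' (the targets). Each step it first decides whether to unbind into the
#' bulk (probability `p_off`); an unbind-rebind cycle costs the residence
#' time `tau` plus the bulk exploration time `tau_f`, after which the walker
#' rebinds uniformly over all `L + 1` beads (landing on a target counts as
#' success). Otherwise it moves to a uniformly chosen bonded neighbour:
#' a backbone move (slide) costs `tau`, a non-backbone move
#' (intersegmental hop) costs `t_jump`.
#'
#' @param tau Time per sliding step; sets the time unit (default 1).
#' @param t_jump Time per intersegmental hop (default `tau`).
#' @param p_off Per-step unbinding probability in `[0, 1]` (default 0).
#' @param tau_f Mean bulk exploration time before rebinding
#'   (default `100 * tau`).
#' @param start Starting bead; default `floor(L / 2)`, resolved when the
#'   walk is run.
#' @param t_config_switch Number of walker moves between reshuffles of the
#'   non-backbone bonds. `Inf` (default) keeps the network static; 1 makes
#'   it fully dynamic (a fresh configuration every step).
#' @return An object of class `walker_params`.
#' @export
walker_params <- function(tau = 1, t_jump = tau, p_off = 0, tau_f = 100 * tau,
                          start = NULL, t_config_switch = Inf) {
  stopifnot(tau > 0, t_jump > 0, tau_f > 0,
            p_off >= 0, p_off <= 1,
            is.infinite(t_config_switch) ||
              (t_config_switch >= 1 && t_config_switch == round(t_config_switch)))
  structure(list(tau = tau, t_jump = t_jump, p_off = p_off, tau_f = tau_f,
                 start = start, t_config_switch = t_config_switch),
            class = "walker_params")
}

resolve_start <- function(params, L) {
  start <- if (is.null(params$start)) L %/% 2L else as.integer(params$start)
  if (start < 1 || start > L - 1)
    stop("start bead must be interior (1..L-1)")
  start
}

#' Simulate first-passage searches on a contact network
#'
#' `simulate_walks()` runs `n_walks` independent trajectories on the
#' network `C` and returns their first-passage times to bead 0 or bead `L`.
#' `simulate_first_passage()` runs a single trajectory. For a dynamic
#' network (finite `t_config_switch`) the generating `model` must be
#' supplied so bonds can be redrawn during the walk.
#'
#' @param C A `connectivity_matrix`.
#' @param params A [walker_params()].
#' @param n_walks Number of independent trajectories.
#' @param model The [contact_model()] used for reshuffling (dynamic mode
#'   only).
#' @param rng_seed Optional integer seed.
#' @return Numeric vector of first-passage times (units of `tau`);
#'   `simulate_first_passage()` returns a single number.
#' @examples
#' C <- build_connectivity(contact_model("uniform", p_u = 0), L = 20)
#' mean(simulate_walks(C, walker_params(), n_walks = 200, rng_seed = 1))
#' @export
simulate_walks <- function(C, params = walker_params(), n_walks = 1,
                           model = NULL, rng_seed = NULL) {
  stopifnot(inherits(C, "connectivity_matrix"),
            inherits(params, "walker_params"), n_walks >= 1)
  dynamic <- is.finite(params$t_config_switch)
  if (dynamic && is.null(model))
    stop("dynamic mode (finite t_config_switch) needs the contact `model`")
  if (!is.null(rng_seed)) set.seed(rng_seed)
  p_by_sep <- if (dynamic) pc_by_separation(model, C$L) else numeric(C$L)
  bf <- if (dynamic) model$boundary_factor else 0
  cpp_simulate_walks(C$bonds, C$L, as.integer(n_walks), params$p_off,
                     params$tau, params$t_jump, params$tau_f,
                     resolve_start(params, C$L),
                     if (dynamic) params$t_config_switch else -1,
                     p_by_sep, bf)
}

#' @rdname simulate_walks
#' @export
simulate_first_passage <- function(C, params = walker_params(), model = NULL,
                                   rng_seed = NULL) {
  simulate_walks(C, params, n_walks = 1, model = model, rng_seed = rng_seed)[1]
}

new_search_estimate <- function(mean, sem, n_walks, n_configs, L, params) {
  structure(list(mean = mean, sem = sem, n_walks = n_walks,
                 n_configs = n_configs, T_d = L^2 * params$tau / 4, L = L,
                 params = params),
            class = "search_estimate")
}

#' @export
print.search_estimate <- function(x, ...) {
  cat(sprintf(
    "<search_estimate> <T> = %.4g +/- %.3g tau (T/T_d = %.4g; %s walks x %d configs)\n",
    x$mean, x$sem, x$mean / x$T_d,
    if (is.na(x$n_walks)) "solver, no" else format(x$n_walks), x$n_configs))
  invisible(x)
}

#' Ensemble-averaged search time from Monte-Carlo walks
#'
#' Averages first-passage times over `n_configs` freshly sampled network
#' configurations with `n_walks` trajectories each. In dynamic mode (finite
#' `t_config_switch`) the configuration evolves within each trajectory and
#' `n_configs` indexes the initial draws.
#'
#' @param model A [contact_model()].
#' @param L Domain length (beads `0..L`).
#' @param params A [walker_params()].
#' @param n_configs,n_walks Ensemble sizes.
#' @param rng_seed Optional integer seed.
#' @return A `search_estimate`: mean, standard error of the mean over all
#'   trajectories, ensemble sizes, and the pure-sliding reference time
#'   `T_d = L^2 tau / 4`.
#' @export
ensemble_search_time <- function(model, L, params = walker_params(),
                                 n_configs = 1, n_walks = 1, rng_seed = NULL) {
  stopifnot(n_configs >= 1, n_walks >= 1)
  if (!is.null(rng_seed)) set.seed(rng_seed)
  total <- 0
  totsq <- 0
  n <- 0
  for (k in seq_len(n_configs)) {
    C <- build_connectivity(model, L)
    t <- simulate_walks(C, params, n_walks = n_walks, model = model)
    total <- total + sum(t)
    totsq <- totsq + sum(t^2)
    n <- n + length(t)
  }
  m <- total / n
  v <- (totsq - n * m^2) / (n - 1)
  new_search_estimate(m, sqrt(max(v, 0) / n), n_walks, n_configs, L, params)
}
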