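#' Parameter scans of the mean search time
#'
#' Computes the mean search time over a grid of one control variable while
#' the others are held fixed, using the annealed solver, the
#' configuration-averaged quenched solver, or Monte-Carlo simulation.
#' This is the workhorse behind compaction scans (`p_u`, `gamma`),
#' unbinding scans (`p_off`) and length scans (`L`).
#'
#' @param var One of `"pu"`, `"gamma"`, `"poff"`, `"L"`.
#' @param grid Numeric vector of grid values (`p_u` may include 0; for
#'   `var = "L"` values must be integers `>= 2`).
#' @param model Base [contact_model()]; overridden per grid point when
#'   `var` is `"pu"` or `"gamma"`.
#' @param L Domain length (ignored for `var = "L"`).
#' @param params Base [walker_params()]; `p_off` is overridden for
#'   `var = "poff"`.
#' @param mode `"annealed"`, `"quenched"` or `"sim"`.
#' @param n_configs Configurations per grid point (quenched / sim modes).
#' @param n_walks Trajectories per configuration (sim mode).
#' @param rng_seed Optional integer seed.
#' @return A data frame with one row per grid point: `value`, `mean`,
#'   `sem`, `n_walks`, `n_configs`, `mode`, plus `T_d` and `scaled`
#'   (`mean / T_d`). The seed and parameter block are attached as
#'   attributes `seed` and `params`.
#' @examples
#' run_scan("pu", c(0, 1e-3), model = contact_model("uniform", p_u = 0),
#'          L = 50, mode = "annealed")
#' @export
run_scan <- function(var = c("pu", "gamma", "poff", "L"), grid, model, L = NULL,
                     params = walker_params(),
                     mode = c("annealed", "quenched", "sim"),
                     n_configs = 50, n_walks = 1000, rng_seed = NULL) {
  var <- match.arg(var)
  mode <- match.arg(mode)
  if (length(grid) < 1) stop("empty grid")
  if (var == "pu" && (any(grid < 0) || any(grid > 1))) stop("invalid p_u grid")
  if (var == "gamma" && any(grid < 0)) stop("invalid gamma grid")
  if (var == "poff" && (any(grid < 0) || any(grid > 1))) stop("invalid p_off grid")
  if (var == "L" && (any(grid < 2) || any(grid != round(grid))))
    stop("invalid L grid")
  if (var != "L" && is.null(L)) stop("L is required unless var = 'L'")
  if (!is.null(rng_seed)) set.seed(rng_seed)

  one <- function(v) {
    m <- model
    p <- params
    Lv <- L
    if (var == "pu") m <- contact_model("uniform", p_u = v,
                                        boundary_factor = model$boundary_factor)
    if (var == "gamma") m <- contact_model("powerlaw", c = model$c, gamma = v,
                                           boundary_factor = model$boundary_factor)
    if (var == "poff") p <- walker_params(tau = params$tau,
                                          t_jump = params$t_jump, p_off = v,
                                          tau_f = params$tau_f,
                                          start = params$start,
                                          t_config_switch = params$t_config_switch)
    if (var == "L") Lv <- as.integer(v)
    est <- switch(mode,
      annealed = {
        sol <- solve_annealed(m, Lv, p)
        new_search_estimate(sol$T_mid, 0, NA_integer_, 1L, Lv, p)
      },
      quenched = mean_quenched(m, Lv, p, n_configs = n_configs),
      sim = ensemble_search_time(m, Lv, p, n_configs = n_configs,
                                 n_walks = n_walks)
    )
    data.frame(value = v, mean = est$mean, sem = est$sem,
               n_walks = est$n_walks, n_configs = est$n_configs, mode = mode,
               T_d = est$T_d, scaled = est$mean / est$T_d)
  }
  out <- do.call(rbind, lapply(grid, one))
  attr(out, "seed") <- rng_seed
  attr(out, "params") <- list(var = var, model = model, L = L, params = params,
                              n_configs = n_configs, n_walks = n_walks)
  out
}

#' Write and read scan tables
#'
#' TSV with commented header lines carrying the package version, seed and
#' parameter block, so every stochastic output records how it was made.
#'
#' @param scan A data frame from [run_scan()].
#' @param path File path.
#' @return `write_scan_tsv()` returns `path` invisibly; `read_scan_tsv()`
#'   returns the data frame (header metadata in attribute `header`).
#' @export
write_scan_tsv <- function(scan, path) {
  p <- attr(scan, "params")
  hdr <- c(
    sprintf("# tadwalk %s scan", as.character(utils::packageVersion("tadwalk"))),
    sprintf("# seed=%s", deparse(attr(scan, "seed"))),
    sprintf("# params=%s", if (is.null(p)) "NULL" else
      paste(deparse(p, control = "niceNames"), collapse = " "))
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(scan, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_scan_tsv
#' @export
read_scan_tsv <- function(path) {
  lines <- readLines(path)
  hdr <- lines[grepl("^#", lines)]
  out <- utils::read.table(text = lines[!grepl("^#", lines)], sep = "\t",
                           header = TRUE)
  attr(out, "header") <- hdr
  out
}
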