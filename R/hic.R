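#' Hi-C contact map container
#'
#' A symmetric matrix of non-negative contact values over fixed-width
#' genomic bins (1 kb by default, matching high-resolution maps of
#' balanced contact frequencies). The `scaled` flag records whether the
#' map has been converted to contact probabilities via
#' [probability_scale()].
#'
#' @param mat Symmetric numeric matrix of non-negative values.
#' @param resolution Bin width in bp (default 1000).
#' @param scaled Whether values are already probability-scaled.
#' @param offset Genomic start of bin 0 in bp (default 0), used to map TAD
#'   coordinates onto bins.
#' @return An object of class `hic_map`.
#' @export
hic_map <- function(mat, resolution = 1000, scaled = FALSE, offset = 0) {
  stopifnot(is.matrix(mat), nrow(mat) == ncol(mat), all(mat >= 0, na.rm = TRUE))
  if (max(abs(mat - t(mat)), na.rm = TRUE) > 1e-8 * max(mat, 1, na.rm = TRUE))
    stop("contact map must be symmetric")
  structure(list(mat = mat, resolution = resolution, scaled = scaled,
                 offset = offset),
            class = "hic_map")
}

#' @export
print.hic_map <- function(x, ...) {
  cat(sprintf("<hic_map> %d x %d bins @ %d bp, %s\n", nrow(x$mat), ncol(x$mat),
              x$resolution, if (x$scaled) "probability-scaled" else "raw"))
  invisible(x)
}

#' Scale a contact map to contact probabilities
#'
#' Divides every entry by the maximum off-diagonal contact value, so all
#' off-diagonal entries lie in `[0, 1]` with the maximum exactly 1. The
#' operation is idempotent. For multi-chromosome data, apply per
#' chromosome.
#'
#' @param map An `hic_map`.
#' @return The scaled `hic_map`.
#' @export
probability_scale <- function(map) {
  stopifnot(inherits(map, "hic_map"))
  off <- map$mat
  diag(off) <- NA
  mx <- max(off, na.rm = TRUE)
  if (!is.finite(mx) || mx <= 0)
    stop("map has no positive off-diagonal entry")
  map$mat <- map$mat / mx
  map$scaled <- TRUE
  map
}

#' TAD interval records
#'
#' Validates a set of TAD annotations (0-based, half-open bp coordinates,
#' BED convention) against a bin resolution. Intervals not divisible by
#' the resolution are truncated to whole bins.
#'
#' @param chrom Chromosome labels.
#' @param start,end Interval bounds in bp, `end > start`.
#' @param resolution Bin width in bp.
#' @return A data frame with columns `chrom`, `start`, `end`, `L_kb`
#'   (interval length in bins).
#' @export
tad_records <- function(chrom, start, end, resolution = 1000) {
  stopifnot(length(chrom) == length(start), length(start) == length(end),
            all(end > start), all(start >= 0))
  end <- start + ((end - start) %/% resolution) * resolution
  if (any(end <= start)) stop("TAD shorter than one bin")
  data.frame(chrom = as.character(chrom), start = as.integer(start),
             end = as.integer(end), L_kb = as.integer((end - start) / resolution))
}

#' Read and write TAD lists in BED3 format
#'
#' Three tab-separated columns `chrom start end`, 0-based half-open bp
#' coordinates; lines starting with `#`, `track` or `browser` are skipped.
#'
#' @param path File path.
#' @param tads A data frame as returned by [tad_records()].
#' @param resolution Bin width used to compute `L_kb` on read.
#' @return `read_tads()` returns a [tad_records()] data frame;
#'   `write_tads()` returns `path` invisibly.
#' @export
read_tads <- function(path, resolution = 1000) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  f <- strsplit(lines, "\t")
  tad_records(vapply(f, `[`, "", 1),
              as.numeric(vapply(f, `[`, "", 2)),
              as.numeric(vapply(f, `[`, "", 3)),
              resolution = resolution)
}

#' @rdname read_tads
#' @export
write_tads <- function(tads, path) {
  utils::write.table(tads[, c("chrom", "start", "end")], path, sep = "\t",
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

# bin index range of a TAD within a map (0-based bins)
tad_bins <- function(map, tad) {
  res <- map$resolution
  b0 <- (tad$start - map$offset) / res
  b1 <- (tad$end - map$offset) / res  # exclusive
  if (b0 != round(b0) || b1 != round(b1))
    stop("TAD boundaries not aligned to map bins")
  if (b0 < 0 || b1 > nrow(map$mat))
    stop("TAD outside the extent of the contact map")
  c(as.integer(b0), as.integer(b1))
}

#' Intra-TAD contact probability curve
#'
#' For each genomic separation `s` (in bins), the mean contact probability
#' over all bin pairs inside the TAD with `|i - j| = s`.
#'
#' @param map An `hic_map`.
#' @param tad A single-row [tad_records()] data frame (or list with
#'   `start` and `end` in bp).
#' @return A data frame with columns `s` (bins) and `p`.
#' @export
intra_tad_contact_curve <- function(map, tad) {
  stopifnot(inherits(map, "hic_map"))
  b <- tad_bins(map, tad)
  sub <- map$mat[(b[1] + 1):b[2], (b[1] + 1):b[2], drop = FALSE]
  n <- nrow(sub)
  p <- vapply(seq_len(n - 1), function(s) {
    idx <- seq_len(n - s)
    mean(sub[cbind(idx, idx + s)])
  }, 0)
  data.frame(s = seq_len(n - 1), p = p)
}

#' Fit a power law to a contact-probability curve
#'
#' Least-squares straight line on `(log s, log P)` within the fit range;
#' `gamma` is minus the slope and `c` the exponentiated intercept. The
#' default range follows the TAD-fitting convention `s = 10` to
#' `L - 100` kb; non-positive probabilities in range are dropped with a
#' warning.
#'
#' @param curve Data frame with columns `s` and `p` (as from
#'   [intra_tad_contact_curve()]).
#' @param s_min,s_max Fit range in bins (kb at 1-kb resolution); `s_max`
#'   defaults to `max(s) - 99` so that a TAD of `L` bins is fitted on
#'   `[10, L - 100]`.
#' @return An object of class `power_law_fit`: `c`, `gamma`, `fit_range`,
#'   `r_squared`, `n_points`.
#' @examples
#' s <- 1:200
#' fit_power_law(data.frame(s = s, p = 0.02 * s^-0.8))
#' @export
fit_power_law <- function(curve, s_min = 10, s_max = NULL) {
  stopifnot(all(c("s", "p") %in% names(curve)))
  if (is.null(s_max)) s_max <- max(curve$s) - 99
  if (s_max <= s_min) stop("empty fit range [s_min, s_max]")
  sel <- curve$s >= s_min & curve$s <= s_max
  cur <- curve[sel, , drop = FALSE]
  bad <- !(cur$p > 0) | !is.finite(cur$p)
  if (any(bad)) {
    warning(sprintf("dropping %d non-positive contact values from the fit",
                    sum(bad)))
    cur <- cur[!bad, , drop = FALSE]
  }
  if (nrow(cur) < 4) stop("fewer than 4 usable points in the fit range")
  fit <- stats::lm(log(p) ~ log(s), data = cur)
  y <- log(cur$p)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::residuals(fit)^2) / ss_tot else 1
  structure(list(c = exp(unname(stats::coef(fit)[1])),
                 gamma = -unname(stats::coef(fit)[2]),
                 fit_range = c(s_min, s_max),
                 r_squared = r2,
                 n_points = nrow(cur)),
            class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("<power_law_fit> P_c(s) = %.4g * s^-%.3g (R^2 = %.3f, %d points, s in [%g, %g])\n",
              x$c, x$gamma, x$r_squared, x$n_points,
              x$fit_range[1], x$fit_range[2]))
  invisible(x)
}

#' Fit power laws for every sufficiently long TAD in a map
#'
#' Applies [intra_tad_contact_curve()] and [fit_power_law()] to each TAD.
#' TADs shorter than `min_L_kb` bins cannot accommodate the `[10, L - 100]`
#' fit range and are skipped (reported in the `skipped` attribute).
#'
#' @param map A probability-scaled `hic_map`.
#' @param tads A [tad_records()] data frame.
#' @param min_L_kb Minimum TAD length in bins for a fit (default 111).
#' @return Data frame with one row per fitted TAD: `chrom`, `start`,
#'   `end`, `L_kb`, `c`, `gamma`, `r2`.
#' @export
tad_fit_all <- function(map, tads, min_L_kb = 111) {
  stopifnot(inherits(map, "hic_map"))
  ok <- tads$L_kb >= min_L_kb
  rows <- lapply(which(ok), function(k) {
    tad <- tads[k, ]
    fit <- fit_power_law(intra_tad_contact_curve(map, tad))
    cbind(tad[, c("chrom", "start", "end", "L_kb")],
          data.frame(c = fit$c, gamma = fit$gamma, r2 = fit$r_squared))
  })
  out <- do.call(rbind, rows)
  attr(out, "skipped") <- tads[!ok, , drop = FALSE]
  out
}

#' Bernoulli contact network from Hi-C probabilities
#'
#' Samples one network realisation for a TAD: each non-backbone bin pair
#' `(i, j)` inside the TAD receives a bond with probability `P_ij` from
#' the scaled map, and backbone bonds are enforced. Bead 0 of the network
#' is the first bin of the TAD.
#'
#' @param map A probability-scaled `hic_map`.
#' @param tad A single-row [tad_records()] data frame.
#' @param rng_seed Optional integer seed.
#' @return A `connectivity_matrix` with `L = L_kb - 1`.
#' @export
build_hic_network <- function(map, tad, rng_seed = NULL) {
  stopifnot(inherits(map, "hic_map"))
  if (!map$scaled)
    stop("map must be probability-scaled first (see probability_scale())")
  if (!is.null(rng_seed)) set.seed(rng_seed)
  b <- tad_bins(map, tad)
  sub <- map$mat[(b[1] + 1):b[2], (b[1] + 1):b[2], drop = FALSE]
  n <- nrow(sub)
  idx <- which(upper.tri(sub), arr.ind = TRUE)
  idx <- idx[idx[, 2] - idx[, 1] >= 2, , drop = FALSE]
  p <- pmin(1, sub[idx])
  keep <- stats::runif(nrow(idx)) < p
  new_connectivity(n - 1L, idx[keep, , drop = FALSE] - 1L)
}

#' Search-time scaling exponent
#'
#' Fits `<T> ~ L^nu` by least squares on `(log L, log T)`.
#'
#' @param L Domain lengths (at least 4 values).
#' @param T Mean search times, positive, same length as `L`.
#' @return An object of class `scaling_fit`: `nu`, `prefactor`,
#'   `r_squared`, `n_points`.
#' @examples
#' fit_scaling_exponent(c(100, 200, 400, 800), c(100, 200, 400, 800)^2 / 4)
#' @export
fit_scaling_exponent <- function(L, T) {
  stopifnot(length(L) == length(T), length(L) >= 4, all(T > 0), all(L > 0))
  fit <- stats::lm(log(T) ~ log(L))
  y <- log(T)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::residuals(fit)^2) / ss_tot else 1
  structure(list(nu = unname(stats::coef(fit)[2]),
                 prefactor = exp(unname(stats::coef(fit)[1])),
                 r_squared = r2,
                 n_points = length(L)),
            class = "scaling_fit")
}

#' @export
print.scaling_fit <- function(x, ...) {
  cat(sprintf("<scaling_fit> <T> ~ %.4g * L^%.3f (R^2 = %.4f, %d lengths)\n",
              x$prefactor, x$nu, x$r_squared, x$n_points))
  invisible(x)
}

#' Monte-Carlo search time within one TAD (Hi-C network method)
#'
#' Averages walker first-passage times over an ensemble of Bernoulli
#' networks drawn from the TAD's Hi-C contact probabilities
#' ([build_hic_network()]), with the walker started at the middle bin.
#'
#' @inheritParams build_hic_network
#' @param params A [walker_params()].
#' @param n_configs,n_walks Ensemble sizes.
#' @return A `search_estimate`.
#' @export
tad_search_time <- function(map, tad, params = walker_params(),
                            n_configs = 100, n_walks = 100, rng_seed = NULL) {
  if (!is.null(rng_seed)) set.seed(rng_seed)
  b <- tad_bins(map, tad)
  L <- b[2] - b[1] - 1L
  total <- 0; totsq <- 0; n <- 0
  for (k in seq_len(n_configs)) {
    C <- build_hic_network(map, tad)
    t <- simulate_walks(C, params, n_walks = n_walks)
    total <- total + sum(t); totsq <- totsq + sum(t^2); n <- n + length(t)
  }
  m <- total / n
  v <- (totsq - n * m^2) / (n - 1)
  new_search_estimate(m, sqrt(max(v, 0) / n), n_walks, n_configs, L, params)
}

#' Read and write contact maps
#'
#' `read_hic_coo()` reads sparse triplet text (`bin_i`, `bin_j`, `value`,
#' 0-based, tab- or space-separated) and symmetrises; `read_hic_dense()`
#' reads a dense TSV matrix. `write_hic_coo()` writes the upper triangle
#' (including the diagonal) as triplets.
#'
#' @param path File path.
#' @param n_bins Number of bins; defaults to `1 + max(bin index)`.
#' @param resolution Bin width in bp.
#' @param map An `hic_map`.
#' @return An `hic_map`, or `path` invisibly for the writer.
#' @export
read_hic_coo <- function(path, n_bins = NULL, resolution = 1000) {
  d <- utils::read.table(path, col.names = c("i", "j", "x"))
  if (is.null(n_bins)) n_bins <- max(d$i, d$j) + 1L
  M <- matrix(0, n_bins, n_bins)
  M[cbind(d$i + 1L, d$j + 1L)] <- d$x
  M[cbind(d$j + 1L, d$i + 1L)] <- d$x
  hic_map(M, resolution = resolution)
}

#' @rdname read_hic_coo
#' @export
read_hic_dense <- function(path, resolution = 1000) {
  M <- as.matrix(utils::read.table(path, sep = "\t"))
  dimnames(M) <- NULL
  hic_map(M, resolution = resolution)
}

#' @rdname read_hic_coo
#' @export
write_hic_coo <- function(map, path) {
  stopifnot(inherits(map, "hic_map"))
  idx <- which(upper.tri(map$mat, diag = TRUE) & map$mat != 0, arr.ind = TRUE)
  d <- data.frame(i = idx[, 1] - 1L, j = idx[, 2] - 1L, x = map$mat[idx])
  utils::write.table(d, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}
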