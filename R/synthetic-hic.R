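#' Specification of a synthetic contact map
#'
#' Describes a mock chromosome segment whose intra-TAD contact
#' probabilities follow `c * s^-gamma` with per-TAD parameters, a weaker
#' power-law background between all other pairs, and multiplicative
#' lognormal noise. Ground truth is known exactly, which makes the map
#' suitable for validating the TAD-fitting pipeline without external data.
#'
#' @param n_bins Number of 1-kb bins of the mock chromosome.
#' @param tads Data frame with columns `start`, `end` (bin indices,
#'   0-based half-open), `c`, `gamma`: one row per non-overlapping TAD.
#' @param background_c,background_gamma Power law for pairs not inside a
#'   common TAD. Defaults mimic a weak genome-wide decay.
#' @param sigma_log Log-sd of the multiplicative lognormal noise applied
#'   to each probability (0 = noiseless).
#' @param resolution Bin width in bp (default 1000).
#' @param chrom Name of the mock chromosome.
#' @return An object of class `synthetic_map_spec`.
#' @export
synthetic_map_spec <- function(n_bins, tads, background_c = 0.005,
                               background_gamma = 1.08, sigma_log = 0,
                               resolution = 1000, chrom = "chrS") {
  stopifnot(n_bins >= 2,
            all(c("start", "end", "c", "gamma") %in% names(tads)),
            all(tads$end > tads$start), all(tads$start >= 0),
            all(tads$end <= n_bins), all(tads$c > 0), all(tads$gamma >= 0),
            sigma_log >= 0, background_c > 0, background_gamma >= 0)
  tads <- tads[order(tads$start), , drop = FALSE]
  if (nrow(tads) > 1 && any(tads$start[-1] < tads$end[-nrow(tads)]))
    stop("TADs must not overlap")
  structure(list(n_bins = as.integer(n_bins), tads = tads,
                 background_c = background_c,
                 background_gamma = background_gamma,
                 sigma_log = sigma_log, resolution = resolution,
                 chrom = chrom),
            class = "synthetic_map_spec")
}

#' Generate a synthetic contact map with known ground truth
#'
#' Builds the probability matrix described by the spec: for each pair of
#' bins at separation `s`, `P = c_TAD * s^-gamma_TAD` when both bins lie
#' in the same TAD and the background law otherwise, multiplied by
#' lognormal noise `exp(N(0, sigma_log^2))`, capped at 1, symmetrised.
#' The diagonal is set to 1 (self-contact), as in normalised experimental
#' maps it is excluded from scaling and fits anyway.
#'
#' @param spec A [synthetic_map_spec()].
#' @param rng_seed Optional integer seed.
#' @return A list with `map` (an unscaled `hic_map`) and `tads` (a
#'   [tad_records()] data frame in bp coordinates).
#' @examples
#' spec <- synthetic_map_spec(
#'   n_bins = 150,
#'   tads = data.frame(start = 10, end = 140, c = 0.0214, gamma = 0.71)
#' )
#' gen <- generate_map(spec, rng_seed = 1)
#' @export
generate_map <- function(spec, rng_seed = NULL) {
  stopifnot(inherits(spec, "synthetic_map_spec"))
  if (!is.null(rng_seed)) set.seed(rng_seed)
  n <- spec$n_bins
  bins <- 0:(n - 1)
  # TAD id per bin (NA = background)
  tid <- rep(NA_integer_, n)
  for (k in seq_len(nrow(spec$tads)))
    tid[bins >= spec$tads$start[k] & bins < spec$tads$end[k]] <- k

  s <- abs(outer(bins, bins, "-"))
  P <- spec$background_c * ifelse(s > 0, s, 1)^(-spec$background_gamma)
  for (k in seq_len(nrow(spec$tads))) {
    inb <- which(tid == k)
    sk <- s[inb, inb]
    P[inb, inb] <- spec$tads$c[k] * ifelse(sk > 0, sk, 1)^(-spec$tads$gamma[k])
  }
  if (spec$sigma_log > 0) {
    noise <- matrix(1, n, n)
    up <- upper.tri(noise)
    noise[up] <- exp(stats::rnorm(sum(up), 0, spec$sigma_log))
    noise <- noise * t(noise)  # lower triangle mirrors the upper
    diag(noise) <- 1
    P <- P * noise
  }
  P <- pmin(P, 1)
  diag(P) <- 1
  P <- (P + t(P)) / 2  # guard against numeric asymmetry
  res <- spec$resolution
  tads <- tad_records(rep(spec$chrom, nrow(spec$tads)),
                      spec$tads$start * res, spec$tads$end * res,
                      resolution = res)
  list(map = hic_map(P, resolution = res), tads = tads)
}
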