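#' Generate a freely rotating chain conformation
#'
#' Unit-length bonds with a fixed angle `theta` between successive bond
#' vectors and uniformly distributed azimuth (dihedral). `theta = 0` gives
#' a straight rod; large angles fold the chain back on itself and compact
#' it. The first bond points along the z axis.
#'
#' @param theta Bond angle in degrees, in `[0, 180)`.
#' @param n_beads Number of beads (`>= 2`).
#' @param rng_seed Optional integer seed.
#' @return A `polymer_conformation`: list with `coords` (an
#'   `n_beads x 3` matrix, bond-length units) and `provenance = "frc"`.
#' @examples
#' conf <- generate_frc(theta = 60, n_beads = 100, rng_seed = 1)
#' radius_of_gyration(conf)
#' @export
generate_frc <- function(theta, n_beads, rng_seed = NULL) {
  stopifnot(theta >= 0, theta < 180, n_beads >= 2)
  if (!is.null(rng_seed)) set.seed(rng_seed)
  coords <- cpp_generate_frc(as.integer(n_beads), theta * pi / 180)
  new_conformation(coords, "frc")
}

new_conformation <- function(coords, provenance) {
  colnames(coords) <- c("x", "y", "z")
  structure(list(coords = coords, provenance = provenance),
            class = "polymer_conformation")
}

#' @export
print.polymer_conformation <- function(x, ...) {
  cat(sprintf("<polymer_conformation> %d beads (%s), R_g = %.3g\n",
              nrow(x$coords), x$provenance, radius_of_gyration(x)))
  invisible(x)
}

#' Radius of gyration
#'
#' Root-mean-square distance of the beads from their centroid.
#'
#' @param conf A `polymer_conformation` (or bare coordinate matrix).
#' @return A length (in bond units).
#' @export
radius_of_gyration <- function(conf) {
  xyz <- if (inherits(conf, "polymer_conformation")) conf$coords else conf
  stopifnot(nrow(xyz) >= 2)
  ctr <- colMeans(xyz)
  sqrt(mean(rowSums(sweep(xyz, 2, ctr)^2)))
}

#' Squared end-to-end distance
#'
#' @inheritParams radius_of_gyration
#' @return Squared distance between the first and last bead.
#' @export
end_to_end_sq <- function(conf) {
  xyz <- if (inherits(conf, "polymer_conformation")) conf$coords else conf
  sum((xyz[nrow(xyz), ] - xyz[1, ])^2)
}

#' Convert a 3D conformation to a contact network
#'
#' Two non-bonded beads (`|i - j| >= 2`) are in contact when their 3D
#' distance is at most the cutoff radius `r_c`; backbone bonds are always
#' present. The cutoff is not prescribed by theory; 1.5 bead diameters
#' is the package default and should be stated with any result.
#'
#' @param conf A `polymer_conformation` with `n` beads.
#' @param r_c Contact cutoff radius (bond-length units), default 1.5.
#' @return A `connectivity_matrix` with `L = n - 1` (beads `0..n-1`).
#' @export
conformation_to_network <- function(conf, r_c = 1.5) {
  stopifnot(r_c > 0)
  xyz <- if (inherits(conf, "polymer_conformation")) conf$coords else conf
  n <- nrow(xyz)
  d <- as.matrix(stats::dist(xyz))
  idx <- which(upper.tri(d) & d <= r_c, arr.ind = TRUE)
  idx <- idx[idx[, 2] - idx[, 1] >= 2, , drop = FALSE]
  new_connectivity(n - 1L, idx - 1L)
}

#' Chain energy terms
#'
#' Piecewise potentials of the bead-spring chromatin models: harmonic
#' springs between consecutive beads, a truncated Lennard-Jones attraction
#' between non-bonded beads, and a soft-core variant that allows partial
#' bead overlap at finite energy cost `V0 - epsilon` (softness set by
#' `eta1`; the potential crosses over to plain LJ at `r_m` and vanishes
#' beyond `2.5 sigma`).
#'
#' @param r Distance(s), `> 0`.
#' @param params An [energy_params()].
#' @return Energy value(s).
#' @name energies
#' @export
spring_energy <- function(r, params = energy_params()) {
  stopifnot(all(r > 0))
  params$k / 2 * (r - params$sigma)^2
}

#' @rdname energies
#' @export
lj_energy <- function(r, params = energy_params()) {
  stopifnot(all(r > 0))
  sr6 <- (params$sigma / r)^6
  ifelse(r < params$cutoff, 4 * params$epsilon * (sr6^2 - sr6), 0)
}

#' @rdname energies
#' @export
soft_lj_energy <- function(r, params = energy_params()) {
  stopifnot(all(r >= 0))
  u <- (r / params$r_m)^params$eta1
  soft <- params$V0 * (1 - u)^params$eta2 - params$epsilon
  ifelse(r < params$r_m, soft, lj_energy(pmax(r, 1e-12), params))
}

#' Energy parameters of the bead-spring models
#'
#' @param k Spring constant (default 100, a stiff bond at `kBT = 1`).
#' @param epsilon LJ well depth.
#' @param sigma Bead diameter (sets the length unit; default 1).
#' @param cutoff Interaction cutoff, `2.5 sigma`.
#' @param V0 Soft-core overlap scale (default `1e7`).
#' @param eta1 Softness exponent (smaller = softer; default 0.02).
#' @param eta2 Outer exponent of the soft branch (default 3.16).
#' @param r_m Soft/LJ crossover distance (default 1.12).
#' @return An object of class `energy_params`.
#' @export
energy_params <- function(k = 100, epsilon = 1, sigma = 1, cutoff = 2.5 * sigma,
                          V0 = 1e7, eta1 = 0.02, eta2 = 3.16, r_m = 1.12) {
  stopifnot(k > 0, epsilon >= 0, sigma > 0, cutoff == 2.5 * sigma,
            V0 > 0, eta1 > 0, eta2 > 0, r_m > 0)
  structure(list(k = k, epsilon = epsilon, sigma = sigma, cutoff = cutoff,
                 V0 = V0, eta1 = eta1, eta2 = eta2, r_m = r_m),
            class = "energy_params")
}

#' Langevin integrator parameters
#'
#' @param m Bead mass (default 1).
#' @param gamma_fric Friction coefficient (default 1).
#' @param kBT Thermal energy (default 1).
#' @param dt Time step in simulation units (default 0.01).
#' @param n_steps Number of integration steps.
#' @param rng_seed Optional integer seed.
#' @return An object of class `langevin_params`.
#' @export
langevin_params <- function(m = 1, gamma_fric = 1, kBT = 1, dt = 0.01,
                            n_steps = 1000, rng_seed = NULL) {
  stopifnot(m > 0, gamma_fric >= 0, kBT >= 0, dt > 0, n_steps >= 0)
  structure(list(m = m, gamma_fric = gamma_fric, kBT = kBT, dt = dt,
                 n_steps = n_steps, rng_seed = rng_seed),
            class = "langevin_params")
}

#' Evolve a bead-spring chain by Langevin dynamics
#'
#' Velocity-Verlet integration of
#' `m r'' = -grad E - gamma r' + sqrt(2 gamma kBT) eta(t)`
#' for a chain with harmonic springs and the chosen non-bonded pair
#' potential. Intended for moderate chain lengths (roughly `<= 300`
#' beads); equilibration at larger scales should use a dedicated MD engine
#' and be imported via [read_xyz()].
#'
#' @param conf Initial `polymer_conformation`.
#' @param energy An [energy_params()].
#' @param dynamics A [langevin_params()].
#' @param pair `"lj"` or `"soft_lj"` non-bonded potential.
#' @return The evolved `polymer_conformation` (provenance `"lj"` or
#'   `"soft_lj"`).
#' @export
langevin_evolve <- function(conf, energy = energy_params(),
                            dynamics = langevin_params(),
                            pair = c("lj", "soft_lj")) {
  pair <- match.arg(pair)
  stopifnot(inherits(conf, "polymer_conformation"),
            inherits(energy, "energy_params"),
            inherits(dynamics, "langevin_params"))
  if (!is.null(dynamics$rng_seed)) set.seed(dynamics$rng_seed)
  out <- cpp_langevin(conf$coords, energy$k, energy$epsilon, energy$sigma,
                      energy$cutoff, if (pair == "soft_lj") 1L else 0L,
                      energy$V0, energy$eta1, energy$eta2, energy$r_m,
                      dynamics$kBT, dynamics$gamma_fric, dynamics$m,
                      dynamics$dt, as.integer(dynamics$n_steps))
  new_conformation(out, pair)
}

#' Empirical contact-probability curve of a network ensemble
#'
#' Fraction of configurations in which a pair at separation `s` is in
#' contact, averaged over all pairs at that separation, for
#' `s = 1..L` (the backbone gives `P_c(1) = 1` by construction).
#'
#' @param networks A list of `connectivity_matrix` objects of equal length.
#' @return A data frame with columns `s` and `p`.
#' @export
contact_probability_curve <- function(networks) {
  if (inherits(networks, "connectivity_matrix")) networks <- list(networks)
  stopifnot(length(networks) >= 1)
  L <- networks[[1]]$L
  if (!all(vapply(networks, function(C) C$L, 0L) == L))
    stop("all networks must have the same length")
  counts <- numeric(L)
  counts[1] <- L * length(networks)
  for (C in networks) {
    if (nrow(C$bonds) > 0) {
      seps <- C$bonds[, 2] - C$bonds[, 1]
      tab <- tabulate(seps, nbins = L)
      counts <- counts + tab
    }
  }
  n_pairs <- (L + 1 - seq_len(L)) * length(networks)
  data.frame(s = seq_len(L), p = counts / n_pairs)
}

#' Read and write conformations in xyz format
#'
#' Standard single-frame xyz layout: bead count, comment line, then one
#' `element x y z` row per bead (the element field is ignored on read and
#' written as `C`).
#'
#' @param conf A `polymer_conformation`.
#' @param path File path.
#' @param comment Comment line for the second row.
#' @return `write_xyz()` returns `path` invisibly; `read_xyz()` returns a
#'   `polymer_conformation` with provenance `"external"`.
#' @export
write_xyz <- function(conf, path, comment = "tadwalk conformation") {
  stopifnot(inherits(conf, "polymer_conformation"))
  xyz <- conf$coords
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(as.character(nrow(xyz)), comment), con)
  utils::write.table(cbind("C", format(xyz, digits = 10)), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_xyz
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  n <- as.integer(trimws(lines[1]))
  if (is.na(n) || length(lines) < n + 2) stop("malformed xyz file")
  fields <- strsplit(trimws(lines[3:(n + 2)]), "\\s+")
  coords <- t(vapply(fields, function(f) as.numeric(f[2:4]), numeric(3)))
  new_conformation(coords, "external")
}
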