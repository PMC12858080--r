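make_map <- function(mat, resolution = 1000, scaled = FALSE) {
  hic_map(mat, resolution = resolution, scaled = scaled)
}

test_that("probability_scale normalises by the off-diagonal maximum", {
  M <- matrix(0, 4, 4)
  M[1, 3] <- M[3, 1] <- 8
  M[2, 4] <- M[4, 2] <- 2
  diag(M) <- 100
  scaled <- probability_scale(make_map(M))
  expect_true(scaled$scaled)
  expect_equal(scaled$mat[1, 3], 1)
  expect_equal(scaled$mat[2, 4], 0.25)

  # idempotent: a second application changes nothing
  twice <- probability_scale(scaled)
  expect_equal(twice$mat, scaled$mat)

  expect_error(probability_scale(make_map(diag(4) * 3)), "positive")
})

test_that("intra_tad_contact_curve averages pairs at each separation", {
  # 4-bin TAD with hand-filled values
  M <- matrix(0, 6, 6)
  vals <- list(c(1, 2, 0.1), c(2, 3, 0.2), c(3, 4, 0.3), c(4, 5, 0.4),
               c(1, 3, 0.5), c(2, 4, 0.6), c(3, 5, 0.7),
               c(1, 4, 0.8), c(2, 5, 0.9), c(1, 5, 0.05))
  for (v in vals) M[v[1], v[2]] <- M[v[2], v[1]] <- v[3]
  map <- make_map(M)
  tad <- tad_records("chrT", 0, 4000)
  curve <- intra_tad_contact_curve(map, tad)
  expect_equal(curve$s, 1:3)
  expect_equal(curve$p, c(mean(c(0.1, 0.2, 0.3)), mean(c(0.5, 0.6)), 0.8))

  # constant matrix -> flat curve
  flat <- intra_tad_contact_curve(make_map(matrix(0.4, 8, 8)),
                                  tad_records("chrT", 0, 8000))
  expect_equal(flat$p, rep(0.4, 7))

  expect_error(intra_tad_contact_curve(map, tad_records("chrT", 0, 9000)),
               "extent")
})

test_that("fit_power_law recovers exact and degenerate curves", {
  s <- 1:300
  fit <- fit_power_law(data.frame(s = s, p = 0.02 * s^(-0.8)))
  expect_equal(fit$c, 0.02, tolerance = 1e-10)
  expect_equal(fit$gamma, 0.8, tolerance = 1e-10)
  expect_equal(fit$fit_range, c(10, 201))

  flat <- fit_power_law(data.frame(s = s, p = rep(0.3, 300)))
  expect_equal(flat$gamma, 0, tolerance = 1e-12)

  expect_error(fit_power_law(data.frame(s = 1:30, p = 1 / (1:30))),
               "empty fit range")
  few <- data.frame(s = 1:200, p = c(rep(0, 197), 1, 1, 1))
  expect_warning(expect_error(fit_power_law(few), "fewer than 4"),
                 "non-positive")
})

test_that("noisy power-law fits are nearly unbiased in gamma", {
  set.seed(1)
  s <- 1:260
  g_hat <- replicate(60, {
    p <- 0.02 * s^(-0.8) * exp(stats::rnorm(length(s), 0, 0.2))
    fit_power_law(data.frame(s = s, p = p))$gamma
  })
  expect_lt(abs(mean(g_hat) - 0.8), 0.05)
})

test_that("build_hic_network respects probabilities and the backbone", {
  n <- 8
  ones <- make_map(matrix(1, n, n), scaled = TRUE)
  tad <- tad_records("chrT", 0, n * 1000)
  Cfull <- build_hic_network(ones, tad, rng_seed = 1)
  expect_equal(count_bonds(Cfull)$N_b, count_bonds(Cfull)$N_b_max)

  zero <- make_map(diag(n), scaled = TRUE)
  expect_equal(count_bonds(build_hic_network(zero, tad, rng_seed = 1))$N_b, 0)

  expect_error(build_hic_network(make_map(matrix(1, n, n)), tad), "scaled")

  # empirical bond frequency over many draws matches P_ij
  M <- matrix(0, 6, 6)
  M[1, 3] <- M[3, 1] <- 0.2
  M[2, 6] <- M[6, 2] <- 0.7
  M[1, 6] <- M[6, 1] <- 0.05
  map <- make_map(M, scaled = TRUE)
  tad6 <- tad_records("chrT", 0, 6000)
  set.seed(2)
  n_rep <- 10000
  hits <- matrix(0, 3, 1)
  probes <- rbind(c(0, 2), c(1, 5), c(0, 5))
  counts <- numeric(3)
  for (k in seq_len(n_rep)) {
    b <- build_hic_network(map, tad6)$bonds
    key <- paste(b[, 1], b[, 2])
    counts <- counts + (paste(probes[, 1], probes[, 2]) %in% key)
  }
  p_true <- c(0.2, 0.7, 0.05)
  se <- sqrt(p_true * (1 - p_true) / n_rep)
  expect_true(all(abs(counts / n_rep - p_true) < 3 * se))
})

test_that("fit_scaling_exponent reproduces known scaling laws", {
  L <- c(100, 200, 400, 800)
  expect_equal(fit_scaling_exponent(L, L^2 / 4)$nu, 2, tolerance = 1e-12)
  expect_equal(fit_scaling_exponent(L, 3 * L)$nu, 1, tolerance = 1e-12)
  expect_error(fit_scaling_exponent(c(100, 200, 400), c(1, 2, 3)), "length")
})

test_that("TAD records validate, truncate, and round-trip as BED3", {
  tads <- tad_records(c("chr1", "chr2"), c(0, 5500), c(120000, 245700))
  expect_equal(tads$L_kb, c(120, 240))
  expect_equal(tads$end, c(120000, 245500))   # truncated to whole bins

  path <- withr::local_tempfile(fileext = ".bed")
  write_tads(tads, path)
  back <- read_tads(path)
  expect_equal(back, tads)

  expect_error(tad_records("chr1", 1000, 1000))
})

test_that("contact maps round-trip through COO triplets and dense TSV", {
  set.seed(3)
  M <- matrix(0, 10, 10)
  up <- which(upper.tri(M))
  M[up[sample(length(up), 20)]] <- runif(20)
  M <- M + t(M)
  map <- make_map(M)

  coo <- withr::local_tempfile(fileext = ".tsv")
  write_hic_coo(map, coo)
  expect_equal(read_hic_coo(coo, n_bins = 10)$mat, M)

  dense <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(M, dense, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  expect_equal(read_hic_dense(dense)$mat, M)
})

test_that("tad_fit_all fits long TADs and reports skipped short ones", {
  spec <- synthetic_map_spec(
    400,
    tads = data.frame(start = c(5, 220), end = c(205, 280),
                      c = c(0.0214, 0.03), gamma = c(0.71, 1.1)))
  gen <- generate_map(spec, rng_seed = 4)
  fits <- tad_fit_all(gen$map, gen$tads)
  expect_equal(nrow(fits), 1)                    # 60-bin TAD is too short
  expect_equal(nrow(attr(fits, "skipped")), 1)
  expect_equal(fits$gamma, 0.71, tolerance = 1e-6)
  expect_equal(fits$c, 0.0214, tolerance = 1e-6)
})

test_that("solver route and Hi-C walk route agree on matched networks", {
  # same ensemble two ways: quenched solves on model-drawn networks
  # (boundary contacts included) vs Monte-Carlo walks on networks drawn
  # from a noiseless map carrying the identical power law
  L_bins <- 151
  spec <- synthetic_map_spec(
    L_bins, tads = data.frame(start = 0, end = L_bins, c = 0.0214, gamma = 0.71),
    background_c = 0.0214, background_gamma = 0.71)
  gen <- generate_map(spec)
  map <- gen$map
  map$scaled <- TRUE  # probabilities by construction
  walks <- tad_search_time(map, gen$tads[1, ], n_configs = 150, n_walks = 150,
                           rng_seed = 5)
  solver <- mean_quenched(powerlaw_model(0.0214, 0.71, bf = 1), L_bins - 1,
                          n_configs = 250, rng_seed = 6)
  expect_lt(abs(walks$mean - solver$mean) / solver$mean, 0.1)
})
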