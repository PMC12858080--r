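test_that("FRC geometry: unit bonds, exact bond angle, rod limit", {
  conf <- generate_frc(theta = 60, n_beads = 200, rng_seed = 1)
  xyz <- conf$coords
  b <- diff(xyz)
  expect_equal(sqrt(rowSums(b^2)), rep(1, 199), tolerance = 1e-12)
  cosang <- rowSums(b[-1, ] * b[-nrow(b), ])
  expect_equal(cosang, rep(cos(60 * pi / 180), 198), tolerance = 1e-12)

  rod <- generate_frc(theta = 0, n_beads = 50, rng_seed = 1)
  # straight rod of n equally spaced beads: R_g^2 = (n^2 - 1) / 12
  expect_equal(radius_of_gyration(rod)^2, (50^2 - 1) / 12, tolerance = 1e-10)
})

test_that("FRC end-to-end distance follows the fixed-angle closed form", {
  # <R^2> = n b^2 [ (1+a)/(1-a) - 2a(1-a^n)/(n(1-a)^2) ], a = cos(theta)
  set.seed(2)
  for (th in c(60, 90)) {
    n_bonds <- 300
    r2 <- mean(replicate(400, end_to_end_sq(generate_frc(th, n_bonds + 1))))
    a <- cos(th * pi / 180)
    exact <- n_bonds * (1 + a) / (1 - a) - 2 * a * (1 - a^n_bonds) / (1 - a)^2
    expect_lt(abs(r2 - exact) / exact, 0.1, label = paste("theta =", th))
  }
})

test_that("larger bond angles compact the chain", {
  set.seed(3)
  rg <- vapply(c(30, 60, 120), function(th) {
    mean(replicate(60, radius_of_gyration(generate_frc(th, 300))))
  }, 0)
  expect_true(all(diff(rg) < 0))
})

test_that("radius_of_gyration handles elementary configurations", {
  expect_equal(radius_of_gyration(cbind(c(0, 1), 0, 0)), 0.5)
  expect_equal(radius_of_gyration(cbind(0, 0, 0:2)), sqrt(2 / 3))
  expect_equal(radius_of_gyration(matrix(1, 5, 3)), 0)
})

test_that("conformation_to_network applies the cutoff inclusively", {
  rod5 <- tadwalk:::new_conformation(cbind(0, 0, 0:4), "external")
  expect_equal(count_bonds(conformation_to_network(rod5, r_c = 1.5))$N_b, 0)
  # at r_c = 2 the three (i, i+2) pairs sit exactly on the cutoff
  C <- conformation_to_network(rod5, r_c = 2)
  expect_equal(count_bonds(C)$N_b, 3)
  expect_equal(unname(C$bonds), cbind(0:2, 2:4 + 0L))
})

test_that("bond counts grow with FRC compaction", {
  set.seed(4)
  nb <- vapply(c(30, 90, 150), function(th) {
    mean(replicate(20, {
      count_bonds(conformation_to_network(generate_frc(th, 200)))$N_b
    }))
  }, 0)
  expect_true(all(diff(nb) > 0))
})

test_that("pair energies satisfy the printed identities", {
  ep <- energy_params(epsilon = 2)
  expect_equal(lj_energy(1, ep), 0)
  expect_equal(lj_energy(2^(1 / 6), ep), -2)
  expect_equal(lj_energy(2.5, ep), 0)   # zero at and beyond the cutoff
  expect_equal(lj_energy(3, ep), 0)

  expect_equal(soft_lj_energy(0, ep), ep$V0 - 2)
  # first branch hits exactly -epsilon at r_m; the LJ branch there is within
  # 1e-3 epsilon, so the potential is nearly continuous at the crossover
  expect_equal(soft_lj_energy(ep$r_m - 1e-12, ep), -2, tolerance = 1e-9)
  expect_lt(abs(soft_lj_energy(ep$r_m - 1e-12, ep) - lj_energy(ep$r_m, ep)),
            1e-3 * 2)

  expect_equal(spring_energy(1, ep), 0)
  expect_equal(spring_energy(1.5, ep), ep$k / 2 * 0.25)
})

test_that("langevin dynamics preserves a force-free rod and is seeded", {
  rod <- tadwalk:::new_conformation(cbind(0, 0, 0:39), "external")
  still <- langevin_evolve(rod, energy_params(epsilon = 0),
                           langevin_params(kBT = 0, n_steps = 300))
  expect_equal(still$coords, rod$coords, tolerance = 1e-12)

  a <- langevin_evolve(rod, energy_params(epsilon = 0.5),
                       langevin_params(n_steps = 100, rng_seed = 5))
  b <- langevin_evolve(rod, energy_params(epsilon = 0.5),
                       langevin_params(n_steps = 100, rng_seed = 5))
  expect_equal(a$coords, b$coords)
})

test_that("hard-core overlap aborts with a force overflow error", {
  overlap <- tadwalk:::new_conformation(rbind(c(0, 0, 0), c(0, 0, 1),
                                              c(0, 0, 1e-5)), "external")
  expect_error(
    langevin_evolve(overlap, energy_params(epsilon = 1),
                    langevin_params(kBT = 0, n_steps = 2)),
    "overflow")
})

test_that("stronger LJ attraction collapses the chain and adds contacts", {
  run <- function(eps) {
    set.seed(7)
    conf <- generate_frc(45, 60)
    ev <- langevin_evolve(conf, energy_params(epsilon = eps),
                          langevin_params(n_steps = 8000, rng_seed = 3))
    c(rg = radius_of_gyration(ev),
      nb = count_bonds(conformation_to_network(ev))$N_b)
  }
  open <- run(0.1)
  compact <- run(1.2)
  expect_lt(compact["rg"], open["rg"])
  expect_gt(compact["nb"], open["nb"])
})

test_that("contact_probability_curve recovers generator probabilities", {
  expect_equal(contact_probability_curve(chain(10))$p, c(1, rep(0, 9)))

  model <- powerlaw_model(c = 0.6, gamma = 0.8)
  set.seed(8)
  nets <- replicate(2000, build_connectivity(model, 20), simplify = FALSE)
  curve <- contact_probability_curve(nets)
  for (s in 2:17) {
    # only interior pairs are eligible; scale the expectation accordingly
    n_all <- 21 - s
    n_elig <- max(0, 19 - s)
    p_exp <- contact_probability(model, s) * n_elig / n_all
    se <- sqrt(p_exp * (1 - p_exp) / (n_all * 2000))
    expect_lt(abs(curve$p[s] - p_exp), 4 * se + 1e-12,
              label = sprintf("s = %d", s))
  }
})

test_that("compact FRC ensembles carry more long-range contact weight", {
  set.seed(9)
  curve_at <- function(th) {
    nets <- replicate(30, conformation_to_network(generate_frc(th, 150)),
                      simplify = FALSE)
    contact_probability_curve(nets)
  }
  open <- curve_at(30)
  folded <- curve_at(120)
  s_far <- 20:100
  expect_gt(mean(folded$p[s_far]), mean(open$p[s_far]))
})

test_that("soft chains show a stronger search-time rebound after collapse", {
  # reduced-scale comparison: the post-minimum rise of the search time
  # across the collapse transition is larger for the softer potential
  run_one <- function(eta1, eps, rep_seed) {
    set.seed(rep_seed)
    conf <- generate_frc(45, 80)
    ev <- langevin_evolve(conf, energy_params(epsilon = eps, eta1 = eta1),
                          langevin_params(n_steps = 10000),
                          pair = "soft_lj")
    solve_quenched(insulate_boundary(conformation_to_network(ev)))$T_mid
  }
  eps_grid <- c(0.1, 0.4, 0.8, 1.2)
  rise <- vapply(c(0.02, 0.05), function(eta1) {
    Tm <- vapply(eps_grid, function(e) {
      mean(vapply(1:6, function(r) run_one(eta1, e, 100 * r + round(10 * e)), 0))
    }, 0)
    Tm[length(Tm)] / min(Tm)
  }, 0)
  expect_gt(rise[1], rise[2])
})

test_that("xyz files round-trip conformations", {
  conf <- generate_frc(70, 25, rng_seed = 10)
  path <- withr::local_tempfile(fileext = ".xyz")
  write_xyz(conf, path)
  back <- read_xyz(path)
  expect_equal(back$coords, conf$coords, tolerance = 1e-8)
  expect_equal(back$provenance, "external")
})
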