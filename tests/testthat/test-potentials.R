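p_free <- model_params(n_bonds = 10, b = 0, eps_a = 0)

test_that("FENE potential matches its closed form and diverges at the range", {
  expect_equal(fene_energy(0.7, p_free), 0)
  expect_equal(fene_energy(0.85, p_free), -(20 * 0.09 / 2) * log(0.75),
               tolerance = 1e-12)
  expect_identical(fene_energy(1.0, p_free), Inf)
  expect_identical(fene_energy(0.4, p_free), Inf)
  expect_identical(fene_energy(1.7, p_free), Inf)
  # symmetry about l0
  d <- seq(0.001, 0.299, length.out = 50)
  expect_equal(fene_energy(0.7 + d, p_free), fene_energy(0.7 - d, p_free),
               tolerance = 1e-12)
})

test_that("Morse pair potential has its minimum at r_min and a consistent cutoff", {
  expect_equal(morse_pair_energy(0.8, p_free), -1.0)
  expect_equal(morse_pair_energy(1.0, p_free, cutoff = FALSE),
               exp(-9.6) - 2 * exp(-4.8), tolerance = 1e-12)
  expect_identical(morse_pair_energy(5.0, p_free), 0)
  expect_identical(morse_pair_energy(1.0, p_free), 0)
  # strict monotonicity on either side of the minimum
  up <- morse_pair_energy(seq(0.801, 0.999, length.out = 100), p_free)
  expect_true(all(diff(up) > 0))
  down <- morse_pair_energy(seq(0.4, 0.799, length.out = 100), p_free)
  expect_true(all(diff(down) < 0))
})

test_that("bending energy vanishes for straight bonds and is 2b at fold-back", {
  p <- model_params(n_bonds = 10, b = 7, eps_a = 0)
  expect_equal(bending_energy(pi, p), 0, tolerance = 1e-12)
  expect_equal(bending_energy(pi / 2, p), 7)
  expect_equal(bending_energy(0, p), 14)
  # rod fixture has all interior angles straight
  rod <- make_fixture("rod", 10)
  expect_equal(sum(bending_energy(bond_angles(rod), p)), 0, tolerance = 1e-9)
})

test_that("surface potential has depth eps_a at r_min_s and a negligible tail", {
  p <- model_params(n_bonds = 10, b = 0, eps_a = 4)
  expect_equal(surface_energy(0.8, p), -4.0)
  p1 <- model_params(n_bonds = 10, b = 0, eps_a = 1)
  expect_equal(surface_energy(0.8, p1), -1.0)
  expect_lt(abs(surface_energy(2.0, p1)), 1e-12)
  expect_error(surface_energy(-0.1, p1), "invalid position")
})

test_that("total energy: rod at the surface minimum hits every term's zero", {
  rod <- make_fixture("rod", 10, height = 0.8)
  e <- total_energy(rod, p_free)
  expect_equal(e$u_fene, 0, tolerance = 1e-12)
  expect_equal(e$u_bend, 0, tolerance = 1e-12)
  expect_equal(e$u_morse, 0)   # all pairs at >= 1.4, beyond the cutoff
  expect_equal(e$u_total, 0, tolerance = 1e-12)
  p_ads <- model_params(n_bonds = 10, b = 0, eps_a = 2)
  e2 <- total_energy(rod, p_ads)
  expect_equal(e2$u_surf, -2 * 11, tolerance = 1e-9)
})

test_that("total energy equals brute-force double-loop summation on fixtures", {
  p <- model_params(n_bonds = 40, b = 9, eps_a = 2.5)
  for (conf in list(make_fixture("coil", 40, height = 0.8, seed = 11),
                    make_fixture("toroid_spiral", 40, turns = 2, height = 0.8),
                    make_fixture("helix", 40, radius = 1.2, pitch = 1.5))) {
    e <- total_energy(conf, p)
    o <- brute_total_energy(conf, p)
    expect_equal(e$u_fene, o$u_fene, tolerance = 1e-10)
    expect_equal(e$u_morse, o$u_morse, tolerance = 1e-10)
    expect_equal(e$u_bend, o$u_bend, tolerance = 1e-10)
    expect_equal(e$u_surf, o$u_surf, tolerance = 1e-10)
    expect_equal(e$u_total, o$u_total, tolerance = 1e-10)
    expect_equal(e$u_total, e$u_fene + e$u_morse + e$u_bend + e$u_surf,
                 tolerance = 1e-9)
  }
})

test_that("bonds outside the FENE range give the infinite-energy sentinel", {
  rod <- make_fixture("rod", 5, height = 0.8)
  stretched <- rod
  stretched[6, 1] <- stretched[5, 1] + 1.05
  expect_identical(total_energy(stretched, p_free)$u_total, Inf)
  d <- delta_energy(rod, 6, rod[6, ] + c(0.36, 0, 0), p_free)
  expect_identical(d, Inf)
})

test_that("delta_energy is exact for the identity move and against recomputation", {
  p <- model_params(n_bonds = 30, b = 12, eps_a = 3)
  conf <- make_fixture("coil", 30, height = 0.8, seed = 4)
  expect_equal(delta_energy(conf, 7, conf[7, ], p), 0, tolerance = 1e-12)
  set.seed(101)
  n_checked <- 0
  for (i in 1:300) {
    bead <- sample(nrow(conf), 1)
    np <- conf[bead, ] + stats::runif(3, -0.15, 0.15)
    if (np[3] < 0) next
    d_inc <- delta_energy(conf, bead, np, p)
    moved <- conf
    moved[bead, ] <- np
    d_full <- total_energy(moved, p)$u_total - total_energy(conf, p)$u_total
    if (!is.finite(d_inc)) {
      expect_false(is.finite(d_full))
      next
    }
    expect_equal(d_inc, d_full, tolerance = 1e-8)
    n_checked <- n_checked + 1
  }
  expect_gt(n_checked, 200)
})

test_that("disabling the pair cutoff shifts the total by at most the tail bound", {
  fixtures <- list(make_fixture("coil", 60, height = 0.8, seed = 8),
                   make_fixture("helix", 60, radius = 1.5, pitch = 1.2),
                   make_fixture("circle", 40, height = 0.8),
                   make_fixture("toroid_spiral", 60, turns = 2, gap = 1.1,
                                height = 0.8))
  for (conf in fixtures) {
    nbonds <- nrow(conf) - 1L
    p_cut <- model_params(n_bonds = nbonds, b = 5, eps_a = 1)
    p_nocut <- model_params(n_bonds = nbonds, b = 5, eps_a = 1,
                            pair_cutoff = 0)
    u_cut <- total_energy(conf, p_cut)$u_total
    u_nocut <- total_energy(conf, p_nocut)$u_total
    d2 <- as.matrix(stats::dist(conf))
    idx <- which(upper.tri(d2), arr.ind = TRUE)
    nonbonded <- idx[abs(idx[, 1] - idx[, 2]) > 1, , drop = FALSE]
    r <- d2[nonbonded]
    # |morse| is monotone on the tail, so each truncated pair contributes at
    # most |morse(1.0)| and pairs beyond 2 are < 1e-12 each
    bound <- sum(r >= 1 & r < 2) *
      abs(morse_pair_energy(1.0, p_cut, cutoff = FALSE)) +
      length(r) * 1e-12
    expect_lt(abs(u_cut - u_nocut), bound)
  }
})

test_that("model parameters validate invariants and round-trip through YAML/JSON", {
  p <- model_params(n_bonds = 12, b = 3, eps_a = 1.5)
  expect_equal(p$r0, 0.3)
  expect_equal(p$l_max - p$l0, p$l0 - p$l_min)
  expect_error(model_params(n_bonds = 12, b = -1), "b")
  expect_error(model_params(n_bonds = 12, l0 = 1.2), "l0")
  for (ext in c("yaml", "json")) {
    f <- tempfile(fileext = paste0(".", ext))
    write_params(p, f)
    q <- read_params(f)
    expect_equal(unclass(q), unclass(p))
    unlink(f)
  }
})
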