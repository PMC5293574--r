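test_that("height histogram bins beads into unit bins with integer centers", {
  flat <- make_fixture("rod", 9, height = 0.8)
  h <- height_histogram(flat)
  expect_equal(h$proportion[h$bin_center == 1], 1.0)
  expect_equal(sum(h$proportion), 1.0, tolerance = 1e-9)
  expect_equal(sum(h$count), 10)

  # vertical rod: bead heights 0.8, 1.5, 2.2, ... -> hand-enumerated bins
  vert <- cbind(0, 0, 0.8 + 0.7 * (0:9))
  hv <- height_histogram(vert)
  expected <- table(floor(vert[, 3] + 0.5))
  got <- hv$count[hv$count > 0]
  names(got) <- hv$bin_center[hv$count > 0]
  expect_equal(got, c(expected), tolerance = 0)

  # pooling two conformations is linear in counts
  both <- height_histogram(list(flat, vert))
  expect_equal(sum(both$count), 20)
  expect_equal(both$count[both$bin_center == 1],
               h$count[h$bin_center == 1] + hv$count[hv$bin_center == 1])
})

test_that("adsorbed fraction counts beads within the attraction range", {
  flat <- make_fixture("rod", 9, height = 0.8)
  expect_equal(adsorbed_fraction(flat), 1.0)
  vert <- cbind(0, 0, 0.8 + 0.7 * (0:9))
  expect_equal(adsorbed_fraction(vert), 1 / 10)
  heights <- c(0.5, 0.9, 1.2, 3.0, 0.95)
  conf <- cbind(0.7 * (0:4), 0, heights)
  expect_equal(adsorbed_fraction(conf), 3 / 5)
  expect_equal(binding_proportion(flat), 1.0)
})

test_that("G(m) matches the direct-formula oracle and oscillates on a circle", {
  circ <- make_fixture("circle", 20, height = 0.8)
  G <- spatial_correlation_G(circ)
  # independent direct evaluation of the printed double average
  U <- diff(circ); U <- U / sqrt(rowSums(U^2))
  C <- U %*% t(U)
  nb <- nrow(U)
  brute <- vapply(1:(nb - 3), function(m) {
    mean(vapply(2:(nb - 1), function(i) {
      cb <- mean(C[i, ])
      num <- mean((C[i, 1:(nb - m)] - cb) * (C[i, (1 + m):nb] - cb))
      num / mean((C[i, ] - cb)^2)
    }, numeric(1)))
  }, numeric(1))
  expect_equal(G$value, brute, tolerance = 1e-12)
  # one full oscillation with period = n_bonds (window-edge corrections small)
  expect_equal(G$value[1:10], cos(2 * pi * (1:10) / 20), tolerance = 0.05)
  expect_error(spatial_correlation_G(make_fixture("rod", 4)), "5 bonds")
})

test_that("G(m) of independent random bond directions stays inside the null bound", {
  set.seed(9)
  for (r in 1:100) {
    conf <- random_direction_chain(60)
    g <- spatial_correlation_G(conf)
    bound <- 3 / sqrt(60 - g$lag)
    expect_true(all(abs(g$value) < bound | !is.finite(g$value)))
  }
})

test_that("G and C are invariant under rigid rotation about z and xy-translation", {
  conf <- make_fixture("toroid_spiral", 50, turns = 2, height = 0.8)
  moved <- rotate_z(conf, 1.234)
  moved[, 1] <- moved[, 1] + 3.7
  moved[, 2] <- moved[, 2] - 1.1
  expect_equal(spatial_correlation_G(conf)$value,
               spatial_correlation_G(moved)$value, tolerance = 1e-10)
  ens1 <- list(conf, rotate_z(conf, 0.3), rotate_z(conf, 2.1))
  ens2 <- lapply(ens1, function(p) {
    q <- rotate_z(p, 0.77); q[, 1] <- q[, 1] + 5; q
  })
  expect_equal(tangent_correlation_C(ens1)$value,
               tangent_correlation_C(ens2)$value, tolerance = 1e-10)
})

test_that("C(s) of rotation-randomised circles follows cos(2 pi s / n)", {
  set.seed(5)
  n <- 20
  circ <- make_fixture("circle", n, height = 0.8)
  ens <- lapply(stats::runif(500, 0, 2 * pi), function(th) rotate_z(circ, th))
  cs <- tangent_correlation_C(ens)
  expect_lt(max(abs(cs$normalized - cos(2 * pi * cs$lag / n))), 0.05)
  expect_error(tangent_correlation_C(list(circ)), "2 samples")
})

test_that("C(s) is symmetric under chain reversal and near zero for noise", {
  set.seed(41)
  ens <- lapply(1:200, function(i) random_direction_chain(30))
  cs <- tangent_correlation_C(ens)
  # null: |C(s)| below a 3-sigma band, sigma ~ 1/sqrt(samples)
  expect_true(all(abs(cs$value[-1]) < 3 / sqrt(200)))
  # reversing every sample through the chain midpoint leaves C unchanged
  rev_ens <- lapply(ens, function(p) p[nrow(p):1, ])
  expect_equal(tangent_correlation_C(rev_ens)$value, cs$value,
               tolerance = 1e-12)
})

test_that("surface-energy fluctuation recovers known variances", {
  expect_equal(surface_energy_fluctuation(rep(-3, 50))$value, 0)
  expect_equal(surface_energy_fluctuation(rep(c(-1, 1), 25))$value, 1)
  set.seed(33)
  us <- stats::rnorm(4000, mean = -40, sd = 3)
  rep_id <- rep(1:8, each = 500)
  fl <- surface_energy_fluctuation(us, replica = rep_id, seed = 2)
  expect_lt(abs(fl$value - 9), 3 * fl$stderr)
  # scale covariance: multiplying U_s by c multiplies the fluctuation by c^2
  fl2 <- surface_energy_fluctuation(2.5 * us, replica = rep_id, seed = 2)
  expect_equal(fl2$value, 2.5^2 * fl$value, tolerance = 1e-9)
  expect_gte(fl$value, 0)
})

test_that("toroid classifier recovers constructed turn counts 1..5", {
  nb <- c(24, 60, 110, 170, 240)
  for (n in 1:5) {
    tc <- classify_toroid(make_fixture("toroid_spiral", nb[n], turns = n,
                                       height = 0.8))
    expect_true(tc$is_toroid)
    expect_equal(tc$n_turns, n)
    expect_gte(tc$n_turns, 1L)
    expect_lte(tc$height_extent, 1.0)
  }
})

test_that("rods, desorbed coils and 3D coils are not classified as toroids", {
  expect_false(classify_toroid(make_fixture("rod", 30))$is_toroid)
  # degenerate G (zero variance everywhere) must score 0, not NaN
  expect_equal(classify_toroid(make_fixture("rod", 30))$periodicity_score, 0)
  desorbed <- make_fixture("coil", 60, height = 5, seed = 2)
  expect_false(classify_toroid(desorbed)$is_toroid)
  set.seed(13)
  for (i in 1:50) {
    conf <- random_direction_chain(60, height = 0.2)
    expect_false(classify_toroid(conf)$is_toroid)
  }
})
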