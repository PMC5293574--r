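tiny_spec <- function(seed = 1L, b = c(2, 20), eps = c(1, 5, 10)) {
  sweep_spec(b_values = b, eps_a_values = eps, profile = "smoke", seed = seed,
             n_bonds = 12L,
             schedule = run_schedule(n_replicas = 2, equilibration_mcs = 2e3,
                                     n_samples_per_replica = 2,
                                     sampling_interval_mcs = 1e3,
                                     seed = seed, restart_limit = 2L))
}

test_that("a smoke sweep emits one labelled phase point per grid point", {
  pts <- run_sweep(tiny_spec())
  expect_equal(nrow(pts), 6L)
  expect_true(all(pts$state_label %in% c("fully_adsorbed",
                                         "partially_adsorbed")))
  expect_true(all(pts$mean_adsorbed_fraction >= 0 &
                    pts$mean_adsorbed_fraction <= 1, na.rm = TRUE))
  expect_true(all(pts$n_replicas == 2))
  # strong attraction on a tiny chain adsorbs fully
  strong <- pts[pts$eps_a == 10 & pts$b == 2, ]
  expect_gt(strong$mean_adsorbed_fraction, 0.9)
})

test_that("sweeps are deterministic in the seed and resumable byte-identically", {
  spec <- tiny_spec(seed = 4L, b = c(2, 20), eps = c(2, 6, 10))
  d1 <- file.path(tempdir(), "sweep1")
  unlink(d1, recursive = TRUE)
  pts1 <- run_sweep(spec, out_dir = d1)
  # resume: cached points are reused, result identical
  pts2 <- run_sweep(spec, out_dir = d1)
  expect_identical(pts1, pts2)
  # partial interruption: drop one cache file, resume fills it identically
  cache_files <- list.files(d1, full.names = TRUE)
  unlink(cache_files[2])
  pts3 <- run_sweep(spec, out_dir = d1)
  expect_identical(pts1, pts3)
  # fresh directory, same spec: same values
  d2 <- file.path(tempdir(), "sweep2")
  unlink(d2, recursive = TRUE)
  pts4 <- run_sweep(spec, out_dir = d2)
  expect_identical(pts1, pts4)
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("locate_transition finds an injected fluctuation peak and flags edges", {
  grid <- seq(1, 3, by = 0.5)
  mk <- function(fl, se = 0.01) data.frame(b = 100, eps_a = grid,
                                           fluctuation = fl,
                                           fluctuation_se = se)
  peaked <- mk(c(1, 4, 9, 3, 2))
  tr <- locate_transition(peaked)
  expect_equal(tr$critical_eps_a, 2.0)
  expect_false(tr$on_boundary)
  expect_false(tr$ambiguous)
  edge <- locate_transition(mk(c(9, 4, 3, 2, 1)))
  expect_true(edge$on_boundary)
  expect_equal(edge$critical_eps_a, 1.0)
  # flat curve + noise: maximum within one stderr of the runner-up
  flat <- locate_transition(mk(c(5.00, 5.01, 5.02, 5.015, 5.00), se = 0.5))
  expect_true(flat$ambiguous)
  expect_error(locate_transition(mk(c(1, 2, 3, 2, 1))[1:3, ]), "5 grid")
})

test_that("phase_diagram fits the boundary and reports monotonicity honestly", {
  two <- data.frame(b = c(100, 300), critical_eps_a = c(2.0, 5.0))
  pd <- phase_diagram(two)
  expect_equal(nrow(pd$boundary), 2L)
  expect_true(pd$monotone)
  expect_equal(pd$slope, 3 / 200, tolerance = 1e-12)

  # synthetic fluctuation curves: peak injected at a known eps_a per b
  grid <- seq(1, 6, by = 0.25)
  mk_b <- function(b, peak) {
    data.frame(b = b, eps_a = grid,
               fluctuation = exp(-(grid - peak)^2 / 0.5),
               fluctuation_se = 0.001)
  }
  pts <- rbind(mk_b(100, 2.0), mk_b(300, 3.5), mk_b(500, 5.0))
  pd2 <- phase_diagram(pts)
  expect_equal(pd2$boundary$critical_eps_a, c(2.0, 3.5, 5.0))
  expect_true(pd2$monotone)
  # shuffled input order gives identical output
  set.seed(1)
  pd3 <- phase_diagram(pts[sample(nrow(pts)), ])
  expect_identical(pd2$boundary, pd3$boundary)
  expect_identical(pd2$slope, pd3$slope)

  dip <- data.frame(b = c(100, 200, 300), critical_eps_a = c(2, 1.5, 3))
  pd4 <- phase_diagram(dip)
  expect_false(pd4$monotone)
  expect_equal(pd4$violations, 200)
})

test_that("turns_vs_parameters detects constructed monotone trends", {
  calls <- do.call(rbind, lapply(1:3, function(k) {
    data.frame(b = 50, eps_a = k, is_toroid = TRUE, n_turns = k + 1,
               mean_radius = 5 - k, row.names = NULL)[rep(1, 4), ]
  }))
  out <- turns_vs_parameters(calls)
  expect_equal(nrow(out$table), 3L)
  expect_equal(out$trend_vs_eps_a$tau_n_turns_vs_eps_a, 1)
  expect_equal(out$trend_vs_eps_a$tau_radius_vs_eps_a, -1)

  # single point: no trend, no error
  single <- calls[calls$eps_a == 1, ]
  out1 <- turns_vs_parameters(single)
  expect_true(is.na(out1$trend_vs_eps_a$tau_n_turns_vs_eps_a))

  # points with fewer than 3 toroidal samples are excluded and listed
  sparse <- rbind(calls, data.frame(b = 300, eps_a = 1, is_toroid = TRUE,
                                    n_turns = 9, mean_radius = 1))
  out2 <- turns_vs_parameters(sparse)
  expect_false(any(out2$table$b == 300))
  expect_true(any(out2$excluded$b == 300))
})

test_that("constructed toroid ensembles at rising attraction show the N_t trend", {
  # fixture ensembles standing in for (b, eps_a) grid points: turn count
  # rises with the attraction label, toroid radius falls
  nb <- c(60, 110, 170)
  calls <- do.call(rbind, lapply(1:3, function(k) {
    tc <- classify_toroid(make_fixture("toroid_spiral", nb[k], turns = k + 1,
                                       height = 0.8))
    data.frame(b = 50, eps_a = c(2, 4, 6)[k], is_toroid = tc$is_toroid,
               n_turns = tc$n_turns, mean_radius = tc$mean_radius)[rep(1, 3), ]
  }))
  out <- turns_vs_parameters(calls)
  expect_equal(out$trend_vs_eps_a$tau_n_turns_vs_eps_a, 1)
})

test_that("profile presets scale one schema from smoke to production", {
  for (pr in c("smoke", "desk", "full")) {
    cfg <- profile_config(pr, seed = 9L)
    expect_s3_class(cfg$schedule, "run_schedule")
    expect_equal(cfg$schedule$seed, 9L)
  }
  full <- profile_config("full")
  expect_equal(full$n_bonds, 300L)
  expect_equal(full$schedule$n_replicas, 100L)
  expect_equal(full$schedule$n_samples_per_replica, 100L)
  expect_equal(full$schedule$sampling_interval_mcs, 1e6)
  expect_equal(full$schedule$n_replicas * full$schedule$n_samples_per_replica,
               10000L)
})
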