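#' Reference results for the production-scale model
#'
#' The quantitative results the model reproduces at production scale
#' (N = 300 bonds, 100 replicas, 100 samples at 1e6-MCS intervals):
#' the critical surface attraction located by the fluctuation peak for
#' each bending energy, the bound-monomer proportions P(D <= 1) at three
#' reference parameter points, and the toroid probability in the moderate
#' (b, eps_a) regime.
#'
#' @return a list of data.frames: \code{transitions} (b,
#'   critical_eps_a), \code{binding} (b, eps_a, proportion),
#'   \code{toroid} (b, eps_a, min_probability).
#' @export
full_profile_targets <- function() {
  list(
    transitions = data.frame(
      b = c(100, 200, 300, 400, 500),
      critical_eps_a = c(2.0, 2.75, 3.5, 4.25, 5.0)),
    binding = data.frame(
      b = c(50, 100, 300),
      eps_a = c(1.5, 1.5, 3.0),
      proportion = c(0.93, 0.64, 0.87)),
    toroid = data.frame(b = 300, eps_a = 4.0, min_probability = 0.80)
  )
}

#' Check full-scale results against the reference values
#'
#' Pure comparison step of the long-run validation gate: transition
#' points must match within one eps_a grid step, binding proportions
#' within +/- 0.05, and the toroid probability must exceed its floor.
#'
#' @param transitions data.frame with \code{b}, \code{critical_eps_a}
#'   from [phase_diagram()] on full-profile results.
#' @param binding data.frame with \code{b}, \code{eps_a},
#'   \code{proportion} (measured P(D <= 1)).
#' @param toroid_probability measured toroid probability at the moderate
#'   regime point.
#' @param grid_step eps_a grid resolution (tolerance for transitions).
#' @param targets reference values, see [full_profile_targets()].
#' @return a data.frame with one row per check: \code{check},
#'   \code{measured}, \code{expected}, \code{tolerance}, \code{pass}.
#' @export
check_full_validation <- function(transitions, binding, toroid_probability,
                                  grid_step = 0.25,
                                  targets = full_profile_targets()) {
  rows <- list()
  tt <- merge(targets$transitions, transitions, by = "b",
              suffixes = c("_ref", ""))
  for (i in seq_len(nrow(tt))) {
    rows[[length(rows) + 1L]] <- data.frame(
      check = sprintf("transition_b%d", tt$b[i]),
      measured = tt$critical_eps_a[i],
      expected = tt$critical_eps_a_ref[i],
      tolerance = grid_step,
      pass = abs(tt$critical_eps_a[i] - tt$critical_eps_a_ref[i]) <=
        grid_step + 1e-12)
  }
  bb <- merge(targets$binding, binding, by = c("b", "eps_a"),
              suffixes = c("_ref", ""))
  for (i in seq_len(nrow(bb))) {
    rows[[length(rows) + 1L]] <- data.frame(
      check = sprintf("binding_b%g_eps%g", bb$b[i], bb$eps_a[i]),
      measured = bb$proportion[i],
      expected = bb$proportion_ref[i],
      tolerance = 0.05,
      pass = abs(bb$proportion[i] - bb$proportion_ref[i]) <= 0.05 + 1e-12)
  }
  rows[[length(rows) + 1L]] <- data.frame(
    check = "toroid_probability",
    measured = toroid_probability,
    expected = targets$toroid$min_probability,
    tolerance = NA_real_,
    pass = toroid_probability > targets$toroid$min_probability)
  do.call(rbind, rows)
}

#' Run the production-scale validation campaign
#'
#' Executes the full profile end to end: an eps_a scan (0.25 grid) for
#' every reference bending energy, transition location from the
#' fluctuation peaks, P(D <= 1) at the reference binding points, toroid
#' probability in the moderate regime, and the comparison of
#' [check_full_validation()]. At N = 300 with 100 replicas and 1e6-MCS
#' sampling intervals this runs for hours to days on one CPU; it is the
#' long-run validation gate, not part of the routine test suite.
#'
#' @param seed master seed.
#' @param out_dir results directory (resumable; strongly recommended).
#' @param eps_a_values eps_a scan grid.
#' @return a list: \code{points} (all phase points), \code{diagram},
#'   \code{checks} (the [check_full_validation()] table).
#' @export
run_full_validation <- function(seed = 1L, out_dir = "full_validation",
                                eps_a_values = seq(1, 6.5, by = 0.25)) {
  targets <- full_profile_targets()
  spec <- sweep_spec(b_values = targets$transitions$b,
                     eps_a_values = eps_a_values,
                     profile = "full", seed = seed)
  points <- run_sweep(spec, out_dir = out_dir, verbose = TRUE)
  pd <- phase_diagram(points)
  binding <- do.call(rbind, lapply(seq_len(nrow(targets$binding)), function(i) {
    b <- targets$binding$b[i]; eps_a <- targets$binding$eps_a[i]
    bspec <- sweep_spec(b_values = b, eps_a_values = eps_a,
                        profile = "full", seed = seed)
    params <- model_params(n_bonds = bspec$n_bonds, b = b, eps_a = eps_a)
    sch <- bspec$schedule
    sch$seed <- point_seed(bspec, b, eps_a)
    ss <- run_ensemble(params, sch)
    data.frame(b = b, eps_a = eps_a, proportion = binding_proportion(ss))
  }))
  tspec <- sweep_spec(b_values = targets$toroid$b,
                      eps_a_values = targets$toroid$eps_a,
                      profile = "full", seed = seed)
  tor <- run_phase_point(tspec, targets$toroid$b, targets$toroid$eps_a)
  checks <- check_full_validation(pd$boundary, binding,
                                  tor$toroid_probability)
  list(points = points, diagram = pd, checks = checks)
}
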