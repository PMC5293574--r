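#' Preset problem sizes for sweeps
#'
#' Three profiles share one schema and differ only in scale:
#' \describe{
#'   \item{smoke}{N = 32 bonds, 4 replicas, 3 samples at 1e4-MCS
#'     intervals — plumbing checks, minutes.}
#'   \item{desk}{N = 64 bonds, 8 replicas, 3 samples at 1e5-MCS
#'     intervals — trend reproduction on one CPU.}
#'   \item{full}{N = 300 bonds, 100 replicas, 100 samples at 1e6-MCS
#'     intervals (10^4 samples per point) — the production scale;
#'     hours to days per grid point.}
#' }
#'
#' @param profile one of "smoke", "desk", "full".
#' @param seed master seed for the schedule.
#' @return a list with \code{n_bonds} and a [run_schedule()].
#' @export
profile_config <- function(profile = c("smoke", "desk", "full"), seed = 1L) {
  profile <- match.arg(profile)
  switch(profile,
    smoke = list(n_bonds = 32L,
                 schedule = run_schedule(n_replicas = 4L,
                                         equilibration_mcs = 5e4,
                                         n_samples_per_replica = 3L,
                                         sampling_interval_mcs = 1e4,
                                         seed = seed, restart_limit = 3L)),
    desk = list(n_bonds = 64L,
                schedule = run_schedule(n_replicas = 8L,
                                        equilibration_mcs = 3e5,
                                        n_samples_per_replica = 2L,
                                        sampling_interval_mcs = 1e5,
                                        seed = seed, restart_limit = 2L)),
    full = list(n_bonds = 300L,
                schedule = run_schedule(n_replicas = 100L,
                                        equilibration_mcs = 1e7,
                                        n_samples_per_replica = 100L,
                                        sampling_interval_mcs = 1e6,
                                        seed = seed))
  )
}

#' Specify a (b, eps_a) parameter sweep
#'
#' @param b_values strictly increasing bending energies.
#' @param eps_a_values strictly increasing surface attraction strengths.
#' @param profile scale preset, see [profile_config()].
#' @param seed master seed.
#' @param n_bonds,schedule overrides of the profile's defaults.
#' @return an object of class \code{sweep_spec}.
#' @export
sweep_spec <- function(b_values, eps_a_values,
                       profile = c("smoke", "desk", "full"), seed = 1L,
                       n_bonds = NULL, schedule = NULL) {
  profile <- match.arg(profile)
  stopifnot(length(b_values) >= 1, length(eps_a_values) >= 1,
            !is.unsorted(b_values, strictly = TRUE),
            !is.unsorted(eps_a_values, strictly = TRUE))
  cfg <- profile_config(profile, seed)
  s <- list(b_values = as.numeric(b_values),
            eps_a_values = as.numeric(eps_a_values),
            profile = profile,
            n_bonds = if (is.null(n_bonds)) cfg$n_bonds else as.integer(n_bonds),
            schedule = if (is.null(schedule)) cfg$schedule else schedule)
  class(s) <- "sweep_spec"
  s
}

# 32-bit FNV-1a hash of a string; used for content-addressed resume files
# and for order-invariant per-point seeds.
fnv1a32 <- function(s) {
  h <- 2166136261
  for (byte in utf8ToInt(s)) {
    # xor on the low byte only (h is kept as a double below 2^32)
    h <- (h %/% 256) * 256 + bitwXor(h %% 256, byte %% 256)
    h <- (h * 16777619) %% 4294967296
  }
  h
}

point_key <- function(spec, b, eps_a) {
  sch <- spec$schedule
  sprintf("b=%.6g|eps=%.6g|N=%d|rep=%d|eq=%.6g|ns=%d|int=%.6g|seed=%d",
          b, eps_a, spec$n_bonds, sch$n_replicas, sch$equilibration_mcs,
          sch$n_samples_per_replica, sch$sampling_interval_mcs, sch$seed)
}

point_seed <- function(spec, b, eps_a) {
  as.integer(fnv1a32(point_key(spec, b, eps_a)) %% 2147483647)
}

#' Run one (b, eps_a) grid point
#'
#' Runs the scheduled replicas and condenses the ensemble into a phase
#' point: mean adsorbed fraction (with standard error over replica
#' means), surface-energy fluctuation (with bootstrap standard error),
#' toroid probability (fraction of replicas whose final sample classifies
#' toroidal), mean turn count and toroid radius over toroidal finals, and
#' the fully/partially adsorbed state label.
#'
#' @param spec a [sweep_spec()].
#' @param b,eps_a the grid point.
#' @param full_threshold adsorbed-fraction threshold for the
#'   \code{fully_adsorbed} label (default 0.99, "almost reaches 1").
#' @return a one-row data.frame.
#' @export
run_phase_point <- function(spec, b, eps_a, full_threshold = 0.99) {
  params <- model_params(n_bonds = spec$n_bonds, b = b, eps_a = eps_a)
  sch <- spec$schedule
  sch$seed <- point_seed(spec, b, eps_a)
  ss <- run_ensemble(params, sch)
  n_rep <- sch$n_replicas
  n_failed <- sum(ss$restart_log$failed)
  if (n_samples(ss) > 0) {
    af <- vapply(conformations(ss), adsorbed_fraction, numeric(1))
    rep_means <- tapply(af, ss$replica, mean)
    mean_af <- mean(af)
    se_af <- if (length(rep_means) > 1)
      stats::sd(rep_means) / sqrt(length(rep_means)) else NA_real_
    fl <- if (n_samples(ss) > 1) {
      surface_energy_fluctuation(ss, n_boot = 400L, seed = sch$seed)
    } else list(value = NA_real_, stderr = NA_real_)
    finals <- tapply(seq_len(n_samples(ss)), ss$replica, max)
    calls <- lapply(conformations(ss, as.integer(finals)), classify_toroid)
    tor <- vapply(calls, function(tc) tc$is_toroid, TRUE)
    p_tor <- mean(tor)
    mean_nt <- if (any(tor))
      mean(vapply(calls[tor], function(tc) tc$n_turns, 1L)) else NA_real_
    mean_rad <- if (any(tor))
      mean(vapply(calls[tor], function(tc) tc$mean_radius, 1)) else NA_real_
  } else {
    mean_af <- se_af <- NA_real_
    fl <- list(value = NA_real_, stderr = NA_real_)
    p_tor <- mean_nt <- mean_rad <- NA_real_
  }
  data.frame(
    b = b, eps_a = eps_a,
    mean_adsorbed_fraction = mean_af, adsorbed_se = se_af,
    fluctuation = fl$value, fluctuation_se = fl$stderr,
    toroid_probability = p_tor, mean_n_turns = mean_nt,
    mean_toroid_radius = mean_rad,
    n_samples = n_samples(ss), n_replicas = n_rep, n_failed = n_failed,
    incomplete = n_failed > 0.2 * n_rep,
    state_label = if (!is.na(mean_af) && mean_af >= full_threshold)
      "fully_adsorbed" else "partially_adsorbed"
  )
}

#' Run a full parameter sweep
#'
#' Runs [run_phase_point()] over the whole (b, eps_a) grid. With an
#' output directory the sweep is resumable: each point is persisted in a
#' CSV keyed by the content hash of its spec, and completed points are
#' loaded instead of recomputed, so interrupting and resuming yields
#' byte-identical results tables. Per-point seeds derive from the point's
#' parameter values, not grid order.
#'
#' @param spec a [sweep_spec()].
#' @param out_dir optional results directory for resumable execution.
#' @param verbose print a line per completed point.
#' @return a data.frame of phase points, one row per grid point.
#' @export
run_sweep <- function(spec, out_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(spec, "sweep_spec"))
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE,
                                    recursive = TRUE)
  rows <- list()
  for (b in spec$b_values) {
    for (eps_a in spec$eps_a_values) {
      cache <- if (!is.null(out_dir))
        file.path(out_dir, sprintf("point_%.0f.csv",
                                   fnv1a32(point_key(spec, b, eps_a))))
      row <- if (!is.null(cache) && file.exists(cache)) {
        utils::read.csv(cache, stringsAsFactors = FALSE)
      } else {
        r <- run_phase_point(spec, b, eps_a)
        if (!is.null(cache)) {
          utils::write.csv(r, cache, row.names = FALSE)
          # round-trip through the cache so fresh and resumed sweeps are
          # byte-identical
          r <- utils::read.csv(cache, stringsAsFactors = FALSE)
        }
        r
      }
      if (verbose)
        message(sprintf("point b=%g eps_a=%g: adsorbed=%.3f state=%s",
                        b, eps_a, row$mean_adsorbed_fraction,
                        row$state_label))
      rows[[length(rows) + 1L]] <- row
    }
  }
  do.call(rbind, rows)
}

#' Locate the adsorption transition along an eps_a scan
#'
#' The critical attraction strength for fixed bending energy b is the
#' grid \code{eps_a} at which the surface-energy fluctuation peaks (no
#' interpolation: grid resolution is reporting resolution). The estimate
#' is flagged when the maximum sits on a grid boundary, and as ambiguous
#' when it exceeds the runner-up by less than one standard error.
#'
#' @param points phase-point rows for a single b (>= 5 grid points).
#' @return a one-row data.frame: \code{b}, \code{critical_eps_a},
#'   \code{on_boundary}, \code{ambiguous}.
#' @export
locate_transition <- function(points) {
  stopifnot(length(unique(points$b)) == 1)
  if (nrow(points) < 5)
    stop("need >= 5 grid points spanning the peak", call. = FALSE)
  points <- points[order(points$eps_a), ]
  k <- which.max(points$fluctuation)
  runner <- sort(points$fluctuation, decreasing = TRUE)[2]
  se <- points$fluctuation_se[k]
  data.frame(
    b = points$b[1],
    critical_eps_a = points$eps_a[k],
    on_boundary = k == 1L || k == nrow(points),
    ambiguous = is.finite(se) && (points$fluctuation[k] - runner) < se
  )
}

#' Phase diagram: the partially/fully adsorbed boundary
#'
#' Locates the transition for every bending energy in the input and
#' assembles the boundary curve \eqn{\varepsilon_a^{crit}(b)} together
#' with a least-squares linear fit and a monotonicity check (the critical
#' attraction strength must not decrease with stiffness; violations are
#' reported, not hidden). Output is independent of input row order.
#'
#' @param points a phase-point data.frame covering >= 2 b-values, or a
#'   precomputed boundary data.frame with columns \code{b} and
#'   \code{critical_eps_a}.
#' @return a list of class \code{phase_diagram}: \code{boundary} (per-b
#'   rows), \code{slope}, \code{intercept}, \code{monotone},
#'   \code{violations} (b-values where the boundary decreases),
#'   \code{points} (the labelled input, if phase points were given).
#' @export
phase_diagram <- function(points) {
  if (all(c("b", "critical_eps_a") %in% names(points)) &&
      !"fluctuation" %in% names(points)) {
    boundary <- points[order(points$b), c("b", "critical_eps_a")]
    boundary$on_boundary <- FALSE
    boundary$ambiguous <- FALSE
    pts <- NULL
  } else {
    stopifnot(length(unique(points$b)) >= 2)
    boundary <- do.call(rbind, lapply(split(points, points$b),
                                      locate_transition))
    boundary <- boundary[order(boundary$b), ]
    pts <- points[order(points$b, points$eps_a), ]
  }
  rownames(boundary) <- NULL
  fit <- stats::lm(critical_eps_a ~ b, data = boundary)
  dec <- diff(boundary$critical_eps_a) < 0
  out <- list(boundary = boundary,
              slope = unname(stats::coef(fit)["b"]),
              intercept = unname(stats::coef(fit)[1]),
              monotone = !any(dec),
              violations = boundary$b[-1][dec],
              points = pts)
  class(out) <- "phase_diagram"
  out
}

#' @export
print.phase_diagram <- function(x, ...) {
  cat("phase boundary (critical eps_a vs b):\n")
  print(x$boundary, row.names = FALSE)
  cat(sprintf("linear fit: slope = %.6g, intercept = %.6g; monotone: %s\n",
              x$slope, x$intercept, x$monotone))
  if (length(x$violations))
    cat("monotonicity violations at b =",
        paste(x$violations, collapse = ", "), "\n")
  invisible(x)
}

#' Toroid turn count and size against the control parameters
#'
#' Aggregates per-sample toroid calls over the (b, eps_a) grid and tests
#' the two expected trends with Kendall's tau: the turn count N_t grows
#' with the surface attraction at fixed stiffness and shrinks with
#' stiffness at fixed attraction (toroid radius moves oppositely).
#'
#' @param calls a data.frame with one row per classified sample:
#'   \code{b}, \code{eps_a}, \code{is_toroid}, \code{n_turns},
#'   \code{mean_radius}.
#' @param min_toroids grid points with fewer toroidal samples are
#'   excluded (and listed in the \code{excluded} element).
#' @return a list: \code{table} (per-point mean N_t and radius),
#'   \code{trend_vs_eps_a} and \code{trend_vs_b} (Kendall tau per fixed
#'   other parameter), \code{excluded}.
#' @export
turns_vs_parameters <- function(calls, min_toroids = 3L) {
  tor <- calls[calls$is_toroid, , drop = FALSE]
  if (nrow(tor) == 0)
    return(list(table = tor[, 0], trend_vs_eps_a = NULL, trend_vs_b = NULL,
                excluded = unique(calls[, c("b", "eps_a")])))
  key <- interaction(tor$b, tor$eps_a, drop = TRUE)
  tab <- do.call(rbind, lapply(split(tor, key), function(g) {
    data.frame(b = g$b[1], eps_a = g$eps_a[1], n_toroids = nrow(g),
               mean_n_turns = mean(g$n_turns),
               mean_radius = mean(g$mean_radius))
  }))
  excluded <- tab[tab$n_toroids < min_toroids, c("b", "eps_a")]
  tab <- tab[tab$n_toroids >= min_toroids, , drop = FALSE]
  rownames(tab) <- NULL
  kendall <- function(x, y) {
    if (length(unique(x)) < 2 || length(y) < 2) return(NA_real_)
    suppressWarnings(stats::cor(x, y, method = "kendall"))
  }
  trend_eps <- if (nrow(tab)) do.call(rbind, lapply(split(tab, tab$b),
    function(g) data.frame(b = g$b[1],
                           tau_n_turns_vs_eps_a = kendall(g$eps_a, g$mean_n_turns),
                           tau_radius_vs_eps_a = kendall(g$eps_a, g$mean_radius))))
  trend_b <- if (nrow(tab)) do.call(rbind, lapply(split(tab, tab$eps_a),
    function(g) data.frame(eps_a = g$eps_a[1],
                           tau_n_turns_vs_b = kendall(g$b, g$mean_n_turns),
                           tau_radius_vs_b = kendall(g$b, g$mean_radius))))
  list(table = tab, trend_vs_eps_a = trend_eps, trend_vs_b = trend_b,
       excluded = excluded)
}

#' Plot a phase diagram
#'
#' Simple state map in the (b, eps_a) plane with the located boundary.
#' Requires ggplot2.
#'
#' @param pd a [phase_diagram()] result with labelled points.
#' @return a ggplot object.
#' @export
plot_phase_diagram <- function(pd) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting", call. = FALSE)
  stopifnot(inherits(pd, "phase_diagram"), !is.null(pd$points))
  ggplot2::ggplot(pd$points,
                  ggplot2::aes(x = b, y = eps_a, shape = state_label)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::geom_line(data = pd$boundary,
                       ggplot2::aes(x = b, y = critical_eps_a),
                       inherit.aes = FALSE, linetype = 2) +
    ggplot2::labs(x = "bending energy b (kT)",
                  y = expression(epsilon[a] ~ "(kT)"),
                  shape = "state")
}
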