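#' Grow an initial conformation near the wall
#'
#' Grows a self-avoiding chain as a free bending-biased random walk at the
#' model's stiffness (successive bond directions drawn from the Boltzmann
#' weight \eqn{\exp(-b(1 - \cos\varphi))}, all bonds at \eqn{l_0}), then
#' rigidly translates it so the lowest bead sits exactly at the surface
#' minimum, \eqn{\min_i z_i = r_{min,s}} — the monomer closest to the
#' surface starts inside the attraction range.
#'
#' @param params a [model_params()] object.
#' @param max_attempts chain regrowth attempts before giving up.
#' @return an (N+1) x 3 position matrix satisfying all conformation
#'   invariants, with all non-bonded pair distances >= 0.9 r_min_ev.
#' @export
initial_conformation <- function(params, max_attempts = 100L) {
  for (att in seq_len(max_attempts)) {
    pos <- grow_chain(params)
    if (!is.null(pos)) {
      pos[, 3] <- pos[, 3] - min(pos[, 3]) + params$r_min_s
      return(pos)
    }
  }
  stop(sprintf("failed to grow a self-avoiding chain in %d attempts",
               max_attempts), call. = FALSE)
}

# Bending-biased self-avoiding growth; NULL on failure.
grow_chain <- function(params, tries_per_step = 50L) {
  n <- params$n_bonds + 1L
  l0 <- params$l0
  dmin2 <- (0.9 * params$r_min_ev)^2
  pos <- matrix(0, n, 3)
  d <- random_unit_vector()
  pos[2, ] <- pos[1, ] + l0 * d
  b <- params$b
  for (i in seq_len(n - 2L) + 2L) {
    placed <- FALSE
    for (t in seq_len(tries_per_step)) {
      dn <- biased_direction(d, b)
      cand <- pos[i - 1L, ] + l0 * dn
      prev <- pos[seq_len(i - 2L), , drop = FALSE]
      dd <- (prev[, 1] - cand[1])^2 + (prev[, 2] - cand[2])^2 +
        (prev[, 3] - cand[3])^2
      if (all(dd >= dmin2)) {
        pos[i, ] <- cand
        d <- dn
        placed <- TRUE
        break
      }
    }
    if (!placed) return(NULL)
  }
  pos
}

random_unit_vector <- function() {
  z <- stats::runif(1, -1, 1)
  psi <- stats::runif(1, 0, 2 * pi)
  s <- sqrt(1 - z^2)
  c(s * cos(psi), s * sin(psi), z)
}

# Draw a new bond direction at angle phi from `d`, with cos(phi) from the
# density proportional to exp(b * cos(phi)) on [-1, 1] (inverse CDF).
biased_direction <- function(d, b) {
  u <- stats::runif(1)
  cphi <- if (b < 1e-12) {
    2 * u - 1
  } else if (b > 350) {
    1 + log(u) / b          # exp(-2b) underflows; exact in that regime
  } else {
    1 + log(u + (1 - u) * exp(-2 * b)) / b
  }
  cphi <- min(1, max(-1, cphi))
  # orthonormal frame around d
  a <- if (abs(d[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- a - sum(a * d) * d
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(d[2] * e1[3] - d[3] * e1[2],
          d[3] * e1[1] - d[1] * e1[3],
          d[1] * e1[2] - d[2] * e1[1])
  psi <- stats::runif(1, 0, 2 * pi)
  s <- sqrt(max(0, 1 - cphi^2))
  cphi * d + s * (cos(psi) * e1 + sin(psi) * e2)
}

#' One Metropolis trial move
#'
#' Chooses one bead uniformly at random, displaces it by a uniform draw
#' from \eqn{[-\delta, \delta]^3}, and accepts with probability
#' \eqn{\min(e^{-\Delta U}, 1)}. Moves placing the bead below the wall
#' (z < 0) or stretching a bond out of the FENE range are always rejected.
#'
#' @param conf an (N+1) x 3 position matrix.
#' @param params a [model_params()] object.
#' @param max_displacement trial displacement half-width (default 0.15).
#' @param wall enforce the z >= 0 half-space (default TRUE).
#' @param z_max optional ceiling; trial positions above it are rejected
#'   (used to make small test systems normalisable; default \code{Inf}).
#' @return a list with \code{conformation}, \code{accepted}, \code{dU}
#'   and \code{bead} (the bead attempted).
#' @export
metropolis_step <- function(conf, params, max_displacement = 0.15,
                            wall = TRUE, z_max = Inf) {
  r <- cpp_trial_move(conf, params, max_displacement, wall, z_max)
  list(conformation = r$positions, accepted = r$accepted,
       dU = r$dU, bead = r$bead)
}

#' Run a block of Monte Carlo steps
#'
#' One Monte Carlo step (MCS) is N + 1 single-monomer trial moves. The
#' whole block runs in compiled code; randomness comes from R's RNG so a
#' prior \code{set.seed()} makes the trajectory reproducible.
#'
#' @inheritParams metropolis_step
#' @param n_mcs number of MCS to run (>= 0).
#' @return a list with \code{conformation}, \code{acceptance_rate},
#'   \code{du_sum} (sum of accepted \eqn{\Delta U}, for bookkeeping
#'   checks) and \code{trials}.
#' @export
run_mcs <- function(conf, params, n_mcs, max_displacement = 0.15,
                    wall = TRUE, z_max = Inf) {
  stopifnot(n_mcs >= 0)
  if (n_mcs == 0) {
    return(list(conformation = conf, acceptance_rate = NA_real_,
                du_sum = 0, trials = 0))
  }
  r <- cpp_run_mcs(conf, params, n_mcs, max_displacement, wall, z_max)
  list(conformation = r$positions,
       acceptance_rate = r$accepted / r$trials,
       du_sum = r$du_sum, trials = r$trials)
}

#' Run one replica of the sampling campaign
#'
#' Seeds the RNG from (schedule seed, replica id), grows an initial
#' conformation, equilibrates, then records a sample every
#' \code{sampling_interval_mcs}. At every sampling boundary the escape
#' rule is checked: if all beads are above \code{escape_threshold} the
#' chain has diffused away from the surface and the replica restarts from
#' a fresh conformation (samples discarded, restart counted). Exceeding
#' \code{restart_limit} marks the replica failed rather than dropping it.
#'
#' Equilibration runs in eight blocks; the surface energies of the last
#' four blocks are compared (last two vs previous two) and the fragment's
#' \code{equilibrated} flag records whether they agree within one standard
#' error. The burn-in is never extended silently.
#'
#' @param params a [model_params()] object.
#' @param schedule a [run_schedule()] object.
#' @param replica_id replica index (1-based).
#' @param z_max optional ceiling passed to [run_mcs()].
#' @return a replica fragment: list with \code{positions} (list of
#'   matrices), \code{energies} (samples x 5 matrix), \code{mcs},
#'   \code{replica_id}, \code{restarts}, \code{failed},
#'   \code{equilibrated}, \code{acceptance_rate}.
#' @export
run_replica <- function(params, schedule, replica_id, z_max = Inf) {
  set.seed(replica_seed(schedule$seed, replica_id))
  restarts <- 0L
  md <- schedule$max_displacement
  repeat {
    conf <- initial_conformation(params)
    eq <- equilibrate(conf, params, schedule, md, z_max)
    conf <- eq$conformation
    escaped <- min(conf[, 3]) > schedule$escape_threshold
    positions <- vector("list", schedule$n_samples_per_replica)
    energies <- matrix(NA_real_, schedule$n_samples_per_replica, 5,
                       dimnames = list(NULL, c("u_fene", "u_morse", "u_bend",
                                               "u_surf", "u_total")))
    mcs <- numeric(schedule$n_samples_per_replica)
    acc <- numeric(0)
    if (!escaped) {
      for (s in seq_len(schedule$n_samples_per_replica)) {
        r <- run_mcs(conf, params, schedule$sampling_interval_mcs, md,
                     wall = TRUE, z_max = z_max)
        conf <- r$conformation
        acc <- c(acc, r$acceptance_rate)
        if (min(conf[, 3]) > schedule$escape_threshold) {
          escaped <- TRUE
          break
        }
        positions[[s]] <- conf
        energies[s, ] <- unlist(total_energy(conf, params))
        mcs[s] <- schedule$equilibration_mcs +
          s * schedule$sampling_interval_mcs
      }
    }
    if (!escaped) {
      return(list(positions = positions, energies = energies, mcs = mcs,
                  replica_id = replica_id, restarts = restarts,
                  failed = FALSE, equilibrated = eq$equilibrated,
                  acceptance_rate = mean(acc)))
    }
    restarts <- restarts + 1L
    if (restarts > schedule$restart_limit) {
      return(list(positions = list(), energies = energies[0, , drop = FALSE],
                  mcs = numeric(0), replica_id = replica_id,
                  restarts = restarts, failed = TRUE,
                  equilibrated = NA, acceptance_rate = NA_real_))
    }
  }
}

equilibrate <- function(conf, params, schedule, max_displacement, z_max) {
  n_mcs <- schedule$equilibration_mcs
  if (n_mcs <= 0) return(list(conformation = conf, equilibrated = NA))
  chunk <- n_mcs / 8
  us <- numeric(8)
  for (i in 1:8) {
    r <- run_mcs(conf, params, chunk, max_displacement,
                 wall = TRUE, z_max = z_max)
    conf <- r$conformation
    us[i] <- total_energy(conf, params)$u_surf
  }
  se <- stats::sd(us[5:8]) / sqrt(2)
  eqd <- if (se > 0) abs(mean(us[5:6]) - mean(us[7:8])) < se else TRUE
  list(conformation = conf, equilibrated = eqd)
}

#' Run the full replica ensemble for one parameter point
#'
#' Runs every replica of the schedule (independent, individually seeded)
#' and pools the recorded samples into a \code{sample_set}.
#'
#' @inheritParams run_replica
#' @param verbose print one line per replica.
#' @return a \code{sample_set}: list with \code{positions} (array
#'   samples x beads x 3), \code{energies} (samples x 5), \code{mcs},
#'   \code{replica}, \code{params}, \code{schedule}, \code{restart_log}
#'   (one row per replica: restarts, failed, equilibrated,
#'   acceptance_rate).
#' @export
run_ensemble <- function(params, schedule, z_max = Inf, verbose = FALSE) {
  frags <- lapply(seq_len(schedule$n_replicas), function(r) {
    f <- run_replica(params, schedule, r, z_max = z_max)
    if (verbose)
      message(sprintf("replica %d: %s, restarts = %d", r,
                      if (f$failed) "FAILED" else "ok", f$restarts))
    f
  })
  sample_set(frags, params, schedule)
}

#' Assemble replica fragments into a sample set
#'
#' @param fragments list of fragments from [run_replica()].
#' @param params,schedule the generating parameters and schedule.
#' @return a \code{sample_set} object; see [run_ensemble()].
#' @export
sample_set <- function(fragments, params, schedule) {
  keep <- lapply(fragments, function(f) f$positions[!vapply(f$positions, is.null, TRUE)])
  n_per <- vapply(keep, length, 1L)
  total <- sum(n_per)
  nb <- params$n_bonds + 1L
  pos <- array(NA_real_, c(total, nb, 3))
  i <- 0L
  for (fr in keep) {
    for (p in fr) {
      i <- i + 1L
      pos[i, , ] <- p
    }
  }
  energies <- do.call(rbind, lapply(seq_along(fragments), function(j) {
    fragments[[j]]$energies[seq_len(n_per[j]), , drop = FALSE]
  }))
  ss <- list(
    positions = pos,
    energies = energies,
    mcs = unlist(lapply(seq_along(fragments),
                        function(j) fragments[[j]]$mcs[seq_len(n_per[j])])),
    replica = rep(vapply(fragments, function(f) f$replica_id, 1L), n_per),
    params = params,
    schedule = schedule,
    restart_log = data.frame(
      replica_id = vapply(fragments, function(f) f$replica_id, 1L),
      restarts = vapply(fragments, function(f) f$restarts, 1L),
      failed = vapply(fragments, function(f) f$failed, TRUE),
      equilibrated = vapply(fragments, function(f) as.logical(f$equilibrated), TRUE),
      acceptance_rate = vapply(fragments, function(f) f$acceptance_rate, 1.0)
    )
  )
  class(ss) <- "sample_set"
  ss
}

#' @export
print.sample_set <- function(x, ...) {
  cat(sprintf("sample_set: %d samples (%d beads), b = %g, eps_a = %g\n",
              n_samples(x), dim(x$positions)[2], x$params$b, x$params$eps_a))
  cat(sprintf("  replicas: %d (%d failed), restarts total: %d\n",
              nrow(x$restart_log), sum(x$restart_log$failed),
              sum(x$restart_log$restarts)))
  invisible(x)
}

#' @rdname sample_set
#' @param ss a \code{sample_set}.
#' @export
n_samples <- function(ss) dim(ss$positions)[1]

#' Extract sample conformations
#'
#' @param ss a \code{sample_set}.
#' @param which sample indices (default all).
#' @return a list of (N+1) x 3 position matrices.
#' @export
conformations <- function(ss, which = seq_len(n_samples(ss))) {
  lapply(which, function(i) ss$positions[i, , ])
}
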