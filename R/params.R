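#' Model parameters for the bead-spring chain and the attractive wall
#'
#' Container for every physical constant of the energy model. Energies are
#' in units of \eqn{k_B T}, lengths in units of the maximum bond extension
#' \eqn{l_{max}}. Defaults are the standard parameterisation of the
#' coarse-grained model: FENE bonds confined to \eqn{(l_{min}, l_{max}) =
#' (0.4, 1.0)} with preferred length \eqn{l_0 = 0.7} and spring constant
#' \eqn{k = 20}; a Morse excluded-volume pair potential with steepness
#' \eqn{\alpha = 24}, minimum at \eqn{r_{min} = 0.8} and depth
#' \eqn{\varepsilon = 1}; and a Morse monomer-surface attraction of depth
#' \code{eps_a} with the same steepness and minimum distance.
#'
#' @param n_bonds integer, number of bonds N (the chain has N + 1 beads).
#' @param b bending energy (chain stiffness) in \eqn{k_B T}; 0 = fully
#'   flexible.
#' @param eps_a depth of the monomer-surface attraction in \eqn{k_B T};
#'   0 = purely repulsive wall absent.
#' @param l_min,l_max,l0 FENE bond-length bounds and preferred length.
#' @param k_spring FENE spring constant.
#' @param alpha,r_min_ev,eps_ev Morse excluded-volume steepness, minimum
#'   position and depth.
#' @param alpha_s,r_min_s surface Morse steepness and minimum distance.
#' @param pair_cutoff distance beyond which the excluded-volume pair term
#'   is treated as exactly zero (the potential is negligible beyond unit
#'   length); set to 0 to disable the cutoff.
#'
#' @return an object of class \code{model_params} (a validated named list
#'   that also carries \code{r0 = l_max - l0}).
#' @export
model_params <- function(n_bonds = 300L, b = 0, eps_a = 0,
                         l_min = 0.4, l_max = 1.0, l0 = 0.7,
                         k_spring = 20, alpha = 24, r_min_ev = 0.8,
                         eps_ev = 1, alpha_s = 24, r_min_s = 0.8,
                         pair_cutoff = 1.0) {
  p <- list(n_bonds = as.integer(n_bonds), b = b, eps_a = eps_a,
            l_min = l_min, l_max = l_max, l0 = l0, r0 = l_max - l0,
            k_spring = k_spring, alpha = alpha, r_min_ev = r_min_ev,
            eps_ev = eps_ev, alpha_s = alpha_s, r_min_s = r_min_s,
            pair_cutoff = pair_cutoff)
  class(p) <- "model_params"
  validate_model_params(p)
  p
}

validate_model_params <- function(p) {
  stopifnot(p$n_bonds >= 1,
            p$l_min < p$l0, p$l0 < p$l_max,
            p$k_spring > 0, p$alpha > 0, p$eps_ev > 0,
            p$b >= 0, p$eps_a >= 0,
            p$alpha_s > 0, p$r_min_s > 0, p$r_min_ev > 0)
  if (abs((p$l_max - p$l0) - (p$l0 - p$l_min)) > 1e-12)
    warning("FENE range is asymmetric about l0: l_max - l0 != l0 - l_min",
            call. = FALSE)
  invisible(p)
}

#' @export
print.model_params <- function(x, ...) {
  cat(sprintf("model_params: N = %d bonds (%d beads), b = %g, eps_a = %g\n",
              x$n_bonds, x$n_bonds + 1L, x$b, x$eps_a))
  cat(sprintf("  FENE: l in (%g, %g), l0 = %g, k = %g\n",
              x$l_min, x$l_max, x$l0, x$k_spring))
  cat(sprintf("  Morse EV: alpha = %g, r_min = %g, eps = %g, cutoff = %g\n",
              x$alpha, x$r_min_ev, x$eps_ev, x$pair_cutoff))
  cat(sprintf("  Surface:  alpha_s = %g, r_min_s = %g\n", x$alpha_s, x$r_min_s))
  invisible(x)
}

#' Run schedule for the Metropolis engine
#'
#' Describes one sampling campaign: how many independent replicas, how much
#' equilibration, and how often to record a sample. The production-scale
#' schedule is 100 replicas each yielding 100 measurements at intervals of
#' \eqn{10^6} MCS (one MCS = N + 1 single-monomer trial moves).
#'
#' @param n_replicas number of independent runs.
#' @param equilibration_mcs burn-in MCS before the first sample.
#' @param n_samples_per_replica samples recorded per replica.
#' @param sampling_interval_mcs MCS between successive samples.
#' @param max_displacement half-width of the uniform trial displacement for
#'   each coordinate (moves are drawn from \eqn{[-0.15, 0.15]^3} by
#'   default).
#' @param seed master integer seed; per-replica streams are derived from
#'   (seed, replica_id) so each replica is individually reproducible.
#' @param escape_threshold if every bead is above this height at a sampling
#'   boundary, the chain has diffused away and the replica restarts.
#' @param restart_limit maximum restarts before a replica is marked failed.
#' @return an object of class \code{run_schedule}.
#' @export
run_schedule <- function(n_replicas = 100L, equilibration_mcs = 1e7,
                         n_samples_per_replica = 100L,
                         sampling_interval_mcs = 1e6,
                         max_displacement = 0.15, seed = 1L,
                         escape_threshold = 5.0, restart_limit = 10L) {
  s <- list(n_replicas = as.integer(n_replicas),
            equilibration_mcs = equilibration_mcs,
            n_samples_per_replica = as.integer(n_samples_per_replica),
            sampling_interval_mcs = sampling_interval_mcs,
            max_displacement = max_displacement,
            seed = as.integer(seed),
            escape_threshold = escape_threshold,
            restart_limit = as.integer(restart_limit))
  stopifnot(s$n_replicas >= 1, s$sampling_interval_mcs >= 1,
            s$max_displacement > 0, s$n_samples_per_replica >= 1,
            s$equilibration_mcs >= 0)
  class(s) <- "run_schedule"
  s
}

#' Derive the RNG seed for one replica
#'
#' A fixed affine map of (master seed, replica id) into the 32-bit integer
#' range, so replicas are independent and individually reproducible.
#'
#' @param seed master seed.
#' @param replica_id replica index (1-based).
#' @return an integer seed.
#' @export
replica_seed <- function(seed, replica_id) {
  as.integer((as.double(seed) + 1000003 * as.double(replica_id)) %% 2147483647)
}

#' Read or write model parameters as a flat YAML or JSON block
#'
#' Serialises every field of [model_params()] (minus the derived `r0`)
#' under exactly its field name; files written by one format can be read
#' back by the matching reader.
#'
#' @param params a \code{model_params} object.
#' @param path file path; format chosen by extension (.yaml/.yml or .json).
#' @return \code{read_params()} returns a \code{model_params} object;
#'   \code{write_params()} returns the path invisibly.
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, "model_params"))
  x <- unclass(params)
  x$r0 <- NULL
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(x, path)
  }
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  x <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  do.call(model_params, x[setdiff(names(x), "r0")])
}
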