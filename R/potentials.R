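#' FENE bond potential
#'
#' Finitely extendable nonlinear elastic energy of a single bond,
#' \deqn{U(l) = -\tfrac{1}{2} k r_0^2 \ln[1 - ((l - l_0)/r_0)^2],}
#' symmetric about the preferred length \eqn{l_0} and divergent at the
#' range limits \eqn{l_0 \pm r_0}. Bond lengths at or beyond the limits
#' return \code{Inf} (the infinite-energy sentinel: such a trial move is
#' always rejected).
#'
#' @param l bond length(s).
#' @param params a [model_params()] object.
#' @return energy in \eqn{k_B T}; \code{Inf} outside the FENE range.
#' @export
fene_energy <- function(l, params = model_params()) {
  out <- rep(Inf, length(l))
  ok <- l > params$l_min & l < params$l_max
  x <- (l[ok] - params$l0) / params$r0
  out[ok] <- -0.5 * params$k_spring * params$r0^2 * log1p(-x^2)
  out
}

#' Morse excluded-volume pair potential
#'
#' \deqn{U(r) = \varepsilon (e^{-2\alpha(r - r_{min})} -
#'   2 e^{-\alpha(r - r_{min})})}
#' for non-bonded bead pairs, with minimum \eqn{-\varepsilon} at
#' \eqn{r_{min}}. With the default steepness the tail is negligible beyond
#' unit length, so the energy is treated as exactly zero at and beyond
#' \code{params$pair_cutoff} (applied identically in full and incremental
#' evaluation).
#'
#' @param r pair distance(s), must be positive.
#' @param params a [model_params()] object.
#' @param cutoff apply the tail cutoff (default TRUE; FALSE gives the bare
#'   potential, used for cutoff-consistency checks).
#' @return energy in \eqn{k_B T}.
#' @export
morse_pair_energy <- function(r, params = model_params(), cutoff = TRUE) {
  stopifnot(all(r > 0))
  e <- exp(-params$alpha * (r - params$r_min_ev))
  out <- params$eps_ev * (e^2 - 2 * e)
  if (cutoff && params$pair_cutoff > 0) out[r >= params$pair_cutoff] <- 0
  out
}

#' Angular bending potential
#'
#' \deqn{U(\theta) = b (1 + \cos\theta)} where \eqn{\theta} is the
#' interior angle between two consecutive bonds, with the convention that
#' a straight (collinear) arrangement has \eqn{\theta = \pi} and so zero
#' energy; a complete fold-back costs \eqn{2b}. Internally the engine uses
#' the algebraically identical form \eqn{b (1 - \cos\varphi)} with
#' \eqn{\varphi} the angle between successive bond vectors.
#'
#' @param theta interior bond-bond angle(s) in radians, in \eqn{[0, \pi]}.
#' @param params a [model_params()] object (supplies \code{b}).
#' @return energy in \eqn{k_B T}.
#' @export
bending_energy <- function(theta, params = model_params()) {
  params$b * (1 + cos(theta))
}

#' Monomer-surface Morse attraction
#'
#' \deqn{U(z) = \varepsilon_a (e^{-2\alpha_s(z - r_{min,s})} -
#'   2 e^{-\alpha_s(z - r_{min,s})})}
#' for a bead at height \eqn{z} above the wall at \eqn{z = 0}; minimum
#' \eqn{-\varepsilon_a} at \eqn{z = r_{min,s}}, strongly repulsive as
#' \eqn{z \to 0} (soft wall). No tail cutoff is applied: the term is a
#' single cheap evaluation per bead and the tail is \eqn{\sim 10^{-13}
#' \varepsilon_a} already at \eqn{z = 2}.
#'
#' @param z bead height(s); negative heights are invalid positions and
#'   raise an error (the engine rejects such trial moves before energy
#'   evaluation).
#' @param params a [model_params()] object.
#' @return energy in \eqn{k_B T}.
#' @export
surface_energy <- function(z, params = model_params()) {
  if (any(z < 0)) stop("invalid position: bead height z < 0", call. = FALSE)
  e <- exp(-params$alpha_s * (z - params$r_min_s))
  params$eps_a * (e^2 - 2 * e)
}

#' Total energy of a conformation, by component
#'
#' Sums the FENE term over all N bonds, the Morse excluded-volume term over
#' all pairs with \eqn{|i - j| > 1}, the bending term over all N - 1
#' interior angles, and the surface term over all N + 1 beads.
#'
#' @param conf an (N+1) x 3 position matrix.
#' @param params a [model_params()] object.
#' @return a named list of class \code{energy_breakdown} with components
#'   \code{u_fene}, \code{u_morse}, \code{u_bend}, \code{u_surf},
#'   \code{u_total}. Any bond outside the FENE range makes \code{u_fene}
#'   and \code{u_total} infinite.
#' @export
total_energy <- function(conf, params) {
  v <- cpp_total_energy(conf, params)
  out <- as.list(v)
  class(out) <- "energy_breakdown"
  out
}

#' Energy change of a single-monomer trial move
#'
#' Incremental evaluation touching only the terms involving the moved
#' bead: its one or two bonds, up to three interior angles, its surface
#' term, and its non-bonded pair terms. Equals the full-recomputation
#' difference \code{total_energy(moved) - total_energy(old)} to floating
#' point accuracy, at O(N) instead of O(N^2) cost.
#'
#' @param conf an (N+1) x 3 position matrix.
#' @param bead_index bead to move (1-based, in 1..N+1).
#' @param new_position length-3 numeric, the trial position.
#' @param params a [model_params()] object.
#' @return the energy difference \eqn{\Delta U}; \code{Inf} if a resulting
#'   bond leaves the FENE range.
#' @export
delta_energy <- function(conf, bead_index, new_position, params) {
  stopifnot(bead_index >= 1, bead_index <= nrow(conf),
            length(new_position) == 3)
  cpp_delta_energy(conf, as.integer(bead_index),
                   as.numeric(new_position), params)
}
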