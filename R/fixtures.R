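#' Deterministic conformation fixtures
#'
#' Exact analytic geometries used to validate the observable suite:
#' \describe{
#'   \item{rod}{collinear chain along x at the given height.}
#'   \item{circle}{the chain traverses the edges of a regular
#'     \code{n_bonds}-gon (the last bead coincides with the first), lying
#'     flat at the given height; radius follows from the chord condition
#'     \eqn{R = l / (2 \sin(\pi/n))}.}
#'   \item{toroid_spiral}{flat Archimedean spiral of \code{turns} full
#'     loops at the given height with inter-loop gap \code{gap}; the inner
#'     radius is chosen so the total arc length matches the chain length,
#'     and each bond is placed by solving the exact chord equation.}
#'   \item{helix}{circular helix of given \code{radius} and \code{pitch}
#'     (rise per turn), climbing from the given height.}
#'   \item{coil}{seeded self-avoiding random walk (flexible-chain
#'     statistics), translated so its lowest bead sits at the given
#'     height.}
#' }
#' All bond lengths equal \code{bond_length} exactly (to solver tolerance
#' for the spiral), so every fixture satisfies the conformation
#' invariants; generation is a pure function of its arguments.
#'
#' @param kind one of "rod", "circle", "toroid_spiral", "helix", "coil".
#' @param n_bonds number of bonds (beads = n_bonds + 1).
#' @param bond_length bond length (default the preferred length 0.7).
#' @param turns full loops of the spiral.
#' @param gap radial distance between successive spiral loops (>= 0.8 so
#'   neighbouring loops sit at the excluded-volume minimum distance).
#' @param radius,pitch helix geometry.
#' @param height placement height above the wall.
#' @param seed RNG seed (coil only).
#' @return an (N+1) x 3 position matrix.
#' @export
make_fixture <- function(kind = c("rod", "circle", "toroid_spiral",
                                  "helix", "coil"),
                         n_bonds, bond_length = 0.7, turns = 3, gap = 0.9,
                         radius = 1.5, pitch = 1.0, height = 0.8,
                         seed = 1L) {
  kind <- match.arg(kind)
  stopifnot(n_bonds >= 1, bond_length > 0, height >= 0)
  n <- n_bonds + 1L
  pos <- switch(
    kind,
    rod = cbind(x = (0:n_bonds) * bond_length, y = 0, z = height),
    circle = {
      R <- bond_length / (2 * sin(pi / n_bonds))
      a <- 2 * pi * (0:n_bonds) / n_bonds
      cbind(x = R * cos(a), y = R * sin(a), z = height)
    },
    toroid_spiral = fixture_spiral(n_bonds, bond_length, turns, gap, height),
    helix = fixture_helix(n_bonds, bond_length, radius, pitch, height),
    coil = fixture_coil(n_bonds, bond_length, height, seed)
  )
  dimnames(pos) <- NULL
  pos
}

fixture_spiral <- function(n_bonds, bond_length, turns, gap, height) {
  if (gap < 0.8)
    stop("infeasible toroid_spiral: inter-loop gap must be >= 0.8", call. = FALSE)
  L <- n_bonds * bond_length
  a <- L / (2 * pi * turns) - gap * turns / 2   # inner radius from arc length
  if (a < 0.5)
    stop(sprintf(paste0("infeasible toroid_spiral: inner radius %.3f < 0.5; ",
                        "increase n_bonds or decrease turns"), a),
         call. = FALSE)
  r_of <- function(phi) a + gap * phi / (2 * pi)
  pt <- function(phi) r_of(phi) * c(cos(phi), sin(phi))
  pos <- matrix(0, n_bonds + 1L, 3)
  pos[, 3] <- height
  phi <- 0
  pos[1, 1:2] <- pt(0)
  for (k in seq_len(n_bonds)) {
    p0 <- pos[k, 1:2]
    chord <- function(dphi) sqrt(sum((pt(phi + dphi) - p0)^2)) - bond_length
    guess <- bond_length / r_of(phi)
    dphi <- stats::uniroot(chord, c(0.2 * guess, 3 * guess),
                           tol = 1e-12)$root
    phi <- phi + dphi
    pos[k + 1L, 1:2] <- pt(phi)
  }
  pos
}

fixture_helix <- function(n_bonds, bond_length, radius, pitch, height) {
  chord <- function(d) {
    sqrt(4 * radius^2 * sin(d / 2)^2 + (pitch * d / (2 * pi))^2) - bond_length
  }
  if (chord(pi) < 0)
    stop("infeasible helix: radius/pitch too small for the bond length",
         call. = FALSE)
  d <- stats::uniroot(chord, c(1e-9, pi), tol = 1e-12)$root
  a <- (0:n_bonds) * d
  cbind(x = radius * cos(a), y = radius * sin(a),
        z = height + pitch * a / (2 * pi))
}

fixture_coil <- function(n_bonds, bond_length, height, seed) {
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(seed)
  p <- model_params(n_bonds = n_bonds, b = 0, eps_a = 0, l0 = bond_length)
  pos <- NULL
  for (att in 1:100) {
    pos <- grow_chain(p)
    if (!is.null(pos)) break
  }
  if (is.null(pos)) stop("coil fixture: self-avoiding growth failed", call. = FALSE)
  pos[, 3] <- pos[, 3] - min(pos[, 3]) + height
  pos
}
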