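as_conformation_list <- function(x) {
  if (inherits(x, "sample_set")) return(conformations(x))
  if (is.matrix(x)) return(list(x))
  if (is.list(x)) return(x)
  stop("expected a position matrix, a list of them, or a sample_set",
       call. = FALSE)
}

#' Monomer height histogram N_m / P(D)
#'
#' Bins bead heights into unit-width bins centred at integer distances D,
#' each bin spanning \eqn{[D - 0.5, D + 0.5)}. The adsorbed well (z near
#' 0.8) therefore falls in the D = 1 bin. Counts (\eqn{N_m}) are pooled
#' over all supplied conformations; proportions (\eqn{P(D)}) divide by the
#' total number of beads counted.
#'
#' @param confs a position matrix, list of them, or a \code{sample_set}.
#' @return a data.frame with \code{bin_center}, \code{count},
#'   \code{proportion} (proportions sum to 1).
#' @export
height_histogram <- function(confs) {
  confs <- as_conformation_list(confs)
  stopifnot(length(confs) >= 1)
  z <- unlist(lapply(confs, function(p) p[, 3]))
  d <- floor(z + 0.5)               # bin center for z in [D - 0.5, D + 0.5)
  counts <- tabulate(d + 1L, nbins = max(d) + 1L)
  data.frame(bin_center = seq_along(counts) - 1L,
             count = counts,
             proportion = counts / length(z))
}

#' Fraction of beads adsorbed on the wall
#'
#' A bead counts as bound when its height is within the attraction range
#' of the wall, \eqn{z \le} \code{cutoff} (default 1.0, the distance
#' beyond which the surface potential is negligible).
#'
#' @param conf an (N+1) x 3 position matrix.
#' @param cutoff adsorption distance cutoff.
#' @return a proportion in \eqn{[0, 1]}.
#' @export
adsorbed_fraction <- function(conf, cutoff = 1.0) {
  mean(conf[, 3] <= cutoff)
}

#' Proportion of monomers bound to the surface, P(D <= 1)
#'
#' The pooled height-histogram mass of the bins within the attraction
#' range (centres 0 and 1, i.e. z < 1.5): the "monomers binding to
#' surface" proportion plotted against the control parameters.
#'
#' @inheritParams height_histogram
#' @return a proportion.
#' @export
binding_proportion <- function(confs) {
  h <- height_histogram(confs)
  sum(h$proportion[h$bin_center <= 1])
}

#' Spatial correlation function G(m) of bond direction cosines
#'
#' For a single conformation with N' beads and bond unit vectors
#' \eqn{\hat l_1 \dots \hat l_{N'-1}}, let \eqn{\cos\theta_{i,j} = \hat
#' l_i \cdot \hat l_j}. For each reference bond i the sequence
#' \eqn{\{\cos\theta_{i,j}\}_j} is autocorrelated at lag m, normalised by
#' its own variance:
#' \deqn{g(m,i) = \frac{\frac{1}{N'-m-1} \sum_{j=1}^{N'-m-1}
#'   (c_{ij} - \bar c_i)(c_{i,j+m} - \bar c_i)}
#'   {\frac{1}{N'-1} \sum_{j=1}^{N'-1} (c_{ij} - \bar c_i)^2},}
#' and \eqn{G(m) = \frac{1}{N'-3} \sum_{i=2}^{N'-2} g(m,i)}. A periodic
#' G(m) diagnoses helical/toroidal winding; the number of full periods
#' over the lag range counts the turns.
#'
#' Reference bonds with zero variance contribute nothing and are skipped;
#' a lag where every reference bond has zero variance is NaN.
#'
#' @param conf an (N+1) x 3 position matrix with at least 5 bonds.
#' @return a data.frame with \code{lag} (1 .. N'-4), \code{value},
#'   \code{n_pairs} (reference bonds contributing).
#' @export
spatial_correlation_G <- function(conf) {
  B <- bond_vectors(conf)
  nb <- nrow(B)                      # nb = N' - 1 bonds
  if (nb < 5) stop("G(m) requires a chain with at least 5 bonds", call. = FALSE)
  U <- B / sqrt(rowSums(B^2))
  C <- U %*% t(U)                    # cos(theta_{i,j})
  X <- C - rowMeans(C)
  den <- rowSums(X^2) / nb           # per-reference variance
  iref <- 2:(nb - 1)                 # i = 2 .. N' - 2
  ok <- den[iref] > 1e-14
  m_max <- nb - 3                    # m = 1 .. N' - 4
  value <- n_pairs <- numeric(m_max)
  for (m in seq_len(m_max)) {
    num <- rowSums(X[, 1:(nb - m), drop = FALSE] *
                     X[, (1 + m):nb, drop = FALSE]) / (nb - m)
    g <- (num / den)[iref]
    n_pairs[m] <- sum(ok)
    value[m] <- if (any(ok)) mean(g[ok]) else NaN
  }
  data.frame(lag = seq_len(m_max), value = value, n_pairs = n_pairs)
}

unit_tangents <- function(conf) {
  B <- bond_vectors(conf)
  B / sqrt(rowSums(B^2))
}

#' Ensemble tangent-tangent correlation C(s)
#'
#' With \eqn{u(s)} the unit bond (tangent) vector at contour index s and
#' \eqn{\langle\cdot\rangle} the ensemble average over samples,
#' \deqn{C(s) = \langle (u(s) - \langle u(s)\rangle) \cdot
#'   (u(0) - \langle u(0)\rangle) \rangle,}
#' i.e. C(s, 0) measured from the chain end. Because the two chain ends
#' are indistinguishable the estimate is averaged over both orientations
#' (reading the chain from either end). Both the raw covariance and the
#' variance-normalised curve C(s)/C(0) are returned; the normalised
#' variant is the one used for period counting. Periodic oscillation of
#' C(s) diagnoses a wound (toroidal) conformation.
#'
#' @param samples a \code{sample_set} or a list of at least 2 position
#'   matrices with identical bead counts.
#' @return a data.frame with \code{lag} (s = 0 .. N'-2), \code{value},
#'   \code{normalized}, \code{n_samples}.
#' @export
tangent_correlation_C <- function(samples) {
  confs <- as_conformation_list(samples)
  if (length(confs) < 2)
    stop("C(s) needs at least 2 samples (no fluctuation otherwise)",
         call. = FALSE)
  U <- lapply(confs, unit_tangents)
  nb <- nrow(U[[1]])
  cs_oriented <- function(ulist) {
    M <- Reduce(`+`, ulist) / length(ulist)
    u0 <- t(vapply(ulist, function(u) u[1, ] - M[1, ], numeric(3)))
    v <- vapply(seq_len(nb), function(s) {
      us <- t(vapply(ulist, function(u) u[s, ], numeric(3))) -
        matrix(M[s, ], length(ulist), 3, byrow = TRUE)
      mean(rowSums(us * u0))
    }, numeric(1))
    v
  }
  fwd <- cs_oriented(U)
  rev_ <- cs_oriented(lapply(U, function(u) -u[nb:1, , drop = FALSE]))
  value <- (fwd + rev_) / 2
  data.frame(lag = 0:(nb - 1), value = value,
             normalized = value / value[1],
             n_samples = length(confs))
}

#' Surface-energy fluctuation
#'
#' The variance \eqn{\langle U_s^2\rangle - \langle U_s\rangle^2} of the
#' total surface attraction energy over all pooled samples — the analogue
#' of a specific heat for the adsorption transition; its peak along an
#' \eqn{\varepsilon_a} scan locates the critical attraction strength.
#' The standard error is a bootstrap over replicas (resampling whole
#' replicas with replacement); with a single replica the bootstrap
#' resamples individual samples instead.
#'
#' @param samples a \code{sample_set}, or a numeric vector of per-sample
#'   surface energies (then \code{replica} may give replica ids).
#' @param n_boot bootstrap resamples.
#' @param seed RNG seed for the bootstrap.
#' @param replica optional replica ids when \code{samples} is a vector.
#' @return a list with \code{value} and \code{stderr}.
#' @export
surface_energy_fluctuation <- function(samples, n_boot = 1000L, seed = 1L,
                                       replica = NULL) {
  if (inherits(samples, "sample_set")) {
    us <- samples$energies[, "u_surf"]
    replica <- samples$replica
  } else {
    us <- as.numeric(samples)
    if (is.null(replica)) replica <- rep(1L, length(us))
  }
  if (length(us) < 2) stop("need at least 2 samples", call. = FALSE)
  fluct <- function(x) mean(x^2) - mean(x)^2
  ids <- unique(replica)
  old <- .Random.seed_get()
  set.seed(seed)
  boots <- if (length(ids) > 1) {
    by_rep <- split(us, replica)
    vapply(seq_len(n_boot), function(i) {
      fluct(unlist(by_rep[sample.int(length(ids), replace = TRUE)],
                   use.names = FALSE))
    }, numeric(1))
  } else {
    vapply(seq_len(n_boot), function(i) {
      fluct(us[sample.int(length(us), replace = TRUE)])
    }, numeric(1))
  }
  .Random.seed_set(old)
  list(value = fluct(us), stderr = stats::sd(boots))
}

.Random.seed_get <- function() {
  if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
}
.Random.seed_set <- function(s) {
  if (!is.null(s)) assign(".Random.seed", s, globalenv())
}

#' Classify a conformation as a film-like toroid
#'
#' A fully adsorbed stiff chain winds into a flat spiral ("film-like
#' toroid"). The classifier requires (i) adsorbed fraction >= 0.9, (ii)
#' height extent (max z - min z) <= 1.0 (quasi-2D film), and (iii) a
#' periodic G(m): the dominant non-zero frequency of the discrete spectrum
#' of G must carry at least \code{score_threshold} times the median
#' spectral power. The turn count \eqn{N_t} is the number of full G(m)
#' periods over the lag range, i.e. the dominant frequency index.
#'
#' @param conf an (N+1) x 3 position matrix.
#' @param adsorption_cutoff height cutoff for [adsorbed_fraction()].
#' @param film_threshold maximum height extent of a film.
#' @param score_threshold minimum peak-to-median spectral power ratio.
#' @return a list of class \code{toroid_call}: \code{is_toroid},
#'   \code{n_turns}, \code{mean_radius} (mean in-plane distance of beads
#'   from their centroid), \code{height_extent}, \code{periodicity_score},
#'   \code{adsorbed_fraction}.
#' @export
classify_toroid <- function(conf, adsorption_cutoff = 1.0,
                            film_threshold = 1.0, score_threshold = 4.0) {
  af <- adsorbed_fraction(conf, adsorption_cutoff)
  extent <- max(conf[, 3]) - min(conf[, 3])
  ctr <- colMeans(conf[, 1:2, drop = FALSE])
  mean_radius <- mean(sqrt((conf[, 1] - ctr[1])^2 + (conf[, 2] - ctr[2])^2))
  g <- spatial_correlation_G(conf)$value
  per <- g_periodicity(g)
  out <- list(is_toroid = af >= 0.9 && extent <= film_threshold &&
                per$score >= score_threshold,
              n_turns = per$n_turns, mean_radius = mean_radius,
              height_extent = extent, periodicity_score = per$score,
              adsorbed_fraction = af)
  class(out) <- "toroid_call"
  out
}

# Dominant-frequency analysis of a G(m) curve: returns the frequency index
# (= number of full periods over the lag range) and the peak/median power
# ratio. Degenerate (all-NaN or flat) curves score 0.
g_periodicity <- function(g) {
  ok <- is.finite(g)
  if (sum(ok) < 8) return(list(n_turns = 0L, score = 0))
  if (!all(ok)) g <- stats::approx(seq_along(g)[ok], g[ok],
                                   xout = seq_along(g), rule = 2)$y
  x <- g - mean(g)
  if (sum(x^2) < 1e-20) return(list(n_turns = 0L, score = 0))
  pw <- Mod(stats::fft(x))^2
  m <- length(x)
  kmax <- floor(m / 2)
  pw <- pw[2:(kmax + 1)]            # frequency indices 1 .. floor(m/2)
  k <- which.max(pw)
  med <- stats::median(pw)
  score <- if (med > 0) pw[k] / med else Inf
  list(n_turns = as.integer(k), score = score)
}

#' @export
print.toroid_call <- function(x, ...) {
  cat(sprintf(
    "toroid_call: %s (N_t = %d, score = %.2f, adsorbed = %.3f, extent = %.3f)\n",
    if (x$is_toroid) "toroid" else "not a toroid",
    x$n_turns, x$periodicity_score, x$adsorbed_fraction, x$height_extent))
  invisible(x)
}
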