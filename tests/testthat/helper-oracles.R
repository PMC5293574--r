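# Independent oracles used across the suite.

# Brute-force total energy: plain R double loops over the vectorised scalar
# potentials, independent of the compiled incremental path.
brute_total_energy <- function(conf, params, cutoff = TRUE) {
  n <- nrow(conf)
  u_fene <- sum(fene_energy(bond_lengths(conf), params))
  u_bend <- sum(bending_energy(bond_angles(conf), params))
  u_surf <- sum(surface_energy(conf[, 3], params))
  u_morse <- 0
  for (i in seq_len(n - 2)) {
    for (j in (i + 2):n) {
      r <- sqrt(sum((conf[i, ] - conf[j, ])^2))
      u_morse <- u_morse + morse_pair_energy(r, params, cutoff = cutoff)
    }
  }
  list(u_fene = u_fene, u_morse = u_morse, u_bend = u_bend,
       u_surf = u_surf, u_total = u_fene + u_morse + u_bend + u_surf)
}

# Two-sided KS distance between samples and a CDF function.
ks_distance <- function(x, cdf) {
  x <- sort(x)
  n <- length(x)
  f <- cdf(x)
  max(abs(seq_len(n) / n - f), abs((seq_len(n) - 1) / n - f))
}

# Boltzmann CDF of the bond length of a free FENE bond (Cartesian measure
# gives the l^2 Jacobian), by numeric quadrature.
bond_length_cdf <- function(params) {
  l <- seq(params$l_min + 1e-9, params$l_max - 1e-9, length.out = 4001)
  dens <- l^2 * exp(-fene_energy(l, params))
  cdf <- cumsum(c(0, diff(l) * (dens[-1] + dens[-length(dens)]) / 2))
  cdf <- cdf / cdf[length(cdf)]
  stats::approxfun(l, cdf, yleft = 0, yright = 1)
}

# Boltzmann CDF of cos(phi) (phi = angle between successive bond vectors)
# under the bending weight exp(-b (1 - cos phi)); closed form.
bond_angle_cos_cdf <- function(b) {
  function(c) (exp(b * c) - exp(-b)) / (exp(b) - exp(-b))
}

# Boltzmann CDF of a bead height for a 2-bead chain above the wall with a
# ceiling at z_max: 2D quadrature over bond length and orientation.
height_cdf_2bead <- function(params, z_max) {
  z <- seq(1e-6, z_max, length.out = 701)
  l <- seq(params$l_min + 1e-6, params$l_max - 1e-6, length.out = 81)
  cc <- seq(-1, 1, length.out = 161)
  wl <- l^2 * exp(-fene_energy(l, params))
  inner <- vapply(z, function(z1) {
    z2 <- outer(l, cc)              # l x c grid of partner heights offset
    z2 <- z1 + z2
    ok <- z2 >= 0 & z2 <= z_max
    w <- matrix(0, length(l), length(cc))
    w[ok] <- exp(-surface_energy(z2[ok], params))
    sum(wl * rowSums(w))
  }, numeric(1))
  dens <- exp(-surface_energy(z, params)) * inner
  cdf <- cumsum(c(0, diff(z) * (dens[-1] + dens[-length(dens)]) / 2))
  cdf <- cdf / cdf[length(cdf)]
  stats::approxfun(z, cdf, yleft = 0, yright = 1)
}

# Sample a scalar observable every `spacing` MCS from the engine.
sample_chain <- function(conf, params, n_samples, spacing, extract,
                         wall = TRUE, z_max = Inf, equil = 1000) {
  conf <- run_mcs(conf, params, equil, wall = wall, z_max = z_max)$conformation
  out <- vector("list", n_samples)
  for (i in seq_len(n_samples)) {
    conf <- run_mcs(conf, params, spacing, wall = wall,
                    z_max = z_max)$conformation
    out[[i]] <- extract(conf)
  }
  unlist(out)
}

rotate_z <- function(conf, theta) {
  R <- matrix(c(cos(theta), -sin(theta), 0,
                sin(theta),  cos(theta), 0,
                0, 0, 1), 3, 3, byrow = TRUE)
  conf %*% t(R)
}

# Chain of independent uniformly random bond directions (not self-avoiding);
# the null case for correlation observables.
random_direction_chain <- function(n_bonds, bond_length = 0.7, height = 5) {
  u <- matrix(stats::rnorm(n_bonds * 3), n_bonds, 3)
  u <- u / sqrt(rowSums(u^2))
  pos <- rbind(c(0, 0, 0), apply(u * bond_length, 2, cumsum))
  pos[, 3] <- pos[, 3] - min(pos[, 3]) + height
  pos
}
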