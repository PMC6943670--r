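# small in-code fixtures shared across tests

# random molecule with the atom fields the field engine needs
random_molecule <- function(n_atoms, id = "rand", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  compound_structure(id, data.frame(
    element = sample(c("C", "N", "O", "H"), n_atoms, replace = TRUE),
    x = runif(n_atoms, -3, 3),
    y = runif(n_atoms, -3, 3),
    z = runif(n_atoms, -3, 3) + 0.1,   # avoid an accidental all-z-zero plane
    charge = runif(n_atoms, -0.5, 0.5),
    vdw_radius = runif(n_atoms, 1.2, 1.9)))
}

# random proper rotation matrix
random_rotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# independent brute-force field oracles: plain per-atom loops written against
# the stated formulas, no shared code with the field engine
oracle_comfa_steric <- function(s, points, probe, params) {
  sapply(seq_len(nrow(points)), function(g) {
    e <- 0
    for (i in seq_len(nrow(s$atoms))) {
      r <- sqrt(sum((points[g, ] - c(s$atoms$x[i], s$atoms$y[i],
                                     s$atoms$z[i]))^2))
      Rij <- s$atoms$vdw_radius[i] + probe$vdw_radius
      eps <- sqrt(params$atom_epsilon * probe$steric_epsilon)
      e <- e + if (r == 0) Inf else eps * ((Rij / r)^12 - 2 * (Rij / r)^6)
    }
    min(max(e, -params$energy_cutoff), params$energy_cutoff)
  })
}

oracle_comfa_electrostatic <- function(s, points, probe, params) {
  sapply(seq_len(nrow(points)), function(g) {
    e <- 0
    for (i in seq_len(nrow(s$atoms))) {
      r <- sqrt(sum((points[g, ] - c(s$atoms$x[i], s$atoms$y[i],
                                     s$atoms$z[i]))^2))
      eps_r <- if (params$dielectric_model == "distance_dependent") r else 1
      e <- e + params$coulomb_constant * s$atoms$charge[i] * probe$charge /
        (eps_r * r)
    }
    min(max(e, -params$energy_cutoff), params$energy_cutoff)
  })
}

oracle_comsia_steric <- function(s, points, params) {
  sapply(seq_len(nrow(points)), function(g) {
    a <- 0
    for (i in seq_len(nrow(s$atoms))) {
      r2 <- sum((points[g, ] - c(s$atoms$x[i], s$atoms$y[i],
                                 s$atoms$z[i]))^2)
      a <- a - (s$atoms$vdw_radius[i] / 1.70)^3 *
        exp(-params$attenuation_alpha * r2)
    }
    a
  })
}
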