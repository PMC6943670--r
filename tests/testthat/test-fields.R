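probe <- probe_spec()
params <- field_params()

test_that("the lattice covers every structure with closed bounds", {
  one <- compound_structure("o", data.frame(element = "C", x = 0, y = 0,
                                            z = 0))
  g <- build_grid(one, spacing = 2, margin = 4)
  pts <- grid_points(g)
  expect_true(all(apply(pts, 2, min) <= -4) && all(apply(pts, 2, max) >= 4))
  expect_equal(nrow(pts), prod(g$shape))
  # two structures: both bounding boxes inside
  a <- random_molecule(5, "a", seed = 1)
  b <- apply_transform(random_molecule(5, "b", seed = 2),
                       list(rotation = diag(3), translation = c(8, 0, 0)))
  g2 <- build_grid(list(a, b), spacing = 2, margin = 4)
  xyz <- rbind(coords(a), coords(b))
  lo <- grid_points(g2)
  expect_true(all(sweep(xyz, 2, apply(lo, 2, min), ">=")))
  expect_true(all(sweep(xyz, 2, apply(lo, 2, max), "<=")))
  # margin 0 with an atom exactly on a lattice node: node present
  node <- compound_structure("n", data.frame(element = c("C", "C"),
                                             x = c(0, 4), y = c(0, 2),
                                             z = c(0, 2)))
  g3 <- build_grid(node, spacing = 2, margin = 0)
  p3 <- grid_points(g3)
  expect_true(any(rowSums(abs(sweep(p3, 2, c(4, 2, 2)))) == 0))
  expect_true(any(rowSums(abs(p3)) == 0))
  expect_error(build_grid(list()), "no structures")
})

test_that("CoMFA steric energies follow the 6-12 form with clamping", {
  g <- build_grid(compound_structure("c", data.frame(element = "C", x = 0,
                                                     y = 0, z = 0)),
                  spacing = 2, margin = 4)
  atom <- compound_structure("c", data.frame(element = "C", x = 0, y = 0,
                                             z = 0, charge = 0))
  E <- comfa_steric_field(atom, g, probe, params)
  expect_true(all(E <= params$energy_cutoff))
  expect_true(all(abs(E) <= params$energy_cutoff))
  # point at r = R_ij sits at the potential minimum -eps_ij
  Rij <- 1.70 + probe$vdw_radius
  pt <- matrix(c(Rij, 0, 0), 1)
  e_min <- oracle_comfa_steric(atom, pt, probe, params)
  expect_equal(e_min, -sqrt(params$atom_epsilon * probe$steric_epsilon),
               tolerance = 1e-12)
  # deep inside the atom the clamp gives exactly +30
  atom_on_node <- compound_structure("c", data.frame(element = "C",
                                                     x = 0.01, y = 0, z = 0))
  E2 <- comfa_steric_field(atom_on_node, g, probe, params)
  expect_equal(max(E2), 30)
  expect_true(any(attr(E2, "buried")))
})

test_that("CoMFA electrostatics follow the Coulomb form and clamp rule", {
  base <- compound_structure("q", data.frame(element = "N", x = 0, y = 0,
                                             z = 0, charge = 1))
  g <- build_grid(base, spacing = 2, margin = 4)
  E <- comfa_electrostatic_field(base, g, probe, params)
  pts <- grid_points(g)
  # +1 e at 2 A from the +1 probe: 332.0636/(2*2) = 83.016, clamped to 30
  at2 <- which(abs(sqrt(rowSums(pts^2)) - 2) < 1e-9)
  expect_true(all(E[at2] == 30))
  # unclamped far point matches the closed form with eps(r) = r
  far <- which(abs(pts[, 1] - 4) < 1e-9 & pts[, 2] == 0 & pts[, 3] == 0)
  expect_equal(E[far], 332.0636 / 16, tolerance = 1e-10)
  # charge-sign antisymmetry away from the clamp
  neg <- base
  neg$atoms$charge <- -1
  En <- comfa_electrostatic_field(neg, g, probe, params)
  free <- abs(E) < params$energy_cutoff
  expect_equal(En[free], -E[free], tolerance = 1e-12)
  # all-zero charges give a zero field; missing charges error
  zero <- base; zero$atoms$charge <- 0
  expect_true(all(comfa_electrostatic_field(zero, g, probe, params) == 0))
  nochg <- base; nochg$atoms$charge <- NA_real_
  expect_error(comfa_electrostatic_field(nochg, g, probe, params),
               "charges")
})

test_that("CoMSIA similarity follows the Gaussian closed form", {
  atom <- compound_structure("s", data.frame(element = "C", x = 0, y = 0,
                                             z = 0, charge = 0.3))
  g <- build_grid(atom, spacing = 1, margin = 3)
  A <- comsia_field(atom, g, probe, params, kind = "S")
  pts <- grid_points(g)
  origin <- which(rowSums(abs(pts)) == 0)
  expect_equal(A[origin], -1)                       # w = 1 (carbon), r = 0
  at1 <- which(abs(sqrt(rowSums(pts^2)) - 1) < 1e-9)
  expect_equal(A[at1], rep(-exp(-0.3), length(at1)), tolerance = 1e-12)
  # additivity: two superposed unit atoms double the field everywhere
  two <- compound_structure("s2", data.frame(element = c("C", "C"),
                                             x = c(0, 0), y = c(0, 0),
                                             z = c(0, 0)))
  expect_equal(comsia_field(two, g, probe, params, kind = "S"), 2 * A,
               tolerance = 1e-12)
  # monotone non-increasing magnitude in alpha for positive weights
  a_small <- comsia_field(atom, g, probe, field_params(attenuation_alpha = 0.3),
                          kind = "S")
  a_large <- comsia_field(atom, g, probe, field_params(attenuation_alpha = 0.8),
                          kind = "S")
  expect_true(all(a_large >= a_small - 1e-12))      # less negative everywhere
  expect_error(comsia_field(atom, g, probe, params, kind = "Z"))
})

test_that("field values equal a naive per-atom brute-force sum", {
  for (seed in 1:3) {
    mol <- random_molecule(20, "bf", seed = seed)
    g <- build_grid(mol, spacing = 2, margin = 2)
    pts <- grid_points(g)
    mid <- pts[seq(1, nrow(pts), by = 17), , drop = FALSE]  # subsample
    idx <- seq(1, nrow(pts), by = 17)
    expect_equal(comfa_steric_field(mol, g, probe, params)[idx],
                 oracle_comfa_steric(mol, mid, probe, params),
                 tolerance = 1e-10)
    expect_equal(as.numeric(comfa_electrostatic_field(mol, g, probe,
                                                      params))[idx],
                 oracle_comfa_electrostatic(mol, mid, probe, params),
                 tolerance = 1e-10)
    expect_equal(comsia_field(mol, g, probe, params, kind = "S")[idx],
                 oracle_comsia_steric(mol, mid, params),
                 tolerance = 1e-10)
  }
})

test_that("fields are invariant under a joint translation of grid and molecules", {
  mol <- random_molecule(8, "t", seed = 13)
  g <- build_grid(mol, spacing = 2, margin = 3)
  shift <- c(5.25, -3.5, 1.75)
  mol2 <- apply_transform(mol, list(rotation = diag(3), translation = shift))
  g2 <- g
  g2$origin <- g$origin + shift
  expect_equal(comfa_steric_field(mol2, g2, probe, params),
               comfa_steric_field(mol, g, probe, params),
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(comsia_field(mol2, g2, probe, params, "H"),
               comsia_field(mol, g, probe, params, "H"), tolerance = 1e-10)
})

test_that("descriptor assembly masks flat columns and substitutes buried points", {
  set.seed(17)
  mols <- setNames(lapply(1:4, function(j) random_molecule(6, paste0("m", j))),
                   paste0("m", 1:4))
  fs <- compute_fields(mols, kinds = c("comfa.S", "comfa.E"))
  blk0 <- assemble_descriptor_matrix(fs, filtering_sigma = 0)
  expect_true(all(blk0$mask))                         # sigma 0 keeps all
  blk <- assemble_descriptor_matrix(fs, filtering_sigma = 2)
  sds <- apply(blk$values[, blk$mask, drop = FALSE], 2, sd)
  expect_true(all(sds > 0))
  # constant column is masked for any positive sigma: far corners are flat
  tiny <- assemble_descriptor_matrix(fs, filtering_sigma = 1e-9,
                                     block_scaling = FALSE)
  expect_true(any(!tiny$mask))
  # hand-computed mask on a 2-compound toy: stds known exactly
  toy <- fs
  toy$values <- list("comfa.S" = matrix(c(0, 1, 5, 5), 2, 2),
                     "comfa.E" = matrix(0, 2, 2))
  toy$kinds <- c("comfa.S", "comfa.E")
  toy$buried <- matrix(FALSE, 2, 2)
  toy$compound_ids <- c("m1", "m2")
  toy$grid <- build_grid(mols[[1]], spacing = 2, margin = 0)
  toy$grid$shape <- c(2, 1, 1)
  tb <- assemble_descriptor_matrix(toy, filtering_sigma = 0.5,
                                   block_scaling = FALSE)
  expect_equal(unname(tb$mask), c(TRUE, FALSE, FALSE, FALSE))
  # buried electrostatic values are replaced by the open-column training mean
  fs2 <- fs
  fs2$buried[1, 3] <- TRUE
  blk2 <- assemble_descriptor_matrix(fs2, filtering_sigma = 0,
                                     block_scaling = FALSE)
  ncol_s <- prod(fs$grid$shape)
  expect_equal(blk2$values[1, ncol_s + 3],
               mean(fs$values[["comfa.E"]][2:4, 3]))
})

test_that("block scaling equalises per-kind training variance", {
  set.seed(23)
  mols <- setNames(lapply(1:5, function(j) random_molecule(8, paste0("m", j))),
                   paste0("m", 1:5))
  fs <- compute_fields(mols, kinds = c("comsia.S", "comsia.E"))
  blk <- assemble_descriptor_matrix(fs, filtering_sigma = 1e-6,
                                    block_scaling = TRUE)
  kinds <- blk$columns$kind[blk$mask]
  X <- descriptor_matrix(blk)
  tot <- tapply(apply(X, 2, var), kinds, sum)
  expect_equal(unname(tot["comsia.S"]), unname(tot["comsia.E"]),
               tolerance = 1e-6)
})
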