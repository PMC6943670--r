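#' Probe atom specification
#'
#' The CoMFA/CoMSIA probe is an sp3 carbon-like atom: van der Waals radius
#' 1.52 Angstrom, net charge +1 e, and unit weights for the similarity
#' (hydrophobic, donor, acceptor) fields.
#'
#' @param vdw_radius Probe van der Waals radius (Angstrom).
#' @param charge Probe charge (e).
#' @param steric_epsilon Probe Lennard-Jones well depth (kcal/mol).
#' @param hydrophobic_weight,donor_weight,acceptor_weight Probe weights for
#'   the CoMSIA similarity fields.
#' @return List of class \code{probe_spec}.
#' @export
probe_spec <- function(vdw_radius = 1.52, charge = 1.0,
                       steric_epsilon = 0.107,
                       hydrophobic_weight = 1, donor_weight = 1,
                       acceptor_weight = 1) {
  stopifnot(vdw_radius > 0, steric_epsilon > 0)
  structure(list(vdw_radius = vdw_radius, charge = charge,
                 steric_epsilon = steric_epsilon,
                 hydrophobic_weight = hydrophobic_weight,
                 donor_weight = donor_weight,
                 acceptor_weight = acceptor_weight),
            class = "probe_spec")
}

#' Field computation parameters
#'
#' @param energy_cutoff Truncation for the CoMFA potentials (kcal/mol);
#'   steric energies are clamped to \code{+cutoff}, electrostatic to
#'   \code{+/-cutoff}.
#' @param attenuation_alpha Gaussian attenuation factor for CoMSIA
#'   similarity fields (1/Angstrom^2).
#' @param coulomb_constant Conversion constant in kcal A / (mol e^2).
#' @param dielectric_model \code{"distance_dependent"} (epsilon(r) = r, the
#'   SYBYL convention) or \code{"constant"} (epsilon = 1).
#' @param atom_epsilon Default atomic Lennard-Jones well depth (kcal/mol).
#' @return List of class \code{field_params}.
#' @export
field_params <- function(energy_cutoff = 30, attenuation_alpha = 0.3,
                         coulomb_constant = 332.0636,
                         dielectric_model = c("distance_dependent",
                                              "constant"),
                         atom_epsilon = 0.107) {
  dielectric_model <- match.arg(dielectric_model)
  stopifnot(energy_cutoff > 0, attenuation_alpha > 0)
  structure(list(energy_cutoff = energy_cutoff,
                 attenuation_alpha = attenuation_alpha,
                 coulomb_constant = coulomb_constant,
                 dielectric_model = dielectric_model,
                 atom_epsilon = atom_epsilon),
            class = "field_params")
}

#' Build a cubic lattice enclosing a set of aligned structures
#'
#' The grid is axis-aligned with the stated spacing; the origin is the
#' bounding-box minimum minus the margin floored to a multiple of the
#' spacing, and the extent covers the bounding-box maximum plus the margin
#' with closed bounds (an atom sitting exactly on a lattice node is inside).
#'
#' @param structures List of \code{compound_structure} objects (>= 1).
#' @param spacing Lattice edge length (Angstrom; default 2).
#' @param margin Padding added around the union bounding box (Angstrom).
#' @return List of class \code{grid_spec} with \code{origin}, \code{spacing},
#'   \code{shape} and \code{margin}.
#' @export
build_grid <- function(structures, spacing = 2.0, margin = 4.0) {
  if (inherits(structures, "compound_structure"))
    structures <- list(structures)
  if (!length(structures)) stop("no structures supplied")
  stopifnot(spacing > 0)
  xyz <- do.call(rbind, lapply(structures, coords))
  if (!all(is.finite(xyz))) stop("non-finite coordinates")
  lo <- apply(xyz, 2, min) - margin
  hi <- apply(xyz, 2, max) + margin
  origin <- spacing * floor(lo / spacing + 1e-9)
  shape <- pmax(2L, as.integer(ceiling((hi - origin) / spacing - 1e-9)) + 1L)
  structure(list(origin = origin, spacing = spacing, shape = shape,
                 margin = margin),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("grid_spec: %d x %d x %d nodes, spacing %g A, origin (%g, %g, %g)\n",
              x$shape[1], x$shape[2], x$shape[3], x$spacing,
              x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

#' Enumerate the lattice nodes of a grid
#'
#' Node order is fixed: z varies fastest, then y, then x.
#'
#' @param grid A \code{grid_spec}.
#' @return Matrix (n_points x 3) of node coordinates.
#' @export
grid_points <- function(grid) {
  ax <- lapply(1:3, function(k)
    grid$origin[k] + grid$spacing * (seq_len(grid$shape[k]) - 1L))
  g <- expand.grid(z = ax[[3]], y = ax[[2]], x = ax[[1]],
                   KEEP.OUT.ATTRS = FALSE)
  unname(as.matrix(g[, c("x", "y", "z")]))
}

# squared distances from every grid point (rows of G) to one atom position
.d2_to_atom <- function(G, pos) {
  (G[, 1] - pos[1])^2 + (G[, 2] - pos[2])^2 + (G[, 3] - pos[3])^2
}

#' CoMFA steric field (Lennard-Jones probe energies)
#'
#' Tripos 6-12 potential summed over atoms:
#' \code{E = sum eps_ij * ((R_ij/r)^12 - 2 (R_ij/r)^6)} with
#' \code{R_ij = r_atom + r_probe} and \code{eps_ij = sqrt(eps_atom *
#' eps_probe)}; the minimum of this form is \code{-eps_ij} at
#' \code{r = R_ij}.  Energies are clamped to the cutoff; a grid point
#' coinciding with an atom position gets \code{+cutoff}.
#'
#' @param s Aligned \code{compound_structure}.
#' @param grid A \code{grid_spec}.
#' @param probe A [probe_spec()].
#' @param params A [field_params()].
#' @return Vector of per-node energies (kcal/mol) in [grid_points()] order,
#'   with a logical attribute \code{"buried"} marking nodes at the positive
#'   clamp (sterically buried inside the molecule).
#' @export
comfa_steric_field <- function(s, grid, probe = probe_spec(),
                               params = field_params()) {
  G <- grid_points(grid)
  E <- numeric(nrow(G))
  a <- s$atoms
  for (i in seq_len(nrow(a))) {
    r2 <- .d2_to_atom(G, c(a$x[i], a$y[i], a$z[i]))
    Rij <- a$vdw_radius[i] + probe$vdw_radius
    eps <- sqrt(params$atom_epsilon * probe$steric_epsilon)
    s6 <- (Rij * Rij / r2)^3
    e <- eps * (s6 * s6 - 2 * s6)
    e[r2 == 0] <- Inf                      # atom exactly on the node
    E <- E + e
  }
  E <- pmin(pmax(E, -params$energy_cutoff), params$energy_cutoff)
  attr(E, "buried") <- E >= params$energy_cutoff
  E
}

#' CoMFA electrostatic field (Coulomb probe energies)
#'
#' \code{E = sum k * q_i * q_probe / (eps(r) * r)} with the
#' distance-dependent dielectric \code{eps(r) = r} by default.  Values are
#' clamped to \code{+/-cutoff}.  Substitution of sterically buried nodes by
#' the training-column mean happens at descriptor assembly
#' ([assemble_descriptor_matrix()]), where the steric field is available.
#'
#' @inheritParams comfa_steric_field
#' @return Vector of per-node energies (kcal/mol).
#' @export
comfa_electrostatic_field <- function(s, grid, probe = probe_spec(),
                                      params = field_params()) {
  if (!has_charges(s))
    stop("structure '", s$compound_id, "' has no partial charges")
  G <- grid_points(grid)
  E <- numeric(nrow(G))
  a <- s$atoms
  for (i in seq_len(nrow(a))) {
    if (a$charge[i] == 0) next
    r2 <- .d2_to_atom(G, c(a$x[i], a$y[i], a$z[i]))
    denom <- if (params$dielectric_model == "distance_dependent") r2
             else sqrt(r2)
    e <- params$coulomb_constant * a$charge[i] * probe$charge / denom
    e[r2 == 0] <- sign(a$charge[i] * probe$charge) * Inf
    E <- E + e
  }
  pmin(pmax(E, -params$energy_cutoff), params$energy_cutoff)
}

# per-atom weights for a CoMSIA field kind; steric weight is the cube of the
# vdW radius normalised to carbon (= 1 for a 1.70 A atom)
comsia_atom_weights <- function(s, kind) {
  a <- s$atoms
  switch(kind,
         S = (a$vdw_radius / 1.70)^3,
         E = {
           if (!has_charges(s))
             stop("structure '", s$compound_id, "' has no partial charges")
           a$charge
         },
         H = a$hydrophobic,
         D = as.numeric(a$is_donor),
         A = as.numeric(a$is_acceptor),
         stop("unknown CoMSIA field kind '", kind, "'"))
}

comsia_probe_weight <- function(probe, kind) {
  switch(kind, S = 1, E = probe$charge, H = probe$hydrophobic_weight,
         D = probe$donor_weight, A = probe$acceptor_weight)
}

#' CoMSIA similarity field
#'
#' Gaussian-attenuated similarity between the probe and each atom,
#' \code{A(point) = -sum w_probe * w_i * exp(-alpha * r_i^2)}; no energy
#' cutoff is applied (the Gaussian makes the field everywhere finite).
#'
#' @inheritParams comfa_steric_field
#' @param kind One of \code{"S"} (steric), \code{"E"} (electrostatic),
#'   \code{"H"} (hydrophobic), \code{"D"} (H-bond donor), \code{"A"}
#'   (H-bond acceptor).
#' @return Vector of per-node similarity values.
#' @export
comsia_field <- function(s, grid, probe = probe_spec(),
                         params = field_params(),
                         kind = c("S", "E", "H", "A", "D")) {
  kind <- match.arg(kind)
  w <- comsia_atom_weights(s, kind)
  wp <- comsia_probe_weight(probe, kind)
  G <- grid_points(grid)
  A <- numeric(nrow(G))
  a <- s$atoms
  for (i in seq_len(nrow(a))) {
    if (w[i] == 0) next
    r2 <- .d2_to_atom(G, c(a$x[i], a$y[i], a$z[i]))
    A <- A - wp * w[i] * exp(-params$attenuation_alpha * r2)
  }
  A
}

#' Compute a set of molecular fields for aligned compounds
#'
#' @param structures Named list of aligned \code{compound_structure}s.
#' @param grid A \code{grid_spec}; default built from the structures.
#' @param kinds Character vector of field kinds, each
#'   \code{"comfa.S"}, \code{"comfa.E"}, or \code{"comsia.X"} with X in
#'   S, E, H, A, D (e.g. \code{c("comfa.S", "comfa.E")}).
#' @param probe A [probe_spec()].
#' @param params A [field_params()].
#' @return List of class \code{field_set}: per-kind matrices
#'   (compounds x nodes), the grid, and a buried-node indicator matrix when
#'   the CoMFA steric field is among the kinds.
#' @export
compute_fields <- function(structures, grid = build_grid(structures),
                           kinds = c("comfa.S", "comfa.E"),
                           probe = probe_spec(), params = field_params()) {
  ok <- grepl("^comfa\\.[SE]$|^comsia\\.[SEHAD]$", kinds)
  if (any(!ok)) stop("unknown field kinds: ", paste(kinds[!ok], collapse = ", "))
  n <- length(structures)
  npt <- prod(grid$shape)
  values <- lapply(kinds, function(k) matrix(0, n, npt))
  names(values) <- kinds
  buried <- NULL
  for (j in seq_along(structures)) {
    s <- structures[[j]]
    for (k in kinds) {
      part <- strsplit(k, ".", fixed = TRUE)[[1]]
      v <- if (part[1] == "comfa") {
        if (part[2] == "S") comfa_steric_field(s, grid, probe, params)
        else comfa_electrostatic_field(s, grid, probe, params)
      } else {
        comsia_field(s, grid, probe, params, part[2])
      }
      if (k == "comfa.S") {
        if (is.null(buried)) buried <- matrix(FALSE, n, npt)
        buried[j, ] <- attr(v, "buried")
      }
      values[[k]][j, ] <- as.numeric(v)
    }
  }
  for (k in kinds) rownames(values[[k]]) <- names(structures)
  structure(list(values = values, grid = grid, kinds = kinds,
                 buried = buried, compound_ids = names(structures)),
            class = "field_set")
}

#' Assemble the PLS descriptor matrix from computed fields
#'
#' Concatenates the per-kind field matrices into one compounds x columns
#' block (column order: kind blocks in the order given, nodes within a kind
#' in [grid_points()] order, i.e. z fastest, then y, then x).  Electrostatic
#' CoMFA values at sterically buried nodes are replaced by the column mean
#' over the non-buried training compounds (SYBYL behaviour).  Columns whose
#' standard deviation across the training compounds is below
#' \code{filtering_sigma} are masked.  With \code{block_scaling} each kind
#' block is scaled to unit total training variance (CoMFA-STD convention).
#'
#' @param fields A \code{field_set} from [compute_fields()].
#' @param train_ids Compound ids that constitute the training set (defaults
#'   to all compounds); filtering, buried-node means and scaling use these
#'   rows only.
#' @param filtering_sigma Minimum column standard deviation (same units as
#'   the field); 0 disables filtering.
#' @param block_scaling Logical; scale each field kind to equal total
#'   variance.
#' @return Object of class \code{field_block} with the full value matrix,
#'   the kept-column mask, per-column metadata (kind, x, y, z) and the grid.
#' @export
assemble_descriptor_matrix <- function(fields, train_ids = NULL,
                                       filtering_sigma = 2.0,
                                       block_scaling = TRUE) {
  stopifnot(inherits(fields, "field_set"))
  ids <- fields$compound_ids
  if (is.null(train_ids)) train_ids <- ids
  tr <- match(train_ids, ids)
  if (any(is.na(tr))) stop("train_ids not present in field set")
  G <- grid_points(fields$grid)
  vals <- fields$values
  # buried-node substitution for the CoMFA electrostatic block
  if ("comfa.E" %in% fields$kinds && !is.null(fields$buried)) {
    E <- vals[["comfa.E"]]
    B <- fields$buried
    for (g in which(colSums(B) > 0)) {
      open_tr <- tr[!B[tr, g]]
      m <- if (length(open_tr)) mean(E[open_tr, g]) else 0
      E[B[, g], g] <- m
    }
    vals[["comfa.E"]] <- E
  }
  scale_factors <- setNames(rep(1, length(fields$kinds)), fields$kinds)
  X <- NULL; meta <- NULL; mask <- NULL
  for (k in fields$kinds) {
    V <- vals[[k]]
    sds <- apply(V[tr, , drop = FALSE], 2, stats::sd)
    keep <- sds >= filtering_sigma | filtering_sigma <= 0
    if (block_scaling) {
      tot <- sum(sds[keep]^2)
      if (tot > 0) {
        scale_factors[k] <- 1 / sqrt(tot)
        V <- V * scale_factors[k]
      }
    }
    X <- cbind(X, V)
    mask <- c(mask, keep)
    meta <- rbind(meta, data.frame(kind = k, x = G[, 1], y = G[, 2],
                                   z = G[, 3]))
  }
  if (any(!is.finite(X))) stop("non-finite descriptor values after assembly")
  rownames(X) <- ids
  colnames(X) <- sprintf("%s_%d", meta$kind,
                         sequence(rle(meta$kind)$lengths))
  structure(list(values = X, mask = mask, columns = meta,
                 grid = fields$grid, kinds = fields$kinds,
                 compound_ids = ids, train_ids = train_ids,
                 filtering_sigma = filtering_sigma,
                 block_scaling = block_scaling,
                 scale_factors = scale_factors),
            class = "field_block")
}

#' Retained descriptor matrix of a field block
#' @param block A \code{field_block}.
#' @return Matrix of kept columns (compounds x retained nodes*kinds).
#' @export
descriptor_matrix <- function(block) {
  stopifnot(inherits(block, "field_block"))
  block$values[, block$mask, drop = FALSE]
}

#' @export
print.field_block <- function(x, ...) {
  cat(sprintf("field_block: %d compounds x %d columns (%d retained), kinds: %s\n",
              nrow(x$values), ncol(x$values), sum(x$mask),
              paste(x$kinds, collapse = ", ")))
  invisible(x)
}

#' Export one field (or contour values) as an OpenDX volumetric file
#'
#' Writes a minimal OpenDX scalar field (regular grid, z fastest) readable
#' by PyMOL/VMD.
#'
#' @param values Numeric vector in [grid_points()] order.
#' @param grid The \code{grid_spec} the values live on.
#' @param path Output path.
#' @export
write_dx <- function(values, grid, path) {
  n <- grid$shape
  if (length(values) != prod(n)) stop("value count does not match grid")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("object 1 class gridpositions counts %d %d %d", n[1], n[2], n[3]),
    sprintf("origin %g %g %g", grid$origin[1], grid$origin[2], grid$origin[3]),
    sprintf("delta %g 0 0", grid$spacing),
    sprintf("delta 0 %g 0", grid$spacing),
    sprintf("delta 0 0 %g", grid$spacing),
    sprintf("object 2 class gridconnections counts %d %d %d",
            n[1], n[2], n[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows",
            length(values))), con)
  full <- length(values) %/% 3L
  if (full > 0) {
    m <- matrix(values[seq_len(full * 3L)], ncol = 3, byrow = TRUE)
    writeLines(sprintf("%g %g %g", m[, 1], m[, 2], m[, 3]), con)
  }
  rest <- values[seq_len(length(values)) > full * 3L]
  if (length(rest))
    writeLines(paste(sprintf("%g", rest), collapse = " "), con)
  writeLines('attribute "dep" string "positions"', con)
  invisible(path)
}
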