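# Bondi van der Waals radii (Angstrom); unlisted elements fall back to carbon.
.vdw_radii <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, F = 1.47, P = 1.80,
                S = 1.80, Cl = 1.75, Br = 1.85, I = 1.98)

vdw_radius_for <- function(element) {
  r <- .vdw_radii[element]
  r[is.na(r)] <- 1.70
  unname(r)
}

# Element rule for CoMSIA hydrophobic weights: carbon and halogens are
# hydrophobic, N/O polar, H and S neutral.  Configurable per atom by passing
# a 'hydrophobic' column to compound_structure().
hydrophobic_weight_for <- function(element) {
  w <- rep(0, length(element))
  w[element %in% "C"] <- 1
  w[element %in% c("F", "Cl", "Br", "I")] <- 0.5
  w[element %in% c("N", "O")] <- -1
  w
}

# H-bond donor/acceptor flags by element/valence rule: N and O are acceptors;
# an N or O with a covalently bound hydrogen (within 1.2 A, when explicit
# hydrogens are present) is a donor.
derive_donor_acceptor <- function(atoms) {
  el <- atoms$element
  acceptor <- el %in% c("N", "O")
  donor <- rep(FALSE, nrow(atoms))
  h <- which(el == "H")
  if (length(h)) {
    xyz <- as.matrix(atoms[, c("x", "y", "z")])
    for (i in which(acceptor)) {
      d2 <- colSums((t(xyz[h, , drop = FALSE]) - xyz[i, ])^2)
      if (any(d2 < 1.2^2)) donor[i] <- TRUE
    }
  }
  list(donor = donor, acceptor = acceptor)
}

#' Construct an aligned conformer structure
#'
#' Holds one conformer's atoms (coordinates, partial charges, van der Waals
#' radii and the per-atom CoMSIA weights) together with the indices of the
#' common-skeleton atoms used as the alignment anchor.
#'
#' @param compound_id Identifier token.
#' @param atoms Data frame with columns \code{element}, \code{x}, \code{y},
#'   \code{z}; optional \code{charge}, \code{vdw_radius},
#'   \code{hydrophobic}, \code{is_donor}, \code{is_acceptor}.  Missing
#'   radii/weights/flags are derived by element rule.
#' @param skeleton Integer indices of the skeleton atoms (alignment anchor);
#'   may be empty when no alignment is intended.
#' @return Object of class \code{compound_structure}.
#' @export
compound_structure <- function(compound_id, atoms, skeleton = integer()) {
  stopifnot(is.data.frame(atoms), nrow(atoms) >= 1)
  need <- c("element", "x", "y", "z")
  if (!all(need %in% names(atoms)))
    stop("atoms must have columns: ", paste(need, collapse = ", "))
  atoms$element <- as.character(atoms$element)
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(xyz))) stop("non-finite atom coordinates")
  if (is.null(atoms$charge)) atoms$charge <- NA_real_
  if (is.null(atoms$vdw_radius)) atoms$vdw_radius <- vdw_radius_for(atoms$element)
  if (any(!is.finite(atoms$vdw_radius)) || any(atoms$vdw_radius <= 0))
    stop("van der Waals radii must be positive")
  if (is.null(atoms$hydrophobic))
    atoms$hydrophobic <- hydrophobic_weight_for(atoms$element)
  if (is.null(atoms$is_donor) || is.null(atoms$is_acceptor)) {
    da <- derive_donor_acceptor(atoms)
    if (is.null(atoms$is_donor)) atoms$is_donor <- da$donor
    if (is.null(atoms$is_acceptor)) atoms$is_acceptor <- da$acceptor
  }
  skeleton <- as.integer(skeleton)
  if (length(skeleton)) {
    if (anyDuplicated(skeleton) || any(skeleton < 1) ||
        any(skeleton > nrow(atoms)))
      stop("skeleton indices must be distinct and within 1..n_atoms")
  }
  structure(list(compound_id = as.character(compound_id),
                 atoms = atoms, skeleton = skeleton),
            class = "compound_structure")
}

#' @export
print.compound_structure <- function(x, ...) {
  cat(sprintf("compound_structure '%s': %d atoms, %d skeleton atoms\n",
              x$compound_id, nrow(x$atoms), length(x$skeleton)))
  invisible(x)
}

#' Atom coordinates of a structure as a matrix
#' @param s A \code{compound_structure}.
#' @return Numeric matrix with one row per atom and columns x, y, z.
#' @export
coords <- function(s) {
  stopifnot(inherits(s, "compound_structure"))
  unname(as.matrix(s$atoms[, c("x", "y", "z")]))
}

has_charges <- function(s) all(!is.na(s$atoms$charge))

.structure_list <- function(structures) {
  ids <- vapply(structures, `[[`, "", "compound_id")
  if (anyDuplicated(ids))
    stop("duplicate compound ids in file: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  setNames(structures, ids)
}

.check_3d <- function(xyz, id) {
  if (nrow(xyz) > 1 && all(xyz[, 3] == 0) && all(xyz[, 2] == 0))
    stop("structure '", id, "' has 1D coordinates only")
  if (nrow(xyz) > 2 && all(xyz[, 3] == 0))
    stop("structure '", id, "' has 2D coordinates only (all z = 0)")
  invisible(TRUE)
}

# fixed-format fallback for molecules ChemmineR cannot represent (it drops
# the coordinates of bond-free single-atom records): V2000 columns are
# positional, x/y/z in 1-30, element in 32-34
.parse_v2000_chunk <- function(chunk) {
  natoms <- as.integer(substr(chunk[4], 1, 3))
  if (is.na(natoms) || natoms < 1 || length(chunk) < 4 + natoms)
    stop("unparseable SDF molecule record '", trimws(chunk[1]), "'")
  al <- chunk[5:(4 + natoms)]
  atoms <- data.frame(
    element = trimws(substr(al, 32, 34)),
    x = as.numeric(substr(al, 1, 10)),
    y = as.numeric(substr(al, 11, 20)),
    z = as.numeric(substr(al, 21, 30)))
  fields <- list()
  tags <- grep("^>", chunk)
  for (t in tags) {
    nm <- sub("^>.*<([^>]+)>.*$", "\\1", chunk[t])
    val <- character()
    j <- t + 1
    while (j <= length(chunk) && nzchar(trimws(chunk[j])) &&
           !grepl("^(>|\\$\\$\\$\\$)", chunk[j])) {
      val <- c(val, chunk[j]); j <- j + 1
    }
    fields[[nm]] <- paste(val, collapse = " ")
  }
  list(atoms = atoms, fields = fields)
}

.apply_partial_charges <- function(atoms, value, id) {
  q <- suppressWarnings(as.numeric(strsplit(trimws(value),
                                            "[[:space:]]+")[[1]]))
  if (length(q) != nrow(atoms) || any(is.na(q)))
    stop("malformed PARTIAL_CHARGES field for '", id, "'")
  atoms$charge <- q
  atoms
}

read_sdf_structures <- function(path) {
  lines <- readLines(path)
  ends <- grep("^\\$\\$\\$\\$", lines)
  if (!length(ends)) stop("not an SDF file (no $$$$ record terminator)")
  starts <- c(1L, head(ends, -1) + 1L)
  sdfset <- suppressWarnings(ChemmineR::read.SDFset(path))
  ids <- ChemmineR::sdfid(sdfset)
  blocks <- ChemmineR::atomblock(sdfset)
  datas <- ChemmineR::datablock(sdfset)
  if (length(blocks) != length(starts))
    stop("SDF molecule count mismatch while parsing ", path)
  structures <- vector("list", length(blocks))
  for (i in seq_along(blocks)) {
    chunk <- lines[starts[i]:ends[i]]
    natoms <- as.integer(substr(chunk[4], 1, 3))
    ab <- blocks[[i]]
    id <- if (nzchar(trimws(chunk[1]))) trimws(chunk[1]) else ids[i]
    if (all(c("C1", "C2", "C3") %in% colnames(ab)) &&
        nrow(ab) == natoms) {
      atoms <- data.frame(element = sub("_[0-9]+$", "", rownames(ab)),
                          x = ab[, "C1"], y = ab[, "C2"], z = ab[, "C3"],
                          row.names = NULL)
      db <- datas[[i]]
      if (!is.null(db) && "PARTIAL_CHARGES" %in% names(db))
        atoms <- .apply_partial_charges(atoms, db[["PARTIAL_CHARGES"]], id)
    } else {
      parsed <- .parse_v2000_chunk(chunk)
      atoms <- parsed$atoms
      if ("PARTIAL_CHARGES" %in% names(parsed$fields))
        atoms <- .apply_partial_charges(atoms,
                                        parsed$fields$PARTIAL_CHARGES, id)
    }
    .check_3d(as.matrix(atoms[, c("x", "y", "z")]), id)
    structures[[i]] <- compound_structure(id, atoms)
  }
  structures
}

read_mol2_structures <- function(path) {
  lines <- readLines(path)
  starts <- grep("^@<TRIPOS>MOLECULE", lines)
  if (!length(starts)) stop("not a MOL2 file (no @<TRIPOS>MOLECULE record)")
  bounds <- c(starts, length(lines) + 1L)
  structures <- vector("list", length(starts))
  for (i in seq_along(starts)) {
    chunk <- lines[bounds[i]:(bounds[i + 1L] - 1L)]
    # bio3d cannot parse a BOND header with no bond rows (OpenBabel emits
    # one for bond-free molecules); drop such empty sections
    bnd <- which(grepl("^@<TRIPOS>BOND", chunk))
    if (length(bnd)) {
      rest <- if (bnd[1] < length(chunk))
        chunk[(bnd[1] + 1):length(chunk)] else character()
      rest <- rest[seq_len(match(TRUE, grepl("^@<TRIPOS>", rest),
                                 nomatch = length(rest) + 1L) - 1L)]
      if (!any(nzchar(trimws(rest)))) chunk <- chunk[-bnd[1]]
    }
    tmp <- tempfile(fileext = ".mol2")
    on.exit(unlink(tmp), add = TRUE)
    writeLines(chunk, tmp)
    m <- suppressWarnings(bio3d::read.mol2(tmp))
    id <- trimws(chunk[2])
    a <- m$atom
    el <- sub("\\..*$", "", a$elety)
    atoms <- data.frame(element = el, x = a$x, y = a$y, z = a$z,
                        charge = suppressWarnings(as.numeric(a$charge)))
    if (all(is.na(atoms$charge))) atoms$charge <- NA_real_
    .check_3d(as.matrix(atoms[, c("x", "y", "z")]), id)
    structures[[i]] <- compound_structure(id, atoms)
  }
  structures
}

#' Read 3D structures from SDF or MOL2
#'
#' SDF files are parsed with ChemmineR; partial charges are taken from a
#' \code{PARTIAL_CHARGES} data field (whitespace-separated, one value per
#' atom) when present, else flagged missing.  MOL2 files are parsed with
#' bio3d and carry charges natively.  With \code{charges = "gasteiger"}
#' missing charges are assigned with the Gasteiger method through OpenBabel
#' (ChemmineOB).
#'
#' @param path File path.
#' @param format \code{"sdf"} or \code{"mol2"}; default guessed from the
#'   file extension.
#' @param charges \code{"file"} (use what the file provides) or
#'   \code{"gasteiger"}.
#' @return Named list of [compound_structure()] objects.
#' @export
load_structures <- function(path,
                            format = c("auto", "sdf", "mol2"),
                            charges = c("file", "gasteiger")) {
  format <- match.arg(format)
  charges <- match.arg(charges)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, sdf = "sdf", sd = "sdf", mol2 = "mol2",
                     stop("cannot guess format from extension '", ext,
                          "'; pass format="))
  }
  structures <- switch(format,
                       sdf = read_sdf_structures(path),
                       mol2 = read_mol2_structures(path))
  if (charges == "gasteiger") {
    q <- gasteiger_charges(path, format)
    if (length(q) != length(structures))
      stop("charge assignment returned ", length(q),
           " molecules for ", length(structures), " structures")
    for (i in seq_along(structures)) {
      if (length(q[[i]]) != nrow(structures[[i]]$atoms))
        stop("charge assignment atom-count mismatch for molecule ", i)
      structures[[i]]$atoms$charge <- q[[i]]
    }
  }
  .structure_list(structures)
}

# Gasteiger partial charges via OpenBabel: convert to MOL2 (which carries a
# charge column) with explicit Gasteiger assignment and read the charges
# back.  The obabel binary is preferred; ChemmineOB::convertFormat is the
# in-process fallback.
gasteiger_charges <- function(path, format) {
  tmp <- tempfile(fileext = ".mol2")
  on.exit(unlink(tmp), add = TRUE)
  if (nzchar(Sys.which("obabel"))) {
    system2("obabel", c(shQuote(path), "-omol2", "-O", shQuote(tmp),
                        "--partialcharge", "gasteiger"),
            stdout = FALSE, stderr = FALSE)
    if (!file.exists(tmp) || !length(readLines(tmp, n = 1)))
      stop("obabel conversion produced no output for ", path)
  } else if (requireNamespace("ChemmineOB", quietly = TRUE)) {
    txt <- paste(readLines(path), collapse = "\n")
    out <- ChemmineOB::convertFormat(toupper(format), "MOL2",
                                     paste0(txt, "\n"))
    writeLines(out, tmp)
  } else {
    stop("Gasteiger charge assignment needs the obabel binary or ChemmineOB")
  }
  lapply(read_mol2_structures(tmp), function(s) s$atoms$charge)
}

#' Write structures to an SDF file
#'
#' Emits a minimal V2000 SDF (atoms only, no bond block) with partial
#' charges stored in a \code{PARTIAL_CHARGES} data field, the dialect
#' [load_structures()] reads back.
#'
#' @param structures List of [compound_structure()] objects.
#' @param path Output path.
#' @export
write_structures <- function(structures, path) {
  if (inherits(structures, "compound_structure")) structures <- list(structures)
  con <- file(path, "w")
  on.exit(close(con))
  for (s in structures) {
    a <- s$atoms
    lines <- c(s$compound_id, "  qsar3d", "",
               sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                       nrow(a), 0L))
    lines <- c(lines, sprintf(
      "%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
      a$x, a$y, a$z, a$element))
    lines <- c(lines, "M  END")
    if (all(!is.na(a$charge)))
      lines <- c(lines, "> <PARTIAL_CHARGES>",
                 paste(sprintf("%.6f", a$charge), collapse = " "), "")
    lines <- c(lines, "$$$$")
    writeLines(lines, con)
  }
  invisible(path)
}
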