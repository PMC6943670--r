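#' Kabsch rigid-body superposition
#'
#' Finds the proper rotation \code{R} and translation \code{t} minimizing the
#' RMSD of the moved point set \code{Q} onto the reference \code{P} over all
#' rigid transforms (SVD solution with a reflection guard so that
#' \code{det(R) = +1} always; mirror images are never matched by an improper
#' rotation).
#'
#' @param P Reference points, n x 3 matrix (n >= 3, not all collinear).
#' @param Q Moving points, n x 3 matrix in one-to-one correspondence with
#'   \code{P}.
#' @return List with \code{rotation} (3 x 3), \code{translation} (length 3)
#'   and \code{rmsd} (Angstrom) after applying the transform to \code{Q}.
#'   The transform maps a row vector x to \code{R \%*\% x + t}.
#' @export
kabsch_superpose <- function(P, Q) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  if (!all(dim(P) == dim(Q))) stop("point sets differ in size")
  if (nrow(P) < 3 || ncol(P) != 3)
    stop("need at least 3 points with 3 coordinates each")
  if (!all(is.finite(P)) || !all(is.finite(Q))) stop("non-finite points")
  cP <- colMeans(P); cQ <- colMeans(Q)
  Pc <- sweep(P, 2, cP); Qc <- sweep(Q, 2, cQ)
  # degenerate (coincident or collinear) sets have covariance rank < 2
  if (qr(Pc)$rank < 2 || qr(Qc)$rank < 2)
    stop("degenerate point set (collinear or coincident points)")
  H <- crossprod(Qc, Pc)            # 3x3 covariance
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  t <- cP - as.vector(R %*% cQ)
  moved <- sweep(Q %*% t(R), 2, t, "+")
  rmsd <- sqrt(mean(rowSums((moved - P)^2)))
  list(rotation = R, translation = t, rmsd = rmsd)
}

#' Apply a rigid transform to a structure or coordinate matrix
#'
#' @param x A \code{compound_structure} or an n x 3 matrix.
#' @param transform List with \code{rotation} and \code{translation} as
#'   returned by [kabsch_superpose()].
#' @return Object of the same type with transformed coordinates.
#' @export
apply_transform <- function(x, transform) {
  R <- transform$rotation; t <- transform$translation
  if (inherits(x, "compound_structure")) {
    xyz <- sweep(coords(x) %*% t(R), 2, t, "+")
    x$atoms$x <- xyz[, 1]; x$atoms$y <- xyz[, 2]; x$atoms$z <- xyz[, 3]
    x
  } else {
    sweep(as.matrix(x) %*% t(R), 2, t, "+")
  }
}

#' Superpose a compound onto a template by its common skeleton
#'
#' Fits the rigid transform on the skeleton correspondence only (all skeleton
#' atoms weighted equally) and applies it to every atom of the target.  The
#' input is not modified.
#'
#' @param target,template \code{compound_structure} objects.
#' @param correspondence Two-column matrix/data frame of
#'   (template_atom_index, target_atom_index) pairs; defaults to pairing the
#'   two structures' skeleton index lists in order.
#' @return The aligned copy of \code{target}, with the skeleton RMSD in
#'   attribute \code{"rmsd"}.
#' @export
align_to_template <- function(target, template, correspondence = NULL) {
  stopifnot(inherits(target, "compound_structure"),
            inherits(template, "compound_structure"))
  if (is.null(correspondence)) {
    if (length(template$skeleton) < 3 || length(target$skeleton) < 3)
      stop("need >= 3 skeleton atoms (or an explicit correspondence)")
    if (length(template$skeleton) != length(target$skeleton))
      stop("skeleton sizes differ; supply an explicit correspondence")
    correspondence <- cbind(template$skeleton, target$skeleton)
  }
  correspondence <- as.matrix(correspondence)
  if (ncol(correspondence) != 2 || nrow(correspondence) < 3)
    stop("correspondence must be >= 3 (template, target) index pairs")
  ti <- correspondence[, 1]; gi <- correspondence[, 2]
  if (anyDuplicated(ti) || anyDuplicated(gi) ||
      any(ti < 1) || any(ti > nrow(template$atoms)) ||
      any(gi < 1) || any(gi > nrow(target$atoms)))
    stop("invalid correspondence indices")
  fit <- kabsch_superpose(coords(template)[ti, , drop = FALSE],
                          coords(target)[gi, , drop = FALSE])
  out <- apply_transform(target, fit)
  attr(out, "rmsd") <- fit$rmsd
  out
}

#' Align a set of compounds onto a template structure
#'
#' @param structures Named list of \code{compound_structure} objects.
#' @param template The template structure (e.g. the most active compound).
#' @param correspondences Optional named list of per-compound correspondence
#'   matrices; default uses each structure's skeleton indices.
#' @return Named list of aligned structures; per-compound skeleton RMSDs in
#'   attribute \code{"rmsd"}.
#' @export
align_set <- function(structures, template, correspondences = NULL) {
  out <- lapply(names(structures), function(id) {
    corr <- if (!is.null(correspondences)) correspondences[[id]] else NULL
    align_to_template(structures[[id]], template, corr)
  })
  names(out) <- names(structures)
  rmsd <- vapply(out, attr, 0, "rmsd")
  attr(out, "rmsd") <- rmsd
  out
}

#' Read a skeleton correspondence file
#'
#' Two-column delimited text of 0-based (template_index, target_index) pairs.
#'
#' @param path File path.
#' @return Two-column integer matrix of 1-based index pairs.
#' @export
read_correspondence <- function(path) {
  m <- as.matrix(utils::read.table(path, header = FALSE))
  if (ncol(m) != 2) stop("correspondence file must have two columns")
  m + 1L
}
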