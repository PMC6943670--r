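#' Specification for the synthetic compound-set generator
#'
#' Describes a set of pseudo-compounds sharing a rigid common skeleton, with
#' per-compound decoration atoms, whose activity is a linear function of a
#' few spatial field regions plus Gaussian noise -- the statistical structure
#' the field-PLS analysis assumes.
#'
#' @param n_compounds Number of compounds (>= 4; default 40).
#' @param n_atoms_range Min/max total atoms per compound (must be >=
#'   \code{skeleton_size}).
#' @param skeleton_size Number of shared skeleton atoms (>= 3).
#' @param n_active_regions Number of activity-determining spatial regions.
#' @param planted_weights Region weights (length \code{n_active_regions}).
#' @param intercept Baseline activity (pIC50-like scale).
#' @param noise_sigma Gaussian activity noise (pIC50 units, >= 0).
#' @param pose_jitter Length-2 vector: max random rotation (degrees) and
#'   max |translation| per axis (Angstrom) applied to each compound's pose,
#'   so that downstream alignment is exercised.
#' @param seed Mandatory RNG seed.
#' @return List of class \code{synthetic_spec}.
#' @export
synthetic_spec <- function(n_compounds = 40, n_atoms_range = c(10, 16),
                           skeleton_size = 6, n_active_regions = 4,
                           planted_weights = c(1.5, -1.0, 0.8, -0.6),
                           intercept = 6, noise_sigma = 0.1,
                           pose_jitter = c(180, 5), seed) {
  if (missing(seed)) stop("a seed is mandatory")
  if (n_compounds < 4) stop("n_compounds must be >= 4")
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  if (skeleton_size < 3) stop("skeleton_size must be >= 3")
  if (length(n_atoms_range) != 2 || n_atoms_range[1] > n_atoms_range[2] ||
      n_atoms_range[1] < skeleton_size)
    stop("n_atoms_range must be (min, max) with min >= skeleton_size")
  if (length(planted_weights) != n_active_regions)
    stop("planted_weights must have length n_active_regions")
  if (length(pose_jitter) != 2 || any(pose_jitter < 0))
    stop("pose_jitter must be (rotation_deg, translation_A), both >= 0")
  structure(list(n_compounds = n_compounds, n_atoms_range = n_atoms_range,
                 skeleton_size = skeleton_size,
                 n_active_regions = n_active_regions,
                 planted_weights = planted_weights, intercept = intercept,
                 noise_sigma = noise_sigma, pose_jitter = pose_jitter,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# deterministic skeleton geometry: points on a short helix (never collinear)
skeleton_coords <- function(m) {
  k <- seq_len(m) - 1
  cbind(x = 1.4 * cos(2 * pi * k / 6),
        y = 1.4 * sin(2 * pi * k / 6),
        z = 0.35 * k)
}

rotation_about_axis <- function(axis, angle_rad) {
  u <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0),
              3, 3, byrow = TRUE)
  diag(3) + sin(angle_rad) * K + (1 - cos(angle_rad)) * (K %*% K)
}

random_unit_vector <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v^2))
}

# the per-region local field summary the activities are planted on: the
# (negated) CoMSIA steric similarity of the molecule at the region centre
steric_summary <- function(atoms, center, alpha = 0.3) {
  d2 <- (atoms$x - center[1])^2 + (atoms$y - center[2])^2 +
    (atoms$z - center[3])^2
  sum((atoms$vdw_radius / 1.70)^3 * exp(-alpha * d2))
}

#' Generate a synthetic compound set with planted regional activity weights
#'
#' Every compound shares a rigid skeleton (identical local geometry) and
#' carries random decoration atoms (positions near random skeleton atoms,
#' charges in [-0.5, 0.5] e, radii in [1.2, 1.9] Angstrom).  Activity is
#' \code{intercept + sum_k w_k * (S_k - mean(S_k)) + N(0, sigma)}, where
#' \code{S_k} is the CoMSIA-steric field summary of the compound at region
#' centre k in the canonical (skeleton) frame -- so a field-PLS model is the
#' correct model class for the data.  Each compound is then randomly
#' rotated/translated (pose jitter) to exercise the alignment stage.
#'
#' @param spec A [synthetic_spec()].
#' @return List with \code{dataset} (a [qsar_dataset()] whose structures are
#'   in jittered poses) and \code{truth} (region centres, weights, the
#'   field-summary matrix, canonical-pose structures, and the noise-free
#'   activities).
#' @export
generate_pseudo_compounds <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  m <- spec$skeleton_size
  skel <- skeleton_coords(m)
  centroid <- colMeans(skel)
  centers <- matrix(NA_real_, 0, 3)
  tries <- 0
  while (nrow(centers) < spec$n_active_regions) {
    tries <- tries + 1
    if (tries > 5000)
      stop("infeasible geometry: cannot place ", spec$n_active_regions,
           " mutually separated region centres")
    cand <- centroid + stats::runif(1, 2.5, 4.5) * random_unit_vector()
    if (nrow(centers) == 0 ||
        min(sqrt(rowSums(sweep(centers, 2, cand)^2))) >= 3)
      centers <- rbind(centers, cand)
  }
  rownames(centers) <- NULL
  canonical <- vector("list", spec$n_compounds)
  jittered <- vector("list", spec$n_compounds)
  S <- matrix(0, spec$n_compounds, spec$n_active_regions)
  ids <- sprintf("S%02d", seq_len(spec$n_compounds))
  for (j in seq_len(spec$n_compounds)) {
    n_total <- sample(seq(spec$n_atoms_range[1], spec$n_atoms_range[2]), 1)
    n_dec <- n_total - m
    dec <- matrix(NA_real_, n_dec, 3)
    for (d in seq_len(n_dec)) {
      anchor <- skel[sample(m, 1), ]
      dec[d, ] <- anchor + stats::runif(1, 1.5, 4.0) * random_unit_vector()
    }
    atoms <- data.frame(
      element = c(rep("C", m),
                  sample(c("C", "C", "N", "O"), n_dec, replace = TRUE)),
      x = c(skel[, 1], dec[, 1]),
      y = c(skel[, 2], dec[, 2]),
      z = c(skel[, 3], dec[, 3]),
      charge = c(rep(0, m), stats::runif(n_dec, -0.5, 0.5)),
      vdw_radius = c(rep(1.70, m), stats::runif(n_dec, 1.2, 1.9)))
    s <- compound_structure(ids[j], atoms, skeleton = seq_len(m))
    canonical[[j]] <- s
    for (k in seq_len(spec$n_active_regions))
      S[j, k] <- steric_summary(s$atoms, centers[k, ])
    R <- rotation_about_axis(random_unit_vector(),
                             stats::runif(1, 0, spec$pose_jitter[1]) *
                               pi / 180)
    t <- stats::runif(3, -spec$pose_jitter[2], spec$pose_jitter[2])
    jittered[[j]] <- apply_transform(s, list(rotation = R, translation = t))
  }
  names(canonical) <- ids
  names(jittered) <- ids
  Sc <- sweep(S, 2, colMeans(S))
  signal <- spec$intercept + as.vector(Sc %*% spec$planted_weights)
  y <- signal + stats::rnorm(spec$n_compounds, 0, spec$noise_sigma)
  records <- data.frame(compound_id = ids, pic50 = y, is_test = FALSE,
                        stringsAsFactors = FALSE)
  list(dataset = qsar_dataset(records, structures = jittered),
       truth = list(region_centers = centers,
                    weights = spec$planted_weights,
                    intercept = spec$intercept,
                    field_summaries = S,
                    signal = signal,
                    canonical = canonical,
                    spec = spec))
}

#' Generate observed/predicted activity pairs at a controlled correlation
#'
#' Draws observed activities and adds calibrated Gaussian noise to produce
#' predictions whose empirical squared correlation is within +/- 0.05 of the
#' target (rejection-adjusted); used to exercise the external-validation
#' battery under known conditions.
#'
#' @param n Number of pairs (>= 3).
#' @param target_r2 Target squared correlation in (0, 1].
#' @param seed RNG seed.
#' @return List with \code{y_obs} and \code{y_pred}.
#' @export
make_activity_pairs <- function(n, target_r2, seed) {
  if (n < 3) stop("n must be >= 3")
  if (target_r2 <= 0 || target_r2 > 1)
    stop("target_r2 must be in (0, 1]")
  set.seed(seed)
  y_obs <- stats::rnorm(n, 5.7, 0.8)
  if (target_r2 > 1 - 1e-12)
    return(list(y_obs = y_obs, y_pred = y_obs))
  noise_var <- stats::var(y_obs) * (1 - target_r2) / target_r2
  for (try in seq_len(5000)) {
    y_pred <- y_obs + stats::rnorm(n, 0, sqrt(noise_var))
    if (abs(stats::cor(y_obs, y_pred)^2 - target_r2) <= 0.05)
      return(list(y_obs = y_obs, y_pred = y_pred))
  }
  stop("could not reach target_r2 = ", target_r2, " within tolerance")
}
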