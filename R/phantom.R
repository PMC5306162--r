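# ---------------------------------------------------------------------------
# Synthetic vascular phantoms
#
# A phantom cohort emulates the statistical structure the atlas pipeline
# assumes: a template set of named tubular arteries, per-artery
# prevalence (some arteries missing in some subjects), a per-subject
# smooth non-linear warp composed with a small rigid transform, image
# noise, and ground-truth label volumes plus the exact transform.
# ---------------------------------------------------------------------------

#' Specify a phantom artery
#'
#' An artery is a tube swept along a polyline of control points in
#' template mm coordinates.  The intensity profile is a flat core of
#' `peak_intensity` out to `radius_mm`, then a cosine falloff to zero
#' over one further voxel, so that fractional-maximum thresholding
#' recovers the tube to within about one voxel of the true radius.
#'
#' @param name artery identifier.
#' @param centerline n x 3 matrix of control points (mm), n >= 2.
#' @param radius_mm tube radius in mm (> 0).
#' @param prevalence probability in \[0, 1\] that a subject has this
#'   artery.
#' @param peak_intensity positive core intensity.
#' @return An object of class `artery_spec`.
#' @export
artery_spec <- function(name, centerline, radius_mm, prevalence = 1,
                        peak_intensity = 100) {
  centerline <- matrix(as.numeric(centerline), ncol = 3)
  if (nrow(centerline) < 2)
    stop("artery '", name, "': centerline needs at least 2 control points")
  steps <- diff(centerline)
  if (any(rowSums(steps^2) == 0))
    stop("artery '", name, "': consecutive control points must be distinct")
  if (radius_mm <= 0) stop("artery '", name, "': radius_mm must be > 0")
  if (prevalence < 0 || prevalence > 1)
    stop("artery '", name, "': prevalence must be in [0, 1]")
  if (peak_intensity <= 0)
    stop("artery '", name, "': peak_intensity must be > 0")
  structure(list(name = name, centerline = centerline,
                 radius_mm = radius_mm, prevalence = prevalence,
                 peak_intensity = peak_intensity),
            class = "artery_spec")
}

#' Configure a phantom cohort
#'
#' @param n_subjects number of subjects (>= 1).
#' @param grid_shape template grid dimensions (3 positive integers).
#' @param voxel_size_mm isotropic voxel size in mm (default 0.7, the
#'   resolution of high-resolution 4D flow angiography).
#' @param deform_amplitude_mm maximum magnitude of the smooth random
#'   displacement field, mm.
#' @param deform_smoothness_mm Gaussian smoothing scale of the
#'   displacement field, mm.
#' @param rigid_rot_deg,rigid_trans_mm maximum rotation (degrees, per
#'   axis) and translation (mm, per axis) of the random rigid component.
#' @param noise_sd standard deviation of additive Gaussian image noise.
#' @param seed integer seed; identical config + seed reproduces the
#'   cohort bit for bit.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects, grid_shape = c(64L, 64L, 64L),
                          voxel_size_mm = 0.7,
                          deform_amplitude_mm = 2,
                          deform_smoothness_mm = 8,
                          rigid_rot_deg = 3, rigid_trans_mm = 2,
                          noise_sd = 4, seed = 1L) {
  n_subjects <- as.integer(n_subjects)
  if (is.na(n_subjects) || n_subjects < 1)
    stop("n_subjects must be a positive integer")
  grid_shape <- as.integer(rep_len(grid_shape, 3L))
  if (any(grid_shape < 1)) stop("grid_shape must be positive")
  stopifnot(voxel_size_mm > 0, deform_amplitude_mm >= 0,
            deform_smoothness_mm > 0, rigid_rot_deg >= 0,
            rigid_trans_mm >= 0, noise_sd >= 0)
  structure(list(n_subjects = n_subjects, grid_shape = grid_shape,
                 voxel_size_mm = voxel_size_mm,
                 deform_amplitude_mm = deform_amplitude_mm,
                 deform_smoothness_mm = deform_smoothness_mm,
                 rigid_rot_deg = rigid_rot_deg,
                 rigid_trans_mm = rigid_trans_mm,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "cohort_config")
}

# run code under a seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# distance from grid voxels (within a bounding box) to a polyline;
# returns list(index = linear voxel indices, dist = mm distances)
polyline_distances <- function(centerline, max_dist_mm, grid_shape, affine) {
  # densify not needed: exact point-segment distances, vectorised per segment
  lo <- apply(centerline, 2, min) - max_dist_mm
  hi <- apply(centerline, 2, max) + max_dist_mm
  lo_v <- floor(world_to_voxel(rbind(lo), affine))
  hi_v <- ceiling(world_to_voxel(rbind(hi), affine))
  rng <- lapply(1:3, function(a)
    max(0, lo_v[a]):min(grid_shape[a] - 1, hi_v[a]))
  if (any(vapply(rng, length, 1L) == 0))
    return(list(index = integer(), dist = numeric()))
  idx <- as.matrix(expand.grid(x = rng[[1]], y = rng[[2]], z = rng[[3]]))
  pts <- voxel_to_world(idx, affine)
  best <- rep(Inf, nrow(pts))
  for (s in seq_len(nrow(centerline) - 1)) {
    p0 <- centerline[s, ]
    v <- centerline[s + 1, ] - p0
    L2 <- sum(v^2)
    w <- sweep(pts, 2, p0)
    t_ <- pmin(1, pmax(0, (w %*% v)[, 1] / L2))
    d2 <- rowSums((w - outer(t_, v))^2)
    best <- pmin(best, d2)
  }
  lin <- 1L + idx[, 1] + grid_shape[1] * (idx[, 2] + grid_shape[2] * idx[, 3])
  keep <- best <= max_dist_mm^2
  list(index = lin[keep], dist = sqrt(best[keep]))
}

# per-artery intensity/support/distance fields on the template grid
render_artery_fields <- function(specs, config) {
  affine <- default_affine(config$voxel_size_mm)
  gs <- config$grid_shape
  extent <- gs * config$voxel_size_mm
  falloff <- config$voxel_size_mm  # cosine rim width: one voxel
  lapply(specs, function(sp) {
    if (any(sp$centerline < 0) ||
        any(sweep(sp$centerline, 2, extent) > 0))
      stop("artery '", sp$name, "': centerline lies outside the grid extent")
    pd <- polyline_distances(sp$centerline, sp$radius_mm, gs, affine)
    d <- pd$dist
    # flat core, cosine rim over (at most) one voxel, zero exactly at the
    # tube radius: the segmentation mask then sits just inside the
    # ground-truth tube, which keeps labels a superset of the mask
    w <- min(falloff, sp$radius_mm)
    rc <- sp$radius_mm - w
    intensity <- ifelse(d <= rc, sp$peak_intensity,
                        sp$peak_intensity * 0.5 *
                          (1 + cos(pi * (d - rc) / w)))
    list(name = sp$name, index = pd$index, dist = d, intensity = intensity)
  })
}

#' Render the template phantom
#'
#' Renders the summed tube intensities and the ground-truth label volume
#' on the template grid.  A voxel inside several tubes takes the label
#' of the artery whose centerline is nearest (ties go to the lower
#' artery id); its intensity is the sum of the overlapping profiles.
#'
#' @param specs list of [artery_spec()].
#' @param config a [cohort_config()].
#' @param present optional logical vector selecting a subset of arteries
#'   (label ids keep their position in `specs`).
#' @param fields precomputed [render_artery_fields] output (internal
#'   reuse).
#' @return A list with elements `angio` ([scalar_volume()]) and
#'   `labels` ([label_volume()]).
#' @export
render_template <- function(specs, config, present = NULL, fields = NULL) {
  affine <- default_affine(config$voxel_size_mm)
  gs <- config$grid_shape
  n <- prod(gs)
  if (is.null(present)) present <- rep(TRUE, length(specs))
  if (is.null(fields)) fields <- render_artery_fields(specs, config)
  intensity <- numeric(n)
  labels <- integer(n)
  bestd <- rep(Inf, n)
  for (k in seq_along(fields)) {
    if (!present[k]) next
    f <- fields[[k]]
    intensity[f$index] <- intensity[f$index] + f$intensity
    closer <- f$dist < bestd[f$index]  # ties keep the earlier, lower id
    labels[f$index[closer]] <- k
    bestd[f$index[closer]] <- f$dist[closer]
  }
  nm <- vapply(specs, `[[`, "", "name")
  list(angio = scalar_volume(array(intensity, gs), config$voxel_size_mm,
                             affine),
       labels = label_volume(array(labels, gs), nm, config$voxel_size_mm,
                             affine))
}

# smooth random displacement field: Gaussian-filtered white noise,
# rescaled so the maximum displacement magnitude equals amplitude_mm
random_displacement <- function(config) {
  gs <- config$grid_shape
  if (config$deform_amplitude_mm == 0) return(NULL)
  sigma_vox <- config$deform_smoothness_mm / config$voxel_size_mm
  kr <- max(1L, ceiling(3 * sigma_vox))
  kern <- exp(-0.5 * ((-kr:kr) / sigma_vox)^2)
  kern <- kern / sum(kern)
  d <- array(0, c(gs, 3))
  for (k in 1:3) {
    noise <- array(rnorm(prod(gs)), gs)
    d[, , , k] <- .cpp_convolve_sep(as.vector(noise), gs, kern)
  }
  mag <- sqrt(rowSums(matrix(d, ncol = 3)^2))
  mx <- max(mag)
  if (mx > 0) d <- d * (config$deform_amplitude_mm / mx)
  d
}

random_rigid <- function(config) {
  if (config$rigid_rot_deg == 0 && config$rigid_trans_mm == 0)
    return(diag(4))
  ang <- runif(3, -config$rigid_rot_deg, config$rigid_rot_deg) * pi / 180
  tr <- runif(3, -config$rigid_trans_mm, config$rigid_trans_mm)
  cx <- cos(ang[1]); sx <- sin(ang[1])
  cy <- cos(ang[2]); sy <- sin(ang[2])
  cz <- cos(ang[3]); sz <- sin(ang[3])
  Rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
  Ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
  Rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
  R <- Rz %*% Ry %*% Rx
  centre <- config$grid_shape * config$voxel_size_mm / 2
  A <- diag(4)
  A[1:3, 1:3] <- R
  A[1:3, 4] <- centre - R %*% centre + tr  # rotate about the grid centre
  A
}

#' Generate a synthetic cohort
#'
#' For each subject: artery presence is drawn per prevalence; a smooth
#' random displacement field plus a small random rigid transform define
#' the subject's warp; template intensities are resampled into subject
#' space (trilinear) and labels follow by nearest-neighbour; Gaussian
#' noise is added (clamped at zero so intensities stay non-negative).
#' The exact warp is stored with each subject, so downstream
#' normalization is the known ground truth rather than an estimated
#' registration.
#'
#' @param specs list of [artery_spec()].
#' @param config a [cohort_config()].
#' @return A list of `synthetic_subject` objects, each with elements
#'   `angio`, `truth_labels`, `presence` (named logical) and
#'   `warp_to_template` (a [subject_transform()]).
#' @details
#' The ground-truth labels emulate manual labeling of the segmented
#' vessel tree: the noise-free template is segmented exactly as the
#' pipeline would segment it ([box_smooth()] then
#' [threshold_binarize()]), the segmentation is thinned, every skeleton
#' voxel takes the label of its geometrically nearest artery, and the
#' labeled skeleton is re-inflated into the (slightly dilated) vessel
#' tree with [reinflate()] — the same constrained dilation a manual
#' rater's branch labels go through.  Truth labels therefore cover the
#' tubes plus the one-voxel segmentation halo, with inter-artery
#' borders at the same skeleton-distance boundaries the automatic
#' pipeline produces.
#' @export
generate_cohort <- function(specs, config) {
  stopifnot(inherits(config, "cohort_config"))
  nm <- vapply(specs, `[[`, "", "name")
  prev <- vapply(specs, `[[`, 1.0, "prevalence")
  fields <- render_artery_fields(specs, config)
  grid_aff <- default_affine(config$voxel_size_mm)
  truth_cache <- new.env(parent = emptyenv())
  template_truth <- function(presence, tmpl) {
    key <- paste(as.integer(presence), collapse = "")
    if (!is.null(truth_cache[[key]])) return(truth_cache[[key]])
    seg <- threshold_binarize(box_smooth(tmpl$angio), 0.18)
    skl <- thin(seg)
    seeds <- array(0L, dim(seg))
    on_skel <- as.vector(skl) & as.vector(tmpl$labels) > 0
    seeds[on_skel] <- as.vector(tmpl$labels)[on_skel]
    tree <- as.vector(seg) | as.vector(tmpl$labels) > 0
    # one-voxel margin: the reference tree is labeled generously at
    # its boundary, as a rater marking whole branches would do
    tree <- .cpp_convolve_sep(as.numeric(tree), dim(seg),
                              rep(1, 3)) > 1e-9
    truth <- reinflate(label_volume(seeds, attr(tmpl$labels, "name_table"),
                                    voxel_size(seg), vol_affine(seg)),
                       binary_volume(array(tree, dim(seg)),
                                     voxel_size(seg), vol_affine(seg)),
                       7L)
    truth_cache[[key]] <- truth
    truth
  }
  with_seed(config$seed, {
    lapply(seq_len(config$n_subjects), function(i) {
      presence <- stats::rbinom(length(specs), 1, prev) == 1
      tmpl <- render_template(specs, config, present = presence,
                              fields = fields)
      if (any(presence)) tmpl$labels <- template_truth(presence, tmpl)
      A <- random_rigid(config)
      D <- random_displacement(config)
      tr <- subject_transform(affine = A, displacement = D,
                              grid_affine = if (is.null(D)) NULL else
                                grid_aff)
      angio <- apply_transform(tmpl$angio, tr, "inverse", "linear")
      labels <- apply_transform(tmpl$labels, tr, "inverse", "nearest")
      if (config$noise_sd > 0) {
        noisy <- as.vector(angio) + rnorm(length(angio), 0, config$noise_sd)
        angio <- vol_like(pmax(noisy, 0), angio)
      }
      names(presence) <- nm
      structure(list(id = i, angio = angio, truth_labels = labels,
                     presence = presence, warp_to_template = tr),
                class = "synthetic_subject")
    })
  })
}

#' @export
print.synthetic_subject <- function(x, ...) {
  cat(sprintf("<synthetic_subject #%d> arteries present: %s\n", x$id,
              paste(names(x$presence)[x$presence], collapse = ", ")))
  invisible(x)
}

#' Example phantom artery set
#'
#' Seven tubes laid out as a topological analogue of the major cerebral
#' arteries on a 64^3, 0.7 mm grid: two paired carotid-like trunks, a
#' midline basilar-like trunk, paired lateral middle-cerebral-like
#' branches, an anterior communicating-like bridge, and one
#' low-prevalence posterior communicating-like connector (present in
#' 38% of subjects, the population prevalence reported for that
#' artery).  The geometry is schematic, not anatomical.
#'
#' @param extent_mm physical extent of the template grid (default
#'   `64 * 0.7`).
#' @return A list of [artery_spec()].
#' @export
example_artery_specs <- function(extent_mm = 64 * 0.7) {
  e <- extent_mm
  u <- e / 44.8  # scale relative to the default 44.8 mm box
  list(
    artery_spec("ica_left",
                rbind(c(14, 20, 3), c(14, 21, 16), c(15, 22, 27)) * u,
                radius_mm = 1.8 * u),
    artery_spec("ica_right",
                rbind(c(31, 20, 3), c(31, 21, 16), c(30, 22, 27)) * u,
                radius_mm = 1.8 * u),
    artery_spec("basilar",
                rbind(c(22.4, 31, 6), c(22.4, 31, 22)) * u,
                radius_mm = 1.4 * u),
    artery_spec("mca_left",
                rbind(c(15, 22, 27), c(9, 24, 31), c(5, 27, 34)) * u,
                radius_mm = 1.3 * u),
    artery_spec("mca_right",
                rbind(c(30, 22, 27), c(36, 24, 31), c(40, 27, 34)) * u,
                radius_mm = 1.3 * u),
    artery_spec("aca",
                rbind(c(15, 22, 27), c(22.4, 16, 33), c(30, 22, 27)) * u,
                radius_mm = 1.35 * u),
    artery_spec("pcoa_left",
                rbind(c(14, 20.9, 14), c(22.4, 31, 14)) * u,
                radius_mm = 1.2 * u, prevalence = 0.38)
  )
}
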