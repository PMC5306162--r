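#' @useDynLib vascatlas, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm runif rbinom
#' @importFrom utils read.csv
#' @keywords internal
"_PACKAGE"

# ---------------------------------------------------------------------------
# Volume containers
#
# Volumes are plain 3D arrays carrying grid metadata as attributes:
#   voxel_size : length-3 positive numeric, mm per voxel along each axis
#   affine     : 4x4 matrix mapping 0-based voxel indices to world mm
# Three classes share this layout: scalar_volume (angiographic
# intensities), binary_volume (segmentation masks) and label_volume
# (integer artery labels plus a name table).
# ---------------------------------------------------------------------------

default_affine <- function(voxel_size) {
  voxel_size <- rep_len(as.numeric(voxel_size), 3L)
  diag(c(voxel_size, 1))
}

new_volume <- function(values, voxel_size, affine, class) {
  if (length(dim(values)) != 3L)
    stop("volume values must be a 3D array")
  voxel_size <- rep_len(as.numeric(voxel_size), 3L)
  if (any(voxel_size <= 0)) stop("voxel_size_mm must be positive")
  if (is.null(affine)) affine <- default_affine(voxel_size)
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L))) stop("affine must be a 4x4 matrix")
  structure(values,
            voxel_size = voxel_size, affine = affine,
            class = c(class, "vas_volume"))
}

#' Construct a scalar (angiographic) volume
#'
#' A `scalar_volume` is a 3D grid of non-negative intensities with voxel
#' size and a 4x4 voxel-to-world affine (0-based voxel indices, world
#' coordinates in mm).
#'
#' @param values 3D numeric array of intensities.
#' @param voxel_size_mm voxel edge length(s) in mm (scalar or length 3).
#' @param affine optional 4x4 voxel-index-to-mm matrix; defaults to a
#'   diagonal scaling by `voxel_size_mm` with the origin at voxel
#'   (0,0,0).
#' @return An object of class `scalar_volume`.
#' @export
scalar_volume <- function(values, voxel_size_mm = 1, affine = NULL) {
  storage.mode(values) <- "double"
  new_volume(values, voxel_size_mm, affine, "scalar_volume")
}

#' Construct a binary segmentation volume
#'
#' @param mask 3D logical array.
#' @inheritParams scalar_volume
#' @return An object of class `binary_volume`.
#' @export
binary_volume <- function(mask, voxel_size_mm = 1, affine = NULL) {
  storage.mode(mask) <- "logical"
  new_volume(mask, voxel_size_mm, affine, "binary_volume")
}

#' Construct an artery label volume
#'
#' Voxel value 0 is background; value `k` refers to the artery named
#' `name_table[k]`.
#'
#' @param labels 3D array of non-negative integers.
#' @param name_table character vector; entry `k` names label id `k`.
#' @inheritParams scalar_volume
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(labels, name_table = character(),
                         voxel_size_mm = 1, affine = NULL) {
  storage.mode(labels) <- "integer"
  ids <- setdiff(unique(as.vector(labels)), 0L)
  if (length(ids) && max(ids) > length(name_table))
    stop("label id ", max(ids), " has no entry in name_table")
  vol <- new_volume(labels, voxel_size_mm, affine, "label_volume")
  attr(vol, "name_table") <- as.character(name_table)
  vol
}

#' @export
print.vas_volume <- function(x, ...) {
  cat(sprintf("<%s> %s voxels, %.3g x %.3g x %.3g mm\n",
              class(x)[1], paste(dim(x), collapse = " x "),
              attr(x, "voxel_size")[1], attr(x, "voxel_size")[2],
              attr(x, "voxel_size")[3]))
  if (inherits(x, "label_volume"))
    cat("  labels:", paste(attr(x, "name_table"), collapse = ", "), "\n")
  invisible(x)
}

voxel_size <- function(vol) attr(vol, "voxel_size")
vol_affine <- function(vol) attr(vol, "affine")
voxel_volume_mm3 <- function(vol) prod(voxel_size(vol))

# rebuild a volume of the same class/grid with new values
vol_like <- function(values, template, class = NULL) {
  dim(values) <- dim(template)
  cls <- if (is.null(class)) class(template)[1] else class
  out <- switch(cls,
    scalar_volume = scalar_volume(values, voxel_size(template),
                                  vol_affine(template)),
    binary_volume = binary_volume(values, voxel_size(template),
                                  vol_affine(template)),
    label_volume  = label_volume(values, attr(template, "name_table"),
                                 voxel_size(template), vol_affine(template)))
  out
}

# 0-based voxel index matrix (n x 3) -> world mm (n x 3)
voxel_to_world <- function(idx0, affine) {
  idx0 <- matrix(idx0, ncol = 3L)
  t(affine %*% rbind(t(idx0), 1))[, 1:3, drop = FALSE]
}

world_to_voxel <- function(mm, affine) {
  mm <- matrix(mm, ncol = 3L)
  t(solve(affine) %*% rbind(t(mm), 1))[, 1:3, drop = FALSE]
}

# all voxel centres of a grid in world mm, in array (column-major) order
grid_world_coords <- function(dim3, affine) {
  idx <- as.matrix(expand.grid(x = seq_len(dim3[1]) - 1,
                               y = seq_len(dim3[2]) - 1,
                               z = seq_len(dim3[3]) - 1))
  voxel_to_world(idx, affine)
}

# ---------------------------------------------------------------------------
# NIfTI I/O
# ---------------------------------------------------------------------------

#' Read a NIfTI volume
#'
#' Reads a NIfTI-1/2 file into a [scalar_volume()] or, when
#' `as = "labels"`, a [label_volume()].  Voxel size and the sform affine
#' are taken from the header.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @param as `"scalar"` or `"labels"`.
#' @param name_table artery names for label volumes.
#' @return A `scalar_volume` or `label_volume`.
#' @export
read_volume <- function(path, as = c("scalar", "labels"),
                        name_table = character()) {
  as <- match.arg(as)
  if (!file.exists(path))
    stop("volume file does not exist: ", path)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e)
                    stop("not a readable NIfTI file: ", path, " (",
                         conditionMessage(e), ")"))
  vals <- array(as.vector(img), dim = dim(img)[1:3])
  vs <- RNifti::pixdim(img)[1:3]
  aff <- unclass(RNifti::xform(img))[1:4, 1:4]
  if (all(aff[1:3, 1:3] == 0)) aff <- default_affine(vs)
  if (as == "labels")
    label_volume(round(vals),
                 name_table = if (length(name_table)) name_table else
                   as.character(seq_len(max(0, round(max(vals))))),
                 voxel_size_mm = vs, affine = aff)
  else
    scalar_volume(vals, voxel_size_mm = vs, affine = aff)
}

#' Write a volume to NIfTI
#'
#' Round-trips values, voxel size and affine through the NIfTI-1 header.
#' Label and binary volumes are stored as integers.
#'
#' @param vol a `scalar_volume`, `binary_volume` or `label_volume`.
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  vals <- array(as.vector(vol), dim = dim(vol))
  dt <- if (inherits(vol, "scalar_volume")) "double" else "int32"
  if (is.logical(vals)) storage.mode(vals) <- "integer"
  img <- RNifti::asNifti(vals)
  img <- RNifti::`pixdim<-`(img, voxel_size(vol))
  aff <- structure(vol_affine(vol), code = 2L)
  img <- RNifti::`sform<-`(img, aff)
  img <- RNifti::`qform<-`(img, aff)
  RNifti::writeNifti(img, path, datatype = dt)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Smoothing and segmentation
# ---------------------------------------------------------------------------

#' Box-filter smoothing
#'
#' Low-pass filters an intensity volume with a cubic box kernel: each
#' output voxel is the mean of its `width_vox`^3 neighbourhood, with the
#' volume zero-padded at the borders (so border means still divide by
#' the full kernel size, keeping the operation linear and
#' sum-preserving on interior-supported images).
#'
#' @param vol a [scalar_volume()].
#' @param width_vox odd kernel width in voxels (default 3).
#' @return A smoothed `scalar_volume`.
#' @export
box_smooth <- function(vol, width_vox = 3L) {
  width_vox <- as.integer(width_vox)
  if (width_vox < 1L || width_vox %% 2L == 0L)
    stop("width_vox must be a positive odd integer")
  k <- rep(1 / width_vox, width_vox)
  out <- .cpp_convolve_sep(as.vector(vol), dim(vol), k)
  vol_like(out, vol)
}

#' Fractional-maximum threshold segmentation
#'
#' Binarizes an angiographic volume at a fraction of its global maximum
#' intensity (inclusive: voxels exactly at the threshold are kept).  The
#' conventional setting for angiographic vessel segmentation is 18% of
#' the maximum of the smoothed image.
#'
#' @param vol a [scalar_volume()], normally already smoothed with
#'   [box_smooth()].
#' @param fraction threshold as a fraction of the maximum, in (0, 1).
#' @return A [binary_volume()].
#' @export
threshold_binarize <- function(vol, fraction = 0.18) {
  if (fraction <= 0 || fraction >= 1)
    stop("fraction must be in (0, 1)")
  m <- max(vol)
  if (m <= 0) stop("volume has no positive intensities; cannot threshold")
  binary_volume(array(as.vector(vol) >= fraction * m, dim(vol)),
                voxel_size(vol), vol_affine(vol))
}

# ---------------------------------------------------------------------------
# Subject transforms
# ---------------------------------------------------------------------------

#' Construct a subject spatial transform
#'
#' A `subject_transform` describes the mapping used to resample a
#' subject's volumes into template space.  It is stored in pull form on
#' the template grid: a template-space point `x` (mm) corresponds to the
#' subject-space point `affine %*% x + displacement(x)`.  The affine
#' holds the rigid/affine component; the optional displacement field
#' holds the smooth non-linear residual (mm, one 3-vector per template
#' voxel).
#'
#' @param affine 4x4 matrix mapping template mm to subject mm.
#' @param displacement optional 4D array `c(grid_dim, 3)` of mm offsets
#'   on the template grid.
#' @param grid_affine 4x4 voxel-to-mm affine of the template grid the
#'   displacement field lives on (required with a displacement field).
#' @return An object of class `subject_transform`.
#' @export
subject_transform <- function(affine = diag(4), displacement = NULL,
                              grid_affine = NULL) {
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4, 4))) stop("affine must be 4x4")
  if (abs(det(affine)) < 1e-12) stop("affine component is singular")
  if (!is.null(displacement)) {
    d <- dim(displacement)
    if (length(d) != 4L || d[4] != 3L)
      stop("displacement must be a 4D array with 3 components")
    if (is.null(grid_affine))
      stop("grid_affine is required with a displacement field")
    grid_affine <- as.matrix(grid_affine)
  }
  structure(list(affine = affine, displacement = displacement,
                 grid_affine = grid_affine),
            class = "subject_transform")
}

#' @export
print.subject_transform <- function(x, ...) {
  cat("<subject_transform>",
      if (is.null(x$displacement)) "affine only" else
        sprintf("affine + displacement field (max |d| = %.2f mm)",
                max(sqrt(rowSums(matrix(x$displacement, ncol = 3)^2)))),
      "\n")
  invisible(x)
}

# evaluate the displacement field (mm) at template-space mm points
eval_displacement <- function(transform, pts_mm) {
  if (is.null(transform$displacement))
    return(matrix(0, nrow(pts_mm), 3))
  d <- transform$displacement
  gd <- dim(d)[1:3]
  vox <- world_to_voxel(pts_mm, transform$grid_affine)
  out <- matrix(0, nrow(pts_mm), 3)
  for (k in 1:3)
    out[, k] <- .cpp_sample_trilinear(as.vector(d[, , , k]), gd, vox, 0)
  out
}

#' Map points through a subject transform
#'
#' `direction = "forward"` maps template-space points to subject space
#' (affine plus displacement); `"inverse"` maps subject-space points
#' back to template space, inverting the non-linear part by fixed-point
#' iteration (free-form displacement fields have no closed-form
#' inverse).
#'
#' @param transform a [subject_transform()].
#' @param pts_mm n x 3 matrix of points in mm.
#' @param direction `"forward"` or `"inverse"`.
#' @param iterations fixed-point iterations for the inverse (default 10).
#' @return n x 3 matrix of mapped points in mm.
#' @export
transform_points <- function(transform, pts_mm,
                             direction = c("forward", "inverse"),
                             iterations = 10L) {
  direction <- match.arg(direction)
  pts_mm <- matrix(pts_mm, ncol = 3)
  A <- transform$affine
  if (direction == "forward") {
    out <- t(A %*% rbind(t(pts_mm), 1))[, 1:3, drop = FALSE]
    out + eval_displacement(transform, pts_mm)
  } else {
    Ainv <- solve(A)
    affine_back <- function(p)
      t(Ainv %*% rbind(t(p), 1))[, 1:3, drop = FALSE]
    x <- affine_back(pts_mm)
    if (!is.null(transform$displacement)) {
      for (i in seq_len(iterations))
        x <- affine_back(pts_mm - eval_displacement(transform, x))
    }
    x
  }
}

#' Resample a volume through a subject transform
#'
#' `direction = "forward"` pulls a subject-space volume onto the
#' template grid (the spatial-normalization step); `"inverse"` pushes a
#' template-space volume onto the subject grid using the approximate
#' inverse map.  Intensities are interpolated trilinearly; label and
#' binary volumes use nearest-neighbour so values stay integral.
#'
#' @param vol volume to resample.
#' @param transform a [subject_transform()].
#' @param direction `"forward"` (to template) or `"inverse"` (to subject).
#' @param interp `"linear"` or `"nearest"`; defaults to `"nearest"` for
#'   label/binary volumes and `"linear"` otherwise.
#' @param target_dim,target_affine output grid (defaults to the input
#'   grid, cohorts here share one grid shape).
#' @return A volume of the same class on the target grid.
#' @export
apply_transform <- function(vol, transform,
                            direction = c("forward", "inverse"),
                            interp = NULL,
                            target_dim = dim(vol),
                            target_affine = vol_affine(vol)) {
  direction <- match.arg(direction)
  if (is.null(interp))
    interp <- if (inherits(vol, "scalar_volume")) "linear" else "nearest"
  interp <- match.arg(interp, c("linear", "nearest"))
  out_mm <- grid_world_coords(target_dim, target_affine)
  src_mm <- transform_points(transform, out_mm, direction)
  src_vox <- world_to_voxel(src_mm, vol_affine(vol))
  v <- as.vector(vol)
  storage.mode(v) <- "double"
  smp <- if (interp == "linear")
    .cpp_sample_trilinear(v, dim(vol), src_vox, 0)
  else
    .cpp_sample_nearest(v, dim(vol), src_vox, 0)
  out <- array(smp, target_dim)
  if (inherits(vol, "label_volume"))
    label_volume(round(out), attr(vol, "name_table"),
                 voxel_size(vol), target_affine)
  else if (inherits(vol, "binary_volume"))
    binary_volume(out > 0.5, voxel_size(vol), target_affine)
  else
    scalar_volume(out, voxel_size(vol), target_affine)
}

#' Reduce a transform to its rigid-body component
#'
#' Drops the non-linear displacement field and replaces the affine by
#' its closest rotation + translation: the rotation factor of the polar
#' decomposition of the 3x3 block (scale and shear discarded), keeping
#' the translation column.  This is the alignment used to build the
#' rigid-body comparison atlas.
#'
#' @param transform a [subject_transform()].
#' @return A rigid [subject_transform()] without displacement field.
#' @export
rigid_only <- function(transform) {
  A <- transform$affine
  M <- A[1:3, 1:3]
  if (abs(det(M)) < 1e-12) stop("affine component is singular")
  sv <- svd(M)
  R <- sv$u %*% t(sv$v)
  if (det(R) < 0) {           # keep a proper rotation
    u <- sv$u
    u[, 3] <- -u[, 3]
    R <- u %*% t(sv$v)
  }
  out <- diag(4)
  out[1:3, 1:3] <- R
  out[1:3, 4] <- A[1:3, 4]
  subject_transform(affine = out)
}
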