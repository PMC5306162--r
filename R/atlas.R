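# ---------------------------------------------------------------------------
# Atlas construction and characterization
#
# Labeled skeleton branches are re-inflated into volumetric artery
# labels, per-artery probability maps are accumulated across subjects
# in template space, and the alignment of the cohort is characterized
# by concatenated volume, arterial volume ratio (AVR), dominating
# volume and maximum probability.  A rigid-body comparison atlas uses
# volume-conserving re-binarization after resampling.
# ---------------------------------------------------------------------------

#' Re-inflate labeled skeleton voxels into the vessel mask
#'
#' Propagates each labeled skeleton voxel's label through a cubic
#' neighbourhood of `kernel_vox` voxels (a dilation with a
#' `kernel_vox`^3 cube) and intersects the result with the binary
#' vessel tree.  A mask voxel reachable from several labels takes the
#' label of the Euclidean-nearest labeled skeleton voxel (ties go to
#' the lower label id); mask voxels reached by no label stay 0.
#'
#' @param branch_labels a [label_volume()] whose nonzero voxels lie on
#'   the skeleton.
#' @param mask the [binary_volume()] vessel tree.
#' @param kernel_vox odd cubic kernel width (default 7).
#' @return A [label_volume()] confined to the mask.
#' @export
reinflate <- function(branch_labels, mask, kernel_vox = 7L) {
  kernel_vox <- as.integer(kernel_vox)
  if (kernel_vox < 1L || kernel_vox %% 2L == 0L)
    stop("kernel_vox must be a positive odd integer")
  stopifnot(all(dim(branch_labels) == dim(mask)))
  out <- .cpp_reinflate(array(as.integer(branch_labels), dim(mask)),
                        array(as.vector(mask) > 0, dim(mask)),
                        dim(mask), (kernel_vox - 1L) %/% 2L)
  label_volume(array(out, dim(mask)), attr(branch_labels, "name_table"),
               voxel_size(mask), vol_affine(mask))
}

#' Build a per-artery probability map
#'
#' Adds the binary occupancy of one artery over all subjects that
#' possess it and divides by that count, so each voxel holds the
#' proportion of included arteries overlapping there.  Subjects without
#' the artery are excluded from the denominator.
#'
#' @param artery_name name of the artery.
#' @param binaries list of 3D logical arrays (or binary volumes), one
#'   per subject, on a common template grid: occupancy of this artery.
#' @param voxel_size_mm,affine grid metadata.
#' @return An object of class `probability_map` (a 3D array with
#'   attributes `artery_name`, `n_included`, `voxel_size`, `affine`).
#' @export
build_probability_map <- function(artery_name, binaries,
                                  voxel_size_mm = 1, affine = NULL) {
  stopifnot(length(binaries) >= 1)
  d <- dim(binaries[[1]])
  has <- vapply(binaries, function(b) any(b > 0), TRUE)
  n_included <- sum(has)
  if (n_included == 0)
    stop("artery '", artery_name, "' is absent from every subject")
  acc <- array(0, d)
  for (b in binaries[has]) {
    stopifnot(all(dim(b) == d))
    acc <- acc + (b > 0)
  }
  if (!is.null(attr(binaries[[1]], "voxel_size")))
    voxel_size_mm <- attr(binaries[[1]], "voxel_size")
  if (is.null(affine) && !is.null(attr(binaries[[1]], "affine")))
    affine <- attr(binaries[[1]], "affine")
  new_probability_map(acc / n_included, artery_name, n_included,
                      voxel_size_mm, affine)
}

new_probability_map <- function(values, artery_name, n_included,
                                voxel_size_mm, affine = NULL) {
  voxel_size_mm <- rep_len(as.numeric(voxel_size_mm), 3L)
  if (is.null(affine)) affine <- default_affine(voxel_size_mm)
  structure(values, artery_name = artery_name,
            n_included = as.integer(n_included),
            voxel_size = voxel_size_mm, affine = as.matrix(affine),
            class = c("probability_map"))
}

#' @export
print.probability_map <- function(x, ...) {
  cat(sprintf("<probability_map> %s: n = %d, max p = %.3f\n",
              attr(x, "artery_name"), attr(x, "n_included"), max(x)))
  invisible(x)
}

#' Concatenated volume of a probability map
#'
#' Physical volume of the voxels occupied by the artery in at least one
#' included subject (all nonzero map voxels), in cm^3.
#'
#' @param map a `probability_map`.
#' @return Volume in cm^3.
#' @export
concatenated_volume <- function(map) {
  sum(map > 0) * prod(attr(map, "voxel_size")) / 1000
}

#' Arterial volume ratio (AVR)
#'
#' Concatenated volume of the probability map divided by the average
#' per-subject artery volume over the included subjects.  Perfect
#' inter-subject alignment gives 1.0; larger values mean the artery is
#' smeared over a larger template region than any single subject
#' occupies.
#'
#' @param map a `probability_map`.
#' @param subject_volumes_cm3 per-included-subject artery volumes, cm^3.
#' @return The AVR (dimensionless, >= 1 when every subject volume > 0).
#' @export
arterial_volume_ratio <- function(map, subject_volumes_cm3) {
  if (!length(subject_volumes_cm3))
    stop("no subject volumes supplied")
  if (any(subject_volumes_cm3 <= 0))
    stop("subject volumes must be positive")
  concatenated_volume(map) / mean(subject_volumes_cm3)
}

#' Maximum probability of a map
#'
#' @param map a `probability_map`.
#' @return Maximum voxel value, in (0, 1].
#' @export
max_probability <- function(map) {
  m <- max(map)
  if (m <= 0) stop("probability map is empty")
  m
}

#' Dominating volume of a map within an atlas
#'
#' Percentage of the map's nonzero voxels where its probability strictly
#' exceeds every other artery's probability (exact ties do not
#' dominate).
#'
#' @param target name of the artery, or a `probability_map` from the
#'   atlas.
#' @param atlas a `vascular_atlas`.
#' @return Percentage in \[0, 100\].
#' @export
dominating_volume <- function(target, atlas) {
  name <- if (is.character(target)) target else attr(target, "artery_name")
  if (!name %in% names(atlas$maps))
    stop("artery '", name, "' is not in the atlas")
  tv <- atlas$maps[[name]]
  nz <- tv > 0
  if (!any(nz)) return(0)
  others <- atlas$maps[setdiff(names(atlas$maps), name)]
  if (!length(others)) return(100)
  omax <- array(0, dim(tv))
  for (o in others) omax <- pmax(omax, o)
  100 * sum(nz & (tv > omax)) / sum(nz)
}

#' Whole-atlas arterial volume ratio
#'
#' Aggregates per-artery rows into a single AVR for the atlas: the sum
#' of concatenated volumes divided by the sum of mean per-subject
#' volumes.
#'
#' @param rows data frame with columns `concatenated_volume_cm3` and
#'   `mean_subject_volume_cm3` (one row per artery), as produced by
#'   [build_atlas()].
#' @return The whole-atlas AVR.
#' @export
whole_atlas_avr <- function(rows) {
  stopifnot(nrow(rows) >= 1)
  sum(rows$concatenated_volume_cm3) / sum(rows$mean_subject_volume_cm3)
}

#' Volume-conserving re-binarization
#'
#' After resampling a binary artery through a transform with linear
#' interpolation, partial-volume effects leave fractional values.  This
#' rebinarizes at the threshold that conserves the target voxel count:
#' the `target_volume_vox`-th largest value.  Ties at the threshold are
#' all kept, so the output count is the smallest count >= the target
#' achievable by thresholding.
#'
#' @param resampled a [scalar_volume()] (or numeric array) of
#'   fractional occupancies.
#' @param target_volume_vox target voxel count (>= 1).
#' @return A [binary_volume()]; if fewer than `target_volume_vox`
#'   positive voxels exist, all positive voxels are returned and the
#'   result carries attribute `underfilled = TRUE` plus a warning.
#' @export
volume_conserving_binarize <- function(resampled, target_volume_vox) {
  target_volume_vox <- as.integer(target_volume_vox)
  if (target_volume_vox < 1) stop("target_volume_vox must be >= 1")
  v <- as.vector(resampled)
  pos <- v > 0
  vs <- if (!is.null(attr(resampled, "voxel_size")))
    attr(resampled, "voxel_size") else rep(1, 3)
  aff <- attr(resampled, "affine")
  if (sum(pos) < target_volume_vox) {
    warning("fewer positive voxels (", sum(pos),
            ") than the target volume (", target_volume_vox, ")")
    out <- binary_volume(array(pos, dim(resampled)), vs, aff)
    attr(out, "underfilled") <- TRUE
    return(out)
  }
  thr <- sort(v[pos], decreasing = TRUE)[target_volume_vox]
  binary_volume(array(v >= thr, dim(resampled)), vs, aff)
}

# ---------------------------------------------------------------------------
# Atlas assembly
# ---------------------------------------------------------------------------

#' Build an atlas and its metrics table from template-space labels
#'
#' Takes one label volume per subject, all on a common template grid,
#' and assembles one probability map per artery (arteries absent from
#' every subject are skipped) plus the characterization table:
#' subjects included, mean subject volume, concatenated volume, AVR,
#' dominating volume and maximum probability.
#'
#' @param label_volumes list of [label_volume()] on a common grid.
#' @param artery_names names for label ids; defaults to the first
#'   volume's name table.
#' @param space_tag identifier for the template space.
#' @return A list with `atlas` (class `vascular_atlas`: named `maps`,
#'   `space_tag`) and `metrics` (data frame, one row per artery).
#' @export
build_atlas <- function(label_volumes, artery_names = NULL,
                        space_tag = "template") {
  stopifnot(length(label_volumes) >= 1)
  if (is.null(artery_names))
    artery_names <- attr(label_volumes[[1]], "name_table")
  d <- dim(label_volumes[[1]])
  vs <- voxel_size(label_volumes[[1]])
  aff <- vol_affine(label_volumes[[1]])
  vox_cm3 <- prod(vs) / 1000
  maps <- list()
  rows <- list()
  for (k in seq_along(artery_names)) {
    counts <- vapply(label_volumes, function(lv) sum(lv == k), 1.0)
    has <- counts > 0
    if (!any(has)) next
    acc <- array(0, d)
    for (lv in label_volumes[has]) acc <- acc + (lv == k)
    map <- new_probability_map(acc / sum(has), artery_names[k], sum(has),
                               vs, aff)
    maps[[artery_names[k]]] <- map
    rows[[artery_names[k]]] <- data.frame(
      artery_name = artery_names[k],
      n_included = sum(has),
      mean_subject_volume_cm3 = mean(counts[has]) * vox_cm3,
      concatenated_volume_cm3 = concatenated_volume(map),
      avr = NA_real_, dominating_volume_pct = NA_real_,
      max_probability = max(map))
  }
  if (!length(maps)) stop("no artery is present in any subject")
  atlas <- structure(list(maps = maps, space_tag = space_tag),
                     class = "vascular_atlas")
  metrics <- do.call(rbind, rows)
  rownames(metrics) <- NULL
  # AVR from voxel counts directly: the voxel-volume factor cancels, so
  # identical cohorts give exactly 1
  metrics$avr <- vapply(metrics$artery_name, function(nm) {
    k <- match(nm, artery_names)
    counts <- vapply(label_volumes, function(lv) sum(lv == k), 1.0)
    sum(maps[[nm]] > 0) / mean(counts[counts > 0])
  }, 1.0)
  metrics$dominating_volume_pct <-
    vapply(metrics$artery_name, dominating_volume, 1.0, atlas = atlas)
  list(atlas = atlas, metrics = metrics)
}

#' @export
print.vascular_atlas <- function(x, ...) {
  cat(sprintf("<vascular_atlas> %d probability maps in space '%s'\n",
              length(x$maps), x$space_tag))
  for (m in x$maps)
    cat(sprintf("  %-14s n = %3d, max p = %.2f\n",
                attr(m, "artery_name"), attr(m, "n_included"), max(m)))
  invisible(x)
}

#' Normalize a phantom cohort's artery labels to template space
#'
#' For each subject and artery, the binary artery volume is resampled
#' to the template grid through the subject's stored transform — either
#' the full non-linear warp (`mode = "nonlinear"`) or its rigid-body
#' reduction (`mode = "rigid"`, see [rigid_only()]) — with linear
#' interpolation, then re-binarized conserving the subject's native
#' voxel count ([volume_conserving_binarize()]).  Returns one
#' template-space label volume per subject (overlaps after
#' re-binarization resolve to the lower artery id).
#'
#' @param cohort list of `synthetic_subject` (see [generate_cohort()]).
#' @param mode `"nonlinear"` or `"rigid"`.
#' @param labels optional list of subject-space [label_volume()]s to
#'   normalize instead of each subject's ground-truth labels (e.g.
#'   automatic labels).
#' @return List of template-space [label_volume()]s.
#' @export
normalize_cohort <- function(cohort, mode = c("nonlinear", "rigid"),
                             labels = NULL) {
  mode <- match.arg(mode)
  lapply(seq_along(cohort), function(i) {
    sub <- cohort[[i]]
    lab <- if (is.null(labels)) sub$truth_labels else labels[[i]]
    tr <- sub$warp_to_template
    if (mode == "rigid") tr <- rigid_only(tr)
    nt <- attr(lab, "name_table")
    out <- array(0L, dim(lab))
    for (k in sort(setdiff(unique(as.vector(lab)), 0L))) {
      native <- sum(lab == k)
      bin <- scalar_volume(array(as.numeric(lab == k), dim(lab)),
                           voxel_size(lab), vol_affine(lab))
      res <- apply_transform(bin, tr, "forward", "linear")
      reb <- suppressWarnings(volume_conserving_binarize(res, native))
      out[reb & out == 0L] <- as.integer(k)
    }
    label_volume(out, nt, voxel_size(lab), vol_affine(lab))
  })
}

# ---------------------------------------------------------------------------
# Atlas I/O
# ---------------------------------------------------------------------------

#' Write an atlas to disk
#'
#' One NIfTI probability map per artery (`<name>_prob.nii.gz`) plus an
#' `atlas.json` sidecar with names, inclusion counts, space tag and
#' grid metadata.
#'
#' @param atlas a `vascular_atlas`.
#' @param dir output directory (created if needed).
#' @param metrics optional metrics table, written as `metrics.csv`.
#' @return `dir`, invisibly.
#' @export
write_atlas <- function(atlas, dir, metrics = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(atlas$maps)) {
    m <- atlas$maps[[nm]]
    write_volume(scalar_volume(array(as.vector(m), dim(m)),
                               attr(m, "voxel_size"), attr(m, "affine")),
                 file.path(dir, paste0(nm, "_prob.nii.gz")))
  }
  meta <- list(
    space_tag = atlas$space_tag,
    arteries = unname(lapply(atlas$maps, function(m)
      list(name = attr(m, "artery_name"),
           n_included = attr(m, "n_included")))),
    grid = list(dim = dim(atlas$maps[[1]]),
                voxel_size_mm = attr(atlas$maps[[1]], "voxel_size"),
                affine = attr(atlas$maps[[1]], "affine")))
  jsonlite::write_json(meta, file.path(dir, "atlas.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(metrics))
    utils::write.csv(metrics, file.path(dir, "metrics.csv"),
                     row.names = FALSE)
  invisible(dir)
}

#' Read an atlas written by [write_atlas()]
#'
#' @param dir atlas directory.
#' @return A `vascular_atlas`.
#' @export
read_atlas <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "atlas.json"),
                              simplifyVector = TRUE)
  arts <- meta$arteries
  n_art <- if (is.data.frame(arts)) nrow(arts) else length(arts)
  maps <- list()
  for (i in seq_len(n_art)) {
    nm <- if (is.data.frame(arts)) arts$name[i] else arts[[i]]$name
    ni <- if (is.data.frame(arts)) arts$n_included[i] else
      arts[[i]]$n_included
    vol <- read_volume(file.path(dir, paste0(nm, "_prob.nii.gz")))
    maps[[nm]] <- new_probability_map(array(as.vector(vol), dim(vol)), nm,
                                      ni, voxel_size(vol), vol_affine(vol))
  }
  structure(list(maps = maps, space_tag = meta$space_tag),
            class = "vascular_atlas")
}
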