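# ---------------------------------------------------------------------------
# Atlas-based automatic artery identification (AAIM)
#
# A new subject's vessel skeleton is mapped into template space, each
# branch is scored against every probability map (mean map value along
# the branch), and branches are assigned to the best-scoring artery if
# that score clears an existence threshold.  An artery is "found" when
# at least one branch is assigned to it.  The procedure is entirely
# deterministic.
# ---------------------------------------------------------------------------

#' Score skeleton branches against an atlas
#'
#' Every branch voxel is mapped from subject space to template space
#' through the inverse of the subject's normalization transform, and
#' each artery's probability map is sampled there with trilinear
#' interpolation.  The score of (branch, artery) is the mean sampled
#' probability over the branch's voxels; branches falling outside the
#' atlas grid score 0.
#'
#' @param skel a `skeleton` built from the subject's vessel mask.
#' @param atlas a `vascular_atlas`.
#' @param transform the subject's [subject_transform()] (template-to-
#'   subject pull map, as used to normalize the subject).
#' @return A `score_table`: data frame with `branch_id`, one score
#'   column per artery, and attribute `n_voxels` (per-branch voxel
#'   counts, for sum-based tie-breaking).
#' @export
score_branches <- function(skel, atlas, transform) {
  arteries <- names(atlas$maps)
  nb <- length(skel$branches)
  scores <- matrix(0, nb, length(arteries),
                   dimnames = list(NULL, arteries))
  nvox <- integer(nb)
  if (nb) {
    map0 <- atlas$maps[[1]]
    gd <- dim(map0)
    gaff <- attr(map0, "affine")
    for (i in seq_len(nb)) {
      b <- skel$branches[[i]]
      nvox[i] <- nrow(b$path)
      mm_sub <- voxel_to_world(b$path, skel$affine)
      mm_tmpl <- transform_points(transform, mm_sub, "inverse")
      vox <- world_to_voxel(mm_tmpl, gaff)
      for (a in arteries)
        scores[i, a] <- mean(.cpp_sample_trilinear(
          as.vector(atlas$maps[[a]]), gd, vox, 0))
    }
  }
  out <- data.frame(branch_id = vapply(skel$branches, `[[`, 1L, "id"),
                    scores, check.names = FALSE)
  attr(out, "n_voxels") <- nvox
  class(out) <- c("score_table", "data.frame")
  out
}

#' Assign branches to arteries
#'
#' Each branch is assigned to its argmax-scoring artery provided the
#' score reaches `tau`; otherwise it stays unlabeled.  Ties at the
#' argmax are broken by the higher summed (voxel-count-weighted)
#' probability, then by the lexicographically lower artery name.  An
#' artery is `found` iff at least one branch is assigned to it.
#'
#' @param table a `score_table` from [score_branches()].
#' @param tau existence threshold in (0, 1), default 0.1.
#' @return A list with `assignment` (data frame `branch_id`, `artery`,
#'   `score`; `artery` is `NA` for unlabeled branches) and `status`
#'   (named character, `"found"`/`"not_found"` per artery).
#' @export
assign_labels <- function(table, tau = 0.1) {
  if (tau <= 0 || tau >= 1) stop("tau must be in (0, 1)")
  arteries <- setdiff(names(table), "branch_id")
  nb <- nrow(table)
  nvox <- attr(table, "n_voxels")
  if (is.null(nvox)) nvox <- rep(1L, nb)
  assigned <- rep(NA_character_, nb)
  best_score <- rep(NA_real_, nb)
  for (i in seq_len(nb)) {
    s <- as.numeric(table[i, arteries])
    mx <- max(s)
    if (!length(s) || mx < tau) next
    cand <- arteries[s == mx]
    if (length(cand) > 1) {
      sums <- s[s == mx] * nvox[i]      # summed probability tie-break
      cand <- cand[sums == max(sums)]
      cand <- sort(cand)[1]             # then lexicographic
    }
    assigned[i] <- cand[1]
    best_score[i] <- mx
  }
  status <- stats::setNames(
    ifelse(arteries %in% assigned, "found", "not_found"), arteries)
  list(assignment = data.frame(branch_id = table$branch_id,
                               artery = assigned, score = best_score),
       status = status)
}

#' Label a subject's arteries with an atlas
#'
#' Runs the full identification pipeline on an angiographic volume:
#' box smoothing, fractional-maximum thresholding, thinning, branch
#' decomposition and pruning, branch scoring against the atlas,
#' threshold-based assignment, and re-inflation of the assigned
#' branches into the vessel mask.
#'
#' @param angio the subject's [scalar_volume()].
#' @param atlas a `vascular_atlas`.
#' @param transform the subject's [subject_transform()].
#' @param tau existence threshold for [assign_labels()].
#' @param fraction segmentation threshold fraction (default 0.18).
#' @param smooth_width box-filter width in voxels (default 3).
#' @param min_branch_vox pruning threshold (default 8).
#' @param kernel_vox re-inflation kernel (default 7).
#' @return A `labeling_result`: list with `status`, `branches` (named
#'   list of branch ids per found artery), `labels` (subject-space
#'   [label_volume()] of artery ids ordered as in the atlas), `skeleton`
#'   and `scores`.
#' @export
label_subject <- function(angio, atlas, transform, tau = 0.1,
                          fraction = 0.18, smooth_width = 3L,
                          min_branch_vox = 8L, kernel_vox = 7L) {
  mask <- threshold_binarize(box_smooth(angio, smooth_width), fraction)
  skel <- prune(build_graph(thin(mask)), min_branch_vox)
  scores <- score_branches(skel, atlas, transform)
  asg <- assign_labels(scores, tau)
  arteries <- names(atlas$maps)
  # artery id = position in the atlas's map list
  blab <- array(0L, dim(mask))
  for (i in seq_len(nrow(asg$assignment))) {
    a <- asg$assignment$artery[i]
    if (is.na(a)) next
    b <- skel$branches[[which(vapply(skel$branches, `[[`, 1L, "id") ==
                                asg$assignment$branch_id[i])]]
    blab[coord_key(b$path, dim(mask)) + 1L] <- match(a, arteries)
  }
  labels <- reinflate(label_volume(blab, arteries, voxel_size(mask),
                                   vol_affine(mask)),
                      mask, kernel_vox)
  branches <- lapply(stats::setNames(arteries, arteries), function(a)
    asg$assignment$branch_id[!is.na(asg$assignment$artery) &
                               asg$assignment$artery == a])
  structure(list(status = asg$status, branches = branches,
                 labels = labels, skeleton = skel, scores = scores),
            class = "labeling_result")
}

#' @export
print.labeling_result <- function(x, ...) {
  found <- names(x$status)[x$status == "found"]
  cat("<labeling_result>\n  found:    ",
      paste(found, collapse = ", "), "\n  not found:",
      paste(setdiff(names(x$status), found), collapse = ", "), "\n")
  invisible(x)
}
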