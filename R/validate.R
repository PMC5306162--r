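# ---------------------------------------------------------------------------
# Validation: outcome categories, confusion metrics, leave-one-out
# harness, and the nonparametric statistics used to compare atlases.
# ---------------------------------------------------------------------------

#' Segment criterion for accepting a labeled artery
#'
#' An artery label is accepted only if its skeleton contains a
#' connected run of at least `min_length_mm`, optionally confined to an
#' axis-aligned template-space box (e.g. "a 1 cm straight segment near
#' the foramen magnum" becomes a length plus a box).
#'
#' @param artery_name artery the criterion applies to.
#' @param min_length_mm minimum qualifying run length in mm (> 0).
#' @param region optional 2 x 3 matrix `rbind(lo, hi)` of mm bounds.
#' @return An object of class `segment_criterion`.
#' @export
segment_criterion <- function(artery_name, min_length_mm, region = NULL) {
  if (min_length_mm <= 0) stop("min_length_mm must be > 0")
  if (!is.null(region)) {
    region <- matrix(as.numeric(region), 2, 3)
    if (any(region[1, ] > region[2, ])) stop("region lo must be <= hi")
  }
  structure(list(artery_name = artery_name,
                 min_length_mm = min_length_mm, region = region),
            class = "segment_criterion")
}

# length of a branch path restricted to a region: longest contiguous
# run of in-region voxels, measured as one voxel-size plus the summed
# step lengths (diagonal steps scaled), so an n-voxel straight run at
# spacing h has length n * h
path_run_length_mm <- function(path, affine, region = NULL) {
  mm <- voxel_to_world(path, affine)
  inside <- if (is.null(region)) rep(TRUE, nrow(mm)) else
    mm[, 1] >= region[1, 1] & mm[, 1] <= region[2, 1] &
    mm[, 2] >= region[1, 2] & mm[, 2] <= region[2, 2] &
    mm[, 3] >= region[1, 3] & mm[, 3] <= region[2, 3]
  if (!any(inside)) return(0)
  runs <- rle(inside)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  best <- 0
  vox_mm <- sqrt(sum((affine %*% c(1, 0, 0, 0))[1:3]^2))
  for (r in which(runs$values)) {
    seg <- starts[r]:ends[r]
    if (length(seg) == 1) {
      best <- max(best, vox_mm)
      next
    }
    steps <- sqrt(rowSums(diff(mm[seg, , drop = FALSE])^2))
    best <- max(best, vox_mm + sum(steps))
  }
  best
}

#' Check a segment criterion against a labeled artery
#'
#' `TRUE` iff the artery's skeleton branches contain a connected run of
#' path length at least `min_length_mm` (voxel steps scaled by their
#' physical length) lying inside the criterion's region (the whole grid
#' when no region is given).
#'
#' @param skel the subject's pruned `skeleton`.
#' @param branch_ids ids of the branches labeled as this artery.
#' @param criterion a [segment_criterion()].
#' @return Logical.
#' @export
check_criterion <- function(skel, branch_ids, criterion) {
  if (!length(branch_ids)) return(FALSE)
  ids <- vapply(skel$branches, `[[`, 1L, "id")
  for (bid in branch_ids) {
    b <- skel$branches[[match(bid, ids)]]
    if (path_run_length_mm(b$path, skel$affine, criterion$region) >=
        criterion$min_length_mm)
      return(TRUE)
  }
  FALSE
}

#' Categorize automatic labeling outcomes
#'
#' Compares an automatic [label_subject()] result against the
#' ground-truth labels and presence flags, assigning each artery
#' exactly one of six categories:
#' * `correctly_identified_existing` — present, found, the label is
#'   pure (at least `purity` of auto-labeled voxels inside the truth
#'   artery) and the segment criterion is met;
#' * `too_short` — present, found and pure, but the criterion run
#'   length is not met;
#' * `mislabeled_existing` — present and found but impure;
#' * `not_identified` — present but not found;
#' * `correctly_identified_nonexisting` — absent and not found;
#' * `mislabeled_nonexisting` — absent but found.
#'
#' @param auto a `labeling_result`.
#' @param truth ground-truth [label_volume()] on the same grid.
#' @param presence named logical vector of true artery presence.
#' @param criteria named list of [segment_criterion()] per artery
#'   (arteries without a criterion only need a nonempty pure label).
#' @param purity minimum fraction of auto-labeled voxels inside the
#'   truth artery (default 0.9).
#' @param boundary_tolerance_vox voxels of dilation applied to the
#'   truth artery before the purity check (default 1).  Inter-artery
#'   borders drawn at skeleton junctions are ambiguous to about a
#'   voxel; the tolerance is the quantitative stand-in for the
#'   human judgment of whether a border shift amounts to a relevant
#'   mislabeling, while branches assigned to the wrong artery remain
#'   far outside the tolerance and are still flagged.
#' @return Named character vector of categories, one per artery in
#'   `auto$status`.
#' @export
categorize <- function(auto, truth, presence, criteria = list(),
                       purity = 0.9, boundary_tolerance_vox = 1L) {
  if (!all(dim(auto$labels) == dim(truth)))
    stop("automatic and truth label volumes are on different grids")
  arteries <- names(auto$status)
  truth_names <- attr(truth, "name_table")
  out <- character(length(arteries))
  names(out) <- arteries
  auto_vec <- as.vector(auto$labels)
  truth_vec <- as.vector(truth)
  for (a in arteries) {
    k_auto <- match(a, attr(auto$labels, "name_table"))
    k_truth <- match(a, truth_names)
    is_present <- isTRUE(presence[[a]])
    found <- auto$status[[a]] == "found"
    if (!is_present) {
      out[a] <- if (found) "mislabeled_nonexisting" else
        "correctly_identified_nonexisting"
      next
    }
    if (!found) {
      out[a] <- "not_identified"
      next
    }
    sel <- auto_vec == k_auto
    n_auto <- sum(sel)
    tmem <- truth_vec == k_truth
    if (boundary_tolerance_vox > 0) {
      w <- 2L * as.integer(boundary_tolerance_vox) + 1L
      tmem <- .cpp_convolve_sep(as.numeric(tmem), dim(truth),
                                rep(1, w)) > 1e-9
    }
    pur <- if (n_auto == 0) 0 else sum(sel & tmem) / n_auto
    if (pur < purity) {
      out[a] <- "mislabeled_existing"
      next
    }
    crit <- criteria[[a]]
    ok <- if (is.null(crit)) n_auto > 0 else
      check_criterion(auto$skeleton, auto$branches[[a]], crit)
    out[a] <- if (ok) "correctly_identified_existing" else "too_short"
  }
  out
}

outcome_levels <- c("correctly_identified_existing",
                    "correctly_identified_nonexisting",
                    "mislabeled_existing", "mislabeled_nonexisting",
                    "not_identified", "too_short")

#' Tally outcome categories into confusion counts
#'
#' @param categories character vector of outcome categories for one
#'   artery across subjects.
#' @return A one-row data frame with `tp`, `tn`, `fp`, `fn_mislabeled`,
#'   `fn_not_identified`, `fn_too_short`.
#' @export
confusion_counts <- function(categories) {
  stopifnot(all(categories %in% outcome_levels))
  data.frame(
    tp = sum(categories == "correctly_identified_existing"),
    tn = sum(categories == "correctly_identified_nonexisting"),
    fp = sum(categories == "mislabeled_nonexisting"),
    fn_mislabeled = sum(categories == "mislabeled_existing"),
    fn_not_identified = sum(categories == "not_identified"),
    fn_too_short = sum(categories == "too_short"))
}

round_half_up <- function(x) floor(x + 0.5)

#' Sensitivity, specificity and accuracy from confusion counts
#'
#' Sensitivity = 100 tp / (tp + all false negatives); specificity =
#' 100 tn / (tn + fp), undefined (`NA`) when there are no negatives;
#' accuracy = 100 (tp + tn) / total.  Percentages are rounded to the
#' nearest integer, halves up.
#'
#' @param counts a row as produced by [confusion_counts()] (columns
#'   `tp`, `tn`, `fp`, and one or more `fn*` columns).
#' @return A one-row data frame `sensitivity`, `specificity`,
#'   `accuracy`.
#' @export
confusion_metrics <- function(counts) {
  fn <- sum(unlist(counts[grep("^fn", names(counts))]))
  tp <- counts$tp
  tn <- counts$tn
  fp <- counts$fp
  total <- tp + tn + fp + fn
  sens <- if (tp + fn == 0) NA_real_ else
    round_half_up(100 * tp / (tp + fn))
  spec <- if (tn + fp == 0) NA_real_ else
    round_half_up(100 * tn / (tn + fp))
  acc <- round_half_up(100 * (tp + tn) / total)
  data.frame(sensitivity = sens, specificity = spec, accuracy = acc)
}

#' Leave-one-out validation of a phantom cohort
#'
#' For every subject, an atlas is built from the remaining subjects'
#' template-space labels (computed once and reduced by subtraction,
#' which is identical to rebuilding without the subject), the held-out
#' subject is labeled with [label_subject()], and the outcome is
#' categorized per artery.  Results are aggregated into per-artery
#' confusion counts, sensitivity/specificity/accuracy, and the
#' unweighted mean accuracy across arteries.
#'
#' @param cohort list of `synthetic_subject`.
#' @param criteria named list of [segment_criterion()].
#' @param tau existence threshold for assignment.
#' @param mode normalization mode for atlas building (see
#'   [normalize_cohort()]).
#' @param purity purity threshold for [categorize()].
#' @param ... further arguments passed to [label_subject()].
#' @return A list with `table` (per-artery counts and metrics),
#'   `mean_accuracy`, and `categories` (subject x artery matrix).
#' @export
leave_one_out <- function(cohort, criteria = list(), tau = 0.1,
                          mode = "nonlinear", purity = 0.9, ...) {
  n <- length(cohort)
  if (n < 2) stop("leave-one-out needs at least 2 subjects")
  template_labels <- normalize_cohort(cohort, mode)
  arteries <- attr(cohort[[1]]$truth_labels, "name_table")
  d <- dim(template_labels[[1]])
  vs <- voxel_size(template_labels[[1]])
  aff <- vol_affine(template_labels[[1]])
  # total occupancy per artery across the cohort
  occ <- lapply(seq_along(arteries), function(k) {
    acc <- array(0L, d)
    for (lv in template_labels) acc <- acc + (lv == k)
    acc
  })
  n_with <- vapply(seq_along(arteries), function(k)
    sum(vapply(template_labels, function(lv) any(lv == k), TRUE)), 1L)
  cats <- matrix(NA_character_, n, length(arteries),
                 dimnames = list(NULL, arteries))
  for (i in seq_len(n)) {
    maps <- list()
    for (k in seq_along(arteries)) {
      self <- template_labels[[i]] == k
      has_self <- any(self)
      ni <- n_with[k] - has_self
      if (ni < 1) next
      maps[[arteries[k]]] <- new_probability_map(
        (occ[[k]] - self) / ni, arteries[k], ni, vs, aff)
    }
    atlas <- structure(list(maps = maps, space_tag = "template"),
                       class = "vascular_atlas")
    res <- label_subject(cohort[[i]]$angio, atlas,
                         cohort[[i]]$warp_to_template, tau = tau, ...)
    cc <- categorize(res, cohort[[i]]$truth_labels,
                     cohort[[i]]$presence, criteria, purity)
    # arteries missing from the reduced atlas count as not found
    cats[i, names(cc)] <- cc
    absent_from_atlas <- setdiff(arteries, names(maps))
    for (a in absent_from_atlas)
      cats[i, a] <- if (isTRUE(cohort[[i]]$presence[[a]]))
        "not_identified" else "correctly_identified_nonexisting"
  }
  rows <- lapply(arteries, function(a) {
    counts <- confusion_counts(cats[, a])
    cbind(data.frame(artery_name = a), counts, confusion_metrics(counts))
  })
  table <- do.call(rbind, rows)
  list(table = table,
       mean_accuracy = mean(table$accuracy),
       categories = cats)
}

# ---------------------------------------------------------------------------
# Nonparametric statistics
# ---------------------------------------------------------------------------

#' Exact Wilcoxon signed-rank test (two-sided)
#'
#' Paired test with zero differences dropped and average ranks for ties
#' in |difference|.  The p-value is computed from the exact permutation
#' distribution of the positive-rank sum over all 2^n sign assignments
#' (enumerated by dynamic programming, exact up to n = 50):
#' `p = min(1, 2 * min(P(W <= w), P(W >= w)))`.
#'
#' @param a,b paired samples of equal length (>= 5 pairs).
#' @return A list with `statistic` (positive-rank sum W), `n` (pairs
#'   after dropping zeros) and `p_value`.
#' @export
wilcoxon_signed_rank <- function(a, b) {
  if (length(a) != length(b)) stop("a and b must have equal length")
  if (length(a) < 5) stop("need at least 5 pairs")
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(list(statistic = 0, n = 0L, p_value = 1))
  if (n > 50) stop("exact enumeration supported up to 50 nonzero pairs")
  r <- rank(abs(d))            # average ranks for ties
  w <- sum(r[d > 0])
  # doubled ranks are integers even with .5 average ranks
  r2 <- as.integer(round(2 * r))
  total <- sum(r2)
  # dp[s+1] = number of sign assignments with doubled positive-rank sum s
  dp <- numeric(total + 1)
  dp[1] <- 1
  for (ri in r2) {
    shifted <- c(numeric(ri), dp[seq_len(total + 1 - ri)])
    dp <- dp + shifted
  }
  probs <- dp / 2^n
  w2 <- as.integer(round(2 * w))
  p_le <- sum(probs[seq_len(w2 + 1)])
  p_ge <- sum(probs[(w2 + 1):(total + 1)])
  list(statistic = w, n = n, p_value = min(1, 2 * min(p_le, p_ge)))
}

#' Spearman rank correlation
#'
#' Pearson correlation of average-ranked values (ties get average
#' ranks).
#'
#' @param x,y numeric vectors of equal length.
#' @return The correlation coefficient rho.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  rx <- rank(x)
  ry <- rank(y)
  dx <- rx - mean(rx)
  dy <- ry - mean(ry)
  sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
}
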