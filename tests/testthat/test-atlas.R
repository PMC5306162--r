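test_that("re-inflation fills a cube from a single labeled seed", {
  lab <- array(0L, c(7, 7, 7)); lab[4, 4, 4] <- 1L
  mask <- array(FALSE, c(7, 7, 7)); mask[3:5, 3:5, 3:5] <- TRUE
  out <- reinflate(label_volume(lab, "a"), as_mask(mask), 7)
  expect_true(all(out[3:5, 3:5, 3:5] == 1L))
  expect_equal(sum(out > 0), 27)
})

test_that("competing labels split a tube at the midpoint", {
  d <- c(9, 9, 31)
  lab <- array(0L, d); lab[5, 5, 5] <- 1L; lab[5, 5, 25] <- 2L
  mask <- array(FALSE, d); mask[4:6, 4:6, 3:28] <- TRUE
  out <- reinflate(label_volume(lab, c("a", "b")), as_mask(mask), 41)
  oracle <- r_nearest_label(lab, mask, 20)
  expect_identical(as.vector(out), as.vector(oracle))
  # boundary at the midpoint +- 1 voxel
  z_a <- range(which(apply(out == 1, 3, any)))
  expect_lte(abs(z_a[2] - 15), 1)
})

test_that("mask voxels out of kernel reach stay unlabeled", {
  d <- c(5, 5, 30)
  lab <- array(0L, d); lab[3, 3, 3] <- 1L
  mask <- array(FALSE, d); mask[3, 3, 3:25] <- TRUE
  out <- reinflate(label_volume(lab, "a"), as_mask(mask), 7)
  expect_true(all(out[3, 3, 3:6] == 1L))   # within Chebyshev 3
  expect_true(all(out[3, 3, 14:25] == 0L)) # 10+ voxels away
  expect_error(reinflate(label_volume(lab, "a"), as_mask(mask), 4),
               "odd")
})

test_that("re-inflation never labels outside the vessel mask", {
  coh <- small_cohort()
  mask <- threshold_binarize(box_smooth(coh[[1]]$angio), 0.18)
  skel <- prune(build_graph(thin(mask)))
  blab <- skeleton_branch_labels(skel)
  out <- reinflate(blab, mask, 7)
  expect_true(all(as.vector(mask)[as.vector(out) > 0]))
})

test_that("probability maps use the per-artery denominator", {
  d <- c(4, 4, 4)
  occ <- function(ix) { a <- array(FALSE, d); a[ix] <- TRUE; a }
  # artery present in all 3 subjects, one voxel shared by 2
  m <- build_probability_map("a", list(occ(1:2), occ(2:3), occ(3:4)))
  expect_equal(m[2], 2 / 3)
  expect_equal(attr(m, "n_included"), 3L)

  # subjects lacking the artery are excluded from the denominator
  m2 <- build_probability_map("a", list(occ(5), occ(integer(0)),
                                        occ(5:6)))
  expect_equal(m2[5], 1)        # 2 of 2 included subjects
  expect_equal(m2[6], 1 / 2)    # 1 of 2 included subjects
  expect_equal(attr(m2, "n_included"), 2L)

  # identical volumes give a 0/1 map
  m3 <- build_probability_map("a", list(occ(7:9), occ(7:9)))
  expect_setequal(unique(as.vector(m3)), c(0, 1))

  expect_error(build_probability_map("a", list(occ(integer(0)))),
               "absent")
})

test_that("probability mass is conserved exactly", {
  coh <- small_cohort()
  tl <- normalize_cohort(coh, "nonlinear")
  for (k in 1:3) {
    bins <- lapply(tl, function(lv) array(lv == k, dim(lv)))
    has <- vapply(bins, any, TRUE)
    if (!any(has)) next
    m <- build_probability_map(paste0("k", k), bins)
    expect_equal(sum(m) * attr(m, "n_included"),
                 sum(vapply(bins, sum, 1.0)))
  }
})

test_that("concatenated volume converts voxel counts to cm3", {
  d <- c(20, 20, 20)
  occ <- array(FALSE, d); occ[seq_len(1000)] <- TRUE
  m1 <- build_probability_map("a", list(occ), voxel_size_mm = 1)
  expect_equal(concatenated_volume(m1), 1.0)

  occ2 <- array(FALSE, c(20, 20, 20)); occ2[seq_len(5832)] <- TRUE
  m2 <- build_probability_map("a", list(occ2), voxel_size_mm = 0.7)
  expect_equal(concatenated_volume(m2), 5832 * 0.343 / 1000)
  expect_equal(concatenated_volume(m2), 2.000, tolerance = 1e-3)
})

test_that("the AVR is 1 for identical cohorts and 2 for disjoint halves", {
  d <- c(6, 6, 6)
  occ <- array(FALSE, d); occ[2:3, 2:3, 2:3] <- TRUE
  vols <- rep(sum(occ) * 1e-3, 5)
  m <- build_probability_map("a", rep(list(occ), 5), voxel_size_mm = 1)
  expect_identical(arterial_volume_ratio(m, vols), 1)

  occ2 <- array(FALSE, d); occ2[5, 5:6, 5] <- TRUE
  occ3 <- array(FALSE, d); occ3[1, 1:2, 1] <- TRUE
  m2 <- build_probability_map("b", list(occ2, occ3), voxel_size_mm = 1)
  expect_identical(arterial_volume_ratio(m2, rep(2e-3, 2)), 2)

  expect_error(arterial_volume_ratio(m, numeric(0)), "no subject")
  expect_error(arterial_volume_ratio(m, c(1, 0)), "positive")
})

test_that("dominating volume uses strict inequality", {
  d <- c(2, 2, 1)
  mk <- function(v, n = 2) vascatlas:::new_probability_map(
    array(v, d), "x", n, 1)
  A <- mk(c(0.5, 0.2, 0, 0)); attr(A, "artery_name") <- "A"
  B <- mk(c(0.3, 0.4, 0, 0)); attr(B, "artery_name") <- "B"
  atlas <- structure(list(maps = list(A = A, B = B), space_tag = "t"),
                     class = "vascular_atlas")
  expect_equal(dominating_volume("A", atlas), 50)
  expect_equal(dominating_volume("B", atlas), 50)

  # exact ties do not dominate
  C <- mk(c(0.5, 0.2, 0, 0)); attr(C, "artery_name") <- "C"
  atlas2 <- structure(list(maps = list(A = A, C = C), space_tag = "t"),
                      class = "vascular_atlas")
  expect_equal(dominating_volume("A", atlas2), 0)

  # single-map atlas dominates everywhere
  atlas3 <- structure(list(maps = list(A = A), space_tag = "t"),
                      class = "vascular_atlas")
  expect_equal(dominating_volume("A", atlas3), 100)
})

test_that("maximum probability hits 1 on shared voxels", {
  d <- c(3, 3, 3)
  occ1 <- array(FALSE, d); occ1[1:4] <- TRUE
  occ2 <- array(FALSE, d); occ2[4:7] <- TRUE
  m <- build_probability_map("a", list(occ1, occ2))
  expect_equal(max_probability(m), 1)

  occ3 <- array(FALSE, d); occ3[10] <- TRUE
  m2 <- build_probability_map("a", list(occ1, occ3))
  expect_equal(max_probability(m2), 0.5)

  empty <- vascatlas:::new_probability_map(array(0, d), "e", 1L, 1)
  expect_error(max_probability(empty), "empty")
})

test_that("whole-atlas AVR is the ratio of summed volumes", {
  rows <- data.frame(concatenated_volume_cm3 = c(4, 6),
                     mean_subject_volume_cm3 = c(2, 3))
  expect_equal(whole_atlas_avr(rows), 2)
  expect_equal(whole_atlas_avr(rows[1, ]),
               rows$concatenated_volume_cm3[1] /
                 rows$mean_subject_volume_cm3[1])
})

test_that("volume-conserving binarization keeps the top-k voxels", {
  v <- scalar_volume(array(c(0.9, 0.6, 0.4, 0.1, 0, 0, 0, 0), c(2, 2, 2)))
  out <- volume_conserving_binarize(v, 2)
  expect_identical(as.vector(out)[1:4], c(TRUE, TRUE, FALSE, FALSE))

  # binary input and its own volume: identity
  b <- scalar_volume(array(c(1, 1, 0, 0, 1, 0, 0, 0), c(2, 2, 2)))
  expect_equal(sum(volume_conserving_binarize(b, 3)), 3)

  # ties at the threshold are all kept
  tv <- scalar_volume(array(c(0.8, 0.5, 0.5, 0.5, 0, 0, 0, 0), c(2, 2, 2)))
  expect_equal(sum(volume_conserving_binarize(tv, 2)), 4)

  # fewer positives than the target: warn and keep all positives
  expect_warning(out2 <- volume_conserving_binarize(b, 7), "fewer")
  expect_equal(sum(out2), 3)
  expect_true(attr(out2, "underfilled"))
})

test_that("resampled arteries regain their native volume", {
  coh <- small_cohort()
  sub <- coh[[2]]
  lab <- sub$truth_labels
  k <- which(sub$presence)[1]
  native <- sum(lab == k)
  bin <- scalar_volume(array(as.numeric(lab == k), dim(lab)),
                       attr(lab, "voxel_size"), attr(lab, "affine"))
  res <- apply_transform(bin, sub$warp_to_template, "forward", "linear")
  out <- volume_conserving_binarize(res, native)
  # ties can overshoot slightly; sort-based oracle gives the bound
  vals <- sort(as.vector(res), decreasing = TRUE)
  max_with_ties <- sum(as.vector(res) >= vals[native])
  expect_gte(sum(out), native)
  expect_lte(sum(out), max_with_ties)
  expect_lt((sum(out) - native) / native, 0.02)
})

test_that("build_atlas composes maps and metrics per artery", {
  coh <- small_cohort()
  tl <- normalize_cohort(coh, "nonlinear")
  ba <- build_atlas(tl)
  present_any <- names(which(Reduce(`|`, lapply(coh, `[[`, "presence"))))
  expect_setequal(names(ba$atlas$maps), present_any)
  expect_equal(nrow(ba$metrics), length(present_any))
  expect_true(all(ba$metrics$avr >= 1))
  expect_true(all(ba$metrics$max_probability > 0 &
                    ba$metrics$max_probability <= 1))
  expect_true(all(ba$metrics$dominating_volume_pct >= 0 &
                    ba$metrics$dominating_volume_pct <= 100))

  # single-subject atlas: maps are that subject's binary arteries
  ba1 <- build_atlas(tl[1])
  for (nm in names(ba1$atlas$maps))
    expect_setequal(unique(as.vector(ba1$atlas$maps[[nm]])), c(0, 1))
})

test_that("zero-deformation cohorts give exact unit AVR and probability", {
  specs <- example_artery_specs()[1:3]
  cfg <- cohort_config(4, deform_amplitude_mm = 0, rigid_rot_deg = 0,
                       rigid_trans_mm = 0, noise_sd = 0, seed = 2)
  coh <- generate_cohort(specs, cfg)
  tl <- normalize_cohort(coh, "nonlinear")
  ba <- build_atlas(tl)
  expect_identical(unname(ba$metrics$avr), rep(1, nrow(ba$metrics)))
  expect_identical(unname(ba$metrics$max_probability),
                   rep(1, nrow(ba$metrics)))
})

test_that("atlas write/read round-trips maps and metadata", {
  coh <- small_cohort()
  ba <- build_atlas(normalize_cohort(coh, "nonlinear"))
  dir <- tempfile("atlas")
  write_atlas(ba$atlas, dir, ba$metrics)
  back <- read_atlas(dir)
  expect_setequal(names(back$maps), names(ba$atlas$maps))
  nm <- names(ba$atlas$maps)[1]
  expect_equal(as.vector(back$maps[[nm]]),
               as.vector(ba$atlas$maps[[nm]]), tolerance = 1e-6)
  expect_equal(attr(back$maps[[nm]], "n_included"),
               attr(ba$atlas$maps[[nm]], "n_included"))
  expect_true(file.exists(file.path(dir, "metrics.csv")))
  unlink(dir, recursive = TRUE)
})
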