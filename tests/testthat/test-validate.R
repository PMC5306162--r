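# minimal hand-built labeling_result for forced categorize cases
fake_result <- function(status, label_ix = integer(0), d = c(10, 10, 20),
                        branch_zr = NULL) {
  lab <- array(0L, d)
  lab[label_ix] <- 1L
  m <- array(FALSE, d)
  if (!is.null(branch_zr)) m[5, 5, branch_zr] <- TRUE else m[5, 5, 3] <- TRUE
  skel <- build_graph(binary_volume(m, 0.7))
  structure(list(status = c(a = status),
                 branches = list(a = if (status == "found")
                   vapply(skel$branches, `[[`, 1L, "id") else integer(0)),
                 labels = label_volume(lab, "a", 0.7),
                 skeleton = skel, scores = NULL),
            class = "labeling_result")
}

test_that("outcome categories cover the six cases", {
  d <- c(10, 10, 20)
  zr <- 3:17
  ix <- cbind(5, 5, zr)
  truth <- array(0L, d); truth[ix] <- 1L
  truth_v <- label_volume(truth, "a", 0.7)
  crit <- list(a = segment_criterion("a", 5))

  # perfect label of an existing artery
  auto <- fake_result("found", ix, d, zr)
  expect_identical(unname(categorize(auto, truth_v, c(a = TRUE), crit)),
                   "correctly_identified_existing")

  # absent artery reported found
  empty_truth <- label_volume(array(0L, d), "a", 0.7)
  expect_identical(unname(categorize(auto, empty_truth, c(a = FALSE),
                                     crit)),
                   "mislabeled_nonexisting")

  # absent artery reported not found
  auto_nf <- fake_result("not_found", integer(0), d)
  expect_identical(unname(categorize(auto_nf, empty_truth, c(a = FALSE),
                                     crit)),
                   "correctly_identified_nonexisting")

  # present artery not labeled
  expect_identical(unname(categorize(auto_nf, truth_v, c(a = TRUE), crit)),
                   "not_identified")

  # correct branch but too little of it: 4 voxels at 0.7 mm = 2.8 mm
  short_zr <- 3:6
  auto_short <- fake_result("found", cbind(5, 5, short_zr), d, short_zr)
  expect_identical(unname(categorize(auto_short, truth_v, c(a = TRUE),
                                     crit)),
                   "too_short")

  # label far away from the truth: mislabeled
  far <- cbind(9, 9, zr)
  auto_far <- fake_result("found", far, d, zr)
  truth_far <- array(0L, d); truth_far[cbind(2, 2, zr)] <- 1L
  expect_identical(unname(categorize(auto_far,
                                     label_volume(truth_far, "a", 0.7),
                                     c(a = TRUE), crit)),
                   "mislabeled_existing")

  expect_error(categorize(auto, label_volume(array(0L, c(4, 4, 4)), "a"),
                          c(a = TRUE)), "grids")
})

test_that("segment criteria measure connected run length in mm", {
  mk_skel <- function(n) {
    m <- array(FALSE, c(8, 8, 40))
    m[4, 4, 3:(2 + n)] <- TRUE
    build_graph(binary_volume(m, 0.7))
  }
  crit10 <- segment_criterion("a", 10)
  # 15 voxels at 0.7 mm: 10.5 mm >= 10 mm
  expect_true(check_criterion(mk_skel(15), 1L, crit10))
  # 12 voxels: 8.4 mm < 10 mm
  expect_false(check_criterion(mk_skel(12), 1L, crit10))
  # no branches assigned
  expect_false(check_criterion(mk_skel(15), integer(0), crit10))

  # a qualifying run outside the region box does not count
  box <- rbind(c(0, 0, 0), c(8 * 0.7, 8 * 0.7, 1.4))
  crit_box <- segment_criterion("a", 10, region = box)
  expect_false(check_criterion(mk_skel(15), 1L, crit_box))
  box2 <- rbind(c(0, 0, 0), c(8 * 0.7, 8 * 0.7, 28))
  expect_true(check_criterion(mk_skel(15), 1L,
                              segment_criterion("a", 10, region = box2)))

  expect_error(segment_criterion("a", 0), "min_length")
})

test_that("confusion metrics follow the rounded percentage definitions", {
  m <- confusion_metrics(data.frame(tp = 43, tn = 112, fp = 5,
                                    fn_mislabeled = 0,
                                    fn_not_identified = 7,
                                    fn_too_short = 0))
  expect_equal(m$sensitivity, 86)
  expect_equal(m$specificity, 96)
  expect_equal(m$accuracy, 93)

  m2 <- confusion_metrics(data.frame(tp = 26, tn = 124, fp = 13,
                                     fn_not_identified = 4))
  expect_equal(m2$accuracy, 90)
  expect_equal(m2$sensitivity, 87)
  expect_equal(m2$specificity, 91)

  # no negatives at all: specificity undefined
  m3 <- confusion_metrics(data.frame(tp = 167, tn = 0, fp = 0,
                                     fn_not_identified = 0))
  expect_equal(m3$sensitivity, 100)
  expect_true(is.na(m3$specificity))
  expect_equal(m3$accuracy, 100)

  # half-up rounding: 92.5 -> 93
  m4 <- confusion_metrics(data.frame(tp = 37, tn = 0, fp = 0,
                                     fn_not_identified = 3))
  expect_equal(m4$sensitivity, 93)
})

test_that("category tallies are exhaustive and sum to the cohort size", {
  set.seed(5)
  cats <- sample(vascatlas:::outcome_levels, 50, replace = TRUE)
  counts <- confusion_counts(cats)
  expect_equal(sum(unlist(counts)), 50)
  expect_error(confusion_counts(c(cats, "nonsense")))
})

test_that("exact signed-rank p-values match brute-force enumeration", {
  # all-positive differences, n = 5: p = 2/32
  a <- c(2, 3, 4, 5, 6); b <- c(1, 1, 1, 1, 1)
  expect_equal(wilcoxon_signed_rank(a, b)$p_value, 0.0625)

  # identical samples degenerate to p = 1
  expect_equal(wilcoxon_signed_rank(a, a)$p_value, 1)

  # random cases, with and without ties, against 2^n enumeration
  set.seed(31)
  for (rep in 1:6) {
    n <- sample(5:10, 1)
    x <- round(rnorm(n, 0, 2), 1)
    y <- round(rnorm(n, 0.5, 2), 1)
    got <- wilcoxon_signed_rank(x, y)$p_value
    expect_equal(got, brute_wilcoxon_p(x, y), tolerance = 1e-12)
  }

  # tie-free case agrees with the reference implementation
  x <- c(1.1, 2.3, 0.2, 4.7, 5.1, 6.0, 2.9, 3.3)
  y <- c(0.6, 2.9, 1.4, 1.2, 4.0, 5.5, 3.8, 1.0)
  expect_equal(wilcoxon_signed_rank(x, y)$p_value,
               stats::wilcox.test(x, y, paired = TRUE,
                                  exact = TRUE)$p.value,
               tolerance = 1e-12)

  expect_error(wilcoxon_signed_rank(1:3, 4:6), "5")
  expect_error(wilcoxon_signed_rank(1:5, 1:6), "equal length")
})

test_that("spearman rho matches the closed form and handles ties", {
  x <- c(3, 1, 4, 1.5, 9, 2.6, 5.3, 5.8)
  y <- c(2, 7, 1, 8, 2.8, 1.8, 2.2, 0.4)
  d <- rank(x) - rank(y)
  n <- length(x)
  expect_equal(spearman_rho(x, y), 1 - 6 * sum(d^2) / (n * (n^2 - 1)))
  expect_equal(spearman_rho(x, sort(x)[rank(x)]), 1)
  expect_equal(spearman_rho(1:7, 7:1), -1)
  # agreement with the reference implementation under ties
  xt <- c(1, 2, 2, 3, 4, 4, 5)
  yt <- c(2, 1, 3, 3, 5, 4, 6)
  expect_equal(spearman_rho(xt, yt),
               unname(stats::cor(xt, yt, method = "spearman")))
})

test_that("leave-one-out on a degenerate cohort is perfect", {
  specs <- list(
    artery_spec("left", rbind(c(8, 8, 3), c(8, 8, 24)), 1.6),
    artery_spec("right", rbind(c(20, 20, 3), c(20, 20, 24)), 1.6),
    artery_spec("ghost", rbind(c(14, 14, 3), c(14, 14, 24)), 1.6,
                prevalence = 0))
  cfg <- cohort_config(5, grid_shape = c(40, 40, 40),
                       deform_amplitude_mm = 0, rigid_rot_deg = 0,
                       rigid_trans_mm = 0, noise_sd = 0, seed = 8)
  coh <- generate_cohort(specs, cfg)
  crit <- list(left = segment_criterion("left", 8),
               right = segment_criterion("right", 8))
  loo <- leave_one_out(coh, crit)
  expect_equal(loo$mean_accuracy, 100)
  expect_true(all(loo$table$accuracy == 100))
  # the never-present artery is all true negatives
  ghost <- loo$table[loo$table$artery_name == "ghost", ]
  expect_equal(ghost$tn, 5)
  expect_equal(ghost$tp + ghost$fp + ghost$fn_mislabeled +
                 ghost$fn_not_identified + ghost$fn_too_short, 0)
  expect_error(leave_one_out(coh[1], crit), "at least 2")
})
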