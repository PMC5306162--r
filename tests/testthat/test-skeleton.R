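test_that("thinning a solid tube yields a single path of the right length", {
  m <- solid_cylinder(c(20, 20, 40), c(10, 10), 2, 5:35)
  sk <- thin(as_mask(m))
  expect_equal(r_components(array(as.vector(sk), dim(sk)), 26), 1)
  # 31 slices of tube; the centerline may lose a little at the caps
  expect_lte(abs(sum(sk) - 31), 3)
  # all skeleton voxels inside the mask
  expect_true(all(m[array(as.vector(sk), dim(sk))]))
  # within one voxel of the true centerline for at least 95% of voxels
  ijk <- which(array(as.vector(sk), dim(sk)), arr.ind = TRUE)
  off_axis <- sqrt((ijk[, 1] - 10)^2 + (ijk[, 2] - 10)^2)
  expect_gte(mean(off_axis <= 1), 0.95)
})

test_that("a one-voxel line is a fixed point of thinning", {
  m <- array(FALSE, c(10, 10, 30))
  m[5, 5, 3:27] <- TRUE
  sk <- thin(as_mask(m))
  expect_identical(array(as.vector(sk), dim(sk)), m)
})

test_that("thinning is topology preserving on components and tunnels", {
  # two separate blobs stay two components
  m <- array(FALSE, c(24, 24, 24))
  m[3:8, 3:8, 3:8] <- TRUE
  m[14:20, 14:20, 14:20] <- TRUE
  sk <- thin(as_mask(m))
  expect_equal(r_components(array(as.vector(sk), dim(sk)), 26), 2)

  # a hollow torus keeps its single cycle
  tor <- array(FALSE, c(30, 30, 10))
  for (x in 1:30) for (y in 1:30) for (z in 1:10) {
    r <- sqrt((x - 15)^2 + (y - 15)^2)
    if ((r - 8)^2 + (z - 5)^2 <= 4) tor[x, y, z] <- TRUE
  }
  sk_t <- thin(as_mask(tor))
  g <- build_graph(sk_t)
  expect_equal(vascatlas:::count_cycles(g), 1)
})

test_that("thinning never leaves a 2x2x2 solid block", {
  shapes <- list(
    solid_cylinder(c(16, 16, 30), c(8, 8), 2.5, 4:26),
    {m <- array(FALSE, c(16, 16, 16)); m[4:12, 4:12, 4:12] <- TRUE; m},
    {m <- array(FALSE, c(16, 20, 16)); m[5:11, 3:17, 7:9] <- TRUE; m})
  for (m in shapes) {
    sk <- thin(as_mask(m))
    expect_false(has_2x2x2_block(array(as.vector(sk), dim(sk))))
  }
})

test_that("thinning an empty mask errors", {
  expect_error(thin(as_mask(array(FALSE, c(4, 4, 4)))), "empty")
})

# draw a 1-voxel-wide digital segment into a mask
draw_path <- function(m, from, to) {
  n <- max(abs(to - from)) + 1
  for (t in seq(0, 1, length.out = n)) {
    p <- round(from + t * (to - from))
    m[p[1], p[2], p[3]] <- TRUE
  }
  m
}

test_that("a Y shape decomposes into three branches and one junction", {
  m <- array(FALSE, c(30, 30, 30))
  m <- draw_path(m, c(15, 15, 3), c(15, 15, 13))
  m <- draw_path(m, c(15, 15, 14), c(8, 15, 24))
  m <- draw_path(m, c(15, 15, 14), c(22, 15, 24))
  g <- build_graph(as_mask(m))
  expect_equal(length(g$branches), 3)
  expect_equal(max(g$junction_cluster), 1)
  # ids deterministic, 1..3
  expect_identical(vapply(g$branches, `[[`, 1L, "id"), 1:3)
})

test_that("an X of four arms yields four branches around one junction", {
  m <- array(FALSE, c(30, 30, 5))
  for (arm in list(c(5, 5, 3), c(25, 5, 3), c(5, 25, 3), c(25, 25, 3)))
    m <- draw_path(m, c(15, 15, 3), arm)
  g <- build_graph(as_mask(m))
  expect_equal(length(g$branches), 4)
  expect_equal(max(g$junction_cluster), 1)
})

test_that("an open path is a single branch without junctions", {
  m <- array(FALSE, c(10, 10, 30))
  m[5, 5, 3:25] <- TRUE
  g <- build_graph(as_mask(m))
  expect_equal(length(g$branches), 1)
  expect_equal(nrow(g$junctions), 0)
  expect_equal(nrow(g$branches[[1]]$path), 23)
  expect_identical(g$branches[[1]]$end_types, c("terminal", "terminal"))
})

test_that("branch decomposition partitions the skeleton voxels", {
  coh <- small_cohort()
  mask <- threshold_binarize(box_smooth(coh[[2]]$angio), 0.18)
  g <- build_graph(thin(mask))
  in_branches <- sum(vapply(g$branches, function(b) nrow(b$path), 1L))
  expect_equal(in_branches + nrow(g$junctions), nrow(g$voxels))
  # no voxel appears in two branches
  all_keys <- unlist(lapply(g$branches, `[[`, "keys"))
  expect_equal(anyDuplicated(all_keys), 0)
})

test_that("pruning removes short spurs but keeps 8-voxel branches", {
  m <- array(FALSE, c(30, 30, 10))
  m <- draw_path(m, c(3, 15, 5), c(24, 15, 5))    # main path, 22 voxels
  m <- draw_path(m, c(14, 16, 5), c(14, 20, 5))   # 5-voxel spur
  g <- build_graph(as_mask(m))
  expect_equal(length(g$branches), 3)
  p <- prune(g, 8)
  expect_equal(length(p$branches), 1)
  expect_gte(nrow(p$branches[[1]]$path), 21)      # main path survives

  # a spur branch of exactly 8 voxels is retained ("shorter than" only;
  # the spur's base voxel joins the junction cluster, so 9 drawn voxels
  # leave an 8-voxel branch)
  m2 <- array(FALSE, c(30, 30, 10))
  m2 <- draw_path(m2, c(3, 15, 5), c(24, 15, 5))
  m2 <- draw_path(m2, c(14, 16, 5), c(14, 24, 5))
  p2 <- prune(build_graph(as_mask(m2)), 8)
  expect_equal(length(p2$branches), 3)
})

test_that("cycles are broken by deleting the shortest participating branch", {
  # theta shape: two junctions joined by three paths of different length
  m <- array(FALSE, c(40, 40, 5))
  m <- draw_path(m, c(5, 20, 3), c(35, 20, 3))       # middle bar
  for (x in 6:34) {                                  # long top arc
    y <- round(20 + 10 * sin(pi * (x - 5) / 30))
    m[x, y, 3] <- TRUE
  }
  for (x in 6:34) {                                  # long bottom arc
    y <- round(20 - 10 * sin(pi * (x - 5) / 30))
    m[x, y, 3] <- TRUE
  }
  sk <- thin(as_mask(m))   # clean up double diagonals first
  g <- build_graph(sk)
  expect_gte(vascatlas:::count_cycles(g), 1)
  p <- prune(g, 3)
  expect_equal(vascatlas:::count_cycles(p), 0)
  # the longest arcs survive; total retained length dominates
  lens <- vapply(p$branches, function(b) nrow(b$path), 1L)
  expect_gte(sum(lens), 50)
})

test_that("pruning is idempotent", {
  coh <- small_cohort()
  mask <- threshold_binarize(box_smooth(coh[[3]]$angio), 0.18)
  p1 <- prune(build_graph(thin(mask)))
  p2 <- prune(p1)
  expect_identical(p1$voxels, p2$voxels)
  expect_equal(length(p1$branches), length(p2$branches))
  expect_identical(lapply(p1$branches, `[[`, "path"),
                   lapply(p2$branches, `[[`, "path"))
})

test_that("pruning a skeleton to nothing is flagged as degenerate", {
  m <- array(FALSE, c(10, 10, 10))
  m[5, 5, 4:6] <- TRUE     # 3-voxel fragment, below any sane threshold
  expect_error(prune(build_graph(as_mask(m)), 8), "degenerate")
})

test_that("skeleton serialization produces branch labels and JSON", {
  m <- array(FALSE, c(20, 20, 10))
  m <- draw_path(m, c(3, 10, 5), c(17, 10, 5))
  g <- build_graph(as_mask(m))
  lab <- skeleton_branch_labels(g)
  expect_equal(sum(lab > 0), nrow(g$voxels))
  f <- tempfile(fileext = ".json")
  write_skeleton_json(g, f)
  parsed <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(length(parsed$branches$id), 1)
  unlink(f)
})
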