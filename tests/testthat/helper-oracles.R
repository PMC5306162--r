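# Independent oracles used to check the implementation.  These are
# deliberately naive (brute force, direct enumeration) and share no
# code with the package internals.

# connected components by BFS over an explicit voxel list
r_components <- function(mask, connectivity = 26) {
  d <- dim(mask)
  idx <- which(mask, arr.ind = TRUE)
  n <- nrow(idx)
  if (n == 0) return(0L)
  key <- function(m) paste(m[, 1], m[, 2], m[, 3])
  lookup <- match(key(idx), key(idx))
  seen <- logical(n)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  if (connectivity == 6) offs <- offs[rowSums(abs(offs)) == 1, ]
  keys <- key(idx)
  comp <- 0L
  for (s in seq_len(n)) {
    if (seen[s]) next
    comp <- comp + 1L
    queue <- s
    seen[s] <- TRUE
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      nb <- sweep(offs, 2, as.numeric(idx[v, ]), "+")
      hit <- match(paste(nb[, 1], nb[, 2], nb[, 3]), keys)
      hit <- hit[!is.na(hit)]
      hit <- hit[!seen[hit]]
      seen[hit] <- TRUE
      queue <- c(queue, hit)
    }
  }
  comp
}

# direct 27-term box mean at one (interior or border) voxel
r_box_mean_at <- function(vol, at, width = 3) {
  r <- (width - 1) / 2
  d <- dim(vol)
  s <- 0
  for (dx in -r:r) for (dy in -r:r) for (dz in -r:r) {
    p <- at + c(dx, dy, dz)
    if (all(p >= 1) && all(p <= d)) s <- s + vol[p[1], p[2], p[3]]
  }
  s / width^3
}

# exact two-sided signed-rank p by enumerating all 2^n sign patterns
brute_wilcoxon_p <- function(a, b) {
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(1)
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  ws <- vapply(0:(2^n - 1), function(m) {
    signs <- as.integer(intToBits(m))[1:n]
    sum(r[signs == 1])
  }, 1.0)
  p_le <- mean(ws <= w + 1e-9)
  p_ge <- mean(ws >= w - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

# voxel-in-cylinder count for a straight tube (brute force)
r_cylinder_count <- function(p0, p1, radius, dim3, voxel) {
  cnt <- 0L
  v <- p1 - p0
  L2 <- sum(v^2)
  for (i in 0:(dim3[1] - 1)) for (j in 0:(dim3[2] - 1))
    for (k in 0:(dim3[3] - 1)) {
      p <- c(i, j, k) * voxel
      t_ <- min(1, max(0, sum((p - p0) * v) / L2))
      if (sum((p - p0 - t_ * v)^2) <= radius^2) cnt <- cnt + 1L
    }
  cnt
}

# 3^3 binary dilation by array shifting
r_dilate <- function(mask) {
  d <- dim(mask)
  out <- array(FALSE, d)
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    xs <- pmin(pmax(seq_len(d[1]) + dx, 1), d[1])
    ys <- pmin(pmax(seq_len(d[2]) + dy, 1), d[2])
    zs <- pmin(pmax(seq_len(d[3]) + dz, 1), d[3])
    out <- out | mask[xs, ys, zs]
  }
  out
}

# any 2x2x2 all-true block?
has_2x2x2_block <- function(mask) {
  d <- dim(mask)
  for (x in seq_len(d[1] - 1)) for (y in seq_len(d[2] - 1))
    for (z in seq_len(d[3] - 1))
      if (all(mask[x:(x + 1), y:(y + 1), z:(z + 1)])) return(TRUE)
  FALSE
}

# nearest labeled voxel assignment, brute force over all labeled voxels
r_nearest_label <- function(labels, mask, radius_vox) {
  d <- dim(labels)
  seeds <- which(labels > 0, arr.ind = TRUE)
  out <- array(0L, d)
  for (v in which(mask)) {
    at <- arrayInd(v, d)
    dd <- sweep(seeds, 2, as.numeric(at))
    cheb <- apply(abs(dd), 1, max)
    ok <- cheb <= radius_vox
    if (!any(ok)) next
    d2 <- rowSums(dd[ok, , drop = FALSE]^2)
    lab <- labels[seeds[ok, , drop = FALSE]]
    best <- which(d2 == min(d2))
    out[v] <- min(lab[best])
  }
  out
}
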