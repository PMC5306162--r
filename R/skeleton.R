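# ---------------------------------------------------------------------------
# Skeletonization and branch decomposition
#
# The centerline of a binary vessel tree is extracted by sequential
# topology-preserving thinning (simple-point deletion with curve
# endpoints protected), decomposed into branches separated by junction
# clusters, and pruned: terminal branches shorter than a minimum length
# are removed, and every remaining cycle is broken by deleting its
# shortest branch.
# ---------------------------------------------------------------------------

#' Thin a binary volume to a one-voxel-thick skeleton
#'
#' Sequential 3D thinning by simple-point removal: border voxels whose
#' deletion provably preserves local topology (one 26-connected
#' foreground component and one 6-connected background component in the
#' neighbourhood) are deleted shell by shell, with curve endpoints
#' protected, until no further voxel can be removed.  The result is a
#' subset of the mask with the same number of 26-connected components
#' and the same tunnels, at most one voxel thick.
#'
#' @param mask a [binary_volume()] (or 3D logical array).
#' @return A [binary_volume()] containing the skeleton voxels.
#' @export
thin <- function(mask) {
  m <- as.vector(mask) & !is.na(as.vector(mask))
  if (!any(m)) stop("cannot thin an empty mask")
  out <- .cpp_thin(array(m, dim(mask)), dim(mask))
  if (inherits(mask, "binary_volume"))
    vol_like(out, mask)
  else
    binary_volume(array(out, dim(mask)))
}

#' Label connected components
#'
#' @param mask binary volume or 3D logical array.
#' @param connectivity 6 or 26.
#' @return Integer array of component labels (0 = background).
#' @export
label_components <- function(mask, connectivity = 26L) {
  stopifnot(connectivity %in% c(6L, 26L))
  array(.cpp_label_components(array(as.vector(mask) > 0, dim(mask)),
                              dim(mask), as.integer(connectivity)),
        dim(mask))
}

# ---------------------------------------------------------------------------
# Skeleton graph
# ---------------------------------------------------------------------------

# internal representation:
#   voxels    : n x 3 integer matrix, 0-based coordinates
#   branches  : list of (id, path = m x 3 matrix, end_types = chr 2)
#   junctions : j x 3 matrix of junction voxels
#   junction_id : per junction voxel, cluster id

coord_key <- function(xyz, dims) {
  xyz[, 1] + dims[1] * (xyz[, 2] + dims[2] * xyz[, 3])
}

neighbours26_of <- function(key, keyset, dims) {
  # returns keys of 26-neighbours present in keyset (an environment hash)
  x <- key %% dims[1]
  y <- (key %/% dims[1]) %% dims[2]
  z <- key %/% (dims[1] * dims[2])
  offs <- .offs26
  nx <- x + offs[, 1]; ny <- y + offs[, 2]; nz <- z + offs[, 3]
  ok <- nx >= 0 & nx < dims[1] & ny >= 0 & ny < dims[2] &
    nz >= 0 & nz < dims[3]
  k <- nx[ok] + dims[1] * (ny[ok] + dims[2] * nz[ok])
  k[k %in% keyset]
}

.offs26 <- local({
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g[rowSums(abs(g)) > 0, , drop = FALSE]
})

#' Decompose a skeleton voxel set into a branch graph
#'
#' Skeleton voxels with three or more 26-neighbours are junction voxels;
#' mutually adjacent junction voxels are merged into junction clusters
#' (so a thick T-joint yields one junction).  The remaining voxels form
#' maximal 26-connected paths: the branches.  Each branch endpoint is
#' typed `"junction"` (adjacent to a cluster), `"terminal"` (free end)
#' or `"loop"` (the branch closes on itself with no junction).  Branch
#' ids are assigned in lexicographic scan order of each branch's
#' smallest endpoint coordinate, so the decomposition is deterministic.
#'
#' @param skel_mask a [binary_volume()] of one-voxel-thick skeleton
#'   voxels (output of [thin()]), or a `skeleton` object to recompute.
#' @return An object of class `skeleton` with fields `voxels`,
#'   `branches`, `junctions`, `junction_cluster`, `dims`, `voxel_size`,
#'   `affine`.
#' @export
build_graph <- function(skel_mask) {
  if (inherits(skel_mask, "skeleton"))
    skel_mask <- skeleton_mask(skel_mask)
  dims <- dim(skel_mask)
  m <- array(as.vector(skel_mask) > 0, dims)
  ncount <- .cpp_neighbour_counts(m, dims)
  lin <- which(as.vector(m)) - 1L
  if (!length(lin)) stop("empty skeleton")
  deg <- ncount[lin + 1L]
  is_junction <- deg >= 3L

  # junction clusters: 26-components of the junction voxels
  jmask <- array(FALSE, dims)
  jmask[lin[is_junction] + 1L] <- TRUE
  jlab <- .cpp_label_components(jmask, dims, 26L)
  junction_cluster <- jlab[lin[is_junction] + 1L]

  # branch tracing on the non-junction subgraph
  jkeys <- lin[is_junction]
  pkeys <- lin[!is_junction]
  # adjacency restricted to path voxels, from the C++ edge list
  pmask <- array(FALSE, dims)
  pmask[pkeys + 1L] <- TRUE
  edges <- .cpp_adjacency_edges(pmask, dims)
  ef <- match(edges$from, pkeys)
  et <- match(edges$to, pkeys)
  nb_list <- vector("list", length(pkeys))
  for (i in seq_along(pkeys)) nb_list[[i]] <- integer(0)
  if (length(ef)) {
    grp <- split(c(et, ef), c(ef, et))
    nb_list[as.integer(names(grp))] <- grp
  }
  deg_in_path <- lengths(nb_list)
  visited <- logical(length(pkeys))
  branches <- list()
  trace_from <- function(start) {
    path <- integer(0)
    cur <- start
    prev <- -1L
    repeat {
      visited[cur] <<- TRUE
      path <- c(path, cur)
      nxt <- setdiff(nb_list[[cur]], prev)
      nxt <- nxt[!visited[nxt]]
      if (!length(nxt)) break
      prev <- cur
      cur <- nxt[1]
    }
    path
  }
  ends <- which(deg_in_path <= 1L)
  for (s in ends) {
    if (visited[s]) next
    branches[[length(branches) + 1L]] <- trace_from(s)
  }
  # remaining unvisited path voxels belong to closed loops (all degree 2)
  for (s in seq_along(pkeys)) {
    if (visited[s]) next
    branches[[length(branches) + 1L]] <- trace_from(s)
  }

  key_to_xyz <- function(keys) {
    cbind(keys %% dims[1], (keys %/% dims[1]) %% dims[2],
          keys %/% (dims[1] * dims[2]))
  }
  jset <- jkeys
  branch_objs <- lapply(branches, function(pidx) {
    keys <- pkeys[pidx]
    xyz <- key_to_xyz(keys)
    n <- length(keys)
    end_type <- function(k) {
      adj_j <- neighbours26_of(k, jset, dims)
      if (length(adj_j)) "junction" else "terminal"
    }
    closed <- n > 2 &&
      length(neighbours26_of(keys[1], keys[n], dims)) > 0 &&
      deg_in_path[pidx[1]] == 2L && deg_in_path[pidx[n]] == 2L &&
      !length(neighbours26_of(keys[1], jset, dims)) &&
      !length(neighbours26_of(keys[n], jset, dims))
    et <- if (closed) {
      c("loop", "loop")
    } else if (n == 1L && deg[match(keys, lin)] <= 1L) {
      # pendant tip: one junction neighbour, nothing beyond -> one end
      # is the junction attachment, the other the free terminal
      c(end_type(keys[1]), "terminal")
    } else {
      c(end_type(keys[1]), end_type(keys[n]))
    }
    list(path = xyz, keys = keys, end_types = et)
  })
  # deterministic ids: order by smallest endpoint coordinate (z, y, x)
  endpoint_rank <- vapply(branch_objs, function(b) {
    e1 <- b$keys[1]
    e2 <- b$keys[length(b$keys)]
    min(e1, e2)
  }, 1.0)
  ord <- order(endpoint_rank)
  branch_objs <- branch_objs[ord]
  for (i in seq_along(branch_objs)) branch_objs[[i]]$id <- i

  structure(list(
    voxels = key_to_xyz(lin),
    branches = branch_objs,
    junctions = key_to_xyz(jkeys),
    junction_keys = jkeys,
    junction_cluster = junction_cluster,
    dims = dims,
    voxel_size = if (inherits(skel_mask, "vas_volume"))
      voxel_size(skel_mask) else rep(1, 3),
    affine = if (inherits(skel_mask, "vas_volume"))
      vol_affine(skel_mask) else default_affine(rep(1, 3))
  ), class = "skeleton")
}

#' @export
print.skeleton <- function(x, ...) {
  cat(sprintf(
    "<skeleton> %d voxels, %d branches, %d junction clusters\n",
    nrow(x$voxels), length(x$branches),
    if (length(x$junction_cluster)) max(x$junction_cluster) else 0L))
  invisible(x)
}

# binary mask of all skeleton voxels
skeleton_mask <- function(skel) {
  m <- array(FALSE, skel$dims)
  m[coord_key(skel$voxels, skel$dims) + 1L] <- TRUE
  binary_volume(m, skel$voxel_size, skel$affine)
}

branch_lengths <- function(skel)
  vapply(skel$branches, function(b) nrow(b$path), 1L)

# multigraph over junction clusters / terminal endpoints; returns an
# igraph with edge attribute branch (index into skel$branches)
skeleton_igraph <- function(skel) {
  jclust <- skel$junction_cluster
  jkeys <- skel$junction_keys
  node_of_end <- function(b, which_end) {
    k <- if (which_end == 1) b$keys[1] else b$keys[length(b$keys)]
    et <- b$end_types[which_end]
    if (et == "junction") {
      adj <- neighbours26_of(k, jkeys, skel$dims)
      cl <- jclust[match(adj, jkeys)]
      # a single-voxel branch can touch two clusters: attach each end
      # to a different one so the edge is not a spurious self-loop
      paste0("J", if (which_end == 1) cl[1] else cl[length(cl)])
    } else if (et == "loop") {
      paste0("L", b$id)
    } else {
      paste0("T", k)
    }
  }
  if (!length(skel$branches))
    return(igraph::make_empty_graph(directed = FALSE))
  edges <- do.call(rbind, lapply(skel$branches, function(b)
    c(node_of_end(b, 1), node_of_end(b, 2), b$id)))
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges[, 1], to = edges[, 2],
               branch = as.integer(edges[, 3])),
    directed = FALSE)
  g
}

count_cycles <- function(skel) {
  g <- skeleton_igraph(skel)
  igraph::ecount(g) - igraph::vcount(g) +
    igraph::count_components(g)
}

#' Prune a skeleton
#'
#' Two-phase pruning, iterated to a fixed point: (a) terminal branches
#' shorter than `min_branch_vox` voxels are removed (branches of exactly
#' `min_branch_vox` voxels are kept); (b) cycles are broken by deleting
#' the shortest branch participating in a cycle, one at a time, with the
#' graph recomputed after every removal.  The result is an acyclic
#' skeleton; pruning is idempotent.
#'
#' @param skel a `skeleton` (from [build_graph()]) or a binary skeleton
#'   mask.
#' @param min_branch_vox minimum terminal-branch length in voxels
#'   (default 8).
#' @return A pruned `skeleton`.
#' @export
prune <- function(skel, min_branch_vox = 8L) {
  if (!inherits(skel, "skeleton")) skel <- build_graph(skel)
  repeat {
    changed <- FALSE
    # (a) iterative removal of short terminal branches, shortest first
    # and one at a time: removing a side spur can reunite the branch it
    # interrupted, which must be re-measured before it is judged
    repeat {
      lens <- branch_lengths(skel)
      term <- vapply(skel$branches, function(b)
        any(b$end_types == "terminal"), TRUE)
      short <- which(term & lens < min_branch_vox)
      if (!length(short)) break
      victim <- short[order(lens[short], short)][1]
      drop_keys <- skel$branches[[victim]]$keys
      remaining <- setdiff(coord_key(skel$voxels, skel$dims), drop_keys)
      if (!length(remaining))
        stop("pruning removed every skeleton voxel; degenerate input")
      skel <- rebuild_from_keys(skel, remaining)
      changed <- TRUE
    }
    # (b) break cycles: delete the shortest branch lying on a cycle
    repeat {
      g <- skeleton_igraph(skel)
      if (igraph::ecount(g) == 0) break
      bridges <- as.integer(igraph::bridges(g))
      eb <- igraph::E(g)$branch
      loops <- which(igraph::which_loop(g))
      in_cycle <- union(setdiff(seq_len(igraph::ecount(g)), bridges), loops)
      if (!length(in_cycle)) break
      cyc_branches <- eb[in_cycle]
      lens <- branch_lengths(skel)[cyc_branches]
      victim <- cyc_branches[order(lens, cyc_branches)][1]
      vb <- skel$branches[[victim]]
      # an isolated closed ring is opened (one voxel removed), not
      # deleted wholesale; junction-anchored cycle branches are removed
      drop_keys <- if (vb$end_types[1] == "loop") vb$keys[1] else vb$keys
      remaining <- setdiff(coord_key(skel$voxels, skel$dims), drop_keys)
      if (!length(remaining))
        stop("pruning removed every skeleton voxel; degenerate input")
      skel <- rebuild_from_keys(skel, remaining)
      changed <- TRUE
    }
    if (!changed) break
  }
  skel
}

rebuild_from_keys <- function(skel, keys) {
  m <- array(FALSE, skel$dims)
  m[keys + 1L] <- TRUE
  # re-thin: removing a branch can leave redundant simple voxels (e.g.
  # a former junction voxel diagonal to a straight run), which would
  # otherwise persist as spurious junctions
  m <- array(.cpp_thin(m, skel$dims), skel$dims)
  build_graph(binary_volume(m, skel$voxel_size, skel$affine))
}

#' Render a skeleton's branches as a label volume
#'
#' Branch path voxels get their branch id; junction voxels get 0 (they
#' belong to no branch) unless `junction_value` says otherwise.
#'
#' @param skel a `skeleton`.
#' @param junction_value value for junction voxels (default 0).
#' @return A [label_volume()] of branch ids.
#' @export
skeleton_branch_labels <- function(skel, junction_value = 0L) {
  lab <- array(0L, skel$dims)
  for (b in skel$branches)
    lab[b$keys + 1L] <- b$id
  if (junction_value != 0 && length(skel$junction_keys))
    lab[skel$junction_keys + 1L] <- as.integer(junction_value)
  label_volume(lab, as.character(seq_along(skel$branches)),
               skel$voxel_size, skel$affine)
}

#' Serialize a skeleton graph to JSON
#'
#' @param skel a `skeleton`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_skeleton_json <- function(skel, path) {
  obj <- list(
    branches = lapply(skel$branches, function(b)
      list(id = b$id, voxels = unname(b$path),
           end_types = b$end_types)),
    junctions = unname(skel$junctions),
    dims = skel$dims,
    voxel_size_mm = skel$voxel_size
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
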