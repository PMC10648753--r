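# Skeleton-based pore-throat network: Euclidean distance transform,
# topology-preserving thinning, conversion of the voxel skeleton to a
# spatial graph with throat radii, and connectivity summaries.
#
# The throat radius of a segment is the minimum distance-map value along
# its polyline - the physical bottleneck between the two pore bodies it
# connects; larger throats mean better connectivity between pores.

#' Euclidean distance transform
#'
#' Exact Euclidean distance (mm) from each in-mask voxel to the nearest
#' out-of-mask voxel center; zero outside the mask. Anisotropic spacing is
#' honored. Voxels outside the grid are not treated as background, so a
#' mask spanning the full grid measures distance only to internal
#' background. A single isolated true voxel has distance one voxel spacing
#' (to its nearest false neighbor center).
#'
#' @param mask A [voxel_mask()].
#' @return A list of class `distance_map`: `values` (3D array, mm) and
#'   `spacing_mm`.
#' @export
distance_transform <- function(mask) {
  stopifnot(inherits(mask, "voxel_mask"))
  g <- mask$grid
  dsq <- cpp_edt_sq(as.logical(g), dim(g), mask$spacing_mm)
  v <- array(sqrt(dsq), dim(g))
  v[is.na(v)] <- Inf              # foreground with no background in grid
  structure(list(values = v, spacing_mm = mask$spacing_mm),
            class = "distance_map")
}

#' @export
print.distance_map <- function(x, ...) {
  f <- x$values[is.finite(x$values) & x$values > 0]
  cat(sprintf("Distance map: %s voxels, max distance %.3f mm\n",
              paste(dim(x$values), collapse = " x "),
              if (length(f)) max(f) else 0))
  invisible(x)
}

#' Skeletonize a mask
#'
#' Topology-preserving 3D curve thinning by distance-ordered homotopic
#' thinning: voxels are deleted in increasing order of their Euclidean
#' distance to the background, a voxel is deleted only if it is a simple
#' point (deletion preserves the topology of object and background), and
#' curve endpoints (voxels with exactly one 26-neighbor) and isolated
#' voxels are kept. The skeleton is a subset of the mask, has the same
#' number of connected components, and lies on the distance ridge, so a
#' straight solid cylinder reduces to an approximately 1-voxel-wide axial
#' path.
#'
#' @param mask A [voxel_mask()].
#' @return The skeleton as a [voxel_mask()].
#' @export
skeletonize <- function(mask) {
  stopifnot(inherits(mask, "voxel_mask"))
  g <- mask$grid
  sk <- cpp_thin(as.logical(g), dim(g), mask$spacing_mm)
  voxel_mask(array(sk, dim(g)), mask$spacing_mm)
}

# 26-neighbor offsets as linear-index deltas plus coordinate deltas
offsets26 <- function() {
  g <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  g[!(g$dx == 0 & g$dy == 0 & g$dz == 0), ]
}

#' Convert a voxel skeleton to a spatial pore network
#'
#' Skeleton voxels with a 26-neighbor count different from 2 become nodes
#' (endpoints and junctions); maximal voxel paths between nodes become
#' segments with a polyline, a length (sum of inter-voxel center
#' distances), and minimum/mean distance-map radii along the polyline (the
#' minimum is the throat radius). Isolated cycles are emitted as one closed
#' segment anchored at their raster-first voxel. Spurious side branches
#' shorter than `prune_factor` times the local radius at their junction are
#' pruned, and the degree-2 nodes that pruning (or node definition) leaves
#' behind are merged away.
#'
#' @param skeleton A [voxel_mask()] from [skeletonize()].
#' @param dist A `distance_map` of the mask the skeleton came from.
#' @param prune_factor Branch-pruning threshold as a multiple of the local
#'   radius; default 1.0. Set 0 to disable pruning.
#' @return A list of class `pore_network`: `nodes` (data.frame: `id`,
#'   `x_mm`, `y_mm`, `z_mm`, `radius_mm`, `degree`), `segments`
#'   (data.frame: `id`, `node_a`, `node_b`, `length_mm`, `min_radius_mm`,
#'   `mean_radius_mm`), `polylines` (list of 0-based voxel coordinate
#'   matrices), `n_components`.
#' @export
skeleton_to_graph <- function(skeleton, dist, prune_factor = 1.0) {
  stopifnot(inherits(skeleton, "voxel_mask"))
  s <- skeleton$spacing_mm
  shp <- dim(skeleton$grid)
  idx <- which(skeleton$grid)
  empty <- structure(list(
    nodes = data.frame(id = integer(0), x_mm = numeric(0), y_mm = numeric(0),
                       z_mm = numeric(0), radius_mm = numeric(0),
                       degree = integer(0)),
    segments = data.frame(id = integer(0), node_a = integer(0),
                          node_b = integer(0), length_mm = numeric(0),
                          min_radius_mm = numeric(0),
                          mean_radius_mm = numeric(0)),
    polylines = list(), n_components = 0L), class = "pore_network")
  if (length(idx) == 0L) return(empty)
  co <- arrayInd(idx, shp) - 1L                    # 0-based, raster order
  n <- length(idx)
  rad <- if (inherits(dist, "distance_map")) dist$values[idx] else rep(NA_real_, n)

  # adjacency among skeleton voxels (26-connectivity)
  off <- offsets26()
  adj <- vector("list", n)
  ord <- order(idx)                                # idx already sorted
  for (k in seq_len(nrow(off))) {
    nb <- co + matrix(as.integer(off[k, ]), n, 3, byrow = TRUE)
    ok <- nb[, 1] >= 0 & nb[, 2] >= 0 & nb[, 3] >= 0 &
      nb[, 1] < shp[1] & nb[, 2] < shp[2] & nb[, 3] < shp[3]
    nb_lin <- rep(NA_integer_, n)
    nb_lin[ok] <- nb[ok, 1] + shp[1] * (nb[ok, 2] + shp[2] * nb[ok, 3]) + 1L
    hit <- match(nb_lin, idx)
    for (i in which(!is.na(hit))) adj[[i]] <- c(adj[[i]], hit[i])
  }
  deg <- lengths(adj)
  is_node <- deg != 2L

  step_mm <- function(a, b) sqrt(sum(((co[a, ] - co[b, ]) * s)^2))

  nodes_idx <- which(is_node)
  seg_list <- list()
  used <- new.env(hash = TRUE)                     # visited directed edges
  ekey <- function(a, b) paste0(a, "_", b)
  walk <- function(start, nxt) {
    path <- c(start, nxt)
    assign(ekey(start, nxt), TRUE, envir = used)
    prev <- start; cur <- nxt
    while (!is_node[cur]) {
      nb <- adj[[cur]]
      nxt2 <- nb[nb != prev]
      if (length(nxt2) == 0L) break                # degenerate
      nxt2 <- nxt2[1]
      assign(ekey(cur, nxt2), TRUE, envir = used)
      path <- c(path, nxt2)
      prev <- cur; cur <- nxt2
    }
    assign(ekey(cur, prev), TRUE, envir = used)    # mark reverse entry
    path
  }
  for (v in nodes_idx) {
    for (nb in adj[[v]]) {
      if (exists(ekey(v, nb), envir = used)) next
      seg_list[[length(seg_list) + 1L]] <- walk(v, nb)
    }
  }
  # isolated cycles: degree-2 voxels not covered by any node walk
  covered <- logical(n)
  for (p in seg_list) covered[p] <- TRUE
  covered[nodes_idx] <- TRUE
  for (v in seq_len(n)) {
    if (covered[v] || deg[v] != 2L) next
    # anchor at raster-first voxel of the cycle, walk all the way around
    path <- c(v, adj[[v]][1])
    prev <- v; cur <- adj[[v]][1]
    while (cur != v) {
      nb <- adj[[cur]]
      nxt <- nb[nb != prev][1]
      path <- c(path, nxt)
      prev <- cur; cur <- nxt
    }
    covered[path] <- TRUE
    is_node[v] <- TRUE
    seg_list[[length(seg_list) + 1L]] <- path
  }

  seg_df <- function(paths) {
    data.frame(
      id = seq_along(paths),
      a = vapply(paths, function(p) p[1], 1L),
      b = vapply(paths, function(p) p[length(p)], 1L),
      length_mm = vapply(paths, function(p) {
        if (length(p) < 2) return(0)
        sum(vapply(seq_len(length(p) - 1L),
                   function(i) step_mm(p[i], p[i + 1]), 1.0))
      }, 1.0),
      min_radius_mm = vapply(paths, function(p) min(rad[p]), 1.0),
      mean_radius_mm = vapply(paths, function(p) mean(rad[p]), 1.0))
  }
  segs <- seg_df(seg_list)

  # prune short terminal branches: a leaf segment much shorter than the
  # radius at its junction end is a thinning artifact, not a throat
  if (prune_factor > 0 && nrow(segs) > 1) {
    repeat {
      deg_node <- table(c(segs$a, segs$b))
      leaf_end <- function(i) {
        da <- deg_node[as.character(segs$a[i])]
        db <- deg_node[as.character(segs$b[i])]
        if (da == 1 && db > 1) "a" else if (db == 1 && da > 1) "b" else NA
      }
      drop <- integer(0)
      for (i in seq_len(nrow(segs))) {
        le <- leaf_end(i)
        if (is.na(le)) next
        junction <- if (le == "a") segs$b[i] else segs$a[i]
        if (segs$length_mm[i] < prune_factor * rad[junction])
          drop <- c(drop, i)
      }
      if (length(drop) == 0L || length(drop) == nrow(segs)) break
      segs <- segs[-drop, , drop = FALSE]
      seg_list <- seg_list[-drop]
      if (length(drop)) message(sprintf("skeleton_to_graph: pruned %d spurious branch(es)", length(drop)))
    }
    # merge degree-2 junctions left by pruning
    repeat {
      deg_node <- table(c(segs$a, segs$b))
      mid <- as.integer(names(deg_node)[deg_node == 2])
      mid <- setdiff(mid, c(segs$a[segs$a == segs$b]))   # keep cycle anchors
      merged <- FALSE
      for (v in mid) {
        at <- which(segs$a == v | segs$b == v)
        if (length(at) != 2L) next
        p1 <- seg_list[[at[1]]]; p2 <- seg_list[[at[2]]]
        if (p1[1] == v) p1 <- rev(p1)
        if (p2[length(p2)] == v) p2 <- rev(p2)
        seg_list[[at[1]]] <- c(p1, p2[-1])
        seg_list <- seg_list[-at[2]]
        segs <- seg_df(seg_list)
        merged <- TRUE
        break
      }
      if (!merged) break
    }
  }

  node_ids <- sort(unique(c(segs$a, segs$b)))
  node_map <- match(seq_len(n), node_ids)
  deg_out <- tabulate(match(c(segs$a, segs$b), node_ids),
                      nbins = length(node_ids))
  nodes <- data.frame(
    id = seq_along(node_ids),
    x_mm = (co[node_ids, 1] + 0.5) * s[1],
    y_mm = (co[node_ids, 2] + 0.5) * s[2],
    z_mm = (co[node_ids, 3] + 0.5) * s[3],
    radius_mm = rad[node_ids],
    degree = deg_out)
  segments <- data.frame(id = seq_len(nrow(segs)),
                         node_a = node_map[segs$a], node_b = node_map[segs$b],
                         length_mm = segs$length_mm,
                         min_radius_mm = segs$min_radius_mm,
                         mean_radius_mm = segs$mean_radius_mm)
  # connected components of the graph (union-find over nodes)
  parent <- seq_along(node_ids)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (i in seq_len(nrow(segments))) {
    ra <- find(segments$node_a[i]); rb <- find(segments$node_b[i])
    if (ra != rb) parent[ra] <- rb
  }
  n_comp <- length(unique(vapply(seq_along(node_ids), find, 1L)))

  structure(list(nodes = nodes, segments = segments,
                 polylines = lapply(seg_list, function(p) co[p, , drop = FALSE]),
                 n_components = n_comp),
            class = "pore_network")
}

#' @export
print.pore_network <- function(x, ...) {
  cat(sprintf("Pore network: %d nodes, %d segments, %d component(s)\n",
              nrow(x$nodes), nrow(x$segments), x$n_components))
  if (nrow(x$segments) > 0)
    cat(sprintf("  total length %.2f mm, mean throat radius %.3f mm\n",
                sum(x$segments$length_mm), mean(x$segments$min_radius_mm)))
  invisible(x)
}

#' Summarize a pore network
#'
#' @param net A `pore_network`.
#' @return A one-row data.frame: `n_nodes`, `n_segments`, `n_components`,
#'   `total_length_mm`, `mean_throat_radius_mm`, `max_throat_radius_mm`,
#'   `mean_degree`. All zeros for an empty network.
#' @export
network_summary <- function(net) {
  stopifnot(inherits(net, "pore_network"))
  if (nrow(net$segments) == 0L)
    return(data.frame(n_nodes = 0L, n_segments = 0L, n_components = 0L,
                      total_length_mm = 0, mean_throat_radius_mm = 0,
                      max_throat_radius_mm = 0, mean_degree = 0))
  data.frame(n_nodes = nrow(net$nodes), n_segments = nrow(net$segments),
             n_components = net$n_components,
             total_length_mm = sum(net$segments$length_mm),
             mean_throat_radius_mm = mean(net$segments$min_radius_mm),
             max_throat_radius_mm = max(net$segments$min_radius_mm),
             mean_degree = mean(net$nodes$degree))
}

#' Write network node and edge tables as CSV
#' @param net A `pore_network`.
#' @param nodes_path,edges_path Output paths.
#' @export
write_network <- function(net, nodes_path, edges_path) {
  write.csv(net$nodes, nodes_path, row.names = FALSE)
  write.csv(net$segments, edges_path, row.names = FALSE)
  invisible(c(nodes_path, edges_path))
}
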