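# Skeleton analysis: topological thinning (Zhang-Suen), voxel
# classification (endpoint / junction / slab by 8-neighbour count), and a
# branch graph with calibrated lengths. Junction voxels that touch are merged
# into a single junction node, as in the standard skeleton-analysis tools.

#' Zhang-Suen topological thinning
#'
#' @param mask logical matrix.
#' @return logical matrix: 1-pixel-wide skeleton.
#' @export
skeletonize <- function(mask) {
  m <- mask
  nr <- nrow(m); nc <- ncol(m)
  repeat {
    changed <- FALSE
    for (sub in 1:2) {
      p <- matrix(FALSE, nr + 2L, nc + 2L)
      p[2:(nr + 1L), 2:(nc + 1L)] <- m
      sh <- function(dy, dx) p[(2 + dy):(nr + 1L + dy), (2 + dx):(nc + 1L + dx)]
      # neighbours in circular order P2..P9: N, NE, E, SE, S, SW, W, NW
      P2 <- sh(-1, 0); P3 <- sh(-1, 1); P4 <- sh(0, 1); P5 <- sh(1, 1)
      P6 <- sh(1, 0); P7 <- sh(1, -1); P8 <- sh(0, -1); P9 <- sh(-1, -1)
      B <- P2 + P3 + P4 + P5 + P6 + P7 + P8 + P9
      A <- (!P2 & P3) + (!P3 & P4) + (!P4 & P5) + (!P5 & P6) +
        (!P6 & P7) + (!P7 & P8) + (!P8 & P9) + (!P9 & P2)
      cond <- m & B >= 2 & B <= 6 & A == 1
      if (sub == 1L) {
        cond <- cond & !(P2 & P4 & P6) & !(P4 & P6 & P8)
      } else {
        cond <- cond & !(P2 & P4 & P8) & !(P2 & P6 & P8)
      }
      if (any(cond)) {
        m[cond] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m
}

# 8-neighbour count of each skeleton pixel within the skeleton.
.skel_nbr_count <- function(skel) {
  nr <- nrow(skel); nc <- ncol(skel)
  p <- matrix(FALSE, nr + 2L, nc + 2L)
  p[2:(nr + 1L), 2:(nc + 1L)] <- skel
  cnt <- matrix(0L, nr, nc)
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0L && dx == 0L) next
    cnt <- cnt + p[(2 + dy):(nr + 1L + dy), (2 + dx):(nc + 1L + dx)]
  }
  cnt
}

#' Classify skeleton voxels
#'
#' @param skel logical skeleton matrix.
#' @return integer matrix: 0 background, 1 endpoint (< 2 neighbours),
#'   2 slab (= 2), 3 junction (> 2).
#' @export
classify_skeleton <- function(skel) {
  cnt <- .skel_nbr_count(skel)
  cls <- matrix(0L, nrow(skel), ncol(skel))
  cls[skel & cnt < 2L] <- 1L
  cls[skel & cnt == 2L] <- 2L
  cls[skel & cnt > 2L] <- 3L
  cls
}

#' Build the branch graph of a skeleton
#'
#' Nodes are endpoints and junction clusters (8-connected groups of junction
#' voxels); edges are branches traced through slab voxels, weighted by their
#' calibrated euclidean path length.
#'
#' @param skel logical skeleton matrix.
#' @param calibration micrometres per pixel.
#' @return list: `nodes` (data frame id/y/x/type), `edges` (data frame
#'   from/to/length), `cls` (classification matrix).
#' @export
skeleton_graph <- function(skel, calibration = 1) {
  nr <- nrow(skel); nc <- ncol(skel)
  cls <- classify_skeleton(skel)
  nodemap <- matrix(0L, nr, nc)
  ntypes <- character(0)
  nys <- nxs <- numeric(0)
  # junction clusters
  jlab <- label_components(cls == 3L)
  nj <- attr(jlab, "n")
  for (k in seq_len(nj)) {
    idx <- which(jlab == k)
    nodemap[idx] <- k
    nys <- c(nys, mean(((idx - 1L) %% nr) + 1L))
    nxs <- c(nxs, mean(((idx - 1L) %/% nr) + 1L))
    ntypes <- c(ntypes, "junction")
  }
  ep <- which(cls == 1L)
  for (i in seq_along(ep)) {
    nodemap[ep[i]] <- nj + i
    nys <- c(nys, ((ep[i] - 1L) %% nr) + 1L)
    nxs <- c(nxs, ((ep[i] - 1L) %/% nr) + 1L)
    ntypes <- c(ntypes, "endpoint")
  }
  n_nodes <- nj + length(ep)
  step_len <- function(a, b) {
    dy <- abs(((a - 1L) %% nr) - ((b - 1L) %% nr))
    dx <- abs(((a - 1L) %/% nr) - ((b - 1L) %/% nr))
    sqrt(dy^2 + dx^2)
  }
  edges_from <- edges_to <- integer(0)
  edges_len <- numeric(0)
  add_edge <- function(a, b, len) {
    edges_from <<- c(edges_from, a)
    edges_to <<- c(edges_to, b)
    edges_len <<- c(edges_len, len * calibration)
  }
  visited <- matrix(FALSE, nr, nc)  # slab pixels consumed by a trace
  is_skel <- skel
  # trace branches leaving every node pixel through slab voxels
  node_px <- which(nodemap > 0L)
  for (p in node_px) {
    for (q in .neighbours8(p, nr, nc)) {
      if (!is_skel[q] || cls[q] != 2L || visited[q]) next
      # walk the slab path
      path_len <- step_len(p, q)
      prev <- p; cur <- q
      visited[cur] <- TRUE
      end_node <- 0L
      repeat {
        nbs <- .neighbours8(cur, nr, nc)
        nbs <- nbs[is_skel[nbs] & nbs != prev]
        # prefer continuing through slab; a node neighbour terminates
        node_nb <- nbs[nodemap[nbs] > 0L]
        slab_nb <- nbs[cls[nbs] == 2L & !visited[nbs]]
        if (length(node_nb) && (!length(slab_nb) ||
                                nodemap[node_nb[1L]] != nodemap[prev])) {
          end_node <- nodemap[node_nb[1L]]
          path_len <- path_len + step_len(cur, node_nb[1L])
          break
        }
        if (!length(slab_nb)) break  # dangling slab end (shouldn't happen)
        prev <- cur
        cur <- slab_nb[1L]
        visited[cur] <- TRUE
        path_len <- path_len + step_len(prev, cur)
      }
      if (end_node > 0L) {
        add_edge(nodemap[p], end_node, path_len)
      } else {
        add_edge(nodemap[p], nodemap[p], path_len)  # open stub back to source
      }
    }
  }
  # direct node-node adjacencies (no slab voxel between)
  seen_pairs <- character(0)
  for (p in node_px) {
    for (q in .neighbours8(p, nr, nc)) {
      if (nodemap[q] > 0L && nodemap[q] != nodemap[p] && q > p) {
        key <- paste0(min(nodemap[p], nodemap[q]), "_",
                      max(nodemap[p], nodemap[q]), "_", p, "_", q)
        # junction clusters may touch an endpoint at several pixels; count one
        pk <- paste0(min(nodemap[p], nodemap[q]), "_", max(nodemap[p], nodemap[q]))
        if (pk %in% seen_pairs) next
        seen_pairs <- c(seen_pairs, pk)
        add_edge(nodemap[p], nodemap[q], step_len(p, q))
      }
    }
  }
  # pure cycles: slab components never visited and touching no node
  left <- which(cls == 2L & !visited)
  if (length(left)) {
    sub <- matrix(FALSE, nr, nc)
    sub[left] <- TRUE
    lab <- label_components(sub)
    for (k in seq_len(attr(lab, "n"))) {
      idx <- which(lab == k)
      n_nodes <- n_nodes + 1L
      nys <- c(nys, ((idx[1L] - 1L) %% nr) + 1L)
      nxs <- c(nxs, ((idx[1L] - 1L) %/% nr) + 1L)
      ntypes <- c(ntypes, "cycle")
      add_edge(n_nodes, n_nodes, length(idx) * calibration)
    }
  }
  list(nodes = data.frame(id = seq_len(n_nodes), y = nys, x = nxs,
                          type = ntypes, stringsAsFactors = FALSE),
       edges = data.frame(from = edges_from, to = edges_to, length = edges_len),
       cls = cls)
}

#' The 11 skeleton descriptors of a cell mask
#'
#' Thins the mask, classifies voxels and traces the branch graph, reporting:
#' branches, junctions, endpoint/junction/slab voxel counts, average and
#' maximum branch length, triple points, quadruple points, longest shortest
#' path (graph diameter over calibrated branch lengths), and skeleton area.
#'
#' @param mask logical matrix (non-empty).
#' @param calibration micrometres per pixel.
#' @param lsp_mode `"diameter"` (default: maximum over vertex pairs of the
#'   geodesic distance, the standard meaning of "longest shortest path") or
#'   `"sum"` (sum of shortest paths over all vertex pairs, the alternative
#'   literal reading).
#' @return list with `features` (named numeric, 11 entries), `skeleton`
#'   (logical matrix) and `graph`.
#' @export
skeleton_descriptors <- function(mask, calibration = 1,
                                 lsp_mode = c("diameter", "sum")) {
  lsp_mode <- match.arg(lsp_mode)
  if (!any(mask)) stop("empty mask")
  skel <- skeletonize(mask)
  if (!any(skel)) skel <- mask  # mask everywhere thinner than the operator
  g <- skeleton_graph(skel, calibration)
  cls <- g$cls
  ne <- nrow(g$edges)
  deg <- tabulate(c(g$edges$from, g$edges$to), nbins = nrow(g$nodes))
  jn <- which(g$nodes$type == "junction")
  lens <- g$edges$length
  lsp <- 0
  if (ne > 0L) {
    ig <- igraph::graph_from_data_frame(g$edges[, c("from", "to")],
                                        directed = FALSE,
                                        vertices = data.frame(name = g$nodes$id))
    d <- igraph::distances(ig, weights = g$edges$length)
    d[!is.finite(d)] <- 0
    lsp <- if (lsp_mode == "diameter") max(d) else sum(d[upper.tri(d)])
  }
  feats <- c(
    "branches" = ne,
    "junctions" = length(jn),
    "endpoint voxels" = sum(cls == 1L),
    "junction voxels" = sum(cls == 3L),
    "slab voxels" = sum(cls == 2L),
    "average branch length" = if (ne) mean(lens) else 0,
    "triple points" = sum(deg[jn] == 3L),
    "quadruple points" = sum(deg[jn] == 4L),
    "maximum branch length" = if (ne) max(lens) else 0,
    "longest shortest path" = lsp,
    "skeleton area" = sum(skel) * calibration^2)
  list(features = feats, skeleton = skel, graph = g)
}
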