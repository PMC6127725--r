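#' Skeletonize a 3D mask
#'
#' Topology-preserving curve thinning: border voxels are deleted from the
#' six face directions in turn whenever they are simple points (their
#' removal changes neither the foreground 26-connectivity nor the
#' background 6-connectivity locally) and not curve endpoints. Elongated
#' patches reduce to one-voxel-wide centrelines; the number of connected
#' components is preserved.
#'
#' @param mask logical 3D array (Z, Y, X).
#' @return Logical skeleton mask, a subset of \code{mask}.
#' @export
skeletonize_frame <- function(mask) {
  d <- dim(mask)
  if (is.null(d) || length(d) != 3) abort("mask must be a 3D (Z, Y, X) array")
  if (!any(mask)) return(mask)
  array(.skeletonize3d(mask, d), d)
}

#' Remove skeleton voxels inside the cell body
#'
#' @param skeleton logical skeleton mask.
#' @param cell_body logical cell-body mask of the same shape.
#' @return \code{skeleton & !cell_body}.
#' @export
mask_skeleton <- function(skeleton, cell_body) {
  if (!identical(dim(skeleton), dim(cell_body))) {
    abort("skeleton and cell-body masks must have identical shapes")
  }
  skeleton & !cell_body
}

# 26-neighbourhood offsets in lexicographic (z, y, x) order
offsets26 <- function() {
  g <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  g <- g[!(g$dz == 0 & g$dy == 0 & g$dx == 0), ]
  m <- as.matrix(g[order(g$dz, g$dy, g$dx), c("dz", "dy", "dx")])
  dimnames(m) <- NULL
  m
}

#' Decompose a skeleton into line segments
#'
#' Labels the connected regions of a thinned mask and splits each
#' branched region into simple paths meeting only at branch voxels
#' (voxels with three or more skeleton neighbours). Redundant diagonal
#' adjacencies (chords of a one-voxel step) are pruned first so corners
#' of digitised curves are not mistaken for branches. Traversal order is
#' fixed by lexicographic (z, y, x) voxel order, making the decomposition
#' deterministic.
#'
#' @param skeleton logical skeleton mask (Z, Y, X).
#' @param frame frame index recorded in the output (1-based).
#' @param prune_spurs when positive, side branches of at most this many
#'   voxels that dead-end off a branch point are removed before the final
#'   decomposition (thinning artefacts on thick tubes), letting the main
#'   path run through the former junction uninterrupted.
#' @return A \code{\link{segment_table}}; isolated single voxels yield no
#'   segment (a path needs at least two voxels).
#' @export
split_segments <- function(skeleton, frame = 1L, prune_spurs = 0L) {
  d <- dim(skeleton)
  idx <- which(skeleton)
  if (length(idx) == 0) return(segment_table())
  i0 <- idx - 1L
  coords <- cbind(z = i0 %% d[1],
                  y = (i0 %/% d[1]) %% d[2],
                  x = i0 %/% (d[1] * d[2]))
  for (iter in 1:5) {
    res <- decompose_paths(coords, d)
    if (prune_spurs <= 0 || length(res$paths) == 0) break
    spur <- vapply(res$paths, function(p) {
      length(p) <= prune_spurs + 1L &&
        xor(res$deg[p[1]] >= 3L, res$deg[p[length(p)]] >= 3L) &&
        (res$deg[p[1]] == 1L || res$deg[p[length(p)]] == 1L)
    }, logical(1))
    if (!any(spur) || all(spur)) break
    drop_ids <- unique(unlist(lapply(res$paths[spur], function(p) {
      p[res$deg[p] < 3L] # keep the junction voxel itself
    })))
    coords <- res$coords[-drop_ids, , drop = FALSE]
    if (nrow(coords) == 0) break
  }
  res <- decompose_paths(coords, d)
  paths <- res$paths
  coords <- res$coords
  if (length(paths) == 0) return(segment_table())
  segment_table(frame = rep(as.integer(frame), length(paths)),
                segment_id = seq_along(paths),
                path = lapply(paths, function(p) coords[p, , drop = FALSE]))
}

decompose_paths <- function(coords, d) {
  o <- order(coords[, 1], coords[, 2], coords[, 3])
  coords <- coords[o, , drop = FALSE]
  n <- nrow(coords)
  key <- coords[, 1] + d[1] * (coords[, 2] + d[2] * coords[, 3])
  vol_id <- integer(prod(d))
  vol_id[key + 1] <- seq_len(n)

  off <- offsets26()
  # adjacency lists (ids), lexicographic neighbour order
  adj <- vector("list", n)
  for (i in seq_len(n)) {
    nz <- coords[i, 1] + off[, 1]
    ny <- coords[i, 2] + off[, 2]
    nx <- coords[i, 3] + off[, 3]
    ok <- nz >= 0 & nz < d[1] & ny >= 0 & ny < d[2] & nx >= 0 & nx < d[3]
    ids <- vol_id[nz[ok] + d[1] * (ny[ok] + d[2] * nx[ok]) + 1]
    adj[[i]] <- ids[ids > 0L]
  }
  # prune diagonal chords: drop edge (a, b) when some common neighbour c
  # is strictly closer to both than a is to b
  dist2 <- function(a, b) sum((coords[a, ] - coords[b, ])^2)
  for (a in seq_len(n)) {
    keep <- logical(length(adj[[a]]))
    for (j in seq_along(adj[[a]])) {
      b <- adj[[a]][j]
      dab <- dist2(a, b)
      common <- intersect(adj[[a]], adj[[b]])
      redundant <- any(vapply(common, function(cc) {
        max(dist2(a, cc), dist2(cc, b)) < dab
      }, logical(1)))
      keep[j] <- !redundant
    }
    adj[[a]] <- adj[[a]][keep]
  }
  # pruning is symmetric (the criterion depends only on the pair), so the
  # graph stays undirected
  deg <- lengths(adj)

  comp <- integer(n)
  cc <- 0L
  for (i in seq_len(n)) {
    if (comp[i] != 0L) next
    cc <- cc + 1L
    stack <- i
    comp[i] <- cc
    while (length(stack)) {
      v <- stack[length(stack)]; stack <- stack[-length(stack)]
      for (w in adj[[v]]) if (comp[w] == 0L) { comp[w] <- cc; stack <- c(stack, w) }
    }
  }

  visited <- new.env(hash = TRUE, parent = emptyenv())
  ekey <- function(a, b) paste0(min(a, b), "_", max(a, b))
  paths <- list()
  for (comp_id in seq_len(cc)) {
    nodes <- which(comp == comp_id)
    if (length(nodes) < 2) next
    terminals <- nodes[deg[nodes] == 1L | deg[nodes] >= 3L]
    if (length(terminals) == 0) {
      # pure cycle: open it at the lexicographically smallest node
      start <- nodes[1]
      path <- start
      prev <- 0L
      cur <- start
      repeat {
        nxt <- setdiff(adj[[cur]], prev)[1]
        if (is.na(nxt) || nxt == start) break
        path <- c(path, nxt)
        prev <- cur; cur <- nxt
      }
      paths[[length(paths) + 1]] <- path
      next
    }
    for (t0 in terminals) {
      for (nb in adj[[t0]]) {
        if (!is.null(visited[[ekey(t0, nb)]])) next
        path <- c(t0, nb)
        visited[[ekey(t0, nb)]] <- TRUE
        prev <- t0; cur <- nb
        while (deg[cur] == 2L) {
          nxt <- setdiff(adj[[cur]], prev)
          if (length(nxt) == 0) break
          nxt <- nxt[1]
          if (!is.null(visited[[ekey(cur, nxt)]])) break
          visited[[ekey(cur, nxt)]] <- TRUE
          if (nxt == t0) break # closed loop back to the start: keep path open
          path <- c(path, nxt)
          prev <- cur; cur <- nxt
        }
        paths[[length(paths) + 1]] <- path
      }
    }
  }
  list(paths = paths, coords = coords, deg = deg)
}
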