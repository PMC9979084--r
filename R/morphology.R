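# Internal 3D binary-array machinery: neighbour shifts, morphology,
# flood fill and connected components. All functions operate on logical
# 3D arrays and are fully vectorised; none of the installed imaging
# packages provides 3D morphology, so these primitives are local.

# linear-index coordinates (1-based) for a vector of linear indices
lin_to_coord <- function(idx, d) {
  i1 <- (idx - 1L) %% d[1] + 1L
  rest <- (idx - 1L) %/% d[1]
  i2 <- rest %% d[2] + 1L
  i3 <- rest %/% d[2] + 1L
  cbind(i1, i2, i3)
}

# 6-neighbour linear offsets and the coordinate bound they must respect
neighbour_table <- function(d) {
  strides <- c(1L, d[1], d[1] * d[2])
  list(
    offset = c(strides, -strides),
    axis   = c(1L, 2L, 3L, 1L, 2L, 3L),
    dir    = c(1L, 1L, 1L, -1L, -1L, -1L)
  )
}

# indices of in-bounds 6-neighbours of `idx`; returns a list per direction
neighbours6 <- function(idx, coord, d) {
  nt <- neighbour_table(d)
  out <- vector("list", 6L)
  for (k in seq_len(6L)) {
    ax <- nt$axis[k]
    ok <- if (nt$dir[k] > 0) coord[, ax] < d[ax] else coord[, ax] > 1L
    out[[k]] <- idx[ok] + nt$offset[k]
  }
  out
}

# Binary dilation with the 6-connected cross structuring element.
dilate6 <- function(m) {
  d <- dim(m)
  out <- m
  out[-1, , ] <- out[-1, , ] | m[-d[1], , ]
  out[-d[1], , ] <- out[-d[1], , ] | m[-1, , ]
  out[, -1, ] <- out[, -1, ] | m[, -d[2], ]
  out[, -d[2], ] <- out[, -d[2], ] | m[, -1, ]
  out[, , -1] <- out[, , -1] | m[, , -d[3]]
  out[, , -d[3]] <- out[, , -d[3]] | m[, , -1]
  out
}

# Binary erosion, 6-connected. Out-of-volume neighbours count as foreground
# so structures touching a volume face are not eaten at the face.
erode6 <- function(m) {
  d <- dim(m)
  out <- m
  out[-1, , ] <- out[-1, , ] & m[-d[1], , ]
  out[-d[1], , ] <- out[-d[1], , ] & m[-1, , ]
  out[, -1, ] <- out[, -1, ] & m[, -d[2], ]
  out[, -d[2], ] <- out[, -d[2], ] & m[, -1, ]
  out[, , -1] <- out[, , -1] & m[, , -d[3]]
  out[, , -d[3]] <- out[, , -d[3]] & m[, , -1]
  out
}

binary_closing <- function(m, iterations = 1L) {
  for (i in seq_len(iterations)) m <- dilate6(m)
  for (i in seq_len(iterations)) m <- erode6(m)
  m
}

# Flood fill of `free` (logical array) starting from all TRUE voxels on the
# volume boundary; returns the reached logical array. Used to identify the
# exterior background component.
flood_from_border <- function(free, seeds = NULL) {
  d <- dim(free)
  visited <- array(FALSE, d)
  if (is.null(seeds)) {
    border <- array(FALSE, d)
    border[c(1, d[1]), , ] <- TRUE
    border[, c(1, d[2]), ] <- TRUE
    border[, , c(1, d[3])] <- TRUE
    seeds <- which(border & free)
  } else {
    seeds <- seeds[free[seeds]]
  }
  if (length(seeds) == 0L) return(visited)
  visited[seeds] <- TRUE
  frontier <- seeds
  while (length(frontier) > 0L) {
    coord <- lin_to_coord(frontier, d)
    nb <- unlist(neighbours6(frontier, coord, d), use.names = FALSE)
    nb <- nb[free[nb] & !visited[nb]]
    if (length(nb) == 0L) break
    nb <- unique(nb)
    visited[nb] <- TRUE
    frontier <- nb
  }
  visited
}

# Exterior background: the non-mask component(s) reachable from the volume's
# corner voxels. Interior cavities (e.g. an enclosed dentin core) are not
# exterior. Falls back to all border voxels if every corner lies inside the
# mask.
exterior_background <- function(mask_arr) {
  d <- dim(mask_arr)
  corners <- as.integer(
    outer(outer(c(1L, d[1]), (c(1L, d[2]) - 1L) * d[1], `+`) - 1L,
          (c(1L, d[3]) - 1L) * d[1] * d[2], `+`) + 1L)
  free <- !mask_arr
  if (!any(free[corners])) return(flood_from_border(free))
  flood_from_border(free, seeds = corners)
}

# Connected-component labelling (6-connectivity) of a logical array via the
# voxel adjacency graph. Returns an integer array (0 = background) plus
# component sizes.
label_components <- function(m) {
  d <- dim(m)
  idx <- which(m)
  n_fg <- length(idx)
  lab <- array(0L, d)
  if (n_fg == 0L) return(list(labels = lab, sizes = integer(0)))
  map <- integer(prod(d))
  map[idx] <- seq_len(n_fg)
  coord <- lin_to_coord(idx, d)
  strides <- c(1L, d[1], d[1] * d[2])
  edges <- vector("list", 3L)
  for (ax in 1:3) {
    ok <- coord[, ax] < d[ax]
    nb <- idx[ok] + strides[ax]
    keep <- m[nb]
    edges[[ax]] <- cbind(map[idx[ok][keep]], map[nb[keep]])
  }
  em <- do.call(rbind, edges)
  if (is.null(em) || nrow(em) == 0L) {
    lab[idx] <- seq_len(n_fg)
    return(list(labels = lab, sizes = rep(1L, n_fg)))
  }
  g <- igraph::make_graph(edges = as.vector(t(em)), n = n_fg,
                          directed = FALSE)
  memb <- igraph::components(g)$membership
  lab[idx] <- memb
  list(labels = lab, sizes = tabulate(memb))
}
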