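# Internal rigid-rotation resampling. Coordinates are in voxel units
# relative to a rotation centre; `rot` maps source directions to target
# directions, so source coords of a target point are t(rot) %*% p.

# Gather with trilinear interpolation; out-of-volume reads return `fill`.
trilinear_gather <- function(vol, x, y, z, fill = 0) {
  d <- dim(vol)
  x0 <- floor(x); y0 <- floor(y); z0 <- floor(z)
  tx <- x - x0; ty <- y - y0; tz <- z - z0
  inb <- x0 >= 1 & x0 + 1 <= d[1] & y0 >= 1 & y0 + 1 <= d[2] &
    z0 >= 1 & z0 + 1 <= d[3]
  out <- rep(fill, length(x))
  if (!any(inb)) return(out)
  x0 <- x0[inb]; y0 <- y0[inb]; z0 <- z0[inb]
  tx <- tx[inb]; ty <- ty[inb]; tz <- tz[inb]
  at <- function(i, j, k) vol[cbind(i, j, k)]
  v <- at(x0, y0, z0) * (1 - tx) * (1 - ty) * (1 - tz) +
    at(x0 + 1, y0, z0) * tx * (1 - ty) * (1 - tz) +
    at(x0, y0 + 1, z0) * (1 - tx) * ty * (1 - tz) +
    at(x0 + 1, y0 + 1, z0) * tx * ty * (1 - tz) +
    at(x0, y0, z0 + 1) * (1 - tx) * (1 - ty) * tz +
    at(x0 + 1, y0, z0 + 1) * tx * (1 - ty) * tz +
    at(x0, y0 + 1, z0 + 1) * (1 - tx) * ty * tz +
    at(x0 + 1, y0 + 1, z0 + 1) * tx * ty * tz
  out[inb] <- v
  out
}

nearest_gather <- function(vol, x, y, z, fill = 0) {
  d <- dim(vol)
  xi <- round(x); yi <- round(y); zi <- round(z)
  inb <- xi >= 1 & xi <= d[1] & yi >= 1 & yi <= d[2] & zi >= 1 & zi <= d[3]
  out <- rep(fill, length(x))
  if (any(inb)) out[inb] <- vol[cbind(xi[inb], yi[inb], zi[inb])]
  out
}

# Resample `vol` onto a target grid of dims `dims_out` such that the target
# frame is the source frame rotated by `rot` about `centre_src` (voxel
# coords); the target centre sits at the middle of the output grid.
resample_rotated <- function(vol, rot, centre_src, dims_out,
                             method = c("trilinear", "nearest")) {
  method <- match.arg(method)
  centre_tgt <- (dims_out + 1) / 2
  out <- array(if (method == "nearest") FALSE else 0, dim = dims_out)
  rot_t <- t(rot)
  gx <- seq_len(dims_out[1]) - centre_tgt[1]
  gy <- seq_len(dims_out[2]) - centre_tgt[2]
  xy <- cbind(rep(gx, times = dims_out[2]), rep(gy, each = dims_out[1]))
  for (k in seq_len(dims_out[3])) {
    pz <- k - centre_tgt[3]
    src <- cbind(xy[, 1], xy[, 2], pz) %*% t(rot_t)
    sx <- src[, 1] + centre_src[1]
    sy <- src[, 2] + centre_src[2]
    sz <- src[, 3] + centre_src[3]
    out[, , k] <- if (method == "trilinear") {
      trilinear_gather(vol, sx, sy, sz)
    } else {
      nearest_gather(vol, sx, sy, sz, fill = FALSE)
    }
  }
  out
}

# Rodrigues rotation taking unit vector `u` onto unit vector `v`.
rotation_between <- function(u, v) {
  u <- u / sqrt(sum(u^2)); v <- v / sqrt(sum(v^2))
  a <- c(u[2] * v[3] - u[3] * v[2],
         u[3] * v[1] - u[1] * v[3],
         u[1] * v[2] - u[2] * v[1])
  s2 <- sum(a^2)
  cth <- sum(u * v)
  if (s2 < 1e-20) {
    if (cth > 0) return(diag(3))
    # antiparallel: rotate pi about any axis orthogonal to u
    w <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    a <- w - sum(w * u) * u
    a <- a / sqrt(sum(a^2))
    K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
    return(diag(3) + 2 * K %*% K)
  }
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + K + K %*% K * ((1 - cth) / s2)
}
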