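# Shared fixtures and independent oracles used across the suite.
# Oracles are deliberately naive (enumeration / projection algebra) and
# never call the code paths they check.

# A small, fast phantom for generic pipeline tests (48 um pitch).
small_spec <- function(seed = 1L, noise_sd = 0, age_ref = 2, voxel_um = 48,
                       ...) {
  phantom_spec(crown_length_mm = 6, enamel_thickness_mm = 0.3,
               dentin_radius_mm = 0.8, voxel_um = voxel_um, gumline_mm = 3,
               maturation_ramp_mm = 4, noise_sd = noise_sd,
               front_age_weeks = age_ref, seed = seed, ...)
}

# linear index -> 1-based coordinates
coords_of <- function(idx, d) {
  cbind((idx - 1L) %% d[1] + 1L,
        ((idx - 1L) %/% d[1]) %% d[2] + 1L,
        (idx - 1L) %/% (d[1] * d[2]) + 1L)
}

# Brute-force surface shell: exterior background found by repeated
# constrained dilation from the volume border, then all-pairs voxel-centre
# distances (chunked) between mask and exterior voxels.
oracle_shell <- function(mask_arr, depth_um, voxel_um) {
  d <- dim(mask_arr)
  border <- array(FALSE, d)
  border[c(1, d[1]), , ] <- TRUE
  border[, c(1, d[2]), ] <- TRUE
  border[, , c(1, d[3])] <- TRUE
  # find corner-connected exterior by growing from the corners only
  ext <- array(FALSE, d)
  ext[1, 1, 1] <- ext[d[1], 1, 1] <- ext[1, d[2], 1] <- ext[1, 1, d[3]] <-
    ext[d[1], d[2], 1] <- ext[d[1], 1, d[3]] <- ext[1, d[2], d[3]] <-
    ext[d[1], d[2], d[3]] <- TRUE
  ext <- ext & !mask_arr
  repeat {
    grown <- ext
    grown[-1, , ] <- grown[-1, , ] | ext[-d[1], , ]
    grown[-d[1], , ] <- grown[-d[1], , ] | ext[-1, , ]
    grown[, -1, ] <- grown[, -1, ] | ext[, -d[2], ]
    grown[, -d[2], ] <- grown[, -d[2], ] | ext[, -1, ]
    grown[, , -1] <- grown[, , -1] | ext[, , -d[3]]
    grown[, , -d[3]] <- grown[, , -d[3]] | ext[, , -1]
    grown <- grown & !mask_arr
    if (identical(grown, ext)) break
    ext <- grown
  }
  mi <- which(mask_arr)
  ei <- which(ext)
  shell <- array(FALSE, d)
  if (length(ei) == 0L || length(mi) == 0L) return(shell)
  mc <- coords_of(mi, d)
  ec <- coords_of(ei, d)
  chunk <- 1000L
  within <- logical(length(mi))
  ec2 <- rowSums(ec^2)
  for (s in seq(1L, length(mi), by = chunk)) {
    e <- min(s + chunk - 1L, length(mi))
    block <- mc[s:e, , drop = FALSE]
    d2 <- outer(rowSums(block^2), ec2, `+`) - 2 * block %*% t(ec)
    rmin <- d2[cbind(seq_len(nrow(d2)), max.col(-d2, ties.method = "first"))]
    within[s:e] <- sqrt(pmax(0, rmin)) * voxel_um <= depth_um
  }
  shell[mi[within]] <- TRUE
  shell
}

# random blob mask: union of random balls, optionally with a carved cavity
random_blob_mask <- function(seed, side = 20L, n_balls = 3L,
                             cavity = FALSE) {
  set.seed(seed)
  d <- rep(side, 3L)
  g <- expand.grid(x = 1:side, y = 1:side, z = 1:side)
  m <- rep(FALSE, nrow(g))
  for (i in seq_len(n_balls)) {
    c0 <- runif(3, side * 0.3, side * 0.7)
    r0 <- runif(1, side * 0.15, side * 0.3)
    m <- m | ((g$x - c0[1])^2 + (g$y - c0[2])^2 + (g$z - c0[3])^2 <= r0^2)
  }
  m <- array(m, d)
  if (cavity && any(m)) {
    c0 <- colMeans(coords_of(which(m), d))
    hole <- array(((g$x - c0[1])^2 + (g$y - c0[2])^2 +
                     (g$z - c0[3])^2) <= (side * 0.1)^2, d)
    m <- m & !hole
  }
  m
}

# Type III two-way ANOVA by explicit projection: sum-to-zero design
# matrices, residual sums of squares of full vs column-dropped models.
oracle_type3_anova <- function(y, A, B) {
  A <- factor(A); B <- factor(B)
  Xa <- stats::model.matrix(~A, contrasts.arg = list(A = "contr.sum"))[, -1,
                                                                       drop = FALSE]
  Xb <- stats::model.matrix(~B, contrasts.arg = list(B = "contr.sum"))[, -1,
                                                                       drop = FALSE]
  Xab <- matrix(0, length(y), ncol(Xa) * ncol(Xb))
  k <- 0L
  for (i in seq_len(ncol(Xa))) {
    for (j in seq_len(ncol(Xb))) {
      k <- k + 1L
      Xab[, k] <- Xa[, i] * Xb[, j]
    }
  }
  one <- matrix(1, length(y), 1)
  rss <- function(X) sum(stats::resid(stats::lm.fit(X, y))^2)
  X_full <- cbind(one, Xa, Xb, Xab)
  rss_full <- rss(X_full)
  rdf <- length(y) - qr(X_full)$rank
  out <- list()
  drops <- list(A = cbind(one, Xb, Xab), B = cbind(one, Xa, Xab),
                AB = cbind(one, Xa, Xb))
  dfs <- c(A = ncol(Xa), B = ncol(Xb), AB = ncol(Xab))
  for (nm in names(drops)) {
    ss <- rss(drops[[nm]]) - rss_full
    f <- (ss / dfs[[nm]]) / (rss_full / rdf)
    out[[nm]] <- c(ss = ss, df = dfs[[nm]], F = f,
                   p = stats::pf(f, dfs[[nm]], rdf, lower.tail = FALSE))
  }
  out$rss <- rss_full
  out$rdf <- rdf
  out
}

# random unbalanced hardness-style table
random_anova_table <- function(seed, max_n_per_cell = 4L) {
  set.seed(seed)
  levels_a <- c("2", "4", "16")
  levels_b <- c("below", "at", "above")
  rows <- list()
  for (a in levels_a) {
    for (b in levels_b) {
      n <- sample(1:max_n_per_cell, 1)
      rows[[paste(a, b)]] <- data.frame(
        age_weeks = as.numeric(a), level = b,
        hv = 300 + rnorm(n, 0, 40) + as.numeric(a) * runif(1, 0, 3))
    }
  }
  do.call(rbind, rows)
}
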