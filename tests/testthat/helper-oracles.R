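# Independent oracles kept deliberately naive: these re-derive quantities by
# exhaustive enumeration so the package's optimized routines are checked
# against a different code path.

# Brute-force 3D convex hull volume by facet enumeration: a triple of points
# is a hull facet iff every other point lies on one side of its plane.
brute_hull_volume <- function(pts) {
  pts <- as.matrix(pts)
  n <- nrow(pts)
  if (n < 4L) return(0)
  ctr <- colMeans(pts)
  vol <- 0
  for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
    a <- pts[i, ]; b <- pts[j, ]; c <- pts[k, ]
    nrm <- c((b[2] - a[2]) * (c[3] - a[3]) - (b[3] - a[3]) * (c[2] - a[2]),
             (b[3] - a[3]) * (c[1] - a[1]) - (b[1] - a[1]) * (c[3] - a[3]),
             (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1]))
    s <- as.numeric((pts[-c(i, j, k), , drop = FALSE] -
                       matrix(a, n - 3L, 3L, byrow = TRUE)) %*% nrm)
    if (all(s <= 0) || all(s >= 0))
      vol <- vol + abs(sum(nrm * (a - ctr))) / 6
  }
  vol
}

# Naive double-loop time-averaged MSD.
naive_msd <- function(xyz, dt) {
  n <- nrow(xyz)
  sapply(1:(n - 1), function(k) {
    acc <- 0
    for (i in 1:(n - k)) acc <- acc + sum((xyz[i + k, ] - xyz[i, ])^2)
    acc / (n - k)
  })
}

# Exhaustive structure counting on a thresholded image: R-level flood-fill
# labeling plus explicit per-pixel boundary distances (no distance
# transform), applying the area and rim filters.
brute_structure_count <- function(candidate, nucleus, threshold_um = 0.8,
                                  area_bounds = c(0.0001, 5), pixel_size) {
  lab <- matrix(0L, nrow(candidate), ncol(candidate))
  cur <- 0L
  outside <- which(!nucleus, arr.ind = TRUE)
  count <- 0L
  for (start in which(candidate)) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    px <- integer(0)
    lab[start] <- cur
    while (length(queue)) {
      idx <- queue[1L]; queue <- queue[-1L]
      px <- c(px, idx)
      r <- (idx - 1L) %% nrow(candidate) + 1L
      c0 <- (idx - 1L) %/% nrow(candidate) + 1L
      for (dr in -1:1) for (dc in -1:1) {
        r2 <- r + dr; c2 <- c0 + dc
        if (r2 < 1 || r2 > nrow(candidate) || c2 < 1 || c2 > ncol(candidate))
          next
        i2 <- r2 + (c2 - 1L) * nrow(candidate)
        if (candidate[i2] && lab[i2] == 0L) {
          lab[i2] <- cur
          queue <- c(queue, i2)
        }
      }
    }
    area <- length(px) * pixel_size^2
    rows <- (px - 1L) %% nrow(candidate) + 1L
    cols <- (px - 1L) %/% nrow(candidate) + 1L
    cy <- mean(rows); cx <- mean(cols)
    bd <- min(sqrt((outside[, 1L] - cy)^2 + (outside[, 2L] - cx)^2)) *
      pixel_size
    if (area >= area_bounds[1L] && area <= area_bounds[2L] &&
        bd > threshold_um)
      count <- count + 1L
  }
  count
}

# Random rotation matrix (QR of a Gaussian matrix, det +1).
random_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3L)))
  if (det(q) < 0) q[, 1L] <- -q[, 1L]
  q
}
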