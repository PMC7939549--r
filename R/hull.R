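#' Volume of the 3D convex hull of a point set
#'
#' Incremental (quickhull-style) construction: an initial extreme
#' tetrahedron is grown by adding each outside point, deleting the faces it
#' sees and stitching new faces along the horizon. Degenerate inputs (fewer
#' than four points, or all points collinear/coplanar within tolerance)
#' return volume 0 rather than erroring, since a locus that never leaves a
#' plane has explored zero volume.
#'
#' @param pts Numeric matrix with 3 columns (x, y, z), one row per point.
#' @return Hull volume (same cubed units as the coordinates).
#' @export
convhull3d_volume <- function(pts) {
  pts <- as.matrix(pts)
  stopifnot(ncol(pts) == 3L)
  pts <- pts[rowSums(is.finite(pts)) == 3L, , drop = FALSE]
  n <- nrow(pts)
  if (n < 4L) return(0)
  scale <- max(apply(pts, 2L, function(v) diff(range(v))))
  if (scale == 0) return(0)
  eps <- 1e-12 * scale^3

  tri_normal <- function(a, b, c) c(
    (b[2] - a[2]) * (c[3] - a[3]) - (b[3] - a[3]) * (c[2] - a[2]),
    (b[3] - a[3]) * (c[1] - a[1]) - (b[1] - a[1]) * (c[3] - a[3]),
    (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1]))

  # initial extreme tetrahedron
  i1 <- which.min(pts[, 1L])
  d1 <- sqrt(colSums((t(pts) - pts[i1, ])^2))
  i2 <- which.max(d1)
  if (d1[i2] < 1e-9 * scale) return(0)
  u <- (pts[i2, ] - pts[i1, ]) / d1[i2]
  rel <- sweep(pts, 2L, pts[i1, ])
  proj <- rel %*% u
  perp2 <- rowSums(rel^2) - proj^2
  i3 <- which.max(perp2)
  if (perp2[i3] < (1e-9 * scale)^2) return(0) # collinear
  nrm <- tri_normal(pts[i1, ], pts[i2, ], pts[i3, ])
  h <- abs(rel %*% nrm) / sqrt(sum(nrm^2))
  i4 <- which.max(h)
  if (h[i4] < 1e-9 * scale) return(0) # coplanar
  interior <- colMeans(pts[c(i1, i2, i3, i4), ])

  faces <- list(c(i1, i2, i3), c(i1, i2, i4), c(i1, i3, i4), c(i2, i3, i4))
  orient_out <- function(f) {
    nrm <- tri_normal(pts[f[1L], ], pts[f[2L], ], pts[f[3L], ])
    if (sum(nrm * (interior - pts[f[1L], ])) > 0) f[c(1L, 3L, 2L)] else f
  }
  faces <- lapply(faces, orient_out)
  normals <- lapply(faces, function(f)
    tri_normal(pts[f[1L], ], pts[f[2L], ], pts[f[3L], ]))

  rest <- setdiff(seq_len(n), c(i1, i2, i3, i4))
  for (p in rest) {
    vis <- vapply(seq_along(faces), function(fi) {
      f <- faces[[fi]]
      sum(normals[[fi]] * (pts[p, ] - pts[f[1L], ])) > eps
    }, logical(1L))
    if (!any(vis)) next
    # horizon: directed edges of visible faces whose reverse is not visible
    edges <- do.call(rbind, lapply(faces[vis], function(f)
      rbind(f[c(1L, 2L)], f[c(2L, 3L)], f[c(3L, 1L)])))
    keys <- paste(edges[, 1L], edges[, 2L])
    rev_keys <- paste(edges[, 2L], edges[, 1L])
    horizon <- edges[!(keys %in% rev_keys), , drop = FALSE]
    faces <- faces[!vis]
    normals <- normals[!vis]
    for (e in seq_len(nrow(horizon))) {
      f <- c(horizon[e, 1L], horizon[e, 2L], p)
      faces[[length(faces) + 1L]] <- f
      normals[[length(normals) + 1L]] <-
        tri_normal(pts[f[1L], ], pts[f[2L], ], pts[f[3L], ])
    }
  }
  vol <- 0
  for (fi in seq_along(faces)) {
    f <- faces[[fi]]
    vol <- vol + sum(normals[[fi]] * (pts[f[1L], ] - interior)) / 6
  }
  abs(vol)
}
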