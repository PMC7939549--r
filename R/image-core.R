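#' Multi-channel nucleus image
#'
#' Container for a fluorescence microscopy field: one or more role-tagged
#' channels (`lamin`, `dna`, ...) stored as matrices (single plane) or 3-D
#' arrays (z-stacks, dimension order y, x, z), plus the lateral pixel size.
#'
#' @param channels Named list of numeric matrices or 3-D arrays sharing
#'   identical x/y (and z) dimensions. Intensities are arbitrary units and
#'   must be non-negative.
#' @param pixel_size Lateral pixel size in micrometres per pixel.
#' @param z_step Axial step in micrometres, or `NULL` for single-plane data.
#' @return An object of class `nucleus_image`.
#' @export
nucleus_image <- function(channels, pixel_size, z_step = NULL) {
  stopifnot(is.list(channels), length(channels) >= 1L, !is.null(names(channels)))
  stop_if_not_number(pixel_size, "pixel_size", positive = TRUE)
  dims <- lapply(channels, dim)
  ref <- dims[[1L]]
  for (d in dims)
    if (!identical(d, ref))
      stop("all channels must share identical dimensions", call. = FALSE)
  for (ch in channels)
    if (any(ch < 0)) stop("intensities must be >= 0", call. = FALSE)
  structure(list(channels = channels, pixel_size = pixel_size, z_step = z_step),
            class = "nucleus_image")
}

#' @export
print.nucleus_image <- function(x, ...) {
  d <- dim(x$channels[[1L]])
  cat(sprintf("<nucleus_image> %s px, %d channel(s): %s; pixel size %.4g um\n",
              paste(d, collapse = " x "), length(x$channels),
              paste(names(x$channels), collapse = ", "), x$pixel_size))
  invisible(x)
}

get_channel <- function(image, channel) {
  if (!inherits(image, "nucleus_image")) stop("not a nucleus_image", call. = FALSE)
  ch <- image$channels[[channel]]
  if (is.null(ch)) stop(sprintf("channel '%s' not present", channel), call. = FALSE)
  ch
}

#' Project a z-stack along z
#'
#' Single-plane matrices are returned unchanged so downstream statistics treat
#' the plane as its own projection.
#'
#' @param x Matrix or 3-D array (y, x, z).
#' @param fun One of "min", "max", "mean".
#' @return A matrix.
#' @export
z_project <- function(x, fun = c("min", "max", "mean")) {
  fun <- match.arg(fun)
  if (is.matrix(x) || length(dim(x)) == 2L) return(as.matrix(x))
  if (length(dim(x)) != 3L) stop("expected a matrix or 3-D array", call. = FALSE)
  f <- switch(fun, min = pmin, max = pmax, mean = NULL)
  if (fun == "mean") return(apply(x, c(1, 2), mean))
  out <- x[, , 1L]
  nz <- dim(x)[3L]
  if (nz > 1L) for (k in 2L:nz) out <- f(out, x[, , k])
  out
}

#' Otsu automatic threshold
#'
#' Maximizes between-class variance on a 256-bin histogram; the default global
#' threshold used for nucleus segmentation.
#'
#' @param x Numeric vector/matrix of intensities.
#' @param n_bins Number of histogram bins.
#' @return Threshold value on the intensity scale; pixels strictly above it
#'   are foreground.
#' @export
otsu_threshold <- function(x, n_bins = 256L) {
  v <- as.numeric(x)
  v <- v[is.finite(v)]
  rng <- range(v)
  if (diff(rng) == 0) return(rng[1L])
  h <- tabulate(pmin(n_bins, 1L + floor((v - rng[1L]) / diff(rng) * n_bins)),
                nbins = n_bins)
  p <- h / sum(h)
  mids <- rng[1L] + (seq_len(n_bins) - 0.5) / n_bins * diff(rng)
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  sigma_b <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  sigma_b[!is.finite(sigma_b)] <- -Inf
  mids[which.max(sigma_b)]
}

#' Huang fuzzy-entropy threshold
#'
#' Minimizes the Shannon entropy of fuzzy membership (Huang & Wang), the
#' method used for intranuclear structure detection.
#'
#' @inheritParams otsu_threshold
#' @return Threshold value; pixels strictly above it are foreground.
#' @export
huang_threshold <- function(x, n_bins = 256L) {
  v <- as.numeric(x)
  v <- v[is.finite(v)]
  rng <- range(v)
  if (diff(rng) == 0) return(rng[1L])
  h <- tabulate(pmin(n_bins, 1L + floor((v - rng[1L]) / diff(rng) * n_bins)),
                nbins = n_bins)
  first <- which(h > 0)[1L]
  last <- tail(which(h > 0), 1L)
  mids <- seq_len(n_bins)
  # cumulative class means (in bin units)
  W <- cumsum(h)
  S <- cumsum(h * mids)
  Wt <- W[n_bins]; St <- S[n_bins]
  C <- (last - first) # fuzzy membership scale
  best <- Inf; best_t <- first
  for (t in first:(last - 1L)) {
    mu0 <- S[t] / W[t]
    mu1 <- (St - S[t]) / (Wt - W[t])
    # membership of bin g to its class: 1/(1 + |g - mu_class|/C)
    g <- mids
    mu <- ifelse(g <= t, 1 / (1 + abs(g - mu0) / C), 1 / (1 + abs(g - mu1) / C))
    ent <- -mu * log(mu) - (1 - mu) * log(1 - mu)
    ent[!is.finite(ent)] <- 0
    E <- sum(h * ent)
    if (E < best) { best <- E; best_t <- t }
  }
  rng[1L] + best_t / n_bins * diff(rng)
}

# Euclidean distance transform in pixels: distance from each TRUE pixel to the
# nearest FALSE pixel (0 on FALSE pixels).
distance_transform <- function(mask) {
  sqrt(.edt_sq(mask))
}

# Fill holes: background components not touching the image border become
# foreground.
fill_holes <- function(mask) {
  bg <- .cc_label(!mask, 4L)
  border <- unique(c(bg[1L, ], bg[nrow(bg), ], bg[, 1L], bg[, ncol(bg)]))
  border <- border[border > 0]
  hole <- bg > 0 & !(bg %in% border)
  dim(hole) <- dim(mask)
  mask | hole
}
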