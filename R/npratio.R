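#' Automated nucleoplasmic/peripheral intensity ratio
#'
#' The nucleoplasmic intensity is the median over nucleoplasm pixels of the
#' z-minimum projection; the peripheral intensity is the upper quartile (75th
#' percentile) over periphery pixels of the z-maximum projection. A
#' single-plane image serves as both projections. The minimum projection
#' suppresses out-of-focus peripheral light in the nucleoplasm reading, while
#' the maximum projection captures the brightest in-focus lamina section.
#'
#' @param image A [nucleus_image()] (single plane or z-stack).
#' @param part A `region_partition` from [partition_regions()].
#' @param channel Channel role measured (default `"lamin"`).
#' @return A one-row data frame (`nucleus_id`, `n_intensity`, `p_intensity`,
#'   `ratio`, `flag`). `flag` is `"ok"`, `"too-small"` (empty nucleoplasm) or
#'   `"zero-periphery"` (undefined ratio); flagged rows carry `NA` ratios.
#' @export
np_ratio_auto <- function(image, part, channel = "lamin") {
  stopifnot(inherits(part, "region_partition"))
  rec <- data.frame(nucleus_id = part$nucleus_id, n_intensity = NA_real_,
                    p_intensity = NA_real_, ratio = NA_real_, flag = "ok",
                    stringsAsFactors = FALSE)
  if (part$too_small || !any(part$periphery)) {
    rec$flag <- "too-small"
    return(rec)
  }
  ch <- get_channel(image, channel)
  minp <- z_project(ch, "min")
  maxp <- z_project(ch, "max")
  rec$n_intensity <- median(minp[part$nucleoplasm])
  rec$p_intensity <- unname(quantile(maxp[part$periphery], 0.75))
  if (rec$p_intensity == 0) {
    rec$flag <- "zero-periphery"
  } else {
    rec$ratio <- rec$n_intensity / rec$p_intensity
  }
  rec
}

#' N/P ratio of every nucleus in an image
#'
#' Convenience wrapper: segment (or use a supplied mask), partition, and
#' measure each nucleus.
#'
#' @inheritParams np_ratio_auto
#' @inheritParams partition_regions
#' @param mask Optional precomputed `nucleus_mask`.
#' @param dna_channel If present in the image, per-nucleus integrated DNA
#'   intensity is added as `dapi_integrated`.
#' @return Data frame with one row per nucleus.
#' @export
np_ratio_image <- function(image, channel = "lamin", rim_width = 0.8,
                           mask = NULL, dna_channel = "dna") {
  if (is.null(mask)) mask <- segment_nuclei(image, channel)
  parts <- partition_regions(mask, rim_width)
  recs <- do.call(rbind, lapply(parts, function(p) np_ratio_auto(image, p, channel)))
  if (is.null(recs))
    recs <- data.frame(nucleus_id = integer(), n_intensity = numeric(),
                       p_intensity = numeric(), ratio = numeric(),
                       flag = character(), stringsAsFactors = FALSE)
  if (dna_channel %in% names(image$channels) && nrow(recs) > 0)
    recs$dapi_integrated <- integrated_dapi(mask, image, dna_channel)
  recs
}

#' Extract a width-averaged line profile across a nucleus
#'
#' Samples intensities along a straight bar of the given width (default three
#' pixels, averaged perpendicular to the line) using bilinear interpolation,
#' emulating a plot-profile drawn across a nucleus.
#'
#' @param image A [nucleus_image()] or a plain matrix.
#' @param from,to Numeric `(x, y)` pixel coordinates of the bar end points.
#' @param width Bar width in pixels.
#' @param channel Channel role if `image` is a `nucleus_image`.
#' @return An object of class `line_profile`: list with `positions` (pixel
#'   index along the bar) and `intensities`.
#' @export
line_profile <- function(image, from, to, width = 3, channel = "lamin") {
  m <- if (inherits(image, "nucleus_image"))
    z_project(get_channel(image, channel), "mean") else as.matrix(image)
  v <- c(to[1L] - from[1L], to[2L] - from[2L])
  len <- sqrt(sum(v^2))
  if (len < 1) stop("line too short", call. = FALSE)
  u <- v / len
  perp <- c(-u[2L], u[1L])
  n <- floor(len) + 1L
  offs <- seq(-(width - 1) / 2, (width - 1) / 2, length.out = max(1L, width))
  vals <- vapply(seq_len(n) - 1L, function(s) {
    mean(vapply(offs, function(o) {
      x <- from[1L] + s * u[1L] + o * perp[1L]
      y <- from[2L] + s * u[2L] + o * perp[2L]
      bilinear_at(m, x, y)
    }, numeric(1L)))
  }, numeric(1L))
  structure(list(positions = seq_len(n), intensities = vals),
            class = "line_profile")
}

bilinear_at <- function(m, x, y) {
  # x = column coordinate, y = row coordinate, 1-based pixel centers
  x <- min(max(x, 1), ncol(m)); y <- min(max(y, 1), nrow(m))
  x0 <- floor(x); y0 <- floor(y)
  x1 <- min(x0 + 1L, ncol(m)); y1 <- min(y0 + 1L, nrow(m))
  fx <- x - x0; fy <- y - y0
  m[y0, x0] * (1 - fx) * (1 - fy) + m[y0, x1] * fx * (1 - fy) +
    m[y1, x0] * (1 - fx) * fy + m[y1, x1] * fx * fy
}

#' Manual (line-profile) N/P ratio
#'
#' The peripheral intensity is the mean of the two end-peak maxima (one from
#' each half of the profile); the nucleoplasmic intensity is the mean of the
#' 30 samples centred on the profile midpoint.
#'
#' @param profile A `line_profile` or plain numeric vector of intensities.
#' @param n_center Number of central samples averaged (default 30).
#' @return One-row data frame (`n_intensity`, `p_intensity`, `ratio`).
#' @export
np_ratio_line <- function(profile, n_center = 30L) {
  v <- if (inherits(profile, "line_profile")) profile$intensities
       else as.numeric(profile)
  n <- length(v)
  if (n < n_center + 2L)
    stop(sprintf("profile has %d samples; need at least %d", n, n_center + 2L),
         call. = FALSE)
  half <- floor(n / 2)
  p <- mean(c(max(v[seq_len(half)]), max(v[(half + 1L):n])))
  start <- floor((n - n_center) / 2) + 1L
  nn <- mean(v[start:(start + n_center - 1L)])
  data.frame(n_intensity = nn, p_intensity = p, ratio = nn / p)
}

#' Normalize a time series of N/P ratios to an anchor time point
#'
#' Each ratio is divided by the ratio at the anchor. The anchor is either an
#' explicit index (e.g. 1 for mitosis/early-G1 normalization) or `"auto"`,
#' which finds time point T preceding the first significant rise: the last
#' index before the first value exceeding the running baseline mean by
#' `multiple` baseline standard deviations.
#'
#' @param ratios Numeric vector, time-ordered.
#' @param anchor Integer index or `"auto"`.
#' @param multiple Baseline SD multiple for the auto rule (default 2).
#' @param min_baseline Minimum number of baseline points before a rise can be
#'   declared.
#' @return List with `normalized` (vector) and `anchor` (resolved index).
#' @export
normalize_series <- function(ratios, anchor = "auto", multiple = 2,
                             min_baseline = 2L) {
  stopifnot(is.numeric(ratios), length(ratios) >= 1L)
  if (identical(anchor, "auto")) {
    idx <- length(ratios) # fall back: no rise detected
    if (length(ratios) > min_baseline) {
      for (t in (min_baseline + 1L):length(ratios)) {
        base <- ratios[seq_len(t - 1L)]
        if (ratios[t] > mean(base) + multiple * sd(base)) { idx <- t - 1L; break }
      }
    }
    anchor <- idx
  }
  anchor <- as.integer(anchor)
  if (anchor < 1L || anchor > length(ratios))
    stop("anchor index out of range", call. = FALSE)
  if (ratios[anchor] == 0) stop("anchor ratio is zero", call. = FALSE)
  list(normalized = ratios / ratios[anchor], anchor = anchor)
}
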