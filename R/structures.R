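#' Detect extraction-resistant intranuclear structures
#'
#' Candidate structures are found by a Huang-method threshold of the lamin
#' channel inside each nucleus, labeled as connected components and measured.
#' A component is retained when its area lies within `area_bounds` and its
#' centroid is farther than `rim` from the nucleus boundary, excluding
#' signals within the peripheral lamina itself.
#'
#' @param image A [nucleus_image()].
#' @param mask A `nucleus_mask`; if `NULL`, segmented from the z-average
#'   projection with the default (Otsu) threshold.
#' @param rim Peripheral exclusion rim in micrometres (default 0.8).
#' @param area_bounds Inclusive area bounds in square micrometres
#'   (default `c(0.0001, 5)`).
#' @param channel Channel holding the structure signal.
#' @return Data frame of `ParticleRecord`s: `nucleus_id`, `area_um2`,
#'   `x_um`, `y_um` (centroid), `boundary_distance_um`.
#' @export
detect_structures <- function(image, mask = NULL, rim = 0.8,
                              area_bounds = c(0.0001, 5), channel = "lamin") {
  psz <- image$pixel_size
  if (is.null(mask)) mask <- segment_nuclei(image, channel)
  if (n_nuclei(mask) == 0) stop("mask is empty", call. = FALSE)
  proj <- z_project(get_channel(image, channel), "mean")
  empty <- data.frame(nucleus_id = integer(), area_um2 = numeric(),
                      x_um = numeric(), y_um = numeric(),
                      boundary_distance_um = numeric())
  out <- list()
  for (i in seq_len(n_nuclei(mask))) {
    inside <- unclass(mask) == i
    vals <- proj[inside]
    if (diff(range(vals)) == 0) next
    thr <- huang_threshold(vals)
    cand <- inside & proj > thr
    dim(cand) <- dim(proj)
    if (!any(cand)) next
    lab <- .cc_label(cand, 8L)
    d_boundary <- distance_transform(inside) * psz
    for (j in seq_len(max(lab))) {
      w <- which(lab == j, arr.ind = TRUE)
      area <- nrow(w) * psz^2
      cy <- mean(w[, 1L]); cx <- mean(w[, 2L])
      bd <- bilinear_at(d_boundary, cx, cy)
      if (area >= area_bounds[1L] && area <= area_bounds[2L] && bd > rim)
        out[[length(out) + 1L]] <- data.frame(
          nucleus_id = i, area_um2 = area,
          x_um = cx * psz, y_um = cy * psz, boundary_distance_um = bd)
    }
  }
  if (length(out) == 0) empty else do.call(rbind, out)
}

#' Per-cell structure counts and pooled mean area
#'
#' @param records Data frame from [detect_structures()].
#' @param n_cells Total number of cells analysed (so cells with zero
#'   structures appear with count 0); defaults to the labels present.
#' @return List with `counts` (per-cell structure count) and
#'   `mean_area_um2` (mean over all retained structures; `NA` when none).
#' @export
summarize_structures <- function(records, n_cells = NULL) {
  ids <- records$nucleus_id
  if (is.null(n_cells)) n_cells <- if (length(ids)) max(ids) else 0L
  counts <- tabulate(ids, nbins = n_cells)
  mean_area <- if (nrow(records) > 0) mean(records$area_um2) else NA_real_
  list(counts = counts, mean_area_um2 = mean_area)
}
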