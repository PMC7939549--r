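traj_columns <- c("telomere_id", "frame", "t_s", "x_um", "y_um", "z_um")

check_traj <- function(trajs) {
  miss <- setdiff(traj_columns, names(trajs))
  if (length(miss))
    stop("trajectory data lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  invisible(trajs)
}

#' Keep only complete tracks
#'
#' A telomere enters the motion analysis only when it was tracked at every
#' one of the `n_required` time points (no missing frames, no non-finite
#' coordinates); incomplete tracks are dropped, not interpolated.
#'
#' @param trajs Trajectory data frame (`telomere_id`, `frame`, `t_s`,
#'   `x_um`, `y_um`, `z_um`).
#' @param n_required Required number of time points (default 50).
#' @return The subset of rows belonging to complete tracks.
#' @export
filter_complete <- function(trajs, n_required = 50L) {
  check_traj(trajs)
  if (nrow(trajs) == 0) return(trajs)
  ok_row <- is.finite(trajs$x_um) & is.finite(trajs$y_um) & is.finite(trajs$z_um)
  counts <- tapply(ok_row & !duplicated(trajs[c("telomere_id", "frame")]),
                   trajs$telomere_id, sum)
  keep <- names(counts)[counts >= n_required]
  trajs[trajs$telomere_id %in% keep & ok_row, , drop = FALSE]
}

# least-squares rigid alignment (Kabsch): find R, t with R p + t ~ q
kabsch <- function(p, q) {
  mp <- colMeans(p); mq <- colMeans(q)
  pc <- sweep(p, 2L, mp); qc <- sweep(q, 2L, mq)
  H <- crossprod(pc, qc)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  list(rotation = R, translation = as.numeric(mq - R %*% mp))
}

#' Correct nucleus drift and rotation by rigid registration
#'
#' For every frame, the constellation of telomeres shared with frame 1 is
#' aligned to its frame-1 position by the closed-form least-squares rigid
#' transform (SVD-based optimal rotation plus translation), and the inverse
#' motion is applied to all loci of that frame. Frames with fewer than three
#' usable points are left uncorrected and flagged.
#'
#' @param trajs Trajectory data frame for one nucleus.
#' @return List with `trajectories` (corrected data frame) and `transforms`
#'   (per frame: `rotation`, `translation`, `corrected`).
#' @export
register_frames <- function(trajs) {
  check_traj(trajs)
  frames <- sort(unique(trajs$frame))
  ids <- unique(trajs$telomere_id)
  ref <- trajs[trajs$frame == frames[1L], ]
  out <- trajs
  transforms <- vector("list", length(frames))
  names(transforms) <- frames
  for (fi in seq_along(frames)) {
    f <- frames[fi]
    cur <- trajs[trajs$frame == f, ]
    shared <- intersect(ref$telomere_id, cur$telomere_id)
    p <- as.matrix(cur[match(shared, cur$telomere_id), c("x_um", "y_um", "z_um")])
    q <- as.matrix(ref[match(shared, ref$telomere_id), c("x_um", "y_um", "z_um")])
    fin <- rowSums(is.finite(p)) == 3L & rowSums(is.finite(q)) == 3L
    p <- p[fin, , drop = FALSE]; q <- q[fin, , drop = FALSE]
    collinear <- nrow(p) >= 3L &&
      svd(sweep(p, 2L, colMeans(p)))$d[2L] < 1e-9
    if (nrow(p) < 3L || collinear) {
      transforms[[fi]] <- list(rotation = diag(3), translation = c(0, 0, 0),
                               frame = f, corrected = FALSE)
      next
    }
    tr <- kabsch(p, q)
    rows <- which(out$frame == f)
    xyz <- as.matrix(out[rows, c("x_um", "y_um", "z_um")])
    out[rows, c("x_um", "y_um", "z_um")] <-
      sweep(xyz %*% t(tr$rotation), 2L, tr$translation, `+`)
    transforms[[fi]] <- list(rotation = tr$rotation,
                             translation = tr$translation,
                             frame = f, corrected = TRUE)
  }
  list(trajectories = out, transforms = transforms)
}

#' Convex-hull motion volume of one track
#'
#' The volume of nuclear space explored by a locus: the convex hull of all
#' its positions. Degenerate (collinear/coplanar) tracks give 0.
#'
#' @param traj Trajectory data frame rows of a single telomere.
#' @return Volume in cubic micrometres.
#' @export
hull_volume <- function(traj) {
  check_traj(traj)
  convhull3d_volume(as.matrix(traj[, c("x_um", "y_um", "z_um")]))
}

#' Time-averaged mean square displacement of one track
#'
#' `MSD(k dt) = mean_i |r(t_i + k dt) - r(t_i)|^2` over all ordered pairs at
#' each lag multiple of the frame interval.
#'
#' @param traj Trajectory data frame rows of a single telomere (uniform
#'   sampling assumed).
#' @return Data frame (`lag_s`, `msd_um2`), starting at lag 0 with MSD 0.
#' @export
msd <- function(traj) {
  check_traj(traj)
  traj <- traj[order(traj$frame), ]
  xyz <- as.matrix(traj[, c("x_um", "y_um", "z_um")])
  n <- nrow(xyz)
  dt <- if (n > 1L) (traj$t_s[n] - traj$t_s[1L]) / (n - 1L) else 0
  lags <- 0:(n - 1L)
  vals <- c(0, vapply(seq_len(n - 1L), function(k) {
    d <- xyz[(k + 1L):n, , drop = FALSE] - xyz[seq_len(n - k), , drop = FALSE]
    mean(rowSums(d^2))
  }, numeric(1L)))
  data.frame(lag_s = lags * dt, msd_um2 = vals)
}

#' Summarize the motion of every complete track
#'
#' @param trajs Trajectory data frame (one nucleus or pooled).
#' @param n_required Completeness filter passed to [filter_complete()].
#' @param register Apply [register_frames()] first (default `TRUE`).
#' @return List with `summaries` (per-track data frame: `telomere_id`,
#'   `hull_volume_um3`, `n_points_used`) and `msd` (list of per-track MSD
#'   curves, named by telomere id).
#' @export
motion_summary <- function(trajs, n_required = 50L, register = TRUE) {
  trajs <- filter_complete(trajs, n_required)
  if (register && nrow(trajs) > 0)
    trajs <- register_frames(trajs)$trajectories
  ids <- unique(trajs$telomere_id)
  msds <- list()
  rows <- lapply(ids, function(id) {
    tr <- trajs[trajs$telomere_id == id, ]
    msds[[as.character(id)]] <<- msd(tr)
    data.frame(telomere_id = id, hull_volume_um3 = hull_volume(tr),
               n_points_used = nrow(tr))
  })
  list(summaries = if (length(rows)) do.call(rbind, rows) else
         data.frame(telomere_id = integer(), hull_volume_um3 = numeric(),
                    n_points_used = integer()),
       msd = msds)
}

#' Population MSD curve with central band, and hull-volume box summary
#'
#' Per lag: the mean MSD over tracks and the central 70% of the population
#' (15th to 85th percentile). Hull volumes are summarized with the Tukey
#' box-plot rule.
#'
#' @param msd_list List of per-track MSD data frames on a common lag grid.
#' @param hull_volumes Optional numeric vector of per-track hull volumes.
#' @param band Lower/upper band quantiles (default `c(0.15, 0.85)`).
#' @return List with `msd_band` (data frame `lag_s`, `mean`, `lo`, `hi`) and
#'   `hull_box` (from [tukey_box()]) when volumes are given.
#' @export
population_curves <- function(msd_list, hull_volumes = NULL,
                              band = c(0.15, 0.85)) {
  if (length(msd_list) < 2L) stop("need at least 2 tracks", call. = FALSE)
  lag <- msd_list[[1L]]$lag_s
  m <- vapply(msd_list, function(d) d$msd_um2, numeric(length(lag)))
  out <- list(msd_band = data.frame(
    lag_s = lag,
    mean = rowMeans(m),
    lo = apply(m, 1L, quantile, probs = band[1L]),
    hi = apply(m, 1L, quantile, probs = band[2L])))
  if (!is.null(hull_volumes)) out$hull_box <- tukey_box(hull_volumes)
  out
}

#' Diffusion coefficient from the initial MSD slope
#'
#' Fits `MSD = 6 D lag` through the origin over the first few lags; for free
#' 3D diffusion the slope is `6 D`.
#'
#' @param msd_df MSD data frame from [msd()] (or a population mean curve
#'   with columns `lag_s` and `msd_um2`).
#' @param n_lags Number of nonzero lags used (default 5).
#' @return Estimated `D` in um^2/s.
#' @export
fit_msd_diffusion <- function(msd_df, n_lags = 5L) {
  d <- msd_df[msd_df$lag_s > 0, ][seq_len(n_lags), ]
  unname(coef(lm(msd_um2 ~ 0 + lag_s, data = d))[1L] / 6)
}
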