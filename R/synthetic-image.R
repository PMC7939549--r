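#' Configuration for synthetic nucleus images
#'
#' Describes the stated world the image generator renders: round nuclei with
#' a bright peripheral lamina rim and a dimmer nucleoplasm (the appearance of
#' a lamin-tagged cell), plus a DNA channel whose integrated density is
#' bimodal around 2C and 4C content.
#'
#' @param image_size Image side length in pixels (square field).
#' @param pixel_size Micrometres per pixel.
#' @param nucleus_radius Nucleus radius in micrometres.
#' @param rim_width_true Width of the bright peripheral rim, micrometres.
#' @param peripheral_intensity,nucleoplasm_intensity,background_intensity
#'   Intensities in arbitrary units; must satisfy
#'   peripheral >= nucleoplasm >= background >= 0.
#' @param noise_sd Gaussian noise SD added to every pixel.
#' @param n_nuclei Number of nuclei to place.
#' @param dna_2c_mean,dna_4c_mean Mean integrated DNA density of the 2C (G1)
#'   and 4C (G2) populations.
#' @param dna_cv Lognormal coefficient of variation of integrated DNA density
#'   within each population.
#' @param seed Integer seed; identical config + seed gives bit-identical
#'   output.
#' @return A validated `synthetic_nucleus_config` list.
#' @export
synthetic_nucleus_config <- function(image_size = 256L, pixel_size = 0.2,
                                     nucleus_radius = 5, rim_width_true = 0.8,
                                     peripheral_intensity = 200,
                                     nucleoplasm_intensity = 50,
                                     background_intensity = 5,
                                     noise_sd = 0, n_nuclei = 1L,
                                     dna_2c_mean = 1e5, dna_4c_mean = 2e5,
                                     dna_cv = 0.05, seed = 1L) {
  cfg <- list(image_size = as.integer(image_size), pixel_size = pixel_size,
              nucleus_radius = nucleus_radius, rim_width_true = rim_width_true,
              peripheral_intensity = peripheral_intensity,
              nucleoplasm_intensity = nucleoplasm_intensity,
              background_intensity = background_intensity, noise_sd = noise_sd,
              n_nuclei = as.integer(n_nuclei), dna_2c_mean = dna_2c_mean,
              dna_4c_mean = dna_4c_mean, dna_cv = dna_cv,
              seed = as.integer(seed))
  if (!(cfg$peripheral_intensity >= cfg$nucleoplasm_intensity &&
        cfg$nucleoplasm_intensity >= cfg$background_intensity &&
        cfg$background_intensity >= 0))
    stop("need peripheral >= nucleoplasm >= background >= 0", call. = FALSE)
  if (cfg$rim_width_true >= cfg$nucleus_radius)
    stop("rim_width_true must be smaller than nucleus_radius", call. = FALSE)
  stop_if_not_number(cfg$pixel_size, "pixel_size", positive = TRUE)
  if (cfg$noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  class(cfg) <- "synthetic_nucleus_config"
  cfg
}

# non-overlapping circle placement with bounded retries
place_nuclei <- function(cfg, max_attempts = 200L) {
  r_px <- cfg$nucleus_radius / cfg$pixel_size
  margin <- r_px + 2
  lo <- margin + 1; hi <- cfg$image_size - margin
  if (hi <= lo) stop("image too small for the requested nucleus size", call. = FALSE)
  centers <- matrix(numeric(0), ncol = 2L)
  for (i in seq_len(cfg$n_nuclei)) {
    ok <- FALSE
    for (a in seq_len(max_attempts)) {
      cand <- runif(2L, lo, hi)
      if (nrow(centers) == 0 ||
          all(sqrt(rowSums((centers - matrix(cand, nrow(centers), 2,
                                             byrow = TRUE))^2)) > 2 * r_px + 4)) {
        centers <- rbind(centers, cand)
        ok <- TRUE
        break
      }
    }
    if (!ok) stop("could not place nuclei without overlap", call. = FALSE)
  }
  centers
}

render_nuclei <- function(cfg, centers, nucleoplasm_intensity) {
  n <- cfg$image_size
  xs <- matrix(rep(seq_len(n), each = n), n, n)  # column index
  ys <- matrix(rep(seq_len(n), times = n), n, n) # row index
  r_px <- cfg$nucleus_radius / cfg$pixel_size
  rim_px <- cfg$rim_width_true / cfg$pixel_size
  lamin <- matrix(cfg$background_intensity, n, n)
  inside <- vector("list", nrow(centers))
  for (i in seq_len(nrow(centers))) {
    rho <- sqrt((xs - centers[i, 1L])^2 + (ys - centers[i, 2L])^2)
    disk <- rho <= r_px
    core <- rho <= r_px - rim_px
    lamin[disk] <- cfg$peripheral_intensity
    lamin[core] <- nucleoplasm_intensity
    inside[[i]] <- disk
  }
  list(lamin = lamin, inside = inside)
}

#' Generate a synthetic two-channel nucleus image with ground truth
#'
#' Each nucleus is a disk with a bright annulus of the configured rim width
#' at `peripheral_intensity` and an interior at `nucleoplasm_intensity`; the
#' DNA channel gives each nucleus a total integrated density drawn lognormally
#' around the 2C or 4C mean according to a random truth label.
#'
#' @param cfg A [synthetic_nucleus_config()].
#' @return List with `image` (a [nucleus_image()] with `lamin` and `dna`
#'   channels) and `truth` (data frame: per-nucleus centre, radius,
#'   `true_np_ratio`, `cycle_label`, `dna_total`).
#' @export
gen_nucleus_image <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_nucleus_config"))
  with_seed(cfg$seed, {
    n <- cfg$image_size
    if (cfg$n_nuclei == 0L) {
      lamin <- matrix(cfg$background_intensity, n, n)
      dna <- matrix(0, n, n)
      if (cfg$noise_sd > 0) {
        lamin <- pmax(lamin + rnorm(n * n, sd = cfg$noise_sd), 0)
        dna <- pmax(dna + rnorm(n * n, sd = cfg$noise_sd), 0)
      }
      return(list(image = nucleus_image(list(lamin = lamin, dna = dna),
                                        cfg$pixel_size),
                  truth = data.frame(center_x = numeric(), center_y = numeric(),
                                     radius_um = numeric(),
                                     true_np_ratio = numeric(),
                                     cycle_label = character(),
                                     dna_total = numeric())))
    }
    centers <- place_nuclei(cfg)
    rend <- render_nuclei(cfg, centers, cfg$nucleoplasm_intensity)
    lamin <- rend$lamin
    labels <- ifelse(runif(cfg$n_nuclei) < 0.5, "G1", "S-G2")
    means <- ifelse(labels == "G1", cfg$dna_2c_mean, cfg$dna_4c_mean)
    sdlog <- sqrt(log(1 + cfg$dna_cv^2))
    totals <- rlnorm(cfg$n_nuclei, meanlog = log(means) - sdlog^2 / 2,
                     sdlog = sdlog)
    dna <- matrix(0, n, n)
    for (i in seq_len(cfg$n_nuclei)) {
      npix <- sum(rend$inside[[i]])
      dna[rend$inside[[i]]] <- totals[i] / npix
    }
    if (cfg$noise_sd > 0) {
      lamin <- pmax(lamin + rnorm(n * n, sd = cfg$noise_sd), 0)
      dna <- pmax(dna + rnorm(n * n, sd = cfg$noise_sd), 0)
    }
    list(image = nucleus_image(list(lamin = lamin, dna = dna), cfg$pixel_size),
         truth = data.frame(center_x = centers[, 1L], center_y = centers[, 2L],
                            radius_um = cfg$nucleus_radius,
                            true_np_ratio = cfg$nucleoplasm_intensity /
                              cfg$peripheral_intensity,
                            cycle_label = labels, dna_total = totals,
                            stringsAsFactors = FALSE))
  })
}

#' Generate a synthetic time lapse with a prescribed N/P truth curve
#'
#' Frame t renders the nucleoplasm at `ratio_curve[t] * peripheral_intensity`
#' (nucleus placement is drawn once and shared by all frames), emulating the
#' post-mitotic redistribution of lamin from a uniform to a rim-dominated
#' pattern.
#'
#' @param cfg A [synthetic_nucleus_config()].
#' @param ratio_curve Numeric vector of true N/P ratios in (0, 1], one per
#'   frame.
#' @return List with `frames` (list of [nucleus_image()]) and `truth`
#'   (the curve plus nucleus placement).
#' @export
gen_timelapse <- function(cfg, ratio_curve) {
  stopifnot(inherits(cfg, "synthetic_nucleus_config"))
  if (length(ratio_curve) == 0) stop("ratio_curve is empty", call. = FALSE)
  if (any(ratio_curve <= 0 | ratio_curve > 1))
    stop("ratio_curve values must lie in (0, 1]", call. = FALSE)
  with_seed(cfg$seed, {
    centers <- place_nuclei(cfg)
    frames <- lapply(ratio_curve, function(rho) {
      lamin <- render_nuclei(cfg, centers, rho * cfg$peripheral_intensity)$lamin
      if (cfg$noise_sd > 0)
        lamin <- pmax(lamin + rnorm(length(lamin), sd = cfg$noise_sd), 0)
      nucleus_image(list(lamin = lamin), cfg$pixel_size)
    })
    list(frames = frames,
         truth = list(ratio_curve = ratio_curve, centers = centers,
                      radius_um = cfg$nucleus_radius))
  })
}

#' Generate a single-nucleus image carrying punctate intranuclear structures
#'
#' One nucleus is rendered at the field centre; bright spots of the stated
#' areas are drawn on the nucleoplasmic background at positions given
#' relative to the nucleus centre. The stored truth count applies the same
#' filters the structure detector uses: area within `area_bounds` and
#' centroid farther than `rim` from the nuclear boundary.
#'
#' @param spots Data frame with columns `x_um`, `y_um` (centroid offsets from
#'   the nucleus centre) and `area_um2`.
#' @param cfg A [synthetic_nucleus_config()] (only the first nucleus is
#'   used; `n_nuclei` is forced to 1).
#' @param spot_intensity Spot intensity (default: the peripheral intensity).
#' @param rim,area_bounds Truth filters, matching [detect_structures()]
#'   defaults.
#' @return List with `image`, and `truth` containing `true_structure_count`
#'   and the per-spot bookkeeping (`kept` flags).
#' @export
gen_structure_image <- function(spots, cfg, spot_intensity = NULL,
                                rim = 0.8, area_bounds = c(0.0001, 5)) {
  stopifnot(inherits(cfg, "synthetic_nucleus_config"))
  if (nrow(spots) > 0 && any(spots$area_um2 <= 0))
    stop("spot areas must be positive", call. = FALSE)
  spot_intensity <- spot_intensity %||% cfg$peripheral_intensity
  with_seed(cfg$seed, {
    n <- cfg$image_size
    ctr <- c((n + 1) / 2, (n + 1) / 2)
    rend <- render_nuclei(cfg, matrix(ctr, 1L), cfg$nucleoplasm_intensity)
    lamin <- rend$lamin
    xs <- matrix(rep(seq_len(n), each = n), n, n)
    ys <- matrix(rep(seq_len(n), times = n), n, n)
    kept <- logical(nrow(spots))
    for (i in seq_len(nrow(spots))) {
      r_um <- sqrt(spots$area_um2[i] / pi)
      d_ctr <- sqrt(spots$x_um[i]^2 + spots$y_um[i]^2)
      if (d_ctr + r_um > cfg$nucleus_radius)
        stop(sprintf("spot %d extends outside the nucleus", i), call. = FALSE)
      cx <- ctr[1L] + spots$x_um[i] / cfg$pixel_size
      cy <- ctr[2L] + spots$y_um[i] / cfg$pixel_size
      rho <- sqrt((xs - cx)^2 + (ys - cy)^2)
      lamin[rho <= r_um / cfg$pixel_size] <- spot_intensity
      boundary_dist <- cfg$nucleus_radius - d_ctr
      kept[i] <- spots$area_um2[i] >= area_bounds[1L] &&
        spots$area_um2[i] <= area_bounds[2L] && boundary_dist > rim
    }
    if (cfg$noise_sd > 0)
      lamin <- pmax(lamin + rnorm(n * n, sd = cfg$noise_sd), 0)
    list(image = nucleus_image(list(lamin = lamin), cfg$pixel_size),
         truth = list(true_structure_count = sum(kept), kept = kept,
                      center_px = ctr, radius_um = cfg$nucleus_radius))
  })
}
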