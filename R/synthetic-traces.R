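#' Configuration for synthetic continuous-photobleaching traces
#'
#' The generative surrogate for a confocal point measurement: an immobile
#' fraction bleaching fast at `k_fast` while the mobile pool, replenished by
#' exchange with the unbleached reservoir, decays slowly at `k_slow`.
#'
#' @param f_immobile_true True immobile fraction in `[0, 1]`.
#' @param k_fast,k_slow Bleaching rates (1/s); `k_fast > k_slow > 0`.
#' @param duration Trace length in seconds (default 60, one cell's point
#'   measurement).
#' @param sample_rate Sampling frequency in Hz (default 1000).
#' @param i0 Initial intensity (arbitrary units).
#' @param noise_sd Additive Gaussian noise SD (same units as `i0`).
#' @param seed Integer seed.
#' @return A validated `synthetic_cp_config` list.
#' @export
synthetic_cp_config <- function(f_immobile_true = 0.3, k_fast = 1,
                                k_slow = 0.01, duration = 60,
                                sample_rate = 1000, i0 = 1,
                                noise_sd = 0.02, seed = 1L) {
  cfg <- list(f_immobile_true = f_immobile_true, k_fast = k_fast,
              k_slow = k_slow, duration = duration,
              sample_rate = sample_rate, i0 = i0, noise_sd = noise_sd,
              seed = as.integer(seed))
  if (f_immobile_true < 0 || f_immobile_true > 1)
    stop("f_immobile_true must lie in [0, 1]", call. = FALSE)
  if (!(k_fast > k_slow && k_slow > 0))
    stop("need k_fast > k_slow > 0", call. = FALSE)
  if (duration * sample_rate < 2)
    stop("duration x sample_rate must yield at least 2 samples", call. = FALSE)
  class(cfg) <- "synthetic_cp_config"
  cfg
}

#' Generate a synthetic continuous-photobleaching trace
#'
#' `I(t) = I0 * (f * exp(-k_fast t) + (1 - f) * exp(-k_slow t))` plus
#' Gaussian noise; negative post-noise intensities are clipped at zero and
#' flagged in the metadata.
#'
#' @param cfg A [synthetic_cp_config()].
#' @return List with `trace` (data frame `t_s`, `intensity`, plus metadata
#'   attributes `sample_rate`, `duration`, `clipped`) and `truth`.
#' @export
gen_cp_trace <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_cp_config"))
  with_seed(cfg$seed, {
    t <- seq(0, cfg$duration, by = 1 / cfg$sample_rate)
    f <- cfg$f_immobile_true
    ideal <- cfg$i0 * (f * exp(-cfg$k_fast * t) + (1 - f) * exp(-cfg$k_slow * t))
    y <- ideal + if (cfg$noise_sd > 0) rnorm(length(t), sd = cfg$noise_sd) else 0
    clipped <- any(y < 0)
    y <- pmax(y, 0)
    trace <- data.frame(t_s = t, intensity = y)
    attr(trace, "sample_rate") <- cfg$sample_rate
    attr(trace, "duration") <- cfg$duration
    attr(trace, "clipped") <- clipped
    list(trace = trace,
         truth = list(true_f_immobile = f, k_fast = cfg$k_fast,
                      k_slow = cfg$k_slow, i0 = cfg$i0))
  })
}

#' Generate a synthetic FCS correlation curve from model parameters
#'
#' Evaluates the triplet-3D model on a log-spaced lag grid spanning at least
#' four decades around all diffusion times and adds per-lag Gaussian noise
#' with standard deviation `noise_rel * |G(tau)|`.
#'
#' @param params An [fcs_params()] parameter set (the generating truth).
#' @param noise_rel Relative noise level per lag (0 = noiseless).
#' @param seed Integer seed (only needed when `noise_rel > 0`).
#' @param n_per_decade Lag-grid density.
#' @param lag Optional explicit lag grid (seconds, strictly increasing).
#' @return Data frame of class `fcs_curve` with columns `lag_s`, `G`.
#' @export
gen_fcs_curve <- function(params, noise_rel = 0, seed = NULL,
                          n_per_decade = 16, lag = NULL) {
  stopifnot(inherits(params, "fcs_params"))
  if (is.null(lag)) {
    lo <- min(c(params$tau_trip / 10, min(params$tau_diff) / 100))
    hi <- max(params$tau_diff) * 1000
    if (hi / lo < 1e4) hi <- lo * 1e4
    lag <- 10^seq(log10(lo), log10(hi),
                  by = 1 / n_per_decade)
  }
  if (any(diff(lag) <= 0))
    stop("lag grid must be strictly increasing", call. = FALSE)
  g <- eval_fcs_model(params, lag)
  if (noise_rel > 0)
    g <- with_seed(seed, g + rnorm(length(g), sd = noise_rel * abs(g)))
  structure(data.frame(lag_s = lag, G = g), class = c("fcs_curve", "data.frame"))
}

#' Configuration for synthetic 3D telomere trajectories
#'
#' Trajectories of nuclear loci sampled (by default) 50 times over 20.5
#' minutes, under one of three motion models, with a shared rigid nucleus
#' drift/rotation and localization noise applied on top.
#'
#' @param motion_model `"free"`, `"anomalous"` or `"confined"`.
#' @param D_true Diffusion coefficient, um^2/s (generalized coefficient
#'   um^2/s^alpha for the anomalous model).
#' @param alpha_true Anomaly exponent (forced to 1 for free diffusion).
#' @param confinement_radius Sphere radius for the confined model, um.
#' @param n_points Time points per track (default 50).
#' @param total_time Total duration in minutes (default 20.5).
#' @param drift_velocity Rigid drift speed applied to the whole nucleus,
#'   um/s (direction drawn once per nucleus).
#' @param rotation_rate Rigid rotation about the z axis through the nucleus
#'   centre, rad/s.
#' @param n_telomeres Tracks per nucleus.
#' @param nucleus_radius Radius of the sphere in which starting positions are
#'   drawn, um.
#' @param localization_noise_sd Isotropic localization error SD, um.
#' @param seed Integer seed.
#' @return A validated `synthetic_trajectory_config` list.
#' @export
synthetic_trajectory_config <- function(motion_model = c("free", "anomalous",
                                                         "confined"),
                                        D_true = 5e-4, alpha_true = 1,
                                        confinement_radius = 0.5,
                                        n_points = 50L, total_time = 20.5,
                                        drift_velocity = 0, rotation_rate = 0,
                                        n_telomeres = 10L, nucleus_radius = 5,
                                        localization_noise_sd = 0, seed = 1L) {
  motion_model <- match.arg(motion_model)
  if (motion_model == "free") alpha_true <- 1
  cfg <- list(motion_model = motion_model, D_true = D_true,
              alpha_true = alpha_true, confinement_radius = confinement_radius,
              n_points = as.integer(n_points), total_time = total_time,
              drift_velocity = drift_velocity, rotation_rate = rotation_rate,
              n_telomeres = as.integer(n_telomeres),
              nucleus_radius = nucleus_radius,
              localization_noise_sd = localization_noise_sd,
              seed = as.integer(seed))
  if (cfg$n_points < 2L) stop("n_points must be >= 2", call. = FALSE)
  if (cfg$total_time <= 0) stop("total_time must be positive", call. = FALSE)
  if (cfg$D_true < 0) stop("D_true must be >= 0", call. = FALSE)
  if (motion_model == "confined" && cfg$confinement_radius <= 0)
    stop("confinement_radius must be positive for the confined model",
         call. = FALSE)
  if (motion_model == "anomalous" &&
      (cfg$alpha_true <= 0 || cfg$alpha_true >= 2))
    stop("alpha_true must lie in (0, 2)", call. = FALSE)
  class(cfg) <- "synthetic_trajectory_config"
  cfg
}

# fractional-Gaussian-noise increments for one axis: covariance of fGn with
# Hurst exponent H = alpha/2 and per-step variance sigma2
fgn_increments <- function(n, alpha, sigma2) {
  h2 <- alpha # = 2H
  k <- outer(seq_len(n), seq_len(n), function(i, j) abs(i - j))
  cov <- sigma2 / 2 * (abs(k + 1)^h2 - 2 * abs(k)^h2 + abs(k - 1)^h2)
  ch <- chol(cov + diag(1e-12 * sigma2, n))
  as.numeric(crossprod(ch, rnorm(n)))
}

#' Generate synthetic 3D telomere trajectories with ground truth
#'
#' Free diffusion uses Gaussian steps with per-axis variance `2 D dt`;
#' confined diffusion reflects steps at a sphere of the configured radius
#' around each track's start; anomalous diffusion uses fractional-Gaussian
#' increments with exponent `alpha_true`. All tracks of the nucleus then
#' share a rigid drift and rotation, and localization noise is added last.
#'
#' @param cfg A [synthetic_trajectory_config()].
#' @return List with `trajectories` (data frame: `telomere_id`, `nucleus_id`,
#'   `frame`, `t_s`, `x_um`, `y_um`, `z_um`) and `truth` (model parameters
#'   plus the drift/noise-free coordinates `clean`).
#' @export
gen_trajectories <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_trajectory_config"))
  with_seed(cfg$seed, {
    np <- cfg$n_points
    dt <- cfg$total_time * 60 / (np - 1)
    t_s <- (seq_len(np) - 1L) * dt
    # starting positions uniform in the nucleus sphere
    starts <- matrix(rnorm(3L * cfg$n_telomeres), ncol = 3L)
    starts <- starts / sqrt(rowSums(starts^2)) *
      cfg$nucleus_radius * runif(cfg$n_telomeres)^(1 / 3)
    clean <- vector("list", cfg$n_telomeres)
    for (i in seq_len(cfg$n_telomeres)) {
      pos <- matrix(0, np, 3L)
      pos[1L, ] <- starts[i, ]
      if (cfg$motion_model == "anomalous") {
        sigma2 <- 2 * cfg$D_true * dt^cfg$alpha_true
        steps <- vapply(1:3, function(a) fgn_increments(np - 1L,
                                                        cfg$alpha_true, sigma2),
                        numeric(np - 1L))
        pos[-1L, ] <- matrix(starts[i, ], np - 1L, 3L, byrow = TRUE) +
          apply(steps, 2L, cumsum)
      } else {
        sd_step <- sqrt(2 * cfg$D_true * dt)
        for (k in 2:np) {
          stp <- rnorm(3L, sd = sd_step)
          cand <- pos[k - 1L, ] + stp
          if (cfg$motion_model == "confined") {
            rel <- cand - starts[i, ]
            r <- sqrt(sum(rel^2))
            if (r > cfg$confinement_radius && r > 0)
              cand <- starts[i, ] + rel / r * (2 * cfg$confinement_radius - r)
          }
          pos[k, ] <- cand
        }
      }
      clean[[i]] <- pos
    }
    # shared rigid drift + rotation about z through the nucleus centre
    drift_dir <- rnorm(3L)
    drift_dir <- drift_dir / sqrt(sum(drift_dir^2))
    out <- vector("list", cfg$n_telomeres)
    for (i in seq_len(cfg$n_telomeres)) {
      pos <- clean[[i]]
      moved <- pos
      for (k in seq_len(np)) {
        th <- cfg$rotation_rate * t_s[k]
        R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3L)
        moved[k, ] <- as.numeric(R %*% pos[k, ]) +
          drift_dir * cfg$drift_velocity * t_s[k]
      }
      if (cfg$localization_noise_sd > 0)
        moved <- moved + matrix(rnorm(np * 3L, sd = cfg$localization_noise_sd),
                                np, 3L)
      out[[i]] <- data.frame(telomere_id = i, nucleus_id = 1L,
                             frame = seq_len(np), t_s = t_s,
                             x_um = moved[, 1L], y_um = moved[, 2L],
                             z_um = moved[, 3L])
    }
    list(trajectories = do.call(rbind, out),
         truth = list(motion_model = cfg$motion_model, D_true = cfg$D_true,
                      alpha_true = cfg$alpha_true,
                      confinement_radius = cfg$confinement_radius,
                      drift_velocity = cfg$drift_velocity,
                      drift_dir = drift_dir,
                      rotation_rate = cfg$rotation_rate, dt = dt,
                      clean = clean))
  })
}
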