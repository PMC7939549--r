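test_that("complete-track filtering follows the all-frames rule", {
  gen <- gen_trajectories(synthetic_trajectory_config(n_telomeres = 3L,
                                                      seed = 1L))
  trajs <- gen$trajectories
  # drop one frame of telomere 2
  holed <- trajs[!(trajs$telomere_id == 2 & trajs$frame == 17), ]
  kept <- filter_complete(holed, 50L)
  expect_setequal(unique(kept$telomere_id), c(1L, 3L))
  expect_equal(nrow(filter_complete(trajs[0, ], 50L)), 0L)
  # NA coordinates count as missing
  nad <- trajs
  nad$x_um[nad$telomere_id == 1 & nad$frame == 5] <- NA
  expect_setequal(unique(filter_complete(nad, 50L)$telomere_id), c(2L, 3L))
})

test_that("rigid registration recovers known transforms exactly", {
  # rigid constellation (no diffusion) so the transform is exactly
  # identifiable
  gen <- gen_trajectories(synthetic_trajectory_config(
    n_telomeres = 6L, D_true = 0, seed = 8L))
  trajs <- gen$trajectories
  # static nucleus: identity transforms
  reg0 <- register_frames(trajs)
  for (tr in reg0$transforms[2:5]) expect_true(tr$corrected)
  # apply a known rotation + translation to one frame
  R <- random_rotation()
  v <- c(0.8, -0.3, 0.5)
  moved <- trajs
  sel <- moved$frame == 25
  xyz <- as.matrix(moved[sel, c("x_um", "y_um", "z_um")])
  moved[sel, c("x_um", "y_um", "z_um")] <- sweep(xyz %*% t(R), 2L, v, `+`)
  reg <- register_frames(moved)
  tr <- reg$transforms[["25"]]
  # the estimated correction is the inverse motion
  expect_equal(tr$rotation %*% R, diag(3), tolerance = 1e-9)
  expect_equal(as.numeric(tr$rotation %*% v + tr$translation), c(0, 0, 0),
               tolerance = 1e-9)
  expect_equal(as.matrix(reg$trajectories[sel, c("x_um", "y_um", "z_um")]),
               as.matrix(trajs[sel, c("x_um", "y_um", "z_um")]),
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("registration residuals stay bounded by the localization noise", {
  set.seed(30)
  sigma <- 0.02
  gen <- gen_trajectories(synthetic_trajectory_config(
    n_telomeres = 12L, D_true = 0, drift_velocity = 2e-3,
    rotation_rate = 5e-4, localization_noise_sd = sigma, seed = 31L))
  reg <- register_frames(gen$trajectories)$trajectories
  # after registration every telomere should sit near its frame-1 position
  resid <- unlist(lapply(split(reg, reg$telomere_id), function(tr) {
    xyz <- as.matrix(tr[, c("x_um", "y_um", "z_um")])
    rowSums(sweep(xyz, 2L, xyz[1L, ])^2)
  }))
  expect_lt(sqrt(mean(resid)), 2 * sigma * sqrt(3))
})

test_that("frames with fewer than three usable points are flagged", {
  gen <- gen_trajectories(synthetic_trajectory_config(n_telomeres = 2L,
                                                      seed = 3L))
  reg <- register_frames(gen$trajectories)
  expect_false(any(vapply(reg$transforms, `[[`, logical(1L), "corrected")))
})

test_that("hull volumes match closed forms and the brute-force oracle", {
  # a stationary point explores no volume
  still <- data.frame(telomere_id = 1L, frame = 1:10, t_s = 1:10,
                      x_um = 1, y_um = 2, z_um = 3)
  expect_equal(hull_volume(still), 0)
  # unit tetrahedron
  expect_equal(convhull3d_volume(rbind(c(0, 0, 0), c(1, 0, 0),
                                       c(0, 1, 0), c(0, 0, 1))), 1 / 6)
  # coplanar points are degenerate, not an error
  flat <- cbind(runif(20), runif(20), 0.5)
  expect_equal(convhull3d_volume(flat), 0)
  # random 50-point tracks against exhaustive facet enumeration
  set.seed(17)
  for (i in 1:20) {
    pts <- apply(matrix(rnorm(150, sd = 0.1), ncol = 3L), 2L, cumsum)
    expect_equal(convhull3d_volume(pts), brute_hull_volume(pts),
                 tolerance = 1e-9)
  }
})

test_that("hull volume is invariant under rigid motion", {
  set.seed(23)
  for (i in 1:5) {
    pts <- apply(matrix(rnorm(150, sd = 0.1), ncol = 3L), 2L, cumsum)
    R <- random_rotation()
    v <- rnorm(3L, sd = 5)
    moved <- sweep(pts %*% t(R), 2L, v, `+`)
    expect_equal(convhull3d_volume(moved), convhull3d_volume(pts),
                 tolerance = 1e-9)
  }
})

test_that("MSD matches closed forms and the double-loop oracle", {
  still <- data.frame(telomere_id = 1L, frame = 1:10, t_s = 0:9,
                      x_um = 1, y_um = 2, z_um = 3)
  expect_true(all(msd(still)$msd_um2 == 0))
  # pure drift: MSD(tau) = |v|^2 tau^2
  v <- c(0.02, -0.01, 0.03)
  tt <- 0:19
  drift <- data.frame(telomere_id = 1L, frame = 1:20, t_s = tt,
                      x_um = v[1L] * tt, y_um = v[2L] * tt, z_um = v[3L] * tt)
  m <- msd(drift)
  expect_equal(m$msd_um2, sum(v^2) * m$lag_s^2, tolerance = 1e-12)
  # exact agreement with the naive estimator
  set.seed(40)
  gen <- gen_trajectories(synthetic_trajectory_config(n_telomeres = 1L,
                                                      seed = 41L))
  tr <- gen$trajectories
  m2 <- msd(tr)
  expect_equal(m2$msd_um2[-1L],
               naive_msd(as.matrix(tr[, c("x_um", "y_um", "z_um")]),
                         tr$t_s[2L] - tr$t_s[1L]),
               tolerance = 1e-12)
})

test_that("population curves band the ensemble and separate motion regimes", {
  genA <- gen_trajectories(synthetic_trajectory_config(
    motion_model = "free", D_true = 5e-4, n_telomeres = 30L, seed = 50L))
  msA <- motion_summary(genA$trajectories, register = FALSE)
  pc <- population_curves(msA$msd, msA$summaries$hull_volume_um3)
  # identical tracks give a zero-width band
  same <- population_curves(rep(msA$msd[1L], 3L))
  expect_equal(same$msd_band$lo, same$msd_band$hi)
  expect_equal(same$msd_band$mean, same$msd_band$lo)
  # the band and the box are internally consistent
  expect_true(all(pc$msd_band$lo <= pc$msd_band$hi))
  expect_true(pc$hull_box$whisker_lo <= pc$hull_box$median &&
                pc$hull_box$median <= pc$hull_box$whisker_hi)
})

test_that("confined and anomalous models curb long-lag displacement", {
  free <- gen_trajectories(synthetic_trajectory_config(
    motion_model = "free", D_true = 1e-3, n_telomeres = 25L, seed = 60L))
  conf <- gen_trajectories(synthetic_trajectory_config(
    motion_model = "confined", D_true = 1e-3, confinement_radius = 0.4,
    n_telomeres = 25L, seed = 61L))
  msd_at_end <- function(gen) {
    ms <- motion_summary(gen$trajectories, register = FALSE)
    mean(vapply(ms$msd, function(d) tail(d$msd_um2, 1L), numeric(1L)))
  }
  expect_lt(msd_at_end(conf), 0.3 * msd_at_end(free))
  # confined MSD plateaus below the sphere bound (2R)^2
  expect_lt(msd_at_end(conf), (2 * 0.4)^2)
  anom <- gen_trajectories(synthetic_trajectory_config(
    motion_model = "anomalous", D_true = 1e-3, alpha_true = 0.5,
    n_telomeres = 25L, seed = 62L))
  expect_lt(msd_at_end(anom), msd_at_end(free))
})

test_that("registration restores drift-free hull volumes", {
  # dense TRF1 labeling: constellation registration absorbs ~2/n of the
  # diffusive variance, so a sparse constellation would bias volumes down
  set.seed(70)
  errs <- c(); raw_errs <- c()
  for (s in 1:2) {
    cfg <- synthetic_trajectory_config(
      motion_model = "free", D_true = 5e-4, n_telomeres = 60L,
      drift_velocity = 2e-3, rotation_rate = 2e-4, seed = 210L + s)
    gen <- gen_trajectories(cfg)
    truth_vols <- vapply(gen$truth$clean, convhull3d_volume, numeric(1L))
    reg <- motion_summary(gen$trajectories, register = TRUE)
    raw <- motion_summary(gen$trajectories, register = FALSE)
    errs <- c(errs, abs(reg$summaries$hull_volume_um3 - truth_vols) /
                truth_vols)
    raw_errs <- c(raw_errs, abs(raw$summaries$hull_volume_um3 - truth_vols) /
                    truth_vols)
  }
  expect_lt(median(errs), 0.1)
  # registration clearly beats using the drift-contaminated coordinates
  expect_lt(median(errs), 0.5 * median(raw_errs))
})

test_that("hull volumes separate populations with twofold diffusion difference", {
  slow <- gen_trajectories(synthetic_trajectory_config(
    motion_model = "free", D_true = 5e-4, n_telomeres = 100L, seed = 81L))
  fast <- gen_trajectories(synthetic_trajectory_config(
    motion_model = "free", D_true = 1e-3, n_telomeres = 100L, seed = 82L))
  vol <- function(gen) motion_summary(gen$trajectories,
                                      register = FALSE)$summaries$hull_volume_um3
  res <- compare_groups(data.frame(value = c(vol(slow), vol(fast)),
                                   group = rep(c("slow", "fast"), each = 100L)),
                        design = "mann_whitney")
  expect_lt(res$p_value, 0.01)
})
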