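make_disk <- function(size, cx, cy, r) {
  xs <- matrix(rep(seq_len(size), each = size), size, size)
  ys <- matrix(rep(seq_len(size), times = size), size, size)
  sqrt((xs - cx)^2 + (ys - cy)^2) <= r
}

test_that("segmentation recovers disjoint nuclei with high overlap", {
  cfg <- synthetic_nucleus_config(n_nuclei = 3L, noise_sd = 0,
                                  image_size = 300L, seed = 2L)
  gen <- gen_nucleus_image(cfg)
  mask <- segment_nuclei(gen$image)
  expect_equal(n_nuclei(mask), 3L)
  r_px <- cfg$nucleus_radius / cfg$pixel_size
  for (i in seq_len(3L)) {
    truth_disk <- make_disk(cfg$image_size, gen$truth$center_x[i],
                            gen$truth$center_y[i], r_px)
    overlaps <- vapply(seq_len(3L), function(l)
      sum(truth_disk & mask == l), numeric(1L))
    l <- which.max(overlaps)
    jac <- sum(truth_disk & mask == l) / sum(truth_disk | mask == l)
    expect_gt(jac, 0.95)
  }
})

test_that("blank images give an empty mask, not an error", {
  img <- nucleus_image(list(lamin = matrix(3, 64L, 64L)), 0.2)
  expect_equal(n_nuclei(segment_nuclei(img)), 0L)
})

test_that("watershed splits two disks overlapping by less than 30% of radius", {
  m <- matrix(5, 200L, 200L)
  m[make_disk(200L, 70, 100, 20)] <- 100
  m[make_disk(200L, 105, 100, 20)] <- 100 # centres 35 px apart (1.75 r)
  img <- nucleus_image(list(lamin = m), 0.2)
  mask <- segment_nuclei(img)
  expect_equal(n_nuclei(mask), 2L)
})

test_that("region partition obeys its set identities and erosion depth", {
  disk <- make_disk(101L, 51, 51, 20)
  mask <- laminquant:::new_nucleus_mask(ifelse(disk, 1L, 0L), 1)
  parts <- partition_regions(mask, rim_width = 3, pixel_size = 1)
  p <- parts[[1L]]
  expect_false(any(p$periphery & p$nucleoplasm))
  expect_identical(p$periphery | p$nucleoplasm, disk)
  # nucleoplasm along the axes reaches exactly radius 17
  expect_true(p$nucleoplasm[51, 51 + 17])
  expect_false(p$nucleoplasm[51, 51 + 18])
  # rim of at least the nucleus radius empties the nucleoplasm
  too <- partition_regions(mask, rim_width = 25, pixel_size = 1)[[1L]]
  expect_true(too$too_small)
  expect_false(any(too$nucleoplasm))
})

test_that("partition invariants hold over random blob masks", {
  set.seed(42)
  for (rep in 1:5) {
    m <- matrix(FALSE, 80L, 80L)
    for (b in 1:3)
      m <- m | make_disk(80L, runif(1, 20, 60), runif(1, 20, 60),
                         runif(1, 6, 14))
    lab <- laminquant:::.cc_label(m, 8L)
    mask <- laminquant:::new_nucleus_mask(lab, 1)
    rim <- sample(2:5, 1L)
    outside <- which(!m, arr.ind = TRUE)
    for (p in partition_regions(mask, rim_width = rim, pixel_size = 1)) {
      expect_false(any(p$periphery & p$nucleoplasm))
      nucleus <- unclass(mask) == p$nucleus_id
      expect_true(all(nucleus[p$periphery | p$nucleoplasm]))
      expect_identical(p$periphery | p$nucleoplasm, nucleus)
      # every nucleoplasm pixel strictly farther than rim from background
      # (other nuclei count as background for the per-nucleus transform)
      bg <- which(!nucleus, arr.ind = TRUE)
      for (idx in which(p$nucleoplasm)) {
        r <- (idx - 1L) %% 80L + 1L
        c0 <- (idx - 1L) %/% 80L + 1L
        expect_gt(min(sqrt((bg[, 1L] - r)^2 + (bg[, 2L] - c0)^2)), rim)
      }
    }
  }
})

test_that("automated N/P ratio matches projection-statistic definitions", {
  # uniform image: ratio is exactly 1
  uni <- nucleus_image(list(lamin = matrix(80, 101L, 101L)), 1)
  disk <- make_disk(101L, 51, 51, 30)
  mask <- laminquant:::new_nucleus_mask(ifelse(disk, 1L, 0L), 1)
  p <- partition_regions(mask, rim_width = 4, pixel_size = 1)[[1L]]
  expect_equal(np_ratio_auto(uni, p)$ratio, 1)
  # noiseless synthetic nucleus: exact truth ratio
  cfg <- synthetic_nucleus_config(noise_sd = 0, seed = 4L)
  gen <- gen_nucleus_image(cfg)
  rec <- np_ratio_image(gen$image, rim_width = cfg$rim_width_true)
  expect_equal(rec$ratio, 0.25, tolerance = 1e-12)
  # zero nucleoplasm intensity gives ratio 0
  m <- matrix(0, 101L, 101L)
  m[disk] <- 100
  m[make_disk(101L, 51, 51, 26)] <- 0
  z <- nucleus_image(list(lamin = m), 1)
  expect_equal(np_ratio_auto(z, p)$ratio, 0)
})

test_that("N/P ratio is invariant under global intensity scaling", {
  cfg <- synthetic_nucleus_config(noise_sd = 3, seed = 14L)
  gen <- gen_nucleus_image(cfg)
  r1 <- np_ratio_image(gen$image)$ratio
  scaled <- nucleus_image(lapply(gen$image$channels, function(x) 7.3 * x),
                          gen$image$pixel_size)
  r2 <- np_ratio_image(scaled)$ratio
  expect_equal(r1, r2, tolerance = 1e-12)
})

test_that("z-stacks use the min projection for N and max projection for P", {
  disk <- make_disk(61L, 31, 31, 20)
  planes <- array(0, c(61L, 61L, 2L))
  p1 <- matrix(0, 61L, 61L); p1[disk] <- 100
  p2 <- matrix(0, 61L, 61L); p2[disk] <- 40
  planes[, , 1L] <- p1; planes[, , 2L] <- p2
  img <- nucleus_image(list(lamin = planes), 1)
  mask <- laminquant:::new_nucleus_mask(ifelse(disk, 1L, 0L), 1)
  part <- partition_regions(mask, rim_width = 3, pixel_size = 1)[[1L]]
  rec <- np_ratio_auto(img, part)
  expect_equal(rec$n_intensity, 40)  # median of the minimum projection
  expect_equal(rec$p_intensity, 100) # upper quartile of the max projection
})

test_that("line-profile N/P follows the two-peak / 30-centre rule", {
  v <- rep(10, 60)
  v[5] <- 100; v[55] <- 100
  v[16:45] <- 25
  expect_equal(np_ratio_line(v)$ratio, 0.25)
  expect_equal(np_ratio_line(rep(7, 40))$ratio, 1)
  v2 <- rep(0, 60)
  v2[3] <- 80; v2[57] <- 120
  v2[16:45] <- 50
  expect_equal(np_ratio_line(v2)$ratio, 0.5)
  expect_error(np_ratio_line(rep(1, 20)), "at least")
})

test_that("series normalization finds the pre-rise anchor", {
  out <- normalize_series(c(0.2, 0.2, 0.4, 0.6), anchor = "auto")
  expect_equal(out$anchor, 2L)
  expect_equal(out$normalized, c(1, 1, 2, 3))
  expect_equal(normalize_series(c(0.5, 1, 2), anchor = 1L)$normalized[1L], 1)
  expect_equal(normalize_series(rep(0.3, 5), anchor = "auto")$normalized,
               rep(1, 5))
  expect_error(normalize_series(c(0, 1), anchor = 1L), "zero")
})

test_that("integrated DNA density sums the stain and doubles at 4C", {
  m <- matrix(0L, 20L, 20L)
  m[1:10, 1:10] <- 1L
  mask <- laminquant:::new_nucleus_mask(m, 1)
  img <- nucleus_image(list(dna = matrix(2, 20L, 20L)), 1)
  expect_equal(integrated_dapi(mask, img), 200)
  img2 <- nucleus_image(list(dna = matrix(4, 20L, 20L)), 1)
  expect_equal(integrated_dapi(mask, img2), 400)
  # synthetic 4C vs 2C nuclei measure ~2x apart
  cfg <- synthetic_nucleus_config(n_nuclei = 4L, image_size = 380L,
                                  noise_sd = 0, dna_cv = 1e-6, seed = 31L)
  gen <- gen_nucleus_image(cfg)
  mask <- segment_nuclei(gen$image)
  dens <- integrated_dapi(mask, gen$image)
  # match segmented labels to truth nuclei by centre proximity
  bb <- attr(mask, "bbox")
  cx <- (bb["xmin", ] + bb["xmax", ]) / 2
  cy <- (bb["ymin", ] + bb["ymax", ]) / 2
  ord <- vapply(seq_len(4L), function(i)
    which.min((cx - gen$truth$center_x[i])^2 + (cy - gen$truth$center_y[i])^2),
    integer(1L))
  ratio <- dens[ord] / gen$truth$dna_total
  expect_true(all(abs(ratio - 1) < 0.02))
  if (any(gen$truth$cycle_label == "G1") && any(gen$truth$cycle_label == "S-G2")) {
    r42 <- mean(dens[ord][gen$truth$cycle_label == "S-G2"]) /
      mean(dens[ord][gen$truth$cycle_label == "G1"])
    expect_equal(r42, 2, tolerance = 0.05)
  }
})

test_that("cell-cycle gating labels a bimodal population correctly", {
  set.seed(8)
  cfgs <- lapply(1:8, function(s)
    synthetic_nucleus_config(n_nuclei = 6L, image_size = 260L,
                             pixel_size = 0.4, nucleus_radius = 4,
                             noise_sd = 2, seed = 100L + s))
  truth_lab <- character(); meas <- numeric()
  for (cfg in cfgs) {
    gen <- gen_nucleus_image(cfg)
    mask <- segment_nuclei(gen$image)
    dens <- integrated_dapi(mask, gen$image)
    bb <- attr(mask, "bbox")
    cx <- (bb["xmin", ] + bb["xmax", ]) / 2
    cy <- (bb["ymin", ] + bb["ymax", ]) / 2
    ord <- vapply(seq_len(nrow(gen$truth)), function(i)
      which.min((cx - gen$truth$center_x[i])^2 +
                  (cy - gen$truth$center_y[i])^2), integer(1L))
    truth_lab <- c(truth_lab, gen$truth$cycle_label)
    meas <- c(meas, dens[ord])
  }
  gates <- c(0.6e5, sqrt(1e5 * 2e5), 2.8e5)
  st <- stage_cell_cycle(meas, gates)
  agree <- mean(as.character(st$stage) == truth_lab)
  expect_gte(agree, 0.95)
  expect_equal(sum(st$histogram$count), length(meas))
  # trivial gate behaviour
  expect_equal(as.character(stage_cell_cycle(0.1e5, gates)$stage),
               "unassigned")
  empty <- stage_cell_cycle(numeric(0), gates)
  expect_equal(nrow(empty$histogram), 0L)
  expect_error(stage_cell_cycle(1, c(2, 1, 3)), "increasing")
})

test_that("structure detection matches truth and the brute-force oracle", {
  cfg <- synthetic_nucleus_config(seed = 9L, noise_sd = 0)
  spots <- data.frame(
    x_um = c(0, 1, -1.5, 2, -2, 4.4, 0),
    y_um = c(0, 1.5, 0.5, -1, -2, 0, -4.5),
    area_um2 = c(0.5, 0.8, 0.3, 1.0, 0.6, 0.4, 0.4))
  gen <- gen_structure_image(spots, cfg)
  recs <- detect_structures(gen$image)
  expect_equal(nrow(recs), gen$truth$true_structure_count)
  # independent oracle on the same thresholded candidates
  img <- gen$image$channels$lamin
  mask <- segment_nuclei(gen$image)
  nucleus <- unclass(mask) == 1L
  thr <- huang_threshold(img[nucleus])
  candidate <- nucleus & img > thr
  expect_equal(nrow(recs),
               brute_structure_count(candidate, nucleus,
                                     pixel_size = cfg$pixel_size))
  # oversized spot alone yields zero records
  big <- gen_structure_image(data.frame(x_um = 0, y_um = 0, area_um2 = 6),
                             cfg)
  expect_equal(nrow(detect_structures(big$image)), 0L)
  # featureless nucleoplasm yields zero records
  plain <- gen_nucleus_image(synthetic_nucleus_config(seed = 5L))
  expect_equal(nrow(detect_structures(plain$image)), 0L)
})

test_that("structure summaries pool areas and report per-cell counts", {
  recs <- data.frame(nucleus_id = c(1, 1, 1, 2, 2, 2, 2, 2),
                     area_um2 = rep(0.5, 8),
                     x_um = 0, y_um = 0, boundary_distance_um = 2)
  s <- summarize_structures(recs)
  expect_equal(s$counts, c(3L, 5L))
  expect_equal(s$mean_area_um2, 0.5)
  none <- summarize_structures(recs[0, ], n_cells = 2L)
  expect_equal(none$counts, c(0L, 0L))
  expect_true(is.na(none$mean_area_um2))
})
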