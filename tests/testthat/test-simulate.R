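test_that("the simulator is bit-identical under a fixed seed", {
  cfg <- sim_config(frames = 3, height = 96, width = 96, n_filopodia = 3,
                    seed = 5)
  a <- simulate_movie(cfg)
  b <- simulate_movie(cfg)
  expect_identical(a$stack$voxels, b$stack$voxels)
  expect_equal(tibble::as_tibble(a$truth$instances),
               tibble::as_tibble(b$truth$instances))
  # different seed, different noise
  c2 <- simulate_movie(sim_config(frames = 3, height = 96, width = 96,
                                  n_filopodia = 3, seed = 6))
  expect_false(identical(a$stack$voxels, c2$stack$voxels))
})

test_that("zero filopodia gives a body-only movie with an empty truth", {
  sim <- simulate_movie(sim_config(frames = 2, n_filopodia = 0, seed = 1))
  expect_equal(nrow(sim$truth$instances), 0)
  expect_true(any(sim$truth$body_mask))
  # the body is visible in the image
  vol <- stack_frame(sim$stack, 1)
  expect_gt(mean(vol[sim$truth$body_mask]), mean(vol[!sim$truth$body_mask]))
})

test_that("exponential length draws have the stated offset-exponential mean", {
  sim <- simulate_movie(sim_config(frames = 1, n_filopodia = 150,
                                   height = 64, width = 64,
                                   length_dist = "exponential",
                                   length_rate = 0.5, length_offset = 3,
                                   noise_sd = 0, seed = 10))
  lens <- sim$truth$filopodia$max_length_um
  # mean 3 + 1/lambda = 5, within 3 standard errors
  se <- 2 / sqrt(length(lens))
  expect_lt(abs(mean(lens) - 5), 3 * se)
  # trajectories leaving the small volume are flagged as clipped
  expect_true(any(sim$truth$filopodia$clipped))
})

test_that("analytic and rasterised path lengths agree within a diagonal", {
  sim <- simulate_movie(sim_config(frames = 15, seed = 12))
  cal <- sim$stack$calibration
  diag_um <- sqrt(sum(filotrack:::cal_steps(cal)^2))
  tr <- sim$truth$instances
  tr <- tr[!sim$truth$filopodia$clipped[tr$id], ]
  raster <- vapply(tr$path, filotrack:::path_length_um, numeric(1), cal)
  expect_true(all(abs(raster - tr$length_um) <= diag_um))
})

test_that("rasterised filopodia are present in the rendered frames", {
  sim <- simulate_movie(sim_config(frames = 10, noise_sd = 0, seed = 13))
  d <- dim(sim$truth$body_mask)
  for (t in c(5, 10)) {
    vol <- stack_frame(sim$stack, t)
    tr <- sim$truth$instances[sim$truth$instances$frame == t, ]
    for (i in seq_len(nrow(tr))) {
      p <- tr$path[[i]]
      l <- (p[, 1] + 1) + d[1] * (p[, 2] + d[2] * p[, 3])
      # centreline intensity well above background where outside the body
      outside <- !sim$truth$body_mask[l]
      if (any(outside)) {
        expect_gt(median(vol[l][outside]), 100)
      }
    }
  }
})

test_that("feeding the truth back scores perfectly", {
  sim <- simulate_movie(sim_config(frames = 12, n_filopodia = 3, seed = 8,
                                   filopodia = list(
                                     list(anchor = c(3, 50, 50), phi = 0,
                                          max_length_um = 5),
                                     list(anchor = c(3, 128, 40), phi = 0,
                                          max_length_um = 6),
                                     list(anchor = c(3, 206, 50), phi = 0,
                                          max_length_um = 7))))
  inst <- truth_to_instances(sim$truth)
  tracks <- track_movie(inst)
  sc <- score_against_truth(tracks, sim$truth, eval_min_length_um = 0)
  expect_equal(sc$recall, 1)
  expect_equal(sc$precision, 1)
  expect_equal(sc$identity_accuracy, 1)
  expect_equal(sc$length_rmse_um, 0)
  # empty tracks: zero recall
  empty <- tracks[0, ]
  attr(empty, "calibration") <- attr(tracks, "calibration")
  sc0 <- score_against_truth(empty, sim$truth, eval_min_length_um = 0)
  expect_equal(sc0$recall, 0)
})

test_that("permuting identities at one frame lowers identity accuracy by the miscount", {
  sim <- simulate_movie(sim_config(frames = 6, n_filopodia = 3, seed = 9,
                                   min_visible_um = 0,
                                   filopodia = list(
                                     list(anchor = c(3, 40, 40), phi = 0,
                                          max_length_um = 5, birth = 1),
                                     list(anchor = c(3, 128, 40), phi = 0,
                                          max_length_um = 5, birth = 1),
                                     list(anchor = c(3, 216, 40), phi = 0,
                                          max_length_um = 5, birth = 1))))
  inst <- truth_to_instances(sim$truth)
  tracks <- track_movie(inst)
  sc <- score_against_truth(tracks, sim$truth, eval_min_length_um = 0)
  expect_equal(sc$identity_accuracy, 1)
  # swap two instances' track assignment at one interior frame
  perm <- tracks
  f0 <- 3
  d1 <- perm$data[[1]]; d2 <- perm$data[[2]]
  r1 <- which(d1$frame == f0); r2 <- which(d2$frame == f0)
  tmp <- d1[r1, c("path", "length_um", "direction", "instance_id")]
  d1[r1, c("path", "length_um", "direction", "instance_id")] <-
    d2[r2, c("path", "length_um", "direction", "instance_id")]
  d2[r2, c("path", "length_um", "direction", "instance_id")] <- tmp
  perm$data[[1]] <- d1; perm$data[[2]] <- d2
  scp <- score_against_truth(perm, sim$truth, eval_min_length_um = 0)
  # two tracks each gain two wrong consecutive pairs: 4 of 15 pairs wrong
  expect_equal(scp$identity_accuracy, (sc$n_identity_pairs - 4) / sc$n_identity_pairs)
})

test_that("recall does not improve as noise increases", {
  recalls <- vapply(c(5, 60), function(sd) {
    vals <- vapply(1:3, function(seed) {
      sim <- simulate_movie(sim_config(frames = 4, height = 128, width = 128,
                                       n_filopodia = 2, noise_sd = sd,
                                       seed = seed,
                                       body = list(radii = c(2.2, 30, 25)),
                                       filopodia = list(
                                         list(anchor = c(3, 40, 60), phi = 70 * pi / 180,
                                              max_length_um = 4, birth = 1),
                                         list(anchor = c(3, 90, 60), phi = -70 * pi / 180,
                                              max_length_um = 4, birth = 1))))
      tracks <- run_pipeline(sim$stack)
      sc <- score_against_truth(tracks, sim$truth)
      if (is.na(sc$recall)) 0 else sc$recall
    }, numeric(1))
    mean(vals)
  }, numeric(1))
  expect_gte(recalls[1], recalls[2])
})
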