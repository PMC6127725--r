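test_that("length measure matches its closed form", {
  expect_equal(length_measure(4, 4), 0)
  expect_equal(length_measure(2, 4), 0.5)
  expect_equal(length_measure(1, 100), 0.99)
  withr::local_seed(2)
  lc <- runif(1000, 0.1, 20); lp <- runif(1000, 0.1, 20)
  expect_equal(length_measure(lc, lp), abs(lc - lp) / pmax(lc, lp))
  expect_equal(length_measure(lc, lp), length_measure(lp, lc))
  expect_true(all(length_measure(lc, lp) >= 0 & length_measure(lc, lp) <= 1))
  expect_error(length_measure(0, 1), "positive")
})

test_that("direction measure is 0 parallel, 1 antiparallel, 0.5 orthogonal", {
  expect_equal(direction_measure(c(0, 0, 2), c(0, 0, 5)), 0)
  expect_equal(direction_measure(c(0, 0, 2), c(0, 0, -1)), 1)
  expect_equal(direction_measure(c(0, 1, 0), c(0, 0, 3)), 0.5)
  expect_warning(md <- direction_measure(c(0, 0, 0), c(1, 0, 0)), "zero")
  expect_equal(md, 0.5)
  # bounded for random vectors
  withr::local_seed(3)
  for (i in 1:50) {
    md <- direction_measure(rnorm(3), rnorm(3))
    expect_true(md >= 0 && md <= 1)
  }
})

test_that("candidates require paths within the cutoff radius", {
  cal <- voxel_calibration(1, 1, 1, 1)
  cur <- instances_from_paths(2, list(straight_path(10, c(1, 50, 0))), cal)
  hist_far <- instances_from_paths(1, list(straight_path(10, c(1, 90, 0))),
                                   cal)
  history <- tibble::tibble(track_id = 1L, frame = 1L,
                            path = hist_far$path,
                            length_um = hist_far$length_um,
                            direction = hist_far$direction)
  expect_equal(nrow(find_candidates(cur, history)), 0) # 40 px > 25 px

  # identical path in consecutive frames: perfect candidate
  hist_same <- instances_from_paths(1, list(straight_path(10, c(1, 50, 0))),
                                    cal)
  history2 <- tibble::tibble(track_id = 1L, frame = 1L,
                             path = hist_same$path,
                             length_um = hist_same$length_um,
                             direction = hist_same$direction)
  cand <- find_candidates(cur, history2)
  expect_equal(nrow(cand), 1)
  expect_equal(cand$M_L, 0)
  expect_equal(cand$M_D, 0)
  expect_equal(cand$S, 0)
})

test_that("candidate search equals a brute-force all-pairs oracle", {
  withr::local_seed(9)
  cal <- voxel_calibration(1, 1, 1, 1)
  cfg <- tracking_config()
  for (rep in 1:20) {
    ni <- sample(1:4, 1); nt <- sample(1:4, 1)
    cur_paths <- lapply(seq_len(ni), function(i)
      straight_path(sample(3:12, 1), c(1, sample(0:60, 1), sample(0:60, 1)),
                    c(0, 0, 1)))
    hist_paths <- lapply(seq_len(nt), function(i)
      straight_path(sample(3:12, 1), c(1, sample(0:60, 1), sample(0:60, 1)),
                    c(0, 1, 0)))
    cur <- instances_from_paths(2, cur_paths, cal)
    hi <- instances_from_paths(1, hist_paths, cal)
    history <- tibble::tibble(track_id = seq_len(nt), frame = 1L,
                              path = hi$path, length_um = hi$length_um,
                              direction = hi$direction)
    cand <- find_candidates(cur, history, cfg)
    for (i in seq_len(ni)) for (j in seq_len(nt)) {
      d <- oracle_min_dist(cur$path[[i]], history$path[[j]])
      hit <- any(cand$instance_id == cur$instance_id[i] &
                   cand$track_id == j)
      expect_equal(hit, d <= cfg$cutoff_radius_px)
      if (hit) {
        row <- cand[cand$instance_id == cur$instance_id[i] &
                      cand$track_id == j, ]
        expect_equal(row$dist, d)
        expect_equal(row$S, 0.46 * row$M_L + 0.6 * row$M_D)
      }
    }
  }
})

test_that("greedy linking follows ascending score with one-to-one matching", {
  cand <- tibble::tibble(
    instance_id = c(1L, 1L, 2L, 2L), track_id = c(1L, 2L, 1L, 2L),
    dist = 1, M_L = 0, M_D = 0, S = c(0.1, 0.2, 0.15, 0.4))
  links <- link_frame(cand)
  expect_equal(links$track_id[links$instance_id == 1], 1L)
  expect_equal(links$track_id[links$instance_id == 2], 2L)
  expect_equal(nrow(link_frame(filotrack:::empty_candidates())), 0)
})

test_that("greedy linking matches an independent oracle on random scenes", {
  withr::local_seed(13)
  for (rep in 1:100) {
    ni <- sample(1:6, 1); nt <- sample(1:6, 1)
    g <- expand.grid(instance_id = seq_len(ni), track_id = seq_len(nt))
    keep <- runif(nrow(g)) < 0.7
    if (!any(keep)) next
    cand <- tibble::tibble(
      instance_id = as.integer(g$instance_id[keep]),
      track_id = as.integer(g$track_id[keep]),
      dist = runif(sum(keep), 0, 25),
      M_L = runif(sum(keep)), M_D = runif(sum(keep)))
    cand$S <- 0.46 * cand$M_L + 0.6 * cand$M_D
    got <- link_frame(cand)
    want <- oracle_link(as.data.frame(cand))
    got <- got[order(got$instance_id), ]
    want <- want[order(want$instance_id), ]
    expect_equal(as.data.frame(got), as.data.frame(want),
                 ignore_attr = TRUE)
    # injectivity both ways
    expect_false(any(duplicated(got$instance_id)))
    expect_false(any(duplicated(got$track_id)))
  }
})

test_that("a drifting instance stays one track across the movie", {
  cal <- voxel_calibration(1, 1, 1, 1)
  inst <- dplyr::bind_rows(lapply(1:10, function(t) {
    instances_from_paths(t, list(straight_path(12, c(1, 20 + t, 5))), cal)
  }))
  attr(inst, "calibration") <- cal
  tracks <- track_movie(inst)
  expect_equal(nrow(tracks), 1)
  expect_equal(tracks$lifetime_frames, 10L)
  expect_equal(tracks$birth_frame, 1L)
  expect_equal(tracks$last_frame, 10L)
})

test_that("absences of a full lookback window split identities", {
  cal <- voxel_calibration(1, 1, 1, 1)
  cfg <- tracking_config(lookback_frames = 5)
  frames_present <- c(1, 2, 8, 9) # gap of 5 frames: 2 -> 8
  inst <- dplyr::bind_rows(lapply(frames_present, function(t) {
    instances_from_paths(t, list(straight_path(12, c(1, 20, 5))), cal)
  }))
  attr(inst, "calibration") <- cal
  tracks <- track_movie(inst, cfg)
  expect_equal(nrow(tracks), 2)
  # a gap within the window is bridged
  inst2 <- dplyr::bind_rows(lapply(c(1, 2, 6), function(t) {
    instances_from_paths(t, list(straight_path(12, c(1, 20, 5))), cal)
  }))
  attr(inst2, "calibration") <- cal
  tracks2 <- track_movie(inst2, cfg)
  expect_equal(nrow(tracks2), 1)
  expect_equal(tracks2$lifetime_frames, 3L)
})

test_that("track count is invariant under a global translation", {
  withr::local_seed(21)
  cal <- voxel_calibration(1, 1, 1, 1)
  mk <- function(shift) {
    inst <- dplyr::bind_rows(lapply(1:6, function(t) {
      paths <- lapply(1:3, function(i)
        straight_path(10, c(1, 30 * i + t + shift[1], 5 + shift[2])))
      instances_from_paths(t, paths, cal)
    }))
    attr(inst, "calibration") <- cal
    track_movie(inst)
  }
  t0 <- mk(c(0, 0)); t1 <- mk(c(17, 40))
  expect_equal(nrow(t0), nrow(t1))
  expect_equal(sort(t0$lifetime_frames), sort(t1$lifetime_frames))
})

test_that("well-separated simulated identities are recovered exactly", {
  # anchors far apart (>= 3x cutoff), drift small relative to the cutoff
  for (seed in 1:3) {
    cfg <- sim_config(
      frames = 20, n_filopodia = 3, seed = seed, drift_px = 2,
      filopodia = list(
        list(anchor = c(3, 40, 40), phi = -40 * pi / 180, max_length_um = 6),
        list(anchor = c(3, 40, 216), phi = 40 * pi / 180, max_length_um = 8),
        list(anchor = c(3, 216, 128), phi = 0, max_length_um = 5)))
    sim <- simulate_movie(cfg)
    inst <- truth_to_instances(sim$truth)
    tracks <- track_movie(inst)
    sc <- score_against_truth(tracks, sim$truth, eval_min_length_um = 0)
    expect_equal(sc$identity_accuracy, 1)
  }
})
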