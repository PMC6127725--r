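test_that("a solid tube thins to a single centreline of the right length", {
  tube <- make_tube_mask()
  sk <- skeletonize_frame(tube)
  expect_true(all(tube[sk])) # skeleton is a subset of the mask
  segs <- split_segments(sk)
  expect_equal(nrow(segs), 1)
  expect_gte(nrow(segs$path[[1]]), 37)
  expect_lte(nrow(segs$path[[1]]), 43)
})

test_that("a solid ball collapses to a tiny skeleton", {
  ball <- make_ball_mask()
  sk <- skeletonize_frame(ball)
  expect_lte(sum(sk) / sum(ball), 0.05)
  expect_gte(sum(sk), 1)
})

test_that("thinning preserves connected-component count and empty masks", {
  m <- make_tube_mask(c(9, 30, 50))
  m[1:4, 25:29, 40:48] <- TRUE # second component
  sk <- skeletonize_frame(m)
  n0 <- max(filotrack:::.label_components(m, dim(m), 26L))
  n1 <- max(filotrack:::.label_components(sk, dim(sk), 26L))
  expect_equal(n1, n0)
  empty <- array(FALSE, c(4, 5, 6))
  expect_identical(skeletonize_frame(empty), empty)
})

test_that("mask_skeleton is exactly the set difference", {
  sk <- array(FALSE, c(3, 10, 10)); sk[2, 5, 1:10] <- TRUE
  body <- array(FALSE, c(3, 10, 10)); body[, , 1:4] <- TRUE
  out <- mask_skeleton(sk, body)
  expect_identical(out, sk & !body)
  expect_equal(sum(out), 6)
  # disjoint body leaves the skeleton unchanged
  body2 <- array(FALSE, c(3, 10, 10)); body2[1, 1, 1] <- TRUE
  expect_identical(mask_skeleton(sk, body2), sk)
  # fully covering body empties it
  expect_false(any(mask_skeleton(sk, array(TRUE, c(3, 10, 10)))))
  expect_error(mask_skeleton(sk, array(FALSE, c(3, 9, 10))), "shape")
})

test_that("a Y-shaped skeleton splits into three segments at the branch", {
  sk <- array(FALSE, c(3, 21, 21))
  sk[2, 11, 1:11] <- TRUE            # stem along x
  for (i in 1:8) sk[2, 11 - i, 11 + i] <- TRUE # arm 1 (diagonal)
  for (i in 1:8) sk[2, 11 + i, 11 + i] <- TRUE # arm 2 (diagonal)
  segs <- split_segments(sk)
  expect_equal(nrow(segs), 3)
  # segments share only the branch voxel (2,11,11) -> 0-based (1,10,10)
  all_vox <- do.call(rbind, segs$path)
  dup <- all_vox[duplicated(all_vox), , drop = FALSE]
  expect_true(all(apply(dup, 1, function(r) all(r == c(1, 10, 10)))))
  # union covers the component
  expect_equal(nrow(unique(all_vox)), sum(sk))
})

test_that("simple open curves come back as one segment with endpoints kept", {
  p <- straight_path(15, origin = c(1, 3, 2), step = c(0, 1, 1))
  sk <- array(FALSE, c(4, 20, 20))
  for (i in seq_len(nrow(p))) sk[p[i, 1] + 1, p[i, 2] + 1, p[i, 3] + 1] <- TRUE
  segs <- split_segments(sk)
  expect_equal(nrow(segs), 1)
  path <- segs$path[[1]]
  expect_equal(nrow(path), 15)
  ends <- path[c(1, nrow(path)), ]
  expect_true(all(p[1, ] == ends[1, ]) || all(p[1, ] == ends[2, ]))
})

test_that("random thin components decompose into covering simple paths", {
  withr::local_seed(5)
  for (rep in 1:5) {
    # random tree-like thin structure: random walk with occasional branches
    sk <- array(FALSE, c(5, 30, 30))
    pos <- c(3, 15, 15)
    sk[pos[1], pos[2], pos[3]] <- TRUE
    nodes <- list(pos)
    for (s in 1:40) {
      base <- nodes[[sample(length(nodes), 1)]]
      step <- sample(c(-1, 0, 1), 3, replace = TRUE)
      np <- pmin(pmax(base + step, c(1, 1, 1)), c(5, 30, 30))
      sk[np[1], np[2], np[3]] <- TRUE
      nodes[[length(nodes) + 1]] <- np
    }
    segs <- split_segments(sk)
    if (nrow(segs) == 0) next
    all_vox <- unique(do.call(rbind, segs$path))
    vox_idx <- (all_vox[, 1] + 1) + 5 * all_vox[, 2] + 150 * all_vox[, 3]
    # every returned voxel is a skeleton voxel
    expect_true(all(sk[vox_idx]))
    # paths are simple: no repeats, consecutive voxels 26-adjacent
    for (p in segs$path) {
      expect_false(any(duplicated(p)))
      if (nrow(p) > 1) {
        d <- abs(diff(p))
        expect_true(all(apply(d, 1, max) == 1))
      }
    }
  }
})

test_that("edits remove, merge and orient segments into instances", {
  cal <- voxel_calibration(dx = 0.1)
  # two collinear pieces with a 2-voxel gap along x
  p1 <- straight_path(10, c(2, 5, 0), c(0, 0, 1))
  p2 <- straight_path(8, c(2, 5, 12), c(0, 0, 1))
  segs <- segment_table(frame = c(1, 1), segment_id = c(1, 2),
                        path = list(p1, p2))
  edits <- edit_merge(1, c(1, 2), 1)
  inst <- apply_edits(segs, edits, calibration = cal)
  expect_equal(nrow(inst), 1)
  expect_equal(inst$n_vox, 18)
  # length ~ sum of parts + gap: 9 + 7 + 3 steps of 0.1 um
  expect_equal(inst$length_um, (9 + 7 + 3) * 0.1)
  # voxel conservation: all voxels from the inputs, each once
  expect_equal(nrow(unique(inst$path[[1]])), 18)

  # remove-all leaves nothing
  rm_all <- dplyr::bind_rows(edit_remove(1, 1), edit_remove(1, 2))
  expect_equal(nrow(apply_edits(segs, rm_all, calibration = cal)), 0)

  # accepted straight +y segment has direction proportional to (0, 1, 0)
  py <- straight_path(6, c(1, 0, 4), c(0, 1, 0))
  segy <- segment_table(1, 1, list(py))
  body <- array(FALSE, c(3, 10, 10)); body[2, 1, 5] <- TRUE # base at y = 0
  insty <- apply_edits(segy, auto_accept(segy), cell_body = body,
                       calibration = cal)
  d <- unname(insty$direction[[1]])
  expect_equal(d[1], 0); expect_equal(d[3], 0); expect_gt(d[2], 0)
})

test_that("merging segments whose endpoints are too far apart fails loudly", {
  p1 <- straight_path(5, c(1, 1, 0), c(0, 0, 1))
  p2 <- straight_path(5, c(1, 20, 0), c(0, 0, 1))
  segs <- segment_table(frame = c(1, 1), segment_id = c(1, 2),
                        path = list(p1, p2))
  expect_error(apply_edits(segs, edit_merge(1, c(1, 2), 1)), "merge_gap")
})

test_that("base/tip orientation flips with the anchor side", {
  cal <- voxel_calibration(dx = 0.1)
  p <- straight_path(10, c(1, 5, 3), c(0, 0, 1))
  segs <- segment_table(1, 1, list(p))
  body_lo <- array(FALSE, c(3, 12, 20)); body_lo[2, 6, 1] <- TRUE
  body_hi <- array(FALSE, c(3, 12, 20)); body_hi[2, 6, 19] <- TRUE
  i_lo <- apply_edits(segs, cell_body = body_lo, calibration = cal)
  i_hi <- apply_edits(segs, cell_body = body_hi, calibration = cal)
  expect_equal(unname(i_lo$base[[1]]), unname(p[1, ]))
  expect_equal(unname(i_hi$base[[1]]), unname(p[10, ]))
  expect_equal(i_lo$length_um, i_hi$length_um)
  expect_equal(i_lo$direction[[1]], -i_hi$direction[[1]])
})

test_that("auto_accept accepts every segment and is idempotent", {
  segs <- segment_table(frame = c(1, 1, 2), segment_id = c(1, 2, 1),
                        path = list(straight_path(3), straight_path(4),
                                    straight_path(5)))
  sc <- auto_accept(segs)
  expect_equal(nrow(sc), 3)
  expect_true(all(sc$op == "accept"))
  i1 <- apply_edits(segs, sc)
  i2 <- apply_edits(segs, auto_accept(segs))
  expect_equal(tibble::as_tibble(i1), tibble::as_tibble(i2))
  expect_equal(nrow(auto_accept(segment_table())), 0)
})

test_that("edits reject unknown and doubly-consumed segments", {
  segs <- segment_table(1, 1, list(straight_path(4)))
  expect_error(apply_edits(segs, edit_remove(1, 99)), "unknown")
  dup <- dplyr::bind_rows(edit_accept(1, 1, 1), edit_remove(1, 1))
  expect_error(apply_edits(segs, dup), "twice")
})
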