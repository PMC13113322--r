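blob_image <- function(nr, nc, centers, sigma = 2, amp = 1) {
  img <- matrix(0, nr, nc)
  for (i in seq_len(nrow(centers))) {
    for (row in 1:nr) for (col in 1:nc) {
      img[row, col] <- img[row, col] + amp *
        exp(-((col - 1 - centers[i, 1])^2 + (row - 1 - centers[i, 2])^2) /
              (2 * sigma^2))
    }
  }
  img
}

test_that("detect_nuclei finds constructed maxima and nothing on flat images", {
  img <- blob_image(24, 24, cbind(10, 10))
  s <- detect_nuclei(img, smooth_sigma = 1, min_distance_px = 3,
                     min_intensity = 0.05)
  expect_equal(nrow(s$seeds), 1L)
  expect_equal(c(s$seeds$x, s$seeds$y), c(10, 10))

  flat <- matrix(1, 20, 20)
  expect_equal(nrow(detect_nuclei(flat)$seeds), 0L)

  two <- blob_image(40, 40, rbind(c(8, 20), c(28, 20)))
  s2 <- detect_nuclei(two, smooth_sigma = 1, min_distance_px = 5,
                      min_intensity = 0.05)
  expect_equal(nrow(s2$seeds), 2L)
  expect_setequal(s2$seeds$x, c(8, 28))
  expect_true(all(s2$seeds$y == 20))
})

test_that("detect_nuclei orders ids by intensity with (y, x) tie-break", {
  img <- blob_image(40, 40, cbind(30, 8), amp = 0.5) +
         blob_image(40, 40, cbind(10, 25), amp = 1)
  s <- detect_nuclei(img, smooth_sigma = 1, min_distance_px = 3,
                     min_intensity = 0.05)
  expect_equal(nrow(s$seeds), 2L)
  expect_equal(s$seeds$x[1], 10)  # the brighter peak gets id 1
  expect_error(detect_nuclei(matrix(numeric(0), 0, 0)), "non-empty")
})

test_that("a single seed with radius 6 claims exactly the 113 lattice pixels", {
  s <- seed_set(data.frame(id = 1L, x = 32, y = 32, dapi_intensity = 1),
                c(64, 64))
  seg <- grow_segments(s, radius_px = 6)
  expect_equal(sum(seg$labels == 1L), 113L)
  # oracle: direct lattice enumeration
  expect_equal(sum(outer((-10:10)^2, (-10:10)^2, "+") <= 36), 113L)
  # every labeled pixel respects the cap
  idx <- which(seg$labels == 1L, arr.ind = TRUE)
  expect_true(all((idx[, "col"] - 1 - 32)^2 + (idx[, "row"] - 1 - 32)^2 <= 36))
})

test_that("two distant seeds grow two disjoint 113-pixel disks", {
  s <- seed_set(data.frame(id = 1:2, x = c(20, 40), y = c(32, 32),
                           dapi_intensity = c(2, 1)), c(64, 64))
  seg <- grow_segments(s, radius_px = 6)
  expect_equal(unname(table(seg$labels[seg$labels > 0])), c(113L, 113L),
               ignore_attr = TRUE)
})

test_that("grow_segments equals the brute-force capped-Voronoi oracle", {
  set.seed(13)
  for (i in 1:8) {
    nr <- sample(20:48, 1); nc <- sample(20:48, 1)
    n <- sample(3:12, 1)
    repeat {
      xy <- cbind(sample(0:(nc - 1), n, TRUE), sample(0:(nr - 1), n, TRUE))
      if (!anyDuplicated(xy)) break
    }
    sds <- data.frame(id = seq_len(n), x = xy[, 1], y = xy[, 2],
                      dapi_intensity = runif(n))
    r <- sample(c(3, 4.5, 6, 8), 1)
    seg <- grow_segments(seed_set(sds, c(nr, nc)), radius_px = r)
    expect_identical(seg$labels,
                     capped_voronoi_oracle(sds, c(nr, nc), r))
  }
})

test_that("equidistant pixels go to the smaller seed id", {
  # seeds at x = 10 and x = 14: the column x = 12 is equidistant
  s <- seed_set(data.frame(id = 1:2, x = c(10, 14), y = c(10, 10),
                           dapi_intensity = c(1, 1)), c(21, 25))
  seg <- grow_segments(s, radius_px = 6)
  expect_true(all(seg$labels[, 13][seg$labels[, 13] > 0] == 1L))
})

test_that("segments only grow when the radius increases", {
  set.seed(3)
  sds <- data.frame(id = 1:6, x = sample(0:40, 6), y = sample(0:40, 6),
                    dapi_intensity = 1)
  s <- seed_set(sds, c(41, 41))
  seg4 <- grow_segments(s, radius_px = 4)
  seg7 <- grow_segments(s, radius_px = 7)
  for (k in 1:6) {
    grown <- which(seg4$labels == k)
    # a pixel can change owner only if it was contested; owned pixels within
    # the smaller radius stay with their nearest seed
    expect_true(all(seg7$labels[grown] == k))
  }
  expect_gte(sum(seg7$labels > 0), sum(seg4$labels > 0))
})

test_that("duplicate or out-of-bounds seeds are rejected", {
  dup <- data.frame(id = 1:2, x = c(5, 5), y = c(5, 5), dapi_intensity = 1)
  expect_error(grow_segments(seed_set(dup[1, ], c(10, 10))), NA)
  expect_error(grow_segments(seed_set(dup, c(10, 10))), "duplicate")
  out <- data.frame(id = 1L, x = 12, y = 5, dapi_intensity = 1)
  expect_error(seed_set(out, c(10, 10)), "bounds")
})

test_that("contact_graph captures shared edges and connectivity semantics", {
  seg <- segment_map(rbind(c(1L, 1L), c(2L, 2L)), 6)
  g <- contact_graph(seg, 4)
  expect_equal(g$edges, matrix(c(1L, 2L), 1))

  # diagonal-only contact
  segd <- segment_map(rbind(c(1L, 0L), c(0L, 2L)), 6)
  expect_equal(nrow(contact_graph(segd, 4)$edges), 0L)
  expect_equal(contact_graph(segd, 8)$edges, matrix(c(1L, 2L), 1))

  # separated by a 2-px background gap
  lab <- matrix(0L, 10, 16)
  lab[5, 2:4] <- 1L; lab[5, 7:9] <- 2L
  expect_equal(nrow(contact_graph(segment_map(lab, 6), 8)$edges), 0L)

  # background never creates edges
  expect_false(any(contact_graph(segment_map(lab, 6), 8)$nodes == 0L))
})

test_that("seed detection and segmentation recover the synthetic ground truth", {
  ch <- default_chain()
  expect_gte(ch$match$precision, 0.95)
  expect_gte(ch$match$recall, 0.95)
  tr <- ch$sim$truth
  true_seeds <- seed_set(data.frame(id = tr$cell_id, x = round(tr$x),
                                    y = round(tr$y), dapi_intensity = 1),
                         c(ch$cfg$height_px, ch$cfg$width_px))
  true_seg <- grow_segments(true_seeds, radius_px = 6)
  sel <- ch$seg$labels > 0 | true_seg$labels > 0
  expect_gte(ari(ch$seg$labels[sel], true_seg$labels[sel]), 0.8)
})
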