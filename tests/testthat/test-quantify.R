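simple_seg <- function() {
  lab <- matrix(0L, 8, 8)
  lab[2:4, 2:4] <- 1L
  lab[6:8, 6:8] <- 2L
  segment_map(lab, 6)
}

test_that("assign_transcripts credits counts to the right segments", {
  seg <- simple_seg()
  s <- sdge_table(data.frame(x = 2.7, y = 1.3, gene = "Alb", count = 3), 2.5)
  r <- assign_transcripts(s, seg)
  expect_equal(as.vector(r$matrix$counts[1, "Alb"]), 3)
  expect_equal(sum(r$matrix$counts), 3)
  expect_equal(r$unassigned_count, 0)

  # a record on background is tallied as unassigned
  s0 <- sdge_table(data.frame(x = 0.5, y = 0.5, gene = "Alb", count = 4), 2.5)
  r0 <- assign_transcripts(s0, seg)
  expect_equal(sum(r0$matrix$counts), 0)
  expect_equal(r0$unassigned_count, 4)

  # out-of-bounds records are rejected and reported
  sx <- sdge_table(data.frame(x = c(2.5, 99), y = c(2.5, 2), gene = "Alb",
                              count = c(1L, 2L)), 2.5)
  expect_warning(rx <- assign_transcripts(sx, seg), "rejected")
  expect_equal(rx$rejected_count, 2)
  expect_equal(sum(rx$matrix$counts) + rx$unassigned_count + rx$rejected_count,
               3)
})

test_that("counts are conserved exactly on random instances", {
  set.seed(17)
  for (i in 1:20) {
    nr <- sample(10:30, 1); nc <- sample(10:30, 1)
    lab <- matrix(sample(0:5, nr * nc, TRUE), nr, nc)
    seg <- segment_map(lab, 6)
    n <- 500
    s <- sdge_table(data.frame(x = runif(n, 0, nc), y = runif(n, 0, nr),
                               gene = sample(letters[1:6], n, TRUE),
                               count = sample(1:4, n, TRUE)), 2.5)
    r <- assign_transcripts(s, seg)
    expect_equal(sum(r$matrix$counts) + r$unassigned_count,
                 sum(s$records$count))
    # brute-force per-record re-tally for one gene/segment pair
    px <- floor(s$records$x); py <- floor(s$records$y)
    want <- sum(s$records$count[lab[cbind(py + 1, px + 1)] == 1L &
                                s$records$gene == "a"])
    got <- if (1L %in% r$matrix$cell_meta$segment_id &&
               "a" %in% r$matrix$gene_ids)
      as.vector(r$matrix$counts[match(1L, r$matrix$cell_meta$segment_id), "a"])
    else 0
    expect_equal(got, want)
  }
})

test_that("qc_filter applies the inclusive unique-feature rule and is idempotent", {
  counts <- rbind(c(rep(1L, 50), rep(0L, 200)),
                  c(rep(1L, 100), rep(0L, 150)),
                  rep(1L, 250))
  m <- cell_matrix(counts, data.frame(segment_id = 1:3),
                   paste0("g", 1:250))
  f <- qc_filter(m, qc_config(100))
  expect_equal(f$cell_meta$segment_id, c(2L, 3L))  # 100 features retained
  expect_equal(qc_filter(f, qc_config(100))$cell_meta$segment_id, c(2L, 3L))
  expect_equal(nrow(qc_filter(m, qc_config(0))$cell_meta), 3L)
  mz <- cell_matrix(matrix(0L, 2, 250), data.frame(segment_id = 1:2),
                    paste0("g", 1:250))
  expect_equal(nrow(qc_filter(mz, qc_config(100))$cell_meta), 0L)
})

test_that("quantify_fluorescence matches the per-pixel oracle", {
  seg <- simple_seg()
  const <- fluorescence_stack(list(GFP = matrix(5, 8, 8),
                                   tdTomato = matrix(5, 8, 8)), 2.5)
  f <- quantify_fluorescence(seg, const)
  expect_equal(f$GFP, c(5, 5))

  loc <- matrix(0, 8, 8); loc[7, 7] <- 2
  fl <- quantify_fluorescence(seg, fluorescence_stack(list(GFP = loc), 2.5))
  expect_equal(fl$GFP[fl$segment_id == 1], 0)
  expect_gt(fl$GFP[fl$segment_id == 2], 0)

  set.seed(2)
  rnd <- matrix(runif(64), 8, 8)
  fr <- quantify_fluorescence(seg, fluorescence_stack(list(GFP = rnd), 2.5))
  for (k in 1:2)
    expect_equal(fr$GFP[fr$segment_id == k], mean(rnd[seg$labels == k]))
  # max summary
  fm <- quantify_fluorescence(seg, fluorescence_stack(list(GFP = rnd), 2.5),
                              summary = "max")
  expect_equal(fm$GFP[1], max(rnd[seg$labels == 1]))
  expect_error(quantify_fluorescence(
    seg, fluorescence_stack(list(GFP = matrix(0, 4, 4)), 2.5)), "shape")
})

test_that("call_reporter follows the GFP/tdTomato truth table", {
  f <- data.frame(segment_id = 1:4,
                  GFP = c(2, 0.1, 2, 0.1),
                  tdTomato = c(2, 2, 0.1, 0.1))
  thr <- c(GFP = 1, tdTomato = 1)
  r <- call_reporter(f, thr)
  expect_equal(r$class, c("double", "tdtomato_only", "gfp_only", "none"))
  expect_equal(r$is_p21_positive, c(TRUE, TRUE, TRUE, FALSE))
  # restricted rule counts only tdTomato-involved classes
  r2 <- call_reporter(f, thr, p21_rule = "tdtomato")
  expect_equal(r2$is_p21_positive, c(TRUE, TRUE, FALSE, FALSE))
  # p21-positivity is equivalent to a non-none class under the "or" rule
  expect_equal(r$is_p21_positive, r$class != "none")
})

test_that("raising a threshold never converts a negative channel to positive", {
  set.seed(9)
  f <- data.frame(segment_id = 1:50, GFP = runif(50), tdTomato = runif(50))
  r1 <- call_reporter(f, c(GFP = 0.3, tdTomato = 0.3))
  r2 <- call_reporter(f, c(GFP = 0.6, tdTomato = 0.6))
  expect_true(all(r1$is_p21_positive | !r2$is_p21_positive))
  expect_true(all(!(r1$class == "none" & r2$class != "none")))
})

test_that("planted reporter cells are recovered from fluorescence", {
  ch <- default_chain()
  tr <- ch$sim$truth
  truth_p21 <- tr$is_p21_positive[ch$seg2true[match(ch$calls$segment_id,
                                                    ch$seeds$seeds$id)]]
  sens <- sum(ch$calls$is_p21_positive & truth_p21, na.rm = TRUE) /
    sum(truth_p21, na.rm = TRUE)
  fpr <- sum(ch$calls$is_p21_positive & !truth_p21, na.rm = TRUE) /
    sum(!truth_p21, na.rm = TRUE)
  expect_gte(sens, 0.9)
  expect_lte(fpr, 0.01)
  # called classes match the planted classes on the called positives
  called <- ch$calls[ch$calls$is_p21_positive, ]
  planted_cls <- tr$reporter_class[ch$seg2true[match(called$segment_id,
                                                     ch$seeds$seeds$id)]]
  expect_gte(mean(called$class == planted_cls, na.rm = TRUE), 0.9)
})
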