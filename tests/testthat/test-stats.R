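test_that("rank_sum_test matches exact enumeration on small samples", {
  # fully separated groups: only the observed extreme split on each side
  expect_equal(rank_sum_test(c(1, 2, 3), c(4, 5, 6)), 0.1, tolerance = 1e-12)
  # identical multisets are exchangeable
  expect_equal(rank_sum_test(c(2, 5, 9), c(2, 5, 9)), 1)
  expect_equal(rank_sum_test(rep(3, 4), rep(3, 5)), 1)
  expect_error(rank_sum_test(numeric(), 1:3), "non-empty")

  set.seed(15)
  for (i in 1:40) {
    m <- sample(2:6, 1); n <- sample(2:6, 1)
    v <- sample(1000, m + n)  # distinct values, no ties
    a <- v[seq_len(m)]; b <- v[-seq_len(m)]
    expect_equal(rank_sum_test(a, b), ranksum_enum_oracle(a, b),
                 tolerance = 1e-12)
  }
})

test_that("the normal approximation stays close to enumeration at n = 12", {
  set.seed(26)
  for (i in 1:20) {
    v <- sample(10000, 12)
    a <- v[1:6]; b <- v[7:12]
    p_norm <- suppressWarnings(
      stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value)
    expect_lte(abs(p_norm - ranksum_enum_oracle(a, b)), 0.02)
  }
})

test_that("bh_adjust reproduces the step-up procedure", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
  # order invariance up to the inverse permutation; monotone in raw-p order
  set.seed(19)
  p <- runif(30)
  q <- bh_adjust(p)
  o <- sample(30)
  expect_equal(bh_adjust(p[o]), q[o])
  expect_true(all(diff(q[order(p)]) >= -1e-12))
  expect_true(all(q <= 1))
  # bonferroni alternative
  expect_equal(bh_adjust(c(0.01, 0.4), method = "bonferroni"), c(0.02, 0.8))
})

test_that("fisher_exact_2x2 matches hypergeometric enumeration", {
  r <- fisher_exact_2x2(rbind(c(3, 1), c(1, 3)))
  expect_equal(r$p_value, 34 / 70, tolerance = 1e-9)
  expect_equal(r$odds_ratio, 9)

  # zero margin
  r0 <- fisher_exact_2x2(rbind(c(0, 0), c(5, 7)))
  expect_equal(r0$p_value, 1)
  expect_true(is.na(r0$odds_ratio))

  # infinite odds ratio when the off-diagonal vanishes
  ri <- fisher_exact_2x2(rbind(c(4, 0), c(2, 6)))
  expect_equal(ri$odds_ratio, Inf)

  set.seed(33)
  for (i in 1:60) {
    tab <- matrix(rpois(4, 4), 2, 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(fisher_exact_2x2(tab)$p_value, fisher_enum_oracle(tab),
                 tolerance = 1e-12)
  }
})

test_that("isg_score averages the panel and isg_call thresholds by quantile", {
  counts <- rbind(c(0L, 0L, 0L, 0L, 2L),
                  c(3L, 3L, 3L, 3L, 0L))
  m <- cell_matrix(counts, data.frame(segment_id = 1:2),
                   c("Rsad2", "Ifit1", "Cmpk2", "Ifit3", "Alb"))
  nm <- normalize_counts(m, target_sum = 2)
  sc <- isg_score(nm)
  expect_equal(unname(sc[1]), 0)
  # constant panel values average to themselves
  expect_equal(unname(sc[2]), mean(nm$values[2, 1:4]))
  set.seed(40)
  rn <- cell_matrix(matrix(rpois(50, 3) + 1L, 5, 10),
                    data.frame(segment_id = 1:5), paste0("g", 1:10))
  nmr <- normalize_counts(rn, 30)
  expect_equal(isg_score(nmr, panel = c("g2", "g5", "g9")),
               rowMeans(nmr$values[, c("g2", "g5", "g9")]))
  expect_equal(isg_score(nmr, panel = c("g2", "g5"), method = "sum"),
               rowSums(nmr$values[, c("g2", "g5")]))
  expect_error(isg_score(nmr, panel = "nope"), "no ISG panel genes")

  # constant scores: nothing exceeds the quantile strictly
  expect_equal(sum(isg_call(rep(2, 50), 0.9)), 0)
  # n distinct scores at quantile 0.99 -> exactly 10 positives
  set.seed(41)
  s1000 <- sample(seq(0, 1, length.out = 5000), 1000)
  expect_equal(sum(isg_call(s1000, 0.99)), 10L)
  expect_error(isg_call(1:5, 1.2), "between 0 and 1")
  # cluster mode
  expect_equal(isg_call(1:4, clusters = c(1, 2, 2, 1), isg_cluster = 2),
               c(FALSE, TRUE, TRUE, FALSE))
})

test_that("overlap_analysis calibrates on independent planted statuses", {
  set.seed(14)
  n <- 5000
  p21 <- runif(n) < 0.015
  isg <- runif(n) < 0.02
  repl <- sample(1:3, n, TRUE)
  ov <- overlap_analysis(p21, isg, repl)
  expect_equal(nrow(ov$per_replicate), 3L)
  expect_gte(sum(ov$per_replicate$p_value > 0.05), 2L)
  expect_equal(sum(ov$pooled$n), n)
  expect_equal(sum(ov$pooled$percent), 100, tolerance = 1e-9)
})

test_that("overlap_analysis detects perfectly nested statuses", {
  n <- 1000
  p21 <- c(rep(TRUE, 50), rep(FALSE, 950))
  isg <- p21  # nested: every p21+ cell is ISG+
  ov <- overlap_analysis(p21, isg)
  expect_lt(ov$per_replicate$p_value, 1e-6)
  # all-double-negative input: 100% in one category, p = 1 (zero margin)
  ov0 <- overlap_analysis(rep(FALSE, 20), rep(FALSE, 20))
  expect_equal(ov0$pooled$percent,
               c(0, 0, 0, 100))
  expect_equal(ov0$per_replicate$p_value, 1)
})

test_that("run_contrasts flags separated genes and skips tiny groups", {
  set.seed(50)
  n <- 60
  counts <- matrix(rpois(n * 20, 5) + 1L, n, 20)
  roles <- c(rep("p21_positive", 8), rep("neighbor", 10), rep("other", 42))
  counts[roles == "p21_positive", 1] <- counts[roles == "p21_positive", 1] + 40L
  m <- cell_matrix(counts, data.frame(segment_id = 1:n), paste0("g", 1:20))
  nm <- normalize_counts(m)
  ct <- run_contrasts(nm, roles, rep("hep", n))
  res <- ct$results[["hep.p21_vs_rest"]]
  expect_true(res$significant[res$gene == "g1"])
  expect_equal(res$p[res$gene == "g1"], min(res$p))
  expect_gt(res$log2fc[res$gene == "g1"], 0)

  # under-powered groups are skipped with a reason
  roles2 <- c(rep("p21_positive", 2), rep("other", 58))
  ct2 <- run_contrasts(nm, roles2, rep("hep", n))
  expect_null(ct2$results[["hep.p21_vs_rest"]])
  expect_match(ct2$skipped$reason[ct2$skipped$contrast == "p21_vs_rest"],
               "below min_cells")
  expect_error(run_contrasts(nm, rep("weird", n), rep("hep", n)), "unknown")
})

test_that("planted SASP genes reach significance in the p21+ macrophage contrast", {
  ch <- default_chain()
  ct <- run_contrasts(ch$nm, ch$roles, ch$types)
  mac <- ct$results[["macrophage.p21_vs_rest"]]
  expect_false(is.null(mac))
  planted <- c("Gpnmb", "Cxcl9", "Cxcl10")
  expect_true(all(mac$significant[mac$gene %in% planted]))
})

test_that("permuted niche labels produce almost no significant genes", {
  ch <- default_chain()
  set.seed(77)
  fracs <- replicate(20, {
    perm <- sample(ch$roles)
    ct <- run_contrasts(ch$nm, perm, ch$types)
    sig <- unlist(lapply(ct$results, function(r) r$significant))
    if (length(sig)) mean(sig) else 0
  })
  se <- stats::sd(fracs) / sqrt(length(fracs))
  expect_lte(mean(fracs), 0.05 + 3 * se)
})
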