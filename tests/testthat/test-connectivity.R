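test_that("unit traces are exact member-pixel means", {
  h <- matrix(0L, 1, 4); h[1, ] <- c(1L, 1L, 2L, 2L)
  mask <- mask_set(h)
  x <- matrix(rnorm(80), 20, 4)
  hm <- hemo_stack(x, -x, mask, 8)

  # single-pixel unit returns that pixel's trace
  tr <- unit_traces(hm, c(1L, 2L, 3L, 4L))
  expect_equal(tr[, 3], x[, 3])

  # x and -x cancel
  hm2 <- hm; hm2$hbo2[, 2] <- -x[, 1]
  tr2 <- unit_traces(hm2, c(1L, 1L, 2L, 2L))
  expect_equal(tr2[, 1], rep(0, 20))

  # equals a naive loop mean to 1e-12
  mem <- c(1L, 2L, 1L, 2L)
  tr3 <- unit_traces(hm, mem)
  for (u in 1:2) {
    expect_equal(tr3[, u], rowMeans(x[, mem == u, drop = FALSE]),
                 tolerance = 1e-12)
  }
  expect_error(unit_traces(hm, c(1L, 1L, 3L, 3L)), "empty unit")
})

test_that("two-path equality: region correlations from pixels equal trace correlations", {
  hemo <- small_processed()
  gt <- small_scenario()$ground_truth
  reg <- region_membership(gt, hemo)
  tr <- unit_traces(hemo, reg)
  direct <- matrix(0, ncol(tr), ncol(tr))
  for (i in seq_len(ncol(tr))) {
    for (j in seq_len(ncol(tr))) {
      direct[i, j] <- cor(rowMeans(hemo$hbo2[, reg == i, drop = FALSE]),
                          rowMeans(hemo$hbo2[, reg == j, drop = FALSE]))
    }
  }
  cm <- correlation_matrix(tr)
  expect_equal(unclass(cm)[, ], direct, tolerance = 1e-12)
  expect_identical(unclass(cm)[, ], t(unclass(cm)[, ]))
})

test_that("hemisphere/cluster reordering is a pure permutation with addressable quadrants", {
  set.seed(14)
  n <- 8
  tr <- matrix(rnorm(400 * n), 400, n)
  lab <- data.frame(id = 1:n,
                    hemisphere = rep(c("right", "left"), each = 4),
                    cluster = c(2, 1, 2, 1, 2, 1, 2, 1),
                    region = 1:n)
  cm <- correlation_matrix(tr, labels = lab)
  ro <- reorder_by_hemisphere_cluster(cm)
  lab2 <- attr(ro, "labels")
  expect_equal(lab2$hemisphere, rep(c("left", "right"), each = 4))
  expect_true(all(diff(lab2$cluster[lab2$hemisphere == "left"]) >= 0))

  # permutation invariants: off-diagonal multiset and eigenvalues unchanged
  expect_equal(sort(unclass(ro)[upper.tri(ro)]),
               sort(unclass(cm)[upper.tri(cm)]), tolerance = 1e-14)
  expect_equal(sort(eigen(unclass(ro)[, ], symmetric = TRUE)$values),
               sort(eigen(unclass(cm)[, ], symmetric = TRUE)$values),
               tolerance = 1e-12)

  # already-ordered input keeps the identity permutation
  ro2 <- reorder_by_hemisphere_cluster(ro)
  expect_equal(attr(ro2, "permutation"), seq_len(n))
  expect_equal(unclass(ro2)[, ], unclass(ro)[, ])

  q <- corr_quadrant(ro, "cross")
  expect_equal(dim(q), c(4L, 4L))
  expect_equal(attr(q, "row_labels")$hemisphere, rep("left", 4))
  expect_equal(attr(q, "col_labels")$hemisphere, rep("right", 4))
  expect_equal(q[2, 3], unclass(ro)[2, 4 + 3])

  lab_bad <- lab; lab_bad$hemisphere[2] <- "unknown"
  cm_bad <- correlation_matrix(tr, labels = lab_bad)
  expect_error(reorder_by_hemisphere_cluster(cm_bad), "unlabeled")
})

test_that("homotopic extraction partitions region pairs with the right counts", {
  set.seed(15)
  k <- 5
  tr <- matrix(rnorm(300 * 2 * k), 300, 2 * k)
  lab <- data.frame(id = 1:(2 * k), region = 1:(2 * k),
                    hemisphere = rep(c("left", "right"), each = k))
  cm <- correlation_matrix(tr, labels = lab, level = "region")
  rt <- region_table(data.frame(region = 1:(2 * k),
                                name = rep(paste0("R", 1:k), 2),
                                hemisphere = rep(c("left", "right"), each = k)))
  ex <- extract_homotopic(cm, rt)
  expect_length(ex$homotopic, 5)
  expect_equal(nrow(ex$non_homotopic), 40)    # 45 total pairs - 5 homotopic
  expect_equal(sum(ex$non_homotopic$category == "within"), 20)
  expect_equal(sum(ex$non_homotopic$category == "cross"), 20)
  for (i in 1:k) {
    expect_equal(unname(ex$homotopic[i]), unclass(cm)[i, k + i])
  }

  # cross-quadrant diagonal equals the homotopic values (two-path check)
  clv <- rep(1L, 2 * k)
  cm2 <- correlation_matrix(tr, labels = cbind(lab, cluster = clv))
  ro <- reorder_by_hemisphere_cluster(cm2)
  q <- corr_quadrant(ro, "cross")
  expect_equal(unname(diag(q)), unname(ex$homotopic))

  # no declared partners -> empty homotopic set
  rt0 <- region_table(data.frame(region = 1:(2 * k),
                                 name = paste0("U", 1:(2 * k)),
                                 hemisphere = rep(c("left", "right"), each = k)))
  ex0 <- extract_homotopic(cm, rt0)
  expect_length(ex0$homotopic, 0)
  expect_equal(nrow(ex0$non_homotopic), 45)

  # a partner missing from the matrix is an error
  cm_small <- correlation_matrix(tr[, 1:9],
                                 labels = lab[1:9, ])
  expect_error(extract_homotopic(cm_small, rt), "missing")
})

test_that("pooled pair counts reproduce the study's bookkeeping", {
  counts <- pooled_pair_counts(example_subject_regions())
  expect_equal(unname(counts["homotopic"]), 30L)
  expect_equal(unname(counts["non_homotopic"]), 84L)

  # the per-region multiplicities behind the pool
  tab <- table(unlist(example_subject_regions()))
  expect_equal(as.vector(tab[c("nidopallium", "mesopallium", "somatosensory Wulst",
                               "visual Wulst", "hippocampal formation")]),
               c(2L, 7L, 8L, 8L, 5L))
})

test_that("seed correlation maps are bounded, masked, and self-consistent", {
  hemo <- small_processed()
  gt <- small_scenario()$ground_truth
  reg <- region_membership(gt, hemo)

  img <- seed_correlation_map(hemo, reg == 1L)
  expect_true(all(is.na(img[!hemo$mask$brain])))
  vals <- img[hemo$mask$brain]
  expect_true(all(vals >= -1 - 1e-12 & vals <= 1 + 1e-12))
  # the seed's own region correlates strongly with its mean trace
  expect_gt(median(img[gt$region_map == 1L & hemo$mask$brain], na.rm = TRUE), 0.5)

  # a pixel whose trace equals the seed mean has r = 1
  h <- matrix(0L, 1, 3); h[1, ] <- c(1L, 1L, 2L)
  mask <- mask_set(h)
  x <- matrix(rnorm(60), 20, 3)
  x[, 3] <- rowMeans(x[, 1:2])
  hm <- hemo_stack(x, -x, mask, 8)
  m <- seed_correlation_map(hm, c(TRUE, TRUE, FALSE))
  expect_equal(m[1, 3], 1)

  expect_error(seed_correlation_map(hm, logical(3)), "non-empty")
  x0 <- x; x0[, 1:2] <- 1
  expect_error(seed_correlation_map(hemo_stack(x0, -x0, mask, 8),
                                    c(TRUE, TRUE, FALSE)), "zero-variance")
})
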