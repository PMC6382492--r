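test_that("geodesic distance takes unit and diagonal steps correctly", {
  d <- c(7, 7, 7)
  seed <- array(FALSE, d); seed[4, 4, 4] <- TRUE
  domain <- array(TRUE, d)
  D <- geodesic_distance(seed, domain)
  expect_equal(D[4, 4, 4], 0)
  expect_equal(D[5, 4, 4], 1)
  expect_equal(D[5, 5, 4], sqrt(2))
  expect_equal(D[5, 5, 5], sqrt(3))
  expect_equal(D[6, 4, 4], 2)
  # spacing-aware mm mode
  Dmm <- geodesic_distance(seed, domain, spacing = c(2, 1, 1))
  expect_equal(Dmm[5, 4, 4], 2)
  expect_equal(Dmm[4, 5, 4], 1)
  expect_error(geodesic_distance(seed & FALSE, domain), "empty seed")
})

test_that("non-traversable and unreachable voxels are infinite", {
  d <- c(9, 9, 9)
  seed <- array(FALSE, d); seed[2, 2, 2] <- TRUE
  domain <- array(FALSE, d)
  domain[2:4, 2, 2] <- TRUE      # a reachable arm
  domain[8, 8, 8] <- TRUE        # an island
  D <- geodesic_distance(seed, domain)
  expect_equal(D[4, 2, 2], 2)
  expect_true(is.infinite(D[8, 8, 8]))
  expect_true(is.infinite(D[5, 5, 5]))  # not in the domain at all
})

test_that("geodesic distances match an independent Dijkstra oracle", {
  set.seed(31)
  for (i in 1:6) {
    d <- c(12, 12, 12)
    domain <- array(runif(prod(d)) < 0.55, d)
    seed <- array(FALSE, d)
    seed[sample(prod(d), 3)] <- TRUE
    D <- geodesic_distance(seed, domain)
    O <- igraph_geodesic(seed, domain)
    expect_lt(max(abs(D[is.finite(D)] - O[is.finite(O)])), 1e-9)
    expect_identical(is.infinite(D), is.infinite(O))
  }
})

test_that("finite geodesic distances satisfy the triangle property", {
  set.seed(41)
  d <- c(16, 16, 16)
  domain <- array(runif(prod(d)) < 0.6, d)
  seed <- array(FALSE, d); seed[8, 8, 8] <- TRUE
  D <- geodesic_distance(seed, domain)
  trav <- domain | seed
  co <- arrayInd(which(trav & is.finite(D)), d)
  for (r in seq_len(nrow(co))) {
    p <- co[r, ]
    for (off in list(c(1, 0, 0), c(0, 1, 0), c(1, 1, 0), c(1, 1, 1))) {
      q <- p + off
      if (any(q < 1) || any(q > d)) next
      if (!trav[q[1], q[2], q[3]]) next
      step <- sqrt(sum(off^2))
      expect_lte(D[p[1], p[2], p[3]],
                 D[q[1], q[2], q[3]] + step + 1e-12)
    }
  }
})

test_that("leukoaraiosis weight is (1+S)^2 with clipping", {
  svd <- array(c(0, 0.5, 1, rep(0, 24)), c(3, 3, 3))
  L <- leukoaraiosis_weight(svd)
  expect_equal(L[1, 1, 1], 1)
  expect_equal(L[2, 1, 1], 2.25)
  expect_equal(L[3, 1, 1], 4)
  expect_true(all(L >= 1 & L <= 4))
  bad <- array(1.5, c(2, 2, 2))
  expect_warning(Lb <- leukoaraiosis_weight(bad), "clipped")
  expect_true(all(Lb == 4))
})

test_that("dynamic threshold map has the right boundary behaviour", {
  D <- array(c(0, Inf, 15, 30), c(4, 1, 1))
  L <- array(1, c(4, 1, 1))
  tm <- dynamic_threshold_map(200, D, L, lambda = 15)
  expect_equal(tm[1, 1, 1], 100)            # base_T / 2 on the haematoma
  expect_true(is.infinite(tm[2, 1, 1]))     # unreachable: never included
  expect_equal(tm[3, 1, 1], 200)            # crosses base_T at D*L = lambda
  expect_equal(tm[4, 1, 1], 300)
  # weighting inflates effective distance
  L2 <- array(2, c(4, 1, 1))
  tm2 <- dynamic_threshold_map(200, D, L2, lambda = 15)
  expect_gt(tm2[3, 1, 1], tm[3, 1, 1])
  expect_error(dynamic_threshold_map(200, D, L, lambda = 0), "positive")
  # squared variant shares the boundary behaviour at D = 0 and D = Inf
  tms <- dynamic_threshold_map(200, D, L, lambda = 15, variant = "squared")
  expect_equal(tms[1, 1, 1], 100)
  expect_true(is.infinite(tms[2, 1, 1]))
})

test_that("oedema recovery, distant-lesion exclusion and SVD weighting", {
  spec <- fixture_catalogue()$connected_leukoaraiosis
  case <- generate_case(spec)
  res <- suppressMessages(run_case(case$t2s, case$flair, case$labels, case$svd))
  expect_gte(dice_score(res$oedema, case$truth_oedema), 0.90)

  # the unreachable distant lesion is never claimed as oedema
  far <- spec$leukoaraiosis[[2]]
  blob_far <- array(FALSE, dim(case$svd))
  co <- arrayInd(seq_along(blob_far), dim(blob_far))
  dist2 <- (co[, 1] - far$centre[1])^2 + (co[, 2] - far$centre[2])^2 +
    (co[, 3] - far$centre[3])^2
  blob_far[dist2 <= far$radius^2] <- TRUE
  expect_equal(sum(res$oedema & blob_far), 0)

  # zeroing the SVD map can only add oedema voxels
  res0 <- suppressMessages(run_case(case$t2s, case$flair, case$labels,
                                    array(0, dim(case$svd))))
  expect_gt(sum(res0$oedema), sum(res$oedema))
  near <- spec$leukoaraiosis[[1]]
  blob_near <- array(FALSE, dim(case$svd))
  dist2n <- (co[, 1] - near$centre[1])^2 + (co[, 2] - near$centre[2])^2 +
    (co[, 3] - near$centre[3])^2
  blob_near[dist2n <= near$radius^2] <- TRUE
  expect_lt(sum(res$oedema & blob_near), sum(res0$oedema & blob_near))
})

test_that("pre-morphology oedema is monotone in lambda and in the SVD map", {
  case <- generate_case(phantom_spec())
  res <- suppressMessages(run_case(case$t2s, case$flair, case$labels, case$svd))
  stats_flair <- suppressMessages(
    robust_stats(case$flair, res$bundle$brain))
  segs <- lapply(c(5, 15, 50), function(lam)
    segment_oedema(case$flair, res$bundle$brain, res$haematoma, stats_flair,
                   case$svd, lambda = lam)$initial)
  expect_true(all(segs[[2]][segs[[1]]]))   # lambda 5 subset of lambda 15
  expect_true(all(segs[[3]][segs[[2]]]))   # lambda 15 subset of lambda 50
  # raising SVD voxel-wise never adds voxels
  hi <- segment_oedema(case$flair, res$bundle$brain, res$haematoma, stats_flair,
                       array(0.8, dim(case$svd)), lambda = 15)$initial
  lo <- segment_oedema(case$flair, res$bundle$brain, res$haematoma, stats_flair,
                       array(0, dim(case$svd)), lambda = 15)$initial
  expect_true(all(lo[hi]))
})

test_that("oedema and haematoma labels are disjoint", {
  case <- generate_case(phantom_spec())
  res <- suppressMessages(run_case(case$t2s, case$flair, case$labels, case$svd))
  expect_equal(sum(res$oedema & res$haematoma), 0)
  expect_error(
    segment_oedema(case$flair, res$bundle$brain,
                   array(FALSE, dim(case$svd)),
                   suppressMessages(robust_stats(case$flair, res$bundle$brain)),
                   case$svd),
    "empty haematoma")
})
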