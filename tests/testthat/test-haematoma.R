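test_that("component weight follows o^2 (l+1)/(s+1)", {
  expect_equal(component_weight(0, 5, 100), 0)   # no hyper overlap: zero
  expect_equal(component_weight(0, 0, 0), 0)
  expect_equal(component_weight(2, 1, 3), 8)     # 4 * 4/2
  expect_equal(component_weight(5, 0, 0), 25)
  expect_equal(component_weight(c(0, 2, 5), c(0, 1, 0), c(0, 3, 0)),
               c(0, 8, 25))
})

test_that("component selection maximises w*S with deterministic ties", {
  mk <- function(scores) {
    tab <- data.frame(id = seq_along(scores), volume = rev(seq_along(scores)),
                      score = scores)
    structure(list(labels = NULL, table = tab), class = "ich_components")
  }
  expect_equal(select_t2s_component(mk(c(80, 50)))$id, 1)
  expect_equal(select_t2s_component(mk(c(50, 80)))$id, 2)
  expect_equal(select_t2s_component(mk(c(3, 7, 7)))$id, 2)  # first max wins
  expect_error(select_t2s_component(mk(c(0, 0))), "no haematoma",
               class = "ich_no_haematoma")
  # random tables vs a linear-scan oracle
  set.seed(77)
  for (i in 1:20) {
    s <- runif(sample(2:8, 1)) * sample(c(0, 1), 1)
    if (all(s == 0)) next
    expect_equal(select_t2s_component(mk(s))$id, which.max(s))
  }
})

test_that("scored components count overlaps against context masks", {
  m <- array(FALSE, c(10, 10, 10))
  m[2:4, 2:4, 2] <- TRUE             # 9-voxel sheet
  m[8, 8, 8] <- TRUE                 # singleton
  cc <- connected_components(m, 6)
  hyper <- array(FALSE, c(10, 10, 10)); hyper[2:3, 2:4, 2] <- TRUE
  susc <- array(FALSE, c(10, 10, 10)); susc[8, 8, 8] <- TRUE
  lesion <- array(FALSE, c(10, 10, 10)); lesion[2:4, 2:4, 1:3] <- TRUE
  cc <- score_components(cc, hyper, susc, lesion)
  big <- cc$table[cc$table$volume == 9, ]
  small <- cc$table[cc$table$volume == 1, ]
  expect_equal(big$o, 6); expect_equal(big$s, 0); expect_equal(big$l, 9)
  expect_equal(big$w, 36 * 10)
  expect_equal(small$o, 0); expect_equal(small$s, 1)
  expect_equal(small$w, 0)
})

test_that("haemorrhage threshold implements the skewness-corrected rule", {
  t1 <- haemorrhage_threshold(c(1, 2, 3))
  expect_equal(t1$H, 2); expect_false(t1$corrected)

  t2 <- haemorrhage_threshold(c(0, 10, 11, 12, 13))
  expect_equal(t2$mu, 9.2)
  expect_equal(t2$nu, 11)
  expect_true(t2$corrected)
  expect_equal(t2$H, -1.6)
  # population sd and the 2k-sigma identity: H - mu = 2 k sigma
  expect_equal(t2$sigma, sqrt(mean((c(0, 10, 11, 12, 13) - 9.2)^2)))
  expect_equal(t2$H - t2$mu, 2 * t2$k * t2$sigma, tolerance = 1e-9)

  t3 <- haemorrhage_threshold(rep(42, 10))
  expect_equal(t3$H, 42); expect_false(t3$corrected)

  set.seed(88)
  for (i in 1:20) {
    x <- rnorm(50)^3  # skewed draws in both directions across repeats
    tt <- haemorrhage_threshold(x)
    if (tt$corrected) {
      expect_lt(tt$H, tt$mu)
      expect_equal(tt$H - tt$mu, 2 * tt$k * tt$sigma, tolerance = 1e-9)
    } else {
      expect_equal(tt$H, tt$mu)
    }
  }
})

test_that("weak-link removal deletes exactly the axis-aligned bridge voxels", {
  seg <- array(FALSE, c(7, 7, 7))
  seg[3:5, 4, 4] <- TRUE             # straight 3-voxel segment
  out <- break_weak_links(seg)
  expect_false(out[4, 4, 4])
  expect_equal(sum(out), 2)

  cube <- array(FALSE, c(7, 7, 7)); cube[3:5, 3:5, 3:5] <- TRUE
  expect_identical(break_weak_links(cube), cube)

  lone <- array(FALSE, c(7, 7, 7)); lone[4, 4, 4] <- TRUE
  expect_identical(break_weak_links(lone), lone)

  # diagonal bridges are not linear patterns and survive
  diagseg <- array(FALSE, c(7, 7, 7))
  diagseg[3, 3, 3] <- diagseg[4, 4, 4] <- diagseg[5, 5, 5] <- TRUE
  expect_identical(break_weak_links(diagseg), diagseg)
})

test_that("weak-link removal is anti-extensive and one-pass idempotent on bridges", {
  for (s in 1:20) {
    m <- random_mask(c(9, 9, 9), p = 0.25, seed = 100 + s)
    out <- break_weak_links(m)
    expect_true(all(m[out]))  # output subset of input
  }
  # two blobs joined by a thin one-voxel tube get separated at the tube's
  # interior voxel, whose 26-neighbourhood is exactly the axis-aligned pair
  m <- array(FALSE, c(13, 13, 13))
  m[2:4, 4:6, 4:6] <- TRUE
  m[8:10, 4:6, 4:6] <- TRUE
  bridge <- m
  bridge[5:7, 5, 5] <- TRUE
  expect_equal(nrow(connected_components(bridge, 26)$table), 1)
  cut <- break_weak_links(bridge)
  expected <- bridge; expected[6, 5, 5] <- FALSE
  expect_identical(cut, expected)
  expect_equal(nrow(connected_components(cut, 26)$table), 2)
})

test_that("haematoma segmentation recovers the phantom and rejects decoys", {
  case <- generate_case(fixture_catalogue()$susceptibility_decoy)
  res <- suppressMessages(run_case(case$t2s, case$flair, case$labels, case$svd))
  expect_gte(dice_score(res$haematoma, case$truth_haematoma), 0.95)
  cand <- res$provenance$candidates
  decoy_rows <- cand[cand$s > 0 & cand$volume > 100, ]
  expect_gte(nrow(decoy_rows), 1)           # the decoy is present as a component
  expect_true(all(decoy_rows$w == 0))       # with zero context weight
  sel <- res$provenance$selected_component
  expect_gt(sel$o, 0)
  expect_equal(sel$s, 0)
})

test_that("final haematoma never enters the ventricles", {
  case <- generate_case(fixture_catalogue()$intraventricular)
  res <- suppressMessages(run_case(case$t2s, case$flair, case$labels, case$svd))
  expect_gt(sum(res$haematoma), 0)
  expect_equal(sum(res$haematoma & res$bundle$ventricle), 0)
})

test_that("an all-background scene raises a no-haematoma error", {
  d <- c(24, 24, 24)
  labels <- array(0L, d); labels[3:22, 3:22, 3:22] <- 16L
  set.seed(9)
  inten <- array(0, d)
  inten[labels != 0] <- rnorm(sum(labels != 0), 100, 2)
  vol <- intensity_volume(inten)
  bundle <- suppressMessages(build_mask_bundle(labels, vol, vol))
  stats <- robust_stats(vol, bundle$brain)
  # hypo voxels exist only as texture tail speckles with no hyper ring;
  # either no component scores, or nothing survives thresholding
  expect_error(
    segment_haematoma(vol, vol, bundle, stats, stats),
    class = "ich_no_haematoma")
})
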