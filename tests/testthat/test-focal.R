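make_suv <- function(values, spacing = c(1, 1, 1))
  suv_volume(values, spacing)

mask_of <- function(logical_arr, spacing = c(1, 1, 1))
  binary_mask(logical_arr, spacing)

test_that("threshold is marrow mean plus two population SDs", {
  v <- array(5, c(4, 4, 4))
  m <- array(FALSE, c(4, 4, 4)); m[1:2, 1, 1] <- TRUE
  # zero variance: THR equals the constant
  expect_equal(compute_threshold(make_suv(v), mask_of(m)), 5)
  # {0, 2}: mean 1, population SD 1 -> THR 3
  v[1, 1, 1] <- 0; v[2, 1, 1] <- 2
  expect_equal(compute_threshold(make_suv(v), mask_of(m)), 3)
  # empty marrow is an error
  expect_error(compute_threshold(make_suv(v),
                                 mask_of(array(FALSE, c(4, 4, 4)))),
               "threshold undefined")
})

test_that("threshold recovers mu + 2 sigma on Normal marrow samples", {
  set.seed(42)
  n <- c(22, 22, 22)  # ~10^4 voxels
  v <- array(pmax(rnorm(prod(n), 1.5, 0.2), 0), n)
  m <- array(TRUE, n)
  thr <- compute_threshold(make_suv(v), mask_of(m))
  # Monte-Carlo tolerance ~ 3 * sigma / sqrt(n)
  expect_lt(abs(thr - 1.9), 3 * 0.2 / sqrt(prod(n)) * 3)
})

test_that("MSAU matches hand arithmetic and a brute-force voxel loop", {
  v <- array(0, c(3, 3, 3))
  m <- array(FALSE, c(3, 3, 3))
  v[1, 1, 1] <- 2.5; v[2, 1, 1] <- 4.5; m[1:2, 1, 1] <- TRUE
  expect_equal(compute_msau(make_suv(v), 1.5, mask_of(m)), (1 + 9) / 2)
  # empty region: 0 by convention, so TSAU needs no special case
  expect_equal(compute_msau(make_suv(v), 1.5,
                            mask_of(array(FALSE, c(3, 3, 3)))), 0)
  # random region vs explicit loop
  set.seed(7)
  v <- array(runif(125, 0, 5), c(5, 5, 5))
  m <- array(runif(125) < 0.3, c(5, 5, 5))
  thr <- 1.2
  acc <- 0; cnt <- 0
  for (i in 1:5) for (j in 1:5) for (k in 1:5)
    if (m[i, j, k]) { acc <- acc + (v[i, j, k] - thr)^2; cnt <- cnt + 1 }
  expect_equal(compute_msau(make_suv(v), thr, mask_of(m)), acc / cnt)
})

test_that("TSAU is the product form and equals the direct voxel sum", {
  expect_equal(compute_tsau(5, 2), 10)
  expect_equal(compute_tsau(0, 0), 0)
  set.seed(8)
  v <- array(runif(216, 0, 4), c(6, 6, 6))
  m <- array(runif(216) < 0.25, c(6, 6, 6))
  spacing <- c(2, 3, 1.5)
  suv <- make_suv(v, spacing)
  msk <- mask_of(m, spacing)
  thr <- 0.8
  msau <- compute_msau(suv, thr, msk)
  tsau <- compute_tsau(msau, mask_volume_ml(msk))
  direct <- sum((v[m] - thr)^2) * prod(spacing) / 1000
  expect_equal(tsau, direct)
})

test_that("TSAU strictly increases when an abnormal voxel gets hotter", {
  v <- array(1, c(3, 3, 3)); v[2, 2, 2] <- 3
  m <- array(FALSE, c(3, 3, 3)); m[2, 2, 2] <- TRUE
  base <- compute_tsau(compute_msau(make_suv(v), 2, mask_of(m)),
                       mask_volume_ml(mask_of(m)))
  v[2, 2, 2] <- 3.5
  hotter <- compute_tsau(compute_msau(make_suv(v), 2, mask_of(m)),
                         mask_volume_ml(mask_of(m)))
  expect_gt(hotter, base)
})

test_that("focal classification uses strict cut-offs 0.5 and 3.0", {
  expect_true(classify_focal(0.6, 0.0))
  expect_true(classify_focal(0.0, 3.1))
  expect_false(classify_focal(0.5, 3.0))  # exactly at cut-offs: not focal
  expect_false(classify_focal(0.0, 0.0))
})

test_that("raising the threshold never enlarges the candidate set", {
  set.seed(10)
  v <- array(runif(512, 0, 3), c(8, 8, 8))
  bone <- array(runif(512) < 0.5, c(8, 8, 8))
  prev <- sum(bone & v > 0.5)
  for (thr in c(1, 1.5, 2, 2.5)) {
    cur <- sum(bone & v > thr)
    expect_lte(cur, prev)
    prev <- cur
  }
})

test_that("watershed assigns candidates to in-bone vs out-of-bone maxima", {
  # two Gaussian bumps on a 1 mm grid: one peak inside bone, one outside
  n <- c(21, 9, 9)
  co <- coords_mm(n, c(1, 1, 1))
  g <- function(ctr, amp, sig) {
    d2 <- outer(outer((co[[1]] - ctr[1])^2, (co[[2]] - ctr[2])^2, `+`),
                (co[[3]] - ctr[3])^2, `+`)
    amp * exp(-d2 / (2 * sig^2))
  }
  v <- 0.2 + g(c(5, 4, 4), 3, 2.5) + g(c(15, 4, 4), 4, 2.5)
  # bone covers the left bump and reaches past the watershed divide, so
  # its far edge is lit by the out-of-bone (right) peak
  bone <- array(FALSE, n); bone[1:12, , ] <- TRUE
  suv <- make_suv(v)
  bm <- mask_of(bone)
  ws <- suv_watershed(suv)
  expect_equal(length(ws$maxima), 2)
  abn <- extract_abnormal_region(suv, bm, bm, 0.5,
                                 focal_config(min_region_ml = 0),
                                 watershed = ws)
  kept <- which(abn$voxels, arr.ind = TRUE)
  # survivors exist and all lie in the in-bone (left) catchment basin
  expect_gt(nrow(kept), 0)
  expect_true(all(kept[, 1] <= 10))
  # bone voxels lit by the out-of-bone bump were all removed
  removed <- bone & (v > 0.5) & !abn$voxels
  expect_gt(sum(removed), 0)
  rem_idx <- which(removed, arr.ind = TRUE)
  expect_true(all(rem_idx[, 1] >= 11))
})

test_that("plateau maxima are merged into a single basin", {
  v <- array(0, c(7, 7, 3))
  v[3:5, 3:5, 2] <- 1   # flat-topped ridge
  ws <- suv_watershed(make_suv(v))
  expect_equal(length(ws$maxima), 1)
  expect_equal(max(ws$labels), 1)
})

test_that("the minimum-volume filter is strict and idempotent", {
  # two components: 3 voxels (0.003 mL) and 150 voxels, 1 mm voxels
  m <- array(FALSE, c(12, 12, 12))
  m[1:3, 1, 1] <- TRUE
  m[5:10, 5:9, 5:9] <- TRUE
  f1 <- tsau:::filter_small_regions(m, c(1, 1, 1), 0.1)
  expect_equal(sum(f1), 150)
  expect_identical(tsau:::filter_small_regions(f1, c(1, 1, 1), 0.1), f1)
  # exactly at the limit survives ("smaller than" is strict)
  m2 <- array(FALSE, c(120, 2, 2)); m2[1:100, 1, 1] <- TRUE  # 0.1 mL
  expect_equal(sum(tsau:::filter_small_regions(m2, c(1, 1, 1), 0.1)), 100)
})

test_that("no candidate voxels means an empty abnormal region and TSAU 0", {
  lab <- tiny_bone_fixture()
  v <- array(1, dim(lab$labels))
  suv <- make_suv(v, lab$spacing)
  bone <- mask_of(array(lab$labels == 1L, dim(lab$labels)), lab$spacing)
  abn <- extract_abnormal_region(suv, bone, bone, 2)
  expect_equal(sum(abn$voxels), 0)
  expect_equal(compute_tsau(compute_msau(suv, 2, abn),
                            mask_volume_ml(abn)), 0)
})

test_that("cut-off tuning prefers PPV at target with the NPV floor met", {
  res <- tune_cutoff(c(1, 2, 3, 4), c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(res$cutoff, 2.5)
  expect_equal(res$ppv, 1)
  expect_equal(res$npv, 1)
  expect_error(tune_cutoff(c(1, 2), c(FALSE, FALSE)), "positive label")
  expect_error(tune_cutoff(c(1, 2), c(TRUE, TRUE)), "negative label")
})

test_that("tuned cut-off agrees with an exhaustive scan", {
  set.seed(21)
  scores <- round(c(rnorm(14, 3, 1.2), rnorm(6, 5.5, 1)), 2)
  labels <- c(rep(FALSE, 14), rep(TRUE, 6))
  labels[20] <- FALSE  # one mislabelled high score
  res <- tune_cutoff(scores, labels, ppv_target = 0.65, npv_target = 0.9)
  # oracle: scan a dense threshold sequence, apply the same decision rule
  cand <- seq(min(scores) - 1, max(scores) + 1, by = 0.001)
  eval_at <- function(cut) {
    pred <- scores > cut
    c(ppv = if (any(pred)) sum(pred & labels) / sum(pred) else NA,
      npv = if (any(!pred)) sum(!pred & !labels) / sum(!pred) else NA)
  }
  stats <- t(vapply(cand, eval_at, c(ppv = 0, npv = 0)))
  ok <- !is.na(stats[, "npv"]) & stats[, "npv"] >= 0.9 & !is.na(stats[, "ppv"])
  reach <- ok & stats[, "ppv"] >= 0.65
  best_ppv <- if (any(reach)) max(stats[reach, "ppv"]) else
    stats[ok, "ppv"][which.min(abs(stats[ok, "ppv"] - 0.65))]
  at <- eval_at(res$cutoff)
  expect_equal(unname(at["ppv"]), res$ppv)
  expect_equal(unname(at["npv"]), res$npv)
  expect_equal(res$ppv, best_ppv)
  expect_gte(res$npv, 0.9)
})

test_that("an unreachable NPV floor reports the best achievable NPV", {
  # positives and negatives fully interleaved: every split leaves FNs
  scores <- c(1, 2, 3, 4, 5, 6)
  labels <- c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE)
  expect_error(tune_cutoff(scores, labels, npv_target = 0.999),
               "best achievable NPV")
})
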