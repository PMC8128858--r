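test_that("zero margins reproduce the bone mask exactly", {
  lab <- tiny_bone_fixture()
  cfg <- marrow_config(margins = setNames(
    rep(0, 10), c("humerus", "femur", "vertebra", "hip_bone", "sacrum",
                  "coccyx", "scapula", "clavicle", "rib", "sternum")))
  marrow <- extract_marrow(lab, cfg)
  expect_identical(marrow$voxels, array(lab$labels == 1L, dim(lab$labels)))
})

test_that("erosion of a 10 mm sphere matches the brute-force distance oracle", {
  # 1 mm isotropic grid, sphere radius 10 mm, margin 3 mm
  n <- 25
  co <- coords_mm(c(n, n, n), c(1, 1, 1))
  ctr <- rep(12, 3)
  d2 <- outer(outer((co[[1]] - ctr[1])^2, (co[[2]] - ctr[2])^2, `+`),
              (co[[3]] - ctr[3])^2, `+`)
  labels <- array(0L, c(n, n, n))
  labels[d2 <= 10^2] <- 1L
  lab <- bone_label_volume(labels, data.frame(label = 1, name = "vertebra"),
                           spacing = c(1, 1, 1))
  marrow <- extract_marrow(lab, marrow_config(margins = c(vertebra = 3)))

  inside <- array(labels == 1L, dim(labels))
  dist <- brute_force_boundary_dist(inside, c(1, 1, 1))
  expected <- array(FALSE, dim(labels))
  expected[inside] <- dist >= 3
  expect_identical(marrow$voxels, expected)
})

test_that("erosion respects anisotropic spacing in physical mm", {
  # slab 3 voxels thick along z at 4 mm spacing: a 5 mm margin from each
  # face leaves exactly the central plane; at 1 mm z-spacing it empties
  labels <- array(0L, c(9, 9, 5)); labels[3:7, 3:7, 2:4] <- 1L
  tax <- data.frame(label = 1, name = "sternum")
  thick <- extract_marrow(bone_label_volume(labels, tax, c(20, 20, 4)),
                          marrow_config(margins = c(sternum = 5)))
  expect_true(all(which(thick$voxels, arr.ind = TRUE)[, 3] == 3))
  expect_gt(sum(thick$voxels), 0)
  thin <- extract_marrow(bone_label_volume(labels, tax, c(20, 20, 1)),
                         marrow_config(margins = c(sternum = 5)))
  expect_equal(sum(thin$voxels), 0)
})

test_that("margin above the inradius empties the bone without error", {
  lab <- tiny_bone_fixture(bone_radius = 4)
  marrow <- extract_marrow(lab, marrow_config(margins = c(vertebra = 50)))
  expect_equal(sum(marrow$voxels), 0)
})

test_that("increasing a margin never adds marrow voxels", {
  lab <- generate_phantom(compact_spec(seed = 5))$labels
  prev <- extract_marrow(lab, marrow_config())$voxels
  for (extra in c(2, 5)) {
    cfg <- marrow_config(margins = c(humerus = 7 + extra, femur = 7 + extra,
                                     vertebra = 5 + extra, hip_bone = 5 + extra,
                                     sacrum = 3 + extra, coccyx = 3 + extra,
                                     scapula = 3 + extra, clavicle = 3 + extra,
                                     rib = 3 + extra, sternum = 3 + extra))
    cur <- extract_marrow(lab, cfg)$voxels
    expect_true(all(prev | !cur))  # cur subset of prev
    prev <- cur
  }
})

test_that("erosion is invariant under relabelling within a class", {
  ph <- generate_phantom(compact_spec(seed = 5))
  lab <- ph$labels
  m1 <- extract_marrow(lab)
  # swap the ids of two vertebrae
  v_ids <- lab$taxonomy$label[lab$taxonomy$name == "vertebra"][1:2]
  swapped <- lab$labels
  swapped[lab$labels == v_ids[1]] <- -1L
  swapped[lab$labels == v_ids[2]] <- v_ids[1]
  swapped[swapped == -1L] <- v_ids[2]
  lab2 <- bone_label_volume(swapped, lab$taxonomy, lab$spacing)
  m2 <- extract_marrow(lab2)
  expect_identical(m1$voxels, m2$voxels)
})

test_that("unclassified bone labels are rejected", {
  labels <- array(0L, c(6, 6, 6)); labels[3, 3, 3] <- 1L
  lab <- bone_label_volume(labels, data.frame(label = 1, name = "rib"),
                           c(1, 1, 1))
  cfg <- marrow_config()
  cfg$margins <- cfg$margins[names(cfg$margins) != "rib"]
  expect_error(extract_marrow(lab, cfg), "no erosion margin")
})

test_that("hip voxels split at the 50 mm shell, verified by all-pairs distance", {
  # small grid: one vertebra blob and a hip bar straddling 50 mm
  labels <- array(0L, c(40, 8, 8))
  labels[2:4, 4:6, 4:6] <- 1L             # spine core
  labels[8:35, 4:6, 4:6] <- 2L            # hip bar along x
  tax <- data.frame(label = 1:2, name = c("vertebra", "hip_bone"))
  lab <- bone_label_volume(labels, tax, spacing = c(3, 3, 3))
  marrow <- extract_marrow(lab, marrow_config(
    margins = c(vertebra = 0, hip_bone = 0)))
  g <- assign_groups(lab, marrow)

  co <- coords_mm(dim(labels), c(3, 3, 3))
  spine_idx <- which(labels == 1L, arr.ind = TRUE)
  spine_pos <- cbind(co[[1]][spine_idx[, 1]], co[[2]][spine_idx[, 2]],
                     co[[3]][spine_idx[, 3]])
  hip_idx <- which(labels == 2L, arr.ind = TRUE)
  for (k in seq_len(nrow(hip_idx))) {
    p <- c(co[[1]][hip_idx[k, 1]], co[[2]][hip_idx[k, 2]],
           co[[3]][hip_idx[k, 3]])
    dmin <- min(sqrt(rowSums((spine_pos -
      matrix(p, nrow(spine_pos), 3, byrow = TRUE))^2)))
    in_spine <- g$spine$voxels[hip_idx[k, 1], hip_idx[k, 2], hip_idx[k, 3]]
    expect_equal(in_spine, dmin <= 50)
  }
  # both sides of the shell are populated
  expect_gt(sum(g$spine$voxels & labels == 2L), 0)
  expect_gt(sum(g$other$voxels & labels == 2L), 0)
})

test_that("spine and other groups partition the skeleton", {
  ph <- generate_phantom(compact_spec(seed = 9))
  marrow <- extract_marrow(ph$labels)
  g <- assign_groups(ph$labels, marrow)
  skel <- array(ph$labels$labels %in% ph$labels$taxonomy$label[
    ph$labels$taxonomy$name != "liver"], dim(ph$labels$labels))
  expect_false(any(g$spine$voxels & g$other$voxels))
  expect_identical(g$spine$voxels | g$other$voxels, skel)
  expect_true(all(!g$marrow_spine$voxels | g$spine$voxels))
  expect_true(all(!g$marrow_other$voxels | g$other$voxels))
  # marrow masks partition the marrow
  expect_identical(g$marrow_spine$voxels | g$marrow_other$voxels,
                   marrow$voxels)
})

test_that("without hip bones the spine group is exactly the spine core", {
  labels <- array(0L, c(10, 10, 10))
  labels[4:6, 4:6, 2:4] <- 1L; labels[4:6, 4:6, 6:8] <- 2L
  tax <- data.frame(label = 1:2, name = c("vertebra", "sacrum"))
  lab <- bone_label_volume(labels, tax, c(3, 3, 3))
  marrow <- extract_marrow(lab, marrow_config(
    margins = c(vertebra = 0, sacrum = 0)))
  g <- assign_groups(lab, marrow)
  expect_identical(g$spine$voxels, array(labels > 0L, dim(labels)))
  expect_equal(sum(g$other$voxels), 0)
})

test_that("an empty spine group is an error", {
  labels <- array(0L, c(6, 6, 6)); labels[2:4, 2:4, 2:4] <- 1L
  lab <- bone_label_volume(labels, data.frame(label = 1, name = "femur"),
                           c(3, 3, 3))
  marrow <- extract_marrow(lab)
  expect_error(assign_groups(lab, marrow), "empty spine group")
})
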