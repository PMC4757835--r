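test_that("orientation fields follow closed forms on simple patterns", {
  roi <- matrix(TRUE, 10, 10)
  # constant image: zero magnitude, no valid pixels
  of <- orientation_field(matrix(5, 10, 10), roi)
  expect_equal(max(of$magnitude), 0)
  expect_equal(sum(of$valid), 0L)
  # ramp increasing along +x (columns): all orientations 0 degrees
  ramp <- matrix(rep(1:10, each = 10), 10, 10, byrow = TRUE)
  ramp <- t(ramp)  # value = column index
  of2 <- orientation_field(ramp, roi)
  expect_true(all(of2$orientation[of2$valid] == 0))
  # 90-degree rotation shifts orientations by 90 (mod 360): compare the
  # multisets of inner-pixel orientations (the rotation maps the inner
  # region, unaffected by padding, onto itself)
  set.seed(4)
  img <- matrix(runif(144), 12, 12)
  rot <- t(img)[12:1, ]  # counter-clockwise rotation
  o1 <- orientation_field(img, matrix(TRUE, 12, 12))
  o2 <- orientation_field(rot, matrix(TRUE, 12, 12))
  inner <- 2:11
  a1 <- o1$orientation[inner, inner]
  a2 <- o2$orientation[inner, inner]
  expect_equal(sort((a1[!is.na(a1)] + 90) %% 360),
               sort(a2[!is.na(a2)]), tolerance = 1e-9)
})

test_that("LBP codes match hand enumeration and brute-force loops", {
  patch <- matrix(c(5, 2, 0, 4, 6, 9, 3, 1, 8), 3, 3)  # [[5,4,3],[2,6,1],[0,9,8]]
  lc <- lbp_codes(patch, matrix(TRUE, 3, 3))
  expect_identical(lc$codes[2, 2], 12L)  # neighbours (5,4,3,1,8,9,0,2) vs 6
  # constant image: every comparison ties, >= gives all ones
  cc <- lbp_codes(matrix(7, 5, 5), matrix(TRUE, 5, 5))
  expect_true(all(cc$codes[2:4, 2:4] == 255L))
  # strict peak at the centre
  peak <- matrix(1, 3, 3); peak[2, 2] <- 9
  expect_identical(lbp_codes(peak, matrix(TRUE, 3, 3))$codes[2, 2], 0L)
  # brute-force loop oracle on random images
  set.seed(31)
  for (rep in 1:5) {
    img <- matrix(sample.int(32, 144, replace = TRUE), 12, 12)
    lc <- lbp_codes(img, matrix(TRUE, 12, 12))
    for (r in 2:11) for (c in 2:11) {
      nb <- c(img[r - 1, c - 1], img[r - 1, c], img[r - 1, c + 1],
              img[r, c + 1], img[r + 1, c + 1], img[r + 1, c],
              img[r + 1, c - 1], img[r, c - 1])
      code <- sum((nb >= img[r, c]) * 2^(7:0))
      expect_identical(lc$codes[r, c], as.integer(code))
    }
  }
})

test_that("DHoG conserves counts and collapses on directional patterns", {
  l <- phantom_lesion()
  for (B in c(2L, 4L, 10L)) {
    d <- dhog_descriptor(l$series, l$mask, B = B, L = 3L)
    # each valid pixel is counted once per pyramid level
    expect_equal(rowSums(d$per_phase), d$valid_pixels * 3)
  }
  # pure ramp series: one orientation, a single nonzero bin, zero entropy
  s <- synth_series(16, 16, 5, function(r, c, t) 10 * c)
  m <- square_roi(16)
  for (B in c(2L, 4L, 8L)) {
    d <- dhog_descriptor(s, m, B = B)
    expect_equal(sum(d$histogram > 0), 1L)
    expect_equal(d$scalar, 0)
  }
  expect_error(dhog_descriptor(l$series, l$mask, B = 1L), "invalid")
})

test_that("rotating the series by 90 degrees cyclically shifts the 4-bin histogram", {
  l <- phantom_lesion()
  d1 <- dhog_descriptor(l$series, l$mask, B = 4L, L = 1L)
  dms <- dim(l$series$frames)
  rot_frames <- array(0, c(dms[2], dms[1], dms[3]))
  for (t in seq_len(dms[3]))  # counter-clockwise rotation of each frame
    rot_frames[, , t] <- t(l$series$frames[, , t])[dms[2]:1, ]
  rot_mask <- roi_mask(t(unclass(l$mask))[dms[2]:1, ])
  d2 <- dhog_descriptor(dce_series(rot_frames, l$series$times),
                        rot_mask, B = 4L, L = 1L)
  expect_equal(unname(d2$histogram), unname(d1$histogram[c(4, 1, 2, 3)]),
               tolerance = 1e-6)
})

test_that("DHoG panel has 5 entries and is offset/scale invariant", {
  l <- phantom_lesion()
  f1 <- dhog_features(l$series, l$mask)
  expect_length(f1, 5L)
  expect_identical(names(f1), feature_registry()$dhog)
  s2 <- dce_series(l$series$frames * 3 + 100, l$series$times)
  expect_equal(dhog_features(s2, l$mask), f1, tolerance = 1e-9)
  expect_identical(dhog_features(l$series, l$mask), f1)  # determinism
})

test_that("DLBP cell histograms are normalised with refinement consistency", {
  l <- phantom_lesion()
  d <- dlbp_descriptor(l$series, l$mask, B = 256L)
  sums <- rowSums(d$cell_hist)
  expect_true(all(abs(sums[sums > 0] - 1) < 1e-12))
  d8 <- dlbp_descriptor(l$series, l$mask, B = 8L)
  agg <- t(apply(d$cell_hist, 1, function(h) tapply(h, rep(1:8, each = 32), sum)))
  expect_equal(unname(as.matrix(agg)), unname(d8$cell_hist), tolerance = 1e-12)
  expect_error(dlbp_descriptor(l$series, l$mask, B = 7L), "invalid")
})

test_that("constant series concentrates DLBP mass into one bin per cell", {
  s <- const_series(24, 5, 60)
  m <- square_roi(24, margin = 3)
  d <- dlbp_descriptor(s, m, B = 256L, grid = 4L)
  # every cell is a point mass at code 255; the concatenation is uniform over
  # the nonempty cells, so the entropy is log2(#nonempty cells)
  nonzero <- which(d$cell_hist > 0, arr.ind = TRUE)
  expect_true(all(nonzero[, 2] == 256L))
  expect_equal(d$scalar, log2(sum(rowSums(d$cell_hist) > 0)))
  expect_equal(d$scalar, log2(16))
})

test_that("DLBP panel has 6 entries and is invariant to intensity offsets", {
  l <- phantom_lesion()
  f1 <- dlbp_features(l$series, l$mask)
  expect_length(f1, 6L)
  expect_identical(names(f1), feature_registry()$dlbp)
  s2 <- dce_series(l$series$frames + 250, l$series$times)
  expect_equal(dlbp_features(s2, l$mask), f1, tolerance = 1e-12)
})

test_that("per-cell histograms match a brute-force loop implementation", {
  set.seed(77)
  img <- matrix(sample.int(64, 144, replace = TRUE), 12, 12)
  fr <- array(img, c(12, 12, 4))
  s <- dce_series(fr, 0:3)
  m <- square_roi(12, margin = 2)
  d <- dlbp_descriptor(s, m, B = 256L, grid = 2L)
  # oracle: explicit loops over the bounding-box crop (codes are defined on
  # the working box, with box-border pixels invalid)
  bb <- 3:10
  crop <- img[bb, bb]
  roi <- unclass(m)[bb, bb]
  hists <- matrix(0, 4, 256)
  cells <- kinetex:::grid_cells(8, 8, 2L)
  for (r in 2:7) for (c in 2:7) {
    if (!roi[r, c]) next
    nb <- c(crop[r - 1, c - 1], crop[r - 1, c], crop[r - 1, c + 1],
            crop[r, c + 1], crop[r + 1, c + 1], crop[r + 1, c],
            crop[r + 1, c - 1], crop[r, c - 1])
    code <- sum((nb >= crop[r, c]) * 2^(7:0))
    cid <- cells[r, c]
    hists[cid, code + 1] <- hists[cid, code + 1] + 1
  }
  for (cid in 1:4) {
    if (sum(hists[cid, ]) == 0) next
    expect_equal(unname(d$cell_hist[cid, ]),
                 hists[cid, ] / sum(hists[cid, ]), tolerance = 1e-12)
  }
})

test_that("dynamic texture scalars respond to lesion heterogeneity", {
  # heterogeneity is the only varied parameter; cohort means over seeds
  hets <- c(0.05, 0.2, 0.5)
  m <- cached("het_mask", disk_mask(14, 48))
  vals <- sapply(hets, function(h) {
    per_seed <- sapply(1:6, function(s) {
      pk <- make_pk_field(m, heterogeneity = h, seed = s)
      sim <- simulate_dce(m, pk, dce_acquisition(), seed = 1000 + s)
      c(dlbp_descriptor(sim$series, m, B = 256L)$scalar,
        dhog_descriptor(sim$series, m, B = 4L)$scalar)
    })
    rowMeans(per_seed)
  })
  # DLBP entropy rises with heterogeneity (richer micro-pattern spectrum)
  expect_true(all(diff(vals[1, ]) > 0))
  # DHoG orientation entropy saturates near log2(4) and declines as
  # structured gradients concentrate orientations
  expect_true(all(diff(vals[2, ]) < 0))
  expect_lt(max(abs(vals[2, ] - 2)), 0.01)
})

test_that("heterogeneous and homogeneous classes separate on DLBP (rank-sum)", {
  m <- cached("het_mask", disk_mask(14, 48))
  lo <- sapply(1:10, function(s) {
    pk <- make_pk_field(m, heterogeneity = 0.05, seed = s)
    sim <- simulate_dce(m, pk, dce_acquisition(), seed = 2000 + s)
    dlbp_descriptor(sim$series, m, B = 256L)$scalar
  })
  hi <- sapply(1:10, function(s) {
    pk <- make_pk_field(m, heterogeneity = 0.5, seed = 100 + s)
    sim <- simulate_dce(m, pk, dce_acquisition(), seed = 3000 + s)
    dlbp_descriptor(sim$series, m, B = 256L)$scalar
  })
  w <- stats::wilcox.test(hi, lo, alternative = "greater")
  expect_lt(w$p.value, 0.01)
})
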