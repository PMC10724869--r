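test_that("vectorized indices match naive loop references on random subjects", {
  set.seed(11)
  for (k in 1:100) {
    hp <- random_hemi_pair()
    expect_equal(unname(distance_index(hp$left, hp$right)),
                 naive_distance_index(hp$left, hp$right), tolerance = 1e-12)
    expect_equal(unname(laterality_index(hp$left, hp$right)),
                 naive_laterality_index(hp$left, hp$right), tolerance = 1e-12)
    expect_equal(unname(subtraction_index(hp$left, hp$right)),
                 naive_subtraction_index(hp$left, hp$right), tolerance = 1e-12)
  }
})

test_that("mirror-symmetric and proportional hemispheres give the analytic values", {
  left <- dk_roi_means("volume")
  expect_equal(unname(distance_index(left, left)), rep(0, 34))
  expect_equal(unname(laterality_index(left, left)), rep(0, 34))
  expect_equal(unname(subtraction_index(left, left)), rep(0, 34))
  for (c_scale in c(0.5, 2, 1.3)) {
    right <- c_scale * left
    expect_equal(unname(distance_index(left, right)), rep(0, 34), tolerance = 1e-12)
    expect_equal(unname(laterality_index(left, right)),
                 rep(abs(1 - c_scale) / abs(1 + c_scale), 34), tolerance = 1e-12)
    expect_equal(unname(subtraction_index(left, right)),
                 abs(1 - c_scale) * unname(left), tolerance = 1e-12)
  }
})

test_that("4-ROI toy reproduces the hand-computed Pearson value", {
  left <- c(1, 2, 4, 8); right <- c(1, 2, 4, 7)
  di <- distance_index(left, right)
  # ROI 1 difference profiles: (1, 3, 7) vs (1, 3, 6)
  expect_equal(di[1], 1 - abs(stats::cor(c(1, 3, 7), c(1, 3, 6))), tolerance = 1e-12)
  expect_equal(di[1], 0.0029, tolerance = 0.1)
  expect_lt(abs(di[1] - 0.0029), 2e-4)
  expect_equal(di[4], 0)  # profiles (7, 6, 4) vs (6, 5, 3): both differences shift by 1
})

test_that("laterality index handles the worked pairwise examples and sign mixes", {
  expect_equal(unname(laterality_index(10, 8)), 1 / 9, tolerance = 1e-12)
  expect_equal(unname(subtraction_index(10, 8)), 2)
  # curvature-like sign mix: |0.3 / 0.1| = 3, > 1 permitted
  expect_equal(unname(laterality_index(0.2, -0.1)), 3, tolerance = 1e-12)
  expect_true(is.na(laterality_index(1, -1)))
})

test_that("indices respect bounds, scale invariance and zero-variance flagging", {
  set.seed(21)
  for (k in 1:20) {
    hp <- random_hemi_pair()
    di <- distance_index(hp$left, hp$right)
    li <- laterality_index(hp$left, hp$right)
    si <- subtraction_index(hp$left, hp$right)
    expect_true(all(di >= 0 & di <= 1, na.rm = TRUE))
    expect_true(all(li >= 0, na.rm = TRUE))
    expect_true(all(si >= 0))
    c_scale <- runif(1, 0.5, 3)
    expect_equal(distance_index(c_scale * hp$left, c_scale * hp$right), di,
                 tolerance = 1e-9)
    expect_equal(laterality_index(c_scale * hp$left, c_scale * hp$right), li,
                 tolerance = 1e-12)
    expect_equal(subtraction_index(c_scale * hp$left, c_scale * hp$right),
                 c_scale * si, tolerance = 1e-9)
  }
  # zero variance in a difference profile -> undefined, not zero
  left <- c(1, 3, 3, 3)  # ROI 2..4 profiles vs right all-constant
  expect_true(is.na(distance_index(left, rep(2, 4))[1]))
  expect_error(distance_index(c(1, 2), c(1, 2)), "at least 4")
})

test_that("proportionality blindness separates DI from SI", {
  left <- dk_roi_means("area")
  right <- 1.4 * left
  expect_equal(unname(distance_index(left, right)), rep(0, 34), tolerance = 1e-12)
  expect_true(all(subtraction_index(left, right) > 0))
})

test_that("upper-triangular difference scheme matches its definition", {
  set.seed(31)
  hp <- random_hemi_pair(8)
  di <- distance_index(hp$left, hp$right, scheme = "upper")
  for (i in 1:5) {
    j <- (i + 1):8
    expect_equal(unname(di[i]),
                 1 - abs(cor(abs(hp$left[i] - hp$left[j]),
                             abs(hp$right[i] - hp$right[j]))), tolerance = 1e-12)
  }
  expect_true(all(is.na(di[6:8])))  # profile shorter than 3 elements
})

test_that("table-level computation matches per-subject application and QC counts", {
  coh <- small_cohort(n = 10)
  mt <- coh$morphometry$volume
  ix <- compute_index_tables(mt)
  for (s in c(1, 7, 20)) {
    expect_equal(ix$DI[s, ], distance_index(mt$left[s, ], mt$right[s, ]))
    expect_equal(ix$LI[s, ], laterality_index(mt$left[s, ], mt$right[s, ]))
    expect_equal(ix$SI[s, ], subtraction_index(mt$left[s, ], mt$right[s, ]))
  }
  expect_equal(ix$qc$n_undefined, c(0L, 0L, 0L))
  # permuting subjects permutes rows only
  perm <- rev(seq_along(mt$subjects))
  mt2 <- morph_table(mt$left[perm, ], mt$right[perm, ], "volume")
  ix2 <- compute_index_tables(mt2, kinds = "DI")
  expect_equal(ix2$DI, ix$DI[perm, ])
})

test_that("mirror-symmetric cohort yields identically zero index tables", {
  coh <- small_cohort(n = 2)
  mt <- coh$morphometry$volume
  mirror <- morph_table(mt$left, mt$left, "volume")
  ix <- compute_index_tables(mirror)
  expect_lt(max(ix$DI), 1e-12)
  expect_true(all(ix$LI == 0))
  expect_true(all(ix$SI == 0))
})
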