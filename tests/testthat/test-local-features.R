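test_that("pick_analysis_slice takes the largest-area slice, ties low", {
  dims <- c(10L, 10L, 6L)
  mask <- array(FALSE, dims)
  mask[1:5, 1:10, 3] <- TRUE   # 50
  mask[1:8, 1:10, 4] <- TRUE   # 80
  mask[1:2, 1:10, 5] <- TRUE   # 20
  sl <- pick_analysis_slice(toy_volume(dims, mask = mask))
  expect_identical(sl$slice_index, 4L)
  expect_identical(sl$mask, mask[, , 4])

  tie <- array(FALSE, dims)
  tie[1:8, 1:10, 2] <- TRUE
  tie[1:8, 1:10, 5] <- TRUE
  expect_identical(pick_analysis_slice(toy_volume(dims, mask = tie))$slice_index, 2L)

  single <- array(FALSE, dims); single[3:6, 3:6, 5] <- TRUE
  expect_identical(pick_analysis_slice(toy_volume(dims, mask = single))$slice_index, 5L)

  expect_error(pick_analysis_slice(toy_volume(dims, mask = array(FALSE, dims))),
               class = "ith_empty_roi_error")
})

test_that("constant windows give the degenerate feature signature", {
  sl <- toy_slice(matrix(3.7, 7, 7))
  fmap <- suppressWarnings(extract_local_features(sl))
  center <- which(fmap$coords[, 1] == 4 & fmap$coords[, 2] == 4)
  f <- fmap$features[center, ]
  expect_equal(unname(f["fo_mean"]), 3.7)
  expect_equal(unname(f["fo_sd"]), 0)
  expect_equal(unname(f["fo_skewness"]), 0)
  expect_equal(unname(f["fo_kurtosis"]), 0)
  expect_equal(unname(f["fo_entropy"]), 0)
  expect_equal(unname(f["glcm_contrast"]), 0)
  expect_equal(unname(f["glcm_homogeneity"]), 1)
  expect_equal(unname(f["glcm_asm"]), 1)
  expect_equal(unname(f["glcm_correlation"]), 0)
})

test_that("3x3 window features match exhaustive pair enumeration", {
  # five 0s and four 1s, 2-level quantization
  win <- matrix(c(0, 1, 0,
                  1, 0, 1,
                  0, 1, 0), 3, 3, byrow = TRUE)
  sl <- toy_slice(win)
  fmap <- suppressWarnings(extract_local_features(sl, window = 3, nlevels = 2))
  center <- which(fmap$coords[, 1] == 2 & fmap$coords[, 2] == 2)
  f <- fmap$features[center, ]
  expect_equal(unname(f["fo_mean"]), 4 / 9)

  orc <- oracle_glcm(win + 1L, levels = 2)
  expect_equal(unname(f["glcm_contrast"]), orc$contrast)
  expect_equal(unname(f["glcm_homogeneity"]), orc$homogeneity)
  expect_equal(unname(f["glcm_asm"]), orc$asm)
  expect_equal(unname(f["glcm_correlation"]), orc$correlation)
})

test_that("the extractor agrees with brute force on extremal binary textures", {
  # brute force over all 2^9 binary 3x3 windows (excluding constants);
  # under 4-direction pooling the argmax-contrast pattern is striped, not
  # the checkerboard (whose diagonal pairs agree)
  best_contrast <- -Inf; worst_homog <- Inf
  best_win <- NULL; worst_win <- NULL
  for (bits in 0:511) {
    win <- matrix(as.integer(intToBits(bits))[1:9], 3, 3)
    if (length(unique(as.vector(win))) < 2) next
    orc <- oracle_glcm(win + 1L, 2)
    if (orc$contrast > best_contrast) { best_contrast <- orc$contrast; best_win <- win }
    if (orc$homogeneity < worst_homog) { worst_homog <- orc$homogeneity; worst_win <- win }
  }
  checker <- matrix(c(0, 1, 0, 1, 0, 1, 0, 1, 0), 3, 3)
  orc_c <- oracle_glcm(checker + 1L, 2)
  expect_gt(orc_c$contrast, 0.5)          # checkerboard is near-extremal...
  expect_gte(best_contrast, orc_c$contrast) # ...but stripes dominate

  for (win in list(best_win, worst_win, checker)) {
    orc <- oracle_glcm(win + 1L, 2)
    fmap <- suppressWarnings(extract_local_features(toy_slice(win),
                                                    window = 3, nlevels = 2))
    center <- which(fmap$coords[, 1] == 2 & fmap$coords[, 2] == 2)
    expect_equal(unname(fmap$features[center, "glcm_contrast"]), orc$contrast)
    expect_equal(unname(fmap$features[center, "glcm_homogeneity"]), orc$homogeneity)
    expect_equal(unname(fmap$features[center, "glcm_asm"]), orc$asm)
  }
})

test_that("feature maps cover the ROI with finite rows", {
  set.seed(5)
  for (i in 1:5) {
    mask <- matrix(runif(400) < 0.6, 20, 20)
    if (sum(mask) < 10) next
    vals <- matrix(rnorm(400), 20, 20) * mask
    sl <- toy_slice(vals, mask)
    fmap <- suppressWarnings(extract_local_features(sl))
    expect_identical(nrow(fmap$features), sum(mask))
    expect_true(all(is.finite(fmap$features)))
    expect_identical(nrow(fmap$coords), sum(mask))
  }
})

test_that("texture features are invariant to intensity shifts", {
  set.seed(8)
  vals <- matrix(rnorm(225), 15, 15)
  tex_cols <- c("fo_sd", "fo_skewness", "fo_kurtosis", "fo_entropy",
                "glcm_contrast", "glcm_homogeneity", "glcm_asm",
                "glcm_correlation")
  f1 <- suppressWarnings(extract_local_features(toy_slice(vals)))
  f2 <- suppressWarnings(extract_local_features(toy_slice(vals + 11.3)))
  expect_equal(f1$features[, tex_cols], f2$features[, tex_cols],
               tolerance = 1e-9)
})

test_that("starved windows inherit the nearest valid feature vector", {
  mask <- matrix(FALSE, 9, 9)
  mask[2:6, 2:6] <- TRUE     # a solid block...
  mask[8, 8] <- TRUE         # ...plus an isolated pixel (1-pixel window)
  vals <- matrix(rnorm(81), 9, 9)
  fmap <- suppressWarnings(extract_local_features(toy_slice(vals, mask)))
  iso <- which(fmap$coords[, 1] == 8 & fmap$coords[, 2] == 8)
  donor <- which(fmap$coords[, 1] == 6 & fmap$coords[, 2] == 6)
  expect_equal(fmap$features[iso, ], fmap$features[donor, ])
})

test_that("window validation and normalization warning behave as specified", {
  sl <- toy_slice(matrix(rnorm(49), 7, 7))
  expect_error(suppressWarnings(extract_local_features(sl, window = 2)),
               class = "ith_parameter_error")
  expect_error(suppressWarnings(extract_local_features(sl, window = 1)),
               class = "ith_parameter_error")
  expect_warning(extract_local_features(toy_slice(matrix(rnorm(49) * 10, 7, 7))),
                 "normalized")
  normalized <- matrix(rnorm(100), 10, 10)
  normalized <- (normalized - mean(normalized)) /
    sqrt(mean((normalized - mean(normalized))^2))
  expect_no_warning(extract_local_features(toy_slice(normalized)))
})
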