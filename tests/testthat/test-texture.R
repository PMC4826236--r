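test_that("quantization bins the 8-bit axis uniformly", {
  img <- image_grid(matrix(0:255, 16, 16))
  # G = 256 is the identity binning
  expect_identical(quantize_image(img, levels = 256), as_matrix(img))
  # extremes map to the extreme levels at G = 2
  two <- image_grid(matrix(c(0L, 255L), 2, 2))
  expect_setequal(unique(as.vector(quantize_image(two, levels = 2))), c(0L, 1L))
  # G = 8: every bin spans exactly 32 intensity units
  q <- quantize_image(img, levels = 8)
  expect_identical(q, matrix(as.integer(0:255 %/% 32L), 16, 16))
  # masked-out pixels carry the NA sentinel; empty masks are unusable
  mask <- matrix(FALSE, 16, 16); mask[1:4, 1:4] <- TRUE
  qm <- quantize_image(img, mask = mask, levels = 8)
  expect_true(all(is.na(qm[!mask])) && !anyNA(qm[mask]))
  expect_error(quantize_image(img, mask = matrix(FALSE, 16, 16), levels = 8),
               "empty mask")
  expect_error(quantize_image(image_grid(matrix(0L, 2, 2), bit_depth = 16L)),
               "8-bit")
})

test_that("GLCM of simple grids matches hand enumeration", {
  p <- glcm_params(levels = 8, distance = 1, angles = 0, symmetric = TRUE)
  # constant grid: all mass at (5, 5)
  g <- compute_glcm(matrix(5L, 4, 4), p)[[1]]
  expect_equal(g$p[6, 6], 1)
  expect_equal(sum(g$p), 1)
  # alternating 1 x 4 strip [0,1,0,1]: 3 ordered pairs plus reverses
  p2 <- glcm_params(levels = 2, distance = 1, angles = 0, symmetric = TRUE)
  g2 <- compute_glcm(matrix(c(0L, 1L, 0L, 1L), 1, 4), p2)[[1]]
  expect_equal(g2$p[1, 2], 0.5)
  expect_equal(g2$p[2, 1], 0.5)
  expect_equal(g2$n_pairs, 6)
  # a single pixel has no pairs at any offset
  expect_error(compute_glcm(matrix(0L, 1, 1), p2), "no valid pixel pairs")
})

test_that("GLCM equals the brute-force pair-enumeration oracle", {
  set.seed(101)
  offsets <- list("0" = c(0, 1), "45" = c(-1, 1), "90" = c(-1, 0),
                  "135" = c(-1, -1))
  for (rep in 1:10) {
    g <- matrix(sample(0:7, 100, replace = TRUE), 10, 10)
    # poke some NA holes to exercise mask-boundary pair rejection
    g[sample(100, 15)] <- NA_integer_
    for (sym in c(TRUE, FALSE)) {
      params <- glcm_params(levels = 8, distance = 1,
                            angles = c(0, 45, 90, 135), symmetric = sym)
      got <- compute_glcm(g, params)
      for (ang in names(offsets)) {
        want <- oracle_glcm(g, offsets[[ang]][1], offsets[[ang]][2], 8, sym)
        expect_equal(got[[paste0("angle_", ang)]]$p, want, tolerance = 1e-14)
      }
    }
  }
})

test_that("GLCM matrices are normalized and symmetric on request", {
  set.seed(5)
  g <- matrix(sample(0:15, 400, replace = TRUE), 20, 20)
  for (sym in c(TRUE, FALSE)) {
    ms <- compute_glcm(g, glcm_params(levels = 16, symmetric = sym))
    for (m in ms) {
      expect_equal(sum(m$p), 1, tolerance = 1e-12)
      if (sym) expect_equal(m$p, t(m$p))
    }
  }
})

test_that("Haralick features match closed forms", {
  # single-cell GLCM: perfectly uniform texture, correlation undefined
  p1 <- glcm_params(levels = 4, angles = 0)
  f1 <- haralick_features(compute_glcm(matrix(2L, 3, 3), p1))
  expect_equal(f1$asm, 1)
  expect_equal(f1$contrast, 0)
  expect_equal(f1$idm, 1)
  expect_equal(f1$entropy, 0)
  expect_false(f1$correlation_defined)
  expect_true(is.na(f1$correlation))
  # 2-level checkerboard at distance 1, 0 degrees
  cb <- matrix(as.integer((outer(1:6, 1:6, "+")) %% 2), 6, 6)
  f2 <- haralick_features(compute_glcm(cb, glcm_params(levels = 2, angles = 0)))
  expect_equal(f2$asm, 0.5)
  expect_equal(f2$contrast, 1)
  expect_equal(f2$idm, 0.5)
  expect_equal(f2$entropy, 1)
  expect_equal(f2$correlation, -1)
  # uniform GLCM over {0,1}^2
  unif <- structure(list(p = matrix(0.25, 2, 2), angle = 0, n_pairs = 4,
                         params = glcm_params(levels = 2)), class = "glcm")
  f3 <- haralick_features(unif)
  expect_equal(f3$asm, 0.25)
  expect_equal(f3$contrast, 0.5)
  expect_equal(f3$idm, 0.75)
  expect_equal(f3$entropy, 2)
  expect_equal(f3$correlation, 0)
})

test_that("features average over angles, correlation only where defined", {
  diag_g <- structure(list(p = diag(c(0.5, 0.5)), angle = 0, n_pairs = 4,
                           params = glcm_params(levels = 2)), class = "glcm")
  degen <- structure(list(p = matrix(c(1, 0, 0, 0), 2, 2), angle = 90,
                          n_pairs = 4, params = glcm_params(levels = 2)),
                     class = "glcm")
  f <- haralick_features(list(diag_g, degen))
  expect_equal(f$asm, mean(c(0.5, 1)))
  expect_equal(f$entropy, mean(c(1, 0)))
  # degenerate angle abstains from the correlation average
  expect_equal(f$correlation, 1)
  expect_true(f$correlation_defined)
})

test_that("features are invariant to a gain that preserves bin assignment", {
  base <- matrix(c(40L, 200L), 12, 12)
  shifted <- matrix(as.integer(round(c(40, 200) * 1.05)), 12, 12)
  p <- glcm_params(levels = 8)
  f1 <- haralick_features(compute_glcm(
    quantize_image(image_grid(base), levels = 8), p))
  f2 <- haralick_features(compute_glcm(
    quantize_image(image_grid(shifted), levels = 8), p))
  expect_equal(f1, f2)
})

test_that("per-nucleus profile handles constant and stamped nuclei", {
  # one constant-interior nucleus reproduces the degenerate closed form
  img <- image_grid(matrix(120L, 60, 60))
  nuc <- label_mask(disc_label(60, 60, 30, 30, 18))
  prof <- nucleus_texture_profile(img, nuc)
  expect_equal(prof$n_nuclei, 1L)
  expect_equal(prof$per_nucleus$asm, 1)
  expect_equal(prof$per_nucleus$contrast, 0)
  expect_equal(prof$per_nucleus$idm, 1)
  expect_equal(prof$per_nucleus$entropy, 0)
  expect_false(prof$per_nucleus$correlation_defined)
  expect_equal(prof$n_correlation_undefined, 1L)
  expect_true(is.na(prof$sample_means[["correlation"]]))
  # four identical stamped nuclei: zero feature spread
  set.seed(3)
  patch <- matrix(sample(80:160, 31 * 31, replace = TRUE), 31, 31)
  canvas <- matrix(0L, 80, 80)
  lab <- matrix(0L, 80, 80)
  centres <- list(c(20, 20), c(20, 60), c(60, 20), c(60, 60))
  for (k in seq_along(centres)) {
    ct <- centres[[k]]
    rows <- (ct[1] - 15):(ct[1] + 15); cols <- (ct[2] - 15):(ct[2] + 15)
    canvas[rows, cols] <- patch
    lab <- disc_label(80, 80, ct[1], ct[2], 12, lab = k, base = lab)
  }
  prof4 <- nucleus_texture_profile(image_grid(canvas), label_mask(lab))
  for (f in c("asm", "contrast", "correlation", "idm", "entropy")) {
    expect_equal(stats::sd(prof4$per_nucleus[[f]]), 0, tolerance = 1e-12)
  }
  # zero nuclei: empty table, undefined-flagged means
  prof0 <- nucleus_texture_profile(img, label_mask(matrix(0L, 60, 60)))
  expect_equal(nrow(prof0$per_nucleus), 0L)
  expect_true(all(is.na(prof0$sample_means)))
})

test_that("percent change is plain relative-difference arithmetic", {
  expect_equal(percent_change(c(asm = 0.2), c(asm = 0.2))[["asm"]], 0)
  expect_equal(percent_change(c(asm = 0.16), c(asm = 0.20))[["asm"]], -20)
  expect_equal(percent_change(c(asm = 0.14), c(asm = 0.10))[["asm"]], 40)
  # zero control mean and undefined features propagate as NA
  out <- percent_change(c(asm = 1, idm = NA, contrast = 2),
                        c(asm = 0, idm = 1, contrast = 1))
  expect_true(is.na(out[["asm"]]) && is.na(out[["idm"]]))
  expect_equal(out[["contrast"]], 100)
})

test_that("chromatin-pattern interpretation reproduces known signatures", {
  # cisplatin/radiation-like signature: less homogeneous, more
  # heterogeneous, higher contrast
  cis <- interpret_chromatin_pattern(
    c(asm = -20, correlation = -25, entropy = 6, idm = -15, contrast = 40))
  expect_equal(cis$homogeneity, "decreased")
  expect_equal(cis$heterogeneity, "increased")
  expect_equal(cis$contrast_pattern, "increased")
  # HDAC-inhibition-like signature reverses every pattern
  tsa <- interpret_chromatin_pattern(
    c(asm = 15, correlation = 20, entropy = -10, idm = 12, contrast = -30))
  expect_equal(tsa$homogeneity, "increased")
  expect_equal(tsa$heterogeneity, "decreased")
  expect_equal(tsa$contrast_pattern, "decreased")
  # all-zero changes: everything unchanged
  none <- interpret_chromatin_pattern(
    c(asm = 0, correlation = 0, entropy = 0, idm = 0, contrast = 0))
  expect_equal(none$homogeneity, "unchanged")
  expect_equal(none$heterogeneity, "unchanged")
  expect_equal(none$contrast_pattern, "unchanged")
  # conflicting votes are flagged, sub-threshold changes abstain
  conflict <- interpret_chromatin_pattern(
    c(asm = 10, entropy = 10, idm = 2, correlation = 0, contrast = 0))
  expect_equal(conflict$homogeneity, "indeterminate")
  expect_error(interpret_chromatin_pattern(c(asm = NA_real_)), "undefined")
})
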