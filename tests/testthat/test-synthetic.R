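test_that("scene generation is deterministic given (spec, seed)", {
  s1 <- generate_texture_scene(tiny_texture_spec(seed = 9, regime = "treated"))
  s2 <- generate_texture_scene(tiny_texture_spec(seed = 9, regime = "treated"))
  expect_identical(as_matrix(s1$channels$dapi), as_matrix(s2$channels$dapi))
  expect_identical(as_matrix(s1$truth_nuclei), as_matrix(s2$truth_nuclei))
  f1 <- generate_foci_scene(tiny_foci_spec(seed = 4))
  f2 <- generate_foci_scene(tiny_foci_spec(seed = 4))
  expect_identical(as_matrix(f1$channels$foci), as_matrix(f2$channels$foci))
  expect_identical(f1$truth_foci, f2$truth_foci)
  t1 <- generate_tma_scene(tma_scene_spec(seed = 4))
  t2 <- generate_tma_scene(tma_scene_spec(seed = 4))
  expect_identical(as_matrix(t1$channels$target), as_matrix(t2$channels$target))
})

test_that("generators do not disturb the caller's RNG stream", {
  set.seed(123)
  before <- runif(1)
  set.seed(123)
  invisible(generate_texture_scene(tiny_texture_spec(seed = 77)))
  expect_identical(runif(1), before)
})

test_that("the requested number of nuclei is placed, without overlap", {
  sc <- generate_texture_scene(scene_spec(n_nuclei = 12, seed = 2))
  expect_equal(n_labels(sc$truth_nuclei), 12L)
  # labels partition: areas are positive and pairwise disjoint by design
  areas <- tabulate(sc$truth_nuclei[sc$truth_nuclei > 0], nbins = 12)
  expect_true(all(areas > 0))
})

test_that("an overfull canvas raises a generation error", {
  expect_error(
    generate_texture_scene(scene_spec(height = 64, width = 64, n_nuclei = 30,
                                      seed = 1)),
    "larger canvas")
})

test_that("control regime forces zero clumpiness and conserves the mean", {
  spec <- scene_spec(texture_regime = "control", clumpiness = 0.7, seed = 5)
  expect_equal(spec$clumpiness, 0)
  # treated and control nuclei share the same mean intensity: the regimes
  # differ in pattern, not brightness
  ctrl <- generate_texture_scene(scene_spec(seed = 31))
  trt <- generate_texture_scene(scene_spec(seed = 31, texture_regime = "treated"))
  m_ctrl <- mean(ctrl$channels$dapi[ctrl$truth_nuclei > 0])
  m_trt <- mean(trt$channels$dapi[trt$truth_nuclei > 0])
  expect_lt(abs(m_trt - m_ctrl) / m_ctrl, 0.03)
  expect_error(scene_spec(texture_regime = "treated", clumpiness = 0.8,
                          clump_gain = 1.5),
               "conserve")
})

test_that("planted foci respect counts, containment and separation", {
  spec <- foci_scene_spec(n_nuclei = 10, foci_per_nucleus = 7, seed = 8,
                          height = 500, width = 500)
  sc <- generate_foci_scene(spec)
  expect_equal(nrow(sc$truth_foci), 70L)
  # every focus lies inside its own nucleus mask (truth is 0-based)
  idx <- cbind(sc$truth_foci$row + 1, sc$truth_foci$col + 1)
  expect_equal(sc$truth_nuclei[idx], sc$truth_foci$nucleus)
  # pairwise separation >= 4 sigma within each nucleus
  sep <- 4 * spec$focus_sigma
  for (k in unique(sc$truth_foci$nucleus)) {
    pts <- sc$truth_foci[sc$truth_foci$nucleus == k, c("row", "col")]
    if (nrow(pts) > 1) expect_gte(min(stats::dist(pts)), sep)
  }
})

test_that("zero foci per nucleus gives a pure background channel", {
  sc <- generate_foci_scene(tiny_foci_spec(foci_per_nucleus = 0, noise_sd = 0))
  expect_equal(nrow(sc$truth_foci), 0L)
  expect_equal(length(unique(as.vector(sc$channels$foci))), 1L)
})

test_that("an unsatisfiable separation constraint errors", {
  expect_error(
    generate_foci_scene(scene_spec(height = 200, width = 200, n_nuclei = 2,
                                   nucleus_radius_range = c(8, 9),
                                   foci_per_nucleus = 40, seed = 1)),
    "cannot place")
})

test_that("TMA scenes realize the requested epithelium fraction", {
  sc <- generate_tma_scene(tma_scene_spec(epithelium_fraction = 0.5, seed = 6))
  frac <- mean((sc$truth_compartments > 0)[sc$truth_core])
  expect_lt(abs(frac - 0.5), 0.05)
  # compartment truth: nuclear and cytoplasmic partition the epithelium
  expect_setequal(unique(as.vector(sc$truth_compartments)), c(0L, 1L, 2L))
  # epithelium_fraction 0: no cytokeratin signal at all
  sc0 <- generate_tma_scene(tma_scene_spec(epithelium_fraction = 0,
                                           noise_sd = 0, seed = 6))
  expect_true(all(sc0$channels$cytokeratin == 0))
  expect_error(tma_scene_spec(epithelium_fraction = 0.99), "0.95")
})

test_that("scenes round trip through TIFF plus JSON sidecar", {
  sc <- generate_foci_scene(tiny_foci_spec(seed = 2))
  path <- withr::local_tempfile(fileext = ".tif")
  paths <- write_scene(sc, path)
  expect_true(file.exists(paths[["json"]]))
  back <- read_image(paths[["tiff"]], channel_index = 2)
  expect_identical(as_matrix(back), as_matrix(sc$channels$foci))
  sidecar <- jsonlite::read_json(paths[["json"]])
  expect_equal(length(sidecar$nuclei), n_labels(sc$truth_nuclei))
  expect_equal(length(sidecar$foci), nrow(sc$truth_foci))
})
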