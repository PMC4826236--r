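test_that("Mann-Whitney worked examples give the expected exact p", {
  # complete separation of 3 vs 3: 1 assignment per tail out of C(6,3)=20
  sep <- mann_whitney_u(c(1, 2, 3), c(10, 20, 30))
  expect_equal(sep$statistic, 0)
  expect_equal(sep$p_value, 0.1)
  expect_equal(sep$method, "mann_whitney_exact")
  # identical multisets carry ties, so the corrected normal path is used
  same <- mann_whitney_u(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p_value, 1)
  # single observations per group: only two assignments, p = 1
  one <- mann_whitney_u(5, 9)
  expect_equal(one$p_value, 1)
  expect_equal(one$method, "mann_whitney_exact")
  expect_error(mann_whitney_u(numeric(), 1), "non-empty")
})

test_that("exact Mann-Whitney p matches the enumeration oracle", {
  set.seed(77)
  for (rep in 1:40) {
    na <- sample(1:6, 1); nb <- sample(1:6, 1)
    repeat {
      x <- round(stats::rnorm(na + nb), 6)
      if (!anyDuplicated(x)) break
    }
    a <- x[seq_len(na)]; b <- x[-seq_len(na)]
    got <- mann_whitney_u(a, b)
    expect_equal(got$method, "mann_whitney_exact")
    expect_equal(got$p_value, oracle_mwu_p(a, b), tolerance = 1e-14)
  }
})

test_that("the U test is invariant under strictly monotone transforms", {
  set.seed(8)
  a <- stats::rnorm(6); b <- stats::rnorm(7, mean = 1)
  p0 <- mann_whitney_u(a, b)$p_value
  expect_equal(mann_whitney_u(exp(a), exp(b))$p_value, p0)
  expect_equal(mann_whitney_u(a^3, b^3)$p_value, p0)
})

test_that("the normal approximation converges to the exact p", {
  set.seed(15)
  deltas <- replicate(40, {
    a <- stats::rnorm(10); b <- stats::rnorm(10, mean = 0.5)
    abs(mann_whitney_u(a, b, exact = TRUE)$p_value -
          mann_whitney_u(a, b, exact = FALSE)$p_value)
  })
  expect_lt(max(deltas), 0.01)
})

test_that("pooled t-test matches the reference implementation", {
  tt <- t_test_groups(c(1, 2, 3), c(4, 5, 6))
  expect_equal(tt$statistic, -3.674235, tolerance = 1e-6)
  expect_equal(tt$p_value, 0.02131164, tolerance = 1e-6)
  set.seed(21)
  for (rep in 1:10) {
    a <- stats::rnorm(sample(3:9, 1)); b <- stats::rnorm(sample(3:9, 1), 0.5)
    want <- stats::t.test(a, b, var.equal = TRUE)
    got <- t_test_groups(a, b)
    expect_equal(got$statistic, unname(want$statistic), tolerance = 1e-12)
    expect_equal(got$p_value, want$p.value, tolerance = 1e-12)
  }
  # swapping groups negates t and keeps p
  fwd <- t_test_groups(c(1, 4, 2), c(5, 7, 6))
  rev <- t_test_groups(c(5, 7, 6), c(1, 4, 2))
  expect_equal(fwd$statistic, -rev$statistic)
  expect_equal(fwd$p_value, rev$p_value)
  # degenerate zero-variance conventions are flagged
  eq <- t_test_groups(c(2, 2), c(2, 2))
  expect_equal(eq$p_value, 1)
  ne <- t_test_groups(c(2, 2), c(3, 3))
  expect_equal(ne$p_value, 0)
  expect_equal(ne$method, "t_test_degenerate")
})

test_that("group comparison runs once per shared texture feature", {
  df <- data.frame(asm = c(0.5, 0.6, 0.55), contrast = c(1, 2, 1.5),
                   correlation = c(0.7, 0.8, 0.75), idm = c(0.6, 0.7, 0.65),
                   entropy = c(3, 4, 3.5), correlation_defined = TRUE)
  same <- compare_texture_groups(df, df)
  expect_equal(nrow(same), 5L)
  expect_true(all(same$p_value == 1))
  # strongly separated generator arms yield a significant contrast test
  arm <- function(cl, seeds) {
    do.call(rbind, lapply(seeds, function(s) {
      spec <- scene_spec(seed = s, n_nuclei = 6, height = 192, width = 192,
                         texture_regime = if (cl > 0) "treated" else "control",
                         clumpiness = cl)
      sc <- generate_texture_scene(spec)
      prof <- nucleus_texture_profile(sc$channels$dapi, sc$truth_nuclei)
      as.data.frame(as.list(prof$sample_means))
    }))
  }
  cmp <- compare_texture_groups(arm(0, 1:5), arm(0.8, 1:5))
  expect_lt(cmp$p_value[cmp$parameter == "contrast"], 0.05)
  # undefined correlations are dropped pairwise with counts reported
  df2 <- df; df2$correlation_defined <- c(TRUE, FALSE, TRUE)
  out <- compare_texture_groups(df2, df)
  expect_equal(out$n_control[out$parameter == "correlation"], 2L)
  expect_error(compare_texture_groups(df["asm"], df["contrast"]),
               "no shared")
})
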