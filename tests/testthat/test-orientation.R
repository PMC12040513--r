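test_that("axial angle follows the dot-product formula on [0, 90]", {
  expect_equal(angle_between_axes(c(1, 0, 0), c(0, 1, 0)), 90)
  expect_lt(angle_between_axes(c(0.3, -0.2, 0.9), -c(0.3, -0.2, 0.9)), 1e-4)
  expect_equal(angle_between_axes(c(1, 1, 0) / sqrt(2), c(1, 0, 0)), 45)
  expect_error(angle_between_axes(c(0, 0, 0), c(1, 0, 0)),
               class = "ldr_error_zero_vector")
})

test_that("strict <45 rule: coincident, tied and shared alignments", {
  z <- c(0, 0, 1); x <- c(1, 0, 0); y <- c(0, 1, 0)
  # major axis on the vein, gradient/tract orthogonal: exclusive V
  cl <- classify_lesion(z, g = x, w = y, v = z, v90 = x)
  expect_equal(cl$category, "V")
  expect_true(cl$exclusive)
  expect_false(cl$excluded)

  # an angle exactly at the threshold does not align (strict inequality)
  w45 <- c(1, 1, 0) / sqrt(2)
  a <- angle_between_axes(x, w45)
  cl45 <- classify_lesion(x, w = w45, v = z, v90 = x, threshold = a)
  expect_false("W" %in% cl45$aligned)

  # 40/40 geometry: aligned with both tract and vein, not exclusive
  rot <- function(axis, th) { # rotate x towards `axis` by th degrees
    c(cos(th * pi / 180), sin(th * pi / 180) * axis)[c(1, 2, 3)]
  }
  v40 <- c(cos(40 * pi / 180), sin(40 * pi / 180), 0)
  w40 <- c(cos(40 * pi / 180), 0, sin(40 * pi / 180))
  clwv <- classify_lesion(x, w = w40, v = v40)
  expect_equal(clwv$category, "WV")
  expect_false(clwv$exclusive)

  # undefined vein: excluded from classification, not forced into a category
  clx <- classify_lesion(x, g = x, w = y, v = NULL)
  expect_true(clx$excluded)
  expect_true(is.na(clx$category))

  expect_error(classify_lesion(c(NA, NA, NA), v = z),
               class = "ldr_error_undefined_axis")
  expect_error(classify_lesion(x, v = z, threshold = 90),
               class = "ldr_error_threshold")
})

test_that("V and V90 are mutually exclusive under both constructions", {
  z <- c(0, 0, 1)
  withr::with_seed(31, {
    for (i in 1:50) {
      e1 <- sample_axes_for_test(1)
      v90 <- orthogonal_vein_axis(z, e1)$axis
      for (mode in c("projection", "plane")) {
        cl <- classify_lesion(e1, v = z, v90 = v90, v90_mode = mode)
        expect_false(all(c("V", "V90") %in% cl$aligned))
      }
    }
  })
})

test_that("chance of aligning with one fixed axis is the cap fraction", {
  expect_equal(chance_single(45), 1 - cos(pi / 4))
  expect_equal(chance_single(90), 1)
  expect_equal(chance_single(60), 0.5)
  expect_error(chance_single(0), class = "ldr_error_threshold")
  expect_error(chance_single(95), class = "ldr_error_threshold")
})

test_that("Monte-Carlo joint chance model matches analytic building blocks", {
  n <- 1e5
  se <- sqrt(0.293 * 0.707 / n)
  # single defined axis: exclusive probability = the analytic cap fraction
  cj <- chance_joint(v = c(0, 0, 1), n_samples = n, seed = 101)
  pv <- cj$probability[cj$category == "V"]
  expect_lt(abs(pv - chance_single(45)), 3 * se)
  expect_equal(sum(cj$probability), 1)

  # coincident tract and vein axes: everything lands in WV, nothing in V
  cj2 <- chance_joint(w = c(0, 0, 1), v = c(0, 0, 1), n_samples = n, seed = 102)
  expect_equal(cj2$probability[cj2$category == "V"], 0)
  expect_lt(abs(cj2$probability[cj2$category == "WV"] - chance_single(45)),
            3 * se)

  # three mutually orthogonal axes: a partition, probabilities sum to 1
  cj3 <- chance_joint(g = c(1, 0, 0), w = c(0, 1, 0), v = c(0, 0, 1),
                      n_samples = n, seed = 103)
  expect_equal(sum(cj3$probability), 1)

  # orthogonal independent axes factorize: P(W only) + P(V only) = 2 * cap
  # (overlap of two orthogonal 45-degree cones is a null set)
  cj4 <- chance_joint(w = c(1, 0, 0), v = c(0, 0, 1), n_samples = n, seed = 104)
  pWonly <- cj4$probability[cj4$category == "W"]
  pVonly <- cj4$probability[cj4$category == "V"]
  expect_lt(abs(pWonly + pVonly - 2 * chance_single(45)), 3 * sqrt(2) * se)

  # reproducible under a fixed seed
  expect_identical(chance_joint(v = c(0, 0, 1), n_samples = 1000, seed = 7),
                   chance_joint(v = c(0, 0, 1), n_samples = 1000, seed = 7))
  expect_error(chance_joint(), class = "ldr_error_undefined_axis")
})

test_that("classification is invariant to sign flips of every axis", {
  withr::with_seed(17, {
    for (i in 1:20) {
      e1 <- sample_axes_for_test(1)
      g <- sample_axes_for_test(1); w <- sample_axes_for_test(1)
      v <- sample_axes_for_test(1)
      v90 <- orthogonal_vein_axis(v, e1)$axis
      ref <- classify_lesion(e1, g = g, w = w, v = v, v90 = v90)
      s <- sample(c(-1, 1), 5, replace = TRUE)
      flipped <- classify_lesion(s[1] * e1, g = s[2] * g, w = s[3] * w,
                                 v = s[4] * v, v90 = s[5] * v90)
      expect_identical(ref$category, flipped$category)
      expect_equal(ref$angles, flipped$angles)
    }
  })
})

test_that("tightening 45 to 30 degrees only shrinks alignment", {
  withr::with_seed(23, {
    n_none_45 <- 0; n_none_30 <- 0
    for (i in 1:100) {
      e1 <- sample_axes_for_test(1)
      g <- sample_axes_for_test(1); w <- sample_axes_for_test(1)
      v <- sample_axes_for_test(1)
      v90 <- orthogonal_vein_axis(v, e1)$axis
      c45 <- classify_lesion(e1, g = g, w = w, v = v, v90 = v90, threshold = 45)
      c30 <- classify_lesion(e1, g = g, w = w, v = v, v90 = v90, threshold = 30)
      expect_true(all(c30$aligned %in% c45$aligned))
      n_none_45 <- n_none_45 + (c45$category == "NONE")
      n_none_30 <- n_none_30 + (c30$category == "NONE")
    }
    # no-dominant-orientation lesions become more, never fewer
    expect_gte(n_none_30, n_none_45)
    expect_gt(n_none_30, 0)
  })
})
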