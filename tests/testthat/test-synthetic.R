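test_that("a fixed seed builds a bit-identical phantom", {
  sp <- phantom_spec(n_lesions = 2, categories = c("V", "WV"),
                     dynamics = c("expanding", "stable"),
                     grid = c(64L, 64L, 64L), seed = 5)
  a <- build_phantom(sp)
  b <- build_phantom(sp)
  expect_identical(a$labels$data, b$labels$data)
  expect_identical(a$veins$data, b$veins$data)
  expect_identical(a$displacement$data, b$displacement$data)
  expect_identical(a$mt_on_followup$data, b$mt_on_followup$data)
  expect_identical(a$truth, b$truth)
})

test_that("unrealizable intended categories are rejected at build time", {
  expect_error(phantom_spec(categories = "VV90"),
               class = "ldr_error_unrealizable_category")
  expect_error(phantom_spec(categories = c("V", "NONE")),
               class = "ldr_error_unrealizable_category")
  expect_error(phantom_spec(categories = "G"),
               class = "ldr_error_unrealizable_category")
  expect_error(phantom_spec(categories = "V", dynamics = "wobbling"),
               class = "ldr_error_bad_spec")
})

test_that("generated MT pairs satisfy the MTR identity exactly before noise", {
  sp <- phantom_spec(n_lesions = 2, categories = c("V", "GV"),
                     delta_mtr = c(0.4, -0.2), grid = c(64L, 64L, 64L),
                     seed = 9)
  ph <- build_phantom(sp)
  mtr_b <- compute_mtr(ph$mt_off_baseline, ph$mt_on_baseline)
  mtr_f <- compute_mtr(ph$mt_off_followup, ph$mt_on_followup)
  # normal-appearing tissue at the generator's WM value
  expect_lt(abs(mtr_b$data[2, 2, 2] - sp$mtr_wm_pu), 1e-9)
  # lesion voxels at the lesion value, shifted by the injected change
  for (i in 1:2) {
    vox <- which(ph$labels$data == i, arr.ind = TRUE) - 1L
    ch <- lesion_mtr_change(mtr_b, mtr_f, vox)
    expect_lt(abs(ch$mean_baseline - sp$mtr_lesion_pu), 1e-9)
    expect_lt(abs(ch$delta_mtr - sp$delta_mtr[i]), 1e-9)
  }
})

test_that("injected stretch yields the exact volume ratio on lesion voxels", {
  sp <- phantom_spec(n_lesions = 2, categories = c("V", "V"),
                     dynamics = c("expanding", "stable"),
                     volume_ratio = c(1.08, 1), grid = c(64L, 64L, 64L),
                     seed = 3)
  ph <- build_phantom(sp)
  jac <- jacobian_determinant(ph$displacement)
  vox1 <- which(ph$labels$data == 1, arr.ind = TRUE)
  expect_lt(max(abs(jac$data[vox1] - 1.08)), 1e-6)
  vox2 <- which(ph$labels$data == 2, arr.ind = TRUE)
  expect_lt(max(abs(jac$data[vox2] - 1)), 1e-12)
  expect_equal(ph$truth$volume_ratio, c(1.08, 1))
})

test_that("a lesion laid along its vein is recovered as V end to end", {
  sp <- phantom_spec(n_lesions = 3, categories = c("V", "GWV", "EXCLUDED"),
                     grid = c(72L, 72L, 72L), seed = 11)
  ph <- build_phantom(sp)
  res <- analyze_phantom(ph)
  expect_equal(as.character(res$category[res$lesion_id == 1]), "V")
  expect_equal(as.character(res$category[res$lesion_id == 2]), "GWV")
  expect_true(res$excluded[res$lesion_id == 3])
  # per-lesion axis recovery at phantom resolution
  for (i in 1:3) {
    est <- unlist(res[res$lesion_id == i, c("e1_x", "e1_y", "e1_z")])
    tru <- unlist(ph$truth[i, c("e1_x", "e1_y", "e1_z")])
    expect_lt(axial_deg(est, tru), 5)
  }
})

test_that("cohort sampler respects mixtures, arms and reproducibility", {
  specs <- sample_cohort(n_patients = 4, n_lesions = 6,
                         mixture = c(V = 1), p_excluded = 0, seed = 2)
  expect_length(specs, 4)
  expect_true(all(vapply(specs, function(s) all(s$categories == "V"),
                         logical(1))))
  expect_equal(vapply(specs, `[[`, "", "arm"),
               c("placebo", "active", "placebo", "active"))
  specs2 <- sample_cohort(n_patients = 4, n_lesions = 6,
                          mixture = c(V = 1), p_excluded = 0, seed = 2)
  expect_identical(lapply(specs, unclass), lapply(specs2, unclass))

  expect_identical(sample_cohort(n_patients = 0), list())
  expect_error(sample_cohort(mixture = c(V = 0.5, WV = 0.2)),
               class = "ldr_error_degenerate_mixture")
  expect_error(sample_cohort(mixture = c(G = 1)),
               class = "ldr_error_unrealizable_category")

  # intended category frequencies track the mixture within sampling error
  mix <- c(V = 0.5, WV = 0.5)
  specs3 <- sample_cohort(n_patients = 30, n_lesions = 20, mixture = mix,
                          p_excluded = 0, seed = 13)
  cats <- unlist(lapply(specs3, `[[`, "categories"))
  phat <- mean(cats == "V")
  expect_lt(abs(phat - 0.5), 3 * sqrt(0.25 / length(cats)))
})

test_that("arm effects are injected only into the matching arm and category", {
  specs <- sample_cohort(n_patients = 2, n_lesions = 40,
                         mixture = c(V = 0.5, GV = 0.5), p_excluded = 0,
                         delta_mtr_sd = 0, seed = 19,
                         arm_effect = list(arm = "active", category = "GV",
                                           delta = 0.6))
  placebo <- specs[[1]]; active <- specs[[2]]
  expect_true(all(placebo$delta_mtr == 0))
  expect_true(all(active$delta_mtr[active$categories == "GV"] == 0.6))
  expect_true(all(active$delta_mtr[active$categories == "V"] == 0))
})
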