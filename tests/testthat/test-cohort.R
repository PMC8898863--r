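test_that("generation is deterministic under a seed and varies across seeds", {
  s <- cohort_spec(seed = 11)
  a <- generate_cohort(s)
  b <- generate_cohort(s)
  expect_identical(as.data.frame(a), as.data.frame(b))
  c_ <- generate_cohort(cohort_spec(seed = 12))
  expect_false(identical(a$preop_eq5d, c_$preop_eq5d))
  expect_equal(as.integer(table(a$group)), c(512L, 48L))
})

test_that("noise-free, coefficient-free limit gives postop = preop + intercept", {
  s <- cohort_spec(
    eq5d_mean = c(0.2, 0.25), eq5d_sd = c(0.05, 0.05),
    group_effect = 0, coef = c(female = 0, age = 0, ohs = 0, fjs = 0,
                               preop_eq5d = 0, eqvas = 0),
    mtha_mean_change = 0.3, residual_sd = 0, seed = 3
  )
  expect_equal(solve_change_intercept(s), 0.3)
  coh <- generate_cohort(s)
  expect_equal(coh$eq5d_change, rep(0.3, nrow(coh)), tolerance = 1e-12)
  expect_equal(coh$postop_eq5d, coh$preop_eq5d + 0.3, tolerance = 1e-12)
})

test_that("all generated values respect instrument ranges and the change identity", {
  coh <- generate_cohort(cohort_spec(seed = 5))
  expect_true(all(coh$preop_ohs >= 0 & coh$preop_ohs <= 48))
  expect_true(all(coh$preop_fjs >= 0 & coh$preop_fjs <= 100))
  expect_true(all(coh$preop_eqvas >= 0 & coh$preop_eqvas <= 100))
  expect_true(all(coh$preop_eq5d >= -0.56 & coh$preop_eq5d <= 1))
  expect_true(all(coh$postop_eq5d >= -0.56 & coh$postop_eq5d <= 1))
  expect_equal(coh$eq5d_change, coh$postop_eq5d - coh$preop_eq5d)
})

test_that("group means sit within 3 SE of the published targets at study size", {
  coh <- generate_cohort(cohort_spec(seed = 8))
  m <- coh[coh$group == "mTHA", ]
  r <- coh[coh$group == "rTHA", ]
  # 3-SE bands, SE = SD/sqrt(n), of the published cohort table
  expect_lt(abs(mean(m$preop_eq5d) - 0.384), 3 * 0.320 / sqrt(512))
  expect_lt(abs(mean(r$preop_eq5d) - 0.630), 3 * 0.196 / sqrt(48))
  expect_lt(abs(mean(m$age) - 67.5), 3 * 12.1 / sqrt(512))
  expect_lt(abs(mean(r$preop_eqvas) - 77.5), 3 * 13.9 / sqrt(48))
})

test_that("empirical means converge to the closed-form truncated means (LLN)", {
  s <- cohort_spec(n = c(mTHA = 10000L, rTHA = 10000L), seed = 101)
  coh <- generate_cohort(s)
  truth <- cohort_true_means(s)
  cols <- c(age = "age", ohs = "preop_ohs", fjs = "preop_fjs",
            eq5d = "preop_eq5d", eqvas = "preop_eqvas")
  # 4-SE bands: 20 simultaneous checks, so 3 SE would false-fail ~5% of seeds
  for (g in c("mTHA", "rTHA")) {
    gg <- coh[coh$group == g, ]
    for (v in names(cols)) {
      sd_v <- sd(gg[[cols[[v]]]])
      expect_lt(abs(mean(gg[[cols[[v]]]]) - truth[g, v]),
                4 * sd_v / sqrt(nrow(gg)))
    }
  }
  # truncation bias is real and measured: FJS floor pulls the mean up
  expect_gt(truth["mTHA", "fjs"], 12.3)
})

test_that("construction yields the ceiling effect: preop EQ-5D anticorrelated with change", {
  coh <- generate_cohort(cohort_spec(seed = 19))
  expect_lt(cor(coh$preop_eq5d, coh$eq5d_change), -0.4)
})

test_that("infeasible specifications are rejected", {
  expect_error(cohort_spec(eq5d_mean = c(1.5, 0.6)),
               class = "hipcea_validation_error")
  expect_error(cohort_spec(n = c(1L, 48L)), class = "hipcea_validation_error")
  expect_error(cohort_spec(residual_sd = -1), class = "hipcea_validation_error")
  expect_error(cohort_spec(coef = c(bad = 1)), class = "hipcea_validation_error")
})

test_that("cohort_summary reproduces the published utility block on exact fixtures", {
  # two records per group whose means are exactly the printed pre/post means
  pre_m <- c(0.384 - 0.1, 0.384 + 0.1); post_m <- c(0.754 - 0.05, 0.754 + 0.05)
  pre_r <- c(0.630 - 0.1, 0.630 + 0.1); post_r <- c(0.905 - 0.05, 0.905 + 0.05)
  coh <- make_cohort(
    group = c("mTHA", "mTHA", "rTHA", "rTHA"),
    sex = c("male", "female", "male", "female"),
    age = c(65, 70, 55, 60), ohs = c(20, 22, 18, 21), fjs = c(10, 14, 11, 13),
    preop_eq5d = c(pre_m, pre_r), eqvas = c(60, 70, 75, 80),
    postop_eq5d = c(post_m, post_r)
  )
  cs <- cohort_summary(coh)
  eq <- cs$eq5d
  expect_equal(eq$change_mean[eq$group == "mTHA"], 0.370)
  expect_equal(eq$change_mean[eq$group == "rTHA"], 0.275)
  expect_equal(eq$preop_mean, c(0.384, 0.630))
  expect_equal(eq$postop_mean, c(0.754, 0.905))
})

test_that("identical records within a group give SD 0 without crashing", {
  coh <- make_cohort(
    group = rep(c("mTHA", "rTHA"), each = 3),
    sex = rep("male", 6), age = rep(c(65, 60), each = 3),
    ohs = rep(c(20, 19), each = 3), fjs = rep(c(12, 12), each = 3),
    preop_eq5d = rep(c(0.4, 0.6), each = 3), eqvas = rep(c(68, 77), each = 3),
    postop_eq5d = rep(c(0.75, 0.9), each = 3)
  )
  cs <- cohort_summary(coh)
  expect_equal(cs$eq5d$preop_sd, c(0, 0))
  expect_equal(cs$demographics$mtha_sd, rep(0, 5))
  expect_true(is.na(cs$eq5d$change_p[1]))    # degenerate paired t flagged NA
  expect_true(cs$sex$undefined)              # zero female cell
})

test_that("cohorts round-trip through delimited text", {
  coh <- generate_cohort(cohort_spec(n = c(mTHA = 20L, rTHA = 10L), seed = 4))
  path <- tempfile(fileext = ".tsv")
  on.exit(unlink(path))
  write_cohort(coh, path)
  back <- read_cohort(path)
  expect_equal(as.data.frame(back)[, -2:-3], as.data.frame(coh)[, -2:-3],
               tolerance = 1e-12)
  expect_identical(as.character(back$group), as.character(coh$group))
  expect_identical(as.character(back$sex), as.character(coh$sex))
  expect_error(read_cohort("no/such/cohort.tsv"), class = "hipcea_parse_error")
})
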