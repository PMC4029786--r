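test_that("the piecewise length-to-area model evaluates both branches", {
  # linear branch below the cutoff
  expect_equal(leafAreaFromTip(100, 0.05), 32.9 * 100 - 769.9)
  # a cr exactly at the cutoff takes the exponential branch
  expect_equal(leafAreaFromTip(100, 0.07), 513.8 * exp(0.0146 * 100))
  expect_equal(leafAreaFromTip(100, 0.07), 2212.4, tolerance = 1e-4)
  # short leaves below the linear root are clamped to zero with a warning
  expect_warning(a <- leafAreaFromTip(20, 0.05), "clamped")
  expect_equal(a, 0)
  expect_error(leafAreaFromTip(-5, 0.05), "positive")
})

test_that("the mixture cutoff lands at the equal-posterior point", {
  set.seed(11)
  v <- c(rnorm(500, 0.03, 0.01), rnorm(500, 0.15, 0.03))
  cut <- fitCutoff(v)
  # analytic equal-posterior point for equal weights is about 0.063
  expect_gt(cut, 0.05)
  expect_lt(cut, 0.09)
})

test_that("degenerate cr distributions fall back to the default cutoff", {
  expect_warning(cut <- fitCutoff(rep(0.05, 30)), "degenerate")
  expect_equal(cut, 0.07)
  expect_error(fitCutoff(c(0.01, 0.2)), "at least 20")
})

test_that("noiseless self-calibration reproduces the shipped coefficients", {
  r <- seq(30, 200, length.out = 40)
  train <- rbind(data.frame(r = r, cr = 0.03, area = 32.9 * r - 769.9),
                 data.frame(r = r, cr = 0.20, area = 513.8 * exp(0.0146 * r)))
  mdl <- suppressWarnings(fitLengthAreaModel(train, cutoff = 0.07))
  expect_equal(mdl@linear_slope, 32.9, tolerance = 1e-4)
  expect_equal(mdl@linear_intercept, -769.9, tolerance = 1e-4)
  expect_equal(mdl@exp_scale, 513.8, tolerance = 1e-4)
  expect_equal(mdl@exp_rate, 0.0146, tolerance = 1e-4)
  expect_equal(mdl@r2_linear, 1)
  expect_equal(mdl@r2_exp, 1, tolerance = 1e-8)
})

test_that("noisy calibration recovers the slope within its own interval", {
  set.seed(21)
  n <- 80
  r <- runif(n, 40, 150)
  truth <- 32.9 * r - 769.9
  train <- rbind(
    data.frame(r = r, cr = 0.03, area = truth * (1 + rnorm(n, 0, 0.05))),
    data.frame(r = seq(60, 200, length.out = 20), cr = 0.2,
               area = 513.8 * exp(0.0146 * seq(60, 200, length.out = 20))))
  mdl <- suppressWarnings(fitLengthAreaModel(train))
  expect_gte(32.9, mdl@ci["linear_slope", "lower"])
  expect_lte(32.9, mdl@ci["linear_slope", "upper"])
})

test_that("single-branch training data is an error for the other branch", {
  r <- seq(30, 100, length.out = 20)
  lin_only <- data.frame(r = r, cr = 0.03, area = 32.9 * r - 769.9)
  expect_error(fitLengthAreaModel(lin_only), "exponential")
  exp_only <- data.frame(r = r, cr = 0.2, area = 513.8 * exp(0.0146 * r))
  expect_error(fitLengthAreaModel(exp_only), "linear")
})

test_that("the overlap-corrected plant area follows the printed identities", {
  # no overlap: the corrected area is exactly the leaf-area sum
  rec0 <- plantArea(c(400, 600), a_t = 1000)
  expect_equal(rec0@p_overlap, 0)
  expect_equal(rec0@a, 1000)

  # a_l > a_t: a = 2 a_l - a_t
  rec1 <- plantArea(c(400, 600), a_t = 800)
  expect_equal(rec1@p_overlap, 0.2)
  expect_equal(rec1@a, 1200)
  expect_equal(rec1@a, 2 * 1000 - 800)

  # a_l < a_t: a = 2 a_l - a_l^2 / a_t
  rec2 <- plantArea(c(800), a_t = 1000)
  expect_equal(rec2@p_overlap, 0.2)
  expect_equal(rec2@a, 960)
  expect_equal(rec2@a, 2 * 800 - 800^2 / 1000)

  expect_error(plantArea(numeric(0), 100), "tips")
  expect_error(plantArea(c(100), 0), "positive")
})

test_that("the overlap identities hold over random (a_l, a_t) pairs", {
  set.seed(5)
  a_l <- runif(2000, 1, 1e5)
  a_t <- runif(2000, 1, 1e5)
  for (i in seq_len(2000)) {
    rec <- plantArea(a_l[i], a_t[i])
    want <- if (a_l[i] > a_t[i]) 2 * a_l[i] - a_t[i]
            else 2 * a_l[i] - a_l[i]^2 / a_t[i]
    expect_equal(rec@a, want, tolerance = 1e-12)
  }
})

test_that("the corrected area is continuous across a_l = a_t", {
  eps <- 1e-8
  below <- plantArea(1000 - eps, 1000)@a
  at <- plantArea(1000, 1000)@a
  above <- plantArea(1000 + eps, 1000)@a
  expect_equal(below, at, tolerance = 1e-6)
  expect_equal(above, at, tolerance = 1e-6)
})

test_that("overlap correction beats the naive top-view area when overlap is high", {
  # full tip -> model -> correction chain on rosettes whose leaves obey the
  # length-to-area law; the truth is the summed complete leaf area (what a
  # manual measurement with completed edges reports). Wherever the true
  # overlap fraction is at least 0.15, the corrected estimate must have a
  # smaller relative error than the raw top-view pixel count.
  configs <- list(c(11, 2000), c(12, 2000), c(12, 2400), c(10, 1600),
                  c(9, 1400))
  qualifying <- 0
  for (cfg in configs) {
    n <- cfg[1]; target <- cfg[2]
    sp0 <- starRosette(n, 40, 16, image_size = c(400, 400),
                       petiole_fraction = 0.1, seed = n)
    fr <- growSeries(sp0, c(gamma = 0.04, A0 = target, Aa = 2 * target),
                     times = 0)[[1]]
    tr <- fr$truth
    if (tr@overlap_fraction < 0.15) next
    qualifying <- qualifying + 1
    tot <- sum(tr@per_leaf_areas)
    fm <- buildForegroundMask(fr$image)
    ctr <- findPlantCenter(fr$image, fm)
    pr <- polarProfile(fm, ctr)
    tips <- detectTips(pr, smoothProfile(pr, 9))
    la <- suppressWarnings(leafAreaFromTip(tips$r, tips$cr))
    rec <- plantArea(la, observedArea(fm))
    expect_lt(abs(rec@a - tot) / tot, abs(rec@a_t - tot) / tot)
  }
  expect_gte(qualifying, 3)
})
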