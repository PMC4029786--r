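test_that("the logistic curve hits its anchors", {
  expect_equal(logistic3(0, A0 = 150, Aa = 25000, gamma = 0.04), 150)
  expect_equal(logistic3(1e6, A0 = 150, Aa = 25000, gamma = 0.04), 25000)
  # at the inflection time the curve is at half the asymptote
  g <- 0.03823; A0 <- 210.1; Aa <- 53640
  tstar <- log((Aa - A0) / A0) / g
  expect_equal(logistic3(tstar, A0, Aa, g), Aa / 2, tolerance = 1e-12)
  expect_error(logistic3(0, A0 = -5, Aa = 10, gamma = 0.1), "parameters")
})

test_that("the logistic satisfies its own ODE dA/dt = gamma A (1 - A/Aa)", {
  g <- 0.05; A0 <- 100; Aa <- 20000
  fit <- as3plFit(g, A0, Aa)
  tt <- seq(-50, 300, by = 0.5)
  der <- curveDerivatives(fit, tt)
  expect_equal(der$velocity, g * der$area * (1 - der$area / Aa),
               tolerance = 1e-12)
  # velocity is nonnegative with maximum gamma*Aa/4 at A = Aa/2
  expect_true(all(der$velocity >= 0))
  expect_lte(max(der$velocity), g * Aa / 4 + 1e-9)
})

test_that("closed-form derivatives match central finite differences", {
  fit <- as3plFit(0.03823, 210.1, 53640)
  tt <- seq(20, 260, by = 1)
  der <- curveDerivatives(fit, tt)
  h <- 1e-3
  vfd <- (logistic3(tt + h, 210.1, 53640, 0.03823) -
            logistic3(tt - h, 210.1, 53640, 0.03823)) / (2 * h)
  afd <- (logistic3(tt + h, 210.1, 53640, 0.03823) - 2 * der$area +
            logistic3(tt - h, 210.1, 53640, 0.03823)) / h^2
  big <- abs(der$velocity) > 0.01 * max(der$velocity)
  expect_true(all(abs(der$velocity - vfd)[big] / abs(der$velocity[big]) < 1e-3))
  biga <- abs(der$acceleration) > 0.01 * max(abs(der$acceleration))
  expect_true(all(abs(der$acceleration - afd)[biga] /
                    abs(der$acceleration[biga]) < 1e-3))
})

test_that("velocity and acceleration landmarks match the analytic values", {
  # velocity at the inflection = gamma*Aa/4; acceleration extrema where
  # A/Aa = (3 -/+ sqrt(3))/6
  fit <- as3plFit(0.03823, 210.1, 53640)
  pp <- phasePlaneFeatures(fit)
  expect_equal(pp@point_c[["velocity"]], 0.03823 * 53640 / 4,
               tolerance = 1e-6)
  expect_equal(pp@point_c[["acceleration"]], 0, tolerance = 1e-6)
  expect_equal(pp@point_b[["acceleration"]], 7.54, tolerance = 0.01)
  expect_equal(pp@point_b[["acceleration"]],
               0.03823^2 * 53640 / (6 * sqrt(3)), tolerance = 1e-6)
  expect_equal(pp@point_d[["acceleration"]], -pp@point_b[["acceleration"]],
               tolerance = 1e-6)
  # the landmark order is b, then c, then d
  expect_lt(pp@point_b[["time"]], pp@point_c[["time"]])
  expect_lt(pp@point_c[["time"]], pp@point_d[["time"]])
})

test_that("the phase-plane loop area matches the analytic gamma^3 Aa^2 / 30", {
  for (par in list(c(0.03823, 210.1, 53640), c(0.04296, 127.2, 24850),
                   c(0.1, 50, 4000))) {
    fit <- as3plFit(par[1], par[2], par[3])
    pp <- phasePlaneFeatures(fit)
    expect_equal(loopArea(pp) / (par[1]^3 * par[3]^2), 1 / 30,
                 tolerance = 0.005)
  }
})

test_that("acceleration integrates to zero over the full growth span", {
  fit <- as3plFit(0.05, 100, 20000)
  tt <- seq(-400, 700, by = 0.25)
  a <- curveDerivatives(fit, tt)$acceleration
  integral <- sum((a[-1] + a[-length(a)]) / 2 * diff(tt))
  expect_lt(abs(integral), 0.001 * max(abs(a)) * diff(range(tt)))
})

test_that("phase-plane features from a sampled curve track the exact ones", {
  fit <- as3plFit(0.04, 150, 25000)
  tt <- seq(-120, 420, by = 0.25)
  series <- data.frame(time = tt, area = logistic3(tt, 150, 25000, 0.04))
  pp_s <- phasePlaneFeatures(series)
  pp_f <- phasePlaneFeatures(fit)
  expect_equal(pp_s@point_b[["acceleration"]], pp_f@point_b[["acceleration"]],
               tolerance = 1e-3)
  expect_equal(loopArea(pp_s), loopArea(pp_f), tolerance = 0.01)
  # degenerate flat series is flagged, not computed
  flat <- data.frame(time = 0:99, area = rep(500, 100))
  expect_true(phasePlaneFeatures(flat)@degenerate)
  # sparse sampling is refused
  sparse <- data.frame(time = seq(-120, 420, by = 30),
                       area = logistic3(seq(-120, 420, by = 30), 150, 25000, 0.04))
  expect_error(phasePlaneFeatures(sparse), "sparse")
})

test_that("noiseless logistic series are recovered to high precision", {
  tt <- seq(0, 250, length.out = 60)
  fit <- fit3plm(tt, logistic3(tt, 150, 25000, 0.04))
  expect_equal(unname(coef(fit)), c(0.04, 150, 25000), tolerance = 1e-6)
  expect_true(fit@converged)
  expect_false(fit@decreasing)
})

test_that("constant series are rejected as unidentifiable", {
  expect_error(fit3plm(1:20, rep(100, 20)), "unidentifiable|constant")
  expect_error(fit3plm(1:5, 1:5), "at least 10")
  expect_error(fit3plm(1:10, c(1:9, NA)), "finite")
})

test_that("parameter recovery under noise stays within 5% (spot check)", {
  # the full 100-repetition calibration lives with the acceptance checks
  set.seed(33)
  tt <- seq(0, 250, length.out = 900)
  truth <- logistic3(tt, 150, 25000, 0.04)
  for (rep in 1:5) {
    fit <- fit3plm(tt, truth + rnorm(900, 0, 0.02 * 25000))
    expect_equal(unname(coef(fit)), c(0.04, 150, 25000), tolerance = 0.05)
  }
})

test_that("growth rates reproduce the defining finite differences", {
  # constant area: both rates are zero
  cseries <- data.frame(time = seq(0, 20, by = 0.35),
                        area = rep(40, 58))
  gr <- growthRates(cseries, dt = 0.35)
  expect_true(all(abs(gr@agr) < 1e-12, na.rm = TRUE))
  expect_true(all(abs(gr@rgr) < 1e-12, na.rm = TRUE))

  # linear area A = 10 t: AGR = 10 everywhere
  tt <- seq(1, 30, by = 0.5)
  lin <- data.frame(time = tt, area = 10 * tt)
  grl <- growthRates(lin, dt = 0.5)
  expect_equal(grl@agr[!is.na(grl@agr)],
               rep(10, sum(!is.na(grl@agr))), tolerance = 1e-9)

  # exponential area: RGR equals the exponent for any dt
  ex <- data.frame(time = tt, area = exp(0.2 * tt))
  for (dt in c(0.5, 1.5)) {
    gre <- growthRates(ex, dt = dt)
    expect_equal(gre@rgr[!is.na(gre@rgr)],
                 rep(0.2, sum(!is.na(gre@rgr))), tolerance = 1e-9)
  }
  expect_error(growthRates(ex, dt = 0), "positive")
})

test_that("outlier replicates are flagged by the Welch test", {
  tt <- seq(0, 20, length.out = 30)
  base <- logistic3(tt, 100, 5000, 0.4)
  # three identical series: no flags, p = 1
  same <- rbind(base, base, base)
  fl <- flagOutlierReplicates(same)
  expect_true(all(fl$p_value == 1))
  expect_false(any(fl$flagged))

  # one replicate shifted by ten pooled standard deviations
  set.seed(4)
  reps <- rbind(base + rnorm(30, 0, 50), base + rnorm(30, 0, 50),
                base + 10 * stats::sd(base) )
  fl2 <- flagOutlierReplicates(reps)
  expect_true(fl2$flagged[3])
  expect_lt(fl2$p_value[3], 1e-6)
  # the outlier is by far the most extreme replicate
  expect_equal(which.min(fl2$p_value), 3L)

  # alpha = 0 never flags
  fl0 <- flagOutlierReplicates(reps, alpha = 0)
  expect_false(any(fl0$flagged))
  expect_error(flagOutlierReplicates(reps[1:2, ]), "3 replicates")
})

test_that("replicate averaging reproduces identical fits exactly", {
  f <- as3plFit(0.04, 150, 25000)
  av <- averageReplicates(list(f, f))
  expect_equal(av$mean, logistic3(av$times, 150, 25000, 0.04))
  expect_true(all(av$sd == 0))
  expect_error(averageReplicates(list(f)), "2 retained")
})

test_that("genotype-averaged phase-plane extrema match the reference plants", {
  # wild-type samples 1 and 3: mean maximal acceleration about 8.6;
  # cfq samples 2 and 3: about 4.0
  wt <- averageReplicates(list(table2Fit("WT", 1), table2Fit("WT", 3)))
  expect_equal(wt$features@point_b[["acceleration"]], 8.6, tolerance = 0.01)
  cfq <- averageReplicates(list(table2Fit("cfq", 2), table2Fit("cfq", 3)))
  expect_equal(cfq$features@point_b[["acceleration"]], 4.0, tolerance = 0.02)
})

test_that("curve-first averaging is exposed as an alternative mode", {
  wt <- averageReplicates(list(table2Fit("WT", 1), table2Fit("WT", 3)),
                          mode = "curve")
  expect_identical(wt$mode, "curve")
  expect_false(wt$features@degenerate)
  # same order of magnitude as the per-replicate mode, not identical
  expect_equal(wt$features@point_b[["acceleration"]], 8.6, tolerance = 0.15)
})
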