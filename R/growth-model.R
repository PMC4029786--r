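#' Three-parameter logistic growth curve
#'
#' Evaluates `A(t) = A0 * Aa / (A0 + (Aa - A0) * exp(-gamma * t))`: plant
#' area `A0` at `t = 0`, upper asymptote `Aa` as `t -> Inf`, growth rate
#' `gamma` in 1/time. The curve satisfies the logistic ODE
#' `dA/dt = gamma * A * (1 - A/Aa)` with inflection (maximal velocity
#' `gamma * Aa / 4`) where `A = Aa / 2`.
#'
#' @param t time (vectorized).
#' @param A0 initial area (px^2), `0 < A0 < Aa`.
#' @param Aa upper asymptote (px^2).
#' @param gamma rate (1/time), > 0.
#' @return numeric vector of areas.
#' @examples
#' logistic3(0, A0 = 150, Aa = 25000, gamma = 0.04)  # = A0
#' @export
logistic3 <- function(t, A0, Aa, gamma) {
  if (!(A0 > 0 && A0 < Aa && gamma > 0))
    stop("parameters must satisfy 0 < A0 < Aa and gamma > 0")
  A0 * Aa / (A0 + (Aa - A0) * exp(-gamma * t))
}

.logistic3V <- function(t, A0, Aa, gamma) {
  A <- logistic3(t, A0, Aa, gamma)
  gamma * A * (1 - A / Aa)
}

.logistic3Acc <- function(t, A0, Aa, gamma) {
  A <- logistic3(t, A0, Aa, gamma)
  gamma^2 * A * (1 - A / Aa) * (1 - 2 * A / Aa)
}

# time at which A(t) = x * Aa, 0 < x < 1
.logistic3TimeAt <- function(x, A0, Aa, gamma) {
  C <- (Aa - A0) / A0
  log(C * x / (1 - x)) / gamma
}

#' Fit the three-parameter logistic model to an area series
#'
#' Nonlinear least squares (Levenberg-Marquardt) fit of [logistic3()] to a
#' plant area time series. Starting values: `A0` = first positive
#' observation, `Aa` = 1.2 x the maximum observation, `gamma` from the
#' slope of `logit((A - A0)/(Aa - A0))` against time. Parameter 95%
#' confidence intervals are first-order (Jacobian-based) normal intervals
#' at the optimum. Non-convergence is an error, never silent; a series that
#' trends downward is fitted but flagged (`@decreasing`).
#'
#' @param times,areas numeric vectors (at least 10 finite observations; a
#'   max/min area ratio of 2 or more is recommended for identifiability).
#' @return a [ThreePLFit-class].
#' @examples
#' t <- seq(0, 250, length.out = 60)
#' fit <- fit3plm(t, logistic3(t, 150, 25000, 0.04))
#' coef(fit)
#' @export
fit3plm <- function(times, areas) {
  if (length(times) != length(areas)) stop("times and areas differ in length")
  ok <- is.finite(times) & is.finite(areas)
  if (!all(ok)) stop("non-finite observations in the area series")
  if (length(times) < 10) stop("at least 10 observations are required")
  if (diff(range(areas)) <= 0)
    stop("degenerate (constant) area series: logistic parameters are unidentifiable")
  slope <- stats::coef(stats::lm(areas ~ times))[2]
  decreasing <- unname(slope < 0)

  A0s <- areas[areas > 0][1]
  if (is.na(A0s)) stop("no positive areas in the series")
  Aas <- 1.2 * max(areas)
  z <- pmin(pmax((areas - A0s) / (Aas - A0s), 1e-4), 1 - 1e-4)
  gs <- unname(stats::coef(stats::lm(stats::qlogis(z) ~ times))[2])
  if (!is.finite(gs) || gs <= 0) gs <- 0.05

  df <- data.frame(t = times, A = areas)
  fit <- tryCatch(
    minpack.lm::nlsLM(A ~ A0 * Aa / (A0 + (Aa - A0) * exp(-gamma * t)),
                      data = df,
                      start = list(gamma = gs, A0 = A0s, Aa = Aas),
                      lower = c(1e-10, 1e-10, 1e-10),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e)
      stop("3PLM fit did not converge: ", conditionMessage(e), call. = FALSE))
  cf <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  tq <- stats::qt(0.975, length(areas) - 3)
  ci <- cbind(cf - tq * se, cf + tq * se)
  dimnames(ci) <- list(c("gamma", "A0", "Aa"), c("lower", "upper"))
  new("ThreePLFit", gamma = unname(cf["gamma"]), A0 = unname(cf["A0"]),
      Aa = unname(cf["Aa"]), ci = ci,
      residual_sd = stats::sigma(fit), n_obs = length(areas),
      converged = TRUE, decreasing = decreasing)
}

#' Absolute and relative growth rates
#'
#' Finite-difference growth rates at step `dt`:
#' `AGR(t) = (A(t) - A(t - dt)) / dt` (px^2/time) and
#' `RGR(t) = (ln A(t) - ln A(t - dt)) / dt` (1/time). For a fitted curve
#' the logistic is evaluated exactly at `t` and `t - dt`; for a raw series
#' the areas at `t - dt` are linearly interpolated. The default step is
#' 0.35 days, matching quarter-hourly imaging aggregated over a workday.
#'
#' @param x a [ThreePLFit-class], or a data frame with columns `time` and
#'   `area`.
#' @param dt finite-difference step, > 0 (default 0.35).
#' @param times evaluation times; default: the series' own times, or for a
#'   fit an evenly spaced grid must be supplied.
#' @return a [GrowthRates-class]; RGR is NA wherever an involved area is
#'   not positive.
#' @export
growthRates <- function(x, dt = 0.35, times = NULL) {
  if (dt <= 0) stop("dt must be positive")
  if (is(x, "ThreePLFit")) {
    if (is.null(times)) stop("supply evaluation times for a fitted curve")
    A1 <- logistic3(times, x@A0, x@Aa, x@gamma)
    A0_ <- logistic3(times - dt, x@A0, x@Aa, x@gamma)
  } else {
    stopifnot(is.data.frame(x), all(c("time", "area") %in% names(x)))
    if (is.null(times)) times <- x$time
    A1 <- stats::approx(x$time, x$area, xout = times, rule = 1)$y
    A0_ <- stats::approx(x$time, x$area, xout = times - dt, rule = 1)$y
  }
  agr <- (A1 - A0_) / dt
  pos <- !is.na(A1) & !is.na(A0_) & A1 > 0 & A0_ > 0
  rgr <- rep(NA_real_, length(times))
  rgr[pos] <- (log(A1[pos]) - log(A0_[pos])) / dt
  new("GrowthRates", times = times, agr = agr, rgr = rgr, dt = dt)
}

#' Velocity and acceleration of a fitted growth curve
#'
#' Closed-form first and second derivatives of the three-parameter
#' logistic: `velocity = dA/dt = gamma * A * (1 - A/Aa)` and
#' `acceleration = d^2A/dt^2 = gamma^2 * A * (1 - A/Aa) * (1 - 2A/Aa)`.
#' Velocity is nonnegative everywhere and maximal (`gamma*Aa/4`) at the
#' inflection `A = Aa/2`, where the acceleration crosses zero;
#' acceleration is extremal where `A/Aa = (3 -/+ sqrt(3))/6`.
#'
#' @param fit a [ThreePLFit-class].
#' @param times evaluation times.
#' @return a data frame with columns `time`, `area`, `velocity`,
#'   `acceleration`.
#' @export
curveDerivatives <- function(fit, times) {
  stopifnot(is(fit, "ThreePLFit"))
  data.frame(time = times,
             area = logistic3(times, fit@A0, fit@Aa, fit@gamma),
             velocity = .logistic3V(times, fit@A0, fit@Aa, fit@gamma),
             acceleration = .logistic3Acc(times, fit@A0, fit@Aa, fit@gamma))
}

.featuresFromSeries <- function(tt, v, a, refine = NULL) {
  pick <- function(i) c(velocity = v[i], acceleration = a[i], time = tt[i])
  ib <- which.max(a); ic <- which.max(v); id <- which.min(a)
  b <- pick(ib); c_ <- pick(ic); d <- pick(id)
  if (!is.null(refine)) {
    # polish the grid argmax against the closed-form derivatives
    win <- function(i) c(tt[max(1, i - 1)], tt[min(length(tt), i + 1)])
    ob <- stats::optimize(refine$acc, win(ib), maximum = TRUE)
    b <- c(velocity = refine$vel(ob$maximum), acceleration = ob$objective,
           time = ob$maximum)
    oc <- stats::optimize(refine$vel, win(ic), maximum = TRUE)
    c_ <- c(velocity = oc$objective, acceleration = refine$acc(oc$maximum),
            time = oc$maximum)
    od <- stats::optimize(refine$acc, win(id), maximum = FALSE)
    d <- c(velocity = refine$vel(od$minimum), acceleration = od$objective,
           time = od$minimum)
  }
  # loop area: |closed-path integral of acceleration over velocity|,
  # equal to the time integral of acceleration^2
  la <- abs(.trapz(v, a))
  new("PhasePlaneFeatures", point_b = b, point_c = c_, point_d = d,
      loop_area = la, degenerate = FALSE)
}

#' Phase-plane features of a growth curve
#'
#' Computes the landmarks of the acceleration-versus-velocity trajectory
#' ("phase plane") of a growth curve. The trajectory is a closed loop from
#' the origin (dormant, both zero) through point b (maximal acceleration:
#' fastest build-up of growth capacity), point c (maximal velocity, zero
#' acceleration, at the inflection `A = Aa/2`), point d (most negative
#' acceleration: strongest deceleration) and back to the origin at the
#' upper asymptote. The enclosed loop area -- the path integral of
#' acceleration over velocity, accumulated by trapezoids -- is an
#' energy-transfer proxy for the whole growth episode. Velocity is reported
#' on its natural nonnegative scale (the first derivative of a logistic is
#' never negative, so point d has positive velocity).
#'
#' For a [ThreePLFit-class] the curve is sampled densely over the full
#' growth span (from `A = q*Aa` to `A = (1-q)*Aa`) and the landmark
#' positions are polished against the closed-form derivatives. For a raw
#' `(time, area)` series the derivatives come from centered finite
#' differences; the sampling must be sorted and dense (velocity steps below
#' 1% of the maximal velocity).
#'
#' @param x a [ThreePLFit-class] or a data frame with columns `time`,
#'   `area`.
#' @param n_grid grid size for a fitted curve (default 20001).
#' @param q tail cut for the growth span (default 1e-4).
#' @return a [PhasePlaneFeatures-class]; degenerate (flat) curves return
#'   all-NA features with `@degenerate = TRUE`.
#' @examples
#' fit <- new("ThreePLFit", gamma = 0.03823, A0 = 210.1, Aa = 53640,
#'            ci = matrix(NA_real_, 3, 2), residual_sd = 0, n_obs = 0L,
#'            converged = TRUE, decreasing = FALSE)
#' phasePlaneFeatures(fit)
#' @export
phasePlaneFeatures <- function(x, n_grid = 20001L, q = 1e-4) {
  degen <- new("PhasePlaneFeatures",
               point_b = c(velocity = NA_real_, acceleration = NA_real_, time = NA_real_),
               point_c = c(velocity = NA_real_, acceleration = NA_real_, time = NA_real_),
               point_d = c(velocity = NA_real_, acceleration = NA_real_, time = NA_real_),
               loop_area = NA_real_, degenerate = TRUE)
  if (is(x, "ThreePLFit")) {
    t1 <- .logistic3TimeAt(q, x@A0, x@Aa, x@gamma)
    t2 <- .logistic3TimeAt(1 - q, x@A0, x@Aa, x@gamma)
    tt <- seq(t1, t2, length.out = n_grid)
    v <- .logistic3V(tt, x@A0, x@Aa, x@gamma)
    a <- .logistic3Acc(tt, x@A0, x@Aa, x@gamma)
    refine <- list(vel = function(t) .logistic3V(t, x@A0, x@Aa, x@gamma),
                   acc = function(t) .logistic3Acc(t, x@A0, x@Aa, x@gamma))
    return(.featuresFromSeries(tt, v, a, refine))
  }
  stopifnot(is.data.frame(x), all(c("time", "area") %in% names(x)))
  tt <- x$time; A <- x$area
  if (any(diff(tt) <= 0)) stop("time series must be strictly increasing")
  if (diff(range(A)) <= 1e-9 * max(abs(A), 1)) return(degen)
  n <- length(tt)
  if (n < 5) stop("sampling too sparse for derivatives")
  v <- a <- rep(NA_real_, n)
  i <- 2:(n - 1)
  v[i] <- (A[i + 1] - A[i - 1]) / (tt[i + 1] - tt[i - 1])
  a[i] <- 2 * (A[i + 1] * (tt[i] - tt[i - 1]) + A[i - 1] * (tt[i + 1] - tt[i]) -
                 A[i] * (tt[i + 1] - tt[i - 1])) /
    ((tt[i + 1] - tt[i]) * (tt[i] - tt[i - 1]) * (tt[i + 1] - tt[i - 1]))
  keep <- !is.na(v)
  tt <- tt[keep]; v <- v[keep]; a <- a[keep]
  if (max(abs(diff(v))) > 0.01 * max(abs(v)))
    stop("sampling too sparse: velocity steps exceed 1% of the maximal velocity")
  .featuresFromSeries(tt, v, a)
}

#' Flag replicate plants statistically different from the rest
#'
#' For each replicate, a two-tailed Welch t-test (unequal variances)
#' compares its per-timepoint areas against the pooled per-timepoint areas
#' of the remaining replicates; replicates with `p < alpha` are flagged for
#' exclusion from genotype averaging (biological outliers).
#'
#' @param series numeric matrix of areas, one row per replicate, one column
#'   per time point (at least 3 replicates), or a list of equal-length
#'   numeric vectors.
#' @param alpha significance level (default 0.05); `alpha = 0` never flags.
#' @return data frame with columns `replicate`, `p_value`, `flagged`.
#' @export
flagOutlierReplicates <- function(series, alpha = 0.05) {
  if (is.list(series)) series <- do.call(rbind, series)
  if (nrow(series) < 3) stop("at least 3 replicates are required")
  p <- vapply(seq_len(nrow(series)), function(i) {
    x <- series[i, ]
    y <- as.vector(series[-i, ])
    if (stats::sd(x) == 0 && stats::sd(y) == 0)
      return(if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0)
    tryCatch(stats::t.test(x, y, var.equal = FALSE)$p.value,
             error = function(e) 1)
  }, numeric(1))
  data.frame(replicate = seq_len(nrow(series)), p_value = p,
             flagged = p < alpha)
}

#' Average replicate growth curves and their phase-plane features
#'
#' Pointwise mean and standard deviation of fitted growth curves over a
#' common time grid, plus genotype-level phase-plane features. Two
#' averaging conventions are exposed: `"replicates"` (default) computes the
#' features of each replicate's curve and averages them component-wise --
#' extrema of individual plants, then the mean; `"curve"` first averages
#' the curves and then extracts features from the mean curve (which is no
#' longer an exact logistic). The two disagree when replicates are
#' staggered in time; the per-replicate mode is the default summary.
#'
#' @param fits list of at least 2 [ThreePLFit-class] objects (retained
#'   replicates of one genotype).
#' @param times common evaluation grid; default spans the slowest
#'   replicate's growth span on 2001 points.
#' @param mode `"replicates"` or `"curve"`.
#' @return a list with elements `times`, `mean`, `sd` (curve band),
#'   `features` ([PhasePlaneFeatures-class]) and `mode`.
#' @export
averageReplicates <- function(fits, times = NULL,
                              mode = c("replicates", "curve")) {
  mode <- match.arg(mode)
  if (length(fits) < 2) stop("at least 2 retained replicates are required")
  if (is.null(times)) {
    span <- vapply(fits, function(f)
      c(.logistic3TimeAt(1e-4, f@A0, f@Aa, f@gamma),
        .logistic3TimeAt(1 - 1e-4, f@A0, f@Aa, f@gamma)), numeric(2))
    times <- seq(min(span[1, ]), max(span[2, ]), length.out = 2001L)
  }
  curves <- vapply(fits, function(f) logistic3(times, f@A0, f@Aa, f@gamma),
                   numeric(length(times)))
  mcurve <- rowMeans(curves)
  scurve <- apply(curves, 1, stats::sd)
  if (mode == "replicates") {
    fl <- lapply(fits, phasePlaneFeatures)
    avg <- function(get) rowMeans(vapply(fl, get, numeric(3)))
    features <- new("PhasePlaneFeatures",
                    point_b = avg(function(f) f@point_b),
                    point_c = avg(function(f) f@point_c),
                    point_d = avg(function(f) f@point_d),
                    loop_area = mean(vapply(fl, loopArea, numeric(1))),
                    degenerate = FALSE)
  } else {
    features <- phasePlaneFeatures(data.frame(time = times, area = mcurve))
  }
  list(times = times, mean = mcurve, sd = scurve, features = features,
       mode = mode)
}

#' Bundled logistic growth parameters of six Arabidopsis plants
#'
#' Three-parameter logistic fits (with 95% confidence bounds) for three
#' wild-type and three cfq-mutant Arabidopsis thaliana plants grown for 15
#' days under fluctuating light, imaged every 15 minutes from above;
#' shipped as a plain-text reference table for worked examples and the
#' phase-plane analysis. `retained` marks the replicates kept for genotype
#' averaging (one replicate per genotype was excluded as a biological
#' outlier by a Welch t-test against its peers). Units: `gamma` in inverse
#' time units of the original series, areas in pixels^2.
#'
#' @return data frame with columns `genotype`, `sample`, `gamma`, `A0`,
#'   `Aa`, their `_lo`/`_hi` 95% bounds, and `retained`.
#' @examples
#' fits <- arabidopsisLogisticFits()
#' subset(fits, retained & genotype == "WT")
#' @export
arabidopsisLogisticFits <- function() {
  path <- system.file("extdata", "arabidopsis_3plm_fits.csv",
                      package = "RosetteGrowth", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Build a ThreePLFit from known parameters
#'
#' Wraps externally obtained logistic parameters (for example a row of
#' [arabidopsisLogisticFits()]) into a [ThreePLFit-class] so the
#' functional-analysis tools can be applied to published parameter sets.
#'
#' @param gamma,A0,Aa logistic parameters (`0 < A0 < Aa`, `gamma > 0`).
#' @param ci optional 3 x 2 matrix of 95% bounds (rows gamma, A0, Aa).
#' @return a [ThreePLFit-class].
#' @export
as3plFit <- function(gamma, A0, Aa, ci = NULL) {
  if (is.null(ci)) ci <- matrix(NA_real_, 3, 2,
                                dimnames = list(c("gamma", "A0", "Aa"),
                                                c("lower", "upper")))
  new("ThreePLFit", gamma = gamma, A0 = A0, Aa = Aa, ci = ci,
      residual_sd = NA_real_, n_obs = 0L, converged = TRUE,
      decreasing = FALSE)
}
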