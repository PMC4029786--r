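#' Default leaf length-to-area model
#'
#' The shipped piecewise model mapping leaf length `r` (px) and curvature
#' ratio `cr` to leaf area (px^2):
#' `area = 32.9 * r - 769.9` when `cr < 0.07` (round leaves, R^2 = 0.90)
#' and `area = 513.8 * exp(0.0146 * r)` otherwise (elongated leaves,
#' R^2 = 0.88). The coefficients were calibrated on 87 wild-type
#' Arabidopsis leaves aged 1-5 weeks at the original imaging scale; they
#' are genotype- and setup-specific, so recalibrate with
#' [fitLengthAreaModel()] when the optics or species change. The stored
#' 95% confidence bounds of the calibration are (29.9, 36.0),
#' (-1012.0, -527.6), (406.1, 621.6) and (0.0130, 0.0162).
#'
#' @return a [LengthAreaModel-class].
#' @examples
#' defaultLengthAreaModel()
#' @export
defaultLengthAreaModel <- function() {
  ci <- matrix(c(29.9, 36.0, -1012.0, -527.6, 406.1, 621.6, 0.0130, 0.0162),
               ncol = 2, byrow = TRUE,
               dimnames = list(c("linear_slope", "linear_intercept",
                                 "exp_scale", "exp_rate"),
                               c("lower", "upper")))
  new("LengthAreaModel", linear_slope = 32.9, linear_intercept = -769.9,
      exp_scale = 513.8, exp_rate = 0.0146, cr_cutoff = 0.07,
      r2_linear = 0.90, r2_exp = 0.88, ci = ci)
}

#' Leaf area from a detected tip
#'
#' Evaluates the piecewise length-to-area model for one leaf: the linear
#' branch when `cr < cr_cutoff`, the exponential branch otherwise (a `cr`
#' exactly at the cutoff takes the exponential branch). Negative linear
#' predictions (very short leaves below the model's root) are clamped to 0
#' with a warning.
#'
#' @param r leaf length in pixels (center-to-tip radius, > 0). Vectorized.
#' @param cr curvature ratio, same length as `r` (or length 1).
#' @param model a [LengthAreaModel-class].
#' @return numeric vector of leaf areas (px^2).
#' @examples
#' leafAreaFromTip(100, 0.05)  # linear branch: 32.9*100 - 769.9
#' leafAreaFromTip(100, 0.07)  # exponential branch: 513.8*exp(1.46)
#' @export
leafAreaFromTip <- function(r, cr, model = defaultLengthAreaModel()) {
  if (any(r <= 0)) stop("leaf length r must be positive")
  cr <- rep_len(cr, length(r))
  area <- ifelse(cr < model@cr_cutoff,
                 model@linear_slope * r + model@linear_intercept,
                 model@exp_scale * exp(model@exp_rate * r))
  if (any(area < 0)) {
    warning(sprintf("%d leaf area prediction(s) below 0 clamped to 0 (leaf length below the linear model's root)",
                    sum(area < 0)))
    area <- pmax(area, 0)
  }
  area
}

#' Curvature-ratio cutoff from a Gaussian mixture
#'
#' The distribution of curvature ratios over a population of leaves is
#' bimodal: a tight low-`cr` mode (round leaves) and a broader high-`cr`
#' mode (elongated leaves). This fits a 2-component univariate Gaussian
#' mixture by EM (unequal variances, deterministic model-based
#' initialization) and returns the point between the two component means at
#' which the posterior responsibilities are equal -- the natural split for
#' routing leaves to the two branches of the length-to-area model. If the
#' mixture is degenerate (a component weight below 0.05, or means closer
#' than a quarter of the pooled standard deviation) the shipped default
#' cutoff 0.07 is returned with a warning.
#'
#' @param cr_values numeric vector of at least 20 curvature ratios.
#' @return numeric(1), the cutoff.
#' @importFrom mclust Mclust mclustBIC
#' @export
fitCutoff <- function(cr_values) {
  if (length(cr_values) < 20) stop("at least 20 cr values are required")
  fallback <- function(why) {
    warning(sprintf("degenerate cr mixture (%s); returning default cutoff 0.07", why))
    0.07
  }
  if (stats::sd(cr_values) == 0) return(fallback("no spread"))
  fit <- tryCatch(
    Mclust(cr_values, G = 2, modelNames = "V", verbose = FALSE),
    error = function(e) NULL)
  if (is.null(fit)) return(fallback("EM failed"))
  mu <- as.numeric(fit$parameters$mean)
  sig <- sqrt(as.numeric(fit$parameters$variance$sigmasq))
  if (length(sig) == 1) sig <- rep(sig, 2)
  w <- as.numeric(fit$parameters$pro)
  if (min(w) < 0.05) return(fallback("component weight < 0.05"))
  pooled <- sqrt(sum(w * sig^2))
  if (abs(diff(mu)) < pooled / 4) return(fallback("component means too close"))
  o <- order(mu)
  mu <- mu[o]; sig <- sig[o]; w <- w[o]
  f <- function(x) {
    log(w[1]) + stats::dnorm(x, mu[1], sig[1], log = TRUE) -
      log(w[2]) - stats::dnorm(x, mu[2], sig[2], log = TRUE)
  }
  if (f(mu[1]) * f(mu[2]) > 0) return(fallback("no equal-posterior point between means"))
  stats::uniroot(f, c(mu[1], mu[2]), tol = 1e-10)$root
}

#' Fit the leaf length-to-area model from training leaves
#'
#' Recalibrates the piecewise model from measured leaves (length `r`,
#' curvature ratio `cr`, true area). Leaves are routed to the linear or
#' exponential branch by `cutoff`; the linear branch is ordinary least
#' squares of area on length, the exponential branch is least squares of
#' log(area) on length refined by one nonlinear least-squares pass on the
#' original scale. Each branch reports its R^2 on the original scale and
#' 95% confidence intervals for all four coefficients.
#'
#' @param training data frame with columns `r`, `cr`, `area` (at least 3
#'   leaves in each branch).
#' @param cutoff curvature-ratio split point (default 0.07; see
#'   [fitCutoff()]).
#' @return a [LengthAreaModel-class].
#' @export
fitLengthAreaModel <- function(training, cutoff = 0.07) {
  stopifnot(all(c("r", "cr", "area") %in% names(training)))
  lin <- training[training$cr < cutoff, ]
  ex <- training[training$cr >= cutoff, ]
  if (nrow(lin) < 3) stop("fewer than 3 leaves in the linear (cr < cutoff) branch")
  if (nrow(ex) < 3) stop("fewer than 3 leaves in the exponential (cr >= cutoff) branch")

  lfit <- stats::lm(area ~ r, data = lin)
  lci <- stats::confint(lfit)
  r2 <- function(obs, pred) {
    ss <- sum((obs - mean(obs))^2)
    if (ss == 0) 1 else 1 - sum((obs - pred)^2) / ss
  }
  r2l <- r2(lin$area, stats::fitted(lfit))

  if (any(ex$area <= 0)) stop("exponential-branch areas must be positive")
  lg <- stats::lm(log(area) ~ r, data = ex)
  s0 <- unname(exp(stats::coef(lg)[1])); b0 <- unname(stats::coef(lg)[2])
  efit <- tryCatch(
    minpack.lm::nlsLM(area ~ s * exp(b * r), data = ex,
                      start = list(s = s0, b = b0)),
    error = function(e) NULL)
  if (is.null(efit)) {
    es <- s0; eb <- b0
    eci <- matrix(NA_real_, 2, 2)
    pred <- es * exp(eb * ex$r)
  } else {
    cf <- stats::coef(efit)
    es <- cf[["s"]]; eb <- cf[["b"]]
    se <- sqrt(diag(stats::vcov(efit)))
    tq <- stats::qt(0.975, nrow(ex) - 2)
    eci <- cbind(cf - tq * se, cf + tq * se)
    pred <- stats::fitted(efit)
  }
  r2e <- r2(ex$area, pred)

  ci <- rbind(lci[2, ], lci[1, ], eci[1, ], eci[2, ])
  dimnames(ci) <- list(c("linear_slope", "linear_intercept",
                         "exp_scale", "exp_rate"), c("lower", "upper"))
  new("LengthAreaModel",
      linear_slope = unname(stats::coef(lfit)[2]),
      linear_intercept = unname(stats::coef(lfit)[1]),
      exp_scale = unname(es), exp_rate = unname(eb),
      cr_cutoff = cutoff, r2_linear = r2l, r2_exp = r2e, ci = ci)
}

#' Overlap-corrected plant area from leaf areas and the observed area
#'
#' Combines the summed per-leaf model areas `a_l` with the observed
#' top-view area `a_t` into the corrected plant area. The leaf overlap
#' percentage is `p_overlap = |a_t - a_l| / max(a_t, a_l)` and the plant
#' area is `a = a_l * (1 + p_overlap)`; equivalently `a = 2*a_l - a_t` when
#' `a_l > a_t` (tips were found for overlapping leaves, so the top view
#' undercounts) and `a = 2*a_l - a_l^2 / a_t` otherwise (some inner tips
#' were missed, so `a_l` undercounts). With no overlap the plant area is
#' exactly the sum of the leaf areas.
#'
#' @param leaf_areas numeric vector of per-leaf areas (px^2), non-empty.
#' @param a_t observed top-view area (px^2, > 0).
#' @param time optional frame time stored in the record.
#' @return a [PlantAreaRecord-class].
#' @examples
#' plantArea(c(600, 400), a_t = 800)   # a_l = 1000 > a_t: a = 2*1000 - 800
#' @export
plantArea <- function(leaf_areas, a_t, time = NA_real_) {
  if (length(leaf_areas) == 0) stop("no leaf areas: no tips were detected")
  if (!is.finite(a_t) || a_t <= 0) stop("a_t must be positive (empty mask upstream?)")
  a_l <- sum(leaf_areas)
  p <- abs(a_t - a_l) / max(a_t, a_l)
  a <- a_l * (1 + p)
  new("PlantAreaRecord", time = as.numeric(time), a_l = a_l, a_t = a_t,
      p_overlap = p, a = a, m = length(leaf_areas))
}
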