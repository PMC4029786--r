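#' Observed top-view area (pixel count) of a mask
#'
#' @param x a [ForegroundMask-class].
#' @return numeric(1), the number of foreground pixels (`a_t`).
#' @export
setGeneric("observedArea", function(x) standardGeneric("observedArea"))

#' Logical mask matrix
#'
#' @param x a [ForegroundMask-class].
#' @return the logical matrix of plant pixels.
#' @export
setGeneric("maskMatrix", function(x) standardGeneric("maskMatrix"))

#' Center point coordinates
#'
#' @param x a [PlantCenter-class] or [GroundTruth-class].
#' @return numeric(2), (row, col) in 0-based pixel coordinates.
#' @export
setGeneric("centerPoint", function(x) standardGeneric("centerPoint"))

#' Radii of a polar profile
#'
#' @param x a [PolarProfile-class] or [SmoothedProfile-class].
#' @return numeric vector of per-bin radii (px).
#' @export
setGeneric("radii", function(x) standardGeneric("radii"))

#' Enclosed phase-plane loop area
#'
#' @param x a [PhasePlaneFeatures-class].
#' @return numeric(1).
#' @export
setGeneric("loopArea", function(x) standardGeneric("loopArea"))

setMethod("observedArea", "ForegroundMask", function(x) x@observed_area)
setMethod("maskMatrix", "ForegroundMask", function(x) x@mask)
setMethod("centerPoint", "PlantCenter", function(x) x@point)
setMethod("centerPoint", "GroundTruth", function(x) x@center)
setMethod("radii", "PolarProfile", function(x) x@radii)
setMethod("radii", "SmoothedProfile", function(x) x@radii)
setMethod("loopArea", "PhasePlaneFeatures", function(x) x@loop_area)

#' @describeIn ThreePLFit-class parameter estimates as a named vector
#'   (gamma, A0, Aa).
#' @param object a `ThreePLFit`.
#' @param ... ignored.
#' @export
setMethod("coef", "ThreePLFit", function(object, ...) {
  c(gamma = object@gamma, A0 = object@A0, Aa = object@Aa)
})

#' @describeIn ThreePLFit-class 95% confidence bounds, a 3 x 2 matrix.
#' @param parm,level ignored (the interval is the stored 95% one).
#' @export
setMethod("confint", "ThreePLFit", function(object, parm, level = 0.95, ...) {
  object@ci
})

#' @describeIn PlantAreaRecord-class one-row data frame with columns
#'   time, m, a_l, a_t, p_overlap, a.
#' @param x a `PlantAreaRecord`.
#' @param row.names,optional,... passed over (ignored).
#' @export
setMethod("as.data.frame", "PlantAreaRecord",
  function(x, row.names = NULL, optional = FALSE, ...) {
    data.frame(time = x@time, m = x@m, a_l = x@a_l, a_t = x@a_t,
               p_overlap = x@p_overlap, a = x@a)
  })

setMethod("show", "LeafSpec", function(object) {
  cat(sprintf("LeafSpec: %s at %.1f deg, length %.1f px, width %.1f px (petiole %.0f%%)\n",
              object@shape, object@angle, object@length, object@width,
              100 * object@petiole_fraction))
})

setMethod("show", "RosetteSpec", function(object) {
  cat(sprintf("RosetteSpec: %d leaves, %d x %d px, center (%.1f, %.1f), seed %d\n",
              length(object@leaves), object@image_size[1], object@image_size[2],
              object@center[1], object@center[2], object@seed))
})

setMethod("show", "GroundTruth", function(object) {
  cat(sprintf("GroundTruth: %d leaves, union area %.1f px^2, overlap fraction %.3f\n",
              nrow(object@tip_points), object@union_area, object@overlap_fraction))
})

setMethod("show", "ForegroundMask", function(object) {
  cat(sprintf("ForegroundMask: %d x %d px, a_t = %d foreground px\n",
              nrow(object@mask), ncol(object@mask), as.integer(object@observed_area)))
})

setMethod("show", "PlantCenter", function(object) {
  cat(sprintf("PlantCenter: (%.2f, %.2f) by %s (%d leaves)\n",
              object@point[1], object@point[2], object@method,
              object@n_leaves_used))
})

setMethod("show", "PolarProfile", function(object) {
  cat(sprintf("PolarProfile: %d bins of %.1f deg, radii %.1f-%.1f px (%d interpolated)\n",
              length(object@radii), object@bin_width, min(object@radii),
              max(object@radii), sum(object@interpolated)))
})

setMethod("show", "SmoothedProfile", function(object) {
  cat(sprintf("SmoothedProfile: %d bins, window k = %d\n",
              length(object@radii), object@k))
})

setMethod("show", "LengthAreaModel", function(object) {
  cat("LengthAreaModel (leaf length -> area):\n")
  cat(sprintf("  cr < %.3g : area = %.4g * r + %.4g   (R^2 = %.3g)\n",
              object@cr_cutoff, object@linear_slope, object@linear_intercept,
              object@r2_linear))
  cat(sprintf("  cr >= %.3g: area = %.4g * exp(%.4g * r)   (R^2 = %.3g)\n",
              object@cr_cutoff, object@exp_scale, object@exp_rate,
              object@r2_exp))
})

setMethod("show", "PlantAreaRecord", function(object) {
  cat(sprintf("PlantAreaRecord: a = %.1f px^2 (a_l = %.1f, a_t = %.1f, overlap %.1f%%, %d tips)\n",
              object@a, object@a_l, object@a_t, 100 * object@p_overlap,
              object@m))
})

setMethod("show", "ThreePLFit", function(object) {
  cat("Three-parameter logistic fit A(t) = A0*Aa / (A0 + (Aa - A0)*exp(-gamma*t))\n")
  est <- coef(object)
  for (i in seq_len(3)) {
    cat(sprintf("  %-6s %10.5g   95%% CI [%.5g, %.5g]\n",
                names(est)[i], est[i], object@ci[i, 1], object@ci[i, 2]))
  }
  cat(sprintf("  residual sd %.4g on %d observations%s\n", object@residual_sd,
              object@n_obs,
              if (object@decreasing) " (decreasing series!)" else ""))
})

setMethod("show", "GrowthRates", function(object) {
  cat(sprintf("GrowthRates: %d time points, dt = %.3g; AGR max %.4g, RGR max %.4g\n",
              length(object@times), object@dt, max(object@agr, na.rm = TRUE),
              max(object@rgr, na.rm = TRUE)))
})

setMethod("show", "PhasePlaneFeatures", function(object) {
  if (object@degenerate) {
    cat("PhasePlaneFeatures: degenerate (flat curve), all features NA\n")
    return(invisible(NULL))
  }
  cat("PhasePlaneFeatures (velocity, acceleration, time):\n")
  cat(sprintf("  b (max accel): (%.4g, %.4g, %.4g)\n",
              object@point_b[1], object@point_b[2], object@point_b[3]))
  cat(sprintf("  c (max veloc): (%.4g, %.4g, %.4g)\n",
              object@point_c[1], object@point_c[2], object@point_c[3]))
  cat(sprintf("  d (min accel): (%.4g, %.4g, %.4g)\n",
              object@point_d[1], object@point_d[2], object@point_d[3]))
  cat(sprintf("  loop area: %.6g\n", object@loop_area))
})
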