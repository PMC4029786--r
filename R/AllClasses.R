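#' @import methods
NULL

#' Single-leaf geometry specification
#'
#' Describes one leaf of a synthetic rosette: the direction it points in, its
#' center-to-tip length (petiole included, measured from the plant center),
#' its maximal width, and its outline family. `"ellipse"` gives a rounded
#' leaf (an ellipse whose near end sits at `petiole_fraction * length` from
#' the plant center); `"teardrop"` gives an elongated leaf built from two
#' circular arcs joining the petiole base to the tip.
#'
#' @slot angle numeric(1), direction of the leaf axis in degrees, in
#'   \[0, 360). Angle 0 points along increasing column; angles increase
#'   counter-clockwise when the image is viewed with row 0 at the top.
#' @slot length numeric(1), center-to-tip distance in pixels (> 0).
#' @slot width numeric(1), maximal leaf width in pixels (0 < width < 2 * length).
#' @slot shape character(1), `"ellipse"` or `"teardrop"`.
#' @slot petiole_fraction numeric(1) in \[0, 1), fraction of the length taken
#'   by the bare petiole before the blade begins.
#' @seealso [LeafSpec()], [RosetteSpec-class]
#' @exportClass LeafSpec
setClass("LeafSpec",
  representation(
    angle = "numeric",
    length = "numeric",
    width = "numeric",
    shape = "character",
    petiole_fraction = "numeric"
  )
)

setValidity("LeafSpec", function(object) {
  msg <- character()
  if (length(object@length) != 1 || !is.finite(object@length) || object@length <= 0)
    msg <- c(msg, "length must be a single positive number")
  if (length(object@width) != 1 || !is.finite(object@width) || object@width <= 0)
    msg <- c(msg, "width must be a single positive number")
  if (length(object@width) == 1 && length(object@length) == 1 &&
      is.finite(object@width) && is.finite(object@length) &&
      object@width >= 2 * object@length)
    msg <- c(msg, "width must be smaller than twice the length")
  if (!object@shape %in% c("ellipse", "teardrop"))
    msg <- c(msg, "shape must be 'ellipse' or 'teardrop'")
  if (object@petiole_fraction < 0 || object@petiole_fraction >= 1)
    msg <- c(msg, "petiole_fraction must be in [0, 1)")
  if (length(msg)) msg else TRUE
})

#' Synthetic rosette specification
#'
#' Full description of a synthetic top-view rosette image: plant center,
#' leaves, raster geometry and intensity model. Rendering is deterministic
#' given `seed`. Coordinates are 0-based `(row, col)` with pixel centers at
#' integer positions.
#'
#' @slot center numeric(2), plant center as (row, col) in pixels; must lie
#'   inside the image.
#' @slot leaves list of [LeafSpec-class] objects (at least one).
#' @slot image_size integer(2), (height, width) in pixels.
#' @slot background_level,foreground_level numeric(1), intensity of
#'   background and plant pixels before noise.
#' @slot noise_sd numeric(1) >= 0, standard deviation of additive Gaussian
#'   intensity noise (clipped to \[0, max_intensity\]).
#' @slot max_intensity numeric(1), top of the intensity range (default 4095,
#'   a 12-bit sensor).
#' @slot seed integer(1), RNG seed used when rendering.
#' @seealso [RosetteSpec()], [renderRosette()], [growSeries()]
#' @exportClass RosetteSpec
setClass("RosetteSpec",
  representation(
    center = "numeric",
    leaves = "list",
    image_size = "integer",
    background_level = "numeric",
    foreground_level = "numeric",
    noise_sd = "numeric",
    max_intensity = "numeric",
    seed = "integer"
  )
)

setValidity("RosetteSpec", function(object) {
  msg <- character()
  if (length(object@center) != 2 || any(!is.finite(object@center)))
    msg <- c(msg, "center must be a finite (row, col) pair")
  if (length(object@image_size) != 2 || any(object@image_size < 16))
    msg <- c(msg, "image_size must be (height, width), each >= 16")
  else if (length(object@center) == 2 &&
           (any(object@center < 0) ||
            object@center[1] > object@image_size[1] - 1 ||
            object@center[2] > object@image_size[2] - 1))
    msg <- c(msg, "center must lie inside the image bounds")
  if (length(object@leaves) < 1)
    msg <- c(msg, "at least one leaf is required")
  if (!all(vapply(object@leaves, is, logical(1), class2 = "LeafSpec")))
    msg <- c(msg, "leaves must all be LeafSpec objects")
  if (object@noise_sd < 0)
    msg <- c(msg, "noise_sd must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Exact ground truth for a synthetic rosette
#'
#' Geometry-derived truth accompanying a rendered rosette: the generating
#' center, the tip coordinates, exact per-leaf polygon areas, the exact area
#' of the union of the leaf polygons (computed by polygon clipping, not by
#' pixel counting) and the overlap fraction
#' `(sum of leaf areas - union area) / sum of leaf areas`.
#'
#' @slot center numeric(2), (row, col).
#' @slot tip_points matrix with one (row, col) row per leaf.
#' @slot per_leaf_areas numeric, exact polygon area of each leaf in px^2.
#' @slot union_area numeric(1), exact area of the union of all leaves.
#' @slot overlap_fraction numeric(1) in \[0, 1).
#' @exportClass GroundTruth
setClass("GroundTruth",
  representation(
    center = "numeric",
    tip_points = "matrix",
    per_leaf_areas = "numeric",
    union_area = "numeric",
    overlap_fraction = "numeric"
  )
)

setValidity("GroundTruth", function(object) {
  msg <- character()
  tot <- sum(object@per_leaf_areas)
  if (object@union_area > tot * (1 + 1e-8))
    msg <- c(msg, "union_area cannot exceed the sum of per-leaf areas")
  if (object@overlap_fraction < 0 || object@overlap_fraction >= 1)
    msg <- c(msg, "overlap_fraction must be in [0, 1)")
  if (length(msg)) msg else TRUE
})

#' Binary plant/background mask
#'
#' Boolean raster marking plant pixels in a top-view image, produced by
#' [buildForegroundMask()]. The number of `TRUE` pixels is the observed
#' top-view plant area `a_t`.
#'
#' @slot mask logical matrix, same shape as the source image.
#' @slot observed_area numeric(1), number of `TRUE` pixels (`a_t`).
#' @seealso [buildForegroundMask()], [observedArea()]
#' @exportClass ForegroundMask
setClass("ForegroundMask",
  representation(mask = "matrix", observed_area = "numeric")
)

setValidity("ForegroundMask", function(object) {
  if (!is.logical(object@mask)) return("mask must be a logical matrix")
  if (object@observed_area != sum(object@mask))
    return("observed_area must equal the number of TRUE pixels")
  TRUE
})

#' Connected leaf region used for center finding
#'
#' A connected component of the foreground mask that passed the simple-leaf
#' screen (single closed hole-free contour, high solidity, plausible size).
#'
#' @slot pixels matrix of (row, col) pixel coordinates (0-based).
#' @slot boundary matrix of (row, col) boundary coordinates, a closed contour.
#' @slot solidity numeric(1) in (0, 1\], pixel area / convex hull area.
#' @exportClass LeafRegion
setClass("LeafRegion",
  representation(pixels = "matrix", boundary = "matrix", solidity = "numeric")
)

#' Leaf orientation line
#'
#' The longest chord across a leaf region: the pair of boundary points at
#' maximal Euclidean distance. The implied infinite line is used for plant
#' center estimation.
#'
#' @slot p1,p2 numeric(2), the two (row, col) endpoints (distinct).
#' @exportClass OrientationLine
setClass("OrientationLine",
  representation(p1 = "numeric", p2 = "numeric")
)

setValidity("OrientationLine", function(object) {
  if (sqrt(sum((object@p1 - object@p2)^2)) <= .Machine$double.eps * 64)
    return("endpoints must be distinct")
  TRUE
})

#' Estimated plant center
#'
#' @slot point numeric(2), (row, col) in pixels.
#' @slot method character(1), `"orientation_lines"` or `"center_of_mass"`.
#' @slot n_leaves_used integer(1), number of simple leaves behind the
#'   estimate (0 for center of mass).
#' @seealso [findPlantCenter()], [estimateCenter()], [centerOfMass()]
#' @exportClass PlantCenter
setClass("PlantCenter",
  representation(point = "numeric", method = "character",
                 n_leaves_used = "integer")
)

setValidity("PlantCenter", function(object) {
  if (length(object@point) != 2 || any(!is.finite(object@point)))
    return("point must be a finite (row, col) pair")
  if (!object@method %in% c("orientation_lines", "center_of_mass"))
    return("method must be 'orientation_lines' or 'center_of_mass'")
  TRUE
})

#' Polar radius profile of the plant outline
#'
#' For each angular bin about the plant center, the distance from the center
#' to the outermost foreground boundary pixel falling in that bin. Bins with
#' no boundary pixel are filled by circular linear interpolation and flagged.
#'
#' @slot radii numeric vector of length `360 / bin_width`.
#' @slot bin_width numeric(1), angular bin width in degrees.
#' @slot center numeric(2), the (row, col) center used.
#' @slot interpolated logical vector flagging interpolated bins.
#' @seealso [polarProfile()], [smoothProfile()], [detectTips()]
#' @exportClass PolarProfile
setClass("PolarProfile",
  representation(radii = "numeric", bin_width = "numeric",
                 center = "numeric", interpolated = "logical")
)

setValidity("PolarProfile", function(object) {
  msg <- character()
  if (any(object@radii < 0)) msg <- c(msg, "radii must be >= 0")
  if (length(object@radii) != round(360 / object@bin_width))
    msg <- c(msg, "length(radii) must equal 360 / bin_width")
  if (length(msg)) msg else TRUE
})

#' Smoothed polar radius profile
#'
#' Circular moving average of a [PolarProfile-class] over an odd window of
#' `k` bins. Local maxima of the smoothed profile mark candidate leaf tips.
#'
#' @slot radii numeric vector aligned with the source profile.
#' @slot k integer(1), odd window size in bins.
#' @slot bin_width numeric(1), degrees per bin.
#' @exportClass SmoothedProfile
setClass("SmoothedProfile",
  representation(radii = "numeric", k = "integer", bin_width = "numeric")
)

#' Piecewise leaf length-to-area model
#'
#' Maps a leaf length `r` (center-to-tip radius, px) and curvature ratio
#' `cr` to a leaf area: a linear law `slope * r + intercept` for round
#' leaves (`cr < cr_cutoff`) and an exponential law `scale * exp(rate * r)`
#' for elongated leaves (`cr >= cr_cutoff`). The shipped defaults were
#' calibrated on 87 wild-type Arabidopsis leaves at the original imaging
#' scale and are imaging-setup specific; see [fitLengthAreaModel()] to
#' recalibrate.
#'
#' @slot linear_slope,linear_intercept numeric(1), linear branch (px^2/px,
#'   px^2).
#' @slot exp_scale,exp_rate numeric(1), exponential branch (px^2, 1/px).
#' @slot cr_cutoff numeric(1) in (0, 1), curvature-ratio split point.
#' @slot r2_linear,r2_exp numeric(1), coefficient of determination of each
#'   branch on its training leaves (NA if unknown).
#' @slot ci numeric matrix (4 x 2) of 95% confidence bounds for
#'   (linear_slope, linear_intercept, exp_scale, exp_rate).
#' @seealso [defaultLengthAreaModel()], [leafAreaFromTip()],
#'   [fitLengthAreaModel()], [fitCutoff()]
#' @exportClass LengthAreaModel
setClass("LengthAreaModel",
  representation(
    linear_slope = "numeric", linear_intercept = "numeric",
    exp_scale = "numeric", exp_rate = "numeric",
    cr_cutoff = "numeric",
    r2_linear = "numeric", r2_exp = "numeric",
    ci = "matrix"
  )
)

setValidity("LengthAreaModel", function(object) {
  msg <- character()
  if (object@cr_cutoff <= 0 || object@cr_cutoff >= 1)
    msg <- c(msg, "cr_cutoff must be in (0, 1)")
  if (object@exp_scale <= 0)
    msg <- c(msg, "exp_scale must be positive")
  if (length(msg)) msg else TRUE
})

#' Overlap-corrected plant area for one frame
#'
#' Combines the summed per-leaf model areas `a_l` with the observed top-view
#' area `a_t` into the corrected plant area
#' `a = a_l * (1 + p_overlap)`, where
#' `p_overlap = |a_t - a_l| / max(a_t, a_l)` is the leaf overlap percentage.
#'
#' @slot time numeric(1), frame time (NA if unknown).
#' @slot a_l numeric(1), sum of per-leaf model areas (px^2).
#' @slot a_t numeric(1), observed top-view area (px^2).
#' @slot p_overlap numeric(1) in \[0, 1\].
#' @slot a numeric(1), corrected plant area (px^2).
#' @slot m integer(1), number of detected leaf tips.
#' @seealso [plantArea()]
#' @exportClass PlantAreaRecord
setClass("PlantAreaRecord",
  representation(time = "numeric", a_l = "numeric", a_t = "numeric",
                 p_overlap = "numeric", a = "numeric", m = "integer")
)

setValidity("PlantAreaRecord", function(object) {
  msg <- character()
  if (object@p_overlap < 0 || object@p_overlap > 1)
    msg <- c(msg, "p_overlap must be in [0, 1]")
  if (object@a < 0) msg <- c(msg, "corrected area must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Three-parameter logistic growth fit
#'
#' Result of fitting `A(t) = A0 * Aa / (A0 + (Aa - A0) * exp(-gamma * t))`
#' to a plant area series by nonlinear least squares: the rate `gamma`
#' (1/time), initial area `A0` and upper asymptote `Aa` (px^2), with
#' first-order (Jacobian-based) 95% confidence intervals.
#'
#' @slot gamma,A0,Aa numeric(1), parameter estimates.
#' @slot ci numeric matrix (3 x 2), rows gamma/A0/Aa, columns lower/upper
#'   95% bounds.
#' @slot residual_sd numeric(1), residual standard deviation.
#' @slot n_obs integer(1), number of observations fitted.
#' @slot converged logical(1).
#' @slot decreasing logical(1), flag set when the observed series trends
#'   downward (the model assumes growth).
#' @seealso [fit3plm()], [logistic3()], [phasePlaneFeatures()]
#' @exportClass ThreePLFit
setClass("ThreePLFit",
  representation(
    gamma = "numeric", A0 = "numeric", Aa = "numeric",
    ci = "matrix", residual_sd = "numeric", n_obs = "integer",
    converged = "logical", decreasing = "logical"
  )
)

setValidity("ThreePLFit", function(object) {
  msg <- character()
  if (object@gamma <= 0) msg <- c(msg, "gamma must be positive")
  if (!(object@A0 > 0 && object@A0 < object@Aa))
    msg <- c(msg, "parameters must satisfy 0 < A0 < Aa")
  if (!all(dim(object@ci) == c(3, 2)))
    msg <- c(msg, "ci must be a 3 x 2 matrix")
  if (length(msg)) msg else TRUE
})

#' Absolute and relative growth rates
#'
#' Finite-difference growth rates over a step `dt`:
#' `AGR(t) = (A(t) - A(t - dt)) / dt` and
#' `RGR(t) = (ln A(t) - ln A(t - dt)) / dt`.
#'
#' @slot times numeric, evaluation times.
#' @slot agr numeric, absolute growth rate (px^2 / time).
#' @slot rgr numeric, relative growth rate (1 / time); NA where the area is
#'   not positive.
#' @slot dt numeric(1), the finite-difference step.
#' @seealso [growthRates()]
#' @exportClass GrowthRates
setClass("GrowthRates",
  representation(times = "numeric", agr = "numeric", rgr = "numeric",
                 dt = "numeric")
)

#' Phase-plane features of a growth curve
#'
#' Landmarks of the acceleration-versus-velocity trajectory of a growth
#' curve: point b (maximal acceleration), point c (maximal velocity, zero
#' acceleration), point d (most negative acceleration), and the area
#' enclosed by the loop, `|loop integral of acceleration d(velocity)|`,
#' an energy-transfer proxy. Each point is stored as
#' (velocity, acceleration, time).
#'
#' @slot point_b,point_c,point_d named numeric(3):
#'   velocity, acceleration, time.
#' @slot loop_area numeric(1), enclosed phase-plane area
#'   ((px^2)^2 / time^3).
#' @slot degenerate logical(1), TRUE when the curve is flat and features are
#'   undefined (all values NA).
#' @seealso [phasePlaneFeatures()], [curveDerivatives()]
#' @exportClass PhasePlaneFeatures
setClass("PhasePlaneFeatures",
  representation(point_b = "numeric", point_c = "numeric",
                 point_d = "numeric", loop_area = "numeric",
                 degenerate = "logical")
)
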