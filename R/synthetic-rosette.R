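#' Create a leaf specification
#'
#' Constructor for [LeafSpec-class]. Lengths are center-to-tip distances in
#' pixels, petiole included: the leaf length convention is the distance from
#' the base of the petiole (assumed at the plant center) to the outermost
#' point of the blade.
#'
#' @param angle direction of the leaf axis in degrees, \[0, 360).
#' @param length center-to-tip distance in pixels (> 0).
#' @param width maximal blade width in pixels (0 < width < 2 * length).
#' @param shape `"ellipse"` (round leaf) or `"teardrop"` (elongated leaf,
#'   two circular arcs).
#' @param petiole_fraction fraction of the length occupied by the petiole
#'   before the blade starts, in \[0, 1).
#' @return a [LeafSpec-class] object.
#' @examples
#' LeafSpec(angle = 45, length = 60, width = 24)
#' @export
LeafSpec <- function(angle, length, width, shape = c("ellipse", "teardrop"),
                     petiole_fraction = 0.2) {
  shape <- match.arg(shape)
  new("LeafSpec", angle = as.numeric(angle %% 360), length = as.numeric(length),
      width = as.numeric(width), shape = shape,
      petiole_fraction = as.numeric(petiole_fraction))
}

#' Create a synthetic rosette specification
#'
#' Constructor for [RosetteSpec-class]. Intensity defaults emulate a 12-bit
#' fluorescence frame: dim background, bright plant, additive Gaussian noise
#' with a standard deviation of 2% of the dynamic range.
#'
#' @param center plant center as (row, col), 0-based pixels. Default: image
#'   center.
#' @param leaves list of [LeafSpec-class] objects.
#' @param image_size (height, width) in pixels.
#' @param background_level,foreground_level background and plant intensity.
#' @param noise_sd standard deviation of additive Gaussian noise;
#'   default 2% of `max_intensity`.
#' @param max_intensity top of the intensity range (default 4095, 12-bit).
#' @param seed integer RNG seed used by [renderRosette()].
#' @return a [RosetteSpec-class] object.
#' @examples
#' sp <- RosetteSpec(leaves = list(LeafSpec(0, 50, 20), LeafSpec(120, 40, 18)))
#' sp
#' @export
RosetteSpec <- function(leaves, center = NULL, image_size = c(256L, 256L),
                        background_level = 100, foreground_level = 3000,
                        noise_sd = 0.02 * max_intensity, max_intensity = 4095,
                        seed = 1L) {
  image_size <- as.integer(image_size)
  if (is.null(center)) center <- (image_size - 1) / 2
  new("RosetteSpec", center = as.numeric(center), leaves = leaves,
      image_size = image_size, background_level = background_level,
      foreground_level = foreground_level, noise_sd = noise_sd,
      max_intensity = max_intensity, seed = as.integer(seed))
}

#' Evenly spaced rosette of identical leaves
#'
#' Convenience constructor: `n_leaves` identical leaves radiating from the
#' center at evenly spaced angles (a star rosette), the standard fixture for
#' tip-detection and center-finding tests.
#'
#' @param n_leaves number of leaves (1-12 is the intended range).
#' @param length,width,shape,petiole_fraction passed to [LeafSpec()].
#' @param angle0 angle of the first leaf in degrees.
#' @param ... further arguments passed to [RosetteSpec()].
#' @return a [RosetteSpec-class] object.
#' @examples
#' starRosette(5, length = 80, width = 30, image_size = c(256, 256))
#' @export
starRosette <- function(n_leaves, length, width, shape = "ellipse",
                        petiole_fraction = 0.2, angle0 = 0, ...) {
  angles <- (angle0 + 360 * (seq_len(n_leaves) - 1) / n_leaves) %% 360
  leaves <- lapply(angles, LeafSpec, length = length, width = width,
                   shape = shape, petiole_fraction = petiole_fraction)
  RosetteSpec(leaves = leaves, ...)
}

.leafPolygons <- function(spec) {
  lapply(spec@leaves, .leafPolygon, center = spec@center)
}

.groundTruthFromPolys <- function(spec, polys) {
  areas <- vapply(polys, .polyArea, numeric(1))
  union_area <- if (length(polys) == 1) areas else .unionAreaConvex(polys)
  tot <- sum(areas)
  ov <- max(0, (tot - union_area) / tot)
  tips <- t(vapply(spec@leaves, .leafTipPoint, numeric(2), center = spec@center))
  colnames(tips) <- c("row", "col")
  new("GroundTruth", center = spec@center, tip_points = tips,
      per_leaf_areas = areas, union_area = union_area, overlap_fraction = ov)
}

#' Render a synthetic rosette image with exact ground truth
#'
#' Rasterizes the leaf polygons of a [RosetteSpec-class] at
#' `foreground_level`, adds Gaussian noise (clipped to the intensity range)
#' and returns the image together with a [GroundTruth-class] object whose
#' areas come from exact polygon geometry (convex clipping for the union),
#' not from pixel counting. Rasterization uses the pixel-center-in-polygon
#' rule on 0-based (row, col) coordinates with pixel centers at integers.
#' Rendering is deterministic given `spec@seed`.
#'
#' @param spec a [RosetteSpec-class].
#' @return a list with elements `image` (numeric matrix, height x width) and
#'   `truth` ([GroundTruth-class]).
#' @examples
#' out <- renderRosette(starRosette(4, 60, 24, image_size = c(192, 192)))
#' out$truth
#' @export
renderRosette <- function(spec) {
  validObject(spec)
  polys <- .leafPolygons(spec)
  h <- spec@image_size[1]; w <- spec@image_size[2]
  for (i in seq_along(polys)) {
    p <- polys[[i]]
    if (min(p[, 1]) < 0 || max(p[, 1]) > w - 1 ||
        min(p[, 2]) < 0 || max(p[, 2]) > h - 1)
      stop(sprintf("leaf %d (angle %.1f deg) extends outside the image", i,
                   spec@leaves[[i]]@angle))
  }
  mask <- matrix(FALSE, h, w)
  for (p in polys) mask <- mask | .rasterizeConvex(p, spec@image_size)
  img <- matrix(spec@background_level, h, w)
  img[mask] <- spec@foreground_level
  if (spec@noise_sd > 0) {
    img <- img + withr::with_seed(spec@seed,
                                  matrix(stats::rnorm(h * w, 0, spec@noise_sd), h, w))
  }
  img <- pmin(pmax(img, 0), spec@max_intensity)
  list(image = img, truth = .groundTruthFromPolys(spec, polys))
}

# invert the length-to-area law for one leaf shape; teardrops use the
# exponential branch where it is invertible (area > exp_scale), otherwise
# the (always invertible) linear branch
.lengthForArea <- function(area, shape, model) {
  if (shape == "teardrop" && area > model@exp_scale * exp(model@exp_rate)) {
    log(area / model@exp_scale) / model@exp_rate
  } else {
    (area - model@linear_intercept) / model@linear_slope
  }
}

.widthForArea <- function(leaf, center, target) {
  f <- function(w) {
    l2 <- leaf; l2@width <- w
    .polyArea(.leafPolygon(l2, center)) - target
  }
  wmax <- 1.999 * leaf@length
  if (f(wmax) < 0)
    stop(sprintf("target leaf area %.1f px^2 is not achievable at length %.1f px",
                 target, leaf@length))
  stats::uniroot(f, c(1e-6, wmax), tol = 1e-10)$root
}

#' Generate a growth series of rosette images with ground truth
#'
#' Evolves each leaf of a starting rosette through time so that its exact
#' polygon area follows the three-parameter logistic law
#' `A(t) = A0 * Aa / (A0 + (Aa - A0) * exp(-gamma * t))`. At each time the
#' leaf length is set by inverting the leaf length-to-area model (linear
#' branch for ellipse leaves, exponential branch for teardrops where
#' invertible) and the width is then solved numerically so the polygon area
#' matches the logistic value exactly, keeping the length-area relation and
#' an exact area oracle simultaneously.
#'
#' @param spec0 a [RosetteSpec-class] providing leaf angles, shapes, image
#'   geometry and intensity model.
#' @param growth either a single named vector `c(gamma=, A0=, Aa=)` applied
#'   to every leaf, or a list of such vectors, one per leaf. Units: `A0`,
#'   `Aa` in px^2 (per leaf), `gamma` in 1/time.
#' @param times strictly increasing vector of frame times.
#' @param model [LengthAreaModel-class] used for the length inversion.
#' @return a list with one element per time point, each a list
#'   `(time, image, truth)` as in [renderRosette()].
#' @examples
#' sp <- starRosette(3, 40, 16, image_size = c(220, 220))
#' ser <- growSeries(sp, c(gamma = 0.1, A0 = 120, Aa = 900), times = c(0, 10, 20))
#' sapply(ser, function(f) f$truth@union_area)
#' @export
growSeries <- function(spec0, growth, times, model = defaultLengthAreaModel()) {
  validObject(spec0)
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  nl <- length(spec0@leaves)
  if (!is.list(growth)) growth <- rep(list(growth), nl)
  if (length(growth) != nl)
    stop("growth must give one (gamma, A0, Aa) set per leaf")
  lapply(seq_along(times), function(fi) {
    t <- times[fi]
    leaves <- lapply(seq_len(nl), function(i) {
      g <- growth[[i]]
      target <- logistic3(t, A0 = g[["A0"]], Aa = g[["Aa"]], gamma = g[["gamma"]])
      lf <- spec0@leaves[[i]]
      lf@length <- .lengthForArea(target, lf@shape, model)
      lf@width <- .widthForArea(lf, spec0@center, target)
      validObject(lf)
      lf
    })
    sp <- spec0
    sp@leaves <- leaves
    sp@seed <- spec0@seed + as.integer(fi)
    out <- renderRosette(sp)
    list(time = t, image = out$image, truth = out$truth)
  })
}
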