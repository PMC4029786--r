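#' Build the binary plant/background mask
#'
#' Segments the plant from the background of a top-view grayscale image:
#' Sobel gradient magnitude, thresholding (Otsu on the gradient by default
#' -- a fixed global intensity threshold is deliberately avoided, since
#' fluorescence intensity drifts over time), morphological dilation of the
#' edge map with a disk, and a 4-connected flood fill from the four image
#' corners that labels the connected non-edge region as background.
#' Everything not reached from a corner is plant, so holes inside the plant
#' are foreground. A final erosion (default `dilation_radius + 1`, the
#' dilation plus the Sobel half-band) compensates the outward bias the
#' dilated edge band would otherwise add to the plant outline.
#'
#' @param image numeric matrix of intensities (at least 16 x 16, finite).
#' @param edge_threshold relative gradient cutoff in (0, 1\], as a fraction
#'   of the maximal gradient magnitude; `NULL` (default) uses Otsu's
#'   threshold on the gradient magnitude.
#' @param dilation_radius disk radius in pixels for edge dilation
#'   (default 2).
#' @param erosion_radius disk radius of the compensating final erosion;
#'   `NULL` (default) uses `dilation_radius + 1`. Set to 0 to disable.
#' @return a [ForegroundMask-class]; `observedArea()` gives the top-view
#'   area `a_t`.
#' @details If the plant touches an image corner (gradient above threshold
#'   at the corner) a warning is issued and only the remaining corners seed
#'   the flood fill; if all four corners are covered the image cannot be
#'   segmented and an error is raised.
#' @examples
#' out <- renderRosette(starRosette(4, 60, 24, image_size = c(192, 192)))
#' fm <- buildForegroundMask(out$image)
#' observedArea(fm)
#' @export
buildForegroundMask <- function(image, edge_threshold = NULL,
                                dilation_radius = 2, erosion_radius = NULL) {
  if (!is.matrix(image) || nrow(image) < 16 || ncol(image) < 16)
    stop("image must be a matrix of at least 16 x 16 pixels")
  if (any(!is.finite(image))) stop("image intensities must be finite")
  if (is.null(erosion_radius)) erosion_radius <- dilation_radius + 1
  h <- nrow(image); w <- ncol(image)

  kx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)
  gx <- EBImage::filter2(image, kx, boundary = "replicate")
  gy <- EBImage::filter2(image, t(kx), boundary = "replicate")
  grad <- sqrt(gx^2 + gy^2)
  gmax <- max(grad)

  empty <- function() new("ForegroundMask", mask = matrix(FALSE, h, w),
                          observed_area = 0)
  # constant image: all background (tolerance absorbs FFT round-off)
  if (gmax <= 1e-8 * max(abs(image), 1)) return(empty())

  thr <- if (is.null(edge_threshold)) {
    gmax * as.numeric(EBImage::otsu(EBImage::Image(grad / gmax)))
  } else {
    gmax * edge_threshold
  }
  edge <- grad > thr
  if (!any(edge)) return(empty())

  if (dilation_radius > 0) {
    brush <- EBImage::makeBrush(2L * as.integer(dilation_radius) + 1L, "disc")
    edge <- EBImage::dilate(edge, brush) > 0
  }

  corners <- rbind(c(1L, 1L), c(1L, w), c(h, 1L), c(h, w))
  usable <- !edge[corners]
  if (!any(usable))
    stop("plant covers all four image corners; cannot seed the background fill")
  if (!all(usable)) {
    # background is by definition the corner-connected non-edge region, so
    # every edge-free corner (the darkest included) stays a seed
    warning(sprintf("%d image corner(s) lie on the plant edge; seeding the background fill from the remaining corner(s)",
                    sum(!usable)))
  }
  fillmap <- matrix(0, h, w)
  fillmap[edge] <- 1
  for (ci in which(usable)) {
    pt <- corners[ci, ]
    if (fillmap[pt[1], pt[2]] == 0)
      fillmap <- EBImage::floodFill(fillmap, c(pt[1], pt[2]), col = 2)
  }
  mask <- fillmap != 2

  if (erosion_radius > 0) {
    brush <- EBImage::makeBrush(2L * as.integer(erosion_radius) + 1L, "disc")
    mask <- EBImage::erode(mask, brush) > 0
  }
  mask <- matrix(as.logical(mask), h, w)
  new("ForegroundMask", mask = mask, observed_area = sum(mask))
}
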