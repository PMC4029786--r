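# Plant center identification: segment a few simple (non-overlapping)
# leaves, draw each leaf's orientation line (its longest chord), and place
# the center at the point closest to all lines; center of mass is the
# baseline and fallback.

.regionHullPixels <- function(pts) {
  # estimated pixel count of the filled convex hull of lattice points
  # (Pick: lattice area = interior + boundary/2 - 1, so pixel count of the
  # filled hull is about polygon area + perimeter/2 + 1)
  hi <- grDevices::chull(pts[, 2], pts[, 1])
  hull <- pts[hi, , drop = FALSE]
  n <- nrow(hull)
  if (n < 3) return(list(hull = hull, npix = nrow(pts)))
  per <- sum(sqrt(rowSums((hull - hull[c(2:n, 1), , drop = FALSE])^2)))
  a <- .polyArea(cbind(hull[, 2], hull[, 1]))
  list(hull = hull, npix = a + per / 2 + 1)
}

#' Detect simple (non-overlapping) leaves in a foreground mask
#'
#' Finds the connected foreground regions that look like single isolated
#' leaves and can therefore anchor orientation lines for center finding.
#' Rosette leaves fall into simple leaves (isolated, one closed hole-free
#' outline, high solidity) and leaf complexes (fused or overlapping leaves,
#' which produce lobed low-solidity regions); only the former are returned,
#' complexes are excluded wholesale rather than segmented. Regions are
#' 8-connected; screening is geometric: a region passes if it is hole-free
#' with a single closed boundary, has solidity at least `s_min` and area in
#' `[A_min, A_max]`.
#'
#' @param image numeric matrix (the source image; the mask drives the
#'   geometry, the image is smoothed with a Gaussian of sd `sigma` before
#'   gradient-based sanity checks).
#' @param mask a [ForegroundMask-class].
#' @param sigma Gaussian smoothing sd in pixels (default 2).
#' @param s_min minimal solidity (region area / convex hull area),
#'   default 0.85.
#' @param A_min minimal region area in px^2 (default 100).
#' @param A_max maximal region area; `NULL` (default) means half the total
#'   foreground area.
#' @return a list of [LeafRegion-class] objects, sorted by decreasing area.
#'   If fewer than 2 simple leaves are found the list is empty and carries
#'   `attr(, "insufficient") = TRUE`; callers fall back to
#'   [centerOfMass()].
#' @seealso [findPlantCenter()]
#' @export
detectSimpleLeaves <- function(image, mask, sigma = 2, s_min = 0.85,
                               A_min = 100, A_max = NULL) {
  m <- maskMatrix(mask)
  insufficient <- function() structure(list(), insufficient = TRUE)
  if (!any(m)) return(insufficient())
  if (is.null(A_max)) A_max <- observedArea(mask) / 2
  lbl <- .label8(m)
  nreg <- max(lbl)
  regions <- list()
  for (i in seq_len(nreg)) {
    rm_ <- lbl == i
    npix <- sum(rm_)
    if (npix < A_min || npix > A_max) next
    # hole-free single closed contour: filling the hull of holes changes
    # nothing on a simple leaf
    filled <- EBImage::fillHull(rm_) > 0
    if (sum(filled) != npix) next
    pts <- which(rm_, arr.ind = TRUE) - 1L   # 0-based (row, col)
    hp <- .regionHullPixels(pts)
    solidity <- min(1, npix / hp$npix)
    if (solidity < s_min) next
    bnd <- .boundaryPixels(rm_)
    regions[[length(regions) + 1]] <-
      new("LeafRegion", pixels = pts, boundary = bnd, solidity = solidity)
  }
  if (length(regions) < 2) return(insufficient())
  ord <- order(vapply(regions, function(r) nrow(r@pixels), numeric(1)),
               decreasing = TRUE)
  structure(regions[ord], insufficient = FALSE)
}

# 8-connected labeling of a logical matrix via bwlabel on a bridged image:
# EBImage::bwlabel is 4-connected, so diagonal adjacencies are bridged by
# dilation with a 3x3 box, labeled, and labels restricted to the original.
.label8 <- function(m) {
  lbl <- EBImage::bwlabel(m)
  if (max(lbl) <= 1) return(matrix(as.integer(lbl), nrow(m), ncol(m)))
  fat <- EBImage::dilate(m, matrix(1, 3, 3)) > 0
  lblf <- EBImage::bwlabel(fat)
  out <- matrix(0L, nrow(m), ncol(m))
  out[m] <- as.integer(lblf[m])
  u <- sort(unique(out[out > 0]))
  ren <- integer(max(u)); ren[u] <- seq_along(u)
  out[out > 0] <- ren[out[out > 0]]
  out
}

# boundary pixels (0-based row, col) of a logical region: foreground pixels
# with at least one 4-neighbor outside the region
.boundaryPixels <- function(m) {
  h <- nrow(m); w <- ncol(m)
  pad <- matrix(FALSE, h + 2, w + 2)
  pad[2:(h + 1), 2:(w + 1)] <- m
  core <- pad[2:(h + 1), 2:(w + 1)] &
    pad[1:h, 2:(w + 1)] & pad[3:(h + 2), 2:(w + 1)] &
    pad[2:(h + 1), 1:w] & pad[2:(h + 1), 3:(w + 2)]
  which(m & !core, arr.ind = TRUE) - 1L
}

#' Leaf orientation line: the longest chord across a leaf
#'
#' Finds the pair of boundary points of a leaf region at maximal Euclidean
#' distance. Ties are broken by the smallest (row, col) lexicographic order
#' of the first endpoint, then of the second, making the result
#' deterministic (a perfect circle returns a fixed diameter).
#'
#' @param region a [LeafRegion-class] (at least 3 boundary points).
#' @return an [OrientationLine-class].
#' @seealso [estimateCenter()]
#' @export
orientationLine <- function(region) {
  b <- region@boundary
  if (nrow(b) < 3) stop("region must have at least 3 boundary points")
  hi <- grDevices::chull(b[, 2], b[, 1])
  hull <- b[hi, , drop = FALSE]
  # deterministic order: sort hull points lexicographically by (row, col)
  ord <- order(hull[, 1], hull[, 2])
  hull <- hull[ord, , drop = FALSE]
  n <- nrow(hull)
  best <- -1; bi <- bj <- 1L
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d <- sum((hull[i, ] - hull[j, ])^2)
    if (d > best + 1e-12) { best <- d; bi <- i; bj <- j }
  }
  if (best <= 0) stop("degenerate region: no distinct boundary point pair")
  new("OrientationLine", p1 = as.numeric(hull[bi, ]),
      p2 = as.numeric(hull[bj, ]))
}

.lineNormalForm <- function(line) {
  u <- line@p2 - line@p1
  u <- u / sqrt(sum(u^2))
  n <- c(-u[2], u[1])
  list(n = n, d = sum(n * line@p1))
}

#' Estimate the plant center from leaf orientation lines
#'
#' The plant center is the point closest to all leaf orientation lines,
#' since every leaf radiates from the center. The default solves the
#' least-squares problem (minimizing the sum of squared perpendicular
#' distances to the infinite lines) in closed form via the normal
#' equations; `method = "l1"` minimizes the plain sum of distances by
#' iteratively reweighted least squares, which matters only when one line
#' is a gross outlier.
#'
#' @param lines list of at least 2 [OrientationLine-class] objects, not all
#'   parallel.
#' @param method `"l2"` (default, closed form) or `"l1"` (IRLS).
#' @return a [PlantCenter-class] with `method = "orientation_lines"`.
#' @examples
#' l1 <- new("OrientationLine", p1 = c(0, 50), p2 = c(100, 50))
#' l2 <- new("OrientationLine", p1 = c(50, 0), p2 = c(50, 100))
#' centerPoint(estimateCenter(list(l1, l2)))  # (50, 50)
#' @export
estimateCenter <- function(lines, method = c("l2", "l1")) {
  method <- match.arg(method)
  if (length(lines) < 2) stop("at least 2 orientation lines are required")
  nf <- lapply(lines, .lineNormalForm)
  N <- t(vapply(nf, `[[`, numeric(2), "n"))
  d <- vapply(nf, `[[`, numeric(1), "d")
  solveW <- function(wt) {
    A <- crossprod(N * sqrt(wt))
    if (abs(det(A)) < 1e-9 * sum(diag(A))^2 / 4)
      stop("all orientation lines are (near) parallel; center is undetermined")
    as.numeric(solve(A, crossprod(N * wt, d)))
  }
  c0 <- solveW(rep(1, length(d)))
  if (method == "l1") {
    for (it in seq_len(100)) {
      r <- abs(as.numeric(N %*% c0) - d)
      w <- 1 / pmax(r, 1e-6)
      c1 <- solveW(w)
      if (sum(abs(c1 - c0)) < 1e-10) { c0 <- c1; break }
      c0 <- c1
    }
  }
  new("PlantCenter", point = c0, method = "orientation_lines",
      n_leaves_used = length(lines))
}

#' Center of mass of the foreground mask
#'
#' Baseline plant-center estimate: the arithmetic mean of the foreground
#' pixel coordinates. Used as fallback when fewer than two simple leaves
#' are available for [estimateCenter()].
#'
#' @param mask a non-empty [ForegroundMask-class].
#' @return a [PlantCenter-class] with `method = "center_of_mass"`.
#' @export
centerOfMass <- function(mask) {
  m <- maskMatrix(mask)
  if (!any(m)) stop("mask is empty; no center of mass")
  pts <- which(m, arr.ind = TRUE) - 1L
  new("PlantCenter", point = unname(colMeans(pts)), method = "center_of_mass",
      n_leaves_used = 0L)
}

# longest chord / minimal hull width; round leaves (ratio < round_min) give
# unstable orientation lines and are skipped
.elongationRatio <- function(region) {
  b <- region@boundary
  hi <- grDevices::chull(b[, 2], b[, 1])
  hull <- b[hi, , drop = FALSE]
  n <- nrow(hull)
  if (n < 3) return(Inf)
  maxchord <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    maxchord <- max(maxchord, sum((hull[i, ] - hull[j, ])^2))
  maxchord <- sqrt(maxchord)
  minw <- Inf
  for (e in seq_len(n)) {
    a <- hull[e, ]; bb <- hull[if (e == n) 1 else e + 1, ]
    u <- bb - a
    len <- sqrt(sum(u^2))
    if (len < 1e-9) next
    nn <- c(-u[2], u[1]) / len
    minw <- min(minw, max(abs(as.numeric((hull - rep(a, each = n)) %*% nn))))
  }
  maxchord / max(minw, 1e-9)
}

#' Find the plant center of a top-view image
#'
#' Full center-identification step: detect simple leaves, draw their
#' orientation lines (skipping round leaves, whose longest chord is an
#' unstable axis), and solve for the point closest to all lines. Falls back
#' to the center of mass when fewer than two usable leaves are found or the
#' lines are degenerate. In a growth experiment the center does not move,
#' so it is typically computed once per plant and reused across frames.
#'
#' @inheritParams detectSimpleLeaves
#' @param round_min minimal elongation (longest chord / minimal width) for
#'   a leaf to contribute an orientation line (default 1.2).
#' @param method passed to [estimateCenter()].
#' @return a [PlantCenter-class].
#' @examples
#' out <- renderRosette(starRosette(4, 70, 24, image_size = c(224, 224)))
#' fm <- buildForegroundMask(out$image)
#' findPlantCenter(out$image, fm)
#' @export
findPlantCenter <- function(image, mask, sigma = 2, s_min = 0.85,
                            A_min = 100, A_max = NULL, round_min = 1.2,
                            method = "l2") {
  regions <- detectSimpleLeaves(image, mask, sigma = sigma, s_min = s_min,
                                A_min = A_min, A_max = A_max)
  if (length(regions) >= 2) {
    keep <- vapply(regions, function(r) .elongationRatio(r) >= round_min,
                   logical(1))
    regions <- regions[keep]
  }
  if (length(regions) >= 2) {
    lines <- lapply(regions, orientationLine)
    ctr <- tryCatch(estimateCenter(lines, method = method),
                    error = function(e) NULL)
    if (!is.null(ctr)) return(ctr)
  }
  centerOfMass(mask)
}
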