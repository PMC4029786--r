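#' Polar radius profile of the plant outline
#'
#' Sweeps a ray from the plant center through 360 degrees and records, for
#' each angular bin, the distance to the outermost boundary pixel of the
#' foreground mask falling in that bin -- the shape of the plant outline in
#' polar coordinates, where each peak marks a leaf tip. Bins containing no
#' boundary pixel are filled by circular linear interpolation and flagged.
#' Angle 0 points along increasing column; angles increase
#' counter-clockwise with row 0 at the top.
#'
#' @param mask a non-empty [ForegroundMask-class].
#' @param center a [PlantCenter-class] (or numeric (row, col)); must lie
#'   inside the image.
#' @param bin_width angular bin width in degrees (default 1; must divide
#'   360).
#' @return a [PolarProfile-class].
#' @seealso [smoothProfile()], [detectTips()]
#' @export
polarProfile <- function(mask, center, bin_width = 1) {
  m <- maskMatrix(mask)
  if (!any(m)) stop("mask is empty; no outline to profile")
  ctr <- if (is(center, "PlantCenter")) centerPoint(center) else as.numeric(center)
  if (ctr[1] < 0 || ctr[1] > nrow(m) - 1 || ctr[2] < 0 || ctr[2] > ncol(m) - 1)
    stop("center lies outside the image")
  nb <- round(360 / bin_width)
  if (abs(nb * bin_width - 360) > 1e-9) stop("bin_width must divide 360")
  b <- .boundaryPixels(m)                      # 0-based (row, col)
  dx <- b[, 2] - ctr[2]
  dy <- ctr[1] - b[, 1]
  r <- sqrt(dx^2 + dy^2)
  phi <- (atan2(dy, dx) * 180 / pi) %% 360
  bin <- floor(phi / bin_width) %% nb + 1L
  radii <- rep(NA_real_, nb)
  agg <- tapply(r, bin, max)
  radii[as.integer(names(agg))] <- agg
  interp <- is.na(radii)
  if (any(interp)) {
    if (all(interp)) stop("no boundary pixels found")
    # circular linear interpolation across empty bins
    idx <- which(!interp)
    x <- c(idx - nb, idx, idx + nb)
    y <- rep(radii[idx], 3)
    radii[interp] <- stats::approx(x, y, xout = which(interp))$y
  }
  new("PolarProfile", radii = as.numeric(radii), bin_width = bin_width,
      center = ctr, interpolated = interp)
}

#' Smooth a polar profile by a circular moving average
#'
#' Replaces each bin's radius by the unweighted mean of the `k` bins
#' flanking it (the bin itself plus `(k-1)/2` neighbors on each side), with
#' wrap-around at 0/360 degrees. Smoothing merges the serrated raw outline
#' into one hump per leaf so that each leaf yields a single local maximum,
#' at the cost of underestimating the radius -- which is why tips are read
#' from the raw profile afterwards.
#'
#' @param profile a [PolarProfile-class].
#' @param k odd window size in bins, `1 <= k < length(radii)` (default 9).
#' @return a [SmoothedProfile-class].
#' @export
smoothProfile <- function(profile, k = 9L) {
  k <- as.integer(k)
  nb <- length(profile@radii)
  if (k %% 2L == 0L || k < 1L || k >= nb)
    stop("k must be an odd integer in [1, number of bins)")
  if (k == 1L)
    return(new("SmoothedProfile", radii = profile@radii, k = k,
               bin_width = profile@bin_width))
  half <- (k - 1L) %/% 2L
  ext <- c(utils::tail(profile@radii, half), profile@radii,
           utils::head(profile@radii, half))
  sm <- as.numeric(stats::filter(ext, rep(1 / k, k), sides = 2))
  sm <- sm[(half + 1L):(half + nb)]
  new("SmoothedProfile", radii = sm, k = k, bin_width = profile@bin_width)
}

# circular local maxima with plateau handling: collapse runs of equal
# values, call a run a maximum if both neighboring runs are lower, return
# the central index of the run (lower of the two central for even runs)
.circularMaxima <- function(x) {
  n <- length(x)
  if (n < 3 || diff(range(x)) == 0) return(integer(0))
  # run-length encode circularly: rotate so position 1 starts a run
  brk <- which(x != c(x[n], x[-n])) # indices where a new run starts
  if (length(brk) == 0) return(integer(0))
  starts <- brk
  nr <- length(starts)
  ends <- c(starts[-1] - 1L, starts[1] - 1L + n) # circular ends
  vals <- x[starts]
  out <- integer(0)
  for (i in seq_len(nr)) {
    prv <- if (i == 1) nr else i - 1L
    nxt <- if (i == nr) 1L else i + 1L
    if (vals[i] > vals[prv] && vals[i] > vals[nxt]) {
      len <- ends[i] - starts[i] + 1L
      mid <- starts[i] + (len - 1L) %/% 2L   # lower-central for even runs
      out <- c(out, (mid - 1L) %% n + 1L)
    }
  }
  sort(out)
}

#' Detect leaf tips from the polar radius profile
#'
#' Leaf tips are the circular local maxima of the smoothed radius profile;
#' because smoothing underestimates the radius, the tip radius reported is
#' the raw (non-smoothed) radius at the maximum. Each tip also carries its
#' curvature ratio `cr = (r - r_s) / r`, a leaf-shape index (near 0 for
#' round leaves, larger for elongated ones) used by the length-to-area
#' model. Maxima whose raw radius falls below the threshold `T_r` are
#' discarded as false tips; inner leaves hidden behind the outline are
#' missed by construction, which the overlap correction of [plantArea()]
#' compensates.
#'
#' @param profile a [PolarProfile-class].
#' @param smoothed the matching [SmoothedProfile-class].
#' @param T_r radius threshold in pixels. The default, `NULL`, uses
#'   `T_r_rel * max(r)`, adapting across plant ages.
#' @param T_r_rel relative threshold used when `T_r` is `NULL`
#'   (default 0.15).
#' @return a data frame with one row per tip, sorted by angle: `phi`
#'   (degrees, bin center), `r` (raw radius, px), `cr` (curvature ratio).
#' @export
detectTips <- function(profile, smoothed, T_r = NULL, T_r_rel = 0.15) {
  if (length(profile@radii) != length(smoothed@radii))
    stop("profile and smoothed profile are not aligned")
  r <- profile@radii
  rs <- smoothed@radii
  if (all(r == 0)) return(data.frame(phi = numeric(0), r = numeric(0),
                                     cr = numeric(0)))
  if (is.null(T_r)) T_r <- T_r_rel * max(r)
  idx <- .circularMaxima(rs)
  if (length(idx) == 0 && diff(range(rs)) == 0 && max(r) > 0) {
    # perfectly flat smoothed profile (e.g. a disk): single tip at the raw max
    idx <- which.max(r)
  }
  raw <- r[idx]
  # a maximum whose bin and both circular neighbors are interpolated lies
  # deep inside an empty gap: an artifact of gap bridging, not a leaf tip
  # (a single empty bin can still hold a real tip -- diagonal quantization)
  nb <- length(r)
  gap <- profile@interpolated[idx] &
    profile@interpolated[(idx - 2) %% nb + 1L] &
    profile@interpolated[idx %% nb + 1L]
  keep <- raw >= T_r & !gap
  idx <- idx[keep]; raw <- raw[keep]
  cr <- ifelse(raw > 0, (raw - rs[idx]) / raw, 0)
  phi <- (idx - 1) * profile@bin_width
  ord <- order(phi)
  data.frame(phi = phi[ord], r = raw[ord], cr = cr[ord])
}
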