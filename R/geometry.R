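# Internal polygon geometry for the synthetic-rosette ground truth.
# Polygons are n x 2 matrices of (x, y) = (col, row) vertices in continuous
# 0-based pixel coordinates; leaf polygons are convex by construction, which
# is what makes exact union areas via inclusion-exclusion tractable.

.polySignedArea <- function(p) {
  n <- nrow(p)
  i2 <- c(2:n, 1)
  sum(p[, 1] * p[i2, 2] - p[i2, 1] * p[, 2]) / 2
}

.polyArea <- function(p) abs(.polySignedArea(p))

.ensureCCW <- function(p) {
  if (.polySignedArea(p) < 0) p[rev(seq_len(nrow(p))), , drop = FALSE] else p
}

# Sutherland-Hodgman: clip polygon `subject` by convex polygon `clip` (CCW).
# Returns a matrix with 0 rows when the intersection is empty.
.clipConvex <- function(subject, clip) {
  clip <- .ensureCCW(clip)
  out <- subject
  nc <- nrow(clip)
  for (e in seq_len(nc)) {
    if (nrow(out) < 3) return(out[0, , drop = FALSE])
    a <- clip[e, ]
    b <- clip[if (e == nc) 1 else e + 1, ]
    ex <- b[1] - a[1]; ey <- b[2] - a[2]
    # inside = left of directed edge a->b
    s <- ex * (out[, 2] - a[2]) - ey * (out[, 1] - a[1])
    inside <- s >= -1e-12
    n <- nrow(out)
    nxt <- c(2:n, 1)
    keep <- vector("list", n)
    for (i in seq_len(n)) {
      j <- nxt[i]
      pts <- NULL
      if (inside[i]) pts <- rbind(pts, out[i, ])
      if (inside[i] != inside[j]) {
        # segment crosses the edge line; compute intersection
        d <- s[i] - s[j]
        t <- if (abs(d) < 1e-300) 0 else s[i] / d
        pts <- rbind(pts, out[i, ] + t * (out[j, ] - out[i, ]))
      }
      keep[[i]] <- pts
    }
    out <- do.call(rbind, keep)
    if (is.null(out)) return(matrix(numeric(0), 0, 2))
  }
  out
}

# Exact area of the union of convex polygons by inclusion-exclusion with
# pruning (subsets whose running intersection is empty contribute nothing
# and are never extended).
.unionAreaConvex <- function(polys) {
  n <- length(polys)
  total <- 0
  rec <- function(i0, cur, sgn) {
    for (i in i0:n) {
      p <- if (is.null(cur)) polys[[i]] else .clipConvex(cur, polys[[i]])
      if (nrow(p) < 3) next
      a <- .polyArea(p)
      if (a <= 1e-12) next
      total <<- total + sgn * a
      if (i < n) rec(i + 1, p, -sgn)
    }
  }
  rec(1, NULL, 1)
  total
}

.pairwiseIntersectionArea <- function(polys) {
  n <- length(polys)
  if (n < 2) return(0)
  tot <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    p <- .clipConvex(polys[[i]], polys[[j]])
    if (nrow(p) >= 3) tot <- tot + .polyArea(p)
  }
  tot
}

# Which pixel centers (integer x, y) fall inside a convex polygon.
# Returns a logical matrix of dim (height, width); m[row+1, col+1] maps to
# pixel center (row, col), x = col, y = row.
.rasterizeConvex <- function(poly, image_size) {
  h <- image_size[1]; w <- image_size[2]
  m <- matrix(FALSE, h, w)
  poly <- .ensureCCW(poly)
  xlo <- max(0L, floor(min(poly[, 1]))); xhi <- min(w - 1L, ceiling(max(poly[, 1])))
  ylo <- max(0L, floor(min(poly[, 2]))); yhi <- min(h - 1L, ceiling(max(poly[, 2])))
  if (xlo > xhi || ylo > yhi) return(m)
  xs <- xlo:xhi; ys <- ylo:yhi
  px <- rep(xs, each = length(ys))
  py <- rep(ys, times = length(xs))
  inside <- rep(TRUE, length(px))
  n <- nrow(poly)
  for (e in seq_len(n)) {
    a <- poly[e, ]; b <- poly[if (e == n) 1 else e + 1, ]
    s <- (b[1] - a[1]) * (py - a[2]) - (b[2] - a[2]) * (px - a[1])
    inside <- inside & (s >= 0)
    if (!any(inside)) return(m)
  }
  m[cbind(py + 1L, px + 1L)[inside, , drop = FALSE]] <- TRUE
  m
}

# Leaf outline polygon for a LeafSpec, in (x, y) = (col, row) coordinates.
# Angle phi: direction (cos phi, -sin phi), i.e. counter-clockwise from the
# +col axis when the image is viewed with row 0 at the top.
.shiftPts <- function(offsets, origin) {
  sweep(offsets, 2, origin, `+`)
}

.leafPolygon <- function(leaf, center, n_arc = 48L) {
  phi <- leaf@angle * pi / 180
  dir <- c(cos(phi), -sin(phi))
  per <- c(-dir[2], dir[1])
  c0 <- c(center[2], center[1])           # (x, y)
  base <- leaf@petiole_fraction * leaf@length
  chord <- leaf@length - base
  if (leaf@shape == "ellipse") {
    ec <- c0 + dir * (base + chord / 2)
    a <- chord / 2; b <- leaf@width / 2
    t <- seq(0, 2 * pi, length.out = n_arc + 1L)[-(n_arc + 1L)]
    pts <- .shiftPts(outer(a * cos(t), dir) + outer(b * sin(t), per), ec)
  } else {
    # teardrop/lens: two circular arcs joining petiole base to tip,
    # maximal half-width s at the chord midpoint
    s <- leaf@width / 2
    R <- (chord^2 / 4 + s^2) / (2 * s)
    g <- atan2(chord / 2, R - s)          # half-aperture seen from arc center
    m <- c0 + dir * (base + chord / 2)
    n1 <- max(8L, n_arc %/% 2L)
    t <- seq(pi / 2 + g, pi / 2 - g, length.out = n1)
    # local frame: x along chord (dir), y along per; arc center at (0, s - R)
    lx <- R * cos(t); ly <- (s - R) + R * sin(t)
    upper <- .shiftPts(outer(lx, dir) + outer(ly, per), m)
    lower <- .shiftPts(outer(rev(lx), dir) - outer(rev(ly), per), m)
    pts <- rbind(upper, lower[-c(1L, nrow(lower)), , drop = FALSE])
  }
  pts
}

.leafTipPoint <- function(leaf, center) {
  phi <- leaf@angle * pi / 180
  c(center[1] - leaf@length * sin(phi), center[2] + leaf@length * cos(phi))
}

.trapz <- function(x, y) sum((y[-1] + y[-length(y)]) / 2 * diff(x))
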