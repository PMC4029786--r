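# Fixtures are built in code at test time; coordinates are 0-based (row,
# col) with pixel centers at integers throughout.

# noiseless image with a filled disk of radius R
diskImage <- function(R = 50, size = 160, bg = 100, fg = 3000,
                      center = (size - 1) / 2) {
  idx <- 0:(size - 1)
  d2 <- outer((idx - center[1])^2, (idx - center[length(center)])^2, `+`)
  img <- matrix(bg, size, size)
  img[d2 <= R^2] <- fg
  img
}

diskMask <- function(R = 40, size = 128, center = (size - 1) / 2) {
  idx <- 0:(size - 1)
  d2 <- outer((idx - center[1])^2, (idx - center[length(center)])^2, `+`)
  m <- d2 <= R^2
  new("ForegroundMask", mask = m, observed_area = sum(m))
}

# star-shaped mask defined directly in polar coordinates: n_petals smooth
# humps, tips at angles k * 360 / n_petals + angle0
starMask <- function(n_petals, base = 18, amp = 30, size = 141,
                     angle0 = 0) {
  ctr <- (size - 1) / 2
  idx <- 0:(size - 1)
  cols <- matrix(idx, size, size, byrow = TRUE)
  rows <- matrix(idx, size, size)
  dx <- cols - ctr
  dy <- ctr - rows
  r <- sqrt(dx^2 + dy^2)
  phi <- atan2(dy, dx) - angle0 * pi / 180
  lim <- base + amp * (cos(n_petals * phi) + 1) / 2
  m <- r <= lim
  new("ForegroundMask", mask = m, observed_area = sum(m))
}

maskFromMatrix <- function(m) new("ForegroundMask", mask = m,
                                  observed_area = sum(m))

# breadth-first-search oracle for the corner-connected background of a
# binary edge map (4-connectivity), independent of EBImage
bfsBackground <- function(edge) {
  h <- nrow(edge); w <- ncol(edge)
  bg <- matrix(FALSE, h, w)
  queue <- list()
  push <- function(i, j) {
    if (i >= 1 && i <= h && j >= 1 && j <= w && !bg[i, j] && !edge[i, j]) {
      bg[i, j] <<- TRUE
      queue[[length(queue) + 1]] <<- c(i, j)
    }
  }
  for (p in list(c(1, 1), c(1, w), c(h, 1), c(h, w))) push(p[1], p[2])
  while (length(queue)) {
    p <- queue[[length(queue)]]
    queue[[length(queue)]] <- NULL
    push(p[1] - 1, p[2]); push(p[1] + 1, p[2])
    push(p[1], p[2] - 1); push(p[1], p[2] + 1)
  }
  bg
}

# grid-search oracle for the summed squared perpendicular distance
# objective over orientation lines
gridSearchCenter <- function(lines, lo, hi, step = 0.1) {
  nf <- lapply(lines, function(l) {
    u <- l@p2 - l@p1; u <- u / sqrt(sum(u^2))
    n <- c(-u[2], u[1])
    list(n = n, d = sum(n * l@p1))
  })
  rows <- seq(lo[1], hi[1], by = step)
  cols <- seq(lo[2], hi[2], by = step)
  best <- c(NA, NA); bestv <- Inf
  for (r in rows) {
    vals <- rep(0, length(cols))
    for (f in nf) vals <- vals + (f$n[1] * r + f$n[2] * cols - f$d)^2
    i <- which.min(vals)
    if (vals[i] < bestv) { bestv <- vals[i]; best <- c(r, cols[i]) }
  }
  best
}

table2Fit <- function(genotype, sample) {
  fits <- arabidopsisLogisticFits()
  row <- fits[fits$genotype == genotype & fits$sample == sample, ]
  as3plFit(gamma = row$gamma, A0 = row$A0, Aa = row$Aa)
}
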