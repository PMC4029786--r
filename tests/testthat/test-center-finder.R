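test_that("simple-leaf detection finds isolated leaves and drops complexes", {
  # four mutually disjoint leaves -> four regions
  sp4 <- starRosette(4, 70, 26, image_size = c(256, 256))
  out4 <- renderRosette(sp4)
  fm4 <- buildForegroundMask(out4$image)
  regs4 <- detectSimpleLeaves(out4$image, fm4)
  expect_length(regs4, 4)
  expect_false(attr(regs4, "insufficient"))
  expect_true(all(vapply(regs4, function(r) r@solidity, numeric(1)) >= 0.85))

  # five leaves of which exactly two overlap -> the pair is one lobed,
  # low-solidity complex and is excluded, leaving three regions
  leaves <- list(LeafSpec(0, 80, 26, petiole_fraction = 0.1),
                 LeafSpec(40, 80, 26, petiole_fraction = 0.1),
                 LeafSpec(140, 80, 26), LeafSpec(220, 80, 26),
                 LeafSpec(290, 80, 26))
  sp5 <- RosetteSpec(leaves, image_size = c(300, 300))
  out5 <- renderRosette(sp5)
  expect_gt(out5$truth@overlap_fraction, 0)
  regs5 <- detectSimpleLeaves(out5$image, buildForegroundMask(out5$image))
  expect_length(regs5, 3)
})

test_that("an empty mask gives an empty result with the insufficient flag", {
  fm <- maskFromMatrix(matrix(FALSE, 64, 64))
  regs <- detectSimpleLeaves(matrix(100, 64, 64), fm)
  expect_length(regs, 0)
  expect_true(attr(regs, "insufficient"))
})

test_that("the orientation line matches a brute-force longest-chord oracle", {
  bruteForce <- function(b) {
    best <- 0; pair <- NULL
    for (i in 1:(nrow(b) - 1)) for (j in (i + 1):nrow(b)) {
      d <- sum((b[i, ] - b[j, ])^2)
      if (d > best) { best <- d; pair <- rbind(b[i, ], b[j, ]) }
    }
    list(len = sqrt(best), pair = pair)
  }
  # axis-aligned ellipse, semi-axes (40, 10): endpoints at the major
  # vertices (rows index first, so the major axis runs along rows)
  idx <- 0:120
  m <- outer((idx - 60)^2 / 40^2, (idx - 60)^2 / 10^2, `+`) <= 1
  reg <- new("LeafRegion", pixels = which(m, arr.ind = TRUE) - 1L,
             boundary = RosetteGrowth:::.boundaryPixels(m), solidity = 1)
  ol <- orientationLine(reg)
  or <- bruteForce(reg@boundary)
  expect_equal(sqrt(sum((ol@p1 - ol@p2)^2)), or$len, tolerance = 1e-9)
  expect_true(all(abs(c(ol@p1[1], ol@p2[1]) - c(20, 100)) <= 1))
  expect_true(all(abs(c(ol@p1[2], ol@p2[2]) - 60) <= 1))

  # perfect circle: some diameter, length within 1 px of 2R
  mc <- outer((idx - 60)^2, (idx - 60)^2, `+`) <= 35^2
  regc <- new("LeafRegion", pixels = which(mc, arr.ind = TRUE) - 1L,
              boundary = RosetteGrowth:::.boundaryPixels(mc), solidity = 1)
  olc <- orientationLine(regc)
  expect_equal(sqrt(sum((olc@p1 - olc@p2)^2)), 70, tolerance = 1 / 70 * 2)

  # rotated rectangle: a main diagonal
  rot <- function(p, th) cbind(cos(th) * p[, 1] - sin(th) * p[, 2],
                               sin(th) * p[, 1] + cos(th) * p[, 2])
  pts <- expand.grid(r = seq(-30, 30, by = 0.5), c = seq(-12, 12, by = 0.5))
  rp <- rot(as.matrix(pts), 25 * pi / 180)
  mr <- matrix(FALSE, 121, 121)
  mr[round(rp[, 1]) + 61 + 121 * (round(rp[, 2]) + 60)] <- TRUE
  regr <- new("LeafRegion", pixels = which(mr, arr.ind = TRUE) - 1L,
              boundary = RosetteGrowth:::.boundaryPixels(mr), solidity = 1)
  olr <- orientationLine(regr)
  orr <- bruteForce(regr@boundary)
  expect_equal(sqrt(sum((olr@p1 - olr@p2)^2)), orr$len, tolerance = 1e-9)
})

test_that("center estimation solves the line-distance problem exactly", {
  # two perpendicular lines crossing at p
  l1 <- new("OrientationLine", p1 = c(10, 40), p2 = c(90, 40))
  l2 <- new("OrientationLine", p1 = c(50, 0), p2 = c(50, 80))
  ctr <- estimateCenter(list(l1, l2))
  expect_equal(centerPoint(ctr), c(50, 40), tolerance = 1e-9)
  expect_identical(ctr@method, "orientation_lines")

  # three concurrent lines through p
  p <- c(33, 57)
  mk <- function(th) new("OrientationLine", p1 = p - 40 * c(cos(th), sin(th)),
                         p2 = p + 40 * c(cos(th), sin(th)))
  ctr3 <- estimateCenter(list(mk(0.3), mk(1.5), mk(2.4)))
  expect_equal(centerPoint(ctr3), p, tolerance = 1e-9)
})

test_that("center estimation agrees with a 0.1-px grid-search oracle", {
  # three lines forming a triangle: minimizer compared to grid search of
  # the same summed-squared-distance objective
  l1 <- new("OrientationLine", p1 = c(20, 10), p2 = c(30, 90))
  l2 <- new("OrientationLine", p1 = c(80, 20), p2 = c(25, 30))
  l3 <- new("OrientationLine", p1 = c(60, 90), p2 = c(90, 40))
  ctr <- estimateCenter(list(l1, l2, l3))
  oracle <- gridSearchCenter(list(l1, l2, l3), lo = c(20, 10), hi = c(90, 90))
  expect_lt(sqrt(sum((centerPoint(ctr) - oracle)^2)), 0.5)
})

test_that("center estimation is invariant to line order and duplication", {
  l1 <- new("OrientationLine", p1 = c(20, 10), p2 = c(30, 90))
  l2 <- new("OrientationLine", p1 = c(80, 20), p2 = c(25, 30))
  l3 <- new("OrientationLine", p1 = c(60, 90), p2 = c(90, 40))
  a <- centerPoint(estimateCenter(list(l1, l2, l3)))
  b <- centerPoint(estimateCenter(list(l3, l1, l2)))
  d <- centerPoint(estimateCenter(list(l1, l2, l3, l1, l2, l3)))
  expect_equal(a, b, tolerance = 1e-12)
  expect_equal(a, d, tolerance = 1e-12)
})

test_that("degenerate line sets are rejected", {
  l1 <- new("OrientationLine", p1 = c(0, 0), p2 = c(0, 10))
  l2 <- new("OrientationLine", p1 = c(5, 0), p2 = c(5, 10))
  expect_error(estimateCenter(list(l1)), "at least 2")
  expect_error(estimateCenter(list(l1, l2)), "parallel")
})

test_that("center of mass behaves linearly", {
  m <- matrix(FALSE, 64, 64)
  m[11, 21] <- TRUE
  expect_equal(centerPoint(centerOfMass(maskFromMatrix(m))), c(10, 20))

  # centered disk -> image center
  fm <- diskMask(R = 20, size = 101)
  expect_equal(centerPoint(centerOfMass(fm)), c(50, 50), tolerance = 0.5)

  # two equal disjoint blobs -> midpoint of centroids
  m2 <- matrix(FALSE, 100, 100)
  m2[10:19, 10:19] <- TRUE
  m2[70:79, 80:89] <- TRUE
  expect_equal(centerPoint(centerOfMass(maskFromMatrix(m2))),
               (c(13.5, 13.5) + c(73.5, 83.5)) / 2)
  expect_error(centerOfMass(maskFromMatrix(matrix(FALSE, 8, 8))), "empty")
})

test_that("orientation-line centers beat center of mass on asymmetric plants", {
  # leaf axes pass through the true center; removing one leaf biases the
  # center of mass but barely moves the line-based estimate
  sp <- starRosette(5, 75, 24, image_size = c(256, 256))
  sp@leaves <- sp@leaves[-1]          # asymmetric: one leaf removed
  out <- renderRosette(sp)
  fm <- buildForegroundMask(out$image)
  truec <- out$truth@center
  ctr_l <- findPlantCenter(out$image, fm)
  ctr_m <- centerOfMass(fm)
  expect_identical(ctr_l@method, "orientation_lines")
  err_l <- sqrt(sum((centerPoint(ctr_l) - truec)^2))
  err_m <- sqrt(sum((centerPoint(ctr_m) - truec)^2))
  expect_lte(err_l, err_m)
})

test_that("the pipeline falls back to center of mass when leaves are scarce", {
  # a plain disk has no elongated simple leaves
  img <- diskImage(R = 40, size = 160)
  fm <- buildForegroundMask(img)
  ctr <- findPlantCenter(img, fm)
  expect_identical(ctr@method, "center_of_mass")
  expect_equal(centerPoint(ctr), c(79.5, 79.5), tolerance = 1)
})
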