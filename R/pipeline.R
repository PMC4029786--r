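#' Default pipeline configuration
#'
#' All tunables of the area-estimation and growth-analysis pipeline in one
#' serializable list. Every entry is documented with its unit and default:
#' \describe{
#'   \item{sigma}{Gaussian smoothing sd for simple-leaf detection, px (2).}
#'   \item{edge_threshold}{relative gradient cutoff for the edge map in
#'     (0, 1\]; `NULL` = Otsu on the gradient magnitude.}
#'   \item{dilation_radius}{edge dilation disk radius, px (2).}
#'   \item{erosion_radius}{compensating erosion radius, px; `NULL` =
#'     `dilation_radius + 1`.}
#'   \item{bin_width}{polar profile bin width, degrees (1).}
#'   \item{k}{profile smoothing window, bins, odd (9).}
#'   \item{T_r}{absolute tip radius threshold, px; `NULL` = relative.}
#'   \item{T_r_rel}{relative tip threshold as a fraction of the maximal
#'     radius (0.15).}
#'   \item{s_min, A_min, A_max}{simple-leaf solidity and area screen;
#'     `A_max = NULL` means half the foreground area.}
#'   \item{round_min}{minimal elongation for orientation leaves (1.2).}
#'   \item{center_method}{`"l2"` (closed form) or `"l1"` (IRLS).}
#'   \item{center_frame}{frame used to locate the center once per plant:
#'     `"median_area"` or a frame index.}
#'   \item{model}{the four length-to-area coefficients plus `cr_cutoff`
#'     (the shipped calibration).}
#'   \item{dt}{finite-difference step for growth rates, time units (0.35).}
#'   \item{alpha}{outlier-flagging significance level (0.05).}
#'   \item{time_unit}{label for the time axis (`"days"`); `gamma` is
#'     reported in the inverse of the input time unit.}
#'   \item{seed}{base RNG seed (1).}
#' }
#'
#' @return named list of settings.
#' @seealso [saveConfig()], [runPipeline()]
#' @export
defaultConfig <- function() {
  m <- defaultLengthAreaModel()
  list(
    sigma = 2, edge_threshold = NULL, dilation_radius = 2,
    erosion_radius = NULL,
    bin_width = 1, k = 9, T_r = NULL, T_r_rel = 0.15,
    s_min = 0.85, A_min = 100, A_max = NULL, round_min = 1.2,
    center_method = "l2", center_frame = "median_area",
    model = list(linear_slope = m@linear_slope,
                 linear_intercept = m@linear_intercept,
                 exp_scale = m@exp_scale, exp_rate = m@exp_rate,
                 cr_cutoff = m@cr_cutoff),
    dt = 0.35, alpha = 0.05, time_unit = "days", seed = 1
  )
}

.modelFromConfig <- function(config) {
  m <- config$model
  new("LengthAreaModel", linear_slope = m$linear_slope,
      linear_intercept = m$linear_intercept, exp_scale = m$exp_scale,
      exp_rate = m$exp_rate, cr_cutoff = m$cr_cutoff,
      r2_linear = NA_real_, r2_exp = NA_real_,
      ci = matrix(NA_real_, 4, 2))
}

#' Save or load a pipeline configuration
#'
#' YAML serialization of the configuration list;
#' `loadConfig(saveConfig(cfg, f))` reproduces `cfg`.
#'
#' @param config a configuration list (see [defaultConfig()]).
#' @param path file path.
#' @return `saveConfig` returns `path` invisibly; `loadConfig` returns the
#'   configuration list.
#' @export
saveConfig <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname saveConfig
#' @export
loadConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- defaultConfig()
  # preserve explicit NULLs for keys yaml drops
  for (nm in names(base)) if (!nm %in% names(cfg)) cfg[nm] <- list(NULL)
  cfg[names(base)]
}

#' Read a grayscale plant image from PNG or TIFF
#'
#' Reads 8/16-bit PNG or 8/12/16-bit TIFF (12-bit frames are stored in
#' 16-bit containers) as a numeric intensity matrix; multi-channel images
#' are reduced to their first channel.
#'
#' @param path image file path.
#' @return numeric matrix (height x width).
#' @export
readPlantImage <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = , tiff = tiff::readTIFF(path),
    stop("unsupported image format: ", ext))
  if (length(dim(img)) == 3) img <- img[, , 1]
  img
}

.frameRecordNA <- function(time) {
  data.frame(time = time, m = NA_integer_, a_l = NA_real_, a_t = NA_real_,
             p_overlap = NA_real_, a = NA_real_)
}

#' Run the full area-estimation and growth-modeling pipeline
#'
#' End-to-end orchestration over a time series of top-view frames of one
#' plant: foreground mask per frame, plant center located once (on the
#' median-area frame by default, since the center does not move during a
#' growth experiment), polar profile, tip detection and per-leaf areas per
#' frame, overlap-corrected plant area, and finally a three-parameter
#' logistic fit with phase-plane features. Deterministic given the frames
#' and configuration. Frames whose mask is empty or that yield no tips
#' produce an NA record with a warning; the growth fit proceeds on the
#' remaining frames (and is skipped, with a message, when fewer than 10
#' usable frames remain).
#'
#' @param frames list of numeric image matrices, or a character vector of
#'   PNG/TIFF paths (read in order).
#' @param times frame times; default `0, 1, 2, ...` in `config$time_unit`.
#' @param config configuration list from [defaultConfig()].
#' @return a list: `records` (data frame, one row per frame: time, m, a_l,
#'   a_t, p_overlap, a), `tips` (per-frame tip data frames), `center`
#'   ([PlantCenter-class]), `fit` ([ThreePLFit-class] or NULL), `rates`
#'   ([GrowthRates-class] or NULL), `features` ([PhasePlaneFeatures-class]
#'   or NULL).
#' @examples
#' ser <- growSeries(starRosette(3, 40, 16, image_size = c(220, 220)),
#'                   c(gamma = 0.25, A0 = 400, Aa = 3000), times = 0:11)
#' res <- runPipeline(lapply(ser, `[[`, "image"),
#'                    times = sapply(ser, `[[`, "time"))
#' head(res$records)
#' @export
runPipeline <- function(frames, times = NULL, config = defaultConfig()) {
  if (is.character(frames)) frames <- lapply(frames, readPlantImage)
  n <- length(frames)
  if (n < 1) stop("at least one frame is required")
  if (is.null(times)) times <- seq_len(n) - 1
  stopifnot(length(times) == n)
  model <- .modelFromConfig(config)

  masks <- lapply(frames, function(im)
    buildForegroundMask(im, edge_threshold = config$edge_threshold,
                        dilation_radius = config$dilation_radius,
                        erosion_radius = config$erosion_radius))
  at <- vapply(masks, observedArea, numeric(1))

  ci <- if (identical(config$center_frame, "median_area")) {
    ok <- which(at > 0)
    if (length(ok) == 0) stop("all frames have an empty mask")
    ok[which.min(abs(at[ok] - stats::median(at[ok])))]
  } else as.integer(config$center_frame)
  center <- findPlantCenter(frames[[ci]], masks[[ci]], sigma = config$sigma,
                            s_min = config$s_min, A_min = config$A_min,
                            A_max = config$A_max,
                            round_min = config$round_min,
                            method = config$center_method)

  tips_list <- vector("list", n)
  records <- vector("list", n)
  for (i in seq_len(n)) {
    if (at[i] <= 0) {
      warning(sprintf("frame %d: empty mask; recording NA area", i))
      records[[i]] <- .frameRecordNA(times[i])
      tips_list[[i]] <- data.frame(phi = numeric(0), r = numeric(0),
                                   cr = numeric(0))
      next
    }
    prof <- polarProfile(masks[[i]], center, bin_width = config$bin_width)
    sm <- smoothProfile(prof, k = config$k)
    tips <- detectTips(prof, sm, T_r = config$T_r, T_r_rel = config$T_r_rel)
    tips_list[[i]] <- tips
    if (nrow(tips) == 0) {
      warning(sprintf("frame %d: no leaf tips detected; recording NA area", i))
      records[[i]] <- .frameRecordNA(times[i])
      next
    }
    la <- leafAreaFromTip(tips$r, tips$cr, model)
    rec <- plantArea(la, a_t = at[i], time = times[i])
    records[[i]] <- as.data.frame(rec)
  }
  records <- do.call(rbind, records)

  fit <- rates <- features <- NULL
  ok <- stats::complete.cases(records[, c("time", "a")])
  if (sum(ok) >= 10) {
    fit <- tryCatch(fit3plm(records$time[ok], records$a[ok]),
                    error = function(e) {
                      message("growth fit skipped: ", conditionMessage(e))
                      NULL
                    })
    if (!is.null(fit)) {
      rates <- growthRates(fit, dt = config$dt, times = records$time[ok])
      features <- phasePlaneFeatures(fit)
    }
  } else {
    message("growth fit skipped: fewer than 10 usable frames")
  }
  list(records = records, tips = tips_list, center = center, fit = fit,
       rates = rates, features = features, config = config)
}

.matchTips <- function(pred, truth_tips, true_center, angle_tol, radius_tol) {
  # truth tips in polar coordinates about the true center
  dy <- true_center[1] - truth_tips[, 1]
  dx <- truth_tips[, 2] - true_center[2]
  tphi <- (atan2(dy, dx) * 180 / pi) %% 360
  tr <- sqrt(dx^2 + dy^2)
  used <- rep(FALSE, nrow(pred))
  hit <- 0L
  for (j in order(tr, decreasing = TRUE)) {
    if (nrow(pred) == 0) break
    dphi <- abs((pred$phi - tphi[j] + 180) %% 360 - 180)
    cand <- which(!used & dphi <= angle_tol &
                    abs(pred$r - tr[j]) <= radius_tol * tr[j])
    if (length(cand)) {
      used[cand[which.min(dphi[cand])]] <- TRUE
      hit <- hit + 1L
    }
  }
  c(hit = hit, n = nrow(truth_tips))
}

#' Evaluate pipeline output against synthetic ground truth
#'
#' Mirrors the evaluation harness of the method's validation: per-frame tip
#' true-positive rate (a predicted tip matches a true tip within an angular
#' and a relative radial tolerance), the area error rate of the corrected
#' estimate (mean |a - truth| / truth, in %), the same error for the naive
#' top-view area `a_t`, and the center distance in pixels. The area truth
#' is the summed complete per-leaf area of the ground truth (the quantity a
#' manual measurement with completed leaf edges reports), which the naive
#' top-view count undershoots whenever leaves overlap.
#'
#' @param result output of [runPipeline()].
#' @param truths list of [GroundTruth-class], one per frame.
#' @param angle_tol tip matching tolerance in degrees (default 5).
#' @param radius_tol relative radial matching tolerance (default 0.10).
#' @return a list: `tip_tpr` (%), `area_error_rate` (%),
#'   `naive_error_rate` (%), `center_distance` (px) and `per_frame` (data
#'   frame with frame-wise TPR and errors).
#' @export
evaluateEstimates <- function(result, truths, angle_tol = 5,
                              radius_tol = 0.10) {
  n <- nrow(result$records)
  if (length(truths) != n) stop("frame counts of result and truth differ")
  per <- lapply(seq_len(n), function(i) {
    tru <- truths[[i]]
    m <- .matchTips(result$tips[[i]], tru@tip_points, tru@center,
                    angle_tol, radius_tol)
    a <- result$records$a[i]
    at <- result$records$a_t[i]
    truth_area <- sum(tru@per_leaf_areas)
    data.frame(frame = i, tips_matched = m["hit"], tips_true = m["n"],
               tpr = 100 * m["hit"] / m["n"],
               area_err = 100 * abs(a - truth_area) / truth_area,
               naive_err = 100 * abs(at - truth_area) / truth_area)
  })
  per <- do.call(rbind, per)
  rownames(per) <- NULL
  ctr_d <- sqrt(sum((centerPoint(result$center) - truths[[1]]@center)^2))
  list(tip_tpr = 100 * sum(per$tips_matched) / sum(per$tips_true),
       area_error_rate = mean(per$area_err, na.rm = TRUE),
       naive_error_rate = mean(per$naive_err, na.rm = TRUE),
       center_distance = ctr_d,
       per_frame = per)
}

#' Write a synthetic growth series to disk
#'
#' Persists a [growSeries()] result the way the `simulate` command does:
#' 8-bit PNG frames (`frame_###.png`, intensities normalized by the
#' `RosetteSpec` `max_intensity`), a ground-truth JSON (center, tips, per-leaf and union
#' areas per frame) and a CSV of per-frame union areas.
#'
#' @param series result of [growSeries()].
#' @param dir output directory (created if missing).
#' @param max_intensity intensity scale used for PNG normalization
#'   (default 4095).
#' @return invisibly, the directory.
#' @export
writeRosetteSeries <- function(series, dir, max_intensity = 4095) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  truth <- lapply(seq_along(series), function(i) {
    fr <- series[[i]]
    png::writePNG(pmin(pmax(fr$image / max_intensity, 0), 1),
                  file.path(dir, sprintf("frame_%03d.png", i)))
    list(time = fr$time, center = fr$truth@center,
         tips = fr$truth@tip_points,
         per_leaf_areas = fr$truth@per_leaf_areas,
         union_area = fr$truth@union_area,
         overlap_fraction = fr$truth@overlap_fraction)
  })
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.csv(
    data.frame(time = vapply(series, `[[`, numeric(1), "time"),
               union_area = vapply(series, function(f) f$truth@union_area,
                                   numeric(1))),
    file.path(dir, "union_areas.csv"), row.names = FALSE)
  invisible(dir)
}
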