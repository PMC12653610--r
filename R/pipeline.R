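# End-to-end orchestration: average -> flat-field -> denoise -> quality
# gates -> segmentation -> color transform -> yellowness index -> grade.
# A quality-gate failure or invalid ROI halts with a reacquisition status;
# a specimen is never silently assigned a default grade.

#' Pipeline configuration
#'
#' Bundles the stage configurations used by \code{\link{run_specimen}} and
#' \code{\link{run_batch}}.
#'
#' @param lin_cfg \code{\link{linearization_config}} for the CIELAB path.
#' @param pre_cfg \code{\link{preprocess_config}}.
#' @param model \code{\link{grade_model}}.
#' @param wp \code{\link{white_point}}.
#' @param roi_erosion_px Radius of the erosion applied to the validated ROI
#'   before color statistics, so boundary pixels blurred into the
#'   background do not bias the specimen mean. Default 2.
#' @param seed Seed recorded for provenance.
#' @return An object of class \code{pipeline_config}.
#' @export
pipeline_config <- function(lin_cfg = linearization_config(),
                            pre_cfg = preprocess_config(),
                            model = grade_model(), wp = white_point(),
                            roi_erosion_px = 2, seed = 1) {
  structure(list(lin_cfg = lin_cfg, pre_cfg = pre_cfg, model = model,
                 wp = wp, roi_erosion_px = roi_erosion_px, seed = seed),
            class = "pipeline_config")
}

config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(config, f)
  unname(tools::md5sum(f))
}

erode_mask <- function(mask, px) {
  if (px <= 0) return(mask)
  m <- EBImage::erode(EBImage::Image(mask * 1),
                      EBImage::makeBrush(2 * px + 1, shape = "box"))
  out <- matrix(as.numeric(m) > 0.5, nrow = nrow(mask))
  if (any(out)) out else mask
}

#' Measure and grade a single specimen
#'
#' Executes the full pipeline on a frame set. Stage order: frame averaging,
#' quality gates (focus, uniformity, saturation), flat-field correction,
#' Gaussian denoising, ROI segmentation with geometric validation, mean-RGB
#' extraction over the (slightly eroded) ROI, dual-path color conversion,
#' and decision-tree grading.
#'
#' @param x A \code{\link{raw_frame_set}} or \code{synthetic_scene}.
#' @param config A \code{\link{pipeline_config}}.
#' @return An object of class \code{specimen_result} with \code{status}
#'   (\code{"ok"} or \code{"reacquisition_required"}), \code{grade} (NA
#'   unless status is ok), \code{color} (\code{\link{color_vector}}),
#'   \code{decision}, \code{quality}, \code{segmentation}, \code{timings}
#'   (seconds per stage) and \code{config_hash}.
#' @export
run_specimen <- function(x, config = pipeline_config()) {
  if (inherits(x, "synthetic_scene")) x <- x$frameset
  stopifnot(inherits(x, "raw_frame_set"), inherits(config, "pipeline_config"))
  timings <- c()
  tic <- function() proc.time()[["elapsed"]]
  t0 <- tic()
  avg <- average_frames(x$frames)
  timings["average"] <- tic() - t0

  t0 <- tic()
  qc <- compute_quality(x, config$pre_cfg)
  timings["quality"] <- tic() - t0
  result <- function(status, grade = NA_character_, color = NULL,
                     decision = NULL, seg = NULL, reason = NULL) {
    structure(list(status = status, grade = grade, color = color,
                   decision = decision, quality = qc, segmentation = seg,
                   reason = reason, timings = timings,
                   config_hash = config_hash(config)),
              class = "specimen_result")
  }
  if (!qc$pass_flags$all) {
    failed <- names(Filter(isFALSE, qc$pass_flags[c("focus", "uniformity",
                                                    "saturation")]))
    return(result("reacquisition_required",
                  reason = paste0("quality gate failed: ",
                                  paste(failed, collapse = ", "),
                                  " (adjust acquisition and re-image)")))
  }

  t0 <- tic()
  corr <- flat_field_correct(avg, x$dark, x$white, bit_depth = x$bit_depth)
  den <- gaussian_denoise(corr, config$pre_cfg$gaussian_sigma)
  timings["preprocess"] <- tic() - t0

  t0 <- tic()
  seg <- segment_specimen(den, pixel_pitch_mm = x$pixel_pitch_mm,
                          bit_depth = x$bit_depth)
  timings["segment"] <- tic() - t0
  if (!seg$valid) {
    return(result("reacquisition_required", seg = seg,
                  reason = paste0("ROI validation failed: ",
                                  paste(seg$failure_reasons, collapse = "; "),
                                  " (reposition specimen and re-image)")))
  }

  t0 <- tic()
  roi <- erode_mask(seg$mask, config$roi_erosion_px)
  scale8 <- 255 / full_scale(x$bit_depth)
  rgb_mean <- vapply(1:3, function(ch) {
    v <- corr[, , ch]
    excl <- attr(corr, "excluded")
    use <- roi & !(if (is.null(excl)) FALSE else excl[, , ch])
    mean(v[use]) * scale8
  }, numeric(1))
  rgb_mean <- pmin(pmax(rgb_mean, 0), 255)
  cv <- color_vector(rgb_mean, lin_cfg = config$lin_cfg, wp = config$wp)
  decision <- assign_grade(cv, config$model)
  timings["colorimetry"] <- tic() - t0
  result("ok", grade = decision$grade, color = cv, decision = decision,
         seg = seg)
}

#' @export
print.specimen_result <- function(x, ...) {
  cat("<specimen_result> status:", x$status, "\n")
  if (x$status == "ok") {
    cat("  grade:", x$grade, sprintf(" (YI %.2f, L* %.2f, a* %.2f)\n",
        x$color$yi, x$color$lab[1], x$color$lab[2]))
  } else {
    cat("  reason:", x$reason, "\n")
  }
  invisible(x)
}

#' Run the pipeline over a batch of specimens
#'
#' Processes each scene/frame set, collecting per-specimen rows and, when
#' ground-truth labels are available, an aggregate accuracy and confusion
#' table. A failing specimen contributes an error row; the batch continues.
#'
#' @param scenes List of \code{synthetic_scene} or \code{raw_frame_set}
#'   objects (a \code{synthetic_scene} supplies its own true grade), or a
#'   data frame manifest with columns \code{frame1[,frame2,frame3]},
#'   \code{dark}, \code{white} and optionally \code{label}, whose paths are
#'   loaded with \code{\link{read_raster}}.
#' @param config A \code{\link{pipeline_config}}.
#' @param labels Optional character vector of true grades (overrides
#'   scene-carried labels).
#' @return An object of class \code{batch_result}: \code{results} (one data
#'   frame row per specimen), \code{accuracy} (NA without labels),
#'   \code{confusion} (table or NULL), \code{n_failed}.
#' @export
run_batch <- function(scenes, config = pipeline_config(), labels = NULL) {
  if (is.data.frame(scenes)) {
    scenes <- manifest_to_framesets(scenes)
    if (is.null(labels)) labels <- attr(scenes, "labels")
  }
  if (length(scenes) == 0) stop("empty batch: no specimens to process")
  hash <- config_hash(config)
  rows <- lapply(seq_along(scenes), function(i) {
    sc <- scenes[[i]]
    true_grade <- if (!is.null(labels)) labels[i]
                  else if (inherits(sc, "synthetic_scene")) sc$grade
                  else NA_character_
    row <- data.frame(id = i, true_grade = true_grade,
                      grade = NA_character_, status = NA_character_,
                      yi = NA_real_, l_star = NA_real_, a_star = NA_real_,
                      b_star = NA_real_, area_mm2 = NA_real_,
                      circularity = NA_real_, comparisons = NA_integer_,
                      error = NA_character_, config_hash = hash,
                      elapsed_s = NA_real_, stringsAsFactors = FALSE)
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(run_specimen(sc, config), error = function(e) e)
    row$elapsed_s <- proc.time()[["elapsed"]] - t0
    if (inherits(res, "error")) {
      row$status <- "error"
      row$error <- conditionMessage(res)
      return(row)
    }
    row$status <- res$status
    if (!is.null(res$segmentation)) {
      row$area_mm2 <- res$segmentation$area_mm2
      row$circularity <- res$segmentation$circularity
    }
    if (res$status == "ok") {
      row$grade <- res$grade
      row$yi <- res$color$yi
      row$l_star <- res$color$lab[["L_star"]]
      row$a_star <- res$color$lab[["a_star"]]
      row$b_star <- res$color$lab[["b_star"]]
      row$comparisons <- res$decision$comparisons_used
    } else {
      row$error <- res$reason
    }
    row
  })
  results <- do.call(rbind, rows)
  have_labels <- !all(is.na(results$true_grade))
  ok <- results$status == "ok"
  accuracy <- if (have_labels && any(ok)) {
    mean(results$grade[ok] == results$true_grade[ok])
  } else NA_real_
  confusion <- if (have_labels && any(ok)) {
    table(truth = results$true_grade[ok], assigned = results$grade[ok])
  } else NULL
  structure(list(results = results, accuracy = accuracy,
                 confusion = confusion, n_failed = sum(!ok)),
            class = "batch_result")
}

#' @export
print.batch_result <- function(x, ...) {
  cat("<batch_result>", nrow(x$results), "specimens,", x$n_failed,
      "not graded\n")
  if (!is.na(x$accuracy)) {
    cat(sprintf("  accuracy: %.1f%%\n", 100 * x$accuracy))
    print(x$confusion)
  }
  invisible(x)
}

# resolve a manifest data frame into raw_frame_set objects
manifest_to_framesets <- function(manifest) {
  if (nrow(manifest) == 0) stop("empty manifest")
  need <- c("frame1", "dark", "white")
  if (!all(need %in% names(manifest))) {
    stop("manifest needs columns: ", paste(need, collapse = ", "))
  }
  bit_depth <- if ("bit_depth" %in% names(manifest)) manifest$bit_depth else rep(8, nrow(manifest))
  out <- lapply(seq_len(nrow(manifest)), function(i) {
    fcols <- intersect(c("frame1", "frame2", "frame3"), names(manifest))
    paths <- unlist(manifest[i, fcols])
    paths <- paths[!is.na(paths) & nzchar(paths)]
    frames <- lapply(paths, read_raster, bit_depth = bit_depth[i])
    raw_frame_set(frames,
                  dark = read_raster(manifest$dark[i], bit_depth[i]),
                  white = read_raster(manifest$white[i], bit_depth[i]),
                  bit_depth = bit_depth[i],
                  pixel_pitch_mm = if ("pixel_pitch_mm" %in% names(manifest))
                    manifest$pixel_pitch_mm[i] else 0.5)
  })
  attr(out, "labels") <- if ("label" %in% names(manifest)) manifest$label else NULL
  out
}

#' Read an RGB raster from TIFF or PNG
#'
#' @param path File path (.tif/.tiff/.png).
#' @param bit_depth Intensity scale to return values on. Default 8
#'   (0..255).
#' @return H x W x 3 numeric array of intensities.
#' @export
read_raster <- function(path, bit_depth = 8) {
  if (!file.exists(path)) stop("cannot read raster: ", path)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    tif = , tiff = tiff::readTIFF(path),
    png = png::readPNG(path),
    stop("unsupported raster format: .", ext))
  if (length(dim(img)) == 2) img <- array(rep(img, 3), c(dim(img), 3))
  img[, , 1:3, drop = FALSE] * full_scale(bit_depth)
}

#' Write an RGB raster to TIFF (float) or PNG
#'
#' @param img H x W (x 3) numeric array of intensities.
#' @param path Destination path; format chosen by extension.
#' @param bit_depth Intensity scale of \code{img}. Default 8.
#' @export
write_raster <- function(img, path, bit_depth = 8) {
  v <- img / full_scale(bit_depth)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(v, path, bits.per.sample = 32L)
  } else if (ext == "png") {
    png::writePNG(pmin(pmax(v, 0), 1), path)
  } else stop("unsupported raster format: .", ext)
  invisible(path)
}
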