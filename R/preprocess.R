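# Radiometric correction, denoising, frame averaging and quality gating.
# Rasters are H x W x 3 numeric arrays of sensor intensities on the
# 0..full-scale range of the declared bit depth.

full_scale <- function(bit_depth) 2^bit_depth - 1

#' Rec.709 luminance of an RGB raster
#'
#' @param img H x W x 3 array (or N x 3 matrix).
#' @return H x W matrix (or vector) of luminance values on the input scale.
#' @export
luminance <- function(img) {
  w <- c(0.2126, 0.7152, 0.0722)
  if (is.matrix(img) && ncol(img) == 3) return(drop(img %*% w))
  stopifnot(length(dim(img)) == 3, dim(img)[3] == 3)
  img[, , 1] * w[1] + img[, , 2] * w[2] + img[, , 3] * w[3]
}

#' Bundle specimen frames with their reference frames
#'
#' @param frames List of 1-3 H x W x 3 specimen exposures.
#' @param dark H x W x 3 dark-current reference (shutter closed).
#' @param white H x W x 3 white-reference exposure (uniform reflectance
#'   standard in place).
#' @param bit_depth 8 or 16.
#' @param exposure_ms Exposure time (> 0).
#' @param pixel_pitch_mm Physical size of one pixel at the specimen plane.
#'   Default 0.5 mm.
#' @return An object of class \code{raw_frame_set}.
#' @export
raw_frame_set <- function(frames, dark, white, bit_depth = 8,
                          exposure_ms = 100, pixel_pitch_mm = 0.5) {
  if (!is.list(frames)) frames <- list(frames)
  stopifnot(length(frames) >= 1, bit_depth %in% c(8, 16),
            exposure_ms > 0, pixel_pitch_mm > 0)
  d <- dim(frames[[1]])
  ok <- vapply(frames, function(f) identical(dim(f), d), logical(1))
  if (!all(ok) || !identical(dim(dark), d) || !identical(dim(white), d)) {
    stop("all frames and references must share the same H x W x 3 shape")
  }
  if (mean(white) <= mean(dark)) {
    stop("white reference is not brighter than the dark frame on average")
  }
  structure(list(frames = frames, dark = dark, white = white,
                 bit_depth = bit_depth, exposure_ms = exposure_ms,
                 pixel_pitch_mm = pixel_pitch_mm),
            class = "raw_frame_set")
}

#' Pixel-wise mean of repeated exposures
#'
#' Averaging n exposures with i.i.d. additive noise reduces the residual
#' noise standard deviation by sqrt(n); three frames are used in routine
#' acquisition.
#'
#' @param frames List of congruent H x W x 3 arrays (or a single array).
#' @return An array of the same shape.
#' @export
average_frames <- function(frames) {
  if (!is.list(frames)) frames <- list(frames)
  stopifnot(length(frames) >= 1)
  d <- dim(frames[[1]])
  if (!all(vapply(frames, function(f) identical(dim(f), d), logical(1)))) {
    stop("frame shape mismatch: all frames must be congruent")
  }
  Reduce(`+`, frames) / length(frames)
}

#' Flat-field correction with dark and white references
#'
#' Removes illumination non-uniformity and pixel response variation:
#' \deqn{I_{corr} = (I_{raw} - I_{dark}) / (I_{white} - I_{dark}) \times \bar I_{white}}
#' applied per channel, where \eqn{\bar I_{white}} is the spatial mean of
#' the dark-subtracted white reference over the analysis region. Pixels
#' where the white-dark difference falls below \code{eps_frac} of full
#' scale cannot be corrected; they are reported in the \code{excluded}
#' attribute (and set to 0) rather than propagating non-finite values.
#'
#' @param raw,dark,white Congruent H x W x 3 arrays.
#' @param eps_frac Division floor as a fraction of full scale. Default 1e-6.
#' @param bit_depth Bit depth used to interpret \code{eps_frac}. Default 8.
#' @return Corrected array with a logical \code{excluded} attribute
#'   (H x W x 3) marking unusable pixels.
#' @export
flat_field_correct <- function(raw, dark, white, eps_frac = 1e-6,
                               bit_depth = 8) {
  stopifnot(identical(dim(raw), dim(dark)), identical(dim(raw), dim(white)))
  eps <- eps_frac * full_scale(bit_depth)
  denom <- white - dark
  excluded <- abs(denom) < eps
  gain <- apply(white - dark, 3, function(ch) mean(ch))  # per-channel Ibar
  out <- raw * 0
  for (ch in 1:3) {
    d <- denom[, , ch]
    bad <- excluded[, , ch]
    num <- raw[, , ch] - dark[, , ch]
    v <- num
    v[!bad] <- num[!bad] / d[!bad] * gain[ch]
    v[bad] <- 0
    out[, , ch] <- v
  }
  attr(out, "excluded") <- excluded
  out
}

#' Pixels excluded by flat-field correction
#'
#' @param img Output of \code{\link{flat_field_correct}}.
#' @return Logical array, or NULL if nothing was excluded/recorded.
#' @export
excluded_mask <- function(img) attr(img, "excluded")

#' Gaussian denoising
#'
#' Convolution with a normalized Gaussian kernel (weights sum to 1);
#' constant images are fixed points. The default sigma of 1.2 px balances
#' noise suppression against edge blur for boundary-accurate segmentation.
#'
#' @param img H x W matrix or H x W x 3 array.
#' @param sigma Kernel standard deviation in pixels (> 0). Default 1.2.
#' @return Filtered raster, same shape.
#' @export
gaussian_denoise <- function(img, sigma = 1.2) {
  stopifnot(sigma > 0)
  if (is.matrix(img)) return(EBImage::gblur(img, sigma = sigma))
  out <- img
  for (ch in seq_len(dim(img)[3])) {
    out[, , ch] <- EBImage::gblur(img[, , ch], sigma = sigma)
  }
  attr(out, "excluded") <- attr(img, "excluded")
  out
}

#' Preprocessing and quality-gate configuration
#'
#' @param gaussian_sigma Denoising kernel SD in pixels. Default 1.2.
#' @param gate_focus_min Minimum focus score (normalized gradient
#'   contrast, 0..1). Default 0.7.
#' @param gate_uniformity_cv_max Maximum white-reference spatial CV.
#'   Default 0.05.
#' @param gate_saturation_max Maximum fraction of clipped pixels.
#'   Default 0.001.
#' @param target_range Acceptable exposure window as a fraction of dynamic
#'   range for the 99th-percentile luminance. Default c(0.60, 0.80).
#' @param window_mm Side of the central analysis window used for
#'   uniformity and SNR statistics. Default 30 mm.
#' @return An object of class \code{preprocess_config}.
#' @export
preprocess_config <- function(gaussian_sigma = 1.2, gate_focus_min = 0.7,
                              gate_uniformity_cv_max = 0.05,
                              gate_saturation_max = 0.001,
                              target_range = c(0.60, 0.80),
                              window_mm = 30) {
  stopifnot(gaussian_sigma > 0,
            gate_focus_min > 0, gate_focus_min < 1,
            gate_uniformity_cv_max > 0, gate_uniformity_cv_max < 1,
            gate_saturation_max > 0, gate_saturation_max < 1,
            length(target_range) == 2, target_range[1] < target_range[2])
  structure(list(gaussian_sigma = gaussian_sigma,
                 gate_focus_min = gate_focus_min,
                 gate_uniformity_cv_max = gate_uniformity_cv_max,
                 gate_saturation_max = gate_saturation_max,
                 target_range = target_range,
                 window_mm = window_mm),
            class = "preprocess_config")
}

central_window <- function(dims, pixel_pitch_mm, window_mm) {
  half <- round(window_mm / pixel_pitch_mm / 2)
  cr <- round(dims[1] / 2); cc <- round(dims[2] / 2)
  rows <- max(1, cr - half + 1):min(dims[1], cr + half)
  cols <- max(1, cc - half + 1):min(dims[2], cc + half)
  list(rows = rows, cols = cols)
}

sobel_magnitude <- function(lum) {
  kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3)
  gx <- EBImage::filter2(lum, kx)
  gy <- EBImage::filter2(lum, t(kx))
  sqrt(gx^2 + gy^2)
}

# Blur-referenced sharpness in [0, 1]: fraction of Tenengrad gradient
# energy (sum of squared Sobel magnitude) removed by an additional
# reference defocus of sigma_ref px. A sharp image loses most of its
# gradient energy to the extra blur (score near 1); an already-defocused
# image loses little (score near 0). Scale-free in intensity and contrast.
focus_score <- function(lum, sigma_ref = 2) {
  g <- sum(sobel_magnitude(lum)^2)
  if (g <= 0) return(0)
  gb <- sum(sobel_magnitude(EBImage::gblur(lum, sigma = sigma_ref))^2)
  min(max(1 - gb / g, 0), 1)
}

#' Image-quality metrics and acquisition gates
#'
#' Computes, from a frame set:
#' \itemize{
#'   \item \code{snr_db}: 20 log10 of the white-reference mean luminance in
#'     the central analysis window over the dark-frame luminance SD.
#'   \item \code{uniformity_cv}: spatial SD/mean of white-reference
#'     luminance in the central window.
#'   \item \code{saturation_fraction}: worst-case fraction (over frames) of
#'     pixels clipped at 0 or full scale in any channel.
#'   \item \code{focus_score}: normalized mean gradient contrast of the
#'     averaged specimen frame, in [0, 1].
#'   \item \code{pass_flags}: the three acquisition gates (focus,
#'     uniformity, saturation) plus an overall flag.
#' }
#'
#' @param frameset A \code{\link{raw_frame_set}}.
#' @param cfg A \code{\link{preprocess_config}}.
#' @return An object of class \code{quality_metrics}.
#' @export
compute_quality <- function(frameset, cfg = preprocess_config()) {
  stopifnot(inherits(frameset, "raw_frame_set"))
  fs <- full_scale(frameset$bit_depth)
  d <- dim(frameset$white)
  win <- central_window(d[1:2], frameset$pixel_pitch_mm, cfg$window_mm)
  wlum <- luminance(frameset$white)[win$rows, win$cols]
  dlum <- luminance(frameset$dark)
  sigma_noise <- stats::sd(as.vector(dlum))
  snr_warning <- FALSE
  if (sigma_noise == 0) {
    snr_db <- Inf
    snr_warning <- TRUE
    warning("dark-frame noise SD is zero; SNR reported as +Inf")
  } else {
    snr_db <- 20 * log10(mean(wlum) / sigma_noise)
  }
  uniformity_cv <- stats::sd(as.vector(wlum)) / mean(wlum)
  sat <- max(vapply(frameset$frames, function(f) {
    mean(f <= 0 | f >= fs)
  }, numeric(1)))
  # focus is judged on the flat-field-corrected average so that smooth
  # illumination gradients do not mask (de)focus of the actual content
  corr <- flat_field_correct(average_frames(frameset$frames),
                             frameset$dark, frameset$white,
                             bit_depth = frameset$bit_depth)
  fsc <- focus_score(luminance(corr))
  flags <- list(
    focus = fsc > cfg$gate_focus_min,
    uniformity = uniformity_cv < cfg$gate_uniformity_cv_max,
    saturation = sat < cfg$gate_saturation_max
  )
  flags$all <- flags$focus && flags$uniformity && flags$saturation
  structure(list(snr_db = snr_db, uniformity_cv = uniformity_cv,
                 saturation_fraction = sat, focus_score = fsc,
                 pass_flags = flags, snr_warning = snr_warning),
            class = "quality_metrics")
}

#' @export
print.quality_metrics <- function(x, ...) {
  cat("<quality_metrics>\n")
  cat(sprintf("  SNR            : %.1f dB\n", x$snr_db))
  cat(sprintf("  uniformity CV  : %.2f %%  [%s]\n", 100 * x$uniformity_cv,
              if (x$pass_flags$uniformity) "pass" else "FAIL"))
  cat(sprintf("  saturation     : %.3f %%  [%s]\n",
              100 * x$saturation_fraction,
              if (x$pass_flags$saturation) "pass" else "FAIL"))
  cat(sprintf("  focus score    : %.2f  [%s]\n", x$focus_score,
              if (x$pass_flags$focus) "pass" else "FAIL"))
  invisible(x)
}

#' Exposure check against the target dynamic-range window
#'
#' Classifies an exposure by the 99th percentile of luminance relative to
#' full scale: below the target window is under-exposed, above it (where
#' clipping becomes likely) over-exposed.
#'
#' @param img H x W x 3 array of raw intensities.
#' @param cfg A \code{\link{preprocess_config}}.
#' @param bit_depth Bit depth of the encoding. Default 8.
#' @return One of \code{"ok"}, \code{"too_low"}, \code{"too_high"}.
#' @export
check_exposure <- function(img, cfg = preprocess_config(), bit_depth = 8) {
  p99 <- stats::quantile(as.vector(luminance(img)), 0.99, names = FALSE)
  frac <- p99 / full_scale(bit_depth)
  if (frac < cfg$target_range[1]) "too_low"
  else if (frac > cfg$target_range[2]) "too_high"
  else "ok"
}
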