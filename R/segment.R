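# Specimen ROI extraction: Otsu thresholding on luminance, morphological
# refinement, 8-connected component selection and geometric validation.

#' 256-bin intensity histogram
#'
#' @param x Numeric raster or vector of intensities.
#' @param bit_depth Bit depth used to map intensities onto bins. Default 8.
#' @return Integer vector of 256 counts for intensity levels 0..255 (16-bit
#'   input is binned onto the 8-bit scale).
#' @export
image_histogram <- function(x, bit_depth = 8) {
  v <- as.vector(x) / full_scale(bit_depth) * 255
  v <- pmin(pmax(round(v), 0), 255)
  tabulate(v + 1L, nbins = 256L)
}

#' Otsu threshold by exhaustive inter-class variance maximization
#'
#' Scans every candidate cut point T (class 0 = levels 0..T, class 1 =
#' levels T+1..255) and returns the first T maximizing
#' \eqn{\omega_0 \omega_1 (\mu_0 - \mu_1)^2}. When the criterion has a
#' plateau (e.g. an empty gap between two modes), the lowest maximizing cut
#' is reported; any cut on the plateau separates the classes identically.
#'
#' @param histogram Integer vector of 256 counts for levels 0..255.
#' @return An object of class \code{otsu_result} with fields
#'   \code{threshold}, \code{class_probabilities}, \code{class_means},
#'   \code{inter_class_variance}.
#' @export
otsu_threshold <- function(histogram) {
  stopifnot(length(histogram) == 256, all(histogram >= 0))
  n <- sum(histogram)
  if (n == 0) stop("empty histogram")
  if (sum(histogram > 0) < 2) {
    stop("degenerate histogram: all mass in a single intensity level")
  }
  levels <- 0:255
  p <- histogram / n
  omega0 <- cumsum(p)                 # P(level <= T)
  mu_cum <- cumsum(p * levels)
  mu_total <- mu_cum[256]
  # candidates T = 0..254 (index i = T + 1)
  w0 <- omega0[1:255]
  w1 <- 1 - w0
  valid <- w0 > 0 & w1 > 0
  sigma_b <- rep(-Inf, 255)
  mu0 <- mu_cum[1:255] / w0
  mu1 <- (mu_total - mu_cum[1:255]) / w1
  sigma_b[valid] <- (w0 * w1 * (mu0 - mu1)^2)[valid]
  i <- which.max(sigma_b)
  structure(list(threshold = levels[i],
                 class_probabilities = c(omega0 = w0[i], omega1 = w1[i]),
                 class_means = c(mu0 = mu0[i], mu1 = mu1[i]),
                 inter_class_variance = sigma_b[i]),
            class = "otsu_result")
}

# 8-connected component labelling of a logical mask
label_components_8 <- function(mask) {
  stopifnot(is.matrix(mask))
  H <- nrow(mask); W <- ncol(mask)
  idx <- which(mask)
  lab <- matrix(0L, H, W)
  if (length(idx) == 0) return(lab)
  pos <- matrix(0L, H, W)
  pos[idx] <- seq_along(idx)
  r <- ((idx - 1L) %% H) + 1L
  cc <- ((idx - 1L) %/% H) + 1L
  edges <- integer(0)
  for (off in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))) {
    r2 <- r + off[1]; c2 <- cc + off[2]
    ok <- r2 >= 1L & r2 <= H & c2 >= 1L & c2 <= W
    ok[ok] <- mask[cbind(r2[ok], c2[ok])]
    if (any(ok)) {
      edges <- c(edges, rbind(pos[idx[ok]], pos[cbind(r2[ok], c2[ok])]))
    }
  }
  g <- igraph::make_graph(edges = edges, n = length(idx), directed = FALSE)
  comp <- igraph::components(g)$membership
  lab[idx] <- comp
  lab
}

#' Morphological refinement of a binary segmentation
#'
#' In order: opening with a 3 x 3 structuring element (removes isolated
#' speckles), closing with a 5 x 5 element (bridges small gaps, smooths the
#' boundary), then hole filling by connected-component analysis of the
#' background. Idempotent on its own output.
#'
#' @param binary Logical (or 0/1) matrix.
#' @return Logical matrix of the same shape.
#' @export
refine_mask <- function(binary) {
  m <- EBImage::Image(binary * 1)
  m <- EBImage::opening(m, EBImage::makeBrush(3, shape = "box"))
  m <- EBImage::closing(m, EBImage::makeBrush(5, shape = "box"))
  m <- EBImage::fillHull(m)
  matrix(as.numeric(m) > 0.5, nrow = nrow(binary))
}

# chain-code perimeter of a single-component mask: ordered boundary contour
# with unit steps for 4-neighbors and sqrt(2) for diagonals
chain_perimeter <- function(mask) {
  if (sum(mask) == 1) return(4)           # lone pixel: its own boundary
  oc <- EBImage::ocontour(EBImage::Image(mask * 1))[[1]]
  if (nrow(oc) < 2) return(4)
  d <- rbind(diff(oc), oc[1, ] - oc[nrow(oc), ])
  sum(sqrt(rowSums(d^2)))
}

#' Select and validate the specimen region of interest
#'
#' Keeps the largest 8-connected foreground component, measures its area,
#' circularity (4 pi A / P^2, chain-code perimeter) and centroid, and checks
#' the geometry gates: physical area inside \code{area_range_mm2},
#' circularity above \code{circularity_min}, and centroid inside the central
#' \code{central_frac} of both image dimensions. An invalid ROI signals that
#' the specimen should be repositioned and re-imaged.
#'
#' A sharp 25 mm square, note, scores circularity ~pi/4 = 0.785 and fails
#' the default 0.85 gate; acceptable specimens are expected to have rounded
#' outlines.
#'
#' @param mask Logical matrix (foreground = specimen hypothesis).
#' @param pixel_pitch_mm Physical pixel size. Default 0.5 mm.
#' @param area_range_mm2 Acceptable specimen area. Default c(620, 630).
#' @param circularity_min Minimum circularity. Default 0.85.
#' @param central_frac Central fraction of each dimension the centroid must
#'   fall into. Default 0.8.
#' @return An object of class \code{segmentation_result}: \code{mask},
#'   \code{area_mm2}, \code{circularity}, \code{centroid_px},
#'   \code{n_components_rejected}, \code{valid}, \code{failure_reasons}.
#' @export
select_roi <- function(mask, pixel_pitch_mm = 0.5,
                       area_range_mm2 = c(620, 630),
                       circularity_min = 0.85, central_frac = 0.8) {
  stopifnot(is.matrix(mask))
  if (!any(mask)) {
    stop("no specimen found: segmentation mask is empty (reacquisition required)")
  }
  lab <- label_components_8(mask)
  sizes <- tabulate(lab[lab > 0])
  keep <- which.max(sizes)
  roi <- lab == keep
  n_rej <- length(sizes) - 1L
  area_px <- sizes[keep]
  area_mm2 <- area_px * pixel_pitch_mm^2
  per <- chain_perimeter(roi)
  circularity <- 4 * pi * area_px / per^2
  idx <- which(roi)
  centroid <- c(row = mean((idx - 1) %% nrow(roi) + 1),
                col = mean((idx - 1) %/% nrow(roi) + 1))
  lo <- (1 - central_frac) / 2
  central_ok <-
    centroid[1] >= lo * nrow(roi) && centroid[1] <= (1 - lo) * nrow(roi) &&
    centroid[2] >= lo * ncol(roi) && centroid[2] <= (1 - lo) * ncol(roi)
  reasons <- character(0)
  if (area_mm2 < area_range_mm2[1] || area_mm2 > area_range_mm2[2]) {
    reasons <- c(reasons, sprintf("area %.1f mm2 outside [%g, %g]",
                                  area_mm2, area_range_mm2[1], area_range_mm2[2]))
  }
  if (circularity <= circularity_min) {
    reasons <- c(reasons, sprintf("circularity %.3f <= %.2f",
                                  circularity, circularity_min))
  }
  if (!central_ok) {
    reasons <- c(reasons, "centroid outside central region")
  }
  structure(list(mask = roi, area_mm2 = area_mm2, circularity = circularity,
                 centroid_px = centroid, n_components_rejected = n_rej,
                 valid = length(reasons) == 0, failure_reasons = reasons),
            class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat("<segmentation_result>", if (x$valid) "valid" else "INVALID", "\n")
  cat(sprintf("  area        : %.1f mm2\n", x$area_mm2))
  cat(sprintf("  circularity : %.3f\n", x$circularity))
  cat(sprintf("  centroid    : (%.1f, %.1f) px\n",
              x$centroid_px[1], x$centroid_px[2]))
  cat(sprintf("  rejected components: %d\n", x$n_components_rejected))
  if (!x$valid) cat("  reasons: ", paste(x$failure_reasons, collapse = "; "), "\n")
  invisible(x)
}

#' Segment a specimen from a preprocessed image
#'
#' Runs Otsu thresholding on the luminance channel, then evaluates both
#' foreground polarities (specimen darker or brighter than background),
#' refines each candidate mask morphologically and validates it
#' geometrically. The polarity yielding a valid ROI wins; if both or
#' neither are valid, the larger area wins.
#'
#' @param img Preprocessed H x W x 3 array (flat-field corrected, denoised).
#' @param pixel_pitch_mm Physical pixel size. Default 0.5 mm.
#' @param bit_depth Bit depth for histogram binning. Default 8.
#' @param ... Gate parameters passed to \code{\link{select_roi}}.
#' @return A \code{segmentation_result} with the winning polarity's ROI and
#'   an \code{otsu} element holding the threshold diagnostics.
#' @export
segment_specimen <- function(img, pixel_pitch_mm = 0.5, bit_depth = 8, ...) {
  lum <- luminance(img)
  ot <- otsu_threshold(image_histogram(lum, bit_depth = bit_depth))
  thr <- ot$threshold / 255 * full_scale(bit_depth)
  candidates <- list(dark = lum <= thr, bright = lum > thr)
  results <- lapply(candidates, function(m) {
    m <- refine_mask(m)
    if (!any(m)) return(NULL)
    select_roi(m, pixel_pitch_mm = pixel_pitch_mm, ...)
  })
  results <- Filter(Negate(is.null), results)
  if (length(results) == 0) {
    stop("no specimen found: both threshold polarities gave empty masks")
  }
  valid <- vapply(results, function(r) r$valid, logical(1))
  if (any(valid)) {
    pool <- results[valid]
    areas <- vapply(pool, function(r) r$area_mm2, numeric(1))
    best <- pool[[which.max(areas)]]
  } else {
    # neither polarity passed: report the nearer miss (fewest violated
    # gates, then higher circularity) so the failure reasons are about the
    # specimen-like component, not the background
    nfail <- vapply(results, function(r) length(r$failure_reasons), integer(1))
    circ <- vapply(results, function(r) r$circularity, numeric(1))
    best <- results[[order(nfail, -circ)[1]]]
  }
  best$otsu <- ot
  best
}
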