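# Device-independent color math: sensor linearization, RGB -> CIE XYZ
# tristimulus transform, CIELAB, yellowness index, and CIE76 color
# difference. Two conversion paths are maintained throughout:
#
#   * "gamma_linearized": normalize to [0,1], invert the sRGB transfer
#     function (piecewise IEC 61966-2-1 by default, pure power gamma
#     selectable), apply the sRGB/D65 matrix, scale so reference white has
#     Y = 100. This is the physically conventional route and reproduces the
#     reference CIELAB coordinates of the rubber grades.
#   * "raw_linear": apply the matrix directly to 8-bit channel means with no
#     transfer function and unit scale. The reference tristimulus tabulation
#     for the rubber grades, and the yellowness index values used by the
#     grading thresholds, are consistent with this route combined with the
#     "table_consistent" yellowness coefficients.
#
# Every tristimulus vector carries a `path` tag so downstream operations can
# verify which variant they received.

#' sRGB (D65) RGB -> XYZ conversion matrix
#'
#' The standard 3x3 linear-RGB to CIE 1931 XYZ matrix for the sRGB primaries
#' and D65 illuminant. Row 2 (luminance) sums to 1.
#'
#' @return A 3x3 numeric matrix.
#' @export
srgb_d65_matrix <- function() {
  matrix(c(0.4124, 0.3576, 0.1805,
           0.2126, 0.7152, 0.0722,
           0.0193, 0.1192, 0.9505),
         nrow = 3, byrow = TRUE,
         dimnames = list(c("X", "Y", "Z"), c("R", "G", "B")))
}

#' Linearization configuration
#'
#' @param mode One of \code{"srgb_piecewise"} (IEC 61966-2-1 inverse transfer
#'   function, the default), \code{"power_gamma"} (pure power law), or
#'   \code{"none"} (identity on normalized values).
#' @param gamma Exponent for \code{power_gamma} mode (> 0). Default 2.2.
#' @param bit_depth_max Full-scale intensity of the input encoding. Default
#'   255 (8-bit).
#' @return An object of class \code{linearization_config}.
#' @export
linearization_config <- function(mode = c("srgb_piecewise", "power_gamma", "none"),
                                 gamma = 2.2, bit_depth_max = 255) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(gamma), length(gamma) == 1, gamma > 0,
            is.numeric(bit_depth_max), length(bit_depth_max) == 1,
            bit_depth_max > 0)
  structure(list(mode = mode, gamma = gamma, bit_depth_max = bit_depth_max),
            class = "linearization_config")
}

#' Linearize encoded channel intensities
#'
#' Maps encoded intensities in \code{[0, bit_depth_max]} to linear
#' reflectance in \code{[0, 1]}. All modes fix 0 -> 0 and full scale -> 1 and
#' are monotone non-decreasing.
#'
#' @param rgb Numeric vector, matrix or array of encoded intensities.
#' @param cfg A \code{\link{linearization_config}}.
#' @return Linear values in \code{[0, 1]}, same shape as \code{rgb}.
#' @export
linearize <- function(rgb, cfg = linearization_config()) {
  stopifnot(inherits(cfg, "linearization_config"))
  if (any(!is.finite(rgb))) stop("non-finite intensity in input")
  bad <- rgb < 0 | rgb > cfg$bit_depth_max
  if (any(bad)) {
    ch <- c("R", "G", "B")
    idx <- which(bad)[1]
    chn <- if (is.matrix(rgb) && ncol(rgb) == 3) ch[(idx - 1) %/% nrow(rgb) + 1]
           else if (length(rgb) == 3) ch[idx] else as.character(idx)
    stop("intensity out of range [0, ", cfg$bit_depth_max, "] in channel ", chn)
  }
  v <- rgb / cfg$bit_depth_max
  out <- switch(cfg$mode,
    none = v,
    power_gamma = v^cfg$gamma,
    srgb_piecewise = ifelse(v <= 0.04045, v / 12.92,
                            ((v + 0.055) / 1.055)^2.4))
  if (!is.null(dim(rgb))) dim(out) <- dim(rgb)
  out
}

#' Color transform configuration
#'
#' @param matrix 3x3 RGB -> XYZ conversion matrix. Default
#'   \code{\link{srgb_d65_matrix}}.
#' @param output_scale Scalar multiplying the matrix output: use 100 with
#'   normalized linear input (so reference white has Y = 100), 1 for direct
#'   8-bit passthrough.
#' @return An object of class \code{color_transform_config}.
#' @export
color_transform_config <- function(matrix = srgb_d65_matrix(), output_scale = 100) {
  stopifnot(is.matrix(matrix), all(dim(matrix) == c(3, 3)),
            all(is.finite(matrix)),
            is.numeric(output_scale), length(output_scale) == 1,
            is.finite(output_scale))
  structure(list(matrix = matrix, output_scale = output_scale),
            class = "color_transform_config")
}

#' D65 reference white point
#'
#' @param Xn,Yn,Zn Tristimulus values of the reference white
#'   (defaults: D65, 2-degree observer, Yn = 100 convention).
#' @return An object of class \code{white_point}.
#' @export
white_point <- function(Xn = 95.047, Yn = 100.000, Zn = 108.883) {
  stopifnot(Xn > 0, Yn > 0, Zn > 0)
  structure(c(Xn = Xn, Yn = Yn, Zn = Zn), class = "white_point")
}

#' Linear RGB -> CIE XYZ tristimulus values
#'
#' Computes \code{matrix \%*\% rgb * output_scale}. The result carries a
#' \code{path} tag recording which linearization variant produced the input,
#' so downstream consumers can verify they received the intended one.
#'
#' @param rgb_linear Numeric 3-vector (or N x 3 matrix, one color per row).
#' @param cfg A \code{\link{color_transform_config}}.
#' @param path Provenance of the input: \code{"gamma_linearized"} if the
#'   input went through a transfer-function inversion, \code{"raw_linear"}
#'   if raw channel values are transformed directly.
#' @return For a 3-vector input, a named numeric vector \code{c(X, Y, Z)} of
#'   class \code{xyz_color} with attribute \code{path}; for a matrix input,
#'   an N x 3 matrix with the same attribute.
#' @export
rgb_to_xyz <- function(rgb_linear, cfg = color_transform_config(),
                       path = c("gamma_linearized", "raw_linear")) {
  path <- match.arg(path)
  stopifnot(inherits(cfg, "color_transform_config"))
  if (any(!is.finite(rgb_linear))) stop("non-finite value in linear RGB input")
  if (is.matrix(rgb_linear)) {
    stopifnot(ncol(rgb_linear) == 3)
    out <- rgb_linear %*% t(cfg$matrix) * cfg$output_scale
    colnames(out) <- c("X", "Y", "Z")
  } else {
    stopifnot(length(rgb_linear) == 3)
    out <- as.vector(cfg$matrix %*% rgb_linear) * cfg$output_scale
    names(out) <- c("X", "Y", "Z")
    class(out) <- "xyz_color"
  }
  attr(out, "path") <- path
  out
}

# CIE 15:2004 cube-root companding with linear branch below (6/29)^3
lab_f <- function(t) {
  delta <- 6 / 29
  ifelse(t > delta^3, t^(1 / 3), t / (3 * delta^2) + 4 / 29)
}

#' CIE XYZ -> CIELAB
#'
#' Implements the CIE 15:2004 transform, including the linear branch of the
#' companding function below (6/29)^3. Input must share the scale of the
#' white point (Yn = 100 convention).
#'
#' @param xyz Named 3-vector \code{c(X, Y, Z)} or N x 3 matrix.
#' @param wp A \code{\link{white_point}}.
#' @return Named vector \code{c(L_star, a_star, b_star)} of class
#'   \code{lab_color} (or N x 3 matrix).
#' @export
xyz_to_lab <- function(xyz, wp = white_point()) {
  stopifnot(inherits(wp, "white_point"))
  if (any(xyz < 0)) stop("negative tristimulus value; XYZ must be non-negative")
  if (is.matrix(xyz)) {
    fr <- cbind(lab_f(xyz[, 1] / wp[["Xn"]]),
                lab_f(xyz[, 2] / wp[["Yn"]]),
                lab_f(xyz[, 3] / wp[["Zn"]]))
    out <- cbind(L_star = 116 * fr[, 2] - 16,
                 a_star = 500 * (fr[, 1] - fr[, 2]),
                 b_star = 200 * (fr[, 2] - fr[, 3]))
    return(out)
  }
  fx <- lab_f(xyz[[1]] / wp[["Xn"]])
  fy <- lab_f(xyz[[2]] / wp[["Yn"]])
  fz <- lab_f(xyz[[3]] / wp[["Zn"]])
  structure(c(L_star = 116 * fy - 16,
              a_star = 500 * (fx - fy),
              b_star = 200 * (fy - fz)),
            class = "lab_color")
}

#' Yellowness-index coefficient presets
#'
#' @param preset \code{"astm_e313_d65"} uses the D65 / 2-degree coefficient
#'   pair (1.2985, 1.1335); \code{"table_consistent"} uses (1.28, 1.06),
#'   the pair consistent with the reference yellowness tabulation for the
#'   rubber grades when applied to the raw-linear tristimulus path.
#' @param cx,cz Optional explicit coefficient overrides (> 0).
#' @return An object of class \code{yellowness_config}.
#' @export
yellowness_config <- function(preset = c("table_consistent", "astm_e313_d65"),
                              cx = NULL, cz = NULL) {
  preset <- match.arg(preset)
  co <- switch(preset,
               astm_e313_d65 = c(1.2985, 1.1335),
               table_consistent = c(1.28, 1.06))
  if (!is.null(cx)) co[1] <- cx
  if (!is.null(cz)) co[2] <- cz
  stopifnot(co[1] > 0, co[2] > 0)
  structure(list(cx = co[1], cz = co[2], preset = preset),
            class = "yellowness_config")
}

#' Yellowness index from tristimulus values
#'
#' YI = 100 (cx X - cz Z) / Y. Positive values indicate yellowish color;
#' an achromatic point under the matched illuminant scores ~0. Invariant to
#' uniform scaling of (X, Y, Z).
#'
#' @param xyz Named 3-vector \code{c(X, Y, Z)} or N x 3 matrix.
#' @param cfg A \code{\link{yellowness_config}}.
#' @return Numeric YI (scalar or vector).
#' @export
yellowness_index <- function(xyz, cfg = yellowness_config()) {
  stopifnot(inherits(cfg, "yellowness_config"))
  if (is.matrix(xyz)) {
    if (any(xyz[, 2] <= 0)) stop("Y must be strictly positive")
    return(100 * (cfg$cx * xyz[, 1] - cfg$cz * xyz[, 3]) / xyz[, 2])
  }
  if (xyz[[2]] <= 0) stop("Y must be strictly positive")
  100 * (cfg$cx * xyz[[1]] - cfg$cz * xyz[[3]]) / xyz[[2]]
}

#' CIE76 color difference
#'
#' Euclidean distance in CIELAB space. Symmetric; zero iff the colors are
#' equal.
#'
#' @param a,b CIELAB colors: named 3-vectors or N x 3 matrices (rowwise).
#' @return Numeric distance(s).
#' @export
delta_e_ab <- function(a, b) {
  if (is.matrix(a) || is.matrix(b)) {
    a <- rbind(a); b <- rbind(b)
    stopifnot(nrow(a) == nrow(b))
    return(sqrt(rowSums((a - b)^2)))
  }
  sqrt(sum((unclass(a) - unclass(b))^2))
}

#' Full colorimetric summary of a specimen from its mean RGB
#'
#' Computes both conversion paths from a mean 8-bit RGB triple and derives
#' all quantities the grading pipeline uses: raw-linear XYZ (unit scale, no
#' transfer function), gamma-linearized XYZ (Yn = 100 scale), CIELAB from
#' the linearized path, and the yellowness index under both coefficient
#' presets (\code{yi} = table-consistent coefficients on raw-linear XYZ,
#' which is the variant the grading thresholds are defined on;
#' \code{yi_astm} = ASTM D65 coefficients on the linearized path).
#'
#' @param rgb_mean Numeric 3-vector of mean channel intensities
#'   (0..\code{bit_depth_max}).
#' @param lin_cfg Linearization for the gamma path. Default sRGB piecewise.
#' @param wp White point. Default D65.
#' @param id Optional specimen identifier.
#' @return An object of class \code{color_vector}: a list with elements
#'   \code{rgb}, \code{xyz_raw}, \code{xyz_lin}, \code{lab}, \code{yi},
#'   \code{yi_astm}, \code{id}.
#' @export
#' @examples
#' cv <- color_vector(c(124.7, 122.3, 120.2))  # white crepe grade means
#' round(cv$yi, 2)   # ~8.5, near-white
#' round(cv$lab, 2)  # L* ~51.5
color_vector <- function(rgb_mean, lin_cfg = linearization_config(),
                         wp = white_point(), id = NULL) {
  stopifnot(length(rgb_mean) == 3)
  rgb_mean <- as.numeric(rgb_mean)
  xyz_raw <- rgb_to_xyz(rgb_mean, color_transform_config(output_scale = 1),
                        path = "raw_linear")
  xyz_lin <- rgb_to_xyz(linearize(rgb_mean, lin_cfg),
                        color_transform_config(output_scale = 100),
                        path = "gamma_linearized")
  lab <- xyz_to_lab(xyz_lin, wp)
  structure(list(
    rgb = c(R = rgb_mean[1], G = rgb_mean[2], B = rgb_mean[3]),
    xyz_raw = xyz_raw,
    xyz_lin = xyz_lin,
    lab = lab,
    yi = yellowness_index(xyz_raw, yellowness_config("table_consistent")),
    yi_astm = yellowness_index(xyz_lin, yellowness_config("astm_e313_d65")),
    id = id
  ), class = "color_vector")
}

#' @export
print.color_vector <- function(x, ...) {
  cat("<color_vector>", if (!is.null(x$id)) paste0(" id: ", x$id), "\n")
  cat(sprintf("  RGB  : %6.1f %6.1f %6.1f\n", x$rgb[1], x$rgb[2], x$rgb[3]))
  cat(sprintf("  L*a*b*: %6.2f %6.2f %6.2f   (sRGB-linearized path)\n",
              x$lab[1], x$lab[2], x$lab[3]))
  cat(sprintf("  YI   : %6.2f (grading)   %6.2f (ASTM/linearized)\n",
              x$yi, x$yi_astm))
  invisible(x)
}

#' Serialize color vectors to a data frame
#'
#' Flattens a list of \code{\link{color_vector}} objects into one row each,
#' with explicit \code{path} and \code{preset} provenance columns.
#'
#' @param cvs List of \code{color_vector} objects.
#' @return A data frame.
#' @export
color_vectors_to_df <- function(cvs) {
  if (inherits(cvs, "color_vector")) cvs <- list(cvs)
  do.call(rbind, lapply(seq_along(cvs), function(i) {
    v <- cvs[[i]]
    data.frame(id = if (is.null(v$id)) i else v$id,
               R = v$rgb[[1]], G = v$rgb[[2]], B = v$rgb[[3]],
               X_raw = v$xyz_raw[[1]], Y_raw = v$xyz_raw[[2]],
               Z_raw = v$xyz_raw[[3]],
               l_star = v$lab[[1]], a_star = v$lab[[2]], b_star = v$lab[[3]],
               yi = v$yi, yi_astm = v$yi_astm,
               lab_path = attr(v$xyz_lin, "path"),
               yi_path = attr(v$xyz_raw, "path"),
               yi_preset = "table_consistent",
               stringsAsFactors = FALSE, row.names = NULL)
  }))
}
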