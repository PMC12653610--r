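#' Reference colorimetric parameters for the five commercial rubber grades
#'
#' Per-grade mean and standard deviation of the 8-bit RGB channel intensities
#' and of the derived colorimetric quantities (CIELAB coordinates and
#' yellowness index) measured on standardized 25 x 25 mm specimens under
#' controlled illumination. These distributions parameterize the synthetic
#' scene generator and the classifier calibration examples, and anchor the
#' reproduction tests for the color-math pipeline.
#'
#' Grades, palest to darkest substrate: white crepe (premium, near-achromatic),
#' STR5 / STR5L (Standard Thai Rubber mid-grades; 5L carries a slight green
#' undertone, i.e. negative a*), RSS3 and RSS5 (ribbed smoked sheets; RSS3 the
#' most yellow, RSS5 the darkest).
#'
#' @return A data frame with one row per grade and columns
#'   \code{grade}, \code{r}, \code{g}, \code{b} (channel means),
#'   \code{r_sd}, \code{g_sd}, \code{b_sd},
#'   \code{l_star}, \code{a_star}, \code{b_star} (+ \code{_sd} columns),
#'   \code{yi}, \code{yi_sd}.
#' @export
#' @examples
#' rubber_reference_colors()
rubber_reference_colors <- function() {
  data.frame(
    grade = c("white_crepe", "STR5", "STR5L", "RSS3", "RSS5"),
    r    = c(124.7, 129.0, 128.9, 80.4, 27.6),
    g    = c(122.3, 107.6, 109.9, 59.1, 25.0),
    b    = c(120.2,  43.2,  40.9, 21.2, 19.4),
    r_sd = c(3.2, 8.1, 7.8, 9.5, 2.1),
    g_sd = c(2.8, 6.9, 7.2, 7.2, 1.9),
    b_sd = c(2.5, 4.2, 3.9, 3.1, 1.5),
    l_star    = c(51.5, 46.3, 46.9, 26.5, 8.86),
    a_star    = c(0.52, 0.61, -0.88, 4.85, 0.02),
    b_star    = c(1.43, 38.1, 39.8, 26.4, 4.17),
    l_star_sd = c(1.1, 3.8, 3.6, 4.2, 0.95),
    a_star_sd = c(0.15, 0.28, 0.31, 0.89, 0.18),
    b_star_sd = c(0.22, 4.7, 4.9, 5.3, 0.48),
    yi    = c(8.52, 62.8, 64.3, 72.2, 28.8),
    yi_sd = c(0.52, 6.08, 6.21, 7.47, 1.81),
    stringsAsFactors = FALSE
  )
}

#' Canonical grade labels
#'
#' @return Character vector of the five grade labels in reference-table order.
#' @export
rubber_grades <- function() rubber_reference_colors()$grade

grade_row <- function(grade) {
  tab <- rubber_reference_colors()
  i <- match(grade, tab$grade)
  if (is.na(i)) {
    stop("unknown rubber grade '", grade, "'; expected one of: ",
         paste(tab$grade, collapse = ", "))
  }
  tab[i, , drop = FALSE]
}
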