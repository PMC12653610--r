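# Threshold calibration from labelled training measurements and
# hierarchical decision-tree grade assignment.
#
# The tree routes on the grading yellowness index (table-consistent
# coefficients on the raw-linear tristimulus path) plus the CIELAB L* and
# a* coordinates:
#
#   1. YI < 9.5                -> white_crepe   (near-white premium grade)
#   2. else YI < 31            -> RSS5          (dark sheet, low YI despite
#                                                brown appearance)
#   3. else 20 < L* < 36.4     -> RSS3          (dark, strongly yellow)
#   4. else a* < -0.5          -> STR5L         (green undertone)
#   5. else                    -> STR5
#
# The lightness window is evaluated before the a* split because RSS3 has a
# strongly positive a* (~4.9) and a YI overlapping the STR grades: only its
# low lightness separates it. The lower bound L* > 20 guards against
# extreme outliers. All comparisons are strict, and at most five are made
# per specimen.

#' Grade model: decision-tree split points and per-grade ranges
#'
#' @param yi_white_crepe_max Primary split: YI below this is white crepe.
#'   Default 9.5.
#' @param yi_rss5_max Secondary split: remaining YI below this is RSS5.
#'   Default 31.
#' @param a_star_split a* split distinguishing STR5L (below) from STR5.
#'   Default -0.5.
#' @param l_star_rss3_max Upper lightness bound of the RSS3 window; default
#'   36.4, the midpoint between the RSS3 and STR5 mean lightness.
#' @param l_star_outlier_min Lower lightness guard of the RSS3 window.
#'   Default 20.
#' @param per_grade_ranges Optional list: grade -> list of parameter ->
#'   c(lower, upper) intervals (typically mean +/- 2 SD from
#'   \code{\link{calibrate}}). Used to flag out-of-range specimens as
#'   unclassified.
#' @param range_margin Relative widening of each interval half-width
#'   tolerated before a specimen is declared out of range. Default 0.5
#'   (i.e. a +/- 2 SD interval is enforced at +/- 3 SD).
#' @return An object of class \code{grade_model}.
#' @export
grade_model <- function(yi_white_crepe_max = 9.5, yi_rss5_max = 31,
                        a_star_split = -0.5, l_star_rss3_max = 36.4,
                        l_star_outlier_min = 20, per_grade_ranges = NULL,
                        range_margin = 0.5) {
  stopifnot(yi_white_crepe_max < yi_rss5_max,
            l_star_outlier_min < l_star_rss3_max, range_margin >= 0)
  if (!is.null(per_grade_ranges)) {
    for (g in names(per_grade_ranges)) {
      for (p in names(per_grade_ranges[[g]])) {
        iv <- per_grade_ranges[[g]][[p]]
        if (length(iv) != 2 || iv[1] > iv[2]) {
          stop("invalid interval for ", g, "/", p)
        }
      }
    }
  }
  structure(list(yi_white_crepe_max = yi_white_crepe_max,
                 yi_rss5_max = yi_rss5_max,
                 a_star_split = a_star_split,
                 l_star_rss3_max = l_star_rss3_max,
                 l_star_outlier_min = l_star_outlier_min,
                 per_grade_ranges = per_grade_ranges,
                 range_margin = range_margin),
            class = "grade_model")
}

#' Calibrate per-grade parameter ranges from labelled training data
#'
#' Threshold ranges are the sample mean +/- 2 sample standard deviations of
#' each colorimetric parameter within each grade (covering ~95% of training
#' data under normality). Tree split points keep their documented defaults
#' unless overridden via \code{...}.
#'
#' @param training Data frame with columns \code{grade}, \code{yi},
#'   \code{l_star}, \code{a_star}, \code{b_star} (one row per specimen), or
#'   a list of \code{\link{color_vector}} objects plus a \code{labels}
#'   vector.
#' @param labels Grade labels when \code{training} is a list of color
#'   vectors.
#' @param ... Split-point overrides passed to \code{\link{grade_model}}.
#' @return A \code{grade_model} with \code{per_grade_ranges} filled in.
#' @export
calibrate <- function(training, labels = NULL, ...) {
  if (!is.data.frame(training)) {
    stopifnot(!is.null(labels), length(labels) == length(training))
    df <- color_vectors_to_df(training)
    df$grade <- labels
    training <- df
  }
  need <- c("grade", "yi", "l_star", "a_star", "b_star")
  if (!all(need %in% names(training))) {
    stop("training data must have columns: ", paste(need, collapse = ", "))
  }
  counts <- table(training$grade)
  if (any(counts < 2)) {
    stop("grade(s) with fewer than 2 training specimens: ",
         paste(names(counts)[counts < 2], collapse = ", "))
  }
  params <- c("yi", "l_star", "a_star", "b_star")
  ranges <- lapply(split(training, training$grade), function(d) {
    iv <- lapply(params, function(p) {
      m <- mean(d[[p]]); s <- stats::sd(d[[p]])
      c(m - 2 * s, m + 2 * s)
    })
    names(iv) <- params
    iv
  })
  grade_model(per_grade_ranges = ranges, ...)
}

# does v fit grade g's calibrated ranges, widened by the margin?
fits_ranges <- function(v, ranges, margin) {
  for (p in names(ranges)) {
    if (is.null(v[[p]]) || is.na(v[[p]])) next
    iv <- ranges[[p]]
    half <- (iv[2] - iv[1]) / 2
    if (v[[p]] < iv[1] - margin * half || v[[p]] > iv[2] + margin * half) {
      return(FALSE)
    }
  }
  TRUE
}

#' Assign a rubber grade by hierarchical threshold comparison
#'
#' Routes the specimen through the decision tree (see
#' \code{\link{grade_model}}), recording every comparison. If the model
#' carries calibrated per-grade ranges and the specimen fits none of them
#' even after widening by the range margin, the decision is
#' \code{"unclassified"} rather than a silently wrong grade.
#'
#' @param v A \code{\link{color_vector}}, or a list/data frame row with
#'   elements \code{yi}, \code{l_star}, \code{a_star} (and optionally
#'   \code{b_star}).
#' @param m A \code{\link{grade_model}}.
#' @return An object of class \code{grade_decision}: \code{grade},
#'   \code{comparisons_used}, \code{trace} (data frame of rule, value,
#'   outcome), \code{out_of_range}.
#' @export
assign_grade <- function(v, m = grade_model()) {
  stopifnot(inherits(m, "grade_model"))
  if (inherits(v, "color_vector")) {
    v <- list(yi = v$yi, l_star = v$lab[["L_star"]],
              a_star = v$lab[["a_star"]], b_star = v$lab[["b_star"]])
  }
  for (p in c("yi", "l_star", "a_star")) {
    if (is.null(v[[p]]) || is.na(v[[p]])) {
      stop("input is missing colorimetric component '", p, "'")
    }
  }
  trace <- list()
  note <- function(rule, value, outcome) {
    trace[[length(trace) + 1]] <<- data.frame(
      rule = rule, value = value, outcome = outcome,
      stringsAsFactors = FALSE)
  }
  grade <- NULL
  if (v$yi < m$yi_white_crepe_max) {
    note(sprintf("YI < %g", m$yi_white_crepe_max), v$yi, TRUE)
    grade <- "white_crepe"
  } else {
    note(sprintf("YI < %g", m$yi_white_crepe_max), v$yi, FALSE)
    if (v$yi < m$yi_rss5_max) {
      note(sprintf("YI < %g", m$yi_rss5_max), v$yi, TRUE)
      grade <- "RSS5"
    } else {
      note(sprintf("YI < %g", m$yi_rss5_max), v$yi, FALSE)
      if (v$l_star < m$l_star_rss3_max) {
        note(sprintf("L* < %g", m$l_star_rss3_max), v$l_star, TRUE)
        if (v$l_star > m$l_star_outlier_min) {
          note(sprintf("L* > %g", m$l_star_outlier_min), v$l_star, TRUE)
          grade <- "RSS3"
        } else {
          note(sprintf("L* > %g", m$l_star_outlier_min), v$l_star, FALSE)
        }
      } else {
        note(sprintf("L* < %g", m$l_star_rss3_max), v$l_star, FALSE)
      }
      if (is.null(grade)) {
        if (v$a_star < m$a_star_split) {
          note(sprintf("a* < %g", m$a_star_split), v$a_star, TRUE)
          grade <- "STR5L"
        } else {
          note(sprintf("a* < %g", m$a_star_split), v$a_star, FALSE)
          grade <- "STR5"
        }
      }
    }
  }
  out_of_range <- FALSE
  if (!is.null(m$per_grade_ranges)) {
    fits <- vapply(m$per_grade_ranges, fits_ranges, logical(1),
                   v = v, margin = m$range_margin)
    if (!any(fits)) {
      out_of_range <- TRUE
      grade <- "unclassified"
    }
  }
  trace <- do.call(rbind, trace)
  structure(list(grade = grade, comparisons_used = nrow(trace),
                 trace = trace, out_of_range = out_of_range),
            class = "grade_decision")
}

#' @export
print.grade_decision <- function(x, ...) {
  cat("<grade_decision> ", x$grade,
      sprintf("  (%d comparisons)\n", x$comparisons_used))
  for (i in seq_len(nrow(x$trace))) {
    cat(sprintf("  %-12s value %8.2f  -> %s\n", x$trace$rule[i],
                x$trace$value[i], x$trace$outcome[i]))
  }
  invisible(x)
}
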