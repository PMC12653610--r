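# Statistical validation layer: one-way ANOVA, Tukey HSD, ISO 5725-style
# repeatability/reproducibility, Monte-Carlo uncertainty propagation and
# color-chart calibration summaries.

#' One-way analysis of variance
#'
#' Classical fixed-effects between/within decomposition
#' \eqn{Y_{ij} = \mu + \tau_i + \epsilon_{ij}}, fitted via
#' \code{stats::aov}. The degenerate case of zero within-group variance
#' with unequal group means is reported as F = Inf, p = 0 rather than
#' crashing on the division.
#'
#' @param groups List of numeric vectors (>= 2 groups, each >= 2 values),
#'   or a data frame with columns \code{value} and \code{group}.
#' @return An object of class \code{anova_result}: \code{f_statistic},
#'   \code{p_value}, \code{df_between}, \code{df_within},
#'   \code{group_means}, \code{grand_mean}.
#' @export
one_way_anova <- function(groups) {
  if (is.data.frame(groups)) {
    groups <- split(groups$value, groups$group)
  }
  stopifnot(length(groups) >= 2,
            all(vapply(groups, length, integer(1)) >= 2))
  value <- unlist(groups, use.names = FALSE)
  group <- factor(rep(names2(groups), vapply(groups, length, integer(1))))
  fit <- stats::aov(value ~ group)
  tab <- summary(fit)[[1]]
  msw <- tab["Residuals", "Mean Sq"]
  f <- tab[1, "F value"]
  p <- tab[1, "Pr(>F)"]
  msb <- tab[1, "Mean Sq"]
  # zero residual variance (aov may leave rounding residue ~1e-30)
  if (!is.finite(f) || msw <= msb * .Machine$double.eps) {
    if (msb > msw) { f <- Inf; p <- 0 } else { f <- 0; p <- 1 }
  }
  structure(list(f_statistic = f, p_value = p,
                 df_between = tab[1, "Df"],
                 df_within = tab["Residuals", "Df"],
                 group_means = vapply(groups, mean, numeric(1)),
                 grand_mean = mean(value)),
            class = "anova_result")
}

names2 <- function(x) {
  nm <- names(x)
  if (is.null(nm)) nm <- as.character(seq_along(x))
  nm[nm == ""] <- as.character(which(nm == ""))
  nm
}

#' Tukey honestly-significant-difference pairwise comparisons
#'
#' Studentized-range based all-pairs comparisons with family-wise error
#' control, via \code{stats::TukeyHSD}.
#'
#' @param groups List of named numeric vectors or a data frame with
#'   \code{value} and \code{group} columns.
#' @param alpha Family-wise significance level. Default 0.05.
#' @return Data frame with columns \code{pair}, \code{diff}, \code{lwr},
#'   \code{upr}, \code{p_adj}, \code{significant}.
#' @export
tukey_hsd <- function(groups, alpha = 0.05) {
  if (is.data.frame(groups)) groups <- split(groups$value, groups$group)
  if (length(groups) < 2) stop("Tukey HSD needs at least 2 groups")
  value <- unlist(groups, use.names = FALSE)
  group <- factor(rep(names2(groups), vapply(groups, length, integer(1))))
  tk <- stats::TukeyHSD(stats::aov(value ~ group), conf.level = 1 - alpha)$group
  data.frame(pair = rownames(tk), diff = tk[, "diff"], lwr = tk[, "lwr"],
             upr = tk[, "upr"], p_adj = tk[, "p adj"],
             significant = tk[, "p adj"] < alpha,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Repeatability and reproducibility of replicated measurements
#'
#' One-factor precision decomposition in the ISO 5725-2 style: the
#' repeatability variance is the pooled within-session variance, the
#' between-session variance is estimated from the session mean square
#' (clamped at zero), and the reproducibility variance is their sum. Both
#' are reported as coefficients of variation relative to the grand mean.
#'
#' @param values Numeric measurements.
#' @param session Factor/vector identifying the session (or operator/day
#'   cell) of each measurement; each session needs >= 2 replicates.
#' @return An object of class \code{precision_report}:
#'   \code{repeatability_cv}, \code{reproducibility_cv},
#'   \code{repeatability_sd}, \code{between_session_sd},
#'   \code{reproducibility_sd}, \code{grand_mean}, \code{n_sessions},
#'   \code{single_session} flag.
#' @export
precision_metrics <- function(values, session) {
  stopifnot(length(values) == length(session))
  session <- factor(session)
  n_per <- table(session)
  if (any(n_per < 2)) stop("each session needs at least 2 replicates")
  gm <- mean(values)
  if (nlevels(session) == 1) {
    s_r <- stats::sd(values)
    return(structure(list(repeatability_cv = s_r / gm,
                          reproducibility_cv = NA_real_,
                          repeatability_sd = s_r,
                          between_session_sd = NA_real_,
                          reproducibility_sd = NA_real_,
                          grand_mean = gm, n_sessions = 1L,
                          single_session = TRUE),
                     class = "precision_report"))
  }
  fit <- stats::aov(values ~ session)
  tab <- summary(fit)[[1]]
  msw <- tab["Residuals", "Mean Sq"]
  msb <- tab[1, "Mean Sq"]
  # effective replicates per session (exact when balanced)
  n0 <- (sum(n_per) - sum(n_per^2) / sum(n_per)) / (nlevels(session) - 1)
  s_r2 <- msw
  s_L2 <- max(0, (msb - msw) / n0)
  s_R2 <- s_r2 + s_L2
  structure(list(repeatability_cv = sqrt(s_r2) / gm,
                 reproducibility_cv = sqrt(s_R2) / gm,
                 repeatability_sd = sqrt(s_r2),
                 between_session_sd = sqrt(s_L2),
                 reproducibility_sd = sqrt(s_R2),
                 grand_mean = gm, n_sessions = nlevels(session),
                 single_session = FALSE),
            class = "precision_report")
}

#' Monte-Carlo propagation of RGB uncertainty to the yellowness index
#'
#' Samples RGB triples from independent normal distributions, pushes each
#' through the grading yellowness-index path (raw-linear tristimulus
#' transform, table-consistent coefficients), and returns the sample
#' standard deviation of YI as the combined standard uncertainty.
#'
#' @param rgb_mean,rgb_sd Numeric 3-vectors of channel means and SDs.
#' @param n_mc Number of Monte-Carlo draws (>= 1000). Default 1e5.
#' @param seed Integer RNG seed.
#' @return List with \code{u_yi} (standard uncertainty, YI units),
#'   \code{yi_mean}, \code{n_mc}.
#' @export
propagate_uncertainty <- function(rgb_mean, rgb_sd, n_mc = 1e5, seed = 1) {
  stopifnot(length(rgb_mean) == 3, length(rgb_sd) == 3, all(rgb_sd >= 0),
            n_mc >= 1000)
  if (all(rgb_sd == 0)) {
    yi <- yellowness_index(rgb_to_xyz(rgb_mean,
            color_transform_config(output_scale = 1), path = "raw_linear"))
    return(list(u_yi = 0, yi_mean = yi, n_mc = n_mc))
  }
  set.seed(seed)
  draws <- cbind(stats::rnorm(n_mc, rgb_mean[1], rgb_sd[1]),
                 stats::rnorm(n_mc, rgb_mean[2], rgb_sd[2]),
                 stats::rnorm(n_mc, rgb_mean[3], rgb_sd[3]))
  draws <- pmin(pmax(draws, 0.01), 255)
  xyz <- rgb_to_xyz(draws, color_transform_config(output_scale = 1),
                    path = "raw_linear")
  yi <- yellowness_index(xyz, yellowness_config("table_consistent"))
  list(u_yi = stats::sd(yi), yi_mean = mean(yi), n_mc = n_mc)
}

#' Color-chart calibration report
#'
#' Per-patch CIE76 color differences between measured and certified CIELAB
#' coordinates, with summary statistics and a pass fraction against a QC
#' tolerance.
#'
#' @param measured,reference N x 3 matrices (or data frames) of L*, a*, b*
#'   rows, equal lengths.
#' @param tolerance Acceptability threshold on each patch's delta E.
#'   Default 2.0.
#' @return An object of class \code{calibration_report}: \code{table}
#'   (patch, delta_e, pass), \code{mean_de}, \code{sd_de}, \code{max_de},
#'   \code{pass_fraction}, \code{tolerance}.
#' @export
calibration_report <- function(measured, reference, tolerance = 2.0) {
  measured <- as.matrix(measured); reference <- as.matrix(reference)
  if (nrow(measured) != nrow(reference)) {
    stop("measured and reference patch lists differ in length")
  }
  de <- delta_e_ab(measured, reference)
  structure(list(table = data.frame(patch = seq_along(de), delta_e = de,
                                    pass = de <= tolerance),
                 mean_de = mean(de), sd_de = stats::sd(de), max_de = max(de),
                 pass_fraction = mean(de <= tolerance),
                 tolerance = tolerance),
            class = "calibration_report")
}

#' @export
print.calibration_report <- function(x, ...) {
  cat("<calibration_report>\n")
  cat(sprintf("  patches : %d   mean dE %.2f (sd %.2f)   max %.2f\n",
              nrow(x$table), x$mean_de, x$sd_de, x$max_de))
  cat(sprintf("  pass    : %.0f%% at tolerance %.1f\n",
              100 * x$pass_fraction, x$tolerance))
  invisible(x)
}
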