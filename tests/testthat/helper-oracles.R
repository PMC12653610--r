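# Independent brute-force oracles used across the suite. These deliberately
# re-derive results from first principles rather than calling the package's
# own code paths.

# Otsu by direct evaluation of the between-class variance at every cut
otsu_brute <- function(histogram) {
  levels <- 0:255
  n <- sum(histogram)
  best <- -Inf; best_t <- NA
  for (t in 0:254) {
    in0 <- levels <= t
    w0 <- sum(histogram[in0]) / n
    w1 <- 1 - w0
    if (w0 == 0 || w1 == 0) next
    mu0 <- sum(histogram[in0] * levels[in0]) / sum(histogram[in0])
    mu1 <- sum(histogram[!in0] * levels[!in0]) / sum(histogram[!in0])
    s <- w0 * w1 * (mu0 - mu1)^2
    if (s > best) { best <- s; best_t <- t }
  }
  list(threshold = best_t, sigma_b = best)
}

# one-way ANOVA from raw sums of squares
anova_brute <- function(groups) {
  all <- unlist(groups)
  gm <- mean(all)
  ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - gm)^2, 0))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0))
  dfb <- length(groups) - 1
  dfw <- length(all) - length(groups)
  f <- (ssb / dfb) / (ssw / dfw)
  list(f = f, p = stats::pf(f, dfb, dfw, lower.tail = FALSE))
}

# discrete normalized Gaussian kernel, brute-force accumulation
gauss_kernel <- function(sigma, radius = ceiling(4 * sigma)) {
  x <- -radius:radius
  k <- outer(x, x, function(i, j) exp(-(i^2 + j^2) / (2 * sigma^2)))
  k / sum(k)
}

# grade reference rows as plain vectors, for readable tests
ref_rgb <- function(grade) {
  r <- rubber_reference_colors()
  unlist(r[r$grade == grade, c("r", "g", "b")], use.names = FALSE)
}
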