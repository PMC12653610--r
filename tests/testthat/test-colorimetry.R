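test_that("linearization fixes the endpoints and inverts the sRGB transfer function", {
  for (mode in c("none", "power_gamma", "srgb_piecewise")) {
    cfg <- linearization_config(mode)
    expect_identical(linearize(0, cfg), 0)
    expect_equal(linearize(255, cfg), 1)
  }
  # high-precision evaluation of the piecewise inverse transfer function
  expect_equal(linearize(124.7, linearization_config("srgb_piecewise")),
               0.2040182529, tolerance = 1e-8)
  expect_error(linearize(300, linearization_config()), "out of range")
  expect_error(linearize(c(10, -1, 20), linearization_config()), "channel G")
})

test_that("linearization is monotone in every mode", {
  x <- seq(0, 255, by = 0.5)
  for (mode in c("none", "power_gamma", "srgb_piecewise")) {
    y <- linearize(x, linearization_config(mode))
    expect_true(all(diff(y) >= 0))
  }
})

test_that("raw-linear matrix transform reproduces the reference tristimulus table", {
  ref <- rubber_reference_colors()
  expected <- rbind(c(116.9, 122.7, 131.3),   # white crepe
                    c(99.5, 107.5, 56.4),     # STR5
                    c(99.8, 109.0, 54.5),     # STR5L
                    c(58.1, 60.9, 28.7),      # RSS3
                    c(23.8, 25.2, 22.0))      # RSS5
  cfg <- color_transform_config(output_scale = 1)
  for (i in seq_len(nrow(ref))) {
    xyz <- rgb_to_xyz(c(ref$r[i], ref$g[i], ref$b[i]), cfg, path = "raw_linear")
    expect_equal(unclass(xyz), expected[i, ], tolerance = 0.1,
                 ignore_attr = TRUE)
    expect_identical(attr(xyz, "path"), "raw_linear")
  }
  expect_equal(unname(unclass(rgb_to_xyz(c(0, 0, 0), cfg))), c(0, 0, 0),
               ignore_attr = TRUE)
  expect_error(rgb_to_xyz(c(1, NA, 2)), "non-finite")
})

test_that("sRGB-linearized path reproduces the reference CIELAB coordinates", {
  # L* to 0.1, a*/b* to 0.2 against the tabulated grade values
  ref <- rubber_reference_colors()
  for (i in seq_len(nrow(ref))) {
    cv <- color_vector(c(ref$r[i], ref$g[i], ref$b[i]))
    expect_equal(cv$lab[["L_star"]], ref$l_star[i], tolerance = 0.11)
    expect_equal(cv$lab[["a_star"]], ref$a_star[i], tolerance = 0.2)
    expect_equal(cv$lab[["b_star"]], ref$b_star[i], tolerance = 0.2)
  }
})

test_that("CIELAB transform maps the white point to L*=100, a*=b*=0", {
  wp <- white_point()
  lab <- xyz_to_lab(c(wp[["Xn"]], wp[["Yn"]], wp[["Zn"]]), wp)
  expect_equal(unname(unclass(lab)), c(100, 0, 0), tolerance = 1e-12)
  expect_error(xyz_to_lab(c(-1, 50, 50)), "negative")
})

test_that("full white-point round trip through linearize/matrix/CIELAB is exact", {
  cv <- color_vector(c(255, 255, 255))
  # the sRGB matrix white differs from the D65 tabulated white in the 4th
  # decimal; L* must still be 100 to ~1e-3 and exactly 100 with the
  # matrix's own white
  expect_equal(cv$lab[["L_star"]], 100, tolerance = 1e-3)
  m <- srgb_d65_matrix()
  wp_m <- white_point(sum(m[1, ]) * 100, sum(m[2, ]) * 100, sum(m[3, ]) * 100)
  lab <- xyz_to_lab(rgb_to_xyz(linearize(c(255, 255, 255)),
                               color_transform_config()), wp_m)
  expect_equal(unname(unclass(lab)), c(100, 0, 0), tolerance = 1e-9)
})

test_that("lightness is strictly increasing in gray level", {
  # gray 0 is excluded: the yellowness index is undefined at Y = 0
  grays <- seq(5, 255, by = 5)
  L <- vapply(grays, function(g) color_vector(c(g, g, g))$lab[["L_star"]],
              numeric(1))
  expect_true(all(diff(L) > 0))
  expect_true(all(L >= 0 & L <= 100 + 1e-9))
})

test_that("yellowness index matches the reference values on the grading path", {
  ref <- rubber_reference_colors()
  for (i in seq_len(nrow(ref))) {
    cv <- color_vector(c(ref$r[i], ref$g[i], ref$b[i]))
    expect_equal(cv$yi, ref$yi[i], tolerance = 0.1)
  }
})

test_that("yellowness index nulls the achromatic point and scales invariantly", {
  wp <- white_point()
  xyz <- c(X = wp[["Xn"]], Y = wp[["Yn"]], Z = wp[["Zn"]])
  expect_lt(abs(yellowness_index(xyz, yellowness_config("astm_e313_d65"))), 0.01)
  set.seed(11)
  for (i in 1:20) {
    v <- c(X = runif(1, 10, 120), Y = runif(1, 10, 120), Z = runif(1, 10, 120))
    cfg <- yellowness_config("table_consistent")
    expect_equal(yellowness_index(v, cfg), yellowness_index(v * 7.3, cfg),
                 tolerance = 1e-12)
  }
  expect_error(yellowness_index(c(X = 10, Y = 0, Z = 10)), "positive")
})

test_that("CIE76 color difference matches a brute-force component oracle", {
  a <- structure(c(L_star = 50, a_star = 0, b_star = 0), class = "lab_color")
  b <- structure(c(L_star = 53, a_star = 4, b_star = 0), class = "lab_color")
  expect_identical(delta_e_ab(a, a), 0)
  expect_equal(delta_e_ab(a, b), 5)
  expect_equal(delta_e_ab(b, a), 5)
  set.seed(21)
  m1 <- matrix(runif(30, -50, 100), ncol = 3)
  m2 <- matrix(runif(30, -50, 100), ncol = 3)
  brute <- vapply(1:10, function(i) {
    sqrt((m1[i, 1] - m2[i, 1])^2 + (m1[i, 2] - m2[i, 2])^2 +
         (m1[i, 3] - m2[i, 3])^2)
  }, numeric(1))
  expect_equal(delta_e_ab(m1, m2), brute, tolerance = 1e-12)
})

test_that("color vectors serialize with explicit path and preset provenance", {
  cvs <- list(color_vector(ref_rgb("white_crepe"), id = "wc1"),
              color_vector(ref_rgb("RSS3"), id = "r3"))
  df <- color_vectors_to_df(cvs)
  expect_equal(nrow(df), 2)
  expect_identical(df$yi_path, rep("raw_linear", 2))
  expect_identical(df$lab_path, rep("gamma_linearized", 2))
  expect_identical(df$yi_preset, rep("table_consistent", 2))
})
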