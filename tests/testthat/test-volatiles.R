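test_that("fit_calibration recovers exact and noisy lines", {
  std <- tibble::tibble(concentration = c(1, 2, 3),
                        area = c(2, 4, 6) * 1e4, is_area = 1e4)
  cv <- fit_calibration(std)
  expect_equal(cv$slope, 2, tolerance = 1e-12)
  expect_equal(cv$intercept, 0, tolerance = 1e-12)
  expect_equal(cv$r2, 1, tolerance = 1e-12)

  # two points give r2 = 1 by construction
  cv2 <- fit_calibration(tibble::tibble(concentration = c(0.5, 2),
                                        area = c(1, 3) * 1e3,
                                        is_area = 1e3))
  expect_equal(cv2$r2, 1, tolerance = 1e-12)

  # 20 noisy points from a = 1.5, b = 0.1
  set.seed(6)
  conc <- runif(20, 0.1, 5)
  ratio <- 1.5 * conc + 0.1 + rnorm(20, 0, 0.01)
  cv3 <- fit_calibration(tibble::tibble(concentration = conc,
                                        area = ratio * 5e4, is_area = 5e4))
  expect_lt(abs(cv3$slope - 1.5), 0.05)

  expect_error(fit_calibration(tibble::tibble(concentration = c(1, 1),
                                              area = c(1, 2),
                                              is_area = 1)), "identical")
})

test_that("quantify back-calculates, clamps and flags fallback use", {
  cv <- fit_calibration(tibble::tibble(concentration = 0:2,
                                       area = c(0, 2, 4) * 1e4,
                                       is_area = 1e4))
  peaks <- tibble::tibble(
    sample_id = c("a", "a", "b"),
    compound = c("known", "mystery", "known"),
    peak_area = c(4e4, 2e4, 0.0), is_area = 1e4, tissue_mass = 1)
  out <- quantify(peaks, list(known = cv), fallback = cv)
  expect_equal(out$concentration, c(2, 1, 0))
  expect_equal(out$mode, c("standard", "semi-quantitative", "standard"))
  expect_false(any(out$clamped[1:2]))

  # below-intercept ratios clamp to zero with a flag
  cvb <- fit_calibration(tibble::tibble(concentration = c(1, 2),
                                        area = c(3, 5) * 1e4,
                                        is_area = 1e4))
  low <- tibble::tibble(sample_id = "x", compound = "known",
                        peak_area = 1, is_area = 1e4, tissue_mass = 0.01)
  outl <- quantify(low, list(known = cvb))
  expect_equal(outl$concentration, 0)
  expect_true(outl$clamped)

  bad <- tibble::tibble(sample_id = "s9", compound = "known",
                        peak_area = 1, is_area = 0, tissue_mass = 1)
  expect_error(quantify(bad, list(known = cv)), "s9")
  expect_error(quantify(low, list(other = cv)), "fallback")
})

test_that("composition forms percentages that sum to 100 and scale-invariantly", {
  conc <- make_conc(c(a = 2, b = 1, c = 1))
  comp <- composition(conc)
  expect_equal(sort(comp$percentage, decreasing = TRUE), c(50, 25, 25))
  expect_equal(sum(comp$percentage), 100, tolerance = 1e-9)

  # single-compound class is 100%
  comp1 <- composition(conc, compounds = "a")
  expect_equal(comp1$percentage, 100)

  # permutation of compound order and uniform scaling change nothing
  conc_perm <- conc[c(3, 1, 2), ]
  conc_scaled <- conc
  conc_scaled$concentration <- conc_scaled$concentration * 7.3
  get <- function(x) {
    cp <- composition(x)
    setNames(cp$percentage, cp$compound)[c("a", "b", "c")]
  }
  expect_equal(get(conc), get(conc_perm))
  expect_equal(get(conc), get(conc_scaled))

  # all-zero samples are excluded and recorded
  zero <- make_conc(c(a = 0, b = 0), sample_id = "z")
  both <- dplyr::bind_rows(conc, zero)
  cb <- composition(both)
  expect_false("z" %in% cb$sample_id)
  expect_equal(attr(cb, "excluded_samples"), "z")
})

test_that("relative_change matches hand arithmetic and inverts correctly", {
  conc <- dplyr::bind_rows(
    make_conc(c(x = 8.7), stage = "EL-18", sample_id = "m18"),
    make_conc(c(x = 5.0), stage = "EL-26", sample_id = "m26"))
  expect_equal(relative_change(conc, "x", c("MA", "EL-18"),
                               c("MA", "EL-26")), 74, tolerance = 1e-12)
  r_ab <- relative_change(conc, "x", c("MA", "EL-18"), c("MA", "EL-26"))
  r_ba <- relative_change(conc, "x", c("MA", "EL-26"), c("MA", "EL-18"))
  expect_equal((1 + r_ab / 100) * (1 + r_ba / 100), 1, tolerance = 1e-12)

  # equal means give 0
  same <- dplyr::bind_rows(
    make_conc(c(x = 3), stage = "EL-18", sample_id = "a"),
    make_conc(c(x = 3), stage = "EL-26", sample_id = "b"))
  expect_equal(relative_change(same, "x", c("MA", "EL-18"),
                               c("MA", "EL-26")), 0)

  zero <- dplyr::bind_rows(
    make_conc(c(x = 3), stage = "EL-18", sample_id = "a"),
    make_conc(c(x = 0), stage = "EL-26", sample_id = "b"))
  expect_error(relative_change(zero, "x", c("MA", "EL-18"),
                               c("MA", "EL-26")), "zero")
})

test_that("pca_chemotype matches an SVD oracle and handles symmetry", {
  # perfectly collinear two-compound data -> PC1 explains everything
  x <- cbind(a = c(1, 2, 3, 4), b = 2 * c(1, 2, 3, 4))
  p <- pca_chemotype(x)
  expect_equal(unname(p$percent_variance[1]), 100, tolerance = 1e-9)

  # symmetric cross: two equal 50% components
  x2 <- rbind(c(-1, -1), c(1, 1), c(-1, 1), c(1, -1))
  p2 <- pca_chemotype(x2)
  expect_equal(unname(p2$percent_variance), c(50, 50), tolerance = 1e-9)

  set.seed(15)
  for (i in 1:10) {
    m <- matrix(rnorm(24 * 12), 24, 12)
    p3 <- pca_chemotype(m)
    sv <- prcomp(m, center = TRUE, scale. = FALSE)
    expect_equal(unname(p3$percent_variance),
                 100 * sv$sdev^2 / sum(sv$sdev^2), tolerance = 1e-8)
    # permutation of compound columns leaves explained variance unchanged
    p4 <- pca_chemotype(m[, sample(12)])
    expect_equal(p4$percent_variance, p3$percent_variance,
                 tolerance = 1e-8)
    expect_equal(sum(p3$percent_variance), 100, tolerance = 1e-9)
  }
})

test_that("pca_chemotype rejects zero-variance compounds under scaling", {
  m <- cbind(a = rnorm(5), flat = rep(2, 5))
  expect_error(pca_chemotype(m, scale = TRUE), "flat")
  expect_silent(pca_chemotype(m, scale = FALSE))
})
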