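# The preprocessing chain: trim -> max-normalize -> Savitzky-Golay -> center.

random_table <- function(n = 8, B = 40, seed = 1, wl = NULL) {
  set.seed(seed)
  if (is.null(wl)) wl <- seq(900, 1700, length.out = B)
  pixel_spectra_table(matrix(runif(n * B, 0.1, 1), n, B), wl,
                      rep(c("healthy", "infested"), length.out = n),
                      data.frame(sample_id = "s", cultivar = "", orientation = "",
                                 row = seq_len(n), col = 1L))
}

test_that("trimming keeps exactly the bands inside the window", {
  tab <- random_table(B = 4, wl = c(900, 1000, 1100, 1700))
  expect_identical(trim_bands(tab, 900, 1700)$spectra, tab$spectra)
  two <- trim_bands(tab, 950, 1150)
  expect_identical(two$wavelengths, c(1000, 1100))
  expect_identical(two$spectra, tab$spectra[, 2:3])
  # random windows vs a comparison-loop oracle
  set.seed(4)
  big <- random_table(B = 50, seed = 5)
  for (i in 1:5) {
    lo <- runif(1, 900, 1500); hi <- lo + runif(1, 30, 250)
    keep <- integer(0)
    for (b in seq_along(big$wavelengths)) {
      if (big$wavelengths[b] >= lo && big$wavelengths[b] <= hi) {
        keep <- c(keep, b)
      }
    }
    if (!length(keep)) {
      expect_error(trim_bands(big, lo, hi), class = "calyxscan_parameter_error")
    } else {
      expect_identical(trim_bands(big, lo, hi)$wavelengths,
                       big$wavelengths[keep])
    }
  }
  expect_error(trim_bands(tab, 1710, 1800), class = "calyxscan_parameter_error")
})

test_that("max normalization scales every spectrum to peak exactly at 1", {
  tab <- random_table(6, 20, seed = 2)
  out <- max_normalize(tab)
  expect_true(all(apply(out$spectra, 1, max) == 1))
  # constant positive row -> all ones
  const <- random_table(1, 5, seed = 3)
  const$spectra[1, ] <- 3.7
  expect_identical(max_normalize(const)$spectra[1, ], rep(1, 5))
  row124 <- random_table(1, 3, seed = 3)
  row124$spectra[1, ] <- c(1, 2, 4)
  expect_identical(max_normalize(row124)$spectra[1, ], c(0.25, 0.5, 1))
  # scale invariance under any positive gain
  set.seed(7)
  for (g in runif(3, 0.1, 9)) {
    scaled <- tab; scaled$spectra <- g * tab$spectra
    expect_equal(max_normalize(scaled)$spectra, out$spectra,
                 tolerance = 1e-12)
  }
  bad <- tab; bad$spectra[3, ] <- -1
  expect_error(max_normalize(bad), "3",
               class = "calyxscan_degenerate_spectrum_error")
})

test_that("Savitzky-Golay smoothing reproduces low-order polynomials", {
  B <- 80
  tab <- random_table(3, B, seed = 6)
  # rows sampled from degree <= 2 polynomials in the band index
  x <- seq_len(B)
  tab$spectra[1, ] <- 2 + 0.5 * x
  tab$spectra[2, ] <- 1 - 0.03 * x + 0.002 * x^2
  tab$spectra[3, ] <- 4
  sm <- savgol_smooth(tab, window = 31, order = 2)
  interior <- 16:(B - 15)
  expect_equal(sm$spectra[, interior], tab$spectra[, interior],
               tolerance = 1e-8)
  # window 1 is the identity
  expect_identical(savgol_smooth(tab, 1, 0)$spectra, tab$spectra)
  expect_error(savgol_smooth(random_table(2, 10), 11, 2),
               class = "calyxscan_parameter_error")
})

test_that("window-5 order-2 interior weights equal the normal-equations solution", {
  # independent derivation: solve the local least-squares system directly
  coefs <- oracle_sg_central_coefs(5, 2)
  expect_equal(coefs, c(-3, 12, 17, 12, -3) / 35, tolerance = 1e-12)
  # a unit impulse propagated through the package filter exposes its weights
  B <- 11
  tab <- random_table(1, B, seed = 8)
  tab$spectra[1, ] <- 0; tab$spectra[1, 6] <- 1
  sm <- savgol_smooth(tab, 5, 2)
  expect_equal(sm$spectra[1, 4:8], rev(coefs), tolerance = 1e-12)
})

test_that("smoothing commutes with adding a global quadratic (interior)", {
  B <- 60
  tab <- random_table(2, B, seed = 9)
  poly <- 0.3 + 0.01 * seq_len(B) - 1e-4 * seq_len(B)^2
  shifted <- tab; shifted$spectra <- sweep(tab$spectra, 2, poly, `+`)
  a <- savgol_smooth(shifted, 15, 2)$spectra
  b <- sweep(savgol_smooth(tab, 15, 2)$spectra, 2, poly, `+`)
  interior <- 8:(B - 7)
  expect_equal(a[, interior], b[, interior], tolerance = 1e-10)
})

test_that("mean centering stores and reuses the training mean", {
  tab <- random_table(10, 25, seed = 10)
  fit <- mean_center(tab)
  expect_lt(max(abs(colMeans(fit$table$spectra))), 1e-10)
  # centering again with the same mean subtracts ~0
  again <- mean_center(fit$table, fit$center)
  expect_equal(again$table$spectra,
               sweep(fit$table$spectra, 2, fit$center), tolerance = 1e-12)
  single <- random_table(1, 5, seed = 11)
  expect_identical(mean_center(single)$table$spectra[1, ], rep(0, 5))
  expect_error(mean_center(tab, numeric(3)),
               class = "calyxscan_alignment_error")
})

test_that("the chain runs in fixed order and conserves rows", {
  tab <- random_table(12, 64, seed = 12)
  cfg <- preprocess_config(trim_low_nm = 950, trim_high_nm = 1650,
                           sg_window = 15)
  out <- preprocess(tab, cfg)
  expect_identical(nrow(out$table$spectra), 12L)
  expect_true(all(out$table$wavelengths >= 950 &
                    out$table$wavelengths <= 1650))
  expect_lt(max(abs(colMeans(out$table$spectra))), 1e-10)
  # validation reuse: centering with the stored mean reproduces train stats
  val <- random_table(5, 64, seed = 13)
  vout <- preprocess(val, cfg, center = out$center)
  expect_identical(length(out$center), ncol(vout$table$spectra))
  # invalid configurations are rejected up front
  expect_error(preprocess_config(sg_window = 30), "odd")
  expect_error(preprocess_config(sg_window = 5, sg_order = 7), "order")
  expect_error(preprocess_config(trim_low_nm = 1700, trim_high_nm = 900))
})
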