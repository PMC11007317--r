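test_that("a bin-centred sinusoid yields total band power A^2/2", {
  fs <- 500
  t <- (0:(30 * fs - 1)) / fs
  x <- rbind(10 * sin(2 * pi * 2 * t))
  sp <- epoch_psd(x, fs)
  expect_equal(sp$freq[2] - sp$freq[1], 0.2)
  expect_equal(band_power(sp, swa_band()), 50, tolerance = 0.01,
               ignore_attr = TRUE)
  # off-band power is negligible
  expect_lt(band_power(sp, artifact_band()), 1e-6)
})

test_that("a constant epoch puts all power at 0 Hz", {
  fs <- 100
  sp <- epoch_psd(rbind(rep(5, 30 * fs)), fs)
  expect_equal(sp$power[1, 1], 25)
  expect_lt(max(sp$power[1, -1]), 1e-20)
  expect_equal(band_power(sp, swa_band()), 0, ignore_attr = TRUE)
})

test_that("PSD bin sum satisfies Parseval against the windowed mean square", {
  fs <- 250
  set.seed(5)
  x <- rnorm(30 * fs, sd = 3)
  sp <- epoch_psd(rbind(x), fs)
  # exact identity: bin sum equals mean^2 plus window-corrected power,
  # per subepoch, averaged
  nsub <- 5 * fs
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(nsub - 1)) / nsub)
  ref <- mean(vapply(1:6, function(s) {
    seg <- x[((s - 1) * nsub + 1):(s * nsub)]
    mean(seg)^2 + sum(((seg - mean(seg)) * w)^2) / sum(w^2)
  }, 0))
  expect_equal(sum(sp$power), ref, tolerance = 1e-10)
  # and the raw sample mean square agrees at 30-s length
  expect_equal(sum(sp$power) / mean(x^2), 1, tolerance = 0.05)
})

test_that("epoch length must divide into subepochs", {
  expect_error(epoch_psd(rbind(rnorm(1001)), 100), class = "swatopo_parameter_error")
})

test_that("band_power selects inclusive bin ranges", {
  sp <- list(freq = seq(0, 10, by = 0.2), power = rbind(rep(0, 51)))
  sp$power[1, which(abs(sp$freq - 2.0) < 1e-9)] <- 7
  expect_equal(band_power(sp, swa_band()), 7, ignore_attr = TRUE)
  expect_equal(band_power(sp, band(4.6, 10)), 0, ignore_attr = TRUE)
  # edge bins are included
  sp$power[1, ] <- 0
  sp$power[1, which(abs(sp$freq - 0.8) < 1e-9)] <- 1
  sp$power[1, which(abs(sp$freq - 4.6) < 1e-9)] <- 2
  expect_equal(band_power(sp, swa_band()), 3, ignore_attr = TRUE)
  expect_error(band_power(sp, band(20, 40)), class = "swatopo_parameter_error")
})

test_that("artifact screening flags isolated high-power epochs", {
  n <- 31
  base <- matrix(10, n, 3)
  swa <- fake_band_power(base, rep("N2", n))
  hf <- fake_band_power(base / 10, rep("N2", n), bd = artifact_band())
  expect_false(any(detect_artifacts(swa, hf)))   # flat power, no flags

  spike <- base
  spike[16, ] <- 100
  swa2 <- fake_band_power(spike, rep("N2", n))
  mask <- detect_artifacts(swa2, hf, window = 15, factor_swa = 2)
  expect_true(mask[16])
  expect_identical(sum(mask), 1L)

  # infinite factors flag nothing
  expect_false(any(detect_artifacts(swa2, hf, factor_swa = Inf,
                                    factor_hf = Inf)))
  expect_error(detect_artifacts(swa, hf, window = 2),
               class = "swatopo_parameter_error")
})

test_that("artifact thresholds are computed within stage class", {
  # high REM power must not flag NREM epochs at the transition
  stages <- c(rep("N2", 15), rep("REM", 15))
  p <- matrix(c(rep(10, 15), rep(100, 15)), ncol = 1)
  swa <- fake_band_power(p, stages)
  hf <- fake_band_power(p * 0, stages, bd = artifact_band())
  expect_false(any(detect_artifacts(swa, hf)))
})

test_that("swa_map averages artifact-free N2/N3 epochs", {
  p <- rbind(c(1, 2), c(3, 6), c(100, 100), c(50, 50))
  bp <- fake_band_power(p, c("N2", "N3", "N2", "REM"))
  bp <- set_artifacts(bp, c(FALSE, FALSE, TRUE, FALSE))
  m <- swa_map(bp)
  expect_equal(m$value, c(2, 4))            # mean of epochs 1 and 2
  # permutation invariance over epoch order
  bp2 <- fake_band_power(p[c(2, 4, 1, 3), ], c("N3", "REM", "N2", "N2"))
  bp2 <- set_artifacts(bp2, c(FALSE, FALSE, FALSE, TRUE))
  expect_equal(swa_map(bp2)$value, m$value)
  # all flagged -> error
  bp3 <- set_artifacts(bp, c(TRUE, TRUE, TRUE, FALSE))
  expect_error(swa_map(bp3), class = "swatopo_validation_error")
})

test_that("bad-channel interpolation is a convex combination of donors", {
  mont <- mini_montage()
  # constant map: interpolated channel receives the constant
  mc <- topomap(stats::setNames(rep(4, 12), mont$label), "absolute")
  expect_equal(interpolate_bad_channels(mc, mont, "P4")$value, rep(4, 12))

  set.seed(8)
  v <- stats::setNames(runif(12, 10, 100), mont$label)
  m <- topomap(v, "absolute")
  out <- interpolate_bad_channels(m, mont, c("CP4", "P6"), k = 4)
  good <- setdiff(mont$label, c("CP4", "P6"))
  rng <- range(v[good])
  got <- stats::setNames(out$value, out$electrode)
  expect_true(all(got[c("CP4", "P6")] >= rng[1] & got[c("CP4", "P6")] <= rng[2]))
  expect_identical(got[good], v[good])      # donors untouched
})

test_that("symmetrically placed donors average evenly", {
  mont <- montage(tibble::tibble(
    label = c("L", "M", "R", "far"),
    x = c(-50, 0, 50, 0), y = c(0, 0, 0, -85), z = c(
      sqrt(85^2 - 2500), 85, sqrt(85^2 - 2500), 0)
  ), head_radius = 85)
  m <- topomap(c(L = 80, M = 0, R = 120, far = 1000), "absolute")
  out <- interpolate_bad_channels(m, mont, "M", k = 2)
  expect_equal(out$value[out$electrode == "M"], 100)
})

test_that("relativize and log_map enforce and preserve their invariants", {
  m <- topomap(c(a = 1, b = 3), "absolute")
  r <- relativize(m)
  expect_equal(r$value, c(0.5, 1.5))
  expect_identical(attr(r, "kind"), "relative")

  set.seed(9)
  m2 <- topomap(stats::setNames(runif(20, 0.1, 9), paste0("e", 1:20)),
                "absolute")
  expect_equal(mean(relativize(m2)$value), 1, tolerance = 1e-13)

  lg <- log_map(relativize(m))
  expect_equal(lg$value, c(log(0.5), log(1.5)))
  expect_equal(log_map(relativize(topomap(c(a = 2, b = 2), "absolute")))$value,
               c(0, 0))
  expect_error(relativize(topomap(c(a = 0, b = 0), "absolute")),
               class = "swatopo_validation_error")
  expect_error(log_map(r)$value, NA)
  expect_error(log_map(m), class = "swatopo_parameter_error")
})

test_that("relativize after interpolation keeps the mean-1 invariant", {
  mont <- mini_montage()
  set.seed(10)
  v <- stats::setNames(runif(12, 1, 5), mont$label)
  m <- interpolate_bad_channels(topomap(v, "absolute"), mont, "FT8")
  expect_equal(mean(relativize(m)$value), 1, tolerance = 1e-13)
})
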