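test_that("EDF write/read round-trips labels, rate and quantized samples", {
  set.seed(7)
  x <- matrix(rnorm(2 * 1000, sd = 50), 2)
  rec <- raw_recording(x, c("Cz", "C3"), 250)
  path <- withr::local_tempfile(fileext = ".edf")
  write_edf(rec, path)
  back <- read_edf(path)
  expect_identical(back$channel_labels, c("Cz", "C3"))
  expect_equal(back$sampling_rate, 250)
  # one quantization step is 0.01 uV at this amplitude
  expect_lt(max(abs(back$samples - rec$samples)), 0.005 + 1e-12)
  # write-then-read is idempotent: a second pass is bit-exact
  path2 <- withr::local_tempfile(fileext = ".edf")
  write_edf(back, path2)
  expect_identical(read_edf(path2)$samples, back$samples)
})

test_that("EDF reader rejects duplicated channel labels and bad headers", {
  rec <- raw_recording(matrix(0, 2, 500), c("a", "b"), 250)
  path <- withr::local_tempfile(fileext = ".edf")
  write_edf(rec, path)
  # patch the second label field (bytes 273..288) to duplicate the first
  con <- file(path, "r+b")
  seek(con, 256, rw = "write")
  writeChar(formatC("a", width = -16), con, nchars = 16, eos = NULL)
  seek(con, 272, rw = "write")
  writeChar(formatC("a", width = -16), con, nchars = 16, eos = NULL)
  close(con)
  expect_error(read_edf(path), "duplicated channel label")
  # not-an-EDF header
  bad <- withr::local_tempfile()
  writeLines("this is not edf and certainly not binary", bad)
  expect_error(read_edf(bad), class = "swatopo_error")
})

test_that("BrainVision triplet round-trips and reports missing components", {
  x <- matrix(round(rnorm(3 * 400, sd = 20)), 3)  # integers: exact in float32
  rec <- raw_recording(x, c("Fz", "Cz", "Pz"), 200)
  base <- withr::local_tempfile(fileext = ".vhdr")
  write_brainvision(rec, base)
  back <- read_brainvision(base)
  expect_identical(back$channel_labels, rec$channel_labels)
  expect_equal(back$sampling_rate, 200)
  expect_equal(back$samples, rec$samples, ignore_attr = TRUE)
  # remove the data file: error must name it
  eeg <- sub("\\.vhdr$", ".eeg", base)
  unlink(eeg)
  expect_error(read_brainvision(base), basename(eeg), fixed = TRUE)
})

test_that("hypnogram parser maps aliases, reports bad tokens with line number", {
  path <- withr::local_tempfile()
  writeLines(c("W", "w", "0", "1", "n2", "3", "R", "REM", "5"), path)
  hyp <- read_hypnogram(path)
  expect_identical(hyp$stages,
                   c("W", "W", "W", "N1", "N2", "N3", "REM", "REM", "REM"))
  expect_identical(hyp$lights_off, 0L)
  expect_identical(hyp$wake_up, 9L)

  writeLines(c("W", "N2", "N4"), path)
  expect_error(read_hypnogram(path), "line 3")
  writeLines(character(), path)
  expect_error(read_hypnogram(path), "no epochs")
})

test_that("hypnogram header lines set epoch length and in-bed window", {
  path <- withr::local_tempfile()
  writeLines(c("# epoch_length: 30", "# lights_off: 1", "# wake_up: 4",
               "W", "N2", "N2", "N3", "W"), path)
  hyp <- read_hypnogram(path)
  expect_identical(hyp$lights_off, 1L)
  expect_identical(hyp$wake_up, 4L)
  # writer round trip
  out <- withr::local_tempfile()
  write_hypnogram(hyp, out)
  hyp2 <- read_hypnogram(out)
  expect_identical(hyp2$stages, hyp$stages)
  expect_identical(hyp2$lights_off, hyp$lights_off)
  expect_identical(hyp2$wake_up, hyp$wake_up)
})

test_that("behavior table computes scores and validates bounds", {
  path <- withr::local_tempfile()
  writeLines(c("subject_id\tcontribution\tbelief\tage",
               "s1\t10\t10\t21", "s2\t20\t10\t24", "s3\t0\t20\t19"), path)
  beh <- read_behavior(path)
  expect_identical(beh$score, c(0L, 10L, -20L))
  expect_true("age" %in% names(beh))

  writeLines(c("subject_id\tcontribution\tbelief", "s1\t25\t10"), path)
  expect_error(read_behavior(path), class = "swatopo_validation_error")
})

test_that("montage IO round-trips exactly and validates the sphere", {
  m <- standard_montage_59()
  expect_identical(nrow(m), 59L)
  expect_false(anyDuplicated(m$label) > 0)
  expect_true(all(c("C6", "CP4", "CP6", "FT8", "P4", "P6") %in% m$label))
  r <- sqrt(m$x^2 + m$y^2 + m$z^2)
  expect_equal(r, rep(85, 59), tolerance = 1e-9)

  path <- withr::local_tempfile()
  write_montage(m, path)
  m2 <- read_montage(path)
  expect_identical(m2$label, m$label)
  expect_identical(m2$x, m$x)

  off <- m
  off$z[1] <- off$z[1] + 5
  expect_error(montage(off, head_radius = 85), "sphere")
})

test_that("topomap TSV round-trips values exactly", {
  v <- c(Cz = 1.0, Pz = exp(1) / 7, Fz = 1 / 3)
  m <- topomap(v * 3 / sum(v), "relative")
  path <- withr::local_tempfile()
  write_topomap(m, path)
  back <- read_topomap(path)
  expect_identical(back$value, m$value)
  expect_identical(back$electrode, m$electrode)
  expect_identical(attr(back, "kind"), "relative")
})

test_that("cluster report JSON is stable and survives zero clusters", {
  set.seed(11)
  mont <- mini_montage()
  maps <- matrix(rnorm(12 * 12), 12, dimnames = list(NULL, mont$label))
  ds <- swa_dataset(maps, rnorm(12), mont = mont)
  ct <- cluster_permutation_test(ds, adjacency_graph(mont, 40),
                                 n_permutations = 200, seed = 3)
  p1 <- withr::local_tempfile(fileext = ".json")
  p2 <- withr::local_tempfile(fileext = ".json")
  write_cluster_report(ct, p1)
  write_cluster_report(ct, p2)
  expect_identical(readLines(p1), readLines(p2))   # byte-identical rewrite
  rep <- read_cluster_report(p1)
  expect_identical(rep$parameters$n_permutations, ct$n_permutations)
  expect_true(!is.null(rep$null_max_size_counts))
})
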