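test_that("csv recordings load with preserved channel order and metadata", {
  labs8 <- c("P4", "T8", "C4", "F4", "F3", "C3", "T7", "P3")
  set.seed(1)
  d <- matrix(rnorm(8 * 400), 8, 400)
  p <- write_csv_recording(d, labs8)
  rec <- load_recording(p, format = "csv", fs = 250)
  expect_s3_class(rec, "mc_recording")
  expect_equal(dim(rec), c(8L, 400L))
  expect_equal(rec$fs, 250)
  expect_equal(rec$channel_labels, labs8)
  expect_false(rec$standardized)
  expect_equal(unname(rec$data), d)

  labs10 <- c(labs8, "O1", "O2")
  d10 <- matrix(rnorm(10 * 300), 10, 300)
  rec10 <- load_recording(write_csv_recording(d10, labs10), fs = 100)
  expect_equal(nrow(rec10$data), 10L)
  expect_true(all(c("O1", "O2") %in% rec10$channel_labels))
})

test_that("csv loader rejects contract violations", {
  d <- matrix(rnorm(4 * 300), 4, 300)
  p <- write_csv_recording(d, paste0("ch", 1:4))
  expect_error(load_recording(p, format = "csv", fs = 100, labels = c("a", "b", "c")),
               "label count")
  expect_error(load_recording(p, format = "csv"), "fs must be supplied")
  expect_error(load_recording(tempfile(), format = "csv", fs = 100),
               "not found")
  bad <- tempfile(fileext = ".csv")
  writeLines(c("a,b", "1,x", "2,3"), bad)
  expect_error(load_recording(bad, format = "csv", fs = 100), "non-numeric")
})

test_that("EDF round-trip recovers rate, labels and signal", {
  set.seed(7)
  d <- matrix(rnorm(3 * 500, sd = 50), 3, 500)
  p <- write_edf_fixture(d, fs = 100, labels = c("F3", "C3", "O1"))
  rec <- load_recording(p)                 # format guessed from extension
  expect_equal(rec$fs, 100)
  expect_equal(rec$channel_labels, c("F3", "C3", "O1"))
  expect_equal(dim(rec$data), c(3L, 500L))
  # int16 quantization over +/-1000 uV: step ~0.03
  expect_lt(max(abs(rec$data - d)), 0.05)
})

test_that("standardize z-scores every channel and is idempotent", {
  t <- seq(0, 10, by = 0.01)
  d <- rbind(5 + sin(2 * pi * t), -3 + rnorm(length(t)))
  rec <- mc_recording(d, fs = 100, channel_labels = c("a", "b"))
  s <- standardize(rec)
  expect_true(s$standardized)
  expect_lt(max(abs(rowMeans(s$data))), 1e-9)
  expect_lt(max(abs(apply(s$data, 1, sd) - 1)), 1e-9)
  s2 <- standardize(s)
  expect_lt(max(abs(s2$data - s$data)), 1e-9)
})

test_that("standardize names zero-variance channels in its error", {
  d <- rbind(rep(2, 300), rnorm(300))
  rec <- mc_recording(d, fs = 100, channel_labels = c("FLAT", "ok"))
  expect_error(standardize(rec), "FLAT")
})

test_that("segment_windows matches the 1-based window arithmetic", {
  set.seed(2)
  rec <- mc_recording(matrix(rnorm(2 * 21000), 2, 21000), fs = 100,
                      channel_labels = c("a", "b"))
  w <- segment_windows(rec, 10, standardize_scope = "none")
  expect_length(w, 21)
  expect_equal(w[[15]]$spec$index, 15)
  expect_equal(w[[15]]$spec$start_s, 140.01)
  expect_equal(w[[15]]$spec$end_s, 150)
  expect_equal(ncol(w[[1]]$rec$data), 1000L)

  rec25 <- mc_recording(matrix(rnorm(2 * 2500), 2, 2500), fs = 100,
                        channel_labels = c("a", "b"))
  expect_length(segment_windows(rec25, 10, standardize_scope = "none"), 2)

  rec9 <- mc_recording(matrix(rnorm(2 * 900), 2, 900), fs = 100,
                       channel_labels = c("a", "b"))
  expect_error(segment_windows(rec9, 10), "shorter than one window")
  expect_error(segment_windows(rec25, 0.5), "floor")
})

test_that("windows concatenate back to the truncated original bit-exactly", {
  set.seed(3)
  rec <- mc_recording(matrix(rnorm(3 * 2500), 3, 2500), fs = 100,
                      channel_labels = c("a", "b", "c"))
  w <- segment_windows(rec, 10, standardize_scope = "none")
  cat_data <- do.call(cbind, lapply(w, function(x) x$rec$data))
  expect_identical(cat_data, rec$data[, 1:2000])
})

test_that("build_augmented stacks channels and records block boundaries", {
  set.seed(4)
  a <- mc_recording(matrix(rnorm(8 * 400), 8, 400), fs = 250,
                    channel_labels = paste0("A", 1:8), subject_id = "pianist")
  b <- mc_recording(matrix(rnorm(8 * 400), 8, 400), fs = 250,
                    channel_labels = paste0("B", 1:8), subject_id = "listener")
  aug <- build_augmented(a, b)
  expect_equal(nrow(aug$data), 16L)
  expect_equal(aug$block_boundaries,
               list(pianist = c(1L, 8L), listener = c(9L, 16L)))
  expect_equal(aug$channel_labels[1], "pianist.A1")
  expect_equal(aug$channel_labels[16], "listener.B8")

  a10 <- mc_recording(matrix(rnorm(10 * 400), 10, 400), fs = 100,
                      channel_labels = paste0("A", 1:10))
  b10 <- mc_recording(matrix(rnorm(10 * 400), 10, 400), fs = 100,
                      channel_labels = paste0("B", 1:10), subject_id = "S2")
  expect_equal(nrow(build_augmented(a10, b10)$data), 20L)

  bad <- mc_recording(matrix(rnorm(8 * 400), 8, 400), fs = 100,
                      channel_labels = paste0("B", 1:8))
  expect_error(build_augmented(a, bad), "sampling rates differ")
  short <- mc_recording(matrix(rnorm(8 * 390), 8, 390), fs = 250,
                        channel_labels = paste0("B", 1:8))
  expect_error(build_augmented(a, short), "not synchronized")
})

test_that("recording constructor enforces its invariants", {
  expect_error(mc_recording(matrix(rnorm(300), 1, 300), 100, "a"),
               "at least 2 channels")
  expect_error(mc_recording(matrix(rnorm(4 * 5), 4, 5), 100, paste0("c", 1:4)),
               "n_samples")
  expect_error(mc_recording(matrix(rnorm(2 * 300), 2, 300), 100, c("a", "a")),
               "unique")
  expect_error(mc_recording(matrix(rnorm(2 * 300), 2, 300), -1, c("a", "b")),
               "fs")
})
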