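test_that("mime_params validates its invariants", {
  p <- mime_params()
  expect_equal(p$A, 0.95)
  expect_equal(p$T, 1L)
  expect_error(mime_params(A = 1), "A")
  expect_error(mime_params(A = 0), "A")
  expect_error(mime_params(T = 6, Lx = 5, Ly = 5), "min\\(Lx, Ly\\)")
})

test_that("build_candidates lays out lag clouds with aligned indices", {
  set.seed(20)
  x <- rnorm(300); y <- rnorm(300)
  bc <- build_candidates(x, y, mime_params(T = 1, Lx = 5, Ly = 5))
  expect_equal(ncol(bc$candidates), 10L)
  expect_equal(ncol(bc$future), 1L)
  expect_equal(nrow(bc$future), nrow(bc$candidates))
  expect_equal(bc$info$source, c(rep("driver", 5), rep("driven", 5)))
  expect_equal(bc$info$lag, c(0:4, 0:4))

  bc2 <- build_candidates(x, y, mime_params(T = 2, Lx = 3, Ly = 5))
  expect_equal(ncol(bc2$candidates), 8L)
  expect_equal(ncol(bc2$future), 2L)

  # alignment: candidate "driver lag 2" at row t equals x[t_idx - 2]
  p0 <- mime_params(jitter = 0)
  bc3 <- build_candidates(x, y, p0)
  t_idx <- 5:299
  expect_identical(bc3$candidates[, 3], x[t_idx - 2])
  expect_identical(bc3$future[, 1], y[t_idx + 1])

  expect_error(build_candidates(rnorm(20), rnorm(20), mime_params()),
               "too short")
})

test_that("selection picks the generating driver lag first and matches the
           brute-force criterion argmax", {
  set.seed(21)
  n <- 1200
  x <- as.numeric(arima.sim(list(ar = 0.9), n))
  y <- c(rep(0, 2), 0.9 * x[1:(n - 2)]) + 0.1 * rnorm(n)
  x <- scale(x)[, 1]; y <- scale(y)[, 1]
  p <- mime_params()
  bc <- build_candidates(x, y, p)
  emb <- select_mixed_embedding(bc$future, bc$candidates, p, info = bc$info)
  # y_{t+1} = 0.9 x_{t-1}: generating component is driver lag 1
  expect_equal(emb$components$source[1], "driver")
  expect_equal(emb$components$lag[1], 1L)
  # oracle: exhaustive first-cycle MI over all candidates
  crit <- vapply(seq_len(ncol(bc$candidates)), function(ci)
    estimate_mi(bc$future, bc$candidates[, ci, drop = FALSE], k = p$k), 0)
  expect_equal(emb$selection_trace$chosen[1], which.max(crit))
})

test_that("a pure autoregression selects only driven-source components", {
  set.seed(22)
  n <- 1200
  y <- as.numeric(arima.sim(list(ar = c(0.5, 0.3)), n))
  x <- rnorm(n)                       # candidate driver, truly independent
  x <- scale(x)[, 1]; y <- scale(y)[, 1]
  bc <- build_candidates(x, y, mime_params())
  emb <- select_mixed_embedding(bc$future, bc$candidates, mime_params(),
                                info = bc$info)
  expect_gt(nrow(emb$components), 0)
  expect_true(all(emb$components$source == "driven"))
})

test_that("mime_causality honors the empty-driver and range conventions", {
  set.seed(23)
  n <- 1200
  y <- as.numeric(arima.sim(list(ar = 0.9), n))
  x <- rnorm(n)
  d <- mime_causality(scale(x)[, 1], scale(y)[, 1], detail = TRUE)
  if (!any(d$embedding$components$source == "driver")) {
    expect_identical(d$R, 0)
  } else {
    expect_gte(d$R, 0); expect_lte(d$R, 1)
  }

  pair <- coupled_pair(1500, seed = 31)
  r <- mime_causality(pair$x, pair$y)
  expect_gte(r, 0); expect_lte(r, 1)
})

test_that("direction is recovered on unidirectional coupling", {
  ok <- 0
  for (s in 1:8) {
    pair <- coupled_pair(1000, strength = 0.8, seed = 40 + s)
    fwd <- mime_causality(pair$x, pair$y)
    rev <- mime_causality(pair$y, pair$x)
    if (fwd > rev) ok <- ok + 1
  }
  expect_gte(ok, 7)
})

test_that("causality_matrix recovers a planted coupling graph", {
  g <- gen_coupled_linear(coupling_spec(
    n_channels = 4,
    couplings = data.frame(source = c(1, 3), target = c(2, 4), lag = 1,
                           strength = 0.8),
    base = "ar1", fs = 100, duration_s = 11.1, seed = 5))
  rec <- standardize(g$rec, "global")
  rec$data <- rec$data[, 1:1000]
  rec <- standardize(rec, "global")
  cm <- causality_matrix(rec)
  v <- cm$values
  expect_true(all(diag(v) == 0))
  expect_true(all(v >= 0 & v <= 1))
  off <- v[row(v) != col(v)]
  top2 <- sort(off, decreasing = TRUE)[2]
  expect_true(v[1, 2] >= top2 && v[3, 4] >= top2)
})

test_that("augmented matrices carry the two-block structure", {
  set.seed(24)
  mk <- function(id) mc_recording(matrix(rnorm(8 * 300), 8, 300), fs = 100,
                                  channel_labels = paste0("c", 1:8),
                                  subject_id = id)
  aug <- build_augmented(mk("A"), mk("B"))
  cm <- causality_matrix(standardize(aug, "global"))
  expect_equal(dim(cm$values), c(16L, 16L))
  expect_equal(cm$block_boundaries, list(A = c(1L, 8L), B = c(9L, 16L)))
})

test_that("causality matrices are deterministic and stacking-order equivariant", {
  set.seed(25)
  a <- mc_recording(matrix(rnorm(2 * 400), 2, 400), fs = 100,
                    channel_labels = c("a1", "a2"), subject_id = "A")
  b <- mc_recording(matrix(rnorm(2 * 400), 2, 400), fs = 100,
                    channel_labels = c("b1", "b2"), subject_id = "B")
  ab <- causality_matrix(standardize(build_augmented(a, b), "global"))
  ab2 <- causality_matrix(standardize(build_augmented(a, b), "global"))
  expect_identical(ab$values, ab2$values)

  ba <- causality_matrix(standardize(build_augmented(b, a), "global"))
  perm <- c(3, 4, 1, 2)
  expect_identical(unname(ab$values), unname(ba$values[perm, perm]))
})

test_that("causality matrix CSV + sidecar round-trips", {
  m <- matrix(c(0, 0.2, 0.1, 0), 2, 2, byrow = TRUE)
  cm <- as_cm(m, labels = c("F3", "F4"), blocks = list(A = c(1L, 1L), B = c(2L, 2L)))
  p <- tempfile(fileext = ".csv")
  write_causality_matrix(cm, p, params = mime_params())
  back <- read_causality_matrix(p)
  expect_equal(unname(back$values), unname(cm$values))
  expect_equal(back$channel_labels, cm$channel_labels)
  expect_equal(back$block_boundaries, cm$block_boundaries)
})
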