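test_that("coupling_spec validates its invariants", {
  expect_error(coupling_spec(couplings = data.frame(source = 1, target = 2,
                                                    lag = 0, strength = 1)),
               "lags")
  expect_error(coupling_spec(couplings = data.frame(source = 1, target = 2,
                                                    lag = 1, strength = -1)),
               "strengths")
  expect_error(coupling_spec(n_channels = 2,
                             couplings = data.frame(source = 1, target = 5,
                                                    lag = 1, strength = 1)),
               "out of range")
  expect_error(coupling_spec(ar_coef = 1.2), "unstable")
  expect_error(coupling_spec(n_channels = 4, ar_coef = c(0.5, 0.9)),
               "per channel")
})

test_that("linear generator is seed-deterministic with the right shape", {
  sp <- coupling_spec(n_channels = 3, fs = 100, duration_s = 5, seed = 9)
  g1 <- gen_coupled_linear(sp)
  g2 <- gen_coupled_linear(sp)
  expect_identical(g1$rec$data, g2$rec$data)
  expect_equal(dim(g1$rec$data), c(3L, 500L))
  g3 <- gen_coupled_linear(coupling_spec(n_channels = 3, fs = 100,
                                         duration_s = 5, seed = 10))
  expect_false(identical(g1$rec$data, g3$rec$data))
  # generator must not disturb the caller's RNG stream
  set.seed(42); before <- rnorm(1)
  set.seed(42); invisible(gen_coupled_linear(sp)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("planted lagged coupling dominates the cross-correlation", {
  g <- gen_coupled_linear(coupling_spec(
    n_channels = 2,
    couplings = data.frame(source = 1, target = 2, lag = 3, strength = 0.8),
    fs = 100, duration_s = 20, seed = 3))
  x <- g$rec$data[1, ]; y <- g$rec$data[2, ]
  # regression oracle: y_t = 0.9 y_{t-1} + 0.8 x_{t-3} + e by construction
  n <- length(y)
  fit <- lm(y[4:n] ~ 0 + y[3:(n - 1)] + x[1:(n - 3)])
  expect_equal(unname(coef(fit)), c(0.9, 0.8), tolerance = 0.05)
  expect_equal(g$truth$lag, 3)
})

test_that("bandmix base has EEG-like autocorrelation decaying within 0.5 s", {
  g <- gen_coupled_linear(coupling_spec(n_channels = 2, base = "bandmix",
                                        fs = 100, duration_s = 60, seed = 4))
  a <- acf(g$rec$data[1, ], lag.max = 60, plot = FALSE)$acf
  expect_gt(abs(a[2]), 0.5)          # strongly correlated at 10 ms
  expect_lt(max(abs(a[51:61])), 0.1) # decorrelated by 0.5 s
})

test_that("Henon orbits stay bounded and reject the linear path", {
  sp <- coupling_spec(n_channels = 2,
                      couplings = data.frame(source = 1, target = 2, lag = 1,
                                             strength = 0.4),
                      base = "henon", fs = 100, duration_s = 10, seed = 6)
  g <- gen_coupled_nonlinear(sp)
  expect_true(all(abs(g$rec$data) < 3))
  expect_identical(g$rec$data, gen_coupled_nonlinear(sp)$rec$data)
  expect_error(gen_coupled_linear(sp), "gen_coupled_nonlinear")
  expect_error(gen_coupled_nonlinear(coupling_spec(
    n_channels = 2, couplings = data.frame(source = 1, target = 2, lag = 1,
                                           strength = 1.4),
    base = "henon")), "<= 1")
})

test_that("Henon causality grows with coupling strength", {
  med_r <- sapply(c(0, 0.2, 0.4), function(cc) {
    median(sapply(1:5, function(s) {
      sp <- coupling_spec(n_channels = 2,
        couplings = if (cc > 0) data.frame(source = 1, target = 2, lag = 1,
                                           strength = cc),
        base = "henon", fs = 100, duration_s = 11.1, seed = 60 + s)
      g <- gen_coupled_nonlinear(sp)
      r <- standardize(g$rec, "global")
      mime_causality(r$data[1, 1:1000], r$data[2, 1:1000])
    }))
  })
  expect_true(all(diff(med_r) >= 0))
  expect_gt(med_r[3], med_r[1])
})

test_that("two-brain generator plants a one-way driver-responder system", {
  mk <- function(seed) coupling_spec(n_channels = 3, fs = 100,
                                     duration_s = 8, seed = seed)
  g <- gen_two_brain(mk(1), mk(1), coupling = 0.8, lag = 1)
  expect_equal(nrow(g$rec$data), 6L)
  expect_equal(g$rec$block_boundaries,
               list(reader = c(1L, 3L), listener = c(4L, 6L)))
  expect_equal(g$truth$from, "reader")
  # regression oracle: listener ch1 = 0.9 self + 0.8 reader ch1 (lag 1)
  xa <- g$recA$data[1, ]; yb <- g$recB$data[1, ]
  n <- length(yb)
  fit <- lm(yb[2:n] ~ 0 + yb[1:(n - 1)] + xa[1:(n - 1)])
  expect_equal(unname(coef(fit)), c(0.9, 0.8), tolerance = 0.05)

  g0 <- gen_two_brain(mk(2), mk(3), coupling = 0)
  expect_null(g0$truth)
  cc0 <- ccf(g0$recA$data[1, ], g0$recB$data[1, ], lag.max = 4, plot = FALSE)
  expect_lt(max(abs(cc0$acf)), 0.2)
})

test_that("ensemble generator routes edges onto dedicated channels", {
  graph <- data.frame(from = c(1, 1, 1, 2, 3, 2), to = c(2, 3, 4, 4, 4, 3),
                      strength = 0.8,
                      mode = c(rep("fixed", 5), "pingpong"))
  g <- gen_ensemble(4, graph,
                    coupling_spec(n_channels = 3, fs = 100, duration_s = 20,
                                  seed = 11),
                    window_s = 5, subject_ids = c("h", "f", "v", "l"),
                    n_channels = c(2, 2, 2, 3))
  expect_equal(vapply(g$recs, function(r) nrow(r$data), 0L),
               c(h = 2L, f = 2L, v = 2L, l = 3L))
  # listener in-edges each landed on a distinct channel
  listener_edges <- g$truth[g$truth$to == 4, ]
  expect_equal(sort(listener_edges$target_ch), 1:3)
  expect_length(g$pairs, 6)
  expect_identical(g$pairs[["h+f"]]$block_boundaries,
                   list(h = c(1L, 2L), f = c(3L, 4L)))
  # determinism
  g2 <- gen_ensemble(4, graph,
                     coupling_spec(n_channels = 3, fs = 100, duration_s = 20,
                                   seed = 11),
                     window_s = 5, subject_ids = c("h", "f", "v", "l"),
                     n_channels = c(2, 2, 2, 3))
  expect_identical(g$recs$l$data, g2$recs$l$data)
})

test_that("ping-pong coupling alternates direction across window blocks", {
  graph <- data.frame(from = 1, to = 2, strength = 0.9, mode = "pingpong")
  g <- gen_ensemble(2, graph,
                    coupling_spec(n_channels = 2, fs = 100, duration_s = 20,
                                  seed = 12),
                    window_s = 5, pingpong_block = 1)
  a <- g$recs$S1$data; b <- g$recs$S2$data
  lagcor <- function(x, y, rng) cor(x[rng][-length(rng)], y[rng][-1])
  w1 <- 1:500; w2 <- 501:1000
  # block 0: S1 ch1 drives S2 ch1; block 1: reversed
  expect_gt(lagcor(a[1, ], b[1, ], w1), lagcor(b[1, ], a[1, ], w1))
  expect_gt(lagcor(b[1, ], a[1, ], w2), lagcor(a[1, ], b[1, ], w2))
})

test_that("two-condition generator isolates the planted difference", {
  base <- coupling_spec(n_channels = 4, fs = 100, duration_s = 6, seed = 13)
  same <- gen_two_condition(base, deltaEdges = NULL)
  expect_identical(same$recA$data, same$recB$data)

  delta <- data.frame(source = 1, target = 2, lag = 1, strength = 0.8)
  g <- gen_two_condition(base, deltaEdges = delta)
  expect_identical(g$recA$data[c(1, 3, 4), ], g$recB$data[c(1, 3, 4), ])
  expect_false(identical(g$recA$data[2, ], g$recB$data[2, ]))
  expect_equal(g$truth, delta)
})
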