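#' Ground-truth coupling specification for the synthetic generators
#'
#' @param n_channels channels per subject.
#' @param couplings data frame with columns `source`, `target` (channel
#'   indices), `lag` (samples, >= 1) and `strength` (>= 0); `NULL` for no
#'   coupling.
#' @param base base process for every channel: `"ar1"` (first-order
#'   autoregression), `"bandmix"` (resonant second-order autoregression, an
#'   EEG-like band-limited noise mix whose autocorrelation decays within
#'   0.5 s), or `"henon"` (chaotic Henon map).
#' @param ar_coef AR(1) coefficient for `base = "ar1"`; scalar or one value
#'   per channel.  The default 0.9 matches the strong lag-1 autocorrelation
#'   of band-limited EEG sampled at around 100 Hz.
#' @param noise_sd innovation standard deviation.
#' @param fs sampling rate in Hz.
#' @param duration_s recording length in seconds.
#' @param seed RNG seed; the seed fully determines the output.
#' @return a `coupling_spec` list.
#' @export
coupling_spec <- function(n_channels = 10L, couplings = NULL,
                          base = c("ar1", "bandmix", "henon"),
                          ar_coef = 0.9, noise_sd = 1, fs = 100,
                          duration_s = 200, seed = 1L) {
  base <- match.arg(base)
  if (!is.null(couplings)) {
    stopifnot(all(c("source", "target", "lag", "strength") %in%
                    names(couplings)))
    if (any(couplings$lag < 1L)) stop("lags must be >= 1", call. = FALSE)
    if (any(couplings$strength < 0)) stop("strengths must be >= 0", call. = FALSE)
    if (any(couplings$source > n_channels | couplings$target > n_channels))
      stop("coupling channel index out of range", call. = FALSE)
  }
  if (base == "ar1") {
    if (any(abs(ar_coef) >= 1))
      stop("unstable AR(1) coefficient", call. = FALSE)
    if (!length(ar_coef) %in% c(1L, n_channels))
      stop("ar_coef must be scalar or one value per channel", call. = FALSE)
  }
  structure(list(n_channels = as.integer(n_channels), couplings = couplings,
                 base = base, ar_coef = ar_coef, noise_sd = noise_sd,
                 fs = fs, duration_s = duration_s, seed = as.integer(seed)),
            class = "coupling_spec")
}

default_labels <- function(k) {
  std <- c("P4", "T8", "C4", "F4", "F3", "C3", "T7", "P3", "O1", "O2")
  if (k <= length(std)) std[seq_len(k)] else c(std, paste0("X", seq_len(k - 10)))
}

BURN_IN <- 1000L

# innovation matrix for the linear bases, one row per channel
linear_innovations <- function(k, n_total, noise_sd) {
  matrix(rnorm(k * n_total, sd = noise_sd), k, n_total)
}

#' Linear coupled-channel generator
#'
#' Every channel follows its base autoregression (`ar1` or the EEG-like
#' `bandmix` resonance) plus lagged linear influences from its coupling
#' sources plus Gaussian innovations.  A 1000-sample burn-in is discarded.
#'
#' @param spec a [coupling_spec()] with `base` `"ar1"` or `"bandmix"`.
#' @param subject_id subject id for the returned recording.
#' @return list with `rec` (an [mc_recording()]) and `truth` (the planted
#'   coupling data frame).
#' @export
gen_coupled_linear <- function(spec, subject_id = "S1") {
  if (spec$base == "henon")
    stop("use gen_coupled_nonlinear for the Henon base", call. = FALSE)
  k <- spec$n_channels
  n <- as.integer(round(spec$duration_s * spec$fs))
  n_total <- n + BURN_IN
  cp <- spec$couplings
  ar <- rep_len(spec$ar_coef, k)
  x <- with_seed(spec$seed, {
    eps <- linear_innovations(k, n_total, spec$noise_sd)
    x <- matrix(0, k, n_total)
    if (spec$base == "bandmix") {
      # resonant AR(2): poles at radius r, frequency f0; ACF decays within
      # r^(0.5*fs) ~ 0.005 at r = 0.9, fs = 100
      r <- 0.9; f0 <- 10
      a1 <- 2 * r * cos(2 * pi * f0 / spec$fs); a2 <- -r^2
    }
    maxlag <- max(2L, if (!is.null(cp)) max(cp$lag) else 1L)
    for (t in (maxlag + 1L):n_total) {
      drive <- numeric(k)
      if (!is.null(cp) && nrow(cp)) {
        for (e in seq_len(nrow(cp)))
          drive[cp$target[e]] <- drive[cp$target[e]] +
            cp$strength[e] * x[cp$source[e], t - cp$lag[e]]
      }
      base <- if (spec$base == "ar1") ar * x[, t - 1L]
              else a1 * x[, t - 1L] + a2 * x[, t - 2L]
      x[, t] <- base + drive + eps[, t]
    }
    x
  })
  rec <- mc_recording(x[, (BURN_IN + 1L):n_total, drop = FALSE], fs = spec$fs,
                      channel_labels = default_labels(k),
                      subject_id = subject_id)
  list(rec = rec, truth = cp)
}

#' Coupled Henon-map generator (nonlinear benchmark)
#'
#' Channels are Henon maps; a coupling `source -> target` with strength `c`
#' replaces the target's quadratic argument by the mixture
#' `c * x_source + (1 - c) * x_target` (the standard unidirectionally
#' coupled Henon benchmark).  Diverging orbits are rejected and re-seeded
#' with a notice.
#'
#' @param spec a [coupling_spec()] with `base = "henon"`; `lag` entries are
#'   ignored (the map couples at lag 1) and a small observation noise of sd
#'   `noise_sd * 0.01` is added to break exact determinism ties.
#' @param subject_id subject id.
#' @param max_reseed attempts before giving up on a bounded orbit.
#' @return list with `rec` and `truth` as in [gen_coupled_linear()].
#' @export
gen_coupled_nonlinear <- function(spec, subject_id = "S1", max_reseed = 20L) {
  k <- spec$n_channels
  n <- as.integer(round(spec$duration_s * spec$fs))
  n_total <- n + BURN_IN
  cp <- spec$couplings
  cstr <- numeric(k)          # per-target mixing strength
  csrc <- rep(NA_integer_, k)
  if (!is.null(cp) && nrow(cp)) {
    for (e in seq_len(nrow(cp))) {
      if (cp$strength[e] > 1) stop("Henon coupling strength must be <= 1",
                                   call. = FALSE)
      cstr[cp$target[e]] <- cp$strength[e]
      csrc[cp$target[e]] <- cp$source[e]
    }
  }
  seed <- spec$seed
  for (attempt in seq_len(max_reseed)) {
    x <- with_seed(seed, {
      x <- matrix(0, k, n_total)
      x[, 1:2] <- matrix(runif(2 * k, -0.1, 0.1), k, 2)
      ok <- TRUE
      for (t in 3:n_total) {
        for (ch in seq_len(k)) {
          u <- if (cstr[ch] > 0)
            cstr[ch] * x[csrc[ch], t - 1L] + (1 - cstr[ch]) * x[ch, t - 1L]
          else x[ch, t - 1L]
          x[ch, t] <- 1.4 - u * x[ch, t - 1L] + 0.3 * x[ch, t - 2L]
        }
        if (any(!is.finite(x[, t])) || any(abs(x[, t]) > 1e6)) { ok <- FALSE; break }
      }
      if (ok) x + matrix(rnorm(k * n_total, sd = spec$noise_sd * 0.01),
                         k, n_total)
      else NULL
    })
    if (!is.null(x)) break
    message("diverging Henon orbit; re-seeding (attempt ", attempt, ")")
    seed <- derive_seed(seed, attempt)
  }
  if (is.null(x)) stop("all re-seeds diverged", call. = FALSE)
  rec <- mc_recording(x[, (BURN_IN + 1L):n_total, drop = FALSE], fs = spec$fs,
                      channel_labels = default_labels(k),
                      subject_id = subject_id)
  list(rec = rec, truth = cp)
}

#' Two-subject driver-responder generator (reading-experiment emulation)
#'
#' Generates two synchronized "brains"; a subset of the driver's channels
#' feeds a subset of the responder's channels with the given lag and
#' strength, with no reverse coupling.  Swapping the two specs swaps the
#' roles.
#'
#' @param readerSpec,listenerSpec [coupling_spec()] objects for the two
#'   subjects (same `fs` and `duration_s`); their own `couplings` entries
#'   plant intra-brain structure.
#' @param coupling cross-subject coupling strength (0 disables).
#' @param lag cross-subject lag in samples.
#' @param n_drive number of reader channels driving an equal number of
#'   listener channels (channels `1..n_drive` on both sides).
#' @return list with `rec` (augmented [mc_recording()]), `recA`, `recB`, and
#'   `truth` (subject-level edge, or `NULL` when `coupling = 0`).
#' @export
gen_two_brain <- function(readerSpec, listenerSpec, coupling = 0.8, lag = 1L,
                          n_drive = 2L) {
  stopifnot(readerSpec$fs == listenerSpec$fs,
            readerSpec$duration_s == listenerSpec$duration_s)
  kA <- readerSpec$n_channels; kB <- listenerSpec$n_channels
  n_drive <- min(n_drive, kA, kB)
  # build one joint spec over kA + kB channels so the cross coupling enters
  # the same recursion as the intra couplings
  cp <- readerSpec$couplings
  cpB <- listenerSpec$couplings
  if (!is.null(cpB)) {
    cpB$source <- cpB$source + kA
    cpB$target <- cpB$target + kA
    cp <- rbind(cp, cpB)
  }
  if (coupling > 0) {
    cross <- data.frame(source = seq_len(n_drive),
                        target = kA + seq_len(n_drive),
                        lag = lag, strength = coupling)
    cp <- rbind(cp, cross)
  }
  joint <- coupling_spec(n_channels = kA + kB, couplings = cp,
                         base = readerSpec$base, ar_coef = readerSpec$ar_coef,
                         noise_sd = readerSpec$noise_sd, fs = readerSpec$fs,
                         duration_s = readerSpec$duration_s,
                         seed = readerSpec$seed)
  g <- gen_coupled_linear(joint)
  labsA <- default_labels(kA); labsB <- default_labels(kB)
  recA <- mc_recording(g$rec$data[seq_len(kA), , drop = FALSE],
                       fs = readerSpec$fs, channel_labels = labsA,
                       subject_id = "reader")
  recB <- mc_recording(g$rec$data[kA + seq_len(kB), , drop = FALSE],
                       fs = listenerSpec$fs, channel_labels = labsB,
                       subject_id = "listener")
  truth <- if (coupling > 0) {
    data.frame(from = "reader", to = "listener", strength = coupling,
               stringsAsFactors = FALSE)
  } else NULL
  list(rec = build_augmented(recA, recB), recA = recA, recB = recB,
       truth = truth)
}

#' Multi-subject ensemble generator with a planted subject-level graph
#'
#' Emulates an ensemble (e.g. three musicians plus a listener): every edge
#' of the subject-level coupling graph routes one source channel into one
#' dedicated target channel (round-robin over the target's channels, so
#' concurrent influences land on distinct electrodes, as distinct cortical
#' regions would respond to distinct streams).  Edges with
#' `mode = "pingpong"` alternate the active direction in blocks of
#' `pingpong_block` windows, so per-window dominance swaps while the
#' time-averaged weights stay comparable.
#'
#' @param n_subjects number of subjects.
#' @param graph data frame with columns `from`, `to` (subject indices),
#'   `strength`, and optionally `mode` (`"fixed"` or `"pingpong"`) and
#'   explicit `source_ch`, `target_ch` channel assignments.
#' @param spec template [coupling_spec()] shared by all subjects;
#'   `n_channels` must be at least the maximum in-degree of `graph`.
#' @param window_s window length used to lay out ping-pong blocks.
#' @param pingpong_block number of consecutive windows per dominance block.
#' @param lag coupling lag in samples.
#' @param subject_ids subject names; default `S1..Sn`.
#' @param n_channels optional per-subject channel counts overriding
#'   `spec$n_channels` (every subject needs one channel per in-edge to give
#'   each influence a dedicated electrode).
#' @return list with `recs` (per-subject recordings), `truth` (the graph
#'   including resolved channel routing), and `pairs` (augmented recordings
#'   per unordered subject pair).
#' @export
gen_ensemble <- function(n_subjects, graph, spec, window_s = 10,
                         pingpong_block = 1L, lag = 1L,
                         subject_ids = NULL, n_channels = NULL) {
  stopifnot(all(c("from", "to", "strength") %in% names(graph)))
  if (is.null(graph$mode)) graph$mode <- "fixed"
  if (is.null(subject_ids)) subject_ids <- paste0("S", seq_len(n_subjects))
  ks <- rep_len(if (is.null(n_channels)) spec$n_channels else n_channels,
                n_subjects)
  if (is.null(graph$source_ch)) graph$source_ch <- 1L
  if (is.null(graph$target_ch)) {
    # round-robin a dedicated channel per in-edge (ping-pong edges reserve a
    # slot on both endpoints)
    nxt <- rep(1L, n_subjects)
    graph$target_ch <- NA_integer_
    for (e in seq_len(nrow(graph))) {
      to <- graph$to[e]
      graph$target_ch[e] <- ((nxt[to] - 1L) %% ks[to]) + 1L
      nxt[to] <- nxt[to] + 1L
      if (graph$mode[e] == "pingpong") {
        fr <- graph$from[e]
        graph$source_ch[e] <- ((nxt[fr] - 1L) %% ks[fr]) + 1L
        nxt[fr] <- nxt[fr] + 1L
      }
    }
  }
  n <- as.integer(round(spec$duration_s * spec$fs))
  n_total <- n + BURN_IN
  wlen <- as.integer(round(window_s * spec$fs))
  off <- c(0L, cumsum(ks))
  K <- off[n_subjects + 1L]
  chan <- function(s, c) off[s] + c

  arK <- unlist(lapply(ks, function(k1) rep_len(spec$ar_coef, k1)))
  x <- with_seed(spec$seed, {
    eps <- linear_innovations(K, n_total, spec$noise_sd)
    x <- matrix(0, K, n_total)
    if (spec$base == "bandmix") {
      r <- 0.9; f0 <- 10
      a1 <- 2 * r * cos(2 * pi * f0 / spec$fs); a2 <- -r^2
    }
    for (t in 3:n_total) {
      # window index of the post-burn-in sample, for ping-pong scheduling
      w <- max(0L, (t - BURN_IN - 1L)) %/% wlen
      block <- (w %/% pingpong_block) %% 2L
      drive <- numeric(K)
      for (e in seq_len(nrow(graph))) {
        from <- graph$from[e]; to <- graph$to[e]
        sc <- graph$source_ch[e]; tc0 <- graph$target_ch[e]
        if (graph$mode[e] == "pingpong" && block == 1L) {
          tmp <- from; from <- to; to <- tmp
          tmp <- sc; sc <- tc0; tc0 <- tmp
        }
        tc <- chan(to, tc0)
        drive[tc] <- drive[tc] + graph$strength[e] * x[chan(from, sc), t - lag]
      }
      base <- if (spec$base == "ar1") arK * x[, t - 1L]
              else a1 * x[, t - 1L] + a2 * x[, t - 2L]
      x[, t] <- base + drive + eps[, t]
    }
    x
  })
  recs <- lapply(seq_len(n_subjects), function(s) {
    mc_recording(x[chan(s, 1L):chan(s, ks[s]), (BURN_IN + 1L):n_total,
                   drop = FALSE],
                 fs = spec$fs, channel_labels = default_labels(ks[s]),
                 subject_id = subject_ids[s])
  })
  names(recs) <- subject_ids
  pairs <- list()
  for (a in seq_len(n_subjects - 1L)) for (b in (a + 1L):n_subjects) {
    pairs[[paste(subject_ids[a], subject_ids[b], sep = "+")]] <-
      build_augmented(recs[[a]], recs[[b]])
  }
  graph$from_id <- subject_ids[graph$from]
  graph$to_id <- subject_ids[graph$to]
  list(recs = recs, truth = graph, pairs = pairs)
}

#' Two-condition generator with a planted contrast
#'
#' Condition B shares condition A's generative model and base noise (same
#' seed) with the strengths of `deltaEdges` added, so the causality contrast
#' isolates the planted difference.
#'
#' @param baseSpec a [coupling_spec()] describing condition A.
#' @param deltaEdges data frame (`source`, `target`, `lag`, `strength`) of
#'   coupling increments defining condition B; `NULL` for none.
#' @return list with `recA`, `recB` and `truth = deltaEdges`.
#' @export
gen_two_condition <- function(baseSpec, deltaEdges = NULL) {
  a <- gen_coupled_linear(baseSpec, subject_id = "condA")
  specB <- baseSpec
  if (!is.null(deltaEdges) && nrow(deltaEdges)) {
    cp <- baseSpec$couplings
    for (e in seq_len(nrow(deltaEdges))) {
      hit <- FALSE
      if (!is.null(cp)) {
        same <- cp$source == deltaEdges$source[e] &
                cp$target == deltaEdges$target[e] &
                cp$lag == deltaEdges$lag[e]
        if (any(same)) { cp$strength[same] <- cp$strength[same] + deltaEdges$strength[e]; hit <- TRUE }
      }
      if (!hit) cp <- rbind(cp, deltaEdges[e, c("source", "target", "lag", "strength")])
    }
    specB$couplings <- cp
  }
  b <- gen_coupled_linear(
    coupling_spec(n_channels = specB$n_channels, couplings = specB$couplings,
                  base = specB$base, ar_coef = specB$ar_coef,
                  noise_sd = specB$noise_sd, fs = specB$fs,
                  duration_s = specB$duration_s, seed = specB$seed),
    subject_id = "condB")
  list(recA = a$rec, recB = b$rec, truth = deltaEdges)
}
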