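#' MIME parameters
#'
#' @param T prediction horizon in samples: the future vector is
#'   `(y[t+1], ..., y[t+T])`.  Must not exceed `min(Lx, Ly)`.
#' @param Lx,Ly maximum lag counts for the driver and driven series; the
#'   candidate set holds lags `0 .. Lx-1` of the driver and `0 .. Ly-1` of
#'   the driven series.
#' @param A stopping threshold in (0,1), close to 1: embedding growth stops
#'   when the information already captured is at least `A` times the
#'   information after adding the best remaining candidate.
#' @param k neighbour count for the CMI estimator.
#' @param max_cycles cap on the number of selected embedding components.
#' @param jitter amplitude of the tie-breaking jitter applied once to the
#'   lag clouds (guards against quantized signals).
#' @param jitter_seed seed for the jitter stream.
#' @return a `mime_params` list.
#' @export
mime_params <- function(T = 1L, Lx = 5L, Ly = 5L, A = 0.95, k = 4L,
                        max_cycles = 10L, jitter = 1e-10, jitter_seed = 1L) {
  stopifnot(T >= 1L, Lx >= 1L, Ly >= 1L, A > 0, A < 1, k >= 1L,
            max_cycles >= 1L)
  if (T > min(Lx, Ly))
    stop("T must not exceed min(Lx, Ly)", call. = FALSE)
  structure(list(T = as.integer(T), Lx = as.integer(Lx), Ly = as.integer(Ly),
                 A = A, k = as.integer(k), max_cycles = as.integer(max_cycles),
                 jitter = jitter, jitter_seed = as.integer(jitter_seed)),
            class = "mime_params")
}

#' Build lag-candidate clouds and the future cloud for one channel pair
#'
#' The candidate set pools lagged values of the driver `x` (lags
#' `0 .. Lx-1`) and of the driven series `y` (lags `0 .. Ly-1`); the future
#' cloud stacks `y[t+1] .. y[t+T]`.  All clouds are aligned on the same
#' valid time indices, and the tie-breaking jitter is applied here, once,
#' so that every downstream criterion evaluation sees identical coordinates.
#'
#' @param x driver series (numeric vector).
#' @param y driven series.
#' @param params a [mime_params()] object.
#' @return list with `future` (n x T matrix), `candidates` (n x (Lx+Ly)
#'   matrix, one column per candidate) and `info` (data frame with `source`
#'   in {driver, driven} and `lag` per candidate).
#' @export
build_candidates <- function(x, y, params = mime_params()) {
  n <- length(x)
  if (length(y) != n) stop("series lengths differ", call. = FALSE)
  Lmax <- max(params$Lx, params$Ly)
  if (n < Lmax + params$T + 100L)
    stop("series too short: need at least Lmax + T + 100 = ",
         Lmax + params$T + 100L, " samples, got ", n, call. = FALSE)
  # valid t: lags reach back to t-(L-1) >= 1, future reaches t+T <= n
  t_idx <- Lmax:(n - params$T)
  future <- vapply(seq_len(params$T), function(h) y[t_idx + h],
                   numeric(length(t_idx)))
  future <- matrix(future, ncol = params$T)
  cand_x <- vapply(0:(params$Lx - 1L), function(l) x[t_idx - l],
                   numeric(length(t_idx)))
  cand_y <- vapply(0:(params$Ly - 1L), function(l) y[t_idx - l],
                   numeric(length(t_idx)))
  candidates <- cbind(matrix(cand_x, ncol = params$Lx),
                      matrix(cand_y, ncol = params$Ly))
  info <- data.frame(
    source = c(rep("driver", params$Lx), rep("driven", params$Ly)),
    lag = c(0:(params$Lx - 1L), 0:(params$Ly - 1L)),
    stringsAsFactors = FALSE)
  colnames(candidates) <- paste0(ifelse(info$source == "driver", "x", "y"),
                                 ".l", info$lag)
  if (params$jitter > 0) {
    jf <- with_seed(params$jitter_seed, {
      f <- future +
        matrix(runif(length(future), -params$jitter, params$jitter),
               nrow(future), ncol(future))
      c <- candidates +
        matrix(runif(length(candidates), -params$jitter, params$jitter),
               nrow(candidates), ncol(candidates))
      list(f, c)
    })
    future <- jf[[1]]; candidates <- jf[[2]]
  }
  list(future = future, candidates = candidates, info = info)
}

#' Greedy selection of a non-uniform mixed embedding
#'
#' Cycle `j` picks the candidate maximizing the estimated
#' `I(future; candidate | B[j-1])` (plain MI on the first cycle, where the
#' selected set is empty) and appends it.  Growth stops when the stopping
#' ratio `I(future; B[j-1]) / I(future; B[j])` reaches the threshold `A`
#' (the new component added almost nothing; the previous embedding is
#' returned), when the best criterion value is non-positive, or at
#' `max_cycles`.
#'
#' @param future future cloud (matrix) from [build_candidates()].
#' @param candidates candidate matrix from [build_candidates()].
#' @param params a [mime_params()] object.
#' @param info candidate metadata (`source`, `lag`); defaults to the layout
#'   produced by [build_candidates()].
#' @return a `mixed_embedding`: list with `components` (data frame of
#'   selected `source`/`lag`/`column`) and `selection_trace` (one row per
#'   cycle: chosen candidate, criterion value, stopping ratio, accepted).
#' @export
select_mixed_embedding <- function(future, candidates, params = mime_params(),
                                   info = NULL) {
  if (ncol(candidates) == 0L) stop("empty candidate set", call. = FALSE)
  if (is.null(info)) {
    info <- data.frame(source = c(rep("driver", params$Lx),
                                  rep("driven", params$Ly)),
                       lag = c(0:(params$Lx - 1L), 0:(params$Ly - 1L)),
                       stringsAsFactors = FALSE)
  }
  sel <- integer(0)
  i_old <- 0      # I(future; B_{j-1}), clamped
  trace <- list()
  for (cycle in seq_len(params$max_cycles)) {
    remaining <- setdiff(seq_len(ncol(candidates)), sel)
    if (!length(remaining)) break
    B <- candidates[, sel, drop = FALSE]
    crit <- vapply(remaining, function(ci) {
      estimate_cmi(future, candidates[, ci, drop = FALSE], B,
                   k = params$k, jitter = 0)
    }, 0)
    best <- which.max(crit)
    chosen <- remaining[best]
    if (crit[best] <= 0) {
      trace[[cycle]] <- data.frame(cycle = cycle, chosen = chosen,
                                   criterion = crit[best], ratio = NA_real_,
                                   accepted = FALSE)
      break
    }
    B_new <- candidates[, c(sel, chosen), drop = FALSE]
    i_new <- estimate_mi(future, B_new, k = params$k, clamp = TRUE, jitter = 0)
    ratio <- if (i_new > 0) i_old / i_new else 1
    trace[[cycle]] <- data.frame(cycle = cycle, chosen = chosen,
                                 criterion = crit[best], ratio = ratio,
                                 accepted = ratio < params$A)
    if (ratio >= params$A) break
    sel <- c(sel, chosen)
    i_old <- i_new
  }
  comps <- info[sel, , drop = FALSE]
  comps$column <- sel
  rownames(comps) <- NULL
  structure(list(components = comps,
                 selection_trace = do.call(rbind, trace)),
            class = "mixed_embedding")
}

#' @export
print.mixed_embedding <- function(x, ...) {
  k <- nrow(x$components)
  cat(sprintf("<mixed_embedding> %d component(s)\n", k))
  if (k) print(x$components)
  invisible(x)
}

#' MIME causality index from one series to another
#'
#' Selects the mixed embedding for predicting `y`'s future from lagged
#' values of both series, then returns
#' `R(X -> Y) = I(future; Bx | By) / I(future; B)` where `Bx`/`By` are the
#' driver/driven components of the final embedding `B`.  Conventions: no
#' driver components selected gives exactly 0; a non-positive denominator
#' gives 0; the result is clipped into \[0, 1\].
#'
#' @param x driver series.
#' @param y driven (target) series.
#' @param params a [mime_params()] object.
#' @param detail if `TRUE`, also return the embedding and the ratio parts.
#' @return the causality index in \[0, 1\] (or a list when `detail = TRUE`).
#' @export
mime_causality <- function(x, y, params = mime_params(), detail = FALSE) {
  bc <- build_candidates(x, y, params)
  emb <- select_mixed_embedding(bc$future, bc$candidates, params,
                                info = bc$info)
  comps <- emb$components
  out <- function(R, num = NA_real_, den = NA_real_) {
    if (detail) list(R = R, embedding = emb, numerator = num, denominator = den)
    else R
  }
  if (!nrow(comps) || !any(comps$source == "driver")) return(out(0))
  Bx <- bc$candidates[, comps$column[comps$source == "driver"], drop = FALSE]
  By <- bc$candidates[, comps$column[comps$source == "driven"], drop = FALSE]
  B <- bc$candidates[, comps$column, drop = FALSE]
  num <- estimate_cmi(bc$future, Bx, By, k = params$k, clamp = TRUE, jitter = 0)
  den <- estimate_mi(bc$future, B, k = params$k, clamp = TRUE, jitter = 0)
  if (den <= 0) return(out(0, num, den))
  out(min(1, max(0, num / den)), num, den)
}

#' Causality matrix of a (windowed) recording
#'
#' Entry `(i, j)` is `mime_causality(channel_i, channel_j)`: row = source,
#' column = target; the diagonal is zero.  Block boundaries of augmented
#' recordings are carried along so intra- and cross-brain blocks can be
#' split downstream.
#'
#' @param rec a standardized [mc_recording()] (typically one window).
#' @param params a [mime_params()] object.
#' @param pairs optional 2-column integer matrix of (source, target) channel
#'   index pairs to evaluate; all other entries stay 0.  Lets cross-brain
#'   analyses skip the intra blocks.
#' @param window window spec from [segment_windows()] to attach as metadata.
#' @return a `causality_matrix`: list with `values`, `channel_labels`,
#'   `window`, `block_boundaries`.
#' @export
causality_matrix <- function(rec, params = mime_params(), pairs = NULL,
                             window = NULL) {
  K <- nrow(rec$data)
  if (!isTRUE(rec$standardized))
    stop("causality_matrix expects a standardized recording", call. = FALSE)
  vals <- matrix(0, K, K, dimnames = list(rec$channel_labels,
                                          rec$channel_labels))
  if (is.null(pairs)) {
    pairs <- cbind(rep(seq_len(K), each = K), rep(seq_len(K), K))
    pairs <- pairs[pairs[, 1] != pairs[, 2], , drop = FALSE]
  }
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    if (i == j) next
    vals[i, j] <- mime_causality(rec$data[i, ], rec$data[j, ], params)
  }
  structure(list(values = vals, channel_labels = rec$channel_labels,
                 window = window, block_boundaries = rec$block_boundaries),
            class = "causality_matrix")
}

#' @export
print.causality_matrix <- function(x, ...) {
  cat(sprintf("<causality_matrix> %d x %d (row = source, column = target)\n",
              nrow(x$values), ncol(x$values)))
  if (!is.null(x$window))
    cat(sprintf("  window %d: %.2f-%.2f s\n", x$window$index,
                x$window$start_s, x$window$end_s))
  print(round(x$values, 3))
  invisible(x)
}

#' Write a causality matrix as labelled CSV plus a JSON metadata sidecar
#'
#' @param cm a [causality_matrix()].
#' @param path output CSV path; the sidecar is written to `<path>.json`.
#' @param params optional [mime_params()] recorded in the sidecar.
#' @return `path`, invisibly.
#' @export
write_causality_matrix <- function(cm, path, params = NULL) {
  write.csv(cm$values, path, row.names = TRUE)
  meta <- list(channel_labels = cm$channel_labels, window = cm$window,
               block_boundaries = cm$block_boundaries,
               params = if (!is.null(params)) unclass(params))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read a causality matrix written by [write_causality_matrix()]
#'
#' @param path CSV path.
#' @return a `causality_matrix`.
#' @export
read_causality_matrix <- function(path) {
  tab <- read.csv(path, row.names = 1, check.names = FALSE)
  vals <- as.matrix(tab)
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path) else list()
  bb <- meta$block_boundaries
  if (!is.null(bb)) bb <- lapply(bb, function(b) as.integer(unlist(b)))
  structure(list(values = vals, channel_labels = colnames(vals),
                 window = meta$window, block_boundaries = bb),
            class = "causality_matrix")
}
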