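#' Multichannel recording container
#'
#' Bundles a synchronized channels-by-samples signal matrix with its sampling
#' rate, channel labels (10-20 system names for EEG) and a subject id.
#'
#' @param data numeric matrix, `n_channels x n_samples`.
#' @param fs sampling rate in Hz.
#' @param channel_labels character vector, one unique label per channel.
#' @param subject_id subject identifier string.
#' @param standardized logical; `TRUE` once each channel has been z-scored.
#' @param block_boundaries for augmented multi-subject recordings, a named
#'   list mapping subject id to the channel index range it occupies.
#' @return an object of class `mc_recording`.
#' @export
mc_recording <- function(data, fs, channel_labels,
                         subject_id = "S1", standardized = FALSE,
                         block_boundaries = NULL) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (nrow(data) < 2L)
    stop("recording needs at least 2 channels", call. = FALSE)
  if (ncol(data) < 2L * nrow(data))
    stop("recording needs n_samples >= 2 * n_channels", call. = FALSE)
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("fs must be a positive sampling rate in Hz", call. = FALSE)
  channel_labels <- as.character(channel_labels)
  if (length(channel_labels) != nrow(data))
    stop("label count (", length(channel_labels),
         ") differs from channel count (", nrow(data), ")", call. = FALSE)
  if (anyDuplicated(channel_labels))
    stop("channel labels must be unique", call. = FALSE)
  if (any(!is.finite(data)))
    stop("recording contains non-finite values", call. = FALSE)
  rownames(data) <- channel_labels
  structure(
    list(data = data, fs = fs, channel_labels = channel_labels,
         subject_id = subject_id, standardized = standardized,
         block_boundaries = block_boundaries),
    class = "mc_recording")
}

#' @export
print.mc_recording <- function(x, ...) {
  cat(sprintf("<mc_recording> subject '%s': %d channels x %d samples @ %g Hz (%.2f s)%s\n",
              x$subject_id, nrow(x$data), ncol(x$data), x$fs,
              ncol(x$data) / x$fs,
              if (x$standardized) ", standardized" else ""))
  cat("  channels:", paste(x$channel_labels, collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.mc_recording <- function(x) dim(x$data)

#' Load a multichannel recording from disk
#'
#' CSV files hold one row per sample and one column per channel, with a
#' header row of channel labels; the sampling rate is supplied out of band.
#' EDF (European Data Format) files carry rate and labels in their header.
#'
#' @param path file path.
#' @param format `"csv"` or `"edf"`; default guessed from the extension.
#' @param fs sampling rate in Hz (required for csv; ignored for edf).
#' @param labels optional channel labels overriding the csv header.
#' @param subject_id subject identifier.
#' @return an unstandardized [mc_recording()], channel order as stored.
#' @export
load_recording <- function(path, format = c("csv", "edf"), fs = NULL,
                           labels = NULL, subject_id = "S1") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (missing(format))
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "csv"
  format <- match.arg(format)
  if (format == "edf") return(read_edf(path, subject_id = subject_id))

  if (is.null(fs)) stop("fs must be supplied for csv input", call. = FALSE)
  tab <- read.csv(path, check.names = FALSE)
  if (!all(vapply(tab, is.numeric, logical(1))))
    stop("non-numeric cells in ", path, call. = FALSE)
  if (is.null(labels)) labels <- names(tab)
  if (length(labels) != ncol(tab))
    stop("label count (", length(labels), ") differs from column count (",
         ncol(tab), ")", call. = FALSE)
  mc_recording(t(as.matrix(tab)), fs = fs, channel_labels = labels,
               subject_id = subject_id)
}

# Minimal EDF reader (no EDF package ships with the target library set).
# Reads the 256-byte fixed header, the per-signal header block, and the
# int16 data records; assumes a common sampling rate across signals.
read_edf <- function(path, subject_id = "S1") {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_chr <- function(nch) trimws(rawToChar(readBin(con, "raw", nch)))
  hdr_num <- function(nch) as.numeric(hdr_chr(nch))
  hdr_chr(8)                      # version
  hdr_chr(80); hdr_chr(80)        # patient / recording id
  hdr_chr(8); hdr_chr(8)          # start date / time
  hdr_num(8)                      # header bytes
  hdr_chr(44)                     # reserved
  n_rec <- hdr_num(8)
  rec_dur <- hdr_num(8)
  ns <- as.integer(hdr_num(4))
  if (is.na(ns) || ns < 1L) stop("corrupt EDF header", call. = FALSE)
  field <- function(nch) vapply(seq_len(ns), function(i) hdr_chr(nch), "")
  labels <- field(16)
  field(80); field(8)                           # transducer, unit
  pmin <- as.numeric(field(8)); pmax <- as.numeric(field(8))
  dmin <- as.numeric(field(8)); dmax <- as.numeric(field(8))
  field(80)                                     # prefiltering
  nsamp <- as.integer(field(8))                 # samples per record
  field(32)                                     # reserved
  if (length(unique(nsamp)) != 1L)
    stop("EDF signals with differing rates are not supported", call. = FALSE)
  fs <- nsamp[1] / rec_dur
  gain <- (pmax - pmin) / (dmax - dmin)
  data <- matrix(0, ns, n_rec * nsamp[1])
  for (r in seq_len(n_rec)) {
    for (s in seq_len(ns)) {
      raw <- readBin(con, "integer", nsamp[s], size = 2, endian = "little")
      data[s, ((r - 1) * nsamp[s] + 1):(r * nsamp[s])] <-
        pmin[s] + (raw - dmin[s]) * gain[s]
    }
  }
  mc_recording(data, fs = fs, channel_labels = labels,
               subject_id = subject_id)
}

#' Z-score every channel of a recording
#'
#' MIME operates on standardized voltages: each channel has its mean removed
#' and is scaled to unit standard deviation over the chosen span.
#'
#' @param rec an [mc_recording()].
#' @param scope standardization span; kept for symmetry with windowed use —
#'   calling this on a whole recording gives `"global"` scope, calling it on
#'   each window gives `"per_window"` scope.
#' @return the standardized recording.
#' @export
standardize <- function(rec, scope = c("per_window", "global")) {
  scope <- match.arg(scope)
  m <- rowMeans(rec$data)
  s <- apply(rec$data, 1, sd)
  bad <- which(s <= 0 | !is.finite(s))
  if (length(bad))
    stop("zero-variance channel(s): ",
         paste(rec$channel_labels[bad], collapse = ", "), call. = FALSE)
  rec$data <- (rec$data - m) / s
  rec$standardized <- TRUE
  rec
}

#' Cut a recording into consecutive non-overlapping windows
#'
#' Windows are indexed from 1; under 1-based sample indexing window `i` at
#' 100 Hz and 10 s spans, e.g., 140.01-150.00 s for `i = 15`.  A trailing
#' partial window is discarded.
#'
#' @param rec an [mc_recording()].
#' @param length_s window duration in seconds; `length_s * fs` must be at
#'   least 100 samples (estimator floor).
#' @param overlap fraction of a window shared with its successor; default 0
#'   (consecutive windows).
#' @param standardize_scope `"per_window"` re-z-scores every window
#'   independently; `"global"` standardizes once over the full recording;
#'   `"none"` leaves the data untouched.
#' @return list of elements `list(spec = window spec, rec = window recording)`;
#'   each spec has fields `index`, `start_s`, `end_s`, `length_s`.
#' @export
segment_windows <- function(rec, length_s,
                            overlap = 0,
                            standardize_scope = c("per_window", "global", "none")) {
  standardize_scope <- match.arg(standardize_scope)
  wlen <- as.integer(round(length_s * rec$fs))
  if (wlen < 100L)
    stop("window of ", wlen, " samples is below the 100-sample estimator floor",
         call. = FALSE)
  n <- ncol(rec$data)
  if (n < wlen) stop("recording shorter than one window", call. = FALSE)
  if (overlap < 0 || overlap >= 1) stop("overlap must be in [0, 1)", call. = FALSE)
  step <- max(1L, as.integer(round(wlen * (1 - overlap))))
  starts <- seq(1L, n - wlen + 1L, by = step)
  if (standardize_scope == "global") rec <- standardize(rec, "global")
  lapply(seq_along(starts), function(i) {
    s0 <- starts[i]
    w <- rec
    w$data <- rec$data[, s0:(s0 + wlen - 1L), drop = FALSE]
    if (standardize_scope == "per_window") w <- standardize(w, "per_window")
    list(spec = list(index = i,
                     start_s = (s0 - 1L) / rec$fs + 1 / rec$fs,
                     end_s = (s0 + wlen - 1L) / rec$fs,
                     length_s = wlen / rec$fs),
         rec = w)
  })
}

#' Stack two synchronized recordings into an augmented recording
#'
#' Channel-stacks subject A on top of subject B so that one causality matrix
#' holds two intra-brain diagonal blocks and two cross-brain off-diagonal
#' blocks.  Labels are prefixed with the subject id; block boundaries are
#' recorded for downstream block extraction.
#'
#' @param recA,recB synchronized [mc_recording()] objects with equal `fs`
#'   and equal length (up to one sample, the shorter length is used).
#' @return an augmented [mc_recording()].
#' @export
build_augmented <- function(recA, recB) {
  if (recA$fs != recB$fs)
    stop("sampling rates differ: ", recA$fs, " vs ", recB$fs, call. = FALSE)
  nA <- ncol(recA$data); nB <- ncol(recB$data)
  if (abs(nA - nB) > 1L)
    stop("recordings are not synchronized: ", nA, " vs ", nB, " samples",
         call. = FALSE)
  n <- min(nA, nB)
  kA <- nrow(recA$data); kB <- nrow(recB$data)
  data <- rbind(recA$data[, 1:n, drop = FALSE], recB$data[, 1:n, drop = FALSE])
  labels <- c(paste(recA$subject_id, recA$channel_labels, sep = "."),
              paste(recB$subject_id, recB$channel_labels, sep = "."))
  blocks <- list()
  blocks[[recA$subject_id]] <- c(1L, kA)
  blocks[[recB$subject_id]] <- c(kA + 1L, kA + kB)
  mc_recording(data, fs = recA$fs, channel_labels = labels,
               subject_id = paste(recA$subject_id, recB$subject_id, sep = "+"),
               standardized = recA$standardized && recB$standardized,
               block_boundaries = blocks)
}
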