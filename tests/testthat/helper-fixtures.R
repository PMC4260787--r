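# shared fixture builders; everything is generated in code at test time

# plain CSV recording on disk: one row per sample, one column per channel
write_csv_recording <- function(data, labels, path = tempfile(fileext = ".csv")) {
  tab <- as.data.frame(t(data))
  names(tab) <- labels
  write.csv(tab, path, row.names = FALSE)
  path
}

# minimal EDF writer, independent of the package reader: 256-byte fixed
# header, one per-signal header block, int16 data records
write_edf_fixture <- function(data, fs, labels,
                              path = tempfile(fileext = ".edf")) {
  ns <- nrow(data)
  nsamp <- ncol(data)              # one record holding everything
  pad <- function(x, n) {
    x <- as.character(x)
    paste0(x, strrep(" ", n - nchar(x)))
  }
  pmin <- -1000; pmax <- 1000; dmin <- -32768; dmax <- 32767
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, n) writeBin(charToRaw(pad(x, n)), con)
  wr("0", 8); wr("patient", 80); wr("recording", 80)
  wr("01.01.20", 8); wr("00.00.00", 8)
  wr(256 + ns * 256, 8); wr("", 44)
  wr(1, 8)                         # one data record
  wr(format(nsamp / fs, digits = 10), 8)
  wr(ns, 4)
  for (l in labels) wr(l, 16)
  for (i in 1:ns) wr("transducer", 80)
  for (i in 1:ns) wr("uV", 8)
  for (i in 1:ns) wr(pmin, 8)
  for (i in 1:ns) wr(pmax, 8)
  for (i in 1:ns) wr(dmin, 8)
  for (i in 1:ns) wr(dmax, 8)
  for (i in 1:ns) wr("", 80)
  for (i in 1:ns) wr(nsamp, 8)
  for (i in 1:ns) wr("", 32)
  gain <- (pmax - pmin) / (dmax - dmin)
  for (s in 1:ns) {
    dig <- as.integer(round((data[s, ] - pmin) / gain + dmin))
    writeBin(dig, con, size = 2, endian = "little")
  }
  path
}

# standardized channel pair with planted linear coupling source -> target
coupled_pair <- function(n, strength = 0.8, lag = 1L, seed = 1L,
                         ar = c(0.9, 0.5)) {
  g <- gen_coupled_linear(coupling_spec(
    n_channels = 2L,
    couplings = data.frame(source = 1, target = 2, lag = lag,
                           strength = strength),
    base = "ar1", ar_coef = ar, fs = 100,
    duration_s = n / 100 + 1.1, seed = seed))
  r <- standardize(g$rec, "global")
  list(x = r$data[1, 1:n], y = r$data[2, 1:n])
}

# independent standardized channel pair
independent_pair <- function(n, seed = 1L) {
  g <- gen_coupled_linear(coupling_spec(
    n_channels = 2L, couplings = NULL, base = "ar1", fs = 100,
    duration_s = n / 100 + 1.1, seed = seed))
  r <- standardize(g$rec, "global")
  list(x = r$data[1, 1:n], y = r$data[2, 1:n])
}

# causality_matrix object from a plain numeric matrix, for network-layer tests
as_cm <- function(values, labels = NULL, blocks = NULL) {
  if (is.null(labels)) labels <- paste0("ch", seq_len(nrow(values)))
  dimnames(values) <- list(labels, labels)
  structure(list(values = values, channel_labels = labels, window = NULL,
                 block_boundaries = blocks),
            class = "causality_matrix")
}
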