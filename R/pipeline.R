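#' Resolved run configuration
#'
#' Collects every tunable of the analysis: estimator and embedding
#' parameters, windowing, thresholding rules, cross-brain dominance margin,
#' and the master seed.  A resolved copy is written beside every output
#' bundle so a run is reproducible from its artifacts alone.
#'
#' @param window_s moving-window length in seconds (default 10).
#' @param overlap window overlap fraction (default 0, consecutive windows).
#' @param standardize_scope `"per_window"` or `"global"`.
#' @param frac_intra named or unnamed numeric vector of intra-brain threshold
#'   fractions (the study used 0.2 for the performer, 0.1 for the listener).
#' @param radius_divisor contrast threshold = radius / divisor (default 2).
#' @param delta cross-brain dominance margin (default 0.10).
#' @param channel_subset optional character vector restricting the analysis
#'   to these channel labels.
#' @param seed master seed; per-stage seeds are derived from it.
#' @param mime a [mime_params()] object.
#' @param out_dir output directory for [run_pipeline()].
#' @return a `run_config` list.
#' @export
run_config <- function(window_s = 10, overlap = 0,
                       standardize_scope = "per_window",
                       frac_intra = 0.2, radius_divisor = 2, delta = 0.10,
                       channel_subset = NULL,
                       seed = 1L, mime = mime_params(), out_dir = tempdir()) {
  structure(list(window_s = window_s, overlap = overlap,
                 standardize_scope = standardize_scope,
                 frac_intra = frac_intra, radius_divisor = radius_divisor,
                 delta = delta, channel_subset = channel_subset,
                 seed = as.integer(seed), mime = mime,
                 out_dir = out_dir),
            class = "run_config")
}

config_to_list <- function(cfg) {
  out <- unclass(cfg)
  out$mime <- unclass(out$mime)
  # named vectors must survive JSON as objects, not bare arrays
  if (!is.null(names(out$frac_intra))) out$frac_intra <- as.list(out$frac_intra)
  out
}

#' Write a config as flat JSON
#' @param cfg a [run_config()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  jsonlite::write_json(config_to_list(cfg), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a config written by [write_config()]
#' @param path JSON path.
#' @return a `run_config`.
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  mp <- do.call(mime_params, raw$mime)
  raw$mime <- NULL
  if (is.list(raw$frac_intra)) raw$frac_intra <- unlist(raw$frac_intra)
  do.call(run_config, c(raw, list(mime = mp)))
}

#' Windowed causality matrices of one recording
#'
#' Standardizes, windows, and computes one causality matrix per window.
#'
#' @param rec an [mc_recording()] (plain or augmented).
#' @param config a [run_config()].
#' @param pairs optional channel-pair subset passed to [causality_matrix()].
#' @return list of `causality_matrix` objects, one per window.
#' @export
windowed_matrices <- function(rec, config = run_config(), pairs = NULL) {
  if (!is.null(config$channel_subset)) {
    keep <- which(rec$channel_labels %in% config$channel_subset)
    if (length(keep) < 2L)
      stop("channel_subset keeps fewer than 2 channels", call. = FALSE)
    rec$data <- rec$data[keep, , drop = FALSE]
    rec$channel_labels <- rec$channel_labels[keep]
    rec$block_boundaries <- NULL
  }
  wins <- segment_windows(rec, config$window_s, overlap = config$overlap,
                          standardize_scope = config$standardize_scope)
  lapply(wins, function(w)
    causality_matrix(w$rec, params = config$mime, pairs = pairs,
                     window = w$spec))
}

cross_block_pairs <- function(rec) {
  bb <- rec$block_boundaries
  if (is.null(bb) || length(bb) < 2L) return(NULL)
  out <- NULL
  subj <- names(bb)
  for (a in subj) for (b in subj) {
    if (a == b) next
    ra <- bb[[a]][1]:bb[[a]][2]; rb <- bb[[b]][1]:bb[[b]][2]
    out <- rbind(out, cbind(rep(ra, each = length(rb)), rep(rb, length(ra))))
  }
  out
}

#' End-to-end analysis of a synthetic scenario or supplied recordings
#'
#' Runs the full pipeline and writes an artifact bundle: windowed causality
#' matrices, condition averages, intra networks, contrast matrix/network for
#' condition pairs, degree profiles and contrasts, cross-brain weight series
#' and links, a threshold-sweep report, the resolved config and a log.
#'
#' @param config a [run_config()].
#' @param scenario one of `"intra"`, `"reading"`, `"ensemble"`,
#'   `"contrast"` for a built-in synthetic scenario, or `NULL` when
#'   `recordings` are supplied.
#' @param recordings optional named list of [mc_recording()] objects
#'   analysed instead of a synthetic scenario (each gets windowed matrices,
#'   an averaged matrix and an intra network).
#' @param cross_only for augmented inputs, compute only cross-block entries
#'   (faster when only cross-brain weights are needed).
#' @return named list of in-memory results; files are written under
#'   `config$out_dir`.
#' @export
run_pipeline <- function(config = run_config(), scenario = NULL,
                         recordings = NULL, cross_only = FALSE) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "run.log")
  logf <- function(...) cat(sprintf("[%s] %s\n", format(Sys.time(), "%H:%M:%S"),
                                    sprintf(...)),
                            file = log_path, append = TRUE)
  write_config(config, file.path(config$out_dir, "config.json"))
  cfg_hash <- sum(utf8ToInt(jsonlite::toJSON(config_to_list(config),
                                             auto_unbox = TRUE, digits = NA)))
  logf("resolved config hash %d, seed %d", cfg_hash, config$seed)
  results <- list(config = config, config_hash = cfg_hash)

  if (is.null(recordings)) {
    if (is.null(scenario))
      stop("supply either a scenario or recordings", call. = FALSE)
    scenario <- match.arg(scenario, c("intra", "reading", "ensemble",
                                      "contrast"))
    logf("generating scenario '%s'", scenario)
    sseed <- derive_seed(config$seed, 1L)
    recordings <- switch(scenario,
      intra = {
        g <- gen_coupled_linear(coupling_spec(
          n_channels = 4L,
          couplings = data.frame(source = c(1, 3), target = c(2, 4),
                                 lag = 1L, strength = 0.8),
          base = "ar1", fs = 100, duration_s = 3 * config$window_s + 1,
          seed = sseed))
        results$truth <- g$truth
        list(subject = g$rec)
      },
      reading = {
        g <- gen_two_brain(
          coupling_spec(n_channels = 3L, base = "ar1", fs = 100,
                        duration_s = 5 * config$window_s + 1, seed = sseed),
          coupling_spec(n_channels = 3L, base = "ar1", fs = 100,
                        duration_s = 5 * config$window_s + 1, seed = sseed),
          coupling = 0.8, lag = 1L)
        results$truth <- g$truth
        list(pair = g$rec)
      },
      ensemble = {
        g <- gen_ensemble(
          4L,
          data.frame(from = c(1, 1, 1, 2, 3), to = c(2, 3, 4, 4, 4),
                     strength = 0.7,
                     mode = c("fixed", "fixed", "fixed", "fixed", "fixed")),
          coupling_spec(n_channels = 2L, base = "ar1", fs = 100,
                        duration_s = 5 * config$window_s + 1, seed = sseed),
          window_s = config$window_s)
        results$truth <- g$truth
        g$pairs
      },
      contrast = {
        g <- gen_two_condition(
          coupling_spec(n_channels = 4L, base = "ar1", fs = 100,
                        duration_s = 3 * config$window_s + 1, seed = sseed),
          deltaEdges = data.frame(source = 1, target = 2, lag = 1L,
                                  strength = 0.8))
        results$truth <- g$truth
        list(condA = g$recA, condB = g$recB)
      })
  }

  mats <- list(); avgs <- list(); nets <- list()
  fr <- config$frac_intra
  for (nm in names(recordings)) {
    rec <- recordings[[nm]]
    pairs <- if (cross_only) cross_block_pairs(rec) else NULL
    logf("windowed matrices for '%s' (%d channels)", nm, nrow(rec$data))
    m <- windowed_matrices(rec, config, pairs = pairs)
    for (i in seq_along(m))
      write_causality_matrix(m[[i]],
        file.path(config$out_dir, sprintf("matrix_%s_w%02d.csv", nm, i)),
        params = config$mime)
    avg <- average_matrices(m)
    write_causality_matrix(avg,
      file.path(config$out_dir, sprintf("matrix_%s_avg.csv", nm)))
    mats[[nm]] <- m; avgs[[nm]] <- avg
    if (is.null(rec$block_boundaries)) {
      f <- if (!is.null(names(fr)) && nm %in% names(fr)) fr[[nm]] else fr[[1]]
      logf("intra network '%s': threshold = %g x max = %g", nm, f,
           f * max(avg$values))
      net <- intra_network(avg, frac = f)
      write_network_csv(net, file.path(config$out_dir,
                                       sprintf("intra_%s.csv", nm)))
      nets[[nm]] <- net
    }
  }
  results$matrices <- mats
  results$averages <- avgs
  results$intra_networks <- nets

  # contrast layer over consecutive condition pairs of plain recordings
  plain <- names(recordings)[vapply(recordings, function(r)
    is.null(r$block_boundaries), TRUE)]
  if (length(plain) >= 2L) {
    a <- plain[1]; b <- plain[2]
    cm <- contrast_matrix(avgs[[a]], avgs[[b]])
    cn <- contrast_network(cm, radius_divisor = config$radius_divisor)
    logf("contrast %s vs %s: radius %g, threshold %g", a, b,
         cn$radius %||% 0, cn$threshold %||% 0)
    write_network_csv(cn, file.path(config$out_dir,
                                    sprintf("contrast_%s_vs_%s.csv", a, b)))
    results$contrast <- list(matrix = cm, network = cn)
    profs <- lapply(list(a, b), function(nm)
      average_degree_profiles(lapply(mats[[nm]], function(m)
        degree_profiles(intra_network(average_matrices(list(m)),
                                      frac = fr[[1]])))))
    dc <- degree_contrast(profs[[1]], profs[[2]])
    write.csv(dc, file.path(config$out_dir, "degree_contrast.csv"),
              row.names = FALSE)
    results$degree_contrast <- dc
  }

  # cross-brain layer over augmented recordings
  aug <- names(recordings)[vapply(recordings, function(r)
    !is.null(r$block_boundaries), TRUE)]
  if (length(aug)) {
    links <- list(); weights <- list()
    for (nm in aug) {
      w <- cross_brain_weights(mats[[nm]])
      weights[[nm]] <- w
      dirs <- unique(w[c("from", "to")])
      done <- character(0)
      for (r in seq_len(nrow(dirs))) {
        a <- dirs$from[r]; b <- dirs$to[r]
        key <- paste(sort(c(a, b)), collapse = "|")
        if (key %in% done) next
        done <- c(done, key)
        wab <- w$weight[w$from == a & w$to == b]
        wba <- w$weight[w$from == b & w$to == a]
        lk <- cross_brain_link(wab, wba, delta = config$delta)
        logf("cross-brain %s/%s: link %s (means %.4f / %.4f)", a, b,
             lk$link, lk$mean_AB, lk$mean_BA)
        links[[paste(a, b, sep = "|")]] <-
          data.frame(A = a, B = b, link = lk$link, mean_AB = lk$mean_AB,
                     mean_BA = lk$mean_BA, stringsAsFactors = FALSE)
      }
      write.csv(w, file.path(config$out_dir,
                             sprintf("cross_weights_%s.csv",
                                     gsub("[^A-Za-z0-9]+", "_", nm))),
                row.names = FALSE)
    }
    links <- do.call(rbind, links)
    write.csv(links, file.path(config$out_dir, "cross_links.csv"),
              row.names = FALSE)
    results$cross_weights <- weights
    results$cross_links <- links
  }

  # threshold-robustness report on the first available analysis
  sweep <- NULL
  if (length(nets)) {
    sweep <- threshold_sweep(avgs[[names(nets)[1]]], type = "intra",
                             frac = fr[[1]])
  } else if (!is.null(results$contrast)) {
    sweep <- threshold_sweep(results$contrast$matrix, type = "contrast")
  }
  if (!is.null(sweep)) {
    jsonlite::write_json(sweep, file.path(config$out_dir, "threshold_sweep.json"),
                         auto_unbox = TRUE, digits = NA)
    results$threshold_sweep <- sweep
  }
  logf("done")
  results
}

#' Command-line entry point
#'
#' Subcommands: `simulate` (write a synthetic scenario as CSV plus a truth
#' JSON), `analyze` (recording CSV to windowed matrices and networks via
#' [run_pipeline()]), `networks` (saved averaged matrix to an intra or
#' contrast network edge list), `centrality` (edge-list CSV to degree
#' profiles), `sweep` (saved matrix to a threshold-robustness report).
#' Mirrors the main config keys as flags.
#'
#' @param args character vector, e.g. `commandArgs(trailingOnly = TRUE)`.
#' @return exit status, invisibly.
#' @export
mimenet_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: mimenet <simulate|analyze|networks|centrality|sweep> [options]",
    "  simulate   --scenario {intra,reading,ensemble,contrast} --seed N --out DIR",
    "  analyze    [--scenario NAME | --csv FILE --fs HZ] [--window-s S]",
    "             [--frac F] [--delta D] [--seed N] --out DIR",
    "  networks   --matrix FILE.csv [--type intra|contrast] [--frac F] --out FILE.csv",
    "  centrality --edges FILE.csv --out FILE.csv",
    "  sweep      --matrix FILE.csv [--type intra|contrast] [--frac F] --out FILE.json",
    sep = "\n")
  if (!length(args)) { message(usage); return(invisible(1L)) }
  cmd <- args[1]; args <- args[-1]
  opt <- list(scenario = NULL, seed = 1L, out = "mimenet_out",
              window_s = 10, frac = 0.2, delta = 0.10, csv = NULL, fs = NULL,
              matrix = NULL, edges = NULL, type = "intra")
  i <- 1L
  while (i <= length(args)) {
    key <- sub("^--", "", args[i])
    key <- gsub("-", "_", key)
    if (i == length(args)) stop("missing value for --", key, call. = FALSE)
    val <- args[i + 1L]
    opt[[key]] <- if (key %in% c("seed")) as.integer(val)
                  else if (key %in% c("window_s", "frac", "delta", "fs"))
                    as.numeric(val)
                  else val
    i <- i + 2L
  }
  cfg <- run_config(window_s = opt$window_s, frac_intra = opt$frac,
                    delta = opt$delta, seed = opt$seed, out_dir = opt$out)
  if (cmd == "simulate") {
    if (is.null(opt$scenario)) stop("simulate needs --scenario", call. = FALSE)
    dir.create(opt$out, showWarnings = FALSE, recursive = TRUE)
    sseed <- derive_seed(opt$seed, 1L)
    g <- switch(opt$scenario,
      intra = gen_coupled_linear(coupling_spec(
        n_channels = 4L,
        couplings = data.frame(source = 1, target = 2, lag = 1L,
                               strength = 0.8),
        fs = 100, duration_s = 3 * opt$window_s + 1, seed = sseed)),
      reading = gen_two_brain(
        coupling_spec(n_channels = 3L, fs = 100,
                      duration_s = 5 * opt$window_s + 1, seed = sseed),
        coupling_spec(n_channels = 3L, fs = 100,
                      duration_s = 5 * opt$window_s + 1, seed = sseed)),
      contrast = {
        g2 <- gen_two_condition(
          coupling_spec(n_channels = 4L, fs = 100,
                        duration_s = 3 * opt$window_s + 1, seed = sseed),
          deltaEdges = data.frame(source = 1, target = 2, lag = 1L,
                                  strength = 0.8))
        list(rec = g2$recA, rec2 = g2$recB, truth = g2$truth)
      },
      stop("unknown scenario: ", opt$scenario, call. = FALSE))
    for (nm in intersect(names(g), c("rec", "rec2", "recA", "recB"))) {
      write.csv(t(g[[nm]]$data),
                file.path(opt$out, paste0("signal_", nm, ".csv")),
                row.names = FALSE)
    }
    jsonlite::write_json(g$truth, file.path(opt$out, "truth.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    message("wrote scenario '", opt$scenario, "' to ", opt$out)
    return(invisible(0L))
  }
  if (cmd == "analyze") {
    if (!is.null(opt$csv)) {
      rec <- load_recording(opt$csv, format = "csv", fs = opt$fs)
      run_pipeline(cfg, recordings = list(input = rec))
    } else if (!is.null(opt$scenario)) {
      run_pipeline(cfg, scenario = opt$scenario)
    } else stop("analyze needs --csv or --scenario", call. = FALSE)
    message("analysis written to ", opt$out)
    return(invisible(0L))
  }
  if (cmd == "networks") {
    if (is.null(opt$matrix)) stop("networks needs --matrix", call. = FALSE)
    cm <- read_causality_matrix(opt$matrix)
    net <- if (opt$type == "contrast") contrast_network(cm)
           else intra_network(cm, frac = opt$frac)
    write_network_csv(net, opt$out)
    message(nrow(net$edges), " edge(s) written to ", opt$out)
    return(invisible(0L))
  }
  if (cmd == "centrality") {
    if (is.null(opt$edges)) stop("centrality needs --edges", call. = FALSE)
    e <- read.csv(opt$edges, stringsAsFactors = FALSE)
    nodes <- sort(unique(c(e$source, e$target)))
    net <- structure(list(nodes = nodes, edges = e, signed = FALSE),
                     class = "directed_network")
    write.csv(degree_profiles(net), opt$out, row.names = FALSE)
    message("degree profiles written to ", opt$out)
    return(invisible(0L))
  }
  if (cmd == "sweep") {
    if (is.null(opt$matrix)) stop("sweep needs --matrix", call. = FALSE)
    cm <- read_causality_matrix(opt$matrix)
    sw <- threshold_sweep(cm, type = opt$type, frac = opt$frac)
    jsonlite::write_json(sw, opt$out, auto_unbox = TRUE, digits = NA)
    message("sweep report written to ", opt$out)
    return(invisible(0L))
  }
  message(usage)
  invisible(1L)
}
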