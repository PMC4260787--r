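#' Entrywise mean of causality matrices
#'
#' Time-averaging over moving windows is the first step of intra-brain and
#' contrast network construction.
#'
#' @param mats list of `causality_matrix` objects with identical shape and
#'   labels.
#' @return a `causality_matrix` whose window metadata records the covered
#'   span.
#' @export
average_matrices <- function(mats) {
  if (!length(mats)) stop("no matrices to average", call. = FALSE)
  labs <- mats[[1]]$channel_labels
  for (m in mats) {
    if (!identical(dim(m$values), dim(mats[[1]]$values)) ||
        !identical(m$channel_labels, labs))
      stop("matrices differ in shape or labels", call. = FALSE)
  }
  avg <- Reduce(`+`, lapply(mats, `[[`, "values")) / length(mats)
  spans <- lapply(mats, `[[`, "window")
  window <- NULL
  if (!any(vapply(spans, is.null, TRUE))) {
    window <- list(index = NA_integer_,
                   start_s = min(vapply(spans, `[[`, 0, "start_s")),
                   end_s = max(vapply(spans, `[[`, 0, "end_s")),
                   length_s = NA_real_, n_windows = length(mats))
  }
  structure(list(values = avg, channel_labels = labs, window = window,
                 block_boundaries = mats[[1]]$block_boundaries),
            class = "causality_matrix")
}

new_network <- function(nodes, edges, signed = FALSE) {
  if (is.null(edges) || !nrow(edges)) {
    edges <- data.frame(source = character(0), target = character(0),
                        weight = numeric(0), sign = character(0),
                        stringsAsFactors = FALSE)
  }
  structure(list(nodes = nodes, edges = edges, signed = signed),
            class = "directed_network")
}

#' @export
print.directed_network <- function(x, ...) {
  cat(sprintf("<directed_network> %d nodes, %d edges%s\n", length(x$nodes),
              nrow(x$edges), if (x$signed) " (signed contrast)" else ""))
  if (nrow(x$edges)) print(x$edges)
  invisible(x)
}

#' Convert a directed network to an igraph object
#'
#' @param net a `directed_network`.
#' @return an [igraph::graph_from_data_frame()] directed graph.
#' @export
as_igraph <- function(net) {
  igraph::graph_from_data_frame(net$edges, directed = TRUE,
                                vertices = data.frame(name = net$nodes))
}

#' Intra-brain network from an averaged causality matrix
#'
#' The significance threshold is `frac` times the maximum off-diagonal entry
#' of the time-averaged matrix; an edge `i -> j` is drawn when the entry is
#' positive and at or above the threshold (inclusive comparison, so a
#' uniform matrix yields the complete directed graph).
#'
#' @param avg averaged `causality_matrix` for one subject.
#' @param frac threshold fraction in (0, 1); the study used 0.2 for the
#'   performer and 0.1 for the listener.
#' @return an unsigned `directed_network` with edge weight = averaged
#'   causality.
#' @export
intra_network <- function(avg, frac = 0.2) {
  if (frac <= 0 || frac >= 1) stop("frac must be in (0,1)", call. = FALSE)
  v <- avg$values
  off <- v[row(v) != col(v)]
  thr <- frac * max(off)
  idx <- which(v >= thr & v > 0 & row(v) != col(v), arr.ind = TRUE)
  if (!nrow(idx)) return(new_network(avg$channel_labels, NULL))
  edges <- data.frame(source = avg$channel_labels[idx[, 1]],
                      target = avg$channel_labels[idx[, 2]],
                      weight = v[idx], sign = NA_character_,
                      stringsAsFactors = FALSE)
  new_network(avg$channel_labels, edges)
}

#' Contrast matrix between two condition-averaged causality matrices
#'
#' @param avgA,avgB averaged `causality_matrix` objects for the two
#'   conditions, same shape and labels.
#' @return a signed `causality_matrix` (entries `A - B`).
#' @export
contrast_matrix <- function(avgA, avgB) {
  if (!identical(avgA$channel_labels, avgB$channel_labels) ||
      !identical(dim(avgA$values), dim(avgB$values)))
    stop("matrices differ in shape or labels", call. = FALSE)
  structure(list(values = avgA$values - avgB$values,
                 channel_labels = avgA$channel_labels,
                 window = NULL, block_boundaries = avgA$block_boundaries),
            class = "causality_matrix")
}

#' Signed contrast network via the radius rule
#'
#' The radius is `R = (global max - global min) / 2` of the contrast
#' entries; entries outside `[-R/2, +R/2]` are significant.  Positive
#' significant entries become `A_stronger` ("red") edges, negative ones
#' `B_stronger` ("green") edges.  A zero-range contrast yields an empty
#' network.
#'
#' @param contrast signed `causality_matrix` from [contrast_matrix()].
#' @param radius_divisor the significance threshold is `R / radius_divisor`;
#'   default 2 (threshold = half the radius).
#' @param threshold_scale multiplier applied to the threshold (used by
#'   [threshold_sweep()] for the +/-10% robustness analysis).
#' @return a signed `directed_network`.
#' @export
contrast_network <- function(contrast, radius_divisor = 2,
                             threshold_scale = 1) {
  v <- contrast$values
  off <- v[row(v) != col(v)]
  R <- (max(off) - min(off)) / 2
  thr <- R / radius_divisor * threshold_scale
  if (R <= 0) return(new_network(contrast$channel_labels, NULL, signed = TRUE))
  idx <- which(abs(v) >= thr & abs(v) > 0 & row(v) != col(v), arr.ind = TRUE)
  if (!nrow(idx)) {
    net <- new_network(contrast$channel_labels, NULL, signed = TRUE)
    net$radius <- R; net$threshold <- thr
    return(net)
  }
  edges <- data.frame(source = contrast$channel_labels[idx[, 1]],
                      target = contrast$channel_labels[idx[, 2]],
                      weight = v[idx],
                      sign = ifelse(v[idx] > 0, "A_stronger", "B_stronger"),
                      stringsAsFactors = FALSE)
  net <- new_network(contrast$channel_labels, edges, signed = TRUE)
  net$radius <- R
  net$threshold <- thr
  net
}

#' Binary adjacency matrix of the intra-brain network
#'
#' Thresholds the averaged matrix with the [intra_network()] rule, then
#' transposes, so that `adjacency[i, j] = 1` encodes an edge `j -> i` of the
#' causality matrix — i.e. the row convention in which the graph built from
#' the adjacency equals the graph built by [intra_network()].
#'
#' @inheritParams intra_network
#' @param mat averaged `causality_matrix`.
#' @return binary integer matrix (transposed adjacency).
#' @export
binarize_and_transpose <- function(mat, frac = 0.2) {
  v <- mat$values
  off <- v[row(v) != col(v)]
  thr <- frac * max(off)
  b <- (v >= thr & v > 0 & row(v) != col(v)) * 1L
  t(b)
}

#' In/out degree profile of a directed network
#'
#' Counts in-going and out-going edges per node and appends the mean over
#' nodes as a pseudo-node `"mean"`, mirroring degree-centrality plots that
#' show each electrode plus the overall average.
#'
#' @param net a `directed_network`.
#' @return data frame with columns `node`, `in_degree`, `out_degree`.
#' @export
degree_profiles <- function(net) {
  ind <- vapply(net$nodes, function(nd) sum(net$edges$target == nd), 0)
  outd <- vapply(net$nodes, function(nd) sum(net$edges$source == nd), 0)
  data.frame(node = c(net$nodes, "mean"),
             in_degree = c(ind, mean(ind)),
             out_degree = c(outd, mean(outd)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Average degree profiles over windows (or conditions)
#'
#' @param profiles list of data frames from [degree_profiles()] over the
#'   same node set.
#' @return data frame of real-valued averaged degrees.
#' @export
average_degree_profiles <- function(profiles) {
  base <- profiles[[1]]
  for (p in profiles) if (!identical(p$node, base$node))
    stop("degree profiles have mismatched nodes", call. = FALSE)
  data.frame(node = base$node,
             in_degree = rowMeans(sapply(profiles, `[[`, "in_degree")),
             out_degree = rowMeans(sapply(profiles, `[[`, "out_degree")),
             stringsAsFactors = FALSE)
}

#' Per-node degree-centrality contrast between two conditions
#'
#' @param profA,profB (averaged) degree profiles over the same node set;
#'   contrast is `A - B`.
#' @return data frame with per-node `in_contrast` and `out_contrast`
#'   (including the `"mean"` pseudo-node).
#' @export
degree_contrast <- function(profA, profB) {
  if (!identical(profA$node, profB$node))
    stop("degree profiles have mismatched nodes", call. = FALSE)
  data.frame(node = profA$node,
             in_contrast = profA$in_degree - profB$in_degree,
             out_contrast = profA$out_degree - profB$out_degree,
             stringsAsFactors = FALSE)
}

#' Per-window cross-brain weights from augmented causality matrices
#'
#' For every ordered subject pair the weight in a window is the mean of the
#' corresponding off-diagonal block of the augmented matrix (averaging the
#' cross-brain causalities over electrodes).  Entries below `noise_floor`
#' are treated as residual flow from estimator noise and zeroed before
#' averaging: spurious causality indices on independent channels stay below
#' 0.1, so the default floor of 0.1 removes them while leaving genuine
#' couplings untouched.
#'
#' @param mats list of augmented `causality_matrix` objects (one per window)
#'   carrying `block_boundaries`.
#' @param noise_floor entries below this value are zeroed before block
#'   averaging (default 0.1; set 0 to disable).
#' @return data frame with columns `window`, `from`, `to`, `weight`.
#' @export
cross_brain_weights <- function(mats, noise_floor = 0.1) {
  out <- list()
  for (w in seq_along(mats)) {
    m <- mats[[w]]
    bb <- m$block_boundaries
    if (is.null(bb) || length(bb) < 2L)
      stop("matrix lacks block boundaries; build it from an augmented recording",
           call. = FALSE)
    subj <- names(bb)
    widx <- if (!is.null(m$window)) m$window$index else w
    v <- m$values
    v[v < noise_floor] <- 0
    for (a in subj) for (b in subj) {
      if (a == b) next
      ra <- bb[[a]][1]:bb[[a]][2]
      rb <- bb[[b]][1]:bb[[b]][2]
      out[[length(out) + 1L]] <-
        data.frame(window = widx, from = a, to = b,
                   weight = mean(v[ra, rb]),
                   stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Cross-brain link decision by per-window dominance
#'
#' Direction `d` dominates a window when its weight exceeds
#' `(1 + delta)` times the mean of the two directional weights in that
#' window.  A link is drawn in direction `d` if `d` dominates a majority of
#' windows and its time-averaged weight exceeds the reverse direction's;
#' with equivalent weights in the two directions the causalities cancel and
#' no link is drawn.
#'
#' @param wAB,wBA numeric per-window weight vectors for the two directions
#'   (equal length).
#' @param delta dominance margin above the per-window mean (default 0.10).
#' @return list with `link` in `c("AB", "BA", "none")`, per-window
#'   `dominance` (`"AB"`, `"BA"` or `"none"`), and the time-averaged
#'   weights `mean_AB`, `mean_BA`.
#' @export
cross_brain_link <- function(wAB, wBA, delta = 0.10) {
  if (length(wAB) != length(wBA))
    stop("weight series lengths differ", call. = FALSE)
  mid <- (wAB + wBA) / 2
  dom <- rep("none", length(wAB))
  dom[wAB > (1 + delta) * mid] <- "AB"
  dom[wBA > (1 + delta) * mid] <- "BA"
  nw <- length(wAB)
  link <- "none"
  if (sum(dom == "AB") > nw / 2 && mean(wAB) > mean(wBA)) link <- "AB"
  else if (sum(dom == "BA") > nw / 2 && mean(wBA) > mean(wAB)) link <- "BA"
  list(link = link, dominance = dom,
       mean_AB = mean(wAB), mean_BA = mean(wBA))
}

#' Threshold-robustness sweep
#'
#' Re-extracts the network at perturbed thresholds (e.g. +/-10%) and reports
#' which edges survive every perturbation ("dominant links") and which are
#' gained or lost per perturbation.
#'
#' @param mat a `causality_matrix`: an averaged intra matrix
#'   (`type = "intra"`) or a signed contrast matrix (`type = "contrast"`).
#' @param type thresholding rule to perturb.
#' @param frac base threshold fraction for the intra rule.
#' @param perturbations relative threshold changes; `0.1` means "+10%".
#' @return list with `base` (edge key vector), `perturbed` (per perturbation:
#'   edges, gained, lost), and `dominant` (edges present at the base and at
#'   every perturbation).
#' @export
threshold_sweep <- function(mat, type = c("intra", "contrast"), frac = 0.2,
                            perturbations = c(-0.1, 0.1)) {
  type <- match.arg(type)
  if (any(perturbations <= -1)) stop("perturbations must exceed -1", call. = FALSE)
  edge_keys <- function(net) {
    if (!nrow(net$edges)) return(character(0))
    paste(net$edges$source, net$edges$target,
          if (net$signed) net$edges$sign else "", sep = "|")
  }
  extract <- function(scale) {
    if (type == "intra") {
      # scaling the fraction scales the threshold frac * max
      f <- min(frac * scale, 1 - 1e-12)
      intra_network(mat, frac = f)
    } else {
      contrast_network(mat, threshold_scale = scale)
    }
  }
  base <- edge_keys(extract(1))
  perturbed <- lapply(perturbations, function(p) {
    e <- edge_keys(extract(1 + p))
    list(perturbation = p, edges = e,
         gained = setdiff(e, base), lost = setdiff(base, e))
  })
  names(perturbed) <- sprintf("%+.0f%%", 100 * perturbations)
  dominant <- Reduce(intersect, c(list(base), lapply(perturbed, `[[`, "edges")))
  list(base = base, perturbed = perturbed, dominant = dominant)
}

#' Export a directed network as an edge-list CSV
#'
#' @param net a `directed_network`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_network_csv <- function(net, path) {
  write.csv(net$edges, path, row.names = FALSE)
  invisible(path)
}

#' Export a directed network as GraphML
#'
#' @param net a `directed_network`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_network_graphml <- function(net, path) {
  igraph::write_graph(as_igraph(net), path, format = "graphml")
  invisible(path)
}
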