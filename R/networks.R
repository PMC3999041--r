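## Co-occurrence networks from pairwise ReBoot-validated correlations,
## NetworkAnalyzer-style graph properties, and the sliding-window
## topology-trend analysis.

#' Build a co-occurrence network
#'
#' Computes, for every unordered pair of features, the Spearman
#' correlation across the selected samples together with its ReBoot z and
#' p (see [rebootSignificance()]), and links the pair by an edge when
#' `p < alpha`.  Nodes are edge endpoints only.  Edge inclusion is
#' computed once per pair and filtered afterwards, so lowering `alpha`
#' can only remove edges at a fixed seed.
#'
#' @param table a normalized-state [FeatureTable-class].
#' @param subset optional character vector of sample ids to build on
#'   (default: all samples).
#' @param alpha edge-calling level (0.05 for whole-cohort networks, 0.01
#'   for per-class networks in the bundled defaults).
#' @param params a [RebootParams-class]; its seed (when set) governs the
#'   whole pairwise scan.
#' @param context label stored on the network.
#' @return a [CooccurrenceNetwork-class].
#' @export
buildNetwork <- function(table, subset = NULL, alpha = 0.05,
                         params = rebootParams(), context = "whole-cohort") {
  stopifnot(methods::is(table, "FeatureTable"))
  if (tableState(table) == "ranked")
    stop("ReBoot needs the relative-abundance composition, not ranks; ",
         "pass the normalized-state table (Spearman rho is identical)")
  if (!is.null(subset)) {
    miss <- setdiff(subset, sampleIds(table))
    if (length(miss)) stop("unknown sample id(s): ",
                           paste(miss, collapse = ", "))
    table <- table[, subset]
  }
  if (ncol(table) < 4L) stop("need at least 4 samples to build a network")
  v <- abundanceValues(table)
  varying <- rownames(v)[apply(v, 1L, function(r) stats::sd(r) > 0)]
  emptyEdges <- data.frame(a = character(), b = character(), rho = numeric(),
                           reboot_z = numeric(), p_value = numeric(),
                           sign = character(), stringsAsFactors = FALSE)
  if (length(varying) < 2L) {
    warning("fewer than 2 varying features in the subset: empty network")
    return(methods::new("CooccurrenceNetwork", nodes = character(),
                        edges = emptyEdges, alpha = alpha, context = context))
  }
  varying <- sort(varying)
  pairs <- utils::combn(varying, 2L)
  totals <- colSums(v)
  edges <- .withSeed(params@seed, function() {
    rows <- lapply(seq_len(ncol(pairs)), function(i) {
      r <- .rebootRaw(v[pairs[1L, i], ], TRUE, v[pairs[2L, i], ], TRUE,
                      totals, params@nPermutations, params@nBootstraps)
      data.frame(a = pairs[1L, i], b = pairs[2L, i], rho = r$rho,
                 reboot_z = r$reboot_z, p_value = r$p_value,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
  edges <- edges[!is.na(edges$p_value) & edges$p_value < alpha, , drop = FALSE]
  edges$sign <- ifelse(edges$rho >= 0, "+", "-")
  rownames(edges) <- NULL
  if (nrow(edges) == 0L) edges <- emptyEdges
  methods::new("CooccurrenceNetwork",
               nodes = sort(unique(c(edges$a, edges$b))), edges = edges,
               alpha = alpha, context = context)
}

#' @rdname asIgraph
#' @export
setMethod("asIgraph", "CooccurrenceNetwork", function(x) {
  if (length(x@nodes) == 0L)
    return(igraph::make_empty_graph(0, directed = FALSE))
  igraph::graph_from_data_frame(
    x@edges[, c("a", "b", "rho", "reboot_z", "p_value", "sign")],
    directed = FALSE, vertices = x@nodes)
})

#' @describeIn graphProperties NetworkAnalyzer-style properties of a
#'   co-occurrence network: `avg_num_neighbors` (mean degree),
#'   `characteristic_path_length` (mean shortest-path length over
#'   connected ordered pairs; disconnected pairs are excluded, not
#'   infinite), `clustering_coefficient` (mean local clustering over
#'   nodes of degree >= 2; 0 when no such node exists),
#'   `centralization` (`N/(N-2) * (max_degree/(N-1) - density)`, `NA`
#'   for fewer than 3 nodes), `density` (`2E / (N(N-1))`),
#'   `heterogeneity` (population sd of the degree distribution divided
#'   by its mean), `n_shortest_paths` (number of connected ordered
#'   pairs), plus `n_nodes` and `n_edges`.
#' @export
setMethod("graphProperties", "CooccurrenceNetwork", function(x, ...) {
  graphProperties(asIgraph(x))
})

#' @rdname graphProperties
#' @export
setMethod("graphProperties", "ANY", function(x, ...) {
  if (!igraph::is_igraph(x))
    stop("graphProperties needs a CooccurrenceNetwork or an igraph graph")
  n <- igraph::gorder(x)
  e <- igraph::gsize(x)
  if (n == 0L)
    return(data.frame(n_nodes = 0L, n_edges = 0L, avg_num_neighbors = NA_real_,
                      characteristic_path_length = NA_real_,
                      clustering_coefficient = NA_real_,
                      centralization = NA_real_, density = NA_real_,
                      heterogeneity = NA_real_, n_shortest_paths = 0L))
  deg <- igraph::degree(x)
  density <- if (n > 1L) 2 * e / (n * (n - 1)) else NA_real_
  D <- igraph::distances(x)
  off <- D[row(D) != col(D)]
  reachable <- is.finite(off)
  cpl <- if (any(reachable)) mean(off[reachable]) else NA_real_
  loc <- suppressWarnings(igraph::transitivity(x, type = "local"))
  eligible <- deg >= 2L
  cc <- if (any(eligible)) mean(loc[eligible]) else 0
  centralization <- if (n >= 3L)
    (n / (n - 2)) * (max(deg) / (n - 1) - density) else NA_real_
  mdeg <- mean(deg)
  heterogeneity <- if (mdeg > 0)
    sqrt(mean((deg - mdeg)^2)) / mdeg else NA_real_
  data.frame(n_nodes = n, n_edges = e, avg_num_neighbors = mdeg,
             characteristic_path_length = cpl, clustering_coefficient = cc,
             centralization = centralization, density = density,
             heterogeneity = heterogeneity,
             n_shortest_paths = sum(reachable))
})

#' Sliding windows over samples ordered by nutritional index
#'
#' Samples are sorted by ascending cumulative nutritional index (ties by
#' sample id) and grouped into overlapping runs of `windowSize`
#' consecutive samples advancing by `step`; 20 samples with the default
#' 7-sample window and step 1 give 14 windows.
#'
#' @param metadata scored metadata data.frame (`sample_id`,
#'   `cumulative_index`).
#' @param windowSize samples per window.
#' @param step window advance.
#' @return list of windows, each a list with `samples` (ids) and
#'   `mean_index`.
#' @export
slidingWindows <- function(metadata, windowSize = 7L, step = 1L) {
  stopifnot(windowSize >= 1L, step >= 1L)
  n <- nrow(metadata)
  if (windowSize > n) stop("windowSize exceeds the number of samples")
  ord <- order(metadata$cumulative_index, metadata$sample_id)
  ids <- metadata$sample_id[ord]
  idx <- metadata$cumulative_index[ord]
  starts <- seq(1L, n - windowSize + 1L, by = step)
  lapply(seq_along(starts), function(k) {
    span <- starts[k]:(starts[k] + windowSize - 1L)
    list(window = k, samples = ids[span], mean_index = mean(idx[span]))
  })
}

#' Sliding-window network property series
#'
#' Builds a co-occurrence network on every sliding window and assembles
#' the per-window graph properties together with Spearman trend
#' statistics of each property against the windows' mean nutritional
#' index.
#'
#' @inheritParams slidingWindows
#' @param table a normalized-state [FeatureTable-class].
#' @param alpha edge-calling level per window.
#' @param params a [RebootParams-class]; the seed (when set) governs all
#'   windows.
#' @return a [WindowSeries-class].
#' @export
windowSeries <- function(table, metadata, windowSize = 7L, step = 1L,
                         alpha = 0.05, params = rebootParams()) {
  wins <- slidingWindows(metadata, windowSize, step)
  built <- .withSeed(params@seed, function() {
    inner <- methods::new("RebootParams",
                          nPermutations = params@nPermutations,
                          nBootstraps = params@nBootstraps,
                          seed = NA_integer_, zThreshold = params@zThreshold)
    lapply(wins, function(w) {
      net <- suppressWarnings(buildNetwork(
        table, subset = w$samples, alpha = alpha, params = inner,
        context = sprintf("window-%02d", w$window)))
      c(w, list(network = net))
    })
  })
  props <- do.call(rbind, lapply(built, function(w) {
    cbind(data.frame(window = w$window, mean_index = w$mean_index),
          graphProperties(w$network))
  }))
  series <- methods::new("WindowSeries", windows = built, properties = props,
                         trends = data.frame(), windowSize = as.integer(windowSize),
                         step = as.integer(step))
  series@trends <- windowTrend(series)
  series
}

#' Property-vs-index trends across windows
#'
#' Spearman correlation (and p-value) between each graph property and the
#' windows' mean cumulative nutritional index.  Windows with an undefined
#' property value are dropped pairwise; a property needs at least 4
#' defined windows (and non-zero spread) for a trend.
#'
#' @param series a [WindowSeries-class], or its `properties` data.frame.
#' @return data.frame with columns `property`, `rho`, `p_value`,
#'   `n_windows`.
#' @export
windowTrend <- function(series) {
  props <- if (methods::is(series, "WindowSeries"))
    series@properties else series
  cols <- setdiff(names(props), c("window", "mean_index"))
  rows <- lapply(cols, function(pc) {
    y <- props[[pc]]
    ok <- is.finite(y) & is.finite(props$mean_index)
    if (sum(ok) < 4L || stats::sd(y[ok]) == 0 ||
        stats::sd(props$mean_index[ok]) == 0)
      return(data.frame(property = pc, rho = NA_real_, p_value = NA_real_,
                        n_windows = sum(ok)))
    ct <- suppressWarnings(stats::cor.test(props$mean_index[ok], y[ok],
                                           method = "spearman",
                                           exact = FALSE))
    data.frame(property = pc, rho = unname(ct$estimate),
               p_value = ct$p.value, n_windows = sum(ok))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Export a network edge list as TSV
#'
#' @param network a [CooccurrenceNetwork-class].
#' @param path file path.
#' @export
writeEdgeList <- function(network, path) {
  stopifnot(methods::is(network, "CooccurrenceNetwork"))
  utils::write.table(network@edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Export a network as GraphML
#'
#' Written with `igraph`, loadable by Cytoscape and other graph tools.
#'
#' @inheritParams writeEdgeList
#' @export
exportGraphML <- function(network, path) {
  stopifnot(methods::is(network, "CooccurrenceNetwork"))
  igraph::write_graph(asIgraph(network), path, format = "graphml")
  invisible(path)
}
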