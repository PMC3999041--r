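# Independent brute-force oracles used to cross-check the package's
# statistics and graph properties.

# Spearman rho as Pearson on explicit average ranks, from the raw
# product-moment formula.
bruteSpearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  num / den
}

# Benjamini-Hochberg step-up from first principles.
bruteBH <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- p[o] * n / seq_len(n)
  q <- pmin(rev(cummin(rev(q))), 1)
  out <- numeric(n)
  out[o] <- q
  out
}

# Kruskal-Wallis H with tie correction, from the rank-sum formula.
bruteKW <- function(y, g) {
  N <- length(y)
  r <- rank(y)
  rbar <- tapply(r, g, mean)
  ns <- tapply(r, g, length)
  H <- 12 / (N * (N + 1)) * sum(ns * (rbar - (N + 1) / 2)^2)
  ties <- table(y)
  H / (1 - sum(ties^3 - ties) / (N^3 - N))
}

# eta-squared = SS_between / SS_total.
bruteEta2 <- function(y, g) {
  gm <- mean(y)
  ssb <- sum(tapply(y, g, function(v) length(v) * (mean(v) - gm)^2))
  sst <- sum((y - gm)^2)
  ssb / sst
}

# One-way ANOVA F from sums of squares.
bruteF <- function(y, g) {
  k <- nlevels(factor(g)); N <- length(y)
  gm <- mean(y)
  ssb <- sum(tapply(y, g, function(v) length(v) * (mean(v) - gm)^2))
  ssw <- sum((y - ave(y, g))^2)
  (ssb / (k - 1)) / (ssw / (N - k))
}

# Graph-property oracle on a 0/1 adjacency matrix: Floyd-Warshall paths,
# explicit triangle counting, NetworkAnalyzer formulas.
bruteGraphProps <- function(A) {
  n <- nrow(A)
  deg <- rowSums(A)
  e <- sum(A) / 2
  D <- matrix(Inf, n, n)
  D[A == 1] <- 1
  diag(D) <- 0
  for (k in seq_len(n)) D <- pmin(D, outer(D[, k], D[k, ], "+"))
  off <- D[row(D) != col(D)]
  reach <- is.finite(off)
  cpl <- if (any(reach)) mean(off[reach]) else NA_real_
  loc <- vapply(seq_len(n), function(i) {
    nb <- which(A[i, ] == 1)
    if (length(nb) < 2L) return(NA_real_)
    sum(A[nb, nb]) / (length(nb) * (length(nb) - 1))
  }, numeric(1))
  cc <- if (any(deg >= 2)) mean(loc[deg >= 2]) else 0
  dens <- if (n > 1) 2 * e / (n * (n - 1)) else NA_real_
  centr <- if (n >= 3) (n / (n - 2)) * (max(deg) / (n - 1) - dens)
           else NA_real_
  mdeg <- mean(deg)
  het <- if (mdeg > 0) sqrt(mean((deg - mdeg)^2)) / mdeg else NA_real_
  c(n_nodes = n, n_edges = e, avg_num_neighbors = mdeg,
    characteristic_path_length = cpl, clustering_coefficient = cc,
    centralization = centr, density = dens, heterogeneity = het,
    n_shortest_paths = sum(reach))
}

# igraph graph from an adjacency matrix (vertices kept even if isolated).
igraphFromAdjacency <- function(A) {
  igraph::graph_from_adjacency_matrix(A, mode = "undirected")
}

# max |package - oracle| over all defined graph properties; Inf if the
# two disagree about which properties are defined
graphPropsDiff <- function(A) {
  got <- graphProperties(igraphFromAdjacency(A))
  want <- bruteGraphProps(A)
  d <- 0
  for (nm in names(want)) {
    g <- got[[nm]]; w <- unname(want[[nm]])
    if (is.na(w) != is.na(g)) return(Inf)
    if (!is.na(w)) d <- max(d, abs(g - w))
  }
  d
}

# random Erdos-Renyi adjacency matrix
randomAdjacency <- function(n, p) {
  A <- matrix(0L, n, n)
  up <- upper.tri(A)
  A[up] <- rbinom(sum(up), 1L, p)
  A + t(A)
}

# small feature table fixture
makeTable <- function(values, kind = "taxon-genus", state = "counts") {
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("f%02d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("S%02d", seq_len(ncol(values)))
  FeatureTable(values, kind = kind, state = state)
}
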