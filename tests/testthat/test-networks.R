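test_that("graph properties match hand values on canonical graphs", {
  triangle <- matrix(c(0, 1, 1, 1, 0, 1, 1, 1, 0), 3, 3)
  got <- graphProperties(igraphFromAdjacency(triangle))
  expect_equal(got$density, 1)
  expect_equal(got$avg_num_neighbors, 2)
  expect_equal(got$clustering_coefficient, 1)
  expect_equal(got$characteristic_path_length, 1)
  expect_equal(got$centralization, 0)
  expect_equal(got$heterogeneity, 0)

  path <- matrix(c(0, 1, 0, 1, 0, 1, 0, 1, 0), 3, 3)  # A - B - C
  got <- graphProperties(igraphFromAdjacency(path))
  expect_equal(got$avg_num_neighbors, 4 / 3)
  expect_equal(got$density, 2 / 3)
  expect_equal(got$clustering_coefficient, 0)
  expect_equal(got$characteristic_path_length, 4 / 3)
  expect_equal(got$centralization, 1)
  expect_equal(got$heterogeneity, sqrt(2) / 4)
  expect_equal(got$n_shortest_paths, 6)

  # a single edge has no node of degree >= 2 and no centralization
  edge <- matrix(c(0, 1, 1, 0), 2, 2)
  got <- graphProperties(igraphFromAdjacency(edge))
  expect_equal(got$clustering_coefficient, 0)
  expect_true(is.na(got$centralization))
})

test_that("graph properties agree with the brute-force oracle on random graphs", {
  # exhaustive over all 4-node graphs, random spot checks larger
  pairs <- combn(4, 2)
  maxErr <- 0
  for (mask in 0:(2^ncol(pairs) - 1)) {
    A <- matrix(0L, 4, 4)
    on <- which(bitwAnd(mask, 2^(seq_len(ncol(pairs)) - 1)) > 0)
    for (k in on) {
      A[pairs[1, k], pairs[2, k]] <- 1L
      A[pairs[2, k], pairs[1, k]] <- 1L
    }
    maxErr <- max(maxErr, graphPropsDiff(A))
  }
  set.seed(6)
  for (i in 1:60) {
    n <- sample(5:30, 1)
    maxErr <- max(maxErr,
                  graphPropsDiff(randomAdjacency(n, runif(1, 0.05, 0.6))))
  }
  expect_lt(maxErr, 1e-10)
})

test_that("networks link only ReBoot-significant pairs, canonically ordered", {
  set.seed(12)
  n <- 20
  shared <- rnorm(n)
  v <- rbind(x1 = exp(shared + rnorm(n, 0, 0.05)),
             x2 = exp(shared + rnorm(n, 0, 0.05)),
             y1 = exp(rnorm(n)), y2 = exp(rnorm(n)), y3 = exp(rnorm(n)))
  v <- sweep(v, 2, colSums(v), "/")
  tab <- makeTable(v, state = "normalized")
  params <- rebootParams(300, 300, seed = 3L)
  net <- buildNetwork(tab, alpha = 0.01, params = params)
  e <- networkEdges(net)
  expect_true(any(e$a == "x1" & e$b == "x2"))
  hub <- e[e$a == "x1" & e$b == "x2", ]
  expect_identical(hub$sign, "+")
  expect_lt(hub$p_value, 0.01)
  expect_true(all(e$a < e$b))
  expect_true(all(e$p_value < networkAlpha(net)))
  expect_setequal(networkNodes(net), union(e$a, e$b))

  # alpha = 0 yields no edges; lowering alpha never adds edges
  none <- buildNetwork(tab, alpha = 0, params = params)
  expect_identical(nrow(networkEdges(none)), 0L)
  loose <- buildNetwork(tab, alpha = 0.2, params = params)
  strictKeys <- with(networkEdges(net), paste(a, b))
  looseKeys <- with(networkEdges(loose), paste(a, b))
  expect_true(all(strictKeys %in% looseKeys))

  # deterministic rebuild
  again <- buildNetwork(tab, alpha = 0.01, params = params)
  expect_identical(networkEdges(again), e)

  # degenerate subset: constant features give an empty network
  flat <- makeTable(matrix(0.1, 3, 5), state = "normalized")
  expect_warning(emptyNet <- buildNetwork(flat, params = params), "varying")
  expect_identical(length(networkNodes(emptyNet)), 0L)
})

test_that("sliding windows honour ordering, counts and overlap", {
  md <- data.frame(sample_id = sprintf("S%02d", 1:20),
                   cumulative_index = seq(-11.58, -2.18, length.out = 20))
  md <- md[sample(20), ]  # order must not matter
  wins <- slidingWindows(md, 7, 1)
  expect_length(wins, 14)
  means <- vapply(wins, `[[`, numeric(1), "mean_index")
  expect_true(all(diff(means) > 0))
  for (k in 2:14)
    expect_length(intersect(wins[[k - 1]]$samples, wins[[k]]$samples), 6)
  expect_length(slidingWindows(md[1:7, ], 7), 1)
  expect_length(slidingWindows(md[1:10, ], 3), 8)
  expect_length(slidingWindows(md, 7, 2), 7)
  expect_error(slidingWindows(md[1:5, ], 7), "exceeds")
})

test_that("window trends correlate properties with the mean index", {
  props <- data.frame(window = 1:6, mean_index = sort(runif(6, -10, -3)))
  props$rising <- seq_len(6)
  props$flat <- 1
  props$gappy <- c(NA, NA, NA, 1, 2, 3)
  tr <- windowTrend(props)
  expect_equal(tr$rho[tr$property == "rising"], 1)
  expect_true(is.na(tr$rho[tr$property == "flat"]))
  expect_true(is.na(tr$rho[tr$property == "gappy"]))  # < 4 defined windows
  expect_identical(tr$n_windows[tr$property == "gappy"], 3L)
})

test_that("window series composes networks over windows deterministically", {
  co <- generateCohort(syntheticConfig(nSamples = 12L, seed = 23L))
  norm <- normalizeAbundance(co@genusCounts, co@metadata)
  core <- coreFeatures(norm)
  params <- rebootParams(80, 80, seed = 5L)
  ser <- windowSeries(norm[core, ], co@metadata, windowSize = 7,
                      alpha = 0.05, params = params)
  expect_s4_class(ser, "WindowSeries")
  expect_identical(nrow(windowProperties(ser)), 6L)  # 12 - 7 + 1
  expect_true(all(diff(windowProperties(ser)$mean_index) > 0))
  ser2 <- windowSeries(norm[core, ], co@metadata, windowSize = 7,
                       alpha = 0.05, params = params)
  expect_identical(windowProperties(ser), windowProperties(ser2))
})

test_that("networks export to edge-list TSV and GraphML", {
  set.seed(14)
  n <- 16
  shared <- rnorm(n)
  v <- rbind(a = exp(shared + rnorm(n, 0, 0.1)),
             b = exp(shared + rnorm(n, 0, 0.1)),
             c = exp(rnorm(n)))
  v <- sweep(v, 2, colSums(v), "/")
  net <- buildNetwork(makeTable(v, state = "normalized"), alpha = 0.05,
                      params = rebootParams(200, 200, seed = 2L))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeEdgeList(net, tsv)
  back <- read.delim(tsv)
  expect_identical(nrow(back), nrow(networkEdges(net)))
  gml <- withr::local_tempfile(fileext = ".graphml")
  exportGraphML(net, gml)
  g <- igraph::read_graph(gml, format = "graphml")
  expect_identical(as.integer(igraph::gorder(g)), length(networkNodes(net)))
  expect_identical(as.integer(igraph::gsize(g)), nrow(networkEdges(net)))
})
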