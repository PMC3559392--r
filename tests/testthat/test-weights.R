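test_that("weights are the energy-flux product with exact zero closure", {
  dGm <- c(r1 = -10, r2 = 4, r3 = 250)
  v <- c(r1 = 5, r2 = 0, r3 = 1e-12)
  w <- computeWeights(dGm, v)
  expect_equal(unname(w["r1"]), -50)
  expect_identical(unname(w["r2"]), 0)       # zero flux
  expect_identical(unname(w["r3"]), 0)       # sub-tolerance flux snapped

  # element-wise product against a naive loop oracle
  set.seed(99)
  dG <- stats::setNames(rnorm(20, sd = 50), paste0("x", 1:20))
  vv <- stats::setNames(rnorm(20, sd = 5), names(dG))
  got <- computeWeights(dG, vv)
  want <- vapply(names(dG), function(i) {
    val <- dG[[i]] * vv[[i]]
    if (abs(val) < 1e-9) 0 else val
  }, numeric(1))
  expect_equal(got, want)

  expect_error(computeWeights(c(r1 = NA_real_), c(r1 = 1)), "r1")
  expect_error(computeWeights(c(r1 = 1), c(other = 1)), "missing flux")
})

test_that("weight signs encode thermodynamic favourability", {
  set.seed(7)
  dG <- rnorm(50, sd = 30); v <- rnorm(50, sd = 3)
  names(dG) <- names(v) <- paste0("r", 1:50)
  w <- computeWeights(dG, v)
  nz <- w != 0
  expect_true(all((w[nz] < 0) == (sign(dG[nz]) != sign(v[nz]))))
})

test_that("histogram bins partition the weight set under the edge convention", {
  w <- c(-250, -10, 0, 5)
  h <- binWeights(w)
  expect_equal(h$count, c(1, 0, 0, 1, 1, 1, 0, 0))
  expect_equal(sum(h$count), length(w))

  # boundary handling: negative bins are [lo, hi), positive bins (lo, hi]
  wb <- c(-200, -100, -50, 40, 100, 0)
  hb <- binWeights(wb)
  expect_equal(hb$count[hb$scope == "<-200"], 0)        # -200 not in "<-200"
  expect_equal(hb$count[hb$scope == "-200~-100"], 1)    # -200 included left
  expect_equal(hb$count[hb$scope == "-100~-50"], 1)
  expect_equal(hb$count[hb$scope == "0~40"], 1)         # 40 included right
  expect_equal(hb$count[hb$scope == "40~100"], 1)
  expect_equal(hb$count[hb$scope == ">100"], 0)

  # sub-tolerance values land in the exact-zero bin
  h0 <- binWeights(c(0, 1e-12, -1e-12, 2))
  expect_equal(h0$count[h0$scope == "0"], 3)

  # percentages carry two decimals of the share of all weighted reactions
  wz <- c(rep(0, 1753), rep(1, 2077 - 1753))
  hz <- binWeights(wz)
  expect_equal(hz$pct[hz$scope == "0"], 84.40)

  expect_error(binWeights(1, edges = c(0, -1)), "strictly increasing")
  expect_error(binWeights(1, edges = c(-1, 1)), "contain 0")

  # partition property for arbitrary covers
  set.seed(13)
  for (k in 1:5) {
    wr <- rnorm(200, sd = 150)
    edges <- sort(sample(setdiff(-300:300, 0), 4))
    edges <- sort(c(edges, 0))
    expect_equal(sum(binWeights(wr, edges = edges)$count), length(wr))
  }
})

test_that("extreme-reaction reports honour scopes and ordering", {
  w <- c(big = -300, mid = -75, small = -10, pos = 50, zero = 0)
  rep1 <- extremeReactions(w, c("<-200", "-100~-50", ">40"))
  expect_equal(rep1[["<-200"]]$id, "big")
  expect_equal(rep1[["-100~-50"]]$id, "mid")
  expect_equal(rep1[[">40"]]$id, "pos")
  expect_equal(nrow(extremeReactions(w, ">1000")[[1]]), 0L)
  # sorted by |w| descending, annotations passed through
  w2 <- c(a = -210, b = -500)
  ann <- data.frame(id = c("a", "b"), gene = c("gA", "gB"))
  r2 <- extremeReactions(w2, "<-200", annotations = ann)[[1]]
  expect_equal(r2$id, c("b", "a"))
  expect_equal(r2$gene, c("gB", "gA"))
})

test_that("weight-flux correlation matches the textbook formula", {
  w <- c(1, 2, 3, 4); v <- 2.5 * w
  expect_equal(scatterCorrelation(w, v)$r, 1)
  res0 <- scatterCorrelation(rep(1, 5), 1:5)
  expect_true(res0$undefined)
  expect_true(is.na(res0$r))

  set.seed(5)
  w <- rnorm(50); v <- 0.3 * w + rnorm(50)
  res <- scatterCorrelation(w, v)
  r_hand <- sum((w - mean(w)) * (v - mean(v))) /
    ((length(w) - 1) * sd(w) * sd(v))
  expect_equal(res$r, r_hand, tolerance = 1e-10)
  expect_false(res$undefined)
  expect_equal(nrow(res$pairs), 50L)

  expect_error(scatterCorrelation(1:3, 1:4), "equal length")
})

test_that("graph export is bipartite, attributed and round-trips", {
  dir <- writeTabularToy()
  m <- suppressWarnings(loadModel(dir, "tabular"))
  w <- c(r1 = -2.5, r2 = 0)
  g <- buildWeightedGraph(m, w)
  expect_equal(igraph::vcount(g), 5L)          # 3 species + 2 reactions
  expect_equal(igraph::ecount(g), 4L)
  types <- igraph::V(g)$type
  expect_equal(sum(types == "reaction"), 2L)

  path <- withr::local_tempfile(fileext = ".graphml")
  exportGraph(m, w, path)
  g2 <- importGraph(path)
  expect_equal(igraph::vcount(g2), igraph::vcount(g))
  expect_equal(igraph::ecount(g2), igraph::ecount(g))
  nodes <- igraph::as_data_frame(g2, what = "vertices")
  expect_equal(sort(nodes$w[nodes$type == "reaction"]), c(-2.5, 0))

  # edge-list dialect and the optional reaction projection
  path2 <- withr::local_tempfile(fileext = ".tsv")
  exportGraph(m, w, path2, format = "edgelist", projection = TRUE)
  el <- read.delim(path2)
  expect_equal(nrow(el), 4L)
  proj <- read.delim(sub("\\.tsv$", ".projection.tsv", path2))
  expect_equal(proj$from, "r1")               # r1, r2 share species b
  expect_equal(proj$weight, -1.25)
})
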