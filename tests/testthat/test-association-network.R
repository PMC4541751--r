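test_that("network construction uses set semantics over bipartite edges", {
  recs <- data.frame(vaccine = "V", symptom = c("a", "b", "c", "d"))
  net <- buildNetwork(recs)
  expect_identical(vaccineNodes(net), "V")
  expect_identical(aeNodes(net), c("a", "b", "c", "d"))
  expect_identical(nrow(edgeTable(net)), 4L)

  # duplicates collapse to one edge
  net2 <- buildNetwork(rbind(recs, recs))
  expect_identical(edgeTable(net2), edgeTable(net))

  # empty input is a valid empty network
  empty <- buildNetwork(data.frame(vaccine = character(0),
                                   symptom = character(0)))
  expect_identical(nrow(edgeTable(empty)), 0L)

  # bipartite purity: the same label on both sides is rejected
  expect_error(buildNetwork(data.frame(vaccine = c("A", "B"),
                                       symptom = c("B", "C"))),
               "both as vaccine and symptom")
})

test_that("star and single-edge metrics match hand enumeration", {
  star <- buildNetwork(data.frame(vaccine = "V",
                                  symptom = c("a", "b", "c", "d")))
  m <- networkMetrics(star)
  expect_identical(m@nNode, 5L)
  expect_identical(m@nLink, 4L)
  expect_equal(m@averageDegree, 1.6)
  # 4 pairs at distance 1 and 6 at distance 2 -> mean 1.6, diameter 2
  expect_equal(m@averagePathLength, 1.6)
  expect_identical(m@diameter, 2L)

  single <- buildNetwork(data.frame(vaccine = "V", symptom = "a"))
  s <- networkMetrics(single)
  expect_equal(s@averageDegree, 1)
  expect_equal(s@averagePathLength, 1)
  expect_identical(s@diameter, 1L)

  empty <- buildNetwork(data.frame(vaccine = character(0),
                                   symptom = character(0)))
  expect_warning(e <- networkMetrics(empty), "empty")
  expect_true(e@empty)
  expect_identical(e@nNode, 0L)
})

test_that("the disproportionate pairs of the toy star corpus form exactly the star", {
  a <- computePrr(countPairs(makeFixture("toy_star")))
  sig <- significantAssociations(a, "overall")
  net <- buildNetwork(sig)
  expect_identical(vaccineNodes(net), "V")
  expect_setequal(aeNodes(net), c("AE_a", "AE_b", "AE_c", "AE_d"))
  expect_identical(nrow(edgeTable(net)), 4L)
})

test_that("BFS-based path metrics equal the Floyd-Warshall oracle on random bipartite graphs", {
  set.seed(501)
  for (i in seq_len(12)) {
    e <- randomBipartiteEdges(sample(2:12, 1), sample(2:15, 1), runif(1, 0.1, 0.5))
    net <- buildNetwork(e)
    m <- networkMetrics(net)
    o <- fwPathStats(edgeTable(net))
    expect_identical(as.integer(o$diameter), m@diameter)
    expect_equal(m@averagePathLength, o$apl, tolerance = 1e-12)
    expect_equal(m@averageDegree, 2 * m@nLink / m@nNode, tolerance = 0)
  }
})

test_that("unordered-pair averaging equals ordered-pair averaging on undirected graphs", {
  set.seed(502)
  e <- randomBipartiteEdges(6, 9, 0.3)
  net <- buildNetwork(e)
  g <- asIgraph(net)
  d <- igraph::distances(g)
  ordered <- d[row(d) != col(d)]
  ordered <- ordered[is.finite(ordered)]
  expect_equal(networkMetrics(net)@averagePathLength, mean(ordered),
               tolerance = 1e-12)
})

test_that("the strata metrics table has one row per year plus Female, Male, Overall", {
  cfg <- syntheticConfig(nReports = 1500L, years = c(2010L, 2011L), seed = 8L)
  rs <- generateReports(cfg)$reports
  tab <- strataMetricsTable(rs)
  expect_identical(tab$stratum,
                   c("2010", "2011", "Female", "Male", "Overall"))
  nz <- tab[!tab$empty, ]
  expect_equal(nz$average_degree,
               roundHalfUp(2 * nz$n_link / nz$n_node, 2))
  expect_true(all(nz$network_diameter + 0.005 >= nz$average_path_length))

  sexOnly <- strataMetricsTable(rs, strata = c("sexes", "overall"))
  expect_identical(sexOnly$stratum, c("Female", "Male", "Overall"))
})

test_that("strata metrics agree with independently recomputed per-stratum networks", {
  set.seed(503)
  rs <- randomReportSet(250, nv = 5, ns = 8)
  a <- computePrr(countPairs(rs))
  tab <- strataMetricsTable(a)
  for (lab in c("F", "M", "overall")) {
    rowLab <- c(F = "Female", M = "Male", overall = "Overall")[[lab]]
    sig <- significantAssociations(a, lab)
    row <- tab[tab$stratum == rowLab, ]
    if (nrow(sig) == 0) {
      expect_true(row$empty)
      next
    }
    o <- fwPathStats(unique(sig[c("vaccine", "symptom")]))
    expect_equal(row$average_path_length, roundHalfUp(o$apl, 2))
    expect_identical(row$network_diameter, as.integer(o$diameter))
  }
})

test_that("GraphML export carries node types and is byte-deterministic", {
  net <- buildNetwork(data.frame(vaccine = c("V1", "V2"),
                                 symptom = c("a", "a")))
  f1 <- withr::local_tempfile(fileext = ".graphml")
  f2 <- withr::local_tempfile(fileext = ".graphml")
  writeGraphML(net, f1)
  writeGraphML(net, f2)
  expect_identical(readLines(f1), readLines(f2))
  txt <- paste(readLines(f1), collapse = "\n")
  expect_match(txt, "vaccine")
  expect_match(txt, "ae")
})
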