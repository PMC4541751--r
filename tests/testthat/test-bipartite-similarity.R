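test_that("the association index hits its closed-form anchor points", {
  # identical neighbourhoods: perfect overlap
  expect_equal(pccIndex(4, 4, 4, 10), 1)
  expect_equal(pccIndex(7, 7, 7, 19), 1)
  # shared count equal to deg_a*deg_b/n_y: exactly the chance expectation
  expect_equal(pccIndex(4, 5, 2, 10), 0)
  # complementary halves: perfect anti-correlation
  expect_equal(pccIndex(5, 5, 0, 10), -1)
  # undefined when a degree is 0 or the whole opposite set
  expect_true(is.na(pccIndex(0, 3, 0, 10)))
  expect_true(is.na(pccIndex(10, 3, 3, 10)))
  # precondition violations are errors
  expect_error(pccIndex(2, 3, 4, 10), "shared")
  expect_error(pccIndex(11, 3, 1, 10), "degrees")
})

test_that("the index equals the Pearson correlation of binary incidence vectors", {
  set.seed(601)
  for (rep in seq_len(250)) {
    nY <- sample(3:40, 1)
    degA <- sample(1:(nY - 1), 1)
    degB <- sample(1:(nY - 1), 1)
    lo <- max(0, degA + degB - nY)
    hi <- min(degA, degB)
    shared <- if (lo == hi) lo else sample(lo:hi, 1)
    vecs <- incidencePair(degA, degB, shared, nY)
    expect_equal(pccIndex(degA, degB, shared, nY), cor(vecs$a, vecs$b),
                 tolerance = 1e-12)
  }
})

test_that("the index is symmetric in its nodes and strictly increasing in shared", {
  set.seed(602)
  for (rep in seq_len(50)) {
    nY <- sample(4:30, 1)
    degA <- sample(1:(nY - 1), 1)
    degB <- sample(1:(nY - 1), 1)
    lo <- max(0, degA + degB - nY)
    hi <- min(degA, degB)
    vals <- vapply(lo:hi, function(s) pccIndex(degA, degB, s, nY),
                   numeric(1))
    if (length(vals) > 1) expect_true(all(diff(vals) > 0))
    expect_identical(pccIndex(degA, degB, hi, nY),
                     pccIndex(degB, degA, hi, nY))
  }
})

test_that("similarity matrices match a set-based brute-force recomputation", {
  set.seed(603)
  for (rep in seq_len(10)) {
    net <- buildNetwork(randomBipartiteEdges(sample(3:8, 1),
                                             sample(3:10, 1),
                                             runif(1, 0.2, 0.6)))
    if (length(vaccineNodes(net)) < 2) next
    sim <- similarityMatrix(net, "vaccine")
    v <- similarityValues(sim)
    expect_identical(v, t(v))
    e <- edgeTable(net)
    nbrs <- split(e$symptom, e$vaccine)
    nY <- length(aeNodes(net))
    for (a in rownames(v)) {
      for (b in colnames(v)) {
        want <- pccIndex(length(nbrs[[a]]), length(nbrs[[b]]),
                         length(intersect(nbrs[[a]], nbrs[[b]])), nY)
        expect_equal(v[a, b], want, tolerance = 1e-12)
      }
    }
  }
})

test_that("two vaccines with identical AE neighbourhoods get off-diagonal 1", {
  net <- buildNetwork(data.frame(vaccine = rep(c("V1", "V2"), each = 3),
                                 symptom = rep(c("a", "b", "c"), 2)))
  # add a third node so degrees stay below the opposite-set size
  net <- buildNetwork(rbind(edgeTable(net),
                            data.frame(vaccine = "V3", symptom = "d")))
  v <- similarityValues(similarityMatrix(net, "vaccine"))
  expect_equal(v["V1", "V2"], 1)
  expect_equal(diag(v), c(V1 = 1, V2 = 1, V3 = 1))
  expect_error(similarityMatrix(buildNetwork(
    data.frame(vaccine = "V", symptom = c("a", "b"))), "vaccine"),
    "at least 2")
})

test_that("clustering merges the tight pair first and is stable under label permutation", {
  sim <- new("SimilarityMatrix", labels = c("A", "B", "C"),
             values = matrix(c(1, 0.9, 0.1,
                               0.9, 1, 0.1,
                               0.1, 0.1, 1), 3, 3, byrow = TRUE),
             nY = 10L)
  tree <- clusterVaccines(sim)
  first <- tree@hclust$merge[1, ]
  expect_setequal(tree@labels[-first], c("A", "B"))

  perm <- c(3, 1, 2)
  simP <- new("SimilarityMatrix", labels = sim@labels[perm],
              values = sim@values[perm, perm], nY = 10L)
  treeP <- clusterVaccines(simP)
  cp <- as.matrix(cophenetic(tree@hclust))
  cpP <- as.matrix(cophenetic(treeP@hclust))
  expect_equal(cp[tree@labels, tree@labels],
               cpP[tree@labels, tree@labels], tolerance = 1e-12)
})

test_that("undefined entries are imputed as zero with a warning; all-undefined is an error", {
  vals <- matrix(c(1, 0.4, NA,
                   0.4, 1, 0.2,
                   NA, 0.2, 1), 3, 3, byrow = TRUE)
  sim <- new("SimilarityMatrix", labels = c("A", "B", "C"), values = vals,
             nY = 5L)
  expect_warning(tree <- clusterVaccines(sim), "imputed")
  expect_identical(tree@imputed, 1L)
  allNA <- new("SimilarityMatrix", labels = c("A", "B"),
               values = matrix(c(1, NA, NA, 1), 2, 2), nY = 5L)
  expect_error(clusterVaccines(allNA), "undefined")
})

test_that("two planted vaccine groups with disjoint AE repertoires are recovered at k = 2", {
  # group 1 shares AEs a1..a4; group 2 shares b1..b4
  e <- rbind(expand.grid(vaccine = c("G1V1", "G1V2", "G1V3"),
                         symptom = sprintf("a%d", 1:4)),
             expand.grid(vaccine = c("G2V1", "G2V2", "G2V3"),
                         symptom = sprintf("b%d", 1:4)))
  e[] <- lapply(e, as.character)
  net <- buildNetwork(e)
  tree <- clusterVaccines(similarityMatrix(net, "vaccine"))
  cl <- cutClusters(tree, 2)
  expect_identical(length(unique(cl[c("G1V1", "G1V2", "G1V3")])), 1L)
  expect_identical(length(unique(cl[c("G2V1", "G2V2", "G2V3")])), 1L)
  expect_false(cl[["G1V1"]] == cl[["G2V1"]])
})

test_that("Newick export writes a tree over exactly the vaccine labels", {
  e <- expand.grid(vaccine = c("X", "Y", "Z"),
                   symptom = c("s1", "s2", "s3", "s4"))
  e[] <- lapply(e, as.character)
  e <- e[-c(4, 8, 12), ]  # keep every degree strictly below the AE count
  tree <- clusterVaccines(similarityMatrix(buildNetwork(e), "vaccine"))
  f <- withr::local_tempfile(fileext = ".nwk")
  writeNewick(tree, f)
  phy <- ape::read.tree(f)
  expect_setequal(phy$tip.label, c("X", "Y", "Z"))
})

test_that("strata comparison pairs common labels and reports a KS distance", {
  vals <- matrix(c(1, 0.2, 0.5,
                   0.2, 1, -0.1,
                   0.5, -0.1, 1), 3, 3, byrow = TRUE)
  simF <- new("SimilarityMatrix", labels = c("A", "B", "C"), values = vals,
              nY = 8L)
  simM <- new("SimilarityMatrix", labels = c("B", "C", "D"),
              values = vals, nY = 8L)
  cmp <- compareStrata(simF, simM)
  expect_identical(cmp@labels, c("B", "C"))   # intersection only
  expect_length(cmp@valuesF, 1L)

  # identical matrices: zero distance
  same <- compareStrata(simF, simF)
  expect_identical(same@ksDistance, 0)
  expect_identical(sum(same@density$count_f), length(same@valuesF))
  expect_identical(same@density$count_f, same@density$count_m)

  single <- new("SimilarityMatrix", labels = c("A", "E"),
                values = diag(2), nY = 8L)
  expect_error(compareStrata(simF, single), "common labels")
})

test_that("differently structured strata show a positive KS distance", {
  set.seed(604)
  eF <- rbind(expand.grid(vaccine = sprintf("V%d", 1:4),
                          symptom = sprintf("a%d", 1:3)),
              data.frame(vaccine = "V5", symptom = "a4"))
  eM <- data.frame(vaccine = sprintf("V%d", 1:5),
                   symptom = sprintf("m%d", 1:5))
  eM <- rbind(eM, data.frame(vaccine = "V1", symptom = "m2"))
  eF[] <- lapply(eF, as.character)
  simF <- similarityMatrix(buildNetwork(eF), "vaccine")
  simM <- similarityMatrix(buildNetwork(eM), "vaccine")
  cmp <- compareStrata(simF, simM)
  expect_gt(cmp@ksDistance, 0)
})
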