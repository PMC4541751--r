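#' Pearson association index between two same-type nodes
#'
#' For two nodes A and B of the same type in a bipartite network, with
#' neighbour-set sizes |N(A)| and |N(B)|, shared-neighbour count
#' |N(A) n N(B)| and opposite-type set size n_y, the index is
#' \deqn{(|N(A) \cap N(B)| \cdot n_y - |N(A)||N(B)|) /
#'       \sqrt{|N(A)||N(B)| (n_y - |N(A)|)(n_y - |N(B)|)}}
#' which is exactly the Pearson correlation of the two binary incidence
#' vectors over the n_y opposite-type nodes. A value of 1 indicates perfect
#' overlap, 0 the shared-neighbour count expected by chance, and -1 perfect
#' anti-correlation. The index is undefined (returned as \code{NA}) when
#' either degree is 0 or equals n_y, i.e. when an incidence vector is
#' constant.
#'
#' @param degA,degB neighbour counts of the two nodes.
#' @param shared number of opposite-type nodes adjacent to both.
#' @param nY total number of opposite-type nodes in the network.
#' @return numeric in [-1, 1], or \code{NA} when undefined.
#' @examples
#' pccIndex(4, 4, 4, 10)   # identical neighbourhoods: 1
#' pccIndex(4, 5, 2, 10)   # 2 shared = 4*5/10 expected by chance: 0
#' pccIndex(5, 5, 0, 10)   # complementary halves: -1
#' @export
pccIndex <- function(degA, degB, shared, nY) {
  if (any(shared < 0) || any(shared > pmin(degA, degB))) {
    .stopf("shared count must lie in [0, min(degA, degB)]")
  }
  if (any(degA < 0) || any(degB < 0) || any(degA > nY) || any(degB > nY)) {
    .stopf("degrees must lie in [0, nY]")
  }
  num <- shared * nY - degA * degB
  den2 <- degA * degB * (nY - degA) * (nY - degB)
  out <- ifelse(den2 > 0, num / sqrt(den2), NA_real_)
  unname(out)
}

#' All-pairs association-index matrix of one node type
#'
#' Projects a bipartite network onto its vaccine (or AE) side: every pair of
#' same-type nodes gets the \code{\link{pccIndex}} of their incidence
#' vectors, with the opposite node set of this network as the universe
#' (n_y). Diagonal entries are 1 whenever defined.
#'
#' @param net a \code{BipartiteNetwork} with at least 2 nodes of the chosen
#'   type.
#' @param projectOnto \code{"vaccine"} or \code{"ae"}.
#' @return a \code{\linkS4class{SimilarityMatrix}}.
#' @export
similarityMatrix <- function(net, projectOnto = c("vaccine", "ae")) {
  stopifnot(is(net, "BipartiteNetwork"))
  projectOnto <- match.arg(projectOnto)
  if (projectOnto == "vaccine") {
    labels <- net@vaccineNodes
    opp <- net@aeNodes
    inc <- table(factor(net@edges$vaccine, labels),
                 factor(net@edges$symptom, opp))
  } else {
    labels <- net@aeNodes
    opp <- net@vaccineNodes
    inc <- table(factor(net@edges$symptom, labels),
                 factor(net@edges$vaccine, opp))
  }
  if (length(labels) < 2) {
    .stopf("similarityMatrix: need at least 2 %s nodes", projectOnto)
  }
  inc <- matrix(as.integer(inc > 0), nrow = length(labels),
                dimnames = list(labels, opp))
  deg <- rowSums(inc)
  shared <- tcrossprod(inc)
  nY <- length(opp)
  num <- shared * nY - outer(deg, deg)
  den2 <- outer(deg, deg) * outer(nY - deg, nY - deg)
  vals <- ifelse(den2 > 0, num / sqrt(den2), NA_real_)
  dimnames(vals) <- NULL
  new("SimilarityMatrix", labels = labels, values = vals, nY = as.integer(nY))
}

#' Agglomerative clustering of vaccines by association profile
#'
#' Average-linkage hierarchical clustering on the distance 1 - PCC.
#' Undefined similarity entries are imputed as 0 — the "expected by chance"
#' reference point of the index — with a warning. Labels are processed in
#' lexicographic order so ties break deterministically regardless of input
#' order.
#'
#' @param sim a \code{SimilarityMatrix} with at least 2 labels.
#' @param method linkage passed to \code{stats::hclust} (default
#'   \code{"average"}).
#' @return a \code{\linkS4class{ClusterTree}}.
#' @export
clusterVaccines <- function(sim, method = "average") {
  stopifnot(is(sim, "SimilarityMatrix"))
  if (length(sim@labels) < 2) .stopf("need at least 2 labels to cluster")
  ord <- order(sim@labels)
  labels <- sim@labels[ord]
  v <- sim@values[ord, ord, drop = FALSE]
  nImputed <- sum(is.na(v[upper.tri(v)]))
  if (all(is.na(v[upper.tri(v)]))) {
    .stopf("all similarity values undefined; nothing to cluster")
  }
  if (nImputed > 0) {
    .warnf("clusterVaccines: %d undefined similarity value(s) imputed as 0",
           nImputed)
    v[is.na(v)] <- 0
  }
  d <- 1 - v
  diag(d) <- 0
  dimnames(d) <- list(labels, labels)
  h <- stats::hclust(stats::as.dist(d), method = method)
  new("ClusterTree", hclust = h, labels = labels,
      imputed = as.integer(nImputed))
}

#' Cut a cluster tree into k groups
#'
#' @param tree a \code{ClusterTree}.
#' @param k number of clusters.
#' @return named integer vector of cluster memberships.
#' @export
cutClusters <- function(tree, k) {
  stopifnot(is(tree, "ClusterTree"))
  stats::cutree(tree@hclust, k = k)
}

#' Write a cluster tree as Newick
#'
#' Branch lengths are merge-height differences, so root-to-leaf distances
#' reproduce the dendrogram heights.
#'
#' @param tree a \code{ClusterTree}.
#' @param path output file.
#' @return invisible \code{path}.
#' @export
writeNewick <- function(tree, path) {
  stopifnot(is(tree, "ClusterTree"))
  phy <- ape::as.phylo(tree@hclust)
  ape::write.tree(phy, file = path)
  invisible(path)
}

#' Write a similarity matrix as a labelled TSV
#'
#' @param sim a \code{SimilarityMatrix}.
#' @param path output file.
#' @return invisible \code{path}.
#' @export
writeSimilarityMatrix <- function(sim, path) {
  stopifnot(is(sim, "SimilarityMatrix"))
  v <- similarityValues(sim)
  utils::write.table(data.frame(label = rownames(v), v, check.names = FALSE),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Compare vaccine similarity structure between two strata
#'
#' Restricts both matrices to their common vaccine labels, pairs the
#' off-diagonal association-index values, bins each stratum's values into
#' fixed-width histograms (bin width 0.05 over [-1, 1]) so the two densities
#' overlay directly, and reports the two-sample Kolmogorov-Smirnov distance
#' as a descriptive summary of how much the distributions differ (no p-value
#' is attached).
#'
#' @param simF,simM \code{SimilarityMatrix} objects for the two strata
#'   (conventionally female and male).
#' @param binWidth histogram bin width over [-1, 1].
#' @return a \code{\linkS4class{StrataComparison}}.
#' @export
compareStrata <- function(simF, simM, binWidth = 0.05) {
  stopifnot(is(simF, "SimilarityMatrix"), is(simM, "SimilarityMatrix"))
  common <- sort(intersect(simF@labels, simM@labels))
  if (length(common) < 2) {
    .stopf("compareStrata: need at least 2 common labels, got %d",
           length(common))
  }
  vf <- similarityValues(simF)[common, common]
  vm <- similarityValues(simM)[common, common]
  up <- upper.tri(vf)
  keep <- !is.na(vf[up]) & !is.na(vm[up])
  xf <- vf[up][keep]
  xm <- vm[up][keep]
  breaks <- seq(-1, 1, by = binWidth)
  if (breaks[length(breaks)] < 1) breaks <- c(breaks, 1)
  cf <- as.integer(table(cut(xf, breaks, include.lowest = TRUE)))
  cm <- as.integer(table(cut(xm, breaks, include.lowest = TRUE)))
  density <- data.frame(bin_left = breaks[-length(breaks)],
                        bin_right = breaks[-1], count_f = cf, count_m = cm)
  ks <- if (length(xf) > 0) {
    unname(suppressWarnings(stats::ks.test(xf, xm)$statistic))
  } else {
    NA_real_
  }
  new("StrataComparison", labels = common, valuesF = xf, valuesM = xm,
      density = density, ksDistance = ks)
}

#' Write the paired density summary of a strata comparison
#'
#' @param cmp a \code{StrataComparison}.
#' @param path output TSV (bin_left, bin_right, count_f, count_m).
#' @return invisible \code{path}.
#' @export
writeDensityComparison <- function(cmp, path) {
  stopifnot(is(cmp, "StrataComparison"))
  utils::write.table(cmp@density, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
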