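#' Build the bipartite vaccine-AE association network
#'
#' One undirected edge per disproportionally reported (vaccine, symptom)
#' pair; node sets are the union of edge endpoints, so the network carries no
#' isolated nodes. Duplicate input pairs collapse to a single edge. Because
#' a symptom term could in principle coincide with a vaccine code, AE node
#' labels are kept in a separate namespace within the object.
#'
#' @param significant data.frame with columns \code{vaccine} and
#'   \code{symptom} (e.g. from \code{\link{significantAssociations}}).
#' @return a \code{\linkS4class{BipartiteNetwork}} (empty input gives an
#'   empty network).
#' @export
buildNetwork <- function(significant) {
  stopifnot(is.data.frame(significant),
            all(c("vaccine", "symptom") %in% names(significant)))
  e <- unique(data.frame(vaccine = as.character(significant$vaccine),
                         symptom = as.character(significant$symptom),
                         stringsAsFactors = FALSE))
  e <- e[order(e$vaccine, e$symptom), , drop = FALSE]
  rownames(e) <- NULL
  clash <- intersect(unique(e$vaccine), unique(e$symptom))
  if (length(clash) > 0) {
    .stopf("labels occur both as vaccine and symptom: %s",
           paste(clash, collapse = ", "))
  }
  new("BipartiteNetwork",
      vaccineNodes = sort(unique(e$vaccine)),
      aeNodes = sort(unique(e$symptom)),
      edges = e)
}

#' Convert a BipartiteNetwork to an igraph object
#'
#' Nodes carry a \code{type} attribute, \code{"vaccine"} or \code{"ae"}
#' (and the logical \code{bipartite} \code{type} used by igraph's bipartite
#' machinery). Node and edge order is deterministic (sorted), so downstream
#' file exports are reproducible byte for byte.
#'
#' @param net a \code{BipartiteNetwork}.
#' @return an \code{igraph} graph.
#' @export
asIgraph <- function(net) {
  stopifnot(is(net, "BipartiteNetwork"))
  nodes <- data.frame(
    name = c(net@vaccineNodes, net@aeNodes),
    type = c(rep("vaccine", length(net@vaccineNodes)),
             rep("ae", length(net@aeNodes))),
    stringsAsFactors = FALSE)
  igraph::graph_from_data_frame(net@edges, directed = FALSE,
                                vertices = nodes)
}

#' Characterize an association network
#'
#' Computes the standard summary row for one network: node and link counts,
#' average node degree (2E/N), average unweighted shortest-path length and
#' diameter. Shortest paths come from breadth-first search on the undirected
#' graph; the average is taken over unordered pairs of distinct, mutually
#' reachable nodes, and the diameter is the largest finite shortest-path
#' length — the usual network-analyzer convention for disconnected graphs.
#'
#' @param net a \code{BipartiteNetwork}.
#' @return a \code{\linkS4class{NetworkMetrics}} object; an empty network
#'   yields all-zero metrics with the \code{empty} flag set (and a warning).
#' @examples
#' star <- buildNetwork(data.frame(vaccine = "V",
#'                                 symptom = c("a", "b", "c", "d")))
#' networkMetrics(star)   # N=5, E=4, <k>=1.6, <l>=1.6, diameter 2
#' @export
networkMetrics <- function(net) {
  stopifnot(is(net, "BipartiteNetwork"))
  nNode <- length(net@vaccineNodes) + length(net@aeNodes)
  nLink <- nrow(net@edges)
  if (nLink == 0) {
    .warnf("networkMetrics: empty network, metrics set to zero")
    return(new("NetworkMetrics", nNode = 0L, nLink = 0L, averageDegree = 0,
               averagePathLength = 0, diameter = 0L, empty = TRUE))
  }
  g <- asIgraph(net)
  d <- igraph::distances(g, algorithm = "unweighted")
  finite <- d[upper.tri(d)]
  finite <- finite[is.finite(finite)]
  new("NetworkMetrics",
      nNode = as.integer(nNode), nLink = as.integer(nLink),
      averageDegree = 2 * nLink / nNode,
      averagePathLength = mean(finite),
      diameter = as.integer(max(finite)),
      empty = FALSE)
}

.metricsRow <- function(stratum, m) {
  data.frame(stratum = stratum, n_node = m@nNode, n_link = m@nLink,
             average_degree = roundHalfUp(m@averageDegree, 2),
             average_path_length = roundHalfUp(m@averagePathLength, 2),
             network_diameter = m@diameter, empty = m@empty,
             stringsAsFactors = FALSE)
}

#' Per-stratum network characteristics table
#'
#' Builds, for every requested stratum, the network of that stratum's
#' disproportionally reported associations and its summary metrics: one row
#' per reporting year present in the corpus, plus "Female", "Male" and
#' "Overall". Average degree and path length are rounded half-up to two
#' decimals in the emitted table (full precision is available via
#' \code{\link{networkMetrics}}).
#'
#' @param assoc an \code{AssociationSet} with PRRs computed (or a
#'   \code{ReportSet}, in which case counting and PRR computation are run
#'   first).
#' @param strata character vector drawn from "years", "sexes", "overall".
#' @param threshold PRR significance cutoff (default 1, strict).
#' @return data.frame with columns \code{stratum}, \code{n_node},
#'   \code{n_link}, \code{average_degree}, \code{average_path_length},
#'   \code{network_diameter}, \code{empty} (TRUE marks strata with no
#'   significant association, reported as zeros).
#' @export
strataMetricsTable <- function(assoc, strata = c("years", "sexes", "overall"),
                               threshold = 1) {
  if (is(assoc, "ReportSet")) assoc <- computePrr(countPairs(assoc))
  stopifnot(is(assoc, "AssociationSet"))
  rows <- list()
  metricsOf <- function(stratum) {
    sig <- significantAssociations(assoc, stratum, threshold)
    suppressWarnings(networkMetrics(buildNetwork(sig)))
  }
  if ("years" %in% strata) {
    for (y in sort(unique(assoc@yearly$year))) {
      rows[[length(rows) + 1L]] <- .metricsRow(as.character(y), metricsOf(y))
    }
  }
  if ("sexes" %in% strata) {
    rows[[length(rows) + 1L]] <- .metricsRow("Female", metricsOf("F"))
    rows[[length(rows) + 1L]] <- .metricsRow("Male", metricsOf("M"))
  }
  if ("overall" %in% strata) {
    rows[[length(rows) + 1L]] <- .metricsRow("Overall", metricsOf("overall"))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Export a bipartite network as GraphML
#'
#' Nodes carry a \code{type} attribute with values \code{"vaccine"} or
#' \code{"ae"}; node and edge order is deterministic.
#'
#' @param net a \code{BipartiteNetwork}.
#' @param path output file.
#' @return invisible \code{path}.
#' @export
writeGraphML <- function(net, path) {
  g <- asIgraph(net)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
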