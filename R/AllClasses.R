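#' @import methods
#' @importFrom stats as.dist cor cophenetic hclust ks.test rgamma runif setNames
#' @importFrom utils read.csv write.csv head
NULL

#' ReportSet: a normalized collection of spontaneous reports
#'
#' One row per report: an opaque identifier, the calendar year the report was
#' received, patient sex (F/M/U), age in years (possibly \code{NA}), and the
#' deduplicated sets of administered vaccine types and reported symptom terms
#' (stored as list columns of sorted character vectors).
#'
#' @slot reports data.frame with columns \code{report_id}, \code{year},
#'   \code{sex}, \code{age} and list columns \code{vaccines}, \code{symptoms}.
#' @slot provenance free-text description of where the reports came from.
#' @export
setClass("ReportSet", slots = c(reports = "data.frame", provenance = "character"))

setValidity("ReportSet", function(object) {
  df <- object@reports
  need <- c("report_id", "year", "sex", "age", "vaccines", "symptoms")
  if (!all(need %in% names(df))) {
    return(paste("missing report columns:",
                 paste(setdiff(need, names(df)), collapse = ", ")))
  }
  if (anyDuplicated(df$report_id)) return("duplicate report_id values")
  if (!all(df$sex %in% c("F", "M", "U"))) return("sex must be one of F, M, U")
  if (any(!is.na(df$age) & df$age < 0)) return("negative ages")
  bad <- function(col) {
    vals <- unlist(df[[col]], use.names = FALSE)
    if (is.null(vals) || length(vals) == 0) return(FALSE)
    any(is.na(vals)) || any(!nzchar(vals)) || any(vals != trimws(vals)) ||
      any(vapply(df[[col]], anyDuplicated, integer(1)) > 0)
  }
  if (nrow(df) > 0 && (bad("vaccines") || bad("symptoms"))) {
    return("vaccine/symptom sets must be trimmed, non-empty strings, deduplicated")
  }
  TRUE
})

#' AssociationSet: vaccine-symptom pair counts, denominators and PRRs
#'
#' Produced by \code{\link{countPairs}} (counts + denominators) and completed
#' by \code{\link{computePrr}} (PRR columns). One record per distinct
#' (vaccine, symptom) pair co-occurring in at least one report.
#'
#' @slot records data.frame: \code{vaccine}, \code{symptom}, \code{nTotal},
#'   \code{nF}, \code{nM}, and after \code{computePrr} also \code{prrOverall},
#'   \code{prrF}, \code{prrM} (\code{NA} = undefined, flagged, never 0/Inf).
#' @slot yearly data.frame: \code{vaccine}, \code{symptom}, \code{year},
#'   \code{n} and (after \code{computePrr}) \code{prr}.
#' @slot context list of per-stratum denominators (total reports, reports per
#'   vaccine, reports per symptom; overall, per year, per sex).
#' @slot prrComputed logical flag.
#' @export
setClass("AssociationSet",
         slots = c(records = "data.frame", yearly = "data.frame",
                   context = "list", prrComputed = "logical"))

setValidity("AssociationSet", function(object) {
  rec <- object@records
  if (anyDuplicated(rec[c("vaccine", "symptom")])) {
    return("duplicate (vaccine, symptom) records")
  }
  if (nrow(object@yearly) > 0) {
    ytot <- tapply(object@yearly$n, paste(object@yearly$vaccine,
                                          object@yearly$symptom, sep = "\r"),
                   sum)
    key <- paste(rec$vaccine, rec$symptom, sep = "\r")
    known <- key %in% names(ytot)
    # reports with unparseable years appear in totals but in no yearly row,
    # so the yearly sum can only fall short of the total, never exceed it
    if (any(known) && !all(ytot[key[known]] <= rec$nTotal[known])) {
      return("yearly pair counts exceed totals")
    }
  }
  if (object@prrComputed) {
    prr <- c(rec$prrOverall, rec$prrF, rec$prrM, object@yearly$prr)
    if (any(!is.na(prr) & prr < 0)) return("negative PRR")
  }
  TRUE
})

#' DemographicDistribution: who reported a given vaccine-AE pair
#'
#' Counts of the reports containing one (vaccine, symptom) pair, broken down
#' by sex and by age group, in total and per reporting year.
#'
#' @slot vaccine,symptom the pair described.
#' @slot nTotal number of reports containing the pair.
#' @slot sexCounts named integer vector over F, M, U.
#' @slot ageCounts named integer vector over the age-group labels plus
#'   "unknown".
#' @slot byYearSex data.frame: \code{year}, \code{sex}, \code{n}.
#' @slot byYearAge data.frame: \code{year}, \code{ageGroup}, \code{n}.
#' @export
setClass("DemographicDistribution",
         slots = c(vaccine = "character", symptom = "character",
                   nTotal = "integer", sexCounts = "integer",
                   ageCounts = "integer", byYearSex = "data.frame",
                   byYearAge = "data.frame"))

setValidity("DemographicDistribution", function(object) {
  if (sum(object@sexCounts) != object@nTotal) {
    return("sex counts must sum to the pair total")
  }
  if (sum(object@ageCounts) != object@nTotal) {
    return("age-group counts must sum to the pair total")
  }
  TRUE
})

#' BipartiteNetwork: vaccine and adverse-event nodes linked by associations
#'
#' Undirected bipartite graph; edges join exactly one vaccine node and one
#' adverse-event node, and nodes exist only through edges (no isolates).
#'
#' @slot vaccineNodes character vector of vaccine-type codes.
#' @slot aeNodes character vector of adverse-event (symptom) terms.
#' @slot edges data.frame with columns \code{vaccine}, \code{symptom}.
#' @export
setClass("BipartiteNetwork",
         slots = c(vaccineNodes = "character", aeNodes = "character",
                   edges = "data.frame"))

setValidity("BipartiteNetwork", function(object) {
  e <- object@edges
  if (!all(c("vaccine", "symptom") %in% names(e))) {
    return("edges need vaccine and symptom columns")
  }
  if (anyDuplicated(e)) return("duplicate edges")
  if (!setequal(unique(e$vaccine), object@vaccineNodes) ||
      !setequal(unique(e$symptom), object@aeNodes)) {
    return("isolated nodes: node sets must equal the union of edge endpoints")
  }
  if (length(intersect(object@vaccineNodes, object@aeNodes)) > 0) {
    return("a label occurs as both vaccine and AE node")
  }
  TRUE
})

#' NetworkMetrics: the summary row of one association network
#'
#' @slot nNode,nLink node and edge counts.
#' @slot averageDegree 2E/N at full precision.
#' @slot averagePathLength mean unweighted shortest-path length over reachable
#'   unordered node pairs.
#' @slot diameter largest finite shortest-path length.
#' @slot empty TRUE when the network had no edges (all metrics zero).
#' @export
setClass("NetworkMetrics",
         slots = c(nNode = "integer", nLink = "integer",
                   averageDegree = "numeric", averagePathLength = "numeric",
                   diameter = "integer", empty = "logical"))

setValidity("NetworkMetrics", function(object) {
  if (object@nNode > 0 && object@nLink > 0) {
    if (abs(object@averageDegree - 2 * object@nLink / object@nNode) > 1e-12) {
      return("averageDegree must equal 2*nLink/nNode")
    }
    if (object@diameter + 1e-12 < object@averagePathLength) {
      return("diameter cannot be below the average path length")
    }
  }
  TRUE
})

#' SimilarityMatrix: pairwise association-index values among same-type nodes
#'
#' Symmetric matrix of Pearson association indexes over the chosen node type
#' of a bipartite network; \code{NA} marks undefined entries (degree 0 or
#' degree equal to the opposite-set size).
#'
#' @slot labels ordered node labels (rows/columns of \code{values}).
#' @slot values symmetric numeric matrix in [-1, 1] with \code{NA} allowed.
#' @slot nY size of the opposite-type node set used as the universe.
#' @export
setClass("SimilarityMatrix",
         slots = c(labels = "character", values = "matrix", nY = "integer"))

setValidity("SimilarityMatrix", function(object) {
  v <- object@values
  n <- length(object@labels)
  if (!all(dim(v) == c(n, n))) return("matrix dimensions do not match labels")
  if (!isTRUE(all.equal(v, t(v), tolerance = 1e-12))) return("matrix not symmetric")
  off <- v[upper.tri(v)]
  if (any(!is.na(off) & (off < -1 - 1e-9 | off > 1 + 1e-9))) {
    return("association index outside [-1, 1]")
  }
  TRUE
})

#' ClusterTree: agglomerative clustering of vaccines by association profile
#'
#' Wraps the \code{hclust} merge tree built on distance 1 - PCC.
#'
#' @slot hclust the \code{stats::hclust} object.
#' @slot labels leaf labels, each exactly once.
#' @slot imputed number of undefined similarity entries imputed before
#'   clustering.
#' @export
setClass("ClusterTree",
         slots = c(hclust = "ANY", labels = "character", imputed = "integer"))

setValidity("ClusterTree", function(object) {
  h <- object@hclust
  if (!inherits(h, "hclust")) return("hclust slot must be an hclust object")
  if (!setequal(h$labels, object@labels) ||
      length(h$labels) != length(object@labels)) {
    return("leaves must be the labels, each exactly once")
  }
  if (is.unsorted(h$height, strictly = FALSE)) {
    return("merge heights must be non-decreasing")
  }
  TRUE
})

#' StrataComparison: similarity structure compared between two strata
#'
#' @slot labels common vaccine labels the comparison is restricted to.
#' @slot valuesF,valuesM paired off-diagonal association-index values.
#' @slot density data.frame of binned counts (\code{bin_left},
#'   \code{bin_right}, \code{count_f}, \code{count_m}) over [-1, 1].
#' @slot ksDistance two-sample Kolmogorov-Smirnov distance (descriptive).
#' @export
setClass("StrataComparison",
         slots = c(labels = "character", valuesF = "numeric",
                   valuesM = "numeric", density = "data.frame",
                   ksDistance = "numeric"))

#' AssociationGraph: RDF triples describing vaccine-AE associations
#'
#' A minimal in-memory triple store over the package namespace; one
#' association resource per (vaccine, symptom) pair, carrying links to its
#' vaccine, symptom, stratified counts and PRR values.
#'
#' @slot triples data.frame: \code{subject}, \code{predicate}, \code{object},
#'   \code{objectType} ("iri" or "literal"), \code{datatype} (xsd IRI or NA).
#' @slot namespace base IRI of the vocabulary.
#' @export
setClass("AssociationGraph",
         slots = c(triples = "data.frame", namespace = "character"))

setValidity("AssociationGraph", function(object) {
  tr <- object@triples
  need <- c("subject", "predicate", "object", "objectType", "datatype")
  if (!all(need %in% names(tr))) return("triple table missing columns")
  if (nrow(tr) > 0 && !all(tr$objectType %in% c("iri", "literal"))) {
    return("objectType must be iri or literal")
  }
  TRUE
})
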