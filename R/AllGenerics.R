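#' @rdname ReportSet-class
#' @param object a \code{ReportSet}.
#' @export
setGeneric("nReports", function(object) standardGeneric("nReports"))

#' @rdname ReportSet-class
#' @export
setMethod("nReports", "ReportSet", function(object) nrow(object@reports))

#' Report table accessor
#'
#' @param object a \code{ReportSet}.
#' @return the underlying normalized data.frame (list columns for vaccine and
#'   symptom sets).
#' @export
setGeneric("reportTable", function(object) standardGeneric("reportTable"))

#' @rdname reportTable
#' @export
setMethod("reportTable", "ReportSet", function(object) object@reports)

#' Association record accessor
#'
#' @param object an \code{AssociationSet}.
#' @return data.frame of per-pair records (counts and, once computed, PRRs).
#' @export
setGeneric("associationRecords",
           function(object) standardGeneric("associationRecords"))

#' @rdname associationRecords
#' @export
setMethod("associationRecords", "AssociationSet", function(object) object@records)

#' Yearly association record accessor
#'
#' @param object an \code{AssociationSet}.
#' @return data.frame of per-pair, per-year counts (and PRRs once computed).
#' @export
setGeneric("yearlyRecords", function(object) standardGeneric("yearlyRecords"))

#' @rdname yearlyRecords
#' @export
setMethod("yearlyRecords", "AssociationSet", function(object) object@yearly)

#' Denominator context accessor
#'
#' @param object an \code{AssociationSet}.
#' @return list of per-stratum totals used as PRR denominators.
#' @export
setGeneric("countContext", function(object) standardGeneric("countContext"))

#' @rdname countContext
#' @export
setMethod("countContext", "AssociationSet", function(object) object@context)

#' Edge table accessor
#'
#' @param object a \code{BipartiteNetwork}.
#' @return data.frame of (vaccine, symptom) edges.
#' @export
setGeneric("edgeTable", function(object) standardGeneric("edgeTable"))

#' @rdname edgeTable
#' @export
setMethod("edgeTable", "BipartiteNetwork", function(object) object@edges)

#' Node accessors for bipartite networks
#'
#' @param object a \code{BipartiteNetwork}.
#' @return character vector of node labels of the requested type.
#' @export
setGeneric("vaccineNodes", function(object) standardGeneric("vaccineNodes"))

#' @rdname vaccineNodes
#' @export
setMethod("vaccineNodes", "BipartiteNetwork", function(object) object@vaccineNodes)

#' @rdname vaccineNodes
#' @export
setGeneric("aeNodes", function(object) standardGeneric("aeNodes"))

#' @rdname vaccineNodes
#' @export
setMethod("aeNodes", "BipartiteNetwork", function(object) object@aeNodes)

#' Similarity values accessor
#'
#' @param object a \code{SimilarityMatrix}.
#' @return the symmetric numeric matrix (labels as dimnames).
#' @export
setGeneric("similarityValues",
           function(object) standardGeneric("similarityValues"))

#' @rdname similarityValues
#' @export
setMethod("similarityValues", "SimilarityMatrix", function(object) {
  v <- object@values
  dimnames(v) <- list(object@labels, object@labels)
  v
})

#' Triple table accessor
#'
#' @param object an \code{AssociationGraph}.
#' @return data.frame of RDF triples.
#' @export
setGeneric("tripleTable", function(object) standardGeneric("tripleTable"))

#' @rdname tripleTable
#' @export
setMethod("tripleTable", "AssociationGraph", function(object) object@triples)

setMethod("show", "ReportSet", function(object) {
  df <- object@reports
  cat(sprintf("ReportSet with %d reports (%s)\n", nrow(df), object@provenance))
  if (nrow(df) > 0) {
    cat(sprintf("  years: %s  sex: F=%d M=%d U=%d\n",
                paste(range(df$year, na.rm = TRUE), collapse = "-"),
                sum(df$sex == "F"), sum(df$sex == "M"), sum(df$sex == "U")))
    cat(sprintf("  distinct vaccines: %d  distinct symptoms: %d\n",
                length(unique(unlist(df$vaccines))),
                length(unique(unlist(df$symptoms)))))
  }
})

setMethod("show", "AssociationSet", function(object) {
  cat(sprintf("AssociationSet with %d distinct vaccine-AE pairs (PRR %s)\n",
              nrow(object@records),
              if (object@prrComputed) "computed" else "not computed"))
})

setMethod("show", "BipartiteNetwork", function(object) {
  cat(sprintf("BipartiteNetwork: %d vaccine + %d AE nodes, %d links\n",
              length(object@vaccineNodes), length(object@aeNodes),
              nrow(object@edges)))
})

setMethod("show", "NetworkMetrics", function(object) {
  if (object@empty) {
    cat("NetworkMetrics: empty network (all metrics zero)\n")
  } else {
    cat(sprintf(paste0("NetworkMetrics: N=%d, E=%d, <k>=%.2f, ",
                       "<l>=%.2f, diameter=%d\n"),
                object@nNode, object@nLink,
                roundHalfUp(object@averageDegree, 2),
                roundHalfUp(object@averagePathLength, 2), object@diameter))
  }
})

setMethod("show", "SimilarityMatrix", function(object) {
  cat(sprintf("SimilarityMatrix over %d labels (opposite set size %d), %d undefined entries\n",
              length(object@labels), object@nY, sum(is.na(object@values))))
})

setMethod("show", "ClusterTree", function(object) {
  cat(sprintf("ClusterTree over %d vaccines (average linkage on 1 - PCC)\n",
              length(object@labels)))
})

setMethod("show", "StrataComparison", function(object) {
  cat(sprintf("StrataComparison over %d common vaccines: KS distance %.3f\n",
              length(object@labels), object@ksDistance))
})

setMethod("show", "AssociationGraph", function(object) {
  cat(sprintf("AssociationGraph: %d triples under <%s>\n",
              nrow(object@triples), object@namespace))
})
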