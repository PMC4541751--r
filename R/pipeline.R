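#' Configuration of an end-to-end pipeline run
#'
#' The pipeline ingests reports (from a VAERS-style CSV triplet, a
#' normalized flat CSV, or the synthetic generator), computes stratified
#' pair counts and PRRs, filters disproportionally reported pairs, builds
#' and characterizes per-stratum association networks, projects the
#' sex-specific networks onto vaccines for clustering and cross-sex
#' comparison, and exports the association summary as RDF. All outputs land
#' under \code{outDir} and are deterministic given the config and seed.
#'
#' @param input one of: a \code{syntheticConfig}; a \code{ReportSet}; a named
#'   list \code{list(data=, vaccine=, symptom=)} of CSV paths; or a single
#'   path to a normalized flat CSV.
#' @param outDir output directory (created if needed).
#' @param threshold PRR significance cutoff (> 0; default 1, strict).
#' @param strata subset of \code{c("years", "sexes", "overall")}.
#' @param clusterMethod linkage method for vaccine clustering.
#' @param binWidth density bin width for the cross-sex comparison.
#' @param seed integer seed applied to any stochastic input.
#' @return a validated list of class \code{pipelineConfig}.
#' @export
pipelineConfig <- function(input, outDir,
                           threshold = 1,
                           strata = c("years", "sexes", "overall"),
                           clusterMethod = "average",
                           binWidth = 0.05,
                           seed = 1L) {
  if (!is.numeric(threshold) || threshold <= 0) {
    .stopf("threshold must be > 0")
  }
  if (!all(strata %in% c("years", "sexes", "overall"))) {
    .stopf("strata must be drawn from 'years', 'sexes', 'overall'")
  }
  structure(list(input = input, outDir = outDir, threshold = threshold,
                 strata = strata, clusterMethod = clusterMethod,
                 binWidth = binWidth, seed = as.integer(seed)),
            class = "pipelineConfig")
}

.ingest <- function(input, seed) {
  if (is(input, "ReportSet")) return(input)
  if (inherits(input, "syntheticConfig")) {
    input$seed <- as.integer(seed)
    return(generateReports(input)$reports)
  }
  if (is.list(input) && all(c("data", "vaccine", "symptom") %in% names(input))) {
    return(readReports(input$data, input$vaccine, input$symptom))
  }
  if (is.character(input) && length(input) == 1) {
    return(readNormalizedReports(input))
  }
  .stopf("unrecognized pipeline input")
}

#' Run the full association-analysis pipeline
#'
#' Stages: \code{ingest} (reports in), \code{summarize} (pair counts and
#' stratified PRRs; association TSVs), \code{rdf} (Turtle export),
#' \code{network} (per-stratum GraphML + metrics table), \code{similarity}
#' (sex-specific vaccine similarity matrices, dendrograms, and the paired
#' density/KS comparison). A stage failure aborts with a stage-named error
#' after writing a manifest flagging the partial outputs.
#'
#' @param config a \code{\link{pipelineConfig}}.
#' @return the run manifest (list): per-artifact paths and MD5 checksums,
#'   the stage log (record counts in/out per stage), and a status flag.
#'   Also written to \code{manifest.json} in the output directory.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "pipelineConfig"))
  dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
  artifacts <- list()
  log <- character(0)
  note <- function(fmt, ...) log <<- c(log, sprintf(fmt, ...))
  keep <- function(class, path) {
    artifacts[[class]] <<- c(artifacts[[class]], path)
  }
  out <- function(...) file.path(config$outDir, ...)
  finish <- function(status, failedStage = NA_character_) {
    manifest <- list(
      status = status, failed_stage = failedStage,
      seed = config$seed, threshold = config$threshold,
      strata = config$strata,
      artifacts = lapply(artifacts, function(p) {
        lapply(p, function(f) list(path = basename(f),
                                   md5 = unname(tools::md5sum(f))))
      }),
      log = log)
    jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
    manifest$manifest_path <- out("manifest.json")
    manifest
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      note("stage %s: FAILED (%s)", name, conditionMessage(e))
      finish("failed", name)
      .stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e))
    })
  }

  reports <- stage("ingest", .ingest(config$input, config$seed))
  note("stage ingest: %d reports in", nReports(reports))

  assoc <- stage("summarize", computePrr(countPairs(reports)))
  note("stage summarize: %d pair mentions over %d distinct pairs",
       sum(associationRecords(assoc)$nTotal), nrow(associationRecords(assoc)))
  stage("summarize", {
    paths <- writeAssociationTable(assoc, out("associations.tsv"))
    keep("association_table", paths[1])
    keep("association_table", paths[2])
  })

  stage("rdf", {
    graph <- toRdf(assoc)
    keep("rdf", writeRdf(graph, out("associations.ttl"), format = "turtle"))
    note("stage rdf: %d triples", nrow(tripleTable(graph)))
  })

  sigOf <- function(stratum) {
    significantAssociations(assoc, stratum, config$threshold)
  }
  netLabels <- c(
    if ("years" %in% config$strata) {
      as.character(sort(unique(yearlyRecords(assoc)$year)))
    },
    if ("sexes" %in% config$strata) c("F", "M"),
    if ("overall" %in% config$strata) "overall")
  nets <- stage("network", {
    nets <- list()
    for (lab in netLabels) {
      sig <- sigOf(lab)
      nets[[lab]] <- buildNetwork(sig)
      note("stage network [%s]: %d significant pairs -> %d nodes, %d links",
           lab, nrow(sig),
           length(vaccineNodes(nets[[lab]])) + length(aeNodes(nets[[lab]])),
           nrow(edgeTable(nets[[lab]])))
      if (nrow(edgeTable(nets[[lab]])) > 0) {
        keep("network_graphml",
             writeGraphML(nets[[lab]], out(sprintf("network_%s.graphml", lab))))
      }
    }
    keep("metrics_table", {
      m <- strataMetricsTable(assoc, strata = config$strata,
                              threshold = config$threshold)
      utils::write.table(m, out("network_metrics.tsv"), sep = "\t",
                         row.names = FALSE, quote = FALSE)
      out("network_metrics.tsv")
    })
    nets
  })

  if ("sexes" %in% config$strata) {
    stage("similarity", {
      sims <- list()
      for (sx in c("F", "M")) {
        net <- nets[[sx]]
        if (length(vaccineNodes(net)) >= 2) {
          sims[[sx]] <- similarityMatrix(net, "vaccine")
          keep("similarity_matrix",
               writeSimilarityMatrix(sims[[sx]],
                                     out(sprintf("similarity_%s.tsv", sx))))
          tree <- suppressWarnings(clusterVaccines(sims[[sx]],
                                                   config$clusterMethod))
          keep("dendrogram",
               writeNewick(tree, out(sprintf("dendrogram_%s.nwk", sx))))
        } else {
          note("stage similarity [%s]: fewer than 2 vaccine nodes, skipped", sx)
        }
      }
      if (length(sims) == 2 &&
          length(intersect(sims$F@labels, sims$M@labels)) >= 2) {
        cmp <- compareStrata(sims$F, sims$M, config$binWidth)
        keep("density_comparison",
             writeDensityComparison(cmp, out("pcc_density_comparison.tsv")))
        note("stage similarity: KS distance F vs M = %.4f", cmp@ksDistance)
      } else {
        note("stage similarity: cross-sex comparison skipped (insufficient common labels)")
      }
    })
  }

  finish("ok")
}
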