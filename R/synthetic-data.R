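#' Configuration for the synthetic spontaneous-report generator
#'
#' Builds and validates the configuration driving
#' \code{\link{generateReports}}. Reports are generated independently: the
#' reporting year is uniform over \code{years}, sex follows \code{sexProbs},
#' the number of co-administered vaccines follows \code{vaccinesPerReport},
#' vaccines are drawn without replacement proportionally to their usage
#' weights, and each symptom enters a report independently with probability
#' \emph{background x product of applicable planted multipliers}, capped at 1.
#' A planted signal is a (vaccine, symptom, sex, multiplier) quadruple;
#' \code{sex = "both"} applies to F and M reports but not U, and a multiplier
#' of 1 means no planted effect.
#'
#' The defaults emulate a mid-sized passive-surveillance corpus: 50,000
#' reports over two reporting years, a dozen vaccine types with skewed usage,
#' fifty symptom terms with background reporting probabilities between 0.004
#' and 0.08, and the female-skewed sex mix typical of spontaneous reporting
#' (54\% F / 40\% M / 6\% unknown).
#'
#' @param nReports number of reports to generate.
#' @param years integer vector of candidate reporting years.
#' @param vaccineCatalog named numeric vector: per-report usage weight of each
#'   vaccine code (normalized internally).
#' @param symptomCatalog named numeric vector: background per-report inclusion
#'   probability of each symptom term, each in [0, 1].
#' @param sexProbs named probabilities over F, M, U summing to 1.
#' @param plantedSignals data.frame with columns \code{vaccine},
#'   \code{symptom}, \code{sex} (one of "F", "M", "both") and
#'   \code{multiplier} (>= 0), or NULL for a pure background corpus.
#' @param vaccinesPerReport named numeric vector: probability of a report
#'   listing 1, 2, ... vaccines (names are the counts).
#' @param seed integer seed; identical seeds give identical corpora.
#' @return a validated list of class \code{syntheticConfig}.
#' @export
syntheticConfig <- function(nReports = 50000L,
                            years = c(2010L, 2011L),
                            vaccineCatalog = NULL,
                            symptomCatalog = NULL,
                            sexProbs = c(F = 0.54, M = 0.40, U = 0.06),
                            plantedSignals = NULL,
                            vaccinesPerReport = c("1" = 0.70, "2" = 0.22,
                                                  "3" = 0.08),
                            seed = 1L) {
  if (is.null(vaccineCatalog)) {
    codes <- c("FLU", "MMR", "DTAP", "HEPB", "HIBV", "IPV", "PNC", "VARCEL",
               "TD", "HPV4", "ROTA", "MENB")
    w <- c(0.24, 0.14, 0.12, 0.10, 0.09, 0.08, 0.07, 0.05, 0.04, 0.03,
           0.02, 0.02)
    vaccineCatalog <- stats::setNames(w, codes)
  }
  if (is.null(symptomCatalog)) {
    terms <- sprintf("AE_%02d", seq_len(50))
    probs <- round(exp(seq(log(0.08), log(0.004), length.out = 50)), 5)
    symptomCatalog <- stats::setNames(probs, terms)
  }
  if (is.null(plantedSignals)) {
    plantedSignals <- data.frame(vaccine = character(0), symptom = character(0),
                                 sex = character(0), multiplier = numeric(0),
                                 stringsAsFactors = FALSE)
  }
  cfg <- list(nReports = as.integer(nReports), years = as.integer(years),
              vaccineCatalog = vaccineCatalog, symptomCatalog = symptomCatalog,
              sexProbs = sexProbs,
              plantedSignals = as.data.frame(plantedSignals),
              vaccinesPerReport = vaccinesPerReport, seed = as.integer(seed))
  .validateSyntheticConfig(cfg)
  class(cfg) <- "syntheticConfig"
  cfg
}

.validateSyntheticConfig <- function(cfg) {
  if (cfg$nReports < 1) .stopf("nReports must be positive")
  if (length(cfg$years) < 1) .stopf("years must be non-empty")
  if (length(cfg$vaccineCatalog) < 1 || length(cfg$symptomCatalog) < 1) {
    .stopf("vaccine and symptom catalogs must be non-empty")
  }
  if (any(cfg$vaccineCatalog < 0)) .stopf("vaccine usage weights must be >= 0")
  if (any(cfg$symptomCatalog < 0 | cfg$symptomCatalog > 1)) {
    .stopf("symptom background probabilities must lie in [0, 1]")
  }
  if (!setequal(names(cfg$sexProbs), c("F", "M", "U")) ||
      any(cfg$sexProbs < 0 | cfg$sexProbs > 1) ||
      abs(sum(cfg$sexProbs) - 1) > 1e-9) {
    .stopf("sexProbs must be probabilities over F, M, U summing to 1")
  }
  ps <- cfg$plantedSignals
  if (nrow(ps) > 0) {
    need <- c("vaccine", "symptom", "sex", "multiplier")
    if (!all(need %in% names(ps))) {
      .stopf("plantedSignals needs columns %s", paste(need, collapse = ", "))
    }
    if (!all(ps$sex %in% c("F", "M", "both"))) {
      .stopf("plantedSignals$sex must be 'F', 'M' or 'both'")
    }
    if (any(ps$multiplier < 0)) .stopf("multipliers must be >= 0")
    if (!all(ps$vaccine %in% names(cfg$vaccineCatalog)) ||
        !all(ps$symptom %in% names(cfg$symptomCatalog))) {
      .stopf("planted signals must reference catalog vaccines/symptoms")
    }
  }
  k <- suppressWarnings(as.integer(names(cfg$vaccinesPerReport)))
  if (any(is.na(k)) || any(k < 1) || any(cfg$vaccinesPerReport < 0) ||
      abs(sum(cfg$vaccinesPerReport) - 1) > 1e-9) {
    .stopf("vaccinesPerReport must be probabilities over positive counts summing to 1")
  }
  invisible(TRUE)
}

#' Write / read a synthetic-generator configuration as JSON
#'
#' @param cfg a \code{syntheticConfig}.
#' @param path JSON file path.
#' @return \code{readSyntheticConfig} returns a validated
#'   \code{syntheticConfig}; \code{writeSyntheticConfig} returns \code{path}
#'   invisibly.
#' @export
writeSyntheticConfig <- function(cfg, path) {
  x <- unclass(cfg)
  # named vectors must serialize as JSON objects, not bare arrays
  for (f in c("vaccineCatalog", "symptomCatalog", "sexProbs",
              "vaccinesPerReport")) {
    x[[f]] <- as.list(x[[f]])
  }
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname writeSyntheticConfig
#' @export
readSyntheticConfig <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  syntheticConfig(nReports = raw$nReports, years = raw$years,
                  vaccineCatalog = unlist(raw$vaccineCatalog),
                  symptomCatalog = unlist(raw$symptomCatalog),
                  sexProbs = unlist(raw$sexProbs),
                  plantedSignals = raw$plantedSignals,
                  vaccinesPerReport = unlist(raw$vaccinesPerReport),
                  seed = raw$seed)
}

#' Generate a synthetic VAERS-like report corpus with ground truth
#'
#' Draws \code{nReports} independent reports under the model described in
#' \code{\link{syntheticConfig}} and returns both the \code{ReportSet} and a
#' ground-truth object: the planted signals as configured plus the realized
#' per-stratum co-report counts of each planted pair, recounted from the
#' emitted corpus.
#'
#' @param cfg a \code{syntheticConfig}.
#' @return list with elements \code{reports} (a
#'   \code{\linkS4class{ReportSet}}) and \code{truth} (list: \code{planted},
#'   \code{realized}).
#' @export
generateReports <- function(cfg) {
  stopifnot(inherits(cfg, "syntheticConfig"))
  .validateSyntheticConfig(cfg)
  .withSeed(cfg$seed, {
    n <- cfg$nReports
    year <- sample(cfg$years, n, replace = TRUE)
    sex <- sample(names(cfg$sexProbs), n, replace = TRUE, prob = cfg$sexProbs)
    # right-skewed adult-dominated age mix with some infants; 5% unrecorded
    age <- roundHalfUp(stats::rgamma(n, shape = 1.6, scale = 20), 1)
    age[stats::runif(n) < 0.05] <- NA_real_

    vcodes <- names(cfg$vaccineCatalog)
    vw <- cfg$vaccineCatalog / sum(cfg$vaccineCatalog)
    k <- sample(as.integer(names(cfg$vaccinesPerReport)), n, replace = TRUE,
                prob = cfg$vaccinesPerReport)
    k <- pmin(k, length(vcodes))
    vaccines <- vector("list", n)
    one <- k == 1L
    vaccines[one] <- as.list(vcodes[sample.int(length(vcodes), sum(one),
                                               replace = TRUE, prob = vw)])
    for (i in which(!one)) {
      vaccines[[i]] <- vcodes[sample.int(length(vcodes), k[i], prob = vw)]
    }

    # symptom inclusion: background prob scaled by planted multipliers that
    # match the report's vaccines and sex stratum, capped at 1
    scodes <- names(cfg$symptomCatalog)
    ps <- cfg$plantedSignals
    hasVac <- function(v) vapply(vaccines, function(x) v %in% x, logical(1))
    symMat <- matrix(FALSE, n, length(scodes))
    for (j in seq_along(scodes)) {
      p <- rep(cfg$symptomCatalog[[j]], n)
      if (nrow(ps) > 0) {
        rows <- which(ps$symptom == scodes[j])
        for (r in rows) {
          hit <- hasVac(ps$vaccine[r])
          hit <- hit & switch(ps$sex[r],
                              "F" = sex == "F", "M" = sex == "M",
                              "both" = sex %in% c("F", "M"))
          p[hit] <- p[hit] * ps$multiplier[r]
        }
      }
      symMat[, j] <- stats::runif(n) < pmin(p, 1)
    }
    symptoms <- lapply(seq_len(n), function(i) scodes[symMat[i, ]])

    rs <- ReportSet(report_id = sprintf("S%07d", seq_len(n)),
                    year = year, sex = sex, age = age,
                    vaccines = vaccines, symptoms = symptoms,
                    provenance = sprintf("synthetic corpus (seed %d)", cfg$seed))

    realized <- if (nrow(ps) > 0) {
      do.call(rbind, lapply(seq_len(nrow(ps)), function(r) {
        hit <- hasVac(ps$vaccine[r]) & symMat[, match(ps$symptom[r], scodes)]
        data.frame(vaccine = ps$vaccine[r], symptom = ps$symptom[r],
                   nOverall = sum(hit), nF = sum(hit & sex == "F"),
                   nM = sum(hit & sex == "M"), stringsAsFactors = FALSE)
      }))
    } else {
      data.frame(vaccine = character(0), symptom = character(0),
                 nOverall = integer(0), nF = integer(0), nM = integer(0))
    }
    list(reports = rs, truth = list(planted = ps, realized = realized))
  })
}

#' Deterministic hand-written fixtures used across the test suite
#'
#' \describe{
#'   \item{tiny3}{three reports exercising the three-table join: R1 has
#'     vaccines DTAP+MMR and symptom Fever; R2 has FLU with Rash+Fever;
#'     R3 has neither vaccines nor symptoms.}
#'   \item{toy_prr}{100 reports in which vaccine V appears in 10 reports,
#'     4 of them with symptom S, and S appears in 20 reports overall, so the
#'     reporting ratio of (V, S) is (4/10)/(20/100) = 2.}
#'   \item{toy_star}{20 reports whose disproportionally reported pairs form a
#'     star: vaccine V linked to the four adverse events AE_a..AE_d.}
#' }
#'
#' @param name one of \code{"tiny3"}, \code{"toy_prr"}, \code{"toy_star"}.
#' @return a \code{\linkS4class{ReportSet}}.
#' @export
makeFixture <- function(name) {
  switch(name,
    tiny3 = ReportSet(
      report_id = c("R1", "R2", "R3"),
      year = c(1991L, 1991L, 1992L),
      sex = c("F", "F", "M"),
      age = c(1, 30, NA),
      vaccines = list(c("DTAP", "MMR"), "FLU", character(0)),
      symptoms = list("Fever", c("Rash", "Fever"), character(0)),
      provenance = "fixture tiny3"),
    toy_prr = {
      # V in reports 1-10; S in 1-4 and 11-26 (20 total); filler elsewhere
      n <- 100L
      vaccines <- c(rep(list("V"), 10), rep(list("OTH"), 90))
      symptoms <- lapply(seq_len(n), function(i) {
        if (i <= 4 || (i >= 11 && i <= 26)) "S" else "Headache"
      })
      ReportSet(report_id = sprintf("P%03d", seq_len(n)),
                year = rep(2000L, n),
                sex = rep(c("F", "M"), length.out = n),
                age = rep(25, n),
                vaccines = vaccines, symptoms = symptoms,
                provenance = "fixture toy_prr")
    },
    toy_star = {
      # 4 reports pair V with one rare AE each (PRR 5); the shared AE_common
      # term lands everywhere so the (W, AE_common) ratio is exactly 1
      n <- 20L
      vaccines <- c(rep(list("V"), 4), rep(list("W"), 16))
      symptoms <- c(lapply(c("AE_a", "AE_b", "AE_c", "AE_d"),
                           function(s) c(s, "AE_common")),
                    rep(list("AE_common"), 16))
      ReportSet(report_id = sprintf("T%03d", seq_len(n)),
                year = rep(2005L, n),
                sex = rep(c("F", "M"), length.out = n),
                age = rep(10, n),
                vaccines = vaccines, symptoms = symptoms,
                provenance = "fixture toy_star")
    },
    .stopf("unknown fixture '%s' (expected tiny3, toy_prr or toy_star)", name)
  )
}
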