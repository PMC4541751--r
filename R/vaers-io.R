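#' Construct a ReportSet from raw columns
#'
#' Normalizes the inputs: sex codes are folded to F/M/U, vaccine and symptom
#' sets are trimmed, deduplicated and sorted, ages below zero rejected.
#'
#' @param report_id character vector of unique report identifiers.
#' @param year integer reporting year (NA allowed).
#' @param sex sex codes; anything other than F/M (case-insensitive) maps to U.
#' @param age age in years, NA allowed.
#' @param vaccines list of character vectors of vaccine-type codes.
#' @param symptoms list of character vectors of symptom terms.
#' @param provenance free-text source description.
#' @return a \code{\linkS4class{ReportSet}}.
#' @export
ReportSet <- function(report_id, year, sex, age, vaccines, symptoms,
                      provenance = "constructed") {
  n <- length(report_id)
  stopifnot(length(year) == n, length(sex) == n, length(age) == n,
            length(vaccines) == n, length(symptoms) == n)
  df <- data.frame(report_id = as.character(report_id),
                   year = as.integer(year),
                   sex = .normalizeSex(sex),
                   age = as.numeric(age),
                   stringsAsFactors = FALSE)
  df$vaccines <- .normalizeTermList(vaccines)
  df$symptoms <- .normalizeTermList(symptoms)
  if (anyDuplicated(df$report_id)) {
    .stopf("duplicate report_id values in ReportSet")
  }
  new("ReportSet", reports = df, provenance = provenance)
}

.requireColumns <- function(df, cols, table, path) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    .stopf("table '%s' (%s) is missing required column(s): %s",
           table, path, paste(missing, collapse = ", "))
  }
}

.readCsvTable <- function(path, table) {
  if (!file.exists(path)) {
    .stopf("cannot read %s table: no such file '%s'", table, path)
  }
  # VAERS raw exports are 8-bit text of uncertain encoding; read permissively
  # (latin1 never fails byte-wise) with the standard comma/double-quote dialect.
  # everything as character: fields like SEX ("F") or zip-like IDs must not
  # be coerced by type sniffing
  utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "latin1",
                  check.names = FALSE, colClasses = "character")
}

#' Read and join a VAERS-style three-table CSV data set
#'
#' The VAERS public download splits each report across three CSV tables keyed
#' by the report identifier: a Data table (one row per report: receipt date,
#' sex, age, ...), a Vaccine table (one row per administered vaccine) and a
#' Symptom table (one row per reported symptom term). This joins them into one
#' normalized \code{ReportSet}: one report per distinct identifier in the Data
#' table, with vaccine and symptom sets aggregated by the join. Reports with
#' no vaccine or no symptom rows are retained (with empty sets) so that total
#' report counts, the denominators of the reporting-ratio statistics, are
#' preserved.
#'
#' Receipt dates are parsed as MM/DD/YYYY and the reporting year is taken from
#' them; rows whose date does not parse keep the report with a missing year
#' (a message reports the tally).
#'
#' @param dataPath,vaccinePath,symptomPath paths to the three CSV files.
#' @param idColumn report-identifier column name shared by all three tables.
#' @param dateColumn received-date column in the Data table.
#' @param sexColumn,ageColumn optional demographic columns in the Data table
#'   (absent columns yield sex U / age NA).
#' @param vaccineColumn vaccine-type column in the Vaccine table.
#' @param symptomColumn symptom-term column in the Symptom table.
#' @return a \code{\linkS4class{ReportSet}}.
#' @examples
#' dir <- system.file("extdata", "tiny3", package = "vaersnet")
#' rs <- readReports(file.path(dir, "DATA.csv"),
#'                   file.path(dir, "VACCINE.csv"),
#'                   file.path(dir, "SYMPTOMS.csv"))
#' rs
#' @export
readReports <- function(dataPath, vaccinePath, symptomPath,
                        idColumn = "VAERS_ID", dateColumn = "RECVDATE",
                        sexColumn = "SEX", ageColumn = "AGE_YRS",
                        vaccineColumn = "VAX_TYPE",
                        symptomColumn = "SYMPTOM") {
  dat <- .readCsvTable(dataPath, "Data")
  vax <- .readCsvTable(vaccinePath, "Vaccine")
  sym <- .readCsvTable(symptomPath, "Symptom")
  .requireColumns(dat, c(idColumn, dateColumn), "Data", dataPath)
  .requireColumns(vax, c(idColumn, vaccineColumn), "Vaccine", vaccinePath)
  .requireColumns(sym, c(idColumn, symptomColumn), "Symptom", symptomPath)

  ids <- as.character(dat[[idColumn]])
  keep <- !duplicated(ids)
  dat <- dat[keep, , drop = FALSE]
  ids <- ids[keep]

  dates <- as.Date(trimws(as.character(dat[[dateColumn]])), format = "%m/%d/%Y")
  year <- as.integer(format(dates, "%Y"))
  nbad <- sum(is.na(year))
  if (nbad > 0) {
    message(sprintf("readReports: %d report(s) with unparseable received date; year set to NA",
                    nbad))
  }

  sex <- if (sexColumn %in% names(dat)) dat[[sexColumn]] else rep(NA, nrow(dat))
  age <- if (ageColumn %in% names(dat)) {
    suppressWarnings(as.numeric(dat[[ageColumn]]))
  } else {
    rep(NA_real_, nrow(dat))
  }
  age[!is.na(age) & age < 0] <- NA_real_

  gather <- function(tab, valueColumn) {
    v <- trimws(as.character(tab[[valueColumn]]))
    id <- as.character(tab[[idColumn]])
    ok <- !is.na(v) & nzchar(v) & id %in% ids
    split(v[ok], factor(id[ok], levels = ids))
  }
  vaccines <- gather(vax, vaccineColumn)
  symptoms <- gather(sym, symptomColumn)

  ReportSet(report_id = ids, year = year, sex = sex, age = age,
            vaccines = vaccines, symptoms = symptoms,
            provenance = sprintf("VAERS-style CSV triplet: %s",
                                 basename(dataPath)))
}

#' Write / read the normalized flat-file form of a ReportSet
#'
#' One CSV row per report with pipe-delimited vaccine and symptom sets;
#' \code{readNormalizedReports(writeReports(x))} is the identity on
#' normalized sets.
#'
#' @param reports a \code{ReportSet}.
#' @param path destination (for write) or source (for read) CSV file.
#' @return \code{writeReports} returns \code{path} invisibly;
#'   \code{readNormalizedReports} returns a \code{ReportSet}.
#' @export
writeReports <- function(reports, path) {
  stopifnot(is(reports, "ReportSet"))
  df <- reports@reports
  flat <- data.frame(report_id = df$report_id, year = df$year, sex = df$sex,
                     age = df$age,
                     vaccines = vapply(df$vaccines, paste, character(1),
                                       collapse = "|"),
                     symptoms = vapply(df$symptoms, paste, character(1),
                                       collapse = "|"),
                     stringsAsFactors = FALSE)
  status <- try(utils::write.csv(flat, path, row.names = FALSE, na = ""),
                silent = TRUE)
  if (inherits(status, "try-error")) {
    .stopf("cannot write reports to '%s'", path)
  }
  invisible(path)
}

#' @rdname writeReports
#' @export
readNormalizedReports <- function(path) {
  if (!file.exists(path)) .stopf("no such file '%s'", path)
  flat <- utils::read.csv(path, stringsAsFactors = FALSE,
                          colClasses = c(report_id = "character",
                                         sex = "character",
                                         vaccines = "character",
                                         symptoms = "character"))
  unsplit <- function(x) {
    lapply(x, function(s) if (is.na(s) || !nzchar(s)) character(0)
                          else strsplit(s, "|", fixed = TRUE)[[1]])
  }
  ReportSet(report_id = flat$report_id,
            year = ifelse(is.na(flat$year), NA_integer_, flat$year),
            sex = flat$sex, age = flat$age,
            vaccines = unsplit(flat$vaccines),
            symptoms = unsplit(flat$symptoms),
            provenance = sprintf("normalized CSV: %s", basename(path)))
}

#' Emit a ReportSet as a VAERS-style three-table CSV triplet
#'
#' Writes DATA.csv, VACCINE.csv and SYMPTOMS.csv under \code{dir} in the
#' dialect \code{\link{readReports}} consumes, so synthetic corpora can
#' exercise the raw-file ingestion path end to end. Years are rendered as a
#' mid-year receipt date (07/01/YYYY); missing years yield an empty date field.
#'
#' @param reports a \code{ReportSet}.
#' @param dir destination directory (created if needed).
#' @return invisible character vector of the three file paths.
#' @export
writeVaersCsv <- function(reports, dir) {
  stopifnot(is(reports, "ReportSet"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  df <- reports@reports
  dat <- data.frame(VAERS_ID = df$report_id,
                    RECVDATE = ifelse(is.na(df$year), "",
                                      sprintf("07/01/%04d", df$year)),
                    SEX = df$sex, AGE_YRS = df$age, stringsAsFactors = FALSE)
  lens <- lengths(df$vaccines)
  vax <- data.frame(VAERS_ID = rep(df$report_id, lens),
                    VAX_TYPE = unlist(df$vaccines, use.names = FALSE),
                    stringsAsFactors = FALSE)
  lens <- lengths(df$symptoms)
  sym <- data.frame(VAERS_ID = rep(df$report_id, lens),
                    SYMPTOM = unlist(df$symptoms, use.names = FALSE),
                    stringsAsFactors = FALSE)
  paths <- file.path(dir, c("DATA.csv", "VACCINE.csv", "SYMPTOMS.csv"))
  utils::write.csv(dat, paths[1], row.names = FALSE, na = "")
  utils::write.csv(vax, paths[2], row.names = FALSE, na = "")
  utils::write.csv(sym, paths[3], row.names = FALSE, na = "")
  invisible(paths)
}
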