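#' @importFrom data.table data.table setnames as.data.table setorder := .N
NULL

# Long-format views of a report table: one row per (report, vaccine),
# (report, symptom) and report metadata. Sets are already deduplicated at
# ReportSet construction, so each row is a distinct (report, term) incidence.
.longTables <- function(df) {
  v <- data.table::data.table(
    rid = rep(df$report_id, lengths(df$vaccines)),
    vaccine = unlist(df$vaccines, use.names = FALSE))
  s <- data.table::data.table(
    rid = rep(df$report_id, lengths(df$symptoms)),
    symptom = unlist(df$symptoms, use.names = FALSE))
  meta <- data.table::data.table(rid = df$report_id, year = df$year,
                                 sex = df$sex)
  list(v = v, s = s, meta = meta)
}

#' Count vaccine-symptom pair occurrences with all PRR denominators
#'
#' Enumerates every distinct (vaccine, symptom) pair co-occurring in at least
#' one report — a report listing j vaccines and k symptoms contributes to all
#' j x k pairs, once each — and tallies, per pair: total co-report count,
#' per-year counts and per-sex (F/M) counts. Alongside, it captures the
#' denominator context needed by the reporting-ratio statistics: for the
#' overall corpus, each year and each sex, the number of reports listing each
#' vaccine, the number containing each symptom, and the total number of
#' reports (reports with empty vaccine or symptom sets still count toward the
#' totals).
#'
#' @param reports a non-empty \code{\linkS4class{ReportSet}}.
#' @return an \code{\linkS4class{AssociationSet}} with counts and context;
#'   PRRs are not yet computed (see \code{\link{computePrr}}).
#' @examples
#' a <- countPairs(makeFixture("tiny3"))
#' associationRecords(a)
#' @export
countPairs <- function(reports) {
  stopifnot(is(reports, "ReportSet"))
  df <- reports@reports
  if (nrow(df) == 0) .stopf("countPairs: empty ReportSet")
  lt <- .longTables(df)
  rid <- vaccine <- symptom <- sex <- year <- N <- NULL  # NSE bindings

  pairs <- merge(lt$v, lt$s, by = "rid", allow.cartesian = TRUE)
  pairs <- merge(pairs, lt$meta, by = "rid")

  rec <- pairs[, list(
    nTotal = .N,
    nF = sum(sex == "F"),
    nM = sum(sex == "M")), by = c("vaccine", "symptom")]
  data.table::setorder(rec, vaccine, symptom)

  yearly <- pairs[!is.na(year), list(n = .N),
                  by = c("vaccine", "symptom", "year")]
  data.table::setorder(yearly, vaccine, symptom, year)

  vm <- merge(lt$v, lt$meta, by = "rid")
  sm <- merge(lt$s, lt$meta, by = "rid")
  tallies <- function(dt, col) {
    list(
      overall = {
        x <- dt[, .N, by = col]
        stats::setNames(x$N, x[[col]])
      },
      byYear = as.data.frame(dt[!is.na(year), .N, by = c(col, "year")]),
      bySex = as.data.frame(dt[sex %in% c("F", "M"), .N, by = c(col, "sex")]))
  }
  context <- list(
    total = nrow(df),
    totalByYear = {
      y <- df$year[!is.na(df$year)]
      tab <- table(y)
      stats::setNames(as.integer(tab), names(tab))
    },
    totalBySex = c(F = sum(df$sex == "F"), M = sum(df$sex == "M"),
                   U = sum(df$sex == "U")),
    vaccine = tallies(vm, "vaccine"),
    symptom = tallies(sm, "symptom"))

  new("AssociationSet",
      records = as.data.frame(rec), yearly = as.data.frame(yearly),
      context = context, prrComputed = FALSE)
}

#' The proportional reporting ratio, in closed form
#'
#' Within one stratum of a spontaneous-report corpus, the PRR of a vaccine V
#' and symptom S is \code{(a/b) / (c/d)} where \code{a} = reports for V
#' containing S, \code{b} = all reports for V, \code{c} = all reports
#' containing S and \code{d} = all reports in the stratum. The comparator is
#' the whole stratum (including V's own reports), so a vaccine present in
#' every report has PRR exactly 1 for any symptom. When \code{b}, \code{c} or
#' \code{d} is zero the ratio is undefined and returned as \code{NA} — a
#' flagged missing value, never 0 or Inf.
#'
#' @param a,b,c,d counts as above (vectorized).
#' @return numeric vector of PRR values with \code{NA} for undefined entries.
#' @examples
#' prr(4, 10, 20, 100)   # 2
#' @export
prr <- function(a, b, c, d) {
  stopifnot(all(a >= 0), all(b >= 0, na.rm = TRUE),
            all(c >= 0, na.rm = TRUE), all(d >= 0, na.rm = TRUE))
  out <- (a / b) / (c / d)
  undef <- is.na(b) | is.na(c) | is.na(d) | b == 0 | c == 0 | d == 0
  out[undef] <- NA_real_
  out
}

#' Compute overall, yearly and sex-specific PRRs for every pair
#'
#' Fills the PRR columns of an \code{AssociationSet} from its stored
#' denominator context, one value per record per stratum: the overall corpus,
#' each reporting year (numerators and denominators restricted to that
#' year's reports) and each sex (restricted to F or M reports; reports of
#' unknown sex contribute to the overall statistics only).
#'
#' @param assoc an \code{\linkS4class{AssociationSet}} from
#'   \code{\link{countPairs}}.
#' @return the \code{AssociationSet} with \code{prrOverall}, \code{prrF},
#'   \code{prrM} and yearly \code{prr} columns filled.
#' @export
computePrr <- function(assoc) {
  stopifnot(is(assoc, "AssociationSet"))
  rec <- assoc@records
  ctx <- assoc@context
  lookup <- function(tab, keys) {
    out <- tab[keys]
    out[is.na(out)] <- 0
    unname(out)
  }
  bOverall <- lookup(ctx$vaccine$overall, rec$vaccine)
  cOverall <- lookup(ctx$symptom$overall, rec$symptom)
  rec$prrOverall <- prr(rec$nTotal, bOverall, cOverall, ctx$total)

  sexCounts <- function(tab, col, keys, sexValue) {
    sub <- tab[tab$sex == sexValue, ]
    m <- stats::setNames(sub$N, sub[[col]])
    lookup(m, keys)
  }
  for (sx in c("F", "M")) {
    aVal <- if (sx == "F") rec$nF else rec$nM
    bVal <- sexCounts(ctx$vaccine$bySex, "vaccine", rec$vaccine, sx)
    cVal <- sexCounts(ctx$symptom$bySex, "symptom", rec$symptom, sx)
    dVal <- unname(ctx$totalBySex[sx])
    rec[[paste0("prr", sx)]] <- prr(aVal, bVal, cVal, rep(dVal, nrow(rec)))
  }

  yr <- assoc@yearly
  if (nrow(yr) > 0) {
    keyOf <- function(x, y) paste(x, y, sep = "\r")
    vb <- ctx$vaccine$byYear
    sb <- ctx$symptom$byYear
    bMap <- stats::setNames(vb$N, keyOf(vb$vaccine, vb$year))
    cMap <- stats::setNames(sb$N, keyOf(sb$symptom, sb$year))
    dMap <- ctx$totalByYear
    bVal <- lookup(bMap, keyOf(yr$vaccine, yr$year))
    cVal <- lookup(cMap, keyOf(yr$symptom, yr$year))
    dVal <- lookup(dMap, as.character(yr$year))
    yr$prr <- prr(yr$n, bVal, cVal, dVal)
  }

  methods::initialize(assoc, records = rec, yearly = yr, prrComputed = TRUE)
}

# Resolve a user-facing stratum spec ("overall", "F"/"M", a year) to
# a type tag plus value.
.resolveStratum <- function(stratum) {
  s <- as.character(stratum)
  if (identical(s, "overall")) return(list(type = "overall"))
  if (s %in% c("F", "M")) return(list(type = "sex", sex = s))
  yr <- suppressWarnings(as.integer(s))
  if (!is.na(yr)) return(list(type = "year", year = yr))
  .stopf("unknown stratum '%s' (expected 'overall', 'F', 'M' or a year)", s)
}

#' Filter the disproportionally reported associations of one stratum
#'
#' Keeps (vaccine, symptom) pairs whose PRR in the requested stratum is
#' strictly greater than the threshold; pairs with an undefined PRR are
#' dropped.
#'
#' @param assoc an \code{AssociationSet} with PRRs computed.
#' @param stratum \code{"overall"}, \code{"F"}, \code{"M"} or a year.
#' @param threshold positive significance cutoff (default 1, strict).
#' @return data.frame with columns \code{vaccine}, \code{symptom}, \code{prr}.
#' @export
significantAssociations <- function(assoc, stratum = "overall",
                                    threshold = 1) {
  stopifnot(is(assoc, "AssociationSet"))
  if (!assoc@prrComputed) .stopf("run computePrr() first")
  if (!is.numeric(threshold) || threshold <= 0) {
    .stopf("threshold must be positive")
  }
  st <- .resolveStratum(stratum)
  out <- switch(st$type,
    overall = data.frame(vaccine = assoc@records$vaccine,
                         symptom = assoc@records$symptom,
                         prr = assoc@records$prrOverall,
                         stringsAsFactors = FALSE),
    sex = data.frame(vaccine = assoc@records$vaccine,
                     symptom = assoc@records$symptom,
                     prr = assoc@records[[paste0("prr", st$sex)]],
                     stringsAsFactors = FALSE),
    year = {
      yr <- assoc@yearly[assoc@yearly$year == st$year, ]
      data.frame(vaccine = yr$vaccine, symptom = yr$symptom, prr = yr$prr,
                 stringsAsFactors = FALSE)
    })
  out <- out[!is.na(out$prr) & out$prr > threshold, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Demographic distribution of the reports containing one pair
#'
#' Counts the reports containing both the vaccine and the symptom, grouped by
#' sex (F/M/U) and by age group, in total and per reporting year. The default
#' age bins are the standard vaccine-surveillance groups: under 2, 2-17,
#' 18-64, 65 and over, plus "unknown" for missing ages.
#'
#' @param reports a \code{ReportSet}.
#' @param vaccine,symptom the pair of interest.
#' @param ageBreaks increasing numeric cut points (left-closed bins, the last
#'   extending to infinity).
#' @param ageLabels labels for the bins, one fewer than breaks has elements
#'   plus the implicit top bin.
#' @return a \code{\linkS4class{DemographicDistribution}}.
#' @export
demographicDistribution <- function(reports, vaccine, symptom,
                                    ageBreaks = c(0, 2, 18, 65, Inf),
                                    ageLabels = c("<2", "2-17", "18-64",
                                                  "65+")) {
  stopifnot(is(reports, "ReportSet"), length(ageLabels) ==
              length(ageBreaks) - 1)
  df <- reports@reports
  hit <- vapply(df$vaccines, function(v) vaccine %in% v, logical(1)) &
         vapply(df$symptoms, function(s) symptom %in% s, logical(1))
  sub <- df[hit, , drop = FALSE]
  grp <- as.character(cut(sub$age, breaks = ageBreaks, labels = ageLabels,
                          right = FALSE, include.lowest = TRUE))
  grp[is.na(grp)] <- "unknown"
  lv <- c(ageLabels, "unknown")
  sexCounts <- vapply(c("F", "M", "U"), function(x) sum(sub$sex == x),
                      integer(1))
  ageCounts <- vapply(lv, function(x) sum(grp == x), integer(1))
  bys <- as.data.frame(table(year = sub$year, sex = factor(sub$sex,
                                                           c("F", "M", "U"))),
                       stringsAsFactors = FALSE)
  bya <- as.data.frame(table(year = sub$year, ageGroup = factor(grp, lv)),
                       stringsAsFactors = FALSE)
  names(bys)[3] <- "n"
  names(bya)[3] <- "n"
  bys$year <- as.integer(bys$year)
  bya$year <- as.integer(bya$year)
  bys <- bys[bys$n > 0, , drop = FALSE]
  bya <- bya[bya$n > 0, , drop = FALSE]
  rownames(bys) <- rownames(bya) <- NULL
  new("DemographicDistribution", vaccine = vaccine, symptom = symptom,
      nTotal = nrow(sub), sexCounts = sexCounts, ageCounts = ageCounts,
      byYearSex = bys, byYearAge = bya)
}

#' Write the association summary table
#'
#' Tab-separated twin of the RDF export: one row per pair with counts and the
#' overall / per-sex PRRs, plus one row per (pair, year) in a companion long
#' block when \code{yearly = TRUE}.
#'
#' @param assoc an \code{AssociationSet} with PRRs computed.
#' @param path output TSV path.
#' @param yearly also write the per-year table to
#'   \code{<path base>_yearly.tsv}.
#' @return invisible vector of the file paths written.
#' @export
writeAssociationTable <- function(assoc, path, yearly = TRUE) {
  stopifnot(is(assoc, "AssociationSet"))
  if (!assoc@prrComputed) .stopf("run computePrr() first")
  utils::write.table(assoc@records, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  paths <- path
  if (yearly) {
    ypath <- paste0(sub("\\.tsv$", "", path), "_yearly.tsv")
    utils::write.table(assoc@yearly, ypath, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    paths <- c(paths, ypath)
  }
  invisible(paths)
}
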