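# Minimal RDF layer: an in-memory triple table with Turtle / N-Triples
# writers and a reader for the subset those writers emit. The vocabulary is
# a small project namespace (prefix vaers:) with predicates hasVaccine,
# hasSymptom, reportCount, hasPRR, prrUndefined, hasStratum, forYear, forSex.

.VAERS_NS <- "http://vaersnet.org/ns/"
.RDF_NS <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#"
.RDFS_NS <- "http://www.w3.org/2000/01/rdf-schema#"
.XSD_NS <- "http://www.w3.org/2001/XMLSchema#"

.assocIRI <- function(vaccine, symptom) {
  paste0(.VAERS_NS, "association/", .percentEncode(vaccine), "_",
         .fnv1a32(symptom))
}

.numLit <- function(x) sprintf("%.17g", x)

#' Convert association records to an RDF graph
#'
#' Every distinct (vaccine, symptom) pair becomes one association resource
#' with a deterministic identifier (percent-encoded vaccine code joined to a
#' 32-bit hash of the symptom term). Each association links to its vaccine
#' and symptom resources (which carry label triples), its total co-report
#' count, and its overall PRR — or an explicit undefined marker when the
#' ratio could not be computed. Yearly and sex-specific PRRs hang off
#' reified stratum nodes carrying a year or sex literal, the stratum
#' co-report count and the stratum PRR (or undefined marker).
#'
#' Per record the construction emits 7 base triples plus 4 per stratum node;
#' vaccine/symptom label triples shared between records are deduplicated at
#' the graph level.
#'
#' @param assoc an \code{\linkS4class{AssociationSet}} with PRRs computed.
#' @return an \code{\linkS4class{AssociationGraph}}.
#' @export
toRdf <- function(assoc) {
  stopifnot(is(assoc, "AssociationSet"))
  if (!assoc@prrComputed) .stopf("run computePrr() first")
  rec <- assoc@records
  if (anyDuplicated(rec[c("vaccine", "symptom")])) {
    .stopf("duplicate (vaccine, symptom) inputs")
  }
  n <- nrow(rec)
  rows <- vector("list", 64)
  nrows <- 0L
  add <- function(s, p, o, type, dt = NA_character_) {
    nrows <<- nrows + 1L
    rows[[nrows]] <<- c(s, p, o, type, dt)
  }
  v <- function(x) paste0(.VAERS_NS, x)
  xsd <- function(x) paste0(.XSD_NS, x)
  prrTriples <- function(subj, value) {
    if (is.na(value)) {
      add(subj, v("prrUndefined"), "true", "literal", xsd("boolean"))
    } else {
      add(subj, v("hasPRR"), .numLit(value), "literal", xsd("double"))
    }
  }
  if (n > 0) {
    for (i in seq_len(n)) {
      aIRI <- .assocIRI(rec$vaccine[i], rec$symptom[i])
      vIRI <- paste0(.VAERS_NS, "vaccine/", .percentEncode(rec$vaccine[i]))
      sIRI <- paste0(.VAERS_NS, "symptom/", .percentEncode(rec$symptom[i]))
      add(aIRI, paste0(.RDF_NS, "type"), v("Association"), "iri")
      add(aIRI, v("hasVaccine"), vIRI, "iri")
      add(aIRI, v("hasSymptom"), sIRI, "iri")
      add(vIRI, paste0(.RDFS_NS, "label"), rec$vaccine[i], "literal")
      add(sIRI, paste0(.RDFS_NS, "label"), rec$symptom[i], "literal")
      add(aIRI, v("reportCount"), as.character(rec$nTotal[i]), "literal",
          xsd("integer"))
      prrTriples(aIRI, rec$prrOverall[i])
      for (sx in c("F", "M")) {
        node <- paste0(aIRI, "/sex/", sx)
        add(aIRI, v("hasStratum"), node, "iri")
        add(node, v("forSex"), sx, "literal")
        add(node, v("reportCount"),
            as.character(if (sx == "F") rec$nF[i] else rec$nM[i]),
            "literal", xsd("integer"))
        prrTriples(node, rec[[paste0("prr", sx)]][i])
      }
    }
    yr <- assoc@yearly
    for (i in seq_len(nrow(yr))) {
      aIRI <- .assocIRI(yr$vaccine[i], yr$symptom[i])
      node <- paste0(aIRI, "/year/", yr$year[i])
      add(aIRI, v("hasStratum"), node, "iri")
      add(node, v("forYear"), as.character(yr$year[i]), "literal",
          xsd("gYear"))
      add(node, v("reportCount"), as.character(yr$n[i]), "literal",
          xsd("integer"))
      prrTriples(node, yr$prr[i])
    }
  }
  triples <- if (nrows > 0) {
    m <- do.call(rbind, rows[seq_len(nrows)])
    unique(data.frame(subject = m[, 1], predicate = m[, 2], object = m[, 3],
                      objectType = m[, 4], datatype = m[, 5],
                      stringsAsFactors = FALSE))
  } else {
    data.frame(subject = character(0), predicate = character(0),
               object = character(0), objectType = character(0),
               datatype = character(0), stringsAsFactors = FALSE)
  }
  rownames(triples) <- NULL
  new("AssociationGraph", triples = triples, namespace = .VAERS_NS)
}

.escapeLit <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub("\"", "\\\"", x, fixed = TRUE)
  x <- gsub("\n", "\\n", x, fixed = TRUE)
  x <- gsub("\r", "\\r", x, fixed = TRUE)
  gsub("\t", "\\t", x, fixed = TRUE)
}

.unescapeLit <- function(x) {
  out <- character(length(x))
  for (i in seq_along(x)) {
    s <- x[i]
    res <- character(0)
    j <- 1
    chars <- strsplit(s, "")[[1]]
    while (j <= length(chars)) {
      ch <- chars[j]
      if (ch == "\\" && j < length(chars)) {
        nxt <- chars[j + 1]
        res <- c(res, switch(nxt, n = "\n", r = "\r", t = "\t",
                             "\"" = "\"", "\\" = "\\", nxt))
        j <- j + 2
      } else {
        res <- c(res, ch)
        j <- j + 1
      }
    }
    out[i] <- paste(res, collapse = "")
  }
  out
}

.tripleLines <- function(triples) {
  obj <- ifelse(triples$objectType == "iri",
                sprintf("<%s>", triples$object),
                ifelse(is.na(triples$datatype),
                       sprintf("\"%s\"", .escapeLit(triples$object)),
                       sprintf("\"%s\"^^<%s>", .escapeLit(triples$object),
                               triples$datatype)))
  sprintf("<%s> <%s> %s .", triples$subject, triples$predicate, obj)
}

#' Canonical N-Triples form of a graph
#'
#' Sorted, deduplicated N-Triples lines: two graphs with the same triple set
#' serialize identically, whatever the construction order.
#'
#' @param graph an \code{AssociationGraph}.
#' @return character vector of N-Triples lines, sorted.
#' @export
canonicalNTriples <- function(graph) {
  stopifnot(is(graph, "AssociationGraph"))
  sort(unique(.tripleLines(graph@triples)), method = "radix")
}

#' Write an RDF graph to file
#'
#' Turtle output declares the project, rdf, rdfs and xsd prefixes and writes
#' one triple per line with prefixed names where possible; N-Triples output
#' is the canonical sorted form.
#'
#' @param graph an \code{AssociationGraph}.
#' @param path output file.
#' @param format \code{"turtle"} or \code{"ntriples"}.
#' @return invisible \code{path}.
#' @export
writeRdf <- function(graph, path, format = c("turtle", "ntriples")) {
  stopifnot(is(graph, "AssociationGraph"))
  format <- match.arg(format)
  if (format == "ntriples") {
    writeLines(canonicalNTriples(graph), path)
    return(invisible(path))
  }
  prefixes <- c(vaers = .VAERS_NS, rdf = .RDF_NS, rdfs = .RDFS_NS,
                xsd = .XSD_NS)
  shorten <- function(iri) {
    for (p in names(prefixes)) {
      ns <- prefixes[[p]]
      hit <- startsWith(iri, ns)
      local <- substring(iri, nchar(ns) + 1)
      ok <- hit & grepl("^[A-Za-z0-9_.%-]*$", local) & nzchar(local)
      iri[ok] <- paste0(p, ":", local[ok])
    }
    ifelse(grepl(":", iri) & !grepl("^[a-z]+://", iri), iri,
           sprintf("<%s>", iri))
  }
  tr <- graph@triples
  obj <- ifelse(tr$objectType == "iri", shorten(tr$object),
                ifelse(is.na(tr$datatype),
                       sprintf("\"%s\"", .escapeLit(tr$object)),
                       sprintf("\"%s\"^^%s", .escapeLit(tr$object),
                               shorten(tr$datatype))))
  lines <- c(sprintf("@prefix %s: <%s> .", names(prefixes), prefixes), "",
             sprintf("%s %s %s .", shorten(tr$subject), shorten(tr$predicate),
                     obj))
  writeLines(lines, path)
  invisible(path)
}

# Parse one term as produced by writeRdf: <iri>, prefix:local, or
# "literal"(^^type)?. Returns list(value, type, datatype).
.parseTerm <- function(term, prefixes) {
  expand <- function(x) {
    if (startsWith(x, "<")) return(sub("^<(.*)>$", "\\1", x))
    m <- regmatches(x, regexec("^([A-Za-z]+):(.*)$", x))[[1]]
    if (length(m) == 3 && m[2] %in% names(prefixes)) {
      return(paste0(prefixes[[m[2]]], m[3]))
    }
    .stopf("cannot parse RDF term '%s'", x)
  }
  if (startsWith(term, "\"")) {
    m <- regmatches(term,
                    regexec("^\"((?:[^\"\\\\]|\\\\.)*)\"(\\^\\^(.+))?$",
                            term))[[1]]
    if (length(m) == 0) .stopf("cannot parse literal '%s'", term)
    dt <- if (nzchar(m[4])) expand(m[4]) else NA_character_
    list(value = .unescapeLit(m[2]), type = "literal", datatype = dt)
  } else {
    list(value = expand(term), type = "iri", datatype = NA_character_)
  }
}

#' Read an RDF graph written by \code{\link{writeRdf}}
#'
#' Parses the line-oriented Turtle and N-Triples dialects this package
#' emits (one triple per line; prefixed names or angle-bracket IRIs; plain
#' or typed literals). Not a general-purpose RDF parser.
#'
#' @param path file produced by \code{writeRdf}.
#' @return an \code{AssociationGraph}.
#' @export
readRdf <- function(path) {
  if (!file.exists(path)) .stopf("no such file '%s'", path)
  lines <- readLines(path, encoding = "UTF-8")
  prefixes <- character(0)
  rows <- list()
  for (ln in lines) {
    ln <- trimws(ln)
    if (!nzchar(ln) || startsWith(ln, "#")) next
    if (startsWith(ln, "@prefix")) {
      m <- regmatches(ln,
                      regexec("^@prefix\\s+([A-Za-z]+):\\s+<([^>]*)>\\s*\\.$",
                              ln))[[1]]
      if (length(m) != 3) .stopf("cannot parse prefix line '%s'", ln)
      prefixes[m[2]] <- m[3]
      next
    }
    body <- sub("\\s*\\.$", "", ln)
    m <- regmatches(body, regexec("^(\\S+)\\s+(\\S+)\\s+(.*)$", body))[[1]]
    if (length(m) != 4) .stopf("cannot parse triple line '%s'", ln)
    s <- .parseTerm(m[2], prefixes)
    p <- .parseTerm(m[3], prefixes)
    o <- .parseTerm(m[4], prefixes)
    rows[[length(rows) + 1L]] <- c(s$value, p$value, o$value, o$type,
                                   o$datatype)
  }
  triples <- if (length(rows) > 0) {
    m <- do.call(rbind, rows)
    unique(data.frame(subject = m[, 1], predicate = m[, 2], object = m[, 3],
                      objectType = m[, 4], datatype = m[, 5],
                      stringsAsFactors = FALSE))
  } else {
    data.frame(subject = character(0), predicate = character(0),
               object = character(0), objectType = character(0),
               datatype = character(0), stringsAsFactors = FALSE)
  }
  rownames(triples) <- NULL
  new("AssociationGraph", triples = triples, namespace = .VAERS_NS)
}

#' Retrieve one association record from an RDF graph
#'
#' Pattern-matches the graph for the association resource of the given
#' (vaccine, symptom) pair and reassembles its record: total and per-stratum
#' co-report counts and PRR values. An absent pair yields \code{NULL} (not
#' an error); a malformed association (missing its vaccine or symptom link
#' or overall PRR statement) raises an integrity error naming the resource.
#'
#' @param graph an \code{AssociationGraph} from \code{\link{toRdf}} (or read
#'   back from file).
#' @param vaccine,symptom the pair to look up.
#' @return list with elements \code{vaccine}, \code{symptom}, \code{nTotal},
#'   \code{prrOverall}, \code{nF}, \code{nM}, \code{prrF}, \code{prrM} and a
#'   \code{yearly} data.frame (\code{year}, \code{n}, \code{prr}), or
#'   \code{NULL} when the pair is absent.
#' @export
queryAssociation <- function(graph, vaccine, symptom) {
  stopifnot(is(graph, "AssociationGraph"))
  tr <- graph@triples
  aIRI <- .assocIRI(vaccine, symptom)
  mine <- tr[tr$subject == aIRI, , drop = FALSE]
  if (nrow(mine) == 0) return(NULL)
  v <- function(x) paste0(.VAERS_NS, x)
  getOne <- function(sub, pred) {
    hit <- sub$object[sub$predicate == pred]
    if (length(hit) == 1) hit else NA_character_
  }
  if (is.na(getOne(mine, v("hasVaccine"))) ||
      is.na(getOne(mine, v("hasSymptom")))) {
    .stopf("malformed association <%s>: missing vaccine or symptom link", aIRI)
  }
  readPrr <- function(sub, iri) {
    val <- getOne(sub, v("hasPRR"))
    if (!is.na(val)) return(as.numeric(val))
    if (!is.na(getOne(sub, v("prrUndefined")))) return(NA_real_)
    .stopf("malformed association <%s>: no PRR statement", iri)
  }
  out <- list(vaccine = vaccine, symptom = symptom,
              nTotal = as.integer(getOne(mine, v("reportCount"))),
              prrOverall = readPrr(mine, aIRI))
  strata <- mine$object[mine$predicate == v("hasStratum")]
  yearly <- list()
  for (node in strata) {
    sub <- tr[tr$subject == node, , drop = FALSE]
    sx <- getOne(sub, v("forSex"))
    yr <- getOne(sub, v("forYear"))
    nCount <- as.integer(getOne(sub, v("reportCount")))
    if (!is.na(sx)) {
      out[[paste0("n", sx)]] <- nCount
      out[[paste0("prr", sx)]] <- readPrr(sub, node)
    } else if (!is.na(yr)) {
      yearly[[length(yearly) + 1L]] <- data.frame(
        year = as.integer(yr), n = nCount, prr = readPrr(sub, node))
    }
  }
  out$yearly <- if (length(yearly) > 0) {
    y <- do.call(rbind, yearly)
    y <- y[order(y$year), , drop = FALSE]
    rownames(y) <- NULL
    y
  } else {
    data.frame(year = integer(0), n = integer(0), prr = numeric(0))
  }
  out
}
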