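# Independent oracles and small random-instance generators used across the
# suite. These deliberately recompute quantities by brute force (exhaustive
# report scans, Floyd-Warshall, explicit incidence vectors) so they share no
# code with the implementation paths they check.

# PRR by exhaustive report scanning within a stratum.
oraclePrr <- function(reports, vaccine, symptom, stratum = "overall") {
  df <- reportTable(reports)
  sel <- if (identical(stratum, "overall")) {
    rep(TRUE, nrow(df))
  } else if (stratum %in% c("F", "M")) {
    df$sex == stratum
  } else {
    !is.na(df$year) & df$year == as.integer(stratum)
  }
  hasV <- vapply(df$vaccines, function(v) vaccine %in% v, logical(1))
  hasS <- vapply(df$symptoms, function(s) symptom %in% s, logical(1))
  a <- sum(sel & hasV & hasS)
  b <- sum(sel & hasV)
  cc <- sum(sel & hasS)
  d <- sum(sel)
  if (b == 0 || cc == 0 || d == 0) NA_real_ else (a / b) / (cc / d)
}

# All-pairs shortest paths by vectorized Floyd-Warshall on an edge list.
fwPathStats <- function(edges) {
  nodes <- sort(unique(c(edges$vaccine, edges$symptom)))
  n <- length(nodes)
  D <- matrix(Inf, n, n, dimnames = list(nodes, nodes))
  diag(D) <- 0
  i <- match(edges$vaccine, nodes)
  j <- match(edges$symptom, nodes)
  D[cbind(i, j)] <- 1
  D[cbind(j, i)] <- 1
  for (k in seq_len(n)) {
    D <- pmin(D, outer(D[, k], D[k, ], "+"))
  }
  vals <- D[upper.tri(D)]
  vals <- vals[is.finite(vals)]
  list(lengths = sort(vals), apl = mean(vals), diameter = max(vals))
}

# Random bipartite edge list: each of nv x na possible links present with
# probability p; isolated nodes drop out by construction of buildNetwork.
randomBipartiteEdges <- function(nv, na, p) {
  grid <- expand.grid(vaccine = sprintf("V%03d", seq_len(nv)),
                      symptom = sprintf("A%03d", seq_len(na)),
                      stringsAsFactors = FALSE)
  keep <- stats::runif(nrow(grid)) < p
  if (!any(keep)) keep[sample.int(nrow(grid), 1)] <- TRUE
  grid[keep, , drop = FALSE]
}

# Small random ReportSet for property tests (a few vaccines/symptoms, two
# years, all three sex codes).
randomReportSet <- function(n = 100, nv = 4, ns = 6) {
  vcodes <- sprintf("VAC%d", seq_len(nv))
  scodes <- sprintf("SYM%d", seq_len(ns))
  vaccines <- lapply(seq_len(n), function(i) {
    sample(vcodes, sample(0:2, 1, prob = c(0.1, 0.6, 0.3)))
  })
  symptoms <- lapply(seq_len(n), function(i) {
    sample(scodes, sample(0:3, 1, prob = c(0.15, 0.45, 0.3, 0.1)))
  })
  ReportSet(report_id = sprintf("RR%04d", seq_len(n)),
            year = sample(c(2001L, 2002L, NA), n, replace = TRUE,
                          prob = c(0.45, 0.45, 0.1)),
            sex = sample(c("F", "M", "U"), n, replace = TRUE),
            age = ifelse(stats::runif(n) < 0.1, NA, stats::runif(n, 0, 90)),
            vaccines = vaccines, symptoms = symptoms,
            provenance = "random property-test set")
}

# Binary incidence vectors with prescribed degrees and overlap, for checking
# the association index against the textbook Pearson correlation.
incidencePair <- function(degA, degB, shared, nY) {
  a <- rep(0L, nY)
  b <- rep(0L, nY)
  a[seq_len(degA)] <- 1L
  if (shared > 0) b[seq_len(shared)] <- 1L
  extra <- degB - shared
  if (extra > 0) b[degA + seq_len(extra)] <- 1L
  list(a = a, b = b)
}
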