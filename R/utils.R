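# Internal helpers shared across modules.

#' Round half-up to a fixed number of decimals
#'
#' Base \code{round()} rounds half to even; surveillance tables in this field
#' are conventionally printed with half-up rounding, which this helper applies.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half-up.
#' @export
roundHalfUp <- function(x, digits = 2L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Trim whitespace, drop empties, dedupe and sort -- canonical form for
# vaccine-code / symptom-term sets.
.normalizeTerms <- function(x) {
  x <- trimws(as.character(x))
  x <- x[!is.na(x) & nzchar(x)]
  sort(unique(x))
}

# Vectorized version of .normalizeTerms over a list of term vectors:
# one pass over the flattened values instead of a loop over reports.
.normalizeTermList <- function(lst) {
  lens <- lengths(lst)
  vals <- unlist(lst, use.names = FALSE)
  if (is.null(vals) || length(vals) == 0) {
    return(rep(list(character(0)), length(lst)))
  }
  vals <- trimws(as.character(vals))
  grp <- rep.int(seq_along(lst), lens)
  keep <- !is.na(vals) & nzchar(vals)
  vals <- vals[keep]
  grp <- grp[keep]
  o <- order(grp, vals, method = "radix")
  grp <- grp[o]
  vals <- vals[o]
  n <- length(grp)
  if (n > 1) {
    dup <- c(FALSE, grp[-1] == grp[-n] & vals[-1] == vals[-n])
    grp <- grp[!dup]
    vals <- vals[!dup]
  }
  out <- rep(list(character(0)), length(lst))
  if (length(grp) > 0) out[unique(grp)] <- unname(split(vals, grp))
  out
}

# Map arbitrary sex codes onto the F/M/U enum (case-insensitive; anything
# unrecognized, including NA and blank, becomes U).
.normalizeSex <- function(x) {
  x <- toupper(trimws(as.character(x)))
  out <- rep("U", length(x))
  out[!is.na(x) & x == "F"] <- "F"
  out[!is.na(x) & x == "M"] <- "M"
  out
}

# 32-bit FNV-1a hash of a character vector, returned as 8 hex digits.
# Used for stable association identifiers; implemented here because no
# general-purpose digest function ships with base R.
.fnv1a32 <- function(x) {
  vapply(x, function(s) {
    h <- 2166136261
    for (byte in as.integer(charToRaw(enc2utf8(s)))) {
      low <- h %% 256
      h <- h - low + bitwXor(as.integer(low), byte)  # byte < 256: XOR only low 8 bits
      # 32-bit modular multiply split into 16-bit halves (doubles stay exact)
      h1 <- h %/% 65536
      h0 <- h %% 65536
      h <- (h0 * 16777619 + ((h1 * 16777619) %% 65536) * 65536) %% 2^32
    }
    sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
  }, character(1), USE.NAMES = FALSE)
}

# Percent-encode everything outside [A-Za-z0-9._~-] (RFC 3986 unreserved).
.percentEncode <- function(x) {
  vapply(x, function(s) {
    bytes <- charToRaw(enc2utf8(s))
    chars <- rawToChar(bytes, multiple = TRUE)
    ok <- grepl("^[A-Za-z0-9._~-]$", chars)
    chars[!ok] <- sprintf("%%%02X", as.integer(bytes[!ok]))
    paste(chars, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Seed helper: all exported stochastic entry points funnel through this so
# results are reproducible across platforms and R versions.
.withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed), kind = "Mersenne-Twister",
             normal.kind = "Inversion", sample.kind = "Rejection")
  }
  force(expr)
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
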