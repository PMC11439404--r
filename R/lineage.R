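#' @keywords internal
"_PACKAGE"

# Canonical GTDB rank order and prefixes. A lineage string is rank-prefixed
# labels joined by "; ", truncated at any depth >= 0 (depth 0 = root,
# written as the empty string).

.RANKS <- c("domain", "phylum", "class", "order", "family", "genus", "species")
.PREFIXES <- c("d__", "p__", "c__", "o__", "f__", "g__", "s__")
.LINEAGE_SEP <- "; "

#' Parse a GTDB-style lineage string
#'
#' Splits a `"; "`-separated lineage such as
#' `"d__Bacteria; p__Acidobacteriota"` into its rank labels and validates
#' that rank prefixes (`d__`, `p__`, `c__`, `o__`, `f__`, `g__`, `s__`)
#' appear in canonical order with no gaps and that no label is empty after
#' its prefix. The empty string denotes the root (an entirely unassigned
#' lineage).
#'
#' @param x a single lineage string.
#' @return a character vector of prefixed labels (length 0 to 7) with class
#'   `"lineage"`, named by rank.
#' @examples
#' parse_lineage("d__Bacteria; p__Pseudomonadota")
#' lineage_depth(parse_lineage(""))
#' @export
parse_lineage <- function(x) {
  if (!is.character(x) || length(x) != 1L || is.na(x)) {
    stop("lineage must be a single non-NA character string", call. = FALSE)
  }
  x <- trimws(x)
  if (x == "") {
    out <- character(0)
    class(out) <- "lineage"
    return(out)
  }
  parts <- trimws(strsplit(x, ";", fixed = TRUE)[[1L]])
  n <- length(parts)
  if (n > 7L) {
    stop("lineage has more than 7 ranks: ", x, call. = FALSE)
  }
  for (i in seq_len(n)) {
    pre <- substr(parts[i], 1L, 3L)
    if (pre != .PREFIXES[i]) {
      stop(sprintf(
        "unknown or out-of-order rank prefix %s at position %d (expected %s) in: %s",
        sQuote(pre), i, sQuote(.PREFIXES[i]), x
      ), call. = FALSE)
    }
    if (nchar(parts[i]) <= 3L) {
      stop(sprintf("empty %s label in lineage: %s", .RANKS[i], x),
        call. = FALSE
      )
    }
  }
  names(parts) <- .RANKS[seq_len(n)]
  class(parts) <- "lineage"
  parts
}

#' Format a lineage back to its string form
#'
#' Inverse of [parse_lineage()]: `parse_lineage(format_lineage(l))` is
#' identical to `l`.
#'
#' @param l a `lineage` object (or bare character vector of prefixed labels).
#' @return a single string; the empty string for a zero-depth lineage.
#' @export
format_lineage <- function(l) {
  paste(unclass(l), collapse = .LINEAGE_SEP)
}

#' @export
format.lineage <- function(x, ...) format_lineage(x)

#' @export
print.lineage <- function(x, ...) {
  if (length(x) == 0L) {
    cat("<lineage: root>\n")
  } else {
    cat("<lineage depth", length(x), ">", format_lineage(x), "\n")
  }
  invisible(x)
}

#' Depth of a lineage
#'
#' @param l a `lineage`, or a character vector of lineage strings
#'   (vectorized over strings).
#' @return integer depth(s) in 0..7 (0 = root, 7 = species).
#' @export
lineage_depth <- function(l) {
  if (inherits(l, "lineage")) {
    return(length(l))
  }
  vapply(l, function(s) length(parse_lineage(s)), integer(1), USE.NAMES = FALSE)
}

# Depth without re-validating each string; callers guarantee prior validation.
.fast_depth <- function(strings) {
  ifelse(
    trimws(strings) == "", 0L,
    lengths(strsplit(strings, ";", fixed = TRUE))
  )
}

# All ancestor strings of a validated lineage string, from depth 1 to its own
# depth (excludes the root).
.lineage_prefixes <- function(s) {
  parts <- unclass(parse_lineage(s))
  vapply(
    seq_along(parts),
    function(i) paste(parts[seq_len(i)], collapse = .LINEAGE_SEP),
    character(1)
  )
}

# Truncate a validated lineage string to a given depth.
.truncate_lineage <- function(s, depth) {
  if (depth <= 0L) {
    return("")
  }
  parts <- unclass(parse_lineage(s))
  paste(parts[seq_len(min(depth, length(parts)))], collapse = .LINEAGE_SEP)
}
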