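# Genome-size-annotated taxonomy: corrected per-genome sizes -> species AGS ->
# level-wise mean propagation up the rank tree. Sizes are held in base pairs
# as doubles throughout; Mbp is a display unit only.

#' Correct an assembly size for completeness and contamination
#'
#' Removes the estimated contaminant bases and rescales for incompleteness:
#' `corrected = assembly_size * (1 - contamination/100) / (completeness/100)`.
#' The correction first strips the fraction of the assembly attributed to
#' contamination, then divides by the recovered fraction of the genome so the
#' result estimates the true genome size.
#'
#' @param assembly_size assembly size(s) in base pairs, > 0.
#' @param completeness completeness percent in (0, 100].
#' @param contamination contamination percent in [0, 100).
#' @return corrected genome size(s) in base pairs. Vectorized; arguments are
#'   recycled by the usual rules.
#' @examples
#' corrected_genome_size(3e6, 100, 0) # 3 Mbp unchanged
#' corrected_genome_size(4e6, 80, 10) # 4.5 Mbp
#' @export
corrected_genome_size <- function(assembly_size, completeness, contamination) {
  if (any(!is.finite(assembly_size)) || any(assembly_size <= 0)) {
    stop("assembly_size must be finite and > 0", call. = FALSE)
  }
  if (any(!is.finite(completeness)) || any(completeness <= 0) ||
    any(completeness > 100)) {
    stop("completeness must be in (0, 100]", call. = FALSE)
  }
  if (any(!is.finite(contamination)) || any(contamination < 0)) {
    stop("contamination must be >= 0", call. = FALSE)
  }
  if (any(contamination >= 100)) {
    stop("contamination >= 100% would yield a non-positive size", call. = FALSE)
  }
  assembly_size * (1 - contamination / 100) / (completeness / 100)
}

#' Average genome size of one species from its member genomes
#'
#' The species AGS is the arithmetic mean of the completeness/contamination-
#' corrected sizes of all genomes assigned to the species.
#'
#' @param genomes a data.frame with columns `lineage` (identical 7-rank
#'   strings), `assembly_size`, `completeness`, `contamination`.
#' @return the species AGS in base pairs.
#' @export
species_ags <- function(genomes) {
  if (!is.data.frame(genomes) || nrow(genomes) == 0L) {
    stop("genomes must be a non-empty data.frame", call. = FALSE)
  }
  if (length(unique(genomes$lineage)) != 1L) {
    stop("all genomes must share one species lineage", call. = FALSE)
  }
  if (lineage_depth(parse_lineage(genomes$lineage[1L])) != 7L) {
    stop("species lineage must be resolved to all 7 ranks", call. = FALSE)
  }
  mean(corrected_genome_size(
    genomes$assembly_size, genomes$completeness, genomes$contamination
  ))
}

#' Read a genome metadata table
#'
#' Tab-delimited with a header: `accession`, `lineage` (7-rank GTDB-prefixed
#' string), `assembly_size` (bp), `completeness` (%), `contamination` (%).
#'
#' @param path path to the TSV file.
#' @return a validated data.frame of genome records.
#' @export
read_genome_table <- function(path) {
  if (!file.exists(path)) {
    stop("genome table not found: ", path, call. = FALSE)
  }
  df <- utils::read.delim(path,
    sep = "\t", quote = "", stringsAsFactors = FALSE,
    colClasses = "character"
  )
  need <- c("accession", "lineage", "assembly_size", "completeness", "contamination")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0L) {
    stop("genome table missing column(s): ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  df$assembly_size <- as.numeric(df$assembly_size)
  df$completeness <- as.numeric(df$completeness)
  df$contamination <- as.numeric(df$contamination)
  validate_genome_records(df)
  df[need]
}

#' Validate a data.frame of genome records
#'
#' Checks the per-record invariants: positive assembly size, completeness in
#' (0, 100], contamination in [0, 100), and a full 7-rank lineage.
#'
#' @param records data.frame with genome-record columns.
#' @return the records, invisibly, if valid; otherwise an error.
#' @export
validate_genome_records <- function(records) {
  if (!is.data.frame(records) || nrow(records) == 0L) {
    stop("need at least one genome record", call. = FALSE)
  }
  for (i in seq_len(nrow(records))) {
    line <- function(msg) {
      stop(sprintf("genome record %d (%s): %s", i, records$accession[i], msg),
        call. = FALSE
      )
    }
    if (!is.finite(records$assembly_size[i]) || records$assembly_size[i] <= 0) {
      line("assembly_size must be > 0")
    }
    if (!is.finite(records$completeness[i]) ||
      records$completeness[i] <= 0 || records$completeness[i] > 100) {
      line("completeness must be in (0, 100]")
    }
    if (!is.finite(records$contamination[i]) || records$contamination[i] < 0 ||
      records$contamination[i] >= 100) {
      line("contamination must be in [0, 100)")
    }
    l <- tryCatch(parse_lineage(records$lineage[i]), error = function(e) line(conditionMessage(e)))
    if (length(l) != 7L) line("lineage must have all 7 ranks")
  }
  invisible(records)
}

#' Build a genome-size-annotated taxonomy
#'
#' Computes the AGS of every species as the mean corrected size of its member
#' genomes, then propagates sizes up the rank tree: the AGS of every internal
#' node is the unweighted arithmetic mean of its immediate children's AGS
#' (e.g. a family's AGS is the mean over its genera, not over all descendant
#' species), and the root AGS is the mean over domains.
#'
#' @param records genome records, as from [read_genome_table()].
#' @return a `size_taxonomy` object: a node table (lineage, rank, name,
#'   parent, depth, ags) plus a fast lookup index.
#' @examples
#' g <- data.frame(
#'   accession = c("G1", "G2"),
#'   lineage = c(
#'     "d__Bacteria; p__P; c__C; o__O; f__F; g__G; s__G sp1",
#'     "d__Bacteria; p__P; c__C; o__O; f__F; g__G; s__G sp2"
#'   ),
#'   assembly_size = c(3e6, 5e6), completeness = c(100, 100),
#'   contamination = c(0, 0)
#' )
#' tax <- build_taxonomy(g)
#' lookup_ags(tax, "d__Bacteria; p__P; c__C; o__O; f__F; g__G")
#' @export
build_taxonomy <- function(records) {
  validate_genome_records(records)
  corrected <- corrected_genome_size(
    records$assembly_size, records$completeness, records$contamination
  )
  sp_ags <- tapply(corrected, records$lineage, mean)
  species <- names(sp_ags)

  # Enumerate every node path present in the records.
  all_paths <- unique(unlist(lapply(species, .lineage_prefixes)))
  depth <- .fast_depth(all_paths)
  parent <- vapply(
    seq_along(all_paths),
    function(i) .truncate_lineage(all_paths[i], depth[i] - 1L),
    character(1)
  )
  name <- vapply(
    strsplit(all_paths, .LINEAGE_SEP, fixed = TRUE),
    function(p) p[length(p)], character(1)
  )

  # Same named taxon at one rank must have a single parent path.
  key <- paste(depth, name, sep = "\r")
  n_parents <- tapply(parent, key, function(p) length(unique(p)))
  if (any(n_parents > 1L)) {
    bad <- sub("^[0-9]+\r", "", names(n_parents)[n_parents > 1L][1L])
    stop("inconsistent parentage: taxon ", sQuote(bad),
      " appears under more than one parent at the same rank",
      call. = FALSE
    )
  }

  nodes <- data.frame(
    lineage = all_paths, rank = .RANKS[depth], name = name,
    parent = parent, depth = depth, ags = NA_real_,
    stringsAsFactors = FALSE
  )
  nodes$ags[match(species, nodes$lineage)] <- as.numeric(sp_ags)

  # Level-wise propagation: each internal node is the mean of its children.
  for (d in 6:1) {
    at_d <- which(nodes$depth == d)
    kids <- nodes[nodes$depth == d + 1L, ]
    child_mean <- tapply(kids$ags, kids$parent, mean)
    has_kids <- nodes$lineage[at_d] %in% names(child_mean)
    nodes$ags[at_d[has_kids]] <-
      as.numeric(child_mean[nodes$lineage[at_d[has_kids]]])
  }
  root_ags <- mean(nodes$ags[nodes$depth == 1L])
  nodes <- rbind(
    data.frame(
      lineage = "", rank = "root", name = "root", parent = NA_character_,
      depth = 0L, ags = root_ags, stringsAsFactors = FALSE
    ),
    nodes[order(nodes$depth, nodes$lineage), ]
  )
  rownames(nodes) <- NULL

  idx <- nodes$ags[nodes$depth > 0L]
  names(idx) <- nodes$lineage[nodes$depth > 0L]
  structure(list(nodes = nodes, index = idx, root_ags = root_ags),
    class = "size_taxonomy"
  )
}

#' @export
print.size_taxonomy <- function(x, ...) {
  n <- x$nodes
  cat("Genome-size taxonomy:",
    sum(n$rank == "species"), "species,",
    nrow(n) - 1L, "taxa;",
    sprintf("root AGS %.1f Mbp\n", n$ags[n$depth == 0L] / 1e6)
  )
  invisible(x)
}

#' Look up the average genome size of a lineage
#'
#' Returns the AGS of the deepest taxonomy node matching the lineage. When
#' the exact node is absent, falls back to the deepest present ancestor with
#' a warning; a zero-depth (root) lineage returns the root AGS. A lineage
#' whose domain is unknown to the taxonomy is an error.
#'
#' @param taxonomy a `size_taxonomy`.
#' @param lineage a lineage string or `lineage` object.
#' @return AGS in base pairs.
#' @export
lookup_ags <- function(taxonomy, lineage) {
  stopifnot(inherits(taxonomy, "size_taxonomy"))
  s <- if (inherits(lineage, "lineage")) format_lineage(lineage) else lineage
  l <- parse_lineage(s) # validates
  if (length(l) == 0L) {
    return(taxonomy$root_ags)
  }
  paths <- .lineage_prefixes(format_lineage(l))
  present <- paths %in% names(taxonomy$index)
  if (!present[1L]) {
    stop("domain ", sQuote(unclass(l)[1L]), " is absent from the taxonomy",
      call. = FALSE
    )
  }
  deepest <- max(which(present))
  if (deepest < length(paths)) {
    warning(sprintf(
      "lineage %s not in taxonomy; using ancestor %s",
      sQuote(format_lineage(l)), sQuote(paths[deepest])
    ), call. = FALSE)
  }
  unname(taxonomy$index[paths[deepest]])
}

# Vectorized lookup over validated lineage strings, collecting fallbacks into
# a single warning. Used by the estimator where profiles can be large.
.lookup_ags_many <- function(taxonomy, strings) {
  idx <- taxonomy$index
  out <- numeric(length(strings))
  fell_back <- character(0)
  for (i in seq_along(strings)) {
    s <- strings[i]
    if (s == "") {
      out[i] <- taxonomy$root_ags
      next
    }
    hit <- idx[s]
    if (!is.na(hit)) {
      out[i] <- hit
      next
    }
    paths <- .lineage_prefixes(s)
    present <- paths %in% names(idx)
    if (!present[1L]) {
      stop("domain of lineage ", sQuote(s), " is absent from the taxonomy",
        call. = FALSE
      )
    }
    out[i] <- idx[[paths[max(which(present))]]]
    fell_back <- c(fell_back, s)
  }
  if (length(fell_back) > 0L) {
    warning(length(fell_back), " lineage(s) not in taxonomy; ",
      "used deepest present ancestor (first: ",
      sQuote(fell_back[1L]), ")",
      call. = FALSE
    )
  }
  out
}

#' Write a size taxonomy to TSV
#'
#' Three tab-delimited columns: `lineage`, `rank`, `ags_bp`, one row per
#' node (the root row has an empty lineage and rank `root`). AGS values are
#' written with full double precision so `read_taxonomy(write_taxonomy(t))`
#' reproduces every node exactly.
#'
#' @param taxonomy a `size_taxonomy`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_taxonomy <- function(taxonomy, path) {
  stopifnot(inherits(taxonomy, "size_taxonomy"))
  n <- taxonomy$nodes
  df <- data.frame(
    lineage = n$lineage, rank = n$rank,
    ags_bp = sprintf("%.17g", n$ags), stringsAsFactors = FALSE
  )
  utils::write.table(df, path,
    sep = "\t", quote = FALSE, row.names = FALSE,
    fileEncoding = "UTF-8"
  )
  invisible(path)
}

#' Write a genome metadata table
#'
#' Inverse of [read_genome_table()].
#'
#' @param records genome-record data.frame.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_genome_table <- function(records, path) {
  validate_genome_records(records)
  df <- records[c(
    "accession", "lineage", "assembly_size", "completeness", "contamination"
  )]
  df$assembly_size <- sprintf("%.17g", df$assembly_size)
  utils::write.table(df, path,
    sep = "\t", quote = FALSE, row.names = FALSE,
    fileEncoding = "UTF-8"
  )
  invisible(path)
}

#' Read a size taxonomy from TSV
#'
#' @param path a file written by [write_taxonomy()].
#' @return a `size_taxonomy`.
#' @export
read_taxonomy <- function(path) {
  if (!file.exists(path)) {
    stop("taxonomy file not found: ", path, call. = FALSE)
  }
  df <- tryCatch(
    utils::read.delim(path,
      sep = "\t", quote = "", stringsAsFactors = FALSE,
      colClasses = c("character", "character", "character"),
      na.strings = NULL
    ),
    error = function(e) stop("cannot parse taxonomy file: ", conditionMessage(e), call. = FALSE)
  )
  if (nrow(df) == 0L) stop("taxonomy file is empty: ", path, call. = FALSE)
  need <- c("lineage", "rank", "ags_bp")
  if (!all(need %in% names(df))) {
    stop("taxonomy file must have columns lineage, rank, ags_bp", call. = FALSE)
  }
  ags <- suppressWarnings(as.numeric(df$ags_bp))
  bad <- which(!is.finite(ags) | ags <= 0)
  if (length(bad) > 0L) {
    stop("malformed ags_bp at line ", bad[1L] + 1L, " of ", path, call. = FALSE)
  }
  if (anyDuplicated(df$lineage)) {
    dup <- df$lineage[duplicated(df$lineage)][1L]
    stop("duplicate lineage row in taxonomy file: ", sQuote(dup), call. = FALSE)
  }
  depth <- integer(nrow(df))
  for (i in seq_len(nrow(df))) {
    l <- tryCatch(parse_lineage(df$lineage[i]), error = function(e) {
      stop("malformed lineage at line ", i + 1L, " of ", path, ": ",
        conditionMessage(e),
        call. = FALSE
      )
    })
    depth[i] <- length(l)
  }
  if (!any(depth == 0L)) stop("taxonomy file has no root row", call. = FALSE)
  nodes <- data.frame(
    lineage = df$lineage,
    rank = ifelse(depth == 0L, "root", .RANKS[pmax(depth, 1L)]),
    name = vapply(seq_len(nrow(df)), function(i) {
      if (depth[i] == 0L) {
        return("root")
      }
      p <- strsplit(df$lineage[i], .LINEAGE_SEP, fixed = TRUE)[[1L]]
      p[length(p)]
    }, character(1)),
    parent = vapply(seq_len(nrow(df)), function(i) {
      if (depth[i] == 0L) {
        return(NA_character_)
      }
      .truncate_lineage(df$lineage[i], depth[i] - 1L)
    }, character(1)),
    depth = depth, ags = ags, stringsAsFactors = FALSE
  )
  nodes <- nodes[order(nodes$depth, nodes$lineage), ]
  rownames(nodes) <- NULL
  idx <- nodes$ags[nodes$depth > 0L]
  names(idx) <- nodes$lineage[nodes$depth > 0L]
  structure(
    list(
      nodes = nodes, index = idx,
      root_ags = nodes$ags[nodes$depth == 0L][1L]
    ),
    class = "size_taxonomy"
  )
}
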