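# Per-sample taxonomic coverage profiles. A profile entry attributes
# coverage x genome-size base pairs to a (possibly rank-truncated) lineage;
# total_bases is the metagenome's total sequenced base pairs and is the
# denominator of the microbial fraction.

#' Construct a sample profile
#'
#' @param sample_id sample identifier.
#' @param entries data.frame with columns `lineage` (validated lineage
#'   strings, depth 0-7, unique) and `coverage` (fold-coverage >= 0).
#'   Zero-coverage entries are dropped.
#' @param total_bases total sequenced base pairs in the metagenome, > 0.
#' @param ph optional soil pH.
#' @param environment optional environment-type label.
#' @return a `sample_profile` object.
#' @export
sample_profile <- function(sample_id, entries, total_bases,
                           ph = NA_real_, environment = NA_character_) {
  stopifnot(is.character(sample_id), length(sample_id) == 1L)
  if (!is.data.frame(entries) || !all(c("lineage", "coverage") %in% names(entries))) {
    stop("entries must be a data.frame with columns lineage, coverage",
      call. = FALSE
    )
  }
  if (any(!is.finite(entries$coverage)) || any(entries$coverage < 0)) {
    stop("sample ", sample_id, ": coverage must be finite and >= 0",
      call. = FALSE
    )
  }
  for (s in entries$lineage) parse_lineage(s)
  entries <- entries[entries$coverage > 0, c("lineage", "coverage"), drop = FALSE]
  if (anyDuplicated(entries$lineage)) {
    dup <- entries$lineage[duplicated(entries$lineage)][1L]
    stop("sample ", sample_id, ": duplicate lineage ", sQuote(dup),
      call. = FALSE
    )
  }
  if (!is.finite(total_bases) || total_bases <= 0) {
    stop("sample ", sample_id, ": total_bases must be > 0", call. = FALSE)
  }
  rownames(entries) <- NULL
  structure(
    list(
      sample_id = sample_id, entries = entries,
      total_bases = as.numeric(total_bases),
      ph = as.numeric(ph), environment = as.character(environment)
    ),
    class = "sample_profile"
  )
}

#' @export
print.sample_profile <- function(x, ...) {
  cat(sprintf(
    "Sample %s: %d taxa, total coverage %.3g, %.3g bp sequenced\n",
    x$sample_id, nrow(x$entries), sum(x$entries$coverage), x$total_bases
  ))
  invisible(x)
}

#' Read per-sample taxonomic coverage profiles
#'
#' The profile TSV has header columns `sample`, `lineage`, `coverage`; the
#' sample metadata TSV has `sample`, `total_bases` (or `read_count` and
#' `mean_read_length`, from which `total_bases` is computed) and optional
#' `ph` and `environment` columns. Every profiled sample must appear in the
#' metadata; duplicate (sample, lineage) rows, negative coverages and
#' malformed lineages are errors.
#'
#' @param profile_tsv path to the profile table.
#' @param metadata_tsv path to the sample metadata table.
#' @return a named list of [sample_profile()] objects, ordered by sample id.
#' @export
read_profiles <- function(profile_tsv, metadata_tsv) {
  for (p in c(profile_tsv, metadata_tsv)) {
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  }
  prof <- utils::read.delim(profile_tsv,
    sep = "\t", quote = "",
    stringsAsFactors = FALSE, na.strings = NULL,
    colClasses = "character"
  )
  if (!all(c("sample", "lineage", "coverage") %in% names(prof))) {
    stop("profile table must have columns sample, lineage, coverage",
      call. = FALSE
    )
  }
  prof$coverage <- suppressWarnings(as.numeric(prof$coverage))
  bad <- which(!is.finite(prof$coverage) | prof$coverage < 0)
  if (length(bad) > 0L) {
    stop("invalid coverage at line ", bad[1L] + 1L, " of ", profile_tsv,
      call. = FALSE
    )
  }
  key <- paste(prof$sample, prof$lineage, sep = "\r")
  if (anyDuplicated(key)) {
    i <- which(duplicated(key))[1L]
    stop(sprintf(
      "duplicate (sample, lineage) row: (%s, %s)",
      prof$sample[i], sQuote(prof$lineage[i])
    ), call. = FALSE)
  }

  meta <- read_sample_metadata(metadata_tsv)
  samples <- sort(unique(prof$sample))
  absent <- setdiff(samples, meta$sample)
  if (length(absent) > 0L) {
    stop("sample(s) missing from metadata: ", paste(absent, collapse = ", "),
      call. = FALSE
    )
  }
  out <- lapply(samples, function(sid) {
    m <- meta[meta$sample == sid, ]
    sample_profile(
      sample_id = sid,
      entries = prof[prof$sample == sid, c("lineage", "coverage")],
      total_bases = m$total_bases[1L],
      ph = m$ph[1L], environment = m$environment[1L]
    )
  })
  names(out) <- samples
  out
}

#' Read a sample metadata table
#'
#' @param metadata_tsv TSV with columns `sample`, `total_bases` (or
#'   `read_count` + `mean_read_length`), optional `ph`, `environment`.
#' @return a data.frame with columns sample, total_bases, ph, environment.
#' @export
read_sample_metadata <- function(metadata_tsv) {
  meta <- utils::read.delim(metadata_tsv,
    sep = "\t", quote = "",
    stringsAsFactors = FALSE, na.strings = c("NA", "")
  )
  if (!"sample" %in% names(meta)) {
    stop("metadata must have a sample column", call. = FALSE)
  }
  meta$sample <- as.character(meta$sample)
  if (!"total_bases" %in% names(meta)) {
    if (all(c("read_count", "mean_read_length") %in% names(meta))) {
      meta$total_bases <- as.numeric(meta$read_count) *
        as.numeric(meta$mean_read_length)
    } else {
      stop("metadata must have total_bases (or read_count and mean_read_length)",
        call. = FALSE
      )
    }
  }
  meta$total_bases <- as.numeric(meta$total_bases)
  if (any(!is.finite(meta$total_bases) | meta$total_bases <= 0)) {
    stop("total_bases must be > 0 for every sample", call. = FALSE)
  }
  if (anyDuplicated(meta$sample)) {
    stop("duplicate sample in metadata: ",
      meta$sample[duplicated(meta$sample)][1L],
      call. = FALSE
    )
  }
  if (!"ph" %in% names(meta)) meta$ph <- NA_real_
  if (!"environment" %in% names(meta)) meta$environment <- NA_character_
  meta$ph <- as.numeric(meta$ph)
  meta$environment <- as.character(meta$environment)
  meta[c("sample", "total_bases", "ph", "environment")]
}

#' Merge run-level profiles into sample-level profiles
#'
#' Sequencing runs belonging to one sample are combined by summing coverage
#' per lineage and summing total sequenced bases; merging a single run is the
#' identity. Coverage mass is conserved and the merge is order-invariant.
#'
#' @param run_profiles list of [sample_profile()] objects, one per run (the
#'   profile's `sample_id` is the run id).
#' @param run_to_sample named character vector mapping run id to sample id;
#'   every run must be mapped.
#' @return a named list of merged `sample_profile` objects, ordered by
#'   sample id. pH/environment are taken from the first run of each sample.
#' @export
merge_runs <- function(run_profiles, run_to_sample) {
  stopifnot(is.list(run_profiles), length(run_profiles) > 0L)
  run_ids <- vapply(run_profiles, function(p) p$sample_id, character(1))
  unmapped <- setdiff(run_ids, names(run_to_sample))
  if (length(unmapped) > 0L) {
    stop("run(s) not in run_to_sample mapping: ",
      paste(unmapped, collapse = ", "),
      call. = FALSE
    )
  }
  by_sample <- split(run_profiles, unname(run_to_sample[run_ids]))
  out <- lapply(names(by_sample), function(sid) {
    runs <- by_sample[[sid]]
    lin <- unlist(lapply(runs, function(p) p$entries$lineage))
    cov <- unlist(lapply(runs, function(p) p$entries$coverage))
    summed <- tapply(cov, lin, sum)
    sample_profile(
      sample_id = sid,
      entries = data.frame(
        lineage = names(summed), coverage = as.numeric(summed),
        stringsAsFactors = FALSE
      ),
      total_bases = sum(vapply(runs, function(p) p$total_bases, numeric(1))),
      ph = runs[[1L]]$ph, environment = runs[[1L]]$environment
    )
  })
  names(out) <- names(by_sample)
  out[order(names(out))]
}

#' Write profiles to a TSV pair
#'
#' Writes the profile table (`sample`, `lineage`, `coverage`) and the sample
#' metadata table (`sample`, `total_bases`, `ph`, `environment`) consumed by
#' [read_profiles()].
#'
#' @param profiles list of `sample_profile` objects.
#' @param profile_tsv,metadata_tsv output paths.
#' @return invisibly, the two paths.
#' @export
write_profiles <- function(profiles, profile_tsv, metadata_tsv) {
  rows <- do.call(rbind, lapply(profiles, function(p) {
    data.frame(
      sample = p$sample_id, lineage = p$entries$lineage,
      coverage = sprintf("%.17g", p$entries$coverage),
      stringsAsFactors = FALSE
    )
  }))
  utils::write.table(rows, profile_tsv,
    sep = "\t", quote = FALSE,
    row.names = FALSE, fileEncoding = "UTF-8"
  )
  meta <- do.call(rbind, lapply(profiles, function(p) {
    data.frame(
      sample = p$sample_id,
      total_bases = sprintf("%.17g", p$total_bases),
      ph = p$ph, environment = p$environment, stringsAsFactors = FALSE
    )
  }))
  utils::write.table(meta, metadata_tsv,
    sep = "\t", quote = FALSE,
    row.names = FALSE, fileEncoding = "UTF-8"
  )
  invisible(c(profile_tsv, metadata_tsv))
}
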