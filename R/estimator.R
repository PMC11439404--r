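# Per-sample community statistics from a coverage profile and a size
# taxonomy. All percentages are carried on the 0-100 scale.

#' Coverage-weighted community average genome size
#'
#' The community AGS is the genome size of each taxon present, weighted by
#' that taxon's fold-coverage:
#' `sum(coverage_i * ags_i) / sum(coverage_i)`, where `ags_i` is the
#' taxonomy AGS of the entry's lineage (deepest present ancestor when the
#' exact taxon is absent). Coverage assigned at the root is priced at the
#' root AGS: marker-based profiles attribute such coverage to unresolved
#' bacteria/archaea, not to non-microbial DNA.
#'
#' @param profile a [sample_profile()].
#' @param taxonomy a `size_taxonomy`.
#' @return AGS in base pairs.
#' @export
estimate_ags <- function(profile, taxonomy) {
  stopifnot(inherits(profile, "sample_profile"))
  e <- profile$entries
  if (nrow(e) == 0L || sum(e$coverage) <= 0) {
    stop("sample ", profile$sample_id, ": no positive coverage", call. = FALSE)
  }
  sizes <- .lookup_ags_many(taxonomy, e$lineage)
  sum(e$coverage * sizes) / sum(e$coverage)
}

#' Microbial base pairs predicted from a profile
#'
#' `sum(coverage_i * ags_i)` over all entries, the numerator of the microbial
#' fraction. An empty profile yields 0.
#'
#' @inheritParams estimate_ags
#' @return predicted bacterial + archaeal base pairs.
#' @export
microbial_bases <- function(profile, taxonomy) {
  stopifnot(inherits(profile, "sample_profile"))
  e <- profile$entries
  if (nrow(e) == 0L) {
    return(0)
  }
  sizes <- .lookup_ags_many(taxonomy, e$lineage)
  sum(e$coverage * sizes)
}

#' Microbial fraction of a metagenome
#'
#' The percentage of the metagenome's sequenced base pairs attributable to
#' bacteria and archaea: `100 * microbial_bases / total_bases`, capped at
#' 100% (coverage noise can push the prediction past the total; the cap is
#' reported with a warning). The non-microbial (eukaryotic + viral) fraction
#' is its complement, `100 - smf`.
#'
#' @inheritParams estimate_ags
#' @return SMF as a percent in (0, 100].
#' @export
smf <- function(profile, taxonomy) {
  stopifnot(inherits(profile, "sample_profile"))
  if (!is.finite(profile$total_bases) || profile$total_bases <= 0) {
    stop("sample ", profile$sample_id, ": total_bases must be > 0",
      call. = FALSE
    )
  }
  mb <- microbial_bases(profile, taxonomy)
  pct <- 100 * mb / profile$total_bases
  if (pct > 100) {
    warning(sprintf(
      "sample %s: predicted microbial bases (%.3g) exceed total bases (%.3g); capping SMF at 100%%",
      profile$sample_id, mb, profile$total_bases
    ), call. = FALSE)
    pct <- 100
  }
  pct
}

#' Fraction of community coverage resolved to species rank
#'
#' `100 * (coverage of species-depth entries) / (coverage of all entries)`,
#' the share of the community matching a reference species.
#'
#' @param profile a [sample_profile()].
#' @return percent in [0, 100].
#' @export
known_species_fraction <- function(profile) {
  stopifnot(inherits(profile, "sample_profile"))
  e <- profile$entries
  total <- sum(e$coverage)
  if (total <= 0) {
    stop("sample ", profile$sample_id, ": zero total coverage", call. = FALSE)
  }
  depth <- .fast_depth(e$lineage)
  100 * sum(e$coverage[depth == 7L]) / total
}

#' Fraction of domain-assigned coverage under one domain
#'
#' `100 * coverage under the named domain / coverage under all domains`.
#' Root-level (fully unresolved) coverage is excluded from both numerator
#' and denominator.
#'
#' @param profile a [sample_profile()].
#' @param domain_name prefixed domain label, e.g. `"d__Archaea"`.
#' @return percent in [0, 100].
#' @export
domain_fraction <- function(profile, domain_name) {
  stopifnot(inherits(profile, "sample_profile"))
  e <- profile$entries
  depth <- .fast_depth(e$lineage)
  assigned <- depth >= 1L
  denom <- sum(e$coverage[assigned])
  if (denom <= 0) {
    stop("sample ", profile$sample_id, ": no domain-assigned coverage",
      call. = FALSE
    )
  }
  dom <- vapply(
    strsplit(e$lineage[assigned], ";", fixed = TRUE),
    function(p) trimws(p[1L]), character(1)
  )
  100 * sum(e$coverage[assigned][dom == domain_name]) / denom
}

#' Estimate all per-sample statistics
#'
#' Applies [estimate_ags()], [microbial_bases()], [smf()],
#' [known_species_fraction()] and [domain_fraction()] to every sample and
#' assembles the results, ordered by sample id. Errors in any sample are
#' reported with the sample id attached.
#'
#' @param profiles list of [sample_profile()] objects.
#' @param taxonomy a `size_taxonomy`.
#' @return a data.frame with one row per sample and columns `sample`,
#'   `ags_mbp` (AGS in Mbp), `ags_bp`, `microbial_bases_bp`, `smf_pct`,
#'   `non_microbial_pct`, `known_species_pct`, `archaea_pct`, `bacteria_pct`,
#'   `ph`, `environment`.
#' @export
estimate_all <- function(profiles, taxonomy) {
  if (!is.list(profiles) || length(profiles) == 0L) {
    stop("need at least one sample profile", call. = FALSE)
  }
  rows <- lapply(profiles, function(p) {
    tryCatch(
      {
        ags <- estimate_ags(p, taxonomy)
        mb <- microbial_bases(p, taxonomy)
        sm <- smf(p, taxonomy)
        data.frame(
          sample = p$sample_id,
          ags_mbp = ags / 1e6,
          ags_bp = ags,
          microbial_bases_bp = mb,
          smf_pct = sm,
          non_microbial_pct = 100 - sm,
          known_species_pct = known_species_fraction(p),
          archaea_pct = domain_fraction(p, "d__Archaea"),
          bacteria_pct = domain_fraction(p, "d__Bacteria"),
          ph = p$ph,
          environment = p$environment,
          stringsAsFactors = FALSE
        )
      },
      error = function(e) {
        stop("sample ", p$sample_id, ": ", conditionMessage(e), call. = FALSE)
      }
    )
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$sample), ]
  rownames(out) <- NULL
  out
}

#' Dataset-level summary of per-sample estimates
#'
#' Mean and median of every per-sample statistic across the dataset (genome
#' sizes are conventionally summarized by the mean; non-microbial fractions
#' by the median; both are reported for every column).
#'
#' @param estimates output of [estimate_all()].
#' @return a data.frame with columns `statistic`, `mean`, `median`.
#' @export
summarize_estimates <- function(estimates) {
  stat_cols <- c(
    "ags_mbp", "smf_pct", "non_microbial_pct",
    "known_species_pct", "archaea_pct", "bacteria_pct"
  )
  data.frame(
    statistic = stat_cols,
    mean = vapply(stat_cols, function(cn) mean(estimates[[cn]]), numeric(1)),
    median = vapply(stat_cols, function(cn) stats::median(estimates[[cn]]), numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Write per-sample estimates (and their summary) to CSV
#'
#' @param estimates output of [estimate_all()].
#' @param path output CSV path for per-sample rows.
#' @param summary_path optional path for the dataset summary CSV.
#' @return `path`, invisibly.
#' @export
write_estimates <- function(estimates, path, summary_path = NULL) {
  utils::write.csv(estimates, path, row.names = FALSE, quote = FALSE)
  if (!is.null(summary_path)) {
    utils::write.csv(summarize_estimates(estimates), summary_path,
      row.names = FALSE, quote = FALSE
    )
  }
  invisible(path)
}

#' Read a per-sample estimates CSV
#'
#' @param path a CSV written by [write_estimates()].
#' @return a data.frame of per-sample estimates.
#' @export
read_estimates <- function(path) {
  if (!file.exists(path)) stop("estimates file not found: ", path, call. = FALSE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
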