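# Synthetic communities with fully known ground truth. Genome sizes and
# relative abundances are lognormal; a controlled eukaryotic fraction enters
# only as unattributed base pairs in total_bases (marker-based profiles never
# see eukaryotic lineages); lineage truncation emulates partial taxonomic
# resolution; assembly sizes are back-computed from drawn completeness and
# contamination so the corrected size recovers the true size exactly.

#' Specification of a synthetic community simulation
#'
#' Bundles and validates the parameters of the generator. Defaults emulate a
#' soil shotgun metagenome: genome sizes lognormal around 4 Mbp, lognormal
#' cell abundances, a 38.8% non-microbial (eukaryotic + viral) share of the
#' sequenced bases, ~1.2% archaeal coverage, partial taxonomic resolution,
#' and mild multiplicative coverage noise.
#'
#' @param n_species number of species in the community, >= 1.
#' @param size_log_mean,size_log_sd lognormal parameters of true genome
#'   sizes in bp (defaults `log(4e6)` and 0.4 span roughly 1.5-11 Mbp).
#' @param abundance_log_sd lognormal sd of relative cell abundances.
#' @param euk_fraction percent of `total_bases` that is non-microbial, in
#'   `[0, 100)`.
#' @param archaea_fraction percent of microbial coverage under
#'   `d__Archaea`, in `[0, 100]`.
#' @param truncation_prob per-step probability that a profile entry's
#'   lineage is truncated by one rank (applied repeatedly: species -> genus
#'   -> family -> ... -> root), in `[0, 1)`.
#' @param total_bases total sequenced base pairs per sample, > 0.
#' @param coverage_noise_sd sd of multiplicative lognormal coverage noise
#'   (0 = noise-free).
#' @param completeness_range,contamination_range uniform draw ranges (%) for
#'   genome completeness and contamination.
#' @param genomes_per_species genomes emitted per species, >= 1.
#' @return a validated `simulation_spec` list.
#' @export
simulation_spec <- function(n_species = 100,
                            size_log_mean = log(4e6),
                            size_log_sd = 0.4,
                            abundance_log_sd = 1.0,
                            euk_fraction = 38.8,
                            archaea_fraction = 1.2,
                            truncation_prob = 0.3,
                            total_bases = 1e9,
                            coverage_noise_sd = 0.1,
                            completeness_range = c(70, 100),
                            contamination_range = c(0, 10),
                            genomes_per_species = 1) {
  spec <- list(
    n_species = as.integer(n_species),
    size_log_mean = size_log_mean, size_log_sd = size_log_sd,
    abundance_log_sd = abundance_log_sd,
    euk_fraction = euk_fraction, archaea_fraction = archaea_fraction,
    truncation_prob = truncation_prob, total_bases = total_bases,
    coverage_noise_sd = coverage_noise_sd,
    completeness_range = as.numeric(completeness_range),
    contamination_range = as.numeric(contamination_range),
    genomes_per_species = as.integer(genomes_per_species)
  )
  with(spec, {
    stopifnot(
      n_species >= 1L,
      is.finite(size_log_mean), size_log_sd > 0,
      abundance_log_sd > 0,
      euk_fraction >= 0, euk_fraction < 100,
      archaea_fraction >= 0, archaea_fraction <= 100,
      truncation_prob >= 0, truncation_prob < 1,
      total_bases > 0,
      coverage_noise_sd >= 0,
      length(completeness_range) == 2L,
      completeness_range[1] > 0, completeness_range[2] <= 100,
      completeness_range[1] <= completeness_range[2],
      length(contamination_range) == 2L,
      contamination_range[1] >= 0, contamination_range[2] < 100,
      contamination_range[1] <= contamination_range[2],
      genomes_per_species >= 1L
    )
  })
  class(spec) <- "simulation_spec"
  spec
}

#' Read a simulation spec from a YAML file
#'
#' Fields are the arguments of [simulation_spec()]; absent fields take the
#' defaults.
#'
#' @param path YAML file path.
#' @return a `simulation_spec`.
#' @export
read_simulation_spec <- function(path) {
  if (!file.exists(path)) stop("spec file not found: ", path, call. = FALSE)
  x <- yaml::read_yaml(path)
  known <- names(formals(simulation_spec))
  unknown <- setdiff(names(x), known)
  if (length(unknown) > 0L) {
    stop("unknown simulation spec field(s): ", paste(unknown, collapse = ", "),
      call. = FALSE
    )
  }
  do.call(simulation_spec, x)
}

# Random rank structure for one domain: each species gets a genus, each
# genus a family, and so on, drawn once so parentage is consistent.
.simulate_domain_lineages <- function(n_species, domain, tag) {
  n_gen <- max(1L, ceiling(n_species / 3))
  n_fam <- max(1L, ceiling(n_gen / 2))
  n_ord <- max(1L, ceiling(n_fam / 2))
  n_cls <- max(1L, ceiling(n_ord / 2))
  n_phy <- max(1L, ceiling(n_cls / 2))
  gen_of_sp <- sample.int(n_gen, n_species, replace = TRUE)
  fam_of_gen <- sample.int(n_fam, n_gen, replace = TRUE)
  ord_of_fam <- sample.int(n_ord, n_fam, replace = TRUE)
  cls_of_ord <- sample.int(n_cls, n_ord, replace = TRUE)
  phy_of_cls <- sample.int(n_phy, n_cls, replace = TRUE)
  vapply(seq_len(n_species), function(i) {
    g <- gen_of_sp[i]
    f <- fam_of_gen[g]
    o <- ord_of_fam[f]
    cl <- cls_of_ord[o]
    p <- phy_of_cls[cl]
    paste(
      paste0("d__", domain),
      sprintf("p__%s.P%d", tag, p),
      sprintf("c__%s.C%d", tag, cl),
      sprintf("o__%s.O%d", tag, o),
      sprintf("f__%s.F%d", tag, f),
      sprintf("g__%s.G%d", tag, g),
      sprintf("s__%s.G%d sp%d", tag, g, i),
      sep = .LINEAGE_SEP
    )
  }, character(1))
}

#' Simulate a genome table and its size taxonomy
#'
#' Draws true genome sizes from the spec's lognormal law, assigns species to
#' a random but internally consistent rank structure (split between
#' `d__Bacteria` and `d__Archaea` when the archaeal fraction is positive),
#' draws completeness and contamination uniformly from the spec ranges, and
#' back-computes each assembly size so that
#' [corrected_genome_size()] recovers the drawn true size exactly.
#'
#' @param spec a [simulation_spec()].
#' @param seed integer RNG seed; identical spec + seed give identical output.
#' @return a `simulated_taxonomy` list: `genomes` (a genome-record
#'   data.frame), `taxonomy` (the [build_taxonomy()] of those records),
#'   `true_sizes` (named by species lineage), `species` (lineage strings),
#'   `seed`.
#' @export
simulate_taxonomy <- function(spec, seed) {
  stopifnot(inherits(spec, "simulation_spec"))
  set.seed(as.integer(seed))
  n <- spec$n_species
  n_arch <- if (spec$archaea_fraction > 0 && n >= 2L) {
    max(1L, round(n * 0.05))
  } else {
    0L
  }
  n_bact <- n - n_arch
  lineages <- character(0)
  if (n_bact > 0L) {
    lineages <- .simulate_domain_lineages(n_bact, "Bacteria", "Bact")
  }
  if (n_arch > 0L) {
    lineages <- c(lineages, .simulate_domain_lineages(n_arch, "Archaea", "Arch"))
  }
  true_sizes <- stats::rlnorm(n, spec$size_log_mean, spec$size_log_sd)
  names(true_sizes) <- lineages

  k <- spec$genomes_per_species
  idx <- rep(seq_len(n), each = k)
  completeness <- stats::runif(
    n * k, spec$completeness_range[1], spec$completeness_range[2]
  )
  contamination <- stats::runif(
    n * k, spec$contamination_range[1], spec$contamination_range[2]
  )
  # invert the correction so corrected size == true size for every genome
  assembly <- true_sizes[idx] * (completeness / 100) / (1 - contamination / 100)
  genomes <- data.frame(
    accession = sprintf("SIM%05d", seq_len(n * k)),
    lineage = lineages[idx],
    assembly_size = unname(assembly),
    completeness = completeness,
    contamination = contamination,
    stringsAsFactors = FALSE
  )
  structure(
    list(
      genomes = genomes,
      taxonomy = build_taxonomy(genomes),
      true_sizes = true_sizes,
      species = lineages,
      seed = as.integer(seed)
    ),
    class = "simulated_taxonomy"
  )
}

#' Simulate one sample profile with known truth
#'
#' Draws lognormal relative cell abundances (rescaled so the archaeal share
#' of coverage matches the spec), sets fold-coverages so that the microbial
#' base pairs sum exactly to `(1 - euk_fraction/100) * total_bases`, records
#' the exact pre-noise truth, then applies lineage truncation (each entry's
#' lineage loses one rank with probability `truncation_prob`, repeatedly)
#' and multiplicative lognormal coverage noise.
#'
#' @param sim_tax a `simulated_taxonomy` from [simulate_taxonomy()].
#' @param spec the [simulation_spec()].
#' @param seed integer RNG seed for this sample.
#' @param sample_id sample identifier for the emitted profile.
#' @return a list: `profile` (a [sample_profile()]) and `truth` (true AGS in
#'   bp, true SMF / non-microbial percents, true per-species coverages).
#' @export
simulate_sample <- function(sim_tax, spec, seed, sample_id = "S1") {
  stopifnot(
    inherits(sim_tax, "simulated_taxonomy"),
    inherits(spec, "simulation_spec")
  )
  set.seed(as.integer(seed))
  sizes <- sim_tax$true_sizes
  n <- length(sizes)
  a <- stats::rlnorm(n, 0, spec$abundance_log_sd)

  is_arch <- startsWith(names(sizes), "d__Archaea")
  f <- spec$archaea_fraction / 100
  if (any(is_arch) && any(!is_arch) && f > 0 && f < 1) {
    # rescale archaeal abundances so their coverage share is exactly f
    a[is_arch] <- a[is_arch] *
      (f * sum(a[!is_arch])) / ((1 - f) * sum(a[is_arch]))
  }

  microbial_target <- (1 - spec$euk_fraction / 100) * spec$total_bases
  cov <- a * microbial_target / sum(a * sizes)

  truth <- list(
    true_ags = sum(cov * sizes) / sum(cov),
    true_smf = 100 - spec$euk_fraction,
    true_non_microbial = spec$euk_fraction,
    true_coverages = stats::setNames(cov, names(sizes)),
    euk_fraction = spec$euk_fraction,
    seed = as.integer(seed)
  )

  depth <- rep(7L, n)
  if (spec$truncation_prob > 0) {
    steps <- stats::rgeom(n, prob = 1 - spec$truncation_prob)
    depth <- pmax(0L, 7L - pmin(steps, 7L))
  }
  trunc_lineage <- vapply(
    seq_len(n),
    function(i) .truncate_lineage(names(sizes)[i], depth[i]),
    character(1)
  )
  agg <- tapply(cov, trunc_lineage, sum)
  entries <- data.frame(
    lineage = names(agg), coverage = as.numeric(agg),
    stringsAsFactors = FALSE
  )
  if (spec$coverage_noise_sd > 0) {
    entries$coverage <- entries$coverage *
      stats::rlnorm(nrow(entries), 0, spec$coverage_noise_sd)
  }
  list(
    profile = sample_profile(sample_id, entries, spec$total_bases),
    truth = truth
  )
}

#' Simulate a multi-sample dataset
#'
#' One shared simulated taxonomy (seeded with `seed`) and `n_samples`
#' profiles seeded with `seed + 1 ... seed + n_samples`.
#'
#' @param spec a [simulation_spec()].
#' @param n_samples number of samples.
#' @param seed global integer seed.
#' @return a list: `sim_tax`, `profiles` (named list of `sample_profile`),
#'   `truths` (named list of per-sample truth).
#' @export
simulate_dataset <- function(spec, n_samples, seed) {
  stopifnot(n_samples >= 1L)
  sim_tax <- simulate_taxonomy(spec, seed)
  ids <- sprintf("S%03d", seq_len(n_samples))
  sims <- lapply(seq_len(n_samples), function(i) {
    simulate_sample(sim_tax, spec, seed = as.integer(seed) + i, sample_id = ids[i])
  })
  list(
    sim_tax = sim_tax,
    profiles = stats::setNames(lapply(sims, `[[`, "profile"), ids),
    truths = stats::setNames(lapply(sims, `[[`, "truth"), ids)
  )
}

#' Simulate a pH / AGS dataset from a Gamma GLM
#'
#' Draws soil pH uniformly over `ph_range`, sets the mean AGS through the
#' chosen link (`mu = 1/eta` for the inverse link, `mu = exp(eta)` for the
#' log link, with `eta = intercept + slope * ph`), and draws AGS from a
#' Gamma distribution with that mean and the stated shape. Environment
#' labels are assigned round-robin for grouped-fit tests.
#'
#' @param n_samples number of samples, >= 3.
#' @param link `"log"` or `"inverse"`.
#' @param intercept,slope generating coefficients on the link scale.
#' @param shape Gamma shape; larger = less noise (variance = mu^2 / shape).
#' @param ph_range length-2 uniform draw range for pH.
#' @param seed integer RNG seed.
#' @param environments label pool assigned round-robin.
#' @return a data.frame with columns `ph`, `ags` (bp), `environment`.
#' @export
simulate_ph_dataset <- function(n_samples, link = c("log", "inverse"),
                                intercept = 15.5, slope = -0.15, shape = 20,
                                ph_range = c(3.5, 9), seed = 1,
                                environments = c(
                                  "cropland", "forest",
                                  "grassland", "tundra"
                                )) {
  link <- match.arg(link)
  if (n_samples < 3L) stop("need n_samples >= 3", call. = FALSE)
  stopifnot(shape > 0, length(ph_range) == 2L, ph_range[1] <= ph_range[2])
  set.seed(as.integer(seed))
  ph <- stats::runif(n_samples, ph_range[1], ph_range[2])
  eta <- intercept + slope * ph
  mu <- switch(link,
    log = exp(eta),
    inverse = {
      if (any(eta <= 0)) {
        stop("inverse link requires intercept + slope * ph > 0 over ph_range",
          call. = FALSE
        )
      }
      1 / eta
    }
  )
  ags <- stats::rgamma(n_samples, shape = shape, rate = shape / mu)
  data.frame(
    ph = ph, ags = ags,
    environment = rep_len(environments, n_samples),
    stringsAsFactors = FALSE
  )
}

#' Expected AGS from a total-reads-per-marker estimator (test foil)
#'
#' An estimator that divides total read count by detected marker-gene count
#' counts non-microbial reads in its numerator, so its expected AGS is the
#' true AGS inflated by `1 / (1 - euk_fraction/100)`. Provided purely as an
#' analytic foil to demonstrate the bias that coverage-based estimation
#' avoids.
#'
#' @param true_ags true community AGS in bp (or a `truth` list from
#'   [simulate_sample()]).
#' @param euk_fraction non-microbial percent of total bases, in `[0, 100)`.
#' @return the inflated AGS in bp.
#' @export
reads_per_marker_foil <- function(true_ags, euk_fraction) {
  if (is.list(true_ags)) true_ags <- true_ags$true_ags
  if (!is.finite(euk_fraction) || euk_fraction < 0 || euk_fraction >= 100) {
    stop("euk_fraction must be in [0, 100)", call. = FALSE)
  }
  true_ags / (1 - euk_fraction / 100)
}
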