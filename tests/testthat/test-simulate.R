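test_that("simulation_spec validates its fields", {
  expect_s3_class(simulation_spec(), "simulation_spec")
  expect_error(simulation_spec(n_species = 0))
  expect_error(simulation_spec(euk_fraction = 100))
  expect_error(simulation_spec(truncation_prob = 1))
  expect_error(simulation_spec(completeness_range = c(0, 100)))
  expect_error(simulation_spec(contamination_range = c(5, 100)))
})

test_that("simulation specs load from YAML with defaults for absent fields", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines("n_species: 12\neuk_fraction: 20\ncoverage_noise_sd: 0", f)
  spec <- read_simulation_spec(f)
  expect_equal(spec$n_species, 12L)
  expect_equal(spec$euk_fraction, 20)
  expect_equal(spec$coverage_noise_sd, 0)
  expect_equal(spec$total_bases, 1e9) # default retained
  bad <- withr::local_tempfile(fileext = ".yaml")
  writeLines("not_a_field: 1", bad)
  expect_error(read_simulation_spec(bad), "unknown")
})

test_that("simulate_taxonomy is deterministic under a seed", {
  spec <- simulation_spec(n_species = 10)
  a <- simulate_taxonomy(spec, 7)
  b <- simulate_taxonomy(spec, 7)
  expect_identical(a$genomes, b$genomes)
  expect_identical(a$true_sizes, b$true_sizes)
  c <- simulate_taxonomy(spec, 8)
  expect_false(identical(a$genomes, c$genomes))
})

test_that("assembly sizes are back-computed so corrected sizes equal true sizes", {
  spec <- simulation_spec(n_species = 25, genomes_per_species = 3)
  st <- simulate_taxonomy(spec, 11)
  g <- st$genomes
  corrected <- corrected_genome_size(g$assembly_size, g$completeness, g$contamination)
  expect_equal(corrected, unname(st$true_sizes[g$lineage]), tolerance = 1e-12)
  # species AGS in the built taxonomy equals the drawn true size
  expect_equal(
    unname(st$taxonomy$index[names(st$true_sizes)]),
    unname(st$true_sizes),
    tolerance = 1e-9
  )

  perfect <- simulation_spec(
    n_species = 5,
    completeness_range = c(100, 100), contamination_range = c(0, 0)
  )
  stp <- simulate_taxonomy(perfect, 3)
  expect_equal(stp$genomes$assembly_size, unname(stp$true_sizes),
    tolerance = 1e-12
  )
})

test_that("noise-free samples conserve bases: microbial + eukaryotic = total", {
  spec <- simulation_spec(
    n_species = 40, euk_fraction = 35,
    truncation_prob = 0, coverage_noise_sd = 0
  )
  st <- simulate_taxonomy(spec, 2)
  s <- simulate_sample(st, spec, 5)
  cov <- s$profile$entries$coverage
  sizes <- unname(st$true_sizes[s$profile$entries$lineage])
  euk_bases <- spec$euk_fraction / 100 * spec$total_bases
  expect_equal(sum(cov * sizes) + euk_bases, spec$total_bases, tolerance = 1e-9)
  # emitted profile agrees exactly with the recorded truth
  expect_equal(
    sum(cov * sizes) / sum(cov), s$truth$true_ags,
    tolerance = 1e-12
  )
})

test_that("samples are deterministic and truncation moves coverage to ancestors", {
  spec <- simulation_spec(n_species = 30, truncation_prob = 0.5)
  st <- simulate_taxonomy(spec, 1)
  s1 <- simulate_sample(st, spec, 9)
  s2 <- simulate_sample(st, spec, 9)
  expect_identical(s1$profile$entries, s2$profile$entries)
  depths <- lineage_depth(s1$profile$entries$lineage)
  expect_true(any(depths < 7L))
  # coverage mass conserved by truncation + aggregation (no noise term here)
  spec0 <- simulation_spec(
    n_species = 30, truncation_prob = 0.5,
    coverage_noise_sd = 0
  )
  s3 <- simulate_sample(st, spec0, 9)
  expect_equal(
    sum(s3$profile$entries$coverage),
    sum(s3$truth$true_coverages),
    tolerance = 1e-9
  )
})

test_that("all-genus truncation matches a genus-level oracle", {
  spec <- simulation_spec(
    n_species = 20, truncation_prob = 0,
    coverage_noise_sd = 0
  )
  st <- simulate_taxonomy(spec, 6)
  s <- simulate_sample(st, spec, 7)
  # truncate every entry to genus by hand and re-estimate
  e <- s$profile$entries
  genus <- vapply(strsplit(e$lineage, "; ", fixed = TRUE), function(p) {
    paste(p[1:6], collapse = "; ")
  }, character(1))
  agg <- tapply(e$coverage, genus, sum)
  gprof <- sample_profile("G", data.frame(
    lineage = names(agg),
    coverage = as.numeric(agg)
  ), spec$total_bases)
  got <- estimate_ags(gprof, st$taxonomy)
  oracle <- sum(agg * st$taxonomy$index[names(agg)]) / sum(agg)
  expect_equal(got, oracle, tolerance = 1e-9)
  # bias is bounded by the within-genus spread of species sizes
  expect_gte(got, min(st$true_sizes))
  expect_lte(got, max(st$true_sizes))
})

test_that("archaeal coverage share matches the spec fraction", {
  spec <- simulation_spec(
    n_species = 100, archaea_fraction = 1.2,
    truncation_prob = 0, coverage_noise_sd = 0
  )
  st <- simulate_taxonomy(spec, 4)
  s <- simulate_sample(st, spec, 8)
  expect_equal(domain_fraction(s$profile, "d__Archaea"), 1.2, tolerance = 1e-9)
})

test_that("simulate_ph_dataset approaches the mean curve as shape grows", {
  d <- simulate_ph_dataset(100,
    link = "log", intercept = 15.5, slope = -0.15,
    shape = 1e6, seed = 13
  )
  mu <- exp(15.5 - 0.15 * d$ph)
  expect_lt(max(abs(d$ags - mu) / mu), 0.01)
  expect_setequal(
    unique(d$environment),
    c("cropland", "forest", "grassland", "tundra")
  )
  expect_error(simulate_ph_dataset(2, "log"), "n_samples")
  expect_error(simulate_ph_dataset(10, "probit"), "arg")
  # inverse link must keep the linear predictor positive
  expect_error(
    simulate_ph_dataset(10, "inverse", intercept = 0.1, slope = -0.15),
    "inverse link"
  )
  di <- simulate_ph_dataset(10, "inverse",
    intercept = 1e-7, slope = 2e-8,
    shape = 100, seed = 3
  )
  expect_true(all(di$ags > 0))
})

test_that("the reads-per-marker foil inflates by exactly 1/(1 - euk/100)", {
  expect_equal(reads_per_marker_foil(4e6, 0), 4e6)
  expect_equal(reads_per_marker_foil(4e6, 50), 8e6)
  # at the dataset's observed non-microbial median the foil lands near the
  # magnitude of uncorrected estimates
  expect_equal(reads_per_marker_foil(4.7e6, 38.8), 4.7e6 / (1 - 0.388))
  expect_error(reads_per_marker_foil(4e6, 100), "euk_fraction")
  # accepts a simulate_sample truth list
  spec <- simulation_spec(n_species = 5, euk_fraction = 20)
  st <- simulate_taxonomy(spec, 1)
  s <- simulate_sample(st, spec, 2)
  expect_equal(
    reads_per_marker_foil(s$truth, 20),
    s$truth$true_ags / 0.8
  )
})

test_that("simulate_dataset shares one taxonomy and offsets per-sample seeds", {
  spec <- simulation_spec(n_species = 20)
  ds <- simulate_dataset(spec, 3, 42)
  expect_length(ds$profiles, 3L)
  expect_named(ds$profiles, c("S001", "S002", "S003"))
  # distinct seeds -> distinct profiles
  expect_false(identical(
    ds$profiles$S001$entries,
    ds$profiles$S002$entries
  ))
  ds2 <- simulate_dataset(spec, 3, 42)
  expect_identical(ds$profiles$S002$entries, ds2$profiles$S002$entries)
})
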