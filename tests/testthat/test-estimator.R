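# Two-species reference community used throughout: sizes 2 and 4 Mbp.
two_species_tax <- function() {
  build_taxonomy(make_genomes(
    c(lin7(g = "G1", s = "G1 sp1"), lin7(g = "G2", s = "G2 sp1")),
    c(2e6, 4e6)
  ))
}
SP1 <- lin7(g = "G1", s = "G1 sp1")
SP2 <- lin7(g = "G2", s = "G2 sp1")

test_that("estimate_ags is the coverage-weighted mean genome size", {
  tax <- two_species_tax()
  expect_equal(estimate_ags(make_profile(c(SP1, SP2), c(1, 1)), tax), 3e6)
  # (3*2 + 1*4) / 4 Mbp, brute-force weighted mean
  expect_equal(estimate_ags(make_profile(c(SP1, SP2), c(3, 1)), tax), 2.5e6)
  expect_equal(estimate_ags(make_profile(SP1, 0.37), tax), 2e6)
  expect_error(
    estimate_ags(make_profile(character(0), numeric(0)), tax),
    "no positive coverage"
  )
})

test_that("estimate_ags is invariant to rescaling all coverages", {
  tax <- two_species_tax()
  p1 <- make_profile(c(SP1, SP2), c(3, 1))
  p2 <- make_profile(c(SP1, SP2), c(3, 1) * 17.3)
  expect_equal(estimate_ags(p1, tax), estimate_ags(p2, tax))
})

test_that("estimate_ags and microbial_bases match a brute-force loop on larger profiles", {
  set.seed(21)
  spec <- simulation_spec(n_species = 50, truncation_prob = 0.4)
  st <- simulate_taxonomy(spec, 3)
  s <- simulate_sample(st, spec, 4)
  e <- s$profile$entries
  # independent loop: price each entry at the deepest present node
  expected_mb <- 0
  for (i in seq_len(nrow(e))) {
    lin <- e$lineage[i]
    size <- if (lin == "") {
      st$taxonomy$root_ags
    } else {
      repeat {
        if (lin %in% names(st$taxonomy$index)) break
        parts <- strsplit(lin, "; ", fixed = TRUE)[[1L]]
        lin <- paste(parts[-length(parts)], collapse = "; ")
      }
      unname(st$taxonomy$index[lin])
    }
    expected_mb <- expected_mb + e$coverage[i] * size
  }
  expect_equal(microbial_bases(s$profile, st$taxonomy), expected_mb,
    tolerance = 1e-9
  )
  expect_equal(estimate_ags(s$profile, st$taxonomy),
    expected_mb / sum(e$coverage),
    tolerance = 1e-9
  )
})

test_that("microbial_bases sums coverage times genome size, pricing root coverage", {
  tax <- two_species_tax()
  expect_equal(microbial_bases(make_profile(SP2, 2), tax), 8e6)
  expect_equal(microbial_bases(make_profile(c(SP1, SP2), c(1, 0.5)), tax), 4e6)
  # root-assigned coverage priced at root AGS (mean of domains = 3 Mbp here)
  expect_equal(microbial_bases(make_profile("", 2), tax), 6e6)
  empty <- suppressWarnings(make_profile(SP1, 0))
  expect_equal(nrow(empty$entries), 0L)
  expect_equal(microbial_bases(empty, tax), 0)
})

test_that("smf is the microbial percent of total bases, capped at 100 with a warning", {
  tax <- two_species_tax()
  # microbial bases 8 Mbp of 16 Mbp total
  expect_equal(smf(make_profile(SP2, 2, total_bases = 16e6), tax), 50)
  expect_equal(smf(make_profile(SP2, 2, total_bases = 8e6), tax), 100)
  expect_warning(
    capped <- smf(make_profile(SP2, 5, total_bases = 16e6), tax),
    "capping"
  )
  expect_equal(capped, 100)
})

test_that("known_species_fraction is the species-resolved share of coverage", {
  all_sp <- make_profile(c(SP1, SP2), c(1, 2))
  expect_equal(known_species_fraction(all_sp), 100)
  half <- make_profile(c(SP1, "d__Bacteria; p__P; c__C; o__O; f__F; g__G1"), c(1, 1))
  expect_equal(known_species_fraction(half), 50)
  mix <- make_profile(
    c(SP1, "d__Bacteria; p__P; c__C; o__O; f__F", ""),
    c(0.2, 0.3, 0.5)
  )
  expect_equal(known_species_fraction(mix), 20)
})

test_that("domain_fraction excludes root coverage and splits by domain", {
  only_bact <- make_profile(SP1, 1)
  expect_equal(domain_fraction(only_bact, "d__Archaea"), 0)
  mix <- make_profile(c(SP1, "d__Archaea"), c(9.9, 0.1))
  expect_equal(domain_fraction(mix, "d__Archaea"), 1.0)
  even <- make_profile(c("d__Bacteria", "d__Archaea", ""), c(1, 1, 5))
  expect_equal(domain_fraction(even, "d__Bacteria"), 50)
  expect_equal(domain_fraction(even, "d__Archaea"), 50)
  root_only <- make_profile("", 1)
  expect_error(domain_fraction(root_only, "d__Bacteria"), "domain-assigned")
})

test_that("estimate_all composes the per-sample statistics deterministically", {
  tax <- two_species_tax()
  profs <- list(
    make_profile(SP2, 2, total_bases = 16e6, sample_id = "c"),
    make_profile(c(SP1, SP2), c(1, 1), total_bases = 10e6, sample_id = "a"),
    make_profile(SP1, 1, total_bases = 5e6, sample_id = "b")
  )
  est <- estimate_all(profs, tax)
  expect_identical(est$sample, c("a", "b", "c")) # ordered by id
  expect_equal(est$ags_bp[est$sample == "a"], 3e6)
  expect_equal(est$smf_pct[est$sample == "c"], 50)
  expect_equal(est$non_microbial_pct + est$smf_pct, rep(100, 3))
  expect_equal(est$archaea_pct + est$bacteria_pct, rep(100, 3))

  s <- summarize_estimates(data.frame(
    ags_mbp = c(4, 5, 6), smf_pct = c(90, 61.2, 40),
    non_microbial_pct = c(10, 38.8, 60), known_species_pct = 0,
    archaea_pct = 0, bacteria_pct = 100
  ))
  expect_equal(s$median[s$statistic == "non_microbial_pct"], 38.8)
  expect_equal(s$mean[s$statistic == "ags_mbp"], 5)

  expect_error(estimate_all(list(), tax), "at least one")
})

test_that("estimate errors carry the sample id", {
  tax <- two_species_tax()
  bad <- suppressWarnings(make_profile(SP1, 0, sample_id = "empty1"))
  expect_error(estimate_all(list(bad), tax), "empty1")
})

test_that("estimates CSV round-trips with the documented columns", {
  tax <- two_species_tax()
  est <- estimate_all(list(make_profile(c(SP1, SP2), c(1, 1), total_bases = 1e7)), tax)
  f <- withr::local_tempfile(fileext = ".csv")
  sf <- withr::local_tempfile(fileext = ".csv")
  write_estimates(est, f, summary_path = sf)
  back <- read_estimates(f)
  expect_true(all(c(
    "sample", "ags_mbp", "microbial_bases_bp", "smf_pct",
    "non_microbial_pct", "known_species_pct", "archaea_pct", "bacteria_pct"
  ) %in% names(back)))
  expect_equal(back$ags_mbp, est$ags_mbp)
  expect_true(file.exists(sf))
})

test_that("fully resolved profile with exact total bases gives SMF 100 and true AGS", {
  tax <- two_species_tax()
  cov <- c(2, 3)
  sizes <- c(2e6, 4e6)
  p <- make_profile(c(SP1, SP2), cov, total_bases = sum(cov * sizes))
  expect_equal(smf(p, tax), 100)
  expect_equal(estimate_ags(p, tax), sum(cov * sizes) / sum(cov))
})
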