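# Fixture builders and independent oracles shared by the tests. The oracles
# deliberately re-derive everything from first principles (recursive tree
# walks, plain loops) so they stay independent of the package's vectorized
# implementations.

lin7 <- function(p = "P", c = "C", o = "O", f = "F", g = "G", s = "sp1",
                 d = "Bacteria") {
  sprintf(
    "d__%s; p__%s; c__%s; o__%s; f__%s; g__%s; s__%s",
    d, p, c, o, f, g, s
  )
}

make_genomes <- function(lineages, sizes, completeness = 100, contamination = 0) {
  data.frame(
    accession = sprintf("G%03d", seq_along(lineages)),
    lineage = lineages,
    assembly_size = sizes,
    completeness = rep_len(completeness, length(lineages)),
    contamination = rep_len(contamination, length(lineages)),
    stringsAsFactors = FALSE
  )
}

three_genome_fixture <- function() {
  make_genomes(
    c(
      lin7(g = "G1", s = "G1 sp1"),
      lin7(g = "G1", s = "G1 sp2"),
      lin7(g = "G2", s = "G2 sp1")
    ),
    c(2e6, 4e6, 6e6)
  )
}

make_profile <- function(lineages, coverages, total_bases = 1e7,
                         sample_id = "S1", ...) {
  sample_profile(
    sample_id,
    data.frame(lineage = lineages, coverage = coverages, stringsAsFactors = FALSE),
    total_bases, ...
  )
}

# Brute-force taxonomy oracle: recursive level-wise mean over the tree
# implied by the species lineage strings. Returns a named vector
# lineage -> AGS, with the root under "(root)".
oracle_taxonomy_ags <- function(records) {
  corrected <- records$assembly_size * (1 - records$contamination / 100) /
    (records$completeness / 100)
  sp <- tapply(corrected, records$lineage, mean)
  parts_list <- strsplit(names(sp), "; ", fixed = TRUE)
  acc <- list()
  node_ags <- function(path_parts) {
    depth <- length(path_parts)
    path <- paste(path_parts, collapse = "; ")
    if (depth == 7L) {
      v <- unname(sp[[path]])
    } else {
      descends <- vapply(parts_list, function(p) {
        depth == 0L || identical(p[seq_len(depth)], path_parts)
      }, logical(1))
      kids <- unique(vapply(
        parts_list[descends],
        function(p) p[depth + 1L], character(1)
      ))
      v <- mean(vapply(
        kids,
        function(k) node_ags(c(path_parts, k)), numeric(1)
      ))
    }
    acc[[if (path == "") "(root)" else path]] <<- v
    v
  }
  node_ags(character(0))
  unlist(acc)
}
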