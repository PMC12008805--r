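test_that("array geometry is realized exactly, including the empty array", {
  expect_equal(realized_array_length(array_spec(n_units = 0)), 0L)
  expect_equal(realized_array_length(array_spec(n_units = 3)), 6000L)
  expect_equal(
    realized_array_length(array_spec(n_units = 2, intervening_length = 3400)),
    7400L
  )

  g0 <- build_array_genome(array_spec(n_units = 0), 12000, seed = 3)
  expect_equal(g0$array_locus$start, g0$array_locus$end)
  expect_equal(nrow(g0$truth$units), 0L)
  a <- g0$truth$anchors
  expect_equal(a$end[a$side == "5prime"], a$start[a$side == "3prime"])
})

test_that("one- to three-copy genomes list the right unit intervals", {
  for (n in 1:3) {
    g <- fixture_genome(n, seed = 40L + n)
    expect_equal(nrow(g$truth$units), n)
    expect_true(all(g$truth$units$end - g$truth$units$start == 2000L))
  }
})

test_that("interrupted-array sequence re-parses to the declared layout", {
  g <- build_array_genome(array_spec(n_units = 2, intervening_length = 3400),
                          20000, seed = 7)
  expect_equal(g$array_locus$end - g$array_locus$start, 7400L)
  chr <- genome_sequences(g)[[g$array_locus$chrom]]
  # independent re-parse: locate the exact unit occurrences in the emitted
  # sequence and check spacing
  occ <- gregexpr(g$unit_sequence, chr, fixed = TRUE)[[1]]
  expect_equal(length(occ), 2L)
  expect_equal(as.integer(occ), g$truth$units$start + 1L)
  expect_equal(diff(as.integer(occ)), 2000L + 3400L)
})

test_that("genome construction is bit-reproducible and anchors are unique", {
  g1 <- build_array_genome(array_spec(n_units = 2), 15000, seed = 5,
                           n_chromosomes = 2)
  g2 <- build_array_genome(array_spec(n_units = 2), 15000, seed = 5,
                           n_chromosomes = 2)
  expect_identical(genome_sequences(g1), genome_sequences(g2))
  anc <- genome_anchors(g1)
  for (a in anc) {
    expect_equal(
      sum(vapply(genome_sequences(g1), function(s) {
        length(gregexpr(a, s, fixed = TRUE)[[1]][
          gregexpr(a, s, fixed = TRUE)[[1]] > 0])
      }, integer(1))),
      1L
    )
  }
})

test_that("per-copy divergence substitutes at the requested rate", {
  g <- build_array_genome(
    array_spec(n_units = 4, unit_divergence_rate = 0.05), 20000, seed = 9
  )
  chr <- genome_sequences(g)[[g$array_locus$chrom]]
  rates <- vapply(seq_len(4), function(i) {
    u <- g$truth$units[i, ]
    copy <- substring(chr, u$start + 1L, u$end)
    1 - mean(utf8ToInt(copy) == utf8ToInt(g$unit_sequence))
  }, numeric(1))
  expect_true(all(rates > 0.03 & rates < 0.07))
})

test_that("precondition and error paths are enforced", {
  expect_error(build_array_genome(array_spec(n_units = 5), 10000, seed = 1),
               "background_length")
  expect_error(array_spec(n_units = -1))
  expect_error(array_spec(n_units = 1, unit_divergence_rate = 1.5))
})

test_that("engineered rearrangements land where the truth table says", {
  base <- fixture_genome(3, seed = 21L, n_chromosomes = 2L)
  tr <- inject_rearrangement(base, "translocation", seed = 5)
  rec <- tr$truth$rearrangements
  expect_equal(rec$kind, "translocation")
  # chr1 up to the breakpoint is unchanged; beyond it, sequence comes from
  # the partner chromosome
  s_new <- genome_sequences(tr)
  s_old <- genome_sequences(base)
  expect_identical(substring(s_new[["chr1"]], 1, rec$pos),
                   substring(s_old[["chr1"]], 1, rec$pos))
  expect_identical(substring(s_new[["chr1"]], rec$pos + 1, rec$pos + 500),
                   substring(s_old[["chr2"]], rec$partner_pos + 1,
                             rec$partner_pos + 500))

  ec <- inject_rearrangement(base, "ectopic_circle", seed = 6,
                             circle_units = 2)
  rec <- ec$truth$rearrangements
  ins <- substring(genome_sequences(ec)[["chr2"]], rec$pos + 1,
                   rec$partner_pos)
  expect_identical(ins, strrep(base$unit_sequence, 2))

  cg <- inject_rearrangement(base, "chromosome_gain", seed = 7)
  expect_identical(genome_sequences(cg)[["chr1_gain"]],
                   genome_sequences(base)[["chr1"]])
  expect_error(inject_rearrangement(base, "inversion", seed = 1))
})

test_that("genome round-trips through FASTA/BED/JSON on disk", {
  g <- fixture_genome(2, seed = 33L)
  dir <- withr::local_tempdir()
  paths <- write_genome(g, dir)
  expect_true(all(file.exists(paths)))
  fa <- Biostrings::readDNAStringSet(paths[["fasta"]])
  expect_identical(stats::setNames(as.character(fa), names(fa)),
                   genome_sequences(g))
  bed <- rtracklayer::import(paths[["bed"]])
  expect_equal(length(bed), nrow(g$truth$units) + 2L)
  js <- jsonlite::read_json(paths[["json"]], simplifyVector = TRUE)
  expect_equal(js$array_locus$start, g$array_locus$start)
  expect_equal(nrow(js$units), nrow(g$truth$units))
})
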