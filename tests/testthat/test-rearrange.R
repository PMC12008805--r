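test_that("split at units emits the correct flank segments and reconstructs the read", {
  g <- fixture_genome(3, seed = 81L)
  rd <- spanning_read(g, pad = 400)
  sp <- split_at_units(rd, g$unit_sequence)
  expect_true(sp$has_unit)
  expect_equal(sp$n_units, 3L)
  expect_setequal(sp$segments$side, c("5prime", "3prime"))
  five <- sp$segments[sp$segments$side == "5prime", ]
  three <- sp$segments[sp$segments$side == "3prime", ]
  # flanks abut the outermost unit matches; re-concatenation with the
  # discarded core reconstructs the read exactly
  core <- substring(rd, five$read_end + 1L, three$read_start)
  expect_identical(paste0(five$sequence, core, three$sequence), rd)
  # flank truth: the 5' flank ends exactly where the first unit starts
  expect_equal(five$read_end, 400L + 1000L)

  # no unit: passthrough flag
  expect_false(split_at_units(rand_dna(3000, seed = 5),
                              g$unit_sequence)$has_unit)

  # read starting inside the array: only a 3' segment
  chr <- genome_sequences(g)[[g$array_locus$chrom]]
  u <- g$truth$units
  rd2 <- substring(chr, u$start[2] + 100L, max(g$truth$anchors$end) + 400L)
  sp2 <- split_at_units(rd2, g$unit_sequence)
  expect_equal(sp2$segments$side, "3prime")
})

test_that("sub-length flanks are dropped with a count", {
  g <- fixture_genome(2, seed = 82L)
  chr <- genome_sequences(g)[[g$array_locus$chrom]]
  u <- g$truth$units
  rd <- substring(chr, u$start[1] + 1L - 150L, u$end[2] + 150L)
  sp <- split_at_units(rd, g$unit_sequence, min_flank_length = 200L)
  expect_equal(nrow(sp$segments), 0L)
  expect_equal(sp$dropped, 2L)
})

test_that("segments map uniquely to their source locus", {
  g <- fixture_genome(2, seed = 83L, n_chromosomes = 2L)
  idx <- genome_index(g)
  chr2_piece <- substring(genome_sequences(g)[["chr2"]], 2001L, 4000L)
  segs <- data.frame(side = "5prime", read_start = 0L, read_end = 2000L,
                     sequence = chr2_piece, stringsAsFactors = FALSE)
  mapped <- map_segments(segs, idx)
  expect_equal(mapped$status, "mapped")
  expect_equal(mapped$chrom, "chr2")
  expect_equal(mapped$ref_start, 2000L)
  # a repeat-unit sequence in a multi-copy genome is ambiguous
  amb <- map_segments(
    data.frame(side = "5prime", read_start = 0L, read_end = 2000L,
               sequence = g$unit_sequence, stringsAsFactors = FALSE),
    idx
  )
  expect_equal(amb$status, "ambiguous")
})

test_that("clean simulations yield no rearrangement calls at all", {
  g <- fixture_genome(3, seed = 84L, n_chromosomes = 2L)
  idx <- genome_index(g)
  rp <- read_sim_params(
    length_distribution = list(type = "fixed", length = 8000), n_reads = 40,
    seed = 85L
  )
  rs <- simulate_reads(g, rp)
  res <- sv_screen(rs, idx, g$unit_sequence, expected_flank_loci(g))
  s <- res$summary
  expect_equal(s$n[s$classification == "translocation"], 0L)
  expect_equal(s$n[s$classification == "ectopic_integration"], 0L)
  expect_gt(s$n[s$classification == "in_situ"], 0L)
})

test_that("an injected translocation is called with the right breakpoint side", {
  base <- fixture_genome(3, seed = 86L, n_chromosomes = 2L)
  tr <- inject_rearrangement(base, "translocation", seed = 5)
  rec <- tr$truth$rearrangements
  idx <- genome_index(base)
  rs <- simulate_reads(tr, read_sim_params(
    length_distribution = list(type = "fixed", length = 8000), n_reads = 80,
    seed = 87L
  ))
  res <- sv_screen(rs, idx, base$unit_sequence, expected_flank_loci(base))
  calls <- res$calls[res$calls$classification == "translocation", ]
  expect_gt(nrow(calls), 0L)
  # evidence names the partner chromosome near the engineered breakpoint
  expect_true(any(grepl(rec$partner_chrom, calls$evidence)))
})

test_that("an integrated ectopic circle is called at its common locus", {
  base <- fixture_genome(3, seed = 88L, n_chromosomes = 2L)
  ec <- inject_rearrangement(base, "ectopic_circle", seed = 6,
                             circle_units = 2)
  idx <- genome_index(base)
  rs <- simulate_reads(ec, read_sim_params(
    length_distribution = list(type = "fixed", length = 9000), n_reads = 80,
    seed = 89L
  ))
  res <- sv_screen(rs, idx, base$unit_sequence, expected_flank_loci(base))
  ecalls <- res$calls[res$calls$classification == "ectopic_integration", ]
  expect_gt(nrow(ecalls), 0L)
  expect_true(all(grepl("chr2", ecalls$evidence)))
})

test_that("unmapped flanks classify as unmapped, not as rearrangements", {
  g <- fixture_genome(2, seed = 90L)
  idx <- genome_index(g)
  rd <- paste0(rand_dna(1500, seed = 91), g$unit_sequence,
               rand_dna(1500))
  res <- sv_screen(stats::setNames(rd, "alien"), idx, g$unit_sequence,
                   expected_flank_loci(g))
  expect_equal(res$calls$classification, "unmapped")
})
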