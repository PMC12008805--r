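test_that("exact and reverse-complement anchors are located with identity 1", {
  g <- fixture_genome(3, seed = 61L)
  anc <- genome_anchors(g)
  rd <- spanning_read(g, pad = 300)
  h <- locate_anchor(rd, anc$left)
  expect_equal(h$strand, "+")
  expect_equal(h$identity, 1)
  expect_equal(h$read_start, 300)            # pad bases precede the anchor
  expect_equal(h$read_end, 300 + 1000)
  hr <- locate_anchor(bitrexkit:::revcomp(rd), anc$left)
  expect_equal(hr$strand, "-")
  # mirrored coordinates point at the same bases
  expect_equal(nchar(rd) - hr$read_end, h$read_start)
  expect_null(locate_anchor(rd, rand_dna(1000)))
})

test_that("anchors with 5% substitutions are still found at ~0.95 identity", {
  g <- fixture_genome(3, seed = 62L)
  anc <- genome_anchors(g)
  rd <- spanning_read(g)
  set.seed(5)
  for (i in 1:5) {
    rde <- bitrexkit:::add_substitutions(rd, 0.05)
    h <- locate_anchor(rde, anc$left)
    expect_false(is.null(h))
    expect_gt(h$identity, 0.90)
    expect_lt(h$identity, 0.99)
  }
})

test_that("spanning selection matches truth exactly on error-free reads", {
  g <- fixture_genome(5, seed = 63L)
  anc <- genome_anchors(g)
  rp <- read_sim_params(
    length_distribution = list(type = "lognormal", meanlog = log(16000),
                               sdlog = 0.5),
    n_reads = 40, seed = 5
  )
  rs <- simulate_reads(g, rp)
  sel <- select_spanning_reads(rs, anc$left, anc$right)
  expect_identical(sel$spanning, rs$truth$spans_array)
  expect_true(any(sel$spanning))
  expect_error(select_spanning_reads(rs, anc$left, anc$left), "distinct")
})

test_that("reads with inverted anchor order are excluded and flagged", {
  g <- fixture_genome(2, seed = 64L)
  anc <- genome_anchors(g)
  # construct an anomalous molecule: right anchor before left anchor
  rd <- paste0(rand_dna(400), anc$right,
               rand_dna(800), anc$left,
               rand_dna(400))
  sel <- select_spanning_reads(stats::setNames(rd, "inv"), anc$left,
                               anc$right)
  expect_false(sel$spanning)
  expect_true(sel$anomalous)
  # read missing the right anchor is simply excluded
  rd2 <- paste0(rand_dna(400), anc$left,
                rand_dna(800))
  sel2 <- select_spanning_reads(stats::setNames(rd2, "norr"), anc$left,
                                anc$right)
  expect_false(sel2$spanning)
  expect_false(sel2$anomalous)
})

test_that("unit counting equals the exhaustive-substring oracle on clean reads", {
  for (n in c(1L, 3L, 14L)) {
    g <- fixture_genome(n, seed = 65L)
    rd <- spanning_read(g)
    cu <- count_units(rd, g$unit_sequence)
    expect_equal(cu$n_units, n)
    expect_equal(cu$n_units, substring_unit_count(rd, g$unit_sequence))
    expect_equal(nrow(cu$segments), n)
    expect_true(all(cu$segments$strand == "+"))
  }
})

test_that("partial terminal units follow the coverage threshold", {
  g <- fixture_genome(3, seed = 66L)
  chr <- genome_sequences(g)[[g$array_locus$chrom]]
  u <- g$truth$units
  # a read covering 2 full units plus 50% of the third
  rd <- substring(chr, u$start[1] + 1L, u$start[3] + 1000L)
  expect_equal(count_units(rd, g$unit_sequence,
                           min_unit_fraction = 0.6)$n_units, 2L)
  expect_equal(count_units(rd, g$unit_sequence,
                           min_unit_fraction = 0.4)$n_units, 3L)
})

test_that("inverted unit copies are reported on the minus strand", {
  g <- fixture_genome(2, seed = 67L)
  rd <- paste0(rand_dna(300), g$unit_sequence,
               bitrexkit:::revcomp(g$unit_sequence),
               rand_dna(300))
  cu <- count_units(rd, g$unit_sequence)
  expect_equal(cu$n_units, 2L)
  expect_setequal(cu$segments$strand, c("+", "-"))
})

test_that("unit counting survives 5% substitution errors", {
  g <- fixture_genome(8, seed = 68L)
  rd <- spanning_read(g)
  set.seed(12)
  exact <- vapply(1:10, function(i) {
    count_units(bitrexkit:::add_substitutions(rd, 0.05),
                g$unit_sequence)$n_units == 8L
  }, logical(1))
  expect_gte(mean(exact), 0.9)
})

test_that("copy-number distribution summarises counts and rejects emptiness", {
  d <- copy_number_distribution(c(5L, 5L, 5L))
  expect_equal(d$mode, 5L)
  expect_equal(d$max, 5L)
  expect_equal(d$n, 3L)
  d2 <- copy_number_distribution(data.frame(n_units = c(10L, 10L, 20L)))
  expect_equal(d2$mode, 10L)
  expect_equal(d2$max, 20L)
  expect_error(copy_number_distribution(integer(0)), "empty|no spanning")
})

test_that("hit counts agree with unit counts on spanning reads and drop unitless reads", {
  g <- fixture_genome(5, seed = 69L)
  rd <- spanning_read(g)
  other <- rand_dna(3000)
  hc <- hit_count_estimate(c(span = rd, none = other), g$unit_sequence)
  expect_equal(hc$per_read$n_hits[hc$per_read$read_id == "span"], 5L)
  expect_equal(hc$dropped, "none")
  expect_equal(hc$max, 5L)
  expect_error(hit_count_estimate(c(x = other), g$unit_sequence), "unit")
})

test_that("spanning probability is decreasing in array length and enumerable", {
  m_fixed <- ascertainment_model(list(type = "fixed", length = 50),
                                 anchor_length = 0, chrom_length = 100)
  # the worked start-position example: window [35, 65) on C = 100, L = 50
  expect_equal(spanning_probability(m_fixed, 30), 21 / 51)
  m <- ascertainment_model(list(type = "lognormal", meanlog = log(30000),
                                sdlog = 0.5),
                           anchor_length = 1000, chrom_length = 80000,
                           seed = 3)
  p <- spanning_probability(m, c(5, 10, 15, 20) * 2000)
  expect_true(all(diff(p) < 0))
  expect_true(all(p > 0 & p <= 1))
  # arrays longer than the chromosome can never be spanned
  expect_equal(spanning_probability(m, 100 * 2000), 0)
})

test_that("inverse-probability weighting removes the length ascertainment bias", {
  # truth-labelled mixture: equal numbers of 10- and 20-unit molecules,
  # spanning reads ascertained by the analytic probability
  m <- ascertainment_model(list(type = "lognormal", meanlog = log(45000),
                                sdlog = 0.35),
                           anchor_length = 1000, chrom_length = 80000,
                           seed = 4)
  p10 <- spanning_probability(m, 10 * 2000)
  p20 <- spanning_probability(m, 20 * 2000)
  set.seed(31)
  n10 <- stats::rbinom(1, 400, p10)
  n20 <- stats::rbinom(1, 400, p20)
  counts <- data.frame(n_units = c(rep(10L, n10), rep(20L, n20)))
  bc <- bias_corrected_mean(counts, m, unit_length = 2000, n_boot = 400,
                            seed = 6)
  expect_lt(bc$naive_mean, 15)
  expect_lt(abs(bc$mean - 15), abs(bc$naive_mean - 15))
  expect_true(bc$ci[1] <= 15 && 15 <= bc$ci[2])
  expect_true(all(bc$weights > 0))
  # single array length: weights constant, corrected equals naive
  one <- bias_corrected_mean(data.frame(n_units = rep(10L, 50)), m,
                             unit_length = 2000, n_boot = 50, seed = 7)
  expect_equal(one$mean, one$naive_mean)
})

test_that("dot-plot export draws one diagonal per unit copy", {
  g <- fixture_genome(3, seed = 70L)
  rd <- spanning_read(g)
  dp <- export_dotplot(rd, g$unit_sequence)
  segs <- attr(dp, "segments")
  expect_equal(nrow(segs), 3L)
  expect_equal(sort(unique(dp$segment)), 1:3)
  # every emitted point is an exact k-mer anchor of its segment
  expect_true(all(dp$read_pos - dp$unit_pos %in%
                    (segs$read_start - segs$ref_start)))
})
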