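ref_and_reads <- function(n_units, seed, depth = 30, read_len = 300L,
                          error = 0) {
  sp <- array_spec(n_units = n_units)
  bg <- max(12000L, realized_array_length(sp) + 2001L)
  sample_genome <- build_array_genome(sp, bg, seed = seed)
  reference <- build_array_genome(array_spec(n_units = min(n_units, 1L)),
                                 bg, seed = seed)
  rp <- read_sim_params(
    length_distribution = list(type = "fixed", length = read_len),
    depth = depth, substitution_error_rate = error, seed = seed + 1L
  )
  list(sample = sample_genome, reference = reference,
       reads = simulate_reads(sample_genome, rp))
}

array_region <- function(reference) {
  data.frame(chrom = reference$array_locus$chrom,
             start = reference$array_locus$start,
             end = reference$array_locus$end)
}

background_excluding_array <- function(reference, seqlengths, pad = 1000L) {
  bitrexkit:::gr_complement(
    data.frame(chrom = reference$array_locus$chrom,
               start = reference$array_locus$start - pad,
               end = reference$array_locus$end + pad),
    seqlengths
  )
}

test_that("single placements produce unit coverage exactly where placed", {
  sl <- c(chr1 = 1000L)
  prof <- compute_depth(
    placements = data.frame(chrom = "chr1", start = 0L, end = 10L),
    seqlengths = sl, bin_size = 10L
  )
  expect_equal(prof$bins$score[1], 1)
  expect_true(all(prof$bins$score[-1] == 0))
  # empty input: all-zero profile
  empty <- compute_depth(
    placements = data.frame(chrom = character(0), start = integer(0),
                            end = integer(0)),
    seqlengths = sl, bin_size = 100L
  )
  expect_true(all(empty$bins$score == 0))
})

test_that("binned counts conserve total placed bases", {
  set.seed(8)
  sl <- c(chr1 = 5000L, chr2 = 3000L)
  pl <- data.frame(
    chrom = sample(c("chr1", "chr2"), 200, replace = TRUE),
    start = sample(0:2500, 200, replace = TRUE)
  )
  pl$end <- pl$start + sample(50:300, 200, replace = TRUE)
  pl$end <- pmin(pl$end, sl[pl$chrom])
  prof <- compute_depth(placements = pl, seqlengths = sl, bin_size = 100L)
  expect_equal(sum(prof$bins$score) * 100, sum(pl$end - pl$start))
})

test_that("uniform coverage normalizes to 1 and normalization is idempotent", {
  sl <- c(chr1 = 2000L)
  pl <- data.frame(chrom = "chr1", start = seq(0L, 1900L, by = 100L))
  pl$end <- pl$start + 100L
  prof <- normalize_depth(compute_depth(placements = pl, seqlengths = sl,
                                        bin_size = 100L))
  expect_true(all(abs(prof$bins$score - 1) < 1e-12))
  again <- normalize_depth(prof)
  expect_true(all(abs(again$bins$score - prof$bins$score) < 1e-12))
  expect_error(
    normalize_depth(prof, mask = data.frame(chrom = "chr1", start = 0L,
                                            end = 2000L)),
    "background"
  )
})

test_that("masked-duplicate mapping recovers the simulated copy number", {
  x <- ref_and_reads(5, seed = 71L)
  idx <- genome_index(x$reference)
  prof <- compute_depth(reads = x$reads, index = idx)
  prof <- normalize_depth(
    prof, background = background_excluding_array(x$reference, idx$seqlengths)
  )
  cn <- region_copy_number(prof, array_region(x$reference))
  expect_lt(abs(cn$mean - 5) / 5, 0.1)
  # background sits at 1
  bgcn <- region_copy_number(
    prof, data.frame(chrom = "chr1", start = 0L, end = 3000L)
  )
  expect_lt(abs(bgcn$mean - 1), 0.1)
})

test_that("region summaries respect masks and flag single-bin regions", {
  sl <- c(chr1 = 2000L)
  pl <- data.frame(chrom = "chr1", start = seq(0L, 1900L, by = 100L))
  pl$end <- pl$start + 100L
  prof <- normalize_depth(compute_depth(placements = pl, seqlengths = sl,
                                        bin_size = 100L))
  one <- region_copy_number(prof, data.frame(chrom = "chr1", start = 0L,
                                             end = 100L))
  expect_true(one$sd_undefined)
  expect_equal(one$n_bins, 1L)
  masked <- normalize_depth(
    compute_depth(placements = pl, seqlengths = sl, bin_size = 100L),
    mask = data.frame(chrom = "chr1", start = 0L, end = 500L)
  )
  expect_error(
    region_copy_number(masked, data.frame(chrom = "chr1", start = 0L,
                                          end = 500L)),
    "masked|unmasked"
  )
})

test_that("region ratio reads out relative copy number", {
  x <- ref_and_reads(17, seed = 72L)
  idx <- genome_index(x$reference)
  prof <- normalize_depth(
    compute_depth(reads = x$reads, index = idx),
    background = background_excluding_array(x$reference, idx$seqlengths)
  )
  expect_equal(
    region_ratio(prof, array_region(x$reference), array_region(x$reference)),
    1
  )
  flank <- data.frame(chrom = "chr1", start = 0L, end = 4000L)
  r <- region_ratio(prof, array_region(x$reference), flank)
  expect_lt(abs(r - 17) / 17, 0.1)
})

test_that("ploidy calls flag a gained chromosome and use strict thresholds", {
  base <- fixture_genome(2, seed = 73L, n_chromosomes = 2L)
  gained <- inject_rearrangement(base, "chromosome_gain", seed = 3,
                                 chrom = "chr2")
  rp <- read_sim_params(
    length_distribution = list(type = "fixed", length = 300), depth = 20,
    seed = 74L
  )
  rs <- simulate_reads(gained, rp)
  # reads from the duplicate place on the original chr2 of the reference;
  # normalize against the non-array part of chr1, which is unaffected by
  # the gain, so chr2 reads out its doubled dosage
  idx <- genome_index(base)
  chr1_len <- idx$seqlengths[["chr1"]]
  prof <- normalize_depth(
    compute_depth(reads = rs, index = idx),
    background = data.frame(
      chrom = "chr1",
      start = c(0L, base$array_locus$end + 1000L),
      end = c(base$array_locus$start - 1000L, chr1_len)
    )
  )
  calls <- chromosome_ploidy(
    prof, exclude = data.frame(chrom = "chr1",
                               start = base$array_locus$start - 1000L,
                               end = base$array_locus$end + 1000L)
  )
  expect_equal(calls$call[calls$chrom == "chr2"], "gain")
  expect_equal(calls$call[calls$chrom == "chr1"], "euploid")
  expect_gt(calls$mean_depth[calls$chrom == "chr2"], 1.7)
  # strict inequality at the threshold: a mean of exactly 1.25 is euploid
  sl <- c(chrA = 1000L)
  pl <- data.frame(chrom = "chrA", start = seq(0L, 900L, by = 100L))
  pl$end <- pl$start + 100L
  prof2 <- compute_depth(placements = pl, seqlengths = sl, bin_size = 100L)
  prof2$bins$score <- rep(1.25, length(prof2$bins))
  prof2$normalized <- TRUE
  expect_equal(chromosome_ploidy(prof2)$call, "euploid")
})

test_that("normalized profiles export as bedGraph", {
  sl <- c(chr1 = 1000L)
  pl <- data.frame(chrom = "chr1", start = 0L, end = 1000L)
  prof <- normalize_depth(compute_depth(placements = pl, seqlengths = sl,
                                        bin_size = 100L))
  path <- withr::local_tempfile(fileext = ".bedgraph")
  write_depth_bedgraph(prof, path)
  back <- rtracklayer::import(path, format = "bedGraph")
  expect_equal(sum(back$score * IRanges::width(back)) / 1000, 1)
})
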