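#' Locate a flank anchor on a read
#'
#' Searches a read for a unique flank anchor (the ~1-kb sequences
#' immediately up/downstream of the array used to select spanning reads):
#' k-mer seeds on both strands are chained into diagonal segments, the
#' highest-scoring chains (most seeds, then leftmost on the read) are
#' extended along their diagonal to the full anchor, clipped at the read
#' ends, and scored by base identity. The best candidate is returned if its
#' identity and anchor coverage both reach their floors.
#'
#' @param read read sequence.
#' @param anchor_sequence anchor sequence (length >= `k`).
#' @param min_identity identity floor over the aligned region (default 0.8).
#' @param k seed length (default 15).
#' @param min_coverage minimum fraction of the anchor covered (default 0.8).
#' @return a list (`read_start`, `read_end`, `ref_start`, `ref_end`,
#'   `strand`, `identity`, `coverage`, `n_seeds`) or `NULL` when the anchor
#'   is absent.
#' @export
locate_anchor <- function(read, anchor_sequence, min_identity = 0.8,
                          k = 15L, min_coverage = 0.8) {
  if (nchar(anchor_sequence) < k) stop("anchor shorter than seed length k")
  segs <- chain_segments(read, anchor_sequence, k = k, min_seeds = 3L)
  if (nrow(segs) == 0L) return(NULL)
  segs <- segs[order(-segs$n_seeds, segs$read_start), , drop = FALSE]
  best <- NULL
  for (i in seq_len(min(nrow(segs), 5L))) {
    cand <- project_and_score(read, anchor_sequence, segs[i, ])
    if (is.null(cand)) next
    if (cand$identity >= min_identity && cand$coverage >= min_coverage) {
      if (is.null(best) ||
          cand$identity * cand$coverage > best$identity * best$coverage) {
        best <- cand
      }
    }
  }
  best
}

#' Select reads spanning the whole array
#'
#' A read spans the array iff both flank anchors are found on it, on a
#' consistent strand, with the 5' anchor preceding the 3' anchor in array
#' orientation. Reads carrying both anchors in inverted order are excluded
#' and flagged anomalous (they indicate a rearranged molecule, not a
#' spanning one).
#'
#' @param reads named character vector of read sequences (or a
#'   [simulate_reads()] result).
#' @param left_anchor,right_anchor the 5' and 3' flank anchor sequences
#'   (must differ).
#' @param min_identity,k passed to [locate_anchor()].
#' @return a `data.frame` with one row per read: `read_id`, `spanning`,
#'   `anomalous`, `strand`, left/right anchor coordinates (`NA` when
#'   absent). Spanning rows carry the skeleton [count_units()] fills in.
#' @export
select_spanning_reads <- function(reads, left_anchor, right_anchor,
                                  min_identity = 0.8, k = 15L) {
  if (is.list(reads)) reads <- reads$sequences
  if (identical(left_anchor, right_anchor)) {
    stop("left and right anchors must be distinct sequences")
  }
  rows <- lapply(names(reads), function(id) {
    rd <- reads[[id]]
    lh <- locate_anchor(rd, left_anchor, min_identity = min_identity, k = k)
    rh <- locate_anchor(rd, right_anchor, min_identity = min_identity, k = k)
    # spanning demands the complete anchors on the read: substitutions do
    # not reduce coverage, only a read end truncating the anchor does, so
    # full coverage is exactly the "fully spans" truth condition
    if (!is.null(lh) && lh$coverage < 0.999) lh <- NULL
    if (!is.null(rh) && rh$coverage < 0.999) rh <- NULL
    spanning <- FALSE
    anomalous <- FALSE
    strand <- NA_character_
    if (!is.null(lh) && !is.null(rh) && lh$strand == rh$strand) {
      strand <- lh$strand
      ordered <- if (strand == "+") lh$read_end <= rh$read_start else
        rh$read_end <= lh$read_start
      if (ordered) spanning <- TRUE else anomalous <- TRUE
    }
    data.frame(
      read_id = id, spanning = spanning, anomalous = anomalous,
      strand = strand,
      left_start = if (is.null(lh)) NA_integer_ else lh$read_start,
      left_end = if (is.null(lh)) NA_integer_ else lh$read_end,
      right_start = if (is.null(rh)) NA_integer_ else rh$read_start,
      right_end = if (is.null(rh)) NA_integer_ else rh$read_end,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

merge_read_overlaps <- function(segs) {
  # accepted unit segments must not overlap on the read; segments whose
  # read intervals overlap by more than half the shorter one are collapsed
  if (nrow(segs) <= 1L) return(segs)
  segs <- segs[order(segs$read_start, -segs$read_end), , drop = FALSE]
  keep <- rep(TRUE, nrow(segs))
  last <- 1L
  for (i in 2L:nrow(segs)) {
    ov <- min(segs$read_end[last], segs$read_end[i]) -
      max(segs$read_start[last], segs$read_start[i])
    shorter <- min(segs$read_end[i] - segs$read_start[i],
                   segs$read_end[last] - segs$read_start[last])
    if (ov > 0.5 * shorter) {
      keep[i] <- FALSE
    } else {
      last <- i
    }
  }
  segs[keep, , drop = FALSE]
}

#' Count repeat units on a read (automated dot-plot diagonal count)
#'
#' Replaces manual counting of diagonal lines in a read-versus-unit dot
#' plot: every local match of the repeat unit on the read is found by
#' seeding and diagonal chaining ([chain_segments()]), maximal diagonal
#' segments are the candidate unit copies, and a segment counts as one unit
#' iff it covers at least `min_unit_fraction` of the unit — the declared
#' handling of partial terminal diagonals. Overlapping accepted segments
#' are merged so each stretch of read is counted once.
#'
#' @param read read sequence.
#' @param unit_reference the repeat-unit reference sequence (>= 50 bp).
#' @param min_unit_fraction minimum unit coverage for a segment to count
#'   (default 0.6).
#' @param k seed length.
#' @param gap_tol see [chain_segments()] (default 10% of the unit length).
#' @return a list of class `spanning_read_result`: `n_units`, `segments`
#'   (accepted unit segments), `all_segments` (including sub-threshold
#'   ones).
#' @export
count_units <- function(read, unit_reference, min_unit_fraction = 0.6,
                        k = 15L, gap_tol = NULL) {
  if (nchar(unit_reference) < 50L) {
    stop("unit_reference must be at least 50 bp")
  }
  segs <- chain_segments(read, unit_reference, k = k, gap_tol = gap_tol)
  accepted <- segs[segs$ref_coverage >= min_unit_fraction, , drop = FALSE]
  accepted <- merge_read_overlaps(accepted)
  rownames(accepted) <- NULL
  structure(
    list(n_units = nrow(accepted), segments = accepted, all_segments = segs),
    class = "spanning_read_result"
  )
}

#' @export
print.spanning_read_result <- function(x, ...) {
  cat("spanning_read_result:", x$n_units, "repeat unit(s);",
      nrow(x$all_segments), "raw diagonal segment(s)\n")
  invisible(x)
}

#' Count units on every spanning read
#'
#' Convenience wrapper: runs [select_spanning_reads()] then [count_units()]
#' on each spanning read, returning the per-read table the population
#' summaries consume.
#'
#' @inheritParams select_spanning_reads
#' @param unit_reference repeat-unit reference sequence.
#' @param min_unit_fraction passed to [count_units()].
#' @return a `data.frame`: `read_id`, `n_units`, `strand`.
#' @export
span_count <- function(reads, left_anchor, right_anchor, unit_reference,
                       min_identity = 0.8, min_unit_fraction = 0.6,
                       k = 15L) {
  if (is.list(reads)) reads <- reads$sequences
  sel <- select_spanning_reads(reads, left_anchor, right_anchor,
                               min_identity = min_identity, k = k)
  sp <- sel[sel$spanning, , drop = FALSE]
  n_units <- vapply(sp$read_id, function(id) {
    count_units(reads[[id]], unit_reference,
                min_unit_fraction = min_unit_fraction, k = k)$n_units
  }, integer(1))
  data.frame(read_id = sp$read_id,
             n_units = as.integer(n_units),
             strand = sp$strand,
             stringsAsFactors = FALSE)
}

#' Copy-number distribution over spanning reads
#'
#' @param results a `data.frame` with an `n_units` column (e.g. from
#'   [span_count()]), or an integer vector of per-read counts.
#' @return a list: `histogram` (named table over `n_units`), `mode`, `max`,
#'   `n`. Errors on empty input — no spanning read means no per-molecule
#'   genotype.
#' @export
copy_number_distribution <- function(results) {
  counts <- if (is.data.frame(results)) results$n_units else results
  if (length(counts) == 0L) stop("no spanning reads: empty copy-number input")
  h <- table(counts)
  list(
    histogram = h,
    mode = as.integer(names(h)[which.max(h)]),
    max = max(counts),
    n = length(counts)
  )
}

#' Per-read unit hit counts for unit-containing reads
#'
#' The read-depth-free copy-number estimate from local unit matches: every
#' read already known to contain the unit is scanned with the same matcher
#' as [count_units()], without requiring the read to span the array, and the
#' per-read hit counts are aggregated. How per-read counts collapse to one
#' copy number is ambiguous for non-spanning reads (a read sees only part of
#' the array), so the full distribution and its maximum are reported rather
#' than a single number.
#'
#' @param reads named character vector of reads pre-filtered to those
#'   containing the unit; reads without any unit match are dropped from the
#'   aggregate (and listed in `dropped`).
#' @param unit_reference repeat-unit reference sequence.
#' @param min_unit_fraction passed to [count_units()].
#' @param k seed length.
#' @return a list: `per_read` (data frame `read_id`, `n_hits`),
#'   `distribution` (table), `max`, `dropped` (read ids with zero hits).
#' @export
hit_count_estimate <- function(reads, unit_reference,
                               min_unit_fraction = 0.6, k = 15L) {
  if (is.list(reads)) reads <- reads$sequences
  if (length(reads) == 0L) stop("empty read set")
  hits <- vapply(names(reads), function(id) {
    count_units(reads[[id]], unit_reference,
                min_unit_fraction = min_unit_fraction, k = k)$n_units
  }, integer(1))
  keep <- hits > 0L
  if (!any(keep)) stop("no read contains the unit")
  per_read <- data.frame(read_id = names(reads)[keep],
                         n_hits = as.integer(hits[keep]),
                         stringsAsFactors = FALSE)
  list(per_read = per_read,
       distribution = table(per_read$n_hits),
       max = max(per_read$n_hits),
       dropped = names(reads)[!keep])
}

#' Ascertainment model for spanning reads
#'
#' Longer arrays are seen less often among spanning reads: a read spans the
#' array only if it covers the array plus both anchors, a window of
#' `S = A + 2 a` bp. For a read of length `L` starting uniformly at one of
#' the `C - L + 1` admissible positions on a chromosome of length `C`,
#' `P(span | A, L) = max(L - S + 1, 0) / (C - L + 1)`; the model averages
#' this over the read-length distribution by direct Monte Carlo of the
#' length law (closed-form for fixed lengths).
#'
#' @param length_distribution as in [read_sim_params()].
#' @param anchor_length flank anchor length `a` (bp).
#' @param chrom_length chromosome length `C` (bp).
#' @param n_mc Monte Carlo draws for lognormal lengths.
#' @param seed seed for the Monte Carlo average.
#' @return an object of class `ascertainment_model`; use
#'   [spanning_probability()] to evaluate it.
#' @export
ascertainment_model <- function(length_distribution, anchor_length,
                                chrom_length, n_mc = 200000L, seed = 1L) {
  lens <- if (length_distribution$type == "fixed") {
    as.numeric(length_distribution$length)
  } else {
    with_seed(derive_seed(seed, 5L), {
      pmax(round(stats::rlnorm(n_mc, length_distribution$meanlog,
                               length_distribution$sdlog)), 1)
    })
  }
  lens <- pmin(lens, chrom_length)
  structure(
    list(lengths = lens, anchor_length = anchor_length,
         chrom_length = chrom_length),
    class = "ascertainment_model"
  )
}

#' Spanning probability for a given array length
#'
#' @param model an [ascertainment_model()].
#' @param array_length array length `A` in bp (vectorized).
#' @return `P(span | A)`, decreasing in `A`.
#' @export
spanning_probability <- function(model, array_length) {
  C <- model$chrom_length
  vapply(array_length, function(A) {
    S <- A + 2 * model$anchor_length
    # spanning starts can never exceed the admissible starts C - L + 1
    # (reads nearly as long as the chromosome span wherever they start)
    mean(pmin(pmax(model$lengths - S + 1, 0), C - model$lengths + 1) /
           (C - model$lengths + 1))
  }, numeric(1))
}

#' Ascertainment-bias-corrected mean copy number
#'
#' The naive mean over spanning reads is biased low because long arrays are
#' spanned less often. Each read is reweighted by the inverse of its
#' spanning probability, `1 / P(span | A(n))` with
#' `A(n) = n * unit_length + 2 * anchor_length` — a Horvitz-Thompson
#' estimate of the population mean copy number — with a case-resampling
#' bootstrap percentile interval. Reads whose spanning probability is zero
#' under the model cannot be reweighted and are excluded with a warning.
#'
#' @param results data frame with `n_units` (e.g. [span_count()] output).
#' @param model an [ascertainment_model()].
#' @param unit_length repeat unit length (bp).
#' @param n_boot bootstrap draws.
#' @param conf confidence level.
#' @param seed bootstrap seed.
#' @return a list: `mean` (corrected), `naive_mean`, `ci`, `weights`, `n`.
#' @export
bias_corrected_mean <- function(results, model, unit_length = 2000L,
                                n_boot = 1000L, conf = 0.95, seed = 1L) {
  counts <- if (is.data.frame(results)) results$n_units else results
  if (length(counts) == 0L) stop("no spanning-read results")
  A <- counts * unit_length    # anchors enter through the +2a in the model
  p <- spanning_probability(model, A)
  if (any(p <= 0)) {
    warning(sum(p <= 0), " read(s) with zero spanning probability excluded")
    counts <- counts[p > 0]
    p <- p[p > 0]
    if (length(counts) == 0L) stop("all reads had zero spanning probability")
  }
  w <- 1 / p
  est <- sum(w * counts) / sum(w)
  boot <- with_seed(derive_seed(seed, 11L), {
    vapply(seq_len(n_boot), function(b) {
      i <- sample.int(length(counts), replace = TRUE)
      sum(w[i] * counts[i]) / sum(w[i])
    }, numeric(1))
  })
  a <- (1 - conf) / 2
  list(mean = est,
       naive_mean = mean(counts),
       ci = unname(stats::quantile(boot, c(a, 1 - a))),
       weights = w,
       n = length(counts))
}

#' Export dot-plot match coordinates for a read
#'
#' Emits the table behind a read-versus-unit dot plot: one row per accepted
#' seed-chain anchor match, with read position, unit position, strand, and
#' the id of the diagonal segment it belongs to, ready for scatter
#' plotting. Segment boundaries are annotated in the companion `segments`
#' attribute.
#'
#' @param read read sequence.
#' @param unit_reference repeat-unit reference sequence.
#' @param k seed length.
#' @param gap_tol see [chain_segments()].
#' @return a `data.frame` (`read_pos`, `unit_pos`, `strand`, `segment`);
#'   attribute `"segments"` holds the [chain_segments()] table.
#' @export
export_dotplot <- function(read, unit_reference, k = 15L, gap_tol = NULL) {
  segs <- chain_segments(read, unit_reference, k = k, gap_tol = gap_tol)
  if (is.null(gap_tol)) {
    gap_tol <- max(2L * k, round(0.1 * nchar(unit_reference)))
  }
  idx <- kmer_table(unit_reference, k)
  rows <- list()
  L <- nchar(read)
  fw <- seed_hits(read, idx, k)
  if (nrow(fw)) {
    rows[[1]] <- data.frame(read_pos = fw$rpos, unit_pos = fw$qpos,
                            strand = "+", stringsAsFactors = FALSE)
  }
  rc <- revcomp(read)
  rv <- seed_hits(rc, idx, k)
  if (nrow(rv)) {
    rows[[2]] <- data.frame(read_pos = L - rv$rpos - k, unit_pos = rv$qpos,
                            strand = "-", stringsAsFactors = FALSE)
  }
  pts <- do.call(rbind, rows)
  if (is.null(pts)) {
    pts <- data.frame(read_pos = integer(0), unit_pos = integer(0),
                      strand = character(0), segment = integer(0))
    attr(pts, "segments") <- segs
    return(pts)
  }
  pts$segment <- NA_integer_
  if (nrow(segs)) {
    for (i in seq_len(nrow(segs))) {
      inseg <- pts$strand == segs$strand[i] &
        pts$read_pos >= segs$read_start[i] &
        pts$read_pos + k <= segs$read_end[i]
      pts$segment[inseg & is.na(pts$segment)] <- i
    }
  }
  pts <- pts[!is.na(pts$segment), , drop = FALSE]
  rownames(pts) <- NULL
  attr(pts, "segments") <- segs
  pts
}
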