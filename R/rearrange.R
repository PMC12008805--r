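# Split-read screen for rearrangements involving the array locus.
#
# Reads containing the repeat unit are split at the unit occurrences; the
# sequence before the first unit segment is the 5' flank, the sequence
# after the last the 3' flank, and the repetitive core is discarded. Each
# flank is mapped uniquely to the expected genome and reduced to its
# breakpoint: the position where it abuts the array in read orientation.
# Breakpoints at the expected array edges mean the array is in place;
# breakpoints elsewhere are rearrangement evidence.

#' Split a read at its repeat-unit occurrences
#'
#' @param read read sequence.
#' @param unit_reference repeat-unit reference sequence.
#' @param min_flank_length flank segments shorter than this are dropped
#'   (default 200 bp — too short to map uniquely next to a repeat).
#' @param min_unit_fraction,k passed to [count_units()].
#' @return a list: `has_unit` (flag; reads without a unit match pass
#'   through untouched), `segments` (data frame with `side`
#'   `"5prime"`/`"3prime"`, `read_start`, `read_end`, `sequence`),
#'   `dropped` (count of sub-length flanks), `n_units`.
#' @export
split_at_units <- function(read, unit_reference, min_flank_length = 200L,
                           min_unit_fraction = 0.6, k = 15L) {
  cu <- count_units(read, unit_reference,
                    min_unit_fraction = min_unit_fraction, k = k)
  empty <- data.frame(side = character(0), read_start = integer(0),
                      read_end = integer(0), sequence = character(0),
                      stringsAsFactors = FALSE)
  if (cu$n_units == 0L) {
    return(list(has_unit = FALSE, segments = empty, dropped = 0L,
                n_units = 0L))
  }
  L <- nchar(read)
  first_start <- min(cu$segments$read_start)
  last_end <- max(cu$segments$read_end)
  segs <- list()
  dropped <- 0L
  if (first_start > 0L) {
    if (first_start >= min_flank_length) {
      segs[[length(segs) + 1L]] <- data.frame(
        side = "5prime", read_start = 0L, read_end = first_start,
        sequence = substring(read, 1L, first_start), stringsAsFactors = FALSE)
    } else dropped <- dropped + 1L
  }
  if (last_end < L) {
    if (L - last_end >= min_flank_length) {
      segs[[length(segs) + 1L]] <- data.frame(
        side = "3prime", read_start = last_end, read_end = L,
        sequence = substring(read, last_end + 1L, L),
        stringsAsFactors = FALSE)
    } else dropped <- dropped + 1L
  }
  list(has_unit = TRUE,
       segments = if (length(segs)) do.call(rbind, segs) else empty,
       dropped = dropped, n_units = cu$n_units)
}

#' Map flank segments onto a genome
#'
#' Places each flank segment with the unique-best-placement rule of
#' [place_sequence()]; multi-mapped segments come back `ambiguous` and are
#' never used as rearrangement evidence. Each mapped segment is reduced to
#' its breakpoint: the reference position of the flank end that abuts the
#' array in read orientation (the 3' end of a 5' flank, the 5' end of a 3'
#' flank, strand-corrected).
#'
#' @param segments the `segments` data frame from [split_at_units()].
#' @param index a [genome_index()] of the expected genome.
#' @param min_identity identity floor.
#' @return the data frame with added columns `chrom`, `ref_start`,
#'   `ref_end`, `mapped_strand`, `breakpoint`, `status`.
#' @export
map_segments <- function(segments, index, min_identity = 0.8) {
  add <- data.frame(chrom = character(0), ref_start = integer(0),
                    ref_end = integer(0), mapped_strand = character(0),
                    breakpoint = integer(0), status = character(0),
                    stringsAsFactors = FALSE)
  if (nrow(segments) == 0L) return(cbind(segments, add[0, ]))
  res <- lapply(seq_len(nrow(segments)), function(i) {
    pl <- place_sequence(segments$sequence[i], index,
                         min_identity = min_identity)
    if (pl$status != "mapped") {
      return(data.frame(chrom = NA_character_, ref_start = NA_integer_,
                        ref_end = NA_integer_, mapped_strand = NA_character_,
                        breakpoint = NA_integer_, status = pl$status,
                        stringsAsFactors = FALSE))
    }
    # array-proximal end of the flank, in reference coordinates
    proximal_is_end <- segments$side[i] == "5prime"   # in read orientation
    if (pl$strand == "-") proximal_is_end <- !proximal_is_end
    bp <- if (proximal_is_end) pl$ref_end else pl$ref_start
    data.frame(chrom = pl$chrom, ref_start = pl$ref_start,
               ref_end = pl$ref_end, mapped_strand = pl$strand,
               breakpoint = bp, status = "mapped", stringsAsFactors = FALSE)
  })
  cbind(segments, do.call(rbind, res))
}

near_expected <- function(chrom, bp, expected, window) {
  (!is.na(chrom)) &
    ((chrom == expected$left$chrom &
        abs(bp - expected$left$pos) <= window) |
       (chrom == expected$right$chrom &
          abs(bp - expected$right$pos) <= window))
}

#' Classify split reads against the expected flank loci
#'
#' A read is `in_situ` when every usable flank breakpoint lies within
#' `window` of an expected array edge; `translocation` when a uniquely
#' mapped breakpoint lies elsewhere (one-sided evidence suffices);
#' `ectopic_integration` when both flanks are off-site but land close
#' together at a common locus — the signature of an excised repeat circle
#' re-integrated elsewhere; `unmapped` when no flank placed; `ambiguous`
#' otherwise (including multi-mapped flanks, which are never evidence).
#'
#' @param read_results a list of per-read results, each a list with
#'   `read_id` and the mapped `segments` from [map_segments()].
#' @param expected a list with `left` and `right`, each
#'   `list(chrom =, pos =)`: the positions where the flanks abut the array
#'   (the array start for `left`, the array end for `right`, 0-based).
#' @param window tolerance around the expected positions (default 2000 bp).
#' @return a list: `calls` (data frame `read_id`, `classification`,
#'   `evidence`), `summary` (per-class counts and rates).
#' @export
classify_rearrangements <- function(read_results, expected, window = 2000L) {
  if (is.null(expected$left) || is.null(expected$right)) {
    stop("expected flank loci (left, right) must be supplied")
  }
  calls <- lapply(read_results, function(rr) {
    segs <- rr$segments
    mapped <- segs[segs$status == "mapped", , drop = FALSE]
    cls <- if (nrow(segs) == 0L) {
      "ambiguous"                          # read entirely repeat: uninformative
    } else if (nrow(mapped) == 0L) {
      if (all(segs$status == "unmapped")) "unmapped" else "ambiguous"
    } else {
      ok <- near_expected(mapped$chrom, mapped$breakpoint, expected, window)
      n_away <- sum(!ok)
      if (n_away == 0L && nrow(mapped) == nrow(segs)) {
        "in_situ"
      } else if (n_away == 0L) {
        "ambiguous"                        # in place but a flank didn't map
      } else if (n_away == 2L) {
        away <- mapped[!ok, , drop = FALSE]
        if (away$chrom[1] == away$chrom[2] &&
            abs(away$breakpoint[1] - away$breakpoint[2]) <= 10L * window) {
          "ectopic_integration"
        } else "translocation"
      } else {
        "translocation"
      }
    }
    ev <- if (nrow(segs) == 0L) "" else {
      paste(sprintf("%s:%s:%s", segs$side,
                    ifelse(is.na(segs$chrom), segs$status, segs$chrom),
                    ifelse(is.na(segs$breakpoint), "-", segs$breakpoint)),
            collapse = ";")
    }
    data.frame(read_id = rr$read_id, classification = cls,
               evidence = ev, stringsAsFactors = FALSE)
  })
  calls <- do.call(rbind, calls)
  lvls <- c("in_situ", "translocation", "ectopic_integration", "unmapped",
            "ambiguous")
  counts <- table(factor(calls$classification, levels = lvls))
  list(calls = calls,
       summary = data.frame(classification = lvls,
                            n = as.integer(counts),
                            rate = as.numeric(counts) / max(nrow(calls), 1L),
                            stringsAsFactors = FALSE))
}

#' Expected flank loci of a synthetic genome
#'
#' Convenience accessor: the array edges recorded in a genome's truth
#' table, in the form [classify_rearrangements()] expects.
#'
#' @param genome a [build_array_genome()] result.
#' @return `list(left = list(chrom, pos), right = list(chrom, pos))`.
#' @export
expected_flank_loci <- function(genome) {
  stopifnot(inherits(genome, "repeat_array_genome"))
  list(
    left = list(chrom = genome$array_locus$chrom,
                pos = genome$array_locus$start),
    right = list(chrom = genome$array_locus$chrom,
                 pos = genome$array_locus$end)
  )
}

#' End-to-end rearrangement screen over a read set
#'
#' Runs [split_at_units()], [map_segments()] and
#' [classify_rearrangements()] over all reads; reads without a unit match
#' are skipped (they carry no information about the array locus).
#'
#' @param reads named character vector of reads (or [simulate_reads()]
#'   output).
#' @param index a [genome_index()] of the expected (pre-rearrangement)
#'   genome.
#' @param unit_reference repeat-unit reference sequence.
#' @param expected expected flank loci, as in [classify_rearrangements()]
#'   or from [expected_flank_loci()].
#' @param min_flank_length,window see the per-step functions.
#' @return as [classify_rearrangements()], plus `n_reads_screened` and
#'   `n_reads_with_unit`.
#' @export
sv_screen <- function(reads, index, unit_reference, expected,
                      min_flank_length = 200L, window = 2000L) {
  if (is.list(reads) && !is.null(reads$sequences)) reads <- reads$sequences
  results <- list()
  n_unit <- 0L
  for (id in names(reads)) {
    sp <- split_at_units(reads[[id]], unit_reference,
                         min_flank_length = min_flank_length)
    if (!sp$has_unit) next
    n_unit <- n_unit + 1L
    mapped <- map_segments(sp$segments, index)
    results[[length(results) + 1L]] <- list(read_id = id, segments = mapped)
  }
  if (length(results) == 0L) {
    return(list(calls = data.frame(read_id = character(0),
                                   classification = character(0),
                                   evidence = character(0)),
                summary = NULL,
                n_reads_screened = length(reads), n_reads_with_unit = 0L))
  }
  out <- classify_rearrangements(results, expected, window = window)
  out$n_reads_screened <- length(reads)
  out$n_reads_with_unit <- n_unit
  out
}
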