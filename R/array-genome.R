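#' Declarative description of a tandem repeat array
#'
#' An `array_spec` describes the geometry of a tandem gene array before any
#' sequence is drawn: `n_units` identical (or slightly diverged) copies of a
#' `unit_length`-bp repeat unit, optionally separated by an intervening
#' segment (an interrupted array, as produced by plasmid integration between
#' two unit copies), flanked on both sides by unique anchor sequences used
#' for spanning-read selection.
#'
#' The realized array length is
#' `n_units * unit_length + max(n_units - 1, 0) * intervening_length`.
#'
#' @param n_units non-negative integer number of repeat-unit copies.
#' @param unit_length repeat unit length in bp (default 2000, a gene-sized
#'   unit such as the ~2-kb CUP1 repeat or the 3.3-kb D4Z4 macrosatellite).
#' @param intervening_length bp of unique sequence between consecutive unit
#'   copies; 0 gives an uninterrupted array.
#' @param flank_anchor_length length of the unique flank anchors (default
#'   1000 bp, matching the 1-kb flank queries used for spanning-read
#'   selection).
#' @param unit_divergence_rate per-base substitution probability applied
#'   independently to every unit copy, emulating paralog-like divergence.
#' @param locus_offset 0-based position of the array start within the
#'   background chromosome; `NULL` centres the array.
#' @return an object of class `array_spec`.
#' @export
array_spec <- function(n_units,
                       unit_length = 2000L,
                       intervening_length = 0L,
                       flank_anchor_length = 1000L,
                       unit_divergence_rate = 0,
                       locus_offset = NULL) {
  stopifnot(
    n_units >= 0, n_units == as.integer(n_units),
    unit_length >= 1,
    intervening_length >= 0,
    flank_anchor_length >= 1,
    unit_divergence_rate >= 0, unit_divergence_rate <= 1
  )
  structure(
    list(
      n_units = as.integer(n_units),
      unit_length = as.integer(unit_length),
      intervening_length = as.integer(intervening_length),
      flank_anchor_length = as.integer(flank_anchor_length),
      unit_divergence_rate = unit_divergence_rate,
      locus_offset = if (is.null(locus_offset)) NULL else as.integer(locus_offset)
    ),
    class = "array_spec"
  )
}

#' Realized length of the array described by an `array_spec`
#' @param spec an [array_spec()].
#' @return integer length in bp.
#' @export
realized_array_length <- function(spec) {
  spec$n_units * spec$unit_length +
    max(spec$n_units - 1L, 0L) * spec$intervening_length
}

random_dna <- function(n) {
  if (n <= 0) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# substitute exactly at `hit` positions, always to a different base
substitute_bases <- function(seq, hit) {
  if (length(hit) == 0L) return(seq)
  bases <- strsplit(seq, "", fixed = TRUE)[[1]]
  alt <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
              G = c("A", "C", "T"), T = c("A", "C", "G"))
  pick <- sample.int(3L, length(hit), replace = TRUE)
  bases[hit] <- mapply(function(b, i) alt[[b]][i], bases[hit], pick,
                       USE.NAMES = FALSE)
  paste(bases, collapse = "")
}

add_substitutions <- function(seq, rate) {
  n <- nchar(seq)
  if (rate <= 0 || n == 0L) return(seq)
  substitute_bases(seq, which(stats::runif(n) < rate))
}

revcomp <- function(seq) {
  if (nchar(seq) == 0L) return(seq)
  intToUtf8(rev(utf8ToInt(chartr("ACGTacgt", "TGCAtgca", seq))))
}

count_occurrences <- function(pattern, genome_seqs) {
  pat <- Biostrings::DNAString(pattern)
  subj <- Biostrings::DNAStringSet(genome_seqs)
  sum(Biostrings::vcountPattern(pat, subj)) +
    sum(Biostrings::vcountPattern(Biostrings::reverseComplement(pat), subj))
}

#' Build a synthetic genome carrying a tandem repeat array
#'
#' Draws a random background chromosome, embeds the array described by `spec`
#' at its locus offset, and records a complete truth table: the interval of
#' every unit copy, the two flank anchor intervals, and (initially empty)
#' engineered-rearrangement records. After construction the two anchor
#' sequences are checked to occur exactly once in the whole genome (on either
#' strand); the background is re-drawn up to 10 times before failing, since a
#' chance second anchor occurrence would break spanning-read selection.
#'
#' @param spec an [array_spec()].
#' @param background_length length in bp of the background chromosome the
#'   array is inserted into (total chromosome length is `background_length`
#'   plus the realized array length). Must exceed the realized array length
#'   plus twice the anchor length so both flanks exist.
#' @param seed integer seed; construction is bit-reproducible for a fixed
#'   seed.
#' @param n_chromosomes total number of chromosomes; chromosomes beyond the
#'   first are plain background (no array) and provide targets for engineered
#'   translocations and ectopic integrations.
#' @return an object of class `repeat_array_genome`: a list with
#'   `chromosomes` (a named [Biostrings::DNAStringSet]), `array_locus`
#'   (chrom/start/end, 0-based half-open), `truth` (data frames `units`,
#'   `anchors`, `rearrangements`), `spec`, and `seed`.
#' @export
build_array_genome <- function(spec, background_length, seed,
                               n_chromosomes = 1L) {
  stopifnot(inherits(spec, "array_spec"))
  arr_len <- realized_array_length(spec)
  a <- spec$flank_anchor_length
  if (background_length <= arr_len + 2L * a) {
    stop("background_length must exceed realized array length + 2*flank_anchor_length")
  }
  offset <- if (is.null(spec$locus_offset)) background_length %/% 2L else spec$locus_offset
  if (offset < a || background_length - offset < a) {
    stop("locus_offset leaves less than one anchor length of flank on one side")
  }

  for (attempt in seq_len(10L)) {
    built <- with_seed(derive_seed(seed, attempt - 1L), {
      # background and unit are drawn before the per-copy divergence, so
      # genomes differing only in n_units share flanks and unit sequence
      unit <- random_dna(spec$unit_length)
      intervening <- random_dna(spec$intervening_length)
      bg <- random_dna(background_length)
      copies <- character(spec$n_units)
      if (spec$n_units > 0L) {
        for (i in seq_len(spec$n_units)) {
          copies[i] <- add_substitutions(unit, spec$unit_divergence_rate)
        }
      }
      array_seq <- if (spec$n_units == 0L) "" else {
        paste(copies, collapse = intervening)
      }
      chrom1 <- paste0(substring(bg, 1L, offset), array_seq,
                       substring(bg, offset + 1L, background_length))
      extra <- character(0)
      if (n_chromosomes > 1L) {
        extra <- vapply(seq_len(n_chromosomes - 1L),
                        function(i) random_dna(background_length), character(1))
      }
      list(unit = unit, intervening = intervening, chrom1 = chrom1, extra = extra)
    })

    seqs <- c(built$chrom1, built$extra)
    names(seqs) <- paste0("chr", seq_along(seqs))
    start <- offset
    end <- offset + arr_len
    left_anchor <- substring(built$chrom1, start - a + 1L, start)
    right_anchor <- substring(built$chrom1, end + 1L, end + a)
    if (count_occurrences(left_anchor, seqs) == 1L &&
        count_occurrences(right_anchor, seqs) == 1L) {
      unit_starts <- if (spec$n_units == 0L) integer(0) else {
        start + (seq_len(spec$n_units) - 1L) *
          (spec$unit_length + spec$intervening_length)
      }
      units <- data.frame(
        chrom = rep("chr1", spec$n_units),
        start = unit_starts,
        end = unit_starts + spec$unit_length,
        name = if (spec$n_units == 0L) character(0) else
          paste0("unit_", seq_len(spec$n_units)),
        stringsAsFactors = FALSE
      )
      anchors <- data.frame(
        side = c("5prime", "3prime"),
        chrom = "chr1",
        start = c(start - a, end),
        end = c(start, end + a),
        stringsAsFactors = FALSE
      )
      genome <- structure(
        list(
          chromosomes = Biostrings::DNAStringSet(seqs),
          array_locus = list(chrom = "chr1", start = start, end = end),
          unit_sequence = built$unit,
          intervening_sequence = built$intervening,
          truth = list(
            units = units,
            anchors = anchors,
            rearrangements = data.frame(
              kind = character(0), chrom = character(0), pos = integer(0),
              partner_chrom = character(0), partner_pos = integer(0),
              detail = character(0), stringsAsFactors = FALSE
            )
          ),
          spec = spec,
          seed = as.integer(seed)
        ),
        class = "repeat_array_genome"
      )
      return(genome)
    }
  }
  stop("could not construct genome with unique flank anchors after 10 attempts")
}

#' @export
print.repeat_array_genome <- function(x, ...) {
  cat("repeat_array_genome:", length(x$chromosomes), "chromosome(s),",
      sum(Biostrings::width(x$chromosomes)), "bp total\n")
  cat(sprintf("  array: %s:%d-%d (%d units of %d bp",
              x$array_locus$chrom, x$array_locus$start, x$array_locus$end,
              x$spec$n_units, x$spec$unit_length))
  if (x$spec$intervening_length > 0) {
    cat(sprintf(", %d-bp intervening segments", x$spec$intervening_length))
  }
  cat(")\n")
  if (nrow(x$truth$rearrangements) > 0) {
    cat("  engineered rearrangements:",
        paste(x$truth$rearrangements$kind, collapse = ", "), "\n")
  }
  invisible(x)
}

genome_sequences <- function(genome) {
  stats::setNames(as.character(genome$chromosomes), names(genome$chromosomes))
}

#' Engineer a rearrangement into a synthetic genome
#'
#' Injects one of the rearrangement classes the split-read screen is designed
#' to detect, recording exact breakpoints in the truth table:
#'
#' * `translocation` — a reciprocal exchange between the array chromosome,
#'   broken at the array 3' edge, and a random position on a partner
#'   chromosome; downstream of the array the sequence now belongs to the
#'   partner chromosome, so the 3' flank of array-spanning reads maps there.
#' * `ectopic_circle` — a circular excision product of `circle_units` unit
#'   copies integrated at a random non-array site on a partner chromosome,
#'   the signature of re-integrated extrachromosomal repeat circles.
#' * `chromosome_gain` — a whole-chromosome duplication (aneuploidy); the
#'   duplicate is stored under `<name>_gain` and doubles expected read depth
#'   on the affected chromosome.
#'
#' @param genome a [build_array_genome()] result.
#' @param kind one of `"translocation"`, `"ectopic_circle"`,
#'   `"chromosome_gain"`.
#' @param seed integer seed for breakpoint choice.
#' @param circle_units units in the ectopic circle (default 2).
#' @param chrom chromosome to duplicate for `chromosome_gain` (default the
#'   array chromosome).
#' @return the modified genome, with the event appended to
#'   `truth$rearrangements`.
#' @export
inject_rearrangement <- function(genome, kind, seed, circle_units = 2L,
                                 chrom = NULL) {
  stopifnot(inherits(genome, "repeat_array_genome"))
  kind <- match.arg(kind, c("translocation", "ectopic_circle", "chromosome_gain"))
  seqs <- genome_sequences(genome)
  if (kind %in% c("translocation", "ectopic_circle") && length(seqs) < 2L) {
    stop("translocation/ectopic_circle require a genome with >= 2 chromosomes")
  }
  rec <- NULL
  if (kind == "translocation") {
    bp1 <- genome$array_locus$end          # break at the array 3' edge
    len2 <- nchar(seqs[["chr2"]])
    bp2 <- with_seed(derive_seed(seed, 0L), sample.int(len2 - 2000L, 1L) + 1000L)
    tail1 <- substring(seqs[["chr1"]], bp1 + 1L)
    tail2 <- substring(seqs[["chr2"]], bp2 + 1L)
    seqs[["chr1"]] <- paste0(substring(seqs[["chr1"]], 1L, bp1), tail2)
    seqs[["chr2"]] <- paste0(substring(seqs[["chr2"]], 1L, bp2), tail1)
    rec <- data.frame(kind = kind, chrom = "chr1", pos = bp1,
                      partner_chrom = "chr2", partner_pos = bp2,
                      detail = "reciprocal exchange at array 3' edge",
                      stringsAsFactors = FALSE)
  } else if (kind == "ectopic_circle") {
    circle <- paste(rep(genome$unit_sequence, circle_units), collapse = "")
    len2 <- nchar(seqs[["chr2"]])
    pos <- with_seed(derive_seed(seed, 1L), sample.int(len2 - 2000L, 1L) + 1000L)
    seqs[["chr2"]] <- paste0(substring(seqs[["chr2"]], 1L, pos), circle,
                             substring(seqs[["chr2"]], pos + 1L))
    rec <- data.frame(kind = kind, chrom = "chr2", pos = pos,
                      partner_chrom = "chr2",
                      partner_pos = pos + nchar(circle),
                      detail = sprintf("%d-unit circle integration", circle_units),
                      stringsAsFactors = FALSE)
  } else {
    if (is.null(chrom)) chrom <- genome$array_locus$chrom
    if (!chrom %in% names(seqs)) stop("unknown chromosome: ", chrom)
    dup_name <- paste0(chrom, "_gain")
    seqs[[dup_name]] <- seqs[[chrom]]
    rec <- data.frame(kind = kind, chrom = dup_name, pos = 0L,
                      partner_chrom = chrom, partner_pos = 0L,
                      detail = "whole-chromosome duplication",
                      stringsAsFactors = FALSE)
  }
  genome$chromosomes <- Biostrings::DNAStringSet(seqs)
  genome$truth$rearrangements <- rbind(genome$truth$rearrangements, rec)
  genome
}

#' Write a synthetic genome and its truth table to disk
#'
#' Emits the chromosome sequences as FASTA, the truth unit and anchor
#' intervals as BED (0-based half-open, via \pkg{rtracklayer}), and the full
#' truth table (including rearrangement records) as JSON.
#'
#' @param genome a [build_array_genome()] result.
#' @param dir output directory (created if absent).
#' @param prefix file name prefix (default `"genome"`).
#' @return invisibly, the named character vector of paths written.
#' @export
write_genome <- function(genome, dir, prefix = "genome") {
  stopifnot(inherits(genome, "repeat_array_genome"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fa <- file.path(dir, paste0(prefix, ".fa"))
  Biostrings::writeXStringSet(genome$chromosomes, fa)
  bed <- file.path(dir, paste0(prefix, "_truth.bed"))
  feats <- rbind(
    data.frame(chrom = genome$truth$units$chrom,
               start = genome$truth$units$start,
               end = genome$truth$units$end,
               name = genome$truth$units$name,
               stringsAsFactors = FALSE),
    data.frame(chrom = genome$truth$anchors$chrom,
               start = genome$truth$anchors$start,
               end = genome$truth$anchors$end,
               name = paste0("anchor_", genome$truth$anchors$side),
               stringsAsFactors = FALSE)
  )
  gr <- GenomicRanges::GRanges(
    feats$chrom,
    IRanges::IRanges(start = feats$start + 1L, end = feats$end),
    name = feats$name
  )
  rtracklayer::export(gr, bed, format = "BED")
  js <- file.path(dir, paste0(prefix, "_truth.json"))
  jsonlite::write_json(
    list(array_locus = genome$array_locus,
         spec = unclass(genome$spec),
         units = genome$truth$units,
         anchors = genome$truth$anchors,
         rearrangements = genome$truth$rearrangements,
         seed = genome$seed),
    js, auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(c(fasta = fa, bed = bed, json = js))
}
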