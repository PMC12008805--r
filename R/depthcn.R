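# Masked-depth copy-number estimation.
#
# The population-average copy number of a tandem array can be read off
# normalized sequencing depth: with every duplicate reference copy of the
# unit masked before mapping, all unit-derived reads pile onto the single
# retained copy, and after dividing by the mean depth of single-copy
# background the retained copy's normalized depth equals the copy number.

as_granges0 <- function(x) {
  if (is.null(x)) return(GenomicRanges::GRanges())
  if (methods::is(x, "GRanges")) return(x)
  stopifnot(is.data.frame(x), all(c("chrom", "start", "end") %in% names(x)))
  GenomicRanges::GRanges(x$chrom,
                         IRanges::IRanges(start = x$start + 1L, end = x$end))
}

#' K-mer index of a reference genome, with masking
#'
#' Builds the seed index used by the internal read placer. Masked intervals
#' are excluded from the index — the in-silico equivalent of replacing a
#' duplicate reference copy with `"N"` before mapping, which forces reads
#' from any copy of a repeat onto the retained (unmasked) copy.
#'
#' @param reference named character vector of chromosome sequences, a
#'   [Biostrings::DNAStringSet], or a [build_array_genome()] result.
#' @param k seed length (default 15).
#' @param mask intervals to mask: a `GRanges` or a data frame
#'   `chrom`/`start`/`end` (0-based half-open).
#' @return an object of class `genome_index`.
#' @export
genome_index <- function(reference, k = 15L, mask = NULL) {
  seqs <- if (inherits(reference, "repeat_array_genome")) {
    genome_sequences(reference)
  } else if (methods::is(reference, "DNAStringSet")) {
    stats::setNames(as.character(reference), names(reference))
  } else reference
  maskgr <- as_granges0(mask)
  tables <- lapply(names(seqs), function(chr) {
    s <- seqs[[chr]]
    n <- nchar(s) - k + 1L
    if (n < 1L) return(new.env(hash = TRUE, parent = emptyenv()))
    keep <- rep(TRUE, n)
    m <- maskgr[GenomicRanges::seqnames(maskgr) == chr]
    if (length(m) > 0L) {
      kgr <- IRanges::IRanges(start = seq_len(n), width = k)
      keep <- !IRanges::overlapsAny(kgr, IRanges::ranges(m))
    }
    tab <- kmer_table(s, k, keep = keep)
    # environment hash: O(1) lookup per read k-mer, no per-query re-hash
    e <- new.env(hash = TRUE, parent = emptyenv(), size = length(tab$kmers))
    for (i in seq_along(tab$kmers)) assign(tab$kmers[i], tab$pos[[i]], envir = e)
    e
  })
  names(tables) <- names(seqs)
  structure(
    list(tables = tables, seqs = seqs, k = k, mask = maskgr,
         seqlengths = stats::setNames(nchar(seqs), names(seqs))),
    class = "genome_index"
  )
}

place_candidates <- function(query, index, stride, gap_tol) {
  k <- index$k
  L <- nchar(query)
  n <- L - k + 1L
  if (n < 1L) return(NULL)
  take <- seq(1L, n, by = stride)
  out <- list()
  for (strand in c("+", "-")) {
    q <- if (strand == "+") query else revcomp(query)
    kmers <- substring(q, take, take + k - 1L)
    for (chr in names(index$tables)) {
      plist <- mget(kmers, envir = index$tables[[chr]],
                    ifnotfound = list(NULL))
      lens <- lengths(plist)
      if (sum(lens) == 0L) next
      rpos <- rep(take - 1L, lens)
      qpos <- as.integer(unlist(plist, use.names = FALSE))
      segs <- cluster_hits(rpos, qpos, k, gap_tol, diag_band = 16L)
      if (nrow(segs) == 0L) next
      segs$chrom <- chr
      segs$strand <- strand
      out[[length(out) + 1L]] <- segs
    }
  }
  if (length(out) == 0L) return(NULL)
  do.call(rbind, out)
}

# x-drop extension along a diagonal: starting from the seed-chain extent,
# extend outward while the running score (+1 match, -2 mismatch) stays
# within `xdrop` of its maximum. Substitution noise survives; the abrupt
# mismatch wall at a split-read junction stops the extension there.
xdrop_extend <- function(m, lo, hi, xdrop = 20L) {
  extend_side <- function(step) {
    if (length(step) == 0L) return(0L)
    s <- cumsum(step)
    drop <- which(s < cummax(s) - xdrop)
    lim <- if (length(drop)) drop[1L] - 1L else length(s)
    if (lim == 0L) return(0L)
    best <- which.max(s[seq_len(lim)])
    if (s[best] > 0L) best else 0L
  }
  n <- length(m)
  step <- ifelse(m, 1L, -2L)
  if (hi < n) hi <- hi + extend_side(step[(hi + 1L):n])
  if (lo > 1L) lo <- lo - extend_side(step[(lo - 1L):1L])
  c(lo, hi)
}

score_candidate <- function(query, index, cand) {
  L <- nchar(query)
  ref <- index$seqs[[cand$chrom]]
  reflen <- nchar(ref)
  q <- if (cand$strand == "+") query else revcomp(query)
  d <- cand$ref_start - cand$read_start       # ref offset of query start
  qs <- max(0L, -d)
  qe <- min(L, reflen - d)
  if (qe <= qs) return(NULL)
  a <- substring(q, qs + 1L, qe)
  b <- substring(ref, qs + d + 1L, qe + d)
  m <- utf8ToInt(a) == utf8ToInt(b)
  # anchor on the seed chain, extend while matches keep accumulating
  lo0 <- max(cand$read_start, qs) - qs + 1L
  hi0 <- min(cand$read_end, qe) - qs
  if (hi0 < lo0) return(NULL)
  ext <- xdrop_extend(m, lo0, hi0)
  qs2 <- qs + ext[1] - 1L
  qe2 <- qs + ext[2]
  ident <- mean(m[ext[1]:ext[2]])
  rs <- if (cand$strand == "+") qs2 else L - qe2
  re <- if (cand$strand == "+") qe2 else L - qs2
  list(chrom = cand$chrom, strand = cand$strand,
       ref_start = qs2 + d, ref_end = qe2 + d,
       read_start = rs, read_end = re,
       diag = d, identity = ident,
       aligned = qe2 - qs2, score = ident * (qe2 - qs2),
       n_seeds = cand$n_seeds)
}

#' Place a sequence on an indexed genome (unique best placement)
#'
#' Seed-chain-extend against every chromosome and strand; the best-scoring
#' diagonal (identity times aligned length, substitution-only extension) is
#' reported. Placements are `"mapped"` only when unique: a second candidate
#' at a different locus scoring within 5% of the best makes the result
#' `"ambiguous"` — multi-mapping sequences are never used as evidence.
#' Sub-threshold placements are `"unmapped"`.
#'
#' @param query sequence to place.
#' @param index a [genome_index()].
#' @param min_identity identity floor (default 0.8).
#' @param min_len minimum aligned length (default 50 bp).
#' @param max_candidates diagonal candidates to score fully.
#' @return a list: `status` (`mapped`/`ambiguous`/`unmapped`), and for
#'   scored candidates `chrom`, `strand`, `ref_start`, `ref_end`,
#'   `read_start`, `read_end`, `identity`.
#' @export
place_sequence <- function(query, index, min_identity = 0.8, min_len = 50L,
                           max_candidates = 8L) {
  k <- index$k
  L <- nchar(query)
  if (L < k) return(list(status = "unmapped"))
  stride <- max(1L, (L - k + 1L) %/% 64L)
  gap_tol <- max(2L * k, 8L * stride)
  cands <- place_candidates(query, index, stride, gap_tol)
  if (is.null(cands)) return(list(status = "unmapped"))
  cands <- cands[order(-cands$n_seeds), , drop = FALSE]
  cands <- cands[seq_len(min(nrow(cands), max_candidates)), , drop = FALSE]
  scored <- list()
  for (i in seq_len(nrow(cands))) {
    sc <- score_candidate(query, index, cands[i, ])
    if (!is.null(sc)) {
      sc$cand_row <- i
      scored[[length(scored) + 1L]] <- sc
    }
  }
  if (length(scored) == 0L) return(list(status = "unmapped"))
  scores <- vapply(scored, `[[`, numeric(1), "score")
  o <- order(-scores)
  best <- scored[[o[1]]]
  if (best$identity < min_identity || best$aligned < min_len) {
    return(list(status = "unmapped"))
  }
  # uniqueness: next-best candidate at a genuinely different locus
  for (j in o[-1]) {
    other <- scored[[j]]
    different <- other$chrom != best$chrom ||
      other$strand != best$strand ||
      abs(other$diag - best$diag) > 100L
    if (different && other$score >= 0.95 * best$score &&
        other$identity >= min_identity) {
      best$status <- "ambiguous"
      return(best)
    }
  }
  best$status <- "mapped"
  best
}

#' Raw binned depth profile from placements or reads
#'
#' Accumulates per-base coverage and bins it (bin value = covered bases in
#' the bin divided by `bin_size`, so the binned counts sum to total placed
#' bases / bin size). Input is either a table of known placements
#' (`chrom`/`start`/`end`, 0-based half-open — e.g. a simulator truth
#' table), or raw reads plus an indexed reference, in which case each read
#' is placed by [place_sequence()]; unplaced read prefixes/suffixes at least
#' 50 bp long get one re-placement pass, so reads crossing repeat-unit
#' junctions contribute both pieces. Multi-mapping reads are discarded and
#' counted. Placements running off chromosome ends are clipped with a
#' warning.
#'
#' @param placements data frame of placements (exclusive with `reads`).
#' @param reads named character vector of read sequences (or a
#'   [simulate_reads()] result).
#' @param index a [genome_index()] (required with `reads`; its mask is the
#'   mapping mask).
#' @param seqlengths named chromosome lengths (required with `placements`).
#' @param bin_size bin width in bp (default 100).
#' @return an object of class `depth_profile`: `bins` (a `GRanges` with a
#'   `score` column), `bin_size`, `seqlengths`, `normalized`,
#'   `norm_factor`, `placer_stats`.
#' @export
compute_depth <- function(placements = NULL, reads = NULL, index = NULL,
                          seqlengths = NULL, bin_size = 100L) {
  stats <- c(mapped = 0L, ambiguous = 0L, unmapped = 0L)
  if (is.null(placements)) {
    if (is.null(reads) || is.null(index)) {
      stop("supply either placements+seqlengths or reads+index")
    }
    if (is.list(reads) && !is.null(reads$sequences)) reads <- reads$sequences
    seqlengths <- index$seqlengths
    rows <- list()
    for (id in names(reads)) {
      rd <- reads[[id]]
      pl <- place_sequence(rd, index)
      stats[pl$status] <- stats[pl$status] + 1L
      if (pl$status != "mapped") next
      rows[[length(rows) + 1L]] <-
        data.frame(chrom = pl$chrom, start = pl$ref_start, end = pl$ref_end)
      # one remainder pass for unplaced read ends (junction reads)
      L <- nchar(rd)
      for (piece in list(c(0L, pl$read_start), c(pl$read_end, L))) {
        if (piece[2] - piece[1] >= 50L) {
          sub <- substring(rd, piece[1] + 1L, piece[2])
          pl2 <- place_sequence(sub, index)
          if (pl2$status == "mapped") {
            rows[[length(rows) + 1L]] <-
              data.frame(chrom = pl2$chrom, start = pl2$ref_start,
                         end = pl2$ref_end)
          }
        }
      }
    }
    placements <- if (length(rows)) do.call(rbind, rows) else
      data.frame(chrom = character(0), start = integer(0), end = integer(0))
  } else {
    if (is.null(seqlengths)) stop("seqlengths required with placements")
  }

  if (nrow(placements) > 0L) {
    placements <- placements[placements$chrom %in% names(seqlengths), ,
                             drop = FALSE]
    lens <- seqlengths[placements$chrom]
    if (any(placements$start < 0) || any(placements$end > lens)) {
      warning("placements beyond chromosome ends were clipped")
      placements$start <- pmax(placements$start, 0L)
      placements$end <- pmin(placements$end, lens)
    }
    placements <- placements[placements$end > placements$start, , drop = FALSE]
  }

  cov <- if (nrow(placements) > 0L) {
    GenomicRanges::coverage(
      GenomicRanges::GRanges(
        placements$chrom,
        IRanges::IRanges(start = placements$start + 1L, end = placements$end),
        seqlengths = seqlengths
      )
    )
  } else {
    methods::as(lapply(seqlengths, function(l) S4Vectors::Rle(0L, l)),
                "SimpleRleList")
  }

  bins_by_chr <- lapply(names(seqlengths), function(chr) {
    len <- seqlengths[[chr]]
    starts <- seq(1L, len, by = bin_size)
    ends <- pmin(starts + bin_size - 1L, len)
    v <- IRanges::Views(cov[[chr]], start = starts, end = ends)
    GenomicRanges::GRanges(chr, IRanges::IRanges(start = starts, end = ends),
                           score = IRanges::viewSums(v) / bin_size,
                           seqlengths = seqlengths)
  })
  bins <- suppressWarnings(do.call(c, bins_by_chr))
  structure(
    list(bins = bins, bin_size = as.integer(bin_size),
         seqlengths = seqlengths, normalized = FALSE, norm_factor = NA_real_,
         mask = GenomicRanges::GRanges(), placer_stats = stats),
    class = "depth_profile"
  )
}

#' @export
print.depth_profile <- function(x, ...) {
  cat(sprintf("depth_profile: %d bins of %d bp over %d chromosome(s); %s\n",
              length(x$bins), x$bin_size, length(x$seqlengths),
              if (x$normalized)
                sprintf("normalized (factor %.3f)", x$norm_factor)
              else "raw counts"))
  invisible(x)
}

#' Background-normalize a depth profile
#'
#' Divides every bin by the mean raw depth over the background — the
#' genomic regions declared free of copy-number structure (everything minus
#' an exclusion list of repeats, organelle DNA, and the array itself) —
#' after removing masked bins. Single-copy background then sits at a
#' normalized depth of 1, and the retained repeat-unit copy directly reads
#' out the array copy number. Normalization is idempotent: re-normalizing
#' with the same background divides by 1.
#'
#' @param profile a [compute_depth()] result.
#' @param mask intervals excluded everywhere (bins overlapping them are
#'   flagged and never used); `GRanges` or 0-based `chrom`/`start`/`end`
#'   data frame.
#' @param background background intervals; default the whole genome.
#' @return the profile with `score` normalized, `normalized = TRUE`,
#'   `norm_factor` set, and a logical `masked` column on the bins.
#' @export
normalize_depth <- function(profile, mask = NULL, background = NULL) {
  stopifnot(inherits(profile, "depth_profile"))
  maskgr <- as_granges0(mask)
  bggr <- if (is.null(background)) {
    GenomicRanges::GRanges(names(profile$seqlengths),
                           IRanges::IRanges(1L, profile$seqlengths))
  } else as_granges0(background)
  bins <- profile$bins
  masked <- IRanges::overlapsAny(bins, maskgr)
  in_bg <- IRanges::overlapsAny(bins, bggr)
  eff <- in_bg & !masked
  if (!any(eff)) stop("empty effective background (all masked or outside)")
  factor <- mean(bins$score[eff])
  if (factor <= 0) stop("background mean depth is zero")
  bins$score <- bins$score / factor
  bins$masked <- masked
  profile$bins <- bins
  profile$normalized <- TRUE
  profile$norm_factor <- factor
  profile$mask <- maskgr
  profile$background <- bggr
  profile
}

profile_masked <- function(profile) {
  if (!is.null(profile$bins$masked)) profile$bins$masked
  else rep(FALSE, length(profile$bins))
}

#' Mean normalized depth over a region
#'
#' @param profile a (normalized) [depth_profile].
#' @param region a `GRanges` or 0-based `chrom`/`start`/`end` data frame
#'   (one region).
#' @return a list of class `region_cn`: `mean`, `sd` (`NA` with an
#'   `sd_undefined` flag for single-bin regions), `n_bins`, `region`.
#'   Errors when the region is fully masked or off the profile.
#' @export
region_copy_number <- function(profile, region) {
  stopifnot(inherits(profile, "depth_profile"))
  gr <- as_granges0(region)
  hit <- IRanges::overlapsAny(profile$bins, gr) & !profile_masked(profile)
  if (!any(hit)) stop("region has no unmasked bins in the profile")
  v <- profile$bins$score[hit]
  structure(
    list(mean = mean(v),
         sd = if (length(v) > 1L) stats::sd(v) else NA_real_,
         sd_undefined = length(v) == 1L,
         n_bins = length(v),
         region = gr),
    class = "region_cn"
  )
}

#' @export
print.region_cn <- function(x, ...) {
  cat(sprintf("region copy number: %.3f +/- %s over %d bin(s)\n",
              x$mean, if (x$sd_undefined) "NA" else sprintf("%.3f", x$sd),
              x$n_bins))
  invisible(x)
}

#' Ratio of normalized depth between two regions
#'
#' The generic region-ratio operation (e.g. a macrosatellite versus its
#' single-copy centromeric flank): the ratio of unmasked mean normalized
#' depths.
#'
#' @param profile a normalized [depth_profile].
#' @param numerator,denominator regions as in [region_copy_number()].
#' @return the ratio (scalar).
#' @export
region_ratio <- function(profile, numerator, denominator) {
  num <- region_copy_number(profile, numerator)
  den <- region_copy_number(profile, denominator)
  if (den$mean == 0) stop("denominator region has zero mean depth")
  num$mean / den$mean
}

#' Per-chromosome ploidy calls from normalized depth
#'
#' Classifies each chromosome by its mean normalized depth over unmasked
#' bins outside excluded regions (the array locus should be excluded — its
#' depth reflects repeat copy number, not ploidy). Calls use strict
#' inequalities, so a mean exactly at a threshold stays euploid.
#'
#' @param profile a normalized [depth_profile].
#' @param gain_threshold call `gain` when mean depth exceeds this (default
#'   1.25).
#' @param loss_threshold call `loss` when mean depth is below this (default
#'   0.75).
#' @param exclude regions ignored in the per-chromosome mean (e.g. the
#'   array locus).
#' @return a `data.frame`: `chrom`, `mean_depth`, `n_bins`, `call`.
#' @export
chromosome_ploidy <- function(profile, gain_threshold = 1.25,
                              loss_threshold = 0.75, exclude = NULL) {
  stopifnot(inherits(profile, "depth_profile"))
  excl <- as_granges0(exclude)
  usable <- !profile_masked(profile) &
    !IRanges::overlapsAny(profile$bins, excl)
  chroms <- names(profile$seqlengths)
  rows <- lapply(chroms, function(chr) {
    sel <- usable & as.character(GenomicRanges::seqnames(profile$bins)) == chr
    m <- if (any(sel)) mean(profile$bins$score[sel]) else NA_real_
    call <- if (is.na(m)) NA_character_
    else if (m > gain_threshold) "gain"
    else if (m < loss_threshold) "loss"
    else "euploid"
    data.frame(chrom = chr, mean_depth = m, n_bins = sum(sel), call = call,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Export a depth profile as bedGraph
#'
#' @param profile a [depth_profile].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_depth_bedgraph <- function(profile, path) {
  gr <- profile$bins
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(score = profile$bins$score)
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}
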