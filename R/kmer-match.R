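# Seed-and-chain local matcher.
#
# All per-read analyses in the package (anchor location, dot-plot unit
# counting, flank mapping, the internal read placer) share one primitive:
# exact k-mer seeds between a query ("ref") and a read, grouped into
# collinear diagonal segments. With a substitution-only error model there
# are no indels, so every true local match lies on a single diagonal
# (read_pos - ref_pos constant) and chaining reduces to clustering seed hits
# by diagonal and splitting clusters at large positional gaps — exactly the
# "diagonal lines" of a dot plot, counted programmatically instead of by
# eye. A small diagonal band is still tolerated so near-diagonal seeds from
# repeated k-mers do not fragment segments.
#
# Coordinates are 0-based half-open everywhere; reverse-strand segments
# report read coordinates mirrored back onto the original read.

extract_kmers <- function(seq, k) {
  n <- nchar(seq) - k + 1L
  if (n < 1L) return(character(0))
  substring(seq, seq_len(n), seq_len(n) + k - 1L)
}

# index: unique k-mers plus a parallel list of their 0-based positions
kmer_table <- function(seq, k, keep = NULL) {
  kmers <- extract_kmers(seq, k)
  pos <- seq_along(kmers) - 1L
  if (!is.null(keep)) {
    kmers <- kmers[keep]
    pos <- pos[keep]
  }
  if (length(kmers) == 0L) {
    return(list(kmers = character(0), pos = list()))
  }
  byk <- split(pos, kmers)
  list(kmers = names(byk), pos = unname(byk))
}

seed_hits <- function(read, ref_index, k) {
  kmers <- extract_kmers(read, k)
  if (length(kmers) == 0L || length(ref_index$kmers) == 0L) {
    return(data.frame(rpos = integer(0), qpos = integer(0)))
  }
  m <- match(kmers, ref_index$kmers)
  sel <- which(!is.na(m))
  if (length(sel) == 0L) {
    return(data.frame(rpos = integer(0), qpos = integer(0)))
  }
  plist <- ref_index$pos[m[sel]]
  lens <- lengths(plist)
  data.frame(
    rpos = rep(sel - 1L, lens),
    qpos = as.integer(unlist(plist, use.names = FALSE))
  )
}

cluster_hits <- function(rpos, qpos, k, gap_tol, diag_band) {
  if (length(rpos) == 0L) {
    return(data.frame(read_start = integer(0), read_end = integer(0),
                      ref_start = integer(0), ref_end = integer(0),
                      n_seeds = integer(0)))
  }
  d <- rpos - qpos
  o <- order(d, rpos)
  rpos <- rpos[o]; qpos <- qpos[o]; d <- d[o]
  cid <- cumsum(c(TRUE, diff(d) > diag_band))
  out <- vector("list", max(cid))
  i <- 0L
  for (cl in split(seq_along(rpos), cid)) {
    rp <- rpos[cl]; qp <- qpos[cl]
    o2 <- order(rp); rp <- rp[o2]; qp <- qp[o2]
    sid <- cumsum(c(TRUE, diff(rp) > gap_tol))
    for (sg in split(seq_along(rp), sid)) {
      i <- i + 1L
      out[[i]] <- c(min(rp[sg]), max(rp[sg]) + k,
                    min(qp[sg]), max(qp[sg]) + k, length(sg))
    }
  }
  m <- do.call(rbind, out[seq_len(i)])
  data.frame(read_start = as.integer(m[, 1]), read_end = as.integer(m[, 2]),
             ref_start = as.integer(m[, 3]), ref_end = as.integer(m[, 4]),
             n_seeds = as.integer(m[, 5]))
}

empty_segments <- function() {
  data.frame(read_start = integer(0), read_end = integer(0),
             ref_start = integer(0), ref_end = integer(0),
             strand = character(0), n_seeds = integer(0),
             ref_coverage = numeric(0), stringsAsFactors = FALSE)
}

#' Collinear diagonal segments between a read and a reference sequence
#'
#' Finds all local matches of `ref` within `read` by exact `k`-mer seeding
#' followed by diagonal clustering: seeds whose diagonals differ by at most
#' `diag_band` and whose read positions are within `gap_tol` of their
#' neighbour are merged into one maximal segment, one segment per dot-plot
#' diagonal line. Both strands are scanned (reverse-strand matches are
#' detected on the reverse-complemented read and reported in original read
#' coordinates).
#'
#' @param read read sequence (character scalar).
#' @param ref reference sequence (e.g. a repeat unit or flank anchor).
#' @param k seed length (default 15).
#' @param gap_tol maximum seed gap (bp) within a segment; default 10% of the
#'   reference length (at least `2 k`), the dot-plot diagonal-break
#'   tolerance.
#' @param diag_band diagonal tolerance for merging near-diagonal seeds.
#' @param min_seeds discard segments supported by fewer seeds.
#' @param both_strands scan the reverse strand too.
#' @return a `data.frame` with columns `read_start`, `read_end`,
#'   `ref_start`, `ref_end` (0-based half-open), `strand`, `n_seeds`,
#'   `ref_coverage` (fraction of the reference covered by the segment).
#' @export
chain_segments <- function(read, ref, k = 15L, gap_tol = NULL,
                           diag_band = 16L, min_seeds = 3L,
                           both_strands = TRUE) {
  if (nchar(ref) < k) stop("reference shorter than the seed length k")
  if (is.null(gap_tol)) gap_tol <- max(2L * k, round(0.1 * nchar(ref)))
  idx <- kmer_table(ref, k)
  L <- nchar(read)
  fw <- seed_hits(read, idx, k)
  segs_f <- cluster_hits(fw$rpos, fw$qpos, k, gap_tol, diag_band)
  if (nrow(segs_f)) segs_f$strand <- "+"
  segs <- segs_f
  if (both_strands) {
    rc <- revcomp(read)
    rv <- seed_hits(rc, idx, k)
    segs_r <- cluster_hits(rv$rpos, rv$qpos, k, gap_tol, diag_band)
    if (nrow(segs_r)) {
      segs_r$strand <- "-"
      # mirror read coordinates back to the original read
      rs <- L - segs_r$read_end
      re <- L - segs_r$read_start
      segs_r$read_start <- rs
      segs_r$read_end <- re
      segs <- rbind(segs, segs_r)
    }
  }
  if (nrow(segs) == 0L) return(empty_segments())
  segs <- segs[segs$n_seeds >= min_seeds, , drop = FALSE]
  if (nrow(segs) == 0L) return(empty_segments())
  segs$ref_coverage <- (segs$ref_end - segs$ref_start) / nchar(ref)
  segs <- segs[order(segs$read_start, segs$read_end), , drop = FALSE]
  rownames(segs) <- NULL
  segs
}

seq_identity <- function(a, b) {
  if (nchar(a) == 0L || nchar(a) != nchar(b)) return(0)
  mean(utf8ToInt(a) == utf8ToInt(b))
}

# identity/coverage of the full-reference projection of a diagonal segment:
# extend the segment to the whole reference along its diagonal, clip to the
# read, and compare base-by-base (substitution-only model: band width 0).
project_and_score <- function(read, ref, seg) {
  L <- nchar(read)
  ref_len <- nchar(ref)
  if (seg$strand == "-") {
    read_cmp <- revcomp(read)
    rs <- L - seg$read_end
  } else {
    read_cmp <- read
    rs <- seg$read_start
  }
  d <- rs - seg$ref_start            # implied diagonal on the compared strand
  full_start <- max(d, 0L)
  full_end <- min(d + ref_len, L)
  if (full_end <= full_start) return(NULL)
  a <- substring(read_cmp, full_start + 1L, full_end)
  b <- substring(ref, full_start - d + 1L, full_end - d)
  ident <- seq_identity(a, b)
  list(
    read_start = if (seg$strand == "-") L - full_end else full_start,
    read_end = if (seg$strand == "-") L - full_start else full_end,
    ref_start = full_start - d,
    ref_end = full_end - d,
    strand = seg$strand,
    identity = ident,
    coverage = (full_end - full_start) / ref_len,
    n_seeds = seg$n_seeds
  )
}
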