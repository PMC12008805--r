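#' Parameters of the long-read simulator
#'
#' Emulates ligation-based long-read (nanopore-like) whole-genome sequencing
#' of a synthetic genome: read lengths are either fixed or drawn from a
#' heavy-tailed lognormal, starts are uniform along each (linear)
#' chromosome, strands are sampled uniformly when `both_strands`, and errors
#' are independent substitutions at `substitution_error_rate` (no indels).
#'
#' Exactly one of `depth` or `n_reads` must be supplied: `depth` is expected
#' mean coverage (reads are allocated so total sequenced bases approximate
#' `depth *` genome size), `n_reads` a fixed read count.
#'
#' @param length_distribution either `list(type = "fixed", length = L)` or
#'   `list(type = "lognormal", meanlog = mu, sdlog = sigma)` (natural-log
#'   scale).
#' @param depth target mean coverage (exclusive with `n_reads`).
#' @param n_reads fixed number of reads (exclusive with `depth`).
#' @param substitution_error_rate per-base substitution probability in
#'   `[0, 1]`.
#' @param both_strands sample reads from both strands (reverse-strand reads
#'   are stored reverse-complemented, as a sequencer emits them).
#' @param seed integer seed.
#' @return an object of class `read_sim_params`.
#' @export
read_sim_params <- function(length_distribution = list(type = "lognormal",
                                                       meanlog = log(8000),
                                                       sdlog = 0.6),
                            depth = NULL, n_reads = NULL,
                            substitution_error_rate = 0,
                            both_strands = TRUE,
                            seed = 1L) {
  stopifnot(is.list(length_distribution),
            length_distribution$type %in% c("fixed", "lognormal"))
  if (length_distribution$type == "fixed" &&
      (is.null(length_distribution$length) || length_distribution$length < 1)) {
    stop("fixed length distribution requires a positive length")
  }
  if (is.null(depth) == is.null(n_reads)) {
    stop("supply exactly one of depth or n_reads")
  }
  if (!is.null(depth) && depth <= 0) stop("depth must be positive")
  if (!is.null(n_reads) && n_reads < 0) stop("n_reads must be >= 0")
  stopifnot(substitution_error_rate >= 0, substitution_error_rate <= 1)
  structure(
    list(length_distribution = length_distribution,
         depth = depth, n_reads = n_reads,
         substitution_error_rate = substitution_error_rate,
         both_strands = isTRUE(both_strands),
         seed = as.integer(seed)),
    class = "read_sim_params"
  )
}

draw_lengths <- function(n, dist) {
  if (n == 0L) return(integer(0))
  if (dist$type == "fixed") {
    rep(as.integer(dist$length), n)
  } else {
    out <- integer(0)
    while (length(out) < n) {
      l <- as.integer(round(stats::rlnorm(n, dist$meanlog, dist$sdlog)))
      out <- c(out, l[l >= 1L])   # non-positive draws rejected and re-drawn
    }
    out[seq_len(n)]
  }
}

mean_read_length <- function(dist) {
  if (dist$type == "fixed") dist$length
  else exp(dist$meanlog + dist$sdlog^2 / 2)
}

#' Simulate long reads from a synthetic genome
#'
#' Reads start uniformly on their chromosome: a read of drawn length `L` on
#' a chromosome of length `C` starts at one of the `C - L + 1` positions
#' when `L <= C`, and is truncated to the whole chromosome otherwise. The
#' truth table records, per read, the source interval (0-based half-open on
#' the forward strand), the strand, and whether the read fully spans the
#' array together with both flank anchors.
#'
#' @param genome a [build_array_genome()] result.
#' @param params a [read_sim_params()].
#' @return a list with `sequences` (named character vector of read
#'   sequences, reverse-strand reads reverse-complemented) and `truth` (a
#'   data frame: `read_id`, `chrom`, `start`, `end`, `strand`,
#'   `spans_array`).
#' @export
simulate_reads <- function(genome, params) {
  stopifnot(inherits(genome, "repeat_array_genome"),
            inherits(params, "read_sim_params"))
  seqs <- genome_sequences(genome)
  if (length(seqs) == 0L) stop("genome has no chromosomes")
  clens <- nchar(seqs)
  n <- if (!is.null(params$n_reads)) as.integer(params$n_reads) else {
    as.integer(ceiling(params$depth * sum(clens) /
                         mean_read_length(params$length_distribution)))
  }
  anchors <- genome$truth$anchors
  span_chrom <- genome$array_locus$chrom
  span_lo <- min(anchors$start)
  span_hi <- max(anchors$end)

  if (n == 0L) {
    return(list(
      sequences = stats::setNames(character(0), character(0)),
      truth = data.frame(read_id = character(0), chrom = character(0),
                         start = integer(0), end = integer(0),
                         strand = character(0), spans_array = logical(0))
    ))
  }
  with_seed(derive_seed(params$seed, 3L), {
    chrom_idx <- sample.int(length(seqs), n, replace = TRUE,
                            prob = clens / sum(clens))
    lens <- draw_lengths(n, params$length_distribution)
    C <- clens[chrom_idx]
    lens <- pmin(lens, C)                       # truncate at chromosome ends
    starts <- vapply(seq_len(n), function(i) {
      sample.int(C[i] - lens[i] + 1L, 1L) - 1L  # 0-based
    }, integer(1))
    strand <- if (params$both_strands) {
      sample(c("+", "-"), n, replace = TRUE)
    } else rep("+", n)
    ids <- sprintf("read_%06d", seq_len(n))
    reads <- character(n)
    for (i in seq_len(n)) {
      s <- substring(seqs[[chrom_idx[i]]], starts[i] + 1L, starts[i] + lens[i])
      if (strand[i] == "-") s <- revcomp(s)
      if (params$substitution_error_rate > 0) {
        s <- add_substitutions(s, params$substitution_error_rate)
      }
      reads[i] <- s
    }
    names(reads) <- ids
    truth <- data.frame(
      read_id = ids,
      chrom = names(seqs)[chrom_idx],
      start = starts,
      end = starts + lens,
      strand = strand,
      spans_array = names(seqs)[chrom_idx] == span_chrom &
        starts <= span_lo & (starts + lens) >= span_hi,
      stringsAsFactors = FALSE
    )
    list(sequences = reads, truth = truth)
  })
}

#' Write simulated reads as FASTQ
#'
#' Dummy `"I"` base qualities are used (error-free or substitution-only
#' simulated reads carry no per-base quality information). A `.gz` suffix
#' triggers gzip compression.
#'
#' @param reads a [simulate_reads()] result, or a named character vector of
#'   sequences.
#' @param path output FASTQ path.
#' @return invisibly, `path`.
#' @export
write_reads_fastq <- function(reads, path) {
  seqs <- if (is.list(reads)) reads$sequences else reads
  # records are written directly: four-line FASTQ with constant qualities
  # (read-length-robust; C-level FASTQ writers cap the line length well
  # below nanopore read lengths)
  recs <- as.character(rbind(paste0("@", names(seqs)),
                             unname(seqs),
                             "+",
                             strrep("I", nchar(seqs))))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(recs, con)
  invisible(path)
}

#' Read sequences from FASTA/FASTQ into a named character vector
#'
#' Thin wrapper over [Biostrings::readDNAStringSet()]; gzip input is handled
#' transparently. The returned vector is the form every matcher in the
#' package accepts.
#'
#' @param path FASTA or FASTQ file (optionally gzipped).
#' @param format `"fasta"` or `"fastq"`; guessed from the file name by
#'   default.
#' @return named character vector of sequences.
#' @export
read_sequences <- function(path, format = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.f(ast)?q(\\.gz)?$", path)) "fastq" else "fasta"
  }
  x <- Biostrings::readDNAStringSet(path, format = format)
  stats::setNames(as.character(x), sub("\\s.*$", "", names(x)))
}
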