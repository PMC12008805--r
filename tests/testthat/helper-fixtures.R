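# Shared fixtures and independent oracles.
# Everything is generated in code at test time; genomes are cached per
# session so repeated tests do not rebuild them.

.fixture_cache <- new.env(parent = emptyenv())

fixture_genome <- function(n_units, seed = 11L, n_chromosomes = 1L,
                           intervening_length = 0L,
                           unit_divergence_rate = 0,
                           background_length = NULL) {
  key <- paste(n_units, seed, n_chromosomes, intervening_length,
               unit_divergence_rate, background_length, sep = "_")
  if (!is.null(.fixture_cache[[key]])) return(.fixture_cache[[key]])
  sp <- array_spec(n_units = n_units,
                   intervening_length = intervening_length,
                   unit_divergence_rate = unit_divergence_rate)
  if (is.null(background_length)) {
    background_length <- realized_array_length(sp) + 2001L + 10000L
  }
  g <- build_array_genome(sp, background_length, seed = seed,
                          n_chromosomes = n_chromosomes)
  .fixture_cache[[key]] <- g
  g
}

genome_anchors <- function(genome) {
  chr <- genome_sequences(genome)[[genome$array_locus$chrom]]
  a <- genome$truth$anchors
  list(
    left = substring(chr, a$start[a$side == "5prime"] + 1L,
                     a$end[a$side == "5prime"]),
    right = substring(chr, a$start[a$side == "3prime"] + 1L,
                      a$end[a$side == "3prime"])
  )
}

# an error-free spanning read: genome substring covering both anchors plus
# `pad` extra bases on each side
spanning_read <- function(genome, pad = 200L) {
  chr <- genome_sequences(genome)[[genome$array_locus$chrom]]
  a <- genome$truth$anchors
  substring(chr, min(a$start) - pad + 1L, max(a$end) + pad)
}

rand_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  bitrexkit:::random_dna(n)
}

# --- oracles -----------------------------------------------------------

# full lineage tree under deterministic expansion (p_exp = 1, step = 1,
# k = 0): every division one daughter keeps X, the other gets X + 1 when
# X >= 2. Returns the copy-number multiset after G generations.
enumerate_lineages <- function(x0, G) {
  pop <- x0
  for (g in seq_len(G)) {
    pop <- c(pop, pop + as.integer(pop >= 2))
  }
  sort(pop)
}

# exhaustive exact-substring count of full unit copies on a read
substring_unit_count <- function(read, unit) {
  m <- gregexpr(unit, read, fixed = TRUE)[[1]]
  if (length(m) == 1L && m[1] == -1L) 0L else length(m)
}

# analytic number of start positions yielding a spanning read: fixed read
# length L on a chromosome of length C with span window [s, e)
spanning_start_count <- function(C, L, s, e) {
  if (L > C) L <- C
  lo <- max(0L, e - L)
  hi <- min(s, C - L)
  max(0L, hi - lo + 1L)
}

# 4th/5th-order Runge-Kutta integration of dX/dt = -k X^2
ode_contraction <- function(X0, k, t_end) {
  if (t_end == 0) return(X0)
  # intermediate output times keep the adaptive stepper within its
  # per-interval step budget on stiff draws (large k * X0^2)
  times <- seq(0, t_end, length.out = 201)
  sol <- deSolve::ode(y = c(X = X0), times = times,
                      func = function(t, y, p) list(-k * y^2),
                      parms = NULL, method = "ode45",
                      rtol = 1e-10, atol = 1e-12, maxsteps = 100000)
  unname(sol[nrow(sol), "X"])
}
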