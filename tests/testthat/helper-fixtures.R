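# Shared fixtures and independent oracles. Fixtures are built in code; the
# oracles deliberately use a different route than the implementation
# (choose()-based enumeration, window scans, run-length recounts).

# a tiny two-chromosome map: chrA 10 probes at 10,20,...,100; chrB 5 probes
tiny_map <- function() {
  snp_map(list(chrA = seq(10L, 100L, by = 10L),
               chrB = seq(100L, 500L, by = 100L)))
}

# a profile holding constant (total, minor) over a map
flat_profile <- function(sample = "S1", map = tiny_map(), total = 2L,
                         minor = 1L, ploidy = "undeclared") {
  segs <- do.call(rbind, lapply(map$chrom, function(chr) {
    p <- map$positions[[chr]]
    data.frame(chrom = chr, start = p[1], end = p[length(p)],
               total_cn = total, minor_cn = minor,
               stringsAsFactors = FALSE)
  }))
  segment_profile(sample, segs, ploidy = ploidy)
}

# build a status_matrix directly from a samples x probes state matrix
matrix_from_states <- function(states, map) {
  stopifnot(ncol(states) == map$n_probes)
  ids <- sprintf("S%02d", seq_len(nrow(states)))
  profs <- lapply(seq_len(nrow(states)), function(i) {
    structure(list(sample = ids[i], ploidy = "near_diploid",
                   state = states[i, ],
                   loh = rep(FALSE, ncol(states)),
                   homdel = rep(FALSE, ncol(states)), map = map),
              class = "status_profile")
  })
  status_matrix(profs)
}

# random run-structured state matrix: each sample gets a few random event
# runs over a single-chromosome map of n probes
random_state_matrix <- function(n_samples, n_probes, n_runs = 3L,
                                states = c("LOSS", "GAIN", "AMP")) {
  m <- matrix("NEUTRAL", n_samples, n_probes)
  for (i in seq_len(n_samples)) {
    for (r in seq_len(sample.int(n_runs, 1L))) {
      len <- sample(5:min(80L, n_probes), 1L)
      start <- sample.int(max(1L, n_probes - len + 1L), 1L)
      m[i, start:(start + len - 1L)] <- sample(states, 1L)
    }
  }
  m
}

# --- independent oracles ---------------------------------------------------

# brute-force window scan: enumerate every window (i, j) of length
# >= min_snps whose per-probe frequency strictly exceeds min_freq at all
# probes (checked via prefix sums over the qualifying mask), then keep the
# windows that cannot be extended on either side. Independent of the
# implementation's run-length route.
oracle_regions_1chr <- function(freq, min_snps, min_freq) {
  n <- length(freq)
  qual <- freq > min_freq
  cs <- c(0L, cumsum(qual))
  i <- rep(seq_len(n), each = n)
  j <- rep(seq_len(n), times = n)
  len <- j - i + 1L
  all_qual <- len >= min_snps & (cs[j + 1L] - cs[i]) == len
  i <- i[all_qual]; j <- j[all_qual]
  if (length(i) == 0L) {
    return(data.frame(start = integer(), end = integer()))
  }
  keep <- (i == 1L | !qual[pmax(i - 1L, 1L)]) &
    (j == n | !qual[pmin(j + 1L, n)])
  out <- data.frame(start = i[keep], end = j[keep])
  out[order(out$start), , drop = FALSE]
}

# exhaustive hypergeometric enumeration with fixed margins via choose();
# one-sided tail for >= observed tumour alt count
oracle_fisher_greater <- function(tumor_ref, tumor_alt, normal_ref,
                                  normal_alt) {
  N <- tumor_ref + tumor_alt + normal_ref + normal_alt
  K <- tumor_alt + normal_alt
  n_t <- tumor_ref + tumor_alt
  ks <- max(0, n_t - (N - K)):min(n_t, K)
  probs <- choose(K, ks) * choose(N - K, n_t - ks) / choose(N, n_t)
  sum(probs[ks >= tumor_alt])
}

# run-length recount of breakpoints: maximal constant (total, minor) runs
# minus number of chromosomes present
oracle_breakpoints <- function(profile) {
  s <- profile$segments
  total <- 0L
  for (chr in unique(s$chrom)) {
    x <- s[s$chrom == chr, ]
    key <- paste(x$total_cn, x$minor_cn)
    total <- total + length(rle(key)$values) - 1L
  }
  total
}

# random segmented profile on a map: random cut points, random states
random_profile <- function(map, sample = "R1", max_cn = 8L) {
  segs <- do.call(rbind, lapply(map$chrom, function(chr) {
    p <- map$positions[[chr]]
    n <- length(p)
    n_cut <- sample.int(min(6L, n), 1L)
    bounds <- sort(unique(c(1L, sample.int(n, n_cut), n + 1L)))
    do.call(rbind, lapply(seq_len(length(bounds) - 1L), function(i) {
      tot <- sample.int(max_cn + 1L, 1L) - 1L
      mnr <- sample.int(tot %/% 2L + 1L, 1L) - 1L
      data.frame(chrom = chr, start = p[bounds[i]],
                 end = p[bounds[i + 1L] - 1L],
                 total_cn = tot, minor_cn = mnr, stringsAsFactors = FALSE)
    }))
  }))
  segment_profile(sample, segs)
}

# two-archetype acceptance cohort at the stated world's defaults
two_archetype_cohort <- function(n_per_arm = 20L, map, seed) {
  generate_cohort(
    list(list(spec = archetype_sawtooth(0.9), n = n_per_arm),
         list(spec = archetype_firestorm(0.9), n = n_per_arm)),
    map = map, seed = seed
  )
}
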