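#' Genomic archetype specification
#'
#' Describes one of the two tumour archetypes observed in micropapillary
#' breast carcinoma cohorts: whole-arm low-level events
#' ("Sawtooth/8/16": 8p-, 8q+, 16p-, 16q+) versus focal high-level
#' amplicons on 8q/17q/20q with 17p loss ("Firestorm/Amplifier").
#'
#' @param name Archetype label.
#' @param arm_events `data.frame(arm, event, prob)` of whole-arm events;
#'   `event` is `"loss"` or `"gain"`, `prob` the per-sample probability.
#' @param amplicons `data.frame(arm, start_bp, length_bp, cn_diploid,
#'   cn_tetraploid, prob)` of focal amplicons.  `start_bp = NA` centres the
#'   amplicon in its arm.  Amplified copy numbers must reach the
#'   amplification cutoff of their ploidy class (6 near-diploid,
#'   8 near-tetraploid).
#' @param ploidy_mix Named numeric, probabilities of `near_diploid` /
#'   `near_tetraploid` backgrounds (must sum to 1).
#' @return An `archetype_spec` object.
#' @export
archetype_spec <- function(name,
                           arm_events = NULL,
                           amplicons = NULL,
                           ploidy_mix = c(near_diploid = 0.5,
                                          near_tetraploid = 0.5)) {
  stopifnot(is.character(name), length(name) == 1L)
  if (is.null(arm_events)) {
    arm_events <- data.frame(arm = character(), event = character(),
                             prob = numeric(), stringsAsFactors = FALSE)
  }
  if (is.null(amplicons)) {
    amplicons <- data.frame(arm = character(), start_bp = numeric(),
                            length_bp = numeric(), cn_diploid = integer(),
                            cn_tetraploid = integer(), prob = numeric(),
                            stringsAsFactors = FALSE)
  }
  stopifnot(all(c("arm", "event", "prob") %in% names(arm_events)),
            all(c("arm", "length_bp", "cn_diploid", "cn_tetraploid",
                  "prob") %in% names(amplicons)))
  if (!"start_bp" %in% names(amplicons)) amplicons$start_bp <- NA_real_
  if (any(arm_events$prob < 0 | arm_events$prob > 1) ||
      any(amplicons$prob < 0 | amplicons$prob > 1)) {
    stop("event probabilities must lie in [0, 1]")
  }
  if (!all(arm_events$event %in% c("loss", "gain"))) {
    stop("arm events must be 'loss' or 'gain'")
  }
  cut <- ploidy_cutoffs()
  if (nrow(amplicons) > 0 &&
      (any(amplicons$cn_diploid < cut$near_diploid[["amp_min"]]) ||
       any(amplicons$cn_tetraploid < cut$near_tetraploid[["amp_min"]]))) {
    stop("amplicon copy numbers must reach the amplification cutoff ",
         "of their ploidy class")
  }
  if (!setequal(names(ploidy_mix), c("near_diploid", "near_tetraploid")) ||
      abs(sum(ploidy_mix) - 1) > 1e-8 || any(ploidy_mix < 0)) {
    stop("`ploidy_mix` must be probabilities over near_diploid/near_tetraploid")
  }
  structure(list(name = name, arm_events = arm_events,
                 amplicons = amplicons, ploidy_mix = ploidy_mix),
            class = "archetype_spec")
}

#' @rdname archetype_spec
#' @param event_prob Probability of each planted event (default 0.9, which
#'   gives the clean qualitative contrast between the two archetypes).
#' @export
archetype_sawtooth <- function(event_prob = 0.9,
                               ploidy_mix = c(near_diploid = 0.5,
                                              near_tetraploid = 0.5)) {
  archetype_spec(
    "sawtooth_8_16",
    arm_events = data.frame(
      arm = c("8p", "8q", "16p", "16q"),
      event = c("loss", "gain", "loss", "gain"),
      prob = event_prob,
      stringsAsFactors = FALSE
    ),
    ploidy_mix = ploidy_mix
  )
}

#' @rdname archetype_spec
#' @export
archetype_firestorm <- function(event_prob = 0.9,
                                ploidy_mix = c(near_diploid = 0.5,
                                               near_tetraploid = 0.5)) {
  archetype_spec(
    "firestorm_amplifier",
    arm_events = data.frame(
      arm = "17p", event = "loss", prob = event_prob,
      stringsAsFactors = FALSE
    ),
    # focal amplicons at the recurrently amplified loci: 8q22.1,
    # 17q22-q23.3 and 20q13.2
    amplicons = data.frame(
      arm = c("8q", "17q", "20q"),
      start_bp = c(95e6, 57.2e6, 50.7e6),
      length_bp = c(2e6, 5.2e6, 1.9e6),
      cn_diploid = 8L, cn_tetraploid = 10L,
      prob = event_prob,
      stringsAsFactors = FALSE
    ),
    ploidy_mix = ploidy_mix
  )
}

# baseline and event copy numbers per ploidy class: c(total, minor)
.baseline_cn <- function(ploidy) {
  if (ploidy == "near_diploid") c(2L, 1L) else c(4L, 2L)
}
.event_cn <- function(event, ploidy) {
  if (ploidy == "near_diploid") {
    switch(event, loss = c(1L, 0L), gain = c(3L, 1L),
           stop("unknown event: ", event))
  } else {
    switch(event, loss = c(2L, 1L), gain = c(6L, 2L),
           stop("unknown event: ", event))
  }
}
.expected_state <- function(event) {
  switch(event, loss = "LOSS", gain = "GAIN", amp = "AMP",
         stop("unknown event: ", event))
}

# One sample's probe-level copy numbers, compressed to segments, plus the
# planted-event records. Events snap to probe positions; amplicons override
# arm events where they overlap.
.simulate_profile <- function(sample, spec, map, ploidy) {
  base <- .baseline_cn(ploidy)
  tot <- lapply(map$n_per_chrom, function(n) rep(base[1], n))
  mnr <- lapply(map$n_per_chrom, function(n) rep(base[2], n))
  planted <- list()

  plant <- function(chrom, idx, cn, event, origin) {
    tot[[chrom]][idx] <<- cn[1]
    mnr[[chrom]][idx] <<- cn[2]
    p <- map$positions[[chrom]]
    planted[[length(planted) + 1L]] <<- data.frame(
      sample = sample, chrom = chrom,
      start = p[idx[1]], end = p[idx[length(idx)]],
      start_probe = idx[1], end_probe = idx[length(idx)],
      n_probes = length(idx), event = event, origin = origin,
      total_cn = cn[1], minor_cn = cn[2], stringsAsFactors = FALSE
    )
  }

  ae <- spec$arm_events
  for (i in seq_len(nrow(ae))) {
    if (stats::runif(1) >= ae$prob[i]) next
    iv <- arm_interval(map, ae$arm[i])
    chrom <- paste0("chr", sub("[pq]$", "", sub("^chr", "", ae$arm[i])))
    idx <- probes_in_interval(map, chrom, iv["start"], iv["end"])
    if (length(idx) == 0L) next
    plant(chrom, idx, .event_cn(ae$event[i], ploidy),
          .expected_state(ae$event[i]), ae$arm[i])
  }
  am <- spec$amplicons
  for (i in seq_len(nrow(am))) {
    if (stats::runif(1) >= am$prob[i]) next
    iv <- arm_interval(map, am$arm[i])
    chrom <- paste0("chr", sub("[pq]$", "", sub("^chr", "", am$arm[i])))
    start <- am$start_bp[i]
    if (is.na(start)) start <- iv["start"] + (iv["end"] - iv["start"]) / 2
    end <- start + am$length_bp[i] - 1
    if (start < iv["start"] || end > iv["end"]) {
      stop("amplicon outside arm ", am$arm[i])
    }
    idx <- probes_in_interval(map, chrom, start, end)
    if (length(idx) == 0L) next
    cn <- if (ploidy == "near_diploid") am$cn_diploid[i] else am$cn_tetraploid[i]
    plant(chrom, idx, c(as.integer(cn), base[2]), "AMP", am$arm[i])
  }

  segs <- lapply(map$chrom, function(chrom) {
    t <- tot[[chrom]]; m <- mnr[[chrom]]; p <- map$positions[[chrom]]
    key <- paste(t, m)
    r <- rle(key)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    data.frame(chrom = chrom, start = p[starts], end = p[ends],
               total_cn = t[starts], minor_cn = m[starts],
               stringsAsFactors = FALSE)
  })
  segs <- do.call(rbind, segs)
  list(profile = segment_profile(sample, segs, ploidy),
       planted = if (length(planted)) do.call(rbind, planted) else NULL)
}

#' Simulate a cohort of allele-specific copy-number profiles
#'
#' Draws samples from a mix of archetypes on near-diploid / near-tetraploid
#' backgrounds and plants whole-arm events and focal amplicons segment-wise
#' (boundaries snap to probe positions; no probe-level noise).  The returned
#' truth manifest is the ground-truth oracle for downstream tests.
#'
#' @param archetype_mix List of `list(spec = archetype_spec, n = count)`.
#' @param map A `snp_map` (default [default_snp_map()]).
#' @param seed Integer seed; identical seeds give bit-identical cohorts.
#' @return List with `profiles` (list of [segment_profile()]) and `truth`,
#'   a `cohort_truth` list carrying `samples` (sample, archetype, ploidy),
#'   `events` (every planted event with coordinates) and `regions`
#'   (distinct planted regions with carrier ids and carrier fraction).
#' @export
generate_cohort <- function(archetype_mix, map = default_snp_map(), seed) {
  stopifnot(inherits(map, "snp_map"), is.list(archetype_mix),
            length(archetype_mix) > 0L)
  for (m in archetype_mix) {
    if (!inherits(m$spec, "archetype_spec") || is.null(m$n) || m$n < 1) {
      stop("each mix entry needs an archetype_spec `spec` and a count `n` >= 1")
    }
  }
  if (missing(seed)) stop("`seed` is required")
  set.seed(as.integer(seed))

  profiles <- list()
  samples <- list()
  events <- list()
  k <- 0L
  for (m in archetype_mix) {
    for (j in seq_len(m$n)) {
      k <- k + 1L
      id <- sprintf("S%03d", k)
      ploidy <- sample(names(m$spec$ploidy_mix), 1L, prob = m$spec$ploidy_mix)
      sim <- .simulate_profile(id, m$spec, map, ploidy)
      profiles[[id]] <- sim$profile
      samples[[id]] <- data.frame(sample = id, archetype = m$spec$name,
                                  ploidy = ploidy, stringsAsFactors = FALSE)
      if (!is.null(sim$planted)) {
        sim$planted$archetype <- m$spec$name
        events[[id]] <- sim$planted
      }
    }
  }
  samples <- do.call(rbind, samples)
  rownames(samples) <- NULL
  events <- if (length(events)) do.call(rbind, events) else NULL
  regions <- NULL
  if (!is.null(events)) {
    rownames(events) <- NULL
    key <- paste(events$archetype, events$chrom, events$start, events$end,
                 events$event, sep = "|")
    regions <- do.call(rbind, lapply(split(events, key), function(e) {
      data.frame(archetype = e$archetype[1], chrom = e$chrom[1],
                 start = e$start[1], end = e$end[1],
                 start_probe = e$start_probe[1], end_probe = e$end_probe[1],
                 n_probes = e$n_probes[1], event = e$event[1],
                 origin = e$origin[1], n_carriers = nrow(e),
                 carrier_fraction = nrow(e) / nrow(samples),
                 carriers = I(list(e$sample)), stringsAsFactors = FALSE)
    }))
    rownames(regions) <- NULL
  }
  truth <- structure(list(samples = samples, events = events,
                          regions = regions, seed = as.integer(seed)),
                     class = "cohort_truth")
  list(profiles = profiles, truth = truth)
}

#' Simulate a tumour/normal candidate-variant table with known truth
#'
#' Somatic sites carry alternate reads in the tumour only, with the variant
#' allele fraction drawn from a Beta distribution centred at `vaf_mean`
#' (0.4 by default, reflecting >70% tumour cellularity: most somatic sites
#' clear the 20% VAF filter while borderline cases still occur).  Germline
#' sites are heterozygous in both tumour and normal.
#'
#' @param n_sites Number of candidate sites.
#' @param somatic_fraction Proportion of sites that are truly somatic.
#' @param depth_model Named numeric `c(tumor=, normal=)` mean depths.
#' @param seed Integer seed.
#' @param vaf_mean,vaf_concentration Beta mean/concentration of the somatic
#'   VAF (shape1 = mean*conc, shape2 = (1-mean)*conc).
#' @param error_rate Sequencing-error alternate-read rate at somatic sites
#'   in the normal.
#' @return List with `variants` (a variant table `data.frame`) and
#'   `truth` (logical vector, `TRUE` = somatic).
#' @export
generate_variant_table <- function(n_sites,
                                   somatic_fraction = 0.5,
                                   depth_model = c(tumor = 100, normal = 100),
                                   seed,
                                   vaf_mean = 0.4,
                                   vaf_concentration = 30,
                                   error_rate = 0.001) {
  stopifnot(n_sites >= 1, somatic_fraction >= 0, somatic_fraction <= 1,
            all(depth_model > 0))
  if (missing(seed)) stop("`seed` is required")
  set.seed(as.integer(seed))

  somatic <- stats::runif(n_sites) < somatic_fraction
  dp_t <- pmax(1L, stats::rpois(n_sites, depth_model[["tumor"]]))
  dp_n <- pmax(1L, stats::rpois(n_sites, depth_model[["normal"]]))
  vaf_true <- ifelse(
    somatic,
    stats::rbeta(n_sites, vaf_mean * vaf_concentration,
                 (1 - vaf_mean) * vaf_concentration),
    0.5
  )
  alt_t <- stats::rbinom(n_sites, dp_t, vaf_true)
  alt_n <- stats::rbinom(n_sites, dp_n, ifelse(somatic, error_rate, vaf_true))
  bq <- round(pmin(40, pmax(2, stats::rnorm(n_sites, 32, 4))), 1)
  hq_alt <- stats::rbinom(n_sites, alt_t, 0.95)

  codons <- .random_codon_changes(n_sites)
  variants <- data.frame(
    site = sprintf("V%04d", seq_len(n_sites)),
    gene = sprintf("GENE%03d", sample.int(max(50L, n_sites %/% 5L),
                                          n_sites, replace = TRUE)),
    chrom = sample(paste0("chr", c(1:22, "X")), n_sites, replace = TRUE),
    pos = sample.int(1e8, n_sites),
    ref_codon = codons$ref,
    alt_codon = codons$alt,
    tumor_ref = dp_t - alt_t,
    tumor_alt = alt_t,
    normal_ref = dp_n - alt_n,
    normal_alt = alt_n,
    base_quality = bq,
    hq_alt_reads = hq_alt,
    known_variant = ifelse(somatic, stats::runif(n_sites) < 0.02,
                           stats::runif(n_sites) < 0.9),
    polyphen2 = ifelse(stats::runif(n_sites) < 0.8,
                       round(stats::rbeta(n_sites, 0.5, 0.5), 2), NA_real_),
    gerp = ifelse(stats::runif(n_sites) < 0.5,
                  round(stats::runif(n_sites, -2, 6), 2), NA_real_),
    stringsAsFactors = FALSE
  )
  list(variants = variants, truth = somatic)
}

# random single-base codon substitutions (non-stop reference codons)
.random_codon_changes <- function(n) {
  bases <- c("A", "C", "G", "T")
  ref <- character(n); alt <- character(n)
  stops <- c("TAA", "TAG", "TGA")
  for (i in seq_len(n)) {
    repeat {
      r <- paste(sample(bases, 3L, replace = TRUE), collapse = "")
      if (!r %in% stops) break
    }
    pos <- sample.int(3L, 1L)
    b <- substr(r, pos, pos)
    nb <- sample(setdiff(bases, b), 1L)
    a <- r
    substr(a, pos, pos) <- nb
    ref[i] <- r; alt[i] <- a
  }
  list(ref = ref, alt = alt)
}

#' Simulate an expression matrix coupled to copy number
#'
#' Coupled genes follow `slope * local_copy_number + N(0, noise_sd)`;
#' uncoupled genes are pure Gaussian noise.  Local copy number at a locus is
#' the total copy number of the profile segment containing the nearest probe.
#'
#' @param profiles List of [segment_profile()] objects.
#' @param coupled_genes `data.frame(gene, chrom, pos, slope)`.
#' @param map The `snp_map` the profiles live on.
#' @param noise_sd Gaussian noise standard deviation (>= 0).
#' @param n_uncoupled Number of additional pure-noise genes.
#' @param seed Integer seed.
#' @return Numeric matrix, genes x samples.
#' @export
generate_expression <- function(profiles, coupled_genes,
                                map = default_snp_map(),
                                noise_sd = 0.5, n_uncoupled = 0L, seed) {
  stopifnot(length(profiles) > 0L, noise_sd >= 0,
            all(c("gene", "chrom", "pos", "slope") %in% names(coupled_genes)))
  if (missing(seed)) stop("`seed` is required")
  for (i in seq_len(nrow(coupled_genes))) {
    chrom <- coupled_genes$chrom[i]
    if (!chrom %in% map$chrom) {
      stop("gene ", coupled_genes$gene[i], ": unknown chromosome ", chrom)
    }
    p <- map$positions[[chrom]]
    if (coupled_genes$pos[i] < p[1] || coupled_genes$pos[i] > p[length(p)]) {
      stop("gene ", coupled_genes$gene[i], " position outside probe territory")
    }
  }
  set.seed(as.integer(seed))
  ids <- unname(vapply(profiles, function(p) p$sample, character(1)))
  n <- length(profiles)
  cn <- vapply(profiles, function(prof) {
    vapply(seq_len(nrow(coupled_genes)), function(i) {
      cn_at_locus(prof, coupled_genes$chrom[i], coupled_genes$pos[i], map)
    }, numeric(1))
  }, numeric(nrow(coupled_genes)))
  cn <- matrix(cn, nrow = nrow(coupled_genes))
  expr <- cn * coupled_genes$slope +
    matrix(stats::rnorm(length(cn), 0, noise_sd), nrow = nrow(cn))
  rownames(expr) <- coupled_genes$gene
  if (n_uncoupled > 0L) {
    noise <- matrix(stats::rnorm(n_uncoupled * n, 0, max(noise_sd, 1)),
                    nrow = n_uncoupled,
                    dimnames = list(sprintf("NOISE%03d", seq_len(n_uncoupled)),
                                    NULL))
    expr <- rbind(expr, noise)
  }
  colnames(expr) <- ids
  expr
}

#' Total copy number at a genomic locus
#'
#' Returns the total copy number of the segment containing the probe nearest
#' to `pos` on `chrom` (segment-wise profiles have no sub-probe resolution).
#'
#' @param profile A [segment_profile()].
#' @param chrom,pos Locus.
#' @param map The `snp_map` the profile lives on.
#' @return Integer copy number, or `NA` if no segment covers the locus.
#' @export
cn_at_locus <- function(profile, chrom, pos, map = default_snp_map()) {
  stopifnot(inherits(profile, "segment_profile"))
  if (!chrom %in% map$chrom) stop("unknown chromosome: ", chrom)
  p <- map$positions[[chrom]]
  probe_pos <- p[which.min(abs(p - pos))]
  s <- profile$segments
  hit <- which(s$chrom == chrom & s$start <= probe_pos & s$end >= probe_pos)
  if (length(hit) == 0L) return(NA_integer_)
  s$total_cn[hit[1]]
}
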