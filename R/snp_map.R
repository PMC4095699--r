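# Approximate GRCh37 chromosome lengths and centromere midpoints (bp).
# Used only to lay out the reduced default probe map and to resolve
# chromosome-arm labels such as "8q"; probe-level analyses never depend on
# these numbers being exact.
.chrom_info <- data.frame(
  chrom = paste0("chr", c(1:22, "X")),
  length_bp = c(
    249250621L, 243199373L, 198022430L, 191154276L, 180915260L,
    171115067L, 159138663L, 146364022L, 141213431L, 135534747L,
    135006516L, 133851895L, 115169878L, 107349540L, 102531392L,
    90354753L, 81195210L, 78077248L, 59128983L, 63025520L,
    48129895L, 51304566L, 155270560L
  ),
  centromere_bp = c(
    125000000L, 93300000L, 91000000L, 50400000L, 48400000L,
    61000000L, 59900000L, 45600000L, 49000000L, 40200000L,
    53700000L, 35800000L, 17900000L, 17600000L, 19000000L,
    36600000L, 24000000L, 17200000L, 26500000L, 27500000L,
    13200000L, 14700000L, 60600000L
  ),
  stringsAsFactors = FALSE
)

#' SNP probe position map
#'
#' A `snp_map` carries the ordered chromosomes and the strictly increasing
#' probe positions the whole pipeline is indexed on.  Run-length rules such
#' as "at least 25 consecutive SNPs" are counted on this map.
#'
#' @param positions Named list of integer vectors; one strictly increasing
#'   position vector (bp) per chromosome, in chromosome order.
#' @param chrom_info Optional `data.frame` with columns `chrom`, `length_bp`
#'   and `centromere_bp`; required for chromosome-arm lookups (e.g. "8q").
#' @return An object of class `snp_map`.
#' @export
snp_map <- function(positions, chrom_info = NULL) {
  if (!is.list(positions) || length(positions) == 0L ||
      is.null(names(positions)) || any(!nzchar(names(positions)))) {
    stop("`positions` must be a non-empty named list of position vectors")
  }
  positions <- lapply(positions, function(p) as.integer(round(p)))
  for (chr in names(positions)) {
    p <- positions[[chr]]
    if (length(p) == 0L) stop("chromosome ", chr, " has no probes")
    if (any(p <= 0L)) stop("probe positions must be positive on ", chr)
    if (length(p) > 1L && any(diff(p) <= 0L)) {
      stop("probe positions must be strictly increasing on ", chr)
    }
  }
  if (!is.null(chrom_info)) {
    need <- c("chrom", "length_bp", "centromere_bp")
    if (!all(need %in% names(chrom_info))) {
      stop("`chrom_info` must have columns ", paste(need, collapse = ", "))
    }
    if (!all(names(positions) %in% chrom_info$chrom)) {
      stop("every chromosome in `positions` must appear in `chrom_info`")
    }
  }
  structure(
    list(
      chrom = names(positions),
      positions = positions,
      n_per_chrom = vapply(positions, length, integer(1)),
      n_probes = sum(vapply(positions, length, integer(1))),
      chrom_info = chrom_info
    ),
    class = "snp_map"
  )
}

#' Reduced default genome map
#'
#' 22 autosomes plus X with `probes_per_chrom` evenly spaced probes each,
#' over approximate GRCh37 chromosome lengths.  Small enough that full
#' cohorts simulate and cluster in seconds, while keeping realistic
#' chromosome/arm proportions.
#'
#' @param probes_per_chrom Probes per chromosome (default 1000).
#' @return A `snp_map`.
#' @export
default_snp_map <- function(probes_per_chrom = 1000L) {
  stopifnot(probes_per_chrom >= 2L)
  pos <- lapply(seq_len(nrow(.chrom_info)), function(i) {
    as.integer(round(seq(100000, .chrom_info$length_bp[i] - 100000,
                         length.out = probes_per_chrom)))
  })
  names(pos) <- .chrom_info$chrom
  snp_map(pos, .chrom_info)
}

#' @export
print.snp_map <- function(x, ...) {
  cat("snp_map:", length(x$chrom), "chromosomes,", x$n_probes, "probes\n")
  invisible(x)
}

#' Flat probe table for a map
#'
#' @param map A `snp_map`.
#' @return `data.frame` with columns `probe` (global 1-based index),
#'   `chrom`, `pos`.
#' @export
probe_table <- function(map) {
  stopifnot(inherits(map, "snp_map"))
  data.frame(
    probe = seq_len(map$n_probes),
    chrom = rep(map$chrom, map$n_per_chrom),
    pos = unlist(map$positions, use.names = FALSE),
    stringsAsFactors = FALSE
  )
}

# Resolve an arm label like "8q" or "Xp" to (chrom, start_bp, end_bp).
# Unknown chromosome or missing chrom_info is a configuration error.
arm_interval <- function(map, arm) {
  stopifnot(inherits(map, "snp_map"), is.character(arm), length(arm) == 1L)
  if (is.null(map$chrom_info)) {
    stop("map has no chromosome info; cannot resolve arm '", arm, "'")
  }
  m <- regmatches(arm, regexec("^(chr)?([0-9XY]+)([pq])$", arm))[[1]]
  if (length(m) == 0L) stop("malformed chromosome arm: '", arm, "'")
  chrom <- paste0("chr", m[3])
  side <- m[4]
  info <- map$chrom_info
  row <- match(chrom, info$chrom)
  if (is.na(row) || !(chrom %in% map$chrom)) {
    stop("unknown chromosome arm: '", arm, "'")
  }
  cen <- info$centromere_bp[row]
  if (side == "p") c(start = 1, end = cen - 1) else {
    c(start = cen, end = info$length_bp[row])
  }
}

# Local (within-chromosome) probe indices falling in [start_bp, end_bp].
probes_in_interval <- function(map, chrom, start_bp, end_bp) {
  if (!chrom %in% map$chrom) stop("unknown chromosome: ", chrom)
  p <- map$positions[[chrom]]
  which(p >= start_bp & p <= end_bp)
}

# Offset of a chromosome's first probe in the global probe index.
chrom_offset <- function(map, chrom) {
  i <- match(chrom, map$chrom)
  if (is.na(i)) stop("unknown chromosome: ", chrom)
  if (i == 1L) 0L else sum(map$n_per_chrom[seq_len(i - 1L)])
}
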