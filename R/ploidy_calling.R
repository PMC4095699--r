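#' Ploidy-adaptive alteration cutoffs
#'
#' Integer total-copy-number cutoffs per ploidy class: a region is a LOSS at
#' `total <= loss_max`, an AMP at `total >= amp_min`, a GAIN in between at
#' `total >= gain_min`, and NEUTRAL otherwise.  Defaults follow the
#' SNP-array convention for GAP-style integer profiles: near-diploid
#' (1, 3, 6) and near-tetraploid (2, 6, 8).
#'
#' @param near_diploid,near_tetraploid Named numeric
#'   `c(loss_max=, gain_min=, amp_min=)`.
#' @return Named list of the two cutoff vectors, class `ploidy_cutoffs`.
#' @export
ploidy_cutoffs <- function(near_diploid = c(loss_max = 1, gain_min = 3,
                                            amp_min = 6),
                           near_tetraploid = c(loss_max = 2, gain_min = 6,
                                               amp_min = 8)) {
  chk <- function(x, nm) {
    if (!all(c("loss_max", "gain_min", "amp_min") %in% names(x))) {
      stop(nm, " must name loss_max, gain_min, amp_min")
    }
    if (!(x[["loss_max"]] < x[["gain_min"]] &&
          x[["gain_min"]] < x[["amp_min"]])) {
      stop(nm, ": need loss_max < gain_min < amp_min")
    }
    x[c("loss_max", "gain_min", "amp_min")]
  }
  structure(list(near_diploid = chk(near_diploid, "near_diploid"),
                 near_tetraploid = chk(near_tetraploid, "near_tetraploid")),
            class = "ploidy_cutoffs")
}

#' Classify tumour ploidy from a segmented profile
#'
#' Simplified rule standing in for full allele-specific pattern recognition:
#' near-tetraploid iff the length-weighted (bp) mean total copy number is
#' >= 3.0, else near-diploid.  The tie at exactly 3.0 goes to
#' near-tetraploid.  A ploidy class already declared on the profile is
#' returned unchanged.
#'
#' @param profile A [segment_profile()].
#' @return `"near_diploid"` or `"near_tetraploid"`.
#' @export
estimate_ploidy_class <- function(profile) {
  stopifnot(inherits(profile, "segment_profile"))
  if (profile$ploidy != "undeclared") return(profile$ploidy)
  s <- profile$segments
  if (nrow(s) == 0L) stop("empty profile")
  w <- as.numeric(s$end - s$start + 1)
  mean_cn <- sum(w * s$total_cn) / sum(w)
  if (mean_cn >= 3.0) "near_tetraploid" else "near_diploid"
}

#' Discrete alteration state of a total copy number
#'
#' @param total_cn Integer vector of total copy numbers (>= 0).
#' @param cutoffs One entry of [ploidy_cutoffs()] (named vector with
#'   `loss_max`, `gain_min`, `amp_min`).
#' @return Character vector over `LOSS`, `NEUTRAL`, `GAIN`, `AMP`.
#' @export
call_status <- function(total_cn, cutoffs) {
  stopifnot(all(total_cn >= 0), all(total_cn == round(total_cn)),
            all(c("loss_max", "gain_min", "amp_min") %in% names(cutoffs)))
  out <- rep("NEUTRAL", length(total_cn))
  out[total_cn <= cutoffs[["loss_max"]]] <- "LOSS"
  out[total_cn >= cutoffs[["gain_min"]]] <- "GAIN"
  out[total_cn >= cutoffs[["amp_min"]]] <- "AMP"
  out
}

#' Loss of heterozygosity flag
#'
#' LOH iff the minor-allele copy number is zero while at least one copy
#' remains (covers both hemizygous deletion and copy-neutral LOH).
#' `total_cn == 0` is a homozygous deletion, flagged separately via
#' [homozygous_deletion()].
#'
#' @param total_cn,minor_cn Integer vectors.
#' @return Logical vector.
#' @export
detect_loh <- function(total_cn, minor_cn) {
  stopifnot(length(total_cn) == length(minor_cn))
  minor_cn == 0L & total_cn >= 1L
}

#' @rdname detect_loh
#' @export
homozygous_deletion <- function(total_cn) {
  total_cn == 0L
}

#' Project a segmented profile onto probe-level alteration states
#'
#' Each probe takes the state of the segment containing it under the
#' profile's ploidy-class cutoffs; probes outside all segments are NEUTRAL
#' with a warning (tolerates sparse SEG input).
#'
#' @param profile A [segment_profile()]; ploidy is resolved with
#'   [estimate_ploidy_class()] if undeclared.
#' @param map A `snp_map`.
#' @param cutoffs A [ploidy_cutoffs()] object.
#' @param exclude_x If `TRUE`, chrX probes are forced NEUTRAL (the cutoffs
#'   otherwise treat X like an autosome).
#' @return A `status_profile`: list with `sample`, `ploidy`, `state`
#'   (character vector over the map's probes), `loh` and `homdel`
#'   (logical vectors).
#' @export
call_profile <- function(profile, map = default_snp_map(),
                         cutoffs = ploidy_cutoffs(), exclude_x = FALSE) {
  stopifnot(inherits(profile, "segment_profile"), inherits(map, "snp_map"),
            inherits(cutoffs, "ploidy_cutoffs"))
  ploidy <- estimate_ploidy_class(profile)
  cut <- cutoffs[[ploidy]]
  state <- rep(NA_character_, map$n_probes)
  loh <- rep(FALSE, map$n_probes)
  homdel <- rep(FALSE, map$n_probes)
  segs <- profile$segments
  for (chrom in unique(segs$chrom)) {
    if (!chrom %in% map$chrom) stop("profile chromosome ", chrom,
                                    " not on map")
    s <- segs[segs$chrom == chrom, , drop = FALSE]
    p <- map$positions[[chrom]]
    off <- chrom_offset(map, chrom)
    # map each probe to the segment containing it (segments are sorted,
    # non-overlapping)
    seg_idx <- findInterval(p, s$start)
    covered <- seg_idx >= 1L & p <= s$end[pmax(seg_idx, 1L)]
    idx <- which(covered)
    if (length(idx)) {
      si <- seg_idx[idx]
      st <- call_status(s$total_cn, cut)
      state[off + idx] <- st[si]
      loh[off + idx] <- detect_loh(s$total_cn, s$minor_cn)[si]
      homdel[off + idx] <- homozygous_deletion(s$total_cn)[si]
    }
  }
  n_uncovered <- sum(is.na(state))
  if (n_uncovered > 0L) {
    warning(n_uncovered, " probes outside all segments for sample ",
            profile$sample, "; set NEUTRAL")
    state[is.na(state)] <- "NEUTRAL"
  }
  if (exclude_x && "chrX" %in% map$chrom) {
    off <- chrom_offset(map, "chrX")
    ix <- off + seq_len(map$n_per_chrom[["chrX"]])
    state[ix] <- "NEUTRAL"; loh[ix] <- FALSE; homdel[ix] <- FALSE
  }
  structure(list(sample = profile$sample, ploidy = ploidy, state = state,
                 loh = loh, homdel = homdel, map = map),
            class = "status_profile")
}

#' Count breakpoints in a segmented profile
#'
#' A breakpoint is a change, between adjacent segments of the same
#' chromosome, in total copy number or in allelic composition
#' (major/minor split).  Chromosome boundaries are never counted.
#'
#' @param profile A [segment_profile()].
#' @return Integer breakpoint count.
#' @export
count_breakpoints <- function(profile) {
  stopifnot(inherits(profile, "segment_profile"))
  s <- profile$segments
  n <- 0L
  for (chrom in unique(s$chrom)) {
    x <- s[s$chrom == chrom, , drop = FALSE]
    if (nrow(x) < 2L) next
    d <- diff(x$total_cn) != 0L | diff(x$minor_cn) != 0L
    n <- n + sum(d)
  }
  n
}
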