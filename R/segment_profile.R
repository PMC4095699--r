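#' Allele-specific segmented copy-number profile
#'
#' One tumour's genome as non-overlapping, sorted segments carrying integer
#' total and minor-allele copy numbers, plus a ploidy class that selects the
#' alteration cutoffs downstream.  Copy numbers are inferred integers from
#' allele-specific segmentation; non-integer input is rejected rather than
#' rounded.
#'
#' @param sample Sample identifier (scalar character).
#' @param segments `data.frame` with columns `chrom`, `start`, `end`
#'   (1-based inclusive bp), `total_cn`, `minor_cn` (non-negative integers).
#' @param ploidy One of `"near_diploid"`, `"near_tetraploid"`,
#'   `"undeclared"`.  A declared class is honoured by
#'   [estimate_ploidy_class()]; `"undeclared"` triggers inference.
#' @return A `segment_profile` object.
#' @export
segment_profile <- function(sample, segments,
                            ploidy = c("undeclared", "near_diploid",
                                       "near_tetraploid")) {
  ploidy <- match.arg(ploidy)
  stopifnot(is.character(sample), length(sample) == 1L, nzchar(sample))
  need <- c("chrom", "start", "end", "total_cn", "minor_cn")
  if (!is.data.frame(segments) || !all(need %in% names(segments))) {
    stop("`segments` must be a data.frame with columns ",
         paste(need, collapse = ", "))
  }
  if (nrow(segments) == 0L) stop("profile for ", sample, " has no segments")
  segments <- segments[, need]
  for (col in c("total_cn", "minor_cn")) {
    v <- segments[[col]]
    if (any(!is.finite(v)) || any(v < 0) || any(v != round(v))) {
      stop("`", col, "` must be non-negative integers (sample ", sample, ")")
    }
    segments[[col]] <- as.integer(v)
  }
  if (any(segments$minor_cn > segments$total_cn - segments$minor_cn)) {
    bad <- which(segments$minor_cn > segments$total_cn - segments$minor_cn)[1]
    stop("minor_cn exceeds major allele count at segment ", bad,
         " of sample ", sample)
  }
  if (any(segments$end < segments$start)) {
    stop("segment end < start in sample ", sample)
  }
  # sort by chromosome (order of first appearance) then start
  chrom_lev <- unique(segments$chrom)
  o <- order(match(segments$chrom, chrom_lev), segments$start)
  segments <- segments[o, , drop = FALSE]
  rownames(segments) <- NULL
  by_chr <- split(seq_len(nrow(segments)), segments$chrom)
  for (idx in by_chr) {
    if (length(idx) > 1L) {
      s <- segments[idx, ]
      if (any(s$start[-1] <= s$end[-length(idx)])) {
        stop("overlapping segments on ", s$chrom[1], " in sample ", sample)
      }
    }
  }
  structure(list(sample = sample, segments = segments, ploidy = ploidy),
            class = "segment_profile")
}

#' @export
print.segment_profile <- function(x, ...) {
  cat("segment_profile:", x$sample, "-", nrow(x$segments), "segments,",
      "ploidy:", x$ploidy, "\n")
  invisible(x)
}
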