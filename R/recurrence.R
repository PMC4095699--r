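#' Assemble probe-level status profiles into a cohort matrix
#'
#' @param status_profiles List of `status_profile` objects on a common map.
#' @param groups Optional character vector of group labels (one per sample).
#' @return A `status_matrix`: list with `samples`, `state` (samples x probes
#'   character matrix), `loh` (logical matrix), `map`, `groups`.
#' @export
status_matrix <- function(status_profiles, groups = NULL) {
  stopifnot(is.list(status_profiles), length(status_profiles) > 0L)
  ids <- unname(vapply(status_profiles, function(p) p$sample, character(1)))
  if (anyDuplicated(ids)) stop("sample ids must be unique")
  map <- status_profiles[[1]]$map
  n_probes <- map$n_probes
  for (p in status_profiles) {
    if (length(p$state) != n_probes) stop("profiles are on different maps")
  }
  state <- t(vapply(status_profiles, function(p) p$state,
                    character(n_probes)))
  loh <- t(vapply(status_profiles, function(p) p$loh, logical(n_probes)))
  rownames(state) <- rownames(loh) <- ids
  if (!is.null(groups)) stopifnot(length(groups) == length(ids))
  structure(list(samples = ids, state = state, loh = loh, map = map,
                 groups = groups),
            class = "status_matrix")
}

#' @export
print.status_matrix <- function(x, ...) {
  cat("status_matrix:", length(x$samples), "samples x",
      ncol(x$state), "probes\n")
  invisible(x)
}

#' Per-probe alteration frequency across a cohort
#'
#' @param matrix A [status_matrix()].
#' @param event A state or set of states (e.g. `"AMP"` or
#'   `c("GAIN", "AMP")`).
#' @return Numeric vector in `[0, 1]`, one proportion per probe.
#' @export
frequency_profile <- function(matrix, event) {
  stopifnot(inherits(matrix, "status_matrix"))
  if (length(matrix$samples) == 0L) stop("empty cohort")
  colMeans(matrix(matrix$state %in% event, nrow = nrow(matrix$state)))
}

# Maximal runs of TRUE of length >= min_len within one chromosome;
# returns data.frame(start_idx, end_idx) in local probe indices.
.qualifying_runs <- function(qual, min_len) {
  r <- rle(qual)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_len
  data.frame(start_idx = starts[keep], end_idx = ends[keep])
}

#' Recurrent minimal regions of alteration
#'
#' Maximal runs of at least `min_snps` consecutive probes, within one
#' chromosome, whose event frequency strictly exceeds `min_freq` at every
#' probe (the 25-SNP / >20% rule).  The reported frequency is the minimum
#' over the run; carriers are the samples altered across the whole run.
#'
#' @param matrix A [status_matrix()].
#' @param event State or state set defining the alteration.
#' @param min_snps Minimum run length in probes (default 25).
#' @param min_freq Strict frequency threshold (default 0.20).
#' @return `data.frame` with columns `chrom`, `start`, `end` (bp, 1-based
#'   inclusive), `start_probe`, `end_probe` (global indices), `n_probes`,
#'   `event`, `frequency`, `n_carriers` and a list column `carriers`.
#' @export
recurrent_regions <- function(matrix, event, min_snps = 25L,
                              min_freq = 0.20) {
  stopifnot(inherits(matrix, "status_matrix"), min_snps >= 1L)
  freq <- frequency_profile(matrix, event)
  map <- matrix$map
  out <- list()
  for (chrom in map$chrom) {
    off <- chrom_offset(map, chrom)
    n <- map$n_per_chrom[[chrom]]
    f <- freq[off + seq_len(n)]
    runs <- .qualifying_runs(f > min_freq, min_snps)
    if (nrow(runs) == 0L) next
    p <- map$positions[[chrom]]
    for (i in seq_len(nrow(runs))) {
      a <- runs$start_idx[i]; b <- runs$end_idx[i]
      span <- off + a:b
      in_event <- matrix$state[, span, drop = FALSE] %in% event
      in_event <- matrix(in_event, nrow = nrow(matrix$state))
      carriers <- matrix$samples[rowSums(in_event) == length(span)]
      out[[length(out) + 1L]] <- data.frame(
        chrom = chrom, start = p[a], end = p[b],
        start_probe = off + a, end_probe = off + b,
        n_probes = b - a + 1L,
        event = paste(event, collapse = "|"),
        frequency = min(f[a:b]),
        n_carriers = length(carriers),
        carriers = I(list(carriers)),
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(out) == 0L) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), start_probe = integer(),
                      end_probe = integer(), n_probes = integer(),
                      event = character(), frequency = numeric(),
                      n_carriers = integer(),
                      carriers = I(list()), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Minimal common region of a set of carrier intervals
#'
#' Intersection of one interval per carrier sample; all intervals must lie
#' on the same chromosome.  Returns `NULL` when the intervals are disjoint.
#'
#' @param intervals `data.frame(chrom, start, end)`, one row per carrier.
#' @return One-row `data.frame(chrom, start, end)`, or `NULL`.
#' @export
minimal_common_region <- function(intervals) {
  stopifnot(is.data.frame(intervals),
            all(c("chrom", "start", "end") %in% names(intervals)),
            nrow(intervals) >= 1L)
  if (length(unique(intervals$chrom)) > 1L) {
    stop("intervals span multiple chromosomes")
  }
  start <- max(intervals$start)
  end <- min(intervals$end)
  if (start > end) return(NULL)
  data.frame(chrom = intervals$chrom[1], start = start, end = end,
             stringsAsFactors = FALSE)
}

#' Regions of differing alteration frequency between two cohorts
#'
#' Maximal runs of at least `min_snps` probes where the absolute frequency
#' difference strictly exceeds `min_diff` at every probe, annotated with
#' each group's mean frequency over the run.  An optional per-region
#' two-sided Fisher exact test (on mean carrier counts) with
#' Benjamini-Hochberg correction can be attached; it is off by default
#' because the underlying study reports the contrast without a test.
#'
#' @param matrixA,matrixB Two [status_matrix()] cohorts on the same map.
#' @param event State or state set.
#' @param min_diff Strict threshold on the absolute frequency difference.
#' @param min_snps Minimum run length (default 25).
#' @param fisher If `TRUE`, attach `p_value` and `p_adj` columns.
#' @return `data.frame` with region coordinates, `freq_a`, `freq_b`.
#' @export
compare_group_frequencies <- function(matrixA, matrixB, event, min_diff,
                                      min_snps = 25L, fisher = FALSE) {
  stopifnot(inherits(matrixA, "status_matrix"),
            inherits(matrixB, "status_matrix"))
  if (!identical(matrixA$map$positions, matrixB$map$positions)) {
    stop("cohorts are on different SNP maps")
  }
  fa <- frequency_profile(matrixA, event)
  fb <- frequency_profile(matrixB, event)
  dif <- abs(fa - fb)
  map <- matrixA$map
  out <- list()
  for (chrom in map$chrom) {
    off <- chrom_offset(map, chrom)
    n <- map$n_per_chrom[[chrom]]
    runs <- .qualifying_runs(dif[off + seq_len(n)] > min_diff, min_snps)
    if (nrow(runs) == 0L) next
    p <- map$positions[[chrom]]
    for (i in seq_len(nrow(runs))) {
      a <- runs$start_idx[i]; b <- runs$end_idx[i]
      out[[length(out) + 1L]] <- data.frame(
        chrom = chrom, start = p[a], end = p[b],
        start_probe = off + a, end_probe = off + b,
        n_probes = b - a + 1L,
        event = paste(event, collapse = "|"),
        freq_a = mean(fa[off + a:b]),
        freq_b = mean(fb[off + a:b]),
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(out) == 0L) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), start_probe = integer(),
                      end_probe = integer(), n_probes = integer(),
                      event = character(), freq_a = numeric(),
                      freq_b = numeric(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  if (isTRUE(fisher)) {
    nA <- length(matrixA$samples); nB <- length(matrixB$samples)
    res$p_value <- vapply(seq_len(nrow(res)), function(i) {
      kA <- round(res$freq_a[i] * nA); kB <- round(res$freq_b[i] * nB)
      stats::fisher.test(matrix(c(kA, nA - kA, kB, nB - kB), 2L))$p.value
    }, numeric(1))
    res$p_adj <- stats::p.adjust(res$p_value, method = "BH")
  }
  res
}
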