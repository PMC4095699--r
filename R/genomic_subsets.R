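#' Encode discrete alteration states as an ordinal numeric matrix
#'
#' Default encoding LOSS -1, NEUTRAL 0, GAIN +1, AMP +2: states are already
#' on a common ordinal scale, so no further feature scaling is applied
#' before Euclidean distances.
#'
#' @param matrix A [status_matrix()].
#' @param encoding Named numeric vector mapping states to values.
#' @return Numeric matrix, samples x probes.
#' @export
encode_states <- function(matrix,
                          encoding = c(LOSS = -1, NEUTRAL = 0,
                                       GAIN = 1, AMP = 2)) {
  stopifnot(inherits(matrix, "status_matrix"))
  st <- matrix$state
  if (!all(unique(as.vector(st)) %in% names(encoding))) {
    stop("encoding does not cover all states present")
  }
  enc <- encoding[st]
  out <- base::matrix(as.numeric(enc), nrow = nrow(st),
                      dimnames = dimnames(st))
  out
}

#' Unsupervised genomic-subset discovery (Ward / Euclidean)
#'
#' Agglomerative hierarchical clustering of probe-level state vectors with
#' Ward's minimum-variance criterion on Euclidean distances
#' (`stats::hclust(method = "ward.D2")`), cut into `k` clusters (or at
#' height `h`).  The full tree is returned so other cuts can be taken.
#'
#' @param encoded Numeric samples x probes matrix from [encode_states()].
#' @param k Number of clusters (default 2, the two recognised archetypes).
#' @param h Optional height-based cut, used instead of `k` when given.
#' @return A `subset_result`: list with `labels` (named integer vector),
#'   `tree` (the `hclust` object) and `k`.
#' @export
ward_cluster <- function(encoded, k = 2L, h = NULL) {
  stopifnot(is.matrix(encoded), is.numeric(encoded))
  n <- nrow(encoded)
  if (is.null(h)) {
    if (k < 1L || k > n) stop("`k` must be between 1 and the sample count")
  }
  d <- stats::dist(encoded, method = "euclidean")
  tree <- stats::hclust(d, method = "ward.D2")
  labels <- if (is.null(h)) stats::cutree(tree, k = k) else {
    stats::cutree(tree, h = h)
  }
  names(labels) <- rownames(encoded)
  structure(list(labels = labels, tree = tree,
                 k = length(unique(labels))),
            class = "subset_result")
}

#' @export
print.subset_result <- function(x, ...) {
  cat("subset_result:", length(x$labels), "samples in", x$k, "clusters\n")
  print(table(x$labels))
  invisible(x)
}

#' Characterise discovered genomic subsets
#'
#' Per-subset frequency profiles for the given event sets, plus pairwise
#' subset-versus-subset frequency contrasts (via
#' [compare_group_frequencies()]).
#'
#' @param matrix A [status_matrix()].
#' @param labels Cluster labels, one per sample (any label type).
#' @param events Named list of state sets to profile.
#' @param min_diff,min_snps Contrast thresholds.
#' @return List with `frequencies` (list: subset -> event -> numeric
#'   vector), `sizes`, and `contrasts` (data.frame of contrasted regions
#'   with `subset_a`/`subset_b` columns).
#' @export
characterize_subsets <- function(matrix, labels,
                                 events = list(loss = "LOSS",
                                               gain = c("GAIN", "AMP"),
                                               amp = "AMP"),
                                 min_diff = 0.2, min_snps = 25L) {
  stopifnot(inherits(matrix, "status_matrix"),
            length(labels) == length(matrix$samples))
  labs <- as.character(labels)
  lev <- unique(labs)
  sub_mats <- lapply(lev, function(l) {
    idx <- which(labs == l)
    if (length(idx) == 0L) stop("subset ", l, " has no samples")
    structure(list(samples = matrix$samples[idx],
                   state = matrix$state[idx, , drop = FALSE],
                   loh = matrix$loh[idx, , drop = FALSE],
                   map = matrix$map, groups = NULL),
              class = "status_matrix")
  })
  names(sub_mats) <- lev
  freqs <- lapply(sub_mats, function(sm) {
    lapply(events, function(ev) frequency_profile(sm, ev))
  })
  contrasts <- list()
  if (length(lev) > 1L) {
    for (i in seq_len(length(lev) - 1L)) {
      for (j in seq((i + 1L), length(lev))) {
        for (ev_name in names(events)) {
          cmp <- compare_group_frequencies(sub_mats[[i]], sub_mats[[j]],
                                           events[[ev_name]],
                                           min_diff = min_diff,
                                           min_snps = min_snps)
          if (nrow(cmp) > 0L) {
            cmp$subset_a <- lev[i]; cmp$subset_b <- lev[j]
            contrasts[[length(contrasts) + 1L]] <- cmp
          }
        }
      }
    }
  }
  contrasts <- if (length(contrasts)) do.call(rbind, contrasts) else {
    data.frame()
  }
  list(frequencies = freqs,
       sizes = vapply(sub_mats, function(s) length(s$samples), integer(1)),
       contrasts = contrasts)
}

#' Adjusted Rand index between two partitions
#'
#' Hubert-Arabie adjusted Rand index; 1 for identical partitions (up to
#' label permutation), ~0 for independent ones.
#'
#' @param a,b Two label vectors of equal length.
#' @return Numeric scalar.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) > 0L)
  tab <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}
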