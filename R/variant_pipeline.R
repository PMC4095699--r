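#' Somatic SNV filter thresholds
#'
#' The five-criterion false-positive filter applied to candidate somatic
#' SNVs: Fisher exact P < 0.05 (tumour versus normal read counts),
#' coverage >= 10x, Phred base quality >= 20, variant allele frequency
#' >= 20%, and >= 4 high-quality reads supporting the variant allele.
#' VAF and read-count bounds are inclusive; the P bound is exclusive,
#' exactly as conventionally printed.
#'
#' @param fisher_p_max,min_coverage,min_base_quality,min_vaf,min_alt_reads
#'   Threshold overrides.
#' @return Named list of thresholds, class `filter_thresholds`.
#' @export
filter_thresholds <- function(fisher_p_max = 0.05, min_coverage = 10,
                              min_base_quality = 20, min_vaf = 0.20,
                              min_alt_reads = 4) {
  stopifnot(fisher_p_max > 0, min_coverage > 0, min_base_quality > 0,
            min_vaf > 0, min_vaf <= 1, min_alt_reads > 0)
  structure(list(fisher_p_max = fisher_p_max, min_coverage = min_coverage,
                 min_base_quality = min_base_quality, min_vaf = min_vaf,
                 min_alt_reads = min_alt_reads),
            class = "filter_thresholds")
}

#' Variant prioritisation rules
#'
#' Known variants (dbSNP / 1000 Genomes) are dropped; missense variants are
#' kept when their functional-impact score (PolyPhen-2) exceeds 0.5 and
#' their conservation (GERP) score exceeds 3.0.  Truncating classes
#' (nonsense, frameshift, splice) are kept regardless of scores.
#'
#' @param exclude_known_variants Drop known variants (default `TRUE`).
#' @param functional_score_min PolyPhen-2 threshold (default 0.5).
#' @param gerp_min GERP threshold (default 3.0).
#' @return Named list, class `prioritization_rules`.
#' @export
prioritization_rules <- function(exclude_known_variants = TRUE,
                                 functional_score_min = 0.5,
                                 gerp_min = 3.0) {
  stopifnot(functional_score_min >= 0, functional_score_min <= 1)
  structure(list(exclude_known_variants = exclude_known_variants,
                 functional_score_min = functional_score_min,
                 gerp_min = gerp_min),
            class = "prioritization_rules")
}

#' One-sided Fisher exact test for tumour alt-read enrichment
#'
#' Exact hypergeometric tail probability that, with the table margins
#' fixed, the tumour carries at least as many alternate reads as observed
#' (the somatic-calling convention).  The observed table's own probability
#' mass is included.  No approximation is used.
#'
#' @param tumor_ref,tumor_alt,normal_ref,normal_alt Non-negative read
#'   counts.
#' @param alternative `"greater"` (tumour-enriched alt; default) or
#'   `"two.sided"` (sum of all table probabilities not exceeding the
#'   observed one, the usual two-sided exact convention).
#' @return P-value in `(0, 1]`.
#' @export
fisher_exact_2x2 <- function(tumor_ref, tumor_alt, normal_ref, normal_alt,
                             alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  counts <- c(tumor_ref, tumor_alt, normal_ref, normal_alt)
  if (length(counts) != 4L || any(!is.finite(counts)) || any(counts < 0) ||
      any(counts != round(counts))) {
    stop("counts must be four non-negative integers")
  }
  N <- sum(counts)
  if (N == 0) stop("table total must be positive")
  K <- tumor_alt + normal_alt          # alt reads overall
  n_t <- tumor_ref + tumor_alt         # tumour draws
  kmin <- max(0, n_t - (N - K))
  kmax <- min(n_t, K)
  support <- kmin:kmax
  pmf <- stats::dhyper(support, K, N - K, n_t)
  obs <- stats::dhyper(tumor_alt, K, N - K, n_t)
  p <- if (alternative == "greater") {
    sum(pmf[support >= tumor_alt])
  } else {
    sum(pmf[pmf <= obs * (1 + 1e-7)])
  }
  min(p, 1)
}

#' Apply the five-criterion somatic SNV filter
#'
#' Coverage is `tumor_ref + tumor_alt`; VAF is `tumor_alt / coverage`.
#' Zero coverage fails the coverage and VAF criteria rather than erroring.
#'
#' @param tumor_ref,tumor_alt,normal_ref,normal_alt Read counts (vectors
#'   recycle).
#' @param base_quality Mean Phred base quality of the site.
#' @param hq_alt_reads High-quality reads supporting the variant allele.
#' @param thresholds A [filter_thresholds()] object.
#' @return `data.frame` with per-criterion logical columns `fisher`,
#'   `coverage`, `base_quality`, `vaf`, `alt_reads`, the computed
#'   `p_value` and `vaf_value`, and the overall `pass`.
#' @export
apply_filters <- function(tumor_ref, tumor_alt, normal_ref, normal_alt,
                          base_quality, hq_alt_reads,
                          thresholds = filter_thresholds()) {
  stopifnot(inherits(thresholds, "filter_thresholds"))
  n <- max(lengths(list(tumor_ref, tumor_alt, normal_ref, normal_alt,
                        base_quality, hq_alt_reads)))
  tumor_ref <- rep_len(tumor_ref, n); tumor_alt <- rep_len(tumor_alt, n)
  normal_ref <- rep_len(normal_ref, n); normal_alt <- rep_len(normal_alt, n)
  base_quality <- rep_len(base_quality, n)
  hq_alt_reads <- rep_len(hq_alt_reads, n)
  coverage <- tumor_ref + tumor_alt
  vaf <- ifelse(coverage > 0, tumor_alt / coverage, 0)
  p <- vapply(seq_len(n), function(i) {
    fisher_exact_2x2(tumor_ref[i], tumor_alt[i],
                     normal_ref[i], normal_alt[i])
  }, numeric(1))
  res <- data.frame(
    p_value = p,
    vaf_value = vaf,
    fisher = p < thresholds$fisher_p_max,
    coverage = coverage >= thresholds$min_coverage,
    base_quality = base_quality >= thresholds$min_base_quality,
    vaf = vaf >= thresholds$min_vaf & coverage > 0,
    alt_reads = hq_alt_reads >= thresholds$min_alt_reads
  )
  res$pass <- res$fisher & res$coverage & res$base_quality & res$vaf &
    res$alt_reads
  res$failed <- vapply(seq_len(n), function(i) {
    crit <- c("fisher", "coverage", "base_quality", "vaf", "alt_reads")
    paste(crit[!unlist(res[i, crit])], collapse = ",")
  }, character(1))
  res
}

#' Prioritise a filtered variant
#'
#' @param effect Variant effect (`missense`, `nonsense`, `synonymous`,
#'   `frameshift`, `splice`).
#' @param polyphen2,gerp Scores, `NA` when absent.  For missense variants
#'   both must pass when both are present; when only one score is
#'   available, that one decides.
#' @param known_variant Logical known-variant (dbSNP/1000G) flag.
#' @param rules A [prioritization_rules()] object.
#' @return List with `keep` (logical) and `reason` (character).  Intended
#'   as an advisory flag: several validated low-score variants exist, so
#'   reporting tools should not hard-drop on `keep = FALSE` alone.
#' @export
prioritize <- function(effect, polyphen2 = NA, gerp = NA,
                       known_variant = FALSE,
                       rules = prioritization_rules()) {
  stopifnot(inherits(rules, "prioritization_rules"))
  if (isTRUE(known_variant) && rules$exclude_known_variants) {
    return(list(keep = FALSE, reason = "known_variant"))
  }
  if (!identical(effect, "missense")) {
    return(list(keep = TRUE, reason = "non_missense"))
  }
  pp_ok <- if (is.na(polyphen2)) NA else polyphen2 > rules$functional_score_min
  gp_ok <- if (is.na(gerp)) NA else gerp > rules$gerp_min
  if (is.na(pp_ok) && is.na(gp_ok)) {
    return(list(keep = FALSE, reason = "no_scores"))
  }
  ok <- all(c(pp_ok, gp_ok), na.rm = TRUE)
  list(keep = ok,
       reason = if (ok) "scores_pass" else "scores_below_threshold")
}

#' Classify the protein-level effect of a codon change
#'
#' Standard genetic code; synonymous when ref and alt encode the same
#' residue, nonsense when the alt codon is a stop, missense otherwise.
#' Indel / splice descriptors are handled upstream (they carry no codon
#' pair).
#'
#' @param ref_codon,alt_codon Length-3 strings over A/C/G/T.
#' @return `"missense"`, `"nonsense"` or `"synonymous"`.
#' @export
classify_effect <- function(ref_codon, alt_codon) {
  .check_codon(ref_codon); .check_codon(alt_codon)
  code <- Biostrings::GENETIC_CODE
  aa_ref <- code[[toupper(ref_codon)]]
  aa_alt <- code[[toupper(alt_codon)]]
  if (aa_alt == "*") return("nonsense")
  if (aa_ref == aa_alt) return("synonymous")
  "missense"
}

.check_codon <- function(codon) {
  if (!is.character(codon) || length(codon) != 1L || nchar(codon) != 3L ||
      grepl("[^ACGTacgt]", codon)) {
    stop("invalid codon: '", codon, "'")
  }
}

#' Classify a nucleotide substitution as transition or transversion
#'
#' Transitions exchange purines (A<->G) or pyrimidines (C<->T); everything
#' else is a transversion.  Accepts either a codon pair differing at
#' exactly one position, a bare single-base change (`"A>G"`), or an indel
#' descriptor (anything containing `ins`/`del`), which returns `"indel"`.
#'
#' @param change Descriptor string, e.g. `"ATG>ACG"`, `"A>G"`,
#'   `"c.742_743insA"`.
#' @return `"transition"`, `"transversion"` or `"indel"`.
#' @export
classify_substitution <- function(change) {
  stopifnot(is.character(change), length(change) == 1L)
  if (grepl("ins|del", change, ignore.case = TRUE)) return("indel")
  parts <- strsplit(change, ">", fixed = TRUE)[[1]]
  if (length(parts) != 2L) stop("malformed substitution: '", change, "'")
  ref <- toupper(parts[1]); alt <- toupper(parts[2])
  if (nchar(ref) != nchar(alt)) stop("malformed substitution: '", change, "'")
  if (grepl("[^ACGT]", ref) || grepl("[^ACGT]", alt)) {
    stop("invalid bases in '", change, "'")
  }
  rs <- strsplit(ref, "")[[1]]; as_ <- strsplit(alt, "")[[1]]
  diff <- which(rs != as_)
  if (length(diff) == 0L) stop("no base change in '", change, "'")
  if (length(diff) > 1L) {
    stop("codons differ at more than one position: '", change, "'")
  }
  from <- rs[diff]; to <- as_[diff]
  purines <- c("A", "G")
  if ((from %in% purines) == (to %in% purines)) "transition" else {
    "transversion"
  }
}

#' Deleteriousness call and GERP band
#'
#' A variant is deleterious when its PolyPhen-2 score exceeds 0.5 or its
#' GERP score exceeds 4 (OR across scores: each record typically carries
#' exactly one of the two).  `gerp_bin()` bands GERP as < 3 benign,
#' 3 to 5 possibly damaging (inclusive), > 5 probably damaging.
#'
#' @param polyphen2,gerp Scores, `NA` when absent.
#' @return `classify_deleterious()`: logical (`NA` when both scores are
#'   absent); `gerp_bin()`: character band.
#' @export
classify_deleterious <- function(polyphen2 = NA, gerp = NA) {
  n <- max(length(polyphen2), length(gerp))
  polyphen2 <- rep_len(polyphen2, n); gerp <- rep_len(gerp, n)
  pp <- !is.na(polyphen2) & polyphen2 > 0.5
  gp <- !is.na(gerp) & gerp > 4
  out <- pp | gp
  out[is.na(polyphen2) & is.na(gerp)] <- NA
  out
}

#' @rdname classify_deleterious
#' @export
gerp_bin <- function(gerp) {
  ifelse(is.na(gerp), NA_character_,
         ifelse(gerp < 3, "benign",
                ifelse(gerp <= 5, "possibly_damaging", "probably_damaging")))
}

# round half away from zero, for reported integer percentages
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Summarise a cohort mutation spectrum
#'
#' Counts and whole-percent fractions over a table of nonsynonymous
#' variants: number of variants and of distinct genes, missense and
#' transition fractions, deleterious fraction (PolyPhen-2 > 0.5 or
#' GERP > 4; records with neither score count in the denominator only),
#' and per-gene case counts with cohort percentages.
#'
#' @param records `data.frame` with columns `gene`, `effect`,
#'   `substitution` (`transition`/`transversion`/`indel`), `polyphen2`,
#'   `gerp`, and either a `cases` column (cases per gene) or a `sample`
#'   column (distinct samples are counted).
#' @param n_cohort Cohort denominator for per-gene percentages
#'   (default 50, the sequenced-series size; per-gene sequencing
#'   denominators differ across assays and can be substituted here).
#' @return A `mutation_summary` list; see fields in the source.
#' @export
summarize_mutations <- function(records, n_cohort = 50L) {
  stopifnot(is.data.frame(records), nrow(records) > 0L)
  if (n_cohort <= 0) stop("`n_cohort` must be positive")
  need <- c("gene", "effect", "substitution")
  if (!all(need %in% names(records))) {
    stop("records must have columns ", paste(need, collapse = ", "))
  }
  n <- nrow(records)
  n_missense <- sum(records$effect == "missense")
  n_transitions <- sum(records$substitution == "transition")
  del <- classify_deleterious(records$polyphen2, records$gerp)
  n_deleterious <- sum(del, na.rm = TRUE)
  pct <- function(k) as.integer(round_half_up(100 * k / n))

  genes <- unique(records$gene)
  gene_cases <- vapply(genes, function(g) {
    r <- records[records$gene == g, , drop = FALSE]
    if ("sample" %in% names(records)) {
      length(unique(r$sample))
    } else if ("cases" %in% names(records)) {
      as.integer(max(r$cases))
    } else {
      nrow(r)
    }
  }, integer(1))
  per_gene <- data.frame(
    gene = genes,
    n_variants = as.integer(table(records$gene)[genes]),
    cases = gene_cases,
    cohort_pct = as.integer(round_half_up(100 * gene_cases / n_cohort)),
    stringsAsFactors = FALSE
  )
  per_gene <- per_gene[order(-per_gene$cases, per_gene$gene), ]
  rownames(per_gene) <- NULL

  structure(list(
    n_variants = n,
    n_genes = length(genes),
    n_missense = n_missense, pct_missense = pct(n_missense),
    n_transitions = n_transitions, pct_transitions = pct(n_transitions),
    n_deleterious = n_deleterious, pct_deleterious = pct(n_deleterious),
    n_cohort = as.integer(n_cohort),
    per_gene = per_gene
  ), class = "mutation_summary")
}

#' @export
print.mutation_summary <- function(x, ...) {
  cat("mutation_summary:", x$n_variants, "variants in", x$n_genes,
      "genes\n")
  cat(sprintf("  missense    %d/%d (%d%%)\n", x$n_missense, x$n_variants,
              x$pct_missense))
  cat(sprintf("  transitions %d/%d (%d%%)\n", x$n_transitions,
              x$n_variants, x$pct_transitions))
  cat(sprintf("  deleterious %d/%d (%d%%)\n", x$n_deleterious,
              x$n_variants, x$pct_deleterious))
  cat("  top genes:\n")
  print(utils::head(x$per_gene, 5L))
  invisible(x)
}

#' RNA-level expression support of validated mutations
#'
#' Evaluable records are those with a determined RNA status (`yes` or
#' `no_coverage`; `nd` is excluded).  The supported fraction is
#' yes / (yes + no_coverage).
#'
#' @param rna_status Character vector over `yes`, `no_coverage`, `nd`.
#' @return List with `n_expressed`, `n_evaluable`, `fraction`, and
#'   `pct` (whole percent, half away from zero); all-`nd` input gives
#'   `NA` fraction.
#' @export
expression_support <- function(rna_status) {
  stopifnot(is.character(rna_status))
  rna_status <- tolower(rna_status)
  if (!all(rna_status %in% c("yes", "no_coverage", "nd"))) {
    stop("rna_status values must be yes / no_coverage / nd")
  }
  n_yes <- sum(rna_status == "yes")
  n_eval <- sum(rna_status != "nd")
  if (n_eval == 0L) {
    return(list(n_expressed = 0L, n_evaluable = 0L, fraction = NA_real_,
                pct = NA_integer_))
  }
  list(n_expressed = n_yes, n_evaluable = n_eval,
       fraction = n_yes / n_eval,
       pct = as.integer(round_half_up(100 * n_yes / n_eval)))
}
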