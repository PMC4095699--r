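test_that("fisher_exact_2x2 matches exhaustive enumeration", {
  # balanced table: one-sided tail including the observed mass
  expect_equal(fisher_exact_2x2(5, 5, 5, 5),
               oracle_fisher_greater(5, 5, 5, 5))
  # strong tumour enrichment, checked against the choose() oracle
  expect_equal(fisher_exact_2x2(10, 10, 20, 0),
               oracle_fisher_greater(10, 10, 20, 0))
  # no alt reads in the tumour: p = 1
  expect_equal(fisher_exact_2x2(30, 0, 10, 5), 1)
  expect_equal(fisher_exact_2x2(1, 0, 0, 0), 1)

  set.seed(14)
  for (rep in 1:200) {
    x <- as.integer(stats::rpois(4, 8))
    if (sum(x) == 0) next
    expect_equal(fisher_exact_2x2(x[1], x[2], x[3], x[4]),
                 oracle_fisher_greater(x[1], x[2], x[3], x[4]))
  }
  expect_error(fisher_exact_2x2(-1, 2, 3, 4), "non-negative")
})

test_that("two-sided option agrees with stats::fisher.test", {
  set.seed(15)
  for (rep in 1:50) {
    x <- as.integer(stats::rpois(4, 6))
    if (sum(x) == 0) next
    got <- fisher_exact_2x2(x[1], x[2], x[3], x[4],
                            alternative = "two.sided")
    ref <- stats::fisher.test(matrix(c(x[2], x[1], x[4], x[3]), 2))$p.value
    expect_equal(got, ref, tolerance = 1e-10)
  }
})

test_that("apply_filters enforces all five criteria with named failures", {
  th <- filter_thresholds()
  good <- apply_filters(30, 20, 50, 0, base_quality = 30,
                        hq_alt_reads = 20, thresholds = th)
  expect_true(good$pass)
  expect_equal(good$failed, "")

  # VAF 0.19 with everything else passing
  v <- apply_filters(81, 19, 100, 0, 30, 19, th)
  expect_false(v$pass)
  expect_equal(v$failed, "vaf")

  # coverage 9
  cov <- apply_filters(5, 4, 50, 0, 30, 4, th)
  expect_false(cov$pass)
  expect_match(cov$failed, "coverage")

  # zero coverage fails cleanly rather than erroring
  z <- apply_filters(0, 0, 50, 0, 30, 0, th)
  expect_false(z$pass)
  expect_match(z$failed, "coverage")
  expect_match(z$failed, "vaf")

  # boundary semantics: VAF exactly 20%, 4 alt reads, coverage 10 pass;
  # p exactly at 0.05 would fail (strict), checked via threshold override
  b <- apply_filters(8, 2, 50, 0, 20, 4, th)
  expect_true(b$vaf && b$coverage && b$base_quality && b$alt_reads)
})

test_that("filter verdicts are monotone in the evidence", {
  th <- filter_thresholds()
  set.seed(44)
  for (rep in 1:40) {
    tr <- sample(0:60, 1); ta <- sample(0:60, 1)
    nr <- sample(0:60, 1); na_ <- sample(0:10, 1)
    bq <- sample(10:40, 1); hq <- sample(0:ta, 1)
    base <- apply_filters(tr, ta, nr, na_, bq, hq, th)
    # improve one evidence dimension at a time
    better <- list(
      apply_filters(tr, ta + 5, nr, na_, bq, hq + 5, th),   # more alt
      apply_filters(tr, ta, nr + 20, na_, bq, hq, th),      # deeper normal
      apply_filters(tr, ta, nr, max(0, na_ - 2), bq, hq, th),
      apply_filters(tr, ta, nr, na_, bq + 5, hq, th),
      apply_filters(tr, ta, nr, na_, bq, min(ta, hq + 3), th)
    )
    if (base$pass) {
      for (b in better) expect_true(b$pass)
    }
  }
})

test_that("prioritize applies the known-variant and score rules", {
  r <- prioritization_rules()
  expect_true(prioritize("missense", polyphen2 = 1.00, gerp = NA,
                         rules = r)$keep)
  drop <- prioritize("missense", polyphen2 = 0.02, gerp = NA, rules = r)
  expect_false(drop$keep)
  expect_equal(drop$reason, "scores_below_threshold")
  known <- prioritize("missense", polyphen2 = 1, known_variant = TRUE,
                      rules = r)
  expect_false(known$keep)
  expect_equal(known$reason, "known_variant")
  # both scores present: both must pass
  expect_false(prioritize("missense", polyphen2 = 0.9, gerp = 2.0,
                          rules = r)$keep)
  expect_true(prioritize("missense", polyphen2 = 0.9, gerp = 3.5,
                         rules = r)$keep)
  # truncating classes kept regardless of scores
  for (eff in c("nonsense", "frameshift", "splice")) {
    expect_true(prioritize(eff, polyphen2 = 0.0, rules = r)$keep)
  }
})

test_that("classify_effect follows the standard genetic code", {
  expect_equal(classify_effect("GAA", "CAA"), "missense")   # E>Q
  expect_equal(classify_effect("CAG", "TAG"), "nonsense")   # Q>*
  expect_equal(classify_effect("GAA", "GAG"), "synonymous") # E>E
  expect_equal(classify_effect("ATG", "ACG"), "missense")   # M>T
  expect_error(classify_effect("GXA", "GAA"), "invalid codon")
  expect_error(classify_effect("GA", "GAA"), "invalid codon")
})

test_that("classify_substitution partitions substitutions and indels", {
  expect_equal(classify_substitution("ATG>ACG"), "transition")   # T>C
  expect_equal(classify_substitution("GAA>CAA"), "transversion") # G>C
  expect_equal(classify_substitution("A>G"), "transition")
  expect_equal(classify_substitution("c.742_743insA"), "indel")
  expect_equal(classify_substitution("c.100delT"), "indel")
  expect_error(classify_substitution("ATG>GCA"), "more than one")
  expect_error(classify_substitution("ATG>ATG"), "no base change")

  # complementing both bases preserves the class; the three classes
  # partition all single-base changes
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  bases <- names(comp)
  for (from in bases) for (to in setdiff(bases, from)) {
    cls <- classify_substitution(paste0(from, ">", to))
    expect_true(cls %in% c("transition", "transversion"))
    cls_c <- classify_substitution(paste0(comp[from], ">", comp[to]))
    expect_equal(cls, cls_c)
  }
})

test_that("deleteriousness uses OR across PolyPhen-2 and GERP", {
  expect_false(classify_deleterious(0.04, NA))
  expect_true(classify_deleterious(NA, 5.91))
  expect_true(classify_deleterious(NA, 4.05))   # > 4 rule
  expect_false(classify_deleterious(NA, 4.00))  # strict
  expect_false(classify_deleterious(0.5, NA))   # strict at 0.5
  expect_true(is.na(classify_deleterious(NA, NA)))

  expect_equal(gerp_bin(c(2.9, 3.0, 4.05, 5.0, 5.91, NA)),
               c("benign", "possibly_damaging", "possibly_damaging",
                 "possibly_damaging", "probably_damaging", NA))
})

test_that("summarize_mutations reproduces the packaged table counts", {
  tab <- read_mutation_table()
  ms <- summarize_mutations(tab, n_cohort = 50)
  expect_equal(ms$n_variants, 36L)
  expect_equal(ms$n_genes, 23L)
  expect_equal(ms$n_missense, 32L)
  expect_equal(ms$pct_missense, 89L)
  expect_equal(ms$n_transitions, 22L)
  expect_equal(ms$pct_transitions, 61L)
  expect_equal(ms$n_deleterious, 26L)
  expect_equal(ms$pct_deleterious, 72L)

  # a single missense record: all fractions 100%
  one <- data.frame(gene = "G", effect = "missense",
                    substitution = "transition", polyphen2 = 1, gerp = NA)
  m1 <- summarize_mutations(one, n_cohort = 10)
  expect_equal(m1$n_variants, 1L)
  expect_equal(m1$pct_missense, 100L)
  expect_error(summarize_mutations(one, n_cohort = 0), "positive")
})

test_that("recomputed effect and substitution agree with the printed table", {
  tab <- read_mutation_table()
  printed_effect <- c("Missense" = "missense", "Nonsense" = "nonsense",
                      "Frame shift" = "frameshift",
                      "Splice intron" = "splice")[tab$effect_printed]
  expect_equal(tab$effect, unname(printed_effect))
  printed_type <- c("Transition" = "transition",
                    "Transversion" = "transversion",
                    "Ins/del" = "indel")[tab$type_printed]
  expect_equal(tab$substitution, unname(printed_type))
})

test_that("expression_support counts evaluable records", {
  tab <- read_mutation_table()
  es <- expression_support(tab$rna_expression)
  expect_equal(es$n_expressed, 15L)
  expect_equal(es$n_evaluable, 22L)
  expect_equal(es$pct, 68L)

  expect_true(is.na(expression_support(rep("nd", 5))$fraction))
  expect_equal(expression_support(rep("yes", 4))$pct, 100L)
  expect_error(expression_support("maybe"), "yes / no_coverage / nd")
})

test_that("reported percentages round half away from zero", {
  # 22/36 -> 61.11 -> 61; 5/8 -> 62.5 -> 63 (not banker's 62)
  recs <- data.frame(gene = letters[1:8],
                     effect = c(rep("missense", 5), rep("synonymous", 3)),
                     substitution = "transition",
                     polyphen2 = NA, gerp = NA)
  ms <- summarize_mutations(recs, n_cohort = 8)
  expect_equal(ms$pct_missense, 63L)
})
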