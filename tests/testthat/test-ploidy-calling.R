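test_that("ploidy classification follows the length-weighted mean rule", {
  map <- tiny_map()
  expect_equal(estimate_ploidy_class(flat_profile(total = 2L)),
               "near_diploid")
  expect_equal(estimate_ploidy_class(flat_profile(total = 4L, minor = 2L)),
               "near_tetraploid")

  # half the genome (by bp length) at 2, half at 4: mean exactly 3.0,
  # tie goes to near_tetraploid
  segs <- data.frame(chrom = "chrA",
                     start = c(1L, 101L), end = c(100L, 200L),
                     total_cn = c(2L, 4L), minor_cn = c(1L, 2L))
  p <- segment_profile("S", segs)
  expect_equal(estimate_ploidy_class(p), "near_tetraploid")

  # declared ploidy wins over inference
  pd <- flat_profile(total = 4L, minor = 2L, ploidy = "near_diploid")
  expect_equal(estimate_ploidy_class(pd), "near_diploid")
})

test_that("call_status implements the ploidy-adaptive cutoffs", {
  cut <- ploidy_cutoffs()
  # near-diploid: <=1 loss, >=3 gain, >=6 amplification
  expect_equal(call_status(1, cut$near_diploid), "LOSS")
  expect_equal(call_status(2, cut$near_diploid), "NEUTRAL")
  expect_equal(call_status(c(3, 5), cut$near_diploid), rep("GAIN", 2))
  expect_equal(call_status(6, cut$near_diploid), "AMP")
  # near-tetraploid: 2, 6, 8
  expect_equal(call_status(2, cut$near_tetraploid), "LOSS")
  expect_equal(call_status(c(3, 4, 5), cut$near_tetraploid),
               rep("NEUTRAL", 3))
  expect_equal(call_status(7, cut$near_tetraploid), "GAIN")
  expect_equal(call_status(8, cut$near_tetraploid), "AMP")
})

test_that("call_status partitions copy numbers and is monotone", {
  cut <- ploidy_cutoffs()
  order_of <- c(LOSS = 1, NEUTRAL = 2, GAIN = 3, AMP = 4)
  for (class in names(cut)) {
    states <- call_status(0:20, cut[[class]])
    # exactly one state per copy number, never moving toward LOSS
    expect_length(states, 21L)
    expect_true(all(states %in% names(order_of)))
    expect_true(all(diff(order_of[states]) >= 0))
  }
  expect_error(call_status(2.5, cut$near_diploid))
})

test_that("call_profile projects segments onto probes per ploidy", {
  map <- tiny_map()
  null_p <- flat_profile(map = map)
  sp <- call_profile(null_p, map)
  expect_true(all(sp$state == "NEUTRAL"))
  expect_length(sp$state, map$n_probes)

  # one CN-6 segment: AMP under near-diploid cutoffs, GAIN under
  # near-tetraploid
  segs <- data.frame(chrom = c("chrA", "chrA", "chrB"),
                     start = c(10L, 41L, 100L),
                     end = c(40L, 100L, 500L),
                     total_cn = c(2L, 6L, 2L), minor_cn = c(1L, 1L, 1L))
  p_dip <- segment_profile("S", segs, ploidy = "near_diploid")
  s_dip <- call_profile(p_dip, map)
  expect_equal(unique(s_dip$state[5:10]), "AMP")
  expect_equal(unique(s_dip$state[1:4]), "NEUTRAL")

  p_tet <- segment_profile("S", segs, ploidy = "near_tetraploid")
  s_tet <- call_profile(p_tet, map)
  expect_equal(unique(s_tet$state[5:10]), "GAIN")
  # baseline 2 is LOSS under tetraploid cutoffs
  expect_equal(unique(s_tet$state[1:4]), "LOSS")
})

test_that("uncovered probes become NEUTRAL with a warning", {
  map <- tiny_map()
  segs <- data.frame(chrom = "chrA", start = 10L, end = 50L,
                     total_cn = 1L, minor_cn = 0L)
  p <- segment_profile("S", segs, ploidy = "near_diploid")
  expect_warning(sp <- call_profile(p, map), "outside all segments")
  expect_equal(sum(sp$state == "LOSS"), 5L)
  expect_equal(sum(sp$state == "NEUTRAL"), map$n_probes - 5L)
})

test_that("exclude_x forces chrX probes neutral", {
  map <- default_snp_map(10L)
  segs <- data.frame(chrom = "chrX", start = 100000L, end = 155170560L,
                     total_cn = 6L, minor_cn = 1L)
  other <- do.call(rbind, lapply(setdiff(map$chrom, "chrX"), function(ch) {
    p <- map$positions[[ch]]
    data.frame(chrom = ch, start = p[1], end = p[length(p)],
               total_cn = 2L, minor_cn = 1L)
  }))
  prof <- segment_profile("S", rbind(other, segs), ploidy = "near_diploid")
  s1 <- call_profile(prof, map)
  expect_true(any(s1$state == "AMP"))
  s2 <- call_profile(prof, map, exclude_x = TRUE)
  expect_true(all(s2$state == "NEUTRAL"))
})

test_that("LOH and homozygous deletion flags follow the minor-allele rule", {
  expect_true(detect_loh(1L, 0L))    # hemizygous deletion
  expect_false(detect_loh(2L, 1L))   # heterozygous neutral
  expect_true(detect_loh(2L, 0L))    # copy-neutral LOH
  expect_false(detect_loh(0L, 0L))   # homozygous deletion is separate
  expect_true(homozygous_deletion(0L))
  expect_equal(detect_loh(c(1, 2, 2, 0), c(0, 1, 0, 0)),
               c(TRUE, FALSE, TRUE, FALSE))
})

test_that("breakpoints count copy-number or allelic changes within chroms", {
  map <- tiny_map()
  expect_equal(count_breakpoints(flat_profile(map = map)), 0L)

  segs <- data.frame(chrom = "chrA", start = c(10L, 51L),
                     end = c(50L, 100L),
                     total_cn = c(2L, 3L), minor_cn = c(1L, 1L))
  expect_equal(count_breakpoints(segment_profile("S", segs)), 1L)

  # total constant but allelic composition changes: still a breakpoint
  segs2 <- data.frame(chrom = "chrA", start = c(10L, 51L),
                      end = c(50L, 100L),
                      total_cn = c(2L, 2L), minor_cn = c(1L, 0L))
  expect_equal(count_breakpoints(segment_profile("S", segs2)), 1L)

  # chromosome boundaries never counted
  segs3 <- data.frame(chrom = c("chrA", "chrB"), start = c(10L, 100L),
                      end = c(100L, 500L),
                      total_cn = c(2L, 5L), minor_cn = c(1L, 2L))
  expect_equal(count_breakpoints(segment_profile("S", segs3)), 0L)
})

test_that("breakpoint counts match the run-length oracle on random profiles", {
  set.seed(123)
  map <- tiny_map()
  for (rep in 1:50) {
    p <- random_profile(map)
    expect_equal(count_breakpoints(p), oracle_breakpoints(p))
  }
})

test_that("firestorm cohorts carry more breakpoints than sawtooth", {
  map <- default_snp_map(100L)
  co <- two_archetype_cohort(10L, map, seed = 77)
  bp <- vapply(co$profiles, count_breakpoints, integer(1))
  arch <- co$truth$samples$archetype
  expect_gt(stats::median(bp[arch == "firestorm_amplifier"]),
            stats::median(bp[arch == "sawtooth_8_16"]))
})

test_that("profile validation rejects malformed input", {
  expect_error(segment_profile("S", data.frame(
    chrom = "chrA", start = 1L, end = 10L, total_cn = 2.5, minor_cn = 1L)),
    "integer")
  expect_error(segment_profile("S", data.frame(
    chrom = "chrA", start = 1L, end = 10L, total_cn = 2L, minor_cn = 2L)),
    "minor")
  expect_error(segment_profile("S", data.frame(
    chrom = "chrA", start = c(1L, 5L), end = c(10L, 20L),
    total_cn = 2L, minor_cn = 1L)), "overlap")
})
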