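# Readers and writers for the plain-text interchange formats.  All on-disk
# genomic coordinates are 1-based inclusive; every writer's output is
# re-readable by the matching reader.

#' Read / write SEG-like segment tables
#'
#' Columns: `sample`, `chrom`, `start`, `end`, `total_cn`, `minor_cn`
#' (1-based inclusive bp).  Reading validates sortedness, non-overlap and
#' the allele-count invariant, naming the offending sample and line.
#'
#' @param path File path.
#' @param ploidy Ploidy class to declare on the profiles read
#'   (default `"undeclared"`: inferred downstream).
#' @return `read_seg()`: named list of [segment_profile()] objects.
#' @export
read_seg <- function(path, ploidy = "undeclared") {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           comment.char = "#")
  need <- c("sample", "chrom", "start", "end", "total_cn", "minor_cn")
  if (!all(need %in% names(tab))) {
    stop("SEG file must have columns ", paste(need, collapse = ", "))
  }
  tab$line <- seq_len(nrow(tab)) + 1L  # header is line 1
  profiles <- lapply(split(tab, tab$sample), function(s) {
    tryCatch(
      segment_profile(s$sample[1], s[, need[-1]], ploidy = ploidy),
      error = function(e) {
        stop("invalid segments for sample ", s$sample[1],
             " (lines ", min(s$line), "-", max(s$line), "): ",
             conditionMessage(e), call. = FALSE)
      }
    )
  })
  profiles[unique(tab$sample)]
}

#' @rdname read_seg
#' @param profiles List of [segment_profile()] objects.
#' @export
write_seg <- function(profiles, path) {
  rows <- lapply(profiles, function(p) {
    cbind(sample = p$sample, p$segments, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read / write probe-level status tables
#'
#' Long TSV: `sample`, `probe`, `chrom`, `pos`, `state`, `loh`.
#'
#' @param matrix A [status_matrix()].
#' @param path File path.
#' @export
write_status <- function(matrix, path) {
  stopifnot(inherits(matrix, "status_matrix"))
  pt <- probe_table(matrix$map)
  rows <- lapply(seq_along(matrix$samples), function(i) {
    data.frame(sample = matrix$samples[i], probe = pt$probe,
               chrom = pt$chrom, pos = pt$pos,
               state = matrix$state[i, ], loh = matrix$loh[i, ],
               stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_status
#' @return `read_status()`: a [status_matrix()] (map reconstructed from the
#'   probe coordinates; no arm annotation).
#' @export
read_status <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample", "probe", "chrom", "pos", "state", "loh")
  if (!all(need %in% names(tab))) {
    stop("status file must have columns ", paste(need, collapse = ", "))
  }
  first <- tab[tab$sample == tab$sample[1], ]
  first <- first[order(first$probe), ]
  pos <- split(first$pos, first$chrom)
  pos <- pos[unique(first$chrom)]
  map <- snp_map(pos)
  samples <- unique(tab$sample)
  profs <- lapply(samples, function(id) {
    s <- tab[tab$sample == id, ]
    s <- s[order(s$probe), ]
    if (nrow(s) != map$n_probes) stop("ragged status table for ", id)
    structure(list(sample = id, ploidy = NA_character_,
                   state = s$state, loh = as.logical(s$loh),
                   homdel = rep(FALSE, nrow(s)), map = map),
              class = "status_profile")
  })
  status_matrix(profs)
}

#' Write recurrent regions as BED-style TSV
#'
#' Columns: `chrom`, `start`, `end` (1-based inclusive), `event`,
#' `frequency`, `n_carriers`, `n_probes`.
#'
#' @param regions Output of [recurrent_regions()].
#' @param path File path.
#' @export
write_regions <- function(regions, path) {
  cols <- c("chrom", "start", "end", "event", "frequency", "n_carriers",
            "n_probes")
  utils::write.table(regions[, intersect(cols, names(regions))], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_regions
#' @export
read_regions <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Read / write variant tables
#'
#' Plain TSV with one row per candidate variant (tumour/normal read
#' counts, quality, scores, flags).
#'
#' @param variants Variant `data.frame`.
#' @param path File path.
#' @export
write_variants <- function(variants, path) {
  utils::write.table(variants, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_variants
#' @export
read_variants <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Read / write expression matrices
#'
#' Genes x samples TSV; first column `gene`, remaining columns samples.
#'
#' @param expr Numeric matrix with gene rownames and sample colnames.
#' @param path File path.
#' @export
write_expression <- function(expr, path) {
  tab <- data.frame(gene = rownames(expr), expr, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab$gene
  m
}

#' Read a qPCR Ct table
#'
#' TSV with columns `sample`, `gene`, `ct`.
#'
#' @param path File path.
#' @export
read_ct <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample", "gene", "ct") %in% names(tab))) {
    stop("Ct file must have columns sample, gene, ct")
  }
  tab
}

#' Read / write a cohort truth manifest (JSON)
#'
#' @param truth A `cohort_truth` object from [generate_cohort()].
#' @param path File path.
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "cohort_truth"))
  payload <- list(
    seed = truth$seed,
    samples = truth$samples,
    events = truth$events,
    regions = if (!is.null(truth$regions)) {
      r <- truth$regions
      r$carriers <- vapply(r$carriers, paste, character(1), collapse = ",")
      r
    }
  )
  jsonlite::write_json(payload, path, dataframe = "rows",
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(x$regions) && length(x$regions)) {
    x$regions$carriers <- strsplit(x$regions$carriers, ",", fixed = TRUE)
  }
  structure(list(samples = x$samples, events = x$events,
                 regions = x$regions, seed = x$seed),
            class = "cohort_truth")
}

#' Minimal VCF reader for tumour/normal counts
#'
#' Extracts CHROM, POS, REF, ALT and per-sample AD/DP-style counts from a
#' VCF via the VariantAnnotation parser; intended for interoperability
#' with caller output, not as a general VCF interface.
#'
#' @param path Path to an (uncompressed or bgzipped) VCF.
#' @return `data.frame` with `chrom`, `pos`, `ref`, `alt`, and per-sample
#'   `<sample>_ref` / `<sample>_alt` columns when an AD field is present.
#' @export
read_vcf_subset <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (!requireNamespace("VariantAnnotation", quietly = TRUE)) {
    stop("read_vcf_subset() requires the VariantAnnotation package")
  }
  vcf <- VariantAnnotation::readVcf(path)
  rr <- SummarizedExperiment::rowRanges(vcf)
  alt <- vapply(as.list(rr$ALT), function(a) {
    paste(as.character(a), collapse = ",")
  }, character(1))
  out <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(rr)),
    pos = GenomicRanges::start(rr),
    ref = as.character(rr$REF),
    alt = alt,
    stringsAsFactors = FALSE
  )
  geno <- VariantAnnotation::geno(vcf)
  if ("AD" %in% names(geno)) {
    ad <- geno$AD
    for (s in colnames(ad)) {
      mat <- t(vapply(ad[, s], function(x) {
        if (length(x) >= 2) as.numeric(x[1:2]) else c(NA_real_, NA_real_)
      }, numeric(2)))
      out[[paste0(s, "_ref")]] <- mat[, 1]
      out[[paste0(s, "_alt")]] <- mat[, 2]
    }
  }
  out
}

# md5 of the packaged mutation-table fixture, fixed at transcription time
.mutation_fixture_md5 <- "38d3e756498336fb360595a23b3f8899"

#' The packaged cohort mutation table
#'
#' Path to the transcribed 36-variant mutation table shipped with the
#' package (gene, cases per gene, chromosome, nucleotide change, printed
#' effect/type, PolyPhen-2 and GERP scores, RNA expression status).
#'
#' @return File path.
#' @export
mutation_fixture_path <- function() {
  system.file("extdata", "impc_mutations.tsv", package = "impcna",
              mustWork = TRUE)
}

#' Read a mutation table and derive analysis columns
#'
#' Parses each `mutation` descriptor: `XXX>YYY/p.Z` codon changes yield
#' `ref_codon` / `alt_codon`; bare single-base changes are splice-site
#' substitutions; `ins`/`del` descriptors are indels.  `effect` and
#' `substitution` are recomputed with [classify_effect()] and
#' [classify_substitution()] (printed columns, when present, are kept as
#' `effect_printed` / `type_printed` for cross-checking).
#'
#' @param path TSV path (default: the packaged table).
#' @param verify_checksum Verify the packaged fixture's md5 (ignored for
#'   other paths).
#' @return `data.frame` of mutation records ready for
#'   [summarize_mutations()].
#' @export
read_mutation_table <- function(path = mutation_fixture_path(),
                                verify_checksum = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (verify_checksum && identical(path, mutation_fixture_path())) {
    sum <- unname(tools::md5sum(path))
    if (!identical(sum, .mutation_fixture_md5)) {
      stop("packaged mutation table checksum mismatch")
    }
  }
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           comment.char = "#")
  need <- c("gene", "cases", "chrom", "mutation")
  if (!all(need %in% names(tab))) {
    stop("mutation table must have columns ", paste(need, collapse = ", "))
  }
  n <- nrow(tab)
  tab$ref_codon <- NA_character_
  tab$alt_codon <- NA_character_
  tab$effect <- NA_character_
  tab$substitution <- NA_character_
  for (i in seq_len(n)) {
    mut <- tab$mutation[i]
    change <- sub("/p\\..*$", "", mut)
    if (grepl("ins|del", mut, ignore.case = TRUE)) {
      tab$effect[i] <- "frameshift"
      tab$substitution[i] <- "indel"
    } else if (grepl("^[ACGT]{3}>[ACGT]{3}$", change)) {
      codons <- strsplit(change, ">", fixed = TRUE)[[1]]
      tab$ref_codon[i] <- codons[1]
      tab$alt_codon[i] <- codons[2]
      tab$effect[i] <- classify_effect(codons[1], codons[2])
      tab$substitution[i] <- classify_substitution(change)
    } else if (grepl("^[ACGT]>[ACGT]$", change)) {
      # bare base change with no codon context: splice-site substitution
      tab$effect[i] <- "splice"
      tab$substitution[i] <- classify_substitution(change)
    } else {
      stop("unrecognised mutation descriptor: '", mut, "'")
    }
  }
  if ("rna_expression" %in% names(tab)) {
    tab$rna_expression <- tolower(gsub(" ", "_", tab$rna_expression))
  }
  tab
}

#' Read a run configuration (JSON)
#'
#' Flat JSON object of pipeline settings; unknown keys are rejected so
#' typos fail loudly.
#'
#' @param path JSON file path.
#' @return Named list of settings merged over the documented defaults.
#' @export
read_run_config <- function(path) {
  defaults <- list(
    probes_per_chrom = 1000L, seed = 1L,
    n_sawtooth = 10L, n_firestorm = 10L, event_prob = 0.9,
    min_snps = 25L, min_freq = 0.20, min_diff = 0.20, k = 2L,
    fisher_p_max = 0.05, min_coverage = 10, min_base_quality = 20,
    min_vaf = 0.20, min_alt_reads = 4,
    functional_score_min = 0.5, gerp_min = 3.0,
    exclude_known_variants = TRUE, n_cohort = 50L
  )
  if (is.null(path)) return(defaults)
  if (!file.exists(path)) stop("no such file: ", path)
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  unknown <- setdiff(names(cfg), names(defaults))
  if (length(unknown)) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  }
  utils::modifyList(defaults, cfg)
}
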