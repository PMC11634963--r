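mkcall <- function(chrom = "chr17", pos, ref, alt, vaf = 0.2,
                   alt_reads = 20, caller = "A", sample_id = "s1",
                   context = NA_character_, context_start = NA_real_) {
  data.frame(sample_id = sample_id, caller = caller, chrom = chrom,
             pos = pos, ref = ref, alt = alt, vaf = vaf,
             alt_reads = alt_reads, context = context,
             context_start = context_start, stringsAsFactors = FALSE)
}

mkann <- function(chrom = "chr17", pos, ref, alt, gene,
                  protein_change = "p.X1Y", consequences = "missense",
                  curated = TRUE, onc = "Oncogenic") {
  data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt, gene = gene,
             protein_change = protein_change, consequences = consequences,
             oncokb_curated = curated, oncogenicity = onc,
             stringsAsFactors = FALSE)
}

test_that("MNP decomposition splits equal-length substitutions at differing bases", {
  out <- decompose_and_prefilter(mkcall(pos = 100, ref = "AT", alt = "GC"))
  expect_equal(out$pos, c(100, 101))
  expect_equal(out$ref, c("A", "T"))
  expect_equal(out$alt, c("G", "C"))
  expect_equal(out$vaf, c(0.2, 0.2))  # inherited
  # matching middle base is not emitted as a variant
  out2 <- decompose_and_prefilter(mkcall(pos = 10, ref = "ATG",
                                         alt = "GTC"))
  expect_equal(out2$pos, c(10, 12))
  expect_equal(out2$ref, c("A", "G"))
})

test_that("allele trimming matches a character-comparison oracle", {
  out <- decompose_and_prefilter(mkcall(pos = 50, ref = "CA", alt = "CT"))
  expect_equal(out$pos, 51)
  expect_equal(out$ref, "A")
  expect_equal(out$alt, "T")
  # random trim cases against a per-character oracle
  set.seed(42)
  bases <- c("A", "C", "G", "T")
  for (i in 1:25) {
    core_r <- paste(sample(bases, 3, TRUE), collapse = "")
    core_a <- paste(sample(bases, sample(1:4, 1), TRUE), collapse = "")
    if (core_r == core_a) next
    pre <- paste(sample(bases, 2, TRUE), collapse = "")
    suf <- paste(sample(bases, 2, TRUE), collapse = "")
    ref <- paste0(pre, core_r, suf)
    alt <- paste0(pre, core_a, suf)
    if (nchar(ref) == nchar(alt)) next  # MNP path, not trimming
    out <- decompose_and_prefilter(mkcall(pos = 100, ref = ref, alt = alt))
    # oracle: strip longest common suffix then prefix, keep >= 1 base
    r <- strsplit(ref, "")[[1]]; a <- strsplit(alt, "")[[1]]
    while (length(r) > 1 && length(a) > 1 && r[length(r)] == a[length(a)]) {
      r <- r[-length(r)]; a <- a[-length(a)]
    }
    shift <- 0
    while (length(r) > 1 && length(a) > 1 && r[1] == a[1]) {
      r <- r[-1]; a <- a[-1]; shift <- shift + 1
    }
    expect_equal(out$pos, 100 + shift)
    expect_equal(out$ref, paste(r, collapse = ""))
    expect_equal(out$alt, paste(a, collapse = ""))
  }
})

test_that("alt-read prefilter keeps 6 and drops 5", {
  both <- rbind(mkcall(pos = 1, ref = "A", alt = "G", alt_reads = 5),
                mkcall(pos = 2, ref = "A", alt = "G", alt_reads = 6))
  out <- decompose_and_prefilter(both)
  expect_equal(out$pos, 2)
})

test_that("left alignment makes shifted indel representations identical, matching an exhaustive-shift oracle", {
  # context GCAAAAT starting at 100: one-base deletion from the A run has
  # anchored representations at 101 (CA>C) and 102..104 (AA>A); all must
  # normalize to the leftmost anchored form 101 CA>C
  ctx <- "GCAAAAT"; ctx_start <- 100
  reps <- list(list(pos = 101, ref = "CA", alt = "C"),
               list(pos = 102, ref = "AA", alt = "A"),
               list(pos = 103, ref = "AA", alt = "A"),
               list(pos = 104, ref = "AA", alt = "A"))
  keys <- vapply(reps, function(r) {
    out <- decompose_and_prefilter(mkcall(pos = r$pos, ref = r$ref,
                                          alt = r$alt, context = ctx,
                                          context_start = ctx_start))
    paste(out$chrom, out$pos, out$ref, out$alt)
  }, "")
  expect_equal(unique(keys), "chr17 101 CA C")
  # a shifted pair intersects after normalization (CAA>CA vs AA>A)
  a <- decompose_and_prefilter(mkcall(pos = 101, ref = "CAA", alt = "CA",
                                      context = ctx,
                                      context_start = ctx_start))
  b <- decompose_and_prefilter(mkcall(pos = 103, ref = "AA", alt = "A",
                                      caller = "B", context = ctx,
                                      context_start = ctx_start))
  expect_equal(nrow(intersect_callers(a, b)), 1)
})

test_that("caller intersection keeps only shared keys and carries caller A's numbers", {
  a <- decompose_and_prefilter(rbind(
    mkcall(pos = 10, ref = "A", alt = "G", vaf = 0.11, alt_reads = 11),
    mkcall(pos = 20, ref = "C", alt = "T", vaf = 0.2)))
  b <- decompose_and_prefilter(rbind(
    mkcall(pos = 10, ref = "A", alt = "G", vaf = 0.33, alt_reads = 33,
           caller = "B")))
  cons <- intersect_callers(a, b)
  expect_equal(cons$pos, 10)
  expect_equal(cons$vaf, 0.11)
  expect_equal(cons$alt_reads, 11)
  consB <- intersect_callers(a, b, carry = "B")
  expect_equal(consB$vaf, 0.33)
  # consensus is a subset of each caller's prefiltered set
  ka <- paste(a$chrom, a$pos, a$ref, a$alt)
  kc <- paste(cons$chrom, cons$pos, cons$ref, cons$alt)
  expect_true(all(kc %in% ka))
})

test_that("pathogenicity filter applies curation, splice and ledger rules with one reason each", {
  vars <- rbind(mkcall(pos = 1, ref = "A", alt = "G"),
                mkcall(pos = 2, ref = "A", alt = "G"),
                mkcall(pos = 3, ref = "A", alt = "G"),
                mkcall(pos = 4, ref = "A", alt = "G"),
                mkcall(pos = 5, ref = "A", alt = "G"),
                mkcall(pos = 6, ref = "A", alt = "G"),
                mkcall(pos = 7, ref = "A", alt = "G"))
  vars$caller <- NULL
  ann <- rbind(
    mkann(pos = 1, ref = "A", alt = "G", gene = "TP53"),  # kept
    # AURKA p.Phe31Ile curated Oncogenic: gene-specific ledger
    mkann(pos = 2, ref = "A", alt = "G", gene = "AURKA",
          protein_change = "p.Phe31Ile"),
    # FOXA1 synonymous: dropped despite no OncoKB label
    mkann(pos = 3, ref = "A", alt = "G", gene = "FOXA1",
          protein_change = "p.Ser100Ser", consequences = "synonymous",
          curated = FALSE, onc = "None"),
    # FOXA1 missense with no oncogenic label: kept (FOXA1 override)
    mkann(pos = 4, ref = "A", alt = "G", gene = "FOXA1",
          protein_change = "p.Met253Lys", curated = FALSE, onc = "None"),
    # uncurated LikelyOncogenic with splice-region class: dropped
    mkann(pos = 5, ref = "A", alt = "G", gene = "BRCA2",
          consequences = "missense,splice-region", curated = FALSE,
          onc = "LikelyOncogenic"),
    # curated but not oncogenic: dropped
    mkann(pos = 6, ref = "A", alt = "G", gene = "ATM", onc = "Other"),
    # legacy symbol KMTC2 maps to KMT2C and hits the ledger
    mkann(pos = 7, ref = "A", alt = "G", gene = "KMTC2",
          protein_change = "p.Tyr816Ter"))
  res <- apply_pathogenicity_filter(vars, ann)
  expect_equal(res$kept$pos, c(1, 4))
  drop <- res$dropped[order(res$dropped$pos), ]
  expect_equal(drop$drop_reason,
               c("gene_specific_ledger", "foxa1_synonymous",
                 "uncurated_splice_class", "not_oncogenic",
                 "gene_specific_ledger"))
  # accounting: one reason per dropped variant, kept + dropped = input
  expect_equal(nrow(res$kept) + nrow(res$dropped), nrow(vars))
  expect_false(any(is.na(res$dropped$drop_reason)))
})

test_that("origin classification follows the gene and VAF windows", {
  v <- data.frame(gene = c("BRCA2", "TP53", "BRCA2", "HSD3B1", "BRCA2",
                           "BRCA2", "BRCA2"),
                  vaf = c(0.50, 0.50, 0.20, 0.10, 0.96, 0.45, 0.55))
  out <- classify_origin(v)
  expect_identical(out$origin,
                   c("likely_germline",  # VAF window, non-exempt gene
                     "likely_somatic",   # TP53 exempt
                     "likely_somatic",   # outside both windows
                     "likely_germline",  # HSD3B1 irrespective of VAF
                     "likely_germline",  # > 0.95
                     "likely_germline",  # inclusive 0.45
                     "likely_germline")) # inclusive 0.55
  # 0.95 itself is NOT above the strict bound
  edge <- classify_origin(data.frame(gene = "BRCA2", vaf = 0.95))
  expect_identical(edge$origin, "likely_somatic")
})

test_that("the filter pipeline is idempotent on its own output", {
  calls <- rbind(
    mkcall(pos = 100, ref = "AT", alt = "GC"),
    mkcall(pos = 300, ref = "CAA", alt = "CA"),
    mkcall(pos = 500, ref = "G", alt = "T", alt_reads = 4))
  once <- decompose_and_prefilter(calls)
  twice <- decompose_and_prefilter(once)
  expect_equal(twice, once)
  # intersection against itself is the identity on keys
  self <- intersect_callers(once, once)
  expect_equal(nrow(self), nrow(once))
})

test_that("origin recovery on planted VAFs: somatic f/2 below 0.45 is recovered, germline 0.5 flagged", {
  set.seed(7)
  f <- runif(50, 0.05, 0.85)
  somatic <- data.frame(gene = "BRCA2", vaf = f / 2)
  germ <- data.frame(gene = "BRCA2",
                     vaf = pmin(0.55, pmax(0.45, rnorm(50, 0.5, 0.01))))
  rec_som <- classify_origin(somatic)$origin
  expect_true(all(rec_som[somatic$vaf < 0.45] == "likely_somatic"))
  expect_true(all(classify_origin(germ)$origin == "likely_germline"))
})

test_that("SNV VCF writing and reading round-trips calls", {
  calls <- rbind(
    mkcall(pos = 100, ref = "A", alt = "G", vaf = 0.125, alt_reads = 50),
    mkcall(pos = 300, ref = "CAA", alt = "CA", context = "GCAAAAT",
           context_start = 295))
  path <- withr::local_tempfile(fileext = ".vcf")
  write_snv_vcf(calls, path)
  back <- read_snv_vcf(path, "s1", "A")
  expect_equal(back$pos, calls$pos)
  expect_equal(back$ref, calls$ref)
  expect_equal(back$vaf, calls$vaf, tolerance = 1e-6)
  expect_equal(back$alt_reads, calls$alt_reads)
  expect_equal(back$context[2], "GCAAAAT")
  expect_equal(back$context_start[2], 295)
})
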