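#' @title Two-caller SNV/indel consensus and pathogenicity filtering
#'
#' @description cfDNA mutation calls are taken from two independent callers
#' per sample; a variant is retained only if both callers report the same
#' normalized (chrom, pos, ref, alt) key. Before intersection every call set
#' is decomposed (multi-nucleotide substitutions split into per-base SNVs,
#' shared prefix/suffix bases trimmed from indels, indels left-aligned
#' against a supplied reference context) and prefiltered to alt-read support
#' of at least 6. Retained variants must then pass a pathogenicity filter
#' (curated-and-oncogenic, or uncurated-oncogenic without a splice class)
#' plus a gene-specific removal ledger, and are finally classified as likely
#' germline or likely somatic from their gene and variant allele fraction
#' (VAF): without matched germline material, a VAF near 0.5 or above 0.95 in
#' a non-driver gene is most simply explained by a germline allele.
#'
#' @name variant_filter
NULL

GERMLINE_EXEMPT_GENES <- c("AR", "TP53", "PTEN", "ERF", "PIK3CA", "CDK12")
ONCOGENIC_LABELS <- c("Oncogenic", "LikelyOncogenic")

# gene -> protein changes removed as known germline / non-pathogenic
GENE_REMOVAL_LEDGER <- list(
  PMS2  = "p.Arg20Gln",
  MET   = "p.Glu168Asp",
  KMT2C = "p.Tyr816Ter",
  ATM   = "p.His1380Tyr",
  FANCA = c("p.Ser1088Phe", "p.Ser858Arg"),
  NCOR1 = "p.Arg190Ter",
  AURKA = "p.Phe31Ile")
FOXA1_REMOVALS <- c("p.Ala83Thr", "p.Ser448Asn", "p.Leu148Val")

# historical symbol fixes (KMTC2 is a recurrent typo for KMT2C)
DEFAULT_GENE_SYNONYMS <- c(KMTC2 = "KMT2C")

new_variant_calls <- function(df) {
  need <- c("sample_id", "caller", "chrom", "pos", "ref", "alt", "vaf",
            "alt_reads")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("variant calls missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  bad <- !grepl("^[ACGT]+$", df$ref) | !grepl("^[ACGT]+$", df$alt) |
    df$ref == df$alt | df$vaf < 0 | df$vaf > 1 | df$alt_reads < 0
  if (any(bad)) df <- df[!bad, , drop = FALSE]  # malformed records rejected
  if (is.null(df$context)) df$context <- rep(NA_character_, nrow(df))
  if (is.null(df$context_start)) df$context_start <- rep(NA_real_, nrow(df))
  rownames(df) <- NULL
  df
}

variant_key <- function(df) paste(df$chrom, df$pos, df$ref, df$alt, sep = ":")

# split an equal-length multi-nucleotide substitution into per-base SNVs at
# the positions where ref and alt differ; VAF/alt_reads are inherited.
decompose_mnp_row <- function(row) {
  r <- strsplit(row$ref, "")[[1]]
  a <- strsplit(row$alt, "")[[1]]
  diffs <- which(r != a)
  out <- row[rep(1L, length(diffs)), , drop = FALSE]
  out$pos <- row$pos + diffs - 1L
  out$ref <- r[diffs]
  out$alt <- a[diffs]
  out
}

# trim shared suffix then prefix bases from an allele pair, keeping at least
# one base on each side; pos tracks trimmed prefix bases.
trim_alleles <- function(pos, ref, alt) {
  r <- strsplit(ref, "")[[1]]
  a <- strsplit(alt, "")[[1]]
  while (length(r) > 1L && length(a) > 1L && r[length(r)] == a[length(a)]) {
    r <- r[-length(r)]
    a <- a[-length(a)]
  }
  while (length(r) > 1L && length(a) > 1L && r[1L] == a[1L]) {
    r <- r[-1L]
    a <- a[-1L]
    pos <- pos + 1L
  }
  list(pos = pos, ref = paste(r, collapse = ""), alt = paste(a, collapse = ""))
}

# left-align an indel against its reference context (vt-style): while ref and
# alt end in the same base, drop it and, when an allele would empty, pull in
# the reference base immediately to the left. Shifting stops silently at the
# context boundary.
left_align <- function(pos, ref, alt, context, context_start) {
  if (is.na(context) || !nzchar(context)) return(list(pos = pos, ref = ref,
                                                      alt = alt))
  base_at <- function(p) {
    i <- p - context_start + 1L
    if (i < 1L || i > nchar(context)) NA_character_
    else substr(context, i, i)
  }
  r <- strsplit(ref, "")[[1]]
  a <- strsplit(alt, "")[[1]]
  repeat {
    changed <- FALSE
    if (length(r) && length(a) && r[length(r)] == a[length(a)]) {
      if (length(r) == 1L || length(a) == 1L) {
        b <- base_at(pos - 1L)
        if (is.na(b)) break
        r <- c(b, r[-length(r)])
        a <- c(b, a[-length(a)])
        pos <- pos - 1L
      } else {
        r <- r[-length(r)]
        a <- a[-length(a)]
      }
      changed <- TRUE
    }
    if (length(r) > 1L && length(a) > 1L && r[1L] == a[1L]) {
      r <- r[-1L]
      a <- a[-1L]
      pos <- pos + 1L
      changed <- TRUE
    }
    if (!changed) break
  }
  list(pos = pos, ref = paste(r, collapse = ""), alt = paste(a, collapse = ""))
}

#' Decompose, normalize and prefilter one caller's variant calls
#'
#' Multi-nucleotide substitutions of equal ref/alt length are split into
#' per-base SNVs (inheriting `vaf` and `alt_reads`); shared prefix/suffix
#' bases are trimmed from indels; indels carrying a reference `context` are
#' left-aligned; records with fewer than `min_alt_reads` alternate-allele
#' reads are removed. Exact duplicate keys after normalization are collapsed
#' to one record.
#'
#' @param calls data.frame with columns `sample_id`, `caller`, `chrom`,
#'   `pos` (1-based), `ref`, `alt`, `vaf`, `alt_reads`, and optionally
#'   `context` / `context_start` (a reference sequence window around indels).
#' @param min_alt_reads retention threshold on alternate-allele reads
#'   (default 6).
#' @return normalized data.frame in the same schema.
#' @export
decompose_and_prefilter <- function(calls, min_alt_reads = 6L) {
  calls <- new_variant_calls(calls)
  if (!nrow(calls)) return(calls)
  pieces <- lapply(seq_len(nrow(calls)), function(i) {
    row <- calls[i, , drop = FALSE]
    if (nchar(row$ref) == nchar(row$alt) && nchar(row$ref) > 1L)
      return(decompose_mnp_row(row))
    if (nchar(row$ref) != nchar(row$alt)) {
      t <- trim_alleles(row$pos, row$ref, row$alt)
      la <- left_align(t$pos, t$ref, t$alt, row$context, row$context_start)
      row$pos <- la$pos
      row$ref <- la$ref
      row$alt <- la$alt
    }
    row
  })
  out <- do.call(rbind, pieces)
  out <- out[out$alt_reads >= min_alt_reads, , drop = FALSE]
  out <- out[!duplicated(variant_key(out)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Intersect two callers' normalized call sets
#'
#' A key is consensus iff an identical (chrom, pos, ref, alt) exists in both
#' decomposed/prefiltered sets; genotype and ploidy are ignored. The
#' consensus record carries the numeric fields (`vaf`, `alt_reads`) of the
#' caller named by `carry` (default the first set).
#'
#' @param set_a,set_b normalized data.frames from [decompose_and_prefilter()].
#' @param carry which caller's numeric fields the consensus record keeps:
#'   `"A"` (default) or `"B"`.
#' @return data.frame of consensus variants (caller column dropped).
#' @export
intersect_callers <- function(set_a, set_b, carry = c("A", "B")) {
  carry <- match.arg(carry)
  keys_a <- variant_key(set_a)
  keys_b <- variant_key(set_b)
  src <- if (carry == "A") set_a[keys_a %in% keys_b, , drop = FALSE]
  else set_b[keys_b %in% keys_a, , drop = FALSE]
  src$caller <- NULL
  rownames(src) <- NULL
  src
}

#' Apply the pathogenicity filter and gene-specific removal ledger
#'
#' A variant is kept iff (1) it is curated with an Oncogenic / Likely
#' Oncogenic label, or (2) it is uncurated but labelled Oncogenic / Likely
#' Oncogenic and carries no splice-site or splice-region consequence; and it
#' is not on the gene-specific removal ledger of known germline /
#' non-pathogenic changes. FOXA1 overrides the curation rules entirely: all
#' FOXA1 variants are kept except synonymous ones and three listed protein
#' changes. Every dropped variant carries exactly one machine-readable
#' reason.
#'
#' @param variants consensus variant data.frame.
#' @param annotations data.frame keyed by `chrom`,`pos`,`ref`,`alt` with
#'   columns `gene`, `protein_change`, `consequences` (comma-separated),
#'   `oncokb_curated` (logical), `oncogenicity` (label from the curated
#'   source when curated, otherwise from the secondary annotation source).
#' @param synonyms named character vector mapping legacy gene symbols to
#'   current ones (default fixes KMTC2 -> KMT2C).
#' @return list with `kept` (variants + annotation columns, `pathogenic =
#'   TRUE`) and `dropped` (variants + `drop_reason`).
#' @export
apply_pathogenicity_filter <- function(variants, annotations,
                                       synonyms = DEFAULT_GENE_SYNONYMS) {
  if (!nrow(variants)) {
    variants$drop_reason <- character(0)
    return(list(kept = variants, dropped = variants))
  }
  akey <- paste(annotations$chrom, annotations$pos, annotations$ref,
                annotations$alt, sep = ":")
  idx <- match(variant_key(variants), akey)
  ann <- annotations[idx, c("gene", "protein_change", "consequences",
                            "oncokb_curated", "oncogenicity"), drop = FALSE]
  rownames(ann) <- NULL
  gene <- ann$gene
  fix <- gene %in% names(synonyms)
  gene[fix] <- unname(synonyms[gene[fix]])
  ann$gene <- gene
  conseq <- strsplit(ifelse(is.na(ann$consequences), "", ann$consequences),
                     ",")
  has_splice <- vapply(conseq, function(cc)
    any(trimws(cc) %in% c("splice-site", "splice-region")), logical(1))
  has_syn <- vapply(conseq, function(cc)
    any(trimws(cc) == "synonymous"), logical(1))
  onc <- ann$oncogenicity %in% ONCOGENIC_LABELS
  ledger_hit <- vapply(seq_len(nrow(ann)), function(i) {
    pc <- GENE_REMOVAL_LEDGER[[gene[i]]]
    !is.null(pc) && !is.na(ann$protein_change[i]) &&
      ann$protein_change[i] %in% pc
  }, logical(1))

  reason <- rep(NA_character_, nrow(variants))
  reason[is.na(idx)] <- "no_annotation"
  foxa1 <- !is.na(idx) & gene == "FOXA1"
  std <- !is.na(idx) & !foxa1
  reason[std & !onc] <- "not_oncogenic"
  reason[std & onc & !ann$oncokb_curated & has_splice] <-
    "uncurated_splice_class"
  reason[std & is.na(reason) & ledger_hit] <- "gene_specific_ledger"
  reason[foxa1 & has_syn] <- "foxa1_synonymous"
  reason[foxa1 & is.na(reason) & ann$protein_change %in% FOXA1_REMOVALS] <-
    "gene_specific_ledger"

  keep <- is.na(reason)
  kept <- cbind(variants[keep, , drop = FALSE], ann[keep, , drop = FALSE])
  kept$pathogenic <- rep(TRUE, nrow(kept))
  dropped <- variants[!keep, , drop = FALSE]
  dropped$gene <- gene[!keep]
  dropped$drop_reason <- reason[!keep]
  rownames(kept) <- rownames(dropped) <- NULL
  list(kept = kept, dropped = dropped)
}

#' Classify retained variants as likely germline or likely somatic
#'
#' A variant is likely germline iff it affects HSD3B1, or it affects any
#' gene other than AR, TP53, PTEN, ERF, PIK3CA or CDK12 with a VAF between
#' 0.45 and 0.55 (inclusive) or above 0.95 (strict). Otherwise it is likely
#' somatic. The six exempt genes are recurrent somatic drivers in mCRPC
#' whose VAF may drift into the germline windows under copy-number change.
#'
#' @param variants data.frame with `gene` and `vaf` columns.
#' @return the same data.frame with an `origin` column
#'   (`likely_germline` / `likely_somatic`).
#' @export
classify_origin <- function(variants) {
  in_window <- (variants$vaf >= 0.45 & variants$vaf <= 0.55) |
    variants$vaf > 0.95
  germ <- variants$gene == "HSD3B1" |
    (!(variants$gene %in% GERMLINE_EXEMPT_GENES) & in_window)
  variants$origin <- ifelse(germ, "likely_germline", "likely_somatic")
  variants
}

#' Full variant-filter pipeline for one sample
#'
#' Decompose/prefilter both callers' sets, intersect, apply the
#' pathogenicity filter and classify origin. The audit trail records one
#' drop reason per excluded consensus variant (per-caller records dropped by
#' the alt-read prefilter or for lacking a partner are summarized by count).
#'
#' @param calls_a,calls_b raw per-caller call data.frames (see
#'   [decompose_and_prefilter()]).
#' @param annotations annotation table (see [apply_pathogenicity_filter()]).
#' @param min_alt_reads alt-read prefilter threshold (default 6).
#' @return list with `variants` (filtered, with `origin`), `dropped`
#'   (consensus-level audit), and `counts` (records at each stage).
#' @export
filter_variants <- function(calls_a, calls_b, annotations,
                            min_alt_reads = 6L) {
  a <- decompose_and_prefilter(calls_a, min_alt_reads)
  b <- decompose_and_prefilter(calls_b, min_alt_reads)
  consensus <- intersect_callers(a, b)
  pf <- apply_pathogenicity_filter(consensus, annotations)
  kept <- classify_origin(pf$kept)
  list(variants = kept, dropped = pf$dropped,
       counts = c(caller_a = nrow(a), caller_b = nrow(b),
                  consensus = nrow(consensus), kept = nrow(kept)))
}

#' Write filtered variants (with origin and audit log) to TSV
#' @param result list from [filter_variants()].
#' @param path output TSV for kept variants; the audit log goes to
#'   `<path>.dropped.tsv`.
#' @return `path`, invisibly.
#' @export
write_variant_table <- function(result, path) {
  utils::write.table(result$variants, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(result$dropped, paste0(path, ".dropped.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
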