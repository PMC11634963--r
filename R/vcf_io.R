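#' @title VCF 4.2 input/output
#'
#' @description Readers for per-caller SNV/indel and SV VCFs (via vcfR) and
#' writers used by the synthetic cohort generator. SV records are accepted
#' both in symbolic form (`<DEL>`/`<DUP>`/`<INV>` with INFO END) and in
#' breakend bracket notation; per-caller read-support field names are
#' declared in a small schema so the four SV callers' conventions
#' (FORMAT SR/PR, RV/DV, SR/DR, INFO SR/PE) map onto one internal table.
#'
#' @name vcf_io
NULL

#' Parse a breakend ALT bracket string
#'
#' VCF 4.2 adjacency notation: `t[mate[` keeps the local left flank and the
#' mate's right flank; `t]mate]` keeps left/left; `]mate]t` right/left;
#' `[mate[t` right/right. (A `[` bracket means the mate retains its right
#' flank, `]` its left; bases before the bracket mean the local breakend
#' retains its left flank.)
#'
#' @param alt ALT string, e.g. `"N[chr1:500["`.
#' @return list with `mate_chrom`, `mate_pos`, `local_side`, `mate_side`.
#' @export
parse_bnd_alt <- function(alt) {
  m <- regmatches(alt, regexec("^([ACGTN]*)(\\[|\\])([^:]+):([0-9]+)(\\[|\\])([ACGTN]*)$",
                               alt))[[1]]
  if (length(m) != 7L || m[3] != m[6])
    stop("malformed breakend ALT: ", alt, call. = FALSE)
  local_side <- if (nzchar(m[2])) "retains_left" else "retains_right"
  mate_side <- if (m[3] == "[") "retains_right" else "retains_left"
  list(mate_chrom = m[4], mate_pos = as.numeric(m[5]),
       local_side = local_side, mate_side = mate_side)
}

#' Format a breakend ALT bracket string
#'
#' Inverse of [parse_bnd_alt()].
#'
#' @param ref local REF base.
#' @param local_side,mate_side breakend orientations.
#' @param mate_chrom,mate_pos mate coordinates (1-based).
#' @return ALT string.
#' @export
format_bnd_alt <- function(ref, local_side, mate_side, mate_chrom,
                           mate_pos) {
  br <- if (mate_side == "retains_right") "[" else "]"
  mate <- paste0(br, mate_chrom, ":",
                 format(mate_pos, scientific = FALSE, trim = TRUE), br)
  if (local_side == "retains_left") paste0(ref, mate) else paste0(mate, ref)
}

vcf_header <- function(type = c("snv", "sv"), sample_id = "SAMPLE") {
  type <- match.arg(type)
  common <- c("##fileformat=VCFv4.2",
              "##source=ctdnatriage-synthetic")
  if (type == "snv") {
    info <- c(
      '##INFO=<ID=AF,Number=1,Type=Float,Description="Variant allele fraction">',
      '##INFO=<ID=AO,Number=1,Type=Integer,Description="Alternate allele read count">',
      '##INFO=<ID=CTX,Number=1,Type=String,Description="Reference context window">',
      '##INFO=<ID=CTXS,Number=1,Type=Integer,Description="1-based start of context window">')
  } else {
    info <- c(
      '##INFO=<ID=SVTYPE,Number=1,Type=String,Description="SV type">',
      '##INFO=<ID=END,Number=1,Type=Integer,Description="End position">',
      '##INFO=<ID=MATEID,Number=1,Type=String,Description="Mate breakend id">',
      '##INFO=<ID=SR,Number=1,Type=Integer,Description="Split read support">',
      '##INFO=<ID=PE,Number=1,Type=Integer,Description="Discordant pair support">',
      '##INFO=<ID=IMPRECISE,Number=0,Type=Flag,Description="Imprecise breakpoints">')
  }
  c(common, info,
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"))
}

#' Write SNV/indel calls for one sample/caller as VCF 4.2
#'
#' VAF and alt-read count go to INFO fields `AF` and `AO`; indel reference
#' context (when present) to `CTX`/`CTXS`.
#'
#' @param calls variant call data.frame for a single sample and caller.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_snv_vcf <- function(calls, path) {
  lines <- vcf_header("snv")
  if (nrow(calls)) {
    o <- order(calls$chrom, calls$pos)
    calls <- calls[o, , drop = FALSE]
    info <- sprintf("AF=%.6g;AO=%d", calls$vaf, as.integer(calls$alt_reads))
    has_ctx <- !is.na(calls$context) & nzchar(calls$context %||% "")
    info[has_ctx] <- paste0(info[has_ctx], ";CTX=", calls$context[has_ctx],
                            ";CTXS=",
                            as.integer(calls$context_start[has_ctx]))
    lines <- c(lines, sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t%s",
                              calls$chrom, as.integer(calls$pos), calls$ref,
                              calls$alt, info))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read SNV/indel calls from a caller VCF
#'
#' @param path VCF file.
#' @param sample_id,caller identifiers attached to every record.
#' @param schema field names for VAF and alt reads in INFO (defaults
#'   `AF` / `AO`, matching [write_snv_vcf()]).
#' @return variant call data.frame.
#' @export
read_snv_vcf <- function(path, sample_id, caller,
                         schema = list(vaf = "AF", alt_reads = "AO")) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fixm <- vcfR::getFIX(v)
  if (is.null(dim(fixm))) fixm <- t(fixm)  # single-record VCF drops to vector
  fix <- as.data.frame(fixm, stringsAsFactors = FALSE)
  if (!nrow(fix)) {
    return(new_variant_calls(data.frame(
      sample_id = character(), caller = character(), chrom = character(),
      pos = numeric(), ref = character(), alt = character(), vaf = numeric(),
      alt_reads = numeric(), stringsAsFactors = FALSE)))
  }
  info1 <- function(key) vcfR::extract.info(v, element = key)
  ctx <- info1("CTX")
  ctxs <- suppressWarnings(as.numeric(info1("CTXS")))
  df <- data.frame(
    sample_id = sample_id, caller = caller, chrom = fix$CHROM,
    pos = as.numeric(fix$POS), ref = fix$REF, alt = fix$ALT,
    vaf = suppressWarnings(as.numeric(info1(schema$vaf))),
    alt_reads = suppressWarnings(as.numeric(info1(schema$alt_reads))),
    context = if (is.null(ctx)) NA_character_ else ctx,
    context_start = if (is.null(ctxs)) NA_real_ else ctxs,
    stringsAsFactors = FALSE)
  new_variant_calls(df)
}

#' Write SVs for one sample/caller as VCF 4.2
#'
#' DEL/DUP/INV are written as symbolic records with INFO END; TRA and BND
#' events as mated breakend records in bracket notation. Read support goes
#' to INFO `SR` (split) and `PE` (discordant).
#'
#' @param svs SV data.frame for one sample and caller.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sv_vcf <- function(svs, path) {
  lines <- vcf_header("sv")
  if (nrow(svs)) {
    recs <- character()
    for (i in seq_len(nrow(svs))) {
      s <- svs[i, ]
      supp <- sprintf("SR=%d;PE=%d", as.integer(s$split_reads),
                      as.integer(s$discordant_reads))
      if (s$svtype %in% c("DEL", "DUP", "INV") && s$chrom1 == s$chrom2) {
        recs <- c(recs, sprintf(
          "%s\t%d\tsv%d\tN\t<%s>\t.\tPASS\tSVTYPE=%s;END=%d;%s",
          s$chrom1, as.integer(s$pos1), i, s$svtype, s$svtype,
          as.integer(s$pos2), supp))
      } else {
        alt1 <- format_bnd_alt("N", s$side1, s$side2, s$chrom2, s$pos2)
        alt2 <- format_bnd_alt("N", s$side2, s$side1, s$chrom1, s$pos1)
        recs <- c(recs, sprintf(
          "%s\t%d\tsv%d_1\tN\t%s\t.\tPASS\tSVTYPE=BND;MATEID=sv%d_2;%s",
          s$chrom1, as.integer(s$pos1), i, alt1, i, supp))
        recs <- c(recs, sprintf(
          "%s\t%d\tsv%d_2\tN\t%s\t.\tPASS\tSVTYPE=BND;MATEID=sv%d_1;%s",
          s$chrom2, as.integer(s$pos2), i, alt2, i, supp))
      }
    }
    lines <- c(lines, recs)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read SVs from a caller VCF into the internal breakend-pair table
#'
#' Symbolic DEL/DUP/INV records are decomposed to breakend pairs
#' ([decompose_to_breakends()]); BND records are parsed from bracket
#' notation and mated pairs collapsed to one row. Records flagged
#' IMPRECISE are dropped at parse. Cross-chromosome events are re-labelled
#' TRA; same-chromosome BND pairs get their type from [infer_svtype()].
#'
#' @param path VCF file.
#' @param sample_id,caller identifiers attached to every record.
#' @param schema read-support field names and their location, e.g.
#'   `list(split = "SR", discordant = "PE", source = "info")`. The paper's
#'   four callers map as Manta FORMAT SR/PR, DELLY FORMAT RV/DV, SvABA
#'   FORMAT SR/DR, LUMPY INFO SR/PE; the generator writes INFO SR/PE.
#' @return SV data.frame (one row per breakend pair).
#' @export
read_sv_vcf <- function(path, sample_id, caller,
                        schema = list(split = "SR", discordant = "PE",
                                      source = "info")) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fixm <- vcfR::getFIX(v)
  if (is.null(dim(fixm))) fixm <- t(fixm)  # single-record VCF drops to vector
  fix <- as.data.frame(fixm, stringsAsFactors = FALSE)
  empty <- data.frame(sample_id = character(), caller = character(),
                      chrom1 = character(), pos1 = numeric(),
                      side1 = character(), chrom2 = character(),
                      pos2 = numeric(), side2 = character(),
                      svtype = character(), split_reads = numeric(),
                      discordant_reads = numeric(), stringsAsFactors = FALSE)
  if (!nrow(fix)) return(empty)
  info1 <- function(key) vcfR::extract.info(v, element = key)
  get_support <- function(key) {
    if (identical(schema$source, "format")) {
      gt <- vcfR::extract.gt(v, element = key)
      suppressWarnings(as.numeric(gt[, 1]))
    } else {
      suppressWarnings(as.numeric(info1(key)))
    }
  }
  info_str <- as.character(v@fix[, "INFO"])
  imprecise <- grepl("(^|;)IMPRECISE($|;)", info_str)
  svtype <- info1("SVTYPE")
  endpos <- suppressWarnings(as.numeric(info1("END")))
  sr <- get_support(schema$split)
  dr <- get_support(schema$discordant)
  rows <- list()
  seen_bnd <- character()
  for (i in seq_len(nrow(fix))) {
    if (isTRUE(imprecise[i])) next
    st <- svtype[i]
    if (!is.na(st) && st %in% c("DEL", "DUP", "INV")) {
      bp <- decompose_to_breakends(st, fix$CHROM[i], as.numeric(fix$POS[i]),
                                   endpos[i])
      bp$svtype <- st
    } else {
      # breakend record
      pb <- parse_bnd_alt(fix$ALT[i])
      bp <- data.frame(chrom1 = fix$CHROM[i], pos1 = as.numeric(fix$POS[i]),
                       side1 = pb$local_side, chrom2 = pb$mate_chrom,
                       pos2 = pb$mate_pos, side2 = pb$mate_side,
                       stringsAsFactors = FALSE)
      bp$svtype <- if (bp$chrom1 != bp$chrom2) "TRA"
      else infer_svtype(bp$chrom1, bp$pos1, bp$side1, bp$chrom2, bp$pos2,
                        bp$side2)
      key <- paste(sort(c(paste(bp$chrom1, bp$pos1), paste(bp$chrom2,
                                                           bp$pos2))),
                   collapse = "|")
      if (key %in% seen_bnd) next  # mate line of an already-parsed pair
      seen_bnd <- c(seen_bnd, key)
    }
    bp$sample_id <- sample_id
    bp$caller <- caller
    bp$split_reads <- if (is.na(sr[i])) 0 else sr[i]
    bp$discordant_reads <- if (is.na(dr[i])) 0 else dr[i]
    rows[[length(rows) + 1L]] <- bp
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  new_sv_table(out[, names(empty)])
}
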