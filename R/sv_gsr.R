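#' @title Breakend algebra, multi-caller SV consensus and AR-GSR rules
#'
#' @description A structural variant (SV) is represented as a pair of
#' breakends; each breakend records its position and which flank of that
#' position the joined segment keeps (`retains_left` keeps the sequence up
#' to and including the position, `retains_right` keeps the sequence from
#' the position onward). From the two orientations the SV type follows:
#' on one chromosome, (retains_left, retains_right) with increasing
#' positions is a deletion, (retains_right, retains_left) a tandem
#' duplication, equal sides an inversion; breakends on different
#' chromosomes are translocations (TRA). Four callers' call sets are merged
#' by single-linkage clustering under a 1000 bp positional tolerance; a
#' consensus SV supported by at least two callers, with split-read and
#' discordant-read support of at least 3 each and at least one breakend in
#' the AR gene body, is an AR gene structural rearrangement (AR-GSR).
#' AR-GSRs are further classified by four rules predicting loss of the AR
#' ligand-binding domain (LBD, encoded by exons 4-8), and samples with at
#' least two AR-GSRs plus AR gene-body copy gain carry the ecDNA signature.
#'
#' @name sv_gsr
NULL

SV_SIDES <- c("retains_left", "retains_right")

new_sv_table <- function(df) {
  need <- c("sample_id", "caller", "chrom1", "pos1", "side1",
            "chrom2", "pos2", "side2", "svtype", "split_reads",
            "discordant_reads")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("SV table missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (nrow(df) && (!all(df$side1 %in% SV_SIDES) ||
                   !all(df$side2 %in% SV_SIDES)))
    stop("malformed breakend orientation (side must be retains_left/right)",
         call. = FALSE)
  df
}

# canonical breakend order: (chrom1,pos1) <= (chrom2,pos2)
canonicalize_sv <- function(df) {
  swap <- df$chrom1 > df$chrom2 |
    (df$chrom1 == df$chrom2 & df$pos1 > df$pos2)
  if (any(swap)) {
    tmp <- df[swap, c("chrom1", "pos1", "side1")]
    df[swap, c("chrom1", "pos1", "side1")] <-
      df[swap, c("chrom2", "pos2", "side2")]
    df[swap, c("chrom2", "pos2", "side2")] <- tmp
  }
  df
}

#' Infer the SV type from a breakend pair's orientations
#'
#' Breakends on different chromosomes are translocations (`TRA`). On one
#' chromosome, with positions ordered `p1 < p2`: (`retains_left` at p1,
#' `retains_right` at p2) is `DEL`; (`retains_right` at p1, `retains_left`
#' at p2) is `DUP`; equal sides are `INV`.
#'
#' @param chrom1,pos1,side1,chrom2,pos2,side2 vectors describing breakend
#'   pairs.
#' @return character vector of SV types.
#' @export
infer_svtype <- function(chrom1, pos1, side1, chrom2, pos2, side2) {
  if (!all(c(side1, side2) %in% SV_SIDES))
    stop("malformed breakend orientation", call. = FALSE)
  n <- length(pos1)
  out <- character(n)
  tra <- chrom1 != chrom2
  out[tra] <- "TRA"
  if (any(!tra)) {
    swap <- !tra & pos1 > pos2
    s1 <- ifelse(swap, side2, side1)
    s2 <- ifelse(swap, side1, side2)
    same <- !tra
    out[same & s1 == "retains_left" & s2 == "retains_right"] <- "DEL"
    out[same & s1 == "retains_right" & s2 == "retains_left"] <- "DUP"
    out[same & s1 == s2] <- "INV"
  }
  out
}

#' Decompose a symbolic SV into its breakend pair
#'
#' Emits the two breakends whose orientations round-trip through
#' [infer_svtype()] to the input type. Inversions admit two adjacency
#' layouts (both flanks retained left, or both right); `inv_layout` picks
#' one.
#'
#' @param svtype one of `DEL`, `DUP`, `INV`.
#' @param chrom chromosome.
#' @param start,end 1-based breakend positions (`end` is the symbolic END).
#' @param inv_layout `"left"` or `"right"` adjacency layout for inversions.
#' @return one-row data.frame with breakend-pair columns.
#' @export
decompose_to_breakends <- function(svtype, chrom, start, end,
                                   inv_layout = c("left", "right")) {
  inv_layout <- match.arg(inv_layout)
  if (is.na(end)) stop("symbolic SV missing END coordinate", call. = FALSE)
  sides <- switch(svtype,
    DEL = c("retains_left", "retains_right"),
    DUP = c("retains_right", "retains_left"),
    INV = if (inv_layout == "left") c("retains_left", "retains_left")
          else c("retains_right", "retains_right"),
    stop("cannot decompose symbolic type: ", svtype, call. = FALSE))
  data.frame(chrom1 = chrom, pos1 = start, side1 = sides[1],
             chrom2 = chrom, pos2 = end, side2 = sides[2],
             stringsAsFactors = FALSE)
}

#' SV length
#'
#' Base-pair difference between the breakends; translocations are given
#' length -1.
#'
#' @param svs SV data.frame.
#' @return numeric vector.
#' @export
sv_length <- function(svs) {
  ifelse(svs$chrom1 != svs$chrom2, -1, abs(svs$pos2 - svs$pos1))
}

#' Do two SVs match under a positional tolerance?
#'
#' True iff, under one of the two mate pairings, chromosome pairs agree and
#' BOTH breakend positions differ by at most `tolerance`. Orientation and
#' SV type are not compared. Symmetric in its arguments.
#'
#' @param a,b one-row SV data.frames (or lists) with breakend-pair columns.
#' @param tolerance maximum per-breakend positional difference in bp
#'   (default 1000).
#' @return logical flag.
#' @export
match_sv <- function(a, b, tolerance = 1000) {
  straight <- a$chrom1 == b$chrom1 && a$chrom2 == b$chrom2 &&
    abs(a$pos1 - b$pos1) <= tolerance && abs(a$pos2 - b$pos2) <= tolerance
  crossed <- a$chrom1 == b$chrom2 && a$chrom2 == b$chrom1 &&
    abs(a$pos1 - b$pos2) <= tolerance && abs(a$pos2 - b$pos1) <= tolerance
  straight || crossed
}

# vectorized pairwise match matrix used by the merge
match_sv_matrix <- function(svs, tolerance) {
  n <- nrow(svs)
  c1 <- svs$chrom1; c2 <- svs$chrom2
  p1 <- svs$pos1;   p2 <- svs$pos2
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    straight <- c1 == c1[i] & c2 == c2[i] &
      abs(p1 - p1[i]) <= tolerance & abs(p2 - p2[i]) <= tolerance
    crossed <- c1 == c2[i] & c2 == c1[i] &
      abs(p1 - p2[i]) <= tolerance & abs(p2 - p1[i]) <= tolerance
    adj[i, ] <- straight | crossed
  }
  adj
}

#' Deduplicate one caller's SV calls
#'
#' Exact-key dedup on (chrom1, pos1, chrom2, pos2, svtype) after canonical
#' breakend ordering; read support of duplicates is collapsed to the
#' per-field maxima.
#'
#' @param svs SV data.frame from a single caller.
#' @return deduplicated data.frame.
#' @export
dedup_caller_svs <- function(svs) {
  svs <- canonicalize_sv(new_sv_table(svs))
  if (!nrow(svs)) return(svs)
  key <- paste(svs$chrom1, svs$pos1, svs$chrom2, svs$pos2, svs$svtype,
               sep = ":")
  if (anyDuplicated(key)) {
    sr <- tapply(svs$split_reads, key, max)
    dr <- tapply(svs$discordant_reads, key, max)
    svs <- svs[!duplicated(key), , drop = FALSE]
    k <- paste(svs$chrom1, svs$pos1, svs$chrom2, svs$pos2, svs$svtype,
               sep = ":")
    svs$split_reads <- unname(sr[k])
    svs$discordant_reads <- unname(dr[k])
  }
  rownames(svs) <- NULL
  svs
}

#' Merge four callers' SV sets into consensus SVs
#'
#' Single-linkage clustering (union-find) of all calls under [match_sv()]:
#' each connected component becomes one consensus SV. The representative
#' breakend pair comes from the member with the lexicographically smallest
#' caller ID (ties broken by position); read support fields are per-field
#' maxima over the cluster; `supporting_callers` lists the distinct callers
#' contributing. `n_members` records the chaining depth of the cluster.
#'
#' @param per_caller_sets list of per-caller SV data.frames (each already
#'   deduplicated within caller; [dedup_caller_svs()] is applied
#'   defensively).
#' @param tolerance positional tolerance in bp (default 1000).
#' @return data.frame of consensus SVs, one row per cluster.
#' @export
consensus_merge <- function(per_caller_sets, tolerance = 1000) {
  svs <- do.call(rbind, lapply(per_caller_sets, dedup_caller_svs))
  if (is.null(svs) || !nrow(svs)) {
    return(data.frame(sample_id = character(), chrom1 = character(),
                      pos1 = numeric(), side1 = character(),
                      chrom2 = character(), pos2 = numeric(),
                      side2 = character(), svtype = character(),
                      supporting_callers = character(),
                      n_callers = integer(), best_split_reads = numeric(),
                      best_discordant_reads = numeric(),
                      n_members = integer(), stringsAsFactors = FALSE))
  }
  rownames(svs) <- NULL
  n <- nrow(svs)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  adj <- match_sv_matrix(svs, tolerance)
  for (i in seq_len(n)) {
    js <- which(adj[i, ])
    for (j in js[js > i]) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[rj] <- ri
    }
  }
  comp <- vapply(seq_len(n), find, 0L)
  out <- lapply(split(seq_len(n), comp), function(idx) {
    m <- svs[idx, , drop = FALSE]
    o <- order(m$caller, m$pos1, m$pos2)
    rep <- m[o[1L], , drop = FALSE]
    data.frame(sample_id = rep$sample_id,
               chrom1 = rep$chrom1, pos1 = rep$pos1, side1 = rep$side1,
               chrom2 = rep$chrom2, pos2 = rep$pos2, side2 = rep$side2,
               svtype = rep$svtype,
               supporting_callers = paste(sort(unique(m$caller)),
                                          collapse = ","),
               n_callers = length(unique(m$caller)),
               best_split_reads = max(m$split_reads),
               best_discordant_reads = max(m$discordant_reads),
               n_members = nrow(m), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out <- out[order(out$chrom1, out$pos1, out$chrom2, out$pos2), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Remove SVs with a breakend in a blacklist interval
#'
#' An SV is removed iff either breakend position lies inside any blacklist
#' interval (intervals are 0-based half-open; a breakend exactly at an
#' interval's half-open end is outside and kept).
#'
#' @param svs SV data.frame (consensus or per-caller).
#' @param blacklist `genomic_intervals`.
#' @return retained rows of `svs`.
#' @export
filter_blacklist <- function(svs, blacklist) {
  if (is.null(blacklist) || !nrow(blacklist) || !nrow(svs)) return(svs)
  hit <- point_in_intervals(svs$chrom1, svs$pos1, blacklist) |
    point_in_intervals(svs$chrom2, svs$pos2, blacklist)
  out <- svs[!hit, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Detect AR gene structural rearrangements among consensus SVs
#'
#' Retains exactly those consensus SVs with at least one breakend inside
#' the AR gene body, support from at least two of the four callers, and at
#' least 3 supporting split reads and 3 supporting discordant paired-end
#' reads; then annotates each retained call with its LBD-truncation rule
#' (see [classify_lbd_truncating()]).
#'
#' @param consensus blacklist-filtered consensus SV data.frame.
#' @param ar `ar_model`.
#' @param min_callers,min_split,min_discordant support thresholds
#'   (defaults 2 / 3 / 3).
#' @return data.frame of AR-GSR calls with `in_ar_region`, `matched_rule`
#'   and `lbd_truncating` columns.
#' @export
detect_ar_gsrs <- function(consensus, ar, min_callers = 2L, min_split = 3L,
                           min_discordant = 3L) {
  if (!nrow(consensus)) {
    consensus$in_ar_region <- logical(0)
    consensus$matched_rule <- integer(0)
    consensus$lbd_truncating <- logical(0)
    return(consensus)
  }
  gb <- ar$gene_body
  in_ar <- point_in_intervals(consensus$chrom1, consensus$pos1, gb) |
    point_in_intervals(consensus$chrom2, consensus$pos2, gb)
  keep <- in_ar & consensus$n_callers >= min_callers &
    consensus$best_split_reads >= min_split &
    consensus$best_discordant_reads >= min_discordant
  out <- consensus[keep, , drop = FALSE]
  out$in_ar_region <- rep(TRUE, nrow(out))
  out$matched_rule <- vapply(seq_len(nrow(out)), function(i)
    classify_lbd_truncating(out[i, ], ar), 0L)
  out$lbd_truncating <- out$matched_rule != 0L
  rownames(out) <- NULL
  out
}

#' Classify an AR-GSR against the four LBD-truncation rules
#'
#' With the AR exons 1..8 on the plus strand (lower chrX coordinates are
#' centromere-proximal and contain exons 1-3), let the LBD-coding targets
#' be exons 4, 5, 6, 7 and the start of exon 8 through the stop codon, let
#' A13 span the beginning of exon 1 through the end of exon 3, and let the
#' mid-gene window be positions strictly after the end of exon 3 up to and
#' including the stop codon. The rules, evaluated 1 to 4 with the first
#' match reported:
#' \enumerate{
#' \item a DEL, INV or BND whose span fully or partially overlaps an
#'   LBD-coding target but does not overlap A13;
#' \item a DUP, INV or BND whose span fully contains A13 and has a
#'   breakpoint in the mid-gene window;
#' \item a DUP with both breakpoints inside the AR gene body whose span
#'   fully contains at least one whole exon among exons 3-7;
#' \item a TRA whose AR-side breakend lies in the mid-gene window and
#'   retains the centromeric (left) side of AR encompassing exons 1-3,
#'   i.e. has orientation `retains_left`.
#' }
#' "Breakpoint" means either breakend position; the span of a
#' same-chromosome event is the 0-based half-open interval between its
#' breakend positions; cross-chromosome events use only the AR-side
#' breakend.
#'
#' @param sv one-row SV data.frame (breakend pair + `svtype`).
#' @param ar `ar_model`.
#' @return integer rule number 1-4, or 0 for no match.
#' @export
classify_lbd_truncating <- function(sv, ar) {
  ex <- ar$exons
  gb <- ar$gene_body
  stop_pos <- ar$stop_codon_pos
  a13_start <- ex$start[1L]
  a13_end <- ex$end[3L]
  # LBD-coding targets: exons 4..7 plus [exon8.start, stop codon)
  lbd <- rbind(ex[4:7, c("chrom", "start", "end")],
               data.frame(chrom = ex$chrom[8L], start = ex$start[8L],
                          end = stop_pos))
  in_mid <- function(p0) p0 > a13_end & p0 <= stop_pos
  on_ar <- c(sv$chrom1 == gb$chrom, sv$chrom2 == gb$chrom)
  p0 <- c(sv$pos1, sv$pos2) - 1  # 0-based breakpoint positions
  sides <- c(sv$side1, sv$side2)
  cross <- sv$chrom1 != sv$chrom2

  if (sv$svtype == "TRA" || cross) {
    if (sv$svtype != "TRA") return(0L)
    ar_idx <- which(on_ar & p0 >= gb$start & p0 < gb$end)
    for (i in ar_idx) {
      if (in_mid(p0[i]) && sides[i] == "retains_left") return(4L)
    }
    return(0L)
  }

  span_s <- min(p0)
  span_e <- max(p0)  # span [span_s, span_e), 0-based half-open
  overlaps_lbd <- any(pmax(span_s, lbd$start) < pmin(span_e, lbd$end))
  overlaps_a13 <- max(span_s, a13_start) < min(span_e, a13_end)
  contains_a13 <- span_s <= a13_start && a13_end <= span_e
  bp_in_mid <- any(in_mid(p0))

  if (sv$svtype %in% c("DEL", "INV", "BND") && overlaps_lbd &&
      !overlaps_a13) return(1L)
  if (sv$svtype %in% c("DUP", "INV", "BND") && contains_a13 && bp_in_mid)
    return(2L)
  if (sv$svtype == "DUP") {
    both_in_gene <- all(p0 >= gb$start & p0 < gb$end)
    e37 <- ex[3:7, ]
    contains_exon <- any(span_s <= e37$start & e37$end <= span_e)
    if (both_in_gene && contains_exon) return(3L)
  }
  0L
}

#' ecDNA signature flag for a sample
#'
#' A sample likely carries AR on extrachromosomal circular DNA when it has
#' at least 2 AR-GSRs and AR gene-body copy gain (log2 copy ratio > 0.3,
#' strict).
#'
#' @param ar_gsr_count number of AR-GSRs detected in the sample.
#' @param ar_body_log2 AR gene-body log2 copy ratio.
#' @param gain_threshold log2 gain threshold (default 0.3).
#' @return logical flag.
#' @export
flag_ecdna <- function(ar_gsr_count, ar_body_log2, gain_threshold = 0.3) {
  ar_gsr_count >= 2L & ar_body_log2 > gain_threshold
}

#' Write AR-GSR calls (with rule audit) to TSV
#' @param gsrs data.frame from [detect_ar_gsrs()].
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_ar_gsr_table <- function(gsrs, path) {
  utils::write.table(gsrs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
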