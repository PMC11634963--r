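#' @title Panel coordinate model
#'
#' @description The panel model houses every genomic coordinate the pipeline
#' consults: targeted genes (exon intervals), the five control regions used
#' for within-sample depth normalization, the AR gene model (gene body, eight
#' exons, stop codon, upstream enhancer) used by the structural-rearrangement
#' rules, and the blacklist of artifactual mapping regions. Coordinates are
#' held internally as 0-based half-open intervals.
#'
#' @name panel_model
NULL

CONTROL_LABELS <- paste0("C", 1:5)

#' Construct a gene target
#'
#' @param symbol gene symbol, unique within a panel.
#' @param chrom chromosome name.
#' @param exons `genomic_intervals` table; must be non-overlapping; they are
#'   sorted by coordinate.
#' @param strand "+" or "-".
#' @return list of class `gene_target`.
#' @export
gene_target <- function(symbol, chrom, exons, strand = "+") {
  stopifnot(is.character(symbol), length(symbol) == 1L)
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'", call. = FALSE)
  exons <- exons[order(exons$start), , drop = FALSE]
  if (nrow(exons) > 1L && any(exons$start[-1L] < exons$end[-nrow(exons)]))
    stop("exons of ", symbol, " overlap", call. = FALSE)
  if (!all(exons$chrom == chrom))
    stop("exons of ", symbol, " not all on ", chrom, call. = FALSE)
  structure(list(symbol = symbol, chrom = chrom, exons = exons,
                 strand = strand),
            class = "gene_target")
}

#' Construct the five-region control set
#'
#' Exactly five regions labelled C1..C5; exactly one (C2) lies on chrX. The
#' chrX membership matters because the within-sample normalization doubles
#' the chrX control when scaling chrX targets.
#'
#' @param regions `genomic_intervals` with labels C1..C5.
#' @return `control_region_set`.
#' @export
control_region_set <- function(regions) {
  missing <- setdiff(CONTROL_LABELS, regions$label)
  if (length(missing))
    stop("ControlRegionSet requires 5 regions C1..C5; missing: ",
         paste(missing, collapse = ", "), call. = FALSE)
  regions <- regions[match(CONTROL_LABELS, regions$label), , drop = FALSE]
  structure(list(regions = regions), class = "control_region_set")
}

#' Construct an AR gene model
#'
#' @param gene_body single-row `genomic_intervals` on chrX.
#' @param exons exactly 8 intervals, ordered by increasing coordinate
#'   (AR is plus-strand).
#' @param stop_codon_pos 0-based position of the translational stop inside
#'   exon 8; the coding tail of exon 8 is `[exon8.start, stop_codon_pos)`.
#' @param enhancer single-row interval strictly upstream of (before) the gene
#'   body, non-overlapping.
#' @return list of class `ar_model`.
#' @export
ar_model <- function(gene_body, exons, stop_codon_pos, enhancer) {
  if (nrow(exons) != 8L) stop("AR model requires exactly 8 exons", call. = FALSE)
  if (is.unsorted(exons$start, strictly = TRUE))
    stop("AR exons must be ordered by increasing coordinate", call. = FALSE)
  e8 <- exons[8L, ]
  if (!(e8$start < stop_codon_pos && stop_codon_pos <= e8$end))
    stop("stop_codon_pos must lie inside exon 8", call. = FALSE)
  if (enhancer$chrom != gene_body$chrom)
    stop("enhancer must be on the AR chromosome", call. = FALSE)
  if (max(enhancer$start, gene_body$start) < min(enhancer$end, gene_body$end))
    stop("enhancer must not overlap the AR gene body", call. = FALSE)
  structure(list(gene_body = gene_body, exons = exons,
                 stop_codon_pos = as.numeric(stop_codon_pos),
                 enhancer = enhancer),
            class = "ar_model")
}

#' Assemble a panel model
#'
#' @param genes list of `gene_target`s (must include AR).
#' @param controls a `control_region_set`.
#' @param ar an `ar_model`; its gene body must equal the AR gene target's
#'   span.
#' @param blacklist `genomic_intervals` of artifactual mapping regions
#'   (may be empty).
#' @param assembly free-text assembly tag.
#' @return list of class `panel_model`.
#' @seealso [validate_panel()], [load_panel()], [toy_panel()]
#' @export
panel_model <- function(genes, controls, ar, blacklist = NULL,
                        assembly = "toy") {
  names(genes) <- vapply(genes, `[[`, "", "symbol")
  pm <- structure(list(genes = genes, controls = controls, ar = ar,
                       blacklist = blacklist %||%
                         genomic_intervals(character(), numeric(), numeric())[0, ],
                       assembly = assembly),
                  class = "panel_model")
  v <- validate_panel(pm)
  if (length(v)) stop("invalid panel model:\n  ", paste(v, collapse = "\n  "),
                      call. = FALSE)
  pm
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Validate a panel model
#'
#' Reports, never throws: returns a character vector of violations (empty iff
#' every invariant holds), each naming the offending field and rule.
#'
#' @param panel a `panel_model` (possibly malformed).
#' @return character vector of violations.
#' @export
validate_panel <- function(panel) {
  v <- character()
  syms <- names(panel$genes)
  if (anyDuplicated(syms))
    v <- c(v, "genes: duplicated symbols")
  for (g in panel$genes) {
    ex <- g$exons
    if (nrow(ex) > 1L) {
      ex <- ex[order(ex$start), , drop = FALSE]
      if (any(ex$start[-1L] < ex$end[-nrow(ex)]))
        v <- c(v, paste0("gene ", g$symbol, ": overlapping exons"))
      if (is.unsorted(g$exons$start))
        v <- c(v, paste0("gene ", g$symbol, ": exons not sorted"))
    }
  }
  cr <- panel$controls$regions
  if (is.null(cr) || nrow(cr) != 5L ||
      !setequal(cr$label, CONTROL_LABELS)) {
    v <- c(v, "controls: ControlRegionSet requires 5 regions C1..C5")
  } else {
    on_x <- cr$chrom %in% c("chrX", "X")
    if (sum(on_x) != 1L || cr$label[on_x][1] != "C2")
      v <- c(v, "controls: exactly one control region (C2) must be on chrX")
    o <- order(cr$chrom, cr$start)
    cs <- cr[o, ]
    same <- cs$chrom[-1L] == cs$chrom[-5L]
    if (any(same & cs$start[-1L] < cs$end[-5L]))
      v <- c(v, "controls: regions must be non-overlapping")
  }
  if (is.null(panel$ar)) {
    v <- c(v, "ar: AR model absent")
  } else {
    if (!"AR" %in% syms) {
      v <- c(v, "genes: AR must appear as a gene target")
    } else {
      argene <- panel$genes[["AR"]]
      span <- c(min(argene$exons$start), max(argene$exons$end))
      gb <- panel$ar$gene_body
      if (argene$chrom != gb$chrom ||
          span[1] < gb$start || span[2] > gb$end)
        v <- c(v, "ar: AR gene target exons must lie within ar$gene_body")
    }
  }
  bl <- panel$blacklist
  if (!is.null(bl) && nrow(bl) && any(bl$start >= bl$end))
    v <- c(v, "blacklist: intervals must satisfy start < end")
  v
}

#' Depth-target labels of a panel
#'
#' The targets a depth profile must cover: one per gene symbol, the AR
#' enhancer (`AR_enhancer`), and the five control labels.
#'
#' @param panel `panel_model`.
#' @param controls include the control labels (default TRUE).
#' @return character vector of labels.
#' @export
panel_targets <- function(panel, controls = TRUE) {
  t <- c(names(panel$genes), "AR_enhancer")
  if (controls) t <- c(t, CONTROL_LABELS)
  t
}

# chromosome of a depth target (gene, AR_enhancer or control label)
target_chrom <- function(panel, target) {
  if (target == "AR_enhancer") return(panel$ar$enhancer$chrom)
  if (target %in% CONTROL_LABELS)
    return(panel$controls$regions$chrom[panel$controls$regions$label == target])
  g <- panel$genes[[target]]
  if (is.null(g)) stop("unknown panel target: ", target, call. = FALSE)
  g$chrom
}

#' The five control regions used by the depth normalization
#'
#' Coordinates (1-based, inclusive at input; stored 0-based half-open):
#' C1 chr9:98258995-98264381, C2 chrX:16153017-16159789,
#' C3 chr14:105249980-105255049, C4 chr15:40514992-40520036,
#' C5 chr15:67390102-67395049.
#'
#' @return `control_region_set`.
#' @export
default_controls <- function() {
  control_region_set(genomic_intervals(
    chrom = c("chr9", "chrX", "chr14", "chr15", "chr15"),
    start = c(98258995, 16153017, 105249980, 40514992, 67390102) - 1,
    end = c(98264381, 16159789, 105255049, 40520036, 67395049),
    label = CONTROL_LABELS))
}

#' Toy AR model with round-number coordinates
#'
#' Eight 500 bp-ish exons spanning 1000..8999 on chrX with the stop codon at
#' position 8900 inside exon 8 and an enhancer at 200..600 upstream. All
#' structural-rearrangement rule tests run against this model.
#'
#' @return `ar_model`.
#' @export
toy_ar_model <- function() {
  exons <- genomic_intervals(
    chrom = "chrX",
    start = c(1000, 2000, 3000, 4000, 5000, 6000, 7000, 8000),
    end = c(1500, 2500, 3500, 4500, 5500, 6500, 7500, 8999),
    label = paste0("AR_exon", 1:8))
  ar_model(gene_body = genomic_intervals("chrX", 1000, 8999, "AR"),
           exons = exons, stop_codon_pos = 8900,
           enhancer = genomic_intervals("chrX", 200, 600, "AR_enhancer"))
}

#' Synthetic toy panel
#'
#' A small panel with round-number gene coordinates used throughout the test
#' suite and the synthetic cohort generator: AR (toy model) plus a set of
#' genes recurrently altered in mCRPC. Control regions use the assay's real
#' coordinates; everything else is synthetic.
#'
#' @return `panel_model`.
#' @export
toy_panel <- function() {
  ar <- toy_ar_model()
  mk <- function(symbol, chrom, start0, n_exons = 3L, exon_len = 400,
                 gap = 600) {
    s <- start0 + (seq_len(n_exons) - 1L) * (exon_len + gap)
    gene_target(symbol, chrom,
                genomic_intervals(chrom, s, s + exon_len,
                                  paste0(symbol, "_exon", seq_len(n_exons))))
  }
  spec <- list(
    c("TP53", "chr17"), c("PTEN", "chr10"), c("RB1", "chr13"),
    c("MYC", "chr8"), c("MYCN", "chr2"), c("BRCA2", "chr13"),
    c("HSD3B1", "chr1"), c("ATM", "chr11"), c("FOXA1", "chr14"),
    c("SPOP", "chr17"), c("PIK3CA", "chr3"), c("CDK12", "chr17"),
    c("ERF", "chr19"), c("PMS2", "chr7"), c("MET", "chr7"),
    c("KMT2C", "chr7"), c("FANCA", "chr16"), c("NCOR1", "chr17"),
    c("AURKA", "chr20"))
  genes <- vector("list", length(spec))
  for (i in seq_along(spec))
    genes[[i]] <- mk(spec[[i]][1], spec[[i]][2], start0 = 1e6 * i)
  argene <- gene_target("AR", "chrX", ar$exons)
  panel_model(genes = c(list(argene), genes),
              controls = default_controls(), ar = ar,
              blacklist = genomic_intervals(
                c("chr5", "chr5"), c(5e6, 9e6), c(5.01e6, 9.02e6),
                c("bl1", "bl2")),
              assembly = "toy")
}

#' Load a panel model from a YAML config (plus BED files)
#'
#' The config names the assembly, the gene targets (inline or a BED file
#' whose name column carries the gene symbol, one row per exon), the five
#' control regions, the AR model and the blacklist BED. Config coordinates
#' are 1-based inclusive unless `coordinate_style: bed` is declared; BED
#' files are always native 0-based half-open. Everything is converted to the
#' internal 0-based half-open representation and validated.
#'
#' @param path YAML file; relative file references resolve against its
#'   directory.
#' @return validated `panel_model`.
#' @export
load_panel <- function(path) {
  if (!file.exists(path)) stop("panel config not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  dir <- dirname(path)
  onebased <- !identical(cfg$coordinate_style, "bed")
  cvt <- function(start, end) {  # -> 0-based half-open
    if (onebased) list(start = start - 1, end = end)
    else list(start = start, end = end)
  }
  iv1 <- function(node, label = "") {
    if (is.null(node$chrom) || is.null(node$start) || is.null(node$end))
      stop("malformed interval in panel config (need chrom/start/end)",
           call. = FALSE)
    cc <- cvt(node$start, node$end)
    genomic_intervals(node$chrom, cc$start, cc$end, label)
  }
  # controls
  if (is.null(cfg$controls))
    stop("panel config: missing control regions", call. = FALSE)
  miss <- setdiff(CONTROL_LABELS, names(cfg$controls))
  if (length(miss))
    stop("panel config: missing control region ", paste(miss, collapse = ", "),
         call. = FALSE)
  ctrl <- do.call(rbind, lapply(CONTROL_LABELS, function(l)
    iv1(cfg$controls[[l]], l)))
  class(ctrl) <- c("genomic_intervals", "data.frame")
  controls <- control_region_set(ctrl)
  # AR model
  if (is.null(cfg$ar)) stop("panel config: AR model absent", call. = FALSE)
  exons <- do.call(rbind, lapply(seq_along(cfg$ar$exons), function(i)
    iv1(c(cfg$ar$exons[[i]], list(chrom = cfg$ar$gene_body$chrom)),
        paste0("AR_exon", i))))
  class(exons) <- c("genomic_intervals", "data.frame")
  stop_pos <- cfg$ar$stop_codon
  if (onebased) stop_pos <- stop_pos  # 1-based stop == 0-based exclusive end
  ar <- ar_model(iv1(cfg$ar$gene_body, "AR"), exons, stop_pos,
                 iv1(cfg$ar$enhancer, "AR_enhancer"))
  # genes
  genes <- list()
  if (!is.null(cfg$genes$bed)) {
    bed <- read_bed(file.path(dir, cfg$genes$bed))
    for (sym in unique(bed$label)) {
      rows <- bed[bed$label == sym, , drop = FALSE]
      ex <- genomic_intervals(rows$chrom, rows$start, rows$end,
                              paste0(sym, "_exon", seq_len(nrow(rows))))
      strand <- if (!is.null(rows$strand)) rows$strand[1] else "+"
      genes[[sym]] <- gene_target(sym, rows$chrom[1], ex, strand)
    }
  }
  for (g in cfg$genes$inline) {
    ex <- do.call(rbind, lapply(seq_along(g$exons), function(i)
      iv1(c(g$exons[[i]], list(chrom = g$chrom)),
          paste0(g$symbol, "_exon", i))))
    class(ex) <- c("genomic_intervals", "data.frame")
    genes[[g$symbol]] <- gene_target(g$symbol, g$chrom, ex,
                                     g$strand %||% "+")
  }
  if (!"AR" %in% names(genes))
    genes[["AR"]] <- gene_target("AR", ar$gene_body$chrom, ar$exons)
  blacklist <- NULL
  if (!is.null(cfg$blacklist$bed))
    blacklist <- read_bed(file.path(dir, cfg$blacklist$bed))
  panel_model(genes = genes, controls = controls, ar = ar,
              blacklist = blacklist, assembly = cfg$assembly %||% "unknown")
}

#' Serialize / deserialize a panel model as JSON
#'
#' `panel_to_json()` and `panel_from_json()` round-trip any valid panel
#' (coordinates stay 0-based half-open in the JSON).
#'
#' @param panel `panel_model`.
#' @param path output / input path.
#' @return `panel_from_json()` returns a validated `panel_model`.
#' @export
panel_to_json <- function(panel, path) {
  obj <- list(
    assembly = panel$assembly,
    genes = lapply(panel$genes, function(g)
      list(symbol = g$symbol, chrom = g$chrom, strand = g$strand,
           exons = g$exons[, c("chrom", "start", "end", "label")])),
    controls = panel$controls$regions[, c("chrom", "start", "end", "label")],
    ar = list(gene_body = panel$ar$gene_body,
              exons = panel$ar$exons,
              stop_codon_pos = panel$ar$stop_codon_pos,
              enhancer = panel$ar$enhancer),
    blacklist = panel$blacklist[, c("chrom", "start", "end", "label")])
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' @rdname panel_to_json
#' @export
panel_from_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  df2iv <- function(df) genomic_intervals(df$chrom, df$start, df$end, df$label)
  genes <- lapply(obj$genes, function(g)
    gene_target(g$symbol, g$chrom, df2iv(g$exons), g$strand))
  ar <- ar_model(df2iv(obj$ar$gene_body), df2iv(obj$ar$exons),
                 obj$ar$stop_codon_pos, df2iv(obj$ar$enhancer))
  bl <- if (length(obj$blacklist)) df2iv(obj$blacklist) else NULL
  panel_model(genes = genes,
              controls = control_region_set(df2iv(obj$controls)),
              ar = ar, blacklist = bl, assembly = obj$assembly)
}

#' @export
print.panel_model <- function(x, ...) {
  cat("<panel_model> assembly:", x$assembly, "\n")
  cat("  genes:", length(x$genes), " controls: 5  blacklist:",
      nrow(x$blacklist), "intervals\n")
  invisible(x)
}
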