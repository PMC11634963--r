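#' @title End-to-end cohort pipeline
#'
#' @description Runs the full decision logic over a cohort: derive the
#' aneuploidy threshold from healthy-donor controls, build the panel of
#' normals from low-fraction samples, compute per-sample copy ratios,
#' filter two-caller SNV consensus sets, merge four-caller SV sets and
#' detect AR-GSRs, aggregate per-sample features, assign Groups 1/2/3, and
#' (when survival follow-up is supplied) attach Kaplan-Meier and log-rank
#' summaries. Loss states are called in a second pass once each sample's
#' ctDNA-positivity is known.
#'
#' @name pipeline
NULL

#' Run the cohort pipeline
#'
#' @param bundle a `cohort_bundle` (from [generate_cohort()] or
#'   [read_fixture_bundle()]), or a list with the same elements:
#'   `panel`, `controls`, `depth_profiles`, `fractions`, `snv_calls`,
#'   `annotations`, `sv_calls`, and optionally `survival`.
#' @param pon_cutoff aneuploidy-fraction cutoff for panel-of-normals
#'   membership (default 0.05).
#' @param sv_tolerance breakend matching tolerance in bp (default 1000).
#' @return list of class `pipeline_result` with `threshold_stats`, `pon`,
#'   `copy_ratios`, `variants`, `ar_gsrs`, `features`, `classifications`,
#'   `summary`, and `report` (NULL without survival data).
#' @export
run_pipeline <- function(bundle, pon_cutoff = 0.05, sv_tolerance = 1000) {
  panel <- bundle$panel
  stats_ <- derive_aneuploidy_threshold(bundle$controls)
  profiles <- bundle$depth_profiles
  ids <- vapply(profiles, `[[`, "", "sample_id")
  pon <- build_panel_of_normals(profiles, bundle$fractions, panel,
                                cutoff = pon_cutoff)
  ratios <- lapply(profiles, compute_copy_ratio, pon = pon, panel = panel)
  names(ratios) <- ids

  sub_sample <- function(df, id) {
    if (is.null(df)) return(NULL)
    df[df$sample_id == id, , drop = FALSE]
  }
  empty_calls <- data.frame(
    sample_id = character(), caller = character(), chrom = character(),
    pos = numeric(), ref = character(), alt = character(), vaf = numeric(),
    alt_reads = numeric(), stringsAsFactors = FALSE)

  variants <- lapply(ids, function(id) {
    a <- sub_sample(bundle$snv_calls[[1]], id) %||% empty_calls
    b <- sub_sample(bundle$snv_calls[[2]], id) %||% empty_calls
    filter_variants(a, b, bundle$annotations)$variants
  })
  names(variants) <- ids

  gsrs <- lapply(ids, function(id) {
    sets <- lapply(bundle$sv_calls, sub_sample, id = id)
    sets <- sets[!vapply(sets, is.null, TRUE)]
    cons <- consensus_merge(sets, tolerance = sv_tolerance)
    cons <- filter_blacklist(cons, panel$blacklist)
    detect_ar_gsrs(cons, panel$ar)
  })
  names(gsrs) <- ids

  features <- lapply(ids, function(id)
    build_sample_features(id, ratios[[id]], variants[[id]], gsrs[[id]],
                          fraction = bundle$fractions[[id]]))
  names(features) <- ids
  classifications <- classify_cohort(features, stats_)

  positive <- classifications$group %in% c("Group1", "Group2")
  names(positive) <- classifications$sample_id
  copy_ratios <- do.call(rbind, lapply(ids, function(id)
    call_copy_state(ratios[[id]], positive[[id]])))
  rownames(copy_ratios) <- NULL

  summary <- summarize_cohort(classifications, features)
  report <- NULL
  if (!is.null(bundle$survival))
    report <- cohort_report(classifications, bundle$survival, features)

  structure(list(threshold_stats = stats_, pon = pon,
                 copy_ratios = copy_ratios, variants = variants,
                 ar_gsrs = gsrs, features = features,
                 classifications = classifications, summary = summary,
                 report = report),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result> threshold =",
      format(x$threshold_stats$threshold, digits = 4), "\n")
  print(x$summary)
  if (!is.null(x$report))
    cat(paste0("  ", x$report$text, "\n"), sep = "")
  invisible(x)
}
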