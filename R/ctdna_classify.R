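#' @title Three-group ctDNA-positivity classification
#'
#' @description The assay-specific aneuploidy threshold is the healthy-donor
#' control mean plus three standard deviations: a sample below it is 99.87%
#' likely to lack ctDNA aneuploidy under a normal error model. Samples whose
#' aneuploidy fraction exceeds the threshold (strictly) form ctDNA
#' aneuploidy-high Group 1. Samples at or below it are ctDNA aneuploidy-low
#' Group 2 iff they show at least one of six high-signal features: a likely
#' somatic pathogenic SNV in any targeted gene, AR gene-body gain, AR
#' enhancer gain, an AR-GSR, MYC gain, or MYCN gain (gain = log2 copy ratio
#' > 0.3). Everything else is ctDNA-negative Group 3.
#'
#' @name ctdna_classify
NULL

GROUP_LEVELS <- c("Group1", "Group2", "Group3")

#' Derive the aneuploidy threshold from healthy-donor controls
#'
#' Threshold = mean + 3 * sample standard deviation (n-1 denominator).
#'
#' @param control_fractions numeric vector of control aneuploidy fractions
#'   in \[0, 1\] (at least 2).
#' @return list of class `aneuploidy_control_stats` with `n`, `mean`, `sd`,
#'   `threshold`.
#' @export
derive_aneuploidy_threshold <- function(control_fractions) {
  if (length(control_fractions) < 2L)
    stop("threshold underivable: need at least 2 control fractions",
         call. = FALSE)
  if (any(control_fractions < 0 | control_fractions > 1))
    stop("control fractions must lie in [0, 1]", call. = FALSE)
  m <- mean(control_fractions)
  s <- stats::sd(control_fractions)
  structure(list(n = length(control_fractions), mean = m, sd = s,
                 threshold = m + 3 * s),
            class = "aneuploidy_control_stats")
}

#' Aggregate per-sample features from the pipeline stage outputs
#'
#' @param sample_id sample identifier.
#' @param copy_ratios copy-ratio data.frame for the sample (from
#'   [compute_copy_ratio()]).
#' @param variants filtered variant data.frame for the sample (with
#'   `origin`; may have zero rows).
#' @param ar_gsrs AR-GSR data.frame for the sample (may have zero rows).
#' @param fraction ctDNA aneuploidy fraction.
#' @param cfdna_mass_ng,plasma_volume_ml optional yield inputs; yield =
#'   mass / volume (ng per mL plasma).
#' @return list of class `sample_features`.
#' @export
build_sample_features <- function(sample_id, copy_ratios, variants,
                                  ar_gsrs, fraction, cfdna_mass_ng = NA,
                                  plasma_volume_ml = NA) {
  if (is.null(copy_ratios) || is.null(variants) || is.null(ar_gsrs))
    stop("missing stage output for sample ", sample_id, call. = FALSE)
  if (is.na(fraction) || fraction < 0 || fraction > 1)
    stop("aneuploidy fraction for ", sample_id, " must be in [0, 1]",
         call. = FALSE)
  lg <- function(target) {
    i <- match(target, copy_ratios$target)
    if (is.na(i)) stop("copy-ratio stage output for ", sample_id,
                       " lacks target ", target, call. = FALSE)
    copy_ratios$log2_ratio[i]
  }
  n_gsr <- nrow(ar_gsrs)
  ar_log2 <- lg("AR")
  structure(list(
    sample_id = sample_id,
    aneuploidy_fraction = fraction,
    cfdna_yield = cfdna_mass_ng / plasma_volume_ml,
    has_somatic_pathogenic_snv = nrow(variants) > 0 &&
      any(variants$origin == "likely_somatic"),
    ar_body_log2 = ar_log2,
    ar_enhancer_log2 = lg("AR_enhancer"),
    myc_log2 = lg("MYC"),
    mycn_log2 = lg("MYCN"),
    ar_gsr_count = n_gsr,
    lbd_truncating_count = if (n_gsr) sum(ar_gsrs$lbd_truncating) else 0L,
    ecdna_flag = flag_ecdna(n_gsr, ar_log2)),
    class = "sample_features")
}

#' Assign a sample to Group 1, 2 or 3
#'
#' Group 1 iff fraction strictly exceeds the threshold (a fraction exactly
#' at the threshold is "at or below" and eligible for Group 2). Otherwise
#' Group 2 iff any of the six trigger features fires; otherwise Group 3.
#'
#' @param features `sample_features`.
#' @param stats `aneuploidy_control_stats`.
#' @param gain_threshold log2 gain threshold for the copy-ratio triggers
#'   (default 0.3, strict).
#' @return list of class `sample_classification` with `sample_id`, `group`
#'   and `triggering_features`.
#' @export
assign_group <- function(features, stats, gain_threshold = 0.3) {
  f <- features
  if (f$aneuploidy_fraction > stats$threshold) {
    return(structure(list(sample_id = f$sample_id, group = "Group1",
                          triggering_features = "aneuploidy_high"),
                     class = "sample_classification"))
  }
  triggers <- c(
    somatic_pathogenic_snv = isTRUE(f$has_somatic_pathogenic_snv),
    ar_gain = f$ar_body_log2 > gain_threshold,
    ar_enhancer_gain = f$ar_enhancer_log2 > gain_threshold,
    ar_gsr = f$ar_gsr_count >= 1L,
    myc_gain = f$myc_log2 > gain_threshold,
    mycn_gain = f$mycn_log2 > gain_threshold)
  group <- if (any(triggers)) "Group2" else "Group3"
  structure(list(sample_id = f$sample_id, group = group,
                 triggering_features = names(triggers)[triggers]),
            class = "sample_classification")
}

# round half away from zero to whole percent (matches printed percentages)
round_percent <- function(x) floor(100 * x + 0.5)

#' Whole-percent frequency of a feature among a denominator
#'
#' `feature_percent(k, n)` = 100 * k / n rounded half away from zero, the
#' convention used by every percentage the cohort report prints.
#'
#' @param k feature count.
#' @param n denominator.
#' @return integer percent.
#' @export
feature_percent <- function(k, n) {
  if (n <= 0) stop("feature_percent needs n > 0", call. = FALSE)
  round_percent(k / n)
}

#' Summarize a classified cohort
#'
#' Counts per group, percent ctDNA-positive ((Group1 + Group2) / total,
#' rounded half away from zero to a whole percent), and feature frequencies
#' among positives.
#'
#' @param classifications list of `sample_classification`s, or a data.frame
#'   with `sample_id` and `group` columns.
#' @param features optional list of `sample_features` (keyed like
#'   `classifications`) used for the feature-frequency table.
#' @return list of class `cohort_summary`.
#' @export
summarize_cohort <- function(classifications, features = NULL) {
  df <- as_classification_df(classifications)
  if (!nrow(df)) stop("cohort summary needs at least 1 sample", call. = FALSE)
  counts <- vapply(GROUP_LEVELS, function(g) sum(df$group == g), 0L)
  n <- nrow(df)
  n_pos <- counts[["Group1"]] + counts[["Group2"]]
  out <- list(n = n, counts = counts, n_positive = n_pos,
              percent_positive = round_percent(n_pos / n))
  if (!is.null(features)) {
    fid <- vapply(features, `[[`, "", "sample_id")
    pos_ids <- df$sample_id[df$group %in% c("Group1", "Group2")]
    fp <- features[fid %in% pos_ids]
    if (length(fp) && n_pos > 0) {
      any_ar <- vapply(fp, function(f)
        f$ar_body_log2 > 0.3 || f$ar_enhancer_log2 > 0.3 ||
          f$ar_gsr_count >= 1L, logical(1))
      any_myc <- vapply(fp, function(f)
        f$myc_log2 > 0.3 || f$mycn_log2 > 0.3, logical(1))
      out$feature_frequency <- list(
        n_positive_with_features = length(fp),
        ar_altered = sum(any_ar),
        percent_ar_altered = round_percent(sum(any_ar) / length(fp)),
        myc_mycn_altered = sum(any_myc),
        percent_myc_mycn_altered = round_percent(sum(any_myc) / length(fp)))
    }
  }
  structure(out, class = "cohort_summary")
}

as_classification_df <- function(classifications) {
  if (is.data.frame(classifications)) return(classifications)
  data.frame(
    sample_id = vapply(classifications, `[[`, "", "sample_id"),
    group = vapply(classifications, `[[`, "", "group"),
    triggers = vapply(classifications, function(x)
      paste(x$triggering_features, collapse = ","), ""),
    stringsAsFactors = FALSE)
}

#' Classify a whole cohort
#'
#' Applies [assign_group()] to each sample; the result is deterministic and
#' independent of sample order.
#'
#' @param features_list list of `sample_features`.
#' @param stats `aneuploidy_control_stats`.
#' @return data.frame with `sample_id`, `group`, `triggers`.
#' @export
classify_cohort <- function(features_list, stats) {
  as_classification_df(lapply(features_list, assign_group, stats = stats))
}

#' Write a cohort classification table to TSV
#' @param classifications data.frame from [classify_cohort()].
#' @param features_list optional features to append the fraction column.
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_classification_table <- function(classifications, path,
                                       features_list = NULL) {
  df <- as_classification_df(classifications)
  if (!is.null(features_list)) {
    fid <- vapply(features_list, `[[`, "", "sample_id")
    df$fraction <- vapply(features_list, `[[`, 0,
                          "aneuploidy_fraction")[match(df$sample_id, fid)]
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("<cohort_summary> n =", x$n, "\n")
  cat("  Group1:", x$counts[["Group1"]], " Group2:", x$counts[["Group2"]],
      " Group3:", x$counts[["Group3"]], "\n")
  cat("  ctDNA-positive:", x$n_positive,
      sprintf("(%d%%)\n", x$percent_positive))
  invisible(x)
}
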