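#' @title Gene-level copy-number ratios against a panel of normals
#'
#' @description Per-gene mean read depths are first normalized within each
#' sample against five control regions; because one control region (C2) lies
#' on chrX and the assay analyzes male-derived cfDNA (one germline X copy),
#' the control scale differs for chrX and autosomal targets:
#' \deqn{chrX: \; median(C1, 2 C2, C3, C4, C5)}
#' \deqn{autosome: \; median(C1/2, C2, C3/2, C4/2, C5/2)}
#' The copy ratio of a target is then its normalized depth divided by the
#' mean normalized depth of that target over a panel of normals (samples
#' whose ctDNA aneuploidy fraction is at most 0.05). Targets are called
#' `gain` when log2(ratio) > 0.3 and `loss` when log2(ratio) < -0.3 in a
#' ctDNA-positive sample; loss calls are suppressed in ctDNA-negative
#' samples because low tumor content makes shallow losses unreliable.
#'
#' @name cnv_calls
NULL

#' Construct a depth profile
#'
#' @param sample_id sample identifier.
#' @param depths named numeric vector: mean read depth per target label
#'   (gene symbols, `AR_enhancer`, and controls `C1`..`C5`).
#' @return list of class `depth_profile`.
#' @export
depth_profile <- function(sample_id, depths) {
  if (is.null(names(depths)) || any(!nzchar(names(depths))))
    stop("depths must be a named vector", call. = FALSE)
  if (any(!is.finite(depths)) || any(depths < 0))
    stop("depths must be finite and >= 0", call. = FALSE)
  miss <- setdiff(CONTROL_LABELS, names(depths))
  if (length(miss))
    stop("depth profile for ", sample_id, " missing control depth: ",
         paste(miss, collapse = ", "), call. = FALSE)
  structure(list(sample_id = sample_id, depths = depths),
            class = "depth_profile")
}

#' Read depth profiles from a TSV table
#'
#' Expected columns: `sample_id`, `target_label`, `mean_depth`.
#'
#' @param path TSV file.
#' @return named list of `depth_profile` objects.
#' @export
read_depth_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "target_label", "mean_depth")
  if (!all(need %in% names(df)))
    stop("depth table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  out <- lapply(split(df, df$sample_id), function(d) {
    depth_profile(d$sample_id[1],
                  stats::setNames(d$mean_depth, d$target_label))
  })
  out[unique(df$sample_id)]
}

#' Write depth profiles to a TSV table
#'
#' @param profiles list of `depth_profile`s.
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_depth_table <- function(profiles, path) {
  df <- do.call(rbind, lapply(profiles, function(p)
    data.frame(sample_id = p$sample_id, target_label = names(p$depths),
               mean_depth = unname(p$depths), stringsAsFactors = FALSE)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Within-sample control scale for a target chromosome
#'
#' For chrX targets the scale is `median(C1, 2*C2, C3, C4, C5)`; for
#' autosomal targets it is `median(C1/2, C2, C3/2, C4/2, C5/2)` (C2 is the
#' chrX control; doubling/halving puts it on the same per-copy footing as
#' the autosomal controls). The median over five values is the middle order
#' statistic; for robustness an even count would use the mean of the middle
#' two, but the control set is fixed at five.
#'
#' @param profile `depth_profile`.
#' @param target_chrom chromosome of the target ("chrX"/"X" selects the chrX
#'   scale).
#' @return positive scalar.
#' @export
control_scale <- function(profile, target_chrom) {
  cd <- profile$depths[CONTROL_LABELS]
  if (any(cd <= 0) || any(!is.finite(cd)))
    stop("control scale undefined for ", profile$sample_id,
         ": all five control depths must be > 0", call. = FALSE)
  if (target_chrom %in% c("chrX", "X")) {
    stats::median(c(cd["C1"], 2 * cd["C2"], cd["C3"], cd["C4"], cd["C5"]))
  } else {
    stats::median(c(cd["C1"] / 2, cd["C2"], cd["C3"] / 2, cd["C4"] / 2,
                    cd["C5"] / 2))
  }
}

#' Within-sample normalized depth of a target
#'
#' `norm_depth = mean target depth / control_scale(profile, chrom(target))`.
#' Scaling every depth of a profile by a common factor leaves the result
#' unchanged.
#'
#' @param profile `depth_profile`.
#' @param target target label (gene symbol or `AR_enhancer`).
#' @param panel `panel_model` (supplies the target's chromosome).
#' @return dimensionless normalized depth.
#' @export
normalize_gene_depth <- function(profile, target, panel) {
  if (!target %in% names(profile$depths))
    stop("sample ", profile$sample_id, " has no depth for target ", target,
         call. = FALSE)
  unname(profile$depths[target] / control_scale(profile,
                                                target_chrom(panel, target)))
}

#' Build the panel of normals
#'
#' Members are exactly the samples whose ctDNA aneuploidy fraction is at or
#' below `cutoff`; the reference value per target is the arithmetic mean of
#' the members' normalized depths. A fixed panel of normals is built once
#' from designated low-fraction samples and reused for every query sample.
#'
#' @param profiles list of `depth_profile`s.
#' @param fractions named numeric vector: aneuploidy fraction per sample_id.
#' @param panel `panel_model`.
#' @param cutoff eligibility cutoff on the fraction (default 0.05).
#' @return list of class `panel_of_normals` with `member_sample_ids` and
#'   `mean_norm_depth` (named per target).
#' @export
build_panel_of_normals <- function(profiles, fractions, panel,
                                   cutoff = 0.05) {
  ids <- vapply(profiles, `[[`, "", "sample_id")
  f <- fractions[ids]
  eligible <- !is.na(f) & f <= cutoff
  if (sum(eligible) < 2L)
    stop("panel of normals unbuildable: fewer than 2 samples with fraction <= ",
         cutoff, call. = FALSE)
  members <- profiles[eligible]
  targets <- panel_targets(panel, controls = FALSE)
  m <- vapply(targets, function(t)
    mean(vapply(members, normalize_gene_depth, 0, target = t, panel = panel)),
    0)
  if (any(m <= 0))
    stop("panel of normals has non-positive mean for: ",
         paste(targets[m <= 0], collapse = ", "), call. = FALSE)
  structure(list(member_sample_ids = ids[eligible], mean_norm_depth = m),
            class = "panel_of_normals")
}

#' Serialize / deserialize a panel of normals as JSON
#' @param pon `panel_of_normals`.
#' @param path file path.
#' @return `pon_from_json()` returns a `panel_of_normals`.
#' @export
pon_to_json <- function(pon, path) {
  jsonlite::write_json(list(member_sample_ids = pon$member_sample_ids,
                            mean_norm_depth = as.list(pon$mean_norm_depth)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname pon_to_json
#' @export
pon_from_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(member_sample_ids = obj$member_sample_ids,
                 mean_norm_depth = unlist(obj$mean_norm_depth)),
            class = "panel_of_normals")
}

#' Copy ratios of one sample against the panel of normals
#'
#' One row per panel target (gene symbols plus the AR enhancer) with the
#' normalized depth, ratio vs the panel-of-normals mean, and log2 ratio.
#' `state` is left unset (`NA`) until [call_copy_state()] is applied, since
#' loss calls depend on the sample's ctDNA-positivity.
#'
#' @param profile `depth_profile`.
#' @param pon `panel_of_normals` covering all targets.
#' @param panel `panel_model`.
#' @return data.frame: `sample_id`, `target`, `norm_depth`, `ratio`,
#'   `log2_ratio`, `state` (NA).
#' @export
compute_copy_ratio <- function(profile, pon, panel) {
  targets <- panel_targets(panel, controls = FALSE)
  miss <- setdiff(targets, names(pon$mean_norm_depth))
  if (length(miss))
    stop("panel of normals does not cover: ", paste(miss, collapse = ", "),
         call. = FALSE)
  nd <- vapply(targets, normalize_gene_depth, 0, profile = profile,
               panel = panel)
  ref <- pon$mean_norm_depth[targets]
  if (any(ref <= 0))
    stop("panel-of-normals mean is 0 for: ",
         paste(targets[ref <= 0], collapse = ", "), call. = FALSE)
  ratio <- unname(nd / ref)
  data.frame(sample_id = profile$sample_id, target = targets,
             norm_depth = unname(nd), ratio = ratio,
             log2_ratio = log2(ratio), state = NA_character_,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Call gain / neutral / loss states on copy-ratio rows
#'
#' `gain` iff log2 ratio > 0.3 (strict); `loss` iff log2 ratio < -0.3 AND the
#' sample is ctDNA-positive; otherwise `neutral`. The boundary value 0.3 is
#' neutral under the strict inequality.
#'
#' @param calls data.frame from [compute_copy_ratio()].
#' @param sample_is_ctdna_positive logical flag for the sample.
#' @param gain_threshold,loss_threshold log2 thresholds (defaults +0.3/-0.3).
#' @return the same data.frame with `state` filled in.
#' @export
call_copy_state <- function(calls, sample_is_ctdna_positive,
                            gain_threshold = 0.3, loss_threshold = -0.3) {
  stopifnot(all(is.finite(calls$log2_ratio)))
  state <- rep("neutral", nrow(calls))
  state[calls$log2_ratio > gain_threshold] <- "gain"
  state[calls$log2_ratio < loss_threshold &
          isTRUE(sample_is_ctdna_positive)] <- "loss"
  calls$state <- state
  calls
}

#' Write copy-ratio calls to TSV
#' @param calls data.frame of copy-ratio calls (possibly several samples).
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_copy_ratio_table <- function(calls, path) {
  utils::write.table(calls, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
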