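#' @title Synthetic cohort generator
#'
#' @description Generates a fully synthetic cfDNA cohort with the
#' statistical structure the analysis assumes: healthy-donor control
#' aneuploidy fractions; per-sample depth profiles in which a planted tumor
#' copy number CN_t at ctDNA fraction f dilutes to an expected observed
#' ratio of `1 + f (CN_t/2 - 1)` on autosomes and `1 + f (CN_t - 1)` on
#' chrX (one germline copy in male-derived cfDNA); two pseudo-callers' SNV
#' sets and four pseudo-callers' SV sets with configurable sensitivity,
#' false-positive rate and positional jitter; cfDNA yields increasing with
#' fraction; and exponential survival with per-group medians under
#' independent right censoring. Planted Group 1/2/3 labels are placed
#' relative to the realized control threshold so that, under noise-free
#' settings, the pipeline recovers them exactly. The planted truth is
#' serialized alongside the outputs and never consumed by the pipeline
#' under test.
#'
#' @name synthetic_cohort
NULL

SNV_CALLERS <- c("A", "B")
SV_CALLERS <- c("manta", "delly", "svaba", "lumpy")

#' Simulation configuration
#'
#' Defaults encode the study conditions: a 776-sample cohort mixed
#' 200/256/320 across Groups 1/2/3, eight healthy-donor control assays with
#' mean fraction 0.0698 and SD 0.0241, planted amplifications (AR and its
#' enhancer to 10 copies, MYC/MYCN to 6), single-copy tumor-suppressor
#' losses, somatic VAFs at f/2 (diploid admixture) with binomial read
#' sampling, germline VAFs near 0.5, per-caller SV jitter at most half the
#' 1000 bp matching tolerance, and per-group median survival of 23/29/47
#' months with 20% censoring.
#'
#' @param n_samples cohort size.
#' @param seed RNG seed (mandatory; keep below 2^31).
#' @param group_mix probabilities over planted groups (sum to 1).
#' @param control_params list(mean, sd, n) for healthy-donor fractions.
#' @param fraction_params per-group beta shapes and optional absolute
#'   `range` override for the planted fraction draw.
#' @param gain_params planted tumor copy numbers and per-group alteration
#'   probabilities (`alt_probs`: rows Group1..Group3).
#' @param loss_params tumor-suppressor loss model.
#' @param variant_params SNV caller emulation (sensitivity, false-positive
#'   rate, read depth).
#' @param sv_params SV caller emulation (sensitivity, jitter, support).
#' @param survival_params per-group median survival (months) and censoring
#'   rate.
#' @param depth_params baseline depth and lognormal noise scales.
#' @param noise_free if TRUE, zero all noise sources (perfect callers, no
#'   jitter, exact depths and VAFs) so planted labels are recoverable
#'   exactly.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_samples = 776,
                       seed,
                       group_mix = c(Group1 = 200, Group2 = 256,
                                     Group3 = 320) / 776,
                       control_params = list(mean = 0.0698, sd = 0.0241,
                                             n = 8),
                       fraction_params = list(
                         Group1 = list(shape1 = 1.1, shape2 = 2.5,
                                       range = NULL),
                         Group2 = list(shape1 = 1.3, shape2 = 3,
                                       range = NULL),
                         Group3 = list(shape1 = 1.3, shape2 = 3,
                                       range = NULL)),
                       gain_params = list(
                         ar_copies = 10, enhancer_copies = 10,
                         myc_copies = 6, mycn_copies = 6,
                         alt_probs = rbind(
                           Group1 = c(snv = 0.55, ar_amp = 0.45,
                                      ar_body_only = 0.03,
                                      ar_enh_only = 0.04, ar_gsr = 0.30,
                                      myc_gain = 0.25, mycn_gain = 0.10,
                                      tsg_loss = 0.45),
                           Group2 = c(snv = 0.38, ar_amp = 0.40,
                                      ar_body_only = 0.03,
                                      ar_enh_only = 0.04, ar_gsr = 0.30,
                                      myc_gain = 0.10, mycn_gain = 0.04,
                                      tsg_loss = 0.05),
                           Group3 = c(snv = 0, ar_amp = 0,
                                      ar_body_only = 0, ar_enh_only = 0,
                                      ar_gsr = 0, myc_gain = 0,
                                      mycn_gain = 0, tsg_loss = 0))),
                       loss_params = list(tsg_copies = 1,
                                          genes = c("TP53", "PTEN", "RB1")),
                       variant_params = list(caller_sens = c(A = 0.95,
                                                             B = 0.95),
                                             caller_fp_rate = 0.05,
                                             total_reads = 400,
                                             germline_rate = 0.10,
                                             benign_rate = 0.15,
                                             germline_sd = 0.02),
                       sv_params = list(caller_sens = 0.85,
                                        jitter_max = 500,
                                        split_mean = 8,
                                        discordant_mean = 8,
                                        extra_gsr_mean = 0.85,
                                        fp_rate = 0.10),
                       survival_params = list(medians = c(Group1 = 23,
                                                          Group2 = 29,
                                                          Group3 = 47),
                                              censor_rate = 0.2),
                       depth_params = list(baseline = 400,
                                           baseline_sdlog = 0.15,
                                           target_sdlog = 0.04),
                       noise_free = FALSE) {
  if (missing(seed)) stop("sim_config: seed is mandatory", call. = FALSE)
  if (abs(sum(group_mix) - 1) > 1e-8)
    stop("group_mix probabilities must sum to 1", call. = FALSE)
  if (any(survival_params$medians <= 0))
    stop("survival medians must be > 0", call. = FALSE)
  if (noise_free) {
    variant_params$caller_sens[] <- 1
    variant_params$caller_fp_rate <- 0
    variant_params$germline_sd <- 0
    variant_params$exact_reads <- TRUE
    sv_params$caller_sens <- 1
    sv_params$jitter_max <- 0
    sv_params$fp_rate <- 0
    sv_params$fixed_support <- TRUE
    depth_params$baseline_sdlog <- 0
    depth_params$target_sdlog <- 0
  }
  structure(list(n_samples = n_samples, seed = as.integer(seed),
                 group_mix = group_mix, control_params = control_params,
                 fraction_params = fraction_params,
                 gain_params = gain_params, loss_params = loss_params,
                 variant_params = variant_params, sv_params = sv_params,
                 survival_params = survival_params,
                 depth_params = depth_params, noise_free = noise_free),
            class = "sim_config")
}

#' Draw healthy-donor control aneuploidy fractions
#'
#' n draws from a normal with the configured mean and SD, truncated to
#' \[0, 1\] by redrawing.
#'
#' @param config `sim_config` (uses `control_params`); the caller controls
#'   RNG state ([generate_cohort()] seeds it from `config$seed`).
#' @param n optional override of the number of draws.
#' @return numeric vector of control fractions.
#' @export
generate_controls <- function(config, n = NULL) {
  cp <- config$control_params
  n <- n %||% cp$n
  if (cp$sd == 0) return(rep(cp$mean, n))
  x <- stats::rnorm(n, cp$mean, cp$sd)
  while (any(bad <- x < 0 | x > 1))
    x[bad] <- stats::rnorm(sum(bad), cp$mean, cp$sd)
  x
}

lnoise <- function(n, sdlog) {
  if (sdlog == 0) rep(1, n) else stats::rlnorm(n, 0, sdlog)
}

# minimal fraction at which each trigger's signal clears its detection
# threshold (gain: log2 ratio 0.3; snv: >= 6 alt reads at VAF f/2)
trigger_min_fraction <- function(config) {
  g <- config$gain_params
  gain_lift <- 2^0.3 - 1
  c(snv = 6 / (config$variant_params$total_reads / 2),
    ar_amp = gain_lift / (g$ar_copies - 1),
    ar_body_only = gain_lift / (g$ar_copies - 1),
    ar_enh_only = gain_lift / (g$enhancer_copies - 1),
    ar_gsr = 0.01,
    myc_gain = gain_lift / (g$myc_copies / 2 - 1),
    mycn_gain = gain_lift / (g$mycn_copies / 2 - 1))
}

draw_fraction <- function(config, group, threshold, lo_required = 0) {
  fp <- config$fraction_params[[group]]
  if (!is.null(fp$range)) {
    lo <- fp$range[1]
    hi <- fp$range[2]
  } else if (group == "Group1") {
    lo <- threshold + 1e-6
    hi <- 0.85
  } else {
    lo <- 0.004
    hi <- 0.98 * threshold
  }
  lo <- max(lo, lo_required)
  if (lo >= hi)
    stop("infeasible fraction window for ", group,
         " (threshold too low for planted triggers)", call. = FALSE)
  lo + (hi - lo) * stats::rbeta(1, fp$shape1, fp$shape2)
}

# variant catalog: fixed definitions the generator plants and annotates.
# positions sit inside the toy panel's exons.
variant_catalog <- function(panel) {
  pos_in <- function(gene, off = 50) {
    g <- panel$genes[[gene]]
    c(chrom = g$chrom, pos = g$exons$start[1] + off + 1)  # 1-based
  }
  def <- function(gene, kind, ref, alt, pchg, conseq, curated, onc,
                  off = 50) {
    p <- pos_in(gene, off)
    data.frame(gene = gene, kind = kind, chrom = p[["chrom"]],
               pos = as.numeric(p[["pos"]]), ref = ref, alt = alt,
               protein_change = pchg, consequences = conseq,
               oncokb_curated = curated, oncogenicity = onc,
               stringsAsFactors = FALSE)
  }
  rbind(
    def("TP53", "somatic", "C", "T", "p.Arg175His", "missense", TRUE,
        "Oncogenic"),
    def("SPOP", "somatic", "G", "A", "p.Phe133Leu", "missense", TRUE,
        "Oncogenic"),
    def("PIK3CA", "somatic", "A", "G", "p.Glu545Lys", "missense", TRUE,
        "Oncogenic"),
    def("ATM", "somatic", "G", "T", "p.Arg337Cys", "missense", TRUE,
        "LikelyOncogenic"),
    def("AR", "somatic", "C", "T", "p.His875Tyr", "missense", TRUE,
        "Oncogenic"),
    def("BRCA2", "germline", "A", "T", "p.Lys3326Ter", "nonsense", TRUE,
        "Oncogenic"),
    def("HSD3B1", "germline", "T", "C", "p.Asn367Thr", "missense", FALSE,
        "LikelyOncogenic"),
    def("AURKA", "benign", "T", "A", "p.Phe31Ile", "missense", TRUE,
        "Oncogenic"),
    def("MET", "benign", "G", "A", "p.Glu168Asp", "missense", TRUE,
        "LikelyOncogenic"),
    def("FOXA1", "benign", "C", "G", "p.Ser250Ser", "synonymous", FALSE,
        "Other"),
    def("KMT2C", "benign", "A", "C", "p.Val123Gly",
        "missense,splice-region", FALSE, "LikelyOncogenic"))
}

#' Generate a synthetic cohort bundle
#'
#' Seeds the RNG from `config$seed` and draws, in order: control fractions
#' (the realized mean + 3 SD threshold anchors the planted groups), planted
#' group labels and alterations, depth profiles, per-caller SNV and SV call
#' sets, cfDNA yields and survival outcomes. Samples carrying planted
#' copy-number alterations are given fractions above the panel-of-normals
#' cutoff so the depth reference stays alteration-free; Group 2 fractions
#' additionally sit above the minimal fraction at which at least one
#' planted trigger is detectable, making planted labels recoverable by
#' construction.
#'
#' @param config `sim_config`.
#' @return list of class `cohort_bundle` with `config`, `panel`,
#'   `controls`, `depth_profiles`, `fractions`, `yields`, `snv_calls`
#'   (per caller), `annotations`, `sv_calls` (per caller), `survival`, and
#'   `truth` (planted labels; never consumed by the pipeline under test).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  panel <- toy_panel()
  controls <- generate_controls(config)
  threshold <- derive_aneuploidy_threshold(controls)$threshold
  n <- config$n_samples
  ids <- sprintf("S%04d", seq_len(n))
  groups <- sample(names(config$group_mix), n, replace = TRUE,
                   prob = config$group_mix)
  min_f <- trigger_min_fraction(config)
  ap <- config$gain_params$alt_probs
  trigger_cols <- c("snv", "ar_amp", "ar_body_only", "ar_enh_only",
                    "ar_gsr", "myc_gain", "mycn_gain")
  catalog <- variant_catalog(panel)
  vp <- config$variant_params
  sp <- config$sv_params
  dp <- config$depth_params

  truth <- vector("list", n)
  profiles <- vector("list", n)
  snv_rows <- stats::setNames(vector("list", length(SNV_CALLERS)),
                              SNV_CALLERS)
  sv_rows <- stats::setNames(vector("list", length(SV_CALLERS)),
                             SV_CALLERS)
  fractions <- numeric(n)
  yields <- numeric(n)

  gsr_slots <- c(1800, 4300, 6800)  # spaced > 2x tolerance inside the gene

  for (i in seq_len(n)) {
    gr <- groups[i]
    alts <- stats::setNames(
      stats::runif(ncol(ap)) < ap[gr, ], colnames(ap))
    if (gr == "Group2" && !any(alts[trigger_cols])) {
      pick <- sample(trigger_cols, 1,
                     prob = ap[gr, trigger_cols] + 1e-9)
      alts[pick] <- TRUE
    }
    has_cn <- alts[["ar_amp"]] || alts[["ar_body_only"]] ||
      alts[["ar_enh_only"]] || alts[["myc_gain"]] ||
      alts[["mycn_gain"]] || alts[["tsg_loss"]]
    lo_req <- 0
    if (gr == "Group2") {
      planted <- trigger_cols[alts[trigger_cols]]
      lo_req <- 1.1 * min(min_f[planted])
      if (has_cn) lo_req <- max(lo_req, 0.055)
      hi <- 0.98 * threshold
      if (lo_req >= hi) {  # trigger unreachable below threshold: fall back
        alts[["ar_gsr"]] <- TRUE
        lo_req <- if (has_cn) 0.055 else 0.02
      }
    } else if (gr == "Group3") {
      alts[] <- FALSE
      has_cn <- FALSE
    } else if (has_cn) {
      lo_req <- 0.055
    }
    f <- draw_fraction(config, gr, threshold, lo_req)
    fractions[i] <- f

    # --- depths: per-copy coverage d, controls share the baseline ---
    d <- dp$baseline / 2 * lnoise(1, dp$baseline_sdlog)
    copies <- function(germline, tumor) (1 - f) * germline + f * tumor
    depths <- c(C1 = 2 * d, C2 = d, C3 = 2 * d, C4 = 2 * d, C5 = 2 * d)
    ar_amp <- alts[["ar_amp"]] || alts[["ar_body_only"]]
    enh_amp <- alts[["ar_amp"]] || alts[["ar_enh_only"]]
    for (gsym in names(panel$genes)) {
      germ <- if (target_chrom(panel, gsym) %in% c("chrX", "X")) 1 else 2
      tum <- germ
      if (gsym == "AR" && ar_amp) tum <- config$gain_params$ar_copies
      if (gsym == "MYC" && alts[["myc_gain"]])
        tum <- config$gain_params$myc_copies
      if (gsym == "MYCN" && alts[["mycn_gain"]])
        tum <- config$gain_params$mycn_copies
      if (alts[["tsg_loss"]] && gsym %in% config$loss_params$genes)
        tum <- config$loss_params$tsg_copies
      depths[gsym] <- d * copies(germ, tum)
    }
    depths["AR_enhancer"] <- d * copies(
      1, if (enh_amp) config$gain_params$enhancer_copies else 1)
    depths <- depths * lnoise(length(depths), dp$target_sdlog)
    profiles[[i]] <- depth_profile(ids[i], depths)

    # --- SNVs ---
    planted_vars <- list()
    if (alts[["snv"]]) {
      som <- catalog[catalog$kind == "somatic", ]
      row <- som[sample(nrow(som), 1), ]
      germ_copies <- if (row$gene == "AR") 1 else 2
      vaf <- f / germ_copies  # one mutated allele of the germline copies
      planted_vars[[length(planted_vars) + 1L]] <-
        cbind(row, vaf = vaf, stringsAsFactors = FALSE)
    }
    if (stats::runif(1) < vp$germline_rate) {
      germ <- catalog[catalog$kind == "germline", ]
      row <- germ[sample(nrow(germ), 1), ]
      vaf <- if (vp$germline_sd == 0) 0.5 else
        min(0.99, max(0.01, stats::rnorm(1, 0.5, vp$germline_sd)))
      planted_vars[[length(planted_vars) + 1L]] <-
        cbind(row, vaf = vaf, stringsAsFactors = FALSE)
    }
    if (stats::runif(1) < vp$benign_rate) {
      ben <- catalog[catalog$kind == "benign", ]
      row <- ben[sample(nrow(ben), 1), ]
      planted_vars[[length(planted_vars) + 1L]] <-
        cbind(row, vaf = 0.5, stringsAsFactors = FALSE)
    }
    for (caller in SNV_CALLERS) {
      recs <- list()
      for (pv in planted_vars) {
        if (stats::runif(1) > vp$caller_sens[[caller]]) next
        if (isTRUE(vp$exact_reads)) {
          ar_n <- round(vp$total_reads * pv$vaf)
          vaf_obs <- pv$vaf
        } else {
          ar_n <- stats::rbinom(1, vp$total_reads, pv$vaf)
          vaf_obs <- ar_n / vp$total_reads
        }
        recs[[length(recs) + 1L]] <- data.frame(
          sample_id = ids[i], caller = caller, chrom = pv$chrom,
          pos = pv$pos, ref = pv$ref, alt = pv$alt, vaf = vaf_obs,
          alt_reads = ar_n, stringsAsFactors = FALSE)
      }
      if (stats::runif(1) < vp$caller_fp_rate) {
        # caller-private artifact at a caller-specific position
        fp_pos <- 5e7 + sample.int(1e6, 1) +
          match(caller, SNV_CALLERS) * 2e6
        recs[[length(recs) + 1L]] <- data.frame(
          sample_id = ids[i], caller = caller, chrom = "chr2",
          pos = fp_pos, ref = "G", alt = "C", vaf = 0.02,
          alt_reads = 8, stringsAsFactors = FALSE)
      }
      if (length(recs))
        snv_rows[[caller]] <- c(snv_rows[[caller]], recs)
    }

    # --- SVs ---
    n_gsr <- 0L
    if (alts[["ar_gsr"]]) {
      n_gsr <- min(1L + stats::rpois(1, sp$extra_gsr_mean),
                   length(gsr_slots))
      types <- sample(c("DEL", "DUP", "INV", "TRA"), n_gsr,
                      replace = TRUE)
      for (k in seq_len(n_gsr)) {
        p1 <- gsr_slots[k]
        if (types[k] == "TRA") {
          base <- data.frame(chrom1 = "chrX", pos1 = p1,
                             side1 = "retains_left", chrom2 = "chr7",
                             pos2 = 3e7 + k * 1e5,
                             side2 = "retains_right",
                             svtype = "TRA", stringsAsFactors = FALSE)
        } else {
          bp <- decompose_to_breakends(types[k], "chrX", p1,
                                       p1 + 60000 + k * 5000)
          bp$svtype <- types[k]
          base <- bp
        }
        for (caller in SV_CALLERS) {
          if (stats::runif(1) > sp$caller_sens) next
          rec <- base
          if (sp$jitter_max > 0) {
            rec$pos1 <- rec$pos1 +
              sample(-sp$jitter_max:sp$jitter_max, 1)
            rec$pos2 <- rec$pos2 +
              sample(-sp$jitter_max:sp$jitter_max, 1)
          }
          if (isTRUE(sp$fixed_support)) {
            sr <- sp$split_mean; dr <- sp$discordant_mean
          } else {
            sr <- max(3, stats::rpois(1, sp$split_mean))
            dr <- max(3, stats::rpois(1, sp$discordant_mean))
          }
          rec$sample_id <- ids[i]
          rec$caller <- caller
          rec$split_reads <- sr
          rec$discordant_reads <- dr
          sv_rows[[caller]] <- c(sv_rows[[caller]], list(rec))
        }
      }
    }
    for (caller in SV_CALLERS) {  # caller-private background call
      if (stats::runif(1) < sp$fp_rate) {
        p1 <- 1e7 + sample.int(1e6, 1) + match(caller, SV_CALLERS) * 5e6
        rec <- decompose_to_breakends("DEL", "chr6", p1, p1 + 5e4)
        rec$svtype <- "DEL"
        rec$sample_id <- ids[i]
        rec$caller <- caller
        rec$split_reads <- max(3, stats::rpois(1, sp$split_mean))
        rec$discordant_reads <- max(3, stats::rpois(1, sp$discordant_mean))
        sv_rows[[caller]] <- c(sv_rows[[caller]], list(rec))
      }
    }

    yields[i] <- (8 + 40 * f) * lnoise(1, 0.2)  # ng per mL plasma

    truth[[i]] <- data.frame(
      sample_id = ids[i], group = gr, fraction = f,
      snv = alts[["snv"]], ar_gain = ar_amp, enh_gain = enh_amp,
      ar_gsr = alts[["ar_gsr"]], n_gsr = n_gsr,
      myc_gain = alts[["myc_gain"]], mycn_gain = alts[["mycn_gain"]],
      tsg_loss = alts[["tsg_loss"]],
      ecdna = ar_amp && n_gsr >= 2L, stringsAsFactors = FALSE)
  }

  truth <- do.call(rbind, truth)
  names(fractions) <- ids
  sv <- config$survival_params
  rate <- log(2) / sv$medians[truth$group]
  t_event <- stats::rexp(n, rate)
  survdf <- if (sv$censor_rate > 0) {
    c_rate <- rate * sv$censor_rate / (1 - sv$censor_rate)
    t_cens <- stats::rexp(n, c_rate)
    data.frame(sample_id = ids, time = pmin(t_event, t_cens),
               event = as.integer(t_event <= t_cens),
               stringsAsFactors = FALSE)
  } else {
    data.frame(sample_id = ids, time = t_event, event = 1L,
               stringsAsFactors = FALSE)
  }

  collapse <- function(rows) {
    if (is.null(rows) || !length(rows))
      return(NULL)
    df <- do.call(rbind, rows)
    rownames(df) <- NULL
    df
  }
  ann <- catalog[, c("chrom", "pos", "ref", "alt", "gene",
                     "protein_change", "consequences", "oncokb_curated",
                     "oncogenicity")]
  structure(list(config = config, panel = panel, controls = controls,
                 depth_profiles = stats::setNames(profiles, ids),
                 fractions = fractions, yields = yields,
                 snv_calls = lapply(snv_rows, collapse),
                 annotations = ann,
                 sv_calls = lapply(sv_rows, collapse),
                 survival = survdf, truth = truth),
            class = "cohort_bundle")
}

#' Write a cohort bundle to disk as plain-text fixtures
#'
#' Emits the exact formats the pipeline consumes: depth TSV, fractions and
#' controls TSV, survival TSV, annotation TSV, one VCF 4.2 per caller per
#' sample (SNV and SV), the panel JSON, a truth JSON, and a manifest
#' listing every file's MD5 checksum and the seed. The same seed yields a
#' byte-identical bundle.
#'
#' @param bundle `cohort_bundle`.
#' @param out_dir output directory (created if needed).
#' @return the manifest, invisibly.
#' @export
write_fixture_bundle <- function(bundle, out_dir) {
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE)
  if (!ok) stop("cannot create output directory: ", out_dir, call. = FALSE)
  wpath <- function(...) file.path(out_dir, ...)
  write_depth_table(bundle$depth_profiles, wpath("depth.tsv"))
  utils::write.table(
    data.frame(sample_id = names(bundle$fractions),
               fraction = unname(bundle$fractions),
               yield_ng_per_ml = bundle$yields),
    wpath("fractions.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(control_fraction = bundle$controls),
                     wpath("controls.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  sv_out <- bundle$survival
  names(sv_out)[names(sv_out) == "time"] <- "time_months"
  utils::write.table(sv_out, wpath("survival.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(bundle$annotations, wpath("annotations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  panel_to_json(bundle$panel, wpath("panel.json"))
  ids <- names(bundle$depth_profiles)
  for (caller in SNV_CALLERS) {
    dir.create(wpath("snv", caller), recursive = TRUE, showWarnings = FALSE)
    calls <- bundle$snv_calls[[caller]]
    for (id in ids) {
      sub <- if (is.null(calls)) NULL else
        calls[calls$sample_id == id, , drop = FALSE]
      if (is.null(sub)) sub <- data.frame(chrom = character(),
                                          pos = numeric(),
                                          ref = character(),
                                          alt = character(),
                                          vaf = numeric(),
                                          alt_reads = numeric(),
                                          context = character(),
                                          context_start = numeric())
      if (is.null(sub$context))
        sub$context <- rep(NA_character_, nrow(sub))
      write_snv_vcf(sub, wpath("snv", caller, paste0(id, ".vcf")))
    }
  }
  for (caller in SV_CALLERS) {
    dir.create(wpath("sv", caller), recursive = TRUE, showWarnings = FALSE)
    calls <- bundle$sv_calls[[caller]]
    for (id in ids) {
      sub <- if (is.null(calls)) NULL else
        calls[calls$sample_id == id, , drop = FALSE]
      if (is.null(sub)) sub <- data.frame(chrom1 = character(),
                                          pos1 = numeric(),
                                          side1 = character(),
                                          chrom2 = character(),
                                          pos2 = numeric(),
                                          side2 = character(),
                                          svtype = character(),
                                          split_reads = numeric(),
                                          discordant_reads = numeric())
      write_sv_vcf(sub, wpath("sv", caller, paste0(id, ".vcf")))
    }
  }
  jsonlite::write_json(bundle$truth, wpath("truth.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  files <- list.files(out_dir, recursive = TRUE)
  files <- setdiff(files, "manifest.json")
  manifest <- list(seed = bundle$config$seed,
                   n_samples = bundle$config$n_samples,
                   files = data.frame(
                     path = files,
                     md5 = unname(tools::md5sum(file.path(out_dir, files))),
                     stringsAsFactors = FALSE))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Read a fixture bundle back from disk
#'
#' Inverse of [write_fixture_bundle()] (the truth file is read back for
#' closed-loop testing but is not part of the pipeline inputs).
#'
#' @param dir bundle directory.
#' @return list shaped like a `cohort_bundle` (without `config`).
#' @export
read_fixture_bundle <- function(dir) {
  profiles <- read_depth_table(file.path(dir, "depth.tsv"))
  fr <- utils::read.delim(file.path(dir, "fractions.tsv"),
                          stringsAsFactors = FALSE)
  fractions <- stats::setNames(fr$fraction, fr$sample_id)
  controls <- utils::read.delim(
    file.path(dir, "controls.tsv"))$control_fraction
  survdf <- read_survival_table(file.path(dir, "survival.tsv"))
  ann <- utils::read.delim(file.path(dir, "annotations.tsv"),
                           stringsAsFactors = FALSE)
  panel <- panel_from_json(file.path(dir, "panel.json"))
  ids <- names(profiles)
  read_caller <- function(sub, caller, reader) {
    out <- lapply(ids, function(id)
      reader(file.path(dir, sub, caller, paste0(id, ".vcf")), id, caller))
    out <- out[vapply(out, nrow, 0L) > 0]
    if (!length(out)) NULL else do.call(rbind, out)
  }
  snv <- lapply(stats::setNames(SNV_CALLERS, SNV_CALLERS), function(cl)
    read_caller("snv", cl, read_snv_vcf))
  sv <- lapply(stats::setNames(SV_CALLERS, SV_CALLERS), function(cl)
    read_caller("sv", cl, read_sv_vcf))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  structure(list(panel = panel, controls = controls,
                 depth_profiles = profiles, fractions = fractions,
                 yields = fr$yield_ng_per_ml, snv_calls = snv,
                 annotations = ann, sv_calls = sv, survival = survdf,
                 truth = truth),
            class = "cohort_bundle")
}
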