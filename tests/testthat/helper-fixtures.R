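# Shared fixtures and independent oracles used across the suite.

toy_controls <- function(c1 = 400, c2 = 200, c3 = 400, c4 = 400,
                         c5 = 400) {
  c(C1 = c1, C2 = c2, C3 = c3, C4 = c4, C5 = c5)
}

# depth profile over the toy panel with neutral per-copy coverage d:
# chrX targets get d, autosomes 2d, controls (2d,d,2d,2d,2d); overrides are
# absolute depths per target label.
toy_profile <- function(sample_id, panel, d = 200, overrides = NULL) {
  depths <- toy_controls(2 * d, d, 2 * d, 2 * d, 2 * d)
  for (g in names(panel$genes)) {
    chrx <- panel$genes[[g]]$chrom %in% c("chrX", "X")
    depths[g] <- if (chrx) d else 2 * d
  }
  depths["AR_enhancer"] <- d
  if (!is.null(overrides)) depths[names(overrides)] <- overrides
  depth_profile(sample_id, depths)
}

# one-row SV description as a list (accepted wherever a one-row data.frame
# is: classify_lbd_truncating and match_sv only use $ access)
sv_row <- function(chrom1, pos1, side1, chrom2, pos2, side2, svtype,
                   sample_id = "S1", caller = "manta", sr = 5, dr = 5) {
  data.frame(sample_id = sample_id, caller = caller, chrom1 = chrom1,
             pos1 = pos1, side1 = side1, chrom2 = chrom2, pos2 = pos2,
             side2 = side2, svtype = svtype, split_reads = sr,
             discordant_reads = dr, stringsAsFactors = FALSE)
}

# --- independent brute-force oracle for the LBD-truncation rules --------
# Works on 0-based breakpoint positions and applies each rule's clauses
# directly from their interval definitions, scalar and unoptimized, with no
# shared code with the implementation.
oracle_lbd_rule <- function(svtype, p1_0, p2_0, ar, side1 = "retains_left",
                            tra_mate_other_chrom = TRUE) {
  ex <- ar$exons
  stopc <- ar$stop_codon_pos
  a13 <- c(ex$start[1], ex$end[3])
  gene <- c(ar$gene_body$start, ar$gene_body$end)
  ov <- function(s1, e1, s2, e2) max(s1, s2) < min(e1, e2)
  mid <- function(p) p > a13[2] && p <= stopc
  if (svtype == "TRA") {
    if (!(p1_0 >= gene[1] && p1_0 < gene[2])) return(0L)
    if (mid(p1_0) && side1 == "retains_left") return(4L)
    return(0L)
  }
  lo <- min(p1_0, p2_0)
  hi <- max(p1_0, p2_0)
  lbd_hit <- FALSE
  for (k in 4:7) if (ov(lo, hi, ex$start[k], ex$end[k])) lbd_hit <- TRUE
  if (ov(lo, hi, ex$start[8], stopc)) lbd_hit <- TRUE
  r1 <- svtype %in% c("DEL", "INV", "BND") && lbd_hit &&
    !ov(lo, hi, a13[1], a13[2])
  if (r1) return(1L)
  r2 <- svtype %in% c("DUP", "INV", "BND") &&
    (lo <= a13[1] && a13[2] <= hi) && (mid(p1_0) || mid(p2_0))
  if (r2) return(2L)
  if (svtype == "DUP") {
    both_in <- p1_0 >= gene[1] && p1_0 < gene[2] &&
      p2_0 >= gene[1] && p2_0 < gene[2]
    whole <- FALSE
    for (k in 3:7) if (lo <= ex$start[k] && ex$end[k] <= hi) whole <- TRUE
    if (both_in && whole) return(3L)
  }
  0L
}

# hand product-limit computation: iterate event times, multiply survival
# factors over the risk set (events precede censorings at ties)
oracle_km <- function(time, event) {
  ut <- sort(unique(time[event == 1]))
  s <- 1
  out <- numeric(length(ut))
  for (i in seq_along(ut)) {
    n_i <- sum(time >= ut[i])
    d_i <- sum(time == ut[i] & event == 1)
    s <- s * (1 - d_i / n_i)
    out[i] <- s
  }
  list(time = ut, surv = out,
       median = if (any(out <= 0.5)) ut[min(which(out <= 0.5))] else NA_real_)
}

# small noise-free bundle shared by pipeline-level tests
nf_bundle <- function(n = 40, seed = 404) {
  generate_cohort(sim_config(n_samples = n, seed = seed, noise_free = TRUE))
}
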