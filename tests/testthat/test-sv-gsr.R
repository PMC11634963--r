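ar <- toy_ar_model()

test_that("svtype inference follows the breakend-orientation table", {
  expect_equal(infer_svtype("chr1", 100, "retains_left",
                            "chr1", 500, "retains_right"), "DEL")
  expect_equal(infer_svtype("chr1", 100, "retains_right",
                            "chr1", 500, "retains_left"), "DUP")
  expect_equal(infer_svtype("chr1", 100, "retains_left",
                            "chr1", 500, "retains_left"), "INV")
  expect_equal(infer_svtype("chr1", 100, "retains_right",
                            "chr1", 500, "retains_right"), "INV")
  expect_equal(infer_svtype("chrX", 100, "retains_left",
                            "chr7", 500, "retains_right"), "TRA")
  # order of breakends does not matter
  expect_equal(infer_svtype("chr1", 500, "retains_right",
                            "chr1", 100, "retains_left"), "DEL")
  expect_error(infer_svtype("chr1", 1, "left", "chr1", 2, "retains_left"),
               "orientation")
})

test_that("symbolic decomposition round-trips through svtype inference", {
  for (type in c("DEL", "DUP")) {
    bp <- decompose_to_breakends(type, "chr1", 100, 500)
    expect_equal(infer_svtype(bp$chrom1, bp$pos1, bp$side1, bp$chrom2,
                              bp$pos2, bp$side2), type)
  }
  for (layout in c("left", "right")) {
    bp <- decompose_to_breakends("INV", "chr1", 100, 500,
                                 inv_layout = layout)
    expect_equal(infer_svtype(bp$chrom1, bp$pos1, bp$side1, bp$chrom2,
                              bp$pos2, bp$side2), "INV")
  }
  expect_error(decompose_to_breakends("DEL", "chr1", 100, NA), "END")
})

test_that("breakend bracket notation parses and formats consistently", {
  cases <- list(
    list(alt = "N[chr1:500[", local = "retains_left",
         mate = "retains_right"),
    list(alt = "N]chr1:500]", local = "retains_left",
         mate = "retains_left"),
    list(alt = "]chr1:500]N", local = "retains_right",
         mate = "retains_left"),
    list(alt = "[chr1:500[N", local = "retains_right",
         mate = "retains_right"))
  for (cs in cases) {
    p <- parse_bnd_alt(cs$alt)
    expect_equal(p$local_side, cs$local)
    expect_equal(p$mate_side, cs$mate)
    expect_equal(p$mate_pos, 500)
    expect_equal(format_bnd_alt("N", p$local_side, p$mate_side,
                                p$mate_chrom, p$mate_pos), cs$alt)
  }
  expect_error(parse_bnd_alt("N[chr1:500]"), "malformed")
})

test_that("SV matching applies the 1000 bp tolerance to both breakends and is symmetric", {
  a <- sv_row("chr1", 10000, "retains_left", "chr1", 50000,
              "retains_right", "DEL")
  shift <- function(by) sv_row("chr1", 10000 + by, "retains_left", "chr1",
                               50000 + by, "retains_right", "DEL",
                               caller = "delly")
  expect_true(match_sv(a, a))
  expect_true(match_sv(a, shift(999)))
  expect_true(match_sv(a, shift(1000)))
  expect_false(match_sv(a, shift(1001)))
  # one breakend out of tolerance is enough to fail
  b <- sv_row("chr1", 10000, "retains_left", "chr1", 52000,
              "retains_right", "DEL")
  expect_false(match_sv(a, b))
  # different chromosomes never match
  c2 <- sv_row("chr2", 10000, "retains_left", "chr2", 50000,
               "retains_right", "DEL")
  expect_false(match_sv(a, c2))
  # symmetry on random jittered pairs
  set.seed(5)
  for (i in 1:50) {
    x <- sv_row("chr1", 1e5 + sample(2000, 1), "retains_left", "chr1",
                2e5 + sample(2000, 1), "retains_right", "DEL")
    y <- sv_row("chr1", 1e5 + sample(2000, 1), "retains_left", "chr1",
                2e5 + sample(2000, 1), "retains_right", "DEL")
    expect_identical(match_sv(x, y), match_sv(y, x))
  }
})

test_that("consensus merge equals an independent connected-components oracle on jittered SVs", {
  skip_if_not_installed("igraph")
  set.seed(11)
  n_events <- 50
  base1 <- sort(sample(seq(1e5, 5e7, by = 5e4), n_events))
  base2 <- base1 + 3e4
  sets <- lapply(c("manta", "delly", "svaba", "lumpy"), function(cl) {
    keep <- runif(n_events) < 0.8
    jit1 <- sample(-450:450, n_events, TRUE)
    jit2 <- sample(-450:450, n_events, TRUE)
    do.call(rbind, lapply(which(keep), function(k)
      sv_row("chr3", base1[k] + jit1[k], "retains_left", "chr3",
             base2[k] + jit2[k], "retains_right", "DEL", caller = cl,
             sr = sample(3:20, 1), dr = sample(3:20, 1))))
  })
  merged <- consensus_merge(sets, tolerance = 1000)
  # oracle: direct all-pairs adjacency + igraph components
  all_svs <- do.call(rbind, sets)
  n <- nrow(all_svs)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    adj[i, j] <- all_svs$chrom1[i] == all_svs$chrom1[j] &&
      all_svs$chrom2[i] == all_svs$chrom2[j] &&
      abs(all_svs$pos1[i] - all_svs$pos1[j]) <= 1000 &&
      abs(all_svs$pos2[i] - all_svs$pos2[j]) <= 1000
  }
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  expect_equal(nrow(merged), max(comp))
  # per-cluster caller support and read maxima agree with the oracle
  oracle <- lapply(split(seq_len(n), comp), function(idx)
    list(callers = sort(unique(all_svs$caller[idx])),
         sr = max(all_svs$split_reads[idx]),
         dr = max(all_svs$discordant_reads[idx]),
         pos1_min = min(all_svs$pos1[idx])))
  oracle <- oracle[order(vapply(oracle, `[[`, 0, "pos1_min"))]
  merged <- merged[order(merged$pos1), ]
  for (k in seq_along(oracle)) {
    expect_equal(strsplit(merged$supporting_callers[k], ",")[[1]],
                 oracle[[k]]$callers)
    expect_equal(merged$best_split_reads[k], oracle[[k]]$sr)
    expect_equal(merged$best_discordant_reads[k], oracle[[k]]$dr)
  }
})

test_that("consensus merge is invariant to input ordering", {
  set.seed(21)
  sets <- lapply(c("manta", "delly"), function(cl)
    do.call(rbind, lapply(1:20, function(k)
      sv_row("chr5", k * 1e5 + sample(-400:400, 1), "retains_left",
             "chr5", k * 1e5 + 4e4 + sample(-400:400, 1),
             "retains_right", "DEL", caller = cl))))
  m1 <- consensus_merge(sets)
  shuffled <- lapply(sets, function(s) s[sample(nrow(s)), ])
  m2 <- consensus_merge(rev(shuffled))
  ord <- function(m) m[order(m$chrom1, m$pos1, m$pos2), ]
  expect_equal(ord(m1)$supporting_callers, ord(m2)$supporting_callers)
  expect_equal(ord(m1)$pos1, ord(m2)$pos1)
})

test_that("within-caller dedup collapses exact keys with read-support maxima", {
  dup <- rbind(
    sv_row("chr1", 100, "retains_left", "chr1", 900, "retains_right",
           "DEL", sr = 4, dr = 9),
    sv_row("chr1", 900, "retains_right", "chr1", 100, "retains_left",
           "DEL", sr = 7, dr = 2))  # same SV, swapped breakend order
  out <- dedup_caller_svs(dup)
  expect_equal(nrow(out), 1)
  expect_equal(out$split_reads, 7)
  expect_equal(out$discordant_reads, 9)
})

test_that("blacklist filtering removes SVs by breakend membership with half-open ends", {
  bl <- genomic_intervals("chr1", 100, 200, "bl")
  inside <- sv_row("chr1", 150, "retains_left", "chr1", 5000,
                   "retains_right", "DEL")
  at_end <- sv_row("chr1", 201, "retains_left", "chr1", 5000,
                   "retains_right", "DEL")  # 0-based 200 == interval end
  last_in <- sv_row("chr1", 200, "retains_left", "chr1", 5000,
                    "retains_right", "DEL")
  outside <- sv_row("chr1", 5000, "retains_left", "chr1", 9000,
                    "retains_right", "DEL")
  svs <- rbind(inside, at_end, last_in, outside)
  svs$n_callers <- 2
  kept <- filter_blacklist(svs, bl)
  expect_equal(kept$pos1, c(201, 5000))
})

test_that("AR-GSR detection enforces region, caller and read-support thresholds jointly", {
  mk <- function(pos1, n_callers, sr, dr, chrom = "chrX") {
    data.frame(sample_id = "s", chrom1 = chrom, pos1 = pos1,
               side1 = "retains_left", chrom2 = "chr7", pos2 = 5e6,
               side2 = "retains_right", svtype = "TRA",
               supporting_callers = paste(seq_len(n_callers),
                                          collapse = ","),
               n_callers = n_callers, best_split_reads = sr,
               best_discordant_reads = dr, n_members = n_callers,
               stringsAsFactors = FALSE)
  }
  cons <- rbind(mk(5000, 2, 3, 3),    # retained
                mk(5000, 2, 5, 2),    # discordant support too low
                mk(5000, 1, 10, 10),  # single caller
                mk(5000, 4, 10, 10, chrom = "chr8"))  # not in AR
  out <- detect_ar_gsrs(cons, ar)
  expect_equal(nrow(out), 1)
  expect_true(all(out$in_ar_region))
  expect_equal(out$best_split_reads, 3)
})

test_that("LBD rule examples on the toy AR model", {
  # DEL spanning exons 5-7 only (no A13 overlap): rule 1
  del57 <- sv_row("chrX", 4801, "retains_left", "chrX", 7601,
                  "retains_right", "DEL")
  expect_equal(classify_lbd_truncating(del57, ar), 1L)
  # DUP containing exon 1 with a breakpoint between exon 3 end and the
  # stop codon: rule 2
  dup <- sv_row("chrX", 901, "retains_right", "chrX", 6001,
                "retains_left", "DUP")
  expect_equal(classify_lbd_truncating(dup, ar), 2L)
  # DEL spanning exons 2-5 overlaps the exon 1-3 interval: no rule
  del25 <- sv_row("chrX", 1901, "retains_left", "chrX", 5601,
                  "retains_right", "DEL")
  expect_equal(classify_lbd_truncating(del25, ar), 0L)
  # DUP inside the gene containing whole exons 4-5: rule 3
  dup_in <- sv_row("chrX", 3801, "retains_right", "chrX", 5601,
                   "retains_left", "DUP")
  expect_equal(classify_lbd_truncating(dup_in, ar), 3L)
  # TRA at a mid-gene breakpoint retaining the centromeric side: rule 4
  tra <- sv_row("chrX", 6001, "retains_left", "chr7", 5e6,
                "retains_right", "TRA")
  expect_equal(classify_lbd_truncating(tra, ar), 4L)
  # same TRA retaining the telomeric side: no rule
  tra2 <- sv_row("chrX", 6001, "retains_right", "chr7", 5e6,
                 "retains_left", "TRA")
  expect_equal(classify_lbd_truncating(tra2, ar), 0L)
})

test_that("LBD classifier agrees with the brute-force interval oracle over a breakpoint grid", {
  grid <- seq(0, 10000, by = 250)  # 0-based breakpoints over the toy gene
  pairs <- t(combn(grid, 2))
  count <- 0
  for (type in c("DEL", "DUP", "INV", "BND")) {
    sides <- switch(type,
                    DEL = c("retains_left", "retains_right"),
                    DUP = c("retains_right", "retains_left"),
                    c("retains_left", "retains_left"))
    for (r in seq_len(nrow(pairs))) {
      sv <- list(chrom1 = "chrX", pos1 = pairs[r, 1] + 1,
                 side1 = sides[1], chrom2 = "chrX",
                 pos2 = pairs[r, 2] + 1, side2 = sides[2], svtype = type)
      got <- classify_lbd_truncating(sv, ar)
      want <- oracle_lbd_rule(type, pairs[r, 1], pairs[r, 2], ar)
      if (got != want)
        fail(sprintf("%s %d-%d: got %d want %d", type, pairs[r, 1],
                     pairs[r, 2], got, want))
      count <- count + 1
    }
  }
  for (p in grid) for (side in c("retains_left", "retains_right")) {
    sv <- list(chrom1 = "chrX", pos1 = p + 1, side1 = side,
               chrom2 = "chr7", pos2 = 5e6, side2 = "retains_right",
               svtype = "TRA")
    expect_equal(classify_lbd_truncating(sv, ar),
                 oracle_lbd_rule("TRA", p, 5e6 - 1, ar, side1 = side))
    count <- count + 1
  }
  expect_gte(count, 2000)
})

test_that("every detected AR-GSR reports in_ar_region (filter soundness)", {
  set.seed(9)
  cons <- do.call(rbind, lapply(1:30, function(i)
    data.frame(sample_id = "s", chrom1 = sample(c("chrX", "chr2"), 1),
               pos1 = sample(10000, 1), side1 = "retains_left",
               chrom2 = "chr7", pos2 = 5e6, side2 = "retains_right",
               svtype = "TRA", supporting_callers = "a,b",
               n_callers = sample(1:4, 1),
               best_split_reads = sample(1:10, 1),
               best_discordant_reads = sample(1:10, 1), n_members = 2,
               stringsAsFactors = FALSE)))
  out <- detect_ar_gsrs(cons, ar)
  if (nrow(out)) expect_true(all(out$in_ar_region))
})

test_that("ecDNA signature needs two AR-GSRs and a strict AR gain", {
  expect_true(flag_ecdna(2, 0.5))
  expect_false(flag_ecdna(1, 2.0))
  expect_false(flag_ecdna(3, 0.3))  # boundary value is not a gain
})

test_that("SV length is the breakend difference with TRA at -1", {
  svs <- rbind(sv_row("chr1", 100, "retains_left", "chr1", 600,
                      "retains_right", "DEL"),
               sv_row("chrX", 100, "retains_left", "chr7", 999,
                      "retains_right", "TRA"))
  expect_equal(sv_length(svs), c(500, -1))
})

test_that("SV VCF writing and reading round-trips symbolic and breakend records, dropping IMPRECISE", {
  svs <- rbind(
    sv_row("chr1", 1000, "retains_left", "chr1", 8000, "retains_right",
           "DEL", sr = 7, dr = 9),
    sv_row("chr2", 500, "retains_right", "chr2", 9000, "retains_left",
           "DUP", sr = 4, dr = 5),
    sv_row("chrX", 5000, "retains_left", "chr7", 4e6, "retains_right",
           "TRA", sr = 6, dr = 3))
  path <- withr::local_tempfile(fileext = ".vcf")
  write_sv_vcf(svs, path)
  back <- read_sv_vcf(path, "s1", "manta")
  back <- back[order(back$chrom1, back$pos1), ]
  svs_o <- svs[order(svs$chrom1, svs$pos1), ]
  expect_equal(back$pos1, svs_o$pos1)
  expect_equal(back$pos2, svs_o$pos2)
  expect_equal(back$svtype, svs_o$svtype)
  expect_equal(back$split_reads, svs_o$split_reads)
  expect_equal(back$discordant_reads, svs_o$discordant_reads)
  # IMPRECISE records are dropped at parse
  lines <- readLines(path)
  lines <- c(lines,
             "chr3\t100\tbad\tN\t<DEL>\t.\tPASS\tSVTYPE=DEL;END=900;IMPRECISE;SR=9;PE=9")
  writeLines(lines, path)
  back2 <- read_sv_vcf(path, "s1", "manta")
  expect_equal(nrow(back2), nrow(svs))
})
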