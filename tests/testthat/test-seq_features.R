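test_that("site sequences follow the -1 anchor and strand symmetry", {
  g <- Biostrings::DNAStringSet(c(chr1 = "AACGTTGCAA"))
  # + strand site at pos 4 (base T): window upstream=2, downstream=1
  sq <- site_sequence(g, tibble::tibble(contig = "chr1", strand = "+", pos = 4L), 2, 1)
  expect_equal(nchar(sq$seq), 4L)
  expect_equal(sq$offset, 3L) # the -1 base is the third character
  expect_equal(substr(sq$seq, sq$offset, sq$offset), "T")
  expect_equal(sq$seq, "CGTT")
  # - strand site at pos 5 (genomic T, coding base A): reverse complement
  sqm <- site_sequence(g, tibble::tibble(contig = "chr1", strand = "-", pos = 5L), 2, 1)
  expect_equal(sqm$seq, as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(substr("AACGTTGCAA", 5, 8)))))
  expect_equal(substr(sqm$seq, sqm$offset, sqm$offset), "A")
  # out-of-bounds windows error, or drop on request
  far <- tibble::tibble(contig = "chr1", strand = "+", pos = 1L)
  expect_error(site_sequence(g, far, 5, 1), "bounds")
  dropped <- site_sequence(g, far, 5, 1, on_oob = "drop")
  expect_equal(nrow(dropped), 0L)
  expect_equal(nrow(attr(dropped, "dropped")), 1L)
})

test_that("skew differences follow the formula with antisymmetry", {
  # with offset 30 the upstream window [-29,-10] is characters 2..21 and the
  # downstream window [+10,+29] is characters 40..59
  ch <- rep("T", 60)
  ch[2:21] <- "A"                       # upstream: no G/C/T... all A
  ch[40:59] <- c(rep("G", 6), rep("C", 14)) # downstream: 6 G, 14 C
  seq <- paste(ch, collapse = "")
  sk <- skew_diff_features(tibble::tibble(seq = seq, offset = 30L))
  gc <- function(w) {
    g <- stringr::str_count(w, "G"); c <- stringr::str_count(w, "C")
    if (g + c == 0) 0 else (g - c) / (g + c)
  }
  up <- substr(seq, 2, 21); dn <- substr(seq, 40, 59)
  expect_equal(sk$skew_diff_CG, (14 - 6) / 20 - 0)
  expect_equal(sk$skew_diff_GT, (6 - 0) / 6 - 0) # upstream has neither G nor T
  expect_equal(sk$skew_diff_AT, (0 - 0) - (20 - 0) / 20)
  # a 6 G / 2 C window has GC skew 0.5
  expect_equal(gc(paste0(strrep("G", 6), strrep("C", 2))), 0.5)
  # identical windows give zero differences; swapping pair order flips sign
  sym <- tibble::tibble(seq = strrep("ACGT", 15), offset = 30L)
  expect_true(all(abs(as.numeric(skew_diff_features(sym)[1, ])) < 1e-12))
})

test_that("nucleotide identities are one-hot at +1,-1,-2,-3,-10,-11", {
  seq <- paste0(strrep("A", 18), "G", "T", strrep("A", 6), "C", "C", "G", "T",
                strrep("A", 10))
  # offset 29 -> -1 base is char 29 ("G"), -2 char 28 ("C"), -3 char 27 ("C"),
  # +1 char 30 ("T"), -10 char 20 ("T"), -11 char 19 ("G")
  id <- nucleotide_identity_features(tibble::tibble(seq = seq, offset = 29L))
  expect_equal(ncol(id), 24L)
  expect_equal(id$nt_m1_G, 1); expect_equal(id$nt_m1_A, 0)
  expect_equal(id$nt_m2_C, 1)
  expect_equal(id$nt_m3_C, 1)
  expect_equal(id$nt_p1_T, 1)
  expect_equal(id$nt_m10_T, 1)
  expect_equal(id$nt_m11_G, 1)
  # exactly one flag per position
  for (tag in c("p1", "m1", "m2", "m3", "m10", "m11")) {
    expect_equal(sum(as.numeric(id[1, grepl(paste0("nt_", tag, "_"), names(id))])), 1)
  }
})

test_that("hybrid thermodynamics match a term-by-term summation oracle", {
  tp <- load_thermo_params()
  # homopolymer additivity
  gg <- hybrid_thermo_features(tibble::tibble(seq = strrep("G", 10), offset = 10L), tp)
  expect_equal(gg$hybrid_dH, tp$init_dH + 9 * unname(tp$dH["GG"]))
  expect_equal(gg$hybrid_dS, tp$init_dS + 9 * unname(tp$dS["GG"]))
  set.seed(8)
  for (i in 1:100) {
    dna <- paste(sample(c("A", "C", "G", "T"), 10, replace = TRUE), collapse = "")
    rna <- chartr("T", "U", dna)
    dimers <- substring(rna, 1:9, 2:10)
    dH <- tp$init_dH + sum(tp$dH[dimers])
    dS <- tp$init_dS + sum(tp$dS[dimers])
    got <- hybrid_thermo_features(tibble::tibble(seq = dna, offset = 10L), tp)
    expect_equal(got$hybrid_dH, dH, tolerance = 1e-12)
    expect_equal(got$hybrid_dG37, dH - 310.15 * dS / 1000, tolerance = 1e-12)
    expect_equal(got$hybrid_Tm, 1000 * dH / (dS + 1.987 * log(1e-4 / 4)),
                 tolerance = 1e-12)
  }
  # GC-rich hybrids melt higher than AT-rich ones
  at <- hybrid_thermo_features(tibble::tibble(seq = strrep("AT", 5), offset = 10L), tp)
  gc <- hybrid_thermo_features(tibble::tibble(seq = strrep("GC", 5), offset = 10L), tp)
  expect_gt(gc$hybrid_Tm, at$hybrid_Tm)
})

test_that("builtin folding energy equals exhaustive structure enumeration", {
  expect_equal(nascent_mfe("AAAAAAAAAAAAAAAAAAA"), 0, ignore_attr = TRUE)
  hp <- paste0(strrep("G", 8), "AAA", strrep("C", 8))
  expect_lt(nascent_mfe(hp)[1], 0)
  set.seed(21)
  for (i in 1:25) {
    s <- paste(sample(c("A", "C", "G", "U"), sample(8:12, 1), replace = TRUE),
               collapse = "")
    expect_equal(as.numeric(nascent_mfe(s)), enumerate_mfe(s),
                 label = sprintf("mfe(%s)", s))
  }
})

test_that("shape summaries respond correctly to constant and ramp tables", {
  cfg <- sim_config(seed = 2)
  const <- simulate_feature_resources(cfg, shape_mode = "constant")$shape
  seqs <- tibble::tibble(seq = strrep("ACGT", 20), offset = 40L)
  sf <- shape_features(seqs, const)
  expect_equal(ncol(sf), 25L)
  expect_equal(sf$shape_MGW_min, 1); expect_equal(sf$shape_MGW_span, 0)
  expect_equal(sf$shape_MGW_deriv, 0)
  # value = G count: poly-G forces every stat
  ramp <- simulate_feature_resources(cfg, shape_mode = "gc_ramp")$shape
  gf <- shape_features(tibble::tibble(seq = strrep("G", 80), offset = 40L), ramp)
  expect_equal(gf$shape_EP_mean, 5); expect_equal(gf$shape_EP_span, 0)
  # missing pentamer errors loudly
  bad <- const[-1, ]
  expect_error(load_shape_table(withr::local_tempfile(fileext = ".tsv")))
  expect_error(shape_features(tibble::tibble(seq = strrep("A", 80), offset = 40L),
                              dplyr::filter(const, pentamer != "AAAAA")),
               "missing")
})

test_that("PWM thresholds match exhaustive score enumeration; planted motifs flag", {
  set.seed(5)
  for (w in c(4, 6, 8)) {
    m <- matrix(stats::rgamma(4 * w, 1), 4, w,
                dimnames = list(c("A", "C", "G", "T"), NULL))
    m <- sweep(m, 2, colSums(m), "/")
    thr <- polpause:::pwm_score_threshold(m, p_threshold = 0.01)
    sc <- log2(m / 0.25)
    words <- as.matrix(do.call(expand.grid, rep(list(1:4), w)))
    scores <- rowSums(matrix(sc[cbind(as.vector(words), rep(1:w, each = 4^w))],
                             ncol = w))
    uniq <- sort(unique(round(scores, 9)))
    attain <- uniq[vapply(uniq, function(s) mean(scores >= s - 1e-9) <= 0.01, TRUE)]
    oracle <- if (length(attain) == 0) Inf else min(attain)
    expect_equal(thr, oracle, tolerance = 1e-6, label = sprintf("width %d", w))
  }
  # planted consensus in the footprint region is flagged; absent motif is not
  cfg <- sim_config(seed = 2)
  res <- simulate_feature_resources(cfg, consensus = "TATAATTACG")
  base <- strrep("ACGT", 80) # 320 nt, no TATAATTACG anywhere
  planted <- paste0(substr(base, 1, 140), "TATAATTACG", substr(base, 151, 320))
  seqs <- tibble::tibble(seq = c(planted, base), offset = 160L)
  flags <- pwm_scan_presence(seqs, tf_pwms = res$pwms["planted"],
                             rbp_pwms = res$pwms["planted"])
  expect_equal(flags$tf_planted_footprint, c(1, 0))
  expect_equal(ncol(flags), 4L) # 3 TF regions + 1 RBP flag
})

test_that("methylation and interval-overlap features honor their windows", {
  meth <- tibble::tibble(contig = "chr1", pos = c(100L, 150L, 400L),
                         level = c(1, 0, 0.5))
  sites <- tibble::tibble(contig = "chr1", pos = c(120L, 400L, 900L))
  mf <- methylation_feature(meth, sites)
  expect_equal(mf$meth_mean, c(0.5, 0.5, 0))
  expect_equal(mf$meth_covered, c(1, 1, 0))
  iv <- list(zdna = tibble::tibble(contig = "chr1", start = 200L, end = 220L))
  ov <- interval_overlap_features(tibble::tibble(contig = "chr1", pos = c(100L, 99L, 320L)), iv)
  expect_equal(ov$nonb_zdna, c(1, 0, 0)) # 100+100 touches start 200; 99 does not; 320-100 > end-1
})

test_that("enrichment logos are near zero for fg = bg and spike at planted bases", {
  g <- fixture_genome(len = 20000L)
  set.seed(6)
  pos <- sample(200:19800, 400)
  sites <- tibble::tibble(contig = "chr1", strand = "+", pos = as.integer(pos))
  lg <- enrichment_logo(sites, sites, g, halfwidth = 10)
  expect_true(all(abs(lg) < 1e-12))
  # force G at the pause base of the foreground
  gseq <- strsplit(as.character(g[["chr1"]]), "")[[1]]
  fg <- sites[gseq[sites$pos + 1] == "G", ]
  lg2 <- enrichment_logo(fg, sites, g, halfwidth = 10)
  expect_equal(unname(which.max(lg2["G", ])), which(colnames(lg2) == "-1"))
  expect_error(enrichment_logo(sites[0, ], sites, g), "empty")
})

test_that("the feature matrix assembles the universal block with drops recorded", {
  g <- fixture_genome(len = 5000L)
  pauses <- tibble::tibble(contig = "chr1", strand = c("+", "-", "+"),
                           pos = c(500L, 1500L, 10L)) # third is out of bounds
  ctrl <- tibble::tibble(contig = "chr1", strand = "+", pos = c(800L, 1800L))
  fm <- build_feature_matrix(pauses, ctrl, g)
  expect_equal(ncol(fm) - 2L, 35L) # skew 6 + identity 24 + thermo 4 + mfe 1
  expect_equal(nrow(fm), 4L)
  expect_equal(length(attr(fm, "dropped")), 1L)
  expect_equal(sum(fm$label == "pause"), 2L)
  # recomputation is bit-identical
  expect_identical(tibble::as_tibble(build_feature_matrix(pauses, ctrl, g)),
                   tibble::as_tibble(fm))
  # strand symmetry: a minus-strand site equals its reverse-complement
  # plus-strand construction
  rc <- Biostrings::reverseComplement(g)
  names(rc) <- "chr1"
  fm_rc <- build_feature_matrix(
    tibble::tibble(contig = "chr1", strand = "+", pos = 5000L - 1L - 1500L),
    ctrl, rc)
  m_cols <- setdiff(names(fm), c("site_id", "label"))
  expect_equal(as.numeric(fm[fm$site_id == "chr1:1500:-", m_cols]),
               as.numeric(fm_rc[1, m_cols]))
})
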