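test_that("the 20-case classification rule table is reproduced exactly", {
  ann <- fixture_annotation()
  cases <- tibble::tribble(
    ~strand, ~pos,   ~category,           ~subclass,
    "+",     1200L,  "promoter-proximal", "none",          # 200 nt past TSS 1000
    "+",     1300L,  "promoter-proximal", "none",          # inclusive +300 edge
    "+",     1650L,  "promoter-proximal", "none",          # via second TSS 1600
    "+",     1301L,  "gene-body",         "exonic",        # 301 past TSS1000, 299 before TSS1600? no: upstream of it
    "+",     1400L,  "gene-body",         "exonic",        # between promoter windows
    "+",     2500L,  "gene-body",         "intronic",      # inside intron [2000,3000)
    "+",     3500L,  "gene-body",         "exonic",
    "+",     4999L,  "gene-body",         "exonic",        # the 3'-most pA itself
    "-",     700L,   "antisense",         "divergent",     # upstream of gA TSS
    "-",     3000L,  "antisense",         "convergent",    # over gA body
    "-",     1L,     "antisense",         "divergent",     # deep in the 1 kb flank
    "+",     8501L,  "antisense",         "convergent",    # opposite gB
    "+",     12400L, "antisense",         "divergent",     # upstream of gB's TSS (minus-strand gene)
    "+",     5000L,  "intergenic",        "termination-zone",  # 1 nt past gA pA
    "+",     7999L,  "intergenic",        "termination-zone",
    "+",     19499L, "intergenic",        "termination-zone",  # 3500 nt past gD pA
    "+",     19500L, "intergenic",        "other-intergenic",  # 3501 nt: outside
    "-",     19100L, "intergenic",        "enhancer",
    "+",     12900L, "undetermined",      "undetermined",  # gC body vs gB antisense
    "-",     13800L, "antisense",         "undetermined")  # divergent gD + convergent gC
  got <- classify_pauses(dplyr::mutate(cases, contig = "chr1"), ann)
  expect_equal(got$category, cases$category)
  expect_equal(got$subclass, cases$subclass)
  # promoter-proximal takes precedence over the antisense overlap
  pp <- classify_pauses(tibble::tibble(contig = "chr1", strand = "+", pos = 12600L), ann)
  expect_equal(pp$category, "promoter-proximal")
  # every site receives exactly one category
  expect_equal(nrow(got), 20L)
  expect_false(any(is.na(got$category)))
  # classification is independent of gene order in the annotation
  ann2 <- ann
  ord <- c(3, 1, 4, 2)
  ann2$genes <- ann2$genes[ord, ]
  got2 <- classify_pauses(dplyr::mutate(cases, contig = "chr1"), ann2)
  expect_equal(got2$category, got$category)
  expect_equal(got2$subclass, got$subclass)
  # out-of-bounds site errors
  expect_error(classify_pauses(
    tibble::tibble(contig = "chr1", strand = "+", pos = 200000L), ann), "bounds")
})

test_that("splice proximity labels boundaries within 40 nt, all matches kept", {
  ann <- genome_annotation(
    genes = tibble::tibble(gene_id = c("gS", "gM"), contig = "chr1",
                           strand = c("+", "-"),
                           start = c(1000L, 5000L), end = c(4000L, 7000L)),
    exons = tibble::tibble(
      gene_id = c("gS", "gS", "gS", "gM", "gM"), contig = "chr1",
      strand = c("+", "+", "+", "-", "-"),
      start = c(1000L, 2100L, 3000L, 5000L, 6500L),
      end = c(2000L, 2180L, 4000L, 6000L, 7000L)),
    tss = tibble::tibble(gene_id = c("gS", "gM"), pos = c(1000L, 6999L)),
    pa = tibble::tibble(gene_id = c("gS", "gM"), pos = c(3999L, 5000L)),
    contig_lengths = c(chr1 = 100000L))
  site <- function(pos, gid, strand = "+") {
    tibble::tibble(contig = "chr1", strand = strand, pos = pos, gene_id = gid)
  }
  lab <- function(x) sort(strsplit(x$splice_labels, ",")[[1]])
  # first donor at 1999: 40 nt is proximal, 41 nt is distal
  expect_equal(lab(splice_proximity(site(2039L, "gS"), ann)), "first exon-intron")
  expect_equal(lab(splice_proximity(site(2040L, "gS"), ann)), "distal")
  # short middle exon: within 40 of both its acceptor (2100) and donor (2179)
  both <- lab(splice_proximity(site(2140L, "gS"), ann))
  expect_setequal(both, c("exon-intron", "intron-exon"))
  # acceptor of the last exon
  expect_equal(lab(splice_proximity(site(3010L, "gS"), ann)), "last intron-exon")
  # minus strand: first exon in transcription order is the rightmost
  expect_equal(lab(splice_proximity(site(6520L, "gM", "-"), ann)), "first exon-intron")
  # single-exon genes have no junctions
  expect_equal(lab(splice_proximity(site(2140L, NA_character_), ann)), "distal")
})

test_that("non-pausing controls stay in the stated flanks and are reproducible", {
  ann <- fixture_annotation()
  pauses <- classify_pauses(tibble::tibble(
    contig = "chr1", strand = "+", pos = c(1200L, 3500L)), ann)
  ctrl <- sample_nonpausing(pauses, ann, seed = 3)
  expect_equal(nrow(ctrl), 2L)
  d1 <- abs(ctrl$pos[1] - 1200L) # promoter-proximal: x = 50
  expect_true(d1 >= 50 && d1 <= 70)
  d2 <- abs(ctrl$pos[2] - 3500L) # gene-body: x = 300
  expect_true(d2 >= 300 && d2 <= 320)
  expect_identical(sample_nonpausing(pauses, ann, seed = 3), ctrl)
  # controls never land on a pause position
  many <- classify_pauses(tibble::tibble(
    contig = "chr1", strand = "+", pos = seq(3000L, 4600L, by = 10L)), ann)
  c2 <- sample_nonpausing(many, ann, seed = 5)
  expect_false(any(paste(c2$contig, c2$pos) %in% paste(many$contig, many$pos)))
})

test_that("active gene calls use a strict TPM cutoff", {
  expr <- tibble::tibble(gene_id = c("a", "b", "c"), tpm = c(1.0, 1.01, 0))
  expect_equal(active_genes(expr), "b")
  expect_equal(active_genes(expr[0, ]), character(0))
})

test_that("average pausing distance is the mean consecutive gap", {
  ann <- fixture_annotation()
  pauses <- tibble::tibble(contig = "chr1", strand = "+",
                           pos = c(4000L, 2000L, 1000L), gene_id = "gA")
  d <- average_pause_distance(pauses, ann)
  expect_equal(d$mean_distance, 1500)
  expect_equal(d$n_pauses, 3L)
  # order invariance and the two-point case
  two <- tibble::tibble(contig = "chr1", strand = "+",
                        pos = c(1246L, 1100L), gene_id = "gA")
  expect_equal(average_pause_distance(two, ann)$mean_distance, 146)
  # genes with fewer than 2 pauses are absent
  one <- tibble::tibble(contig = "chr1", strand = "+", pos = 1100L, gene_id = "gA")
  expect_equal(nrow(average_pause_distance(one, ann)), 0L)
})

test_that("pausing-intensity comparison runs a one-sided Welch test across genes", {
  mk <- function(gb_shift) {
    g <- sprintf("g%02d", 1:10)
    dplyr::bind_rows(
      tibble::tibble(gene_id = g, category = "promoter-proximal",
                     count = 10 + seq(0, 4.5, by = 0.5)),
      tibble::tibble(gene_id = g, category = "gene-body",
                     count = 10 + seq(0, 4.5, by = 0.5) + gb_shift))
  }
  expect_equal(compare_intensities(mk(0))$p_value, 0.5, tolerance = 1e-9)
  expect_lt(compare_intensities(mk(5))$p_value, 0.05)
  one <- mk(0)[c(1, 11), ]
  expect_error(compare_intensities(one[one$gene_id == "g01", ]), ">= 2 genes")
})

test_that("site signal density averages windows strand-aware", {
  ones <- make_track(0:999, 1L, contig_lengths = c(chr1 = 100000L))
  s <- tibble::tibble(contig = "chr1", strand = "+", pos = 500L)
  expect_equal(site_signal_density(ones, s, "upstream_only", 200L)$density, 1)
  expect_equal(site_signal_density(ones, s, "centered", 20L)$density, 1)
  empty <- make_track(integer(0), integer(0))
  expect_equal(site_signal_density(empty, s, "centered", 20L)$density, 0)
  # upstream orientation: + strand site at 300 with signal only in [100, 300)
  up <- make_track(100:299, 2L)
  s2 <- tibble::tibble(contig = "chr1", strand = c("+", "-"), pos = 300L)
  d <- site_signal_density(up, s2, "upstream_only", 200L, stranded = FALSE)
  expect_equal(d$density, c(2, 0)) # minus-strand upstream is (300, 500]
  # replicate tracks are averaged
  both <- site_signal_density(list(ones, make_track(0:999, 3L)), s,
                              "centered", 20L)
  expect_equal(both$density, 2)
})

test_that("premature termination flags densities above the pA 25th percentile", {
  pa <- c(0, 1, 2, 3, 4)
  expect_equal(premature_termination_calls(c(1, 1.01, 0.5, 5), pa),
               c(FALSE, TRUE, FALSE, TRUE)) # quantile = 1, strict >
  expect_equal(premature_termination_calls(c(0, 0), c(1, 2, 3)), c(FALSE, FALSE))
  expect_error(premature_termination_calls(1, numeric(0)), "empty")
})
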