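# Shared in-code fixtures: a tiny deterministic genome, a hand-built
# annotation covering every classification rule, and small track builders.

fixture_genome <- function(len = 5000L, seed = 101L, contig = "chr1") {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  g <- Biostrings::DNAStringSet(paste(
    sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""))
  names(g) <- contig
  g
}

make_track <- function(pos, count, strand = "+", contig = "chr1",
                       contig_lengths = c(chr1 = 100000L)) {
  occupancy_track(tibble::tibble(contig = contig, strand = strand,
                                 pos = as.integer(pos),
                                 count = as.integer(count)),
                  contig_lengths)
}

make_reads <- function(end3, strand = "+", umi = NULL, contig = "chr1") {
  n <- length(end3)
  tibble::tibble(contig = contig, end3 = as.integer(end3),
                 strand = rep_len(strand, n),
                 umi = umi %||% strrep("A", 10),
                 read_id = sprintf("rd%04d", seq_len(n)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# annotation fixture used by the classification rule table:
#   gA: + strand [1000, 5000), TSSs 1000 & 1600, pA 4500 & 4999,
#       exons [1000,2000) [3000,5000) (intron [2000,3000))
#   gB: - strand [8000, 12000), TSS 11999, pA 8000, single exon;
#       its antisense region covers plus-strand positions [8000, 12999]
#   gC: + strand [12500, 14000); its gene-body overlaps gB's antisense
#       region (category-undetermined conflict)
#   gD: + strand [14500, 16000); its antisense region [13500, 15999]
#       overlaps gC's ([11500, 13999]) so a minus-strand site near 13800 is
#       divergent for gD and convergent for gC (subclass undetermined)
#   enhancer [19000, 19200)
fixture_annotation <- function() {
  genome_annotation(
    genes = tibble::tibble(
      gene_id = c("gA", "gB", "gC", "gD"), contig = "chr1",
      strand = c("+", "-", "+", "+"),
      start = c(1000L, 8000L, 12500L, 14500L),
      end = c(5000L, 12000L, 14000L, 16000L)),
    exons = tibble::tibble(
      gene_id = c("gA", "gA", "gB", "gC", "gD"), contig = "chr1",
      strand = c("+", "+", "-", "+", "+"),
      start = c(1000L, 3000L, 8000L, 12500L, 14500L),
      end = c(2000L, 5000L, 12000L, 14000L, 16000L)),
    tss = tibble::tibble(gene_id = c("gA", "gA", "gB", "gC", "gD"),
                         pos = c(1000L, 1600L, 11999L, 12500L, 14500L)),
    pa = tibble::tibble(gene_id = c("gA", "gA", "gB", "gC", "gD"),
                        pos = c(4500L, 4999L, 8000L, 13999L, 15999L)),
    enhancers = tibble::tibble(contig = "chr1", start = 19000L, end = 19200L),
    contig_lengths = c(chr1 = 100000L))
}

# brute-force oracle: exact P(max >= k) for M reads over l cells by full
# enumeration of the l^M equally likely assignments
enumerate_max_tail <- function(M, l, k) {
  if (M == 0) return(as.numeric(k <= 0))
  grid <- do.call(expand.grid, rep(list(seq_len(l)), M))
  maxs <- apply(grid, 1, function(a) max(tabulate(a, nbins = l)))
  mean(maxs >= k)
}

# brute-force oracle: two-sided Fisher p by explicit hypergeometric sums
enumerate_fisher_p <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  if (r1 == 0 || c1 == 0 || r1 == n || c1 == n) return(1)
  supp <- max(0, r1 + c1 - n):min(r1, c1)
  pr <- vapply(supp, function(a) {
    choose(c1, a) * choose(n - c1, r1 - a) / choose(n, r1)
  }, 0)
  p0 <- pr[supp == tab[1, 1]]
  sum(pr[pr <= p0 * (1 + 1e-07)])
}

# brute-force oracle: minimum folding energy by exhaustive enumeration of
# all pseudoknot-free structures (interval recursion) under the package's
# stacking-only model
enumerate_mfe <- function(seq) {
  b <- strsplit(chartr("T", "U", seq), "")[[1]]
  n <- length(b)
  strength <- c(GC = 3, CG = 3, AU = 2, UA = 2, GU = 1, UG = 1)
  pairable <- function(i, j) paste0(b[i], b[j]) %in% names(strength)
  structs <- function(i, j) {
    if (j - i < 4) return(list(list()))
    out <- structs(i + 1, j) # i unpaired
    for (k in (i + 4):j) {
      if (!pairable(i, k)) next
      for (L in structs(i + 1, k - 1)) for (R in if (k + 1 <= j) structs(k + 1, j) else list(list())) {
        out[[length(out) + 1]] <- c(list(c(i, k)), L, R)
      }
    }
    out
  }
  energy <- function(pairs) {
    if (length(pairs) < 2) return(0)
    pm <- do.call(rbind, pairs)
    e <- 0
    for (r in seq_len(nrow(pm))) {
      if (any(pm[, 1] == pm[r, 1] + 1 & pm[, 2] == pm[r, 2] - 1)) {
        e <- e - (strength[paste0(b[pm[r, 1]], b[pm[r, 2]])] +
                    strength[paste0(b[pm[r, 1] + 1], b[pm[r, 2] - 1])]) / 2
      }
    }
    unname(e)
  }
  min(vapply(structs(1, n), energy, 0))
}

# separable synthetic feature matrix for model tests: `signal` features
# shifted between classes
make_feature_matrix <- function(n = 600L, p = 40L, signal = 5L, shift = 1.5,
                                seed = 1L) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  x <- matrix(stats::rnorm(n * p), n, p,
              dimnames = list(NULL, sprintf("f%02d", seq_len(p))))
  lab <- rep(c("pause", "non-pause"), length.out = n)
  if (signal > 0) x[lab == "pause", seq_len(signal)] <-
    x[lab == "pause", seq_len(signal)] + shift
  fm <- tibble::as_tibble(x)
  fm$site_id <- as.character(seq_len(n))
  fm$label <- lab
  fm[, c("site_id", "label", sprintf("f%02d", seq_len(p)))]
}
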