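#' Extract site-anchored sequences in the pause coordinate frame
#'
#' Sequences are reported on the coding (non-template) strand, 5' to 3' in
#' transcription direction; minus-strand sites are reverse-complemented.
#' The coordinate frame is anchored on the called pause base, which is
#' relative position **-1** — the last nucleotide added to the nascent RNA.
#' Position +1 is the next base in transcription direction (the incoming-NTP
#' site); negative positions extend upstream; there is no position 0. The
#' RNA-DNA hybrid spans -10..-1.
#'
#' A window of `upstream` extra bases plus the site base plus `downstream`
#' bases therefore covers relative positions `-(upstream+1) .. -1, +1 ..
#' +downstream` and has length `upstream + downstream + 1`.
#'
#' @param genome A [Biostrings::DNAStringSet].
#' @param sites Tibble with `contig`, `strand`, `pos` (0-based genomic
#'   position of the pause base).
#' @param upstream,downstream Bases beyond the site base on each side.
#' @param on_oob `"error"` (default) or `"drop"` for windows leaving the
#'   contig.
#' @return `sites` with `seq` and `offset` columns; `offset` is the 1-based
#'   string index of the site (-1) base. Dropped rows are listed in the
#'   `dropped` attribute when `on_oob = "drop"`.
#' @export
site_sequence <- function(genome, sites, upstream, downstream,
                          on_oob = c("error", "drop")) {
  on_oob <- match.arg(on_oob)
  genome <- as(genome, "DNAStringSet")
  sites <- as_tibble(sites)
  lens <- setNames(Biostrings::width(genome), names(genome))
  plus <- sites$strand == "+"
  g_lo <- ifelse(plus, sites$pos - upstream, sites$pos - downstream)
  g_hi <- ifelse(plus, sites$pos + downstream, sites$pos + upstream)
  ok <- g_lo >= 0 & g_hi < lens[sites$contig] & !is.na(lens[sites$contig])
  if (!all(ok)) {
    if (on_oob == "error") abort("sequence window exceeds contig bounds")
    dropped <- sites[!ok, ]
    sites <- sites[ok, ]
    g_lo <- g_lo[ok]; g_hi <- g_hi[ok]; plus <- plus[ok]
  } else dropped <- sites[0, ]
  if (nrow(sites) == 0) {
    sites$seq <- character(0); sites$offset <- integer(0)
    attr(sites, "dropped") <- dropped
    return(sites)
  }
  raw <- Biostrings::subseq(genome[sites$contig], start = g_lo + 1L, end = g_hi + 1L)
  if (any(!plus)) raw[!plus] <- Biostrings::reverseComplement(raw[!plus])
  sites$seq <- unname(as.character(raw))
  sites$offset <- upstream + 1L
  attr(sites, "dropped") <- dropped
  sites
}

# 1-based string index of relative position r (no position 0)
rel_index <- function(offset, r) {
  stopifnot(all(r != 0))
  offset + ifelse(r < 0, r + 1L, r)
}

# substring of the relative range [from, to] (both nonzero, from < to)
rel_slice <- function(seq, offset, from, to) {
  substr(seq, rel_index(offset, from), rel_index(offset, to))
}

base_counts <- function(seqs) {
  m <- sapply(c("A", "C", "G", "T"), function(b)
    stringr::str_count(seqs, stringr::fixed(b)))
  if (is.null(dim(m))) m <- matrix(m, nrow = 1, dimnames = list(NULL, c("A", "C", "G", "T")))
  m
}

#' Nucleotide skew differences around a site
#'
#' For each unordered nucleotide pair `{X, Y}`, the XY skew of a window is
#' `(|X| - |Y|) / (|X| + |Y|)` (0 when the window contains neither base).
#' The feature is the downstream-window skew minus the upstream-window skew,
#' using the 20-nt windows whose near edges sit 10 nt from the site:
#' upstream relative positions `[-29, -10]`, downstream `[+10, +29]`. An
#' alternative placement with windows abutting the site (`[-20, -1]` /
#' `[+1, +20]`) is available via `placement = "adjacent"`.
#'
#' @param seqs Output of [site_sequence()] spanning at least `[-29, +29]`.
#' @param placement `"offset10"` (default) or `"adjacent"`.
#' @return Tibble of 6 columns `skew_diff_AC` .. `skew_diff_GT`.
#' @export
skew_diff_features <- function(seqs, placement = c("offset10", "adjacent")) {
  placement <- match.arg(placement)
  win <- if (placement == "offset10") list(up = c(-29, -10), down = c(10, 29))
  else list(up = c(-20, -1), down = c(1, 20))
  if (any(seqs$offset < 29) || any(nchar(seqs$seq) - seqs$offset < 29)) {
    abort("sequences must span relative positions [-29, +29]")
  }
  up <- base_counts(rel_slice(seqs$seq, seqs$offset, win$up[1], win$up[2]))
  dn <- base_counts(rel_slice(seqs$seq, seqs$offset, win$down[1], win$down[2]))
  pairs <- list(c("A", "C"), c("A", "G"), c("A", "T"),
                c("C", "G"), c("C", "T"), c("G", "T"))
  skew <- function(m, x, y) {
    s <- m[, x] + m[, y]
    unname(ifelse(s == 0, 0, (m[, x] - m[, y]) / s))
  }
  out <- lapply(pairs, function(pr) skew(dn, pr[1], pr[2]) - skew(up, pr[1], pr[2]))
  names(out) <- vapply(pairs, function(pr) paste0("skew_diff_", pr[1], pr[2]), "")
  as_tibble(out)
}

#' One-hot nucleotide identities at mechanistically salient positions
#'
#' The identities at +1 (incoming NTP site), -1, -2, -3 (active center) and
#' -10, -11 (upstream end of the RNA-DNA hybrid), one-hot encoded over
#' A/C/G/T (24 binary features). Sequences with an ambiguous base at any of
#' these positions yield `NA` flags (callers drop such sites).
#'
#' @param seqs Output of [site_sequence()] spanning at least `[-11, +1]`.
#' @return Tibble of 24 columns named `nt_p1_A`, `nt_m1_A`, ...
#' @export
nucleotide_identity_features <- function(seqs) {
  pos <- c(1, -1, -2, -3, -10, -11)
  out <- list()
  for (r in pos) {
    b <- substr(seqs$seq, rel_index(seqs$offset, r), rel_index(seqs$offset, r))
    tag <- paste0("nt_", ifelse(r > 0, "p", "m"), abs(r))
    for (base in c("A", "C", "G", "T")) {
      v <- as.numeric(b == base)
      v[!b %in% c("A", "C", "G", "T")] <- NA_real_
      out[[paste0(tag, "_", base)]] <- v
    }
  }
  as_tibble(out)
}

#' Position-wise sequence enrichment matrix (logo)
#'
#' Per relative position and base, `log2((fg frequency + eps) / (bg
#' frequency + eps))` between pause-site sequences and matched background
#' sequences, both extracted `halfwidth` bases either side of the site base.
#'
#' @param fg_sites,bg_sites Site tibbles (`contig`, `strand`, `pos`).
#' @param genome A [Biostrings::DNAStringSet].
#' @param halfwidth Bases either side of the site base.
#' @param eps Frequency pseudocount (default 0.01).
#' @return An `enrichment_logo`: 4 x (2*halfwidth+1) matrix, rows A/C/G/T,
#'   columns labelled with relative positions.
#' @export
enrichment_logo <- function(fg_sites, bg_sites, genome, halfwidth = 15L,
                            eps = 0.01) {
  if (nrow(fg_sites) == 0 || nrow(bg_sites) == 0) abort("empty site set")
  freq <- function(sites) {
    sq <- site_sequence(genome, sites, halfwidth, halfwidth, on_oob = "drop")
    if (nrow(sq) == 0) abort("no usable sequences")
    m <- do.call(rbind, strsplit(sq$seq, ""))
    apply(m, 2, function(col) {
      tab <- table(factor(col, levels = c("A", "C", "G", "T")))
      as.numeric(tab) / sum(tab)
    })
  }
  f <- freq(fg_sites)
  b <- freq(bg_sites)
  mat <- log2((f + eps) / (b + eps))
  rownames(mat) <- c("A", "C", "G", "T")
  colnames(mat) <- c(seq(-(halfwidth + 1L), -1L), seq(1L, halfwidth))
  structure(mat, class = c("enrichment_logo", "matrix"))
}
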