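#' Read position weight matrices (JASPAR pfm / MEME-minimal style)
#'
#' Accepts the JASPAR pfm layout — a `>name` header followed by four rows of
#' counts, with or without `A [ ... ]` brackets — and normalises each column
#' to probabilities with a small pseudocount.
#'
#' @param path Motif file.
#' @param pseudocount Added to every count before normalising (default 0.01).
#' @return A named list of 4 x width probability matrices (rows A, C, G, T),
#'   class `pwm_set`.
#' @export
read_pwms <- function(path, pseudocount = 0.01) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  heads <- grep("^>", lines)
  if (length(heads) == 0) abort("no '>' motif headers found")
  out <- list()
  bounds <- c(heads, length(lines) + 1)
  for (i in seq_along(heads)) {
    name <- sub("^>\\s*", "", lines[heads[i]])
    name <- strsplit(name, "\\s+")[[1]][1]
    body <- lines[(heads[i] + 1):(bounds[i + 1] - 1)]
    if (length(body) < 4) abort(sprintf("motif %s: expected 4 base rows", name))
    rows <- lapply(body[1:4], function(x) {
      x <- gsub("^[ACGTUacgtu]\\s*\\[?|\\]$", "", x)
      as.numeric(strsplit(trimws(x), "\\s+")[[1]])
    })
    w <- unique(lengths(rows))
    if (length(w) != 1) abort(sprintf("motif %s: ragged rows", name))
    m <- do.call(rbind, rows) + pseudocount
    m <- sweep(m, 2, colSums(m), "/")
    rownames(m) <- c("A", "C", "G", "T")
    out[[name]] <- m
  }
  structure(out, class = "pwm_set")
}

# exact null distribution of the log2-odds score over background base
# probabilities, by dynamic programming over columns (scores aggregated at
# 1e-9 resolution); returns the lowest score whose exceedance probability
# is <= p_threshold (Inf when unattainable)
pwm_score_threshold <- function(pwm, background = rep(0.25, 4),
                                p_threshold = 1e-4) {
  s <- log2(pwm / background)
  dist <- c(`0` = 1) # named by score value
  for (j in seq_len(ncol(s))) {
    keys <- as.numeric(names(dist))
    new_keys <- round(outer(keys, s[, j], "+"), 9)
    new_p <- outer(unname(dist), background, "*")
    dist <- tapply(as.vector(new_p), as.vector(new_keys), sum)
  }
  keys <- as.numeric(names(dist))
  ord <- order(keys, decreasing = TRUE)
  tail_p <- cumsum(dist[ord])
  ok <- which(tail_p <= p_threshold + 1e-12)
  if (length(ok) == 0) return(Inf)
  keys[ord][max(ok)]
}

pwm_scan_scores <- function(seq, pwm) {
  w <- ncol(pwm)
  n <- nchar(seq)
  if (n < w) return(numeric(0))
  b <- strsplit(seq, "")[[1]]
  idx <- match(b, c("A", "C", "G", "T"))
  sc <- log2(pwm / 0.25)
  vapply(seq_len(n - w + 1), function(p) {
    ii <- idx[p:(p + w - 1)]
    if (anyNA(ii)) return(-Inf)
    sum(sc[cbind(ii, seq_len(w))])
  }, 0)
}

revcomp_chr <- function(x) {
  vapply(x, function(s) {
    chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  }, "", USE.NAMES = FALSE)
}

#' Motif presence flags around genomic sites
#'
#' Scans three site-anchored regions with log2-odds position weight matrix
#' scores against a uniform background: the polymerase footprint (relative
#' positions `[-26, +25]`, i.e. 25 nt either side of the site base), the
#' 100-nt region upstream of the footprint (`[-126, -27]`) and the 100-nt
#' region downstream (`[+26, +125]`). The hit threshold per motif is set
#' from the exact null score distribution (dynamic program over the
#' background) at tail mass `p_threshold`. Transcription-factor motifs are
#' matched on either strand in all three regions; RNA-binding-protein
#' motifs only on the nascent-RNA-equivalent (coding) strand and only in
#' the upstream region, the stretch already transcribed into RNA.
#'
#' @param seqs Output of [site_sequence()] spanning at least
#'   `[-126, +125]`.
#' @param tf_pwms,rbp_pwms `pwm_set` objects (either may be `NULL`).
#' @param p_threshold Null exceedance probability per position
#'   (default 1e-4).
#' @return Tibble of 0/1 flags `tf_<name>_footprint`, `tf_<name>_upstream`,
#'   `tf_<name>_downstream`, `rbp_<name>`.
#' @export
pwm_scan_presence <- function(seqs, tf_pwms = NULL, rbp_pwms = NULL,
                              p_threshold = 1e-4) {
  regions <- list(footprint = c(-26, 25), upstream = c(-126, -27),
                  downstream = c(26, 125))
  out <- list()
  get_region <- function(reg) rel_slice(seqs$seq, seqs$offset, reg[1], reg[2])
  scan_flags <- function(pwm, region_seqs, thr, both_strands) {
    vapply(region_seqs, function(s) {
      if (nchar(s) < ncol(pwm)) {
        warn("region shorter than motif; flag set to 0")
        return(0)
      }
      hit <- any(pwm_scan_scores(s, pwm) >= thr)
      if (!hit && both_strands) hit <- any(pwm_scan_scores(revcomp_chr(s), pwm) >= thr)
      as.numeric(hit)
    }, 0, USE.NAMES = FALSE)
  }
  for (nm in names(tf_pwms)) {
    thr <- pwm_score_threshold(tf_pwms[[nm]], p_threshold = p_threshold)
    for (rg in names(regions)) {
      out[[paste0("tf_", nm, "_", rg)]] <-
        scan_flags(tf_pwms[[nm]], get_region(regions[[rg]]), thr, TRUE)
    }
  }
  for (nm in names(rbp_pwms)) {
    thr <- pwm_score_threshold(rbp_pwms[[nm]], p_threshold = p_threshold)
    out[[paste0("rbp_", nm)]] <-
      scan_flags(rbp_pwms[[nm]], get_region(regions$upstream), thr, FALSE)
  }
  as_tibble(out)
}
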