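#' Mean DNA methylation around sites
#'
#' Mean methylation level over covered CpG positions within `radius`
#' nucleotides of each site (`[pos - radius, pos + radius]`); sites with no
#' covered position get 0 and a coverage flag of 0.
#'
#' @param meth Tibble `contig`, `pos`, `level` with levels in `[0, 1]`.
#' @param sites Site tibble (`contig`, `pos`).
#' @param radius Window half-width (default 100).
#' @return Tibble `meth_mean`, `meth_covered`.
#' @export
methylation_feature <- function(meth, sites, radius = 100L) {
  meth <- as_tibble(meth)
  stopifnot(all(meth$level >= 0 & meth$level <= 1))
  sites <- as_tibble(sites)
  mm <- numeric(nrow(sites)); cov <- numeric(nrow(sites))
  for (i in seq_len(nrow(sites))) {
    sel <- meth$contig == sites$contig[i] &
      abs(meth$pos - sites$pos[i]) <= radius
    if (any(sel)) { mm[i] <- mean(meth$level[sel]); cov[i] <- 1 }
  }
  tibble(meth_mean = mm, meth_covered = cov)
}

#' Interval-set overlap flags around sites
#'
#' Per interval set (non-B DNA forms, G-quadruplex predictions, repeats,
#' ...), 1 iff any interval intersects `[pos - radius, pos + radius]`.
#'
#' @param sites Site tibble (`contig`, `pos`).
#' @param interval_sets Named list of interval tibbles (`contig`, `start`,
#'   `end`, half-open).
#' @param radius Window half-width (default 100).
#' @return Tibble of 0/1 columns `nonb_<set name>`.
#' @export
interval_overlap_features <- function(sites, interval_sets, radius = 100L) {
  sites <- as_tibble(sites)
  out <- list()
  for (nm in names(interval_sets)) {
    iv <- as_tibble(interval_sets[[nm]])
    out[[paste0("nonb_", nm)]] <- vapply(seq_len(nrow(sites)), function(i) {
      as.numeric(nrow(iv) > 0 && any(iv$contig == sites$contig[i] &
                                       iv$start <= sites$pos[i] + radius &
                                       iv$end > sites$pos[i] - radius))
    }, 0)
  }
  as_tibble(out)
}

#' Assemble the site-by-feature matrix for the pause classifier
#'
#' Builds all sequence-derived features for a paired set of pause and
#' non-pause sites. The species-universal block is always computed: 6
#' nucleotide skew differences, 24 one-hot nucleotide identities, 4 RNA-DNA
#' hybrid thermodynamic values and the nascent-RNA folding energy (35
#' columns). Optional resource-dependent blocks are added when the resource
#' is supplied: DNA-shape summaries (`shape`), transcription-factor and
#' RNA-binding-protein motif flags (`tf_pwms`, `rbp_pwms`), non-B DNA /
#' G-quadruplex overlap flags (`nonb`), and DNA methylation (`meth`).
#' Sites whose sequence window leaves the contig or contains an ambiguous
#' base are dropped and recorded in the `dropped` attribute.
#'
#' @param pauses,controls Site tibbles (`contig`, `strand`, `pos`); rows
#'   are labelled `"pause"` / `"non-pause"`.
#' @param genome A [Biostrings::DNAStringSet].
#' @param shape Optional `shape_table`.
#' @param tf_pwms,rbp_pwms Optional `pwm_set`s.
#' @param nonb Optional named list of interval tibbles.
#' @param meth Optional methylation tibble.
#' @param thermo_params Nearest-neighbor parameter set.
#' @param skew_placement Passed to [skew_diff_features()].
#' @return A `feature_matrix` tibble: `site_id`, `label`, then feature
#'   columns; attributes `dropped` (site ids) and `provenance`.
#' @export
build_feature_matrix <- function(pauses, controls, genome, shape = NULL,
                                 tf_pwms = NULL, rbp_pwms = NULL,
                                 nonb = NULL, meth = NULL,
                                 thermo_params = load_thermo_params(),
                                 skew_placement = "offset10") {
  sites <- bind_rows(
    mutate(as_tibble(pauses)[, c("contig", "strand", "pos")], label = "pause"),
    mutate(as_tibble(controls)[, c("contig", "strand", "pos")], label = "non-pause"))
  need_pwm <- !is.null(tf_pwms) || !is.null(rbp_pwms)
  up <- if (need_pwm) 125L else 28L
  dn <- if (need_pwm) 125L else 29L
  seqs <- site_sequence(genome, sites, up, dn, on_oob = "drop")
  oob <- attr(seqs, "dropped")
  # ambiguous bases anywhere in the used window drop the site
  amb <- grepl("[^ACGT]", seqs$seq)
  dropped <- bind_rows(oob[, c("contig", "strand", "pos")],
                       seqs[amb, c("contig", "strand", "pos")])
  seqs <- seqs[!amb, ]
  feats <- list(
    skew_diff_features(seqs, placement = skew_placement),
    nucleotide_identity_features(seqs),
    hybrid_thermo_features(seqs, thermo_params),
    tibble(nascent_mfe = as.numeric(nascent_mfe(seqs)))
  )
  if (!is.null(shape)) feats <- c(feats, list(shape_features(seqs, shape)))
  if (need_pwm) feats <- c(feats, list(pwm_scan_presence(seqs, tf_pwms, rbp_pwms)))
  if (!is.null(nonb)) feats <- c(feats, list(interval_overlap_features(seqs, nonb)))
  if (!is.null(meth)) feats <- c(feats, list(methylation_feature(meth, seqs)))
  fm <- bind_cols(
    tibble(site_id = paste0(seqs$contig, ":", seqs$pos, ":", seqs$strand),
           label = seqs$label),
    do.call(bind_cols, feats))
  keep <- complete.cases(fm)
  dropped <- bind_rows(dropped, seqs[!keep, c("contig", "strand", "pos")])
  fm <- fm[keep, ]
  attr(fm, "dropped") <- paste0(dropped$contig, ":", dropped$pos, ":", dropped$strand)
  attr(fm, "provenance") <- list(
    upstream = up, downstream = dn, skew_placement = skew_placement,
    mfe_engine = "builtin",
    blocks = c("skew", "identity", "thermo", "mfe",
               if (!is.null(shape)) "shape", if (need_pwm) "pwm",
               if (!is.null(nonb)) "nonb", if (!is.null(meth)) "methylation"))
  class(fm) <- c("feature_matrix", class(fm))
  fm
}

#' Write / read a feature matrix with its provenance sidecar
#'
#' TSV of the matrix plus a `<path>.json` sidecar with provenance metadata.
#'
#' @param fm A `feature_matrix`.
#' @param path Output TSV path.
#' @export
write_feature_matrix <- function(fm, path) {
  readr::write_tsv(as_tibble(fm), path)
  jsonlite::write_json(attr(fm, "provenance"), paste0(path, ".json"),
                       auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  fm <- readr::read_tsv(path, col_types = readr::cols(
    site_id = readr::col_character(), label = readr::col_character(),
    .default = readr::col_double()))
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    attr(fm, "provenance") <- jsonlite::read_json(side, simplifyVector = TRUE)
  }
  class(fm) <- c("feature_matrix", class(fm))
  fm
}
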