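#' Collapse PCR duplicates by UMI
#'
#' Reads with identical alignment (contig, strand, 3'-end position) and the
#' same 10-nt unique molecular identifier are PCR copies of one molecule and
#' are collapsed to a single read. `"hamming1"` mode additionally merges,
#' within one position, UMIs at Hamming distance <= 1 into a higher-count
#' UMI (greedy over UMIs in descending count, ties broken by lexicographic
#' order), absorbing the dominant single-error mode of UMI sequencing.
#'
#' @param reads Read-record tibble (see [read_reads_tsv()]).
#' @param collapse_mode `"exact"` or `"hamming1"`.
#' @return Tibble of surviving reads (first read id of each group kept).
#' @export
dedup_reads <- function(reads, collapse_mode = c("exact", "hamming1")) {
  collapse_mode <- match.arg(collapse_mode)
  reads <- validate_reads(reads)
  if (nrow(reads) == 0) return(reads)
  grouped <- reads %>%
    group_by(.data$contig, .data$strand, .data$end3, .data$umi) %>%
    summarise(read_id = .data$read_id[1], n_dup = dplyr::n(), .groups = "drop")
  if (collapse_mode == "exact") {
    return(select(grouped, "contig", "end3", "strand", "umi", "read_id"))
  }
  merged <- grouped %>%
    group_by(.data$contig, .data$strand, .data$end3) %>%
    dplyr::group_modify(~ collapse_hamming1(.x)) %>%
    ungroup()
  select(merged, "contig", "end3", "strand", "umi", "read_id")
}

# greedy absorption of 1-mismatch UMIs into higher-count UMIs at one position
collapse_hamming1 <- function(df) {
  if (nrow(df) <= 1) return(df[, c("umi", "read_id", "n_dup")])
  df <- df[order(-df$n_dup, df$umi), ]
  alive <- rep(TRUE, nrow(df))
  um <- do.call(rbind, strsplit(df$umi, ""))
  for (i in seq_len(nrow(df))) {
    if (!alive[i]) next
    for (j in seq_len(nrow(df))) {
      if (j == i || !alive[j]) next
      # absorb j into i only if i ranks higher (earlier after sort)
      if (j > i && sum(um[i, ] != um[j, ]) <= 1) alive[j] <- FALSE
    }
  }
  df[alive, c("umi", "read_id", "n_dup")]
}

# strand-aware genomic 10-mer immediately downstream (transcription
# direction) of each read's 3' end, reported in the read's sense; NA where
# the window leaves the contig
downstream_10mer <- function(genome, contig, strand, end3) {
  out <- rep(NA_character_, length(end3))
  lens <- Biostrings::width(genome)
  names(lens) <- names(genome)
  plus <- strand == "+"
  ok_p <- plus & (end3 + 10L) < lens[contig]
  ok_m <- !plus & end3 >= 10L
  if (any(ok_p)) {
    out[ok_p] <- as.character(Biostrings::subseq(
      genome[contig[ok_p]], start = end3[ok_p] + 2L, end = end3[ok_p] + 11L))
  }
  if (any(ok_m)) {
    s <- Biostrings::subseq(genome[contig[ok_m]], start = end3[ok_m] - 9L,
                            end = end3[ok_m])
    out[ok_m] <- as.character(Biostrings::reverseComplement(s))
  }
  out
}

# positionwise Hamming similarity of two equal-length strings; N never matches
hamming_similarity <- function(a, b) {
  am <- do.call(rbind, strsplit(a, ""))
  bm <- do.call(rbind, strsplit(b, ""))
  rowMeans(am == bm & am %in% c("A", "C", "G", "T"))
}

#' Detect and remove reverse-transcription mispriming artifacts
#'
#' During library preparation the RT primer can anneal to internal
#' adapter-like RNA, producing artifactual 3'-end pileups whose "UMI" is a
#' copy of the genomic sequence downstream of the alignment. Detection:
#' (1) any read whose UMI equals the 10-nt genomic sequence immediately
#' downstream (transcription direction) of its 3' end is an exact-match
#' mispriming event and is removed; (2) a position where the fraction of
#' exact-match reads exceeds `prone_threshold` is mispriming-prone and all
#' its reads are removed (the position is masked); (3) among reads at prone
#' positions, those whose UMI has Hamming similarity >= `similarity_threshold`
#' to the downstream 10-mer are counted as mispriming events; (4) the
#' escaped fraction is the share of those events whose UMI is not an exact
#' genomic copy (UMIs altered by RT/PCR/sequencing errors escape rule 1).
#'
#' Prone fractions are computed on pre-removal denominators. Reads whose
#' downstream 10-mer would leave the contig are exempt from testing.
#'
#' Run this *before* [dedup_reads()]: independent mispriming events piling
#' up at one locus all carry the identical genomic-copy UMI, so UMI collapse
#' would merge them and deflate the exact-match event count (biasing the
#' escaped fraction upward). The surviving clean read set is identical under
#' either order — removal depends only on position and UMI, which PCR
#' duplicates share — and uniform PCR duplication leaves the escaped/total
#' ratio unbiased, so pre-collapse counting is the consistent estimator.
#'
#' @param reads Read-record tibble (may contain PCR duplicates).
#' @param genome A [Biostrings::DNAStringSet] (or object coercible to one).
#' @param prone_threshold Fraction of exact-match reads above which a
#'   position is prone (strict `>`; default 0.05).
#' @param similarity_threshold Minimum UMI/genome similarity for an event
#'   (default 0.5).
#' @return List with `reads` (clean tibble) and `report`, a
#'   `mispriming_report` carrying `prone_positions` (tibble),
#'   `n_mispriming_events`, `n_exact_match_events`, `escaped_fraction`,
#'   `removed_read_ids` and `n_exempt`.
#' @export
detect_mispriming <- function(reads, genome, prone_threshold = 0.05,
                              similarity_threshold = 0.5) {
  reads <- validate_reads(reads)
  genome <- as(genome, "DNAStringSet")
  if (nrow(reads) == 0) {
    return(list(reads = reads, report = new_mispriming_report()))
  }
  down <- downstream_10mer(genome, reads$contig, reads$strand, reads$end3)
  testable <- !is.na(down)
  exact <- testable & reads$umi == down
  sim <- rep(0, nrow(reads))
  if (any(testable)) {
    sim[testable] <- hamming_similarity(reads$umi[testable], down[testable])
  }
  pos_key <- paste(reads$contig, reads$strand, reads$end3)
  frac_exact <- tapply(exact, pos_key, mean)
  prone_keys <- names(frac_exact)[frac_exact > prone_threshold]
  at_prone <- pos_key %in% prone_keys
  is_event <- at_prone & sim >= similarity_threshold
  n_event <- sum(is_event)
  n_exact_event <- sum(is_event & exact)
  removed <- exact | at_prone
  prone_tbl <- reads[at_prone, c("contig", "strand", "end3")] %>%
    distinct() %>% rename(pos = "end3") %>%
    arrange(.data$contig, .data$strand, .data$pos)
  report <- new_mispriming_report(
    prone_positions = prone_tbl,
    n_mispriming_events = n_event,
    n_exact_match_events = n_exact_event,
    escaped_fraction = if (n_event > 0) (n_event - n_exact_event) / n_event else NA_real_,
    removed_read_ids = reads$read_id[removed],
    n_exempt = sum(!testable))
  list(reads = reads[!removed, ], report = report)
}

new_mispriming_report <- function(prone_positions = tibble(contig = character(),
                                                           strand = character(),
                                                           pos = integer()),
                                  n_mispriming_events = 0L,
                                  n_exact_match_events = 0L,
                                  escaped_fraction = NA_real_,
                                  removed_read_ids = character(0),
                                  n_exempt = 0L) {
  structure(list(prone_positions = prone_positions,
                 n_mispriming_events = as.integer(n_mispriming_events),
                 n_exact_match_events = as.integer(n_exact_match_events),
                 escaped_fraction = escaped_fraction,
                 removed_read_ids = removed_read_ids,
                 n_exempt = as.integer(n_exempt)),
            class = "mispriming_report")
}

#' @export
print.mispriming_report <- function(x, ...) {
  cat(sprintf(paste0("<mispriming_report> %d prone positions, %d events ",
                     "(%d exact-match), escaped fraction %s, %d reads removed\n"),
              nrow(x$prone_positions), x$n_mispriming_events,
              x$n_exact_match_events,
              ifelse(is.na(x$escaped_fraction), "NA",
                     sprintf("%.3f", x$escaped_fraction)),
              length(x$removed_read_ids)))
  invisible(x)
}

#' Mask mispriming-prone positions out of an occupancy track
#'
#' Removes every prone position in `report` from the track. Idempotent.
#'
#' @param track An [occupancy_track()] tibble.
#' @param report A `mispriming_report` from [detect_mispriming()] on the
#'   same sample.
#' @return The masked track.
#' @export
apply_mispriming_mask <- function(track, report) {
  pr <- report$prone_positions
  if (nrow(pr) == 0) return(track)
  cl <- contig_lengths(track)
  out <- anti_join(as_tibble(track), pr, by = c("contig", "strand", "pos"))
  occupancy_track(out, cl)
}
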