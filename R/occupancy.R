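#' Occupancy tracks
#'
#' An occupancy track is a sparse, strand-specific map from genomic position
#' to nascent-RNA 3'-end read count: a tibble with columns `contig`, `strand`
#' (`"+"` or `"-"`), `pos` (0-based nucleotide position) and `count`
#' (positive integer). Positions with zero signal are absent. All coordinates
#' in this package are 0-based and intervals are half-open; GTF input is
#' converted on load.
#'
#' @param x A data frame with columns `contig`, `strand`, `pos`, `count`.
#' @param contig_lengths Named integer vector of contig lengths, used for
#'   bounds checks.
#' @return A tibble of class `occupancy_tbl`, sorted by contig, strand,
#'   position, with `contig_lengths` stored as an attribute.
#' @export
occupancy_track <- function(x, contig_lengths = NULL) {
  x <- as_tibble(x)[, c("contig", "strand", "pos", "count")]
  if (nrow(x) > 0) {
    stopifnot(all(x$strand %in% c("+", "-")))
    if (any(x$count < 1)) abort("occupancy counts must be >= 1 (zeros are absent)")
    if (any(x$count != round(x$count))) abort("occupancy counts must be integers")
    if (any(x$pos < 0)) abort("positions must be >= 0 (0-based)")
    if (!is.null(contig_lengths)) {
      bad <- x$pos >= contig_lengths[x$contig]
      if (any(is.na(bad))) abort("track contains contigs absent from contig_lengths")
      if (any(bad)) abort("positions beyond contig length")
    }
    if (anyDuplicated(x[, c("contig", "strand", "pos")]) > 0) {
      abort("duplicate (contig, strand, pos) entries in track")
    }
  }
  x <- arrange(x, .data$contig, .data$strand, .data$pos)
  x$pos <- as.integer(x$pos)
  x$count <- as.integer(x$count)
  attr(x, "contig_lengths") <- contig_lengths
  class(x) <- c("occupancy_tbl", class(x))
  x
}

#' @rdname occupancy_track
#' @export
contig_lengths <- function(x) attr(x, "contig_lengths")

# parse one bedGraph file into (contig, pos, count) rows, strand attached later
parse_bedgraph <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|track|browser|$)", lines)
  if (!any(keep)) {
    return(tibble(contig = character(), pos = integer(), count = integer()))
  }
  ln <- which(keep)
  fields <- strsplit(trimws(lines[keep]), "\\s+")
  nf <- lengths(fields)
  if (any(nf != 4)) {
    abort(sprintf("%s: expected 4 bedGraph columns at line(s) %s",
                  path, paste(head(ln[nf != 4], 5), collapse = ", ")))
  }
  m <- matrix(unlist(fields), ncol = 4, byrow = TRUE)
  start <- suppressWarnings(as.numeric(m[, 2]))
  end <- suppressWarnings(as.numeric(m[, 3]))
  val <- suppressWarnings(as.numeric(m[, 4]))
  if (anyNA(start) || anyNA(end) || anyNA(val)) {
    abort(sprintf("%s: non-numeric fields at line(s) %s", path,
                  paste(head(ln[is.na(start) | is.na(end) | is.na(val)], 5), collapse = ", ")))
  }
  if (any(val < 0)) abort(sprintf("%s: negative values at line(s) %s", path,
                                  paste(head(ln[val < 0], 5), collapse = ", ")))
  if (any(val != round(val))) {
    abort(sprintf(
      "%s: non-integer counts at line(s) %s (occupancy must be read counts)",
      path, paste(head(ln[val != round(val)], 5), collapse = ", ")))
  }
  # overlap check per contig on the original line order
  ord <- order(m[, 1], start)
  cg <- m[ord, 1]
  s <- start[ord]; e <- end[ord]; lo <- ln[ord]
  same <- cg[-1] == cg[-length(cg)]
  ovl <- which(same & s[-1] < e[-length(e)])
  if (length(ovl) > 0) {
    abort(sprintf("%s: overlapping intervals at lines %s and %s", path,
                  lo[ovl[1]], lo[ovl[1] + 1]))
  }
  nz <- val > 0
  w <- as.integer(end[nz] - start[nz])
  tibble(
    contig = rep(m[nz, 1], w),
    pos = as.integer(sequence(w, from = as.integer(start[nz]))),
    count = as.integer(rep(val[nz], w))
  )
}

#' Read and write strand-paired bedGraph occupancy tracks
#'
#' A sample is stored as two bedGraph files (0-based half-open), one per
#' strand. On read, every covered base becomes one track entry; intervals of
#' width w expand to w positions with equal count and zero-valued records are
#' dropped. On write, runs of adjacent equal-count positions are merged back
#' into single records, sorted by contig then start, so a
#' write/read/write cycle is byte-identical.
#'
#' @param path_plus,path_minus Paths to the plus- and minus-strand bedGraph.
#' @param contig_lengths Named integer vector of contig lengths (optional).
#' @return `read_bedgraph_pair()`: an [occupancy_track()] tibble.
#'   `write_bedgraph_pair()`: the two file paths, invisibly.
#' @export
read_bedgraph_pair <- function(path_plus, path_minus, contig_lengths = NULL) {
  plus <- parse_bedgraph(path_plus)
  minus <- parse_bedgraph(path_minus)
  plus$strand <- if (nrow(plus)) "+" else character(0)
  minus$strand <- if (nrow(minus)) "-" else character(0)
  occupancy_track(bind_rows(plus, minus), contig_lengths)
}

#' @rdname read_bedgraph_pair
#' @param track An [occupancy_track()] tibble.
#' @param out_prefix Output path prefix; writes `<prefix>.plus.bedgraph` and
#'   `<prefix>.minus.bedgraph`.
#' @export
write_bedgraph_pair <- function(track, out_prefix) {
  paths <- paste0(out_prefix, c(".plus.bedgraph", ".minus.bedgraph"))
  for (i in 1:2) {
    st <- c("+", "-")[i]
    sub <- arrange(filter(track, .data$strand == st), .data$contig, .data$pos)
    con <- file(paths[i], open = "wb")  # binary mode: fixed \n line endings
    writeLines(sprintf("# polpause occupancy bedGraph strand=%s", st), con)
    if (nrow(sub) > 0) {
      newrun <- c(TRUE, sub$contig[-1] != sub$contig[-nrow(sub)] |
                    sub$pos[-1] != sub$pos[-nrow(sub)] + 1L |
                    sub$count[-1] != sub$count[-nrow(sub)])
      run <- cumsum(newrun)
      merged <- sub %>%
        group_by(run = run) %>%
        summarise(contig = .data$contig[1], start = min(.data$pos),
                  end = max(.data$pos) + 1L, count = .data$count[1],
                  .groups = "drop") %>%
        arrange(.data$contig, .data$start)
      writeLines(sprintf("%s\t%d\t%d\t%d", merged$contig, merged$start,
                         merged$end, merged$count), con)
    }
    close(con)
  }
  invisible(paths)
}

#' Read records: deduplicable nascent-RNA 3'-end observations
#'
#' A read record is one aligned nascent-RNA fragment reduced to its 3'-end
#' position plus its 10-nt unique molecular identifier (UMI). The on-disk
#' exchange format is a 5-column TSV: `contig`, `end3`, `strand`, `umi`,
#' `read_id`.
#'
#' @param path TSV file path.
#' @return Tibble with columns `contig`, `end3` (0-based), `strand`, `umi`,
#'   `read_id`.
#' @export
read_reads_tsv <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(
    contig = readr::col_character(), end3 = readr::col_integer(),
    strand = readr::col_character(), umi = readr::col_character(),
    read_id = readr::col_character()))
  validate_reads(x)
}

#' @rdname read_reads_tsv
#' @param reads A read-record tibble.
#' @export
write_reads_tsv <- function(reads, path) {
  readr::write_tsv(reads[, c("contig", "end3", "strand", "umi", "read_id")], path)
  invisible(path)
}

validate_reads <- function(x) {
  x <- as_tibble(x)
  stopifnot(all(c("contig", "end3", "strand", "umi", "read_id") %in% names(x)))
  if (nrow(x) > 0) {
    if (any(nchar(x$umi) != 10)) abort("UMIs must be exactly 10 nt")
    stopifnot(all(x$strand %in% c("+", "-")))
  }
  x
}

#' Positions masked before pause analysis
#'
#' Signal at splicing-intermediate positions (the strand-aware 3'-most base
#' of every annotated exon and intron, and polyadenylation sites) reflects
#' co-transcriptional RNA processing rather than polymerase pausing; reads
#' ending exactly there are discarded. Additional intervals (abundant
#' structural RNA classes, repeats) can be masked wholesale.
#'
#' @param annotation A [genome_annotation()] object.
#' @param masked_intervals Optional tibble of half-open intervals to mask
#'   entirely: columns `contig`, `start`, `end` (BED-like, strand-agnostic).
#' @return A `mask_set`: list with `positions` (tibble `contig`, `strand`,
#'   `pos`) and `intervals` (tibble `contig`, `start`, `end`).
#' @export
build_mask <- function(annotation, masked_intervals = NULL) {
  ex <- annotation$exons
  pos_tbl <- tibble(contig = character(), strand = character(), pos = integer())
  if (!is.null(ex) && nrow(ex) > 0) {
    # 3'-most base of each exon, strand-aware
    exon3 <- mutate(ex, pos = if_else(.data$strand == "+", .data$end - 1L, .data$start))
    # introns: gaps between consecutive exons of a gene
    intr <- ex %>%
      arrange(.data$gene_id, .data$start) %>%
      group_by(.data$gene_id) %>%
      summarise(contig = .data$contig[1], strand = .data$strand[1],
                istart = list(.data$end[-dplyr::n()]),
                iend = list(.data$start[-1]), .groups = "drop") %>%
      tidyr::unnest(c("istart", "iend"))
    intr3 <- if (nrow(intr) > 0) {
      mutate(intr, pos = if_else(.data$strand == "+", .data$iend - 1L, .data$istart))
    } else NULL
    pa <- annotation$pa %>%
      left_join(annotation$genes[, c("gene_id", "contig", "strand")], by = "gene_id")
    pos_tbl <- bind_rows(
      exon3[, c("contig", "strand", "pos")],
      if (!is.null(intr3)) intr3[, c("contig", "strand", "pos")],
      pa[, c("contig", "strand", "pos")]
    ) %>% distinct()
  }
  iv <- if (is.null(masked_intervals)) {
    tibble(contig = character(), start = integer(), end = integer())
  } else {
    as_tibble(masked_intervals)[, c("contig", "start", "end")]
  }
  structure(list(positions = arrange(pos_tbl, .data$contig, .data$strand, .data$pos),
                 intervals = arrange(iv, .data$contig, .data$start)),
            class = "mask_set")
}

# TRUE for positions covered by the mask (per-strand positions or any interval)
is_masked <- function(mask, contig, strand, pos) {
  if (is.null(mask)) return(rep(FALSE, length(pos)))
  key <- paste(contig, strand, pos)
  hit <- key %in% paste(mask$positions$contig, mask$positions$strand, mask$positions$pos)
  iv <- mask$intervals
  if (nrow(iv) > 0) {
    for (cg in unique(iv$contig)) {
      sel <- contig == cg
      if (!any(sel)) next
      sub <- iv[iv$contig == cg, ]
      idx <- findInterval(pos[sel], sub$start)
      inside <- idx >= 1 & pos[sel] < sub$end[pmax(idx, 1)]
      hit[sel] <- hit[sel] | inside
    }
  }
  hit
}

#' Collapse read records to a masked 3'-end occupancy track
#'
#' Counts surviving reads per (contig, strand, 3'-end position). Reads whose
#' 3' end falls on a masked position (see [build_mask()]) are discarded
#' before counting. Input reads should already be UMI-deduplicated and
#' mispriming-filtered (see [dedup_reads()], [detect_mispriming()]).
#'
#' @param reads Read-record tibble.
#' @param mask Optional `mask_set` from [build_mask()].
#' @param contig_lengths Named integer vector; reads on unknown contigs error.
#' @return An [occupancy_track()] tibble.
#' @export
three_prime_track <- function(reads, mask = NULL, contig_lengths = NULL) {
  reads <- validate_reads(reads)
  if (!is.null(contig_lengths) && nrow(reads) > 0) {
    unknown <- setdiff(unique(reads$contig), names(contig_lengths))
    if (length(unknown) > 0) {
      abort(sprintf("reads on unknown contig(s): %s", paste(unknown, collapse = ", ")))
    }
  }
  if (nrow(reads) > 0) {
    keep <- !is_masked(mask, reads$contig, reads$strand, reads$end3)
    reads <- reads[keep, ]
  }
  counts <- reads %>%
    count(.data$contig, .data$strand, pos = .data$end3, name = "count")
  occupancy_track(counts, contig_lengths)
}
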