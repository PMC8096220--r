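#' Genome annotation: the coordinate authority for pause classification
#'
#' Bundles gene models (strand, isoform TSSs, polyadenylation sites, exons),
#' enhancer intervals and contig lengths. All coordinates are 0-based
#' half-open; a TSS or pA is the single 0-based position of the first / last
#' transcribed base. GTF input (1-based inclusive) is converted on load.
#'
#' @param genes Tibble: `gene_id`, `contig`, `strand`, `start`, `end`
#'   (gene span, half-open), optional `active` (logical).
#' @param exons Tibble: `gene_id`, `contig`, `strand`, `start`, `end`.
#' @param tss Tibble: `gene_id`, `pos` (one row per isoform TSS).
#' @param pa Tibble: `gene_id`, `pos` (one row per polyadenylation site).
#' @param enhancers Optional tibble: `contig`, `start`, `end`.
#' @param contig_lengths Named integer vector.
#' @return A `genome_annotation` object (list of tibbles).
#' @export
genome_annotation <- function(genes, exons, tss, pa, enhancers = NULL,
                              contig_lengths = NULL) {
  genes <- as_tibble(genes)
  if (!"active" %in% names(genes)) genes$active <- TRUE
  exons <- as_tibble(exons)
  # exons must lie within the gene span
  chk <- left_join(exons, genes[, c("gene_id", "start", "end")],
                   by = "gene_id", suffix = c("", ".g"))
  if (nrow(chk) > 0 && any(chk$start < chk$start.g | chk$end > chk$end.g)) {
    abort("exon outside its gene span")
  }
  enhancers <- if (is.null(enhancers)) {
    tibble(contig = character(), start = integer(), end = integer())
  } else as_tibble(enhancers)
  structure(list(genes = genes, exons = exons, tss = as_tibble(tss),
                 pa = as_tibble(pa), enhancers = enhancers,
                 contig_lengths = contig_lengths),
            class = "genome_annotation")
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat(sprintf("<genome_annotation> %d genes, %d exons, %d TSSs, %d pA sites, %d enhancers\n",
              nrow(x$genes), nrow(x$exons), nrow(x$tss), nrow(x$pa), nrow(x$enhancers)))
  invisible(x)
}

# strand-aware helpers: most upstream / most downstream position in
# transcription direction
upstream_most <- function(pos, strand) if (strand == "+") min(pos) else max(pos)
downstream_most <- function(pos, strand) if (strand == "+") max(pos) else min(pos)

#' Read a gene annotation from GTF
#'
#' Parses gene, transcript and exon records. Each transcript contributes one
#' TSS (its strand-aware 5'-most base) and one pA site (its 3'-most base).
#' Coordinates are converted from GTF's 1-based inclusive convention to the
#' package's 0-based half-open one.
#'
#' @param path GTF file.
#' @param contig_lengths Optional named integer vector.
#' @param enhancers Optional enhancer interval tibble (`contig`,`start`,`end`).
#' @return A [genome_annotation()] object.
#' @export
read_annotation_gtf <- function(path, contig_lengths = NULL, enhancers = NULL) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  f <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(f) != 9)) abort("malformed GTF: expected 9 tab-separated fields")
  m <- matrix(unlist(f), ncol = 9, byrow = TRUE)
  gid <- stringr::str_match(m[, 9], 'gene_id "([^"]+)"')[, 2]
  tid <- stringr::str_match(m[, 9], 'transcript_id "([^"]+)"')[, 2]
  tab <- tibble(contig = m[, 1], type = m[, 3],
                start = as.integer(m[, 4]) - 1L, end = as.integer(m[, 5]),
                strand = m[, 7], gene_id = gid, transcript_id = tid)
  genes <- tab %>% filter(.data$type == "gene") %>%
    select("gene_id", "contig", "strand", "start", "end")
  tx <- tab %>% filter(.data$type == "transcript")
  tss <- tx %>%
    mutate(pos = if_else(.data$strand == "+", .data$start, .data$end - 1L)) %>%
    select("gene_id", "pos") %>% distinct()
  pa <- tx %>%
    mutate(pos = if_else(.data$strand == "+", .data$end - 1L, .data$start)) %>%
    select("gene_id", "pos") %>% distinct()
  exons <- tab %>% filter(.data$type == "exon") %>%
    select("gene_id", "contig", "strand", "start", "end") %>% distinct()
  if (nrow(genes) == 0 && nrow(tx) > 0) {
    genes <- tx %>% group_by(.data$gene_id) %>%
      summarise(contig = .data$contig[1], strand = .data$strand[1],
                start = min(.data$start), end = max(.data$end), .groups = "drop")
  }
  genome_annotation(genes, exons, tss, pa, enhancers, contig_lengths)
}

#' Write a [genome_annotation()] to GTF
#'
#' Emits gene, one transcript per (TSS, pA) span, and exon records in GTF's
#' 1-based inclusive coordinates. [read_annotation_gtf()] round-trips the
#' result.
#'
#' @param annotation A [genome_annotation()] object.
#' @param path Output file.
#' @export
write_annotation_gtf <- function(annotation, path) {
  g <- annotation$genes
  fmt <- function(contig, src, type, start0, end0, strand, attr) {
    sprintf("%s\t%s\t%s\t%d\t%d\t.\t%s\t.\t%s",
            contig, src, type, start0 + 1L, end0, strand, attr)
  }
  out <- character(0)
  for (i in seq_len(nrow(g))) {
    gid <- g$gene_id[i]
    out <- c(out, fmt(g$contig[i], "polpause", "gene", g$start[i], g$end[i],
                      g$strand[i], sprintf('gene_id "%s";', gid)))
    tsss <- annotation$tss$pos[annotation$tss$gene_id == gid]
    pas <- annotation$pa$pos[annotation$pa$gene_id == gid]
    k <- 0
    for (ts in tsss) for (pa in pas) {
      k <- k + 1
      tid <- sprintf("%s.t%d", gid, k)
      lo <- min(ts, pa); hi <- max(ts, pa) + 1L
      out <- c(out, fmt(g$contig[i], "polpause", "transcript", lo, hi, g$strand[i],
                        sprintf('gene_id "%s"; transcript_id "%s";', gid, tid)))
    }
    ex <- annotation$exons[annotation$exons$gene_id == gid, ]
    for (j in seq_len(nrow(ex))) {
      out <- c(out, fmt(ex$contig[j], "polpause", "exon", ex$start[j], ex$end[j],
                        ex$strand[j], sprintf('gene_id "%s"; transcript_id "%s.t1";', gid, gid)))
    }
  }
  con <- file(path, open = "wb")
  writeLines(out, con)
  close(con)
  invisible(path)
}

#' Read a BED file of intervals
#'
#' First three columns only (contig, start, end; BED is already 0-based
#' half-open).
#'
#' @param path BED file.
#' @return Tibble `contig`, `start`, `end`.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  if (length(lines) == 0) return(tibble(contig = character(), start = integer(), end = integer()))
  f <- strsplit(lines, "\\s+")
  tibble(contig = vapply(f, `[`, "", 1),
         start = as.integer(vapply(f, `[`, "", 2)),
         end = as.integer(vapply(f, `[`, "", 3)))
}

#' @rdname read_bed
#' @param intervals Tibble `contig`, `start`, `end`.
#' @export
write_bed <- function(intervals, path) {
  con <- file(path, open = "wb")
  if (nrow(intervals) > 0) {
    writeLines(sprintf("%s\t%d\t%d", intervals$contig, intervals$start,
                       intervals$end), con)
  }
  close(con)
  invisible(path)
}
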