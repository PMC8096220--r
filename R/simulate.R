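#' Synthetic study configuration
#'
#' Defaults describe the conditions the package is exercised under: a
#' megabase-scale random genome carrying tens of multi-exon genes on both
#' strands, sparse background occupancy of 0.1 reads per transcribed
#' nucleotide (typical NET-seq depth away from peaks), planted
#' single-nucleotide pauses at 0.4 per kb with a 20-fold count enrichment
#' over the local per-covered-base mean, and library artifacts at
#' NET-seq-like rates (10% PCR duplication, 5% RT mispriming).
#'
#' @param genome_length Contig length (default 1e6).
#' @param gc_content Genome GC fraction (default 0.41, human-like).
#' @param n_genes Number of genes (default 50).
#' @param gene_length_range Uniform range of gene lengths (default
#'   4000..12000 nt).
#' @param exons_per_gene Range of exon counts per gene (default 2..5).
#' @param pause_rate Planted pauses per kb of gene span (default 0.4).
#' @param pause_fold Planted count multiplier over the local mean count per
#'   covered base (default 20).
#' @param background_rate Background reads per transcribed nucleotide
#'   (default 0.1).
#' @param planted_motif Optional named numeric-to-character map of relative
#'   position (as character, e.g. `"-10"`) to base; when set, pauses are
#'   planted only where the genome matches.
#' @param misprime_rate Fraction of reads that are RT-mispriming artifacts
#'   (default 0.05).
#' @param misprime_loci Number of mispriming-prone loci artifacts
#'   concentrate at (default 20).
#' @param duplication_rate Probability a read gains one PCR duplicate
#'   (default 0.1).
#' @param umi_error_rate Per-base UMI corruption probability of mispriming
#'   reads (default 0.05).
#' @param seed Integer seed (mandatory).
#' @return A `sim_config` list.
#' @export
sim_config <- function(genome_length = 1e6, gc_content = 0.41, n_genes = 50L,
                       gene_length_range = c(4000L, 12000L),
                       exons_per_gene = c(2L, 5L),
                       pause_rate = 0.4, pause_fold = 20,
                       background_rate = 0.1, planted_motif = NULL,
                       misprime_rate = 0.05, misprime_loci = 20L,
                       duplication_rate = 0.1, umi_error_rate = 0.05,
                       seed) {
  stopifnot(!missing(seed), pause_fold > 1, pause_rate >= 0,
            background_rate >= 0, misprime_rate >= 0, duplication_rate >= 0,
            umi_error_rate >= 0)
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate a random genome
#'
#' I.i.d. bases at the configured GC content, as a single contig.
#'
#' @param config A [sim_config()].
#' @param contig Contig name (default `"chrS"`).
#' @return A [Biostrings::DNAStringSet] of one contig.
#' @export
simulate_genome <- function(config, contig = "chrS") {
  with_seed(config$seed, {
    p <- c(A = (1 - config$gc_content) / 2, C = config$gc_content / 2,
           G = config$gc_content / 2, T = (1 - config$gc_content) / 2)
    s <- paste(sample(names(p), config$genome_length, replace = TRUE, prob = p),
               collapse = "")
    g <- Biostrings::DNAStringSet(s)
    names(g) <- contig
    g
  })
}

#' Simulate a gene annotation
#'
#' Places non-overlapping multi-exon genes alternating between strands with
#' intergenic gaps, one TSS and one pA site each; every fifth pair of
#' neighboring genes is placed close enough for their flanks to create
#' antisense-region overlap, exercising the undetermined-classification
#' rules. Enhancer intervals are dropped into intergenic space.
#'
#' @param config A [sim_config()].
#' @param genome Genome from [simulate_genome()].
#' @return A [genome_annotation()] object.
#' @export
simulate_annotation <- function(config, genome) {
  cl <- setNames(Biostrings::width(genome), names(genome))
  contig <- names(cl)[1]
  with_seed(config$seed + 1L, {
    lens <- as.integer(round(runif(config$n_genes, config$gene_length_range[1],
                                   config$gene_length_range[2])))
    # narrow gaps every 5th gene put the antisense flank of a minus-strand
    # gene over its plus-strand neighbor's body, creating conflict loci
    gaps <- ifelse(seq_len(config$n_genes) %% 5L == 0L, 200L, 2000L)
    need <- sum(lens) + sum(gaps) + 2000L
    if (need > cl[contig]) {
      abort(sprintf("genes do not fit: need %d nt, contig has %d; reduce n_genes",
                    need, cl[contig]))
    }
    slack <- cl[contig] - need
    extra <- as.integer(floor(slack / (config$n_genes + 1L)))
    genes <- vector("list", config$n_genes)
    exons <- vector("list", config$n_genes)
    cur <- 2000L + extra
    for (i in seq_len(config$n_genes)) {
      st <- if (i %% 2 == 1) "+" else "-"
      gid <- sprintf("g%03d", i)
      gstart <- cur
      gend <- gstart + lens[i]
      ne <- sample(config$exons_per_gene[1]:config$exons_per_gene[2], 1)
      cuts <- sort(sample(seq(200L, lens[i] - 200L, by = 50L), 2L * (ne - 1L)))
      bounds <- c(0L, cuts, lens[i])
      es <- gstart + bounds[seq(1, length(bounds), by = 2)]
      ee <- gstart + bounds[seq(2, length(bounds), by = 2)]
      genes[[i]] <- tibble(gene_id = gid, contig = contig, strand = st,
                           start = gstart, end = gend)
      exons[[i]] <- tibble(gene_id = gid, contig = contig, strand = st,
                           start = as.integer(es), end = as.integer(ee))
      cur <- gend + gaps[i] + if (gaps[i] > 1000L) extra else 0L
    }
    genes <- bind_rows(genes)
    exons <- bind_rows(exons)
    tss <- genes %>%
      mutate(pos = if_else(.data$strand == "+", .data$start, .data$end - 1L)) %>%
      select("gene_id", "pos")
    pa <- genes %>%
      mutate(pos = if_else(.data$strand == "+", .data$end - 1L, .data$start)) %>%
      select("gene_id", "pos")
    # enhancers in intergenic space: between gene i and i+1
    mid <- (genes$end[-nrow(genes)] + genes$start[-1]) %/% 2L
    wide <- which(genes$start[-1] - genes$end[-nrow(genes)] > 1500L)
    enh_idx <- wide[seq(2, length(wide), by = 4)]
    enhancers <- tibble(contig = contig, start = mid[enh_idx] - 100L,
                        end = mid[enh_idx] + 100L)
    genome_annotation(genes, exons, tss, pa, enhancers, cl)
  })
}

# scan gene spans for positions matching a planted motif (relative
# position -> base map, coding strand)
motif_positions <- function(genome, annotation, motif) {
  rels <- as.integer(names(motif))
  out <- list()
  gseq <- genome[[1]]
  contig <- names(genome)[1]
  glen <- length(gseq)
  for (i in seq_len(nrow(annotation$genes))) {
    g <- annotation$genes[i, ]
    cand <- (g$start + 300L):(g$end - 300L)
    ok <- rep(TRUE, length(cand))
    for (k in seq_along(rels)) {
      r <- rels[k]
      off <- if (r < 0) r + 1L else r
      gp <- if (g$strand == "+") cand + off else cand - off
      b <- as.character(Biostrings::extractAt(
        gseq, IRanges::IRanges(start = gp + 1L, width = 1L)))
      if (g$strand == "-") b <- chartr("ACGT", "TGCA", b)
      want <- motif[[k]]
      ok <- ok & if (want == "Y") b %in% c("C", "T") else
        if (want == "R") b %in% c("A", "G") else b == want
    }
    if (any(ok)) {
      out[[length(out) + 1]] <- tibble(contig = contig, strand = g$strand,
                                       pos = cand[ok], gene_id = g$gene_id)
    }
  }
  bind_rows(out)
}

#' Simulate an occupancy track with planted pauses
#'
#' Background reads are placed uniformly and independently within each gene
#' span (exactly the redistribution null of the pause caller, so a track
#' with `pause_rate = 0` is a true type-I-error benchmark). Planted pause
#' positions are drawn per gene at `pause_rate` per kb and receive
#' `pause_fold` times the mean background count per covered base. With a
#' `planted_motif`, pause positions are restricted to motif matches.
#'
#' @param config A [sim_config()].
#' @param annotation From [simulate_annotation()].
#' @param genome Needed when `planted_motif` is set.
#' @return List with `track` (an [occupancy_track()]) and `truth` (tibble
#'   `contig`, `strand`, `pos`, `planted_count`).
#' @export
simulate_occupancy <- function(config, annotation, genome = NULL) {
  cl <- annotation$contig_lengths
  contig <- annotation$genes$contig[1]
  with_seed(config$seed + 2L, {
    bg <- vector("list", nrow(annotation$genes))
    for (i in seq_len(nrow(annotation$genes))) {
      g <- annotation$genes[i, ]
      span <- g$end - g$start
      nr <- rpois(1, config$background_rate * span)
      if (nr > 0) {
        pos <- g$start + sample.int(span, nr, replace = TRUE) - 1L
        bg[[i]] <- tibble(contig = g$contig, strand = g$strand, pos = pos)
      }
    }
    bg <- bind_rows(bg)
    counts <- bg %>% count(.data$contig, .data$strand, .data$pos, name = "count")
    mean_cov <- if (nrow(counts) > 0) mean(counts$count) else 1
    planted_count <- as.integer(max(2, round(config$pause_fold * mean_cov)))
    motif_pool <- if (!is.null(config$planted_motif)) {
      motif_positions(genome, annotation, config$planted_motif)
    } else NULL
    truth <- vector("list", nrow(annotation$genes))
    for (i in seq_len(nrow(annotation$genes))) {
      g <- annotation$genes[i, ]
      span <- g$end - g$start
      np <- rpois(1, config$pause_rate * span / 1000)
      if (np == 0) next
      if (!is.null(motif_pool)) {
        pool <- motif_pool$pos[motif_pool$gene_id == g$gene_id]
        if (length(pool) == 0) next
        pp <- sample(pool, min(np, length(pool)))
      } else {
        pp <- g$start + 100L + sample.int(span - 200L, np) - 1L # off gene edges
      }
      truth[[i]] <- tibble(contig = g$contig, strand = g$strand, pos = as.integer(pp),
                           planted_count = planted_count)
    }
    truth <- bind_rows(truth)
    if (nrow(truth) > 0) {
      truth <- distinct(truth, .data$contig, .data$strand, .data$pos,
                        .keep_all = TRUE)
      counts <- counts %>%
        dplyr::full_join(truth, by = c("contig", "strand", "pos")) %>%
        mutate(count = dplyr::coalesce(.data$count, 0L) +
                 dplyr::coalesce(.data$planted_count, 0L)) %>%
        select("contig", "strand", "pos", "count")
    }
    list(track = occupancy_track(counts, cl), truth = truth)
  })
}

random_umis <- function(n, len = 10L) {
  m <- matrix(sample(c("A", "C", "G", "T"), n * len, replace = TRUE), ncol = len)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

#' Simulate artifact-bearing read records from a track
#'
#' Expands the track into one read per count with a random 10-nt UMI, adds
#' PCR duplicates (probability `duplication_rate` per read, preserving the
#' UMI), and plants RT-mispriming artifacts: `misprime_rate` of the read
#' total becomes extra reads concentrated at `misprime_loci` random genic
#' loci, each carrying the genomic 10-mer downstream of its 3' end as its
#' UMI, with every UMI base then corrupted at `umi_error_rate` (corrupted
#' copies emulate artifacts that escape exact-match detection).
#'
#' @param config A [sim_config()].
#' @param track An [occupancy_track()].
#' @param genome A [Biostrings::DNAStringSet].
#' @return List with `reads` (read-record tibble) and `truth` (list:
#'   `misprime_ids`, `misprime_loci` tibble, `duplicate_ids`,
#'   `expected_escape` = `1 - (1 - umi_error_rate)^10`).
#' @export
simulate_reads <- function(config, track, genome) {
  with_seed(config$seed + 3L, {
    tr <- as_tibble(track)
    n0 <- sum(tr$count)
    reads <- tibble(contig = rep(tr$contig, tr$count),
                    end3 = rep(tr$pos, tr$count),
                    strand = rep(tr$strand, tr$count),
                    umi = random_umis(n0),
                    read_id = sprintf("r%07d", seq_len(n0)))
    dup <- runif(n0) < config$duplication_rate
    dups <- reads[dup, ]
    if (nrow(dups) > 0) dups$read_id <- sprintf("d%07d", seq_len(nrow(dups)))
    n_mis <- round(config$misprime_rate * n0)
    mis <- NULL
    loci <- NULL
    if (n_mis > 0) {
      # prone loci inside covered genic space, downstream 10-mer available
      pool <- tr[tr$pos > 20 & tr$pos < (contig_lengths(track)[tr$contig] - 20), ]
      take <- sample(nrow(pool), min(config$misprime_loci, nrow(pool)))
      loci <- pool[take, c("contig", "strand", "pos")]
      pick <- sample(nrow(loci), n_mis, replace = TRUE)
      down <- downstream_10mer(genome, loci$contig[pick], loci$strand[pick],
                               loci$pos[pick])
      # corrupt each UMI base independently
      um <- do.call(rbind, strsplit(down, ""))
      err <- matrix(runif(length(um)) < config$umi_error_rate, nrow = nrow(um))
      if (any(err)) {
        repl <- vapply(um[err], function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
        um[err] <- repl
      }
      mis <- tibble(contig = loci$contig[pick], end3 = loci$pos[pick],
                    strand = loci$strand[pick],
                    umi = do.call(paste0, as.data.frame(um, stringsAsFactors = FALSE)),
                    read_id = sprintf("m%07d", seq_len(n_mis)))
    }
    all_reads <- bind_rows(reads, dups, mis)
    list(reads = all_reads,
         truth = list(misprime_ids = if (is.null(mis)) character(0) else mis$read_id,
                      misprime_loci = loci,
                      duplicate_ids = if (nrow(dups) > 0) dups$read_id else character(0),
                      expected_escape = 1 - (1 - config$umi_error_rate)^10))
  })
}

#' Simulate feature resources
#'
#' A complete 1024-pentamer shape table (`"constant"`, `"gc_ramp"` — value
#' = G+C count in the pentamer — or `"random"` structure), a small PWM set
#' containing one planted consensus motif plus random motifs, and a
#' block-structured methylation track.
#'
#' @param config A [sim_config()].
#' @param shape_mode `"constant"`, `"gc_ramp"` or `"random"`.
#' @param consensus Planted motif consensus (default `"TATAAT"`).
#' @param n_random_pwms Random PWMs to add (default 2).
#' @param contig,contig_length Methylation track coordinates.
#' @return List with `shape` (a `shape_table`), `pwms` (a `pwm_set`),
#'   `methylation` (tibble).
#' @export
simulate_feature_resources <- function(config, shape_mode = c("gc_ramp", "constant", "random"),
                                       consensus = "TATAAT", n_random_pwms = 2L,
                                       contig = "chrS", contig_length = NULL) {
  shape_mode <- match.arg(shape_mode)
  with_seed(config$seed + 4L, {
    pent <- do.call(paste0, expand.grid(rep(list(c("A", "C", "G", "T")), 5),
                                        stringsAsFactors = FALSE)[, 5:1])
    val <- switch(shape_mode,
                  constant = rep(1, 1024),
                  gc_ramp = stringr::str_count(pent, "[GC]"),
                  random = stats::rnorm(1024))
    shape <- tibble(pentamer = pent, MGW = val, Roll = val, ProT = val,
                    HelT = val, EP = val)
    class(shape) <- c("shape_table", class(shape))
    cons <- strsplit(consensus, "")[[1]]
    m <- matrix(0.02, 4, length(cons), dimnames = list(c("A", "C", "G", "T"), NULL))
    m[cbind(match(cons, rownames(m)), seq_along(cons))] <- 0.94
    pwms <- list(planted = m)
    for (i in seq_len(n_random_pwms)) {
      r <- matrix(stats::rgamma(4 * 8, 1), 4, 8,
                  dimnames = list(c("A", "C", "G", "T"), NULL))
      pwms[[paste0("rand", i)]] <- sweep(r, 2, colSums(r), "/")
    }
    class(pwms) <- "pwm_set"
    cln <- contig_length %||% config$genome_length
    blocks <- seq(0, cln - 2000, by = 2000)
    lvl <- rep(stats::rbeta(length(blocks), 0.5, 0.5), each = 20)
    cpg <- as.integer(unlist(lapply(blocks, function(b) b + seq(0, 1900, by = 100))))
    meth <- tibble(contig = contig, pos = cpg[seq_along(lvl)], level = lvl)
    list(shape = shape, pwms = pwms, methylation = meth)
  })
}
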