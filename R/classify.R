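#' Classify pause sites into genomic categories
#'
#' Rule-based assignment of each site to one of four major categories, with
#' subclasses, using strand-aware distances in transcription direction:
#'
#' * **promoter-proximal** — same strand, within 300 nt downstream of any
#'   annotated TSS of a gene (interval `[TSS, TSS + 300]`, inclusive).
#' * **gene-body** — same strand, between +301 (relative to the gene's most
#'   upstream TSS) and the 3'-most pA site; subclass `exonic` when
#'   overlapping an annotated exon, else `intronic`.
#' * **antisense** — opposite strand, between 1000 nt upstream of the most
#'   upstream TSS and the most downstream pA site; subclass `divergent`
#'   (upstream of the TSS) or `convergent` (within the gene body);
#'   `undetermined` when both apply through different genes.
#' * **intergenic** — everything else; subclass `termination-zone` (within
#'   3.5 kb downstream of a pA site), `enhancer` (inside an enhancer
#'   interval) or `other-intergenic`.
#'
#' A site matching both the gene-body region of one gene and the antisense
#' region of another is category `undetermined`. Promoter-proximal takes
#' precedence over gene-body where the regions overlap.
#'
#' @param sites Tibble with `contig`, `strand`, `pos` (e.g. a
#'   `pause_calls` tibble, typically filtered to significant calls).
#' @param annotation A [genome_annotation()] object.
#' @param promoter_window Downstream extent of the promoter-proximal class
#'   (default 300 nt).
#' @param antisense_upstream Upstream extent of the antisense region
#'   (default 1000 nt).
#' @param termination_window Downstream extent of the termination zone
#'   (default 3500 nt).
#' @return `sites` with `category`, `subclass` and `gene_id` columns
#'   appended.
#' @export
classify_pauses <- function(sites, annotation, promoter_window = 300L,
                            antisense_upstream = 1000L,
                            termination_window = 3500L) {
  sites <- as_tibble(sites)
  g <- annotation$genes
  tss <- left_join(annotation$tss, g[, c("gene_id", "contig", "strand")], by = "gene_id")
  pa <- left_join(annotation$pa, g[, c("gene_id", "contig", "strand")], by = "gene_id")
  cl <- annotation$contig_lengths
  if (!is.null(cl) && nrow(sites) > 0 &&
      any(sites$pos < 0 | sites$pos >= cl[sites$contig] | is.na(cl[sites$contig]))) {
    abort("site outside contig bounds")
  }
  # per-gene anchors in transcription direction
  anchors <- g %>%
    left_join(tss %>% group_by(.data$gene_id) %>%
                summarise(tss_up = if (.data$strand[1] == "+") min(.data$pos) else max(.data$pos),
                          .groups = "drop"),
              by = "gene_id") %>%
    left_join(pa %>% group_by(.data$gene_id) %>%
                summarise(pa_down = if (.data$strand[1] == "+") max(.data$pos) else min(.data$pos),
                          .groups = "drop"),
              by = "gene_id")
  n <- nrow(sites)
  category <- rep("intergenic", n)
  subclass <- rep("none", n)
  gene_id <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    p <- sites$pos[i]; st <- sites$strand[i]; cg <- sites$contig[i]
    ga <- anchors[anchors$contig == cg, ]
    promo <- gb_gene <- as_div <- as_conv <- character(0)
    gb_exonic <- FALSE
    for (j in seq_len(nrow(ga))) {
      gs <- ga$strand[j]; gid <- ga$gene_id[j]
      dir <- if (gs == "+") 1L else -1L
      # signed distance from a gene anchor, in that gene's transcription direction
      d_tss_any <- dir * (p - tss$pos[tss$gene_id == gid])
      d_tss_up <- dir * (p - ga$tss_up[j])
      d_pa_down <- dir * (p - ga$pa_down[j])
      if (st == gs) {
        if (any(d_tss_any >= 0 & d_tss_any <= promoter_window)) {
          promo <- c(promo, gid)
        } else if (d_tss_up > promoter_window && d_pa_down <= 0) {
          gb_gene <- c(gb_gene, gid)
          ex <- annotation$exons[annotation$exons$gene_id == gid, ]
          if (nrow(ex) > 0 && any(p >= ex$start & p < ex$end)) gb_exonic <- TRUE
        }
      } else {
        if (d_tss_up >= -antisense_upstream && d_pa_down <= 0) {
          if (d_tss_up < 0) as_div <- c(as_div, gid) else as_conv <- c(as_conv, gid)
        }
      }
    }
    if (length(promo) > 0) {
      category[i] <- "promoter-proximal"; subclass[i] <- "none"; gene_id[i] <- promo[1]
    } else if (length(gb_gene) > 0 && (length(as_div) + length(as_conv)) > 0) {
      category[i] <- "undetermined"; subclass[i] <- "undetermined"
    } else if (length(gb_gene) > 0) {
      category[i] <- "gene-body"
      subclass[i] <- if (gb_exonic) "exonic" else "intronic"
      gene_id[i] <- gb_gene[1]
    } else if (length(as_div) + length(as_conv) > 0) {
      category[i] <- "antisense"
      subclass[i] <- if (length(as_div) > 0 && length(as_conv) > 0) "undetermined"
      else if (length(as_div) > 0) "divergent" else "convergent"
      gene_id[i] <- c(as_div, as_conv)[1]
    } else {
      category[i] <- "intergenic"
      # termination zone: within 3.5 kb downstream of any pA, same strand
      term <- FALSE
      for (j in seq_len(nrow(ga))) {
        if (ga$strand[j] != st) next
        dir <- if (ga$strand[j] == "+") 1L else -1L
        d <- dir * (p - pa$pos[pa$gene_id == ga$gene_id[j]])
        if (any(d > 0 & d <= termination_window)) { term <- TRUE; gene_id[i] <- ga$gene_id[j]; break }
      }
      enh <- annotation$enhancers
      in_enh <- nrow(enh) > 0 &&
        any(enh$contig == cg & p >= enh$start & p < enh$end)
      subclass[i] <- if (term) "termination-zone" else if (in_enh) "enhancer"
      else "other-intergenic"
    }
  }
  sites$category <- category
  sites$subclass <- subclass
  sites$gene_id <- gene_id
  sites
}

#' Splice-site proximity of gene-body pauses
#'
#' Labels a site `proximal` when within `radius` nucleotides of a splice
#' junction of its gene, split into `first exon-intron`, `exon-intron`,
#' `intron-exon` and `last intron-exon` boundary types (transcription
#' direction); a site near several boundaries receives all matching labels.
#' Sites farther than `radius` from every junction are `distal`.
#'
#' @param sites Classified sites (must carry `gene_id`; typically the
#'   gene-body subset of [classify_pauses()] output).
#' @param annotation A [genome_annotation()] object.
#' @param radius Maximum distance in nucleotides (default 40).
#' @return `sites` with a `splice_labels` column (comma-separated labels, or
#'   `"distal"`).
#' @export
splice_proximity <- function(sites, annotation, radius = 40L) {
  sites <- as_tibble(sites)
  labs <- character(nrow(sites))
  for (i in seq_len(nrow(sites))) {
    gid <- sites$gene_id[i]
    ex <- annotation$exons[annotation$exons$gene_id == gid, ]
    if (is.na(gid) || nrow(ex) < 2) { labs[i] <- "distal"; next }
    st <- ex$strand[1]
    ex <- ex[order(if (st == "+") ex$start else -ex$start), ] # transcription order
    ne <- nrow(ex)
    # per exon (transcription order): donor = 3'-most base, acceptor = 5'-most
    donor <- if (st == "+") ex$end - 1L else ex$start
    acceptor <- if (st == "+") ex$start else ex$end - 1L
    hits <- character(0)
    p <- sites$pos[i]
    for (e in seq_len(ne - 1)) { # donors: exon -> intron boundaries
      if (abs(p - donor[e]) <= radius) {
        hits <- c(hits, if (e == 1) "first exon-intron" else "exon-intron")
      }
    }
    for (e in 2:ne) { # acceptors: intron -> exon boundaries
      if (abs(p - acceptor[e]) <= radius) {
        hits <- c(hits, if (e == ne) "last intron-exon" else "intron-exon")
      }
    }
    labs[i] <- if (length(hits) == 0) "distal" else paste(unique(hits), collapse = ",")
  }
  sites$splice_labels <- labs
  sites
}

#' Sample matched non-pausing control sites
#'
#' Draws one control per pause from the flanks `[pos + x, pos + x + 20]` or
#' `[pos - x - 20, pos - x]` (side chosen uniformly), with `x = 50` for
#' promoter-proximal pauses and `x = 300` otherwise, so controls share the
#' local genomic context without touching the pause itself. A draw landing
#' on any pause position, a masked position, or outside the contig is
#' rejected and redrawn (up to `max_attempts`); pauses with no valid control
#' are dropped and reported via the `dropped` attribute.
#'
#' @param pauses Classified pause tibble (needs `contig`, `strand`, `pos`,
#'   `category`).
#' @param annotation A [genome_annotation()] object (for contig bounds).
#' @param mask Optional `mask_set`.
#' @param seed Integer seed.
#' @param max_attempts Redraw limit per pause (default 50).
#' @return Tibble of control sites (`contig`, `strand`, `pos`, `source_pos`)
#'   with attribute `dropped` listing source positions without a control.
#' @export
sample_nonpausing <- function(pauses, annotation, mask = NULL, seed = 1L,
                              max_attempts = 50L) {
  pauses <- as_tibble(pauses)
  cl <- annotation$contig_lengths
  pause_key <- paste(pauses$contig, pauses$strand, pauses$pos)
  with_seed(seed, {
    out <- vector("list", nrow(pauses))
    dropped <- integer(0)
    for (i in seq_len(nrow(pauses))) {
      x <- if (identical(pauses$category[i], "promoter-proximal")) 50L else 300L
      found <- FALSE
      for (a in seq_len(max_attempts)) {
        side <- sample(c(-1L, 1L), 1)
        off <- sample.int(21L, 1) - 1L
        cand <- pauses$pos[i] + side * (x + off)
        if (cand < 0) next
        if (!is.null(cl) && cand >= cl[pauses$contig[i]]) next
        key <- paste(pauses$contig[i], pauses$strand[i], cand)
        if (key %in% pause_key) next
        if (is_masked(mask, pauses$contig[i], pauses$strand[i], cand)) next
        out[[i]] <- tibble(contig = pauses$contig[i], strand = pauses$strand[i],
                           pos = cand, source_pos = pauses$pos[i])
        found <- TRUE
        break
      }
      if (!found) dropped <- c(dropped, pauses$pos[i])
    }
    res <- bind_rows(out)
    attr(res, "dropped") <- dropped
    res
  })
}

#' Actively transcribed genes
#'
#' Genes whose steady-state expression exceeds the cutoff (strict `>`,
#' default TPM 1).
#'
#' @param expr Tibble with `gene_id` and `tpm`.
#' @param cutoff Expression threshold (default 1).
#' @return Character vector of active gene ids.
#' @export
active_genes <- function(expr, cutoff = 1) {
  expr <- as_tibble(expr)
  stopifnot(all(expr$tpm >= 0))
  expr$gene_id[expr$tpm > cutoff]
}

#' Average pausing distance per gene
#'
#' For every gene with at least two pauses between its most upstream TSS and
#' most downstream pA site, the mean gap between consecutive pauses.
#'
#' @param pauses Classified pauses carrying `gene_id`.
#' @param annotation A [genome_annotation()] object.
#' @return Tibble `gene_id`, `n_pauses`, `mean_distance` (nt).
#' @export
average_pause_distance <- function(pauses, annotation) {
  pauses <- as_tibble(pauses) %>% filter(!is.na(.data$gene_id))
  g <- annotation$genes
  span <- g %>%
    left_join(annotation$tss %>% group_by(.data$gene_id) %>%
                summarise(lo_t = min(.data$pos), hi_t = max(.data$pos), .groups = "drop"),
              by = "gene_id") %>%
    left_join(annotation$pa %>% group_by(.data$gene_id) %>%
                summarise(lo_p = min(.data$pos), hi_p = max(.data$pos), .groups = "drop"),
              by = "gene_id") %>%
    mutate(lo = pmin(.data$lo_t, .data$lo_p), hi = pmax(.data$hi_t, .data$hi_p))
  pauses %>%
    left_join(span[, c("gene_id", "lo", "hi")], by = "gene_id") %>%
    filter(.data$pos >= .data$lo, .data$pos <= .data$hi) %>%
    group_by(.data$gene_id) %>%
    summarise(n_pauses = dplyr::n(),
              mean_distance = if (dplyr::n() >= 2) mean(diff(sort(.data$pos))) else NA_real_,
              .groups = "drop") %>%
    filter(.data$n_pauses >= 2)
}

#' Compare promoter-proximal and gene-body pausing intensities
#'
#' For every gene with significant pauses in both regions, the mean
#' pause-site signal per region, then a one-sided Welch t-test across genes
#' (alternative: gene-body intensity exceeds promoter-proximal intensity).
#'
#' @param pauses Classified pauses with `count` and `category`, `gene_id`.
#' @return List with `per_gene` tibble (`gene_id`, `mean_promoter`,
#'   `mean_genebody`) and `p_value`.
#' @export
compare_intensities <- function(pauses) {
  pauses <- as_tibble(pauses)
  per_gene <- pauses %>%
    filter(.data$category %in% c("promoter-proximal", "gene-body"),
           !is.na(.data$gene_id)) %>%
    group_by(.data$gene_id, .data$category) %>%
    summarise(mean_count = mean(.data$count), .groups = "drop") %>%
    tidyr::pivot_wider(names_from = "category", values_from = "mean_count") %>%
    rename(mean_promoter = "promoter-proximal", mean_genebody = "gene-body") %>%
    filter(!is.na(.data$mean_promoter), !is.na(.data$mean_genebody))
  if (nrow(per_gene) < 2) abort("need >= 2 genes with pauses in both regions")
  tt <- t.test(per_gene$mean_genebody, per_gene$mean_promoter,
               var.equal = FALSE, alternative = "greater")
  list(per_gene = per_gene, p_value = unname(tt$p.value))
}

#' Mean signal density around sites
#'
#' Sums a signal track within a window at each site and divides by the
#' (clip-adjusted) window width. `upstream_only` windows cover `width`
#' bases strand-aware upstream of the site; `centered` windows cover
#' `[pos - width/2, pos + width/2)`. Several replicate tracks are averaged
#' per site.
#'
#' @param tracks An [occupancy_track()] tibble or list of replicate tracks.
#' @param sites Tibble with `contig`, `strand`, `pos`.
#' @param window `"upstream_only"` or `"centered"`.
#' @param width Window width in nucleotides.
#' @param stranded If `FALSE` the signal of both strands is pooled.
#' @return `sites` with a `density` column appended.
#' @export
site_signal_density <- function(tracks, sites, window = c("upstream_only", "centered"),
                                width = 200L, stranded = TRUE) {
  window <- match.arg(window)
  if (!is.list(tracks) || is.data.frame(tracks)) tracks <- list(tracks)
  sites <- as_tibble(sites)
  half <- width %/% 2L
  a <- ifelse(sites$strand == "+" | window == "centered",
              ifelse(window == "centered", sites$pos - half, sites$pos - width),
              sites$pos + 1L)
  b <- ifelse(sites$strand == "+" | window == "centered",
              ifelse(window == "centered", sites$pos + (width - half), sites$pos),
              sites$pos + width + 1L)
  dens <- matrix(0, nrow(sites), length(tracks))
  for (t in seq_along(tracks)) {
    tr <- as_tibble(tracks[[t]])
    cl <- contig_lengths(tracks[[t]])
    for (i in seq_len(nrow(sites))) {
      lo <- max(a[i], 0L)
      hi <- b[i]
      if (!is.null(cl)) hi <- min(hi, cl[sites$contig[i]])
      w <- hi - lo
      if (w <= 0) { dens[i, t] <- 0; next }
      sel <- tr$contig == sites$contig[i] & tr$pos >= lo & tr$pos < hi
      if (stranded) sel <- sel & tr$strand == sites$strand[i]
      dens[i, t] <- sum(tr$count[sel]) / w
    }
  }
  sites$density <- rowMeans(dens)
  sites
}

#' Flag candidate premature-termination sites
#'
#' A site is flagged when its (nascent RNA 3' end-seq) signal density
#' strictly exceeds the 25th percentile (linear-interpolation quantile) of
#' the density at bona fide polyadenylation sites.
#'
#' @param site_densities Numeric site densities.
#' @param pa_densities Numeric densities at polyadenylation sites
#'   (non-empty).
#' @param probs Reference quantile (default 0.25).
#' @return Logical flags.
#' @export
premature_termination_calls <- function(site_densities, pa_densities,
                                        probs = 0.25) {
  if (length(pa_densities) == 0) abort("empty polyadenylation-site density set")
  site_densities > quantile(pa_densities, probs, type = 7, names = FALSE)
}
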