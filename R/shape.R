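#' Pentamer DNA-shape lookup tables
#'
#' Reads a table mapping every DNA pentamer to five structural descriptors:
#' minor groove width (`MGW`), `Roll`, propeller twist (`ProT`), helix
#' twist (`HelT`) and potential energy (`EP`). The table is user-supplied
#' (published pentamer tables, or synthetic ones from
#' [simulate_feature_resources()]); lookups fail loudly on missing
#' pentamers.
#'
#' @param path TSV with columns `pentamer`, `MGW`, `Roll`, `ProT`, `HelT`,
#'   `EP` and all 1024 pentamer rows.
#' @return A `shape_table` tibble.
#' @export
load_shape_table <- function(path) {
  tab <- readr::read_tsv(path, col_types = "cddddd")
  need <- c("pentamer", "MGW", "Roll", "ProT", "HelT", "EP")
  if (!all(need %in% names(tab))) abort("shape table must have columns pentamer, MGW, Roll, ProT, HelT, EP")
  if (nrow(tab) != 1024 || anyDuplicated(tab$pentamer) > 0) {
    abort("shape table must contain each of the 1024 pentamers exactly once")
  }
  structure(as_tibble(tab), class = c("shape_table", class(tab)))
}

#' Summary DNA-shape features around a site
#'
#' Slides a pentamer window over relative positions -10..+5 (the RNA-DNA
#' hybrid plus five downstream bases), looks up each centered pentamer's
#' five shape descriptors, and summarises each descriptor by minimum,
#' maximum, mean, span (max - min) and mean absolute successive difference
#' (the "first derivative") — 25 features.
#'
#' @param seqs Output of [site_sequence()] spanning at least `[-12, +7]`
#'   (pentamer context for all 16 centers).
#' @param table A `shape_table` from [load_shape_table()].
#' @return Tibble of 25 columns `shape_MGW_min` .. `shape_EP_deriv`.
#' @export
shape_features <- function(seqs, table) {
  centers <- setdiff(-10:5, 0)
  descr <- c("MGW", "Roll", "ProT", "HelT", "EP")
  lut <- lapply(descr, function(d) setNames(table[[d]], table$pentamer))
  names(lut) <- descr
  out <- matrix(NA_real_, nrow(seqs), length(descr) * 5)
  cn <- as.vector(outer(c("min", "max", "mean", "span", "deriv"), descr,
                        function(s, d) paste0("shape_", d, "_", s)))
  colnames(out) <- cn
  for (i in seq_len(nrow(seqs))) {
    pent <- vapply(centers, function(r) {
      substr(seqs$seq[i], rel_index(seqs$offset[i], r) - 2L,
             rel_index(seqs$offset[i], r) + 2L)
    }, "")
    for (d in descr) {
      v <- lut[[d]][pent]
      if (anyNA(v)) abort(sprintf("pentamer(s) missing from shape table: %s",
                                  paste(unique(pent[is.na(v)]), collapse = ", ")))
      out[i, paste0("shape_", d, "_min")] <- min(v)
      out[i, paste0("shape_", d, "_max")] <- max(v)
      out[i, paste0("shape_", d, "_mean")] <- mean(v)
      out[i, paste0("shape_", d, "_span")] <- max(v) - min(v)
      out[i, paste0("shape_", d, "_deriv")] <- mean(abs(diff(v)))
    }
  }
  as_tibble(out)
}
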