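#' RNA/DNA hybrid nearest-neighbor parameters
#'
#' Loads a nearest-neighbor parameter table for RNA/DNA hybrid duplexes:
#' one row per RNA dinucleotide (5'->3') with enthalpy `dH` (kcal/mol) and
#' entropy `dS` (cal/(mol K)), plus an `init` row of initiation terms. The
#' packaged default is the Sugimoto RNA/DNA hybrid set
#' (`inst/extdata/rna_dna_nn_params.tsv`); any table in the same layout can
#' be swapped in — the classifier only needs a monotone energy scale.
#'
#' @param path TSV with columns `dimer`, `dH`, `dS`; defaults to the
#'   packaged parameter file.
#' @param strand_concentration Total strand concentration (molar) used in
#'   the melting-temperature formula (default 1e-4).
#' @return A `thermo_params` list: `nn` (named dH/dS vectors), `init`,
#'   `strand_concentration`.
#' @export
load_thermo_params <- function(path = NULL, strand_concentration = 1e-4) {
  path <- path %||% system.file("extdata", "rna_dna_nn_params.tsv",
                                package = "polpause")
  tab <- readr::read_tsv(path, col_types = "cdd")
  dimers <- tab$dimer[tab$dimer != "init"]
  need <- as.vector(outer(c("A", "C", "G", "U"), c("A", "C", "G", "U"), paste0))
  if (!all(need %in% dimers)) abort("thermo table must contain all 16 RNA dinucleotides")
  if (!"init" %in% tab$dimer) abort("thermo table must contain an 'init' row")
  structure(list(
    dH = setNames(tab$dH[match(need, tab$dimer)], need),
    dS = setNames(tab$dS[match(need, tab$dimer)], need),
    init_dH = tab$dH[tab$dimer == "init"],
    init_dS = tab$dS[tab$dimer == "init"],
    strand_concentration = strand_concentration), class = "thermo_params")
}

#' Thermodynamics of the 10-nt RNA-DNA hybrid
#'
#' Nearest-neighbor enthalpy, entropy, Gibbs free energy at 37 C and
#' two-state melting temperature of the duplex formed by the last 10 nt of
#' the nascent RNA (relative positions -10..-1) and the DNA template:
#' `dH = dH_init + sum of 9 dinucleotide terms` (likewise `dS`),
#' `dG37 = dH - 310.15 * dS / 1000` (kcal/mol), and
#' `Tm = 1000 * dH / (dS + R * ln(CT / 4))` in kelvin with
#' `R = 1.987 cal/(mol K)` and `CT` the strand concentration. No salt
#' correction is applied; the absolute scale is a documented convention.
#'
#' @param seqs Output of [site_sequence()] spanning at least `[-10, -1]`.
#' @param params A `thermo_params` object (defaults to the packaged set).
#' @return Tibble with `hybrid_dH`, `hybrid_dS`, `hybrid_dG37`, `hybrid_Tm`.
#' @export
hybrid_thermo_features <- function(seqs, params = load_thermo_params()) {
  rna <- chartr("T", "U", rel_slice(seqs$seq, seqs$offset, -10, -1))
  n <- nchar(rna)
  if (any(n != 10)) abort("hybrid window must be 10 nt")
  dH <- rep(params$init_dH, length(rna))
  dS <- rep(params$init_dS, length(rna))
  for (i in 1:9) {
    dm <- substr(rna, i, i + 1)
    bad <- !dm %in% names(params$dH)
    if (any(bad)) {
      dH[bad] <- NA_real_; dS[bad] <- NA_real_
      dm[bad] <- "AA"
    }
    dH <- dH + params$dH[dm]
    dS <- dS + params$dS[dm]
  }
  dG37 <- dH - 310.15 * dS / 1000
  tm <- 1000 * dH / (dS + 1.987 * log(params$strand_concentration / 4))
  tibble(hybrid_dH = unname(dH), hybrid_dS = unname(dS),
         hybrid_dG37 = unname(dG37), hybrid_Tm = unname(tm))
}
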