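# Simplified nascent-RNA folding model: pseudoknot-free secondary
# structures over pairs AU/UA, GC/CG, GU/UG with a minimum hairpin loop of
# 3 unpaired bases. Energy is contributed only by stacked pair steps
# (pair (i,j) directly enclosing pair (i+1,j-1)); the stack energy is the
# mean strength of the two pairs, with GC = 3, AU = 2, GU = 1 kcal/mol
# stabilisation. Isolated pairs are energetically neutral, so an
# unstructured sequence scores exactly 0.

mfe_pair_strength <- c(GC = 3, CG = 3, AU = 2, UA = 2, GU = 1, UG = 1)

mfe_pairable <- function(a, b) paste0(a, b) %in% names(mfe_pair_strength)

mfe_stack_energy <- function(a1, b1, a2, b2) {
  -(mfe_pair_strength[paste0(a1, b1)] + mfe_pair_strength[paste0(a2, b2)]) / 2
}

# dynamic program over the stacking-only model; exact for that model
mfe_dp <- function(bases) {
  n <- length(bases)
  if (n < 5) return(0)
  V <- matrix(Inf, n, n)
  W <- matrix(0, n, n)
  for (span in 4:(n - 1)) {
    for (i in 1:(n - span)) {
      j <- i + span
      if (mfe_pairable(bases[i], bases[j])) {
        v <- W[i + 1, j - 1]
        if (j - i >= 6 && mfe_pairable(bases[i + 1], bases[j - 1]) &&
            is.finite(V[i + 1, j - 1])) {
          v <- min(v, mfe_stack_energy(bases[i], bases[j],
                                       bases[i + 1], bases[j - 1]) + V[i + 1, j - 1])
        }
        V[i, j] <- v
      }
      w <- W[i, j - 1]
      for (k in i:(j - 4)) {
        if (is.finite(V[k, j])) {
          w <- min(w, (if (k > i) W[i, k - 1] else 0) + V[k, j])
        }
      }
      W[i, j] <- w
    }
  }
  W[1, n]
}

#' Minimum folding energy of the emerging nascent RNA
#'
#' Folds the nascent-RNA stretch at relative positions -29..-11 — the
#' region just outside the polymerase exit channel where hairpins can
#' form — and returns the minimum free energy over pseudoknot-free
#' secondary structures. The builtin engine is a simplified
#' nearest-neighbor stacking model (see source; exact for that model, with
#' a minimum hairpin loop of 3). An external folding engine (ViennaRNA's
#' `RNAfold` binary) can be selected when installed; the engine used is
#' recorded in the `engine` attribute.
#'
#' @param seqs Output of [site_sequence()] spanning at least `[-29, -11]`,
#'   or a character vector of raw RNA/DNA sequences (then folded as given).
#' @param engine `"builtin"` or `"vienna"`.
#' @return Numeric vector of energies (kcal/mol, <= 0), attribute `engine`.
#' @export
nascent_mfe <- function(seqs, engine = c("builtin", "vienna")) {
  engine <- match.arg(engine)
  rna <- if (is.character(seqs)) chartr("T", "U", seqs)
  else chartr("T", "U", rel_slice(seqs$seq, seqs$offset, -29, -11))
  out <- if (engine == "builtin") {
    vapply(strsplit(rna, ""), mfe_dp, 0)
  } else {
    if (Sys.which("RNAfold") == "") abort("RNAfold binary not found")
    res <- system2("RNAfold", c("--noPS"), input = rna, stdout = TRUE)
    en <- grep("\\(\\s*-?[0-9.]+\\)$", res, value = TRUE)
    as.numeric(sub(".*\\(\\s*(-?[0-9.]+)\\)$", "\\1", en))
  }
  attr(out, "engine") <- engine
  out
}
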