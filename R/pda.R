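#' Parameters for the pause detecting algorithm
#'
#' @param L Window length in nucleotides for the local-density window
#'   centered on each candidate position (even, default 200).
#' @param N Number of resampling draws for the null pool (default 10000).
#' @param alpha Significance level applied to BH-adjusted p-values
#'   (default 0.05).
#' @param seed Integer seed; every stochastic step derives its stream from
#'   it, making a call bit-reproducible.
#' @param exact_cutoff Exact-null feasibility bound: the exact
#'   multinomial-maximum tail replaces resampling when `M * l` is at most
#'   this value (and `M <= 500`, keeping the dynamic program cheap).
#' @param strict If `TRUE`, reproduce the literal resampling rule
#'   `p = #(simulated max > observed) / N`, which can return 0 on discrete
#'   ties; the default add-one rule `p = (1 + #(max >= observed)) / (N + 1)`
#'   is a guaranteed-valid permutation p-value.
#' @return A `pda_params` list.
#' @export
pda_params <- function(L = 200L, N = 10000L, alpha = 0.05, seed = 1L,
                       exact_cutoff = 1e6, strict = FALSE) {
  stopifnot(L >= 2, L %% 2 == 0, N >= 1, alpha > 0, alpha < 1)
  structure(list(L = as.integer(L), N = as.integer(N), alpha = alpha,
                 seed = as.integer(seed), exact_cutoff = exact_cutoff,
                 strict = isTRUE(strict)),
            class = "pda_params")
}

# run code under a fixed RNG state, restoring the caller's stream
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# deterministic per-(M, l) stream seed so the null cache is reproducible
# regardless of candidate order
derive_seed <- function(seed, M, l) {
  as.integer((as.double(seed) * 48271 + M * 131071 + l * 8191) %% 2147483563) + 1L
}

#' Strict single-nucleotide local maxima of an occupancy track
#'
#' A local maximum is a position whose count strictly exceeds both immediate
#' neighbors (absent neighbors count 0). Equal-count plateaus are never
#' maxima.
#'
#' @param track An [occupancy_track()] tibble.
#' @return Tibble `contig`, `strand`, `pos`, `count` of candidate positions.
#' @export
find_local_maxima <- function(track) {
  tr <- as_tibble(track) %>% arrange(.data$contig, .data$strand, .data$pos)
  if (nrow(tr) == 0) return(tr[, c("contig", "strand", "pos", "count")])
  tr %>%
    group_by(.data$contig, .data$strand) %>%
    mutate(
      left = if_else(lag(.data$pos) == .data$pos - 1L, lag(.data$count), 0L, missing = 0L),
      right = if_else(lead(.data$pos) == .data$pos + 1L, lead(.data$count), 0L, missing = 0L)
    ) %>%
    ungroup() %>%
    filter(.data$count > .data$left, .data$count > .data$right) %>%
    select("contig", "strand", "pos", "count")
}

#' Local read density around candidate positions
#'
#' For each site, counts the total reads `M` and the number of non-zero
#' positions `l` within the window `[pos - L/2, pos + L/2)` on the same
#' strand, clipped at contig edges.
#'
#' @param track An [occupancy_track()] tibble.
#' @param sites Tibble with `contig`, `strand`, `pos`.
#' @param L Window length (nucleotides).
#' @return `sites` with columns `M` and `l` appended.
#' @export
local_density <- function(track, sites, L = 200L) {
  half <- as.integer(L) %/% 2L
  cl <- contig_lengths(track)
  tr <- as_tibble(track) %>% arrange(.data$contig, .data$strand, .data$pos)
  sites <- as_tibble(sites)
  sites$M <- 0L
  sites$l <- 0L
  key_t <- paste(tr$contig, tr$strand)
  key_s <- paste(sites$contig, sites$strand)
  for (k in unique(key_s)) {
    sel_t <- key_t == k
    sel_s <- key_s == k
    p <- tr$pos[sel_t]
    cs <- c(0L, cumsum(tr$count[sel_t]))
    a <- pmax(sites$pos[sel_s] - half, 0L)
    b <- sites$pos[sel_s] + half
    if (!is.null(cl)) b <- pmin(b, cl[sites$contig[sel_s]])
    lo <- findInterval(a - 0.5, p) + 1L
    hi <- findInterval(b - 0.5, p)
    sites$M[sel_s] <- as.integer(cs[hi + 1L] - cs[lo])
    sites$l[sel_s] <- pmax(hi - lo + 1L, 0L)
  }
  sites
}

#' Exact tail of the multinomial maximum
#'
#' `P(max cell count >= k)` when `M` reads are dropped uniformly and
#' independently into `l` positions — the PDA's null distribution, computed
#' exactly. Uses the generating-function identity
#' `P(all cells <= c) = M!/l^M * [z^M] (sum_{x<=c} z^x / x!)^l`,
#' evaluated by log-space polynomial exponentiation.
#'
#' @param M Total reads in the window (non-negative integer).
#' @param l Number of occupied positions (positive integer).
#' @param k Threshold count.
#' @return The exact tail probability.
#' @export
exact_max_tail <- function(M, l, k) {
  stopifnot(M >= 0, l >= 1)
  if (k > M) return(0)
  if (k <= ceiling(M / l)) return(1) # pigeonhole: max >= mean
  if (l == 1) return(1)
  # closed forms for small k: sum over cell-count compositions with parts
  # <= k - 1; these cover almost every candidate on sparse tracks
  if (k == 2L) {
    # all M reads in distinct cells (M <= l is guaranteed here)
    return(max(0, min(1, 1 - exp(lgamma(l + 1) - lgamma(l - M + 1) - M * log(l)))))
  }
  if (k == 3L || k == 4L) {
    # c3 cells of 3 (k = 4 only), c2 of 2, rest singletons/zeros
    c3max <- if (k == 4L) M %/% 3L else 0L
    acc <- -Inf
    for (c3 in 0:c3max) {
      c2 <- 0:((M - 3L * c3) %/% 2L)
      b <- M - 3L * c3 - 2L * c2 # singleton cells
      a <- l - b - c2 - c3       # empty cells
      ok <- a >= 0
      if (!any(ok)) next
      v <- (lgamma(l + 1) - lgamma(a[ok] + 1) - lgamma(b[ok] + 1) -
              lgamma(c2[ok] + 1) - lgamma(c3 + 1) +
              lgamma(M + 1) - c2[ok] * log(2) - c3 * log(6))
      m <- max(v, acc)
      acc <- m + log(sum(exp(v - m)) + exp(acc - m))
    }
    log_all_le <- acc - M * log(l)
    return(max(0, min(1, 1 - exp(log_all_le))))
  }
  cmax <- k - 1L
  # log-coefficients of sum_{x=0}^{cmax} z^x / x!
  base <- -lgamma(0:cmax + 1)
  pw <- log_poly_power(base, l, M)
  if (length(pw) < M + 1 || pw[M + 1] == -Inf) return(1)
  log_all_le <- lgamma(M + 1) - M * log(l) + pw[M + 1]
  max(0, min(1, 1 - exp(log_all_le)))
}

# log-space polynomial power by squaring, truncated at degree maxdeg
log_poly_power <- function(la, n, maxdeg) {
  res <- 0 # log-poly "1"
  b <- la
  while (n > 0) {
    if (n %% 2 == 1) res <- log_poly_mult(res, b, maxdeg)
    n <- n %/% 2
    if (n > 0) b <- log_poly_mult(b, b, maxdeg)
  }
  res
}

log_poly_mult <- function(la, lb, maxdeg) {
  na <- length(la); nb <- length(lb)
  nd <- min(na + nb - 1, maxdeg + 1)
  out <- numeric(nd)
  for (kk in seq_len(nd)) {
    i <- max(1, kk - nb + 1):min(na, kk)
    v <- la[i] + lb[kk - i + 1]
    m <- max(v)
    out[kk] <- if (m == -Inf) -Inf else m + log(sum(exp(v - m)))
  }
  out
}

# N simulated values of the window maximum under uniform redistribution of
# M reads over l positions
simulate_max_pool <- function(M, l, N, seed) {
  if (l == 1) return(rep(M, N))
  with_seed(seed, {
    pool <- integer(N)
    chunk <- max(1L, min(N, as.integer(2e7 / l)))
    done <- 0L
    while (done < N) {
      nb <- min(chunk, N - done)
      cells <- sample.int(l, nb * M, replace = TRUE)
      rep_id <- rep(seq_len(nb), each = M)
      tab <- tabulate((rep_id - 1L) * l + cells, nbins = nb * l)
      mat <- matrix(tab, nrow = l)
      pool[done + seq_len(nb)] <- mat[cbind(max.col(t(mat)), seq_len(nb))]
      done <- done + nb
    }
    pool
  })
}

#' Resampling p-value for an observed window maximum
#'
#' Redistributes `M` reads uniformly over the `l` occupied positions of the
#' window `N` times, recording each sample's maximum per-position count.
#' Default p-value is the add-one permutation form
#' `(1 + #(max >= observed)) / (N + 1)`; `strict = TRUE` gives the literal
#' `#(max > observed) / N`.
#'
#' @param M,l Local density (see [local_density()]).
#' @param observed Observed count at the candidate position (`<= M`).
#' @param N Number of resamples.
#' @param seed Integer seed.
#' @param strict Use the strict-inequality rule without the add-one guard.
#' @return A p-value in (0, 1] (strict mode may return 0).
#' @export
resampled_pvalue <- function(M, l, observed, N = 10000L, seed = 1L,
                             strict = FALSE) {
  stopifnot(observed <= M, l >= 1)
  pool <- simulate_max_pool(M, l, N, seed)
  if (strict) sum(pool > observed) / N else (1 + sum(pool >= observed)) / (N + 1)
}

#' Benjamini-Hochberg adjustment
#'
#' Thin wrapper over [stats::p.adjust()] with `method = "BH"`, kept as the
#' package's named multiple-testing step.
#'
#' @param pvals Numeric vector of raw p-values.
#' @return Adjusted p-values, order-preserving.
#' @export
bh_adjust <- function(pvals) {
  if (length(pvals) == 0) return(numeric(0))
  p.adjust(pvals, method = "BH")
}

#' Call pausing sites from an occupancy track
#'
#' The pause detecting algorithm: (1) find strict local maxima; (2) describe
#' each candidate's local read density (`M` reads over `l` occupied
#' positions in a window of `L` nucleotides); (3) test the observed count
#' against the uniform-redistribution null, using the exact
#' multinomial-maximum tail when feasible (`method = "exact"`) and seeded
#' resampling otherwise (`method = "resample"`, null pools cached per
#' `(M, l)`); (4) BH-adjust p-values across all candidates of the sample
#' (both strands pooled); a site is significant when `q < alpha`.
#'
#' @param track An artifact-filtered [occupancy_track()] tibble.
#' @param params A [pda_params()] list.
#' @return A `pause_calls` tibble: `contig`, `strand`, `pos`, `count`, `M`,
#'   `l`, `p`, `q`, `significant`, `method`, with `params` as an attribute.
#'   All candidates are kept; filter on `significant` for called pauses.
#' @export
call_pauses <- function(track, params = pda_params()) {
  cand <- find_local_maxima(track)
  if (nrow(cand) == 0) {
    out <- mutate(cand, M = integer(0), l = integer(0), p = numeric(0),
                  q = numeric(0), significant = logical(0), method = character(0))
    attr(out, "pda_params") <- params
    class(out) <- c("pause_calls", class(out))
    return(out)
  }
  cand <- local_density(track, cand, params$L)
  cand$p <- NA_real_
  cand$method <- NA_character_
  # trivial candidates: observed 1 can never beat the null
  triv <- cand$count == 1L
  cand$p[triv] <- if (params$strict) {
    # P(max > 1) exactly, still cheap for these tiny observed counts
    vapply(which(triv), function(i) exact_max_tail(cand$M[i], cand$l[i], 2L), 0)
  } else 1
  cand$method[triv] <- "exact"
  todo <- which(!triv)
  use_exact <- with(cand[todo, , drop = FALSE],
                    M * l <= params$exact_cutoff & M <= 500)
  # exact path, one DP per unique (M, l, k)
  ex <- todo[use_exact]
  if (length(ex) > 0) {
    kk <- cand$count[ex] + if (params$strict) 1L else 0L
    key <- paste(cand$M[ex], cand$l[ex], kk)
    u <- !duplicated(key)
    tails <- mapply(exact_max_tail, cand$M[ex][u], cand$l[ex][u], kk[u])
    cand$p[ex] <- tails[match(key, key[u])]
    cand$method[ex] <- "exact"
  }
  # resampling path, null pool cached per (M, l)
  rs <- todo[!use_exact]
  if (length(rs) > 0) {
    key <- paste(cand$M[rs], cand$l[rs])
    for (k in unique(key)) {
      idx <- rs[key == k]
      M <- cand$M[idx[1]]; l <- cand$l[idx[1]]
      pool <- simulate_max_pool(M, l, params$N, derive_seed(params$seed, M, l))
      cand$p[idx] <- vapply(cand$count[idx], function(obs) {
        if (params$strict) sum(pool > obs) / params$N
        else (1 + sum(pool >= obs)) / (params$N + 1)
      }, 0)
    }
    cand$method[rs] <- "resample"
  }
  cand$q <- bh_adjust(cand$p)
  cand$significant <- cand$q < params$alpha
  attr(cand, "pda_params") <- params
  class(cand) <- c("pause_calls", class(cand))
  cand
}

#' Write / read a pause-call table
#'
#' BED-like TSV: contig, start, end (= start + 1), strand, count, M, l, p,
#' q, significant, method.
#'
#' @param calls A `pause_calls` tibble.
#' @param path Output TSV.
#' @export
write_pauses_tsv <- function(calls, path) {
  out <- as_tibble(calls) %>%
    mutate(start = .data$pos, end = .data$pos + 1L) %>%
    select("contig", "start", "end", "strand", "count", "M", "l",
           "p", "q", "significant", "method")
  readr::write_tsv(out, path)
  invisible(path)
}

#' @rdname write_pauses_tsv
#' @export
read_pauses_tsv <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(
    contig = readr::col_character(), strand = readr::col_character(),
    method = readr::col_character(), significant = readr::col_logical(),
    .default = readr::col_double()))
  x <- mutate(x, pos = as.integer(.data$start)) %>%
    select("contig", "strand", "pos", "count", "M", "l", "p", "q",
           "significant", "method")
  class(x) <- c("pause_calls", class(x))
  x
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Sums, over the hypergeometric support at fixed margins, the probabilities
#' of all tables no more likely than the observed one. Any zero margin gives
#' p = 1.
#'
#' @param tab 2x2 matrix of non-negative integer counts.
#' @return Two-sided p-value.
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == 2), all(tab >= 0), all(tab == round(tab)))
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  if (r1 == 0 || c1 == 0 || r1 == n || c1 == n) return(1)
  support <- max(0, r1 + c1 - n):min(r1, c1)
  d <- stats::dhyper(support, c1, n - c1, r1)
  p_obs <- stats::dhyper(tab[1, 1], c1, n - c1, r1)
  min(1, sum(d[d <= p_obs * (1 + 1e-07)]))
}

#' Replicate reproducibility of pause calls
#'
#' Per replicate, the percent of its significant pauses that are significant
#' in all replicates, restricted to positions detected as local maxima in
#' every replicate (a pause cannot be reproduced where no candidate exists).
#' The two-sided Fisher exact test is computed over all candidate positions
#' regardless of joint detectability, crossing significance in one replicate
#' against another (for more than two replicates, the least-significant
#' pairwise p is reported).
#'
#' @param calls_list List of two or more `pause_calls` tibbles on the same
#'   genome.
#' @return A `reproducibility_report`: list with `percent_shared` (per
#'   replicate), `fisher_p`, `n_common`, `n_per_replicate`.
#' @export
replicate_overlap <- function(calls_list) {
  if (length(calls_list) < 2) abort("need at least 2 replicates")
  keys <- lapply(calls_list, function(x) paste(x$contig, x$strand, x$pos))
  sig_keys <- lapply(seq_along(calls_list), function(i)
    keys[[i]][calls_list[[i]]$significant])
  cand_common <- Reduce(intersect, keys)
  sig_common <- Reduce(intersect, sig_keys)
  n_per <- vapply(sig_keys, length, 0L)
  pct <- vapply(seq_along(calls_list), function(i) {
    denom <- sum(sig_keys[[i]] %in% cand_common)
    if (denom == 0) return(NA_real_)
    100 * length(sig_common) / denom
  }, 0)
  # pairwise Fisher over the union of candidates
  pairs <- utils::combn(length(calls_list), 2)
  fp <- apply(pairs, 2, function(pr) {
    uni <- union(keys[[pr[1]]], keys[[pr[2]]])
    a <- uni %in% sig_keys[[pr[1]]]
    b <- uni %in% sig_keys[[pr[2]]]
    fisher_exact_2x2(matrix(c(sum(a & b), sum(a & !b),
                              sum(!a & b), sum(!a & !b)), 2, byrow = TRUE))
  })
  structure(list(percent_shared = pct, fisher_p = max(fp),
                 n_common = length(sig_common), n_per_replicate = n_per),
            class = "reproducibility_report")
}

#' @export
print.reproducibility_report <- function(x, ...) {
  cat(sprintf("<reproducibility_report> %s%% shared (n common = %d), Fisher p = %.3g\n",
              paste(sprintf("%.1f", x$percent_shared), collapse = "/"),
              x$n_common, x$fisher_p))
  invisible(x)
}

#' Binomial thinning of an occupancy track
#'
#' Retains each read independently with probability `fraction`, emulating a
#' lower sequencing depth; positions thinned to zero are dropped.
#'
#' @param track An [occupancy_track()] tibble.
#' @param fraction Retention probability in (0, 1].
#' @param seed Integer seed.
#' @return The thinned track.
#' @export
downsample <- function(track, fraction, seed = 1L) {
  stopifnot(fraction > 0, fraction <= 1)
  if (fraction == 1 || nrow(track) == 0) return(track)
  cl <- contig_lengths(track)
  out <- as_tibble(track)
  out$count <- with_seed(seed, rbinom(nrow(out), out$count, fraction))
  occupancy_track(out[out$count > 0, ], cl)
}
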