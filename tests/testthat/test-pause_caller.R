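test_that("local maxima are strict: plateaus excluded, isolated counts kept", {
  expect_equal(find_local_maxima(make_track(10:12, c(1, 5, 2)))$pos, 11L)
  expect_equal(nrow(find_local_maxima(make_track(10:11, c(5, 5)))), 0L)
  expect_equal(find_local_maxima(make_track(50, 1))$pos, 50L)
  # strands are independent
  tr <- occupancy_track(tibble::tibble(
    contig = "chr1", strand = c("+", "-"), pos = c(100L, 101L),
    count = c(2L, 3L)), c(chr1 = 1000L))
  expect_equal(nrow(find_local_maxima(tr)), 2L)
})

test_that("local density counts window reads and occupied positions, clipped", {
  tr <- make_track(c(100L, 150L), c(4L, 6L))
  d <- local_density(tr, tibble::tibble(contig = "chr1", strand = "+", pos = 100L), 200L)
  expect_equal(d$M, 10L)
  expect_equal(d$l, 2L)
  d2 <- local_density(make_track(100L, 4L),
                      tibble::tibble(contig = "chr1", strand = "+", pos = 100L), 200L)
  expect_equal(c(d2$M, d2$l), c(4L, 1L))
  # clipping at contig start: window [0, 110) only
  tr3 <- make_track(c(5L, 115L), c(2L, 7L))
  d3 <- local_density(tr3, tibble::tibble(contig = "chr1", strand = "+", pos = 10L), 200L)
  expect_equal(c(d3$M, d3$l), c(2L, 1L))
})

test_that("exact multinomial-maximum tail matches full enumeration", {
  for (M in 1:6) for (l in 1:4) for (k in 1:(M + 1)) {
    expect_equal(exact_max_tail(M, l, k), enumerate_max_tail(M, l, k),
                 tolerance = 1e-10,
                 label = sprintf("tail(M=%d, l=%d, k=%d)", M, l, k))
  }
  expect_equal(exact_max_tail(5, 1, 5), 1)
  expect_equal(exact_max_tail(4, 2, 3), 0.625)
  expect_equal(exact_max_tail(2, 2, 2), 0.5)
  # a larger case against the binomial tail (l = 2)
  expect_equal(exact_max_tail(40, 2, 26),
               2 * sum(stats::dbinom(26:40, 40, 0.5)), tolerance = 1e-10)
})

test_that("resampled p-values agree with the exact null and behave at edges", {
  p <- resampled_pvalue(3, 3, 2, N = 20000, seed = 2)
  expect_equal(p, 21 / 27, tolerance = 0.02)
  expect_equal(resampled_pvalue(5, 3, 1, N = 100, seed = 1), 1)
  expect_equal(resampled_pvalue(4, 1, 4, N = 100, seed = 1), 1)
  # monotonicity: non-increasing in observed, non-decreasing in M
  ps <- vapply(1:4, function(k) exact_max_tail(4, 3, k), 0)
  expect_true(all(diff(ps) <= 0))
  pm <- vapply(3:8, function(M) exact_max_tail(M, 3, 3), 0)
  expect_true(all(diff(pm) >= 0))
})

test_that("BH adjustment matches the step-up procedure", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.04, 0.05)), c(0.04, 0.04, 0.05, 0.05))
  expect_equal(bh_adjust(0.3), 0.3)
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(bh_adjust(numeric(0)), numeric(0))
})

test_that("call_pauses finds a planted spike and nothing on flat tracks", {
  # uniform 1-read-per-position: no local maxima at all
  flat <- make_track(100:200, 1L)
  expect_equal(nrow(call_pauses(flat, pda_params(seed = 1))), 0L)
  # 50-read spike over a 1-read background
  spike <- make_track(c(300:380, 340L)[-41], c(rep(1L, 80), 50L))
  calls <- call_pauses(spike, pda_params(seed = 7))
  sig <- calls[calls$significant, ]
  expect_equal(sig$pos, 340L)
  expect_equal(sig$count, 50L)
  # defaults carried in params
  p <- pda_params()
  expect_equal(c(p$L, p$N, p$alpha), c(200, 10000, 0.05))
})

test_that("call_pauses is bit-reproducible under a fixed seed", {
  set.seed(99)
  tr <- make_track(sort(sample(1000:3000, 300)),
                   sample(1:6, 300, replace = TRUE))
  a <- call_pauses(tr, pda_params(seed = 5, exact_cutoff = 10)) # force resampling
  b <- call_pauses(tr, pda_params(seed = 5, exact_cutoff = 10))
  expect_identical(tibble::as_tibble(a), tibble::as_tibble(b))
  expect_true(any(a$method == "resample"))
  # resampling path agrees with the exact path at q-level decisions
  ex <- call_pauses(tr, pda_params(seed = 5))
  expect_equal(a$p, ex$p, tolerance = 0.05)
})

test_that("type-I error is controlled on a null track", {
  cfg <- sim_config(genome_length = 2e5, n_genes = 10, pause_rate = 0,
                    background_rate = 0.2, seed = 17)
  g <- simulate_genome(cfg)
  ann <- simulate_annotation(cfg, g)
  occ <- simulate_occupancy(cfg, ann, g)
  calls <- call_pauses(occ$track, pda_params(seed = 17))
  expect_lte(sum(calls$significant) / max(nrow(calls), 1), 0.05)
})

test_that("downsampling thins binomially and never exceeds input", {
  tr <- make_track(1:1000, rep(10L, 1000))
  expect_identical(downsample(tr, 1, seed = 1), tr)
  half <- downsample(tr, 0.5, seed = 1)
  expect_lt(abs(sum(half$count) - 5000), 3 * sqrt(10000 * 0.25))
  j <- dplyr::left_join(tibble::as_tibble(half), tibble::as_tibble(tr),
                        by = c("contig", "strand", "pos"),
                        suffix = c("_d", "_o"))
  expect_true(all(j$count_d <= j$count_o))
  expect_identical(tibble::as_tibble(downsample(tr, 0.5, seed = 1)),
                   tibble::as_tibble(half))
})

test_that("Fisher two-sided p matches hypergeometric enumeration and edge rules", {
  expect_equal(fisher_exact_2x2(matrix(0, 2, 2)), 1)
  expect_equal(fisher_exact_2x2(matrix(c(5, 0, 0, 5), 2)), 2 / 252,
               tolerance = 1e-12)
  expect_equal(fisher_exact_2x2(matrix(c(1, 9, 11, 3), 2, byrow = TRUE)),
               enumerate_fisher_p(matrix(c(1, 9, 11, 3), 2, byrow = TRUE)),
               tolerance = 1e-12)
  set.seed(4)
  for (i in 1:25) {
    tab <- matrix(sample(0:15, 4, replace = TRUE), 2)
    expect_equal(fisher_exact_2x2(tab), enumerate_fisher_p(tab),
                 tolerance = 1e-10)
    expect_equal(fisher_exact_2x2(tab), stats::fisher.test(tab)$p.value,
                 tolerance = 1e-7)
  }
})

test_that("replicate overlap percentages and Fisher test behave", {
  mk <- function(pos, sig) {
    x <- tibble::tibble(contig = "chr1", strand = "+", pos = as.integer(pos),
                        count = 5L, M = 20L, l = 10L, p = 0.01, q = 0.01,
                        significant = sig, method = "exact")
    class(x) <- c("pause_calls", class(x))
    x
  }
  a <- mk(1:20, rep(c(TRUE, FALSE), 10))
  expect_error(replicate_overlap(list(a)), "at least 2")
  same <- replicate_overlap(list(a, a))
  expect_equal(same$percent_shared, c(100, 100))
  expect_lt(same$fisher_p, 0.01)
  disj <- replicate_overlap(list(mk(1:10, TRUE), mk(11:20, TRUE)))
  expect_equal(disj$n_common, 0L)
  # partial overlap: rep1 candidates 1..20 (sig odd), rep2 1..10 (sig 1..6)
  b <- mk(1:10, c(rep(TRUE, 6), rep(FALSE, 4)))
  ov <- replicate_overlap(list(a, b))
  # common significant: odd positions in 1..6 -> {1,3,5}
  expect_equal(ov$n_common, 3L)
  # rep1: significant restricted to joint candidates 1..10 -> {1,3,5,7,9}
  expect_equal(ov$percent_shared[1], 100 * 3 / 5)
  expect_equal(ov$percent_shared[2], 100 * 3 / 6)
})
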