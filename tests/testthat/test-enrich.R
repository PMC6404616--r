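test_that("upper-tail hypergeometric matches exhaustive draw enumeration", {
  # every size-n subset of a small universe, counted directly
  for (N in c(6, 8, 10)) {
    for (n in c(2, N %/% 2)) {
      for (K in c(1, 3, N - 1)) {
        for (k in 0:min(n, K)) {
          expect_equal(hypergeom_upper_tail(k, n, K, N),
                       hyper_tail_enumerate(k, n, K, N),
                       tolerance = 1e-12,
                       label = sprintf("k=%d n=%d K=%d N=%d", k, n, K, N))
        }
      }
    }
  }
  expect_equal(hypergeom_upper_tail(3, 4, 5, 10), 11 / 42,
               tolerance = 1e-12)
})

test_that("tail handles boundary cases and validates inputs", {
  expect_equal(hypergeom_upper_tail(0, 4, 5, 10), 1)
  expect_equal(hypergeom_upper_tail(5, 4, 5, 10), 0)   # k > min(n, K)
  expect_equal(hypergeom_upper_tail(2, 9, 3, 10), 1)   # k at the support floor
  expect_error(hypergeom_upper_tail(1, 11, 5, 10),
               class = "phenolscreen_value_error")
  expect_error(hypergeom_upper_tail(-1, 4, 5, 10),
               class = "phenolscreen_value_error")
})

test_that("tail agrees with the survival function at genome scale", {
  # independent cross-check against the distribution implementation in stats
  cases <- expand.grid(k = c(1, 5, 12, 40), n = c(100, 300),
                       K = c(30, 250), N = 5000)
  for (i in seq_len(nrow(cases))) {
    with(cases[i, ], expect_equal(
      hypergeom_upper_tail(k, n, K, N),
      stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE),
      tolerance = 1e-12))
  }
})

test_that("the underlying point masses sum to one", {
  for (case in list(c(10, 7, 4), c(25, 12, 9), c(30, 30, 15))) {
    N <- case[1]; n <- case[2]; K <- case[3]
    pmf <- vapply(0:min(n, K), function(k) {
      choose(K, k) * choose(N - K, n - k) / choose(N, n)
    }, numeric(1))
    expect_equal(sum(pmf), 1, tolerance = 1e-12)
  }
})

test_that("enrichment p decreases monotonely in the overlap", {
  p <- hypergeom_upper_tail(0:20, 50, 100, 2000)
  expect_true(all(diff(p) <= 0))
})

test_that("p-value correction implements bonferroni and monotone BH", {
  expect_equal(correct_pvalues(rep(0.01, 10), "bonferroni")[1], 0.1)
  expect_equal(correct_pvalues(0.03, "bonferroni"), 0.03)
  expect_equal(correct_pvalues(0.03, "bh"), 0.03)
  p <- withr::with_seed(2, stats::runif(50))
  bh <- correct_pvalues(p, "bh")
  expect_true(!is.unsorted(bh[order(p)]))
  expect_true(all(bh >= p))
  expect_error(correct_pvalues(c(0.5, 0)), class = "phenolscreen_value_error")
})

test_that("gene-set enrichment handles full terms, disjoint queries and warnings", {
  universe <- sprintf("g%02d", 1:20)
  tm <- list(FULL = list(name = "full", genes = universe[1:5]),
             OTHER = list(name = "other", genes = universe[10:14]))
  ann <- gene_annotation(universe, term_map = tm)
  res <- enrich_gene_sets(universe[1:5], ann)
  full <- res[res$term == "FULL", ]
  # query = term = 5 of 20: single point in the tail
  expect_equal(full$p_raw, 1 / choose(20, 5), tolerance = 1e-12)
  expect_equal(full$k, 5)

  res2 <- enrich_gene_sets(universe[15:20], ann)
  expect_false(any(res2$significant[res2$term == "FULL"]))

  expect_warning(res3 <- enrich_gene_sets(c(universe[1:3], "gX"), ann),
                 class = "phenolscreen_query_outside_universe")
  expect_equal(res3$n[1], 3)
  expect_true(all(res3$p_corrected >= res3$p_raw))
})

test_that("a strongly planted term is detected in nearly every replicate", {
  hits <- 0L
  n_seeds <- 20L
  for (s in seq_len(n_seeds)) {
    u <- simulate_annotation_universe(n_genes = 2000, n_terms = 100,
                                      term_size_range = c(50, 50),
                                      query_size = 300,
                                      planted = c(T0001 = 4),
                                      flag_rates = NULL, seed = 400 + s)
    res <- enrich_gene_sets(u$query, u$annotation)
    top <- res[1, ]
    if (top$term == "T0001" && top$significant) hits <- hits + 1L
  }
  expect_gte(hits / n_seeds, 0.95)
})

test_that("flag families are tested and corrected separately", {
  u <- simulate_annotation_universe(n_genes = 500, n_terms = 5,
                                    query_size = 100, seed = 9)
  res <- enrich_gene_sets(u$query, u$annotation)
  expect_setequal(unique(res$family), c("term", "flag"))
  for (fam in c("term", "flag")) {
    sub <- res[res$family == fam, ]
    expect_equal(sub$p_corrected,
                 correct_pvalues(sub$p_raw, "bonferroni"))
  }
})

test_that("bubble layouts keep radius and distance proportional to gene count", {
  res <- data.frame(term = c("T1", "T2"), name = c("a", "b"),
                    family = "term", k = c(10, 20), n = 100,
                    K = c(30, 60), N = 1000,
                    p_raw = c(1e-6, 1e-5), p_corrected = c(1e-5, 1e-4),
                    method = "bonferroni", significant = TRUE)
  lay <- bubble_layout(res)
  expect_equal(lay$radius[lay$term == "T2"],
               2 * lay$radius[lay$term == "T1"])
  expect_equal(lay$radial_distance[lay$term == "T2"],
               2 * lay$radial_distance[lay$term == "T1"])

  empty <- lay[0, c("term", "k", "p_corrected")]
  empty$significant <- logical(0)
  expect_equal(nrow(bubble_layout(empty)), 0)

  res$significant <- c(TRUE, FALSE)
  expect_error(bubble_layout(res), class = "phenolscreen_value_error")
})

test_that("twelve synthetic terms lay out without circle overlaps", {
  u <- simulate_annotation_universe(
    n_genes = 2000, n_terms = 12, term_size_range = c(30, 80),
    query_size = 300,
    planted = stats::setNames(rep(4, 12), sprintf("T%04d", 1:12)),
    flag_rates = NULL, seed = 2)
  res <- enrich_gene_sets(u$query, u$annotation)
  lay <- bubble_layout(res[res$significant, ])
  m <- nrow(lay)
  expect_gte(m, 10)
  for (i in seq_len(m - 1)) for (j in (i + 1):m) {
    gap <- sqrt((lay$x[i] - lay$x[j])^2 + (lay$y[i] - lay$y[j])^2) -
      (lay$radius[i] + lay$radius[j])
    expect_gte(gap, 0)
  }
})
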