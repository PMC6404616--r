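test_that("overlap accounting is exact set arithmetic with inclusion-exclusion", {
  sets <- list(A = sprintf("g%d", 1:3), B = sprintf("g%d", 4:7))
  ov <- overlap_analysis(sets)
  expect_equal(ov$union_size, 7)
  expect_equal(unname(ov$unique_counts), c(3, 4))

  # random triples always satisfy inclusion-exclusion
  for (s in 1:20) {
    sets3 <- withr::with_seed(s, lapply(1:3, function(i) {
      sample(sprintf("g%03d", 1:150), sample(20:80, 1))
    }))
    names(sets3) <- c("A", "B", "C")
    ov3 <- overlap_analysis(sets3)
    pw <- ov3$pairwise
    expect_equal(ov3$union_size,
                 sum(ov3$sizes) - sum(pw[upper.tri(pw)]) + ov3$triple)
    expect_equal(unname(ov3$unique_counts["A"]),
                 ov3$sizes[["A"]] - pw["A", "B"] - pw["A", "C"] + ov3$triple)
  }
})

test_that("printed marginal counts reconstruct unique and union counts", {
  pw <- matrix(NA, 3, 3,
               dimnames = list(c("BHA", "BHT", "BPA"),
                               c("BHA", "BHT", "BPA")))
  pw["BHA", "BPA"] <- 74; pw["BHA", "BHT"] <- 5
  ov <- overlap_from_counts(c(BHA = 300, BHT = 15, BPA = 117),
                            pairwise = pw, triple = 2)
  expect_equal(unname(ov$unique_counts["BHA"]), 223)
  # the BHT/BPA overlap was not supplied: dependent quantities stay NA
  expect_true(is.na(ov$unique_counts[["BHT"]]))
  expect_true(is.na(ov$union_size))

  ov2 <- overlap_from_counts(c(BHA = 154, BPA = 159),
                             unique_counts = c(BHA = 145))
  expect_equal(ov2$union_size, 304)
  expect_equal(unname(ov2$unique_counts["BPA"]), 150)
})

test_that("profile matrices are clipped log2 GSVs with NO_CALL rows dropped", {
  scores <- data.frame(strain = rep(c("a", "b", "c"), each = 2),
                       compound = rep(c("X", "Y"), 3),
                       gsv = c(1, 2, 0.5, 0, 1, NA))
  expect_message(pm <- build_profile_matrix(scores, floor = 0.05),
                 "dropping 1 strain")
  expect_equal(dim(pm), c(2, 2))
  expect_equal(pm["a", "X"], 0)
  expect_equal(pm["a", "Y"], 1)
  expect_equal(pm["b", "X"], -1)
  expect_equal(pm["b", "Y"], log2(0.05))  # clipped at the floor
  expect_error(build_profile_matrix(scores[0, ]),
               class = "phenolscreen_empty_matrix_error")
})

test_that("average-linkage clustering matches a hand calculation", {
  # d(a,b) = 1, d(a,c) = 3, d(b,c) = 2: merge {a,b} at 1,
  # then {ab}-c at mean(3, 2) = 2.5
  m <- rbind(a = c(0, 0), b = c(0, 1), c = c(0, 3))
  cl <- hierarchical_cluster(m)
  expect_equal(cl$height, c(1, 2.5))
  expect_equal(cl$merge[1, ], c(-1, -2))
  expect_equal(cl$merge[2, ], c(-3, 1))

  ident <- rbind(x = c(1, 2, 3), y = c(1, 2, 3), z = c(9, 9, 9))
  expect_equal(hierarchical_cluster(ident)$height[1], 0)

  expect_error(hierarchical_cluster(m[1, , drop = FALSE]),
               class = "phenolscreen_value_error")
  m_bad <- m; m_bad[1, 1] <- NA
  expect_error(hierarchical_cluster(m_bad),
               class = "phenolscreen_value_error")
})

test_that("clustering is invariant to row permutation up to relabeling", {
  m <- withr::with_seed(4, matrix(stats::rnorm(30), nrow = 10,
                                  dimnames = list(sprintf("r%02d", 1:10),
                                                  NULL)))
  cl1 <- hierarchical_cluster(m)
  perm <- withr::with_seed(5, sample(10))
  cl2 <- hierarchical_cluster(m[perm, ])
  coph1 <- as.matrix(stats::cophenetic(cl1$hclust))
  coph2 <- as.matrix(stats::cophenetic(cl2$hclust))
  expect_equal(coph2[rownames(coph1), rownames(coph1)], coph1)
  expect_setequal(cl2$labels, cl1$labels)
})

test_that("average-linkage heights are ultrametric-consistent on fixtures", {
  m <- withr::with_seed(6, matrix(stats::rnorm(24), nrow = 8,
                                  dimnames = list(letters[1:8], NULL)))
  cl <- hierarchical_cluster(m)
  coph <- as.matrix(stats::cophenetic(cl$hclust))
  for (i in 1:8) for (j in 1:8) for (k in 1:8) {
    expect_lte(coph[i, j], max(coph[i, k], coph[k, j]) + 1e-12)
  }
})

test_that("two planted effect regimes split into the top-level clusters", {
  hits <- 0L
  n_seeds <- 20L
  for (s in seq_len(n_seeds)) {
    sim <- simulate_screen(n_strains = 40, compounds = "BHA",
                           frac_sensitive = 0.5,
                           frac_resistant = 0, noise_cv = 0.15,
                           n_replicates = 3, seed = 100 + s,
                           effect_ranges = list(sensitive = c(0.15, 0.25),
                                                resistant = c(2.5, 6)))
    sc <- score_screen(sim$densities)
    pm <- build_profile_matrix(sc[sc$strain != "wt", ])
    cl <- hierarchical_cluster(pm)
    groups <- stats::cutree(cl$hclust, k = 2)
    truth <- sim$truth$effect[names(groups), "BHA"] <= 0.5
    agree <- max(mean((groups == 1) == truth), mean((groups == 2) == truth))
    if (agree == 1) hits <- hits + 1L
  }
  expect_gte(hits / n_seeds, 0.95)
})

test_that("cluster trees export as readable Newick", {
  m <- rbind(a = c(0, 0), b = c(0, 1), c = c(0, 3))
  cl <- hierarchical_cluster(m)
  f <- withr::local_tempfile(fileext = ".nwk")
  write_cluster_newick(cl, f)
  tree <- ape::read.tree(f)
  expect_setequal(tree$tip.label, c("a", "b", "c"))
})
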