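test_that("GSV is the wild-type-normalized treated/untreated density ratio", {
  expect_equal(compute_gsv(80, 80, 100, 100), 1.0)
  expect_equal(compute_gsv(0, 90, 100, 100), 0.0)
  expect_equal(compute_gsv(40, 80, 90, 90), 0.5)
  # scale-free: rescaling either plate's densities leaves the GSV unchanged
  expect_equal(compute_gsv(40 * 7, 80 * 3, 90 * 7, 90 * 3),
               compute_gsv(40, 80, 90, 90))
  expect_error(compute_gsv(10, 0, 100, 100),
               class = "phenolscreen_undefined_gsv_error")
  expect_error(compute_gsv(10, 10, 0, 100),
               class = "phenolscreen_plate_normalization_error")
})

test_that("classification uses inclusive boundaries and is monotone", {
  expect_identical(classify_sensitivity(c(0.5, 2.0, 1.0, 0.11, 24.03)),
                   c("SENSITIVE", "RESISTANT", "NORMAL",
                     "SENSITIVE", "RESISTANT"))
  expect_identical(classify_sensitivity(NA_real_), "NO_CALL")
  # monotone: a smaller gsv never gets a "more resistant" call
  gsv <- sort(withr::with_seed(1, stats::runif(200, 0, 5)))
  rank <- match(classify_sensitivity(gsv),
                c("SENSITIVE", "NORMAL", "RESISTANT"))
  expect_true(!is.unsorted(rank))
})

test_that("replicate aggregation averages defined trials", {
  expect_equal(aggregate_replicates(c(0.4, 0.6))$gsv, 0.5)
  expect_equal(aggregate_replicates(0.5)$gsv, 0.5)
  expect_equal(aggregate_replicates(c(0.2, 0.3, 0.4))$gsv, 0.3)
  gs <- aggregate_replicates(c(0.2, NA, 0.4))
  expect_equal(gs$gsv, 0.3)
  expect_equal(gs$n_replicates, 2)
  nc <- aggregate_replicates(c(NA_real_, NA_real_))
  expect_true(is.na(nc$gsv))
  expect_equal(nc$n_replicates, 0)
})

test_that("consensus calls require m concordant trials and break ties to NO_CALL", {
  S <- "SENSITIVE"; N <- "NORMAL"; R <- "RESISTANT"
  expect_equal(consensus_call(c(S, S, S, N), 3), S)
  expect_equal(consensus_call(c(S, S, N, N), 3), "NO_CALL")
  expect_equal(consensus_call(S, 1), S)
  expect_equal(consensus_call(c(S, S, R, R), 2), "NO_CALL")  # tie
  expect_equal(consensus_call(c(S, "NO_CALL", "NO_CALL"), 2), "NO_CALL")
  expect_error(consensus_call(c(S, N), 3),
               class = "phenolscreen_config_error")
})

test_that("screening-concentration selection applies the 10% rule", {
  summ <- data.frame(concentration = c(0.1, 0.3, 0.9),
                     frac_wt_like = c(0.50, 0.10, 0.01),
                     frac_growing = c(0.95, 0.55, 0.05))
  pick <- select_screening_concentration(summ)
  expect_equal(pick$concentration, 0.3)
  dead <- data.frame(concentration = c(1, 2),
                     frac_wt_like = c(0, 0), frac_growing = c(0.01, 0))
  expect_error(select_screening_concentration(dead),
               class = "phenolscreen_no_valid_concentration_error")
})

test_that("selection on a simulated library matches the exhaustive-scan optimum", {
  # library of strains with a spectrum of IC50s; at each candidate dose a
  # strain is wt-like if barely inhibited, growing if not fully inhibited
  strain_ic50 <- withr::with_seed(5, stats::rlnorm(400, log(0.3), 0.8))
  concs <- c(0.05, 0.1, 0.2, 0.4, 0.8, 1.6)
  tab <- do.call(rbind, lapply(concs, function(cc) {
    g <- 1 / (1 + (cc / strain_ic50)^2)
    data.frame(concentration = cc, wt_like = g > 0.9, grows = g > 0.1)
  }))
  pick <- select_screening_concentration(tab)
  # brute-force scan over candidates
  scan <- vapply(concs, function(cc) {
    g <- 1 / (1 + (cc / strain_ic50)^2)
    c(wt = mean(g > 0.9), grow = mean(g > 0.1))
  }, numeric(2))
  eligible <- concs[scan["grow", ] > 0.10]
  best <- eligible[which.min(abs(scan["wt", match(eligible, concs)] - 0.10))]
  expect_equal(pick$concentration, best)
})

test_that("scored screens self-normalize the wild type and rescale freely", {
  sim <- simulate_screen(n_strains = 40, noise_cv = 0.1, n_replicates = 2,
                         seed = 17)
  sc <- score_screen(sim$densities)
  expect_true(all(sc$gsv[sc$strain == "wt"] == 1))
  # global rescaling of all treated (or control) densities changes nothing
  d2 <- sim$densities
  d2$density_treated <- d2$density_treated * 123.4
  sc2 <- score_screen(d2)
  expect_equal(sc2$gsv, sc$gsv)
})

test_that("noiseless screens reproduce the planted calls exactly", {
  sim <- simulate_screen(n_strains = 200, noise_cv = 0, n_replicates = 2,
                         seed = 3)
  sc <- score_screen(sim$densities)
  called <- paste(sc$strain, sc$compound)[sc$call == "SENSITIVE"]
  truth <- paste(sim$truth$sensitive_truth$strain,
                 sim$truth$sensitive_truth$compound)
  expect_setequal(called, truth)
  called_r <- paste(sc$strain, sc$compound)[sc$call == "RESISTANT"]
  truth_r <- paste(sim$truth$resistant_truth$strain,
                   sim$truth$resistant_truth$compound)
  expect_setequal(called_r, truth_r)
  # consensus agrees in the noiseless limit
  expect_identical(sc$call, sc$consensus_call)
})

test_that("zero untreated densities surface as NO_CALL, never silently", {
  sim <- simulate_screen(n_strains = 10, noise_cv = 0, n_replicates = 2,
                         seed = 2)
  d <- sim$densities
  d$density_control[d$strain == "strain00003"] <- 0
  expect_warning(sc <- score_screen(d),
                 class = "phenolscreen_undefined_gsv")
  expect_true(all(sc$call[sc$strain == "strain00003"] == "NO_CALL"))
  expect_true(all(is.na(sc$gsv[sc$strain == "strain00003"])))
})
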