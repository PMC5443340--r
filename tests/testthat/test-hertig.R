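fixture <- hertig_fixture()

test_that("canonical case set carries the published margins", {
  expect_equal(sum(fixture$n), 107)
  expect_equal(as.vector(tapply(fixture$n, fixture$stratum, sum)),
               c(9, 15, 47, 36))
  expect_equal(as.vector(tapply(fixture$n, fixture$outcome, sum)),
               c(73, 24, 10))
  embryos <- sum(fixture$n[fixture$outcome != "none"])
  expect_equal(embryos, 34)
  expect_equal(round_half_up(100 * embryos / 107, 1), 31.8)
})

test_that("the embryo-loss derivation reproduces the 6:15:15 analysis", {
  e <- derive_estimates(36, 15, 6, 4, 4)
  expect_true(e$valid && e$consistent)
  expect_equal(e$fertility, 100 * 15 / 36)
  expect_equal(e$sterility, 100 * 15 / 36)
  expect_equal(e$infertility, 100 * 6 / 36)
  expect_equal(round_half_up(e$fertilisation_rate, 1), 83.3)
  expect_equal(e$abnormal_total, 15)
  expect_equal(e$failed_implant, 9)
  expect_equal(e$preimplant_loss, 30)
  expect_equal(e$preimplant_survival, 70)
  expect_equal(round_half_up(e$postimplant_survival, 1), 71.4)
  expect_equal(round_half_up(e$detection_rate, 1), 58.3)
})

test_that("counterfactual pre-implantation samples swing the loss estimate", {
  # 3 abnormal of 8 -> pre-implantation loss 12.5%, printed as 13%
  e3 <- derive_estimates(36, 15, 6, 5, 3)
  expect_equal(e3$preimplant_loss, 12.5)
  expect_equal(round_half_up(e3$preimplant_loss), 13)
  # 5 of 8 -> 47.5% (prints 48%) with an impossible 111% fertilisation rate
  e5 <- derive_estimates(36, 15, 6, 3, 5)
  expect_equal(e5$preimplant_loss, 47.5)
  expect_equal(round_half_up(e5$fertilisation_rate), 111)
  expect_lt(e5$infertility, 0)
  # no abnormal embryos anywhere: nothing implied to fail
  e0 <- derive_estimates(36, 15, 0, 4, 0)
  expect_true(e0$valid)
  expect_equal(e0$abnormal_total, 0)
  expect_equal(e0$failed_implant, 0)
  expect_equal(round_half_up(e0$fertility, 1), 41.7)
})

test_that("degenerate inputs yield flagged, not thrown, results", {
  expect_false(derive_estimates(36, 15, 6, 0, 4)$valid)  # all abnormal
  expect_false(derive_estimates(36, 15, 6, 0, 0)$valid)  # no pre-impl sample
  expect_false(derive_estimates(0, 0, 0, 4, 4)$valid)    # no late cases
  # observed abnormal implants above the implied total: computable but
  # inconsistent (negative implied implantation failures)
  e <- derive_estimates(36, 15, 10, 6, 2)
  expect_true(e$valid)
  expect_false(e$consistent)
  expect_lt(e$preimplant_loss, 0)
})

test_that("fertility + sterility + infertility is an algebraic identity", {
  set.seed(201)
  for (i in 1:100) {
    e <- derive_estimates(n_late = sample(1:60, 1), k_norm = sample(0:30, 1),
                          k_abn = sample(0:15, 1), m_norm = sample(1:10, 1),
                          m_abn = sample(0:9, 1))
    expect_equal(e$fertility + e$sterility + e$infertility, 100,
                 tolerance = 1e-9)
  }
})

test_that("pre-implantation loss increases with the abnormal fraction", {
  losses <- vapply(0:6, function(a) {
    derive_estimates(36, 15, 6, 8 - a, a)$preimplant_loss
  }, numeric(1))
  expect_true(all(diff(losses) > 0))
})

test_that("case-set mapping pools early strata and drops days 20-24", {
  expect_equal(unclass(estimates_from_caseset(fixture)),
               unclass(derive_estimates(36, 15, 6, 4, 4)))

  emptied <- fixture
  emptied$n[emptied$stratum == "days_25_plus"] <- 0
  expect_false(estimates_from_caseset(emptied)$valid)

  all_abn <- fixture
  pre <- all_abn$stratum %in% c("days_16_17", "days_18_19")
  all_abn$n[pre & all_abn$outcome == "abnormal"] <-
    all_abn$n[pre & all_abn$outcome == "abnormal"] +
    all_abn$n[pre & all_abn$outcome == "normal"]
  all_abn$n[pre & all_abn$outcome == "normal"] <- 0
  expect_false(estimates_from_caseset(all_abn)$valid)

  # the excluded stratum's counts do not influence the estimates
  perturbed <- fixture
  perturbed$n[perturbed$stratum == "days_20_24"] <- c(0, 40, 7)[
    match(perturbed$outcome[perturbed$stratum == "days_20_24"],
          c("none", "normal", "abnormal"))]
  expect_equal(estimates_from_caseset(perturbed)$preimplant_loss, 30)
})

test_that("balanced bootstrap is exactly balanced", {
  # a single pseudo-dataset must be a permutation of the original
  one <- balanced_bootstrap(fixture, 1, seed = 1)
  expect_equal(one[[1]]$n, fixture$n)

  B <- 50
  reps <- balanced_bootstrap(fixture, B, seed = 2)
  pooled <- Reduce(`+`, lapply(reps, `[[`, "n"))
  expect_equal(pooled, B * fixture$n)
  # balance forces the late-stratum count to average exactly 36
  late <- vapply(reps, function(d) sum(d$n[d$stratum == "days_25_plus"]),
                 numeric(1))
  expect_equal(mean(late), 36)
  expect_gt(stats::var(late), 0)  # but individual replicates vary

  expect_identical(balanced_bootstrap(fixture, 10, seed = 3),
                   balanced_bootstrap(fixture, 10, seed = 3))
})

test_that("bootstrap medians track the point estimates", {
  bs <- bootstrap_summary(fixture, n_datasets = 500, seed = 17)
  point <- estimates_from_caseset(fixture)
  s <- bs$summary
  for (i in seq_len(nrow(s))) {
    expect_lt(abs(s$median[i] - point[[s$quantity[i]]]), 2)
    expect_lte(s$lower[i], s$median[i])
    expect_lte(s$median[i], s$upper[i])
  }
  # a handful of replicates lack usable pre-implantation embryos
  expect_lt(bs$n_invalid, 0.1 * bs$n_datasets)
})

test_that("bootstrap intervals narrow with tenfold sample size", {
  big <- fixture
  big$n <- big$n * 10
  bs1 <- bootstrap_summary(fixture, n_datasets = 200, seed = 4)
  bs10 <- bootstrap_summary(big, n_datasets = 200, seed = 4)
  w1 <- bs1$summary$upper - bs1$summary$lower
  w10 <- bs10$summary$upper - bs10$summary$lower
  expect_true(all(w10 < w1))
})

test_that("Clopper-Pearson matches tail inversion and its boundaries", {
  ci <- clopper_pearson(21, 36)
  expect_equal(round_half_up(100 * ci$lower), 41)
  expect_equal(round_half_up(100 * ci$upper), 74)

  # brute-force oracle: invert the binomial tail probabilities directly
  lower_oracle <- uniroot(function(p) 1 - pbinom(20, 36, p) - 0.025,
                          c(1e-9, 1 - 1e-9), tol = 1e-12)$root
  upper_oracle <- uniroot(function(p) pbinom(21, 36, p) - 0.025,
                          c(1e-9, 1 - 1e-9), tol = 1e-12)$root
  expect_equal(ci$lower, lower_oracle, tolerance = 1e-6)
  expect_equal(ci$upper, upper_oracle, tolerance = 1e-6)

  expect_equal(clopper_pearson(0, 10)$lower, 0)
  expect_equal(clopper_pearson(10, 10)$upper, 1)
  expect_error(clopper_pearson(11, 10), "cannot exceed")
})

test_that("Agresti-Coull is symmetric at one half and nests inside exact", {
  ci <- agresti_coull(21, 36)
  expect_equal(round_half_up(100 * ci$lower), 42)
  expect_equal(round_half_up(100 * ci$upper), 73)

  sym <- agresti_coull(18, 36)
  expect_equal(sym$lower + sym$upper, 1, tolerance = 1e-12)

  cp <- clopper_pearson(21, 36)
  expect_gt(ci$lower, cp$lower)
  expect_lt(ci$upper, cp$upper)
})

test_that("percentile bounds equal brute-force sorted order statistics", {
  type7 <- function(x, p) {
    s <- sort(x)
    h <- (length(x) - 1) * p + 1
    lo <- floor(h)
    unname(s[lo] + (h - lo) * (s[pmin(lo + 1, length(x))] - s[lo]))
  }
  B <- 200
  reps <- balanced_bootstrap(fixture, B, seed = 5)
  fert <- vapply(reps, function(d) estimates_from_caseset(d)$fertility,
                 numeric(1))
  fert <- fert[!is.na(fert)]
  bs <- bootstrap_summary(fixture, n_datasets = B, seed = 5)
  row <- bs$summary[bs$summary$quantity == "fertility", ]
  expect_equal(row$lower, type7(fert, 0.025), tolerance = 1e-10)
  expect_equal(row$upper, type7(fert, 0.975), tolerance = 1e-10)
})

test_that("case tables expand to one row per case", {
  long <- as_case_table(fixture)
  expect_equal(nrow(long), 107)
  expect_equal(sum(long$outcome == "normal"), 24)
})
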