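test_that("contingency counts match the record-level definition", {
  # 10 records: drug in 4, event in 3, overlap 2
  st <- mini_store(10,
    drug = c("ibrutinib", "ibrutinib", "IMBRUVICA", "ibrutinib",
             rep("warfarin", 6)),
    pt = c("Atrial fibrillation", "Atrial fibrillation", "Rash", "Nausea",
           "Atrial fibrillation", rep("Rash", 5)))
  cc <- build_contingency(st, ibrutinib, "Atrial fibrillation")
  expect_equal(cc$n_observed, 2)
  expect_equal(cc$n_drug, 4)
  expect_equal(cc$n_event, 3)
  expect_equal(cc$n_expected, 1.2)

  # event disjoint from the store
  cc0 <- build_contingency(st, ibrutinib, "Absent term")
  expect_equal(cc0$n_observed, 0)
  expect_equal(cc0$n_event, 0)
  expect_equal(cc0$n_expected, 0)

  # event everywhere: n_event = n_total, n_expected = n_drug
  cc1 <- build_contingency(st, ibrutinib, unique(st$events$pt))
  expect_equal(cc1$n_event, cc1$n_total)
  expect_equal(cc1$n_expected, cc1$n_drug)

  expect_error(contingency_counts(5, 4, 10, 20))   # observed > drug
  expect_error(contingency_counts(1, 4, 30, 20))   # event > total
})

test_that("counting agrees with a brute-force oracle on small stores", {
  for (seed in c(101, 202, 303, 404)) {
    sim <- simulate_reports(sim_config(
      n_reports = 20, drug_prevalence = 0.4,
      association_ratios = c("Atrial fibrillation" = 2), seed = seed))
    for (pts in list("Atrial fibrillation",
                     c("Cardiac failure", "Fatigue", "Headache"))) {
      got <- build_contingency(sim$store, ibrutinib, pts)
      want <- oracle_contingency(sim$store, ibrutinib, pts)
      expect_equal(got$n_observed, want$n_observed)
      expect_equal(got$n_drug, want$n_drug)
      expect_equal(got$n_event, want$n_event)
      expect_equal(got$n_expected, want$n_expected)
    }
  }
})

test_that("shrunken IC and ROR follow the 0.5-pseudocount formulas", {
  # observed == expected: ratio exactly 1
  cc <- contingency_counts(10, 20, 50, 100)
  expect_equal(ic_shrunken(cc)[["ic"]], 0)
  expect_equal(ror_shrunken(cc)[["ror"]], 1)

  # hand arithmetic: (7 + .5) / (1.5 + .5) = 3.75
  cc <- contingency_counts(7, 10, 300, 2000)
  expect_equal(ic_shrunken(cc)[["ic"]], log2(3.75))
  expect_equal(ror_shrunken(cc)[["ror"]], 3.75)

  # interval bounds at the published DSN row scale (n = 51, ic = 0.53)
  ic <- ic_shrunken(contingency_counts(51, 51, 3524, 100000))
  expect_equal(ic[["ic025"]], ic[["ic"]] - 3.3 * 51.5^-0.5 - 2 * 51.5^-1.5)
  expect_equal(ic[["ic975"]], ic[["ic"]] + 2.4 * 51.5^-0.5 - 0.5 * 51.5^-1.5)

  # zero observed: IC defined, ROR bounds degenerate
  cc0 <- contingency_counts(0, 10, 10, 100)
  expect_true(is.finite(ic_shrunken(cc0)[["ic"]]))
  r0 <- ror_shrunken(cc0)
  expect_equal(r0[["ror025"]], 0)
  expect_equal(r0[["ror975"]], Inf)
})

test_that("ror equals 2^ic to machine precision for any counts", {
  set.seed(42)
  for (i in 1:200) {
    n_total <- sample(10:100000, 1)
    n_drug <- sample.int(n_total, 1)
    n_event <- sample.int(n_total, 1)
    n_obs <- sample.int(min(n_drug, n_event), 1)
    cc <- contingency_counts(n_obs, n_drug, n_event, n_total)
    expect_equal(ror_shrunken(cc)[["ror"]], 2^ic_shrunken(cc)[["ic"]],
                 tolerance = 1e-12)
  }
})

test_that("IC is monotone in observed and expected counts", {
  ic_at <- function(obs, drug) ic_shrunken(
    contingency_counts(obs, drug, 1000, 10000))[["ic"]]
  # increasing in n_observed at fixed expected
  obs <- 1:50
  expect_true(all(diff(vapply(obs, ic_at, 1, drug = 500)) > 0))
  # decreasing in n_expected at fixed observed
  drugs <- seq(100, 5000, by = 100)
  expect_true(all(diff(vapply(drugs, ic_at, 1, obs = 10)) < 0))
  # CI half-width shrinks as 1/sqrt(n): quadrupling n halves the width
  w <- function(obs) {
    ic <- ic_shrunken(contingency_counts(obs, obs, 1000, 100000))
    ic[["ic975"]] - ic[["ic025"]]
  }
  expect_equal(w(100) / w(400), 2, tolerance = 0.01)
})

test_that("signal classification applies both bounds and the expected gate", {
  crit <- signal_criteria()
  svt <- list(ic025 = 3.02, ror025 = 8.16, n_expected = 300)
  htn <- list(ic025 = -0.14, ror025 = 0.92, n_expected = 1300)
  expect_true(classify_signal(svt, crit))
  expect_false(classify_signal(htn, crit))
  # expected-count gate blocks otherwise-positive pairs
  expect_false(classify_signal(list(ic025 = 0.5, ror025 = 1.4,
                                    n_expected = 2), crit))
  # OR variant needs only one disproportionality bound
  mixed <- list(ic025 = 0.5, ror025 = 0.9, n_expected = 10)
  expect_false(classify_signal(mixed, crit))
  expect_true(classify_signal(mixed, signal_criteria(combine = "or")))
})

test_that("screening flags a planted association and only that one", {
  cfg <- sim_config(n_reports = 50000,
                    association_ratios = c("Atrial fibrillation" = 8),
                    seed = 71)
  sim <- simulate_reports(cfg)
  dd <- deduplicate(sim$store)
  sets <- lapply(sim$truth$pt, identity)
  names(sets) <- sim$truth$pt
  scr <- dispro_screen(dd, ibrutinib, sets)
  res <- as.data.frame(scr)
  expect_s3_class(scr, "dispro_screen")
  expect_true(res$is_signal[res$event == "Atrial fibrillation"])
  expect_false(any(res$is_signal[res$event != "Atrial fibrillation"]))
  # sorted by IC descending; planted signal on top
  expect_equal(res$event[1], "Atrial fibrillation")
  expect_true(!is.unsorted(rev(res$ic)))
  # an empty event set yields a zero row, never a signal
  scr0 <- dispro_screen(dd, ibrutinib, list(nothing = character(0)))
  expect_equal(as.data.frame(scr0)$n_observed, 0)
  expect_false(as.data.frame(scr0)$is_signal)
})

test_that("screen object supports the standard estimator methods", {
  sim <- simulate_reports(sim_config(n_reports = 2000, seed = 5))
  scr <- dispro_screen(sim$store, ibrutinib,
                       list(AF = "Atrial fibrillation", CF = "Cardiac failure"))
  expect_named(coef(scr))
  expect_equal(sort(names(coef(scr))), c("AF", "CF"))
  expect_output(print(scr), "Disproportionality screen")
  expect_output(summary(scr), "event")
  pdf(NULL)
  expect_silent(plot(scr))
  dev.off()
})

test_that("IC trend accumulates reports over receive years", {
  sim <- simulate_reports(sim_config(n_reports = 30000,
                                     association_ratios = c("Atrial fibrillation" = 8),
                                     seed = 31))
  dd <- deduplicate(sim$store)
  tr <- ic_trend(dd, ibrutinib, "Atrial fibrillation", 2014:2021)
  expect_equal(tr$year, 2014:2021)
  expect_true(!is.unsorted(tr$n_observed))
  # final cumulative window is the full store
  cc <- build_contingency(dd, ibrutinib, "Atrial fibrillation")
  ic_all <- ic_shrunken(cc)
  # a cumulative window through the last receive year covers the full store
  last_year <- max(as.integer(substr(dd$reports$receive_date, 1, 4)))
  tr_full <- ic_trend(dd, ibrutinib, "Atrial fibrillation", last_year)
  expect_equal(tr_full$ic, ic_all[["ic"]])
  # interval width narrows as data accrue
  w <- tr$ic975 - tr$ic025
  expect_lt(w[length(w)], w[2])
  # a year before the first record gives an empty row
  tr0 <- ic_trend(dd, ibrutinib, "Atrial fibrillation", 1990)
  expect_equal(tr0$n_observed, 0L)
})
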