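test_that("identical seeds reproduce the database exactly", {
  cfg <- sim_config(n_reports = 300, duplicate_rate = 0.1,
                    association_ratios = c("Cardiac failure" = 4), seed = 1)
  a <- simulate_reports(cfg)
  b <- simulate_reports(cfg)
  expect_identical(a$store$reports, b$store$reports)
  expect_identical(a$store$drugs, b$store$drugs)
  expect_identical(a$store$events, b$store$events)
  expect_identical(a$truth, b$truth)
})

test_that("invalid configurations are rejected with the offending fields", {
  expect_error(sim_config(n_reports = 0), "n_reports")
  expect_error(sim_config(drug_prevalence = 1.4), "drug_prevalence")
  expect_error(sim_config(association_ratios = c("Not a modelled PT" = 2)),
               "association_ratios")
  expect_error(sim_config(duplicate_rate = -0.1), "duplicate_rate")
  err <- tryCatch(sim_config(n_reports = 0, duplicate_rate = 2),
                  error = conditionMessage)
  expect_match(err, "n_reports")
  expect_match(err, "duplicate_rate")
  # filler events may not overlap the modelled PTs
  expect_error(sim_config(filler_pts = c("Fatigue", "Atrial fibrillation")),
               "filler_pts")
})

test_that("ground truth flags probability truncation", {
  cfg <- sim_config(background_event_probs = c("Atrial fibrillation" = 0.3,
                                               "Cardiac failure" = 0.01),
                    drug_prevalence = 0.05,
                    association_ratios = c("Atrial fibrillation" = 8),
                    n_reports = 50, seed = 2)
  truth <- simulate_reports(cfg)$truth
  expect_true(truth$truncated[truth$pt == "Atrial fibrillation"])  # 2.4 capped
  expect_false(truth$truncated[truth$pt == "Cardiac failure"])
})

test_that("duplicate injection then deduplication restores the count", {
  # key fields fully observed: the only dedup classes are injected ones
  no_miss <- list(sex = 0, age = 0, country = 0, outcomes = 0,
                  start_date = 0, event_onset = 0)
  cfg_dup <- sim_config(n_reports = 3000, duplicate_rate = 0.15,
                        missingness = no_miss, seed = 8)
  sim <- simulate_reports(cfg_dup)
  expect_gt(n_reports(sim$store), 3000)
  expect_equal(n_reports(deduplicate(sim$store)), 3000)

  # under field missingness the duplicate copies still collapse: a store
  # with injected duplicates deduplicates to the same count as one without
  with_dups <- simulate_reports(sim_config(n_reports = 3000,
                                           duplicate_rate = 0.15, seed = 8))
  base <- simulate_reports(sim_config(n_reports = 3000,
                                      duplicate_rate = 0, seed = 8))
  expect_gt(n_reports(with_dups$store), n_reports(base$store))
  expect_equal(n_reports(deduplicate(with_dups$store)),
               n_reports(deduplicate(base$store)))
})

test_that("missingness produces NA fields, never sentinel values", {
  cfg <- sim_config(n_reports = 2000,
                    missingness = list(sex = 0.5, age = 0.5, country = 0.5,
                                       outcomes = 0.5, start_date = 0.5,
                                       event_onset = 0.5), seed = 3)
  st <- simulate_reports(cfg)$store
  expect_true(anyNA(st$reports$sex) && anyNA(st$reports$age))
  expect_true(all(st$reports$sex %in% c("male", "female", NA)))
  expect_true(all(st$reports$age >= 0 & st$reports$age <= 130, na.rm = TRUE))
  expect_true(all(is.na(st$reports$event_onset) |
                    nchar(st$reports$event_onset) == 8))
  # every report still carries at least one event
  expect_true(all(st$reports$report_id %in% st$events$report_id))
})

test_that("planted reporting-rate ratios are recovered across 1..8", {
  # three modelled PTs per ratio; the median estimated shrunken ratio per
  # ratio level must land within 10% of the planted truth
  pts <- c("Hypertension", "Cardiac failure", "Cerebral haemorrhage",
           "Atrial fibrillation", "Cardiomyopathy", "Myocardial infarction",
           "Ventricular tachycardia", "Sinus node dysfunction",
           "Cardiac arrest", "Cerebral infarction", "Atrioventricular block",
           "Deep vein thrombosis")
  ratios <- rep(c(1, 2, 4, 8), each = 3)
  cfg <- sim_config(n_reports = 200000,
                    association_ratios = stats::setNames(ratios, pts),
                    seed = 20)
  sim <- simulate_reports(cfg)
  flag <- match_drug(sim$store, ibrutinib)
  est <- vapply(pts, function(p)
    ror_shrunken(build_contingency(sim$store, flag, p))[["ror"]], 1)
  med <- tapply(est, ratios, stats::median)
  expect_true(all(abs(med - c(1, 2, 4, 8)) / c(1, 2, 4, 8) < 0.10))
})

test_that("FAERS dialect fixtures carry the quarterly table layout", {
  sim <- simulate_reports(sim_config(n_reports = 50, seed = 4))
  dir <- withr::local_tempdir()
  write_fixture(sim$store, dir, "faers_ascii")
  files <- list.files(dir)
  expect_setequal(files, c("demo.txt", "drug.txt", "reac.txt", "outc.txt",
                           "ther.txt"))
  hdr <- readLines(file.path(dir, "demo.txt"), n = 1)
  expect_equal(hdr, "primaryid|caseid|caseversion|event_dt|fda_dt|sex|age|age_cod|occr_country")
  # re-reading preserves the record structure (ages in years survive)
  back <- read_reports(dir, "faers_ascii")
  expect_equal(n_reports(back), 50)
  expect_equal(back$reports$age, sim$store$reports$age)
  expect_equal(back$reports$sex, sim$store$reports$sex)
  expect_setequal(back$events$pt, sim$store$events$pt)

  # an empty collection writes headers-only files
  one <- mini_store(1)
  empty <- structure(list(reports = one$reports[0, ], drugs = one$drugs[0, ],
                          events = one$events[0, ]), class = "report_store")
  dir2 <- withr::local_tempdir()
  write_fixture(empty, dir2, "simple_tsv")
  expect_equal(length(readLines(file.path(dir2, "reports.tsv"))), 1L)
  expect_equal(readLines(file.path(dir2, "events.tsv")), "report_id\tpt")
})
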