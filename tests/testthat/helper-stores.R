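# shared fixtures, all built in code

ibrutinib <- drug_synonyms("ibrutinib", c("IMBRUVICA", "PCI-32765"))

toy_dict <- function() {
  meddra_dictionary(system.file("extdata", "smq_map.tsv", package = "pvsignal"),
                    system.file("extdata", "soc_map.tsv", package = "pvsignal"))
}

# published SMQ-level screen summary (ibrutinib, FAERS 2014-2021): the
# regression reference for the statistic and interval formulas
reference_screen <- function() {
  utils::read.table(system.file("extdata", "ibrutinib_cv_smq_reference.tsv",
                                package = "pvsignal"),
                    sep = "\t", header = TRUE, quote = "",
                    stringsAsFactors = FALSE)
}

# minimal store builder: one drug name + one PT per report unless overridden
mini_store <- function(n, drug = rep("aspirin", n), pt = rep("Headache", n),
                       sex = rep("male", n), age = rep(60, n),
                       country = rep("US", n),
                       receive = rep("20200101", n),
                       onset = rep(NA_character_, n),
                       start = rep(NA_character_, n),
                       end = rep(NA_character_, n),
                       outcomes = rep(NA_character_, n),
                       id = sprintf("r%03d", seq_len(n))) {
  report_store(
    data.frame(report_id = id, sex = sex, age = age, country = country,
               receive_date = receive, event_onset = onset,
               outcomes = outcomes, stringsAsFactors = FALSE),
    data.frame(report_id = id, reported_name = drug, role = "suspect",
               start_date = start, end_date = end, dose_mg = NA_real_,
               indication_pt = NA_character_, stringsAsFactors = FALSE),
    data.frame(report_id = id, pt = pt, stringsAsFactors = FALSE))
}

# brute-force contingency oracle: per-record loop, independent of the
# package's vectorised counting and token matcher
oracle_contingency <- function(store, synonyms, event_pts) {
  n_obs <- n_drug <- n_event <- 0L
  for (id in store$reports$report_id) {
    nms <- store$drugs$reported_name[store$drugs$report_id == id]
    has_drug <- FALSE
    for (nm in nms) {
      toks <- strsplit(gsub("[^a-z0-9]+", " ", tolower(nm)), " +")[[1]]
      toks <- toks[nzchar(toks)]
      for (syn in synonyms$names) {
        syn_toks <- strsplit(gsub("[^a-z0-9]+", " ", tolower(syn)), " +")[[1]]
        k <- length(syn_toks)
        if (k > 0 && length(toks) >= k)
          for (i in seq_len(length(toks) - k + 1))
            if (all(toks[i:(i + k - 1)] == syn_toks)) has_drug <- TRUE
      }
    }
    pts <- store$events$pt[store$events$report_id == id]
    has_event <- any(pts %in% event_pts)
    n_drug <- n_drug + has_drug
    n_event <- n_event + has_event
    n_obs <- n_obs + (has_drug && has_event)
  }
  list(n_observed = n_obs, n_drug = n_drug, n_event = n_event,
       n_total = nrow(store$reports),
       n_expected = n_drug * n_event / nrow(store$reports))
}

# hand-written FAERS ASCII fixture: 3 cases across 5 pipe-delimited files,
# plus one superseded case version
write_faers_fixture <- function(dir) {
  dir.create(dir, showWarnings = FALSE)
  writeLines(c(
    "primaryid|caseid|caseversion|event_dt|fda_dt|sex|age|age_cod|occr_country",
    "1001|C1|1|20200409|20200501|M|63|YR|US",
    "1002|C2|1|202003|20200315|F|720|MON|FR",
    "999|C3|1|20190601|20191201|M|50|YR|DE",
    "1003|C3|2|20190701|20200101|UNK||YR|"), file.path(dir, "demo.txt"))
  writeLines(c(
    "primaryid|drug_seq|role_cod|drugname|dose_amt",
    "1001|1|PS|IMBRUVICA|420",
    "1001|2|C|rituximab|",
    "1002|1|PS|ibrutinib.|560",
    "1003|1|SS|Acalabrutinib|100"), file.path(dir, "drug.txt"))
  writeLines(c(
    "primaryid|pt",
    "1001|Atrial fibrillation",
    "1001|Fatigue",
    "1002|Cardiac failure",
    "1003|Hypertension",
    "999|Rash"), file.path(dir, "reac.txt"))
  writeLines(c(
    "primaryid|outc_cod",
    "1001|HO",
    "1001|DE",
    "1002|OT",
    "999|DE"), file.path(dir, "outc.txt"))
  writeLines(c(
    "primaryid|dsg_drug_seq|start_dt|end_dt",
    "1001|1|20200101|20200601",
    "1002|1|2019|"), file.path(dir, "ther.txt"))
  dir
}
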