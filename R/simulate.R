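#' Configuration for the synthetic spontaneous-report generator
#'
#' Defines a FAERS-like reporting database with known ground truth. The
#' association between the target drug and a PT is parameterised as a
#' reporting-rate \emph{lift}: for a PT with background probability \eqn{p}
#' and ratio \eqn{r}, drug-exposed reports list the PT with probability
#' \eqn{r p} while unexposed reports use \eqn{p (1 - \pi r) / (1 - \pi)}
#' (\eqn{\pi} = drug prevalence), which keeps the database-marginal rate at
#' \eqn{p} exactly. The observed-to-expected ratio of the drug-PT pair
#' therefore converges to \eqn{r} and the asymptotic IC is
#' \eqn{\log_2 r} — closed-form truth for validation. Probabilities that
#' leave \eqn{[0,1]} after the lift are capped and the PT is flagged
#' \code{truncated} in the ground-truth table.
#'
#' Every synthetic report additionally receives one filler event drawn from
#' \code{filler_pts} (disjoint from the modelled PTs), so the invariant that
#' a spontaneous report lists at least one adverse event always holds
#' without disturbing the modelled margins.
#'
#' @param n_reports number of reports before duplicate injection.
#' @param background_event_probs named vector of per-PT background reporting
#'   probabilities.
#' @param drug_prevalence probability a report lists the target drug.
#' @param association_ratios named vector of reporting-rate ratios for
#'   (subsets of) the modelled PTs; unnamed PTs default to ratio 1 (null).
#' @param duplicate_rate probability a report is emitted twice with
#'   identical dedup-key fields.
#' @param missingness named list of per-field missing probabilities
#'   (\code{sex}, \code{age}, \code{country}, \code{outcomes},
#'   \code{start_date}, \code{event_onset}).
#' @param tto_model list: \code{family} (\code{"lognormal"} or
#'   \code{"weibull"}) plus its parameters (\code{meanlog}/\code{sdlog} or
#'   \code{shape}/\code{scale}); defaults to a log-normal with median 99
#'   days and Q1-Q3 spread matching published onset spectra.
#' @param outcome_probs named vector of outcome-category probabilities.
#' @param drug_names names under which the target drug is reported.
#' @param filler_pts pool of filler PT names.
#' @param date_range two dates bounding therapy start dates.
#' @param seed integer seed; identical seeds give identical databases.
#' @return an object of class \code{sim_config}.
#' @export
sim_config <- function(n_reports = 10000,
                       background_event_probs = stats::setNames(
                         rep(0.01, 16), .default_sim_pts),
                       drug_prevalence = 0.05,
                       association_ratios = numeric(),
                       duplicate_rate = 0,
                       missingness = list(sex = 0.07, age = 0.45,
                                          country = 0.01, outcomes = 0.21,
                                          start_date = 0.5, event_onset = 0.5),
                       tto_model = list(family = "lognormal",
                                        meanlog = log(99), sdlog = 1.8),
                       outcome_probs = c(hospitalisation = 0.414,
                                         death = 0.210, other_serious = 0.361,
                                         disability = 0.008,
                                         life_threatening = 0.007),
                       drug_names = c("ibrutinib", "IMBRUVICA"),
                       filler_pts = c("Fatigue", "Nausea", "Headache",
                                      "Diarrhoea", "Pyrexia", "Rash",
                                      "Dizziness", "Vomiting", "Arthralgia",
                                      "Cough"),
                       date_range = as.Date(c("2014-01-01", "2021-06-30")),
                       seed = NULL) {
  cfg <- structure(as.list(environment()), class = "sim_config")
  bad <- character(0)
  chk <- function(cond, field) if (!isTRUE(all(cond))) bad <<- c(bad, field)
  chk(is.numeric(n_reports) && length(n_reports) == 1 && n_reports >= 1,
      "n_reports")
  chk(length(background_event_probs) > 0 &&
        !is.null(names(background_event_probs)) &&
        all(background_event_probs >= 0 & background_event_probs <= 1),
      "background_event_probs")
  chk(drug_prevalence >= 0 & drug_prevalence <= 1, "drug_prevalence")
  chk(all(association_ratios > 0) &&
        all(names(association_ratios) %in% names(background_event_probs)),
      "association_ratios")
  chk(duplicate_rate >= 0 & duplicate_rate <= 1, "duplicate_rate")
  chk(all(unlist(missingness) >= 0 & unlist(missingness) <= 1), "missingness")
  chk(tto_model$family %in% c("lognormal", "weibull"), "tto_model")
  chk(all(outcome_probs >= 0) && sum(outcome_probs) > 0, "outcome_probs")
  chk(!any(filler_pts %in% names(background_event_probs)), "filler_pts")
  if (length(bad))
    stop("invalid simulation config field(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  cfg
}

# modelled PTs used by the default config: cardiovascular-flavoured names
.default_sim_pts <- c(
  "Atrial fibrillation", "Supraventricular tachycardia",
  "Ventricular tachycardia", "Cardiac failure", "Cerebral haemorrhage",
  "Cerebral infarction", "Cardiomyopathy", "Atrioventricular block",
  "Myocardial infarction", "Electrocardiogram QT prolonged",
  "Sinus node dysfunction", "Hypertension", "Pulmonary hypertension",
  "Deep vein thrombosis", "Embolism arterial", "Cardiac arrest")

#' @export
print.sim_config <- function(x, ...) {
  planted <- x$association_ratios[x$association_ratios != 1]
  cat("<sim_config>", x$n_reports, "reports, drug prevalence",
      x$drug_prevalence, "\n  ", length(x$background_event_probs),
      "modelled PT(s),", length(planted), "with planted ratio != 1\n")
  invisible(x)
}

.draw_tto <- function(n, model) {
  switch(model$family,
         lognormal = stats::rlnorm(n, model$meanlog, model$sdlog),
         weibull = stats::rweibull(n, model$shape, model$scale))
}

#' Simulate a spontaneous-report database with known ground truth
#'
#' Draws independent reports under \code{\link{sim_config}}: drug exposure,
#' per-PT event inclusion with the configured rate lift, demographics,
#' therapy start dates, event onset dates following the configured
#' time-to-onset model, outcome codes, per-field missingness and optional
#' duplicate injection (duplicates copy all seven dedup-key fields).
#'
#' @param config a \code{\link{sim_config}}.
#' @return list with elements \code{store} (a \code{\link{report_store}})
#'   and \code{truth} (data frame \code{pt}, \code{ratio},
#'   \code{p_exposed}, \code{p_unexposed}, \code{truncated}).
#' @export
simulate_reports <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- as.integer(config$n_reports)
  prev <- config$drug_prevalence

  ids <- sprintf("R%07d", seq_len(n))
  exposed <- stats::runif(n) < prev

  bg <- config$background_event_probs
  ratios <- stats::setNames(rep(1, length(bg)), names(bg))
  ratios[names(config$association_ratios)] <- config$association_ratios
  p_exp_raw <- bg * ratios
  p_unexp_raw <- if (prev < 1) bg * (1 - prev * ratios) / (1 - prev) else bg
  p_exp <- pmin(p_exp_raw, 1)
  p_unexp <- pmin(pmax(p_unexp_raw, 0), 1)
  truth <- data.frame(pt = names(bg), ratio = unname(ratios),
                      p_exposed = unname(p_exp),
                      p_unexposed = unname(p_unexp),
                      truncated = unname(p_exp_raw > 1 | p_unexp_raw < 0 |
                                           p_unexp_raw > 1),
                      stringsAsFactors = FALSE)

  ev <- lapply(seq_along(bg), function(j) {
    p <- ifelse(exposed, p_exp[j], p_unexp[j])
    which(stats::runif(n) < p)
  })
  events <- data.frame(
    report_id = c(ids[unlist(ev)],
                  ids), # one filler event per report
    pt = c(rep(names(bg), lengths(ev)),
           sample(config$filler_pts, n, replace = TRUE)),
    stringsAsFactors = FALSE
  )

  # demographics loosely matching published ibrutinib report characteristics
  sex <- sample(c("male", "female"), n, TRUE, prob = c(0.626, 0.374))
  age <- round(pmin(pmax(stats::rnorm(n, 68, 10), 18), 100))
  country <- sample(c("US", "FR", "CA", "GB", "DE", "IT", "JP", "AU"), n,
                    TRUE, prob = c(0.741, 0.036, 0.032, 0.023, 0.021,
                                   0.06, 0.05, 0.037))
  start <- config$date_range[1] +
    floor(stats::runif(n) * as.numeric(diff(config$date_range)))
  tto <- round(.draw_tto(n, config$tto_model))
  onset <- start + tto
  receive <- onset + stats::rpois(n, 30)
  op <- config$outcome_probs / sum(config$outcome_probs)
  outcomes <- sample(names(op), n, TRUE, prob = op)

  miss <- function(x, p) { x[stats::runif(n) < p] <- NA; x }
  m <- config$missingness
  reports <- data.frame(
    report_id = ids,
    sex = miss(sex, m$sex), age = miss(age, m$age),
    country = miss(country, m$country),
    receive_date = format_ymd(receive),
    event_onset = miss(format_ymd(onset), m$event_onset),
    outcomes = miss(outcomes, m$outcomes),
    stringsAsFactors = FALSE
  )

  start_chr <- miss(format_ymd(start), m$start_date)
  target_name <- sample(config$drug_names, n, TRUE)
  # co-medication sets are drawn with enough cardinality that distinct
  # reports essentially never collide on the 7-field dedup key by chance
  comeds <- c("rituximab", "prednisone", "allopurinol", "aspirin",
              "omeprazole", "metoprolol", "furosemide", "warfarin",
              "paracetamol", "atorvastatin", "venetoclax", "acalabrutinib",
              "bendamustine", "obinutuzumab", "dexamethasone", "amlodipine",
              "lisinopril", "pantoprazole", "amiodarone", "digoxin",
              "apixaban", "rivaroxaban", "clopidogrel", "simvastatin",
              "levothyroxine", "metformin", "insulin glargine",
              "salbutamol", "co-trimoxazole", "valaciclovir")
  indications <- sample(c("Chronic lymphocytic leukaemia",
                          "Mantle cell lymphoma",
                          "Waldenstrom's macroglobulinaemia",
                          "Non-Hodgkin's lymphoma", "B-cell lymphoma",
                          "Marginal zone lymphoma"), n, TRUE,
                        prob = c(0.489, 0.086, 0.061, 0.02, 0.018, 0.326))
  dose <- sample(c(140, 280, 420, 560, 100), n, TRUE,
                 prob = c(0.108, 0.117, 0.623, 0.128, 0.024))
  target_rows <- data.frame(
    report_id = ids[exposed], reported_name = target_name[exposed],
    role = "suspect", start_date = start_chr[exposed],
    end_date = NA_character_, dose_mg = dose[exposed],
    indication_pt = indications[exposed], stringsAsFactors = FALSE)
  n_comed <- sample(1:3, n, TRUE)
  comed_id <- rep(seq_len(n), n_comed)
  first_of_report <- !duplicated(comed_id)
  comed_rows <- data.frame(
    report_id = ids[comed_id],
    reported_name = sample(comeds, length(comed_id), TRUE),
    role = "concomitant",
    start_date = ifelse(first_of_report & !exposed[comed_id],
                        start_chr[comed_id], NA_character_),
    end_date = NA_character_, dose_mg = NA_real_,
    indication_pt = NA_character_, stringsAsFactors = FALSE)
  drugs <- rbind(target_rows, comed_rows)

  # duplicate injection: copies of all 7 dedup-key fields, later receive date
  dup <- which(stats::runif(n) < config$duplicate_rate)
  if (length(dup)) {
    dup_ids <- paste0(ids[dup], "D")
    r2 <- reports[dup, , drop = FALSE]
    r2$report_id <- dup_ids
    r2$receive_date <- format_ymd(receive[dup] + 14)
    reports <- rbind(reports, r2)
    d2 <- drugs[drugs$report_id %in% ids[dup], , drop = FALSE]
    e2 <- events[events$report_id %in% ids[dup], , drop = FALSE]
    d2$report_id <- paste0(d2$report_id, "D")
    e2$report_id <- paste0(e2$report_id, "D")
    drugs <- rbind(drugs, d2)
    events <- rbind(events, e2)
  }

  list(store = report_store(reports, drugs, events), truth = truth)
}

## ---------------------------------------------------------------------------
## fixture writing

#' Write a report store to disk
#'
#' \code{"simple_tsv"} writes \code{reports.tsv}, \code{drugs.tsv} and
#' \code{events.tsv}; \code{\link{read_reports}} is its exact inverse.
#' \code{"faers_ascii"} writes pipe-delimited DEMO, DRUG, REAC, OUTC and
#' THER tables with quarterly-style column names (ages in years, sex coded
#' M/F, outcome categories recoded to DE/LT/HO/DS/OT).
#'
#' @param store a \code{\link{report_store}}.
#' @param dir output directory (created if absent).
#' @param dialect \code{"simple_tsv"} or \code{"faers_ascii"}.
#' @return invisibly, the written file paths.
#' @export
write_fixture <- function(store, dir, dialect = c("simple_tsv", "faers_ascii")) {
  dialect <- match.arg(dialect)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, name, sep) {
    path <- file.path(dir, name)
    utils::write.table(df, path, sep = sep, quote = FALSE, na = "",
                       row.names = FALSE)
    path
  }
  if (dialect == "simple_tsv") {
    paths <- c(wr(store$reports, "reports.tsv", "\t"),
               wr(store$drugs, "drugs.tsv", "\t"),
               wr(store$events, "events.tsv", "\t"))
    return(invisible(paths))
  }
  rid <- store$reports$report_id
  demo <- data.frame(primaryid = rid, caseid = rid, caseversion = 1,
                     event_dt = store$reports$event_onset,
                     fda_dt = store$reports$receive_date,
                     sex = unname(c(male = "M", female = "F")[store$reports$sex]),
                     age = store$reports$age, age_cod = "YR",
                     occr_country = store$reports$country,
                     stringsAsFactors = FALSE)
  seq_in <- stats::ave(seq_len(nrow(store$drugs)), store$drugs$report_id,
                       FUN = seq_along)
  role_out <- unname(c(suspect = "PS", concomitant = "C", interacting = "I",
                       unknown = "")[store$drugs$role])
  drug <- data.frame(primaryid = store$drugs$report_id, drug_seq = seq_in,
                     role_cod = role_out,
                     drugname = store$drugs$reported_name,
                     dose_amt = store$drugs$dose_mg, stringsAsFactors = FALSE)
  ther <- data.frame(primaryid = store$drugs$report_id,
                     dsg_drug_seq = seq_in,
                     start_dt = store$drugs$start_date,
                     end_dt = store$drugs$end_date, stringsAsFactors = FALSE)
  reac <- data.frame(primaryid = store$events$report_id, pt = store$events$pt,
                     stringsAsFactors = FALSE)
  rev_outc <- stats::setNames(names(.outc_map), .outc_map)
  oc <- strsplit(ifelse(is.na(store$reports$outcomes), "",
                        store$reports$outcomes), ",")
  oc_flat <- trimws(unlist(oc))
  outc <- data.frame(primaryid = rep(rid, lengths(oc)),
                     outc_cod = unname(rev_outc[oc_flat]),
                     stringsAsFactors = FALSE)
  invisible(c(wr(demo, "demo.txt", "|"), wr(drug, "drug.txt", "|"),
              wr(reac, "reac.txt", "|"), wr(outc, "outc.txt", "|"),
              wr(ther, "ther.txt", "|")))
}
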