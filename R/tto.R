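#' Time to onset per report
#'
#' Days from the start of therapy with the target drug to the onset of the
#' adverse event: the earliest \emph{complete} start date among the report's
#' matching drug entries to the report's (complete) event onset date.
#' Reports where either date is missing or only partially reported, or where
#' the onset precedes the start, get \code{NA} — excluded, never imputed.
#'
#' @param store a \code{\link{report_store}}.
#' @param drug a \code{\link{drug_synonyms}}.
#' @param role_filter optional roles restricting which drug entries count
#'   (e.g. \code{"suspect"}).
#' @return named numeric vector of days (one element per report, store
#'   order), \code{NA} where no TTO is computable.
#' @export
compute_tto <- function(store, drug, role_filter = NULL) {
  d <- store$drugs
  if (!is.null(role_filter)) d <- d[d$role %in% role_filter, , drop = FALSE]
  toks <- .tokenize(d$reported_name)
  hit <- rep(FALSE, nrow(d))
  for (syn in .tokenize(drug$names)) hit <- hit | grepl(syn, toks, fixed = TRUE)
  d <- d[hit & is_complete_date(d$start_date), , drop = FALSE]

  ids <- store$reports$report_id
  start <- rep(NA_character_, length(ids))
  if (nrow(d)) {
    first <- tapply(d$start_date, factor(d$report_id, levels = ids), min)
    start <- unname(first)
  }
  onset <- partial_as_date(store$reports$event_onset)
  tto <- as.numeric(onset - partial_as_date(start))
  tto[!is.na(tto) & tto < 0] <- NA_real_
  names(tto) <- ids
  tto
}

#' Summarise a time-to-onset distribution
#'
#' Median and first/third quartiles of onset latency, quartiles by linear
#' interpolation between order statistics (\code{\link[stats]{quantile}}
#' type 7). \code{NA} latencies (non-computable TTOs) are dropped first.
#'
#' @param ttos numeric vector of days (may contain \code{NA}; may be empty).
#' @return an object of class \code{tto_summary} with fields \code{n},
#'   \code{median_days}, \code{q1_days}, \code{q3_days}.
#' @export
summarize_tto <- function(ttos) {
  ttos <- ttos[!is.na(ttos)]
  if (length(ttos) == 0L)
    return(structure(list(n = 0L, median_days = NA_real_, q1_days = NA_real_,
                          q3_days = NA_real_), class = "tto_summary"))
  q <- unname(stats::quantile(ttos, c(0.25, 0.5, 0.75), type = 7))
  structure(list(n = length(ttos), median_days = q[2], q1_days = q[1],
                 q3_days = q[3]), class = "tto_summary")
}

#' @export
print.tto_summary <- function(x, ...) {
  cat(sprintf("Time to onset: n = %d, median %.0f days (Q1-Q3 %.0f-%.0f)\n",
              x$n, x$median_days, x$q1_days, x$q3_days))
  invisible(x)
}

# severity order: a report with several outcome codes contributes once,
# to the most severe category
.outcome_severity <- c("death", "life_threatening", "disability",
                       "hospitalisation", "other_serious", "unknown")

#' Outcome summary from per-category counts
#'
#' @param counts named integer vector of outcome category counts.
#' @return an object of class \code{outcome_summary}: \code{counts},
#'   \code{data_available} (their sum) and \code{proportions} in percent.
#' @export
outcome_summary <- function(counts) {
  counts <- counts[counts > 0]
  total <- sum(counts)
  props <- if (total > 0) 100 * counts / total else stats::setNames(numeric(0), character(0))
  structure(list(counts = counts, data_available = total, proportions = props),
            class = "outcome_summary")
}

#' @export
print.outcome_summary <- function(x, ...) {
  cat("Outcomes (n =", x$data_available, "with data):\n")
  for (nm in names(x$counts))
    cat(sprintf("  %-18s %6d (%.1f%%)\n", nm, x$counts[[nm]], x$proportions[[nm]]))
  invisible(x)
}

#' Outcome distribution over a set of reports
#'
#' Counts reports by outcome over those with a non-missing outcome field. A
#' report reporting several outcome codes contributes once, to its most
#' severe category (death > life-threatening > disability > hospitalisation
#' > other serious).
#'
#' @param store a \code{\link{report_store}} (typically already restricted
#'   to a drug-event pair of interest).
#' @return an \code{\link{outcome_summary}}.
#' @export
outcome_distribution <- function(store) {
  oc <- store$reports$outcomes
  oc <- oc[!is.na(oc) & nzchar(oc)]
  worst <- vapply(strsplit(oc, ","), function(v) {
    v <- trimws(v)
    .outcome_severity[min(match(v, .outcome_severity), na.rm = TRUE)]
  }, character(1))
  lev <- .outcome_severity[.outcome_severity %in% worst]
  outcome_summary(table(factor(worst, levels = lev)))
}

.age_band <- function(age) {
  cut(age, breaks = c(-Inf, 45, 60, Inf), right = FALSE,
      labels = c("<45", "45-59", ">=60"))
}

.dose_band <- function(dose) {
  ifelse(is.na(dose), NA_character_,
         ifelse(dose %in% c(140, 280, 420, 560), as.character(dose), "other"))
}

#' Descriptive characteristics table
#'
#' Per-stratum counts and percentages for sex, age band (<45, 45-59, >=60
#' years), reporting country, indication and daily-dose band (140/280/420/560
#' mg, other). Each block uses its own denominator: the number of reports
#' with that field non-missing (\code{data_available}), the convention of
#' published spontaneous-report characteristics tables. Indication and dose
#' are taken from the target drug's entries when \code{drug} is supplied,
#' otherwise from suspect-role entries.
#'
#' @param store a \code{\link{report_store}}.
#' @param drug optional \code{\link{drug_synonyms}} locating the entries that
#'   carry dose and indication.
#' @return a named list of blocks; each block is a data frame with columns
#'   \code{stratum}, \code{n}, \code{percent} plus an attribute
#'   \code{data_available}.
#' @export
descriptive_table <- function(store, drug = NULL) {
  block <- function(values, levels = NULL) {
    values <- values[!is.na(values)]
    avail <- length(values)
    tab <- if (is.null(levels)) sort(table(values), decreasing = TRUE)
           else table(factor(values, levels = levels))
    df <- data.frame(stratum = names(tab), n = as.integer(tab),
                     percent = if (avail > 0) round(100 * as.integer(tab) / avail, 1)
                               else numeric(length(tab)),
                     stringsAsFactors = FALSE)
    attr(df, "data_available") <- avail
    df
  }
  d <- store$drugs
  if (!is.null(drug)) {
    toks <- .tokenize(d$reported_name)
    hit <- rep(FALSE, nrow(d))
    for (syn in .tokenize(drug$names)) hit <- hit | grepl(syn, toks, fixed = TRUE)
    d <- d[hit, , drop = FALSE]
  } else {
    d <- d[d$role == "suspect", , drop = FALSE]
  }
  per_report <- function(values) {
    v <- tapply(values, factor(d$report_id, levels = store$reports$report_id),
                function(x) { x <- x[!is.na(x)]; if (length(x)) x[1] else NA })
    unname(unlist(v))
  }
  list(sex = block(store$reports$sex, c("male", "female")),
       age = block(as.character(.age_band(store$reports$age)),
                   c("<45", "45-59", ">=60")),
       country = block(store$reports$country),
       indication = block(per_report(d$indication_pt)),
       dose = block(.dose_band(per_report(d$dose_mg)),
                    c("140", "280", "420", "560", "other")))
}
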