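#' Drug-event contingency counts
#'
#' Builds the observed/expected record counts of the case/non-case design:
#' \code{n_observed} reports listing both the target drug and the target
#' event, \code{n_drug} reports listing the drug, \code{n_event} reports
#' listing the event, \code{n_total} reports in the database, and
#' \code{n_expected = n_drug * n_event / n_total}. The counting unit is the
#' deduplicated report: a report counts for the event when any of its PTs is
#' in \code{event_pts}.
#'
#' @param store a deduplicated \code{\link{report_store}}.
#' @param drug a \code{\link{drug_synonyms}} object, or a logical exposure
#'   vector of length \code{n_reports(store)} (one flag per report, in store
#'   order) when the drug match has been precomputed.
#' @param event_pts character vector of PT names defining the event.
#' @param role_filter passed to \code{\link{match_drug}} when \code{drug} is
#'   a synonym set.
#' @return an object of class \code{contingency_counts}.
#' @export
build_contingency <- function(store, drug, event_pts, role_filter = NULL) {
  n_total <- n_reports(store)
  if (n_total == 0L) stop("empty report database", call. = FALSE)
  drug_flag <- if (is.logical(drug)) {
    stopifnot(length(drug) == n_total)
    drug
  } else match_drug(store, drug, role_filter)
  event_ids <- unique(store$events$report_id[store$events$pt %in% event_pts])
  event_flag <- store$reports$report_id %in% event_ids
  contingency_counts(n_observed = sum(drug_flag & event_flag),
                     n_drug = sum(drug_flag),
                     n_event = sum(event_flag),
                     n_total = n_total)
}

#' Construct contingency counts directly
#'
#' @param n_observed,n_drug,n_event,n_total non-negative record counts with
#'   \code{n_observed <= min(n_drug, n_event)} and
#'   \code{n_drug, n_event <= n_total}.
#' @return an object of class \code{contingency_counts}; \code{n_expected}
#'   is computed as \code{n_drug * n_event / n_total}.
#' @export
contingency_counts <- function(n_observed, n_drug, n_event, n_total) {
  stopifnot(n_observed >= 0, n_drug >= 0, n_event >= 0, n_total > 0,
            n_observed <= min(n_drug, n_event),
            n_drug <= n_total, n_event <= n_total)
  structure(list(n_observed = n_observed, n_drug = n_drug, n_event = n_event,
                 n_total = n_total,
                 n_expected = as.numeric(n_drug) * n_event / n_total),
            class = "contingency_counts")
}

#' @export
print.contingency_counts <- function(x, ...) {
  cat(sprintf("<contingency_counts> observed %d, drug %d, event %d, total %d, expected %.3f\n",
              x$n_observed, x$n_drug, x$n_event, x$n_total, x$n_expected))
  invisible(x)
}

#' Shrunken information component with 95\% interval
#'
#' The shrunken IC is \code{log2((n_obs + 0.5) / (n_exp + 0.5))}: the 0.5
#' pseudo-counts pull small-count ratios toward 1, trading a little bias for
#' stability. The 95\% credible bounds use the standard closed-form
#' approximation to the shrinkage-IC posterior,
#' \deqn{IC_{025} = IC - 3.3 (n+0.5)^{-1/2} - 2 (n+0.5)^{-3/2}}
#' \deqn{IC_{975} = IC + 2.4 (n+0.5)^{-1/2} - 0.5 (n+0.5)^{-3/2}}
#' with \eqn{n} the observed count. Defined for all counts including
#' \code{n_observed = 0}.
#'
#' @param counts a \code{\link{contingency_counts}}.
#' @return named numeric vector \code{c(ic, ic025, ic975)} in bits.
#' @export
ic_shrunken <- function(counts) {
  ic <- log2((counts$n_observed + 0.5) / (counts$n_expected + 0.5))
  n5 <- counts$n_observed + 0.5
  c(ic = ic,
    ic025 = ic - 3.3 * n5^(-0.5) - 2 * n5^(-1.5),
    ic975 = ic + 2.4 * n5^(-0.5) - 0.5 * n5^(-1.5))
}

#' Shrunken reporting odds ratio with 95\% interval
#'
#' Here the ROR is the shrunken observed-to-expected ratio itself,
#' \code{(n_obs + 0.5) / (n_exp + 0.5)}, so \code{ror == 2^ic} holds exactly.
#' Interval bounds are log-normal, \code{ror * exp(+/- 1.96 / sqrt(n_obs))};
#' with \code{n_observed = 0} the bounds degenerate to \code{(0, Inf)}.
#'
#' @param counts a \code{\link{contingency_counts}}.
#' @return named numeric vector \code{c(ror, ror025, ror975)}.
#' @export
ror_shrunken <- function(counts) {
  ror <- (counts$n_observed + 0.5) / (counts$n_expected + 0.5)
  if (counts$n_observed == 0)
    return(c(ror = ror, ror025 = 0, ror975 = Inf))
  half <- 1.96 / sqrt(counts$n_observed)
  c(ror = ror, ror025 = ror * exp(-half), ror975 = ror * exp(half))
}

#' Signal classification criteria
#'
#' The default criterion flags a drug-event pair when the IC lower bound
#' exceeds 0 \emph{and} the ROR lower bound exceeds 1, with expected count
#' above 3. \code{combine = "or"} requires either disproportionality bound
#' (the expected-count gate always applies).
#'
#' @param ic025_threshold IC lower-bound threshold in bits.
#' @param ror025_threshold ROR lower-bound threshold.
#' @param min_expected minimum expected record count.
#' @param combine \code{"and"} or \code{"or"}.
#' @return an object of class \code{signal_criteria}.
#' @export
signal_criteria <- function(ic025_threshold = 0, ror025_threshold = 1,
                            min_expected = 3, combine = c("and", "or")) {
  combine <- match.arg(combine)
  stopifnot(is.finite(ic025_threshold), is.finite(ror025_threshold),
            is.finite(min_expected))
  structure(list(ic025_threshold = ic025_threshold,
                 ror025_threshold = ror025_threshold,
                 min_expected = min_expected, combine = combine),
            class = "signal_criteria")
}

#' Classify a drug-event pair as a signal
#'
#' @param result a list or one-row data frame with elements \code{ic025},
#'   \code{ror025} and \code{n_expected} (e.g. a row of
#'   \code{\link{dispro_screen}} output, or published interval bounds).
#' @param criteria a \code{\link{signal_criteria}}.
#' @return logical: is the pair a signal under the criteria? Vectorised over
#'   the elements of \code{result}.
#' @export
classify_signal <- function(result, criteria = signal_criteria()) {
  ic_pass <- result$ic025 > criteria$ic025_threshold
  ror_pass <- result$ror025 > criteria$ror025_threshold
  dispro <- if (criteria$combine == "and") ic_pass & ror_pass
            else ic_pass | ror_pass
  dispro & result$n_expected > criteria$min_expected
}

#' Screen event sets for disproportionality signals
#'
#' The package's central estimator. For each named event set (typically one
#' PT set per SMQ from \code{\link{smq_event_sets}}, or single PTs for a
#' PT-level screen) it builds the drug-event contingency table over the
#' deduplicated store, computes the shrunken IC and ROR with 95\% intervals,
#' and classifies the pair against \code{criteria}. No multiplicity
#' correction is applied across event sets; the shrinkage of the statistics
#' is the guard against spurious small-count signals.
#'
#' @param store a deduplicated \code{\link{report_store}}.
#' @param drug a \code{\link{drug_synonyms}} or precomputed logical exposure
#'   vector (see \code{\link{build_contingency}}).
#' @param event_sets named list of character PT vectors; an optional
#'   \code{smq_code} attribute on each element is carried into the output.
#' @param criteria a \code{\link{signal_criteria}}.
#' @return an object of class \code{dispro_screen}: a list with
#'   \code{results} (one row per event set, sorted by IC descending),
#'   \code{criteria}, \code{drug}, \code{n_total} and \code{call}.
#' @examples
#' cfg <- sim_config(n_reports = 5000, association_ratios = c("Atrial fibrillation" = 8),
#'                   seed = 42)
#' sim <- simulate_reports(cfg)
#' scr <- dispro_screen(deduplicate(sim$store), drug_synonyms("ibrutinib", "imbruvica"),
#'                      list(AF = "Atrial fibrillation"))
#' summary(scr)
#' @export
dispro_screen <- function(store, drug, event_sets,
                          criteria = signal_criteria()) {
  stopifnot(length(event_sets) > 0, !is.null(names(event_sets)))
  drug_flag <- if (is.logical(drug)) drug else match_drug(store, drug)
  rows <- lapply(names(event_sets), function(nm) {
    cc <- build_contingency(store, drug_flag, event_sets[[nm]])
    ic <- ic_shrunken(cc)
    ror <- ror_shrunken(cc)
    code <- attr(event_sets[[nm]], "smq_code")
    data.frame(event = nm,
               smq_code = if (is.null(code)) NA_real_ else as.numeric(code),
               n_observed = cc$n_observed, n_expected = cc$n_expected,
               ic = ic[["ic"]], ic025 = ic[["ic025"]], ic975 = ic[["ic975"]],
               ror = ror[["ror"]], ror025 = ror[["ror025"]],
               ror975 = ror[["ror975"]], stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$is_signal <- classify_signal(res, criteria)
  res <- res[order(-res$ic, res$event), , drop = FALSE]
  rownames(res) <- NULL
  structure(list(results = res, criteria = criteria,
                 drug = if (is.logical(drug)) "<precomputed exposure>"
                        else drug$canonical,
                 n_total = n_reports(store), call = match.call()),
            class = "dispro_screen")
}

#' @export
print.dispro_screen <- function(x, digits = 2, ...) {
  cat("Disproportionality screen:", x$drug, "|", nrow(x$results),
      "event set(s) |", x$n_total, "reports\n")
  cat(sum(x$results$is_signal), "positive signal(s) (IC lower bound >",
      x$criteria$ic025_threshold,
      if (x$criteria$combine == "and") "and" else "or",
      "ROR lower bound >", x$criteria$ror025_threshold,
      ", expected >", x$criteria$min_expected, ")\n")
  invisible(x)
}

#' @export
summary.dispro_screen <- function(object, digits = 2, ...) {
  r <- object$results
  fmt <- function(est, lo, hi)
    sprintf("%.*f (%.*f-%.*f)", digits, est, digits, lo, digits, hi)
  out <- data.frame(event = r$event, n = r$n_observed,
                    ic = fmt(r$ic, r$ic025, r$ic975),
                    ror = fmt(r$ror, r$ror025, r$ror975),
                    signal = ifelse(r$is_signal, "*", ""),
                    stringsAsFactors = FALSE)
  print(object, digits = digits)
  cat("\n")
  print(out, right = FALSE, row.names = FALSE)
  invisible(r)
}

#' @export
as.data.frame.dispro_screen <- function(x, ...) x$results

#' @export
coef.dispro_screen <- function(object, ...) {
  stats::setNames(object$results$ic, object$results$event)
}

#' Forest-style plot of a disproportionality screen
#'
#' Draws the shrunken IC point estimates and 95\% intervals, one row per
#' event set, with the signal threshold as a reference line.
#'
#' @param x a \code{\link{dispro_screen}}.
#' @param ... passed to \code{\link[graphics]{plot}}.
#' @export
plot.dispro_screen <- function(x, ...) {
  r <- x$results[nrow(x$results):1, , drop = FALSE]
  y <- seq_len(nrow(r))
  old <- graphics::par(mar = c(4, 14, 2, 1))
  on.exit(graphics::par(old))
  graphics::plot(r$ic, y, xlim = range(r$ic025, r$ic975, finite = TRUE),
                 pch = ifelse(r$is_signal, 19, 1), yaxt = "n",
                 xlab = "Information component (bits)", ylab = "", ...)
  graphics::segments(r$ic025, y, r$ic975, y)
  graphics::abline(v = x$criteria$ic025_threshold, lty = 2, col = "grey40")
  graphics::axis(2, at = y, labels = r$event, las = 1, cex.axis = 0.7)
  invisible(x)
}

#' IC trend over cumulative reporting years
#'
#' Recomputes the shrunken IC on the sub-database of reports received on or
#' before each year end, the standard way of watching a signal strengthen as
#' reports accrue. Interval half-widths shrink roughly as
#' \code{1/sqrt(n_observed)}.
#'
#' @param store a deduplicated \code{\link{report_store}} whose reports carry
#'   receive dates.
#' @param drug a \code{\link{drug_synonyms}} or logical exposure vector.
#' @param event_pts character PT set defining the event.
#' @param year_ends integer vector of calendar years; each window is all
#'   reports with \code{receive_date <= 31 Dec} of that year.
#' @param window \code{"cumulative"} (default) or \code{"per_year"} (only
#'   reports received within the year).
#' @return data frame with columns \code{year}, \code{n_observed},
#'   \code{ic}, \code{ic025}, \code{ic975}.
#' @export
ic_trend <- function(store, drug, event_pts, year_ends,
                     window = c("cumulative", "per_year")) {
  window <- match.arg(window)
  drug_flag <- if (is.logical(drug)) drug else match_drug(store, drug)
  yr <- suppressWarnings(as.integer(substr(store$reports$receive_date, 1, 4)))
  rows <- lapply(sort(year_ends), function(y) {
    keep <- !is.na(yr) & if (window == "cumulative") yr <= y else yr == y
    if (!any(keep))
      return(data.frame(year = y, n_observed = 0L, ic = NA_real_,
                        ic025 = NA_real_, ic975 = NA_real_))
    sub <- store_subset(store, store$reports$report_id[keep])
    cc <- build_contingency(sub, unname(drug_flag[keep]), event_pts)
    ic <- ic_shrunken(cc)
    data.frame(year = y, n_observed = cc$n_observed, ic = ic[["ic"]],
               ic025 = ic[["ic025"]], ic975 = ic[["ic975"]])
  })
  do.call(rbind, rows)
}
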