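#' Spontaneous-report store
#'
#' A \code{report_store} holds one deduplicatable slice of a spontaneous
#' adverse-event reporting database as three linked tables keyed by
#' \code{report_id}:
#' \describe{
#'   \item{reports}{one row per case: \code{report_id}, \code{sex}
#'     (\code{"male"}/\code{"female"}, \code{NA} = unknown), \code{age} in
#'     years, \code{country}, \code{receive_date} and \code{event_onset}
#'     (partial dates, see \code{\link{normalize_partial_date}}) and
#'     \code{outcomes} (comma-separated outcome categories, \code{NA} =
#'     not reported).}
#'   \item{drugs}{one row per reported drug: \code{report_id},
#'     \code{reported_name}, \code{role} (\code{suspect}, \code{concomitant},
#'     \code{interacting}, \code{unknown}), therapy \code{start_date} and
#'     \code{end_date} (partial dates), \code{dose_mg},
#'     \code{indication_pt}.}
#'   \item{events}{one row per adverse event: \code{report_id}, \code{pt}
#'     (MedDRA preferred term). Every report has at least one event.}
#' }
#'
#' Missing fields are \code{NA}; no value is ever imputed.
#'
#' @param reports,drugs,events data frames as described above.
#' @return an object of class \code{report_store}.
#' @export
report_store <- function(reports, drugs, events) {
  need <- function(df, cols, what) {
    miss <- setdiff(cols, names(df))
    if (length(miss))
      stop(sprintf("%s table is missing column(s): %s", what,
                   paste(miss, collapse = ", ")), call. = FALSE)
  }
  need(reports, c("report_id", "sex", "age", "country", "receive_date",
                  "event_onset", "outcomes"), "reports")
  need(drugs, c("report_id", "reported_name", "role", "start_date",
                "end_date", "dose_mg", "indication_pt"), "drugs")
  need(events, c("report_id", "pt"), "events")

  reports$report_id <- as.character(reports$report_id)
  drugs$report_id <- as.character(drugs$report_id)
  events$report_id <- as.character(events$report_id)
  if (anyDuplicated(reports$report_id))
    stop("duplicate report_id in reports table", call. = FALSE)

  bad_age <- !is.na(reports$age) & (reports$age < 0 | reports$age > 130)
  if (any(bad_age)) {
    message(sum(bad_age), " implausible age value(s) (<0 or >130 years) set to NA")
    reports$age[bad_age] <- NA_real_
  }
  sex <- tolower(as.character(reports$sex))
  sex[!sex %in% c("male", "female")] <- NA_character_
  reports$sex <- sex
  role <- tolower(as.character(drugs$role))
  role[!role %in% c("suspect", "concomitant", "interacting")] <- "unknown"
  drugs$role <- role

  orphan <- setdiff(c(drugs$report_id, events$report_id), reports$report_id)
  if (length(orphan))
    stop(sprintf("drug/event rows reference unknown report_id(s): %s",
                 paste(utils::head(orphan, 5), collapse = ", ")), call. = FALSE)
  no_event <- setdiff(reports$report_id, events$report_id)
  if (length(no_event)) {
    message(length(no_event), " report(s) without any adverse event dropped")
    keep <- !reports$report_id %in% no_event
    reports <- reports[keep, , drop = FALSE]
    drugs <- drugs[drugs$report_id %in% reports$report_id, , drop = FALSE]
  }
  if (nrow(reports) == 0L)
    stop("report store is empty: reports must have adverse events", call. = FALSE)

  rownames(reports) <- rownames(drugs) <- rownames(events) <- NULL
  structure(list(reports = reports, drugs = drugs, events = events),
            class = "report_store")
}

#' @export
print.report_store <- function(x, ...) {
  cat("<report_store>\n")
  cat("  reports:", nrow(x$reports), "\n")
  cat("  drug rows:", nrow(x$drugs),
      sprintf("(%d distinct names)", length(unique(tolower(x$drugs$reported_name)))), "\n")
  cat("  event rows:", nrow(x$events),
      sprintf("(%d distinct PTs)", length(unique(x$events$pt))), "\n")
  invisible(x)
}

#' Number of reports in a store
#' @param store a \code{report_store}.
#' @return integer count of reports.
#' @export
n_reports <- function(store) nrow(store$reports)

#' Subset a report store by report id
#'
#' Keeps the given reports (in store order) together with their drug and
#' event rows.
#'
#' @param store a \code{report_store}.
#' @param report_ids character vector of ids to keep.
#' @return a \code{report_store}.
#' @export
store_subset <- function(store, report_ids) {
  keep <- store$reports$report_id %in% report_ids
  report_store(store$reports[keep, , drop = FALSE],
               store$drugs[store$drugs$report_id %in% report_ids, , drop = FALSE],
               store$events[store$events$report_id %in% report_ids, , drop = FALSE])
}

## ---------------------------------------------------------------------------
## reading

.simple_tsv_schema <- list(
  reports = c("report_id", "sex", "age", "country", "receive_date",
              "event_onset", "outcomes"),
  drugs   = c("report_id", "reported_name", "role", "start_date", "end_date",
              "dose_mg", "indication_pt"),
  events  = c("report_id", "pt")
)

.faers_schema <- list(
  demo = c("primaryid", "caseid", "caseversion", "event_dt", "fda_dt", "sex",
           "age", "age_cod", "occr_country"),
  drug = c("primaryid", "drug_seq", "role_cod", "drugname", "dose_amt"),
  reac = c("primaryid", "pt"),
  outc = c("primaryid", "outc_cod"),
  ther = c("primaryid", "dsg_drug_seq", "start_dt", "end_dt")
)

.read_table <- function(path, sep, required) {
  df <- utils::read.table(path, sep = sep, header = TRUE, quote = "",
                          comment.char = "", stringsAsFactors = FALSE,
                          colClasses = "character", na.strings = c("NA", ""))
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop(sprintf("schema error in '%s': missing required column(s) %s",
                 basename(path), paste(miss, collapse = ", ")), call. = FALSE)
  extra <- setdiff(names(df), required)
  if (length(extra))
    stop(sprintf("schema error in '%s': unrecognised column(s) %s",
                 basename(path), paste(extra, collapse = ", ")), call. = FALSE)
  df
}

.locate_files <- function(paths, stems) {
  if (length(paths) == 1L && dir.exists(paths))
    paths <- list.files(paths, full.names = TRUE)
  found <- lapply(stems, function(s) {
    hit <- paths[grepl(paste0("^", s), tolower(basename(paths)))]
    if (length(hit) == 0L)
      stop(sprintf("no file matching '%s*' among inputs", s), call. = FALSE)
    hit
  })
  names(found) <- stems
  found
}

# FAERS ages arrive in assorted units; Table-style summaries need years
.age_years <- function(age, age_cod) {
  a <- suppressWarnings(as.numeric(age))
  f <- c(YR = 1, DEC = 10, MON = 1 / 12, WK = 1 / 52.18, DY = 1 / 365.25,
         HR = 1 / 8766)
  cod <- toupper(ifelse(is.na(age_cod) | age_cod == "", "YR", age_cod))
  mult <- unname(f[cod])
  mult[is.na(mult)] <- 1
  a * mult
}

.outc_map <- c(DE = "death", LT = "life_threatening", HO = "hospitalisation",
               DS = "disability", OT = "other_serious")

#' Read spontaneous reports from disk
#'
#' Two dialects are supported. \code{"simple_tsv"} is the package's native
#' schema: tab-separated \code{reports.tsv}, \code{drugs.tsv} and
#' \code{events.tsv} with the columns documented in
#' \code{\link{report_store}}. \code{"faers_ascii"} reads quarterly-style
#' pipe-delimited DEMO, DRUG, REAC, OUTC and THER tables (columns
#' \code{primaryid}, \code{caseid}, \code{caseversion}, \code{sex},
#' \code{age}, \code{age_cod}, \code{occr_country}, \code{event_dt},
#' \code{fda_dt}; \code{drug_seq}, \code{role_cod}, \code{drugname},
#' \code{dose_amt}; \code{pt}; \code{outc_cod}; \code{dsg_drug_seq},
#' \code{start_dt}, \code{end_dt}).
#'
#' When a FAERS case appears in several versions only the highest
#' \code{caseversion} per \code{caseid} is kept. Ages are converted to years
#' from \code{age_cod} units. Unparseable dates are kept at the precision
#' that does parse; missing fields become \code{NA} (no imputation). The
#' event onset date is taken from DEMO \code{event_dt} (FAERS) or the
#' \code{event_onset} column (TSV).
#'
#' @param paths a directory containing the tables, or a character vector of
#'   file paths.
#' @param dialect \code{"simple_tsv"} or \code{"faers_ascii"}.
#' @return a \code{\link{report_store}}.
#' @export
read_reports <- function(paths, dialect = c("simple_tsv", "faers_ascii")) {
  dialect <- match.arg(dialect)
  if (dialect == "simple_tsv") {
    f <- .locate_files(paths, c("reports", "drugs", "events"))
    reports <- .read_table(f$reports[1], "\t", .simple_tsv_schema$reports)
    drugs <- .read_table(f$drugs[1], "\t", .simple_tsv_schema$drugs)
    events <- .read_table(f$events[1], "\t", .simple_tsv_schema$events)
    if (nrow(events) == 0L)
      stop("events table is empty: reports must have adverse events", call. = FALSE)
    reports$age <- suppressWarnings(as.numeric(reports$age))
    reports$receive_date <- normalize_partial_date(reports$receive_date)
    reports$event_onset <- normalize_partial_date(reports$event_onset)
    drugs$start_date <- normalize_partial_date(drugs$start_date)
    drugs$end_date <- normalize_partial_date(drugs$end_date)
    drugs$dose_mg <- suppressWarnings(as.numeric(drugs$dose_mg))
    return(report_store(reports, drugs, events))
  }

  f <- .locate_files(paths, c("demo", "drug", "reac", "outc", "ther"))
  rbind_files <- function(paths, required)
    do.call(rbind, lapply(paths, .read_table, sep = "|", required = required))
  demo <- rbind_files(f$demo, .faers_schema$demo)
  drug <- rbind_files(f$drug, .faers_schema$drug)
  reac <- rbind_files(f$reac, .faers_schema$reac)
  outc <- rbind_files(f$outc, .faers_schema$outc)
  ther <- rbind_files(f$ther, .faers_schema$ther)
  if (nrow(reac) == 0L)
    stop("REAC table is empty: reports must have adverse events", call. = FALSE)

  # keep highest caseversion per caseid
  ver <- suppressWarnings(as.numeric(demo$caseversion))
  ver[is.na(ver)] <- 0
  ord <- order(demo$caseid, -ver, demo$primaryid)
  demo <- demo[ord, , drop = FALSE]
  dup <- duplicated(demo$caseid)
  if (any(dup)) {
    message(sum(dup), " superseded case version(s) dropped (kept highest caseversion)")
    demo <- demo[!dup, , drop = FALSE]
  }

  reports <- data.frame(
    report_id = demo$primaryid,
    sex = unname(c(M = "male", F = "female")[toupper(demo$sex)]),
    age = .age_years(demo$age, demo$age_cod),
    country = demo$occr_country,
    receive_date = normalize_partial_date(demo$fda_dt),
    event_onset = normalize_partial_date(demo$event_dt),
    outcomes = NA_character_,
    stringsAsFactors = FALSE
  )
  oc <- .outc_map[toupper(outc$outc_cod)]
  oc[is.na(oc) & !is.na(outc$outc_cod)] <- "unknown"
  if (nrow(outc)) {
    agg <- tapply(oc, outc$primaryid, function(v)
      paste(sort(unique(v[!is.na(v)])), collapse = ","))
    agg[agg == ""] <- NA_character_
    reports$outcomes <- unname(agg[reports$report_id])
  }

  key <- paste(drug$primaryid, drug$drug_seq, sep = "\x1f")
  tkey <- paste(ther$primaryid, ther$dsg_drug_seq, sep = "\x1f")
  i <- match(key, tkey)
  drugs <- data.frame(
    report_id = drug$primaryid,
    reported_name = drug$drugname,
    role = unname(c(PS = "suspect", SS = "suspect", C = "concomitant",
                    I = "interacting")[toupper(drug$role_cod)]),
    start_date = normalize_partial_date(ther$start_dt[i]),
    end_date = normalize_partial_date(ther$end_dt[i]),
    dose_mg = suppressWarnings(as.numeric(drug$dose_amt)),
    indication_pt = NA_character_,
    stringsAsFactors = FALSE
  )
  events <- data.frame(report_id = reac$primaryid, pt = reac$pt,
                       stringsAsFactors = FALSE)
  drugs <- drugs[drugs$report_id %in% reports$report_id, , drop = FALSE]
  events <- events[events$report_id %in% reports$report_id, , drop = FALSE]
  report_store(reports, drugs, events)
}

## ---------------------------------------------------------------------------
## deduplication

# one key string per report over the 7 dedup fields; partial dates compare
# equal only when their known components are identical (string equality)
.dedup_keys <- function(store) {
  ids <- store$reports$report_id
  chr <- function(x) ifelse(is.na(x), "\x01NA", as.character(x))
  agg_set <- function(values, by) {
    dt <- data.table::data.table(id = by, v = values)
    dt <- unique(dt)
    data.table::setkey(dt, id, v)  # values pre-sorted within group
    agg <- dt[, list(k = paste(v, collapse = "\x1f")), by = "id"]
    out <- agg$k[match(ids, agg$id)]
    ifelse(is.na(out), "", out)
  }
  pts <- agg_set(store$events$pt, store$events$report_id)
  dn <- agg_set(tolower(trimws(store$drugs$reported_name)),
                store$drugs$report_id)
  rng <- function(values, by, last) {
    keep <- !is.na(values)
    dt <- data.table::data.table(id = by[keep], v = values[keep])
    data.table::setkey(dt, id, v)
    agg <- dt[, list(k = if (last) v[.N] else v[1L]), by = "id"]
    chr(agg$k[match(ids, agg$id)])
  }
  start <- rng(store$drugs$start_date, store$drugs$report_id, last = FALSE)
  end <- rng(store$drugs$end_date, store$drugs$report_id, last = TRUE)
  paste(chr(store$reports$sex), chr(store$reports$age),
        chr(store$reports$country), pts, dn, start, end, sep = "\x1e")
}

#' Deduplicate spontaneous reports
#'
#' Reports with the same sex, age, reporting country, adverse-event PT set,
#' set of reported drug names, earliest therapy start date and latest therapy
#' end date are treated as duplicates of one case. One representative is
#' kept per duplicate class: the report with the latest receive date,
#' ties broken by lexicographically smallest \code{report_id}. Missing key
#' fields compare equal to missing; partial dates compare on their known
#' components only. Survivor order is the input order. Idempotent.
#'
#' @param store a \code{\link{report_store}}.
#' @return a deduplicated \code{report_store}.
#' @export
deduplicate <- function(store) {
  key <- .dedup_keys(store)
  rec <- store$reports$receive_date
  rec <- ifelse(is.na(rec), "", rec)
  # winner per key: latest receive_date, then smallest report_id
  ord <- order(key, -xtfrm(rec), store$reports$report_id)
  winner_id <- store$reports$report_id[ord][!duplicated(key[ord])]
  store_subset(store, winner_id)
}

## ---------------------------------------------------------------------------
## drug identification

#' Drug synonym set
#'
#' Bundles the generic and brand names under which a target drug is reported
#' (e.g. ibrutinib is reported both as \code{"ibrutinib"} and as
#' \code{"Imbruvica"}). Matching is case-insensitive and token-based.
#'
#' @param canonical canonical (generic) name.
#' @param names character vector of synonyms; the canonical name is always
#'   included.
#' @return an object of class \code{drug_synonyms}.
#' @export
drug_synonyms <- function(canonical, names = character()) {
  stopifnot(is.character(canonical), length(canonical) == 1L, nzchar(canonical))
  nm <- unique(tolower(trimws(c(canonical, names))))
  nm <- nm[nzchar(nm)]
  structure(list(canonical = tolower(trimws(canonical)), names = nm),
            class = "drug_synonyms")
}

#' @export
print.drug_synonyms <- function(x, ...) {
  cat("<drug_synonyms>", x$canonical, "=",
      paste(x$names, collapse = ", "), "\n")
  invisible(x)
}

#' Read a drug synonym list
#'
#' Expects a TSV with columns \code{canonical} and \code{name}; all rows for
#' the (single) canonical drug are collected into one synonym set.
#'
#' @param path file path.
#' @return a \code{\link{drug_synonyms}}.
#' @export
read_drug_synonyms <- function(path) {
  df <- .read_table(path, "\t", c("canonical", "name"))
  can <- unique(tolower(trimws(df$canonical)))
  if (length(can) != 1L)
    stop("synonym file must describe exactly one canonical drug", call. = FALSE)
  drug_synonyms(can, df$name)
}

# " tok1 tok2 " form so token sequences can be matched with fixed grepl
.tokenize <- function(x) {
  x <- gsub("[^a-z0-9]+", " ", tolower(x))
  paste0(" ", trimws(x), " ")
}

#' Identify reports listing a target drug
#'
#' A report matches when any of its drug entries, after trimming and case
#' folding, contains a synonym as a whole token sequence. Token matching is
#' deliberate: \code{"ibrutinib."} and \code{"IMBRUVICA (ibrutinib) 420mg"}
#' match ibrutinib, while \code{"acalabrutinib"} does not (no raw substring
#' matching).
#'
#' @param store a \code{\link{report_store}}.
#' @param synonyms a \code{\link{drug_synonyms}}.
#' @param role_filter optional character vector of roles (\code{"suspect"},
#'   \code{"concomitant"}, \code{"interacting"}, \code{"unknown"}) restricting
#'   which drug entries are considered.
#' @return named logical vector, one element per report in store order.
#' @export
match_drug <- function(store, synonyms, role_filter = NULL) {
  stopifnot(inherits(synonyms, "drug_synonyms"))
  d <- store$drugs
  if (!is.null(role_filter)) d <- d[d$role %in% role_filter, , drop = FALSE]
  hit_rows <- rep(FALSE, nrow(d))
  if (nrow(d)) {
    toks <- .tokenize(d$reported_name)
    for (syn in .tokenize(synonyms$names))
      hit_rows <- hit_rows | grepl(syn, toks, fixed = TRUE)
  }
  ids <- store$reports$report_id
  out <- ids %in% unique(d$report_id[hit_rows])
  names(out) <- ids
  out
}
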