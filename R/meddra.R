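#' MedDRA PT-to-SMQ/SOC mapping dictionary
#'
#' MedDRA content is licensed and is not shipped with the package; the user
#' supplies two tab-separated mapping tables. \code{smq_path} needs columns
#' \code{pt}, \code{smq_name}, \code{smq_code} and optionally \code{scope}
#' (\code{"narrow"} or \code{"broad"}; rows without a scope count as both).
#' \code{soc_path} needs columns \code{pt}, \code{soc_code}.
#'
#' @param smq_path path to the PT-to-SMQ table.
#' @param soc_path optional path to the PT-to-SOC table.
#' @return an object of class \code{meddra_dictionary} with elements
#'   \code{pt_to_smq} (data frame \code{pt}, \code{smq_name},
#'   \code{smq_code}, \code{scope}), \code{pt_to_soc} (data frame \code{pt},
#'   \code{soc_code}) and \code{smq_catalog} (data frame \code{smq_name},
#'   \code{smq_code}).
#' @export
meddra_dictionary <- function(smq_path, soc_path = NULL) {
  smq <- tryCatch(
    .read_table(smq_path, "\t", c("pt", "smq_name", "smq_code", "scope")),
    error = function(e) .read_table(smq_path, "\t", c("pt", "smq_name", "smq_code"))
  )
  if (is.null(smq$scope)) smq$scope <- NA_character_
  if (nrow(smq)) {
    code <- suppressWarnings(as.numeric(smq$smq_code))
    if (anyNA(code))
      stop("non-numeric smq_code in SMQ map: ",
           paste(unique(smq$smq_code[is.na(code)]), collapse = ", "),
           call. = FALSE)
    smq$smq_code <- code
    sc <- tolower(smq$scope)
    sc[is.na(sc) | !sc %in% c("narrow", "broad")] <- "both"
    smq$scope <- sc
  } else {
    smq$smq_code <- numeric(0)
  }
  smq$pt_key <- tolower(trimws(smq$pt))

  soc <- data.frame(pt = character(0), soc_code = character(0),
                    stringsAsFactors = FALSE)
  if (!is.null(soc_path)) {
    soc <- .read_table(soc_path, "\t", c("pt", "soc_code"))
    key <- tolower(trimws(soc$pt))
    conflict <- tapply(soc$soc_code, key, function(x) length(unique(x)) > 1L)
    if (any(conflict))
      stop("conflicting PT-to-SOC rows for: ",
           paste(names(conflict)[conflict], collapse = ", "), call. = FALSE)
    soc <- soc[!duplicated(key), , drop = FALSE]
  }
  soc$pt_key <- tolower(trimws(soc$pt))

  catalog <- unique(smq[, c("smq_name", "smq_code"), drop = FALSE])
  rownames(smq) <- rownames(soc) <- rownames(catalog) <- NULL
  structure(list(pt_to_smq = smq, pt_to_soc = soc, smq_catalog = catalog),
            class = "meddra_dictionary")
}

#' @export
print.meddra_dictionary <- function(x, ...) {
  cat("<meddra_dictionary>\n")
  cat("  SMQs:", nrow(x$smq_catalog), " PT-SMQ rows:", nrow(x$pt_to_smq), "\n")
  cat("  PT-SOC rows:", nrow(x$pt_to_soc), "\n")
  invisible(x)
}

#' Map a preferred term to its SMQ memberships
#'
#' Pure case-insensitive lookup; a PT absent from the dictionary maps to the
#' empty set, never an error.
#'
#' @param pt a single PT name.
#' @param dict a \code{\link{meddra_dictionary}}.
#' @param scope SMQ scopes to include; the default includes narrow and broad
#'   memberships.
#' @return data frame with columns \code{smq_name}, \code{smq_code} (zero or
#'   more rows).
#' @export
map_pt <- function(pt, dict, scope = c("narrow", "broad")) {
  m <- dict$pt_to_smq
  hit <- m$pt_key == tolower(trimws(pt)) &
    (m$scope == "both" | m$scope %in% scope)
  out <- unique(m[hit, c("smq_name", "smq_code"), drop = FALSE])
  rownames(out) <- NULL
  out
}

#' Restrict a PT set to one system organ class
#'
#' @param pts character vector of PT names.
#' @param dict a \code{\link{meddra_dictionary}}.
#' @param soc_code SOC code, e.g. \code{10007541} for Cardiac disorders.
#' @return the subset of \code{pts} mapped to \code{soc_code} (always a
#'   subset of the input; unknown PTs are dropped).
#' @export
soc_filter <- function(pts, dict, soc_code) {
  s <- dict$pt_to_soc
  keep <- tolower(trimws(pts)) %in%
    s$pt_key[as.character(s$soc_code) == as.character(soc_code)]
  pts[keep]
}

#' Event-set definitions from the SMQ catalog
#'
#' Expands a dictionary into one PT set per SMQ, the shape
#' \code{\link{dispro_screen}} consumes.
#'
#' @param dict a \code{\link{meddra_dictionary}}.
#' @param scope SMQ scopes to include.
#' @return named list of character PT vectors; names are SMQ names, with the
#'   SMQ code attached as attribute \code{smq_code} on each element.
#' @export
smq_event_sets <- function(dict, scope = c("narrow", "broad")) {
  m <- dict$pt_to_smq
  m <- m[m$scope == "both" | m$scope %in% scope, , drop = FALSE]
  out <- lapply(seq_len(nrow(dict$smq_catalog)), function(i) {
    nm <- dict$smq_catalog$smq_name[i]
    pts <- unique(m$pt[m$smq_name == nm])
    attr(pts, "smq_code") <- dict$smq_catalog$smq_code[i]
    pts
  })
  names(out) <- dict$smq_catalog$smq_name
  out
}
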