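#' Construct a validated long-format item panel
#'
#' A `dsem_panel` holds long-format repeated item responses: one row per
#' person-session, one column per item, plus optional person-constant
#' covariates. Item responses are treated as continuous reals; missing
#' responses are `NA`. Persons contribute at least two sessions; persons
#' failing that inclusion rule are dropped and recorded, mirroring standard
#' practice for session-to-session carryover models.
#'
#' @param df data.frame with columns `person_id`, `session`, the item
#'   columns, and any covariate columns.
#' @param item_ids character vector of item column names (K items).
#' @param covariate_ids character vector of person-level covariate column
#'   names (possibly empty).
#' @return An object of class `dsem_panel`: a list with elements `data`
#'   (the retained rows, ordered by person then session), `item_ids`,
#'   `covariate_ids`, and `dropped` (data.frame of person_id/reason).
#' @export
as_dsem_panel <- function(df, item_ids, covariate_ids = character()) {
  stopifnot(is.data.frame(df))
  needed <- c("person_id", "session", item_ids, covariate_ids)
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols) > 0L) {
    stop("panel schema error: missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (col in c("session", item_ids, covariate_ids)) {
    v <- df[[col]]
    if (!is.numeric(v) && !is.logical(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(as.character(v)))) & !is.na(v))
      stop("parse error: non-numeric value in column '", col, "' at row(s) ",
           paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
    }
    df[[col]] <- as.numeric(v)
  }
  df <- df[, needed, drop = FALSE]
  df <- df[order(df$person_id, df$session), , drop = FALSE]

  if (any(!is.finite(df$session) | df$session < 1 | df$session != round(df$session))) {
    stop("panel schema error: sessions must be integers >= 1", call. = FALSE)
  }

  dropped <- data.frame(person_id = character(0), reason = character(0),
                        stringsAsFactors = FALSE)

  # rows with every item missing carry no information and are removed
  all_missing <- rowSums(!is.na(as.matrix(df[, item_ids, drop = FALSE]))) == 0L
  df <- df[!all_missing, , drop = FALSE]

  keep <- rep(TRUE, nrow(df))
  for (pid in unique(df$person_id)) {
    idx <- which(df$person_id == pid)
    ses <- df$session[idx]
    if (anyDuplicated(ses)) {
      stop("panel schema error: duplicated session for person ", pid, call. = FALSE)
    }
    for (cv in covariate_ids) {
      vals <- unique(df[[cv]][idx])
      vals <- vals[!is.na(vals)]
      if (length(vals) > 1L) {
        stop("panel schema error: covariate '", cv,
             "' varies within person ", pid, call. = FALSE)
      }
    }
    if (length(idx) < 2L) {
      keep[idx] <- FALSE
      dropped <- rbind(dropped, data.frame(
        person_id = as.character(pid),
        reason = "fewer than 2 sessions", stringsAsFactors = FALSE))
    }
  }
  df <- df[keep, , drop = FALSE]
  rownames(df) <- NULL

  structure(
    list(data = df, item_ids = item_ids, covariate_ids = covariate_ids,
         dropped = dropped),
    class = "dsem_panel")
}

#' Read a long-format item panel from CSV
#'
#' The CSV must be comma-separated with a header row (UTF-8) and contain
#' `person_id`, `session`, the declared item columns and covariate columns.
#' Empty cells and `NA` are treated as missing responses. Persons observed
#' for fewer than two sessions are dropped and listed in the returned
#' object's `dropped` element.
#'
#' @param path path to the CSV file.
#' @param item_ids character vector of item column names.
#' @param covariate_ids character vector of covariate column names.
#' @return A [as_dsem_panel()] object.
#' @export
read_panel <- function(path, item_ids, covariate_ids = character()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  as_dsem_panel(df, item_ids = item_ids, covariate_ids = covariate_ids)
}

#' Write a panel back to CSV
#'
#' Responses are written at full double precision (17 significant digits) so
#' that a write/read round trip reproduces the panel exactly.
#'
#' @param panel a `dsem_panel`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  stopifnot(inherits(panel, "dsem_panel"))
  df <- panel$data
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) {
    ifelse(is.na(x), NA, formatC(x, digits = 17, format = "g"))
  })
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Summarise and validate a panel
#'
#' Computes the descriptive summary used throughout the package: number of
#' retained persons and rows, per-person series-length summary (mean / SD /
#' min / max), per-item missingness proportions, and the list of persons
#' dropped at construction.
#'
#' @param panel a `dsem_panel`.
#' @return A `dsem_validation` list with fields `n_persons`, `n_rows`,
#'   `series_length_summary`, `missing_rate_per_item`, `dropped_persons`.
#' @export
validate_panel <- function(panel) {
  stopifnot(inherits(panel, "dsem_panel"))
  df <- panel$data
  if (nrow(df) == 0L) stop("empty panel: no retained rows", call. = FALSE)
  lens <- as.numeric(table(df$person_id))
  y <- as.matrix(df[, panel$item_ids, drop = FALSE])
  miss <- colMeans(is.na(y))
  names(miss) <- panel$item_ids
  out <- list(
    n_persons = length(lens),
    n_rows = nrow(df),
    series_length_summary = c(mean = mean(lens), sd = stats::sd(lens),
                              min = min(lens), max = max(lens)),
    missing_rate_per_item = miss,
    dropped_persons = panel$dropped)
  class(out) <- "dsem_validation"
  out
}

#' @export
print.dsem_validation <- function(x, ...) {
  cat("Panel validation report\n")
  cat(sprintf("  persons: %d   rows: %d\n", x$n_persons, x$n_rows))
  s <- x$series_length_summary
  cat(sprintf("  series length: mean %.2f, sd %.2f, range [%d, %d]\n",
              s["mean"], s["sd"], s["min"], s["max"]))
  cat(sprintf("  missingness: %.1f%% (max item %.1f%%)\n",
              100 * mean(x$missing_rate_per_item),
              100 * max(x$missing_rate_per_item)))
  if (nrow(x$dropped_persons) > 0L) {
    cat(sprintf("  dropped persons: %d (%s)\n", nrow(x$dropped_persons),
                x$dropped_persons$reason[1L]))
  }
  invisible(x)
}

#' @export
print.dsem_panel <- function(x, ...) {
  cat(sprintf("dsem_panel: %d persons, %d rows, %d items",
              length(unique(x$data$person_id)), nrow(x$data),
              length(x$item_ids)))
  if (length(x$covariate_ids)) {
    cat(", covariates:", paste(x$covariate_ids, collapse = ", "))
  }
  cat("\n")
  invisible(x)
}

# internal: matrix view of one person's item responses (T x K), plus covariates
panel_person_split <- function(panel) {
  df <- panel$data
  ids <- unique(df$person_id)
  lapply(ids, function(pid) {
    rows <- df[df$person_id == pid, , drop = FALSE]
    y <- as.matrix(rows[, panel$item_ids, drop = FALSE])
    x <- if (length(panel$covariate_ids)) {
      vapply(panel$covariate_ids, function(cv) rows[[cv]][1L], numeric(1))
    } else numeric(0)
    list(person_id = pid, y = y, x = x, sessions = rows$session)
  })
}
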