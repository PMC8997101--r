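# CSV schemas and validated readers/writers for the four record streams,
# rater-response tables and truth tables. Dialect: UTF-8, comma separator,
# mandatory header, ISO-8601 dates, decimal point.

#' CSV schemas of the record streams
#'
#' Column names and types of every stream the pipeline reads or writes.
#'
#' @return Named list of schemas; each schema is a named character vector
#'   mapping column name to type (`character`, `integer`, `date`,
#'   `character_or_empty`).
#' @export
clawbench_schemas <- function() {
  list(
    trimming = c(herd_id = "character", cow_id = "character", date = "date",
                 lesion_code = "character", zone = "integer",
                 severity = "integer_or_empty", recorder = "character",
                 observer_id = "character"),
    locomotion = c(herd_id = "character", cow_id = "character", date = "date",
                   score = "integer", observer_id = "character"),
    roster = c(herd_id = "character", cow_id = "character",
               entry_date = "date", exit_date = "date_or_empty",
               calving_dates = "character_or_empty",
               dryoff_dates = "character_or_empty"),
    culling = c(herd_id = "character", cow_id = "character", date = "date",
                reason = "character"),
    ratings = c(observer_id = "character", item = "integer",
                rating = "integer", reference = "integer")
  )
}

parse_iso_date <- function(x) as.Date(x, format = "%Y-%m-%d")

# ";"-separated ISO date lists (calving_dates / dryoff_dates roster columns)
parse_date_list <- function(x) {
  x[is.na(x)] <- ""
  lapply(strsplit(x, ";", fixed = TRUE),
         function(p) parse_iso_date(p[nzchar(p)]))
}

format_date_list <- function(lst) {
  vapply(lst, function(d) paste(format(d, "%Y-%m-%d"), collapse = ";"), "")
}

# per-field checks; return character problem or NA if fine
.check_field <- function(values, type, col) {
  n <- length(values)
  problem <- rep(NA_character_, n)
  blank <- is.na(values) | values == ""
  if (type %in% c("character", "date", "integer"))
    problem[blank] <- paste0("missing value in '", col, "'")
  if (type %in% c("date", "date_or_empty")) {
    d <- parse_iso_date(values)
    bad <- !blank & is.na(d)
    problem[bad & is.na(problem)] <- paste0("unparseable ISO date in '", col, "'")
  }
  if (type %in% c("integer", "integer_or_empty")) {
    v <- suppressWarnings(as.numeric(values))
    bad <- !blank & (is.na(v) | v != round(v))
    problem[bad & is.na(problem)] <- paste0("non-integer value in '", col, "'")
  }
  problem
}

# stream-specific domain bounds
.check_domain <- function(df, stream) {
  n <- nrow(df)
  problem <- rep(NA_character_, n)
  flag <- function(bad, msg) {
    problem[bad & is.na(problem)] <<- msg
  }
  if (stream == "locomotion") {
    s <- suppressWarnings(as.numeric(df$score))
    flag(!is.na(s) & (s < 1 | s > 5),
         "locomotion score outside the 1-5 scale")
  }
  if (stream == "trimming") {
    z <- suppressWarnings(as.numeric(df$zone))
    flag(!is.na(z) & (z < 0 | z > 10), "claw zone outside 0-10")
    sev <- suppressWarnings(as.numeric(df$severity))
    flag(!is.na(sev) & !sev %in% 1:3, "severity outside 1-3")
    flag(!df$recorder %in% c("trimmer", "farmer"),
         "recorder must be 'trimmer' or 'farmer'")
    no_sev_needed <- df$lesion_code %in% c("NL", "M0")  # non-lesion records
    flag(df$recorder == "trimmer" & is.na(sev) & !no_sev_needed,
         "trimmer lesion records must carry a severity score")
  }
  if (stream == "culling")
    flag(!df$reason %in% culling_reasons(), "unknown culling reason code")
  if (stream == "ratings") {
    r <- suppressWarnings(as.numeric(df$rating))
    f <- suppressWarnings(as.numeric(df$reference))
    flag(!is.na(r) & (r < 1), "rating below 1")
    flag(!is.na(f) & (f < 1), "reference below 1")
  }
  problem
}

#' Read a validated record stream from CSV
#'
#' Reads one of the pipeline's CSV streams, checks header and per-row types
#' and domain bounds, and returns typed records. Malformed rows are dropped
#' and reported (with line numbers) in the `"malformed"` attribute; the read
#' aborts when the malformed fraction exceeds `max_malformed`.
#'
#' @param path file path.
#' @param stream schema id, one of `names(clawbench_schemas())`.
#' @param max_malformed maximum tolerated fraction of malformed data rows.
#' @return A data.frame of typed records; attribute `"malformed"` holds a
#'   data.frame (`line`, `problem`) of dropped rows.
#' @export
read_stream <- function(path, stream, max_malformed = 0.05) {
  schemas <- clawbench_schemas()
  stream <- match.arg(stream, names(schemas))
  schema <- schemas[[stream]]
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", na.strings = character())
  missing_cols <- setdiff(names(schema), names(raw))
  if (length(missing_cols))
    stop("stream '", stream, "' is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  raw <- raw[names(schema)]
  n <- nrow(raw)
  problem <- rep(NA_character_, n)
  for (col in names(schema)) {
    p <- .check_field(raw[[col]], schema[[col]], col)
    problem[is.na(problem) & !is.na(p)] <- p[is.na(problem) & !is.na(p)]
  }
  pd <- .check_domain(raw, stream)
  problem[is.na(problem) & !is.na(pd)] <- pd[is.na(problem) & !is.na(pd)]

  bad <- !is.na(problem)
  malformed <- data.frame(line = which(bad) + 1L,  # +1 for the header line
                          problem = problem[bad],
                          stringsAsFactors = FALSE)
  if (n > 0 && nrow(malformed) / n > max_malformed)
    stop("stream '", stream, "': ", nrow(malformed), " of ", n,
         " rows malformed (first: ", malformed$problem[1],
         "), above the configured cap", call. = FALSE)
  df <- raw[!bad, , drop = FALSE]
  for (col in names(schema)) {
    type <- schema[[col]]
    if (type %in% c("date", "date_or_empty")) {
      df[[col]] <- parse_iso_date(df[[col]])
    } else if (type %in% c("integer", "integer_or_empty")) {
      df[[col]] <- as.integer(suppressWarnings(as.numeric(df[[col]])))
    } else {
      df[[col]][df[[col]] == ""] <- NA_character_
      if (col %in% c("calving_dates", "dryoff_dates"))
        df[[col]][is.na(df[[col]])] <- ""
    }
  }
  rownames(df) <- NULL
  attr(df, "malformed") <- malformed
  df
}

#' Write a record stream to CSV
#'
#' Inverse of [read_stream()]; dates are written ISO-8601 so that a
#' write/read round trip reproduces the records exactly.
#'
#' @param df data.frame of records.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_stream <- function(df, path) {
  out <- df
  for (col in names(out)) {
    if (inherits(out[[col]], "Date")) out[[col]] <- format(out[[col]], "%Y-%m-%d")
  }
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}
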