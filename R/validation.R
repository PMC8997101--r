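# Record-level plausibility checks and herd-level inclusion criteria, with a
# machine-readable rejection ledger.

#' Validation configuration
#'
#' @param year study year; records outside it are rejected.
#' @param trained_share minimum share of a herd's records that must come
#'   from trained recorders (default 0.95).
#' @param trim_share minimum (distinct cows trimmed) / (mean cow number)
#'   ratio per herd (default 0.50).
#' @param min_diagnoses minimum number of distinct lesion groups among a
#'   herd's records (default 5).
#' @param require_lesion_free require at least one explicit no-lesion
#'   (`NL`) documentation per herd.
#' @param trained_observers character vector of observer ids that passed the
#'   reliability gate (see [gate_observers()]); `NULL` disables the
#'   trained-recorder rule (all observers treated as trained).
#' @return A classed list (`validation_config`).
#' @export
validation_config <- function(year = 2020,
                              trained_share = 0.95,
                              trim_share = 0.50,
                              min_diagnoses = 5,
                              require_lesion_free = TRUE,
                              trained_observers = NULL) {
  if (trained_share < 0 || trained_share > 1 || trim_share < 0)
    stop("thresholds must lie in [0, 1]", call. = FALSE)
  if (min_diagnoses < 1) stop("min_diagnoses must be >= 1", call. = FALSE)
  structure(as.list(environment()), class = "validation_config")
}

.empty_record_ledger <- function() {
  data.frame(index = integer(), herd_id = character(), cow_id = character(),
             date = as.Date(character()), rule = character(),
             all_rules = character(), stringsAsFactors = FALSE)
}

.empty_herd_ledger <- function() {
  data.frame(herd_id = character(), rule = character(), first_failing = logical(),
             measured = numeric(), threshold = numeric(),
             stringsAsFactors = FALSE)
}

new_rejection_ledger <- function(records = .empty_record_ledger(),
                                 herds = .empty_herd_ledger(),
                                 n_input = 0L, n_accepted = 0L) {
  structure(list(records = records, herds = herds,
                 summary = c(n_input = n_input, n_accepted = n_accepted,
                             n_rejected = nrow(records),
                             n_herds_excluded = length(unique(herds$herd_id)))),
            class = "rejection_ledger")
}

#' @export
print.rejection_ledger <- function(x, ...) {
  s <- x$summary
  cat("Rejection ledger:", s["n_accepted"], "of", s["n_input"],
      "records accepted,", s["n_rejected"], "rejected\n")
  if (nrow(x$records))
    print(table(rule = x$records$rule))
  if (nrow(x$herds)) {
    cat("Herd exclusions (first-failing rule):\n")
    print(table(rule = x$herds$rule[x$herds$first_failing]))
  }
  invisible(x)
}

#' Record-level validation
#'
#' Applies the record-level plausibility rules, in this order for
#' first-failing-rule reporting: `animal-id` (the cow must be on the herd
#' roster and present at the record date), `date-window` (the record date
#' must fall inside the study year) and, for trimming records,
#' `lesion-code` (the code must resolve against the vocabulary). A record is
#' rejected when any rule fails, so the accepted set does not depend on rule
#' order. Accepted records are returned unmodified.
#'
#' @param records a trimming, locomotion or culling record data.frame.
#' @param roster herd-roster data.frame ([clawbench_schemas()] `roster`).
#' @param config a [validation_config()].
#' @param stream which record stream `records` is.
#' @return list(`records` = accepted rows, `ledger` = [rejection ledger]).
#' @export
validate_records <- function(records, roster, config = validation_config(),
                             stream = c("trimming", "locomotion", "culling")) {
  stream <- match.arg(stream)
  n <- nrow(records)
  if (n == 0L)
    return(list(records = records, ledger = new_rejection_ledger()))

  # animal-id: cow on roster and present at the record date
  key <- paste(roster$herd_id, roster$cow_id)
  i <- match(paste(records$herd_id, records$cow_id), key)
  entry <- roster$entry_date[i]
  exit <- roster$exit_date[i]
  present <- !is.na(i) & records$date >= entry &
    (is.na(exit) | records$date <= exit)
  fail_id <- !present

  ystart <- as.Date(sprintf("%d-01-01", config$year))
  yend <- as.Date(sprintf("%d-12-31", config$year))
  fail_date <- is.na(records$date) | records$date < ystart | records$date > yend

  fail_code <- rep(FALSE, n)
  if (stream == "trimming")
    fail_code <- !(records$lesion_code %in% claw_lesion_codes()$code)

  fails <- cbind(`animal-id` = fail_id, `date-window` = fail_date,
                 `lesion-code` = fail_code)
  rejected <- rowSums(fails) > 0
  first_rule <- colnames(fails)[apply(fails, 1, which.max)]
  all_rules <- apply(fails, 1, function(f)
    paste(colnames(fails)[f], collapse = ";"))

  led_rec <- data.frame(index = which(rejected),
                        herd_id = records$herd_id[rejected],
                        cow_id = records$cow_id[rejected],
                        date = records$date[rejected],
                        rule = first_rule[rejected],
                        all_rules = all_rules[rejected],
                        stringsAsFactors = FALSE)
  clean <- records[!rejected, , drop = FALSE]
  rownames(clean) <- NULL
  list(records = clean,
       ledger = new_rejection_ledger(records = led_rec, n_input = n,
                                     n_accepted = nrow(clean)))
}

#' Herd-level inclusion filter
#'
#' A herd is included iff all criteria hold, evaluated in this
#' (first-failing) order: `no-roster` (the herd must have roster entries),
#' `recorder-share` (share of its records from trained recorders >=
#' `trained_share`), `trim-share` (distinct cows with a trimming record /
#' mean cow number >= `trim_share`), `lesion-free` (at least one explicit
#' no-lesion documentation, when required), `min-diagnoses` (distinct lesion
#' groups >= `min_diagnoses`). All thresholds are inclusive ("at least").
#' Measured values are stored in the ledger for every failing rule.
#'
#' @param records record-validated trimming records.
#' @param roster herd-roster data.frame.
#' @param config a [validation_config()].
#' @return list(`included` = character vector of herd ids, `ledger`).
#' @export
filter_herds <- function(records, roster, config = validation_config()) {
  herds <- sort(unique(records$herd_id))
  rows <- list()
  included <- character()
  mc_all <- mean_cow_number(roster, config$year)

  for (h in herds) {
    rec <- records[records$herd_id == h, , drop = FALSE]
    fails <- list()  # rule -> c(measured, threshold)

    if (!h %in% roster$herd_id) {
      fails[["no-roster"]] <- c(0, 1)
    } else {
      trained <- if (is.null(config$trained_observers)) {
        rep(TRUE, nrow(rec))
      } else {
        rec$observer_id %in% config$trained_observers
      }
      share_trained <- mean(trained)
      if (share_trained < config$trained_share)
        fails[["recorder-share"]] <- c(share_trained, config$trained_share)

      mc <- mc_all[match(h, names(mc_all))]
      share_trim <- if (isTRUE(mc > 0)) {
        length(unique(rec$cow_id)) / mc
      } else {
        0
      }
      if (share_trim < config$trim_share)
        fails[["trim-share"]] <- c(share_trim, config$trim_share)

      if (config$require_lesion_free && !any(rec$lesion_code == "NL"))
        fails[["lesion-free"]] <- c(0, 1)

      grp <- lesion_group(rec$lesion_code, rec$severity)
      n_diag <- length(unique(grp[!is.na(grp)]))
      if (n_diag < config$min_diagnoses)
        fails[["min-diagnoses"]] <- c(n_diag, config$min_diagnoses)
    }

    if (length(fails)) {
      rows[[h]] <- data.frame(
        herd_id = h, rule = names(fails),
        first_failing = seq_along(fails) == 1L,
        measured = vapply(fails, `[`, 0, 1),
        threshold = vapply(fails, `[`, 0, 2),
        stringsAsFactors = FALSE)
    } else {
      included <- c(included, h)
    }
  }
  led_herds <- if (length(rows)) do.call(rbind, c(rows, make.row.names = FALSE))
               else .empty_herd_ledger()
  list(included = included,
       ledger = new_rejection_ledger(herds = led_herds,
                                     n_input = nrow(records),
                                     n_accepted = nrow(records)))
}
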