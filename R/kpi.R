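# Per-herd key performance indicators: mean cow number, severity recoding,
# lameness incidence risk by threshold and cow group, the 13 lesion-group
# incidence risks, the painful-'alarm' incidence risk, the DD-endemic flag
# and the annual claw/limb culling risk.

#' Mean cow number per herd
#'
#' Total cow-days within the year divided by the number of days in the year
#' (366 in leap years unless `days_in_year` is fixed); the denominator of
#' the claw-lesion incidence risks.
#'
#' @param roster herd-roster data.frame.
#' @param year study year.
#' @param days_in_year `"auto"` (calendar length of `year`) or a number.
#' @return Named numeric vector (herd id -> mean cow number). Empty-roster
#'   herds are simply absent; callers treat missing herds as 0 with a flag.
#' @export
#' @examples
#' r <- data.frame(herd_id = "H1", cow_id = "c1",
#'                 entry_date = as.Date("2020-01-01"),
#'                 exit_date = as.Date(NA),
#'                 calving_dates = "", dryoff_dates = "")
#' mean_cow_number(r, 2020)  # 1
mean_cow_number <- function(roster, year, days_in_year = "auto") {
  ystart <- as.Date(sprintf("%d-01-01", year))
  yend <- as.Date(sprintf("%d-12-31", year))
  denom <- if (identical(days_in_year, "auto")) {
    as.numeric(yend - ystart) + 1
  } else {
    as.numeric(days_in_year)
  }
  if (nrow(roster) == 0L) {
    warning("empty roster: mean cow number undefined", call. = FALSE)
    return(stats::setNames(numeric(0), character(0)))
  }
  exit <- roster$exit_date
  exit[is.na(exit)] <- yend
  days <- pmax(0, as.numeric(pmin(exit, yend) - pmax(roster$entry_date, ystart)) + 1)
  out <- tapply(days, roster$herd_id, sum) / denom
  stats::setNames(as.numeric(out), names(out))
}

#' Severity recoding of validated trimming records
#'
#' Prepares analysis records: farmer-app records without a severity score
#' receive the configured conventional severity (default 2, so they survive
#' the mild-lesion drop); severity-1 trimmer records of the
#' severity-sensitive lesions (sole haemorrhage, double sole, white line
#' disease, heel horn erosion) are dropped; the analysis columns `group`
#' (with white line disease of severity 2-3 regrouped as `WLA`) and `alarm`
#' are appended.
#'
#' @param records validated trimming records.
#' @param farmer_severity severity assigned to severity-less farmer-app
#'   records.
#' @return The analysis records (a subset of rows, two extra columns).
#' @export
recode_severity <- function(records, farmer_severity = 2L) {
  rec <- records
  fill <- rec$recorder == "farmer" & is.na(rec$severity)
  rec$severity[fill] <- as.integer(farmer_severity)
  v <- claw_lesion_codes()
  sens <- v$code[v$severity_sensitive]
  drop <- rec$recorder == "trimmer" & !is.na(rec$severity) &
    rec$severity == 1L & rec$lesion_code %in% sens
  rec <- rec[!drop, , drop = FALSE]
  rec$group <- lesion_group(rec$lesion_code, rec$severity)
  rec$alarm <- is_alarm(rec$lesion_code, rec$severity)
  rownames(rec) <- NULL
  rec
}

# roster-derived cow-state lookup: for cow indices `i` and dates `d`,
# returns the latest calving <= d and dry status at d
.cow_state <- function(roster, i, d) {
  if (is.null(attr(roster, "cb_parsed"))) {
    stop("internal: roster must be prepared with .prepare_roster")
  }
  prep <- attr(roster, "cb_parsed")
  last_before <- function(mat, d) {
    best <- rep(-Inf, length(d))
    if (ncol(mat)) {
      for (k in seq_len(ncol(mat))) {
        v <- mat[i, k]
        ok <- !is.na(v) & v <= as.numeric(d)
        best[ok] <- pmax(best[ok], v[ok])
      }
    }
    best
  }
  last_calv <- last_before(prep$calv, d)
  last_dry <- last_before(prep$dry, d)
  dry <- is.finite(last_dry) & last_dry > last_calv
  list(last_calving = last_calv, dry = dry,
       dim = as.numeric(d) - last_calv)
}

.prepare_roster <- function(roster) {
  to_mat <- function(lst) {
    k <- max(1L, max(lengths(lst)))
    m <- matrix(NA_real_, nrow = length(lst), ncol = k)
    for (j in seq_along(lst)) {
      v <- as.numeric(lst[[j]])
      if (length(v)) m[j, seq_along(v)] <- v
    }
    m
  }
  attr(roster, "cb_parsed") <- list(
    calv = to_mat(parse_date_list(roster$calving_dates)),
    dry = to_mat(parse_date_list(roster$dryoff_dates))
  )
  roster
}

#' Lameness incidence risk per herd
#'
#' For each locomotion-scoring date, the share of scored cows in the cow
#' group with a locomotion score at or above the threshold; every lame cow
#' at a scoring date counts as a new case. The herd value is the mean of the
#' per-date shares over the year, in percent. Cows present but not scored at
#' a date are excluded from that date's denominator; dates with no scored
#' cows in the group are skipped.
#'
#' @param locomotion validated locomotion records.
#' @param roster herd-roster data.frame.
#' @param threshold lameness threshold on the 1-5 scale: 2, 3 or 4.
#' @param group `"all"` (all lactating cows), `"dry"` (between dry-off and
#'   next calving) or `"dim100"` (first 100 days in milk).
#' @param year study year.
#' @return data.frame `herd_id`, `value` (%; `NA` when the group was never
#'   scored), `n_dates`, `n_scorings`.
#' @export
ir_lame <- function(locomotion, roster, threshold = 2,
                    group = c("all", "dry", "dim100"), year = 2020) {
  group <- match.arg(group)
  stopifnot(threshold %in% 2:4)
  herds <- sort(unique(locomotion$herd_id))
  if (!nrow(locomotion))
    return(data.frame(herd_id = character(), value = numeric(),
                      n_dates = integer(), n_scorings = integer(),
                      stringsAsFactors = FALSE))
  roster <- .prepare_roster(roster)
  i <- match(paste(locomotion$herd_id, locomotion$cow_id),
             paste(roster$herd_id, roster$cow_id))
  st <- .cow_state(roster, i, locomotion$date)
  member <- switch(group,
    all = is.finite(st$last_calving) & !st$dry,
    dry = st$dry,
    dim100 = !st$dry & is.finite(st$dim) & st$dim >= 0 & st$dim <= 100)
  member[is.na(member)] <- FALSE

  loc <- locomotion[member, , drop = FALSE]
  out <- lapply(herds, function(h) {
    d <- loc[loc$herd_id == h, , drop = FALSE]
    if (!nrow(d))
      return(data.frame(herd_id = h, value = NA_real_, n_dates = 0L,
                        n_scorings = 0L, stringsAsFactors = FALSE))
    shares <- tapply(d$score >= threshold, format(d$date), mean)
    data.frame(herd_id = h, value = 100 * mean(shares),
               n_dates = length(shares), n_scorings = nrow(d),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# shared engine of ir_clawl / ir_alarm: counts distinct affected cows
# (cow-year) or distinct cow x visit-date pairs (cow-visit) per herd
.ir_records <- function(records, roster, select, year, mode) {
  mc <- mean_cow_number(roster, year)
  herds <- sort(unique(c(names(mc), records$herd_id)))
  sel <- records[select, , drop = FALSE]
  num <- if (mode == "cow-year") {
    tapply(sel$cow_id, sel$herd_id, function(x) length(unique(x)))
  } else {
    tapply(paste(sel$cow_id, sel$date), sel$herd_id,
           function(x) length(unique(x)))
  }
  n <- as.numeric(num[match(herds, names(num))])
  n[is.na(n)] <- 0
  m <- as.numeric(mc[match(herds, names(mc))])
  undefined <- is.na(m) | m <= 0
  value <- ifelse(undefined, NA_real_, 100 * n / m)
  data.frame(herd_id = herds, value = value, n_cases = n,
             mean_cows = ifelse(undefined, NA_real_, m),
             undefined = undefined, stringsAsFactors = FALSE)
}

#' Claw-lesion incidence risk per herd
#'
#' Incidence risk of one lesion group: new cases within the year divided by
#' the mean cow number, in percent. In the default `"cow-year"` counting
#' mode a cow counts once per group and year (share of cattle with at least
#' one documented lesion of the group); in `"cow-visit"` mode each affected
#' cow x visit-date pair counts as a new case.
#'
#' @param records analysis records from [recode_severity()].
#' @param roster herd-roster data.frame.
#' @param group one of [benchmark_groups()] (or `"other"`).
#' @param year study year.
#' @param mode counting mode.
#' @return data.frame `herd_id`, `value` (%), `n_cases`, `mean_cows`,
#'   `undefined` (zero mean cow number).
#' @export
ir_clawl <- function(records, roster, group, year = 2020,
                     mode = c("cow-year", "cow-visit")) {
  mode <- match.arg(mode)
  if (is.null(records$group))
    stop("records must carry the analysis 'group' column; run recode_severity()",
         call. = FALSE)
  .ir_records(records, roster, !is.na(records$group) & records$group == group,
              year, mode)
}

#' 'Alarm' lesion incidence risk per herd
#'
#' As [ir_clawl()], with the painful-lesion predicate [is_alarm()] in place
#' of a single lesion group.
#'
#' @inheritParams ir_clawl
#' @return data.frame as [ir_clawl()].
#' @export
ir_alarm <- function(records, roster, year = 2020,
                     mode = c("cow-year", "cow-visit")) {
  mode <- match.arg(mode)
  if (is.null(records$alarm))
    stop("records must carry the analysis 'alarm' column; run recode_severity()",
         call. = FALSE)
  .ir_records(records, roster, isTRUE_v(records$alarm), year, mode)
}

isTRUE_v <- function(x) !is.na(x) & x

#' Digital-dermatitis endemicity per herd
#'
#' A herd is endemically DD-infected when more than `dd_min_cows - 1`
#' distinct cows (default: more than two, i.e. at least three) have a record
#' of any DD stage M1-M4.1 in the year. Only endemic herds enter the DD
#' benchmark.
#'
#' @param records analysis (or validated) trimming records.
#' @param dd_min_cows minimum distinct affected cows (default 3).
#' @return data.frame `herd_id`, `n_dd_cows`, `dd_endemic`.
#' @export
dd_endemic <- function(records, dd_min_cows = 3L) {
  m <- records$lesion_code %in% setdiff(dd_stages(), "M0")
  herds <- sort(unique(records$herd_id))
  cnt <- tapply(records$cow_id[m], records$herd_id[m],
                function(x) length(unique(x)))
  n <- as.integer(cnt[match(herds, names(cnt))])
  n[is.na(n)] <- 0L
  data.frame(herd_id = herds, n_dd_cows = n,
             dd_endemic = n >= dd_min_cows, stringsAsFactors = FALSE)
}

#' Annual culling risk due to claw and limb disorders
#'
#' Per herd-year: culls with reason `"claw_limb"` as a percentage of all
#' culls. Herds with no culls at all report 0 with `zero_culls = TRUE` (they
#' enter the benchmark distribution at 0).
#'
#' @param culling validated culling records.
#' @param herds optional herd ids to report (default: herds in `culling`).
#' @return data.frame `herd_id`, `value` (%), `n_culls`, `n_claw_culls`,
#'   `zero_culls`.
#' @export
acr_claw <- function(culling, herds = NULL) {
  if (is.null(herds)) herds <- sort(unique(culling$herd_id))
  tot <- tapply(culling$cow_id, culling$herd_id, length)
  claw <- tapply(culling$reason == "claw_limb", culling$herd_id, sum)
  n <- as.integer(tot[match(herds, names(tot))])
  n[is.na(n)] <- 0L
  k <- as.integer(claw[match(herds, names(claw))])
  k[is.na(k)] <- 0L
  data.frame(herd_id = herds,
             value = ifelse(n == 0L, 0, 100 * k / n),
             n_culls = n, n_claw_culls = k, zero_culls = n == 0L,
             stringsAsFactors = FALSE)
}

#' All KPIs per herd-year
#'
#' Assembles the full per-herd KPI set: mean cow number, lameness incidence
#' risks at thresholds >=2/>=3/>=4 for all-lactating, dry and first-100-DIM
#' cows, the 13 lesion-group incidence risks, the 'alarm' incidence risk,
#' the DD-endemic flag and the annual claw/limb culling risk.
#'
#' @param trimming analysis trimming records ([recode_severity()] output).
#' @param locomotion validated locomotion records (may be empty).
#' @param roster herd-roster data.frame.
#' @param culling validated culling records.
#' @param year study year.
#' @param mode counting mode for lesion incidence risks.
#' @param dd_min_cows endemicity threshold, see [dd_endemic()].
#' @return data.frame of class `herd_kpi_set`, one row per herd. Lameness
#'   columns are `NA` for herds without locomotion scorings; `ir_DD` is `NA`
#'   (not applicable) for non-endemic herds.
#' @export
herd_kpis <- function(trimming, locomotion, roster, culling, year = 2020,
                      mode = c("cow-year", "cow-visit"), dd_min_cows = 3L) {
  mode <- match.arg(mode)
  mc <- mean_cow_number(roster, year)
  herds <- sort(unique(c(trimming$herd_id, names(mc))))
  out <- data.frame(herd_id = herds, year = year,
                    mean_cows = as.numeric(mc[match(herds, names(mc))]),
                    stringsAsFactors = FALSE)

  for (thr in 2:4) {
    for (g in c("all", "dry", "dim100")) {
      col <- sprintf("ir_lame_ge%d_%s", thr, g)
      r <- ir_lame(locomotion, roster, threshold = thr, group = g, year = year)
      out[[col]] <- r$value[match(herds, r$herd_id)]
    }
  }
  for (g in benchmark_groups()) {
    r <- ir_clawl(trimming, roster, group = g, year = year, mode = mode)
    out[[paste0("ir_", g)]] <- r$value[match(herds, r$herd_id)]
  }
  al <- ir_alarm(trimming, roster, year = year, mode = mode)
  out$ir_alarm <- al$value[match(herds, al$herd_id)]
  dd <- dd_endemic(trimming, dd_min_cows = dd_min_cows)
  out$dd_endemic <- dd$dd_endemic[match(herds, dd$herd_id)]
  out$dd_endemic[is.na(out$dd_endemic)] <- FALSE
  out$ir_DD[!out$dd_endemic] <- NA_real_  # DD benchmarked in endemic herds only
  ac <- acr_claw(culling, herds = herds)
  out$acr_claw <- ac$value[match(herds, ac$herd_id)]
  out$n_culls <- ac$n_culls[match(herds, ac$herd_id)]
  class(out) <- c("herd_kpi_set", "data.frame")
  out
}

#' @export
print.herd_kpi_set <- function(x, ...) {
  cat("Herd KPI set:", nrow(x), "herds, year", x$year[1], "\n")
  print.data.frame(utils::head(as.data.frame(x), 6), digits = 3)
  if (nrow(x) > 6) cat("...", nrow(x) - 6, "more herds\n")
  invisible(x)
}
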