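# Percentile benchmark tables, six-band farm classification and the
# MY FARM comparison report.

.percentile_probs <- c(p10 = 0.10, p25 = 0.25, p50 = 0.50,
                       p75 = 0.75, p90 = 0.90)

#' Percentile benchmark row for one KPI
#'
#' Summarises one KPI over the included herds into min, mean, SD and the
#' 10th/25th/50th/75th/90th percentiles (linear interpolation between order
#' statistics, `stats::quantile` type 7). Values are kept at full precision;
#' rounding to one decimal happens only when rendering.
#'
#' @param values numeric vector of per-herd KPI values (`NA`s are herds for
#'   which the KPI is undefined and are dropped).
#' @param kpi id of the KPI.
#' @param note free-text inclusion note (e.g. "endemic herds only").
#' @return One-row data.frame: `kpi`, `n`, `min`, `mean`, `sd`, `p10`,
#'   `p25`, `p50`, `p75`, `p90`, `max`, `empty`, `note`. With fewer than two
#'   defined values the row is flagged `empty` and statistics are `NA`.
#' @export
#' @examples
#' build_benchmark(c(rep(0, 9), 100), "acr_claw")
build_benchmark <- function(values, kpi, note = "") {
  v <- values[!is.na(values)]
  if (length(v) < 2) {
    return(data.frame(kpi = kpi, n = length(v), min = NA_real_,
                      mean = NA_real_, sd = NA_real_, p10 = NA_real_,
                      p25 = NA_real_, p50 = NA_real_, p75 = NA_real_,
                      p90 = NA_real_, max = NA_real_, empty = TRUE,
                      note = note, stringsAsFactors = FALSE))
  }
  q <- stats::quantile(v, probs = .percentile_probs, type = 7, names = FALSE)
  data.frame(kpi = kpi, n = length(v), min = min(v), mean = mean(v),
             sd = stats::sd(v), p10 = q[1], p25 = q[2], p50 = q[3],
             p75 = q[4], p90 = q[5], max = max(v), empty = FALSE,
             note = note, stringsAsFactors = FALSE)
}

#' Benchmark tables for a herd KPI set
#'
#' One [build_benchmark()] row per KPI column of a [herd_kpis()] table. The
#' digital-dermatitis KPI is restricted to endemically infected herds.
#'
#' @param kpis a `herd_kpi_set` data.frame.
#' @param kpi_cols KPI columns to benchmark (default: every `ir_*` column
#'   plus `acr_claw`).
#' @return data.frame of class `benchmark_table`, one row per KPI.
#' @export
benchmark_tables <- function(kpis, kpi_cols = NULL) {
  if (is.null(kpi_cols))
    kpi_cols <- c(grep("^ir_", names(kpis), value = TRUE), "acr_claw")
  rows <- lapply(kpi_cols, function(col) {
    v <- kpis[[col]]
    note <- ""
    if (col == "ir_DD") {
      v <- v[isTRUE_v(kpis$dd_endemic)]
      note <- sprintf("DD-endemic herds only (n = %d)", sum(!is.na(v)))
    }
    build_benchmark(v, col, note = note)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("benchmark_table", "data.frame")
  out
}

#' @export
print.benchmark_table <- function(x, ...) {
  cat("Benchmark table (", nrow(x), " KPIs)\n", sep = "")
  d <- as.data.frame(x)
  num <- vapply(d, is.numeric, TRUE)
  d[num] <- lapply(d[num], round, 1)
  print.data.frame(d[c("kpi", "n", "min", "mean", "p10", "p25", "p50",
                       "p75", "p90", "max")], row.names = FALSE)
  invisible(x)
}

#' Classify a farm value into a percentile band
#'
#' Assigns one of six contiguous bands (lower is better for every KPI in
#' scope); boundary values go to the better (lower) band, matching the
#' inclusive "good (<= 10th percentile)" convention. The conventional
#' good/moderate/poor labels are attached where defined: good for values
#' <= P10, moderate for values in [P25, P50), poor for values >= P50 (the
#' interval (P10, P25) carries no label).
#'
#' @param value the farm's KPI value.
#' @param table one-row benchmark data.frame from [build_benchmark()].
#' @return list(`kpi`, `value`, `band`, `label`).
#' @export
#' @examples
#' tab <- build_benchmark(1:100, "demo")
#' classify_farm(tab$p10, tab)$band  # "<=P10"
classify_farm <- function(value, table) {
  stopifnot(nrow(table) == 1)
  if (isTRUE(table$empty) || is.na(value)) {
    return(list(kpi = table$kpi, value = value, band = "not evaluable",
                label = NA_character_))
  }
  cuts <- c(table$p10, table$p25, table$p50, table$p75, table$p90)
  bands <- c("<=P10", "(P10,P25]", "(P25,P50]", "(P50,P75]", "(P75,P90]",
             ">P90")
  band <- bands[findInterval(value, cuts, left.open = TRUE) + 1L]
  label <- if (value <= table$p10) {
    "good"
  } else if (value >= table$p25 && value < table$p50) {
    "moderate"
  } else if (value >= table$p50) {
    "poor"
  } else {
    NA_character_
  }
  list(kpi = table$kpi, value = value, band = band, label = label)
}

#' MY FARM comparison report
#'
#' The percentile benchmark grid with an additional column holding one
#' farm's own KPI values and their band assignment. The farm must be present
#' in the KPI table but need not belong to the benchmark population. The DD
#' row of a non-endemic farm is reported as not applicable (herd DD-free).
#'
#' @param herd_id the farm.
#' @param kpis `herd_kpi_set` containing the farm.
#' @param tables `benchmark_table` from [benchmark_tables()].
#' @return data.frame of class `my_farm_report`: the benchmark columns plus
#'   `my_farm`, `band`, `label`, `farm_note`.
#' @export
my_farm_report <- function(herd_id, kpis, tables) {
  row <- kpis[kpis$herd_id == herd_id, , drop = FALSE]
  if (nrow(row) != 1)
    stop("herd '", herd_id, "' not found in the KPI table", call. = FALSE)
  res <- tables
  res$my_farm <- NA_real_
  res$band <- NA_character_
  res$label <- NA_character_
  res$farm_note <- ""
  for (i in seq_len(nrow(res))) {
    kpi <- res$kpi[i]
    val <- row[[kpi]]
    if (kpi == "ir_DD" && !isTRUE(row$dd_endemic)) {
      res$band[i] <- "not applicable (herd DD-free)"
      next
    }
    cl <- classify_farm(val, tables[i, , drop = FALSE])
    res$my_farm[i] <- val
    res$band[i] <- cl$band
    res$label[i] <- cl$label
  }
  attr(res, "herd_id") <- herd_id
  class(res) <- c("my_farm_report", "data.frame")
  res
}

#' @export
print.my_farm_report <- function(x, ...) {
  cat("MY FARM report for herd", attr(x, "herd_id"), "\n")
  d <- as.data.frame(x)
  num <- vapply(d, is.numeric, TRUE)
  d[num] <- lapply(d[num], round, 1)
  print.data.frame(d[c("kpi", "mean", "p10", "p25", "p50", "p75", "p90",
                       "my_farm", "band", "label")], row.names = FALSE)
  invisible(x)
}

#' Render a MY FARM report as markdown lines
#'
#' Deterministic human-readable rendering (one value per KPI, rounded to one
#' decimal at rendering only).
#'
#' @param report a [my_farm_report()].
#' @return Character vector of markdown lines.
#' @export
render_report_md <- function(report) {
  stopifnot(inherits(report, "my_farm_report"))
  fmt <- function(x) ifelse(is.na(x), "-", sprintf("%.1f", x))
  lines <- c(sprintf("# MY FARM claw-health report: %s", attr(report, "herd_id")),
             "",
             "| KPI | Mean | 10th | 25th | Median | 75th | 90th | MY FARM | Band | Label |",
             "|---|---|---|---|---|---|---|---|---|---|")
  for (i in seq_len(nrow(report))) {
    r <- report[i, ]
    lines <- c(lines, sprintf("| %s | %s | %s | %s | %s | %s | %s | %s | %s | %s |",
                              r$kpi, fmt(r$mean), fmt(r$p10), fmt(r$p25),
                              fmt(r$p50), fmt(r$p75), fmt(r$p90),
                              fmt(r$my_farm), r$band,
                              ifelse(is.na(r$label), "-", r$label)))
  }
  lines
}
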