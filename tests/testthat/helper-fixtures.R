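# Shared fixtures, built in code.

# simple roster row constructor
roster_row <- function(herd, cow, entry, exit = NA, calvings = "", dryoffs = "") {
  data.frame(herd_id = herd, cow_id = cow,
             entry_date = as.Date(entry),
             exit_date = as.Date(exit),
             calving_dates = calvings, dryoff_dates = dryoffs,
             stringsAsFactors = FALSE)
}

trim_row <- function(herd, cow, date, code, sev = 2L, recorder = "trimmer",
                     observer = "T1", zone = 5L) {
  data.frame(herd_id = herd, cow_id = cow, date = as.Date(date),
             lesion_code = code, zone = zone, severity = as.integer(sev),
             recorder = recorder, observer_id = observer,
             stringsAsFactors = FALSE)
}

# One shared moderately sized simulated population (cached across test files)
.fixture_env <- new.env()

get_sim500 <- function() {
  if (is.null(.fixture_env$sim500)) {
    .fixture_env$sim500 <- simulate_population(
      sim_config(n_herds = 500, seed = 20260920L))
  }
  .fixture_env$sim500
}

get_kpis500 <- function() {
  if (is.null(.fixture_env$kpis500)) {
    pop <- get_sim500()
    an <- recode_severity(pop$trimming)
    .fixture_env$kpis500 <- herd_kpis(an, pop$locomotion, pop$roster,
                                      pop$culling, year = 2020)
  }
  .fixture_env$kpis500
}

# The constructed record/herd filter-cascade fixture: 20 records, 6 herds.
# Record-rule violations (exactly one each): an animal-id violation (herd F6
# has no roster), a date-window violation and an unresolvable lesion code
# (both in herd F1). Herd-rule failures (exactly one herd each, with
# min_diagnoses = 3): F2 recorder-share, F3 trim-share, F4 lesion-free,
# F5 min-diagnoses; F1 passes everything.
cascade_fixture <- function() {
  roster <- rbind(
    roster_row("F1", "c1", "2019-01-01"), roster_row("F1", "c2", "2019-01-01"),
    roster_row("F2", "c1", "2019-01-01"), roster_row("F2", "c2", "2019-01-01"),
    roster_row("F3", "c1", "2019-01-01"), roster_row("F3", "c2", "2019-01-01"),
    roster_row("F3", "c3", "2019-01-01"), roster_row("F3", "c4", "2019-01-01"),
    roster_row("F4", "c1", "2019-01-01"), roster_row("F4", "c2", "2019-01-01"),
    roster_row("F5", "c1", "2019-01-01"), roster_row("F5", "c2", "2019-01-01")
  )
  records <- rbind(
    # F1: clean herd (3 groups + NL) plus the two in-herd record violations
    trim_row("F1", "c1", "2020-04-01", "SU"),
    trim_row("F1", "c2", "2020-04-01", "M2"),
    trim_row("F1", "c1", "2020-04-01", "CC"),
    trim_row("F1", "c2", "2020-04-01", "NL", sev = NA),
    trim_row("F1", "c1", "2019-12-31", "SU"),          # date-window
    trim_row("F1", "c2", "2020-04-01", "XX"),          # lesion-code
    # F2: one untrained recorder among four records
    trim_row("F2", "c1", "2020-04-01", "SU"),
    trim_row("F2", "c2", "2020-04-01", "M2"),
    trim_row("F2", "c1", "2020-04-01", "CC", observer = "TX"),
    trim_row("F2", "c2", "2020-04-01", "NL", sev = NA),
    # F3: all records on one cow of four -> trim share 0.25
    trim_row("F3", "c1", "2020-04-01", "SU"),
    trim_row("F3", "c1", "2020-04-01", "M2"),
    trim_row("F3", "c1", "2020-04-01", "CC"),
    trim_row("F3", "c1", "2020-04-01", "NL", sev = NA),
    # F4: no lesion-free documentation
    trim_row("F4", "c1", "2020-04-01", "SU"),
    trim_row("F4", "c2", "2020-04-01", "M2"),
    trim_row("F4", "c1", "2020-04-01", "CC"),
    # F5: only one lesion group
    trim_row("F5", "c1", "2020-04-01", "SU"),
    trim_row("F5", "c2", "2020-04-01", "NL", sev = NA),
    # F6: herd without roster -> animal-id violation
    trim_row("F6", "c1", "2020-04-01", "SU")
  )
  config <- validation_config(year = 2020, min_diagnoses = 3,
                              trained_observers = c("T1"))
  list(roster = roster, records = records, config = config)
}

# independent percentile oracle: sort and linearly interpolate order stats
oracle_percentile <- function(v, p) {
  v <- sort(v)
  n <- length(v)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  v[lo] + (h - lo) * (v[hi] - v[lo])
}

# independent weighted-kappa oracle: explicit cell enumeration on a k x k
# contingency table of counts
oracle_kappa_table <- function(tab, weights = "linear") {
  k <- nrow(tab)
  n <- sum(tab)
  wo <- 0
  we <- 0
  pr <- rowSums(tab) / n
  pc <- colSums(tab) / n
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      w <- abs(i - j) / (k - 1)
      if (weights == "quadratic") w <- w^2
      wo <- wo + w * tab[i, j] / n
      we <- we + w * pr[i] * pc[j]
    }
  }
  if (we == 0) {
    if (wo == 0) return(1)
    return(NA_real_)
  }
  unname(1 - wo / we)
}

# expand a k x k count table into the two rating vectors it tabulates
expand_table <- function(tab) {
  k <- nrow(tab)
  idx <- which(tab > 0, arr.ind = TRUE)
  reps <- tab[tab > 0]
  list(ratings = rep(idx[, 1], reps), reference = rep(idx[, 2], reps))
}
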