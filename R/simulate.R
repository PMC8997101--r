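# Synthetic herd generator: rosters, trimming visits with lesions,
# locomotion scorings, culling events and rater-response tables with the
# statistical structure the analysis pipeline assumes, under a fixed seed.

#' Default between-herd lesion-incidence priors
#'
#' Per benchmark group (digital dermatitis excluded; it is driven by the
#' endemicity model): the population mean annual cow-level incidence, the
#' probability that a herd is entirely free of the lesion (zero inflation,
#' chosen so rare lesions show the many-zero-herd, long-right-tail spread
#' seen in routinely recorded trimming data) and the beta shape mass `phi`
#' (= alpha + beta) of the non-zero herd incidences.
#'
#' @return data.frame with columns `group`, `mean`, `zero_prob`, `phi`.
#' @export
default_lesion_priors <- function() {
  data.frame(
    group     = c("TS",   "IP",   "SW",   "HF",   "IH",  "DS",  "CC",
                  "HHE",  "SH",   "WLA",  "UL",   "CD"),
    mean      = c(0.007,  0.008,  0.019,  0.026,  0.050, 0.081, 0.083,
                  0.110,  0.121,  0.125,  0.136,  0.181),
    zero_prob = c(0.92,   0.82,   0.78,   0.55,   0.42,  0.32,  0.45,
                  0.50,   0.35,   0.20,   0.15,   0.18),
    phi       = c(3, 6, 6, 8, 9, 9, 5, 3, 7, 8, 9, 6),
    stringsAsFactors = FALSE
  )
}

#' Simulation configuration
#'
#' Study conditions of the synthetic population. Defaults emulate a
#' routinely recorded national claw-health data set: 512 herds with mean
#' size 34.8 cows (range 16-163), two to three trimming visits per herd-year
#' at 4-6-month spacing, locomotion scores with marginal multinomial
#' (61.7, 24.2, 8.8, 4.3, 1.0)% for scores 1-5, 55.8% of herds endemically
#' DD-infected, about 6.7 scorings per cow-year in the scored herds, and
#' zero-inflated claw-related culling (median herd has none).
#'
#' @param n_herds number of herds.
#' @param year study year (closed calendar year).
#' @param herd_size_meanlog,herd_size_sdlog lognormal herd-size parameters
#'   (truncated to `[herd_size_min, herd_size_max]`; defaults give mean
#'   ~34.8).
#' @param herd_size_min,herd_size_max herd-size truncation bounds.
#' @param p_three_visits probability a herd is trimmed three (rather than
#'   two) times in the year.
#' @param visit_spacing_days min/max days between consecutive visits.
#' @param trimmed_fraction fraction of present cows trimmed at each visit.
#' @param lesion_priors data.frame as [default_lesion_priors()].
#' @param locomotion_probs multinomial probabilities of locomotion scores
#'   1-5 (must sum to 1).
#' @param herd_lame_sd,cow_lame_sd between-herd and within-herd SD of the
#'   lameness (score >= 2) propensity.
#' @param scoring_interval_days days between herd locomotion-scoring dates.
#' @param p_scored_lactating,p_scored_dry probability a present lactating /
#'   dry cow is scored at a scoring date.
#' @param locomotion_herd_fraction fraction of herds with locomotion
#'   scoring at all (the lameness stream typically covers a subset of the
#'   claw-trimmed herds).
#' @param dd_endemic_fraction fraction of herds endemically DD-infected.
#' @param dd_beta_shape1,dd_beta_shape2 beta shape of the within-herd DD
#'   incidence of endemic herds above its floor.
#' @param annual_cull_prob per-cow annual culling probability.
#' @param claw_cull_zero_prob probability a herd has no claw/limb-related
#'   culling propensity at all (zero inflation).
#' @param claw_cull_share_mean,claw_cull_share_phi beta mean/shape-mass of
#'   the claw/limb share among culls for herds with non-zero propensity.
#' @param severity1_noise_rate per cow-visit rate of incidental severity-1
#'   records of the severity-sensitive lesions (dropped during severity
#'   recoding).
#' @param calving_interval_days,dry_period_days reproduction cycle used to
#'   build cow timelines (dry-off `dry_period_days` before next calving).
#' @param seed integer seed; expanded into independent substreams per
#'   record stream so adding a stream does not perturb the others.
#' @return A classed list (`sim_config`).
#' @export
sim_config <- function(n_herds = 512,
                       year = 2020,
                       herd_size_meanlog = 3.395,
                       herd_size_sdlog = 0.45,
                       herd_size_min = 16,
                       herd_size_max = 163,
                       p_three_visits = 0.3,
                       visit_spacing_days = c(120, 180),
                       trimmed_fraction = 0.8,
                       lesion_priors = default_lesion_priors(),
                       locomotion_probs = c(0.617, 0.242, 0.088, 0.043, 0.010),
                       herd_lame_sd = 0.16,
                       cow_lame_sd = 0.12,
                       scoring_interval_days = 35,
                       p_scored_lactating = 0.70,
                       p_scored_dry = 0.25,
                       locomotion_herd_fraction = 99 / 512,
                       dd_endemic_fraction = 0.558,
                       dd_beta_shape1 = 0.5,
                       dd_beta_shape2 = 2.3,
                       annual_cull_prob = 0.25,
                       claw_cull_zero_prob = 0.52,
                       claw_cull_share_mean = 0.177,
                       claw_cull_share_phi = 2.5,
                       severity1_noise_rate = 0.04,
                       calving_interval_days = 380,
                       dry_period_days = 60,
                       seed = 1L) {
  cfg <- as.list(environment())
  if (cfg$herd_size_min > cfg$herd_size_max)
    stop("infeasible config: herd_size_min > herd_size_max", call. = FALSE)
  if (abs(sum(cfg$locomotion_probs) - 1) > 1e-6 ||
      any(cfg$locomotion_probs < 0))
    stop("locomotion_probs must be a probability vector summing to 1",
         call. = FALSE)
  probs01 <- c(cfg$trimmed_fraction, cfg$dd_endemic_fraction,
               cfg$annual_cull_prob, cfg$claw_cull_zero_prob,
               cfg$p_scored_lactating, cfg$p_scored_dry,
               cfg$locomotion_herd_fraction, cfg$p_three_visits)
  if (any(probs01 < 0 | probs01 > 1))
    stop("probability parameters must lie in [0, 1]", call. = FALSE)
  class(cfg) <- "sim_config"
  cfg
}

# substream seeds: one global seed expands deterministically per stream
.stream_seed <- function(seed, k) (abs(as.integer(seed)) %% 2^27L) * 16L + k

# truncated lognormal herd sizes
.sim_herd_sizes <- function(n, cfg) {
  out <- integer(0)
  while (length(out) < n) {
    x <- stats::rlnorm(2 * n + 20, cfg$herd_size_meanlog, cfg$herd_size_sdlog)
    x <- x[x >= cfg$herd_size_min & x <= cfg$herd_size_max]
    out <- c(out, as.integer(round(x)))
  }
  out[seq_len(n)]
}

# zero-inflated beta herd-level incidences for one lesion group
.sim_group_probs <- function(n, mean, zero_prob, phi) {
  p <- numeric(n)
  nz <- stats::runif(n) >= zero_prob
  mc <- min(mean / max(1 - zero_prob, 1e-9), 0.95)
  p[nz] <- stats::rbeta(sum(nz), mc * phi, (1 - mc) * phi)
  p
}

#' Simulate a synthetic herd population
#'
#' Generates the four record streams (roster, trimming, locomotion, culling)
#' plus a truth table of the per-herd generating parameters. Cow-level
#' lesion events are Bernoulli per cow, group and year with probability
#' \eqn{1 - (1 - p_{hg})^{f_c}} (herd incidence \eqn{p_{hg}} scaled by the
#' cow's presence fraction \eqn{f_c}), so the cow-year incidence-risk
#' estimator of the KPI module is an unbiased estimate of the generating
#' probability. Same seed, same config: byte-identical output.
#'
#' @param config a [sim_config()].
#' @return list with data.frames `roster`, `trimming`, `locomotion`,
#'   `culling`, and `truth` = list(`herds`, `lesions`) carrying the
#'   generating parameters, plus the `config`.
#' @export
simulate_population <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  ystart <- as.Date(sprintf("%d-01-01", cfg$year))
  yend <- as.Date(sprintf("%d-12-31", cfg$year))
  ndays <- as.integer(yend - ystart) + 1L

  ## ---- herd-level parameters -------------------------------------------
  set.seed(.stream_seed(cfg$seed, 1L))
  nh <- cfg$n_herds
  herd_id <- sprintf("H%04d", seq_len(nh))
  size <- .sim_herd_sizes(nh, cfg)
  endemic <- stats::runif(nh) < cfg$dd_endemic_fraction
  # endemic within-herd DD incidence: floored so that an endemic herd almost
  # surely shows >2 affected cows (the herd-level detection rule)
  dd_floor <- pmax(0.2, 8 / size)
  p_dd <- ifelse(endemic,
                 pmin(0.9, dd_floor + (0.9 - dd_floor) *
                        stats::rbeta(nh, cfg$dd_beta_shape1, cfg$dd_beta_shape2)),
                 0)
  pri <- cfg$lesion_priors
  pmat <- vapply(seq_len(nrow(pri)), function(i) {
    .sim_group_probs(nh, pri$mean[i], pri$zero_prob[i], pri$phi[i])
  }, numeric(nh))
  colnames(pmat) <- pri$group
  pmat <- cbind(pmat, DD = p_dd)
  # herd lameness propensity (score >= 2), beta around the marginal mean
  lame_mean <- 1 - cfg$locomotion_probs[1]
  hl_phi <- lame_mean * (1 - lame_mean) / cfg$herd_lame_sd^2 - 1
  lame_prob <- stats::rbeta(nh, lame_mean * hl_phi, (1 - lame_mean) * hl_phi)
  scored_herd <- stats::runif(nh) < cfg$locomotion_herd_fraction
  claw_share <- ifelse(stats::runif(nh) < cfg$claw_cull_zero_prob, 0,
                       stats::rbeta(nh,
                                    cfg$claw_cull_share_mean * cfg$claw_cull_share_phi,
                                    (1 - cfg$claw_cull_share_mean) * cfg$claw_cull_share_phi))
  trimmer_id <- sprintf("T%02d", 1L + (seq_len(nh) - 1L) %% 31L)
  scorer_id <- sprintf("L%02d", 1L + (seq_len(nh) - 1L) %% 24L)

  # trimming visit dates: 2-3 per year at 4-6-month spacing
  n_visits <- 2L + (stats::runif(nh) < cfg$p_three_visits)
  sp <- cfg$visit_spacing_days
  first_visit <- ifelse(n_visits == 3L,
                        sample.int(45L, nh, replace = TRUE) + 14L,
                        sample.int(90L, nh, replace = TRUE) + 59L)
  # three-visit herds use the tight end of the spacing window so all visits
  # fit inside the year
  gap_hi <- ifelse(n_visits == 3L, pmin(sp[2], 150L), sp[2])
  gap1 <- sp[1] + floor(stats::runif(nh) * (gap_hi - sp[1] + 1L))
  gap2 <- sp[1] + floor(stats::runif(nh) * (gap_hi - sp[1] + 1L))
  visit_list <- lapply(seq_len(nh), function(h) {
    d <- first_visit[h] + c(0L, cumsum(c(gap1[h], gap2[h])))[seq_len(n_visits[h])]
    ystart + pmin(d, ndays - 1L)
  })

  ## ---- cow timelines ----------------------------------------------------
  set.seed(.stream_seed(cfg$seed, 2L))
  base_n <- size
  herd_of_base <- rep(seq_len(nh), base_n)
  n_base <- length(herd_of_base)
  entry0 <- ystart - sample.int(700L, n_base, replace = TRUE)
  dim0 <- sample.int(cfg$calving_interval_days, n_base, replace = TRUE) - 1L
  last_calv <- ystart - dim0
  culled <- stats::runif(n_base) < cfg$annual_cull_prob
  exit0 <- as.Date(ifelse(culled,
                          ystart + sample.int(ndays, n_base, replace = TRUE) - 1L,
                          NA), origin = "1970-01-01")
  # replacements: one fresh heifer per culled cow, entering shortly after
  repl_idx <- which(culled)
  n_repl <- length(repl_idx)
  repl_entry <- pmin(exit0[repl_idx] + sample.int(20L, n_repl, replace = TRUE),
                     yend)

  cows <- data.frame(
    herd = c(herd_of_base, herd_of_base[repl_idx]),
    entry = c(entry0, repl_entry),
    exit = c(exit0, as.Date(rep(NA, n_repl))),
    calv1 = c(last_calv, repl_entry),
    stringsAsFactors = FALSE
  )
  nc <- nrow(cows)
  cows$cow_id <- sprintf("%s-C%04d", herd_id[cows$herd],
                         stats::ave(seq_len(nc), cows$herd, FUN = seq_along))
  # next calving + dry-off inside the presence interval
  cows$calv2 <- cows$calv1 + cfg$calving_interval_days
  cows$dry1 <- cows$calv2 - cfg$dry_period_days
  eff_exit <- as.Date(ifelse(is.na(cows$exit), as.numeric(yend + 400),
                             as.numeric(cows$exit)), origin = "1970-01-01")
  has2 <- cows$calv2 <= eff_exit
  cows$calv2[!has2] <- NA
  cows$dry1[!has2 | cows$dry1 > eff_exit] <- NA

  roster <- data.frame(
    herd_id = herd_id[cows$herd],
    cow_id = cows$cow_id,
    entry_date = cows$entry,
    exit_date = cows$exit,
    calving_dates = format_date_list(.mapply(function(a, b) {
      d <- c(a, b); as.Date(d[!is.na(d)], origin = "1970-01-01")
    }, list(as.numeric(cows$calv1), as.numeric(cows$calv2)), NULL)),
    dryoff_dates = ifelse(is.na(cows$dry1), "", format(cows$dry1, "%Y-%m-%d")),
    stringsAsFactors = FALSE
  )

  # presence fraction within the study year
  pstart <- pmax(cows$entry, ystart)
  pend <- pmin(eff_exit, yend)
  pres_frac <- pmax(0, as.numeric(pend - pstart) + 1) / ndays

  ## ---- trimming records -------------------------------------------------
  set.seed(.stream_seed(cfg$seed, 3L))
  groups <- colnames(pmat)
  # per cow x group Bernoulli events, presence-scaled
  pcow <- pmat[cows$herd, , drop = FALSE]
  pev <- 1 - (1 - pcow)^pres_frac
  ev <- matrix(stats::runif(nc * ncol(pev)) < pev, nc)
  ev_idx <- which(ev, arr.ind = TRUE)
  ev_cow <- ev_idx[, 1]
  ev_group <- groups[ev_idx[, 2]]
  # assign each event to a visit inside the cow's presence interval
  pick_visit <- function(cow) {
    v <- visit_list[[cows$herd[cow]]]
    v <- v[v >= pstart[cow] & v <= pend[cow]]
    if (!length(v)) return(as.Date(NA))
    v[sample.int(length(v), 1L)]
  }
  ev_date <- as.Date(vapply(ev_cow, function(i) as.numeric(pick_visit(i)),
                            numeric(1)), origin = "1970-01-01")
  keep <- !is.na(ev_date)
  ev_cow <- ev_cow[keep]; ev_group <- ev_group[keep]; ev_date <- ev_date[keep]
  ne <- length(ev_cow)

  code_pool <- list(
    TS = c("TS"), IP = c("IP"), SW = c("SW"),
    HF = c("HF", "HF", "HF", "HF", "HFH"),
    IH = c("IH"), DS = c("DS"), CC = c("CC"), HHE = c("HHE"),
    SH = c("SH-D", "SH-D", "SH-C"),
    WLA = c("WLD"),
    UL = c("SU", "SU", "SU", "SU", "SU", "TU", "TU", "BU", "BU", "TN"),
    CD = c("CD"),
    DD = c("M1", "M1", "M2", "M2", "M2", "M3", "M4", "M4", "M4", "M4.1")
  )
  ev_code <- vapply(ev_group, function(g) {
    pool <- code_pool[[g]]
    pool[sample.int(length(pool), 1L)]
  }, "")
  ev_sev <- sample(2:3, ne, replace = TRUE, prob = c(0.7, 0.3))

  trimming <- data.frame(
    herd_id = herd_id[cows$herd[ev_cow]],
    cow_id = cows$cow_id[ev_cow],
    date = ev_date,
    lesion_code = ev_code,
    zone = sample(0:10, ne, replace = TRUE),
    severity = ev_sev,
    recorder = "trimmer",
    observer_id = trimmer_id[cows$herd[ev_cow]],
    stringsAsFactors = FALSE
  )

  # routinely trimmed cows at each visit (lesion-free ones documented as NL),
  # plus incidental severity-1 records of the severity-sensitive lesions
  routine <- do.call(rbind, lapply(seq_len(nh), function(h) {
    idx <- which(cows$herd == h)
    out <- lapply(visit_list[[h]], function(vd) {
      present <- idx[pstart[idx] <= vd & pend[idx] >= vd]
      trimmed <- present[stats::runif(length(present)) < cfg$trimmed_fraction]
      if (!length(trimmed)) return(NULL)
      data.frame(cow = trimmed, date = vd)
    })
    do.call(rbind, out)
  }))
  sev1_codes <- c("SH-D", "DS", "WLD", "HHE")
  noise_pick <- stats::runif(nrow(routine)) < cfg$severity1_noise_rate
  noise <- routine[noise_pick, , drop = FALSE]
  if (nrow(noise)) {
    trimming <- rbind(trimming, data.frame(
      herd_id = herd_id[cows$herd[noise$cow]],
      cow_id = cows$cow_id[noise$cow],
      date = noise$date,
      lesion_code = sample(sev1_codes, nrow(noise), replace = TRUE),
      zone = sample(0:10, nrow(noise), replace = TRUE),
      severity = 1L,
      recorder = "trimmer",
      observer_id = trimmer_id[cows$herd[noise$cow]],
      stringsAsFactors = FALSE
    ))
  }
  # NL documentation for trimmed cow-visits without any lesion record
  key_rec <- paste(trimming$cow_id, trimming$date)
  key_rt <- paste(cows$cow_id[routine$cow], routine$date)
  nl <- routine[!(key_rt %in% key_rec), , drop = FALSE]
  if (nrow(nl)) {
    trimming <- rbind(trimming, data.frame(
      herd_id = herd_id[cows$herd[nl$cow]],
      cow_id = cows$cow_id[nl$cow],
      date = nl$date,
      lesion_code = "NL",
      zone = 0L,
      severity = NA_integer_,
      recorder = "trimmer",
      observer_id = trimmer_id[cows$herd[nl$cow]],
      stringsAsFactors = FALSE
    ))
  }
  trimming <- trimming[order(trimming$herd_id, trimming$date,
                             trimming$cow_id, trimming$lesion_code), ]
  rownames(trimming) <- NULL

  ## ---- locomotion records -----------------------------------------------
  set.seed(.stream_seed(cfg$seed, 4L))
  # per-cow lameness propensity around the herd level
  cl_phi <- pmax(lame_prob[cows$herd] * (1 - lame_prob[cows$herd]) /
                   cfg$cow_lame_sd^2 - 1, 0.5)
  p_lame_cow <- stats::rbeta(nc, lame_prob[cows$herd] * cl_phi,
                             (1 - lame_prob[cows$herd]) * cl_phi)
  lame_score_probs <- cfg$locomotion_probs[2:5] / sum(cfg$locomotion_probs[2:5])

  loco <- do.call(rbind, lapply(which(scored_herd), function(h) {
    start <- sample.int(cfg$scoring_interval_days, 1L)
    dates <- ystart + seq(start, ndays - 1L, by = cfg$scoring_interval_days)
    idx <- which(cows$herd == h)
    out <- lapply(dates, function(d) {
      present <- idx[pstart[idx] <= d & pend[idx] >= d]
      if (!length(present)) return(NULL)
      dry <- !is.na(cows$dry1[present]) & cows$dry1[present] <= d &
        (is.na(cows$calv2[present]) | cows$calv2[present] > d)
      p_sc <- ifelse(dry, cfg$p_scored_dry, cfg$p_scored_lactating)
      scored <- present[stats::runif(length(present)) < p_sc]
      if (!length(scored)) return(NULL)
      lame <- stats::runif(length(scored)) < p_lame_cow[scored]
      score <- rep(1L, length(scored))
      if (any(lame))
        score[lame] <- sample(2:5, sum(lame), replace = TRUE,
                              prob = lame_score_probs)
      data.frame(cow = scored, date = d, score = score)
    })
    out <- do.call(rbind, out)
    if (is.null(out)) return(NULL)
    data.frame(herd_id = herd_id[h], cow_id = cows$cow_id[out$cow],
               date = out$date, score = out$score,
               observer_id = scorer_id[h], stringsAsFactors = FALSE)
  }))
  if (is.null(loco))
    loco <- data.frame(herd_id = character(), cow_id = character(),
                       date = as.Date(character()), score = integer(),
                       observer_id = character(), stringsAsFactors = FALSE)

  ## ---- culling records --------------------------------------------------
  set.seed(.stream_seed(cfg$seed, 5L))
  cu <- which(!is.na(cows$exit) & cows$exit >= ystart & cows$exit <= yend)
  other_reasons <- setdiff(culling_reasons(), "claw_limb")
  other_w <- c(0.18, 0.25, 0.12, 0.10, 0.10, 0.05, 0.06, 0.05, 0.09)
  is_claw <- stats::runif(length(cu)) < claw_share[cows$herd[cu]]
  reason <- ifelse(is_claw, "claw_limb",
                   sample(other_reasons, length(cu), replace = TRUE,
                          prob = other_w))
  culling <- data.frame(herd_id = herd_id[cows$herd[cu]],
                        cow_id = cows$cow_id[cu],
                        date = cows$exit[cu],
                        reason = reason, stringsAsFactors = FALSE)
  culling <- culling[order(culling$herd_id, culling$date, culling$cow_id), ]
  rownames(culling) <- NULL

  ## ---- truth tables ------------------------------------------------------
  truth_herds <- data.frame(
    herd_id = herd_id, n_cows = size, n_visits = n_visits,
    lame_prob = lame_prob, dd_endemic = endemic,
    claw_cull_share = claw_share, scored = scored_herd,
    stringsAsFactors = FALSE
  )
  truth_lesions <- data.frame(
    herd_id = rep(herd_id, ncol(pmat)),
    group = rep(colnames(pmat), each = nh),
    prob = as.vector(pmat),
    stringsAsFactors = FALSE
  )

  list(roster = roster, trimming = trimming, locomotion = loco,
       culling = culling,
       truth = list(herds = truth_herds, lesions = truth_lesions),
       config = cfg)
}

#' Simulate a rater-response table
#'
#' Draws observer responses against a reference category vector under a
#' row-stochastic confusion matrix, mimicking picture/video interobserver
#' reliability tests.
#'
#' @param n_observers,n_items table dimensions.
#' @param confusion square row-stochastic matrix: `confusion[r, ]` is the
#'   response distribution given reference category `r`.
#' @param reference_probs category distribution of the reference items
#'   (default uniform).
#' @param seed integer seed.
#' @return data.frame in the `ratings` schema: `observer_id`, `item`,
#'   `rating`, `reference`.
#' @export
#' @examples
#' simulate_raters(2, 10, diag(5), seed = 1)
simulate_raters <- function(n_observers, n_items, confusion,
                            reference_probs = NULL, seed = 1L) {
  confusion <- as.matrix(confusion)
  k <- nrow(confusion)
  if (ncol(confusion) != k || any(confusion < 0) ||
      any(abs(rowSums(confusion) - 1) > 1e-8))
    stop("confusion must be a square row-stochastic matrix", call. = FALSE)
  if (is.null(reference_probs)) reference_probs <- rep(1 / k, k)
  set.seed(seed)
  reference <- sample.int(k, n_items, replace = TRUE, prob = reference_probs)
  out <- lapply(seq_len(n_observers), function(o) {
    rating <- vapply(reference, function(r) {
      sample.int(k, 1L, prob = confusion[r, ])
    }, 1L)
    data.frame(observer_id = sprintf("O%03d", o), item = seq_len(n_items),
               rating = rating, reference = reference,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Adjacent-error confusion matrix for a five-point scale
#'
#' Misclassification limited to adjacent categories, concentrated on the
#' hard-to-separate pairs 1/2 and 4/5 (the pairs that the 12|3|45 category
#' merge collapses), with a smaller error rate across the 2-3 and 3-4
#' boundaries.
#'
#' @param e_within adjacent error rate inside the merged blocks (1<->2,
#'   4<->5).
#' @param e_cross adjacent error rate across block boundaries.
#' @return 5x5 row-stochastic matrix.
#' @export
adjacent_confusion <- function(e_within = 0.35, e_cross = 0.05) {
  C <- diag(5)
  shift <- function(C, i, j, p) {
    C[i, i] <- C[i, i] - p
    C[i, j] <- C[i, j] + p
    C
  }
  C <- shift(C, 1, 2, e_within)
  C <- shift(C, 2, 1, e_within)
  C <- shift(C, 4, 5, e_within)
  C <- shift(C, 5, 4, e_within)
  C <- shift(C, 2, 3, e_cross)
  C <- shift(C, 3, 2, e_cross / 2)
  C <- shift(C, 3, 4, e_cross / 2)
  C <- shift(C, 4, 3, e_cross)
  C
}
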