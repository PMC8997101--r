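test_that("mean cow number equals cow-days over days-in-year", {
  # one cow present the whole (non-leap) year
  r1 <- roster_row("H1", "c1", "2021-01-01", "2021-12-31")
  expect_equal(unname(mean_cow_number(r1, 2021)), 1.0)
  # two cows covering complementary halves of the year
  r2 <- rbind(roster_row("H1", "c1", "2021-01-01", "2021-06-30"),
              roster_row("H1", "c2", "2021-07-01", "2021-12-31"))
  expect_equal(unname(mean_cow_number(r2, 2021)), 1.0)
  # leap year uses 366 days
  r3 <- roster_row("H1", "c1", "2020-01-01", "2020-12-31")
  expect_equal(unname(mean_cow_number(r3, 2020)), 1.0)
  expect_equal(unname(mean_cow_number(r3, 2020, days_in_year = 365)),
               366 / 365)
  expect_warning(mean_cow_number(r1[0, ], 2021), "empty roster")
})

test_that("mean cow number matches a brute-force daily head count", {
  set.seed(99)
  ystart <- as.Date("2021-01-01")
  for (rep in 1:20) {
    n <- sample(3:8, 1)
    entry <- ystart + sample(-100:300, n, replace = TRUE)
    exit <- entry + sample(30:500, n, replace = TRUE)
    exit[sample(n, 1)] <- NA  # keep one open interval
    ros <- do.call(rbind, lapply(seq_len(n), function(i)
      roster_row("H1", paste0("c", i), entry[i], exit[i])))
    got <- unname(mean_cow_number(ros, 2021))
    days <- seq(ystart, as.Date("2021-12-31"), by = "day")
    count <- vapply(days, function(d)
      sum(ros$entry_date <= d & (is.na(ros$exit_date) | ros$exit_date >= d)),
      numeric(1))
    expect_equal(got, mean(count), tolerance = 1e-12)
  }
})

test_that("severity recoding drops mild records of the four sensitive lesions", {
  rec <- rbind(
    trim_row("H1", "c1", "2020-05-01", "SH-D", sev = 1),  # dropped
    trim_row("H1", "c1", "2020-05-01", "WLD", sev = 3),   # kept as WLA
    trim_row("H1", "c2", "2020-05-01", "SU", sev = 1),    # kept (not sensitive)
    trim_row("H1", "c2", "2020-05-01", "HHE", sev = 1),   # dropped
    trim_row("H1", "c3", "2020-05-01", "DS", sev = NA, recorder = "farmer")
  )
  out <- recode_severity(rec)
  expect_equal(nrow(out), 3)
  expect_false(any(out$lesion_code %in% c("SH-D", "HHE")))
  expect_equal(out$group[out$lesion_code == "WLD"], "WLA")
  expect_true("SU" %in% out$lesion_code)
  # farmer records without severity get the conventional severity and survive
  expect_equal(out$severity[out$recorder == "farmer"], 2L)
  # configurable convention: severity 1 would drop the farmer double sole too
  out1 <- recode_severity(rec, farmer_severity = 1L)
  expect_true("DS" %in% out1$lesion_code)  # drop rule applies to trimmers only
})

test_that("lameness incidence risk matches hand-computed worked example", {
  ros <- do.call(rbind, lapply(1:10, function(i)
    roster_row("H1", paste0("c", i), "2019-06-01",
               calvings = "2020-01-15")))
  loc <- data.frame(herd_id = "H1", cow_id = paste0("c", 1:10),
                    date = as.Date("2020-06-01"),
                    score = c(1, 1, 1, 2, 2, 3, 3, 4, 5, 1),
                    observer_id = "L1", stringsAsFactors = FALSE)
  expect_equal(ir_lame(loc, ros, threshold = 2, group = "all")$value, 60)
  expect_equal(ir_lame(loc, ros, threshold = 3, group = "all")$value, 40)
  expect_equal(ir_lame(loc, ros, threshold = 4, group = "all")$value, 20)
  # all cows sound all year -> 0 at every threshold
  loc0 <- loc
  loc0$score <- 1
  for (thr in 2:4)
    expect_equal(ir_lame(loc0, ros, threshold = thr, group = "all")$value, 0)
  # never-scored group is flagged undefined
  expect_true(is.na(ir_lame(loc, ros, threshold = 2, group = "dry")$value))
})

test_that("cow groups derive from the roster timeline", {
  ros <- rbind(
    # dry on the test date: dried off 2020-05-01, next calving 2020-07-01
    roster_row("H1", "dry1", "2019-01-01",
               calvings = "2019-08-20;2020-07-01", dryoffs = "2020-05-01"),
    # fresh: calved 30 days before the test date
    roster_row("H1", "fresh1", "2019-01-01", calvings = "2020-05-02"),
    # mid-lactation: calved 200 days before
    roster_row("H1", "mid1", "2019-01-01", calvings = "2019-11-14")
  )
  loc <- data.frame(herd_id = "H1",
                    cow_id = c("dry1", "fresh1", "mid1"),
                    date = as.Date("2020-06-01"),
                    score = c(3, 2, 1), observer_id = "L1",
                    stringsAsFactors = FALSE)
  # dry group: only dry1 (score 3) -> 100% at >=2
  expect_equal(ir_lame(loc, ros, 2, "dry")$value, 100)
  # first-100-DIM group: only fresh1 (score 2) -> 100% at >=2, 0% at >=3
  expect_equal(ir_lame(loc, ros, 2, "dim100")$value, 100)
  expect_equal(ir_lame(loc, ros, 3, "dim100")$value, 0)
  # lactating group: fresh1 + mid1 -> 50% at >=2
  expect_equal(ir_lame(loc, ros, 2, "all")$value, 50)
})

test_that("claw-lesion incidence risk implements both counting modes", {
  ros <- do.call(rbind, lapply(1:20, function(i)
    roster_row("H1", paste0("c", i), "2020-01-01", "2020-12-31")))
  rec <- recode_severity(do.call(rbind, lapply(1:5, function(i)
    trim_row("H1", paste0("c", i), "2020-04-01", "SU"))))
  # 5 distinct cows with an ulcer, mean 20 cows -> 25%
  r <- ir_clawl(rec, ros, "UL", year = 2020)
  expect_equal(r$value, 25)
  # one cow seen at spring and autumn visits: 1 case cow-year, 2 cow-visit
  rec2 <- recode_severity(rbind(
    trim_row("H1", "c1", "2020-04-01", "SU"),
    trim_row("H1", "c1", "2020-10-01", "SU")))
  expect_equal(ir_clawl(rec2, ros, "UL", mode = "cow-year")$n_cases, 1)
  expect_equal(ir_clawl(rec2, ros, "UL", mode = "cow-visit")$n_cases, 2)
  # group with no records at all -> 0
  expect_equal(ir_clawl(rec, ros, "TS")$value, 0)
})

test_that("alarm incidence counts only painful lesions", {
  ros <- do.call(rbind, lapply(1:10, function(i)
    roster_row("H1", paste0("c", i), "2020-01-01")))
  rec <- recode_severity(rbind(
    trim_row("H1", "c1", "2020-04-01", "HHE", sev = 3),  # severe but not alarm
    trim_row("H1", "c2", "2020-04-01", "M2"),            # acute DD: alarm
    trim_row("H1", "c3", "2020-04-01", "NL", sev = NA)))
  expect_equal(ir_alarm(rec, ros)$value, 10)  # 1 of mean 10 cows
  rec0 <- recode_severity(trim_row("H1", "c1", "2020-04-01", "CC"))
  expect_equal(ir_alarm(rec0, ros)$value, 0)
})

test_that("DD endemicity requires more than two distinct affected cows", {
  rec <- rbind(trim_row("H1", "c1", "2020-04-01", "M2"),
               trim_row("H1", "c2", "2020-04-01", "M2"),
               trim_row("H2", "c1", "2020-04-01", "M4"),
               trim_row("H2", "c2", "2020-04-01", "M4"),
               trim_row("H2", "c3", "2020-04-01", "M4"),
               trim_row("H3", "c1", "2020-04-01", "M1"),
               trim_row("H3", "c1", "2020-05-01", "M2"),
               trim_row("H3", "c1", "2020-06-01", "M3"),
               trim_row("H3", "c1", "2020-07-01", "M4"),
               trim_row("H3", "c1", "2020-08-01", "M4.1"))
  d <- dd_endemic(rec)
  expect_equal(d$dd_endemic[d$herd_id == "H1"], FALSE)  # 2 cows: not endemic
  expect_equal(d$dd_endemic[d$herd_id == "H2"], TRUE)   # 3 cows
  expect_equal(d$dd_endemic[d$herd_id == "H3"], FALSE)  # 5 records, 1 cow
})

test_that("annual claw/limb culling risk is a share of all culls", {
  cu <- data.frame(herd_id = "H1", cow_id = paste0("c", 1:10),
                   date = as.Date("2020-06-01"),
                   reason = c(rep("claw_limb", 2), rep("infertility", 8)),
                   stringsAsFactors = FALSE)
  expect_equal(acr_claw(cu)$value, 20)
  cu$reason <- "claw_limb"
  expect_equal(acr_claw(cu)$value, 100)
  cu$reason <- "age"
  expect_equal(acr_claw(cu)$value, 0)
  # zero-cull herd enters the distribution at 0, flagged
  z <- acr_claw(cu[0, ], herds = "H9")
  expect_equal(z$value, 0)
  expect_true(z$zero_culls)
})

test_that("herd_kpis marks DD as not applicable for non-endemic herds", {
  ros <- do.call(rbind, lapply(1:10, function(i)
    roster_row("H1", paste0("c", i), "2020-01-01")))
  rec <- recode_severity(rbind(
    trim_row("H1", "c1", "2020-04-01", "M2"),
    trim_row("H1", "c2", "2020-04-01", "SU")))
  loc <- data.frame(herd_id = character(), cow_id = character(),
                    date = as.Date(character()), score = integer(),
                    observer_id = character(), stringsAsFactors = FALSE)
  k <- herd_kpis(rec, loc, ros, rec[0, c("herd_id", "cow_id", "date")], 2020)
  expect_false(k$dd_endemic)
  expect_true(is.na(k$ir_DD))
  expect_equal(k$ir_UL, 10)
})
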