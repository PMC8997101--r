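test_that("record rules reject exactly the implausible records", {
  fx <- cascade_fixture()
  v <- validate_records(fx$records, fx$roster, fx$config, "trimming")
  expect_equal(nrow(v$records), 17)
  expect_equal(nrow(v$ledger$records), 3)
  expect_setequal(v$ledger$records$rule,
                  c("animal-id", "date-window", "lesion-code"))
  # accepted records are returned unmodified
  clean_in <- fx$records[-v$ledger$records$index, ]
  rownames(clean_in) <- NULL
  expect_identical(v$records, clean_in)
  # empty input: empty output, empty ledger, no error
  v0 <- validate_records(fx$records[0, ], fx$roster, fx$config, "trimming")
  expect_equal(nrow(v0$records), 0)
  expect_equal(nrow(v0$ledger$records), 0)
})

test_that("record validation is idempotent", {
  fx <- cascade_fixture()
  v1 <- validate_records(fx$records, fx$roster, fx$config, "trimming")
  v2 <- validate_records(v1$records, fx$roster, fx$config, "trimming")
  expect_identical(v2$records, v1$records)
  expect_equal(nrow(v2$ledger$records), 0)
})

test_that("herd filter excludes one herd per rule with measured values", {
  fx <- cascade_fixture()
  v <- validate_records(fx$records, fx$roster, fx$config, "trimming")
  fh <- filter_herds(v$records, fx$roster, fx$config)
  expect_equal(fh$included, "F1")
  led <- fh$ledger$herds[fh$ledger$herds$first_failing, ]
  expect_equal(stats::setNames(led$rule, led$herd_id),
               c(F2 = "recorder-share", F3 = "trim-share",
                 F4 = "lesion-free", F5 = "min-diagnoses"))
  expect_equal(led$measured[led$herd_id == "F2"], 0.75)
  expect_equal(led$measured[led$herd_id == "F3"], 0.25)
  expect_equal(led$measured[led$herd_id == "F5"], 1)
  # a herd with records but no roster is excluded, not a crash
  fh6 <- filter_herds(fx$records[fx$records$herd_id == "F6", ],
                      fx$roster, fx$config)
  expect_equal(fh6$ledger$herds$rule, "no-roster")
})

test_that("herds exactly at the thresholds are included", {
  # 2 cows, trim share exactly 0.5; recorder share exactly 0.95 (19/20
  # trained); exactly min_diagnoses distinct groups; one NL record
  ros <- rbind(roster_row("B1", "c1", "2020-01-01"),
               roster_row("B1", "c2", "2020-01-01"))
  groups <- c("SU", "M2", "CC")  # 3 distinct groups with min_diagnoses = 3
  rec <- do.call(rbind, c(
    lapply(groups, function(g) trim_row("B1", "c1", "2020-04-01", g)),
    lapply(1:16, function(i) trim_row("B1", "c1", "2020-04-01", "SU")),
    list(trim_row("B1", "c1", "2020-04-01", "NL", sev = NA, observer = "TX"))
  ))
  stopifnot(nrow(rec) == 20)
  cfg <- validation_config(year = 2020, min_diagnoses = 3,
                           trained_observers = "T1")
  fh <- filter_herds(rec, ros, cfg)
  expect_equal(fh$included, "B1")  # 0.95 trained, 0.5 trimmed, 3 groups: in
})

test_that("relaxing thresholds never shrinks the included herd set", {
  fx <- cascade_fixture()
  v <- validate_records(fx$records, fx$roster, fx$config, "trimming")
  base <- filter_herds(v$records, fx$roster, fx$config)$included
  relaxed_cfgs <- list(
    validation_config(2020, trained_share = 0.5, min_diagnoses = 3,
                      trained_observers = "T1"),
    validation_config(2020, trim_share = 0.2, min_diagnoses = 3,
                      trained_observers = "T1"),
    validation_config(2020, min_diagnoses = 1, trained_observers = "T1"),
    validation_config(2020, min_diagnoses = 3, require_lesion_free = FALSE,
                      trained_observers = "T1"),
    validation_config(2020, min_diagnoses = 3, trained_observers = NULL)
  )
  for (cfg in relaxed_cfgs) {
    inc <- filter_herds(v$records, fx$roster, cfg)$included
    expect_true(all(base %in% inc))
  }
})

test_that("record rules are order-independent (any-fail semantics)", {
  fx <- cascade_fixture()
  v <- validate_records(fx$records, fx$roster, fx$config, "trimming")
  # shuffling the input rows yields the same accepted record set
  set.seed(1)
  perm <- sample(nrow(fx$records))
  vp <- validate_records(fx$records[perm, ], fx$roster, fx$config, "trimming")
  key <- function(d) sort(paste(d$herd_id, d$cow_id, d$date, d$lesion_code))
  expect_identical(key(vp$records), key(v$records))
})

test_that("validation applies to locomotion and culling streams too", {
  ros <- roster_row("H1", "c1", "2020-01-01", "2020-06-30")
  loc <- data.frame(herd_id = "H1", cow_id = c("c1", "c1", "ghost"),
                    date = as.Date(c("2020-03-01", "2020-08-01", "2020-03-01")),
                    score = c(2L, 3L, 1L), observer_id = "L1",
                    stringsAsFactors = FALSE)
  v <- validate_records(loc, ros, validation_config(2020), "locomotion")
  expect_equal(nrow(v$records), 1)  # after exit and unknown cow both rejected
  expect_setequal(v$ledger$records$rule, c("animal-id"))
  # the post-exit record fails presence (animal-id), in-year date is fine
  expect_equal(v$ledger$records$all_rules, c("animal-id", "animal-id"))
})
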