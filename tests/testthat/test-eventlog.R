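test_that("read_log parses the episode/cohort dialect", {
  path <- write_dialect_csv(
    "24972,18 May 2021,Chemotherapy,Abiraterona,,65,10-20,Grade group 1,OBS,ADT + QT"
  )
  log <- read_log(path)
  expect_equal(n_traces(log), 1)
  ev <- log$events
  expect_equal(ev$case_id, "24972")
  expect_equal(ev$timestamp, as.Date("2021-05-18"))
  expect_equal(ev$activity, "Chemotherapy")
  expect_equal(ev$detail, "Abiraterona")
  expect_equal(log$cases$Age, "65")
  expect_equal(log$cases$Grade, "Grade group 1")
})

test_that("header-only input yields an empty log", {
  log <- read_log(write_dialect_csv(character()))
  expect_equal(n_traces(log), 0)
  expect_equal(nrow(log$events), 0)
})

test_that("events are date-sorted per trace and sorting is idempotent", {
  path <- write_dialect_csv(c(
    "1,2020-03-01,PSA,,5,70,<10,Grade group 1,RP,RP",
    "2,2020-05-01,Diagnosis,,,71,<10,Grade group 2,RP,RP",
    "1,2020-01-01,Diagnosis,,,70,<10,Grade group 1,RP,RP"
  ))
  log <- read_log(path)
  expect_equal(n_traces(log), 2)
  # independent re-sort oracle: order by (case, date) must be a no-op
  ev <- log$events
  oracle <- ev[order(ev$case_id, ev$timestamp), ]
  expect_identical(ev, oracle)
  expect_equal(ev$activity[ev$case_id == "1"], c("Diagnosis", "PSA"))
})

test_that("same-day ordering puts Diagnosis first and Exitus last", {
  path <- write_dialect_csv(c(
    "1,2020-01-01,Radical Prostatectomy,,,70,<10,Grade group 1,RP,RP",
    "1,2020-01-01,Diagnosis,,,70,<10,Grade group 1,RP,RP",
    "1,2020-02-01,Exitus,,,70,<10,Grade group 1,RP,RP",
    "1,2020-02-01,PSA,,4,70,<10,Grade group 1,RP,RP"
  ))
  log <- read_log(path)
  expect_equal(log$events$activity,
               c("Diagnosis", "Radical Prostatectomy", "PSA", "Exitus"))
})

test_that("schema and date errors are reported; duplicates deduplicated", {
  bad <- tempfile(fileext = ".csv")
  writeLines(c("Patient ID,Episode", "1,Diagnosis"), bad)
  expect_error(read_log(bad), "Date")

  bad2 <- write_dialect_csv("1,not a date,Diagnosis,,,70,<10,G1,RP,RP")
  expect_error(read_log(bad2), "unparseable date")

  dup <- write_dialect_csv(rep(
    "1,2020-01-01,Diagnosis,,,70,<10,G1,RP,RP", 2))
  expect_warning(log <- read_log(dup), "duplicate")
  expect_equal(nrow(log$events), 1)
})

test_that("write_log / read_log round-trip is idempotent", {
  log <- simulate_care_log(n_patients = 15, seed = 11)
  path <- tempfile(fileext = ".csv")
  write_log(log, path)
  back <- read_log(path)
  expect_equal(back$events$activity, log$events$activity)
  expect_equal(back$events$timestamp, log$events$timestamp)
  expect_equal(back$events$case_id, log$events$case_id)
  expect_equal(back$cases, log$cases)
  # second round-trip is byte-stable
  path2 <- tempfile(fileext = ".csv")
  write_log(back, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("mixed date styles parse to the same calendar date", {
  expect_equal(parse_mixed_date(c("2021-05-18", "18 May 2021", "18/05/2021")),
               rep(as.Date("2021-05-18"), 3))
  expect_true(is.na(parse_mixed_date("May 2021")))
})

test_that("quality_report fires the documented rules", {
  d0 <- as.Date("2020-01-01")
  log <- eventlog(data.frame(
    case_id = "p1", timestamp = d0 + c(0, 10, 20),
    activity = c("Diagnosis", "Exitus", "Chemotherapy")
  ))
  rep1 <- quality_report(log)
  expect_equal(unname(rep1$counts["treatment-after-exitus"]), 1)
  expect_equal(sum(rep1$counts), 1)

  clean <- eventlog(data.frame(
    case_id = "p1", timestamp = d0 + c(0, 30),
    activity = c("Diagnosis", "Radical Prostatectomy")
  ))
  expect_equal(sum(quality_report(clean)$counts), 0)

  pre <- eventlog(data.frame(
    case_id = "p1", timestamp = d0 + c(0, 5),
    activity = c("Hormonal Therapy", "Diagnosis")
  ))
  rep3 <- quality_report(pre)
  expect_equal(unname(rep3$counts["pre-diagnosis-treatment"]), 1)

  # same-date diagnosis + treatment is a note, not an error
  same <- eventlog(data.frame(
    case_id = "p1", timestamp = d0 + c(0, 0),
    activity = c("Diagnosis", "Radical Prostatectomy")
  ))
  rep4 <- quality_report(same)
  expect_equal(sum(rep4$counts), 0)
  expect_true("same-date-diagnosis-treatment" %in% rep4$issues$rule)

  nodx <- eventlog(data.frame(case_id = "p1", timestamp = d0,
                              activity = "PSA", value = NA_real_))
  rep5 <- quality_report(nodx)
  expect_equal(unname(rep5$counts["missing-diagnosis"]), 1)
  expect_equal(unname(rep5$counts["invalid-psa-value"]), 1)
})

test_that("group_by_metadata partitions the log and matches a bucketing oracle", {
  set.seed(21)
  seqs <- random_sequences(10)
  labels <- sample(c("a", "b", NA), 10, replace = TRUE)
  meta <- data.frame(case_id = sprintf("c%02d", 1:10), Grade = labels,
                     stringsAsFactors = FALSE)
  log <- make_log(seqs, meta = meta)
  groups <- group_by_metadata(log, "Grade")

  oracle <- oracle_partition(meta$case_id, labels)
  expect_setequal(names(groups), names(oracle))
  for (k in names(groups)) {
    expect_setequal(case_ids(groups[[k]]), oracle[[k]])
  }
  # disjoint cover
  all_ids <- unname(unlist(lapply(groups, case_ids)))
  expect_equal(sort(all_ids), sort(case_ids(log)))
  expect_equal(sum(vapply(groups, n_traces, integer(1))), n_traces(log))

  expect_error(group_by_metadata(log, "nope"), "available")

  single <- group_by_metadata(
    make_log(seqs[1:3], meta = data.frame(case_id = c("c01", "c02", "c03"),
                                          Grade = "x")), "Grade")
  expect_equal(length(single), 1)
  expect_equal(n_traces(single$x), 3)
})

test_that("filter_traverses matches a brute-force bigram scan", {
  set.seed(31)
  seqs <- random_sequences(30, alphabet = c("Diagnosis",
                                            "Radical Prostatectomy",
                                            "PSA", "Exitus"))
  names(seqs) <- sprintf("c%02d", seq_along(seqs))
  log <- make_log(seqs)

  got <- case_ids(filter_traverses(log, "Exitus"))
  want <- names(seqs)[vapply(seqs, function(s) "Exitus" %in% s, logical(1))]
  expect_equal(got, want)

  expect_equal(n_traces(filter_traverses(log, "Never Seen")), 0)

  pair <- c("Diagnosis", "Radical Prostatectomy")
  got_pair <- case_ids(filter_traverses(log, pair))
  want_pair <- names(seqs)[vapply(seqs, function(s) {
    hit <- FALSE
    for (i in seq_len(length(s) - 1)) {
      if (s[i] == pair[1] && s[i + 1] == pair[2]) hit <- TRUE
    }
    hit
  }, logical(1))]
  expect_equal(got_pair, want_pair)

  # node filter is a superset of every pair filter rooted at that node
  for (second in c("PSA", "Exitus")) {
    sub <- case_ids(filter_traverses(log, c("Diagnosis", second)))
    expect_true(all(sub %in% case_ids(filter_traverses(log, "Diagnosis"))))
  }
})

test_that("derive_state_traces bins, collapses and preserves timestamps", {
  d0 <- as.Date("2020-01-01")
  log <- eventlog(data.frame(
    case_id = "p1", timestamp = d0 + c(0, 30, 60),
    activity = "PSA", value = c(5, 15, 25)
  ))
  st <- derive_state_traces(log)
  expect_equal(st$events$activity, c("<10", "10-20", ">20"))
  expect_equal(st$events$timestamp, d0 + c(0, 30, 60))

  flat <- eventlog(data.frame(
    case_id = "p1", timestamp = d0 + c(0, 30, 60),
    activity = "PSA", value = c(5, 6, 7)
  ))
  st2 <- derive_state_traces(flat)
  expect_equal(st2$events$activity, "<10")
  expect_equal(st2$events$timestamp, d0)

  # boundary values: both 10 and 20 fall in the middle bin
  expect_equal(careflowr:::bin_value(c(10, 20), c(10, 20)), c(2L, 2L))
  expect_equal(careflowr:::bin_value(c(9.99, 20.01), c(10, 20)), c(1L, 3L))

  expect_error(derive_state_traces(log, breakpoints = c(20, 10)),
               "strictly increasing")
  expect_error(derive_state_traces(log, labels = c("a", "b")), "labels")

  # per-trace output length never exceeds the number of value events
  log2 <- simulate_care_log(n_patients = 20, seed = 13)
  st3 <- suppressWarnings(derive_state_traces(log2))
  for (cid in case_ids(st3)) {
    n_states <- sum(st3$events$case_id == cid)
    n_psa <- sum(log2$events$case_id == cid & log2$events$activity == "PSA")
    expect_lte(n_states, n_psa)
  }
})
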