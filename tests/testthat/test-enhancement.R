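test_that("palette registry matches the documented contract", {
  reg <- palette_registry()
  expect_length(reg, 9)
  kinds <- vapply(reg, function(p) p$kind, character(1))
  cb <- vapply(reg, function(p) p$colorblind_safe, logical(1))
  expect_equal(sum(cb), 5)
  expect_true(all(kinds %in% c("heat", "difference")))
  expect_true(any(kinds == "heat") && any(kinds == "difference"))
  for (p in reg) {
    expect_equal(nrow(p$stops), if (p$kind == "heat") 3 else 4)
  }
  ids <- vapply(reg, function(p) p$id, character(1))
  expect_equal(anyDuplicated(ids), 0)
  expect_error(get_palette("no_such"), "available")
})

test_that("colour-blind palettes keep a minimum luminance separation", {
  for (p in palette_registry()) {
    if (!p$colorblind_safe) next
    stops <- p$stops
    if (p$kind == "difference") stops <- stops[-nrow(stops), , drop = FALSE]
    lum <- apply(stops, 1, rgb_luminance)
    expect_true(all(abs(diff(lum)) >= 40),
                info = paste("palette", p$id))
    # luminance must also be monotone along the gradient
    expect_true(all(diff(lum) > 0) || all(diff(lum) < 0),
                info = paste("palette", p$id))
  }
})

test_that("gradient interpolation is piecewise linear across stops", {
  pal <- get_palette("heat_traffic")
  expect_equal(interpolate_color(pal, 0), unname(pal$stops[1, ]))
  expect_equal(interpolate_color(pal, 1), unname(pal$stops[3, ]))
  expect_equal(interpolate_color(pal, 0.5), unname(pal$stops[2, ]))

  bwb <- structure(list(id = "t", kind = "heat",
                        stops = rbind(c(0, 0, 0), c(255, 255, 255),
                                      c(0, 0, 0)),
                        colorblind_safe = FALSE), class = "palette")
  expect_equal(interpolate_color(bwb, 0.25), c(128, 128, 128))
  expect_error(interpolate_color(pal, 1.5), "\\[0, 1\\]")
  expect_error(interpolate_color(pal, -0.1), "\\[0, 1\\]")
})

test_that("criterion values follow their definitions", {
  d0 <- as.Date("2020-01-01")
  # A traversed 3 times by 2 traces
  log <- eventlog(data.frame(
    case_id = c("t1", "t1", "t1", "t2", "t2"),
    timestamp = d0 + c(0, 5, 10, 0, 7),
    activity = c("A", "B", "A", "A", "B")
  ))
  m <- discover_workflow(log)
  expect_equal(criterion_value(m, "A", "execution_number"), 3)
  expect_equal(criterion_value(m, "A", "trace_number"), 2)
  expect_error(criterion_value(m, "A", "full_duration_average"),
               "not applicable")

  # arc with start-to-start gaps 10, 20, 60
  gaps <- c(10, 20, 60)
  events <- do.call(rbind, lapply(seq_along(gaps), function(i) {
    data.frame(case_id = paste0("p", i), timestamp = d0 + c(0, gaps[i]),
               activity = c("X", "Y"))
  }))
  m2 <- discover_workflow(eventlog(events))
  expect_equal(criterion_value(m2, c("X", "Y"), "full_duration_median"), 20)
  expect_equal(criterion_value(m2, c("X", "Y"), "full_duration_average"), 30)

  # unreachable element counts 0
  expect_equal(criterion_value(m, "Unseen", "execution_number"), 0)
  expect_equal(criterion_value(m, "Unseen", "trace_number"), 0)
})

test_that("fraction-of-trace criterion divides by total trace time", {
  d0 <- as.Date("2020-01-01")
  # trace time 10 days, 4 of them in A
  log <- eventlog(data.frame(
    case_id = "t1", timestamp = d0 + c(0, 4, 10),
    activity = c("A", "B", "C")
  ))
  m <- discover_workflow(log)
  expect_equal(criterion_value(m, "A", "duration_fraction_of_trace"), 0.4)
})

test_that("clamped normalization follows the 20/80 rule", {
  # execution numbers 10, 50, 100 for A, B, C
  seqs <- c(rep(list(c("A", "B", "C")), 10),
            rep(list(c("B", "C")), 40),
            rep(list("C"), 50))
  log <- make_log(seqs)
  m <- discover_workflow(log)
  enh <- build_enhancement(m, node_criterion = "execution_number",
                           arc_criterion = "execution_number",
                           palette_id = "heat_traffic")
  norm <- stats::setNames(enh$nodes$normalized, enh$nodes$label)
  # max is 100: 10 <= 20% -> 0; 50 -> (50-20)/(80-20) = 0.5; 100 >= 80% -> 1
  expect_equal(unname(norm["A"]), 0)
  expect_equal(unname(norm["B"]), 0.5)
  expect_equal(unname(norm["C"]), 1)
  pal <- get_palette("heat_traffic")
  col <- stats::setNames(enh$nodes$color, enh$nodes$label)
  expect_equal(unname(col["A"]), careflowr:::rgb_to_hex(pal$stops[1, ]))
  expect_equal(unname(col["C"]), careflowr:::rgb_to_hex(pal$stops[3, ]))
})

test_that("uniform criterion values normalize to the top stop", {
  log <- make_log(list(a = c("A", "B"), b = c("A", "B")))
  m <- discover_workflow(log)
  enh <- build_enhancement(m, "execution_number", "execution_number",
                           "heat_traffic")
  clinical <- !enh$nodes$label %in% c("@Start", "@End")
  expect_true(all(enh$nodes$normalized[clinical] == 1))
})

test_that("artificial endpoints are coloured but excluded from extremes", {
  # @Start/@End have 20 executions, clinical max is 5
  seqs <- rep(list(c("A")), 20)
  seqs[1:5] <- list(c("A", "B"))
  log <- make_log(seqs)
  m <- discover_workflow(log)
  enh <- build_enhancement(m, "execution_number", "execution_number",
                           "heat_traffic")
  norm <- stats::setNames(enh$nodes$normalized, enh$nodes$label)
  expect_equal(unname(norm["A"]), 1)   # A = 20 = clinical max? no: A is 20
  expect_true(all(c("@Start", "@End") %in% enh$nodes$label))
  expect_true(all(!is.na(enh$nodes$color)))
})

test_that("normalization is monotone in the raw criterion", {
  set.seed(61)
  for (rep in 1:5) {
    log <- make_log(random_sequences(25))
    m <- discover_workflow(log)
    enh <- build_enhancement(m, "execution_number", "execution_number",
                             "heat_viridis")
    ord <- order(enh$nodes$raw)
    expect_true(!is.unsorted(enh$nodes$normalized[ord]))
  }
})

test_that("narrowing the clamp band saturates more elements", {
  log <- make_log(random_sequences(30))
  m <- discover_workflow(log)
  wide <- build_enhancement(m, "execution_number", "execution_number",
                            "heat_traffic", low_pct = 10, high_pct = 90)
  narrow <- build_enhancement(m, "execution_number", "execution_number",
                              "heat_traffic", low_pct = 40, high_pct = 60)
  extreme <- function(e) mean(e$nodes$normalized %in% c(0, 1))
  expect_gte(extreme(narrow), extreme(wide))
})

test_that("palette kind mismatches are rejected", {
  log <- make_log(list(a = c("A", "B")))
  m <- discover_workflow(log)
  expect_error(build_enhancement(m, palette_id = "diff_purple"),
               "kind mismatch")
  expect_error(difference_map(m, m, palette_id = "heat_traffic"),
               "kind mismatch")
})
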