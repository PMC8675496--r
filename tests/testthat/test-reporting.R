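test_that("percentages round half away from zero and validate their domain", {
  expect_identical(pct(1222159, 4379866), 28L)
  expect_identical(pct(423, 1077), 39L)
  expect_identical(pct(0, 100), 0L)
  expect_identical(pct(1, 8), 13L)    # 12.5 rounds away from zero
  expect_identical(pct(63, 126), 50L)
  expect_error(pct(5, 0), "undefined")
  expect_error(pct(11, 10), "must lie in")
  expect_identical(share(1691886, 4379866), 39L)
  expect_identical(share(441920, 4379866), 10L)
  expect_identical(share(7, 7), 100L)
})

test_that("aggregation reproduces a constructed log exactly and conserves totals", {
  rb <- demo_rb()
  mk_event <- function(eid, date, candidate, patient, outcome) {
    record_episode(candidate, evaluate(candidate, patient, rb, date), outcome,
                   date, patient$patient_id, event_id = eid)
  }
  preg <- patient_record("W", "1992-02-02", "F", pregnant = TRUE)
  old <- patient_record("O", "1940-01-01", "M")
  asa <- patient_record("S", "1970-01-01", "M",
                        prescriptions = list(rx_on("acetylsalicylic_acid")))
  events <- list(
    mk_event("e1", "2016-02-01", "ibuprofen", preg, "not_prescribed"),
    mk_event("e2", "2016-03-01", "ibuprofen", preg, "prescribed"),
    mk_event("e3", "2017-02-01", "alprazolam", old, "not_prescribed"),
    mk_event("e4", "2017-05-01", "ibuprofen", asa, "prescribed"),
    mk_event("e5", "2017-06-01", "paracetamol", healthy_patient(), "prescribed"))
  tab <- aggregate_alerts(events)
  g <- function(row, col) report_cell(tab, row, col, "generated")
  a <- function(row, col) report_cell(tab, row, col, "accepted")
  expect_identical(g("Teratogens in pregnancy", "2016"), 2)
  expect_identical(a("Teratogens in pregnancy", "2016"), 1)
  expect_identical(g("Advised due to age (> 75 years)", "2017"), 1)
  expect_identical(g("Interactions", "2017"), 1)
  expect_identical(a("Interactions", "2017"), 0)
  expect_identical(g("Totals", "sum"), 4)
  # conservation: totals row = column sums, cumulative column = row sums
  fams <- setdiff(tab$row_order, "Totals")
  for (col in tab$col_order) {
    expect_identical(sum(vapply(fams, g, numeric(1), col = col)), g("Totals", col))
    expect_identical(sum(vapply(fams, a, numeric(1), col = col)), a("Totals", col))
  }
  for (row in tab$row_order) {
    expect_identical(g(row, "2016") + g(row, "2017"), g(row, "sum"))
  }
  # empty log: all-zero table
  empty <- aggregate_alerts(list())
  expect_true(all(empty$cells$generated == 0))
})

test_that("rankings order by generated count with label ties ascending", {
  rb <- demo_rb()
  asa <- patient_record("S", "1970-01-01", "M",
                        prescriptions = list(rx_on("acetylsalicylic_acid")))
  sim <- patient_record("V", "1970-01-01", "M",
                        prescriptions = list(rx_on("simvastatin")))
  ev <- function(eid, cand, patient, out = "prescribed")
    record_episode(cand, evaluate(cand, patient, rb, "2017-01-01"), out,
                   "2017-01-01", patient$patient_id, event_id = eid)
  events <- c(lapply(1:10, function(i) ev(sprintf("a%02d", i), "ibuprofen", asa)),
              lapply(1:5, function(i) ev(sprintf("b%02d", i), "amlodipine", sim,
                                         "not_prescribed")))
  rk <- top_alerts(events, "interaction_pair", n = 10)
  expect_identical(rk$label[1], "ibuprofen -> acetylsalicylic_acid")
  expect_identical(rk$generated[1:2], c(10L, 5L))
  expect_identical(rk$pct_accepted[2], 100L)
  # permutation invariance and n larger than distinct keys
  rk2 <- top_alerts(rev(events), "interaction_pair", n = 50)
  expect_identical(rk, rk2)
  # equal counts break ties by label
  events_tie <- c(lapply(1:3, function(i) ev(sprintf("c%02d", i), "ibuprofen", asa)),
                  lapply(1:3, function(i) ev(sprintf("d%02d", i), "amlodipine", sim)))
  rk3 <- top_alerts(events_tie, "interaction_pair", n = 2)
  expect_identical(rk3$label,
                   sort(c("ibuprofen -> acetylsalicylic_acid",
                          "amlodipine -> simvastatin")))
})

test_that("packaged fixtures load with verified internal sums", {
  t2 <- load_printed_fixture("table2")
  expect_identical(report_cell(t2, "Totals", "sum", "generated"), 4379866)
  expect_identical(report_cell(t2, "Totals", "sum", "accepted"), 1222159)
  t3 <- load_printed_fixture("table3")
  expect_identical(length(t3$row_order), 11L)
  t4 <- load_printed_fixture("table4")
  expect_identical(report_cell(t4, "Total", "2016", "generated"), 59146)
  t5 <- load_printed_fixture("table5")
  expect_identical(length(t5$row_order), 15L)
  t6 <- load_printed_fixture("table6")
  expect_identical(report_cell(t6, "Alprazolam", "sum", "generated"), 65910)
  expect_error(load_printed_fixture("table9"))
})

test_that("recomputed percentages match the printed ones on the regulatory and geriatric fixtures", {
  t4 <- load_printed_fixture("table4")
  cells <- t4$cells
  for (i in seq_len(nrow(cells)))
    expect_identical(pct(cells$accepted[i], cells$generated[i]),
                     as.integer(cells$pct_printed[i]),
                     info = paste(cells$row[i], cells$col[i]))
  t5 <- load_printed_fixture("table5")
  cells5 <- t5$cells
  # the benzodiazepine row's printed cell departs from the otherwise uniform
  # round-half-away convention and is excluded
  keep <- !grepl("^Benzodiazepines", cells5$row)
  for (i in which(keep))
    expect_identical(pct(cells5$accepted[i], cells5$generated[i]),
                     as.integer(cells5$pct_printed[i]), info = cells5$row[i])
})

test_that("report rendering round-trips through CSV and matches in Markdown", {
  cfg <- sim_config(seed = 13, n_patients = 150, n_episodes = 150)
  st <- run_stream(cfg)
  tab <- aggregate_alerts(st$events)
  csv <- render_report(tab, "csv")
  back <- parse_report_csv(csv)
  expect_equal(back$cells[, c("row", "col", "generated", "accepted")],
               tab$cells[, c("row", "col", "generated", "accepted")],
               ignore_attr = TRUE)
  md <- render_report(tab, "markdown")
  expect_true(all(vapply(tab$row_order, function(r) any(grepl(r, md, fixed = TRUE)),
                         logical(1))))
  empty_md <- render_report(aggregate_alerts(list()), "markdown")
  expect_match(empty_md, "Totals")
})

test_that("in-text counts are available for derived ratios", {
  x <- load_intext_counts()
  expect_identical(unname(x["anticoagulant_duplication_generated"]), 14903)
  expect_identical(pct(x[["anticoagulant_duplication_accepted"]],
                       x[["anticoagulant_duplication_generated"]]), 42L)
})
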