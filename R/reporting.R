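# Reporting: aggregate audit logs into generated/accepted/% tables by alert
# family and year, rankings (top interaction pairs, top geriatric drugs),
# and packaged fixtures transcribing the published three-year audit summary
# of the production system this engine models.

FAMILY_LABELS <- c(
  interactions = "Interactions",
  duplications = "Duplicate therapies",
  geriatrics = "Advised due to age (> 75 years)",
  aemps = "AEMPS safety alerts",
  contra_health = "Contraindications due to health issues",
  teratogens = "Teratogens in pregnancy",
  anticholinergics = "Combinations of anticholinergic drugs",
  hypersensitivity = "Suspicions of hypersensitivity",
  adr = "Adverse drug reactions")

#' Integer acceptance percentage, rounding half away from zero
#'
#' `round(100 * accepted / generated)` with halves away from zero, the
#' convention every percentage cell of the published summary follows.
#' Undefined (error) when generated is zero; callers render such cells
#' blank.
#' @export
pct <- function(accepted, generated) {
  if (!is_scalar_number(accepted) || !is_scalar_number(generated))
    abort_fmt("pct() expects scalar counts")
  if (generated <= 0) abort_fmt("pct() undefined for generated = %g", generated)
  if (accepted < 0 || accepted > generated)
    abort_fmt("pct(): accepted (%g) must lie in [0, generated = %g]", accepted, generated)
  as.integer(floor(100 * accepted / generated + 0.5))
}

#' Integer share of a whole, same rounding as [pct()]
#' @export
share <- function(part, whole) {
  if (!is_scalar_number(part) || !is_scalar_number(whole))
    abort_fmt("share() expects scalar counts")
  if (whole <= 0) abort_fmt("share() undefined for whole = %g", whole)
  if (part < 0 || part > whole)
    abort_fmt("share(): part (%g) must lie in [0, whole = %g]", part, whole)
  as.integer(floor(100 * part / whole + 0.5))
}

new_report <- function(cells, row_order, col_order) {
  structure(list(cells = cells, row_order = row_order, col_order = col_order),
            class = "mrp_report")
}

#' Look up one cell of a report table
#' @param field "generated", "accepted", "pct" (recomputed via [pct()]) or
#'   "pct_printed" (fixture transcription, when present)
#' @export
report_cell <- function(table, row, col, field = "generated") {
  stopifnot(inherits(table, "mrp_report"))
  i <- which(table$cells$row == row & table$cells$col == col)
  if (length(i) == 0L) return(NA_real_)
  if (field == "pct") {
    g <- table$cells$generated[i]; a <- table$cells$accepted[i]
    if (is.na(g) || g == 0 || is.na(a)) return(NA_integer_)
    return(pct(a, g))
  }
  table$cells[[field]][i]
}

#' Aggregate an audit log into a family-by-year report table
#'
#' Every alert of every event contributes one count to its family/year
#' generated cell, and one to the accepted cell iff the episode outcome was
#' "not_prescribed". Events without alerts are loggable but contribute
#' nothing. A cumulative "sum" column (row-wise year totals) and a "Totals"
#' row (column-wise family sums) are added; the output is deterministic.
#' @export
aggregate_alerts <- function(events) {
  years <- sort(unique(vapply(events, function(e) as.character(e$year), character(1))))
  fams <- names(FAMILY_LABELS)
  gen <- matrix(0L, nrow = length(fams), ncol = length(years),
                dimnames = list(fams, years))
  acc <- gen
  for (e in events) {
    if (length(e$alerts) == 0L) next
    ok <- is_accepted(e)
    y <- as.character(e$year)
    for (a in e$alerts) {
      gen[a$family, y] <- gen[a$family, y] + 1L
      if (ok) acc[a$family, y] <- acc[a$family, y] + 1L
    }
  }
  rows <- c(unname(FAMILY_LABELS), "Totals")
  cols <- c(years, "sum")
  cells <- do.call(rbind, lapply(seq_along(fams), function(i) {
    data.frame(row = FAMILY_LABELS[[fams[i]]],
               col = cols,
               generated = c(gen[i, ], sum(gen[i, ])),
               accepted = c(acc[i, ], sum(acc[i, ])),
               stringsAsFactors = FALSE)
  }))
  totals <- data.frame(row = "Totals", col = cols,
                       generated = c(colSums(gen), sum(gen)),
                       accepted = c(colSums(acc), sum(acc)),
                       stringsAsFactors = FALSE)
  new_report(rbind(cells, totals), rows, cols)
}

#' Ranking of alert keys by generated count
#'
#' Counts alerts (not episodes): one episode can contribute to several
#' keys. Keys: "interaction_pair" (directional candidate -> conflicting
#' product pair over interaction alerts), "ingredient" (candidate product of
#' geriatric alerts), or "rule". Descending by generated count, ties broken
#' by label ascending.
#' @export
top_alerts <- function(events, key = c("interaction_pair", "ingredient", "rule"),
                       n = 10L, family = NULL) {
  key <- match.arg(key)
  if (n < 1L) abort_fmt("n must be >= 1")
  labs <- character(0); accepted_flags <- logical(0)
  for (e in events) {
    if (length(e$alerts) == 0L) next
    ok <- is_accepted(e)
    for (a in e$alerts) {
      lab <- switch(key,
        interaction_pair = if (a$checker == "interactions")
          paste(a$candidate_product, a$conflicting_id, sep = " -> ") else NA_character_,
        ingredient = if (a$checker == "geriatrics") a$candidate_product else NA_character_,
        rule = a$rule_id)
      if (!is.null(family) && a$family != family) lab <- NA_character_
      if (!is.na(lab)) {
        labs <- c(labs, lab); accepted_flags <- c(accepted_flags, ok)
      }
    }
  }
  if (length(labs) == 0L)
    return(data.frame(label = character(0), generated = integer(0),
                      accepted = integer(0), pct_accepted = integer(0),
                      stringsAsFactors = FALSE))
  gen <- tapply(rep(1L, length(labs)), labs, sum)
  acc <- tapply(as.integer(accepted_flags), labs, sum)
  ord <- order(-gen, names(gen))
  keep <- utils::head(ord, n)
  data.frame(label = names(gen)[keep],
             generated = as.integer(gen[keep]),
             accepted = as.integer(acc[keep]),
             pct_accepted = vapply(keep, function(i) pct(acc[i], gen[i]), integer(1)),
             row.names = NULL, stringsAsFactors = FALSE)
}

fixture_path <- function(name) {
  p <- system.file("extdata", "fixtures", paste0(name, ".csv"), package = "rxscreen")
  if (!nzchar(p)) abort_fmt("unknown fixture '%s'", name)
  p
}

#' Load a packaged transcription of the published audit summary tables
#'
#' `name` is one of "table2" (generated/accepted/% by alert family and
#' year), "table3" (top interaction pairs), "table4" (regulatory safety
#' alerts by year), "table5" (geriatric pharmacological groups) or "table6"
#' (top geriatric drugs). Internal sums are verified on load: the family
#' table's year columns must sum to its printed totals and each cumulative
#' cell must equal the sum of its year cells; the regulatory table's year
#' columns must sum to their printed Total row.
#' @export
load_printed_fixture <- function(name = c("table2", "table3", "table4",
                                          "table5", "table6")) {
  name <- match.arg(name)
  df <- read_csv_strict(fixture_path(name))
  require_columns(df, c("row", "col", "generated", "accepted", "pct_printed"),
                  fixture_path(name))
  df$generated <- as.numeric(df$generated)
  df$accepted <- suppressWarnings(as.numeric(ifelse(nzchar(df$accepted), df$accepted, NA)))
  df$pct_printed <- suppressWarnings(as.numeric(ifelse(nzchar(df$pct_printed),
                                                       df$pct_printed, NA)))
  rows <- unique(df$row); cols <- unique(df$col)
  tab <- new_report(df, rows, cols)
  check_sum <- function(total_row, value_col) {
    for (fld in c("generated", "accepted")) {
      body <- df[df$row != total_row & df$col == value_col, fld]
      tot <- df[df$row == total_row & df$col == value_col, fld]
      if (length(tot) == 1L && !is.na(tot) && !all(is.na(body)) &&
          sum(body, na.rm = TRUE) != tot)
        abort_fmt("fixture %s: %s column '%s' sums to %g, printed total is %g",
                  name, fld, value_col, sum(body, na.rm = TRUE), tot)
    }
  }
  if (name == "table2") {
    for (cl in cols) check_sum("Totals", cl)
    for (rw in rows) {
      for (fld in c("generated", "accepted")) {
        ycells <- df[df$row == rw & df$col != "sum", fld]
        scell <- df[df$row == rw & df$col == "sum", fld]
        if (length(scell) == 1L && sum(ycells) != scell)
          abort_fmt("fixture table2: row '%s' %s year cells sum to %g, cumulative is %g",
                    rw, fld, sum(ycells), scell)
      }
    }
  }
  if (name == "table4") for (cl in cols) check_sum("Total", cl)
  tab
}

#' Counts quoted only in the running text of the published summary
#' (named count -> value), e.g. oral-anticoagulant duplication totals.
#' @export
load_intext_counts <- function() {
  df <- read_csv_strict(system.file("extdata", "fixtures", "intext.csv",
                                    package = "rxscreen"))
  stats::setNames(as.numeric(df$value), df$name)
}

#' Render a report table as CSV or a Markdown grid
#'
#' CSV output is the long cell list (round-trip parseable); Markdown output
#' is one row per label with "generated / accepted (pct%)" cells. Undefined
#' percentages render blank.
#' @export
render_report <- function(table, format = c("csv", "markdown")) {
  stopifnot(inherits(table, "mrp_report"))
  format <- match.arg(format)
  cells <- table$cells
  if (format == "csv") {
    con <- textConnection("out", "w", local = TRUE)
    utils::write.csv(cells[, c("row", "col", "generated", "accepted")],
                     con, row.names = FALSE, na = "")
    close(con)
    return(paste(out, collapse = "\n"))
  }
  fmt_cell <- function(rw, cl) {
    i <- which(cells$row == rw & cells$col == cl)
    if (length(i) == 0L) return("")
    g <- cells$generated[i]; a <- cells$accepted[i]
    p <- if (!is.na(g) && g > 0 && !is.na(a)) sprintf(" (%d%%)", pct(a, g)) else ""
    sprintf("%s / %s%s", format(g, big.mark = ","),
            if (is.na(a)) "-" else format(a, big.mark = ","), p)
  }
  header <- paste0("| ", paste(c("", table$col_order), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", length(table$col_order) + 1L), collapse = "|"), "|")
  body <- vapply(table$row_order, function(rw)
    paste0("| ", paste(c(rw, vapply(table$col_order, function(cl)
      fmt_cell(rw, cl), character(1))), collapse = " | "), " |"),
    character(1))
  paste(c(header, sep, body), collapse = "\n")
}

#' Parse the CSV produced by [render_report()] back into a report table
#' @export
parse_report_csv <- function(text) {
  df <- utils::read.csv(textConnection(text), colClasses = c(
    row = "character", col = "character", generated = "numeric",
    accepted = "numeric"), stringsAsFactors = FALSE)
  new_report(df, unique(df$row), unique(df$col))
}
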