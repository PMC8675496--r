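# Typed knowledge base for the nine MRP alert families, loaded from one CSV
# per family plus a formulary, drug-group and problem-group table and a YAML
# manifest. Severities: RED = absolute contraindication (regulatory safety
# alerts, teratogens), ORANGE = precautionary. The family set is closed;
# extensibility is via content, not new families.

RULE_FAMILIES <- c("interactions", "duplications", "aemps", "geriatrics",
                   "problem_contra", "clinical_vars", "teratogens",
                   "anticholinergics", "sensitivity")

RULEBASE_FILES <- c(
  formulary = "formulary.csv", drug_groups = "drug_groups.csv",
  problem_groups = "problem_groups.csv",
  interactions = "interactions.csv", duplications = "duplications.csv",
  aemps = "aemps.csv", geriatrics = "geriatrics.csv",
  problem_contra = "problem_contra.csv", clinical_vars = "clinical_vars.csv",
  teratogens = "teratogens.csv", anticholinergics = "anticholinergics.csv",
  sensitivity = "sensitivity.csv")

.parse_num_or_na <- function(x) {
  if (is.null(x) || is.na(x) || !nzchar(trimws(x))) return(NA_real_)
  suppressWarnings(as.numeric(x))
}

.norm_comparator <- function(x) {
  x <- trimws(x)
  if (x == "≤") x <- "<="
  if (x == "≥") x <- ">="
  x
}

#' Load a rulebase from a directory of configuration tables
#'
#' The directory must contain `rulebase.yaml` (version label) plus the
#' formulary, drug-group, problem-group and nine per-family CSV files.
#' Loading is deterministic; all structural violations (dangling group
#' references, duplicate rule ids, bad severities, malformed codes) are
#' reported together in one error.
#'
#' @param dir path to the rulebase directory
#' @return an object of class `rulebase`
#' @export
load_rulebase <- function(dir) {
  if (!dir.exists(dir)) abort_fmt("rulebase directory not found: %s", dir)
  manifest_path <- file.path(dir, "rulebase.yaml")
  manifest <- if (file.exists(manifest_path)) yaml::read_yaml(manifest_path) else list()
  version <- manifest$version %||% "unversioned"

  path_of <- function(key) file.path(dir, RULEBASE_FILES[[key]])
  for (key in names(RULEBASE_FILES)) {
    if (!file.exists(path_of(key)))
      abort_fmt("rulebase directory %s: missing %s", dir, RULEBASE_FILES[[key]])
  }

  formulary <- read_formulary(path_of("formulary"))

  gdf <- require_columns(read_csv_strict(path_of("drug_groups")),
                         c("group_id", "label", "include_prefixes",
                           "exclude_prefixes", "member_ingredients"),
                         path_of("drug_groups"))
  drug_groups <- lapply(seq_len(nrow(gdf)), function(i)
    drug_group(gdf$group_id[i], gdf$label[i],
               split_list_field(gdf$include_prefixes[i]),
               split_list_field(gdf$exclude_prefixes[i]),
               split_list_field(gdf$member_ingredients[i])))
  names(drug_groups) <- gdf$group_id

  pdf <- require_columns(read_csv_strict(path_of("problem_groups")),
                         c("group_id", "label", "include_prefixes"),
                         path_of("problem_groups"))
  problem_groups <- lapply(seq_len(nrow(pdf)), function(i)
    problem_group(pdf$group_id[i], pdf$label[i], split_list_field(pdf$include_prefixes[i])))
  names(problem_groups) <- pdf$group_id

  read_rules <- function(key, cols, builder) {
    df <- require_columns(read_csv_strict(path_of(key)), cols, path_of(key))
    lapply(seq_len(nrow(df)), function(i) builder(df[i, , drop = FALSE]))
  }

  rules <- list(
    interactions = read_rules("interactions",
      c("rule_id", "group_a", "group_b", "severity", "risk_text", "alternatives"),
      function(r) list(rule_id = r$rule_id, group_a = r$group_a, group_b = r$group_b,
                       severity = r$severity, risk_text = r$risk_text,
                       alternatives = split_list_field(r$alternatives))),
    duplications = read_rules("duplications",
      c("rule_id", "group", "subtype", "severity", "risk_text"),
      function(r) list(rule_id = r$rule_id, group = r$group, subtype = r$subtype,
                       severity = r$severity, risk_text = r$risk_text)),
    aemps = read_rules("aemps",
      c("rule_id", "label", "trigger_group", "required_comed_groups", "min_age",
        "max_age", "problem_groups", "dose_comparator", "dose_threshold",
        "dose_unit", "severity", "risk_text", "alternatives"),
      function(r) list(rule_id = r$rule_id, label = r$label,
                       trigger_group = r$trigger_group,
                       required_comed_groups = split_list_field(r$required_comed_groups),
                       min_age = .parse_num_or_na(r$min_age),
                       max_age = .parse_num_or_na(r$max_age),
                       problem_groups = split_list_field(r$problem_groups),
                       dose_comparator = if (nzchar(trimws(r$dose_comparator)))
                         .norm_comparator(r$dose_comparator) else NA_character_,
                       dose_threshold = .parse_num_or_na(r$dose_threshold),
                       dose_unit = if (nzchar(trimws(r$dose_unit))) trimws(r$dose_unit)
                         else NA_character_,
                       severity = r$severity, risk_text = r$risk_text,
                       alternatives = split_list_field(r$alternatives))),
    geriatrics = read_rules("geriatrics",
      c("rule_id", "group", "min_age", "severity", "risk_text", "alternatives"),
      function(r) list(rule_id = r$rule_id, group = r$group,
                       min_age = .parse_num_or_na(r$min_age),
                       severity = r$severity, risk_text = r$risk_text,
                       alternatives = split_list_field(r$alternatives))),
    problem_contra = read_rules("problem_contra",
      c("rule_id", "group", "problem_group", "severity", "risk_text"),
      function(r) list(rule_id = r$rule_id, group = r$group,
                       problem_group = r$problem_group,
                       severity = r$severity, risk_text = r$risk_text)),
    clinical_vars = read_rules("clinical_vars",
      c("rule_id", "group", "variable_label", "comparator", "threshold",
        "unit", "severity", "risk_text"),
      function(r) list(rule_id = r$rule_id, group = r$group,
                       variable_label = r$variable_label,
                       comparator = .norm_comparator(r$comparator),
                       threshold = .parse_num_or_na(r$threshold), unit = r$unit,
                       severity = r$severity, risk_text = r$risk_text)),
    teratogens = read_rules("teratogens",
      c("rule_id", "group", "severity", "risk_text"),
      function(r) list(rule_id = r$rule_id, group = r$group,
                       severity = r$severity, risk_text = r$risk_text)),
    anticholinergics = read_rules("anticholinergics",
      c("rule_id", "group", "min_concomitant", "severity", "risk_text"),
      function(r) list(rule_id = r$rule_id, group = r$group,
                       min_concomitant = .parse_num_or_na(r$min_concomitant),
                       severity = r$severity, risk_text = r$risk_text)),
    sensitivity = read_rules("sensitivity",
      c("rule_id", "kind", "group", "severity", "risk_text"),
      function(r) list(rule_id = r$rule_id, kind = r$kind, group = r$group,
                       severity = r$severity, risk_text = r$risk_text))
  )

  rb <- structure(list(version = version, formulary = formulary,
                       drug_groups = drug_groups, problem_groups = problem_groups,
                       rules = rules),
                  class = "rulebase")
  diags <- validate_rulebase(rb)
  errs <- diags[diags$level == "error", , drop = FALSE]
  if (nrow(errs) > 0L)
    abort_fmt("rulebase %s failed validation with %d error(s):\n%s", dir, nrow(errs),
              paste(sprintf("  [%s] %s", errs$rule_id, errs$message), collapse = "\n"))
  rb
}

rb_group <- function(rb, id) rb$drug_groups[[id]]
rb_problem_group <- function(rb, id) rb$problem_groups[[id]]
rb_product <- function(rb, id) rb$formulary[[id]]

#' Validate a rulebase
#'
#' Returns a data frame of diagnostics with columns `level` ("error" or
#' "warning"), `rule_id` and `message`; zero rows iff all invariants hold.
#' Errors: dangling group references, duplicate rule ids, unknown
#' severities/subtypes/comparators, AEMPS rules not RED, geriatrics rules
#' not ORANGE, dose thresholds without a unit. Warnings: interaction rules
#' whose two groups overlap, geriatric age cut-offs other than 75, AEMPS
#' trigger/co-medication group overlap.
#' @export
validate_rulebase <- function(rb) {
  stopifnot(inherits(rb, "rulebase"))
  level <- character(0); rid <- character(0); msg <- character(0)
  note <- function(lv, id, m) {
    level <<- c(level, lv); rid <<- c(rid, id); msg <<- c(msg, m)
  }
  all_rules <- unlist(rb$rules, recursive = FALSE, use.names = FALSE)
  ids <- vapply(all_rules, `[[`, character(1), "rule_id")
  for (dup in unique(ids[duplicated(ids)]))
    note("error", dup, "duplicate rule_id")

  chk_group <- function(id, gid) {
    if (is.null(rb_group(rb, gid)))
      note("error", id, sprintf("unknown drug group '%s'", gid))
  }
  chk_pgroup <- function(id, gid) {
    if (is.null(rb_problem_group(rb, gid)))
      note("error", id, sprintf("unknown problem group '%s'", gid))
  }
  chk_sev <- function(id, sev, allowed = c("RED", "ORANGE")) {
    if (!sev %in% c("RED", "ORANGE"))
      note("error", id, sprintf("bad severity '%s' (must be RED or ORANGE)", sev))
    else if (!sev %in% allowed)
      note("error", id, sprintf("severity must be %s for this family, got %s",
                                paste(allowed, collapse = "/"), sev))
  }

  groups_overlap <- function(ga, gb) {
    if (length(intersect(ga$member_ingredients, gb$member_ingredients)) > 0L) return(TRUE)
    for (a in ga$include_prefixes) for (b in gb$include_prefixes)
      if (startsWith(a, b) || startsWith(b, a)) return(TRUE)
    for (p in rb$formulary)
      if (product_in_group(p, ga) && product_in_group(p, gb)) return(TRUE)
    FALSE
  }

  for (r in rb$rules$interactions) {
    chk_group(r$rule_id, r$group_a); chk_group(r$rule_id, r$group_b)
    chk_sev(r$rule_id, r$severity)
    ga <- rb_group(rb, r$group_a); gb <- rb_group(rb, r$group_b)
    if (!is.null(ga) && !is.null(gb) && groups_overlap(ga, gb))
      note("warning", r$rule_id, "interaction groups overlap (self-interaction?)")
  }
  for (r in rb$rules$duplications) {
    chk_group(r$rule_id, r$group); chk_sev(r$rule_id, r$severity)
    if (!r$subtype %in% c("clinically_relevant", "dose_adjustment"))
      note("error", r$rule_id, sprintf("bad duplication subtype '%s'", r$subtype))
  }
  for (r in rb$rules$aemps) {
    chk_group(r$rule_id, r$trigger_group)
    for (g in r$required_comed_groups) chk_group(r$rule_id, g)
    for (g in r$problem_groups) chk_pgroup(r$rule_id, g)
    chk_sev(r$rule_id, r$severity, allowed = "RED")
    if (!is.na(r$dose_threshold)) {
      if (is.na(r$dose_unit))
        note("error", r$rule_id, "dose threshold without a unit")
      if (is.na(r$dose_comparator) || !r$dose_comparator %in% c("<", "<=", ">", ">="))
        note("error", r$rule_id, "dose threshold without a valid comparator")
    }
    tg <- rb_group(rb, r$trigger_group)
    for (g in r$required_comed_groups) {
      cg <- rb_group(rb, g)
      if (!is.null(tg) && !is.null(cg) && groups_overlap(tg, cg))
        note("warning", r$rule_id,
             sprintf("trigger group overlaps required co-medication group '%s'", g))
    }
  }
  for (r in rb$rules$geriatrics) {
    chk_group(r$rule_id, r$group)
    chk_sev(r$rule_id, r$severity, allowed = "ORANGE")
    if (is.na(r$min_age))
      note("error", r$rule_id, "geriatric rule without min_age")
    else if (r$min_age != 75)
      note("warning", r$rule_id,
           sprintf("geriatric age cut-off %g differs from the reference value 75", r$min_age))
  }
  for (r in rb$rules$problem_contra) {
    chk_group(r$rule_id, r$group); chk_pgroup(r$rule_id, r$problem_group)
    chk_sev(r$rule_id, r$severity)
  }
  for (r in rb$rules$clinical_vars) {
    chk_group(r$rule_id, r$group); chk_sev(r$rule_id, r$severity)
    if (!r$comparator %in% c("<", "<=", ">", ">="))
      note("error", r$rule_id, sprintf("bad comparator '%s'", r$comparator))
    if (is.na(r$threshold))
      note("error", r$rule_id, "threshold is not a finite number")
  }
  for (r in rb$rules$teratogens) {
    chk_group(r$rule_id, r$group); chk_sev(r$rule_id, r$severity)
  }
  for (r in rb$rules$anticholinergics) {
    chk_group(r$rule_id, r$group); chk_sev(r$rule_id, r$severity)
    if (is.na(r$min_concomitant) || r$min_concomitant < 1)
      note("error", r$rule_id, "min_concomitant must be >= 1")
  }
  for (r in rb$rules$sensitivity) {
    chk_group(r$rule_id, r$group); chk_sev(r$rule_id, r$severity)
    if (!r$kind %in% c("suspected_hypersensitivity", "adverse_drug_reaction"))
      note("error", r$rule_id, sprintf("bad sensitivity kind '%s'", r$kind))
  }
  data.frame(level = level, rule_id = rid, message = msg, stringsAsFactors = FALSE)
}

#' Write a rulebase back to a directory (round-trip inverse of
#' [load_rulebase()])
#' @export
write_rulebase <- function(rb, dir) {
  stopifnot(inherits(rb, "rulebase"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wcsv <- function(df, key) utils::write.csv(df, file.path(dir, RULEBASE_FILES[[key]]),
                                             row.names = FALSE, fileEncoding = "UTF-8")
  write_formulary(rb$formulary, file.path(dir, RULEBASE_FILES[["formulary"]]))
  wcsv(data.frame(
    group_id = vapply(rb$drug_groups, `[[`, character(1), "group_id"),
    label = vapply(rb$drug_groups, `[[`, character(1), "label"),
    include_prefixes = vapply(rb$drug_groups, function(g) join_list_field(g$include_prefixes), character(1)),
    exclude_prefixes = vapply(rb$drug_groups, function(g) join_list_field(g$exclude_prefixes), character(1)),
    member_ingredients = vapply(rb$drug_groups, function(g) join_list_field(g$member_ingredients), character(1)),
    stringsAsFactors = FALSE), "drug_groups")
  wcsv(data.frame(
    group_id = vapply(rb$problem_groups, `[[`, character(1), "group_id"),
    label = vapply(rb$problem_groups, `[[`, character(1), "label"),
    include_prefixes = vapply(rb$problem_groups, function(g) join_list_field(g$include_prefixes), character(1)),
    stringsAsFactors = FALSE), "problem_groups")

  col <- function(rules, f, fmt = identity)
    vapply(rules, function(r) {
      v <- r[[f]]
      if (is.null(v) || (length(v) == 1L && is.na(v))) "" else as.character(fmt(v))
    }, character(1))
  lcol <- function(rules, f) vapply(rules, function(r) join_list_field(r[[f]]), character(1))
  rr <- rb$rules
  wcsv(data.frame(rule_id = col(rr$interactions, "rule_id"),
                  group_a = col(rr$interactions, "group_a"),
                  group_b = col(rr$interactions, "group_b"),
                  severity = col(rr$interactions, "severity"),
                  risk_text = col(rr$interactions, "risk_text"),
                  alternatives = lcol(rr$interactions, "alternatives"),
                  stringsAsFactors = FALSE), "interactions")
  wcsv(data.frame(rule_id = col(rr$duplications, "rule_id"),
                  group = col(rr$duplications, "group"),
                  subtype = col(rr$duplications, "subtype"),
                  severity = col(rr$duplications, "severity"),
                  risk_text = col(rr$duplications, "risk_text"),
                  stringsAsFactors = FALSE), "duplications")
  wcsv(data.frame(rule_id = col(rr$aemps, "rule_id"), label = col(rr$aemps, "label"),
                  trigger_group = col(rr$aemps, "trigger_group"),
                  required_comed_groups = lcol(rr$aemps, "required_comed_groups"),
                  min_age = col(rr$aemps, "min_age"), max_age = col(rr$aemps, "max_age"),
                  problem_groups = lcol(rr$aemps, "problem_groups"),
                  dose_comparator = col(rr$aemps, "dose_comparator"),
                  dose_threshold = col(rr$aemps, "dose_threshold"),
                  dose_unit = col(rr$aemps, "dose_unit"),
                  severity = col(rr$aemps, "severity"),
                  risk_text = col(rr$aemps, "risk_text"),
                  alternatives = lcol(rr$aemps, "alternatives"),
                  stringsAsFactors = FALSE), "aemps")
  wcsv(data.frame(rule_id = col(rr$geriatrics, "rule_id"),
                  group = col(rr$geriatrics, "group"),
                  min_age = col(rr$geriatrics, "min_age"),
                  severity = col(rr$geriatrics, "severity"),
                  risk_text = col(rr$geriatrics, "risk_text"),
                  alternatives = lcol(rr$geriatrics, "alternatives"),
                  stringsAsFactors = FALSE), "geriatrics")
  wcsv(data.frame(rule_id = col(rr$problem_contra, "rule_id"),
                  group = col(rr$problem_contra, "group"),
                  problem_group = col(rr$problem_contra, "problem_group"),
                  severity = col(rr$problem_contra, "severity"),
                  risk_text = col(rr$problem_contra, "risk_text"),
                  stringsAsFactors = FALSE), "problem_contra")
  wcsv(data.frame(rule_id = col(rr$clinical_vars, "rule_id"),
                  group = col(rr$clinical_vars, "group"),
                  variable_label = col(rr$clinical_vars, "variable_label"),
                  comparator = col(rr$clinical_vars, "comparator"),
                  threshold = col(rr$clinical_vars, "threshold"),
                  unit = col(rr$clinical_vars, "unit"),
                  severity = col(rr$clinical_vars, "severity"),
                  risk_text = col(rr$clinical_vars, "risk_text"),
                  stringsAsFactors = FALSE), "clinical_vars")
  wcsv(data.frame(rule_id = col(rr$teratogens, "rule_id"),
                  group = col(rr$teratogens, "group"),
                  severity = col(rr$teratogens, "severity"),
                  risk_text = col(rr$teratogens, "risk_text"),
                  stringsAsFactors = FALSE), "teratogens")
  wcsv(data.frame(rule_id = col(rr$anticholinergics, "rule_id"),
                  group = col(rr$anticholinergics, "group"),
                  min_concomitant = col(rr$anticholinergics, "min_concomitant"),
                  severity = col(rr$anticholinergics, "severity"),
                  risk_text = col(rr$anticholinergics, "risk_text"),
                  stringsAsFactors = FALSE), "anticholinergics")
  wcsv(data.frame(rule_id = col(rr$sensitivity, "rule_id"),
                  kind = col(rr$sensitivity, "kind"),
                  group = col(rr$sensitivity, "group"),
                  severity = col(rr$sensitivity, "severity"),
                  risk_text = col(rr$sensitivity, "risk_text"),
                  stringsAsFactors = FALSE), "sensitivity")
  yaml::write_yaml(list(version = rb$version,
                        files = unname(as.list(RULEBASE_FILES))),
                   file.path(dir, "rulebase.yaml"))
  invisible(dir)
}

#' The packaged demonstration rulebase
#'
#' Loads the demo content shipped with the package: a small formulary of the
#' drugs the reference deployment is known to cover, the 14 regulatory
#' (AEMPS-style) RED rules including the Triple Whammy (NSAID trigger with
#' renin-angiotensin-system inhibitors and diuretics as required
#' co-medication), 15 geriatric ORANGE groups for patients aged 75 and over,
#' the named therapeutic-duplication groups, the published top interaction
#' pairs, NSAID and beta-lactam cross-reactivity groups, a teratogen group,
#' an anticholinergic combination group, and eGFR/potassium
#' clinical-variable rules.
#' @export
demo_rulebase <- function() {
  dir <- system.file("extdata", "demo_rulebase", package = "rxscreen")
  if (!nzchar(dir)) abort_fmt("demo rulebase content not found in installed package")
  load_rulebase(dir)
}

#' Demo formulary and groups (deterministic)
#'
#' Returns the packaged demo formulary together with its drug and problem
#' groups. The content is fixed, so the result is identical for every seed;
#' the argument exists for interface symmetry with the other generators.
#' @export
generate_formulary <- function(seed = NULL) {
  rb <- demo_rulebase()
  list(formulary = rb$formulary, drug_groups = rb$drug_groups,
       problem_groups = rb$problem_groups)
}
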