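# The evaluation core: given a candidate prescription, a patient record and
# a rulebase, run all alert-family checkers and assemble an ordered alert
# screen. The engine is one-directional (it screens the candidate against
# the existing record at prescribing time, never old co-prescriptions
# against each other), purely advisory (it never blocks) and a pure
# function of its inputs.

# Checker enumeration fixes the within-severity display order of the
# screen. Both contraindication checkers report the same alert family
# ("contra_health"), matching how generated/accepted statistics are
# aggregated.
CHECKER_ORDER <- c("aemps", "interactions", "duplications", "problem_contra",
                   "clinical_vars", "teratogens", "geriatrics",
                   "anticholinergics", "hypersensitivity", "adr")

ALERT_FAMILIES <- c("interactions", "duplications", "geriatrics", "aemps",
                    "contra_health", "teratogens", "anticholinergics",
                    "hypersensitivity", "adr")

checker_family <- function(checker) {
  switch(checker,
         problem_contra = "contra_health",
         clinical_vars = "contra_health",
         checker)
}

new_alert <- function(rule_id, checker, severity, candidate_product,
                      conflicting_type, conflicting_id, risk_text,
                      alternatives = character(0), subtype = NA_character_) {
  structure(list(rule_id = rule_id, checker = checker,
                 family = checker_family(checker), severity = severity,
                 candidate_product = candidate_product,
                 conflicting_type = conflicting_type,
                 conflicting_id = conflicting_id,
                 risk_text = risk_text, alternatives = alternatives,
                 subtype = subtype),
            class = "mrp_alert")
}

alert_key <- function(a) paste(a$rule_id, a$conflicting_type, a$conflicting_id, sep = "\r")

# Normalize the candidate argument: a product_id string or a list with
# product_id and optional daily_dose / dose_unit.
resolve_candidate <- function(candidate, rb) {
  if (is.character(candidate)) candidate <- list(product_id = candidate)
  pid <- candidate$product_id
  prod <- rb_product(rb, pid)
  if (is.null(prod)) abort_fmt("unknown product '%s' (not in formulary)", pid %||% "<missing>")
  list(product = prod,
       daily_dose = candidate$daily_dose %||% NA_real_,
       dose_unit = candidate$dose_unit %||% NA_character_)
}

# Concomitant medication at the prescribing date: active prescriptions
# joined to their formulary products. Prescriptions whose product is not in
# the formulary are skipped (they can trigger no rule).
concomitant_products <- function(patient, rb, date) {
  act <- active_prescriptions(patient, date)
  out <- list()
  for (rx in act) {
    p <- rb_product(rb, rx$product_id)
    if (!is.null(p)) out[[length(out) + 1L]] <- list(rx = rx, product = p)
  }
  out
}

compare_with <- function(value, comparator, threshold) {
  switch(comparator,
         "<"  = value < threshold,
         "<=" = value <= threshold,
         ">"  = value > threshold,
         ">=" = value >= threshold,
         abort_fmt("bad comparator '%s'", comparator))
}

#' Drug-drug interaction checker
#'
#' One alert per (rule, conflicting active prescription) where the candidate
#' falls in one of the rule's two groups and a concomitant product falls in
#' the other. Interaction rules are unordered pairs; the alert records the
#' direction by naming the concrete conflicting product. Attribution works
#' at ingredient level through fixed combinations.
#' @export
check_interactions <- function(candidate, patient, rb, date) {
  cand <- resolve_candidate(candidate, rb)
  comeds <- concomitant_products(patient, rb, date)
  alerts <- list()
  for (r in rb$rules$interactions) {
    ga <- rb_group(rb, r$group_a); gb <- rb_group(rb, r$group_b)
    in_a <- product_in_group(cand$product, ga)
    in_b <- product_in_group(cand$product, gb)
    if (!in_a && !in_b) next
    other <- if (in_a) gb else ga
    for (cm in comeds) {
      if (cm$product$product_id == cand$product$product_id) next
      if (product_in_group(cm$product, other))
        alerts[[length(alerts) + 1L]] <- new_alert(
          r$rule_id, "interactions", r$severity, cand$product$product_id,
          "product", cm$product$product_id, r$risk_text, r$alternatives)
    }
  }
  alerts
}

#' Therapeutic duplication checker
#'
#' Fires when (a) any candidate ingredient equals any concomitant ingredient
#' (same-ingredient duplication, intrinsic, no configured content needed),
#' or (b) candidate and a concomitant product both fall in a configured
#' duplication group. Alerts carry the configured subtype
#' ("clinically_relevant" or "dose_adjustment").
#' @export
check_duplications <- function(candidate, patient, rb, date) {
  cand <- resolve_candidate(candidate, rb)
  comeds <- concomitant_products(patient, rb, date)
  alerts <- list()
  for (cm in comeds) {
    shared <- intersect(cand$product$ingredients, cm$product$ingredients)
    for (ing in shared)
      alerts[[length(alerts) + 1L]] <- new_alert(
        "DUP-SAME-INGREDIENT", "duplications", "ORANGE",
        cand$product$product_id, "ingredient",
        paste(cm$product$product_id, ing, sep = ":"),
        sprintf("The active ingredient %s is already prescribed (%s)",
                ing, cm$product$label),
        subtype = "clinically_relevant")
  }
  for (r in rb$rules$duplications) {
    g <- rb_group(rb, r$group)
    if (!product_in_group(cand$product, g)) next
    for (cm in comeds) {
      if (cm$product$product_id == cand$product$product_id) next
      if (product_in_group(cm$product, g))
        alerts[[length(alerts) + 1L]] <- new_alert(
          r$rule_id, "duplications", r$severity, cand$product$product_id,
          "product", cm$product$product_id, r$risk_text, subtype = r$subtype)
    }
  }
  alerts
}

#' Regulatory (AEMPS-style) safety-alert checker
#'
#' For each rule whose trigger group contains the candidate, the alert fires
#' iff every required co-medication group has at least one concomitant
#' member and all configured age, health-problem and daily-dose constraints
#' hold. A dose-thresholded rule does not fire when the prescribed dose is
#' unknown or recorded in a different unit. Severity is always RED.
#' @export
check_aemps <- function(candidate, patient, rb, date) {
  cand <- resolve_candidate(candidate, rb)
  comeds <- concomitant_products(patient, rb, date)
  age <- age_at(patient, date)
  alerts <- list()
  for (r in rb$rules$aemps) {
    if (!product_in_group(cand$product, rb_group(rb, r$trigger_group))) next
    comeds_ok <- all(vapply(r$required_comed_groups, function(gid) {
      g <- rb_group(rb, gid)
      any(vapply(comeds, function(cm) product_in_group(cm$product, g), logical(1)))
    }, logical(1)))
    if (!comeds_ok) next
    if (!is.na(r$min_age) && age < r$min_age) next
    if (!is.na(r$max_age) && age > r$max_age) next
    if (length(r$problem_groups) > 0L) {
      hit <- any(vapply(r$problem_groups, function(gid) {
        pg <- rb_problem_group(rb, gid)
        any(vapply(patient$problems, function(p) icd10_in_group(p$code, pg), logical(1)))
      }, logical(1)))
      if (!hit) next
    }
    if (!is.na(r$dose_threshold)) {
      if (is.na(cand$daily_dose)) next
      if (is.na(cand$dose_unit) || cand$dose_unit != r$dose_unit) next
      if (!compare_with(cand$daily_dose, r$dose_comparator, r$dose_threshold)) next
    }
    conflicting <- if (length(r$required_comed_groups) > 0L) {
      hits <- Filter(function(cm) any(vapply(r$required_comed_groups, function(gid)
        product_in_group(cm$product, rb_group(rb, gid)), logical(1))), comeds)
      paste(sort(unique(vapply(hits, function(cm) cm$product$product_id, character(1)))),
            collapse = "+")
    } else if (length(r$problem_groups) > 0L) paste(r$problem_groups, collapse = "+")
    else if (!is.na(r$dose_threshold)) sprintf("dose %s %g %s", r$dose_comparator,
                                               r$dose_threshold, r$dose_unit)
    else "regulatory"
    ctype <- if (length(r$required_comed_groups) > 0L) "product"
             else if (length(r$problem_groups) > 0L) "health_problem"
             else if (!is.na(r$dose_threshold)) "dose" else "regulatory"
    alerts[[length(alerts) + 1L]] <- new_alert(
      r$rule_id, "aemps", r$severity, cand$product$product_id,
      ctype, conflicting, r$risk_text, r$alternatives)
  }
  alerts
}

#' Geriatrics (potentially inappropriate medication) checker: fires iff the
#' patient's completed age reaches the rule's cut-off (75 in the packaged
#' content) and the candidate is in the rule's group. ORANGE.
#' @export
check_geriatrics <- function(candidate, patient, rb, date) {
  cand <- resolve_candidate(candidate, rb)
  age <- age_at(patient, date)
  alerts <- list()
  for (r in rb$rules$geriatrics) {
    if (age < r$min_age) next
    if (!product_in_group(cand$product, rb_group(rb, r$group))) next
    alerts[[length(alerts) + 1L]] <- new_alert(
      r$rule_id, "geriatrics", r$severity, cand$product$product_id,
      "age", sprintf("age>=%g", r$min_age), r$risk_text, r$alternatives)
  }
  alerts
}

#' Health-problem contraindication checker
#' @export
check_problem_contraindications <- function(candidate, patient, rb, date) {
  cand <- resolve_candidate(candidate, rb)
  alerts <- list()
  for (r in rb$rules$problem_contra) {
    if (!product_in_group(cand$product, rb_group(rb, r$group))) next
    pg <- rb_problem_group(rb, r$problem_group)
    hits <- Filter(function(p) icd10_in_group(p$code, pg), patient$problems)
    for (p in hits)
      alerts[[length(alerts) + 1L]] <- new_alert(
        r$rule_id, "problem_contra", r$severity, cand$product$product_id,
        "health_problem", p$code, r$risk_text)
  }
  alerts
}

#' Clinical-variable contraindication checker
#'
#' Uses the most recent measurement of the rule's variable within the
#' staleness window (default 365 days); an absent or stale measurement
#' silently keeps the rule from firing.
#' @export
check_clinical_variables <- function(candidate, patient, rb, date,
                                     max_age_days = 365L) {
  cand <- resolve_candidate(candidate, rb)
  alerts <- list()
  for (r in rb$rules$clinical_vars) {
    if (!product_in_group(cand$product, rb_group(rb, r$group))) next
    m <- latest_measurement(patient, r$variable_label, date, max_age_days)
    if (is.null(m)) next
    if (!compare_with(m$value, r$comparator, r$threshold)) next
    alerts[[length(alerts) + 1L]] <- new_alert(
      r$rule_id, "clinical_vars", r$severity, cand$product$product_id,
      "clinical_variable",
      sprintf("%s=%g on %s", r$variable_label, m$value, format(m$date)),
      r$risk_text)
  }
  alerts
}

#' Teratogen checker: fires iff the patient is flagged pregnant and the
#' candidate is in a configured teratogen group.
#' @export
check_teratogens <- function(candidate, patient, rb, date) {
  if (!isTRUE(patient$pregnant)) return(list())
  cand <- resolve_candidate(candidate, rb)
  alerts <- list()
  for (r in rb$rules$teratogens) {
    if (!product_in_group(cand$product, rb_group(rb, r$group))) next
    alerts[[length(alerts) + 1L]] <- new_alert(
      r$rule_id, "teratogens", r$severity, cand$product$product_id,
      "pregnancy", "pregnant", r$risk_text)
  }
  alerts
}

#' Anticholinergic combination checker: fires iff the candidate is in the
#' anticholinergic group and at least `min_concomitant` distinct active
#' products of the same group are already on the record.
#' @export
check_anticholinergics <- function(candidate, patient, rb, date) {
  cand <- resolve_candidate(candidate, rb)
  comeds <- concomitant_products(patient, rb, date)
  alerts <- list()
  for (r in rb$rules$anticholinergics) {
    g <- rb_group(rb, r$group)
    if (!product_in_group(cand$product, g)) next
    members <- Filter(function(cm) cm$product$product_id != cand$product$product_id &&
                        product_in_group(cm$product, g), comeds)
    ids <- unique(vapply(members, function(cm) cm$product$product_id, character(1)))
    if (length(ids) < r$min_concomitant) next
    alerts[[length(alerts) + 1L]] <- new_alert(
      r$rule_id, "anticholinergics", r$severity, cand$product$product_id,
      "product", paste(sort(ids), collapse = "+"), r$risk_text)
  }
  alerts
}

check_sensitivity_kind <- function(candidate, patient, rb, date, kind, checker) {
  cand <- resolve_candidate(candidate, rb)
  alerts <- list()
  for (r in rb$rules$sensitivity) {
    if (r$kind != kind) next
    g <- rb_group(rb, r$group)
    if (!product_in_group(cand$product, g)) next
    recs <- Filter(function(s) s$kind == kind &&
                     (s$target == g$group_id ||
                        ingredient_in_group(s$target, g, rb$formulary)),
                   patient$sensitivities)
    for (s in recs)
      alerts[[length(alerts) + 1L]] <- new_alert(
        r$rule_id, checker, r$severity, cand$product$product_id,
        "sensitivity", sprintf("%s:%s", s$kind, s$target), r$risk_text)
  }
  alerts
}

#' Suspected-hypersensitivity checker: fires per matching rule when the
#' candidate falls in a cross-reactivity group into which a recorded
#' suspected-hypersensitivity target (group id or ingredient) resolves.
#' @export
check_hypersensitivity <- function(candidate, patient, rb, date)
  check_sensitivity_kind(candidate, patient, rb, date,
                         "suspected_hypersensitivity", "hypersensitivity")

#' Adverse-drug-reaction history checker (same semantics as
#' [check_hypersensitivity()], for recorded ADRs).
#' @export
check_adr <- function(candidate, patient, rb, date)
  check_sensitivity_kind(candidate, patient, rb, date,
                         "adverse_drug_reaction", "adr")

#' Assemble an alert screen from raw checker output
#'
#' Deduplicates on (rule_id, conflicting entity) and orders alerts RED
#' before ORANGE, then by the fixed checker enumeration, then rule id, then
#' conflicting entity: a total, deterministic order, so any permutation of
#' the same alert set yields an identical screen.
#' @export
assemble_screen <- function(alerts) {
  keys <- vapply(alerts, alert_key, character(1))
  alerts <- alerts[!duplicated(keys)]
  if (length(alerts) > 0L) {
    sev <- match(vapply(alerts, `[[`, character(1), "severity"), c("RED", "ORANGE"))
    chk <- match(vapply(alerts, `[[`, character(1), "checker"), CHECKER_ORDER)
    rid <- vapply(alerts, `[[`, character(1), "rule_id")
    cid <- vapply(alerts, `[[`, character(1), "conflicting_id")
    alerts <- alerts[order(sev, chk, rid, cid)]
  }
  structure(alerts, class = "alert_screen")
}

#' Evaluate a candidate prescription against a patient record
#'
#' Runs all alert-family checkers and assembles the resulting screen. A
#' candidate outside the formulary is an error; otherwise evaluation never
#' raises on valid input and an empty screen is a legitimate result.
#'
#' @param candidate a formulary product_id, or a list with `product_id` and
#'   optional `daily_dose` / `dose_unit`
#' @param patient a [patient_record()]
#' @param rb a [load_rulebase()] result
#' @param date the prescribing date
#' @return an `alert_screen`: ordered, deduplicated list of alerts
#' @export
evaluate <- function(candidate, patient, rb, date) {
  stopifnot(inherits(patient, "patient_record"), inherits(rb, "rulebase"))
  resolve_candidate(candidate, rb)  # fail fast on unknown product
  assemble_screen(c(
    check_aemps(candidate, patient, rb, date),
    check_interactions(candidate, patient, rb, date),
    check_duplications(candidate, patient, rb, date),
    check_problem_contraindications(candidate, patient, rb, date),
    check_clinical_variables(candidate, patient, rb, date),
    check_teratogens(candidate, patient, rb, date),
    check_geriatrics(candidate, patient, rb, date),
    check_anticholinergics(candidate, patient, rb, date),
    check_hypersensitivity(candidate, patient, rb, date),
    check_adr(candidate, patient, rb, date)))
}

#' @export
print.alert_screen <- function(x, ...) {
  if (length(x) == 0L) {
    cat("<alert screen: no alerts>\n")
    return(invisible(x))
  }
  cat(sprintf("<alert screen: %d alert(s)>\n", length(x)))
  for (a in x)
    cat(sprintf("  [%s] %-16s %-12s %s | %s\n", a$severity, a$rule_id,
                a$family, a$candidate_product, a$risk_text))
  invisible(x)
}
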