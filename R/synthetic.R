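# Seeded generator of synthetic ambulatory cohorts and prescription-episode
# streams with planted MRP conflicts, plus a stochastic prescriber
# acceptance model. Planted conflicts are single-family by construction on
# the orthogonal demo content, which makes exact per-family sensitivity and
# specificity measurable. Draw order is documented: the population uses the
# substream seeded with `seed`, the episode stream the substream seeded
# with `seed + 1`.

# Per-family defaults reproduce the deployment-scale conditions of the
# published three-year audit: one alerting episode per 15 new
# prescriptions, family mix proportional to the published family totals,
# and per-family acceptance probabilities equal to the published cumulative
# acceptance rates.
.FAMILY_TOTALS <- c(interactions = 1691886, duplications = 1436721,
                    geriatrics = 441920, aemps = 229612,
                    contra_health = 208365, teratogens = 34063,
                    anticholinergics = 6867, hypersensitivity = 254834,
                    adr = 75598)

.DEFAULT_ACCEPTANCE <- c(interactions = 0.25, duplications = 0.30,
                         geriatrics = 0.28, aemps = 0.26,
                         contra_health = 0.30, teratogens = 0.34,
                         anticholinergics = 0.31, hypersensitivity = 0.35,
                         adr = 0.29)

#' Simulation configuration
#'
#' Defaults emulate the reference deployment conditions: one alerting
#' episode per 15 prescriptions (planted family mix proportional to the
#' published family totals, the rest "none"), published per-family
#' acceptance probabilities, a fifth of the cohort aged 75 or over, and a
#' 3% pregnancy rate among women of childbearing age.
#'
#' @param seed integer seed driving every random draw
#' @param n_patients cohort size; must be >= n_episodes (each planted
#'   episode constructs the state of its own patient)
#' @param n_episodes number of candidate prescribing episodes
#' @param age_mix fraction of the cohort aged >= 75
#' @param pregnancy_rate pregnancy probability among women aged 18-45
#' @param planted_mix named probabilities over the nine alert families plus
#'   "none"; must sum to 1
#' @param acceptance_probs named per-family probability that the prescriber
#'   abandons the candidate (outcome "not_prescribed")
#' @param modified_prob probability that a non-abandoned alerted episode is
#'   logged as "prescribed_modified" (dose reduced / follow-up ordered but
#'   drug issued - counted as not accepted)
#' @param start_date,end_date episode date window
#' @export
sim_config <- function(seed = 1L, n_patients = 1000L, n_episodes = n_patients,
                       age_mix = 0.2, pregnancy_rate = 0.03,
                       planted_mix = NULL, acceptance_probs = NULL,
                       modified_prob = 0.1,
                       start_date = "2016-01-01", end_date = "2018-12-31") {
  if (is.null(planted_mix)) {
    fam <- .FAMILY_TOTALS / sum(.FAMILY_TOTALS) / 15
    planted_mix <- c(fam, none = 1 - sum(fam))
  }
  if (is.null(acceptance_probs)) acceptance_probs <- .DEFAULT_ACCEPTANCE
  fams <- names(.FAMILY_TOTALS)
  if (!setequal(names(planted_mix), c(fams, "none")))
    abort_fmt("planted_mix must be named over the nine families plus 'none'")
  if (abs(sum(planted_mix) - 1) > 1e-8)
    abort_fmt("planted_mix probabilities must sum to 1 (got %g)", sum(planted_mix))
  if (any(planted_mix < 0) || any(acceptance_probs < 0) || any(acceptance_probs > 1))
    abort_fmt("probabilities must lie in [0, 1]")
  if (!setequal(names(acceptance_probs), fams))
    abort_fmt("acceptance_probs must be named over the nine families")
  if (modified_prob < 0 || modified_prob > 1) abort_fmt("modified_prob must lie in [0, 1]")
  if (age_mix < 0 || age_mix > 1) abort_fmt("age_mix must lie in [0, 1]")
  if (n_episodes > n_patients)
    abort_fmt("n_patients (%d) must be >= n_episodes (%d)", n_patients, n_episodes)
  structure(list(seed = as.integer(seed), n_patients = as.integer(n_patients),
                 n_episodes = as.integer(n_episodes), age_mix = age_mix,
                 pregnancy_rate = pregnancy_rate,
                 planted_mix = planted_mix[c(fams, "none")],
                 acceptance_probs = acceptance_probs[fams],
                 modified_prob = modified_prob,
                 start_date = as_iso_date(start_date),
                 end_date = as_iso_date(end_date)),
            class = "sim_config")
}

#' Read a simulation configuration from YAML
#' @export
read_sim_config <- function(path) {
  x <- yaml::read_yaml(path)
  do.call(sim_config, x[intersect(names(x), names(formals(sim_config)))])
}

# Draw a birth date giving a completed age of exactly `age` years at `ref`:
# the anniversary minus a uniform 0-364 day offset. A Feb 29 reference maps
# to Feb 28 so the anniversary always exists.
.birth_for_age <- function(ref, age) {
  md <- format(ref, "-%m-%d")
  if (md == "-02-29") md <- "-02-28"
  anniv <- as.Date(paste0(as.integer(format(ref, "%Y")) - age, md))
  anniv - sample.int(365L, 1L) + 1L
}

#' Generate a synthetic ambulatory cohort
#'
#' Demographics only (no prescriptions or clinical state): ages 18-74 or,
#' with probability `age_mix`, 75-94 at the midpoint of the episode window;
#' pregnancy only in women aged 18-45. Deterministic under the seed.
#' @export
generate_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  ref <- config$start_date + floor(as.numeric(config$end_date - config$start_date) / 2)
  lapply(seq_len(config$n_patients), function(i) {
    elderly <- stats::runif(1) < config$age_mix
    age <- if (elderly) 75L + sample.int(20L, 1L) - 1L else 18L + sample.int(57L, 1L) - 1L
    sex <- if (stats::runif(1) < 0.5) "F" else "M"
    pregnant <- sex == "F" && age >= 18 && age <= 45 &&
      stats::runif(1) < config$pregnancy_rate
    patient_record(sprintf("P%06d", i), .birth_for_age(ref, age), sex, pregnant)
  })
}

# Planting recipes: for each family, one or more (candidate, patient-state)
# constructions guaranteed on the demo content to raise exactly that family
# and nothing else. age_class: "adult" -> 40-70, "elderly" -> 75-94,
# "pregnant" -> F 20-40 pregnant.
.PLANT_RECIPES <- list(
  interactions = list(
    list(candidate = "ibuprofen", comeds = "acetylsalicylic_acid", rule = "I-NSAID-ASA"),
    list(candidate = "amlodipine", comeds = "simvastatin", rule = "I-CCB-STATIN"),
    list(candidate = "simvastatin", comeds = "amlodipine", rule = "I-CCB-STATIN"),
    list(candidate = "citalopram", comeds = "tramadol_paracetamol", rule = "I-TRAMADOL-SSRI"),
    list(candidate = "enoxaparin", comeds = "acetylsalicylic_acid", rule = "I-HEPARIN-ASA")),
  duplications = list(
    list(candidate = "omeprazole", comeds = "omeprazole", rule = "DUP-SAME-INGREDIENT"),
    list(candidate = "ibuprofen", comeds = "naproxen", rule = "D-NSAID"),
    list(candidate = "amoxicillin_clavulanate", comeds = "amoxicillin", rule = "D-ANTIBIOTIC"),
    list(candidate = "enalapril", comeds = "enalapril", rule = "DUP-SAME-INGREDIENT")),
  aemps = list(
    list(candidate = "naproxen", comeds = c("enalapril", "furosemide"),
         rule = "A-TRIPLE-WHAMMY"),
    list(candidate = "ibuprofen", comeds = c("enalapril", "hydrochlorothiazide"),
         rule = "A-TRIPLE-WHAMMY")),
  geriatrics = list(
    list(candidate = "alprazolam", age_class = "elderly", rule = "G-BENZO"),
    list(candidate = "dexketoprofen", age_class = "elderly", rule = "G-NSAID"),
    list(candidate = "doxazosin", age_class = "elderly", rule = "G-ANTIHYPERT"),
    list(candidate = "zolpidem", age_class = "elderly", rule = "G-BENZO")),
  contra_health = list(
    list(candidate = "ibuprofen", problems = "N18.3", rule = "PC-NSAID-CKD"),
    list(candidate = "dexketoprofen", measurements = list(list(label = "eGFR", value = 25)),
         rule = "CV-NSAID-EGFR")),
  teratogens = list(
    list(candidate = "ibuprofen", age_class = "pregnant", rule = "T-NSAID-PREG"),
    list(candidate = "acetylsalicylic_acid", age_class = "pregnant", rule = "T-NSAID-PREG")),
  anticholinergics = list(
    list(candidate = "hydroxyzine", comeds = "oxybutynin", rule = "AC-DEMO"),
    list(candidate = "oxybutynin", comeds = "cyclobenzaprine", rule = "AC-DEMO")),
  hypersensitivity = list(
    list(candidate = "ibuprofen",
         sensitivities = list(list(kind = "suspected_hypersensitivity", target = "XR_NSAIDS")),
         rule = "S-HS-NSAID"),
    list(candidate = "amoxicillin_clavulanate",
         sensitivities = list(list(kind = "suspected_hypersensitivity",
                                   target = "ANTIBIOTICS_BETALACTAM")),
         rule = "S-HS-BETALACTAM")),
  adr = list(
    list(candidate = "sertraline",
         sensitivities = list(list(kind = "adverse_drug_reaction", target = "SSRI")),
         rule = "S-ADR-SSRI"),
    list(candidate = "ibuprofen",
         sensitivities = list(list(kind = "adverse_drug_reaction", target = "XR_NSAIDS")),
         rule = "S-ADR-NSAID")),
  none = list(
    list(candidate = "paracetamol"),
    list(candidate = "paracetamol", comeds = "simvastatin"),
    list(candidate = "enalapril", comeds = "omeprazole"),
    list(candidate = "omeprazole")))

.plant_patient <- function(base, recipe, date) {
  age_class <- recipe$age_class %||% "adult"
  age <- switch(age_class,
                adult = 40L + sample.int(31L, 1L) - 1L,
                elderly = 75L + sample.int(20L, 1L) - 1L,
                pregnant = 20L + sample.int(21L, 1L) - 1L)
  sex <- if (age_class == "pregnant") "F" else base$sex
  comeds <- recipe$comeds %||% character(0)
  patient_record(
    patient_id = base$patient_id,
    birth_date = .birth_for_age(as_iso_date(date), age),
    sex = sex,
    pregnant = age_class == "pregnant",
    prescriptions = lapply(seq_along(comeds), function(j)
      prescription(sprintf("%s-rx%d", base$patient_id, j), comeds[j],
                   start_date = as_iso_date(date) - 120L)),
    problems = lapply(recipe$problems %||% character(0), function(code)
      list(code = code, onset = format(as_iso_date(date) - 400L))),
    measurements = lapply(recipe$measurements %||% list(), function(m)
      clinical_measurement(m$label, m$value, as_iso_date(date) - 30L)),
    sensitivities = lapply(recipe$sensitivities %||% list(), function(s)
      sensitivity_record(s$kind, s$target, as_iso_date(date) - 500L)))
}

#' Generate a prescription-episode stream with planted conflicts
#'
#' For each episode a family (or "none") is drawn from `planted_mix`, a
#' recipe of that family is drawn, and the episode's patient state is
#' constructed to guarantee exactly that conflict. The prescriber outcome
#' is drawn from the acceptance model: `not_prescribed` with the family's
#' acceptance probability, otherwise `prescribed_modified` with
#' `modified_prob` or plain `prescribed`; "none" episodes are conflict-free
#' by construction and logged as prescribed.
#'
#' @return a list with elements `patients` (cohort with episode states
#'   installed), `episodes`, `truth` (data frame event_id / family /
#'   rule_id, family "none" for clean episodes) and `outcomes` (data frame
#'   event_id / outcome)
#' @export
generate_episode_stream <- function(config, population, rb) {
  stopifnot(inherits(config, "sim_config"), inherits(rb, "rulebase"))
  if (length(population) < config$n_episodes)
    abort_fmt("population (%d) smaller than n_episodes (%d)",
              length(population), config$n_episodes)
  planted_fams <- names(config$planted_mix)[config$planted_mix > 0]
  for (fam in setdiff(intersect(planted_fams, names(.PLANT_RECIPES)), "none")) {
    rules <- unlist(lapply(.PLANT_RECIPES[[fam]], `[[`, "rule"))
    known <- c(unlist(lapply(unlist(rb$rules, recursive = FALSE), `[[`, "rule_id")),
               "DUP-SAME-INGREDIENT")
    if (!all(rules %in% known))
      abort_fmt("rulebase lacks demo content for family '%s'", fam)
  }
  set.seed(config$seed + 1L)
  n <- config$n_episodes
  fams <- sample(names(config$planted_mix), n, replace = TRUE,
                 prob = config$planted_mix)
  span <- as.integer(config$end_date - config$start_date)
  dates <- config$start_date + sample.int(span + 1L, n, replace = TRUE) - 1L
  patients <- population
  episodes <- vector("list", n)
  truth <- vector("list", n)
  outcomes <- vector("list", n)
  for (i in seq_len(n)) {
    fam <- fams[i]
    recipes <- .PLANT_RECIPES[[fam]]
    recipe <- recipes[[sample.int(length(recipes), 1L)]]
    date <- dates[i]
    eid <- sprintf("E%06d", i)
    patients[[i]] <- .plant_patient(population[[i]], recipe, date)
    episodes[[i]] <- list(event_id = eid, patient_id = patients[[i]]$patient_id,
                          product_id = recipe$candidate,
                          daily_dose = NA_real_, dose_unit = NA_character_,
                          date = format(date))
    outcome <- if (fam == "none") "prescribed"
    else if (stats::runif(1) < config$acceptance_probs[[fam]]) "not_prescribed"
    else if (stats::runif(1) < config$modified_prob) "prescribed_modified"
    else "prescribed"
    truth[[i]] <- data.frame(event_id = eid, family = fam,
                             rule_id = recipe$rule %||% NA_character_,
                             stringsAsFactors = FALSE)
    outcomes[[i]] <- data.frame(event_id = eid, outcome = outcome,
                                stringsAsFactors = FALSE)
  }
  list(patients = patients, episodes = episodes,
       truth = do.call(rbind, truth), outcomes = do.call(rbind, outcomes))
}

#' Compare engine output with planted ground truth
#'
#' Per family: planted episode count, detected count (planted episodes
#' whose screen raised the family), misses, and false positives (episodes
#' raising a family that was not planted). `attr(result, "exact")` is TRUE
#' iff there are no misses and no false positives anywhere and every "none"
#' episode raised nothing.
#' @export
evaluate_recovery <- function(events, truth) {
  ev_ids <- vapply(events, `[[`, character(1), "event_id")
  if (!setequal(ev_ids, truth$event_id))
    abort_fmt("event ids do not align with truth (%d events vs %d truth rows)",
              length(ev_ids), nrow(truth))
  detected <- lapply(events, function(e)
    unique(vapply(e$alerts, `[[`, character(1), "family")))
  names(detected) <- ev_ids
  fams <- names(.FAMILY_TOTALS)
  out <- do.call(rbind, lapply(fams, function(f) {
    planted_ids <- truth$event_id[truth$family == f]
    hit <- sum(vapply(planted_ids, function(id) f %in% detected[[id]], logical(1)))
    fp <- sum(vapply(setdiff(ev_ids, planted_ids), function(id)
      f %in% detected[[id]], logical(1)))
    data.frame(family = f, planted = length(planted_ids), detected = hit,
               missed = length(planted_ids) - hit, false_positives = fp,
               stringsAsFactors = FALSE)
  }))
  none_ids <- truth$event_id[truth$family == "none"]
  clean <- sum(vapply(none_ids, function(id) length(detected[[id]]) == 0L, logical(1)))
  attr(out, "none_planted") <- length(none_ids)
  attr(out, "none_clean") <- clean
  attr(out, "exact") <- all(out$missed == 0L) && all(out$false_positives == 0L) &&
    clean == length(none_ids)
  out
}
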