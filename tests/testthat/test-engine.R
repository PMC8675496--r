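test_that("a healthy patient with no active medication gets an empty screen", {
  rb <- demo_rb()
  s <- evaluate("paracetamol", healthy_patient(), rb, "2018-06-01")
  expect_s3_class(s, "alert_screen")
  expect_length(s, 0L)
  expect_error(evaluate("unobtainium", healthy_patient(), rb, "2018-06-01"),
               "unknown product")
})

test_that("an elderly patient on ASA + RAS inhibitor + diuretic triggers a composite screen", {
  rb <- demo_rb()
  p <- patient_record("G1", "1938-03-10", "M", prescriptions = list(
    rx_on("acetylsalicylic_acid"), rx_on("enalapril"), rx_on("furosemide")))
  s <- evaluate("ibuprofen", p, rb, "2018-06-01")
  expect_gte(length(s), 3L)
  rules <- vapply(s, `[[`, character(1), "rule_id")
  expect_true(all(c("A-TRIPLE-WHAMMY", "I-NSAID-ASA", "G-NSAID") %in% rules))
  sev <- vapply(s, `[[`, character(1), "severity")
  expect_true(all(which(sev == "RED") < which(sev == "ORANGE")))
})

test_that("interactions attribute through combination products at ingredient level", {
  rb <- demo_rb()
  p <- patient_record("C1", "1970-01-01", "F",
                      prescriptions = list(rx_on("tramadol_paracetamol")))
  alerts <- check_interactions("citalopram", p, rb, "2018-06-01")
  expect_length(alerts, 1L)
  expect_identical(alerts[[1]]$rule_id, "I-TRAMADOL-SSRI")
  expect_identical(alerts[[1]]$conflicting_id, "tramadol_paracetamol")
  expect_length(check_interactions("citalopram", healthy_patient(), rb, "2018-06-01"), 0L)
})

test_that("duplications fire on shared ingredients and on configured groups", {
  rb <- demo_rb()
  d <- "2018-06-01"
  p_par <- patient_record("D1", "1970-01-01", "M",
                          prescriptions = list(rx_on("paracetamol")))
  a1 <- check_duplications("tramadol_paracetamol", p_par, rb, d)
  expect_true("DUP-SAME-INGREDIENT" %in% vapply(a1, `[[`, character(1), "rule_id"))
  p_ome <- patient_record("D2", "1970-01-01", "M",
                          prescriptions = list(rx_on("omeprazole")))
  a2 <- check_duplications("omeprazole", p_ome, rb, d)
  expect_gte(length(a2), 1L)
  p_amx <- patient_record("D3", "1970-01-01", "M",
                          prescriptions = list(rx_on("amoxicillin")))
  a3 <- check_duplications("amoxicillin_clavulanate", p_amx, rb, d)
  ids <- vapply(a3, `[[`, character(1), "rule_id")
  expect_true("D-ANTIBIOTIC" %in% ids)
  grp <- a3[[which(ids == "D-ANTIBIOTIC")]]
  expect_identical(grp$subtype, "dose_adjustment")
})

test_that("the Triple Whammy fires exactly when both co-medication classes are covered", {
  rb <- demo_rb()
  d <- "2018-06-01"
  pool <- c(ras = "enalapril", diuretic = "furosemide", nsaid = "naproxen")
  for (mask in 0:7) {
    active <- pool[c(bitwAnd(mask, 1) > 0, bitwAnd(mask, 2) > 0, bitwAnd(mask, 4) > 0)]
    p <- patient_record("TW", "1970-01-01", "M",
                        prescriptions = lapply(active, rx_on))
    fired <- "A-TRIPLE-WHAMMY" %in% vapply(check_aemps("ibuprofen", p, rb, d),
                                           `[[`, character(1), "rule_id")
    expect_identical(fired, all(c("enalapril", "furosemide") %in% active),
                     info = paste("active:", paste(active, collapse = "+")))
  }
})

test_that("geriatric alerts fire at completed age 75 and never below", {
  rb <- demo_rb()
  d <- as.Date("2018-06-01")
  drugs <- c("alprazolam", "dexketoprofen", "doxazosin", "oxybutynin", "paracetamol")
  geri_groups <- lapply(rb$rules$geriatrics, function(r) rb$drug_groups[[r$group]])
  for (age in 70:80) {
    p <- patient_record("A", d - 1L - round(age * 365.25) - 100L, "M")
    p$birth_date <- as.Date(paste0(2018 - age, "-06-01"))  # exact anniversary
    for (drug in drugs) {
      fired <- length(check_geriatrics(drug, p, rb, d)) > 0L
      in_any <- any(vapply(geri_groups, function(g)
        product_in_group(rb$formulary[[drug]], g), logical(1)))
      expect_identical(fired, age >= 75 && in_any,
                       info = sprintf("age %d drug %s", age, drug))
    }
  }
})

test_that("clinical-variable rules compare strictly and skip missing or stale data", {
  rb <- demo_rb()
  d <- as.Date("2018-06-01")
  mk <- function(value, when = d - 20) patient_record("CV", "1970-01-01", "M",
    measurements = list(clinical_measurement("eGFR", value, when)))
  expect_length(check_clinical_variables("dexketoprofen", mk(25), rb, d), 1L)
  expect_length(check_clinical_variables("dexketoprofen", mk(30), rb, d), 0L)
  expect_length(check_clinical_variables("dexketoprofen", healthy_patient(), rb, d), 0L)
  expect_length(check_clinical_variables("dexketoprofen", mk(25, d - 400), rb, d), 0L)
})

test_that("regulatory dose thresholds need a known dose in the rule's unit", {
  rb <- demo_rb()
  d <- "2018-06-01"
  p <- healthy_patient()
  fire <- function(dose, unit) length(check_aemps(
    list(product_id = "citalopram", daily_dose = dose, dose_unit = unit), p, rb, d))
  expect_identical(fire(60, "mg"), 1L)
  expect_identical(fire(40, "mg"), 0L)   # strict > threshold
  expect_identical(fire(NA_real_, NA_character_), 0L)
  expect_identical(fire(60, "tablets"), 0L)
})

test_that("teratogen alerts require the pregnancy flag and group membership", {
  rb <- demo_rb()
  d <- "2018-06-01"
  preg <- patient_record("T1", "1990-01-01", "F", pregnant = TRUE)
  a <- check_teratogens("ibuprofen", preg, rb, d)
  expect_length(a, 1L)
  expect_identical(a[[1]]$severity, "RED")
  expect_length(check_teratogens("ibuprofen", healthy_patient(), rb, d), 0L)
  expect_length(check_teratogens("sertraline", preg, rb, d), 0L)
})

test_that("anticholinergic combinations respect the concomitant-member threshold", {
  rb <- demo_rb()
  d <- "2018-06-01"
  p1 <- patient_record("AC", "1970-01-01", "M",
                       prescriptions = list(rx_on("oxybutynin")))
  expect_length(check_anticholinergics("hydroxyzine", p1, rb, d), 1L)
  expect_length(check_anticholinergics("hydroxyzine", healthy_patient(), rb, d), 0L)
  rb2 <- rb
  rb2$rules$anticholinergics[[1]]$min_concomitant <- 2
  expect_length(check_anticholinergics("hydroxyzine", p1, rb2, d), 0L)
  p2 <- patient_record("AC2", "1970-01-01", "M", prescriptions = list(
    rx_on("oxybutynin"), rx_on("cyclobenzaprine")))
  expect_length(check_anticholinergics("hydroxyzine", p2, rb2, d), 1L)
})

test_that("hypersensitivity and ADR history resolve targets through cross-reactivity groups", {
  rb <- demo_rb()
  d <- "2018-06-01"
  hs <- function(target, kind = "suspected_hypersensitivity")
    patient_record("H", "1970-01-01", "M",
                   sensitivities = list(sensitivity_record(kind, target, "2015-01-01")))
  expect_length(check_hypersensitivity("ibuprofen", hs("XR_NSAIDS"), rb, d), 1L)
  # ingredient-level target resolves into the group
  expect_length(check_hypersensitivity("ibuprofen", hs("naproxen"), rb, d), 1L)
  expect_length(check_hypersensitivity("amoxicillin_clavulanate",
                                       hs("ANTIBIOTICS_BETALACTAM"), rb, d), 1L)
  expect_length(check_hypersensitivity("ibuprofen", healthy_patient(), rb, d), 0L)
  # kinds do not cross over
  expect_length(check_hypersensitivity("ibuprofen",
                                       hs("XR_NSAIDS", "adverse_drug_reaction"), rb, d), 0L)
  expect_length(check_adr("sertraline", hs("SSRI", "adverse_drug_reaction"), rb, d), 1L)
})

test_that("screen assembly deduplicates and imposes a total deterministic order", {
  rb <- demo_rb()
  p <- patient_record("S1", "1938-01-01", "F", pregnant = FALSE,
                      prescriptions = list(rx_on("acetylsalicylic_acid"),
                                           rx_on("enalapril"), rx_on("furosemide")))
  alerts <- c(check_aemps("ibuprofen", p, rb, "2018-06-01"),
              check_interactions("ibuprofen", p, rb, "2018-06-01"),
              check_geriatrics("ibuprofen", p, rb, "2018-06-01"))
  dup <- assemble_screen(c(alerts, alerts, rev(alerts)))
  expect_identical(screen_keys(dup), screen_keys(assemble_screen(alerts)))
  set.seed(99)
  for (i in 1:10) {
    perm <- assemble_screen(sample(alerts))
    expect_identical(screen_keys(perm), screen_keys(assemble_screen(alerts)))
  }
  sev <- vapply(assemble_screen(alerts), `[[`, character(1), "severity")
  expect_true(!is.unsorted(match(sev, c("RED", "ORANGE"))))
})

test_that("evaluation equals the union of the family checkers on random fixtures", {
  rb <- demo_rb()
  d <- "2017-06-15"
  set.seed(314)
  for (i in 1:200) {
    p <- random_patient(rb)
    cand <- random_candidate(rb)
    s <- evaluate(cand, p, rb, d)
    union <- assemble_screen(c(
      check_aemps(cand, p, rb, d), check_interactions(cand, p, rb, d),
      check_duplications(cand, p, rb, d),
      check_problem_contraindications(cand, p, rb, d),
      check_clinical_variables(cand, p, rb, d),
      check_teratogens(cand, p, rb, d), check_geriatrics(cand, p, rb, d),
      check_anticholinergics(cand, p, rb, d),
      check_hypersensitivity(cand, p, rb, d), check_adr(cand, p, rb, d)))
    expect_identical(screen_keys(s), screen_keys(union))
    expect_identical(screen_keys(evaluate(cand, p, rb, d)), screen_keys(s))
  }
})

test_that("adding a co-prescription never removes interaction, duplication or regulatory alerts", {
  rb <- demo_rb()
  d <- "2017-06-15"
  set.seed(271)
  mono_fams <- c("interactions", "duplications", "aemps")
  for (i in 1:100) {
    p <- random_patient(rb)
    cand <- random_candidate(rb)
    before <- evaluate(cand, p, rb, d)
    extra <- sample(names(rb$formulary), 1L)
    p2 <- p
    p2$prescriptions <- c(p2$prescriptions,
                          list(prescription("rx-extra", extra, start_date = "2016-01-01")))
    after <- evaluate(cand, p2, rb, d)
    keys_f <- function(s) screen_keys(s)[vapply(s, `[[`, character(1), "family")
                                         %in% mono_fams]
    expect_true(all(keys_f(before) %in% keys_f(after)))
  }
})
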