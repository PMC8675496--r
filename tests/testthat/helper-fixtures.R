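# Shared fixtures: the demo rulebase is loaded once per test run, and
# random patients/candidates are built in code under the caller's seed.

demo_rb <- local({
  rb <- NULL
  function() {
    if (is.null(rb)) rb <<- demo_rulebase()
    rb
  }
})

healthy_patient <- function(id = "P1", birth = "1980-04-05", sex = "M") {
  patient_record(id, birth, sex)
}

rx_on <- function(product_id, start = "2017-01-01", ...) {
  prescription(paste0("rx-", product_id), product_id, start_date = start, ...)
}

# A random but valid ATC code at a random level.
random_atc <- function() {
  lvl <- sample(c(1L, 3L, 4L, 5L, 7L), 1L)
  chars <- c(sample(LETTERS, 1L), sample(0:9, 1L), sample(0:9, 1L),
             sample(LETTERS, 1L), sample(LETTERS, 1L),
             sample(0:9, 1L), sample(0:9, 1L))
  paste(chars[seq_len(lvl)], collapse = "")
}

# A random patient over the demo formulary; clinically arbitrary on
# purpose (any family can fire).
random_patient <- function(rb, id = "R1", date = as.Date("2017-06-15")) {
  age <- sample(20:90, 1L)
  sex <- sample(c("F", "M"), 1L)
  pregnant <- sex == "F" && age < 50 && stats::runif(1) < 0.3
  n_rx <- sample(0:4, 1L)
  prods <- sample(names(rb$formulary), n_rx)
  problems <- sample(c("N18.3", "I25.9", "K70.0", "G20", "I80.2"),
                     sample(0:2, 1L))
  meas <- list()
  if (stats::runif(1) < 0.4)
    meas <- c(meas, list(clinical_measurement("eGFR", stats::runif(1, 10, 90),
                                              date - sample(1:400, 1L))))
  if (stats::runif(1) < 0.3)
    meas <- c(meas, list(clinical_measurement("potassium", stats::runif(1, 3.0, 6.5),
                                              date - sample(1:400, 1L))))
  sens <- list()
  if (stats::runif(1) < 0.3)
    sens <- list(sensitivity_record(
      sample(c("suspected_hypersensitivity", "adverse_drug_reaction"), 1L),
      sample(c("XR_NSAIDS", "ANTIBIOTICS_BETALACTAM", "SSRI", "naproxen"), 1L),
      date - 500L))
  patient_record(
    id, format(date - round(age * 365.25) - sample(0:200, 1L)), sex, pregnant,
    prescriptions = lapply(prods, function(p)
      prescription(paste0("rx-", p), p, start_date = date - sample(1:300, 1L))),
    problems = lapply(problems, function(code) list(code = code)),
    measurements = meas, sensitivities = sens)
}

random_candidate <- function(rb) {
  cand <- list(product_id = sample(names(rb$formulary), 1L))
  if (stats::runif(1) < 0.2) {
    cand$daily_dose <- sample(c(10, 20, 30, 50, 100), 1L)
    cand$dose_unit <- "mg"
  }
  cand
}

screen_keys <- function(screen)
  vapply(screen, function(a) paste(a$rule_id, a$conflicting_type,
                                   a$conflicting_id, sep = "|"), character(1))

run_stream <- function(cfg, rb = demo_rb()) {
  pop <- generate_population(cfg)
  st <- generate_episode_stream(cfg, pop, rb)
  st$events <- lapply(seq_along(st$episodes), function(i) {
    ep <- st$episodes[[i]]
    record_episode(ep$product_id,
                   evaluate(ep$product_id, st$patients[[i]], rb, ep$date),
                   st$outcomes$outcome[i], ep$date, ep$patient_id,
                   event_id = ep$event_id)
  })
  st
}
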