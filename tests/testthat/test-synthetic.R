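test_that("identical configurations reproduce byte-identical streams", {
  rb <- demo_rb()
  cfg <- sim_config(seed = 77, n_patients = 120, n_episodes = 120)
  s1 <- generate_episode_stream(cfg, generate_population(cfg), rb)
  s2 <- generate_episode_stream(cfg, generate_population(cfg), rb)
  ser <- function(st) jsonlite::toJSON(
    list(p = lapply(st$patients, rxscreen:::patient_to_list), e = st$episodes,
         t = st$truth, o = st$outcomes), auto_unbox = TRUE, digits = NA)
  expect_identical(as.character(ser(s1)), as.character(ser(s2)))
  s3 <- generate_episode_stream(sim_config(seed = 78, n_patients = 120,
                                           n_episodes = 120),
                                generate_population(cfg), rb)
  expect_false(identical(as.character(ser(s1)), as.character(ser(s3))))
})

test_that("population age structure follows the configured elderly fraction", {
  cfg0 <- sim_config(seed = 3, n_patients = 200, age_mix = 0)
  pop0 <- generate_population(cfg0)
  ref <- as.Date("2017-07-01")
  ages0 <- vapply(pop0, age_at, integer(1), date = ref)
  expect_true(all(ages0 < 75))
  cfg <- sim_config(seed = 4, n_patients = 5000, age_mix = 0.2)
  pop <- generate_population(cfg)
  ages <- vapply(pop, age_at, integer(1), date = ref)
  n75 <- sum(ages >= 75)
  expect_gte(n75, stats::qbinom(0.005, 5000, 0.2))
  expect_lte(n75, stats::qbinom(0.995, 5000, 0.2))
  # pregnancy only in women of childbearing age
  for (p in pop[vapply(pop, `[[`, logical(1), "pregnant")]) {
    expect_identical(p$sex, "F")
    expect_lt(age_at(p, ref), 50L)
  }
})

test_that("degenerate planted mixes produce the promised extreme streams", {
  rb <- demo_rb()
  fams <- setdiff(names(rxscreen:::.PLANT_RECIPES), "none")
  none_mix <- stats::setNames(c(rep(0, length(fams)), 1), c(fams, "none"))
  cfg <- sim_config(seed = 21, n_patients = 80, n_episodes = 80,
                    planted_mix = none_mix)
  st <- run_stream(cfg)
  expect_true(all(vapply(st$events, function(e) length(e$alerts) == 0L, logical(1))))
  geri_mix <- stats::setNames(as.numeric(c(fams, "none") == "geriatrics"),
                              c(fams, "none"))
  cfg2 <- sim_config(seed = 22, n_patients = 80, n_episodes = 80,
                     planted_mix = geri_mix)
  st2 <- run_stream(cfg2)
  dates <- vapply(st2$episodes, `[[`, character(1), "date")
  ages <- mapply(function(p, d) age_at(p, d), st2$patients, dates)
  expect_true(all(ages >= 75))
  expect_true(all(vapply(st2$events, function(e)
    "geriatrics" %in% vapply(e$alerts, `[[`, character(1), "family"), logical(1))))
})

test_that("the engine recovers every planted conflict on orthogonal content", {
  cfg <- sim_config(seed = 55, n_patients = 600, n_episodes = 600)
  st <- run_stream(cfg)
  rec <- evaluate_recovery(st$events, st$truth)
  expect_true(all(rec$missed == 0L))
  expect_true(all(rec$false_positives == 0L))
  expect_true(attr(rec, "exact"))
  expect_identical(attr(rec, "none_clean"), attr(rec, "none_planted"))
})

test_that("disabling a family's rules converts its planted episodes into misses", {
  ablated <- demo_rb()
  ablated$rules$geriatrics <- list()
  fams <- setdiff(names(rxscreen:::.PLANT_RECIPES), "none")
  mix <- stats::setNames(c(rep(1 / 18, length(fams)), 0.5), c(fams, "none"))
  cfg <- sim_config(seed = 56, n_patients = 300, n_episodes = 300,
                    planted_mix = mix)
  pop <- generate_population(cfg)
  st <- generate_episode_stream(cfg, pop, demo_rb())
  st$events <- lapply(seq_along(st$episodes), function(i) {
    ep <- st$episodes[[i]]
    record_episode(ep$product_id,
                   evaluate(ep$product_id, st$patients[[i]], ablated, ep$date),
                   st$outcomes$outcome[i], ep$date, ep$patient_id,
                   event_id = ep$event_id)
  })
  rec <- evaluate_recovery(st$events, st$truth)
  g <- rec[rec$family == "geriatrics", ]
  expect_gt(g$planted, 0L)
  expect_identical(g$missed, g$planted)
  expect_false(attr(rec, "exact"))
  # empty stream: all zeros
  rec0 <- evaluate_recovery(list(), st$truth[0, ])
  expect_true(all(rec0$planted == 0L) && all(rec0$false_positives == 0L))
})

test_that("observed acceptance converges to the configured probabilities", {
  fams <- setdiff(names(rxscreen:::.PLANT_RECIPES), "none")
  mix <- stats::setNames(c(rep(0.1, 9), 0.1), c(fams, "none"))
  cfg <- sim_config(seed = 88, n_patients = 2000, n_episodes = 2000,
                    planted_mix = mix,
                    acceptance_probs = stats::setNames(rep(0.28, 9), fams))
  st <- run_stream(cfg)
  alerted <- Filter(function(e) length(e$alerts) > 0L, st$events)
  k <- sum(vapply(alerted, is_accepted, logical(1)))
  n <- length(alerted)
  expect_gte(k, stats::qbinom(0.005, n, 0.28))
  expect_lte(k, stats::qbinom(0.995, n, 0.28))
})

test_that("configuration invariants are enforced", {
  expect_error(sim_config(planted_mix = c(none = 0.5)), "named over")
  fams <- c("interactions", "duplications", "geriatrics", "aemps",
            "contra_health", "teratogens", "anticholinergics",
            "hypersensitivity", "adr")
  bad <- stats::setNames(c(rep(0.2, 9), 0.2), c(fams, "none"))
  expect_error(sim_config(planted_mix = bad), "sum to 1")
  expect_error(sim_config(n_patients = 10, n_episodes = 20), ">= n_episodes")
  expect_error(sim_config(modified_prob = 1.5), "modified_prob")
})
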