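test_that("source libraries are seeded, normalised and separation-sensitive", {
  lib <- generate_source_library(3, 8, separation = 1, seed = 42)
  expect_length(lib, 3)
  for (s in lib) {
    expect_equal(sum(s$means), 100, tolerance = 1e-9)
    expect_equal(s$space, "prey")
    expect_equal(unname(s$sds), unname(0.1 * s$means))
  }
  lib2 <- generate_source_library(3, 8, separation = 1, seed = 42)
  expect_identical(lapply(lib, `[[`, "means"), lapply(lib2, `[[`, "means"))
  expect_error(generate_source_library(3, 8, separation = 0), "> 0")
  expect_error(generate_source_library(1, 8), ">= 2")

  # mean pairwise divergence grows with separation
  div <- function(sep) {
    l <- generate_source_library(2, 10, separation = sep, seed = 7)
    mean(abs(l[[1]]$means - l[[2]]$means))
  }
  expect_gt(div(1.5), div(0.1))
})

test_that("strong separation is detected by PERMANOVA, none under the null", {
  lib <- generate_source_library(3, 8, separation = 1.5, seed = 3)
  profiles <- do.call(rbind, lapply(seq_along(lib), function(i)
    simulate_consumers_from_summary(lib[[i]]$means, lib[[i]]$sds,
                                    n = 8, seed = 100 + i)$fa))
  g <- rep(c("a", "b", "c"), each = 8)
  pw <- pairwise_permanova(profiles, g, n_permutations = 199, seed = 1)
  # minimal attainable p, up to a permutation that recreates the exact split
  expect_true(all(pw$p_raw <= 2 / 200))

  # separation near zero: sources indistinguishable
  lib0 <- generate_source_library(3, 8, separation = 1e-4, seed = 3)
  profiles0 <- do.call(rbind, lapply(seq_along(lib0), function(i)
    simulate_consumers_from_summary(lib0[[i]]$means, lib0[[i]]$sds,
                                    n = 8, seed = 100 + i)$fa))
  pw0 <- pairwise_permanova(profiles0, g, n_permutations = 199, seed = 1)
  expect_true(all(pw0$p_adj > 0.05))
})

test_that("synthetic CCs respect the redraw bound", {
  cc <- generate_cc_set(paste0("FA", 1:50), seed = 2, cc_max = 1.5)
  expect_true(all(cc$cc <= 1.5 & cc$cc > 0))
  expect_identical(generate_cc_set(paste0("FA", 1:50), seed = 2, cc_max = 1.5)$cc,
                   cc$cc)
})

test_that("turnover kinetics obey the closed-form endpoints", {
  lib <- generate_source_library(2, 6, separation = 1, seed = 5)
  cc <- generate_cc_set(fa_names(lib[[1]]), seed = 6)
  pred <- apply_ccs(lib, cc)
  target_init <- pred[[1]]$means
  target_new <- pred[[2]]$means

  # complete replacement in one day at lambda = 1
  sc1 <- trial_scenario(lib, cc,
    diet_schedule = list(list(duration = 30, diet = c(1, 0)),
                         list(duration = 10, diet = c(0, 1))),
    turnover_rate = 1, n_consumers = 2, noise_sd_scale = 0, seed = 1)
  expect_equal(expected_signature(sc1, 0), target_init, tolerance = 1e-12)
  expect_equal(expected_signature(sc1, 1), target_new, tolerance = 1e-12)

  # no turnover: frozen at the acclimation equilibrium
  sc0 <- trial_scenario(lib, cc,
    diet_schedule = list(list(duration = 30, diet = c(1, 0)),
                         list(duration = 10, diet = c(0, 1))),
    turnover_rate = 0, n_consumers = 2, noise_sd_scale = 0, seed = 1)
  expect_equal(expected_signature(sc0, 10), target_init, tolerance = 1e-12)

  # geometric approach: remaining fraction (1 - lambda)^t
  lam <- 0.2
  scl <- trial_scenario(lib, cc,
    diet_schedule = list(list(duration = 30, diet = c(1, 0)),
                         list(duration = 20, diet = c(0, 1))),
    turnover_rate = lam, n_consumers = 2, noise_sd_scale = 0, seed = 1)
  s5 <- expected_signature(scl, 5)
  expect_equal(s5, (1 - lam)^5 * target_init + (1 - (1 - lam)^5) * target_new,
               tolerance = 1e-12)
})

test_that("lower deposition keeps the signature closer to the start", {
  lib <- generate_source_library(2, 6, separation = 1, seed = 5)
  cc <- generate_cc_set(fa_names(lib[[1]]), seed = 6)
  sched <- list(list(duration = 30, diet = c(1, 0)),
                list(duration = 30, diet = c(0, 1)))
  sig_at <- function(dep) {
    sc <- trial_scenario(lib, cc, diet_schedule = sched, turnover_rate = 0.2,
                         deposition_fraction = dep, n_consumers = 2,
                         noise_sd_scale = 0, seed = 1)
    expected_signature(sc, 30)
  }
  init <- expected_signature(
    trial_scenario(lib, cc, diet_schedule = sched, turnover_rate = 0.2,
                   n_consumers = 2, noise_sd_scale = 0, seed = 1), 0)
  d25 <- sum(abs(sig_at(0.25) - init))
  d50 <- sum(abs(sig_at(0.5) - init))
  d100 <- sum(abs(sig_at(1) - init))
  expect_true(d25 < d50 && d50 < d100)
})

test_that("noise-free signatures stay in the convex hull of the diet targets", {
  sc <- scenario_preset("eider_switch")
  sc$noise_sd_scale <- 0
  pred <- apply_ccs(sc$sources, sc$true_cc)
  targets <- vapply(sc$diet_schedule, function(e)
    Reduce(`+`, Map(function(s, w) w * s$means, pred, as.list(e$diet))),
    numeric(length(fa_names(pred[[1]]))))
  lo <- apply(targets, 1, min)
  hi <- apply(targets, 1, max)
  for (d in c(0, 10, 21, 35, 50)) {
    s <- expected_signature(sc, d)
    expect_true(all(s >= lo - 1e-9 & s <= hi + 1e-9))
  }
})

test_that("cohort simulation is seeded and labelled", {
  sc <- scenario_preset("harpseal_lowfat")
  a <- simulate_consumer_signature(sc, 14)
  b <- simulate_consumer_signature(sc, 14)
  expect_identical(a$fa, b$fa)
  expect_equal(unique(a$factors$day), "14")
  expect_equal(nrow(a$fa), 5)
  expect_error(simulate_consumer_signature(sc, 31), "beyond the schedule")
  expect_error(expected_signature(sc, -1), "before schedule start")
})

test_that("presets transcribe the trial designs", {
  e <- scenario_preset("eider_switch")
  expect_equal(e$diet_schedule[[1]]$diet, c(0.01, 0.03, 0.88, 0.04, 0.04))
  expect_equal(e$diet_schedule[[2]]$diet, c(0, 0.56, 0.44, 0, 0))
  expect_equal(e$diet_schedule[[2]]$duration, 21)
  expect_equal(e$diet_schedule[[3]]$diet, c(0, 0, 0.48, 0, 0.52))
  expect_equal(e$n_consumers, 8)
  expect_equal(vapply(e$sources, `[[`, character(1), "source_name"),
               c("clam", "krill", "mazuri", "mussel", "silverside"))

  s <- scenario_preset("salmon_cc")
  expect_named(s, c("herring", "krill", "h70k30", "h30k70"))
  expect_equal(s$h70k30$diet_schedule[[1]]$diet, c(0.7, 0.3))
  expect_equal(vapply(s, `[[`, numeric(1), "n_consumers"),
               c(herring = 36, krill = 28, h70k30 = 34, h30k70 = 34))

  p <- scenario_preset("puffin_priors")
  w <- attr(p, "prior_weights")
  expect_equal(unname(w["sandlance"]), 0.72)
  expect_equal(sum(w), 1)
  expect_equal(p$diet_schedule[[2]]$diet[6], 1)  # herring-only phase

  h <- scenario_preset("harpseal_lowfat")
  expect_equal(h$deposition_fraction, 0.25)
  expect_equal(h$n_consumers, 5)

  hs <- scenario_preset("harbourseal_groups")
  expect_equal(vapply(hs, `[[`, numeric(1), "n_consumers"),
               c(herring = 3, smelt = 6, switch = 7))
  expect_error(scenario_preset("nope"), "eider_switch")
})

test_that("multi-cohort trials bind into one labelled dataset", {
  hs <- scenario_preset("harbourseal_groups")
  cons <- simulate_trial(hs, days = 42)
  expect_equal(nrow(cons$fa), 3 + 6 + 7)
  expect_setequal(unique(cons$factors$group), c("herring", "smelt", "switch"))
  expect_equal(unique(cons$factors$day), "42")
})

test_that("scenario CSVs round-trip through the manifest", {
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  sc <- scenario_preset("harpseal_lowfat")
  write_scenario_csvs(sc, dir1, days = c(0, 30), force = TRUE)
  write_scenario_csvs(sc, dir2, days = c(0, 30), force = TRUE)
  for (f in c("consumers.csv", "sources.csv", "cc.csv", "manifest.json"))
    expect_identical(readLines(file.path(dir1, f)),
                     readLines(file.path(dir2, f)))
  man <- jsonlite::read_json(file.path(dir1, "manifest.json"))
  expect_equal(man$cohorts[[1]]$seed, sc$seed)
  expect_error(write_scenario_csvs(sc, dir1, days = 0), "not empty")
})
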