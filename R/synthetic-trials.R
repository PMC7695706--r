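# Synthetic feeding trials: source libraries with controllable separation,
# diet-switch schedules with first-order (geometric) turnover kinetics,
# reduced lipid deposition on low-fat diets, and per-consumer noise. The
# generator emulates the statistical structure of captive feeding-trial
# case studies, so the whole estimation pipeline can be benchmarked against
# known diets without external data.

#' Generate a library of synthetic prey sources
#'
#' Draws `K` prey-space FA compositions over `J` tracers. Each source's
#' mean composition is a shared baseline perturbed on the log scale by an
#' amount proportional to `separation`, then renormalised to 100%;
#' pairwise distinguishability therefore grows with `separation` and
#' vanishes as it approaches 0. Per-FA SDs are a fixed fraction of the
#' means. FA names are taken from the packaged dietary/extended-dietary
#' pool so the selection filters apply cleanly downstream.
#'
#' @param K number of sources (>= 2).
#' @param J number of FAs (>= 2).
#' @param separation positive scale of inter-source divergence (log-scale
#'   SD of the per-source perturbation; around 1 gives strongly separated
#'   sources, near 0 indistinguishable ones).
#' @param seed integer seed.
#' @param sd_frac per-FA SD as a fraction of the mean (default 0.1).
#' @param source_names optional labels (default `source1..K`).
#' @return list of prey-space [source_summary()] objects.
#' @export
generate_source_library <- function(K, J, separation = 1, seed = 1,
                                    sd_frac = 0.1, source_names = NULL) {
  if (K < 2L) stop("K must be >= 2")
  if (J < 2L) stop("J must be >= 2")
  if (separation <= 0) stop("separation must be > 0")
  cls <- default_fa_classes()
  pool <- names(cls)[cls %in% c("dietary", "extended_dietary")]
  if (J > length(pool))
    stop("at most ", length(pool), " FAs available in the packaged pool")
  fa <- pool[seq_len(J)]
  if (is.null(source_names)) source_names <- paste0("source", seq_len(K))
  set.seed(as.integer(seed))
  base <- rgamma(J, shape = 2, rate = 1) + 0.05
  lapply(seq_len(K), function(k) {
    m <- base * exp(rnorm(J, 0, separation))
    m <- 100 * m / sum(m)
    source_summary(source_names[k],
                   stats::setNames(m, fa),
                   stats::setNames(sd_frac * m, fa),
                   space = "prey")
  })
}

#' Generate a synthetic calibration-coefficient set
#'
#' Log-normal multipliers around 1, redrawn per FA until they do not
#' exceed `cc_max` (so the CC filter keeps every tracer unless the user
#' asks otherwise).
#'
#' @param fa FA names.
#' @param seed integer seed.
#' @param log_sd log-scale SD of the multipliers (default 0.2).
#' @param cc_max upper bound enforced by redrawing (default 2).
#' @return a [cc_set()].
#' @export
generate_cc_set <- function(fa, seed = 1, log_sd = 0.2, cc_max = 2) {
  set.seed(as.integer(seed))
  cc <- exp(rnorm(length(fa), 0, log_sd))
  while (any(bad <- cc > cc_max))
    cc[bad] <- exp(rnorm(sum(bad), 0, log_sd))
  cc_set(stats::setNames(cc, fa), provenance = "synthetic")
}

#' Define a feeding-trial scenario
#'
#' A scenario is one cohort of consumers following a diet schedule. The
#' first schedule entry is the acclimation diet: consumers are assumed at
#' its equilibrium signature on day 0 (its duration is recorded for
#' provenance only). Subsequent entries are diet switches; day counting
#' starts at 0 at the first switch.
#'
#' Signature kinetics are first-order: each day a fraction
#' `lambda = turnover_rate * deposition_fraction` of the stored signature
#' is replaced by the current diet's predator-space target, giving an
#' exponential approach to equilibrium. `deposition_fraction < 1` models
#' low-fat diets on which only part of the dietary FA intake is stored.
#'
#' @param sources list of prey-space [source_summary()] objects.
#' @param true_cc a [cc_set()] covering the sources' FAs.
#' @param diet_schedule list of `list(duration = days, diet = proportions)`
#'   entries; each diet has one proportion per source, summing to 1.
#' @param turnover_rate fraction of the signature replaced per day at full
#'   deposition, in `[0, 1]`.
#' @param deposition_fraction fraction of dietary FA stored, in `(0, 1]`.
#' @param n_consumers cohort size.
#' @param noise_sd_scale multiplier on the per-FA SD used for individual
#'   noise (0 disables noise).
#' @param seed integer seed.
#' @param group optional cohort label (becomes a `group` factor).
#' @return object of class `trial_scenario`.
#' @export
trial_scenario <- function(sources, true_cc, diet_schedule, turnover_rate,
                           deposition_fraction = 1, n_consumers = 8,
                           noise_sd_scale = 1, seed = 1, group = NULL) {
  stopifnot(inherits(true_cc, "cc_set"))
  K <- length(sources)
  if (!length(diet_schedule)) stop("diet_schedule must have at least one entry")
  for (e in diet_schedule) {
    if (!all(c("duration", "diet") %in% names(e)))
      stop("each schedule entry needs duration and diet")
    if (length(e$diet) != K) stop("each diet needs one proportion per source")
    if (abs(sum(e$diet) - 1) > 1e-6) stop("each diet must sum to 1")
    if (any(e$diet < 0)) stop("diet proportions must be non-negative")
  }
  if (turnover_rate < 0 || turnover_rate > 1)
    stop("turnover_rate must lie in [0, 1]")
  if (deposition_fraction <= 0 || deposition_fraction > 1)
    stop("deposition_fraction must lie in (0, 1]")
  structure(list(sources = sources, true_cc = true_cc,
                 diet_schedule = diet_schedule,
                 turnover_rate = turnover_rate,
                 deposition_fraction = deposition_fraction,
                 n_consumers = n_consumers,
                 noise_sd_scale = noise_sd_scale,
                 seed = as.integer(seed), group = group),
            class = "trial_scenario")
}

# predator-space target signature and SD for one diet vector
.diet_target <- function(scenario, diet) {
  pred <- apply_ccs(scenario$sources, scenario$true_cc)
  mu <- Reduce(`+`, Map(function(s, w) w * s$means, pred, as.list(diet)))
  sd <- Reduce(`+`, Map(function(s, w) w * s$sds, pred, as.list(diet)))
  list(mu = mu, sd = sd)
}

.active_diet <- function(scenario, day) {
  # schedule entry 1 is acclimation; switches start at day 0
  durs <- vapply(scenario$diet_schedule[-1L], `[[`, numeric(1), "duration")
  if (day <= 0) return(scenario$diet_schedule[[1L]]$diet)
  if (!length(durs))
    stop("day ", day, " lies beyond the schedule horizon (no post-acclimation segment)")
  ends <- cumsum(durs)
  if (day > ends[length(ends)] + 1e-9)
    stop("day ", day, " lies beyond the schedule horizon (", ends[length(ends)], ")")
  seg <- which(day <= ends + 1e-9)[1L]
  scenario$diet_schedule[[seg + 1L]]$diet
}

#' Expected (noise-free) signature on a given day
#'
#' Iterates the daily turnover recursion from the acclimation equilibrium
#' through the schedule: `S(t+1) = (1 - lambda) S(t) + lambda T(t)` with
#' `lambda = turnover_rate * deposition_fraction` and `T(t)` the
#' predator-space target of the diet active on day `t`.
#'
#' @param scenario a [trial_scenario()].
#' @param at_day day index (0 = first switch; must lie within the schedule
#'   horizon).
#' @return named numeric vector, expected percent per FA.
#' @export
expected_signature <- function(scenario, at_day) {
  if (at_day < 0) stop("day before schedule start")
  lambda <- scenario$turnover_rate * scenario$deposition_fraction
  s <- .diet_target(scenario, scenario$diet_schedule[[1L]]$diet)$mu
  if (at_day > 0) {
    .active_diet(scenario, at_day)  # validates the horizon
    for (t in seq_len(at_day)) {
      target <- .diet_target(scenario, .active_diet(scenario, t))$mu
      s <- (1 - lambda) * s + lambda * target
    }
  }
  s
}

#' Simulate a cohort's FA profiles on a given day
#'
#' Adds independent per-FA normal noise (SD = `noise_sd_scale` times the
#' diet-weighted predator-space source SD of the currently active diet) to
#' the [expected_signature()], redrawing negative values. The RNG seed is
#' `scenario$seed + at_day`, so each sampling day is independently
#' reproducible.
#'
#' @inheritParams expected_signature
#' @return a [consumer_dataset()] with a `day` factor (and `group` if the
#'   scenario carries a cohort label).
#' @export
simulate_consumer_signature <- function(scenario, at_day) {
  s <- expected_signature(scenario, at_day)
  noise_sd <- scenario$noise_sd_scale *
    .diet_target(scenario, .active_diet(scenario, at_day))$sd
  factors <- data.frame(day = rep(as.character(at_day), scenario$n_consumers),
                        stringsAsFactors = FALSE)
  if (!is.null(scenario$group))
    factors$group <- rep(scenario$group, scenario$n_consumers)
  prefix <- if (is.null(scenario$group)) "c" else paste0(scenario$group, "_")
  out <- simulate_consumers_from_summary(
    s, noise_sd, n = scenario$n_consumers,
    seed = (scenario$seed + at_day) %% .Machine$integer.max,
    subject_prefix = paste0(prefix, "d", at_day, "_"))
  out$factors <- factors
  out$factor_names <- names(factors)
  out
}

#' Simulate a whole trial design
#'
#' Runs [simulate_consumer_signature()] for one scenario or a named list of
#' cohort scenarios over the requested sampling days and binds everything
#' into a single consumer dataset with `day` (and `group`) factors.
#'
#' @param scenarios a [trial_scenario()] or list thereof.
#' @param days sampling days (vector, or named list of vectors per cohort).
#' @return a [consumer_dataset()].
#' @export
simulate_trial <- function(scenarios, days) {
  if (inherits(scenarios, "trial_scenario")) scenarios <- list(scenarios)
  parts <- list()
  for (i in seq_along(scenarios)) {
    sc_days <- if (is.list(days)) days[[i]] else days
    for (d in sc_days)
      parts[[length(parts) + 1L]] <- simulate_consumer_signature(scenarios[[i]], d)
  }
  fa <- do.call(rbind, lapply(parts, `[[`, "fa"))
  factors <- do.call(rbind, lapply(parts, `[[`, "factors"))
  consumer_dataset(fa,
                   subject_id = unlist(lapply(parts, `[[`, "subject_id")),
                   factors = factors, check_sums = FALSE)
}

#' Preset feeding-trial scenarios
#'
#' Ready-made scenarios whose designs (sources, true diets, schedules,
#' sample sizes, deposition) transcribe well-documented captive feeding
#' trials; FA compositions and CCs are synthetic.
#'
#' * `eider_switch` — sea ducks (n = 8) acclimated on a five-component
#'   diet (1/3/88/4/4% clam/krill/formula/mussel/silverside), switched at
#'   day 0 to 56% krill + 44% formula, and at day 21 to 48% formula + 52%
#'   silverside; sampled at days 0, 21, 50 with incomplete turnover.
#' * `salmon_cc` — four cohorts of farmed salmon at complete turnover on
#'   herring oil, krill oil, or 70:30 / 30:70 blends (n = 36, 28, 34, 34).
#' * `puffin_priors` — seabird chicks fed by their parents (prey mass
#'   ranking sandlance > capelin > sandfish > salmonid > cod, herring
#'   absent) for 10 days, then herring only for 27 days (n = 6); the
#'   parental mass proportions are attached as `prior_weights` for
#'   informative-prior analyses.
#' * `harpseal_lowfat` — seals (n = 5) at equilibrium on herring switched
#'   to low-fat pollock for 30 days with deposition fraction 0.25.
#' * `harbourseal_groups` — three seal cohorts (n = 3, 6, 7): herring
#'   only, smelt only, or smelt then herring, over 42 days with slow
#'   turnover.
#'
#' @param name preset name.
#' @return a [trial_scenario()], or a named list of cohort scenarios for
#'   the multi-cohort designs (with a `prior_weights` attribute where
#'   informative priors apply).
#' @export
scenario_preset <- function(name) {
  presets <- c("eider_switch", "salmon_cc", "puffin_priors",
               "harpseal_lowfat", "harbourseal_groups")
  if (!name %in% presets)
    stop("unknown preset '", name, "'; available: ",
         paste(presets, collapse = ", "))
  switch(name,
    eider_switch = {
      src <- generate_source_library(5, 14, separation = 1.2, seed = 2101,
        sd_frac = 0.12,
        source_names = c("clam", "krill", "mazuri", "mussel", "silverside"))
      cc <- generate_cc_set(fa_names(src[[1L]]), seed = 2102)
      trial_scenario(src, cc,
        diet_schedule = list(
          list(duration = 69, diet = c(0.01, 0.03, 0.88, 0.04, 0.04)),
          list(duration = 21, diet = c(0, 0.56, 0.44, 0, 0)),
          list(duration = 29, diet = c(0, 0, 0.48, 0, 0.52))),
        turnover_rate = 0.065, n_consumers = 8, seed = 2103)
    },
    salmon_cc = {
      src <- generate_source_library(2, 14, separation = 1.2, seed = 2201,
        source_names = c("herring_oil", "krill_oil"))
      cc <- generate_cc_set(fa_names(src[[1L]]), seed = 2202)
      diets <- list(herring = c(1, 0), krill = c(0, 1),
                    h70k30 = c(0.7, 0.3), h30k70 = c(0.3, 0.7))
      ns <- c(herring = 36, krill = 28, h70k30 = 34, h30k70 = 34)
      out <- lapply(names(diets), function(g)
        trial_scenario(src, cc,
          diet_schedule = list(list(duration = 154, diet = diets[[g]])),
          turnover_rate = 0.03, n_consumers = ns[[g]],
          seed = 2203 + match(g, names(diets)), group = g))
      stats::setNames(out, names(diets))
    },
    puffin_priors = {
      src <- generate_source_library(6, 14, separation = 1.2, seed = 2301,
        source_names = c("sandlance", "capelin", "sandfish", "salmonid",
                         "cod", "herring"))
      cc <- generate_cc_set(fa_names(src[[1L]]), seed = 2302)
      sc <- trial_scenario(src, cc,
        diet_schedule = list(
          list(duration = 10, diet = c(0.72, 0.15, 0.06, 0.04, 0.03, 0)),
          list(duration = 27, diet = c(0, 0, 0, 0, 0, 1))),
        turnover_rate = 0.1, n_consumers = 6, seed = 2303)
      attr(sc, "prior_weights") <-
        c(sandlance = 0.72, capelin = 0.15, sandfish = 0.06,
          salmonid = 0.04, cod = 0.03)
      sc
    },
    harpseal_lowfat = {
      src <- generate_source_library(2, 14, separation = 1.2, seed = 2401,
        source_names = c("herring", "pollock"))
      cc <- generate_cc_set(fa_names(src[[1L]]), seed = 2402)
      trial_scenario(src, cc,
        diet_schedule = list(
          list(duration = 365, diet = c(1, 0)),
          list(duration = 30, diet = c(0, 1))),
        turnover_rate = 0.08, deposition_fraction = 0.25,
        n_consumers = 5, seed = 2403)
    },
    harbourseal_groups = {
      src <- generate_source_library(3, 14, separation = 1.2, seed = 2501,
        source_names = c("herring", "smelt", "salmon"))
      cc <- generate_cc_set(fa_names(src[[1L]]), seed = 2502)
      accl <- list(duration = 25, diet = c(2 / 3, 0, 1 / 3))
      scheds <- list(
        herring = list(accl, list(duration = 42, diet = c(1, 0, 0))),
        smelt = list(accl, list(duration = 42, diet = c(0, 1, 0))),
        switch = list(accl, list(duration = 21, diet = c(0, 1, 0)),
                      list(duration = 21, diet = c(1, 0, 0))))
      ns <- c(herring = 3, smelt = 6, switch = 7)
      out <- lapply(names(scheds), function(g)
        trial_scenario(src, cc, diet_schedule = scheds[[g]],
          turnover_rate = 0.05, n_consumers = ns[[g]],
          seed = 2503 + match(g, names(scheds)), group = g))
      stats::setNames(out, names(scheds))
    })
}

#' Write a scenario's dataset to disk
#'
#' Emits the same CSV formats the readers consume — `consumers.csv`,
#' `sources.csv` (prey space), `cc.csv` — plus a `manifest.json` recording
#' scenario parameters and seed for exact replay.
#'
#' @param scenarios a [trial_scenario()] or named list of cohorts.
#' @param dir output directory (created if needed).
#' @param days sampling days.
#' @param force overwrite a non-empty directory?
#' @return the directory, invisibly.
#' @export
write_scenario_csvs <- function(scenarios, dir, days, force = FALSE) {
  if (dir.exists(dir) && length(list.files(dir)) && !force)
    stop("output directory ", dir, " is not empty (use force = TRUE)")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  single <- inherits(scenarios, "trial_scenario")
  sc1 <- if (single) scenarios else scenarios[[1L]]
  consumers <- simulate_trial(scenarios, days)
  write_consumer_csv(consumers, file.path(dir, "consumers.csv"))
  write_source_csv(sc1$sources, file.path(dir, "sources.csv"))
  write_cc_csv(sc1$true_cc, file.path(dir, "cc.csv"))
  manifest <- list(
    days = days,
    cohorts = lapply(if (single) list(scenarios) else scenarios, function(s)
      list(group = s$group, n_consumers = s$n_consumers,
           turnover_rate = s$turnover_rate,
           deposition_fraction = s$deposition_fraction,
           noise_sd_scale = s$noise_sd_scale, seed = s$seed,
           diet_schedule = lapply(s$diet_schedule, function(e)
             list(duration = e$duration, diet = as.numeric(e$diet))))))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
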