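#!/usr/bin/env Rscript
# Stage 3: fit the Bayesian mixing model to every simulated trial.
#
# All fits use the standard pipeline: tracer filters (>0.5% abundance,
# dietary/extended-dietary class, CC <= 2), sources taken to predator
# space with the trial's CCs, Residual*Process error, and a fixed factor
# where the design has one (sampling day or diet group). 3 chains x
# 20,000 iterations (half burn-in, thinned by 10).
#
# Run stage 1 first: inputs are read from results/trials/.

library(famix)

mcmc <- list(n_iter = 20000, n_burnin = 10000, thin = 10,
             n_permutations = 999)
fit_cfg <- function(preset, factor_name, factor_columns = factor_name) {
  dir <- file.path("results/trials", preset)
  c(list(seed = 300,
         consumer_file = file.path(dir, "consumers.csv"),
         source_file = file.path(dir, "sources.csv"),
         cc_file = file.path(dir, "cc.csv"),
         factor_name = factor_name, factor_columns = factor_columns,
         output_dir = file.path("results/fits", preset)),
    mcmc)
}

for (job in list(list("eider_switch", "day"),
                 list("salmon_cc", "group", c("day", "group")),
                 list("harpseal_lowfat", "day"),
                 list("harbourseal_groups", "group", c("day", "group")))) {
  post <- run_fit(fit_cfg(job[[1]], job[[2]],
                          if (length(job) > 2) job[[3]] else job[[2]]))
  cat(sprintf("\n== %s (fixed factor: %s) ==\n", job[[1]], job[[2]]))
  print(post$summaries[, c("level", "source", "median", "q2.5", "q97.5")],
        row.names = FALSE, digits = 3)
}

## Tufted-puffin day-0 models: the parental diet is estimated three ways —
## with informative priors from the parental prey-mass proportions, without
## priors, and without priors but with the never-fed herring included.
sc <- scenario_preset("puffin_priors")
w <- attr(sc, "prior_weights")
dir <- "results/trials/puffin_priors"
cons <- read_consumer_csv(file.path(dir, "consumers.csv"),
                          factor_names = "day", check_sums = FALSE)
day0 <- which(cons$factors$day == "0")
cons0 <- consumer_dataset(cons$fa[day0, , drop = FALSE],
                          subject_id = cons$subject_id[day0],
                          check_sums = FALSE)
sources <- read_source_csv(file.path(dir, "sources.csv"))
cc <- read_cc_csv(file.path(dir, "cc.csv"))
tracers <- select_fas(cons0, cc)
pred <- apply_ccs(sources, cc)
names(pred) <- vapply(pred, `[[`, character(1), "source_name")
parental <- pred[names(w)]

models <- list(
  informative = mixing_model_spec(parental, fa_names = tracers,
                                  prior_alpha = informative_alpha(unname(w))),
  flat = mixing_model_spec(parental, fa_names = tracers),
  flat_with_herring = mixing_model_spec(pred, fa_names = tracers))
dir.create("results/fits/puffin_day0", showWarnings = FALSE, recursive = TRUE)
for (nm in names(models)) {
  post <- fit(build_model(subset_fas(cons0, tracers), models[[nm]]),
              n_chains = 3, n_iter = mcmc$n_iter, n_burnin = mcmc$n_burnin,
              thin = mcmc$thin, seed = 301)
  write_posterior_csv(post, file.path("results/fits/puffin_day0",
                                      paste0(nm, ".csv")))
  cat(sprintf("\n== puffin day 0, %s ==\n", nm))
  print(rank_sources(post), row.names = FALSE, digits = 3)
}
cat("\nAll posterior summaries are under results/fits/.\n")
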