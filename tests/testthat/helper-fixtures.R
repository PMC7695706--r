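# Shared fixture builders. Everything is generated in code at test time.

# two well-separated predator-space sources over two tracers
two_source_setup <- function() {
  src <- list(
    source_summary("A", c(`18:1n-9` = 30, `22:6n-3` = 5),
                   c(`18:1n-9` = 2, `22:6n-3` = 1)),
    source_summary("B", c(`18:1n-9` = 5, `22:6n-3` = 25),
                   c(`18:1n-9` = 1, `22:6n-3` = 2)))
  identity_cc <- cc_set(c(`18:1n-9` = 1, `22:6n-3` = 1))
  list(prey = src, pred = apply_ccs(src, identity_cc), cc = identity_cc)
}

# consumers drawn around a fixed mixture of the two predator-space sources
two_source_consumers <- function(p_a, n = 8, seed = 5, sd = c(1, 1)) {
  s <- two_source_setup()
  mix <- p_a * s$pred[[1]]$means + (1 - p_a) * s$pred[[2]]$means
  simulate_consumers_from_summary(mix, stats::setNames(sd, names(mix)),
                                  n = n, seed = seed)
}

# short-run MCMC settings for unit tests (production defaults are far longer)
quick_fit <- function(model, seed = 1, n_iter = 6000, n_burnin = 3000,
                      thin = 3, ...) {
  fit(model, n_chains = 3, n_iter = n_iter, n_burnin = n_burnin,
      thin = thin, seed = seed, ...)
}

# textbook Bray-Curtis: sum |x-y| / sum (x+y), independent of vegan
bray_textbook <- function(x, y) sum(abs(x - y)) / sum(x + y)

# a class table that marks every named FA dietary (for synthetic tracers)
all_dietary <- function(fa) stats::setNames(rep("dietary", length(fa)), fa)
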