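test_that("model specification enforces the mixing geometry contracts", {
  s <- two_source_setup()
  expect_error(mixing_model_spec(s$pred[1]), "at least 2 sources")
  expect_error(mixing_model_spec(s$prey), "prey space")
  expect_error(mixing_model_spec(s$pred, prior_alpha = c(0, 1)), "> 0")
  spec <- mixing_model_spec(s$pred)
  expect_equal(spec$error_structure, "residual_times_process")
  expect_true(all(spec$trophic_modification == 0))

  # J < K - 1 warns about under-determined geometry
  src5 <- generate_source_library(5, 2, separation = 1, seed = 1)
  pred5 <- apply_ccs(src5, cc_set(stats::setNames(rep(1, 2), fa_names(src5[[1]]))))
  cons <- simulate_consumers_from_summary(pred5[[1]]$means, pred5[[1]]$sds,
                                          n = 3, seed = 1)
  expect_warning(build_model(cons, mixing_model_spec(pred5)),
                 "under-determined")
})

test_that("informative_alpha keeps total concentration K and floors zeros", {
  expect_equal(informative_alpha(rep(0.25, 4)), rep(1, 4))
  expect_equal(informative_alpha(c(0.7, 0.15, 0.1, 0.04, 0.01)),
               c(3.5, 0.75, 0.5, 0.2, 0.05))
  expect_equal(informative_alpha(c(1, 0))[2], 0.01)
  expect_error(informative_alpha(c(0, 0)), "all-zero")
  expect_error(informative_alpha(c(0.5, 0.2)), "sum to 1")
})

test_that("prior-predictive ordering follows the weights", {
  set.seed(31)
  a <- informative_alpha(c(0.6, 0.3, 0.1))
  draws <- t(replicate(4000, {
    g <- rgamma(3, a, 1)
    g / sum(g)
  }))
  med <- apply(draws, 2, median)
  expect_true(med[1] > med[2] && med[2] > med[3])
})

test_that("prior-only fit reproduces the closed-form Dirichlet marginals", {
  s <- two_source_setup()
  alpha <- c(2, 1)
  spec <- mixing_model_spec(s$pred, prior_alpha = alpha)
  m <- build_model(NULL, spec)
  post <- quick_fit(m, seed = 4, n_iter = 26000, n_burnin = 6000, thin = 5)
  sm <- post$summaries
  a0 <- sum(alpha)
  for (k in 1:2) {
    expect_equal(sm$median[k], qbeta(0.5, alpha[k], a0 - alpha[k]),
                 tolerance = 0.03)
    expect_equal(sm$q2.5[k], qbeta(0.025, alpha[k], a0 - alpha[k]),
                 tolerance = 0.03)
    expect_equal(sm$q97.5[k], qbeta(0.975, alpha[k], a0 - alpha[k]),
                 tolerance = 0.03)
  }
})

test_that("a consumer sitting on one source's mean is attributed to it", {
  s <- two_source_setup()
  cons <- two_source_consumers(p_a = 1, n = 6, seed = 2, sd = c(0.3, 0.3))
  post <- quick_fit(build_model(cons, mixing_model_spec(s$pred)), seed = 3)
  expect_gt(post$summaries$median[post$summaries$source == "A"], 0.95)
})

test_that("identical sources leave the posterior at the flat prior", {
  fa <- c(x = 20, y = 20)
  sds <- c(x = 2, y = 2)
  twin <- list(source_summary("A", fa, sds), source_summary("B", fa, sds))
  pred <- apply_ccs(twin, cc_set(c(x = 1, y = 1)))
  cons <- simulate_consumers_from_summary(fa, sds / 2, n = 6, seed = 9)
  post <- quick_fit(build_model(cons, mixing_model_spec(pred)), seed = 5,
                    n_iter = 16000, n_burnin = 6000, thin = 5)
  # Dirichlet(1,1) marginal median is 0.5
  expect_equal(post$summaries$median, rep(0.5, 2), tolerance = 0.05)
})

test_that("MCMC matches deterministic grid integration on a 50/50 mixture", {
  s <- two_source_setup()
  cons <- two_source_consumers(p_a = 0.5, n = 8, seed = 5)
  m <- build_model(cons, mixing_model_spec(s$pred))
  oracle <- grid_posterior_2source(m)
  post <- quick_fit(m, seed = 9, n_iter = 26000, n_burnin = 6000, thin = 4)
  pa <- as.vector(post$draws[, , "p[all,A]"])
  mcse <- sd(pa) / sqrt(coda::effectiveSize(coda::mcmc(pa)))
  expect_lt(abs(mean(pa) - oracle$mean["A"]), 3 * mcse + 1e-4)
  expect_equal(post$summaries$median[post$summaries$source == "A"], 0.5,
               tolerance = 0.05)
})

test_that("fits are exactly reproducible under a fixed seed", {
  s <- two_source_setup()
  cons <- two_source_consumers(p_a = 0.7, n = 4, seed = 11)
  m <- build_model(cons, mixing_model_spec(s$pred))
  p1 <- quick_fit(m, seed = 21, n_iter = 3000, n_burnin = 1500)
  p2 <- quick_fit(m, seed = 21, n_iter = 3000, n_burnin = 1500)
  expect_identical(p1$summaries, p2$summaries)
  expect_identical(p1$draws, p2$draws)
})

test_that("every saved diet vector closes the simplex exactly", {
  sc <- scenario_preset("harpseal_lowfat")
  cons <- simulate_trial(sc, days = c(0, 30))
  pred <- apply_ccs(sc$sources, sc$true_cc)
  spec <- mixing_model_spec(pred, factor_name = "day")
  post <- quick_fit(build_model(cons, spec), seed = 6,
                    n_iter = 3000, n_burnin = 1500)
  for (l in post$levels) {
    pars <- sprintf("p[%s,%s]", l, post$source_names)
    sums <- apply(post$draws[, , pars, drop = FALSE], c(1, 2), sum)
    expect_true(all(abs(sums - 1) < 1e-12))
    expect_true(all(post$draws[, , pars] > 0 & post$draws[, , pars] < 1))
  }
  # residual multipliers are positive
  eps_pars <- grep("^eps\\[", dimnames(post$draws)[[3]], value = TRUE)
  expect_true(all(post$draws[, , eps_pars] > 0))
})

test_that("factor levels get independent diet vectors and priors", {
  s <- two_source_setup()
  consA <- two_source_consumers(p_a = 0.9, n = 5, seed = 31)
  consB <- two_source_consumers(p_a = 0.2, n = 5, seed = 32)
  fa <- rbind(consA$fa, consB$fa)
  cons <- consumer_dataset(fa, subject_id = paste0("s", 1:10),
                           factors = data.frame(grp = rep(c("A", "B"), each = 5)),
                           check_sums = FALSE)
  spec <- mixing_model_spec(s$pred, factor_name = "grp")
  post <- quick_fit(build_model(cons, spec), seed = 7)
  sm <- post$summaries
  expect_gt(sm$median[sm$level == "A" & sm$source == "A"], 0.8)
  expect_lt(sm$median[sm$level == "B" & sm$source == "A"], 0.4)
  # missing factor level errors
  spec_bad <- mixing_model_spec(s$pred, factor_name = "nope")
  expect_error(build_model(cons, spec_bad), "no factor 'nope'")
})
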