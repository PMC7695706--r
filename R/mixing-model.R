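# Bayesian FA mixing model. Each consumer tracer value is modelled as a
# diet-weighted combination of predator-space source means with
# Residual*Process variance:
#
#   y_ij ~ Normal(mu_ij, sigma_ij),   mu_ij   = sum_k p_lk * mu'_jk
#                                     sigma^2 = eps_j * sum_k p_lk^2 * s'^2_jk
#
# with p_l ~ Dirichlet(alpha_l) per factor level l (independent across
# levels) and eps_j a per-tracer multiplicative residual with a vague
# uniform prior. Trophic modification is additive in the general tracer
# mixing equation but is fixed at zero here because CCs are applied to the
# sources beforehand (multiplicative modification, predator space).
#
# The model is written in the JAGS language and sampled with rjags; the
# Dirichlet is parameterised through independent Gamma(alpha_k, 1) draws
# normalised onto the simplex, which JAGS samples in unconstrained positive
# space and which makes every saved diet vector sum to 1 exactly.

#' Specify a fatty-acid mixing model
#'
#' @param sources list of predator-space [source_summary()] objects
#'   (apply CCs first, see [apply_ccs()]); at least two.
#' @param fa_names tracer subset, in order (default: all FAs of the first
#'   source; normally the output of [select_fas()]).
#' @param factor_name optional fixed factor: one independent diet vector
#'   (and Dirichlet prior) per level, no pooling.
#' @param prior_alpha Dirichlet concentration: `NULL` for the
#'   non-informative `(1, ..., 1)`, a length-K vector used at every level,
#'   or a levels x K matrix (rows named by level). See
#'   [informative_alpha()].
#' @param eps_upper upper bound of the uniform prior on the per-tracer
#'   residual multiplier (default 20, vague relative to percent-scale
#'   tracers).
#' @param sd_floor variance floor applied to source SDs so zero-SD sources
#'   keep the likelihood proper.
#' @return object of class `mixing_model_spec`.
#' @export
mixing_model_spec <- function(sources, fa_names = NULL, factor_name = NULL,
                              prior_alpha = NULL, eps_upper = 20,
                              sd_floor = 1e-3) {
  if (inherits(sources, "source_summary")) sources <- list(sources)
  K <- length(sources)
  if (K < 2L) stop("mixing needs at least 2 sources")
  for (s in sources)
    if (s$space != "predator")
      stop("source '", s$source_name, "' is in prey space; apply_ccs() first ",
           "(or read CC-incorporated files with space = \"predator\")")
  if (is.null(fa_names)) fa_names <- names(sources[[1L]]$means)
  for (s in sources) {
    missing <- setdiff(fa_names, names(s$means))
    if (length(missing))
      stop("source '", s$source_name, "' lacks FA(s): ",
           paste(missing, collapse = ", "))
  }
  if (length(fa_names) < 1L) stop("need at least 1 tracer")
  if (!is.null(prior_alpha)) {
    if (is.matrix(prior_alpha)) {
      if (ncol(prior_alpha) != K) stop("prior_alpha needs K columns")
    } else if (length(prior_alpha) != K)
      stop("prior_alpha must have one entry per source")
    if (any(prior_alpha <= 0)) stop("prior_alpha must be > 0")
  }
  structure(list(sources = sources, fa_names = fa_names,
                 factor_name = factor_name, prior_alpha = prior_alpha,
                 eps_upper = eps_upper, sd_floor = sd_floor,
                 error_structure = "residual_times_process",
                 trophic_modification = rep(0, length(fa_names))),
            class = "mixing_model_spec")
}

#' Dirichlet concentrations from prior diet weights
#'
#' Encodes external knowledge of diet composition (e.g. prey mass
#' proportions observed in the field) as an informative Dirichlet prior.
#' The total concentration is kept at K — the same overall prior weight as
#' the non-informative `(1, ..., 1)` — so the prior informs the location of
#' the diet vector without inflating its strength: `alpha_k = K * w_k`,
#' floored at 0.01 so zero-weight sources stay admissible.
#'
#' @param weights non-negative prior mass proportions, one per source,
#'   summing to 1.
#' @return numeric concentration vector of length K.
#' @export
informative_alpha <- function(weights) {
  if (any(weights < 0)) stop("weights must be non-negative")
  if (all(weights == 0)) stop("all-zero prior weights")
  if (abs(sum(weights) - 1) > 1e-6) stop("weights must sum to 1")
  pmax(length(weights) * weights, 0.01)
}

.jags_mixing_string <- function(has_data) {
  likelihood <- if (has_data) "
  for (i in 1:N) {
    for (j in 1:J) {
      mu[i,j] <- inprod(p[level[i],1:K], smu[j,1:K])
      v[i,j] <- eps[j] * inprod(psq[level[i],1:K], ss2[j,1:K])
      y[i,j] ~ dnorm(mu[i,j], 1/v[i,j])
    }
  }" else ""
  paste0("model {
  for (l in 1:L) {
    for (k in 1:K) { g[l,k] ~ dgamma(alpha[l,k], 1) }
    for (k in 1:K) { p[l,k] <- g[l,k] / sum(g[l,1:K]) }
    for (k in 1:K) { psq[l,k] <- p[l,k] * p[l,k] }
  }
  for (j in 1:J) { eps[j] ~ dunif(0, eps_upper) }
", likelihood, "
}")
}

#' Assemble a fit-ready mixing model
#'
#' Restricts the consumers to the spec's tracers, resolves factor levels,
#' expands the Dirichlet prior per level and bundles the JAGS data block.
#' With `consumers = NULL` the model is prior-only (no likelihood), which
#' is useful for prior-sensitivity checks: the posterior then equals the
#' Dirichlet prior.
#'
#' @param consumers a [consumer_dataset()] carrying the spec's factor, or
#'   `NULL` for a prior-only model.
#' @param spec a [mixing_model_spec()].
#' @return object of class `fa_mixing_model`, ready for [fit()].
#' @export
build_model <- function(consumers, spec) {
  stopifnot(inherits(spec, "mixing_model_spec"))
  K <- length(spec$sources)
  J <- length(spec$fa_names)
  if (J < K - 1L)
    warning("fewer tracers (", J, ") than sources minus one (", K - 1L,
            "): mixing geometry is under-determined")
  src_names <- vapply(spec$sources, `[[`, character(1), "source_name")
  smu <- vapply(spec$sources, function(s) unname(s$means[spec$fa_names]),
                numeric(J))
  ssd <- vapply(spec$sources, function(s) unname(s$sds[spec$fa_names]),
                numeric(J))
  smu <- matrix(smu, J, K); ssd <- matrix(ssd, J, K)
  ss2 <- pmax(ssd^2, spec$sd_floor^2)
  if (is.null(consumers)) {
    levels <- "prior"; level_idx <- integer(); y <- NULL
  } else {
    stopifnot(inherits(consumers, "consumer_dataset"))
    missing <- setdiff(spec$fa_names, fa_names(consumers))
    if (length(missing))
      stop("consumers lack tracer(s): ", paste(missing, collapse = ", "))
    if (!is.null(spec$factor_name)) {
      if (!spec$factor_name %in% consumers$factor_names)
        stop("consumers carry no factor '", spec$factor_name, "'")
      labels <- consumers$factors[[spec$factor_name]]
      if (anyNA(labels)) stop("missing factor level for some consumers")
      levels <- unique(labels)
      level_idx <- match(labels, levels)
    } else {
      levels <- "all"
      level_idx <- rep(1L, nrow(consumers$fa))
    }
    y <- consumers$fa[, spec$fa_names, drop = FALSE]
  }
  L <- length(levels)
  alpha <- spec$prior_alpha
  if (is.null(alpha)) alpha <- rep(1, K)
  if (is.matrix(alpha)) {
    if (nrow(alpha) != L) stop("prior_alpha has ", nrow(alpha),
                               " rows but the design has ", L, " levels")
    if (!is.null(rownames(alpha))) alpha <- alpha[levels, , drop = FALSE]
  } else {
    alpha <- matrix(rep(alpha, each = L), L, K)
  }
  structure(list(spec = spec, y = y, level_idx = level_idx,
                 levels = levels, source_names = src_names,
                 smu = smu, ss2 = ss2, alpha = alpha,
                 K = K, J = J, L = L,
                 model_string = .jags_mixing_string(!is.null(y))),
            class = "fa_mixing_model")
}

#' @export
print.fa_mixing_model <- function(x, ...) {
  cat(sprintf("FA mixing model: %d sources, %d tracers, %d level(s)%s, n = %d\n",
              x$K, x$J, x$L,
              if (!is.null(x$spec$factor_name))
                paste0(" of '", x$spec$factor_name, "'") else "",
              if (is.null(x$y)) 0L else nrow(x$y)))
  invisible(x)
}

#' Fit a mixing model by MCMC
#'
#' Samples diet proportions and residual multipliers with JAGS. Chains are
#' initialised at the prior mean and seeded individually from `seed`, so a
#' run is exactly reproducible. The defaults mirror a "normal" mixing-model
#' run length: 3 chains of 100,000 iterations, the first 50,000 discarded
#' as burn-in, thinned by 50. Convergence is assessed with Gelman-Rubin and
#' Geweke diagnostics on the saved draws.
#'
#' @param model a `fa_mixing_model` from [build_model()].
#' @param n_chains number of chains (>= 2; the diagnostics need several).
#' @param n_iter total iterations per chain, including burn-in.
#' @param n_burnin burn-in iterations discarded per chain.
#' @param thin thinning interval for the saved draws.
#' @param seed integer seed controlling all chains.
#' @param n_adapt JAGS adaptation steps.
#' @param rhat_threshold,geweke_threshold convergence thresholds passed to
#'   [convergence_report()].
#' @param max_init_retries reinitialisation attempts if the sampler cannot
#'   start (non-finite likelihood at the initial values).
#' @return object of class `diet_posterior`: `draws` (chains x iterations x
#'   parameters, parameters named `p[level,source]` and `eps[fa]`),
#'   `summaries` (median and central intervals per diet proportion),
#'   `diagnostics` (a `convergence_report`), plus design metadata.
#' @export
fit <- function(model, n_chains = 3, n_iter = 100000, n_burnin = 50000,
                thin = 50, seed = 1, n_adapt = 1000,
                rhat_threshold = 1.05, geweke_threshold = 2,
                max_init_retries = 3) {
  stopifnot(inherits(model, "fa_mixing_model"))
  if (n_chains < 2L) stop("need at least 2 chains for convergence diagnostics")
  if (n_burnin >= n_iter) stop("n_burnin must be smaller than n_iter")
  seed <- as.integer(seed)
  dat <- list(K = model$K, J = model$J, L = model$L,
              alpha = model$alpha, eps_upper = model$spec$eps_upper)
  if (!is.null(model$y)) {
    dat$N <- nrow(model$y); dat$y <- unname(model$y)
    dat$level <- model$level_idx
    dat$smu <- model$smu; dat$ss2 <- model$ss2
  }
  make_inits <- function(jitter) lapply(seq_len(n_chains), function(c) {
    g0 <- model$alpha
    if (jitter > 0) g0 <- g0 * exp(matrix(rnorm(length(g0), 0, jitter),
                                          nrow(g0)))
    list(g = g0, eps = rep(1, model$J),
         .RNG.name = "base::Mersenne-Twister",
         .RNG.seed = (seed + 1000L * c) %% .Machine$integer.max)
  })
  jm <- NULL
  set.seed(seed)
  for (attempt in 0:max_init_retries) {
    jm <- try(rjags::jags.model(textConnection(model$model_string),
                                data = dat, inits = make_inits(0.1 * attempt),
                                n.chains = n_chains, n.adapt = n_adapt,
                                quiet = TRUE),
              silent = TRUE)
    if (!inherits(jm, "try-error")) break
  }
  if (inherits(jm, "try-error"))
    stop("sampler failed to initialise after ", max_init_retries,
         " retries: ", attr(jm, "condition")$message)
  update(jm, n_burnin, progress.bar = "none")
  samp <- rjags::coda.samples(jm, c("p", "eps"),
                              n.iter = n_iter - n_burnin, thin = thin,
                              progress.bar = "none")
  # rename p[l,k] / eps[j] with the design labels and stack into an array
  raw_names <- colnames(samp[[1L]])
  pretty <- raw_names
  pm <- regmatches(raw_names, regexec("^p\\[(\\d+),(\\d+)\\]$", raw_names))
  em <- regmatches(raw_names, regexec("^eps\\[(\\d+)\\]$", raw_names))
  for (i in seq_along(raw_names)) {
    if (length(pm[[i]]))
      pretty[i] <- sprintf("p[%s,%s]",
                           model$levels[as.integer(pm[[i]][2L])],
                           model$source_names[as.integer(pm[[i]][3L])])
    else if (length(em[[i]]))
      pretty[i] <- sprintf("eps[%s]",
                           model$spec$fa_names[as.integer(em[[i]][2L])])
  }
  niter_kept <- nrow(samp[[1L]])
  draws <- array(NA_real_, c(n_chains, niter_kept, length(raw_names)),
                 dimnames = list(NULL, NULL, pretty))
  for (c in seq_len(n_chains)) draws[c, , ] <- as.matrix(samp[[c]])
  summaries <- .summarise_diet(draws, model)
  diag <- convergence_report(draws, rhat_threshold = rhat_threshold,
                             geweke_threshold = geweke_threshold)
  structure(list(draws = draws, summaries = summaries, diagnostics = diag,
                 levels = model$levels, source_names = model$source_names,
                 fa_names = model$spec$fa_names,
                 factor_name = model$spec$factor_name,
                 settings = list(n_chains = n_chains, n_iter = n_iter,
                                 n_burnin = n_burnin, thin = thin,
                                 seed = seed),
                 mcmc = samp),
            class = "diet_posterior")
}

.summarise_diet <- function(draws, model) {
  qs <- c(0.025, 0.25, 0.5, 0.75, 0.975)
  rows <- list()
  for (l in model$levels) for (k in model$source_names) {
    par <- sprintf("p[%s,%s]", l, k)
    x <- as.vector(draws[, , par])
    q <- quantile(x, qs, names = FALSE)
    rows[[length(rows) + 1L]] <-
      data.frame(level = l, source = k, mean = mean(x),
                 median = q[3L], q2.5 = q[1L], q25 = q[2L],
                 q75 = q[4L], q97.5 = q[5L], stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' @export
print.diet_posterior <- function(x, digits = 3, ...) {
  cat("Diet posterior (", dim(x$draws)[1L], " chains x ", dim(x$draws)[2L],
      " saved draws)\n", sep = "")
  df <- x$summaries
  df[, sapply(df, is.numeric)] <- round(df[, sapply(df, is.numeric)], digits)
  print(df, row.names = FALSE)
  print(x$diagnostics)
  invisible(x)
}

#' Export posterior summaries / draws
#'
#' `write_posterior_csv` writes the per-level, per-source medians and
#' central intervals; `write_draws_csv` writes every saved draw in a plain
#' chain/iteration/parameter-column table.
#'
#' @param posterior a `diet_posterior`.
#' @param path output CSV path.
#' @export
write_posterior_csv <- function(posterior, path) {
  write.csv(posterior$summaries, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_posterior_csv
#' @export
write_draws_csv <- function(posterior, path) {
  d <- posterior$draws
  nc <- dim(d)[1L]; ni <- dim(d)[2L]
  flat <- do.call(rbind, lapply(seq_len(nc), function(c) d[c, , ]))
  df <- data.frame(chain = rep(seq_len(nc), each = ni),
                   iteration = rep(seq_len(ni), nc),
                   check.names = FALSE)
  df <- cbind(df, as.data.frame(flat, check.names = FALSE))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Deterministic two-source posterior by grid integration
#'
#' Independent numerical check of the MCMC sampler for K = 2 sources and a
#' single factor level: the diet simplex is one-dimensional, so the
#' posterior mean of each proportion can be computed by brute-force
#' quadrature over a fine grid on p, integrating the per-tracer residual
#' multipliers over their uniform prior on a secondary grid. Completely
#' independent of JAGS.
#'
#' @param model a `fa_mixing_model` with K = 2, one level, and data.
#' @param n_grid number of grid points on the simplex (default 2000).
#' @param n_eps_grid quadrature points for each residual multiplier.
#' @return list with `mean` (posterior mean per source), `median`, and the
#'   grid posterior density.
#' @export
grid_posterior_2source <- function(model, n_grid = 2000, n_eps_grid = 60) {
  stopifnot(inherits(model, "fa_mixing_model"), model$K == 2L,
            model$L == 1L, !is.null(model$y))
  p <- (seq_len(n_grid) - 0.5) / n_grid
  eps <- (seq_len(n_eps_grid) - 0.5) / n_eps_grid * model$spec$eps_upper
  a <- model$alpha[1L, ]
  logpost <- (a[1L] - 1) * log(p) + (a[2L] - 1) * log1p(-p)
  for (j in seq_len(model$J)) {
    muj <- p * model$smu[j, 1L] + (1 - p) * model$smu[j, 2L]
    s2j <- p^2 * model$ss2[j, 1L] + (1 - p)^2 * model$ss2[j, 2L]
    y <- model$y[, j]
    # integrate the tracer's likelihood over eps_j (uniform prior)
    ll <- matrix(0, n_grid, n_eps_grid)
    for (t in seq_len(n_eps_grid)) {
      v <- eps[t] * s2j
      ll[, t] <- vapply(seq_len(n_grid), function(g)
        sum(stats::dnorm(y, muj[g], sqrt(v[g]), log = TRUE)), numeric(1))
    }
    mx <- apply(ll, 1L, max)
    logpost <- logpost + mx + log(rowMeans(exp(ll - mx)))
  }
  w <- exp(logpost - max(logpost))
  w <- w / sum(w)
  cdf <- cumsum(w)
  med1 <- p[which.max(cdf >= 0.5)]
  m1 <- sum(w * p)
  list(mean = stats::setNames(c(m1, 1 - m1), model$source_names),
       median = stats::setNames(c(med1, 1 - med1), model$source_names),
       grid = p, weights = w)
}
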