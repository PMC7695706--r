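# FA data model: consumer datasets, source summaries, calibration
# coefficients, CSV I/O, simulation from published summary statistics, and
# the tracer selection filters.

#' Construct a consumer dataset
#'
#' A consumer dataset holds one proportional FA signature per individual
#' (percent of total identified FAs), plus any design factors (sampling day,
#' diet group, ...). Raw empirical profiles are required to sum to 100
#' within `sum_tol` percentage points; profiles that have been taken through
#' CC multiplication (predator space) or simulated from per-FA summary
#' statistics intentionally break the closure constraint, so the check can
#' be disabled.
#'
#' @param fa numeric matrix, one row per individual, one named column per
#'   FA, values in percent.
#' @param subject_id character vector of individual labels (defaults to row
#'   names or `ind<i>`).
#' @param factors `NULL` or a data.frame of factor columns (one row per
#'   individual).
#' @param check_sums enforce the 100% closure constraint?
#' @param sum_tol tolerance, in percentage points, on the row sums
#'   (published FA tables routinely omit trace FAs).
#' @return an object of class `consumer_dataset`.
#' @export
consumer_dataset <- function(fa, subject_id = NULL, factors = NULL,
                             check_sums = TRUE, sum_tol = 2) {
  fa <- as.matrix(fa)
  storage.mode(fa) <- "double"
  if (is.null(colnames(fa)) || anyNA(colnames(fa)) || any(colnames(fa) == ""))
    stop("FA columns must be named")
  colnames(fa) <- trimws(colnames(fa))
  if (anyDuplicated(colnames(fa)))
    stop("duplicate FA name: ", colnames(fa)[duplicated(colnames(fa))][1L])
  if (anyNA(fa)) stop("FA values contain missing/non-numeric entries")
  if (any(fa < 0)) stop("FA values must be non-negative")
  if (is.null(subject_id)) {
    subject_id <- rownames(fa)
    if (is.null(subject_id)) subject_id <- paste0("ind", seq_len(nrow(fa)))
  }
  subject_id <- as.character(subject_id)
  if (length(subject_id) != nrow(fa))
    stop("subject_id length does not match number of profiles")
  if (!is.null(factors)) {
    factors <- as.data.frame(factors, stringsAsFactors = FALSE)
    if (nrow(factors) != nrow(fa))
      stop("factors must have one row per profile")
    factors[] <- lapply(factors, as.character)
  }
  if (check_sums) {
    rs <- rowSums(fa)
    bad <- which(abs(rs - 100) > sum_tol)
    if (length(bad))
      stop(sprintf(
        "profile '%s' sums to %.2f%%, outside 100 +/- %.1f (set check_sums = FALSE for predator-space or simulated profiles)",
        subject_id[bad[1L]], rs[bad[1L]], sum_tol))
  }
  rownames(fa) <- subject_id
  structure(list(fa = fa, subject_id = subject_id, factors = factors,
                 factor_names = if (is.null(factors)) character() else names(factors)),
            class = "consumer_dataset")
}

#' @export
print.consumer_dataset <- function(x, ...) {
  cat(sprintf("Consumer dataset: %d profiles x %d FAs\n",
              nrow(x$fa), ncol(x$fa)))
  if (length(x$factor_names))
    cat("  factors:", paste(x$factor_names, collapse = ", "), "\n")
  invisible(x)
}

#' FA names of a famix object
#'
#' @param x a `consumer_dataset`, `source_summary` or `cc_set`.
#' @return character vector of FA identifiers, in stored order.
#' @export
fa_names <- function(x) UseMethod("fa_names")
#' @export
fa_names.consumer_dataset <- function(x) colnames(x$fa)
#' @export
fa_names.source_summary <- function(x) names(x$means)
#' @export
fa_names.cc_set <- function(x) names(x$cc)

#' Construct a per-source FA summary
#'
#' Sources enter the mixing model as per-FA means and standard deviations,
#' in prey space (as measured on the prey) or predator space (after CC
#' multiplication, see [apply_ccs()]).
#'
#' @param source_name label for the source (prey type).
#' @param means,sds named numeric vectors, percent per FA.
#' @param space `"prey"` or `"predator"`; predator-space summaries are
#'   produced by [apply_ccs()].
#' @return object of class `source_summary`.
#' @export
source_summary <- function(source_name, means, sds, space = "prey") {
  space <- match.arg(space, c("prey", "predator"))
  if (is.null(names(means))) stop("means must be named by FA")
  names(means) <- trimws(names(means))
  if (is.null(names(sds))) names(sds) <- names(means)
  names(sds) <- trimws(names(sds))
  if (!identical(names(means), names(sds)))
    stop("means and sds must share one FA ordering")
  if (any(means < 0) || any(sds < 0))
    stop("source means and SDs must be non-negative")
  structure(list(source_name = as.character(source_name),
                 means = means, sds = sds, space = space),
            class = "source_summary")
}

#' @export
print.source_summary <- function(x, ...) {
  cat(sprintf("Source '%s' (%s space): %d FAs\n",
              x$source_name, x$space, length(x$means)))
  invisible(x)
}

#' Construct a calibration-coefficient set
#'
#' A CC is a unitless multiplicative factor per FA describing trophic
#' modification from prey to predator tissue: consumer value = prey value
#' times CC.
#'
#' @param cc named positive numeric vector, one multiplier per FA.
#' @param provenance free text recording the diet and species the CCs
#'   derive from.
#' @return object of class `cc_set`.
#' @export
cc_set <- function(cc, provenance = "") {
  if (is.null(names(cc))) stop("cc must be named by FA")
  names(cc) <- trimws(names(cc))
  if (anyNA(cc) || any(!is.finite(cc)) || any(cc <= 0))
    stop("calibration coefficients must be finite and > 0")
  structure(list(cc = cc, provenance = as.character(provenance)),
            class = "cc_set")
}

#' @export
print.cc_set <- function(x, ...) {
  cat(sprintf("Calibration coefficients for %d FAs (range %.3g-%.3g)\n",
              length(x$cc), min(x$cc), max(x$cc)))
  if (nzchar(x$provenance)) cat("  provenance:", x$provenance, "\n")
  invisible(x)
}

# ---- CSV I/O ---------------------------------------------------------------

#' Read a consumer FA table
#'
#' Wide format: first column the subject id, then the declared factor
#' columns, then one numeric column per FA (percent units) — the "raw data"
#' layout used by mixing-model front ends.
#'
#' @param path CSV file path.
#' @param factor_names names of the factor columns (may be empty).
#' @inheritParams consumer_dataset
#' @return a [consumer_dataset()].
#' @export
read_consumer_csv <- function(path, factor_names = character(),
                              check_sums = TRUE, sum_tol = 2) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("consumer CSV needs id plus at least one FA column")
  names(df) <- trimws(names(df))
  id <- as.character(df[[1L]])
  missing_fac <- setdiff(factor_names, names(df))
  if (length(missing_fac))
    stop("factor column(s) not in file: ", paste(missing_fac, collapse = ", "))
  fa_cols <- names(df)[-1L]
  fa_cols <- fa_cols[!fa_cols %in% factor_names]
  if (anyDuplicated(fa_cols))
    stop("duplicate FA name: ", fa_cols[duplicated(fa_cols)][1L])
  fa <- matrix(NA_real_, nrow(df), length(fa_cols),
               dimnames = list(id, fa_cols))
  for (j in seq_along(fa_cols)) {
    v <- df[[fa_cols[j]]]
    num <- suppressWarnings(as.numeric(v))
    if (anyNA(num)) {
      bad <- which(is.na(num))[1L]
      stop(sprintf("non-numeric FA value '%s' at row %d, column '%s'",
                   as.character(v[bad]), bad, fa_cols[j]))
    }
    fa[, j] <- num
  }
  factors <- if (length(factor_names)) df[factor_names] else NULL
  consumer_dataset(fa, subject_id = id, factors = factors,
                   check_sums = check_sums, sum_tol = sum_tol)
}

#' Write a consumer FA table
#'
#' Inverse of [read_consumer_csv()]: id column, factor columns, FA columns.
#' @param x a [consumer_dataset()].
#' @param path output CSV path.
#' @export
write_consumer_csv <- function(x, path) {
  stopifnot(inherits(x, "consumer_dataset"))
  df <- data.frame(subject_id = x$subject_id, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (!is.null(x$factors)) df <- cbind(df, x$factors)
  df <- cbind(df, as.data.frame(x$fa, check.names = FALSE))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write source summaries
#'
#' Wide "means and SDs" layout: one row per source, a `source` column, then
#' `Mean<FA>` / `SD<FA>` column pairs.
#'
#' @param path CSV file path.
#' @param space space the stored values live in.
#' @return `read_source_csv`: list of [source_summary()] objects.
#' @export
read_source_csv <- function(path, space = "prey") {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- trimws(names(df))
  mean_cols <- grep("^Mean", names(df), value = TRUE)
  fa <- sub("^Mean", "", mean_cols)
  sd_cols <- paste0("SD", fa)
  if (!all(sd_cols %in% names(df)))
    stop("missing SD column(s): ",
         paste(setdiff(sd_cols, names(df)), collapse = ", "))
  lapply(seq_len(nrow(df)), function(i) {
    m <- as.numeric(df[i, mean_cols]); names(m) <- fa
    s <- as.numeric(df[i, sd_cols]); names(s) <- fa
    source_summary(df[[1L]][i], m, s, space = space)
  })
}

#' @rdname read_source_csv
#' @param sources list of [source_summary()] objects sharing one FA ordering.
#' @export
write_source_csv <- function(sources, path) {
  fa <- fa_names(sources[[1L]])
  rows <- lapply(sources, function(s) {
    stopifnot(identical(fa_names(s), fa))
    c(list(source = s$source_name),
      as.list(stats::setNames(s$means, paste0("Mean", fa))),
      as.list(stats::setNames(s$sds, paste0("SD", fa))))
  })
  df <- do.call(rbind, lapply(rows, function(r) as.data.frame(r, check.names = FALSE)))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write calibration coefficients
#'
#' Two columns: FA name and multiplier.
#' @param path CSV file path.
#' @param provenance provenance note attached on read.
#' @return `read_cc_csv`: a [cc_set()].
#' @export
read_cc_csv <- function(path, provenance = "") {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  cc_set(stats::setNames(as.numeric(df[[2L]]), df[[1L]]), provenance)
}

#' @rdname read_cc_csv
#' @param x a [cc_set()].
#' @export
write_cc_csv <- function(x, path) {
  stopifnot(inherits(x, "cc_set"))
  write.csv(data.frame(fa = names(x$cc), cc = unname(x$cc)),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---- simulation from summary statistics ------------------------------------

#' Simulate consumer profiles from published means and SDs
#'
#' Published FA tables usually report per-FA mean and SD rather than
#' individual profiles, while the mixing model wants raw consumer rows. This
#' draws each FA independently from Normal(mean_j, sd_j); negative draws are
#' redrawn per cell (truncating at zero would bias the mean downwards more
#' than resampling). Profiles are not renormalised to 100%.
#'
#' @param means,sds named numeric vectors, percent per FA.
#' @param n number of profiles to draw.
#' @param seed integer seed; same seed, same dataset.
#' @param factors optional data.frame (or named list of scalars, recycled)
#'   of factor labels to attach.
#' @param subject_prefix prefix for generated subject ids.
#' @return a [consumer_dataset()] (closure check disabled).
#' @export
simulate_consumers_from_summary <- function(means, sds, n, seed,
                                            factors = NULL,
                                            subject_prefix = "sim") {
  if (length(means) != length(sds)) stop("means and sds must match in length")
  if (any(sds < 0)) stop("sds must be non-negative")
  if (n < 1) stop("n must be >= 1")
  if (is.null(names(means))) names(means) <- paste0("FA", seq_along(means))
  set.seed(as.integer(seed))
  J <- length(means)
  fa <- matrix(rnorm(n * J, rep(means, each = n), rep(sds, each = n)), n, J)
  while (any(neg <- fa < 0)) {
    idx <- which(neg)
    j <- (idx - 1L) %/% n + 1L
    fa[idx] <- rnorm(length(idx), means[j], sds[j])
  }
  colnames(fa) <- names(means)
  if (!is.null(factors) && !is.data.frame(factors))
    factors <- as.data.frame(factors, stringsAsFactors = FALSE)[rep(1L, n), , drop = FALSE]
  consumer_dataset(fa, subject_id = paste0(subject_prefix, seq_len(n)),
                   factors = factors, check_sums = FALSE)
}

# ---- calibration coefficients ---------------------------------------------

#' Compute calibration coefficients from a feeding trial
#'
#' Given consumers at (near-)complete turnover on a known diet, the CC for
#' FA j is the consumer mean divided by the diet-weighted prey mean:
#' `cc_j = mean(consumer FA_j) / sum_d w_d * mu_jd`. A single-prey diet
#' reduces to consumer mean / prey mean.
#'
#' @param consumers a [consumer_dataset()] at equilibrium on the diet.
#' @param sources list of prey-space [source_summary()] objects.
#' @param weights diet mass proportions, one per source, summing to 1
#'   (default: single source, weight 1).
#' @param provenance provenance note for the resulting [cc_set()].
#' @return a [cc_set()].
#' @export
compute_ccs <- function(consumers, sources, weights = NULL, provenance = "") {
  stopifnot(inherits(consumers, "consumer_dataset"))
  if (inherits(sources, "source_summary")) sources <- list(sources)
  if (is.null(weights)) {
    if (length(sources) != 1L) stop("weights required for a mixed diet")
    weights <- 1
  }
  if (length(weights) != length(sources))
    stop("one weight per source required")
  if (abs(sum(weights) - 1) > 1e-6) stop("diet weights must sum to 1")
  fa <- fa_names(consumers)
  for (s in sources) {
    if (!identical(fa_names(s), fa))
      stop("source '", s$source_name, "' FA names do not match consumers")
    if (s$space != "prey") stop("CCs are computed against prey-space sources")
  }
  cons_mean <- colMeans(consumers$fa)
  denom <- Reduce(`+`, Map(function(s, w) w * s$means, sources, as.list(weights)))
  zero <- denom == 0
  if (any(zero & cons_mean > 0))
    stop("diet mean is 0 for FA(s) with nonzero consumer mean: ",
         paste(fa[zero & cons_mean > 0], collapse = ", "),
         " (exclude these FAs upstream)")
  if (any(zero) || any(cons_mean == 0))
    stop("FA(s) with zero mean cannot yield a positive CC: ",
         paste(fa[zero | cons_mean == 0], collapse = ", "))
  cc_set(cons_mean / denom, provenance)
}

#' Take sources to predator space
#'
#' Multiplies each source's per-FA mean and SD by the corresponding CC, so
#' that trophic modification in the mixing model can be set to zero. CCs
#' act as deterministic scalars on the source distribution, hence SDs scale
#' by the same factor. Predator-space summaries are not renormalised: the
#' likelihood operates per tracer, so the 100% closure is not needed.
#'
#' @param sources list of prey-space [source_summary()] objects (a single
#'   summary is accepted).
#' @param cc a [cc_set()] covering every source FA.
#' @return list of predator-space [source_summary()] objects.
#' @export
apply_ccs <- function(sources, cc) {
  stopifnot(inherits(cc, "cc_set"))
  single <- inherits(sources, "source_summary")
  if (single) sources <- list(sources)
  out <- lapply(sources, function(s) {
    if (s$space != "prey") stop("source '", s$source_name, "' already in predator space")
    missing <- setdiff(fa_names(s), names(cc$cc))
    if (length(missing))
      stop("no CC for FA(s): ", paste(missing, collapse = ", "))
    m <- cc$cc[fa_names(s)]
    source_summary(s$source_name, s$means * m, s$sds * m, space = "prey")
  })
  # flip the label after construction: predator space is only producible here
  out <- lapply(out, function(s) { s$space <- "predator"; s })
  if (single) out[[1L]] else out
}

# ---- FA classes and tracer selection ---------------------------------------

#' Default dietary classification of common marine FAs
#'
#' "Dietary" FAs cannot be synthesised by the consumer; "extended dietary"
#' FAs are of both dietary and endogenous origin; "endogenous" FAs mostly
#' reflect the consumer's own metabolism and are excluded from diet
#' estimation. Classification is data, not code: this packaged table covers
#' common marine FAs and can be replaced by any named vector or two-column
#' data.frame.
#'
#' @return named character vector, FA name -> class.
#' @export
default_fa_classes <- function() {
  path <- system.file("extdata", "fa_classes.csv", package = "famix")
  df <- read.csv(path, stringsAsFactors = FALSE)
  stats::setNames(df$class, df$fa)
}

as_fa_class_table <- function(classes) {
  if (is.data.frame(classes))
    classes <- stats::setNames(classes[[2L]], classes[[1L]])
  names(classes) <- trimws(names(classes))
  ok <- classes %in% c("dietary", "extended_dietary", "endogenous")
  if (!all(ok))
    stop("unknown FA class: ", paste(unique(classes[!ok]), collapse = ", "))
  classes
}

#' Select FA tracers for diet estimation
#'
#' An FA is retained iff it (1) exceeds `abundance_min` percent as a grand
#' mean over consumers, (2) is classified dietary or extended dietary, and
#' (3) has a calibration coefficient of at most `cc_max` (a CC above 2
#' means the consumer holds at least twice the prey proportion, suggesting
#' endogenous origin or preferential accrual). Order follows the consumer
#' dataset.
#'
#' @param consumers a [consumer_dataset()].
#' @param cc a [cc_set()].
#' @param classes FA class table (named vector or two-column data.frame);
#'   every consumer FA must have an entry.
#' @param abundance_min grand-mean abundance threshold, percent.
#' @param cc_max maximum admissible CC.
#' @return character vector of retained FA names.
#' @export
select_fas <- function(consumers, cc, classes = default_fa_classes(),
                       abundance_min = 0.5, cc_max = 2) {
  stopifnot(inherits(consumers, "consumer_dataset"), inherits(cc, "cc_set"))
  fa <- fa_names(consumers)
  classes <- as_fa_class_table(classes)
  missing <- setdiff(fa, names(classes))
  if (length(missing))
    stop("no class entry for FA(s): ", paste(missing, collapse = ", "))
  missing_cc <- setdiff(fa, names(cc$cc))
  if (length(missing_cc))
    stop("no CC for FA(s): ", paste(missing_cc, collapse = ", "))
  grand <- colMeans(consumers$fa)
  keep <- grand > abundance_min &
    classes[fa] %in% c("dietary", "extended_dietary") &
    cc$cc[fa] <= cc_max
  out <- fa[keep]
  if (!length(out))
    stop("no FA tracer passes the filters (abundance > ", abundance_min,
         "%, dietary/extended class, CC <= ", cc_max, ")")
  out
}

#' Restrict a consumer dataset to a tracer subset
#'
#' @param consumers a [consumer_dataset()].
#' @param fas FA names to keep, in the order given.
#' @return a [consumer_dataset()] on the subset (closure check off).
#' @export
subset_fas <- function(consumers, fas) {
  missing <- setdiff(fas, fa_names(consumers))
  if (length(missing)) stop("unknown FA(s): ", paste(missing, collapse = ", "))
  consumer_dataset(consumers$fa[, fas, drop = FALSE],
                   subject_id = consumers$subject_id,
                   factors = consumers$factors, check_sums = FALSE)
}
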