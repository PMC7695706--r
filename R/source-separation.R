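# Source separation: mixing models require sources with statistically
# distinguishable FA signatures. One-way PERMANOVA (Anderson's pseudo-F on a
# dissimilarity matrix, label-permutation null) plus corrected pairwise
# comparisons.

#' Pairwise dissimilarity matrix between FA profiles
#'
#' @param x a [consumer_dataset()] or a numeric matrix of profiles (rows =
#'   individuals).
#' @param metric `"bray_curtis"` (default; standard for proportional
#'   composition data) or `"euclidean"`.
#' @return symmetric matrix of pairwise dissimilarities, zero diagonal;
#'   Bray-Curtis values lie in \[0, 1\].
#' @export
distance_matrix <- function(x, metric = c("bray_curtis", "euclidean")) {
  metric <- match.arg(metric)
  m <- if (inherits(x, "consumer_dataset")) x$fa else as.matrix(x)
  if (nrow(m) < 2L) stop("need at least 2 profiles")
  if (metric == "bray_curtis" && any(rowSums(m) == 0))
    stop("all-zero profile: Bray-Curtis undefined")
  d <- vegan::vegdist(m, method = if (metric == "bray_curtis") "bray" else "euclidean")
  as.matrix(d)
}

# pseudo-F for one set of group index vectors on squared dissimilarities
.pseudo_f <- function(d2, idx, ss_total, n, a) {
  ss_within <- 0
  for (g in idx)
    ss_within <- ss_within + sum(d2[g, g]) / (2 * length(g))
  ((ss_total - ss_within) / (a - 1)) / (ss_within / (n - a))
}

#' One-way PERMANOVA
#'
#' Permutational multivariate analysis of variance on a dissimilarity
#' matrix: the total sum of squared dissimilarities is partitioned into
#' among- and within-group components, the pseudo-F statistic is compared to
#' its distribution under random relabeling, and
#' `p = (#\{permuted F >= observed F\} + 1) / (n_permutations + 1)`.
#' Permutations shuffle raw group labels (one-way design only).
#'
#' @param x a [consumer_dataset()], profile matrix, or precomputed
#'   symmetric dissimilarity matrix (detected by zero diagonal and
#'   symmetry).
#' @param groups group label per profile (at least two distinct labels).
#' @param n_permutations number of random label permutations (default 999,
#'   so the smallest attainable p is 0.001).
#' @param seed integer seed for the permutation stream.
#' @param metric dissimilarity metric when `x` holds profiles.
#' @return object of class `permanova_result` with fields `pseudo_F`,
#'   `p_value`, `n_permutations`, `df_between`, `df_within`.
#' @export
permanova <- function(x, groups, n_permutations = 999, seed = 1,
                      metric = c("bray_curtis", "euclidean")) {
  groups <- as.character(groups)
  is_dist <- is.matrix(x) && nrow(x) == ncol(x) &&
    all(abs(diag(x)) < 1e-12) && isTRUE(all.equal(x, t(x), tolerance = 1e-8))
  d <- if (is_dist) x else distance_matrix(x, metric)
  n <- nrow(d)
  if (length(groups) != n) stop("one group label per profile required")
  lev <- unique(groups)
  a <- length(lev)
  if (a < 2L) stop("all group labels identical: nothing to test")
  sizes <- table(groups)
  if (any(sizes < 2L))
    warning("group(s) with a single member: ",
            paste(names(sizes)[sizes < 2L], collapse = ", "))
  d2 <- d^2
  ss_total <- sum(d2) / (2 * n)
  idx <- split(seq_len(n), groups)
  f_obs <- .pseudo_f(d2, idx, ss_total, n, a)
  set.seed(as.integer(seed))
  sizes_v <- lengths(idx)
  f_perm <- vapply(seq_len(n_permutations), function(i) {
    perm <- sample.int(n)
    .pseudo_f(d2, split(perm, rep.int(seq_len(a), sizes_v)), ss_total, n, a)
  }, numeric(1))
  structure(list(pseudo_F = f_obs,
                 p_value = (sum(f_perm >= f_obs) + 1) / (n_permutations + 1),
                 n_permutations = n_permutations,
                 df_between = a - 1L, df_within = n - a,
                 groups = lev),
            class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf("PERMANOVA: pseudo-F(%d, %d) = %.4g, P = %.4g (%d permutations)\n",
              x$df_between, x$df_within, x$pseudo_F, x$p_value,
              x$n_permutations))
  invisible(x)
}

#' Pairwise PERMANOVA with multiple-testing correction
#'
#' One one-way PERMANOVA per unordered pair of groups, each on its own
#' pair-specific seed (`seed + pair index`), with Bonferroni adjustment of
#' the permutation p-values (capped at 1).
#'
#' @inheritParams permanova
#' @param p_adjust correction method passed to [stats::p.adjust()]
#'   (default `"bonferroni"`).
#' @return data.frame with one row per pair: `group1`, `group2`,
#'   `pseudo_F`, `df_between`, `df_within`, `p_raw`, `p_adj` — ready for
#'   CSV export.
#' @export
pairwise_permanova <- function(x, groups, n_permutations = 999, seed = 1,
                               metric = c("bray_curtis", "euclidean"),
                               p_adjust = "bonferroni") {
  groups <- as.character(groups)
  m <- if (inherits(x, "consumer_dataset")) x$fa else as.matrix(x)
  lev <- unique(groups)
  if (length(lev) < 2L) stop("need at least 2 groups")
  pairs <- utils::combn(lev, 2L, simplify = FALSE)
  rows <- vector("list", length(pairs))
  for (i in seq_along(pairs)) {
    pr <- pairs[[i]]
    sel <- groups %in% pr
    res <- permanova(m[sel, , drop = FALSE], groups[sel],
                     n_permutations = n_permutations,
                     seed = as.integer(seed) + i, metric = metric)
    rows[[i]] <- data.frame(group1 = pr[1L], group2 = pr[2L],
                            pseudo_F = res$pseudo_F,
                            df_between = res$df_between,
                            df_within = res$df_within,
                            p_raw = res$p_value,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p_raw, method = p_adjust)
  out
}
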