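test_that("consumer CSV round-trips and preserves shape and factors", {
  set.seed(11)
  fa <- matrix(rgamma(8 * 20, 3), 8, 20)
  fa <- 100 * fa / rowSums(fa)
  colnames(fa) <- paste0("FA", 1:20)
  ds <- consumer_dataset(fa, subject_id = paste0("e", 1:8),
                         factors = data.frame(day = rep(c("0", "21"), 4)))
  expect_equal(nrow(ds$fa), 8)
  expect_equal(ncol(ds$fa), 20)
  expect_equal(ds$factor_names, "day")

  path <- withr::local_tempfile(fileext = ".csv")
  write_consumer_csv(ds, path)
  back <- read_consumer_csv(path, factor_names = "day")
  expect_equal(back$fa, ds$fa, tolerance = 1e-12)
  expect_equal(back$subject_id, ds$subject_id)
  expect_equal(back$factors$day, ds$factors$day)
})

test_that("closure constraint rejects bad row sums but spares transformed data", {
  fa <- matrix(c(150, 100), 1, 2, dimnames = list("x", c("a", "b")))
  expect_error(consumer_dataset(fa), "sums to 250")
  expect_silent(consumer_dataset(fa, check_sums = FALSE))
  # within the default +/- 2 point tolerance
  fa2 <- matrix(c(60, 41.5), 1, 2, dimnames = list("x", c("a", "b")))
  expect_s3_class(consumer_dataset(fa2), "consumer_dataset")
})

test_that("consumer CSV parse errors name the offending cell", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,FAa,FAb", "s1,50,oops"), path)
  expect_error(read_consumer_csv(path), "row 1, column 'FAb'")
  writeLines(c("id,FAa,FAa", "s1,50,50"), path)
  expect_error(read_consumer_csv(path), "duplicate FA")
})

test_that("source and CC CSVs round-trip", {
  s <- two_source_setup()$prey
  sp <- withr::local_tempfile(fileext = ".csv")
  write_source_csv(s, sp)
  back <- read_source_csv(sp)
  expect_equal(back[[1]]$means, s[[1]]$means, tolerance = 1e-12)
  expect_equal(back[[2]]$sds, s[[2]]$sds, tolerance = 1e-12)
  expect_equal(back[[1]]$space, "prey")

  cc <- cc_set(c(`18:1n-9` = 1.3, `22:6n-3` = 0.8), provenance = "trial")
  cp <- withr::local_tempfile(fileext = ".csv")
  write_cc_csv(cc, cp)
  expect_equal(read_cc_csv(cp)$cc, cc$cc, tolerance = 1e-12)
})

test_that("simulation from summary statistics honours its contract", {
  # degenerate: zero SDs reproduce the means exactly
  m <- c(a = 40, b = 60)
  d0 <- simulate_consumers_from_summary(m, c(a = 0, b = 0), n = 5, seed = 1)
  expect_true(all(t(d0$fa) == m))

  # CLT: sample means within 3 sd/sqrt(n) of inputs
  d <- simulate_consumers_from_summary(c(a = 50, b = 50), c(a = 5, b = 5),
                                       n = 1000, seed = 42)
  expect_true(all(abs(colMeans(d$fa) - 50) < 3 * 5 / sqrt(1000)))
  expect_true(all(d$fa >= 0))

  # seeded determinism
  d2 <- simulate_consumers_from_summary(c(a = 50, b = 50), c(a = 5, b = 5),
                                        n = 1000, seed = 42)
  expect_identical(d$fa, d2$fa)

  expect_error(
    simulate_consumers_from_summary(c(a = 1), c(a = -1), n = 2, seed = 1),
    "non-negative")
})

test_that("simulation recovers input SDs within sampling error", {
  d <- simulate_consumers_from_summary(c(a = 50), c(a = 5), n = 2000, seed = 7)
  expect_equal(sd(d$fa[, "a"]), 5, tolerance = 0.1)
})

test_that("calibration coefficients divide consumer by diet-weighted prey means", {
  prey <- source_summary("p1", c(x = 10, y = 8), c(x = 1, y = 1))
  cons <- consumer_dataset(matrix(c(10, 8), 1, 2, dimnames = list("c", c("x", "y"))),
                           check_sums = FALSE)
  expect_equal(unname(compute_ccs(cons, prey)$cc), c(1, 1))

  # consumer mean 12% over a sole prey mean of 8% gives cc = 1.5
  prey8 <- source_summary("p8", c(x = 8), c(x = 1))
  cons2 <- consumer_dataset(matrix(12, 1, 1, dimnames = list("c", "x")),
                            check_sums = FALSE)
  expect_equal(unname(compute_ccs(cons2, prey8)$cc), 1.5)

  # mixed diet: weighted denominator 0.6*10 + 0.4*5 = 8, consumer 8 -> cc 1
  preyA <- source_summary("A", c(x = 10), c(x = 1))
  preyB <- source_summary("B", c(x = 5), c(x = 1))
  consM <- consumer_dataset(matrix(8, 1, 1, dimnames = list("c", "x")),
                            check_sums = FALSE)
  expect_equal(unname(compute_ccs(consM, list(preyA, preyB),
                                  weights = c(0.6, 0.4))$cc), 1)

  # zero diet mean with nonzero consumer mean is a hard error
  prey0 <- source_summary("z", c(x = 0), c(x = 0))
  expect_error(compute_ccs(consM, prey0), "exclude these FAs upstream")
})

test_that("apply_ccs scales means and SDs and only runs prey -> predator", {
  s <- source_summary("s", c(x = 10), c(x = 2))
  out <- apply_ccs(s, cc_set(c(x = 1.5)))
  expect_equal(unname(out$means), 15)
  expect_equal(unname(out$sds), 3)
  expect_equal(out$space, "predator")
  expect_error(apply_ccs(out, cc_set(c(x = 1))), "already in predator space")
  expect_error(apply_ccs(s, cc_set(c(other = 1))), "no CC for FA")

  ident <- apply_ccs(s, cc_set(c(x = 1)))
  expect_equal(ident$means, s$means)
  expect_equal(ident$sds, s$sds)
})

test_that("CC round trip: consumer built as the CC image recovers the CCs", {
  set.seed(21)
  fa <- paste0("FA", 1:6)
  prey <- source_summary("prey", stats::setNames(rgamma(6, 5) + 1, fa),
                         stats::setNames(runif(6, 0.5, 2), fa))
  true_cc <- cc_set(stats::setNames(exp(rnorm(6, 0, 0.3)), fa))
  cons <- consumer_dataset(matrix(prey$means * true_cc$cc, 1, 6,
                                  dimnames = list("c", fa)),
                           check_sums = FALSE)
  rec <- compute_ccs(cons, prey)
  expect_equal(rec$cc, true_cc$cc, tolerance = 1e-12)
  # and applying the recovered CCs makes the source equal the consumer
  pred <- apply_ccs(prey, rec)
  expect_equal(unname(pred$means), unname(cons$fa[1, ]), tolerance = 1e-12)
})

test_that("tracer selection applies the abundance, class and CC gates", {
  fa <- c("d_low", "d_highcc", "ext_ok", "endo", "d_ok")
  m <- matrix(c(0.4, 3.0, 1.0, 5.0, 2.0), 2, 5, byrow = TRUE,
              dimnames = list(NULL, fa))
  cons <- consumer_dataset(m, check_sums = FALSE)
  cc <- cc_set(stats::setNames(c(1, 2.3, 1.2, 1, 0.9), fa))
  classes <- stats::setNames(
    c("dietary", "dietary", "extended_dietary", "endogenous", "dietary"), fa)
  expect_equal(select_fas(cons, cc, classes), c("ext_ok", "d_ok"))

  # boundary behaviour: abundance must exceed 0.5 strictly, cc = 2 is kept
  cc2 <- cc_set(stats::setNames(c(1, 2, 1.2, 1, 0.9), fa))
  m2 <- m; m2[, "d_low"] <- 0.5
  kept <- select_fas(consumer_dataset(m2, check_sums = FALSE), cc2, classes)
  expect_equal(kept, c("d_highcc", "ext_ok", "d_ok"))
  expect_false("d_low" %in% kept)

  expect_error(select_fas(cons, cc, classes[-1]), "no class entry")
  none <- stats::setNames(rep("endogenous", 5), fa)
  expect_error(select_fas(cons, cc, none), "no FA tracer passes")
})

test_that("raising the abundance threshold never grows the retained set", {
  set.seed(33)
  fa <- paste0("FA", 1:12)
  for (rep in 1:5) {
    m <- matrix(rgamma(6 * 12, 1.5), 6, 12, dimnames = list(NULL, fa))
    cons <- consumer_dataset(m, check_sums = FALSE)
    cc <- cc_set(stats::setNames(runif(12, 0.5, 1.9), fa))
    classes <- all_dietary(fa)
    prev <- NULL
    for (thr in c(0.2, 0.5, 1, 2)) {
      cur <- tryCatch(select_fas(cons, cc, classes, abundance_min = thr),
                      error = function(e) character())
      if (!is.null(prev)) expect_true(all(cur %in% prev))
      prev <- cur
    }
  }
})

test_that("default FA class table covers the standard marine FAs", {
  cls <- default_fa_classes()
  expect_true(all(c("22:6n-3", "20:5n-3") %in% names(cls)))
  expect_equal(unname(cls["16:0"]), "endogenous")
  expect_true(all(cls %in% c("dietary", "extended_dietary", "endogenous")))
})
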