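single_pop_template <- function(Ne = 1000) {
  # minimal one-population template used for degenerate-case checks
  tpl <- get_template("TT1")
  tpl$id <- "ONE"
  tpl$params <- tpl$params[tpl$params$name == "Ne_TT", ]
  tpl$k <- 1L
  tpl$par_names <- "Ne_TT"
  tpl$lower <- tpl$params$lower
  tpl$upper <- tpl$params$upper
  tpl$log10 <- tpl$params$log10
  tpl$constraints <- function(th) NULL
  tpl$obs_pops <- "A"
  tpl$build <- function(theta) {
    demog_model(data.frame(name = "A", Ne = unname(theta[["Ne_TT"]])))
  }
  tpl$encode_fast <- function(theta) {
    list(Ne0 = unname(theta[["Ne_TT"]]), mig = 0, ev_time = double(),
         ev_kind = integer(), ev_a = integer(), ev_b = integer(),
         ev_par = double(), pops = "A")
  }
  tpl
}

test_that("the expected SFS of two haplotypes is a point mass on singletons", {
  tpl <- single_pop_template()
  p <- expected_sfs(tpl, c(Ne_TT = 1000), c(A = 2), n_sims = 100, seed = 1)
  expect_equal(p$counts[!p$mask], 1)
  p2 <- expected_sfs(tpl, c(Ne_TT = 1000), c(A = 2), n_sims = 100, seed = 1)
  expect_identical(p$counts, p2$counts)
})

test_that("a symmetric two-population split has an axis-symmetric spectrum", {
  bg <- scan_background()
  tpl <- get_template("TT1")
  # symmetric case: TT splits from NAW but both observed pops get equal
  # sizes and drift is dominated by the shared deep structure
  m <- demog_model(
    data.frame(name = c("A", "B"), Ne = c(5000, 5000)),
    data.frame(time = 4000, kind = "split", pop = "B", dest = "A",
               param = NA))
  enc <- coalscan:::encode_model(m)
  counts <- coalscan:::cpp_sfs_counts(enc$Ne0, enc$mig, enc$ev_time,
                                      enc$ev_kind,
                                      enc$ev_a, enc$ev_b, enc$ev_par,
                                      c(6L, 6L), 200000L, 5)
  p <- array(counts / sum(counts), dim = c(7, 7))
  expect_lt(max(abs(p - t(p))), 0.01)
})

test_that("composite and saturated likelihoods match hand arithmetic", {
  obs1 <- coalscan:::new_sfs(array(c(0, 10, 0), dim = 3), "A",
                             folded = FALSE)
  p1 <- coalscan:::new_sfs(array(c(0, 1, 0), dim = 3), "A", folded = FALSE)
  expect_equal(composite_loglik(obs1, p1), 0)
  expect_equal(saturated_loglik(obs1), 0)

  obs2 <- coalscan:::new_sfs(array(c(0, 5, 5, 0), dim = 4), "A", FALSE)
  p2 <- coalscan:::new_sfs(array(c(0, 0.5, 0.5, 0), dim = 4), "A", FALSE)
  expect_equal(composite_loglik(obs2, p2), 10 * log10(0.5),
               tolerance = 1e-12)
  expect_equal(saturated_loglik(obs2), 10 * log10(0.5), tolerance = 1e-12)
  expect_error(composite_loglik(obs1, p2), "dimensions differ")
})

test_that("zero-probability cells are floored so likelihoods stay finite", {
  tpl <- single_pop_template()
  p <- expected_sfs(tpl, c(Ne_TT = 1000), c(A = 6), n_sims = 50, seed = 2)
  open <- !p$mask
  expect_true(all(p$counts[open] > 0))
  expect_equal(sum(p$counts[open]), 1)
  # a cell observed but unsimulated still yields a finite likelihood
  obs <- coalscan:::new_sfs(array(c(0, rep(2, 5), 0), dim = 7), "A", FALSE)
  expect_true(is.finite(composite_loglik(obs, p)))
})

test_that("composite likelihood is invariant under consistent permutation", {
  set.seed(3)
  m <- c(0, rpois(5, 20), 0)
  pr <- c(0, runif(5), 0)
  pr[2:6] <- pr[2:6] / sum(pr[2:6])
  obs <- coalscan:::new_sfs(array(m, dim = 7), "A", FALSE)
  p <- coalscan:::new_sfs(array(pr, dim = 7), "A", FALSE)
  l1 <- composite_loglik(obs, p)
  perm <- c(1, 4, 2, 6, 3, 5, 7)
  obs2 <- coalscan:::new_sfs(array(m[perm], dim = 7), "A", FALSE)
  p2 <- coalscan:::new_sfs(array(pr[perm], dim = 7), "A", FALSE)
  expect_equal(composite_loglik(obs2, p2), l1, tolerance = 1e-12)
})

test_that("fitting is reproducible and respects parameter bounds", {
  tpl <- single_pop_template()
  m <- demog_model(data.frame(name = "A", Ne = 5000))
  sim <- sim_genotypes(m, c(A = 4), n_loci = 2000, locus_length = 1000,
                       seed = 17, mode = "snp")
  obs <- build_sfs(sim$geno, "A")
  obs$pops <- "A"
  f1 <- fit_model(obs, tpl, n_cycles_initial = 10, n_cycles_total = 14,
                  n_sims = 2000, n_runs = 3, seed = 5,
                  n_sims_initial = 500, n_sims_final = 5000)
  f2 <- fit_model(obs, tpl, n_cycles_initial = 10, n_cycles_total = 14,
                  n_sims = 2000, n_runs = 3, seed = 5,
                  n_sims_initial = 500, n_sims_final = 5000)
  expect_equal(tidy(f1), tidy(f2))
  est <- tidy(f1)$Ne_TT
  expect_true(all(est >= 1e2 & est <= 1e6))
  expect_true(all(!is.na(tidy(f1)$delta)))
})

test_that("model ranking is by delta with AIC tie-breaks toward fewer parameters", {
  mk <- function(id, k, lnL, fp = "x") {
    structure(list(results = tibble::tibble(model_id = id, run = 1,
                                            lnL_est = lnL,
                                            lnL_obs = 0,
                                            delta = -lnL,
                                            AIC = 2 * k - 2 * log(10) * lnL),
                   model_id = id, k = k, lnL_obs = 0, fingerprint = fp,
                   params = character(), folded = FALSE,
                   settings = list()), class = "sfs_fit")
  }
  fits <- list(mk("A", 4, -100), mk("B", 2, -100), mk("C", 2, -90))
  r <- compare_models(fits)
  expect_identical(r$model_id, c("C", "B", "A"))
  expect_error(compare_models(list(mk("A", 2, -1, "x"),
                                   mk("B", 2, -1, "y"))),
               "same observed spectrum")
})

test_that("delta is non-negative up to Monte-Carlo noise in a well-specified fit", {
  tpl <- single_pop_template()
  m <- demog_model(data.frame(name = "A", Ne = 2000))
  sim <- sim_genotypes(m, c(A = 4), n_loci = 3000, locus_length = 1000,
                       seed = 23, mode = "snp")
  obs <- build_sfs(sim$geno, "A")
  obs$pops <- "A"
  f <- fit_model(obs, tpl, n_cycles_initial = 10, n_cycles_total = 14,
                 n_sims = 2000, n_runs = 2, seed = 9,
                 n_sims_initial = 500, n_sims_final = 20000)
  expect_gt(tidy(f)$delta[1], -5)
})

test_that("parametric bootstrap intervals behave and are reproducible", {
  tpl <- single_pop_template()
  m <- demog_model(data.frame(name = "A", Ne = 3000))
  sim <- sim_genotypes(m, c(A = 4), n_loci = 2000, locus_length = 1000,
                       seed = 31, mode = "snp")
  obs <- build_sfs(sim$geno, "A")
  obs$pops <- "A"
  f <- fit_model(obs, tpl, n_cycles_initial = 8, n_cycles_total = 12,
                 n_sims = 1000, n_runs = 2, seed = 3,
                 n_sims_initial = 300, n_sims_final = 5000)
  ci <- bootstrap_ci(f, tpl, c(A = 4), S = 2000, n_boot = 4,
                     n_runs_per_boot = 1, seed = 11,
                     n_cycles_initial = 6, n_cycles_total = 9,
                     n_sims = 1000, n_sims_initial = 300,
                     n_sims_final = 2000)
  expect_identical(nrow(ci), 1L)
  expect_true(ci$lower <= ci$upper)
  ci2 <- bootstrap_ci(f, tpl, c(A = 4), S = 2000, n_boot = 4,
                      n_runs_per_boot = 1, seed = 11,
                      n_cycles_initial = 6, n_cycles_total = 9,
                      n_sims = 1000, n_sims_initial = 300,
                      n_sims_final = 2000)
  expect_equal(ci$lower, ci2$lower)
  expect_equal(ci$upper, ci2$upper)
  expect_error(bootstrap_ci(f, tpl, c(A = 4), S = 100, n_boot = 1),
               "n_boot")
})
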