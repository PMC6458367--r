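test_that("log multivariate beta matches exact factorial values", {
  expect_equal(log_multivariate_beta(c(1, 1)), 0)
  # B(7,13) = 6! 12! / 19!, B(3,6) = 2! 5! / 8!
  expect_equal(log_multivariate_beta(c(7, 13)),
               log(factorial(6) * factorial(12) / factorial(19)))
  expect_equal(log_multivariate_beta(c(7, 13)), -12.77342, tolerance = 1e-6)
  expect_equal(log_multivariate_beta(c(3, 6)), -5.12396, tolerance = 1e-5)
  expect_error(log_multivariate_beta(c(1, 0)), "positive")
  expect_error(log_multivariate_beta(c(-1, 2)), "positive")
})

test_that("Stirling expansion agrees with the exact log-beta for large components", {
  expect_equal(stirling_log_beta(c(100, 100)),
               log_multivariate_beta(c(100, 100)),
               tolerance = 1e-6)
  expect_lt(abs(stirling_log_beta(c(1000, 2000, 3000)) -
                  log_multivariate_beta(c(1000, 2000, 3000))) /
              abs(log_multivariate_beta(c(1000, 2000, 3000))), 1e-8)
  # small arguments are merely inaccurate, not an error
  expect_true(is.finite(stirling_log_beta(c(1, 1))))
})

test_that("AIC/BIC reproduce the worked example in both counting modes", {
  ct0 <- count_transitions(worked_trajs(), 0)
  ct1 <- count_transitions(worked_trajs(), 1)
  a0 <- aic_bic(ct0, "literal")
  expect_equal(a0$AIC, 24.91451, tolerance = 1e-6)
  expect_equal(a0$k, 1)
  a1 <- aic_bic(ct1, "literal")
  expect_equal(a1$AIC, 24.16223, tolerance = 1e-6)
  expect_equal(a1$k, 2)
  expect_equal(a1$BIC - (a1$AIC - 2 * a1$k), log(18) * 2)
  a1c <- aic_bic(ct1, "contexts")
  expect_equal(a1c$k, 3)
  expect_equal(a1c$AIC, 26.16223, tolerance = 1e-6)
  # empty table: zero deviance, penalty only
  expect_equal(aic_bic(empty_count_table(worked_alphabet(), 0), "literal")$AIC, 2)
  # literal counting is undefined for merged tables
  m <- merge_contexts(ct1, memory_spec(partition = list("-", c("+", "."))))
  expect_error(aic_bic(m, "literal"), "undefined")
  expect_equal(aic_bic(m, "contexts")$k, 2)
})

test_that("AIC deviance term is nonnegative and non-increasing in h", {
  set.seed(53)
  for (i in 1:6) {
    ts <- random_trajs()
    devs <- vapply(0:3, function(h) {
      ab <- aic_bic(count_transitions(ts, h), "literal")
      ab$AIC - 2 * ab$k
    }, numeric(1L))
    expect_true(all(devs >= -1e-10))
    expect_true(all(diff(devs) <= 1e-10))
  }
})

test_that("marginal criteria match frozen values and degenerate cases", {
  ct0 <- count_transitions(worked_trajs(), 0)
  expect_equal(marginal_criteria(ct0)$nLML, 25.54684, tolerance = 1e-6)
  expect_equal(marginal_criteria(ct0)$nLML,
               -2 * log(factorial(6) * factorial(12) / factorial(19)))

  e <- empty_count_table(worked_alphabet())
  me <- marginal_criteria(e)
  expect_equal(me$nLML, 0)
  expect_equal(me$nLPD, 0)
  expect_equal(me$nLPPD, 0)

  # single trajectory: the pointwise sum collapses onto the LPD
  one <- parse_trajectories("+-++-++", worked_alphabet())
  m1 <- marginal_criteria(count_transitions(one, 0))
  expect_equal(m1$nLPPD, m1$nLPD)
})

test_that("LOO matches its exact-factorial value and reduces to nLML at J = 1", {
  ct0 <- count_transitions(worked_trajs(), 0)
  expect_equal(loo(ct0), 24.27775, tolerance = 1e-5)
  lb <- function(x) sum(lgamma(x)) - lgamma(sum(x))
  expect_equal(loo(ct0),
               -2 * ((lb(c(7, 13)) - lb(c(5, 8))) +
                       (lb(c(7, 13)) - lb(c(3, 6)))))

  one <- parse_trajectories("+-++-++", worked_alphabet())
  ct <- count_transitions(one, 1)
  expect_equal(loo(ct), marginal_criteria(ct)$nLML)
})

test_that("LHO matches its defining two-block expression and is symmetric for identical halves", {
  ct1 <- count_transitions(worked_trajs(), 1)
  lb <- function(x) sum(lgamma(x)) - lgamma(sum(x))
  n1 <- ct1$per_traj[[1]]
  n2 <- ct1$per_traj[[2]]
  keys <- rownames(ct1$pooled)
  row_of <- function(m, k) if (k %in% rownames(m)) m[k, ] else c(0, 0)
  expected <- 0
  for (k in keys) {
    a <- row_of(n1, k); b <- row_of(n2, k)
    expected <- expected +
      (lb(b + a + 1) - lb(b + 1)) + (lb(a + b + 1) - lb(a + 1))
  }
  expect_equal(lho(ct1), -2 * expected)

  twin <- parse_trajectories("+-++\n+-++", worked_alphabet())
  ctt <- count_transitions(twin, 1)
  halves <- split_half(ctt)
  expect_identical(halves$first$pooled, halves$second$pooled)
  expect_equal(lho(ctt), loo(ctt))  # J = 2: the two splits coincide

  expect_error(lho(count_transitions(parse_trajectories("+", worked_alphabet()), 1)),
               "J >= 2")
})

test_that("closed-form LML, LPPD, LOO and LHO match the sequential urn oracle", {
  set.seed(61)
  for (i in 1:40) {
    ts <- random_trajs()
    for (h in 0:2) {
      for (a in c(1, 0.5)) {
        ct <- count_transitions(ts, h)
        r <- criteria_core(ct, a, which = c("nLML", "nLPPD", "LOO"))
        expect_equal(r$nLML, oracle_nLML(ts, h, a), tolerance = 1e-11)
        expect_equal(r$nLPPD, oracle_nLPPD(ts, h, a), tolerance = 1e-11)
        expect_equal(r$LOO, oracle_LOO(ts, h, a), tolerance = 1e-11)
        if (length(ts) >= 2L)
          expect_equal(lho(ct, a), oracle_LHO(ts, h, a), tolerance = 1e-11)
      }
    }
  }
})

test_that("WAIC effective sizes match an independent term-by-term summation", {
  ct <- count_transitions(worked_trajs(), 1)
  a <- 1
  # direct double loop over trajectories j and contexts x, straight from the
  # trigamma form
  kw2 <- 0
  for (j in 1:2) {
    ptj <- ct$per_traj[[j]]
    for (x in rownames(ptj)) {
      Nx <- ct$pooled[x, ]
      Nxj <- ptj[x, ]
      kw2 <- kw2 + sum(Nxj^2 * trigamma(a + Nx)) -
        sum(Nxj)^2 * trigamma(sum(Nx) + 2 * a)
    }
  }
  expect_equal(waic(ct, a, variant = 2)$k_eff, kw2)

  # digamma form of the WAIC1 penalty
  lppd <- -marginal_criteria(ct)$nLPPD / 2
  kw1 <- 2 * lppd -
    2 * (sum(ct$pooled * digamma(ct$pooled + 1)) -
           sum(rowSums(ct$pooled) * digamma(rowSums(ct$pooled) + 2)))
  expect_equal(waic(ct, a, variant = 1)$k_eff, kw1)

  e <- empty_count_table(worked_alphabet())
  expect_equal(waic(e)$WAIC, 0)
  expect_equal(waic(e)$k_eff, 0)
})

test_that("DIC uses the posterior-mean plug-in deviance", {
  ct0 <- count_transitions(worked_trajs(), 0)
  plug <- -2 * (6 * log(7 / 20) + 12 * log(13 / 20))
  d1 <- dic(ct0, variant = 1)
  d2 <- dic(ct0, variant = 2)
  expect_equal(d1$DIC - 2 * d1$k_eff, plug)
  expect_equal(d2$DIC - 2 * d2$k_eff, plug)
  e <- empty_count_table(worked_alphabet())
  expect_equal(dic(e)$DIC, 0)
  expect_equal(dic(e)$k_eff, 0)
})

test_that("posterior-sampling Monte Carlo confirms nLPD, the WAIC1 expectation and k_DIC2", {
  ct0 <- count_transitions(worked_trajs(), 0)
  N <- ct0$pooled[1, ]
  set.seed(67)
  ll <- mc_loglik_draws(N, alpha = 1, R = 1e5)

  # nLPD: -2 log E_post[Pr(N | p)]
  mx <- max(ll)
  w <- exp(ll - mx)
  lpd_mc <- mx + log(mean(w))
  se_lpd <- stats::sd(w) / (mean(w) * sqrt(length(w)))
  expect_lt(abs(marginal_criteria(ct0)$nLPD - (-2 * lpd_mc)), 3 * 2 * se_lpd)

  # WAIC1 expectation term: E_post[log Pr(N | p)]
  e_mc <- mean(ll)
  se_e <- stats::sd(ll) / sqrt(length(ll))
  lppd <- -marginal_criteria(ct0)$nLPPD / 2
  k1 <- waic(ct0, variant = 1)$k_eff
  expect_lt(abs((lppd - k1 / 2) - e_mc), 3 * se_e)

  # k_DIC2 = 2 var_post[log Pr(N | p)]
  v_mc <- stats::var(ll)
  se_v <- stats::sd((ll - mean(ll))^2) / sqrt(length(ll))
  expect_lt(abs(dic(ct0, variant = 2)$k_eff - 2 * v_mc), 3 * 2 * se_v)
})

test_that("evaluate_all assembles one row per candidate with consistent columns", {
  ts <- worked_trajs()
  r <- evaluate_all(ts, 0:1)
  expect_s3_class(r, "criteria_report")
  expect_equal(r$AIC, c(24.91451, 24.16223), tolerance = 1e-6)
  expect_equal(r$k_param, c(1, 2))
  expect_equal(r$LOO[1], 24.27775, tolerance = 1e-5)

  # variable-length row uses context counting (two blocks, M - 1 = 1 each)
  specs <- list(memory_spec(order = 0), memory_spec(order = 1),
                memory_spec(partition = list("-", c("+", "."))))
  r3 <- evaluate_all(ts, specs)
  expect_equal(nrow(r3), 3L)
  expect_equal(r3$k_param[3], 2)

  expect_error(evaluate_all(ts, list()), "at least one")
  one <- parse_trajectories("+-++-++", worked_alphabet())
  expect_warning(r1 <- evaluate_all(one, 0:1), "LHO")
  expect_false("LHO" %in% names(r1))
})

test_that("reports round-trip through CSV and JSON", {
  r <- evaluate_all(worked_trajs(), 0:1)
  csv <- withr::local_tempfile(fileext = ".csv")
  write_report_csv(r, csv)
  back <- utils::read.csv(csv)
  expect_equal(back$LOO, r$LOO)
  expect_equal(names(back), names(r))
  js <- withr::local_tempfile(fileext = ".json")
  write_report_json(r, js)
  parsed <- jsonlite::fromJSON(js)
  expect_equal(parsed$J, 2L)
  expect_equal(parsed$models$AIC, r$AIC)
})

test_that("select_model takes the argmin and breaks ties toward simplicity", {
  ts <- worked_trajs()
  r <- evaluate_all(ts, 0:1)
  expect_identical(select_model(r, "AIC")$order, 1L)
  expect_error(select_model(r, "nope"), "not present")

  # force a tie: identical values should pick the fewer-parameter model
  r$AIC <- c(10, 10)
  expect_identical(select_model(r, "AIC")$order, 0L)
})

test_that("LOO grows insensitive to the prior as counts scale up", {
  ts <- worked_trajs()
  gaps <- vapply(c(1, 10, 100), function(f) {
    ct <- count_transitions(ts, 1)
    ct$pooled <- ct$pooled * f
    ct$per_traj <- lapply(ct$per_traj, function(m) m * f)
    abs(loo(ct, 1) - loo(ct, 0.5)) / f
  }, numeric(1L))
  expect_true(all(diff(gaps) < 0))
})
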