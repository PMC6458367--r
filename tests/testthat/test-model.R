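test_that("MLE reproduces the worked-example estimates exactly", {
  ct1 <- count_transitions(worked_trajs(), 1)
  p <- mle(ct1)
  expect_equal(p["-", ], c("-" = 1 / 5, "+" = 4 / 5))
  expect_equal(p["+", ], c("-" = 5 / 11, "+" = 6 / 11))
  expect_equal(p[".", ], c("-" = 0, "+" = 1))

  ct0 <- count_transitions(worked_trajs(), 0)
  expect_equal(unname(mle(ct0)[1, ]), c(1 / 3, 2 / 3))
})

test_that("MLE maximizes the context likelihood on the M = 2 simplex", {
  set.seed(41)
  for (i in 1:5) {
    ts <- random_trajs(M = 2)
    ct <- count_transitions(ts, 1)
    phat <- mle(ct)
    grid <- seq(0.001, 0.999, by = 0.001)
    for (x in rownames(phat)) {
      N <- ct$pooled[x, ]
      ll <- function(p1) N[1] * log(p1) + N[2] * log(1 - p1)
      best_grid <- grid[which.max(ll(grid))]
      expect_lt(abs(best_grid - phat[x, 1]), 1e-3 + 1 / (2 * 1000))
      expect_gte(ll(min(max(phat[x, 1], 1e-12), 1 - 1e-12)), max(ll(grid)))
    }
  }
})

test_that("posterior parameters and means follow conjugate updating", {
  ct1 <- count_transitions(worked_trajs(), 1)
  post <- posterior_params(ct1, 1)
  expect_equal(post["-", ], c("-" = 2, "+" = 5))
  expect_equal(post["+", ], c("-" = 6, "+" = 7))
  expect_equal(post[".", ], c("-" = 1, "+" = 3))
  # Jeffreys' prior is just a different increment
  expect_equal(posterior_params(ct1, 0.5)["-", ], c("-" = 1.5, "+" = 4.5))

  pm <- posterior_mean(ct1, 1)
  expect_equal(pm["-", ], c("-" = 2 / 7, "+" = 5 / 7))
  expect_true(all(abs(rowSums(pm) - 1) < 1e-12))

  # no data: posterior is the prior
  e <- empty_count_table(worked_alphabet())
  expect_identical(nrow(posterior_params(e, 1)), 0L)

  # large-count limit approaches the MLE
  big <- ct1
  big$pooled <- ct1$pooled * 1e6
  expect_lt(max(abs(posterior_mean(big, 1) - mle(big))), 1e-5)
})

test_that("log-likelihood matches the worked example and handles zeros", {
  ct1 <- count_transitions(worked_trajs(), 1)
  ct0 <- count_transitions(worked_trajs(), 0)
  expect_equal(log_likelihood(ct1, mle(ct1)), -10.08111, tolerance = 1e-6)
  expect_equal(log_likelihood(ct0, mle(ct0)), -11.45726, tolerance = 1e-6)
  expect_equal(log_likelihood(empty_count_table(worked_alphabet()),
                              matrix(numeric(0), 0, 2)), 0)
  # observed transition with zero probability flags -Inf
  bad <- mle(ct0)
  bad[1, ] <- c(1, 0)
  expect_warning(ll <- log_likelihood(ct0, bad), "-Inf")
  expect_identical(ll, -Inf)
})

test_that("max log-likelihood is non-decreasing in the order h", {
  set.seed(43)
  for (i in 1:6) {
    ts <- random_trajs()
    lls <- vapply(0:3, function(h) {
      ct <- count_transitions(ts, h)
      log_likelihood(ct, mle(ct))
    }, numeric(1L))
    expect_true(all(diff(lls) >= -1e-10))
  }
})

test_that("merge_contexts pools blocks and conserves counts", {
  ct1 <- count_transitions(worked_trajs(), 1)
  spec <- memory_spec(partition = list("-", c("+", ".")))
  m <- merge_contexts(ct1, spec)
  expect_equal(m$pooled["-", ], c("-" = 1, "+" = 4))
  expect_equal(m$pooled["+,.", ], c("-" = 5, "+" = 8))
  expect_equal(sum(m$pooled), sum(ct1$pooled))

  # identity partition leaves counts unchanged (up to row order)
  idp <- memory_spec(partition = as.list(rownames(ct1$pooled)))
  mi <- merge_contexts(ct1, idp)
  expect_equal(mi$pooled[rownames(ct1$pooled), ], ct1$pooled)

  # one-block partition equals the h = 0 counts
  all1 <- memory_spec(partition = list(rownames(ct1$pooled)))
  ma <- merge_contexts(ct1, all1)
  expect_equal(unname(ma$pooled[1, ]),
               unname(count_transitions(worked_trajs(), 0)$pooled[1, ]))

  expect_error(merge_contexts(ct1, memory_spec(partition = list("-"))),
               "does not cover")
})

test_that("merged MLE equals the shared-parameter pooled ratio", {
  set.seed(47)
  for (i in 1:5) {
    ts <- random_trajs(M = 2)
    ct <- count_transitions(ts, 1)
    keys <- rownames(ct$pooled)
    if (length(keys) < 2L) next
    blocks <- split(keys, rep(1:2, length.out = length(keys)))
    spec <- memory_spec(partition = unname(blocks))
    m <- merge_contexts(ct, spec)
    for (b in seq_along(blocks)) {
      pooled <- colSums(ct$pooled[blocks[[b]], , drop = FALSE])
      expect_equal(unname(mle(m)[b, ]), unname(pooled / sum(pooled)))
    }
  }
})

test_that("memory specs validate and round-trip through JSON", {
  expect_error(memory_spec(), "exactly one")
  expect_error(memory_spec(order = -1), "nonnegative")
  expect_error(memory_spec(partition = list(c("-", "+"), "+")), "disjoint")

  s1 <- memory_spec(order = 2)
  expect_identical(memory_spec_from_json(memory_spec_to_json(s1))$order, 2L)
  s2 <- memory_spec(partition = list("-", c("+", ".")))
  s2b <- memory_spec_from_json(memory_spec_to_json(s2))
  expect_identical(s2b$partition, s2$partition)
  expect_identical(s2b$h_base, 1L)
})

test_that("fit_markov ties the pieces together with standard S3 methods", {
  fit <- fit_markov(worked_text(), order = 1, alphabet = worked_alphabet())
  expect_s3_class(fit, "markov_fit")
  expect_equal(coef(fit)["-", ], c("-" = 2 / 7, "+" = 5 / 7))
  expect_equal(coef(fit, "mle")["+", ], c("-" = 5 / 11, "+" = 6 / 11))
  expect_equal(as.numeric(logLik(fit)), -10.08111, tolerance = 1e-6)
  expect_output(print(fit), "h=1")
  expect_output(print(summary(fit)), "AIC")

  # prediction pads short histories and falls back to the prior mean
  pr <- predict(fit, c("", "+", "-++"))
  expect_equal(unname(pr[1, ]), c(1 / 4, 3 / 4))       # boundary context
  expect_equal(unname(pr[2, ]), c(6 / 13, 7 / 13))
  expect_equal(unname(pr[3, ]), c(6 / 13, 7 / 13))     # last symbol rules
  pr2 <- predict(fit_markov(worked_trajs(), order = 2), "..")
  expect_equal(unname(pr2[1, ]), c(1 / 4, 3 / 4))

  # variable-length fit maps histories to blocks
  vfit <- fit_markov(worked_trajs(),
                     spec = memory_spec(partition = list("-", c("+", "."))))
  expect_equal(unname(predict(vfit, "-")[1, ]), c(2 / 7, 5 / 7))
  expect_equal(unname(predict(vfit, "+")[1, ]),
               unname(predict(vfit, "")[1, ]))

  sim <- simulate(fit, nsim = 2, seed = 9)
  expect_length(sim, 2L)
  expect_s3_class(sim[[1]], "trajectory_set")
  expect_true(all(lengths(sim[[1]]$sequences) %in% c(7L, 11L)))
})
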