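test_that("the ICC has the right closed-form values, floor and ceiling", {
  # logistic midpoint and the exact value at theta = ln 3
  expect_equal(eval_icc(0, easiness = 0), 0.25 + 0.75 * 0.5)
  expect_equal(eval_icc(log(3), easiness = 0), 0.25 + 0.75 * 0.75)
  # floor/ceiling across a spread of item parameters
  for (b in c(-3, 0, 2)) {
    for (a in c(0.8, 1, 2)) {
      lo <- eval_icc(-30, easiness = b, discrimination = a)
      hi <- eval_icc(30, easiness = b, discrimination = a)
      expect_lte(abs(lo - 0.25), 1e-6)
      expect_gte(hi, 1 - 1e-6)
    }
  }
  # strictly increasing in theta
  th <- seq(-6, 6, length.out = 50)
  expect_true(all(diff(eval_icc(th, easiness = 1)) > 0))
  expect_error(eval_icc(0, discrimination = -1), "discrimination")
  expect_error(eval_icc(0, guessing = 1), "guessing")
})

test_that("Rasch calibration respects symmetries and rejects degenerate input", {
  st <- simulate_study(sim_config(n_persons = 150, n_items = 6, seed = 11))
  rm <- st$responses
  df <- tibble::as_tibble(as.data.frame(rm))
  # duplicate one item column: identical responses must get equal easiness
  df$dup <- df[[rm_items(rm)[1]]]
  rm2 <- response_matrix(df)
  fit <- fit_rasch(rm2)
  est <- fit$items
  expect_equal(est$easiness[est$item_id == "dup"],
               est$easiness[est$item_id == rm_items(rm)[1]],
               tolerance = 1e-6)
  expect_true(all(fit$items$discrimination == 1))

  # permuting item columns permutes estimates identically
  perm <- rev(rm_items(rm))
  dfp <- tibble::as_tibble(as.data.frame(rm))[, c("person_id", "age", "sex",
                                                  "order_group", perm)]
  fitp <- fit_rasch(response_matrix(dfp, items = perm))
  expect_equal(fitp$items$easiness[match(rm_items(rm), fitp$items$item_id)],
               fit_rasch(rm)$items$easiness, tolerance = 1e-6)

  # degenerate items are named in the error
  bad <- tibble::tibble(person_id = c("a", "b", "c"),
                        good = c(0, 1, 0), allone = c(1, 1, 1))
  expect_error(fit_rasch(response_matrix(bad)), "allone")
  one_item <- tibble::tibble(person_id = c("a", "b"), i1 = c(0, 1))
  expect_error(fit_2pl(response_matrix(one_item)), "2 items")
})

test_that("the EM objective ascends and the 2PL nests the Rasch fit", {
  fit1 <- default_rasch()
  fit2 <- default_2pl()
  expect_true(fit1$converged)
  expect_true(fit2$converged)
  # penalized marginal likelihood is non-decreasing across EM iterations
  expect_true(all(diff(fit1$trace$penalized_loglik) > -1e-6))
  expect_true(all(diff(fit2$trace$penalized_loglik) > -1e-6))
  # a Rasch model with estimated scale is a constrained 2PL
  expect_gte(fit2$loglik_marginal, fit1$loglik_marginal - 1e-3)
})

test_that("2PL recovers discrimination structure", {
  # under Rasch truth, estimated discriminations are nearly constant
  fit2 <- default_2pl()
  expect_lte(stats::var(fit2$items$discrimination), 0.1)

  # two-block truth: between-block ordering recovered for >= 90% of pairs
  cfg <- sim_config(n_persons = 600, n_items = 20, seed = 17)
  bank <- simulate_bank(cfg)
  bank$true_discrimination <- rep(c(0.5, 2), each = 10)
  persons <- simulate_persons(cfg)
  rm <- simulate_responses(persons, bank, cfg)
  est <- fit_2pl(rm)$items$discrimination
  lo <- est[1:10]
  hi <- est[11:20]
  frac <- mean(outer(hi, lo, `>`))
  expect_gte(frac, 0.9)
})

test_that("EAP abilities match a brute-force quadrature oracle", {
  st <- simulate_study(sim_config(n_persons = 40, n_items = 10, seed = 23))
  fit <- fit_rasch(st$responses)
  eap <- estimate_abilities(fit, st$responses)

  # oracle: 200-point trapezoid integration over the fitted prior
  X <- irtforge:::rm_as_matrix(st$responses)
  sig <- fit$ability_scale
  grid <- seq(-6 * sig, 6 * sig, length.out = 200)
  prior <- stats::dnorm(grid, 0, sig)
  pars <- fit$items[match(colnames(X), fit$items$item_id), ]
  for (i in c(1, 17, 40)) {
    lik <- vapply(grid, function(th) {
      p <- eval_icc(th, pars$easiness, pars$discrimination, fit$guessing)
      prod(ifelse(is.na(X[i, ]), 1, ifelse(X[i, ] == 1, p, 1 - p)))
    }, numeric(1))
    post <- lik * prior
    post <- post / sum(post)
    expect_equal(eap$theta[i], sum(post * grid), tolerance = 1e-3)
  }
})

test_that("without a guessing floor the sum score is sufficient for ability", {
  cfg <- sim_config(n_persons = 120, n_items = 12, guessing = 0, seed = 31)
  st <- simulate_study(cfg)
  fit <- fit_rasch(st$responses, guessing = 0)
  ab <- fit$persons
  ss <- sum_scores(st$responses)
  # equal sum scores (complete data) -> equal EAP thetas
  for (s in unique(ss$score)) {
    th <- ab$theta[ss$score == s]
    if (length(th) > 1) expect_lt(max(th) - min(th), 1e-6)
  }
  # theta is a strictly monotone function of the score
  agg <- tapply(ab$theta, ss$score, mean)
  expect_true(all(diff(agg[order(as.numeric(names(agg)))]) > 0))
  # rank correlation is 1 once sub-femto tie-breaking noise is rounded away
  expect_equal(stats::cor(round(ab$theta, 8), ss$score,
                          method = "spearman"), 1)
  # the all-correct pattern, if present, tops the sample; check endpoint
  expect_equal(which.max(ab$theta), which.max(ss$score))

  # with the guessing floor, score ordering is still respected to ties
  fit25 <- fit_rasch(st$responses, guessing = 0.25)
  expect_gte(stats::cor(fit25$persons$theta, ss$score, method = "spearman"),
             0.98)
})

test_that("pointwise log-likelihoods have closed-form cells and sum to the total", {
  rm <- response_matrix(tibble::tibble(person_id = c("p1", "p2"),
                                       i1 = c(1, 0), i2 = c(0, 1)))
  fit <- flat_fit(c("i1", "i2"), easiness = c(0, 0), c("p1", "p2"))
  ll <- pointwise_loglik(fit, rm)   # P = 0.5 everywhere
  expect_equal(unname(as.vector(ll)), rep(log(0.5), 4))

  fit2 <- flat_fit("i1", easiness = stats::qlogis(0.625), "p1")
  rm2 <- response_matrix(tibble::tibble(person_id = "p1", i1 = 1))
  expect_equal(as.vector(pointwise_loglik(fit2, rm2)), log(0.625),
               tolerance = 1e-12)

  # accumulation oracle on a fitted model with missing cells
  st <- simulate_study(sim_config(n_persons = 50, n_items = 8, seed = 41))
  m <- irtforge:::rm_as_matrix(st$responses)
  m[1, 2] <- NA
  df <- tibble::as_tibble(as.data.frame(st$responses))
  df[, rm_items(st$responses)] <- m
  rm3 <- response_matrix(df, items = rm_items(st$responses))
  fit3 <- fit_rasch(rm3)
  pw <- pointwise_loglik(fit3, rm3)
  expect_true(all(pw[!is.na(pw)] <= 0))
  expect_true(is.na(pw[1, 2]))
  acc <- 0
  pars <- fit3$items
  for (i in seq_len(nrow(m))) {
    for (j in seq_len(ncol(m))) {
      if (is.na(m[i, j])) next
      p <- eval_icc(fit3$persons$theta[i], pars$easiness[j],
                    pars$discrimination[j], fit3$guessing)
      acc <- acc + ifelse(m[i, j] == 1, log(p), log(1 - p))
    }
  }
  expect_equal(sum(pw, na.rm = TRUE), acc, tolerance = 1e-8)
  expect_equal(fit3$loglik, acc, tolerance = 1e-8)
})

test_that("persons without responses get flagged missing abilities", {
  df <- tibble::tibble(person_id = c("p1", "p2", "p3"),
                       i1 = c(1, 0, NA), i2 = c(0, 1, NA), i3 = c(1, 0, NA))
  fit <- fit_rasch(response_matrix(df))
  expect_true(is.na(fit$persons$theta[3]))
  expect_equal(fit$persons$n_answered, c(3L, 3L, 0L))
  expect_true(all(fit$persons$se_theta[1:2] > 0))
})
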