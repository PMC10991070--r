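#' Item characteristic curve with a guessing floor
#'
#' Probability of a correct response for a four-alternative forced-choice
#' item: `P(theta) = c + (1 - c) * plogis(a * theta + b)`, where `b` is the
#' item's easiness (the additive inverse of difficulty), `a` its
#' discrimination and `c` the guessing floor (0.25 for a 4AFC task). The
#' curve is strictly increasing in `theta` with range `(c, 1)`.
#'
#' @param theta Ability value(s) on the logit scale.
#' @param easiness Item easiness `b` (logits).
#' @param discrimination Slope `a > 0`; 1 under the Rasch model.
#' @param guessing Lower asymptote `c` in `[0, 1)`.
#' @return Probability of a correct response, vectorized over inputs.
#' @examples
#' eval_icc(0, easiness = 0)        # 0.25 + 0.75 * 0.5 = 0.625
#' eval_icc(-30, easiness = 0)      # the guessing floor, 0.25
#' @export
eval_icc <- function(theta, easiness = 0, discrimination = 1, guessing = 0.25) {
  if (any(discrimination <= 0)) rlang::abort("discrimination must be > 0.")
  if (any(guessing < 0 | guessing >= 1)) {
    rlang::abort("guessing must be in [0, 1).")
  }
  guessing + (1 - guessing) * stats::plogis(discrimination * theta + easiness)
}

# Standard-normal quadrature grid: nodes z and weights w with sum(w) = 1.
gh_grid <- function(n_quad) {
  gh <- pracma::gaussHermite(n_quad)
  list(z = gh$x * sqrt(2), w = gh$w / sqrt(pi))
}

# Person x node log-likelihood given item log-probabilities (J x K).
# X1: responses with NA -> 0; M: observed mask.
person_node_loglik <- function(X1, M, logP, log1mP) {
  X1 %*% logP + (M - X1) %*% log1mP
}

# log-sum-exp by row
row_lse <- function(m) {
  mx <- apply(m, 1, max)
  mx + log(rowSums(exp(m - mx)))
}

irt_check_input <- function(X) {
  if (ncol(X) < 2) rlang::abort("At least 2 items are required.")
  p <- colMeans(X, na.rm = TRUE)
  n_obs <- colSums(!is.na(X))
  degenerate <- n_obs == 0 | p == 0 | p == 1
  if (any(degenerate)) {
    rlang::abort(paste0(
      "Degenerate item(s) with all-correct, all-incorrect or no responses: ",
      paste(colnames(X)[degenerate], collapse = ", ")
    ))
  }
}

# Penalised expected complete-data log-likelihood for one item.
# r_k / n_k: expected correct / administered counts at each node ability.
item_obj <- function(beta, loga, theta, r_k, n_k, guessing,
                     ridge_beta_sd, ridge_loga_sd) {
  p <- eval_icc(theta, easiness = beta, discrimination = exp(loga),
                guessing = guessing)
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  sum(r_k * log(p) + (n_k - r_k) * log1p(-p)) -
    beta^2 / (2 * ridge_beta_sd^2) - loga^2 / (2 * ridge_loga_sd^2)
}

#' Calibrate an item pool with a Rasch or 2PL model
#'
#' Marginal maximum likelihood via an EM algorithm with Gauss--Hermite
#' quadrature over a normal latent-ability distribution, with the guessing
#' floor held fixed (never estimated). `fit_rasch()` constrains all
#' discriminations to 1 and estimates the SD of the ability distribution;
#' `fit_2pl()` frees a per-item discrimination and fixes the ability
#' distribution to N(0, 1) for identification. Weak ridge penalties on
#' easiness (SD 5) and log-discrimination (SD 1) stabilize near-degenerate
#' items. Estimation is deterministic: identical data give identical fits.
#'
#' @param rm A [response_matrix()]. Every item must show both correct and
#'   incorrect responses.
#' @param guessing Fixed lower asymptote; 0.25 for 4-alternative choice.
#' @param seed Unused by the deterministic EM; accepted so calibration calls
#'   are interchangeable with stochastic backends.
#' @param n_quad Number of quadrature nodes (default 61).
#' @param max_iter,tol EM iteration cap and parameter-change tolerance.
#' @return An object of class `irt_fit`: tibbles of item parameters
#'   (easiness, discrimination, SEs) and person abilities (EAP `theta`,
#'   `se_theta`), the estimated `ability_scale`, the conditional training
#'   log-likelihood `loglik` and marginal `loglik_marginal`, a per-cell
#'   `pointwise` log-likelihood matrix, and convergence metadata including
#'   a `trace` of the penalized marginal log-likelihood.
#' @seealso [estimate_abilities()], [pointwise_loglik()], [item_fit_stats()]
#' @export
fit_rasch <- function(rm, guessing = 0.25, seed = NULL, n_quad = 61,
                      max_iter = 500, tol = 1e-5) {
  fit_irt_em(rm, model = "rasch", guessing = guessing, n_quad = n_quad,
             max_iter = max_iter, tol = tol)
}

#' @rdname fit_rasch
#' @param disc_bound Upper bound for 2PL discriminations; estimates at the
#'   bound are flagged in the item table (`disc_at_bound`).
#' @export
fit_2pl <- function(rm, guessing = 0.25, seed = NULL, n_quad = 61,
                    max_iter = 500, tol = 1e-5, disc_bound = 10) {
  fit_irt_em(rm, model = "twopl", guessing = guessing, n_quad = n_quad,
             max_iter = max_iter, tol = tol, disc_bound = disc_bound)
}

fit_irt_em <- function(rm, model, guessing, n_quad, max_iter, tol,
                       disc_bound = 10, groups = NULL,
                       ridge_beta_sd = 5, ridge_loga_sd = 1) {
  X <- rm_as_matrix(rm)
  irt_check_input(X)
  items <- colnames(X)
  J <- length(items)
  N <- nrow(X)
  M <- (!is.na(X)) * 1
  X1 <- X
  X1[is.na(X1)] <- 0L
  storage.mode(X1) <- "double"

  grid <- gh_grid(n_quad)
  z <- grid$z
  w <- grid$w
  K <- length(z)

  # start values from classical proportions
  p0 <- colSums(X1) / pmax(colSums(M), 1)
  p0 <- pmin(pmax((p0 - guessing) / (1 - guessing), 0.02), 0.98)
  beta <- stats::qlogis(p0)
  loga <- rep(0, J)
  sigma <- 1

  trace_ll <- numeric(0)
  converged <- FALSE
  iter <- 0
  A <- NULL

  for (iter in seq_len(max_iter)) {
    theta_k <- if (model == "rasch") sigma * z else z
    a <- exp(loga)
    eta <- sweep(outer(theta_k, a), 2, beta, `+`)  # K x J
    P <- guessing + (1 - guessing) * stats::plogis(eta)
    P <- pmin(pmax(P, 1e-12), 1 - 1e-12)
    logP <- log(P)          # K x J
    log1mP <- log1p(-P)

    LL <- person_node_loglik(X1, M, t(logP), t(log1mP))  # N x K
    LLw <- sweep(LL, 2, log(w), `+`)
    lse <- row_lse(LLw)
    marg_ll <- sum(lse)
    pen <- -sum(beta^2) / (2 * ridge_beta_sd^2) -
      sum(loga^2) / (2 * ridge_loga_sd^2)
    trace_ll <- c(trace_ll, marg_ll + pen)

    A <- exp(LLw - lse)  # posterior node probabilities, N x K

    n_jk <- t(M) %*% A   # J x K expected administered
    r_jk <- t(X1) %*% A  # J x K expected correct

    beta_new <- beta
    loga_new <- loga
    for (j in seq_len(J)) {
      if (model == "rasch") {
        opt <- stats::optimize(
          function(b) item_obj(b, 0, theta_k, r_jk[j, ], n_jk[j, ], guessing,
                               ridge_beta_sd, Inf),
          interval = c(-20, 20), maximum = TRUE, tol = 1e-8
        )
        beta_new[j] <- opt$maximum
      } else {
        opt <- stats::optim(
          c(beta[j], loga[j]),
          function(par) -item_obj(par[1], par[2], theta_k, r_jk[j, ],
                                  n_jk[j, ], guessing,
                                  ridge_beta_sd, ridge_loga_sd),
          method = "L-BFGS-B",
          lower = c(-20, log(0.05)), upper = c(20, log(disc_bound))
        )
        beta_new[j] <- opt$par[1]
        loga_new[j] <- opt$par[2]
      }
    }

    sigma_new <- sigma
    if (model == "rasch") {
      sigma_new <- sqrt(sum(A %*% theta_k^2) / N)
      sigma_new <- min(max(sigma_new, 0.05), 10)
    }

    delta <- max(abs(beta_new - beta), abs(loga_new - loga),
                 abs(sigma_new - sigma))
    beta <- beta_new
    loga <- loga_new
    sigma <- sigma_new
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }

  # final E-step quantities at the converged parameters
  theta_k <- if (model == "rasch") sigma * z else z
  a <- exp(loga)
  eta <- sweep(outer(theta_k, a), 2, beta, `+`)
  P <- pmin(pmax(guessing + (1 - guessing) * stats::plogis(eta), 1e-12),
            1 - 1e-12)
  LL <- person_node_loglik(X1, M, t(log(P)), t(log1p(-P)))
  LLw <- sweep(LL, 2, log(w), `+`)
  lse <- row_lse(LLw)
  marg_ll <- sum(lse)
  A <- exp(LLw - lse)
  n_jk <- t(M) %*% A
  r_jk <- t(X1) %*% A

  # EAP abilities
  theta_hat <- as.numeric(A %*% theta_k)
  theta_var <- as.numeric(A %*% theta_k^2) - theta_hat^2
  se_theta <- sqrt(pmax(theta_var, 0))
  n_answered <- rowSums(M)
  theta_hat[n_answered == 0] <- NA_real_
  se_theta[n_answered == 0] <- NA_real_

  # item standard errors from the expected information at the optimum
  se_beta <- rep(NA_real_, J)
  se_disc <- rep(NA_real_, J)
  for (j in seq_len(J)) {
    lam <- stats::plogis(a[j] * theta_k + beta[j])
    pj <- pmin(pmax(guessing + (1 - guessing) * lam, 1e-12), 1 - 1e-12)
    dP_db <- (1 - guessing) * lam * (1 - lam)
    info_bb <- sum(n_jk[j, ] * dP_db^2 / (pj * (1 - pj))) +
      1 / ridge_beta_sd^2
    if (model == "rasch") {
      se_beta[j] <- 1 / sqrt(info_bb)
    } else {
      dP_da <- dP_db * theta_k
      info_aa <- sum(n_jk[j, ] * dP_da^2 / (pj * (1 - pj))) +
        1 / (ridge_loga_sd^2 * a[j]^2)
      info_ab <- sum(n_jk[j, ] * dP_db * dP_da / (pj * (1 - pj)))
      det_i <- info_bb * info_aa - info_ab^2
      if (det_i > 0) {
        se_beta[j] <- sqrt(info_aa / det_i)
        se_disc[j] <- sqrt(info_bb / det_i)
      }
    }
  }

  item_tbl <- tibble::tibble(
    item_id = items,
    easiness = as.numeric(beta),
    discrimination = as.numeric(a),
    guessing = guessing,
    se_easiness = se_beta,
    se_discrimination = se_disc,
    disc_at_bound = if (model == "twopl") a >= disc_bound * 0.999 else FALSE
  )
  person_tbl <- tibble::tibble(
    person_id = rownames(X),
    theta = theta_hat,
    se_theta = se_theta,
    n_answered = as.integer(n_answered)
  )

  fit <- structure(list(
    model = model,
    items = item_tbl,
    persons = person_tbl,
    ability_scale = if (model == "rasch") sigma else 1,
    loglik_marginal = marg_ll,
    converged = converged,
    n_iter = iter,
    trace = tibble::tibble(iter = seq_along(trace_ll),
                           penalized_loglik = trace_ll),
    guessing = guessing,
    n_quad = n_quad
  ), class = "irt_fit")

  pw <- pointwise_loglik(fit, rm)
  fit$pointwise <- pw
  fit$loglik <- sum(pw, na.rm = TRUE)
  fit
}

#' @export
print.irt_fit <- function(x, ...) {
  cat(sprintf(
    "<irt_fit> %s model: %d items, %d persons (guessing = %.3g)\n",
    x$model, nrow(x$items), nrow(x$persons), x$guessing))
  cat(sprintf("  ability scale SD: %.3f | marginal loglik: %.2f | %s in %d EM iterations\n",
              x$ability_scale, x$loglik_marginal,
              if (x$converged) "converged" else "NOT converged", x$n_iter))
  invisible(x)
}

#' Expected-a-posteriori ability estimates
#'
#' Recomputes EAP abilities (posterior mean and SD over the quadrature grid)
#' for the persons in `rm` under the item parameters of `fit`. Under a Rasch
#' fit with complete data and no guessing floor, the EAP is a function of
#' the sum score alone.
#'
#' @param fit An `irt_fit`.
#' @param rm A [response_matrix()] whose items are all covered by `fit`.
#' @return A tibble `person_id`, `theta`, `se_theta`, `n_answered`; persons
#'   with no scored responses get `NA` ability.
#' @export
estimate_abilities <- function(fit, rm) {
  items <- rm_items(rm)
  missing <- setdiff(items, fit$items$item_id)
  if (length(missing) > 0) {
    rlang::abort(paste0("Fit does not cover item(s): ",
                        paste(missing, collapse = ", ")))
  }
  X <- rm_as_matrix(rm)
  pars <- fit$items[match(items, fit$items$item_id), ]
  grid <- gh_grid(fit$n_quad)
  theta_k <- grid$z * fit$ability_scale
  eta <- sweep(outer(theta_k, pars$discrimination), 2, pars$easiness, `+`)
  P <- pmin(pmax(fit$guessing + (1 - fit$guessing) * stats::plogis(eta),
                 1e-12), 1 - 1e-12)
  M <- (!is.na(X)) * 1
  X1 <- X
  X1[is.na(X1)] <- 0L
  storage.mode(X1) <- "double"
  LL <- person_node_loglik(X1, M, t(log(P)), t(log1p(-P)))
  LLw <- sweep(LL, 2, log(grid$w), `+`)
  A <- exp(LLw - row_lse(LLw))
  theta_hat <- as.numeric(A %*% theta_k)
  se <- sqrt(pmax(as.numeric(A %*% theta_k^2) - theta_hat^2, 0))
  n_answered <- rowSums(M)
  theta_hat[n_answered == 0] <- NA_real_
  se[n_answered == 0] <- NA_real_
  tibble::tibble(person_id = rownames(X), theta = theta_hat, se_theta = se,
                 n_answered = as.integer(n_answered))
}

#' Per-cell log-likelihood at the fitted parameters
#'
#' For each non-missing cell, `x * log(P) + (1 - x) * log(1 - P)` with `P`
#' the model probability at the item's parameters and the person's EAP
#' ability. Missing cells are `NA`. The matrix sums to the fit's conditional
#' training log-likelihood and feeds the model-comparison machinery.
#'
#' @param fit An `irt_fit`.
#' @param rm A [response_matrix()] covered by `fit`.
#' @return A persons x items numeric matrix with `NA` at missing cells.
#' @export
pointwise_loglik <- function(fit, rm) {
  items <- rm_items(rm)
  missing <- setdiff(items, fit$items$item_id)
  if (length(missing) > 0) {
    rlang::abort(paste0("Fit does not cover item(s): ",
                        paste(missing, collapse = ", ")))
  }
  X <- rm_as_matrix(rm)
  pars <- fit$items[match(items, fit$items$item_id), ]
  persons <- fit$persons[match(rownames(X), fit$persons$person_id), ]
  if (anyNA(persons$person_id)) {
    rlang::abort("Fit does not cover all persons in the matrix.")
  }
  P <- fitted_prob_matrix(persons$theta, pars, fit$guessing)
  ll <- X * log(P) + (1 - X) * log1p(-P)
  dimnames(ll) <- dimnames(X)
  ll
}

# persons x items probability matrix at plug-in abilities
fitted_prob_matrix <- function(theta, pars, guessing) {
  eta <- outer(theta, pars$discrimination) +
    matrix(pars$easiness, nrow = length(theta), ncol = nrow(pars),
           byrow = TRUE)
  pmin(pmax(guessing + (1 - guessing) * stats::plogis(eta), 1e-12), 1 - 1e-12)
}
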