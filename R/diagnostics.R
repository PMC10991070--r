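#' Infit and outfit mean-square item-fit statistics
#'
#' Residual-based diagnostics of how well a Rasch calibration captures each
#' item. With expected probability `E`, binomial variance `W = E(1 - E)` and
#' squared standardized residual `z2 = (x - E)^2 / W`, the outfit is the
#' plain mean of `z2` over persons and the infit the information-weighted
#' version `sum((x - E)^2) / sum(W)`. Both have expectation close to 1 when
#' the model holds; the conventional screening band is `[0.7, 1.3]`.
#' Expected probabilities include the fixed guessing floor.
#'
#' @param fit A Rasch `irt_fit`.
#' @param rm The [response_matrix()] the fit was computed on.
#' @return A tibble `item_id`, `infit`, `outfit`, `n_used`; items with no
#'   scored responses get `NA` statistics.
#' @export
item_fit_stats <- function(fit, rm) {
  X <- rm_as_matrix(rm)
  items <- colnames(X)
  pars <- fit$items[match(items, fit$items$item_id), ]
  if (anyNA(pars$item_id)) rlang::abort("Fit does not cover all items.")
  persons <- fit$persons[match(rownames(X), fit$persons$person_id), ]
  E <- fitted_prob_matrix(persons$theta, pars, fit$guessing)
  W <- E * (1 - E)
  R2 <- (X - E)^2
  n_used <- colSums(!is.na(X))
  outfit <- colMeans(R2 / W, na.rm = TRUE)
  infit <- colSums(R2, na.rm = TRUE) / colSums(ifelse(is.na(X), NA, W),
                                               na.rm = TRUE)
  outfit[n_used == 0] <- NA_real_
  infit[n_used == 0] <- NA_real_
  tibble::tibble(item_id = items, infit = as.numeric(infit),
                 outfit = as.numeric(outfit), n_used = as.integer(n_used))
}

#' Kuder--Richardson 20 internal consistency
#'
#' Classical reliability for dichotomous items:
#' `KR-20 = k/(k-1) * (1 - sum(p_j q_j) / Var(sum score))` with `p_j` the
#' item proportion correct and the sum-score variance taken with the sample
#' (n - 1) denominator. Persons with any missing response on the subset are
#' dropped listwise (their count is attached as an attribute).
#'
#' @param rm A [response_matrix()].
#' @param subset Character vector of item ids, or `"all"`.
#' @return The coefficient (scalar, at most 1), with attributes `n_used`,
#'   `n_dropped` and `k`. Zero score variance gives `NA` with a warning.
#' @export
kr20 <- function(rm, subset = "all") {
  items <- rm_items(rm)
  if (identical(subset, "all")) subset <- items
  unknown <- setdiff(subset, items)
  if (length(unknown) > 0) {
    rlang::abort(paste0("Unknown item id(s): ", paste(unknown, collapse = ", ")))
  }
  k <- length(subset)
  if (k < 2) rlang::abort("KR-20 needs at least 2 items.")
  X <- rm_as_matrix(rm)[, subset, drop = FALSE]
  complete <- stats::complete.cases(X)
  n_dropped <- sum(!complete)
  X <- X[complete, , drop = FALSE]
  if (nrow(X) < 2) rlang::abort("KR-20 needs at least 2 complete persons.")
  p <- colMeans(X)
  scores <- rowSums(X)
  v <- stats::var(scores)
  if (v == 0) {
    warning("Zero sum-score variance; KR-20 undefined.")
    coef <- NA_real_
  } else {
    coef <- k / (k - 1) * (1 - sum(p * (1 - p)) / v)
  }
  structure(coef, n_used = nrow(X), n_dropped = n_dropped, k = k)
}

#' Andrich person-separation reliability
#'
#' Proportion of observed ability variance not attributable to measurement
#' error: `R = (Var(theta_hat) - mean(se_theta^2)) / Var(theta_hat)`,
#' floored at 0. Uses the EAP abilities and their posterior SDs stored in
#' the fit; persons without a scored response are excluded.
#'
#' @param fit An `irt_fit` with person abilities and standard errors.
#' @return The reliability coefficient in `[0, 1]`.
#' @export
andrich_reliability <- function(fit) {
  p <- fit$persons[!is.na(fit$persons$theta), ]
  if (nrow(p) < 2) rlang::abort("Need at least 2 persons with abilities.")
  v <- stats::var(p$theta)
  err <- mean(p$se_theta^2)
  max(0, (v - err) / v)
}

#' Reliability report for an item subset
#'
#' Convenience wrapper pairing the classical KR-20 with the model-based
#' Andrich coefficient, the way short forms are usually reported.
#'
#' @param fit A Rasch `irt_fit` on the subset (used for Andrich).
#' @param rm A [response_matrix()] (used for KR-20).
#' @param subset Item ids or `"all"`.
#' @return One-row tibble: `kr20`, `andrich`, `k`, `n`.
#' @export
reliability_report <- function(fit, rm, subset = "all") {
  kc <- kr20(rm, subset)
  tibble::tibble(
    kr20 = as.numeric(kc),
    andrich = andrich_reliability(fit),
    k = attr(kc, "k"),
    n = attr(kc, "n_used")
  )
}

#' Differential item functioning by group-specific easiness
#'
#' Fits a single joint Rasch model in which each item carries a separate
#' easiness parameter per group while all persons share one zero-mean
#' normal ability distribution (common estimated SD). Keeping both groups
#' on the one latent scale avoids a post-hoc equating step. An item is
#' flagged when the two groups' Wald 95% intervals do not overlap; a
#' whole-test summary correlates the per-item estimates across groups.
#'
#' @param rm A [response_matrix()] with the grouping covariate.
#' @param grouping `"sex"` or `"order_group"` (any 2-level column works).
#' @param guessing Fixed guessing floor.
#' @param conf_level Interval coverage for the flag (default 0.95).
#' @param seed Unused by the deterministic fit; kept for interface parity.
#' @param n_quad,max_iter,tol Quadrature and EM controls, as in
#'   [fit_rasch()].
#' @return A tibble of class `dif_result`, one row per item: group-specific
#'   easiness with interval bounds, `delta` (group1 - group2),
#'   `intervals_overlap`; attributes `group_correlation`, `groups`,
#'   `n_excluded` (persons with missing grouping).
#' @export
dif_analysis <- function(rm, grouping = c("sex", "order_group"),
                         guessing = 0.25, conf_level = 0.95, seed = NULL,
                         n_quad = 61, max_iter = 500, tol = 1e-5) {
  grouping <- grouping[1]
  if (!grouping %in% names(rm)) {
    rlang::abort(paste0("Grouping column '", grouping, "' not present."))
  }
  g <- as.character(rm[[grouping]])
  keep <- !is.na(g)
  n_excluded <- sum(!keep)
  rm2 <- response_matrix(tibble::as_tibble(as.data.frame(rm))[keep, ],
                         items = rm_items(rm))
  g <- g[keep]
  levels_g <- sort(unique(g))
  if (length(levels_g) != 2) {
    rlang::abort("Grouping must have exactly 2 observed levels.")
  }
  if (any(table(g) < 20)) {
    rlang::abort("Each group needs at least 20 persons.")
  }

  X <- rm_as_matrix(rm2)
  irt_check_input(X)
  items <- colnames(X)
  J <- ncol(X)
  N <- nrow(X)
  gi <- match(g, levels_g)
  M <- (!is.na(X)) * 1
  X1 <- X
  X1[is.na(X1)] <- 0L
  storage.mode(X1) <- "double"

  grid <- gh_grid(n_quad)
  z <- grid$z
  w <- grid$w

  p0 <- colSums(X1) / pmax(colSums(M), 1)
  p0 <- pmin(pmax((p0 - guessing) / (1 - guessing), 0.02), 0.98)
  beta <- cbind(stats::qlogis(p0), stats::qlogis(p0))  # J x 2
  sigma <- 1
  converged <- FALSE

  for (iter in seq_len(max_iter)) {
    theta_k <- sigma * z
    A <- matrix(0, N, length(z))
    n_jk <- vector("list", 2)
    r_jk <- vector("list", 2)
    for (grp in 1:2) {
      idx <- gi == grp
      eta <- sweep(matrix(theta_k, length(theta_k), J), 2, beta[, grp], `+`)
      P <- pmin(pmax(guessing + (1 - guessing) * stats::plogis(eta), 1e-12),
                1 - 1e-12)
      LL <- person_node_loglik(X1[idx, , drop = FALSE], M[idx, , drop = FALSE],
                               t(log(P)), t(log1p(-P)))
      LLw <- sweep(LL, 2, log(w), `+`)
      A[idx, ] <- exp(LLw - row_lse(LLw))
      n_jk[[grp]] <- t(M[idx, , drop = FALSE]) %*% A[idx, , drop = FALSE]
      r_jk[[grp]] <- t(X1[idx, , drop = FALSE]) %*% A[idx, , drop = FALSE]
    }

    beta_new <- beta
    for (grp in 1:2) {
      for (j in seq_len(J)) {
        opt <- stats::optimize(
          function(b) item_obj(b, 0, theta_k, r_jk[[grp]][j, ],
                               n_jk[[grp]][j, ], guessing, 5, Inf),
          interval = c(-20, 20), maximum = TRUE, tol = 1e-8
        )
        beta_new[j, grp] <- opt$maximum
      }
    }
    sigma_new <- min(max(sqrt(sum(A %*% theta_k^2) / N), 0.05), 10)
    delta <- max(abs(beta_new - beta), abs(sigma_new - sigma))
    beta <- beta_new
    sigma <- sigma_new
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }

  # Wald SEs from the expected information at the optimum
  theta_k <- sigma * z
  se <- matrix(NA_real_, J, 2)
  for (grp in 1:2) {
    for (j in seq_len(J)) {
      lam <- stats::plogis(theta_k + beta[j, grp])
      pj <- pmin(pmax(guessing + (1 - guessing) * lam, 1e-12), 1 - 1e-12)
      dP <- (1 - guessing) * lam * (1 - lam)
      info <- sum(n_jk[[grp]][j, ] * dP^2 / (pj * (1 - pj))) + 1 / 25
      se[j, grp] <- 1 / sqrt(info)
    }
  }

  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  lwr <- beta - zq * se
  upr <- beta + zq * se
  out <- tibble::tibble(
    item_id = items,
    easiness_1 = beta[, 1], se_1 = se[, 1],
    lwr_1 = lwr[, 1], upr_1 = upr[, 1],
    easiness_2 = beta[, 2], se_2 = se[, 2],
    lwr_2 = lwr[, 2], upr_2 = upr[, 2],
    delta = beta[, 1] - beta[, 2],
    intervals_overlap = !(lwr[, 1] > upr[, 2] | lwr[, 2] > upr[, 1])
  )
  structure(out,
            group_correlation = stats::cor(beta[, 1], beta[, 2]),
            groups = levels_g, grouping = grouping,
            n_excluded = n_excluded, converged = converged,
            ability_scale = sigma,
            class = c("dif_result", class(out)))
}

#' @export
print.dif_result <- function(x, ...) {
  gr <- attr(x, "groups")
  cat(sprintf("<dif_result> %s: %s vs %s | group correlation r = %.3f | %d item(s) flagged\n",
              attr(x, "grouping"), gr[1], gr[2],
              attr(x, "group_correlation"), sum(!x$intervals_overlap)))
  NextMethod()
}
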