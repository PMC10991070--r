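#' Objective components of an item subset
#'
#' Four per-subset summaries drive the automated short-form search, all of
#' which are better when smaller: `spread`, the SD of the gaps between
#' adjacent sorted Rasch easiness values (0 means perfectly equal spacing
#' across the latent scale); `infit_dev` and `outfit_dev`, the mean absolute
#' deviation of the Rasch fit statistics from their ideal of 1; and
#' `disc_var`, the variance of the 2PL discriminations (0 means the subset
#' behaves like a Rasch-homogeneous test). Sample (n - 1) variances are
#' used throughout.
#'
#' @param subset Character vector of item ids (at least 3: gaps need >= 2
#'   values for an SD).
#' @param rasch Rasch `irt_fit` on the full pool (easiness source).
#' @param twopl 2PL `irt_fit` on the full pool (discrimination source).
#' @param fitstats [item_fit_stats()] table for the Rasch fit.
#' @return One-row tibble: `spread`, `infit_dev`, `outfit_dev`, `disc_var`.
#' @export
objective_components <- function(subset, rasch, twopl, fitstats) {
  if (length(subset) < 3) {
    rlang::abort("Subset must have at least 3 items (spread undefined).")
  }
  tbl <- selection_table(rasch, twopl, fitstats)
  idx <- match(subset, tbl$item_id)
  if (anyNA(idx)) {
    rlang::abort(paste0("Uncalibrated item(s): ",
                        paste(subset[is.na(idx)], collapse = ", ")))
  }
  components_from_table(tbl, idx)
}

# Precompute the per-item columns the objective needs, aligned by item_id.
selection_table <- function(rasch, twopl, fitstats) {
  ids <- rasch$items$item_id
  tibble::tibble(
    item_id = ids,
    easiness = rasch$items$easiness,
    infit = fitstats$infit[match(ids, fitstats$item_id)],
    outfit = fitstats$outfit[match(ids, fitstats$item_id)],
    discrimination = twopl$items$discrimination[match(ids, twopl$items$item_id)]
  )
}

components_from_table <- function(tbl, idx) {
  tibble::tibble(
    spread = stats::sd(diff(sort(tbl$easiness[idx]))),
    infit_dev = mean(abs(tbl$infit[idx] - 1)),
    outfit_dev = mean(abs(tbl$outfit[idx] - 1)),
    disc_var = stats::var(tbl$discrimination[idx])
  )
}

# Numeric-only objective evaluator for the hot search loops; arithmetic
# matches objective_components() + scale_components() exactly.
make_objective_fun <- function(tbl, weights) {
  e <- tbl$easiness
  ai <- abs(tbl$infit - 1)
  ao <- abs(tbl$outfit - 1)
  d <- tbl$discrimination
  w <- weights$weights
  s <- weights$normalizers
  if (is.null(s)) rlang::abort("Normalizers missing.")
  function(idx) {
    m <- length(idx)
    es <- sort(e[idx])
    gaps <- es[-1] - es[-m]
    spread <- stats::sd(gaps)
    dm <- d[idx]
    -(w[["spread"]] * spread / s[["spread"]] +
        w[["infit_dev"]] * (sum(ai[idx]) / m) / s[["infit_dev"]] +
        w[["outfit_dev"]] * (sum(ao[idx]) / m) / s[["outfit_dev"]] +
        w[["disc_var"]] * stats::var(dm) / s[["disc_var"]])
  }
}

# Raw component matrix (rows: draws) without tibble overhead.
raw_components <- function(tbl, idx) {
  m <- length(idx)
  es <- sort(tbl$easiness[idx])
  c(spread = stats::sd(es[-1] - es[-m]),
    infit_dev = sum(abs(tbl$infit[idx] - 1)) / m,
    outfit_dev = sum(abs(tbl$outfit[idx] - 1)) / m,
    disc_var = stats::var(tbl$discrimination[idx]))
}

#' Objective weights and per-component normalizers
#'
#' The four components live on different numeric scales, so each is divided
#' by a normalizer (its mean over random same-size subsets, see
#' [calibrate_normalizers()]) before being weighted and summed. The default
#' weights emphasize model fit (in/outfit) and equal spacing over
#' discrimination homogeneity.
#'
#' @param w_spread,w_infit,w_outfit,w_disc Positive weights.
#' @param normalizers Named numeric vector (`spread`, `infit_dev`,
#'   `outfit_dev`, `disc_var`) or `NULL` until calibrated.
#' @return A list of class `objective_weights`.
#' @export
objective_weights <- function(w_spread = 2, w_infit = 2, w_outfit = 2,
                              w_disc = 1, normalizers = NULL) {
  w <- c(spread = w_spread, infit_dev = w_infit, outfit_dev = w_outfit,
         disc_var = w_disc)
  if (any(w <= 0)) rlang::abort("Weights must be positive.")
  structure(list(weights = w, normalizers = normalizers),
            class = "objective_weights")
}

#' Scale and combine components into the objective
#'
#' The scalar being maximized by the annealer:
#' `objective = -(w_s * spread/s1 + w_i * infit_dev/s2 +
#' w_o * outfit_dev/s3 + w_d * disc_var/s4)`. The global maximum 0 is
#' attained only when every component is 0; lowering any component (others
#' fixed) always increases the objective.
#'
#' @param components One-row tibble from [objective_components()].
#' @param weights An [objective_weights()] with calibrated normalizers.
#' @return The objective scalar (higher is better, always <= 0).
#' @export
scale_components <- function(components, weights) {
  s <- weights$normalizers
  if (is.null(s)) {
    rlang::abort("Normalizers missing; run calibrate_normalizers() first.")
  }
  nm <- names(weights$weights)
  if (any(!is.finite(s[nm]) | s[nm] == 0)) {
    rlang::abort("Zero or non-finite normalizer.")
  }
  vals <- unlist(components[1, nm])
  -sum(weights$weights * vals / s[nm])
}

#' Calibrate component normalizers from random subsets
#'
#' Draws `n_random` uniformly random size-`m` subsets of the calibrated
#' pool and sets each component's normalizer to its mean over the draws, so
#' that on a typical random subset every normalized component is about 1
#' and the weights alone control the emphasis.
#'
#' @param weights An [objective_weights()].
#' @param rasch,twopl,fitstats Calibration inputs as in
#'   [objective_components()].
#' @param size Subset size `m` the normalizers are calibrated for.
#' @param n_random Number of random subsets (>= 100).
#' @param seed Integer seed; the draw is deterministic given it.
#' @return The `weights` object with `normalizers` filled in.
#' @export
calibrate_normalizers <- function(weights, rasch, twopl, fitstats, size,
                                  n_random = 1000, seed = 1L) {
  if (n_random < 100) rlang::abort("n_random must be at least 100.")
  tbl <- selection_table(rasch, twopl, fitstats)
  pool_n <- nrow(tbl)
  if (size < 3 || size > pool_n) rlang::abort("size out of range.")
  comp <- withr::with_seed(seed, {
    t(vapply(seq_len(n_random),
             function(i) raw_components(tbl, sample.int(pool_n, size)),
             numeric(4)))
  })
  weights$normalizers <- colMeans(comp)
  bad <- weights$normalizers == 0 | !is.finite(weights$normalizers)
  if (any(bad)) {
    rlang::abort(paste0("Degenerate normalizer (component constant at 0): ",
                        paste(names(weights$normalizers)[bad], collapse = ", ")))
  }
  weights
}

#' Annealing schedule
#'
#' Geometric cooling schedule for [anneal_select()]. When `t_initial` is
#' `NULL` it is tuned from 200 warm-up proposals so that roughly 80% of
#' objective-worsening moves would be accepted at the start; the
#' temperature is then multiplied by `cooling` after every `iters_per_temp`
#' proposals until `n_proposals` have been made, by which point the search
#' is effectively strict hill climbing.
#'
#' @param t_initial Starting temperature, or `NULL` to auto-tune.
#' @param t_final Optional floor for the temperature.
#' @param cooling Geometric factor in (0, 1).
#' @param iters_per_temp Proposals between cooling steps.
#' @param swap_size Items exchanged per proposal.
#' @param n_proposals Total proposals.
#' @return A list of class `anneal_schedule`.
#' @export
anneal_schedule <- function(t_initial = NULL, t_final = NULL, cooling = 0.995,
                            iters_per_temp = 10, swap_size = 1,
                            n_proposals = 20000) {
  if (cooling <= 0 || cooling >= 1) rlang::abort("cooling must be in (0,1).")
  if (!is.null(t_initial) && !is.null(t_final) &&
      (t_initial <= t_final || t_final <= 0)) {
    rlang::abort("Need t_initial > t_final > 0.")
  }
  structure(list(t_initial = t_initial, t_final = t_final, cooling = cooling,
                 iters_per_temp = iters_per_temp, swap_size = swap_size,
                 n_proposals = n_proposals),
            class = "anneal_schedule")
}

#' Select an item subset by simulated annealing
#'
#' Searches the space of size-`m` subsets for the maximizer of the scaled
#' objective. From a random initial subset, each proposal exchanges
#' `swap_size` selected items against unselected ones; improvements are
#' always accepted and worsenings with probability `exp(delta / T)` under
#' the geometric temperature schedule, so the search can cross valleys
#' early and fine-tunes greedily late. The best subset ever visited is
#' returned, with the accepted-move trace for auditing.
#'
#' @param rasch,twopl,fitstats Full-pool calibration, as in
#'   [objective_components()].
#' @param size Subset size `m` (3 <= m <= pool size; `m` = pool size
#'   returns the identity selection without searching).
#' @param weights Calibrated [objective_weights()]; if its normalizers are
#'   missing they are calibrated internally from `seed`.
#' @param schedule An [anneal_schedule()].
#' @param seed Integer seed; the whole search is deterministic given it.
#' @return A list of class `subset_solution`: sorted `item_ids`, `size`,
#'   `objective`, `components`, `trace` (iteration, temperature, objective,
#'   best so far), `seed`.
#' @export
anneal_select <- function(rasch, twopl, fitstats, size, weights = NULL,
                          schedule = anneal_schedule(), seed = 1L) {
  tbl <- selection_table(rasch, twopl, fitstats)
  pool_n <- nrow(tbl)
  if (size > pool_n) rlang::abort("size exceeds pool size.")
  if (size < 3) rlang::abort("size must be at least 3.")
  if (is.null(weights)) weights <- objective_weights()
  if (is.null(weights$normalizers)) {
    weights <- calibrate_normalizers(weights, rasch, twopl, fitstats,
                                     size = min(size, pool_n - 1) ,
                                     seed = seed)
  }
  obj_of <- make_objective_fun(tbl, weights)

  if (size == pool_n) {
    idx <- seq_len(pool_n)
    sol <- list(item_ids = sort(tbl$item_id), size = size,
                objective = obj_of(idx),
                components = components_from_table(tbl, idx),
                trace = tibble::tibble(iter = 0L, temperature = 0,
                                       objective = obj_of(idx),
                                       best_objective = obj_of(idx)),
                seed = seed)
    class(sol) <- "subset_solution"
    return(sol)
  }

  withr::with_seed(seed, {
    perm <- sample.int(pool_n)
    cur <- perm[seq_len(size)]          # selected item indices
    outv <- perm[-seq_len(size)]        # unselected item indices
    cur_obj <- obj_of(cur)
    k <- min(schedule$swap_size, size, pool_n - size)

    t0 <- schedule$t_initial
    if (is.null(t0)) {
      # warm-up: typical worsening magnitude -> ~80% early acceptance
      drops <- numeric(0)
      p_cur <- cur
      p_out <- outv
      p_obj <- cur_obj
      for (i in seq_len(200)) {
        di <- sample.int(size, k)
        ai <- sample.int(pool_n - size, k)
        tmp <- p_cur[di]
        p_cur[di] <- p_out[ai]
        p_out[ai] <- tmp
        new_obj <- obj_of(p_cur)
        if (new_obj < p_obj) drops <- c(drops, p_obj - new_obj)
        p_obj <- new_obj
      }
      t0 <- if (length(drops) > 0) mean(drops) / (-log(0.8)) else 1e-3
    }

    temp <- t0
    best <- cur
    best_obj <- cur_obj
    n_steps <- schedule$n_proposals
    rec_every <- max(1L, n_steps %/% 400L)
    tr_iter <- integer(0); tr_temp <- numeric(0)
    tr_obj <- numeric(0); tr_best <- numeric(0)

    for (it in seq_len(n_steps)) {
      di <- sample.int(size, k)
      ai <- sample.int(pool_n - size, k)
      cand <- cur
      cand[di] <- outv[ai]
      cand_obj <- obj_of(cand)
      d <- cand_obj - cur_obj
      if (d > 0 || stats::runif(1) < exp(d / temp)) {
        outv[ai] <- cur[di]
        cur <- cand
        cur_obj <- cand_obj
        if (cur_obj > best_obj) {
          best <- cur
          best_obj <- cur_obj
        }
      }
      if (it %% schedule$iters_per_temp == 0) {
        temp <- temp * schedule$cooling
        if (!is.null(schedule$t_final)) temp <- max(temp, schedule$t_final)
      }
      if (it %% rec_every == 0 || it == n_steps) {
        tr_iter <- c(tr_iter, it); tr_temp <- c(tr_temp, temp)
        tr_obj <- c(tr_obj, cur_obj); tr_best <- c(tr_best, best_obj)
      }
    }

    sol <- list(
      item_ids = sort(tbl$item_id[best]),
      size = size,
      objective = best_obj,
      components = components_from_table(tbl, best),
      trace = tibble::tibble(iter = tr_iter, temperature = tr_temp,
                             objective = tr_obj, best_objective = tr_best),
      seed = seed,
      weights = weights
    )
    class(sol) <- "subset_solution"
    sol
  })
}

#' @export
print.subset_solution <- function(x, ...) {
  cat(sprintf("<subset_solution> %d items, objective %.4f\n",
              x$size, x$objective))
  cat("  items:", paste(x$item_ids, collapse = ", "), "\n")
  invisible(x)
}

#' Exhaustive subset search (annealer oracle)
#'
#' Enumerates every size-`m` subset and returns the objective maximizer;
#' ties are broken in favor of the lexicographically smallest item-id
#' vector. Intended as a ground-truth check for [anneal_select()] on small
#' pools; refuses to enumerate more than one million subsets.
#'
#' @inheritParams anneal_select
#' @return A `subset_solution` (with a degenerate one-row trace).
#' @export
exhaustive_select <- function(rasch, twopl, fitstats, size, weights) {
  tbl <- selection_table(rasch, twopl, fitstats)
  tbl <- tbl[order(tbl$item_id), ]
  pool_n <- nrow(tbl)
  if (size > pool_n) rlang::abort("size exceeds pool size.")
  if (choose(pool_n, size) > 1e6) {
    rlang::abort("More than 1e6 subsets; use anneal_select() instead.")
  }
  if (is.null(weights$normalizers)) {
    rlang::abort("Normalizers missing; run calibrate_normalizers() first.")
  }
  obj_of <- make_objective_fun(tbl, weights)
  combs <- utils::combn(pool_n, size)
  objs <- apply(combs, 2, obj_of)
  best_i <- which.max(objs)  # first maximizer = lexicographic tie-break
  idx <- combs[, best_i]
  sol <- list(item_ids = tbl$item_id[idx], size = size,
              objective = objs[best_i],
              components = components_from_table(tbl, idx),
              trace = tibble::tibble(iter = 0L, temperature = 0,
                                     objective = objs[best_i],
                                     best_objective = objs[best_i]),
              seed = NA_integer_, weights = weights)
  class(sol) <- "subset_solution"
  sol
}

#' Compare Rasch and 2PL fits by expected log predictive density
#'
#' Deterministic stand-in for Bayesian approximate leave-one-out
#' cross-validation: each fit's per-cell conditional log-likelihood is
#' penalized by its effective parameter count spread over the cells
#' (`elpd = sum(loglik) - p`), and the comparison uses the same
#' difference/standard-error algebra as PSIS-LOO:
#' `se_diff = sqrt(N) * sd(per-cell differences)`. The headline `ratio`,
#' `max(0, elpd_2pl - elpd_rasch) / (2 * se_diff)`, implements the 2-SE
#' rule of thumb: values at or below 1 mean the extra discrimination
#' parameters buy no predictive improvement worth their complexity, i.e.
#' the subset is Rasch-conforming; 0 means the Rasch model fits better
#' outright.
#'
#' @param rasch,twopl `irt_fit` objects fitted to `rm` (identical cells).
#' @param rm The [response_matrix()] both models were fitted to.
#' @return One-row tibble: `elpd_rasch`, `elpd_2pl`, `elpd_diff`,
#'   `se_diff`, `ratio`, `n_cells`.
#' @export
compare_models <- function(rasch, twopl, rm) {
  ll1 <- pointwise_loglik(rasch, rm)
  ll2 <- pointwise_loglik(twopl, rm)
  obs1 <- !is.na(ll1)
  obs2 <- !is.na(ll2)
  if (!identical(obs1, obs2)) {
    rlang::abort("Fits cover different cell sets.")
  }
  n_cells <- sum(obs1)
  p1 <- effective_params(rasch)
  p2 <- effective_params(twopl)
  d <- (ll2[obs2] - p2 / n_cells) - (ll1[obs1] - p1 / n_cells)
  elpd1 <- sum(ll1[obs1]) - p1
  elpd2 <- sum(ll2[obs2]) - p2
  elpd_diff <- elpd2 - elpd1
  se_diff <- sqrt(n_cells) * stats::sd(d)
  ratio <- if (elpd_diff <= 0 || se_diff == 0) 0 else elpd_diff / (2 * se_diff)
  tibble::tibble(elpd_rasch = elpd1, elpd_2pl = elpd2,
                 elpd_diff = elpd_diff, se_diff = se_diff,
                 ratio = ratio, n_cells = n_cells)
}

effective_params <- function(fit) {
  J <- nrow(fit$items)
  if (fit$model == "rasch") J + 1 else 2 * J  # + ability-scale SD for Rasch
}

#' Sweep candidate short-form sizes
#'
#' Runs the full selection pipeline over a range of subset sizes: for each
#' size, calibrate normalizers, anneal (`n_runs` independent seeds), refit
#' Rasch and 2PL models on the selected items, compare them
#' ([compare_models()]), and correlate the subset sum score with the
#' full-pool sum score, overall and within covariate strata (sex levels and
#' age terciles when present). The resulting table is the evidence base for
#' choosing the short-form length: the smallest size whose correlation has
#' plateaued while the comparison ratio stays at or below 1.
#'
#' @param rm A [response_matrix()] for the full pool.
#' @param sizes Integer vector of subset sizes.
#' @param weights An [objective_weights()] (normalizers recalibrated per
#'   size).
#' @param schedule An [anneal_schedule()].
#' @param n_runs Independent annealing runs per size.
#' @param seed Integer master seed.
#' @param guessing Fixed guessing floor for all fits.
#' @return A tibble with one row per (size, run, stratum): `size`, `run`,
#'   `objective`, `elpd_diff`, `se_diff`, `ratio`, `stratum`, `r`
#'   (subset/full sum-score Pearson correlation), and the selected
#'   `item_ids` as a list-column.
#' @export
size_sweep <- function(rm, sizes, weights = objective_weights(),
                       schedule = anneal_schedule(), n_runs = 1, seed = 1L,
                       guessing = 0.25) {
  rasch <- fit_rasch(rm, guessing = guessing)
  twopl <- fit_2pl(rm, guessing = guessing)
  fitstats <- item_fit_stats(rasch, rm)
  pool_n <- length(rm_items(rm))
  if (any(sizes < 3 | sizes > pool_n)) {
    rlang::abort("sizes must lie in [3, pool size].")
  }
  full_scores <- sum_scores(rm, "all")$score
  strata <- list(overall = rep(TRUE, nrow(rm)))
  if ("sex" %in% names(rm) && !all(is.na(rm$sex))) {
    for (lv in sort(unique(stats::na.omit(rm$sex)))) {
      strata[[paste0("sex:", lv)]] <- !is.na(rm$sex) & rm$sex == lv
    }
  }
  if ("age" %in% names(rm) && !all(is.na(rm$age))) {
    br <- stats::quantile(rm$age, c(0, 1 / 3, 2 / 3, 1), na.rm = TRUE)
    grp <- cut(rm$age, unique(br), include.lowest = TRUE,
               labels = FALSE)
    for (g in sort(unique(stats::na.omit(grp)))) {
      strata[[paste0("age_tercile:", g)]] <- !is.na(grp) & grp == g
    }
  }

  rows <- list()
  for (m in sizes) {
    w_m <- calibrate_normalizers(weights, rasch, twopl, fitstats, size = m,
                                 seed = seed)
    for (run in seq_len(n_runs)) {
      run_seed <- (seed + 7919L * m + run) %% .Machine$integer.max
      sol <- anneal_select(rasch, twopl, fitstats, m, w_m, schedule, run_seed)
      sub_rm <- response_matrix(
        tibble::as_tibble(as.data.frame(rm)[, c(intersect(RESERVED_COLS,
                                                          names(rm)),
                                                sol$item_ids)]),
        items = sol$item_ids)
      cmp <- if (m == pool_n) {
        tibble::tibble(elpd_diff = 0, se_diff = NA_real_, ratio = 0)
      } else {
        r1 <- fit_rasch(sub_rm, guessing = guessing)
        r2 <- fit_2pl(sub_rm, guessing = guessing)
        compare_models(r1, r2, sub_rm)
      }
      sub_scores <- sum_scores(rm, sol$item_ids)$score
      for (s in names(strata)) {
        sel <- strata[[s]]
        r_val <- if (sum(sel) >= 3 && stats::sd(sub_scores[sel]) > 0 &&
                     stats::sd(full_scores[sel]) > 0) {
          stats::cor(sub_scores[sel], full_scores[sel])
        } else NA_real_
        rows[[length(rows) + 1]] <- tibble::tibble(
          size = m, run = run, objective = sol$objective,
          elpd_diff = cmp$elpd_diff, se_diff = cmp$se_diff,
          ratio = cmp$ratio, stratum = s, r = r_val,
          item_ids = list(sol$item_ids)
        )
      }
    }
  }
  dplyr::bind_rows(rows)
}
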