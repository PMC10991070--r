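POSITIONS <- c("UL", "UR", "LL", "LR")
DISTRACTOR_TYPES <- c("unrelated", "semantic", "phonological")

#' Counterbalanced target positions
#'
#' Assigns the target picture's corner (upper/lower x left/right) for each
#' trial under three rules: (1) each position is used equally often (within
#' 1 when 4 does not divide the number of trials); (2) no position repeats
#' in more than three consecutive trials; (3) every window of seven
#' consecutive trials contains all four positions. Sequences are built by
#' seeded randomized construction with restarts, so a valid sequence is
#' always found.
#'
#' @param n_trials Number of trials (>= 7).
#' @param seed Integer seed; output is deterministic given it.
#' @return Character vector of positions (`"UL"`, `"UR"`, `"LL"`, `"LR"`).
#' @export
assign_positions <- function(n_trials, seed = 1L) {
  if (n_trials < 7) rlang::abort("n_trials must be at least 7.")
  withr::with_seed(seed, {
    for (attempt in seq_len(10000)) {
      seq_out <- try_build_positions(n_trials)
      if (!is.null(seq_out)) return(POSITIONS[seq_out])
    }
    rlang::abort("Could not construct a valid position sequence.")
  })
}

# One randomized construction pass; NULL on dead end.
try_build_positions <- function(n) {
  cap <- rep(ceiling(n / 4), 4)
  # distribute the floor counts when 4 does not divide n
  if (n %% 4 != 0) {
    hi <- sample.int(4, n %% 4)
    cap <- rep(floor(n / 4), 4)
    cap[hi] <- cap[hi] + 1
  }
  count <- rep(0L, 4)
  last <- rep(0L, 4)   # index of last occurrence
  run_pos <- 0L
  run_len <- 0L
  out <- integer(n)
  for (i in seq_len(n)) {
    # rule 3: positions unseen for 6 trials must be played now
    urgent <- which(i >= 7 & last <= i - 7L)
    feasible <- which(count < cap)
    if (run_len >= 3L) feasible <- setdiff(feasible, run_pos)
    if (length(urgent) > 1) return(NULL)
    if (length(urgent) == 1) {
      if (!urgent %in% feasible) return(NULL)
      p <- urgent
    } else {
      if (length(feasible) == 0) return(NULL)
      p <- feasible[sample.int(length(feasible), 1)]
    }
    out[i] <- p
    count[p] <- count[p] + 1L
    last[p] <- i
    if (p == run_pos) run_len <- run_len + 1L else {
      run_pos <- p
      run_len <- 1L
    }
  }
  out
}

#' Verify the three counterbalancing rules
#'
#' @param positions Character vector of corner labels.
#' @return A list: `balanced`, `max_run`, `windows_ok`, `passed`.
#' @export
check_counterbalancing <- function(positions) {
  n <- length(positions)
  counts <- table(factor(positions, levels = POSITIONS))
  balanced <- max(counts) - min(counts) <= (n %% 4 != 0)
  r <- rle(positions)
  max_run <- max(r$lengths)
  windows_ok <- TRUE
  if (n >= 7) {
    for (i in seq_len(n - 6)) {
      if (length(unique(positions[i:(i + 6)])) < 4) {
        windows_ok <- FALSE
        break
      }
    }
  }
  list(balanced = balanced, max_run = max_run, windows_ok = windows_ok,
       passed = balanced && max_run <= 3 && windows_ok)
}

#' Distractor corner assignment
#'
#' Places the three distractor types (unrelated, semantic, phonological) on
#' the corners left free by the target so that, across trials, each type
#' occupies each corner about equally often (per-corner counts differ by at
#' most 1 between types). A greedy balancer picks, per trial, the
#' permutation of types that best evens out the running counts, with seeded
#' random tie-breaks.
#'
#' @param positions Target positions from [assign_positions()].
#' @param seed Integer seed.
#' @return A tibble: `trial`, `target_position`, and one column per
#'   distractor type giving its corner.
#' @export
assign_distractor_positions <- function(positions, seed = 1L) {
  n <- length(positions)
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                c(3, 1, 2), c(3, 2, 1))
  withr::with_seed(seed, {
    counts <- matrix(0L, nrow = 3, ncol = 4,
                     dimnames = list(DISTRACTOR_TYPES, POSITIONS))
    out <- matrix(NA_character_, nrow = n, ncol = 3,
                  dimnames = list(NULL, DISTRACTOR_TYPES))
    for (i in seq_len(n)) {
      free <- setdiff(POSITIONS, positions[i])
      # score each permutation by the imbalance it would leave behind
      scores <- vapply(perms, function(p) {
        cnt <- counts
        for (k in 1:3) cnt[p[k], free[k]] <- cnt[p[k], free[k]] + 1L
        sum(apply(cnt, 2, function(col) max(col) - min(col)))
      }, numeric(1))
      best <- which(scores == min(scores))
      p <- perms[[best[sample.int(length(best), 1)]]]
      for (k in 1:3) {
        out[i, p[k]] <- free[k]
        counts[p[k], free[k]] <- counts[p[k], free[k]] + 1L
      }
    }
    tibble::tibble(trial = seq_len(n), target_position = positions,
                   unrelated = out[, "unrelated"],
                   semantic = out[, "semantic"],
                   phonological = out[, "phonological"])
  })
}

#' Generate an administration order with an AoA difficulty gradient
#'
#' Orders the item bank so that trial number and age-of-acquisition rating
#' correlate at a target level (0.85 by default): later trials are harder,
#' but not perfectly so. The order starts from the AoA-sorted sequence and
#' applies seeded random transpositions, accepting a swap only if it moves
#' the correlation toward the target, until the achieved value is within
#' `tol`. Target and distractor corners are then counterbalanced via
#' [assign_positions()] and [assign_distractor_positions()].
#'
#' @param bank Item-bank tibble with `item_id` and complete `aoa_rating`.
#' @param target_r Target Pearson correlation between trial index and AoA.
#' @param tol Acceptable deviation from `target_r` (default 0.02).
#' @param seed Integer seed.
#' @param order_label Label stored on the output (e.g. `"A"` or `"B"`).
#' @param max_iter Swap budget before giving up.
#' @return A tibble of class `trial_order`: `trial`, `item_id`,
#'   `aoa_rating`, `target_position`, distractor corners; attributes
#'   `achieved_correlation` and `order_label`.
#' @export
generate_order <- function(bank, target_r = 0.85, tol = 0.02, seed = 1L,
                           order_label = "A", max_iter = 200000) {
  bank <- validate_item_bank(bank)
  if (!"aoa_rating" %in% names(bank) || anyNA(bank$aoa_rating)) {
    rlang::abort("All items need an aoa_rating to generate an order.")
  }
  if (abs(target_r) > 1) rlang::abort("|target_r| must be <= 1.")
  n <- nrow(bank)
  aoa <- bank$aoa_rating
  idx_time <- seq_len(n)

  ord <- withr::with_seed(seed, {
    ord <- order(aoa, bank$item_id)  # ascending AoA start, r ~ 1
    r_cur <- stats::cor(idx_time, aoa[ord])
    it <- 0
    while (abs(r_cur - target_r) > tol && it < max_iter) {
      it <- it + 1
      ij <- sample.int(n, 2)
      cand <- ord
      cand[ij] <- cand[rev(ij)]
      r_new <- stats::cor(idx_time, aoa[cand])
      if (abs(r_new - target_r) < abs(r_cur - target_r)) {
        ord <- cand
        r_cur <- r_new
      }
    }
    if (abs(r_cur - target_r) > tol) {
      rlang::abort(sprintf(
        "Could not reach target correlation %.3f (best achieved %.3f).",
        target_r, r_cur))
    }
    ord
  })

  positions <- assign_positions(n, seed = seed)
  corners <- assign_distractor_positions(positions, seed = seed)
  out <- tibble::tibble(
    trial = idx_time,
    item_id = bank$item_id[ord],
    aoa_rating = aoa[ord],
    target_position = positions,
    unrelated = corners$unrelated,
    semantic = corners$semantic,
    phonological = corners$phonological
  )
  structure(out,
            achieved_correlation = stats::cor(idx_time, aoa[ord]),
            order_label = order_label,
            class = c("trial_order", class(out)))
}

#' @export
print.trial_order <- function(x, ...) {
  cat(sprintf("<trial_order> %s: %d trials, r(trial, AoA) = %.3f\n",
              attr(x, "order_label"), nrow(x),
              attr(x, "achieved_correlation")))
  NextMethod()
}

#' Write a trial order to CSV or JSON
#'
#' @param order A `trial_order`.
#' @param path Output path (`.csv` or `.json`).
#' @return `path`, invisibly.
#' @export
write_order <- function(order, path) {
  df <- tibble::as_tibble(as.data.frame(order))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(
      list(order_label = attr(order, "order_label"),
           achieved_correlation = attr(order, "achieved_correlation"),
           trials = df),
      path, dataframe = "rows", auto_unbox = TRUE, digits = NA)
  } else {
    readr::write_csv(df, path)
  }
  invisible(path)
}
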