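# Shared fixtures, computed once per test run and memoised.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_env)) {
    assign(key, force(expr), envir = .fixture_env)
  }
  get(key, envir = .fixture_env)
}

# Rasch-truth cohort at the default study scale, with easiness spread -3..3
# (AoA 6..10, slope -1.5, intercept 12, no residual noise).
rasch_truth_cfg <- function(seed, n_persons = 581, n_items = 52,
                            disc_sdlog = 0) {
  sim_config(n_persons = n_persons, n_items = n_items,
             easiness_intercept = 12, easiness_aoa_slope = -1.5,
             easiness_sd = 0, disc_sdlog = disc_sdlog, seed = seed)
}

default_study <- function() {
  memo("default_study", simulate_study(rasch_truth_cfg(seed = 1)))
}

default_rasch <- function() {
  memo("default_rasch", fit_rasch(default_study()$responses))
}

default_2pl <- function() {
  memo("default_2pl", fit_2pl(default_study()$responses))
}

default_fitstats <- function() {
  memo("default_fitstats",
       item_fit_stats(default_rasch(), default_study()$responses))
}

# Small calibrated pool for selection tests (12 items, modest cohort).
small_pool <- function() {
  memo("small_pool", {
    st <- simulate_study(sim_config(n_persons = 400, n_items = 12,
                                    disc_sdlog = 0.3, seed = 7))
    rasch <- fit_rasch(st$responses)
    twopl <- fit_2pl(st$responses)
    fitstats <- item_fit_stats(rasch, st$responses)
    list(study = st, rasch = rasch, twopl = twopl, fitstats = fitstats)
  })
}

# Fabricate a calibrated pool directly from item parameters, bypassing
# estimation: used to exercise the subset optimizer in isolation.
fake_pool <- function(easiness, infit = NULL, outfit = NULL, disc = NULL,
                      ids = NULL) {
  J <- length(easiness)
  if (is.null(ids)) ids <- sprintf("it%02d", seq_len(J))
  if (is.null(infit)) infit <- rep(1, J)
  if (is.null(outfit)) outfit <- rep(1, J)
  if (is.null(disc)) disc <- rep(1, J)
  items <- tibble::tibble(
    item_id = ids, easiness = easiness, discrimination = 1,
    guessing = 0.25, se_easiness = NA_real_, se_discrimination = NA_real_,
    disc_at_bound = FALSE
  )
  rasch <- structure(list(model = "rasch", items = items, guessing = 0.25,
                          n_quad = 61, ability_scale = 1),
                     class = "irt_fit")
  items2 <- items
  items2$discrimination <- disc
  twopl <- structure(list(model = "twopl", items = items2, guessing = 0.25,
                          n_quad = 61, ability_scale = 1),
                     class = "irt_fit")
  fitstats <- tibble::tibble(item_id = ids, infit = infit, outfit = outfit,
                             n_used = 100L)
  list(rasch = rasch, twopl = twopl, fitstats = fitstats)
}

random_fake_pool <- function(J, seed) {
  withr::with_seed(seed, {
    fake_pool(easiness = stats::runif(J, -3, 3),
              infit = 1 + stats::rnorm(J, 0, 0.1),
              outfit = 1 + stats::rnorm(J, 0, 0.15),
              disc = stats::rlnorm(J, 0, 0.3))
  })
}

# A synthetic item bank with evenly spread AoA ratings.
toy_bank <- function(n = 52, seed = 1) {
  simulate_bank(sim_config(n_items = n, seed = seed))
}

# Minimal hand-built fit for closed-form diagnostics: all persons at
# theta = 0 and the given item parameters, no guessing.
flat_fit <- function(item_ids, easiness, person_ids, theta = 0,
                     se_theta = 1, guessing = 0) {
  structure(list(
    model = "rasch",
    items = tibble::tibble(
      item_id = item_ids, easiness = easiness, discrimination = 1,
      guessing = guessing, se_easiness = NA_real_,
      se_discrimination = NA_real_, disc_at_bound = FALSE),
    persons = tibble::tibble(
      person_id = person_ids,
      theta = rep_len(theta, length(person_ids)),
      se_theta = rep_len(se_theta, length(person_ids)),
      n_answered = length(item_ids)),
    ability_scale = 1, guessing = guessing, n_quad = 61
  ), class = "irt_fit")
}
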