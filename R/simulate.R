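#' Synthetic-cohort configuration
#'
#' Parameters of the synthetic data generator, which emulates the
#' statistical structure of a web-administered 4-alternative receptive
#' vocabulary study: a cohort of preschool/primary-school children whose
#' latent ability grows with age, and an item pool whose easiness declines
#' with the target word's rated age of acquisition (AoA), under a fixed
#' 1-in-4 guessing floor. The defaults mirror the study conditions the
#' package is designed around: 581 children aged 3--8, 52 items with AoA
#' ratings spread evenly between 6 and 10 years, guessing 0.25, a balanced
#' sex covariate and two administration orders. Effect magnitudes
#' (ability/age slope, residual SDs, easiness/AoA slope) are generator
#' configuration, not estimates from any real cohort.
#'
#' @param n_persons,n_items Cohort and pool sizes.
#' @param guessing Lower asymptote of every item (0.25 for 4AFC).
#' @param age_range Age interval in years; ages are uniform over it.
#' @param ability_age_slope Logits of ability per year of age.
#' @param ability_sd Residual SD of ability around the age trend (logits).
#' @param aoa_range AoA rating interval in years (evenly spread).
#' @param easiness_intercept,easiness_aoa_slope Linear AoA-to-easiness
#'   link, logits (slope negative: later-acquired words are harder).
#' @param easiness_sd Residual SD of easiness around the AoA trend.
#' @param disc_sdlog SD of log-normal true discriminations; 0 gives exact
#'   Rasch truth (all discriminations 1).
#' @param dif_items Character vector of item ids whose easiness is shifted
#'   for order group B (uniform DIF), or `NULL`.
#' @param dif_shift Logit shift applied to `dif_items` for group B.
#' @param seed Integer master seed; each stage derives its own substream
#'   so bank, persons and responses can be regenerated independently.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_persons = 581, n_items = 52, guessing = 0.25,
                       age_range = c(3, 8), ability_age_slope = 0.5,
                       ability_sd = 1, aoa_range = c(6, 10),
                       easiness_intercept = 4.8, easiness_aoa_slope = -0.6,
                       easiness_sd = 0.5, disc_sdlog = 0,
                       dif_items = NULL, dif_shift = 0, seed = 1L) {
  stopifnot(n_persons > 0, n_items > 0, guessing >= 0, guessing < 1,
            disc_sdlog >= 0, ability_sd >= 0, easiness_sd >= 0)
  structure(list(
    n_persons = n_persons, n_items = n_items, guessing = guessing,
    age_range = age_range, ability_age_slope = ability_age_slope,
    ability_sd = ability_sd, aoa_range = aoa_range,
    easiness_intercept = easiness_intercept,
    easiness_aoa_slope = easiness_aoa_slope, easiness_sd = easiness_sd,
    disc_sdlog = disc_sdlog, dif_items = dif_items, dif_shift = dif_shift,
    seed = as.integer(seed)
  ), class = "sim_config")
}

# per-stage substream seeds, kept below 2^31
sub_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) * 1009 + stage * 7907) %% 2147483647)
}

#' Simulate an item bank with known true parameters
#'
#' AoA ratings are spread evenly over `aoa_range`; true easiness follows
#' the linear AoA link plus normal noise, and true discriminations are
#' log-normal (all exactly 1 when `disc_sdlog = 0`). Distractor-type labels
#' are attached so the bank passes full validation.
#'
#' @param cfg A [sim_config()].
#' @return An item-bank tibble with extra columns `true_easiness`,
#'   `true_discrimination`.
#' @export
simulate_bank <- function(cfg) {
  withr::with_seed(sub_seed(cfg$seed, 1L), {
    J <- cfg$n_items
    aoa <- seq(cfg$aoa_range[1], cfg$aoa_range[2], length.out = J)
    bank <- tibble::tibble(
      item_id = sprintf("it%02d", seq_len(J)),
      target_word = sprintf("word%02d", seq_len(J)),
      aoa_rating = aoa,
      distractor_types = "unrelated,semantic,phonological",
      source = ifelse(seq_len(J) <= ceiling(J * 32 / 52), "clt", "new"),
      true_easiness = cfg$easiness_intercept +
        cfg$easiness_aoa_slope * aoa +
        stats::rnorm(J, 0, cfg$easiness_sd),
      true_discrimination = stats::rlnorm(J, 0, cfg$disc_sdlog)
    )
    if (cfg$disc_sdlog == 0) bank$true_discrimination <- rep(1, J)
    bank
  })
}

#' Simulate a cohort of persons with known true abilities
#'
#' Ages are uniform over the configured range; true ability is the age
#' trend (centered at the range midpoint) plus normal residual; sex and
#' order group are assigned 50/50.
#'
#' @param cfg A [sim_config()].
#' @return A tibble: `person_id`, `age`, `sex`, `order_group`,
#'   `true_theta`.
#' @export
simulate_persons <- function(cfg) {
  withr::with_seed(sub_seed(cfg$seed, 2L), {
    N <- cfg$n_persons
    age <- stats::runif(N, cfg$age_range[1], cfg$age_range[2])
    mid <- mean(cfg$age_range)
    tibble::tibble(
      person_id = sprintf("p%04d", seq_len(N)),
      age = age,
      sex = sample(rep_len(c("f", "m"), N)),
      order_group = sample(rep_len(c("A", "B"), N)),
      true_theta = cfg$ability_age_slope * (age - mid) +
        stats::rnorm(N, 0, cfg$ability_sd)
    )
  })
}

#' Simulate binary responses from true parameters
#'
#' Each cell is Bernoulli with probability
#' `c + (1 - c) * plogis(a_j * theta_i + b_j)`; items listed in
#' `cfg$dif_items` have their easiness shifted by `cfg$dif_shift` for
#' persons in order group B.
#'
#' @param persons Output of [simulate_persons()] (or any tibble with
#'   `person_id`, `true_theta`, optional covariates).
#' @param bank Output of [simulate_bank()] (needs `item_id`,
#'   `true_easiness`, `true_discrimination`).
#' @param cfg A [sim_config()].
#' @return A [response_matrix()] carrying the persons' covariates.
#' @export
simulate_responses <- function(persons, bank, cfg) {
  withr::with_seed(sub_seed(cfg$seed, 3L), {
    N <- nrow(persons)
    J <- nrow(bank)
    beta <- matrix(bank$true_easiness, N, J, byrow = TRUE)
    if (!is.null(cfg$dif_items) && cfg$dif_shift != 0 &&
        "order_group" %in% names(persons)) {
      jdx <- match(cfg$dif_items, bank$item_id)
      if (anyNA(jdx)) rlang::abort("dif_items not all in the bank.")
      isB <- persons$order_group == "B"
      beta[isB, jdx] <- beta[isB, jdx] + cfg$dif_shift
    }
    eta <- outer(persons$true_theta, bank$true_discrimination) + beta
    P <- cfg$guessing + (1 - cfg$guessing) * stats::plogis(eta)
    X <- matrix(stats::rbinom(N * J, 1, as.vector(P)), N, J)
    colnames(X) <- bank$item_id
    covs <- intersect(c("person_id", "age", "sex", "order_group"),
                      names(persons))
    df <- dplyr::bind_cols(persons[, covs], tibble::as_tibble(X))
    response_matrix(df, items = bank$item_id)
  })
}

#' Simulate a complete study
#'
#' Convenience wrapper running bank, cohort and response generation from
#' one configuration.
#'
#' @param cfg A [sim_config()].
#' @return A list with elements `bank`, `persons`, `responses`, `config`.
#' @export
simulate_study <- function(cfg = sim_config()) {
  bank <- simulate_bank(cfg)
  persons <- simulate_persons(cfg)
  responses <- simulate_responses(persons, bank, cfg)
  list(bank = bank, persons = persons, responses = responses, config = cfg)
}
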