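#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an IRT fit
#'
#' @param x An `irt_fit`.
#' @param what `"items"` for item parameters (default) or `"persons"` for
#'   EAP abilities.
#' @param ... Unused.
#' @return A tibble of parameter estimates with standard errors.
#' @export
tidy.irt_fit <- function(x, what = c("items", "persons"), ...) {
  what <- rlang::arg_match(what)
  if (what == "items") x$items else x$persons
}

#' @rdname tidy.irt_fit
#' @return For `glance()`: a one-row model summary.
#' @export
glance.irt_fit <- function(x, ...) {
  tibble::tibble(
    model = x$model,
    n_items = nrow(x$items),
    n_persons = nrow(x$persons),
    ability_scale = x$ability_scale,
    loglik = x$loglik,
    loglik_marginal = x$loglik_marginal,
    converged = x$converged,
    n_iter = x$n_iter
  )
}

#' Tidy a subset solution
#'
#' @param x A `subset_solution` from [anneal_select()] or
#'   [exhaustive_select()].
#' @param ... Unused.
#' @return One row per selected item id.
#' @export
tidy.subset_solution <- function(x, ...) {
  tibble::tibble(item_id = x$item_ids)
}

#' @rdname tidy.subset_solution
#' @export
glance.subset_solution <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(size = x$size, objective = x$objective),
    x$components,
    tibble::tibble(seed = x$seed)
  )
}

#' Tidy a DIF analysis
#'
#' @param x A `dif_result` from [dif_analysis()].
#' @param ... Unused.
#' @return The per-item table as a plain tibble.
#' @export
tidy.dif_result <- function(x, ...) {
  tibble::as_tibble(as.data.frame(x))
}

#' @rdname tidy.dif_result
#' @export
glance.dif_result <- function(x, ...) {
  tibble::tibble(
    grouping = attr(x, "grouping"),
    group_1 = attr(x, "groups")[1],
    group_2 = attr(x, "groups")[2],
    group_correlation = attr(x, "group_correlation"),
    n_flagged = sum(!x$intervals_overlap),
    n_items = nrow(x),
    n_excluded = attr(x, "n_excluded")
  )
}
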