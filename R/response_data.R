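# Reserved covariate columns in a wide response table; everything else is an item.
RESERVED_COLS <- c("person_id", "age", "sex", "order_group")

#' Construct a response matrix
#'
#' A response matrix is a wide tibble with one row per person: a `person_id`
#' column, optional covariate columns (`age`, `sex`, `order_group`), and one
#' column per item holding correctness coded 0/1 (NA = not administered /
#' no response). It is the common currency of the whole package: every
#' calibration, diagnostic and selection function consumes one.
#'
#' @param data A data frame in wide person-by-item form.
#' @param items Character vector naming the item columns. Defaults to every
#'   column not among `person_id`, `age`, `sex`, `order_group`.
#' @return A tibble of class `response_matrix` with an `items` attribute.
#' @examples
#' df <- tibble::tibble(person_id = c("p1", "p2"), i1 = c(1, 0), i2 = c(0, NA))
#' rm <- response_matrix(df)
#' rm_items(rm)
#' @export
response_matrix <- function(data, items = NULL) {
  data <- tibble::as_tibble(data)
  if (!"person_id" %in% names(data)) {
    rlang::abort("`data` must have a `person_id` column.")
  }
  data$person_id <- as.character(data$person_id)
  if (is.null(items)) {
    items <- setdiff(names(data), RESERVED_COLS)
  }
  if (length(items) == 0) rlang::abort("No item columns found.")
  if (anyDuplicated(items)) rlang::abort("Duplicate item ids in `items`.")
  missing_items <- setdiff(items, names(data))
  if (length(missing_items) > 0) {
    rlang::abort(paste0("Item columns not in `data`: ",
                        paste(missing_items, collapse = ", ")))
  }
  if (anyDuplicated(data$person_id)) {
    rlang::abort("Duplicate person_id values.")
  }
  for (it in items) {
    v <- data[[it]]
    if (!all(v %in% c(0, 1) | is.na(v))) {
      rlang::abort(paste0("Non-binary response code in item '", it,
                          "': responses must be 0, 1 or missing."))
    }
    data[[it]] <- as.integer(v)
  }
  structure(data, items = items,
            class = c("response_matrix", class(tibble::tibble())))
}

#' @rdname response_matrix
#' @param rm A `response_matrix`.
#' @export
rm_items <- function(rm) {
  items <- attr(rm, "items", exact = TRUE)
  if (is.null(items)) items <- setdiff(names(rm), RESERVED_COLS)
  items
}

# Numeric person x item matrix (0/1/NA) with dimnames from ids.
rm_as_matrix <- function(rm) {
  items <- rm_items(rm)
  m <- as.matrix(as.data.frame(rm)[, items, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- rm$person_id
  m
}

rm_persons <- function(rm) {
  covs <- intersect(RESERVED_COLS, names(rm))
  tibble::as_tibble(as.data.frame(rm)[, covs, drop = FALSE])
}

#' Read a response matrix from CSV
#'
#' Two layouts are supported. `wide`: one row per person with a `person_id`
#' column, optional covariates (`age`, `sex`, `order_group`) and one column
#' per item. `long`: columns `person_id`, `item_id`, `response`, one row per
#' administered cell; cells absent from the file become missing.
#'
#' @param path Path to a CSV file.
#' @param layout `"wide"` or `"long"`.
#' @return A [response_matrix()].
#' @export
read_responses <- function(path, layout = c("wide", "long")) {
  layout <- rlang::arg_match(layout)
  if (!file.exists(path)) rlang::abort(paste0("File not found: ", path))
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (layout == "wide") {
    return(response_matrix(df))
  }
  need <- c("person_id", "item_id", "response")
  if (!all(need %in% names(df))) {
    rlang::abort("Long layout requires columns person_id, item_id, response.")
  }
  df$person_id <- as.character(df$person_id)
  df$item_id <- as.character(df$item_id)
  dup <- duplicated(df[, c("person_id", "item_id")])
  if (any(dup)) {
    k <- df[dup, c("person_id", "item_id")][1, ]
    rlang::abort(paste0("Duplicate (person_id, item_id) pair: (",
                        k$person_id, ", ", k$item_id, ")."))
  }
  if (!all(df$response %in% c(0, 1) | is.na(df$response))) {
    rlang::abort("Non-binary response code in long file.")
  }
  # preserve first-appearance order of persons and items
  porder <- unique(df$person_id)
  iorder <- unique(df$item_id)
  wide <- tidyr::pivot_wider(df, id_cols = "person_id",
                             names_from = "item_id",
                             values_from = "response")
  wide <- wide[match(porder, wide$person_id), c("person_id", iorder)]
  response_matrix(wide, items = iorder)
}

#' Write a response matrix to CSV
#'
#' @param rm A [response_matrix()].
#' @param path Output CSV path.
#' @param layout `"wide"` or `"long"`. The long layout omits missing cells
#'   and drops covariates; a wide write round-trips covariates too.
#' @return `path`, invisibly.
#' @export
write_responses <- function(rm, path, layout = c("wide", "long")) {
  layout <- rlang::arg_match(layout)
  if (layout == "wide") {
    readr::write_csv(tibble::as_tibble(as.data.frame(rm)), path, na = "")
  } else {
    long <- tidyr::pivot_longer(
      tibble::as_tibble(as.data.frame(rm)[, c("person_id", rm_items(rm))]),
      cols = -"person_id", names_to = "item_id", values_to = "response"
    )
    long <- long[!is.na(long$response), ]
    readr::write_csv(long, path)
  }
  invisible(path)
}

#' Sum scores over an item subset
#'
#' The count of correct responses is the working score of a Rasch-conforming
#' task: for items that fit the Rasch model it is a sufficient statistic for
#' ability. Missing cells are excluded from both the score and the count of
#' answered items.
#'
#' @param rm A [response_matrix()].
#' @param subset Character vector of item ids, or `"all"`.
#' @return A tibble with columns `person_id`, `score`, `n_answered`.
#' @export
sum_scores <- function(rm, subset = "all") {
  items <- rm_items(rm)
  if (identical(subset, "all")) subset <- items
  if (length(subset) == 0) rlang::abort("Empty item subset.")
  unknown <- setdiff(subset, items)
  if (length(unknown) > 0) {
    rlang::abort(paste0("Unknown item id(s) in subset: ",
                        paste(unknown, collapse = ", ")))
  }
  m <- rm_as_matrix(rm)[, subset, drop = FALSE]
  tibble::tibble(
    person_id = rm$person_id,
    score = as.integer(rowSums(m == 1, na.rm = TRUE)),
    n_answered = as.integer(rowSums(!is.na(m)))
  )
}

#' Read or write an item bank
#'
#' An item bank is a tibble with one row per item: `item_id`, `target_word`,
#' `aoa_rating` (rated age of acquisition in years), `distractor_types`
#' (comma-separated labels among unrelated/semantic/phonological) and
#' `source` (`clt` for legacy items, `new` for pool extensions). CSV and
#' JSON round-trip the same columns.
#'
#' @param path CSV or JSON file path (by extension).
#' @return A validated item-bank tibble.
#' @export
read_item_bank <- function(path) {
  if (!file.exists(path)) rlang::abort(paste0("File not found: ", path))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    bank <- tibble::as_tibble(jsonlite::fromJSON(path))
  } else {
    bank <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  }
  validate_item_bank(bank)
}

#' @rdname read_item_bank
#' @param bank An item-bank tibble.
#' @export
write_item_bank <- function(bank, path) {
  bank <- validate_item_bank(bank)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(bank, path, dataframe = "rows", na = "null",
                         auto_unbox = TRUE, digits = NA)
  } else {
    readr::write_csv(bank, path, na = "")
  }
  invisible(path)
}

#' @rdname read_item_bank
#' @export
validate_item_bank <- function(bank) {
  bank <- tibble::as_tibble(bank)
  if (!"item_id" %in% names(bank)) rlang::abort("Item bank needs `item_id`.")
  bank$item_id <- as.character(bank$item_id)
  if (anyDuplicated(bank$item_id)) rlang::abort("Duplicate item_id in bank.")
  if ("aoa_rating" %in% names(bank)) {
    bad <- !is.na(bank$aoa_rating) & bank$aoa_rating <= 0
    if (any(bad)) rlang::abort("aoa_rating must be positive when present.")
  }
  if ("distractor_types" %in% names(bank)) {
    ok_set <- c("phonological", "semantic", "unrelated")
    parsed <- strsplit(as.character(bank$distractor_types), "\\s*,\\s*")
    bad <- vapply(seq_along(parsed), function(i) {
      x <- parsed[[i]]
      if (length(x) == 1 && is.na(x)) return(FALSE)
      !setequal(sort(x), ok_set)
    }, logical(1))
    if (any(bad)) {
      rlang::abort(paste0("distractor_types must contain exactly ",
                          "{unrelated, semantic, phonological}; bad item(s): ",
                          paste(bank$item_id[bad], collapse = ", ")))
    }
  }
  bank
}

#' Cross-check an item bank against a response matrix
#'
#' Report-only consistency check: which item ids appear on one side but not
#' the other. The check passes iff the two id sets coincide.
#'
#' @param bank An item-bank tibble.
#' @param rm A [response_matrix()].
#' @return A list of class `bank_match_report` with elements
#'   `missing_in_bank`, `missing_in_matrix`, `passed`.
#' @export
validate_bank_against_matrix <- function(bank, rm) {
  bank_ids <- as.character(bank$item_id)
  rm_ids <- rm_items(rm)
  out <- list(
    missing_in_bank = setdiff(rm_ids, bank_ids),
    missing_in_matrix = setdiff(bank_ids, rm_ids),
    passed = setequal(bank_ids, rm_ids)
  )
  class(out) <- "bank_match_report"
  out
}

#' @export
print.bank_match_report <- function(x, ...) {
  cat("Item bank / response matrix cross-check:",
      if (x$passed) "PASS" else "FAIL", "\n")
  if (length(x$missing_in_bank)) {
    cat("  In matrix, absent from bank:",
        paste(x$missing_in_bank, collapse = ", "), "\n")
  }
  if (length(x$missing_in_matrix)) {
    cat("  In bank, absent from matrix:",
        paste(x$missing_in_matrix, collapse = ", "), "\n")
  }
  invisible(x)
}
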