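#' Read and write observation datasets as CSV
#'
#' The four record types (stem survey, flower-level records, plant
#' monitoring, flower pairs) are stored as UTF-8 comma-delimited files with
#' a header row; sex is coded `F`/`H`, booleans as `0`/`1`, missing values
#' as empty fields. A write followed by a read restores the tibble exactly.
#'
#' @param data A tibble produced by one of the generators (or real data with
#'   the same headers).
#' @param path CSV file path.
#' @param type One of `"survey"`, `"flowers"`, `"plants"`, `"pairs"`, or
#'   `"auto"` (default) to detect the type from the header.
#' @return `write_dataset()` returns `path` invisibly. `read_dataset()`
#'   returns a validated tibble; a header-only file gives an empty tibble.
#' @examples
#' path <- tempfile(fileext = ".csv")
#' survey <- simulate_survey(sim_config(n_units = 10, n_populations = 2))
#' write_dataset(survey, path)
#' identical(read_dataset(path), survey)
#' @export
write_dataset <- function(data, path) {
  stopifnot(is.data.frame(data))
  out <- data |>
    dplyr::mutate(dplyr::across(dplyr::where(is.logical), as.integer)) |>
    # full-precision decimal rendering so numeric fields round-trip exactly
    dplyr::mutate(dplyr::across(
      dplyr::where(function(x) is.double(x) && !is.integer(x)),
      function(x) ifelse(is.na(x), NA_character_, sprintf("%.17g", x))
    ))
  readr::write_csv(out, path, na = "")
  invisible(path)
}

# columns stored as integers in each schema (restored after readr's guess)
dataset_int_cols <- function(type, cols) {
  fixed <- switch(type,
    survey = c("open_flowers", "eggs", "caterpillars", "leaf_damage",
               "flower_damage"),
    flowers = "egg",
    plants = c("stems", "open_flowers", "egg_any", "eggs_total",
               "fruits_expanded", "fruits_damaged"),
    pairs = "seeds"
  )
  patterns <- if (type == "plants") {
    grep("^egg_census_[0-9]+$|_damage_[0-9]+$", cols, value = TRUE)
  } else {
    character(0)
  }
  intersect(c(fixed, patterns), cols)
}

dataset_dbl_cols <- function(type, cols) {
  fixed <- switch(type,
    plants = c("height", "projected_area", "flower_depth", "flower_width"),
    pairs = c("calyx_width", "calyx_length", "flower_length",
              "floral_face_width", "tube_opening", "fruit_mass"),
    character(0)
  )
  intersect(fixed, cols)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path, type = c("auto", "survey", "flowers",
                                        "plants", "pairs")) {
  type <- rlang::arg_match(type)
  if (!file.exists(path)) {
    rlang::abort(sprintf("Input file does not exist: %s", path))
  }
  # read as character, then coerce with base R's correctly rounded numeric
  # parser so written doubles are restored bit-for-bit
  data <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                          progress = FALSE, show_col_types = FALSE,
                          na = "")
  probs <- readr::problems(data)
  if (nrow(probs) > 0) {
    rlang::abort(sprintf(
      "Malformed rows in %s (first at line %d: expected %s, got %s).",
      path, probs$row[1] + 1L, probs$expected[1], probs$actual[1]
    ))
  }
  if (type == "auto") type <- detect_dataset_type(names(data))
  coerce <- function(cl, fun, what) {
    parsed <- suppressWarnings(fun(data[[cl]]))
    bad <- which(is.na(parsed) & !is.na(data[[cl]]))
    if (length(bad)) {
      abort_rows(sprintf("Non-%s value \"%s\" in `%s`", what,
                         data[[cl]][bad[1]], cl), bad)
    }
    parsed
  }
  for (cl in dataset_int_cols(type, names(data))) {
    data[[cl]] <- coerce(cl, function(x) as.integer(as.numeric(x)), "integer")
  }
  for (cl in dataset_dbl_cols(type, names(data))) {
    data[[cl]] <- coerce(cl, as.numeric, "numeric")
  }
  validator <- switch(type,
    survey = validate_survey, flowers = validate_flowers,
    plants = validate_plants, pairs = validate_pairs
  )
  validator(data)
  data
}

detect_dataset_type <- function(cols) {
  if (all(c("population", "stem_id", "sex", "egg") %in% cols) &&
      !"eggs" %in% cols) return("flowers")
  if (all(c("population", "sex", "open_flowers", "eggs") %in% cols)) {
    return("survey")
  }
  if (all(c("plant_id", "flower_depth", "fruits_expanded") %in% cols)) {
    return("plants")
  }
  if (all(c("pair_id", "flower", "calyx_width", "seeds") %in% cols)) {
    return("pairs")
  }
  rlang::abort("Cannot detect dataset type from the header; pass `type=`.")
}

# --- validators (shared by read_dataset and the analysis entry points) ----

abort_rows <- function(what, rows) {
  # +1 converts data-row index to file line number (header is line 1)
  rlang::abort(sprintf("%s at line%s %s.", what,
                       if (length(rows) > 1) "s" else "",
                       paste(utils::head(rows, 5) + 1L, collapse = ", ")))
}

check_sex <- function(data) {
  bad <- which(!data$sex %in% c("F", "H"))
  if (length(bad)) {
    abort_rows(sprintf("Unknown sex code \"%s\"", data$sex[bad[1]]), bad)
  }
}

check_cols <- function(data, cols, what) {
  missing <- setdiff(cols, names(data))
  if (length(missing)) {
    rlang::abort(sprintf("%s data is missing column%s: %s.", what,
                         if (length(missing) > 1) "s" else "",
                         paste(missing, collapse = ", ")))
  }
}

check_nonneg_int <- function(data, cols) {
  for (cl in cols) {
    v <- data[[cl]]
    bad <- which(!is.na(v) & (v < 0 | v != floor(v)))
    if (length(bad)) abort_rows(sprintf("Negative or non-integer `%s`", cl), bad)
  }
}

validate_survey <- function(data) {
  check_cols(data, c("population", "sex", "open_flowers", "eggs",
                     "caterpillars", "leaf_damage", "flower_damage"),
             "Survey")
  if (nrow(data) == 0) return(invisible(data))
  check_sex(data)
  check_nonneg_int(data, c("open_flowers", "eggs", "caterpillars"))
  bad <- which(data$open_flowers < 1)
  if (length(bad)) abort_rows("Stem without an open flower", bad)
  invisible(data)
}

validate_flowers <- function(data) {
  check_cols(data, c("population", "sex", "egg"), "Flower")
  if (nrow(data) == 0) return(invisible(data))
  check_sex(data)
  bad <- which(!data$egg %in% c(0, 1))
  if (length(bad)) abort_rows("Non-binary `egg` indicator", bad)
  invisible(data)
}

validate_plants <- function(data) {
  check_cols(data, c("plant_id", "sex", "stems", "height", "projected_area",
                     "open_flowers", "flower_depth", "flower_width",
                     "egg_any", "fruits_expanded", "fruits_damaged"),
             "Monitoring")
  if (nrow(data) == 0) return(invisible(data))
  check_sex(data)
  check_nonneg_int(data, c("stems", "open_flowers", "fruits_expanded",
                           "fruits_damaged"))
  bad <- which(data$flower_depth <= 0)
  if (length(bad)) abort_rows("Nonpositive `flower_depth`", bad)
  invisible(data)
}

validate_pairs <- function(data) {
  check_cols(data, c("pair_id", "plant_id", "flower", "calyx_width",
                     "seeds"), "Pair")
  if (nrow(data) == 0) return(invisible(data))
  bad <- which(!data$flower %in% c("egg", "control"))
  if (length(bad)) abort_rows("Unknown `flower` arm label", bad)
  arm_ok <- data |>
    dplyr::count(.data$pair_id, .data$flower) |>
    tidyr::pivot_wider(names_from = "flower", values_from = "n",
                       values_fill = 0L)
  if (!all(arm_ok$egg == 1L) || !all(arm_ok$control == 1L)) {
    rlang::abort("Every pair must have exactly one egg and one control flower.")
  }
  check_nonneg_int(data, "seeds")
  invisible(data)
}

#' Reshape flower pairs to one row per pair
#'
#' Turns the long two-rows-per-pair representation into a wide table with
#' `egg_*` and `control_*` columns for each measured variable, which is the
#' natural shape for paired tests.
#'
#' @param pairs A long pair tibble as from [simulate_pairs()].
#' @return A tibble with one row per pair.
#' @export
pairs_wide <- function(pairs) {
  validate_pairs(pairs)
  value_cols <- setdiff(names(pairs), c("pair_id", "plant_id", "sex", "flower"))
  tidyr::pivot_wider(pairs,
    id_cols = dplyr::any_of(c("pair_id", "plant_id", "sex")),
    names_from = "flower", values_from = dplyr::all_of(value_cols),
    names_glue = "{flower}_{.value}"
  )
}
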