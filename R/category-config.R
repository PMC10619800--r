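#' Category configuration for a demand system
#'
#' Declares the product categories of the demand system and the columns of
#' the purchase microdata that identify geography, income and the household
#' covariates used by the first-stage probits and the expenditure regression.
#'
#' @param categories Character vector of category labels (length `n >= 2`,
#'   unique). The order fixes the ordering of all matrices downstream.
#' @param reference_category Label of the residual catch-all category (the
#'   "other foods" role). Must be one of `categories`.
#' @param covariate_columns Character vector (non-empty) naming the
#'   sociodemographic columns used as probit and expenditure-regression
#'   regressors.
#' @param state_column,region_column,income_column Column names for the state
#'   identifier, the region identifier and monthly household income.
#'
#' @return An object of class `category_config`.
#' @examples
#' category_config(c("ssb", "milk", "other_foods"),
#'                 reference_category = "other_foods",
#'                 covariate_columns = c("urban", "log_income"))
#' @export
category_config <- function(categories,
                            reference_category = categories[length(categories)],
                            covariate_columns,
                            state_column = "state",
                            region_column = "region",
                            income_column = "income") {
  categories <- as.character(categories)
  if (length(categories) < 2L)
    stop("at least two categories are required", call. = FALSE)
  if (anyDuplicated(categories))
    stop("category labels must be unique", call. = FALSE)
  if (!reference_category %in% categories)
    stop("reference_category '", reference_category,
         "' is not among the categories", call. = FALSE)
  if (missing(covariate_columns) || length(covariate_columns) == 0L)
    stop("covariate_columns must be non-empty", call. = FALSE)
  structure(
    list(categories = categories,
         reference_category = reference_category,
         covariate_columns = as.character(covariate_columns),
         state_column = state_column,
         region_column = region_column,
         income_column = income_column),
    class = "category_config")
}

#' @export
print.category_config <- function(x, ...) {
  cat("Demand-system category configuration\n")
  cat("  categories (", length(x$categories), "): ",
      paste(x$categories, collapse = ", "), "\n", sep = "")
  cat("  reference: ", x$reference_category, "\n", sep = "")
  cat("  covariates: ", paste(x$covariate_columns, collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Read a category configuration from YAML or JSON
#'
#' @param path Path to a YAML (`.yml`/`.yaml`) or JSON file holding the
#'   fields of [category_config()].
#' @return A `category_config` object.
#' @export
read_category_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  spec <- if (ext %in% c("yml", "yaml")) yaml::read_yaml(path)
          else jsonlite::fromJSON(path, simplifyVector = TRUE)
  do.call(category_config, spec[intersect(names(spec), c(
    "categories", "reference_category", "covariate_columns",
    "state_column", "region_column", "income_column"))])
}

#' Write a category configuration to YAML or JSON
#'
#' @param config A `category_config`.
#' @param path Destination path; format chosen from the extension.
#' @export
write_category_config <- function(config, path) {
  stopifnot(inherits(config, "category_config"))
  ext <- tolower(tools::file_ext(path))
  x <- unclass(config)
  if (ext %in% c("yml", "yaml")) yaml::write_yaml(x, path)
  else jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

n_categories <- function(config) length(config$categories)

reference_index <- function(config)
  match(config$reference_category, config$categories)
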