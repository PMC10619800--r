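#' Read household purchase microdata
#'
#' Reads long-format purchase-diary records: one row per household x
#' category with positive expenditure; (household, category) pairs that do
#' not appear are zero purchases. The delimiter (comma or tab) is
#' auto-detected. Required columns: `household_id`, `category`,
#' `expenditure`, `quantity`, plus the state, region, income and covariate
#' columns named by `config`.
#'
#' Households with a missing value in any required covariate are dropped
#' (complete-case construction of the estimation sample); the count is
#' recorded in the `dropped_households` attribute.
#'
#' @param path Delimited text file (CSV/TSV, UTF-8, header row).
#' @param config A [category_config()].
#' @return A `data.frame` of class `purchase_table` with attributes
#'   `config` and `dropped_households`.
#' @export
read_purchases <- function(path, config) {
  stopifnot(inherits(config, "category_config"))
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE,
                          encoding = "UTF-8")
  as_purchase_table(dt, config)
}

#' Validate a purchase data frame against a configuration
#'
#' @param df Long-format data frame (see [read_purchases()]).
#' @param config A [category_config()].
#' @return A validated `purchase_table`.
#' @export
as_purchase_table <- function(df, config) {
  stopifnot(inherits(config, "category_config"))
  required <- c("household_id", "category", "expenditure", "quantity",
                config$state_column, config$region_column,
                config$income_column, config$covariate_columns)
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  df$expenditure <- as.numeric(df$expenditure)
  df$quantity <- as.numeric(df$quantity)
  unknown <- setdiff(unique(df$category), config$categories)
  if (length(unknown))
    stop("unknown category label(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  bad <- which(df$expenditure < 0 | df$quantity < 0)
  if (length(bad))
    stop("negative expenditure or quantity in row(s): ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  # purchase rows must carry both a positive expenditure and quantity
  incons <- which(xor(df$expenditure > 0, df$quantity > 0))
  if (length(incons))
    stop("expenditure and quantity must be jointly positive on purchase ",
         "rows; offending row(s): ",
         paste(utils::head(incons, 5L), collapse = ", "), call. = FALSE)

  n_in <- length(unique(df$household_id))
  cc <- stats::complete.cases(df[, required, drop = FALSE])
  bad_hh <- unique(df$household_id[!cc])
  df <- df[!df$household_id %in% bad_hh, , drop = FALSE]
  if (length(bad_hh))
    message(length(bad_hh), " household(s) dropped for incomplete covariates")
  structure(df,
            config = config,
            dropped_households = length(bad_hh),
            input_households = n_in,
            class = c("purchase_table", "data.frame"))
}

#' Convert wide purchase data to the canonical long format
#'
#' Convenience reader for tables with one row per household and one pair of
#' `<category>_expenditure` / `<category>_quantity` columns per category;
#' converted immediately to the long layout and validated.
#'
#' @param df Wide-format data frame.
#' @param config A [category_config()].
#' @return A `purchase_table`.
#' @export
wide_to_purchases <- function(df, config) {
  stopifnot(inherits(config, "category_config"))
  keep <- c("household_id", config$state_column, config$region_column,
            config$income_column, config$covariate_columns)
  out <- list()
  for (cat in config$categories) {
    ec <- paste0(cat, "_expenditure"); qc <- paste0(cat, "_quantity")
    if (!all(c(ec, qc) %in% names(df))) next
    pos <- df[[ec]] > 0
    if (!any(pos)) next
    block <- df[pos, keep, drop = FALSE]
    block$category <- cat
    block$expenditure <- df[[ec]][pos]
    block$quantity <- df[[qc]][pos]
    out[[cat]] <- block
  }
  as_purchase_table(do.call(rbind, out), config)
}

#' Write a purchase table to delimited text
#'
#' @param purchases A `purchase_table`.
#' @param path Destination (`.csv` or `.tsv`).
#' @export
write_purchases <- function(purchases, path) {
  sep <- if (tolower(tools::file_ext(path)) == "tsv") "\t" else ","
  df <- as.data.frame(purchases)
  # shortest round-trip representation so numeric fields survive exactly
  for (col in names(df))
    if (is.double(df[[col]]))
      df[[col]] <- vapply(df[[col]], function(v)
        formatC(v, digits = 17, format = "g"), character(1))
  data.table::fwrite(df, path, sep = sep)
  invisible(path)
}

households_of <- function(purchases) unique(purchases$household_id)
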