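#' Significance stars from z-ratios
#'
#' Two-sided normal-reference stars at p < 0.01 (`***`), p < 0.05 (`**`)
#' and p < 0.1 (`*`).
#'
#' @param estimate,se Numeric vectors/matrices of equal shape.
#' @return Character object of the same shape.
#' @export
significance_stars <- function(estimate, se) {
  p <- 2 * stats::pnorm(-abs(estimate / se))
  out <- ifelse(p < 0.01, "***", ifelse(p < 0.05, "**",
                ifelse(p < 0.1, "*", "")))
  out[!is.finite(p)] <- ""
  dim(out) <- dim(estimate)
  out
}

#' Write an elasticity report
#'
#' Writes (a) the n x n price-elasticity matrix with significance stars,
#' (b) the expenditure-elasticity vector, and optionally (c) subgroup
#' (e.g. income-quintile) own-price columns, as a set of CSV files plus a
#' single JSON bundle preserving full numeric precision.
#'
#' @param result An `elasticity_result`.
#' @param path Output stem: `<path>_price.csv`,
#'   `<path>_expenditure.csv`, `<path>.json` are written (and
#'   `<path>_subgroups.csv` when `subgroups` given).
#' @param subgroups Optional named list of `elasticity_result` for
#'   subgroup columns.
#' @return Invisibly, the paths written.
#' @export
write_elasticity_report <- function(result, path, subgroups = NULL) {
  stopifnot(inherits(result, "elasticity_result"))
  E <- result$price_elasticities
  cats <- result$categories
  if (is.null(result$se_price)) {
    warning("standard errors absent; report written without stars",
            call. = FALSE)
    stars_p <- matrix("", nrow(E), ncol(E))
    stars_e <- rep("", length(cats))
  } else {
    stars_p <- significance_stars(E, result$se_price)
    stars_e <- significance_stars(result$expenditure_elasticities,
                                  result$se_expenditure)
  }
  cells <- matrix(paste0(formatC(E, digits = 4, format = "f"), stars_p),
                  nrow(E), dimnames = dimnames(E))
  p1 <- paste0(path, "_price.csv")
  utils::write.csv(data.frame(category = cats, cells,
                              check.names = FALSE), p1, row.names = FALSE)
  p2 <- paste0(path, "_expenditure.csv")
  utils::write.csv(
    data.frame(category = cats,
               estimate = paste0(
                 formatC(result$expenditure_elasticities, digits = 4,
                         format = "f"), stars_e)),
    p2, row.names = FALSE)
  paths <- c(p1, p2)
  if (!is.null(subgroups)) {
    p3 <- paste0(path, "_subgroups.csv")
    own <- vapply(subgroups,
                  function(r) diag(r$price_elasticities), numeric(length(cats)))
    utils::write.csv(data.frame(category = cats, own, check.names = FALSE),
                     p3, row.names = FALSE)
    paths <- c(paths, p3)
  }
  pj <- paste0(path, ".json")
  jsonlite::write_json(
    list(categories = cats,
         price_elasticities = E,
         expenditure_elasticities = result$expenditure_elasticities,
         se_price = result$se_price,
         se_expenditure = result$se_expenditure,
         evaluation = result$evaluation[c("subgroup_label", "lnm",
                                          "n_households")],
         derivation_mode = result$derivation_mode),
    pj, auto_unbox = TRUE, digits = NA, na = "null", matrix = "rowmajor")
  invisible(c(paths, pj))
}

#' Read back the JSON dialect of an elasticity report
#'
#' @param path Path to the `.json` file written by
#'   [write_elasticity_report()].
#' @return List with `price_elasticities` (matrix),
#'   `expenditure_elasticities` and standard errors.
#' @export
read_elasticity_report <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  cats <- obj$categories
  fixmat <- function(m) {
    if (is.null(m)) return(NULL)
    m <- as.matrix(m)
    dimnames(m) <- list(cats, cats)
    m
  }
  list(categories = cats,
       price_elasticities = fixmat(obj$price_elasticities),
       expenditure_elasticities = stats::setNames(
         as.numeric(obj$expenditure_elasticities), cats),
       se_price = fixmat(obj$se_price),
       se_expenditure = if (is.null(obj$se_expenditure)) NULL else
         stats::setNames(as.numeric(obj$se_expenditure), cats))
}

#' Descriptive consumption tables
#'
#' Per category: percentage of households with a positive purchase, mean
#' expenditure over all households, conditional mean expenditure over
#' purchasers, and mean share of total food expenditure. With `by`, the
#' same quantities per level of a grouping column.
#'
#' @param purchases A `purchase_table`.
#' @param config A [category_config()]; defaults to the attached one.
#' @param by Optional name of a household-level column to break down by.
#' @return Data frame (category rows; plus a `group` column with `by`).
#' @export
descriptive_tables <- function(purchases,
                               config = attr(purchases, "config"),
                               by = NULL) {
  df <- as.data.frame(purchases)
  hh <- unique(df$household_id)
  H <- length(hh)
  first <- df[!duplicated(df$household_id), , drop = FALSE]
  first <- first[match(hh, first$household_id), , drop = FALSE]
  m_tot <- tapply(df$expenditure, df$household_id, sum)[as.character(hh)]

  one_block <- function(sel_hh, label = NULL) {
    sub <- df[df$household_id %in% sel_hh, , drop = FALSE]
    Hs <- length(sel_hh)
    rows <- lapply(config$categories, function(cat) {
      rows_c <- sub[sub$category == cat & sub$expenditure > 0, ,
                    drop = FALSE]
      spend <- tapply(rows_c$expenditure, rows_c$household_id, sum)
      n_buy <- length(spend)
      total <- sum(spend)
      share <- sum(spend / m_tot[names(spend)])
      data.frame(category = cat,
                 prevalence_pct = 100 * n_buy / Hs,
                 mean_expenditure = total / Hs,
                 conditional_mean_expenditure =
                   if (n_buy) total / n_buy else NA_real_,
                 mean_share_pct = 100 * share / Hs)
    })
    out <- do.call(rbind, rows)
    if (!is.null(label)) out <- cbind(group = label, out)
    out
  }
  if (is.null(by)) return(one_block(hh))
  stopifnot(by %in% names(first))
  lv <- sort(unique(first[[by]]))
  do.call(rbind, lapply(lv, function(g)
    one_block(first$household_id[first[[by]] == g], label = g)))
}

#' Joint purchase share of two categories
#'
#' Percentage of households purchasing both named categories (the joint
#' consumption of the two sweetened-beverage types in the motivating
#' application).
#'
#' @param purchases A `purchase_table`.
#' @param cat_a,cat_b Category labels.
#' @return Scalar percentage.
#' @export
joint_purchase_share <- function(purchases, cat_a, cat_b) {
  df <- as.data.frame(purchases)
  hh <- unique(df$household_id)
  buy <- function(cat)
    unique(df$household_id[df$category == cat & df$expenditure > 0])
  100 * length(intersect(buy(cat_a), buy(cat_b))) / length(hh)
}
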