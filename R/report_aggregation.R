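# Cross-strain / cross-class total rows for report tables.  All summary
# totals in the report bundle flow through this one aggregator so that every
# printed total is a recount of the underlying per-strain table.

#' Append margin-total rows to a count table
#'
#' Sums `count_col` over `margin_col`, grouping by every other column, and
#' appends the sums as rows labelled `total_label` in `margin_col`. Feeding
#' the per-strain transporter totals of three strains, for example, yields
#' one extra cross-strain `Total` row; feeding a family-by-strain table
#' yields one `Total` row per family.
#'
#' @param df count data frame.
#' @param margin_col column to sum over (default `"strain"`).
#' @param count_col numeric count column (default `"count"`).
#' @param total_label label written into `margin_col` (default `"Total"`).
#' @return `df` with total rows appended.
#' @export
add_margin_totals <- function(df, margin_col = "strain",
                              count_col = "count", total_label = "Total") {
  stopifnot(margin_col %in% names(df), count_col %in% names(df))
  others <- setdiff(names(df), c(margin_col, count_col))
  if (!nrow(df)) return(df)
  if (length(others)) {
    tot <- stats::aggregate(df[[count_col]], by = as.list(df[others]),
                            FUN = sum)
    names(tot)[ncol(tot)] <- count_col
  } else {
    tot <- stats::setNames(data.frame(sum(df[[count_col]])), count_col)
  }
  tot[[margin_col]] <- total_label
  rbind(df, tot[, names(df), drop = FALSE])
}

#' Read a margin total back out of an aggregated table
#'
#' @param df output of [add_margin_totals()].
#' @param margin_col,count_col,total_label as in [add_margin_totals()].
#' @param where optional named list of column filters applied first.
#' @return numeric vector of the selected total counts.
#' @export
margin_total <- function(df, margin_col = "strain", count_col = "count",
                         total_label = "Total", where = list()) {
  keep <- df[[margin_col]] == total_label
  for (nm in names(where)) keep <- keep & df[[nm]] == where[[nm]]
  df[[count_col]][keep]
}
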