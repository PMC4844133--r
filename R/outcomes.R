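#' Country-year record table
#'
#' Long-format records of one value per country and year: a polity score,
#' or a default-event flag/count for one creditor stream.
#'
#' @param country Character vector of country ids.
#' @param year Integer years.
#' @param value Numeric values.
#' @return A validated data frame of class `country_year_table`.
#' @export
country_year_table <- function(country, year, value) {
  if (any(year != round(year))) stop("years must be integers")
  df <- data.frame(country = as.character(country),
                   year = as.integer(year), value = as.numeric(value))
  if (anyDuplicated(df[c("country", "year")]))
    stop("one record per (country, year) allowed")
  class(df) <- c("country_year_table", "data.frame")
  df
}

#' Time-binned outcome panel
#'
#' Country x time-bin outcome values with missingness, tagged with the bin
#' start years, bin width and outcome variable kind.
#'
#' @param values Numeric matrix, one row per country (rownames = ids), one
#'   column per bin.
#' @param bin_start Integer start year per bin.
#' @param bin_width Bin width in years.
#' @param variable One of `"polity_state"`, `"polity_change"`,
#'   `"default_count"`, `"default_change"`.
#' @return An object of class `panel_outcome`.
#' @export
panel_outcome <- function(values, bin_start, bin_width,
                          variable = c("polity_state", "polity_change",
                                       "default_count", "default_change")) {
  variable <- match.arg(variable)
  values <- as.matrix(values)
  if (length(bin_start) != ncol(values))
    stop("one bin start per column required")
  if (variable == "polity_state" &&
      any(values < -10 | values > 10, na.rm = TRUE))
    stop("polity state values must lie in [-10, 10]")
  if (variable == "default_count" &&
      any(values < 0 | values != round(values), na.rm = TRUE))
    stop("default counts must be nonnegative integers")
  colnames(values) <- as.character(bin_start)
  structure(list(values = values, bin_start = as.integer(bin_start),
                 bin_width = as.integer(bin_width), variable = variable),
            class = "panel_outcome")
}

#' @export
print.panel_outcome <- function(x, ...) {
  cat("panel_outcome (", x$variable, "): ", nrow(x$values), " countries x ",
      ncol(x$values), " bins of width ", x$bin_width, ", ",
      sum(is.na(x$values)), " missing\n", sep = "")
  invisible(x)
}

#' Biennial polity panel
#'
#' Samples the polity score at every other year from `start` to `end`
#' (defaults 1898..2012, giving 58 columns). The Polity project's special
#' codes -66 / -77 / -88 (interruption, interregnum, transition) are not
#' scale values and become missing.
#'
#' @param table A [country_year_table] of polity scores.
#' @param start,end First and last sampled year.
#' @param countries Optional id vector fixing row order (ids absent from
#'   the table get all-missing rows).
#' @return A [panel_outcome] of variable `polity_state`.
#' @export
biennial_polity <- function(table, start = 1898, end = 2012, countries = NULL) {
  if (start > end) stop("start must not exceed end")
  years <- seq(start, end, by = 2)
  if (is.null(countries)) countries <- sort(unique(table$country))
  vals <- matrix(NA_real_, length(countries), length(years),
                 dimnames = list(countries, years))
  tab <- table[table$year %in% years & table$country %in% countries, ]
  tab$value[tab$value %in% c(-66, -77, -88)] <- NA_real_
  vals[cbind(match(tab$country, countries), match(tab$year, years))] <- tab$value
  panel_outcome(vals, years, 2L, "polity_state")
}

#' First differences of a panel
#'
#' Bin-to-bin change: value at bin t minus value at bin t-1, missing when
#' either side is missing. The result has one fewer bin than the source.
#'
#' @param p A [panel_outcome] with at least 2 bins.
#' @return A [panel_outcome] of the matching `*_change` variable.
#' @export
panel_change <- function(p) {
  stopifnot(inherits(p, "panel_outcome"))
  B <- ncol(p$values)
  if (B < 2) stop("need at least 2 bins to difference")
  d <- p$values[, -1, drop = FALSE] - p$values[, -B, drop = FALSE]
  variable <- switch(p$variable,
                     polity_state = "polity_change",
                     default_count = "default_change",
                     p$variable)
  out <- list(values = d, bin_start = p$bin_start[-1],
              bin_width = p$bin_width, variable = variable)
  colnames(out$values) <- as.character(out$bin_start)
  class(out) <- "panel_outcome"
  out
}

#' Five-year default-count panel
#'
#' Sums foreign plus domestic default event-years into bins of `width`
#' years starting at `start`: bin b covers `[start + width*b,
#' start + width*b + width - 1]`. The grid runs until `end` is covered, so
#' trailing bins the event records do not reach are all-zero (they are
#' later dropped as inestimable, which is why a change panel can have more
#' usable bins than a state panel tested from a later start).
#'
#' @param foreign,domestic [country_year_table]s of per-year event flags
#'   (or counts) for the two creditor streams.
#' @param start First year of the first bin.
#' @param width Bin width in years.
#' @param end Last year the bin grid must cover; default the last event year.
#' @param countries Optional id vector fixing row order.
#' @return A [panel_outcome] of variable `default_count`.
#' @export
bin_defaults <- function(foreign, domestic, start = 1899, width = 5,
                         end = NULL, countries = NULL) {
  if (width < 1) stop("width must be >= 1")
  fo <- as.data.frame(foreign); fo$stream <- rep("foreign", nrow(fo))
  dom <- as.data.frame(domestic); dom$stream <- rep("domestic", nrow(dom))
  ev <- rbind(fo, dom)
  if (anyDuplicated(ev[c("country", "year", "stream")]))
    stop("duplicate (country, year, stream) records")
  ev <- ev[ev$year >= start & ev$value != 0, ]
  if (is.null(end)) end <- max(c(ev$year, start + width - 1))
  n_bins <- floor((end - start) / width) + 1
  starts <- start + width * (0:(n_bins - 1))
  if (is.null(countries))
    countries <- sort(unique(c(foreign$country, domestic$country)))
  vals <- matrix(0, length(countries), n_bins,
                 dimnames = list(countries, starts))
  if (nrow(ev)) {
    b <- floor((ev$year - start) / width) + 1
    keep <- b >= 1 & b <= n_bins & ev$country %in% countries
    ev <- ev[keep, ]; b <- b[keep]
    for (r in seq_len(nrow(ev)))
      vals[ev$country[r], b[r]] <- vals[ev$country[r], b[r]] + ev$value[r]
  }
  panel_outcome(vals, starts, as.integer(width), "default_count")
}

#' Align one bin's outcomes with the weight matrices
#'
#' Drops countries missing in that bin, subsets every weight matrix to the
#' retained nodes (see [subset_weights()]), and returns the aligned system.
#'
#' @param p A [panel_outcome].
#' @param bin Bin index (1-based) or bin start year as character.
#' @param weights List of [weight_matrix] objects covering the panel's rows.
#' @return List with `y` (named vector), `weights` (subset list), `nodes`
#'   (retained ids), `bin_start`.
#' @export
align_bin <- function(p, bin, weights) {
  stopifnot(inherits(p, "panel_outcome"))
  if (is.character(bin)) bin <- match(bin, colnames(p$values))
  if (is.na(bin) || bin < 1 || bin > ncol(p$values)) stop("no such bin")
  y <- p$values[, bin]
  keep <- names(y)[!is.na(y)]
  if (length(keep) < 3) {
    stop(structure(class = c("solnet_insufficient_data", "error", "condition"),
                   list(message = paste0("bin ", colnames(p$values)[bin],
                                         ": fewer than 3 countries with data"),
                        call = NULL)))
  }
  for (w in weights)
    if (!all(keep %in% rownames(w)))
      stop("weight matrix '", attr(w, "label"), "' does not cover all panel countries")
  list(y = y[keep],
       weights = lapply(weights, subset_weights, keep = keep),
       nodes = keep,
       bin_start = p$bin_start[bin])
}

#' Read the default-grid CSV dialect (countries x years of 0/1 flags)
#'
#' First column country id, remaining column names are years.
#'
#' @param path File path.
#' @return A [country_year_table] (zero flags dropped).
#' @export
read_default_grid_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  id_col <- names(df)[1]
  years <- suppressWarnings(as.integer(names(df)[-1]))
  if (anyNA(years)) stop("non-year column names in default grid")
  long <- data.frame(
    country = rep(df[[id_col]], times = length(years)),
    year = rep(years, each = nrow(df)),
    value = as.numeric(unlist(df[-1], use.names = FALSE))
  )
  long <- long[!is.na(long$value) & long$value != 0, ]
  country_year_table(long$country, long$year, long$value)
}

#' Read a long-format polity CSV (columns country, year, value)
#'
#' @param path File path.
#' @param cols Column-name mapping, `c(country=, year=, value=)`.
#' @return A [country_year_table].
#' @export
read_polity_csv <- function(path,
                            cols = c(country = "country", year = "year",
                                     value = "polity")) {
  df <- utils::read.csv(path, check.names = FALSE)
  stopifnot(all(cols %in% names(df)))
  country_year_table(df[[cols["country"]]], df[[cols["year"]]],
                     df[[cols["value"]]])
}

#' Write a panel as labelled CSV (countries x bins)
#'
#' @param p A [panel_outcome].
#' @param path File path.
#' @export
write_panel_csv <- function(p, path) {
  df <- data.frame(country = rownames(p$values), p$values, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
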