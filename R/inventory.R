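# Preprocessing of raw 10-minute pharmacy inventory traces into average
# customers served per day: hourly net stock changes -> daily sales (sum of
# the negative changes) -> average sales per day -> customers via the ration
# quota. A restock and sales landing in the same clock hour partially cancel
# (the net change is what the procedure sees); that bias is documented, not
# corrected.

#' Hourly net stock changes of one inventory trace
#'
#' Aggregates the 10-minute stock series to one value per clock hour (the
#' last observation within the hour, matching stock-level semantics) and
#' differences consecutive observed hours. Hours with no observation are
#' skipped; each difference is attributed to the later hour.
#'
#' @param series data.frame with `timestamp` (POSIXct) and `stock` for a
#'   single store.
#' @return data.frame with `hour` (POSIXct, start of the later hour) and
#'   `change` (stock difference from the previous observed hour). Zero rows
#'   when fewer than two hours are observed.
#' @export
hourly_decrements <- function(series) {
  if (nrow(series) == 0) stop("empty inventory series")
  o <- order(series$timestamp)
  ts <- series$timestamp[o]
  st <- series$stock[o]
  hour <- as.POSIXct(trunc(ts, "hours"))
  last <- !duplicated(hour, fromLast = TRUE)
  h <- hour[last]
  s <- st[last]
  if (length(s) < 2) {
    return(data.frame(hour = h[0], change = numeric(0)))
  }
  data.frame(hour = h[-1], change = diff(s))
}

#' Daily sales extracted from an inventory trace
#'
#' For each calendar date, sums the absolute values of the negative hourly
#' stock changes attributed to that date; positive changes (restocks) are
#' ignored.
#'
#' @inheritParams hourly_decrements
#' @return data.frame with `date` and `sales` (non-negative).
#' @export
daily_sales <- function(series) {
  hd <- hourly_decrements(series)
  dates <- as.Date(hd$hour, tz = "UTC")
  neg <- pmin(hd$change, 0)
  agg <- tapply(-neg, dates, sum)
  all_days <- as.Date(unique(as.Date(series$timestamp, tz = "UTC")))
  sales <- agg[as.character(all_days)]
  sales[is.na(sales)] <- 0
  data.frame(date = all_days[order(all_days)],
             sales = as.numeric(sales[order(all_days)]),
             row.names = NULL)
}

#' Per-store supply summary: average daily sales and customers served
#'
#' Averages the extracted daily sales over the observed days and converts
#' them to customers via the ration quota (nine adult masks per person per
#' two weeks in the emulated rationing system, so one purchase serves one
#' customer with nine masks).
#'
#' @inheritParams hourly_decrements
#' @param location numeric length-2 planar coordinates of the store, metres.
#' @param quota masks per person per ration period (default 9).
#' @return one-row data.frame: `store_id`, `x`, `y`, `n_days` (calendar days
#'   with at least one observation), `avg_daily_sales`, `avg_daily_customers`.
#' @export
store_supply <- function(series, location = c(NA_real_, NA_real_), quota = 9) {
  if (nrow(series) == 0) stop("empty inventory series")
  stopifnot(quota >= 1)
  ds <- daily_sales(series)
  t_days <- nrow(ds)
  avg <- sum(ds$sales) / t_days
  data.frame(
    store_id = series$store_id[1],
    x = location[1], y = location[2],
    n_days = t_days,
    avg_daily_sales = avg,
    avg_daily_customers = avg / quota,
    stringsAsFactors = FALSE
  )
}

#' Preprocess a multi-store inventory table into store supply
#'
#' Applies [store_supply()] to every store in a long inventory table.
#'
#' @param inventory data.frame with `store_id`, `timestamp`, `stock`.
#' @param stores data.frame with `store_id`, `x`, `y`.
#' @param quota masks per person per ration period.
#' @return data.frame, one row per store, as in [store_supply()].
#' @export
supply_from_inventory <- function(inventory, stores, quota = 9) {
  ids <- unique(inventory$store_id)
  loc <- stores[match(ids, stores$store_id), , drop = FALSE]
  rows <- lapply(seq_along(ids), function(i) {
    ser <- inventory[inventory$store_id == ids[i], , drop = FALSE]
    store_supply(ser, c(loc$x[i], loc$y[i]), quota)
  })
  do.call(rbind, rows)
}

#' Read an inventory CSV (store_id, timestamp ISO-8601, stock)
#' @param path file path.
#' @return data.frame with parsed POSIXct timestamps (UTC).
#' @export
read_inventory_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$timestamp <- as.POSIXct(df$timestamp, tz = "UTC",
                             tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S"))
  df
}

#' Write an inventory table to CSV with ISO-8601 timestamps
#' @param inventory data.frame with `store_id`, `timestamp`, `stock`.
#' @param path file path.
#' @export
write_inventory_csv <- function(inventory, path) {
  inventory$timestamp <- format(inventory$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  utils::write.csv(inventory, path, row.names = FALSE)
}
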