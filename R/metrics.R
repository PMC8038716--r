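# Batch aggregation into the standard six summary statistics and map-form
# output layers.

#' Summarize a simulation batch
#'
#' The six conventional statistics over a batch of runs:
#' (a) residents present; (b) total successful evacuations over all runs;
#' (c) evacuation success rate = ((b)/n_runs)/(a) x 100;
#' (d) total people requiring mutual assistance over all runs;
#' (e) total people receiving mutual assistance over all runs;
#' (f) assistance success rate = (e)/(d) x 100.
#' Rates are presented round-half-up at 2 decimals; exact fractions are
#' also returned. When (d) = 0 the rate (f) is undefined and reported as
#' `NA`, not 0.
#'
#' @param batch a `sim_batch` (or list of `sim_result`)
#' @param n_residents residents present (a); defaults to the value
#'   recorded in the first run
#' @return list of class `batch_summary` with fields `a` .. `f`,
#'   `c_raw`, `f_raw`, `n_runs`, `per_run`
#' @export
summarize_batch <- function(batch, n_residents = NULL) {
  stopifnot(length(batch) >= 1)
  a <- n_residents %||% batch[[1]]$counts$n_present
  per_run <- data.frame(
    run = seq_along(batch),
    evacuated = vapply(batch, function(r) r$counts$n_evacuated, numeric(1)),
    requiring = vapply(batch, function(r) r$counts$n_requiring, numeric(1)),
    receiving = vapply(batch, function(r) r$counts$n_receiving, numeric(1))
  )
  b <- sum(per_run$evacuated)
  d <- sum(per_run$requiring)
  e <- sum(per_run$receiving)
  c_raw <- (b / length(batch)) / a * 100
  f_raw <- if (d > 0) e / d * 100 else NA_real_
  structure(list(
    a = a, b = b,
    c = round_half_up(c_raw, 2),
    d = d, e = e,
    f = if (is.na(f_raw)) NA_real_ else round_half_up(f_raw, 2),
    c_raw = c_raw, f_raw = f_raw,
    n_runs = length(batch), per_run = per_run
  ), class = "batch_summary")
}

#' @export
print.batch_summary <- function(x, ...) {
  cat("<batch_summary> over ", x$n_runs, " runs\n",
      " (a) residents:                   ", x$a, "\n",
      " (b) successful evacuations:      ", x$b, "\n",
      " (c) evacuation success rate:     ", sprintf("%.2f%%", x$c), "\n",
      " (d) requiring mutual assistance: ", x$d, "\n",
      " (e) receiving mutual assistance: ", x$e, "\n",
      " (f) assistance success rate:     ",
      if (is.na(x$f)) "undefined" else sprintf("%.2f%%", x$f), "\n",
      sep = "")
  invisible(x)
}

#' Per-run successful-evacuation table
#'
#' Successful-evacuation counts in run order with their total and the
#' average (total / runs, 1 decimal), the per-run presentation used
#' alongside the batch summary.
#'
#' @param batch a `sim_batch` or a plain numeric vector of per-run counts
#' @return data.frame: one column per run, plus `total` and `average`
#' @export
per_run_table <- function(batch) {
  counts <- if (is.numeric(batch)) {
    batch
  } else {
    vapply(batch, function(r) r$counts$n_evacuated, numeric(1))
  }
  stopifnot(length(counts) >= 1)
  out <- as.data.frame(as.list(stats::setNames(
    counts, paste0("run", seq_along(counts))
  )))
  out$total <- sum(counts)
  out$average <- round_half_up(sum(counts) / length(counts), 1)
  out
}

#' Map-form result layer
#'
#' Per-building counts of residents helped by mutual assistance, victims
#' left unhelped, and members awaiting public support, as a GeoJSON point
#' layer -- the display by which users see where help did and did not reach.
#'
#' @param result a `sim_result`
#' @param town the `town` it was run on
#' @return a `geojson` FeatureCollection (one Point per building)
#' @export
map_output <- function(result, town) {
  ag <- result$agents
  b <- town$buildings
  feats <- lapply(seq_len(nrow(b)), function(i) {
    rows <- ag[ag$building_id == b$id[i], , drop = FALSE]
    geojson_feature(
      "Point", c(b$x[i], b$y[i]),
      list(building_id = b$id[i],
           residents = nrow(rows),
           helped = sum(rows$received_assistance),
           unhelped = sum(rows$was_victim & !rows$received_assistance),
           awaiting_public = sum(rows$outcome == "awaiting_public"),
           evacuated = sum(rows$outcome == "evacuated"))
    )
  })
  structure(list(features = feats), class = "geojson")
}
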