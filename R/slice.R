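#' Construct a multi-ROI slice trace set
#'
#' @param time sample times, seconds, strictly increasing.
#' @param cells named list of per-cell fluorescence traces (>= 2 cells, all
#'   the same length as `time`).
#' @param background background ROI trace, same length.
#' @param meta list with `slice_id`, `animal_id`, `drug_epochs` (named list
#'   of `c(start, end)`).
#' @return an object of class `roi_trace_set`.
#' @export
new_roi_trace_set <- function(time, cells, background, meta = list()) {
  time <- as.numeric(time)
  if (any(diff(time) <= 0)) stop_input("time must be strictly increasing")
  if (!is.list(cells) || length(cells) < 2L)
    stop_input("at least 2 cell traces are required")
  if (is.null(names(cells)) || any(!nzchar(names(cells))))
    stop_input("cell traces must be named")
  lens <- vapply(cells, length, 1L)
  if (any(lens != length(time)) || length(background) != length(time))
    stop_input("all traces must have the same length as time")
  structure(list(time = time, cells = lapply(cells, as.numeric),
                 background = as.numeric(background), meta = meta),
            class = "roi_trace_set")
}

#' @export
print.roi_trace_set <- function(x, ...) {
  cat(sprintf("roi_trace_set: %d cells, %d samples over %.1f s\n",
              length(x$cells), length(x$time), diff(range(x$time))))
  invisible(x)
}

#' Compute dF/F traces from a ROI set
#'
#' Per cell: the background ROI is subtracted, the resting fluorescence F0 is
#' estimated as the 20th percentile of the background-subtracted trace
#' (robust to sparse transients), and dF/F = (F - F0)/F0.
#'
#' @param roi_set a [new_roi_trace_set()].
#' @param f0_quantile quantile used for the F0 estimate (default 0.2).
#' @return class `dff_set`: list with `time` and `dff` (named list of per-cell
#'   dF/F traces); attribute `f0` holds the per-cell estimates.
#' @export
compute_dff <- function(roi_set, f0_quantile = 0.2) {
  stopifnot(inherits(roi_set, "roi_trace_set"))
  f0s <- numeric(length(roi_set$cells))
  dff <- vector("list", length(roi_set$cells))
  names(dff) <- names(roi_set$cells)
  for (i in seq_along(roi_set$cells)) {
    fp <- roi_set$cells[[i]] - roi_set$background
    f0 <- quantile(fp, f0_quantile, names = FALSE)
    if (!is.finite(f0) || f0 <= 0)
      stop_input("degenerate cell '", names(roi_set$cells)[i],
                 "': baseline fluorescence F0 <= 0 after background subtraction")
    f0s[i] <- f0
    dff[[i]] <- (fp - f0) / f0
  }
  structure(list(time = roi_set$time, dff = dff, meta = roi_set$meta),
            class = "dff_set", f0 = setNames(f0s, names(roi_set$cells)))
}

#' Detect calcium events in dF/F traces
#'
#' An event is a maximal run of samples exceeding `mean + 2 SD` of the full
#' trace (mean and SD computed over the whole recording, events included);
#' runs separated by at least one sub-threshold sample are distinct events.
#' The event peak is the maximum within the run.
#'
#' @param dff a `dff_set` from [compute_dff()], or a single numeric dF/F
#'   trace (then `time` is required).
#' @param n_sd threshold in SDs above the trace mean (default 2).
#' @param time sample times when `dff` is a bare numeric trace.
#' @return a `data.frame` (class `event_table`) with columns `cell_id`,
#'   `peak_time`, `peak_dff`, `start`, `end`, sorted by `peak_time`.
#' @export
detect_events <- function(dff, n_sd = 2, time = NULL) {
  if (is.numeric(dff)) {
    if (is.null(time)) stop_input("'time' is required for a bare trace")
    dff <- structure(list(time = time, dff = list(cell = dff)),
                     class = "dff_set")
  }
  stopifnot(inherits(dff, "dff_set"))
  out <- list()
  for (cid in names(dff$dff)) {
    x <- dff$dff[[cid]]
    s <- sd(x)
    if (!is.finite(s) || s == 0) {
      warning("cell '", cid, "': zero-variance trace, no events detected",
              call. = FALSE)
      next
    }
    thr <- mean(x) + n_sd * s
    above <- x > thr
    if (!any(above)) next
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- which(r$values)
    for (k in runs) {
      i0 <- starts[k]; i1 <- ends[k]
      pk <- i0 + which.max(x[i0:i1]) - 1L
      out[[length(out) + 1L]] <- data.frame(
        cell_id = cid, peak_time = dff$time[pk], peak_dff = x[pk],
        start = dff$time[i0], end = dff$time[i1])
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(cell_id = character(0), peak_time = numeric(0),
               peak_dff = numeric(0), start = numeric(0), end = numeric(0))
  res <- res[order(res$peak_time), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("event_table", "data.frame")
  res
}

#' Group calcium events into miniature synchronization events
#'
#' Events from all cells are time-sorted by peak and chained greedily from
#' the earliest unconsumed event: an event joins the current chain while its
#' peak is less than `max_gap` seconds after the previous member's peak.
#' Chains containing events from at least two distinct neurons are emitted as
#' mSEs; every event belongs to at most one chain.
#'
#' @param events an `event_table` from [detect_events()].
#' @param max_gap maximum consecutive peak-to-peak gap, seconds (default 10,
#'   strict `<`).
#' @return a `data.frame` (class `mse_table`) with one row per mSE:
#'   `mse_id`, `n_cells`, `n_events`, `cell_ids` (comma-joined),
#'   `first_peak`, `last_peak`; attribute `membership` maps each event row of
#'   `events` to its mSE id (NA if none).
#' @export
detect_mses <- function(events, max_gap = 10) {
  stopifnot(inherits(events, "data.frame"))
  n <- nrow(events)
  membership <- rep(NA_integer_, n)
  rows <- list()
  if (n) {
    ord <- order(events$peak_time)
    pt <- events$peak_time[ord]
    # chains are maximal runs with consecutive peak gaps < max_gap
    brk <- c(0L, which(diff(pt) >= max_gap), n)
    mse_id <- 0L
    for (b in seq_len(length(brk) - 1L)) {
      idx <- ord[(brk[b] + 1L):brk[b + 1L]]
      cells <- unique(events$cell_id[idx])
      if (length(idx) >= 2L && length(cells) >= 2L) {
        mse_id <- mse_id + 1L
        membership[idx] <- mse_id
        rows[[mse_id]] <- data.frame(
          mse_id = mse_id, n_cells = length(cells), n_events = length(idx),
          cell_ids = paste(sort(cells), collapse = ","),
          first_peak = min(events$peak_time[idx]),
          last_peak = max(events$peak_time[idx]))
      }
    }
  }
  res <- if (length(rows)) do.call(rbind, rows) else
    data.frame(mse_id = integer(0), n_cells = integer(0),
               n_events = integer(0), cell_ids = character(0),
               first_peak = numeric(0), last_peak = numeric(0))
  rownames(res) <- NULL
  attr(res, "membership") <- membership
  class(res) <- c("mse_table", "data.frame")
  res
}

#' Build a baseline/drug/wash epoch plan
#'
#' Measurement windows of `measure` seconds (default 12 min) separated by
#' `gap`-second wash-in/out transitions (default 2 min), aligned so the drug
#' measurement window starts `gap` seconds after drug onset.
#'
#' @param drug_start drug application onset, seconds.
#' @param measure measurement window length, seconds.
#' @param gap transition gap, seconds.
#' @return class `epoch_plan`: data.frame with `label`, `start`, `end`.
#' @export
epoch_plan <- function(drug_start, measure = 720, gap = 120) {
  drug_start <- check_number(drug_start, "drug_start", min = 0)
  baseline_end <- drug_start
  plan <- data.frame(
    label = c("baseline", "drug", "wash"),
    start = c(baseline_end - measure, drug_start + gap,
              drug_start + gap + measure + gap),
    end = c(baseline_end, drug_start + gap + measure,
            drug_start + gap + measure + gap + measure))
  if (plan$start[1] < 0)
    stop_input("drug_start too early for a full baseline window")
  class(plan) <- c("epoch_plan", "data.frame")
  plan
}

#' Per-cell-per-hour event and mSE rates by epoch
#'
#' Rates are normalized as total count / n_cells / epoch hours to control for
#' the number of neurons in the field of view.  mSEs are assigned to the
#' epoch containing their first peak.
#'
#' @param events an `event_table`.
#' @param mses an `mse_table` (optional; `NULL` skips mSE rates).
#' @param plan an [epoch_plan()] (or data.frame with `label`, `start`, `end`).
#' @param n_cells number of neurons recorded.
#' @param time_range recording time range for bounds checking (optional).
#' @return class `rate_summary`: data.frame with `label`, `events_per_cell_h`,
#'   `mses_per_cell_h`, `n_events`, `n_mses`; attribute `participation` holds
#'   per-cell mSE participation counts per hour per epoch.
#' @export
epoch_rates <- function(events, mses, plan, n_cells, time_range = NULL) {
  stopifnot(is.data.frame(plan), all(c("label", "start", "end") %in% names(plan)))
  n_cells <- check_number(n_cells, "n_cells", min = 1)
  if (!is.null(time_range)) {
    if (any(plan$start < time_range[1] - 1e-9) ||
        any(plan$end > time_range[2] + 1e-9))
      stop_input("epoch plan extends outside the recording")
  }
  part <- list()
  rows <- lapply(seq_len(nrow(plan)), function(i) {
    s <- plan$start[i]; e <- plan$end[i]
    hours <- (e - s) / 3600
    ne <- sum(events$peak_time >= s & events$peak_time < e)
    nm <- if (is.null(mses)) NA_integer_ else
      sum(mses$first_peak >= s & mses$first_peak < e)
    if (!is.null(mses) && nrow(mses)) {
      inwin <- mses[mses$first_peak >= s & mses$first_peak < e, , drop = FALSE]
      cells <- unlist(strsplit(inwin$cell_ids, ","))
      part[[plan$label[i]]] <<- table(cells) / hours
    }
    data.frame(label = plan$label[i],
               events_per_cell_h = ne / n_cells / hours,
               mses_per_cell_h = if (is.na(nm)) NA_real_ else
                 nm / n_cells / hours,
               n_events = ne, n_mses = nm)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  attr(res, "participation") <- part
  class(res) <- c("rate_summary", "data.frame")
  res
}

#' @export
print.rate_summary <- function(x, ...) {
  cat("Per-cell-per-hour rates by epoch:\n")
  print.data.frame(as.data.frame(x), digits = 3, row.names = FALSE)
  invisible(x)
}
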