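read_csv_checked <- function(path, required) {
  if (!file.exists(path)) stop_input("file not found: ", path)
  d <- read.csv(path, check.names = FALSE)
  missing <- setdiff(required, names(d))
  if (length(missing))
    stop_input("file ", path, " is missing column(s): ",
               paste(missing, collapse = ", "))
  d
}

check_time_column <- function(time, path) {
  bad <- which(diff(time) <= 0)
  if (length(bad))
    stop_input("non-monotone time in ", path, " at row(s) ",
               paste(head(bad + 1L, 5), collapse = ", "))
  nas <- which(is.na(time))
  if (length(nas))
    stop_input("NA timestamps in ", path, " at row(s) ",
               paste(head(nas, 5), collapse = ", "))
}

#' Read a recording from CSV
#'
#' Uniform typed reader for the package's four trace kinds.  Expected
#' schemas (comma-separated, UTF-8, header mandatory, time in seconds):
#' \describe{
#'   \item{photometry}{`time_s, f465, f405, mask`}
#'   \item{slice}{`time_s, cell_..., background` (wide, one column per ROI)}
#'   \item{vmem}{`time_s, vmem_mV`}
#'   \item{spikes}{`spike_time_s`}
#' }
#'
#' @param path CSV file path.
#' @param kind one of `"photometry"`, `"slice"`, `"vmem"`, `"spikes"`.
#' @param meta optional metadata list attached to the returned object.
#' @return a `dual_channel_trace`, `roi_trace_set`, `vm_trace` or
#'   `spike_train`.
#' @export
read_trace <- function(path, kind = c("photometry", "slice", "vmem", "spikes"),
                       meta = list()) {
  kind <- match.arg(kind)
  switch(kind,
    photometry = {
      d <- read_csv_checked(path, c("time_s", "f465", "f405", "mask"))
      check_time_column(d$time_s, path)
      new_dual_channel_trace(d$time_s, d$f465, d$f405, d$mask, meta = meta)
    },
    slice = {
      d <- read_csv_checked(path, c("time_s", "background"))
      check_time_column(d$time_s, path)
      cell_cols <- grep("^cell", names(d), value = TRUE)
      if (length(cell_cols) < 2)
        stop_input("slice file needs >= 2 cell_* columns: ", path)
      new_roi_trace_set(d$time_s, as.list(d[cell_cols]), d$background,
                        meta = meta)
    },
    vmem = {
      d <- read_csv_checked(path, c("time_s", "vmem_mV"))
      check_time_column(d$time_s, path)
      new_vm_trace(d$time_s, d$vmem_mV,
                   drug_windows = meta$drug_windows %||% list(), meta = meta)
    },
    spikes = {
      d <- read_csv_checked(path, "spike_time_s")
      st <- sort(d$spike_time_s)
      structure(list(spike_times = st,
                     application_windows = meta$application_windows %||% list(),
                     duration = meta$duration %||%
                       (if (length(st)) max(st) else 0)),
                class = "spike_train")
    })
}

#' Write a recording to CSV
#'
#' Inverse of [read_trace()]: writes the schema that `read_trace` expects for
#' the object's kind.
#'
#' @param x a `dual_channel_trace`, `roi_trace_set`, `vm_trace` or
#'   `spike_train`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(x, path) {
  d <- if (inherits(x, "dual_channel_trace")) {
    data.frame(time_s = x$time, f465 = x$f465, f405 = x$f405, mask = x$mask)
  } else if (inherits(x, "roi_trace_set")) {
    cbind(data.frame(time_s = x$time), as.data.frame(x$cells),
          data.frame(background = x$background))
  } else if (inherits(x, "vm_trace")) {
    data.frame(time_s = x$time, vmem_mV = x$vmem)
  } else if (inherits(x, "spike_train")) {
    data.frame(spike_time_s = x$spike_times)
  } else stop_input("unsupported object for write_trace")
  write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Write ground truth as a JSON sidecar
#'
#' @param truth a `ground_truth` object from any simulator.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Write an SE table to CSV
#'
#' Columns: `peak_time_s`, `onset_time_s`, `amplitude_z`, `fwhm_s`.
#'
#' @param ses an `se_set`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_se_table <- function(ses, path) {
  write.csv(data.frame(peak_time_s = ses$peak_time,
                       onset_time_s = ses$onset_time,
                       amplitude_z = ses$amplitude,
                       fwhm_s = ses$fwhm),
            path, row.names = FALSE)
  invisible(path)
}
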