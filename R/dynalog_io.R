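#' Delivery log for one leaf bank
#'
#' One per-bank log of a dynamic delivery, sampled every 55 ms by the MLC
#' controller. Each snapshot carries the elapsed time, the dose index (the
#' cumulative fractional MU scaled to an integer 0..25000), the current
#' segment number (the control-point interval being delivered), a beam-on
#' flag (FALSE during a beam hold), and the planned and recorded tip
#' positions of all leaves in the bank, in mm at isocenter, signed on the
#' leaf-travel axis.
#'
#' @param field_id character field identifier.
#' @param bank `"A"` or `"B"`.
#' @param time_ms integer vector of snapshot times, strictly increasing in
#'   55 ms steps.
#' @param dose_index integer vector 0..25000, non-decreasing.
#' @param segment integer vector of segment numbers (1-based control-point
#'   interval), non-decreasing.
#' @param beam_on logical vector.
#' @param planned,recorded numeric matrices (`n_snapshots` x `n_pairs`), mm.
#' @param boundaries planned segment-boundary meterset fractions (the plan's
#'   control-point indices), length `max(segment) + 1`, from 0 to 1.
#' @param total_mu total MU of the delivered field.
#' @param gantry_angle gantry angle, degrees.
#' @param hold_tolerance_mm controller hold tolerance recorded in the header.
#' @param geometry a [leaf_bank_geometry()].
#' @return object of class `delivery_log`.
#' @export
delivery_log <- function(field_id, bank, time_ms, dose_index, segment, beam_on,
                         planned, recorded, boundaries, total_mu,
                         gantry_angle = 0, hold_tolerance_mm = 2,
                         geometry = leaf_bank_geometry()) {
  log <- structure(
    list(field_id = as.character(field_id), bank = match.arg(bank, c("A", "B")),
         time_ms = as.integer(time_ms), dose_index = as.integer(dose_index),
         segment = as.integer(segment), beam_on = as.logical(beam_on),
         planned = as.matrix(planned), recorded = as.matrix(recorded),
         boundaries = as.numeric(boundaries), total_mu = as.numeric(total_mu),
         gantry_angle = as.numeric(gantry_angle),
         hold_tolerance_mm = as.numeric(hold_tolerance_mm),
         geometry = geometry),
    class = "delivery_log"
  )
  validate_delivery_log(log)
  log
}

validate_delivery_log <- function(log) {
  n <- length(log$time_ms)
  if (n < 1L) stop("delivery log has no snapshots", call. = FALSE)
  if (n > 1L && any(diff(log$time_ms) != 55L)) {
    stop("snapshot times must increase in 55 ms steps", call. = FALSE)
  }
  if (any(diff(log$dose_index) < 0L)) {
    k <- which(diff(log$dose_index) < 0L)[1] + 1L
    stop(sprintf("corrupt log: dose index decreases at snapshot %d", k),
         call. = FALSE)
  }
  if (any(log$dose_index < 0L | log$dose_index > 25000L)) {
    stop("corrupt log: dose index outside 0..25000", call. = FALSE)
  }
  np <- log$geometry$n_pairs
  if (!all(dim(log$planned) == c(n, np)) || !all(dim(log$recorded) == c(n, np))) {
    stop("position matrices must be n_snapshots x n_pairs", call. = FALSE)
  }
  if (any(!is.finite(log$planned)) || any(!is.finite(log$recorded))) {
    stop("corrupt log: non-finite positions", call. = FALSE)
  }
  nb <- length(log$boundaries)
  if (nb < 2L || abs(log$boundaries[1]) > 1e-9 || abs(log$boundaries[nb] - 1) > 1e-9 ||
      any(diff(log$boundaries) < 0)) {
    stop("segment boundaries must run non-decreasing from 0 to 1", call. = FALSE)
  }
  if (max(log$segment) > nb - 1L || min(log$segment) < 1L) {
    stop("segment numbers inconsistent with boundary list", call. = FALSE)
  }
  invisible(log)
}

#' @export
print.delivery_log <- function(x, ...) {
  cat(sprintf("<delivery_log> field '%s' bank %s: %d snapshots (%.2f s), final dose index %d\n",
              x$field_id, x$bank, length(x$time_ms),
              max(x$time_ms) / 1000, x$dose_index[length(x$dose_index)]))
  invisible(x)
}

#' Paired bank-A/bank-B delivery record
#'
#' Binds the two per-bank logs of one field. The dose-index and segment
#' streams must be identical across banks (they are written by the same
#' controller clock); otherwise the inputs are mismatched.
#'
#' @param bank_a_log,bank_b_log `delivery_log` objects for banks A and B.
#' @return object of class `delivery_record`.
#' @export
delivery_record <- function(bank_a_log, bank_b_log) {
  if (bank_a_log$bank != "A" || bank_b_log$bank != "B") {
    stop("mismatched inputs: expected bank A then bank B logs", call. = FALSE)
  }
  if (bank_a_log$field_id != bank_b_log$field_id) {
    stop("mismatched inputs: logs belong to different fields ('",
         bank_a_log$field_id, "' vs '", bank_b_log$field_id, "')", call. = FALSE)
  }
  if (length(bank_a_log$time_ms) != length(bank_b_log$time_ms)) {
    stop("mismatched inputs: unequal snapshot count between banks", call. = FALSE)
  }
  if (!identical(bank_a_log$dose_index, bank_b_log$dose_index) ||
      !identical(bank_a_log$segment, bank_b_log$segment)) {
    stop("mismatched inputs: dose-index/segment streams differ between banks",
         call. = FALSE)
  }
  structure(list(bank_a_log = bank_a_log, bank_b_log = bank_b_log),
            class = "delivery_record")
}

#' @export
print.delivery_record <- function(x, ...) {
  a <- x$bank_a_log
  cat(sprintf("<delivery_record> field '%s': %d snapshots, %d segments, final fractional MU %.4f\n",
              a$field_id, length(a$time_ms), length(a$boundaries) - 1L,
              a$dose_index[length(a$dose_index)] / 25000))
  invisible(x)
}

#' Fractional MU stream of a delivery record
#'
#' The dose index is the cumulative fractional MU scaled by 25000; this
#' returns `dose_index / 25000` per snapshot, non-decreasing in `[0, 1]` and
#' ending at 1 for a completed delivery.
#'
#' @param record a [delivery_record()].
#' @return numeric vector, one value per snapshot.
#' @export
fractional_mu <- function(record) {
  record$bank_a_log$dose_index / 25000
}

log_header_fmt <- c(version = "Version", field = "Field ID", bank = "Bank",
                    mu = "Total MU", gantry = "Gantry",
                    tol = "Hold Tolerance mm", snaps = "Snapshots",
                    bounds = "Segment Boundaries")

#' Write a paired delivery record to two per-bank log files
#'
#' Serialises to the package's delivery-log dialect: a `key = value` header
#' (version, field id, bank, total MU, gantry, hold tolerance, snapshot
#' count, planned segment-boundary meterset fractions), then one CSV row per
#' 55 ms snapshot: `time_ms, dose_index, segment, beam_on`, the planned
#' positions (integer 0.01 mm units) and the recorded positions (quantized to
#' 0.01 cm, the finite recording precision of the controller, stored in the
#' same 0.01 mm units).
#'
#' @param record a valid [delivery_record()].
#' @param dir output directory (created if missing).
#' @return character vector of the two file paths (A then B), invisibly.
#' @export
write_dynalog_pair <- function(record, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(2)
  for (i in 1:2) {
    log <- if (i == 1) record$bank_a_log else record$bank_b_log
    validate_delivery_log(log)
    path <- file.path(dir, sprintf("%s_%s.dlg", log$field_id, log$bank))
    con <- file(path, "w")
    writeLines(c(
      "Version = 1",
      sprintf("Field ID = %s", log$field_id),
      sprintf("Bank = %s", log$bank),
      sprintf("Total MU = %s", format(log$total_mu)),
      sprintf("Gantry = %s", format(log$gantry_angle)),
      sprintf("Hold Tolerance mm = %s", format(log$hold_tolerance_mm)),
      sprintf("Snapshots = %d", length(log$time_ms)),
      sprintf("Segment Boundaries = %s",
              paste(sprintf("%.5f", log$boundaries), collapse = " "))
    ), con)
    planned_units <- round(log$planned * 100)           # 0.01 mm units
    recorded_units <- round(log$recorded / 0.1) * 10    # quantized to 0.01 cm
    rows <- cbind(log$time_ms, log$dose_index, log$segment,
                  as.integer(log$beam_on), planned_units, recorded_units)
    writeLines(apply(rows, 1, paste, collapse = ","), con)
    close(con)
    paths[i] <- path
  }
  invisible(paths)
}

read_one_dynalog <- function(path, geometry) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  hdr <- list()
  i <- 1L
  while (i <= length(lines) && grepl("=", lines[i], fixed = TRUE)) {
    kv <- regmatches(lines[i], regexec("^\\s*([^=]*?)\\s*=\\s*(.*?)\\s*$", lines[i]))[[1]]
    hdr[[kv[2]]] <- kv[3]
    i <- i + 1L
  }
  need <- unname(log_header_fmt)
  miss <- setdiff(need, names(hdr))
  if (length(miss)) {
    stop("corrupt log ", path, ": missing header key(s) ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  n <- as.integer(hdr[["Snapshots"]])
  body <- lines[i:length(lines)]
  body <- body[nzchar(body)]
  if (length(body) != n) {
    stop(sprintf("corrupt log %s: header announces %d snapshots, found %d rows",
                 path, n, length(body)), call. = FALSE)
  }
  np <- geometry$n_pairs
  m <- matrix(as.numeric(unlist(strsplit(body, ",", fixed = TRUE))),
              nrow = n, byrow = TRUE)
  if (ncol(m) != 4 + 2 * np) {
    stop(sprintf("corrupt log %s: expected %d columns per row, found %d",
                 path, 4 + 2 * np, ncol(m)), call. = FALSE)
  }
  delivery_log(
    field_id = hdr[["Field ID"]], bank = hdr[["Bank"]],
    time_ms = m[, 1], dose_index = m[, 2], segment = m[, 3],
    beam_on = m[, 4] != 0,
    planned = m[, 4 + seq_len(np), drop = FALSE] / 100,
    recorded = m[, 4 + np + seq_len(np), drop = FALSE] / 100,
    boundaries = as.numeric(strsplit(hdr[["Segment Boundaries"]], "\\s+")[[1]]),
    total_mu = as.numeric(hdr[["Total MU"]]),
    gantry_angle = as.numeric(hdr[["Gantry"]]),
    hold_tolerance_mm = as.numeric(hdr[["Hold Tolerance mm"]]),
    geometry = geometry
  )
}

#' Read a paired set of per-bank delivery log files
#'
#' Parses both per-bank files (dialect documented at [write_dynalog_pair()])
#' and pairs them, distinguishing corrupt files (bad header, decreasing dose
#' index, malformed rows) from mismatched pairs (different fields, unequal
#' snapshot counts, diverging dose-index/segment streams).
#'
#' @param path_a,path_b paths to the bank-A and bank-B files.
#' @param geometry a [leaf_bank_geometry()].
#' @return a [delivery_record()], positions in mm at isocenter.
#' @export
read_dynalog_pair <- function(path_a, path_b, geometry = leaf_bank_geometry()) {
  delivery_record(read_one_dynalog(path_a, geometry),
                  read_one_dynalog(path_b, geometry))
}
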