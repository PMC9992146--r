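#' MRF acquisition schedules
#'
#' An acquisition schedule is an ordered table of saturation/readout events
#' (class `mrf_schedule`): one row per raw encoding image, in acquisition
#' order (order matters because spin history is carried across entries).
#'
#' @param entries data.frame with columns `sat_power` (microtesla),
#'   `sat_offset` (ppm), `n_pulses`, `pulse_duration` (s),
#'   `interpulse_delay` (s), `recovery_delay` (s), `flip_angle` (degrees),
#'   `echo_time` (s, informational)
#' @param label free-text provenance label
#' @return an `mrf_schedule`
#' @export
mrf_schedule <- function(entries, label = "") {
  req <- schedule_columns()
  missing <- setdiff(req, names(entries))
  if (length(missing))
    stopf("schedule is missing column(s): %s", paste(missing, collapse = ", "))
  entries <- as.data.frame(entries)[, req]
  if (nrow(entries) < 1) stopf("a schedule needs at least one entry")
  for (cc in req) {
    if (!is.numeric(entries[[cc]]) || any(!is.finite(entries[[cc]])))
      stopf("schedule column '%s' must be finite numeric", cc)
  }
  if (any(entries$sat_power < 0)) stopf("negative saturation power")
  dur <- c("pulse_duration", "interpulse_delay", "recovery_delay", "echo_time")
  if (any(as.matrix(entries[, dur]) < 0)) stopf("negative duration")
  if (any(entries$n_pulses < 1)) stopf("n_pulses must be >= 1")
  structure(entries, label = label, class = c("mrf_schedule", "data.frame"))
}

schedule_columns <- function() {
  c("sat_power", "sat_offset", "n_pulses", "pulse_duration",
    "interpulse_delay", "recovery_delay", "flip_angle", "echo_time")
}

as_mrf_schedule <- function(x) {
  if (inherits(x, "mrf_schedule")) x else mrf_schedule(x)
}

#' @export
as.data.frame.mrf_schedule <- function(x, ...) {
  attr(x, "label") <- NULL
  class(x) <- "data.frame"
  x
}

#' Number of entries of a schedule
#' @param schedule an `mrf_schedule`
#' @return integer M
#' @export
schedule_length <- function(schedule) nrow(schedule)

#' @export
print.mrf_schedule <- function(x, ...) {
  cat(sprintf("MRF acquisition schedule: M = %d entries%s\n", nrow(x),
              if (nzchar(attr(x, "label"))) paste0(" [", attr(x, "label"), "]")
              else ""))
  cat(sprintf("  power %.3g-%.3g uT, offsets %.3g-%.3g ppm, flip %.3g deg\n",
              min(x$sat_power), max(x$sat_power), min(x$sat_offset),
              max(x$sat_offset), x$flip_angle[1]))
  invisible(x)
}

#' Generate a pseudo-random MRF schedule
#'
#' Draws per-entry saturation powers uniformly on [0, 4] microtesla from a
#' seeded Mersenne-Twister generator. Offsets are fixed at 3 ppm for
#' L-arginine CEST imaging (`cest_3ppm`) or drawn uniformly on [6, 14] ppm
#' for semisolid-MT imaging (`mt_sweep`). Each entry uses the 13 x 100 ms
#' 50%-duty-cycle spin-lock saturation train, a 15 degree flip and an
#' 11 ms echo time.
#'
#' @param m number of entries (M >= 1)
#' @param mode `"cest_3ppm"` or `"mt_sweep"`
#' @param seed integer seed; the same seed reproduces the schedule exactly
#' @param recovery_delay recovery delay after each readout, seconds
#' @return an `mrf_schedule` of M entries
#' @examples
#' sched <- generate_pseudorandom_schedule(30, "cest_3ppm", seed = 7)
#' truncate_schedule(sched, 9)   # keep the first 9 encoding images
#' @export
generate_pseudorandom_schedule <- function(m, mode = c("cest_3ppm", "mt_sweep"),
                                           seed = 1, recovery_delay = 2.5) {
  if (m < 1) stopf("m must be >= 1")
  mode <- match.arg(mode)
  with_seed(seed, {
    power <- runif(m, 0, 4)
    offset <- if (mode == "cest_3ppm") rep(3, m) else runif(m, 6, 14)
    mrf_schedule(data.frame(
      sat_power = power, sat_offset = offset, n_pulses = 13,
      pulse_duration = 0.1, interpulse_delay = 0.1,
      recovery_delay = recovery_delay, flip_angle = 15, echo_time = 0.011),
      label = sprintf("%s_m%d_seed%d", mode, m, as.integer(seed)))
  })
}

#' Truncate a schedule to its first N entries
#'
#' Only images at the end of the acquisition can be dropped - never the
#' beginning - because the spin history accumulated by earlier entries
#' shapes every later signal. Truncation therefore returns the first `n`
#' entries in order.
#'
#' @param schedule an `mrf_schedule` of length M
#' @param n number of entries to keep (1 <= n <= M)
#' @return the truncated `mrf_schedule`
#' @export
truncate_schedule <- function(schedule, n) {
  schedule <- as_mrf_schedule(schedule)
  m <- nrow(schedule)
  if (n < 1 || n > m) stopf("n must be in [1, M = %d]", m)
  out <- schedule[seq_len(n), , drop = FALSE]
  mrf_schedule(out, label = sprintf("%s_trunc%d", attr(schedule, "label"), n))
}

#' Read / write schedules as TSV
#'
#' Plain tab-separated files with a header row naming the schedule columns,
#' one row per entry. Values are serialized with 17 significant digits so a
#' write-read round trip reproduces the schedule exactly.
#'
#' @param schedule an `mrf_schedule`
#' @param path file path
#' @return `read_schedule` returns an `mrf_schedule`; `write_schedule`
#'   returns `path` invisibly
#' @export
write_schedule <- function(schedule, path) {
  schedule <- as_mrf_schedule(schedule)
  df <- as.data.frame(lapply(schedule, function(x) sprintf("%.17g", x)))
  names(df) <- names(schedule)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path) {
  if (!file.exists(path)) stopf("no such schedule file: %s", path)
  df <- tryCatch(read.delim(path, sep = "\t", stringsAsFactors = FALSE),
                 error = function(e) stopf("cannot parse %s: %s", path,
                                           conditionMessage(e)))
  if (nrow(df) == 0) stopf("schedule file %s has a header but no entries", path)
  missing <- setdiff(schedule_columns(), names(df))
  if (length(missing))
    stopf("%s: missing column(s) %s", path, paste(missing, collapse = ", "))
  for (cc in schedule_columns()) {
    v <- suppressWarnings(as.numeric(df[[cc]]))
    if (any(is.na(v))) {
      stopf("%s: non-numeric value in column '%s' (row %d)", path, cc,
            which(is.na(v))[1])
    }
    df[[cc]] <- v
  }
  mrf_schedule(df, label = sub("\\.[^.]*$", "", basename(path)))
}
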