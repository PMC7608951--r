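#' Embryonic cell-cycle schedule
#'
#' Builds the per-cycle timing table that drives the transcriptional-window
#' model. Each cycle contributes an interphase and a mitosis duration; two
#' global parameters describe transcription itself: the post-mitotic lag
#' before initiation resumes and the elongation time per kilobase of primary
#' transcription unit (TU). One cycle, the terminal cycle, is treated as an
#' unbounded interphase: the embryo stops dividing, so transcripts of any
#' length can be completed.
#'
#' Pre-MBT embryonic cycles are simple alternations of S phase and mitosis
#' (no gap phases), so interphase duration here is the S-phase duration.
#'
#' @param cycles integer vector of cycle indices (strictly increasing,
#'   unique), e.g. `8:14`.
#' @param interphase_min numeric vector of interphase durations in minutes
#'   (> 0), one per cycle. For the default schedule these are non-decreasing:
#'   pre-MBT cycles slow incrementally.
#' @param mitosis_min mitosis duration in minutes (>= 0); recycled across
#'   cycles. Default 5.
#' @param lag_min delay in minutes between exit from mitosis and productive
#'   transcription initiation. Default 4.
#' @param elongation_min_per_kb elongation time in minutes per kb of primary
#'   TU; sets the eclipse time. Default 0.7.
#' @param terminal_cycle cycle index whose interphase is treated as
#'   unbounded. Default 14.
#' @return an object of class `cycle_schedule`.
#' @seealso [default_cycle_schedule()], [transcription_window()],
#'   [expression_efficiency()]
#' @export
cycle_schedule <- function(cycles, interphase_min, mitosis_min = 5,
                           lag_min = 4, elongation_min_per_kb = 0.7,
                           terminal_cycle = 14L) {
  cycles <- as.integer(cycles)
  if (length(cycles) == 0L) stop("schedule must contain at least one cycle")
  if (anyNA(cycles)) stop("cycle indices must be integers")
  if (any(diff(cycles) <= 0L)) {
    stop("cycle indices must be strictly increasing and unique")
  }
  interphase_min <- as.numeric(interphase_min)
  if (length(interphase_min) != length(cycles)) {
    stop("need one interphase duration per cycle")
  }
  if (anyNA(interphase_min) || any(!is.finite(interphase_min)) ||
      any(interphase_min <= 0)) {
    stop("interphase durations must be finite and > 0 minutes")
  }
  mitosis_min <- rep_len(as.numeric(mitosis_min), length(cycles))
  if (anyNA(mitosis_min) || any(mitosis_min < 0)) {
    stop("mitosis durations must be >= 0 minutes")
  }
  if (!is.numeric(lag_min) || length(lag_min) != 1L || lag_min < 0) {
    stop("lag_min must be a single number >= 0")
  }
  if (!is.numeric(elongation_min_per_kb) || length(elongation_min_per_kb) != 1L ||
      elongation_min_per_kb <= 0) {
    stop("elongation_min_per_kb must be a single number > 0")
  }
  structure(
    list(
      table = data.frame(cycle = cycles,
                         interphase_min = interphase_min,
                         mitosis_min = mitosis_min),
      lag_min = as.numeric(lag_min),
      elongation_min_per_kb = as.numeric(elongation_min_per_kb),
      terminal_cycle = as.integer(terminal_cycle)
    ),
    class = "cycle_schedule"
  )
}

#' Default pre-MBT cycle schedule
#'
#' Interphase (= S-phase) durations for cycles 8-14 reconstructed from the
#' printed anchors: a cycle-8 transcriptional window of about 12 s (so
#' interphase 4.2 min with the 4-min lag), S phase of 7 min at cycle 10 and
#' 15 min at cycle 13, mitosis about 5 min. Cycles 9, 11 and 12 are
#' monotone interpolations between those anchors; cycle 14 is the terminal
#' cycle (interphase effectively unbounded — its tabulated value is nominal).
#' The same table ships as a TSV in `inst/extdata/default_schedule.tsv` and
#' can be overridden via [read_cycle_schedule()].
#'
#' @return a `cycle_schedule` object covering cycles 8-14.
#' @export
default_cycle_schedule <- function() {
  cycle_schedule(
    cycles = 8:14,
    interphase_min = c(4.2, 5.5, 7, 9.5, 12, 15, 70),
    mitosis_min = 5,
    lag_min = 4,
    elongation_min_per_kb = 0.7,
    terminal_cycle = 14L
  )
}

#' Read / write a cycle schedule as TSV
#'
#' The file has columns `cycle`, `interphase_min`, `mitosis_min`; lines
#' starting with `#` are comments. Global parameters are arguments rather
#' than file content so that a schedule file is a pure timing table.
#'
#' @param path path to a tab-separated schedule file.
#' @inheritParams cycle_schedule
#' @return `read_cycle_schedule`: a `cycle_schedule`.
#' @export
read_cycle_schedule <- function(path, lag_min = 4, elongation_min_per_kb = 0.7,
                                terminal_cycle = 14L) {
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("cycle", "interphase_min", "mitosis_min")
  if (!all(need %in% names(tab))) {
    stop("schedule file must have columns: ", paste(need, collapse = ", "))
  }
  cycle_schedule(tab$cycle, tab$interphase_min, tab$mitosis_min,
                 lag_min = lag_min,
                 elongation_min_per_kb = elongation_min_per_kb,
                 terminal_cycle = terminal_cycle)
}

#' @rdname read_cycle_schedule
#' @param schedule a `cycle_schedule`.
#' @return `write_cycle_schedule`: the path, invisibly.
#' @export
write_cycle_schedule <- function(schedule, path) {
  stopifnot(inherits(schedule, "cycle_schedule"))
  utils::write.table(schedule$table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @export
print.cycle_schedule <- function(x, ...) {
  cat("Embryonic cell-cycle schedule (", nrow(x$table), " cycles)\n", sep = "")
  cat("  lag: ", x$lag_min, " min; elongation: ", x$elongation_min_per_kb,
      " min/kb; terminal cycle: ", x$terminal_cycle, "\n", sep = "")
  print(x$table, row.names = FALSE)
  invisible(x)
}

# internal: row lookup with a clear error for unknown cycles
.schedule_row <- function(schedule, cycle_index) {
  stopifnot(inherits(schedule, "cycle_schedule"))
  idx <- match(as.integer(cycle_index), schedule$table$cycle)
  if (anyNA(idx)) {
    stop("cycle ", paste(cycle_index[is.na(idx)], collapse = ", "),
         " not present in schedule")
  }
  idx
}
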