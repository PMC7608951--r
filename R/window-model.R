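#' Eclipse time of a primary transcription unit
#'
#' The eclipse time is the delay between initiation of transcription and the
#' first complete transcript: the time a polymerase needs to traverse the
#' whole primary TU. It is linear in TU length, `tu_length_kb *
#' elongation_min_per_kb` (0.7 min/kb by default).
#'
#' @param tu_length_kb TU length(s) in kilobases (>= 0); vectorized.
#' @param schedule a [cycle_schedule()]; only its elongation rate is used.
#' @return eclipse time(s) in minutes.
#' @export
eclipse_time <- function(tu_length_kb, schedule = default_cycle_schedule()) {
  stopifnot(inherits(schedule, "cycle_schedule"))
  tu_length_kb <- as.numeric(tu_length_kb)
  if (anyNA(tu_length_kb) || any(!is.finite(tu_length_kb))) {
    stop("TU lengths must be finite")
  }
  if (any(tu_length_kb < 0)) stop("TU length must be >= 0 kb")
  tu_length_kb * schedule$elongation_min_per_kb
}

#' Transcriptional window of a cycle
#'
#' Interphase duration minus the post-mitotic lag: the time available to
#' elongate transcripts before the next mitosis aborts all incomplete ones.
#' Clamped at zero when the lag exceeds interphase. For the terminal cycle
#' the tabulated (nominal) interphase is used; see
#' [earliest_expressible_cycle()] for where the terminal cycle is instead
#' treated as unbounded.
#'
#' @param cycle_index cycle index (vectorized); must be present in the
#'   schedule.
#' @param schedule a [cycle_schedule()].
#' @return window duration(s) in minutes, >= 0.
#' @export
transcription_window <- function(cycle_index,
                                 schedule = default_cycle_schedule()) {
  idx <- .schedule_row(schedule, cycle_index)
  pmax(0, schedule$table$interphase_min[idx] - schedule$lag_min)
}

#' Productive window for a TU in a cycle
#'
#' Transcriptional window minus eclipse time: the span during which
#' initiations still complete before mitosis. Monotone non-increasing in TU
#' length and non-decreasing in interphase duration; clamped at zero.
#'
#' @inheritParams transcription_window
#' @inheritParams eclipse_time
#' @return productive window(s) in minutes, >= 0.
#' @export
productive_window <- function(cycle_index, tu_length_kb,
                              schedule = default_cycle_schedule()) {
  pmax(0, transcription_window(cycle_index, schedule) -
         eclipse_time(tu_length_kb, schedule))
}

#' Time-averaged expression efficiency
#'
#' The fraction of total cell-cycle time (interphase + mitosis) during which
#' complete transcripts of a TU can be produced, as a percentage:
#' `100 * productive_window / (interphase + mitosis)`. The terminal cycle is
#' set to 100% regardless of length (cell cycling has stopped, so any TU can
#' eventually be completed); pass `terminal_override = FALSE` to instead
#' apply the finite-cycle formula to the tabulated terminal interphase, e.g.
#' for sensitivity analyses.
#'
#' @inheritParams productive_window
#' @param terminal_override logical; return exactly 100 for the terminal
#'   cycle (default TRUE).
#' @return percentage(s) in [0, 100].
#' @export
expression_efficiency <- function(cycle_index, tu_length_kb,
                                  schedule = default_cycle_schedule(),
                                  terminal_override = TRUE) {
  idx <- .schedule_row(schedule, cycle_index)
  tot <- schedule$table$interphase_min[idx] + schedule$table$mitosis_min[idx]
  eff <- 100 * productive_window(cycle_index, tu_length_kb, schedule) / tot
  if (terminal_override) {
    eff[schedule$table$cycle[idx] == schedule$terminal_cycle] <- 100
  }
  pmin(100, pmax(0, eff))
}

#' First cycle compatible with productive expression
#'
#' Smallest cycle index whose productive window for the TU is positive. Each
#' successive (longer) cycle is compatible with longer primary transcripts,
#' so the result is monotone non-decreasing in TU length. The terminal cycle
#' counts as always compatible (unbounded interphase) unless
#' `include_terminal = FALSE`, in which case `NA` is returned when no
#' pre-terminal cycle qualifies.
#'
#' @inheritParams eclipse_time
#' @param include_terminal logical; treat the terminal cycle as always
#'   expressible (default TRUE).
#' @return a cycle index, or `NA_integer_`.
#' @export
earliest_expressible_cycle <- function(tu_length_kb,
                                       schedule = default_cycle_schedule(),
                                       include_terminal = TRUE) {
  stopifnot(length(tu_length_kb) == 1L)
  tab <- schedule$table
  pre <- tab$cycle[tab$cycle != schedule$terminal_cycle]
  if (length(pre)) {
    pw <- productive_window(pre, tu_length_kb, schedule)
    hit <- pre[pw > 0]
    if (length(hit)) return(hit[1L])
  }
  if (include_terminal && schedule$terminal_cycle %in% tab$cycle) {
    return(schedule$terminal_cycle)
  }
  NA_integer_
}

#' Expression-efficiency table over cycles and TU lengths
#'
#' Evaluates [expression_efficiency()] for every (cycle, length) pair,
#' giving the familiar staircase in which longer TUs have a later and more
#' abrupt onset of productive expression.
#'
#' @param lengths_kb numeric vector of TU lengths in kb (non-empty).
#' @param schedule a [cycle_schedule()].
#' @param terminal_override see [expression_efficiency()].
#' @return an `efficiency_table`: a cycles x lengths numeric matrix of
#'   percentages, with dimnames `cycle` and `tu_kb`.
#' @export
efficiency_table <- function(lengths_kb, schedule = default_cycle_schedule(),
                             terminal_override = TRUE) {
  lengths_kb <- as.numeric(lengths_kb)
  if (length(lengths_kb) == 0L) stop("need at least one TU length")
  cyc <- schedule$table$cycle
  m <- vapply(lengths_kb, function(L) {
    expression_efficiency(cyc, L, schedule, terminal_override)
  }, numeric(length(cyc)))
  m <- matrix(m, nrow = length(cyc),
              dimnames = list(cycle = cyc, tu_kb = lengths_kb))
  structure(m, class = c("efficiency_table", "matrix"))
}

#' @export
print.efficiency_table <- function(x, digits = 1, ...) {
  cat("Time-averaged expression efficiency (%) by cycle and TU length (kb)\n")
  print(round(unclass(x), digits), ...)
  invisible(x)
}

#' Plot an efficiency table
#'
#' One line per TU length across cycles, base graphics.
#'
#' @param x an `efficiency_table`.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.efficiency_table <- function(x, ...) {
  cyc <- as.numeric(rownames(x))
  graphics::matplot(cyc, unclass(x), type = "b", pch = 19, lty = 1,
                    xlab = "cell cycle", ylab = "expression efficiency (%)",
                    ylim = c(0, 100), ...)
  graphics::legend("topleft", legend = paste0(colnames(x), " kb"),
                   col = seq_len(ncol(x)), lty = 1, pch = 19, bty = "n")
  invisible(x)
}
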