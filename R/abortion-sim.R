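#' Simulation parameters for the initiation/abortion simulator
#'
#' @param initiation_rate productive initiations per minute per nucleus
#'   (>= 0).
#' @param n_nuclei_by_cycle either a single positive count used for every
#'   cycle, or a named numeric vector mapping cycle index to nucleus count
#'   (nuclei double each syncytial cycle in a normal embryo).
#' @param seed integer root seed; per-cycle RNG substreams are derived from
#'   it so results do not depend on the order cycles are simulated in.
#' @return an object of class `sim_params`.
#' @export
sim_params <- function(initiation_rate, n_nuclei_by_cycle = 1, seed = 1L) {
  if (!is.numeric(initiation_rate) || length(initiation_rate) != 1L ||
      !is.finite(initiation_rate) || initiation_rate < 0) {
    stop("initiation_rate must be a single finite number >= 0")
  }
  if (any(n_nuclei_by_cycle < 1)) stop("nucleus counts must be >= 1")
  structure(list(initiation_rate = initiation_rate,
                 n_nuclei_by_cycle = n_nuclei_by_cycle,
                 seed = as.integer(seed)),
            class = "sim_params")
}

# internal: nuclei for a given cycle
.n_nuclei <- function(params, cycle_index) {
  n <- params$n_nuclei_by_cycle
  if (is.null(names(n))) {
    if (length(n) != 1L) stop("unnamed n_nuclei_by_cycle must be scalar")
    return(rep(as.numeric(n), length(cycle_index)))
  }
  out <- n[as.character(cycle_index)]
  if (anyNA(out)) {
    stop("no nucleus count for cycle ",
         paste(cycle_index[is.na(out)], collapse = ", "))
  }
  as.numeric(out)
}

#' Expected completed transcripts per cycle
#'
#' Closed-form expectation of the abortion simulator: initiations occur at a
#' constant rate per nucleus during the transcriptional window, and an
#' initiation at time t completes iff the polymerase reaches the TU end
#' (t + eclipse time) before interphase ends — all later initiations are
#' aborted at mitosis. Hence the expectation is
#' `rate * nuclei(cycle) * productive_window(cycle, length)`.
#'
#' @param cycle_index cycle index (vectorized).
#' @param tu_length_kb TU length in kb.
#' @param params a [sim_params()].
#' @param schedule a [cycle_schedule()].
#' @return expected number(s) of completed transcripts.
#' @export
expected_completed <- function(cycle_index, tu_length_kb, params,
                               schedule = default_cycle_schedule()) {
  stopifnot(inherits(params, "sim_params"))
  params$initiation_rate * .n_nuclei(params, cycle_index) *
    productive_window(cycle_index, tu_length_kb, schedule)
}

#' Event-level simulation of initiation, elongation, and mitotic abortion
#'
#' For each cycle, initiation events are drawn as a homogeneous Poisson
#' process over the transcriptional window (lag, interphase]; a transcript
#' completes iff its start time plus the eclipse time falls within
#' interphase, and is otherwise aborted by the next mitosis (incomplete
#' nascent transcripts are abandoned and degraded). In the terminal cycle
#' interphase is unbounded, so nothing is aborted. Reproducible: each cycle
#' uses an RNG substream derived from `params$seed`, so simulating cycles in
#' any order (or one at a time) gives identical per-cycle counts.
#'
#' @param cycle_range integer vector of cycles to simulate.
#' @param tu_length_kb TU length in kb.
#' @param params a [sim_params()].
#' @param schedule a [cycle_schedule()].
#' @return data.frame with columns `cycle`, `initiated`, `completed`,
#'   `aborted` (completed + aborted == initiated).
#' @export
simulate_completed <- function(cycle_range, tu_length_kb, params,
                               schedule = default_cycle_schedule()) {
  stopifnot(inherits(params, "sim_params"))
  idx <- .schedule_row(schedule, cycle_range)
  ecl <- eclipse_time(tu_length_kb, schedule)
  out <- data.frame(cycle = as.integer(cycle_range), initiated = 0L,
                    completed = 0L, aborted = 0L)
  for (k in seq_along(cycle_range)) {
    cyc <- as.integer(cycle_range[k])
    iph <- schedule$table$interphase_min[idx[k]]
    win <- max(0, iph - schedule$lag_min)
    lambda <- params$initiation_rate * .n_nuclei(params, cyc) * win
    # deterministic per-cycle substream; restore RNG state afterwards
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    set.seed(params$seed + 10007L * cyc)
    n_init <- stats::rpois(1L, lambda)
    if (n_init > 0L) {
      starts <- stats::runif(n_init, min = schedule$lag_min, max = iph)
      done <- if (cyc == schedule$terminal_cycle) {
        rep(TRUE, n_init)  # no next mitosis: nothing aborted
      } else {
        starts + ecl <= iph
      }
      out$initiated[k] <- n_init
      out$completed[k] <- sum(done)
      out$aborted[k] <- n_init - sum(done)
    }
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }
  out
}

#' Onset cycle of productive expression
#'
#' First cycle with a nonzero expected number of completed transcripts;
#' agrees with [earliest_expressible_cycle()] by construction (the
#' expectation is rate x nuclei x productive window, and the terminal cycle
#' always completes transcripts).
#'
#' @inheritParams simulate_completed
#' @return a cycle index, or `NA_integer_` if the rate is zero.
#' @export
onset_profile <- function(tu_length_kb, params,
                          schedule = default_cycle_schedule()) {
  stopifnot(inherits(params, "sim_params"))
  if (params$initiation_rate == 0) return(NA_integer_)
  earliest_expressible_cycle(tu_length_kb, schedule, include_terminal = TRUE)
}
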