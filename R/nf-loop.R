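# Discrete-time simulator for coupled negative-feedback units.  Each unit is
# a threshold receptor plus an effector: the effector produces product at a
# fixed rate until the receptor sees the delayed concentration exceed its
# sensitivity, at which point it inhibits the effector; decay then brings the
# concentration back under threshold and production resumes.  The delay makes
# the threshold switch a relaxation oscillator.

#' Specify one negative-feedback unit
#'
#' @param name Loop name (unique within a system).
#' @param effector_rate Product units produced per time step while active
#'   (the effector's turnover).
#' @param decay_rate Fraction of the product removed per step, in \[0, 1).
#' @param sensitivity Product concentration above which the receptor sends
#'   the inhibition signal (strict comparison; equality keeps the effector
#'   active).  `Inf` disables inhibition.
#' @param delay Steps for the inhibition signal to act, >= 1.
#' @param initial_concentration Starting product concentration, >= 0.
#' @param initial_active Whether the effector starts active.
#' @return One-row tibble describing the loop.
#' @export
loop_spec <- function(name, effector_rate = 1.0, decay_rate = 0.1,
                      sensitivity = 5.0, delay = 3L,
                      initial_concentration = 0, initial_active = TRUE) {
  stopifnot(effector_rate >= 0, decay_rate >= 0, decay_rate < 1,
            sensitivity >= 0, delay >= 1, initial_concentration >= 0)
  tibble::tibble(
    name = as.character(name), effector_rate = effector_rate,
    decay_rate = decay_rate, sensitivity = sensitivity,
    delay = as.integer(delay),
    initial_concentration = initial_concentration,
    initial_active = isTRUE(initial_active)
  )
}

#' Specify a directed coupling between two loops
#'
#' The source loop's product concentration modulates a parameter of the
#' target loop multiplicatively: the target's effector rate (`mode =
#' "effector"`) or receptor sensitivity (`mode = "receptor"`) is scaled by
#' `1 + gain * C_source / S_source`, where the source sensitivity provides
#' the concentration normalization.  Positive gain activates, negative gain
#' inhibits.
#'
#' @param source,target Loop names.
#' @param mode `"effector"` or `"receptor"`.
#' @param gain Dimensionless coupling strength.
#' @return One-row tibble describing the coupling.
#' @export
coupling_spec <- function(source, target, mode = c("effector", "receptor"),
                          gain = 1.0) {
  mode <- match.arg(mode)
  if (identical(source, target)) stop("coupling source and target must differ", call. = FALSE)
  tibble::tibble(source = as.character(source), target = as.character(target),
                 mode = mode, gain = gain)
}

#' Assemble a negative-feedback system
#'
#' @param loops Tibble of loops (rows from [loop_spec()]).
#' @param couplings Tibble of couplings (rows from [coupling_spec()]), or
#'   `NULL` for uncoupled loops.
#' @param allow_large Lift the default cap of three loops.
#' @return A `nf_system` object.
#' @export
nf_system <- function(loops, couplings = NULL, allow_large = FALSE) {
  loops <- dplyr::bind_rows(loops)
  if (anyDuplicated(loops$name)) stop("loop names must be unique", call. = FALSE)
  if (nrow(loops) > 3L && !allow_large) {
    stop("more than 3 loops: pass allow_large = TRUE to lift the cap", call. = FALSE)
  }
  if (is.null(couplings)) {
    couplings <- tibble::tibble(source = character(), target = character(),
                                mode = character(), gain = numeric())
  } else {
    couplings <- dplyr::bind_rows(couplings)
    bad <- setdiff(c(couplings$source, couplings$target), loops$name)
    if (length(bad) > 0L) {
      stop("coupling refers to unknown loop(s): ", paste(unique(bad), collapse = ", "),
           call. = FALSE)
    }
  }
  structure(list(loops = loops, couplings = couplings), class = "nf_system")
}

#' @export
print.nf_system <- function(x, ...) {
  cat("<nf_system> ", nrow(x$loops), " loop(s), ", nrow(x$couplings),
      " coupling(s)\n", sep = "")
  print(x$loops)
  if (nrow(x$couplings)) print(x$couplings)
  invisible(x)
}

#' Read a system specification from a YAML or JSON config file
#'
#' The config mirrors the constructor field names: a `loops` list (each entry with
#' `name`, `effector_rate`, `decay_rate`, `sensitivity`, `delay`,
#' `initial_concentration`, `initial_active`) and an optional `couplings`
#' list (each with `source`, `target`, `mode`, `gain`).  Omitted loop fields
#' take the documented defaults.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @param allow_large Lift the three-loop cap.
#' @return A `nf_system`.
#' @export
read_system_config <- function(path, allow_large = FALSE) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  cfg <- if (ext == "json") {
    jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(cfg$loops)) stop("config has no 'loops' entry", call. = FALSE)
  loops <- purrr::map(cfg$loops, function(l) do.call(loop_spec, l))
  couplings <- if (length(cfg$couplings)) {
    purrr::map(cfg$couplings, function(cp) do.call(coupling_spec, cp))
  } else NULL
  nf_system(loops, couplings, allow_large = allow_large)
}

#' Simulate a negative-feedback system
#'
#' Deterministic synchronous update.  At each step t (concentrations C(t),
#' with C(0) the initial concentrations):
#' \enumerate{
#'   \item each loop's effective rate v' and sensitivity S' are its base
#'     values scaled by `1 + gain * C_source(t) / S_source` for every
#'     incoming coupling on the matching channel;
#'   \item activity A(t) = 0 if the concentration `delay` steps earlier
#'     exceeded S' (strictly), else 1; before step `delay` the initial
#'     concentration is used as history;
#'   \item C(t+1) = C(t) + v' A(t) - decay_rate C(t), floored at 0.
#' }
#' The model is deterministic; `seed` is recorded in the trajectory
#' attributes for provenance and reserved for optional noise extensions.
#'
#' @param system A `nf_system`.
#' @param steps Number of update steps, >= 1.
#' @param seed Recorded but unused (deterministic model).
#' @return A `nf_trajectory`: tibble with columns `step` (0..steps), `loop`,
#'   `concentration`, `active`.
#' @examples
#' traj <- nf_simulate(gen_loop_fixture(1), steps = 100)
#' measure_oscillation(traj, "loop1", burn_in = 20)
#' @export
nf_simulate <- function(system, steps, seed = NULL) {
  stopifnot(inherits(system, "nf_system"), steps >= 1)
  lp <- system$loops
  cp <- system$couplings
  nl <- nrow(lp)
  idx <- stats::setNames(seq_len(nl), lp$name)

  conc <- matrix(0, nrow = steps + 1L, ncol = nl)
  act <- matrix(1L, nrow = steps + 1L, ncol = nl)
  conc[1L, ] <- lp$initial_concentration
  act[1L, ] <- as.integer(lp$initial_active)

  eff_cp <- cp[cp$mode == "effector", , drop = FALSE]
  rec_cp <- cp[cp$mode == "receptor", , drop = FALSE]

  modulate <- function(base, cps, C) {
    out <- base
    if (nrow(cps)) {
      for (r in seq_len(nrow(cps))) {
        s <- idx[[cps$source[r]]]
        t <- idx[[cps$target[r]]]
        s_ref <- lp$sensitivity[s]
        norm <- if (is.finite(s_ref) && s_ref > 0) C[s] / s_ref else C[s]
        out[t] <- out[t] * (1 + cps$gain[r] * norm)
      }
    }
    out
  }

  for (ti in seq_len(steps)) {   # computing state at row ti + 1 from row ti
    C <- conc[ti, ]
    v_eff <- modulate(lp$effector_rate, eff_cp, C)
    s_eff <- modulate(lp$sensitivity, rec_cp, C)
    if (any(v_eff < 0)) stop("coupling drove an effector rate negative", call. = FALSE)
    if (any(s_eff < 0)) stop("coupling drove a sensitivity negative", call. = FALSE)
    delayed <- conc[cbind(pmax(ti - lp$delay, 1L), seq_len(nl))]
    A <- as.integer(!(delayed > s_eff))
    no_history <- ti - lp$delay < 1L
    A[no_history] <- as.integer(lp$initial_active[no_history])
    act[ti, ] <- A
    conc[ti + 1L, ] <- pmax(C + v_eff * A - lp$decay_rate * C, 0)
  }
  # activity at the final recorded state, for completeness of the table
  act[steps + 1L, ] <- act[steps, ]

  out <- tibble::tibble(
    step = rep(0:steps, times = nl),
    loop = rep(lp$name, each = steps + 1L),
    concentration = as.vector(conc),
    active = as.integer(as.vector(act))
  )
  attr(out, "system") <- system
  attr(out, "seed") <- seed
  class(out) <- c("nf_trajectory", class(out))
  out
}

#' Summarize the oscillation of one loop's concentration series
#'
#' Over the post-burn-in window: minimum, maximum, amplitude
#' `(max - min)/2`, and the period as the mean interval between successive
#' upward crossings of the window mean.  Windows with fewer than two upward
#' crossings report an undefined period (`NA`) and frequency 0.
#'
#' @param trajectory A `nf_trajectory`.
#' @param loop Loop name.
#' @param burn_in Steps discarded before analysis.
#' @return One-row tibble: `loop`, `min`, `max`, `amplitude`, `period`,
#'   `frequency`, `n_crossings`.
#' @export
measure_oscillation <- function(trajectory, loop, burn_in = 100) {
  stopifnot(is.data.frame(trajectory))
  if (!loop %in% trajectory$loop) stop("no loop named '", loop, "' in trajectory", call. = FALSE)
  x <- trajectory$concentration[trajectory$loop == loop &
                                  trajectory$step > burn_in]
  if (length(x) < 2L) stop("analysis window is empty after burn-in", call. = FALSE)
  m <- mean(x)
  up <- which(x[-length(x)] < m & x[-1] >= m)  # upward mean-crossings
  period <- if (length(up) >= 2L) mean(diff(up)) else NA_real_
  tibble::tibble(
    loop = loop, min = min(x), max = max(x),
    amplitude = (max(x) - min(x)) / 2,
    period = period,
    frequency = if (is.na(period)) 0 else 1 / period,
    n_crossings = length(up)
  )
}

#' Check an oscillation summary against a reference concentration range
#'
#' Physiological product concentrations stay within a known reference range;
#' a trajectory leaving the range models pathology.  Bounds are inclusive.
#'
#' @param summary Tibble with `min` and `max` columns
#'   (from [measure_oscillation()]); may have several rows.
#' @param low,high Reference range bounds, `low <= high`.
#' @return The summary with an added logical `in_range` column.
#' @export
check_range <- function(summary, low, high) {
  if (low > high) stop("invalid range: low > high", call. = FALSE)
  dplyr::mutate(summary, in_range = .data$min >= low & .data$max <= high)
}

#' Disturbance-propagation experiment
#'
#' Runs the system twice — as specified, and with one loop's parameter
#' multiplied by `factor` — and reports the oscillation summary of every loop
#' under both conditions side by side.  Used to trace how a perturbation of
#' one unit (e.g. doubling its effector turnover) propagates through the
#' couplings to downstream units.
#'
#' @param system A `nf_system`.
#' @param loop Name of the disturbed loop.
#' @param parameter One of `"effector_rate"`, `"sensitivity"`,
#'   `"decay_rate"`.
#' @param factor Positive multiplier applied to the parameter.
#' @param steps Simulation length.
#' @param burn_in Steps discarded before measuring.
#' @return Tibble of per-loop summaries with a `condition` column
#'   (`baseline` / `disturbed`).
#' @export
disturbance_experiment <- function(system, loop,
                                   parameter = c("effector_rate",
                                                 "sensitivity", "decay_rate"),
                                   factor, steps = 500, burn_in = 100) {
  parameter <- match.arg(parameter)
  stopifnot(inherits(system, "nf_system"), factor > 0)
  if (!loop %in% system$loops$name) stop("no loop named '", loop, "'", call. = FALSE)

  disturbed <- system
  i <- which(disturbed$loops$name == loop)
  newval <- disturbed$loops[[parameter]][i] * factor
  if (parameter == "decay_rate" && newval >= 1) {
    stop("disturbed decay_rate would be >= 1", call. = FALSE)
  }
  disturbed$loops[[parameter]][i] <- newval

  summarize_all_loops <- function(sys, label) {
    traj <- nf_simulate(sys, steps = steps)
    dplyr::bind_rows(lapply(sys$loops$name, function(nm) {
      measure_oscillation(traj, nm, burn_in = burn_in)
    })) |>
      dplyr::mutate(condition = label, .before = 1)
  }
  dplyr::bind_rows(
    summarize_all_loops(system, "baseline"),
    summarize_all_loops(disturbed, "disturbed")
  )
}

#' Trajectory plot for a simulated feedback system
#'
#' @param object A `nf_trajectory`.
#' @param ... Ignored.
#' @return A ggplot object: concentration versus step, one panel per loop,
#'   with inhibition intervals shaded.
#' @export
autoplot.nf_trajectory <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$step, y = .data$concentration)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_point(
      data = dplyr::filter(object, .data$active == 0L),
      colour = "firebrick", size = 0.4
    ) +
    ggplot2::facet_wrap(~loop, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time step", y = "product concentration",
                  subtitle = "red points: effector inhibited") +
    ggplot2::theme_minimal()
}
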