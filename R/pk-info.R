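# Specificity-versus-repetition planner: a goal can be reached either by
# encoding enough recognition specificity (high per-attempt success p) or by
# brute repetition (many attempts k) — antibodies and seeds being the
# biological archetypes.  Attempts are independent, so k attempts succeed at
# least once with probability 1 - (1 - p)^k.

#' Probability that at least one of k attempts succeeds
#'
#' @param p Per-attempt success probability in (0, 1\].
#' @param k Number of independent attempts, integer >= 1.
#' @return `1 - (1 - p)^k`.
#' @examples
#' success_prob(0.5, 2)  # 0.75
#' @export
success_prob <- function(p, k) {
  if (any(p <= 0 | p > 1)) stop("p must lie in (0, 1]", call. = FALSE)
  if (any(k < 1 | k != floor(k))) stop("k must be an integer >= 1", call. = FALSE)
  1 - (1 - p)^k
}

#' Minimum repetitions to reach a target success probability
#'
#' Smallest k >= 1 with `1 - (1 - p)^k >= target`, computed from the
#' closed-form `ceiling(log(1 - target) / log(1 - p))` and then verified by
#' direct evaluation at k and k - 1 (guarding against floating-point error
#' at the ceiling boundary).
#'
#' @param p Per-attempt success probability in (0, 1).
#' @param target Target overall success probability in (0, 1).
#' @return Integer number of repetitions.
#' @examples
#' min_repetitions(0.5, 0.95)  # 5
#' @export
min_repetitions <- function(p, target) {
  if (length(p) > 1L || length(target) > 1L) {
    return(as.integer(mapply(min_repetitions, p, target)))
  }
  if (p <= 0 || p >= 1) stop("p must lie in (0, 1)", call. = FALSE)
  if (target <= 0 || target >= 1) stop("target must lie in (0, 1)", call. = FALSE)
  k <- max(1L, as.integer(ceiling(log1p(-target) / log1p(-p))))
  while (success_prob(p, k) < target) k <- k + 1L
  while (k > 1L && success_prob(p, k - 1L) >= target) k <- k - 1L
  k
}

#' Energy cost of a (p, k) plan
#'
#' Each attempt costs a base amount plus a specificity surcharge proportional
#' to the coding burden `b(p) = -log2(1 - p)` bits: every added independent
#' recognition element halves the per-attempt failure probability, so the
#' number of elements needed grows as the negative log of the failure rate.
#' Total energy is `k * (base_cost + specificity_cost * b(p))`.
#'
#' @param p Per-attempt success probability in (0, 1); p = 1 has infinite
#'   coding burden under this model and is rejected.
#' @param k Number of attempts.
#' @param base_cost Energy per attempt.
#' @param specificity_cost Energy per bit of coding.
#' @return Energy in cost units.
#' @export
plan_energy <- function(p, k, base_cost = 1, specificity_cost = 1) {
  if (any(p >= 1)) stop("p = 1 implies an infinite coding burden", call. = FALSE)
  if (any(p <= 0)) stop("p must lie in (0, 1)", call. = FALSE)
  stopifnot(all(k >= 1), base_cost >= 0, specificity_cost >= 0)
  b <- -log2(1 - p)
  k * (base_cost + specificity_cost * b)
}

#' Full (p, k, energy) trade-off grid
#'
#' For every p in the grid: the minimum k reaching the target, the achieved
#' success probability, the energy, and feasibility under the k cap.
#'
#' @inheritParams pk_optimize
#' @return Tibble with columns `p`, `k`, `achieved`, `energy`, `feasible`.
#' @export
pk_grid <- function(p_grid, target_success, base_cost = 1,
                    specificity_cost = 1, k_max = 1000L) {
  stopifnot(length(p_grid) >= 1L, all(p_grid > 0 & p_grid < 1),
            target_success > 0, target_success < 1, k_max >= 1)
  tibble::tibble(p = sort(unique(p_grid))) |>
    dplyr::mutate(
      k = min_repetitions(.data$p, target_success),
      achieved = success_prob(.data$p, .data$k),
      energy = plan_energy(.data$p, .data$k, base_cost, specificity_cost),
      feasible = .data$k <= k_max
    )
}

#' Minimum-energy (p, k) plan for a target success probability
#'
#' For each candidate specificity p, takes the minimum number of repetitions
#' k reaching the target, prices the plan with [plan_energy()], and returns
#' the cheapest feasible plan.  Ties break toward smaller k, then smaller p.
#' When base cost dominates, high-specificity/few-attempt plans win; when
#' the specificity surcharge dominates, cheap low-specificity attempts in
#' bulk win.
#'
#' @param p_grid Candidate per-attempt success probabilities in (0, 1).
#' @param target_success Required overall success probability in (0, 1).
#' @param base_cost Energy per attempt.
#' @param specificity_cost Energy per bit of coding specificity.
#' @param k_max Cap on the number of repetitions.
#' @return A `pk_plan`: one-row tibble with `p`, `k`, `achieved`, `energy`.
#' @examples
#' pk_optimize(seq(0.05, 0.95, by = 0.05), target_success = 0.95)
#' @export
pk_optimize <- function(p_grid, target_success, base_cost = 1,
                        specificity_cost = 1, k_max = 1000L) {
  grid <- pk_grid(p_grid, target_success, base_cost, specificity_cost, k_max)
  feas <- dplyr::filter(grid, .data$feasible)
  if (nrow(feas) == 0L) {
    stop("no feasible (p, k) plan: every p needs more than k_max = ",
         k_max, " repetitions", call. = FALSE)
  }
  best <- feas |>
    dplyr::arrange(.data$energy, .data$k, .data$p) |>
    dplyr::slice(1) |>
    dplyr::select(-"feasible")
  attr(best, "query") <- list(p_grid = p_grid, target_success = target_success,
                              base_cost = base_cost,
                              specificity_cost = specificity_cost,
                              k_max = as.integer(k_max))
  class(best) <- c("pk_plan", class(best))
  best
}

#' Trade-off plot of energy against specificity
#'
#' @param object A tibble from [pk_grid()].
#' @param ... Ignored.
#' @return A ggplot object of energy (and k) against p.
#' @export
plot_pk_grid <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$p, y = .data$energy)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_point(ggplot2::aes(shape = .data$feasible)) +
    ggplot2::labs(x = "per-attempt specificity p", y = "plan energy",
                  title = "Energy of the minimal plan reaching the target") +
    ggplot2::theme_minimal()
}
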