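#' Simulate multi-day retrieval-learning cohorts
#'
#' Each subject draws a "learning day" from a geometric distribution with its
#' condition's per-day hazard. Before that day the subject fails all ten
#' daily retrieval trials; from the learning day onwards trials succeed with
#' high probability (at least one success on the learning day is guaranteed,
#' matching the observer learning criterion). Subjects whose learning day
#' falls beyond the final observation day are right-censored.
#'
#' @param config A [sim_config()]; cohort sizes and hazards come from
#'   `config$cohorts`, observation length from `config$n_days`.
#' @param p_success_after Per-trial success probability once a subject has
#'   learned.
#' @return Tibble `subject`, `condition`, `day`, `trial`, `success`,
#'   `latency_s` (`NA` for failures, otherwise <= 120 s).
#' @export
#' @examples
#' coh <- simulate_learning_cohort(sim_config(seed = 4))
#' dplyr::count(coh, condition)
simulate_learning_cohort <- function(config, p_success_after = 0.6) {
  cfg <- validate_sim_config(config)
  set.seed(cfg$seed + 4000L)
  n_days <- cfg$n_days
  out <- purrr::pmap(cfg$cohorts, function(condition, n, hazard) {
    purrr::map(seq_len(n), function(s) {
      subject <- sprintf("%s_%02d", condition, s)
      learn_day <- if (hazard <= 0) Inf else {
        d <- which(runif(n_days) < hazard)
        if (length(d) == 0) Inf else d[1]
      }
      purrr::map(seq_len(n_days), function(day) {
        if (day < learn_day) {
          succ <- rep(FALSE, 10)
        } else {
          succ <- runif(10) < p_success_after
          if (day == learn_day && !any(succ)) succ[sample(10, 1)] <- TRUE
        }
        tibble(subject = subject, condition = condition, day = day,
               trial = 1:10, success = succ,
               latency_s = ifelse(succ, runif(10, 5, 115), NA_real_))
      }) |> purrr::list_rbind()
    }) |> purrr::list_rbind()
  }) |> purrr::list_rbind()
  out
}
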