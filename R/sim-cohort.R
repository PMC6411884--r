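#' Specify a DDI cohort to simulate
#'
#' A cohort is a set of treatment groups of embryos (e.g. fresh sperm,
#' frozen-thawed, DNase-treated) each with its own true-damage distribution.
#' True damage is expressed on the DDI scale, i.e. a group with mean 1 sits
#' at the undamaged reference level.
#'
#' @param groups named list; each element is a list with `n` (embryos,
#'   >= 1), `damage_mean` (> 0) and optionally `damage_cv` (coefficient of
#'   variation of the gamma-distributed true damage, default 0.3).
#' @param reference_group name of the control group (must be in `groups`).
#' @return A `cohort_spec` object.
#' @seealso [sim_ddi_cohort()]
#' @export
cohort_spec <- function(groups, reference_group) {
  assert_that(length(groups) >= 1 && !is.null(names(groups)) &&
                all(nzchar(names(groups))), "groups must be a named list")
  assert_that(reference_group %in% names(groups),
              sprintf("unknown reference group '%s'", reference_group))
  for (g in groups) {
    assert_that(!is.null(g$n) && g$n >= 1, "each group needs n >= 1")
    assert_that(!is.null(g$damage_mean) && g$damage_mean > 0,
                "each group needs damage_mean > 0")
  }
  structure(list(groups = groups, reference_group = reference_group),
            class = "cohort_spec")
}

#' Simulate a DDI cohort with developmental outcomes
#'
#' Per embryo: true damage is drawn from the group's gamma distribution; the
#' raw H2B signal from a lognormal around `h2b_mean`; the raw gamma-H2A.X
#' signal is proportional to damage times H2B with multiplicative lognormal
#' measurement noise. The development outcome is Bernoulli with success
#' probability logistic in true damage, centred at damage = 2 (the DDI level
#' above which development usually fails) with configurable slope.
#'
#' @param spec a [cohort_spec()].
#' @param seed integer seed.
#' @param h2b_mean mean raw H2B signal, a.u.
#' @param ratio_noise_sd sd of the lognormal measurement noise on the raw
#'   ratio (log scale).
#' @param outcome_midpoint damage level at which success probability is 0.5.
#' @param outcome_slope logistic slope per damage unit.
#' @return Tibble: `group`, `embryo`, `gamma_signal`, `h2b_signal`,
#'   `true_damage`, `developed` (logical).
#' @export
sim_ddi_cohort <- function(spec, seed = 1L, h2b_mean = 1e4,
                           ratio_noise_sd = 0.15,
                           outcome_midpoint = 2, outcome_slope = 2) {
  stopifnot(inherits(spec, "cohort_spec"))
  withr::with_seed(as.integer(seed), {
    rows <- lapply(names(spec$groups), function(gname) {
      g <- spec$groups[[gname]]
      cv <- g$damage_cv %||% 0.3
      shape <- 1 / cv^2
      damage <- stats::rgamma(g$n, shape = shape,
                              rate = shape / g$damage_mean)
      h2b <- stats::rlnorm(g$n, log(h2b_mean), 0.2)
      ratio <- damage * exp(rnorm(g$n, 0, ratio_noise_sd))
      p_dev <- stats::plogis(-(damage - outcome_midpoint) * outcome_slope)
      tibble::tibble(
        group = gname,
        embryo = paste0(gname, "_", seq_len(g$n)),
        gamma_signal = ratio * h2b,
        h2b_signal = h2b,
        true_damage = damage,
        developed = runif(g$n) < p_dev
      )
    })
    dplyr::bind_rows(rows)
  })
}
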