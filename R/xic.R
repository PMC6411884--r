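#' Decompose an extracted-ion chromatogram into deamidated and interference components
#'
#' The m/z channel that monitors the deamidated peptide (+0.984 Da) also
#' collects the first 13C isotopologue of the non-deamidated form
#' (+1.0034 Da); the two are unresolvable in mass but have different
#' retention times. The decomposition therefore (i) fits a Gaussian peak to
#' the non-deamidated channel, (ii) models the deamidated channel as an
#' interference component *constrained to the non-deamidated peak's
#' retention time and width* (free amplitude) plus a free Gaussian for the
#' genuinely deamidated peptide, and (iii) quantifies the deamidated area
#' from the free component only. All fits are nonlinear least squares
#' (Levenberg-Marquardt) with non-negative amplitudes.
#'
#' When the free component's fitted retention time sits closer to the
#' interference than `min_separation_widths` fitted widths the two cannot be
#' told apart chromatographically; the result is flagged `unresolved` and
#' the deamidated fraction is reported as bounds instead of a point value.
#'
#' If the trace carries a peptide sequence (see [sim_xic_trace()]), the
#' fitted interference/non-deamidated area ratio is compared against the
#' M+1/M isotopologue ratio expected from elemental composition
#' ([isotope_m1_ratio()]) as a consistency check; the check never alters the
#' quantification.
#'
#' @param trace an `xic_trace` (columns `time`, `nondeamidated`,
#'   `deamidated`) with a strictly increasing time axis.
#' @param charge precursor charge (recorded in the result; the areas are
#'   charge-independent).
#' @param min_separation_widths resolvability limit in units of the larger
#'   fitted width (default 1).
#' @return Object of class `peak_decomposition`: areas (`nondeam_area`,
#'   `interference_area`, `deamidated_area`), `deamidated_fraction` =
#'   deamidated / (deamidated + non-deamidated) (`NA` when unresolved, with
#'   `fraction_bounds`), fitted `rt` and `widths` (min), `unresolved` flag,
#'   residual sums of squares, per-channel fitted vs trapezoidal areas, and
#'   the optional `isotope_check`.
#' @export
decompose_xic <- function(trace, charge = 2L, min_separation_widths = 1) {
  trace <- tibble::as_tibble(trace)
  assert_that(all(c("time", "nondeamidated", "deamidated") %in% names(trace)),
              "trace needs columns time, nondeamidated, deamidated")
  t <- trace$time
  assert_that(all(diff(t) > 0), "time axis must be strictly increasing")
  ynd <- trace$nondeamidated
  yd <- trace$deamidated
  step <- median(diff(t))

  assert_that(max(ynd) > 0,
              "no resolvable peak in the nondeamidated channel")

  # Levenberg-Marquardt with box constraints via the residual-function
  # interface; info codes 1-4 indicate convergence
  lm_fit <- function(resid_fn, par, lower, upper, label) {
    fit <- minpack.lm::nls.lm(
      par = par, lower = lower, upper = upper, fn = resid_fn,
      control = minpack.lm::nls.lm.control(maxiter = 500)
    )
    if (!fit$info %in% 1:4) {
      stop(sprintf(
        "%s fit did not converge (info %d: %s); residual sum of squares %.4g",
        label, fit$info, fit$message, fit$deviance), call. = FALSE)
    }
    fit
  }

  fit_one <- function(y, label) {
    mu0 <- t[which.max(y)]
    w0 <- max(step, sqrt(sum(y * (t - mu0)^2) / sum(y)))
    a0 <- max(trapz_area(t, y), .Machine$double.eps)
    fit <- lm_fit(
      function(p) y - p[1] * dnorm(t, p[2], p[3]),
      par = c(A = a0, mu = mu0, w = w0),
      lower = c(0, min(t), step / 2),
      upper = c(Inf, max(t), diff(range(t))),
      label = paste0(label, "-channel peak")
    )
    cf <- fit$par
    list(A = cf[["A"]], mu = cf[["mu"]], w = cf[["w"]], rss = fit$deviance)
  }

  nd <- fit_one(ynd, "nondeamidated")

  peak_scale <- max(ynd)
  if (max(yd) <= 1e-9 * peak_scale) {
    # flat deamidated channel: nothing to decompose
    res <- list(
      nondeam_area = nd$A, interference_area = 0, deamidated_area = 0,
      deamidated_fraction = 0, fraction_bounds = c(0, 0),
      rt = c(nondeamidated = nd$mu, deamidated = NA_real_),
      widths = c(nondeamidated = nd$w, deamidated = NA_real_),
      unresolved = FALSE, charge = as.integer(charge),
      rss = c(nondeamidated = nd$rss, deamidated = sum(yd^2)),
      fitted_channel_areas = c(nondeamidated = nd$A, deamidated = 0),
      trapz_channel_areas = c(nondeamidated = trapz_area(t, ynd),
                              deamidated = trapz_area(t, yd)),
      isotope_check = NULL
    )
    class(res) <- "peak_decomposition"
    return(res)
  }

  # starting values: project the interference from the nondeamidated fit,
  # seed the free component at the masked residual maximum
  ai0 <- max(0, stats::approx(t, yd, nd$mu, rule = 2)$y * nd$w * sqrt(2 * pi))
  resid_masked <- yd
  resid_masked[abs(t - nd$mu) <= 2 * nd$w] <- 0
  if (max(resid_masked) > 1e-6 * max(yd)) {
    mud0 <- t[which.max(resid_masked)]
  } else {
    mud0 <- nd$mu + nd$w  # co-elution candidate; the fit decides
  }
  ad0 <- max(trapz_area(t, yd) - ai0, 1e-6 * max(trapz_area(t, yd), 1))

  mu_i <- nd$mu
  w_i <- nd$w
  fit2 <- lm_fit(
    function(p) yd - p[1] * dnorm(t, mu_i, w_i) - p[2] * dnorm(t, p[3], p[4]),
    par = c(Ai = ai0, Ad = ad0, mud = mud0, wd = nd$w),
    lower = c(0, 0, min(t), step / 2),
    upper = c(Inf, Inf, max(t), diff(range(t))),
    label = "deamidated-channel decomposition"
  )
  cf <- fit2$par
  ai <- cf[["Ai"]]; ad <- cf[["Ad"]]; mud <- cf[["mud"]]; wd <- cf[["wd"]]
  rss_d <- fit2$deviance

  unresolved <- abs(mud - mu_i) < min_separation_widths * max(w_i, wd)
  total_d <- ai + ad
  if (unresolved) {
    fraction <- NA_real_
    bounds <- c(0, total_d / (total_d + nd$A))
    warning("deamidated component co-elutes with the isotope interference; ",
            "fraction reported as bounds")
  } else {
    fraction <- ad / (ad + nd$A)
    bounds <- c(fraction, fraction)
  }

  peptide <- attr(trace, "peptide")
  isotope_check <- NULL
  if (!is.null(peptide)) {
    isotope_check <- list(
      expected_m1_ratio = isotope_m1_ratio(peptide),
      fitted_interference_ratio = if (nd$A > 0) ai / nd$A else NA_real_
    )
  }

  res <- list(
    nondeam_area = nd$A, interference_area = ai, deamidated_area = ad,
    deamidated_fraction = fraction, fraction_bounds = bounds,
    rt = c(nondeamidated = nd$mu, deamidated = mud),
    widths = c(nondeamidated = w_i, deamidated = wd),
    unresolved = unresolved, charge = as.integer(charge),
    rss = c(nondeamidated = nd$rss, deamidated = rss_d),
    fitted_channel_areas = c(nondeamidated = nd$A, deamidated = total_d),
    trapz_channel_areas = c(nondeamidated = trapz_area(t, ynd),
                            deamidated = trapz_area(t, yd)),
    isotope_check = isotope_check
  )
  class(res) <- "peak_decomposition"
  res
}

#' @export
print.peak_decomposition <- function(x, ...) {
  cat("<peak_decomposition>\n")
  cat(sprintf("  nondeamidated area: %.4g (RT %.3f min, width %.3f)\n",
              x$nondeam_area, x$rt[["nondeamidated"]],
              x$widths[["nondeamidated"]]))
  cat(sprintf("  isotope interference area: %.4g\n", x$interference_area))
  cat(sprintf("  deamidated area: %.4g (RT %s min)\n", x$deamidated_area,
              ifelse(is.na(x$rt[["deamidated"]]), "-",
                     sprintf("%.3f", x$rt[["deamidated"]]))))
  if (isTRUE(x$unresolved)) {
    cat(sprintf("  UNRESOLVED: fraction in [%.3f, %.3f]\n",
                x$fraction_bounds[1], x$fraction_bounds[2]))
  } else {
    cat(sprintf("  deamidated fraction: %.4f\n", x$deamidated_fraction))
  }
  invisible(x)
}
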