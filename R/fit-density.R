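#' Corrected Akaike information criterion
#'
#' \code{AICc = -2 logL + 2k + 2k(k+1)/(n - k - 1)}, the small-sample
#' correction of AIC used to compare the candidate density-signal models.
#' \code{k} counts fixed-effect coefficients plus variance components.
#'
#' @param log_likelihood maximized log-likelihood.
#' @param k_parameters total parameter count.
#' @param n_obs number of observations; must exceed \code{k + 1}.
#' @return The AICc value.
#' @examples
#' aicc(0, 2, 44)  # 4 + 12/41
#' @export
aicc <- function(log_likelihood, k_parameters, n_obs) {
  if (n_obs - k_parameters - 1 <= 0)
    stop("AICc undefined: need n_obs > k_parameters + 1")
  -2 * log_likelihood + 2 * k_parameters +
    2 * k_parameters * (k_parameters + 1) / (n_obs - k_parameters - 1)
}

## fit y ~ x (+ injured) with a per-sample random intercept by ML, falling
## back to a fixed-effects-only fit when the mixed fit is singular or fails
ml_random_intercept_fit <- function(df, with_injury) {
  fixed <- if (with_injury) y ~ x + injured else y ~ x
  mixed <- tryCatch(
    nlme::lme(fixed, random = ~ 1 | sid, data = df, method = "ML",
              control = nlme::lmeControl(returnObject = TRUE)),
    error = function(e) NULL)
  if (!is.null(mixed)) {
    vc <- as.numeric(nlme::VarCorr(mixed)[, "Variance"])
    sigma_sample2 <- vc[1L]
    sigma_resid2 <- vc[2L]
    if (is.finite(sigma_sample2) && is.finite(sigma_resid2) &&
        (sigma_sample2 + sigma_resid2) > 0 &&
        sigma_sample2 > 1e-10 * (sigma_sample2 + sigma_resid2)) {
      return(list(fit = mixed, logLik = as.numeric(stats::logLik(mixed)),
                  coefficients = nlme::fixef(mixed),
                  sigma_sample = sqrt(sigma_sample2),
                  sigma_resid = sqrt(sigma_resid2),
                  k = length(nlme::fixef(mixed)) + 2L, singular = FALSE))
    }
  }
  ## between-sample variance absent (or mixed fit failed): plain ML
  ## least-squares fit; one residual variance component
  warning("between-sample variance is zero or the mixed fit failed; ",
          "using a fixed-effects-only fit", call. = FALSE)
  ls <- stats::lm(fixed, data = df)
  list(fit = ls, logLik = as.numeric(stats::logLik(ls)),
       coefficients = stats::coef(ls),
       sigma_sample = 0,
       sigma_resid = sqrt(mean(stats::residuals(ls)^2)),
       k = length(stats::coef(ls)) + 1L, singular = TRUE)
}

#' Fit the density-signal calibration model
#'
#' Models gravimetric lung density (g/mL) as a function of the mean lung
#' MRI signal, with a random intercept per lung sample (repeated scans at
#' several airway pressures) and a fixed additive effect of the injury
#' (instilled extravascular lung water) indicator. Two fixed-effect forms
#' are supported, \code{density = a*x + b} (linear) and
#' \code{density = a*x^2 + b} (quadratic, no linear term), with the signal
#' either raw or normalized to the water or muscle reference. Fits are by
#' maximum likelihood so AICc is comparable across fixed-effect structures;
#' the injury-effect p-value comes from a likelihood-ratio test against the
#' same model without the indicator.
#'
#' @param samples ex vivo sample table (see [validate_sample_table()]).
#' @param model_form \code{"linear"} or \code{"quadratic"}.
#' @param normalization \code{"none"}, \code{"water"} or \code{"muscle"}.
#' @return An object of class \code{density_fit} with coefficients
#'   \code{a}, \code{b}, the injury effect and its LRT p-value, variance
#'   components, AICc and bookkeeping. Methods: \code{print},
#'   \code{summary}, \code{coef}, \code{predict}, \code{plot}.
#' @export
fit_density_signal <- function(samples,
                               model_form = c("linear", "quadratic"),
                               normalization = c("none", "water", "muscle")) {
  model_form <- match.arg(model_form)
  normalization <- match.arg(normalization)
  validate_sample_table(samples)
  n_samples <- length(unique(samples$sample_id))
  if (n_samples < 3L) stop("need at least 3 samples to fit the calibration model")
  n_levels <- tapply(samples$cpap_cmh2o, samples$sample_id,
                     function(p) length(unique(p)))
  if (any(n_levels < 2L))
    stop("each sample needs at least 2 airway-pressure levels")
  s <- normalized_signal(samples, normalization)
  df <- data.frame(
    y = compute_density(samples$mass_g, samples$volume_ml),
    x = if (model_form == "quadratic") s^2 else s,
    injured = as.numeric(samples$group == "injured"),
    sid = factor(samples$sample_id))
  full <- ml_random_intercept_fit(df, with_injury = TRUE)
  reduced <- suppressWarnings(ml_random_intercept_fit(df, with_injury = FALSE))
  lrt <- max(0, 2 * (full$logLik - reduced$logLik))
  p_evlw <- stats::pchisq(lrt, df = 1L, lower.tail = FALSE)
  cf <- full$coefficients
  structure(
    list(model_form = model_form, normalization = normalization,
         a = unname(cf[["x"]]), b = unname(cf[["(Intercept)"]]),
         injury_effect = unname(cf[["injured"]]),
         evlw_effect_p = p_evlw,
         sigma_sample = full$sigma_sample, sigma_resid = full$sigma_resid,
         log_likelihood = full$logLik, k_parameters = full$k,
         aicc = aicc(full$logLik, full$k, nrow(df)),
         n_obs = nrow(df), n_samples = n_samples,
         singular = full$singular, fit = full$fit, data = df),
    class = "density_fit")
}

#' @export
print.density_fit <- function(x, ...) {
  form <- if (x$model_form == "quadratic") "density = a*signal^2 + b"
          else "density = a*signal + b"
  cat(sprintf("Density-signal calibration (%s, signal normalization: %s)\n",
              x$model_form, x$normalization))
  cat(sprintf("  %s:  a = %.5g, b = %.5g\n", form, x$a, x$b))
  cat(sprintf("  injury effect: %+.4g g/mL (LRT p = %.3g)\n",
              x$injury_effect, x$evlw_effect_p))
  cat(sprintf("  AICc = %.1f  (%d obs, %d samples%s)\n", x$aicc, x$n_obs,
              x$n_samples,
              if (x$singular) ", fixed-effects fallback" else ""))
  invisible(x)
}

#' @export
summary.density_fit <- function(object, ...) {
  out <- object[c("model_form", "normalization", "a", "b", "injury_effect",
                  "evlw_effect_p", "sigma_sample", "sigma_resid", "aicc",
                  "n_obs", "n_samples", "singular")]
  class(out) <- "summary.density_fit"
  out
}

#' @export
print.summary.density_fit <- function(x, ...) {
  cat(sprintf("density_fit: %s form, %s normalization\n", x$model_form,
              x$normalization))
  cat(sprintf("  a = %.6g, b = %.6g, injury = %+.4g (p = %.3g)\n",
              x$a, x$b, x$injury_effect, x$evlw_effect_p))
  cat(sprintf("  sd(sample) = %.4g, sd(resid) = %.4g, AICc = %.2f\n",
              x$sigma_sample, x$sigma_resid, x$aicc))
  invisible(x)
}

#' @export
coef.density_fit <- function(object, ...) {
  c(a = object$a, b = object$b, injury = object$injury_effect)
}

#' Predict density from signal
#'
#' @param object a \code{density_fit}.
#' @param signal mean lung signal on the fit's normalization scale.
#' @param injured logical/0-1; whether the injury offset applies.
#' @param ... unused.
#' @return Predicted density (g/mL), fixed effects only.
#' @export
predict.density_fit <- function(object, signal, injured = FALSE, ...) {
  x <- if (object$model_form == "quadratic") signal^2 else signal
  object$b + object$a * x + object$injury_effect * as.numeric(injured)
}

#' @export
plot.density_fit <- function(x, ...) {
  s <- sqrt(abs(x$data$x)) * sign(x$data$x)
  sig <- if (x$model_form == "quadratic") s else x$data$x
  graphics::plot(sig, x$data$y,
                 col = ifelse(x$data$injured > 0, "firebrick", "steelblue"),
                 pch = 16, xlab = sprintf("lung signal (%s)", x$normalization),
                 ylab = "density (g/mL)", ...)
  grid_s <- seq(min(sig), max(sig), length.out = 100)
  graphics::lines(grid_s, predict(x, grid_s), lwd = 2)
  graphics::legend("topleft", c("healthy", "injured"), pch = 16,
                   col = c("steelblue", "firebrick"), bty = "n")
  invisible(x)
}

#' AICc comparison of candidate density-signal models
#'
#' Fits every combination of model form (linear, quadratic) and signal
#' normalization (none, water, muscle) and tabulates AICc with the
#' injury-effect p-value — the model-selection table of the ex vivo
#' calibration.
#'
#' @param samples ex vivo sample table.
#' @return data.frame with one row per (form, normalization): columns
#'   \code{model_form}, \code{normalization}, \code{aicc},
#'   \code{evlw_effect_p}, \code{best} (logical, lowest AICc).
#' @export
density_model_table <- function(samples) {
  combos <- expand.grid(model_form = c("linear", "quadratic"),
                        normalization = c("none", "water", "muscle"),
                        stringsAsFactors = FALSE)
  fits <- Map(function(f, n) suppressWarnings(
                fit_density_signal(samples, f, n)),
              combos$model_form, combos$normalization)
  out <- data.frame(combos,
                    aicc = vapply(fits, `[[`, 0, "aicc"),
                    evlw_effect_p = vapply(fits, `[[`, 0, "evlw_effect_p"))
  out$best <- out$aicc == min(out$aicc)
  attr(out, "fits") <- fits
  out
}
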