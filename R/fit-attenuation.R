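#' Fit the attenuation-gas fraction line
#'
#' Fits \code{MRI_ATT = slope * GAS_F + intercept} with a per-lung random
#' intercept (maximum likelihood), the relation through which aeration
#' thresholds are read off. Deflated reference observations (gas fraction
#' 0, attenuation 1 by construction) are excluded from the regression by
#' default: the ratio definition pins them to (0, 1), so they carry no
#' information about the relation and would bias the intercept.
#'
#' Accepts either a raw ex vivo sample table (attenuation and gas fraction
#' are derived per sample via [attenuation_table()]) or a pre-built
#' data.frame with columns \code{sample_id}, \code{gas_fraction},
#' \code{attenuation} and optionally \code{reference}.
#'
#' @param data sample table or attenuation table (see Details).
#' @param normalization \code{"water"} or \code{"muscle"}; used only when
#'   \code{data} is a raw sample table.
#' @param include_reference keep the deflated (0, 1) rows in the fit.
#' @return An object of class \code{attenuation_fit}: \code{slope},
#'   \code{intercept}, \code{r_squared} (of the fixed-effect prediction),
#'   variance components, and the per-observation data retained for
#'   bootstrap resampling. Methods: \code{print}, \code{summary},
#'   \code{coef}, \code{predict}, \code{plot}.
#' @export
fit_attenuation_line <- function(data, normalization = c("water", "muscle"),
                                 include_reference = FALSE) {
  normalization <- match.arg(normalization)
  if (!all(c("gas_fraction", "attenuation") %in% names(data))) {
    data <- attenuation_table(data, normalization)
  }
  if (is.null(data$reference))
    data$reference <- data$gas_fraction == 0 & data$attenuation == 1
  fit_rows <- if (include_reference) data else data[!data$reference, ]
  if (length(unique(fit_rows$sample_id)) < 3L)
    stop("need at least 3 samples to fit the attenuation line")
  if (diff(range(fit_rows$gas_fraction)) < 1e-12)
    stop("degenerate gas-fraction range: all values equal")
  df <- data.frame(y = fit_rows$attenuation, x = fit_rows$gas_fraction,
                   injured = 0, sid = factor(fit_rows$sample_id))
  fit <- suppressWarnings(ml_random_intercept_fit(df, with_injury = FALSE))
  cf <- fit$coefficients
  yhat <- cf[["(Intercept)"]] + cf[["x"]] * df$x
  ss_tot <- sum((df$y - mean(df$y))^2)
  r2 <- if (ss_tot > 0) 1 - sum((df$y - yhat)^2) / ss_tot else NA_real_
  structure(
    list(normalization = normalization,
         slope = unname(cf[["x"]]), intercept = unname(cf[["(Intercept)"]]),
         r_squared = r2,
         sigma_sample = fit$sigma_sample, sigma_resid = fit$sigma_resid,
         log_likelihood = fit$logLik,
         aicc = aicc(fit$logLik, fit$k, nrow(df)),
         n_obs = nrow(df), n_samples = length(unique(fit_rows$sample_id)),
         singular = fit$singular, include_reference = include_reference,
         data = fit_rows),
    class = "attenuation_fit")
}

#' @export
print.attenuation_fit <- function(x, ...) {
  cat(sprintf("Attenuation line (%s-normalized signal)\n", x$normalization))
  cat(sprintf("  MRI_ATT = %.4f * GAS_F + %.4f   (R^2 = %.3f)\n",
              x$slope, x$intercept, x$r_squared))
  cat(sprintf("  %d obs, %d lungs; sd(sample) = %.3g, sd(resid) = %.3g\n",
              x$n_obs, x$n_samples, x$sigma_sample, x$sigma_resid))
  invisible(x)
}

#' @export
summary.attenuation_fit <- function(object, ...) {
  object[c("normalization", "slope", "intercept", "r_squared",
           "sigma_sample", "sigma_resid", "aicc", "n_obs", "n_samples",
           "singular")]
}

#' @export
coef.attenuation_fit <- function(object, ...) {
  c(slope = object$slope, intercept = object$intercept)
}

#' Predict attenuation at given gas fractions
#'
#' @param object an \code{attenuation_fit}.
#' @param gas_fraction numeric gas fractions.
#' @param ... unused.
#' @return Fixed-effect predicted attenuation.
#' @export
predict.attenuation_fit <- function(object, gas_fraction, ...) {
  object$intercept + object$slope * gas_fraction
}

#' @export
plot.attenuation_fit <- function(x, ...) {
  graphics::plot(x$data$gas_fraction, x$data$attenuation, pch = 16,
                 col = "grey35", xlab = "gas fraction",
                 ylab = "MRI signal attenuation", ...)
  graphics::abline(x$intercept, x$slope, lwd = 2, col = "steelblue")
  invisible(x)
}

#' Aeration thresholds from the attenuation line
#'
#' Reads the attenuation thresholds off the fitted line at the gas-fraction
#' cut-offs separating the aeration compartments (0.1: non-aerated below;
#' 0.5: poorly aerated below, normally/hyper-aerated above):
#' \code{threshold = slope * cutoff + intercept}. 95% confidence intervals
#' come from a nonparametric cluster bootstrap: lungs are resampled with
#' replacement, the line refit on the pooled resampled observations, and
#' percentile intervals taken over the replicate thresholds.
#'
#' @param fit an \code{attenuation_fit}.
#' @param cutoffs gas-fraction cut-offs in [0, 1), default \code{c(0.1, 0.5)}
#'   (non-aerated, poorly aerated).
#' @param reps bootstrap replicates (default 1000).
#' @param seed RNG seed recorded in the output.
#' @param level confidence level.
#' @return An object of class \code{aeration_thresholds} on the
#'   \code{"attenuation"} scale: \code{t_nonaerated}, \code{t_poor}, their
#'   CIs, and provenance.
#' @examples
#' \donttest{
#' tab <- simulate_attenuation_data(seed = 1)
#' fit <- fit_attenuation_line(tab)
#' derive_thresholds(fit, reps = 200, seed = 1)
#' }
#' @export
derive_thresholds <- function(fit, cutoffs = c(0.1, 0.5), reps = 1000L,
                              seed = 1L, level = 0.95) {
  if (!inherits(fit, "attenuation_fit")) stop("'fit' must be an attenuation_fit")
  if (any(cutoffs < 0 | cutoffs >= 1)) stop("cutoffs must lie in [0, 1)")
  if (length(cutoffs) != 2L || cutoffs[1L] >= cutoffs[2L])
    stop("expected two increasing cutoffs (non-aerated, poorly aerated)")
  point <- fit$intercept + fit$slope * cutoffs
  rows <- fit$data[!fit$data$reference | fit$include_reference, , drop = FALSE]
  ids <- unique(rows$sample_id)
  by_id <- split(rows[, c("gas_fraction", "attenuation")], rows$sample_id)
  boot <- matrix(NA_real_, reps, length(cutoffs))
  set.seed(seed)
  for (r in seq_len(reps)) {
    draw <- sample(ids, length(ids), replace = TRUE)
    d <- do.call(rbind, by_id[as.character(draw)])
    X <- cbind(1, d$gas_fraction)
    cf <- tryCatch(stats::lm.fit(X, d$attenuation)$coefficients,
                   error = function(e) c(NA_real_, NA_real_))
    boot[r, ] <- cf[1L] + cf[2L] * cutoffs
  }
  alpha <- (1 - level) / 2
  ci <- apply(boot, 2L, stats::quantile, probs = c(alpha, 1 - alpha),
              na.rm = TRUE)
  if (fit$slope >= 0)
    warning("attenuation slope is non-negative; thresholds are not ordered")
  structure(
    list(scale = "attenuation",
         t_nonaerated = point[1L], t_poor = point[2L],
         ci_nonaerated = unname(ci[, 1L]), ci_poor = unname(ci[, 2L]),
         cutoffs = cutoffs, level = level,
         bootstrap_reps = reps, seed = seed,
         normalization = fit$normalization,
         provenance = list(slope = fit$slope, intercept = fit$intercept)),
    class = "aeration_thresholds")
}

#' Translate ex vivo attenuation thresholds to in vivo intensity thresholds
#'
#' In vivo scans are on the muscle-normalized intensity scale, not the
#' attenuation scale: the bridge is the intensity of fully non-aerated
#' tissue (atelectasis), which plays the role of the deflated ex vivo
#' sample. Each in vivo threshold is
#' \code{MRI_ATEL * attenuation threshold}. Thresholds are kept at full
#' precision; two-decimal rounded convenience values are carried alongside
#' for strict reproduction of reported analyses.
#'
#' @param mri_atel mean muscle-normalized intensity of an atelectasis
#'   reference ROI; > 0.
#' @param exvivo an \code{aeration_thresholds} on the attenuation scale, or
#'   a numeric vector of the two attenuation thresholds (non-aerated,
#'   poorly aerated), e.g. \code{c(0.70, 0.28)}.
#' @return An \code{aeration_thresholds} on the
#'   \code{"muscle_normalized"} scale with elements \code{t_nonaerated},
#'   \code{t_poor}, \code{rounded} (two-decimal pair) and provenance.
#' @examples
#' translate_thresholds(0.92, c(0.70, 0.28))  # 0.644 / 0.2576 -> 0.64 / 0.26
#' @export
translate_thresholds <- function(mri_atel, exvivo) {
  if (!is.numeric(mri_atel) || length(mri_atel) != 1L || mri_atel <= 0)
    stop("'mri_atel' must be a single positive value")
  if (inherits(exvivo, "aeration_thresholds")) {
    if (exvivo$scale != "attenuation")
      stop("'exvivo' thresholds must be on the attenuation scale")
    tt <- c(exvivo$t_nonaerated, exvivo$t_poor)
  } else {
    tt <- as.numeric(exvivo)
    if (length(tt) != 2L || any(tt <= 0) || tt[1L] <= tt[2L])
      stop("'exvivo' must be two positive thresholds with non-aerated > poor")
  }
  structure(
    list(scale = "muscle_normalized",
         t_nonaerated = mri_atel * tt[1L], t_poor = mri_atel * tt[2L],
         rounded = round(mri_atel * tt, 2L),
         provenance = list(mri_atel = mri_atel, exvivo_thresholds = tt,
                           rounding = "round half to even, 2 decimals")),
    class = "aeration_thresholds")
}

#' Construct explicit intensity thresholds
#'
#' For analyses that apply reported thresholds directly (bypassing an
#' ex vivo fit), e.g. \code{threshold_set(0.64, 0.26)}.
#'
#' @param t_nonaerated intensity at and above which tissue is non-aerated.
#' @param t_poor intensity at and above which (below
#'   \code{t_nonaerated}) tissue is poorly aerated.
#' @param scale threshold scale; in vivo classification requires
#'   \code{"muscle_normalized"}.
#' @return An \code{aeration_thresholds}.
#' @export
threshold_set <- function(t_nonaerated, t_poor,
                          scale = c("muscle_normalized", "attenuation")) {
  scale <- match.arg(scale)
  if (!(t_nonaerated > t_poor && t_poor > 0))
    stop("need t_nonaerated > t_poor > 0")
  structure(list(scale = scale, t_nonaerated = t_nonaerated, t_poor = t_poor,
                 rounded = round(c(t_nonaerated, t_poor), 2L),
                 provenance = list(source = "explicit")),
            class = "aeration_thresholds")
}

#' @export
print.aeration_thresholds <- function(x, ...) {
  cat(sprintf("Aeration thresholds (%s scale)\n", x$scale))
  fmt_ci <- function(ci) if (is.null(ci)) "" else
    sprintf(" [%.0f%% CI %.3f-%.3f]", 100 * (x$level %||% 0.95), ci[1L], ci[2L])
  cat(sprintf("  non-aerated at/above: %.4f%s\n", x$t_nonaerated,
              fmt_ci(x$ci_nonaerated)))
  cat(sprintf("  poorly aerated at/above: %.4f%s\n", x$t_poor,
              fmt_ci(x$ci_poor)))
  if (!is.null(x$rounded))
    cat(sprintf("  rounded (2 dp): %.2f / %.2f\n", x$rounded[1L], x$rounded[2L]))
  if (!is.null(x$bootstrap_reps))
    cat(sprintf("  bootstrap: %d reps, seed %d\n", x$bootstrap_reps, x$seed))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
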