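#' Paired Wilcoxon signed-rank test (normal approximation)
#'
#' Two-sided signed-rank test for paired pre/post summary measures, using
#' the large-sample normal approximation without continuity correction
#' (tie-corrected variance), zero differences dropped. This is the exact
#' convention under which six uniformly signed differences give
#' p = 0.0278; the exact permutation test would give 0.03125.
#'
#' @param pre,post equal-length paired numeric vectors, length >= 4.
#' @return list with \code{statistic} (V, sum of positive ranks),
#'   \code{z}, \code{p_value}, \code{n_effective}.
#' @examples
#' paired_wilcoxon(rep(0, 6), 1:6)  # p = 0.0278
#' @export
paired_wilcoxon <- function(pre, post) {
  if (length(pre) != length(post)) stop("'pre' and 'post' must be paired")
  if (length(pre) < 4L) stop("need at least 4 pairs")
  d <- post - pre
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) stop("all differences are zero: test undefined")
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  ties <- table(r)
  sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  if (sig2 <= 0) stop("zero variance in signed ranks")
  z <- (v - mu) / sqrt(sig2)
  list(statistic = v, z = z, p_value = 2 * stats::pnorm(-abs(z)),
       n_effective = n)
}

#' Sidak multiple-comparison adjustment
#'
#' \code{p_adj = 1 - (1 - p)^m} for a family of m comparisons.
#'
#' @param p raw p-value(s).
#' @param m family size.
#' @return Adjusted p-value(s), capped at 1.
#' @examples
#' sidak_adjust(0.05, 2)  # 0.0975
#' @export
sidak_adjust <- function(p, m) {
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  if (m < 1) stop("'m' must be >= 1")
  pmin(1, 1 - (1 - p)^m)
}

#' Two-way repeated-measures ANOVA for the regional aeration analysis
#'
#' Classical within-subject two-way ANOVA for the 2 x 2 design ROI
#' (ventral/dorsal) x time (pre/post), subject as blocking factor, with
#' Sidak-adjusted paired post hoc contrasts: pre vs post within each ROI
#' (family of 2) and ventral vs dorsal within each time (family of 2).
#' Degenerate inputs with zero variance return p = 1 everywhere with a
#' warning rather than failing.
#'
#' @param data data.frame with columns \code{subject}, \code{roi}
#'   (\code{"ventral"}/\code{"dorsal"}), \code{time}
#'   (\code{"pre"}/\code{"post"}), \code{value}; complete balanced design,
#'   at least 3 subjects.
#' @return list with \code{p_roi}, \code{p_time}, \code{p_interaction} and
#'   a \code{contrasts} data.frame (raw and Sidak-adjusted paired-t
#'   p-values).
#' @export
rm_anova_roi_time <- function(data) {
  need <- c("subject", "roi", "time", "value")
  if (!all(need %in% names(data)))
    stop("'data' must have columns subject, roi, time, value")
  data$subject <- factor(data$subject)
  data$roi <- factor(data$roi, levels = c("ventral", "dorsal"))
  data$time <- factor(data$time, levels = c("pre", "post"))
  if (anyNA(data$roi) || anyNA(data$time))
    stop("roi must be ventral/dorsal and time pre/post")
  tab <- table(data$subject, data$roi, data$time)
  if (any(tab != 1L))
    stop("design must be complete and balanced: one value per subject x roi x time")
  if (nlevels(data$subject) < 3L) stop("need at least 3 subjects")

  if (stats::var(data$value) < .Machine$double.eps) {
    warning("zero variance in 'value'; returning p = 1 for all effects")
    contrasts <- data.frame(
      contrast = c("pre vs post | ventral", "pre vs post | dorsal",
                   "ventral vs dorsal | pre", "ventral vs dorsal | post"),
      p_raw = 1, p_sidak = 1)
    return(list(p_roi = 1, p_time = 1, p_interaction = 1,
                contrasts = contrasts))
  }

  fit <- stats::aov(value ~ roi * time + Error(subject / (roi * time)),
                    data = data)
  sm <- summary(fit)
  pick_p <- function(stratum, term) {
    tb <- sm[[stratum]][[1L]]
    p <- tb[trimws(rownames(tb)) == term, "Pr(>F)"]
    if (length(p) == 0L || is.na(p)) 1 else p
  }
  p_roi <- pick_p("Error: subject:roi", "roi")
  p_time <- pick_p("Error: subject:time", "time")
  p_int <- pick_p("Error: subject:roi:time", "roi:time")

  paired_p <- function(a, b) {
    d <- a - b
    if (stats::sd(d) < .Machine$double.eps) return(1)
    stats::t.test(d)$p.value
  }
  cell <- function(r, t) data$value[data$roi == r & data$time == t][
    order(data$subject[data$roi == r & data$time == t])]
  p1 <- paired_p(cell("ventral", "pre"), cell("ventral", "post"))
  p2 <- paired_p(cell("dorsal", "pre"), cell("dorsal", "post"))
  p3 <- paired_p(cell("ventral", "pre"), cell("dorsal", "pre"))
  p4 <- paired_p(cell("ventral", "post"), cell("dorsal", "post"))
  contrasts <- data.frame(
    contrast = c("pre vs post | ventral", "pre vs post | dorsal",
                 "ventral vs dorsal | pre", "ventral vs dorsal | post"),
    p_raw = c(p1, p2, p3, p4),
    p_sidak = c(sidak_adjust(c(p1, p2), 2), sidak_adjust(c(p3, p4), 2)))
  list(p_roi = p_roi, p_time = p_time, p_interaction = p_int,
       contrasts = contrasts)
}
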