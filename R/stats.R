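#' Arcsine square-root transform for proportions
#'
#' The classical variance-stabilizing transform for proportion-like
#' metrics: \eqn{asin(\sqrt{x})}, radians, mapping [0, 1] onto [0, pi/2] and
#' strictly increasing. Values outside [0, 1] (e.g. mitigation above 1) are
#' clipped with a warning reporting the count.
#'
#' @param x numeric vector of proportions.
#' @return transformed values, radians.
#' @export
arcsineTransform <- function(x) {
  out <- sum(x < 0 | x > 1, na.rm = TRUE)
  if (out > 0)
    warning(sprintf("%d value(s) outside [0, 1] clipped before arcsine", out))
  asin(sqrt(pmin(pmax(x, 0), 1)))
}

#' Subset linear regressions of a transformed metric
#'
#' The factorial design's interactions are read through simple regressions
#' on data subsets: for each extent level, an ordinary least-squares
#' regression of the arcsine-transformed metric on intensity, and for each
#' intensity level, on extent. Fits use \code{stats::lm}. Subsets with
#' fewer than 3 points are omitted with a warning.
#'
#' @param metrics a metric table (e.g. from \code{\link{metricTable}}) for
#'   one scale, with columns extent, intensity, and the metric.
#' @param metric name of the metric column (default "skew").
#' @param transform transformation applied before fitting (default
#'   \code{\link{arcsineTransform}}; use \code{identity} for none).
#' @return data.frame with one row per subset: subsetVariable ("extent" or
#'   "intensity" — the predictor), subsetValue (percent), beta (slope per
#'   unit predictor fraction), rSquared, df, p.
#' @export
subsetRegressions <- function(metrics, metric = "skew",
                              transform = arcsineTransform) {
  y <- transform(metrics[[metric]])
  rows <- list()
  fitOne <- function(predictor, subsetVar, subsetVal, sel) {
    sel <- sel & !is.na(y)
    if (sum(sel) < 3) {
      warning(sprintf("subset %s=%g%% has < 3 points; omitted",
                      subsetVar, 100 * subsetVal))
      return(NULL)
    }
    if (length(unique(metrics[[predictor]][sel])) < 2L) {
      warning(sprintf("subset %s=%g%% has a constant predictor; omitted",
                      subsetVar, 100 * subsetVal))
      return(NULL)
    }
    fit <- stats::lm(y[sel] ~ metrics[[predictor]][sel])
    s <- summary(fit)
    data.frame(subsetVariable = predictor,
               subsetValue = 100 * subsetVal,
               beta = unname(stats::coef(fit)[2]),
               rSquared = s$r.squared,
               df = unname(fit$df.residual),
               p = unname(s$coefficients[2, 4]))
  }
  for (ev in sort(unique(metrics$extent)))
    rows[[length(rows) + 1L]] <-
      fitOne("intensity", "extent", ev, metrics$extent == ev)
  for (iv in sort(unique(metrics$intensity)))
    rows[[length(rows) + 1L]] <-
      fitOne("extent", "intensity", iv, metrics$intensity == iv)
  do.call(rbind, rows)
}

#' Paired comparison between matched scenarios
#'
#' Aligns two metric vectors by pairing keys (e.g. treatment x replicate)
#' and performs a paired t-test on the differences a - b, reporting the t
#' statistic, df = n - 1, two-sided p, and the mean of differences
#' (m.o.d.). A zero-variance difference vector (e.g. identical inputs) has
#' an undefined t; the result then carries t = NA, p = NA, and
#' \code{degenerate = TRUE}.
#'
#' @param a,b numeric metric vectors.
#' @param keysA,keysB pairing keys aligning the vectors; every key must
#'   match one-to-one.
#' @return list(t, df, p, meanOfDifferences, n, degenerate).
#' @export
pairedComparison <- function(a, b, keysA = seq_along(a),
                             keysB = seq_along(b)) {
  stopifnot2(length(a) == length(keysA) && length(b) == length(keysB),
             "keys must align with values")
  idx <- match(keysA, keysB)
  if (anyNA(idx)) {
    missing <- keysA[is.na(idx)]
    stop("unmatched pairing keys: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  d <- a - b[idx]
  keep <- !is.na(d)
  d <- d[keep]
  n <- length(d)
  stopifnot2(n >= 2, "need at least 2 complete pairs")
  mod <- mean(d)
  if (stats::sd(d) == 0) {
    return(list(t = NA_real_, df = n - 1L, p = NA_real_,
                meanOfDifferences = mod, n = n, degenerate = TRUE))
  }
  tt <- stats::t.test(d)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, meanOfDifferences = mod, n = n, degenerate = FALSE)
}

#' Mean pairwise percentage contrast
#'
#' Mean over pairs of 100 x (a - b) / b, the "percent higher" reading of a
#' paired contrast. Pairs with a zero denominator are excluded with a
#' warning.
#'
#' @inheritParams pairedComparison
#' @return mean pairwise percentage difference (scalar).
#' @export
percentageContrast <- function(a, b, keysA = seq_along(a),
                               keysB = seq_along(b)) {
  idx <- match(keysA, keysB)
  stopifnot2(!anyNA(idx), "unmatched pairing keys")
  bb <- b[idx]
  bad <- !is.na(bb) & bb == 0
  if (any(bad))
    warning(sprintf("%d pair(s) with zero denominator excluded", sum(bad)))
  keep <- !bad & !is.na(a) & !is.na(bb)
  mean(100 * (a[keep] - bb[keep]) / bb[keep])
}

#' Configuration contrast table for an experiment
#'
#' Convenience wrapper: for one scale, pairs random against continuous
#' treatments with matching extent, intensity, and replicate (partial
#' extents only — at 100\% extent the configurations coincide) and returns
#' the paired t-test and percentage contrast for a metric.
#'
#' @param metrics a metric table from \code{\link{metricTable}} for one
#'   scale.
#' @param metric metric column name (default "skew").
#' @param transform transformation applied before the t-test (default
#'   arcsine; the percentage contrast always uses raw values).
#' @return list(test, percent): the \code{\link{pairedComparison}} result on
#'   transformed values and the raw \code{\link{percentageContrast}}.
#' @export
configurationContrast <- function(metrics, metric = "skew",
                                  transform = arcsineTransform) {
  part <- metrics[metrics$extent < 1, ]
  rnd <- part[part$configuration == "random", ]
  cnt <- part[part$configuration == "continuous", ]
  keyOf <- function(d) paste(d$extent, d$intensity, d$replicate)
  vr <- rnd[[metric]]; vc <- cnt[[metric]]
  test <- pairedComparison(transform(vr), transform(vc),
                           keyOf(rnd), keyOf(cnt))
  pct <- percentageContrast(vr, vc, keyOf(rnd), keyOf(cnt))
  list(test = test, percent = pct)
}
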