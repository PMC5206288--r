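#' Mean unsigned error
#'
#' @param pred,ref Equal-length numeric vectors (length >= 1).
#' @return Mean of |pred - ref| in the native units.
#' @export
mue <- function(pred, ref) {
  if (length(pred) == 0L) stop("empty input")
  if (length(pred) != length(ref)) stop("length mismatch")
  mean(abs(pred - ref))
}

#' Determination coefficient
#'
#' By default the squared Pearson correlation between predictions and
#' reference (sign-blind: a perfect anti-correlation also scores 1). The
#' regression-style alternative 1 - SS_res/SS_tot is available with
#' `method = "ss"`.
#'
#' @param pred,ref Equal-length numeric vectors, length >= 3, each with
#'   nonzero variance.
#' @param method "pearson" (default) or "ss".
#' @return R^2; in [0, 1] for "pearson".
#' @export
r_squared <- function(pred, ref, method = c("pearson", "ss")) {
  method <- match.arg(method)
  if (length(pred) != length(ref)) stop("length mismatch")
  if (length(pred) < 3L) stop("need at least 3 points")
  if (stats::var(pred) == 0 || stats::var(ref) == 0) {
    stop("zero variance input")
  }
  if (method == "pearson") {
    stats::cor(pred, ref)^2
  } else {
    1 - sum((ref - pred)^2) / sum((ref - mean(ref))^2)
  }
}

#' Mean unsigned deviation between two prediction sets
#'
#' Like [mue()] but between two computed datasets, with no experimental
#' reference implied. Symmetric in its arguments.
#'
#' @param a,b Equal-length numeric vectors.
#' @return Mean of |a - b|.
#' @export
mud <- function(a, b) {
  if (length(a) != length(b)) stop("length mismatch")
  mean(abs(a - b))
}

#' Bootstrap distribution of benchmark metrics
#'
#' Parametric bootstrap over prediction uncertainty: each replicate draws
#' every prediction from Normal(pred_i, pred_err_i), recomputes the metrics
#' against the reference, and the resulting distributions are summarized by
#' their mean and empirical 2.5/97.5 percentiles (a 95 percent interval
#' reported as z- < mu < z+). Only predictions are perturbed unless
#' reference uncertainties are supplied and `perturb_ref = TRUE`.
#' Deterministic for a fixed seed; the caller's RNG state is restored.
#'
#' @param pred Predicted values.
#' @param pred_err Per-value standard deviations (>= 0).
#' @param ref Reference values.
#' @param n_samples Number of bootstrap replicates (>= 100; default 10000).
#' @param seed RNG seed.
#' @param metrics Character subset of c("MUE", "R2").
#' @param ref_err Optional reference standard deviations.
#' @param perturb_ref Whether to also perturb the reference values.
#' @param r2_method Passed to [r_squared()].
#' @return A data.frame (one row per metric) with columns `metric`,
#'   `estimate` (deterministic point value), `mean`, `ci_low`, `ci_high`,
#'   `n_samples`, `seed`.
#' @export
bootstrap_metrics <- function(pred, pred_err, ref, n_samples = 10000L,
                              seed = 1L, metrics = c("MUE", "R2"),
                              ref_err = NULL, perturb_ref = FALSE,
                              r2_method = "pearson") {
  n <- length(pred)
  if (length(ref) != n || length(pred_err) != n) stop("length mismatch")
  if (any(pred_err < 0)) stop("pred_err must be >= 0")
  if (n_samples < 100L) stop("n_samples must be >= 100")
  metrics <- match.arg(metrics, c("MUE", "R2"), several.ok = TRUE)

  draws <- with_seed(seed, {
    P <- matrix(stats::rnorm(n_samples * n,
                             mean = rep(pred, each = n_samples),
                             sd = rep(pred_err, each = n_samples)),
                nrow = n_samples)
    Rf <- if (perturb_ref && !is.null(ref_err)) {
      matrix(stats::rnorm(n_samples * n,
                          mean = rep(ref, each = n_samples),
                          sd = rep(ref_err, each = n_samples)),
             nrow = n_samples)
    } else {
      matrix(ref, nrow = n_samples, ncol = n, byrow = TRUE)
    }
    list(P = P, Rf = Rf)
  })
  P <- draws$P; Rf <- draws$Rf

  rows <- lapply(metrics, function(m) {
    if (m == "MUE") {
      point <- mue(pred, ref)
      vals <- rowMeans(abs(P - Rf))
    } else {
      point <- r_squared(pred, ref, method = r2_method)
      if (r2_method == "pearson") {
        Pc <- P - rowMeans(P)
        Rc <- Rf - rowMeans(Rf)
        num <- rowSums(Pc * Rc)
        vals <- num^2 / (rowSums(Pc^2) * rowSums(Rc^2))
      } else {
        vals <- 1 - rowSums((Rf - P)^2) /
          rowSums((Rf - rowMeans(Rf))^2)
      }
    }
    ci <- unname(stats::quantile(vals, c(0.025, 0.975), type = 7))
    data.frame(metric = m, estimate = point, mean = mean(vals),
               ci_low = ci[1L], ci_high = ci[2L],
               n_samples = n_samples, seed = seed,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Format a metric report line
#'
#' Renders the z- < mu < z+ convention used for 95 percent bootstrap
#' intervals.
#'
#' @param report One row of a [bootstrap_metrics()] result.
#' @param digits Digits after the decimal point.
#' @return A character string.
#' @export
format_metric_report <- function(report, digits = 2) {
  sprintf(paste0("%s = %.", digits, "f < %.", digits, "f < %.",
                 digits, "f"),
          report$metric, report$ci_low, report$mean, report$ci_high)
}
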