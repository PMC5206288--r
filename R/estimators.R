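#' Free-energy estimate container
#'
#' @param delta_g Free-energy difference in kcal/mol.
#' @param uncertainty One-standard-error uncertainty in kcal/mol (>= 0).
#' @param method Estimator tag, one of "zwanzig", "mbar", "run-pair",
#'   "assembled", "derived".
#' @return An object of class `free_energy_estimate`.
#' @export
free_energy_estimate <- function(delta_g, uncertainty = 0,
                                 method = "derived") {
  if (!is.finite(delta_g)) stop("delta_g must be finite")
  if (!is.finite(uncertainty) || uncertainty < 0) {
    stop("uncertainty must be finite and >= 0")
  }
  structure(list(delta_g = delta_g, uncertainty = uncertainty,
                 method = method),
            class = "free_energy_estimate")
}

#' @export
print.free_energy_estimate <- function(x, ...) {
  cat(sprintf("dG = %.4f +/- %.4f kcal/mol [%s]\n",
              x$delta_g, x$uncertainty, x$method))
  invisible(x)
}

as_fee <- function(x, method = "derived") {
  if (inherits(x, "free_energy_estimate")) return(x)
  if (is.numeric(x) && length(x) == 1L) return(free_energy_estimate(x, 0, method))
  stop("expected a free_energy_estimate or a single number")
}

#' Zwanzig (exponential-averaging) free-energy perturbation
#'
#' One-sided free-energy perturbation:
#' dG = -beta^-1 ln < exp(-beta dU) >, evaluated through log-sum-exp so that
#' large perturbation energies cannot overflow. The uncertainty is the
#' delta-method (asymptotic) standard error of the exponential average,
#' which assumes uncorrelated samples; subsample correlated series first
#' (see [subsample_uncorrelated()]).
#'
#' @param delta_u Numeric vector of perturbation energies U_target - U_ref
#'   in kcal/mol, sampled from the reference ensemble.
#' @param state A [thermo_state()].
#' @return A [free_energy_estimate()] with method "zwanzig".
#' @examples
#' zwanzig_fep(c(0, 0, 0))                    # identity perturbation: 0
#' zwanzig_fep(rnorm(1000, mean = 2, sd = 1)) # ~ 2 - beta/2
#' @export
zwanzig_fep <- function(delta_u, state = thermo_state()) {
  state <- as_thermo_state(state)
  if (length(delta_u) == 0L) stop("no samples")
  if (!all(is.finite(delta_u))) stop("delta_u must be finite")
  b <- state$beta
  x <- -b * delta_u
  n <- length(x)
  dg <- -(logsumexp(x) - log(n)) / b
  # delta method on X = exp(-beta dU); scale-invariant, so work with the
  # max-shifted weights to stay in range
  w <- exp(x - max(x))
  se <- if (n > 1L) sqrt(stats::var(w) / (n * mean(w)^2)) / b else 0
  free_energy_estimate(dg, se, "zwanzig")
}

#' Reduced-potential matrix for multistate estimation
#'
#' @param u K x N matrix of reduced potentials: `u[k, n]` is beta * U_k
#'   evaluated at sample n, for every thermodynamic state k. Samples are
#'   pooled over states; `n_k[k]` of them were drawn from state k.
#' @param n_k Integer vector of per-state sample counts, `sum(n_k) == ncol(u)`.
#' @return An object of class `reduced_potential_matrix`.
#' @export
reduced_potential_matrix <- function(u, n_k) {
  u <- as.matrix(u)
  if (!all(is.finite(u))) stop("reduced potentials must be finite")
  if (length(n_k) != nrow(u)) stop("length(n_k) must equal nrow(u)")
  if (any(n_k < 0)) stop("n_k must be >= 0")
  if (sum(n_k) != ncol(u)) stop("sum(n_k) must equal ncol(u)")
  structure(list(u = u, n_k = as.numeric(n_k)),
            class = "reduced_potential_matrix")
}

#' Multistate Bennett acceptance ratio (MBAR) free energies
#'
#' Solves the MBAR self-consistent equations
#' f_i = -ln sum_n exp(-u_i(x_n)) / sum_k N_k exp(f_k - u_k(x_n))
#' by direct iteration with log-sum-exp evaluation, to a residual below
#' `tol` on the dimensionless free energies (max 'max_iter' sweeps).
#' Uncertainties come from the asymptotic covariance of the estimator,
#' computed from the N x K weight matrix via its singular value
#' decomposition and a pseudo-inverse.
#'
#' @param m A [reduced_potential_matrix()], or a K x N matrix together with
#'   `n_k`.
#' @param n_k Per-state sample counts when `m` is a plain matrix.
#' @param state A [thermo_state()] used to convert the dimensionless free
#'   energies to kcal/mol.
#' @param tol Convergence tolerance on the dimensionless free energies.
#' @param max_iter Maximum number of self-consistent sweeps.
#' @return A data.frame with one row per state: `state`, `delta_g`
#'   (kcal/mol, relative to state 1), `uncertainty` (kcal/mol), `method`.
#'   The dimensionless free energies are attached as attribute `"f"`, the
#'   final residual as `"residual"`.
#' @export
mbar_free_energies <- function(m, n_k = NULL, state = thermo_state(),
                               tol = 1e-8, max_iter = 10000L) {
  if (!inherits(m, "reduced_potential_matrix")) {
    m <- reduced_potential_matrix(m, n_k)
  }
  state <- as_thermo_state(state)
  u <- m$u
  nk <- m$n_k
  K <- nrow(u)
  N <- ncol(u)
  if (K < 2L) stop("MBAR needs at least 2 states")
  if (any(nk == 0) && all(nk == 0)) stop("no samples")

  log_nk <- ifelse(nk > 0, log(nk), -Inf)
  f <- numeric(K)
  resid <- Inf
  for (it in seq_len(max_iter)) {
    # log denominator per sample: logsumexp_k(log N_k + f_k - u_kn)
    M <- (log_nk + f) - u           # K x N, column-wise recycling over rows
    cmax <- M[1L, ]
    if (K > 1L) for (k in 2L:K) cmax <- pmax(cmax, M[k, ])
    log_denom <- cmax + log(colSums(exp(sweep(M, 2L, cmax, "-"))))

    B <- -u - matrix(log_denom, K, N, byrow = TRUE)
    rmax <- apply(B, 1L, max)
    f_new <- -(rmax + log(rowSums(exp(B - rmax))))
    f_new <- f_new - f_new[1L]
    resid <- max(abs(f_new - f))
    f <- f_new
    if (resid < tol) break
  }
  if (resid >= tol) {
    stop(sprintf("MBAR did not converge in %d iterations (residual %.3e)",
                 max_iter, resid))
  }

  # weight matrix W[n, i] = exp(f_i - u_in) / sum_k N_k exp(f_k - u_kn)
  M <- (log_nk + f) - u
  cmax <- M[1L, ]
  if (K > 1L) for (k in 2L:K) cmax <- pmax(cmax, M[k, ])
  log_denom <- cmax + log(colSums(exp(sweep(M, 2L, cmax, "-"))))
  W <- t(exp(sweep(f - u, 2L, log_denom, "-")))  # N x K

  theta <- mbar_covariance(W, nk)
  var0i <- theta[1L, 1L] + diag(theta) - 2 * theta[1L, ]
  var0i[var0i < 0] <- 0  # numerical noise near zero
  kT <- 1 / state$beta
  data.frame(
    state = seq_len(K),
    delta_g = f * kT,
    uncertainty = sqrt(var0i) * kT,
    method = "mbar",
    stringsAsFactors = FALSE
  ) -> out
  attr(out, "f") <- f
  attr(out, "residual") <- resid
  attr(out, "iterations") <- it
  out
}

# Asymptotic covariance of the dimensionless free energies from the MBAR
# weight matrix: Theta = V S (I - S V' N V S)^+ S V' with W = U S V'.
mbar_covariance <- function(W, nk) {
  sv <- svd(W)
  S <- diag(sv$d, nrow = length(sv$d))
  V <- sv$v
  K <- ncol(W)
  inner <- diag(K) - S %*% t(V) %*% (nk * V) %*% S
  V %*% S %*% MASS::ginv(inner) %*% S %*% t(V)
}

#' Two-run error rule
#'
#' Combines two independent repeats of the same free-energy calculation:
#' the estimate is their mean and the uncertainty sigma/sqrt(n) with n = 2
#' and sigma the sample standard deviation (n - 1 denominator), which
#' reduces to |g1 - g2| / 2.
#'
#' @param g1,g2 Free energies from the two runs, kcal/mol.
#' @return A [free_energy_estimate()] with method "run-pair".
#' @examples
#' run_pair_error(1.0, 2.0)  # 1.5 +/- 0.5
#' @export
run_pair_error <- function(g1, g2) {
  if (!is.finite(g1) || !is.finite(g2)) stop("run values must be finite")
  free_energy_estimate(mean(c(g1, g2)), abs(g1 - g2) / 2, "run-pair")
}

#' Statistical inefficiency and uncorrelated subsampling
#'
#' Estimates the statistical inefficiency g = 1 + 2 sum_t (1 - t/N) C(t)
#' of a scalar time series, where C(t) is the normalized autocorrelation
#' function, accumulating the triangle-windowed sum until the first
#' non-positive autocovariance. A constant series has g = 1 by convention.
#' Effectively independent samples are taken every ceiling(g) steps.
#'
#' @param series Numeric time series, length >= 2.
#' @return A list with `g` (statistical inefficiency, >= 1), `stride`
#'   (ceiling(g)) and `indices` (positions of the retained samples).
#' @examples
#' subsample_uncorrelated(rnorm(1000))$g  # ~ 1 for white noise
#' @export
subsample_uncorrelated <- function(series) {
  n <- length(series)
  if (n < 2L) stop("series must have length >= 2")
  if (!all(is.finite(series))) stop("series must be finite")
  x <- series - mean(series)
  c0 <- mean(x^2)
  g <- 1
  if (c0 > 0) {
    for (t in seq_len(n - 1L)) {
      ct <- sum(x[seq_len(n - t)] * x[(t + 1L):n]) / (n - t) / c0
      if (ct <= 0) break
      g <- g + 2 * (1 - t / n) * ct
    }
  }
  g <- max(g, 1)
  stride <- as.integer(ceiling(g))
  list(g = g, stride = stride, indices = seq.int(1L, n, by = stride))
}
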