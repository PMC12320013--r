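# Core second-order causality (SOC) estimator: windowed covariances,
# Gaussian mutual information via log-determinants, and the sign-of-C
# decision rule for instantaneous causal direction.

#' Standardize a time series to zero mean and unit variance
#'
#' Uses the population convention (divisor = length, not length - 1), so the
#' output has sample variance exactly 1 under that divisor.
#'
#' @param series Numeric vector, length >= 2.
#' @return Numeric vector of the same length with mean 0 and population
#'   variance 1.
#' @export
#' @examples
#' standardize(c(1, 2, 3))
standardize <- function(series) {
  if (!is.numeric(series) || length(series) < 2) {
    stop("`series` must be a numeric vector of length >= 2")
  }
  if (any(!is.finite(series))) stop("`series` contains non-finite values")
  mu <- mean(series)
  v <- mean((series - mu)^2)
  if (v <= 0) stop("zero-variance input: series is constant")
  (series - mu) / sqrt(v)
}

#' Construct a window set from a single long series
#'
#' Cuts a stationary series into fixed-length windows starting at offsets
#' 0, stride, 2*stride, ...; a trailing partial window is discarded. The
#' rows of the result are the empirical "instances" over which window
#' covariance matrices are estimated. Use identical `window_length` and
#' `stride` for a paired variable so rows align in time.
#'
#' @param series Numeric vector.
#' @param window_length Window length L (number of time points per row).
#' @param stride Offset between consecutive window starts; `stride = L`
#'   gives non-overlapping windows.
#' @return A `window_set`: a list with `values` (m x L matrix),
#'   `window_length` and `n_instances`.
#' @export
build_window_set <- function(series, window_length, stride = window_length) {
  if (window_length < 1 || stride < 1) stop("window_length and stride must be >= 1")
  n <- length(series)
  starts <- seq.int(1L, by = stride, length.out = max(0L, (n - window_length) %/% stride + 1L))
  starts <- starts[starts + window_length - 1L <= n]
  if (length(starts) < 2L) {
    stop("insufficient data: fewer than 2 complete windows (n = ", n,
         ", L = ", window_length, ", stride = ", stride, ")")
  }
  idx <- outer(starts, 0:(window_length - 1L), `+`)
  window_set(matrix(series[idx], nrow = length(starts)))
}

#' Create a window set from a matrix of instances
#'
#' @param values Numeric matrix, rows = instances, columns = time points.
#' @return A `window_set` object.
#' @export
window_set <- function(values) {
  values <- as.matrix(values)
  if (!is.numeric(values) || any(!is.finite(values))) {
    stop("window values must be finite numeric")
  }
  if (nrow(values) < 2L) stop("a window set needs at least 2 instances")
  structure(
    list(values = values, window_length = ncol(values), n_instances = nrow(values)),
    class = "window_set"
  )
}

#' @export
print.window_set <- function(x, ...) {
  cat("window_set:", x$n_instances, "instances x", x$window_length, "time points\n")
  invisible(x)
}

check_aligned <- function(wa, wb) {
  stopifnot(inherits(wa, "window_set"), inherits(wb, "window_set"))
  if (wa$window_length != wb$window_length || wa$n_instances != wb$n_instances) {
    stop("window sets have mismatched shapes")
  }
}

#' Estimate the shared regression coefficient of an instantaneous pair
#'
#' The instantaneous model `y = alpha * x + d` (and its reverse) share one
#' regression coefficient when both variables are standardized; the pooled
#' lag-0 estimate is the sample covariance of all aligned (x, y) window
#' entries divided by the pooled variance of the x entries. On standardized
#' input this equals the pooled lag-0 correlation.
#'
#' @param wx,wy Aligned `window_set`s of the two variables.
#' @return Scalar estimate of the coupling coefficient.
#' @export
estimate_alpha <- function(wx, wy) {
  check_aligned(wx, wy)
  x <- as.vector(wx$values); y <- as.vector(wy$values)
  vx <- mean((x - mean(x))^2)
  if (vx <= 0) stop("zero-variance input in `wx`")
  mean((x - mean(x)) * (y - mean(y))) / vx
}

pooled_correlation <- function(wx, wy) {
  x <- as.vector(wx$values); y <- as.vector(wy$values)
  xc <- x - mean(x); yc <- y - mean(y)
  mean(xc * yc) / sqrt(mean(xc^2) * mean(yc^2))
}

#' Residual windows of the instantaneous regression
#'
#' Entrywise `effect - alpha * cause`; the residual is deliberately not
#' re-standardized, its covariance enters the criterion as-is.
#'
#' @param wcause,weffect Aligned `window_set`s.
#' @param alpha Regression coefficient.
#' @return A `window_set` of residuals.
#' @export
residual_windows <- function(wcause, weffect, alpha) {
  check_aligned(wcause, weffect)
  window_set(weffect$values - alpha * wcause$values)
}

toeplitz_project <- function(S) {
  L <- nrow(S)
  d <- row(S) - col(S)
  means <- tapply(S, abs(d), mean)
  matrix(means[as.character(abs(d))], L, L)
}

make_cov_estimate <- function(S, ridge, toeplitz) {
  if (toeplitz) S <- toeplitz_project(S)
  S <- (S + t(S)) / 2
  ridge_abs <- ridge * mean(diag(S))
  if (ridge > 0) S <- S + diag(ridge_abs, nrow(S))
  structure(
    list(matrix = S, ridge_used = ridge_abs, toeplitz_projected = toeplitz),
    class = "covariance_estimate"
  )
}

#' Window covariance matrix of one variable
#'
#' L x L sample covariance across window instances, population divisor m.
#' An optional Toeplitz projection (averaging along diagonals) enforces
#' stationarity; a relative ridge `ridge * mean(diag)` is added to the
#' diagonal for numerical stability.
#'
#' @param ws A `window_set`.
#' @param ridge Relative ridge coefficient (0 disables).
#' @param toeplitz Logical; average along diagonals before the ridge.
#' @return A `covariance_estimate` with fields `matrix`, `ridge_used`,
#'   `toeplitz_projected`.
#' @export
window_covariance <- function(ws, ridge = 0, toeplitz = FALSE) {
  stopifnot(inherits(ws, "window_set"))
  V <- ws$values
  Vc <- sweep(V, 2L, colMeans(V))
  S <- crossprod(Vc) / nrow(V)
  make_cov_estimate(S, ridge, toeplitz)
}

#' Joint covariance of two aligned window sets
#'
#' 2L x 2L covariance of the row-wise concatenation `[a; b]`, same divisor
#' and ridge rule as [window_covariance()].
#'
#' @param wa,wb Aligned `window_set`s.
#' @inheritParams window_covariance
#' @return A `covariance_estimate` of dimension 2L.
#' @export
joint_covariance <- function(wa, wb, ridge = 0) {
  check_aligned(wa, wb)
  window_covariance(window_set(cbind(wa$values, wb$values)), ridge = ridge)
}

logdet_psd <- function(M) {
  R <- tryCatch(chol(M), error = function(e) NULL)
  if (is.null(R)) return(NA_real_)
  2 * sum(log(diag(R)))
}

#' Differential entropy of a Gaussian with the given covariance
#'
#' `h = 1/2 logdet(cov) + (dim/2) (1 + log 2*pi)` nats, with the
#' log-determinant computed by Cholesky factorization.
#'
#' @param cov A `covariance_estimate` or positive-definite matrix.
#' @return Entropy in nats.
#' @export
gaussian_entropy <- function(cov) {
  M <- if (inherits(cov, "covariance_estimate")) cov$matrix else as.matrix(cov)
  ld <- logdet_psd(M)
  if (is.na(ld)) stop("covariance matrix is numerically singular (not PD)")
  0.5 * ld + (nrow(M) / 2) * (1 + log(2 * pi))
}

#' Gaussian mutual information between two window variables
#'
#' Plug-in estimate `I = 1/2 [logdet cov(a) + logdet cov(b) -
#' logdet cov([a; b])]` in nats; the entropy constants cancel. Nonnegative
#' (up to roundoff) for any PSD sample covariances by Fischer's inequality.
#'
#' @param wa,wb Aligned `window_set`s.
#' @param ridge Relative ridge applied to all three covariance estimates.
#' @return Mutual information in nats.
#' @export
gaussian_mi <- function(wa, wb, ridge = 1e-6) {
  check_aligned(wa, wb)
  la <- logdet_psd(window_covariance(wa, ridge = ridge)$matrix)
  lb <- logdet_psd(window_covariance(wb, ridge = ridge)$matrix)
  lab <- logdet_psd(joint_covariance(wa, wb, ridge = ridge)$matrix)
  if (anyNA(c(la, lb, lab))) stop("singular covariance after ridge; increase `ridge`")
  0.5 * (la + lb - lab)
}

#' Configuration for the SOC decision pipeline
#'
#' @param window_length Window length L (time points per window instance).
#' @param stride Offset between window starts; defaults to `window_length`
#'   (non-overlapping windows, limiting inter-window dependence).
#' @param ridge Relative diagonal ridge for covariance estimates; escalated
#'   tenfold (up to `ridge_max`) if a Cholesky factorization fails.
#' @param ridge_max Upper bound of the ridge escalation.
#' @param toeplitz Average window covariances along diagonals (stationarity
#'   projection); off by default.
#' @param tie_tol Criterion values with `|C| <= tie_tol` give direction
#'   `"undetermined"`.
#' @param m_min Minimum number of complete windows required.
#' @return A list of class `soc_config`.
#' @export
soc_config <- function(window_length = 5, stride = window_length,
                       ridge = 1e-6, ridge_max = 1e-2, toeplitz = FALSE,
                       tie_tol = 1e-12,
                       m_min = max(20, 10 * window_length)) {
  stopifnot(window_length >= 1, stride >= 1, ridge >= 0, tie_tol >= 0)
  structure(list(window_length = window_length, stride = stride,
                 ridge = ridge, ridge_max = ridge_max, toeplitz = toeplitz,
                 tie_tol = tie_tol, m_min = m_min),
            class = "soc_config")
}

direction_from_C <- function(C, tie_tol) {
  if (!is.finite(C)) stop("criterion is not finite")
  if (C < -tie_tol) "x_to_y" else if (C > tie_tol) "y_to_x" else "undetermined"
}

decision_result <- function(criterion_C, alpha_hat, mi_x_d, mi_y_e, method,
                            tie_tol, config = NULL) {
  structure(
    list(criterion_C = criterion_C,
         direction = direction_from_C(criterion_C, tie_tol),
         alpha_hat = alpha_hat, mi_x_d = mi_x_d, mi_y_e = mi_y_e,
         method = method, config = config),
    class = "soc_decision"
  )
}

#' @export
print.soc_decision <- function(x, ...) {
  cat(sprintf("%s decision: %s\n", x$method, x$direction))
  cat(sprintf("  criterion C = %.6g nats (negative => x -> y)\n", x$criterion_C))
  cat(sprintf("  alpha_hat = %.4f, I(x,d) = %.6g, I(y,e) = %.6g\n",
              x$alpha_hat, x$mi_x_d, x$mi_y_e))
  invisible(x)
}

as_window_pair <- function(x, y, config) {
  if (is.matrix(x) || is.matrix(y)) {
    # multi-instance mode: rows are instances; standardize each time index
    # across instances
    x <- as.matrix(x); y <- as.matrix(y)
    if (!all(dim(x) == dim(y))) stop("x and y instance matrices must share shape")
    std_cols <- function(M) {
      mu <- colMeans(M)
      sd <- sqrt(colMeans(sweep(M, 2L, mu)^2))
      if (any(sd <= 0)) stop("zero-variance input: constant time index across instances")
      sweep(sweep(M, 2L, mu), 2L, sd, `/`)
    }
    list(wx = window_set(std_cols(x)), wy = window_set(std_cols(y)))
  } else {
    if (length(x) != length(y)) stop("x and y must have equal length")
    xs <- standardize(x); ys <- standardize(y)
    list(wx = build_window_set(xs, config$window_length, config$stride),
         wy = build_window_set(ys, config$window_length, config$stride))
  }
}

soc_criterion_from_windows <- function(wx, wy, config) {
  alpha <- pooled_correlation(wx, wy)
  wd <- residual_windows(wx, wy, alpha)   # d = y - alpha x  (model x -> y)
  we <- residual_windows(wy, wx, alpha)   # e = x - alpha y  (model y -> x)
  ridge <- config$ridge
  repeat {
    ld <- c(
      x  = logdet_psd(window_covariance(wx, ridge, config$toeplitz)$matrix),
      d  = logdet_psd(window_covariance(wd, ridge, config$toeplitz)$matrix),
      xd = logdet_psd(joint_covariance(wx, wd, ridge)$matrix),
      y  = logdet_psd(window_covariance(wy, ridge, config$toeplitz)$matrix),
      e  = logdet_psd(window_covariance(we, ridge, config$toeplitz)$matrix),
      ye = logdet_psd(joint_covariance(wy, we, ridge)$matrix)
    )
    if (!anyNA(ld)) break
    ridge <- ifelse(ridge > 0, ridge * 10, 1e-6)
    if (ridge > config$ridge_max) {
      stop("covariance singular beyond ridge repair (ridge > ", config$ridge_max, ")")
    }
  }
  mi_x_d <- 0.5 * (ld[["x"]] + ld[["d"]] - ld[["xd"]])
  mi_y_e <- 0.5 * (ld[["y"]] + ld[["e"]] - ld[["ye"]])
  list(C = 2 * mi_x_d - 2 * mi_y_e, alpha = alpha,
       mi_x_d = mi_x_d, mi_y_e = mi_y_e, ridge = ridge)
}

#' Decide the instantaneous causal direction by second-order statistics
#'
#' Implements the SOC pipeline: standardize both variables, cut them into
#' time-aligned windows, estimate the shared coupling coefficient, form the
#' residuals of the two candidate models `y = alpha x + d` and
#' `x = alpha y + e`, and compare the Gaussian mutual informations
#' `C = 2 I(x, d) - 2 I(y, e)`. A negative criterion selects `x -> y`
#' (the residual of the correct model is the more independent one), a
#' positive criterion selects `y -> x`.
#'
#' @param x,y Numeric vectors of equal length (one long stationary series
#'   each), or matrices of aligned instances (rows = instances, columns =
#'   time points) in which case each time index is standardized across
#'   instances.
#' @param config A [soc_config()].
#' @return A `soc_decision` with the criterion value (nats), the inferred
#'   direction, the coupling estimate and both mutual informations.
#' @export
#' @examples
#' set.seed(1)
#' x <- as.numeric(arima.sim(list(ar = 0.8), 4000))
#' y <- 0.7 * x + as.numeric(arima.sim(list(ar = 0.2), 4000))
#' soc_decide(x, y)
soc_decide <- function(x, y, config = soc_config()) {
  stopifnot(inherits(config, "soc_config"))
  w <- as_window_pair(x, y, config)
  if (w$wx$n_instances < config$m_min) {
    stop("insufficient data: ", w$wx$n_instances, " windows < m_min = ", config$m_min)
  }
  res <- soc_criterion_from_windows(w$wx, w$wy, config)
  decision_result(res$C, res$alpha, res$mi_x_d, res$mi_y_e,
                  method = "soc", tie_tol = config$tie_tol, config = config)
}

ar1_toeplitz <- function(coef, L) {
  stats::toeplitz(coef^(0:(L - 1)))
}

#' Analytic population SOC criterion for the AR(1) generative model
#'
#' For a standardized AR(1) regressor with coefficient `r`, AR(1) noise
#' with coefficient `noise_coef`, and instantaneous coupling `alpha`
#' (`y = alpha x + d`), all window covariances are closed-form Toeplitz
#' matrices; this computes the exact population value of the decision
#' criterion for windows of length `L`. It is the infinite-data limit of
#' [soc_decide()] and is 0 exactly when `r == noise_coef` (the
#' identifiability boundary: direction is recoverable only if regressor
#' and noise have different autocorrelation functions).
#'
#' @param r AR(1) coefficient of the regressor.
#' @param alpha Instantaneous coupling coefficient.
#' @param noise_coef AR(1) coefficient of the model noise.
#' @param L Window length.
#' @return List with `C`, `mi_x_d`, `mi_y_e` and the population
#'   standardized coupling `alpha_pop`.
#' @export
soc_population_criterion <- function(r, alpha, noise_coef = 0.2, L = 5) {
  stopifnot(abs(r) < 1, abs(noise_coef) < 1, L >= 1)
  vx <- 1 / (1 - r^2)
  vd <- 1 / (1 - noise_coef^2)
  vy <- alpha^2 * vx + vd
  rho <- alpha * sqrt(vx) / sqrt(vy)        # population corr(x, y)
  Rx <- ar1_toeplitz(r, L)
  Rd <- ar1_toeplitz(noise_coef, L)
  Cxx <- Rx
  Cyy <- (alpha^2 * vx * Rx + vd * Rd) / vy
  Cxy <- rho * Rx
  # d = y_std - rho x_std ; e = x_std - rho y_std
  Cdd <- Cyy - 2 * rho * Cxy + rho^2 * Cxx
  Cxd <- Cxy - rho * Cxx
  Cee <- Cxx - 2 * rho * Cxy + rho^2 * Cyy
  Cye <- Cxy - rho * Cyy
  mi <- function(Caa, Cbb, Cab) {
    J <- rbind(cbind(Caa, Cab), cbind(t(Cab), Cbb))
    0.5 * (logdet_psd(Caa) + logdet_psd(Cbb) - logdet_psd(J))
  }
  mi_x_d <- mi(Cxx, Cdd, Cxd)
  mi_y_e <- mi(Cyy, Cee, Cye)
  list(C = 2 * mi_x_d - 2 * mi_y_e, mi_x_d = mi_x_d, mi_y_e = mi_y_e,
       alpha_pop = rho)
}
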