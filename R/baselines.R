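# Reference pairwise direction detectors: pairwise LiNGAM (non-Gaussianity
# likelihood ratio) and bivariate Granger causality with AIC order selection.

#' Pairwise LiNGAM direction decision
#'
#' Likelihood-ratio statistic for the linear non-Gaussian acyclic model on
#' a standardized pair: `R = rho_hat * mean(x g(y) - g(x) y)` with
#' `g = tanh` (the nonlinearity suited to sparse/super-Gaussian sources);
#' `R > 0` selects `x -> y`. Requires non-Gaussian disturbances — on
#' jointly Gaussian data the statistic carries no directional information
#' and decisions are at chance. The `criterion_C` field stores `-R` so the
#' sign convention matches [soc_decide()] (negative means `x -> y`).
#'
#' @param x,y Numeric vectors of equal length (>= 50).
#' @param variant `"tanh"` (default) or the `"cumulant"` form
#'   `rho_hat * mean(x^3 y - x y^3)` for sensitivity checks.
#' @param tie_tol Tie tolerance on the statistic.
#' @return A `soc_decision` with `method = "pwlingam"`.
#' @export
pwlingam_decide <- function(x, y, variant = c("tanh", "cumulant"),
                            tie_tol = 1e-12) {
  variant <- match.arg(variant)
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 50) stop("insufficient data: need at least 50 samples")
  xs <- standardize(x); ys <- standardize(y)
  rho <- mean(xs * ys)
  R <- if (variant == "tanh") {
    rho * mean(xs * tanh(ys) - tanh(xs) * ys)
  } else {
    rho * mean(xs^3 * ys - xs * ys^3)
  }
  decision_result(-R, alpha_hat = rho, mi_x_d = NA_real_, mi_y_e = NA_real_,
                  method = "pwlingam", tie_tol = tie_tol,
                  config = list(variant = variant))
}

lag_matrix <- function(z, p, t_start, t_end) {
  sapply(1:p, function(k) z[(t_start - k):(t_end - k)])
}

fit_var2 <- function(xs, ys, p, t_start) {
  n <- length(xs)
  t_end <- n
  Y <- cbind(xs[t_start:t_end], ys[t_start:t_end])
  Z <- cbind(1, lag_matrix(xs, p, t_start, t_end), lag_matrix(ys, p, t_start, t_end))
  B <- tryCatch(qr.solve(Z, Y), error = function(e) NULL)
  if (is.null(B)) return(NULL)
  E <- Y - Z %*% B
  n_eff <- nrow(Y)
  Sigma <- crossprod(E) / n_eff
  list(Sigma = Sigma, resid = E, n_eff = n_eff, p = p,
       n_params = ncol(Z) * 2)
}

restricted_resid_var <- function(target, own, p, t_start) {
  n <- length(target)
  Y <- target[t_start:n]
  Z <- cbind(1, lag_matrix(own, p, t_start, n))
  b <- qr.solve(Z, Y)
  mean((Y - Z %*% b)^2)
}

#' Bivariate Granger-causality direction decision
#'
#' Fits a bivariate VAR by per-equation OLS (intercept included, series
#' standardized first), selecting the order `p` in `1..p_max` that
#' minimizes the AIC of the full model's Gaussian log-likelihood over a
#' common estimation sample. The Granger statistic per direction is the
#' log ratio of restricted (own lags only) to full residual variance;
#' the larger statistic wins. `criterion_C` stores
#' `GC(y -> x) - GC(x -> y)` (negative means `x -> y`).
#'
#' @param x,y Numeric vectors of equal length, length > 10 * `p_max`.
#' @param p_max Maximum VAR order considered.
#' @param tie_tol Tie tolerance on the criterion.
#' @return A `soc_decision` with `method = "granger"`; attributes carry the
#'   selected order and the four residual variances.
#' @export
granger_decide <- function(x, y, p_max = 10, tie_tol = 1e-12) {
  if (p_max < 1) stop("p_max must be >= 1")
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) <= 10 * p_max) {
    stop("insufficient data: need length > 10 * p_max = ", 10 * p_max)
  }
  xs <- standardize(x); ys <- standardize(y)
  t_start <- p_max + 1   # common sample across candidate orders
  fits <- lapply(1:p_max, function(p) fit_var2(xs, ys, p, t_start))
  aic <- vapply(fits, function(f) {
    if (is.null(f)) return(Inf)
    ld <- determinant(f$Sigma, logarithm = TRUE)
    if (ld$sign <= 0) return(Inf)
    f$n_eff * as.numeric(ld$modulus) + 2 * f$n_params
  }, numeric(1))
  if (all(!is.finite(aic))) stop("non-finite VAR fit for all candidate orders")
  p <- which.min(aic)
  full <- fits[[p]]
  rv_full_x <- full$Sigma[1, 1]   # x equation (does y -> x help?)
  rv_full_y <- full$Sigma[2, 2]   # y equation (does x -> y help?)
  rv_restr_y <- restricted_resid_var(ys, ys, p, t_start)
  rv_restr_x <- restricted_resid_var(xs, xs, p, t_start)
  gc_xy <- log(rv_restr_y / rv_full_y)   # x Granger-causes y
  gc_yx <- log(rv_restr_x / rv_full_x)   # y Granger-causes x
  res <- decision_result(gc_yx - gc_xy, alpha_hat = mean(xs * ys),
                         mi_x_d = NA_real_, mi_y_e = NA_real_,
                         method = "granger", tie_tol = tie_tol,
                         config = list(p_max = p_max))
  res$granger <- list(order_p = p, aic = aic[p],
                      resid_var_full_xy = rv_full_y,
                      resid_var_restricted_xy = rv_restr_y,
                      resid_var_full_yx = rv_full_x,
                      resid_var_restricted_yx = rv_restr_x)
  res
}
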