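# Two-stage effective-connectivity estimation: cross-validated
# graphical-lasso skeleton, then pairwise orientation of each retained edge.

soft_threshold <- function(z, t) sign(z) * pmax(abs(z) - t, 0)

# Lasso subproblem of the graphical lasso by coordinate descent:
# minimize 1/2 b' W11 b - s12' b + rho |b|_1
glasso_lasso_cd <- function(W11, s12, rho, beta, tol = 1e-6, max_iter = 500) {
  p1 <- length(s12)
  for (it in seq_len(max_iter)) {
    delta <- 0
    for (j in seq_len(p1)) {
      resid <- s12[j] - sum(W11[j, -j] * beta[-j])
      new <- soft_threshold(resid, rho) / W11[j, j]
      delta <- max(delta, abs(new - beta[j]))
      beta[j] <- new
    }
    if (delta < tol) break
  }
  beta
}

#' Graphical lasso at a fixed penalty
#'
#' Blockwise coordinate-descent solver for the L1-penalized Gaussian
#' maximum-likelihood precision matrix: maximize
#' `logdet(Theta) - tr(S Theta) - rho ||Theta||_1` (off-diagonal penalty).
#'
#' @param S Sample covariance (or correlation) matrix.
#' @param rho Nonnegative L1 penalty.
#' @param tol Convergence tolerance on the covariance update.
#' @param max_iter Maximum outer sweeps.
#' @param init Optional warm start: a previous fit's `covariance` and
#'   `coefficients` (used when tracing a penalty path).
#' @return List with `precision` (Theta), `covariance` (its inverse
#'   estimate W) and `coefficients` (per-column lasso coefficients, for
#'   warm starts).
#' @export
graphical_lasso <- function(S, rho, tol = 1e-5, max_iter = 200, init = NULL) {
  p <- ncol(S)
  stopifnot(nrow(S) == p, rho >= 0)
  if (p == 1) return(list(precision = 1 / S, covariance = S))
  if (!is.null(init)) {
    W <- init$covariance
    diag(W) <- diag(S) + rho
    B <- init$coefficients
  } else {
    W <- S + diag(rho, p)
    B <- matrix(0, p - 1, p)   # warm-started lasso coefficients per column
  }
  for (it in seq_len(max_iter)) {
    W_old <- W
    for (j in seq_len(p)) {
      idx <- setdiff(seq_len(p), j)
      W11 <- W[idx, idx, drop = FALSE]
      beta <- glasso_lasso_cd(W11, S[idx, j], rho, B[, j])
      B[, j] <- beta
      w12 <- W11 %*% beta
      W[idx, j] <- w12
      W[j, idx] <- w12
    }
    if (mean(abs(W - W_old)) < tol * mean(abs(S - diag(diag(S)))) ||
        mean(abs(W - W_old)) < 1e-12) break
  }
  # recover Theta from the final W and regression coefficients
  Theta <- matrix(0, p, p)
  for (j in seq_len(p)) {
    idx <- setdiff(seq_len(p), j)
    theta_jj <- 1 / (W[j, j] - sum(W[idx, j] * B[, j]))
    Theta[j, j] <- theta_jj
    Theta[idx, j] <- -B[, j] * theta_jj
  }
  Theta <- (Theta + t(Theta)) / 2
  dimnames(Theta) <- dimnames(S)
  list(precision = Theta, covariance = W, coefficients = B)
}

gaussian_nll_score <- function(Theta, S_test) {
  ld <- determinant(Theta, logarithm = TRUE)
  if (ld$sign <= 0) return(-Inf)
  as.numeric(ld$modulus) - sum(S_test * Theta)
}

#' Cross-validated sparse precision matrix
#'
#' Selects the graphical-lasso penalty by K-fold cross-validation of the
#' out-of-fold Gaussian log-likelihood over a logarithmic penalty grid,
#' then refits on the full (column-standardized) data.
#'
#' @param X n x p data matrix (rows = observations).
#' @param cv_folds Number of folds.
#' @param n_penalties Size of the log-spaced penalty grid; the grid upper
#'   end is the smallest penalty giving a fully diagonal precision.
#' @param seed Integer seed controlling fold assignment.
#' @param rule `"1se"` (default) picks the sparsest penalty whose mean CV
#'   score is within one standard error of the best, guarding against the
#'   over-selection typical of raw likelihood CV; `"max"` picks the score
#'   maximizer.
#' @return List with `precision`, `rho` (selected penalty), `rho_grid`,
#'   and `cv_scores`.
#' @export
cv_graphical_lasso <- function(X, cv_folds = 5, n_penalties = 10, seed = 1,
                               rule = c("1se", "max")) {
  rule <- match.arg(rule)
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (n <= p) warning("n <= p: precision estimate may be unstable")
  Xs <- scale(X)
  S <- crossprod(Xs) / n
  rho_max <- max(abs(S[upper.tri(S)]))
  if (!is.finite(rho_max) || rho_max <= 0) rho_max <- 1
  rho_grid <- exp(seq(log(rho_max), log(rho_max * 1e-2), length.out = n_penalties))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  folds <- sample(rep_len(seq_len(cv_folds), n))
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  scores <- matrix(NA_real_, cv_folds, length(rho_grid))
  for (k in seq_len(cv_folds)) {
    tr <- Xs[folds != k, , drop = FALSE]
    te <- Xs[folds == k, , drop = FALSE]
    S_tr <- crossprod(scale(tr, scale = FALSE)) / nrow(tr)
    S_te <- crossprod(scale(te, scale = FALSE)) / nrow(te)
    fit <- NULL
    for (g in seq_along(rho_grid)) {   # descending grid: warm starts
      fit <- graphical_lasso(S_tr, rho_grid[g], init = fit)
      scores[k, g] <- gaussian_nll_score(fit$precision, S_te)
    }
  }
  mean_scores <- colMeans(scores)
  best <- which.max(mean_scores)
  if (rule == "1se") {
    se <- stats::sd(scores[, best]) / sqrt(cv_folds)
    # grid is descending, so the first qualifying index is the sparsest
    best <- which(mean_scores >= mean_scores[best] - se)[1]
  }
  rho <- rho_grid[best]
  fit <- graphical_lasso(S, rho)
  list(precision = fit$precision, rho = rho, rho_grid = rho_grid,
       cv_scores = mean_scores)
}

#' Estimate the undirected skeleton by sparse inverse covariance
#'
#' An edge (i, j) is present when the corresponding off-diagonal entry of
#' the cross-validated L1-penalized precision matrix is nonzero (above a
#' small floating-point guard). Columns are standardized internally, so
#' the skeleton is invariant to affine rescaling of individual columns.
#'
#' @param X n x p data matrix (rows = time points, columns = variables).
#' @param cv_folds Cross-validation folds for the penalty.
#' @param seed Integer seed (fold assignment).
#' @param zero_tol Absolute threshold on precision entries.
#' @return Symmetric logical p x p adjacency matrix with FALSE diagonal;
#'   attribute `"precision"` carries the fitted precision matrix.
#' @export
estimate_skeleton <- function(X, cv_folds = 5, seed = 1, zero_tol = 1e-8) {
  X <- as.matrix(X)
  fit <- cv_graphical_lasso(X, cv_folds = cv_folds, seed = seed)
  A <- abs(fit$precision) > zero_tol
  diag(A) <- FALSE
  A <- A | t(A)
  dimnames(A) <- list(colnames(X), colnames(X))
  attr(A, "precision") <- fit$precision
  attr(A, "rho") <- fit$rho
  A
}

#' Orient the edges of a skeleton with a pairwise detector
#'
#' Runs the chosen pairwise direction method on the two data columns of
#' every skeleton edge and records the direction and criterion magnitude.
#'
#' @param X n x p data matrix.
#' @param skeleton Symmetric logical adjacency (as from
#'   [estimate_skeleton()]).
#' @param method `"soc"`, `"pwlingam"`, `"granger"`, or a function
#'   `(x, y) -> soc_decision`.
#' @param config Detector settings (see [run_benchmark()]).
#' @return A `directed_network`: list with `n_nodes`, `skeleton`, and an
#'   `edges` data frame (i, j with i < j, direction, criterion_C,
#'   strength).
#' @export
orient_edges <- function(X, skeleton, method = "soc",
                         config = list(soc = soc_config(), granger_p_max = 10)) {
  X <- as.matrix(X)
  p <- ncol(X)
  stopifnot(nrow(skeleton) == p, ncol(skeleton) == p)
  if (is.null(config$soc)) config$soc <- soc_config()
  if (is.null(config$granger_p_max)) config$granger_p_max <- 10
  idx <- which(skeleton & upper.tri(skeleton), arr.ind = TRUE)
  edges <- data.frame(i = integer(0), j = integer(0),
                      direction = character(0), criterion_C = numeric(0),
                      strength = numeric(0), stringsAsFactors = FALSE)
  if (nrow(idx) > 0) {
    rows <- lapply(seq_len(nrow(idx)), function(k) {
      i <- idx[k, 1]; j <- idx[k, 2]
      dec <- apply_method(method, X[, i], X[, j], config)
      dir <- switch(dec$direction, x_to_y = "i_to_j", y_to_x = "j_to_i",
                    "undetermined")
      data.frame(i = i, j = j, direction = dir,
                 criterion_C = dec$criterion_C,
                 strength = abs(dec$criterion_C), stringsAsFactors = FALSE)
    })
    edges <- do.call(rbind, rows)
  }
  method_label <- if (is.function(method)) "custom" else method
  structure(list(n_nodes = p, skeleton = skeleton, edges = edges,
                 node_names = colnames(X), method = method_label),
            class = "directed_network")
}

#' @export
print.directed_network <- function(x, ...) {
  cat("directed_network:", x$n_nodes, "nodes,", nrow(x$edges),
      "edges, method =", x$method, "\n")
  if (nrow(x$edges) > 0) print(utils::head(x$edges, 10))
  invisible(x)
}

#' Two-stage effective-connectivity network estimation
#'
#' Stage 1 finds which nodes are connected (cross-validated graphical
#' lasso on the inverse covariance); stage 2 orients each retained edge
#' with a pairwise direction method on the full-length columns.
#'
#' @inheritParams orient_edges
#' @param cv_folds Folds for the skeleton stage.
#' @param seed Integer seed (fold assignment).
#' @return A `directed_network`.
#' @export
two_stage <- function(X, method = "soc", cv_folds = 5, seed = 1,
                      config = list(soc = soc_config(), granger_p_max = 10)) {
  skeleton <- estimate_skeleton(X, cv_folds = cv_folds, seed = seed)
  orient_edges(X, skeleton, method = method, config = config)
}

#' Signed flow matrix of a directed network
#'
#' Heatmap-ready p x p matrix: entry (i, j) is +|C| when i sends flow to j
#' (out-flow positive) and -|C| when i receives from j.
#'
#' @param net A `directed_network`.
#' @return Numeric p x p matrix.
#' @export
flow_matrix <- function(net) {
  stopifnot(inherits(net, "directed_network"))
  M <- matrix(0, net$n_nodes, net$n_nodes,
              dimnames = list(net$node_names, net$node_names))
  for (k in seq_len(nrow(net$edges))) {
    e <- net$edges[k, ]
    if (e$direction == "i_to_j") {
      M[e$i, e$j] <- e$strength; M[e$j, e$i] <- -e$strength
    } else if (e$direction == "j_to_i") {
      M[e$j, e$i] <- e$strength; M[e$i, e$j] <- -e$strength
    }
  }
  M
}
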