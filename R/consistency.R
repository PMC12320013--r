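# Split-half reliability and group-template accuracy procedures for
# multi-subject source time series.

utri <- function(M) M[upper.tri(M)]

default_net_config <- function(config) {
  if (is.null(config$soc)) config$soc <- soc_config()
  if (is.null(config$granger_p_max)) config$granger_p_max <- 10
  if (is.null(config$cv_folds)) config$cv_folds <- 5
  config
}

#' Edge-wise connectivity values of one metric on one dataset
#'
#' Vectorized (upper-triangle, i < j) edge values for the three metrics
#' whose reliability is examined: `"precision"` (entries of the
#' cross-validated L1-penalized precision matrix), `"causal_raw"` (the
#' pairwise causal criterion on every pair), and `"two_stage"` (the
#' criterion on skeleton edges, 0 elsewhere, with the skeleton mask
#' attached as attribute `"mask"`).
#'
#' @param X n x p data matrix.
#' @param metric `"precision"`, `"causal_raw"` or `"two_stage"`.
#' @param method Pairwise detector for the causal metrics.
#' @param config Detector/skeleton settings.
#' @param seed Integer seed (graphical-lasso fold assignment).
#' @return Numeric vector of length `p (p - 1) / 2`.
#' @export
edge_metric_values <- function(X, metric = c("two_stage", "causal_raw", "precision"),
                               method = "soc", config = list(), seed = 1) {
  metric <- match.arg(metric)
  config <- default_net_config(config)
  X <- as.matrix(X)
  p <- ncol(X)
  if (metric == "precision") {
    fit <- cv_graphical_lasso(X, cv_folds = config$cv_folds, seed = seed)
    return(utri(fit$precision))
  }
  if (metric == "causal_raw") {
    pairs <- which(upper.tri(diag(p)), arr.ind = TRUE)
    return(vapply(seq_len(nrow(pairs)), function(k) {
      apply_method(method, X[, pairs[k, 1]], X[, pairs[k, 2]], config)$criterion_C
    }, numeric(1)))
  }
  net <- two_stage(X, method = method, cv_folds = config$cv_folds,
                   seed = seed, config = config)
  M <- matrix(0, p, p)
  for (k in seq_len(nrow(net$edges))) {
    e <- net$edges[k, ]
    M[e$i, e$j] <- e$criterion_C
  }
  vals <- utri(M)
  attr(vals, "mask") <- utri(net$skeleton)
  vals
}

split_half_cor <- function(v1, v2, metric, cor_method) {
  if (metric == "two_stage") {
    keep <- attr(v1, "mask") | attr(v2, "mask")   # union of skeletons
    v1 <- v1[keep]; v2 <- v2[keep]
  }
  if (length(v1) < 2 || stats::sd(v1) == 0 || stats::sd(v2) == 0) {
    return(NA_real_)
  }
  stats::cor(as.numeric(v1), as.numeric(v2), method = cor_method)
}

consistency_report <- function(metric, values) {
  structure(list(metric = metric, correlations = values,
                 mean = mean(values, na.rm = TRUE),
                 sd = stats::sd(values, na.rm = TRUE)),
            class = "consistency_report")
}

#' @export
print.consistency_report <- function(x, ...) {
  cat(sprintf("split-half consistency (%s): %.3f +/- %.3f over %d units\n",
              x$metric, x$mean, x$sd, length(x$correlations)))
  invisible(x)
}

#' Intra-subject split-half consistency
#'
#' Splits each subject's series at the temporal midpoint (an odd sample
#' goes to the first half), computes the chosen edge metric on each half,
#' and correlates the vectorized edge values between halves, per subject.
#'
#' @param subjects List of n x p matrices (rows = time, columns = sources);
#'   all subjects must share p.
#' @inheritParams edge_metric_values
#' @param cor_method `"pearson"` (default) or `"spearman"`.
#' @return A `consistency_report` with one correlation per subject.
#' @export
intra_subject_split_half <- function(subjects,
                                     metric = c("two_stage", "causal_raw", "precision"),
                                     method = "soc", config = list(),
                                     cor_method = c("pearson", "spearman"),
                                     seed = 1) {
  metric <- match.arg(metric)
  cor_method <- match.arg(cor_method)
  subjects <- lapply(subjects, as.matrix)
  cors <- vapply(seq_along(subjects), function(s) {
    X <- subjects[[s]]
    n <- nrow(X)
    cut <- ceiling(n / 2)
    v1 <- edge_metric_values(X[1:cut, , drop = FALSE], metric, method, config, seed)
    v2 <- edge_metric_values(X[(cut + 1):n, , drop = FALSE], metric, method, config, seed)
    split_half_cor(v1, v2, metric, cor_method)
  }, numeric(1))
  consistency_report(metric, cors)
}

#' Inter-group split-half consistency
#'
#' Randomly divides the subjects into two disjoint halves, temporally
#' concatenates each half, computes the edge metric on each concatenation,
#' and correlates the two; repeated `n_repeats` times.
#'
#' @inheritParams intra_subject_split_half
#' @param n_repeats Number of random partitions.
#' @param seed Integer seed driving the partitions.
#' @return A `consistency_report` with one correlation per repeat.
#' @export
inter_group_split_half <- function(subjects, n_repeats = 100,
                                   metric = c("two_stage", "causal_raw", "precision"),
                                   method = "soc", config = list(),
                                   cor_method = c("pearson", "spearman"),
                                   seed = 1) {
  metric <- match.arg(metric)
  cor_method <- match.arg(cor_method)
  subjects <- lapply(subjects, as.matrix)
  S <- length(subjects)
  if (S < 4) stop("need at least 4 subjects for a group split")
  half <- S %/% 2
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  cors <- vapply(seq_len(n_repeats), function(rep) {
    perm <- sample(S)
    g1 <- do.call(rbind, subjects[perm[1:half]])
    g2 <- do.call(rbind, subjects[perm[(half + 1):(2 * half)]])
    v1 <- edge_metric_values(g1, metric, method, config, seed)
    v2 <- edge_metric_values(g2, metric, method, config, seed)
    split_half_cor(v1, v2, metric, cor_method)
  }, numeric(1))
  consistency_report(metric, cors)
}

orient_on_edges <- function(X, edges, method, config) {
  vapply(seq_len(nrow(edges)), function(k) {
    dec <- apply_method(method, X[, edges$i[k]], X[, edges$j[k]], config)
    switch(dec$direction, x_to_y = "i_to_j", y_to_x = "j_to_i", "undetermined")
  }, character(1))
}

#' Per-edge accuracy of subject-level directions against a group template
#'
#' Estimates a group-level directed network (two-stage method on the
#' temporal concatenation of all subjects) as a proxy for ground truth,
#' then repeatedly samples subjects, re-orients the template's edges on
#' each subject's data alone, and reports the fraction of subjects whose
#' direction matches the template, per edge and globally.
#'
#' @inheritParams intra_subject_split_half
#' @param template_method Pairwise detector used both for the template and
#'   the subject-level orientation (or a function `(x, y) -> soc_decision`).
#' @param n_subjects_drawn Subjects sampled (without replacement) per
#'   repeat.
#' @param n_repeats Number of sampling repeats.
#' @return List with `template` (a `directed_network`), `edge_accuracy`
#'   (per template edge, pooled over draws), `accuracy_matrix` (p x p,
#'   NA off the template skeleton) and `global_accuracy`.
#' @export
template_accuracy <- function(subjects, template_method = "soc",
                              config = list(), n_subjects_drawn = 20,
                              n_repeats = 5, seed = 1) {
  config <- default_net_config(config)
  subjects <- lapply(subjects, as.matrix)
  S <- length(subjects)
  all_X <- do.call(rbind, subjects)
  template <- two_stage(all_X, method = template_method,
                        cv_folds = config$cv_folds, seed = seed, config = config)
  edges <- template$edges[template$edges$direction != "undetermined", , drop = FALSE]
  if (nrow(edges) == 0) stop("empty template skeleton: no edges to score")
  n_subjects_drawn <- min(n_subjects_drawn, S)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  match_counts <- matrix(0, nrow(edges), 2,
                         dimnames = list(NULL, c("match", "total")))
  for (rep in seq_len(n_repeats)) {
    drawn <- sample(S, n_subjects_drawn)
    for (s in drawn) {
      dirs <- orient_on_edges(subjects[[s]], edges, template_method, config)
      match_counts[, "match"] <- match_counts[, "match"] + (dirs == edges$direction)
      match_counts[, "total"] <- match_counts[, "total"] + 1
    }
  }
  edge_acc <- match_counts[, "match"] / match_counts[, "total"]
  p <- template$n_nodes
  acc_mat <- matrix(NA_real_, p, p,
                    dimnames = list(template$node_names, template$node_names))
  for (k in seq_len(nrow(edges))) {
    acc_mat[edges$i[k], edges$j[k]] <- edge_acc[k]
    acc_mat[edges$j[k], edges$i[k]] <- edge_acc[k]
  }
  list(template = template,
       edge_accuracy = cbind(edges[, c("i", "j")], accuracy = edge_acc),
       accuracy_matrix = acc_mat,
       global_accuracy = mean(edge_acc))
}
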