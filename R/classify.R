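#' Symmetrical uncertainty between two discrete variables
#'
#' SU(X, Y) = 2 * I(X; Y) / (H(X) + H(Y)), a normalized mutual information
#' in \[0, 1\] used as the correlation measure of CFS on binary CNV features.
#' Returns `NA` when either variable is constant (zero entropy).
#'
#' @param x,y Discrete (here binary) vectors of equal length.
#' @return Symmetrical uncertainty in \[0, 1\], or `NA`.
#' @export
symmetrical_uncertainty <- function(x, y) {
  ent <- function(tab) {
    p <- tab[tab > 0] / sum(tab)
    -sum(p * log2(p))
  }
  hx <- ent(table(x))
  hy <- ent(table(y))
  if (hx == 0 || hy == 0) return(NA_real_)
  hxy <- ent(table(x, y))
  2 * (hx + hy - hxy) / (hx + hy)
}

#' CFS merit of a feature subset
#'
#' Correlation-based feature selection scores a subset of k features by
#' merit = k * mean(feature-class SU) / sqrt(k + k (k - 1) * mean(feature-feature SU)),
#' rewarding class relevance while penalizing redundancy among the chosen
#' features. Correlations are symmetrical uncertainties on binary variables.
#'
#' @param subset Integer or character indices of features (columns of `x`).
#' @param x Binary feature matrix or data frame (samples x features).
#' @param y Class labels (two classes).
#' @param su_class Optional precomputed feature-class SU vector (named by
#'   column), to avoid recomputation inside search loops.
#' @return The merit score.
#' @export
cfs_merit <- function(subset, x, y, su_class = NULL) {
  x <- as.matrix(x)
  if (is.character(subset)) subset <- match(subset, colnames(x))
  k <- length(subset)
  if (k == 0) stop("subset must be non-empty", call. = FALSE)
  if (is.null(su_class)) {
    su_class <- apply(x, 2, symmetrical_uncertainty, y = y)
  }
  rcf <- mean(su_class[subset])
  if (is.na(rcf)) stop("subset contains a constant feature", call. = FALSE)
  if (k == 1) return(rcf)
  pairs <- utils::combn(subset, 2)
  rff <- mean(apply(pairs, 2, function(ij) {
    symmetrical_uncertainty(x[, ij[1]], x[, ij[2]])
  }))
  k * rcf / sqrt(k + k * (k - 1) * rff)
}

#' Best-first forward search over CFS merit
#'
#' Greedy best-first subset search: starting from the empty set, repeatedly
#' expands the best-scoring open subset by each unused feature, keeping the
#' best subset seen; terminates after `max_stale` consecutive expansions
#' that fail to improve the best merit. Ties break to the lower feature
#' index, making the search deterministic.
#'
#' @param x Binary feature matrix/data frame (samples x features).
#' @param y Class labels (two classes).
#' @param max_stale Consecutive non-improving expansions tolerated
#'   (default 5).
#' @return Character vector of selected feature names (column names of `x`),
#'   in selection order.
#' @export
best_first_select <- function(x, y, max_stale = 5) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  su_class <- vapply(seq_len(ncol(x)), function(j) {
    symmetrical_uncertainty(x[, j], y)
  }, numeric(1))
  usable <- which(!is.na(su_class))
  if (!length(usable)) stop("no usable (non-constant) feature", call. = FALSE)

  # pairwise SU cache, filled lazily
  su_ff <- new.env(parent = emptyenv())
  pair_su <- function(a, b) {
    key <- paste(min(a, b), max(a, b))
    v <- su_ff[[key]]
    if (is.null(v)) {
      v <- symmetrical_uncertainty(x[, a], x[, b])
      su_ff[[key]] <- v
    }
    v
  }
  # incremental merit from cached sums: subset stored with its rcf-sum and
  # pairwise-sum so extending by one feature costs k SU evaluations
  merit_of <- function(sum_cf, sum_ff, k) {
    if (k == 1) return(sum_cf)
    k * (sum_cf / k) / sqrt(k + k * (k - 1) * (sum_ff / (k * (k - 1) / 2)))
  }

  open <- list(list(feats = integer(0), sum_cf = 0, sum_ff = 0, score = -Inf))
  best <- open[[1]]
  stale <- 0L
  visited <- new.env(parent = emptyenv())
  while (length(open) && stale < max_stale) {
    scores <- vapply(open, `[[`, numeric(1), "score")
    pick <- which.max(scores)
    node <- open[[pick]]
    open[[pick]] <- NULL
    improved <- FALSE
    for (j in usable) {
      if (j %in% node$feats) next
      feats <- sort(c(node$feats, j))
      key <- paste(feats, collapse = ",")
      if (!is.null(visited[[key]])) next
      visited[[key]] <- TRUE
      sum_cf <- node$sum_cf + su_class[j]
      sum_ff <- node$sum_ff +
        sum(vapply(node$feats, pair_su, numeric(1), b = j))
      score <- merit_of(sum_cf, sum_ff, length(feats))
      child <- list(feats = feats, sum_cf = sum_cf, sum_ff = sum_ff,
                    score = score)
      open <- c(open, list(child))
      if (score > best$score + 1e-12) {
        best <- child
        improved <- TRUE
      }
    }
    stale <- if (improved) 0L else stale + 1L
    # keep the open list bounded; best-first only ever expands the top
    if (length(open) > 50) {
      scores <- vapply(open, `[[`, numeric(1), "score")
      open <- open[order(scores, decreasing = TRUE)[1:50]]
    }
  }
  colnames(x)[best$feats]
}

#' F-score from confusion counts
#'
#' F = 2 TP / (2 TP + FP + FN).
#'
#' @param tp,fp,fn True-positive, false-positive and false-negative counts.
#' @return The F-score in \[0, 1\].
#' @export
f_score <- function(tp, fp, fn) {
  if (any(c(tp, fp, fn) < 0)) stop("counts must be non-negative", call. = FALSE)
  if (tp + fp + fn == 0) stop("F-score undefined when all counts are zero", call. = FALSE)
  2 * tp / (2 * tp + fp + fn)
}

# Mann-Whitney AUC of scores for the positive class
rank_auc <- function(scores, is_pos) {
  n1 <- sum(is_pos)
  n0 <- sum(!is_pos)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[is_pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Repeated stratified cross-validation with naive Bayes
#'
#' Evaluates a binary feature set by `iterations` repetitions of stratified
#' `folds`-fold cross-validation with a naive Bayes classifier
#' (Laplace-smoothed, via \pkg{e1071}). AUC is computed per iteration from
#' the pooled held-out posterior probabilities by the Mann-Whitney rank
#' statistic and averaged over iterations; the F-score is computed from the
#' confusion counts pooled over all iterations.
#'
#' @param x Binary feature matrix/data frame (samples x features).
#' @param y Class labels (factor or coercible; exactly two classes).
#' @param features Optional subset of feature names/indices to use
#'   (default: all columns).
#' @param iterations Number of CV repetitions (default 1000).
#' @param folds Number of folds (default 2).
#' @param seed Optional seed for the fold splits.
#' @param positive Label treated as the positive class for the F-score
#'   (default: first factor level).
#' @return A list of class `nb_cv`: `auc` (mean over iterations), `f_score`,
#'   `auc_per_iteration`, confusion counts, `iterations`, `folds`, `seed`,
#'   `positive`.
#' @export
naive_bayes_cv <- function(x, y, features = NULL, iterations = 1000,
                           folds = 2, seed = NULL, positive = NULL) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  if (!is.null(features)) x <- x[, features, drop = FALSE]
  y <- factor(y)
  if (nlevels(y) != 2) stop("exactly two classes required", call. = FALSE)
  if (min(table(y)) < folds) {
    stop("each class must have at least `folds` samples", call. = FALSE)
  }
  positive <- positive %||% levels(y)[1]
  stopifnot(positive %in% levels(y))
  xf <- as.data.frame(lapply(as.data.frame(x), factor, levels = c(0, 1)))

  run <- function() {
    auc_it <- numeric(iterations)
    tp <- fp <- fn <- tn <- 0
    n <- length(y)
    for (it in seq_len(iterations)) {
      fold <- integer(n)
      for (cl in levels(y)) {
        idx <- sample(which(y == cl))
        fold[idx] <- rep_len(seq_len(folds), length(idx))
      }
      post <- numeric(n)
      pred <- character(n)
      for (f in seq_len(folds)) {
        test_i <- which(fold == f)
        train_i <- which(fold != f)
        fit <- e1071::naiveBayes(xf[train_i, , drop = FALSE], y[train_i],
                                 laplace = 1)
        pr <- stats::predict(fit, xf[test_i, , drop = FALSE], type = "raw")
        post[test_i] <- pr[, positive]
        pred[test_i] <- colnames(pr)[max.col(pr, ties.method = "first")]
      }
      auc_it[it] <- rank_auc(post, y == positive)
      tp <- tp + sum(pred == positive & y == positive)
      fp <- fp + sum(pred == positive & y != positive)
      fn <- fn + sum(pred != positive & y == positive)
      tn <- tn + sum(pred != positive & y != positive)
    }
    list(auc = mean(auc_it), auc_per_iteration = auc_it,
         f_score = f_score(tp, fp, fn),
         tp = tp, fp = fp, fn = fn, tn = tn)
  }
  res <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  structure(c(res, list(iterations = iterations, folds = folds, seed = seed,
                        positive = positive, features = colnames(x))),
            class = "nb_cv")
}

#' @export
print.nb_cv <- function(x, ...) {
  cat("Naive Bayes ", x$iterations, " x ", x$folds, "-fold CV on ",
      length(x$features), " feature(s)\n", sep = "")
  cat("AUC = ", round(x$auc, 4), ", F-score = ", round(x$f_score, 4),
      " (positive class: ", x$positive, ")\n", sep = "")
  invisible(x)
}

#' Select CNV features and evaluate a cohort classifier
#'
#' End-to-end classification stage: drops constant features, selects a
#' discriminative subset with CFS + best-first search, and evaluates it by
#' repeated stratified naive Bayes cross-validation.
#'
#' @inheritParams naive_bayes_cv
#' @param max_stale Best-first stopping patience (default 5).
#' @return A list of class `cnv_classifier`: `selected_features`, the
#'   `nb_cv` report, and the inputs' dimensions.
#' @export
cnv_classify <- function(x, y, iterations = 1000, folds = 2, max_stale = 5,
                         seed = NULL, positive = NULL) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  keep <- apply(x, 2, function(v) length(unique(v)) > 1)
  x <- x[, keep, drop = FALSE]
  selected <- best_first_select(x, y, max_stale = max_stale)
  report <- naive_bayes_cv(x, y, features = selected, iterations = iterations,
                           folds = folds, seed = seed, positive = positive)
  structure(list(selected_features = selected, cv = report,
                 n_samples = nrow(x), n_features = ncol(x)),
            class = "cnv_classifier")
}

#' @export
print.cnv_classifier <- function(x, ...) {
  cat("CNV-feature classifier: ", length(x$selected_features), " of ",
      x$n_features, " features selected\n", sep = "")
  print(x$cv)
  invisible(x)
}

#' @method tidy cnv_classifier
#' @export
tidy.cnv_classifier <- function(x, ...) {
  tibble::tibble(feature = x$selected_features)
}

#' @method glance cnv_classifier
#' @export
glance.cnv_classifier <- function(x, ...) {
  tibble::tibble(
    n_selected = length(x$selected_features),
    auc = x$cv$auc,
    f_score = x$cv$f_score,
    iterations = x$cv$iterations,
    folds = x$cv$folds,
    positive = x$cv$positive
  )
}

#' Hierarchical clustering with bootstrap support
#'
#' Agglomerative clustering of samples on binary CNV features (Euclidean
#' distance, Ward linkage in its classic unsquared `ward.D` form) with
#' per-node support computed as the proportion of feature-resampled
#' bootstrap trees containing the node's sample set.
#'
#' @param x Binary feature matrix/data frame (samples x features).
#' @param features Optional subset of features to cluster on.
#' @param n_boot Number of feature bootstrap replicates (default 1000).
#' @param seed Optional seed for the bootstrap.
#' @return A list of class `cnv_hclust`: `hclust` (the reference tree),
#'   `phylo` (ape tree with node labels = bootstrap proportions), `support`
#'   (numeric vector per internal node), `n_boot`.
#' @export
hier_cluster <- function(x, features = NULL, n_boot = 1000, seed = NULL) {
  x <- as.matrix(x)
  if (!is.null(features)) x <- x[, features, drop = FALSE]
  if (nrow(x) < 3) stop("need at least 3 samples to cluster", call. = FALSE)
  if (is.null(rownames(x))) rownames(x) <- paste0("s", seq_len(nrow(x)))
  hc <- stats::hclust(stats::dist(x, method = "euclidean"), method = "ward.D")
  phy <- ape::as.phylo(hc)
  run <- function() {
    boots <- vector("list", n_boot)
    for (b in seq_len(n_boot)) {
      cols <- sample.int(ncol(x), replace = TRUE)
      hb <- stats::hclust(stats::dist(x[, cols, drop = FALSE]), method = "ward.D")
      boots[[b]] <- ape::as.phylo(hb)
    }
    ape::prop.clades(phy, boots, rooted = TRUE)
  }
  counts <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  support <- counts / n_boot
  support[is.na(support)] <- 0
  phy$node.label <- format(round(support, 3))
  structure(list(hclust = hc, phylo = phy, support = support, n_boot = n_boot),
            class = "cnv_hclust")
}

#' Write a support-annotated dendrogram as Newick
#'
#' @param clustering A `cnv_hclust` from [hier_cluster()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_dendrogram <- function(clustering, path) {
  ape::write.tree(clustering$phylo, file = path)
  invisible(path)
}
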