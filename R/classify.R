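#' Rule-based functional-group assignment
#'
#' Applies the pathway-band rules, in order, first match wins:
#' \itemize{
#'   \item Ferment to Intermediates: any carbohydrate-fermentation pathway
#'     (bifid shunt, phosphoketolase or homolactic) at or above `high`,
#'     and both lactic acid utilization (LAU) and reverse beta-oxidation
#'     (rBOX) at or below `low`.
#'   \item Intermediate Chain Elongators: bifid shunt and phosphoketolase
#'     at or below `low`, LAU and rBOX at or above `high`.
#'   \item Carbohydrate Chain Elongators: bifid shunt, phosphoketolase and
#'     LAU at or below `low`, rBOX at or above `high`.
#'   \item Otherwise: uninvolved.
#' }
#'
#' @param profile a `pathway_profile`, or a named numeric vector of the
#'   five pathway completeness percentages.
#' @param thresholds a [rule_thresholds()] object.
#' @return A one-row data frame (`genome_id`, `group`, `method = "rule"`).
#' @export
rule_classify <- function(profile, thresholds = rule_thresholds()) {
  if (inherits(profile, "pathway_profile")) {
    p <- profile$per_pathway_percent
    id <- profile$genome_id
  } else {
    p <- profile
    id <- attr(profile, "genome_id") %||% "genome"
  }
  hi <- thresholds$high
  lo <- thresholds$low
  bif <- p[["bifid_shunt"]]
  pk <- p[["phosphoketolase"]]
  hom <- p[["homolactic_fermentation"]]
  lau <- p[["lactic_acid_utilization"]]
  rbo <- p[["reverse_beta_oxidation"]]
  group <- if (max(bif, pk, hom) >= hi && lau <= lo && rbo <= lo) {
    "ferment_to_intermediates"
  } else if (max(bif, pk) <= lo && lau >= hi && rbo >= hi) {
    "intermediate_ce"
  } else if (max(bif, pk) <= lo && lau <= lo && rbo >= hi) {
    "carbohydrate_ce"
  } else {
    "uninvolved"
  }
  data.frame(genome_id = id, group = group, method = "rule")
}

#' Rule-classify a list of profiles
#'
#' @param profiles list of `pathway_profile` objects.
#' @param thresholds a [rule_thresholds()] object.
#' @return Data frame of calls, one row per genome.
#' @export
rule_classify_all <- function(profiles, thresholds = rule_thresholds()) {
  out <- do.call(rbind, lapply(profiles, rule_classify,
                               thresholds = thresholds))
  rownames(out) <- NULL
  out
}

#' Multiclass log loss
#'
#' Mean over examples of `-ln p(true class)`, probabilities clipped to
#' `[1e-15, 1 - 1e-15]`.
#'
#' @param prob numeric matrix of class probabilities, columns named by
#'   class.
#' @param labels true class labels (character or factor).
#' @return Log loss (natural log).
#' @export
logloss <- function(prob, labels) {
  labels <- as.character(labels)
  stopifnot(nrow(prob) == length(labels), all(labels %in% colnames(prob)))
  p <- prob[cbind(seq_along(labels), match(labels, colnames(prob)))]
  p <- pmin(pmax(p, 1e-15), 1 - 1e-15)
  mean(-log(p))
}

#' Percent improvement in log loss over a baseline
#'
#' `100 * (baseline - model) / baseline`, the baseline being the
#' class-frequency predictor's log loss on the same split.
#'
#' @param model_logloss model log loss.
#' @param baseline_logloss baseline log loss.
#' @return Percent improvement.
#' @export
baseline_improvement <- function(model_logloss, baseline_logloss) {
  100 * (baseline_logloss - model_logloss) / baseline_logloss
}

# ---------------------------------------------------------------------------
# in-package default algorithm: L2-penalised multinomial softmax regression,
# full-batch gradient descent, zero init (deterministic)
# ---------------------------------------------------------------------------

softmax_prob <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

softmax_fit <- function(x, y, lambda = 1e-4, learning_rate = 0.5,
                        n_iter = 600) {
  lev <- levels(y)
  K <- length(lev)
  mu <- colMeans(x)
  sd <- apply(x, 2, stats::sd)
  sd[sd == 0] <- 1
  Xs <- sweep(sweep(x, 2, mu), 2, sd, "/")
  X1 <- cbind(1, Xs)
  n <- nrow(X1)
  Y <- outer(as.integer(y), seq_len(K), "==") * 1
  W <- matrix(0, ncol(X1), K)
  lr <- learning_rate
  loss <- function(W) {
    P <- softmax_prob(X1 %*% W)
    -sum(Y * log(pmax(P, 1e-15))) / n + lambda / 2 * sum(W[-1, ]^2)
  }
  cur <- loss(W)
  for (it in seq_len(n_iter)) {
    P <- softmax_prob(X1 %*% W)
    G <- t(X1) %*% (P - Y) / n
    G[-1, ] <- G[-1, ] + lambda * W[-1, ]
    Wn <- W - lr * G
    ln <- loss(Wn)
    if (!is.finite(ln) || ln > cur) {
      lr <- lr / 2
      if (lr < 1e-6) break
    } else {
      W <- Wn
      if (cur - ln < 1e-10) { cur <- ln; break }
      cur <- ln
    }
  }
  structure(list(W = W, mu = mu, sd = sd, levels = lev), class = "softmax_fit")
}

softmax_predict <- function(fit, newx) {
  Xs <- sweep(sweep(newx, 2, fit$mu), 2, fit$sd, "/")
  P <- softmax_prob(cbind(1, Xs) %*% fit$W)
  colnames(P) <- fit$levels
  rownames(P) <- rownames(newx)
  P
}

average_precision <- function(truth, score) {
  ord <- order(-score)
  truth <- truth[ord]
  if (sum(truth) == 0) return(NA_real_)
  prec <- cumsum(truth) / seq_along(truth)
  sum(prec * truth) / sum(truth)
}

stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (lev in levels(y)) {
    idx <- sample(which(y == lev))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Train a multiclass functional-group classifier
#'
#' Fits a classifier on a labeled feature matrix (rows of
#' [profile_matrix()]) under a pluggable algorithm contract: any function
#' `fit(x, y)` returning an object whose `predict_prob(object, newx)`
#' yields a class-probability matrix can be plugged in.  The in-package
#' default is an L2-penalised multinomial softmax regression trained by
#' full-batch gradient descent with zero initialisation, so training is
#' deterministic; `seed` only governs the cross-validation folds.
#' `algorithm = "multinom"` plugs in `nnet::multinom` when installed.
#'
#' The training report carries stratified cross-validated log loss, the
#' class-frequency baseline log loss on the same folds, the percent
#' improvement, and per-class one-vs-rest average precision and ROC AUC
#' computed from out-of-fold probabilities.
#'
#' @param x numeric feature matrix.
#' @param y group labels (factor or character), at least 2 classes, at
#'   least 2 examples per class.
#' @param algorithm `"softmax"` (default), `"multinom"`, or a function
#'   `function(x, y)` returning a list with elements `predict_prob`
#'   (function of the fit and new data) and `fit`.
#' @param seed integer seed for fold assignment.
#' @param n_folds cross-validation folds (default 5, reduced to the
#'   smallest class size if needed).
#' @param lambda,learning_rate,n_iter softmax hyperparameters.
#' @return An object of class `ce_classifier` with elements `algorithm`,
#'   `fit`, `levels`, `report`.
#' @export
train_classifier <- function(x, y, algorithm = "softmax", seed = 1,
                             n_folds = 5, lambda = 1e-4,
                             learning_rate = 0.5, n_iter = 600) {
  y <- droplevels(as.factor(y))
  stopifnot(nrow(x) == length(y))
  if (nlevels(y) < 2) stop("need at least 2 classes")
  if (any(table(y) < 2))
    stop("every class needs at least 2 training examples for ",
         "cross-validation; enlarge the training set")
  x <- as.matrix(x)

  fitter <- if (is.function(algorithm)) {
    algorithm
  } else if (identical(algorithm, "softmax")) {
    function(x, y) {
      f <- softmax_fit(x, y, lambda = lambda,
                       learning_rate = learning_rate, n_iter = n_iter)
      list(fit = f, predict_prob = function(fit, newx)
        softmax_predict(fit, newx))
    }
  } else if (identical(algorithm, "multinom")) {
    if (!requireNamespace("nnet", quietly = TRUE))
      stop("algorithm 'multinom' needs the nnet package")
    function(x, y) {
      df <- data.frame(.y = y, x, check.names = FALSE)
      f <- nnet::multinom(.y ~ ., data = df, trace = FALSE, maxit = 500)
      lev <- levels(y)
      list(fit = f, predict_prob = function(fit, newx) {
        p <- predict(fit, newdata = data.frame(newx, check.names = FALSE),
                     type = "probs")
        if (is.null(dim(p))) {
          # nnet returns a bare vector for 2 classes or a single row
          p <- if (length(lev) == 2) cbind(1 - p, p) else rbind(p)
          colnames(p) <- lev
        }
        p
      })
    }
  } else {
    stop("unknown algorithm: ", algorithm)
  }

  k <- min(n_folds, min(table(y)))
  folds <- with_seed(seed, stratified_folds(y, k))
  oof <- matrix(NA_real_, nrow(x), nlevels(y),
                dimnames = list(rownames(x), levels(y)))
  base_oof <- oof
  for (f in seq_len(k)) {
    tr <- folds != f
    m <- fitter(x[tr, , drop = FALSE], droplevels(y[tr]))
    p <- m$predict_prob(m$fit, x[!tr, , drop = FALSE])
    oof[!tr, colnames(p)] <- p
    oof[!tr, setdiff(levels(y), colnames(p))] <- 0
    freq <- as.numeric(table(y[tr])) / sum(tr)
    base_oof[!tr, ] <- matrix(freq, sum(!tr), nlevels(y), byrow = TRUE)
  }
  cv_ll <- logloss(oof, y)
  base_ll <- logloss(base_oof, y)
  per_class <- do.call(rbind, lapply(levels(y), function(lev) {
    truth <- as.integer(y == lev)
    auc <- as.numeric(pROC::auc(pROC::roc(truth, oof[, lev], quiet = TRUE,
                                          direction = "<", levels = c(0, 1))))
    data.frame(class = lev, average_precision =
                 average_precision(truth, oof[, lev]), roc_auc = auc)
  }))

  final <- fitter(x, y)
  structure(list(algorithm = if (is.function(algorithm)) "custom"
                             else algorithm,
                 fit = final, levels = levels(y),
                 report = list(cv_logloss = cv_ll,
                               baseline_logloss = base_ll,
                               improvement_pct =
                                 baseline_improvement(cv_ll, base_ll),
                               n_folds = k, per_class = per_class)),
            class = "ce_classifier")
}

#' Predict class probabilities or classes
#'
#' @param object a [train_classifier()] model.
#' @param newdata feature matrix with the training columns.
#' @param type `"prob"` (default) or `"class"`.
#' @param ... unused.
#' @return Probability matrix (rows sum to 1) or character vector of
#'   classes.
#' @export
predict.ce_classifier <- function(object, newdata, type = c("prob", "class"),
                                  ...) {
  type <- match.arg(type)
  p <- object$fit$predict_prob(object$fit$fit, as.matrix(newdata))
  colnames(p) <- object$levels
  if (type == "prob") p else object$levels[max.col(p, ties.method = "first")]
}

#' @export
print.ce_classifier <- function(x, ...) {
  r <- x$report
  cat(sprintf(
    "functional-group classifier (%s): CV logloss %.4f vs baseline %.4f (%.1f%% improvement, %d folds)\n",
    x$algorithm, r$cv_logloss, r$baseline_logloss, r$improvement_pct,
    r$n_folds))
  invisible(x)
}

#' Classify a cohort and summarise the calls
#'
#' Applies a trained classifier to the profiles of a cohort, restricted to
#' the high-abundance genome set, and tabulates group counts and (when an
#' abundance table is supplied) the per-experiment distribution of calls:
#' a genome counts towards an experiment when it reaches the
#' high-abundance floor in at least one of that experiment's samples.
#'
#' @param classifier a [train_classifier()] model.
#' @param profiles list of `pathway_profile` objects (or a profile
#'   matrix).
#' @param high_abundance genome ids to classify; an empty set yields an
#'   empty result.  Every requested genome must have a profile.
#' @param abundance optional [abundance_table()] for the per-experiment
#'   breakdown.
#' @param high_floor abundance floor used for the per-experiment
#'   membership (default 1).
#' @return A list with `calls` (data frame `genome_id`, `group`, `method`,
#'   probability columns), `group_counts` and `by_experiment` (or NULL).
#' @export
classify_cohort <- function(classifier, profiles, high_abundance,
                            abundance = NULL, high_floor = 1) {
  m <- if (is.matrix(profiles)) profiles else profile_matrix(profiles)
  groups <- factor(character(0), levels = classifier$levels)
  if (length(high_abundance) == 0) {
    calls <- data.frame(genome_id = character(0), group = character(0),
                        method = character(0))
    return(list(calls = calls, group_counts = table(groups),
                by_experiment = NULL))
  }
  missing <- setdiff(high_abundance, rownames(m))
  if (length(missing))
    stop("no profile for requested genomes: ",
         paste(missing, collapse = ", "))
  m <- m[high_abundance, , drop = FALSE]
  prob <- predict(classifier, m, type = "prob")
  group <- classifier$levels[max.col(prob, ties.method = "first")]
  calls <- data.frame(genome_id = high_abundance, group = group,
                      method = "ml")
  calls <- cbind(calls, as.data.frame(prob))
  counts <- table(factor(group, levels = union(classifier$levels,
                                               ce_groups())))
  by_exp <- NULL
  if (!is.null(abundance)) {
    exps <- unique(abundance$metadata$experiment)
    by_exp <- do.call(rbind, lapply(exps, function(e) {
      cols <- abundance$metadata$sample_id[abundance$metadata$experiment == e]
      sub <- abundance$abund[, cols, drop = FALSE]
      members <- intersect(
        rownames(sub)[apply(sub >= high_floor, 1, any)], high_abundance)
      data.frame(experiment = e,
                 t(as.matrix(table(factor(
                   calls$group[match(members, calls$genome_id)],
                   levels = ce_groups())))), check.names = FALSE)
    }))
  }
  list(calls = calls, group_counts = counts, by_experiment = by_exp)
}

#' Compare rule-based and ML call sets
#'
#' For each of the three productive groups, counts genomes called by the
#' rule only, by the ML classifier only, and by both (Venn counts).
#'
#' @param rule_calls,ml_calls data frames with `genome_id` and `group`.
#' @return Data frame with columns `group`, `rule_only`, `ml_only`,
#'   `both`.
#' @export
compare_methods <- function(rule_calls, ml_calls) {
  groups <- setdiff(ce_groups(), "uninvolved")
  out <- do.call(rbind, lapply(groups, function(g) {
    r <- rule_calls$genome_id[rule_calls$group == g]
    m <- ml_calls$genome_id[ml_calls$group == g]
    data.frame(group = g, rule_only = length(setdiff(r, m)),
               ml_only = length(setdiff(m, r)),
               both = length(intersect(r, m)))
  }))
  rownames(out) <- NULL
  out
}
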