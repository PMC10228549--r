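#' Relative-abundance table
#'
#' Container for a genomes x samples matrix of relative abundances in
#' percent, a per-sample "unmapped" residual, and sample metadata.  Every
#' column must satisfy `sum(abundances) + residual == 100` within 1e-6.
#'
#' @param abund numeric matrix, rows genomes, columns samples.
#' @param residual named numeric vector of per-sample unmapped percent.
#' @param metadata data frame with columns `sample_id`, `experiment` and
#'   optionally `timepoint`.
#' @return An object of class `abundance_table`.
#' @export
abundance_table <- function(abund, residual, metadata) {
  stopifnot(is.matrix(abund), all(abund >= 0),
            identical(colnames(abund), names(residual)),
            identical(colnames(abund), metadata$sample_id))
  sums <- colSums(abund) + residual
  if (any(abs(sums - 100) > 1e-6))
    stop("column totals (abundance + residual) must equal 100")
  structure(list(abund = abund, residual = residual, metadata = metadata),
            class = "abundance_table")
}

#' @export
print.abundance_table <- function(x, ...) {
  cat("abundance table:", nrow(x$abund), "genomes x", ncol(x$abund),
      "samples,", length(unique(x$metadata$experiment)), "experiments\n")
  invisible(x)
}

#' Presence accounting and high-abundance filter
#'
#' Computes, per experiment, the set of genomes detected as present
#' (abundance strictly above `presence_floor` in at least one sample of the
#' experiment), the overall high-abundance genome set (abundance at or
#' above `high_floor` in at least one sample anywhere), and per-experiment
#' summaries of the total represented abundance (min, max and median across
#' samples of the per-sample sum of genome fractions).
#'
#' @param table an [abundance_table()].
#' @param presence_floor presence threshold in percent, exclusive
#'   (default 0).
#' @param high_floor high-abundance threshold in percent, inclusive
#'   (default 1).
#' @return A list with `present` (named list of genome id vectors per
#'   experiment), `high_abundance` (character vector) and `summary` (data
#'   frame with columns `experiment`, `n_present`, `min_total`,
#'   `max_total`, `median_total`).
#' @export
presence_and_filter <- function(table, presence_floor = 0, high_floor = 1) {
  stopifnot(inherits(table, "abundance_table"))
  if (ncol(table$abund) == 0 || nrow(table$abund) == 0)
    stop("empty abundance table")
  exps <- unique(table$metadata$experiment)
  present <- lapply(exps, function(e) {
    cols <- table$metadata$sample_id[table$metadata$experiment == e]
    sub <- table$abund[, cols, drop = FALSE]
    rownames(sub)[apply(sub > presence_floor, 1, any)]
  })
  names(present) <- exps
  high <- rownames(table$abund)[apply(table$abund >= high_floor, 1, any)]
  summ <- do.call(rbind, lapply(exps, function(e) {
    cols <- table$metadata$sample_id[table$metadata$experiment == e]
    totals <- colSums(table$abund[, cols, drop = FALSE])
    data.frame(experiment = e, n_present = length(present[[e]]),
               min_total = min(totals), max_total = max(totals),
               median_total = median(totals))
  }))
  rownames(summ) <- NULL
  list(present = present, high_abundance = high, summary = summ)
}

#' Bray-Curtis dissimilarity between two sample vectors
#'
#' `BC = 1 - 2 * sum(pmin(x, y)) / sum(x + y)`.
#'
#' @param x,y non-negative numeric vectors of equal length.
#' @return Dissimilarity in \[0, 1\].
#' @export
bray_curtis <- function(x, y) {
  stopifnot(length(x) == length(y), all(x >= 0), all(y >= 0))
  s <- sum(x) + sum(y)
  if (s == 0) return(0)
  1 - 2 * sum(pmin(x, y)) / s
}

#' Bray-Curtis distance matrix of an abundance table
#'
#' Samples are compared on their genome fractions (the unmapped residual is
#' excluded).  Uses `vegan::vegdist`.
#'
#' @param table an [abundance_table()] or a samples x features matrix.
#' @return A `dist` object over samples.
#' @export
bray_curtis_dist <- function(table) {
  m <- if (inherits(table, "abundance_table")) t(table$abund) else table
  vegan::vegdist(m, method = "bray")
}

#' Non-metric multidimensional scaling
#'
#' Minimises Kruskal stress-1,
#' `sqrt(sum((dhat - theta(d))^2) / sum(dhat^2))`, where `dhat` are the
#' configuration distances and `theta` is fitted by isotonic regression on
#' the observed dissimilarity order.  The configuration is initialised from
#' classical metric scaling (PCoA) and refined by Guttman (SMACOF) updates;
#' an update is only accepted if it lowers the stress, so the stress
#' trajectory within a restart is non-increasing by construction.
#' Additional restarts perturb the PCoA solution at random; the best
#' restart is reported.  Deterministic under `seed`.
#'
#' @param d a `dist` or a square symmetric non-negative matrix with zero
#'   diagonal.
#' @param k embedding dimension (default 2).
#' @param n_restarts number of restarts including the PCoA start
#'   (default 10).
#' @param seed integer seed.
#' @param tol stop a restart when the stress improvement falls below this
#'   (default 1e-7).
#' @param max_iter iteration cap per restart (default 300).
#' @return An object of class `magce_nmds`: `points` (n x k), `stress`,
#'   `trajectory` (accepted stress values of the best restart),
#'   `converged`, `n_restarts`.
#' @export
nmds <- function(d, k = 2, n_restarts = 10, seed = 1, tol = 1e-7,
                 max_iter = 300) {
  dm <- as.matrix(d)
  if (nrow(dm) != ncol(dm) || any(abs(dm - t(dm)) > 1e-8))
    stop("distance matrix must be square and symmetric")
  if (any(dm < 0) || any(abs(diag(dm)) > 1e-12))
    stop("distance matrix must be non-negative with zero diagonal")
  n <- nrow(dm)
  low <- lower.tri(dm)
  dvec <- dm[low]
  ord <- order(dvec)

  stress_of <- function(dhat) {
    th <- numeric(length(dhat))
    th[ord] <- isoreg(dhat[ord])$yf
    list(stress = sqrt(sum((dhat - th)^2) / sum(dhat^2)), theta = th)
  }

  run_restart <- function(X) {
    D <- as.matrix(dist(X))
    dhat <- D[low]
    if (all(dhat == 0)) return(list(X = X, stress = 0, traj = 0,
                                    converged = TRUE))
    st <- stress_of(dhat)
    traj <- st$stress
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      theta <- matrix(0, n, n)
      theta[low] <- st$theta
      theta <- theta + t(theta)
      Dsafe <- D + diag(n)
      B <- -theta / pmax(Dsafe, 1e-12)
      B[D == 0] <- 0
      diag(B) <- 0
      diag(B) <- -rowSums(B)
      Xn <- (B %*% X) / n
      Dn <- as.matrix(dist(Xn))
      dh <- Dn[low]
      if (all(dh == 0)) break
      stn <- stress_of(dh)
      cur <- traj[length(traj)]
      if (stn$stress >= cur) break
      improved <- cur - stn$stress
      X <- Xn; D <- Dn; st <- stn
      traj <- c(traj, stn$stress)
      if (improved < tol) { converged <- TRUE; break }
    }
    list(X = X, stress = traj[length(traj)], traj = traj,
         converged = converged)
  }

  with_seed(seed, {
    X0 <- cmdscale(dm, k = k)
    if (ncol(X0) < k)
      X0 <- cbind(X0, matrix(0, n, k - ncol(X0)))
    best <- NULL
    for (r in seq_len(n_restarts)) {
      X <- if (r == 1) X0 else X0 + matrix(rnorm(n * k, sd = 0.1 *
                                                  (max(dvec) + 1e-12)),
                                           n, k)
      res <- run_restart(X)
      if (is.null(best) || res$stress < best$stress) best <- res
    }
    rownames(best$X) <- rownames(dm)
    structure(list(points = best$X, stress = best$stress,
                   trajectory = best$traj, converged = best$converged,
                   n_restarts = n_restarts, k = k),
              class = "magce_nmds")
  })
}

#' @export
print.magce_nmds <- function(x, ...) {
  cat(sprintf("NMDS (k = %d): stress-1 = %.4f over %d restarts (%s)\n",
              x$k, x$stress, x$n_restarts,
              if (x$converged) "converged" else "iteration cap"))
  invisible(x)
}

#' Permutational multivariate analysis of variance
#'
#' One-factor PerMANOVA on a distance matrix.  With `SS_total =
#' sum(d^2)/N` over all pairs and `SS_within` the within-group analogue,
#' the statistic is `pseudo-F = ((SS_total - SS_within)/(a - 1)) /
#' (SS_within/(N - a))` and the p-value is `(1 + #{F_perm >= F_obs}) /
#' (1 + n_perm)` under unrestricted label permutation.
#'
#' @param d a `dist` or square symmetric matrix.
#' @param labels group labels, length = number of samples; every group
#'   needs at least 2 samples.
#' @param n_perm number of permutations (default 999).
#' @param seed integer seed.
#' @return A list with `pseudo_F`, `p_value`, `n_perm`, `df`.
#' @export
permanova <- function(d, labels, n_perm = 999, seed = 1) {
  dm <- as.matrix(d)
  labels <- as.factor(labels)
  stopifnot(nrow(dm) == length(labels))
  if (any(table(labels) < 2))
    stop("every group needs at least 2 samples")
  a <- nlevels(labels)
  if (a < 2) stop("need at least 2 groups")
  n <- nrow(dm)
  d2 <- dm^2
  li <- as.integer(labels)
  perm <- with_seed(seed, {
    t(vapply(seq_len(n_perm), function(i) sample(li), integer(n)))
  })
  Fs <- cpp_permanova_F(d2, rbind(li, perm), a)
  Fobs <- Fs[1]
  p <- (1 + sum(Fs[-1] >= Fobs)) / (1 + n_perm)
  list(pseudo_F = Fobs, p_value = p, n_perm = n_perm,
       df = c(between = a - 1, within = n - a))
}

#' Pairwise PerMANOVA with Benjamini-Hochberg adjustment
#'
#' Tests every pair of groups with [permanova()] and adjusts the raw
#' p-values with the Benjamini-Hochberg step-up procedure.
#'
#' @inheritParams permanova
#' @param alpha significance level applied to the adjusted p-values
#'   (default 0.05).
#' @return Data frame with columns `group1`, `group2`, `pseudo_F`, `p`,
#'   `p_adj`, `significant`.
#' @export
pairwise_permanova_bh <- function(d, labels, n_perm = 999, seed = 1,
                                  alpha = 0.05) {
  dm <- as.matrix(d)
  labels <- as.factor(labels)
  lev <- levels(labels)
  pairs <- utils::combn(lev, 2)
  res <- lapply(seq_len(ncol(pairs)), function(i) {
    keep <- labels %in% pairs[, i]
    pm <- permanova(dm[keep, keep, drop = FALSE], droplevels(labels[keep]),
                    n_perm = n_perm, seed = sub_seed(seed, i))
    data.frame(group1 = pairs[1, i], group2 = pairs[2, i],
               pseudo_F = pm$pseudo_F, p = pm$p_value)
  })
  out <- do.call(rbind, res)
  out$p_adj <- p.adjust(out$p, method = "BH")
  out$significant <- out$p_adj < alpha
  out
}
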