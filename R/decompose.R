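#' Build the participant-by-condition waveform matrix
#'
#' Rows are trial-averaged, baseline-corrected epochs per participant and
#' tone condition (boundary, same-context), columns are timepoints — with 65
#' participants this is the 130-row input of the temporal PCA. Cells with
#' fewer than `cfg$min_trials` trials are dropped with a warning, and
#' participants missing one of the two conditions entirely are dropped and
#' logged.
#'
#' @param epochs An `epoch_matrix`.
#' @param cfg An [analysis_config]; `pca_window_ms` selects the 3-s or 1.5-s
#'   sampling window.
#' @param conditions Conditions entering the matrix.
#' @return A list of class `waveform_matrix`: `x` (rows x timepoints), `keys`
#'   (participant, condition, n_trials per row), `times_ms`.
#' @export
build_waveform_matrix <- function(epochs, cfg = analysis_config(),
                                  conditions = c("boundary", "same_context")) {
  sel_t <- epochs$times_ms >= cfg$epoch_window_ms[1] &
    epochs$times_ms < cfg$epoch_window_ms[1] + cfg$pca_window_ms
  keep <- epochs$info$tone_condition %in% conditions
  info <- epochs$info[keep, , drop = FALSE]
  x <- epochs$x[keep, sel_t, drop = FALSE]
  key <- interaction(info$participant, info$tone_condition, drop = TRUE)
  groups <- split(seq_len(nrow(info)), key)
  n_tr <- vapply(groups, length, integer(1))
  small <- n_tr < cfg$min_trials
  if (any(small)) {
    .warn(sprintf("build_waveform_matrix: dropping %d cell(s) with < %d trials",
                  sum(small), cfg$min_trials))
    groups <- groups[!small]
  }
  rows <- t(vapply(groups, function(idx) colMeans(x[idx, , drop = FALSE]),
                   numeric(ncol(x))))
  keys <- data.frame(
    participant = vapply(groups, function(idx) info$participant[idx[1]], character(1)),
    condition = vapply(groups, function(idx) info$tone_condition[idx[1]], character(1)),
    n_trials = vapply(groups, length, integer(1)), row.names = NULL)
  if (length(conditions) > 1) {
    counts <- table(keys$participant)
    incomplete <- names(counts)[counts < length(conditions)]
    if (length(incomplete) > 0) {
      .warn(sprintf("build_waveform_matrix: dropping participant(s) missing a condition: %s",
                    paste(incomplete, collapse = ", ")))
      keep_row <- !(keys$participant %in% incomplete)
      rows <- rows[keep_row, , drop = FALSE]
      keys <- keys[keep_row, , drop = FALSE]
    }
  }
  ord <- order(keys$participant, keys$condition)
  structure(list(x = rows[ord, , drop = FALSE], keys = keys[ord, ],
                 times_ms = epochs$times_ms[sel_t]),
            class = "waveform_matrix")
}

#' Unrestricted PCA on the timepoint covariance matrix
#'
#' Eigendecomposition of the timepoint-by-timepoint covariance of the row
#' waveforms (column means removed). Unrotated loadings are scaled to the raw
#' covariance metric, `loading_j = eigenvector_j * sqrt(lambda_j)`, so
#' loading waveforms are in the units of the input. Numerically zero
#' eigenvalues (<= 1e-10 of the trace) are truncated.
#'
#' @param wm A `waveform_matrix` (or a plain matrix, rows = observations).
#' @return A list: `eigenvalues` (descending, positive spectrum),
#'   `loadings` (timepoints x components), `center` (column means),
#'   `trace` (total variance).
#' @export
covariance_pca <- function(wm) {
  x <- if (inherits(wm, "waveform_matrix")) wm$x else as.matrix(wm)
  .assert(nrow(x) >= 2, "covariance PCA needs at least 2 rows")
  center <- colMeans(x)
  xc <- sweep(x, 2, center)
  # eigen on the n x n inner-product matrix when n << p (identical nonzero
  # spectrum, much cheaper than the p x p covariance for 750 timepoints)
  n <- nrow(xc); p <- ncol(xc)
  if (n < p) {
    g <- tcrossprod(xc) / (n - 1)
    eg <- eigen(g, symmetric = TRUE)
    tot <- sum(diag(g))
    pos <- eg$values > 1e-10 * tot
    lam <- eg$values[pos]
    vec <- crossprod(xc, eg$vectors[, pos, drop = FALSE])
    vec <- sweep(vec, 2, sqrt(colSums(vec^2)), "/")
  } else {
    cv <- crossprod(xc) / (n - 1)
    eg <- eigen(cv, symmetric = TRUE)
    tot <- sum(diag(cv))
    pos <- eg$values > 1e-10 * tot
    lam <- eg$values[pos]
    vec <- eg$vectors[, pos, drop = FALSE]
  }
  loadings <- sweep(vec, 2, sqrt(lam), "*")
  list(eigenvalues = lam, loadings = loadings, center = center, trace = tot)
}

#' Number of components to retain
#'
#' `mean_eigenvalue`: retain eigenvalues at or above the mean of the positive
#' spectrum — the Kaiser criterion analogue appropriate for covariance-metric
#' PCA (for a correlation matrix the mean eigenvalue is exactly 1).
#' `unit_eigenvalue`: retain eigenvalues > 1 (only meaningful for
#' correlation-metric input).
#'
#' @param eigenvalues Descending positive eigenvalues.
#' @param rule Retention rule.
#' @return Integer `k >= 1` (forced to 1 with a warning if the rule retains
#'   nothing).
#' @export
retain_components <- function(eigenvalues, rule = c("mean_eigenvalue", "unit_eigenvalue")) {
  rule <- match.arg(rule)
  .assert(length(eigenvalues) >= 1 && eigenvalues[1] > 0,
          "need at least one positive eigenvalue")
  k <- switch(rule,
              mean_eigenvalue = sum(eigenvalues >= mean(eigenvalues)),
              unit_eigenvalue = sum(eigenvalues > 1))
  if (k == 0) {
    .warn("retention rule kept no component; forcing k = 1")
    k <- 1L
  }
  as.integer(k)
}

#' Varimax rotation with Kaiser normalization
#'
#' Orthogonal rotation maximizing the varimax criterion (the summed variance
#' of squared loadings per component), optionally after Kaiser normalization
#' (rows scaled to unit communality before rotation and unscaled after).
#' Uses the standard SVD-based iteration. The rotated solution is
#' canonicalized: each component's sign is fixed so its extremum is positive,
#' and components are reordered by descending sum of squared loadings.
#'
#' @param loadings Timepoints x k unrotated loadings.
#' @param kaiser_normalize Apply Kaiser normalization?
#' @param tol Relative convergence tolerance on the criterion.
#' @param max_iter Maximum iterations; on non-convergence the best iterate is
#'   returned with `converged = FALSE` and a warning.
#' @return A list: `loadings` (rotated, canonicalized), `rotation` (orthogonal
#'   matrix such that `input %*% rotation = rotated`), `converged`,
#'   `iterations`.
#' @export
varimax_rotate <- function(loadings, kaiser_normalize = TRUE, tol = 1e-8,
                           max_iter = 1000L) {
  x <- as.matrix(loadings)
  k <- ncol(x)
  .assert(k >= 1, "need at least one component")
  if (k == 1) {
    res <- list(loadings = x, rotation = matrix(1, 1, 1), converged = TRUE,
                iterations = 0L)
    return(.canonicalize(res))
  }
  p <- nrow(x)
  sc <- rep(1, p)
  if (kaiser_normalize) {
    sc <- sqrt(rowSums(x^2))
    sc[sc == 0] <- 1
    x <- x / sc
  }
  # Kaiser's pairwise planar rotations: for each column pair the optimal
  # angle has a closed form, so each update is an exact 2-d maximization
  # (robust to the saddle points that stall gradient-style iterations)
  z <- x
  rot <- diag(k)
  p <- nrow(x)
  crit <- varimax_criterion(z)
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    for (a in seq_len(k - 1)) for (b in (a + 1):k) {
      u <- z[, a]^2 - z[, b]^2
      v <- 2 * z[, a] * z[, b]
      num <- 2 * (sum(u * v) - sum(u) * sum(v) / p)
      den <- sum(u^2 - v^2) - (sum(u)^2 - sum(v)^2) / p
      theta <- atan2(num, den) / 4
      if (abs(theta) < 1e-15) next
      g <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
      z[, c(a, b)] <- z[, c(a, b)] %*% g
      rot[, c(a, b)] <- rot[, c(a, b)] %*% g
    }
    new_crit <- varimax_criterion(z)
    if (new_crit - crit < tol * (abs(crit) + 1e-12)) { converged <- TRUE; break }
    crit <- new_crit
  }
  if (!converged) .warn(sprintf("varimax did not converge in %d sweeps", max_iter))
  rotated <- z * sc
  .canonicalize(list(loadings = rotated, rotation = rot, converged = converged,
                     iterations = iter))
}

# fix component signs (extremum positive) and order (descending sum of
# squared loadings); the rotation matrix is adjusted to stay consistent
.canonicalize <- function(res) {
  x <- res$loadings
  signs <- vapply(seq_len(ncol(x)), function(j) {
    v <- x[, j]
    s <- sign(v[which.max(abs(v))])
    if (s == 0) 1 else s
  }, numeric(1))
  x <- sweep(x, 2, signs, "*")
  ord <- order(colSums(x^2), decreasing = TRUE)
  res$loadings <- x[, ord, drop = FALSE]
  res$rotation <- sweep(res$rotation, 2, signs, "*")[, ord, drop = FALSE]
  res
}

#' Varimax criterion value
#'
#' The raw varimax objective — the sum over components of the variance of
#' squared loadings — used by the rotation and by brute-force oracles.
#'
#' @param x Loadings matrix.
#' @return Scalar criterion value.
#' @export
varimax_criterion <- function(x) {
  sum(apply(x^2, 2, function(v) mean(v^2) - mean(v)^2))
}

#' Component scores
#'
#' Least-squares regression scores of the centered row waveforms on the
#' rotated loading waveforms (default), or correlation-weighted scores
#' (`x_centered %*% loadings`). Scores have zero mean across rows per
#' component by construction.
#'
#' @param wm The `waveform_matrix` the solution came from.
#' @param solution A `component_solution` (or a loadings matrix).
#' @param method `"regression"` or `"correlation"`.
#' @return Rows x k score matrix with row keys as attributes.
#' @export
component_scores <- function(wm, solution, method = c("regression", "correlation")) {
  method <- match.arg(method)
  x <- if (inherits(wm, "waveform_matrix")) wm$x else as.matrix(wm)
  l <- if (is.list(solution)) solution$loadings else as.matrix(solution)
  .assert(nrow(l) == ncol(x), "loadings do not match matrix dimensionality")
  xc <- sweep(x, 2, colMeans(x))
  if (method == "regression") {
    gram <- crossprod(l)
    gi <- tryCatch(solve(gram), error = function(e) {
      .warn("singular loading Gram matrix; using pseudo-inverse")
      sv <- svd(gram)
      pos <- sv$d > max(sv$d) * 1e-12
      sv$v[, pos, drop = FALSE] %*% diag(1 / sv$d[pos], sum(pos)) %*%
        t(sv$u[, pos, drop = FALSE])
    })
    scores <- xc %*% l %*% gi
  } else {
    scores <- xc %*% sweep(l, 2, colSums(l^2), "/")
  }
  colnames(scores) <- paste0("c", seq_len(ncol(scores)))
  scores
}

#' Summarize a component solution
#'
#' Per component: peak latency (time of the maximum absolute loading) and
#' percent variance, reported both against the total waveform variance
#' (`pct_variance_total`) and against the variance captured by the retained
#' set (`pct_variance_retained`).
#'
#' @param solution A `component_solution`.
#' @return A data frame with one row per component.
#' @export
summarize_components <- function(solution) {
  l <- solution$loadings
  ss <- colSums(l^2)
  data.frame(
    component = seq_len(ncol(l)),
    peak_latency_ms = solution$times_ms[apply(abs(l), 2, which.max)],
    pct_variance_total = 100 * ss / solution$trace,
    pct_variance_retained = 100 * ss / sum(ss))
}

#' Temporal PCA of pupil waveforms
#'
#' The full decomposition pathway: waveform matrix (trial-averaged
#' participant-condition epochs over the configured window), covariance-metric
#' PCA, component retention, Kaiser-normalized Varimax rotation, component
#' scores, and summaries.
#'
#' @param epochs An `epoch_matrix`.
#' @param cfg An [analysis_config]; `pca_window_ms` (3000 or 1500) sets the
#'   sampling window and `retention_rule` the retention criterion.
#' @param conditions Conditions entering the matrix (both by default; a
#'   single condition gives the condition-split variant).
#' @return An object of class `component_solution`: `loadings` (timepoints x
#'   k, raw units), `eigenvalues` (full positive spectrum before rotation),
#'   `k`, `scores` (rows x k), `keys` (row keys), `times_ms`, `trace`,
#'   `rotation`, `converged`, `summary` (from [summarize_components]),
#'   `retention_rule`.
#' @export
temporal_pca <- function(epochs, cfg = analysis_config(),
                         conditions = c("boundary", "same_context")) {
  wm <- build_waveform_matrix(epochs, cfg, conditions = conditions)
  pca <- covariance_pca(wm)
  k <- retain_components(pca$eigenvalues, cfg$retention_rule)
  rot <- varimax_rotate(pca$loadings[, seq_len(k), drop = FALSE])
  sol <- structure(list(
    loadings = rot$loadings,
    rotation = rot$rotation,
    unrotated = pca$loadings[, seq_len(k), drop = FALSE],
    eigenvalues = pca$eigenvalues,
    k = k,
    trace = pca$trace,
    times_ms = wm$times_ms,
    keys = wm$keys,
    converged = rot$converged,
    retention_rule = cfg$retention_rule), class = "component_solution")
  sol$scores <- component_scores(wm, sol, method = cfg$score_method)
  sol$summary <- summarize_components(sol)
  sol
}

#' @rdname temporal_pca
#' @param condition Single condition for the split analysis.
#' @export
condition_split_pca <- function(epochs, condition, cfg = analysis_config()) {
  .assert(condition %in% c("boundary", "same_context"),
          "condition must be boundary or same_context")
  temporal_pca(epochs, cfg, conditions = condition)
}

#' @export
print.component_solution <- function(x, ...) {
  cat(sprintf("<component_solution> k = %d (%s), %d rows x %d timepoints%s\n",
              x$k, x$retention_rule, nrow(x$scores), nrow(x$loadings),
              if (x$converged) "" else " [rotation did not converge]"))
  print(x$summary, row.names = FALSE)
  invisible(x)
}
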