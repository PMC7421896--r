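#' Score the temporal order memory test
#'
#' Proportion of correct recency discriminations per participant and pair
#' condition (boundary-spanning vs same-context).
#'
#' @param outcomes A [memory_outcomes] object.
#' @return Data frame: participant, pair_condition, n, prop_correct.
#' @export
score_order <- function(outcomes) {
  p <- outcomes$pairs
  agg <- aggregate(order_correct ~ participant + pair_condition, p,
                   function(v) c(n = length(v), prop = mean(v)))
  data.frame(participant = agg$participant, pair_condition = agg$pair_condition,
             n = agg$order_correct[, "n"], prop_correct = agg$order_correct[, "prop"])
}

#' Score the temporal distance ratings
#'
#' Mean 1-4 rating (very close ... very far) per participant and pair
#' condition.
#'
#' @param outcomes A [memory_outcomes] object.
#' @return Data frame: participant, pair_condition, n, mean_rating.
#' @export
score_distance <- function(outcomes) {
  p <- outcomes$pairs
  .assert(all(p$distance_rating %in% 1:4), "distance rating outside 1..4",
          "pupilbound_data_error")
  agg <- aggregate(distance_rating ~ participant + pair_condition, p,
                   function(v) c(n = length(v), m = mean(v)))
  data.frame(participant = agg$participant, pair_condition = agg$pair_condition,
             n = agg$distance_rating[, "n"], mean_rating = agg$distance_rating[, "m"])
}

#' Score the auditory source memory test
#'
#' Proportion of correctly remembered tone ears per participant and item type
#' (boundary, same-context, first, last).
#'
#' @param outcomes A [memory_outcomes] object.
#' @return Data frame: participant, item_type, n, prop_correct.
#' @export
score_source <- function(outcomes) {
  it <- outcomes$items
  agg <- aggregate(source_correct ~ participant + item_type, it,
                   function(v) c(n = length(v), prop = mean(v)))
  data.frame(participant = agg$participant, item_type = agg$item_type,
             n = agg$source_correct[, "n"], prop_correct = agg$source_correct[, "prop"])
}

#' One-way repeated-measures ANOVA
#'
#' Univariate within-subject decomposition with partial eta squared and a
#' Greenhouse-Geisser corrected p-value, plus the multivariate (Hotelling)
#' test on the difference contrasts, whose F(k-1, n-k+1) degrees of freedom
#' match the convention some statistics packages report for within-subject
#' factors. Both conventions are returned.
#'
#' @param values Numeric outcome.
#' @param subject Subject factor.
#' @param condition Within-subject condition factor.
#' @return A list: `univariate` (F, df1, df2, p, eta_sq_partial, gg_epsilon,
#'   p_gg), `multivariate` (F, df1, df2, p), `n`.
#' @export
rm_anova <- function(values, subject, condition) {
  subject <- factor(subject); condition <- factor(condition)
  wide <- tapply(values, list(subject, condition), mean)
  .assert(!anyNA(wide), "rm_anova requires complete cells",
          "pupilbound_insufficient_data")
  n <- nrow(wide); a <- ncol(wide)
  grand <- mean(wide)
  ss_cond <- n * sum((colMeans(wide) - grand)^2)
  ss_subj <- a * sum((rowMeans(wide) - grand)^2)
  ss_tot <- sum((wide - grand)^2)
  ss_err <- ss_tot - ss_cond - ss_subj
  df1 <- a - 1; df2 <- (a - 1) * (n - 1)
  ms_cond <- ss_cond / df1; ms_err <- ss_err / df2
  f_uni <- if (ms_err > 0) ms_cond / ms_err else if (ms_cond == 0) 0 else Inf
  # Greenhouse-Geisser epsilon from the double-centered covariance
  s <- cov(wide)
  dc <- s - outer(rowMeans(s), colMeans(s), "+") + mean(s)
  eps <- sum(diag(dc))^2 / (df1 * sum(dc^2))
  eps <- min(1, max(1 / df1, eps))
  p_uni <- if (is.finite(f_uni)) pf(f_uni, df1, df2, lower.tail = FALSE) else 0
  p_gg <- if (is.finite(f_uni)) pf(f_uni, df1 * eps, df2 * eps, lower.tail = FALSE) else 0
  uni <- list(F = f_uni, df1 = df1, df2 = df2, p = p_uni,
              eta_sq_partial = if (ss_cond + ss_err > 0) ss_cond / (ss_cond + ss_err) else 0,
              gg_epsilon = eps, p_gg = p_gg)
  # multivariate: Hotelling T^2 on successive difference contrasts
  multi <- tryCatch({
    d <- wide[, -1, drop = FALSE] - wide[, -a, drop = FALSE]
    m <- colMeans(d); sv <- cov(d)
    t2 <- n * drop(crossprod(m, solve(sv, m)))
    fm <- (n - a + 1) / ((a - 1) * (n - 1)) * t2
    list(F = fm, df1 = a - 1, df2 = n - a + 1,
         p = pf(fm, a - 1, n - a + 1, lower.tail = FALSE))
  }, error = function(e) list(F = NA_real_, df1 = a - 1, df2 = n - a + 1, p = NA_real_))
  list(univariate = uni, multivariate = multi, n = n)
}

#' Condition tests for the three memory measures
#'
#' Boundary vs same-context paired t-tests for order accuracy and distance
#' ratings (with dz and CI), one-sample tests of order accuracy against
#' chance (0.5) per condition, and a one-way repeated-measures ANOVA over the
#' four source item types followed by Bonferroni-adjusted pairwise paired
#' comparisons (family = the 6 pairwise tests). Participants with missing
#' cells are excluded listwise per analysis, with a warning.
#'
#' @param outcomes A [memory_outcomes] object.
#' @return A nested list: `order` (contrast, vs_chance), `distance`
#'   (contrast), `source` (anova, pairwise).
#' @export
condition_tests <- function(outcomes) {
  ord <- score_order(outcomes)
  dst <- score_distance(outcomes)
  src <- score_source(outcomes)

  pairwide <- function(df, value) {
    w <- tapply(df[[value]], list(df$participant, df$pair_condition), mean)
    complete <- !apply(is.na(w), 1, any)
    if (any(!complete))
      .warn(sprintf("excluding %d participant(s) with missing cells", sum(!complete)))
    w[complete, , drop = FALSE]
  }
  ow <- pairwide(ord, "prop_correct")
  dw <- pairwide(dst, "mean_rating")

  order_res <- list(
    contrast = paired_contrast(ow[, "boundary_span"], ow[, "same_context"]),
    vs_chance = list(
      boundary_span = against_baseline(ow[, "boundary_span"], mu = 0.5),
      same_context = against_baseline(ow[, "same_context"], mu = 0.5)))
  distance_res <- list(
    contrast = paired_contrast(dw[, "boundary_span"], dw[, "same_context"]))

  sw <- tapply(src$prop_correct, list(src$participant, src$item_type), mean)
  complete <- !apply(is.na(sw), 1, any)
  if (any(!complete))
    .warn(sprintf("excluding %d participant(s) with missing source cells", sum(!complete)))
  sw <- sw[complete, , drop = FALSE]
  long <- data.frame(participant = rep(rownames(sw), times = ncol(sw)),
                     item_type = rep(colnames(sw), each = nrow(sw)),
                     prop = as.vector(sw))
  anova_res <- rm_anova(long$prop, long$participant, long$item_type)
  combos <- utils::combn(colnames(sw), 2)
  pairwise <- lapply(seq_len(ncol(combos)), function(j) {
    a <- combos[1, j]; b <- combos[2, j]
    ct <- paired_contrast(sw[, a], sw[, b])
    ct$p_bonferroni <- if (is.na(ct$p)) NA_real_ else min(1, ct$p * ncol(combos))
    c(list(type_a = a, type_b = b), ct)
  })
  list(order = order_res, distance = distance_res,
       source = list(anova = anova_res, pairwise = pairwise))
}
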