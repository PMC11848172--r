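#' ROC analysis of a staging score
#'
#' AUC via the Mann-Whitney rank statistic with midrank tie handling, plus the
#' full (threshold, sensitivity, specificity) curve. Orientation is fixed by
#' convention, not by the data: for thickness and volume scores the more
#' advanced stage is the positive class and *lower* scores are read as more
#' advanced (`direction = "lower"`), so an effect in the expected direction
#' yields AUC >= 0.5. The stored curve's trapezoidal area equals the rank AUC.
#'
#' @param scores Numeric scores, one per subject.
#' @param labels Logical (or 0/1) positive-class indicator (more advanced
#'   stage = `TRUE`).
#' @param direction `"lower"` (default): lower score means more advanced;
#'   `"higher"`: the reverse.
#' @return `roc_result`: list with `auc`, `curve` (data frame `threshold`,
#'   `sensitivity`, `specificity`), `direction`, `n_pos`, `n_neg`, and the
#'   inputs (`scores`, `labels`) for paired AUC comparison.
#' @export
roc_auc <- function(scores, labels, direction = c("lower", "higher")) {
  direction <- match.arg(direction)
  labels <- as.logical(labels)
  if (length(scores) != length(labels)) stopf("scores/labels length mismatch")
  if (anyNA(scores) || anyNA(labels)) stopf("scores/labels must not be NA")
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L)
    stopf("both classes must be present (n_pos = %d, n_neg = %d)",
          n_pos, n_neg)
  s <- if (direction == "lower") -scores else scores
  r <- rank(s)                                   # midranks
  auc <- (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  # curve: classify positive when oriented score >= threshold
  thr <- c(Inf, sort(unique(s), decreasing = TRUE))
  sens <- vapply(thr, function(th) mean(s[labels] >= th), numeric(1))
  spec <- vapply(thr, function(th) mean(s[!labels] < th), numeric(1))
  curve <- data.frame(
    threshold = if (direction == "lower") -thr else thr,
    sensitivity = sens, specificity = spec)
  structure(list(auc = auc, curve = curve, direction = direction,
                 n_pos = n_pos, n_neg = n_neg,
                 scores = scores, labels = labels),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("roc_result: AUC = %.3f (%d positive / %d negative, %s-score positive)\n",
              x$auc, x$n_pos, x$n_neg, x$direction))
  invisible(x)
}

# DeLong structural components: placements of each positive among negatives
# and vice versa, on oriented scores (higher = more positive).
delong_placements <- function(scores, labels, direction) {
  s <- if (direction == "lower") -scores else scores
  x <- s[labels]; y <- s[!labels]
  psi <- function(a, b) (a > b) + 0.5 * (a == b)
  v10 <- vapply(x, function(xi) mean(psi(xi, y)), numeric(1))
  v01 <- vapply(y, function(yj) mean(psi(x, yj)), numeric(1))
  list(theta = mean(v10), v10 = v10, v01 = v01)
}

#' Compare two AUCs
#'
#' Paired comparison (same subjects scored by two markers) uses the DeLong
#' test on the correlated structural components; unpaired comparison uses a
#' bootstrap z test on the AUC difference.
#'
#' @param roc_a,roc_b [roc_auc()] results. For `paired = TRUE` they must hold
#'   the same subjects in the same order (identical labels).
#' @param paired Logical; default `TRUE`.
#' @param n_boot Bootstrap replicates for the unpaired test (default 2000).
#' @param seed Seed for the bootstrap.
#' @return List with `p_value`, `statistic` (z), `auc` (the two AUCs) and
#'   `method` (`"delong"` or `"bootstrap"`).
#' @export
compare_aucs <- function(roc_a, roc_b, paired = TRUE, n_boot = 2000L,
                         seed = 1L) {
  if (paired) {
    if (!identical(roc_a$labels, roc_b$labels))
      stopf("paired comparison requires identical subjects/labels")
    pa <- delong_placements(roc_a$scores, roc_a$labels, roc_a$direction)
    pb <- delong_placements(roc_b$scores, roc_b$labels, roc_b$direction)
    m <- roc_a$n_pos; n <- roc_a$n_neg
    s10 <- stats::var(pa$v10) + stats::var(pb$v10) -
      2 * stats::cov(pa$v10, pb$v10)
    s01 <- stats::var(pa$v01) + stats::var(pb$v01) -
      2 * stats::cov(pa$v01, pb$v01)
    v <- s10 / m + s01 / n
    z <- if (v <= 0) 0 else (pa$theta - pb$theta) / sqrt(v)
    return(list(p_value = 2 * stats::pnorm(-abs(z)), statistic = z,
                auc = c(roc_a$auc, roc_b$auc), method = "delong"))
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  boot_one <- function(roc) {
    pos <- roc$scores[roc$labels]; neg <- roc$scores[!roc$labels]
    vapply(seq_len(n_boot), function(i) {
      roc_auc(c(sample(pos, replace = TRUE), sample(neg, replace = TRUE)),
              rep(c(TRUE, FALSE), c(length(pos), length(neg))),
              direction = roc$direction)$auc
    }, numeric(1))
  }
  da <- boot_one(roc_a); db <- boot_one(roc_b)
  se <- stats::sd(da - db)
  z <- if (se == 0) 0 else (roc_a$auc - roc_b$auc) / se
  list(p_value = 2 * stats::pnorm(-abs(z)), statistic = z,
       auc = c(roc_a$auc, roc_b$auc), method = "bootstrap")
}
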