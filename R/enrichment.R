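# Early-recognition and global enrichment statistics over labelled screen
# records: ROC/AUC, enrichment factors, and BEDROC (exponentially weighted
# early recognition, sensitivity parameter alpha).

prepare_ranked <- function(records, collapse = TRUE) {
  records <- records[records$label %in% c("active", "decoy"), , drop = FALSE]
  if (collapse) records <- collapse_best_pose(records)
  if (sum(records$label == "active") == 0) {
    abort("enrichment metrics are undefined without active records")
  }
  # rank 1 = best score; ties share the mean rank
  records$rank <- rank(-records$score, ties.method = "average")
  records
}

#' BEDROC early-recognition metric
#'
#' Boltzmann-enhanced discrimination of ROC. With `N` records, `n` actives
#' at ranks `r_i` (1 = best, ties resolved to the mean rank) and
#' `Ra = n/N`:
#' `RIE = (sum_i exp(-alpha r_i / N) / n) / ((1/N)(1 - exp(-alpha)) / (exp(alpha/N) - 1))`
#' and
#' `BEDROC = RIE * Ra sinh(alpha/2) / (cosh(alpha/2) - cosh(alpha/2 - alpha Ra)) + 1 / (1 - exp(alpha (1 - Ra)))`.
#' The all-active limit (`Ra = 1`) is defined as 1.
#'
#' @param records Screen-record table with `active`/`decoy` labels
#'   (`unknown` rows are dropped).
#' @param alpha Early-recognition sensitivity (default 20, weighting roughly
#'   the top 8% of the ranking).
#' @param collapse Collapse to one best-pose row per compound first
#'   (default TRUE, matching compound-level selection).
#' @return BEDROC in `(0, 1]`.
#' @export
bedroc <- function(records, alpha = 20, collapse = TRUE) {
  if (alpha <= 0) abort("alpha must be positive")
  rec <- prepare_ranked(records, collapse)
  N <- nrow(rec)
  r <- rec$rank[rec$label == "active"]
  n <- length(r)
  if (n == N) return(1)
  ra <- n / N
  rie <- (sum(exp(-alpha * r / N)) / n) /
         ((1 / N) * (1 - exp(-alpha)) / (exp(alpha / N) - 1))
  rie * ra * sinh(alpha / 2) /
    (cosh(alpha / 2) - cosh(alpha / 2 - alpha * ra)) +
    1 / (1 - exp(alpha * (1 - ra)))
}

#' Rank-based ROC AUC
#'
#' Midrank (Mann-Whitney) AUC: the probability that a random active
#' outscores a random decoy, ties counting one half.
#'
#' @inheritParams bedroc
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(records, collapse = TRUE) {
  rec <- prepare_ranked(records, collapse)
  n <- sum(rec$label == "active")
  m <- sum(rec$label == "decoy")
  if (m == 0) abort("AUC is undefined without decoy records")
  # ascending ranks for the Mann-Whitney U statistic
  asc <- rank(rec$score, ties.method = "average")
  u <- sum(asc[rec$label == "active"]) - n * (n + 1) / 2
  u / (n * m)
}

#' ROC curve points
#'
#' Step curve from the ranked records; tied scores advance as a single
#' segment. Starts at (0, 0) and ends at (1, 1).
#'
#' @inheritParams bedroc
#' @return Tibble with `fpr` and `tpr` columns, both monotone nondecreasing.
#' @export
roc_points <- function(records, collapse = TRUE) {
  rec <- prepare_ranked(records, collapse)
  n <- sum(rec$label == "active")
  m <- sum(rec$label == "decoy")
  if (m == 0) abort("a ROC curve needs decoy records")
  steps <- rec %>%
    group_by(.data$score) %>%
    summarise(tp = sum(.data$label == "active"),
              fp = sum(.data$label == "decoy"), .groups = "drop") %>%
    arrange(desc(.data$score))
  tibble(fpr = c(0, cumsum(steps$fp) / m), tpr = c(0, cumsum(steps$tp) / n))
}

#' Enrichment factor at a top fraction
#'
#' `EF = (actives in the top ceiling(fraction N) records / that bin size) /
#' (n / N)`; 1 means no enrichment over random.
#'
#' @inheritParams bedroc
#' @param fraction Top fraction of the ranking, in `(0, 1]`.
#' @return The enrichment factor.
#' @export
enrichment_factor <- function(records, fraction = 0.01, collapse = TRUE) {
  if (fraction <= 0 || fraction > 1) abort("fraction must lie in (0, 1]")
  rec <- prepare_ranked(records, collapse)
  N <- nrow(rec)
  n <- sum(rec$label == "active")
  k <- ceiling(fraction * N)
  top <- rec %>% arrange(.data$rank, .data$compound_id) %>% head(k)
  (sum(top$label == "active") / k) / (n / N)
}

#' Full enrichment summary of a labelled screen
#'
#' Computes AUC, BEDROC and enrichment factors in one pass and keeps the
#' ROC points for plotting.
#'
#' @inheritParams bedroc
#' @param ef_fractions Fractions at which to report enrichment factors.
#' @return An `enrichment_result` with [tidy()], [glance()] and
#'   [autoplot()] methods.
#' @export
enrich <- function(records, alpha = 20, ef_fractions = c(0.01, 0.05, 0.1),
                   collapse = TRUE) {
  rec <- prepare_ranked(records, collapse)
  structure(list(
    auc = roc_auc(rec, collapse = FALSE),
    bedroc = bedroc(rec, alpha = alpha, collapse = FALSE),
    alpha = alpha,
    ef = tibble(fraction = ef_fractions,
                ef = map_dbl(ef_fractions, ~ enrichment_factor(rec, .x, collapse = FALSE))),
    roc = roc_points(rec, collapse = FALSE),
    n_active = sum(rec$label == "active"),
    n_decoy = sum(rec$label == "decoy")
  ), class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("<enrichment_result> %d actives / %d decoys\n", x$n_active, x$n_decoy))
  cat(sprintf("  AUC %.4f | BEDROC%g %.4f\n", x$auc, x$alpha, x$bedroc))
  for (i in seq_len(nrow(x$ef))) {
    cat(sprintf("  EF@%g%% %.2f\n", 100 * x$ef$fraction[i], x$ef$ef[i]))
  }
  invisible(x)
}

#' @export
tidy.enrichment_result <- function(x, ...) x$roc

#' @export
glance.enrichment_result <- function(x, ...) {
  ef_wide <- setNames(as.list(x$ef$ef), paste0("ef_", x$ef$fraction))
  as_tibble(c(list(auc = x$auc, bedroc = x$bedroc, alpha = x$alpha,
                   n_active = x$n_active, n_decoy = x$n_decoy), ef_wide))
}

#' Plot a ROC curve
#'
#' @param object An `enrichment_result`.
#' @param semilog_x Log-scale the false-positive axis (the standard view for
#'   early recognition).
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.enrichment_result <- function(object, semilog_x = FALSE, ...) {
  df <- object$roc
  g <- ggplot(df, aes(x = .data$fpr, y = .data$tpr)) +
    geom_step() +
    geom_abline(slope = 1, intercept = 0, linetype = "dotted", colour = "grey") +
    labs(x = "False positive rate", y = "True positive rate",
         title = sprintf("AUC %.3f, BEDROC%g %.3f", object$auc, object$alpha,
                         object$bedroc)) +
    theme_minimal()
  if (semilog_x) {
    df2 <- df[df$fpr > 0, , drop = FALSE]
    g <- ggplot(df2, aes(x = .data$fpr, y = .data$tpr)) +
      geom_step() + scale_x_log10() +
      labs(x = "False positive rate (log)", y = "True positive rate") +
      theme_minimal()
  }
  g
}
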