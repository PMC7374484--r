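#' Correlation / agreement result container
#'
#' @param estimate Point estimate in `[-1, 1]` (`NA` when degenerate).
#' @param ci_low,ci_high 95% confidence bounds (may be `NA`).
#' @param n Number of observations (or subjects).
#' @param df Degrees of freedom (when applicable).
#' @param statistic Test statistic (Z, S, or F depending on method).
#' @param p_value Two-sided p-value.
#' @param method Label.
#' @param degenerate `TRUE` when the estimate is undefined (e.g. zero
#'   expected disagreement or a constant vector).
#' @return A list of class `cor_result`.
#' @export
cor_result <- function(estimate, ci_low = NA_real_, ci_high = NA_real_,
                       n = NA_integer_, df = NA_real_,
                       statistic = NA_real_, p_value = NA_real_,
                       method = "", degenerate = FALSE) {
  structure(list(estimate = estimate, ci_low = ci_low, ci_high = ci_high,
                 n = n, df = df, statistic = statistic, p_value = p_value,
                 method = method, degenerate = degenerate),
            class = "cor_result")
}

#' @export
print.cor_result <- function(x, ...) {
  if (x$degenerate) {
    cat(sprintf("%s: degenerate (estimate undefined)\n", x$method))
    return(invisible(x))
  }
  ci <- if (is.na(x$ci_low)) "" else
    sprintf(" (95%% CI %.3f to %.3f)", x$ci_low, x$ci_high)
  cat(sprintf("%s: %.3f%s, %s = %s, p = %.3g\n", x$method, x$estimate, ci,
              if (!is.na(x$df)) "df" else "n",
              if (!is.na(x$df)) format(x$df) else format(x$n), x$p_value))
  invisible(x)
}

ratings_complete <- function(ratings) {
  m <- as.matrix(ratings)
  m <- m[stats::complete.cases(m), , drop = FALSE]
  mode(m) <- "character"
  m
}

#' Fleiss' kappa for multiple raters
#'
#' Chance-corrected agreement among `m` raters assigning categorical labels
#' (here: antenna IDs) to `n` subjects. Rows with any missing rating are
#' deleted. The Z statistic and p-value use the standard large-sample null
#' variance.
#'
#' @param ratings A subjects x raters matrix or data frame of categorical
#'   labels; `NA` allowed (row-wise deletion).
#' @return A [cor_result()]; `degenerate` when expected agreement is 1 (all
#'   ratings a single category).
#' @export
fleiss_kappa <- function(ratings) {
  m <- ratings_complete(ratings)
  n <- nrow(m); r <- ncol(m)
  if (r < 2) stop("Fleiss' kappa needs at least two raters")
  if (n < 2) stop("fewer than two complete subjects")
  cats <- sort(unique(as.vector(m)))
  counts <- t(apply(m, 1, function(row) table(factor(row, levels = cats))))
  counts <- matrix(as.numeric(counts), nrow = n)
  p_j <- colSums(counts) / (n * r)
  P_i <- (rowSums(counts^2) - r) / (r * (r - 1))
  P_bar <- mean(P_i)
  P_e <- sum(p_j^2)
  if (abs(1 - P_e) < 1e-12)
    return(cor_result(NA_real_, n = n, method = "Fleiss' kappa",
                      degenerate = TRUE))
  kappa <- (P_bar - P_e) / (1 - P_e)
  # large-sample null standard error (Fleiss 1971)
  spj <- sum(p_j * (1 - p_j))
  se <- sqrt(2 / (n * r * (r - 1))) *
    sqrt(spj^2 - sum(p_j * (1 - p_j) * (1 - 2 * p_j))) / spj
  z <- kappa / se
  cor_result(kappa, n = n, statistic = z,
             p_value = 2 * stats::pnorm(-abs(z)),
             method = "Fleiss' kappa")
}

#' Cohen's kappa for two ratings
#'
#' Unweighted chance-corrected agreement between two paired categorical
#' vectors (e.g. the same frames annotated twice by one observer). Pairs with
#' any missing value are deleted.
#'
#' @param r1,r2 Categorical vectors of equal length.
#' @return A [cor_result()]; `degenerate` when expected agreement is 1.
#' @export
cohen_kappa <- function(r1, r2) {
  stopifnot(length(r1) == length(r2))
  keep <- !is.na(r1) & !is.na(r2)
  r1 <- as.character(r1[keep]); r2 <- as.character(r2[keep])
  n <- length(r1)
  if (n < 2) stop("fewer than two complete pairs")
  cats <- sort(unique(c(r1, r2)))
  f1 <- factor(r1, levels = cats); f2 <- factor(r2, levels = cats)
  tab <- table(f1, f2) / n
  po <- sum(diag(tab))
  prow <- rowSums(tab); pcol <- colSums(tab)
  pe <- sum(prow * pcol)
  if (abs(1 - pe) < 1e-12)
    return(cor_result(NA_real_, n = n, method = "Cohen's kappa",
                      degenerate = TRUE))
  kappa <- (po - pe) / (1 - pe)
  # null standard error (Fleiss, Cohen & Everitt 1969)
  se0 <- sqrt((pe + pe^2 - sum(prow * pcol * (prow + pcol))) / (n * (1 - pe)^2))
  z <- kappa / se0
  cor_result(kappa, n = n, statistic = z,
             p_value = 2 * stats::pnorm(-abs(z)),
             method = "Cohen's kappa")
}

#' Spearman rank correlation with a bootstrap confidence interval
#'
#' Spearman's rho with average ranks for ties, a large-sample p-value, and a
#' seeded percentile bootstrap CI over paired resampling of (x, y).
#'
#' @param x,y Paired numeric vectors.
#' @param n_boot Number of bootstrap resamples.
#' @param seed Optional integer seed for the bootstrap.
#' @param conf Confidence level.
#' @return A [cor_result()]; `degenerate` when either vector is constant.
#' @export
spearman_ci <- function(x, y, n_boot = 1000, seed = NULL, conf = 0.95) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 4) stop("need at least 4 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(cor_result(NA_real_, n = n, method = "Spearman rank correlation",
                      degenerate = TRUE))
  rho <- stats::cor(x, y, method = "spearman")
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = FALSE))
  if (!is.null(seed)) set.seed(seed)
  boot <- vapply(seq_len(n_boot), function(i) {
    idx <- sample.int(n, n, replace = TRUE)
    if (stats::sd(x[idx]) == 0 || stats::sd(y[idx]) == 0) NA_real_
    else stats::cor(x[idx], y[idx], method = "spearman")
  }, numeric(1))
  alpha <- 1 - conf
  ci <- stats::quantile(boot, c(alpha / 2, 1 - alpha / 2), na.rm = TRUE,
                        names = FALSE)
  cor_result(rho, ci_low = ci[1], ci_high = ci[2], n = n,
             statistic = unname(ct$statistic), p_value = ct$p.value,
             method = "Spearman rank correlation")
}

#' Repeated-measures correlation
#'
#' Common within-subject correlation between two repeatedly measured
#' variables, estimated by analysis of covariance with subject as a factor
#' and a common slope: the sign of the common slope times
#' `sqrt(SS_x / (SS_x + SS_error))`, on `N - k - 1` degrees of freedom for
#' `N` observations from `k` subjects. Between-subject variance is removed by
#' the subject factor, so the estimate is invariant to per-subject additive
#' shifts. The CI uses the Fisher z transform. Linearity and normal errors
#' are assumed, not enforced.
#'
#' @param subject Subject identifiers.
#' @param x,y Paired numeric measurements.
#' @param conf Confidence level.
#' @return A [cor_result()] with `df = N - k - 1`.
#' @export
rmcorr <- function(subject, x, y, conf = 0.95) {
  keep <- is.finite(x) & is.finite(y) & !is.na(subject)
  subject <- as.character(subject[keep]); x <- x[keep]; y <- y[keep]
  counts <- table(subject)
  small <- names(counts)[counts < 2]
  if (length(small)) {
    warning(length(small), " subject(s) with fewer than 2 observations dropped")
    keep <- !subject %in% small
    subject <- subject[keep]; x <- x[keep]; y <- y[keep]
  }
  k <- length(unique(subject))
  if (k < 2) stop("need at least two subjects with two or more observations")
  N <- length(x)
  sub <- factor(subject)
  fit <- stats::lm(y ~ sub + x)
  an <- stats::anova(fit) # sequential: subject first, then x
  ss_x <- an["x", "Sum Sq"]
  ss_err <- an["Residuals", "Sum Sq"]
  df <- N - k - 1
  slope <- stats::coef(fit)[["x"]]
  r <- sign(slope) * sqrt(ss_x / (ss_x + ss_err))
  p <- an["x", "Pr(>F)"]
  if (df > 2 && abs(r) < 1) {
    zse <- 1 / sqrt(df - 1)
    zz <- atanh(r)
    ci <- tanh(zz + stats::qnorm(c((1 - conf) / 2, 1 - (1 - conf) / 2)) * zse)
  } else {
    ci <- c(NA_real_, NA_real_)
  }
  cor_result(r, ci_low = ci[1], ci_high = ci[2], n = N, df = df,
             statistic = an["x", "F value"], p_value = p,
             method = "Repeated-measures correlation")
}

#' Export a table of correlation results
#'
#' @param results A named list of [cor_result()] objects.
#' @param path Output file path (tab-delimited).
#' @export
write_stats_table <- function(results, path) {
  rows <- lapply(names(results), function(nm) {
    r <- results[[nm]]
    data.frame(name = nm, method = r$method, estimate = r$estimate,
               ci_low = r$ci_low, ci_high = r$ci_high, n = r$n, df = r$df,
               statistic = r$statistic, p_value = r$p_value,
               degenerate = r$degenerate)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
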