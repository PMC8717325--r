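#' Pearson chi-square test on a 2x2 contingency table
#'
#' Population comparison of the proportion of calls with ultrasonic
#' components. No continuity correction is applied: the plain Pearson
#' statistic is the one that matches proportions tabulated from call counts.
#'
#' @param table A 2x2 matrix of non-negative counts (rows: populations;
#'   columns: ultrasound yes/no).
#' @return A list with `statistic`, `df` (= 1) and `p`.
#' @export
chisq_2x2 <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2)) || any(table < 0)) {
    stop("need a 2x2 matrix of non-negative counts", call. = FALSE)
  }
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("degenerate table: zero marginal", call. = FALSE)
  }
  ht <- stats::chisq.test(table, correct = FALSE)
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}

#' Two-sample t test
#'
#' Pooled-variance Student test by default (df = n1 + n2 - 2, the variant
#' whose degrees of freedom match the tabulated inter-population
#' comparisons); Welch's unequal-variance test via `variant = "welch"`.
#'
#' @param x,y Numeric samples with at least 2 observations each.
#' @param variant `"pooled"` (default) or `"welch"`.
#' @return A list with `t`, `df`, `p` and `variant`.
#' @export
two_sample_t <- function(x, y, variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  if (length(x) < 2 || length(y) < 2) {
    stop("each sample needs at least 2 observations", call. = FALSE)
  }
  if (stats::sd(x) == 0 && stats::sd(y) == 0 && mean(x) == mean(y)) {
    return(list(t = 0, df = length(x) + length(y) - 2, p = 1,
                variant = variant))
  }
  ht <- stats::t.test(x, y, var.equal = identical(variant, "pooled"))
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, variant = variant)
}

#' Pooled t statistic from summary statistics
#'
#' Reconstructs the pooled two-sample t statistic from group means, standard
#' errors and sample sizes, as needed when only tabulated summaries are
#' available.
#'
#' @param mean1,mean2 Group means.
#' @param se1,se2 Group standard errors of the mean.
#' @param n1,n2 Group sizes.
#' @return A list with `t` and `df`.
#' @export
t_from_summary <- function(mean1, se1, n1, mean2, se2, n2) {
  s1 <- se1 * sqrt(n1)
  s2 <- se2 * sqrt(n2)
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / df
  t <- (mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = t, df = df)
}

#' Ultrasound contingency table
#'
#' Tabulates ultrasound flags by population into the 2x2 table consumed by
#' [chisq_2x2()].
#'
#' @param population Character vector of population labels, one per call.
#' @param has_ultrasound Logical vector of ultrasound flags, same length.
#' @return A 2x2 matrix (rows: populations in first-appearance order;
#'   columns: `yes`, `no`).
#' @export
ultrasound_contingency <- function(population, has_ultrasound) {
  stopifnot(length(population) == length(has_ultrasound))
  pops <- unique(population)
  out <- t(vapply(pops, function(p) {
    sel <- population == p
    c(yes = sum(has_ultrasound[sel]), no = sum(!has_ultrasound[sel]))
  }, numeric(2)))
  rownames(out) <- pops
  out
}

#' Two-group linear discriminant analysis with stepwise selection
#'
#' Fisher's two-group discriminant with optional forward stepwise variable
#' selection minimizing Wilks' lambda (F-to-enter threshold 3.84 by default).
#' Reports the canonical summary: Wilks' lambda, the discriminant eigenvalue
#' (for one function, `lambda = 1 / (1 + eigenvalue)`), raw and standardized
#' coefficients, the overall F test, and the in-sample classification rate
#' with its confusion matrix.
#'
#' @param features Numeric matrix or data frame (cases x variables).
#' @param labels Two-level factor (or coercible) of group membership.
#' @param stepwise Apply forward selection (default TRUE).
#' @param f_to_enter F threshold for a variable to enter (default 3.84).
#' @return A list of class `lda_two_group`.
#' @export
lda_two_group <- function(features, labels, stepwise = TRUE,
                          f_to_enter = 3.84) {
  X <- as.matrix(features)
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  g <- as.factor(labels)
  if (nlevels(g) != 2) stop("labels must have exactly two levels", call. = FALSE)
  if (min(table(g)) < 2) stop("need at least 2 cases per group", call. = FALSE)
  n <- nrow(X)

  wilks <- function(vars) {
    if (length(vars) == 0) return(1)
    Xs <- X[, vars, drop = FALSE]
    W <- within_scatter(Xs, g)
    T <- crossprod(scale(Xs, scale = FALSE))
    det(W) / det(T)
  }

  if (stepwise) {
    selected <- character(0)
    remaining <- colnames(X)
    repeat {
      lam0 <- wilks(selected)
      best_var <- NULL
      best_lam <- lam0
      for (v in remaining) {
        lam <- wilks(c(selected, v))
        if (lam < best_lam) {
          best_lam <- lam
          best_var <- v
        }
      }
      if (is.null(best_var)) break
      p <- length(selected)
      f_enter <- (n - 2 - p) * (lam0 / best_lam - 1)
      if (!is.finite(f_enter) || f_enter < f_to_enter) break
      selected <- c(selected, best_var)
      remaining <- setdiff(remaining, best_var)
      if (length(remaining) == 0) break
    }
    if (length(selected) == 0) selected <- colnames(X)  # nothing passed: keep all
  } else {
    selected <- colnames(X)
  }

  Xs <- X[, selected, drop = FALSE]
  W <- within_scatter(Xs, g)
  if (abs(det(W)) < 1e-300) stop("singular within-group scatter", call. = FALSE)
  means <- rowsum(Xs, g) / as.vector(table(g))
  d <- means[2, ] - means[1, ]
  n1 <- sum(g == levels(g)[1])
  n2 <- n - n1
  Winv_d <- solve(W, d)
  eigenvalue <- as.numeric((n1 * n2 / n) * crossprod(d, Winv_d))
  lambda <- 1 / (1 + eigenvalue)
  p <- length(selected)
  f_overall <- ((1 - lambda) / lambda) * (n - p - 1) / p

  coef_raw <- Winv_d
  coef_std <- coef_raw * sqrt(diag(W) / (n - 2))
  scores <- drop(Xs %*% coef_raw)
  cut <- (mean(scores[g == levels(g)[1]]) + mean(scores[g == levels(g)[2]])) / 2
  pred <- ifelse(scores > cut, levels(g)[2], levels(g)[1])
  confusion <- table(observed = g, predicted = factor(pred, levels = levels(g)))
  pct_correct <- 100 * sum(diag(confusion)) / n

  structure(list(selected_variables = selected,
                 coefficients = coef_raw,
                 std_coefficients = coef_std,
                 wilks_lambda = lambda,
                 eigenvalue = eigenvalue,
                 f_statistic = f_overall,
                 df = c(p, n - p - 1),
                 p_value = stats::pf(f_overall, p, n - p - 1,
                                     lower.tail = FALSE),
                 scores = scores,
                 pct_correct = pct_correct,
                 confusion = confusion),
            class = "lda_two_group")
}

within_scatter <- function(X, g) {
  W <- matrix(0, ncol(X), ncol(X), dimnames = list(colnames(X), colnames(X)))
  for (lev in levels(g)) {
    Xi <- X[g == lev, , drop = FALSE]
    W <- W + crossprod(scale(Xi, scale = FALSE))
  }
  W
}

#' @export
print.lda_two_group <- function(x, ...) {
  cat("Two-group linear discriminant analysis\n")
  cat(sprintf("  variables: %s\n", paste(x$selected_variables, collapse = ", ")))
  cat(sprintf("  Wilks' lambda = %.4g, eigenvalue = %.4g\n",
              x$wilks_lambda, x$eigenvalue))
  cat(sprintf("  F(%d, %d) = %.4g, p = %.3g\n", x$df[1], x$df[2],
              x$f_statistic, x$p_value))
  cat(sprintf("  %.1f%% of cases classified correctly\n", x$pct_correct))
  invisible(x)
}
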