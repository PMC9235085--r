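# Group summaries and the Mann-Whitney U test used to compare artificial
# vs. clinical reconstruction accuracy.

#' Summarize a group of measurements
#'
#' Arithmetic mean and sample standard deviation (denominator n - 1;
#' population SD with denominator n is also reported as `sd_pop` since
#' published mean +- SD tables do not always state the convention).
#' Values are stored unrounded; rounding happens only at report time.
#'
#' @param values non-empty numeric vector.
#' @param label group label.
#' @return A `group_summary`: list with `n`, `mean`, `sd`, `sd_pop`,
#'   `min`, `max`, `label`.
#' @export
summarize_group <- function(values, label = "") {
  if (length(values) == 0 || any(!is.finite(values)))
    stop("'values' must be non-empty and finite")
  n <- length(values)
  structure(list(
    n = n,
    mean = mean(values),
    sd = if (n > 1) stats::sd(values) else 0,
    sd_pop = sqrt(mean((values - mean(values))^2)),
    min = min(values),
    max = max(values),
    label = label
  ), class = "group_summary")
}

#' @export
print.group_summary <- function(x, ...) {
  cat(sprintf("%s: n = %d, %.2f +- %.2f (range %.2f-%.2f)\n",
              if (nzchar(x$label)) x$label else "group",
              x$n, round_half_up(x$mean, 2), round_half_up(x$sd, 2),
              x$min, x$max))
  invisible(x)
}

#' Mann-Whitney U test
#'
#' U is computed from midrank sums; the reported U for two-sided tests is
#' `min(U1, U2)`. The p value is exact (from the null distribution of U)
#' when `n1 * n2 <= 400` and the pooled data are tie-free, otherwise a
#' normal approximation with tie correction and continuity correction is
#' used. Suited to unbalanced, non-normal groups.
#'
#' @param x,y non-empty numeric samples.
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`
#'   (directions refer to `x` relative to `y`).
#' @return A `u_test`: list with `U` (reported statistic), `U1` (for x),
#'   `U2`, `p`, `n1`, `n2`, `method` (`"exact"` or
#'   `"normal-approximation"`), `alternative`.
#' @export
mann_whitney_u <- function(x, y,
                           alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  if (length(x) == 0 || length(y) == 0) stop("both groups must be non-empty")
  if (any(!is.finite(c(x, y)))) stop("values must be finite")
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled) # midranks
  R1 <- sum(r[seq_len(n1)])
  U1 <- R1 - n1 * (n1 + 1) / 2
  U2 <- n1 * n2 - U1
  ties <- table(pooled)
  has_ties <- any(ties > 1)

  if (!has_ties && n1 * n2 <= 400) {
    method <- "exact"
    # exact null distribution of U (Wilcoxon-Mann-Whitney)
    p <- switch(alternative,
      two.sided = min(1, 2 * min(stats::pwilcox(U1, n1, n2),
                                 1 - stats::pwilcox(U1 - 1, n1, n2))),
      less = stats::pwilcox(U1, n1, n2),
      greater = 1 - stats::pwilcox(U1 - 1, n1, n2))
  } else {
    method <- "normal-approximation"
    N <- n1 + n2
    mu <- n1 * n2 / 2
    tie_term <- sum(ties^3 - ties) / (N * (N - 1))
    sigma <- sqrt(n1 * n2 / 12 * ((N + 1) - tie_term))
    if (sigma == 0) {
      p <- 1
    } else {
      z_upper <- (U1 - mu - 0.5) / sigma # for P(U1 >= u)
      z_lower <- (U1 - mu + 0.5) / sigma # for P(U1 <= u)
      p <- switch(alternative,
        two.sided = min(1, 2 * min(stats::pnorm(z_lower),
                                   stats::pnorm(z_upper, lower.tail = FALSE))),
        less = stats::pnorm(z_lower),
        greater = stats::pnorm(z_upper, lower.tail = FALSE))
    }
  }
  U <- if (alternative == "two.sided") min(U1, U2) else U1
  structure(list(U = U, U1 = U1, U2 = U2, p = max(p, .Machine$double.xmin),
                 n1 = n1, n2 = n2, method = method,
                 alternative = alternative),
            class = "u_test")
}

#' @export
print.u_test <- function(x, ...) {
  cat(sprintf("Mann-Whitney U test (%s, %s)\n", x$method, x$alternative))
  cat(sprintf("  n1 = %d, n2 = %d, U = %g, p = %.4g\n", x$n1, x$n2, x$U, x$p))
  invisible(x)
}

#' Compare artificial vs. clinical reconstruction accuracy
#'
#' Runs [mann_whitney_u()] separately on the cosine similarities and on
#' the mean surface errors of the two groups, and summarizes each group
#' (mean +- SD).
#'
#' @param artificial,clinical data.frames with columns `cosine` and
#'   `mean_error_mm` (one row per case), or lists of `similarity_result`s.
#' @param alpha significance level (default 0.05).
#' @return A `group_comparison`: list with `summary` (named list of
#'   [summarize_group()] results), `tests` (named list of [mann_whitney_u()]
#'   results for `cosine` and `error`), `alpha`, and `significant` (named
#'   logical vector).
#' @export
compare_groups <- function(artificial, clinical, alpha = 0.05) {
  to_df <- function(x) {
    if (is.data.frame(x)) return(x)
    do.call(rbind, lapply(x, function(r)
      data.frame(cosine = r$cosine, mean_error_mm = r$mean_error_mm)))
  }
  a <- to_df(artificial); c_ <- to_df(clinical)
  if (nrow(a) == 0 || nrow(c_) == 0) stop("both groups must be non-empty")
  tests <- list(
    cosine = mann_whitney_u(a$cosine, c_$cosine),
    error = mann_whitney_u(a$mean_error_mm, c_$mean_error_mm)
  )
  structure(list(
    summary = list(
      artificial_cosine = summarize_group(a$cosine, "artificial cosine"),
      clinical_cosine = summarize_group(c_$cosine, "clinical cosine"),
      artificial_error = summarize_group(a$mean_error_mm, "artificial error (mm)"),
      clinical_error = summarize_group(c_$mean_error_mm, "clinical error (mm)")
    ),
    tests = tests,
    alpha = alpha,
    significant = c(cosine = tests$cosine$p < alpha,
                    error = tests$error$p < alpha)
  ), class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("Group comparison (Mann-Whitney U):\n")
  for (s in x$summary) print(s)
  cat(sprintf("  cosine: U = %g, p = %.4g (%s)\n", x$tests$cosine$U,
              x$tests$cosine$p,
              if (x$significant["cosine"]) "significant" else "n.s."))
  cat(sprintf("  error:  U = %g, p = %.4g (%s)\n", x$tests$error$U,
              x$tests$error$p,
              if (x$significant["error"]) "significant" else "n.s."))
  invisible(x)
}
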