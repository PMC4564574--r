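#' Pairwise Pearson correlation matrix
#'
#' Pearson r with two-tailed p for every pair of measures, with pairwise
#' deletion of missing subjects (subjects excluded on one measure still
#' contribute to pairs not involving it).
#'
#' @param measures Tibble with `subject_id` and numeric measure columns.
#' @param vars Columns to correlate (default: all numeric except
#'   `subject_id`).
#' @return A tidy tibble `var1`, `var2`, `r`, `p`, `n` for every unordered
#'   pair (var1 earlier in `vars` than var2).
#' @export
correlation_matrix <- function(measures, vars = NULL) {
  if (is.null(vars)) {
    vars <- names(measures)[purrr::map_lgl(measures, is.numeric)]
    vars <- setdiff(vars, "subject_id")
  }
  pairs <- utils::combn(vars, 2, simplify = FALSE)
  purrr::map_dfr(pairs, function(pr) {
    x <- measures[[pr[1]]]
    y <- measures[[pr[2]]]
    ok <- stats::complete.cases(x, y)
    n <- sum(ok)
    if (n < 3) {
      abort(sprintf("fewer than 3 complete pairs for %s ~ %s", pr[1], pr[2]))
    }
    ct <- stats::cor.test(x[ok], y[ok], method = "pearson", alternative = "two.sided")
    tibble::tibble(var1 = pr[1], var2 = pr[2],
                   r = unname(ct$estimate), p = ct$p.value, n = n)
  })
}

#' Forward stepwise regression with standardized coefficients
#'
#' Builds a parsimonious prediction model: starting from the intercept-only
#' model, repeatedly enters the candidate with the smallest F-change
#' p-value while that p is below `entry_alpha`. Variables are z-scored
#' first, so coefficients are standardized betas; each predictor is also
#' reported with its squared zero-order correlation with the response.
#' When any two candidates correlate above `guard_r` in absolute value the
#' fit is refused with a multicollinearity diagnostic, because unique
#' contributions are then indiscernible.
#'
#' @param data Tibble containing the response and candidate columns; rows
#'   with any missing value among them are dropped (listwise within the
#'   model).
#' @param response Name of the response column.
#' @param candidates Character vector of candidate predictor columns.
#' @param entry_alpha Entry threshold on the F-change p (default 0.05).
#' @param guard_r Multicollinearity guard on pairwise candidate
#'   correlations (default 0.90).
#' @return An object of class `stepwise_fit` with `tidy()` / `glance()`
#'   methods. `tidy()` lists entered terms (standardized `beta`, `t`, `df`,
#'   `p`, `r_squared_zero_order`, `step`) and the non-entered candidates
#'   with their final F-change `p`.
#' @export
stepwise_forward <- function(data, response, candidates, entry_alpha = 0.05,
                             guard_r = 0.90) {
  cols <- c(response, candidates)
  stopifnot(all(cols %in% names(data)))
  d <- data[stats::complete.cases(data[, cols]), cols]
  n <- nrow(d)
  if (n <= length(candidates) + 2) {
    abort(sprintf("insufficient data: n = %d with %d candidate(s)", n, length(candidates)))
  }
  if (length(candidates) > 1) {
    cc <- stats::cor(d[, candidates])
    cc[upper.tri(cc, diag = TRUE)] <- 0
    worst <- which(abs(cc) == max(abs(cc)), arr.ind = TRUE)[1, ]
    if (max(abs(cc)) > guard_r) {
      abort(sprintf(
        "multicollinearity: |r(%s, %s)| = %.2f exceeds the guard %.2f; interpret zero-order correlations instead",
        candidates[worst[2]], candidates[worst[1]], max(abs(cc)), guard_r
      ))
    }
  }
  z <- as.data.frame(lapply(d, function(x) as.numeric(scale(x))))
  names(z) <- cols
  entered <- character(0)
  steps <- list()
  remaining <- candidates
  repeat {
    if (length(remaining) == 0) break
    # F-change p for adding each remaining candidate to the current model
    pvals <- purrr::map_dbl(remaining, function(cand) {
      f0 <- stats::as.formula(paste(response, "~", paste(c("1", entered), collapse = "+")))
      f1 <- stats::as.formula(paste(response, "~", paste(c("1", entered, cand), collapse = "+")))
      a <- stats::anova(stats::lm(f0, data = z), stats::lm(f1, data = z))
      a[["Pr(>F)"]][2]
    })
    best <- which.min(pvals)
    if (pvals[best] >= entry_alpha) break
    entered <- c(entered, remaining[best])
    remaining <- remaining[-best]
  }
  f_final <- stats::as.formula(paste(response, "~", paste(c("1", entered), collapse = "+")))
  fit <- stats::lm(f_final, data = z)
  sm <- summary(fit)
  res_df <- fit$df.residual
  coefs <- if (length(entered) > 0) {
    tibble::tibble(
      term = entered,
      beta = unname(coef(fit)[entered]),
      t = unname(sm$coefficients[entered, "t value"]),
      df = res_df,
      p = unname(sm$coefficients[entered, "Pr(>|t|)"]),
      r_squared_zero_order = purrr::map_dbl(entered, function(v) {
        stats::cor(z[[response]], z[[v]])^2
      }),
      step = seq_along(entered),
      entered = TRUE
    )
  } else {
    tibble::tibble(term = character(0), beta = double(0), t = double(0),
                   df = double(0), p = double(0),
                   r_squared_zero_order = double(0), step = integer(0),
                   entered = logical(0))
  }
  rejected <- if (length(remaining) > 0) {
    pvals <- purrr::map_dbl(remaining, function(cand) {
      f1 <- stats::as.formula(paste(response, "~", paste(c("1", entered, cand), collapse = "+")))
      a <- stats::anova(fit, stats::lm(f1, data = z))
      a[["Pr(>F)"]][2]
    })
    tibble::tibble(term = remaining, beta = NA_real_, t = NA_real_,
                   df = NA_real_, p = pvals, r_squared_zero_order = NA_real_,
                   step = NA_integer_, entered = FALSE)
  } else {
    NULL
  }
  structure(
    list(
      terms = dplyr::bind_rows(coefs, rejected),
      response = response,
      entered = entered,
      n = n,
      r_squared = sm$r.squared,
      adj_r_squared = sm$adj.r.squared,
      entry_alpha = entry_alpha,
      fit = fit
    ),
    class = "stepwise_fit"
  )
}

#' @export
print.stepwise_fit <- function(x, ...) {
  cat(sprintf("Forward stepwise regression of %s (n = %d, entry p < %g)\n",
              x$response, x$n, x$entry_alpha))
  if (length(x$entered) == 0) cat("No predictor entered the model.\n")
  print(x$terms, ...)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.stepwise_fit <- function(x, ...) x$terms

#' @export
glance.stepwise_fit <- function(x, ...) {
  tibble::tibble(r.squared = x$r_squared, adj.r.squared = x$adj_r_squared,
                 n = x$n, n_entered = length(x$entered))
}

#' Two-level repeated-measures contrast with partial eta squared
#'
#' The one-way repeated-measures ANOVA of a two-level within-subject
#' factor, equivalent to the paired t-test: F = t^2 with df = (1, n - 1),
#' and partial eta squared F·df1 / (F·df1 + df2). Pairs with a missing
#' value in either level are dropped.
#'
#' @param a,b Numeric vectors, one value per subject in the same order.
#' @return An object of class `paired_contrast` with `tidy()` / `glance()`
#'   methods and fields `f`, `df1`, `df2`, `p`, `pes` (partial eta
#'   squared), `mean_a`, `mean_b`, `n`. A zero-variance difference is
#'   reported with `degenerate = TRUE` (F = 0 or Inf).
#' @export
#' @examples
#' paired_contrast(c(1, 2, 3, 5), c(0, 1, 2, 3))
paired_contrast <- function(a, b) {
  stopifnot(length(a) == length(b))
  ok <- stats::complete.cases(a, b)
  a <- a[ok]; b <- b[ok]
  n <- length(a)
  if (n < 3) abort("paired_contrast needs at least 3 complete pairs")
  d <- a - b
  sdd <- stats::sd(d)
  degenerate <- sdd == 0
  if (degenerate) {
    f <- if (mean(d) == 0) 0 else Inf
    p <- if (mean(d) == 0) 1 else 0
  } else {
    t <- mean(d) / (sdd / sqrt(n))
    f <- t^2
    p <- 2 * stats::pt(abs(t), df = n - 1, lower.tail = FALSE)
  }
  structure(
    list(f = f, df1 = 1, df2 = n - 1, p = p,
         pes = partial_eta_sq(f, 1, n - 1),
         mean_a = mean(a), mean_b = mean(b), n = n,
         degenerate = degenerate),
    class = "paired_contrast"
  )
}

#' Partial eta squared from F and its degrees of freedom
#'
#' For a one-df effect, SS_effect/(SS_effect + SS_error) reduces to
#' F·df1 / (F·df1 + df2).
#'
#' @param f F statistic.
#' @param df1,df2 Numerator and denominator degrees of freedom.
#' @return Partial eta squared in `[0, 1]`.
#' @export
#' @examples
#' partial_eta_sq(3.77, 1, 33)  # 0.103
partial_eta_sq <- function(f, df1, df2) {
  ifelse(is.infinite(f), 1, (f * df1) / (f * df1 + df2))
}

#' @export
print.paired_contrast <- function(x, ...) {
  cat(sprintf("Repeated-measures contrast: F(%d,%d) = %.3f, p = %.4g, partial eta^2 = %.3f\n",
              x$df1, x$df2, x$f, x$p, x$pes))
  cat(sprintf("Level means: %.4g vs %.4g (n = %d)\n", x$mean_a, x$mean_b, x$n))
  if (x$degenerate) cat("Note: zero-variance difference (degenerate case).\n")
  invisible(x)
}

#' @export
tidy.paired_contrast <- function(x, ...) {
  tibble::tibble(f = x$f, df1 = x$df1, df2 = x$df2, p = x$p,
                 partial_eta_sq = x$pes,
                 mean_a = x$mean_a, mean_b = x$mean_b, n = x$n,
                 degenerate = x$degenerate)
}

#' @export
glance.paired_contrast <- function(x, ...) tidy(x)
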