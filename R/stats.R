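# Normality-gated statistics: Kolmogorov-Smirnov routing between parametric
# and rank-based correlation/group tests, Bonferroni-corrected post hocs.

#' Route a sample to parametric or non-parametric analysis
#'
#' Kolmogorov-Smirnov test of the standardized sample against the standard
#' normal; the parametric route is taken when the KS p-value is at least
#' `alpha`. Samples smaller than 5 or with zero variance are routed
#' non-parametric (with a warning / degenerate flag). Note the KS test with
#' estimated mean and SD is conservative (Lilliefors effect); the plain KS
#' test is nonetheless the default gate, with `alpha` configurable.
#'
#' @param x numeric sample.
#' @param alpha gate level (default 0.05).
#' @return list with `route` (`"parametric"` or `"nonparametric"`), `p`
#'   (KS p-value, NA when not computed) and `degenerate` flag.
#' @export
normality_gate <- function(x, alpha = 0.05) {
  x <- x[is.finite(x)]
  if (length(x) < 5) {
    warning("fewer than 5 observations: routing non-parametric")
    return(list(route = "nonparametric", p = NA_real_, degenerate = FALSE))
  }
  if (stats::sd(x) == 0) {
    return(list(route = "nonparametric", p = NA_real_, degenerate = TRUE))
  }
  p <- suppressWarnings(
    stats::ks.test((x - mean(x)) / stats::sd(x), "pnorm")$p.value
  )
  list(route = if (p >= alpha) "parametric" else "nonparametric",
       p = p, degenerate = FALSE)
}

#' Normality-gated correlation
#'
#' Pearson correlation when both variables pass the normality gate, Spearman
#' otherwise; two-sided p-values throughout.
#'
#' @param x,y paired numeric vectors (n >= 3).
#' @param x_label,y_label variable labels carried into the result.
#' @param alpha gate level passed to [normality_gate()].
#' @return object of class `correlation_result`: `method`, `estimate`, `p`,
#'   `n`, `conf_int` (Pearson only), `x_label`, `y_label`.
#' @export
correlate <- function(x, y, x_label = deparse(substitute(x)),
                      y_label = deparse(substitute(y)), alpha = 0.05) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("undefined correlation: zero variance")
  }
  gx <- suppressWarnings(normality_gate(x, alpha))
  gy <- suppressWarnings(normality_gate(y, alpha))
  method <- if (gx$route == "parametric" && gy$route == "parametric") {
    "pearson"
  } else {
    "spearman"
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = method,
                                         alternative = "two.sided"))
  structure(list(method = method, estimate = unname(ct$estimate),
                 p = ct$p.value, n = length(x),
                 conf_int = if (method == "pearson") unname(ct$conf.int) else NULL,
                 x_label = x_label, y_label = y_label),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("<correlation> %s ~ %s: %s %s = %.3f, p = %.3g, n = %d\n",
              x$y_label, x$x_label, x$method,
              if (x$method == "pearson") "r" else "rho",
              x$estimate, x$p, x$n))
  invisible(x)
}

#' Normality-gated group comparison with Bonferroni post hocs
#'
#' One-way ANOVA when every group passes the normality gate and Levene's
#' test finds no heteroscedasticity (both at `alpha`), Kruskal-Wallis
#' otherwise; post hoc pairwise two-sided tests (pooled-variance t-tests or
#' Wilcoxon rank-sum, matching the omnibus route) with Bonferroni correction
#' over all pairs.
#'
#' @param samples named list of numeric vectors, one per group (>= 2 groups,
#'   each n >= 2).
#' @param alpha gate level (default 0.05).
#' @return object of class `group_comparison`: `omnibus`, `statistic`, `df`,
#'   `p`, `pairwise` (data frame with raw and Bonferroni-corrected p),
#'   `correction`.
#' @export
compare_groups <- function(samples, alpha = 0.05) {
  stopifnot(is.list(samples), length(samples) >= 2,
            !is.null(names(samples)))
  if (any(!vapply(samples, length, integer(1)))) stop("empty group")
  if (any(vapply(samples, length, integer(1)) < 2)) stop("each group needs n >= 2")
  g <- factor(rep(names(samples), vapply(samples, length, integer(1))),
              levels = names(samples))
  v <- unlist(samples, use.names = FALSE)

  gates <- lapply(samples, function(s) suppressWarnings(normality_gate(s, alpha)))
  normal_ok <- all(vapply(gates, function(z) z$route == "parametric", logical(1)))
  lev_p <- tryCatch(car::leveneTest(v, g)[1, "Pr(>F)"], error = function(e) 0)
  parametric <- normal_ok && isTRUE(lev_p >= alpha)

  if (parametric) {
    fit <- stats::aov(v ~ g)
    s <- summary(fit)[[1]]
    omnibus <- "anova"; statistic <- s$`F value`[1]
    df <- c(s$Df[1], s$Df[2]); p <- s$`Pr(>F)`[1]
  } else {
    kw <- stats::kruskal.test(v, g)
    omnibus <- "kruskal_wallis"; statistic <- unname(kw$statistic)
    df <- unname(kw$parameter); p <- kw$p.value
  }

  pairs <- utils::combn(names(samples), 2)
  pw <- apply(pairs, 2, function(pr) {
    a <- samples[[pr[1]]]; b <- samples[[pr[2]]]
    if (parametric) {
      tt <- stats::t.test(a, b, var.equal = TRUE)
      c(stat = unname(tt$statistic), p = tt$p.value)
    } else {
      wt <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE))
      c(stat = unname(wt$statistic), p = wt$p.value)
    }
  })
  pairwise <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                         statistic = pw["stat", ], p_raw = pw["p", ],
                         p_adj = stats::p.adjust(pw["p", ], "bonferroni"))
  structure(list(omnibus = omnibus, statistic = statistic, df = df, p = p,
                 pairwise = pairwise, correction = "bonferroni",
                 levene_p = lev_p),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s: statistic = %.3f, p = %.3g\n",
              x$omnibus, x$statistic, x$p))
  print(x$pairwise, row.names = FALSE)
  invisible(x)
}
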