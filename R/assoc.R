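## Association statistics: Kendall tau-b, quadratic-versus-linear model
## comparison, and a rank-based differential expression utility.

#' Kendall rank correlation (tau-b) with tie correction
#'
#' Pairwise concordance statistic with the tie-corrected tau-b
#' denominator. The p-value uses the tie-corrected normal approximation,
#' or exact permutation enumeration for n <= 8.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return List: `computable`, `tau`, `p_value`, `n`, `method`, `reason`
#'   when degenerate (zero variance).
#' @export
kendall_tau <- function(x, y) {
  n <- length(x)
  if (length(y) != n || n < 3) stop("need equal lengths >= 3", call. = FALSE)
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    return(list(computable = FALSE, tau = NA_real_, p_value = NA_real_,
                n = n, method = NA_character_,
                reason = "zero variance in x or y"))
  }
  tau_stat <- function(x, y) {
    s <- 0
    for (i in seq_len(n - 1)) {
      idx <- (i + 1):n
      s <- s + sum(sign(x[idx] - x[i]) * sign(y[idx] - y[i]))
    }
    tx <- table(x); ty <- table(y)
    n0 <- n * (n - 1) / 2
    n1 <- sum(tx * (tx - 1) / 2)
    n2 <- sum(ty * (ty - 1) / 2)
    denom <- sqrt((n0 - n1) * (n0 - n2))
    list(s = s, tau = if (denom > 0) s / denom else NA_real_)
  }
  obs <- tau_stat(x, y)
  if (!is.finite(obs$tau)) {
    return(list(computable = FALSE, tau = NA_real_, p_value = NA_real_,
                n = n, method = NA_character_,
                reason = "degenerate tie structure"))
  }
  if (n <= 8) {
    perms <- perm_all(n)
    count <- 0L
    for (r in seq_len(nrow(perms))) {
      if (abs(tau_stat(x, y[perms[r, ]])$tau) >= abs(obs$tau) - 1e-12) {
        count <- count + 1L
      }
    }
    p <- count / nrow(perms)
    method <- "exact enumeration"
  } else {
    tx <- table(x); ty <- table(y)
    v0 <- n * (n - 1) * (2 * n + 5)
    vt <- sum(tx * (tx - 1) * (2 * tx + 5))
    vu <- sum(ty * (ty - 1) * (2 * ty + 5))
    v1 <- sum(tx * (tx - 1)) * sum(ty * (ty - 1)) / (2 * n * (n - 1))
    v2 <- sum(tx * (tx - 1) * (tx - 2)) * sum(ty * (ty - 1) * (ty - 2)) /
      (9 * n * (n - 1) * (n - 2))
    var_s <- (v0 - vt - vu) / 18 + v1 + v2
    z <- obs$s / sqrt(var_s)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal approximation"
  }
  list(computable = TRUE, tau = obs$tau, p_value = min(p, 1), n = n,
       method = method)
}

# All permutations of 1..n as a matrix (n <= 8 in practice).
perm_all <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- perm_all(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

#' Quadratic-versus-linear model comparison
#'
#' OLS fits of `y ~ x` and `y ~ x + x^2`, both R-squared values, and the
#' large-sample likelihood-ratio statistic `n * log(RSS1/RSS2)` on 1
#' degree of freedom (chi-squared p). An F-test variant is available.
#'
#' @param x,y Numeric vectors, n >= 4, `x` with at least 3 distinct values.
#' @param test `"lrt"` (default) or `"f"`.
#' @return List: `r2_linear`, `r2_quadratic`, `lrt`, `df`, `p_value`,
#'   `fit_linear`, `fit_quadratic`.
#' @export
quadratic_vs_linear <- function(x, y, test = c("lrt", "f")) {
  test <- match.arg(test)
  n <- length(x)
  if (length(y) != n || n < 4) stop("need equal lengths >= 4", call. = FALSE)
  if (length(unique(x)) < 3) {
    stop("x is degenerate (fewer than 3 distinct values)", call. = FALSE)
  }
  f1 <- stats::lm(y ~ x)
  f2 <- stats::lm(y ~ x + I(x^2))
  rss1 <- sum(stats::residuals(f1)^2)
  rss2 <- sum(stats::residuals(f2)^2)
  r2 <- function(f) summary(f)$r.squared
  tss <- sum((y - mean(y))^2)
  # an (essentially) perfect linear fit leaves nothing for the quadratic
  # term; the ratio of two floating-point zeros is noise, not evidence
  lrt <- if (rss1 <= 1e-10 * max(tss, 1e-300)) 0 else {
    max(0, n * log(max(rss1, 1e-300) / max(rss2, 1e-300)))
  }
  p <- if (test == "lrt") {
    stats::pchisq(lrt, df = 1, lower.tail = FALSE)
  } else {
    stats::anova(f1, f2)[2, "Pr(>F)"]
  }
  list(r2_linear = r2(f1), r2_quadratic = r2(f2), lrt = lrt, df = 1L,
       p_value = p, fit_linear = f1, fit_quadratic = f2)
}

#' Rank-based differential expression between two cell groups
#'
#' Plumbing substitute for a model-based differential test: per gene, a
#' two-sided Mann-Whitney test with `log2((mean_A + 1)/(mean_B + 1))`
#' fold-change and Benjamini-Hochberg correction across genes. Not
#' intended to reproduce model-based gene lists.
#'
#' @param expr_a,expr_b Expression matrices (genes x cells) with matching
#'   rownames; each group needs >= 3 cells.
#' @return data.frame: `gene`, `lfc`, `p`, `fdr`, ordered as the input
#'   genes.
#' @export
rank_de <- function(expr_a, expr_b) {
  expr_a <- as_dense(expr_a); expr_b <- as_dense(expr_b)
  if (!identical(rownames(expr_a), rownames(expr_b))) {
    stop("gene rownames must match between groups", call. = FALSE)
  }
  if (ncol(expr_a) < 3 || ncol(expr_b) < 3) {
    stop("each group needs >= 3 cells", call. = FALSE)
  }
  p <- vapply(seq_len(nrow(expr_a)), function(g) {
    a <- expr_a[g, ]; b <- expr_b[g, ]
    if (stats::var(c(a, b)) == 0) return(1)
    suppressWarnings(stats::wilcox.test(a, b)$p.value)
  }, numeric(1))
  lfc <- log2((rowMeans(expr_a) + 1) / (rowMeans(expr_b) + 1))
  data.frame(gene = rownames(expr_a), lfc = lfc, p = p,
             fdr = stats::p.adjust(p, method = "BH"),
             row.names = NULL, stringsAsFactors = FALSE)
}
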