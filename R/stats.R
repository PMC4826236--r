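#' Two-tailed Mann-Whitney U test
#'
#' Rank-sum test for two independent samples. The U statistic is computed
#' from the rank sum of group `a` with midranks for ties. When the
#' combined sample size is at most 20 and the pooled data are tie-free,
#' the two-tailed p-value is exact — twice the smaller tail probability
#' of the null permutation distribution of U, capped at 1. Otherwise the
#' normal approximation with tie correction and continuity correction is
#' used. The U distribution under exchangeability is the classical
#' Wilcoxon count distribution, so the exact tail equals full enumeration
#' of the `choose(n_a + n_b, n_a)` rank assignments.
#'
#' @param a,b numeric vectors, each non-empty.
#' @param parameter optional name of the compared quantity, echoed into
#'   the result.
#' @param exact force (`TRUE`) or forbid (`FALSE`) the exact method;
#'   `NULL` (default) selects it automatically as described above.
#'   Forcing `TRUE` on tied data is an error.
#' @return A list of class `group_comparison`: `parameter`, `statistic`
#'   (U for group `a`), `p_value`, `method` (`"mann_whitney_exact"` or
#'   `"mann_whitney_normal"`), `n_a`, `n_b`.
#' @export
mann_whitney_u <- function(a, b, parameter = NA_character_, exact = NULL) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) == 0L || length(b) == 0L) stop("both groups must be non-empty")
  if (anyNA(a) || anyNA(b)) stop("missing values in input")
  na <- length(a); nb <- length(b)
  pooled <- c(a, b)
  rk <- rank(pooled)
  U <- sum(rk[seq_len(na)]) - na * (na + 1) / 2
  ties <- anyDuplicated(pooled) > 0L
  use_exact <- if (is.null(exact)) !ties && na + nb <= 20L else isTRUE(exact)
  if (use_exact && ties) stop("exact method requires tie-free data")
  if (use_exact) {
    lower <- stats::pwilcox(U, na, nb)
    upper <- 1 - stats::pwilcox(U - 1, na, nb)
    p <- min(1, 2 * min(lower, upper))
    method <- "mann_whitney_exact"
  } else {
    mu <- na * nb / 2
    n <- na + nb
    tie_tab <- table(pooled)
    sig2 <- na * nb / 12 * ((n + 1) - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
    if (sig2 <= 0) {
      p <- 1
    } else {
      z <- (abs(U - mu) - 0.5) / sqrt(sig2)
      p <- min(1, 2 * stats::pnorm(-z))
    }
    method <- "mann_whitney_normal"
  }
  structure(list(parameter = parameter, statistic = U, p_value = p,
                 method = method, n_a = na, n_b = nb),
            class = "group_comparison")
}

#' Two-sample Student's t-test (pooled variance)
#'
#' Classical equal-variance two-sample t with `n_a + n_b - 2` degrees of
#' freedom and a two-tailed p-value. Degenerate zero-variance input
#' follows the convention: equal means give p = 1, unequal means give
#' p = 0, both flagged via `method = "t_test_degenerate"`.
#'
#' @param a,b numeric vectors of length >= 2.
#' @param parameter optional name of the compared quantity.
#' @return A `group_comparison` list (statistic is t).
#' @export
t_test_groups <- function(a, b, parameter = NA_character_) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2L || length(b) < 2L) stop("both groups need n >= 2")
  if (anyNA(a) || anyNA(b)) stop("missing values in input")
  na <- length(a); nb <- length(b)
  df <- na + nb - 2
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / df
  if (sp2 == 0) {
    eq <- mean(a) == mean(b)
    return(structure(list(parameter = parameter,
                          statistic = if (eq) 0 else sign(mean(a) - mean(b)) * Inf,
                          p_value = if (eq) 1 else 0,
                          method = "t_test_degenerate", n_a = na, n_b = nb),
                     class = "group_comparison"))
  }
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  structure(list(parameter = parameter, statistic = t,
                 p_value = 2 * stats::pt(-abs(t), df),
                 method = "t_test", n_a = na, n_b = nb),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison>%s %s: statistic = %.4g, p = %.4g (n = %d, %d)\n",
              if (is.na(x$parameter)) "" else paste0(" ", x$parameter),
              x$method, x$statistic, x$p_value, x$n_a, x$n_b))
  invisible(x)
}

#' Compare texture features between two groups
#'
#' Runs one two-group comparison per texture feature on per-sample (or
#' per-nucleus) values. Rows with an undefined correlation are dropped
#' from the correlation comparison only, and the number dropped per group
#' is reported.
#'
#' @param control,treated data.frames holding feature columns (any of
#'   `asm`, `contrast`, `correlation`, `idm`, `entropy`; e.g. per-sample
#'   mean tables or `per_nucleus` tables).
#' @param method `"mann_whitney"` (default) or `"t_test"`.
#' @return A data.frame with one row per shared feature: `parameter`,
#'   `statistic`, `p_value`, `method`, `n_control`, `n_treated`,
#'   `n_dropped_control`, `n_dropped_treated`.
#' @export
compare_texture_groups <- function(control, treated,
                                   method = c("mann_whitney", "t_test")) {
  method <- match.arg(method)
  if (!nrow(control) || !nrow(treated)) stop("both group tables must be non-empty")
  feats <- intersect(c("asm", "contrast", "correlation", "idm", "entropy"),
                     intersect(names(control), names(treated)))
  if (length(feats) == 0L) stop("no shared texture feature columns")
  rows <- lapply(feats, function(f) {
    va <- control[[f]]; vb <- treated[[f]]
    if (f == "correlation") {
      if ("correlation_defined" %in% names(control)) va <- va[control$correlation_defined]
      if ("correlation_defined" %in% names(treated)) vb <- vb[treated$correlation_defined]
    }
    da <- sum(is.na(va)); db <- sum(is.na(vb))
    va <- va[!is.na(va)]; vb <- vb[!is.na(vb)]
    if (!length(va) || !length(vb)) {
      return(data.frame(parameter = f, statistic = NA_real_, p_value = NA_real_,
                        method = NA_character_, n_control = length(va),
                        n_treated = length(vb),
                        n_dropped_control = nrow(control) - length(va),
                        n_dropped_treated = nrow(treated) - length(vb)))
    }
    cmp <- if (method == "mann_whitney") mann_whitney_u(va, vb, f)
           else t_test_groups(va, vb, f)
    data.frame(parameter = f, statistic = cmp$statistic, p_value = cmp$p_value,
               method = cmp$method, n_control = cmp$n_a, n_treated = cmp$n_b,
               n_dropped_control = nrow(control) - length(va),
               n_dropped_treated = nrow(treated) - length(vb))
  })
  do.call(rbind, rows)
}
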