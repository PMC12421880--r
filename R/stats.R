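#' Dependent-samples sign-flip permutation t test
#'
#' Two-sided permutation test for a paired mean difference. Under exchange of
#' condition labels within a pair, the paired difference changes sign, so the
#' permutation distribution is realized by sign flips of the differences. The
#' reported p-value is the proportion of permuted |t| statistics that equal
#' or exceed the observed |t| over the permutation set (which always contains
#' the identity flip, so an exact test never reports p = 0 under exhaustive
#' enumeration). When `2^n <= n_perm` all sign patterns are enumerated;
#' otherwise `n_perm` random flips are drawn with replacement.
#'
#' @param x,y Paired samples (equal length, n >= 3); alternatively pass the
#'   differences as `x` and leave `y = NULL`.
#' @param n_perm Number of permutations (default 10000).
#' @param seed Integer seed for the Monte-Carlo branch.
#' @param p_method `"proportion"` (raw proportion over the permutation set,
#'   the convention used here by default) or `"add_one"` (the
#'   `(b + 1) / (m + 1)` estimator counting the observed statistic once).
#' @return Object of class `perm_test_result`: list with `t_obs`, `p_perm`,
#'   `n_permutations`, `exhaustive`, `degenerate` (all differences zero),
#'   `n`, `seed`.
#' @examples
#' set.seed(1)
#' permutation_ttest_paired(rnorm(8, 0.5), rnorm(8))
#' @export
permutation_ttest_paired <- function(x, y = NULL, n_perm = 10000, seed = 1,
                                     p_method = c("proportion", "add_one")) {
  p_method <- match.arg(p_method)
  d <- if (is.null(y)) x else {
    if (length(x) != length(y)) stop("x and y must have equal length")
    x - y
  }
  n <- length(d)
  if (n < 3) stop("need at least 3 pairs")
  if (all(d == 0)) {
    return(structure(list(t_obs = NaN, p_perm = 1, n_permutations = n_perm,
                          exhaustive = FALSE, degenerate = TRUE, n = n,
                          seed = seed),
                     class = "perm_test_result"))
  }
  t_stat <- function(m, ssq) {
    v <- (ssq - n * m^2) / (n - 1)
    ifelse(v <= 0, sign(m) * Inf, m / sqrt(v / n))
  }
  ssq <- sum(d^2)
  t_obs <- t_stat(mean(d), ssq)
  exhaustive <- 2^n <= n_perm
  if (exhaustive) {
    m_flip <- 2^n
    S <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  } else {
    m_flip <- n_perm
    S <- with_seed(seed, matrix(sample(c(-1, 1), m_flip * n, replace = TRUE),
                                m_flip, n))
  }
  means <- as.numeric(S %*% d) / n
  t_perm <- t_stat(means, ssq)
  b <- sum(abs(t_perm) >= abs(t_obs) - 1e-12)
  p <- if (p_method == "proportion") b / m_flip else {
    if (exhaustive) b / m_flip else (b + 1) / (m_flip + 1)
  }
  structure(list(t_obs = t_obs, p_perm = p,
                 n_permutations = m_flip, exhaustive = exhaustive,
                 degenerate = FALSE, n = n, seed = seed),
            class = "perm_test_result")
}

#' @export
print.perm_test_result <- function(x, ...) {
  cat(sprintf("<perm_test> t = %.3f, p_perm = %.4g (%s, %d permutations)\n",
              x$t_obs, x$p_perm,
              if (x$exhaustive) "exhaustive" else "Monte-Carlo",
              x$n_permutations))
  invisible(x)
}

#' Repeated-measures ANOVA with Greenhouse-Geisser correction
#'
#' Fully within-subject ANOVA on a complete long-format table. Each effect is
#' evaluated through its orthonormal contrast matrix on the subject-by-cell
#' matrix: `F = (n * ||mean contrast scores||^2 / df) / (trace(S) / df /
#' (n - 1) ...)` in the standard univariate decomposition, and the
#' Greenhouse-Geisser epsilon is computed from the covariance `S` of the
#' contrast scores as `(tr S)^2 / (df * tr S^2)` (univariate epsilon).
#' Corrected p-values use epsilon-scaled degrees of freedom. Incomplete
#' designs are an error: the analyses here operate on complete cases only.
#'
#' @param data Long-format data frame.
#' @param dv Name of the dependent-variable column.
#' @param within Character vector of within-subject factor columns (1-3).
#' @param subject Name of the subject-identifier column.
#' @return Object of class `rm_anova_result`: data frame with one row per
#'   effect and columns `effect`, `F`, `df_num`, `df_den`, `epsilon_GG`,
#'   `p_uncorrected`, `p_GG`.
#' @examples
#' d <- expand.grid(subject = 1:8, session = c("s1", "s2"),
#'                  rate = c("4", "40"))
#' d$power <- rnorm(nrow(d))
#' rm_anova(d, "power", c("session", "rate"), "subject")
#' @export
rm_anova <- function(data, dv, within, subject) {
  stopifnot(is.data.frame(data), length(within) >= 1, length(within) <= 3,
            all(c(dv, within, subject) %in% names(data)))
  for (w in within) data[[w]] <- factor(data[[w]])
  data[[subject]] <- factor(data[[subject]])
  levs <- lapply(within, function(w) levels(data[[w]]))
  n_cell <- prod(vapply(levs, length, integer(1)))
  cell <- interaction(data[within], drop = FALSE, lex.order = TRUE)
  tab <- table(data[[subject]], cell)
  if (any(tab != 1)) {
    stop("incomplete or replicated within-subject design: every subject ",
         "needs exactly one observation per cell")
  }
  subj <- levels(data[[subject]])
  n <- length(subj)
  if (n < 2) stop("need at least 2 subjects")
  Y <- matrix(NA_real_, n, n_cell,
              dimnames = list(subj, levels(cell)))
  Y[cbind(match(data[[subject]], subj), match(cell, levels(cell)))] <-
    data[[dv]]

  orth_contrast <- function(L) {
    # orthonormal contrasts spanning the deviation space of an L-level factor
    qr.Q(qr(cbind(rep(1, L), stats::contr.poly(L))))[, -1, drop = FALSE]
  }
  avg_vec <- function(L) matrix(rep(1 / sqrt(L), L), ncol = 1)

  effects <- unlist(lapply(seq_along(within), function(k) {
    utils::combn(within, k, simplify = FALSE)
  }), recursive = FALSE)

  ss_floor <- 1e-12 * max(sum((Y - mean(Y))^2), .Machine$double.xmin)
  rows <- lapply(effects, function(eff) {
    M <- matrix(1, 1, 1)
    for (i in seq_along(within)) {
      L <- length(levs[[i]])
      Ci <- if (within[i] %in% eff) orth_contrast(L) else avg_vec(L)
      M <- M %x% Ci
    }
    d_eff <- ncol(M)
    Z <- Y %*% M                       # n x d_eff contrast scores
    zbar <- colMeans(Z)
    ss_eff <- n * sum(zbar^2)
    R <- sweep(Z, 2, zbar)
    ss_err <- sum(R^2)
    S <- crossprod(R) / (n - 1)
    F_ <- if (ss_eff <= ss_floor) 0 else {
      (ss_eff / d_eff) / (ss_err / (d_eff * (n - 1)))
    }
    eps <- sum(diag(S))^2 / (d_eff * sum(S^2))
    if (!is.finite(eps)) eps <- 1
    eps <- min(max(eps, 1 / d_eff), 1)
    df1 <- d_eff
    df2 <- d_eff * (n - 1)
    data.frame(effect = paste(eff, collapse = ":"), F = F_,
               df_num = df1, df_den = df2, epsilon_GG = eps,
               p_uncorrected = stats::pf(F_, df1, df2, lower.tail = FALSE),
               p_GG = stats::pf(F_, eps * df1, eps * df2, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("rm_anova_result", "data.frame")
  out
}

#' Spearman rank correlation
#'
#' Rank correlation with average-rank (midrank) tie handling, computed as the
#' Pearson correlation of midranks.
#'
#' @param x,y Equal-length numeric vectors, n >= 3.
#' @return Spearman's rho; `NA` with a warning when either input is
#'   constant.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 observations")
  if (length(unique(x)) < 2 || length(unique(y)) < 2) {
    warning("constant input: Spearman correlation undefined")
    return(NA_real_)
  }
  stats::cor(rank(x), rank(y))
}
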