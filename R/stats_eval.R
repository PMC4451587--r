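#' Nonparametric group statistics
#'
#' Group comparisons of profile features use the Mann-Whitney U test
#' (rank-sum with midranks; exact two-sided p by enumeration when the
#' smaller sample has at most 8 observations and there are no ties,
#' otherwise the normal approximation with tie-corrected variance and
#' continuity correction). Associations between features use Spearman's
#' rank correlation (midranks, two-sided t approximation). Differences are
#' conventionally reported as significant at p < 0.05; an optional Holm
#' correction is available but off by default, matching common practice of
#' reporting unadjusted p values for these batteries.
#'
#' @name stats_eval
NULL

#' Mann-Whitney U test
#'
#' @param a,b Numeric samples (each non-empty).
#' @param continuity Apply the 0.5 continuity correction in the normal
#'   approximation (default TRUE).
#' @param exact_limit Enumeration is used when `min(n_a, n_b) <=
#'   exact_limit` and the data have no ties (default 8).
#' @return List with `U` (for sample `a`), `Z`, `p` (two-sided), `method`.
#' @export
mann_whitney <- function(a, b, continuity = TRUE, exact_limit = 8) {
  if (!length(a) || !length(b)) stop("empty sample")
  na <- length(a); nb <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled)                        # midranks
  Ua <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  n <- na + nb
  ties <- table(pooled)
  has_ties <- any(ties > 1)
  mu <- na * nb / 2
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  sigma2 <- na * nb / 12 * ((n + 1) - tie_term)
  d <- Ua - mu
  cc <- if (continuity) sign(d) * 0.5 else 0
  Z <- if (sigma2 > 0) (d - cc) / sqrt(sigma2) else 0
  if (min(na, nb) <= exact_limit && !has_ties &&
      choose(n, na) <= 2e6) {
    p <- mw_exact_p(Ua, na, nb, pooled)
    method <- "exact enumeration"
  } else {
    p <- if (sigma2 > 0) 2 * stats::pnorm(-abs(Z)) else 1
    method <- "normal approximation"
  }
  list(U = Ua, Z = Z, p = min(1, p), method = method,
       n_a = na, n_b = nb)
}

# Exact two-sided p: enumerate all C(n, na) assignments of ranks to group a,
# compute the U distribution, and double the smaller tail (capped at 1).
mw_exact_p <- function(Ua, na, nb, pooled) {
  n <- na + nb
  r <- rank(pooled)
  combs <- utils::combn(n, na)
  us <- colSums(matrix(r[combs], nrow = na)) - na * (na + 1) / 2
  lo <- mean(us <= Ua + 1e-9)
  hi <- mean(us >= Ua - 1e-9)
  min(1, 2 * min(lo, hi))
}

#' Spearman rank correlation
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return List with `rho`, `p` (two-sided t approximation), `n`;
#'   `rho = NA` with a warning for constant input.
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3) stop("need at least 3 paired observations")
  if (length(unique(x)) < 2L || length(unique(y)) < 2L) {
    warning("constant input: Spearman rho undefined")
    return(list(rho = NA_real_, p = NA_real_, n = n))
  }
  rx <- rank(x); ry <- rank(y)
  rho <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p = p, n = n)
}

#' Batch group-comparison table
#'
#' Runs [mann_whitney()] for every feature and every pair of groups,
#' mirroring the intergroup-comparison table layout: one row per group
#' pair, one `Z/p` cell per feature.
#'
#' @param table Profile data.frame (numeric feature columns).
#' @param group Character/factor column of group labels (same length as
#'   rows).
#' @param features Feature columns to compare (default: all numeric).
#' @param holm Apply a Holm correction across each feature's pairs.
#' @return List with `results` (long data.frame: feature, group_a, group_b,
#'   U, Z, p, significant) and `formatted` (wide "Z/p" character table).
#' @export
group_comparison_table <- function(table, group,
                                   features = NULL, holm = FALSE) {
  if (is.null(features))
    features <- names(table)[vapply(table, is.numeric, logical(1))]
  gs <- unique(as.character(group))
  pairs <- utils::combn(gs, 2)
  rows <- list()
  for (f in features) {
    ps <- numeric(ncol(pairs))
    tmp <- list()
    for (j in seq_len(ncol(pairs))) {
      ga <- pairs[1, j]; gb <- pairs[2, j]
      mw <- mann_whitney(table[[f]][group == ga], table[[f]][group == gb])
      ps[j] <- mw$p
      tmp[[j]] <- data.frame(feature = f, group_a = ga, group_b = gb,
                             U = mw$U, Z = mw$Z, p = mw$p)
    }
    if (holm) ps <- stats::p.adjust(ps, "holm")
    for (j in seq_along(tmp)) tmp[[j]]$p_adj <- ps[j]
    rows <- c(rows, tmp)
  }
  res <- do.call(rbind, rows)
  res$significant <- (if (holm) res$p_adj else res$p) < 0.05
  pair_lab <- paste(pairs[1, ], "vs.", pairs[2, ])
  wide <- matrix("", nrow = ncol(pairs), ncol = length(features),
                 dimnames = list(pair_lab, features))
  for (i in seq_len(nrow(res))) {
    lab <- paste(res$group_a[i], "vs.", res$group_b[i])
    wide[lab, res$feature[i]] <-
      sprintf("%.3f/%.3f", res$Z[i], res$p[i])
  }
  list(results = res, formatted = as.data.frame(wide))
}

#' Batch Spearman correlation table
#'
#' @param table Profile data.frame.
#' @param features,covariates Column name vectors to correlate (rows x
#'   columns of the output).
#' @return List with `results` (long data.frame) and `formatted` (wide
#'   "rho/p" table).
#' @export
correlation_table <- function(table, features, covariates) {
  rows <- list()
  wide <- matrix("", nrow = length(features), ncol = length(covariates),
                 dimnames = list(features, covariates))
  for (f in features) for (cv in covariates) {
    sp <- spearman_cor(table[[f]], table[[cv]])
    rows[[length(rows) + 1L]] <-
      data.frame(feature = f, covariate = cv, rho = sp$rho, p = sp$p)
    wide[f, cv] <- sprintf("%.3f/%.3f", sp$rho, sp$p)
  }
  list(results = do.call(rbind, rows), formatted = as.data.frame(wide))
}
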