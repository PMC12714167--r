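# Group-level statistics: normality-gated omnibus tests with FDR-corrected
# post hocs, chi-square for categoricals, (partial) correlations, per-gene
# differential expression with hub-gene overlap, and rank-based ROC/AUC.

# Shapiro-Wilk normality gate for one group; constant samples and samples
# outside shapiro.test's size limits are treated as non-normal.
group_is_normal <- function(x, alpha = 0.05) {
  x <- x[is.finite(x)]
  if (length(x) < 3L || length(x) > 5000L) return(FALSE)
  if (stats::sd(x) == 0) return(FALSE)
  stats::shapiro.test(x)$p.value > alpha
}

#' Compare a variable across groups with a normality-gated test
#'
#' Numeric variables: per-group Shapiro-Wilk at `alpha_normal`; if every
#' group passes, one-way ANOVA with pairwise Welch t post hocs, otherwise
#' Kruskal-Wallis with pairwise Wilcoxon rank-sum post hocs. Post hocs run
#' only when the omnibus p-value is below `posthoc_gate` and are
#' Benjamini-Hochberg adjusted. Categorical variables route to a
#' chi-squared test of the group x category contingency table.
#'
#' @param values numeric vector, or factor/character for a categorical
#'   variable.
#' @param labels group labels (coerced to factor), same length as `values`.
#' @param alpha_normal per-group Shapiro-Wilk significance level.
#' @param posthoc_gate omnibus p-value below which pairwise post hocs run.
#' @return list with `test` ("ANOVA", "Kruskal-Wallis" or "chi-square"),
#'   `statistic`, `df`, `p`, and `posthoc` (data.frame of pairwise
#'   comparisons with BH-adjusted p, or NULL).
#' @export
compare_groups <- function(values, labels, alpha_normal = 0.05,
                           posthoc_gate = 0.05) {
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) < 2L) stop("need at least 2 groups")
  if (any(table(labels) < 3L)) stop("every group needs at least 3 observations")
  if (is.factor(values) || is.character(values)) {
    tab <- table(labels, values)
    ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    return(list(test = "chi-square", statistic = unname(ct$statistic),
                df = unname(ct$parameter), p = ct$p.value, posthoc = NULL))
  }
  if (length(values) != length(labels)) stop("values/labels length mismatch")
  if (stats::sd(values) == 0) stop("variable is constant; no test possible")
  normal <- all(vapply(split(values, labels), group_is_normal,
                       logical(1), alpha = alpha_normal))
  if (normal) {
    fit <- stats::aov(values ~ labels)
    s <- summary(fit)[[1]]
    res <- list(test = "ANOVA", statistic = s[["F value"]][1L],
                df = s[["Df"]][1L], p = s[["Pr(>F)"]][1L])
  } else {
    kw <- stats::kruskal.test(values, labels)
    res <- list(test = "Kruskal-Wallis", statistic = unname(kw$statistic),
                df = unname(kw$parameter), p = kw$p.value)
  }
  res$posthoc <- NULL
  if (is.finite(res$p) && res$p < posthoc_gate) {
    combs <- utils::combn(levels(labels), 2)
    ph <- apply(combs, 2, function(pair) {
      a <- values[labels == pair[1]]
      b <- values[labels == pair[2]]
      p <- if (normal) stats::t.test(a, b)$p.value
           else suppressWarnings(stats::wilcox.test(a, b)$p.value)
      data.frame(group_a = pair[1], group_b = pair[2], p = p)
    })
    ph <- do.call(rbind, ph)
    ph$p_adj <- bh_adjust(ph$p)
    res$posthoc <- ph
  }
  res
}

# Residualize a variable on a covariate matrix by least squares (intercept
# always included). Errors on rank-deficient covariates, naming a column
# involved in the collinearity.
residualize <- function(y, covariates) {
  X <- cbind(`(Intercept)` = 1, as.matrix(covariates))
  qr_X <- qr(X)
  if (qr_X$rank < ncol(X)) {
    dropped <- colnames(X)[qr_X$pivot[(qr_X$rank + 1):ncol(X)]][1L]
    stop("covariates are rank deficient; collinear column: ", dropped)
  }
  qr.resid(qr_X, y)
}

#' Correlation with optional covariate adjustment
#'
#' Pearson (or Spearman) correlation; when covariates are supplied, both
#' variables are residualized on them by least squares and the partial
#' correlation p-value uses n - 2 - q degrees of freedom (q covariates).
#'
#' @param x,y numeric vectors of equal length (>= 4 complete cases).
#' @param method "pearson" or "spearman".
#' @param covariates optional data.frame/matrix of nuisance covariates
#'   (numeric; code sex 0/1 upstream).
#' @return list with `r`, `p`, `df`, `n`.
#' @export
correlate <- function(x, y, method = c("pearson", "spearman"),
                      covariates = NULL) {
  method <- match.arg(method)
  if (length(x) != length(y)) stop("x and y must have equal length")
  cc <- stats::complete.cases(x, y,
                              if (!is.null(covariates)) as.matrix(covariates))
  x <- x[cc]; y <- y[cc]
  if (length(x) < 4L) stop("need at least 4 complete cases")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero-variance input")
  q <- 0L
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)[cc, , drop = FALSE]
    # all-zero/constant covariate columns carry no information; drop them so
    # the identity "partial r with null covariates = plain r" holds exactly
    keep <- apply(covariates, 2, function(col) stats::sd(col) > 0)
    covariates <- covariates[, keep, drop = FALSE]
    if (ncol(covariates) > 0L) {
      if (method == "spearman") {
        x <- rank(x); y <- rank(y)
      }
      x <- residualize(x, covariates)
      y <- residualize(y, covariates)
      q <- ncol(covariates)
      method <- "pearson" # residual correlation is Pearson by construction
    }
  }
  n <- length(x)
  r <- stats::cor(x, y, method = method)
  df <- n - 2L - q
  tval <- r * sqrt(df / (1 - r^2))
  p <- if (abs(r) >= 1) 0 else 2 * stats::pt(-abs(tval), df)
  list(r = unname(r), p = unname(p), df = df, n = n)
}

#' Per-gene differential expression between two groups
#'
#' Each gene is tested with a two-sample test chosen by the same
#' Shapiro-Wilk gate as the group comparisons (Welch t if both groups pass,
#' Wilcoxon rank-sum otherwise). Genes with p below `alpha` form the DEG
#' set.
#'
#' @param expr genes x samples numeric matrix.
#' @param group two-level factor over the samples.
#' @param alpha DEG significance threshold (nominal, uncorrected, matching
#'   the validation design).
#' @return data.frame `gene`, `statistic`, `p`, `deg` (logical).
#' @export
deg_analysis <- function(expr, group, alpha = 0.05) {
  group <- droplevels(as.factor(group))
  if (nlevels(group) != 2L) stop("dataset must have exactly two groups")
  if (ncol(expr) != length(group)) stop("expr/group dimension mismatch")
  a <- group == levels(group)[1L]
  res <- t(apply(expr, 1, function(x) {
    xa <- x[a]; xb <- x[!a]
    if (stats::sd(x) == 0) return(c(0, 1))
    if (group_is_normal(xa) && group_is_normal(xb)) {
      tt <- stats::t.test(xa, xb)
      c(unname(tt$statistic), tt$p.value)
    } else {
      wt <- suppressWarnings(stats::wilcox.test(xa, xb))
      c(unname(wt$statistic), wt$p.value)
    }
  }))
  data.frame(gene = rownames(expr), statistic = res[, 1], p = res[, 2],
             deg = res[, 2] < alpha, row.names = NULL)
}

#' Overlap of hub genes with validation-dataset DEGs
#'
#' Runs [deg_analysis()] on the validation dataset and intersects the DEG
#' set with the supplied hub genes. Hub genes absent from the dataset's
#' universe trigger a warning and are ignored.
#'
#' @param hub_genes character vector of hub-gene ids.
#' @param dataset list with `expr` (genes x samples) and `group`, as
#'   produced by [generate_validation_dataset()].
#' @param alpha DEG threshold.
#' @return list with `deg_table`, `deg_genes`, `overlap` (character
#'   vector), `n_overlap`.
#' @export
deg_overlap <- function(hub_genes, dataset, alpha = 0.05) {
  universe <- rownames(dataset$expr)
  outside <- setdiff(hub_genes, universe)
  if (length(outside)) {
    warning(length(outside),
            " hub gene(s) absent from the validation universe; ",
            "overlap computed on the intersection")
    hub_genes <- intersect(hub_genes, universe)
  }
  tab <- deg_analysis(dataset$expr, dataset$group, alpha = alpha)
  deg_genes <- tab$gene[tab$deg]
  overlap <- intersect(hub_genes, deg_genes)
  list(deg_table = tab, deg_genes = deg_genes, overlap = overlap,
       n_overlap = length(overlap))
}

#' ROC area under the curve by the rank statistic
#'
#' AUC = U / (n1 n0) from the Mann-Whitney U computed with midranks, so
#' ties count 1/2. Swapping the positive class maps AUC to 1 - AUC.
#'
#' @param scores numeric scores.
#' @param labels two-level factor/vector; `positive` names the class whose
#'   larger scores mean better discrimination.
#' @param positive positive-class label (default: second factor level).
#' @return object of class `roc_result`: list with `auc`, `positive`,
#'   `n_pos`, `n_neg`.
#' @export
roc_auc <- function(scores, labels, positive = NULL) {
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) != 2L) stop("labels must contain exactly two classes")
  positive <- positive %||% levels(labels)[2L]
  if (!positive %in% levels(labels)) stop("unknown positive class: ", positive)
  pos <- labels == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  r <- rank(scores)
  auc <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  structure(list(auc = unname(auc), positive = positive,
                 n_pos = n1, n_neg = n0),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("AUC = %.4f (positive class '%s', %d vs %d)\n",
              x$auc, x$positive, x$n_pos, x$n_neg))
  invisible(x)
}
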