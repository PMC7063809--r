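#' Keep the most highly expressed genes
#'
#' Retains the \code{ceiling(fraction * G)} genes with the highest mean
#' expression across samples, preserving the input row order of the retained
#' genes. With 19,192 genes and \code{fraction = 0.30} this keeps 5,758 genes
#' (the ceiling rule is the only rounding consistent with that count). Ties
#' at the cutoff are broken by gene ID.
#'
#' @param expr gene x sample matrix.
#' @param fraction fraction of genes to retain, in (0, 1].
#' @return the filtered matrix.
#' @export
filter_top_expressed <- function(expr, fraction) {
  if (!is.numeric(fraction) || length(fraction) != 1 ||
      fraction <= 0 || fraction > 1)
    stop("input error: fraction must lie in (0, 1], got ", fraction)
  g <- nrow(expr)
  keep_n <- ceiling(fraction * g)
  means <- rowMeans(expr)
  ord <- order(-means, rownames(expr), method = "radix")
  keep <- sort(ord[seq_len(keep_n)])
  expr[keep, , drop = FALSE]
}

#' Pairwise covariate/trait association screen
#'
#' For each (outcome, predictor) pair fits either a simple linear regression
#' (quantitative predictor; two-sided slope t test) or a one-way ANOVA
#' (categorical predictor; F test) and reports the raw two-sided p-value.
#' No multiplicity adjustment is applied in this screen.
#'
#' @param tt a \code{\link{trait_table}}.
#' @param outcomes character vector of quantitative outcome trait names.
#' @param predictors character vector of predictor names; kind is taken from
#'   the table's metadata.
#' @return data.frame with columns outcome, predictor, test, statistic, p.
#' @export
screen_covariate_associations <- function(tt, outcomes, predictors) {
  stopifnot(inherits(tt, "trait_table"))
  df <- tt$data
  rows <- list()
  for (out in outcomes) {
    y <- df[[out]]
    if (is.null(y)) stop("unknown outcome: ", out)
    for (pred in predictors) {
      x <- df[[pred]]
      if (is.null(x)) stop("unknown predictor: ", pred)
      j <- match(pred, tt$meta$trait)
      kind <- if (!is.na(j)) tt$meta$kind[j]
        else if (is.numeric(x) && length(unique(stats::na.omit(x))) > 2)
          "quantitative" else "categorical"
      ok <- stats::complete.cases(y, x)
      if (kind == "categorical") {
        xf <- factor(x[ok])
        if (nlevels(xf) < 2)
          stop("input error: categorical predictor ", pred,
               " has a single level")
        fit <- stats::aov(y[ok] ~ xf)
        s <- summary(fit)[[1]]
        rows[[length(rows) + 1]] <- data.frame(
          outcome = out, predictor = pred, test = "anova",
          statistic = s[["F value"]][1], p = s[["Pr(>F)"]][1],
          stringsAsFactors = FALSE)
      } else {
        fit <- stats::lm(y[ok] ~ x[ok])
        s <- summary(fit)$coefficients
        rows[[length(rows) + 1]] <- data.frame(
          outcome = out, predictor = pred, test = "linear_regression",
          statistic = s[2, "t value"], p = s[2, "Pr(>|t|)"],
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Principal-component confounder screen
#'
#' Computes the first \code{n_pcs} principal components of the sample x gene
#' expression matrix (genes standardized), then tests each variable against
#' each component: one-way ANOVA for categorical variables, linear regression
#' for quantitative ones. All raw p-values are Benjamini-Hochberg adjusted
#' jointly across the (variable x component) family. Zero-variance variables
#' are skipped with a warning. Continuous age can be screened alongside a
#' dichotomized age group (the conventional split at age 50) by listing both
#' as variables.
#'
#' @param expr gene x sample matrix.
#' @param tt a \code{\link{trait_table}} covering the expression samples.
#' @param variables variable names to screen (default: all traits in the
#'   table's metadata).
#' @param n_pcs number of leading components (default 3; must be < n samples).
#' @return data.frame with columns variable, pc, test, statistic, p, p_adj.
#' @export
pc_confounder_screen <- function(expr, tt, variables = NULL, n_pcs = 3L) {
  stopifnot(inherits(tt, "trait_table"))
  n <- ncol(expr)
  if (n_pcs < 1) stop("input error: n_pcs must be >= 1")
  if (n_pcs >= n) stop("input error: n_pcs must be < number of samples")
  df <- tt$data[match(colnames(expr), tt$data$sample_id), , drop = FALSE]
  if (anyNA(df$sample_id))
    stop("input error: trait table does not cover all expression samples")
  if (is.null(variables)) variables <- tt$meta$trait

  ## genes standardized => PCA of the correlation structure among samples
  x <- t(expr)
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) x <- x[, sds > 0, drop = FALSE]
  pcs <- stats::prcomp(x, center = TRUE, scale. = TRUE)$x[, seq_len(n_pcs),
                                                          drop = FALSE]
  rows <- list()
  for (v in variables) {
    val <- df[[v]]
    if (is.null(val)) stop("unknown variable: ", v)
    if (length(unique(stats::na.omit(val))) <= 1) {
      warning("skipping zero-variance variable: ", v)
      next
    }
    j <- match(v, tt$meta$trait)
    kind <- if (!is.na(j)) tt$meta$kind[j]
      else if (is.numeric(val) && length(unique(stats::na.omit(val))) > 2)
        "quantitative" else "categorical"
    for (k in seq_len(n_pcs)) {
      pc <- pcs[, k]
      ok <- stats::complete.cases(val, pc)
      if (kind == "categorical") {
        fit <- stats::aov(pc[ok] ~ factor(val[ok]))
        s <- summary(fit)[[1]]
        rows[[length(rows) + 1]] <- data.frame(
          variable = v, pc = paste0("PC", k), test = "anova",
          statistic = s[["F value"]][1], p = s[["Pr(>F)"]][1],
          stringsAsFactors = FALSE)
      } else {
        fit <- stats::lm(val[ok] ~ pc[ok])
        s <- summary(fit)$coefficients
        rows[[length(rows) + 1]] <- data.frame(
          variable = v, pc = paste0("PC", k), test = "linear_regression",
          statistic = s[2, "t value"], p = s[2, "Pr(>|t|)"],
          stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, rows)
  if (is.null(res)) stop("input error: no testable variables")
  res$p_adj <- benjamini_hochberg(res$p)
  res
}
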