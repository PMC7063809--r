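#' Module eigengene
#'
#' First principal component of the module's gene-standardized expression
#' across samples, scaled to unit Euclidean norm (it has zero mean because
#' every standardized gene does). The sign is fixed so that the mean
#' correlation with the module's member genes is positive.
#'
#' @param expr gene x sample matrix.
#' @param module_genes gene IDs of the module (>= 2 genes with variance).
#' @return list with \code{eigengene} (named per-sample vector),
#'   \code{variance_explained}, and \code{sign_flipped}.
#' @export
module_eigengene <- function(expr, module_genes) {
  sub <- expr[intersect(module_genes, rownames(expr)), , drop = FALSE]
  sds <- apply(sub, 1, stats::sd)
  sub <- sub[sds > 0, , drop = FALSE]
  if (nrow(sub) < 2)
    stop("input error: module needs >= 2 genes with nonzero variance")
  z <- t(scale(t(sub)))            # standardize each gene across samples
  sv <- svd(t(z), nu = 1, nv = 0)  # samples x genes
  e <- sv$u[, 1]
  flipped <- FALSE
  if (mean(stats::cor(e, t(sub))) < 0) { e <- -e; flipped <- TRUE }
  list(
    eigengene = stats::setNames(e, colnames(expr)),
    variance_explained = sv$d[1]^2 / sum(sv$d^2),
    sign_flipped = flipped
  )
}

#' Eigengenes for every module of a partition
#'
#' @param expr gene x sample matrix.
#' @param partition a \code{\link{module_partition}} (or an integer label
#'   vector named by gene).
#' @return list of class \code{eigengene_set}: \code{eigengenes}
#'   (module x sample matrix, rows named by module color) and
#'   \code{variance_explained}.
#' @export
eigengene_set <- function(expr, partition) {
  labels <- if (inherits(partition, "module_partition")) partition$labels
            else partition
  cmap <- if (inherits(partition, "module_partition")) partition$color_map
          else assign_colors(labels)
  mods <- sort(unique(labels[labels > 0]))
  if (length(mods) == 0) stop("input error: no modules in partition")
  res <- lapply(mods, function(m)
    module_eigengene(expr, names(labels)[labels == m]))
  eig <- t(sapply(res, `[[`, "eigengene"))
  rownames(eig) <- unname(cmap[as.character(mods)])
  colnames(eig) <- colnames(expr)
  structure(list(
    eigengenes = eig,
    variance_explained = stats::setNames(
      vapply(res, `[[`, 0, "variance_explained"), rownames(eig))
  ), class = "eigengene_set")
}

#' Module membership (kME)
#'
#' Pearson correlation of every gene's profile with every module eigengene;
#' high kME means the gene tracks the module's summary profile closely.
#'
#' @param expr gene x sample matrix.
#' @param eigengenes an \code{\link{eigengene_set}} or module x sample matrix.
#' @return gene x module matrix of correlations.
#' @export
module_membership <- function(expr, eigengenes) {
  eig <- if (inherits(eigengenes, "eigengene_set")) eigengenes$eigengenes
         else eigengenes
  kme <- stats::cor(t(expr), t(eig))
  dimnames(kme) <- list(rownames(expr), rownames(eig))
  kme
}

#' Gene significance for a quantitative trait
#'
#' \eqn{GS_g = |cor(x_g, trait)|} over pairwise-complete samples.
#'
#' @param expr gene x sample matrix.
#' @param trait named numeric vector (names = sample IDs) or plain vector
#'   aligned with \code{colnames(expr)}.
#' @return named vector of absolute correlations.
#' @export
gene_significance <- function(expr, trait) {
  if (!is.null(names(trait))) trait <- trait[colnames(expr)]
  ok <- !is.na(trait)
  if (sum(ok) < 3) stop("input error: need >= 3 overlapping samples")
  if (stats::sd(trait[ok]) == 0)
    stop("input error: trait has zero variance")
  gs <- abs(as.numeric(stats::cor(t(expr[, ok, drop = FALSE]), trait[ok])))
  stats::setNames(gs, rownames(expr))
}

#' Residualize a trait on covariates
#'
#' Ordinary least-squares residuals of the trait on an intercept plus the
#' covariates (categorical covariates should be coded 0/1, reference level
#' alphabetical). Missing trait values propagate as missing.
#'
#' @param trait numeric vector.
#' @param covariates data.frame or matrix of covariates (same row order);
#'   NULL or zero columns returns the trait unchanged.
#' @return residualized trait (same length/names as input).
#' @export
adjust_trait <- function(trait, covariates = NULL) {
  if (is.null(covariates) || NCOL(covariates) == 0) return(trait)
  cov_df <- as.data.frame(covariates)
  for (j in seq_along(cov_df)) {
    if (is.character(cov_df[[j]]) || is.factor(cov_df[[j]]))
      cov_df[[j]] <- as.integer(factor(cov_df[[j]])) - 1L
  }
  x <- stats::model.matrix(~ ., data = cov_df)
  ok <- !is.na(trait) & stats::complete.cases(cov_df)
  if (qr(x[ok, , drop = FALSE])$rank < ncol(x))
    stop("input error: rank-deficient covariate design")
  fit <- stats::lm.fit(x[ok, , drop = FALSE], trait[ok])
  out <- rep(NA_real_, length(trait))
  out[ok] <- fit$residuals
  names(out) <- names(trait)
  out
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' \eqn{q_{(i)} = \min_{j \ge i} p_{(j)} m / j}, capped at 1, returned in
#' the original order.
#'
#' @param pvals numeric vector of p-values in [0,1] (NA allowed).
#' @return adjusted p-values.
#' @export
benjamini_hochberg <- function(pvals) {
  ok <- !is.na(pvals)
  if (any(pvals[ok] < 0 | pvals[ok] > 1))
    stop("input error: p-values must lie in [0,1]")
  stats::p.adjust(pvals, method = "BH")
}

#' Module-trait correlation with covariate adjustment and FDR control
#'
#' For each quantitative trait, first residualizes the trait on its declared
#' adjustment covariates, then correlates it (Pearson) with every module
#' eigengene over the overlapping samples. Two-sided p-values come from
#' \eqn{t = r\sqrt{(n-2)/(1-r^2)}} on \eqn{n-2} degrees of freedom, and all
#' (module x trait) p-values are Benjamini-Hochberg adjusted in one family
#' by default (\code{fdr_scope = "matrix"}; \code{"per_trait"} adjusts each
#' trait's column separately). Pairs whose residualized trait has zero
#' variance are skipped.
#'
#' @param eigengenes an \code{\link{eigengene_set}}.
#' @param tt a \code{\link{trait_table}}; covariate columns named in each
#'   trait's metadata must be present in the table.
#' @param traits trait names to test (default: all quantitative,
#'   non-zero-variance traits that are not themselves covariates).
#' @param fdr_scope \code{"matrix"} or \code{"per_trait"}.
#' @param alpha significance cutoff on adjusted p (default 0.05).
#' @return data.frame of class \code{module_trait_result}: module, trait, r,
#'   p, p_adj, n_used, covariates_adjusted, significant.
#' @export
module_trait_correlation <- function(eigengenes, tt, traits = NULL,
                                     fdr_scope = c("matrix", "per_trait"),
                                     alpha = 0.05) {
  stopifnot(inherits(eigengenes, "eigengene_set"), inherits(tt, "trait_table"))
  fdr_scope <- match.arg(fdr_scope)
  eig <- eigengenes$eigengenes
  df <- tt$data[match(colnames(eig), tt$data$sample_id), , drop = FALSE]
  if (anyNA(df$sample_id))
    stop("input error: trait table does not cover the eigengene samples")
  all_cov <- unique(unlist(lapply(tt$meta$trait, trait_covariates, tt = tt)))
  if (is.null(traits))
    traits <- tt$meta$trait[tt$meta$kind == "quantitative" &
                            !tt$meta$zero_variance &
                            !tt$meta$trait %in% all_cov]
  rows <- list()
  for (tr in traits) {
    covs <- trait_covariates(tt, tr)
    y <- adjust_trait(df[[tr]], if (length(covs)) df[covs] else NULL)
    for (m in rownames(eig)) {
      e <- eig[m, ]
      ok <- !is.na(y)
      n_used <- sum(ok)
      if (n_used < 4) stop("input error: < 4 overlapping samples for ",
                           m, " x ", tr)
      if (stats::sd(y[ok]) == 0) {
        warning("skipping zero-variance residualized trait: ", tr)
        next
      }
      r <- stats::cor(e[ok], y[ok])
      tstat <- r * sqrt((n_used - 2) / max(1 - r^2, .Machine$double.eps))
      p <- 2 * stats::pt(abs(tstat), df = n_used - 2, lower.tail = FALSE)
      rows[[length(rows) + 1]] <- data.frame(
        module = m, trait = tr, r = r, p = p, n_used = n_used,
        covariates_adjusted = paste(covs, collapse = ";"),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  if (is.null(res)) stop("input error: no testable module-trait pairs")
  if (fdr_scope == "matrix") {
    res$p_adj <- benjamini_hochberg(res$p)
  } else {
    res$p_adj <- NA_real_
    for (tr in unique(res$trait)) {
      sel <- res$trait == tr
      res$p_adj[sel] <- benjamini_hochberg(res$p[sel])
    }
  }
  res$significant <- res$p_adj < alpha
  res <- res[, c("module", "trait", "r", "p", "p_adj", "n_used",
                 "covariates_adjusted", "significant")]
  class(res) <- c("module_trait_result", "data.frame")
  res
}
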