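#' Gene-gene Pearson correlation matrix
#'
#' Pearson correlation across samples for every gene pair. Genes with zero
#' variance are an error: they have no defined correlation and would silently
#' poison the adjacency.
#'
#' @param expr gene x sample matrix, >= 3 samples, no missing values.
#' @return symmetric correlation matrix with unit diagonal, gene IDs as
#'   dimnames.
#' @export
pairwise_correlation <- function(expr) {
  if (ncol(expr) < 3) stop("input error: need >= 3 samples")
  validate_expression(expr)
  sds <- apply(expr, 1, stats::sd)
  if (any(sds == 0))
    stop("input error: zero-variance gene(s): ",
         paste(utils::head(rownames(expr)[sds == 0], 5), collapse = ", "))
  r <- stats::cor(t(expr))
  diag(r) <- 1
  r
}

#' Unsigned soft-power adjacency
#'
#' \eqn{a_{ij} = |r_{ij}|^\beta}: the correlation sign is discarded and the
#' soft power suppresses weak correlations without hard thresholding.
#'
#' @param cor_mat correlation matrix.
#' @param power soft-threshold power (positive integer-valued).
#' @param network_type only \code{"unsigned"} is supported.
#' @return adjacency matrix in [0,1] with attribute \code{power}.
#' @export
adjacency <- function(cor_mat, power, network_type = "unsigned") {
  network_type <- match.arg(network_type, "unsigned")
  if (!is.numeric(power) || length(power) != 1 || power < 1)
    stop("input error: power must be a positive number >= 1, got ", power)
  a <- abs(cor_mat)^power
  attr(a, "power") <- power
  a
}

#' Whole-network connectivity
#'
#' \eqn{k_i = \sum_{j \ne i} a_{ij}}: the diagonal is excluded.
#'
#' @param adj adjacency matrix.
#' @return named numeric vector of connectivities.
#' @export
connectivity <- function(adj) {
  k <- rowSums(adj) - diag(adj)
  stats::setNames(as.numeric(k), rownames(adj))
}

#' Scale-free topology fit of a connectivity distribution
#'
#' Bins connectivity into \code{n_bins} equal-width bins and regresses
#' \eqn{\log_{10} p(k)} on \eqn{\log_{10} \bar k} over non-empty bins
#' (unweighted least squares). A connectivity distribution following a power
#' law gives a straight line; the R-squared of that line is the usual
#' criterion for choosing the soft power.
#'
#' @param k non-negative connectivity vector with >= \code{n_bins} distinct
#'   values.
#' @param n_bins number of equal-width bins (default 10).
#' @return data.frame row with r_squared, slope, mean_connectivity, and the
#'   number of non-empty bins used.
#' @export
scale_free_fit <- function(k, n_bins = 10L) {
  if (n_bins < 2) stop("input error: n_bins must be >= 2")
  if (any(k < 0)) stop("input error: connectivity must be non-negative")
  if (length(unique(k)) < 2 || diff(range(k)) == 0)
    stop("input error: all connectivities identical; no distribution to fit")
  breaks <- seq(min(k), max(k), length.out = n_bins + 1)
  bin <- cut(k, breaks = breaks, include.lowest = TRUE)
  freq <- as.numeric(table(bin)) / length(k)
  kmean <- tapply(k, bin, mean)
  keep <- freq > 0 & !is.na(kmean) & kmean > 0
  if (sum(keep) < 3)
    stop("input error: fewer than 3 usable bins; connectivity range too narrow")
  fit <- stats::lm(log10(freq[keep]) ~ log10(kmean[keep]))
  data.frame(
    r_squared = summary(fit)$r.squared,
    slope = unname(stats::coef(fit)[2]),
    mean_connectivity = mean(k),
    n_bins_used = sum(keep)
  )
}

#' Choose a soft-threshold power by scale-free topology fit
#'
#' Evaluates each candidate power and picks the smallest whose fit reaches
#' \code{r2_target} with a negative slope (the conventional criterion, with
#' R-squared around 0.8 regarded as adequate); if none qualifies, falls back
#' to the power with the largest R-squared, with a warning.
#'
#' @param expr gene x sample matrix.
#' @param candidate_powers ascending positive integers (default 1:12).
#' @param r2_target R-squared threshold (default 0.8).
#' @param n_bins bins for \code{\link{scale_free_fit}}.
#' @return list with \code{power} (chosen) and \code{fits} (diagnostic
#'   data.frame, one row per candidate).
#' @export
pick_soft_threshold <- function(expr, candidate_powers = 1:12,
                                r2_target = 0.8, n_bins = 10L) {
  if (length(candidate_powers) == 0)
    stop("input error: candidate_powers is empty")
  if (is.unsorted(candidate_powers, strictly = TRUE))
    stop("input error: candidate_powers must be strictly ascending")
  r <- pairwise_correlation(expr)
  fits <- do.call(rbind, lapply(candidate_powers, function(p) {
    k <- connectivity(adjacency(r, p))
    cbind(power = p, scale_free_fit(k, n_bins = n_bins))
  }))
  ok <- fits$r_squared >= r2_target & fits$slope < 0
  if (any(ok)) {
    chosen <- fits$power[which(ok)[1]]
  } else {
    chosen <- fits$power[which.max(fits$r_squared)]
    warning("no candidate power reached R^2 >= ", r2_target,
            "; falling back to the best fit (power ", chosen, ")")
  }
  list(power = chosen, fits = fits)
}

#' Topological overlap matrix
#'
#' For an unsigned adjacency \eqn{A}, the topological overlap between genes
#' i and j combines their direct connection with their shared neighbourhood:
#' \deqn{TOM_{ij} = \frac{\ell_{ij} + a_{ij}}{\min(k_i, k_j) + 1 - a_{ij}},
#'   \quad \ell_{ij} = \sum_{u \ne i,j} a_{iu} a_{uj},}
#' with \eqn{TOM_{ii} = 1}. Computed in matrix form: \eqn{\ell = A^2 -}
#' row/column corrections, so the cost is one dense matrix product.
#' A degenerate zero denominator (only possible for a fully saturated pair)
#' is guarded to the limiting value 1.
#'
#' @param adj adjacency matrix in [0,1].
#' @return TOM matrix in [0,1] with unit diagonal.
#' @export
topological_overlap <- function(adj) {
  a <- adj
  diag(a) <- 0
  l <- a %*% a            # zero diagonal kills the u = i and u = j terms
  k <- rowSums(a)
  kmin <- outer(k, k, pmin)
  denom <- kmin + 1 - a
  tom <- (l + a) / denom
  tom[denom <= 0] <- 1
  diag(tom) <- 1
  tom[tom > 1] <- 1
  tom[tom < 0] <- 0
  dimnames(tom) <- dimnames(adj)
  tom
}

#' Write a symmetric matrix as (optionally gzip-compressed) TSV
#' @param mat matrix with dimnames.
#' @param path output path; a \code{.gz} suffix triggers compression.
#' @export
write_matrix_tsv <- function(mat, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  utils::write.table(data.frame(id = rownames(mat), mat, check.names = FALSE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
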