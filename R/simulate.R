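#' Simulation configuration for planted co-expression modules
#'
#' Describes a synthetic expression study: a latent-factor model in which each
#' planted module m has a per-sample standard-normal factor f_m, and each gene
#' g in module m is generated as
#' \deqn{x_g = \lambda_m f_m + \sqrt{1 - \lambda_m^2}\,\epsilon_g,}
#' with unit-normal noise, so the expected pairwise correlation inside the
#' module is \eqn{\lambda_m^2 =} \code{within_module_cor[m]}. Background genes
#' are pure noise. Traits are linear combinations of module factors plus
#' sex/race effects plus Gaussian noise, emulating a small clinical cohort
#' (default n = 26, with sex and race drawn Bernoulli(15/26) to match the
#' cohort composition the package's defaults emulate).
#'
#' @param n_samples number of samples (default 26).
#' @param module_sizes integer vector of planted module sizes.
#' @param within_module_cor expected within-module correlation per module in
#'   (0,1] (1 being the degenerate noiseless case); recycled to
#'   \code{length(module_sizes)}.
#' @param n_background number of pure-noise background genes.
#' @param trait_specs list of trait specifications, each a list with elements
#'   \code{name}, \code{effects} (named or two-column matrix/list of
#'   (module index, effect size) pairs), optional \code{sex_effect},
#'   \code{race_effect} and \code{noise_sd} (default 1).
#' @param neg_loading_fraction fraction of modules in which half the genes get
#'   negative loadings, exercising unsigned-adjacency behaviour (default 0).
#' @param hub_loadings optional list of lists with elements \code{module},
#'   \code{gene} (index within the module) and \code{loading}: designated
#'   genes given an elevated loading, planting a connectivity hub.
#' @param prop_female,prop_aa Bernoulli rates for the sex and race covariates.
#' @param seed integer seed; identical seeds give bitwise-identical output.
#'
#' @return an object of class \code{simulation_config}.
#' @export
simulation_config <- function(n_samples = 26L,
                              module_sizes,
                              within_module_cor = 0.5,
                              n_background = 0L,
                              trait_specs = list(),
                              neg_loading_fraction = 0,
                              hub_loadings = NULL,
                              prop_female = 15 / 26,
                              prop_aa = 15 / 26,
                              seed = 1L) {
  if (n_samples < 4)
    stop("configuration error: n_samples must be >= 4, got ", n_samples)
  module_sizes <- as.integer(module_sizes)
  if (any(module_sizes < 1))
    stop("configuration error: module_sizes must be positive integers")
  wmc <- rep_len(within_module_cor, length(module_sizes))
  if (any(wmc <= 0 | wmc > 1))
    stop("configuration error: within_module_cor must lie in (0,1]")
  if (n_background < 0)
    stop("configuration error: n_background must be non-negative")
  for (ts in trait_specs) {
    if (is.null(ts$name)) stop("configuration error: trait_specs entry lacks a name")
    for (ef in ts$effects) {
      if (ef[[1]] < 1 || ef[[1]] > length(module_sizes))
        stop("configuration error: trait_specs for '", ts$name,
             "' references module ", ef[[1]], " but only ",
             length(module_sizes), " modules are defined")
    }
  }
  structure(list(
    n_samples = as.integer(n_samples),
    module_sizes = module_sizes,
    n_genes = sum(module_sizes) + as.integer(n_background),
    within_module_cor = wmc,
    n_background = as.integer(n_background),
    trait_specs = trait_specs,
    neg_loading_fraction = neg_loading_fraction,
    hub_loadings = hub_loadings,
    prop_female = prop_female,
    prop_aa = prop_aa,
    seed = as.integer(seed)
  ), class = "simulation_config")
}

#' Convenience constructor for one trait specification
#'
#' @param name trait name.
#' @param effects list of \code{c(module, effect)} pairs; effect is the
#'   coefficient on the module's latent factor.
#' @param sex_effect,race_effect additive effects of the binary covariates.
#' @param noise_sd standard deviation of the trait's Gaussian noise.
#' @export
trait_spec <- function(name, effects = list(), sex_effect = 0,
                       race_effect = 0, noise_sd = 1) {
  list(name = name, effects = effects, sex_effect = sex_effect,
       race_effect = race_effect, noise_sd = noise_sd)
}

#' Generate a synthetic expression/trait dataset with known ground truth
#'
#' Draws latent module factors, gene expression, covariates and traits under
#' the factor model described in \code{\link{simulation_config}}.
#'
#' @param config a \code{\link{simulation_config}}.
#' @return a list with elements
#'   \item{expr}{gene x sample expression matrix with unique gene/sample ids,}
#'   \item{traits}{data.frame of traits and covariates, one row per sample
#'     (column \code{sample_id} first; \code{sex}, \code{race} coded 0/1),}
#'   \item{truth}{list with \code{planted_labels} (0 = background),
#'     \code{factors} (sample x module latent factors),
#'     \code{trait_effects}, and \code{covariates}.}
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  n <- config$n_samples
  sizes <- config$module_sizes
  M <- length(sizes)
  G <- config$n_genes

  sample_ids <- sprintf("S%02d", seq_len(n))
  gene_ids <- sprintf("G%05d", seq_len(G))

  ## latent factors, one standard-normal column per module
  f <- matrix(rnorm(n * M), nrow = n, ncol = M,
              dimnames = list(sample_ids, sprintf("F%d", seq_len(M))))

  labels <- rep.int(c(seq_len(M), 0L), c(sizes, config$n_background))
  lambda <- sqrt(config$within_module_cor)

  ## per-gene loadings; optionally flip sign on half the genes of some modules
  n_neg <- floor(config$neg_loading_fraction * M)
  neg_modules <- if (n_neg > 0) seq_len(n_neg) else integer(0)

  expr <- matrix(0, nrow = G, ncol = n, dimnames = list(gene_ids, sample_ids))
  for (m in seq_len(M)) {
    idx <- which(labels == m)
    lam <- rep(lambda[m], length(idx))
    if (m %in% neg_modules) {
      flip <- seq_len(floor(length(idx) / 2))
      lam[flip] <- -lam[flip]
    }
    if (!is.null(config$hub_loadings)) {
      for (h in config$hub_loadings) {
        if (h$module == m) lam[h$gene] <- sign(lam[h$gene]) * h$loading
      }
    }
    noise <- matrix(rnorm(length(idx) * n), nrow = length(idx))
    expr[idx, ] <- lam %o% f[, m] + sqrt(1 - lam^2) * noise
  }
  bg <- which(labels == 0L)
  if (length(bg) > 0)
    expr[bg, ] <- matrix(rnorm(length(bg) * n), nrow = length(bg))

  sex <- rbinom(n, 1L, config$prop_female)
  race <- rbinom(n, 1L, config$prop_aa)

  traits <- data.frame(sample_id = sample_ids, sex = sex, race = race,
                       stringsAsFactors = FALSE)
  effects_out <- list()
  for (ts in config$trait_specs) {
    y <- rep(0, n)
    for (ef in ts$effects) y <- y + ef[[2]] * f[, ef[[1]]]
    sx <- if (is.null(ts$sex_effect)) 0 else ts$sex_effect
    rc <- if (is.null(ts$race_effect)) 0 else ts$race_effect
    sdn <- if (is.null(ts$noise_sd)) 1 else ts$noise_sd
    y <- y + sx * sex + rc * race
    if (sdn > 0) y <- y + rnorm(n, sd = sdn)
    traits[[ts$name]] <- y
    effects_out[[ts$name]] <- ts$effects
  }

  list(
    expr = expr,
    traits = traits,
    truth = list(
      planted_labels = stats::setNames(labels, gene_ids),
      factors = f,
      trait_effects = effects_out,
      covariates = data.frame(sample_id = sample_ids, sex = sex, race = race)
    )
  )
}

#' Write a simulated dataset to plain-text files
#'
#' Writes the expression matrix as TSV (genes as rows), the trait table as
#' CSV, and the ground truth as JSON.
#'
#' @param dataset result of \code{\link{generate_dataset}}.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_dataset <- function(dataset, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  expr_path <- file.path(dir, "expression.tsv")
  trait_path <- file.path(dir, "traits.csv")
  truth_path <- file.path(dir, "truth.json")
  write_expression_table(dataset$expr, expr_path)
  utils::write.csv(dataset$traits, trait_path, row.names = FALSE)
  truth <- dataset$truth
  truth$factors <- NULL  # matrices do not round-trip usefully through JSON
  jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA)
  invisible(c(expr = expr_path, traits = trait_path, truth = truth_path))
}

#' Adjusted Rand index between two labelings
#'
#' Used to score recovery of planted module labels by the detection pipeline;
#' background/unassigned (0/"grey") counts as its own class.
#'
#' @param a,b label vectors of equal length.
#' @return the adjusted Rand index (1 = identical partitions).
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("label vectors differ in length")
  tab <- table(a, b)
  n <- length(a)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  expected <- sum_a * sum_b / comb2(n)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}
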