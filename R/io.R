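#' Read an expression matrix from TSV or a GEO Series Matrix file
#'
#' Plain TSV is expected to have a header row of sample identifiers and the
#' feature identifier in the first column. A GEO Series Matrix file carries
#' its numeric table between the \code{!series_matrix_table_begin} and
#' \code{!series_matrix_table_end} fence lines; only fenced rows are parsed,
#' metadata lines are skipped, and sample IDs are taken from the fenced
#' header row. Feature and sample identifiers must be unique and all values
#' finite.
#'
#' @param path file path.
#' @param format \code{"tsv"} or \code{"geo_series_matrix"}.
#' @return numeric matrix, features as rows, samples as columns.
#' @export
read_expression_table <- function(path, format = c("tsv", "geo_series_matrix")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("input error: file not found: ", path)
  if (format == "geo_series_matrix") {
    lines <- readLines(path)
    begin <- grep("^!series_matrix_table_begin", lines)
    end <- grep("^!series_matrix_table_end", lines)
    if (length(begin) != 1 || length(end) != 1 || end <= begin + 1)
      stop("format error: series-matrix table fences not found or empty in ", path)
    lines <- lines[(begin + 1):(end - 1)]
    lines <- gsub('"', "", lines, fixed = TRUE)
    tab <- utils::read.delim(text = paste(lines, collapse = "\n"),
                             check.names = FALSE, stringsAsFactors = FALSE)
  } else {
    tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  }
  if (ncol(tab) < 2) stop("format error: expected an ID column plus >=1 sample")
  feature_ids <- as.character(tab[[1]])
  dup <- feature_ids[duplicated(feature_ids)]
  if (length(dup) > 0)
    stop("format error: duplicate feature ID(s): ",
         paste(unique(dup), collapse = ", "))
  sample_ids <- colnames(tab)[-1]
  if (anyDuplicated(sample_ids))
    stop("format error: duplicate sample ID(s): ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  vals <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(vals)) {
    bad <- which(is.na(suppressWarnings(apply(tab[, -1, drop = FALSE], 2,
                                              as.numeric))) &
                 !is.na(as.matrix(tab[, -1, drop = FALSE])), arr.ind = TRUE)
    if (nrow(bad) > 0)
      stop("parse error: non-numeric value at row ", bad[1, 1],
           ", column ", bad[1, 2] + 1)
    storage.mode(vals) <- "double"
  }
  dimnames(vals) <- list(feature_ids, sample_ids)
  validate_expression(vals)
  vals
}

validate_expression <- function(x) {
  if (anyNA(x) || any(!is.finite(x)))
    stop("format error: expression matrix contains missing or non-finite ",
         "values; impute or remove them before analysis")
  invisible(x)
}

#' Write an expression matrix as TSV (genes as rows)
#' @param expr numeric matrix with dimnames.
#' @param path output file path.
#' @export
write_expression_table <- function(expr, path) {
  df <- data.frame(gene_id = rownames(expr), expr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a transcript-to-gene annotation map
#'
#' Accepts a 2-column TSV (transcript ID, gene symbol) or a GEO
#' \code{.annot}-style tab-delimited file in which the identifier column is
#' named \code{ID} and the symbol column \code{Gene symbol} (metadata lines
#' starting with \code{!} or \code{#} are skipped). Transcripts with an empty
#' symbol are recorded as unmapped.
#'
#' @param path file path.
#' @return named character vector: names are transcript IDs, values gene
#'   symbols, with an attribute \code{unmapped} listing transcripts without a
#'   symbol.
#' @export
read_annotation <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^[!#]", lines) & nzchar(lines)]
  tab <- utils::read.delim(text = paste(lines, collapse = "\n"),
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (all(c("ID", "Gene symbol") %in% colnames(tab))) {
    ids <- as.character(tab[["ID"]])
    sym <- as.character(tab[["Gene symbol"]])
  } else {
    if (ncol(tab) < 2) stop("format error: annotation needs >= 2 columns")
    ids <- as.character(tab[[1]])
    sym <- as.character(tab[[2]])
  }
  if (anyDuplicated(ids))
    stop("format error: transcript ", ids[duplicated(ids)][1],
         " annotated more than once")
  unmapped <- ids[is.na(sym) | sym == ""]
  keep <- !(is.na(sym) | sym == "")
  map <- stats::setNames(sym[keep], ids[keep])
  attr(map, "unmapped") <- unmapped
  map
}

#' Collapse transcript-level expression to gene level
#'
#' For each gene symbol, retains the single transcript with the highest mean
#' expression across samples (arithmetic mean on the stored log scale); ties
#' are broken by the lexicographically smallest transcript ID. Transcripts
#' absent from the annotation are dropped.
#'
#' @param expr transcript x sample matrix.
#' @param annot named character vector from \code{\link{read_annotation}}
#'   (or any transcript -> symbol map).
#' @return gene x sample matrix whose rownames are gene symbols, with an
#'   attribute \code{representative} naming the transcript kept per gene.
#' @export
collapse_to_genes <- function(expr, annot) {
  common <- intersect(rownames(expr), names(annot))
  if (length(common) == 0)
    stop("input error: no transcript of the expression matrix appears in ",
         "the annotation")
  expr <- expr[common, , drop = FALSE]
  genes <- as.character(annot[common])
  means <- rowMeans(expr)
  ## order by symbol, then mean descending, then transcript ID: the first row
  ## per symbol is the max-mean transcript with lexicographic tie-break
  ord <- order(genes, -means, rownames(expr), method = "radix")
  first <- ord[!duplicated(genes[ord])]
  first <- first[order(rownames(expr)[first], method = "radix")]
  out <- expr[first, , drop = FALSE]
  rep_tx <- rownames(out)
  rownames(out) <- genes[first]
  out <- out[order(rownames(out), method = "radix"), , drop = FALSE]
  attr(out, "representative") <- stats::setNames(rep_tx[order(genes[first],
                                                              method = "radix")],
                                                 sort(unique(genes)))
  out
}

#' Read a clinical trait table with its metadata schema
#'
#' Reads a CSV with a \code{sample_id} column. Per-trait metadata (kind,
#' timepoint, adjustment covariates) comes from a sidecar schema CSV with
#' columns \code{trait}, \code{kind} (\code{quantitative} or
#' \code{categorical}), \code{timepoint} (\code{BL}, \code{3M}, \code{6M},
#' \code{12M} or \code{static}) and \code{covariates} (semicolon-separated).
#' Without a schema, kinds are inferred from column type, timepoints from
#' \code{_BL}/\code{_3M}/\code{_6M}/\code{_12M} suffixes, and body-size
#' traits (height, weight, BMI, fat) receive the standard adjustment: sex and
#' race at baseline, sex at the other timepoints. Missing values are kept as
#' \code{NA}; zero-variance traits load but are flagged.
#'
#' @param path CSV path.
#' @param schema_path optional schema CSV path.
#' @return a \code{trait_table}: list with \code{data} (data.frame keyed by
#'   \code{sample_id}) and \code{meta} (data.frame of trait, kind, timepoint,
#'   covariates, zero_variance).
#' @export
read_trait_table <- function(path, schema_path = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"sample_id" %in% colnames(df))
    stop("format error: trait table lacks a sample_id column")
  trait_table(df, schema = if (!is.null(schema_path))
    utils::read.csv(schema_path, stringsAsFactors = FALSE) else NULL)
}

#' Construct a trait table from a data.frame
#' @param df data.frame with a \code{sample_id} column.
#' @param schema optional data.frame (trait, kind, timepoint, covariates).
#' @return a \code{trait_table} object.
#' @export
trait_table <- function(df, schema = NULL) {
  if (!"sample_id" %in% colnames(df))
    stop("format error: trait table lacks a sample_id column")
  if (anyDuplicated(df$sample_id))
    stop("format error: duplicate sample_id in trait table")
  traits <- setdiff(colnames(df), "sample_id")
  meta <- data.frame(trait = traits, stringsAsFactors = FALSE)
  infer_tp <- function(x) {
    tp <- regmatches(x, regexpr("_(BL|3M|6M|12M)$", x))
    if (length(tp) == 0) "static" else sub("^_", "", tp)
  }
  body_size <- grepl("height|weight|wt|bmi|fat", traits, ignore.case = TRUE) &
    !grepl("chg|change", traits, ignore.case = TRUE)
  meta$kind <- vapply(traits, function(tr) {
    if (is.numeric(df[[tr]]) && length(unique(stats::na.omit(df[[tr]]))) > 2)
      "quantitative" else "categorical"
  }, "")
  meta$timepoint <- vapply(traits, infer_tp, "")
  meta$covariates <- vapply(seq_along(traits), function(i) {
    if (!body_size[i]) return("")
    if (meta$timepoint[i] == "BL") "sex;race"
    else if (meta$timepoint[i] %in% c("3M", "6M", "12M")) "sex"
    else "sex;race"
  }, "")
  if (!is.null(schema)) {
    need <- c("trait", "kind")
    if (!all(need %in% colnames(schema)))
      stop("schema error: schema must have columns trait and kind")
    bad_kind <- setdiff(unique(schema$kind), c("quantitative", "categorical"))
    if (length(bad_kind) > 0)
      stop("schema error: unknown trait kind: ", paste(bad_kind, collapse = ", "))
    for (i in seq_len(nrow(schema))) {
      j <- match(schema$trait[i], meta$trait)
      if (is.na(j)) next
      meta$kind[j] <- schema$kind[i]
      if ("timepoint" %in% colnames(schema) && !is.na(schema$timepoint[i]))
        meta$timepoint[j] <- schema$timepoint[i]
      if ("covariates" %in% colnames(schema) && !is.na(schema$covariates[i]))
        meta$covariates[j] <- schema$covariates[i]
    }
  }
  meta$zero_variance <- vapply(traits, function(tr) {
    v <- stats::na.omit(df[[tr]])
    length(unique(v)) <= 1
  }, NA)
  for (tr in traits[meta$kind == "categorical"]) {
    if (!meta$zero_variance[match(tr, meta$trait)] &&
        length(unique(stats::na.omit(df[[tr]]))) < 2)
      stop("format error: categorical trait ", tr, " has < 2 observed levels")
  }
  structure(list(data = df, meta = meta), class = "trait_table")
}

#' @export
print.trait_table <- function(x, ...) {
  cat("trait_table:", nrow(x$data), "samples,", nrow(x$meta), "traits\n")
  print(x$meta, row.names = FALSE)
  invisible(x)
}

#' Adjustment covariate names for one trait
#' @param tt a \code{trait_table}.
#' @param trait trait name.
#' @return character vector of covariate column names (possibly empty).
#' @export
trait_covariates <- function(tt, trait) {
  j <- match(trait, tt$meta$trait)
  if (is.na(j)) stop("unknown trait: ", trait)
  cv <- tt$meta$covariates[j]
  if (is.na(cv) || cv == "") character(0) else strsplit(cv, ";")[[1]]
}
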