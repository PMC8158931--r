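#' Paired abundance tables
#'
#' An `abundance_table` is a numeric samples x features matrix with unique
#' sample and feature identifiers, a record of which omic it holds
#' (`"microbiome"` or `"metabolome"`) and of the compositional transform
#' applied so far (`"raw"`, `"relative"` or `"clr"`). All package functions
#' that take paired data expect two aligned `abundance_table` objects.
#'
#' @param values numeric matrix, samples as rows, features as columns.
#'   Row and column names are used as sample / feature identifiers when
#'   `sample_ids` / `feature_ids` are not given.
#' @param omic `"microbiome"` or `"metabolome"`.
#' @param transform transform state of `values`.
#' @param sample_ids,feature_ids optional identifier vectors overriding the
#'   dimnames of `values`.
#'
#' @return an object of class `abundance_table`: the numeric matrix with
#'   identifiers as dimnames and attributes `omic` and `transform`.
#' @export
abundance_table <- function(values,
                            omic = c("microbiome", "metabolome"),
                            transform = c("raw", "relative", "clr"),
                            sample_ids = NULL, feature_ids = NULL) {
  omic <- match.arg(omic)
  transform <- match.arg(transform)
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("abundance values must be numeric")
  if (!is.null(sample_ids)) rownames(values) <- sample_ids
  if (!is.null(feature_ids)) colnames(values) <- feature_ids
  if (is.null(rownames(values)))
    rownames(values) <- paste0("S", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- paste0("F", seq_len(ncol(values)))
  if (anyDuplicated(rownames(values)))
    stop("duplicate sample identifiers")
  if (anyDuplicated(colnames(values)))
    stop("duplicate feature identifiers")
  if (any(is.na(values)))
    stop("abundance table contains missing values")
  if (transform != "clr" && any(values < 0))
    stop("raw/relative abundance values must be nonnegative")
  structure(values, omic = omic, transform = transform,
            class = c("abundance_table", "matrix", "array"))
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("abundance_table: %d samples x %d features (%s, %s)\n",
              nrow(x), ncol(x), attr(x, "omic"), attr(x, "transform")))
  n <- min(5L, nrow(x)); m <- min(5L, ncol(x))
  print(unclass(x)[seq_len(n), seq_len(m), drop = FALSE])
  if (nrow(x) > n || ncol(x) > m) cat("...\n")
  invisible(x)
}

sample_ids <- function(t) rownames(t)
feature_ids <- function(t) colnames(t)

# rebuild an abundance_table around a transformed value matrix
replace_values <- function(t, values, transform = attr(t, "transform")) {
  abundance_table(values, omic = attr(t, "omic"), transform = transform)
}

#' Read an abundance table from a delimited text file
#'
#' The first column must hold identifiers for the rows and the header line
#' identifiers for the columns; all remaining cells must be numeric.
#'
#' @param path path to a TSV/CSV file.
#' @param omic `"microbiome"` or `"metabolome"`.
#' @param orientation whether the file stores features as rows (common for
#'   taxon x sample tables) or samples as rows.
#' @param delimiter field separator, default tab.
#' @return an [abundance_table] with `transform = "raw"`, oriented
#'   samples x features regardless of the file's orientation.
#' @export
read_abundance <- function(path, omic = c("microbiome", "metabolome"),
                           orientation = c("features_as_rows",
                                           "samples_as_rows"),
                           delimiter = "\t") {
  omic <- match.arg(omic)
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = delimiter,
                          row.names = NULL, check.names = FALSE,
                          colClasses = "character", quote = "\"",
                          comment.char = "")
  ids <- df[[1]]
  if (anyDuplicated(ids)) stop("duplicate identifiers in first column of ", path)
  cells <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(cells), dim = dim(cells)))
  if (any(is.na(num))) {
    bad <- which(is.na(num), arr.ind = TRUE)[1, ]
    stop(sprintf(
      "non-numeric cell '%s' at row '%s', column '%s' in %s",
      cells[bad[1], bad[2]], ids[bad[1]], colnames(cells)[bad[2]], path))
  }
  rownames(num) <- ids
  colnames(num) <- colnames(cells)
  if (orientation == "features_as_rows") num <- t(num)
  abundance_table(num, omic = omic, transform = "raw")
}

#' Write an abundance table as TSV
#'
#' Samples as rows, header row of feature identifiers, first column of
#' sample identifiers (column name `sample_id`).
#'
#' @param t an [abundance_table].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_abundance <- function(t, path) {
  df <- data.frame(sample_id = rownames(t), unclass(t),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Restrict two paired tables to their shared samples
#'
#' @param a,b [abundance_table] objects sharing sample identifiers.
#' @return a list with elements `a` and `b`, both restricted to the
#'   intersection of sample identifiers in identical order.
#' @export
align_samples <- function(a, b) {
  common <- intersect(sample_ids(a), sample_ids(b))
  if (length(common) == 0L) stop("no shared samples between the two tables")
  list(a = replace_values(a, unclass(a)[common, , drop = FALSE]),
       b = replace_values(b, unclass(b)[common, , drop = FALSE]))
}

#' Remove low-prevalence features
#'
#' Drops every feature present (strictly nonzero) in fewer than
#' `min_fraction` of the samples; a feature present in exactly
#' `min_fraction` of samples is retained.
#'
#' @param t an [abundance_table] in raw or relative form.
#' @param min_fraction minimum fraction of samples a feature must be
#'   nonzero in; default 0.10.
#' @return the filtered [abundance_table], feature order preserved.
#' @export
prevalence_filter <- function(t, min_fraction = 0.10) {
  if (attr(t, "transform") == "clr")
    stop("prevalence filter applies to raw/relative values, not CLR")
  stopifnot(min_fraction >= 0, min_fraction <= 1)
  frac <- colMeans(unclass(t) != 0)
  keep <- frac >= min_fraction
  if (!any(keep)) stop("prevalence filter removed every feature")
  replace_values(t, unclass(t)[, keep, drop = FALSE])
}

#' Convert counts to relative abundance
#'
#' @param t an [abundance_table] of raw nonnegative values.
#' @return the table with each row divided by its sum
#'   (`transform = "relative"`).
#' @export
relative_abundance <- function(t) {
  if (attr(t, "transform") != "raw")
    stop("relative_abundance expects a raw table")
  v <- unclass(t)
  rs <- rowSums(v)
  if (any(rs == 0)) {
    stop("all-zero sample row(s): ",
         paste(rownames(v)[rs == 0], collapse = ", "))
  }
  replace_values(t, v / rs, transform = "relative")
}

#' Centered log-ratio transformation
#'
#' Adds a pseudocount to every entry of a sample's abundance vector and
#' maps entry i to `log(x_i / g(x))`. By default `g` is the sum of the
#' (pseudocounted) entries, making the transform a log-proportion; the
#' conventional geometric-mean denominator is available via
#' `denominator = "geometric_mean"`.
#'
#' @param t an [abundance_table] in raw or relative form, all values >= 0.
#' @param pseudocount value added to every entry before taking logs;
#'   default 1. Applied to the values on whatever scale the table holds.
#' @param denominator `"sum"` (default) or `"geometric_mean"`.
#' @return the transformed [abundance_table] (`transform = "clr"`); values
#'   may be negative.
#' @export
clr_transform <- function(t, pseudocount = 1,
                          denominator = c("sum", "geometric_mean")) {
  denominator <- match.arg(denominator)
  if (attr(t, "transform") == "clr") stop("table is already CLR-transformed")
  v <- unclass(t) + pseudocount
  if (any(v < 0)) stop("negative values after pseudocount")
  if (any(rowSums(v) == 0))
    stop("sample with zero total after pseudocount; increase pseudocount")
  if (denominator == "sum") {
    g <- rowSums(v)
  } else {
    if (any(v == 0))
      stop("geometric mean undefined with zero entries; use a pseudocount > 0")
    g <- exp(rowMeans(log(v)))
  }
  replace_values(t, log(v / g), transform = "clr")
}
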