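#' Construct an MvDataset
#'
#' @param values numeric matrix, samples in rows.
#' @param labels character class labels, one per row.
#' @param sampleIds optional sample identifiers; defaults to rownames or
#'   `"s1"`, `"s2"`, ...
#' @param variableNames optional variable names; defaults to colnames or
#'   `"v1"`, `"v2"`, ...
#' @return an [MvDataset-class].
#' @examples
#' d <- mvDataset(matrix(rnorm(12), 6, 2), rep(c("a", "b"), each = 3))
#' nSamples(d)
#' @export
mvDataset <- function(values, labels, sampleIds = NULL, variableNames = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(sampleIds))
    sampleIds <- if (!is.null(rownames(values))) rownames(values) else paste0("s", seq_len(nrow(values)))
  if (is.null(variableNames))
    variableNames <- if (!is.null(colnames(values))) colnames(values) else paste0("v", seq_len(ncol(values)))
  rownames(values) <- sampleIds
  colnames(values) <- variableNames
  new("MvDataset", values = values, sampleIds = as.character(sampleIds),
      variableNames = as.character(variableNames), labels = as.character(labels))
}

#' Read a delimited samples x variables table with a label column
#'
#' Expects a header row; the designated label column supplies class names and
#' is removed from the feature matrix. Feature column order is preserved.
#' Non-numeric feature cells, duplicate sample ids (when `idColumn` is given),
#' missing values and singleton classes are rejected with informative errors.
#'
#' @param path path to a CSV/TSV file (UTF-8).
#' @param labelColumn name of the class-label column in the header.
#' @param delimiter field delimiter, default ",".
#' @param idColumn optional name of a sample-id column; otherwise ids are
#'   `"s<row>"`.
#' @return an [MvDataset-class].
#' @export
readDataset <- function(path, labelColumn, delimiter = ",", idColumn = NULL) {
  if (!file.exists(path)) stopf("input file not found: %s", path)
  df <- utils::read.table(path, header = TRUE, sep = delimiter, quote = "\"",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "", fileEncoding = "UTF-8")
  if (!labelColumn %in% names(df))
    stopf("label column '%s' not found in header (columns: %s)",
          labelColumn, paste(names(df), collapse = ", "))
  labels <- as.character(df[[labelColumn]])
  sampleIds <- NULL
  if (!is.null(idColumn)) {
    if (!idColumn %in% names(df)) stopf("id column '%s' not found in header", idColumn)
    sampleIds <- as.character(df[[idColumn]])
    if (anyDuplicated(sampleIds))
      stopf("duplicate sample id: %s", sampleIds[duplicated(sampleIds)][1])
    df[[idColumn]] <- NULL
  }
  df[[labelColumn]] <- NULL
  for (j in seq_along(df)) {
    col <- df[[j]]
    if (!is.numeric(col)) {
      suppressWarnings(num <- as.numeric(col))
      bad <- which(is.na(num) & !is.na(col) & col != "NA")
      if (length(bad))
        stopf("non-numeric value '%s' in feature column '%s', data row %d",
              col[bad[1]], names(df)[j], bad[1])
      df[[j]] <- num
    }
  }
  values <- as.matrix(df)
  if (anyNA(values)) {
    idx <- which(is.na(values), arr.ind = TRUE)[1, ]
    stopf("missing value in feature column '%s', data row %d; impute upstream or drop the row",
          colnames(values)[idx[2]], idx[1])
  }
  mvDataset(values, labels, sampleIds = sampleIds, variableNames = colnames(values))
}

#' Write an MvDataset back to a delimited file
#'
#' Emits the same dialect [readDataset()] consumes: header row, label column
#' named `labelColumn`, remaining columns the features.
#' @param data an [MvDataset-class].
#' @param path output file path.
#' @param labelColumn name for the label column.
#' @param delimiter field delimiter.
#' @export
writeDataset <- function(data, path, labelColumn = "class", delimiter = ",") {
  df <- data.frame(data@labels, data@values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- labelColumn
  utils::write.table(df, path, sep = delimiter, row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @describeIn mvDataset number of samples
#' @param data an [MvDataset-class].
#' @export
nSamples <- function(data) nrow(data@values)

#' @describeIn mvDataset number of variables
#' @export
nVariables <- function(data) ncol(data@values)

#' @describeIn mvDataset the numeric matrix
#' @export
datasetValues <- function(data) data@values

#' @describeIn mvDataset class labels
#' @export
datasetLabels <- function(data) data@labels

#' @describeIn mvDataset sorted unique class names
#' @export
classNames <- function(data) sort(unique(data@labels))

#' Subset an MvDataset to the samples of the given classes
#' @param data an [MvDataset-class].
#' @param classes class names to keep.
#' @return an [MvDataset-class] with rows restricted to those classes.
#' @export
subsetClasses <- function(data, classes) {
  keep <- data@labels %in% classes
  if (!any(keep)) stopf("no samples in classes: %s", paste(classes, collapse = ", "))
  mvDataset(data@values[keep, , drop = FALSE], data@labels[keep],
            sampleIds = data@sampleIds[keep], variableNames = data@variableNames)
}

setMethod("show", "MvDataset", function(object) {
  tab <- table(object@labels)
  cat("MvDataset:", nrow(object@values), "samples x", ncol(object@values),
      "variables,", length(tab), "classes\n")
  cat("  classes:", paste0(names(tab), " (", as.integer(tab), ")", collapse = ", "), "\n")
})
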