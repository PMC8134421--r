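#' Construct a feature matrix container
#'
#' Holds a variant-by-feature annotation table together with per-column
#' specifications (kind, imputation default, exclusion status), a row id per
#' variant, and — after [impute_and_encode()] — the encoding dictionaries
#' that guarantee train and apply time use identical mappings.
#'
#' @param data data.frame of feature columns; numeric columns numeric,
#'   categorical/binary columns character; `NA` marks missing.
#' @param row_ids character vector of unique variant ids
#'   (`chr:pos:ref:alt`).
#' @param specs data.frame with at least `name` and `kind`
#'   (numeric/categorical/binary); optional `imputation_default`,
#'   `excluded`, `reason`.
#' @return object of class `feature_matrix`.
#' @export
feature_matrix <- function(data, row_ids, specs) {
  if (anyDuplicated(row_ids)) stop("duplicate row ids", call. = FALSE)
  if (nrow(data) != length(row_ids)) stop("row_ids do not align with data", call. = FALSE)
  if (!setequal(names(data), specs$name) || ncol(data) != nrow(specs)) {
    stop("every column must map to exactly one feature spec", call. = FALSE)
  }
  specs <- specs[match(names(data), specs$name), , drop = FALSE]
  if (is.null(specs$imputation_default)) specs$imputation_default <- NA_character_
  if (is.null(specs$excluded)) specs$excluded <- FALSE
  if (is.null(specs$reason)) specs$reason <- "none"
  rownames(specs) <- NULL
  structure(list(data = data, row_ids = as.character(row_ids), specs = specs,
                 encoders = NULL),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("feature matrix: %d variants x %d features (%s)\n",
              nrow(x$data), ncol(x$data),
              if (is.null(x$encoders)) "raw" else "imputed+encoded"))
  invisible(x)
}

#' @export
dim.feature_matrix <- function(x) dim(x$data)

#' @export
as.matrix.feature_matrix <- function(x, ...) {
  if (is.null(x$encoders)) {
    stop("call impute_and_encode() before extracting a numeric matrix", call. = FALSE)
  }
  m <- as.matrix(x$data)
  rownames(m) <- x$row_ids
  m
}

#' Canonical annotation feature names and exclusion lists
#'
#' `ase_feature_names()` returns the 109 candidate feature names used for
#' ASE prediction: the CADD v1.4 annotation columns plus the gene-level
#' `pLI_score` and the population allele frequency `gnomAD_AF`.
#' `ase_feature_exclusions()` returns the three curation lists (features
#' with no functional meaning, features with over 40% missing values, and
#' features correlated with ASE detectability) whose union of 39 names
#' leaves the 70 features used in model training.
#'
#' @return character vector of 109 names, or a named list of three
#'   character vectors.
#' @export
ase_feature_names <- function() {
  readLines(system.file("extdata", "features_109.txt", package = "asepred"))
}

#' @rdname ase_feature_names
#' @export
ase_feature_exclusions <- function() {
  jsonlite::read_json(system.file("extdata", "exclusions.json", package = "asepred"),
                      simplifyVector = TRUE)
}

# CADD-style columns that are not plain numbers
CATEGORICAL_FEATURES <- c("Ref", "Alt", "Type", "AnnoType", "Consequence",
                          "ConsDetail", "oAA", "nAA", "GeneID", "FeatureID",
                          "GeneName", "CCDS", "Intron", "Exon", "Domain",
                          "Dst2SplType", "SIFTcat", "PolyPhenCat", "Segway",
                          "motifEName", "Chrom")
BINARY_FEATURES <- c("motifEHIPos")

#' Default feature specifications for the canonical 109-column table
#'
#' @return data.frame usable as the `spec` argument of [load_annotations()].
#' @export
default_feature_specs <- function() {
  nm <- ase_feature_names()
  kind <- ifelse(nm %in% CATEGORICAL_FEATURES, "categorical",
                 ifelse(nm %in% BINARY_FEATURES, "binary", "numeric"))
  data.frame(name = nm, kind = kind, imputation_default = NA_character_,
             excluded = FALSE, reason = "none", stringsAsFactors = FALSE)
}

#' Load a CADD-style annotation table
#'
#' Reads a tab-separated per-variant annotation table, parses each column
#' according to its declared kind (unparseable cells become missing), and
#' constructs row ids. Ids come from a `locus_id` column if present,
#' otherwise from the `Chrom`/`Pos`/`Ref`/`Alt` columns as
#' `chr:pos:ref:alt` (1-based).
#'
#' @param path TSV file with a header row.
#' @param spec feature specification data.frame (default:
#'   [default_feature_specs()]). Columns present in the file but absent
#'   from the spec are an error.
#' @return a [feature_matrix()].
#' @export
load_annotations <- function(path, spec = default_feature_specs()) {
  raw <- utils::read.delim(path, stringsAsFactors = FALSE, colClasses = "character",
                           check.names = FALSE, na.strings = c("NA", ""))
  id_col <- NULL
  if ("locus_id" %in% names(raw)) {
    row_ids <- raw$locus_id
    raw$locus_id <- NULL
  } else if (all(c("Chrom", "Pos", "Ref", "Alt") %in% names(raw))) {
    row_ids <- paste(raw$Chrom, raw$Pos, raw$Ref, raw$Alt, sep = ":")
  } else {
    stop("cannot construct row ids: need a locus_id column or Chrom/Pos/Ref/Alt",
         call. = FALSE)
  }
  unknown <- setdiff(names(raw), spec$name)
  if (length(unknown)) {
    stop("columns absent from the feature spec: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(row_ids)) {
    stop("duplicate row ids: ", paste(unique(row_ids[duplicated(row_ids)]), collapse = ", "),
         call. = FALSE)
  }
  spec <- spec[spec$name %in% names(raw), , drop = FALSE]
  parsed <- raw
  for (j in seq_len(nrow(spec))) {
    nm <- spec$name[j]
    if (spec$kind[j] == "numeric") {
      parsed[[nm]] <- suppressWarnings(as.numeric(raw[[nm]]))
    }
  }
  feature_matrix(parsed, row_ids = row_ids, specs = spec)
}

#' Remove curated feature columns
#'
#' Drops the union of the supplied named exclusion lists from the matrix,
#' tagging each removed column's reason, and reports per-list counts. With
#' the canonical 109-column table and [ase_feature_exclusions()] this
#' retains the 70 model features.
#'
#' @param fm a [feature_matrix()].
#' @param exclusion_lists named list of character vectors of column names;
#'   a name not present in the matrix is an error.
#' @return the reduced `feature_matrix` (column order preserved).
#' @export
apply_exclusions <- function(fm, exclusion_lists = ase_feature_exclusions()) {
  stopifnot(inherits(fm, "feature_matrix"))
  all_nm <- unlist(exclusion_lists, use.names = FALSE)
  unknown <- setdiff(all_nm, fm$specs$name)
  if (length(unknown)) {
    stop("exclusion list names not in the matrix: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  for (reason in names(exclusion_lists)) {
    message(sprintf("excluding %d feature(s): %s",
                    length(exclusion_lists[[reason]]), reason))
  }
  keep <- setdiff(names(fm$data), all_nm)
  out <- feature_matrix(fm$data[, keep, drop = FALSE], fm$row_ids,
                        fm$specs[fm$specs$name %in% keep, , drop = FALSE])
  out
}

#' Impute missing values and encode non-numeric features
#'
#' Missing numeric entries are replaced by the column's configured default
#' (falling back to the column median computed on the observed values);
#' categorical and binary columns are mapped to integer codes via an
#' alphabetically ordered category dictionary, with missing entries imputed
#' by the configured default level (falling back to the most frequent
#' level). The dictionaries and imputation values are stored on the result
#' so a matrix encoded at apply time uses exactly the training mappings; a
#' category unseen at training time maps to a reserved unknown code (the
#' number of training levels) with a warning.
#'
#' @param fm a [feature_matrix()].
#' @param encoders encoders from a previously encoded (training) matrix, as
#'   found in `x$encoders`; `NULL` fits fresh encoders from `fm`.
#' @return a fully numeric `feature_matrix` (no missing values) with
#'   `$encoders` populated.
#' @export
impute_and_encode <- function(fm, encoders = NULL) {
  stopifnot(inherits(fm, "feature_matrix"))
  fit <- is.null(encoders)
  if (fit) encoders <- list(imputation = list(), categories = list())
  data <- fm$data
  for (j in seq_len(nrow(fm$specs))) {
    nm <- fm$specs$name[j]
    kind <- fm$specs$kind[j]
    x <- data[[nm]]
    if (kind == "numeric") {
      if (fit) {
        dflt <- suppressWarnings(as.numeric(fm$specs$imputation_default[j]))
        if (is.na(dflt)) dflt <- stats::median(x, na.rm = TRUE)
        if (is.na(dflt)) dflt <- 0
        encoders$imputation[[nm]] <- dflt
      }
      x[is.na(x)] <- encoders$imputation[[nm]]
      data[[nm]] <- x
    } else {
      x <- as.character(x)
      if (fit) {
        lev <- sort(unique(x[!is.na(x)]))
        dflt <- fm$specs$imputation_default[j]
        if (is.na(dflt) || !dflt %in% lev) {
          tab <- sort(table(x), decreasing = TRUE)
          dflt <- if (length(tab)) names(tab)[1] else lev[1]
        }
        encoders$categories[[nm]] <- lev
        encoders$imputation[[nm]] <- dflt
      }
      lev <- encoders$categories[[nm]]
      x[is.na(x)] <- encoders$imputation[[nm]]
      code <- match(x, lev) - 1L
      if (anyNA(code)) {
        warning(sprintf("column %s: %d value(s) unseen at training time mapped to the unknown code",
                        nm, sum(is.na(code))))
        code[is.na(code)] <- length(lev)
      }
      data[[nm]] <- as.numeric(code)
    }
  }
  out <- feature_matrix(data, fm$row_ids, fm$specs)
  out$encoders <- encoders
  out
}

#' Write / read an encoded feature matrix with its sidecar metadata
#'
#' `write_feature_matrix` writes `<prefix>.tsv` (row ids plus numeric
#' values) and `<prefix>.json` (column specs, encoding dictionaries,
#' imputation defaults); `read_feature_matrix` restores the object exactly.
#'
#' @param fm an encoded [feature_matrix()].
#' @param prefix output path prefix.
#' @name feature_matrix_io
#' @export
write_feature_matrix <- function(fm, prefix) {
  if (is.null(fm$encoders)) stop("matrix must be encoded before writing", call. = FALSE)
  tab <- cbind(data.frame(locus_id = fm$row_ids, stringsAsFactors = FALSE), fm$data)
  utils::write.table(tab, paste0(prefix, ".tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(list(specs = fm$specs, encoders = fm$encoders),
                       paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' @rdname feature_matrix_io
#' @export
read_feature_matrix <- function(prefix) {
  tab <- utils::read.delim(paste0(prefix, ".tsv"), stringsAsFactors = FALSE,
                           check.names = FALSE)
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  row_ids <- tab$locus_id
  tab$locus_id <- NULL
  specs <- as.data.frame(meta$specs, stringsAsFactors = FALSE)
  fm <- feature_matrix(tab, row_ids, specs)
  enc <- meta$encoders
  enc$imputation <- as.list(enc$imputation)
  enc$categories <- lapply(enc$categories, as.character)
  fm$encoders <- enc
  fm
}
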