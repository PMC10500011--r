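#' Construct an omic data layer
#'
#' An `omic_matrix` holds one molecular layer as a features-by-samples numeric
#' matrix together with a layer label and a flag saying whether values are
#' already on log scale. Units are log2 abundance for expression layers and
#' beta values in \[0, 1\] for methylation.
#'
#' @param values Numeric matrix, features in rows, samples in columns.
#' @param layer_name Layer label, e.g. `"mrna"`, `"protein"`, `"methylation"`.
#' @param feature_ids,sample_ids Optional identifier vectors; default to the
#'   dimnames of `values`. Must be unique and free of surrounding whitespace
#'   (trimmed on construction).
#' @param is_log Logical; `TRUE` when `values` are already log-transformed.
#' @return An object of class `omic_matrix`.
#' @examples
#' m <- omic_matrix(matrix(rnorm(6), 3, 2,
#'                         dimnames = list(paste0("g", 1:3), c("s1", "s2"))),
#'                  layer_name = "mrna")
#' dim(m$values)
#' @export
omic_matrix <- function(values, layer_name, feature_ids = rownames(values),
                        sample_ids = colnames(values), is_log = TRUE) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(feature_ids) || is.null(sample_ids))
    stop("feature_ids and sample_ids are required (or set dimnames on 'values')")
  feature_ids <- trimws(as.character(feature_ids))
  sample_ids <- trimws(as.character(sample_ids))
  if (nrow(values) != length(feature_ids) || ncol(values) != length(sample_ids))
    stop("matrix dimensions do not match the id vectors")
  dup <- feature_ids[duplicated(feature_ids)]
  if (length(dup)) stop("duplicate feature_ids: ", paste(unique(dup), collapse = ", "))
  dup <- sample_ids[duplicated(sample_ids)]
  if (length(dup)) stop("duplicate sample_ids: ", paste(unique(dup), collapse = ", "))
  dimnames(values) <- list(feature_ids, sample_ids)
  if (identical(layer_name, "methylation")) {
    v <- values[is.finite(values)]
    if (length(v) && (min(v) < 0 || max(v) > 1))
      stop("methylation beta values must lie in [0, 1]")
  }
  structure(list(layer_name = as.character(layer_name)[1],
                 feature_ids = feature_ids, sample_ids = sample_ids,
                 values = values, is_log = isTRUE(is_log)),
            class = "omic_matrix")
}

#' @export
print.omic_matrix <- function(x, ...) {
  cat(sprintf("omic_matrix layer '%s': %d features x %d samples (%s scale)\n",
              x$layer_name, length(x$feature_ids), length(x$sample_ids),
              if (x$is_log) "log" else "linear"))
  n_na <- sum(is.na(x$values))
  if (n_na) cat(sprintf("  %d missing values\n", n_na))
  invisible(x)
}

#' @export
dim.omic_matrix <- function(x) dim(x$values)

#' Read an omic layer from a tab-separated file
#'
#' Expects tab-separated text with feature ids in the first column and a
#' header row of sample ids. Missing cells (empty or `NA`) are kept as `NA`,
#' never coerced to zero.
#'
#' @param path File path.
#' @param layer_name Layer label for the resulting object.
#' @param is_log Whether stored values are on log scale.
#' @param transpose If `TRUE` the file is samples-in-rows and is transposed
#'   on load.
#' @return An [omic_matrix()].
#' @export
read_omic_matrix <- function(path, layer_name, is_log = TRUE, transpose = FALSE) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          colClasses = "character", na.strings = c("NA", ""))
  if (ncol(df) < 2) stop("matrix file needs an id column plus >= 1 data column")
  ids <- trimws(df[[1]])
  vals <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals)))
  bad <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("non-numeric cell at row %d ('%s'), column %d ('%s')",
                 bad[1, 1], ids[bad[1, 1]], bad[1, 2], colnames(vals)[bad[1, 2]]))
  if (transpose) {
    omic_matrix(t(num), layer_name, feature_ids = colnames(vals),
                sample_ids = ids, is_log = is_log)
  } else {
    omic_matrix(num, layer_name, feature_ids = ids,
                sample_ids = colnames(vals), is_log = is_log)
  }
}

#' Write an omic layer as tab-separated text
#'
#' Emits UTF-8, tab-delimited, `.` decimal, full double precision so that a
#' read/write round trip preserves values to well below 1e-9.
#'
#' @param x An [omic_matrix()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_omic_matrix <- function(x, path) {
  stopifnot(inherits(x, "omic_matrix"))
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(c("feature_id", x$sample_ids), collapse = "\t"), con)
  body <- apply(x$values, 1, function(r)
    paste(ifelse(is.na(r), "NA", sprintf("%.17g", r)), collapse = "\t"))
  writeLines(paste(x$feature_ids, body, sep = "\t"), con)
  invisible(path)
}

#' Read a gene-set collection in GMT format
#'
#' One set per line: name, description, then member ids, tab-separated
#' (Broad dialect). Duplicate members within a set are dropped with a warning.
#'
#' @param path File path.
#' @return A `gene_set_collection`: list with `sets` (named list of character
#'   vectors) and `descriptions`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  sets <- list(); desc <- character()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop(sprintf("GMT line %d has %d field(s); need name, description, >= 1 member",
                   i, length(f)))
    members <- f[-(1:2)]
    members <- members[nzchar(members)]
    if (anyDuplicated(members)) {
      warning(sprintf("set '%s': duplicate members removed", f[1]))
      members <- unique(members)
    }
    if (!length(members)) stop(sprintf("GMT line %d: set '%s' has no members", i, f[1]))
    if (f[1] %in% names(sets)) stop("duplicate set name: ", f[1])
    sets[[f[1]]] <- members
    desc[f[1]] <- f[2]
  }
  structure(list(sets = sets, descriptions = desc), class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection: %d sets (sizes %s)\n", length(x$sets),
              if (length(x$sets)) paste(range(lengths(x$sets)), collapse = "-") else "-"))
  invisible(x)
}

#' Write a gene-set collection in GMT format
#' @param x A `gene_set_collection`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(x, path) {
  stopifnot(inherits(x, "gene_set_collection"))
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (nm in names(x$sets)) {
    d <- x$descriptions[nm]
    if (is.na(d)) d <- nm
    writeLines(paste(c(nm, d, x$sets[[nm]]), collapse = "\t"), con)
  }
  invisible(path)
}

.clinical_required <- c("sample_id", "age", "sex", "location", "braf_status",
                        "pfs_time", "pfs_event")

#' Construct / validate a clinical annotation table
#'
#' @param df A data.frame with columns `sample_id`, `age` (years), `sex`,
#'   `location`, `braf_status`, `pfs_time` (months), `pfs_event` (0/1) and
#'   optionally `group`; extra columns are preserved. Category columns are
#'   normalized to lower case.
#' @return A `clinical_table` (data.frame subclass).
#' @export
clinical_table <- function(df) {
  miss <- setdiff(.clinical_required, names(df))
  if (length(miss)) stop("missing required column(s): ", paste(miss, collapse = ", "))
  df$sample_id <- trimws(as.character(df$sample_id))
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id: ", df$sample_id[duplicated(df$sample_id)][1])
  for (col in c("sex", "location", "braf_status"))
    df[[col]] <- tolower(trimws(as.character(df[[col]])))
  if ("group" %in% names(df)) df$group <- tolower(trimws(as.character(df$group)))
  df$age <- as.numeric(df$age)
  df$pfs_time <- as.numeric(df$pfs_time)
  df$pfs_event <- as.numeric(df$pfs_event)
  if (any(!is.na(df$pfs_time) & df$pfs_time < 0)) stop("negative pfs_time")
  if (!all(stats::na.omit(df$pfs_event) %in% c(0, 1)))
    stop("pfs_event must be 0 or 1")
  class(df) <- c("clinical_table", "data.frame")
  df
}

#' Read a clinical annotation table
#'
#' Tab-separated with a header; see [clinical_table()] for required columns.
#'
#' @param path File path.
#' @return A `clinical_table`.
#' @export
read_clinical_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          na.strings = c("NA", ""), stringsAsFactors = FALSE)
  clinical_table(df)
}

#' Write a clinical annotation table
#' @param x A `clinical_table`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_clinical_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Construct a cell-type signature matrix
#'
#' @param profiles Non-negative numeric matrix, marker features in rows, cell
#'   types in columns (linear abundance scale).
#' @return A `signature_matrix`.
#' @export
signature_matrix <- function(profiles) {
  profiles <- as.matrix(profiles)
  if (is.null(rownames(profiles)) || is.null(colnames(profiles)))
    stop("profiles need feature row names and cell-type column names")
  if (any(profiles < 0)) stop("signature profiles must be non-negative")
  if (any(colSums(profiles) == 0)) stop("all-zero cell-type column")
  structure(list(cell_types = colnames(profiles),
                 feature_ids = rownames(profiles),
                 profiles = profiles),
            class = "signature_matrix")
}

#' Read a cell-type signature matrix (tab-separated, features x cell types)
#' @param path File path.
#' @return A [signature_matrix()].
#' @export
read_signature_matrix <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          row.names = 1)
  signature_matrix(as.matrix(df))
}

#' Write a cell-type signature matrix
#' @param x A [signature_matrix()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_signature_matrix <- function(x, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(c("feature_id", x$cell_types), collapse = "\t"), con)
  body <- apply(x$profiles, 1, function(r) paste(sprintf("%.17g", r), collapse = "\t"))
  writeLines(paste(x$feature_ids, body, sep = "\t"), con)
  invisible(path)
}

#' Restrict layers and clinical data to their common samples
#'
#' Intersects the sample ids of all supplied layers (and the clinical table,
#' when given) and returns every object restricted to that intersection in
#' one shared sample order (order of appearance in the first layer).
#'
#' @param matrices List of [omic_matrix()] objects.
#' @param clinical Optional `clinical_table`.
#' @return List with `matrices` (same names as input) and `clinical` (or
#'   `NULL`); all with identical sample order.
#' @export
align_cohort <- function(matrices, clinical = NULL) {
  if (!length(matrices)) stop("need at least one omic_matrix")
  stopifnot(all(vapply(matrices, inherits, logical(1), "omic_matrix")))
  common <- Reduce(intersect, lapply(matrices, `[[`, "sample_ids"))
  if (!is.null(clinical)) common <- intersect(common, clinical$sample_id)
  if (!length(common)) stop("no samples shared across the supplied objects")
  # shared order: order of appearance in the first layer
  common <- matrices[[1]]$sample_ids[matrices[[1]]$sample_ids %in% common]
  message(sprintf("align_cohort: %d shared sample(s)", length(common)))
  out <- lapply(matrices, function(m)
    omic_matrix(m$values[, common, drop = FALSE], m$layer_name, is_log = m$is_log))
  cl <- NULL
  if (!is.null(clinical)) {
    cl <- clinical[match(common, clinical$sample_id), , drop = FALSE]
    rownames(cl) <- NULL
    class(cl) <- c("clinical_table", "data.frame")
  }
  list(matrices = out, clinical = cl)
}
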