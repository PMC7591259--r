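# Readers and writers for the pipeline's tabular artifacts. All tables are
# tab-separated UTF-8 with '#' comment lines ignored; readers validate and
# reject malformed values rather than coercing them.

read_tsv_checked <- function(path) {
  if (!file.exists(path)) stop_format("file not found: ", path)
  utils::read.delim(path, comment.char = "#", check.names = FALSE,
                    stringsAsFactors = FALSE)
}

#' Read a library annotation table
#'
#' Expects columns `sgrna_id`, `gene`, `chromosome`, `position` (1-based).
#' Gene symbols are uppercased and whitespace-stripped; each sgRNA must map
#' to exactly one gene and positions must be >= 1.
#'
#' @param path Path to a TSV file.
#' @return A validated annotation `data.frame`.
#' @export
read_library_annotation <- function(path) {
  df <- read_tsv_checked(path)
  need <- c("sgrna_id", "gene", "chromosome", "position")
  if (!all(need %in% names(df)))
    stop_format("annotation must have columns: ", paste(need, collapse = ", "))
  df <- df[need]
  if (anyDuplicated(df$sgrna_id))
    stop_format("duplicate sgrna_id in annotation: ",
                df$sgrna_id[duplicated(df$sgrna_id)][1])
  df$gene <- clean_symbols(df$gene)
  if (!is.numeric(df$position) || any(df$position < 1) ||
      any(df$position != round(df$position)))
    stop_format("positions must be integers >= 1")
  df$position <- as.integer(df$position)
  df
}

#' Construct a validated sgRNA count table
#'
#' The canonical container for screen counts: an integer matrix
#' (sgRNA x sample) plus a sample sheet assigning each column a role
#' (`plasmid` or `endpoint`), a cell-line label, a replicate index and a
#' batch label. Exactly one plasmid column is required.
#'
#' @param counts Non-negative integer matrix with sgRNA row names.
#' @param samples `data.frame` with columns `sample_id`, `role`,
#'   `cell_line`, `replicate`, and optionally `batch`.
#' @return A list of class `count_table` with elements `counts` and
#'   `samples`.
#' @export
count_table <- function(counts, samples) {
  if (is.null(rownames(counts))) stop_format("counts must have sgRNA row names")
  if (is.null(colnames(counts))) colnames(counts) <- samples$sample_id
  if (!identical(colnames(counts), as.character(samples$sample_id)))
    stop_format("column names of counts must match samples$sample_id")
  if (!all(samples$role %in% c("plasmid", "endpoint")))
    stop_format("sample roles must be 'plasmid' or 'endpoint'")
  if (sum(samples$role == "plasmid") != 1L)
    stop_format("exactly one plasmid column is required")
  if (any(counts < 0) || any(is.na(counts)))
    stop_format("counts must be non-negative and complete")
  if (is.null(samples$batch)) samples$batch <- "batch1"
  structure(list(counts = counts, samples = samples), class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("count_table: %d sgRNAs x %d samples (%d cell lines)\n",
              nrow(x$counts), ncol(x$counts),
              length(unique(stats::na.omit(x$samples$cell_line)))))
  invisible(x)
}

plasmid_column <- function(ct) ct$samples$sample_id[ct$samples$role == "plasmid"]

#' Read an sgRNA count table
#'
#' Reads a TSV whose first column is `sgrna_id` and remaining columns are
#' samples. Values must be non-negative integers; sgRNAs absent from the
#' annotation are excluded with a message. Sample roles are taken from
#' `samples` if given, otherwise a column named `plasmid` is the plasmid
#' and other columns are parsed as `<cellline>_R<replicate>`.
#'
#' @param path TSV path.
#' @param annotation A library annotation `data.frame`
#'   (see [read_library_annotation()]).
#' @param samples Optional sample sheet (see [count_table()]).
#' @return A [count_table()].
#' @export
read_counts <- function(path, annotation, samples = NULL) {
  df <- read_tsv_checked(path)
  if (names(df)[1] != "sgrna_id") stop_format("first column must be sgrna_id")
  ids <- as.character(df$sgrna_id)
  if (anyDuplicated(ids))
    stop_format("duplicate sgrna_id: ", ids[duplicated(ids)][1])
  mat <- as.matrix(df[-1])
  for (j in seq_len(ncol(mat))) {
    col <- mat[, j]
    bad <- which(is.na(col) | col < 0 | col != round(col))
    if (length(bad))
      stop_format("invalid count at row '", ids[bad[1]], "', column '",
                  colnames(mat)[j], "': must be a non-negative integer")
  }
  storage.mode(mat) <- "integer"
  rownames(mat) <- ids
  unknown <- setdiff(ids, annotation$sgrna_id)
  if (length(unknown)) {
    message(length(unknown), " sgRNAs absent from annotation were excluded")
    mat <- mat[setdiff(ids, unknown), , drop = FALSE]
  }
  if (is.null(samples)) {
    nm <- colnames(mat)
    role <- ifelse(nm == "plasmid", "plasmid", "endpoint")
    cl  <- ifelse(role == "plasmid", NA, sub("_R[0-9]+$", "", nm))
    rep <- ifelse(role == "plasmid", NA,
                  suppressWarnings(as.integer(sub("^.*_R", "", nm))))
    samples <- data.frame(sample_id = nm, role = role, cell_line = cl,
                          replicate = rep, batch = "batch1",
                          stringsAsFactors = FALSE)
  }
  count_table(mat, samples)
}

#' Read a gene-level expression matrix
#'
#' First column is the gene symbol, remaining columns are samples. Symbols
#' are uppercased; duplicate symbols are collapsed by mean. Values must be
#' non-negative.
#'
#' @param path TSV path.
#' @return Numeric matrix (genes x samples).
#' @export
read_expression <- function(path) {
  df <- read_tsv_checked(path)
  genes <- clean_symbols(df[[1]])
  mat <- as.matrix(df[-1])
  if (!is.numeric(mat) || any(is.na(mat)))
    stop_format("expression values must be numeric and complete")
  if (any(mat < 0)) stop_format("expression values must be non-negative")
  if (anyDuplicated(genes)) {
    message("collapsing ", sum(duplicated(genes)),
            " duplicate gene symbols by mean")
    mat <- rowsum(mat, genes) / as.vector(table(genes)[sort(unique(genes))])
  } else {
    rownames(mat) <- genes
  }
  mat
}

#' Read a GMT gene-set file
#'
#' Standard GMT dialect: one set per line, fields `name`, `description`,
#' then gene symbols, tab-separated. Genes are uppercased; duplicates
#' within a line are removed with a message.
#'
#' @param path GMT path.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop_format("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  out <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3)
      stop_format("GMT line ", i, " has fewer than 3 fields")
    genes <- clean_symbols(fields[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (!length(genes)) stop_format("GMT line ", i, " has an empty gene list")
    if (anyDuplicated(genes)) {
      message("GMT set '", fields[1], "': removed ",
              sum(duplicated(genes)), " duplicate genes")
      genes <- unique(genes)
    }
    out[[fields[1]]] <- genes
  }
  out
}

#' Read a plain gene list (one symbol per line)
#'
#' @param path Text file path; '#' comment lines are ignored.
#' @return Character vector of uppercased symbols.
#' @export
read_gene_list <- function(path) {
  if (!file.exists(path)) stop_format("file not found: ", path)
  x <- readLines(path, warn = FALSE)
  x <- trimws(x[!grepl("^\\s*#", x)])
  x <- clean_symbols(x[nzchar(x)])
  if (!length(x)) stop_format("gene list is empty: ", path)
  unique(x)
}

mutation_vocabulary <- c("wild-type", "driver_mutant", "amplified", "none-assessed")

#' Read a sample-by-gene mutation/CNA status table
#'
#' First column is the sample/cell-line id; remaining columns are genes with
#' values from the closed vocabulary `wild-type`, `driver_mutant`,
#' `amplified`, `none-assessed`.
#'
#' @param path TSV path.
#' @return Character matrix (samples x genes).
#' @export
read_mutation_table <- function(path) {
  df <- read_tsv_checked(path)
  ids <- as.character(df[[1]])
  mat <- as.matrix(df[-1])
  bad <- setdiff(unique(as.vector(mat)), mutation_vocabulary)
  if (length(bad))
    stop_format("mutation status outside vocabulary: ",
                paste(bad, collapse = ", "))
  rownames(mat) <- ids
  colnames(mat) <- clean_symbols(colnames(mat))
  mat
}

#' Read a tractability bucket table (gene -> bucket 1..10)
#'
#' @param path TSV path with columns `gene`, `bucket`.
#' @return `data.frame` with `gene` and integer `bucket`.
#' @export
read_tractability <- function(path) {
  df <- read_tsv_checked(path)
  if (!all(c("gene", "bucket") %in% names(df)))
    stop_format("tractability table needs columns gene, bucket")
  df$gene <- clean_symbols(df$gene)
  if (any(!df$bucket %in% 1:10))
    stop_format("tractability buckets must be in 1..10")
  df$bucket <- as.integer(df$bucket)
  df[c("gene", "bucket")]
}

#' Write a result object to disk
#'
#' Matrices (score matrices, Z matrices) and data frames (depletion results,
#' signature scores) are written as TSV; lists are written as JSON. Written
#' tables round-trip through [read_results()] losslessly up to numeric
#' print precision.
#'
#' @param obj Matrix, data.frame or list.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results <- function(obj, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  if (is.matrix(obj)) {
    df <- data.frame(id = rownames(obj),
                     format(as.data.frame(obj), digits = 17, trim = TRUE,
                            scientific = FALSE),
                     check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else if (is.data.frame(obj)) {
    utils::write.table(obj, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else if (is.list(obj)) {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    stop_format("unsupported result type: ", class(obj)[1])
  }
  invisible(path)
}

#' Read a result written by [write_results()]
#'
#' @param path TSV path written with `write_results()` for a matrix.
#' @param matrix If `TRUE`, return a numeric matrix keyed by the first
#'   column; otherwise the raw `data.frame`.
#' @return Matrix or `data.frame`.
#' @export
read_results <- function(path, matrix = TRUE) {
  df <- read_tsv_checked(path)
  if (!matrix) return(df)
  m <- as.matrix(df[-1])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1]])
  m
}
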