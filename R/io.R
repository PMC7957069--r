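# Tabular readers/writers. All tables are TSV with a header row; floats are
# serialized at 10 significant digits so that write -> read round-trips are
# stable and diffable.

#' Construct and validate an expression matrix
#'
#' An expression matrix is a plain numeric matrix with unique gene ids as row
#' names and unique sample ids as column names, carrying a `scale_tag`
#' attribute (`"linear"` for non-negative normalized abundance such as
#' TPM/FPKM, `"log2p1"` for `log2(x + 1)`-transformed values).
#'
#' @param values Numeric matrix, genes in rows, samples in columns.
#' @param scale_tag `"linear"` (default) or `"log2p1"`.
#' @return The validated matrix with the `scale_tag` attribute set.
#' @export
expression_matrix <- function(values, scale_tag = c("linear", "log2p1")) {
  scale_tag <- match.arg(scale_tag)
  if (!is.matrix(values) || !is.numeric(values))
    stop_typed("tme_parse_error", "expression values must be a numeric matrix")
  gid <- rownames(values); sid <- colnames(values)
  if (is.null(gid) || is.null(sid))
    stop_typed("tme_parse_error", "expression matrix needs gene and sample ids")
  if (anyDuplicated(gid))
    stop_typed("tme_parse_error", "duplicate gene ids: %s",
               paste(unique(gid[duplicated(gid)]), collapse = ", "))
  if (anyDuplicated(sid))
    stop_typed("tme_parse_error", "duplicate sample ids: %s",
               paste(unique(sid[duplicated(sid)]), collapse = ", "))
  if (any(!is.finite(values)))
    stop_typed("tme_parse_error", "expression contains non-finite values")
  if (scale_tag == "linear" && any(values < 0))
    stop_typed("tme_parse_error",
               "negative values are not allowed on the linear scale")
  attr(values, "scale_tag") <- scale_tag
  values
}

expr_scale <- function(x) attr(x, "scale_tag") %||% "linear"

# log2(x + 1) view of an expression matrix (identity if already transformed)
as_log2p1 <- function(x) {
  if (expr_scale(x) == "log2p1") return(x)
  out <- log2(x + 1)
  attr(out, "scale_tag") <- "log2p1"
  out
}

#' Read an expression matrix from TSV/CSV
#'
#' @param path File path; tab- or comma-separated with a header row. The
#'   first column holds ids.
#' @param orientation `"genes_rows"` (canonical; default) or `"samples_rows"`,
#'   in which case the table is transposed on read.
#' @param scale_tag Scale of the stored values; see [expression_matrix()].
#' @return An expression matrix (genes x samples).
#' @export
read_expression <- function(path, orientation = c("genes_rows", "samples_rows"),
                            scale_tag = c("linear", "log2p1")) {
  orientation <- match.arg(orientation)
  df <- read_table_checked(path)
  ids <- as.character(df[[1L]])
  num <- df[, -1L, drop = FALSE]
  bad <- !vapply(num, is.numeric, logical(1))
  if (any(bad))
    stop_typed("tme_parse_error", "non-numeric column(s) in %s: %s", path,
               paste(names(num)[bad], collapse = ", "))
  m <- as.matrix(num)
  storage.mode(m) <- "double"
  rownames(m) <- ids
  if (orientation == "samples_rows") m <- t(m)
  expression_matrix(m, scale_tag = match.arg(scale_tag))
}

#' Write an expression matrix to TSV
#' @param x Expression matrix.
#' @param path Output path.
#' @param id_col Name of the id column (default `"gene_id"`).
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path, id_col = "gene_id") {
  write_tsv(data.frame(setNames(list(rownames(x)), id_col),
                       signif(x, 10L), check.names = FALSE), path)
}

#' Read a clinical table
#'
#' Required columns: `sample_id`, `os_time` (days, non-negative), `os_event`
#' (0/1). Optional: `stage` (I--IV), `msi_status` (MSI-H / MSI-L / MSS),
#' `response_score` (lower = better predicted immunotherapy response),
#' `responder` (0/1).
#'
#' @param path TSV path.
#' @return A validated `data.frame`.
#' @export
read_clinical <- function(path) {
  validate_clinical(read_table_checked(path))
}

#' Validate a clinical table
#' @param df A data.frame with at least sample_id, os_time, os_event.
#' @return The validated data.frame (stage/msi normalized to character).
#' @export
validate_clinical <- function(df) {
  need <- c("sample_id", "os_time", "os_event")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_typed("tme_parse_error", "clinical table missing column(s): %s",
               paste(miss, collapse = ", "))
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id))
    stop_typed("tme_parse_error", "duplicate sample ids in clinical table")
  if (any(!is.finite(df$os_time)) || any(df$os_time < 0))
    stop_typed("tme_parse_error", "os_time must be finite and >= 0")
  if (!is_binary01(df$os_event))
    stop_typed("tme_parse_error", "os_event must be 0/1")
  if ("stage" %in% names(df)) {
    df$stage <- as.character(df$stage)
    ok <- is.na(df$stage) | df$stage %in% c("I", "II", "III", "IV")
    if (!all(ok)) stop_typed("tme_parse_error", "stage must be I/II/III/IV")
  }
  if ("msi_status" %in% names(df)) {
    df$msi_status <- as.character(df$msi_status)
    ok <- is.na(df$msi_status) | df$msi_status %in% c("MSI-H", "MSI-L", "MSS")
    if (!all(ok))
      stop_typed("tme_parse_error", "msi_status must be MSI-H/MSI-L/MSS")
  }
  if ("responder" %in% names(df) &&
      !all(is.na(df$responder) | df$responder %in% c(0, 1)))
    stop_typed("tme_parse_error", "responder must be 0/1")
  df
}

#' Read a somatic mutation table (MAF subset)
#'
#' Requires the five standard MAF columns (matched case-insensitively):
#' `Tumor_Sample_Barcode`, `Hugo_Symbol`, `Variant_Classification`,
#' `t_alt_count`, `t_depth`. Rows with `t_depth == 0` are dropped with a
#' warning naming the count; the returned table gains a `vaf` column
#' (`t_alt_count / t_depth`). MAF genomic coordinates (1-based convention)
#' are never interpreted and may be absent.
#'
#' @param path TSV path (a `#`-prefixed version header line is tolerated).
#' @return A `data.frame` with canonical column names plus `vaf`.
#' @export
read_maf <- function(path) {
  df <- read_table_checked(path, comment.char = "#")
  validate_maf(df)
}

#' Validate a MAF-like data.frame
#' @param df Data frame with the five required MAF columns (any case).
#' @return Canonicalized data.frame with a `vaf` column.
#' @export
validate_maf <- function(df) {
  need <- c("Tumor_Sample_Barcode", "Hugo_Symbol", "Variant_Classification",
            "t_alt_count", "t_depth")
  idx <- match(tolower(need), tolower(names(df)))
  if (anyNA(idx))
    stop_typed("tme_parse_error", "MAF missing required column(s): %s",
               paste(need[is.na(idx)], collapse = ", "))
  out <- df[, idx, drop = FALSE]
  names(out) <- need
  out$Tumor_Sample_Barcode <- as.character(out$Tumor_Sample_Barcode)
  out$Hugo_Symbol <- as.character(out$Hugo_Symbol)
  out$Variant_Classification <- as.character(out$Variant_Classification)
  if (any(out$t_alt_count < 0) || any(out$t_alt_count > out$t_depth))
    stop_typed("tme_parse_error", "need 0 <= t_alt_count <= t_depth")
  zero <- out$t_depth == 0
  if (any(zero)) {
    warn_typed("tme_dropped_rows_warning",
               "dropped %d MAF row(s) with t_depth = 0", sum(zero))
    out <- out[!zero, , drop = FALSE]
  }
  out$vaf <- out$t_alt_count / out$t_depth
  rownames(out) <- NULL
  out
}

#' Read a cell-fraction matrix (samples x cell types)
#' @param path TSV path; first column sample ids.
#' @return Numeric matrix with samples in rows.
#' @export
read_fractions <- function(path) {
  df <- read_table_checked(path)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- as.character(df[[1L]])
  validate_fractions(m)
}

validate_fractions <- function(m, tol = 1e-6) {
  if (any(m < -tol))
    stop_typed("tme_parse_error", "negative cell fractions")
  if (any(abs(rowSums(m) - 1) > tol))
    stop_typed("tme_parse_error", "fraction rows must sum to 1")
  m
}

#' Write a samples-x-cell-types fraction matrix to TSV
#' @param m Fraction matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fractions <- function(m, path) {
  write_tsv(data.frame(sample_id = rownames(m), signif(m, 10L),
                       check.names = FALSE), path)
}

#' Write any data.frame as TSV (floats at 10 significant digits)
#' @param df Data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path) {
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(x) signif(x, 10L))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_table_checked <- function(path, comment.char = "") {
  if (!file.exists(path))
    stop_typed("tme_parse_error", "file not found: %s", path)
  head_lines <- readLines(path, n = 50L)
  if (nzchar(comment.char))
    head_lines <- head_lines[!startsWith(head_lines, comment.char)]
  if (!length(head_lines))
    stop_typed("tme_parse_error", "%s: no non-comment lines", path)
  sep <- if (grepl("\t", head_lines[1L])) "\t" else ","
  df <- read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE, comment.char = comment.char)
  if (ncol(df) < 2L)
    stop_typed("tme_parse_error", "%s: expected a header row and >= 2 columns",
               path)
  df
}
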