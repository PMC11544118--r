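#' Construct an expression matrix with sample and gene annotations
#'
#' The container used throughout the pipeline: a genes x samples numeric
#' matrix plus a gene-class annotation (lncRNA / miRNA / mRNA), a per-sample
#' condition label (tumor / normal), the value scale (`counts` or
#' `log2cpm`), and an optional pairing label for matched designs.
#'
#' @param values numeric matrix, genes in rows, samples in columns; both
#'   dimnames required and unique.
#' @param condition character vector of `"tumor"`/`"normal"`, one per
#'   sample.
#' @param gene_class optional character vector per gene; inferred from the
#'   identifier prefix via [infer_gene_class()] when omitted.
#' @param scale `"counts"` (non-negative) or `"log2cpm"`.
#' @param pair_id optional per-sample pairing label for matched
#'   tumor/adjacent designs.
#' @return object of class `expr_matrix`.
#' @export
expr_matrix <- function(values, condition, gene_class = NULL,
                        scale = c("counts", "log2cpm"), pair_id = NULL) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values)) {
    stopf("expr_matrix: values must be a numeric matrix")
  }
  gid <- rownames(values); sid <- colnames(values)
  if (is.null(gid) || is.null(sid)) {
    stopf("expr_matrix: values needs row and column names")
  }
  if (anyDuplicated(gid)) {
    stopf("expr_matrix: duplicate gene id '%s'", gid[duplicated(gid)][1])
  }
  if (anyDuplicated(sid)) {
    stopf("expr_matrix: duplicate sample id '%s'", sid[duplicated(sid)][1])
  }
  if (length(condition) != ncol(values)) {
    stopf("expr_matrix: one condition per sample required")
  }
  if (!all(condition %in% c("tumor", "normal"))) {
    stopf("expr_matrix: condition must be 'tumor' or 'normal'")
  }
  if (scale == "counts" && any(values < 0)) {
    stopf("expr_matrix: negative counts")
  }
  if (is.null(gene_class)) gene_class <- infer_gene_class(gid)
  if (length(gene_class) != nrow(values)) {
    stopf("expr_matrix: one gene_class per gene required")
  }
  if (!is.null(pair_id) && length(pair_id) != ncol(values)) {
    stopf("expr_matrix: one pair_id per sample required")
  }
  structure(list(values = values,
                 gene_class = stats::setNames(gene_class, gid),
                 condition = stats::setNames(condition, sid),
                 scale = scale,
                 pair_id = if (!is.null(pair_id))
                   stats::setNames(pair_id, sid)),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d genes x %d samples [%s]\n",
              nrow(x$values), ncol(x$values), x$scale))
  cat(sprintf("  classes: %s\n",
              paste(sprintf("%s=%d", names(table(x$gene_class)),
                            table(x$gene_class)), collapse = ", ")))
  cat(sprintf("  conditions: tumor=%d, normal=%d\n",
              sum(x$condition == "tumor"), sum(x$condition == "normal")))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

# Subset samples, keeping annotations aligned.
expr_subset_samples <- function(expr, samples) {
  keep <- colnames(expr$values) %in% samples
  expr$values <- expr$values[, keep, drop = FALSE]
  expr$condition <- expr$condition[colnames(expr$values)]
  if (!is.null(expr$pair_id)) expr$pair_id <- expr$pair_id[colnames(expr$values)]
  expr
}

tumor_samples <- function(expr) names(expr$condition[expr$condition == "tumor"])

#' Normalize counts to log2(CPM + 1)
#'
#' Per sample: `log2(1e6 * count / library_size + 1)`, where the library
#' size is the sample's total count. Doubling every count in a sample leaves
#' its normalized column unchanged.
#'
#' @param counts `expr_matrix` on the `counts` scale.
#' @return `expr_matrix` on the `log2cpm` scale.
#' @export
cpm_log_normalize <- function(counts) {
  stopifnot(inherits(counts, "expr_matrix"))
  if (counts$scale != "counts") {
    stopf("cpm_log_normalize: input already on scale '%s'", counts$scale)
  }
  libsize <- colSums(counts$values)
  if (any(libsize == 0)) {
    stopf("cpm_log_normalize: zero library size in sample '%s'",
          colnames(counts$values)[libsize == 0][1])
  }
  cpm <- sweep(counts$values, 2, libsize, "/") * 1e6
  counts$values <- log2(cpm + 1)
  counts$scale <- "log2cpm"
  counts
}

#' Read an expression matrix from TSV
#'
#' First column gene identifiers, header row of sample identifiers. An
#' optional second row whose first field is `condition` carries the
#' per-sample tumor/normal labels; otherwise `condition` must be supplied.
#' Lines starting with `#` are provenance comments and are skipped.
#'
#' @param path TSV file path.
#' @param condition optional character vector overriding/abetting the
#'   condition row.
#' @param scale value scale of the file contents.
#' @return `expr_matrix`.
#' @export
read_expression_tsv <- function(path, condition = NULL,
                                scale = c("counts", "log2cpm")) {
  scale <- match.arg(scale)
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  if (length(lines) < 2) stopf("read_expression_tsv: no data rows in %s", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(fields)
  if (length(unique(ncols)) != 1) {
    bad <- which(ncols != ncols[1])[1]
    stopf("read_expression_tsv: ragged row %d in %s (expected %d fields, got %d)",
          bad, path, ncols[1], ncols[bad])
  }
  header <- fields[[1]]
  sample_ids <- header[-1]
  body <- fields[-1]
  first_col <- vapply(body, `[`, "", 1L)
  if (tolower(first_col[1]) == "condition") {
    cond_row <- body[[1]][-1]
    body <- body[-1]
    first_col <- first_col[-1]
    if (is.null(condition)) condition <- cond_row
  }
  if (is.null(condition)) {
    stopf("read_expression_tsv: no condition row in %s and none supplied", path)
  }
  if (anyDuplicated(first_col)) {
    stopf("read_expression_tsv: duplicate gene id '%s'",
          first_col[duplicated(first_col)][1])
  }
  vals <- matrix(NA_real_, length(body), length(sample_ids),
                 dimnames = list(first_col, sample_ids))
  for (i in seq_along(body)) {
    v <- suppressWarnings(as.numeric(body[[i]][-1]))
    if (anyNA(v)) {
      j <- which(is.na(v))[1]
      stopf("read_expression_tsv: non-numeric cell at gene '%s', sample '%s'",
            first_col[i], sample_ids[j])
    }
    vals[i, ] <- v
  }
  expr_matrix(vals, condition = condition, scale = scale)
}

#' Write an expression matrix to TSV
#'
#' Inverse of [read_expression_tsv()]: header of sample ids, a `condition`
#' row, then one row per gene. Provenance comment lines are prepended.
#'
#' @param expr `expr_matrix`.
#' @param path output path.
#' @param seed,config_hash optional provenance fields.
#' @export
write_expression_tsv <- function(expr, path, seed = NULL, config_hash = NULL) {
  stopifnot(inherits(expr, "expr_matrix"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(provenance_header(seed = seed, config_hash = config_hash), con)
  writeLines(paste(c("gene_id", colnames(expr$values)), collapse = "\t"), con)
  writeLines(paste(c("condition", unname(expr$condition)), collapse = "\t"),
             con)
  body <- cbind(rownames(expr$values),
                format(expr$values, trim = TRUE, digits = 15,
                       scientific = FALSE))
  writeLines(apply(body, 1, paste, collapse = "\t"), con)
  invisible(path)
}
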