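#' Normalize gene identifiers
#'
#' Strips Ensembl-style version suffixes (e.g. `ENSG00000123456.7` ->
#' `ENSG00000123456`) and upper-cases symbols so that identifiers from
#' different annotation dialects can be compared with set operations.
#'
#' @param ids character vector of gene identifiers.
#' @return character vector of normalized identifiers.
#' @export
#' @examples
#' normalize_gene_ids(c("ENSG00000245532.8", "linc01094"))
normalize_gene_ids <- function(ids) {
  if (!is.character(ids)) ids <- as.character(ids)
  toupper(sub("\\.[0-9]+$", "", ids))
}

#' Infer gene class from an identifier
#'
#' Identifiers starting with `LNC`/`LINC` are long non-coding RNAs, those
#' starting with `MIR` or `HSA-MIR`/`HSA-LET` are microRNAs, everything else
#' is treated as mRNA. Synthetic identifiers (`LNC0001`, `MIR0001`,
#' `MR0001`) and common real-world symbols both resolve correctly.
#'
#' @param ids character vector of gene identifiers.
#' @return character vector with values `"lncRNA"`, `"miRNA"` or `"mRNA"`.
#' @export
infer_gene_class <- function(ids) {
  up <- normalize_gene_ids(ids)
  out <- rep("mRNA", length(up))
  out[grepl("^(LNC|LINC)", up)] <- "lncRNA"
  out[grepl("^(MIR|HSA-MIR|HSA-LET)", up)] <- "miRNA"
  out
}

# Evaluate `code` under a fixed RNG state, restoring the caller's state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Polynomial rolling hash of a character vector; used for lightweight
# provenance fingerprints (no cryptographic intent). Kept below 2^26 per
# step so double-precision arithmetic is exact.
string_fingerprint <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\x1f"))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 67108864
  sprintf("%08x", h)
}

# Provenance header lines written at the top of every output file.
provenance_header <- function(seed = NULL, config_hash = NULL) {
  ver <- as.character(utils::packageVersion("cernascreen"))
  lines <- sprintf("# cernascreen %s", ver)
  if (!is.null(config_hash)) {
    lines <- c(lines, sprintf("# config_hash=%s", config_hash))
  }
  if (!is.null(seed)) lines <- c(lines, sprintf("# seed=%s", seed))
  lines
}

# Write a data.frame as TSV with provenance comment lines.
write_tsv <- function(df, path, seed = NULL, config_hash = NULL,
                      row_names = FALSE) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(provenance_header(seed = seed, config_hash = config_hash), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = row_names, col.names = TRUE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                    check.names = FALSE, ...)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
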