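#' Read a gene-by-sample count matrix from TSV
#'
#' Expects a tab-separated file whose first column holds gene identifiers and
#' whose header row holds sample identifiers. Values must be nonnegative
#' integers; duplicated gene or sample identifiers, negative or non-integer
#' values are rejected with an error naming the offending row — malformed
#' input is never silently coerced.
#'
#' @param path file path.
#' @return integer matrix with gene rownames and sample colnames.
#' @export
read_counts <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("count TSV needs a gene-id column plus >=1 sample")
  genes <- as.character(df[[1]])
  if (anyDuplicated(genes))
    stop("duplicate gene ids: ", paste(unique(genes[duplicated(genes)]), collapse = ", "))
  samples <- colnames(df)[-1]
  if (anyDuplicated(samples))
    stop("duplicate sample ids: ", paste(unique(samples[duplicated(samples)]), collapse = ", "))
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric count values in ", path)
  bad <- which(m < 0 | m != round(m), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop("invalid count (negative or non-integer) for gene ",
         genes[bad[1, 1]], ", sample ", samples[bad[1, 2]])
  storage.mode(m) <- "integer"
  dimnames(m) <- list(genes, samples)
  validate_counts(m)
}

#' Write a count matrix as TSV
#'
#' First column `gene`, then one column per sample. Round-trips through
#' [read_counts()].
#'
#' @param counts integer matrix, genes x samples.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path) {
  validate_counts(counts)
  df <- data.frame(gene = rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

validate_counts <- function(counts) {
  if (!is.matrix(counts) || is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must be a matrix with gene rownames and sample colnames")
  if (anyDuplicated(rownames(counts))) stop("duplicate gene ids")
  if (anyDuplicated(colnames(counts))) stop("duplicate sample ids")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be nonnegative integers")
  counts
}

#' Read / write a sample sheet
#'
#' CSV with columns `sample_id`, `group` (HC, nSS or pSS) and `cohort`.
#' `read_sample_sheet` optionally checks one-to-one correspondence with a
#' count matrix's columns.
#'
#' @param path CSV path.
#' @param counts optional count matrix to validate against.
#' @return data.frame with the three columns.
#' @export
read_sample_sheet <- function(path, counts = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "group", "cohort")
  if (!all(need %in% colnames(df)))
    stop("sample sheet must have columns: ", paste(need, collapse = ", "))
  bad <- setdiff(unique(df$group), c("HC", "nSS", "pSS"))
  if (length(bad) > 0) stop("unknown group label(s): ", paste(bad, collapse = ", "))
  if (anyDuplicated(df$sample_id)) stop("duplicate sample ids in sheet")
  if (!is.null(counts) && !setequal(df$sample_id, colnames(counts)))
    stop("sample sheet ids do not match count matrix columns one-to-one")
  df[, need]
}

#' @rdname read_sample_sheet
#' @param samples sample-sheet data.frame to write.
#' @export
write_sample_sheet <- function(samples, path) {
  utils::write.csv(samples, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' One set per line: name, description, then member gene ids, tab-separated.
#' Duplicated members within a line are removed with a warning; a line with
#' fewer than three fields is a parse error reported with its line number.
#'
#' @param path GMT file path.
#' @return named list of character vectors; each element carries its
#'   description in attribute `"description"`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop("GMT parse error at line ", i, ": fewer than 3 fields")
    members <- f[-(1:2)]
    if (anyDuplicated(members)) {
      warning("GMT line ", i, " ('", f[1], "'): duplicated members removed")
      members <- unique(members)
    }
    sets[[f[1]]] <- structure(members, description = f[2])
  }
  sets
}

#' Write a GMT gene-set collection
#'
#' @param sets named list of character vectors (optional `"description"`
#'   attribute per element).
#' @param path output path.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    desc <- attr(sets[[nm]], "description")
    if (is.null(desc)) desc <- nm
    paste(c(nm, desc, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
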