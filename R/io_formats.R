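# Readers/writers for the external formats the pipeline touches: expression
# matrices (TSV / GCT 1.2), gene sets (GMT), clinical tables, hairpin
# libraries and screen count tables. TSV is the canonical dialect (UTF-8,
# tab-delimited, '.' decimal). All loaders validate strictly and never
# silently drop rows.

#' Construct a validated expression matrix
#'
#' Expression data are held as a plain numeric matrix (genes x samples,
#' log2 scale) with unique, non-empty dimnames. This is the substrate of
#' batch adjustment, clustering, enrichment scoring and prediction.
#'
#' @param values numeric matrix, genes in rows and samples in columns.
#' @param gene_ids,sample_ids optional dimnames (default: taken from
#'   `values`).
#' @return the validated matrix with dimnames set.
#' @export
expression_matrix <- function(values, gene_ids = rownames(values),
                              sample_ids = colnames(values)) {
  .assert(is.matrix(values) && is.numeric(values),
          "expression values must be a numeric matrix")
  .assert(!is.null(gene_ids) && length(gene_ids) == nrow(values),
          "gene_ids must match the row count (%d)", nrow(values))
  .assert(!is.null(sample_ids) && length(sample_ids) == ncol(values),
          "sample_ids must match the column count (%d)", ncol(values))
  .assert(!anyDuplicated(gene_ids),
          "duplicate gene ids: %s",
          paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  .assert(!anyDuplicated(sample_ids),
          "duplicate sample ids: %s",
          paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  .assert(!anyNA(values) && all(is.finite(values)),
          "expression matrix contains missing or non-finite values")
  dimnames(values) <- list(as.character(gene_ids), as.character(sample_ids))
  values
}

#' Read an expression matrix from TSV or GCT 1.2
#'
#' The TSV dialect is a header row of sample ids followed by one row per
#' gene (first column = gene id). GCT 1.2 is the GenePattern dialect: a
#' `#1.2` version line, a dimensions line, then `Name`/`Description`
#' columns ahead of the samples.
#'
#' @param path file path.
#' @param format `"tsv"` or `"gct"`; default guesses from the extension.
#' @return a genes x samples numeric matrix (see [expression_matrix()]).
#' @export
read_expression <- function(path, format = c("auto", "tsv", "gct")) {
  format <- match.arg(format)
  .assert(file.exists(path), "file not found: %s", path)
  if (format == "auto") {
    format <- if (grepl("\\.gct$", path, ignore.case = TRUE)) "gct" else "tsv"
  }
  if (format == "gct") {
    lines <- readLines(path)
    .assert(length(lines) >= 3L, "GCT file too short: %s", path)
    .assert(trimws(lines[[1L]]) == "#1.2",
            "unsupported GCT version line '%s' (expected '#1.2')", lines[[1L]])
    dims <- as.integer(strsplit(lines[[2L]], "\t", fixed = TRUE)[[1L]][1:2])
    tab <- utils::read.delim(text = lines[-(1:2)], header = TRUE,
                             check.names = FALSE, colClasses = "character")
    .assert(nrow(tab) == dims[[1L]] && ncol(tab) - 2L == dims[[2L]],
            "GCT dimension mismatch: dims line says %d x %d, found %d x %d",
            dims[[1L]], dims[[2L]], nrow(tab), ncol(tab) - 2L)
    ids <- tab[[1L]]
    body <- tab[, -(1:2), drop = FALSE]
  } else {
    tab <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                             colClasses = "character")
    .assert(ncol(tab) >= 2L, "expression TSV needs an id column plus samples")
    ids <- tab[[1L]]
    body <- tab[, -1L, drop = FALSE]
  }
  values <- .parse_numeric_block(body, ids)
  expression_matrix(values, gene_ids = ids, sample_ids = colnames(body))
}

.parse_numeric_block <- function(body, row_ids) {
  out <- matrix(NA_real_, nrow(body), ncol(body))
  for (j in seq_len(ncol(body))) {
    v <- suppressWarnings(as.numeric(body[[j]]))
    bad <- which(is.na(v) & !is.na(body[[j]]))
    .assert(length(bad) == 0L,
            "non-numeric value '%s' at row '%s', column '%s'",
            if (length(bad)) body[[j]][bad[[1L]]] else "",
            if (length(bad)) row_ids[bad[[1L]]] else "", colnames(body)[j])
    .assert(!anyNA(v), "missing value in column '%s'", colnames(body)[j])
    out[, j] <- v
  }
  colnames(out) <- colnames(body)
  out
}

#' Write an expression matrix as TSV or GCT 1.2
#'
#' @param expr genes x samples matrix.
#' @param path output path.
#' @param format `"tsv"` or `"gct"`.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path, format = c("tsv", "gct")) {
  format <- match.arg(format)
  expr <- expression_matrix(expr)
  df <- data.frame(id = rownames(expr), expr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (format == "gct") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("#1.2", paste(nrow(expr), ncol(expr), sep = "\t")), con)
    df <- data.frame(Name = rownames(expr), Description = rownames(expr),
                     expr, check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read a gene set collection from a GMT file
#'
#' One set per line: name, description, then member genes, tab-separated.
#' Duplicate genes within a line are deduplicated with a warning; duplicate
#' set names are an error.
#'
#' @param path GMT file path.
#' @return named list of unique gene vectors, with a `description`
#'   attribute (named character vector).
#' @export
read_gmt <- function(path) {
  .assert(file.exists(path), "file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  .assert(length(lines) >= 1L, "GMT file has no sets: %s", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  sets <- vector("list", length(fields))
  names(sets) <- vapply(fields, `[[`, "", 1L)
  desc <- character(length(fields))
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    .assert(length(f) >= 3L, "GMT line %d ('%s') has fewer than 3 fields",
            i, f[[1L]])
    genes <- f[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (anyDuplicated(genes)) {
      warning(sprintf("set '%s': duplicate genes deduplicated", f[[1L]]),
              call. = FALSE)
      genes <- unique(genes)
    }
    .assert(length(genes) >= 1L, "GMT line %d ('%s') has no genes", i, f[[1L]])
    sets[[i]] <- genes
    desc[[i]] <- f[[2L]]
  }
  .assert(!anyDuplicated(names(sets)), "duplicate set name: %s",
          paste(unique(names(sets)[duplicated(names(sets))]), collapse = ", "))
  attr(sets, "description") <- stats::setNames(desc, names(sets))
  sets
}

#' Write a gene set collection to GMT
#'
#' @param sets named list of gene vectors (optionally carrying a
#'   `description` attribute, as from [read_gmt()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  .assert(is.list(sets) && !is.null(names(sets)), "sets must be a named list")
  desc <- attr(sets, "description")
  if (is.null(desc)) desc <- stats::setNames(rep("na", length(sets)), names(sets))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, desc[[nm]], sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a hairpin library table
#'
#' TSV with columns `hairpin_id`, `gene`, `sequence`. Hairpin ids and
#' sequences must be unique; sequences must be uppercase ACGT of a single
#' fixed length.
#'
#' @param path TSV path.
#' @return data.frame with the three columns; attributes `n_genes` and
#'   `hairpins_per_gene` (a table) summarize library structure.
#' @export
read_hairpin_library <- function(path) {
  .assert(file.exists(path), "file not found: %s", path)
  tab <- utils::read.delim(path, header = TRUE, colClasses = "character")
  hairpin_library(tab)
}

#' Validate a hairpin library data.frame
#'
#' @param tab data.frame with `hairpin_id`, `gene`, `sequence` columns.
#' @return the validated data.frame (see [read_hairpin_library()]).
#' @export
hairpin_library <- function(tab) {
  need <- c("hairpin_id", "gene", "sequence")
  .assert(all(need %in% colnames(tab)),
          "hairpin library must have columns: %s", paste(need, collapse = ", "))
  tab <- as.data.frame(tab)[, need]
  .assert(!anyDuplicated(tab$hairpin_id), "duplicate hairpin id: %s",
          paste(unique(tab$hairpin_id[duplicated(tab$hairpin_id)]), collapse = ", "))
  .assert(!anyDuplicated(tab$sequence), "duplicate hairpin sequence: %s",
          paste(unique(tab$sequence[duplicated(tab$sequence)]), collapse = ", "))
  .assert(all(grepl("^[ACGT]+$", tab$sequence)),
          "hairpin sequences must be uppercase ACGT only")
  .assert(length(unique(nchar(tab$sequence))) == 1L,
          "hairpin sequences must share a single fixed length")
  attr(tab, "n_genes") <- length(unique(tab$gene))
  attr(tab, "hairpins_per_gene") <- table(table(tab$gene))
  tab
}

# Allowed clinical category tokens. Missing fields are the explicit token
# "unknown"; operations needing a field reject such records, never impute.
.STAGE_LEVELS <- c("I", "II", "III", "IV", "unknown")
.GRADE_LEVELS <- c("1", "2", "3", "unknown")

#' Read a per-sample clinical annotation table
#'
#' TSV with a `sample_id` column and any of: `age`, `stage` (I-IV),
#' `grade` (1-3), `metastasis` (0/1), `histology`, `os_time`/`os_event`,
#' `pfs_time`/`pfs_event`. Missing categorical values may be written as
#' `unknown` (or left empty, which is coerced to `unknown`).
#'
#' @param path TSV path.
#' @return validated data.frame.
#' @export
read_clinical <- function(path) {
  .assert(file.exists(path), "file not found: %s", path)
  tab <- utils::read.delim(path, header = TRUE, colClasses = "character",
                           na.strings = c("NA", ""))
  clinical_table(tab)
}

#' Validate a clinical table
#'
#' @param tab data.frame as described in [read_clinical()].
#' @return validated data.frame with numeric time/event/age columns.
#' @export
clinical_table <- function(tab) {
  tab <- as.data.frame(tab)
  .assert("sample_id" %in% colnames(tab), "clinical table needs 'sample_id'")
  .assert(!anyDuplicated(tab$sample_id), "duplicate sample ids in clinical table")
  coerce_cat <- function(x, levels, what) {
    x <- as.character(x)
    x[is.na(x)] <- "unknown"
    bad <- setdiff(unique(x), levels)
    .assert(length(bad) == 0L, "unknown %s token(s) %s; allowed: %s", what,
            paste(sQuote(bad), collapse = ", "), paste(levels, collapse = ", "))
    x
  }
  if ("stage" %in% colnames(tab)) {
    tab$stage <- coerce_cat(tab$stage, .STAGE_LEVELS, "stage")
  }
  if ("grade" %in% colnames(tab)) {
    tab$grade <- coerce_cat(tab$grade, .GRADE_LEVELS, "grade")
  }
  for (col in c("age", "os_time", "os_event", "pfs_time", "pfs_event",
                "metastasis")) {
    if (col %in% colnames(tab)) tab[[col]] <- as.numeric(tab[[col]])
  }
  for (tm in c("os_time", "pfs_time")) {
    if (tm %in% colnames(tab)) {
      ok <- is.na(tab[[tm]]) | tab[[tm]] > 0
      .assert(all(ok), "%s must be > 0 (offending sample: %s)",
              tm, paste(tab$sample_id[!ok], collapse = ", "))
    }
  }
  for (ev in c("os_event", "pfs_event", "metastasis")) {
    if (ev %in% colnames(tab)) {
      ok <- is.na(tab[[ev]]) | tab[[ev]] %in% c(0, 1)
      .assert(all(ok), "%s must be 0/1", ev)
    }
  }
  tab
}

#' Write a clinical table to TSV
#' @param tab clinical data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_clinical <- function(tab, path) {
  utils::write.table(clinical_table(tab), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a hairpin-by-sample count table
#'
#' TSV with a leading hairpin id column and one column per sample. Raw
#' counts must be non-negative integers.
#'
#' @param path TSV path.
#' @param raw if `TRUE` (default) enforce integer counts; set `FALSE` for
#'   normalized (real-valued) tables.
#' @return numeric matrix, hairpins x samples.
#' @export
read_counts <- function(path, raw = TRUE) {
  .assert(file.exists(path), "file not found: %s", path)
  tab <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                           colClasses = "character")
  ids <- tab[[1L]]
  .assert(!anyDuplicated(ids), "duplicate hairpin ids in count table")
  m <- .parse_numeric_block(tab[, -1L, drop = FALSE], ids)
  rownames(m) <- ids
  .assert(all(m >= 0), "counts must be non-negative")
  if (raw) {
    .assert(all(m == round(m)), "raw counts must be non-negative integers")
  }
  m
}

#' Write a count table to TSV
#' @param counts hairpins x samples matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path) {
  df <- data.frame(hairpin_id = rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
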