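#' Expression matrix with a declared value kind
#'
#' Container for a genes x samples numeric matrix together with a
#' declaration of what its values are: raw counts (`"counts"`),
#' log-scale expression (`"logexpr"`), or per-sample robust z-scores
#' (`"zscore"`). Counts must be non-negative integers; gene and sample
#' identifiers must be unique. Identifiers are case-sensitive opaque
#' strings: no symbol normalization is ever applied, cross-species joins
#' go through an explicit [ortholog_map()].
#'
#' @param values Numeric matrix with rownames (gene/feature ids) and
#'   colnames (sample/profile ids).
#' @param value_kind One of `"counts"`, `"logexpr"`, `"zscore"`.
#' @return An object of class `ExpressionMatrix`: a list with elements
#'   `values`, `gene_ids`, `sample_ids`, `value_kind`.
#' @export
expression_matrix <- function(values, value_kind = c("counts", "logexpr", "zscore")) {
  value_kind <- match.arg(value_kind)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop_validation("`values` must be a numeric matrix")
  }
  gene_ids <- rownames(values) %||% (if (nrow(values) == 0) character(0))
  sample_ids <- colnames(values) %||% (if (ncol(values) == 0) character(0))
  if (is.null(gene_ids) || is.null(sample_ids)) {
    stop_validation("`values` must carry gene ids as rownames and sample ids as colnames")
  }
  dup_g <- gene_ids[duplicated(gene_ids)]
  if (length(dup_g)) {
    stop_format(sprintf("duplicate gene id: '%s'", dup_g[[1]]))
  }
  dup_s <- sample_ids[duplicated(sample_ids)]
  if (length(dup_s)) {
    stop_format(sprintf("duplicate sample id: '%s'", dup_s[[1]]))
  }
  if (anyNA(values)) {
    stop_validation("missing values are not permitted in an expression matrix")
  }
  if (value_kind == "counts" && any(values < 0 | values != round(values))) {
    bad <- which(values < 0 | values != round(values), arr.ind = TRUE)[1, ]
    stop_validation(sprintf(
      "counts must be non-negative integers; offending entry at gene '%s', sample '%s'",
      gene_ids[bad[1]], sample_ids[bad[2]]))
  }
  structure(
    list(values = values, gene_ids = gene_ids, sample_ids = sample_ids,
         value_kind = value_kind),
    class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d samples (%s)\n",
              length(x$gene_ids), length(x$sample_ids), x$value_kind))
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' Sample-to-group design
#'
#' @param sample_id Character vector of sample identifiers.
#' @param group Character vector of group labels, one per sample.
#' @param group_levels Optional ordered group labels; defaults to order of
#'   first appearance.
#' @return A data.frame of class `SampleDesign` with columns `sample_id`
#'   and `group`.
#' @export
sample_design <- function(sample_id, group, group_levels = NULL) {
  if (length(sample_id) != length(group)) {
    stop_validation("sample_id and group must have equal length")
  }
  if (anyDuplicated(sample_id)) {
    stop_validation(sprintf("duplicate sample id: '%s'",
                            sample_id[duplicated(sample_id)][1]))
  }
  group_levels <- group_levels %||% unique(group)
  if (!all(group %in% group_levels)) {
    stop_validation("every group label must appear in group_levels")
  }
  out <- data.frame(sample_id = as.character(sample_id),
                    group = as.character(group),
                    stringsAsFactors = FALSE)
  attr(out, "group_levels") <- group_levels
  class(out) <- c("SampleDesign", "data.frame")
  out
}

design_samples <- function(design, group) {
  design$sample_id[design$group == group]
}

#' Differential-expression result table
#'
#' Validates and classes a per-gene DE table. Required columns:
#' `gene_id`, `log2fc`, `p`, `p_adj`; `base_mean` and any extra columns
#' are preserved opaquely. `p_adj` may be `NA` only for genes filtered
#' before testing; such rows are excluded from all downstream set
#' constructions.
#'
#' @param df A data.frame with the required columns.
#' @return The validated data.frame with class `DEResultTable`.
#' @export
de_result_table <- function(df) {
  required <- c("gene_id", "log2fc", "p", "p_adj")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop_format(sprintf("missing required column: '%s'", missing_cols[[1]]))
  }
  if (anyDuplicated(df$gene_id)) {
    stop_format(sprintf("duplicate gene id: '%s'",
                        df$gene_id[duplicated(df$gene_id)][1]))
  }
  for (col in c("p", "p_adj")) {
    v <- df[[col]]
    if (any(!is.na(v) & (v < 0 | v > 1))) {
      stop_validation(sprintf("column '%s' must lie in [0, 1]", col))
    }
  }
  ok <- !is.na(df$p) & !is.na(df$p_adj)
  # allow a hair of rounding slack from text round-trips of adjusted values
  if (any(df$p_adj[ok] < df$p[ok] - 1e-12)) {
    bad <- df$gene_id[ok][which(df$p_adj[ok] < df$p[ok] - 1e-12)[1]]
    stop_validation(sprintf(
      "p_adj < p at gene '%s': adjusted values cannot undercut raw p under BH", bad))
  }
  df$gene_id <- as.character(df$gene_id)
  rownames(df) <- NULL
  class(df) <- c("DEResultTable", "data.frame")
  df
}

#' Named gene-set collection
#'
#' @param sets Named list of character vectors (set members).
#' @param descriptions Optional character vector of per-set descriptions.
#' @return Object of class `GeneSetCollection`.
#' @export
gene_set_collection <- function(sets, descriptions = NULL) {
  if (length(sets)) {
    if (is.null(names(sets)) || anyDuplicated(names(sets))) {
      stop_validation("set names must be present and unique")
    }
    if (any(lengths(sets) == 0)) {
      stop_validation(sprintf("set '%s' is empty",
                              names(sets)[lengths(sets) == 0][1]))
    }
  }
  descriptions <- descriptions %||% rep("", length(sets))
  structure(list(sets = lapply(sets, as.character),
                 descriptions = as.character(descriptions)),
            class = "GeneSetCollection")
}

#' @export
print.GeneSetCollection <- function(x, ...) {
  cat(sprintf("GeneSetCollection: %d sets (sizes %s)\n", length(x$sets),
              if (length(x$sets)) paste(range(lengths(x$sets)), collapse = "-") else "-"))
  invisible(x)
}

#' Read a genes x samples TSV into an ExpressionMatrix
#'
#' The file must have a header row of sample ids and gene ids in the
#' first column. Malformed input is rejected, never coerced: duplicate
#' ids and non-numeric cells raise format errors naming the offender.
#'
#' @param path Path to a TSV file.
#' @inheritParams expression_matrix
#' @return An [expression_matrix()].
#' @export
read_expression_matrix <- function(path, value_kind = c("counts", "logexpr", "zscore")) {
  value_kind <- match.arg(value_kind)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                           colClasses = "character", stringsAsFactors = FALSE)
  if (ncol(raw) < 2) stop_format(sprintf("'%s': expected gene id column plus >=1 sample", path))
  gene_ids <- raw[[1]]
  sample_ids <- colnames(raw)[-1]
  dup <- gene_ids[duplicated(gene_ids)]
  if (length(dup)) stop_format(sprintf("duplicate gene id: '%s'", dup[[1]]))
  dup <- sample_ids[duplicated(sample_ids)]
  if (length(dup)) stop_format(sprintf("duplicate sample id: '%s'", dup[[1]]))
  vals <- matrix(NA_real_, nrow = nrow(raw), ncol = length(sample_ids),
                 dimnames = list(gene_ids, sample_ids))
  for (j in seq_along(sample_ids)) {
    txt <- raw[[j + 1]]
    num <- suppressWarnings(as.numeric(txt))
    bad <- which(is.na(num))
    if (length(bad)) {
      stop_format(sprintf("non-numeric cell at gene '%s', sample '%s': '%s'",
                          gene_ids[bad[1]], sample_ids[j], txt[bad[1]]))
    }
    vals[, j] <- num
  }
  expression_matrix(vals, value_kind)
}

#' Write an ExpressionMatrix as TSV
#'
#' @param em An [expression_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(em, path) {
  stopifnot(inherits(em, "ExpressionMatrix"))
  header <- paste(c("gene_id", em$sample_ids), collapse = "\t")
  body <- vapply(seq_along(em$gene_ids), function(i) {
    paste(c(em$gene_ids[i], fmt_num(em$values[i, ])), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a GMT gene-set file
#'
#' Standard dialect: one set per line, `name TAB description TAB members...`.
#' Duplicate members within a line are collapsed with a warning; a line
#' with fewer than three fields is a format error naming the line number.
#' An empty file yields an empty collection.
#'
#' @param path Path to a GMT file.
#' @return A [gene_set_collection()].
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(gene_set_collection(list()))
  sets <- list(); descs <- character(0)
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) {
      stop_format(sprintf("GMT line %d has %d field(s); need name, description, >=1 member",
                          i, length(fields)))
    }
    members <- fields[-(1:2)]
    members <- members[nzchar(members)]
    if (anyDuplicated(members)) {
      warning(sprintf("GMT set '%s': %d duplicate member(s) collapsed",
                      fields[[1]], sum(duplicated(members))), call. = FALSE)
      members <- unique(members)
    }
    sets[[fields[[1]]]] <- members
    descs <- c(descs, fields[[2]])
  }
  gene_set_collection(sets, descs)
}

#' Write a GeneSetCollection as GMT
#'
#' @param gsc A [gene_set_collection()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(gsc, path) {
  stopifnot(inherits(gsc, "GeneSetCollection"))
  lines <- vapply(seq_along(gsc$sets), function(i) {
    paste(c(names(gsc$sets)[i], gsc$descriptions[i], gsc$sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read/write a DE result table as TSV
#'
#' Required columns `gene_id`, `log2fc`, `p`, `p_adj`; extra columns are
#' preserved. Numbers are written with full precision so write-then-read
#' is the identity.
#'
#' @param path TSV path.
#' @return A [de_result_table()].
#' @export
read_de_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  required <- c("gene_id", "log2fc", "p", "p_adj")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop_format(sprintf("'%s': missing required column: '%s'", path, missing_cols[[1]]))
  }
  for (col in setdiff(names(df), "gene_id")) {
    if (is.character(df[[col]])) {
      num <- suppressWarnings(as.numeric(df[[col]]))
      if (!any(is.na(num) & !(df[[col]] %in% c("NA", "")))) df[[col]] <- num
    }
  }
  de_result_table(df)
}

#' @rdname read_de_table
#' @param table A [de_result_table()].
#' @export
write_de_table <- function(table, path) {
  stopifnot(inherits(table, "DEResultTable"))
  df <- as.data.frame(table)
  out <- df
  for (col in names(out)) {
    if (is.numeric(out[[col]])) out[[col]] <- fmt_num(out[[col]])
  }
  lines <- c(paste(names(out), collapse = "\t"),
             if (nrow(out)) do.call(paste, c(unname(out), sep = "\t")))
  writeLines(lines, path)
  invisible(path)
}

#' Read/write one-gene-per-line GRP files (signature arms)
#'
#' @param path GRP path.
#' @return Character vector of ids.
#' @export
read_grp <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines[nzchar(lines) & !startsWith(lines, "#")]
}

#' @rdname read_grp
#' @param ids Character vector of ids.
#' @export
write_grp <- function(ids, path) {
  writeLines(as.character(ids), path)
  invisible(path)
}

#' Read a sample design TSV (columns sample_id, group)
#'
#' @param path TSV path.
#' @return A [sample_design()].
#' @export
read_sample_design <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          colClasses = "character", stringsAsFactors = FALSE)
  missing_cols <- setdiff(c("sample_id", "group"), names(df))
  if (length(missing_cols)) {
    stop_format(sprintf("'%s': missing required column: '%s'", path, missing_cols[[1]]))
  }
  sample_design(df$sample_id, df$group)
}

#' Read a two-column ortholog map TSV
#'
#' Columns `source_id` and `target_id` (header required).
#'
#' @param path TSV path.
#' @param policy Many-to-many resolution policy, see [ortholog_map()].
#' @return An [ortholog_map()].
#' @export
read_ortholog_map <- function(path, policy = c("one2one_only", "first_alphabetical")) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          colClasses = "character", stringsAsFactors = FALSE)
  missing_cols <- setdiff(c("source_id", "target_id"), names(df))
  if (length(missing_cols)) {
    stop_format(sprintf("'%s': missing required column: '%s'", path, missing_cols[[1]]))
  }
  ortholog_map(df$source_id, df$target_id, policy = match.arg(policy))
}

#' Write an ortholog map as TSV
#'
#' @param map An [ortholog_map()].
#' @param path Output path.
#' @export
write_ortholog_map <- function(map, path) {
  stopifnot(inherits(map, "OrthologMap"))
  lines <- c("source_id\ttarget_id",
             if (nrow(map$pairs)) paste(map$pairs$source_id, map$pairs$target_id, sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}
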