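#' Write an expression matrix as GCT v1.2
#'
#' Unavailable entries are written as empty fields, the GCT convention for
#' missing data.
#'
#' @param m an [expr_matrix].
#' @param path output file path.
#' @export
write_gct <- function(m, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#1.2", con)
  writeLines(sprintf("%d\t%d", nrow(m$values), ncol(m$values)), con)
  df <- data.frame(Name = gene_ids(m), Description = gene_ids(m),
                   m$values, check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("Name", "Description", sample_ids(m))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Read a GCT v1.2 expression file
#'
#' @param path GCT file; empty or NA fields become unavailable entries.
#' @param batch optional per-sample batch labels.
#' @return an [expr_matrix].
#' @export
read_gct <- function(path, batch = NULL) {
  header <- readLines(path, n = 1L)
  if (!startsWith(header, "#1.2"))
    stop("not a GCT v1.2 file: ", path)
  df <- utils::read.delim(path, skip = 2L, check.names = FALSE,
                          stringsAsFactors = FALSE)
  vals <- as.matrix(df[, -(1:2), drop = FALSE])
  storage.mode(vals) <- "double"
  rownames(vals) <- df$Name
  expr_matrix(vals, batch = batch)
}

#' Write an expression matrix as plain genes x samples TSV
#'
#' @param m an [expr_matrix].
#' @param path output file path.
#' @export
write_expr_tsv <- function(m, path) {
  df <- data.frame(gene_id = gene_ids(m), m$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("gene_id", sample_ids(m))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Read a survival table from TSV
#'
#' Expects columns `sample_id`, `time_months` (or `time`) and `event`.
#'
#' @param path tab-delimited file.
#' @return a [surv_table].
#' @export
read_surv_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  tcol <- intersect(c("time_months", "time"), names(df))[1]
  if (is.na(tcol) || !all(c("sample_id", "event") %in% names(df)))
    stop("survival table needs columns sample_id, time_months (or time), event")
  surv_table(df$sample_id, df[[tcol]], df$event)
}

#' Write a survival table as TSV
#'
#' @param surv a [surv_table].
#' @param path output file path.
#' @export
write_surv_tsv <- function(surv, path) {
  df <- data.frame(sample_id = surv$sample_id, time_months = surv$time,
                   event = surv$event)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene-set collection from a GMT file
#'
#' Each line is `set_name<TAB>description<TAB>member1<TAB>member2...`.
#' Duplicate members within a set are dropped.
#'
#' @param path GMT file path.
#' @return a `geneset_collection`: a named list of character vectors, with a
#'   `description` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(fields, length, 1L) < 3L)
  if (length(bad))
    stop(sprintf("malformed GMT line %d in %s: need name, description and >=1 member",
                 bad[1], path))
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(names(sets)))
    stop("duplicate set names in GMT file: ", path)
  geneset_collection(sets,
                     description = vapply(fields, `[[`, "", 2L))
}

#' Construct a gene-set collection
#'
#' @param sets named list of character vectors of member gene ids.
#' @param description optional per-set descriptions.
#' @return a `geneset_collection`.
#' @export
geneset_collection <- function(sets, description = NULL) {
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("every gene set needs a name")
  sets <- lapply(sets, function(s) unique(as.character(s)))
  if (any(lengths(sets) == 0L)) stop("empty gene set in collection")
  if (is.null(description)) description <- rep("", length(sets))
  structure(sets, description = stats::setNames(description, names(sets)),
            class = "geneset_collection")
}

#' @export
print.geneset_collection <- function(x, ...) {
  cat(sprintf("geneset_collection: %d sets, median size %d\n",
              length(x), as.integer(stats::median(lengths(x)))))
  invisible(x)
}

#' Write a gene-set collection as GMT
#'
#' @param gs a `geneset_collection`.
#' @param path output file path.
#' @export
write_gmt <- function(gs, path) {
  desc <- attr(gs, "description")
  if (is.null(desc)) desc <- stats::setNames(rep("", length(gs)), names(gs))
  lines <- vapply(names(gs), function(nm) {
    paste(c(nm, if (nzchar(desc[[nm]])) desc[[nm]] else "na", gs[[nm]]),
          collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}
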