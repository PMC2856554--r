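#' Expression matrix with availability mask
#'
#' Container for a genes x samples matrix of log2 expression ratios together
#' with a per-entry availability mask and per-sample batch labels. An entry is
#' "available" when the underlying probe measurement was neither saturated nor
#' below the limit of quantification in either channel; unavailable entries are
#' stored as `NA` and ignored by every downstream statistic.
#'
#' @param values numeric matrix, genes in rows and samples in columns; both
#'   dimnames are required (gene ids, sample ids).
#' @param available logical matrix of the same shape, `TRUE` where the entry is
#'   usable. Defaults to `!is.na(values)`.
#' @param batch batch label per sample (coerced to factor). Defaults to a
#'   single batch.
#' @return an object of class `expr_matrix`: a list with elements `values`,
#'   `available`, `batch`.
#' @export
expr_matrix <- function(values, available = NULL, batch = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must carry gene ids (rownames) and sample ids (colnames)")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene ids in `values`")
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids in `values`")
  if (is.null(available)) available <- !is.na(values)
  if (!is.logical(available) || !identical(dim(available), dim(values)))
    stop("`available` must be a logical matrix with the shape of `values`")
  dimnames(available) <- dimnames(values)
  if (any(is.na(values[available])))
    stop("NA values where `available` is TRUE")
  values[!available] <- NA_real_
  if (is.null(batch)) batch <- rep("batch1", ncol(values))
  if (length(batch) != ncol(values))
    stop("`batch` must have one label per sample")
  structure(list(values = values, available = available,
                 batch = factor(batch)),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d genes x %d samples, %d batch(es), %.1f%% available\n",
              nrow(x$values), ncol(x$values), nlevels(x$batch),
              100 * mean(x$available)))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Subset an expression matrix
#'
#' @param x an [expr_matrix].
#' @param i gene index (integer, logical or character).
#' @param j sample index.
#' @param ... ignored.
#' @export
`[.expr_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$values))
  if (missing(j)) j <- seq_len(ncol(x$values))
  if (is.character(j)) j <- match(j, colnames(x$values))
  if (is.logical(j)) j <- which(j)
  expr_matrix(x$values[i, j, drop = FALSE],
              x$available[i, j, drop = FALSE],
              as.character(x$batch)[j])
}

gene_ids <- function(m) rownames(m$values)
sample_ids <- function(m) colnames(m$values)

#' Survival table for right-censored recurrence-free survival
#'
#' @param sample_id unique sample identifiers.
#' @param time positive follow-up times in months (time to recurrence or to
#'   last recurrence-free follow-up).
#' @param event 1 if recurrence was observed at `time`, 0 if censored.
#' @return a `data.frame` of class `surv_table` with columns `sample_id`,
#'   `time`, `event`.
#' @export
surv_table <- function(sample_id, time, event) {
  sample_id <- as.character(sample_id)
  if (anyDuplicated(sample_id)) stop("sample ids must be unique")
  time <- as.numeric(time); event <- as.numeric(event)
  if (length(time) != length(sample_id) || length(event) != length(sample_id))
    stop("sample_id, time and event must have equal length")
  if (any(!is.finite(time)) || any(time <= 0))
    stop("survival times must be positive and finite")
  if (!all(event %in% c(0, 1)))
    stop("event indicators must be 0 (censored) or 1 (recurrence)")
  structure(data.frame(sample_id = sample_id, time = time, event = event,
                       stringsAsFactors = FALSE),
            class = c("surv_table", "data.frame"))
}

# align a surv_table to the sample order of an expr_matrix
align_surv <- function(m, surv) {
  ids <- sample_ids(m)
  idx <- match(ids, surv$sample_id)
  if (anyNA(idx))
    stop("survival table is missing samples: ",
         paste(ids[is.na(idx)], collapse = ", "))
  surv[idx, , drop = FALSE]
}
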