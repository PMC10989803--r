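# Reading, validation and basic transforms of the two tables everything else
# consumes: an OTU count table (OTUs x samples, nonnegative integers) and an
# environment table (samples x variables, finite reals).

#' Validate an OTU count table
#'
#' Checks the invariants every downstream function relies on: a numeric
#' matrix of finite, nonnegative, integer-valued counts with unique,
#' non-missing row (OTU) and column (sample) names.
#'
#' @param counts Matrix of read counts, OTUs in rows, samples in columns.
#' @return The validated matrix, invisibly with storage mode coerced to
#'   integer-valued numeric.
#' @export
validate_count_table <- function(counts) {
  if (!is.matrix(counts) || !is.numeric(counts))
    stop("count table must be a numeric matrix (OTUs x samples)")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("count table must have OTU row names and sample column names")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate OTU ids: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]),
               collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]),
               collapse = ", "))
  if (any(!is.finite(counts)))
    stop("count table contains missing or non-finite values")
  if (any(counts < 0))
    stop("count table contains negative values")
  if (any(counts != round(counts))) {
    bad <- which(counts != round(counts), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-integer count at OTU '%s', sample '%s'",
                 rownames(counts)[bad[1L]], colnames(counts)[bad[2L]]))
  }
  invisible(counts)
}

#' Read an OTU count table from delimited text
#'
#' Expects a header row of sample ids and a first column of OTU ids (any
#' first-column header, conventionally `otu_id`). Cells must parse as
#' nonnegative integers; the offending OTU/sample pair is named otherwise.
#'
#' @param path Path to the file.
#' @param sep Field delimiter; defaults to tab.
#' @return Numeric matrix of counts, OTUs in rows, samples in columns, in
#'   file order.
#' @export
read_count_table <- function(path, sep = "\t") {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           check.names = FALSE, colClasses = "character",
                           comment.char = "", quote = "\"")
  if (ncol(raw) < 2L) stop("count table needs an OTU id column and at least one sample")
  otu_ids <- raw[[1L]]
  sample_ids <- colnames(raw)[-1L]
  if (anyDuplicated(otu_ids))
    stop("duplicate OTU ids in ", path, ": ",
         paste(unique(otu_ids[duplicated(otu_ids)]), collapse = ", "))
  if (anyDuplicated(sample_ids))
    stop("duplicate sample ids in ", path, ": ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  body <- as.matrix(raw[, -1L, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(body), dim = dim(body)))
  bad <- which(is.na(num) | num < 0 | num != round(num), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf(
      "cell is not a nonnegative integer at OTU '%s', sample '%s' (value '%s')",
      otu_ids[bad[1L, 1L]], sample_ids[bad[1L, 2L]],
      body[bad[1L, 1L], bad[1L, 2L]]))
  dimnames(num) <- list(otu_ids, sample_ids)
  validate_count_table(num)
  num
}

#' Write an OTU count table as delimited text
#'
#' Inverse of [read_count_table()]: integer tables round-trip bit-identically.
#'
#' @param counts Count matrix (OTUs x samples).
#' @param path Output path.
#' @param sep Field delimiter; defaults to tab.
#' @export
write_count_table <- function(counts, path, sep = "\t") {
  validate_count_table(counts)
  df <- data.frame(otu_id = rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an environment table from delimited text
#'
#' Expects samples in rows (first column sample ids) and environmental
#' variables in columns. The delimiter is auto-detected (comma or tab)
#' unless given.
#'
#' @param path Path to the file.
#' @param sep Field delimiter, or `NULL` to auto-detect from the header line.
#' @return Numeric matrix, samples in rows, variables in columns.
#' @export
read_env_table <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep)) {
    header <- readLines(path, n = 1L)
    sep <- if (grepl("\t", header)) "\t" else ","
  }
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           check.names = FALSE, comment.char = "",
                           quote = "\"", stringsAsFactors = FALSE)
  if (ncol(raw) < 2L) stop("environment table needs a sample id column and at least one variable")
  sample_ids <- as.character(raw[[1L]])
  if (anyDuplicated(sample_ids))
    stop("duplicate sample ids in ", path, ": ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  env <- as.matrix(raw[, -1L, drop = FALSE])
  storage.mode(env) <- "double"
  rownames(env) <- sample_ids
  validate_env_table(env)
  env
}

#' Validate an environment table
#'
#' @param env Numeric matrix, samples in rows, variables in columns.
#' @return The matrix, invisibly.
#' @export
validate_env_table <- function(env) {
  if (!is.matrix(env) || !is.numeric(env))
    stop("environment table must be a numeric matrix (samples x variables)")
  if (is.null(rownames(env)) || is.null(colnames(env)))
    stop("environment table must have sample row names and variable column names")
  if (anyDuplicated(rownames(env)))
    stop("duplicate sample ids in environment table")
  if (any(!is.finite(env))) {
    bad <- which(!is.finite(env), arr.ind = TRUE)[1L, ]
    stop(sprintf("missing or non-finite value for variable '%s', sample '%s'",
                 colnames(env)[bad[2L]], rownames(env)[bad[1L]]))
  }
  invisible(env)
}

#' Write an environment table as CSV
#'
#' @param env Numeric matrix, samples in rows, variables in columns.
#' @param path Output path.
#' @param sep Field delimiter; defaults to comma.
#' @export
write_env_table <- function(env, path, sep = ",") {
  df <- data.frame(sample_id = rownames(env), env, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Rarefy a count table to a common depth
#'
#' Subsamples each sample's reads without replacement to exactly `depth`
#' reads (a multivariate-hypergeometric draw per sample), removing
#' sequencing-depth artifacts before richness and tolerance-breadth
#' estimation. One draw is taken per sample.
#'
#' @param counts Count matrix (OTUs x samples).
#' @param depth Target reads per sample (positive integer).
#' @param seed Integer seed; the draw is reproducible given the seed.
#' @param drop_short If `TRUE`, samples whose total is below `depth` are
#'   dropped with a warning; otherwise they are an error.
#' @return Count matrix with every column summing exactly to `depth`.
#' @export
rarefy <- function(counts, depth, seed = 1L, drop_short = FALSE) {
  validate_count_table(counts)
  if (length(depth) != 1L || depth < 1 || depth != round(depth))
    stop("depth must be a single positive integer")
  totals <- colSums(counts)
  short <- names(totals)[totals < depth]
  if (length(short) > 0L) {
    msg <- sprintf("%s (total %d < depth %d)", short,
                   as.integer(totals[short]), as.integer(depth))
    if (!drop_short)
      stop("samples below rarefaction depth: ", paste(msg, collapse = "; "),
           "; set drop_short = TRUE to drop them")
    warning("dropping samples below rarefaction depth: ",
            paste(msg, collapse = "; "))
    counts <- counts[, !(colnames(counts) %in% short), drop = FALSE]
  }
  if (ncol(counts) == 0L) return(counts)
  set.seed(seed)
  # vegan expects sites in rows; transpose in and out. Its "observed
  # counts" heuristic warning misfires on validated integer tables whose
  # smallest count exceeds 1, so it is muffled.
  out <- withCallingHandlers(
    t(vegan::rrarefy(t(counts), sample = depth)),
    warning = function(w) {
      if (grepl("observed counts", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  storage.mode(out) <- "double"
  out
}

#' Convert counts to within-sample relative abundances
#'
#' Each sample column is divided by its column sum, giving the weights used
#' by every community-weighted mean in the package.
#'
#' @param counts Count matrix (OTUs x samples); no all-zero samples.
#' @return Matrix of the same shape; each column sums to 1.
#' @export
to_relative_abundance <- function(counts) {
  validate_count_table(counts)
  totals <- colSums(counts)
  if (any(totals == 0))
    stop("samples with zero total count: ",
         paste(colnames(counts)[totals == 0], collapse = ", "))
  sweep(counts, 2L, totals, "/")
}

#' Observed OTU richness per sample
#'
#' @param counts Count matrix (OTUs x samples).
#' @return Named integer vector: number of OTUs with count > 0 in each sample.
#' @export
richness <- function(counts) {
  validate_count_table(counts)
  colSums(counts > 0)
}
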