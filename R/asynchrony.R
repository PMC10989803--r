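# Pairwise response asynchrony (RA) and its community mean (CMRA).
# RA_ij is the negated Spearman rank correlation of the relative-abundance
# profiles of OTUs i and j across all samples: +1 means the two OTUs rise
# and fall in perfect opposition along the gradient (fully compensatory),
# -1 means they track each other exactly (fully synchronous).

#' Pairwise response asynchrony matrix
#'
#' Computes RA for every pair of the requested OTUs as minus the Spearman
#' correlation of their relative abundances across all samples (zeros
#' included, average ranks for ties). OTUs whose profile is constant across
#' samples have undefined rank correlation; their off-diagonal entries are
#' `NA` and their count is reported via a message (the caller decides
#' whether to exclude them).
#'
#' @param relabund Relative-abundance matrix (OTUs x samples) from
#'   [to_relative_abundance()]; at least 3 samples.
#' @param otus Character vector of OTU ids to include, or `NULL` for all.
#' @return Symmetric matrix of RA values in \[-1, 1\] with OTU ids as
#'   dimnames; the diagonal is -1 (an OTU is perfectly synchronous with
#'   itself).
#' @export
response_asynchrony <- function(relabund, otus = NULL) {
  if (!is.matrix(relabund) || !is.numeric(relabund))
    stop("relabund must be a numeric matrix (OTUs x samples)")
  if (ncol(relabund) < 3L)
    stop("at least 3 samples are required for rank correlations")
  if (!is.null(otus)) {
    missing <- setdiff(otus, rownames(relabund))
    if (length(missing) > 0L)
      stop("unknown OTU id(s): ", paste(utils::head(missing, 5L),
                                        collapse = ", "))
    relabund <- relabund[otus, , drop = FALSE]
  }
  constant <- apply(relabund, 1L, function(x) max(x) == min(x))
  if (any(constant))
    message(sum(constant), " OTU(s) with constant profiles; RA undefined (NA)")
  rho <- suppressWarnings(stats::cor(t(relabund), method = "spearman"))
  ra <- -rho
  diag(ra) <- -1
  ra
}

#' Community mean response asynchrony of one sample
#'
#' The mean RA over all unordered distinct pairs of the selected OTUs,
#' weighted by the products of their within-sample relative abundances:
#' `sum_{i<j} a_i a_j RA_ij / sum_{i<j} a_i a_j`. Pairs with undefined RA
#' are excluded from numerator and denominator alike.
#'
#' @param abund Named vector of within-sample relative abundances (the
#'   sample's column of the relative-abundance table).
#' @param ra RA matrix from [response_asynchrony()] covering the selected
#'   OTUs.
#' @param selected OTU ids to average over, or `NULL` for all OTUs present
#'   (abundance > 0) in the sample.
#' @return CMRA in \[-1, 1\], or `NA` when fewer than two usable OTUs
#'   (positive abundance and defined RA) remain.
#' @export
cmra <- function(abund, ra, selected = NULL) {
  if (is.null(names(abund))) stop("abund must be a named vector of OTU abundances")
  if (is.null(selected)) selected <- names(abund)[abund > 0]
  selected <- selected[abund[selected] > 0]
  missing <- setdiff(selected, rownames(ra))
  if (length(missing) > 0L)
    stop("RA matrix does not cover OTU(s): ",
         paste(utils::head(missing, 5L), collapse = ", "))
  if (length(selected) < 2L) return(NA_real_)
  a <- abund[selected]
  m <- ra[selected, selected]
  diag(m) <- 0
  defined <- !is.na(m)
  m[!defined] <- 0
  num <- drop(crossprod(a, m %*% a)) / 2
  den <- (drop(crossprod(a, defined %*% a)) - sum(a^2)) / 2
  if (den <= 0) return(NA_real_)
  num / den
}

# Batched CMRA for many OTU subsets of one sample (used by compute_indices).
# weights: (K x R) matrix, column r holding the relative abundances of the
# r-th subset in the rows it selects and 0 elsewhere; m: (K x K) RA
# submatrix. Returns a length-R vector of CMRA values.
.cmra_batch <- function(weights, m) {
  diag(m) <- 0
  defined <- !is.na(m)
  if (all(defined)) {
    m_num <- m
    num <- colSums(weights * (m_num %*% weights)) / 2
    den <- (colSums(weights)^2 - colSums(weights^2)) / 2
  } else {
    m[!defined] <- 0
    num <- colSums(weights * (m %*% weights)) / 2
    storage.mode(defined) <- "double"
    den <- (colSums(weights * (defined %*% weights)) - colSums(weights^2)) / 2
  }
  out <- num / den
  out[den <= 0] <- NA_real_
  out
}
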