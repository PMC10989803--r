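# Per-OTU environmental tolerance breadth (TB): the abundance-weighted mean
# Euclidean distance of the samples an OTU occupies to their abundance-
# weighted centroid in z-scored environment space. Large TB = the OTU
# reaches appreciable abundance across disparate environments (a putative
# habitat generalist); TB of a single-sample OTU is 0 by construction.

#' Z-score an environment table
#'
#' Standardizes each environmental variable to mean 0, sd 1 (sample sd,
#' n - 1) across all samples, so that variables measured in different units
#' contribute equally to environment-space distances.
#'
#' @param env Numeric matrix, samples in rows, variables in columns.
#' @return Matrix of the same shape with each column z-scored.
#' @export
standardize_env <- function(env) {
  validate_env_table(env)
  sds <- apply(env, 2L, stats::sd)
  if (any(sds == 0))
    stop("zero-variance environmental variable(s): ",
         paste(colnames(env)[sds == 0], collapse = ", "))
  out <- scale(env)
  attr(out, "scaled:center") <- NULL
  attr(out, "scaled:scale") <- NULL
  out
}

# Core computation shared by the scalar and vectorized entry points.
# a: abundances over occupied samples; x: their standardized environment rows.
.tb_core <- function(a, x) {
  w <- a / sum(a)
  centroid <- colSums(x * w)
  z <- sqrt(rowSums(sweep(x, 2L, centroid)^2))
  sum(w * z)
}

#' Tolerance breadth of one OTU
#'
#' The abundance-weighted mean distance of the OTU's occupied samples to
#' their abundance-weighted centroid in standardized environment space.
#' Weighting uses the OTU's read counts (equivalently its relative-abundance
#' profile: TB is invariant to any positive rescaling of the weights).
#'
#' @param counts Count matrix (OTUs x samples).
#' @param env Standardized environment matrix from [standardize_env()],
#'   covering every sample of `counts`.
#' @param otu OTU id (row name of `counts`).
#' @return Nonnegative scalar TB; 0 for an OTU occupying a single sample.
#' @export
tolerance_breadth <- function(counts, env, otu) {
  if (!otu %in% rownames(counts)) stop("unknown OTU id: ", otu)
  .check_sample_match(counts, env)
  a <- counts[otu, ]
  occ <- a > 0
  if (!any(occ)) stop("OTU '", otu, "' is absent from every sample")
  .tb_core(a[occ], env[colnames(counts)[occ], , drop = FALSE])
}

#' Tolerance breadth of every OTU in a table
#'
#' Vectorized application of [tolerance_breadth()] over all OTUs.
#'
#' @inheritParams tolerance_breadth
#' @return Data frame with columns `otu_id`, `tb`, `n_occupied` (number of
#'   samples the OTU occupies; TB is 0 and flagged when this is 1), in the
#'   OTU order of `counts`.
#' @export
tolerance_breadth_all <- function(counts, env) {
  validate_count_table(counts)
  .check_sample_match(counts, env)
  env <- env[colnames(counts), , drop = FALSE]
  tb <- numeric(nrow(counts))
  n_occ <- integer(nrow(counts))
  for (m in seq_len(nrow(counts))) {
    a <- counts[m, ]
    occ <- a > 0
    n_occ[m] <- sum(occ)
    tb[m] <- if (n_occ[m] == 0L) NA_real_
             else .tb_core(a[occ], env[occ, , drop = FALSE])
  }
  data.frame(otu_id = rownames(counts), tb = tb, n_occupied = n_occ,
             stringsAsFactors = FALSE)
}

#' Abundance-weighted environmental centroid of one OTU
#'
#' The point in standardized environment space around which the OTU's
#' occupied samples disperse; distances to it define the tolerance breadth.
#'
#' @inheritParams tolerance_breadth
#' @return Named numeric vector, one coordinate per environmental variable.
#' @export
tolerance_centroid <- function(counts, env, otu) {
  if (!otu %in% rownames(counts)) stop("unknown OTU id: ", otu)
  .check_sample_match(counts, env)
  a <- counts[otu, ]
  occ <- a > 0
  if (!any(occ)) stop("OTU '", otu, "' is absent from every sample")
  x <- env[colnames(counts)[occ], , drop = FALSE]
  colSums(x * (a[occ] / sum(a[occ])))
}

.check_sample_match <- function(counts, env) {
  cs <- colnames(counts)
  es <- rownames(env)
  if (!setequal(cs, es)) {
    only_counts <- setdiff(cs, es)
    only_env <- setdiff(es, cs)
    stop("sample ids differ between count and environment tables; ",
         "only in counts: {", paste(only_counts, collapse = ", "),
         "}; only in environment: {", paste(only_env, collapse = ", "), "}")
  }
  invisible(TRUE)
}

#' Classify putative generalists and specialists by TB quantile
#'
#' OTUs in the upper tail of the tolerance-breadth distribution are labelled
#' putative generalists, the lower tail putative specialists. At quantile
#' `q`, generalists have TB at or above the empirical `q` quantile
#' (linear-interpolation, type 7) and specialists at or below the `1 - q`
#' quantile. An OTU qualifying for both thresholds (degenerate TB
#' distribution) is labelled `"neither"`.
#'
#' @param tb Data frame from [tolerance_breadth_all()], or a named numeric
#'   vector of TB values.
#' @param quantile Quantile in (0.5, 1); conventional choices are 0.75 to
#'   0.95.
#' @return Data frame with columns `otu_id`, `tb`, `label` (one of
#'   `"generalist"`, `"specialist"`, `"neither"`), with the thresholds in
#'   attributes `tb_threshold_upper`, `tb_threshold_lower` and the quantile
#'   in attribute `quantile`.
#' @export
classify_ecotypes <- function(tb, quantile = 0.95) {
  if (length(quantile) != 1L || quantile <= 0.5 || quantile >= 1)
    stop("quantile must be a single value in (0.5, 1)")
  if (is.data.frame(tb)) {
    otu_id <- tb$otu_id
    tbv <- tb$tb
  } else {
    otu_id <- names(tb)
    tbv <- as.numeric(tb)
  }
  if (length(tbv) == 0L || all(is.na(tbv))) stop("no TB values to classify")
  upper <- stats::quantile(tbv, quantile, na.rm = TRUE, names = FALSE, type = 7)
  lower <- stats::quantile(tbv, 1 - quantile, na.rm = TRUE, names = FALSE,
                           type = 7)
  is_gen <- !is.na(tbv) & tbv >= upper
  is_spec <- !is.na(tbv) & tbv <= lower
  both <- is_gen & is_spec
  if (any(both))
    message(sum(both), " OTU(s) met both thresholds (degenerate TB ",
            "distribution); labelled 'neither'")
  label <- rep("neither", length(tbv))
  label[is_gen & !both] <- "generalist"
  label[is_spec & !both] <- "specialist"
  out <- data.frame(otu_id = otu_id, tb = tbv, label = label,
                    stringsAsFactors = FALSE)
  attr(out, "quantile") <- quantile
  attr(out, "tb_threshold_upper") <- upper
  attr(out, "tb_threshold_lower") <- lower
  out
}

#' Per-sample relative abundance of generalists and specialists
#'
#' Sums the within-sample relative abundances of the OTUs labelled
#' generalist and specialist, the quantities whose balance drives community
#' mean tolerance breadth along a richness gradient.
#'
#' @param counts Count matrix (OTUs x samples).
#' @param classification Output of [classify_ecotypes()] covering all OTUs
#'   of `counts`.
#' @return Data frame with columns `sample_id`, `generalist`, `specialist`
#'   (each in \[0, 1\], summing to at most 1 per sample).
#' @export
group_relative_abundance <- function(counts, classification) {
  rel <- to_relative_abundance(counts)
  missing <- setdiff(rownames(counts), classification$otu_id)
  if (length(missing) > 0L)
    stop("classification does not cover OTU(s): ",
         paste(utils::head(missing, 5L), collapse = ", "))
  lab <- setNames(classification$label, classification$otu_id)[rownames(rel)]
  gen <- colSums(rel[lab == "generalist", , drop = FALSE])
  spec <- colSums(rel[lab == "specialist", , drop = FALSE])
  data.frame(sample_id = colnames(rel), generalist = gen, specialist = spec,
             row.names = NULL, stringsAsFactors = FALSE)
}
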