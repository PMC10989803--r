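# Community-level indexes. Per-sample OTU selection (by cumulative
# abundance or by random draws of a fixed richness), community mean
# tolerance breadth (CMTB) and community mean response asynchrony (CMRA) at
# each selection level, min-max standardization across samples, and the
# combined resistance potential.

#' Define an OTU selection scheme
#'
#' Two ways of putting samples on a comparable footing before computing
#' community means: `"cumulative"` keeps each sample's most abundant OTUs up
#' to a fixed cumulative relative abundance (levels in (0, 1\]);
#' `"random"` draws a fixed number of the OTUs present in each sample
#' (levels are positive integer richness values), repeated `replicates`
#' times and averaged.
#'
#' @param mode `"random"` or `"cumulative"`.
#' @param levels Selection levels; defaults to `c(300, 500, 700, 900)` for
#'   random mode and `c(0.75, 0.80, 0.85, 0.90)` for cumulative mode.
#' @param replicates Random draws per sample and level (default 100 for
#'   random mode; forced to 1 for cumulative mode).
#' @param seed Master seed for the random draws; per-sample, per-level
#'   substreams are derived from it so results do not depend on iteration
#'   order.
#' @return Object of class `selection_scheme`.
#' @export
selection_scheme <- function(mode = c("random", "cumulative"), levels = NULL,
                             replicates = NULL, seed = 1L) {
  mode <- match.arg(mode)
  if (is.null(levels))
    levels <- if (mode == "random") c(300L, 500L, 700L, 900L)
              else c(0.75, 0.80, 0.85, 0.90)
  if (mode == "random") {
    if (any(levels < 1 | levels != round(levels)))
      stop("random-mode levels must be positive integers")
    if (is.null(replicates)) replicates <- 100L
  } else {
    if (any(levels <= 0 | levels > 1))
      stop("cumulative-mode levels must lie in (0, 1]")
    replicates <- 1L
  }
  if (replicates < 1 || replicates != round(replicates))
    stop("replicates must be a positive integer")
  structure(list(mode = mode, levels = levels,
                 replicates = as.integer(replicates),
                 seed = as.integer(seed)),
            class = "selection_scheme")
}

#' @export
print.selection_scheme <- function(x, ...) {
  cat("OTU selection scheme: ", x$mode, "\n",
      "  levels: ", paste(x$levels, collapse = ", "), "\n",
      "  replicates: ", x$replicates, "  seed: ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Select a sample's most abundant OTUs up to a cumulative abundance
#'
#' Ranks the OTUs of one sample by relative abundance in descending order
#' (ties broken by table order, for determinism) and returns the smallest
#' prefix whose cumulative relative abundance reaches `level`.
#'
#' @param abund Named vector of within-sample relative abundances.
#' @param level Cumulative relative abundance in (0, 1\].
#' @return Character vector of selected OTU ids.
#' @export
select_cumulative <- function(abund, level) {
  if (length(level) != 1L || level <= 0 || level > 1)
    stop("level must be a single value in (0, 1]")
  if (is.null(names(abund))) stop("abund must be a named vector")
  present <- abund[abund > 0]
  if (length(present) == 0L) stop("sample has no OTUs with positive abundance")
  ord <- order(-present, seq_along(present))
  cum <- cumsum(present[ord])
  k <- which(cum >= level - 1e-12)[1L]
  if (is.na(k)) k <- length(ord)
  names(present)[ord[seq_len(k)]]
}

#' Randomly select fixed-size OTU subsets from a sample
#'
#' Uniform draws without replacement of `n` OTUs from those present
#' (abundance > 0) in the sample, repeated `replicates` times.
#'
#' @param abund Named vector of within-sample relative abundances.
#' @param n Number of OTUs per draw.
#' @param replicates Number of draws.
#' @param seed Integer seed; the same seed reproduces the same subsets.
#' @return List of `replicates` character vectors, or `NULL` (with a
#'   warning) when the sample's richness is below `n`.
#' @export
select_random <- function(abund, n, replicates = 100L, seed = 1L) {
  if (is.null(names(abund))) stop("abund must be a named vector")
  present <- names(abund)[abund > 0]
  if (length(present) < n) {
    warning(sprintf("sample richness %d is below n = %d; excluded",
                    length(present), as.integer(n)))
    return(NULL)
  }
  set.seed(seed)
  lapply(seq_len(replicates), function(r) sample(present, n))
}

#' Community mean tolerance breadth of one sample
#'
#' The relative-abundance-weighted mean TB of the selected OTUs:
#' `sum_m a_m TB_m / sum_m a_m`. Weights are the sample's original relative
#' abundances (renormalizing over the selection would not change the ratio).
#'
#' @param abund Named vector of within-sample relative abundances.
#' @param tb Data frame from [tolerance_breadth_all()] or named numeric
#'   vector of TB values.
#' @param selected OTU ids to average over, or `NULL` for all present.
#' @return CMTB (nonnegative real, bounded by the selected OTUs' TB range).
#' @export
cmtb <- function(abund, tb, selected = NULL) {
  if (is.null(names(abund))) stop("abund must be a named vector")
  tbv <- if (is.data.frame(tb)) setNames(tb$tb, tb$otu_id) else tb
  if (is.null(selected)) selected <- names(abund)[abund > 0]
  if (length(selected) == 0L) stop("empty OTU selection")
  missing <- setdiff(selected, names(tbv))
  if (length(missing) > 0L)
    stop("TB not available for OTU(s): ",
         paste(utils::head(missing, 5L), collapse = ", "))
  a <- abund[selected]
  if (sum(a) == 0) stop("selected OTUs all have zero abundance in this sample")
  sum(a * tbv[selected]) / sum(a)
}

#' Combine standardized CMTB and CMRA into a resistance potential
#'
#' The Euclidean norm `sqrt(cmtb_stand^2 + cmra_stand^2)` of the two
#' min-max-standardized indexes; ranges over \[0, sqrt(2)\]. Communities
#' scoring high on both a broad mean tolerance and asynchronous member
#' responses are expected to tolerate environmental change best.
#'
#' @param cmtb_stand,cmra_stand Standardized index values in \[0, 1\]
#'   (vectorized).
#' @return Numeric vector of resistance potentials.
#' @export
resistance_potential <- function(cmtb_stand, cmra_stand) {
  ok <- function(x) all(is.na(x) | (x >= 0 & x <= 1))
  if (!ok(cmtb_stand) || !ok(cmra_stand))
    stop("standardized indexes must lie in [0, 1]")
  sqrt(cmtb_stand^2 + cmra_stand^2)
}

# Min-max standardization over a sample set; errors on zero range.
.minmax <- function(x, what) {
  rng <- range(x, na.rm = TRUE)
  if (!is.finite(rng[1L]) || rng[2L] - rng[1L] == 0)
    stop("cannot min-max standardize '", what,
         "': zero range across samples")
  (x - rng[1L]) / (rng[2L] - rng[1L])
}

#' Per-sample community indexes under a selection scheme
#'
#' Runs the full index pipeline: per-OTU tolerance breadths, the global RA
#' matrix, then for every sample and selection level the CMTB and CMRA
#' (averaged over replicates in random mode), min-max standardization of
#' each index across the samples of a level, and the resistance potential.
#'
#' @param counts Count matrix (OTUs x samples), typically rarefied.
#' @param env Environment matrix (samples x variables; raw scale — it is
#'   standardized internally). May be `NULL` when `tb` is supplied.
#' @param scheme A [selection_scheme()].
#' @param tb Optional precomputed [tolerance_breadth_all()] result.
#' @param ra Optional precomputed [response_asynchrony()] matrix over all
#'   OTUs of `counts`.
#' @return Data frame with one row per retained sample and level: columns
#'   `sample_id`, `scheme`, `level`, `replicates`, `richness`, `cmtb`,
#'   `cmra`, `cmtb_stand`, `cmra_stand`, `resistance`. Samples whose
#'   richness is below a random-mode level are absent from that level's
#'   rows (a warning reports them).
#' @export
compute_indices <- function(counts, env = NULL, scheme = selection_scheme(),
                            tb = NULL, ra = NULL) {
  validate_count_table(counts)
  if (!inherits(scheme, "selection_scheme"))
    stop("scheme must be created with selection_scheme()")
  if (is.null(tb)) {
    if (is.null(env)) stop("either env or a precomputed tb must be supplied")
    tb <- tolerance_breadth_all(counts, standardize_env(env))
  }
  rel <- to_relative_abundance(counts)
  if (is.null(ra)) ra <- response_asynchrony(rel)
  tbv <- setNames(tb$tb, tb$otu_id)
  rich <- richness(counts)
  samples <- colnames(counts)

  rows <- vector("list", length(scheme$levels) * length(samples))
  k <- 0L
  for (l in seq_along(scheme$levels)) {
    level <- scheme$levels[l]
    for (s in seq_along(samples)) {
      abund <- rel[, s]
      present <- rownames(rel)[abund > 0]
      if (scheme$mode == "cumulative") {
        sets <- list(select_cumulative(abund, level))
      } else {
        if (length(present) < level) next
        sub_seed <- (scheme$seed %% 1000003L) + 7919L * l + 13L * s
        sets <- select_random(abund, level, scheme$replicates, seed = sub_seed)
        if (is.null(sets)) next
      }
      union_ids <- present
      w <- matrix(0, nrow = length(union_ids), ncol = length(sets),
                  dimnames = list(union_ids, NULL))
      for (r in seq_along(sets)) w[sets[[r]], r] <- abund[sets[[r]]]
      cmtb_r <- colSums(w * tbv[union_ids]) / colSums(w)
      cmra_r <- .cmra_batch(w, ra[union_ids, union_ids])
      k <- k + 1L
      rows[[k]] <- data.frame(
        sample_id = samples[s], scheme = scheme$mode, level = level,
        replicates = length(sets), richness = unname(rich[s]),
        cmtb = mean(cmtb_r), cmra = mean(cmra_r, na.rm = TRUE),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows[seq_len(k)])
  if (is.null(out) || nrow(out) == 0L)
    stop("no sample retained at any level (richness below all random levels?)")
  dropped <- length(scheme$levels) * length(samples) - k
  if (dropped > 0L)
    warning(dropped, " sample-level combination(s) excluded ",
            "(sample richness below the requested level)")
  out <- do.call(rbind, lapply(split(out, out$level), function(d) {
    d$cmtb_stand <- .minmax(d$cmtb, "cmtb")
    d$cmra_stand <- .minmax(d$cmra, "cmra")
    d
  }))
  rownames(out) <- NULL
  out$resistance <- resistance_potential(out$cmtb_stand, out$cmra_stand)
  out
}

#' Cross-variant agreement of community indexes
#'
#' Checks that CMTB and CMRA rank samples the same way regardless of how
#' OTUs were selected: Pearson correlations between the per-sample index
#' vectors of every pair of scheme-by-level variants (pairwise-complete,
#' requiring at least 3 shared samples).
#'
#' @param indices Data frame of [compute_indices()] outputs, possibly
#'   row-bound across several schemes; must contain columns `sample_id`,
#'   `scheme`, `level`, `cmtb`, `cmra`.
#' @return List with correlation matrices `cmtb` and `cmra` (variants as
#'   `scheme:level` labels) and `min`, the minimum off-diagonal correlation
#'   of each.
#' @export
method_independence <- function(indices) {
  need <- c("sample_id", "scheme", "level", "cmtb", "cmra")
  if (!all(need %in% names(indices)))
    stop("indices must contain columns: ", paste(need, collapse = ", "))
  variant <- paste(indices$scheme, indices$level, sep = ":")
  labels <- unique(variant)
  samples <- unique(indices$sample_id)
  one <- function(col) {
    m <- matrix(NA_real_, length(samples), length(labels),
                dimnames = list(samples, labels))
    for (v in labels) {
      d <- indices[variant == v, ]
      m[d$sample_id, v] <- d[[col]]
    }
    r <- matrix(NA_real_, length(labels), length(labels),
                dimnames = list(labels, labels))
    for (i in seq_along(labels)) for (j in seq_along(labels)) {
      shared <- stats::complete.cases(m[, c(i, j)])
      if (sum(shared) >= 3L)
        r[i, j] <- stats::cor(m[shared, i], m[shared, j])
    }
    r
  }
  r_cmtb <- one("cmtb")
  r_cmra <- one("cmra")
  off_min <- function(r) {
    off <- r[row(r) != col(r)]
    if (all(is.na(off))) NA_real_ else min(off, na.rm = TRUE)
  }
  list(cmtb = r_cmtb, cmra = r_cmra,
       min = c(cmtb = off_min(r_cmtb), cmra = off_min(r_cmra)))
}
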