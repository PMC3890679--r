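# Barcode-gap analysis: intra- vs interspecific distance partitions, the
# Wilcoxon comparison between them, per-locus summary statistics, and the
# per-individual barcode gap.

#' Partition pairwise distances into intra- and interspecific sets
#'
#' Every unordered, non-missing pair lands in exactly one set: conspecific
#' pairs are intraspecific, heterospecific pairs interspecific.
#'
#' @param m a distance matrix with record ids as dimnames.
#' @param species_of named character vector mapping record id to species
#'   (see [species_map()]).
#' @return list with numeric vectors `intra` and `inter`.
#' @export
partition_distances <- function(m, species_of) {
  ids <- rownames(m)
  unlabeled <- setdiff(ids, names(species_of))
  if (length(unlabeled) > 0L) {
    stop("no species label for record '", unlabeled[[1L]], "'")
  }
  sp <- species_of[ids]
  ut <- upper.tri(m)
  same <- outer(sp, sp, "==")
  vals <- m[ut]
  keep <- !is.na(vals)
  list(intra = vals[keep & same[ut]], inter = vals[keep & !same[ut]])
}

#' Wilcoxon rank-sum test
#'
#' Compares two samples of distances. Uses the exact distribution when both
#' samples are small (min n <= 20) and untied, otherwise the normal
#' approximation with the standard tie-corrected variance.
#'
#' @param x,y numeric samples (both non-empty).
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`.
#' @return list with `statistic` (the Mann-Whitney U for `x`), `p_value` and
#'   `method` (`"exact"` or `"normal"`).
#' @export
wilcoxon_rank_sum <- function(x, y, alternative = "two.sided") {
  if (length(x) == 0L || length(y) == 0L) {
    stop("both samples must be non-empty")
  }
  exact <- min(length(x), length(y)) <= 20 && !anyDuplicated(c(x, y))
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = alternative, exact = exact)
  )
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       method = if (exact) "exact" else "normal")
}

.range_or_na <- function(v, f) if (length(v) == 0L) NA_real_ else f(v)

#' Per-locus barcode-gap summary
#'
#' Aggregates a library into one summary row: sequence counts, alignment
#' length, Tajima's K mean divergence, ranges / means / SDs / medians of the
#' inter- and intraspecific K2P distances, the Wilcoxon p-value comparing
#' them, and the optimized identification threshold (percent).
#'
#' @param lib a [reference_library()].
#' @param m optional precomputed K2P distance matrix for `lib`.
#' @param min_overlap minimum pairwise overlap in sites.
#' @param grid candidate thresholds for [optimize_threshold()].
#' @return a one-row data.frame (`gap_summary`).
#' @export
summarize_locus <- function(lib, m = NULL, min_overlap = 100,
                            grid = default_threshold_grid()) {
  if (is.null(m)) m <- build_distance_matrix(lib, "k2p", min_overlap)
  pm <- build_distance_matrix(lib, "p", min_overlap)
  sp <- species_map(lib)
  part <- partition_distances(m, sp)
  wil_p <- if (length(part$intra) > 0L && length(part$inter) > 0L) {
    wilcoxon_rank_sum(part$inter, part$intra)$p_value
  } else NA_real_
  thr <- if (length(unique(sp)) >= 2L) {
    optimize_threshold(m, sp, grid = grid)$threshold * 100
  } else NA_real_
  data.frame(
    locus = lib$locus,
    n_sequences = nrow(lib$records),
    alignment_length = lib$alignment_length,
    tajima_K = tajima_K(pm),
    inter_min = .range_or_na(part$inter, min),
    inter_max = .range_or_na(part$inter, max),
    inter_mean = .range_or_na(part$inter, mean),
    inter_sd = .range_or_na(part$inter, stats::sd),
    inter_median = .range_or_na(part$inter, stats::median),
    intra_min = .range_or_na(part$intra, min),
    intra_max = .range_or_na(part$intra, max),
    intra_mean = .range_or_na(part$intra, mean),
    intra_sd = .range_or_na(part$intra, stats::sd),
    intra_median = .range_or_na(part$intra, stats::median),
    wilcoxon_p = wil_p,
    threshold_pct = thr,
    stringsAsFactors = FALSE
  )
}

#' Per-individual barcode gap
#'
#' For each record: the furthest conspecific distance (`max_intra`), the
#' closest heterospecific distance (`min_inter`), and whether the barcode
#' gap holds (`min_inter > max_intra`). Records of singleton species have no
#' conspecifics, so `max_intra` and `has_gap` are `NA` (undefined) for them.
#' Rows are sorted by `max_intra` (undefined last), the order used for
#' gap lineplots.
#'
#' @inheritParams partition_distances
#' @return data.frame with columns `id`, `max_intra`, `min_inter`, `has_gap`.
#' @export
individual_gaps <- function(m, species_of) {
  ids <- rownames(m)
  sp <- species_of[ids]
  out <- lapply(seq_along(ids), function(i) {
    d <- m[i, -i]
    consp <- sp[-i] == sp[i]
    intra <- d[consp & !is.na(d)]
    inter <- d[!consp & !is.na(d)]
    max_intra <- .range_or_na(intra, max)
    min_inter <- .range_or_na(inter, min)
    data.frame(id = ids[i], max_intra = max_intra, min_inter = min_inter,
               has_gap = if (is.na(max_intra) || is.na(min_inter)) NA
                         else min_inter > max_intra,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out[order(out$max_intra, na.last = TRUE), , drop = FALSE]
}
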