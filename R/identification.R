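# Leave-one-out identification estimators over a distance matrix: near
# neighbour, best close match, and fixed-cutoff (BOLD-style) threshold
# identification, plus the threshold optimizer and the efficacy table.

# Per-record leave-one-out profile. Every estimator's verdict is a function
# of the focal record's minimum conspecific distance, minimum heterospecific
# distance, and the species composition of its tied nearest neighbours.
.nearest_profile <- function(m, species_of) {
  ids <- rownames(m)
  unlabeled <- setdiff(ids, names(species_of))
  if (length(unlabeled) > 0L) {
    stop("no species label for record '", unlabeled[[1L]], "'")
  }
  sp <- species_of[ids]
  if (length(unique(sp)) < 2L) stop("identification requires >= 2 species")
  out <- lapply(seq_along(ids), function(i) {
    d <- m[i, -i]
    osp <- sp[-i]
    oid <- ids[-i]
    ok <- !is.na(d)
    if (!any(ok)) {
      return(data.frame(id = ids[i], excluded = TRUE, singleton = NA,
                        min_intra = NA_real_, min_inter = NA_real_,
                        nn_dist = NA_real_, nn_id = NA_character_,
                        tie_consp = NA, tie_hetero = NA,
                        stringsAsFactors = FALSE))
    }
    d <- d[ok]; osp <- osp[ok]; oid <- oid[ok]
    consp <- osp == sp[i]
    min_intra <- if (any(consp)) min(d[consp]) else Inf
    min_inter <- if (any(!consp)) min(d[!consp]) else Inf
    nn <- min(d)
    tie <- d == nn
    nn_id <- sort(oid[tie])[1L]
    data.frame(id = ids[i], excluded = FALSE, singleton = !any(consp),
               min_intra = min_intra, min_inter = min_inter,
               nn_dist = nn, nn_id = nn_id,
               tie_consp = any(tie & consp), tie_hetero = any(tie & !consp),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

.summarize_verdicts <- function(verdicts, levels) {
  n <- as.vector(table(factor(verdicts, levels = levels)))
  data.frame(verdict = levels, n = n,
             pct = if (length(verdicts)) 100 * n / length(verdicts) else 0,
             stringsAsFactors = FALSE)
}

.id_result <- function(prof, verdicts, levels) {
  outcomes <- data.frame(id = prof$id[!prof$excluded],
                         verdict = verdicts,
                         nearest_id = prof$nn_id[!prof$excluded],
                         nearest_dist = prof$nn_dist[!prof$excluded],
                         stringsAsFactors = FALSE)
  list(outcomes = outcomes,
       summary = .summarize_verdicts(verdicts, levels),
       n_excluded = sum(prof$excluded),
       n_singletons = sum(prof$singleton, na.rm = TRUE))
}

#' Near-neighbour identification
#'
#' Leave-one-out over the library: each record's verdict is `"true"` when
#' any of its nearest non-self neighbours (all records at the minimum
#' non-missing distance) is conspecific, `"false"` otherwise. Records of
#' singleton species are necessarily false; records with only missing
#' distances are excluded and counted in `n_excluded`.
#'
#' @param m distance matrix with record ids as dimnames.
#' @param species_of named character vector, record id -> species.
#' @return list with `outcomes` (per-record data.frame), `summary`
#'   (verdict percentages), `n_excluded`, `n_singletons`.
#' @export
near_neighbour <- function(m, species_of) {
  prof <- .nearest_profile(m, species_of)
  p <- prof[!prof$excluded, , drop = FALSE]
  verdicts <- ifelse(p$tie_consp, "true", "false")
  .id_result(prof, verdicts, c("true", "false"))
}

#' Best-close-match identification
#'
#' Leave-one-out: if a record has no neighbour within `threshold` the
#' verdict is `"no_id"`; otherwise the verdict comes from its nearest
#' neighbour(s) at the minimum distance: all conspecific -> `"correct"`,
#' all heterospecific -> `"incorrect"`, mixed tie -> `"ambiguous"`.
#'
#' @inheritParams near_neighbour
#' @param threshold non-negative distance cutoff.
#' @return as [near_neighbour()], with verdict domain
#'   correct/incorrect/ambiguous/no_id.
#' @export
best_close_match <- function(m, species_of, threshold) {
  if (threshold < 0) stop("threshold must be >= 0")
  prof <- .nearest_profile(m, species_of)
  p <- prof[!prof$excluded, , drop = FALSE]
  verdicts <- ifelse(p$nn_dist > threshold, "no_id",
              ifelse(p$tie_consp & p$tie_hetero, "ambiguous",
              ifelse(p$tie_consp, "correct", "incorrect")))
  .id_result(prof, verdicts, c("correct", "incorrect", "ambiguous", "no_id"))
}

#' Fixed-cutoff (BOLD-style) threshold identification
#'
#' Leave-one-out: the verdict comes from the species composition of *all*
#' neighbours within `threshold` (default 1%): none -> `"no_id"`, all
#' conspecific -> `"correct"`, all heterospecific -> `"incorrect"`,
#' mixed -> `"ambiguous"`.
#'
#' @inheritParams best_close_match
#' @export
threshold_id <- function(m, species_of, threshold = 0.01) {
  if (threshold < 0) stop("threshold must be >= 0")
  prof <- .nearest_profile(m, species_of)
  p <- prof[!prof$excluded, , drop = FALSE]
  has_consp <- p$min_intra <= threshold
  has_hetero <- p$min_inter <= threshold
  verdicts <- ifelse(!has_consp & !has_hetero, "no_id",
              ifelse(has_consp & has_hetero, "ambiguous",
              ifelse(has_consp, "correct", "incorrect")))
  .id_result(prof, verdicts, c("correct", "incorrect", "ambiguous", "no_id"))
}

#' Default candidate threshold grid: 0.1% to 5% in 0.01% steps
#' @return numeric vector of distances.
#' @export
default_threshold_grid <- function() {
  seq(0.001, 0.05, by = 0.0001)
}

#' Optimize the identification threshold
#'
#' Scores each candidate threshold t by the cumulative identification error
#' over the library, computed from each record's barcode-gap quantities:
#' a *false negative* is a record whose furthest conspecific lies beyond t
#' (its own species' variation overflows the cutoff), a *false positive* a
#' record with at least one heterospecific within t (another species
#' intrudes). The returned threshold minimizes false negatives + false
#' positives, ties broken toward the smallest candidate; with a clean
#' barcode gap this is the smallest candidate clearing every intraspecific
#' distance. Records of singleton species have no conspecifics and cannot
#' be false negatives; they still count toward false positives.
#'
#' @inheritParams near_neighbour
#' @param grid candidate thresholds (non-empty numeric vector).
#' @return list with `threshold` (the minimizer) and `profile`, a data.frame
#'   of per-candidate `false_neg`, `false_pos` and `error` counts.
#' @export
optimize_threshold <- function(m, species_of,
                               grid = default_threshold_grid()) {
  if (length(grid) == 0L) stop("threshold grid must be non-empty")
  grid <- sort(grid)
  g <- individual_gaps(m, species_of)
  profile <- do.call(rbind, lapply(grid, function(t) {
    false_neg <- sum(g$max_intra > t, na.rm = TRUE)
    false_pos <- sum(g$min_inter <= t, na.rm = TRUE)
    data.frame(threshold = t, false_neg = false_neg, false_pos = false_pos,
               error = false_neg + false_pos)
  }))
  list(threshold = grid[which.min(profile$error)], profile = profile)
}

#' Identification efficacy table
#'
#' Runs the three estimators per locus and tabulates verdict percentages:
#' near neighbour (true/false), fixed 1% cutoff identification, and best
#' close match at the locus' threshold (the optimized threshold by default).
#' Percentages are reported at full precision (`pct`) and rounded to whole
#' numbers (`pct_int`).
#'
#' @param libs named list of [reference_library()] objects (one per locus).
#' @param ms optional named list of precomputed K2P matrices matching `libs`.
#' @param thresholds optional named numeric of best-close-match thresholds
#'   per locus; missing entries are optimized from the data.
#' @param bold_cutoff the fixed cutoff for [threshold_id()] (default 0.01).
#' @param min_overlap minimum pairwise overlap in sites.
#' @return data.frame with columns `locus`, `method`, `verdict`, `n`, `pct`,
#'   `pct_int`.
#' @export
efficacy_table <- function(libs, ms = NULL, thresholds = NULL,
                           bold_cutoff = 0.01, min_overlap = 100) {
  if (is.null(names(libs))) names(libs) <- vapply(libs, `[[`, "", "locus")
  rows <- lapply(names(libs), function(locus) {
    lib <- libs[[locus]]
    m <- if (!is.null(ms) && !is.null(ms[[locus]])) ms[[locus]] else
      build_distance_matrix(lib, "k2p", min_overlap)
    sp <- species_map(lib)
    thr <- if (!is.null(thresholds) && !is.na(thresholds[locus])) {
      unname(thresholds[locus])
    } else {
      optimize_threshold(m, sp)$threshold
    }
    res <- list(
      near_neighbour = near_neighbour(m, sp),
      threshold_id = threshold_id(m, sp, bold_cutoff),
      best_close_match = best_close_match(m, sp, thr)
    )
    do.call(rbind, lapply(names(res), function(method) {
      s <- res[[method]]$summary
      data.frame(locus = locus, method = method, verdict = s$verdict,
                 n = s$n, pct = s$pct, pct_int = round(s$pct),
                 stringsAsFactors = FALSE)
    }))
  })
  do.call(rbind, rows)
}
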