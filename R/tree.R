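# Neighbour-joining trees with column bootstrap and query-placement
# annotation: a deterministic distance-tree check of where unknown samples
# fall relative to the reference species.

#' Build a neighbour-joining tree from a distance matrix
#'
#' Labels are sorted lexicographically before agglomeration so the result
#' is deterministic and independent of input record order. The matrix must
#' be complete: missing entries (insufficient overlap or saturation) must
#' be imputed or their records removed first.
#'
#' @param m a complete square distance matrix with ids as dimnames, n >= 3.
#' @return an unrooted `phylo` tree (tips = record ids).
#' @export
nj_build <- function(m) {
  if (nrow(m) < 3L) stop("neighbour joining requires at least 3 records")
  if (anyNA(m)) {
    bad <- which(is.na(m), arr.ind = TRUE)[1L, ]
    stop("distance matrix has missing entries (e.g. ",
         rownames(m)[bad[1L]], " vs ", colnames(m)[bad[2L]],
         "); impute them or remove the affected records before ",
         "tree building", call. = FALSE)
  }
  ord <- order(rownames(m))
  ape::nj(stats::as.dist(m[ord, ord]))
}

#' Neighbour-joining tree with column-bootstrap support
#'
#' Resamples alignment columns with replacement, rebuilds the distance
#' matrix and NJ tree per replicate, and scores each internal edge of the
#' original tree by the percentage of replicates containing the same
#' bipartition. Replicate r uses `seed + r`, so any single replicate can be
#' reproduced in isolation.
#'
#' @param lib a [reference_library()].
#' @param n_reps number of bootstrap replicates (>= 1).
#' @param seed master RNG seed.
#' @param model distance model passed to [build_distance_matrix()].
#' @param min_overlap minimum pairwise overlap in sites.
#' @return the original NJ tree with `node.label` set to integer support
#'   percentages in \[0, 100\].
#' @export
bootstrap_support <- function(lib, n_reps, seed = 1, model = "k2p",
                              min_overlap = 100) {
  if (n_reps < 1L) stop("n_reps must be >= 1")
  m <- build_distance_matrix(lib, model, min_overlap)
  tree <- nj_build(m)
  L <- lib$alignment_length
  chm <- .char_matrix(lib)
  boot_trees <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    set.seed(seed + r)
    cols <- sample.int(L, L, replace = TRUE)
    bm <- .dist_from_chm(chm[, cols, drop = FALSE], model, min_overlap)
    if (anyNA(bm)) next  # resampled overlap fell below the floor; skip
    boot_trees[[r]] <- nj_build(bm)
  }
  boot_trees <- boot_trees[!vapply(boot_trees, is.null, TRUE)]
  counts <- ape::prop.clades(tree, boot_trees, rooted = FALSE)
  counts[is.na(counts)] <- 0
  tree$node.label <- round(100 * counts / n_reps)
  tree
}

#' Classify a bootstrap support value
#'
#' Conventional bands: 50-74 weak support, 75-100 strong support, below 50
#' unsupported.
#'
#' @param support numeric support percentage(s) in \[0, 100\].
#' @return character vector in `{"unsupported", "weak", "strong"}`.
#' @export
support_class <- function(support) {
  ifelse(support >= 75, "strong", ifelse(support >= 50, "weak", "unsupported"))
}

#' Report where query tips fall on a tree
#'
#' For each query tip: its sister-group species set (the species of the
#' reference tips in its sibling subtree after midpoint rooting) and the
#' bootstrap support of the smallest clade containing the query and at
#' least one reference tip. A query is `placed_with` a species when its
#' sister set is monospecific; a multi-species sister set is flagged
#' unresolved.
#'
#' @param tree a `phylo` tree, typically from [bootstrap_support()].
#' @param query_ids tip labels of the query records.
#' @param species_of named character vector, reference record id -> species.
#' @return data.frame with columns `query`, `sister_species`
#'   (semicolon-collapsed), `support`, `placed_with`, `resolved`.
#' @export
annotate_queries <- function(tree, query_ids, species_of) {
  absent <- setdiff(query_ids, tree$tip.label)
  if (length(absent) > 0L) {
    stop("query id '", absent[[1L]], "' is not a tip of the tree")
  }
  if (length(query_ids) == 0L) {
    return(data.frame(query = character(), sister_species = character(),
                      support = numeric(), placed_with = character(),
                      resolved = logical(), stringsAsFactors = FALSE))
  }
  has_support <- !is.null(tree$node.label)
  rooted <- phangorn::midpoint(tree,
                               node.labels = if (has_support) "support"
                                             else "deleted")
  ntip <- length(rooted$tip.label)
  rows <- lapply(query_ids, function(q) {
    tip <- match(q, rooted$tip.label)
    node <- tip
    repeat {
      parent <- rooted$edge[rooted$edge[, 2] == node, 1]
      clade_tips <- rooted$tip.label[
        phangorn::Descendants(rooted, parent, "tips")[[1L]]]
      sisters <- setdiff(clade_tips, q)
      ref_sisters <- intersect(sisters, names(species_of))
      if (length(ref_sisters) > 0L || parent == ntip + 1L) break
      node <- parent  # sibling subtree was all queries; widen the clade
    }
    spp <- sort(unique(species_of[ref_sisters]))
    support <- if (has_support) {
      as.numeric(rooted$node.label[parent - ntip])
    } else NA_real_
    data.frame(query = q,
               sister_species = paste(spp, collapse = ";"),
               support = support,
               placed_with = if (length(spp) == 1L) spp else NA_character_,
               resolved = length(spp) == 1L,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
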