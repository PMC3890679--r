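# Independent brute-force oracles and small fixture builders shared across
# test files. The oracles deliberately use naive per-row scans and full
# enumeration, never the package's vectorized code paths.

# A tiny two-species library with clean separation, built in code.
toy_library <- function() {
  base <- paste(rep("ACGT", 50), collapse = "")  # 200 bp
  mutate_at <- function(s, pos, to) {
    ch <- strsplit(s, "")[[1]]
    ch[pos] <- to
    paste(ch, collapse = "")
  }
  reference_library(
    ids = c("a1", "a2", "b1", "b2"),
    sequences = c(base,
                  mutate_at(base, 1, "G"),
                  mutate_at(base, seq(2, 40, by = 2), "A"),
                  mutate_at(base, c(seq(2, 40, by = 2), 3), c(rep("A", 20), "T"))),
    species = c("A", "A", "B", "B"),
    locus = "rbcLa"
  )
}

# Random symmetric distance matrix with zero diagonal; optional ties
# (rounding) and missing entries.
random_distance_matrix <- function(n, tie_digits = NULL, na_frac = 0) {
  ids <- sprintf("r%02d", seq_len(n))
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  vals <- runif(n * (n - 1) / 2, 0, 0.2)
  if (!is.null(tie_digits)) vals <- round(vals, tie_digits)
  d[upper.tri(d)] <- vals
  d <- d + t(d)
  if (na_frac > 0) {
    ut <- which(upper.tri(d))
    drop <- sample(ut, floor(na_frac * length(ut)))
    d[drop] <- NA
    d <- t(d)
    d[drop] <- NA
    d <- t(d)
  }
  d
}

random_species_map <- function(m, n_species) {
  ids <- rownames(m)
  setNames(sprintf("sp%02d", sample.int(n_species, length(ids),
                                        replace = TRUE)), ids)
}

# Naive leave-one-out scans -------------------------------------------------

oracle_near_neighbour <- function(m, species_of) {
  ids <- rownames(m)
  sapply(ids, function(id) {
    d <- m[id, setdiff(ids, id)]
    d <- d[!is.na(d)]
    if (length(d) == 0) return(NA_character_)
    nn_ids <- names(d)[d == min(d)]
    if (any(species_of[nn_ids] == species_of[id])) "true" else "false"
  })
}

oracle_best_close_match <- function(m, species_of, threshold) {
  ids <- rownames(m)
  sapply(ids, function(id) {
    d <- m[id, setdiff(ids, id)]
    d <- d[!is.na(d)]
    if (length(d) == 0) return(NA_character_)
    if (min(d) > threshold) return("no_id")
    nn_sp <- unique(species_of[names(d)[d == min(d)]])
    consp <- species_of[id] %in% nn_sp
    hetero <- any(nn_sp != species_of[id])
    if (consp && hetero) "ambiguous" else if (consp) "correct" else "incorrect"
  })
}

oracle_threshold_id <- function(m, species_of, threshold) {
  ids <- rownames(m)
  sapply(ids, function(id) {
    d <- m[id, setdiff(ids, id)]
    d <- d[!is.na(d)]
    if (length(d) == 0) return(NA_character_)
    within <- names(d)[d <= threshold]
    if (length(within) == 0) return("no_id")
    sp <- unique(species_of[within])
    consp <- species_of[id] %in% sp
    hetero <- any(sp != species_of[id])
    if (consp && hetero) "ambiguous" else if (consp) "correct" else "incorrect"
  })
}

# Exact Wilcoxon rank-sum p-value by full enumeration of all C(n1+n2, n1)
# group assignments of the pooled sample (untied data).
oracle_wilcoxon_p <- function(x, y, alternative = "two.sided") {
  pooled <- c(x, y)
  r <- rank(pooled)
  n1 <- length(x)
  u_of <- function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2
  u_obs <- u_of(seq_len(n1))
  all_u <- apply(utils::combn(length(pooled), n1), 2, u_of)
  pl <- mean(all_u <= u_obs)
  pg <- mean(all_u >= u_obs)
  switch(alternative,
         less = pl,
         greater = pg,
         two.sided = min(1, 2 * min(pl, pg)))
}

# Support of the bipartition isolating `tips`, read off the tree after
# rooting at an outside tip (edge labels follow the rerooting).
clade_support <- function(tree, tips) {
  out <- setdiff(tree$tip.label, tips)[1]
  rooted <- ape::root(ape::as.phylo(tree), outgroup = out,
                      resolve.root = TRUE, edgelabel = TRUE)
  if (!ape::is.monophyletic(rooted, tips)) return(NA_real_)
  node <- ape::getMRCA(rooted, tips)
  as.numeric(rooted$node.label[node - length(rooted$tip.label)])
}
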