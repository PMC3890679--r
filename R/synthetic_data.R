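# Synthetic reference libraries, degraded queries, and vernacular lookups
# with the statistical structure the analysis assumes: species radiating
# from a star phylogeny under a two-parameter (transition/transversion)
# substitution process, shallow within-species divergence, and market-style
# query degradation with known ground truth.

#' Configuration for the synthetic-library generator
#'
#' The generator emulates a barcoding reference library: `n_species`
#' species ancestors radiate from a random root on a star phylogeny, each
#' ancestor at expected K2P distance `inter_target / 2` from the root, and
#' each individual at expected K2P distance `intra_target / 2` from its
#' species ancestor — so conspecific pairs diverge by about `intra_target`
#' and heterospecific pairs by about `inter_target`. Substitutions follow
#' the Kimura two-parameter process with transition/transversion rate ratio
#' `kappa`.
#'
#' @param n_species number of species.
#' @param individuals individuals per species: a single count, or a
#'   length-2 range sampled uniformly per species.
#' @param seq_length alignment length in bp.
#' @param inter_target expected K2P distance between heterospecific
#'   individuals.
#' @param intra_target expected K2P distance between conspecific
#'   individuals (must be < `inter_target`).
#' @param kappa transition/transversion rate ratio (> 0).
#' @param seed RNG seed; the generator is deterministic given the seed.
#' @param locus locus label for generated libraries.
#' @param truncate_frac,n_mask_frac,mislabel_rate default degradation and
#'   mislabelling fractions (in \[0, 1\]) used by the query generator.
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(n_species = 108, individuals = c(1, 3),
                             seq_length = 600, inter_target = 0.10,
                             intra_target = 0.003, kappa = 2.0, seed = 1,
                             locus = "rbcLa", truncate_frac = 0,
                             n_mask_frac = 0, mislabel_rate = 0) {
  if (intra_target < 0 || intra_target >= inter_target) {
    stop("need 0 <= intra_target < inter_target")
  }
  if (kappa <= 0) stop("kappa must be > 0")
  fracs <- c(truncate_frac, n_mask_frac, mislabel_rate)
  if (any(fracs < 0 | fracs > 1)) stop("fractions must lie in [0, 1]")
  structure(
    list(n_species = n_species, individuals = individuals,
         seq_length = seq_length, inter_target = inter_target,
         intra_target = intra_target, kappa = kappa, seed = seed,
         locus = locus, truncate_frac = truncate_frac,
         n_mask_frac = n_mask_frac, mislabel_rate = mislabel_rate),
    class = "synthetic_config"
  )
}

# Evolve an integer-coded sequence (1=A, 2=C, 3=G, 4=T) along a branch of
# expected K2P length d under the K80 process with ts/tv rate ratio kappa.
.k80_evolve <- function(x, d, kappa) {
  if (d <= 0) return(x)
  bt <- d / (kappa + 2)
  at <- kappa * bt
  e1 <- exp(-4 * bt)
  e2 <- exp(-2 * (at + bt))
  p_same <- 0.25 + 0.25 * e1 + 0.5 * e2
  p_ts <- 0.25 + 0.25 * e1 - 0.5 * e2
  ts_partner <- c(3L, 4L, 1L, 2L)          # A<->G, C<->T
  tv_first <- c(2L, 1L, 2L, 1L)            # one transversion target
  tv_second <- c(4L, 3L, 4L, 3L)           # the other
  u <- stats::runif(length(x))
  pick <- stats::runif(length(x)) < 0.5
  out <- x
  is_ts <- u >= p_same & u < p_same + p_ts
  is_tv <- u >= p_same + p_ts
  out[is_ts] <- ts_partner[x[is_ts]]
  out[is_tv & pick] <- tv_first[x[is_tv & pick]]
  out[is_tv & !pick] <- tv_second[x[is_tv & !pick]]
  out
}

.int2dna <- function(x) paste(c("A", "C", "G", "T")[x], collapse = "")

#' Generate a synthetic reference library with ground truth
#'
#' See [synthetic_config()] for the generating model. Given the same
#' configuration (including seed), output is byte-identical across runs.
#'
#' @param cfg a [synthetic_config()].
#' @param n_individuals optional integer vector fixing the number of
#'   individuals per species (used to share one sampling structure across
#'   loci); drawn from `cfg$individuals` when `NULL`.
#' @return list with `library` (a [reference_library()]) and `truth`
#'   (data.frame `id`, `species`).
#' @export
generate_library <- function(cfg, n_individuals = NULL) {
  set.seed(cfg$seed)
  if (is.null(n_individuals)) {
    n_individuals <- if (length(cfg$individuals) == 2L) {
      sample(cfg$individuals[1]:cfg$individuals[2], cfg$n_species,
             replace = TRUE)
    } else rep_len(cfg$individuals, cfg$n_species)
  }
  root <- sample.int(4L, cfg$seq_length, replace = TRUE)
  ids <- character(0)
  species <- character(0)
  seqs <- character(0)
  for (s in seq_len(cfg$n_species)) {
    anc <- .k80_evolve(root, cfg$inter_target / 2, cfg$kappa)
    sp_name <- sprintf("species_%03d", s)
    for (i in seq_len(n_individuals[s])) {
      ind <- .k80_evolve(anc, cfg$intra_target / 2, cfg$kappa)
      ids <- c(ids, sprintf("sp%03d_i%d", s, i))
      species <- c(species, sp_name)
      seqs <- c(seqs, .int2dna(ind))
    }
  }
  lib <- reference_library(ids, seqs, species, cfg$locus)
  list(library = lib,
       truth = data.frame(id = ids, species = species,
                          stringsAsFactors = FALSE))
}

#' Generate libraries for several loci over one sampling structure
#'
#' Draws the individuals-per-species structure once, then generates each
#' locus independently (per-locus seed = `seed` + locus index), so records
#' share ids across loci and the loci can be concatenated.
#'
#' @param cfgs named list of [synthetic_config()] objects (one per locus),
#'   all with the same `n_species`.
#' @param seed master seed for the structure and per-locus generation.
#' @return list with `libraries` (named list) and `truth`.
#' @export
generate_study <- function(cfgs, seed = 1) {
  n_sp <- unique(vapply(cfgs, `[[`, 0, "n_species"))
  if (length(n_sp) != 1L) stop("all loci must share n_species")
  set.seed(seed)
  ind_cfg <- cfgs[[1L]]$individuals
  n_individuals <- if (length(ind_cfg) == 2L) {
    sample(ind_cfg[1]:ind_cfg[2], n_sp, replace = TRUE)
  } else rep_len(ind_cfg, n_sp)
  libraries <- list()
  truth <- NULL
  for (k in seq_along(cfgs)) {
    cfg <- cfgs[[k]]
    cfg$seed <- seed + k
    gen <- generate_library(cfg, n_individuals = n_individuals)
    libraries[[names(cfgs)[k]]] <- gen$library
    truth <- gen$truth
  }
  list(libraries = libraries, truth = truth)
}

#' Degrade a record into a market-style query
#'
#' Emulates processed or poorly preserved material: a contiguous terminal
#' fraction of the alignment is lost (replaced by gaps, preserving
#' coordinates) and a fraction of the surviving bases is masked to 'N'. If
#' fewer than `min_bases` bases survive truncation the query is marked as
#' an amplification failure (`NA` sequence). The returned record has
#' `source = "query"` and species `"UNKNOWN"`; ground truth stays with the
#' caller.
#'
#' @param record a one-row data.frame from a library's `records`.
#' @param truncate_frac fraction of alignment columns removed from the 3'
#'   end.
#' @param n_mask_frac fraction of surviving bases masked to 'N'.
#' @param seed optional RNG seed (omit when the caller manages the RNG).
#' @param id id for the query record (default: derived from the source id).
#' @param min_bases minimum surviving bases for a usable sequence.
#' @return one-row query record data.frame; `sequence` is `NA` on failure.
#' @export
degrade_query <- function(record, truncate_frac = 0, n_mask_frac = 0,
                          seed = NULL, id = NULL, min_bases = 50) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(id)) id <- paste0(record$id, "_q")
  chars <- strsplit(record$sequence, "")[[1L]]
  L <- length(chars)
  n_cut <- floor(truncate_frac * L)
  if (n_cut > 0) chars[(L - n_cut + 1L):L] <- "-"
  base_pos <- which(chars %in% c("A", "C", "G", "T"))
  failed <- length(base_pos) < min_bases
  if (!failed && n_mask_frac > 0) {
    n_mask <- floor(n_mask_frac * length(base_pos))
    if (n_mask > 0) {
      chars[sample(base_pos, n_mask)] <- "N"
    }
  }
  data.frame(id = id, species = "UNKNOWN", vernacular = NA_character_,
             source = "query", status = NA_character_,
             sequence = if (failed) NA_character_ else
               paste(chars, collapse = ""),
             stringsAsFactors = FALSE)
}

#' Sample and degrade a panel of queries from a library
#'
#' Samples `n_queries` records (without replacement when possible),
#' degrades each with [degrade_query()], and forces `n_fail` of them to
#' amplification failure by near-total truncation.
#'
#' @param lib a [reference_library()].
#' @param n_queries number of queries to draw.
#' @param truncate_frac,n_mask_frac degradation applied to ordinary queries.
#' @param n_fail number of queries forced to fail.
#' @param seed RNG seed.
#' @return list with `queries` (query records data.frame) and `truth`
#'   (data.frame `query_id`, `source_id`, `true_species`, `failed`).
#' @export
generate_queries <- function(lib, n_queries = 18, truncate_frac = 0,
                             n_mask_frac = 0, n_fail = 0, seed = 1) {
  set.seed(seed)
  n <- nrow(lib$records)
  pick <- sample.int(n, n_queries, replace = n_queries > n)
  fail_idx <- if (n_fail > 0) sample.int(n_queries, n_fail) else integer(0)
  queries <- NULL
  truth <- NULL
  for (i in seq_len(n_queries)) {
    rec <- lib$records[pick[i], , drop = FALSE]
    tf <- if (i %in% fail_idx) 0.999 else truncate_frac
    q <- degrade_query(rec, truncate_frac = tf, n_mask_frac = n_mask_frac,
                       id = sprintf("query_%02d", i))
    queries <- rbind(queries, q)
    truth <- rbind(truth, data.frame(
      query_id = q$id, source_id = rec$id, true_species = rec$species,
      failed = is.na(q$sequence), stringsAsFactors = FALSE))
  }
  list(queries = queries, truth = truth)
}

#' Generate a vernacular lookup and query name assignments
#'
#' Invents one vernacular name per species and assigns each query the
#' vernacular of its true species, except for a `mislabel_rate` fraction
#' (rounded to a whole number of queries, drawn among the queries that
#' yielded sequence) reassigned to a random other species' vernacular —
#' emulating market samples sold under names that do not match the material.
#'
#' @param query_truth the `truth` data.frame from [generate_queries()].
#' @param species_pool species to include in the lookup (defaults to the
#'   species appearing in `query_truth`).
#' @param mislabel_rate fraction of (sequenced) queries to mislabel.
#' @param seed RNG seed.
#' @return list with `lookup` (a [vernacular_lookup()]) and `assignments`
#'   (data.frame `query_id`, `vernacular`, `mislabeled`).
#' @export
generate_lookup <- function(query_truth, species_pool = NULL,
                            mislabel_rate = 0, seed = 1) {
  set.seed(seed)
  if (is.null(species_pool)) species_pool <- unique(query_truth$true_species)
  species_pool <- sort(unique(species_pool))
  vern_of <- stats::setNames(paste0("vern_", species_pool), species_pool)
  lookup <- vernacular_lookup(unname(vern_of), species_pool)
  n <- nrow(query_truth)
  n_mis <- round(mislabel_rate * n)
  eligible <- which(!query_truth$failed)
  mis_idx <- if (n_mis > 0) sample(eligible, min(n_mis, length(eligible)))
             else integer(0)
  vern <- vern_of[query_truth$true_species]
  for (i in mis_idx) {
    other <- setdiff(species_pool, query_truth$true_species[i])
    vern[i] <- vern_of[sample(other, 1L)]
  }
  list(lookup = lookup,
       assignments = data.frame(query_id = query_truth$query_id,
                                vernacular = unname(vern),
                                mislabeled = seq_len(n) %in% mis_idx,
                                stringsAsFactors = FALSE))
}
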