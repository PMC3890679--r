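# End-to-end orchestration: simulate or ingest reference libraries, compute
# distances, barcode-gap summaries, optimized thresholds, identification
# efficacy, the market query report, and the bootstrapped NJ tree, writing
# the standard report tables.

#' Build a pipeline run configuration
#'
#' The default configuration emulates a medicinal-plant barcoding study:
#' 108 species with 1-3 individuals each over two plastid loci — rbcLa
#' (552 bp, mean interspecific K2P about 0.08, intraspecific about 0.0002)
#' and matK (915 bp, about 0.22 / 0.0008) — plus 18 degraded market
#' queries of which 2 fail amplification and 5 are sold under a vernacular
#' name that does not match the material.
#'
#' @param seed master RNG seed; every stage derives its seed from it.
#' @param loci named list of [synthetic_config()] objects (ignored when
#'   `inputs` is supplied).
#' @param inputs optional named list of real input paths:
#'   `fasta`/`metadata` per locus under `$loci`, plus optional
#'   `queries_fasta`, `queries_metadata` and `lookup`.
#' @param n_queries,n_fail,query_truncate,query_mask,mislabel_rate synthetic
#'   market-query panel parameters.
#' @param query_locus locus queried against and used for the tree.
#' @param model distance model, `"k2p"` or `"p"`.
#' @param min_overlap minimum pairwise overlap in sites.
#' @param min_identity percent-identity floor for query hits.
#' @param bootstrap_reps bootstrap replicates for the tree stage.
#' @return a `run_config` list, serializable to JSON.
#' @export
run_config <- function(seed = 1,
                       loci = list(
                         rbcLa = synthetic_config(
                           n_species = 108, individuals = c(1, 3),
                           seq_length = 552, inter_target = 0.08,
                           intra_target = 0.0002, locus = "rbcLa"),
                         matK = synthetic_config(
                           n_species = 108, individuals = c(1, 3),
                           seq_length = 915, inter_target = 0.22,
                           intra_target = 0.0008, locus = "matK")),
                       inputs = NULL,
                       n_queries = 18, n_fail = 2,
                       query_truncate = 0.3, query_mask = 0.02,
                       mislabel_rate = 5 / 18,
                       query_locus = "matK",
                       model = "k2p", min_overlap = 100, min_identity = 90,
                       bootstrap_reps = 100) {
  structure(
    list(seed = seed, loci = loci, inputs = inputs, n_queries = n_queries,
         n_fail = n_fail, query_truncate = query_truncate,
         query_mask = query_mask, mislabel_rate = mislabel_rate,
         query_locus = query_locus, model = model,
         min_overlap = min_overlap, min_identity = min_identity,
         bootstrap_reps = bootstrap_reps),
    class = "run_config"
  )
}

#' Write / read a run configuration as JSON
#' @param cfg a [run_config()].
#' @param path file path.
#' @export
write_run_config <- function(cfg, path) {
  raw <- unclass(cfg)
  raw$loci <- lapply(raw$loci, unclass)
  jsonlite::write_json(raw, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(cfg)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$loci <- lapply(raw$loci, function(l) do.call(synthetic_config, l))
  do.call(run_config, raw)
}

.stage <- function(log, name, expr) {
  log(paste0("INFO stage ", name, ": start"))
  out <- tryCatch(expr, error = function(e) {
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
  })
  log(paste0("INFO stage ", name, ": done"))
  out
}

.table2_wide <- function(eff) {
  wide <- lapply(split(eff, eff$locus), function(g) {
    row <- stats::setNames(as.list(g$pct_int),
                           paste(g$method, g$verdict, sep = "_"))
    cbind(data.frame(locus = g$locus[[1L]], stringsAsFactors = FALSE),
          as.data.frame(row))
  })
  do.call(rbind, wide)
}

#' Run the full barcoding analysis pipeline
#'
#' Simulates (or ingests) the per-locus reference libraries, concatenates
#' them, and writes to `out_dir`: `table1.tsv` (per-locus gap summary),
#' `table2.tsv` (identification efficacy, integer percentages; full
#' precision in `table2.json`), `table3.tsv` (market query report),
#' `gaps.tsv` (per-individual barcode gap), `tree.nwk` (bootstrapped NJ
#' tree with query placements in `placements.tsv`), `run.log`, and the
#' resolved `run_config.json`. The run is a pure function of the
#' configuration: same config, same bytes.
#'
#' @param cfg a [run_config()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with the in-memory results.
#' @export
run_pipeline <- function(cfg, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0)
  log <- function(msg) log_lines <<- c(log_lines, msg)

  libs <- .stage(log, "ingest", {
    if (!is.null(cfg$inputs)) {
      ll <- lapply(names(cfg$inputs$loci), function(locus) {
        p <- cfg$inputs$loci[[locus]]
        read_alignment(p$fasta, p$metadata, locus)
      })
      names(ll) <- names(cfg$inputs$loci)
      ll
    } else {
      generate_study(cfg$loci, seed = cfg$seed)$libraries
    }
  })
  if (length(libs) >= 2L) {
    libs$combined <- .stage(log, "concatenate",
                            concatenate(libs[[1L]], libs[[2L]]))
  }

  mats <- .stage(log, "distances", {
    lapply(libs, build_distance_matrix, model = cfg$model,
           min_overlap = cfg$min_overlap)
  })

  table1 <- .stage(log, "gap_analysis", {
    do.call(rbind, lapply(names(libs), function(l) {
      summarize_locus(libs[[l]], mats[[l]], min_overlap = cfg$min_overlap)
    }))
  })
  gaps <- .stage(log, "individual_gaps", {
    do.call(rbind, lapply(names(libs), function(l) {
      g <- individual_gaps(mats[[l]], species_map(libs[[l]]))
      cbind(locus = l, g)
    }))
  })

  eff <- .stage(log, "identification", {
    thr <- stats::setNames(table1$threshold_pct / 100, table1$locus)
    efficacy_table(libs, mats, thresholds = thr,
                   min_overlap = cfg$min_overlap)
  })

  qlib <- libs[[cfg$query_locus]]
  market <- .stage(log, "market_id", {
    if (!is.null(cfg$inputs)) {
      if (is.null(cfg$inputs$queries_fasta)) return(NULL)
      queries <- read_alignment(cfg$inputs$queries_fasta,
                                cfg$inputs$queries_metadata,
                                cfg$query_locus)$records
      lookup <- read_lookup(cfg$inputs$lookup)
      list(report = market_report(queries, qlib, lookup, cfg$min_identity),
           queries = queries)
    } else {
      qs <- generate_queries(qlib, n_queries = cfg$n_queries,
                             truncate_frac = cfg$query_truncate,
                             n_mask_frac = cfg$query_mask,
                             n_fail = cfg$n_fail, seed = cfg$seed + 101)
      lk <- generate_lookup(qs$truth,
                            species_pool = unique(qlib$records$species),
                            mislabel_rate = cfg$mislabel_rate,
                            seed = cfg$seed + 102)
      qs$queries$vernacular <- lk$assignments$vernacular
      list(report = market_report(qs$queries, qlib, lk$lookup,
                                  cfg$min_identity),
           queries = qs$queries, truth = qs$truth,
           assignments = lk$assignments)
    }
  })

  tree_res <- .stage(log, "tree", {
    tips <- qlib$records
    if (!is.null(market) && !is.null(market$queries)) {
      qrec <- market$queries[!is.na(market$queries$sequence), , drop = FALSE]
      tips <- rbind(tips, qrec[, names(tips)])
    }
    tlib <- reference_library(tips$id, tips$sequence, tips$species,
                              qlib$locus, vernacular = tips$vernacular,
                              source = tips$source, status = tips$status)
    tr <- bootstrap_support(tlib, n_reps = cfg$bootstrap_reps,
                            seed = cfg$seed + 201, model = cfg$model,
                            min_overlap = cfg$min_overlap)
    qids <- tips$id[tips$source == "query"]
    list(tree = tr,
         placements = annotate_queries(tr, qids, species_map(qlib)))
  })

  tsv <- function(x, f) utils::write.table(
    x, file.path(out_dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  tsv(table1, "table1.tsv")
  tsv(.table2_wide(eff), "table2.tsv")
  jsonlite::write_json(eff, file.path(out_dir, "table2.json"),
                       digits = NA, pretty = TRUE)
  if (!is.null(market)) {
    write_market_report(market$report, file.path(out_dir, "table3.tsv"))
  }
  tsv(gaps, "gaps.tsv")
  ape::write.tree(tree_res$tree, file.path(out_dir, "tree.nwk"))
  tsv(tree_res$placements, "placements.tsv")
  write_run_config(cfg, file.path(out_dir, "run_config.json"))
  n_singleton <- sum(table(libs[[1L]]$records$species) == 1L)
  log(paste0("WARN ", n_singleton, " singleton species in ",
             names(libs)[[1L]]))
  writeLines(log_lines, file.path(out_dir, "run.log"))

  invisible(list(libraries = libs, matrices = mats, table1 = table1,
                 efficacy = eff, market = market, gaps = gaps,
                 tree = tree_res$tree, placements = tree_res$placements))
}
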