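# BLAST-style assignment of degraded query sequences against the reference
# library: semi-global percent identity, hit ranking, adjudication against
# vernacular-name expectations, and market-report bookkeeping.

#' Semi-global percent identity between a query and a reference
#'
#' Needleman-Wunsch alignment with free end gaps (match +1, mismatch -1,
#' gap -2, terminal overhangs free), the local stand-in for a BLAST search
#' of a short or truncated query against a full-length reference. Gap
#' characters are stripped from both inputs first. Percent identity is
#' 100 * matches / aligned columns, terminal overhangs excluded.
#'
#' @param query,ref sequence strings (aligned or not; gaps ignored).
#' @return list with `percent_identity` in \[0, 100\] and `aligned_sites`
#'   (aligned columns, gaps included).
#' @export
semiglobal_identity <- function(query, ref) {
  q <- gsub("-", "", normalize_sequence(query), fixed = TRUE)
  r <- gsub("-", "", normalize_sequence(ref), fixed = TRUE)
  if (!nzchar(q) || !nzchar(r)) stop("empty sequence")
  sub_mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = 1, mismatch = -1, baseOnly = FALSE, type = "DNA")
  aln <- Biostrings::pairwiseAlignment(
    q, r, type = "overlap", substitutionMatrix = sub_mat,
    gapOpening = 0, gapExtension = 2)
  ncols <- nchar(as.character(Biostrings::pattern(aln)))
  list(percent_identity = Biostrings::pid(aln, type = "PID1"),
       aligned_sites = ncols)
}

#' Rank reference hits for a query sequence
#'
#' Scores the query against every reference record, drops hits below
#' `min_identity`, and sorts by percent identity (descending), then aligned
#' sites (descending), then hit id (lexicographic). An empty result means
#' no hit.
#'
#' @param query a query sequence string.
#' @param lib a [reference_library()].
#' @param min_identity minimum percent identity to report (default 90).
#' @return data.frame with columns `hit_id`, `hit_species`,
#'   `percent_identity`, `aligned_sites`.
#' @export
rank_hits <- function(query, lib, min_identity = 90) {
  rec <- lib$records
  scores <- lapply(rec$sequence, function(s) semiglobal_identity(query, s))
  out <- data.frame(
    hit_id = rec$id,
    hit_species = rec$species,
    percent_identity = vapply(scores, `[[`, 0, "percent_identity"),
    aligned_sites = vapply(scores, `[[`, 0L, "aligned_sites"),
    stringsAsFactors = FALSE
  )
  out <- out[out$percent_identity >= min_identity, , drop = FALSE]
  out <- out[order(-out$percent_identity, -out$aligned_sites, out$hit_id), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Adjudicate a query's hits against its vernacular-name expectation
#'
#' Looks the query's vernacular up in the lookup table and compares the
#' best-hit species with the expected species (exact match against any
#' listed synonym). Status values: `match`, `mismatch`,
#' `mismatch_unverifiable` (the vernacular has no known scientific name, so
#' the claim cannot be checked), `no_hit` (no reference within the identity
#' floor), and `amplification_failed` (the query yielded no sequence, i.e.
#' `hits = NULL`).
#'
#' @param query_id query identifier.
#' @param vernacular the vernacular name supplied with the query.
#' @param hits a data.frame from [rank_hits()], possibly empty; `NULL` for a
#'   query with no sequence.
#' @param lookup a [vernacular_lookup()].
#' @param status_iucn optional conservation status carried through to the
#'   report.
#' @return one-row data.frame (market-report shape): `query`, `vernacular`,
#'   `expected_species`, `best_species`, `percent_identity`, `status`,
#'   `status_iucn`.
#' @export
adjudicate <- function(query_id, vernacular, hits, lookup,
                       status_iucn = NA_character_) {
  expected <- lookup_expected(lookup, vernacular)
  expected_str <- if (length(expected) == 0L) "?" else
    paste(expected, collapse = ";")
  if (is.null(hits)) {
    status <- "amplification_failed"
    best_species <- NA_character_
    pid <- NA_real_
  } else if (nrow(hits) == 0L) {
    status <- "no_hit"
    best_species <- NA_character_
    pid <- NA_real_
  } else {
    best_species <- hits$hit_species[[1L]]
    pid <- hits$percent_identity[[1L]]
    status <- if (length(expected) == 0L) {
      "mismatch_unverifiable"
    } else if (best_species %in% expected) "match" else "mismatch"
  }
  data.frame(query = query_id, vernacular = vernacular,
             expected_species = expected_str, best_species = best_species,
             percent_identity = pid, status = status,
             status_iucn = status_iucn, stringsAsFactors = FALSE)
}

#' Run the market-identification pipeline over a query library
#'
#' For each query record: no sequence means amplification failed; otherwise
#' hits are ranked with [rank_hits()] and adjudicated against the vernacular
#' lookup.
#'
#' @param queries data.frame of query records (columns `id`, `vernacular`,
#'   `sequence`, optionally `status`); `NA` sequence marks a failed query.
#' @param lib the reference [reference_library()].
#' @param lookup a [vernacular_lookup()].
#' @param min_identity minimum percent identity for a hit.
#' @return market-report data.frame, one row per query.
#' @export
market_report <- function(queries, lib, lookup, min_identity = 90) {
  rows <- lapply(seq_len(nrow(queries)), function(i) {
    q <- queries[i, ]
    hits <- if (is.na(q$sequence)) NULL else
      rank_hits(q$sequence, lib, min_identity)
    adjudicate(q$id, q$vernacular, hits, lookup,
               status_iucn = if ("status" %in% names(queries)) q$status
                             else NA_character_)
  })
  do.call(rbind, rows)
}

#' Summarize a market report
#'
#' Counts per status and the headline percentages: matches over *all*
#' queries (failures included in the denominator) and the share of queries
#' whose material carries a Vulnerable conservation status.
#'
#' @param report a market-report data.frame ([market_report()] or
#'   [read_market_report()]).
#' @return list of counts (`n_queries`, `n_with_sequence`, `n_match`,
#'   `n_mismatch`, `n_unverifiable`, `n_failed`, `n_no_hit`) and percentages
#'   (`pct_match`, `pct_threatened`).
#' @export
market_summary <- function(report) {
  n <- nrow(report)
  count <- function(s) sum(report$status == s)
  n_failed <- count("amplification_failed")
  n_match <- count("match")
  threatened <- if ("status_iucn" %in% names(report)) {
    sum(grepl("Vulnerable", report$status_iucn, ignore.case = TRUE),
        na.rm = TRUE)
  } else NA_integer_
  list(
    n_queries = n,
    n_with_sequence = n - n_failed,
    n_match = n_match,
    n_mismatch = count("mismatch"),
    n_unverifiable = count("mismatch_unverifiable"),
    n_failed = n_failed,
    n_no_hit = count("no_hit"),
    pct_match = if (n > 0L) 100 * n_match / n else 0,
    pct_threatened = if (n > 0L && !is.na(threatened)) 100 * threatened / n
                     else NA_real_
  )
}

#' Read / write a market report TSV
#'
#' The TSV mirrors the published market-survey table shape: one row per
#' query with vernacular name, expected species (`?` when unknown), best-hit
#' species, percent identity and adjudication status.
#'
#' @param path file path.
#' @export
read_market_report <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = "-")
  tab$percent_identity <- suppressWarnings(as.numeric(tab$percent_identity))
  tab
}

#' @rdname read_market_report
#' @param report a market-report data.frame.
#' @export
write_market_report <- function(report, path) {
  out <- report
  for (col in names(out)) out[[col]][is.na(out[[col]])] <- "-"
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(report)
}

#' Packaged market-survey fixture
#'
#' An 18-query market survey (vernacular names, expected species from the
#' ethnobotanical literature, best-hit identity and adjudication) bundled
#' for tests and examples: 16 queries yielded sequence (2 amplification
#' failures), 11 matched their vernacular expectation, and 4 carry a
#' Vulnerable conservation status.
#'
#' @return market-report data.frame.
#' @export
market_fixture <- function() {
  read_market_report(
    system.file("extdata", "table3.tsv", package = "barcodekit",
                mustWork = TRUE))
}
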