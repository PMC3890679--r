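# Domain types and readers/writers for the formats the pipeline touches:
# FASTA alignments, TSV metadata, TSV vernacular lookups, TSV reports.

IUPAC_DNA <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
               "B", "D", "H", "V", "N", "-")

#' Normalize a DNA sequence string
#'
#' Upper-cases and converts '.' gap characters to '-'. All ingest paths go
#' through this, so libraries always store upper-case sequences.
#'
#' @param x character vector of sequences.
#' @return normalized character vector.
#' @keywords internal
normalize_sequence <- function(x) {
  gsub(".", "-", toupper(x), fixed = TRUE)
}

.check_alphabet <- function(seqs, ids) {
  for (i in seq_along(seqs)) {
    chars <- unique(strsplit(seqs[[i]], "")[[1]])
    bad <- setdiff(chars, IUPAC_DNA)
    if (length(bad) > 0L) {
      stop("record '", ids[[i]], "' contains non-IUPAC characters: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Construct a reference library
#'
#' A reference library is one aligned barcode locus: an ordered set of
#' equal-length sequences with species and provenance metadata. It is the
#' unit every downstream analysis consumes.
#'
#' @param ids unique record identifiers.
#' @param sequences aligned sequences (equal length, IUPAC DNA plus '-').
#' @param species species label per record; queries may be `"UNKNOWN"`.
#' @param locus locus label, canonically `"rbcLa"`, `"matK"` or `"combined"`.
#' @param vernacular optional vernacular name per record.
#' @param source `"reference"` or `"query"` per record. Reference records
#'   must carry a species label.
#' @param status optional conservation status per record.
#' @param spans named list of per-locus column spans `c(start, end)`; filled
#'   automatically for single-locus libraries and by [concatenate()].
#' @return an object of class `reference_library` with elements `locus`,
#'   `records` (data.frame), `alignment_length` and `spans`.
#' @export
reference_library <- function(ids, sequences, species, locus,
                              vernacular = NA_character_,
                              source = "reference",
                              status = NA_character_,
                              spans = NULL) {
  if (length(ids) == 0L) stop("library must contain at least one record")
  if (anyDuplicated(ids)) {
    stop("duplicate record ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  if (!is.character(locus) || length(locus) != 1L || !nzchar(locus)) {
    stop("locus must be a single non-empty string")
  }
  sequences <- normalize_sequence(as.character(sequences))
  len <- nchar(sequences[[1L]])
  ragged <- nchar(sequences) != len
  if (any(ragged)) {
    stop("ragged alignment: record '", ids[which(ragged)[1L]],
         "' has length ", nchar(sequences[which(ragged)[1L]]),
         ", expected ", len, call. = FALSE)
  }
  .check_alphabet(sequences, ids)
  records <- data.frame(
    id = as.character(ids),
    species = as.character(rep_len(species, length(ids))),
    vernacular = as.character(rep_len(vernacular, length(ids))),
    source = as.character(rep_len(source, length(ids))),
    status = as.character(rep_len(status, length(ids))),
    sequence = sequences,
    stringsAsFactors = FALSE
  )
  bad_source <- !records$source %in% c("reference", "query")
  if (any(bad_source)) stop("source must be 'reference' or 'query'")
  no_species <- records$source == "reference" &
    (is.na(records$species) | records$species == "UNKNOWN" |
       !nzchar(records$species))
  if (any(no_species)) {
    stop("reference record '", records$id[which(no_species)[1L]],
         "' lacks a species label", call. = FALSE)
  }
  if (is.null(spans)) spans <- stats::setNames(list(c(1L, len)), locus)
  structure(
    list(locus = locus, records = records,
         alignment_length = len, spans = spans),
    class = "reference_library"
  )
}

#' @export
print.reference_library <- function(x, ...) {
  cat("Reference library [", x$locus, "]: ", nrow(x$records),
      " records, ", length(unique(x$records$species)), " species, ",
      x$alignment_length, " aligned columns\n", sep = "")
  invisible(x)
}

#' Map record ids to species labels
#'
#' @param lib a [reference_library()].
#' @return named character vector, names are record ids.
#' @export
species_map <- function(lib) {
  stats::setNames(lib$records$species, lib$records$id)
}

#' Read an aligned FASTA plus metadata TSV into a reference library
#'
#' The FASTA ids and the `id` column of the metadata table must match
#' one-to-one. Wrapped and unwrapped FASTA are both accepted.
#'
#' @param path_fasta path to the aligned FASTA file.
#' @param path_metadata path to a TSV with header
#'   `id species vernacular locus source status`.
#' @param locus locus label for the library.
#' @return a [reference_library()].
#' @export
read_alignment <- function(path_fasta, path_metadata, locus) {
  seqs <- Biostrings::readDNAStringSet(path_fasta)
  if (length(seqs) == 0L) stop("empty FASTA file: ", path_fasta)
  ids <- vapply(strsplit(names(seqs), "[ \t]"), `[[`, character(1), 1L)
  meta <- utils::read.delim(path_metadata, stringsAsFactors = FALSE,
                            colClasses = "character")
  required <- c("id", "species", "vernacular", "locus", "source", "status")
  missing_cols <- setdiff(required, names(meta))
  if (length(missing_cols) > 0L) {
    stop("metadata is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  absent <- setdiff(ids, meta$id)
  if (length(absent) > 0L) {
    stop("no metadata row for record '", absent[[1L]], "'", call. = FALSE)
  }
  extra <- setdiff(meta$id, ids)
  if (length(extra) > 0L) {
    stop("metadata row '", extra[[1L]], "' has no sequence", call. = FALSE)
  }
  meta <- meta[match(ids, meta$id), , drop = FALSE]
  na_if_empty <- function(x) ifelse(is.na(x) | !nzchar(x) | x == "?", NA, x)
  reference_library(
    ids = ids,
    sequences = as.character(seqs),
    species = ifelse(is.na(na_if_empty(meta$species)), "UNKNOWN", meta$species),
    locus = locus,
    vernacular = na_if_empty(meta$vernacular),
    source = meta$source,
    status = na_if_empty(meta$status)
  )
}

#' Write a reference library to FASTA plus metadata TSV
#'
#' Sequences are written unwrapped (one line per record) so round-trips are
#' byte-exact.
#'
#' @param lib a [reference_library()].
#' @param path_fasta,path_metadata output paths.
#' @return invisibly, `lib`.
#' @export
write_alignment <- function(lib, path_fasta, path_metadata) {
  rec <- lib$records
  writeLines(as.vector(rbind(paste0(">", rec$id), rec$sequence)), path_fasta)
  meta <- rec[, c("id", "species", "vernacular", "source", "status")]
  meta$locus <- lib$locus
  meta <- meta[, c("id", "species", "vernacular", "locus", "source", "status")]
  for (col in names(meta)) meta[[col]][is.na(meta[[col]])] <- ""
  utils::write.table(meta, path_metadata, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(lib)
}

#' Concatenate two single-locus libraries into a combined alignment
#'
#' Records are matched by id; the intersection is kept (a record present in
#' only one locus is dropped with a warning), preserving the first library's
#' order. Per-locus column spans are recorded so downstream consumers can
#' recover each partition.
#'
#' @param lib_a,lib_b libraries sharing record ids.
#' @param locus label for the combined library (default `"combined"`).
#' @return a [reference_library()] whose alignment length is the sum of the
#'   two inputs'.
#' @export
concatenate <- function(lib_a, lib_b, locus = "combined") {
  shared <- intersect(lib_a$records$id, lib_b$records$id)
  if (length(shared) == 0L) stop("libraries share no record ids")
  dropped <- setdiff(union(lib_a$records$id, lib_b$records$id), shared)
  if (length(dropped) > 0L) {
    warning(length(dropped), " record(s) present in only one locus dropped: ",
            paste(utils::head(dropped, 5L), collapse = ", "),
            if (length(dropped) > 5L) ", ...")
  }
  a <- lib_a$records[match(shared, lib_a$records$id), , drop = FALSE]
  b <- lib_b$records[match(shared, lib_b$records$id), , drop = FALSE]
  la <- lib_a$alignment_length
  lb <- lib_b$alignment_length
  spans <- stats::setNames(
    list(c(1L, la), c(la + 1L, la + lb)),
    c(lib_a$locus, lib_b$locus)
  )
  reference_library(
    ids = shared,
    sequences = paste0(a$sequence, b$sequence),
    species = a$species,
    locus = locus,
    vernacular = a$vernacular,
    source = a$source,
    status = a$status,
    spans = spans
  )
}

#' Construct a vernacular-name lookup
#'
#' Maps vernacular names to expected scientific names. The mapping is
#' many-to-many: a vernacular may list several synonymous species, and a
#' species may carry several vernaculars. An unknown expectation is
#' represented as `NA` (serialized `"?"`), never dropped.
#'
#' @param vernacular,species equal-length character vectors; `species` may be
#'   `NA` for names whose scientific identity is unknown.
#' @return an object of class `vernacular_lookup` (a data.frame).
#' @export
vernacular_lookup <- function(vernacular, species) {
  if (length(vernacular) != length(species)) {
    stop("vernacular and species must have equal length")
  }
  out <- data.frame(vernacular = as.character(vernacular),
                    species = as.character(species),
                    stringsAsFactors = FALSE)
  class(out) <- c("vernacular_lookup", "data.frame")
  out
}

#' Expected species for a vernacular name
#'
#' @param lookup a [vernacular_lookup()].
#' @param name a vernacular name.
#' @return character vector of expected species; empty when the name is
#'   absent from the lookup or maps only to unknowns.
#' @export
lookup_expected <- function(lookup, name) {
  hit <- lookup$species[lookup$vernacular == name]
  hit[!is.na(hit)]
}

#' Read / write a vernacular lookup TSV
#'
#' Two-column TSV `vernacular species`; `"?"` encodes an unknown species.
#'
#' @param path file path.
#' @return [read_lookup()] returns a [vernacular_lookup()].
#' @export
read_lookup <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  sp <- tab$species
  sp[sp == "?" | !nzchar(sp)] <- NA
  vernacular_lookup(tab$vernacular, sp)
}

#' @rdname read_lookup
#' @param lookup a [vernacular_lookup()].
#' @export
write_lookup <- function(lookup, path) {
  out <- as.data.frame(lookup)
  out$species[is.na(out$species)] <- "?"
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(lookup)
}
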