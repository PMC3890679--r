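# Pairwise genetic distances under pairwise deletion: site-pattern counts,
# the Kimura two-parameter correction, uncorrected p-distance, and the
# Tajima-K mean-divergence summary.

#' Count shared site patterns between two aligned sequences
#'
#' Applies pairwise deletion: only columns where *both* sequences carry an
#' unambiguous A/C/G/T are compared. Gaps ('-') and ambiguity codes
#' (including 'N') exclude a column for this pair only. Differences between
#' two purines or two pyrimidines are transitions; all other differences are
#' transversions.
#'
#' @param a,b aligned sequence strings of equal length.
#' @return list with `n_sites` (compared columns), `transitions`,
#'   `transversions`.
#' @export
count_site_patterns <- function(a, b) {
  if (nchar(a) != nchar(b)) {
    stop("sequences have unequal lengths (", nchar(a), " vs ", nchar(b), ")")
  }
  ca <- strsplit(normalize_sequence(a), "")[[1L]]
  cb <- strsplit(normalize_sequence(b), "")[[1L]]
  bases <- c("A", "C", "G", "T")
  ok <- ca %in% bases & cb %in% bases
  ca <- ca[ok]
  cb <- cb[ok]
  ts <- (ca == "A" & cb == "G") | (ca == "G" & cb == "A") |
    (ca == "C" & cb == "T") | (ca == "T" & cb == "C")
  tv <- ca != cb & !ts
  list(n_sites = sum(ok), transitions = sum(ts), transversions = sum(tv))
}

#' Kimura two-parameter distance from site-pattern counts
#'
#' With P = transitions / n_sites and Q = transversions / n_sites, the
#' corrected distance is d = -1/2 * ln\[(1 - 2P - Q) * sqrt(1 - 2Q)\].
#' Returns `NA` (missing) when the pair overlaps on fewer than `min_overlap`
#' unambiguous sites, or when the correction is undefined because the pair
#' is saturated (1 - 2P - Q <= 0 or 1 - 2Q <= 0).
#'
#' @param counts a list as returned by [count_site_patterns()].
#' @param min_overlap minimum number of compared sites (default 100).
#' @return non-negative numeric distance, or `NA_real_`.
#' @export
k2p_distance <- function(counts, min_overlap = 100) {
  n <- counts$n_sites
  if (n < min_overlap) return(NA_real_)
  P <- counts$transitions / n
  Q <- counts$transversions / n
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0) return(NA_real_)
  -0.5 * log(w1 * sqrt(w2))
}

#' Uncorrected p-distance from site-pattern counts
#'
#' (transitions + transversions) / n_sites; `NA` under `min_overlap`.
#'
#' @inheritParams k2p_distance
#' @return numeric in \[0, 1\], or `NA_real_`.
#' @export
p_distance <- function(counts, min_overlap = 100) {
  n <- counts$n_sites
  if (n < min_overlap) return(NA_real_)
  (counts$transitions + counts$transversions) / n
}

# Records-by-columns character matrix of an alignment.
.char_matrix <- function(lib) {
  matrix(unlist(strsplit(lib$records$sequence, ""), use.names = FALSE),
         nrow = nrow(lib$records), byrow = TRUE,
         dimnames = list(lib$records$id, NULL))
}

# All pairwise distances from a character matrix in a handful of BLAS
# calls: tcrossprod of per-base 0/1 indicators yields every pair's counts
# of compared sites, matches and transitions at once.
.dist_from_chm <- function(chm, model, min_overlap) {
  ind <- lapply(c(A = "A", C = "C", G = "G", T = "T"),
                function(b) (chm == b) * 1)
  V <- ind$A + ind$C + ind$G + ind$T
  N <- tcrossprod(V)
  M <- tcrossprod(ind$A) + tcrossprod(ind$C) +
    tcrossprod(ind$G) + tcrossprod(ind$T)
  TS <- tcrossprod(ind$A, ind$G) + tcrossprod(ind$C, ind$T)
  TS <- TS + t(TS)
  TV <- N - M - TS
  if (model == "p") {
    d <- (TS + TV) / N
  } else {
    P <- TS / N
    Q <- TV / N
    w1 <- 1 - 2 * P - Q
    w2 <- 1 - 2 * Q
    d <- -0.5 * log(w1 * sqrt(w2))
    d[w1 <= 0 | w2 <= 0] <- NA_real_
  }
  d[N < min_overlap] <- NA_real_
  diag(d) <- 0
  ids <- rownames(chm)
  dimnames(d) <- list(ids, ids)
  d
}

#' Pairwise distance matrix over a reference library
#'
#' Computes all pairwise K2P or p-distances under pairwise deletion. Entries
#' are `NA` where a pair's unambiguous overlap falls below `min_overlap` or
#' (K2P only) where the log correction is undefined. The matrix is symmetric
#' with a zero diagonal.
#'
#' @param lib a [reference_library()].
#' @param model `"k2p"` or `"p"`.
#' @param min_overlap minimum pairwise overlap in sites.
#' @return a square numeric matrix with record ids as dimnames and
#'   attributes `model` and `min_overlap`.
#' @export
build_distance_matrix <- function(lib, model = c("k2p", "p"),
                                  min_overlap = 100) {
  model <- match.arg(model)
  d <- .dist_from_chm(.char_matrix(lib), model, min_overlap)
  attr(d, "model") <- model
  attr(d, "min_overlap") <- min_overlap
  d
}

#' Tajima's K: mean pairwise divergence per nucleotide
#'
#' The mean, over all unordered sequence pairs, of the per-nucleotide number
#' of substitutions — i.e. the mean of the non-missing upper triangle of a
#' p-distance matrix.
#'
#' @param m a p-distance matrix from [build_distance_matrix()].
#' @return a single numeric value.
#' @export
tajima_K <- function(m) {
  vals <- m[upper.tri(m)]
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0L) {
    stop("no non-missing pairwise distances; cannot compute mean divergence")
  }
  mean(vals)
}

#' Write / read a distance matrix as square TSV
#'
#' Header row and first column carry record ids; missing values are `NA`.
#'
#' @param m a distance matrix.
#' @param path file path.
#' @export
write_distance_matrix <- function(m, path) {
  out <- data.frame(id = rownames(m), m, check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(m)
}

#' @rdname write_distance_matrix
#' @export
read_distance_matrix <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab$id
  m
}
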