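test_that("site-pattern counting applies pairwise deletion and the
           transition/transversion split", {
  expect_equal(count_site_patterns("ACGT", "ACGT"),
               list(n_sites = 4L, transitions = 0L, transversions = 0L))
  expect_equal(count_site_patterns("ACGT", "GCGT"),
               list(n_sites = 4L, transitions = 1L, transversions = 0L))
  expect_equal(count_site_patterns("ACGT", "TCGT"),
               list(n_sites = 4L, transitions = 0L, transversions = 1L))
  expect_equal(count_site_patterns("AC-T", "ACGT"),
               list(n_sites = 3L, transitions = 0L, transversions = 0L))
  expect_equal(count_site_patterns("ACNT", "ACGT")$n_sites, 3L)
  expect_equal(count_site_patterns("ACRT", "ACGT")$n_sites, 3L)
  expect_error(count_site_patterns("ACGT", "ACGTA"), "unequal")
})

test_that("K2P distance matches the closed form and handles boundaries", {
  # independently evaluated: 100 sites, 10 transitions, 5 transversions
  d <- k2p_distance(list(n_sites = 100L, transitions = 10L,
                         transversions = 5L))
  expect_equal(d, 0.170181165140, tolerance = 1e-10)
  expect_equal(k2p_distance(list(n_sites = 100L, transitions = 0L,
                                 transversions = 0L)), 0)
  # saturation: 1 - 2P - Q = 0
  expect_true(is.na(k2p_distance(list(n_sites = 100L, transitions = 45L,
                                      transversions = 10L))))
  # insufficient overlap
  expect_true(is.na(k2p_distance(list(n_sites = 99L, transitions = 0L,
                                      transversions = 0L))))
})

test_that("p-distance is the raw proportion with the same missing rules", {
  expect_equal(p_distance(list(n_sites = 4L, transitions = 0L,
                               transversions = 0L), min_overlap = 1), 0)
  expect_equal(p_distance(list(n_sites = 100L, transitions = 10L,
                               transversions = 5L)), 0.15)
  expect_true(is.na(p_distance(list(n_sites = 50L, transitions = 1L,
                                    transversions = 0L))))
})

test_that("distance matrix equals the per-pair scan and an independent
           K80 implementation", {
  set.seed(7)
  gen <- generate_library(synthetic_config(n_species = 5, individuals = 2,
                                           seq_length = 300,
                                           inter_target = 0.15,
                                           intra_target = 0.01, seed = 7))
  lib <- gen$library
  # inject gaps and Ns to exercise pairwise deletion
  ch <- strsplit(lib$records$sequence[1], "")[[1]]
  ch[1:30] <- "-"; ch[31:40] <- "N"
  lib$records$sequence[1] <- paste(ch, collapse = "")
  for (model in c("k2p", "p")) {
    m <- build_distance_matrix(lib, model, min_overlap = 100)
    ids <- lib$records$id
    fn <- if (model == "k2p") k2p_distance else p_distance
    for (i in seq_along(ids)) for (j in seq_along(ids)) {
      expected <- if (i == j) 0 else
        fn(count_site_patterns(lib$records$sequence[i],
                               lib$records$sequence[j]), min_overlap = 100)
      expect_equal(unname(m[i, j]), expected, tolerance = 1e-12)
    }
  }
  # cross-check against ape's K80 with pairwise deletion (gap-free library)
  gen2 <- generate_library(synthetic_config(n_species = 4, individuals = 2,
                                            seq_length = 400,
                                            inter_target = 0.12,
                                            intra_target = 0.005, seed = 11))
  m2 <- build_distance_matrix(gen2$library, "k2p")
  bin <- ape::as.DNAbin(lapply(
    setNames(gen2$library$records$sequence, gen2$library$records$id),
    function(s) tolower(strsplit(s, "")[[1]])))
  m_ape <- as.matrix(ape::dist.dna(bin, model = "K80",
                                   pairwise.deletion = TRUE))
  expect_equal(unclass(m2)[rownames(m_ape), colnames(m_ape)],
               m_ape, tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("permuting record order permutes the matrix rows and columns", {
  gen <- generate_library(synthetic_config(n_species = 4, individuals = 2,
                                           seq_length = 300, seed = 3))
  lib <- gen$library
  m <- build_distance_matrix(lib, "k2p")
  set.seed(1)
  perm <- sample(nrow(lib$records))
  lib_p <- lib
  lib_p$records <- lib$records[perm, ]
  m_p <- build_distance_matrix(lib_p, "k2p")
  expect_equal(unclass(m_p), unclass(m)[perm, perm], ignore_attr = TRUE)
})

test_that("K2P dominates p-distance and grows with added substitutions", {
  # Jensen-type correction property on a grid of counts
  for (ts in c(0L, 5L, 20L, 40L)) for (tv in c(0L, 5L, 15L)) {
    cnt <- list(n_sites = 200L, transitions = ts, transversions = tv)
    k <- k2p_distance(cnt)
    p <- p_distance(cnt)
    if (!is.na(k)) {
      expect_gte(k, p)
      if (ts + tv > 0) expect_gt(k, p)
    }
  }
  # monotonicity under simulated accumulating substitutions
  set.seed(42)
  base <- paste(sample(c("A", "C", "G", "T"), 800, replace = TRUE),
                collapse = "")
  ch <- strsplit(base, "")[[1]]
  prev_d <- 0
  mutated <- ch
  for (step in 1:6) {
    pos <- sample(which(mutated == ch), 12)
    mutated[pos] <- vapply(mutated[pos], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
    d <- k2p_distance(count_site_patterns(base, paste(mutated, collapse = "")))
    expect_gte(d, prev_d)
    prev_d <- d
  }
})

test_that("Tajima's K is the mean pairwise per-site divergence", {
  m <- matrix(c(0, 0.02, 0.04,
                0.02, 0, 0.06,
                0.04, 0.06, 0), 3, 3,
              dimnames = list(letters[1:3], letters[1:3]))
  expect_equal(tajima_K(m), 0.04)
  ident <- matrix(0, 3, 3)
  expect_equal(tajima_K(ident), 0)
  all_na <- matrix(NA_real_, 2, 2); diag(all_na) <- 0
  expect_error(tajima_K(all_na), "no non-missing")
})

test_that("distance matrices serialize to square TSV with NA for missing", {
  m <- random_distance_matrix(5, na_frac = 0.2)
  dir <- withr::local_tempdir()
  path <- file.path(dir, "m.tsv")
  write_distance_matrix(m, path)
  m2 <- read_distance_matrix(path)
  expect_equal(m2, m, tolerance = 1e-12, ignore_attr = TRUE)
  expect_identical(rownames(m2), rownames(m))
})
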