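test_that("estimators agree with brute-force leave-one-out scans", {
  set.seed(31)
  for (rep in 1:30) {
    m <- random_distance_matrix(15, tie_digits = 2, na_frac = 0.05)
    sp <- random_species_map(m, 5)
    thr <- runif(1, 0.01, 0.15)
    nn <- near_neighbour(m, sp)
    expect_identical(setNames(nn$outcomes$verdict, nn$outcomes$id),
                     oracle_near_neighbour(m, sp)[nn$outcomes$id])
    bcm <- best_close_match(m, sp, thr)
    expect_identical(setNames(bcm$outcomes$verdict, bcm$outcomes$id),
                     oracle_best_close_match(m, sp, thr)[bcm$outcomes$id])
    tid <- threshold_id(m, sp, thr)
    expect_identical(setNames(tid$outcomes$verdict, tid$outcomes$id),
                     oracle_threshold_id(m, sp, thr)[tid$outcomes$id])
  }
})

test_that("tie rules: any conspecific among tied nearest counts for NN,
           mixed ties are ambiguous for BCM", {
  ids <- c("a1", "a2", "b1", "c1")
  m <- matrix(0.2, 4, 4, dimnames = list(ids, ids)); diag(m) <- 0
  m["a1", "a2"] <- m["a2", "a1"] <- 0.05
  m["a1", "b1"] <- m["b1", "a1"] <- 0.05  # tie: one conspecific, one not
  sp <- setNames(c("A", "A", "B", "C"), ids)
  nn <- near_neighbour(m, sp)
  expect_equal(nn$outcomes$verdict[nn$outcomes$id == "a1"], "true")
  bcm <- best_close_match(m, sp, 0.1)
  expect_equal(bcm$outcomes$verdict[bcm$outcomes$id == "a1"], "ambiguous")
  # singleton species record is necessarily false
  expect_equal(nn$outcomes$verdict[nn$outcomes$id == "c1"], "false")
  expect_equal(nn$n_singletons, 2)
})

test_that("threshold_id composition rule distinguishes from BCM nearest rule", {
  # conspecific at 0.002 and heterospecific at 0.008, cutoff 0.01:
  # BCM looks only at the nearest (conspecific) -> correct;
  # the fixed-cutoff method sees both -> ambiguous.
  ids <- c("x1", "x2", "y1")
  m <- matrix(0, 3, 3, dimnames = list(ids, ids))
  m["x1", "x2"] <- m["x2", "x1"] <- 0.002
  m["x1", "y1"] <- m["y1", "x1"] <- 0.008
  m["x2", "y1"] <- m["y1", "x2"] <- 0.009
  sp <- setNames(c("X", "X", "Y"), ids)
  expect_equal(threshold_id(m, sp, 0.01)$outcomes$verdict[1], "ambiguous")
  expect_equal(best_close_match(m, sp, 0.01)$outcomes$verdict[1], "correct")
  # only conspecifics within the cutoff -> correct
  m["x1", "y1"] <- m["y1", "x1"] <- 0.05
  m["x2", "y1"] <- m["y1", "x2"] <- 0.05
  expect_equal(threshold_id(m, sp, 0.01)$outcomes$verdict[1], "correct")
  # nothing within the cutoff -> no_id
  m["x1", "x2"] <- m["x2", "x1"] <- 0.04
  expect_equal(threshold_id(m, sp, 0.01)$outcomes$verdict[1], "no_id")
})

test_that("best close match at infinite threshold reduces to near neighbour", {
  set.seed(17)
  for (rep in 1:10) {
    m <- random_distance_matrix(12)  # continuous: ties have measure zero
    sp <- random_species_map(m, 4)
    nn <- near_neighbour(m, sp)$outcomes$verdict
    bcm <- best_close_match(m, sp, Inf)$outcomes$verdict
    expect_identical(bcm == "correct", nn == "true")
    expect_identical(bcm == "incorrect", nn == "false")
  }
})

test_that("no_id count is non-increasing as the threshold grows", {
  set.seed(13)
  m <- random_distance_matrix(20, na_frac = 0.05)
  sp <- random_species_map(m, 6)
  counts <- sapply(seq(0.005, 0.2, by = 0.005), function(t) {
    s <- threshold_id(m, sp, t)$summary
    s$n[s$verdict == "no_id"]
  })
  expect_true(all(diff(counts) <= 0))
})

test_that("threshold optimization picks the smallest zero-error cutoff under
           clean separation", {
  gen <- generate_library(synthetic_config(n_species = 10, individuals = 3,
                                           seq_length = 800,
                                           inter_target = 0.10,
                                           intra_target = 0.002, seed = 8))
  m <- build_distance_matrix(gen$library, "k2p")
  sp <- species_map(gen$library)
  part <- partition_distances(m, sp)
  grid <- default_threshold_grid()
  opt <- optimize_threshold(m, sp, grid)
  # every t between max intra and min inter has zero error; ties break
  # toward the smallest grid point clearing all intraspecific distances
  expect_equal(opt$threshold, min(grid[grid >= max(part$intra)]))
  expect_gt(opt$threshold, max(part$intra))
  expect_lt(opt$threshold, min(part$inter))
  expect_equal(min(opt$profile$error), 0)
  # degenerate grid returns its only point
  expect_equal(optimize_threshold(m, sp, grid = 0.02)$threshold, 0.02)
  expect_error(optimize_threshold(m, sp, grid = numeric(0)), "non-empty")
})

test_that("efficacy table is conservative: percentages sum to 100 and a
           mislabeled record costs exactly its share", {
  gen <- generate_library(synthetic_config(n_species = 6, individuals = 3,
                                           seq_length = 600,
                                           inter_target = 0.12,
                                           intra_target = 0.003, seed = 14))
  lib <- gen$library
  eff <- efficacy_table(list(locus_a = lib))
  for (meth in unique(eff$method)) {
    expect_equal(sum(eff$pct[eff$method == meth]), 100)
  }
  # perfectly separated library: everything correct/true
  expect_equal(eff$pct[eff$method == "near_neighbour" &
                         eff$verdict == "true"], 100)
  expect_equal(eff$pct[eff$method == "best_close_match" &
                         eff$verdict == "correct"], 100)
  # relabel one record as a novel species: it alone becomes unmatchable.
  # Pick a record that is no other record's nearest neighbour so every
  # other verdict is untouched; fix the BCM threshold so the comparison
  # is like for like.
  m <- build_distance_matrix(lib, "k2p")
  sp <- species_map(lib)
  nn <- near_neighbour(m, sp)
  rogue <- setdiff(nn$outcomes$id, nn$outcomes$nearest_id)[1]
  expect_false(is.na(rogue))
  lib2 <- lib
  lib2$records$species[lib2$records$id == rogue] <- "species_rogue"
  thr <- c(locus_a = 0.02)  # inside the barcode gap of this panel
  eff_before <- efficacy_table(list(locus_a = lib), thresholds = thr)
  eff2 <- efficacy_table(list(locus_a = lib2), thresholds = thr)
  n <- nrow(lib$records)
  pick <- function(e, meth, v) e$pct[e$method == meth & e$verdict == v]
  expect_equal(pick(eff_before, "near_neighbour", "true"), 100)
  expect_equal(pick(eff2, "near_neighbour", "true"), 100 * (n - 1) / n)
  expect_equal(pick(eff2, "best_close_match", "correct"),
               pick(eff_before, "best_close_match", "correct") - 100 / n)
})
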