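# small fixed study used across blocks: 3 regions with known haplotypes
fixture_dbs <- function() {
  mk <- function(tokens) parse_haplotype(tokens, covered_range = c(16090, 16365))
  recs <- data.frame(
    id = sprintf("d%02d", 1:9),
    population = "db", locality = "x",
    region = c("A", "A", "A", "B", "B", "B", "C", "C", "C"),
    stringsAsFactors = FALSE)
  recs$haplotype <- I(list(
    mk("T16189C T16217C"), mk("T16189C T16217C"), mk("C16223T"),
    mk("G16230A"), mk("G16230A A16235G"), mk("G16230A A16235G C16240T"),
    mk("T16126C"), mk("T16126C G16129A"), mk("A16300G")))
  build_region_db(recs)
}

test_that("database building aggregates identical haplotypes per region", {
  dbs <- fixture_dbs()
  expect_equal(names(dbs), c("A", "B", "C"))
  expect_equal(dbs$A$size, 3L)
  expect_equal(sort(dbs$A$counts), c(1, 2))   # B4 motif seen twice
  expect_equal(length(dbs$B$counts), 3L)

  recs <- data.frame(id = "x", population = "p", locality = "l",
                     region = NA_character_, stringsAsFactors = FALSE)
  recs$haplotype <- I(list(parse_haplotype("T16189C")))
  expect_error(build_region_db(recs), "region label")
})

test_that("match counts agree with an exhaustive scan oracle", {
  dbs <- fixture_dbs()
  b4 <- parse_haplotype("T16189C T16217C", covered_range = c(16090, 16365))
  expect_equal(match_counts(b4, dbs$A, 0), 2)
  expect_equal(match_counts(b4, dbs$B, 0), 0)
  # nearest B entry (G16230A) is 3 steps away from b4
  expect_equal(match_counts(b4, dbs$B, 2), 0)
  expect_equal(match_counts(b4, dbs$A, 1), 2)
  one_off <- parse_haplotype("T16189C", covered_range = c(16090, 16365))
  expect_equal(match_counts(one_off, dbs$A, 0), 0)
  expect_equal(match_counts(one_off, dbs$A, 1), 2)

  ref <- test_reference()
  set.seed(43)
  for (rep in 1:5) {
    recs <- data.frame(id = sprintf("r%02d", 1:30), population = "p",
                       locality = "l", region = "Z",
                       stringsAsFactors = FALSE)
    recs$haplotype <- I(lapply(1:30, function(i)
      random_substitution_haplotype(ref, 16090L, 16365L, sample(0:4, 1L))))
    db <- build_region_db(recs)$Z
    tgt <- random_substitution_haplotype(ref, 16090L, 16365L, 2L)
    tgtn <- restrict_to_range(normalize_haplotype(tgt), 16090, 16365)
    for (m in 0:2) {
      oracle <- sum(db$counts[vapply(db$haplotypes, function(h)
        haplotype_distance(tgtn, h), numeric(1)) <= m])
      expect_equal(match_counts(tgtn, db, m), oracle)
    }
  }
})

test_that("target allocation uses relative frequencies and normalizes", {
  dbs <- fixture_dbs()
  b4 <- parse_haplotype("T16189C T16217C", covered_range = c(16090, 16365))
  w <- allocate_target(b4, dbs, 0)
  expect_equal(unname(w), c(1, 0, 0))

  # equal relative frequency in two regions: C16223T is 1/3 of A;
  # a haplotype matched by exactly one of B's three entries is 1/3 of B
  h <- parse_haplotype("C16223T", covered_range = c(16090, 16365))
  wA <- allocate_target(h, dbs, 0)
  expect_equal(unname(wA), c(1, 0, 0))
  # at m = 1, C16223T also matches the empty-distance-1 entries of C? no:
  # distances to C entries are 2 or 3, so still exclusive to A
  expect_equal(unname(allocate_target(h, dbs, 1)), c(1, 0, 0))

  # hand-enumerated arithmetic: target matching 2/3 in A and 1/3 in B
  t2 <- parse_haplotype("G16230A A16235G", covered_range = c(16090, 16365))
  # m=1: A none; B entries at distance 1, 0, 1 -> c_B = 3, f_B = 1;
  #      C entries at distance >= 3 -> 0
  w2 <- allocate_target(t2, dbs, 1)
  expect_equal(unname(w2), c(0, 1, 0))
  # unmatched target
  far <- parse_haplotype("A16090G C16091A G16092T",
                         covered_range = c(16090, 16365))
  expect_null(allocate_target(far, dbs, 0))

  # symmetric two-region case built explicitly
  recs <- data.frame(id = c("a1", "b1"), population = "p", locality = "l",
                     region = c("A", "B"), stringsAsFactors = FALSE)
  h0 <- parse_haplotype("T16189C", covered_range = c(16090, 16365))
  recs$haplotype <- I(list(h0, h0))
  sym <- build_region_db(recs)
  expect_equal(unname(allocate_target(h0, sym, 0)), c(0.5, 0.5))
})

test_that("the estimator matches hand arithmetic and reports coverage", {
  dbs <- fixture_dbs()
  mk <- function(tokens) parse_haplotype(tokens, covered_range = c(16090, 16365))
  targets <- hap_records(list(mk("T16189C T16217C"), mk("C16223T")))
  est <- estimate_admixture(targets, dbs, 0)
  expect_equal(unname(est$P), c(1, 0, 0))
  expect_equal(est$coverage, 1)

  targets2 <- hap_records(list(mk("T16189C T16217C"), mk("G16230A"),
                               mk("A16090G C16091A G16092T")))
  est2 <- estimate_admixture(targets2, dbs, 0)
  expect_equal(unname(est2$P), c(0.5, 0.5, 0))
  expect_equal(est2$coverage, 2 / 3)
  expect_equal(est2$unmatched, 3L)
  expect_equal(sum(est2$P), 1)

  expect_error(estimate_admixture(
    hap_records(list(mk("A16090G C16091A G16092T"))), dbs, 0), "no target")
})

test_that("match sets are nested in m and scale invariance holds", {
  ref <- test_reference()
  set.seed(47)
  recs <- data.frame(id = sprintf("r%02d", 1:40), population = "p",
                     locality = "l",
                     region = rep(c("A", "B"), each = 20L),
                     stringsAsFactors = FALSE)
  recs$haplotype <- I(lapply(1:40, function(i)
    random_substitution_haplotype(ref, 16090L, 16365L, sample(0:3, 1L))))
  dbs <- build_region_db(recs)
  targets <- hap_records(lapply(1:15, function(i)
    random_substitution_haplotype(ref, 16090L, 16365L, sample(0:3, 1L))))

  prev_cov <- 0
  for (m in 0:3) {
    est <- try(estimate_admixture(targets, dbs, m), silent = TRUE)
    cov <- if (inherits(est, "try-error")) 0 else est$coverage
    expect_gte(cov, prev_cov)
    prev_cov <- cov
    # per-target nesting of match counts
    for (i in 1:5) {
      h <- restrict_to_range(normalize_haplotype(targets$haplotype[[i]]),
                             16090, 16365)
      expect_gte(match_counts(h, dbs$A, m + 1), match_counts(h, dbs$A, m))
    }
  }

  # tripling every database record leaves the estimate unchanged
  recs3 <- do.call(rbind, list(recs, recs, recs))
  recs3$id <- sprintf("r%03d", seq_len(nrow(recs3)))
  dbs3 <- build_region_db(recs3)
  e1 <- estimate_admixture(targets, dbs, 1)
  e3 <- estimate_admixture(targets, dbs3, 1)
  expect_equal(e1$P, e3$P, tolerance = 1e-12)
  expect_equal(e1$coverage, e3$coverage)
})

test_that("bootstrap CIs are deterministic, bounded and degenerate when forced", {
  dbs <- fixture_dbs()
  mk <- function(tokens) parse_haplotype(tokens, covered_range = c(16090, 16365))
  targets <- hap_records(list(mk("T16189C T16217C"), mk("C16223T")))

  for (scheme in c("databases", "targets", "both")) {
    ci1 <- bootstrap_ci(targets, dbs, 0, B = 50, seed = 5, scheme = scheme)
    ci2 <- bootstrap_ci(targets, dbs, 0, B = 50, seed = 5, scheme = scheme)
    expect_equal(ci1, ci2)
    expect_true(all(ci1$ci_low <= ci1$ci_high))
    expect_true(all(ci1$ci_low >= 0 & ci1$ci_high <= 1))
  }

  # single region, all targets exclusive there: CI pinned at [1, 1]
  ci <- bootstrap_ci(targets, dbs["A"], 0, B = 30, seed = 2,
                     scheme = "targets")
  expect_equal(ci$ci_low, 1)
  expect_equal(ci$ci_high, 1)
})

test_that("the P0/P1/P2 table composes per-m estimates and sums to one", {
  dbs <- fixture_dbs()
  mk <- function(tokens) parse_haplotype(tokens, covered_range = c(16090, 16365))
  targets <- hap_records(list(mk("T16189C T16217C"), mk("G16230A"),
                              mk("T16126C")))
  tab <- admixture_table(targets, dbs, m_values = 0:2, B = 40, seed = 9)
  for (m in 0:2) {
    expect_equal(sum(tab[[paste0("P", m)]]), 1, tolerance = 1e-12)
    est <- estimate_admixture(targets, dbs, m)
    expect_equal(tab[[paste0("P", m)]], unname(est$P))
  }
  cov <- attr(tab, "coverage")
  expect_true(all(diff(cov) >= 0))
})
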