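test_that("variant token grammar resolves every dialect", {
  ref <- test_reference()

  v <- parse_variant_token("T16189C")
  expect_equal(v$position, 16189L)
  expect_equal(v$ref, "T")
  expect_equal(v$alt, "C")
  expect_equal(v$kind, "transition")

  v <- parse_variant_token("309.1C")
  expect_equal(v$position, 309L)
  expect_equal(v$insertion_index, 1L)
  expect_equal(v$ref, "")
  expect_equal(v$kind, "insertion")

  v <- parse_variant_token("@152", reference = ref)
  expect_equal(v$kind, "back-mutation-marker")
  expect_equal(v$ref, "C")

  v <- parse_variant_token("16166d", reference = ref)
  expect_equal(v$kind, "deletion")
  expect_equal(v$ref, "C")
  expect_equal(v$alt, "d")

  v <- parse_variant_token("C16223Y")
  expect_equal(v$kind, "heteroplasmy")

  # transversion: suffix base that is not the transition partner
  v <- parse_variant_token("T16189A")
  expect_equal(v$kind, "transversion")

  expect_error(parse_variant_token("not-a-token"), "malformed")
  expect_error(parse_variant_token("16189"), "reference")
  expect_error(parse_variant_token("G16189C", reference = ref), "reference base")
  expect_error(parse_variant_token("@152", allow_back_mutation = FALSE),
               "back-mutation")
  expect_error(parse_variant_token("T16189T"), "identical")
})

test_that("flank-style and bare-position tokens resolve to the same variant", {
  ref <- test_reference()
  h_bare <- parse_haplotype("16189 16217", reference = ref)
  h_flank <- parse_haplotype("T16189C-T16217C", reference = ref)
  expect_same_variants(h_bare, h_flank)
  expect_equal(haplotype_distance(h_bare, h_flank), 0L)
})

test_that("parse_haplotype deduplicates and rejects allele conflicts", {
  h <- parse_haplotype("T16189C T16189C T16217C")
  expect_equal(nrow(h), 2L)
  expect_error(parse_haplotype("T16189C T16189A"), "onflict")
  h0 <- parse_haplotype("")
  expect_equal(nrow(h0), 0L)
})

test_that("sequence variant calling matches a per-position oracle and round-trips", {
  ref <- reference_segment("r", 1L, "ACGT")
  h <- variants_from_sequence(ref, "ACTT", offset = 1L)
  expect_equal(nrow(h), 1L)
  expect_equal(h$position, 3L)
  expect_equal(h$kind, "transversion")

  expect_equal(nrow(variants_from_sequence(ref, "ACGT", offset = 1L)), 0L)
  expect_error(variants_from_sequence(ref, "AC?T", offset = 1L), "IUPAC")

  set.seed(404)
  big <- test_reference()
  for (rep in 1:20) {
    start <- 16100L
    seq0 <- substring(big$bases, start, start + 49L)
    chars <- strsplit(seq0, "")[[1L]]
    idx <- sample(50L, sample(0:6, 1L))
    for (i in idx)
      chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1L)
    mutated <- paste(chars, collapse = "")
    h <- variants_from_sequence(big, mutated, offset = start)
    # oracle: brute-force per-position comparison
    ref_chars <- strsplit(seq0, "")[[1L]]
    expect_equal(h$position, start - 1L + which(chars != ref_chars))
    # round trip through reconstruction
    expect_equal(substring(reconstruct_sequence(big, h), start, start + 49L),
                 mutated)
    h2 <- variants_from_sequence(big,
      substring(reconstruct_sequence(big, h), start, start + 49L),
      offset = start)
    expect_same_variants(h, h2)
  }
})

test_that("reconstruction applies substitutions, deletions and insertions", {
  ref <- reference_segment("r", 1L, "ACGTACGT")
  expect_equal(reconstruct_sequence(ref, haplotype(covered_range = c(1, 8))),
               "ACGTACGT")
  h <- parse_haplotype("C2T 4d 5.1G", reference = ref, covered_range = c(1, 8))
  expect_equal(reconstruct_sequence(ref, h), "ATG-AGCGT")
  hbad <- haplotype(parse_variant_token("T16189C"), c(16090, 16365))
  expect_error(reconstruct_sequence(ref, hbad), "span")
})

test_that("normalization drops excluded positions, poly-C indels and heteroplasmies", {
  h <- parse_haplotype("A16182C A16183C T16189C", covered_range = c(16090, 16365))
  n <- normalize_haplotype(h)
  expect_equal(format_variants(n), "T16189C")

  h <- parse_haplotype("309.1C 315.1C C16223T")
  n <- normalize_haplotype(h)
  expect_equal(format_variants(n), "C16223T")

  h <- parse_haplotype("C16223Y T16189C")
  expect_equal(format_variants(normalize_haplotype(h)), "T16189C")

  # idempotent and never adds
  set.seed(7)
  ref <- test_reference()
  for (rep in 1:10) {
    h <- random_substitution_haplotype(ref, 16090L, 16365L, sample(0:8, 1L))
    n1 <- normalize_haplotype(h)
    expect_same_variants(normalize_haplotype(n1), n1)
    expect_true(all(format_variants(n1) %in% format_variants(h)))
  }
  # a deletion outside the poly-C window survives
  h <- parse_haplotype("16166d", reference = ref)
  expect_equal(nrow(normalize_haplotype(h)), 1L)
})

test_that("range restriction keeps exactly the in-range variants", {
  h <- parse_haplotype("A73G T16189C")
  r <- restrict_to_range(h, 16090, 16365)
  expect_equal(format_variants(r), "T16189C")
  expect_same_variants(restrict_to_range(h, 1, 16569), h)

  set.seed(11)
  ref <- test_reference()
  for (rep in 1:10) {
    h <- random_substitution_haplotype(ref, 16024L, 16365L, sample(1:8, 1L),
                                       covered_range = c(16024, 16365))
    r <- restrict_to_range(h, 16090, 16200)
    expect_equal(r$position, h$position[h$position >= 16090 &
                                          h$position <= 16200])
  }
})

test_that("haplotype distance is a metric and equals sequence Hamming distance", {
  b4 <- parse_haplotype("T16189C T16217C", covered_range = c(16090, 16365))
  b4p <- parse_haplotype("C16188T T16189C T16217C",
                         covered_range = c(16090, 16365))
  expect_equal(haplotype_distance(b4, b4), 0L)
  expect_equal(haplotype_distance(b4, b4p), 1L)
  expect_equal(haplotype_distance(b4p, b4), 1L)

  # same slot, different alternate counts once
  h1 <- parse_haplotype("T16189C", covered_range = c(16090, 16365))
  h2 <- parse_haplotype("T16189A", covered_range = c(16090, 16365))
  expect_equal(haplotype_distance(h1, h2), 1L)

  ref <- test_reference()
  set.seed(21)
  for (rep in 1:15) {
    hs <- lapply(1:3, function(i)
      random_substitution_haplotype(ref, 16090L, 16365L, sample(0:6, 1L)))
    # oracle: Hamming distance of reconstructed sequences
    seqs <- lapply(hs, function(h) {
      s <- reconstruct_sequence(ref, h)
      strsplit(substring(s, 16090, 16365), "")[[1L]]
    })
    for (i in 1:2) for (j in (i + 1):3) {
      expect_equal(haplotype_distance(hs[[i]], hs[[j]]),
                   sum(seqs[[i]] != seqs[[j]]))
    }
    d12 <- haplotype_distance(hs[[1]], hs[[2]])
    d13 <- haplotype_distance(hs[[1]], hs[[3]])
    d23 <- haplotype_distance(hs[[2]], hs[[3]])
    expect_lte(d12, d13 + d23)
  }

  expect_error(
    haplotype_distance(h1, parse_haplotype("T16189A",
                                           covered_range = c(16024, 16365))),
    "range")
})

test_that("sample tables round-trip through write and read", {
  ref <- test_reference()
  set.seed(33)
  n <- 30L
  haps <- lapply(seq_len(n), function(i)
    random_substitution_haplotype(ref, 16090L, 16365L, sample(0:5, 1L)))
  haps[[1L]] <- haplotype(covered_range = c(16090, 16365))  # rCRS-identical
  records <- data.frame(id = sprintf("s%02d", seq_len(n)),
                        population = "pop", locality = "loc",
                        region = c(NA, rep("West-Central", n - 1L)),
                        haplogroup = c(rep(NA, 5L), rep("B4", n - 5L)),
                        stringsAsFactors = FALSE)
  records$haplotype <- I(haps)

  path <- tempfile(fileext = ".tsv")
  write_sample_table(records, path)
  back <- read_sample_table(path, covered_range = c(16090, 16365))
  expect_equal(back$id, records$id)
  expect_equal(back$region, records$region)
  expect_equal(back$haplogroup, records$haplogroup)
  for (i in seq_len(n)) expect_same_variants(back$haplotype[[i]], haps[[i]])

  # schema and duplicate-id errors
  bad <- tempfile(fileext = ".tsv")
  writeLines(c("id\tpopulation\thaplotype", "a\tp\tT16189C"), bad)
  expect_error(read_sample_table(bad), "locality")
  writeLines(c("id\tpopulation\tlocality\thaplotype",
               "a\tp\tl\tT16189C", "a\tp\tl\tT16217C"), bad)
  expect_error(read_sample_table(bad), "duplicate")

  empty <- tempfile(fileext = ".tsv")
  writeLines("id\tpopulation\tlocality\thaplotype", empty)
  expect_equal(nrow(read_sample_table(empty)), 0L)
})
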