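test_that("tree loading validates structure and parses variants", {
  path <- tempfile(fileext = ".json")
  writeLines('{"nodes":[{"name":"R","variants":[]},
                        {"name":"A","parent":"R","variants":["T16189C"]}],
              "continental_map":{"A":"African"}}', path)
  tree <- load_tree(path)
  expect_equal(length(tree$nodes), 2L)
  expect_equal(tree$root, "R")

  writeLines('{"nodes":[{"name":"A","parent":"B","variants":[]},
                        {"name":"B","parent":"A","variants":[]},
                        {"name":"R","variants":[]}],
              "continental_map":{}}', path)
  expect_error(load_tree(path), "cycle")

  writeLines('{"nodes":[{"name":"R","variants":[]},
                        {"name":"R","parent":"R","variants":[]}],
              "continental_map":{}}', path)
  expect_error(load_tree(path), "duplicate")

  writeLines('{"nodes":[{"name":"R","variants":[]},
                        {"name":"A","parent":"Z","variants":[]}],
              "continental_map":{}}', path)
  expect_error(load_tree(path), "unknown parent")

  writeLines('{"nodes":[{"name":"R","variants":["??"]}],
              "continental_map":{}}', path)
  expect_error(load_tree(path), "'R'")
})

test_that("toy tree has the study haplogroups and survives a JSON round trip", {
  tree <- make_toy_tree(1)
  needed <- c("A2", "B4", "C1", "D1", "D4h3a", "HV0", "L0a1b2", "L0a2a2a",
              "L1c3b1a", "L3d1a1a", "L3d1b3")
  expect_true(all(needed %in% names(tree$nodes)))
  expect_gte(length(tree$nodes), 12L)

  path <- tempfile(fileext = ".json")
  write_tree(tree, path)
  back <- load_tree(path)
  expect_equal(names(back$nodes), names(tree$nodes))
  for (nm in names(tree$nodes))
    expect_equal(format_variants(back$nodes[[nm]]$variants),
                 format_variants(tree$nodes[[nm]]$variants))

  # same topology and names but different motifs under another seed
  tree2 <- make_toy_tree(2)
  expect_equal(names(tree2$nodes), names(tree$nodes))
  motif1 <- unlist(lapply(tree$nodes, function(n) format_variants(n$variants)))
  motif2 <- unlist(lapply(tree2$nodes, function(n) format_variants(n$variants)))
  expect_false(identical(motif1, motif2))
})

test_that("classifying a node's exact path motif returns that node with no missing", {
  for (seed in 1:2) {
    tree <- make_toy_tree(seed)
    for (nm in setdiff(names(tree$nodes), "ROOT")) {
      h <- haplotype(path_expected_variants(tree, nm), control_region_range())
      cl <- classify(h, tree)
      expect_equal(cl$haplogroup, nm)
      expect_equal(nrow(cl$missing), 0L)
      expect_equal(nrow(cl$private), 0L)
    }
  }
})

test_that("extra variants become private without changing the call", {
  tree <- make_toy_tree(1)
  h <- parse_haplotype("C16188T T16189C T16217C",
                       covered_range = c(16090, 16365))
  cl <- classify(h, tree)
  expect_equal(cl$haplogroup, "B4")
  expect_equal(format_variants(cl$private), "C16188T")

  # monotone robustness: up to 2 private variants at unused positions
  set.seed(5)
  free <- setdiff(16090:16365, c(tree$positions_used, 16182:16183, 16188))
  bases <- strsplit(tree$reference$bases, "")[[1L]]
  for (nm in c("B4", "L1c3b1a", "C1")) {
    motif <- path_expected_variants(tree, nm)
    for (k in 1:2) {
      pos <- sample(setdiff(free, motif$position), k)
      extra <- do.call(rbind, lapply(pos, function(p)
        parse_variant_token(paste0(
          bases[p], p, popadmix:::.transition_partner[bases[p]]))))
      h <- haplotype(rbind(motif, extra), control_region_range())
      expect_equal(classify(h, tree)$haplogroup, nm)
    }
  }
})

test_that("classification matches an exhaustive scoring oracle", {
  tree <- tiny_tree()
  universe <- do.call(rbind, lapply(names(tree$nodes), function(nm)
    tree$nodes[[nm]]$variants))
  set.seed(9)
  for (rep in 1:40) {
    k <- sample(0:3, 1L)
    v <- universe[sample(nrow(universe), k), , drop = FALSE]
    h <- haplotype(v, c(16090, 16365))
    expect_equal(classify(h, tree)$haplogroup, oracle_classify(h, tree))
  }
  # and on the toy tree with random small haplotypes
  toy <- make_toy_tree(3)
  toyu <- do.call(rbind, lapply(names(toy$nodes), function(nm)
    toy$nodes[[nm]]$variants))
  for (rep in 1:20) {
    v <- toyu[sample(nrow(toyu), sample(1:3, 1L)), , drop = FALSE]
    h <- haplotype(v, control_region_range())
    expect_equal(classify(h, toy)$haplogroup, oracle_classify(h, toy))
  }
})

test_that("back-mutation markers toggle expected variants along the path", {
  nodes <- list(
    list(name = "R", parent = NULL, variants = list("A16111G", "C16112T")),
    list(name = "C", parent = "R", variants = list("@16111", "T16150C")))
  tree <- haplo_tree(nodes, c(C = "African"))
  exp <- path_expected_variants(tree, "C")
  expect_equal(sort(format_variants(exp)), c("C16112T", "T16150C"))
  h <- parse_haplotype("C16112T T16150C", covered_range = c(16090, 16365))
  cl <- classify(h, tree)
  expect_equal(cl$haplogroup, "C")
  expect_equal(nrow(cl$missing), 0L)
})

test_that("continental ancestry uses longest-prefix matching", {
  tree <- make_toy_tree(1)
  expect_equal(continental_ancestry("L1c3b1a", tree), "African")
  expect_equal(continental_ancestry("HV0", tree), "European")
  expect_equal(continental_ancestry("B4", tree), "NativeAmerican")
  expect_equal(continental_ancestry("M", tree), "Other")
  expect_equal(continental_ancestry("N", tree), "Other")
  expect_warning(out <- continental_ancestry("Q9", tree), "Other")
  expect_equal(out, "Other")
})

test_that("ancestry partition counts, proportions and rounding behave", {
  tree <- make_toy_tree(1)
  records <- data.frame(
    haplogroup = c(rep("B4", 85L), rep("L1c3b1a", 19L), "HV0"),
    stringsAsFactors = FALSE)
  part <- ancestry_partition(records, tree)
  expect_equal(unname(part$percent[c("NativeAmerican", "African", "European")]),
               c(81, 18, 1))
  expect_equal(sum(part$proportions), 1)

  one <- ancestry_partition(data.frame(haplogroup = rep("B4", 7L)), tree)
  expect_equal(unname(one$percent["NativeAmerican"]), 100)

  set.seed(13)
  pool <- c("B4", "C1", "L0a1b2", "L3d1b3", "HV0", "A2")
  for (rep in 1:10) {
    hg <- sample(pool, sample(5:60, 1L), replace = TRUE)
    part <- ancestry_partition(data.frame(haplogroup = hg), tree)
    # tally oracle
    lab <- vapply(hg, continental_ancestry, character(1), tree = tree)
    tab <- table(lab)
    expect_setequal(names(part$counts), names(tab))
    for (nm in names(tab))
      expect_equal(unname(part$counts[nm]), unname(as.integer(tab[nm])))
    expect_equal(sum(part$proportions), 1)
    expect_lte(abs(sum(part$percent) - 100), 1)
  }

  expect_error(ancestry_partition(data.frame(haplogroup = character(0)), tree),
               "no records")
})

test_that("clade composition reproduces macro-region shares", {
  members <- data.frame(
    id = c("Toc293", "Toc295", "Toc304", "Kenya1", "Zambia1", "Fang1",
           "Pygmy1", "Morocco1", "PuertoRico1"),
    origin = c("Bolivia", "Bolivia", "Bolivia", "Kenya", "Zambia", "Fang",
               "Pygmy", "Morocco", "PuertoRico"),
    stringsAsFactors = FALSE)
  grouping <- c(Bolivia = "Americas", PuertoRico = "Americas",
                Kenya = "EastAfrica", Zambia = "SoutheastAfrica",
                Fang = "WestCentralAfrica", Pygmy = "WestCentralAfrica",
                Morocco = "NorthAfrica")
  comp <- clade_composition(members, grouping)
  expect_equal(unname(comp$percent["Americas"]), 44)
  expect_equal(sum(comp$counts), 9L)

  single <- clade_composition(members[1L, ], grouping)
  expect_equal(unname(single$percent["Americas"]), 100)

  expect_error(clade_composition(data.frame(id = "x", origin = "Atlantis"),
                                 grouping), "Atlantis")

  set.seed(17)
  for (rep in 1:10) {
    org <- sample(names(grouping), sample(3:20, 1L), replace = TRUE)
    comp <- clade_composition(data.frame(id = seq_along(org), origin = org),
                              grouping)
    tab <- table(unname(grouping[org]))
    expect_setequal(names(comp$counts), names(tab))
    for (nm in names(tab))
      expect_equal(unname(comp$counts[nm]), unname(as.integer(tab[nm])))
  }
})

test_that("private mutations are the set difference from the path expectation", {
  tree <- make_toy_tree(1)
  motif <- path_expected_variants(tree, "L1c3b1a")
  h <- haplotype(motif, control_region_range())
  expect_equal(nrow(private_mutations(h, "L1c3b1a", tree)), 0L)

  extra <- parse_variant_token("C16188T")
  h2 <- haplotype(rbind(motif, extra), control_region_range())
  expect_equal(format_variants(private_mutations(h2, "L1c3b1a", tree)),
               "C16188T")
  expect_error(private_mutations(h2, "NOPE", tree), "unknown")
})
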