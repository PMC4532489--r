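# Shared fixtures, all built in code.

# Deterministic full-length reference: base depends on position so specific
# positions can be pinned without randomness.
test_reference <- function() {
  bases <- rep(c("A", "C", "G", "T"), length.out = 16400L)
  pin <- c("152" = "C", "309" = "C", "16093" = "T", "16166" = "C",
           "16182" = "A", "16183" = "A", "16188" = "C", "16189" = "T",
           "16217" = "T", "16223" = "C")
  bases[as.integer(names(pin))] <- pin
  reference_segment("test-rCRS", 1L, paste(bases, collapse = ""))
}

# records data frame from a list of haplotypes
hap_records <- function(haps) {
  df <- data.frame(id = sprintf("s%03d", seq_along(haps)),
                   stringsAsFactors = FALSE)
  df$haplotype <- I(haps)
  df
}

# random substitution-only haplotype over a reference window; avoids the
# positions that normalization excludes so raw-set oracles stay aligned
random_substitution_haplotype <- function(reference, start, end, k,
                                          covered_range = c(start, end)) {
  pos <- sort(sample(setdiff(seq.int(start, end), c(16182L, 16183L)), k))
  vs <- do.call(rbind, lapply(pos, function(p) {
    refb <- ref_base(reference, p)
    alt <- sample(setdiff(c("A", "C", "G", "T"), refb), 1L)
    parse_variant_token(paste0(refb, p, alt))
  }))
  if (is.null(vs)) vs <- popadmix:::.empty_variants()
  haplotype(vs, covered_range)
}

# hand-built 5-node tree with known motifs for oracle checks
tiny_tree <- function() {
  nodes <- list(
    list(name = "R", parent = NULL, variants = list()),
    list(name = "X", parent = "R", variants = list("A16111G", "C16112T")),
    list(name = "X1", parent = "X", variants = list("G16140A")),
    list(name = "X2", parent = "X", variants = list("T16150C", "A16151G")),
    list(name = "Y", parent = "R", variants = list("C16200T", "G16201A")))
  haplo_tree(nodes, c(X = "African", Y = "European"))
}

# independent scorer used as the classification oracle: recomputes
# root-to-node expected sets by its own tree walk and scores every node
oracle_classify <- function(h, tree, penalty = 0.5) {
  range <- attr(h, "covered_range")
  htok <- if (nrow(h) == 0L) character(0)
          else paste0(h$position, ".",
                      ifelse(is.na(h$insertion_index), 0, h$insertion_index),
                      "=", h$alt)
  best <- NULL
  for (nm in names(tree$nodes)) {
    path <- character(0); cur <- nm
    while (!is.na(cur)) { path <- c(cur, path); cur <- tree$nodes[[cur]]$parent }
    exp <- list()
    for (nd in path) {
      v <- tree$nodes[[nd]]$variants
      for (i in seq_len(nrow(v))) {
        key <- paste0(v$position[i], ".",
                      ifelse(is.na(v$insertion_index[i]), 0,
                             v$insertion_index[i]))
        if (v$kind[i] == "back-mutation-marker") exp[[key]] <- NULL
        else exp[[key]] <- v$alt[i]
      }
    }
    if (length(exp) > 0L) {
      pos <- as.numeric(sub("\\..*", "", names(exp)))
      keep <- popadmix:::.in_range(pos, range)
      exp <- exp[keep]
    }
    etok <- if (length(exp) == 0L) character(0)
            else paste0(names(exp), "=", unlist(exp))
    sc <- sum(etok %in% htok) - penalty * sum(!etok %in% htok)
    cand <- list(name = nm, score = sc, depth = length(path) - 1L)
    if (is.null(best) || sc > best$score ||
        (sc == best$score && cand$depth > best$depth) ||
        (sc == best$score && cand$depth == best$depth && nm < best$name))
      best <- cand
  }
  best$name
}

expect_same_variants <- function(h1, h2) {
  expect_equal(format_variants(h1), format_variants(h2))
}
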