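# -- Haplogroup trees ---------------------------------------------------------

#' Build a haplogroup tree from node and map definitions
#'
#' @param nodes list of lists with fields `name`, `parent` (`NULL` for the
#'   root) and `variants` (character vector of tokens in explicit
#'   ref/alt form; `@`-prefixed back-mutation markers allowed).
#' @param continental_map named character vector mapping haplogroup-name
#'   prefixes to ancestry labels (`NativeAmerican`, `African`, `European`,
#'   `Other`); the longest matching prefix wins.
#' @return Object of class `haplo_tree` with fields `nodes` (named list),
#'   `continental_map`, `root` and `depth` (named integer).
#' @export
haplo_tree <- function(nodes, continental_map) {
  names_ <- vapply(nodes, function(n) as.character(n$name), character(1))
  if (anyDuplicated(names_))
    stop(sprintf("duplicate haplogroup name(s): %s",
                 paste(unique(names_[duplicated(names_)]), collapse = ", ")))
  parents <- vapply(nodes, function(n) {
    p <- n$parent
    if (is.null(p) || length(p) == 0L || is.na(p) || !nzchar(p))
      NA_character_ else as.character(p)
  }, character(1))
  roots <- which(is.na(parents))
  if (length(roots) != 1L)
    stop(sprintf("tree must have exactly one root, found %d", length(roots)))
  bad <- !is.na(parents) & !(parents %in% names_)
  if (any(bad))
    stop(sprintf("node '%s' has unknown parent '%s'",
                 names_[bad][1L], parents[bad][1L]))

  parsed <- vector("list", length(nodes))
  for (i in seq_along(nodes)) {
    toks <- unlist(nodes[[i]]$variants)
    parsed[[i]] <- tryCatch({
      if (length(toks) == 0L) .empty_variants()
      else do.call(rbind, lapply(toks, parse_variant_token,
                                 allow_back_mutation = TRUE))
    }, error = function(e)
      stop(sprintf("node '%s': %s", names_[i], conditionMessage(e)),
           call. = FALSE))
  }

  # depths double as the cycle check: walking to the root must terminate
  depth <- integer(length(names_)); names(depth) <- names_
  for (i in seq_along(names_)) {
    d <- 0L; cur <- names_[i]; seen <- character(0)
    while (!is.na(parents[match(cur, names_)])) {
      if (cur %in% seen)
        stop(sprintf("cycle in tree involving node '%s'", cur))
      seen <- c(seen, cur)
      cur <- parents[match(cur, names_)]
      d <- d + 1L
      if (d > length(names_))
        stop(sprintf("cycle in tree involving node '%s'", names_[i]))
    }
    depth[i] <- d
  }

  node_list <- stats::setNames(lapply(seq_along(nodes), function(i)
    list(name = names_[i], parent = parents[i], variants = parsed[[i]])),
    names_)
  structure(list(nodes = node_list, continental_map = continental_map,
                 root = names_[roots], depth = depth),
            class = "haplo_tree")
}

#' @export
print.haplo_tree <- function(x, ...) {
  cat(sprintf("Haplogroup tree: %d nodes, root '%s', %d ancestry prefixes\n",
              length(x$nodes), x$root, length(x$continental_map)))
  invisible(x)
}

#' Load a haplogroup tree from JSON
#'
#' Expected document shape:
#' `{"nodes": [{"name", "parent", "variants": [...]}, ...],
#'   "continental_map": {"prefix": "label", ...}}`.
#' Variants must be written in explicit ref/alt form (`"T16189C"`,
#' `"309.1C"`, `"C16166d"`, `"@152"`) so that no reference sequence is
#' needed at load time.
#'
#' @param path JSON file.
#' @return A [haplo_tree()].
#' @export
load_tree <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(doc$nodes) || is.null(doc$continental_map))
    stop("tree JSON must have 'nodes' and 'continental_map' entries")
  map <- unlist(doc$continental_map)
  haplo_tree(doc$nodes, map)
}

#' Write a haplogroup tree to JSON
#'
#' @param tree a [haplo_tree()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_tree <- function(tree, path) {
  nodes <- lapply(tree$nodes, function(n) {
    out <- list(name = n$name, variants = as.list(format_variants(n$variants)))
    if (!is.na(n$parent)) out$parent <- n$parent
    out
  })
  doc <- list(nodes = unname(nodes),
              continental_map = as.list(tree$continental_map))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

.path_to_root <- function(tree, name) {
  out <- character(0); cur <- name
  while (!is.na(cur)) {
    out <- c(cur, out)
    cur <- tree$nodes[[cur]]$parent
  }
  out
}

#' Expected variant set along the root-to-node path
#'
#' Accumulates each node's defining variants from the root down.  A
#' back-mutation marker (`@`) toggles off the variant previously expected
#' at its (position, insertion index) slot, in path order.
#'
#' @param tree a [haplo_tree()].
#' @param name node name.
#' @return Variant data frame (substitutions/indels only, markers applied).
#' @export
path_expected_variants <- function(tree, name) {
  if (!name %in% names(tree$nodes))
    stop(sprintf("unknown haplogroup '%s'", name))
  expected <- .empty_variants()
  for (nd in .path_to_root(tree, name)) {
    v <- tree$nodes[[nd]]$variants
    for (i in seq_len(nrow(v))) {
      key <- paste(v$position[i],
                   ifelse(is.na(v$insertion_index[i]), 0L,
                          v$insertion_index[i]))
      ekeys <- paste(expected$position,
                     ifelse(is.na(expected$insertion_index), 0L,
                            expected$insertion_index))
      if (v$kind[i] == "back-mutation-marker") {
        expected <- expected[ekeys != key, , drop = FALSE]
      } else {
        expected <- rbind(expected[ekeys != key, , drop = FALSE], v[i, ])
      }
    }
  }
  rownames(expected) <- NULL
  expected
}

.variant_tokens <- function(v) {
  if (nrow(v) == 0L) return(character(0))
  paste0(v$position, ".", ifelse(is.na(v$insertion_index), 0L,
                                 v$insertion_index), "=", v$alt)
}

.score_node <- function(h_tokens, h_keys, expected, range, penalty = 0.5) {
  if (nrow(expected) > 0L) {
    keep <- .in_range(expected$position, range)
    expected <- expected[keep, , drop = FALSE]
  }
  e_tokens <- .variant_tokens(expected)
  matched <- e_tokens %in% h_tokens
  score <- sum(matched) - penalty * sum(!matched)
  list(score = score, matched = expected[matched, , drop = FALSE],
       missing = expected[!matched, , drop = FALSE], tokens = e_tokens)
}

#' Classify a haplotype against a haplogroup tree
#'
#' Scores every node as `|matched| - penalty * |missing|`, where the
#' expected set is the node's root-to-node variant accumulation restricted
#' to the sample's covered range (so a control-region-only sample is not
#' penalized for coding-region motifs).  Ties are broken by greater path
#' depth, then lexicographically smaller name.  All variants weigh
#' equally.
#'
#' @param h a normalized [haplotype()].
#' @param tree a [haplo_tree()].
#' @param penalty score deduction per expected-but-missing variant.
#' @return Object of class `haplo_classification`: list with `haplogroup`,
#'   `score`, `ancestry`, and variant data frames `matched`, `missing`,
#'   `private`.
#' @export
classify <- function(h, tree, penalty = 0.5) {
  if (length(tree$nodes) == 0L) stop("empty tree")
  range <- attr(h, "covered_range")
  h_tokens <- .hap_tokens(h); h_keys <- .hap_keys(h)
  names_ <- names(tree$nodes)
  scored <- lapply(names_, function(nm)
    .score_node(h_tokens, h_keys, path_expected_variants(tree, nm),
                range, penalty))
  scores <- vapply(scored, `[[`, numeric(1), "score")
  best <- max(scores)
  cand <- names_[scores == best]
  if (length(cand) > 1L) {
    d <- tree$depth[cand]
    cand <- cand[d == max(d)]
    cand <- sort(cand)[1L]
  }
  win <- scored[[match(cand, names_)]]
  hv <- as.data.frame(h)
  private <- hv[!(.hap_tokens(h) %in% win$tokens), , drop = FALSE]
  rownames(private) <- NULL
  structure(list(haplogroup = cand, score = best,
                 ancestry = continental_ancestry(cand, tree, warn = FALSE),
                 matched = win$matched, missing = win$missing,
                 private = private),
            class = "haplo_classification")
}

#' @export
print.haplo_classification <- function(x, ...) {
  cat(sprintf("Haplogroup %s (score %.1f, ancestry %s); %d matched, %d missing, %d private\n",
              x$haplogroup, x$score, x$ancestry, nrow(x$matched),
              nrow(x$missing), nrow(x$private)))
  invisible(x)
}

#' Continental ancestry of a haplogroup name
#'
#' Longest-prefix match in the tree's continental map.  Conventionally the
#' L clades (excluding the out-of-Africa macro-haplogroups M and N) map to
#' African, the pan-American A2/B2/B4/C1/D1/D4 clades to NativeAmerican,
#' and the west-Eurasian H/HV/J/K/T/U/V/W/X clades to European; bare M and
#' N stay Other.
#'
#' @param name haplogroup name.
#' @param tree a [haplo_tree()] (its `continental_map` is used).
#' @param warn warn when no prefix matches (the result is then `"Other"`).
#' @return Ancestry label string.
#' @export
continental_ancestry <- function(name, tree, warn = TRUE) {
  stopifnot(nzchar(name))
  map <- tree$continental_map
  prefixes <- names(map)
  hit <- prefixes[startsWith(name, prefixes)]
  if (length(hit) == 0L) {
    if (warn) warning(sprintf("no ancestry prefix matches '%s'; using Other",
                              name))
    return("Other")
  }
  unname(map[hit[which.max(nchar(hit))]])
}

#' Continental ancestry partition of a sample set
#'
#' Counts samples per ancestry label (using stored haplogroup labels, or
#' classifying on the fly when absent) and returns proportions together
#' with a nearest-integer rounded-percent view.
#'
#' @param records sample data frame from [read_sample_table()] (or any data
#'   frame with a `haplogroup` column, plus `haplotype` for unlabelled
#'   rows).
#' @param tree a [haplo_tree()].
#' @return Object of class `ancestry_partition`: list with `counts`,
#'   `proportions`, `percent` (named numeric vectors) and `n`.
#' @export
ancestry_partition <- function(records, tree) {
  n <- nrow(records)
  if (is.null(n) || n == 0L) stop("no records to partition")
  hg <- records$haplogroup
  if (is.null(hg)) hg <- rep(NA_character_, n)
  for (i in which(is.na(hg))) {
    if (is.null(records$haplotype))
      stop("records without haplogroup labels need a 'haplotype' column")
    hg[i] <- classify(records$haplotype[[i]], tree)$haplogroup
  }
  labels <- vapply(hg, continental_ancestry, character(1), tree = tree,
                   warn = FALSE)
  counts <- table(factor(labels,
                         levels = unique(c(unname(tree$continental_map),
                                           "Other"))))
  counts <- counts[counts > 0 | names(counts) %in% unique(labels)]
  counts <- stats::setNames(as.integer(counts), names(counts))
  props <- counts / n
  structure(list(counts = counts, proportions = props,
                 percent = round(100 * props), n = n),
            class = "ancestry_partition")
}

#' @export
print.ancestry_partition <- function(x, ...) {
  df <- data.frame(label = names(x$counts), count = x$counts,
                   proportion = round(x$proportions, 4),
                   percent = x$percent, row.names = NULL)
  cat(sprintf("Ancestry partition of %d samples:\n", x$n))
  print(df)
  invisible(x)
}

#' Macro-regional composition of a clade
#'
#' Given clade members with origin labels (countries/populations) and a
#' mapping of origins to macro-regions, returns the proportion of members
#' per macro-region (e.g. the share of the Americas within an mtDNA
#' sub-clade).
#'
#' @param members data frame with columns `id` and `origin`.
#' @param grouping named character vector mapping origin to macro-region.
#' @return List with `counts`, `proportions`, `percent` and `n`.
#' @export
clade_composition <- function(members, grouping) {
  stopifnot(is.data.frame(members), all(c("id", "origin") %in% names(members)))
  unmapped <- setdiff(unique(members$origin), names(grouping))
  if (length(unmapped) > 0L)
    stop(sprintf("origin(s) not mapped to a macro-region: %s",
                 paste(unmapped, collapse = ", ")))
  region <- unname(grouping[members$origin])
  counts <- table(region)
  counts <- stats::setNames(as.integer(counts), names(counts))
  n <- nrow(members)
  props <- counts / n
  list(counts = counts, proportions = props, percent = round(100 * props),
       n = n)
}

#' Variants of a haplotype not explained by a haplogroup
#'
#' @param h a [haplotype()].
#' @param node_name haplogroup whose root-to-node expected set is used.
#' @param tree a [haplo_tree()].
#' @return Variant data frame of private mutations.
#' @export
private_mutations <- function(h, node_name, tree) {
  expected <- path_expected_variants(tree, node_name)
  range <- attr(h, "covered_range")
  if (nrow(expected) > 0L)
    expected <- expected[.in_range(expected$position, range), , drop = FALSE]
  e_tokens <- .variant_tokens(expected)
  hv <- as.data.frame(h)
  out <- hv[!(.hap_tokens(h) %in% e_tokens), , drop = FALSE]
  rownames(out) <- NULL
  out
}
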