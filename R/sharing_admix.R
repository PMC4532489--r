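# -- Haplotype-sharing admixture ----------------------------------------------
#
# Sub-continental admixture of a set of target mtDNA haplotypes is
# estimated by sharing against region-labelled reference databases: a
# target matches a database haplotype when their step-mutation distance is
# at most m (P0/P1/P2 for m = 0, 1, 2).  Matching targets are allocated
# across regions in proportion to the relative frequency of their matches
# in each regional database, and the per-region proportions are averaged
# over matched targets.

#' Build region-labelled haplotype databases
#'
#' Normalizes and range-restricts haplotypes, then aggregates identical
#' haplotypes per region with counts.
#'
#' @param records sample data frame with a `region` column and a
#'   `haplotype` list-column (see [read_sample_table()]).
#' @param range common coordinate range, default HVS-I 16090-16365.
#' @param normalize normalize haplotypes first.
#' @return Named list of `region_db` objects (fields `region`,
#'   `haplotypes`, `tokens`, `counts`, `size`), with attributes `range`.
#' @export
build_region_db <- function(records, range = c(16090L, 16365L),
                            normalize = TRUE) {
  if (is.null(records$region) || anyNA(records$region))
    stop("every database record needs a region label")
  haps <- .prepare_haps(records, range, normalize)
  keys <- vapply(haps, function(h) paste(.hap_tokens(h), collapse = " "),
                 character(1))
  out <- list()
  for (r in unique(records$region)) {
    idx <- which(records$region == r)
    if (length(idx) == 0L) {
      warning(sprintf("region '%s' is empty; dropped", r))
      next
    }
    tab <- table(keys[idx])
    first <- idx[!duplicated(keys[idx])]
    ord <- match(keys[first], names(tab))
    db <- structure(list(
      region = r,
      haplotypes = haps[first],
      tokens = lapply(haps[first], .hap_tokens),
      counts = as.numeric(tab[ord]),
      size = length(idx)), class = "region_db")
    out[[r]] <- db
  }
  structure(out, range = as.integer(range), class = "region_db_list")
}

#' @export
`[.region_db_list` <- function(x, i) {
  structure(NextMethod(), range = attr(x, "range"),
            class = "region_db_list")
}

#' @export
print.region_db_list <- function(x, ...) {
  for (db in x)
    cat(sprintf("%-14s N = %5d (%d distinct haplotypes)\n",
                db$region, db$size, length(db$counts)))
  invisible(x)
}

# sparse pattern matrix: one row per haplotype, one column per token
.indicator_matrix <- function(token_lists, universe) {
  lens <- lengths(token_lists)
  i <- rep(seq_along(token_lists), lens)
  j <- match(unlist(token_lists), universe)
  Matrix::sparseMatrix(i = i, j = j, x = 1,
                       dims = c(length(token_lists), length(universe)))
}

# exact step-mutation distance matrix between two haplotype collections:
# d = |A| + |B| - (shared keys) - (shared full tokens); a slot where both
# carry a variant with different alternates counts once.
.distance_matrix <- function(tokens1, tokens2) {
  keys1 <- lapply(tokens1, function(t) sub("=.*", "", t))
  keys2 <- lapply(tokens2, function(t) sub("=.*", "", t))
  tok_univ <- unique(c(unlist(tokens1), unlist(tokens2)))
  key_univ <- unique(c(unlist(keys1), unlist(keys2)))
  if (length(tok_univ) == 0L)
    return(matrix(0, length(tokens1), length(tokens2)))
  Tt <- .indicator_matrix(tokens1, tok_univ)
  Et <- .indicator_matrix(tokens2, tok_univ)
  Tk <- .indicator_matrix(keys1, key_univ)
  Ek <- .indicator_matrix(keys2, key_univ)
  shared_tok <- as.matrix(Matrix::tcrossprod(Tt, Et))
  shared_key <- as.matrix(Matrix::tcrossprod(Tk, Ek))
  outer(lengths(tokens1), lengths(tokens2), "+") - shared_key - shared_tok
}

.check_db_range <- function(h, dbs) {
  range <- attr(dbs, "range")
  hr <- attr(h, "covered_range")
  if (!(nrow(hr) == 1L && hr[1L, 1L] == range[1L] && hr[1L, 2L] == range[2L]))
    stop(sprintf("target covers a different range than the databases (%d-%d)",
                 range[1L], range[2L]))
}

#' Count database haplotypes within m mutation steps of a target
#'
#' @param target a normalized [haplotype()] restricted to the database
#'   range.
#' @param db one `region_db` element of [build_region_db()].
#' @param m step-mutation tolerance (0, 1 or 2 by convention).
#' @return Number of database haplotypes (counting multiplicity) within
#'   `m` steps.
#' @export
match_counts <- function(target, db, m) {
  d <- .distance_matrix(list(.hap_tokens(target)), db$tokens)[1L, ]
  sum(db$counts[d <= m])
}

#' Allocate one target across regions
#'
#' Computes per-region relative match frequencies `f_r = c_r / N_r` and
#' normalized weights `w_r = f_r / sum(f)`.  Relative frequencies (rather
#' than raw counts) are used by default because regional databases can
#' differ in size by more than an order of magnitude.
#'
#' @param target a normalized, range-restricted [haplotype()].
#' @param dbs a `region_db_list` from [build_region_db()].
#' @param m step-mutation tolerance.
#' @param weight_mode `"relative"` (default) or `"raw"` (sensitivity
#'   analysis: weights proportional to raw match counts).
#' @return Named numeric weight vector summing to 1, or `NULL` when the
#'   target matches nowhere.
#' @export
allocate_target <- function(target, dbs, m, weight_mode = c("relative", "raw")) {
  weight_mode <- match.arg(weight_mode)
  stopifnot(length(dbs) >= 1L)
  .check_db_range(target, dbs)
  cr <- vapply(dbs, function(db) match_counts(target, db, m), numeric(1))
  Nr <- vapply(dbs, function(db) db$size, numeric(1))
  f <- if (weight_mode == "relative") cr / Nr else cr
  if (sum(f) == 0) return(NULL)
  f / sum(f)
}

# weight matrix for a set of targets: rows sum to 1 (or are all-NA when
# unmatched); built from precomputed distance matrices for speed
.weight_matrix <- function(target_tokens, dbs, m,
                           weight_mode = "relative",
                           dists = NULL, counts = NULL) {
  R <- length(dbs)
  Tn <- length(target_tokens)
  if (is.null(dists))
    dists <- lapply(dbs, function(db) .distance_matrix(target_tokens,
                                                       db$tokens))
  if (is.null(counts)) counts <- lapply(dbs, function(db) db$counts)
  Nr <- vapply(dbs, function(db) db$size, numeric(1))
  C <- matrix(0, Tn, R, dimnames = list(NULL, names(dbs)))
  for (r in seq_len(R))
    C[, r] <- (dists[[r]] <= m) %*% counts[[r]]
  FF <- if (weight_mode == "relative") sweep(C, 2L, Nr, "/") else C
  tot <- rowSums(FF)
  W <- FF / tot          # rows with tot == 0 become NaN
  W[tot == 0, ] <- NA_real_
  W
}

#' Haplotype-sharing admixture estimate
#'
#' `P_r` is the average allocation weight over matched targets; targets
#' matching no database at tolerance `m` are excluded from the
#' normalization and reported through `coverage`.  Targets are counted per
#' individual, so repeated haplotypes contribute once per carrier (set
#' `per_haplotype = TRUE` to collapse identical targets first).
#'
#' @param targets sample data frame with a `haplotype` list-column, or a
#'   list of [haplotype()] objects.
#' @param dbs a `region_db_list` from [build_region_db()].
#' @param m step-mutation tolerance.
#' @param weight_mode see [allocate_target()].
#' @param per_haplotype collapse identical target haplotypes before
#'   estimating.
#' @param normalize normalize/restrict targets to the database range.
#' @return Object of class `admixture_estimate`: list with `m`, `P` (named
#'   proportions summing to 1), `coverage`, `n_targets`, `n_matched`,
#'   `weights` (per-target matrix) and `unmatched` (indices).
#' @export
estimate_admixture <- function(targets, dbs, m, weight_mode = "relative",
                               per_haplotype = FALSE, normalize = TRUE) {
  range <- attr(dbs, "range")
  haps <- .prepare_haps(targets, range, normalize)
  toks <- lapply(haps, .hap_tokens)
  if (per_haplotype) {
    keys <- vapply(toks, paste, character(1), collapse = " ")
    toks <- toks[!duplicated(keys)]
  }
  W <- .weight_matrix(toks, dbs, m, weight_mode)
  matched <- !is.na(W[, 1L])
  if (!any(matched))
    stop(sprintf("no target matched any database at m = %d", m))
  P <- colMeans(W[matched, , drop = FALSE])
  structure(list(m = m, P = P, coverage = mean(matched),
                 n_targets = nrow(W), n_matched = sum(matched),
                 weights = W, unmatched = which(!matched)),
            class = "admixture_estimate")
}

#' @export
print.admixture_estimate <- function(x, ...) {
  cat(sprintf("Haplotype-sharing admixture at m = %d (%d/%d targets matched):\n",
              x$m, x$n_matched, x$n_targets))
  print(round(x$P, 4))
  invisible(x)
}

#' Bootstrap confidence intervals for admixture proportions
#'
#' Percentile 95% intervals over `B` replicate estimates.  Scheme
#' `"databases"` (default) resamples each regional database with
#' replacement preserving its size; `"targets"` resamples target
#' individuals with replacement; `"both"` does both.  Replicates in which
#' no target matches are skipped and counted; more than 50% skipped is an
#' error.
#'
#' @inheritParams estimate_admixture
#' @param B number of bootstrap replicates.
#' @param seed integer seed (results are reproducible for a fixed seed).
#' @param scheme resampling scheme.
#' @param conf confidence level.
#' @return Data frame with columns `region`, `ci_low`, `ci_high`;
#'   attribute `skipped` gives the number of degenerate replicates.
#' @export
bootstrap_ci <- function(targets, dbs, m, B = 1000L, seed = 1L,
                         scheme = c("databases", "targets", "both"),
                         weight_mode = "relative", normalize = TRUE,
                         conf = 0.95) {
  scheme <- match.arg(scheme)
  stopifnot(B >= 1L)
  range <- attr(dbs, "range")
  haps <- .prepare_haps(targets, range, normalize)
  toks <- lapply(haps, .hap_tokens)
  Tn <- length(toks); R <- length(dbs)
  Nr <- vapply(dbs, function(db) db$size, numeric(1))
  dists <- lapply(dbs, function(db) .distance_matrix(toks, db$tokens))
  match_ind <- lapply(dists, function(d) (d <= m) * 1)   # T x E_r
  counts0 <- lapply(dbs, function(db) db$counts)

  set.seed(as.integer(seed))
  reps <- matrix(NA_real_, B, R, dimnames = list(NULL, names(dbs)))
  skipped <- 0L
  for (b in seq_len(B)) {
    counts <- counts0
    if (scheme %in% c("databases", "both")) {
      counts <- lapply(seq_len(R), function(r)
        as.numeric(stats::rmultinom(1L, Nr[r], counts0[[r]] / Nr[r])))
    }
    C <- matrix(0, Tn, R)
    for (r in seq_len(R)) C[, r] <- match_ind[[r]] %*% counts[[r]]
    FF <- if (weight_mode == "relative") sweep(C, 2L, Nr, "/") else C
    idx <- if (scheme %in% c("targets", "both"))
      sample.int(Tn, Tn, replace = TRUE) else seq_len(Tn)
    FF <- FF[idx, , drop = FALSE]
    tot <- rowSums(FF)
    ok <- tot > 0
    if (!any(ok)) { skipped <- skipped + 1L; next }
    W <- FF[ok, , drop = FALSE] / tot[ok]
    reps[b, ] <- colMeans(W)
  }
  if (skipped > B / 2)
    stop(sprintf("%d of %d bootstrap replicates had no matching target",
                 skipped, B))
  alpha <- (1 - conf) / 2
  qs <- apply(reps, 2L, stats::quantile,
              probs = c(alpha, 1 - alpha), na.rm = TRUE)
  out <- data.frame(region = names(dbs), ci_low = qs[1L, ],
                    ci_high = qs[2L, ], row.names = NULL,
                    stringsAsFactors = FALSE)
  attr(out, "skipped") <- skipped
  out
}

#' Full admixture table over several step tolerances
#'
#' One estimate (with bootstrap CI) per tolerance in `m_values`, laid out
#' one region per row with `P<m>`, `P<m>_low`, `P<m>_high` columns --
#' the publication-style P0/P1/P2 table.
#'
#' @inheritParams bootstrap_ci
#' @param m_values step tolerances (default `c(0, 1, 2)`).
#' @return Object of class `admixture_table` (a data frame); attribute
#'   `coverage` is a named vector of per-m coverage fractions.
#' @export
admixture_table <- function(targets, dbs, m_values = c(0L, 1L, 2L),
                            B = 1000L, seed = 1L,
                            scheme = c("databases", "targets", "both"),
                            weight_mode = "relative", normalize = TRUE) {
  scheme <- match.arg(scheme)
  out <- data.frame(region = names(dbs), stringsAsFactors = FALSE)
  coverage <- stats::setNames(numeric(length(m_values)),
                              paste0("P", m_values))
  for (i in seq_along(m_values)) {
    m <- m_values[i]
    est <- estimate_admixture(targets, dbs, m, weight_mode,
                              normalize = normalize)
    ci <- bootstrap_ci(targets, dbs, m, B = B, seed = seed, scheme = scheme,
                       weight_mode = weight_mode, normalize = normalize)
    out[[paste0("P", m)]] <- unname(est$P)
    out[[paste0("P", m, "_low")]] <- ci$ci_low
    out[[paste0("P", m, "_high")]] <- ci$ci_high
    coverage[i] <- est$coverage
  }
  attr(out, "coverage") <- coverage
  class(out) <- c("admixture_table", "data.frame")
  out
}

#' @export
print.admixture_table <- function(x, ...) {
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round, 4)
  print(df)
  cov <- attr(x, "coverage")
  cat("coverage:", paste(sprintf("%s = %.2f", names(cov), cov),
                         collapse = ", "), "\n")
  invisible(x)
}
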