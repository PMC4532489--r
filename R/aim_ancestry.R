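# -- Supervised ancestry from ancestry-informative markers --------------------
#
# Biallelic genotypes are coded 0/1/2 (copies of allele 1, NA = missing).
# Reference allele frequencies are fixed from labelled panels; individual
# ancestry q on the K-simplex maximizes the multinomial likelihood of the
# observed gene copies via EM.

#' Genotype panel
#'
#' @param genotypes integer matrix, individuals x loci, values 0/1/2/NA.
#' @param ids individual identifiers.
#' @param populations population labels per individual.
#' @param loci locus identifiers.
#' @return Object of class `genotype_panel`.
#' @export
genotype_panel <- function(genotypes, ids = rownames(genotypes),
                           populations = rep(NA_character_, nrow(genotypes)),
                           loci = colnames(genotypes)) {
  genotypes <- as.matrix(genotypes)
  if (is.null(ids)) ids <- paste0("ind", seq_len(nrow(genotypes)))
  if (is.null(loci)) loci <- paste0("locus", seq_len(ncol(genotypes)))
  stopifnot(length(ids) == nrow(genotypes),
            length(populations) == nrow(genotypes),
            length(loci) == ncol(genotypes))
  vals <- genotypes[!is.na(genotypes)]
  if (length(vals) > 0L && !all(vals %in% c(0, 1, 2)))
    stop("genotypes must be 0, 1, 2 or NA")
  dimnames(genotypes) <- list(ids, loci)
  structure(list(genotypes = genotypes, ids = ids,
                 populations = as.character(populations), loci = loci),
            class = "genotype_panel")
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat(sprintf("Genotype panel: %d individuals x %d loci (%d populations)\n",
              length(x$ids), length(x$loci),
              length(unique(x$populations[!is.na(x$populations)]))))
  invisible(x)
}

#' Read a genotype table
#'
#' TSV with columns `id`, `population`, then one column per locus with
#' values 0/1/2 or NA.
#'
#' @param path TSV file.
#' @return A [genotype_panel()].
#' @export
read_genotype_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("id", "population") %in% names(df)))
    stop("genotype table needs 'id' and 'population' columns")
  loci <- setdiff(names(df), c("id", "population"))
  G <- as.matrix(df[, loci, drop = FALSE])
  storage.mode(G) <- "integer"
  genotype_panel(G, ids = df$id, populations = df$population, loci = loci)
}

#' Write a genotype table
#'
#' @param panel a [genotype_panel()].
#' @param path output TSV file.
#' @return `path`, invisibly.
#' @export
write_genotype_table <- function(panel, path) {
  df <- data.frame(id = panel$ids, population = panel$populations,
                   panel$genotypes, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Reference allele frequencies from labelled panels
#'
#' Per locus and population, `f = (x + pseudocount) / (2 n + 2 pseudocount)`
#' where `x` is the allele-1 count over non-missing genotypes and `n` the
#' number of non-missing individuals.  The Jeffreys-style pseudocount
#' keeps frequencies strictly inside (0, 1) so any genotype has finite
#' likelihood.
#'
#' @param panel a [genotype_panel()] of reference individuals.
#' @param labels populations to use (default: all labelled).
#' @param pseudocount smoothing constant, default 0.5.
#' @return Matrix loci x populations of allele-1 frequencies, class
#'   `allele_frequencies`.
#' @export
reference_frequencies <- function(panel, labels = NULL, pseudocount = 0.5) {
  pops <- panel$populations
  if (is.null(labels)) labels <- unique(pops[!is.na(pops)])
  stopifnot(length(labels) >= 1L)
  G <- panel$genotypes
  FF <- matrix(NA_real_, ncol(G), length(labels),
               dimnames = list(panel$loci, labels))
  for (k in seq_along(labels)) {
    rows <- which(pops == labels[k])
    if (length(rows) == 0L)
      stop(sprintf("no reference individuals labelled '%s'", labels[k]))
    sub <- G[rows, , drop = FALSE]
    x <- colSums(sub, na.rm = TRUE)
    n <- colSums(!is.na(sub))
    if (any(n == 0L))
      warning(sprintf(
        "population '%s' has all-missing locus/loci; frequency from pseudocount alone",
        labels[k]))
    FF[, k] <- (x + pseudocount) / (2 * n + 2 * pseudocount)
  }
  structure(FF, class = c("allele_frequencies", "matrix", "array"))
}

#' Supervised individual ancestry by EM
#'
#' Maximizes `sum_l [g_l log(sum_r q_r f_lr) + (2 - g_l) log(sum_r q_r
#' (1 - f_lr))]` over the K-simplex.  The EM step computes, for each gene
#' copy, the responsibility of each ancestral population, and updates `q`
#' as the mean responsibility over the `2 L'` non-missing gene copies.
#' The log-likelihood is non-decreasing across iterations.  When all
#' populations have identical frequencies the likelihood is flat and the
#' uniform vector is returned as converged.
#'
#' @param genotype_row integer vector of 0/1/2/NA genotypes, one per locus.
#' @param freqs loci x populations matrix from [reference_frequencies()].
#' @param tol convergence tolerance on `max |delta q|`.
#' @param maxiter maximum EM iterations.
#' @return Object of class `ancestry_vector`: list with `q` (named, on the
#'   simplex), `loglik`, `iterations`, `converged` and `loglik_trace`.
#' @export
individual_ancestry <- function(genotype_row, freqs, tol = 1e-7,
                                maxiter = 2000L) {
  g <- as.numeric(genotype_row)
  keep <- !is.na(g)
  if (!any(keep)) stop("no non-missing loci for this individual")
  g <- g[keep]
  A <- freqs[keep, , drop = FALSE]
  K <- ncol(A)
  q <- rep(1 / K, K)
  ll <- function(q) {
    p1 <- as.vector(A %*% q); p0 <- as.vector((1 - A) %*% q)
    sum(g * log(p1) + (2 - g) * log(p0))
  }
  trace <- ll(q)
  L2 <- 2 * length(g)
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(maxiter)) {
    p1 <- as.vector(A %*% q)
    p0 <- as.vector((1 - A) %*% q)
    qnew <- q * (as.vector(crossprod(A, g / p1)) +
                 as.vector(crossprod(1 - A, (2 - g) / p0))) / L2
    qnew <- qnew / sum(qnew)
    trace <- c(trace, ll(qnew))
    delta <- max(abs(qnew - q))
    q <- qnew
    if (delta < tol) { converged <- TRUE; break }
  }
  names(q) <- colnames(A)
  structure(list(q = q, loglik = trace[length(trace)], iterations = iter,
                 converged = converged, loglik_trace = trace),
            class = "ancestry_vector")
}

#' @export
print.ancestry_vector <- function(x, ...) {
  cat(sprintf("Ancestry (loglik %.3f, %d iterations%s): %s\n", x$loglik,
              x$iterations, if (x$converged) "" else ", NOT converged",
              paste(sprintf("%s = %.3f", names(x$q), x$q), collapse = ", ")))
  invisible(x)
}

#' Ancestry vectors for every individual of a panel
#'
#' @param panel a [genotype_panel()] of target individuals.
#' @param freqs reference frequencies.
#' @param ... passed to [individual_ancestry()].
#' @return Matrix individuals x populations of ancestry proportions, with
#'   attribute `converged` (logical vector).
#' @export
panel_ancestry <- function(panel, freqs, ...) {
  res <- lapply(seq_len(nrow(panel$genotypes)), function(i)
    individual_ancestry(panel$genotypes[i, ], freqs, ...))
  Q <- do.call(rbind, lapply(res, `[[`, "q"))
  rownames(Q) <- panel$ids
  attr(Q, "converged") <- vapply(res, `[[`, logical(1), "converged")
  Q
}

#' Mean ancestry per group
#'
#' @param Q individuals x populations ancestry matrix (rows on the
#'   simplex), e.g. from [panel_ancestry()].
#' @param groups group label per individual.
#' @return Matrix groups x populations of mean ancestry, plus a
#'   rounded-percent attribute `percent`.
#' @export
population_ancestry <- function(Q, groups) {
  stopifnot(nrow(Q) == length(groups))
  levs <- unique(groups)
  out <- t(vapply(levs, function(gr) {
    rows <- which(groups == gr)
    if (length(rows) == 0L) stop(sprintf("empty group '%s'", gr))
    colMeans(Q[rows, , drop = FALSE])
  }, numeric(ncol(Q))))
  rownames(out) <- levs
  attr(out, "percent") <- round(100 * out)
  out
}

#' Identity-by-state distance matrix
#'
#' For each pair of individuals, the per-locus allele-sharing score is
#' `IBS_l = 1 - |g_i - g_j| / 2` over loci where both are non-missing, and
#' the distance is `D_ij = 1 - mean(IBS_l)`.
#'
#' @param panel a [genotype_panel()].
#' @return Symmetric matrix with zero diagonal, values in \[0, 1\].
#' @export
ibs_distance <- function(panel) {
  G <- panel$genotypes
  n <- nrow(G)
  if (n < 2L) stop("need at least 2 individuals")
  D <- matrix(0, n, n, dimnames = list(panel$ids, panel$ids))
  for (i in seq_len(n - 1L)) {
    gi <- G[i, ]
    for (j in seq.int(i + 1L, n)) {
      gj <- G[j, ]
      shared <- !is.na(gi) & !is.na(gj)
      if (!any(shared))
        stop(sprintf("individuals '%s' and '%s' share no non-missing loci",
                     panel$ids[i], panel$ids[j]))
      d <- mean(abs(gi[shared] - gj[shared]) / 2)
      D[i, j] <- D[j, i] <- d
    }
  }
  D
}

#' Classical multidimensional scaling of a distance matrix
#'
#' Double-centers the squared distances and eigendecomposes (via
#' [stats::cmdscale()]); coordinates are eigenvectors scaled by the square
#' root of their eigenvalues.  Dimensions with non-positive eigenvalues
#' are dropped (distances need not be Euclidean) and variance fractions
#' are computed over the positive eigenvalues only.
#'
#' @param D symmetric distance matrix with zero diagonal.
#' @param k requested number of dimensions.
#' @return Object of class `mds_result`: list with `coordinates` (n x k',
#'   k' <= k), `eigenvalue_fractions` (length k, zero-padded when
#'   truncated) and `eigenvalues`.
#' @export
classical_mds <- function(D, k = 2L) {
  D <- as.matrix(D)
  stopifnot(nrow(D) == ncol(D), k >= 1L)
  n <- nrow(D)
  fit <- suppressWarnings(stats::cmdscale(D, k = min(k, n - 1L), eig = TRUE))
  ev <- fit$eig
  tol <- if (all(ev == 0)) 0 else max(abs(ev)) * 1e-9
  pos <- ev > tol
  npos <- sum(pos)
  keep <- min(k, npos)
  if (keep < k)
    warning(sprintf("only %d positive eigenvalue(s); returning %d dimension(s)",
                    npos, max(keep, 0L)))
  coords <- if (npos == 0L) matrix(0, n, k)   # degenerate: all at the origin
            else fit$points[, seq_len(keep), drop = FALSE]
  fracs <- numeric(k)
  if (npos > 0L) {
    fr <- ev[seq_len(min(k, length(ev)))] / sum(ev[pos])
    fr[fr < 0] <- 0
    fracs[seq_along(fr)] <- fr
  }
  structure(list(coordinates = coords, eigenvalue_fractions = fracs,
                 eigenvalues = ev), class = "mds_result")
}

#' @export
print.mds_result <- function(x, ...) {
  cat(sprintf("Classical MDS: %d points, %d dimension(s); variance fractions %s\n",
              nrow(x$coordinates), ncol(x$coordinates),
              paste(sprintf("%.1f%%", 100 * x$eigenvalue_fractions),
                    collapse = ", ")))
  invisible(x)
}
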