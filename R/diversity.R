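# -- Sequence diversity indices ----------------------------------------------
#
# All indices are computed on a common coordinate segment (for HVS-I
# conventionally 16090-16365) with a complete-deletion site policy: any
# site at which any sample carries an indel or an ambiguous call is
# removed for all samples before counting.  Haplotypes are normalized and
# range-restricted by the caller or via the `normalize` argument.

.prepare_haps <- function(x, range, normalize = TRUE,
                          policy = normalization_policy()) {
  haps <- .as_haplotype_list(x)
  if (length(haps) == 0L) stop("no haplotypes supplied")
  range <- if (is.null(range)) NULL else as.integer(range)
  lapply(haps, function(h) {
    if (normalize) h <- normalize_haplotype(h, policy)
    if (!is.null(range)) h <- restrict_to_range(h, range[1L], range[2L])
    h
  })
}

#' Sites analyzed under the complete-deletion policy
#'
#' All positions in `range` minus every position at which any sample
#' carries an insertion, deletion or ambiguous (heteroplasmic) call.
#'
#' @param x sample data frame (with a `haplotype` list-column) or list of
#'   [haplotype()] objects.
#' @param range length-2 integer vector of closed 1-based bounds.
#' @param normalize normalize haplotypes first (default `TRUE`).
#' @return Integer vector of analyzed positions.
#' @export
analyzed_sites <- function(x, range = c(16090L, 16365L), normalize = TRUE) {
  if (is.null(range) || range[2L] < range[1L]) stop("empty or invalid range")
  haps <- .prepare_haps(x, range, normalize)
  bad <- integer(0)
  for (h in haps) {
    v <- as.data.frame(h)
    drop <- v$kind %in% c("insertion", "deletion", "heteroplasmy") |
      v$alt %in% .IUPAC_AMBIG
    bad <- c(bad, v$position[drop])
  }
  setdiff(seq.int(range[1L], range[2L]), unique(bad))
}

# substitution tokens at the analyzed sites only
.site_tokens <- function(haps, sites) {
  lapply(haps, function(h) {
    v <- as.data.frame(h)
    keep <- which(v$position %in% sites &
                    v$kind %in% c("transition", "transversion"))
    if (length(keep) == 0L) return(character(0))
    sort(paste0(v$position[keep], "=", v$alt[keep]))
  })
}

#' Number of distinct haplotypes
#'
#' Distinct normalized, range-restricted variant sets over the analyzed
#' sites.
#'
#' @inheritParams analyzed_sites
#' @return Integer `k`.
#' @export
count_haplotypes <- function(x, range = c(16090L, 16365L), normalize = TRUE) {
  haps <- .prepare_haps(x, range, normalize)
  sites <- analyzed_sites(x, range, normalize)
  toks <- .site_tokens(haps, sites)
  length(unique(vapply(toks, paste, character(1), collapse = " ")))
}

#' Number of segregating sites
#'
#' Analyzed sites at which at least two states occur across the samples.
#'
#' @inheritParams analyzed_sites
#' @return Integer `S`.
#' @export
segregating_sites <- function(x, range = c(16090L, 16365L), normalize = TRUE) {
  haps <- .prepare_haps(x, range, normalize)
  if (length(haps) < 2L) stop("need at least 2 samples")
  sites <- analyzed_sites(x, range, normalize)
  # a site segregates iff some sample carries a substitution there and not
  # all samples carry the same substitution
  state <- list()
  for (h in haps) {
    v <- as.data.frame(h)
    keep <- v$position %in% sites & v$kind %in% c("transition", "transversion")
    v <- v[keep, , drop = FALSE]
    for (i in seq_len(nrow(v))) {
      p <- as.character(v$position[i])
      state[[p]] <- c(state[[p]], v$alt[i])
    }
  }
  n <- length(haps)
  sum(vapply(state, function(alts)
    length(alts) < n || length(unique(alts)) > 1L, logical(1)))
}

#' Haplotype (gene) diversity with sampling standard deviation
#'
#' Nei's unbiased estimator `H = n (1 - sum p_i^2) / (n - 1)` over
#' haplotype frequencies, with its sampling variance
#' `V = (2 / (n (n-1))) * (2 (n-2) (sum p^3 - (sum p^2)^2) + sum p^2 -
#' (sum p^2)^2)`.
#'
#' @inheritParams analyzed_sites
#' @return List with `H` and `sd`.
#' @export
haplotype_diversity <- function(x, range = c(16090L, 16365L),
                                normalize = TRUE) {
  haps <- .prepare_haps(x, range, normalize)
  n <- length(haps)
  if (n < 2L) stop("haplotype diversity needs n >= 2")
  sites <- analyzed_sites(x, range, normalize)
  toks <- vapply(.site_tokens(haps, sites), paste, character(1),
                 collapse = " ")
  p <- as.numeric(table(toks)) / n
  s2 <- sum(p^2); s3 <- sum(p^3)
  H <- n * (1 - s2) / (n - 1)
  V <- (2 / (n * (n - 1))) * (2 * (n - 2) * (s3 - s2^2) + s2 - s2^2)
  list(H = H, sd = sqrt(max(V, 0)))
}

.pairwise_distance_sum <- function(haps, sites) {
  toks <- .site_tokens(haps, sites)
  n <- length(toks)
  total <- 0
  for (i in seq_len(n - 1L)) {
    ti <- toks[[i]]
    for (j in seq.int(i + 1L, n)) {
      tj <- toks[[j]]
      ki <- sub("=.*", "", ti); kj <- sub("=.*", "", tj)
      shared_keys <- sum(ki %in% kj)
      shared_toks <- sum(ti %in% tj)
      total <- total + length(ti) + length(tj) - shared_keys - shared_toks
    }
  }
  total
}

#' Mean number of pairwise differences
#'
#' `M = (2 / (n (n-1))) * sum_{i<j} d(h_i, h_j)` over the analyzed sites.
#'
#' @inheritParams analyzed_sites
#' @return Numeric `M`.
#' @export
mean_pairwise_differences <- function(x, range = c(16090L, 16365L),
                                      normalize = TRUE) {
  haps <- .prepare_haps(x, range, normalize)
  n <- length(haps)
  if (n < 2L) stop("mean pairwise differences needs n >= 2")
  sites <- analyzed_sites(x, range, normalize)
  2 * .pairwise_distance_sum(haps, sites) / (n * (n - 1))
}

#' Nucleotide diversity with sampling standard deviation
#'
#' `pi = M / L` where `L` is the number of analyzed sites, with the
#' Tajima-type sampling variance
#' `V(pi) = ((n+1) / (3 (n-1) L)) pi + (2 (n^2 + n + 3) / (9 n (n-1))) pi^2`.
#'
#' @inheritParams analyzed_sites
#' @return List with `pi`, `sd` and `L_sites`.
#' @export
nucleotide_diversity <- function(x, range = c(16090L, 16365L),
                                 normalize = TRUE) {
  haps <- .prepare_haps(x, range, normalize)
  n <- length(haps)
  if (n < 2L) stop("nucleotide diversity needs n >= 2")
  sites <- analyzed_sites(x, range, normalize)
  L <- length(sites)
  if (L == 0L) stop("no analyzed sites in range")
  M <- 2 * .pairwise_distance_sum(haps, sites) / (n * (n - 1))
  pi <- M / L
  V <- ((n + 1) / (3 * (n - 1) * L)) * pi +
    (2 * (n^2 + n + 3) / (9 * n * (n - 1))) * pi^2
  list(pi = pi, sd = sqrt(max(V, 0)), L_sites = L)
}

#' Full diversity summary
#'
#' Assembles sample size `n`, distinct haplotypes `k`, segregating sites
#' `S`, haplotype diversity `H` (with sd), nucleotide diversity `pi` (with
#' sd), mean pairwise differences `M` and the analyzed-site count
#' `L_sites`, all under the same complete-deletion site policy.  The
#' identity `M = pi * L_sites` holds exactly.
#'
#' @inheritParams analyzed_sites
#' @param group optional label stored in the output.
#' @return Object of class `diversity_summary` (also a one-row data frame).
#' @export
diversity_summary <- function(x, range = c(16090L, 16365L), normalize = TRUE,
                              group = NA_character_) {
  haps <- .prepare_haps(x, range, normalize)
  n <- length(haps)
  if (n < 2L) stop("diversity summary needs n >= 2")
  sites <- analyzed_sites(x, range, normalize)
  hd <- haplotype_diversity(x, range, normalize)
  nd <- nucleotide_diversity(x, range, normalize)
  out <- data.frame(group = group, n = n,
                    k = count_haplotypes(x, range, normalize),
                    S = segregating_sites(x, range, normalize),
                    H = hd$H, H_sd = hd$sd, pi = nd$pi, pi_sd = nd$sd,
                    M = nd$pi * nd$L_sites, L_sites = nd$L_sites,
                    stringsAsFactors = FALSE)
  class(out) <- c("diversity_summary", "data.frame")
  out
}

#' Format a diversity summary like a publication table row
#'
#' @param x a [diversity_summary()].
#' @param ... unused.
#' @export
print.diversity_summary <- function(x, ...) {
  cat(sprintf("%s\tn=%d\tk=%d\tS=%d\tH=%.3f+/-%.3f\tpi=%.5f+/-%.5f\tM=%.3f\t(L=%d sites)\n",
              ifelse(is.na(x$group), "samples", x$group), x$n, x$k, x$S,
              x$H, x$H_sd, x$pi, x$pi_sd, x$M, x$L_sites))
  invisible(x)
}
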