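# -- Synthetic study generator ------------------------------------------------
#
# Generates data with the statistical structure the analyses assume: a toy
# haplogroup tree with a synthetic reference, region-structured haplotype
# databases (finite-sites mutation, transition-biased), admixed target
# samples with known source regions, and continent-differentiated diploid
# genotype panels under the Balding-Nichols model.  A single root seed
# derives per-stage child seeds so stages regenerate independently and
# bit-for-bit.

.child_seed <- function(seed, k) {
  x <- ((as.numeric(seed) %% 2147483647) * 1009 + k * 9973) %% 2147483645
  as.integer(x) + 1L
}

.AFRICAN_REGIONS <- c("North", "West-Central", "Southwest", "South",
                      "Southeast", "East")

.AFRICAN_LEAVES <- c("L0a1b2", "L0a2a2a", "L1c3b1a", "L3d1a1a", "L3d1b3")

.default_region_freqs <- function() {
  f <- rbind(
    "North"        = c(0.10, 0.05, 0.05, 0.40, 0.40),
    "West-Central" = c(0.05, 0.05, 0.50, 0.10, 0.30),
    "Southwest"    = c(0.10, 0.10, 0.60, 0.10, 0.10),
    "South"        = c(0.30, 0.30, 0.10, 0.15, 0.15),
    "Southeast"    = c(0.25, 0.40, 0.10, 0.15, 0.10),
    "East"         = c(0.15, 0.30, 0.05, 0.45, 0.05))
  colnames(f) <- .AFRICAN_LEAVES
  lapply(stats::setNames(rownames(f), rownames(f)), function(r) f[r, ])
}

#' Simulation configuration
#'
#' Bundles every tunable of the synthetic-study generator.  Defaults
#' mirror the study conditions this package is designed around: six
#' sub-continental African source regions with database sizes 3830, 6868,
#' 522, 357, 1118 and 1010; HVS-I comparison range 16090-16365; a mean of
#' one private mutation per database haplotype and 0.3 extra mutations
#' per target; 0.94 transition bias; and a 46-locus, three-population
#' genotype block with Balding-Nichols divergence F = 0.15 and reference
#' panel sizes 64 (America), 158 (Europe) and 105 (Africa).
#'
#' @param seed root seed; per-stage child seeds are derived from it.
#' @param range coordinate interval for database haplotypes.
#' @param region_freqs named list, per region, of haplogroup-frequency
#'   vectors over the African leaf haplogroups (each summing to 1).
#' @param n_db named integer vector of database sizes per region.
#' @param lambda_private mean private mutations per database haplotype.
#' @param mu_drift mean extra mutations per target haplotype.
#' @param proportions per-region draw probabilities for targets (sums
#'   to 1).
#' @param transition_prob probability that a random mutation is a
#'   transition.
#' @param avoid_tree_positions keep random mutations off positions used by
#'   tree motifs.
#' @param n_targets number of mtDNA target individuals.
#' @param L,K,Fst,alpha,n_ref,n_target genotype block: number of loci,
#'   number of populations, per-population Balding-Nichols divergence,
#'   Dirichlet concentration for individual ancestries, reference panel
#'   sizes, number of target individuals.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       range = c(16090L, 16365L),
                       region_freqs = .default_region_freqs(),
                       n_db = c("North" = 3830L, "West-Central" = 6868L,
                                "Southwest" = 522L, "South" = 357L,
                                "Southeast" = 1118L, "East" = 1010L),
                       lambda_private = 1,
                       mu_drift = 0.3,
                       proportions = NULL,
                       transition_prob = 0.94,
                       avoid_tree_positions = TRUE,
                       n_targets = 19L,
                       L = 46L, K = 3L, Fst = c(0.15, 0.15, 0.15),
                       alpha = c(1, 1, 1),
                       n_ref = c("America" = 64L, "Europe" = 158L,
                                 "Africa" = 105L),
                       n_target = 100L) {
  bad <- vapply(region_freqs, function(p) abs(sum(p) - 1) > 1e-8, logical(1))
  if (any(bad))
    stop(sprintf("region frequency vector(s) not summing to 1: %s",
                 paste(names(region_freqs)[bad], collapse = ", ")))
  if (is.null(proportions)) {
    proportions <- rep(1 / length(region_freqs), length(region_freqs))
    names(proportions) <- names(region_freqs)
  }
  if (abs(sum(proportions) - 1) > 1e-8)
    stop("target draw proportions must sum to 1")
  if (any(Fst <= 0 | Fst >= 1)) stop("Fst values must lie in (0, 1)")
  if (any(alpha <= 0)) stop("Dirichlet alpha must be positive")
  if (lambda_private < 0 || mu_drift < 0) stop("mutation rates must be >= 0")
  structure(list(seed = as.integer(seed), range = as.integer(range),
                 region_freqs = region_freqs, n_db = n_db,
                 lambda_private = lambda_private, mu_drift = mu_drift,
                 proportions = proportions,
                 transition_prob = transition_prob,
                 avoid_tree_positions = avoid_tree_positions,
                 n_targets = as.integer(n_targets),
                 L = as.integer(L), K = as.integer(K), Fst = Fst,
                 alpha = alpha, n_ref = n_ref,
                 n_target = as.integer(n_target)),
            class = "sim_config")
}

#' Toy haplogroup tree with a synthetic reference
#'
#' Builds a fixed topology containing the macro-structure (root, L0, L1,
#' L3, M, N) and the terminal haplogroups A2, B4, C1, D1, D4h3a, HV0,
#' L0a1b2, L0a2a2a, L1c3b1a, L3d1a1a and L3d1b3.  B4 carries its
#' classical diagnostic HVS-I motif (T16189C-T16217C, adjusted to the
#' synthetic reference bases); every other motif is synthetic: 2-4
#' variants at seed-dependent positions (macro-haplogroups in HVS-II,
#' terminal clades in HVS-I), mutually distinct across nodes.  A
#' continental-ancestry prefix map is included, and the tree carries the
#' synthetic reference (`$reference`) and the set of motif positions
#' (`$positions_used`).
#'
#' @param seed integer seed.
#' @return A [haplo_tree()] with extra fields `reference` and
#'   `positions_used`.
#' @export
make_toy_tree <- function(seed = 1L) {
  set.seed(.child_seed(seed, 1L))
  bases <- sample(c("A", "C", "G", "T"), 16400L, replace = TRUE)
  # pin the classical B4 motif alleles
  bases[16189L] <- "T"; bases[16217L] <- "T"
  reference <- reference_segment("synthetic-rCRS", 1L,
                                 paste(bases, collapse = ""))

  topology <- list(
    ROOT = NA, L0 = "ROOT", L1 = "ROOT", L3 = "ROOT",
    L0a1b2 = "L0", L0a2a2a = "L0", L1c3b1a = "L1",
    L3d1a1a = "L3", L3d1b3 = "L3", N = "L3", M = "L3",
    HV0 = "N", A2 = "N", B4 = "N", C1 = "M", D1 = "M",
    D4h3a = "M")
  macro <- c("L0", "L1", "L3", "N", "M")
  terminal <- setdiff(names(topology), c("ROOT", macro))

  reserved <- c(16182L, 16183L, 16188L, 16189L, 16217L)
  pool1 <- setdiff(16090:16365, reserved)             # HVS-I, terminal nodes
  pool2 <- setdiff(73:340, 303:315)                   # HVS-II, macro nodes

  draw_motif <- function(pool, nvar) {
    pos <- sort(sample(pool, nvar))
    do.call(rbind, lapply(pos, function(p) {
      refb <- bases[p]
      trans <- unname(.transition_partner[refb])
      alt <- if (stats::runif(1) < 0.94) trans
             else sample(setdiff(c("A", "C", "G", "T"), c(refb, trans)), 1L)
      .variant_row(p, NA_integer_, refb, alt,
                   .substitution_kind(refb, alt))
    }))
  }

  nodes <- list(); used1 <- integer(0); used2 <- integer(0)
  for (nm in names(topology)) {
    if (nm == "ROOT") {
      v <- .empty_variants()
    } else if (nm == "B4") {
      v <- rbind(
        .variant_row(16189L, NA_integer_, "T", "C", "transition"),
        .variant_row(16217L, NA_integer_, "T", "C", "transition"))
      used1 <- c(used1, 16189L, 16217L)
    } else if (nm %in% macro) {
      v <- draw_motif(setdiff(pool2, used2), sample(2:4, 1L))
      used2 <- c(used2, v$position)
    } else {
      v <- draw_motif(setdiff(pool1, used1), sample(2:4, 1L))
      used1 <- c(used1, v$position)
    }
    nodes[[nm]] <- list(name = nm,
                        parent = if (is.na(topology[[nm]])) NULL
                                 else topology[[nm]],
                        variants = format_variants(v))
  }

  map <- c(L0 = "African", L1 = "African", L2 = "African", L3 = "African",
           L4 = "African", L5 = "African", L6 = "African",
           A2 = "NativeAmerican", B2 = "NativeAmerican",
           B4 = "NativeAmerican", C1 = "NativeAmerican",
           D1 = "NativeAmerican", D4 = "NativeAmerican",
           H = "European", HV = "European", J = "European",
           K = "European", T = "European", U = "European",
           V = "European", W = "European", X = "European",
           M = "Other", N = "Other", ROOT = "Other")
  tree <- haplo_tree(unname(nodes), map)
  tree$reference <- reference
  tree$positions_used <- sort(unique(c(used1, used2)))
  tree
}

# random private mutations at positions drawn from `pool`
.random_mutations <- function(k, pool, bases, transition_prob = 0.94) {
  if (k == 0L || length(pool) == 0L) return(.empty_variants())
  k <- min(k, length(pool))
  pos <- sample(pool, k)
  do.call(rbind, lapply(pos, function(p) {
    refb <- bases[p]
    trans <- unname(.transition_partner[refb])
    alt <- if (stats::runif(1) < transition_prob) trans
           else sample(setdiff(c("A", "C", "G", "T"), c(refb, trans)), 1L)
    .variant_row(p, NA_integer_, refb, alt, .substitution_kind(refb, alt))
  }))
}

.mutation_pool <- function(config, tree, extra_exclude = integer(0)) {
  pool <- seq.int(config$range[1L], config$range[2L])
  pool <- setdiff(pool, c(16182L, 16183L, extra_exclude))
  if (config$avoid_tree_positions) pool <- setdiff(pool, tree$positions_used)
  pool
}

#' Simulate region-structured haplotype databases
#'
#' Per region, draws haplogroups from the region's frequency vector, takes
#' the root-to-node motif restricted to the configured range and adds
#' `Poisson(lambda_private)` private mutations at uniform positions
#' (transitions with the configured bias).
#'
#' @param tree a [make_toy_tree()] tree (its synthetic reference supplies
#'   mutation alleles).
#' @param config a [sim_config()].
#' @return A `region_db_list` (see [build_region_db()]) with attribute
#'   `records`, the underlying sample table including true haplogroups.
#' @export
simulate_region_dbs <- function(tree, config = sim_config()) {
  set.seed(.child_seed(config$seed, 2L))
  bases <- strsplit(tree$reference$bases, "")[[1L]]
  pool <- .mutation_pool(config, tree)
  motifs <- lapply(stats::setNames(nm = names(tree$nodes)), function(nm) {
    v <- path_expected_variants(tree, nm)
    v[v$position >= config$range[1L] & v$position <= config$range[2L], ,
      drop = FALSE]
  })
  rows <- list()
  for (r in names(config$region_freqs)) {
    freqs <- config$region_freqs[[r]]
    n <- config$n_db[[r]]
    hgs <- sample(names(freqs), n, replace = TRUE, prob = freqs)
    k_priv <- stats::rpois(n, config$lambda_private)
    haps <- lapply(seq_len(n), function(i) {
      v <- motifs[[hgs[i]]]
      pv <- .random_mutations(k_priv[i], setdiff(pool, v$position), bases,
                              config$transition_prob)
      haplotype(rbind(v, pv), config$range)
    })
    df <- data.frame(id = sprintf("%s_%05d", gsub("[^A-Za-z]", "", r),
                                  seq_len(n)),
                     population = r, locality = NA_character_, region = r,
                     haplogroup = hgs, stringsAsFactors = FALSE)
    df$haplotype <- I(haps)
    rows[[r]] <- df
  }
  records <- do.call(rbind, rows)
  rownames(records) <- NULL
  dbs <- build_region_db(records, range = config$range, normalize = TRUE)
  attr(dbs, "records") <- records
  dbs
}

#' Simulate admixed target haplotypes with known source regions
#'
#' Each target draws a source region from `proportions`, then a haplotype
#' uniformly from that region's database (individual-weighted), then adds
#' `Poisson(mu_drift)` extra mutations.
#'
#' @param dbs a `region_db_list` from [simulate_region_dbs()].
#' @param tree the tree used to build `dbs`.
#' @param config a [sim_config()]; uses `proportions`, `n_targets`,
#'   `mu_drift` and the mutation settings.
#' @return List with `records` (target sample table) and `truth` (data
#'   frame `id`, `region`; attribute `draw_proportions` gives the realized
#'   per-region draw fractions).
#' @export
simulate_targets <- function(dbs, tree, config = sim_config()) {
  set.seed(.child_seed(config$seed, 3L))
  props <- config$proportions[names(dbs)]
  if (anyNA(props)) stop("proportions must cover every database region")
  bases <- strsplit(tree$reference$bases, "")[[1L]]
  pool <- .mutation_pool(config, tree)
  n <- config$n_targets
  regions <- sample(names(dbs), n, replace = TRUE, prob = props)
  k_extra <- stats::rpois(n, config$mu_drift)
  haps <- lapply(seq_len(n), function(i) {
    db <- dbs[[regions[i]]]
    j <- sample.int(length(db$counts), 1L, prob = db$counts)
    v <- as.data.frame(db$haplotypes[[j]])
    pv <- .random_mutations(k_extra[i], setdiff(pool, v$position), bases,
                            config$transition_prob)
    haplotype(rbind(v, pv), config$range)
  })
  records <- data.frame(id = sprintf("target_%04d", seq_len(n)),
                        population = "targets", locality = NA_character_,
                        region = NA_character_, haplogroup = NA_character_,
                        stringsAsFactors = FALSE)
  records$haplotype <- I(haps)
  truth <- data.frame(id = records$id, region = regions,
                      stringsAsFactors = FALSE)
  draw <- table(factor(regions, levels = names(dbs))) / n
  attr(truth, "draw_proportions") <- stats::setNames(as.numeric(draw),
                                                     names(dbs))
  list(records = records, truth = truth)
}

.rdirichlet <- function(n, alpha) {
  x <- matrix(stats::rgamma(n * length(alpha), shape = alpha), n,
              length(alpha), byrow = TRUE)
  x / rowSums(x)
}

#' Simulate a continent-differentiated genotype study
#'
#' Balding-Nichols model: ancestral allele frequencies `p_l ~ U(0.1,
#' 0.9)`; population frequencies `f_lr ~ Beta(p_l (1-F_r)/F_r, (1-p_l)
#' (1-F_r)/F_r)`; reference individuals are drawn per population and
#' target individuals receive Dirichlet(`alpha`) ancestries with
#' genotypes `~ Binomial(2, sum_r q_r f_lr)`.
#'
#' @param config a [sim_config()].
#' @param pop_labels population names (defaults to the names of
#'   `config$n_ref`).
#' @param target_alpha optional matrix (targets x K) of per-individual
#'   Dirichlet parameters overriding `config$alpha`.
#' @return List with `reference` and `targets` ([genotype_panel()]s),
#'   `truth_q` (targets x K matrix) and `freqs` (true loci x K allele
#'   frequencies).
#' @export
simulate_genotype_study <- function(config = sim_config(),
                                    pop_labels = names(config$n_ref),
                                    target_alpha = NULL) {
  set.seed(.child_seed(config$seed, 4L))
  K <- config$K; L <- config$L
  stopifnot(length(pop_labels) == K, length(config$n_ref) == K)
  Fst <- rep_len(config$Fst, K)
  p <- stats::runif(L, 0.1, 0.9)
  f <- vapply(seq_len(K), function(r)
    stats::rbeta(L, p * (1 - Fst[r]) / Fst[r],
                 (1 - p) * (1 - Fst[r]) / Fst[r]), numeric(L))
  colnames(f) <- pop_labels
  rownames(f) <- sprintf("locus%02d", seq_len(L))

  ref_rows <- list(); ref_pops <- character(0)
  for (r in seq_len(K)) {
    n <- config$n_ref[[r]]
    G <- vapply(seq_len(L), function(l)
      stats::rbinom(n, 2L, f[l, r]), integer(n))
    ref_rows[[r]] <- G
    ref_pops <- c(ref_pops, rep(pop_labels[r], n))
  }
  Gref <- do.call(rbind, ref_rows)
  reference <- genotype_panel(Gref,
                              ids = sprintf("ref_%03d", seq_len(nrow(Gref))),
                              populations = ref_pops,
                              loci = rownames(f))

  n_t <- config$n_target
  Q <- if (is.null(target_alpha)) .rdirichlet(n_t, config$alpha)
       else t(vapply(seq_len(n_t), function(i)
         .rdirichlet(1L, target_alpha[i, ])[1L, ], numeric(K)))
  colnames(Q) <- pop_labels
  pmat <- Q %*% t(f)                      # targets x loci
  Gt <- matrix(stats::rbinom(n_t * L, 2L, as.vector(pmat)), n_t, L)
  targets <- genotype_panel(Gt, ids = sprintf("tgt_%03d", seq_len(n_t)),
                            populations = rep(NA_character_, n_t),
                            loci = rownames(f))
  rownames(Q) <- targets$ids
  list(reference = reference, targets = targets, truth_q = Q, freqs = f)
}

#' Full synthetic study in the shape of an admixed-valley survey
#'
#' Assembles a 105-sample mtDNA study with a pinned continental mix (85
#' Native American, 19 African, 1 European, which rounds to 81/18/1), a
#' 19-sample "Tocana-like" locality holding 16 of the 19 African
#' lineages (84%), six-region African source databases, and a genotype
#' block whose reference panels and target ancestries mirror a
#' three-continent AIM survey.  Counts are pinned by stratified sampling
#' so the headline percentages are exact rather than stochastic.
#'
#' @param seed root seed.
#' @param db_sizes per-region database sizes (defaults to the six-region
#'   study sizes in [sim_config()]).
#' @param mtdna_counts named integer vector of samples per haplogroup
#'   (default pins 85/19/1 across the three continental components).
#' @return List of class `simulated_study` with `records` (105 mtDNA
#'   samples), `tree`, `dbs`, `l_targets` (the African-lineage subset),
#'   `genotypes` (see [simulate_genotype_study()]) and `truth`.
#' @export
yungas_like_scenario <- function(seed = 1L, db_sizes = NULL,
                                 mtdna_counts = NULL) {
  config <- sim_config(seed = seed)
  if (!is.null(db_sizes)) config$n_db[names(db_sizes)] <- db_sizes
  tree <- make_toy_tree(seed)

  if (is.null(mtdna_counts))
    mtdna_counts <- c(B4 = 62L, C1 = 17L, A2 = 3L, D1 = 2L, D4h3a = 1L,
                      L1c3b1a = 5L, L0a1b2 = 3L, L0a2a2a = 2L,
                      L3d1a1a = 5L, L3d1b3 = 4L, HV0 = 1L)
  set.seed(.child_seed(seed, 5L))
  bases <- strsplit(tree$reference$bases, "")[[1L]]
  hgs <- rep(names(mtdna_counts), mtdna_counts)
  n <- length(hgs)
  is_african <- startsWith(hgs, "L")
  # pool for sample private mutations: anywhere in the control region
  cr_pool <- setdiff(c(73:340, 16024:16365),
                     c(303:315, 16182L, 16183L, tree$positions_used))
  k_priv <- stats::rpois(n, config$mu_drift)
  haps <- lapply(seq_len(n), function(i) {
    v <- path_expected_variants(tree, hgs[i])
    pv <- .random_mutations(k_priv[i], setdiff(cr_pool, v$position), bases,
                            config$transition_prob)
    haplotype(rbind(v, pv), control_region_range())
  })

  # locality: 19 samples in Tocana (16 African + 3 Native American),
  # the remaining Africans elsewhere in Nor Yungas; 8 samples in Sud Yungas
  locality <- rep("NorYungas", n)
  afr_idx <- which(is_african)
  toc_afr <- afr_idx[seq_len(16L)]
  toc_other <- setdiff(which(!is_african), integer(0))[1:3]
  locality[c(toc_afr, toc_other)] <- "Tocana"
  non_toc <- setdiff(seq_len(n), c(toc_afr, toc_other))
  locality[non_toc[seq_len(8L)]] <- "SudYungas"

  records <- data.frame(id = sprintf("Y%03d", seq_len(n)),
                        population = "Yungas", locality = locality,
                        region = NA_character_, haplogroup = hgs,
                        stringsAsFactors = FALSE)
  records$haplotype <- I(haps)
  ord <- sample.int(n)                      # shuffle ids over haplogroups
  records <- records[ord, ]
  records$id <- sprintf("Y%03d", seq_len(n))
  rownames(records) <- NULL

  dbs <- simulate_region_dbs(tree, config)
  l_targets <- records[startsWith(records$haplogroup, "L"), ]

  # genotype block: Tocana-like individuals are majority-African, the
  # rest majority-Native-American, mirroring a three-continent AIM survey
  gconf <- config
  gconf$n_target <- n
  toc_rows <- which(records$locality == "Tocana")
  target_alpha <- matrix(rep(c(0.862, 0.116, 0.023) * 8, each = n), n, 3L)
  target_alpha[toc_rows, ] <- matrix(rep(c(0.30, 0.14, 0.56) * 8,
                                         each = length(toc_rows)),
                                     length(toc_rows), 3L)
  genotypes <- simulate_genotype_study(gconf, target_alpha = target_alpha)
  rownames(genotypes$truth_q) <- records$id
  genotypes$targets$ids <- records$id
  rownames(genotypes$targets$genotypes) <- records$id

  structure(list(records = records, tree = tree, dbs = dbs,
                 l_targets = l_targets, genotypes = genotypes,
                 truth = list(haplogroups = stats::setNames(records$haplogroup,
                                                            records$id),
                              continental_counts = c(NativeAmerican = 85L,
                                                     African = 19L,
                                                     European = 1L),
                              q = genotypes$truth_q)),
            class = "simulated_study")
}

#' @export
print.simulated_study <- function(x, ...) {
  cat(sprintf("Simulated study: %d mtDNA samples, %d-region databases, %d AIM loci\n",
              nrow(x$records), length(x$dbs), length(x$genotypes$targets$loci)))
  invisible(x)
}
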