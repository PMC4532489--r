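# -- End-to-end pipeline ------------------------------------------------------

# tiny FNV-1a hash for stamping outputs with their configuration
.config_hash <- function(config) {
  s <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                        force = TRUE)
  bytes <- utf8ToInt(as.character(s))
  h <- 2166136261
  for (b in bytes) h <- (bitwXor(as.integer(h %% 2^31), b) * 16777619) %% 2^31
  sprintf("%08x", as.integer(h))
}

.log_line <- function(logfile, ...) {
  msg <- sprintf(...)
  line <- paste0("[", format(Sys.time(), "%H:%M:%S"), "] ", msg)
  message(line)
  if (!is.null(logfile)) cat(msg, "\n", file = logfile, append = TRUE)
}

#' Marker-system ancestry comparison (gender-bias report)
#'
#' Aligns ancestry partitions obtained from different marker systems
#' (autosomes, mtDNA, Y chromosome) for one population group.  Because
#' mtDNA is maternally and the Y chromosome paternally inherited,
#' asymmetries between the rows reveal sex-biased admixture.  The
#' Y-chromosome partition is typically supplied from published data
#' rather than computed.
#'
#' @param partitions named list (one element per marker system) of named
#'   numeric ancestry proportions, each summing to ~1.
#' @param group group label for the table.
#' @return Object of class `ancestry_comparison`: data frame with one row
#'   per marker system, proportion columns per ancestry label, and
#'   rounded `*_pct` columns.
#' @export
gender_bias_report <- function(partitions, group = "group") {
  stopifnot(is.list(partitions), length(partitions) >= 1L)
  for (nm in names(partitions)) {
    s <- sum(partitions[[nm]])
    if (abs(s - 1) > 0.02)
      stop(sprintf("partition '%s' sums to %.3f, not ~1", nm, s))
  }
  labels <- unique(unlist(lapply(partitions, names)))
  rows <- lapply(names(partitions), function(nm) {
    p <- partitions[[nm]][labels]
    p[is.na(p)] <- 0
    stats::setNames(as.numeric(p), labels)
  })
  out <- data.frame(group = group, marker = names(partitions),
                    do.call(rbind, rows), check.names = FALSE,
                    stringsAsFactors = FALSE)
  for (lab in labels) out[[paste0(lab, "_pct")]] <- round(100 * out[[lab]])
  rownames(out) <- NULL
  class(out) <- c("ancestry_comparison", "data.frame")
  out
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate -> classify -> diversity -> mtDNA admixture ->
#' AIM ancestry -> MDS -> report over a configuration list (or YAML
#' file).  Configuration fields:
#' \describe{
#'   \item{seed}{integer; drives every random stage.}
#'   \item{simulate}{list; `db_sizes` optionally scales the regional
#'     databases of the built-in scenario.}
#'   \item{stages}{subset of `c("classify", "diversity", "mtadmix",
#'     "aimadmix", "mds", "report")`; default all.}
#'   \item{mtadmix}{list with `m_values`, `B`, `scheme`.}
#'   \item{y_partition}{optional named proportions for the Y chromosome,
#'     enabling the marker-comparison report.}
#' }
#' Every output is stamped (in `run_info.json`) with the configuration
#' hash, seed and package version.
#'
#' @param config list or path to a YAML file.
#' @param out_dir output directory (created if needed).
#' @return Invisibly, a named list of the written file paths.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  stages <- config$stages
  if (is.null(stages))
    stages <- c("classify", "diversity", "mtadmix", "aimadmix", "mds",
                "report")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  logfile <- file.path(out_dir, "pipeline.log")
  cat("", file = logfile)
  outputs <- list()
  run_stage <- function(name, expr) {
    .log_line(logfile, "stage %s: start", name)
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  study <- run_stage("simulate",
    yungas_like_scenario(seed, db_sizes = config$simulate$db_sizes))

  if ("classify" %in% stages) {
    cls <- run_stage("classify", {
      lapply(study$records$haplotype, function(h)
        classify(normalize_haplotype(h), study$tree))
    })
    df <- data.frame(
      id = study$records$id,
      haplogroup = vapply(cls, `[[`, character(1), "haplogroup"),
      score = vapply(cls, `[[`, numeric(1), "score"),
      private = vapply(cls, function(x)
        paste(format_variants(x$private), collapse = " "), character(1)),
      ancestry = vapply(cls, `[[`, character(1), "ancestry"),
      stringsAsFactors = FALSE)
    outputs$classify <- file.path(out_dir, "classify.tsv")
    utils::write.table(df, outputs$classify, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    part <- ancestry_partition(
      data.frame(haplogroup = df$haplogroup, stringsAsFactors = FALSE),
      study$tree)
    outputs$partition <- file.path(out_dir, "partition.json")
    jsonlite::write_json(list(counts = as.list(part$counts),
                              proportions = as.list(part$proportions),
                              percent = as.list(part$percent)),
                         outputs$partition, auto_unbox = TRUE, digits = NA)
  }

  if ("diversity" %in% stages) {
    div <- run_stage("diversity", {
      groups <- list(all = study$records,
                     tocana = study$records[study$records$locality ==
                                              "Tocana", ])
      do.call(rbind, lapply(names(groups), function(g)
        as.data.frame(diversity_summary(groups[[g]], group = g))))
    })
    outputs$diversity <- file.path(out_dir, "diversity.tsv")
    utils::write.table(div, outputs$diversity, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }

  if ("mtadmix" %in% stages) {
    ma <- config$mtadmix
    tab <- run_stage("mtadmix", admixture_table(
      study$l_targets, study$dbs,
      m_values = if (is.null(ma$m_values)) c(0L, 1L, 2L) else ma$m_values,
      B = if (is.null(ma$B)) 1000L else as.integer(ma$B),
      seed = seed,
      scheme = if (is.null(ma$scheme)) "databases" else ma$scheme))
    outputs$mtadmix <- file.path(out_dir, "mtadmix.tsv")
    utils::write.table(as.data.frame(tab), outputs$mtadmix,
                       sep = "\t", quote = FALSE, row.names = FALSE)
    outputs$mtadmix_coverage <- file.path(out_dir, "mtadmix_coverage.json")
    jsonlite::write_json(as.list(attr(tab, "coverage")),
                         outputs$mtadmix_coverage, auto_unbox = TRUE,
                         digits = NA)
  }

  aim_part <- NULL
  if ("aimadmix" %in% stages) {
    q_out <- run_stage("aimadmix", {
      freqs <- reference_frequencies(study$genotypes$reference)
      Q <- panel_ancestry(study$genotypes$targets, freqs)
      list(Q = Q,
           groups = population_ancestry(Q, study$records$locality))
    })
    outputs$aimadmix <- file.path(out_dir, "aimadmix.tsv")
    utils::write.table(data.frame(id = rownames(q_out$Q), q_out$Q,
                                  check.names = FALSE),
                       outputs$aimadmix, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    outputs$aimadmix_groups <- file.path(out_dir, "aimadmix_groups.tsv")
    utils::write.table(data.frame(group = rownames(q_out$groups),
                                  q_out$groups, check.names = FALSE),
                       outputs$aimadmix_groups, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    aim_part <- colMeans(q_out$Q)
  }

  if ("mds" %in% stages) {
    mds <- run_stage("mds", {
      both <- rbind(study$genotypes$reference$genotypes,
                    study$genotypes$targets$genotypes)
      pops <- c(study$genotypes$reference$populations,
                rep("target", nrow(study$genotypes$targets$genotypes)))
      panel <- genotype_panel(both, populations = pops)
      fit <- classical_mds(ibs_distance(panel), k = 2L)
      data.frame(id = rownames(fit$coordinates), population = pops,
                 fit$coordinates, check.names = FALSE,
                 frac1 = fit$eigenvalue_fractions[1L],
                 frac2 = fit$eigenvalue_fractions[2L])
    })
    outputs$mds <- file.path(out_dir, "mds.tsv")
    utils::write.table(mds, outputs$mds, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }

  if ("report" %in% stages && "classify" %in% stages) {
    rep_tab <- run_stage("report", {
      part <- jsonlite::fromJSON(outputs$partition)
      partitions <- list(mtDNA = unlist(part$proportions))
      if (!is.null(aim_part)) {
        aim <- c(African = unname(aim_part["Africa"]),
                 NativeAmerican = unname(aim_part["America"]),
                 European = unname(aim_part["Europe"]))
        partitions$autosomes <- aim
      }
      if (!is.null(config$y_partition))
        partitions$Ychromosome <- unlist(config$y_partition)
      gender_bias_report(partitions, group = "Yungas-like")
    })
    outputs$report <- file.path(out_dir, "gender_bias.tsv")
    utils::write.table(as.data.frame(rep_tab), outputs$report, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }

  info <- list(seed = seed, config_hash = .config_hash(config),
               version = as.character(utils::packageVersion("popadmix")),
               stages = stages)
  outputs$run_info <- file.path(out_dir, "run_info.json")
  jsonlite::write_json(info, outputs$run_info, auto_unbox = TRUE)
  .log_line(logfile, "pipeline complete: %d output file(s)",
            length(outputs))
  invisible(outputs)
}
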