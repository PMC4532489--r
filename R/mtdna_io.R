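#' @keywords internal
"_PACKAGE"

# -- Reference segments -------------------------------------------------------

#' Reference segment
#'
#' A contiguous stretch of a reference sequence (e.g. the mtDNA control
#' region) anchored at a 1-based coordinate.  All variant annotation in this
#' package is relative to such a segment; coordinates are 1-based and
#' intervals are closed, following forensic mtDNA convention.
#'
#' @param name label for the segment.
#' @param start 1-based coordinate of the first base.
#' @param bases character string over A/C/G/T.
#' @return An object of class `reference_segment` with fields `name`,
#'   `start`, `end` and `bases`.
#' @export
reference_segment <- function(name, start, bases) {
  stopifnot(is.character(bases), length(bases) == 1L, nchar(bases) >= 1L)
  start <- as.integer(start)
  if (is.na(start) || start < 1L) stop("'start' must be a positive integer")
  bases <- toupper(bases)
  if (grepl("[^ACGT]", bases))
    stop("reference bases must contain only A, C, G, T")
  structure(
    list(name = as.character(name), start = start,
         end = start + nchar(bases) - 1L, bases = bases),
    class = "reference_segment")
}

#' @export
print.reference_segment <- function(x, ...) {
  cat(sprintf("Reference segment '%s': positions %d-%d (%d bases)\n",
              x$name, x$start, x$end, nchar(x$bases)))
  invisible(x)
}

#' Base of a reference segment at given positions
#'
#' @param reference a [reference_segment()].
#' @param position integer vector of 1-based coordinates.
#' @return Character vector of bases.
#' @export
ref_base <- function(reference, position) {
  stopifnot(inherits(reference, "reference_segment"))
  position <- as.integer(position)
  if (any(position < reference$start | position > reference$end))
    stop(sprintf("position outside reference span %d-%d",
                 reference$start, reference$end))
  substring(reference$bases, position - reference$start + 1L,
            position - reference$start + 1L)
}

#' Read a reference segment from FASTA
#'
#' The description line must carry a `start=<int>` tag giving the 1-based
#' coordinate of the first base, e.g. `>HVS1 start=16024`.
#'
#' @param path FASTA file with a single record.
#' @return A [reference_segment()].
#' @export
read_reference_fasta <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- grep("^>", lines)
  if (length(hdr) != 1L || hdr != 1L)
    stop("expected a single-record FASTA file")
  desc <- sub("^>", "", lines[1L])
  m <- regmatches(desc, regexpr("start=\\d+", desc))
  if (length(m) == 0L) stop("FASTA description must carry a 'start=' tag")
  start <- as.integer(sub("start=", "", m))
  name <- strsplit(trimws(desc), "\\s+")[[1L]][1L]
  reference_segment(name, start, paste(lines[-1L], collapse = ""))
}

# -- Variants -----------------------------------------------------------------

.IUPAC_AMBIG <- c("R", "Y", "S", "W", "K", "M", "B", "D", "H", "V", "N")

.transition_partner <- c(A = "G", G = "A", C = "T", T = "C")

.empty_variants <- function() {
  data.frame(position = integer(0), insertion_index = integer(0),
             ref = character(0), alt = character(0), kind = character(0),
             stringsAsFactors = FALSE)
}

.variant_row <- function(position, insertion_index, ref, alt, kind) {
  data.frame(position = as.integer(position),
             insertion_index = as.integer(insertion_index),
             ref = as.character(ref), alt = as.character(alt),
             kind = as.character(kind), stringsAsFactors = FALSE)
}

.substitution_kind <- function(ref, alt) {
  if (alt %in% .IUPAC_AMBIG) return("heteroplasmy")
  if (is.na(ref)) stop("cannot type a substitution with unknown reference base")
  pur <- c("A", "G")
  if ((ref %in% pur) == (alt %in% pur)) "transition" else "transversion"
}

#' Parse a single rCRS-relative variant token
#'
#' Understands the standard forensic/EMPOP notations: flank style
#' (`"T16189C"`), bare position (`"16189"`, a transition whose alleles are
#' resolved from the reference), position+allele (`"16093C"`), insertions
#' (`"309.1C"`), deletions (`"16166d"`, optionally with a reference-base
#' prefix), point heteroplasmies (IUPAC ambiguity alternate, e.g.
#' `"C16223Y"`), and back-mutation markers (`"@152"`), which record the
#' restoration of an ancestral state along a tree branch.
#'
#' Tokens that do not state the reference base (`"16189"`, `"16093C"`,
#' `"16166d"`) require `reference` to resolve it; fully explicit tokens do
#' not.  A stated reference base that disagrees with `reference` is an
#' error.
#'
#' @param token variant token string.
#' @param reference optional [reference_segment()] used to resolve bases.
#' @param allow_back_mutation logical; accept `"@"`-prefixed markers
#'   (tree/mitogenome notation).  Flat sample tables reject them.
#' @return One-row data frame with columns `position`, `insertion_index`
#'   (`NA` unless an insertion), `ref`, `alt` and `kind` (one of
#'   `transition`, `transversion`, `insertion`, `deletion`, `heteroplasmy`,
#'   `back-mutation-marker`).
#' @examples
#' parse_variant_token("T16189C")
#' parse_variant_token("309.1C")
#' @export
parse_variant_token <- function(token, reference = NULL,
                                allow_back_mutation = TRUE) {
  tok <- trimws(token)
  if (!nzchar(tok)) stop("empty variant token")

  if (startsWith(tok, "@")) {
    if (!allow_back_mutation)
      stop(sprintf("back-mutation marker '%s' not allowed in this context", tok))
    inner <- sub("^@", "", tok)
    m <- regexec("^([ACGTacgt])?(\\d+)(?:\\.(\\d+))?([ACGTacgt])?$", inner)
    g <- regmatches(inner, m)[[1L]]
    if (length(g) == 0L) stop(sprintf("malformed back-mutation token '%s'", token))
    pos <- as.integer(g[3L])
    idx <- if (nzchar(g[4L])) as.integer(g[4L]) else NA_integer_
    refb <- if (nzchar(g[2L])) toupper(g[2L]) else NA_character_
    altb <- if (nzchar(g[5L])) toupper(g[5L]) else NA_character_
    if (!is.null(reference) && is.na(refb) &&
        pos >= reference$start && pos <= reference$end)
      refb <- ref_base(reference, pos)
    return(.variant_row(pos, idx, refb, altb, "back-mutation-marker"))
  }

  # insertion: 309.1C
  m <- regexec("^([ACGTacgt])?(\\d+)\\.(\\d+)([ACGTacgt])$", tok)
  g <- regmatches(tok, m)[[1L]]
  if (length(g) > 0L) {
    idx <- as.integer(g[4L])
    if (idx < 1L) stop(sprintf("insertion index must be positive in '%s'", token))
    return(.variant_row(as.integer(g[3L]), idx, "", toupper(g[5L]), "insertion"))
  }

  # deletion: 16166d / C16166d / 16166del / 16166-
  m <- regexec("^([ACGTacgt])?(\\d+)(d|D|del|DEL|-)$", tok)
  g <- regmatches(tok, m)[[1L]]
  if (length(g) > 0L) {
    pos <- as.integer(g[3L])
    refb <- if (nzchar(g[2L])) toupper(g[2L]) else NA_character_
    if (!is.null(reference)) {
      rb <- ref_base(reference, pos)
      if (!is.na(refb) && refb != rb)
        stop(sprintf("token '%s' states reference base %s but reference has %s at %d",
                     token, refb, rb, pos))
      refb <- rb
    }
    return(.variant_row(pos, NA_integer_, refb, "d", "deletion"))
  }

  # flank style: T16189C (alt may be IUPAC ambiguity => heteroplasmy)
  amb <- paste(.IUPAC_AMBIG, collapse = "")
  m <- regexec(sprintf("^([ACGTacgt])(\\d+)([ACGTacgt%s%s])$",
                       amb, tolower(amb)), tok)
  g <- regmatches(tok, m)[[1L]]
  if (length(g) > 0L) {
    refb <- toupper(g[2L]); pos <- as.integer(g[3L]); altb <- toupper(g[4L])
    if (!is.null(reference)) {
      rb <- ref_base(reference, pos)
      if (refb != rb)
        stop(sprintf("token '%s' states reference base %s but reference has %s at %d",
                     token, refb, rb, pos))
    }
    if (refb == altb)
      stop(sprintf("token '%s' has identical reference and alternate base", token))
    return(.variant_row(pos, NA_integer_, refb, altb,
                        .substitution_kind(refb, altb)))
  }

  # position + alternate: 16093C
  m <- regexec(sprintf("^(\\d+)([ACGTacgt%s%s])$", amb, tolower(amb)), tok)
  g <- regmatches(tok, m)[[1L]]
  if (length(g) > 0L) {
    pos <- as.integer(g[2L]); altb <- toupper(g[3L])
    if (is.null(reference))
      stop(sprintf("token '%s' needs a reference to resolve its reference base",
                   token))
    refb <- ref_base(reference, pos)
    if (refb == altb)
      stop(sprintf("token '%s' alternate equals the reference base", token))
    return(.variant_row(pos, NA_integer_, refb, altb,
                        .substitution_kind(refb, altb)))
  }

  # bare position: 16189 (transition)
  if (grepl("^\\d+$", tok)) {
    if (is.null(reference))
      stop(sprintf("bare token '%s' needs a reference to resolve alleles", tok))
    pos <- as.integer(tok)
    refb <- ref_base(reference, pos)
    return(.variant_row(pos, NA_integer_, refb,
                        unname(.transition_partner[refb]), "transition"))
  }

  stop(sprintf("malformed variant token '%s'", token))
}

#' Format variants back to token strings
#'
#' Canonical form: flank style for substitutions and heteroplasmies,
#' `pos.idxBASE` for insertions, `REFposd` for deletions, `@`-prefixed for
#' back-mutation markers.
#'
#' @param variants variant data frame as produced by [parse_variant_token()].
#' @return Character vector of tokens.
#' @export
format_variants <- function(variants) {
  if (nrow(variants) == 0L) return(character(0))
  vapply(seq_len(nrow(variants)), function(i) {
    v <- variants[i, ]
    switch(v$kind,
      insertion = sprintf("%d.%d%s", v$position, v$insertion_index, v$alt),
      deletion = sprintf("%s%dd", if (is.na(v$ref)) "" else v$ref, v$position),
      `back-mutation-marker` = sprintf("@%s%d%s",
        if (is.na(v$ref)) "" else v$ref, v$position,
        if (is.na(v$alt)) "" else v$alt),
      sprintf("%s%d%s", if (is.na(v$ref)) "" else v$ref, v$position, v$alt))
  }, character(1))
}

# -- Haplotypes ---------------------------------------------------------------

#' Default control-region read range
#'
#' HVS-II (73-340) plus HVS-I (16024-16365), the segments conventionally
#' reported for forensic control-region typing.
#'
#' @return Two-column integer matrix of closed intervals (`start`, `end`).
#' @export
control_region_range <- function() {
  cbind(start = c(73L, 16024L), end = c(340L, 16365L))
}

.as_range <- function(range) {
  if (is.null(range)) return(control_region_range())
  if (is.matrix(range)) {
    storage.mode(range) <- "integer"
    colnames(range) <- c("start", "end")
    return(range)
  }
  stopifnot(length(range) == 2L, range[1L] <= range[2L])
  cbind(start = as.integer(range[1L]), end = as.integer(range[2L]))
}

.in_range <- function(position, range) {
  out <- rep(FALSE, length(position))
  for (i in seq_len(nrow(range)))
    out <- out | (position >= range[i, 1L] & position <= range[i, 2L])
  out
}

#' Construct a haplotype from a variant data frame
#'
#' @param variants variant data frame (possibly empty).
#' @param covered_range closed interval(s) the sample was read over: a
#'   length-2 vector or a 2-column matrix; defaults to
#'   [control_region_range()].
#' @return Object of class `haplotype`: the variant data frame with a
#'   `covered_range` attribute, sorted by position then insertion index.
#' @export
haplotype <- function(variants = .empty_variants(), covered_range = NULL) {
  range <- .as_range(covered_range)
  if (nrow(variants) > 0L) {
    key <- paste(variants$position,
                 ifelse(is.na(variants$insertion_index), 0L,
                        variants$insertion_index))
    if (anyDuplicated(key)) {
      dup <- key[duplicated(key)]
      conflict <- any(vapply(unique(dup), function(k) {
        length(unique(variants$alt[key == k])) > 1L
      }, logical(1)))
      if (conflict)
        stop("conflicting variants at the same (position, insertion index)")
      variants <- variants[!duplicated(key), , drop = FALSE]
    }
    if (!all(.in_range(variants$position, range)))
      stop("variant position outside the covered range")
    ord <- order(variants$position,
                 ifelse(is.na(variants$insertion_index), 0L,
                        variants$insertion_index))
    variants <- variants[ord, , drop = FALSE]
    rownames(variants) <- NULL
  }
  structure(variants, covered_range = range,
            class = c("haplotype", "data.frame"))
}

#' @export
print.haplotype <- function(x, ...) {
  toks <- format_variants(x)
  cat(sprintf("Haplotype: %d variant(s)%s\n", nrow(x),
              if (nrow(x)) paste0(" [", paste(toks, collapse = " "), "]")
              else " (reference-identical)"))
  invisible(x)
}

#' Parse a haplotype motif string
#'
#' Tokens may be separated by whitespace or hyphens (motif notation such as
#' `"T16189C-T16217C"`).  The empty string yields the reference-identical
#' haplotype.
#'
#' @inheritParams parse_variant_token
#' @param text motif string.
#' @param covered_range see [haplotype()].
#' @return A [haplotype()].
#' @export
parse_haplotype <- function(text, reference = NULL, covered_range = NULL,
                            allow_back_mutation = FALSE) {
  toks <- unlist(strsplit(trimws(text), "[-[:space:]]+"))
  toks <- toks[nzchar(toks)]
  if (length(toks) == 0L)
    return(haplotype(covered_range = covered_range))
  vs <- do.call(rbind, lapply(toks, parse_variant_token, reference = reference,
                              allow_back_mutation = allow_back_mutation))
  haplotype(vs, covered_range = covered_range)
}

#' Call variants from an aligned sequence
#'
#' Compares a sequence aligned to reference coordinates (gaps written `-`,
#' marking deletions) with the reference, position by position.
#' Substitutions, deletions and point heteroplasmies (IUPAC ambiguity
#' calls) are emitted as variants.  This is the inverse of
#' [reconstruct_sequence()] for substitution-only haplotypes.
#'
#' @param reference a [reference_segment()].
#' @param seq aligned sequence string.
#' @param offset 1-based coordinate of the first character of `seq`.
#' @param covered_range optional; defaults to the interval actually read.
#' @return A [haplotype()].
#' @export
variants_from_sequence <- function(reference, seq, offset = reference$start,
                                   covered_range = NULL) {
  seq <- toupper(seq)
  if (grepl(sprintf("[^ACGT%s-]", paste(.IUPAC_AMBIG, collapse = "")), seq))
    stop("sequence contains a non-IUPAC character")
  offset <- as.integer(offset)
  n <- nchar(seq)
  if (offset < reference$start || offset + n - 1L > reference$end)
    stop("aligned sequence extends outside the reference span")
  if (is.null(covered_range)) covered_range <- c(offset, offset + n - 1L)
  sv <- strsplit(seq, "")[[1L]]
  rv <- strsplit(substring(reference$bases, offset - reference$start + 1L,
                           offset - reference$start + n), "")[[1L]]
  diff <- which(sv != rv)
  if (length(diff) == 0L) return(haplotype(covered_range = covered_range))
  vs <- do.call(rbind, lapply(diff, function(i) {
    pos <- offset + i - 1L
    if (sv[i] == "-") .variant_row(pos, NA_integer_, rv[i], "d", "deletion")
    else .variant_row(pos, NA_integer_, rv[i], sv[i],
                      .substitution_kind(rv[i], sv[i]))
  }))
  haplotype(vs, covered_range = covered_range)
}

#' Reconstruct a sequence from a haplotype
#'
#' Applies substitutions, deletions (as `-`, keeping the alignment frame)
#' and insertions (appended after their anchor position) to the reference
#' in coordinate order.  For substitution-only haplotypes,
#' [variants_from_sequence()] of the result recovers the haplotype.
#'
#' @param reference a [reference_segment()].
#' @param h a [haplotype()].
#' @return Sequence string.
#' @export
reconstruct_sequence <- function(reference, h) {
  v <- as.data.frame(h)
  if (nrow(v) > 0L &&
      (any(v$position < reference$start) || any(v$position > reference$end)))
    stop("variant position outside the reference span")
  chars <- strsplit(reference$bases, "")[[1L]]
  inserts <- rep("", length(chars))
  for (i in seq_len(nrow(v))) {
    off <- v$position[i] - reference$start + 1L
    switch(v$kind[i],
      deletion = { chars[off] <- "-" },
      insertion = { inserts[off] <- paste0(inserts[off], v$alt[i]) },
      `back-mutation-marker` = stop(
        "cannot reconstruct a sequence from a back-mutation marker"),
      { chars[off] <- v$alt[i] })
  }
  paste(paste0(chars, inserts), collapse = "")
}

# -- Normalization, restriction, distance -------------------------------------

#' Normalization policy for control-region haplotypes
#'
#' By common phylogenetic practice, variants at the length-unstable
#' positions 16182/16183, indels in the poly-C tract around position 310,
#' and point/length heteroplasmies are excluded before comparison.
#'
#' @param exclude_positions positions removed outright (any variant kind).
#' @param indel_window closed interval in which insertions/deletions are
#'   removed (the conventional poly-C tract).
#' @param drop_heteroplasmy drop variants whose alternate is an IUPAC
#'   ambiguity code.
#' @return A `normalization_policy` list.
#' @export
normalization_policy <- function(exclude_positions = c(16182L, 16183L),
                                 indel_window = c(303L, 315L),
                                 drop_heteroplasmy = TRUE) {
  structure(list(exclude_positions = as.integer(exclude_positions),
                 indel_window = as.integer(indel_window),
                 drop_heteroplasmy = isTRUE(drop_heteroplasmy)),
            class = "normalization_policy")
}

#' Normalize a haplotype
#'
#' Removes hypermutable/ambiguous calls according to a
#' [normalization_policy()].  Idempotent; never adds variants.
#'
#' @param h a [haplotype()].
#' @param policy a [normalization_policy()].
#' @return Normalized [haplotype()].
#' @export
normalize_haplotype <- function(h, policy = normalization_policy()) {
  v <- as.data.frame(h)
  if (nrow(v) == 0L) return(h)
  drop <- v$position %in% policy$exclude_positions
  indel <- v$kind %in% c("insertion", "deletion")
  drop <- drop | (indel & v$position >= policy$indel_window[1L] &
                  v$position <= policy$indel_window[2L])
  if (policy$drop_heteroplasmy)
    drop <- drop | v$kind == "heteroplasmy" | v$alt %in% .IUPAC_AMBIG
  haplotype(v[!drop, , drop = FALSE], attr(h, "covered_range"))
}

#' Restrict a haplotype to a coordinate range
#'
#' Keeps only variants inside `[start, end]` and intersects the covered
#' range with it.
#'
#' @param h a [haplotype()].
#' @param start,end closed 1-based bounds.
#' @return Restricted [haplotype()].
#' @export
restrict_to_range <- function(h, start, end) {
  stopifnot(start <= end)
  v <- as.data.frame(h)
  keep <- v$position >= start & v$position <= end
  old <- attr(h, "covered_range")
  s <- pmax(old[, 1L], as.integer(start))
  e <- pmin(old[, 2L], as.integer(end))
  ok <- s <= e
  newr <- if (any(ok)) cbind(start = s[ok], end = e[ok])
          else cbind(start = as.integer(start), end = as.integer(end))
  haplotype(v[keep, , drop = FALSE], newr)
}

.hap_keys <- function(h) {
  v <- as.data.frame(h)
  if (nrow(v) == 0L) return(character(0))
  paste0(v$position, ".", ifelse(is.na(v$insertion_index), 0L,
                                 v$insertion_index))
}

.hap_tokens <- function(h) {
  v <- as.data.frame(h)
  if (nrow(v) == 0L) return(character(0))
  paste0(.hap_keys(h), "=", v$alt)
}

.same_range <- function(h1, h2) {
  r1 <- attr(h1, "covered_range"); r2 <- attr(h2, "covered_range")
  isTRUE(all.equal(r1[order(r1[, 1L]), , drop = FALSE],
                   r2[order(r2[, 1L]), , drop = FALSE],
                   check.attributes = FALSE))
}

#' Step-mutation distance between two haplotypes
#'
#' Number of (position, insertion index) slots at which the two haplotypes
#' carry different states: the symmetric difference of their variant sets,
#' with a slot where both carry a variant but with different alternates
#' counted once.  Both haplotypes must be normalized and restricted to the
#' same covered range.
#'
#' @param h1,h2 [haplotype()] objects over a common range.
#' @return Non-negative integer.
#' @export
haplotype_distance <- function(h1, h2) {
  if (!.same_range(h1, h2))
    stop("haplotypes cover different ranges; restrict to a common range first")
  k1 <- .hap_keys(h1); k2 <- .hap_keys(h2)
  t1 <- .hap_tokens(h1); t2 <- .hap_tokens(h2)
  shared_keys <- sum(k1 %in% k2)
  shared_tokens <- sum(t1 %in% t2)
  length(k1) + length(k2) - shared_keys - shared_tokens
}

# -- Sample tables ------------------------------------------------------------

#' Read a sample table
#'
#' TSV with header columns `id`, `population`, `locality`, `haplotype`
#' (space-separated variant tokens) and optionally `region` and
#' `haplogroup`.
#'
#' @param path TSV file.
#' @param reference optional [reference_segment()] for resolving bare tokens.
#' @param covered_range covered range assigned to every parsed haplotype.
#' @return Data frame with one row per sample and a list-column
#'   `haplotype` of [haplotype()] objects.
#' @export
read_sample_table <- function(path, reference = NULL, covered_range = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character", na.strings = NULL)
  required <- c("id", "population", "locality", "haplotype")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L)
    stop(sprintf("sample table is missing required column(s): %s",
                 paste(missing, collapse = ", ")))
  if (anyDuplicated(df$id))
    stop(sprintf("duplicate sample id(s): %s",
                 paste(unique(df$id[duplicated(df$id)]), collapse = ", ")))
  if (!"region" %in% names(df)) df$region <- rep(NA_character_, nrow(df))
  if (!"haplogroup" %in% names(df))
    df$haplogroup <- rep(NA_character_, nrow(df))
  df$region[which(!nzchar(df$region))] <- NA_character_
  df$haplogroup[which(!nzchar(df$haplogroup))] <- NA_character_
  haps <- lapply(df$haplotype, parse_haplotype, reference = reference,
                 covered_range = covered_range, allow_back_mutation = FALSE)
  out <- df[, c("id", "population", "locality", "region", "haplogroup")]
  out$haplotype <- I(haps)
  rownames(out) <- NULL
  out
}

#' Write a sample table
#'
#' Inverse of [read_sample_table()]: `read_sample_table(write_sample_table(x))`
#' recovers `x`.
#'
#' @param records data frame as returned by [read_sample_table()].
#' @param path output TSV file.
#' @return `path`, invisibly.
#' @export
write_sample_table <- function(records, path) {
  df <- data.frame(id = records$id, population = records$population,
                   locality = records$locality, region = records$region,
                   haplogroup = records$haplogroup,
                   haplotype = vapply(records$haplotype, function(h)
                     paste(format_variants(h), collapse = " "), character(1)),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Extract the haplotype list from records or a haplotype list
#' @keywords internal
.as_haplotype_list <- function(x) {
  if (is.data.frame(x) && "haplotype" %in% names(x)) return(x$haplotype)
  if (inherits(x, "haplotype")) return(list(x))
  stopifnot(is.list(x))
  x
}
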