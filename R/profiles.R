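# Construction of phylogenetic profiles from alignment E-values.
#
# A phylogenetic profile describes, for one query protein, how strongly a
# homolog is conserved in each genome of a reference set. Instead of a binary
# presence/absence vector the profile holds graded probabilities derived from
# the best alignment E-value per genome: P = -1/log10(E), with P capped at 1
# for E-values above the 0.1 significance cutoff (and for genomes with no hit
# at all, the "no significant homolog" state).

#' Convert alignment E-values to profile probabilities
#'
#' Applies the transform `P = -1/log10(E)`. E-values above the significance
#' cutoff of 0.1 — and missing hits, encoded as `NA` — map to 1, the "no
#' significant homolog" state. E-values at or below `floor` (alignment tools
#' report `0.0` for underflowed E-values) are clamped to `floor` so the
#' logarithm is defined.
#'
#' The transform is monotone non-decreasing: stronger homology evidence
#' (smaller E) gives a smaller probability value, and the result always lies
#' in `(0, 1]`. At the cutoff itself, `-1/log10(0.1) = 1`, so the cap is
#' continuous.
#'
#' @param e Numeric vector of E-values (each `>= 0`), with `NA` meaning "no
#'   hit".
#' @param floor Positive clamp applied to E-values below it (default
#'   `1e-200`).
#' @return Numeric vector of probabilities in `(0, 1]`.
#' @examples
#' evalue_to_probability(c(1e-10, 0.5, 1e-100, 0.1, NA))
#' @export
evalue_to_probability <- function(e, floor = 1e-200) {
  e <- as.numeric(e)
  if (any(!is.na(e) & e < 0)) {
    stop("E-values must be non-negative", call. = FALSE)
  }
  if (!is.numeric(floor) || length(floor) != 1L || floor <= 0 || floor > 0.1) {
    stop("'floor' must be a single value in (0, 0.1]", call. = FALSE)
  }
  p <- rep(1, length(e))
  sig <- !is.na(e) & e <= 0.1
  p[sig] <- -1 / log10(pmax(e[sig], floor))
  p
}

#' Phylogenetic profile matrix
#'
#' A numeric matrix of proteins (rows) by reference genomes (columns) holding
#' probability values in `(0, 1]`, where 1 encodes "no significant homolog".
#'
#' @param values Numeric matrix of probabilities in `(0, 1]`.
#' @param proteins,genomes Row / column identifiers; default to the dimnames
#'   of `values`.
#' @return A `profile_matrix` object (a classed numeric matrix).
#' @export
profile_matrix <- function(values, proteins = rownames(values),
                           genomes = colnames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(genomes) || length(genomes) != ncol(values)) {
    stop("genome identifiers must match the number of columns", call. = FALSE)
  }
  if (nrow(values) > 0 &&
      (is.null(proteins) || length(proteins) != nrow(values))) {
    stop("protein identifiers must match the number of rows", call. = FALSE)
  }
  if (anyDuplicated(proteins)) {
    stop("duplicate protein identifiers", call. = FALSE)
  }
  if (anyDuplicated(genomes)) {
    stop("duplicate genome identifiers", call. = FALSE)
  }
  bad <- which(is.na(values) | values <= 0 | values > 1)
  if (length(bad)) {
    rc <- arrayInd(bad[1L], dim(values))
    stop(sprintf(
      "profile values must lie in (0, 1]: offending entry at row '%s', column '%s'",
      proteins[rc[1L]], genomes[rc[2L]]
    ), call. = FALSE)
  }
  dimnames(values) <- list(proteins, genomes)
  structure(values, class = c("profile_matrix", "matrix", "array"))
}

#' @export
print.profile_matrix <- function(x, ...) {
  cat(sprintf(
    "Phylogenetic profile matrix: %d proteins x %d genomes\n",
    nrow(x), ncol(x)
  ))
  if (nrow(x)) {
    cat(sprintf(
      "  values in [%.4g, %.4g]; fraction at 1 (no homolog): %.3f\n",
      min(x), max(x), mean(x == 1)
    ))
  }
  invisible(x)
}

#' Parse a 12-column tabular alignment hit table
#'
#' Reads the standard tab-separated alignment output dialect (BLAST
#' `-outfmt 6` / FASTA `-m 8`): query id in column 1, subject id in column 2,
#' E-value in column 11. Lines starting with `#` and blank lines are skipped.
#'
#' @param input Path to a hit-table file, or a character vector of lines.
#' @return A data frame of hit records with columns `query_id`, `subject_id`,
#'   `evalue`.
#' @export
parse_hit_table <- function(input) {
  lines <- if (length(input) == 1L && !grepl("[\t\n]", input) &&
               file.exists(input)) {
    readLines(input)
  } else {
    as.character(input)
  }
  lineno <- seq_along(lines)
  keep <- !grepl("^\\s*(#|$)", lines)
  lines <- lines[keep]
  lineno <- lineno[keep]
  if (!length(lines)) {
    return(data.frame(query_id = character(), subject_id = character(),
                      evalue = numeric(), stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- lengths(fields) < 12L
  if (any(short)) {
    stop(sprintf(
      "malformed hit table: fewer than 12 tab-separated columns at line(s) %s",
      paste(utils::head(lineno[short], 5L), collapse = ", ")
    ), call. = FALSE)
  }
  query <- vapply(fields, `[[`, character(1L), 1L)
  subject <- vapply(fields, `[[`, character(1L), 2L)
  etxt <- vapply(fields, `[[`, character(1L), 11L)
  evalue <- suppressWarnings(as.numeric(etxt))
  bad <- is.na(evalue)
  if (any(bad)) {
    stop(sprintf(
      "non-numeric E-value '%s' at line %d",
      etxt[bad][1L], lineno[bad][1L]
    ), call. = FALSE)
  }
  if (any(evalue < 0)) {
    stop(sprintf(
      "negative E-value at line %d", lineno[evalue < 0][1L]
    ), call. = FALSE)
  }
  if (any(!nzchar(query) | !nzchar(subject))) {
    stop(sprintf(
      "empty query or subject identifier at line %d",
      lineno[!nzchar(query) | !nzchar(subject)][1L]
    ), call. = FALSE)
  }
  data.frame(query_id = query, subject_id = subject, evalue = evalue,
             stringsAsFactors = FALSE)
}

#' Subject-to-genome mapping
#'
#' Associates every subject (reference-set protein) identifier with the genome
#' it belongs to, together with the ordered genome roster that fixes the
#' column order of profile matrices.
#'
#' @param mapping Data frame with columns `subject_id` and `genome_id`.
#' @param roster Ordered character vector of genome identifiers; defaults to
#'   the genomes in `mapping`, in order of first appearance.
#' @return A `genome_map` object.
#' @export
genome_map <- function(mapping, roster = NULL) {
  if (!all(c("subject_id", "genome_id") %in% names(mapping))) {
    stop("mapping needs columns 'subject_id' and 'genome_id'", call. = FALSE)
  }
  mapping <- data.frame(
    subject_id = as.character(mapping$subject_id),
    genome_id = as.character(mapping$genome_id),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(mapping$subject_id)) {
    stop("duplicate subject identifiers in genome map", call. = FALSE)
  }
  if (is.null(roster)) roster <- unique(mapping$genome_id)
  roster <- as.character(roster)
  if (anyDuplicated(roster)) {
    stop("genome roster contains duplicates", call. = FALSE)
  }
  missing <- setdiff(mapping$genome_id, roster)
  if (length(missing)) {
    stop(sprintf(
      "genome(s) in mapping but not in roster: %s",
      paste(utils::head(missing, 5L), collapse = ", ")
    ), call. = FALSE)
  }
  structure(mapping, roster = roster, class = c("genome_map", "data.frame"))
}

#' Read a subject-to-genome map from TSV
#'
#' @param path Two-column TSV (subject id, genome id), no header.
#' @param roster_path Optional one-column file fixing the genome roster order.
#' @return A [genome_map()] object.
#' @export
read_genome_map <- function(path, roster_path = NULL) {
  m <- utils::read.table(path, sep = "\t", header = FALSE,
                         col.names = c("subject_id", "genome_id"),
                         colClasses = "character")
  roster <- if (!is.null(roster_path)) readLines(roster_path) else NULL
  genome_map(m, roster = roster)
}

#' Best alignment hit per genome
#'
#' Aggregates hit records into an E-value matrix with one entry per (query
#' protein, reference genome): the minimum E-value over all subjects of that
#' genome. Cells with no hit are `NA`. Hits to subjects absent from the genome
#' map are skipped with a warning giving their count; the result does not
#' depend on the order of the input records.
#'
#' @param hits Data frame of hit records from [parse_hit_table()].
#' @param gmap A [genome_map()].
#' @param queries Ordered protein identifiers fixing the row order; defaults
#'   to the queries present in `hits`, in order of first appearance.
#' @return An `evalue_matrix`: numeric matrix (queries x roster) with `NA`
#'   marking "no hit".
#' @export
best_hits <- function(hits, gmap, queries = NULL) {
  roster <- attr(gmap, "roster")
  if (!length(roster)) {
    stop("genome roster is empty", call. = FALSE)
  }
  genome <- gmap$genome_id[match(hits$subject_id, gmap$subject_id)]
  unresolved <- is.na(genome)
  if (any(unresolved)) {
    warning(sprintf(
      "%d hit(s) to subjects absent from the genome map were skipped",
      sum(unresolved)
    ), call. = FALSE)
    hits <- hits[!unresolved, , drop = FALSE]
    genome <- genome[!unresolved]
  }
  if (is.null(queries)) queries <- unique(hits$query_id)
  queries <- as.character(queries)
  em <- matrix(NA_real_, nrow = length(queries), ncol = length(roster),
               dimnames = list(queries, roster))
  if (nrow(hits)) {
    qi <- match(hits$query_id, queries)
    known <- !is.na(qi)
    if (any(!known)) {
      warning(sprintf(
        "%d hit(s) for queries outside the requested protein list were skipped",
        sum(!known)
      ), call. = FALSE)
    }
    idx <- cbind(qi[known], match(genome[known], roster))
    ev <- hits$evalue[known]
    # assign in decreasing E-value order so the smallest value wins per cell
    o <- order(ev, decreasing = TRUE)
    em[idx[o, , drop = FALSE]] <- ev[o]
  }
  structure(em, class = c("evalue_matrix", "matrix", "array"))
}

#' Build a profile matrix from an E-value matrix
#'
#' Elementwise application of [evalue_to_probability()]; protein and genome
#' order are preserved.
#'
#' @param em An `evalue_matrix` from [best_hits()] (`NA` = no hit).
#' @param floor E-value clamp, see [evalue_to_probability()].
#' @return A [profile_matrix()].
#' @export
build_profile_matrix <- function(em, floor = 1e-200) {
  values <- matrix(evalue_to_probability(em, floor = floor),
                   nrow = nrow(em), ncol = ncol(em), dimnames = dimnames(em))
  profile_matrix(values)
}

#' Write / read a profile matrix as TSV
#'
#' The on-disk layout is a header row of genome identifiers (first cell
#' `protein_id`), one row per protein, tab-separated, `.` decimal, values
#' printed at 10 significant digits so that write-then-read is an identity up
#' to text round-trip.
#'
#' @param pm A [profile_matrix()].
#' @param path File path.
#' @return `write_profile_tsv` returns `path` invisibly; `read_profile_tsv`
#'   returns a [profile_matrix()].
#' @export
write_profile_tsv <- function(pm, path) {
  stopifnot(inherits(pm, "profile_matrix"))
  header <- paste(c("protein_id", colnames(pm)), collapse = "\t")
  rows <- vapply(seq_len(nrow(pm)), function(i) {
    paste(c(rownames(pm)[i], formatC(pm[i, ], format = "g", digits = 10)),
          collapse = "\t")
  }, character(1L))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' @rdname write_profile_tsv
#' @export
read_profile_tsv <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           check.names = FALSE, colClasses = "character",
                           comment.char = "")
  if (names(tab)[1L] != "protein_id") {
    stop("profile TSV must start with a 'protein_id' column", call. = FALSE)
  }
  proteins <- tab[[1L]]
  if (anyDuplicated(proteins)) {
    stop(sprintf("duplicate protein id '%s' in profile TSV",
                 proteins[duplicated(proteins)][1L]), call. = FALSE)
  }
  genomes <- names(tab)[-1L]
  values <- matrix(NA_real_, length(proteins), length(genomes),
                   dimnames = list(proteins, genomes))
  for (j in seq_along(genomes)) {
    v <- suppressWarnings(as.numeric(tab[[j + 1L]]))
    bad <- which(is.na(v) | v <= 0 | v > 1)
    if (length(bad)) {
      stop(sprintf(
        "invalid profile value '%s' at row '%s', column '%s' (must be in (0, 1])",
        tab[[j + 1L]][bad[1L]], proteins[bad[1L]], genomes[j]
      ), call. = FALSE)
    }
    values[, j] <- v
  }
  profile_matrix(values)
}
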