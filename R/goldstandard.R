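# Gold standards for protein-protein interaction benchmarks.
#
# True positives come either from shared metabolic-pathway membership
# (functional, "fun") or from a curated physical-interaction pair list
# ("phy"). True negatives come from a pathway graph: pathways are nodes,
# connected when they share at least one protein, and a protein pair counts
# as non-interacting when the shortest path between their pathways is at
# least `min_dist` (default 5); unreachable pathways satisfy the criterion.

# canonical unordered pair representation: id1 < id2, deduplicated
.canonical_pairs <- function(id1, id2, drop_self = TRUE) {
  id1 <- as.character(id1)
  id2 <- as.character(id2)
  swap <- id1 > id2
  tmp <- id1[swap]
  id1[swap] <- id2[swap]
  id2[swap] <- tmp
  self <- id1 == id2
  n_self <- sum(self)
  if (drop_self && n_self) {
    id1 <- id1[!self]
    id2 <- id2[!self]
  }
  key <- paste(id1, id2, sep = "\r")
  keep <- !duplicated(key)
  out <- data.frame(id1 = id1[keep], id2 = id2[keep],
                    stringsAsFactors = FALSE)
  out <- out[order(out$id1, out$id2), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_self") <- n_self
  out
}

.pair_key <- function(pairs) paste(pairs$id1, pairs$id2, sep = "\r")

#' Pathway membership table
#'
#' Records of (protein, pathway); a protein may belong to several pathways.
#' Duplicate records are dropped.
#'
#' @param records Data frame with columns `protein_id` and `pathway_id`.
#' @return A `pathway_membership` data frame.
#' @export
pathway_membership <- function(records) {
  if (!all(c("protein_id", "pathway_id") %in% names(records))) {
    stop("membership needs columns 'protein_id' and 'pathway_id'",
         call. = FALSE)
  }
  m <- data.frame(protein_id = as.character(records$protein_id),
                  pathway_id = as.character(records$pathway_id),
                  stringsAsFactors = FALSE)
  m <- m[!duplicated(paste(m$protein_id, m$pathway_id, sep = "\r")), ,
         drop = FALSE]
  rownames(m) <- NULL
  structure(m, class = c("pathway_membership", "data.frame"))
}

#' Read a pathway membership TSV
#'
#' @param path Two-column TSV (protein id, pathway id), no header.
#' @return A [pathway_membership()].
#' @export
read_membership_tsv <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("protein_id", "pathway_id"),
                           colClasses = "character", comment.char = "#")
  pathway_membership(tab)
}

#' Build the pathway graph and its shortest-path table
#'
#' Pathways are nodes; an undirected edge joins two pathways sharing at least
#' `min_shared` proteins (no self-loops). All-pairs shortest-path lengths are
#' computed on the unweighted graph; unreachable pairs are `Inf`.
#'
#' @param m A [pathway_membership()].
#' @param min_shared Minimum number of shared proteins for an edge
#'   (default 1).
#' @return A `pathway_graph`: list with `pathways`, `members` (list of
#'   protein vectors), the igraph object `graph`, and the `dist` matrix.
#' @export
build_pathway_graph <- function(m, min_shared = 1L) {
  if (!nrow(m)) stop("membership table is empty", call. = FALSE)
  members <- split(m$protein_id, m$pathway_id)
  ids <- names(members)
  npw <- length(ids)
  # shared-protein counts via the protein x pathway incidence matrix
  inc <- table(m$protein_id, m$pathway_id)[, ids, drop = FALSE] > 0
  shared <- crossprod(inc * 1L)
  adj <- (shared >= min_shared) * 1L
  diag(adj) <- 0L
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  d <- igraph::distances(g)
  dimnames(d) <- list(ids, ids)
  structure(list(pathways = ids, members = members, graph = g, dist = d),
            class = "pathway_graph")
}

#' Functional true positives: co-pathway protein pairs
#'
#' All unordered pairs of distinct proteins that co-occur in at least one
#' pathway, deduplicated across pathways.
#'
#' @param m A [pathway_membership()].
#' @return Data frame of canonical pairs (`id1 < id2`).
#' @export
true_positives_fun <- function(m) {
  if (!nrow(m)) stop("membership table is empty", call. = FALSE)
  members <- split(unique(m)$protein_id, unique(m)$pathway_id)
  pieces <- lapply(members, function(p) {
    p <- unique(p)
    if (length(p) < 2L) return(NULL)
    cmb <- utils::combn(sort(p), 2L)
    data.frame(id1 = cmb[1L, ], id2 = cmb[2L, ], stringsAsFactors = FALSE)
  })
  all <- do.call(rbind, pieces)
  if (is.null(all)) {
    return(data.frame(id1 = character(), id2 = character(),
                      stringsAsFactors = FALSE))
  }
  .canonical_pairs(all$id1, all$id2)
}

#' True negatives by the pathway-graph distance rule
#'
#' A pair of annotated proteins is a true negative when the minimum
#' shortest-path distance over all pathway pairs (one pathway containing each
#' protein) is at least `min_dist`; unreachable pathways (`Inf`) satisfy the
#' rule. Proteins with no pathway annotation are never TN candidates: absence
#' of annotation is not evidence of non-interaction. Taking the minimum over
#' a protein's pathways is the most conservative choice for declaring
#' non-interaction.
#'
#' @param m A [pathway_membership()].
#' @param min_dist Distance threshold (default 5).
#' @param graph Optional precomputed [build_pathway_graph()] result.
#' @return Data frame of canonical TN pairs.
#' @export
true_negatives <- function(m, min_dist = 5L, graph = NULL) {
  if (min_dist < 1L) stop("min_dist must be >= 1", call. = FALSE)
  if (is.null(graph)) graph <- build_pathway_graph(m)
  d <- graph$dist
  ann <- split(m$pathway_id, m$protein_id)
  prot <- sort(names(ann))
  n <- length(prot)
  if (n < 2L) {
    return(data.frame(id1 = character(), id2 = character(),
                      stringsAsFactors = FALSE))
  }
  out1 <- character()
  out2 <- character()
  for (a in seq_len(n - 1L)) {
    pa <- unique(ann[[prot[a]]])
    for (b in (a + 1L):n) {
      pb <- unique(ann[[prot[b]]])
      if (min(d[pa, pb]) >= min_dist) {
        out1 <- c(out1, prot[a])
        out2 <- c(out2, prot[b])
      }
    }
  }
  .canonical_pairs(out1, out2)
}

#' Load a physical-interaction pair list
#'
#' Two id columns (whitespace- or tab-separated); any further columns (e.g.
#' confidence scores) are ignored. Pairs are canonicalized to unordered form;
#' self-pairs are dropped and counted.
#'
#' @param input File path or character vector of lines.
#' @return Data frame of canonical pairs with attribute `n_self_dropped`.
#' @export
load_physical_pairs <- function(input) {
  lines <- if (length(input) == 1L && !grepl("[\t\n ]", input) &&
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
    out <- data.frame(id1 = character(), id2 = character(),
                      stringsAsFactors = FALSE)
    attr(out, "n_self_dropped") <- 0L
    return(out)
  }
  fields <- strsplit(trimws(lines), "[\t ]+")
  short <- lengths(fields) < 2L
  if (any(short)) {
    stop(sprintf("malformed pair list: fewer than 2 columns at line %d",
                 lineno[short][1L]), call. = FALSE)
  }
  id1 <- vapply(fields, `[[`, character(1L), 1L)
  id2 <- vapply(fields, `[[`, character(1L), 2L)
  out <- .canonical_pairs(id1, id2)
  n_self <- attr(out, "n_self")
  if (n_self) {
    warning(sprintf("%d self-pair(s) dropped", n_self), call. = FALSE)
  }
  attr(out, "n_self_dropped") <- n_self
  attr(out, "n_self") <- NULL
  out
}

#' Assemble a labeled gold standard
#'
#' Combines a positive pair set (functional co-pathway pairs or physical
#' interactions) with true negatives derived from the pathway graph. Any pair
#' appearing in both sets is kept positive only.
#'
#' @param positives Data frame of positive pairs (columns `id1`, `id2`).
#' @param m A [pathway_membership()] used to derive the negatives.
#' @param flavor `"fun"` (functional) or `"phy"` (physical).
#' @param min_dist Pathway distance threshold for negatives.
#' @param graph Optional precomputed pathway graph.
#' @return A `gold_standard`: list with `positives`, `negatives`, `flavor`,
#'   `min_dist` and a `provenance` note.
#' @export
assemble_gold_standard <- function(positives, m, flavor = c("fun", "phy"),
                                   min_dist = 5L, graph = NULL) {
  flavor <- match.arg(flavor)
  if (!nrow(positives)) stop("positive pair set is empty", call. = FALSE)
  pos <- .canonical_pairs(positives$id1, positives$id2)
  neg <- true_negatives(m, min_dist = min_dist, graph = graph)
  overlap <- .pair_key(neg) %in% .pair_key(pos)
  neg <- neg[!overlap, , drop = FALSE]
  rownames(neg) <- NULL
  if (!nrow(neg)) {
    warning("gold standard has an empty negative set", call. = FALSE)
  }
  structure(list(
    positives = pos, negatives = neg, flavor = flavor, min_dist = min_dist,
    provenance = sprintf(
      paste0("negatives: pathway graph (edge = >=1 shared protein, ",
             "multi-pathway proteins use the minimum pathway-pair distance, ",
             "unreachable = Inf counts as TN), min_dist = %d; ",
             "%d overlapping pair(s) kept positive"),
      min_dist, sum(overlap)
    )
  ), class = "gold_standard")
}

#' @export
print.gold_standard <- function(x, ...) {
  cat(sprintf("Gold standard (%s): %d positives, %d negatives\n",
              x$flavor, nrow(x$positives), nrow(x$negatives)))
  cat(" ", x$provenance, "\n")
  invisible(x)
}

#' Write a gold standard as a labeled-pair TSV
#'
#' Columns: `id1`, `id2`, `label` (TP/TN), `flavor`.
#'
#' @param gs A `gold_standard`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_gold_standard_tsv <- function(gs, path) {
  pos <- cbind(gs$positives, label = "TP", flavor = gs$flavor)
  neg <- if (nrow(gs$negatives)) {
    cbind(gs$negatives, label = "TN", flavor = gs$flavor)
  }
  utils::write.table(rbind(pos, neg), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a labeled-pair TSV back into a gold standard
#'
#' @param path File written by [write_gold_standard_tsv()].
#' @return A `gold_standard`.
#' @export
read_gold_standard_tsv <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           colClasses = "character")
  structure(list(
    positives = tab[tab$label == "TP", c("id1", "id2")],
    negatives = tab[tab$label == "TN", c("id1", "id2")],
    flavor = tab$flavor[1L],
    min_dist = NA_integer_,
    provenance = sprintf("read from %s", path)
  ), class = "gold_standard")
}
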