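# Blocked split-apply-combine engine for the all-pairs distance-correlation
# matrix.
#
# The i x j profile matrix is split into N contiguous row chunks. For each
# chunk the double-centered distance matrices of its rows are computed and
# persisted to a repository of versioned .rds files, described by a
# human-readable TSV manifest with md5 checksums. The full i x i matrix is
# then assembled by streaming chunk pairs back: at most two chunks of
# centered matrices are resident at any moment, so peak memory is governed by
# i / N rather than i. Results are bit-for-bit independent of the chunk count
# and of the worker count because every chunk pair is reduced in a fixed
# order.

#' Split a profile matrix into contiguous row chunks
#'
#' @param pm A [profile_matrix()].
#' @param n_chunks Number of chunks, `1 <= n_chunks <= nrow(pm)`; chunk sizes
#'   differ by at most one and the original row order is preserved.
#' @return List of `profile_matrix` row blocks.
#' @export
split_profiles <- function(pm, n_chunks) {
  i <- nrow(pm)
  if (n_chunks < 1L || n_chunks > i) {
    stop(sprintf("n_chunks must lie in [1, %d]", i), call. = FALSE)
  }
  base <- i %/% n_chunks
  extra <- i %% n_chunks
  sizes <- rep(base, n_chunks) + c(rep(1L, extra), rep(0L, n_chunks - extra))
  ends <- cumsum(sizes)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  lapply(seq_len(n_chunks), function(k) {
    profile_matrix(unclass(pm)[starts[k]:ends[k], , drop = FALSE])
  })
}

.REPO_VERSION <- "profcor-repo v1"
.manifest_cols <- c("chunk_id", "proteins", "j", "md5", "file")

#' Open or create a chunk repository
#'
#' A repository is a directory holding one `.rds` file per chunk (the
#' flattened centered distance matrices of its proteins) and a `MANIFEST.tsv`
#' listing chunk id, protein ids, profile length, md5 checksum and file name
#' under a format-version header line.
#'
#' @param dir Directory path; created if absent.
#' @return A `chunk_repository` handle.
#' @export
chunk_repository <- function(dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  mf <- file.path(dir, "MANIFEST.tsv")
  if (!file.exists(mf)) {
    .write_manifest(dir, .empty_manifest())
  }
  structure(list(dir = dir), class = "chunk_repository")
}

.empty_manifest <- function() {
  as.data.frame(stats::setNames(
    list(character(), character(), integer(), character(), character()),
    .manifest_cols
  ), stringsAsFactors = FALSE)
}

.read_manifest <- function(dir) {
  mf <- file.path(dir, "MANIFEST.tsv")
  if (!file.exists(mf)) {
    stop(sprintf("no manifest at '%s'", mf), call. = FALSE)
  }
  lines <- readLines(mf)
  if (!length(lines) || lines[1L] != paste0("# ", .REPO_VERSION)) {
    stop("unrecognized chunk repository format version", call. = FALSE)
  }
  if (length(lines) < 2L) return(.empty_manifest())
  tab <- utils::read.table(text = lines[-1L], sep = "\t", header = TRUE,
                           colClasses = "character", comment.char = "")
  if (!identical(names(tab), .manifest_cols)) {
    stop("corrupt chunk repository manifest", call. = FALSE)
  }
  tab$j <- as.integer(tab$j)
  tab
}

# atomic update: write a temp file in the same directory, then rename
.write_manifest <- function(dir, manifest) {
  tmp <- tempfile("MANIFEST", tmpdir = dir, fileext = ".tmp")
  body <- c(
    paste0("# ", .REPO_VERSION),
    paste(.manifest_cols, collapse = "\t"),
    if (nrow(manifest)) {
      vapply(seq_len(nrow(manifest)), function(r) {
        paste(as.character(unlist(manifest[r, ])), collapse = "\t")
      }, character(1L))
    }
  )
  writeLines(body, tmp)
  if (!file.rename(tmp, file.path(dir, "MANIFEST.tsv"))) {
    stop("failed to update manifest atomically", call. = FALSE)
  }
  invisible(NULL)
}

.manifest_proteins <- function(manifest) {
  if (!nrow(manifest)) return(character())
  unlist(strsplit(manifest$proteins, ",", fixed = TRUE), use.names = FALSE)
}

#' Compute and persist centered distance matrices for a chunk
#'
#' For each protein of the chunk, its double-centered distance matrix (as in
#' [double_center()] of [pairwise_abs_distance()]) is computed; the chunk is
#' written to a versioned `.rds` file and registered in the manifest with its
#' md5 checksum. The manifest update is atomic (temp file + rename), so an
#' interrupted store leaves the repository valid.
#'
#' @param chunk A [profile_matrix()] row block whose proteins are not yet in
#'   the repository.
#' @param repo A [chunk_repository()].
#' @param chunk_id Optional identifier; defaults to the next sequential id.
#' @return The repository handle, invisibly.
#' @export
compute_and_store_centered <- function(chunk, repo, chunk_id = NULL) {
  stopifnot(inherits(repo, "chunk_repository"))
  manifest <- .read_manifest(repo$dir)
  clash <- intersect(rownames(chunk), .manifest_proteins(manifest))
  if (length(clash)) {
    stop(sprintf("protein(s) already stored in repository: %s",
                 paste(utils::head(clash, 5L), collapse = ", ")),
         call. = FALSE)
  }
  if (nrow(manifest) && any(manifest$j != ncol(chunk))) {
    stop("chunk profile length disagrees with repository", call. = FALSE)
  }
  if (is.null(chunk_id)) chunk_id <- sprintf("c%04d", nrow(manifest) + 1L)
  if (chunk_id %in% manifest$chunk_id) {
    stop(sprintf("chunk id '%s' already present", chunk_id), call. = FALSE)
  }
  payload <- list(version = .REPO_VERSION,
                  proteins = rownames(chunk),
                  j = ncol(chunk),
                  flat = .centered_flat(chunk))
  fname <- paste0("chunk_", chunk_id, ".rds")
  fpath <- file.path(repo$dir, fname)
  tmp <- tempfile("chunk", tmpdir = repo$dir, fileext = ".tmp")
  saveRDS(payload, tmp, version = 2L, compress = FALSE)
  if (!file.rename(tmp, fpath)) {
    stop("failed to write chunk file atomically", call. = FALSE)
  }
  row <- data.frame(chunk_id = chunk_id,
                    proteins = paste(rownames(chunk), collapse = ","),
                    j = ncol(chunk),
                    md5 = unname(tools::md5sum(fpath)),
                    file = fname, stringsAsFactors = FALSE)
  .write_manifest(repo$dir, rbind(manifest, row))
  invisible(repo)
}

#' Verify a chunk repository
#'
#' Checks that every manifest entry has its file, that md5 checksums match,
#' and that chunk protein sets do not overlap. Called before any blocked
#' computation so integrity failures surface before work starts.
#'
#' @param repo A [chunk_repository()].
#' @return The manifest data frame, invisibly.
#' @export
repo_verify <- function(repo) {
  manifest <- .read_manifest(repo$dir)
  for (r in seq_len(nrow(manifest))) {
    fpath <- file.path(repo$dir, manifest$file[r])
    if (!file.exists(fpath)) {
      stop(sprintf("integrity error: chunk '%s' file '%s' is missing",
                   manifest$chunk_id[r], manifest$file[r]), call. = FALSE)
    }
    if (unname(tools::md5sum(fpath)) != manifest$md5[r]) {
      stop(sprintf("integrity error: checksum mismatch for chunk '%s'",
                   manifest$chunk_id[r]), call. = FALSE)
    }
  }
  prot <- .manifest_proteins(manifest)
  if (anyDuplicated(prot)) {
    stop("integrity error: overlapping chunk protein sets", call. = FALSE)
  }
  invisible(manifest)
}

.load_chunk <- function(repo, manifest, r) {
  payload <- readRDS(file.path(repo$dir, manifest$file[r]))
  if (!identical(payload$version, .REPO_VERSION)) {
    stop(sprintf("integrity error: chunk '%s' has unexpected format version",
                 manifest$chunk_id[r]), call. = FALSE)
  }
  payload
}

#' Assemble the distance-correlation matrix from a chunk repository
#'
#' Streams stored centered distance matrices back chunk-pair by chunk-pair
#' (upper triangle of chunk blocks, row-major), so at most two chunks are
#' resident at once. The covariance block of a chunk pair is one
#' cross-product of the flattened centered matrices; variances come from the
#' diagonal blocks. The result is identical (within floating-point summation
#' order) to [similarity_matrix()] with `metric = "dcor"` on the same
#' profiles, whatever the chunk count or worker count.
#'
#' @param repo A [chunk_repository()] holding the complete protein set.
#' @param workers Number of parallel workers for the chunk-pair map
#'   (fork-based; results are combined in a fixed order so the output does
#'   not depend on scheduling).
#' @inheritParams similarity_matrix
#' @return A `similarity_matrix` with attribute `max_resident_chunks = 2`.
#' @export
dcor_matrix_from_repository <- function(repo, workers = 1L, root = FALSE) {
  manifest <- repo_verify(repo)
  if (!nrow(manifest)) {
    stop("repository is empty", call. = FALSE)
  }
  ids <- .manifest_proteins(manifest)
  nchunk <- nrow(manifest)
  # pass 1: per-protein variances, one chunk resident at a time
  vars <- vector("list", nchunk)
  for (r in seq_len(nchunk)) {
    payload <- .load_chunk(repo, manifest, r)
    vars[[r]] <- colSums(payload$flat^2) / nrow(payload$flat)
  }
  v <- unlist(vars, use.names = FALSE)
  names(v) <- ids
  deg <- v < .DEGENERATE_VAR
  # pass 2: covariance blocks over the upper triangle of chunk pairs
  pairs <- list()
  for (a in seq_len(nchunk)) {
    for (b in a:nchunk) pairs[[length(pairs) + 1L]] <- c(a, b)
  }
  block_fun <- function(ab) {
    pa <- .load_chunk(repo, manifest, ab[1L])
    pb <- if (ab[2L] == ab[1L]) pa else .load_chunk(repo, manifest, ab[2L])
    crossprod(pa$flat, pb$flat) / nrow(pa$flat)
  }
  blocks <- if (workers > 1L) {
    parallel::mclapply(pairs, block_fun, mc.cores = workers)
  } else {
    lapply(pairs, block_fun)
  }
  failed <- vapply(blocks, inherits, logical(1L), "try-error")
  if (any(failed)) {
    stop(conditionMessage(attr(blocks[[which(failed)[1L]]], "condition")),
         call. = FALSE)
  }
  i <- length(ids)
  s <- matrix(0, i, i, dimnames = list(ids, ids))
  offsets <- c(0L, cumsum(vapply(
    strsplit(manifest$proteins, ",", fixed = TRUE), length, integer(1L)
  )))
  for (k in seq_along(pairs)) {
    a <- pairs[[k]][1L]
    b <- pairs[[k]][2L]
    ra <- (offsets[a] + 1L):offsets[a + 1L]
    rb <- (offsets[b] + 1L):offsets[b + 1L]
    s[ra, rb] <- blocks[[k]] / sqrt(outer(v[ra], v[rb]))
  }
  s[deg, ] <- 0
  s[, deg] <- 0
  if (root) s <- sqrt(pmax(s, 0))
  s[lower.tri(s)] <- t(s)[lower.tri(s)]
  structure(s, class = c("similarity_matrix", "matrix", "array"),
            metric = "dcor", degenerate = ids[deg], max_resident_chunks = 2L)
}

#' Run the blocked distance-correlation pipeline in one call
#'
#' Splits the profiles, stores each chunk's centered matrices in a (by
#' default temporary) repository, and assembles the full matrix.
#'
#' @inheritParams split_profiles
#' @inheritParams dcor_matrix_from_repository
#' @param repo_dir Repository directory; a fresh temporary directory by
#'   default.
#' @param keep_repo Keep the repository on disk after assembly.
#' @return A `similarity_matrix` (metric `"dcor"`).
#' @export
run_blocked_dcor <- function(pm, n_chunks, workers = 1L,
                             repo_dir = tempfile("profcor-repo"),
                             keep_repo = FALSE, root = FALSE) {
  repo <- chunk_repository(repo_dir)
  chunks <- split_profiles(pm, n_chunks)
  for (ch in chunks) compute_and_store_centered(ch, repo)
  out <- dcor_matrix_from_repository(repo, workers = workers, root = root)
  if (!keep_repo) unlink(repo_dir, recursive = TRUE)
  out
}
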