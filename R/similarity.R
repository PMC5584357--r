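# Profile-similarity measures.
#
# Three measures of dependence between two phylogenetic profiles A_p, A_q
# (rows of the profile matrix, length j = number of reference genomes):
#
#  * distance correlation, computed from double-centered matrices of absolute
#    pairwise differences. With DA_p, DA_q the centered matrices, the score is
#    Cov(DA_p, DA_q) / sqrt(Var(DA_p) Var(DA_q)) where Cov and Var are plain
#    means over all j^2 entry pairs. This ratio equals the SQUARE of the
#    classical sample distance correlation (Szekely's V-statistic); the square
#    root is available via `root = TRUE`.
#  * Pearson's product-moment correlation on the raw probability values.
#  * mutual information MI = H(A) + H(B) - H(A,B) with plug-in entropies
#    (natural log) over fixed-width probability bins (default width 0.1).

#' Matrix of absolute pairwise differences of a profile
#'
#' Entry (k, l) is `|a_k - a_l|`, the Euclidean distance between two scalar
#' profile elements; symmetric with a zero diagonal.
#'
#' @param profile Numeric vector of length `>= 2`.
#' @return A j x j numeric matrix.
#' @export
pairwise_abs_distance <- function(profile) {
  profile <- as.numeric(profile)
  if (length(profile) < 2L) {
    stop("profile must have at least 2 elements", call. = FALSE)
  }
  abs(outer(profile, profile, "-"))
}

#' Double-center a distance matrix
#'
#' Subtracts row and column means and adds back the grand mean:
#' `da_kl = d_kl - dbar_k - dbar_l + dbar`, so that every row and column of
#' the result sums to zero. The row means, column means and grand mean are
#' attached as attributes.
#'
#' @param d Square numeric distance matrix.
#' @return The centered matrix, with attributes `row_means`, `col_means`,
#'   `grand_mean`.
#' @export
double_center <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d)) {
    stop("distance matrix must be square", call. = FALSE)
  }
  rm <- rowMeans(d)
  cm <- colMeans(d)
  gm <- mean(d)
  da <- d - outer(rm, rep(1, length(cm))) -
    outer(rep(1, length(rm)), cm) + gm
  structure(da, row_means = rm, col_means = cm, grand_mean = gm)
}

# centered distance matrix of one profile, flattened column-wise
.centered_vec <- function(profile) {
  as.vector(double_center(pairwise_abs_distance(profile)))
}

# j^2 x i matrix of flattened centered distance matrices, one column per row
# of the profile matrix
.centered_flat <- function(pm) {
  m <- unclass(pm)
  out <- vapply(seq_len(nrow(m)), function(i) .centered_vec(m[i, ]),
                numeric(ncol(m)^2))
  colnames(out) <- rownames(m)
  out
}

.DEGENERATE_VAR <- 1e-24

#' Distance correlation of two centered distance matrices
#'
#' The covariance-over-variance ratio of the two double-centered matrices,
#' with means taken over all j^2 entries. Because each centered matrix has
#' grand mean zero, `Cov = mean(dap * daq)` and `Var = mean(da^2)` need no
#' further mean subtraction. The value equals the squared classical sample
#' distance correlation and lies in `[0, 1]`; it is invariant under affine
#' maps of either profile. A matrix with variance below `1e-24` (a constant
#' profile) yields 0 with attribute `degenerate = TRUE` rather than an error.
#'
#' @param dap,daq Centered distance matrices of equal size, as produced by
#'   [double_center()].
#' @param root If `TRUE`, return the square root (the classical distance
#'   correlation scale).
#' @return A single score with logical attribute `degenerate`.
#' @export
dcor_pair <- function(dap, daq, root = FALSE) {
  if (!identical(dim(dap), dim(daq))) {
    stop("centered distance matrices differ in size", call. = FALSE)
  }
  n2 <- length(dap)
  vp <- sum(dap * dap) / n2
  vq <- sum(daq * daq) / n2
  if (vp < .DEGENERATE_VAR || vq < .DEGENERATE_VAR) {
    return(structure(0, degenerate = TRUE))
  }
  s <- (sum(dap * daq) / n2) / sqrt(vp * vq)
  if (root) s <- sqrt(max(s, 0))
  structure(s, degenerate = FALSE)
}

#' Distance correlation of two profiles
#'
#' Convenience wrapper chaining [pairwise_abs_distance()], [double_center()]
#' and [dcor_pair()].
#'
#' @param x,y Numeric profiles of equal length `>= 2`.
#' @inheritParams dcor_pair
#' @return See [dcor_pair()].
#' @export
profile_dcor <- function(x, y, root = FALSE) {
  if (length(x) != length(y)) {
    stop("profiles differ in length", call. = FALSE)
  }
  dcor_pair(double_center(pairwise_abs_distance(x)),
            double_center(pairwise_abs_distance(y)), root = root)
}

#' Pearson correlation of two profiles
#'
#' Standard product-moment correlation. A constant profile yields 0 with a
#' `degenerate` attribute (mirroring the distance-correlation convention)
#' instead of `NA`, so genome-scale runs never abort on one flat profile.
#'
#' @param x,y Numeric profiles of equal length `>= 2`.
#' @return A single score in `[-1, 1]` with logical attribute `degenerate`.
#' @export
pearson_pair <- function(x, y) {
  if (length(x) != length(y)) {
    stop("profiles differ in length", call. = FALSE)
  }
  if (length(x) < 2L) {
    stop("profiles must have at least 2 elements", call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(structure(0, degenerate = TRUE))
  }
  structure(stats::cor(x, y), degenerate = FALSE)
}

#' Bin a pair of profiles into fixed-width probability intervals
#'
#' Bins are `[0, w), [w, 2w), ..., [1 - w, 1]` with the last bin closed so
#' that the very common value 1 ("no homolog") is counted deterministically.
#' The default width 0.1 gives 10 bins.
#'
#' @param x Numeric profile with values in `(0, 1]`.
#' @param y Optional second profile (equal length) for the joint counts.
#' @param width Bin width; must divide 1 exactly.
#' @return A `binned_distribution`: list with `width`, `nbins`, `n`,
#'   `marginal_x`, and when `y` is given `marginal_y` and the
#'   `nbins x nbins` `joint` count matrix.
#' @export
bin_profile <- function(x, y = NULL, width = 0.1) {
  nbins <- round(1 / width)
  if (abs(nbins * width - 1) > 1e-9) {
    stop("bin width must divide 1 exactly", call. = FALSE)
  }
  check <- function(v, name) {
    if (any(is.na(v) | v <= 0 | v > 1)) {
      stop(sprintf("%s has values outside (0, 1]", name), call. = FALSE)
    }
  }
  check(x, "x")
  ix <- pmin(floor(x / width), nbins - 1L) + 1L
  out <- list(width = width, nbins = nbins, n = length(x),
              marginal_x = tabulate(ix, nbins))
  if (!is.null(y)) {
    if (length(y) != length(x)) {
      stop("profiles differ in length", call. = FALSE)
    }
    check(y, "y")
    iy <- pmin(floor(y / width), nbins - 1L) + 1L
    out$marginal_y <- tabulate(iy, nbins)
    joint <- matrix(tabulate((iy - 1L) * nbins + ix, nbins * nbins),
                    nbins, nbins)
    out$joint <- joint
  }
  structure(out, class = "binned_distribution")
}

# plug-in entropy (natural log) from bin counts; 0 * ln 0 contributes 0
.entropy <- function(counts, n) {
  p <- counts[counts > 0] / n
  -sum(p * log(p))
}

#' Marginal entropy of a binned profile
#'
#' @inheritParams bin_profile
#' @return Plug-in entropy (natural log) of the binned value distribution.
#' @export
marginal_entropy <- function(x, width = 0.1) {
  b <- bin_profile(x, width = width)
  .entropy(b$marginal_x, b$n)
}

#' Mutual information of two binned profiles
#'
#' `MI(A, B) = H(A) + H(B) - H(A, B)` with plug-in entropies over the joint
#' and marginal bin counts, natural logarithm. Non-negative up to rounding,
#' symmetric, and equal to `H(A)` when the two profiles coincide.
#'
#' @inheritParams bin_profile
#' @param y Second profile, required.
#' @return A single non-negative score.
#' @export
mutual_information_pair <- function(x, y, width = 0.1) {
  b <- bin_profile(x, y, width = width)
  hx <- .entropy(b$marginal_x, b$n)
  hy <- .entropy(b$marginal_y, b$n)
  hxy <- .entropy(b$joint, b$n)
  hx + hy - hxy
}

#' All-vs-all profile similarity matrix
#'
#' Scores every pair of profile rows with the chosen measure. Only the upper
#' triangle is computed and then mirrored, so the result is exactly
#' symmetric. The diagonal holds the self-score: 1 for `dcor` and `pc` on
#' non-constant rows (0 for constant ones, which are flagged), and the
#' marginal entropy `H(A)` for `mi`.
#'
#' For `dcor` the centered distance matrices of all rows are flattened into
#' one `j^2 x i` array and the covariance block computed with a single
#' cross-product, which is what makes genome-scale runs tractable.
#'
#' @param pm A [profile_matrix()] with at least 2 rows and 2 columns.
#' @param metric One of `"dcor"`, `"pc"`, `"mi"`.
#' @param width Bin width for `mi`.
#' @param root For `dcor`: report the square root (classical distance
#'   correlation) instead of the covariance ratio.
#' @return A `similarity_matrix`: symmetric i x i classed matrix with
#'   attributes `metric` and `degenerate` (ids of constant profiles).
#' @export
similarity_matrix <- function(pm, metric = c("dcor", "pc", "mi"),
                              width = 0.1, root = FALSE) {
  metric <- match.arg(metric)
  m <- unclass(pm)
  if (nrow(m) < 2L || ncol(m) < 2L) {
    stop("similarity_matrix needs at least 2 proteins and 2 genomes",
         call. = FALSE)
  }
  ids <- rownames(m)
  s <- switch(metric,
    dcor = {
      flat <- .centered_flat(m)
      g <- crossprod(flat) / nrow(flat)
      v <- diag(g)
      deg <- v < .DEGENERATE_VAR
      out <- g / sqrt(outer(v, v))
      out[deg, ] <- 0
      out[, deg] <- 0
      if (root) out <- sqrt(pmax(out, 0))
      attr(out, "deg_ids") <- ids[deg]
      out
    },
    pc = {
      sds <- apply(m, 1L, stats::sd)
      deg <- sds == 0
      out <- suppressWarnings(stats::cor(t(m)))
      out[deg, ] <- 0
      out[, deg] <- 0
      diag(out)[!deg] <- 1
      attr(out, "deg_ids") <- ids[deg]
      out
    },
    mi = {
      i <- nrow(m)
      out <- matrix(0, i, i)
      for (p in seq_len(i)) {
        out[p, p] <- marginal_entropy(m[p, ], width = width)
        if (p < i) {
          for (q in seq((p + 1L), i)) {
            out[p, q] <- tryCatch(
              mutual_information_pair(m[p, ], m[q, ], width = width),
              error = function(e) stop(sprintf(
                "mutual information failed for pair ('%s', '%s'): %s",
                ids[p], ids[q], conditionMessage(e)
              ), call. = FALSE)
            )
          }
        }
      }
      attr(out, "deg_ids") <- character()
      out
    }
  )
  deg_ids <- attr(s, "deg_ids")
  attr(s, "deg_ids") <- NULL
  # mirror the upper triangle for exact symmetry
  s[lower.tri(s)] <- t(s)[lower.tri(s)]
  dimnames(s) <- list(ids, ids)
  structure(s, class = c("similarity_matrix", "matrix", "array"),
            metric = metric, degenerate = deg_ids)
}

#' @export
print.similarity_matrix <- function(x, ...) {
  up <- x[upper.tri(x)]
  cat(sprintf(
    "Similarity matrix (%s): %d proteins; off-diagonal range [%.4g, %.4g]\n",
    attr(x, "metric"), nrow(x),
    if (length(up)) min(up) else NA, if (length(up)) max(up) else NA
  ))
  deg <- attr(x, "degenerate")
  if (length(deg)) {
    cat(sprintf("  %d constant (degenerate) profile(s): %s\n", length(deg),
                paste(utils::head(deg, 5L), collapse = ", ")))
  }
  invisible(x)
}

#' Write / read a similarity matrix as TSV
#'
#' @param sm A `similarity_matrix`.
#' @param path File path.
#' @param metric Metric tag to attach on read.
#' @return `write_similarity_tsv` returns `path` invisibly;
#'   `read_similarity_tsv` returns a `similarity_matrix`.
#' @export
write_similarity_tsv <- function(sm, path) {
  header <- paste(c("protein_id", colnames(sm)), collapse = "\t")
  rows <- vapply(seq_len(nrow(sm)), function(i) {
    paste(c(rownames(sm)[i], formatC(sm[i, ], format = "g", digits = 12)),
          collapse = "\t")
  }, character(1L))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' @rdname write_similarity_tsv
#' @export
read_similarity_tsv <- function(path, metric = "dcor") {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           check.names = FALSE, comment.char = "")
  ids <- as.character(tab[[1L]])
  m <- as.matrix(tab[, -1L, drop = FALSE])
  dimnames(m) <- list(ids, colnames(m))
  if (!identical(rownames(m), colnames(m))) {
    stop("similarity TSV row and column ids disagree", call. = FALSE)
  }
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  structure(m, class = c("similarity_matrix", "matrix", "array"),
            metric = metric, degenerate = character())
}
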