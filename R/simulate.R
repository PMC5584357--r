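# Synthetic data with planted dependent profile pairs.
#
# The generator emulates the inputs of the real pipeline without any
# database: a profile matrix whose "interacting modules" share a latent
# genome-occupancy vector, the matching alignment hit table (exact inverse
# of the E-value transform), and toy pathway memberships whose pathway-graph
# distances are known by construction.
#
# Module model: each module draws one latent vector u ~ Uniform(0, 1)^j. Its
# first member carries u itself; every further member carries transform(u),
# where the transform encodes the dependence type (identity for linear, u^2
# for monotone-nonlinear, the parabola 4u(1-u) for non-monotone — a relation
# with essentially zero linear correlation to u but full deterministic
# dependence). Members are mixed with an independent uniform background at
# `strength`, perturbed with Gaussian noise at `noise`, and clipped into the
# profile range. Background proteins are i.i.d.: value 1 ("no homolog") with
# probability `absence_rate`, else uniform on (0, 1).

#' Specification of a synthetic profiling study
#'
#' @param n_proteins Total number of proteins (modules plus background).
#' @param n_genomes Number of reference genomes (profile length).
#' @param n_modules Number of planted interacting modules.
#' @param module_size Proteins per module (`n_modules * module_size <=
#'   n_proteins`).
#' @param dependence Dependence type of module members on the latent vector:
#'   `"non-monotone"` (4u(1-u)), `"linear"` (identity) or
#'   `"monotone-nonlinear"` (u^2).
#' @param strength Dependence strength in `[0, 1]`: weight of the latent
#'   signal against an independent uniform component.
#' @param noise Gaussian noise scale added to module members.
#' @param absence_rate Fraction of background entries forced to 1.
#' @param clip_min Lower clip bound keeping values inside `(0, 1]`.
#' @param seed Integer seed; the same spec always yields identical data.
#' @return A `simulation_spec` list.
#' @export
simulation_spec <- function(n_proteins = 280L, n_genomes = 100L,
                            n_modules = 40L, module_size = 2L,
                            dependence = c("non-monotone", "linear",
                                           "monotone-nonlinear"),
                            strength = 0.9, noise = 0.1,
                            absence_rate = 0.5, clip_min = 1e-6,
                            seed = 1L) {
  dependence <- match.arg(dependence)
  if (n_proteins < 1L || n_genomes < 2L || n_modules < 0L || module_size < 1L) {
    stop("all counts must be positive (n_genomes >= 2)", call. = FALSE)
  }
  if (n_modules * module_size > n_proteins) {
    stop("module_size * n_modules exceeds n_proteins", call. = FALSE)
  }
  if (strength < 0 || strength > 1 || absence_rate < 0 || absence_rate > 1) {
    stop("strength and absence_rate must lie in [0, 1]", call. = FALSE)
  }
  if (noise < 0) stop("noise must be non-negative", call. = FALSE)
  structure(list(
    n_proteins = as.integer(n_proteins), n_genomes = as.integer(n_genomes),
    n_modules = as.integer(n_modules), module_size = as.integer(module_size),
    dependence = dependence, strength = strength, noise = noise,
    absence_rate = absence_rate, clip_min = clip_min, seed = as.integer(seed)
  ), class = "simulation_spec")
}

.dependence_transform <- function(type) {
  switch(type,
    linear = identity,
    `monotone-nonlinear` = function(u) u^2,
    `non-monotone` = function(u) 4 * u * (1 - u)
  )
}

#' Simulate a profile matrix with planted dependent pairs
#'
#' @param spec A [simulation_spec()].
#' @return A `profile_simulation`: list with `profiles` (a
#'   [profile_matrix()]), `truth` (data frame of within-module pairs),
#'   `modules` (list of member id vectors) and the `spec`.
#' @export
simulate_profiles <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  set.seed(spec$seed)
  j <- spec$n_genomes
  transform <- .dependence_transform(spec$dependence)
  clip <- function(v) pmin(pmax(v, spec$clip_min), 1)
  rows <- list()
  modules <- list()
  for (m in seq_len(spec$n_modules)) {
    u <- stats::runif(j)
    ids <- sprintf("mod%03d_p%d", m, seq_len(spec$module_size))
    for (w in seq_len(spec$module_size)) {
      signal <- if (w == 1L) u else transform(u)
      v <- spec$strength * signal +
        (1 - spec$strength) * stats::runif(j) +
        spec$noise * stats::rnorm(j)
      rows[[ids[w]]] <- clip(v)
    }
    modules[[sprintf("mod%03d", m)]] <- ids
  }
  n_bg <- spec$n_proteins - spec$n_modules * spec$module_size
  for (b in seq_len(n_bg)) {
    v <- stats::runif(j)
    v[stats::runif(j) < spec$absence_rate] <- 1
    rows[[sprintf("bg%04d", b)]] <- clip(v)
  }
  pm <- profile_matrix(do.call(rbind, rows),
                       proteins = names(rows),
                       genomes = sprintf("g%03d", seq_len(j)))
  truth <- if (length(modules)) {
    do.call(rbind, lapply(modules, function(ids) {
      if (length(ids) < 2L) return(NULL)
      cmb <- utils::combn(sort(ids), 2L)
      data.frame(id1 = cmb[1L, ], id2 = cmb[2L, ], stringsAsFactors = FALSE)
    }))
  }
  if (is.null(truth)) {
    truth <- data.frame(id1 = character(), id2 = character(),
                        stringsAsFactors = FALSE)
  }
  rownames(truth) <- NULL
  structure(list(profiles = pm, truth = truth, modules = modules,
                 spec = spec),
            class = "profile_simulation")
}

#' @export
print.profile_simulation <- function(x, ...) {
  cat(sprintf(
    "Simulated profiles: %d proteins (%d modules of %d) x %d genomes; %s dependence, strength %.2g, noise %.2g\n",
    nrow(x$profiles), x$spec$n_modules, x$spec$module_size, ncol(x$profiles),
    x$spec$dependence, x$spec$strength, x$spec$noise
  ))
  invisible(x)
}

#' Emit the alignment hit table matching a profile matrix
#'
#' Inverts the E-value transform: every profile entry `P < 1` becomes one
#' 12-column tabular hit line with `E = 10^(-1/P)` against a per-genome
#' reference subject, so that `build_profile_matrix(best_hits(
#' parse_hit_table(...)))` recovers the matrix. Entries equal to 1 emit no
#' line ("no hit"). Values below the smallest probability representable
#' through the parser's E-value floor (`-1/log10(evalue_floor)`, 0.005 at
#' the default floor) are clamped to it and counted.
#'
#' @param pm A [profile_matrix()].
#' @param seed Integer seed used to shuffle the emitted line order (the
#'   pipeline is permutation-invariant; shuffling exercises that).
#' @param evalue_floor E-value floor mirrored from
#'   [evalue_to_probability()].
#' @param path Optional file to write the lines to.
#' @return An `evalue_table`: list with `lines`, the matching `gmap`
#'   ([genome_map()]), `proteins` (row order), and `n_clamped`.
#' @export
profiles_to_evalue_table <- function(pm, seed = 1L, evalue_floor = 1e-200,
                                     path = NULL) {
  stopifnot(inherits(pm, "profile_matrix"))
  p_min <- -1 / log10(evalue_floor)
  m <- unclass(pm)
  idx <- which(m < 1, arr.ind = TRUE)
  vals <- m[idx]
  n_clamped <- sum(vals < p_min)
  vals <- pmax(vals, p_min)
  genomes <- colnames(m)
  subjects <- paste0("ref|", genomes)
  lines <- if (nrow(idx)) {
    sprintf(
      "%s\t%s\t90.0\t100\t10\t0\t1\t100\t1\t100\t%.12e\t180.0",
      rownames(m)[idx[, 1L]], subjects[idx[, 2L]], 10^(-1 / vals)
    )
  } else {
    character()
  }
  set.seed(seed)
  lines <- sample(lines)
  if (!is.null(path)) writeLines(lines, path)
  structure(list(
    lines = lines,
    gmap = genome_map(data.frame(subject_id = subjects, genome_id = genomes,
                                 stringsAsFactors = FALSE), roster = genomes),
    proteins = rownames(m),
    n_clamped = n_clamped
  ), class = "evalue_table")
}

#' Simulate toy pathway memberships around a truth pair set
#'
#' Each connected component of the truth pairs (an interacting module)
#' becomes one pathway; modules share no proteins, so module pathways are
#' mutually unreachable in the pathway graph (distance infinity, hence
#' between-module pairs qualify as true negatives under the distance rule).
#' Additionally, `n_decoy_pathways` decoy pathways are arranged in chains of
#' `chain_length`: consecutive decoys share a single bridge protein and each
#' carries one exclusive protein, so within-chain pathway distances equal
#' the index gap by construction. A manifest of the expected pathway
#' distances is attached.
#'
#' @param truth Data frame of positive pairs (`id1`, `id2`).
#' @param n_decoy_pathways Total number of decoy pathways.
#' @param chain_length Pathways per decoy chain.
#' @param seed Integer seed (construction is deterministic; kept for
#'   interface uniformity).
#' @return A [pathway_membership()] with attribute `expected_dist` (named
#'   list of within-chain distance matrices).
#' @export
simulate_pathways <- function(truth, n_decoy_pathways = 0L,
                              chain_length = 6L, seed = 1L) {
  set.seed(seed)
  rows <- list()
  if (nrow(truth)) {
    g <- igraph::graph_from_data_frame(truth[, c("id1", "id2")],
                                       directed = FALSE)
    comp <- igraph::components(g)
    for (k in seq_len(comp$no)) {
      prot <- names(comp$membership)[comp$membership == k]
      rows[[length(rows) + 1L]] <- data.frame(
        protein_id = prot, pathway_id = sprintf("pw%03d", k),
        stringsAsFactors = FALSE
      )
    }
  }
  expected <- list()
  if (n_decoy_pathways > 0L) {
    if (chain_length < 1L) stop("chain_length must be >= 1", call. = FALSE)
    n_chains <- ceiling(n_decoy_pathways / chain_length)
    pw_left <- n_decoy_pathways
    for (c in seq_len(n_chains)) {
      len <- min(chain_length, pw_left)
      pw_left <- pw_left - len
      pw_ids <- sprintf("decoy%02d_pw%02d", c, seq_len(len))
      for (t in seq_len(len)) {
        prot <- sprintf("decoy%02d_x%02d", c, t)
        if (t > 1L) prot <- c(prot, sprintf("decoy%02d_b%02d", c, t - 1L))
        if (t < len) prot <- c(prot, sprintf("decoy%02d_b%02d", c, t))
        rows[[length(rows) + 1L]] <- data.frame(
          protein_id = prot, pathway_id = pw_ids[t], stringsAsFactors = FALSE
        )
      }
      d <- abs(outer(seq_len(len), seq_len(len), "-"))
      dimnames(d) <- list(pw_ids, pw_ids)
      expected[[sprintf("decoy%02d", c)]] <- d
    }
  }
  if (!length(rows)) {
    stop("nothing to simulate: empty truth and no decoy pathways",
         call. = FALSE)
  }
  m <- pathway_membership(do.call(rbind, rows))
  attr(m, "expected_dist") <- expected
  m
}
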