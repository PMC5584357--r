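# Fixtures built in code; nothing is read from disk.

random_profile_matrix <- function(i, j, seed, absence = 0) {
  set.seed(seed)
  v <- matrix(runif(i * j), i, j)
  if (absence > 0) v[matrix(runif(i * j) < absence, i, j)] <- 1
  profile_matrix(v, proteins = sprintf("p%03d", seq_len(i)),
                 genomes = sprintf("g%03d", seq_len(j)))
}

# Chain of n pathways P1..Pn, each holding one exclusive protein x<t> and
# sharing a single bridge protein b<t> with its successor, so that
# dist(P1, Pn) = n - 1 by construction.
chain_membership <- function(n = 6) {
  rows <- lapply(seq_len(n), function(t) {
    prot <- sprintf("x%d", t)
    if (t > 1) prot <- c(prot, sprintf("b%d", t - 1))
    if (t < n) prot <- c(prot, sprintf("b%d", t))
    data.frame(protein_id = prot, pathway_id = sprintf("P%d", t),
               stringsAsFactors = FALSE)
  })
  pathway_membership(do.call(rbind, rows))
}

# Build a scored_pairs object directly from scores and labels.
make_scored <- function(score, label, metric = "dcor", flavor = "fun") {
  n <- length(score)
  structure(
    data.frame(id1 = sprintf("u%05d", seq_len(n)),
               id2 = sprintf("v%05d", seq_len(n)),
               score = score, label = label, stringsAsFactors = FALSE),
    class = c("scored_pairs", "data.frame"),
    metric = metric, flavor = flavor
  )
}

# Minimum pathway-graph distance between two proteins, straight from the
# membership table and a distance matrix (used to cross-check true_negatives).
pair_min_dist <- function(m, d, a, b) {
  pa <- unique(m$pathway_id[m$protein_id == a])
  pb <- unique(m$pathway_id[m$protein_id == b])
  min(d[pa, pb])
}
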