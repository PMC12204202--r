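# Independent oracles used across the suite.

# Brute-force transitive closure of the pairwise proximity predicate:
# evaluate the predicate on ALL pairs of role-bearing genes and take the
# connected components of the resulting graph (igraph). O(n^2), independent
# of the scanning union-find in cluster_loci().
oracle_cluster_sets <- function(genes, roles, max_intervening, max_gap_bp) {
  rg <- merge(genes, roles[, c("gene_id", "role")], by = "gene_id")
  rg <- rg[rg$role != "none", , drop = FALSE]
  n <- nrow(rg)
  if (n == 0) return(list())
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    if (rg$replicon_id[i] != rg$replicon_id[j]) next
    if (abs(rg$rank[i] - rg$rank[j]) > max_intervening + 1) next
    lo <- if (rg$start[i] <= rg$start[j]) i else j
    hi <- if (lo == i) j else i
    gap <- max(0, rg$start[hi] - rg$end[lo] - 1)
    if (gap <= max_gap_bp) adj[i, j] <- TRUE
  }
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comps <- igraph::components(g)$membership
  sets <- lapply(split(rg$gene_id, comps), sort)
  unname(sets[order(vapply(sets, `[`, character(1), 1))])
}

loci_as_sets <- function(loci) {
  sets <- lapply(loci$gene_ids, sort)
  unname(sets[order(vapply(sets, `[`, character(1), 1))])
}

# Full-enumeration two-sided Mann-Whitney p (no ties): U over every
# C(n1+n2, n1) assignment of pooled ranks to group a; symmetric-tail p.
mw_enum_p <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a); n2 <- length(b)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  idx <- utils::combn(n1 + n2, n1)
  u_all <- apply(idx, 2, function(ix) sum(r[ix]) - n1 * (n1 + 1) / 2)
  mu <- n1 * n2 / 2
  list(U = u_obs, p = mean(abs(u_all - mu) >= abs(u_obs - mu)))
}

# a tiny hand-buildable gene table
mk_genes <- function(starts, ends = starts + 299, replicon = "chr",
                     genome = "g", strand = "+") {
  as_gene_table(data.frame(
    gene_id = sprintf("%s_g%02d", genome, seq_along(starts)),
    genome_id = genome,
    replicon_id = rep_len(replicon, length(starts)),
    start = starts, end = ends,
    strand = rep_len(strand, length(starts)),
    stringsAsFactors = FALSE))
}

mk_roles <- function(gene_ids, roles) {
  data.frame(gene_id = gene_ids, role = roles, ambiguous = FALSE,
             n_hits = 1L, best_pfam = "PF00000", stringsAsFactors = FALSE)
}

mk_hit <- function(gene_id, pfam_acc, bitscore = 200, evalue = 1e-30,
                   env_start = 1L, env_end = 100L) {
  data.frame(gene_id = gene_id, pfam_acc = pfam_acc, bitscore = bitscore,
             evalue = evalue, env_start = env_start, env_end = env_end,
             stringsAsFactors = FALSE)
}

status_rank <- function(s) {
  unname(c(absent = 0, partial = 1, split = 2, complete = 3)[s])
}
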