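#' @importFrom stats runif rnorm
NULL

# gene-name token -> Pfam accessions planted on that gene
synth_token_accs <- list(
  ybgC = "PF03061",
  tolQ = "PF01618", exbB = "PF01618",
  tolR = "PF02472", exbD = "PF02472",
  tolA = "PF06519", tonB = c("PF16031", "PF03544"),
  tonB_ctd = "PF03544",
  tolB = c("PF07676", "PF04052"), tolB_like = "PF07676",
  pal = "PF00691", cpoB = "PF16331",
  tbdt = c("PF00593", "PF07715"), tbdt_barrel = "PF00593")

# token -> the role the catalog resolves it to (design-side arithmetic,
# used only to derive planted-truth labels)
synth_token_role <- c(
  ybgC = "ybgC", tolQ = "motor_pentamer", exbB = "motor_pentamer",
  tolR = "motor_dimer", exbD = "motor_dimer",
  tolA = "transducer", tonB = "transducer", tonB_ctd = "transducer",
  tolB = "tolB", tolB_like = "tolB_like",
  pal = "pal", cpoB = "cpoB_tpr", tbdt = "tbdt", tbdt_barrel = "tbdt_barrel")

default_organization <- function(kind) {
  switch(kind,
    complete_tolpal = list(c("ybgC", "tolQ", "tolR", "tolA", "tolB", "pal", "cpoB")),
    split_tolpal = list(c("ybgC", "tolQ", "tolR", "tolA", "tolB"),
                        c("pal", "cpoB")),
    partial = list(c("tolQ", "tolR", "tolB")),
    ton_only = list(c("exbB", "exbD"), "tonB", "tbdt", "tbdt"),
    none = list(),
    stop("spec error: unknown kind '", kind, "'", call. = FALSE))
}

# truth labels from the planted design alone (set logic on the cluster
# role lists; independent of the locus engine)
planted_truth <- function(clusters, cluster_tokens, gene_ids_by_cluster) {
  complement <- tolpal_complement_roles
  roles_by_cluster <- lapply(cluster_tokens, function(tk) unname(synth_token_role[tk]))
  all_roles <- unlist(roles_by_cluster)
  has_all <- vapply(roles_by_cluster, function(r) all(complement %in% r), logical(1))
  contrib <- vapply(roles_by_cluster, function(r) any(complement %in% r), logical(1))
  union_roles <- unique(unlist(roles_by_cluster[contrib]))
  status <- if (any(has_all)) "complete"
            else if (all(complement %in% union_roles)) "split"
            else if (any(complement %in% union_roles)) "partial"
            else "absent"
  transducer_ids <- character(0); transducer_in_contrib <- character(0)
  for (i in seq_along(cluster_tokens)) {
    ids <- gene_ids_by_cluster[[i]][roles_by_cluster[[i]] == "transducer"]
    transducer_ids <- c(transducer_ids, ids)
    if (status %in% c("complete", "split") && contrib[i])
      transducer_in_contrib <- c(transducer_in_contrib, ids)
  }
  tolA <- if (length(transducer_in_contrib) > 0) transducer_in_contrib[1] else character(0)
  tonB <- sort(setdiff(transducer_ids, tolA))
  motor_pair <- all(c("motor_pentamer", "motor_dimer") %in% all_roles)
  ton_k <- sum(length(tonB) > 0, "tbdt" %in% all_roles, motor_pair)
  ton <- if (ton_k == 3) "complete" else if (ton_k >= 1) "incomplete" else "absent"
  cpo_present <- "cpoB_tpr" %in% all_roles
  cpo_adjacent <- FALSE
  for (i in seq_along(cluster_tokens)) {
    r <- roles_by_cluster[[i]]
    ci <- which(r == "cpoB_tpr")
    for (j in ci) {
      nb <- r[setdiff(c(j - 1, j + 1), c(0, length(r) + 1))]
      if (any(nb %in% complement)) cpo_adjacent <- TRUE
    }
  }
  list(tolpal_status = status, ton_status = ton,
       tolA_gene_ids = tolA, tonB_gene_ids = tonB,
       cpoB_present = cpo_present, cpoB_adjacent = cpo_adjacent)
}

synth_hit_rows <- function(gene_id, accs, aalen) {
  do.call(rbind, lapply(accs, function(acc) data.frame(
    gene_id = gene_id, pfam_acc = acc,
    bitscore = round(runif(1, 100, 500), 1),
    evalue = 10^-runif(1, 10, 50),
    env_start = 1L, env_end = aalen, stringsAsFactors = FALSE)))
}

#' Generate one annotated genome with planted force-transduction systems
#'
#' Plants gene clusters (complete, split, partial, Ton-only or none) among
#' decoy genes on a single replicon, emits the corresponding gene table and
#' domain-hit table, and records the intended per-genome truth labels.
#' Clusters are separated by at least `split_offset` decoy genes so that
#' distinct planted clusters never satisfy the default proximity predicate
#' (`split_offset` must exceed `max_intervening`); genes within a cluster
#' are consecutive with intergenic gaps drawn from `gap_bounds`.
#' Deterministic given `seed`.
#'
#' @param genome_id Genome identifier.
#' @param kind One of `"complete_tolpal"`, `"split_tolpal"`, `"partial"`,
#'   `"ton_only"`, `"none"`.
#' @param n_decoy_genes Number of decoy genes (no catalog accession). Default 40.
#' @param organization Optional list of character vectors of gene-name
#'   tokens, one vector per planted cluster, overriding the kind's default
#'   (tokens: ybgC, tolQ/exbB, tolR/exbD, tolA, tonB, tolB, tolB_like, pal,
#'   cpoB, tbdt, tonB_ctd).
#' @param replicon_length Replicon length in bp; generation fails if the
#'   genes do not fit.
#' @param gap_bounds Intergenic gap range in bp, `c(min, max)`.
#' @param split_offset Minimum number of decoy genes between two planted
#'   clusters.
#' @param n_near_miss Number of decoy-like short transducer-CTD genes
#'   (accession PF03544, ~120 residues) planted as solo clusters; these are
#'   true transducer-role genes that fail the three-domain filter.
#' @param decoy_hit_frac Fraction of decoys receiving an off-catalog
#'   accession hit.
#' @param seed Integer seed.
#' @return List with `genes` (gene table), `hits` (domain-hit table) and
#'   `truth` (planted labels: tolpal_status, ton_status, tolA_gene_ids,
#'   tonB_gene_ids, cpoB_present, cpoB_adjacent).
#' @export
generate_genome <- function(genome_id = "genome1", kind = "complete_tolpal",
                            n_decoy_genes = 40L, organization = NULL,
                            replicon_length = 4e6, gap_bounds = c(50L, 400L),
                            split_offset = 10L, n_near_miss = 0L,
                            decoy_hit_frac = 0.2, seed = 1L) {
  set.seed(seed)
  clusters <- if (is.null(organization)) default_organization(kind) else organization
  clusters <- lapply(clusters, as.character)
  bad <- setdiff(unlist(clusters), names(synth_token_accs))
  if (length(bad) > 0)
    stop("spec error: unknown organization token '", bad[1], "'", call. = FALSE)
  if (n_near_miss > 0)
    clusters <- c(clusters, replicate(n_near_miss, "tonB_ctd", simplify = FALSE))
  n_clusters <- length(clusters)
  if (n_clusters > 1 && (n_decoy_genes - 2L) < (n_clusters - 1L) * split_offset)
    stop("spec error: not enough decoy genes to separate ", n_clusters,
         " clusters by ", split_offset, call. = FALSE)
  # choose insertion slots (after the k-th decoy), pairwise >= split_offset apart
  if (n_clusters > 0) {
    repeat {
      slots <- sort(sample(1:(n_decoy_genes - 1L), n_clusters))
      if (n_clusters == 1 || all(diff(slots) >= split_offset)) break
    }
  } else slots <- integer(0)
  # assemble the gene order: decoys with clusters spliced in
  order_tokens <- character(0); order_is_decoy <- logical(0)
  order_cluster <- integer(0)
  for (d in seq_len(n_decoy_genes)) {
    order_tokens <- c(order_tokens, "decoy")
    order_is_decoy <- c(order_is_decoy, TRUE)
    order_cluster <- c(order_cluster, NA_integer_)
    hit <- which(slots == d)
    for (ci in hit) {
      order_tokens <- c(order_tokens, clusters[[ci]])
      order_is_decoy <- c(order_is_decoy, rep(FALSE, length(clusters[[ci]])))
      order_cluster <- c(order_cluster, rep(ci, length(clusters[[ci]])))
    }
  }
  n <- length(order_tokens)
  aalen <- integer(n)
  for (i in seq_len(n)) {
    aalen[i] <- switch(order_tokens[i],
      decoy = sample(100:600, 1),
      tolA = sample(250:450, 1), tonB = sample(250:450, 1),
      tonB_ctd = sample(110:130, 1),
      tbdt = sample(600:900, 1), tbdt_barrel = sample(600:900, 1),
      sample(100:500, 1))
  }
  len_bp <- 3L * (aalen + 1L)
  gaps <- sample(gap_bounds[1]:gap_bounds[2], n, replace = TRUE)
  starts <- cumsum(c(gaps[1], len_bp[-n] + gaps[-1] + 1L))
  ends <- starts + len_bp - 1L
  if (ends[n] > replicon_length)
    stop("spec error: genes exceed replicon length", call. = FALSE)
  gene_ids <- sprintf("%s_g%04d", genome_id, seq_len(n))
  genes <- as_gene_table(data.frame(
    gene_id = gene_ids, genome_id = genome_id, replicon_id = "chr",
    start = starts, end = ends,
    strand = sample(c("+", "-"), n, replace = TRUE),
    product = ifelse(order_is_decoy, "hypothetical protein", order_tokens),
    protein_length = aalen, stringsAsFactors = FALSE))
  hit_rows <- list()
  for (i in seq_len(n)) {
    if (order_is_decoy[i]) {
      if (runif(1) < decoy_hit_frac)
        hit_rows[[length(hit_rows) + 1]] <-
          synth_hit_rows(gene_ids[i], "PF99999", aalen[i])
    } else {
      hit_rows[[length(hit_rows) + 1]] <-
        synth_hit_rows(gene_ids[i], synth_token_accs[[order_tokens[i]]], aalen[i])
    }
  }
  hits <- if (length(hit_rows) > 0) do.call(rbind, hit_rows) else
    data.frame(gene_id = character(), pfam_acc = character(),
               bitscore = numeric(), evalue = numeric(),
               env_start = integer(), env_end = integer())
  ids_by_cluster <- lapply(seq_along(clusters), function(ci)
    gene_ids[which(order_cluster == ci)])
  truth <- planted_truth(clusters, clusters, ids_by_cluster)
  truth$genome_id <- genome_id
  truth$kind <- kind
  list(genes = genes, hits = hits, truth = truth)
}

#' Generate a genome with randomly scattered role genes
#'
#' Every gene independently receives either no catalog accession or a
#' random one, with intergenic gaps drawn wide enough to straddle the
#' default proximity threshold on both sides. Used to stress-test the
#' locus clustering against the brute-force transitive-closure oracle; no
#' truth labels are attached.
#'
#' @param n_genes Number of genes (default 50).
#' @param role_frac Probability that a gene carries a catalog accession.
#' @param gap_max Maximum intergenic gap in bp (gaps uniform on
#'   `0..gap_max`).
#' @param genome_id Genome identifier.
#' @param seed Integer seed.
#' @return List with `genes` and `hits`.
#' @export
generate_scatter_genome <- function(n_genes = 50L, role_frac = 0.4,
                                    gap_max = 8000L, genome_id = "scatter",
                                    seed = 1L) {
  set.seed(seed)
  tokens <- c("ybgC", "tolQ", "tolR", "tolA", "tonB", "tolB", "tolB_like",
              "pal", "cpoB", "tbdt")
  n <- as.integer(n_genes)
  aalen <- sample(100:600, n, replace = TRUE)
  len_bp <- 3L * (aalen + 1L)
  gaps <- sample(0:gap_max, n, replace = TRUE)
  starts <- cumsum(c(gaps[1] + 1L, len_bp[-n] + gaps[-1] + 1L))
  ends <- starts + len_bp - 1L
  gene_ids <- sprintf("%s_g%04d", genome_id, seq_len(n))
  genes <- as_gene_table(data.frame(
    gene_id = gene_ids, genome_id = genome_id, replicon_id = "chr",
    start = starts, end = ends,
    strand = sample(c("+", "-"), n, replace = TRUE),
    product = "random", protein_length = aalen, stringsAsFactors = FALSE))
  hit_rows <- list()
  for (i in seq_len(n)) {
    if (runif(1) < role_frac) {
      tok <- sample(tokens, 1)
      hit_rows[[length(hit_rows) + 1]] <-
        synth_hit_rows(gene_ids[i], synth_token_accs[[tok]], aalen[i])
    }
  }
  hits <- if (length(hit_rows) > 0) do.call(rbind, hit_rows) else
    data.frame(gene_id = character(), pfam_acc = character(),
               bitscore = numeric(), evalue = numeric(),
               env_start = integer(), env_end = integer())
  list(genes = genes, hits = hits)
}

#' Generate a secondary-structure profile with count-exact composition
#'
#' Builds a three-state profile and matching amino-acid sequence for a
#' transducer with a given TMH span, an exact number of alpha-helical
#' states and an exact number of proline residues within domain II
#' (positions randomised by seed, counts exact by construction), and
#' optionally a planted motor-box strand satisfying the default detection
#' parameters. Residues outside domain II never contain proline, and
#' domain II never contains strand states except the planted motor box.
#'
#' @param gene_id Gene identifier.
#' @param protein_length Protein length in residues.
#' @param tmh_span Integer `c(start, end)` of the TMH.
#' @param helix_count Exact number of H states in domain II.
#' @param proline_count Exact number of prolines in domain II.
#' @param motor_box Plant a flanked beta-strand at the start of domain II.
#' @param strand_len Length of the planted strand (>= default `min_strand`).
#' @param with_ppii Attach per-residue PPII scores (0.8 at prolines, 0.2
#'   elsewhere).
#' @param signal_call Optional external signal classification to attach.
#' @param seed Integer seed.
#' @return List with `profile` (an [ss_profile()]), `sequence`, and `truth`
#'   (`helix_pct`, `proline_pct`, `d2_length`, `motor_box_span`).
#' @export
generate_profile <- function(gene_id = "prot1", protein_length = 300L,
                             tmh_span = c(10L, 30L), helix_count = 60L,
                             proline_count = 20L, motor_box = TRUE,
                             strand_len = 4L, with_ppii = FALSE,
                             signal_call = NULL, seed = 1L) {
  set.seed(seed)
  L <- as.integer(protein_length)
  tmh <- as.integer(tmh_span)
  d2 <- c(tmh[2] + 1L, L - 100L)
  d2_len <- d2[2] - d2[1] + 1L
  if (d2_len < 1)
    stop("spec error: no room for a non-empty domain II", call. = FALSE)
  defaults <- tolton_config()
  reserved <- integer(0)
  mb_span <- NULL
  states <- rep("C", L)
  states[tmh[1]:tmh[2]] <- "H"
  if (motor_box) {
    mc <- defaults$min_coil_flank
    if (strand_len < defaults$min_strand)
      stop("spec error: strand_len below default min_strand", call. = FALSE)
    j_min <- mc + 1L
    j_max <- min(defaults$motor_box_window - strand_len + 1L,
                 d2_len - strand_len - mc + 1L)
    if (j_max < j_min)
      stop("spec error: no room for a motor box in the detection window",
           call. = FALSE)
    j <- sample(j_min:j_max, 1)
    st <- d2[1] + j - 1L
    mb_span <- c(st, st + strand_len - 1L)
    states[mb_span[1]:mb_span[2]] <- "E"
    reserved <- (st - mc):(mb_span[2] + mc) - d2[1] + 1L
  }
  free <- setdiff(seq_len(d2_len), reserved)
  if (helix_count > length(free))
    stop("spec error: helix_count infeasible for this domain II", call. = FALSE)
  if (proline_count > d2_len)
    stop("spec error: proline_count exceeds domain II length", call. = FALSE)
  h_pos <- if (helix_count > 0) sample(free, helix_count) else integer(0)
  states[d2[1] + h_pos - 1L] <- "H"
  # globular C-terminal domain: mixed strand/helix pattern
  d3_pat <- strsplit(strrep("CCEEECCHHHHC", 10), "")[[1]][1:100]
  states[(L - 99L):L] <- d3_pat
  aa_pool <- strsplit("ACDEFGHIKLMNQRSTVWY", "")[[1]]  # no proline
  seq_chars <- sample(aa_pool, L, replace = TRUE)
  seq_chars[1] <- "M"
  p_pos <- if (proline_count > 0) sample(seq_len(d2_len), proline_count) else integer(0)
  seq_chars[d2[1] + p_pos - 1L] <- "P"
  ppii <- NULL
  if (with_ppii) ppii <- ifelse(seq_chars == "P", 0.8, 0.2)
  prof <- ss_profile(gene_id, paste(states, collapse = ""),
                     confidence = round(runif(L, 0.7, 1), 3),
                     tmh_span = tmh, ppii_scores = ppii,
                     signal_call = signal_call)
  list(profile = prof, sequence = paste(seq_chars, collapse = ""),
       truth = list(helix_pct = 100 * helix_count / d2_len,
                    proline_pct = 100 * proline_count / d2_len,
                    d2_length = d2_len, motor_box_span = mb_span))
}

#' Generate a paired TolA/TonB cohort with known parameters
#'
#' Draws one TolA and one TonB domain II length per species from the named
#' marginal distributions, coupled through a Gaussian copula with
#' correlation `rho`, plus class-typical composition percentages, so
#' cohort statistics can be checked against the generating parameters. The
#' defaults emulate the curated proteobacterial cohort: log-normal length
#' marginals with medians 192 (TolA) and 113 (TonB) residues and a weak
#' positive pairing (rho = 0.28).
#'
#' @param n_species Number of species (default 70).
#' @param length_distributions Named list with elements `TolA` and `TonB`,
#'   each `list(family, ...)` where family is `"lnorm"` (meanlog, sdlog),
#'   `"norm"` (mean, sd) or `"unif"` (min, max).
#' @param rho Copula correlation between the paired lengths.
#' @param lipo_prob Probability that a record carries a lipoprotein signal.
#' @param seed Integer seed.
#' @return List with `records` (cohort data frame: species, clade,
#'   protein_class, d2_length, helix_pct, proline_pct, composition_class,
#'   lipo_class) and `truth` (the generating parameters).
#' @export
generate_cohort <- function(n_species = 70L,
                            length_distributions = list(
                              TolA = list(family = "lnorm",
                                          meanlog = log(192), sdlog = 0.28),
                              TonB = list(family = "lnorm",
                                          meanlog = log(113), sdlog = 0.40)),
                            rho = 0.28, lipo_prob = 0.2, seed = 1L) {
  set.seed(seed)
  q_from <- function(dist, u) {
    switch(dist$family,
      lnorm = stats::qlnorm(u, dist$meanlog, dist$sdlog),
      norm = stats::qnorm(u, dist$mean, dist$sd),
      unif = stats::qunif(u, dist$min, dist$max),
      stop("spec error: unknown distribution family '", dist$family, "'",
           call. = FALSE))
  }
  z1 <- rnorm(n_species)
  z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(n_species)
  len_a <- round(q_from(length_distributions$TolA, stats::pnorm(z1)))
  len_b <- round(q_from(length_distributions$TonB, stats::pnorm(z2)))
  clades <- sample(c("Gammaproteobacteria", "Betaproteobacteria",
                     "Alphaproteobacteria", "Epsilonproteobacteria",
                     "Deltaproteobacteria"), n_species, replace = TRUE)
  species <- sprintf("species_%03d", seq_len(n_species))
  mk <- function(class, len, helix, proline) {
    data.frame(species = species, clade = clades, protein_class = class,
               d2_length = as.integer(len),
               helix_pct = round(helix, 2), proline_pct = round(proline, 2),
               composition_class = mapply(classify_composition, helix, proline),
               lipo_class = ifelse(runif(n_species) < lipo_prob,
                                   "lipoprotein", "none"),
               stringsAsFactors = FALSE)
  }
  rec_a <- mk("TolA", len_a, runif(n_species, 5, 75), runif(n_species, 0, 25))
  rec_b <- mk("TonB", len_b, runif(n_species, 0, 20), runif(n_species, 8, 40))
  records <- rbind(rec_a, rec_b)
  rownames(records) <- NULL
  list(records = records,
       truth = list(n_species = n_species, rho = rho,
                    length_distributions = length_distributions,
                    lipo_prob = lipo_prob))
}

#' Write a synthetic genome bundle as external fixture files
#'
#' Emits the dialects the readers consume: a GFF3 gene table, a HMMER
#' per-domain tabular hit file and a JSON truth file.
#'
#' @param bundle Result of [generate_genome()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, the written paths.
#' @export
write_genome_fixture <- function(bundle, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  g <- bundle$genes
  gff <- file.path(dir, paste0(g$genome_id[1], ".gff3"))
  lines <- c("##gff-version 3",
             sprintf("%s\ttolton_synth\tCDS\t%d\t%d\t.\t%s\t0\tID=%s;product=%s;protein_length=%d",
                     g$replicon_id, g$start, g$end, g$strand, g$gene_id,
                     gsub("[;=]", "_", g$product), g$protein_length))
  writeLines(lines, gff)
  h <- bundle$hits
  dom <- file.path(dir, paste0(g$genome_id[1], ".domtblout"))
  hl <- c("# planted domain hits (hmmscan per-domain tabular layout)",
          if (nrow(h) > 0)
            sprintf(paste0("%s %s %d %s - %d %.2g %.1f 0.0 1 1 %.2g %.2g %.1f 0.0",
                           " 1 %d 1 %d %d %d 0.95 planted"),
                    paste0("model_", h$pfam_acc), paste0(h$pfam_acc, ".1"),
                    h$env_end, h$gene_id, h$env_end, h$evalue, h$bitscore,
                    h$evalue, h$evalue, h$bitscore,
                    h$env_end, h$env_end, h$env_start, h$env_end))
  writeLines(hl, dom)
  tr <- file.path(dir, paste0(g$genome_id[1], ".truth.json"))
  jsonlite::write_json(bundle$truth, tr, auto_unbox = TRUE, digits = NA)
  invisible(c(gff = gff, domtblout = dom, truth = tr))
}
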