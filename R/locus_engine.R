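#' Cluster role-bearing genes into candidate loci
#'
#' Builds the graph linking role-bearing genes on the same replicon whose
#' rank distance is at most `max_intervening + 1` and whose intergenic gap
#' is at most `max_gap_bp`, and returns its connected components as loci.
#' Rank is the 0-based gene ordinal along the replicon (strand-agnostic);
#' the intergenic gap between two genes is the number of bases strictly
#' between them (0 for overlapping genes). Widening either threshold can
#' only merge loci, never split them.
#'
#' @param genes Gene table from [read_gene_table()] / [as_gene_table()].
#' @param roles Role assignments from [assign_roles()].
#' @param max_intervening Maximum number of non-role genes between two locus
#'   members.
#' @param max_gap_bp Maximum intergenic distance in bp between two locus
#'   members.
#' @return Data frame with one row per locus: `locus_id`, `genome_id`,
#'   `replicon_id`, `start`, `end`, `n_genes`, `gene_order` (role string in
#'   gene order, `-`-separated), plus list columns `gene_ids` and `roles`
#'   (both in start order).
#' @export
cluster_loci <- function(genes, roles, max_intervening = 3L,
                         max_gap_bp = 5000L) {
  if (max_intervening < 0) stop("config error: max_intervening must be >= 0", call. = FALSE)
  if (max_gap_bp <= 0) stop("config error: max_gap_bp must be > 0", call. = FALSE)
  empty <- data.frame(locus_id = character(), genome_id = character(),
                      replicon_id = character(), start = integer(),
                      end = integer(), n_genes = integer(),
                      gene_order = character(), stringsAsFactors = FALSE)
  empty$gene_ids <- list(); empty$roles <- list()
  if (nrow(roles) == 0 || nrow(genes) == 0) return(empty)
  unknown <- setdiff(roles$gene_id, genes$gene_id)
  if (length(unknown) > 0)
    stop("validation error: role assigned to unknown gene_id '",
         unknown[1], "'", call. = FALSE)
  rg <- merge(genes, roles[, c("gene_id", "role")], by = "gene_id")
  rg <- rg[rg$role != "none", , drop = FALSE]
  if (nrow(rg) == 0) return(empty)
  rg <- rg[order(rg$replicon_id, rg$rank), , drop = FALSE]
  n <- nrow(rg)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (a in seq_len(n - 1)) {
    b <- a + 1L
    while (b <= n && rg$replicon_id[b] == rg$replicon_id[a] &&
           rg$rank[b] - rg$rank[a] <= max_intervening + 1L) {
      gap <- max(0L, rg$start[b] - rg$end[a] - 1L)
      if (gap <= max_gap_bp) {
        ra <- find(a); rb <- find(b)
        if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
      }
      b <- b + 1L
    }
  }
  comp <- vapply(seq_len(n), find, integer(1))
  groups <- split(seq_len(n), comp)
  rows <- lapply(groups, function(ix) {
    g <- rg[ix, , drop = FALSE]
    g <- g[order(g$start), , drop = FALSE]
    data.frame(genome_id = g$genome_id[1], replicon_id = g$replicon_id[1],
               start = min(g$start), end = max(g$end), n_genes = nrow(g),
               gene_order = paste(g$role, collapse = "-"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  ord <- order(out$replicon_id, out$start)
  out <- out[ord, , drop = FALSE]
  out$locus_id <- sprintf("%s_L%03d", out$genome_id, seq_len(nrow(out)))
  out$gene_ids <- lapply(groups[ord], function(ix) {
    g <- rg[ix, , drop = FALSE]; g$gene_id[order(g$start)]
  })
  out$roles <- lapply(groups[ord], function(ix) {
    g <- rg[ix, , drop = FALSE]; g$role[order(g$start)]
  })
  rownames(out) <- NULL
  out[, c("locus_id", "genome_id", "replicon_id", "start", "end", "n_genes",
          "gene_order", "gene_ids", "roles")]
}

#' Classify a genome's tol-pal status from its loci
#'
#' A genome is `complete` when a single locus carries the minimal complement
#' (motor pentamer + motor dimer + force transducer + tolB + pal), `split`
#' when only a union of two or more loci does (each contributing at least
#' one complement role), `partial` when some but not all complement roles
#' exist genome-wide, and `absent` otherwise. The search for split partners
#' is genome-wide with no maximum separation.
#'
#' @param loci Locus table from [cluster_loci()] (one genome).
#' @return List with `tolpal_status` and `contributing_loci` (locus ids).
#' @export
classify_tolpal <- function(loci) {
  complement <- tolpal_complement_roles
  if (nrow(loci) == 0)
    return(list(tolpal_status = "absent", contributing_loci = character(0)))
  has_all <- vapply(loci$roles, function(r) all(complement %in% r), logical(1))
  if (any(has_all))
    return(list(tolpal_status = "complete",
                contributing_loci = loci$locus_id[has_all]))
  contrib <- vapply(loci$roles, function(r) any(complement %in% r), logical(1))
  union_roles <- unique(unlist(loci$roles[contrib]))
  if (all(complement %in% union_roles))
    return(list(tolpal_status = "split",
                contributing_loci = loci$locus_id[contrib]))
  if (any(complement %in% union_roles))
    return(list(tolpal_status = "partial",
                contributing_loci = loci$locus_id[contrib]))
  list(tolpal_status = "absent", contributing_loci = character(0))
}

#' Classify a genome's Ton status
#'
#' Ton detection imposes no proximity requirement: the system is `complete`
#' when the genome carries (anywhere) at least one force transducer not
#' claimed as TolA, at least one TonB-dependent transporter, and the motor
#' pair (pentamer + dimer); `incomplete` when a non-empty proper subset of
#' those three components is present; `absent` otherwise.
#'
#' @param roles Role assignments for one genome.
#' @param tolA_gene_ids Transducer gene ids already claimed as TolA.
#' @return `"complete"`, `"incomplete"` or `"absent"`.
#' @export
classify_ton <- function(roles, tolA_gene_ids = character(0)) {
  free_transducer <- any(roles$role == "transducer" &
                         !roles$gene_id %in% tolA_gene_ids)
  tbdt <- any(roles$role == "tbdt")
  motor_pair <- any(roles$role == "motor_pentamer") &&
                any(roles$role == "motor_dimer")
  k <- sum(free_transducer, tbdt, motor_pair)
  if (k == 3) "complete" else if (k >= 1) "incomplete" else "absent"
}

#' Assign transducer identities (TolA vs TonB) by genomic context
#'
#' A transducer inside a complement-satisfying locus (or inside a member of
#' a split union) is TolA; every other transducer is a TonB candidate. At
#' most one TolA is assigned per genome: the best-supported contributing
#' locus (most complement roles, tie broken by lowest start coordinate)
#' wins, and if that locus holds several transducers the one closest in
#' rank to a tolB gene is picked deterministically and the rest are flagged
#' rather than silently assigned.
#'
#' @param genes Gene table for the genome.
#' @param roles Role assignments.
#' @param loci Locus table from [cluster_loci()].
#' @param tolpal Result of [classify_tolpal()].
#' @return List with `tolA_gene_ids` (length 0 or 1), `tonB_gene_ids`,
#'   `flagged_gene_ids` (extra complement-locus transducers) and
#'   `tolA_ambiguous`.
#' @export
assign_transducer_identity <- function(genes, roles, loci, tolpal) {
  transducers <- roles$gene_id[roles$role == "transducer"]
  res <- list(tolA_gene_ids = character(0), tonB_gene_ids = character(0),
              flagged_gene_ids = character(0), tolA_ambiguous = FALSE)
  if (length(transducers) == 0) return(res)
  if (!tolpal$tolpal_status %in% c("complete", "split")) {
    res$tonB_gene_ids <- sort(transducers)
    return(res)
  }
  contrib <- loci[loci$locus_id %in% tolpal$contributing_loci, , drop = FALSE]
  in_contrib <- transducers[transducers %in% unlist(contrib$gene_ids)]
  if (length(in_contrib) == 0) {
    res$tonB_gene_ids <- sort(transducers)
    return(res)
  }
  # best-supported contributing locus holding a transducer
  holds <- vapply(contrib$gene_ids, function(g) any(g %in% in_contrib), logical(1))
  cand_loci <- contrib[holds, , drop = FALSE]
  support <- vapply(cand_loci$roles,
                    function(r) length(intersect(unique(r), tolpal_complement_roles)),
                    integer(1))
  best <- cand_loci[order(-support, cand_loci$replicon_id, cand_loci$start), ,
                    drop = FALSE][1, , drop = FALSE]
  ids <- best$gene_ids[[1]]; rls <- best$roles[[1]]
  cand <- ids[rls == "transducer"]
  if (length(cand) > 1) {
    res$tolA_ambiguous <- TRUE
    tolb_ranks <- genes$rank[match(ids[rls == "tolB"], genes$gene_id)]
    cand_ranks <- genes$rank[match(cand, genes$gene_id)]
    if (length(tolb_ranks) > 0) {
      d <- vapply(cand_ranks, function(r) min(abs(r - tolb_ranks)), numeric(1))
      cand <- cand[order(d, genes$start[match(cand, genes$gene_id)])]
    } else {
      cand <- cand[order(genes$start[match(cand, genes$gene_id)])]
    }
  }
  tolA <- cand[1]
  res$tolA_gene_ids <- tolA
  res$flagged_gene_ids <- sort(setdiff(in_contrib, tolA))
  res$tonB_gene_ids <- sort(setdiff(transducers, c(tolA, res$flagged_gene_ids)))
  res
}

#' Select the representative TonB for a genome
#'
#' Among TonB candidates, the representative is the first (by replicon then
#' start coordinate) whose architecture permits all three domains — a
#' predicted TMH with room for a non-empty domain II ahead of the 100-residue
#' C-terminal domain (see [is_full_transducer()]).
#'
#' @param tonB_gene_ids Candidate gene ids.
#' @param genes Gene table.
#' @param profiles Named list of [ss_profile()] objects keyed by gene id.
#' @return A single gene id, or `NA_character_` when no candidate qualifies.
#' @export
select_representative_tonb <- function(tonB_gene_ids, genes, profiles) {
  if (length(tonB_gene_ids) == 0) return(NA_character_)
  idx <- match(tonB_gene_ids, genes$gene_id)
  ord <- order(genes$replicon_id[idx], genes$start[idx])
  for (gid in tonB_gene_ids[ord]) {
    ok <- is_full_transducer(profiles[[gid]],
                             genes$protein_length[match(gid, genes$gene_id)])
    if (isTRUE(ok)) return(gid)
  }
  NA_character_
}

#' CpoB presence and adjacency for a genome
#'
#' `cpoB_present` is true when any gene carries a CpoB TPR role;
#' `cpoB_adjacent` when some CpoB gene lies within `adjacency_rank` gene
#' ranks (default: immediate neighbor) of a tol-pal complement gene on the
#' same replicon. Adjacency is defined on gene rank, independent of locus
#' membership.
#'
#' @param genes Gene table.
#' @param roles Role assignments.
#' @param adjacency_rank Maximum rank distance counting as adjacent.
#' @return List with logicals `cpoB_present` and `cpoB_adjacent`.
#' @export
cpob_adjacency <- function(genes, roles, adjacency_rank = 1L) {
  cpo <- roles$gene_id[roles$role == "cpoB_tpr"]
  if (length(cpo) == 0) return(list(cpoB_present = FALSE, cpoB_adjacent = FALSE))
  comp <- roles$gene_id[roles$role %in% tolpal_complement_roles]
  if (length(comp) == 0) return(list(cpoB_present = TRUE, cpoB_adjacent = FALSE))
  ci <- match(cpo, genes$gene_id); pi <- match(comp, genes$gene_id)
  adjacent <- FALSE
  for (i in ci) {
    same <- pi[genes$replicon_id[pi] == genes$replicon_id[i]]
    if (length(same) > 0 &&
        min(abs(genes$rank[same] - genes$rank[i])) <= adjacency_rank) {
      adjacent <- TRUE; break
    }
  }
  list(cpoB_present = TRUE, cpoB_adjacent = adjacent)
}

#' Scan one genome: roles, loci and the per-genome system call
#'
#' Orchestrates role assignment, locus clustering, tol-pal and Ton
#' classification, TolA/TonB identity assignment, representative-TonB
#' selection and the CpoB adjacency call. Every field of the returned
#' system call is a deterministic function of `(genes, hits, config)`.
#'
#' @param genes Gene table for one genome.
#' @param hits Domain-hit table for the same genome.
#' @param config A [tolton_config()].
#' @param profiles Optional named list of [ss_profile()] objects used for
#'   representative-TonB selection.
#' @param catalog Optional role catalog.
#' @return List with `roles`, `loci` and `system_call` (one-row data frame).
#' @export
scan_genome <- function(genes, hits, config = tolton_config(),
                        profiles = NULL, catalog = NULL) {
  config <- as_tolton_config(config)
  roles <- assign_roles(hits, evalue_max = config$evalue_max, catalog = catalog,
                        tbdt_require_plug = config$tbdt_require_plug)
  loci <- cluster_loci(genes, roles, max_intervening = config$max_intervening,
                       max_gap_bp = config$max_gap_bp)
  tolpal <- classify_tolpal(loci)
  ident <- assign_transducer_identity(genes, roles, loci, tolpal)
  ton <- classify_ton(roles, tolA_gene_ids = ident$tolA_gene_ids)
  cpo <- cpob_adjacency(genes, roles, adjacency_rank = config$adjacency_rank)
  rep_tonb <- select_representative_tonb(ident$tonB_gene_ids, genes,
                                         if (is.null(profiles)) list() else profiles)
  genome_id <- if (nrow(genes) > 0) genes$genome_id[1] else NA_character_
  call <- data.frame(
    genome_id = genome_id,
    tolpal_status = tolpal$tolpal_status,
    ton_status = ton,
    tolA_gene_ids = paste(ident$tolA_gene_ids, collapse = ","),
    tonB_gene_ids = paste(ident$tonB_gene_ids, collapse = ","),
    flagged_gene_ids = paste(ident$flagged_gene_ids, collapse = ","),
    tolA_ambiguous = ident$tolA_ambiguous,
    representative_tonB = rep_tonb,
    contributing_loci = paste(tolpal$contributing_loci, collapse = ","),
    cpoB_present = cpo$cpoB_present,
    cpoB_adjacent = cpo$cpoB_adjacent,
    stringsAsFactors = FALSE)
  list(roles = roles, loci = loci, system_call = call)
}

#' Flatten a locus table for TSV output
#'
#' @param loci Locus table from [cluster_loci()].
#' @return Data frame with the list columns collapsed to comma-separated
#'   strings.
#' @export
flatten_loci <- function(loci) {
  out <- loci[, c("locus_id", "genome_id", "replicon_id", "start", "end",
                  "n_genes", "gene_order"), drop = FALSE]
  out$gene_ids <- vapply(loci$gene_ids, paste, character(1), collapse = ",")
  out
}
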