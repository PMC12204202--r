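#' Generate a multi-genome synthetic study
#'
#' Draws a cohort of synthetic genomes with planted system kinds. For
#' genomes carrying a detectable tol-pal system (complete or split), CpoB is
#' planted with probability `cpoB_present_prob`; when present it sits
#' directly adjacent to the pal cluster with probability
#' `cpoB_adjacent_prob` and is otherwise planted as a distal solo gene.
#' The defaults mirror the reported prevalence of CpoB among species with
#' detectable tol-pal systems (86% present, 92% of those adjacent).
#'
#' @param n_genomes Number of genomes.
#' @param kind_probs Named numeric vector of sampling probabilities over the
#'   five planted kinds.
#' @param cpoB_present_prob,cpoB_adjacent_prob CpoB planting rates for
#'   complete/split genomes.
#' @param seed Integer seed.
#' @param ... Passed to [generate_genome()] (e.g. `n_decoy_genes`).
#' @return List of genome bundles (see [generate_genome()]).
#' @export
generate_study <- function(n_genomes = 50L,
                           kind_probs = c(complete_tolpal = 0.55,
                                          split_tolpal = 0.1,
                                          partial = 0.1,
                                          ton_only = 0.15,
                                          none = 0.1),
                           cpoB_present_prob = 0.86,
                           cpoB_adjacent_prob = 0.92,
                           seed = 1L, ...) {
  set.seed(seed)
  kinds <- sample(names(kind_probs), n_genomes, replace = TRUE,
                  prob = kind_probs)
  sub_seeds <- sample.int(.Machine$integer.max %/% 2L, n_genomes)
  cpo_present <- runif(n_genomes) < cpoB_present_prob
  cpo_adjacent <- runif(n_genomes) < cpoB_adjacent_prob
  lapply(seq_len(n_genomes), function(i) {
    kind <- kinds[i]
    org <- NULL
    if (kind %in% c("complete_tolpal", "split_tolpal")) {
      org <- if (kind == "complete_tolpal")
        list(c("ybgC", "tolQ", "tolR", "tolA", "tolB", "pal"))
      else
        list(c("ybgC", "tolQ", "tolR", "tolA", "tolB"), c("pal"))
      if (cpo_present[i]) {
        if (cpo_adjacent[i]) {
          last <- length(org)
          org[[last]] <- c(org[[last]], "cpoB")
        } else {
          org <- c(org, list("cpoB"))
        }
      }
    }
    generate_genome(genome_id = sprintf("genome_%03d", i), kind = kind,
                    organization = org, seed = sub_seeds[i], ...)
  })
}

#' Scan a list of genome bundles
#'
#' Runs [scan_genome()] on each bundle and binds the per-genome results.
#'
#' @param bundles List of lists with `genes` and `hits` (e.g. from
#'   [generate_study()]).
#' @param config A [tolton_config()].
#' @param profiles Optional named list of [ss_profile()] objects across all
#'   genomes.
#' @return List with `system_calls` (one row per genome), `loci` (flattened
#'   locus table) and `truth` (bound truth labels when bundles carry them).
#' @export
scan_study <- function(bundles, config = tolton_config(), profiles = NULL) {
  scans <- lapply(bundles, function(b)
    scan_genome(b$genes, b$hits, config = config, profiles = profiles))
  calls <- do.call(rbind, lapply(scans, `[[`, "system_call"))
  loci <- do.call(rbind, lapply(scans, function(s) flatten_loci(s$loci)))
  truth <- NULL
  if (!is.null(bundles[[1]]$truth))
    truth <- do.call(rbind, lapply(bundles, function(b) data.frame(
      genome_id = b$truth$genome_id,
      kind = b$truth$kind,
      tolpal_status = b$truth$tolpal_status,
      ton_status = b$truth$ton_status,
      tolA_gene_ids = paste(b$truth$tolA_gene_ids, collapse = ","),
      tonB_gene_ids = paste(b$truth$tonB_gene_ids, collapse = ","),
      cpoB_present = b$truth$cpoB_present,
      cpoB_adjacent = b$truth$cpoB_adjacent,
      stringsAsFactors = FALSE)))
  rownames(calls) <- NULL
  list(system_calls = calls, loci = loci, truth = truth)
}

#' Planted-truth recovery accuracy
#'
#' Compares detected system calls with the generator's planted labels field
#' by field and reports the fraction of genomes recovered exactly.
#'
#' @param system_calls System-call table from [scan_study()].
#' @param truth Truth table from [scan_study()].
#' @return List with overall `accuracy` (all compared fields correct),
#'   per-field accuracies, and `n`.
#' @export
recovery_accuracy <- function(system_calls, truth) {
  m <- merge(system_calls, truth, by = "genome_id",
             suffixes = c("", ".truth"))
  fields <- c("tolpal_status", "ton_status", "tolA_gene_ids",
              "tonB_gene_ids", "cpoB_present", "cpoB_adjacent")
  per_field <- vapply(fields, function(f)
    mean(m[[f]] == m[[paste0(f, ".truth")]]), numeric(1))
  all_ok <- rep(TRUE, nrow(m))
  for (f in fields)
    all_ok <- all_ok & (m[[f]] == m[[paste0(f, ".truth")]])
  c(list(accuracy = mean(all_ok), n = nrow(m)), as.list(per_field))
}
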