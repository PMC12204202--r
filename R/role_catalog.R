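#' Load the Pfam-accession to functional-role catalog
#'
#' The catalog maps each Pfam accession to the tol-pal/Ton role it supports
#' (motor subunits, force transducer, TolB domains, Pal, CpoB TPR, YbgC,
#' TBDT barrel/plug). It ships as an editable TSV so new accessions can be
#' added without code changes.
#'
#' @param path Optional path to a catalog TSV (`pfam_acc`, `role` columns);
#'   defaults to the catalog bundled with the package.
#' @return Data frame with columns `pfam_acc` and `role`.
#' @export
load_role_catalog <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "role_catalog.tsv", package = "tolton")
  df <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("pfam_acc", "role") %in% names(df)))
    stop("parse error: role catalog needs pfam_acc and role columns", call. = FALSE)
  df[, c("pfam_acc", "role")]
}

# Roles that satisfy the tol-pal minimal complement
tolpal_complement_roles <- c("motor_pentamer", "motor_dimer", "transducer",
                             "tolB", "pal")

#' Assign a functional role to every gene with passing domain hits
#'
#' Hits with E-value above `evalue_max` are discarded; remaining hits are
#' mapped to roles via the catalog (unknown accessions map to no role).
#' Composite roles are resolved first: a gene with both TolB domains
#' (propeller PF07676 + Rossmann PF04052) is reported once as `tolB`;
#' propeller-only genes become `tolB_like` and N-domain-only genes stay
#' `tolB_nterm` (neither counts toward the minimal complement). Likewise a
#' gene with both TBDT domains becomes `tbdt`; a lone barrel is `tbdt_barrel`
#' unless `tbdt_require_plug` is disabled. When a gene's passing hits still
#' map to more than one role it is flagged ambiguous and resolved
#' deterministically: best bitscore wins, ties broken by lexicographically
#' smallest Pfam accession.
#'
#' The result is a pure function of `(hits, evalue_max, catalog)`:
#' permuting input rows never changes it, and tightening `evalue_max` can
#' only remove roles, never add them.
#'
#' @param hits Domain-hit data frame from [read_domain_hits()].
#' @param evalue_max Maximum passing E-value (> 0).
#' @param catalog Role catalog from [load_role_catalog()].
#' @param tbdt_require_plug Require both barrel and plug for a `tbdt` call.
#' @return Data frame with one row per gene holding at least one passing
#'   catalog hit: `gene_id`, `role`, `ambiguous`, `n_hits`, `best_pfam`.
#' @export
assign_roles <- function(hits, evalue_max = 1e-5, catalog = NULL,
                         tbdt_require_plug = TRUE) {
  if (!is.numeric(evalue_max) || length(evalue_max) != 1 || evalue_max <= 0)
    stop("config error: evalue_max must be a single positive number", call. = FALSE)
  if (is.null(catalog)) catalog <- load_role_catalog()
  empty <- data.frame(gene_id = character(), role = character(),
                      ambiguous = logical(), n_hits = integer(),
                      best_pfam = character(), stringsAsFactors = FALSE)
  if (is.null(hits) || nrow(hits) == 0) return(empty)
  hits <- hits[hits$evalue <= evalue_max, , drop = FALSE]
  hits$role <- catalog$role[match(hits$pfam_acc, catalog$pfam_acc)]
  hits <- hits[!is.na(hits$role), , drop = FALSE]
  if (nrow(hits) == 0) return(empty)
  # canonical order so the result is independent of input row order
  hits <- hits[order(hits$gene_id, hits$pfam_acc, -hits$bitscore), , drop = FALSE]
  per_gene <- split(hits, hits$gene_id)
  rows <- lapply(per_gene, function(h) {
    roles <- unique(h$role)
    # role -> (best bitscore, smallest supporting accession)
    cand <- do.call(rbind, lapply(roles, function(r) {
      hr <- h[h$role == r, , drop = FALSE]
      data.frame(role = r, bitscore = max(hr$bitscore),
                 pfam = min(hr$pfam_acc), stringsAsFactors = FALSE)
    }))
    collapse <- function(parts, whole) {
      if (all(parts %in% cand$role)) {
        keep <- cand[!cand$role %in% parts, , drop = FALSE]
        sub <- cand[cand$role %in% parts, , drop = FALSE]
        cand <<- rbind(keep, data.frame(role = whole,
                                        bitscore = max(sub$bitscore),
                                        pfam = min(sub$pfam),
                                        stringsAsFactors = FALSE))
      }
    }
    collapse(c("tolB_propeller", "tolB_nterm"), "tolB")
    if ("tolB_propeller" %in% cand$role)
      cand$role[cand$role == "tolB_propeller"] <- "tolB_like"
    collapse(c("tbdt_barrel", "tbdt_plug"), "tbdt")
    if (!tbdt_require_plug && "tbdt_barrel" %in% cand$role)
      cand$role[cand$role == "tbdt_barrel"] <- "tbdt"
    cand <- cand[order(-cand$bitscore, cand$pfam), , drop = FALSE]
    data.frame(gene_id = h$gene_id[1], role = cand$role[1],
               ambiguous = nrow(cand) > 1, n_hits = nrow(h),
               best_pfam = cand$pfam[1], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Does a transducer have room for all three domains?
#'
#' A force transducer is "full" when a transmembrane helix is predicted and
#' the protein is long enough that, under the segmentation rule (domain II
#' starts one residue after the TMH; domain III is the final 100 residues),
#' domain II is non-empty.
#'
#' @param profile An [ss_profile()] with a `tmh_span`, or `NULL`.
#' @param protein_length Protein length in residues; defaults to the profile
#'   length.
#' @return `TRUE`/`FALSE`, or `NA` (indeterminate) when no profile is
#'   available.
#' @export
is_full_transducer <- function(profile, protein_length = NULL) {
  if (is.null(profile)) return(NA)
  if (is.null(protein_length)) protein_length <- nchar(profile$states)
  if (is.null(profile$tmh_span)) return(FALSE)
  tmh_end <- profile$tmh_span[2]
  # non-empty domain II: tmh_end + 1 <= protein_length - 100
  isTRUE(tmh_end + 1 <= protein_length - 100)
}
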