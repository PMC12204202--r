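#' Segment a force transducer into its three domains
#'
#' Domain I is the predicted transmembrane helix; domain II runs from the
#' residue after the TMH to the residue before the C-terminal domain; and
#' domain III is the final 100 residues of the protein. When the TMH ends
#' too close to the C-terminus, domain II is empty and the record is
#' flagged.
#'
#' @param profile An [ss_profile()] with a `tmh_span`.
#' @param protein_length Protein length in residues (defaults to the
#'   profile's length).
#' @return List with integer spans `domain1`, `domain2`, `domain3`
#'   (`c(start, end)`; a span with `start > end` is empty), `d2_length`, and
#'   logical `flagged` (empty domain II).
#' @export
segment_domains <- function(profile, protein_length = NULL) {
  if (is.null(protein_length)) protein_length <- nchar(profile$states)
  if (is.null(profile$tmh_span))
    stop("segmentation error: no TMH span in profile for gene '",
         profile$gene_id, "'", call. = FALSE)
  tmh <- profile$tmh_span
  d2 <- c(tmh[2] + 1L, protein_length - 100L)
  d3 <- c(protein_length - 99L, protein_length)
  d2_len <- max(0L, d2[2] - d2[1] + 1L)
  list(domain1 = tmh, domain2 = d2, domain3 = d3,
       d2_length = d2_len, flagged = d2_len == 0L)
}

#' Detect the motor box in domain II
#'
#' The motor box is a short predicted beta-strand in the disordered region
#' immediately after the TMH. Operationally: the first run of at least
#' `min_strand` consecutive E states that begins within the first `window`
#' residues of domain II and is flanked on both sides by at least
#' `min_coil_flank` C states.
#'
#' @param profile An [ss_profile()].
#' @param domain2_span Integer `c(start, end)` of domain II.
#' @param window Residues into domain II within which the strand must begin.
#' @param min_strand Minimum strand run length.
#' @param min_coil_flank Minimum coil run on each side.
#' @return Integer `c(start, end)` of the strand in protein coordinates, or
#'   `NULL` when no qualifying strand exists.
#' @export
detect_motor_box <- function(profile, domain2_span, window = 75L,
                             min_strand = 3L, min_coil_flank = 3L) {
  if (domain2_span[1] > domain2_span[2]) return(NULL)
  s <- strsplit(profile$states, "")[[1]]
  n <- length(s)
  r <- rle(s)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (i in seq_along(r$values)) {
    if (r$values[i] != "E") next
    st <- starts[i]; en <- ends[i]
    if (st < domain2_span[1] || st > domain2_span[2]) next
    # must begin within the first `window` residues of domain II
    if (st - domain2_span[1] + 1L > window) next
    if (r$lengths[i] < min_strand) next
    left_ok <- i > 1 && r$values[i - 1] == "C" && r$lengths[i - 1] >= min_coil_flank
    right_ok <- i < length(r$values) && r$values[i + 1] == "C" &&
                r$lengths[i + 1] >= min_coil_flank
    if (min_coil_flank == 0L) { left_ok <- TRUE; right_ok <- TRUE }
    if (left_ok && right_ok) return(c(st, en))
  }
  NULL
}

#' Domain II composition metrics
#'
#' The number of domain II residues predicted alpha-helical, and the number
#' of proline residues in domain II, each expressed as a percentage of the
#' domain II length. Proline is counted from the amino-acid sequence, not
#' the secondary-structure string.
#'
#' @param profile An [ss_profile()].
#' @param sequence Amino-acid sequence of the protein.
#' @param domain2_span Integer `c(start, end)` of domain II.
#' @return List with `helix_pct`, `proline_pct` and `d2_length`; all `NA`
#'   with `undefined = TRUE` when domain II is empty.
#' @export
composition_metrics <- function(profile, sequence, domain2_span) {
  if (domain2_span[1] > domain2_span[2])
    return(list(helix_pct = NA_real_, proline_pct = NA_real_,
                d2_length = 0L, undefined = TRUE))
  d2_states <- substring(profile$states, domain2_span[1], domain2_span[2])
  d2_seq <- substring(sequence, domain2_span[1], domain2_span[2])
  d2_len <- domain2_span[2] - domain2_span[1] + 1L
  n_h <- lengths(regmatches(d2_states, gregexpr("H", d2_states)))
  n_p <- lengths(regmatches(d2_seq, gregexpr("P", d2_seq)))
  list(helix_pct = 100 * n_h / d2_len, proline_pct = 100 * n_p / d2_len,
       d2_length = d2_len, undefined = FALSE)
}

#' Classify domain II composition
#'
#' Alpha-dominant when the helix percentage is at least `ratio` times the
#' proline percentage and at least `floor`; proline-dominant symmetrically;
#' disordered when both fall below the floor; mixed otherwise.
#'
#' @param helix_pct,proline_pct Domain II composition percentages.
#' @param ratio Dominance ratio (default 2).
#' @param floor Minimum percentage for dominance (default 10).
#' @return One of `"alpha_dominant"`, `"proline_dominant"`, `"mixed"`,
#'   `"disordered"`, or `NA` for undefined metrics.
#' @export
classify_composition <- function(helix_pct, proline_pct, ratio = 2, floor = 10) {
  if (is.na(helix_pct) || is.na(proline_pct)) return(NA_character_)
  if (helix_pct >= floor && helix_pct >= ratio * proline_pct) return("alpha_dominant")
  if (proline_pct >= floor && proline_pct >= ratio * helix_pct) return("proline_dominant")
  if (helix_pct < floor && proline_pct < floor) return("disordered")
  "mixed"
}

#' Domain II PPII propensity summary
#'
#' Fraction of domain II residues whose per-residue PPII propensity score
#' reaches the cutoff.
#'
#' @param ppii_scores Per-residue scores in `[0, 1]`, or `NULL`.
#' @param domain2_span Integer `c(start, end)` of domain II.
#' @param cutoff Score threshold (default 0.5).
#' @return Fraction in `[0, 1]`, or `NA` when scores are absent or domain II
#'   is empty.
#' @export
ppii_summary <- function(ppii_scores, domain2_span, cutoff = 0.5) {
  if (is.null(ppii_scores) || domain2_span[1] > domain2_span[2]) return(NA_real_)
  sc <- ppii_scores[domain2_span[1]:domain2_span[2]]
  mean(sc >= cutoff)
}

#' Classify the lipidation/secretion signal of a protein
#'
#' An external signal prediction, when available, is passed through
#' unchanged. Otherwise a minimal lipobox heuristic is applied to the raw
#' sequence: the pattern `[LIV][ASTVI][GAS]C` with the invariant cysteine
#' falling within residues 10-40 marks a lipoprotein. The heuristic exists
#' so synthetic tests need no external predictor; it is not a replacement
#' for a real signal-peptide prediction.
#'
#' @param signal_call External call (`"none"`, `"sec_signal"`,
#'   `"lipoprotein"`) or `NULL`/`NA`.
#' @param sequence Amino-acid sequence, used only when no external call is
#'   given.
#' @return One of `"none"`, `"sec_signal"`, `"lipoprotein"`.
#' @export
classify_lipoprotein <- function(signal_call = NULL, sequence = NULL) {
  if (!is.null(signal_call) && !is.na(signal_call)) {
    if (!signal_call %in% c("none", "sec_signal", "lipoprotein"))
      stop("validation error: unknown signal_call '", signal_call, "'",
           call. = FALSE)
    return(signal_call)
  }
  if (is.null(sequence) || is.na(sequence) || nchar(sequence) == 0) return("none")
  m <- gregexpr("[LIV][ASTVI][GAS]C", sequence)[[1]]
  if (m[1] == -1) return("none")
  cys_pos <- m + 3L
  if (any(cys_pos >= 10 & cys_pos <= 40)) "lipoprotein" else "none"
}

#' Full architecture record for one transducer
#'
#' Segments the protein, detects the motor box, and computes the domain II
#' composition metrics, PPII summary, lipidation class and composition
#' class. Proteins without a predicted TMH are emitted with empty spans and
#' flagged (they are excluded from cohort statistics downstream).
#'
#' @param profile An [ss_profile()].
#' @param sequence Amino-acid sequence.
#' @param config A [tolton_config()].
#' @param gene_id Identifier for the output row (defaults to the profile's).
#' @return One-row data frame with spans, `d2_length`, `helix_pct`,
#'   `proline_pct`, `ppii_fraction`, `motor_box_start`/`_end`,
#'   `lipo_class`, `composition_class` and `flagged`.
#' @export
analyze_transducer <- function(profile, sequence, config = tolton_config(),
                               gene_id = NULL) {
  config <- as_tolton_config(config)
  if (is.null(gene_id)) gene_id <- profile$gene_id
  L <- nchar(profile$states)
  na_row <- data.frame(
    gene_id = gene_id, protein_length = L,
    d1_start = NA_integer_, d1_end = NA_integer_,
    d2_start = NA_integer_, d2_end = NA_integer_,
    d3_start = NA_integer_, d3_end = NA_integer_,
    d2_length = NA_integer_, helix_pct = NA_real_, proline_pct = NA_real_,
    ppii_fraction = NA_real_, motor_box_start = NA_integer_,
    motor_box_end = NA_integer_,
    lipo_class = classify_lipoprotein(profile$signal_call, sequence),
    composition_class = NA_character_, flagged = TRUE,
    stringsAsFactors = FALSE)
  if (is.null(profile$tmh_span)) return(na_row)
  seg <- segment_domains(profile, L)
  if (seg$flagged) {
    na_row$d1_start <- seg$domain1[1]; na_row$d1_end <- seg$domain1[2]
    na_row$d2_length <- 0L
    return(na_row)
  }
  mb <- detect_motor_box(profile, seg$domain2,
                         window = config$motor_box_window,
                         min_strand = config$min_strand,
                         min_coil_flank = config$min_coil_flank)
  comp <- composition_metrics(profile, sequence, seg$domain2)
  data.frame(
    gene_id = gene_id, protein_length = L,
    d1_start = seg$domain1[1], d1_end = seg$domain1[2],
    d2_start = seg$domain2[1], d2_end = seg$domain2[2],
    d3_start = seg$domain3[1], d3_end = seg$domain3[2],
    d2_length = comp$d2_length,
    helix_pct = comp$helix_pct, proline_pct = comp$proline_pct,
    ppii_fraction = ppii_summary(profile$ppii_scores, seg$domain2,
                                 config$ppii_cutoff),
    motor_box_start = if (is.null(mb)) NA_integer_ else mb[1],
    motor_box_end = if (is.null(mb)) NA_integer_ else mb[2],
    lipo_class = classify_lipoprotein(profile$signal_call, sequence),
    composition_class = classify_composition(comp$helix_pct, comp$proline_pct,
                                             config$comp_ratio,
                                             config$comp_floor),
    flagged = FALSE, stringsAsFactors = FALSE)
}
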