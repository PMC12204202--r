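#' Pipeline configuration
#'
#' Bundles every tunable threshold of the pipeline with its default, after
#' validating each against its documented range. All downstream functions
#' accept a config built here, so one object reproduces a whole run.
#'
#' @param evalue_max Maximum HMMER independent E-value for a domain hit to
#'   support a role assignment. Must be > 0. Default `1e-5`.
#' @param max_intervening Maximum number of non-role genes allowed between two
#'   role-bearing genes in the same locus (rank distance minus one). Default 3.
#' @param max_gap_bp Maximum intergenic distance in bp between two role-bearing
#'   genes in the same locus. Default 5000.
#' @param adjacency_rank Rank distance at or below which a cpoB gene counts as
#'   "directly adjacent" to a tol-pal complement gene. Default 1.
#' @param motor_box_window Number of residues at the start of domain II within
#'   which a motor-box strand must begin. Default 75.
#' @param min_strand Minimum length (residues) of the beta-strand run forming
#'   a motor box. Default 3.
#' @param min_coil_flank Minimum coil run required on each side of the
#'   motor-box strand. Default 3.
#' @param comp_ratio Dominance ratio r for composition classification: a class
#'   is dominant when its percentage is at least r times the other. Default 2.
#' @param comp_floor Minimum percentage for either class to count as dominant;
#'   below the floor on both axes the domain is called disordered. Default 10.
#' @param ppii_cutoff Per-residue PPII propensity score at or above which a
#'   residue counts as PPII-prone. Default 0.5.
#' @param tbdt_require_plug If `TRUE` (default) a TonB-dependent transporter
#'   call requires both the barrel and the plug domain on one gene.
#' @param circular If `TRUE`, rank adjacency wraps around each replicon.
#'   Default `FALSE` (replicons treated as linear).
#'
#' @return A list of class `tolton_config`.
#' @export
tolton_config <- function(evalue_max = 1e-5,
                          max_intervening = 3L,
                          max_gap_bp = 5000L,
                          adjacency_rank = 1L,
                          motor_box_window = 75L,
                          min_strand = 3L,
                          min_coil_flank = 3L,
                          comp_ratio = 2,
                          comp_floor = 10,
                          ppii_cutoff = 0.5,
                          tbdt_require_plug = TRUE,
                          circular = FALSE) {
  stop_cfg <- function(cond, msg) if (cond) stop("config error: ", msg, call. = FALSE)
  stop_cfg(!is.numeric(evalue_max) || length(evalue_max) != 1 || evalue_max <= 0,
           "evalue_max must be a single positive number")
  stop_cfg(max_intervening < 0, "max_intervening must be >= 0")
  stop_cfg(max_gap_bp <= 0, "max_gap_bp must be > 0")
  stop_cfg(adjacency_rank < 1, "adjacency_rank must be >= 1")
  stop_cfg(motor_box_window < 1, "motor_box_window must be >= 1")
  stop_cfg(min_strand < 1, "min_strand must be >= 1")
  stop_cfg(min_coil_flank < 0, "min_coil_flank must be >= 0")
  stop_cfg(comp_ratio < 1, "comp_ratio must be >= 1")
  stop_cfg(comp_floor < 0 || comp_floor > 100, "comp_floor must be in [0, 100]")
  stop_cfg(ppii_cutoff < 0 || ppii_cutoff > 1, "ppii_cutoff must be in [0, 1]")
  structure(list(
    evalue_max = evalue_max,
    max_intervening = as.integer(max_intervening),
    max_gap_bp = as.integer(max_gap_bp),
    adjacency_rank = as.integer(adjacency_rank),
    motor_box_window = as.integer(motor_box_window),
    min_strand = as.integer(min_strand),
    min_coil_flank = as.integer(min_coil_flank),
    comp_ratio = comp_ratio,
    comp_floor = comp_floor,
    ppii_cutoff = ppii_cutoff,
    tbdt_require_plug = isTRUE(tbdt_require_plug),
    circular = isTRUE(circular)
  ), class = "tolton_config")
}

as_tolton_config <- function(config) {
  if (is.null(config)) return(tolton_config())
  if (inherits(config, "tolton_config")) return(config)
  do.call(tolton_config, config)
}
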