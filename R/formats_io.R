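#' @importFrom utils read.delim write.table
#' @importFrom stats setNames
NULL

gene_table_cols <- c("gene_id", "genome_id", "replicon_id", "start", "end",
                     "strand", "rank", "product", "protein_length", "protein_seq")

#' Build a validated gene table
#'
#' Normalises a raw per-gene data frame into the shared gene-record layout:
#' sorted by (replicon, start), with a 0-based rank assigned along each
#' replicon by start coordinate regardless of strand.
#'
#' @param df Data frame with at least `gene_id`, `replicon_id`, `start`,
#'   `end`, `strand`; optional `genome_id`, `product`, `protein_length`,
#'   `protein_seq`.
#' @param genome_id Genome identifier used when `df` lacks the column.
#' @return A data frame with columns `gene_id`, `genome_id`, `replicon_id`,
#'   `start`, `end`, `strand`, `rank`, `product`, `protein_length`,
#'   `protein_seq`.
#' @export
as_gene_table <- function(df, genome_id = NULL) {
  if (nrow(df) == 0) {
    out <- data.frame(gene_id = character(), genome_id = character(),
                      replicon_id = character(), start = integer(),
                      end = integer(), strand = character(), rank = integer(),
                      product = character(), protein_length = integer(),
                      protein_seq = character(), stringsAsFactors = FALSE)
    return(out)
  }
  if (is.null(df$genome_id)) df$genome_id <- if (is.null(genome_id)) "genome" else genome_id
  if (is.null(df$product)) df$product <- NA_character_
  if (is.null(df$protein_length)) df$protein_length <- NA_integer_
  if (is.null(df$protein_seq)) df$protein_seq <- NA_character_
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  df$strand <- as.character(df$strand)
  bad <- which(is.na(df$start) | is.na(df$end) | df$end < df$start)
  if (length(bad) > 0)
    stop("parse error: malformed coordinates (end < start or non-numeric) at row ",
         bad[1], call. = FALSE)
  if (anyDuplicated(df$gene_id))
    stop("validation error: duplicate gene_id '",
         df$gene_id[duplicated(df$gene_id)][1], "'", call. = FALSE)
  if (!all(df$strand %in% c("+", "-")))
    stop("parse error: strand must be '+' or '-'", call. = FALSE)
  has_seq <- !is.na(df$protein_seq) & !is.na(df$protein_length)
  if (any(has_seq & nchar(df$protein_seq) != df$protein_length))
    stop("validation error: protein_length does not match protein_seq length",
         call. = FALSE)
  ord <- order(df$replicon_id, df$start, df$end, df$gene_id)
  df <- df[ord, , drop = FALSE]
  df$rank <- as.integer(stats::ave(seq_len(nrow(df)), df$replicon_id,
                                   FUN = seq_along)) - 1L
  rownames(df) <- NULL
  df[, gene_table_cols]
}

#' Read a per-genome gene table
#'
#' @param path Path to a GFF3 file (CDS/gene features) or a tab-separated
#'   table with the gene-record columns.
#' @param dialect One of `"gff3"` or `"tsv"`.
#' @param genome_id Genome identifier attached to every record (GFF3 carries
#'   none); defaults to the file name without extension.
#' @param proteins Optional named character vector of protein sequences
#'   (names = gene ids), e.g. from [read_protein_fasta()].
#' @return A validated gene table (see [as_gene_table()]).
#' @export
read_gene_table <- function(path, dialect = c("gff3", "tsv"),
                            genome_id = NULL, proteins = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("I/O error: file not found: ", path, call. = FALSE)
  if (is.null(genome_id))
    genome_id <- sub("\\.[^.]*$", "", basename(path))
  if (dialect == "gff3") {
    raw <- tryCatch(as.data.frame(rtracklayer::readGFF(path)),
                    error = function(e) stop("parse error: ", conditionMessage(e),
                                             call. = FALSE))
    if (nrow(raw) > 0) raw <- raw[raw$type %in% c("gene", "CDS"), , drop = FALSE]
    if (nrow(raw) == 0) return(as_gene_table(raw[0, 0, drop = FALSE], genome_id))
    df <- data.frame(
      gene_id = as.character(raw$ID),
      replicon_id = as.character(raw$seqid),
      start = raw$start, end = raw$end,
      strand = as.character(raw$strand),
      product = if (is.null(raw$product)) NA_character_ else as.character(raw$product),
      protein_length = if (is.null(raw$protein_length)) NA_integer_
                       else as.integer(raw$protein_length),
      stringsAsFactors = FALSE)
  } else {
    df <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                     colClasses = "character")
    needed <- c("gene_id", "replicon_id", "start", "end", "strand")
    missing_cols <- setdiff(needed, names(df))
    if (length(missing_cols) > 0)
      stop("parse error: missing columns: ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    suppressWarnings({
      df$start <- as.integer(df$start)
      df$end <- as.integer(df$end)
      if (!is.null(df$protein_length)) df$protein_length <- as.integer(df$protein_length)
      if (!is.null(df$rank)) df$rank <- NULL
    })
  }
  if (!is.null(proteins)) {
    idx <- match(df$gene_id, names(proteins))
    df$protein_seq <- ifelse(is.na(idx), NA_character_, unname(proteins[idx]))
    df$protein_length <- ifelse(is.na(idx),
                                if (is.null(df$protein_length)) NA_integer_ else df$protein_length,
                                nchar(unname(proteins[idx])))
  }
  as_gene_table(df, genome_id)
}

#' Read protein sequences from a FASTA file
#'
#' @param path FASTA file of amino-acid sequences; the record id (first token
#'   of the header) is taken as the gene id.
#' @return Named character vector of sequences.
#' @export
read_protein_fasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  seqs <- as.character(aa)
  names(seqs) <- vapply(strsplit(names(aa), "\\s+"), `[`, character(1), 1)
  seqs
}

#' Read HMMER per-domain tabular output
#'
#' Parses hmmscan `--domtblout` rows into domain hits. The query name is the
#' gene id; the target accession (the Pfam model) becomes `pfam_acc`, with
#' any version suffix stripped (`PF06519.12` to `PF06519`). Envelope
#' coordinates are used as the hit span and the per-domain independent
#' E-value and score as `evalue`/`bitscore`.
#'
#' @param path Path to a domtblout file. Comment lines (`#`) are skipped.
#' @return Data frame with columns `gene_id`, `pfam_acc`, `bitscore`,
#'   `evalue`, `env_start`, `env_end`.
#' @export
read_domain_hits <- function(path) {
  if (!file.exists(path)) stop("I/O error: file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  empty <- data.frame(gene_id = character(), pfam_acc = character(),
                      bitscore = numeric(), evalue = numeric(),
                      env_start = integer(), env_end = integer(),
                      stringsAsFactors = FALSE)
  if (length(lines) == 0) return(empty)
  rows <- lapply(seq_along(lines), function(i) {
    f <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(f) < 23)
      stop("parse error: line ", i, " has ", length(f),
           " columns; expected >= 23 (HMMER per-domain tabular layout)",
           call. = FALSE)
    data.frame(gene_id = f[4],
               pfam_acc = sub("\\.\\d+$", "", f[2]),
               bitscore = as.numeric(f[14]),
               evalue = as.numeric(f[13]),
               env_start = as.integer(f[20]),
               env_end = as.integer(f[21]),
               stringsAsFactors = FALSE)
  })
  hits <- do.call(rbind, rows)
  if (anyNA(hits$evalue) || any(hits$evalue < 0))
    stop("validation error: E-values must be non-negative numbers", call. = FALSE)
  if (any(hits$env_start > hits$env_end))
    stop("validation error: envelope start > end", call. = FALSE)
  hits
}

#' Construct a secondary-structure profile
#'
#' @param gene_id Gene identifier.
#' @param states Character string over `{H, E, C}`, one state per residue.
#' @param confidence Numeric vector in `[0, 1]`, one value per residue.
#' @param tmh_span Optional `c(start, end)` residue interval of the
#'   transmembrane helix.
#' @param ppii_scores Optional per-residue PPII propensity scores in `[0, 1]`.
#' @param signal_call Optional signal classification: `"none"`,
#'   `"sec_signal"` or `"lipoprotein"`.
#' @return A list of class `ss_profile`.
#' @export
ss_profile <- function(gene_id, states, confidence = NULL, tmh_span = NULL,
                       ppii_scores = NULL, signal_call = NULL) {
  n <- nchar(states)
  if (!grepl("^[HEC]*$", states))
    stop("validation error: states must use only H, E, C", call. = FALSE)
  if (is.null(confidence)) confidence <- rep(1, n)
  if (length(confidence) != n)
    stop("validation error: confidence length != states length", call. = FALSE)
  if (!is.null(tmh_span)) {
    tmh_span <- as.integer(tmh_span)
    if (length(tmh_span) != 2 || tmh_span[1] > tmh_span[2] ||
        tmh_span[1] < 1 || tmh_span[2] > n)
      stop("validation error: tmh_span outside [1, protein_length]", call. = FALSE)
  }
  if (!is.null(ppii_scores) && length(ppii_scores) != n)
    stop("validation error: ppii_scores length != states length", call. = FALSE)
  if (!is.null(signal_call) &&
      !signal_call %in% c("none", "sec_signal", "lipoprotein"))
    stop("validation error: unknown signal_call '", signal_call, "'", call. = FALSE)
  structure(list(gene_id = gene_id, states = states,
                 confidence = as.numeric(confidence), tmh_span = tmh_span,
                 ppii_scores = ppii_scores, signal_call = signal_call),
            class = "ss_profile")
}

#' Read a PsiPred secondary-structure prediction
#'
#' Supports the per-residue `ss2` layout (index, residue, state, then the
#' coil/helix/strand confidence columns) and the block-wise `horiz` layout
#' (`Conf:` / `Pred:` lines). For `ss2`, the state is re-derived as the
#' maximum-confidence state per residue; confidence ties are broken by the
#' fixed precedence H > E > C so parsing is deterministic.
#'
#' @param path Input file.
#' @param dialect `"ss2"` or `"horiz"`.
#' @param gene_id Gene identifier for the profile; defaults to the file name.
#' @param expected_length If given, the parsed residue count must equal it.
#' @return An [ss_profile()].
#' @export
read_ss_profile <- function(path, dialect = c("ss2", "horiz"),
                            gene_id = NULL, expected_length = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("I/O error: file not found: ", path, call. = FALSE)
  if (is.null(gene_id)) gene_id <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path)
  if (dialect == "ss2") {
    lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
    if (length(lines) == 0) {
      prof <- ss_profile(gene_id, "", numeric(0))
    } else {
      f <- strsplit(trimws(lines), "\\s+")
      ncol_ok <- vapply(f, length, integer(1)) == 6
      if (!all(ncol_ok))
        stop("parse error: ss2 rows must have 6 columns (row ",
             which(!ncol_ok)[1], ")", call. = FALSE)
      idx <- as.integer(vapply(f, `[`, character(1), 1))
      if (any(idx != seq_along(idx)))
        stop("parse error: residue index gap at row ",
             which(idx != seq_along(idx))[1], call. = FALSE)
      conf_c <- as.numeric(vapply(f, `[`, character(1), 4))
      conf_h <- as.numeric(vapply(f, `[`, character(1), 5))
      conf_e <- as.numeric(vapply(f, `[`, character(1), 6))
      # max-confidence state; ties resolved by precedence H > E > C
      m <- cbind(H = conf_h, E = conf_e, C = conf_c)
      state <- colnames(m)[max.col(m, ties.method = "first")]
      prof <- ss_profile(gene_id, paste(state, collapse = ""),
                         pmin(1, pmax(0, apply(m, 1, max))))
    }
  } else {
    pred <- sub("^\\s*Pred:\\s?", "", lines[grepl("^\\s*Pred:", lines)])
    conf <- sub("^\\s*Conf:\\s?", "", lines[grepl("^\\s*Conf:", lines)])
    states <- gsub("\\s", "", paste(pred, collapse = ""))
    confd <- gsub("\\s", "", paste(conf, collapse = ""))
    if (nchar(states) != nchar(confd))
      stop("parse error: Conf/Pred length mismatch in horiz file", call. = FALSE)
    if (!grepl("^[HEC]*$", states))
      stop("parse error: horiz Pred states must be H/E/C", call. = FALSE)
    prof <- ss_profile(gene_id, states,
                       as.integer(strsplit(confd, "")[[1]]) / 9)
  }
  if (!is.null(expected_length) && nchar(prof$states) != expected_length)
    stop("parse error: profile has ", nchar(prof$states),
         " residues; expected ", expected_length, call. = FALSE)
  prof
}

#' Read a tabular signal-peptide prediction summary
#'
#' Expects a TSV with columns `gene_id` and `prediction`, where the
#' prediction strings follow the usual server vocabulary: values containing
#' `lipo` map to `lipoprotein`, values starting with `SP` map to
#' `sec_signal`, anything else to `none`.
#'
#' @param path TSV file.
#' @return Named character vector gene_id -> {none, sec_signal, lipoprotein}.
#' @export
read_signal_table <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("gene_id", "prediction") %in% names(df)))
    stop("parse error: signal table needs gene_id and prediction columns",
         call. = FALSE)
  cls <- ifelse(grepl("lipo", df$prediction, ignore.case = TRUE), "lipoprotein",
         ifelse(grepl("^SP", df$prediction), "sec_signal", "none"))
  setNames(cls, df$gene_id)
}

#' Read a table of predicted transmembrane-helix spans
#'
#' @param path TSV with columns `gene_id`, `tmh_start`, `tmh_end`.
#' @return Named list gene_id -> integer `c(start, end)`.
#' @export
read_tmh_table <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("gene_id", "tmh_start", "tmh_end") %in% names(df)))
    stop("parse error: TMH table needs gene_id, tmh_start, tmh_end columns",
         call. = FALSE)
  setNames(lapply(seq_len(nrow(df)),
                  function(i) as.integer(c(df$tmh_start[i], df$tmh_end[i]))),
           df$gene_id)
}

#' Write pipeline result tables and a run manifest
#'
#' Writes each result data frame as a TSV under `out_dir` and a JSON
#' manifest recording the configuration, the seed and an md5 checksum of
#' every written table. Output is deterministic: re-running with identical
#' inputs reproduces byte-identical files.
#'
#' @param results Named list of data frames (e.g. `loci`, `system_calls`,
#'   `architecture`, `cohort_summary`).
#' @param out_dir Output directory, created if absent.
#' @param config A [tolton_config()] recorded in the manifest.
#' @param seed Integer seed recorded in the manifest.
#' @return Invisibly, the manifest as a list.
#' @export
write_tables <- function(results, out_dir, config = tolton_config(), seed = NA) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("I/O error: cannot create directory ", out_dir, call. = FALSE)
  }
  config <- as_tolton_config(config)
  paths <- character(0)
  for (nm in names(results)) {
    p <- file.path(out_dir, paste0(nm, ".tsv"))
    df <- as.data.frame(results[[nm]])
    write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE,
                na = "NA", eol = "\n")
    paths[nm] <- p
  }
  manifest <- list(
    config = unclass(config),
    seed = seed,
    tables = lapply(paths, function(p)
      list(file = basename(p), md5 = unname(tools::md5sum(p))))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Read back a TSV written by [write_tables()]
#'
#' @param path TSV file.
#' @return Data frame.
#' @export
read_result_table <- function(path) {
  read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
             na.strings = "NA")
}
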