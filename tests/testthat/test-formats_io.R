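write_toy_gff <- function(rows) {
  tmp <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3", rows), tmp)
  tmp
}

test_that("GFF3 gene tables are sorted by start with 0-based ranks", {
  rows <- c(
    "chr1\ts\tCDS\t500\t900\t.\t-\t0\tID=gB;product=tolB;protein_length=133",
    "chr1\ts\tCDS\t100\t400\t.\t+\t0\tID=gA;product=ybgC;protein_length=100",
    "chr1\ts\tCDS\t1000\t1300\t.\t+\t0\tID=gC;product=pal;protein_length=100")
  tab <- read_gene_table(write_toy_gff(rows), "gff3", genome_id = "g1")
  expect_equal(nrow(tab), 3)
  expect_equal(tab$gene_id, c("gA", "gB", "gC"))
  expect_equal(tab$rank, 0:2)
  expect_equal(tab$genome_id, rep("g1", 3))
  # order independence: shuffled rows give an identical table
  tab2 <- read_gene_table(write_toy_gff(rows[c(3, 1, 2)]), "gff3",
                          genome_id = "g1")
  expect_identical(tab, tab2)
})

test_that("empty and malformed gene tables are handled", {
  empty <- write_toy_gff(character(0))
  expect_equal(nrow(read_gene_table(empty, "gff3")), 0)
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("gene_id\treplicon_id\tstart\tend\tstrand",
               "g1\tchr\t500\t100\t+"), tsv)
  expect_error(read_gene_table(tsv, "tsv"), "parse error")
  writeLines(c("gene_id\treplicon_id\tstart\tend\tstrand",
               "g1\tchr\t100\t500\t+", "g1\tchr\t600\t900\t+"), tsv)
  expect_error(read_gene_table(tsv, "tsv"), "duplicate gene_id")
})

test_that("ranks restart per replicon and proteins attach by id", {
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("gene_id\treplicon_id\tstart\tend\tstrand",
               "a1\tchr2\t100\t400\t+", "a2\tchr1\t100\t400\t-",
               "a3\tchr1\t500\t900\t+"), tsv)
  tab <- read_gene_table(tsv, "tsv",
                         proteins = c(a2 = "MKKL", a3 = "MA"))
  expect_equal(tab$rank[tab$replicon_id == "chr1"], 0:1)
  expect_equal(tab$rank[tab$replicon_id == "chr2"], 0)
  expect_equal(tab$protein_length[tab$gene_id == "a2"], 4)
  expect_true(is.na(tab$protein_seq[tab$gene_id == "a1"]))
})

test_that("auxiliary prediction tables parse into their lookup structures", {
  fa <- tempfile(fileext = ".fasta")
  writeLines(c(">a1 putative transducer", "MKKL", ">a2", "MA"), fa)
  seqs <- read_protein_fasta(fa)
  expect_equal(seqs, c(a1 = "MKKL", a2 = "MA"))
  sig <- tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tprediction", "g1\tSP(lipo)", "g2\tSP(Sec/SPI)",
               "g3\tOTHER"), sig)
  expect_equal(read_signal_table(sig),
               c(g1 = "lipoprotein", g2 = "sec_signal", g3 = "none"))
  tmh <- tempfile(fileext = ".tsv")
  writeLines(c("gene_id\ttmh_start\ttmh_end", "g1\t10\t30"), tmh)
  expect_equal(read_tmh_table(tmh), list(g1 = c(10L, 30L)))
})

test_that("HMMER per-domain rows parse with version-stripped accessions", {
  tmp <- tempfile()
  writeLines(c(
    "# hmmscan per-domain output",
    paste("TolA PF06519.12 120 geneX - 350 1e-30 95.2 0.1 1 1 2e-30 1e-30",
          "94.8 0.1 1 120 10 130 5 135 0.98 force transducer")), tmp)
  hits <- read_domain_hits(tmp)
  expect_equal(hits$pfam_acc, "PF06519")
  expect_equal(hits$gene_id, "geneX")
  expect_equal(hits$evalue, 1e-30)
  expect_equal(hits$bitscore, 94.8)
  expect_equal(hits$env_start, 5)
  expect_equal(hits$env_end, 135)
})

test_that("hit parsing rejects bad layouts and values", {
  tmp <- tempfile()
  writeLines("# only comments here", tmp)
  expect_equal(nrow(read_domain_hits(tmp)), 0)
  writeLines("too few columns on this line", tmp)
  expect_error(read_domain_hits(tmp), "parse error")
  writeLines(paste("T PF1.1 10 g - 10 1e-5 5 0 1 1 1e-5 -2e-5 5 0 1 10 1 10",
                   "1 10 0.9 d"), tmp)
  expect_error(read_domain_hits(tmp), "non-negative")
})

ss2_line <- function(i, aa, st, c, h, e) sprintf("%4d %s %s  %.3f %.3f %.3f",
                                                 i, aa, st, c, h, e)

test_that("ss2 profiles concatenate max-confidence states", {
  tmp <- tempfile(fileext = ".ss2")
  writeLines(c("# PSIPRED VFORMAT", "",
               ss2_line(1, "M", "C", 0.9, 0.1, 0.0),
               ss2_line(2, "K", "C", 0.8, 0.1, 0.1),
               ss2_line(3, "A", "H", 0.1, 0.8, 0.1),
               ss2_line(4, "L", "H", 0.0, 0.9, 0.1),
               ss2_line(5, "V", "H", 0.1, 0.7, 0.2)), tmp)
  prof <- read_ss_profile(tmp, "ss2", gene_id = "p1")
  expect_s3_class(prof, "ss_profile")
  expect_equal(prof$states, "CCHHH")
  expect_equal(length(prof$confidence), 5)
  expect_error(read_ss_profile(tmp, "ss2", expected_length = 9), "expected 9")
})

test_that("ss2 confidence ties resolve by the H > E > C precedence", {
  # enumerate all tied pairs and the full three-way tie
  tmp <- tempfile(fileext = ".ss2")
  writeLines(c(ss2_line(1, "A", "C", 0.5, 0.5, 0.0),   # H ties C -> H
               ss2_line(2, "A", "C", 0.0, 0.5, 0.5),   # H ties E -> H
               ss2_line(3, "A", "C", 0.5, 0.0, 0.5),   # E ties C -> E
               ss2_line(4, "A", "C", 0.4, 0.4, 0.4)),  # three-way -> H
             tmp)
  prof <- read_ss_profile(tmp, "ss2")
  expect_equal(prof$states, "HHEH")
})

test_that("ss2 residue-index gaps are a parse error", {
  tmp <- tempfile(fileext = ".ss2")
  writeLines(c(ss2_line(1, "M", "C", 0.9, 0.1, 0.0),
               ss2_line(3, "K", "C", 0.9, 0.1, 0.0)), tmp)
  expect_error(read_ss_profile(tmp, "ss2"), "index gap")
})

test_that("horiz profiles parse Pred/Conf blocks", {
  tmp <- tempfile(fileext = ".horiz")
  writeLines(c("Conf: 987", "Pred: CCH", "  AA: MKA", "",
               "Conf: 99", "Pred: HH", "  AA: LV"), tmp)
  prof <- read_ss_profile(tmp, "horiz")
  expect_equal(prof$states, "CCHHH")
  expect_equal(prof$confidence[1], 1)
})

test_that("result tables round-trip and runs are byte-identical", {
  b <- generate_genome("gio", "complete_tolpal", seed = 11)
  s <- scan_genome(b$genes, b$hits)
  res <- list(loci = flatten_loci(s$loci), system_calls = s$system_call)
  d1 <- file.path(tempfile(), "run1"); d2 <- file.path(tempfile(), "run2")
  write_tables(res, d1, seed = 11)
  write_tables(res, d2, seed = 11)
  back <- read_result_table(file.path(d1, "system_calls.tsv"))
  expect_equal(back$tolpal_status, s$system_call$tolpal_status)
  expect_equal(back$genome_id, s$system_call$genome_id)
  for (f in c("loci.tsv", "system_calls.tsv"))
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
  man <- jsonlite::read_json(file.path(d1, "manifest.json"))
  expect_equal(man$seed, 11)
  expect_equal(man$config$max_intervening, 3)
})
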