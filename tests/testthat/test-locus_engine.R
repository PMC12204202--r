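ecoli_like <- function() {
  genes <- mk_genes(starts = seq(1000, by = 1500, length.out = 7))
  roles <- mk_roles(genes$gene_id,
                    c("ybgC", "motor_pentamer", "motor_dimer", "transducer",
                      "tolB", "pal", "cpoB_tpr"))
  list(genes = genes, roles = roles)
}

test_that("a seven-gene operon clusters into one locus", {
  x <- ecoli_like()
  loci <- cluster_loci(x$genes, x$roles)
  expect_equal(nrow(loci), 1)
  expect_equal(loci$n_genes, 7)
  expect_equal(loci$gene_order,
               "ybgC-motor_pentamer-motor_dimer-transducer-tolB-pal-cpoB_tpr")
})

test_that("genes on different replicons never co-cluster", {
  genes <- rbind(mk_genes(c(1000, 2500), replicon = "chr"),
                 mk_genes(c(1000, 2500), replicon = "plasmid", genome = "p"))
  genes$genome_id <- "g"
  genes$gene_id <- c("c1", "c2", "p1", "p2")
  genes <- as_gene_table(genes)
  roles <- mk_roles(c("c1", "c2", "p1", "p2"),
                    c("tolB", "pal", "transducer", "motor_pentamer"))
  loci <- cluster_loci(genes, roles)
  expect_equal(nrow(loci), 2)
  expect_setequal(loci$replicon_id, c("chr", "plasmid"))
})

test_that("a role on an unknown gene id is a validation error", {
  x <- ecoli_like()
  bad <- rbind(x$roles, mk_roles("ghost", "pal"))
  expect_error(cluster_loci(x$genes, bad), "unknown gene_id")
})

test_that("clustering equals the brute-force transitive-closure oracle", {
  skip_if_not_installed("igraph")
  for (seed in 1:25) {
    g <- generate_scatter_genome(n_genes = sample(10:50, 1), seed = seed)
    roles <- assign_roles(g$hits)
    loci <- cluster_loci(g$genes, roles)
    expect_identical(loci_as_sets(loci),
                     oracle_cluster_sets(g$genes, roles, 3, 5000),
                     info = paste("seed", seed))
  }
})

test_that("tol-pal classification distinguishes complete, split, partial, absent", {
  x <- ecoli_like()
  loci <- cluster_loci(x$genes, x$roles)
  expect_equal(classify_tolpal(loci)$tolpal_status, "complete")
  # split: tolQRAB cluster + distal pal-cpoB cluster
  genes <- mk_genes(c(seq(1000, by = 1500, length.out = 4),
                      seq(200000, by = 1500, length.out = 2)))
  roles <- mk_roles(genes$gene_id,
                    c("motor_pentamer", "motor_dimer", "transducer", "tolB",
                      "pal", "cpoB_tpr"))
  loci2 <- cluster_loci(genes, roles)
  expect_equal(nrow(loci2), 2)
  cl2 <- classify_tolpal(loci2)
  expect_equal(cl2$tolpal_status, "split")
  expect_equal(sort(cl2$contributing_loci), sort(loci2$locus_id))
  # partial: transducer alone
  genes3 <- mk_genes(1000)
  roles3 <- mk_roles(genes3$gene_id, "transducer")
  expect_equal(classify_tolpal(cluster_loci(genes3, roles3))$tolpal_status,
               "partial")
  expect_equal(classify_tolpal(cluster_loci(genes3, roles3[0, ]))$tolpal_status,
               "absent")
})

test_that("Ton classification needs transducer, TBDT and motor pair anywhere", {
  roles <- mk_roles(c("a", "b", "c", "d"),
                    c("transducer", "tbdt", "motor_pentamer", "motor_dimer"))
  expect_equal(classify_ton(roles), "complete")
  # a transducer claimed as TolA does not count
  expect_equal(classify_ton(roles, tolA_gene_ids = "a"), "incomplete")
  expect_equal(classify_ton(mk_roles("b", "tbdt")), "incomplete")
  expect_equal(classify_ton(mk_roles("x", "ybgC")), "absent")
  # a lone pentamer is not a motor pair
  expect_equal(classify_ton(mk_roles("c", "motor_pentamer")), "absent")
})

test_that("transducers are assigned TolA inside complement loci, TonB outside", {
  # complete locus plus one distal transducer
  genes <- mk_genes(c(seq(1000, by = 1500, length.out = 5), 500000))
  roles <- mk_roles(genes$gene_id,
                    c("motor_pentamer", "motor_dimer", "transducer", "tolB",
                      "pal", "transducer"))
  loci <- cluster_loci(genes, roles)
  tolpal <- classify_tolpal(loci)
  ident <- assign_transducer_identity(genes, roles, loci, tolpal)
  expect_equal(ident$tolA_gene_ids, genes$gene_id[3])
  expect_equal(ident$tonB_gene_ids, genes$gene_id[6])
  expect_false(ident$tolA_ambiguous)
  # with no tolB/pal in the genome every transducer is a TonB candidate
  genes2 <- mk_genes(c(1000, 500000))
  roles2 <- mk_roles(genes2$gene_id, c("transducer", "transducer"))
  loci2 <- cluster_loci(genes2, roles2)
  ident2 <- assign_transducer_identity(genes2, roles2, loci2,
                                       classify_tolpal(loci2))
  expect_equal(ident2$tolA_gene_ids, character(0))
  expect_setequal(ident2$tonB_gene_ids, genes2$gene_id)
  # zero transducers: both lists empty
  x <- ecoli_like()
  roles3 <- x$roles[x$roles$role != "transducer", ]
  loci3 <- cluster_loci(x$genes, roles3)
  ident3 <- assign_transducer_identity(x$genes, roles3, loci3,
                                       classify_tolpal(loci3))
  expect_equal(ident3$tolA_gene_ids, character(0))
  expect_equal(ident3$tonB_gene_ids, character(0))
})

test_that("two transducers in one complete locus flag ambiguity, closest to tolB wins", {
  genes <- mk_genes(seq(1000, by = 1500, length.out = 6))
  roles <- mk_roles(genes$gene_id,
                    c("motor_pentamer", "motor_dimer", "transducer",
                      "transducer", "tolB", "pal"))
  loci <- cluster_loci(genes, roles)
  ident <- assign_transducer_identity(genes, roles, loci,
                                      classify_tolpal(loci))
  expect_true(ident$tolA_ambiguous)
  expect_equal(ident$tolA_gene_ids, genes$gene_id[4])  # adjacent to tolB
  expect_equal(ident$flagged_gene_ids, genes$gene_id[3])
  expect_equal(ident$tonB_gene_ids, character(0))
})

test_that("representative TonB is the first full three-domain candidate", {
  genes <- mk_genes(c(1000, 50000, 90000))
  genes$protein_length <- c(120L, 300L, 300L)
  profiles <- list(
    ss_profile(genes$gene_id[1], strrep("C", 120), tmh_span = c(5, 25)),
    ss_profile(genes$gene_id[2], strrep("C", 300), tmh_span = c(10, 30)),
    ss_profile(genes$gene_id[3], strrep("C", 300), tmh_span = c(10, 30)))
  names(profiles) <- genes$gene_id
  expect_equal(select_representative_tonb(genes$gene_id, genes, profiles),
               genes$gene_id[2])
  # all candidates without a TMH: none
  no_tmh <- lapply(profiles, function(p) ss_profile(p$gene_id, p$states))
  expect_true(is.na(select_representative_tonb(genes$gene_id, genes, no_tmh)))
  expect_equal(select_representative_tonb(genes$gene_id[3], genes, profiles),
               genes$gene_id[3])
  expect_true(is.na(select_representative_tonb(character(0), genes, profiles)))
})

test_that("cpoB presence and adjacency follow rank distance", {
  x <- ecoli_like()  # cpoB immediately downstream of pal
  adj <- cpob_adjacency(x$genes, x$roles)
  expect_true(adj$cpoB_present); expect_true(adj$cpoB_adjacent)
  # cpoB on another replicon: present but not adjacent
  genes <- rbind(mk_genes(c(1000, 2500)),
                 mk_genes(1000, replicon = "plasmid", genome = "q"))
  genes$genome_id <- "g"; genes$gene_id <- c("a", "b", "c")
  genes <- as_gene_table(genes)
  roles <- mk_roles(c("a", "b", "c"), c("tolB", "pal", "cpoB_tpr"))
  adj2 <- cpob_adjacency(genes, roles)
  expect_true(adj2$cpoB_present); expect_false(adj2$cpoB_adjacent)
  # no cpoB at all
  adj3 <- cpob_adjacency(genes, roles[roles$role != "cpoB_tpr", ])
  expect_false(adj3$cpoB_present); expect_false(adj3$cpoB_adjacent)
})

test_that("widening proximity thresholds only merges loci and promotes status", {
  for (seed in 1:20) {
    g <- generate_scatter_genome(n_genes = 40, seed = 1000 + seed)
    roles <- assign_roles(g$hits)
    narrow <- cluster_loci(g$genes, roles, max_intervening = 2,
                           max_gap_bp = 3000)
    wide <- cluster_loci(g$genes, roles, max_intervening = 6,
                         max_gap_bp = 9000)
    wide_sets <- loci_as_sets(wide)
    for (s in loci_as_sets(narrow)) {
      expect_true(any(vapply(wide_sets, function(w) all(s %in% w),
                             logical(1))))
    }
    expect_gte(status_rank(classify_tolpal(wide)$tolpal_status),
               status_rank(classify_tolpal(narrow)$tolpal_status))
  }
})
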