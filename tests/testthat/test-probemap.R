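test_that("hamming_matches handles exact, absent and planted placements", {
  hits <- hamming_matches("ACGT", "ACGTTT", max_mm = 0,
                          orientations = "forward")
  expect_equal(hits$offset, 0L)
  expect_equal(hits$orientation, "forward")
  expect_equal(hits$mismatches, 0L)

  expect_equal(nrow(hamming_matches("AAAA", "CCCCCC", max_mm = 2)), 0)

  # 24-mer planted at offset 100 with 2 substitutions in a 500-nt gene
  set.seed(11)
  gene <- rand_dna(500)
  probe <- substr(gene, 101, 124)
  v <- strsplit(probe, "")[[1]]
  for (p in c(3, 17)) v[p] <- setdiff(c("A", "C", "G", "T"), v[p])[1]
  probe <- paste(v, collapse = "")
  hits <- hamming_matches(probe, gene, max_mm = 2)
  expect_true(any(hits$offset == 100 & hits$orientation == "forward" &
                    hits$mismatches == 2))

  # reverse-complement of gene[11..34] is found at offset 10
  set.seed(12)
  gene <- rand_dna(60)
  probe <- rc_oracle(substr(gene, 11, 34))
  hits <- hamming_matches(probe, gene, max_mm = 0)
  expect_true(any(hits$offset == 10 & hits$orientation == "revcomp"))

  # probe longer than gene
  expect_equal(nrow(hamming_matches("ACGTACGT", "ACG", max_mm = 2)), 0)
})

test_that("hamming_matches rejects bad input and counts N as a mismatch", {
  expect_error(hamming_matches("AC!T", "ACGTACGT", 1), "'!'")
  expect_error(hamming_matches("ACGT", "ACG5ACGT", 1), "'5'")
  # N never matches, not even N against N
  expect_equal(hamming_matches("ANGT", "ANGT", max_mm = 0,
                               orientations = "forward")$offset,
               integer(0))
  hits <- hamming_matches("ANGT", "ANGT", max_mm = 1,
                          orientations = "forward")
  expect_equal(hits$mismatches, 1L)
})

test_that("hamming_matches agrees with a brute-force scan on random pairs", {
  set.seed(101)
  for (i in 1:200) {
    probe <- rand_dna(sample(6:20, 1))
    gene <- rand_dna(sample(30:120, 1))
    mm <- sample(0:3, 1)
    got <- as.data.frame(hamming_matches(probe, gene, max_mm = mm))
    want <- bf_matches(probe, gene, mm)
    got <- got[order(got$orientation, got$offset), ]
    want <- want[order(want$orientation, want$offset), ]
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want)
  }
})

test_that("hamming_matches agrees with Biostrings matchPattern forward scans", {
  set.seed(102)
  for (i in 1:25) {
    probe <- rand_dna(12)
    gene <- rand_dna(200)
    mm <- sample(0:2, 1)
    ours <- hamming_matches(probe, gene, max_mm = mm,
                            orientations = "forward")
    ref <- Biostrings::matchPattern(probe, Biostrings::DNAString(gene),
                                    max.mismatch = mm)
    expect_equal(sort(ours$offset), sort(BiocGenerics::start(ref) - 1L))
  }
})

test_that("map construction collapses placements and rejects duplicates", {
  # same probe placed twice in one gene -> one entry at minimal mismatches
  probe <- "ACGTACGTAC"
  gene <- paste0(probe, "TTTT", probe)
  map <- build_probe_gene_map(
    tibble::tibble(probe_id = "p1", sequence = probe), c(g1 = gene))
  expect_equal(nrow(map$hits), 1)
  expect_equal(map$hits$mismatches, 0L)
  expect_equal(map$hits$offset, 0L)

  expect_error(build_probe_gene_map(
    tibble::tibble(probe_id = c("p1", "p1"), sequence = c(probe, probe)),
    c(g1 = gene)), "duplicate probe_id")
  expect_error(build_probe_gene_map(
    tibble::tibble(probe_id = "p1", sequence = probe),
    c(g1 = gene, g1 = gene)), "duplicate gene_id")

  # no placements at all -> empty map
  empty <- build_probe_gene_map(
    tibble::tibble(probe_id = "p1", sequence = "AAAAAAAAAA"),
    c(g1 = paste(rep("C", 50), collapse = "")))
  expect_equal(nrow(empty$hits), 0)
})

test_that("planted multi-gene probes produce the expected map entries", {
  set.seed(21)
  core <- rand_dna(20)
  q <- rand_dna(20)
  mk_gene <- function(insert) {
    g <- rand_dna(120)
    substr(g, 51, 70) <- insert
    g
  }
  genes <- c(g1 = mk_gene(core), g2 = mk_gene(core), g3 = mk_gene(core),
             g4 = mk_gene(q))
  probes <- tibble::tibble(probe_id = c("P", "Q"), sequence = c(core, q))
  map <- build_probe_gene_map(probes, genes)
  # background could collide by chance with these short seeds; it does not
  expect_equal(nrow(map$hits), 4)
  expect_setequal(map$hits$gene_id[map$hits$probe_id == "P"],
                  c("g1", "g2", "g3"))
  expect_equal(map$hits$gene_id[map$hits$probe_id == "Q"], "g4")
})

test_that("map is invariant to input order and monotone in max_mm", {
  d <- gen_probe_design(n_genes = 4, probes_per_gene = 2, n_ambiguous = 2,
                        gene_length = 200, seed = 31)
  map <- build_probe_gene_map(d$probes, d$genes)
  perm_p <- d$probes[sample(nrow(d$probes)), ]
  perm_g <- d$genes[sample(length(d$genes))]
  map_perm <- build_probe_gene_map(perm_p, perm_g)
  expect_equal(map$hits, map_perm$hits)
  expect_equal(map$probe_ids, map_perm$probe_ids)

  pairs <- function(m) paste(m$hits$probe_id, m$hits$gene_id)
  for (mm in 0:2) {
    lo <- build_probe_gene_map(d$probes, d$genes, max_mm = mm)
    hi <- build_probe_gene_map(d$probes, d$genes, max_mm = mm + 1)
    expect_true(all(pairs(lo) %in% pairs(hi)))
  }
})

test_that("classification partitions probes and reports 1:n ratios", {
  d <- gen_probe_design(n_genes = 6, probes_per_gene = 2, n_ambiguous = 3,
                        ambiguity_degrees = c(2, 3, 6), gene_length = 400,
                        seed = 41)
  map <- build_probe_gene_map(d$probes, d$genes)
  cls <- classify_probes(map)
  expect_setequal(cls$unique, d$expected_unique)
  expect_equal(cls$ambiguous, d$expected_ambiguous)
  expect_setequal(as.integer(cls$ambiguous), c(2L, 3L, 6L))
  expect_setequal(unname(cls$ratios[names(cls$ambiguous)]),
                  c("1:2", "1:3", "1:6"))
  # partition invariant
  expect_equal(length(cls$unique) + length(cls$ambiguous) +
                 length(cls$unmapped), length(map$probe_ids))

  # empty map over 5 probes -> all unmapped
  probes <- tibble::tibble(probe_id = paste0("p", 1:5),
                           sequence = replicate(5, rand_dna(20)))
  empty <- build_probe_gene_map(probes,
                                c(g1 = paste(rep("A", 60), collapse = "")))
  cls0 <- classify_probes(empty)
  expect_equal(length(cls0$unmapped), 5)
  expect_equal(cls0$counts$mapped, 0)
})

test_that("probes_per_gene counts unique probes, with zero-filled genes", {
  d <- gen_probe_design(n_genes = 7, probes_per_gene = 2, n_ambiguous = 4,
                        gene_length = 400, seed = 51)
  map <- build_probe_gene_map(d$probes, d$genes)
  cls <- classify_probes(map)
  ppg <- probes_per_gene(map, cls, unique_only = TRUE)
  expect_equal(length(ppg), 7)
  # trailing 2 genes carry only ambiguous probes
  expect_equal(sum(ppg > 0), 5)
  # with unique_only = FALSE, counts equal gene degree in the map
  deg <- table(map$hits$gene_id)
  all_p <- probes_per_gene(map, unique_only = FALSE)
  expect_equal(all_p[names(deg)], setNames(as.integer(deg), names(deg)))
})
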