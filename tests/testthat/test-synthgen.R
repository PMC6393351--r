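test_that("gen_probe_design plants the requested ambiguity structure", {
  d <- gen_probe_design(n_genes = 5, probes_per_gene = 2, n_ambiguous = 0,
                        seed = 1)
  expect_equal(nrow(d$probes), 10)
  expect_equal(length(d$expected_unique), 10)
  expect_equal(length(d$expected_ambiguous), 0)

  d3 <- gen_probe_design(n_genes = 3, probes_per_gene = 1, n_ambiguous = 1,
                         ambiguity_degrees = 3, seed = 7)
  expect_equal(unname(d3$expected_ambiguous), 3L)
  expect_equal(length(d3$expected_ambiguous), 1)

  # every planted placement really sits in its gene within the stated
  # mismatch count
  for (i in seq_len(nrow(d3$planted))) {
    row <- d3$planted[i, ]
    seqs <- d3$probes$sequence[d3$probes$probe_id == row$probe_id]
    hits <- hamming_matches(seqs, d3$genes[[row$gene_id]], max_mm = 2)
    expect_true(min(hits$mismatches) == row$mismatches)
  }
})

test_that("gen_probe_design is seed-deterministic and validates input", {
  a <- gen_probe_design(n_genes = 4, probes_per_gene = 2, n_ambiguous = 1,
                        seed = 99)
  b <- gen_probe_design(n_genes = 4, probes_per_gene = 2, n_ambiguous = 1,
                        seed = 99)
  expect_identical(a, b)
  expect_error(gen_probe_design(n_genes = 2, probe_length = 100,
                                gene_length = 50), "impossible design")
  expect_error(gen_probe_design(n_genes = 2, probes_per_gene = 1,
                                n_ambiguous = 5), "exceeds")
})

test_that("planted truth is recovered by classification on random designs", {
  set.seed(71)
  for (i in 1:20) {
    n_genes <- sample(3:6, 1)
    ppg <- sample(1:3, 1)
    n_amb <- sample(0:min(3, n_genes * ppg), 1)
    d <- gen_probe_design(n_genes = n_genes, probes_per_gene = ppg,
                          n_ambiguous = n_amb,
                          gene_length = (ppg + n_amb + 1) * 30,
                          probe_length = 24, seed = 500 + i)
    cls <- classify_probes(build_probe_gene_map(d$probes, d$genes))
    expect_setequal(cls$unique, d$expected_unique)
    expect_equal(cls$ambiguous, d$expected_ambiguous)
  }
})

test_that("gen_expression plants recoverable hotspots deterministically", {
  d <- gen_probe_design(n_genes = 8, probes_per_gene = 1, n_ambiguous = 0,
                        gene_length = 120, seed = 5)
  samples <- paste0("s", 1:6)
  expect_error(gen_expression(d, character(0)), "empty")

  # effect 0 -> no hotspot recorded
  e0 <- gen_expression(d, samples,
                       hotspot = list(samples = samples[1:2],
                                      genes = names(d$genes)[1:2],
                                      effect = 0), seed = 2)
  expect_null(e0$hotspot)

  e1 <- gen_expression(d, samples, seed = 3)
  e2 <- gen_expression(d, samples, seed = 3)
  expect_identical(e1$expr, e2$expr)
  expect_equal(dim(e1$expr), c(8, 6))
})

test_that("a planted block is recovered exactly by detect_hotspots", {
  d <- gen_probe_design(n_genes = 20, probes_per_gene = 4, n_ambiguous = 0,
                        gene_length = 240, probe_length = 24, seed = 42)
  map <- build_probe_gene_map(d$probes, d$genes)
  cls <- classify_probes(map)
  samples <- sprintf("S%02d", 1:24)
  hot <- list(genes = names(d$genes)[3:7], samples = samples[c(2, 5, 9, 13, 20)],
              effect = 3)
  es <- gen_expression(d, samples, hotspot = hot, seed = 77)
  ge <- summarize_by_gene(es$expr, cls, map)
  rep <- detect_hotspots(ge$matrix)
  expect_gte(length(rep$blocks), 1)
  expect_equal(rep$blocks[[1]]$genes, sort(hot$genes))
  expect_equal(rep$blocks[[1]]$samples, sort(hot$samples))
})

test_that("gen_volatile_study is exact at zero noise and round-trips", {
  des <- default_volatile_design(sigma = 0)
  st <- gen_volatile_study(des)
  expect_equal(nrow(st$concentrations), 3 * 2 * 4 * 12)
  expect_equal(length(unique(st$concentrations$sample_id)), 24)
  expect_equal(length(unique(st$concentrations$compound)), 12)

  means <- des$means
  joined <- merge(st$concentrations, means,
                  by = c("cultivar", "stage", "compound"))
  expect_equal(joined$concentration, joined$mean)

  conc <- quantify(st$peaks, st$curves,
                   fallback = st$curves[["(+)-valencene"]])
  truth <- st$concentrations
  expect_equal(conc$concentration, truth$concentration, tolerance = 1e-12)

  # semi-quantitation flags: only the four authentic standards are direct
  expect_setequal(unique(conc$compound[conc$mode == "standard"]),
                  c("β-caryophyllene", "α-humulene", "(E)-β-farnesene",
                    "(+)-valencene"))
})

test_that("gen_volatile_study is seed-deterministic and validates sigma", {
  s1 <- gen_volatile_study(default_volatile_design(sigma = 0.2, seed = 4))
  s2 <- gen_volatile_study(default_volatile_design(sigma = 0.2, seed = 4))
  expect_identical(s1$concentrations, s2$concentrations)
  expect_identical(s1$peaks, s2$peaks)
  expect_error(default_volatile_design(sigma = -0.1), "sigma")
  expect_error(default_volatile_design(replicates = 0), "replicates")
})
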