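make_summarized <- function() {
  d <- gen_probe_design(n_genes = 6, probes_per_gene = 2, n_ambiguous = 2,
                        gene_length = 300, seed = 13)
  map <- build_probe_gene_map(d$probes, d$genes)
  cls <- classify_probes(map)
  list(design = d, map = map, cls = cls)
}

test_that("summarize_by_gene averages unique probes and drops the rest", {
  f <- make_summarized()
  samples <- paste0("s", 1:3)
  expr <- matrix(0, nrow(f$design$probes), 3,
                 dimnames = list(f$design$probes$probe_id, samples))

  # hand-set two unique probes of one gene to 4 and 6 -> mean 5
  g <- f$map$hits$gene_id[f$map$hits$probe_id %in% f$cls$unique][1]
  gp <- intersect(f$map$hits$probe_id[f$map$hits$gene_id == g],
                  f$cls$unique)
  expect_gte(length(gp), 2)
  expr[gp[1], ] <- 4
  expr[gp[2], ] <- 6
  ge <- summarize_by_gene(expr, f$cls, f$map)
  expect_equal(unname(ge$matrix[g, ]), rep(5, 3))

  # single-probe gene equals its probe row (identity)
  d1 <- gen_probe_design(n_genes = 3, probes_per_gene = 1, n_ambiguous = 0,
                         gene_length = 120, seed = 14)
  m1 <- build_probe_gene_map(d1$probes, d1$genes)
  c1 <- classify_probes(m1)
  e1 <- matrix(rnorm(9), 3, 3, dimnames = list(d1$probes$probe_id,
                                               paste0("s", 1:3)))
  ge1 <- summarize_by_gene(e1, c1, m1)
  for (g in rownames(ge1$matrix)) {
    p <- ge1$provenance[[g]]
    expect_equal(unname(ge1$matrix[g, ]), unname(e1[p, ]))
  }

  # ambiguous-only genes are dropped
  expect_equal(length(ge$dropped_genes),
               sum(probes_per_gene(f$map, f$cls) == 0))
  expect_equal(nrow(ge$matrix) + length(ge$dropped_genes),
               length(f$map$gene_ids))
})

test_that("summarize_by_gene rejects probes missing from the classification", {
  f <- make_summarized()
  expr <- matrix(0, 2, 2, dimnames = list(c("alien1", "alien2"),
                                          c("s1", "s2")))
  expect_error(summarize_by_gene(expr, f$cls, f$map), "alien1")
})

test_that("retained genes equal genes minus ambiguous-only genes (planted)", {
  # mirrors a 49-model family where 14 models carry only ambiguous probes
  d <- gen_probe_design(n_genes = 49, probes_per_gene = 2, n_ambiguous = 28,
                        gene_length = 720, probe_length = 24, seed = 2024)
  map <- build_probe_gene_map(d$probes, d$genes)
  cls <- classify_probes(map)
  samples <- paste0("s", 1:4)
  es <- gen_expression(d, samples, seed = 8)
  ge <- summarize_by_gene(es$expr, cls, map)
  expect_equal(nrow(ge$matrix), 35)
  expect_equal(length(ge$dropped_genes), 14)
})

test_that("cluster_expression is deterministic and hand-checkable", {
  # two identical rows merge first at distance 0
  m <- rbind(a = c(1, 2, 3), b = c(1, 2, 3), c = c(9, 9, 9))
  cl <- cluster_expression(m, axis = "rows")
  expect_equal(sort(cl$row_hclust$height)[1], 0)

  # 1-D points {0, 1, 10, 11}: average linkage pairs {0,1} and {10,11}
  m2 <- matrix(c(0, 1, 10, 11), ncol = 1,
               dimnames = list(c("p0", "p1", "p10", "p11"), "x"))
  cl2 <- cluster_expression(cbind(m2, m2), axis = "rows")
  k2 <- cutree(cl2$row_hclust, k = 2)
  expect_equal(unname(k2["p0"]), unname(k2["p1"]))
  expect_equal(unname(k2["p10"]), unname(k2["p11"]))
  expect_false(k2[["p0"]] == k2[["p10"]])
  # heights are hand-computable for euclidean average linkage on the
  # duplicated coordinate: sqrt(2) * {1, 1, mean(10, 11, 9, 10)}
  expect_equal(sort(cl2$row_hclust$height),
               sqrt(2) * c(1, 1, 10), tolerance = 1e-12)

  # permuting rows leaves heights identical
  set.seed(3)
  m3 <- matrix(rnorm(40), 8, 5,
               dimnames = list(paste0("g", 1:8), paste0("s", 1:5)))
  cl3 <- cluster_expression(m3)
  cl3p <- cluster_expression(m3[sample(8), sample(5)])
  expect_equal(sort(cl3$row_hclust$height), sort(cl3p$row_hclust$height))
  expect_equal(sort(cl3$col_hclust$height), sort(cl3p$col_hclust$height))
})

test_that("cluster_expression rejects constant rows under correlation", {
  m <- rbind(flat = c(1, 1, 1, 1), wavy = c(1, 2, 1, 2),
             up = c(1, 2, 3, 4))
  expect_error(cluster_expression(m, axis = "rows", metric = "correlation"),
               "flat")
  expect_silent(cluster_expression(m, axis = "rows", metric = "euclidean"))
})

test_that("detect_hotspots finds nothing in flat data and is monotone", {
  flat <- matrix(7, 5, 5)
  expect_equal(length(detect_hotspots(flat)$blocks), 0)

  set.seed(9)
  m <- matrix(rnorm(20 * 10), 20, 10)
  m[1:4, 1:3] <- m[1:4, 1:3] + 4
  n_blocks <- vapply(c(0.5, 1, 1.5, 2.5, 4),
                     function(t) length(detect_hotspots(m, z_threshold = t)$blocks),
                     integer(1))
  expect_true(all(diff(n_blocks) <= 0))
})

test_that("detect_hotspots at threshold 0 reports a block for noisy data", {
  set.seed(10)
  for (i in 1:10) {
    m <- matrix(rnorm(60), 10, 6)
    rep <- detect_hotspots(m, z_threshold = 0, min_genes = 1,
                           min_samples = 1)
    expect_gte(length(rep$blocks), 1)
  }
})
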