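test_that("read_gmt parses, dedupes and rejects malformed lines", {
  p <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("SETA\td\tG1\tG2", "SETB\td\tG1\tG1"), p)
  gs <- read_gmt(p)
  expect_setequal(gs$SETA, c("G1", "G2"))
  expect_equal(gs$SETB, "G1")

  p2 <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("SETA\td\tG1", "BAD\tonly2"), p2)
  expect_error(read_gmt(p2), "line 2")

  # round trip preserves membership
  p3 <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(gs, p3)
  expect_equal(read_gmt(p3)[], gs[])
})

test_that("enrichment_score matches hand cases and the running-sum oracle", {
  stats <- setNames(c(3, 2, 1, 0.5), c("A", "B", "C", "D"))
  es <- enrichment_score(stats, "A", p_weight = 0)
  expect_equal(es$es, 1)                          # running: 1, 2/3, 1/3, 0
  expect_equal(es$running, c(1, 2 / 3, 1 / 3, 0))
  expect_equal(es$leading_edge, "A")

  # bottom-of-list set has negative ES
  expect_lt(enrichment_score(stats, c("C", "D"), p_weight = 0)$es, 0)

  # random instances vs the literal running-sum oracle
  for (s in 1:10) {
    set.seed(s)
    st <- setNames(sort(rnorm(300), decreasing = TRUE),
                   sprintf("g%03d", sample(300)))
    set_genes <- sample(names(st), 25)
    got <- enrichment_score(st, set_genes, p_weight = 1)$es
    want <- gsea_es_oracle(as.numeric(st), names(st), set_genes, 1)
    expect_equal(got, want, tolerance = 1e-12)
  }
  expect_error(enrichment_score(stats, letters, p_weight = 1), "intersect")
  expect_error(enrichment_score(stats, names(stats), 1), "universe")
})

test_that("ES invariances: scale invariance at p=0 and exact reversal antisymmetry", {
  set.seed(5)
  st <- setNames(sort(rnorm(200), decreasing = TRUE), sprintf("g%03d", 1:200))
  set_genes <- sample(names(st), 15)
  e1 <- enrichment_score(st, set_genes, p_weight = 0)$es
  expect_identical(enrichment_score(st * 7, set_genes, p_weight = 0)$es, e1)
  rev_st <- rev(st)
  e_rev <- enrichment_score(rev_st, set_genes, p_weight = 0)$es
  expect_equal(e_rev, -e1, tolerance = 1e-12)
})

test_that("gsea_preranked filters by size, calibrates p, and recovers planted sets", {
  a <- gen_atlas(c(14, 14, 14), 83, seed = 71)
  set.seed(72)
  y <- as.numeric(scale(a$centroids[, 1])) + rnorm(83, 0, 0.3)
  ph <- regional_phenotype(1:83, y)
  coup <- c(setNames(rep(0.8, 30), sprintf("POS%02d", 1:30)),
            setNames(rep(-0.8, 30), sprintf("NEG%02d", 1:30)))
  ex <- gen_expression(a, ph, 1000, coup, 5, seed = 73)
  su <- generate_surrogates(ph, a$centroids, 100, seed = 74)
  rk <- gene_z_scores(ex$expression, y, su)
  gs <- gen_genesets(ex$truth, n_decoys = 30, seed = 75)

  res <- gsea_preranked(rk, gs, n_perm = 300, seed = 76)
  expect_true(all(res$size >= 10 & res$size <= 500))
  expect_true(all(sign(res$nes) == sign(res$es), na.rm = TRUE))
  expect_true(all(res$pval >= 1 / 301))
  pp <- res[res$set == "planted_positive", ]
  pn <- res[res$set == "planted_negative", ]
  expect_gt(pp$nes, 0); expect_lt(pp$padj, 0.05)
  expect_lt(pn$nes, 0); expect_lt(pn$padj, 0.05)
  # leading edges are dominated by the planted genes
  expect_gt(mean(grepl("POS", pp$leading_edge[[1]])), 0.9)

  # a tiny set is excluded by min_size
  gs2 <- structure(c(gs, list(tiny = gs$planted_positive[1:2])),
                   class = "gene_set_collection")
  res2 <- gsea_preranked(rk, gs2, n_perm = 100, seed = 77)
  expect_false("tiny" %in% res2$set)

  expect_warning(gsea_preranked(rk, structure(list(s = "POS01"),
                                              class = "gene_set_collection"),
                                100, 1, min_size = 10),
                 "no gene set")
})

test_that("gsea results agree with an independent implementation on ES", {
  skip_if_not_installed("fgsea")
  set.seed(8)
  st <- setNames(sort(rnorm(500), decreasing = TRUE), sprintf("g%03d", 1:500))
  sets <- lapply(1:10, function(i) sample(names(st), sample(15:40, 1)))
  names(sets) <- paste0("S", 1:10)
  got <- vapply(sets, function(s)
    enrichment_score(st, s, p_weight = 1)$es, numeric(1))
  ref <- vapply(sets, function(s)
    fgsea::calcGseaStat(st, selectedStats = which(names(st) %in% s),
                        gseaParam = 1), numeric(1))
  expect_equal(got, ref, tolerance = 1e-10)
})

test_that("prune_redundant keeps the most significant of overlapping sets", {
  coll <- structure(list(A = letters[1:10], B = letters[1:10],
                         C = letters[15:24]),
                    class = "gene_set_collection")
  res <- data.frame(set = c("A", "B", "C"), size = 10L,
                    es = c(0.9, 0.8, 0.5), nes = c(2.5, 2.2, 1.1),
                    pval = c(0.001, 0.002, 0.04), padj = c(0.01, 0.01, 0.1))
  res$leading_edge <- list(letters[1:3], letters[1:3], letters[15:16])
  class(res) <- c("enrichment_result", "data.frame")
  pr <- prune_redundant(res, coll, 0.7)
  expect_setequal(pr$set, c("A", "C"))        # duplicate B dropped
  pr2 <- prune_redundant(res, coll, 1)
  expect_equal(nrow(pr2), 3)                  # threshold 1: keep everything
  expect_error(prune_redundant(res, coll, 1.2), "jaccard")
})
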