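toy_gsm <- function() {
  gene_set_map(list(`GO:A` = paste0("g", 1:5),
                    `GO:B` = paste0("g", 6:10),
                    `GO:C` = paste0("g", c(1, 6, 11, 16))),
               universe = paste0("g", 1:20))
}

test_that("enrichment p-values are hypergeometric upper tails", {
  gsm <- toy_gsm()
  # selected exactly the 5-gene term: single most extreme table
  res <- enrich(paste0("g", 1:5), gsm)
  top <- res[res$term_id == "GO:A", ]
  expect_equal(top$p, 1 / choose(20, 5), tolerance = 1e-12)
  expect_identical(c(top$k, top$K, top$n, top$N), c(5L, 5L, 5L, 20L))
  expect_identical(res$term_id[1], "GO:A")          # ranked by padj

  empty <- enrich(character(), gsm)
  expect_true(all(empty$p == 1))
  expect_true(all(empty$k == 0))

  expect_error(enrich(c("g1", "nope"), gsm), "outside the universe")

  # oracle agreement on random triples
  set.seed(83)
  for (r in 1:40) {
    N <- sample(15:60, 1)
    universe <- paste0("u", seq_len(N))
    term <- sample(universe, sample(3:10, 1))
    gsm_r <- gene_set_map(list(T1 = term), universe)
    selected <- sample(universe, sample(0:12, 1))
    res <- enrich(selected, gsm_r)
    expect_equal(res$p[1],
                 hyper_tail_brute(length(intersect(selected, term)),
                                  length(term), length(selected), N),
                 tolerance = 1e-10)
  }
})

test_that("adding out-of-term genes to the selection never decreases a term's p", {
  gsm <- toy_gsm()
  s1 <- paste0("g", 1:3)                            # inside GO:A
  s2 <- c(s1, paste0("g", 11:14))                   # plus out-of-term genes
  p1 <- enrich(s1, gsm); p2 <- enrich(s2, gsm)
  pa1 <- p1$p[p1$term_id == "GO:A"]
  pa2 <- p2$p[p2$term_id == "GO:A"]
  expect_gte(pa2, pa1)
})

test_that("restrict_universe re-homes the background and term sets", {
  gsm <- toy_gsm()
  small <- suppressMessages(restrict_universe(gsm, paste0("g", 1:8)))
  expect_identical(small$universe, paste0("g", 1:8))
  expect_identical(small$sets[["GO:B"]], paste0("g", 6:8))
  expect_setequal(names(small$sets), c("GO:A", "GO:B", "GO:C"))
})

test_that("direct GO selects DE mRNAs of the requested direction", {
  gsm <- toy_gsm()
  de <- data.frame(gene_id = paste0("g", 1:10),
                   biotype = c(rep("mRNA", 8), "lncRNA", "lncRNA"),
                   log2fc = c(rep(2, 4), rep(-2, 4), 2, 2),
                   direction = c(rep("up", 4), rep("down", 4), "up", "up"),
                   stringsAsFactors = FALSE)
  both <- direct_go(de, gsm)
  expect_identical(both$n[1], 8L)                   # lncRNAs excluded
  up <- direct_go(de, gsm, direction = "up")
  expect_identical(up$n[1], 4L)
  # selected = universe gives no contrast: every p is 1
  de_all <- data.frame(gene_id = paste0("g", 1:20), biotype = "mRNA",
                       log2fc = 2, direction = "up", stringsAsFactors = FALSE)
  expect_true(all(direct_go(de_all, gsm)$p == 1))
  # empty DE set
  de_none <- de; de_none$direction <- "ns"
  expect_true(all(direct_go(de_none, gsm)$k == 0))
})

test_that("indirect GO ranks targets by best edge and honours top_k and semantics", {
  gsm <- toy_gsm()
  edges <- data.frame(
    regulator_id = c("l1", "l1", "m1", "m1", "l2"),
    regulator_biotype = c("lncRNA", "lncRNA", "miRNA", "miRNA", "lncRNA"),
    target_id = c("g1", "g2", "g1", "g3", "g4"),
    a = 1, se_a = 0.1, p = c(1e-5, 1e-3, 1e-4, 2e-3, 0.2),
    padj = c(1e-4, 1e-2, 1e-3, 2e-2, 0.6),
    sign = "positive", stringsAsFactors = FALSE)
  res <- indirect_go(c("l1", "l2", "m1"), edges, gsm)
  expect_identical(res$n[1], 3L)                    # g1, g2, g3 (g4 edge not significant)
  res_k1 <- indirect_go(c("l1", "l2", "m1"), edges, gsm, top_k = 1)
  expect_identical(res_k1$n[1], 1L)                 # only g1, the best-ranked
  expect_true(all(res_k1$k <= 1L))
  # intersection semantics: a target needs both a lncRNA and a miRNA edge
  res_int <- indirect_go(c("l1", "l2", "m1"), edges, gsm,
                         semantics = "intersection")
  expect_identical(res_int$n[1], 1L)                # only g1 has both
  # regulator set with no significant edges
  expect_message(res0 <- indirect_go("l2", edges[5, ], gsm), "no significant")
  expect_true(all(res0$k == 0))
})
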