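test_that("proliferation removal is set difference with guards", {
  expect_no_warning(out <- remove_proliferation(c("a", "b", "c"), "b"))
  expect_equal(out, c("a", "c"))
  expect_warning(remove_proliferation(c("a", "b"), character(0)),
                 "no proliferation")
  expect_warning(remove_proliferation(c("a", "b"), c("b", "zz")), "not found")
  expect_error(suppressWarnings(remove_proliferation(c("a", "b"), c("a", "b"))),
               "empty")
})

test_that("removal set fans out through shared terms", {
  map <- three_gene_map()
  rs <- removal_set(map, signature("gA"))
  expect_equal(rs$terms, "T1")
  expect_equal(rs$genes, c("gA", "gB"))
  expect_warning(rs0 <- removal_set(map, signature("unannotated1")),
                 "no BP annotation")
  expect_equal(rs0$terms, character(0))
  expect_equal(rs0$genes, character(0))
})

test_that("removal set matches brute force on random instances", {
  withr::local_seed(99)
  for (i in 1:15) {
    inst <- rand_annotation(sample(10:60, 1), sample(3:15, 1), p = 0.1)
    bm <- sample(inst$genes, 4)
    rs <- suppressWarnings(removal_set(inst$map, signature(bm)))
    expect_equal(rs$genes, bf_removal_genes(inst$pairs, bm))
    # annotated signature genes always land in D
    annotated_bm <- intersect(bm, unique(inst$pairs$gene))
    expect_true(all(annotated_bm %in% rs$genes))
  }
})

test_that("the three removal regimes produce the documented pools", {
  map <- three_gene_map()
  pool <- c("gA", "gB", "gC")
  strong <- eligible_pool(pool, map = map, bm = signature("gA"), mode = "strong")
  expect_equal(strong$eligible, "gC")
  weak2 <- eligible_pool(pool, map = map, bm = signature("gA"), mode = "weak_ii")
  expect_equal(weak2$eligible, c("gB", "gC"))
  weak1 <- eligible_pool(pool, map = map, bm = signature("gA"), mode = "weak_i")
  expect_equal(weak1$eligible, pool)
  expect_equal(unname(strong$provenance[["n_eligible"]]), 1)
  expect_s3_class(tidy(strong), "tbl_df")
  expect_equal(glance(strong)$n_eligible, 1)
})

test_that("regimes nest and the strong pool is GO-disjoint from the signature", {
  withr::local_seed(123)
  for (i in 1:10) {
    inst <- rand_annotation(200, 12, p = 0.04)
    bm <- signature(sample(inst$genes, 6))
    pools <- lapply(c("strong", "weak_ii", "weak_i"), function(m) {
      suppressWarnings(eligible_pool(inst$genes, map = inst$map, bm = bm,
                                     mode = m))$eligible
    })
    expect_true(all(pools[[1]] %in% pools[[2]]))
    expect_true(all(pools[[2]] %in% pools[[3]]))
    # every strong-eligible gene satisfies empty common meaning with BM
    for (g in pools[[1]]) {
      expect_length(common_meaning(inst$map, g, bm$genes), 0)
    }
    # and no signature gene survives strong removal
    expect_length(intersect(pools[[1]], bm$genes), 0)
  }
})

test_that("ancestor propagation never enlarges the strong pool", {
  withr::local_seed(5)
  inst <- rand_annotation(100, 6, p = 0.08)
  onto <- tibble::tibble(child = c("tt002", "tt003", "tt004"),
                         parent = c("tt001", "tt001", "tt002"))
  bm <- signature(sample(unique(inst$pairs$gene), 4))
  plain <- suppressWarnings(
    eligible_pool(inst$genes, map = inst$map, bm = bm, mode = "strong"))
  prop <- suppressWarnings(
    eligible_pool(inst$genes, map = propagate_ancestors(inst$map, onto),
                  bm = bm, mode = "strong"))
  expect_true(all(prop$eligible %in% plain$eligible))
})

test_that("a pool smaller than the signature is rejected", {
  map <- three_gene_map()
  expect_error(
    eligible_pool(c("gA", "gB"), map = map, bm = signature(c("gA", "gB")),
                  mode = "strong"),
    "smaller than signature")
})
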