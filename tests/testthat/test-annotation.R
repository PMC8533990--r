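test_that("TSV annotation parsing builds a consistent two-way map", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# comment",
               "gA\tGO:0000001",
               "gA\tGO:0000002",
               "gA\tGO:0000001",   # duplicate collapses
               "gB\tGO:0000002"), path)
  map <- read_annotation(path, format = "tsv")
  expect_equal(meaning_of_gene(map, "gA"), c("GO:0000001", "GO:0000002"))
  expect_equal(meaning_of_gene(map, "gB"), "GO:0000002")
  expect_equal(genes_of_term(map, "GO:0000002"), c("gA", "gB"))
  expect_equal(nrow(map), 3L)  # set semantics
  # transpose consistency over every pair
  for (g in unique(map$gene)) {
    for (t in meaning_of_gene(map, g)) {
      expect_true(g %in% genes_of_term(map, t))
    }
  }
})

test_that("malformed and empty annotation files are rejected with locations", {
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gA\tGO:0000001", "gB\tGO:12"), bad)
  expect_error(read_annotation(bad, format = "tsv"), "line 2.*GO:12")
  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines(character(0), empty)
  expect_error(read_annotation(empty), "empty")
})

gaf_row <- function(gene, term, aspect = "P", qualifier = "", evidence = "EXP") {
  paste(c("DB", paste0("ID_", gene), gene, qualifier, term, "REF", evidence,
          "", aspect, rep("", 8)), collapse = "\t")
}

test_that("GAF parsing keeps only BP rows and drops NOT qualifiers", {
  path <- withr::local_tempfile(fileext = ".gaf")
  writeLines(c("!gaf-version: 2.2",
               gaf_row("gA", "GO:0000001"),
               gaf_row("gA", "GO:0000009", aspect = "F"),
               gaf_row("gB", "GO:0000002", qualifier = "NOT|involved_in"),
               gaf_row("gB", "GO:0000003", evidence = "IEA")), path)
  map <- read_annotation(path)  # auto-detected as GAF
  expect_equal(meaning_of_gene(map, "gA"), "GO:0000001")
  expect_equal(meaning_of_gene(map, "gB"), "GO:0000003")  # NOT row dropped
  map2 <- read_annotation(path, format = "gaf", exclude_iea = TRUE)
  expect_equal(meaning_of_gene(map2, "gB"), character(0))
})

test_that("meaning algebra: lookups, unions, intersections", {
  map <- three_gene_map()
  expect_equal(meaning_of_gene(map, "gA"), "T1")
  expect_equal(meaning_of_gene(map, "unseen"), character(0))
  expect_equal(meaning_of_gene(map, "gA"), meaning_of_gene(map, "gA"))  # purity
  expect_equal(meaning_of_set(map, c("gA", "gC")), c("T1", "T2"))
  expect_equal(meaning_of_set(map, character(0)), character(0))
  expect_equal(common_meaning(map, c("gA", "gB"), c("gA", "gB")),
               meaning_of_set(map, c("gA", "gB")))  # idempotence
  expect_equal(common_meaning(map, "gA", "gC"), character(0))  # disjoint
})

test_that("meaning algebra matches brute force on random maps", {
  withr::local_seed(42)
  for (i in 1:20) {
    inst <- rand_annotation(sample(5:50, 1), sample(3:20, 1), p = 0.15)
    s1 <- sample(inst$genes, sample.int(length(inst$genes), 1))
    s2 <- sample(inst$genes, sample.int(length(inst$genes), 1))
    expect_equal(meaning_of_set(inst$map, s1), bf_meaning(inst$pairs, s1))
    # distributivity over union
    expect_equal(meaning_of_set(inst$map, union(s1, s2)),
                 sort(union(meaning_of_set(inst$map, s1),
                            meaning_of_set(inst$map, s2))))
    # symmetry and brute-force intersection
    expect_equal(common_meaning(inst$map, s1, s2),
                 common_meaning(inst$map, s2, s1))
    expect_equal(common_meaning(inst$map, s1, s2),
                 sort(intersect(bf_meaning(inst$pairs, s1),
                                bf_meaning(inst$pairs, s2))))
    # bounded above by each argument's meaning
    expect_true(all(common_meaning(inst$map, s1, s2) %in%
                      meaning_of_set(inst$map, s1)))
  }
})

test_that("ancestor propagation closes term sets, excludes root, keeps monotonicity", {
  onto <- tibble::tibble(
    child  = c("GO:0000004", "GO:0000004", "GO:0000002", "GO:0000003",
               "GO:0000001"),
    parent = c("GO:0000002", "GO:0000003", "GO:0000001", "GO:0000001",
               "GO:0008150")
  )
  # diamond: 4 -> {2,3} -> 1 -> root
  map <- annotation_map(tibble::tibble(gene = "gA", term = "GO:0000004"))
  prop <- propagate_ancestors(map, onto)
  expect_true(attr(prop, "propagated"))
  expect_equal(meaning_of_gene(prop, "gA"),
               c("GO:0000001", "GO:0000002", "GO:0000003", "GO:0000004"))
  # term with no parent below root unchanged
  map2 <- annotation_map(tibble::tibble(gene = "gB", term = "GO:0000001"))
  expect_equal(meaning_of_gene(propagate_ancestors(map2, onto), "gB"),
               "GO:0000001")
  # monotonicity on a random instance
  withr::local_seed(7)
  inst <- rand_annotation(20, 4, p = 0.3)
  onto2 <- tibble::tibble(child = c("tt002", "tt003"), parent = c("tt001", "tt002"))
  prop2 <- propagate_ancestors(inst$map, onto2)
  for (g in unique(inst$map$gene)) {
    expect_true(all(meaning_of_gene(inst$map, g) %in% meaning_of_gene(prop2, g)))
  }
})

test_that("cyclic ontologies are rejected", {
  map <- annotation_map(tibble::tibble(gene = "gA", term = "GO:0000001"))
  cyc <- tibble::tibble(child = c("GO:0000001", "GO:0000002"),
                        parent = c("GO:0000002", "GO:0000001"))
  expect_error(propagate_ancestors(map, cyc), "cycle")
})

test_that("OBO parsing extracts is_a and part_of edges, skips obsolete terms", {
  path <- withr::local_tempfile(fileext = ".obo")
  writeLines(c("format-version: 1.4", "",
               "[Term]", "id: GO:0000002", "name: child",
               "is_a: GO:0000001 ! parent",
               "relationship: part_of GO:0000003 ! host", "",
               "[Term]", "id: GO:0000009", "name: gone",
               "is_obsolete: true", "is_a: GO:0000001", "",
               "[Typedef]", "id: part_of"), path)
  edges <- read_obo(path)
  expect_equal(nrow(edges), 2L)
  expect_setequal(edges$parent, c("GO:0000001", "GO:0000003"))
  expect_false("GO:0000009" %in% edges$child)
})
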