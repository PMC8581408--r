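test_that("hypergeometric p equals exhaustive enumeration on small universes", {
  set.seed(301)
  for (rep in 1:20) {
    N <- sample(6:12, 1)
    universe <- sprintf("g%02d", seq_len(N))
    set <- sample(universe, sample(2:(N - 1), 1))
    query <- sample(universe, sample(1:(N - 1), 1))
    col <- gene_set_collection(list(s1 = set))
    tab <- ora(query, universe, col, min_size = 1L, max_size = N)
    expect_equal(tab$pvalue, hyper_enum_oracle(universe, set, query),
                 tolerance = 1e-12)
  }
})

test_that("a query equal to the universe overlaps every set fully with p = 1", {
  universe <- sprintf("g%02d", 1:20)
  col <- gene_set_collection(list(a = universe[1:5], b = universe[3:12]))
  tab <- ora(universe, universe, col, min_size = 1L, max_size = 20L)
  expect_equal(tab$k, tab$K)
  expect_equal(tab$pvalue, rep(1, 2))
})

test_that("a fully captured 9-gene set reports k = K = 9", {
  members <- c("Apcdd1", "Arhgef7", "Ccl2", "Ccl3", "Ccl12", "Ccr2",
               "Gpr183", "Hexb", "Scrib")
  universe <- c(members, sprintf("x%02d", 1:91))
  col <- gene_set_collection(list(`Astrocyte Cell Migration` = members))
  tab <- ora(members, universe, col, min_size = 1L, max_size = 100L)
  expect_equal(tab$k, 9L)
  expect_equal(tab$K, 9L)
  expect_lt(tab$pvalue, 1e-10)
})

test_that("queries outside the universe and empty queries are handled", {
  universe <- sprintf("g%02d", 1:10)
  col <- gene_set_collection(list(a = universe[1:4]))
  expect_error(ora(c("g01", "zz"), universe, col), "outside the universe")
  expect_warning(tab <- ora(character(), universe, col), "empty query")
  expect_equal(nrow(tab), 0L)
})

test_that("set-size bounds are applied after universe intersection", {
  universe <- sprintf("g%02d", 1:30)
  col <- gene_set_collection(list(
    small = universe[1:3],
    ok = universe[1:12],
    outside = c(universe[1:8], sprintf("z%02d", 1:20)))) # 8 after intersection
  tab <- ora(universe[1:6], universe, col, min_size = 10L, max_size = 500L)
  expect_equal(tab$set, "ok")
})

test_that("ORA p values are invariant to a consistent relabeling", {
  universe <- sprintf("g%02d", 1:15)
  set <- universe[2:8]
  query <- universe[c(1, 3, 5, 8, 11)]
  p1 <- ora(query, universe, gene_set_collection(list(s = set)),
            min_size = 1L, max_size = 15L)$pvalue
  relab <- setNames(sprintf("R%02d", 15:1), universe)
  p2 <- ora(relab[query], relab[universe],
            gene_set_collection(list(s = unname(relab[set]))),
            min_size = 1L, max_size = 15L)$pvalue
  expect_equal(p1, p2)
})

test_that("adding an in-set gene to the query cannot raise that set's p", {
  universe <- sprintf("g%02d", 1:12)
  set <- universe[1:5]
  col <- gene_set_collection(list(s = set))
  query <- universe[c(1, 2, 7, 9)]
  p_before <- ora(query, universe, col, min_size = 1L, max_size = 12L)$pvalue
  p_after <- ora(c(query, "g03"), universe, col, min_size = 1L,
                 max_size = 12L)$pvalue
  expect_lte(p_after, p_before)
  # and both agree with enumeration
  expect_equal(p_after, hyper_enum_oracle(universe, set, c(query, "g03")),
               tolerance = 1e-12)
})

test_that("redundancy pruning keeps the more significant of identical sets", {
  universe <- sprintf("g%02d", 1:40)
  members <- universe[1:12]
  col <- gene_set_collection(list(dup1 = members, dup2 = members,
                                  other = universe[25:36]))
  query <- universe[c(1:8, 25:27)]
  tab <- ora(query, universe, col, min_size = 5L, max_size = 40L)
  pruned <- prune_redundant(tab, col, jaccard_threshold = 0.7)
  expect_length(intersect(pruned$set, c("dup1", "dup2")), 1L)
  expect_true("other" %in% pruned$set)
  # threshold 1 prunes only exact duplicates
  pruned1 <- prune_redundant(tab, col, jaccard_threshold = 1)
  expect_length(intersect(pruned1$set, c("dup1", "dup2")), 1L)
})

test_that("pruning at a 0.7 threshold matches hand enumeration on a fixture", {
  universe <- sprintf("g%02d", 1:30)
  col <- gene_set_collection(list(
    A = universe[1:10],            # kept (most significant, forced below)
    B = universe[1:9],             # Jaccard with A = 9/10 = 0.9 -> pruned
    C = universe[c(1:5, 11:15)],   # Jaccard with A = 5/15 = 0.33 -> kept
    D = universe[c(1:5, 11:14)],   # with C = 9/11 ~ 0.82 -> pruned
    E = universe[21:28]            # disjoint -> kept
  ))
  tab <- data.frame(set = c("A", "B", "C", "D", "E"),
                    k = 5, K = lengths(col$sets), n = 10, N = 30,
                    pvalue = c(1e-6, 1e-5, 1e-4, 1e-3, 1e-2),
                    padj = c(1e-6, 1e-5, 1e-4, 1e-3, 1e-2),
                    enriched = TRUE,
                    genes = "g01", stringsAsFactors = FALSE)
  class(tab) <- c("ora_table", "data.frame")
  pruned <- prune_redundant(tab, col, jaccard_threshold = 0.7)
  expect_equal(pruned$set, c("A", "C", "E"))
})

test_that("concept networks annotate genes with their pool memberships", {
  p1 <- data.frame(gene = c("A", "B"), sign = "+", best_padj = 0.01)
  p2 <- data.frame(gene = c("A", "C"), sign = "+", best_padj = 0.01)
  pools <- list(CE_6h = p1, MBA_6h = p2)
  tab <- data.frame(set = "s1", k = 3, K = 5, n = 3, N = 20, pvalue = 1e-4,
                    padj = 1e-4, enriched = TRUE, genes = "A,B,C",
                    stringsAsFactors = FALSE)
  net <- concept_network(tab, pools, top_k = 1L)
  expect_equal(nrow(net), 3L)
  expect_equal(net$pools[net$gene == "A"], "CE_6h,MBA_6h")
  expect_equal(net$n_pools[net$gene == "A"], 2L)
  expect_equal(net$pools[net$gene == "B"], "CE_6h")
  # gene in all four pools carries an annotation of size 4
  pools4 <- setNames(rep(list(data.frame(gene = "A")), 4),
                     c("CE_6h", "MBA_6h", "CE_24h", "MBA_24h"))
  net4 <- concept_network(tab, pools4, top_k = 1L)
  expect_equal(net4$n_pools[net4$gene == "A"], 4L)
})
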