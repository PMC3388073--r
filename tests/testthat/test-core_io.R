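test_that("expression matrix TSV round-trip is identity and order-preserving", {
  withr::with_seed(42, {
    vals <- matrix(rnorm(300, 7, 1.5), 50, 6,
                   dimnames = list(sprintf("gene%02d", 1:50),
                                   sprintf("s%d", 1:6)))
  })
  design <- stats::setNames(rep(c("A", "B"), each = 3), colnames(vals))
  em <- expr_matrix(vals, design)
  mp <- withr::local_tempfile(fileext = ".tsv")
  dp <- withr::local_tempfile(fileext = ".tsv")
  write_expression_matrix(em, mp, dp)
  em2 <- read_expression_matrix(mp, dp)
  expect_identical(rownames(em2$values), rownames(em$values))
  expect_identical(colnames(em2$values), colnames(em$values))
  expect_lt(max(abs(em2$values - em$values)), 1e-9)
  expect_identical(em2$design, em$design)
})

test_that("expression loading errors name the offending gene or cell", {
  mp <- withr::local_tempfile(fileext = ".tsv")
  dp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\ts1\ts2\ts3\ts4",
               "ATF3\t1\t2\t3\t4",
               "ID1\t1\t1\t1\t1",
               "ATF3\t2\t2\t2\t2"), mp)
  writeLines(c("sample_id\tlabel", paste0("s", 1:4, "\tA")), dp)
  expect_error(read_expression_matrix(mp, dp), "ATF3")

  writeLines(c("gene\ts1\ts2", "g1\t1\tabc"), mp)
  writeLines(c("sample_id\tlabel", "s1\tA", "s2\tB"), dp)
  expect_error(read_expression_matrix(mp, dp), "g1.*s2")
  # drop_gene policy drops the bad row instead
  writeLines(c("gene\ts1\ts2", "g1\t1\tabc", "g2\t1\t2"), mp)
  em <- read_expression_matrix(mp, dp, missing_policy = "drop_gene")
  expect_identical(rownames(em$values), "g2")

  # sample present in the matrix but absent from the design
  writeLines(c("gene\ts1\ts2", "g1\t1\t2"), mp)
  writeLines(c("sample_id\tlabel", "s1\tA"), dp)
  expect_error(read_expression_matrix(mp, dp), "s2")
})

test_that("small parsed matrix matches its file contents and design groups", {
  mp <- withr::local_tempfile(fileext = ".tsv")
  dp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\ts1\ts2\ts3\ts4",
               "g1\t1\t2\t3\t4", "g2\t5\t6\t7\t8", "g3\t0\t0\t1\t1"), mp)
  writeLines(c("sample_id\tlabel", "s1\tA", "s2\tA", "s3\tB", "s4\tB"), dp)
  em <- read_expression_matrix(mp, dp)
  expect_equal(dim(em$values), c(3L, 4L))
  expect_equal(unname(table(em$design)[c("A", "B")]), c(2L, 2L),
               ignore_attr = TRUE)
  expect_equal(em$values["g2", "s3"], 7)
})

test_that("edge list parsing dedupes, keeps kinds, rejects bad input", {
  sif <- withr::local_tempfile(fileext = ".sif")
  writeLines(c("A\tpp\tB", "B\tpd\tC", "A\tpp\tB"), sif)
  net <- read_edge_list(sif)
  expect_equal(nrow(net$nodes), 3L)
  expect_equal(nrow(net$edges), 2L)
  expect_setequal(net$edges$kind, c("pp", "pd"))

  writeLines("A\tpp\tA", sif)
  expect_error(read_edge_list(sif), "self-loop")
  writeLines("A\tfoo\tB", sif)
  expect_error(read_edge_list(sif), "pp.*pd|'pp' and 'pd'")
})

test_that("edge list round-trip preserves the edge set exactly", {
  withr::with_seed(7, {
    nodes <- sprintf("n%02d", 1:15)
    from <- sample(nodes, 30, replace = TRUE)
    to <- sample(nodes, 30, replace = TRUE)
    keep <- from != to
    edges <- data.frame(from = from[keep], to = to[keep],
                        kind = sample(c("pp", "pd"), sum(keep),
                                      replace = TRUE),
                        stringsAsFactors = FALSE)
  })
  net <- interaction_network(edges)
  sif <- withr::local_tempfile(fileext = ".sif")
  write_edge_list(net, sif)
  net2 <- read_edge_list(sif)
  key <- function(n) sort(paste(n$edges$from, n$edges$to, n$edges$kind))
  expect_identical(key(net2), key(net))
})

test_that("GMT parsing dedupes members and validates structure", {
  gmt <- withr::local_tempfile(fileext = ".gmt")
  writeLines("GO:1\tdesc\tg1\tg2\tg2", gmt)
  sets <- read_gene_sets(gmt)
  expect_identical(sets, list("GO:1" = c("g1", "g2")))

  writeLines(character(), gmt)
  expect_length(read_gene_sets(gmt), 0L)

  writeLines(c("GO:1\td\tg1", "GO:1\td\tg2"), gmt)
  expect_error(read_gene_sets(gmt), "duplicate term")
  writeLines(c("GO:1\td\tg1", "GO:2\tonlytwo"), gmt)
  expect_error(read_gene_sets(gmt), "line 2")
})

test_that("GMT round-trip is set-equal on a 10-term random collection", {
  withr::with_seed(5, {
    sets <- lapply(1:10, function(i) sample(sprintf("g%03d", 1:100),
                                            sample(3:20, 1)))
    names(sets) <- sprintf("TERM_%02d", 1:10)
  })
  gmt <- withr::local_tempfile(fileext = ".gmt")
  write_gene_sets(sets, gmt)
  sets2 <- read_gene_sets(gmt)
  expect_identical(names(sets2), names(sets))
  for (nm in names(sets)) expect_setequal(sets2[[nm]], sets[[nm]])
})

test_that("ortholog map reading collapses duplicate pairs", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("mouse\thuman", "Atf3\tATF3", "Id1\tID1", "Atf3\tATF3"), tsv)
  map <- read_ortholog_map(tsv)
  expect_equal(nrow(map), 2L)
  expect_identical(colnames(map), c("source", "target"))
})

test_that("run configuration validates bounds and reads YAML", {
  expect_error(run_config(alpha = 0), "alpha")
  expect_error(run_config(fc_threshold = -1), "fc_threshold")
  expect_error(run_config(permutation_cap = 0), "permutation_cap")
  yml <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("alpha: 0.01", "fc_threshold: 1.0", "seed: 99"), yml)
  cfg <- read_run_config(yml)
  expect_equal(cfg$alpha, 0.01)
  expect_equal(cfg$fc_threshold, 1.0)
  expect_equal(cfg$seed, 99L)
  expect_equal(cfg$permutation_cap, 10000L)
  writeLines("nonsense_key: 1", yml)
  expect_error(read_run_config(yml), "nonsense_key")
})
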