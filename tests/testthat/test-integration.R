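# minimal DEG-table-like and timecourse-like inputs for integration tests
deg_tab <- function(genes, dirs, fcs = NULL) {
  if (is.null(fcs)) fcs <- ifelse(dirs == "up", 1, ifelse(dirs == "down", -1, 0))
  data.frame(gene = genes, direction = dirs, log2fc = fcs,
             stringsAsFactors = FALSE)
}

tc_calls <- function(genes, s3, s16, f3 = NULL, f16 = NULL) {
  if (is.null(f3)) f3 <- ifelse(s3 == "up", 1, ifelse(s3 == "down", -1, 0))
  if (is.null(f16)) f16 <- ifelse(s16 == "up", 1, ifelse(s16 == "down", -1, 0))
  structure(data.frame(gene = genes, log2fc_3h = f3, state_3h = s3,
                       log2fc_16h = f16, state_16h = s16,
                       stringsAsFactors = FALSE),
            timepoints = c("3h", "16h"), baseline = "0h",
            class = c("timecourse_calls", "data.frame"))
}

test_that("a cholesterol-repressed gene up under depletion is discordant", {
  mouse <- deg_tab(c("Atf3", "Xx"), c("down", "none"))
  human <- tc_calls(c("ATF3", "XX"), c("up", "none"), c("up", "none"))
  map <- data.frame(source = c("Atf3", "Xx"), target = c("ATF3", "XX"))
  rec <- map_and_intersect(mouse, human, map)
  expect_equal(nrow(rec), 1L)
  expect_identical(rec$group, "source_down_target_up")
  expect_true(rec$discordant)
  expect_identical(discordant_set(rec)$target_gene, "ATF3")
})

test_that("genes called in only one dataset are excluded", {
  mouse <- deg_tab(c("m1", "m2"), c("up", "up"))
  human <- tc_calls(c("h1", "h2"), c("up", "none"), c("none", "none"))
  map <- data.frame(source = c("m1", "m2"), target = c("h1", "h2"))
  rec <- map_and_intersect(mouse, human, map)
  expect_identical(rec$source_gene, "m1")
  expect_identical(rec$group, "both_up")
  expect_error(map_and_intersect(mouse, human, map[0, ]), "empty")
})

test_that("the union-of-timepoints direction rule is applied", {
  # called only at 3h -> 3h direction; at both -> 16h; conflict -> larger fc
  human <- tc_calls(
    c("early", "late", "conflict_big3", "conflict_big16"),
    s3 = c("up", "none", "down", "down"),
    s16 = c("none", "down", "up", "up"),
    f3 = c(1, 0, -3, -1), f16 = c(0, -1, 1, 2))
  mouse <- deg_tab(paste0("m_", human$gene), rep("up", 4))
  map <- data.frame(source = mouse$gene, target = human$gene)
  rec <- map_and_intersect(mouse, human, map)
  got <- stats::setNames(rec$sign_target, rec$target_gene)
  expect_identical(got[["early"]], "up")
  expect_identical(got[["late"]], "down")
  expect_identical(got[["conflict_big3"]], "down")
  expect_identical(got[["conflict_big16"]], "up")
})

test_that("planted shared DEGs are recovered exactly under a complete map", {
  study <- simulate_study(n_genes = 400, n_shared_discordant = 30,
                          n_shared_concordant = 10, n_private = 10,
                          noise_group = 0, noise_time = 0, seed = 41)
  degs1 <- deg_two_group(study$source$expr, run_config(seed = 41))
  calls2 <- assign_patterns(call_timecourse(study$target$expr))
  rec <- map_and_intersect(degs1, calls2, study$map)
  expect_equal(nrow(rec), 40L)  # 30 discordant + 10 concordant planted
  disc <- discordant_set(rec)
  expect_setequal(disc$target_gene, study$truth$shared_discordant$target_gene)
  expect_equal(nrow(disc), 30L)
  # discordant set equals a brute-force filter on sign inequality
  expect_identical(disc$target_gene,
                   rec$target_gene[rec$sign_source != rec$sign_target])
})

test_that("the four groups partition the intersection", {
  study <- simulate_study(n_genes = 300, seed = 42)
  degs1 <- deg_two_group(study$source$expr, run_config(seed = 42))
  calls2 <- assign_patterns(call_timecourse(study$target$expr))
  rec <- map_and_intersect(degs1, calls2, study$map)
  tab <- table(factor(rec$group,
                      levels = c("both_up", "both_down",
                                 "source_up_target_down",
                                 "source_down_target_up")))
  expect_equal(sum(tab), nrow(rec))
  expect_equal(sum(rec$discordant),
               sum(tab[c("source_up_target_down", "source_down_target_up")]),
               ignore_attr = TRUE)
})

test_that("swapping dataset roles mirrors the groups", {
  mouse <- deg_tab(c("m1", "m2", "m3"), c("up", "down", "up"))
  human <- deg_tab(c("h1", "h2", "h3"), c("down", "down", "up"))
  map <- data.frame(source = paste0("m", 1:3), target = paste0("h", 1:3))
  fwd <- map_and_intersect(mouse, human, map)
  rev_map <- data.frame(source = map$target, target = map$source)
  bwd <- map_and_intersect(human, mouse, rev_map)
  mirror <- c(both_up = "both_up", both_down = "both_down",
              source_up_target_down = "source_down_target_up",
              source_down_target_up = "source_up_target_down")
  m <- match(fwd$source_gene, bwd$target_gene)
  expect_identical(unname(mirror[fwd$group]), bwd$group[m])
  expect_identical(fwd$discordant, bwd$discordant[m])
})

test_that("one-to-many mappings resolve by the configured policy", {
  mouse <- deg_tab("m1", "up")
  human <- deg_tab(c("hA", "hB"), c("up", "up"), fcs = c(0.9, 2.5))
  map <- data.frame(source = c("m1", "m1"), target = c("hA", "hB"))
  rec <- map_and_intersect(mouse, human, map, policy = "max_abs_fc")
  expect_identical(rec$target_gene, "hB")
  rec2 <- map_and_intersect(mouse, human, map, policy = "first_alphabetical")
  expect_identical(rec2$target_gene, "hA")
  # an identical symbol across namespaces is allowed
  map3 <- data.frame(source = "ATF3", target = "ATF3")
  rec3 <- map_and_intersect(deg_tab("ATF3", "down"),
                            deg_tab("ATF3", "up"), map3)
  expect_equal(nrow(rec3), 1L)
})
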