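test_that("coarse-graining schemes select the documented atom sets", {
  expect_equal(cg_scheme("CG1")$atoms, c("P", "C2'", "C4'"))
  expect_equal(cg_scheme("CG2")$atoms, c("P", "C2'", "C4", "N3"))
  expect_error(cg_scheme("CG3"), "one of")

  s <- fixture_duplex() # GC-capped (CUG)3: 2 chains x 11 nt
  n_res <- nrow(residue_table(s))
  expect_equal(n_res, 22)
  # 4 atoms per residue minus the two absent 5'-terminal phosphates
  expect_equal(nrow(fixture_nodes("CG2")$xyz), 4 * n_res - 2)
  expect_equal(nrow(fixture_nodes("CG1")$xyz), 3 * n_res - 2)
  all_nodes <- suppressMessages(select_nodes(s, cg_scheme("ALL")))
  expect_equal(nrow(all_nodes$xyz), nrow(s$atoms))
})

test_that("uncapped (CUG)3 duplex yields the 70-node CG2 network", {
  s <- build_cug_duplex(3)
  nodes <- suppressMessages(select_nodes(s, cg_scheme("CG2")))
  expect_equal(nrow(nodes$xyz), 70)
  expect_equal(nrow(suppressMessages(select_nodes(s, cg_scheme("CG1")))$xyz),
               52)
})

test_that("node labels are unique and carry provenance", {
  nd <- fixture_nodes()
  key <- with(nd$labels, paste(chain, resno, elety))
  expect_false(any(duplicated(key)))
  expect_true(all(nd$labels$elety %in% cg_scheme("CG2")$atoms))
})

test_that("fragment extraction finds in-phase (CUG)n windows", {
  expect_length(extract_cug_fragments(build_cug_duplex(6), n_repeats = 3), 4)
  expect_length(extract_cug_fragments(build_cug_duplex(6), n_repeats = 3,
                                      stride = 3), 2)
  expect_length(extract_cug_fragments(build_cug_duplex(3), n_repeats = 3), 1)
  # a long enough duplex without any CUG window yields no fragments
  clean <- build_aform_duplex("GGCAUACCG")
  expect_length(extract_cug_fragments(clean, n_repeats = 3), 0)
})

test_that("fragments relabel to chains A/B with residues from 1", {
  fr <- extract_cug_fragments(build_cug_duplex(6), n_repeats = 3)[[2]]
  expect_equal(sort(unique(fr$atoms$chain)), c("A", "B"))
  expect_equal(chain_sequences(fr)[["A"]], "CUGCUGCUG")
  expect_equal(min(fr$atoms$resno), 1)
})

test_that("common_nodes intersects label sets across structures", {
  nd <- fixture_nodes()
  sub <- nd
  keep <- seq_len(nrow(sub$xyz) - 3)
  sub$xyz <- sub$xyz[keep, , drop = FALSE]
  sub$labels <- sub$labels[keep, , drop = FALSE]
  merged <- common_nodes(list(nd, sub))
  expect_equal(nrow(merged[[1]]$xyz), length(keep))
  expect_equal(merged[[1]]$labels$elety, merged[[2]]$labels$elety)
})
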