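demo_result <- function() {
  memo("demo_result", rg_run(demo_fixture()$records,
                             rg_config(similarity_threshold = 0.5,
                                       min_core_size = 4)))
}

test_that("per-node substructure counts partition the core members", {
  res <- demo_result()
  ann <- res$annotations[[1]]
  members <- length(res$assignments[[1]]$member_ids)
  for (node in unique(ann$node_index)) {
    expect_equal(sum(ann$count[ann$node_index == node]), members)
  }
  # records sorted by descending count within node, ties alphabetical
  for (node in unique(ann$node_index)) {
    sub <- ann[ann$node_index == node, ]
    expect_true(all(diff(sub$count) <= 0))
  }
})

test_that("activity statistics agree with an independent recomputation", {
  res <- demo_result()
  ann <- res$annotations[[1]]
  a <- res$assignments[[1]]
  for (r in seq_len(nrow(ann))) {
    ids <- Filter(function(id) {
      rg <- res$rgs[[id]]
      rg$substructure[a$mappings[[id]]$mapping[ann$node_index[r]]] ==
        ann$substructure_smarts[r]
    }, a$member_ids)
    vals <- res$records$pic50[match(ids, res$records$compound_id)]
    expect_equal(ann$count[r], length(vals))
    expect_equal(ann$pic50_mean[r], mean(vals), tolerance = 1e-9)
    expect_equal(ann$pic50_median[r], median(vals), tolerance = 1e-9)
    if (length(vals) > 1) {
      expect_equal(ann$pic50_std[r], sd(vals), tolerance = 1e-9)
    } else {
      expect_true(is.na(ann$pic50_std[r]))
    }
    expect_gte(ann$pic50_mean[r], min(vals))
    expect_lte(ann$pic50_mean[r], max(vals))
    expect_gte(ann$pic50_median[r], min(vals))
    expect_lte(ann$pic50_median[r], max(vals))
  }
})

test_that("core table rows are unique tuples whose counts sum to the member count", {
  res <- demo_result()
  tab <- res$core_tables[[1]]
  expect_equal(sum(tab$molecule_count),
               length(res$assignments[[1]]$member_ids))
  node_cols <- grep("^node_", names(tab), value = TRUE)
  expect_length(node_cols, 4)
  expect_false(any(duplicated(tab[node_cols])))
  # molecules extending beyond the core keep wildcard substitution markers
  expect_true(any(grepl("*", tab$combined_substructure, fixed = TRUE)))
})

test_that("pie metadata fractions sum to one per node", {
  res <- demo_result()
  pies <- pie_metadata(res$cores[[1]], res$annotations[[1]])
  expect_length(pies, 4)
  for (p in pies) {
    expect_equal(sum(p$segments$fraction), 1, tolerance = 1e-9)
    expect_equal(p$size, nrow(p$segments))
    expect_true(all(diff(p$segments$count) <= 0))
  }
  # invariant nodes have a single full segment
  sizes <- vapply(pies, `[[`, integer(1), "size")
  expect_true(any(sizes == 1))
  full <- pies[[which(sizes == 1)[1]]]
  expect_equal(full$segments$fraction, 1)
})

test_that("a single-molecule core gives one full segment everywhere", {
  rec <- tibble::tibble(compound_id = "solo", smiles = "NC(=O)Cc1ccccc1",
                        pic50 = 6.5)
  res <- rg_run(rec, rg_config(min_core_size = 2))
  expect_length(res$cores, 1)
  pies <- pie_metadata(res$cores[[1]], res$annotations[[1]])
  for (p in pies) {
    expect_equal(p$size, 1)
    expect_equal(p$segments$fraction, 1)
  }
})

test_that("overlap matrix counts shared members symmetrically", {
  rgs <- demo_rgs()
  cores <- list(
    rgcore:::new_rg_core(1L, rg_graph(c("Li", "No"), rbind(c(1, 2, 1))),
                         character(0)),
    rgcore:::new_rg_core(2L, rg_graph("Ge"), character(0)),
    rgcore:::new_rg_core(3L, rg_graph("Cd"), character(0))   # matches nothing
  )
  asg <- assign_all(rgs, cores)
  m <- overlap_matrix(asg)
  expect_true(isSymmetric(m))
  expect_equal(diag(m), c(core_1 = 6L, core_2 = 6L, core_3 = 0L))
  expect_equal(m["core_1", "core_2"], 6L)
  expect_equal(m["core_1", "core_3"], 0L)
})

test_that("dataset summary counts unique RGs by canonical RG-SMILES", {
  res <- demo_result()
  s <- res$summary
  expect_equal(s$n_molecules, 6L)
  expect_equal(s$n_unique_rgs, 5L)        # ethyl and methyl variants share one RG
  expect_equal(s$mean_nodes_per_rg,
               mean(vapply(res$rgs, function(r) length(r$labels), integer(1))))

  # n identical molecules (different ids) -> one unique RG
  recs <- tibble::tibble(compound_id = c("x1", "x2", "x3"),
                         smiles = c("Cc1ccccc1", "Cc1ccccc1C", "Cc1ccc(C)cc1"),
                         pic50 = c(5, 6, 7))
  rgs <- build_rgs(clean_dataset(recs))
  expect_equal(dataset_summary(recs, rgs)$n_unique_rgs, 2L)  # toluene vs xylenes

  empty <- dataset_summary(recs[0, ], list())
  expect_equal(empty$n_molecules, 0L)
  expect_equal(empty$n_unique_rgs, 0L)
})

test_that("equal activities collapse the statistics", {
  fx <- make_series("NC(=O)c1ccc({R})cc1", c("Cl", "Br", "F", "C(F)(F)F"),
                    activities = rep(7.2, 4), name = "flat")
  expect_length(unique(fx$expected_rg_smiles), 1)   # identical RGs
  res <- rg_run(fx$records, rg_config(min_core_size = 3))
  ann <- res$annotations[[1]]
  const <- ann[ann$count == 4, ]
  expect_gt(nrow(const), 0)
  expect_true(all(const$pic50_mean == 7.2))
  expect_true(all(const$pic50_median == 7.2))
  expect_true(all(const$pic50_std == 0))
})

test_that("export_results writes a consistent, re-readable bundle", {
  res <- demo_result()
  dir <- withr::local_tempdir()
  files <- export_results(res, dir)
  expect_true(file.exists(file.path(dir, "summary.csv")))
  expect_true(file.exists(file.path(dir, "overlap.csv")))
  expect_true(file.exists(file.path(dir, "assignments.csv")))

  doc <- jsonlite::read_json(file.path(dir, "core_001.json"))
  expect_equal(doc$core_smarts, res$cores[[1]]$core_smarts)
  # round-trip: substructure counts identical to the in-memory annotation
  ann <- res$annotations[[1]]
  for (node in doc$nodes) {
    sub <- ann[ann$node_index == node$node_index, ]
    expect_equal(vapply(node$substructures, function(s) s$count, integer(1)),
                 sub$count)
    expect_equal(vapply(node$substructures, function(s) s$smarts, character(1)),
                 sub$substructure_smarts)
    fr <- vapply(node$segments, as.numeric, numeric(1))
    expect_equal(sum(fr), 1, tolerance = 1e-9)
  }

  # empty core list: summary only
  res0 <- res
  res0$cores <- list()
  dir0 <- withr::local_tempdir()
  export_results(res0, dir0)
  expect_identical(list.files(dir0), "summary.csv")
})
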