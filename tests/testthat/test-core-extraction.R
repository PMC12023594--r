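test_that("graph Tanimoto follows T = MCS / (A + B - MCS)", {
  g5 <- rg_graph(c("Ge", "Li", "No", "Hg", "Li"),
                 rbind(c(1, 2, 1), c(2, 3, 1), c(3, 4, 1), c(1, 5, 1)))
  g6 <- rg_graph(c("Ge", "Li", "No", "Hg", "Li", "Co"),
                 rbind(c(1, 2, 1), c(2, 3, 1), c(3, 4, 1), c(1, 5, 1), c(5, 6, 1)))
  expect_equal(tanimoto(g5, g5)$tanimoto, 1)
  t56 <- tanimoto(g5, g6)
  expect_equal(t56$mcs_size, 5)
  expect_equal(t56$tanimoto, 5 / 6)
  expect_equal(tanimoto(g6, g5)$tanimoto, t56$tanimoto)   # symmetric
  expect_equal(tanimoto(rg_graph("Li"), rg_graph("No"))$tanimoto, 0)
  expect_error(tanimoto(rg_graph(character(0)), rg_graph(character(0))))
})

test_that("rg_mcs matches the brute-force oracle on all small fixture RG pairs", {
  rgs <- Filter(function(r) length(r$labels) <= 7, fixture_rgs())
  codes <- vapply(rgs, function(r) rgcore:::rg_code(rg_graph(r$labels, r$edges)),
                  character(1))
  rgs <- rgs[!duplicated(codes)]
  expect_gte(length(rgs), 10)
  n_checked <- 0
  for (i in seq_len(length(rgs) - 1)) {
    for (j in (i + 1):length(rgs)) {
      a <- rg_graph(rgs[[i]]$labels, rgs[[i]]$edges)
      b <- rg_graph(rgs[[j]]$labels, rgs[[j]]$edges)
      got <- rg_mcs(a, b)
      expect_equal(got$size, oracle_mcs_size(a, b),
                   label = paste(rgs[[i]]$compound_id, rgs[[j]]$compound_id))
      if (got$size > 0) {
        # the reported common subgraph embeds in both inputs
        expect_true(rgcore:::rg_contains(a, got$graph))
        expect_true(rgcore:::rg_contains(b, got$graph))
        expect_true(rgcore:::rg_is_connected(got$graph))
      }
      n_checked <- n_checked + 1
    }
  }
  expect_gte(n_checked, 45)
})

test_that("tanimoto is 1 exactly for isomorphic reduced graphs", {
  rgs <- fixture_rgs()
  idx <- seq(1, length(rgs), by = 4)
  for (i in idx) {
    for (j in idx) {
      if (i >= j) next
      t <- tanimoto(rgs[[i]], rgs[[j]])$tanimoto
      expect_gte(t, 0); expect_lte(t, 1)
      iso <- rgcore:::rg_isomorphic(rg_graph(rgs[[i]]$labels, rgs[[i]]$edges),
                                    rg_graph(rgs[[j]]$labels, rgs[[j]]$edges))
      expect_equal(t == 1, iso)
    }
  }
})

test_that("neighbour lists are sorted descending with the most distant at the tail", {
  rgs <- demo_rgs()
  nbl <- neighbour_lists(rgs, 0.5)
  expect_named(nbl, unname(vapply(rgs, `[[`, character(1), "compound_id")))
  for (nb in nbl) {
    sims <- attr(nb, "similarity")
    expect_true(all(diff(sims) <= 0))
    expect_true(all(sims >= 0.5))
  }
  # demo set: all six molecules are mutual neighbours at 0.5
  expect_true(all(vapply(nbl, length, integer(1)) == 5))

  # threshold 1 with all-distinct RGs: empty everywhere
  distinct <- fixture_rgs()[c("misc_01", "misc_03", "misc_05", "misc_07")]
  nbl1 <- neighbour_lists(distinct, 1.0)
  expect_true(all(vapply(nbl1, length, integer(1)) == 0))
})

test_that("find_candidate_mcs walks from the most distant neighbour and falls back", {
  rgs <- demo_rgs()
  nbl <- neighbour_lists(rgs, 0.5)
  fc <- find_candidate_mcs(rgs[[1]], nbl[[1]], rgs, min_size = 4)
  expect_false(fc$sub_minimal)
  expect_equal(fc$consumed, nbl[[1]][length(nbl[[1]])])   # most distant consumed
  expect_gte(rgcore:::rg_n_nodes(fc$graph), 4)

  # min size larger than any MCS: falls back to the largest, flagged
  fc2 <- find_candidate_mcs(rgs[[1]], nbl[[1]], rgs, min_size = 10)
  expect_true(fc2$sub_minimal)
  expect_lt(rgcore:::rg_n_nodes(fc2$graph), 10)
  expect_error(find_candidate_mcs(rgs[[1]], integer(0), rgs, 4), "non-empty")
})

test_that("core extraction finds the engineered scaffold at both thresholds", {
  fx <- demo_fixture()
  rgs <- demo_rgs()
  for (thr in c(0.5, 0.7)) {
    cores <- extract_cores(rgs, rg_config(similarity_threshold = thr,
                                          min_core_size = 4))
    expect_length(cores, 1)
    expect_equal(cores[[1]]$core_smarts, fx$expected_core_smarts)
    expect_setequal(cores[[1]]$member_ids, names(rgs))
    # the core embeds in every member RG
    for (id in cores[[1]]$member_ids) {
      expect_true(rgcore:::rg_contains(
        rg_graph(rgs[[id]]$labels, rgs[[id]]$edges), cores[[1]]$graph
      ), label = id)
    }
  }
})

test_that("every molecule is associated with at least one core at extraction end", {
  rgs <- fixture_rgs()
  cores <- extract_cores(rgs, rg_config(similarity_threshold = 0.5,
                                        min_core_size = 5))
  covered <- unique(unlist(lapply(cores, `[[`, "member_ids")))
  expect_setequal(covered, names(rgs))
  # candidate refinement never grows a core beyond min acceptance rules
  for (core in cores) {
    expect_true(rgcore:::rg_is_connected(core$graph))
  }
})

test_that("a molecule with no neighbours becomes a singleton core of its whole RG", {
  rgs <- fixture_rgs()[c("misc_10", "misc_02")]   # ethanol vs benzene
  expect_equal(tanimoto(rgs[[1]], rgs[[2]])$tanimoto, 0)
  cores <- extract_cores(rgs, rg_config(similarity_threshold = 0.5,
                                        min_core_size = 2))
  expect_length(cores, 2)
  for (k in 1:2) {
    expect_equal(cores[[k]]$member_ids, names(rgs)[k])
    expect_true(rgcore:::rg_isomorphic(cores[[k]]$graph,
                                       rg_graph(rgs[[k]]$labels, rgs[[k]]$edges)))
  }
})

test_that("core count trends non-decreasing as the minimum core size grows", {
  rgs <- fixture_rgs()
  counts <- vapply(2:7, function(ms) {
    length(extract_cores(rgs, rg_config(similarity_threshold = 0.5,
                                        min_core_size = ms)))
  }, integer(1))
  steps <- diff(counts)
  expect_gte(mean(steps >= 0), 0.8)
})
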