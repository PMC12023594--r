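# Engineered molecules with hand-derived distances:
#   seven_bond: amide carbonyl separated from the aryl ring by a hexamethylene
#   linker, so the Ge-No node pair sits seven bonds apart.
#   sub_sites:  N-methyl amide with two meta ring methyls; the CH2 linker node
#   is 3 bonds from the N-methyl site and 4 from each ring methyl site.

test_that("mapping enumeration counts embeddings up to core automorphism", {
  amb <- amb_fixture()
  rgs <- amb_rgs()
  expect_length(enumerate_mappings(rgs[["amb_01"]], amb$core), 1)
  expect_length(enumerate_mappings(rgs[["amb_amb"]], amb$core), 2)
  # core with a label absent from the molecule: no mappings
  cd_core <- rgcore:::new_rg_core(9L, rg_graph("Cd"), character(0))
  expect_length(enumerate_mappings(rgs[["amb_01"]], cd_core), 0)
})

test_that("node distance maps record shortest through-bond atom distances", {
  rg <- rg_of("NC(=O)CCCCCCc1ccc(Cl)cc1", "seven_bond")
  core <- rgcore:::new_rg_core(1L, rg_graph(
    c("Ge", "Li", "No", "Hg"), rbind(c(1, 2, 1), c(2, 3, 1), c(3, 4, 1))
  ), character(0))
  maps <- enumerate_mappings(rg, core)
  expect_length(maps, 1)
  ndm <- node_distance_map(rg, maps[[1]])
  expect_equal(unname(ndm["1-2"]), 1)    # adjacent nodes: one bond
  expect_equal(unname(ndm["2-3"]), 1)
  expect_equal(unname(ndm["1-3"]), 7)    # carbonyl to ring through the chain
  expect_named(ndm, c("1-2", "1-3", "1-4", "2-3", "2-4", "3-4"))

  # single-node core: empty map
  one <- rgcore:::new_rg_core(2L, rg_graph("No"), character(0))
  m1 <- enumerate_mappings(rg, one)
  expect_length(node_distance_map(rg, m1[[1]]), 0)
})

test_that("substituent distance maps list sorted distances to each site", {
  rg <- rg_of("CNC(=O)Cc1cc(C)cc(C)c1", "sub_sites")
  core <- rgcore:::new_rg_core(1L, rg_graph(
    c("Ge", "Li", "No"), rbind(c(1, 2, 1), c(2, 3, 1))
  ), character(0))
  maps <- enumerate_mappings(rg, core)
  expect_length(maps, 1)
  sdm <- substituent_distance_map(rg, maps[[1]])
  expect_length(sdm, 3)
  expect_equal(sdm[[2]], c(3L, 4L, 4L))     # CH2 linker node: N-methyl, 2 ring methyls
  expect_true(all(vapply(sdm, function(v) !is.unsorted(v), logical(1))))
  expect_true(all(lengths(sdm) == 3))       # one entry per substitution site

  # molecule identical to the core: no substitution sites anywhere
  rg2 <- rg_of("NC(=O)Cc1ccccc1", "bare")
  maps2 <- enumerate_mappings(rg2, core)
  expect_true(all(lengths(substituent_distance_map(rg2, maps2[[1]])) == 0))
})

test_that("reference maps aggregate with frequency counts", {
  m <- stats::setNames(c(1L, 2L, 1L), c("1-2", "1-3", "2-3"))
  m2 <- stats::setNames(c(1L, 3L, 1L), c("1-2", "1-3", "2-3"))
  refs <- aggregate_reference_maps(list(m, m, m, m2))
  expect_length(refs, 2)
  expect_equal(refs[[1]]$count, 3L)
  expect_equal(refs[[2]]$count, 1L)
  expect_length(aggregate_reference_maps(list()), 0)
})

test_that("ambiguous mappings resolve to the constructed ground truth", {
  amb <- amb_fixture()
  rgs <- amb_rgs()
  asg <- assign_all(rgs, list(amb$core))
  a <- asg[[1]]
  expect_setequal(a$member_ids, names(rgs))

  m <- a$mappings[[amb$ambiguous_id]]
  expect_true(m$ambiguous)
  expect_equal(m$stage, "node_map")
  # ground truth: the resolved HBA-HBD node is the acetamide arm, two bonds
  # from the ring (the acid arm sits three bonds away)
  rg <- rgs[[amb$ambiguous_id]]
  ring_atoms <- rg$atom_indices[[m$mapping[3]]]
  ge_atoms <- rg$atom_indices[[m$mapping[1]]]
  dmat <- rgcore:::atom_distances(rg)
  expect_equal(min(dmat[ge_atoms, ring_atoms]), amb$expected_ring_to_ge_distance)

  # uniquely mapped molecules are flagged unique
  expect_false(a$mappings[["amb_01"]]$ambiguous)
  expect_equal(a$mappings[["amb_01"]]$stage, "unique")
})

test_that("resolution is deterministic under candidate order permutation", {
  amb <- amb_fixture()
  rgs <- amb_rgs()
  rg <- rgs[[amb$ambiguous_id]]
  cand <- enumerate_mappings(rg, amb$core)
  refs <- local({
    uniq <- setdiff(names(rgs), amb$ambiguous_id)
    node_maps <- lapply(uniq, function(id) {
      node_distance_map(rgs[[id]], enumerate_mappings(rgs[[id]], amb$core)[[1]])
    })
    sub_maps <- lapply(uniq, function(id) {
      substituent_distance_map(rgs[[id]], enumerate_mappings(rgs[[id]], amb$core)[[1]])
    })
    list(node = aggregate_reference_maps(node_maps, rgcore:::serialise_node_map),
         sub = aggregate_reference_maps(sub_maps, rgcore:::serialise_sub_map))
  })
  r1 <- resolve_mapping(rg, cand, refs$node, refs$sub)
  r2 <- resolve_mapping(rg, rev(cand), refs$node, refs$sub)
  expect_identical(r1$mapping, r2$mapping)
  expect_identical(r1$stage, r2$stage)

  # with no references at all, the deterministic fallback fires
  r3 <- resolve_mapping(rg, cand, list(), list())
  expect_equal(r3$stage, "fallback")
  expect_true(any(vapply(cand, identical, logical(1), r3$mapping)))
})

test_that("frequency rule picks the better-supported reference map", {
  amb <- amb_fixture()
  rgs <- amb_rgs()
  rg <- rgs[[amb$ambiguous_id]]
  cand <- enumerate_mappings(rg, amb$core)
  dmat <- rgcore:::atom_distances(rg)
  # both candidate maps appear as references, with unequal support
  refs <- aggregate_reference_maps(list(
    node_distance_map(rg, cand[[1]], dmat),
    node_distance_map(rg, cand[[1]], dmat),
    node_distance_map(rg, cand[[1]], dmat),
    node_distance_map(rg, cand[[2]], dmat)
  ))
  r <- resolve_mapping(rg, cand, refs, list())
  expect_equal(r$stage, "node_map_frequency")
  expect_identical(r$mapping, cand[[1]])
})

test_that("assignment registers a molecule under every core it contains", {
  rgs <- demo_rgs()
  cores <- list(
    rgcore:::new_rg_core(1L, rg_graph(c("Ge", "Li", "No", "Hg"),
                                      rbind(c(1, 2, 1), c(2, 3, 1), c(3, 4, 1))),
                         character(0)),
    rgcore:::new_rg_core(2L, rg_graph(c("Li", "No"), rbind(c(1, 2, 1))),
                         character(0))
  )
  asg <- assign_all(rgs, cores)
  expect_setequal(asg[[1]]$member_ids, names(rgs))   # scaffold in all six
  expect_setequal(asg[[2]]$member_ids, names(rgs))   # CH2-phenyl also in all
  for (a in asg) {
    for (id in a$member_ids) {
      cand <- enumerate_mappings(rgs[[id]], cores[[a$core_id]])
      expect_true(any(vapply(cand, identical, logical(1),
                             a$mappings[[id]]$mapping)))
    }
  }
})
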