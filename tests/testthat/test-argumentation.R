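test_that("set compatibility distinguishes nesting and overlap", {
  r <- fixture_resolved()
  # clade-of-6 (char 8) nests inside clade-of-8 (char 6)
  expect_true(characters_compatible(derived_taxon_set(r, 6),
                                    derived_taxon_set(r, 8)))
  # chars 3 and 4 overlap in eight taxa, each side with one extra
  expect_false(characters_compatible(derived_taxon_set(r, 3),
                                     derived_taxon_set(r, 4)))
  expect_true(characters_compatible(character(0), c("x", "y")))
  expect_true(characters_compatible(c("a"), c("b")))
})

test_that("synapomorphy grouping recovers the published species groups", {
  g <- group_by_synapomorphy(fixture_resolved())
  by_chars <- function(ids) {
    hit <- Filter(function(h) setequal(h$chars, ids), g$hypotheses)
    expect_length(hit, 1)
    hit[[1]]
  }
  # nine species on the chirocer antennule + P4 endopod seta loss;
  # the species of unknown male (char 2 '?') still counts into the group
  h9 <- by_chars(c(2, 3))
  expect_length(h9$taxa, 9)
  expect_true("sarsi" %in% h9$taxa)
  expect_false("macclintocki" %in% h9$taxa)
  expect_length(by_chars(c(6, 7))$taxa, 8)
  expect_length(by_chars(8)$taxa, 6)
  expect_length(by_chars(9)$taxa, 4)
  expect_length(by_chars(c(10, 11))$taxa, 3)
  expect_equal(sort(by_chars(c(12, 13, 14))$taxa), c("sarsi", "scottorum"))
  # char 1 routed to the whole-group level, not to a clade hypothesis
  expect_equal(g$monophylum_chars, 1L)
  # autapomorphies collected per taxon
  expect_setequal(g$autapomorphies$volkerlehmanskii, 18:23)
  expect_setequal(g$autapomorphies$sabinegeorgeae, 33:37)
  # the conflicts include {2,3} vs {4,5}
  expect_gt(nrow(g$conflicts), 0)
})

test_that("a matrix of autapomorphies only yields no clade hypotheses", {
  m <- character_matrix(
    c("A", "B", "C"),
    data.frame(id = 1:3, description = paste("c", 1:3)),
    rbind(c("1", "0", "0"), c("0", "1", "0"), c("0", "0", "1")))
  g <- group_by_synapomorphy(apply_polarity_policy(m))
  expect_length(g$hypotheses, 0)
  expect_equal(sort(unname(unlist(g$autapomorphies))), 1:3)
})

test_that("arbitration reproduces the published convergence set and clades", {
  r <- fixture_resolved()
  g <- group_by_synapomorphy(r)
  rep <- arbitrate(g, r)
  expect_equal(as.integer(names(rep$convergences)), c(4L, 5L, 17L, 30L))
  expect_equal(sort(vapply(rep$accepted, function(h) length(h$taxa), 1L)),
               c(2, 2, 3, 4, 6, 8, 9))
  expect_setequal(rep$autapomorphies$volkerlehmanskii, 18:23)
  # each convergent character lists its independent origins
  expect_length(rep$convergences[["17"]], 2)
  expect_setequal(unlist(rep$convergences[["30"]]),
                  c("typicus", "macclintocki"))
  # character accounting: every character appears exactly once
  accounted <- c(unlist(lapply(rep$accepted, `[[`, "chars")),
                 unlist(rep$autapomorphies),
                 as.integer(names(rep$convergences)),
                 rep$monophylum_chars, rep$unplaced)
  expect_equal(sort(unname(accounted)), 1:39)
  # conflicts carry resolution notes
  expect_true(all(nzchar(rep$conflicts$resolution)))
})

test_that("arbitration never discards an unconflicted hypothesis", {
  set.seed(7)
  for (seed in c(31, 32, 33)) {
    cfg <- simulation_config(n_taxa = 9, n_chars = 14,
                             homoplasy_fraction = 0.3, seed = seed)
    ds <- simulate_dataset(cfg)
    r <- apply_polarity_policy(ds$matrix)
    g <- group_by_synapomorphy(r)
    rep <- arbitrate(g, r)
    conflicted <- unique(c(g$conflicts$a, g$conflicts$b))
    quiet <- setdiff(seq_along(g$hypotheses), conflicted)
    kept_keys <- vapply(rep$accepted, function(h)
      paste(sort(h$taxa), collapse = "\r"), character(1))
    for (i in quiet) {
      expect_true(paste(sort(g$hypotheses[[i]]$taxa), collapse = "\r")
                  %in% kept_keys)
    }
    # the accepted set is always pairwise compatible
    acc <- lapply(rep$accepted, `[[`, "taxa")
    if (length(acc) > 1) {
      for (i in seq_len(length(acc) - 1)) for (j in (i + 1):length(acc)) {
        expect_true(characters_compatible(acc[[i]], acc[[j]]))
      }
    }
  }
})

test_that("a fully compatible matrix produces no convergences", {
  ds <- simulate_dataset(simulation_config(n_taxa = 8, n_chars = 10,
                                           homoplasy_fraction = 0, seed = 41))
  r <- apply_polarity_policy(ds$matrix)
  rep <- arbitrate(group_by_synapomorphy(r), r)
  expect_length(rep$convergences, 0)
})

test_that("the built cladogram reproduces the reference topology end to end", {
  r <- fixture_resolved()
  rep <- arbitrate(group_by_synapomorphy(r), r)
  tree <- build_cladogram(rep)
  expect_equal(rf_distance(tree, reference_cladogram()), 0)
  expect_equal(parsimony_length(tree, r), fixture_search()$best_length)
  # forced nesting on a toy case
  toy <- tree_from_clades(list(c("A", "B"), c("A", "B", "C")),
                          c("A", "B", "C", "D"))
  expect_equal(format_tree(toy), "(((A,B),C),D);")
})

test_that("the rejected ripples character would indeed be less parsimonious", {
  # appending it as a 40th character and forcing its five carriers into a
  # clade costs more steps than treating it as convergent on the reference
  m <- laophontodes_matrix()
  rip <- laophontodes_ripples_character()
  joint <- character_matrix(
    m$taxa,
    rbind(m$characters, rip$characters),
    rbind(m$cells, rip$cells),
    m$convergences)
  r <- apply_polarity_policy(joint)
  ref_len <- parsimony_length(reference_cladogram(), r)
  carriers <- derived_taxon_set(r, 40)
  ripple_tree <- tree_from_clades(list(carriers), joint$taxa)
  expect_gt(parsimony_length(ripple_tree, r), ref_len)
})
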