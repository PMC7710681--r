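test_that("lengths agree with the exhaustive assignment oracle on small trees", {
  set.seed(421)
  for (rep in 1:6) {
    n <- sample(4:7, 1)
    cfg <- simulation_config(n_taxa = n, n_chars = 8,
                             homoplasy_fraction = 0.3, missing_rate = 0.05,
                             seed = 1000 + rep)
    ds <- simulate_dataset(cfg)
    r <- apply_polarity_policy(ds$matrix)
    tr <- ds$truth$true_tree
    expect_identical(parsimony_length(tr, r, per_character = TRUE),
                     stats::setNames(oracle_length(tr, r, per_character = TRUE),
                                     r$characters$id))
  }
  # polytomies: hard-polytomy semantics checked against the same oracle
  r5 <- apply_polarity_policy(character_matrix(
    LETTERS[1:5], data.frame(id = 1:3, description = paste("c", 1:3)),
    rbind(c("0", "1", "1", "0", "0"),
          c("1", "1", "1", "1", "1"),
          c("0", "?", "1", "1", "0"))))
  poly <- parse_tree("(A,(B,C),(D,E));")
  expect_equal(parsimony_length(poly, r5), oracle_length(poly, r5))
})

test_that("lengths agree with Fitch parsimony after attaching an ancestral outgroup", {
  skip_if_not_installed("phangorn")
  for (seed in c(11, 12, 13)) {
    cfg <- simulation_config(n_taxa = 9, n_chars = 15,
                             homoplasy_fraction = 0.25, missing_rate = 0.05,
                             seed = seed)
    ds <- simulate_dataset(cfg)
    r <- apply_polarity_policy(ds$matrix)
    tr <- ds$truth$true_tree
    expect_equal(parsimony_length(tr, r), phangorn_length(tr, r))
  }
})

test_that("the reference tree needs 43 steps: 35 single origins + 4 double", {
  r <- fixture_resolved()
  ref <- reference_cladogram()
  expect_equal(oracle_length(ref, r), 43)        # independent enumeration
  expect_equal(parsimony_length(ref, r), 43)
  per <- parsimony_length(ref, r, per_character = TRUE)
  expect_equal(sum(per == 1), 35)
  expect_equal(sum(per == 2), 4)
  # an all-plesiomorphic matrix costs nothing
  zero <- r
  zero$cells[] <- 0L
  expect_equal(parsimony_length(ref, zero), 0)
})

test_that("the star tree maximises steps and lowers the consistency index", {
  r <- fixture_resolved()
  star <- parse_tree(paste0("(", paste(r$taxa, collapse = ","), ");"))
  expect_equal(parsimony_length(star, r), oracle_length(star, r))
  expect_gt(parsimony_length(star, r), parsimony_length(reference_cladogram(), r))
  expect_lt(consistency_index(star, r), consistency_index(reference_cladogram(), r))
})

test_that("reconstruction places origins on the argued branches", {
  r <- fixture_resolved()
  rec <- reconstruct(reference_cladogram(), r)
  # whole-group autapomorphy: one origin, on the stem
  expect_equal(rec[["1"]]$origin_count, 1)
  expect_equal(rec[["1"]]$origin_edges[[1]], sort(r$taxa))
  # six unambiguous autapomorphies of the new species, on its terminal edge
  for (id in as.character(18:23)) {
    expect_equal(rec[[id]]$origin_edges, list("volkerlehmanskii"))
  }
  # convergent lateral body extension: two independent terminal origins
  expect_equal(rec[["17"]]$origin_count, 2)
  expect_setequal(unlist(rec[["17"]]$origin_edges),
                  c("scottorum", "spongiosus"))
  # maxilliped seta lost twice; the unknown cell follows its surroundings
  expect_setequal(unlist(rec[["30"]]$origin_edges),
                  c("typicus", "macclintocki"))
  # delay-changes never invokes secondary loss on this matrix
  expect_equal(sum(vapply(rec, function(x) length(x$reversal_edges), 1L)), 0)
  # steps from the reconstruction sum to the tree length
  expect_equal(sum(vapply(rec, `[[`, 1L, "steps")),
               parsimony_length(reference_cladogram(), r))
})

test_that("accelerated placement prefers early origins with reversals below", {
  # derived in A and B, C intervening: delay gives two origins, accelerate
  # one origin above plus one reversal
  m <- character_matrix(c("A", "B", "C"),
                        data.frame(id = 1L, description = "d"),
                        matrix(c("1", "1", "0"), 1))
  r <- apply_polarity_policy(m)
  tr <- parse_tree("((A,C),B);")
  del <- reconstruct(tr, r, "delay-changes")[[1]]
  acc <- reconstruct(tr, r, "accelerate-changes")[[1]]
  expect_equal(del$origin_count, 2)
  expect_length(del$reversal_edges, 0)
  expect_equal(acc$origin_count, 1)
  expect_length(acc$reversal_edges, 1)
  expect_equal(del$steps, acc$steps)   # both most parsimonious
})

test_that("length is invariant under child reordering and label bijections", {
  for (seed in c(5, 6)) {
    cfg <- simulation_config(n_taxa = 8, n_chars = 10,
                             homoplasy_fraction = 0.2, seed = seed)
    ds <- simulate_dataset(cfg)
    r <- apply_polarity_policy(ds$matrix)
    tr <- ds$truth$true_tree
    expect_equal(parsimony_length(mirror_tree(tr), r), parsimony_length(tr, r))
    # relabel leaves by a bijection in both tree and matrix
    perm <- sample(r$taxa)
    tr2 <- tr
    tr2$tip.label <- perm[match(tr$tip.label, r$taxa)]
    r2 <- r
    r2$taxa <- perm[match(r$taxa, r$taxa)]
    colnames(r2$cells) <- r2$taxa
    expect_equal(parsimony_length(tr2, r2), parsimony_length(tr, r))
  }
})

test_that("refining a polytomy never increases the step count", {
  r <- fixture_resolved()
  ref <- reference_cladogram()
  len <- parsimony_length(ref, r)
  set.seed(99)
  for (i in 1:10) {
    bin <- ape::multi2di(ref)
    expect_lte(parsimony_length(bin, r), len)
  }
})

test_that("homoplasy indices hit their bounds on clean and dirty data", {
  clean <- simulate_dataset(simulation_config(n_taxa = 7, n_chars = 9,
                                              homoplasy_fraction = 0, seed = 3))
  rc <- apply_polarity_policy(clean$matrix)
  expect_equal(consistency_index(clean$truth$true_tree, rc), 1)
  expect_equal(retention_index(clean$truth$true_tree, rc), 1)
  r <- fixture_resolved()
  ci <- consistency_index(reference_cladogram(), r)
  expect_equal(ci, 39 / 43)
  expect_true(ci > 0 && ci < 1)
  ri <- retention_index(reference_cladogram(), r)
  expect_true(ri > 0 && ri < 1)
  # degenerate: no derived state anywhere
  zero <- r; zero$cells[] <- 0L
  expect_true(is.na(consistency_index(reference_cladogram(), zero)))
  expect_true(attr(consistency_index(reference_cladogram(), zero), "undefined"))
})

test_that("leaf/taxon mismatches are reported with the symmetric difference", {
  r <- fixture_resolved()
  bad <- parse_tree("(a,b,c);")
  expect_error(parsimony_length(bad, r), "only in tree.*only in matrix")
})
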