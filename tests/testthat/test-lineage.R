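test_that("junction_identity is an exact match fraction", {
  set.seed(7)
  a <- rand_junction(20)
  expect_identical(junction_identity(a, a), 1)
  # 3 mismatches in 20 positions: 17/20 = 0.85
  expect_equal(junction_identity(a, mutate_k(a, 3)), 0.85)
  # 4 mismatches: 16/20 = 0.80
  expect_equal(junction_identity(a, mutate_k(a, 4)), 0.80)
  # symmetry
  b <- mutate_k(a, 5)
  expect_equal(junction_identity(a, b), junction_identity(b, a))
  expect_error(junction_identity("ACGT", "ACGTA"), "length mismatch")
})

test_that("cluster_group applies single linkage with inclusive boundary", {
  # transitivity: A-B and B-C linked, A-C not -> still one lineage
  set.seed(11)
  A <- rand_junction(20)
  B <- mutate_k(A, 2)            # 0.90 to A
  C <- mutate_k(B, 2)            # 0.90 to B, possibly < 0.85 to A
  expect_equal(length(unique(cluster_group(c(A, B, C)))), 1)

  # boundary rule: identity exactly 0.85 links, one mismatch more does not
  bp <- boundary_pairs(L = 60, threshold = 0.85)
  expect_equal(attr(bp, "identity_at"), 51 / 60)  # = 0.85 exactly
  expect_equal(length(unique(cluster_group(bp$at))), 1)
  expect_equal(length(unique(cluster_group(bp$below))), 2)

  # random junctions with all pairwise identities < 0.85 stay singletons
  set.seed(12)
  repeat {
    js <- replicate(10, rand_junction(30))
    chars <- do.call(rbind, strsplit(js, ""))
    idents <- outer(1:10, 1:10, Vectorize(function(i, j)
      sum(chars[i, ] == chars[j, ]) / 30))
    if (all(idents[upper.tri(idents)] < 0.85)) break
  }
  expect_equal(cluster_group(js), 1:10)
})

test_that("cluster_group equals the brute-force all-pairs oracle", {
  skip_if_not_installed("igraph")
  set.seed(13)
  for (rep in 1:25) {
    L <- sample(c(21, 30, 45), 1)
    js <- random_structured_group(n_founders = sample(2:5, 1),
                                  variants_per = sample(3:10, 1), L = L)
    got <- cluster_group(js)
    want <- brute_components(js, 0.85)
    expect_true(partitions_equal(got, want),
                label = sprintf("oracle equality (rep %d, L=%d)", rep, L))
  }
})

test_that("cluster_group is permutation invariant and threshold-monotone", {
  set.seed(14)
  js <- random_structured_group(n_founders = 4, variants_per = 6, L = 30)
  ids <- sprintf("q%03d", seq_along(js))
  base <- cluster_group(js, ids = ids)
  for (k in 1:5) {
    perm <- sample(seq_along(js))
    shuffled <- cluster_group(js[perm], ids = ids[perm])
    expect_true(partitions_equal(base[perm], shuffled))
  }
  # lowering the threshold never increases the number of lineages
  thresholds <- c(0.95, 0.9, 0.85, 0.8, 0.7, 0.5)
  n_lin <- vapply(thresholds, function(t)
    length(unique(cluster_group(js, threshold = t))), integer(1))
  expect_true(all(diff(n_lin) <= 0))
})

test_that("partition_by_key groups by exact normalized V/J/length key", {
  df <- rbind(
    make_rearr(c("ACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTA"),
               v = "IGHV1-69*01"),
    make_rearr(strrep("ACGT", 12), v = "IGHV1-69*02", ids = "x1"),
    make_rearr(strrep("TTTT", 12), v = "IGHV1-69*01", ids = "x2"))
  groups <- partition_by_key(df)
  # lengths 45 and 48 split; alleles *01/*02 of one gene do not
  expect_equal(length(groups), 2)
  sizes <- sort(vapply(groups, nrow, integer(1)))
  expect_equal(unname(sizes), c(1L, 2L))
  expect_equal(length(partition_by_key(df[0, ])), 0)
})

test_that("assign_lineages pools populations and matches generator truth", {
  # a shared junction across two populations forms one spanning lineage
  set.seed(15)
  shared <- rand_junction(36)
  df <- rbind(make_rearr(shared, population = "popA", ids = "a1"),
              make_rearr(shared, population = "popB", ids = "b1"))
  lt <- assign_lineages(df)
  expect_equal(nrow(lt$lineages), 1)
  expect_equal(lt$sizes$n_seq[order(lt$sizes$population)], c(1L, 1L))

  # disjoint keys never span populations
  df2 <- rbind(make_rearr(rand_junction(36), v = "IGHV1-2*02",
                          population = "popA", ids = "a1"),
               make_rearr(rand_junction(36), v = "IGHV4-34*01",
                          population = "popB", ids = "b1"))
  lt2 <- assign_lineages(df2)
  expect_equal(nrow(lt2$lineages), 2)
  expect_equal(nrow(link_table(lt2)), 0)

  expect_error(assign_lineages(rbind(
    make_rearr(rand_junction(30), subject = "S1"),
    make_rearr(rand_junction(30), subject = "S2", ids = "z1"))),
    "subject")

  # recovery of the generator's ground-truth labels
  sim <- simulate_repertoires(sim_config(n_populations = 3, n_lineages = 60,
                                         sharing = 0.5,
                                         sequences_per_population = 400,
                                         seed = 16))
  lt3 <- assign_lineages(sim$rearrangements)
  truth <- sim$truth$sequences$true_lineage[
    match(lt3$assignments$sequence_id, sim$truth$sequences$sequence_id)]
  expect_true(partitions_equal(lt3$assignments$lineage_id, truth))

  # partition property: lineage sizes sum to the pooled total
  expect_equal(sum(lt3$sizes$n_seq), nrow(sim$rearrangements))
  expect_equal(sum(lt3$lineages$n_seq), nrow(sim$rearrangements))
})
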