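# lineage table with prescribed per-population clone sizes, built from
# well-separated junctions so each input junction is its own lineage
sized_table <- function(sizes_by_pop, L = 45) {
  n_lin <- length(sizes_by_pop[[1]])
  founders <- character(n_lin)
  chars <- c("A", "C", "G", "T")
  for (i in seq_len(n_lin)) {
    repeat {
      cand <- rand_junction(L)
      if (i == 1 || all(vapply(founders[seq_len(i - 1)], function(f)
        junction_identity(cand, f) < 0.7, logical(1)))) break
    }
    founders[i] <- cand
  }
  rows <- list()
  k <- 0
  for (p in names(sizes_by_pop)) {
    sz <- sizes_by_pop[[p]]
    for (i in seq_len(n_lin)) {
      if (sz[i] > 0) {
        rows[[length(rows) + 1]] <- make_rearr(
          rep(founders[i], sz[i]), population = p,
          ids = sprintf("s%05d", k + seq_len(sz[i])))
        k <- k + sz[i]
      }
    }
  }
  assign_lineages(do.call(rbind, rows))
}

test_that("rank_profile sorts, normalizes and accumulates correctly", {
  set.seed(21)
  lt <- sized_table(list(pop2 = c(6, 3, 1)))
  prof <- rank_profile(lt, "pop2")
  expect_equal(prof$fraction, c(0.6, 0.3, 0.1))
  expect_equal(prof$cumulative, c(0.6, 0.9, 1.0))
  expect_equal(prof$rank, 1:3)
  # single lineage
  lt1 <- sized_table(list(pop2 = 4))
  expect_equal(rank_profile(lt1, "pop2")$fraction, 1.0)
  expect_error(rank_profile(lt, "nope"), "unknown population")
})

test_that("detect_expanded follows the 0.1pp consecutive-drop rule", {
  # percents (2.0, 1.5, 1.0, 0.95, 0.1) with a flat 0.05% tail:
  # drops (0.5, 0.5, 0.05, 0.85, 0.05, 0...) -> deepest qualifying i = 4
  sizes <- c(40, 30, 20, 19, 2, rep(1, 1889))  # in 0.05% units, sum 2000
  e <- detect_expanded(sizes)
  expect_equal(e$boundary_rank, 4)
  expect_equal(e$lineage_id, as.character(1:4))

  # uniform profile has no qualifying drop
  expect_equal(detect_expanded(rep(1, 10000))$boundary_rank, 0)

  # (50.0, 0.05 x 1000): only the first drop qualifies
  expect_equal(detect_expanded(c(1000, rep(1, 1000)))$boundary_rank, 1)

  # prefix rule stops at the first non-qualifying drop
  e2 <- detect_expanded(sizes, rule = "prefix")
  expect_equal(e2$boundary_rank, 2)

  # the expanded set is always a prefix of the rank order
  set.seed(22)
  for (i in 1:10) {
    sz <- sort(rexp(200, 1) + 0.01, decreasing = TRUE)
    e3 <- detect_expanded(sz)
    if (e3$boundary_rank > 0) {
      expect_equal(e3$lineage_id, as.character(seq_len(e3$boundary_rank)))
    }
  }
})

test_that("morisita_horn matches the formula and its exact limits", {
  set.seed(23)
  lt <- sized_table(list(pop2 = c(5, 3, 2), pop3 = c(5, 3, 2)))
  expect_identical(morisita_horn(lt, "pop2", "pop3"), 1)

  lt_dis <- sized_table(list(pop2 = c(4, 2, 0, 0), pop3 = c(0, 0, 3, 5)))
  expect_identical(morisita_horn(lt_dis, "pop2", "pop3"), 0)

  # p = (0.5, 0.5, 0), q = (1, 0, 0): MH = 2*0.5 / (0.5 + 1) = 2/3
  lt3 <- sized_table(list(pop2 = c(2, 2, 0), pop3 = c(4, 0, 0)))
  expect_equal(morisita_horn(lt3, "pop2", "pop3"), 2 / 3)

  # symmetry
  lt4 <- sized_table(list(pop2 = c(7, 2, 1, 0), pop3 = c(3, 3, 0, 4)))
  expect_equal(morisita_horn(lt4, "pop2", "pop3"),
               morisita_horn(lt4, "pop3", "pop2"))

  # full matrix: symmetric, unit diagonal, values in [0, 1]
  m <- overlap_matrix(lt4)
  expect_equal(m, t(m))
  expect_equal(diag(m), c(pop2 = 1, pop3 = 1))
  expect_true(all(m >= 0 & m <= 1))

  expect_error(morisita_horn(lt4, "pop2", "ghost"), "population")
})

test_that("connectivity counts scoped shared clones, NA on empty scope", {
  set.seed(24)
  # pop3 contains every pop2 lineage -> 100%
  lt <- sized_table(list(pop2 = c(5, 3, 1), pop3 = c(2, 2, 2)))
  expect_equal(connectivity(lt, "pop2", "pop3"), 100)

  # disjoint populations -> 0%
  lt0 <- sized_table(list(pop2 = c(4, 2, 0), pop3 = c(0, 0, 6)))
  expect_equal(connectivity(lt0, "pop2", "pop3"), 0)

  # partial sharing with top_n scope
  lt2 <- sized_table(list(pop2 = c(10, 5, 2, 1), pop3 = c(3, 0, 3, 0)))
  expect_equal(connectivity(lt2, "pop2", "pop3", scope = "top_n", n = 1), 100)
  expect_equal(connectivity(lt2, "pop2", "pop3", scope = "top_n", n = 2), 50)
  expect_equal(connectivity(lt2, "pop2", "pop3", scope = "all"), 50)

  # top_n beyond the available lineages: uses all and flags truncation
  v <- connectivity(lt2, "pop2", "pop3", scope = "top_n", n = 99)
  expect_equal(as.numeric(v), 50)
  expect_true(attr(v, "truncated"))

  # empty expanded scope is NA (missing), not 0
  flat <- sized_table(list(pop2 = rep(2, 5), pop3 = rep(1, 5)))
  expect_warning(ec <- connectivity(flat, "pop2", "pop3", scope = "expanded"),
                 "undefined")
  expect_true(is.na(ec))
})

test_that("sharing_curve evaluates top-n connectivity over the grid", {
  set.seed(25)
  lt <- sized_table(list(pop2 = c(10, 5), pop3 = c(3, 0)))
  sc <- sharing_curve(lt, "pop2", others = "pop3", n_grid = c(1, 2))
  expect_equal(sc$percent, c(100, 50))
  # a population shares 100% with itself at every n
  sc_self <- sharing_curve(lt, "pop2", others = "pop2", n_grid = c(1, 2))
  expect_equal(sc_self$percent, c(100, 100))
})

test_that("link_table emits one row per shared lineage and ordered pair", {
  set.seed(26)
  lt <- sized_table(list(pop2 = c(3, 1), pop3 = c(2, 0)))
  links <- link_table(lt)
  expect_equal(nrow(links), 1)
  expect_equal(links$size_source, 3)
  expect_equal(links$size_target, 2)

  # a lineage in 3 populations yields C(3,2) = 3 link rows
  lt3 <- sized_table(list(pop2 = 2, pop3 = 3, pop4 = 1))
  expect_equal(nrow(link_table(lt3)), 3)

  lt0 <- sized_table(list(pop2 = c(1, 0), pop3 = c(0, 1)))
  expect_equal(nrow(link_table(lt0)), 0)
})

test_that("top_clone_composition traces reference top clones", {
  set.seed(27)
  lt <- sized_table(list(pop2 = c(6, 3, 1, 0), pop3 = c(0, 5, 0, 5)))
  ref <- rank_profile(lt, "pop2")
  other <- rank_profile(lt, "pop3")
  comp <- top_clone_composition(other, ref, n_top = 3)
  expect_equal(nrow(comp), 4)  # 3 clones + remainder
  # reference's top clone is absent from pop3
  expect_equal(comp$fraction[1], 0)
  # its second clone holds 50% of pop3
  expect_equal(comp$fraction[2], 0.5)
  expect_equal(sum(comp$fraction), 1)
  # compared against itself: entries equal own fractions
  self <- top_clone_composition(ref, ref, n_top = 3)
  expect_equal(self$fraction[1:3], ref$fraction[1:3])
})
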