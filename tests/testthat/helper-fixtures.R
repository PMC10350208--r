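# Shared fixtures and independent oracles for the test suite.

# minimal rearrangement data.frame builder
make_rearr <- function(junctions, v = "IGHV1-69*01", j = "IGHJ4*02",
                       population = "pop2", subject = "S1",
                       ids = NULL, dup = 1L, mut = NA_integer_) {
  n <- length(junctions)
  data.frame(
    sequence_id = if (is.null(ids)) sprintf("s%03d", seq_len(n)) else ids,
    v_call = rep_len(v, n), j_call = rep_len(j, n),
    junction = junctions, junction_length = nchar(junctions),
    duplicate_count = rep_len(as.integer(dup), n),
    v_mutation_count = rep_len(as.integer(mut), n),
    population = rep_len(population, n), subject = rep_len(subject, n),
    stringsAsFactors = FALSE)
}

rand_junction <- function(L) {
  paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
}

# a junction differing from `base` at exactly k positions
mutate_k <- function(base, k) {
  ch <- strsplit(base, "")[[1]]
  pos <- sample.int(length(ch), k)
  for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
  paste(ch, collapse = "")
}

# canonical partition labels: label by first occurrence
canon <- function(lab) match(lab, unique(lab))

partitions_equal <- function(a, b) identical(canon(a), canon(b))

# independent single-linkage oracle: explicit all-pairs threshold graph,
# connected components via igraph
brute_components <- function(junctions, threshold = 0.85) {
  n <- length(junctions)
  if (n == 1L) return(1L)
  L <- nchar(junctions[1])
  chars <- do.call(rbind, strsplit(junctions, ""))
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n - 1)) for (jj in seq(i + 1, n)) {
    ident <- sum(chars[i, ] == chars[jj, ]) / L
    # same inclusive boundary as the stated clustering rule
    adj[i, jj] <- adj[jj, i] <- ident >= threshold - 1e-12
  }
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  as.integer(igraph::components(g)$membership)
}

# a random V/J/length group with clustered structure: founders plus
# variants at distances spanning the 85% threshold
random_structured_group <- function(n_founders = 4, variants_per = 8,
                                    L = 30) {
  out <- character(0)
  for (f in seq_len(n_founders)) {
    base <- rand_junction(L)
    k <- sample(0:floor(0.3 * L), variants_per, replace = TRUE)
    out <- c(out, base, vapply(k, function(kk) mutate_k(base, kk),
                               character(1)))
  }
  out
}

# rank profile (as percent sizes) whose consecutive drops are all 0.01 pp
# except an engineered drop `d` between ranks `at` and `at`+1; percents sum
# to 100 so normalization leaves them unchanged
engineered_drop_profile <- function(d, n = 100, at = 3, small = 0.01) {
  drops <- rep(small, n - 1)
  drops[at] <- d
  tail_pct <- (100 - sum(seq_len(n - 1) * drops)) / n
  stopifnot(tail_pct > 0)
  pct <- tail_pct + c(rev(cumsum(rev(drops))), 0)
  pct
}
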