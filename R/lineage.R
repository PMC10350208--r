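#' Pairwise junction identity
#'
#' Fraction of positions at which two equal-length nucleotide junctions
#' carry the same character. This is the similarity that the clonal
#' homology threshold (85\% by default) is applied to. Computed as an exact
#' rational (matching positions / length).
#'
#' @param a,b Nucleotide strings of equal, positive length.
#' @return A fraction in `[0, 1]`; symmetric; `junction_identity(x, x)` is 1.
#' @examples
#' junction_identity("ACGTACGTAC", "ACGTACGTAC")  # 1
#' junction_identity("AAAAAAAAAA", "AAAAAAAAAT")  # 0.9
#' @export
junction_identity <- function(a, b) {
  a <- as.character(a); b <- as.character(b)
  if (length(a) != 1L || length(b) != 1L) {
    stop("junction_identity compares one pair; got vectors", call. = FALSE)
  }
  la <- nchar(a); lb <- nchar(b)
  if (la != lb) {
    stop("length mismatch: junctions of length ", la, " and ", lb,
         " cannot be compared (partition by junction_length first)",
         call. = FALSE)
  }
  if (la == 0L) stop("empty junction", call. = FALSE)
  matches <- sum(charToRaw(a) == charToRaw(b))
  matches / la
}

# Minimum number of matching positions for identity >= threshold at length L.
# ceiling with a small epsilon keeps thresholds like 0.85 * 20 = 17 exact.
.min_matches <- function(threshold, L) {
  as.integer(ceiling(threshold * L - 1e-9))
}

# Union-find with path compression + union by size.
.uf_new <- function(n) list(parent = seq_len(n), size = rep(1L, n))

.uf_find <- function(uf, i) {
  root <- i
  while (uf$parent[root] != root) root <- uf$parent[root]
  while (uf$parent[i] != root) {
    nxt <- uf$parent[i]
    uf$parent[i] <- root
    i <- nxt
  }
  list(uf = uf, root = root)
}

.uf_union <- function(uf, i, j) {
  fi <- .uf_find(uf, i); uf <- fi$uf
  fj <- .uf_find(uf, j); uf <- fj$uf
  ri <- fi$root; rj <- fj$root
  if (ri == rj) return(uf)
  if (uf$size[ri] < uf$size[rj]) { tmp <- ri; ri <- rj; rj <- tmp }
  uf$parent[rj] <- ri
  uf$size[ri] <- uf$size[ri] + uf$size[rj]
  uf
}

# Pairwise match counts between equal-length strings, as an n x n integer
# matrix, via per-base indicator cross-products.
.match_count_matrix <- function(junctions) {
  n <- length(junctions)
  L <- nchar(junctions[1L])
  chars <- matrix(unlist(strsplit(junctions, "", fixed = TRUE), use.names = FALSE),
                  nrow = n, byrow = TRUE)
  M <- matrix(0, n, n)
  for (b in c("A", "C", "G", "T")) {
    ind <- (chars == b) + 0
    M <- M + tcrossprod(ind)
  }
  M
}

#' Single-linkage clustering of equal-length junctions
#'
#' Builds the threshold graph with an edge between every pair of junctions
#' whose identity is at least `threshold` (the boundary is inclusive: a pair
#' at exactly 85\% identity is linked) and returns its connected components
#' as lineage membership labels. Components are labeled `1, 2, ...` in order
#' of their smallest member (by `ids` when given, else by input position),
#' so labels are deterministic and permutation-invariant up to that
#' canonical order.
#'
#' @param junctions Character vector of nucleotide junctions, all of the
#'   same length.
#' @param threshold Identity threshold in `(0, 1]`; default 0.85.
#' @param ids Optional character vector of sequence identifiers used to
#'   canonicalize component label order.
#' @return Integer vector of lineage membership labels, one per junction.
#' @export
cluster_group <- function(junctions, threshold = 0.85, ids = NULL) {
  n <- length(junctions)
  if (n == 0L) return(integer(0))
  stopifnot(threshold > 0, threshold <= 1)
  L <- unique(nchar(junctions))
  if (length(L) != 1L) {
    stop("length mismatch: cluster_group requires equal-length junctions",
         call. = FALSE)
  }
  # collapse duplicate strings first; identical junctions are trivially linked
  uniq <- unique(junctions)
  u <- length(uniq)
  idx <- match(junctions, uniq)
  uf <- .uf_new(u)
  if (u > 1L) {
    need <- .min_matches(threshold, L)
    M <- .match_count_matrix(uniq)
    hits <- which(M >= need & upper.tri(M), arr.ind = TRUE)
    if (nrow(hits) > 0L) {
      for (k in seq_len(nrow(hits))) {
        uf <- .uf_union(uf, hits[k, 1L], hits[k, 2L])
      }
    }
  }
  roots <- integer(u)
  for (i in seq_len(u)) {
    f <- .uf_find(uf, i); uf <- f$uf; roots[i] <- f$root
  }
  comp <- roots[idx]
  # canonical labels: order components by their smallest member
  key <- if (is.null(ids)) seq_len(n) else order(order(as.character(ids)))
  first <- tapply(key, comp, min)
  relabel <- rank(first, ties.method = "first")
  unname(relabel[match(comp, as.integer(names(first)))])
}

#' Partition rearrangements by lineage key
#'
#' Groups pooled rearrangements by the exact lineage key (normalized V gene,
#' normalized J gene, junction length). Two rearrangements fall in the same
#' group if and only if all three components match.
#'
#' @param rearrangements Rearrangement `data.frame` with `v_call`, `j_call`
#'   and `junction_length` columns (calls may still carry alleles; they are
#'   normalized here).
#' @return The input with `v_gene`, `j_gene` and a `.group` key column
#'   added, split into a named list of `data.frame`s, one per key.
#' @export
partition_by_key <- function(rearrangements) {
  if (nrow(rearrangements) == 0L) return(list())
  df <- rearrangements
  df$v_gene <- normalize_gene_call(df$v_call)
  df$j_gene <- normalize_gene_call(df$j_call)
  key <- paste(df$v_gene, df$j_gene, df$junction_length, sep = "|")
  split(df, factor(key, levels = unique(key[order(key)])))
}

#' Assign clonal lineages across the populations of one subject
#'
#' The package's central estimator. Pools all rearrangements of one subject
#' across its sorted populations and partitions them into clonal lineages
#' by the standard heavy-chain rule: members of a lineage share the same V
#' gene, the same J gene, the same junction (CDR3) length, and are
#' connected by single-linkage at `threshold` (default 85\%) nucleotide
#' junction identity. Clustering is joint across populations, so a lineage
#' detected in several populations is one lineage, which is what the
#' connectivity and overlap statistics measure.
#'
#' @param repertoires A single rearrangement `data.frame` (with a
#'   `population` column) or a list of per-population `data.frame`s, all of
#'   one subject, as produced by [read_airr_table()] and
#'   [validate_repertoire()].
#' @param threshold Junction identity threshold in `(0, 1]`; default 0.85.
#'   The boundary is inclusive (identity exactly equal to the threshold
#'   links a pair).
#' @return An object of class `lineage_table`: a list with components
#'   \describe{
#'     \item{assignments}{`data.frame` with one row per rearrangement:
#'       `sequence_id`, `subject`, `population`, `lineage_id`, `v_gene`,
#'       `j_gene`, `junction_length`, `junction`, `duplicate_count`,
#'       `v_mutation_count`.}
#'     \item{lineages}{per-lineage `data.frame`: `lineage_id`, `v_gene`,
#'       `j_gene`, `junction_length`, `n_seq` (unique retained sequences),
#'       `n_dup` (duplicate-weighted size).}
#'     \item{sizes}{long `data.frame` of per-population lineage sizes:
#'       `lineage_id`, `population`, `n_seq`, `n_dup`.}
#'     \item{subject, populations, threshold}{run metadata.}
#'   }
#' @examples
#' sim <- simulate_repertoires(sim_config(n_lineages = 30,
#'   sequences_per_population = 150, seed = 1))
#' lt <- assign_lineages(sim$rearrangements)
#' lt
#' @export
assign_lineages <- function(repertoires, threshold = 0.85) {
  df <- if (is.data.frame(repertoires)) {
    repertoires
  } else {
    do.call(rbind, c(repertoires, list(make.row.names = FALSE)))
  }
  if (nrow(df) == 0L) stop("no rearrangements to assign", call. = FALSE)
  subj <- unique(df$subject)
  if (length(subj) != 1L) {
    stop("mixed subjects in one lineage assignment: ",
         paste(subj, collapse = ", "),
         " (lineages are clustered within a subject only)", call. = FALSE)
  }
  groups <- partition_by_key(df)
  pieces <- vector("list", length(groups))
  offset <- 0L
  for (g in seq_along(groups)) {
    grp <- groups[[g]]
    lab <- cluster_group(grp$junction, threshold = threshold,
                         ids = grp$sequence_id)
    grp$lineage_id <- lab + offset
    offset <- offset + max(lab)
    pieces[[g]] <- grp
  }
  asg <- do.call(rbind, c(pieces, list(make.row.names = FALSE)))
  asg <- asg[order(asg$lineage_id, asg$population, asg$sequence_id), ,
             drop = FALSE]
  rownames(asg) <- NULL
  asg$lineage_id <- sprintf("L%05d", asg$lineage_id)
  keep <- c("sequence_id", "subject", "population", "lineage_id",
            "v_gene", "j_gene", "junction_length", "junction",
            "duplicate_count", "v_mutation_count")
  asg <- asg[, intersect(keep, names(asg)), drop = FALSE]

  sizes <- stats::aggregate(
    cbind(n_seq = rep(1L, nrow(asg)), n_dup = asg$duplicate_count),
    by = list(lineage_id = asg$lineage_id, population = asg$population),
    FUN = sum)
  sizes <- sizes[order(sizes$lineage_id, sizes$population), , drop = FALSE]
  rownames(sizes) <- NULL

  lin <- stats::aggregate(
    cbind(n_seq = rep(1L, nrow(asg)), n_dup = asg$duplicate_count),
    by = list(lineage_id = asg$lineage_id, v_gene = asg$v_gene,
              j_gene = asg$j_gene, junction_length = asg$junction_length),
    FUN = sum)
  lin <- lin[order(lin$lineage_id), , drop = FALSE]
  rownames(lin) <- NULL

  structure(list(assignments = asg, lineages = lin, sizes = sizes,
                 subject = subj,
                 populations = sort(unique(asg$population)),
                 threshold = threshold),
            class = "lineage_table")
}

#' @export
print.lineage_table <- function(x, ...) {
  cat("Clonal lineage table: subject", x$subject, "\n")
  cat(sprintf("  %d rearrangements in %d lineages across %d populations (%s)\n",
              nrow(x$assignments), nrow(x$lineages),
              length(x$populations), paste(x$populations, collapse = ", ")))
  cat(sprintf("  homology threshold: %.0f%% junction identity (single linkage)\n",
              100 * x$threshold))
  invisible(x)
}

#' @export
summary.lineage_table <- function(object, ...) {
  pop_tot <- tapply(object$sizes$n_seq, object$sizes$population, sum)
  pop_lin <- tapply(object$sizes$n_seq > 0, object$sizes$population, sum)
  span <- tapply(object$sizes$population, object$sizes$lineage_id,
                 function(p) length(unique(p)))
  out <- list(
    subject = object$subject,
    threshold = object$threshold,
    n_lineages = nrow(object$lineages),
    populations = data.frame(
      population = names(pop_tot),
      n_sequences = as.integer(pop_tot),
      n_lineages = as.integer(pop_lin),
      row.names = NULL, stringsAsFactors = FALSE),
    n_multi_population = sum(span > 1L),
    largest = utils::head(
      object$lineages[order(-object$lineages$n_seq), , drop = FALSE], 5L)
  )
  class(out) <- "summary.lineage_table"
  out
}

#' @export
print.summary.lineage_table <- function(x, ...) {
  cat("Clonal lineage table: subject", x$subject,
      sprintf("(threshold %.0f%%)\n", 100 * x$threshold))
  cat(sprintf("  %d lineages; %d span more than one population\n",
              x$n_lineages, x$n_multi_population))
  print(x$populations, row.names = FALSE)
  cat("  largest lineages:\n")
  print(x$largest, row.names = FALSE)
  invisible(x)
}

#' Rank-abundance (clonality) plot for a lineage table
#'
#' Draws, per population, the cumulative fraction of sequences against the
#' size-rank of lineages: a strongly clonal repertoire reaches a high
#' cumulative fraction within few top-ranked clones, a polyclonal one rises
#' near-linearly.
#'
#' @param x A `lineage_table`.
#' @param populations Populations to draw; default all.
#' @param ... Further arguments passed to [graphics::plot()].
#' @return Invisibly, `x`.
#' @export
plot.lineage_table <- function(x, populations = x$populations, ...) {
  cols <- grDevices::hcl.colors(max(3L, length(populations)), "Dark 3")
  graphics::plot(NA, xlim = c(1, max(2, max(tapply(
    x$sizes$n_seq > 0, x$sizes$population, sum)))),
    ylim = c(0, 1), log = "x",
    xlab = "lineage rank (descending size)",
    ylab = "cumulative fraction of sequences", ...)
  for (i in seq_along(populations)) {
    prof <- rank_profile(x, populations[i])
    graphics::lines(seq_len(nrow(prof)), prof$cumulative, col = cols[i],
                    lwd = 2)
  }
  graphics::legend("bottomright", legend = populations,
                   col = cols[seq_along(populations)], lwd = 2, bty = "n")
  invisible(x)
}
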