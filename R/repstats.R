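#' Size-ranked clone profile of one population
#'
#' Restricts a lineage table to the lineages detected in one population and
#' ranks them by descending size, reporting each lineage's fraction of the
#' population's sequences and the cumulative fraction — the quantities
#' behind rank-abundance clonality curves. Ties in size are broken by
#' lineage id for determinism.
#'
#' @param table A `lineage_table` from [assign_lineages()].
#' @param population Population label present in the table.
#' @param weighted If `TRUE`, sizes are duplicate-count weighted; the
#'   default counts unique retained sequences.
#' @return A `data.frame` of class `clone_profile` with columns `rank`,
#'   `lineage_id`, `population`, `size`, `fraction`, `cumulative`.
#' @export
rank_profile <- function(table, population, weighted = FALSE) {
  stopifnot(inherits(table, "lineage_table"))
  if (!population %in% table$populations) {
    stop("unknown population: ", population, " (have: ",
         paste(table$populations, collapse = ", "), ")", call. = FALSE)
  }
  s <- table$sizes[table$sizes$population == population, , drop = FALSE]
  size <- if (weighted) s$n_dup else s$n_seq
  s <- s[size > 0, , drop = FALSE]
  size <- size[size > 0]
  ord <- order(-size, s$lineage_id)
  s <- s[ord, , drop = FALSE]
  size <- size[ord]
  total <- sum(size)
  out <- data.frame(
    rank = seq_along(size),
    lineage_id = s$lineage_id,
    population = population,
    size = size,
    fraction = size / total,
    cumulative = cumsum(size) / total,
    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("clone_profile", "data.frame")
  attr(out, "total") <- total
  out
}

#' Composition of one population in terms of another's top clones
#'
#' For the reference population's `n_top` largest clones, reports the
#' fraction each occupies in a second population (0 when absent there),
#' plus the remainder mass, enabling the stacked-bar comparison where the
#' reference's top clones are colored and traced across populations.
#'
#' @param profile `clone_profile` of the population to decompose.
#' @param reference `clone_profile` of the reference population (same
#'   subject).
#' @param n_top Number of reference top clones to trace; default 10.
#' @return A `data.frame` with one row per reference top clone — columns
#'   `lineage_id`, `rank_reference`, `fraction_reference`, `fraction` (in
#'   `profile`'s population) — and a final `remainder` row holding the mass
#'   of `profile` not in those clones.
#' @export
top_clone_composition <- function(profile, reference, n_top = 10L) {
  stopifnot(inherits(profile, "clone_profile"),
            inherits(reference, "clone_profile"))
  if (n_top < 1L) stop("n_top must be >= 1", call. = FALSE)
  top <- utils::head(reference, n_top)
  m <- match(top$lineage_id, profile$lineage_id)
  frac <- ifelse(is.na(m), 0, profile$fraction[m])
  out <- data.frame(
    lineage_id = c(top$lineage_id, "remainder"),
    rank_reference = c(top$rank, NA_integer_),
    fraction_reference = c(top$fraction, 1 - sum(top$fraction)),
    fraction = c(frac, 1 - sum(frac)),
    row.names = NULL, stringsAsFactors = FALSE)
  out
}

#' Detect abnormally expanded clones by the rank-drop rule
#'
#' Scans the size-ranked clone fractions, expressed in percent of the
#' repertoire, for consecutive-rank drops of at least `threshold_pp`
#' percentage points (default 0.1). Under the default `"deepest"` rule the
#' expanded set is the prefix of ranks up to the LAST (deepest) qualifying
#' drop — the visual elbow of the rank plot; under `"prefix"` it is the
#' maximal prefix over which every consecutive drop qualifies. Only
#' observed consecutive pairs are scanned (no virtual clone of size 0 is
#' appended). If no drop qualifies the expanded set is empty.
#'
#' @param profile A `clone_profile`, or a numeric vector of clone sizes
#'   (any positive measure; it is normalized internally and treated as
#'   already size-ranked after sorting descending).
#' @param threshold_pp Drop threshold in percentage points; default 0.1.
#' @param rule `"deepest"` (default) or `"prefix"`; see Details.
#' @return A list of class `expanded_set`: `population`, `threshold_pp`,
#'   `rule`, `boundary_rank` (0 when empty), `lineage_id` (character vector
#'   of expanded clones, a prefix of the rank order), `fractions`.
#' @export
detect_expanded <- function(profile, threshold_pp = 0.1,
                            rule = c("deepest", "prefix")) {
  rule <- match.arg(rule)
  if (inherits(profile, "clone_profile")) {
    fractions <- profile$fraction
    ids <- profile$lineage_id
    population <- profile$population[1L]
  } else {
    sizes <- sort(as.numeric(profile), decreasing = TRUE)
    if (length(sizes) == 0L || any(sizes < 0)) {
      stop("profile must be a clone_profile or non-negative sizes",
           call. = FALSE)
    }
    fractions <- sizes / sum(sizes)
    ids <- as.character(seq_along(fractions))
    population <- NA_character_
  }
  pct <- 100 * fractions
  n <- length(pct)
  boundary <- 0L
  if (n >= 2L) {
    drops <- pct[-n] - pct[-1L]
    qual <- drops >= threshold_pp - 1e-9
    if (any(qual)) {
      boundary <- if (rule == "deepest") max(which(qual)) else {
        if (qual[1L]) max(which(cumsum(!qual) == 0L)) else 0L
      }
    }
  }
  structure(list(population = population,
                 threshold_pp = threshold_pp,
                 rule = rule,
                 boundary_rank = boundary,
                 lineage_id = ids[seq_len(boundary)],
                 fractions = fractions[seq_len(boundary)]),
            class = "expanded_set")
}

#' @export
print.expanded_set <- function(x, ...) {
  cat(sprintf("Expanded clones (%s rule, drop >= %.2f pp): %d clone(s)",
              x$rule, x$threshold_pp, x$boundary_rank))
  if (!is.na(x$population)) cat(" in", x$population)
  cat("\n")
  invisible(x)
}

# per-lineage fraction vectors of two populations over the union of lineages
.fraction_vectors <- function(table, popA, popB, weighted = FALSE) {
  for (p in c(popA, popB)) {
    if (!p %in% table$populations) {
      stop("unknown or empty population: ", p, call. = FALSE)
    }
  }
  s <- table$sizes
  col <- if (weighted) "n_dup" else "n_seq"
  a <- s[s$population == popA, , drop = FALSE]
  b <- s[s$population == popB, , drop = FALSE]
  ids <- sort(unique(c(a$lineage_id, b$lineage_id)))
  x <- numeric(length(ids)); x[match(a$lineage_id, ids)] <- a[[col]]
  y <- numeric(length(ids)); y[match(b$lineage_id, ids)] <- b[[col]]
  list(p = x / sum(x), q = y / sum(y), x = x, y = y)
}

#' Morisita overlap between two populations
#'
#' Similarity of two clonal repertoires as a value from 0 (no shared
#' lineages) to 1 (identical repertoire). The default is the Morisita-Horn
#' form on per-lineage fraction vectors \eqn{p, q} over the union of
#' lineages, \deqn{MH = 2 \sum_i p_i q_i / (\sum_i p_i^2 + \sum_i q_i^2),}
#' which is exactly 1 for identical fraction vectors and exactly 0 for
#' disjoint lineage sets. The classical Morisita index on integer counts is
#' available via `variant = "classical"`.
#'
#' @param table A `lineage_table`.
#' @param popA,popB Population labels.
#' @param variant `"horn"` (default) or `"classical"`.
#' @param weighted Use duplicate-weighted counts; default `FALSE`.
#' @return A number in `[0, 1]` (the classical variant can slightly exceed
#'   1 on small samples); symmetric in its population arguments.
#' @export
morisita_horn <- function(table, popA, popB,
                          variant = c("horn", "classical"),
                          weighted = FALSE) {
  stopifnot(inherits(table, "lineage_table"))
  variant <- match.arg(variant)
  v <- .fraction_vectors(table, popA, popB, weighted = weighted)
  if (variant == "horn") {
    num <- 2 * sum(v$p * v$q)
    den <- sum(v$p * v$p) + sum(v$q * v$q)
    num / den
  } else {
    X <- sum(v$x); Y <- sum(v$y)
    lx <- sum(v$x * (v$x - 1)) / (X * (X - 1))
    ly <- sum(v$y * (v$y - 1)) / (Y * (Y - 1))
    2 * sum(v$x * v$y) / ((lx + ly) * X * Y)
  }
}

#' Pairwise Morisita overlap matrix
#'
#' @param table A `lineage_table`.
#' @param populations Populations to include; default all in the table.
#' @inheritParams morisita_horn
#' @return A symmetric numeric matrix with unit diagonal, dimnames the
#'   population labels.
#' @export
overlap_matrix <- function(table, populations = table$populations,
                           variant = c("horn", "classical"),
                           weighted = FALSE) {
  variant <- match.arg(variant)
  k <- length(populations)
  m <- diag(1, k)
  dimnames(m) <- list(populations, populations)
  if (k >= 2L) {
    for (i in seq_len(k - 1L)) {
      for (j in seq((i + 1L), k)) {
        v <- morisita_horn(table, populations[i], populations[j],
                           variant = variant, weighted = weighted)
        m[i, j] <- v
        m[j, i] <- v
      }
    }
  }
  m
}

# lineage ids of a population restricted to a scope; NULL means undefined
.scoped_lineages <- function(table, ref, scope, n = NULL,
                             threshold_pp = 0.1) {
  prof <- rank_profile(table, ref)
  switch(scope,
    all = prof$lineage_id,
    expanded = detect_expanded(prof, threshold_pp = threshold_pp)$lineage_id,
    top_n = {
      if (is.null(n) || n < 1L) {
        stop("scope = \"top_n\" requires n >= 1", call. = FALSE)
      }
      if (n > nrow(prof)) {
        # fewer lineages than requested: use all, flag via attribute
        structure(prof$lineage_id, truncated = TRUE)
      } else {
        prof$lineage_id[seq_len(n)]
      }
    },
    stop("unknown scope: ", scope, call. = FALSE))
}

#' Inter-population clonal connectivity
#'
#' Percentage of a reference population's clones — optionally restricted to
#' its expanded set or its top-`n` largest clones — that are also detected
#' (size > 0 by unique-sequence count) in another population of the same
#' subject. An empty scope (e.g. no expanded clones) yields `NA` with a
#' warning: undefined connectivity is reported as missing, never as 0.
#'
#' @param table A `lineage_table`.
#' @param ref Reference population label.
#' @param other Comparison population label.
#' @param scope `"all"`, `"expanded"`, or `"top_n"`.
#' @param n Number of top clones when `scope = "top_n"`; if fewer exist,
#'   all are used and the result carries attribute `truncated = TRUE`.
#' @param threshold_pp Expanded-set drop threshold, for `scope = "expanded"`.
#' @return Percent in `[0, 100]`, or `NA` for an empty scope.
#' @export
connectivity <- function(table, ref, other,
                         scope = c("all", "expanded", "top_n"),
                         n = NULL, threshold_pp = 0.1) {
  stopifnot(inherits(table, "lineage_table"))
  scope <- match.arg(scope)
  scoped <- .scoped_lineages(table, ref, scope, n = n,
                             threshold_pp = threshold_pp)
  if (length(scoped) == 0L) {
    warning("empty ", scope, " scope for ", ref,
            ": connectivity undefined, returning NA", call. = FALSE)
    return(NA_real_)
  }
  present <- rank_profile(table, other)$lineage_id
  out <- 100 * sum(scoped %in% present) / length(scoped)
  if (isTRUE(attr(scoped, "truncated"))) attr(out, "truncated") <- TRUE
  out
}

#' Shared-clone curve over top-n grids
#'
#' For each grid value `n` and each comparison population, the percent of
#' the reference population's `n` largest clones also found in that
#' population — the clonal-relatedness curves plotted against the number of
#' top clones considered.
#'
#' @param table A `lineage_table`.
#' @param ref Reference population.
#' @param others Comparison populations; default all other populations.
#' @param n_grid Ascending positive integers; default `c(5, 10, 25, 50, 100)`.
#' @return A `data.frame` with columns `ref`, `other`, `n`, `percent`,
#'   `truncated`.
#' @export
sharing_curve <- function(table, ref, others = setdiff(table$populations, ref),
                          n_grid = c(5L, 10L, 25L, 50L, 100L)) {
  stopifnot(all(n_grid >= 1L), !is.unsorted(n_grid))
  rows <- expand.grid(other = others, n = n_grid,
                      stringsAsFactors = FALSE)
  pct <- numeric(nrow(rows))
  trunc <- logical(nrow(rows))
  for (i in seq_len(nrow(rows))) {
    v <- connectivity(table, ref, rows$other[i], scope = "top_n",
                      n = rows$n[i])
    pct[i] <- as.numeric(v)
    trunc[i] <- isTRUE(attr(v, "truncated"))
  }
  data.frame(ref = ref, other = rows$other, n = rows$n, percent = pct,
             truncated = trunc, row.names = NULL, stringsAsFactors = FALSE)
}

#' Circos-style link table of shared lineages
#'
#' One row per (lineage, ordered population pair) in which the lineage is
#' detected in both populations, with both population sizes — the input for
#' chord/Circos renderings of inter-population clonal interconnectedness.
#'
#' @param table A `lineage_table` with at least two populations.
#' @return A `data.frame` with columns `source_pop`, `target_pop`,
#'   `lineage_id`, `size_source`, `size_target`.
#' @export
link_table <- function(table) {
  stopifnot(inherits(table, "lineage_table"))
  pops <- table$populations
  if (length(pops) < 2L) {
    stop("link_table needs at least two populations", call. = FALSE)
  }
  s <- table$sizes[table$sizes$n_seq > 0, , drop = FALSE]
  out <- list()
  for (i in seq_len(length(pops) - 1L)) {
    for (j in seq((i + 1L), length(pops))) {
      a <- s[s$population == pops[i], , drop = FALSE]
      b <- s[s$population == pops[j], , drop = FALSE]
      shared <- intersect(a$lineage_id, b$lineage_id)
      if (length(shared) > 0L) {
        out[[length(out) + 1L]] <- data.frame(
          source_pop = pops[i], target_pop = pops[j],
          lineage_id = shared,
          size_source = a$n_seq[match(shared, a$lineage_id)],
          size_target = b$n_seq[match(shared, b$lineage_id)],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(source_pop = character(0), target_pop = character(0),
                      lineage_id = character(0),
                      size_source = integer(0), size_target = integer(0),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$source_pop, res$target_pop, res$lineage_id), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}
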