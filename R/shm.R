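#' Somatic hypermutation load per population
#'
#' Location and spread statistics of the per-sequence V-region mutation
#' count, per population. Mutation counts are taken from the input
#' `v_mutation_count` column (assigned upstream by germline alignment),
#' never recomputed from sequence; statistics use only sequences with
#' non-missing counts, and a population with no mutation data is reported
#' with `NA` statistics rather than dropped.
#'
#' @param table A `lineage_table` from [assign_lineages()].
#' @param populations Populations to summarize; default all in the table.
#' @return A `data.frame` with columns `population`, `n_sequences`,
#'   `mean`, `median`, `q1`, `q3` (quartiles type 7).
#' @export
shm_load <- function(table, populations = table$populations) {
  stopifnot(inherits(table, "lineage_table"))
  asg <- table$assignments
  rows <- lapply(populations, function(p) {
    mut <- asg$v_mutation_count[asg$population == p]
    mut <- mut[!is.na(mut)]
    if (length(mut) == 0L) {
      data.frame(population = p, n_sequences = 0L, mean = NA_real_,
                 median = NA_real_, q1 = NA_real_, q3 = NA_real_,
                 stringsAsFactors = FALSE)
    } else {
      q <- stats::quantile(mut, c(0.25, 0.5, 0.75), names = FALSE)
      data.frame(population = p, n_sequences = length(mut),
                 mean = mean(mut), median = q[2L], q1 = q[1L], q3 = q[3L],
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# mean pairwise hamming distance among equal-length junctions
.mean_pairwise_mismatches <- function(junctions) {
  n <- length(junctions)
  if (n < 2L) return(NA_real_)
  L <- nchar(junctions[1L])
  M <- .match_count_matrix(junctions)
  mism <- L - M[upper.tri(M)]
  mean(mism)
}

#' Intraclonal divergence within multi-member lineages
#'
#' For every lineage with at least two members, reports the mean pairwise
#' junction distance (nucleotide mismatches), the range of V-region
#' mutation counts across members, and flags the lineage as divergent when
#' that range exceeds `cutoff`. A wide within-lineage mutation-count range
#' is the operational sign of sequential mutation progression; its cutoff
#' (default 5 mutations) is a tool parameter, not a literature value.
#' Singleton lineages are excluded, never zero-filled. Per-population mean
#' mutation counts within each lineage are attached as the
#' `"by_population"` attribute (a long `data.frame`).
#'
#' @param table A `lineage_table`.
#' @param cutoff Mutation-count range above which a lineage is flagged;
#'   default 5.
#' @return A `data.frame` with columns `lineage_id`, `n_members`,
#'   `mean_pairwise_mismatches`, `mutation_range` (`NA` when no member has
#'   mutation data), `divergent`.
#' @export
intraclonal_divergence <- function(table, cutoff = 5L) {
  stopifnot(inherits(table, "lineage_table"))
  asg <- table$assignments
  counts <- base::table(asg$lineage_id)
  multi <- names(counts)[counts >= 2L]
  if (length(multi) == 0L) {
    out <- data.frame(lineage_id = character(0), n_members = integer(0),
                      mean_pairwise_mismatches = numeric(0),
                      mutation_range = numeric(0), divergent = logical(0),
                      stringsAsFactors = FALSE)
    attr(out, "by_population") <- data.frame(
      lineage_id = character(0), population = character(0),
      mean_mutations = numeric(0), stringsAsFactors = FALSE)
    return(out)
  }
  rows <- vector("list", length(multi))
  bypop <- vector("list", length(multi))
  for (i in seq_along(multi)) {
    lid <- multi[i]
    mem <- asg[asg$lineage_id == lid, , drop = FALSE]
    mut <- mem$v_mutation_count[!is.na(mem$v_mutation_count)]
    mrange <- if (length(mut) > 0L) diff(range(mut)) else NA_real_
    rows[[i]] <- data.frame(
      lineage_id = lid, n_members = nrow(mem),
      mean_pairwise_mismatches = .mean_pairwise_mismatches(mem$junction),
      mutation_range = as.numeric(mrange),
      divergent = !is.na(mrange) && mrange > cutoff,
      stringsAsFactors = FALSE)
    withdata <- mem[!is.na(mem$v_mutation_count), , drop = FALSE]
    if (nrow(withdata) > 0L) {
      mm <- tapply(withdata$v_mutation_count, withdata$population, mean)
      bypop[[i]] <- data.frame(lineage_id = lid, population = names(mm),
                               mean_mutations = as.numeric(mm),
                               stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  bp <- do.call(rbind, bypop[!vapply(bypop, is.null, logical(1L))])
  if (is.null(bp)) {
    bp <- data.frame(lineage_id = character(0), population = character(0),
                     mean_mutations = numeric(0), stringsAsFactors = FALSE)
  }
  rownames(bp) <- NULL
  attr(out, "by_population") <- bp
  out
}
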