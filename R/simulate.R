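# Built-in gene catalogs. Calls carry allele suffixes, and some V entries
# list several comma-separated candidates, so downstream normalization is
# always exercised. Usage frequencies are uniform by design: the generator
# emulates clonal structure, not biological gene usage.
.V_CATALOG <- c("IGHV1-69*01", "IGHV1-2*02", "IGHV3-23*04, IGHV3-23D*01",
                "IGHV3-30*18", "IGHV4-34*01", "IGHV4-59*01",
                "IGHV5-51*01", "IGHV6-1*01")
.J_CATALOG <- c("IGHJ3*02", "IGHJ4*02", "IGHJ5*02", "IGHJ6*03")

#' Simulation configuration for synthetic multi-population repertoires
#'
#' Collects and checks the generator's parameters. Defaults mirror the
#' study design being emulated: four sorted ASC populations labeled
#' pop2-pop5, a sequencing depth of about 50,000 sequences per population,
#' heavy-tailed (Zipf) clone sizes, CDR3 junction lengths that are
#' multiples of 3 between 30 and 66 nt, and within-lineage variants
#' confined to a mutation radius of `floor(0.075 * L)` positions from the
#' lineage founder — so any two variants of one lineage have identity at
#' least 85\%, exactly the clonal clustering threshold, while founders of
#' distinct lineages sharing a V/J/length key are kept below 70\% identity.
#'
#' @param n_populations Number of populations (default 4, labeled
#'   `pop2`..`pop5`; the first label is the base population that contains
#'   every lineage).
#' @param n_lineages Number of clonal lineages per population (default
#'   100). The base population's lineages are shared into additional
#'   populations according to `sharing`; each additional population is
#'   topped up with private lineages so it holds `n_lineages` in total.
#' @param sharing Probability that a base-population lineage is also
#'   present in any given additional population: a single number in
#'   `[0, 1]`, or a vector with one probability per additional population.
#'   The expected connectivity from the base population to an additional
#'   one is therefore `100 * sharing` percent.
#' @param sequences_per_population Target sequencing depth per population
#'   (default 50000; scale down for quick runs).
#' @param zipf_alpha Exponent of the Zipf clone-size law (default 1.5).
#' @param junction_lengths Support of junction lengths in nt; default
#'   multiples of 3 in `[30, 66]`.
#' @param shm_lambda Poisson mean of the per-lineage V-mutation load
#'   (default 8).
#' @param shm_jitter Standard deviation of the per-sequence mutation-count
#'   jitter around the lineage base (default 1; 0 gives zero-jitter mode,
#'   in which all members of a lineage carry identical counts).
#' @param identical_populations If `TRUE`, every lineage is placed in every
#'   population with identical per-lineage counts (identical fraction
#'   vectors; pairwise Morisita overlap 1). Default `FALSE`.
#' @param subject Subject label (default `"S1"`).
#' @param seed Integer seed; the generator is deterministic given the
#'   configuration and seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_populations = 4L,
                       n_lineages = 100L,
                       sharing = 0.3,
                       sequences_per_population = 50000L,
                       zipf_alpha = 1.5,
                       junction_lengths = seq(30L, 66L, by = 3L),
                       shm_lambda = 8,
                       shm_jitter = 1,
                       identical_populations = FALSE,
                       subject = "S1",
                       seed = NULL) {
  stopifnot(n_populations >= 1L, n_lineages >= 1L,
            all(sharing >= 0), all(sharing <= 1),
            sequences_per_population >= n_lineages,
            zipf_alpha > 0, all(junction_lengths > 0),
            shm_lambda >= 0, shm_jitter >= 0)
  if (!length(sharing) %in% c(1L, max(1L, n_populations - 1L))) {
    stop("sharing must be a single probability or one per additional ",
         "population", call. = FALSE)
  }
  structure(list(
    n_populations = as.integer(n_populations),
    populations = paste0("pop", seq(2L, length.out = n_populations)),
    n_lineages = as.integer(n_lineages),
    sharing = sharing,
    sequences_per_population = as.integer(sequences_per_population),
    zipf_alpha = zipf_alpha,
    junction_lengths = as.integer(junction_lengths),
    shm_lambda = shm_lambda,
    shm_jitter = shm_jitter,
    identical_populations = isTRUE(identical_populations),
    subject = subject,
    seed = seed), class = "sim_config")
}

.random_junction <- function(L) {
  paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
}

# mutate exactly m distinct positions of `founder` to a different base
.mutate_junction <- function(founder_chars, m) {
  if (m == 0L) return(paste(founder_chars, collapse = ""))
  pos <- sample.int(length(founder_chars), m)
  for (p in pos) {
    founder_chars[p] <- sample(setdiff(c("A", "C", "G", "T"),
                                       founder_chars[p]), 1L)
  }
  paste(founder_chars, collapse = "")
}

# integer sizes summing ~ total, proportional to rank^(-alpha), all >= 1
.zipf_sizes <- function(n_clones, total, alpha) {
  w <- seq_len(n_clones)^(-alpha)
  w <- w / sum(w)
  sz <- floor(w * total)
  rem <- total - sum(sz)
  if (rem > 0) {
    extra <- order(w * total - sz, decreasing = TRUE)[seq_len(rem)]
    sz[extra] <- sz[extra] + 1L
  }
  pmax(sz, 1L)
}

#' Generate synthetic multi-population AIRR repertoires with ground truth
#'
#' Emits rearrangement tables for the configured populations together with
#' the generating truth (per-sequence lineage labels, per-lineage keys,
#' founders and population membership), so every downstream stage can be
#' validated against a known answer. Lineage founders are drawn per
#' V/J/length key with rejection sampling until all same-key founder pairs
#' are below 70\% identity; within-lineage variants mutate at most
#' `floor(0.075 * L)` positions of the founder. These margins guarantee
#' that single-linkage clustering at the 85\% threshold recovers the true
#' lineages exactly.
#'
#' @param config A [sim_config()].
#' @param out_dir Optional directory; when given, one AIRR TSV per
#'   population plus `truth.tsv` are written there.
#' @return A list of class `sim_result`:
#'   \describe{
#'     \item{rearrangements}{pooled rearrangement `data.frame` (AIRR
#'       columns plus `population` and `subject`).}
#'     \item{truth}{list with `sequences` (sequence_id, population,
#'       true_lineage), `lineages` (true_lineage, v_call, j_call,
#'       junction_length, founder, populations as comma-joined labels),
#'       and `sizes` (realized per-population clone sizes).}
#'     \item{config}{the configuration used.}
#'   }
#' @export
simulate_repertoires <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  pops <- config$populations
  nl <- config$n_lineages
  share <- if (length(config$sharing) == 1L) {
    rep(config$sharing, max(0L, length(pops) - 1L))
  } else config$sharing

  # population membership. The base (first) population carries all
  # `n_lineages` configured lineages; each additional population shares
  # each of them independently with probability s, topped up with private
  # lineages of its own so that every population holds `n_lineages`
  # lineages regardless of s (a population with s = 0 is still a full
  # repertoire, just a disjoint one).
  base_member <- matrix(FALSE, nl, length(pops), dimnames = list(NULL, pops))
  base_member[, 1L] <- TRUE
  if (length(pops) > 1L) {
    for (p in seq(2L, length(pops))) {
      base_member[, p] <- if (config$identical_populations) TRUE else
        stats::runif(nl) < share[p - 1L]
    }
  }
  priv_rows <- list()
  if (length(pops) > 1L && !config$identical_populations) {
    for (p in seq(2L, length(pops))) {
      n_priv <- nl - sum(base_member[, p])
      if (n_priv > 0L) {
        m <- matrix(FALSE, n_priv, length(pops))
        m[, p] <- TRUE
        priv_rows[[length(priv_rows) + 1L]] <- m
      }
    }
  }
  member <- do.call(rbind, c(list(base_member), priv_rows))
  colnames(member) <- pops
  n_total <- nrow(member)

  # lineage keys and founders with the <70% same-key identity margin
  v_call <- sample(.V_CATALOG, n_total, replace = TRUE)
  j_call <- sample(.J_CATALOG, n_total, replace = TRUE)
  jlen <- sample(config$junction_lengths, n_total, replace = TRUE)
  key <- paste(normalize_gene_call(v_call), normalize_gene_call(j_call),
               jlen, sep = "|")
  nl <- n_total
  founder <- character(nl)
  for (i in seq_len(nl)) {
    L <- jlen[i]
    existing <- founder[seq_len(i - 1L)][key[seq_len(i - 1L)] == key[i]]
    ok <- FALSE
    for (try in seq_len(200L)) {
      cand <- .random_junction(L)
      sep_ok <- all(vapply(existing, function(e)
        junction_identity(cand, e) < 0.70, logical(1L)))
      if (sep_ok) { founder[i] <- cand; ok <- TRUE; break }
    }
    if (!ok) {
      stop("infeasible simulation config: cannot place ",
           "lineage founders below 70% identity within key ", key[i],
           "; use longer junction lengths or fewer lineages",
           call. = FALSE)
    }
  }

  # one mutation base per lineage: members share it across populations
  lineage_base_mut <- stats::rpois(nl, config$shm_lambda)

  shared_sizes <- NULL
  seq_rows <- list()
  truth_rows <- list()
  counter <- 0L
  for (p in seq_along(pops)) {
    mem <- which(member[, p])
    if (length(mem) == 0L) next
    if (config$identical_populations) {
      if (is.null(shared_sizes)) {
        shared_sizes <- .zipf_sizes(length(mem),
                                    config$sequences_per_population,
                                    config$zipf_alpha)
      }
      sizes <- shared_sizes
      ord <- mem  # same lineage order in every population
    } else {
      ord <- sample(mem)  # which lineage is large differs per population
      sizes <- .zipf_sizes(length(ord), config$sequences_per_population,
                           config$zipf_alpha)
    }
    for (k in seq_along(ord)) {
      lid <- ord[k]
      n <- sizes[k]
      L <- jlen[lid]
      radius <- floor(0.075 * L)
      fchars <- strsplit(founder[lid], "", fixed = TRUE)[[1L]]
      m <- sample.int(radius + 1L, n, replace = TRUE) - 1L
      junctions <- vapply(m, function(mm) .mutate_junction(fchars, mm),
                          character(1L))
      ids <- sprintf("%s_%s_seq%06d", config$subject, pops[p],
                     counter + seq_len(n))
      counter <- counter + n
      base_mut <- lineage_base_mut[lid]
      mut <- if (config$shm_jitter > 0) {
        pmax(0L, base_mut + as.integer(round(
          stats::rnorm(n, 0, config$shm_jitter))))
      } else rep(base_mut, n)
      seq_rows[[length(seq_rows) + 1L]] <- data.frame(
        sequence_id = ids,
        v_call = v_call[lid], j_call = j_call[lid],
        junction = junctions, junction_length = L,
        duplicate_count = 1L + stats::rpois(n, 0.3),
        v_mutation_count = mut,
        population = pops[p], subject = config$subject,
        stringsAsFactors = FALSE)
      truth_rows[[length(truth_rows) + 1L]] <- data.frame(
        sequence_id = ids, population = pops[p],
        true_lineage = sprintf("T%05d", lid),
        stringsAsFactors = FALSE)
    }
  }
  rearr <- do.call(rbind, c(seq_rows, list(make.row.names = FALSE)))
  truth_seq <- do.call(rbind, c(truth_rows, list(make.row.names = FALSE)))

  realized <- stats::aggregate(
    cbind(n_seq = rep(1L, nrow(truth_seq))),
    by = list(true_lineage = truth_seq$true_lineage,
              population = truth_seq$population), FUN = sum)
  realized <- realized[order(realized$true_lineage, realized$population), ,
                       drop = FALSE]
  rownames(realized) <- NULL

  truth_lin <- data.frame(
    true_lineage = sprintf("T%05d", seq_len(nl)),
    v_call = v_call, j_call = j_call, junction_length = jlen,
    founder = founder,
    populations = apply(member, 1L, function(r)
      paste(pops[r], collapse = ",")),
    stringsAsFactors = FALSE)

  out <- structure(list(
    rearrangements = rearr,
    truth = list(sequences = truth_seq, lineages = truth_lin,
                 sizes = realized),
    config = config), class = "sim_result")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (p in pops) {
      write_airr_table(rearr[rearr$population == p, , drop = FALSE],
                       file.path(out_dir, paste0(p, ".tsv")))
    }
    write_airr_table(merge(truth_seq, truth_lin, by = "true_lineage",
                           sort = FALSE)[, c("sequence_id", "population",
                                             "true_lineage", "v_call",
                                             "j_call", "junction_length",
                                             "founder")],
                     file.path(out_dir, "truth.tsv"))
  }
  out
}

#' @export
print.sim_result <- function(x, ...) {
  cat("Synthetic repertoire:", nrow(x$rearrangements), "sequences,",
      nrow(x$truth$lineages), "true lineages,",
      length(x$config$populations), "populations\n")
  invisible(x)
}

#' Ground-truth connectivity between two populations
#'
#' The generator-side analogue of [connectivity()] with `scope = "all"`:
#' the percentage of the reference population's true lineages that are also
#' present in the other population, computed from the truth labels. Used as
#' the oracle in recovery tests.
#'
#' @param truth The `truth` component of a [simulate_repertoires()] result.
#' @param ref,other Population labels.
#' @return Percent in `[0, 100]`.
#' @export
truth_connectivity <- function(truth, ref, other) {
  sz <- truth$sizes
  in_ref <- unique(sz$true_lineage[sz$population == ref])
  if (length(in_ref) == 0L) {
    stop("population not present in truth: ", ref, call. = FALSE)
  }
  in_other <- unique(sz$true_lineage[sz$population == other])
  100 * sum(in_ref %in% in_other) / length(in_ref)
}

#' Junction pairs at the clustering decision boundary
#'
#' Constructs, for a given junction length, one pair of junctions at
#' identity exactly equal to the threshold (which must co-cluster under the
#' inclusive boundary rule) and one pair one mismatch below it (which must
#' not). Used to probe the boundary behavior of [cluster_group()].
#'
#' @param L Junction length; `threshold * L` should be an integer for an
#'   exact at-threshold pair (e.g. `L = 60` at 0.85).
#' @param threshold Identity threshold; default 0.85.
#' @return A list with elements `at` and `below`, each a character vector
#'   of two junctions, plus the realized identities as attributes.
#' @export
boundary_pairs <- function(L = 60L, threshold = 0.85) {
  base <- .random_junction(L)
  chars <- strsplit(base, "", fixed = TRUE)[[1L]]
  matches_at <- as.integer(ceiling(threshold * L - 1e-9))
  make_pair <- function(n_mismatch) {
    .mutate_junction(chars, n_mismatch)
  }
  at <- c(base, make_pair(L - matches_at))
  below <- c(base, make_pair(L - matches_at + 1L))
  out <- list(at = at, below = below)
  attr(out, "identity_at") <- junction_identity(at[1L], at[2L])
  attr(out, "identity_below") <- junction_identity(below[1L], below[2L])
  out
}

#' Inject malformed rows into a repertoire
#'
#' Corruption mode for exercising [validate_repertoire()]: replaces bases
#' with `N` in `n_non_acgt` rows and corrupts the stored junction length in
#' `n_bad_length` further rows.
#'
#' @param rep Rearrangement `data.frame`.
#' @param n_non_acgt Rows to receive an `N` in the junction.
#' @param n_bad_length Rows to receive an inconsistent `junction_length`.
#' @return The corrupted `data.frame`, with attribute `corrupted_rows`
#'   (integer indices, in the order non-ACGT then bad-length).
#' @export
corrupt_repertoire <- function(rep, n_non_acgt = 1L, n_bad_length = 0L) {
  n_bad <- n_non_acgt + n_bad_length
  stopifnot(n_bad <= nrow(rep))
  idx <- sample.int(nrow(rep), n_bad)
  i_n <- idx[seq_len(n_non_acgt)]
  for (i in i_n) {
    j <- rep$junction[i]
    pos <- sample.int(nchar(j), 1L)
    substr(j, pos, pos) <- "N"
    rep$junction[i] <- j
  }
  if (n_bad_length > 0L) {
    i_l <- idx[n_non_acgt + seq_len(n_bad_length)]
    rep$junction_length[i_l] <- rep$junction_length[i_l] + 1L
  }
  attr(rep, "corrupted_rows") <- idx
  rep
}
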