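.stage <- function(name, quiet, expr) {
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(force(expr), error = function(e) {
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
  })
  if (!quiet) {
    message(sprintf("[ascrep] %-10s %6.2fs", name,
                    proc.time()[["elapsed"]] - t0))
  }
  res
}

#' Run the full repertoire pipeline
#'
#' Orchestrates simulate/read, validate, lineage assignment, clonality and
#' overlap statistics, and SHM summaries as one reproducible run. All
#' derived tables are written as TSV under `out_dir` together with a
#' machine-readable `report.json` that records the resolved configuration,
#' package version, per-population sequence and lineage counts,
#' expanded-set sizes, the Morisita overlap matrix, connectivity at every
#' scope, and the SHM summaries. Runs with identical configuration, inputs
#' and seed produce byte-identical reports.
#'
#' @param input Input rearrangements: a pooled `data.frame` (with
#'   `population` and `subject` columns), or a character vector of AIRR TSV
#'   paths (named by population; unnamed paths use the file name without
#'   extension as the population label). Ignored when `sim` is given.
#' @param sim Optional [sim_config()]; when given, input data are simulated.
#' @param out_dir Output directory, created if needed.
#' @param threshold Clonal homology threshold (default 0.85).
#' @param expanded_pp Expanded-clone drop threshold in percentage points
#'   (default 0.1).
#' @param top_n Grid of top-clone counts for sharing curves
#'   (default `c(5, 10, 25, 50, 100)`).
#' @param seed Seed applied before simulation when `sim` carries none.
#' @param quiet Suppress per-stage timing messages (default `TRUE`).
#' @return Invisibly, the report as a named list (also written as JSON).
#' @export
run_pipeline <- function(input = NULL, sim = NULL, out_dir,
                         threshold = 0.85, expanded_pp = 0.1,
                         top_n = c(5L, 10L, 25L, 50L, 100L),
                         seed = NULL, quiet = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim_truth <- NULL
  if (!is.null(sim)) {
    stopifnot(inherits(sim, "sim_config"))
    if (is.null(sim$seed) && !is.null(seed)) sim$seed <- seed
    res <- .stage("simulate", quiet, simulate_repertoires(sim))
    rearr <- res$rearrangements
    sim_truth <- res$truth
  } else if (is.data.frame(input)) {
    rearr <- input
  } else if (is.character(input)) {
    labels <- names(input)
    if (is.null(labels)) labels <- rep("", length(input))
    parts <- lapply(seq_along(input), function(i) {
      pop <- if (nzchar(labels[i])) labels[i] else
        sub("\\.[^.]*$", "", basename(input[i]))
      tryCatch(read_airr_table(input[i], population = pop),
               error = function(e) {
                 if (grepl("population", conditionMessage(e))) {
                   read_airr_table(input[i])
                 } else stop(e)
               })
    })
    rearr <- do.call(rbind, c(parts, list(make.row.names = FALSE)))
  } else {
    stop("run_pipeline needs `input` (data.frame or file paths) or `sim`",
         call. = FALSE)
  }

  rearr <- .stage("validate", quiet, validate_repertoire(rearr))
  rejections <- attr(rearr, "rejections")
  lt <- .stage("assign", quiet, assign_lineages(rearr, threshold = threshold))

  pops <- lt$populations
  profiles <- lapply(pops, function(p) rank_profile(lt, p))
  names(profiles) <- pops
  expanded <- lapply(profiles, detect_expanded, threshold_pp = expanded_pp)
  ov <- .stage("stats", quiet, overlap_matrix(lt))
  links <- link_table(lt)

  conn_rows <- list()
  for (ref in pops) for (other in setdiff(pops, ref)) {
    for (sc in c("all", "expanded")) {
      v <- suppressWarnings(
        connectivity(lt, ref, other, scope = sc,
                     threshold_pp = expanded_pp))
      conn_rows[[length(conn_rows) + 1L]] <- data.frame(
        ref = ref, other = other, scope = sc, n = NA_integer_,
        percent = as.numeric(v), stringsAsFactors = FALSE)
    }
    sc <- sharing_curve(lt, ref, others = other, n_grid = top_n)
    conn_rows[[length(conn_rows) + 1L]] <- data.frame(
      ref = ref, other = other, scope = "top_n", n = sc$n,
      percent = sc$percent, stringsAsFactors = FALSE)
  }
  conn <- do.call(rbind, conn_rows)

  shm <- .stage("shm", quiet, shm_load(lt))
  div <- intraclonal_divergence(lt)

  # tables
  write_airr_table(lt$assignments[, c("sequence_id", "subject", "population",
                                      "lineage_id", "v_gene", "j_gene",
                                      "junction_length")],
                   file.path(out_dir, "lineages.tsv"))
  write_airr_table(do.call(rbind, lapply(profiles, as.data.frame)),
                   file.path(out_dir, "clone_sizes.tsv"))
  exp_df <- do.call(rbind, lapply(pops, function(p) {
    e <- expanded[[p]]
    if (e$boundary_rank == 0L) return(NULL)
    data.frame(population = p, rank = seq_len(e$boundary_rank),
               lineage_id = e$lineage_id, fraction = e$fractions,
               stringsAsFactors = FALSE)
  }))
  if (is.null(exp_df)) {
    exp_df <- data.frame(population = character(0), rank = integer(0),
                         lineage_id = character(0), fraction = numeric(0))
  }
  write_airr_table(exp_df, file.path(out_dir, "expanded.tsv"))
  ov_df <- data.frame(population = rownames(ov), as.data.frame(ov),
                      check.names = FALSE, stringsAsFactors = FALSE)
  write_airr_table(ov_df, file.path(out_dir, "overlap.tsv"))
  write_airr_table(conn, file.path(out_dir, "connectivity.tsv"))
  write_airr_table(links, file.path(out_dir, "links.tsv"))
  write_airr_table(shm, file.path(out_dir, "shm.tsv"))
  write_airr_table(div, file.path(out_dir, "divergence.tsv"))

  pop_counts <- lapply(pops, function(p) {
    list(n_sequences = sum(lt$assignments$population == p),
         n_lineages = sum(lt$sizes$population == p & lt$sizes$n_seq > 0),
         n_expanded = expanded[[p]]$boundary_rank)
  })
  names(pop_counts) <- pops

  report <- list(
    config = list(
      subject = lt$subject,
      threshold = threshold,
      expanded_threshold_pp = expanded_pp,
      top_n = as.integer(top_n),
      seed = if (is.null(seed)) NA else seed,
      simulated = !is.null(sim),
      version = as.character(utils::packageVersion("ascrep"))),
    rejections = as.list(rejections),
    populations = pop_counts,
    n_lineages = nrow(lt$lineages),
    overlap = apply(ov, 1L, as.list, simplify = FALSE),
    connectivity = conn,
    shm = shm,
    n_divergent_lineages = sum(div$divergent)
  )
  json <- jsonlite::toJSON(report, auto_unbox = TRUE, digits = 10,
                           pretty = TRUE, na = "null", dataframe = "rows")
  writeLines(json, file.path(out_dir, "report.json"))
  if (!is.null(sim_truth)) {
    write_airr_table(sim_truth$sequences, file.path(out_dir, "truth.tsv"))
  }
  invisible(report)
}
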