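#' Run the full comparative plastome analysis
#'
#' Orchestrates every stage over a set of annotated genomes: per-genome
#' feature statistics, quadripartite partitioning and junction profiling,
#' repeat scanning and summary, annotation-anchored extraction and
#' alignment of homologous regions, the seven classical data partitions
#' (whole genome, LSC, SSC, IR, protein-coding genes, intergenic spacers,
#' introns), sliding identity against a reference, p-distances with group
#' means, the hypervariable-marker screen, exon indel coding with its own
#' parsimony tree, and per-partition maximum-parsimony trees with
#' bootstrap support. Every stochastic step is driven by `seed`; two runs
#' with the same inputs and seed produce identical reports.
#'
#' @param records named list of annotated [plastome_record()]s.
#' @param reference id of the reference record (annotation anchor).
#' @param groups optional named character vector taxon -> group label.
#' @param seed RNG seed (mandatory).
#' @param marker_min_len minimum reference length of marker candidates.
#' @param marker_threshold percent-variable-sites cutoff of the marker
#'   screen.
#' @param min_region_len minimum reference length of aligned regions.
#' @param bootstrap_replicates,n_addition parsimony search effort.
#' @param window,step sliding-identity window.
#' @param out_dir optional directory: TSV/JSON reports are written there.
#' @return a `plastocomp_run` list: one element per stage plus `manifest`
#'   (parameters, seed, stage status).
#' @export
run_pipeline <- function(records, reference = names(records)[1],
                         groups = NULL, seed,
                         marker_min_len = 350, marker_threshold = 5.0,
                         min_region_len = 1, bootstrap_replicates = 100,
                         n_addition = 20, window = 100, step = 25,
                         out_dir = NULL) {
  if (missing(seed)) stop("a seed is mandatory")
  stopifnot(length(records) >= 1)
  if (is.null(names(records)) || any(!nzchar(names(records)))) {
    names(records) <- vapply(records, `[[`, character(1), "id")
  }
  if (!reference %in% names(records) ) {
    ids <- vapply(records, `[[`, character(1), "id")
    reference <- names(records)[match(reference, ids)]
    if (is.na(reference)) stop("reference not among the input records")
  }
  set.seed(seed)
  status <- list()
  out <- list()
  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) {
      warning("stage '", name, "' failed: ", conditionMessage(e),
              call. = FALSE)
      structure(list(message = conditionMessage(e)), class = "stage_error")
    })
    status[[name]] <<- if (inherits(res, "stage_error")) {
      paste("failed:", res$message)
    } else "ok"
    out[[name]] <<- res
    res
  }

  parts <- stage("quadripartite", {
    lapply(records, function(r) {
      tryCatch(detect_inverted_repeats(r), error = function(e) NULL)
    })
  })

  stage("genome_stats", {
    do.call(rbind, lapply(names(records), function(tx) {
      r <- records[[tx]]
      gi <- gene_inventory(r)
      bc <- base_composition(r$sequence)
      p <- parts[[tx]]
      rl <- if (!is.null(p)) region_lengths(p) else
        c(lsc = NA, irb = NA, ssc = NA, ira = NA)
      data.frame(taxon = tx, id = r$id, size_bp = r$length,
                 lsc_bp = rl[["lsc"]], ssc_bp = rl[["ssc"]],
                 ir_bp = rl[["irb"]],
                 n_genes = gi$unique_genes,
                 protein_coding = gi$protein_coding,
                 structural_rna = gi$trna + gi$rrna,
                 duplicated_in_ir = gi$duplicated_in_ir,
                 at_percent = bc$at_percent,
                 coding_percent = round(100 * coding_coverage(r), 1))
    }))
  })

  stage("junctions", {
    compare_junctions(lapply(names(records), function(tx) {
      junction_profile(records[[tx]], parts[[tx]])
    }))
  })

  repeats <- stage("repeats", {
    hl <- lapply(names(records), function(tx) {
      scan_repeats(records[[tx]], part = parts[[tx]])
    })
    names(hl) <- names(records)
    list(hits = hl, summary = repeat_summary(hl))
  })

  hom <- stage("homologous_regions", {
    suppressWarnings(extract_homologous_regions(
      records, records[[reference]], category = "both",
      min_len = min_region_len, part = parts[[reference]]))
  })

  aligned <- stage("alignments", {
    msas <- lapply(names(hom$sets), function(nm) {
      progressive_msa(hom$sets[[nm]], region = nm)
    })
    names(msas) <- names(hom$sets)
    msas
  })

  partitions <- stage("partitions", {
    info <- hom$info
    sel <- list(
      whole = info$region,
      lsc = info$region[info$ref_region == "lsc"],
      ssc = info$region[info$ref_region == "ssc"],
      ir = info$region[info$ref_region %in% c("irb", "ira")],
      coding = info$region[info$category == "coding"],
      spacers = info$region[info$category == "noncoding" &
                              !grepl("-intron", info$region)],
      introns = info$region[grepl("-intron", info$region)])
    mats <- lapply(sel, function(regs) {
      regs <- regs[!is.na(regs)]
      if (length(regs) == 0) return(NULL)
      concatenate_msas(aligned[regs])
    })
    stats <- do.call(rbind, lapply(names(mats), function(nm) {
      if (is.null(mats[[nm]])) return(NULL)
      s <- site_stats(mats[[nm]]$supermatrix)
      data.frame(partition = nm, n_regions = nrow(mats[[nm]]$partitions),
                 aligned_length = s$aligned_length,
                 n_variable = s$n_variable,
                 pct_variable = round(s$pct_variable, 2),
                 n_pis = s$n_pis, pct_pis = round(s$pct_pis, 2))
    }))
    list(matrices = mats, stats = stats)
  })

  stage("sliding_identity", {
    ref_taxon <- records[[reference]]$taxon %||% reference
    sm <- partitions$matrices$whole$supermatrix
    if (length(sm$taxa) < 2) stop("need at least two taxa")
    sliding_identity(sm, ref_taxon, window = window, step = step)
  })

  stage("divergence", {
    sm <- partitions$matrices$whole$supermatrix
    dm <- p_distance(sm, deletion = "complete")
    gd <- if (!is.null(groups)) group_divergence(dm, groups) else NULL
    list(p_distance = dm, groups = gd)
  })

  stage("markers", {
    info <- hom$info
    keep <- info$ref_len >= marker_min_len &
      !(info$ref_region %in% c("irb", "ira"))
    regs <- info$region[keep & !is.na(keep)]
    if (length(regs) == 0) stop("no marker candidate passes the filters")
    rep_df <- marker_report(aligned[regs])
    ranked <- rank_markers(rep_df, threshold_pct = marker_threshold)
    regression <- if (nrow(rep_df) >= 3 &&
                      stats::var(rep_df$pct_variable) > 0) {
      pis_variability_regression(rep_df)
    } else NULL
    list(candidates = rep_df, ranked = ranked, regression = regression)
  })

  stage("indels", {
    coding_regs <- hom$info$region[hom$info$category == "coding"]
    ev <- do.call(rbind, lapply(aligned[coding_regs], extract_indel_events))
    mat <- code_binary(ev, taxa = partitions$matrices$whole$supermatrix$taxa,
                       informative_only = TRUE)
    tree <- NULL
    if (!is.null(mat) && ncol(mat) > 0 && nrow(mat) >= 4) {
      tree <- if (nrow(mat) <= 10) exhaustive_search(mat)
              else heuristic_search(mat, n_addition = n_addition)
    }
    list(events = ev, matrix = mat,
         n_events = if (is.null(ev)) 0L else nrow(ev),
         n_informative = if (is.null(mat)) 0L else ncol(mat),
         mp = tree)
  })

  stage("mp_trees", {
    res <- list()
    for (nm in names(partitions$matrices)) {
      pm <- partitions$matrices[[nm]]
      if (is.null(pm) || length(pm$supermatrix$taxa) < 4) next
      cm <- msa_to_charmatrix(pm$supermatrix)
      hs <- heuristic_search(cm, n_addition = n_addition)
      bs <- bootstrap_support(cm, replicates = bootstrap_replicates,
                              best = hs$trees[[1]])
      hi <- ci_ri(hs$trees[[1]], cm)
      res[[nm]] <- list(trees = hs$trees, length = hs$length,
                        ci = hi$ci, ri = hi$ri,
                        tree = bs$tree, support = bs$support)
    }
    res
  })

  out$manifest <- list(
    package = "plastocomp",
    seed = seed,
    reference = reference,
    taxa = names(records),
    groups = groups,
    parameters = list(marker_min_len = marker_min_len,
                      marker_threshold = marker_threshold,
                      min_region_len = min_region_len,
                      bootstrap_replicates = bootstrap_replicates,
                      n_addition = n_addition,
                      window = window, step = step),
    stages = status)
  class(out) <- "plastocomp_run"
  if (!is.null(out_dir)) write_run_reports(out, out_dir)
  out
}

# fraction of the genome covered by gene-type features
coding_coverage <- function(record) {
  n <- record$length
  cov <- rep(FALSE, n)
  for (f in record$features) {
    if (!f$kind %in% c("gene", "CDS", "tRNA", "rRNA") || f$pseudo) next
    for (t in seq_len(nrow(f$intervals))) {
      idx <- (f$intervals$start[t]:(f$intervals$end[t] - 1L)) %% n + 1L
      cov[idx] <- TRUE
    }
  }
  mean(cov)
}

#' @export
print.plastocomp_run <- function(x, ...) {
  cat("<plastocomp_run>\n")
  for (nm in names(x$manifest$stages)) {
    cat(sprintf("  %-20s %s\n", nm, x$manifest$stages[[nm]]))
  }
  invisible(x)
}

# write the machine-readable reports of a pipeline run
write_run_reports <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wtsv <- function(df, name) {
    if (is.null(df) || inherits(df, "stage_error")) return(invisible())
    utils::write.table(df, file.path(dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  wtsv(run$genome_stats, "genome_stats.tsv")
  wtsv(run$junctions, "junctions.tsv")
  if (!inherits(run$repeats, "stage_error")) {
    wtsv(do.call(rbind, lapply(names(run$repeats$hits), function(tx) {
      cbind(taxon = tx, run$repeats$hits[[tx]])
    })), "repeats.tsv")
  }
  if (!inherits(run$partitions, "stage_error")) {
    wtsv(run$partitions$stats, "partition_stats.tsv")
  }
  if (!inherits(run$markers, "stage_error")) {
    wtsv(run$markers$ranked, "markers_ranked.tsv")
  }
  wtsv(run$sliding_identity, "sliding_identity.tsv")
  if (!inherits(run$mp_trees, "stage_error")) {
    trees <- lapply(run$mp_trees, `[[`, "tree")
    class(trees) <- "multiPhylo"
    write_newick(trees, file.path(dir, "mp_trees.nwk"))
  }
  jsonlite::write_json(run$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
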