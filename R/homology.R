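#' Extract homologous regions across annotated plastomes
#'
#' Using a reference annotation, collects per-taxon unaligned sequences for
#' every gene shared by all records, every intron of shared multi-exon
#' genes, and every intergenic spacer between genes consecutive on the
#' reference, ready for [progressive_msa()]. Spacer names follow the
#' `"geneA-geneB"` convention in reference order; intron names are
#' `"gene-intron"` (numbered when a gene has several). IR-duplicated genes
#' contribute one copy (the IRb copy when a partition is supplied).
#'
#' @param records list of annotated [plastome_record()]s.
#' @param reference a [plastome_record()] (or the id of one of `records`)
#'   whose annotation anchors region boundaries and ordering.
#' @param category `"both"`, `"coding"` (genes only) or `"noncoding"`
#'   (introns and spacers only).
#' @param min_len drop regions shorter than this in the reference.
#' @param single_copy_only drop regions whose reference midpoint lies in
#'   the inverted repeat.
#' @param part optional `ir_partition` of the reference (computed when
#'   needed and not supplied).
#' @return object of class `homolog_set`: list with `sets` (named list,
#'   one named character vector of per-taxon sequences per region) and
#'   `info` (data frame `region`, `category`, `ref_len`, `ref_start`,
#'   `ref_region`).
#' @export
extract_homologous_regions <- function(records, reference,
                                       category = c("both", "coding", "noncoding"),
                                       min_len = 200,
                                       single_copy_only = FALSE,
                                       part = NULL) {
  category <- match.arg(category)
  if (is.character(reference)) {
    ids <- vapply(records, `[[`, character(1), "id")
    reference <- records[[match(reference, ids)]]
  }
  stopifnot(inherits(reference, "plastome_record"))
  if (is.null(part)) {
    part <- tryCatch(detect_inverted_repeats(reference), error = function(e) NULL)
  }
  n_ref <- reference$length

  ref_genes <- pick_gene_copies(reference, part)
  taxa <- vapply(records, function(r) r$taxon %||% r$id, character(1))
  names(records) <- taxa

  # one chosen copy per gene per record (the IRb copy where locatable),
  # so spacer coordinates are consistent across taxa
  maps <- lapply(records, function(r) {
    pick_gene_copies(r, tryCatch(detect_inverted_repeats(r),
                                 error = function(e) NULL))
  })
  shared <- Filter(function(g) {
    all(vapply(maps, function(mp) !is.null(mp[[g]]), logical(1)))
  }, names(ref_genes))

  sets <- list()
  info <- list()
  add_region <- function(name, cat, ref_len, ref_start, seqs) {
    if (ref_len < min_len) return(invisible())
    if (single_copy_only && !is.null(part)) {
      mid <- circ_pos(ref_start + ref_len %/% 2, n_ref)
      if (region_of(part, mid) %in% c("irb", "ira")) return(invisible())
    }
    reg <- if (!is.null(part)) {
      region_of(part, circ_pos(ref_start + ref_len %/% 2, n_ref))
    } else NA_character_
    sets[[name]] <<- seqs
    info[[name]] <<- data.frame(region = name, category = cat,
                                ref_len = ref_len, ref_start = ref_start,
                                ref_region = reg)
  }

  # coding: the spliced gene sequences
  if (category %in% c("both", "coding")) {
    for (g in shared) {
      seqs <- vapply(taxa, function(tx) {
        extract_feature_sequence(records[[tx]], maps[[tx]][[g]])
      }, character(1))
      if (any(!nzchar(seqs))) next
      f <- ref_genes[[g]]
      add_region(g, "coding",
                 sum(f$intervals$end - f$intervals$start),
                 min(f$intervals$start), seqs)
    }
  }

  if (category %in% c("both", "noncoding")) {
    # introns of shared multi-exon genes
    for (g in shared) {
      f <- ref_genes[[g]]
      if (nrow(f$intervals) < 2) next
      if (length(unique(f$intervals$strand)) > 1) next  # trans-spliced
      for (t in seq_len(nrow(f$intervals) - 1)) {
        nm <- if (nrow(f$intervals) == 2) paste0(g, "-intron")
              else paste0(g, "-intron", t)
        seqs <- vapply(taxa, function(tx) {
          fr <- maps[[tx]][[g]]
          if (nrow(fr$intervals) != nrow(f$intervals) ||
              length(unique(fr$intervals$strand)) > 1) return("")
          gap_seq(records[[tx]], fr, t)
        }, character(1))
        if (any(!nzchar(seqs))) next
        rb <- intron_bounds(f, t)
        add_region(nm, "noncoding", rb[2] - rb[1], rb[1], seqs)
      }
    }

    # intergenic spacers between reference-consecutive genes
    ord <- shared[order(vapply(ref_genes[shared], function(f) {
      min(f$intervals$start)
    }, numeric(1)))]
    if (length(ord) >= 2) {
      pairs <- cbind(ord, c(ord[-1], ord[1]))
      for (t in seq_len(nrow(pairs))) {
        gA <- pairs[t, 1]; gB <- pairs[t, 2]
        fa <- ref_genes[[gA]]; fb <- ref_genes[[gB]]
        ref_from <- max(fa$intervals$end)
        ref_to <- min(fb$intervals$start)
        ref_len <- circ_pos(ref_to - ref_from, n_ref)
        if (ref_len == 0) next
        seqs <- vapply(taxa, function(tx) {
          r <- records[[tx]]
          fra <- maps[[tx]][[gA]]; frb <- maps[[tx]][[gB]]
          from <- max(fra$intervals$end)
          to <- min(frb$intervals$start)
          len <- circ_pos(to - from, r$length)
          if (len == 0 || len > 5 * ref_len + 1000) return("")
          circ_substr(r$sequence, circ_pos(from, r$length),
                      circ_pos(from, r$length) + len, r$length)
        }, character(1))
        if (any(!nzchar(seqs))) {
          warning("spacer ", gA, "-", gB,
                  " dropped: absent or rearranged in some taxon",
                  call. = FALSE)
          next
        }
        add_region(paste0(gA, "-", gB), "noncoding", ref_len,
                   circ_pos(ref_from, n_ref), seqs)
      }
    }
  }
  structure(list(sets = sets,
                 info = if (length(info)) {
                   out <- do.call(rbind, info); rownames(out) <- NULL; out
                 } else data.frame()),
            class = "homolog_set")
}

#' @export
print.homolog_set <- function(x, ...) {
  cat(sprintf("<homolog_set> %d regions (%d coding, %d noncoding)\n",
              nrow(x$info), sum(x$info$category == "coding"),
              sum(x$info$category == "noncoding")))
  invisible(x)
}

# the non-pseudo gene features of a record, one copy per name (the IRb
# copy when a partition localises the duplicates, else the longest)
pick_gene_copies <- function(record, part = NULL) {
  gf <- Filter(function(f) f$kind %in% c("gene", "CDS", "tRNA", "rRNA") &&
                 !f$pseudo, record$features)
  nm <- vapply(gf, `[[`, character(1), "name")
  out <- list()
  for (g in unique(nm)) {
    copies <- gf[nm == g]
    if (length(copies) > 1 && !is.null(part)) {
      in_irb <- vapply(copies, function(f) {
        region_of(part, circ_pos(f$intervals$start[1], record$length)) == "irb"
      }, logical(1))
      if (any(in_irb)) copies <- copies[in_irb]
    }
    lens <- vapply(copies, function(f) sum(f$intervals$end - f$intervals$start),
                   numeric(1))
    out[[g]] <- copies[[which.max(lens)]]
  }
  out
}

find_gene <- function(record, g) {
  hits <- Filter(function(f) f$name == g && !f$pseudo &&
                   f$kind %in% c("gene", "CDS", "tRNA", "rRNA"),
                 record$features)
  if (length(hits) == 0) return(NULL)
  lens <- vapply(hits, function(f) sum(f$intervals$end - f$intervals$start),
                 numeric(1))
  hits[[which.max(lens)]]
}

# genomic bounds of the t-th intron of a feature whose intervals are in
# reading order (minus-strand exons run high-to-low genomically)
intron_bounds <- function(f, t) {
  if (f$intervals$strand[1] == "-") {
    c(f$intervals$end[t + 1], f$intervals$start[t])
  } else {
    c(f$intervals$end[t], f$intervals$start[t + 1])
  }
}

# the t-th inter-exon (intron) sequence of a feature, strand-corrected
gap_seq <- function(record, f, t) {
  b <- intron_bounds(f, t)
  if (b[2] <= b[1]) return("")
  piece <- circ_substr(record$sequence, circ_pos(b[1], record$length),
                       circ_pos(b[1], record$length) + (b[2] - b[1]),
                       record$length)
  if (f$intervals$strand[1] == "-") revcomp(piece) else piece
}
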