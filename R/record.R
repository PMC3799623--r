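#' Annotated plastome record
#'
#' Container for a (usually circular) annotated chloroplast genome: the
#' uppercase DNA sequence plus a list of strand-aware features. All
#' coordinates in the package are 0-based half-open; an interval whose end
#' exceeds the genome length wraps through the origin of a circular record.
#'
#' @param id nonempty accession or label.
#' @param sequence DNA string over `{A,C,G,T,N}` (lowercase accepted,
#'   stored uppercase). Other IUPAC ambiguity codes are rejected.
#' @param taxon organism name (defaults to `id`).
#' @param circular logical; plastomes are circular.
#' @param features list of [feature()] objects.
#' @return an object of class `plastome_record` with fields `id`, `taxon`,
#'   `sequence`, `circular`, `features`, `length`.
#' @export
plastome_record <- function(id, sequence, taxon = id, circular = TRUE,
                            features = list()) {
  if (!is.character(id) || length(id) != 1L || !nzchar(id)) {
    stop("'id' must be a nonempty string")
  }
  sequence <- toupper(sequence)
  check_dna(sequence, paste0("sequence of '", id, "'"))
  rec <- structure(
    list(id = id, taxon = taxon, sequence = sequence,
         circular = isTRUE(circular), features = features,
         length = nchar(sequence)),
    class = "plastome_record")
  for (f in features) validate_feature(f, rec)
  rec
}

#' Genome feature
#'
#' A named feature (gene, CDS, tRNA, rRNA, exon or intron) with one or more
#' ordered intervals. Multi-interval features (spliced or trans-spliced
#' genes) concatenate their intervals in listed order; minus-strand
#' intervals are reverse-complemented on extraction.
#'
#' @param name gene symbol, e.g. `"rps19"`, `"trnH-GUG"`.
#' @param kind one of `gene`, `CDS`, `tRNA`, `rRNA`, `exon`, `intron`.
#' @param intervals data frame (or matrix-like) with columns `start`, `end`
#'   (0-based half-open, `end` may exceed the genome length to wrap the
#'   origin) and `strand` (`"+"` or `"-"`).
#' @param pseudo logical; `TRUE` for truncated pseudogene copies.
#' @return an object of class `plastome_feature`.
#' @export
feature <- function(name, kind = "gene", intervals, pseudo = FALSE) {
  kinds <- c("gene", "CDS", "tRNA", "rRNA", "exon", "intron")
  if (!kind %in% kinds) stop("unknown feature kind '", kind, "'")
  intervals <- as.data.frame(intervals)
  if (nrow(intervals) == 0) stop("feature '", name, "' has no intervals")
  stopifnot(all(c("start", "end", "strand") %in% names(intervals)))
  intervals$start <- as.integer(intervals$start)
  intervals$end <- as.integer(intervals$end)
  if (any(intervals$end <= intervals$start)) {
    stop("feature '", name, "': interval start must precede end")
  }
  if (!all(intervals$strand %in% c("+", "-"))) {
    stop("feature '", name, "': strand must be '+' or '-'")
  }
  structure(list(name = name, kind = kind,
                 intervals = intervals[, c("start", "end", "strand")],
                 pseudo = isTRUE(pseudo)),
            class = "plastome_feature")
}

validate_feature <- function(f, rec) {
  stopifnot(inherits(f, "plastome_feature"))
  n <- rec$length
  if (any(f$intervals$start < 0) || any(f$intervals$start >= n)) {
    stop("feature '", f$name, "': interval start outside [0, length)")
  }
  over <- f$intervals$end > n
  if (any(over) && !rec$circular) {
    stop("feature '", f$name, "': interval beyond the end of a non-circular record")
  }
  if (any(f$intervals$end - f$intervals$start > n)) {
    stop("feature '", f$name, "': interval longer than the genome")
  }
  invisible(f)
}

#' @export
print.plastome_record <- function(x, ...) {
  cat(sprintf("<plastome_record> %s (%s)\n", x$id, x$taxon))
  cat(sprintf("  %s bp, %s, %d features\n",
              format(x$length, big.mark = ","),
              if (x$circular) "circular" else "linear",
              length(x$features)))
  invisible(x)
}

#' @export
print.plastome_feature <- function(x, ...) {
  loc <- paste(sprintf("%d..%d(%s)", x$intervals$start, x$intervals$end,
                       x$intervals$strand), collapse = ",")
  cat(sprintf("<feature> %s [%s]%s %s\n", x$name, x$kind,
              if (x$pseudo) " pseudo" else "", loc))
  invisible(x)
}

#' Extract the spliced, strand-corrected sequence of a feature
#'
#' Intervals are concatenated in listed order; minus-strand intervals are
#' reverse-complemented; intervals wrapping the origin of a circular record
#' are read through the origin.
#'
#' @param record a [plastome_record()].
#' @param feat a [feature()] (or the name of a feature in `record`).
#' @return DNA string.
#' @export
extract_feature_sequence <- function(record, feat) {
  if (is.character(feat)) {
    hit <- Filter(function(f) f$name == feat, record$features)
    if (length(hit) == 0) stop("no feature named '", feat, "'")
    feat <- hit[[1]]
  }
  validate_feature(feat, record)
  parts <- vapply(seq_len(nrow(feat$intervals)), function(i) {
    s <- feat$intervals$start[i]; e <- feat$intervals$end[i]
    piece <- circ_substr(record$sequence, s, e, record$length)
    if (feat$intervals$strand[i] == "-") revcomp(piece) else piece
  }, character(1))
  paste(parts, collapse = "")
}

classify_gene_name <- function(name) {
  ifelse(grepl("^trn", name), "trna",
         ifelse(grepl("^rrn", name), "rrna", "protein_coding"))
}

#' Gene inventory of an annotated record
#'
#' Counts unique genes (deduplicating IR-duplicated copies by name, counting
#' trans-spliced genes once and excluding pseudogenes), splits them into
#' tRNA / rRNA / protein-coding classes, and reports which genes contain
#' introns (number of intervals minus one, per copy with the most intervals).
#'
#' @param record a [plastome_record()].
#' @return list with fields `unique_genes`, `trna`, `rrna`,
#'   `protein_coding`, `duplicated_in_ir`, `total_with_duplicates`,
#'   `intron_containing` (data frame gene / n_introns).
#' @export
gene_inventory <- function(record) {
  gf <- Filter(function(f) f$kind %in% c("gene", "tRNA", "rRNA") && !f$pseudo,
               record$features)
  # fall back to CDS features for records annotated without 'gene' lines
  if (length(gf) == 0) {
    gf <- Filter(function(f) f$kind == "CDS" && !f$pseudo, record$features)
  }
  if (length(gf) == 0) {
    return(list(unique_genes = 0L, trna = 0L, rrna = 0L, protein_coding = 0L,
                duplicated_in_ir = 0L, total_with_duplicates = 0L,
                intron_containing = data.frame(gene = character(0),
                                               n_introns = integer(0))))
  }
  nm <- vapply(gf, `[[`, character(1), "name")
  tab <- table(nm)
  uniq <- names(tab)
  cls <- classify_gene_name(uniq)
  dup <- sum(tab > 1)
  nint <- vapply(uniq, function(g) {
    max(vapply(gf[nm == g], function(f) nrow(f$intervals), integer(1))) - 1L
  }, integer(1))
  keep <- nint > 0
  list(unique_genes = length(uniq),
       trna = sum(cls == "trna"),
       rrna = sum(cls == "rrna"),
       protein_coding = sum(cls == "protein_coding"),
       duplicated_in_ir = as.integer(dup),
       total_with_duplicates = length(uniq) + as.integer(dup),
       intron_containing = data.frame(gene = uniq[keep],
                                      n_introns = as.integer(nint[keep]),
                                      row.names = NULL))
}

#' Base composition of a DNA sequence
#'
#' @param seq DNA string (or a [plastome_record()]).
#' @return list with `fractions` (A, C, G, T fractions over non-N bases,
#'   summing to 1) and `at_percent` (AT content, one decimal).
#' @export
base_composition <- function(seq) {
  if (inherits(seq, "plastome_record")) seq <- seq$sequence
  if (!nzchar(seq)) stop("empty sequence")
  counts <- Biostrings::letterFrequency(Biostrings::DNAString(seq),
                                        c("A", "C", "G", "T"))
  tot <- sum(counts)
  if (tot == 0) stop("sequence contains no unambiguous bases")
  fr <- as.numeric(counts) / tot
  names(fr) <- c("A", "C", "G", "T")
  list(fractions = fr,
       at_percent = round(100 * (fr[["A"]] + fr[["T"]]), 1))
}
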