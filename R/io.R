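#' Read sequences from a FASTA file
#'
#' @param path FASTA file (plain or gapped/aligned).
#' @return named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    stop("duplicate sequence identifiers in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  out <- toupper(as.character(set))
  names(out) <- ids
  out
}

#' Write sequences to a FASTA file
#'
#' @param seqs named character vector (gaps `-` allowed).
#' @param path output path.
#' @param width line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70) {
  if (is.null(names(seqs)) || anyDuplicated(names(seqs))) {
    stop("sequences must carry unique names")
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1, max(nchar(s), 1), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}

#' Read / write trees in Newick format
#'
#' Thin wrappers over [ape::read.tree()] / [ape::write.tree()]; topology,
#' branch lengths and node (support) labels round-trip losslessly.
#'
#' @param path file path.
#' @return `read_newick` returns an [ape::phylo] object (or `multiPhylo`
#'   when the file holds several trees).
#' @export
read_newick <- function(path) ape::read.tree(path)

#' @rdname read_newick
#' @param tree an [ape::phylo] or `multiPhylo` object.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Multiple sequence alignment container
#'
#' An `plasto_msa` holds equal-length gapped rows over `{A,C,G,T,N,-}`,
#' keyed by taxon, together with a region label. Degapping any row
#' reproduces the extracted source sequence.
#'
#' @param seqs named character vector of equal-length gapped sequences.
#' @param region label of the aligned region (gene, intron or spacer name).
#' @return an object of class `plasto_msa`.
#' @export
msa <- function(seqs, region = "region") {
  if (is.null(names(seqs)) || anyDuplicated(names(seqs))) {
    stop("alignment rows must carry unique taxon names")
  }
  seqs <- toupper(unlist(seqs))
  if (length(unique(nchar(seqs))) > 1) {
    stop("alignment rows must have equal length")
  }
  bad <- gsub("[ACGTN-]", "", seqs)
  if (any(nchar(bad) > 0)) stop("alignment contains characters outside {A,C,G,T,N,-}")
  structure(list(region = region, taxa = names(seqs), seqs = seqs),
            class = "plasto_msa")
}

#' @export
print.plasto_msa <- function(x, ...) {
  cat(sprintf("<plasto_msa> %s: %d taxa x %d columns\n",
              x$region, length(x$taxa), ncol_msa(x)))
  invisible(x)
}

ncol_msa <- function(x) if (length(x$seqs) == 0) 0L else nchar(x$seqs[[1]])

# alignment as a character matrix (rows = taxa)
msa_matrix <- function(x) {
  m <- do.call(rbind, strsplit(x$seqs, "", fixed = TRUE))
  rownames(m) <- x$taxa
  m
}

#' Degap an alignment row
#' @param x a [msa()].
#' @param taxon row name.
#' @return ungapped sequence string.
#' @export
degap <- function(x, taxon) gsub("-", "", x$seqs[[taxon]], fixed = TRUE)

#' Map alignment columns to source coordinates
#'
#' @param x a [msa()].
#' @return named list; per taxon an integer vector of length `ncol` giving
#'   the 0-based source coordinate of each alignment column (`NA` at gaps).
#' @export
msa_source_map <- function(x) {
  lapply(stats::setNames(x$taxa, x$taxa), function(tx) {
    ch <- seq_chars(x$seqs[[tx]])
    out <- rep(NA_integer_, length(ch))
    idx <- which(ch != "-")
    out[idx] <- seq_along(idx) - 1L
    out
  })
}

#' Read / write an aligned FASTA file as an MSA
#' @param path file path.
#' @param region region label for the alignment read.
#' @export
read_msa <- function(path, region = "region") msa(read_fasta(path), region)

#' @rdname read_msa
#' @param x a [msa()].
#' @export
write_msa <- function(x, path) write_fasta(x$seqs, path)
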