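#' Global pairwise alignment with affine gap costs
#'
#' Needleman-Wunsch alignment under match/mismatch scoring with affine
#' gaps (a gap of length l costs `gap_open + (l - 1) * gap_extend`).
#' Tie-breaking is deterministic: diagonal, then up (gap in `b`), then
#' left.
#'
#' @param a,b nonempty DNA strings.
#' @param match,mismatch,gap_open,gap_extend scoring parameters; the
#'   defaults (+1/-1, -4/-1) are a common DNA default.
#' @return a two-row [msa()] (rows named `a` and `b`, or by the names of
#'   the inputs) with attribute `score`.
#' @export
needleman_wunsch <- function(a, b, match = 1, mismatch = -1,
                             gap_open = -4, gap_extend = -1) {
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be nonempty")
  na_ <- names(a) %||% "a"; nb_ <- names(b) %||% "b"
  pa <- seq_profile(toupper(a)); pb <- seq_profile(toupper(b))
  fit <- .nw_profiles_cpp(pa, pb, match, mismatch, gap_open, gap_extend)
  rows <- apply_moves(c(toupper(a)), c(toupper(b)), fit$moves)
  out <- msa(stats::setNames(c(rows$a, rows$b), c(na_, nb_)),
             region = "pairwise")
  attr(out, "score") <- fit$score
  out
}

# 4 x L base-frequency profile of a set of equal-length gapped rows
profile_of <- function(rows) {
  m <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
  L <- ncol(m)
  p <- matrix(0, 4, L, dimnames = list(c("A", "C", "G", "T"), NULL))
  for (b in rownames(p)) p[b, ] <- colSums(m == b) / nrow(m)
  p
}

seq_profile <- function(s) profile_of(s)

# thread two sets of rows through an alignment path
apply_moves <- function(rows_a, rows_b, moves) {
  take_a <- moves != 3L
  take_b <- moves != 2L
  thread <- function(r, take) {
    out <- rep("-", length(take))
    out[take] <- seq_chars(r)
    paste(out, collapse = "")
  }
  list(a = vapply(rows_a, thread, character(1), take = take_a),
       b = vapply(rows_b, thread, character(1), take = take_b))
}

#' Progressive multiple sequence alignment
#'
#' Builds a guide tree from shared k-mer distances by neighbour joining,
#' then merges alignments at each guide-tree node by profile-profile
#' dynamic programming (sum-of-pairs column scoring, affine gaps). Once a
#' gap is introduced it is never removed.
#'
#' @param seqs named character vector of >= 1 DNA sequences.
#' @param region region label of the output alignment.
#' @param k k-mer size for the guide distance.
#' @inheritParams needleman_wunsch
#' @return a [msa()].
#' @export
progressive_msa <- function(seqs, region = "region", k = 8, match = 1,
                            mismatch = -1, gap_open = -4, gap_extend = -1) {
  seqs <- toupper(unlist(seqs))
  if (is.null(names(seqs)) || anyDuplicated(names(seqs))) {
    stop("sequences must carry unique names")
  }
  if (any(!nzchar(seqs))) stop("sequences must be nonempty")
  n <- length(seqs)
  if (n == 1) return(msa(seqs, region))
  if (n == 2) {
    out <- needleman_wunsch(stats::setNames(seqs[1], names(seqs)[1]),
                            stats::setNames(seqs[2], names(seqs)[2]),
                            match, mismatch, gap_open, gap_extend)
    out$region <- region
    return(out)
  }
  guide <- kmer_guide_tree(seqs, k)
  merge_node <- function(node) {
    kids <- guide$edge[guide$edge[, 1] == node, 2]
    parts <- lapply(kids, function(ch) {
      if (ch <= length(guide$tip.label)) {
        stats::setNames(seqs[guide$tip.label[ch]], guide$tip.label[ch])
      } else merge_node(ch)
    })
    acc <- parts[[1]]
    for (t in seq_along(parts)[-1]) {
      fit <- .nw_profiles_cpp(profile_of(acc), profile_of(parts[[t]]),
                              match, mismatch, gap_open, gap_extend)
      g <- apply_moves(acc, parts[[t]], fit$moves)
      acc <- c(g$a, g$b)
    }
    acc
  }
  rows <- merge_node(length(guide$tip.label) + 1L)
  msa(rows[names(seqs)], region)
}

# rooted guide tree over the sequence names from shared k-mer distances
kmer_guide_tree <- function(seqs, k = 8) {
  k <- min(k, min(nchar(seqs)))
  counts <- Biostrings::oligonucleotideFrequency(
    Biostrings::DNAStringSet(gsub("N", "A", seqs)), width = k)
  n <- length(seqs)
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      shared <- sum(pmin(counts[i, ], counts[j, ]))
      denom <- min(nchar(seqs[i]), nchar(seqs[j])) - k + 1
      d[i, j] <- d[j, i] <- 1 - shared / max(denom, 1)
    }
  }
  tr <- if (n == 3) {
    ape::read.tree(text = sprintf("(%s,(%s,%s));", names(seqs)[1],
                                  names(seqs)[2], names(seqs)[3]))
  } else ape::nj(stats::as.dist(d))
  tr <- ape::root(tr, outgroup = names(seqs)[1], resolve.root = TRUE)
  ape::reorder.phylo(tr, "cladewise")
}

#' Concatenate alignments into a partitioned supermatrix
#'
#' @param msas list of [msa()] objects over the same taxon set.
#' @return object of class `partitioned_matrix`: list with `supermatrix`
#'   (a [msa()]) and `partitions` (data frame `region`, `start_col`,
#'   `end_col`, 0-based half-open columns tiling the matrix).
#' @export
concatenate_msas <- function(msas) {
  stopifnot(length(msas) >= 1)
  taxa <- sort(msas[[1]]$taxa)
  for (m in msas) {
    if (!identical(sort(m$taxa), taxa)) {
      stop("all alignments must cover the same taxa")
    }
  }
  lens <- vapply(msas, ncol_msa, integer(1))
  rows <- vapply(taxa, function(tx) {
    paste(vapply(msas, function(m) m$seqs[[tx]], character(1)),
          collapse = "")
  }, character(1))
  ends <- cumsum(lens)
  part <- data.frame(region = vapply(msas, `[[`, character(1), "region"),
                     start_col = c(0L, ends[-length(ends)]),
                     end_col = ends, row.names = NULL)
  structure(list(supermatrix = msa(rows, region = "concatenated"),
                 partitions = part),
            class = "partitioned_matrix")
}

#' @export
print.partitioned_matrix <- function(x, ...) {
  cat(sprintf("<partitioned_matrix> %d taxa x %d columns, %d partitions\n",
              length(x$supermatrix$taxa), ncol_msa(x$supermatrix),
              nrow(x$partitions)))
  invisible(x)
}

#' Sliding-window percent identity against a reference row
#'
#' For each non-reference taxon and each window, identity is the number of
#' matching columns over the number of compared columns (both rows non-gap,
#' non-N). Windows with no compared column yield `NA`.
#'
#' @param x a [msa()].
#' @param reference_taxon row to compare against.
#' @param window,step window size and step in alignment columns.
#' @return data frame `taxon`, `col_start` (0-based window start),
#'   `ref_pos` (0-based reference coordinate at window start),
#'   `compared`, `identity` (percent).
#' @export
sliding_identity <- function(x, reference_taxon, window = 100, step = 25) {
  stopifnot(inherits(x, "plasto_msa"))
  if (!reference_taxon %in% x$taxa) stop("reference taxon not in alignment")
  L <- ncol_msa(x)
  if (window > L) stop("window larger than the alignment")
  m <- msa_matrix(x)
  ref <- m[reference_taxon, ]
  ref_ok <- ref != "-" & ref != "N"
  refmap <- cumsum(ref_ok) - 1L   # last reference position seen, 0-based
  starts <- seq(1L, L - window + 1L, by = step)
  out <- lapply(setdiff(x$taxa, reference_taxon), function(tx) {
    row <- m[tx, ]
    ok <- ref_ok & row != "-" & row != "N"
    eq <- ok & (row == ref)
    cum_ok <- c(0L, cumsum(ok)); cum_eq <- c(0L, cumsum(eq))
    comp <- cum_ok[starts + window] - cum_ok[starts]
    hits <- cum_eq[starts + window] - cum_eq[starts]
    data.frame(taxon = tx, col_start = starts - 1L,
               ref_pos = pmax(refmap[starts], 0L),
               compared = comp,
               identity = ifelse(comp == 0, NA_real_,
                                 round(100 * hits / comp, 2)))
  })
  do.call(rbind, out)
}
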