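`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reverse complement of DNA strings
#'
#' @param x character vector of DNA sequences over `{A,C,G,T,N}` (gaps `-`
#'   are preserved in place-reversed order).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  out <- chartr("ACGTN-", "TGCAN-", x)
  vapply(out, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# split a sequence string into a character vector of single bases
seq_chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

# substring of a circular sequence, 0-based half-open; end may exceed n
# (wraps through the origin)
circ_substr <- function(seq, start, end, n = nchar(seq)) {
  stopifnot(end >= start, end - start <= n)
  if (end <= n) {
    substr(seq, start + 1, end)
  } else {
    paste0(substr(seq, start + 1, n), substr(seq, 1, end - n))
  }
}

# rotate a circular sequence so that 0-based position `offset` becomes
# position 0
rotate_seq <- function(seq, offset) {
  n <- nchar(seq)
  offset <- ((offset %% n) + n) %% n
  if (offset == 0) return(seq)
  paste0(substr(seq, offset + 1, n), substr(seq, 1, offset))
}

# circular (mod n) normalisation of a position
circ_pos <- function(p, n) ((p %% n) + n) %% n

# do two 0-based half-open arcs on a circle of size n overlap?
arcs_overlap <- function(s1, e1, s2, e2, n) {
  # unroll both arcs into [0, 2n)
  s1 <- circ_pos(s1, n); e1 <- s1 + (e1 - s1)
  s2 <- circ_pos(s2, n); e2 <- s2 + (e2 - s2)
  ov <- function(a1, b1, a2, b2) a1 < b2 && a2 < b1
  ov(s1, e1, s2, e2) || ov(s1, e1, s2 + n, e2 + n) || ov(s1 + n, e1 + n, s2, e2)
}

check_dna <- function(seq, what = "sequence") {
  bad <- gsub("[ACGTN]", "", seq)
  if (any(nchar(bad) > 0)) {
    stop(what, " contains characters outside {A,C,G,T,N}: '",
         substr(bad[nchar(bad) > 0][1], 1, 10), "'", call. = FALSE)
  }
  invisible(seq)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
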