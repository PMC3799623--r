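#' Detect the inverted-repeat pair and partition a plastome
#'
#' Finds the maximal-length pair of disjoint, exactly reverse-complementary
#' segments of at least `min_ir_len` bp on the circular genome (seeded
#' k-mer matching between the sequence and its reverse complement, extended
#' to maximality), assigns the longer single-copy region as LSC and the
#' shorter as SSC, and returns the canonical LSC-IRb-SSC-IRa partition with
#' its four junction points.
#'
#' @param record a [plastome_record()]; must be circular.
#' @param min_ir_len minimum IR length in bp. Plastome IRs are >= 10 kb;
#'   the 1 kb default skips small dispersed inverted repeats.
#' @return an object of class `ir_partition` with fields `lsc`, `irb`,
#'   `ssc`, `ira` (0-based half-open `(start, end)` in original record
#'   coordinates, `end` beyond the genome length wrapping the origin),
#'   `junctions` (named positions `J_LB`, `J_SB`, `J_SA`, `J_LA`) and
#'   `length`.
#' @export
detect_inverted_repeats <- function(record, min_ir_len = 1000) {
  stopifnot(inherits(record, "plastome_record"))
  if (!record$circular) stop("IR detection requires a circular record")
  n <- record$length
  if (n < 4 * min_ir_len) {
    stop("genome shorter than 4 * min_ir_len; lower 'min_ir_len'")
  }
  S <- record$sequence
  R <- revcomp(S)

  hits <- inverted_matches(S, R, k = min(31L, as.integer(min_ir_len)))
  if (nrow(hits) > 0) {
    # map matches (i in S, j in revcomp space, length L) to segment pairs
    segB <- hits$i
    segA <- circ_pos(n - hits$j - hits$len, n)
    L <- hits$len
    keep <- L >= min_ir_len & segA != segB
    segA <- segA[keep]; segB <- segB[keep]; L <- L[keep]
    if (length(L) > 0) {
      disj <- vapply(seq_along(L), function(t) {
        !arcs_overlap(segA[t], segA[t] + L[t], segB[t], segB[t] + L[t], n)
      }, logical(1))
      segA <- segA[disj]; segB <- segB[disj]; L <- L[disj]
    }
  } else L <- integer(0)
  if (length(L) == 0) {
    stop("no quadripartite structure: no inverted repeat pair >= ",
         min_ir_len, " bp")
  }
  best <- which(L == max(L))
  # symmetric duplicates and deterministic choice: smallest start first
  s1 <- pmin(segA[best], segB[best])
  s2 <- pmax(segA[best], segB[best])
  o <- order(s1, s2)
  c1 <- s1[o[1]]; c2 <- s2[o[1]]; L <- L[best][o[1]]

  gap12 <- circ_pos(c2 - (c1 + L), n)  # arc after copy1, before copy2
  gap21 <- circ_pos(c1 - (c2 + L), n)
  stopifnot(gap12 + gap21 + 2 * L == n)

  if (gap12 != gap21) {
    lsc_first <- gap12 > gap21
  } else {
    # equal single-copy lengths: the rRNA-free side is LSC
    rrn_mid <- feature_midpoints(record, "^rrn")
    in_gap <- function(gs, glen) {
      any(vapply(rrn_mid, function(p) circ_pos(p - gs, n) < glen, logical(1)))
    }
    r12 <- length(rrn_mid) > 0 && in_gap(circ_pos(c1 + L, n), gap12)
    r21 <- length(rrn_mid) > 0 && in_gap(circ_pos(c2 + L, n), gap21)
    lsc_first <- if (r12 != r21) r21 else TRUE
  }
  if (lsc_first) {
    lsc_start <- circ_pos(c1 + L, n); lsc_len <- gap12
    irb_start <- c2; ssc_start <- circ_pos(c2 + L, n); ssc_len <- gap21
    ira_start <- c1
  } else {
    lsc_start <- circ_pos(c2 + L, n); lsc_len <- gap21
    irb_start <- c1; ssc_start <- circ_pos(c1 + L, n); ssc_len <- gap12
    ira_start <- c2
  }
  part <- structure(list(
    lsc = c(start = lsc_start, end = lsc_start + lsc_len),
    irb = c(start = irb_start, end = irb_start + L),
    ssc = c(start = ssc_start, end = ssc_start + ssc_len),
    ira = c(start = ira_start, end = ira_start + L),
    junctions = c(J_LB = irb_start, J_SB = ssc_start,
                  J_SA = ira_start, J_LA = lsc_start),
    length = n), class = "ir_partition")
  stopifnot(identical(
    revcomp(circ_substr(S, part$irb[["start"]], part$irb[["end"]], n)),
    circ_substr(S, part$ira[["start"]], part$ira[["end"]], n)))
  part
}

# maximal exact common substrings between circular S and circular R
# (both length n), found as runs of step-1 k-mer seed matches along
# diagonals; returns 0-based (i, j, len)
inverted_matches <- function(S, R, k, max_kmer_mult = 25L) {
  n <- nchar(S)
  S2 <- paste0(S, S); R2 <- paste0(R, R)
  pos <- 0:(n - 1L)
  kS <- substring(S2, pos + 1L, pos + k)
  kR <- substring(R2, pos + 1L, pos + k)
  byS <- split(pos, kS)
  byS <- byS[lengths(byS) <= max_kmer_mult]
  hitlist <- byS[kR]
  m <- lengths(hitlist)
  if (sum(m) == 0) {
    return(data.frame(i = integer(0), j = integer(0), len = integer(0)))
  }
  i <- unlist(hitlist, use.names = FALSE)
  j <- rep(pos, m)
  d <- circ_pos(i - j, n)
  o <- order(d, j)
  d <- d[o]; i <- i[o]; j <- j[o]
  new_run <- c(TRUE, !(d[-1] == d[-length(d)] & j[-1] == j[-length(j)] + 1L))
  run_id <- cumsum(new_run)
  j0 <- tapply(j, run_id, min)
  r <- tabulate(run_id)
  dd <- d[new_run]
  out <- data.frame(j = as.integer(j0), d = as.integer(dd),
                    len = as.integer(r + k - 1L))
  # merge runs wrapping j = n-1 -> 0 on the same diagonal
  ends_at_n <- which(out$j + (out$len - k + 1L) == n)
  for (t in ends_at_n) {
    nxt <- which(out$d == out$d[t] & out$j == 0L)
    if (length(nxt) == 1 && nxt != t) {
      out$len[t] <- out$len[t] + out$len[nxt] - k + 1L
      out$len[nxt] <- 0L
    }
  }
  out <- out[out$len > 0, ]
  out$len <- pmin(out$len, n)
  data.frame(i = circ_pos(out$j + out$d, n), j = out$j, len = out$len)
}

feature_midpoints <- function(record, pattern) {
  f <- Filter(function(x) grepl(pattern, x$name), record$features)
  vapply(f, function(x) {
    circ_pos(floor((x$intervals$start[1] + x$intervals$end[1]) / 2),
             record$length)
  }, numeric(1))
}

#' @export
print.ir_partition <- function(x, ...) {
  for (r in c("lsc", "irb", "ssc", "ira")) {
    cat(sprintf("  %s: [%d, %d) %d bp\n", toupper(r), x[[r]][["start"]],
                x[[r]][["end"]], x[[r]][["end"]] - x[[r]][["start"]]))
  }
  cat("  junctions:", paste(names(x$junctions), x$junctions, sep = "=",
                            collapse = " "), "\n")
  invisible(x)
}

#' Region lengths of a partition
#' @param part an `ir_partition`.
#' @return named integer vector (lsc, irb, ssc, ira).
#' @export
region_lengths <- function(part) {
  vapply(part[c("lsc", "irb", "ssc", "ira")],
         function(r) as.integer(r[["end"]] - r[["start"]]), integer(1))
}

# which region contains 0-based position p
region_of <- function(part, p) {
  n <- part$length
  for (r in c("lsc", "irb", "ssc", "ira")) {
    if (circ_pos(p - part[[r]][["start"]], n) <
        part[[r]][["end"]] - part[[r]][["start"]]) return(r)
  }
  stop("position outside the genome")
}

# overlap length between arc (s1,e1) and arc (s2,e2) on circle n
arc_overlap_len <- function(s1, e1, s2, e2, n) {
  s1 <- circ_pos(s1, n); e1 <- s1 + (e1 - s1)
  s2 <- circ_pos(s2, n); e2 <- s2 + (e2 - s2)
  ov <- function(a1, b1, a2, b2) max(0, min(b1, b2) - max(a1, a2))
  ov(s1, e1, s2, e2) + ov(s1, e1, s2 + n, e2 + n) + ov(s1 + n, e1 + n, s2, e2)
}

#' Profile genes at the IR/SC junctions
#'
#' For each profiled gene, reports whether it lies inside a region or spans
#' a junction, how far it extends into an inverted repeat, its distance to
#' the nearest IR border when it lies wholly within a single-copy region,
#' and the length of an annotated pseudogene copy if present. `rps19`
#' classically spans the LSC/IRb border, `ycf1` the SSC/IRa border, `ndhF`
#' sits near the IRb/SSC border and `trnH` near the IRa/LSC border.
#'
#' @param record annotated [plastome_record()].
#' @param part an `ir_partition` for the record (computed with
#'   [detect_inverted_repeats()] when omitted).
#' @param genes gene names (prefix match, so `"trnH"` finds `trnH-GUG`).
#' @return data frame with one row per gene: `id`, `gene`, `found`,
#'   `relation` (`inside_region` / `spans_junction`), `region`,
#'   `overlap_into_IR`, `distance_to_border`, `pseudo_copy_length`.
#' @export
junction_profile <- function(record, part = detect_inverted_repeats(record),
                             genes = c("rps19", "ycf1", "ndhF", "trnH")) {
  n <- record$length
  rows <- lapply(genes, function(g) {
    hits <- Filter(function(f) {
      (f$name == g || startsWith(f$name, paste0(g, "-"))) && !f$pseudo &&
        f$kind %in% c("gene", "CDS", "tRNA", "rRNA")
    }, record$features)
    if (length(hits) == 0) {
      return(data.frame(id = record$id, gene = g, found = FALSE,
                        relation = NA_character_, region = NA_character_,
                        overlap_into_IR = NA_integer_,
                        distance_to_border = NA_integer_,
                        pseudo_copy_length = NA_integer_))
    }
    len <- vapply(hits, function(f) sum(f$intervals$end - f$intervals$start),
                  numeric(1))
    f <- hits[[which.max(len)]]
    gs <- min(f$intervals$start)
    ge <- max(f$intervals$end)

    ov <- arc_overlap_len(gs, ge, part$irb[["start"]], part$irb[["end"]], n) +
      arc_overlap_len(gs, ge, part$ira[["start"]], part$ira[["end"]], n)
    glen <- ge - gs
    spans <- ov > 0 && ov < glen
    if (ov == 0) {
      reg <- region_of(part, circ_pos(gs, n))
      rs <- part[[reg]][["start"]]; rlen <- part[[reg]][["end"]] - rs
      dist <- min(circ_pos(gs - rs, n), rlen - circ_pos(ge - rs, n))
    } else dist <- 0L
    ps <- Filter(function(x) {
      (x$name == g || startsWith(x$name, paste0(g, "-"))) && x$pseudo
    }, record$features)
    plen <- if (length(ps) > 0) {
      as.integer(sum(ps[[1]]$intervals$end - ps[[1]]$intervals$start))
    } else NA_integer_
    data.frame(id = record$id, gene = g, found = TRUE,
               relation = if (spans) "spans_junction" else "inside_region",
               region = region_of(part, circ_pos(gs, n)),
               overlap_into_IR = as.integer(ov),
               distance_to_border = as.integer(dist),
               pseudo_copy_length = plen)
  })
  do.call(rbind, rows)
}

#' Cross-species junction summary
#'
#' @param reports list of [junction_profile()] data frames (or a single
#'   one).
#' @return one data frame, one row per (species, gene), TSV-serialisable.
#' @export
compare_junctions <- function(reports) {
  if (is.data.frame(reports)) reports <- list(reports)
  if (length(reports) == 0) stop("at least one junction report is required")
  out <- do.call(rbind, reports)
  rownames(out) <- NULL
  out
}
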