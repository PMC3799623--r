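# Independent brute-force oracles. These deliberately use different
# algorithms from the package implementation: exhaustive enumeration of
# all candidate windows / alignments / internal-state assignments, at
# sizes where that is feasible.

oracle_encode <- function(s) match(strsplit(s, "")[[1]], c("A", "C", "G", "T"))

# all flush valid diagonal windows between integer-encoded x and y, by
# exhaustive enumeration of every (start, end) pair on every diagonal.
# A window is flush when each side abuts a mismatch, a sequence end, or
# the diagonal's clipped lower bound (t_lo_of, the point where
# palindromic copies would start to overlap). Containment pruning is the
# caller's job, mirroring the reported-hit definition.
oracle_diag_windows <- function(x, y, min_len, max_mm, min_ident,
                                diags = NULL, t_lo_of = NULL) {
  nx <- length(x); ny <- length(y)
  if (is.null(diags)) diags <- (-(ny - 1)):(nx - 1)
  out <- list()
  for (d in diags) {
    lo <- max(0L, d); hi <- min(nx, ny + d)
    if (!is.null(t_lo_of)) lo <- max(lo, as.integer(t_lo_of(d)))
    if (hi - lo < min_len) next
    neq <- x[(lo + 1):hi] != y[(lo - d + 1):(hi - d)]
    neq[is.na(neq)] <- TRUE
    cum <- c(0L, cumsum(neq))
    Ld <- hi - lo
    # every window [s, e) in diagonal coordinates relative to lo
    cand <- expand.grid(s = 0:(Ld - min_len), len = min_len:Ld)
    cand <- cand[cand$s + cand$len <= Ld, ]
    mm <- cum[cand$s + cand$len + 1] - cum[cand$s + 1]
    flush_left <- c(TRUE, neq)[cand$s + 1]
    e <- cand$s + cand$len
    flush_right <- c(neq, TRUE)[e + 1]
    valid <- mm <= max_mm & (cand$len - mm) / cand$len >= min_ident &
      flush_left & flush_right
    if (!any(valid)) next
    out[[length(out) + 1]] <- data.frame(
      i = lo + cand$s[valid], j = lo + cand$s[valid] - d,
      len = cand$len[valid], mm = mm[valid])
  }
  if (length(out) == 0) {
    return(data.frame(i = integer(0), j = integer(0), len = integer(0),
                      mm = integer(0)))
  }
  do.call(rbind, out)
}

# containment filter shared by the oracles (mirrors the reported-hit
# definition: a hit contained in a longer hit of the same type with both
# copies nested is redundant)
oracle_drop_contained <- function(h) {
  if (nrow(h) < 2) return(h)
  keep <- rep(TRUE, nrow(h))
  for (a in seq_len(nrow(h))) {
    for (b in seq_len(nrow(h))) {
      if (a == b || !keep[a]) next
      if (h$start1[a] >= h$start1[b] && h$end1[a] <= h$end1[b] &&
          (is.na(h$start2[a]) && is.na(h$start2[b]) ||
           (!is.na(h$start2[a]) && !is.na(h$start2[b]) &&
            h$start2[a] >= h$start2[b] && h$end2[a] <= h$end2[b])) &&
          h$length[a] < h$length[b]) keep[a] <- FALSE
    }
  }
  h[keep, , drop = FALSE]
}

oracle_dispersed <- function(seq, min_len = 30, max_mm = 3,
                             min_ident = 0.90) {
  x <- oracle_encode(seq)
  w <- oracle_diag_windows(x, x, min_len, max_mm, min_ident,
                           diags = 1:(length(x) - 1))
  # x-vs-x with d > 0 means i > j: copy order (j, i)
  w <- w[w$i - w$j >= w$len, , drop = FALSE]
  if (nrow(w) == 0) return(w)
  h <- data.frame(start1 = w$j, end1 = w$j + w$len, start2 = w$i,
                  end2 = w$i + w$len, length = w$len, mm = w$mm)
  h <- oracle_drop_contained(h)
  h[order(h$start1, h$start2), ]
}

oracle_palindromic <- function(seq, min_len = 20, max_mm = 3,
                               min_ident = 0.90, max_gap = 3000) {
  n <- nchar(seq)
  x <- oracle_encode(seq)
  y <- rev(5L - x)  # encoded reverse complement (A<->T, C<->G)
  w <- oracle_diag_windows(x, y, min_len, max_mm, min_ident,
                           t_lo_of = function(d) ceiling((n + d) / 2))
  if (nrow(w) == 0) {
    return(data.frame(start1 = integer(0), end1 = integer(0),
                      start2 = integer(0), end2 = integer(0),
                      length = integer(0), mm = integer(0)))
  }
  a <- n - w$j - w$len
  b <- w$i
  gap <- b - (a + w$len)
  keep <- gap >= 0 & gap <= max_gap
  h <- data.frame(start1 = a[keep], end1 = a[keep] + w$len[keep],
                  start2 = b[keep], end2 = b[keep] + w$len[keep],
                  length = w$len[keep], mm = w$mm[keep])
  h <- unique(h)
  h <- oracle_drop_contained(h)
  h[order(h$start1, h$start2), ]
}

oracle_tandem <- function(seq, min_total = 15, max_mm = 3,
                          min_ident = 0.90, max_unit = 500) {
  x <- oracle_encode(seq)
  core_min <- as.integer(ceiling(min_total / 2))
  w <- oracle_diag_windows(x, x, core_min, max_mm, min_ident,
                           diags = seq_len(min(max_unit, length(x) - 1)))
  p <- w$i - w$j
  keep <- w$len >= p & w$len + p >= min_total
  w <- w[keep, , drop = FALSE]; p <- p[keep]
  if (nrow(w) == 0) {
    return(data.frame(start1 = integer(0), end1 = integer(0),
                      length = integer(0), unit_len = integer(0)))
  }
  h <- data.frame(start1 = w$j, end1 = w$j + w$len + p,
                  start2 = NA_integer_, end2 = NA_integer_,
                  length = w$len + p, unit_len = p, mm = w$mm)
  h <- h[order(h$start1, h$end1, h$unit_len), ]
  h <- h[!duplicated(h[c("start1", "end1")]), ]
  h <- oracle_drop_contained(h)
  h[order(h$start1), ]
}

# exhaustive global alignment score with affine gaps
# (gap of length l costs open + (l - 1) * ext), by recursive enumeration
oracle_nw_score <- function(a, b, match = 1, mismatch = -1, open = -4,
                            ext = -1) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  rec <- function(i, j, prev) {
    # prev: 0 = none/match, 1 = gap in b, 2 = gap in a
    if (i > length(A) && j > length(B)) return(0)
    best <- -Inf
    if (i <= length(A) && j <= length(B)) {
      s <- if (A[i] == B[j]) match else mismatch
      best <- max(best, s + rec(i + 1, j + 1, 0))
    }
    if (i <= length(A)) {
      g <- if (prev == 1) ext else open
      best <- max(best, g + rec(i + 1, j, 1))
    }
    if (j <= length(B)) {
      g <- if (prev == 2) ext else open
      best <- max(best, g + rec(i, j + 1, 2))
    }
    best
  }
  rec(1, 1, 0)
}

# Fitch length by exhaustive enumeration of internal (and missing-tip)
# state assignments; m is a character matrix, tree an ape::phylo
oracle_fitch <- function(tree, m) {
  tree <- ape::unroot(tree)
  states <- sort(setdiff(unique(as.vector(m)), c("?", "-", "N")))
  nt <- length(tree$tip.label)
  total <- 0
  for (col in seq_len(ncol(m))) {
    tipst <- m[tree$tip.label, col]
    free <- which(tipst %in% c("?", "-", "N"))
    nodes <- tree$Nnode
    combos <- expand.grid(c(
      lapply(seq_len(nodes), function(i) states),
      lapply(free, function(i) states)), stringsAsFactors = FALSE)
    best <- Inf
    for (r in seq_len(nrow(combos))) {
      asg <- tipst
      if (length(free)) asg[free] <- unlist(combos[r, nodes + seq_along(free)])
      full <- c(asg, unlist(combos[r, seq_len(nodes)]))
      cost <- sum(full[tree$edge[, 1]] != full[tree$edge[, 2]])
      best <- min(best, cost)
    }
    total <- total + best
  }
  total
}

# direct per-column site classification
oracle_site_stats <- function(mat) {
  L <- ncol(mat)
  nv <- 0L; np <- 0L
  for (col in seq_len(L)) {
    v <- mat[, col]
    if (any(v %in% c("-", "N"))) next
    tab <- table(v)
    if (length(tab) >= 2) nv <- nv + 1L
    if (sum(tab >= 2) >= 2) np <- np + 1L
  }
  list(n_variable = nv, n_pis = np)
}

# random character matrix over ACGT with optional missing entries
random_charmatrix <- function(ntaxa, nsites, p_missing = 0,
                              prob = c(.4, .2, .2, .2)) {
  m <- matrix(sample(c("A", "C", "G", "T"), ntaxa * nsites, TRUE,
                     prob = prob),
              ntaxa, nsites, dimnames = list(paste0("t", seq_len(ntaxa)),
                                             NULL))
  if (p_missing > 0) {
    m[sample(length(m), round(p_missing * length(m)))] <- "?"
  }
  m
}

random_dna_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# mutate k positions of a DNA string (guaranteed different base)
mutate_str <- function(s, k) {
  ch <- strsplit(s, "")[[1]]
  pos <- sample(length(ch), k)
  for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
  paste(ch, collapse = "")
}

# repeat-hit comparison on the shared coordinate columns
hit_key <- function(h) {
  if (nrow(h) == 0) return(character(0))
  sort(paste(h$start1, h$end1, h$start2, h$end2, sep = ":"))
}
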