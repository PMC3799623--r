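#' @name parsimony
#' @title Maximum-parsimony inference
#'
#' @description
#' Fitch parsimony over unordered characters: tree length by the two-pass
#' set algorithm, exhaustive enumeration of unrooted binary topologies at
#' small taxon numbers, heuristic search with random stepwise addition and
#' NNI/SPR branch swapping, nonparametric bootstrap, majority-rule
#' consensus and the consistency/retention homoplasy indices.
#'
#' Character matrices are plain character matrices (taxa in rows) over
#' `{A,C,G,T}` or `{0,1}`; `?`, `-` and `N` are treated as missing and
#' join any state. Use [msa_to_charmatrix()] to build one from an
#' alignment.
NULL

#' Convert an alignment to a parsimony character matrix
#'
#' Gaps and N become `?` (missing), matching the convention of excluding
#' alignment gaps from the optimisation.
#'
#' @param x a [msa()].
#' @return character matrix taxa x columns.
#' @export
msa_to_charmatrix <- function(x) {
  m <- msa_matrix(x)
  m[m == "-" | m == "N"] <- "?"
  m
}

# ---- internal encoded representation ------------------------------------

# encode a character matrix as bitmasks; missing = all-states mask
encode_charmatrix <- function(m) {
  if (is.null(rownames(m))) stop("character matrix must have row names")
  m[m %in% c("-", "N", "n")] <- "?"
  syms <- sort(setdiff(unique(as.vector(m)), "?"))
  if (length(syms) < 1 || length(syms) > 8) {
    stop("unsupported state alphabet: ", paste(syms, collapse = ""))
  }
  full <- as.integer(2^length(syms) - 1)
  E <- matrix(full, nrow(m), ncol(m), dimnames = dimnames(m))
  for (s in seq_along(syms)) E[m == syms[s]] <- as.integer(2^(s - 1))
  attr(E, "full") <- full
  E
}

# compress columns to unique patterns with weights; classify columns
compress_patterns <- function(E) {
  full <- attr(E, "full")
  key <- apply(E, 2, paste, collapse = ",")
  uk <- unique(key)
  idx <- match(uk, key)
  P <- E[, idx, drop = FALSE]
  w <- as.integer(table(factor(key, levels = uk)))
  nstates <- integer(ncol(P)); informative <- logical(ncol(P))
  minsteps <- integer(ncol(P)); maxsteps <- integer(ncol(P))
  for (t in seq_len(ncol(P))) {
    obs <- P[, t][P[, t] != full]
    cnt <- table(obs)
    nstates[t] <- length(cnt)
    minsteps[t] <- max(0L, length(cnt) - 1L)
    maxsteps[t] <- if (length(cnt) == 0) 0L else length(obs) - max(cnt)
    informative[t] <- sum(cnt >= 2) >= 2
  }
  list(P = P, w = w, minsteps = minsteps, maxsteps = maxsteps,
       informative = informative, full = full)
}

# ---- nested-list tree representation (rooted at a reference tip) --------

# Fitch steps of the unrooted tree (root_tip, sub) on patterns P
# (taxa x patterns bitmask matrix) with column weights w
fitch_engine <- function(root_tip, sub, P, w) {
  rec <- function(node) {
    if (!is.list(node)) return(list(mask = P[node, ], steps = 0))
    a <- rec(node[[1]]); b <- rec(node[[2]])
    inter <- bitwAnd(a$mask, b$mask)
    empty <- inter == 0L
    if (any(empty)) inter[empty] <- bitwOr(a$mask, b$mask)[empty]
    list(mask = inter,
         steps = a$steps + b$steps + sum(w[empty]))
  }
  r <- rec(sub)
  r$steps + sum(w[bitwAnd(r$mask, P[root_tip, ]) == 0L])
}

# all ways of inserting tip x on an edge of the rooted subtree
insert_all <- function(node, x) {
  res <- list(list(node, x))
  if (is.list(node)) {
    for (s in insert_all(node[[1]], x)) res <- c(res, list(list(s, node[[2]])))
    for (s in insert_all(node[[2]], x)) res <- c(res, list(list(node[[1]], s)))
  }
  res
}

node_paths <- function(node, cur = integer(0)) {
  res <- list(cur)
  if (is.list(node)) {
    res <- c(res, node_paths(node[[1]], c(cur, 1L)),
             node_paths(node[[2]], c(cur, 2L)))
  }
  res
}

get_node <- function(node, path) {
  for (p in path) node <- node[[p]]
  node
}

set_node <- function(node, path, val) {
  if (length(path) == 0) return(val)
  node[[path[1]]] <- set_node(node[[path[1]]], path[-1], val)
  node
}

# NNI neighbours: swap the sibling of an internal node with one of its
# children, for every internal edge
nni_neighbours <- function(sub) {
  res <- list()
  for (pv in node_paths(sub)) {
    if (length(pv) == 0) next
    v <- get_node(sub, pv)
    if (!is.list(v)) next
    pp <- pv[-length(pv)]
    sib_path <- c(pp, 3L - pv[length(pv)])
    C <- get_node(sub, sib_path)
    for (child in 1:2) {
      t1 <- set_node(sub, sib_path, v[[child]])
      t1 <- set_node(t1, pv, {
        vv <- v; vv[[child]] <- C; vv
      })
      res <- c(res, list(t1))
    }
  }
  res
}

# SPR neighbours: prune the subtree above any path and regraft it on
# every edge of what remains
spr_neighbours <- function(sub) {
  res <- list()
  for (pv in node_paths(sub)) {
    if (length(pv) == 0) next
    pruned <- get_node(sub, pv)
    pp <- pv[-length(pv)]
    sib <- get_node(sub, c(pp, 3L - pv[length(pv)]))
    remain <- set_node(sub, pp, sib)
    res <- c(res, insert_all(remain, pruned))
  }
  res
}

# nested subtree -> newick over taxon names, with the reference tip as
# basal trifurcation partner
nested_newick <- function(root_tip, sub, taxa) {
  nw <- function(node) {
    if (!is.list(node)) return(taxa[node])
    paste0("(", nw(node[[1]]), ",", nw(node[[2]]), ")")
  }
  if (!is.list(sub)) {
    sprintf("(%s,%s);", taxa[root_tip], taxa[sub])
  } else {
    sprintf("(%s,%s,%s);", taxa[root_tip], nw(sub[[1]]), nw(sub[[2]]))
  }
}

nested_to_phylo <- function(root_tip, sub, taxa) {
  ape::read.tree(text = nested_newick(root_tip, sub, taxa))
}

# phylo -> (root_tip index, nested subtree) over the taxon index space
phylo_to_nested <- function(tree, taxa, root_label = taxa[1]) {
  if (!setequal(tree$tip.label, taxa)) {
    stop("tree leaf set does not match the matrix taxa")
  }
  tree <- ape::unroot(tree)
  nt <- length(tree$tip.label)
  adj <- vector("list", nt + tree$Nnode)
  for (e in seq_len(nrow(tree$edge))) {
    a <- tree$edge[e, 1]; b <- tree$edge[e, 2]
    adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
  }
  build <- function(node, parent) {
    kids <- setdiff(adj[[node]], parent)
    if (length(kids) == 0) return(match(tree$tip.label[node], taxa))
    if (length(kids) != 2) stop("tree must be binary")
    list(build(kids[1], node), build(kids[2], node))
  }
  rt <- which(tree$tip.label == root_label)
  list(root_tip = match(root_label, taxa),
       sub = build(adj[[rt]][1], rt))
}

# canonical key of an unrooted topology: its sorted nontrivial splits
splits_of <- function(tree) {
  tree <- ape::unroot(tree)
  nt <- length(tree$tip.label)
  ref <- sort(tree$tip.label)[1]
  tree <- ape::reorder.phylo(tree, "postorder")
  sets <- vector("list", nt + tree$Nnode)
  for (i in seq_len(nt)) sets[[i]] <- tree$tip.label[i]
  for (e in seq_len(nrow(tree$edge))) {
    a <- tree$edge[e, 1]; b <- tree$edge[e, 2]
    sets[[a]] <- c(sets[[a]], sets[[b]])
  }
  out <- character(0)
  for (e in seq_len(nrow(tree$edge))) {
    b <- tree$edge[e, 2]
    if (b <= nt) next
    side <- sort(sets[[b]])
    if (ref %in% side) side <- sort(setdiff(tree$tip.label, side))
    if (length(side) < 2 || length(side) > nt - 2) next
    out <- c(out, paste(side, collapse = ","))
  }
  sort(unique(out))
}

topology_key <- function(tree) paste(splits_of(tree), collapse = ";")

# ---- exported operations ------------------------------------------------

#' Fitch tree length
#'
#' Minimum number of unordered state changes of a character matrix on a
#' binary tree, by the Fitch set algorithm; missing states (`?`, `-`, `N`)
#' join any state. Invariant under re-rooting.
#'
#' @param tree an [ape::phylo] whose tips are exactly the matrix rows.
#' @param m character matrix (taxa x sites).
#' @return integer number of steps.
#' @export
fitch_length <- function(tree, m) {
  taxa <- rownames(m)
  nest <- phylo_to_nested(tree, taxa)
  E <- encode_charmatrix(m)
  cp <- compress_patterns(E)
  as.integer(fitch_engine(nest$root_tip, nest$sub, cp$P, cp$w))
}

search_setup <- function(m) {
  E <- encode_charmatrix(m)
  cp <- compress_patterns(E)
  keep <- cp$informative
  list(P = cp$P[, keep, drop = FALSE], w = cp$w[keep],
       offset = sum(cp$w[!keep] * cp$minsteps[!keep]),
       taxa = rownames(m))
}

#' Exhaustive maximum-parsimony search
#'
#' Enumerates all `(2n - 5)!!` unrooted binary topologies and returns
#' every tree of minimum Fitch length.
#'
#' @param m character matrix with 3..`max_taxa` rows.
#' @param max_taxa refuse larger problems (use [heuristic_search()]).
#' @return list with `trees` (`multiPhylo` of all MP trees), `length`
#'   (minimum steps) and `n_topologies`.
#' @export
exhaustive_search <- function(m, max_taxa = 10) {
  n <- nrow(m)
  if (n < 3) stop("at least three taxa are required")
  if (n > max_taxa) {
    stop("more than ", max_taxa, " taxa: use heuristic_search()")
  }
  st <- search_setup(m)
  subs <- list(2L)
  for (t in seq_len(n)[-(1:2)]) {
    subs <- do.call(c, lapply(subs, insert_all, x = t))
  }
  lens <- vapply(subs, function(s) fitch_engine(1L, s, st$P, st$w),
                 numeric(1))
  best <- which(lens == min(lens))
  trees <- lapply(subs[best], nested_to_phylo, root_tip = 1L,
                  taxa = st$taxa)
  class(trees) <- "multiPhylo"
  list(trees = trees, length = as.integer(min(lens) + st$offset),
       n_topologies = length(subs))
}

#' Heuristic maximum-parsimony search
#'
#' Random stepwise-addition starting trees, each improved to a local
#' optimum by branch swapping; all shortest trees found across replicates
#' are kept (up to `keep_max` distinct topologies).
#'
#' @param m character matrix (>= 4 taxa).
#' @param n_addition number of random-addition replicates.
#' @param swap branch-swapping neighbourhood, `"SPR"` or `"NNI"`.
#' @param seed optional RNG seed for reproducibility.
#' @param keep_max cap on stored equally parsimonious trees (a message is
#'   emitted when hit).
#' @return list with `trees` (`multiPhylo`), `length`, `n_addition`.
#' @export
heuristic_search <- function(m, n_addition = 1000, swap = c("SPR", "NNI"),
                             seed = NULL, keep_max = 1000) {
  swap <- match.arg(swap)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(m)
  if (n < 4) stop("at least four taxa are required")
  st <- search_setup(m)
  neigh_fun <- if (swap == "NNI") nni_neighbours else spr_neighbours
  best_len <- Inf
  best <- list()
  capped <- FALSE
  for (rep in seq_len(n_addition)) {
    ord <- sample.int(n)
    rt <- ord[1]
    sub <- ord[2]
    for (t in ord[-(1:2)]) {
      cands <- insert_all(sub, t)
      lens <- vapply(cands, function(s) fitch_engine(rt, s, st$P, st$w),
                     numeric(1))
      sub <- cands[[which.min(lens)]]
    }
    cur <- fitch_engine(rt, sub, st$P, st$w)
    repeat {
      nb <- neigh_fun(sub)
      lens <- vapply(nb, function(s) fitch_engine(rt, s, st$P, st$w),
                     numeric(1))
      if (min(lens) < cur) {
        cur <- min(lens)
        sub <- nb[[which.min(lens)]]
      } else break
    }
    if (cur < best_len) { best_len <- cur; best <- list() }
    if (cur == best_len) {
      tr <- nested_to_phylo(rt, sub, st$taxa)
      key <- topology_key(tr)
      if (is.null(best[[key]])) {
        if (length(best) < keep_max) {
          best[[key]] <- tr
        } else if (!capped) {
          message("equally parsimonious tree cap (", keep_max, ") reached")
          capped <- TRUE
        }
      }
    }
  }
  trees <- unname(best)
  class(trees) <- "multiPhylo"
  list(trees = trees, length = as.integer(best_len + st$offset),
       n_addition = n_addition)
}

#' Nonparametric bootstrap support for the MP tree
#'
#' Columns are resampled with replacement; each replicate is analysed by a
#' compact heuristic search and a split is credited when it appears in all
#' of the replicate's shortest trees. Support of each internal edge of the
#' best tree is the percentage of crediting replicates.
#'
#' @param m character matrix.
#' @param replicates bootstrap replicates.
#' @param seed optional RNG seed.
#' @param best optional precomputed best tree ([ape::phylo]); computed by
#'   [heuristic_search()] when absent.
#' @param n_addition addition replicates per bootstrap search.
#' @param swap neighbourhood used in replicate searches.
#' @return list with `tree` (best tree, `node.label` holding support
#'   percentages) and `support` (data frame split / percent).
#' @export
bootstrap_support <- function(m, replicates = 500, seed = NULL,
                              best = NULL, n_addition = 2,
                              swap = c("NNI", "SPR")) {
  swap <- match.arg(swap)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(best)) {
    best <- heuristic_search(m, n_addition = max(10, n_addition),
                             swap = swap)$trees[[1]]
  }
  ref_splits <- splits_of(best)
  hits <- stats::setNames(numeric(length(ref_splits)), ref_splits)
  for (r in seq_len(replicates)) {
    idx <- sample.int(ncol(m), replace = TRUE)
    res <- heuristic_search(m[, idx, drop = FALSE],
                            n_addition = n_addition, swap = swap)
    spl <- Reduce(intersect, lapply(res$trees, splits_of))
    inref <- ref_splits %in% spl
    hits[inref] <- hits[inref] + 1
  }
  pct <- round(100 * hits / replicates, 1)
  tree <- annotate_support(best, pct)
  list(tree = tree,
       support = data.frame(split = ref_splits, support = unname(pct)))
}

# write split supports onto the node labels of a tree
annotate_support <- function(tree, pct) {
  tree <- ape::unroot(tree)
  nt <- length(tree$tip.label)
  ref <- sort(tree$tip.label)[1]
  tr2 <- ape::reorder.phylo(tree, "postorder")
  sets <- vector("list", nt + tr2$Nnode)
  for (i in seq_len(nt)) sets[[i]] <- tr2$tip.label[i]
  for (e in seq_len(nrow(tr2$edge))) {
    sets[[tr2$edge[e, 1]]] <- c(sets[[tr2$edge[e, 1]]],
                                sets[[tr2$edge[e, 2]]])
  }
  labs <- rep("", tr2$Nnode)
  for (v in seq_len(tr2$Nnode)) {
    side <- sort(sets[[nt + v]])
    if (ref %in% side) side <- sort(setdiff(tr2$tip.label, side))
    key <- paste(side, collapse = ",")
    if (key %in% names(pct)) labs[v] <- as.character(pct[[key]])
  }
  tree$node.label <- labs
  tree
}

#' Majority-rule consensus tree
#'
#' @param trees list or `multiPhylo` of trees over one leaf set.
#' @param cutoff retain splits with frequency strictly above this
#'   fraction (0.5 gives the 50% majority rule).
#' @return an [ape::phylo]; node labels carry split frequencies in
#'   percent.
#' @export
majority_consensus <- function(trees, cutoff = 0.5) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  if (length(trees) == 0) stop("at least one tree is required")
  leaves <- sort(trees[[1]]$tip.label)
  for (tr in trees) {
    if (!setequal(tr$tip.label, leaves)) stop("trees must share one leaf set")
  }
  tally <- table(unlist(lapply(trees, splits_of)))
  freq <- as.numeric(tally) / length(trees)
  keep <- freq > cutoff
  clades <- strsplit(names(tally)[keep], ",", fixed = TRUE)
  pcts <- round(100 * freq[keep], 1)
  ref <- leaves[1]
  rest <- setdiff(leaves, ref)
  o <- order(lengths(clades))
  clades <- clades[o]; pcts <- pcts[o]
  build <- function(tipset) {
    inside <- which(vapply(clades, function(cl) {
      length(cl) < length(tipset) && all(cl %in% tipset)
    }, logical(1)))
    # maximal clades strictly inside tipset
    maximal <- inside[vapply(inside, function(a) {
      !any(vapply(inside, function(b) {
        b != a && length(clades[[a]]) < length(clades[[b]]) &&
          all(clades[[a]] %in% clades[[b]])
      }, logical(1)))
    }, logical(1))]
    covered <- unlist(clades[maximal])
    parts <- c(
      vapply(maximal, function(a) {
        paste0(build(clades[[a]]), as.character(pcts[a]))
      }, character(1)),
      setdiff(tipset, covered))
    paste0("(", paste(parts, collapse = ","), ")")
  }
  inner <- build(rest)
  inner <- sub("^\\(", "", sub("\\)$", "", inner))
  ape::read.tree(text = paste0("(", ref, ",", inner, ");"))
}

#' Consistency and retention indices
#'
#' `CI = sum(min steps) / sum(observed steps)` and
#' `RI = (sum(max) - sum(obs)) / (sum(max) - sum(min))`, summed over all
#' columns (parsimony-uninformative ones included). Per column, the
#' minimum is the number of observed states minus one and the maximum is
#' the number of non-missing taxa minus the largest state frequency.
#'
#' @param tree an [ape::phylo] over the matrix taxa.
#' @param m character matrix.
#' @return list `ci`, `ri` (`ri` is `NA` when no informative variation
#'   exists), `tree_length`, `min_length`, `max_length`.
#' @export
ci_ri <- function(tree, m) {
  taxa <- rownames(m)
  nest <- phylo_to_nested(tree, taxa)
  E <- encode_charmatrix(m)
  cp <- compress_patterns(E)
  obs <- vapply(seq_len(ncol(cp$P)), function(t) {
    fitch_engine(nest$root_tip, nest$sub, cp$P[, t, drop = FALSE], 1L)
  }, numeric(1))
  s_obs <- sum(cp$w * obs)
  s_min <- sum(cp$w * cp$minsteps)
  s_max <- sum(cp$w * cp$maxsteps)
  list(ci = if (s_obs > 0) s_min / s_obs else NA_real_,
       ri = if (s_max > s_min) (s_max - s_obs) / (s_max - s_min)
            else NA_real_,
       tree_length = as.integer(s_obs), min_length = as.integer(s_min),
       max_length = as.integer(s_max))
}
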