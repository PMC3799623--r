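#' Simulation configuration for synthetic plastome families
#'
#' Defines a desk-scale circular quadripartite genome (default 20 kb:
#' LSC 12 kb, IRs 3 kb, SSC 2 kb) with a realistic gene layout — genes
#' spanning the LSC/IRb and SSC/IRa junctions with truncated pseudogene
#' copies on the opposite border, rRNA/tRNA genes duplicated in the IR,
#' one spliced gene — plus planted tandem, dispersed and palindromic
#' repeats in intergenic spacers, and the divergence process used by
#' [evolve_family()].
#'
#' @param seed mandatory RNG seed; the same seed yields byte-identical
#'   fixtures.
#' @param n_taxa number of leaves when a random tree is drawn.
#' @param tree optional [ape::phylo] (rooted, branch lengths in expected
#'   substitutions per site); drawn at random when `NULL`.
#' @param lsc_len,irb_len,ssc_len region lengths in bp.
#' @param sub_rate mean root-to-tip path length (substitutions per site)
#'   used to scale a randomly drawn tree.
#' @param indel_rate indel events per site per unit branch length
#'   (relative to the substitution rate of 1).
#' @param indel_geom_p geometric length distribution parameter for indels
#'   (mean length `1/p`).
#' @param indel_max cap on single indel length.
#' @param plant_repeats plant the repeat set listed above.
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed, n_taxa = 8, tree = NULL, lsc_len = 12000,
                       irb_len = 3000, ssc_len = 2000, sub_rate = 0.02,
                       indel_rate = 0.1, indel_geom_p = 0.35,
                       indel_max = 24, plant_repeats = TRUE) {
  if (missing(seed)) stop("a seed is mandatory")
  stopifnot(sub_rate >= 0, indel_rate >= 0, lsc_len >= 6000,
            irb_len >= 1200, ssc_len >= 1200)
  structure(list(seed = as.integer(seed), n_taxa = n_taxa, tree = tree,
                 lsc_len = lsc_len, irb_len = irb_len, ssc_len = ssc_len,
                 sub_rate = sub_rate, indel_rate = indel_rate,
                 indel_geom_p = indel_geom_p, indel_max = indel_max,
                 plant_repeats = isTRUE(plant_repeats)),
            class = "sim_config")
}

# gene layout scaled to the configured region lengths; coordinates are
# full-genome, 0-based half-open, with intervals in reading order
default_layout <- function(cfg) {
  L <- cfg$lsc_len; B <- cfg$irb_len; S <- cfg$ssc_len
  sc <- function(x) as.integer(round(x * L / 12000))
  g <- function(name, kind, s, e, strand = "+") {
    list(name = name, kind = kind,
         intervals = data.frame(start = s, end = e, strand = strand))
  }
  j_lb <- L; j_sb <- L + B; j_sa <- L + B + S
  full <- L + 2L * B + S
  layout <- list(
    g("trnH-GUG", "tRNA", sc(10), sc(85), "-"),
    g("psbA", "gene", sc(200), sc(1250), "-"),
    g("atpA", "gene", sc(1700), sc(3220), "+"),
    g("atpF", "gene", c(sc(3300), sc(4130)), c(sc(3710), sc(4540)), "+"),
    g("rpoB", "gene", sc(4600), sc(7600), "-"),
    g("petN", "gene", sc(7800), sc(7890), "+"),
    g("psbD", "gene", sc(8290), sc(9350), "+"),
    g("rbcL", "gene", sc(9600), sc(11030), "+"),
    g("rps16", "gene", c(sc(11660), sc(11100)), c(sc(11890), sc(11320)), "-"),
    g("rps19", "gene", j_lb - 45L, j_lb + 49L, "+"),
    g("trnI-CAU", "tRNA", j_lb + round(B * 0.2), j_lb + round(B * 0.2) + 74,
      "+"),
    g("rrn16", "rRNA", j_lb + round(B * 0.37), j_lb + round(B * 0.77), "+"),
    g("ndhF", "gene", j_sb + 40L, j_sb + 40L + round(S * 0.4), "-"),
    g("ccsA", "gene", j_sb + round(S * 0.5), j_sb + round(S * 0.63), "+"),
    g("ycf1", "gene", j_sa - round(S * 0.32), j_sa + round(B * 0.17), "+"))
  attr(layout, "junctions") <- c(J_LB = j_lb, J_SB = j_sb, J_SA = j_sa,
                                 J_LA = 0L)
  attr(layout, "full_length") <- full
  layout
}

# planted repeat registry in LSC spacers (full-genome coordinates)
default_repeats <- function(cfg) {
  sc <- function(x) as.integer(round(x * cfg$lsc_len / 12000))
  data.frame(
    type = c("tandem", "dispersed", "palindromic"),
    start1 = c(sc(1300), sc(1360), sc(7940)),
    end1 = c(sc(1300) + 24L, sc(1360) + 40L, sc(7940) + 24L),
    start2 = c(NA, sc(7650), sc(7940) + 24L + 60L),
    end2 = c(NA, sc(7650) + 40L, sc(7940) + 48L + 60L),
    unit_len = c(12L, NA, NA))
}

#' Build the ancestral synthetic plastome
#'
#' Constructs the circular LSC+IRb+SSC+IRa genome (IRa is exactly the
#' reverse complement of IRb), annotates the layout genes including the
#' junction-spanning ones and their pseudogene copies, and plants the
#' configured repeats.
#'
#' @param cfg a [sim_config()].
#' @return list with `record` (annotated [plastome_record()]) and `truth`
#'   (layout, junctions, planted-repeat registry).
#' @export
build_ancestor <- function(cfg) {
  set.seed(cfg$seed)
  L <- cfg$lsc_len; B <- cfg$irb_len; S <- cfg$ssc_len
  lred <- L + B + S
  full <- lred + B
  layout <- default_layout(cfg)
  juncs <- attr(layout, "junctions")
  if (attr(layout, "full_length") != full) stop("layout overflow")
  for (f in layout) {
    if (any(f$intervals$end > full)) stop("layout overflow: ", f$name)
  }
  red <- seq_chars(random_dna(lred))

  reps <- if (cfg$plant_repeats) default_repeats(cfg) else
    default_repeats(cfg)[0, ]
  if (nrow(reps) > 0) {
    unit <- random_dna(reps$unit_len[1])
    red[(reps$start1[1] + 1):reps$end1[1]] <- seq_chars(strrep(unit, 2))
    disp <- random_dna(40)
    red[(reps$start1[2] + 1):reps$end1[2]] <- seq_chars(disp)
    red[(reps$start2[2] + 1):reps$end2[2]] <- seq_chars(disp)
    stem <- random_dna(24)
    red[(reps$start1[3] + 1):reps$end1[3]] <- seq_chars(stem)
    red[(reps$start2[3] + 1):reps$end2[3]] <- seq_chars(revcomp(stem))
  }
  # stop the IR pair from extending by chance past the planted borders:
  # outward extension pairs the first LSC base with the last base before
  # IRb, inward extension pairs the first SSC base with the last SSC base
  comp1 <- chartr("ACGT", "TGCA", red[L])
  if (red[1] == comp1) red[1] <- setdiff(c("A", "C", "G", "T"),
                                         c(red[1], comp1))[1]
  comp2 <- chartr("ACGT", "TGCA", red[L + B + 1])
  if (red[lred] == comp2) red[lred] <- setdiff(c("A", "C", "G", "T"),
                                               c(red[lred], comp2))[1]
  redseq <- paste(red, collapse = "")
  irb_seq <- substr(redseq, L + 1, L + B)
  sequence <- paste0(redseq, revcomp(irb_seq))

  feats <- ancestor_features(layout, juncs, B, lred)
  rec <- plastome_record("SIM-ANC", sequence, taxon = "ancestor",
                         circular = TRUE, features = feats)
  list(record = rec,
       truth = list(layout = layout, junctions = juncs, repeats = reps,
                    lsc_len = L, irb_len = B, ssc_len = S))
}

# mirror IRb-interval (a,b) into IRa space: genome [jsa, jsa+B) mirrors
# [jlb, jlb+B) reversed
mirror_interval <- function(s, e, j_lb, j_sa, B) {
  c(j_sa + (j_lb + B - e), j_sa + (j_lb + B - s))
}

flip <- function(x) ifelse(x == "+", "-", "+")

# full feature list: layout genes + IRa mirror copies + pseudogenes
ancestor_features <- function(layout, juncs, B, lred) {
  j_lb <- juncs[["J_LB"]]; j_sb <- juncs[["J_SB"]]; j_sa <- juncs[["J_SA"]]
  feats <- list()
  for (f in layout) {
    feats[[length(feats) + 1L]] <-
      feature(f$name, f$kind, f$intervals, pseudo = FALSE)
    s <- min(f$intervals$start); e <- max(f$intervals$end)
    if (s >= j_lb && e <= j_sb) {
      # wholly inside IRb: full duplicate in IRa
      mi <- mirror_interval(f$intervals$start, f$intervals$end, j_lb, j_sa, B)
      n <- nrow(f$intervals)
      ints <- data.frame(start = mi[seq_len(n)],
                         end = mi[n + seq_len(n)],
                         strand = flip(f$intervals$strand))
      feats[[length(feats) + 1L]] <-
        feature(f$name, f$kind, ints[rev(seq_len(n)), , drop = FALSE])
    } else if (s < j_lb && e > j_lb && e <= j_sb) {
      # spans LSC/IRb: truncated pseudo copy at the IRa/LSC border
      mi <- mirror_interval(j_lb, e, j_lb, j_sa, B)
      feats[[length(feats) + 1L]] <- feature(
        f$name, f$kind,
        data.frame(start = mi[1], end = mi[2],
                   strand = flip(f$intervals$strand[1])),
        pseudo = TRUE)
    } else if (s < j_sa && e > j_sa) {
      # spans SSC/IRa: the overhang mirrors to a pseudo copy at IRb/SSC
      ov <- e - j_sa
      feats[[length(feats) + 1L]] <- feature(
        f$name, f$kind,
        data.frame(start = j_sb - ov, end = j_sb,
                   strand = flip(f$intervals$strand[1])),
        pseudo = TRUE)
    }
  }
  feats
}

#' Evolve a synthetic plastome family along a tree
#'
#' Applies Jukes-Cantor substitutions (Poisson events, uniform target
#' base) and geometric-length insertions/deletions independently along the
#' branches of a rooted tree, tracking the true multiple alignment through
#' every indel. Only the LSC+IRb+SSC portion evolves; IRa is regenerated
#' as the exact reverse complement of each descendant IRb, so IR copies
#' co-evolve. Indels avoid planted repeats and the junction-spanning
#' genes, keeping the structural ground truth intact.
#'
#' @param ancestor output of [build_ancestor()].
#' @param cfg the same [sim_config()].
#' @return list with `records` (named list of annotated leaf
#'   [plastome_record()]s), and `truth`: `tree` (rooted, branch lengths),
#'   `alignment` (true reduced-genome [msa()] over the leaves),
#'   `col_region` (per alignment column: lsc/irb/ssc), `junctions` (per
#'   leaf), `branch_subs` (per-edge substitution event counts),
#'   `repeats` (ancestral planted-repeat registry), `layout`.
#' @export
evolve_family <- function(ancestor, cfg) {
  set.seed(cfg$seed + 1L)
  tree <- cfg$tree
  if (is.null(tree)) {
    tree <- ape::rtree(cfg$n_taxa)
    depths <- ape::node.depth.edgelength(tree)[seq_len(cfg$n_taxa)]
    tree$edge.length <- tree$edge.length * cfg$sub_rate / mean(depths)
  } else if (is.character(tree)) {
    tree <- ape::read.tree(text = tree)
  }
  if (is.null(tree$edge.length)) stop("the tree needs branch lengths")

  L <- ancestor$truth$lsc_len; B <- ancestor$truth$irb_len
  S <- ancestor$truth$ssc_len
  lred <- L + B + S
  redseq <- substr(ancestor$record$sequence, 1, lred)

  env <- new.env()
  env$col_order <- seq_len(lred)
  env$next_id <- lred + 1L
  env$region <- c(rep("lsc", L), rep("irb", B), rep("ssc", S))
  env$allowed <- !indel_forbidden_mask(ancestor, lred)
  env$leaf <- list()
  env$branch_subs <- list()

  root_state <- list(cols = seq_len(lred), bases = seq_chars(redseq))

  nt <- length(tree$tip.label)
  kids_of <- function(node) tree$edge[tree$edge[, 1] == node, 2]
  blen_of <- function(child) tree$edge.length[tree$edge[, 2] == child]

  walk <- function(node, state) {
    for (ch in kids_of(node)) {
      st <- mutate_branch(state, blen_of(ch), cfg, env, label = ch)
      if (ch <= nt) env$leaf[[tree$tip.label[ch]]] <- st
      else walk(ch, st)
    }
  }
  walk(nt + 1L, root_state)

  ord <- env$col_order
  taxa <- tree$tip.label
  rows <- vapply(taxa, function(tx) {
    st <- env$leaf[[tx]]
    row <- rep("-", length(ord))
    row[match(st$cols, ord)] <- st$bases
    paste(row, collapse = "")
  }, character(1))
  aln <- msa(rows, region = "reduced_genome")
  col_region <- env$region[ord]

  records <- list()
  juncs_leaf <- list()
  for (tx in taxa) {
    st <- env$leaf[[tx]]
    built <- build_leaf_record(tx, st, ord, ancestor, cfg, L, B, S, lred)
    records[[tx]] <- built$record
    juncs_leaf[[tx]] <- built$junctions
  }
  bs <- do.call(rbind, env$branch_subs)
  list(records = records,
       truth = list(tree = tree, alignment = aln, col_region = col_region,
                    junctions = juncs_leaf, branch_subs = bs,
                    repeats = ancestor$truth$repeats,
                    layout = ancestor$truth$layout))
}

# columns where indels must not land: planted repeats and the
# junction-spanning genes, each with a safety margin
indel_forbidden_mask <- function(ancestor, lred, margin = 5L) {
  bad <- rep(FALSE, lred)
  mark <- function(s, e) {
    s <- max(0L, s - margin); e <- min(lred, e + margin)
    if (e > s) bad[(s + 1L):e] <<- TRUE
    bad
  }
  reps <- ancestor$truth$repeats
  for (t in seq_len(nrow(reps))) {
    bad <- mark(reps$start1[t], reps$end1[t])
    if (!is.na(reps$start2[t])) bad <- mark(reps$start2[t], reps$end2[t])
  }
  for (f in ancestor$truth$layout) {
    if (f$name %in% c("rps19", "ycf1")) {
      bad <- mark(min(f$intervals$start), min(lred, max(f$intervals$end)))
    }
  }
  bad
}

mutate_branch <- function(state, t, cfg, env, label) {
  bases <- state$bases; cols <- state$cols
  n <- length(bases)
  nucs <- c("A", "C", "G", "T")

  n_sub <- stats::rpois(1, t * n)
  if (n_sub > 0) {
    pos <- sample.int(n, n_sub, replace = TRUE)
    for (p in pos) {
      bases[p] <- sample(setdiff(nucs, bases[p]), 1)
    }
  }
  env$branch_subs[[length(env$branch_subs) + 1L]] <-
    data.frame(child = label, blen = t, n_sub = n_sub, n_sites = n)

  n_ind <- stats::rpois(1, cfg$indel_rate * t * n)
  for (e in seq_len(n_ind)) {
    len <- min(stats::rgeom(1, cfg$indel_geom_p) + 1L, cfg$indel_max)
    ok <- which(env$allowed[cols])
    if (length(ok) == 0) next
    p <- ok[sample.int(length(ok), 1)]
    if (stats::runif(1) < 0.5) {
      # deletion: run of allowed positions starting at p
      run <- p
      while (length(run) < len && run[length(run)] < length(cols) &&
             env$allowed[cols[run[length(run)] + 1L]]) {
        run <- c(run, run[length(run)] + 1L)
      }
      bases <- bases[-run]; cols <- cols[-run]
    } else {
      # insertion after position p
      new_ids <- env$next_id:(env$next_id + len - 1L)
      env$next_id <- env$next_id + len
      anchor <- cols[p]
      at <- match(anchor, env$col_order)
      env$col_order <- append(env$col_order, new_ids, after = at)
      env$region[new_ids] <- env$region[anchor]
      env$allowed[new_ids] <- TRUE
      bases <- append(bases, sample(nucs, len, replace = TRUE), after = p)
      cols <- append(cols, new_ids, after = p)
    }
  }
  list(cols = cols, bases = bases)
}

# assemble one leaf: full sequence (reduced + revcomp of its IRb) and
# features remapped through the alignment
build_leaf_record <- function(tx, st, ord, ancestor, cfg, L, B, S, lred) {
  leaf_ord <- match(st$cols, ord)
  anc_ord <- match(seq_len(lred), ord)
  # leaf coordinate of an ancestral boundary (0-based, half-open safe)
  coord <- function(p) {
    if (p >= lred) return(length(st$cols))
    sum(leaf_ord < anc_ord[p + 1L])
  }
  map_iv <- function(s, e) c(coord(s), coord(e))

  j_lb <- map_iv(L, L)[1]
  j_sb <- coord(L + B)
  lred_leaf <- length(st$cols)
  irb_leaf <- j_sb - j_lb
  redseq <- paste(st$bases, collapse = "")
  irb_seq <- substr(redseq, j_lb + 1, j_sb)
  sequence <- paste0(redseq, revcomp(irb_seq))
  j_sa <- lred_leaf
  full_leaf <- lred_leaf + irb_leaf

  mirror <- function(s, e) c(j_sa + (j_sb - e), j_sa + (j_sb - s))

  feats <- list()
  for (f in ancestor$truth$layout) {
    n <- nrow(f$intervals)
    ms <- integer(n); me <- integer(n)
    for (t in seq_len(n)) {
      # ycf1-style genes extend past the reduced genome into IRa: the
      # overhang is the mirror of the leaf IRb head
      s <- f$intervals$start[t]; e <- f$intervals$end[t]
      if (e > lred) {
        ov <- map_iv(L, L + (e - lred))
        ms[t] <- map_iv(s, s)[1]
        me[t] <- j_sa + (ov[2] - ov[1])
      } else {
        iv <- map_iv(s, e)
        ms[t] <- iv[1]; me[t] <- iv[2]
      }
    }
    keep <- me > ms
    if (!any(keep)) next
    feats[[length(feats) + 1L]] <- feature(
      f$name, f$kind,
      data.frame(start = ms[keep], end = me[keep],
                 strand = f$intervals$strand[keep]))
    s <- min(f$intervals$start); e <- max(f$intervals$end)
    if (s >= L && e <= L + B) {
      mi <- mirror(min(ms[keep]), max(me[keep]))
      feats[[length(feats) + 1L]] <- feature(
        f$name, f$kind,
        data.frame(start = mi[1], end = mi[2],
                   strand = flip(f$intervals$strand[1])))
    } else if (s < L && e > L && e <= L + B) {
      mi <- mirror(j_lb, max(me[keep]))
      feats[[length(feats) + 1L]] <- feature(
        f$name, f$kind,
        data.frame(start = mi[1], end = mi[2],
                   strand = flip(f$intervals$strand[1])),
        pseudo = TRUE)
    } else if (e > lred) {
      ov <- max(me[keep]) - j_sa
      feats[[length(feats) + 1L]] <- feature(
        f$name, f$kind,
        data.frame(start = j_sb - ov, end = j_sb,
                   strand = flip(f$intervals$strand[1])),
        pseudo = TRUE)
    }
  }
  rec <- plastome_record(tx, sequence, taxon = tx, circular = TRUE,
                         features = feats)
  list(record = rec,
       junctions = c(J_LB = j_lb, J_SB = j_sb, J_SA = j_sa,
                     J_LA = 0L, full_length = full_leaf))
}

#' Simulate a full synthetic plastome family
#'
#' Convenience wrapper: [build_ancestor()] then [evolve_family()].
#'
#' @param cfg a [sim_config()].
#' @return list with `ancestor`, `records`, `truth` (see
#'   [evolve_family()]).
#' @export
simulate_family <- function(cfg) {
  anc <- build_ancestor(cfg)
  fam <- evolve_family(anc, cfg)
  list(ancestor = anc$record, records = fam$records, truth = fam$truth)
}

#' Write a simulated family to disk as standard files
#'
#' GenBank per leaf, a FASTA of the full genomes, the true tree in Newick,
#' the true alignment as aligned FASTA and a JSON truth file (schema
#' version, junctions, planted repeats, per-branch substitution counts).
#'
#' @param fam output of [simulate_family()].
#' @param dir output directory.
#' @param force overwrite an existing directory.
#' @return `dir`, invisibly.
#' @export
write_fixtures <- function(fam, dir, force = FALSE) {
  if (dir.exists(dir) && !force) {
    stop("directory exists (use force = TRUE): ", dir)
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (tx in names(fam$records)) {
    write_genbank(fam$records[[tx]], file.path(dir, paste0(tx, ".gb")))
  }
  write_fasta(vapply(fam$records, `[[`, character(1), "sequence"),
              file.path(dir, "genomes.fasta"))
  write_newick(fam$truth$tree, file.path(dir, "true_tree.nwk"))
  write_msa(fam$truth$alignment, file.path(dir, "true_alignment.fasta"))
  truth <- list(schema = "plastocomp-truth-1",
                junctions = fam$truth$junctions,
                repeats = fam$truth$repeats,
                branch_subs = fam$truth$branch_subs)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
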