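plant <- function(base, at, motif) {
  paste0(substr(base, 1, at), motif,
         substr(base, at + nchar(motif) + 1, nchar(base)))
}

test_that("planted dispersed repeats are found and random noise is not", {
  set.seed(42)
  expect_equal(nrow(find_dispersed(random_dna_str(200))), 0L)

  base <- random_dna_str(2000)
  motif <- random_dna_str(40)
  s <- plant(plant(base, 500, motif), 1500, mutate_str(motif, 2))
  h <- find_dispersed(s)
  expect_true(nrow(h) >= 1)
  # every reported hit covers the planted pair region
  expect_true(any(h$start1 <= 500 & h$end1 >= 538 & h$start2 <= 1502 &
                    h$end2 >= 1538))
  # no spurious distant hits in random background
  expect_true(all(h$start1 >= 480 & h$start2 <= 1560))
})

test_that("planted palindromic repeats respect the gap rule", {
  set.seed(43)
  base <- random_dna_str(2000)
  stem <- random_dna_str(25)
  s <- plant(plant(base, 800, stem), 835, revcomp(stem))
  h <- find_palindromic(s)
  expect_true(any(h$start1 <= 800 & h$end1 >= 823 & h$start2 <= 837))

  # gaps 0, 100 and 2999 are admissible; 3500 is not
  stems <- replicate(4, random_dna_str(22))
  gaps <- c(0, 100, 2999, 3500)
  at <- c(100, 800, 2000, 9000)
  s2 <- random_dna_str(14000)
  for (t in 1:4) {
    s2 <- plant(s2, at[t], paste0(stems[t], strrep("A", 0), ""))
    s2 <- plant(s2, at[t] + 22 + gaps[t], revcomp(stems[t]))
  }
  h2 <- find_palindromic(s2)
  found <- vapply(1:4, function(t) {
    any(h2$start1 <= at[t] & h2$end1 >= at[t] + 20 &
          abs(h2$start2 - (at[t] + 22 + gaps[t])) <= 3)
  }, logical(1))
  expect_identical(found, c(TRUE, TRUE, TRUE, FALSE))
})

test_that("tandem arrays honour the span threshold", {
  set.seed(44)
  base <- random_dna_str(2000)
  s <- plant(base, 300, strrep("AACCGGTTA", 2))          # 18 bp span
  h <- find_tandem(s)
  expect_true(any(h$start1 <= 300 & h$end1 >= 318 & h$unit_len == 9))

  s2 <- plant(base, 300, strrep("ACGT", 3))              # 12 bp: too short
  h2 <- find_tandem(s2)
  expect_false(any(h2$start1 <= 300 & h2$end1 >= 310))
})

test_that("all finders equal the exhaustive oracle on random sequences", {
  set.seed(45)
  for (rep in 1:8) {
    s <- random_dna_str(160)
    # plant structure in half the replicates
    if (rep %% 2 == 0) {
      m <- random_dna_str(32)
      s <- plant(plant(s, 20, m), 100, mutate_str(m, 3))
      s <- plant(s, 60, strrep(random_dna_str(8), 3))
    }
    expect_identical(hit_key(find_dispersed(s, min_len = 25)),
                     hit_key(oracle_dispersed(s, min_len = 25)))
    expect_identical(hit_key(find_palindromic(s, min_len = 18)),
                     hit_key(oracle_palindromic(s, min_len = 18)))
    expect_identical(hit_key(find_tandem(s)), hit_key(oracle_tandem(s)))
  }
})

test_that("finders are deterministic", {
  set.seed(46)
  s <- plant(random_dna_str(1200), 200, strrep(random_dna_str(10), 3))
  expect_identical(find_tandem(s), find_tandem(s))
  expect_identical(find_dispersed(s), find_dispersed(s))
})

test_that("merge is idempotent and respects type precedence", {
  set.seed(47)
  base <- random_dna_str(1500)
  m <- random_dna_str(40)
  s <- plant(plant(base, 200, m), 800, m)
  hits <- rbind(find_tandem(s), find_dispersed(s), find_palindromic(s))
  merged <- merge_and_classify(hits, seq = s)
  expect_identical(merge_and_classify(merged, seq = s), merged)

  # a region that is both a tandem array and one copy of a dispersed
  # pair is emitted as tandem only
  u <- random_dna_str(40)
  s2 <- plant(plant(base, 400, strrep(u, 2)), 1200, u)
  ht <- find_tandem(s2); hd <- find_dispersed(s2)
  expect_true(nrow(ht) > 0 && nrow(hd) > 0)
  m2 <- merge_and_classify(rbind(ht, hd), seq = s2)
  claimed <- m2[m2$start1 <= 440 & m2$end1 >= 440, ]
  expect_true(nrow(claimed) > 0)
  expect_true(all(claimed$type == "tandem"))

  # disjoint hits pass through unchanged (sorted)
  dj <- rbind(find_dispersed(s)[1, ], find_tandem(plant(base, 1200,
                                                        strrep("ACGTTGCAA", 2)))[1, ])
  dj <- dj[!is.na(dj$start1), ]
  mm <- merge_and_classify(dj, seq = NULL)
  expect_equal(nrow(mm), nrow(dj))
})

test_that("two overlapping same-type hits merge into the union motif", {
  h <- data.frame(type = "dispersed",
                  start1 = c(100L, 120L), end1 = c(140L, 160L),
                  start2 = c(500L, 520L), end2 = c(540L, 560L),
                  length = c(40L, 40L), unit_len = NA_integer_,
                  copies = 2L, mismatches = 0L, identity = 1)
  m <- merge_and_classify(h)
  expect_equal(nrow(m), 1L)
  expect_equal(m$start1, 100L); expect_equal(m$end1, 160L)
  expect_equal(m$start2, 500L); expect_equal(m$end2, 560L)
})

test_that("repeat context annotation uses half-open midpoint containment", {
  set.seed(48)
  rec <- plastome_record("L", random_dna_str(600), features = list(
    feature("geneA", "gene", data.frame(start = 100, end = 200,
                                        strand = "+"))))
  hits <- data.frame(type = "dispersed", start1 = c(120L, 400L, 96L),
                     end1 = c(140L, 420L, 104L), start2 = 500L,
                     end2 = 520L, length = 20L, unit_len = NA_integer_,
                     copies = 2L, mismatches = 0L, identity = 1)
  out <- locate_repeats(hits, rec)
  expect_identical(out$context,
                   c("coding(geneA)", "noncoding", "coding(geneA)"))
})

test_that("a repeat spanning the origin is found iff found after rotation", {
  set.seed(49)
  base <- random_dna_str(6000)
  m <- random_dna_str(36)
  # one intact copy at 2000; the second copy straddles the origin
  mid <- plant(base, 2000, m)
  s <- paste0(substr(m, 17, 36), substr(mid, 21, 5980), substr(m, 1, 16))
  rec <- plastome_record("O", s)
  h <- scan_repeats(rec)
  disp <- h[h$type == "dispersed", ]
  expect_true(any(disp$end1 > 5960 | disp$end2 > 5960 |
                    disp$start1 < 20 | disp$start2 > 5900))
  rot <- plastome_record("O2", plastocomp:::rotate_seq(s, 3000))
  h2 <- scan_repeats(rot)
  expect_equal(sort(h$length[h$type == "dispersed"]),
               sort(h2$length[h2$type == "dispersed"]))
})

test_that("per-genome summaries add up", {
  set.seed(50)
  cfg <- sim_config(seed = 50)
  anc <- build_ancestor(cfg)
  part <- detect_inverted_repeats(anc$record)
  hits <- scan_repeats(anc$record, part = part)
  # planted repeats all recovered
  reps <- anc$truth$repeats
  for (t in seq_len(nrow(reps))) {
    cover <- hits$type == reps$type[t] & hits$start1 <= reps$start1[t] &
      hits$end1 >= reps$end1[t]
    expect_true(any(cover))
  }
  sm <- repeat_summary(list(g1 = hits, g2 = hits))
  expect_equal(sm$total, 2L * nrow(hits))
  expect_equal(sum(sm$by_type$n), sm$total)
  expect_equal(sum(sm$by_length$n), sm$total)
  expect_equal(sum(sm$by_location$n), sm$total)
  one <- repeat_summary(list(g = hits[hits$type == "tandem", ]))
  expect_equal(one$by_type$pct[one$by_type$type == "tandem"], 100)
})
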