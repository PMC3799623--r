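test_that("p-distance matches hand counts and the ape oracle", {
  m <- msa(c(a = "AAAA", b = "AAAT"), "x")
  expect_equal(p_distance(m)[1, 2], 0.25)
  m2 <- msa(c(a = "ACGT", b = "ACGT", c = "ACGT"), "x")
  expect_true(all(p_distance(m2)[upper.tri(diag(3))] == 0))

  set.seed(81)
  for (rep in 1:10) {
    rows <- stats::setNames(vapply(1:4, function(i) random_dna_str(200),
                                   character(1)), paste0("t", 1:4))
    m <- msa(rows, "r")
    d <- p_distance(m, deletion = "complete")
    # hand count
    for (i in 1:3) for (j in (i + 1):4) {
      a <- strsplit(rows[[i]], "")[[1]]; b <- strsplit(rows[[j]], "")[[1]]
      expect_equal(d[i, j], mean(a != b))
    }
    # independent oracle
    bin <- ape::as.DNAbin(t(sapply(rows, function(s) strsplit(s, "")[[1]])))
    dd <- as.matrix(ape::dist.dna(bin, model = "raw"))
    expect_equal(unname(d), unname(dd[rownames(d), colnames(d)]),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("deletion policies differ exactly on gapped columns", {
  m <- msa(c(a = "ACGTA", b = "AC-TT", c = "ACGTT"), "x")
  dc <- p_distance(m, "complete")    # columns 3 dropped for everyone
  expect_equal(dc["a", "c"], 1 / 4)
  dp <- p_distance(m, "pairwise")
  expect_equal(dp["a", "c"], 1 / 5)
  expect_equal(dp["a", "b"], 1 / 4)
  expect_error(p_distance(msa(c(a = "--", b = "AA"), "x"), "pairwise"),
               "no compared sites")
})

test_that("p-distance is invariant to row and column order", {
  set.seed(82)
  rows <- stats::setNames(vapply(1:5, function(i) random_dna_str(120),
                                 character(1)), paste0("t", 1:5))
  d1 <- p_distance(msa(rows, "r"))
  perm <- sample(5)
  d2 <- p_distance(msa(rows[perm], "r"))
  expect_equal(d1[names(rows), names(rows)], d2[names(rows), names(rows)])
  cols <- sample(120)
  shuffled <- vapply(rows, function(s) {
    paste(strsplit(s, "")[[1]][cols], collapse = "")
  }, character(1))
  d3 <- p_distance(msa(shuffled, "r"))
  expect_equal(d1, d3)
})

test_that("group divergence means equal hand computation", {
  dm <- matrix(c(0, .1, .2, .3,
                 .1, 0, .4, .5,
                 .2, .4, 0, .6,
                 .3, .5, .6, 0), 4, 4,
               dimnames = list(paste0("t", 1:4), paste0("t", 1:4)))
  g <- c(t1 = "A", t2 = "A", t3 = "B", t4 = "B")
  gd <- group_divergence(dm, g)
  expect_equal(unname(gd$within["A"]), .1)
  expect_equal(unname(gd$within["B"]), .6)
  expect_equal(gd$between["A", "B"], mean(c(.2, .3, .4, .5)))
  expect_equal(gd$overall, mean(c(.1, .2, .3, .4, .5, .6)))
  # two singleton groups: between is the single distance, within undefined
  g2 <- c(t1 = "A", t2 = "B", t3 = "C", t4 = "C")
  gd2 <- group_divergence(dm, g2)
  expect_equal(gd2$between["A", "B"], .1)
  expect_true(is.na(gd2$within[["A"]]))
})

test_that("site classification equals the exhaustive column classifier", {
  m <- msa(c(a = "AAAA", b = "AAAA", c = "AAAA", d = "AAAA"), "x")
  s <- site_stats(m)
  expect_equal(s$n_variable, 0L); expect_equal(s$pct_variable, 0)
  expect_equal(s$n_pis, 0L)

  # A/A/T/T is variable and informative; A/A/A/T variable only
  m2 <- msa(c(a = "AA", b = "AA", c = "TA", d = "TT"), "x")
  s2 <- site_stats(m2)
  expect_equal(s2$n_variable, 2L)
  expect_equal(s2$n_pis, 1L)

  set.seed(83)
  for (rep in 1:10) {
    mat <- random_charmatrix(5, 60)
    mat[sample(length(mat), 20)] <- "-"
    rows <- apply(mat, 1, paste, collapse = "")
    s <- site_stats(msa(rows, "r"))
    o <- oracle_site_stats(mat)
    expect_equal(s$n_variable, o$n_variable)
    expect_equal(s$n_pis, o$n_pis)
    expect_true(s$pct_pis <= s$pct_variable + 1e-12)
  }
})

test_that("mutation-event proportion is (NS / L) x 100", {
  m <- msa(c(a = strrep("A", 100), b = strrep("A", 100)), "x")
  expect_equal(mutation_event_proportion(m), 0)
  m2 <- msa(c(a = strrep("A", 100),
              b = paste0(strrep("T", 5), strrep("A", 95))), "x")
  expect_equal(mutation_event_proportion(m2), 5)
  set.seed(84)
  for (rep in 1:10) {
    rows <- stats::setNames(vapply(1:4, function(i) random_dna_str(80),
                                   character(1)), paste0("t", 1:4))
    m <- msa(rows, "r")
    expect_equal(mutation_event_proportion(m), site_stats(m)$pct_variable)
  }
})

test_that("marker ranking filters, sorts and breaks ties alphabetically", {
  rep_df <- data.frame(
    region = c("zeta", "alpha", "mid", "low"),
    aligned_length = c(100L, 100L, 200L, 300L),
    n_variable = c(8L, 8L, 12L, 3L),
    pct_variable = c(8, 8, 6, 1),
    n_pis = c(2L, 3L, 4L, 1L),
    pct_pis = c(2, 3, 2, 1 / 3))
  rk <- rank_markers(rep_df, threshold_pct = 5)
  expect_identical(rk$region, c("alpha", "zeta", "mid"))
  expect_identical(rk$rank, 1:3)
  expect_equal(nrow(rank_markers(rep_df, threshold_pct = 100)), 0L)
})

test_that("PIS-variability regression matches the closed form", {
  rep_df <- data.frame(region = letters[1:5],
                       pct_variable = c(1, 2, 4, 6, 10),
                       pct_pis = c(0.5, 0.9, 2.2, 2.9, 5.4))
  fit <- pis_variability_regression(rep_df)
  x <- rep_df$pct_variable; y <- rep_df$pct_pis
  beta <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  alpha <- mean(y) - beta * mean(x)
  sse <- sum((y - alpha - beta * x)^2)
  sst <- sum((y - mean(y))^2)
  expect_equal(fit$slope, beta)
  expect_equal(fit$r_squared, 1 - sse / sst)

  collin <- data.frame(region = letters[1:4],
                       pct_variable = 1:4, pct_pis = (1:4) / 2)
  expect_equal(suppressWarnings(pis_variability_regression(collin))$r_squared,
               1)
  flat <- data.frame(region = letters[1:4], pct_variable = rep(2, 4),
                     pct_pis = 1:4 / 4)
  expect_error(pis_variability_regression(flat), "zero variance")
})

test_that("mean p-distance rises with the simulated substitution rate", {
  rates <- c(0.002, 0.01, 0.03)
  means <- vapply(rates, function(r) {
    cfg <- sim_config(seed = 85, n_taxa = 5, lsc_len = 6000,
                      irb_len = 1200, ssc_len = 1200, sub_rate = r,
                      indel_rate = 0)
    fam <- simulate_family(cfg)
    d <- p_distance(fam$truth$alignment)
    mean(d[upper.tri(d)])
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})
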