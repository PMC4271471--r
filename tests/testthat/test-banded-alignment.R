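test_that("perfect and near-perfect extensions score as expected", {
  set.seed(501)
  s <- random_dna(20)
  for (mode in c("global", "local")) {
    h <- banded_extend(s, s, 5, 5, 8, mode, half_width = 10)
    expect_equal(h$score, 20L)
    expect_equal(h$identity, 1)
    expect_equal(h$aln_length, 20L)
  }
  # one substitution outside the seed: global keeps it, local trims a
  # terminal mismatch
  q <- s
  substr(q, 20, 20) <- if (substring(s, 20, 20) == "A") "C" else "A"
  hg <- banded_extend(q, s, 5, 5, 8, "global", 10)
  expect_equal(hg$score, 19L - 3L)
  expect_equal(hg$identity, 19 / 20)
  hl <- banded_extend(q, s, 5, 5, 8, "local", 10)
  expect_equal(hl$score, 19L)
  expect_equal(hl$q_end, 19L)
})

test_that("affine gaps cost open plus extend per base", {
  h <- banded_extend("AAAATTTT", "AAAACCCCTTTT", 0, 0, 4, "global",
                     half_width = 8)
  expect_equal(h$score, 8L * 1L + (-5L) + 4L * (-2L))
  expect_equal(h$gap_opens, 1L)
  expect_equal(h$aln_length, 12L)
  expect_equal(h$matches, 8L)
})

test_that("a zero-width band reduces to the gapless diagonal scan", {
  set.seed(502)
  for (it in 1:25) {
    r <- random_dna(60)
    q <- mutate_dna(r, sub = 0.15, indel = 0)  # no indels: same length
    core <- NULL
    for (o in 0:(nchar(q) - 8)) {
      if (substring(q, o + 1, o + 8) == substring(r, o + 1, o + 8)) {
        core <- o; break
      }
    }
    if (is.null(core)) next
    h <- banded_extend(q, r, core, core, 8, "global", half_width = 0)
    # direct diagonal oracle: column scores along the single diagonal,
    # forced to the full query (free reference end is moot at width 0)
    qs <- strsplit(q, "")[[1]]; rs <- strsplit(r, "")[[1]]
    expect_equal(h$score, sum(ifelse(qs == rs, 1, -3)) -
                   sum(ifelse(qs == rs, 1, -3)[core + seq_len(8)]) + 8)
    expect_equal(h$aln_length, nchar(q))
  }
})

test_that("full-width banded scores equal the unbanded DP oracle in both modes", {
  set.seed(503)
  done <- 0
  while (done < 60) {
    pair <- make_seeded_pair(15, 90, k = 6)
    if (is.null(pair)) next
    done <- done + 1
    W <- max(nchar(pair$q), nchar(pair$r))
    for (global in c(TRUE, FALSE)) {
      h <- banded_extend(pair$q, pair$r, pair$qs, pair$rs, pair$k,
                         if (global) "global" else "local", W)
      expect_equal(h$score,
                   oracle_pair_score(pair$q, pair$r, pair$qs, pair$rs,
                                     pair$k, global))
    }
  }
})

test_that("score is monotone in band width and local >= global", {
  set.seed(504)
  done <- 0
  while (done < 20) {
    pair <- make_seeded_pair(20, 80, k = 6)
    if (is.null(pair)) next
    done <- done + 1
    widths <- c(0, 2, 4, 8, 16, 64, 200)
    for (mode in c("global", "local")) {
      sc <- vapply(widths, function(W)
        banded_extend(pair$q, pair$r, pair$qs, pair$rs, pair$k, mode, W)$score,
        numeric(1))
      expect_true(all(diff(sc) >= 0))
    }
    gl <- banded_extend(pair$q, pair$r, pair$qs, pair$rs, pair$k, "global", 64)
    lo <- banded_extend(pair$q, pair$r, pair$qs, pair$rs, pair$k, "local", 64)
    expect_gte(lo$score, gl$score)
    # identity bounds; identity 1 iff clean alignment
    for (h in list(gl, lo)) {
      expect_gte(h$identity, 0); expect_lte(h$identity, 1)
      expect_equal(h$identity == 1,
                   h$mismatches == 0 && h$aln_length == h$matches)
    }
  }
})

test_that("extension is strand-symmetric", {
  set.seed(505)
  done <- 0
  while (done < 15) {
    pair <- make_seeded_pair(20, 60, k = 6)
    if (is.null(pair)) next
    done <- done + 1
    rcq <- reverse_complement(pair$q); rcr <- reverse_complement(pair$r)
    qs2 <- nchar(pair$q) - pair$qs - pair$k
    rs2 <- nchar(pair$r) - pair$rs - pair$k
    for (mode in c("global", "local")) {
      a <- banded_extend(pair$q, pair$r, pair$qs, pair$rs, pair$k, mode, 100)
      b <- banded_extend(rcq, rcr, qs2, rs2, pair$k, mode, 100)
      expect_equal(a$score, b$score)
    }
  }
})

test_that("mismatched seed windows are an internal consistency error", {
  expect_error(banded_extend("AAAATTTT", "CCCCTTTT", 0, 0, 4, "global", 4),
               "seed windows")
})

test_that("E-values follow the Karlin-Altschul form", {
  sc <- scoring_scheme(lambda = 0.625, K = 0.41)
  # S = 0 collapses to K * m * n
  expect_equal(compute_evalue(0, 100, 1000, sc)$evalue, 0.41 * 100 * 1000)
  # linear in database size
  e1 <- compute_evalue(30, 100, 1e6, sc)$evalue
  e2 <- compute_evalue(30, 100, 2e6, sc)$evalue
  expect_equal(e2, 2 * e1)
  # worked value: K m n exp(-lambda S)
  ev <- compute_evalue(40, 100, 1e6, sc)
  expect_equal(ev$evalue, 0.41 * 1e8 * exp(-25), tolerance = 1e-12)
  expect_equal(ev$bitscore, (0.625 * 40 - log(0.41)) / log(2))
  # strictly decreasing in score, increasing in m and n
  expect_true(all(diff(compute_evalue(1:10, 100, 1e6, sc)$evalue) < 0))
  expect_lt(compute_evalue(10, 50, 1e6, sc)$evalue,
            compute_evalue(10, 100, 1e6, sc)$evalue)
  expect_error(compute_evalue(10, 0, 1e6, sc), ">= 1")
})

test_that("hit filtering is inclusive at both thresholds", {
  hits <- data.frame(evalue = c(10, 1e-3, 1e-9, 1e-9),
                     aln_length = c(100L, 100L, 29L, 30L))
  kept <- filter_hits(hits, evalue_threshold = 1e-3, min_aln_length = 30L)
  expect_equal(nrow(kept), 2L)
  expect_true(all(kept$evalue <= 1e-3 & kept$aln_length >= 30))
  expect_equal(nrow(filter_hits(hits, 1e-3, 0L)), 3L)  # length filter off
})
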