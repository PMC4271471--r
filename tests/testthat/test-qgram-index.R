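test_that("k-mer packing encodes 2 bits per base, MSB first", {
  expect_equal(encode_kmer("AAA", 3), 0)
  expect_equal(encode_kmer("ACGT", 4), 27)   # 0*64 + 1*16 + 2*4 + 3
  expect_true(is.na(encode_kmer("ANA", 3)))
  expect_error(encode_kmer(strrep("A", 32), 32), "\\[1, 31\\]")
  expect_error(encode_kmer("ACG", 4), "length")
  # Horner-accumulation oracle on random windows
  set.seed(201)
  for (it in 1:25) {
    k <- sample(1:12, 1)
    win <- random_dna(k)
    code <- match(strsplit(win, "")[[1]], c("A", "C", "G", "T")) - 1
    expect_equal(encode_kmer(win, k), sum(code * 4^((k - 1):0)))
  }
})

test_that("exclusive prefix sum matches its definition", {
  expect_identical(exclusive_prefix_sum(integer(0)), integer(0))
  expect_identical(exclusive_prefix_sum(c(2, 1, 3)), c(0L, 2L, 3L))
  expect_identical(exclusive_prefix_sum(5), 0L)
  expect_error(exclusive_prefix_sum(c(1, -1)), ">= 0")
})

test_that("index construction sorts stably, deduplicates and masks", {
  vals <- data.frame(sequence_ordinal = c(10L, 20L, 30L, 40L),
                     offset = c(1L, 2L, 3L, 4L))
  ix <- build_index(c(3, 1, 3, 2), vals, repeat_threshold = 10)
  expect_equal(ix$sorted_keys, c(1, 2, 3, 3))
  expect_equal(ix$sorted_values$sequence_ordinal, c(20L, 40L, 10L, 30L))
  expect_equal(ix$nonredundant_keys, c(1, 2, 3))
  expect_equal(ix$cell_size, c(1L, 1L, 2L))
  expect_equal(ix$gateway, c(0L, 1L, 2L))

  # masking zeroes cell_size but never gateway
  ix1 <- build_index(c(3, 1, 3, 2), vals, repeat_threshold = 1)
  expect_equal(ix1$cell_size, c(1L, 1L, 0L))
  expect_equal(ix1$gateway, ix$gateway)

  empty <- build_index(numeric(0),
                       data.frame(sequence_ordinal = integer(0),
                                  offset = integer(0)))
  expect_length(empty$sorted_keys, 0)
  expect_length(empty$nonredundant_keys, 0)

  expect_error(build_index(c(1, 2), vals), "equal length")
  expect_error(build_index(c(1, NA), vals[1:2, ]), "ambiguous")
})

test_that("single-key lookup returns gateway/cell_size slices", {
  vals <- data.frame(sequence_ordinal = c(10L, 20L, 30L, 40L),
                     offset = c(1L, 2L, 3L, 4L))
  ix <- build_index(c(3, 1, 3, 2), vals, repeat_threshold = 10)
  lk <- index_lookup(ix, 3)
  expect_equal(lk$gateway, 2L)
  expect_equal(lk$cell_size, 2L)
  expect_equal(lk$values$sequence_ordinal, c(10L, 30L))
  expect_equal(index_lookup(ix, 7)$cell_size, 0L)
  # masked key yields no values
  ix1 <- build_index(c(3, 1, 3, 2), vals, repeat_threshold = 1)
  lk1 <- index_lookup(ix1, 3)
  expect_equal(lk1$gateway, 2L)
  expect_equal(lk1$cell_size, 0L)
  expect_equal(nrow(lk1$values), 0L)
})

test_that("batched lookup places results by prefix-sum write index", {
  vals <- data.frame(sequence_ordinal = c(10L, 20L, 30L, 40L),
                     offset = c(1L, 2L, 3L, 4L))
  ix <- build_index(c(3, 1, 3, 2), vals, repeat_threshold = 10)
  bl <- batch_lookup(ix, c(3, 1), c(100, 200))
  expect_equal(bl$query_value, c(100, 100, 200))
  expect_equal(bl$sequence_ordinal, c(10L, 30L, 20L))
  expect_equal(nrow(batch_lookup(ix, c(7, 9), c(1, 2))), 0L)
  # duplicate query keys each get their own block
  bl2 <- batch_lookup(ix, c(3, 3), c(1, 2))
  expect_equal(nrow(bl2), 4L)
  expect_equal(bl2$query_value, c(1, 1, 2, 2))
  expect_error(batch_lookup(ix, c(1, 2), 1), "equal length")
})

test_that("lookups agree with a hash-map oracle under masking", {
  set.seed(202)
  for (thr in c(1, 2, 5, Inf)) {
    n <- 2000
    keys <- sample(0:50, n, replace = TRUE)  # small alphabet forces collisions
    vals <- data.frame(sequence_ordinal = sample(1:5, n, TRUE),
                       offset = sample(0:1000, n, TRUE))
    ix <- build_index(keys, vals, repeat_threshold = thr)
    oracle <- oracle_hash_lookup(keys, vals$sequence_ordinal, vals$offset, thr)
    qk <- c(sample(0:50, 100, TRUE), sample(51:60, 20, TRUE))  # present+absent
    for (key in qk) {
      got <- index_lookup(ix, key)$values
      want <- oracle(key)
      expect_equal(nrow(got), nrow(want))
      # same multiset of positions
      expect_equal(sort(paste(got$sequence_ordinal, got$offset)),
                   sort(paste(want$sequence_ordinal, want$offset)))
    }
    bl <- batch_lookup(ix, qk, seq_along(qk))
    want_n <- vapply(qk, function(k) nrow(oracle(k)), integer(1))
    expect_equal(as.integer(table(factor(bl$query_value, levels = seq_along(qk)))),
                 want_n)
  }
})

test_that("gateway reconstructs from pre-mask counts; index size depends only on distinct keys", {
  set.seed(203)
  keys <- sample(0:30, 500, TRUE)
  vals <- data.frame(sequence_ordinal = rep(1L, 500), offset = 1:500)
  ix <- build_index(keys, vals, repeat_threshold = 3)
  premask <- diff(c(ix$gateway, length(ix$sorted_keys)))
  expect_equal(exclusive_prefix_sum(premask), ix$gateway)
  expect_equal(sum(premask), nrow(ix$sorted_values))
  # shifting keys by a huge constant changes nothing structural
  ix2 <- build_index(keys + 2^40, vals, repeat_threshold = 3)
  expect_equal(length(ix2$nonredundant_keys), length(ix$nonredundant_keys))
  expect_equal(ix2$cell_size, ix$cell_size)
  expect_equal(ix2$gateway, ix$gateway)
})
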