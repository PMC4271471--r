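test_that("community generation is reproducible and respects its parameters", {
  a <- generate_community(n_genera = 2, genomes_per_genus = 2,
                          genome_length = 2000, n_reads = 50,
                          read_length = 100, rng_seed = 7)
  b <- generate_community(n_genera = 2, genomes_per_genus = 2,
                          genome_length = 2000, n_reads = 50,
                          read_length = 100, rng_seed = 7)
  expect_identical(a$genomes, b$genomes)
  expect_identical(a$reads, b$reads)
  expect_equal(nrow(a$genomes), 4L)
  expect_equal(nrow(a$reads), 50L)
  expect_error(generate_community(genome_length = 50, read_length = 100),
               "genome_length")
  expect_error(generate_community(intra_rate = 0.7), "rates")
})

test_that("error-free reads are exact (strand-aware) substrings of their genome", {
  com <- generate_community(n_genera = 2, genomes_per_genus = 2,
                            genome_length = 3000, n_reads = 100,
                            read_length = 80, error_rate = 0, rng_seed = 8)
  g <- stats::setNames(com$genomes$residues, com$genomes$id)
  for (i in seq_len(nrow(com$reads))) {
    r <- com$reads[i, ]
    truth <- substring(g[r$true_genome_id], r$true_offset + 1,
                       r$true_offset + 80)
    if (r$true_strand == "reverse") truth <- reverse_complement(truth)
    expect_identical(r$residues, unname(truth))
  }
})

test_that("within-genus divergence matches the closed-form expectation", {
  com <- generate_community(n_genera = 1, genomes_per_genus = 2,
                            genome_length = 10000, n_reads = 1,
                            read_length = 100, intra_rate = 0.05, rng_seed = 9)
  a <- strsplit(com$genomes$residues[1], "")[[1]]
  b <- strsplit(com$genomes$residues[2], "")[[1]]
  d <- sum(a != b)
  # two independent substitution draws at rate r differ at a site with
  # probability 2 r (1 - r) + r^2 * 2/3 (both mutated, to different bases)
  r <- 0.05
  pdiff <- 2 * r * (1 - r) + r^2 * 2 / 3
  expect_lt(abs(d - 10000 * pdiff), 3 * sqrt(10000 * pdiff * (1 - pdiff)))
})

test_that("assignment scoring counts hits and correct genera", {
  com <- generate_community(n_genera = 2, genomes_per_genus = 2,
                            genome_length = 1000, n_reads = 4,
                            read_length = 50, rng_seed = 10)
  # construct a best-hit table by hand: 4 reported, 3 in the right genus
  right <- vapply(com$reads$true_genus[1:3], function(g) {
    setdiff(com$genomes$id[com$genomes$genus == g], NA)[1]
  }, character(1))
  wrong_genus <- setdiff(com$genomes$genus, com$reads$true_genus[4])[1]
  wrong <- com$genomes$id[com$genomes$genus == wrong_genus][1]
  best <- data.frame(query_id = com$reads$id,
                     ref_parent_id = c(right, wrong),
                     stringsAsFactors = FALSE)
  ev <- evaluate_assignment(best, com)
  expect_equal(ev$total_reported_hits, 4L)
  expect_equal(ev$correct_genus_assignments, 3L)
  expect_equal(ev$cga_ratio, 0.75)
  empty <- evaluate_assignment(best[0, ], com)
  expect_equal(empty$total_reported_hits, 0L)
  expect_equal(empty$cga_ratio, 0)
})

test_that("the identity/coverage sweep is monotone and validates thresholds", {
  com <- generate_community(n_genera = 3, genomes_per_genus = 2,
                            genome_length = 8000, n_reads = 120,
                            read_length = 100, intra_rate = 0.04,
                            rng_seed = 11)
  hits <- run_search(community_records(com, "reads"),
                     community_records(com, "genomes"), search_config())
  sw <- threshold_sweep(hits, com)
  expect_equal(nrow(sw), 5L)  # unfiltered + 4 thresholds
  filtered <- sw[-1, ][order(sw$identity_threshold[-1]), ]
  expect_true(all(diff(filtered$total_reported_hits) <= 0))
  expect_true(all(diff(filtered$correct_genus_assignments) <= 0))
  expect_true(all(sw$total_reported_hits[-1] <= sw$total_reported_hits[1]))
  # coverage 0 degenerates to identity-only filtering
  sw0 <- threshold_sweep(hits, com, identity_thresholds = 0,
                         coverage_threshold = 0)
  expect_equal(sw0$total_reported_hits[2], sw0$total_reported_hits[1])
  expect_error(threshold_sweep(hits, com, identity_thresholds = c(95, 90)),
               "fractions")
})

test_that("with self-exclusion off, every error-free read recovers itself exactly", {
  com <- generate_community(n_genera = 2, genomes_per_genus = 2,
                            genome_length = 5000, n_reads = 60,
                            read_length = 100, error_rate = 0, rng_seed = 12)
  hits <- run_search(community_records(com, "reads"),
                     community_records(com, "genomes"), search_config())
  best <- select_best_nonself_hits(hits)  # no origin: self allowed
  m <- match(com$reads$id, best$query_id)
  expect_false(anyNA(m))
  expect_true(all(best$identity[m] == 1))
  expect_equal(best$ref_parent_id[m], com$reads$true_genome_id)
  expect_equal(best$r_start[m], com$reads$true_offset)
})
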