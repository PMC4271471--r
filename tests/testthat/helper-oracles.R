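# Independent oracles used across the suite. These deliberately share no
# code with the package: plain R, brute-force or closed-form throughout.

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")

revstr <- function(s) paste(rev(strsplit(s, "")[[1]]), collapse = "")

# substitution + indel mutator for alignment test pairs
mutate_dna <- function(s, sub = 0.1, indel = 0.05) {
  bases <- c("A", "C", "G", "T")
  out <- character(0)
  for (c in strsplit(s, "")[[1]]) {
    u <- runif(1)
    if (u < indel / 2) next
    if (u < indel) out <- c(out, c, sample(bases, 1))
    else if (runif(1) < sub) out <- c(out, sample(setdiff(bases, c), 1))
    else out <- c(out, c)
  }
  paste(out, collapse = "")
}

# Unbanded affine-gap extension DP anchored at the origin, vectorized per
# row (the horizontal-gap state is folded in exactly via a running-maximum
# transform; chained gap-opens are dominated by one longer gap, so opening
# from gap-derived cells never helps when gap_open <= 0).
oracle_extend <- function(a, b, global, ma = 1, mi = -3, go = -5, ge = -2) {
  M <- nchar(a); N <- nchar(b)
  if (M == 0) return(0)
  NEG <- -1e9
  av <- strsplit(a, "")[[1]]
  bv <- if (N) strsplit(b, "")[[1]] else character(0)
  Hprev <- c(0, if (N > 0) go + ge * seq_len(N) else numeric(0))
  Vprev <- rep(NEG, N + 1)
  best <- 0
  for (i in seq_len(M)) {
    V <- pmax(Hprev + go + ge, Vprev + ge)
    H0 <- c(V[1], if (N > 0)
      pmax(Hprev[1:N] + ifelse(bv == av[i], ma, mi), V[-1]) else numeric(0))
    if (N > 0) {
      t <- H0 - ge * (0:N)
      H <- pmax(H0, c(NEG, go + ge * (1:N) + cummax(t[1:N])))
    } else H <- H0
    best <- max(best, max(H))
    Hprev <- H; Vprev <- V
  }
  if (global) max(Hprev) else max(0, best)
}

# total seed-anchored score: left + seed + right extensions
oracle_pair_score <- function(q, r, qs, rs, k, global,
                              ma = 1, mi = -3, go = -5, ge = -2) {
  right <- oracle_extend(substring(q, qs + k + 1), substring(r, rs + k + 1),
                         global, ma, mi, go, ge)
  left <- oracle_extend(revstr(substring(q, 1, qs)),
                        revstr(substring(r, 1, rs)), global, ma, mi, go, ge)
  k * ma + right + left
}

# plant an exact k-mer seed shared by a mutated pair; returns NULL when the
# core is not found intact on both sides
make_seeded_pair <- function(len_lo = 30, len_hi = 200, k = 8,
                             sub = 0.1, indel = 0.05) {
  core <- random_dna(k)
  nl <- sample(len_lo:len_hi, 1); nr <- sample(len_lo:len_hi, 1)
  left <- random_dna(sample(0:nl, 1)); right <- random_dna(sample(0:nr, 1))
  r <- paste0(left, core, right)
  q <- paste0(mutate_dna(left, sub, indel), core, mutate_dna(right, sub, indel))
  qs <- regexpr(core, q, fixed = TRUE)[1] - 1
  rs <- regexpr(core, r, fixed = TRUE)[1] - 1
  if (qs < 0 || rs < 0) return(NULL)
  list(q = q, r = r, qs = qs, rs = rs, k = k)
}

# hash-map (environment) q-gram lookup oracle with repeat masking
oracle_hash_lookup <- function(keys, seq_ord, off, repeat_threshold) {
  env <- new.env(hash = TRUE, parent = emptyenv())
  for (i in seq_along(keys)) {
    kk <- as.character(keys[i])
    env[[kk]] <- c(get0(kk, envir = env, ifnotfound = integer(0)), i)
  }
  function(key) {
    rows <- get0(as.character(key), envir = env, ifnotfound = integer(0))
    if (length(rows) > repeat_threshold) rows <- integer(0)
    data.frame(sequence_ordinal = seq_ord[rows], offset = off[rows])
  }
}

# brute-force exact k-mer correspondences between a query strand and an
# unsplit reference, restricted to reference offsets on the p-grid
brute_force_seeds <- function(qseq, rseq, k, p = 1) {
  qn <- nchar(qseq); rn <- nchar(rseq)
  out <- list()
  for (ro in seq(0, rn - k, by = p)) {
    win <- substring(rseq, ro + 1, ro + k)
    if (grepl("[^ACGT]", win)) next
    qo <- -1
    repeat {
      hit <- regexpr(win, substring(qseq, qo + 2), fixed = TRUE)[1]
      if (hit < 0) break
      qo <- qo + 1 + hit - 1
      out[[length(out) + 1]] <- c(qo, ro)
    }
  }
  if (!length(out)) return(data.frame(query_offset = integer(0),
                                      ref_offset = integer(0)))
  m <- do.call(rbind, out)
  df <- data.frame(query_offset = m[, 1], ref_offset = m[, 2])
  df[order(df$query_offset, df$ref_offset), ]
}

# direct R transcription of the two-pass surrounding-area filter
oracle_reduce <- function(sd, z, w) {
  n <- nrow(sd)
  if (n == 0) return(sd)
  in_area <- function(i, j) {
    sd$query_ordinal[i] == sd$query_ordinal[j] &&
      sd$ref_ordinal[i] == sd$ref_ordinal[j] &&
      sd$strand[i] == sd$strand[j] &&
      abs(sd$diagonal[j] - sd$diagonal[i]) <= z &&
      (sd$ref_offset[j] - sd$ref_offset[i]) > 0 &&
      (sd$ref_offset[j] - sd$ref_offset[i]) <= w
  }
  surv <- Filter(function(i) i < n && in_area(i, i + 1), seq_len(n))
  keep <- Filter(function(s) {
    pos <- match(s, surv)
    !(pos < length(surv) && in_area(s, surv[pos + 1]))
  }, surv)
  sd[unlist(keep), , drop = FALSE]
}

# uniform-random seed configuration over a mixed-density box
random_seed_config <- function(nmax = 100) {
  n <- sample(2:nmax, 1)
  sd <- data.frame(query_ordinal = sample(1:2, n, TRUE),
                   query_offset = sample(0:150, n, TRUE),
                   ref_ordinal = sample(1:2, n, TRUE),
                   ref_offset = sample(0:400, n, TRUE),
                   strand = sample(c("forward", "reverse"), n, TRUE),
                   stringsAsFactors = FALSE)
  sd$diagonal <- sd$ref_offset - sd$query_offset
  sort_seeds(sd)
}

# successor-chain decomposition of a sorted seed list: maximal runs of
# consecutive in-area links
successor_chains <- function(sd, area) {
  n <- nrow(sd)
  memb <- rep(0L, n)
  if (n < 2) return(memb)
  link <- vapply(seq_len(n - 1), function(i)
    isTRUE(in_surrounding_area(sd[i, ], sd[i + 1, ], area)), logical(1))
  cid <- 0L; i <- 1L
  while (i <= n) {
    j <- i
    while (j < n && link[j]) j <- j + 1L
    if (j > i) { cid <- cid + 1L; memb[i:j] <- cid }
    i <- j + 1L
  }
  memb
}
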