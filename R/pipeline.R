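# Orchestration: batched index-build / seed / reduce / extend / filter over
# query and reference chunks, best non-self hit selection, tabular output.

#' Search configuration
#'
#' All user-adjustable parameters of the search pipeline. `k` and `p`
#' control seeding density (larger k / larger p: faster, less sensitive),
#' `z` and `w` the surrounding-area seed filter, `L` and `overlap` the
#' long-reference splitter, and `repeat_threshold` the masking of
#' over-represented k-mers. References are indexed fresh per batch of at
#' most `reference_batch_residues` residues; queries stream through in
#' chunks of `query_batch_count`.
#'
#' @param k word size, in `[1, 31]`.
#' @param p reference k-mer sampling step, `>= 1`.
#' @param z,w surrounding-area parameters (see [surrounding_area()]).
#' @param L maximum reference fragment length (default 64 Mb).
#' @param overlap fragment overlap; `NA` (default) means
#'   `max(2000, 2 * longest query)`, so no single-read alignment can span
#'   more than one fragment boundary.
#' @param repeat_threshold k-mers occurring more often than this in a
#'   reference batch are masked (default 1000).
#' @param evalue_threshold,min_aln_length hit filters (inclusive bounds).
#' @param mode `"global"` (glocal: full query, free reference ends; the
#'   default, suited to taxonomic assignment) or `"local"`.
#' @param strand_policy `"both"` or `"forward_only"`.
#' @param half_width extension band half-width; `NA` (default) couples it
#'   to the seed filter as `z + k`.
#' @param scoring a [scoring_scheme()].
#' @param reference_batch_residues,query_batch_count batch sizes.
#' @export
search_config <- function(k = 16L, p = 4L, z = 16L, w = 64L,
                          L = 64000000L, overlap = NA_integer_,
                          repeat_threshold = 1000,
                          evalue_threshold = 1e-3, min_aln_length = 30L,
                          mode = c("global", "local"),
                          strand_policy = c("both", "forward_only"),
                          half_width = NA_integer_,
                          scoring = scoring_scheme(),
                          reference_batch_residues = 64000000,
                          query_batch_count = 100000L) {
  mode <- match.arg(mode)
  strand_policy <- match.arg(strand_policy)
  k <- as.integer(k)
  if (is.na(k) || k < 1L || k > 31L) stop("k must be in [1, 31]", call. = FALSE)
  if (p < 1L) stop("p must be >= 1", call. = FALSE)
  if (z < 0L) stop("z must be >= 0", call. = FALSE)
  if (w < 1L) stop("w must be >= 1", call. = FALSE)
  if (L < 1L) stop("L must be >= 1", call. = FALSE)
  if (!is.na(overlap) && L <= overlap)
    stop("L must be greater than overlap", call. = FALSE)
  if (!(repeat_threshold >= 1)) stop("repeat_threshold must be >= 1", call. = FALSE)
  if (min_aln_length < 0L) stop("min_aln_length must be >= 0", call. = FALSE)
  if (is.na(half_width)) half_width <- as.integer(z + k)
  structure(list(k = k, p = as.integer(p), z = as.integer(z), w = as.integer(w),
                 L = as.integer(L), overlap = as.integer(overlap),
                 repeat_threshold = repeat_threshold,
                 evalue_threshold = evalue_threshold,
                 min_aln_length = as.integer(min_aln_length),
                 mode = mode, strand_policy = strand_policy,
                 half_width = as.integer(half_width), scoring = scoring,
                 reference_batch_residues = reference_batch_residues,
                 query_batch_count = as.integer(query_batch_count)),
            class = "search_config")
}

.empty_hits <- function() {
  data.frame(query_id = character(0), ref_parent_id = character(0),
             strand = character(0), q_start = integer(0), q_end = integer(0),
             r_start = integer(0), r_end = integer(0), score = integer(0),
             identity = numeric(0), aln_length = integer(0),
             matches = integer(0), mismatches = integer(0),
             gap_opens = integer(0), evalue = numeric(0),
             bitscore = numeric(0), query_length = integer(0),
             stringsAsFactors = FALSE)
}

#' Run the full seed-and-extend search
#'
#' References are split into overlapping fragments, grouped into batches,
#' and indexed fresh per batch (no preprocessed database); each query batch
#' is then seeded, reduced, extended and filtered against each reference
#' batch. Fragment coordinates are lifted back to parent coordinates,
#' duplicate hits arising inside fragment overlaps are collapsed, and hits
#' whose reference interval abuts an internal fragment boundary are dropped
#' (the overlap guarantees the untruncated hit is recovered from the
#' neighbouring fragment). The final hit set is independent of the batching
#' and, for hits shorter than the overlap, of the splitting.
#'
#' @param queries,references sequence-record data frames
#'   (see [read_fasta()]).
#' @param config a [search_config()].
#' @return hit data frame (one row per reported alignment) with 0-based
#'   half-open coordinates: `query_id`, `ref_parent_id`, `strand`,
#'   `q_start`, `q_end` (forward-query coordinates), `r_start`, `r_end`
#'   (parent-reference coordinates), `score`, `identity`, `aln_length`,
#'   `matches`, `mismatches`, `gap_opens`, `evalue`, `bitscore`,
#'   `query_length`. Rows are ordered by query input order, then
#'   descending score.
#' @export
run_search <- function(queries, references, config = search_config()) {
  if (nrow(queries) == 0L || nrow(references) == 0L) return(.empty_hits())
  .check_unique_ids(queries$id, "query")
  .check_unique_ids(references$id, "reference")
  qlen_all <- nchar(queries$residues)
  overlap <- config$overlap
  if (is.na(overlap)) overlap <- max(2000L, 2L * max(qlen_all))
  if (config$L <= overlap)
    stop("L must be greater than the fragment overlap (", overlap, ")",
         call. = FALSE)
  db_len <- sum(as.numeric(nchar(references$residues)))

  fragments <- split_reference(references, config$L, overlap)
  frag_len <- nchar(fragments$residues)
  # greedy grouping of fragments into batches of bounded residue count
  batch <- integer(nrow(fragments))
  b <- 1L; acc <- 0
  for (i in seq_len(nrow(fragments))) {
    if (acc > 0 && acc + frag_len[i] > config$reference_batch_residues) {
      b <- b + 1L; acc <- 0
    }
    batch[i] <- b
    acc <- acc + frag_len[i]
  }
  qbatches <- split(seq_len(nrow(queries)),
                    ceiling(seq_len(nrow(queries)) / config$query_batch_count))

  rows <- list()
  for (rb in unique(batch)) {
    sel <- which(batch == rb)
    fsub <- fragments[sel, , drop = FALSE]
    idx <- build_reference_index(fsub, config$k, config$p,
                                 config$repeat_threshold)
    for (qb in qbatches) {
      raw <- cpp_search_batch(
        queries$residues[qb], fsub$residues,
        idx$nonredundant_keys, idx$cell_size, idx$gateway,
        idx$sorted_values$sequence_ordinal, idx$sorted_values$offset,
        config$k, config$z, config$w, config$mode == "global",
        config$half_width, config$scoring$match, config$scoring$mismatch,
        config$scoring$gap_open, config$scoring$gap_extend,
        config$strand_policy == "both")
      if (nrow(raw) == 0L) next
      qg <- qb[raw$query]                 # global query row
      fg <- sel[raw$frag]                 # global fragment row
      qlen <- qlen_all[qg]
      rev <- raw$strand == 1L
      flen <- frag_len[fg]
      fi <- fragments$fragment_index[fg]
      nfr <- fragments$n_fragments[fg]
      edge <- (fi > 0L & raw$r_start == 0L) |
              (fi < nfr - 1L & raw$r_end == flen)
      df <- data.frame(
        query_id = queries$id[qg],
        ref_parent_id = fragments$parent_id[fg],
        strand = ifelse(rev, "reverse", "forward"),
        q_start = ifelse(rev, qlen - raw$q_end, raw$q_start),
        q_end = ifelse(rev, qlen - raw$q_start, raw$q_end),
        r_start = raw$r_start + fragments$parent_offset[fg],
        r_end = raw$r_end + fragments$parent_offset[fg],
        score = raw$score, matches = raw$matches,
        mismatches = raw$mismatches, gap_opens = raw$gap_opens,
        aln_length = raw$aln_len, query_length = qlen,
        stringsAsFactors = FALSE)
      df <- df[!edge, , drop = FALSE]
      if (nrow(df)) rows[[length(rows) + 1L]] <- df
    }
  }
  if (length(rows) == 0L) return(.empty_hits())
  hits <- do.call(rbind, rows)
  key <- paste(hits$query_id, hits$ref_parent_id, hits$strand,
               hits$q_start, hits$q_end, hits$r_start, hits$r_end)
  hits <- hits[!duplicated(key), , drop = FALSE]
  hits$identity <- hits$matches / hits$aln_length
  ev <- compute_evalue(hits$score, hits$query_length, db_len, config$scoring)
  hits$evalue <- ev$evalue
  hits$bitscore <- ev$bitscore
  hits <- filter_hits(hits, config$evalue_threshold, config$min_aln_length)
  if (nrow(hits) == 0L) return(.empty_hits())
  ord <- order(match(hits$query_id, queries$id), -hits$score,
               hits$ref_parent_id, hits$r_start, method = "radix")
  hits <- hits[ord, c("query_id", "ref_parent_id", "strand", "q_start",
                      "q_end", "r_start", "r_end", "score", "identity",
                      "aln_length", "matches", "mismatches", "gap_opens",
                      "evalue", "bitscore", "query_length")]
  rownames(hits) <- NULL
  hits
}

#' Select the best non-self hit per query
#'
#' Hits whose reference equals the query's own source sequence (per the
#' `origin` map) are discarded; the remaining best hit per query is chosen
#' by highest score, then lowest E-value, then lexicographically smallest
#' reference id, then smallest reference start (the last two are
#' deterministic tie-breaks). Queries absent from `origin` have no self hit
#' to exclude.
#'
#' @param hits hit data frame from [run_search()].
#' @param origin named character vector mapping `query_id` to its source
#'   reference id, or `NULL` for no self-exclusion.
#' @return one row per query that retains a hit.
#' @export
select_best_nonself_hits <- function(hits, origin = NULL) {
  if (nrow(hits) == 0L) return(hits)
  if (!is.null(origin)) {
    self <- !is.na(origin[hits$query_id]) &
      hits$ref_parent_id == origin[hits$query_id]
    hits <- hits[!self, , drop = FALSE]
  }
  if (nrow(hits) == 0L) { rownames(hits) <- NULL; return(hits) }
  ord <- order(hits$query_id, -hits$score, hits$evalue, hits$ref_parent_id,
               hits$r_start, method = "radix")
  hits <- hits[ord, , drop = FALSE]
  hits <- hits[!duplicated(hits$query_id), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Write hits in 12-column BLAST tabular format
#'
#' Columns: query id, subject id, percent identity (2 decimals), alignment
#' length, mismatches, gap opens, query start, query end, subject start,
#' subject end, E-value, bit score. Coordinates are 1-based inclusive;
#' reverse-strand hits carry subject start > subject end.
#'
#' @param hits hit data frame from [run_search()].
#' @param path output path or connection.
#' @export
write_tabular <- function(hits, path) {
  rev <- hits$strand == "reverse"
  out <- data.frame(
    qseqid = hits$query_id, sseqid = hits$ref_parent_id,
    pident = sprintf("%.2f", 100 * hits$identity),
    length = hits$aln_length, mismatch = hits$mismatches,
    gapopen = hits$gap_opens,
    qstart = hits$q_start + 1L, qend = hits$q_end,
    sstart = ifelse(rev, hits$r_end, hits$r_start + 1L),
    send = ifelse(rev, hits$r_start + 1L, hits$r_end),
    evalue = sprintf("%.2g", hits$evalue),
    bitscore = sprintf("%.1f", hits$bitscore),
    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read 12-column BLAST tabular hits
#'
#' Inverse of [write_tabular()] up to formatting precision: coordinates
#' return to 0-based half-open, the strand is recovered from the subject
#' coordinate order, identity becomes a fraction, and (since the raw DP
#' score is not part of the format) the bit score doubles as the score for
#' best-hit selection.
#'
#' @param path tabular file path.
#' @param query_lengths optional named vector of query lengths (needed for
#'   coverage-based filtering when the queries are not re-read).
#' @export
read_tabular <- function(path, query_lengths = NULL) {
  cols <- c("query_id", "ref_parent_id", "pident", "aln_length", "mismatches",
            "gap_opens", "qstart", "qend", "sstart", "send", "evalue",
            "bitscore")
  tab <- read.delim(path, header = FALSE, col.names = cols,
                    stringsAsFactors = FALSE)
  rev <- tab$sstart > tab$send
  out <- data.frame(
    query_id = as.character(tab$query_id),
    ref_parent_id = as.character(tab$ref_parent_id),
    strand = ifelse(rev, "reverse", "forward"),
    q_start = tab$qstart - 1L, q_end = tab$qend,
    r_start = ifelse(rev, tab$send, tab$sstart) - 1L,
    r_end = ifelse(rev, tab$sstart, tab$send),
    score = tab$bitscore, identity = tab$pident / 100,
    aln_length = tab$aln_length, mismatches = tab$mismatches,
    gap_opens = tab$gap_opens, evalue = tab$evalue,
    bitscore = tab$bitscore, stringsAsFactors = FALSE)
  if (!is.null(query_lengths))
    out$query_length <- as.integer(query_lengths[out$query_id])
  out
}
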