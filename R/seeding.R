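# Seed generation: k-mer extraction from references (sampling step p) and
# queries (step 1), index lookup, and materialization of exact-match seeds
# on one or both strands.

#' Extract reference k-mers for indexing
#'
#' Slides a window of `k` bases with a step of `p` bases along each
#' reference fragment. Windows containing non-ACGT letters are omitted.
#' The step grid is phased to parent coordinates (for a fragment at
#' `parent_offset` 0 — in particular any unsplit reference — windows start
#' at offsets `0, p, 2p, ...`), so splitting a reference never changes
#' which k-mers are sampled.
#'
#' @param fragments fragment data frame from [split_reference()].
#' @param k word size in `[1, 31]`.
#' @param p sampling step, `>= 1`.
#' @return list with `keys` (numeric) and `values` (position-record data
#'   frame: `sequence_ordinal`, `offset`).
#' @export
extract_reference_kmers <- function(fragments, k, p) {
  ko <- lapply(seq_len(nrow(fragments)), function(i) {
    phase <- (p - fragments$parent_offset[i] %% p) %% p
    cpp_extract_kmers(fragments$residues[i], as.integer(k), as.integer(p),
                      as.integer(phase))
  })
  n <- vapply(ko, function(x) length(x$offsets), integer(1))
  list(keys = unlist(lapply(ko, `[[`, "keys")),
       values = data.frame(sequence_ordinal = rep(seq_along(ko), n),
                           offset = unlist(lapply(ko, `[[`, "offsets"))))
}

#' Extract query k-mers
#'
#' As [extract_reference_kmers()] with the step fixed at 1 base. A query
#' shorter than `k` yields an empty result (not an error).
#'
#' @param residues a nucleotide string.
#' @param k word size in `[1, 31]`.
#' @return list with `keys` (numeric) and `offsets` (0-based starts).
#' @export
extract_query_kmers <- function(residues, k) {
  out <- cpp_extract_kmers(residues, as.integer(k), 1L, 0L)
  list(keys = out$keys, offsets = out$offsets)
}

#' Build a q-gram index from reference fragments
#'
#' Convenience wrapper: extracts reference k-mers and builds the read-only
#' index with the fragments attached, ready for [find_seeds()].
#'
#' @inheritParams extract_reference_kmers
#' @inheritParams build_index
#' @export
build_reference_index <- function(fragments, k, p, repeat_threshold = 1000) {
  kv <- extract_reference_kmers(fragments, k, p)
  build_index(kv$keys, kv$values, k = k, p = p,
              repeat_threshold = repeat_threshold, fragments = fragments)
}

#' Find exact k-mer seeds for queries against an indexed reference
#'
#' Slides a window of `k` bases (step 1) across each query, looks the
#' windows up in the index, and materializes one seed per exact k-mer
#' correspondence. Under `strand_policy = "both"` the reverse strand is
#' searched by reverse-complementing the query; reverse-strand seed offsets
#' are expressed on the reverse-complemented sequence. Masked (repeat)
#' k-mers yield no seeds. Every emitted seed's windows are verified to
#' match exactly.
#'
#' @param index a `qgram_index` with fragments attached
#'   (see [build_reference_index()]).
#' @param queries sequence-record data frame.
#' @param strand_policy `"both"` or `"forward_only"`.
#' @return seed data frame with columns `query_ordinal`, `query_offset`,
#'   `ref_ordinal`, `ref_offset`, `strand` (`"forward"`/`"reverse"`), and
#'   `diagonal` (`ref_offset - query_offset`).
#' @export
find_seeds <- function(index, queries, strand_policy = c("both", "forward_only")) {
  strand_policy <- match.arg(strand_policy)
  if (is.null(index$fragments))
    stop("index has no fragments attached; use build_reference_index()",
         call. = FALSE)
  if (is.na(index$k)) stop("index does not record k", call. = FALSE)
  frag_seqs <- index$fragments$residues
  strands <- if (strand_policy == "both") c("forward", "reverse") else "forward"
  out <- list()
  for (qi in seq_len(nrow(queries))) {
    for (strand in strands) {
      s <- if (strand == "forward") queries$residues[qi]
           else reverse_complement(queries$residues[qi])
      df <- cpp_seed_query(s, index$k, index$nonredundant_keys,
                           index$cell_size, index$gateway,
                           index$sorted_values$sequence_ordinal,
                           index$sorted_values$offset, frag_seqs)
      if (nrow(df) == 0L) next
      df$query_ordinal <- qi
      df$strand <- strand
      out[[length(out) + 1L]] <- df
    }
  }
  if (length(out) == 0L)
    return(data.frame(query_ordinal = integer(0), query_offset = integer(0),
                      ref_ordinal = integer(0), ref_offset = integer(0),
                      strand = character(0), diagonal = integer(0),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res$diagonal <- res$ref_offset - res$query_offset
  res[, c("query_ordinal", "query_offset", "ref_ordinal", "ref_offset",
          "strand", "diagonal")]
}
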