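# The read-only q-gram index: sorted data array (keys co-sorted with
# position values), deduplicated key array, per-key redundancy counts
# (cellSize) and their exclusive prefix sum (gateway). Keys are 2-bit packed
# k-mers (A=0, C=1, G=2, T=3, most significant base first) held in unsigned
# 64-bit integers in the C++ core and surfaced to R as doubles.

#' Encode a k-mer as a packed integer key
#'
#' Packs a k-length window 2 bits per base, most significant base first.
#' Windows containing any non-ACGT letter are ambiguous and encode as `NA`
#' (such windows are dropped at extraction time; the 2-bit code has no code
#' point for them). Keys fit a 64-bit integer for all `k <= 31`.
#'
#' @param window nucleotide string of length `k`.
#' @param k word size, in `[1, 31]`.
#' @return numeric key in `[0, 4^k)`, or `NA` if the window is ambiguous.
#' @examples
#' encode_kmer("ACGT", 4)  # 27
#' @export
encode_kmer <- function(window, k = nchar(window)) {
  cpp_encode_kmer(toupper(window), as.integer(k))
}

#' Exclusive prefix sum
#'
#' `out[1] = 0; out[i] = out[i-1] + counts[i-1]` — the gateway construction
#' used both at index build time and for batched lookup result placement.
#'
#' @param counts non-negative integer vector.
#' @export
exclusive_prefix_sum <- function(counts) {
  if (length(counts) == 0L) return(integer(0))
  counts <- as.integer(counts)
  if (anyNA(counts) || any(counts < 0)) stop("counts must be >= 0", call. = FALSE)
  c(0L, cumsum(counts))[seq_along(counts)]
}

#' Build a read-only q-gram index
#'
#' Stably co-sorts the (key, position) pairs by key, deduplicates the key
#' array, records each key's redundancy count (`cell_size`) and the
#' exclusive prefix sum of the pre-masking counts (`gateway`), then
#' overwrites every count larger than `repeat_threshold` with zero so that
#' over-represented k-mers yield no seeds. The gateway is computed before
#' masking, which keeps the value-array slices of unmasked keys valid.
#'
#' @param keys numeric key vector (see [encode_kmer()]); ambiguous (`NA`)
#'   keys must already have been excluded by the caller.
#' @param values data frame of position records with columns
#'   `sequence_ordinal` (1-based fragment index in load order) and `offset`
#'   (0-based k-mer start within the fragment), one row per key.
#' @param k,p word size and reference sampling step, stored for validation.
#' @param repeat_threshold maximum occurrence count for a key to stay
#'   usable as a seed source (default 1000; may be `Inf`).
#' @param fragments optional fragment data frame (see [split_reference()]);
#'   when attached, [find_seeds()] can verify and extend seeds directly.
#' @return object of class `qgram_index`.
#' @export
build_index <- function(keys, values, k = NA_integer_, p = NA_integer_,
                        repeat_threshold = 1000, fragments = NULL) {
  if (anyNA(keys)) stop("ambiguous (NA) keys must be excluded before indexing",
                        call. = FALSE)
  if (length(keys) != nrow(values))
    stop("keys and values must have equal length", call. = FALSE)
  built <- cpp_build_index(as.numeric(keys),
                           as.integer(values$sequence_ordinal),
                           as.integer(values$offset),
                           as.numeric(repeat_threshold))
  structure(list(sorted_keys = built$sorted_keys,
                 sorted_values = data.frame(
                   sequence_ordinal = built$sorted_seq,
                   offset = built$sorted_off),
                 nonredundant_keys = built$nonredundant_keys,
                 cell_size = built$cell_size,
                 gateway = built$gateway,
                 k = as.integer(k), p = as.integer(p),
                 repeat_threshold = repeat_threshold,
                 fragments = fragments),
            class = "qgram_index")
}

#' @export
print.qgram_index <- function(x, ...) {
  cat(sprintf(
    "read-only q-gram index: %d stored positions, %d distinct keys (k=%s, p=%s, repeat_threshold=%s)\n",
    nrow(x$sorted_values), length(x$nonredundant_keys),
    x$k, x$p, format(x$repeat_threshold)))
  invisible(x)
}

#' Look up one key in a q-gram index
#'
#' Binary search of the sorted non-redundant key array (leftmost exact
#' match). A present key returns its gateway and its possibly-masked cell
#' size; the matching positions are the value-array rows
#' `gateway + 1 ... gateway + cell_size`. An absent or masked key returns
#' `cell_size` 0 — absence is a normal outcome, not an error.
#'
#' @param index a `qgram_index`.
#' @param query_key numeric key.
#' @return list with `gateway`, `cell_size`, and `values` (the matching
#'   position records).
#' @export
index_lookup <- function(index, query_key) {
  lk <- cpp_lookup(index$nonredundant_keys, index$cell_size, index$gateway,
                   as.numeric(query_key))
  gw <- lk$gateway[1L]
  cs <- lk$cell_size[1L]
  vals <- if (cs > 0L) index$sorted_values[gw + seq_len(cs), , drop = FALSE]
          else index$sorted_values[0L, , drop = FALSE]
  rownames(vals) <- NULL
  list(gateway = gw, cell_size = cs, values = vals)
}

#' Batched q-gram index lookup
#'
#' Looks up many keys at once and places each query's matches contiguously:
#' with `write_index = exclusive_prefix_sum(cell_size)`, query `i`'s matches
#' occupy result rows `write_index[i] + 1 ... write_index[i] + cell_size[i]`,
#' in stored value-array order. Queries with absent or masked keys
#' contribute no rows.
#'
#' @param index a `qgram_index`.
#' @param query_keys numeric key vector.
#' @param query_values vector of caller-side positions, one per key.
#' @return data frame with columns `query_value`, `sequence_ordinal`,
#'   `ref_offset`.
#' @export
batch_lookup <- function(index, query_keys, query_values) {
  if (length(query_keys) != length(query_values))
    stop("query_keys and query_values must have equal length", call. = FALSE)
  lk <- cpp_lookup(index$nonredundant_keys, index$cell_size, index$gateway,
                   as.numeric(query_keys))
  cs <- lk$cell_size
  if (sum(cs) == 0L)
    return(data.frame(query_value = query_values[0L],
                      sequence_ordinal = integer(0), ref_offset = integer(0)))
  take <- sequence(cs, from = ifelse(cs > 0L, lk$gateway + 1L, 1L))
  data.frame(query_value = rep(query_values, cs),
             sequence_ordinal = index$sorted_values$sequence_ordinal[take],
             ref_offset = index$sorted_values$offset[take],
             stringsAsFactors = FALSE)
}
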