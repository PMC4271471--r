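# Banded affine-gap extension of representative seeds, Karlin-Altschul
# E-values, and hit filtering.

#' Alignment scoring scheme
#'
#' Match/mismatch scores, affine gap penalties (a gap of length g costs
#' `gap_open + g * gap_extend`), and the Karlin-Altschul parameters
#' `lambda` and `K` used for E-values and bit scores. The defaults are
#' megablast-style (+1/-3, gap open -5, gap extend -2) with lambda 1.28 and
#' K 0.46; all are user-adjustable.
#'
#' @param match match score, `> 0`.
#' @param mismatch mismatch score, `< 0`.
#' @param gap_open gap opening penalty, `<= 0`.
#' @param gap_extend per-base gap extension penalty, `< 0`.
#' @param lambda,K Karlin-Altschul statistical parameters, `> 0`.
#' @export
scoring_scheme <- function(match = 1L, mismatch = -3L, gap_open = -5L,
                           gap_extend = -2L, lambda = 1.28, K = 0.46) {
  stopifnot(match > 0, mismatch < 0, gap_open <= 0, gap_extend < 0,
            is.finite(lambda), lambda > 0, is.finite(K), K > 0)
  structure(list(match = as.integer(match), mismatch = as.integer(mismatch),
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend),
                 lambda = lambda, K = K),
            class = "scoring_scheme")
}

#' Banded extension of one seed
#'
#' Runs two affine-gap banded dynamic-programming extensions outward from
#' the seed's two edges (rightward from the seed end, leftward from the seed
#' start), each confined to cells within `half_width` diagonals of the seed
#' diagonal; the seed interior contributes `k * match` and is never
#' realigned. In `"global"` (glocal) mode each extension is forced to
#' consume the query to its end on that side while the reference endpoint
#' floats freely within the band, maximizing the score over reference end
#' positions — the full query is covered. In `"local"` mode each extension
#' stops at its maximum-scoring cell and may be empty.
#'
#' @param query,ref nucleotide strings (the searched-strand query and the
#'   reference fragment).
#' @param q_off,r_off 0-based seed start offsets; the k-length windows at
#'   these offsets must be identical strings.
#' @param k seed length.
#' @param mode `"global"` or `"local"`.
#' @param half_width band half-width in diagonals, `>= 0`
#'   (0 = gapless extension along the seed diagonal).
#' @param scoring a [scoring_scheme()].
#' @return a one-row hit data frame (0-based half-open coordinates on the
#'   given strings), or `NULL` if a local-mode alignment scores `<= 0`.
#' @export
banded_extend <- function(query, ref, q_off, r_off, k,
                          mode = c("global", "local"),
                          half_width = 32L, scoring = scoring_scheme()) {
  mode <- match.arg(mode)
  v <- cpp_banded_extend(query, ref, as.integer(q_off), as.integer(r_off),
                         as.integer(k), mode == "global",
                         as.integer(half_width),
                         scoring$match, scoring$mismatch,
                         scoring$gap_open, scoring$gap_extend)
  if (mode == "local" && v[["score"]] <= 0) return(NULL)
  data.frame(q_start = v[["q_start"]], q_end = v[["q_end"]],
             r_start = v[["r_start"]], r_end = v[["r_end"]],
             score = v[["score"]], matches = v[["matches"]],
             mismatches = v[["mismatches"]], gap_opens = v[["gap_opens"]],
             aln_length = v[["aln_len"]],
             identity = v[["matches"]] / v[["aln_len"]])
}

#' Karlin-Altschul E-value and bit score
#'
#' `bitscore = (lambda * score - ln K) / ln 2` and
#' `evalue = m * n * 2^(-bitscore)` (equivalently
#' `K * m * n * exp(-lambda * score)`), where `m` is the query length and
#' `n` the total residue count of all reference records in the run.
#' Vectorized over `score` and `query_length`.
#'
#' @param score integer alignment score(s).
#' @param query_length,database_length sequence lengths, `>= 1`.
#' @param scoring a [scoring_scheme()] supplying `lambda` and `K`.
#' @return list with components `evalue` and `bitscore`.
#' @export
compute_evalue <- function(score, query_length, database_length,
                           scoring = scoring_scheme()) {
  if (any(query_length < 1) || any(database_length < 1))
    stop("sequence lengths must be >= 1", call. = FALSE)
  bitscore <- (scoring$lambda * score - log(scoring$K)) / log(2)
  evalue <- as.numeric(query_length) * as.numeric(database_length) *
    2^(-bitscore)
  list(evalue = evalue, bitscore = bitscore)
}

#' Filter hits by E-value and alignment length
#'
#' Keeps hits with `evalue <= evalue_threshold` (inclusive) and
#' `aln_length >= min_aln_length`; row order is preserved.
#'
#' @param hits hit data frame.
#' @param evalue_threshold maximum E-value (inclusive).
#' @param min_aln_length minimum alignment length in columns.
#' @export
filter_hits <- function(hits, evalue_threshold = 1e-3, min_aln_length = 30L) {
  keep <- hits$evalue <= evalue_threshold & hits$aln_length >= min_aln_length
  out <- hits[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
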