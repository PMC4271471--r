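# The two-pass surrounding-area seed filter: discards isolated seeds and
# collapses each run of successor-linked seeds to a single representative,
# so that only one banded extension is launched per seed cluster.

#' Surrounding-area parameters
#'
#' The surrounding area of a seed covers seeds of the same query, same
#' reference and same strand that lie within `z` bases parallel to the
#' diagonal and strictly ahead by at most `w` bases in the reference
#' direction.
#'
#' @param z diagonal tolerance in bases, `>= 0`.
#' @param w window along the reference direction in bases, `>= 1`.
#' @export
surrounding_area <- function(z = 16L, w = 64L) {
  z <- as.integer(z); w <- as.integer(w)
  if (is.na(z) || z < 0) stop("z must be >= 0", call. = FALSE)
  if (is.na(w) || w < 1) stop("w must be >= 1", call. = FALSE)
  structure(list(z = z, w = w), class = "surrounding_area")
}

.seed_order <- function(seeds) {
  strand_rank <- match(seeds$strand, c("forward", "reverse"))
  order(seeds$query_ordinal, seeds$ref_ordinal, strand_rank,
        seeds$ref_offset, seeds$diagonal, method = "radix")
}

#' Sort seeds by location in the reference
#'
#' Stable ascending order by (query, reference, strand, reference offset,
#' diagonal) — the order required by [reduce_seeds()].
#'
#' @param seeds seed data frame (see [find_seeds()]).
#' @export
sort_seeds <- function(seeds) {
  out <- seeds[.seed_order(seeds), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Is seed b inside seed a's surrounding area?
#'
#' True iff `a` and `b` share query, reference and strand, their diagonals
#' differ by at most `z`, and `b` lies strictly ahead of `a` in the
#' reference by at most `w` bases. Vectorized over rows.
#'
#' @param a,b single-row (or equal-height) seed data frames.
#' @param area a [surrounding_area()].
#' @export
in_surrounding_area <- function(a, b, area) {
  a$query_ordinal == b$query_ordinal &
    a$ref_ordinal == b$ref_ordinal &
    a$strand == b$strand &
    abs(b$diagonal - a$diagonal) <= area$z &
    (b$ref_offset - a$ref_offset) > 0 &
    (b$ref_offset - a$ref_offset) <= area$w
}

#' Reduce seeds to cluster representatives
#'
#' Two passes over the sorted seed list. Pass 1 removes every seed whose
#' successor (the next seed in sorted order) is not inside its surrounding
#' area — this discards isolated seeds and each cluster's last member.
#' Pass 2 scans the remaining, re-linked list and removes every seed whose
#' successor in that list is inside its surrounding area — collapsing each
#' run of cluster survivors to its final member. A seed with no successor
#' (the end of its query/reference/strand group) counts as "successor not
#' in area" in both passes. A chain of n >= 2 successor-linked seeds thus
#' yields exactly one representative, and isolated seeds vanish.
#'
#' @param seeds seed data frame, already in [sort_seeds()] order
#'   (unsorted input is an error).
#' @param area a [surrounding_area()].
#' @return the representative seeds (a subset of the input rows).
#' @export
reduce_seeds <- function(seeds, area) {
  if (nrow(seeds) == 0L) return(seeds)
  ord <- .seed_order(seeds)
  if (!identical(ord, seq_len(nrow(seeds))))
    stop("seeds must be sorted with sort_seeds() before reduction",
         call. = FALSE)
  strand_rank <- match(seeds$strand, c("forward", "reverse"))
  key <- paste(seeds$query_ordinal, seeds$ref_ordinal, strand_rank)
  grp <- cumsum(c(TRUE, key[-1L] != key[-length(key)]))
  keep <- cpp_reduce_keep(as.integer(grp), as.integer(seeds$ref_offset),
                          as.integer(seeds$diagonal), area$z, area$w)
  out <- seeds[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
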