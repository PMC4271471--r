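# Synthetic-community generator and evaluation harness for the simulated
# metagenomic benchmark: sample fragments from labelled genomes, search,
# drop self hits, take best non-self hits, and score genus assignment by
# the CGA ratio (correct genus assignments / total reported hits).

.random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# i.i.d. per-base substitution; a mutated base is drawn uniformly from the
# three alternatives.
.mutate_seq <- function(seq, rate) {
  if (rate <= 0) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  hit <- which(runif(length(chars)) < rate)
  if (length(hit)) {
    bases <- c("A", "C", "G", "T")
    code <- match(chars[hit], bases) - 1L
    chars[hit] <- bases[(code + sample.int(3L, length(hit), replace = TRUE)) %% 4L + 1L]
  }
  paste(chars, collapse = "")
}

#' Generate a labelled synthetic community
#'
#' Emulates the simulated-metagenome study design: one random ancestral
#' sequence per genus (independent by default; with `inter_rate` set,
#' derived from a common root by i.i.d. substitution at that rate), genomes
#' within a genus derived from their ancestor by i.i.d. substitution at
#' `intra_rate`, and reads sampled uniformly over genomes, positions and
#' strands, then mutated at `error_rate` (substitution-only; reads are
#' retrieved verbatim when `error_rate = 0`, the default). Fully
#' reproducible from `rng_seed`.
#'
#' @param n_genera number of genera.
#' @param genomes_per_genus genomes per genus (use `>= 2` when evaluating
#'   best NON-self assignment, so a same-genus sibling exists).
#' @param genome_length genome length in bases, `>= read_length`.
#' @param n_reads number of sampled reads.
#' @param read_length read length in bases.
#' @param intra_rate within-genus per-base divergence rate, in `[0, 0.5]`.
#' @param inter_rate between-genus divergence rate from a shared root, in
#'   `[0, 0.5]`, or `NULL` (default) for independent genus ancestors.
#' @param error_rate per-base substitution error applied to reads.
#' @param rng_seed integer seed.
#' @return object of class `synthetic_community` with elements `genomes`
#'   (`id`, `genus`, `residues`), `reads` (`id`, `residues`,
#'   `true_genome_id`, `true_genus`, `true_offset`, `true_strand`) and
#'   `parameters`.
#' @export
generate_community <- function(n_genera = 5L, genomes_per_genus = 3L,
                               genome_length = 100000L, n_reads = 1000L,
                               read_length = 100L, intra_rate = 0.05,
                               inter_rate = NULL, error_rate = 0,
                               rng_seed = 1L) {
  rates <- c(intra_rate, error_rate, inter_rate)
  if (any(rates < 0 | rates > 0.5))
    stop("rates must lie in [0, 0.5]", call. = FALSE)
  if (genome_length < read_length)
    stop("genome_length must be >= read_length", call. = FALSE)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  set.seed(rng_seed)

  root <- if (!is.null(inter_rate)) .random_dna(genome_length) else NULL
  genus <- sprintf("genus%02d", seq_len(n_genera))
  genomes <- do.call(rbind, lapply(seq_len(n_genera), function(g) {
    anc <- if (is.null(root)) .random_dna(genome_length)
           else .mutate_seq(root, inter_rate)
    data.frame(id = sprintf("%s_genome%d", genus[g], seq_len(genomes_per_genus)),
               genus = genus[g],
               residues = vapply(seq_len(genomes_per_genus),
                                 function(j) .mutate_seq(anc, intra_rate),
                                 character(1)),
               stringsAsFactors = FALSE)
  }))

  gi <- sample.int(nrow(genomes), n_reads, replace = TRUE)
  off <- sample.int(genome_length - read_length + 1L, n_reads,
                    replace = TRUE) - 1L
  strand <- sample(c("forward", "reverse"), n_reads, replace = TRUE)
  res <- substring(genomes$residues[gi], off + 1L, off + read_length)
  res[strand == "reverse"] <- reverse_complement(res[strand == "reverse"])
  if (error_rate > 0)
    res <- vapply(res, .mutate_seq, character(1), rate = error_rate,
                  USE.NAMES = FALSE)
  reads <- data.frame(id = sprintf("read%06d", seq_len(n_reads)),
                      residues = res,
                      true_genome_id = genomes$id[gi],
                      true_genus = genomes$genus[gi],
                      true_offset = off,
                      true_strand = strand,
                      stringsAsFactors = FALSE)
  structure(list(genomes = genomes, reads = reads,
                 parameters = list(n_genera = n_genera,
                                   genomes_per_genus = genomes_per_genus,
                                   genome_length = genome_length,
                                   n_reads = n_reads,
                                   read_length = read_length,
                                   intra_rate = intra_rate,
                                   inter_rate = inter_rate,
                                   error_rate = error_rate,
                                   rng_seed = rng_seed)),
            class = "synthetic_community")
}

#' @export
print.synthetic_community <- function(x, ...) {
  p <- x$parameters
  cat(sprintf(
    "synthetic community: %d genera x %d genomes (%d bp), %d reads of %d bp (intra %.3g, error %.3g, seed %d)\n",
    p$n_genera, p$genomes_per_genus, p$genome_length, p$n_reads,
    p$read_length, p$intra_rate, p$error_rate, p$rng_seed))
  invisible(x)
}

#' Sequence records of a synthetic community
#'
#' @param community a [generate_community()] result.
#' @param what `"genomes"` or `"reads"`.
#' @export
community_records <- function(community, what = c("genomes", "reads")) {
  what <- match.arg(what)
  if (what == "genomes")
    sequence_records(community$genomes$id, community$genomes$residues,
                     community$genomes$genus)
  else
    sequence_records(community$reads$id, community$reads$residues)
}

#' Self-exclusion map of a synthetic community
#'
#' Named vector mapping each read id to its source genome id, for
#' [select_best_nonself_hits()].
#'
#' @inheritParams community_records
#' @export
community_origin <- function(community) {
  stats::setNames(community$reads$true_genome_id, community$reads$id)
}

#' Score genus-level taxonomic assignment
#'
#' Counts the queries with a reported (best non-self) hit, those whose hit
#' lands in a genome of the query's true genus, and their ratio — the CGA
#' ratio (correct genus assignments / total reported hits; 0 when nothing
#' is reported).
#'
#' @param best best-hit table from [select_best_nonself_hits()] (computed
#'   with self-exclusion via [community_origin()]).
#' @param community the generating [generate_community()] object.
#' @return list with `total_reported_hits`, `correct_genus_assignments`,
#'   `cga_ratio`.
#' @export
evaluate_assignment <- function(best, community) {
  total <- nrow(best)
  if (total == 0L)
    return(list(total_reported_hits = 0L, correct_genus_assignments = 0L,
                cga_ratio = 0))
  genus_of <- stats::setNames(community$genomes$genus, community$genomes$id)
  true_genus <- stats::setNames(community$reads$true_genus,
                                community$reads$id)
  correct <- sum(genus_of[best$ref_parent_id] == true_genus[best$query_id],
                 na.rm = TRUE)
  list(total_reported_hits = total,
       correct_genus_assignments = as.integer(correct),
       cga_ratio = correct / total)
}

#' Identity/coverage threshold sweep
#'
#' Re-evaluates genus assignment after discarding hits below each identity
#' threshold or below the query-coverage threshold
#' (`(q_end - q_start) / query_length`), before best-non-self-hit
#' selection. Returns one row per identity threshold plus one unfiltered
#' row. Thresholds are fractions in `[0, 1]`.
#'
#' @param hits hit data frame from [run_search()] (with `query_length`).
#' @param community the generating [generate_community()] object.
#' @param identity_thresholds fractions in `[0, 1]`.
#' @param coverage_threshold fraction in `[0, 1]`.
#' @return data frame with columns `identity_threshold` (`NA` =
#'   unfiltered), `coverage_threshold`, `total_reported_hits`,
#'   `correct_genus_assignments`, `cga_ratio`.
#' @export
threshold_sweep <- function(hits, community,
                            identity_thresholds = c(0.95, 0.90, 0.85, 0.80),
                            coverage_threshold = 0.5) {
  if (any(identity_thresholds < 0 | identity_thresholds > 1) ||
      coverage_threshold < 0 || coverage_threshold > 1)
    stop("thresholds must be fractions in [0, 1]", call. = FALSE)
  origin <- community_origin(community)
  eval_one <- function(h) {
    r <- evaluate_assignment(select_best_nonself_hits(h, origin), community)
    data.frame(total_reported_hits = r$total_reported_hits,
               correct_genus_assignments = r$correct_genus_assignments,
               cga_ratio = r$cga_ratio)
  }
  rows <- list(cbind(data.frame(identity_threshold = NA_real_,
                                coverage_threshold = NA_real_),
                     eval_one(hits)))
  cov <- (hits$q_end - hits$q_start) / hits$query_length
  for (thr in identity_thresholds) {
    keep <- hits$identity >= thr & cov >= coverage_threshold
    rows[[length(rows) + 1L]] <-
      cbind(data.frame(identity_threshold = thr,
                       coverage_threshold = coverage_threshold),
            eval_one(hits[keep, , drop = FALSE]))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
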