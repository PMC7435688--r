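#' @importFrom Biostrings pairwiseAlignment nmatch AAString AAStringSet
#'   DNAString DNAStringSet writeXStringSet readAAStringSet readDNAStringSet
#' @importFrom stats coef lm optimize pnorm qnorm quantile rbinom rlnorm rnorm
#'   runif sd setNames plogis fisher.test p.adjust model.matrix rpois rnbinom
#' @importFrom utils head read.delim write.table
NULL

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
NT4 <- c("A", "C", "G", "T")

# identity substitution matrix over the full Biostrings alphabet.
# The tiny positive mismatch score keeps ends-free alignments from trimming
# terminal mismatches (which would corrupt coverage) while never changing
# which alignment maximizes the match count.
.identity_matrix <- function(alphabet) {
  letters <- if (alphabet == "aa") Biostrings::AA_ALPHABET else Biostrings::DNA_ALPHABET
  m <- matrix(0.01, length(letters), length(letters),
              dimnames = list(letters, letters))
  diag(m) <- 1
  m
}

.check_alphabet <- function(x, alphabet, what = "sequence") {
  chars <- unique(strsplit(toupper(x), "")[[1]])
  ok <- if (alphabet == "nt") chars %in% c(NT4, "U", "N") else chars %in% AA20
  if (!all(ok)) {
    stop(sprintf("%s contains characters not in the %s alphabet: %s",
                 what, alphabet, paste(chars[!ok], collapse = "")),
         call. = FALSE)
  }
  invisible(TRUE)
}

.as_set <- function(x, alphabet) {
  if (alphabet == "aa") AAStringSet(x) else DNAStringSet(x)
}

# span of the pattern/subject inside an alignment = its non-gap characters
.span <- function(aligned_chars) nchar(gsub("-", "", aligned_chars, fixed = TRUE))

#' Percent identity and coverage between two sequences
#'
#' Aligns two sequences with an ends-free (overlap) alignment — match +1,
#' mismatch ~0, affine gaps (open 10, extend 1) — and reports identity as
#' identical aligned residues divided by the length of the shorter sequence,
#' the CD-HIT convention.  Coverage is the aligned span of the shorter
#' sequence divided by its length.
#'
#' @param a,b character scalars, both in the alphabet given by `alphabet`.
#' @param alphabet `"aa"` (default) or `"nt"`.
#' @return A list of class `alignment_identity` with elements `identity`,
#'   `coverage_shorter`, and `n_match`.
#' @examples
#' pairwise_identity("MKTAYIAKQR", "MKTAYIAKQW")
#' @export
pairwise_identity <- function(a, b, alphabet = c("aa", "nt")) {
  alphabet <- match.arg(alphabet)
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be non-empty", call. = FALSE)
  .check_alphabet(a, alphabet, "sequence 'a'")
  .check_alphabet(b, alphabet, "sequence 'b'")
  al <- pairwiseAlignment(.as_set(a, alphabet)[[1]], .as_set(b, alphabet)[[1]],
                          substitutionMatrix = .identity_matrix(alphabet),
                          gapOpening = 10, gapExtension = 1, type = "overlap")
  shorter <- min(nchar(a), nchar(b))
  spans <- c(.span(as.character(Biostrings::pattern(al))),
             .span(as.character(Biostrings::subject(al))))
  span_shorter <- if (nchar(a) <= nchar(b)) spans[1] else spans[2]
  structure(list(identity = nmatch(al) / shorter,
                 coverage_shorter = span_shorter / shorter,
                 n_match = nmatch(al)),
            class = "alignment_identity")
}

#' @export
print.alignment_identity <- function(x, ...) {
  cat(sprintf("identity %.3f, coverage of shorter %.3f (%d identical residues)\n",
              x$identity, x$coverage_shorter, x$n_match))
  invisible(x)
}

# vectorized identity/coverage of many sequences against one subject
.identity_many <- function(patterns, subject, alphabet) {
  al <- pairwiseAlignment(patterns, subject,
                          substitutionMatrix = .identity_matrix(alphabet),
                          gapOpening = 10, gapExtension = 1, type = "overlap")
  p_len <- Biostrings::width(patterns)
  s_len <- length(subject)
  shorter <- pmin(p_len, s_len)
  span_p <- .span(as.character(Biostrings::pattern(al)))
  span_s <- .span(as.character(Biostrings::subject(al)))
  span_shorter <- ifelse(p_len <= s_len, span_p, span_s)
  list(identity = nmatch(al) / shorter, coverage = span_shorter / shorter)
}

# Lossless prefilter: the free-gap alignment score (match 1, mismatch 0,
# no gap penalty) equals the longest common subsequence, an upper bound on
# the match count of ANY alignment; bound/shorter < threshold can never pass.
.lcs_bound <- function(patterns, subject, alphabet) {
  letters <- if (alphabet == "aa") Biostrings::AA_ALPHABET else Biostrings::DNA_ALPHABET
  m0 <- matrix(0, length(letters), length(letters),
               dimnames = list(letters, letters))
  diag(m0) <- 1
  sc <- pairwiseAlignment(patterns, subject, substitutionMatrix = m0,
                          gapOpening = 0, gapExtension = 0, type = "overlap",
                          scoreOnly = TRUE)
  sc / pmin(Biostrings::width(patterns), length(subject))
}

#' Greedy identity clustering of a sequence catalog
#'
#' Reimplements CD-HIT-style greedy incremental clustering: sequences are
#' sorted longest-first (ties broken by id) and each sequence joins the first
#' existing cluster whose representative it matches at `min_identity` and
#' `min_coverage` of the shorter sequence, otherwise it founds a new cluster.
#' With `strict = TRUE` the identity comparison is exclusive (`>`), matching
#' the ">50% amino-acid identity" convention used for protein families;
#' the inclusive default (`>=`) matches the 95%/90% nucleotide catalog stage.
#'
#' @param sequences named character vector (or `XStringSet`) of sequences;
#'   names are the sequence ids.
#' @param min_identity,min_coverage thresholds in (0, 1].
#' @param alphabet `"aa"` or `"nt"`.
#' @param strict logical; exclusive identity/coverage comparison.
#' @param best_match if `TRUE`, join the best-identity passing representative
#'   instead of the first (CD-HIT semantics are the default).
#' @return An object of class `cluster_set`: list with a `clusters`
#'   data.frame (cluster_id, representative, member) and the call parameters.
#' @export
greedy_cluster <- function(sequences, min_identity, min_coverage,
                           alphabet = c("aa", "nt"), strict = FALSE,
                           best_match = FALSE) {
  alphabet <- match.arg(alphabet)
  stopifnot(min_identity > 0, min_identity <= 1,
            min_coverage > 0, min_coverage <= 1)
  if (inherits(sequences, "XStringSet")) {
    sequences <- setNames(as.character(sequences), names(sequences))
  }
  if (length(sequences) == 0) {
    return(structure(list(clusters = data.frame(cluster_id = character(),
                                                representative = character(),
                                                member = character()),
                          min_identity = min_identity,
                          min_coverage = min_coverage,
                          alphabet = alphabet, strict = strict),
                     class = "cluster_set"))
  }
  if (is.null(names(sequences)) || anyDuplicated(names(sequences))) {
    stop("sequences must have unique names", call. = FALSE)
  }
  ord <- order(-nchar(sequences), names(sequences))
  sequences <- sequences[ord]
  ids <- names(sequences)
  set <- .as_set(sequences, alphabet)

  pass <- if (strict) function(x, thr) x > thr else function(x, thr) x >= thr
  rep_idx <- integer(0)          # indices (into sequences) of representatives
  assignment <- integer(length(sequences))
  for (i in seq_along(sequences)) {
    hit <- 0L
    if (length(rep_idx) > 0) {
      bound <- .lcs_bound(set[rep_idx], set[[i]], alphabet)
      cand <- which(bound >= min_identity - 1e-9)
      if (length(cand) > 0) {
        idcov <- .identity_many(set[rep_idx[cand]], set[[i]], alphabet)
        ok <- pass(idcov$identity, min_identity) & pass(idcov$coverage, min_coverage)
        if (any(ok)) {
          hit <- if (best_match) {
            cand[ok][which.max(idcov$identity[ok])]
          } else {
            cand[ok][1]          # first-founded passing representative
          }
        }
      }
    }
    if (hit == 0L) {
      rep_idx <- c(rep_idx, i)
      assignment[i] <- length(rep_idx)
    } else {
      assignment[i] <- hit
    }
  }
  clusters <- data.frame(
    cluster_id = sprintf("cluster_%04d", assignment),
    representative = ids[rep_idx][assignment],
    member = ids,
    stringsAsFactors = FALSE)
  clusters <- clusters[order(clusters$cluster_id, clusters$member), ]
  rownames(clusters) <- NULL
  structure(list(clusters = clusters, min_identity = min_identity,
                 min_coverage = min_coverage, alphabet = alphabet,
                 strict = strict),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  n_cl <- length(unique(x$clusters$cluster_id))
  cat(sprintf("cluster_set: %d sequences in %d clusters (identity %s%.2f, coverage %.2f, %s)\n",
              nrow(x$clusters), n_cl, if (x$strict) ">" else ">=",
              x$min_identity, x$min_coverage, x$alphabet))
  invisible(x)
}

#' @export
summary.cluster_set <- function(object, ...) {
  sizes <- table(object$clusters$cluster_id)
  cat(sprintf("%d clusters; size distribution:\n", length(sizes)))
  print(summary(as.integer(sizes)))
  invisible(object)
}

#' Transcripts-per-million normalization of a count matrix
#'
#' Counts are divided by gene length to per-base rates, then each sample
#' column is rescaled to sum to one million.  Samples with no counts at all
#' stay all-zero rather than raising a division error.
#'
#' @param counts non-negative integer matrix, genes in rows, samples in
#'   columns, with rownames.
#' @param gene_lengths positive lengths, named by gene or in row order.
#' @return Matrix of TPM values with the same dimnames.
#' @export
compute_tpm <- function(counts, gene_lengths) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  if (!is.null(names(gene_lengths)) && !is.null(rownames(counts))) {
    gene_lengths <- gene_lengths[rownames(counts)]
  }
  if (length(gene_lengths) != nrow(counts)) {
    stop("need one gene length per count row", call. = FALSE)
  }
  if (any(!is.finite(gene_lengths)) || any(gene_lengths <= 0)) {
    stop("gene lengths must be positive", call. = FALSE)
  }
  rate <- counts / gene_lengths
  totals <- colSums(rate)
  tpm <- sweep(rate, 2, ifelse(totals > 0, totals, 1), "/") * 1e6
  tpm[, totals == 0] <- 0
  dimnames(tpm) <- dimnames(counts)
  tpm
}

#' Cluster-level detection matrix from TPM
#'
#' A cluster is detected in a sample when any member gene has TPM > 0.
#'
#' @param tpm TPM matrix, genes in rows (rownames required).
#' @param clusters a `cluster_set` or its `clusters` data.frame.
#' @return Logical matrix, clusters in rows, samples in columns.
#' @export
detection_matrix <- function(tpm, clusters) {
  cl <- if (inherits(clusters, "cluster_set")) clusters$clusters else clusters
  missing <- setdiff(cl$member, rownames(tpm))
  if (length(missing) > 0) {
    stop("cluster member gene(s) missing from the abundance matrix: ",
         paste(head(missing, 5), collapse = ", "), call. = FALSE)
  }
  ids <- sort(unique(cl$cluster_id))
  det <- t(vapply(ids, function(cid) {
    members <- cl$member[cl$cluster_id == cid]
    colSums(tpm[members, , drop = FALSE] > 0) > 0
  }, logical(ncol(tpm))))
  dimnames(det) <- list(ids, colnames(tpm))
  det
}
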