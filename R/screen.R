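#' Confusion counts and sensitivity/specificity for one cluster
#'
#' Treats cluster detection as a classifier of the binary metabolite call:
#' TP = detected & positive, FP = detected & negative, FN = not detected &
#' positive, TN = not detected & negative.  Sensitivity is TP/(TP+FN) and
#' specificity TN/(TN+FP); a zero denominator yields `NA`, never 0.
#'
#' @param detected,metabolite logical vectors of equal length (>= 1).
#' @return List of class `assoc_score`: TP, FP, TN, FN, sensitivity,
#'   specificity, prevalence (fraction of samples with the cluster detected).
#' @export
score_cluster <- function(detected, metabolite) {
  if (length(detected) != length(metabolite)) {
    stop("detected and metabolite vectors must have equal length", call. = FALSE)
  }
  if (length(detected) < 1) stop("need at least one sample", call. = FALSE)
  detected <- as.logical(detected); metabolite <- as.logical(metabolite)
  tp <- sum(detected & metabolite); fp <- sum(detected & !metabolite)
  fn <- sum(!detected & metabolite); tn <- sum(!detected & !metabolite)
  structure(list(
    TP = tp, FP = fp, TN = tn, FN = fn,
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    prevalence = mean(detected)), class = "assoc_score")
}

#' @export
print.assoc_score <- function(x, ...) {
  cat(sprintf("TP %d FP %d TN %d FN %d | sensitivity %s, specificity %s, prevalence %.3f\n",
              x$TP, x$FP, x$TN, x$FN,
              format(round(x$sensitivity, 3)), format(round(x$specificity, 3)),
              x$prevalence))
  invisible(x)
}

#' Extract a binary call vector for one metabolite
#'
#' @param metabolites long data.frame with sample_id, metabolite, detected.
#' @param metabolite which metabolite to use (default coprostanol).
#' @return data.frame with sample_id and logical detected.
#' @export
metabolite_calls <- function(metabolites, metabolite = "coprostanol") {
  m <- metabolites[metabolites$metabolite == metabolite,
                   c("sample_id", "detected")]
  if (nrow(m) == 0) stop("no calls found for metabolite ", metabolite, call. = FALSE)
  m
}

#' Score every protein cluster against a metabolite call
#'
#' Restricts to the samples shared between the detection matrix and the
#' metabolite calls (samples missing from either are dropped), removes
#' clusters below `min_prevalence`, and returns per-cluster confusion
#' counts with sensitivity and specificity, sorted by specificity then
#' sensitivity, both descending.
#'
#' @param det cluster-by-sample logical detection matrix.
#' @param calls data.frame with sample_id and detected (see
#'   [metabolite_calls()]).
#' @param min_prevalence minimum fraction of paired samples in which a
#'   cluster must be detected (default 0.01).
#' @return data.frame of class `cluster_screen` with one row per scored
#'   cluster; attribute `n_paired` records the paired-sample count.
#' @export
screen_clusters <- function(det, calls, min_prevalence = 0.01) {
  paired <- intersect(colnames(det), calls$sample_id)
  if (length(paired) == 0) {
    stop("no samples are shared between detection matrix and metabolite calls",
         call. = FALSE)
  }
  det <- det[, paired, drop = FALSE]
  pos <- calls$detected[match(paired, calls$sample_id)]
  rows <- lapply(rownames(det), function(cid) {
    s <- score_cluster(det[cid, ], pos)
    data.frame(cluster_id = cid, TP = s$TP, FP = s$FP, TN = s$TN, FN = s$FN,
               sensitivity = s$sensitivity, specificity = s$specificity,
               prevalence = s$prevalence, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[out$prevalence >= min_prevalence, , drop = FALSE]
  out <- out[order(-out$specificity, -out$sensitivity, out$cluster_id), ]
  rownames(out) <- NULL
  attr(out, "n_paired") <- length(paired)
  class(out) <- c("cluster_screen", "data.frame")
  out
}

#' @export
print.cluster_screen <- function(x, n = 10, ...) {
  cat(sprintf("cluster_screen: %d clusters scored on %d paired samples\n",
              nrow(x), attr(x, "n_paired")))
  print.data.frame(head(x, n), digits = 3)
  if (nrow(x) > n) cat(sprintf("... and %d more clusters\n", nrow(x) - n))
  invisible(x)
}

#' Filter screened clusters on sensitivity and specificity
#'
#' Retains clusters strictly above both thresholds (the ">0.3 sensitivity
#' and >0.9 specificity" candidate rule; a cluster at exactly 0.3 is
#' rejected).
#'
#' @param scores output of [screen_clusters()].
#' @param min_sensitivity,min_specificity exclusive thresholds.
#' @return The retained subset, same class and ordering.
#' @export
filter_candidates <- function(scores, min_sensitivity = 0.3,
                              min_specificity = 0.9) {
  keep <- !is.na(scores$sensitivity) & !is.na(scores$specificity) &
    scores$sensitivity > min_sensitivity & scores$specificity > min_specificity
  out <- scores[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Map query proteins onto clusters by local alignment
#'
#' Mimics a ublast-style homology search: each query is aligned locally
#' (BLOSUM62, affine gaps) against every member of every cluster.  A
#' (query, cluster) hit is reported when the best member alignment reaches
#' `min_identity` (identical residues / alignment columns) and
#' `min_coverage` of the query; the best member maximizes identity, with
#' ties broken by coverage then id.
#'
#' @param queries named character vector of amino-acid query sequences.
#' @param clusters a `cluster_set` or its `clusters` data.frame.
#' @param member_sequences named character vector with all cluster members.
#' @param min_identity,min_coverage inclusive thresholds (0.5/0.5 for
#'   isolate proteomes, 0.25/0.5 for characterized-enzyme queries).
#' @return data.frame: query_id, cluster_id, member_id, identity, coverage.
#' @export
map_queries <- function(queries, clusters, member_sequences,
                        min_identity = 0.5, min_coverage = 0.5) {
  cl <- if (inherits(clusters, "cluster_set")) clusters$clusters else clusters
  if (length(queries) == 0) {
    return(data.frame(query_id = character(), cluster_id = character(),
                      member_id = character(), identity = numeric(),
                      coverage = numeric(), stringsAsFactors = FALSE))
  }
  missing <- setdiff(cl$member, names(member_sequences))
  if (length(missing) > 0) {
    stop("member sequence(s) missing: ", paste(head(missing, 5), collapse = ", "),
         call. = FALSE)
  }
  data("BLOSUM62", package = "Biostrings", envir = environment())
  B62 <- get("BLOSUM62", envir = environment())
  members <- AAStringSet(member_sequences[cl$member])
  hits <- list()
  for (q in names(queries)) {
    qseq <- AAString(queries[[q]])
    al <- pairwiseAlignment(members, qseq, substitutionMatrix = B62,
                            gapOpening = 10, gapExtension = 1, type = "local")
    aln_cols <- nchar(as.character(Biostrings::pattern(al)))
    identity <- ifelse(aln_cols > 0, nmatch(al) / aln_cols, 0)
    coverage <- .span(as.character(Biostrings::subject(al))) / length(qseq)
    ok <- identity >= min_identity & coverage >= min_coverage
    if (!any(ok)) next
    d <- data.frame(query_id = q, cluster_id = cl$cluster_id,
                    member_id = cl$member, identity = identity,
                    coverage = coverage, stringsAsFactors = FALSE)[ok, ]
    best <- do.call(rbind, lapply(split(d, d$cluster_id), function(g) {
      g[order(-g$identity, -g$coverage, g$member_id), ][1, ]
    }))
    hits[[q]] <- best
  }
  out <- if (length(hits)) do.call(rbind, hits) else
    data.frame(query_id = character(), cluster_id = character(),
               member_id = character(), identity = numeric(),
               coverage = numeric(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Rank candidate clusters by homology evidence
#'
#' Tier 1 candidates pass the sensitivity/specificity filter and are hit by
#' both an isolate-proteome query and a characterized-enzyme query; tier 2
#' have exactly one kind of hit; tier 3 pass on the screen alone.  Within a
#' tier, candidates sort by specificity then sensitivity, descending.
#'
#' @param candidates output of [filter_candidates()].
#' @param genome_hits,enzyme_hits data.frames from [map_queries()].
#' @return data.frame of class `candidate_report` with has_genome_hit,
#'   has_enzyme_hit and tier columns, ranked.
#' @export
prioritize <- function(candidates, genome_hits, enzyme_hits) {
  out <- as.data.frame(candidates)
  out$has_genome_hit <- out$cluster_id %in% genome_hits$cluster_id
  out$has_enzyme_hit <- out$cluster_id %in% enzyme_hits$cluster_id
  out$tier <- ifelse(out$has_genome_hit & out$has_enzyme_hit, 1L,
                     ifelse(out$has_genome_hit | out$has_enzyme_hit, 2L, 3L))
  out <- out[order(out$tier, -out$specificity, -out$sensitivity,
                   out$cluster_id), ]
  rownames(out) <- NULL
  class(out) <- c("candidate_report", "data.frame")
  out
}

#' @export
print.candidate_report <- function(x, ...) {
  cat(sprintf("candidate_report: %d candidates (%d tier-1)\n",
              nrow(x), sum(x$tier == 1)))
  print.data.frame(head(x, 10), digits = 3)
  invisible(x)
}

#' Run the discovery funnel on a synthetic study
#'
#' Convenience wrapper: clusters the study proteins at >50% identity,
#' computes TPM and cluster detection, scores clusters against the
#' coprostanol call, filters, maps homology queries, and prioritizes.
#'
#' @param study a `synthetic_study`.
#' @param genome_queries,enzyme_queries named character vectors of query
#'   proteins (defaults: none, yielding tier-3 candidates only).
#' @param min_sensitivity,min_specificity candidate filter thresholds.
#' @param min_prevalence prevalence filter for scoring.
#' @return List with clusters, detection matrix, scores, candidates and the
#'   prioritized report.
#' @export
run_discovery <- function(study, genome_queries = character(0),
                          enzyme_queries = character(0),
                          min_sensitivity = 0.3, min_specificity = 0.9,
                          min_prevalence = 0.01) {
  stopifnot(inherits(study, "synthetic_study"))
  cl <- greedy_cluster(study$proteins, min_identity = 0.5, min_coverage = 0.5,
                       alphabet = "aa", strict = TRUE)
  tpm <- compute_tpm(study$counts,
                     setNames(study$gene_info$length_nt, study$gene_info$gene_id))
  det <- detection_matrix(tpm, cl)
  calls <- metabolite_calls(study$metabolites, "coprostanol")
  scores <- screen_clusters(det, calls, min_prevalence = min_prevalence)
  candidates <- filter_candidates(scores, min_sensitivity, min_specificity)
  genome_hits <- map_queries(genome_queries, cl, study$proteins,
                             min_identity = 0.5, min_coverage = 0.5)
  enzyme_hits <- map_queries(enzyme_queries, cl, study$proteins,
                             min_identity = 0.25, min_coverage = 0.5)
  report <- prioritize(candidates, genome_hits, enzyme_hits)
  list(clusters = cl, detection = det, scores = scores,
       candidates = candidates, genome_hits = genome_hits,
       enzyme_hits = enzyme_hits, report = report)
}

#' Identify the cluster containing the planted enzyme family
#'
#' @param clusters a `cluster_set` from the study proteins.
#' @param study the `synthetic_study` the clusters were built from.
#' @return The cluster_id containing the most planted genes (NA if none).
#' @export
planted_cluster_id <- function(clusters, study) {
  cl <- if (inherits(clusters, "cluster_set")) clusters$clusters else clusters
  planted <- study$gene_info$gene_id[study$gene_info$planted]
  hit <- cl$cluster_id[cl$member %in% planted]
  if (length(hit) == 0) return(NA_character_)
  names(sort(table(hit), decreasing = TRUE))[1]
}
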