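test_that("cluster scoring reproduces the confusion-matrix definitions", {
  v <- c(TRUE, TRUE, FALSE, FALSE, TRUE)
  s <- score_cluster(v, v)
  expect_equal(s$sensitivity, 1.0)
  expect_equal(s$specificity, 1.0)

  s0 <- score_cluster(rep(FALSE, 5), c(TRUE, rep(FALSE, 4)))
  expect_equal(s0$sensitivity, 0.0)
  expect_equal(s0$specificity, 1.0)

  # undefined ratios are NA, never zero
  s_nopos <- score_cluster(c(TRUE, FALSE), c(FALSE, FALSE))
  expect_true(is.na(s_nopos$sensitivity))
  s_noneg <- score_cluster(c(TRUE, FALSE), c(TRUE, TRUE))
  expect_true(is.na(s_noneg$specificity))

  expect_error(score_cluster(c(TRUE, FALSE), TRUE), "equal length")
})

test_that("confusion counts match a brute-force tally on random vectors", {
  set.seed(77)
  for (r in 1:1000) {
    det <- runif(20) < 0.5
    pos <- runif(20) < 0.5
    s <- score_cluster(det, pos)
    tp <- 0; fp <- 0; tn <- 0; fn <- 0
    for (i in 1:20) {
      if (det[i] && pos[i]) tp <- tp + 1
      else if (det[i] && !pos[i]) fp <- fp + 1
      else if (!det[i] && pos[i]) fn <- fn + 1
      else tn <- tn + 1
    }
    expect_identical(c(s$TP, s$FP, s$TN, s$FN), as.integer(c(tp, fp, tn, fn)))
    expect_equal(s$TP + s$FP + s$TN + s$FN, 20)
    if (tp + fn > 0) expect_equal(s$sensitivity, tp / (tp + fn))
    if (tn + fp > 0) expect_equal(s$specificity, tn / (tn + fp))
  }
})

test_that("screening filters by prevalence and pairs samples by intersection", {
  det <- rbind(common = c(rep(TRUE, 10), rep(FALSE, 190)),
               rare = c(TRUE, rep(FALSE, 199)))
  colnames(det) <- paste0("s", 1:200)
  calls <- data.frame(sample_id = paste0("s", 1:200),
                      detected = rep(c(TRUE, FALSE), 100))
  sc <- screen_clusters(det, calls, min_prevalence = 0.01)
  expect_false("rare" %in% sc$cluster_id)   # 0.5% prevalence excluded
  expect_true("common" %in% sc$cluster_id)
  sc0 <- screen_clusters(det, calls, min_prevalence = 0)
  expect_setequal(sc0$cluster_id, c("common", "rare"))
  # scores are computed on the paired intersection only
  sc_sub <- screen_clusters(det, calls[1:50, ], min_prevalence = 0)
  expect_equal(sc_sub$TP + sc_sub$FP + sc_sub$TN + sc_sub$FN, c(50, 50))
  calls_alien <- data.frame(sample_id = paste0("x", 1:5), detected = TRUE)
  expect_error(screen_clusters(det, calls_alien), "shared")
})

test_that("candidate filter applies strict > thresholds", {
  sc <- data.frame(cluster_id = c("a", "b", "c", "d"),
                   TP = 1, FP = 1, TN = 1, FN = 1,
                   sensitivity = c(0.68, 0.30, 0.20, 0.31),
                   specificity = c(0.92, 0.95, 1.00, 0.90),
                   prevalence = 0.5)
  kept <- filter_candidates(sc, 0.3, 0.9)
  expect_identical(kept$cluster_id, "a")      # 0.68/0.92 retained
  # sensitivity exactly 0.30 rejected; specificity exactly 0.90 rejected
  expect_false("b" %in% kept$cluster_id)
  expect_false("c" %in% kept$cluster_id)
  expect_false("d" %in% kept$cluster_id)
})

test_that("query mapping finds homologs at the configured cutoffs", {
  set.seed(55)
  base <- random_protein(150)
  member_seqs <- c(m1 = base, m2 = mutate_to(base, 0.8),
                   m3 = random_protein(150), m4 = random_protein(150))
  cl <- data.frame(cluster_id = c("c1", "c1", "c2", "c3"),
                   representative = c("m1", "m1", "m3", "m4"),
                   member = c("m1", "m2", "m3", "m4"))
  hits <- map_queries(c(q_exact = base), cl, member_seqs,
                      min_identity = 0.5, min_coverage = 0.5)
  h1 <- hits[hits$cluster_id == "c1", ]
  expect_equal(nrow(h1), 1L)
  expect_equal(h1$member_id, "m1")            # best member wins
  expect_equal(h1$identity, 1.0)
  expect_equal(h1$coverage, 1.0)

  # an unrelated query finds nothing even at the inclusive cutoffs
  hits_none <- map_queries(c(q_none = random_protein(150)), cl, member_seqs,
                           min_identity = 0.25, min_coverage = 0.5)
  expect_equal(nrow(hits_none), 0L)

  expect_equal(nrow(map_queries(character(0), cl, member_seqs)), 0L)
})

test_that("query hits equal an all-pairs alignment oracle at the same thresholds", {
  set.seed(66)
  bases <- vapply(1:5, function(i) random_protein(120), "")
  member_seqs <- unlist(lapply(seq_along(bases), function(i) {
    setNames(c(bases[i], mutate_to(bases[i], 0.85)),
             paste0("f", i, c("a", "b")))
  }))
  cl <- data.frame(cluster_id = rep(paste0("c", 1:5), each = 2),
                   representative = names(member_seqs)[seq(1, 10, 2)][rep(1:5, each = 2)],
                   member = names(member_seqs))
  queries <- setNames(c(mutate_to(bases[1], 0.7), mutate_to(bases[3], 0.6),
                        random_protein(120)), c("q1", "q3", "qx"))
  hits <- map_queries(queries, cl, member_seqs,
                      min_identity = 0.5, min_coverage = 0.5)
  # oracle: align each query against each member independently
  oracle_pairs <- list()
  for (q in names(queries)) {
    for (m in names(member_seqs)) {
      al <- Biostrings::pairwiseAlignment(
        Biostrings::AAString(member_seqs[[m]]),
        Biostrings::AAString(queries[[q]]),
        substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 1,
        type = "local")
      cols <- nchar(as.character(Biostrings::pattern(al)))
      idy <- if (cols > 0) Biostrings::nmatch(al) / cols else 0
      cov <- nchar(gsub("-", "", as.character(Biostrings::subject(al)))) /
        nchar(queries[[q]])
      if (idy >= 0.5 && cov >= 0.5) {
        oracle_pairs[[paste(q, cl$cluster_id[cl$member == m])]] <- TRUE
      }
    }
  }
  got <- paste(hits$query_id, hits$cluster_id)
  expect_setequal(got, names(oracle_pairs))
})

test_that("prioritization tiers combine screen and homology evidence", {
  cand <- data.frame(cluster_id = c("c1", "c2", "c3"),
                     TP = 1, FP = 1, TN = 1, FN = 1,
                     sensitivity = c(0.9, 0.8, 0.7),
                     specificity = c(0.95, 0.99, 0.93), prevalence = 0.4)
  gh <- data.frame(cluster_id = c("c1", "c2"))
  eh <- data.frame(cluster_id = "c1")
  rep1 <- prioritize(cand, gh, eh)
  expect_equal(rep1$tier[rep1$cluster_id == "c1"], 1L)
  expect_equal(rep1$tier[rep1$cluster_id == "c2"], 2L)   # genome hit only
  expect_equal(rep1$tier[rep1$cluster_id == "c3"], 3L)
  expect_equal(rep1$cluster_id[1], "c1")

  # without enzyme hits no cluster can reach tier 1
  rep2 <- prioritize(cand, gh, eh[0, , drop = FALSE])
  expect_false(any(rep2$tier == 1))
  # within a tier, specificity ranks first
  expect_equal(rep2$cluster_id[rep2$tier == 2][1], "c2")
})

test_that("the planted family is recovered tier-1 rank-1 from a full study", {
  st <- small_study(seed = 101, n_samples = 150, n_species = 20,
                    genes_per_species = 4, encoder_species = 4)
  res <- run_discovery(
    st,
    genome_queries = c(isolate = st$root_protein),
    enzyme_queries = c(enzyme = simulate_enzyme_family(
      st$root_protein, 1, c(0.35, 0.40), seed = 1101)))
  pid <- planted_cluster_id(res$clusters, st)
  expect_false(is.na(pid))
  sc <- res$scores[res$scores$cluster_id == pid, ]
  expect_gt(sc$specificity, 0.9)
  expect_gt(sc$sensitivity, 0.3)
  expect_equal(res$report$cluster_id[1], pid)
  expect_equal(res$report$tier[1], 1L)
  # raising epsilon lowers the planted cluster's specificity (stochastically)
  st_hi <- simulate_study(simulation_config(
    n_samples = 150, n_species = 20, genes_per_species = 4,
    encoder_species = 4, background_fp_epsilon = 0.4, seed = 101))
  res_hi <- run_discovery(st_hi)
  pid_hi <- planted_cluster_id(res_hi$clusters, st_hi)
  sc_hi <- res_hi$scores[res_hi$scores$cluster_id == pid_hi, ]
  expect_lt(sc_hi$specificity, sc$specificity)
})
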