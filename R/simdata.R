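#' Configuration for a synthetic paired metagenome-metabolome study
#'
#' Bundles and validates every knob of the generator.  Defaults encode the
#' study conditions the pipeline is built for: a 4-species encoder clade
#' carrying a divergent cholesterol-dehydrogenase-like family (55-90%
#' amino-acid identity to the family root), a mean encoder-clade relative
#' abundance of 1.4%, coprostanol detected with probability 0.95 when an
#' encoder species is present (2% background false-positive rate), stool
#' cholesterol reduced to 0.25-0.45 of baseline and cholestenone raised
#' 3.3-5.4-fold in encoder samples, and serum total cholesterol lower by
#' 0.15 mmol/L in encoders on top of age/sex/antibiotic/statin covariates.
#'
#' @param n_samples,n_species,genes_per_species,encoder_species community
#'   dimensions; `encoder_species <= n_species`.
#' @param planted_identity_range target pairwise amino-acid identity of
#'   planted family members to the family root, fractions in \[0, 1\].
#' @param species_prevalence per-species probability that a species is
#'   present in a sample (scalar, recycled, or length `n_species`).
#' @param encoder_species_prevalence presence probability for each encoder
#'   species when `species_prevalence` is scalar; the default 0.16 puts the
#'   4-species clade in roughly half the samples, the middle of the
#'   37-92% clade prevalence range observed across cohorts.  Set to `NULL`
#'   (or pass a full-length `species_prevalence` vector) to give encoder
#'   species the shared prevalence.
#' @param abundance_lognormal_mu_sigma log-scale mean and sd of species
#'   relative abundances.
#' @param encoder_mean_abundance mean relative abundance of the encoder
#'   clade in samples where it is present.
#' @param sequencing_depth expected total read count per sample.
#' @param detect_prob_delta probability of a positive coprostanol call given
#'   at least one encoder species present.
#' @param background_fp_epsilon probability of a positive call with no
#'   encoder species present.
#' @param cholesterol_reduction_range,cholestenone_fold_range multiplicative
#'   shifts applied to stool cholesterol / cholestenone in encoder samples.
#' @param lipid_effect_beta shift in serum TC (mmol/L) for encoders.
#' @param covariate_effects named vector of mmol/L-per-unit effects for
#'   `age` (per year, centered at 50), `sexM`, `antibiotics`, `statin`.
#' @param tc_baseline,noise_sd serum TC baseline and residual sd (mmol/L).
#' @param protein_length amino-acid length of simulated proteins.
#' @param indel_prob per-site indel probability of the planted-family
#'   mutation model.
#' @param samples_per_participant stool samples per participant; above 1
#'   activates the repeated-measures design with a shared participant
#'   intercept (sd `participant_sd`, log10 metabolite scale).
#' @param participant_sd standard deviation of the participant intercept in
#'   the repeated-measures design.
#' @param overdispersion optional negative-binomial size parameter for gene
#'   counts; `NULL` (default) draws Poisson counts.
#' @param seed integer seed stored with the study.
#' @return A validated list of class `sim_config`.
#' @export
simulation_config <- function(n_samples = 200,
                              n_species = 30,
                              genes_per_species = 6,
                              encoder_species = 4,
                              planted_identity_range = c(0.55, 0.90),
                              species_prevalence = 0.6,
                              encoder_species_prevalence = 0.16,
                              abundance_lognormal_mu_sigma = c(0, 1),
                              encoder_mean_abundance = 0.014,
                              sequencing_depth = 2e5,
                              detect_prob_delta = 0.95,
                              background_fp_epsilon = 0.02,
                              cholesterol_reduction_range = c(0.25, 0.45),
                              cholestenone_fold_range = c(3.3, 5.4),
                              lipid_effect_beta = -0.15,
                              covariate_effects = c(age = 0.015, sexM = -0.3,
                                                    antibiotics = 0, statin = -1.0),
                              tc_baseline = 5.2,
                              noise_sd = 0.9,
                              protein_length = 250,
                              indel_prob = 0.01,
                              samples_per_participant = 1,
                              participant_sd = 0.3,
                              overdispersion = NULL,
                              seed = 1L) {
  cfg <- as.list(environment())
  probs <- c(cfg$species_prevalence, cfg$encoder_species_prevalence,
             cfg$detect_prob_delta,
             cfg$background_fp_epsilon, cfg$planted_identity_range,
             cfg$indel_prob)
  if (any(probs < 0 | probs > 1)) {
    stop("probabilities and identity targets must lie in [0, 1]", call. = FALSE)
  }
  if (diff(cfg$planted_identity_range) < 0) {
    stop("planted_identity_range must be increasing", call. = FALSE)
  }
  if (cfg$n_samples < 0 || cfg$n_species < 0 || cfg$encoder_species < 0) {
    stop("n_samples, n_species, encoder_species must be >= 0", call. = FALSE)
  }
  if (cfg$encoder_species > cfg$n_species) {
    stop("encoder_species cannot exceed n_species", call. = FALSE)
  }
  if (cfg$sequencing_depth < 0) stop("sequencing_depth must be >= 0", call. = FALSE)
  if (!length(cfg$species_prevalence) %in% c(1L, cfg$n_species)) {
    stop("species_prevalence must be scalar or length n_species", call. = FALSE)
  }
  if (cfg$encoder_mean_abundance <= 0 || cfg$encoder_mean_abundance >= 1) {
    stop("encoder_mean_abundance must be in (0, 1)", call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0(
    "sim_config: %d samples, %d species (%d encoders), %d genes/species\n",
    "  planted identity %.2f-%.2f, clade abundance %.3f, delta %.2f, epsilon %.2f\n",
    "  TC effect %.2f mmol/L, noise sd %.2f, seed %d\n"),
    x$n_samples, x$n_species, x$encoder_species, x$genes_per_species,
    x$planted_identity_range[1], x$planted_identity_range[2],
    x$encoder_mean_abundance, x$detect_prob_delta, x$background_fp_epsilon,
    x$lipid_effect_beta, x$noise_sd, x$seed))
  invisible(x)
}

.random_protein <- function(length) paste(sample(AA20, length, TRUE), collapse = "")

# fixed codon per amino acid so genes determine proteins and vice versa
.CODON <- c(A = "GCT", C = "TGT", D = "GAT", E = "GAA", F = "TTT", G = "GGT",
            H = "CAT", I = "ATT", K = "AAA", L = "CTG", M = "ATG", N = "AAT",
            P = "CCG", Q = "CAG", R = "CGT", S = "TCT", T = "ACT", V = "GTT",
            W = "TGG", Y = "TAT")

.back_translate <- function(protein) {
  paste(.CODON[strsplit(protein, "")[[1]]], collapse = "")
}

#' Plant a divergent enzyme family around a root protein
#'
#' Generates variants of a root protein whose pairwise identity to the root
#' (as measured by [pairwise_identity()]) is drawn uniformly from
#' `identity_range`.  Divergence is modelled as uniform random substitutions
#' plus rare single-residue indels.  All variants substitute along one
#' shared, randomly ordered divergence path (a variant with substitution
#' load k carries the first k family-wide substitutions), so members of the
#' family differ from each other only by their difference in load — the
#' nested divergence structure of a clade radiating from a common ancestor.
#' Pairwise identity between any two members is therefore at least
#' `1 - (1 - identity_range[1])`, which keeps a family planted at 0.55-0.90
#' identity to its root in a single >50%-identity cluster.  Indels are
#' drawn per variant and placed well apart and away from the termini so
#' realized alignment identity tracks the substitution load (within about
#' 0.03) instead of being eroded by unrecoverable gap clusters.
#'
#' @param root_protein non-empty amino-acid string.
#' @param n_variants number of variants (0 gives an empty vector).
#' @param identity_range increasing pair of fractions in \[0, 1\]; a target of
#'   exactly 1 yields a verbatim copy.
#' @param indel_prob per-site indel probability (length change capped at 5%).
#' @param seed optional seed; `NULL` continues the current RNG stream.
#' @return Character vector of variant protein sequences.
#' @export
simulate_enzyme_family <- function(root_protein, n_variants, identity_range,
                                   indel_prob = 0.01, seed = NULL) {
  if (!is.character(root_protein) || !nzchar(root_protein)) {
    stop("root_protein must be a non-empty amino-acid string", call. = FALSE)
  }
  .check_alphabet(root_protein, "aa", "root_protein")
  if (n_variants < 0) stop("n_variants must be >= 0", call. = FALSE)
  if (any(identity_range < 0 | identity_range > 1) ||
      diff(range(identity_range)) != diff(identity_range)) {
    stop("identity_range must be an increasing pair in [0, 1]", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  if (n_variants == 0) return(character(0))
  L <- nchar(root_protein)
  path <- sample(L)                     # family-wide substitution order
  alt <- vapply(strsplit(root_protein, "")[[1]],
                function(aa) sample(setdiff(AA20, aa), 1), "",
                USE.NAMES = FALSE)
  vapply(seq_len(n_variants), function(i) {
    target <- runif(1, identity_range[1], identity_range[2])
    .mutate_protein(root_protein, target, indel_prob, path, alt)
  }, character(1))
}

.mutate_protein <- function(root, target, indel_prob, path, alt) {
  r <- strsplit(root, "")[[1]]
  L <- length(r)
  k <- round((1 - target) * L)
  if (k > 0) {
    pos <- path[seq_len(k)]
    r[pos] <- alt[pos]
  }
  if (target < 1 && indel_prob > 0) {
    n_indel <- min(rbinom(1, L, indel_prob), floor(L * 0.05))
    margin <- 60L; min_sep <- 100L
    pos <- integer(0)
    if (L > 2 * margin) {
      allowed <- seq(margin, L - margin)
      for (z in seq_len(n_indel)) {
        ok <- allowed[vapply(allowed, function(p) all(abs(p - pos) >= min_sep), TRUE)]
        if (length(ok) == 0) break
        pos <- c(pos, if (length(ok) == 1) ok else sample(ok, 1))
      }
    }
    for (p in sort(pos, decreasing = TRUE)) {
      if (runif(1) < 0.5) r <- r[-p] else r <- append(r, sample(AA20, 1), after = p)
    }
  }
  paste(r, collapse = "")
}

#' Simulate community composition and gene counts
#'
#' Species occur in samples as independent Bernoulli draws at their
#' prevalence; present species receive log-normal relative abundances,
#' renormalized per sample.  When encoder species are present their joint
#' relative abundance is set by a log-normal draw centred on
#' `encoder_mean_abundance` and split among the present encoders, so the
#' clade calibrates to its configured mean.  Gene counts are Poisson (or
#' negative-binomial) with expectation depth x species abundance x
#' gene length / species gene content.
#'
#' @param config a [simulation_config()] object.
#' @param seed optional; defaults to `config$seed`.
#' @return List with `proteins` and `genes` (named character vectors),
#'   `gene_info` data.frame, `truth` data.frame (species, encoder flag,
#'   planted gene id), `presence` species-by-sample logical matrix, and the
#'   `counts` gene-by-sample integer matrix.
#' @export
simulate_community_samples <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  n_sp <- config$n_species
  n_enc <- config$encoder_species
  species <- sprintf("sp%03d", seq_len(max(n_sp, 1)))[seq_len(n_sp)]
  samples <- sprintf("S%04d", seq_len(config$n_samples))
  encoder <- seq_len(n_sp) <= n_enc
  prev <- rep_len(config$species_prevalence, n_sp)
  if (length(config$species_prevalence) == 1L &&
      !is.null(config$encoder_species_prevalence)) {
    prev[encoder] <- config$encoder_species_prevalence
  }

  # background proteins + one planted family member per encoder species
  root <- .random_protein(config$protein_length)
  family <- simulate_enzyme_family(root, n_enc, config$planted_identity_range,
                                   indel_prob = config$indel_prob, seed = NULL)
  proteins <- character(0); gene_species <- character(0); planted <- logical(0)
  for (s in seq_len(n_sp)) {
    bg <- vapply(seq_len(config$genes_per_species),
                 function(i) .random_protein(config$protein_length), "")
    sp_prot <- if (encoder[s]) c(bg, family[s]) else bg
    proteins <- c(proteins, sp_prot)
    gene_species <- c(gene_species, rep(species[s], length(sp_prot)))
    planted <- c(planted, c(rep(FALSE, length(bg)), TRUE)[seq_along(sp_prot)])
  }
  gene_ids <- sprintf("gene_%05d", seq_along(proteins))
  names(proteins) <- gene_ids
  genes <- vapply(proteins, .back_translate, "")
  gene_len_nt <- nchar(genes)
  gene_info <- data.frame(gene_id = gene_ids, species = gene_species,
                          length_nt = gene_len_nt, planted = planted,
                          stringsAsFactors = FALSE)
  truth <- data.frame(
    species = species, encoder = encoder,
    planted_gene_id = ifelse(encoder, gene_ids[planted][seq_len(n_sp)], NA_character_),
    stringsAsFactors = FALSE)
  truth$planted_gene_id[!encoder] <- NA_character_
  if (n_enc > 0) truth$planted_gene_id[encoder] <- gene_ids[planted]

  presence <- matrix(FALSE, n_sp, config$n_samples,
                     dimnames = list(species, samples))
  counts <- matrix(0L, length(gene_ids), config$n_samples,
                   dimnames = list(gene_ids, samples))
  mu <- config$abundance_lognormal_mu_sigma[1]
  sigma <- config$abundance_lognormal_mu_sigma[2]
  # log-normal for the clade share, mean fixed at the configured value
  clade_sdlog <- 0.5
  clade_meanlog <- log(config$encoder_mean_abundance) - clade_sdlog^2 / 2

  for (j in seq_len(config$n_samples)) {
    here <- runif(n_sp) < prev
    presence[, j] <- here
    if (!any(here)) next
    raw <- ifelse(here, rlnorm(n_sp, mu, sigma), 0)
    enc_here <- here & encoder
    rel <- numeric(n_sp)
    if (any(enc_here)) {
      clade <- min(rlnorm(1, clade_meanlog, clade_sdlog), 0.5)
      bg_here <- here & !encoder
      if (any(bg_here)) {
        rel[bg_here] <- raw[bg_here] / sum(raw[bg_here]) * (1 - clade)
        rel[enc_here] <- raw[enc_here] / sum(raw[enc_here]) * clade
      } else {
        rel[enc_here] <- raw[enc_here] / sum(raw[enc_here])
      }
    } else {
      rel[here] <- raw[here] / sum(raw[here])
    }
    for (s in which(here)) {
      g <- which(gene_species == species[s])
      lam <- config$sequencing_depth * rel[s] * gene_len_nt[g] / sum(gene_len_nt[g])
      counts[g, j] <- if (is.null(config$overdispersion)) {
        rpois(length(g), lam)
      } else {
        rnbinom(length(g), mu = lam, size = config$overdispersion)
      }
    }
  }
  list(proteins = proteins, genes = genes, gene_info = gene_info,
       truth = truth, presence = presence, counts = counts,
       root_protein = root)
}

#' Simulate stool sterol metabolomics for a community
#'
#' Coprostanol is called positive with probability `delta` when at least one
#' encoder species is present in the sample and with probability `epsilon`
#' otherwise.  Encoder samples have stool cholesterol multiplied by a factor
#' drawn from `cholesterol_reduction_range` and cholestenone multiplied by a
#' fold change from `cholestenone_fold_range`.
#'
#' @param species_presence species-by-sample logical matrix.
#' @param encoder_flags logical, one per species row.
#' @param delta,epsilon detection probabilities in \[0, 1\].
#' @param cholesterol_reduction_range,cholestenone_fold_range multiplicative
#'   ranges for encoder samples.
#' @param participant optional participant id per sample; with
#'   `participant_sd > 0` a shared log10-scale intercept is added to each
#'   participant's metabolite abundances (repeated-measures mode).
#' @param participant_sd sd of the participant intercept.
#' @param seed optional seed.
#' @return Long data.frame: sample_id, metabolite, detected,
#'   relative_abundance; one row per sample per sterol.
#' @export
simulate_metabolome <- function(species_presence, encoder_flags,
                                delta = 0.95, epsilon = 0.02,
                                cholesterol_reduction_range = c(0.25, 0.45),
                                cholestenone_fold_range = c(3.3, 5.4),
                                participant = NULL, participant_sd = 0,
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (any(c(delta, epsilon) < 0 | c(delta, epsilon) > 1)) {
    stop("delta and epsilon must be in [0, 1]", call. = FALSE)
  }
  if (nrow(species_presence) != length(encoder_flags)) {
    stop("encoder_flags must have one entry per species row", call. = FALSE)
  }
  samples <- colnames(species_presence)
  n <- ncol(species_presence)
  if (is.null(samples)) samples <- sprintf("S%04d", seq_len(n))
  enc_present <- colSums(species_presence[encoder_flags, , drop = FALSE]) > 0
  p_call <- ifelse(enc_present, delta, epsilon)
  copro_pos <- runif(n) < p_call

  u <- if (!is.null(participant) && participant_sd > 0) {
    ids <- unique(participant)
    setNames(rnorm(length(ids), 0, participant_sd), ids)[participant]
  } else rep(0, n)

  chol <- rlnorm(n, log(0.02), 0.4) * 10^u
  chol[enc_present] <- chol[enc_present] *
    runif(sum(enc_present), cholesterol_reduction_range[1],
          cholesterol_reduction_range[2])
  one <- rlnorm(n, log(0.001), 0.4) * 10^u
  one[enc_present] <- one[enc_present] *
    runif(sum(enc_present), cholestenone_fold_range[1],
          cholestenone_fold_range[2])
  copro <- ifelse(copro_pos, rlnorm(n, log(0.01), 0.6) * 10^u, 0)

  data.frame(
    sample_id = rep(samples, 3),
    metabolite = rep(c("cholesterol", "cholestenone", "coprostanol"), each = n),
    detected = c(rep(TRUE, 2 * n), copro_pos),
    relative_abundance = c(chol, one, copro),
    stringsAsFactors = FALSE)
}

#' Simulate host phenotypes and a serum lipid panel
#'
#' Total cholesterol is built additively: baseline + encoder effect +
#' covariate effects (age centered at 50 years, male sex, antibiotics,
#' statin) + Gaussian noise.  HDL and triglycerides are drawn independently
#' and LDL is derived by the Friedewald equation.
#'
#' @param encoder_status logical per participant.
#' @param config a [simulation_config()].
#' @param seed optional seed.
#' @return data.frame with participant_id, encoder, age, sex, antibiotics,
#'   statin, disease, cvd, TC, HDL, TG, LDL, ldl_derived.
#' @export
simulate_host_phenotypes <- function(encoder_status, config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  n <- length(encoder_status)
  eff <- config$covariate_effects
  age <- rnorm(n, 50, 12)
  sex <- ifelse(runif(n) < 0.5, "M", "F")
  antibiotics <- ifelse(runif(n) < 0.1, "yes", "no")
  statin <- ifelse(runif(n) < 0.15, "yes", "no")
  disease <- sample(c("nonIBD", "CD", "UC"), n, TRUE, prob = c(0.5, 0.3, 0.2))
  cvd <- ifelse(runif(n) < 0.2, "yes", "no")
  tc <- config$tc_baseline +
    config$lipid_effect_beta * encoder_status +
    .eff(eff, "age") * (age - 50) +
    .eff(eff, "sexM") * (sex == "M") +
    .eff(eff, "antibiotics") * (antibiotics == "yes") +
    .eff(eff, "statin") * (statin == "yes") +
    rnorm(n, 0, config$noise_sd)
  hdl <- pmax(rnorm(n, 1.3, 0.3), 0.4)
  tg <- pmin(rlnorm(n, log(1.2), 0.4), 4.4)
  data.frame(
    participant_id = sprintf("P%04d", seq_len(n)),
    encoder = encoder_status, age = age, sex = sex,
    antibiotics = antibiotics, statin = statin, disease = disease, cvd = cvd,
    TC = tc, HDL = hdl, TG = tg,
    LDL = tc - hdl - tg / 2.2, ldl_derived = rep(TRUE, n),
    stringsAsFactors = FALSE)
}

.eff <- function(effects, name) if (name %in% names(effects)) effects[[name]] else 0

#' Simulate a complete synthetic study
#'
#' Orchestrates [simulate_community_samples()], [simulate_metabolome()] and
#' [simulate_host_phenotypes()] under one RNG stream seeded from
#' `config$seed`, with one participant per `samples_per_participant`
#' consecutive samples.
#'
#' @param config a [simulation_config()].
#' @return Object of class `synthetic_study`: config, sequences, truth
#'   table, counts, presence, metabolites, phenotypes, sample metadata, and
#'   `seed_used`.
#' @export
simulate_study <- function(config = simulation_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  com <- simulate_community_samples(config, seed = NULL)
  samples <- colnames(com$counts)
  k <- max(1L, as.integer(config$samples_per_participant))
  participant <- sprintf("P%04d", ceiling(seq_along(samples) / k))
  metabolites <- simulate_metabolome(
    com$presence, com$truth$encoder,
    delta = config$detect_prob_delta, epsilon = config$background_fp_epsilon,
    cholesterol_reduction_range = config$cholesterol_reduction_range,
    cholestenone_fold_range = config$cholestenone_fold_range,
    participant = participant,
    participant_sd = if (k > 1) config$participant_sd else 0,
    seed = NULL)
  enc_sample <- colSums(com$presence[com$truth$encoder, , drop = FALSE]) > 0
  enc_participant <- tapply(enc_sample, participant, any)
  phenotypes <- simulate_host_phenotypes(
    as.logical(enc_participant[unique(participant)]), config, seed = NULL)
  phenotypes$participant_id <- unique(participant)
  structure(list(
    config = config,
    proteins = com$proteins, genes = com$genes, gene_info = com$gene_info,
    root_protein = com$root_protein,
    truth = com$truth, presence = com$presence, counts = com$counts,
    metabolites = metabolites,
    samples = data.frame(sample_id = samples, participant_id = participant,
                         encoder_truth = enc_sample, stringsAsFactors = FALSE),
    phenotypes = phenotypes,
    seed_used = config$seed), class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf(paste0(
    "synthetic_study: %d genes x %d samples (%d species, %d encoders)\n",
    "  %d participants, seed %d; coprostanol positive in %d samples\n"),
    nrow(x$counts), ncol(x$counts), nrow(x$truth), sum(x$truth$encoder),
    nrow(x$phenotypes), x$seed_used,
    sum(x$metabolites$detected[x$metabolites$metabolite == "coprostanol"])))
  invisible(x)
}
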