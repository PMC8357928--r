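# Seeded synthetic-cohort generator with planted ground truth.
#
# The generator emulates the statistical structure the downstream stages
# assume: zero-inflated compositional abundances with monotone gradient
# species, pooled log-linear cytokine responses driven by rank-transformed
# abundances, class-structured metabolite intensities with Gaussian-copula
# species couplings, and species-stratified pathway copy numbers with planted
# enrichment offsets. Every stage is deterministic given the seed.

#' Simulation configuration
#'
#' Defaults mirror the study conditions: 70 rural and 253 urban subjects with
#' a 471-subject Western-European external cohort; five cytokines and nine
#' modeled stimuli (plus one excluded viral-ligand stimulus); ~8.2% of cytokine
#' records missing; cytokine responses decreasing with age and male sex.
#'
#' @param n_rural,n_urban,n_external Group sizes.
#' @param n_species Number of microbial species.
#' @param n_metabolites Number of metabolite peaks.
#' @param n_pathways Number of metabolic pathways.
#' @param n_classes Number of metabolite molecular classes (latent clusters).
#' @param n_gradient_species Number of species with planted monotone
#'   rural-to-urban-to-external abundance shifts.
#' @param gradient_step Log-scale group-mean step per gradient stage.
#' @param detection_prob Per-species probability a species is detected in a
#'   sample (scalar or length `n_species`); 1 - detection_prob is the
#'   zero-inflation rate.
#' @param immunomod_spec Data frame (species, beta, sign ignored beyond beta's
#'   sign) of planted per-rank-unit cytokine effects; NULL for the default of
#'   4 positive and 3 negative species at |beta| = 0.004 per rank unit.
#' @param pathway_spec Data frame (pathway, beta_positive, beta_negative) of
#'   planted copy-number enrichment offsets; NULL for the default of three
#'   enriched pathways at +0.8 / -0.8.
#' @param coupling_spec Data frame (species, metabolite, rho) of planted
#'   species-metabolite Spearman couplings; NULL for the default of one
#'   coupled metabolite per immunomodulatory species (rho 0.8 positive /
#'   -0.7 negative).
#' @param beta0 Intercept of the cytokine model (ln pg/mL).
#' @param beta_age Age coefficient (per year; negative by default).
#' @param beta_sex Male-sex coefficient (female = 0, male = 1; negative by default).
#' @param noise_sd Residual SD of the cytokine model (ln scale).
#' @param missing_fraction Fraction of cytokine records deleted at random.
#' @param n_cytokines,n_stimuli Measured cytokines and modeled stimuli.
#' @param include_excluded_stimulus Also generate the excluded viral-ligand
#'   stimulus ("Poly:IC") so the exclusion path is exercised.
#' @param metab_noise_sd Residual SD of metabolite latent-class structure.
#' @param species_per_pathway Number of species encoding each pathway.
#' @param pathway_noise_sd Residual SD of the pathway copy-number model.
#' @param pathway_beta_depth,pathway_beta_mic Generative coefficients on
#'   ln read depth and relative abundance in the copy-number model.
#' @return Object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_rural = 70, n_urban = 253, n_external = 471,
                       n_species = 100, n_metabolites = 200, n_pathways = 25,
                       n_classes = 5,
                       n_gradient_species = 5, gradient_step = 2.0,
                       detection_prob = 0.7,
                       immunomod_spec = NULL, pathway_spec = NULL,
                       coupling_spec = NULL,
                       beta0 = log(100), beta_age = -0.02, beta_sex = -0.1,
                       noise_sd = 1, missing_fraction = 0.0823,
                       n_cytokines = 5, n_stimuli = 9,
                       include_excluded_stimulus = TRUE,
                       metab_noise_sd = 0.5,
                       species_per_pathway = 15, pathway_noise_sd = 0.5,
                       pathway_beta_depth = 0.5, pathway_beta_mic = 2) {
  stopifnot(n_rural > 0, n_urban > 0, n_external >= 0,
            n_species >= 1, n_gradient_species <= n_species - 1,
            noise_sd >= 0, missing_fraction >= 0, missing_fraction < 1)
  if (is.null(immunomod_spec)) {
    # planted immunomodulators sit after the core species (1) and the
    # gradient species (2 .. n_gradient_species + 1)
    first <- n_gradient_species + 2L
    idx <- seq(first, length.out = 7L)
    if (max(idx) > n_species) idx <- idx[idx <= n_species]
    betas <- c(rep(0.004, 4L), rep(-0.004, 3L))[seq_along(idx)]
    immunomod_spec <- data.frame(species = idx, beta = betas)
  }
  if (is.null(pathway_spec)) {
    k <- min(3L, n_pathways)
    pathway_spec <- data.frame(pathway = seq_len(k),
                               beta_positive = rep(0.8, k),
                               beta_negative = rep(-0.8, k))
  }
  if (is.null(coupling_spec)) {
    imm <- immunomod_spec
    n_pairs <- min(nrow(imm), n_metabolites)
    coupling_spec <- data.frame(
      species = imm$species[seq_len(n_pairs)],
      metabolite = seq_len(n_pairs),
      rho = ifelse(imm$beta[seq_len(n_pairs)] > 0, 0.8, -0.7)
    )
  }
  if (any(abs(coupling_spec$rho) >= 1)) stop("coupling |rho| must be < 1", call. = FALSE)
  if (any(immunomod_spec$species > n_species)) stop("planted species index exceeds n_species", call. = FALSE)
  structure(as.list(environment()), class = "sim_config")
}

default_species_ids <- function(n) sprintf("sp%03d", seq_len(n))

#' Simulate subject metadata
#'
#' Ages uniform on 18-65 years (the enrollment window), sex Bernoulli(0.5)
#' coded female = 0 / male = 1, residency equal to the cohort group.
#'
#' @param config A [sim_config].
#' @param seed Integer seed.
#' @return A [subject_metadata] data frame covering all three groups.
#' @export
simulate_metadata <- function(config, seed) {
  with_seed(derive_seed(seed, 1L), {
    n <- config$n_rural + config$n_urban + config$n_external
    ids <- c(sprintf("R%03d", seq_len(config$n_rural)),
             sprintf("U%03d", seq_len(config$n_urban)),
             if (config$n_external > 0) sprintf("N%03d", seq_len(config$n_external)))
    res <- c(rep("rural", config$n_rural), rep("urban", config$n_urban),
             rep("external", config$n_external))
    subject_metadata(data.frame(
      subject_id = ids,
      age = stats::runif(n, 18, 65),
      sex = stats::rbinom(n, 1, 0.5),
      residency = res,
      stringsAsFactors = FALSE
    ))
  })
}

#' Simulate a zero-inflated compositional abundance table
#'
#' Detected values are log-normal draws around per-species base means;
#' detection is Bernoulli per (species, sample); each sample is renormalized
#' to sum to 1 (closure). Species 1 is a core commensal detected in every
#' sample so no sample is empty. Gradient species receive monotone group-mean
#' shifts rural -> urban -> external of `gradient_step` on the log scale.
#'
#' @param config A [sim_config].
#' @param seed Integer seed.
#' @param metadata Optional pre-simulated [subject_metadata] (defaults to
#'   [simulate_metadata] under the same seed).
#' @return List with `table` (an [abundance_table] with group labels) and
#'   `truth` (planted gradient species, steps, and base parameters).
#' @export
simulate_abundances <- function(config, seed, metadata = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(metadata)) metadata <- simulate_metadata(config, seed)
  with_seed(derive_seed(seed, 2L), {
    n <- nrow(metadata)
    ns <- config$n_species
    species <- default_species_ids(ns)
    group <- metadata$residency
    gi <- if (config$n_gradient_species > 0) seq(2L, length.out = config$n_gradient_species) else integer(0)

    mu <- stats::rnorm(ns, 0, 2)
    mu[1L] <- 2  # core commensal
    # gradient taxa are minor community members (cf. the low-abundance taxa
    # that shift along real urbanization gradients): their planted group
    # shifts then barely perturb the closure denominator, so null species
    # stay null instead of inheriting a mirror-image dilution trend
    mu[gi] <- -2
    det <- rep_len(config$detection_prob, ns)
    det[1L] <- 1

    # alternate planted directions (some taxa rise, some fall with
    # urbanization) so closure does not impose a net monotone dilution on
    # null species
    step_sign <- stats::setNames(rep_len(c(1, -1), length(gi)), species[gi])
    step_of <- c(rural = -1, urban = 0, external = 1) * config$gradient_step
    vals <- matrix(0, n, ns, dimnames = list(metadata$subject_id, species))
    for (m in seq_len(ns)) {
      shift <- if (m %in% gi) step_sign[[species[m]]] * unname(step_of[group]) else rep(0, n)
      detected <- stats::rbinom(n, 1, det[m]) == 1
      x <- numeric(n)
      x[detected] <- exp(stats::rnorm(sum(detected), mu[m] + shift[detected], 1))
      vals[, m] <- x
    }
    rs <- rowSums(vals)
    nz <- rs > 0
    vals[nz, ] <- vals[nz, ] / rs[nz]

    truth <- list(gradient_species = species[gi],
                  gradient_step = config$gradient_step,
                  gradient_sign = step_sign,
                  species_mu = stats::setNames(mu, species),
                  detection_prob = stats::setNames(det, species))
    list(table = abundance_table(vals, group = group), truth = truth)
  })
}

cytokine_names <- function(k) {
  c("IL-6", "TNF-a", "IFN-g", "IL-1b", "IL-10")[seq_len(k)]
}
stimulus_names <- function(k) {
  c("LPS", "S.aureus", "S.pneumoniae", "S.typhi", "S.enteritidis",
    "C.burnetii", "E.coli", "M.tuberculosis", "C.albicans")[seq_len(k)]
}

#' Simulate ex vivo cytokine responses from planted microbial effects
#'
#' Log concentration = intercept + (cytokine x stimulus) mean + age effect +
#' sex effect + sum of planted per-rank-unit microbial effects + Gaussian
#' noise, exponentiated to pg/mL. Only rural/urban (non-external) subjects
#' receive measurements. A configurable fraction of records is deleted at
#' random to emulate missing measurements.
#'
#' @param abundances An [abundance_table] (ranks are computed over the
#'   measured subjects).
#' @param metadata A [subject_metadata] table.
#' @param config A [sim_config].
#' @param seed Integer seed.
#' @return List with `table` (a [cytokine_measurements] data frame) and
#'   `truth` (realized beta_cs matrix and all planted coefficients).
#' @export
simulate_cytokines <- function(abundances, metadata, config, seed) {
  stopifnot(inherits(abundances, "abundance_table"), inherits(config, "sim_config"))
  with_seed(derive_seed(seed, 3L), {
    tz <- metadata$subject_id[metadata$residency != "external"]
    tz <- intersect(rownames(abundances$values), tz)
    n <- length(tz)
    cyts <- cytokine_names(config$n_cytokines)
    stims <- stimulus_names(config$n_stimuli)
    if (config$include_excluded_stimulus) stims <- c(stims, "Poly:IC")

    beta_cs <- matrix(stats::rnorm(length(cyts) * length(stims), 0, 1),
                      length(cyts), length(stims), dimnames = list(cyts, stims))
    md <- metadata[match(tz, metadata$subject_id), ]

    imm <- config$immunomod_spec
    sp_ids <- default_species_ids(config$n_species)[imm$species]
    ranks <- vapply(sp_ids, function(s) {
      rank_transform_abundance(abundances$values[tz, s])
    }, numeric(n))
    microbial <- if (length(sp_ids)) drop(ranks %*% imm$beta) else rep(0, n)

    grid <- expand.grid(subject_id = tz, cytokine = cyts, stimulus = stims,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    i <- match(grid$subject_id, tz)
    logy <- config$beta0 +
      beta_cs[cbind(grid$cytokine, grid$stimulus)] +
      config$beta_age * md$age[i] +
      config$beta_sex * md$sex[i] +
      microbial[i] +
      stats::rnorm(nrow(grid), 0, config$noise_sd)
    grid$concentration <- exp(logy)

    keep <- stats::runif(nrow(grid)) >= config$missing_fraction
    tbl <- cytokine_measurements(grid[keep, , drop = FALSE])
    truth <- list(beta0 = config$beta0, beta_cs = beta_cs,
                  beta_age = config$beta_age, beta_sex = config$beta_sex,
                  immunomod = data.frame(species_id = sp_ids, beta = imm$beta),
                  noise_sd = config$noise_sd,
                  subjects = tz)
    list(table = tbl, truth = truth)
  })
}

#' Simulate plasma metabolome, pathway copy numbers, and annotation maps
#'
#' Metabolite intensities follow class-specific latent factors (yielding
#' planted k-means clusters aligned to molecular-class labels) plus
#' Gaussian-copula couplings to selected species that achieve a target
#' Spearman correlation. Pathway copy numbers per (species, sample) follow the
#' enrichment model's generative form: ln copies = pathway intercept +
#' depth coefficient x ln reads + abundance coefficient x relative abundance +
#' planted class offset + noise. Annotation maps (pathway -> enzymes,
#' pathway -> compounds, peak -> compounds/pathways) are generated
#' consistently.
#'
#' @param abundances An [abundance_table]; non-external samples are profiled.
#' @param config A [sim_config].
#' @param seed Integer seed.
#' @return List with `metabolites` ([metabolite_table]), `pathway_copies`
#'   ([pathway_copy_table]), `annotation` ([pathway_annotation]) and `truth`.
#' @export
simulate_metabolome_and_pathways <- function(abundances, config, seed) {
  stopifnot(inherits(abundances, "abundance_table"), inherits(config, "sim_config"))
  with_seed(derive_seed(seed, 4L), {
    grp <- abundances$group
    samples <- if (is.null(grp)) rownames(abundances$values) else
      rownames(abundances$values)[grp != "external"]
    n <- length(samples)
    nm <- config$n_metabolites
    peaks <- sprintf("mz%04d", seq_len(nm))
    classes <- sprintf("class%02d", 1 + (seq_len(nm) - 1L) %% config$n_classes)

    f <- matrix(stats::rnorm(n * config$n_classes), n, config$n_classes)
    z <- f[, 1 + (seq_len(nm) - 1L) %% config$n_classes] +
      matrix(stats::rnorm(n * nm, 0, config$metab_noise_sd), n, nm)

    # planted species-metabolite couplings: Gaussian copula on abundance ranks
    cpl <- config$coupling_spec
    sp_all <- default_species_ids(config$n_species)
    if (nrow(cpl) > 0) {
      for (j in seq_len(nrow(cpl))) {
        a <- abundances$values[samples, sp_all[cpl$species[j]]]
        zs <- stats::qnorm((rank(a) - 0.375) / (n + 0.25))  # Blom normal scores
        rho <- cpl$rho[j]
        z[, cpl$metabolite[j]] <- rho * zs + sqrt(1 - rho^2) * stats::rnorm(n)
      }
    }
    intens <- exp(z + 5)
    dimnames(intens) <- list(samples, peaks)

    # annotation: compounds per peak, compounds -> pathways, enzymes per pathway
    np <- config$n_pathways
    pwy <- sprintf("pwy%03d", seq_len(np))
    annotated <- sort(unique(c(cpl$metabolite,
                               sample(nm, size = ceiling(0.6 * nm)))))
    peak_cpd <- stats::setNames(sprintf("cpd%04d", annotated), peaks[annotated])
    cpd_pwy <- lapply(annotated, function(i) pwy[sample(np, size = sample(1:3, 1))])
    names(cpd_pwy) <- peaks[annotated]
    pwy_compounds <- stats::setNames(vector("list", np), pwy)
    for (pk in names(cpd_pwy)) {
      for (p in cpd_pwy[[pk]]) pwy_compounds[[p]] <- c(pwy_compounds[[p]], unname(peak_cpd[pk]))
    }
    pwy_enzymes <- stats::setNames(lapply(seq_len(np), function(p) {
      sprintf("K%05d", sample(99999, size = sample(5:30, 1)))
    }), pwy)
    ann <- pathway_annotation(enzymes = pwy_enzymes, compounds = pwy_compounds)
    peak_ann <- data.frame(
      peak_id = peaks,
      molecular_class = classes,
      compound_ids = ifelse(peaks %in% names(peak_cpd), peak_cpd[peaks], ""),
      pathway_ids = vapply(peaks, function(pk) {
        if (pk %in% names(cpd_pwy)) paste(cpd_pwy[[pk]], collapse = ",") else ""
      }, character(1)),
      stringsAsFactors = FALSE
    )
    metab <- metabolite_table(intens, annotation = peak_ann)

    # pathway copy numbers, stratified by species
    imm <- config$immunomod_spec
    pos_sp <- sp_all[imm$species[imm$beta > 0]]
    neg_sp <- sp_all[imm$species[imm$beta < 0]]
    depth <- stats::setNames(round(exp(stats::runif(n, log(4e6), log(2e7)))), samples)
    b0_p <- stats::setNames(stats::rnorm(np, 0, 0.5), pwy)
    pspec <- config$pathway_spec
    beta_pos <- stats::setNames(rep(0, np), pwy)
    beta_neg <- stats::setNames(rep(0, np), pwy)
    beta_pos[pspec$pathway] <- pspec$beta_positive
    beta_neg[pspec$pathway] <- pspec$beta_negative

    kpp <- min(config$species_per_pathway, config$n_species)
    recs <- vector("list", np)
    for (p in seq_len(np)) {
      # each pathway is encoded by a species subset that always includes some
      # planted positive and negative species, so both contrasts are estimable
      base <- unique(c(utils::head(pos_sp, 2), utils::head(neg_sp, 2)))
      others <- setdiff(sp_all, base)
      members <- c(base, sample(others, size = max(0, kpp - length(base))))
      sub <- expand.grid(sample_id = samples, species_id = members,
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
      mic <- abundances$values[cbind(sub$sample_id, sub$species_id)]
      sub <- sub[mic > 0, , drop = FALSE]
      mic <- mic[mic > 0]
      off <- ifelse(sub$species_id %in% pos_sp, beta_pos[p],
                    ifelse(sub$species_id %in% neg_sp, beta_neg[p], 0))
      lc <- b0_p[p] + config$pathway_beta_depth * log(depth[sub$sample_id]) +
        config$pathway_beta_mic * mic + off +
        stats::rnorm(nrow(sub), 0, config$pathway_noise_sd)
      sub$pathway_id <- pwy[p]
      sub$copies <- exp(lc)
      recs[[p]] <- sub[, c("sample_id", "species_id", "pathway_id", "copies")]
    }
    copies <- pathway_copy_table(do.call(rbind, recs), read_depth = depth)

    truth <- list(classes = stats::setNames(classes, peaks),
                  n_classes = config$n_classes,
                  couplings = data.frame(species_id = sp_all[cpl$species],
                                         peak_id = peaks[cpl$metabolite],
                                         rho = cpl$rho),
                  pathway_beta_positive = beta_pos,
                  pathway_beta_negative = beta_neg,
                  pathway_intercepts = b0_p,
                  beta_depth = config$pathway_beta_depth,
                  beta_mic = config$pathway_beta_mic,
                  positive_species = pos_sp, negative_species = neg_sp)
    list(metabolites = metab, pathway_copies = copies, annotation = ann, truth = truth)
  })
}

#' Simulate a full cohort with planted ground truth
#'
#' Runs the metadata, abundance, cytokine, and metabolome/pathway generators
#' under stage-specific streams derived from one master seed.
#'
#' @param config A [sim_config].
#' @param seed Integer master seed.
#' @return List with elements `metadata`, `abundance`, `cytokines`,
#'   `metabolites`, `pathway_copies`, `annotation`, and `truth` (the merged
#'   planted-parameter record, class `synthetic_truth`).
#' @export
simulate_cohort <- function(config, seed) {
  metadata <- simulate_metadata(config, seed)
  ab <- simulate_abundances(config, seed, metadata = metadata)
  cy <- simulate_cytokines(ab$table, metadata, config, seed)
  mp <- simulate_metabolome_and_pathways(ab$table, config, seed)
  truth <- structure(c(ab$truth, cy$truth, mp$truth,
                       list(config = unclass(config), seed = seed)),
                     class = "synthetic_truth")
  list(metadata = metadata, abundance = ab$table, cytokines = cy$table,
       metabolites = mp$metabolites, pathway_copies = mp$pathway_copies,
       annotation = mp$annotation, truth = truth)
}

#' Write a simulated cohort to a directory as TSVs plus truth.json
#'
#' @param cohort Output of [simulate_cohort].
#' @param dir Output directory (created if needed).
#' @return Named character vector of written paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    abundance = file.path(dir, "abundance.tsv"),
    metadata = file.path(dir, "metadata.tsv"),
    cytokines = file.path(dir, "cytokines.tsv"),
    metabolites = file.path(dir, "metabolites.tsv"),
    metabolite_annotation = file.path(dir, "metabolite_annotation.tsv"),
    pathway_copies = file.path(dir, "pathway_copies.tsv"),
    truth = file.path(dir, "truth.json")
  )
  write_table(cohort$abundance, paths["abundance"])
  write_table(as.data.frame(cohort$metadata), paths["metadata"])
  write_table(as.data.frame(cohort$cytokines), paths["cytokines"])
  write_table(cohort$metabolites, paths["metabolites"])
  utils::write.table(cohort$metabolites$annotation, paths["metabolite_annotation"],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_table(cohort$pathway_copies, paths["pathway_copies"])
  truth <- cohort$truth
  truth$beta_cs <- as.data.frame(as.table(truth$beta_cs))
  jsonlite::write_json(unclass(truth), paths["truth"], auto_unbox = TRUE,
                       digits = NA, force = TRUE)
  invisible(paths)
}
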