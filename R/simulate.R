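# Synthetic multi-omic cohort generator.
#
# Tumors are noisy mixtures of three latent cell programs (hepatocyte,
# cholangiocyte, hepatoblast); mutation catalogs are sampled from planted
# 96-motif signatures; copy-number profiles carry class-specific regional
# events; survival times are exponential with class-specific hazards. Every
# generator is a pure function of (config, seed), so the full pipeline can
# be exercised against ground truth.

tumor_classes <- c("CCA", "CCA-Like", "Blast-Like", "HCC")
program_names <- c("hepatocyte", "cholangiocyte", "hepatoblast")

#' Deterministic planted mutational signatures
#'
#' Three 96-motif signatures with disjoint substitution-class support
#' (pairwise cosine similarity 0): an aristolochic-acid-like T>A signature,
#' a mismatch-repair-like C>T signature and an aflatoxin-like C>A signature.
#' Within its 16 motifs each signature decays geometrically, giving a
#' distinct dominant motif.
#'
#' @param decay geometric decay rate of motif weights within a signature.
#' @return 96 x 3 matrix, columns `PS1`, `PS2`, `PS3` summing to 1.
#' @export
default_planted_signatures <- function(decay = 0.7) {
  labels <- motif_labels()
  mk <- function(sub) {
    idx <- grep(sub, labels, fixed = TRUE)
    w <- numeric(96)
    w[idx] <- decay^(seq_along(idx) - 1L)
    w / sum(w)
  }
  m <- cbind(PS1 = mk("[T>A]"), PS2 = mk("[C>T]"), PS3 = mk("[C>A]"))
  rownames(m) <- labels
  m
}

#' Synthetic reference signature catalog
#'
#' A COSMIC-SBS-style stand-in catalog built deterministically: the three
#' planted signatures under etiology-flavored names plus decoy profiles
#' (other substitution classes and a flat background). Synthetic throughout;
#' no external catalog is shipped or required.
#'
#' @return 96 x 7 column-normalized matrix.
#' @export
default_catalog <- function() {
  labels <- motif_labels()
  planted <- default_planted_signatures()
  mk <- function(sub, decay = 0.7) {
    idx <- grep(sub, labels, fixed = TRUE)
    w <- numeric(96); w[idx] <- decay^(seq_along(idx) - 1L); w / sum(w)
  }
  m <- cbind(aristolochic_like = planted[, "PS1"],
             mmr_like = planted[, "PS2"],
             aflatoxin_like = planted[, "PS3"],
             tdecay_cg = mk("[C>G]"),
             tdecay_tc = mk("[T>C]"),
             tdecay_tg = mk("[T>G]"),
             flat = rep(1 / 96, 96))
  rownames(m) <- labels
  signature_catalog(m)
}

default_cn_events <- function() {
  list(
    list(name = "bap1_3p_loss", chrom = "3", start = 51e5, end = 130e5 + 5e4,
         step = -0.8, penetrance = c("CCA" = 0.80, "CCA-Like" = 0.45,
                                     "Blast-Like" = 0.15, "HCC" = 0.12,
                                     "Normal" = 0)),
    list(name = "foxc1_6p_gain", chrom = "6", start = 10e5, end = 60e5 + 5e4,
         step = 0.6, penetrance = c("CCA" = 0.10, "CCA-Like" = 0.45,
                                    "Blast-Like" = 0.50, "HCC" = 0.45,
                                    "Normal" = 0)),
    list(name = "myc_8q_gain", chrom = "8", start = 120e5, end = 180e5 + 5e4,
         step = 0.7, penetrance = c("CCA" = 0.15, "CCA-Like" = 0.50,
                                    "Blast-Like" = 0.55, "HCC" = 0.50,
                                    "Normal" = 0)),
    list(name = "blast_5q_gain", chrom = "5", start = 20e5, end = 100e5 + 5e4,
         step = 0.7, penetrance = c("CCA" = 0.05, "CCA-Like" = 0.05,
                                    "Blast-Like" = 0.60, "HCC" = 0.10,
                                    "Normal" = 0))
  )
}

#' Simulation configuration
#'
#' All knobs of the synthetic cohort in one validated list. The defaults are
#' the study conditions the pipeline is tested under: four tumor classes of
#' 40 samples, 2000 genes with 150 markers per latent program (effect 2.5
#' log2 units), mixture-weight jitter per class, expression noise SD 0.5,
#' lognormal mutation burdens over three planted signatures, four planted
#' regional copy-number events whose penetrances mirror the reported BAP1 /
#' FOXC1 / MYC alteration pattern, and exponential survival with a
#' Blast-Like hazard ratio of 3.72 versus HCC.
#'
#' @param n_per_class named tumor-class sizes.
#' @param n_normal tumor-adjacent normal count (default 0).
#' @param n_genes gene count (must hold all program markers).
#' @param markers_per_program marker genes per latent program.
#' @param marker_effect marker upregulation, log2 units.
#' @param noise_sd per-gene Gaussian expression noise SD.
#' @param mixing_profiles named list of per-class program-weight profiles
#'   (hepatocyte, cholangiocyte, hepatoblast; each sums to 1).
#' @param mixing_concentration named per-class Dirichlet concentration of
#'   the weight jitter (lower = more heterogeneous).
#' @param mutations_meanlog,mutations_sdlog lognormal mutations-per-sample.
#' @param planted_signatures 96 x S motif signature matrix, columns sum 1.
#' @param exposure_profiles class x S exposure profiles (rows sum to 1).
#' @param exposure_concentration Dirichlet concentration of per-sample
#'   exposure jitter.
#' @param r249s_rate fraction of Blast-Like samples carrying TP53 p.R249S.
#' @param r249s_boost exposure tilt toward the aflatoxin-like signature for
#'   R249S carriers (added to the profile weight before normalization).
#' @param aflatoxin_signature name of the aflatoxin-like planted signature.
#' @param cn_events list of planted regional events (name, chrom, start,
#'   end, step, per-class penetrance).
#' @param cn_jitter_sd baseline copy-number jitter SD.
#' @param call_thresholds `c(single, high)` absolute thresholds mapping
#'   continuous values to calls +/-1 and +/-2.
#' @param cn_dosage_coef named per-gene coefficients coupling copy number
#'   into expression (log2 units per copy-number unit).
#' @param baseline_hazard daily baseline hazard of the referent class.
#' @param hazard_ratios named per-class hazard ratios (HCC = 1 referent).
#' @param censor_rate probability an observation is randomly censored.
#' @param seed RNG seed for the whole cohort.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(
    n_per_class = c("CCA" = 40L, "CCA-Like" = 40L, "Blast-Like" = 40L, "HCC" = 40L),
    n_normal = 0L,
    n_genes = 2000L,
    markers_per_program = 150L,
    marker_effect = 2.5,
    noise_sd = 0.5,
    mixing_profiles = list(
      "CCA"        = c(hepatocyte = 0.05, cholangiocyte = 0.75, hepatoblast = 0.20),
      "CCA-Like"   = c(hepatocyte = 0.06, cholangiocyte = 0.73, hepatoblast = 0.21),
      "Blast-Like" = c(hepatocyte = 0.25, cholangiocyte = 0.10, hepatoblast = 0.65),
      "HCC"        = c(hepatocyte = 0.75, cholangiocyte = 0.05, hepatoblast = 0.20),
      "Normal"     = c(hepatocyte = 0.85, cholangiocyte = 0.05, hepatoblast = 0.10)),
    mixing_concentration = c("CCA" = 12, "CCA-Like" = 400, "Blast-Like" = 60,
                             "HCC" = 60, "Normal" = 150),
    mutations_meanlog = log(80),
    mutations_sdlog = 0.6,
    planted_signatures = default_planted_signatures(),
    exposure_profiles = rbind(
      "CCA"        = c(PS1 = 0.15, PS2 = 0.70, PS3 = 0.15),
      "CCA-Like"   = c(PS1 = 0.20, PS2 = 0.60, PS3 = 0.20),
      "Blast-Like" = c(PS1 = 0.45, PS2 = 0.10, PS3 = 0.45),
      "HCC"        = c(PS1 = 0.50, PS2 = 0.25, PS3 = 0.25)),
    exposure_concentration = 8,
    r249s_rate = 0.35,
    r249s_boost = 0.8,
    aflatoxin_signature = "PS3",
    cn_events = default_cn_events(),
    cn_jitter_sd = 0.1,
    call_thresholds = c(0.3, 1.0),
    cn_dosage_coef = c(BAP1 = 1.0, MYC = 1.0, FOXC1 = 0.0),
    baseline_hazard = log(2) / 900,
    hazard_ratios = c("CCA" = 1.6, "CCA-Like" = 1.2, "Blast-Like" = 3.72,
                      "HCC" = 1.0),
    censor_rate = 0.3,
    seed = 1L) {
  cfg <- list(n_per_class = n_per_class, n_normal = n_normal, n_genes = n_genes,
              markers_per_program = markers_per_program,
              marker_effect = marker_effect, noise_sd = noise_sd,
              mixing_profiles = mixing_profiles,
              mixing_concentration = mixing_concentration,
              mutations_meanlog = mutations_meanlog,
              mutations_sdlog = mutations_sdlog,
              planted_signatures = planted_signatures,
              exposure_profiles = exposure_profiles,
              exposure_concentration = exposure_concentration,
              r249s_rate = r249s_rate, r249s_boost = r249s_boost,
              aflatoxin_signature = aflatoxin_signature,
              cn_events = cn_events, cn_jitter_sd = cn_jitter_sd,
              call_thresholds = call_thresholds,
              cn_dosage_coef = cn_dosage_coef,
              baseline_hazard = baseline_hazard,
              hazard_ratios = hazard_ratios,
              censor_rate = censor_rate, seed = as.integer(seed))
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  if (any(cfg$n_per_class <= 0L)) stop("class sizes must be positive")
  if (is.null(names(cfg$n_per_class))) stop("n_per_class must be named")
  if (cfg$n_genes < 3L * cfg$markers_per_program)
    stop("n_genes = ", cfg$n_genes, " is smaller than the ",
         3L * cfg$markers_per_program, " program marker genes")
  pens <- unlist(lapply(cfg$cn_events, `[[`, "penetrance"))
  if (any(pens < 0 | pens > 1)) stop("penetrance outside [0, 1]")
  if (cfg$censor_rate < 0 || cfg$censor_rate > 1) stop("censor_rate outside [0, 1]")
  sig_sums <- colSums(cfg$planted_signatures)
  if (any(abs(sig_sums - 1) > 1e-6))
    stop("planted signature columns must sum to 1")
  if (any(abs(rowSums(cfg$exposure_profiles) - 1) > 1e-6))
    stop("exposure profile rows must sum to 1")
  for (cl in names(cfg$n_per_class))
    if (!cl %in% names(cfg$mixing_profiles))
      stop("no mixing profile for class ", cl)
  structure(cfg, class = "sim_config")
}

# Gene identifiers and coordinates: genes are laid out on 10 chromosomes in
# index order; a few indices are renamed to the anchor genes that planted
# copy-number events target.
gene_features <- function(cfg) {
  n <- cfg$n_genes
  per_chrom <- ceiling(n / 10)
  idx <- seq_len(n)
  chrom <- as.character((idx - 1L) %/% per_chrom + 1L)
  j <- (idx - 1L) %% per_chrom + 1L
  ids <- sprintf("g%04d", idx)
  renames <- c("460" = "BAP1", "1550" = "MYC", "1030" = "FOXC1")
  for (at in names(renames)) {
    i <- as.integer(at)
    if (i <= n && per_chrom == 200L) ids[i] <- renames[[at]]
  }
  data.frame(feature_id = ids, chrom = chrom,
             start = j * 1e5, end = j * 1e5 + 5e4,
             stringsAsFactors = FALSE)
}

#' Sample identifiers and true classes implied by a configuration
#' @param cfg `sim_config`.
#' @return named character vector: class per sample id.
#' @export
sample_classes <- function(cfg) {
  cls <- c(rep(names(cfg$n_per_class), cfg$n_per_class),
           rep("Normal", cfg$n_normal))
  stats::setNames(cls, sprintf("S%03d", seq_along(cls)))
}

#' Simulate cohort expression with planted program structure
#'
#' Each gene's program profiles share a common baseline with marker blocks
#' upregulated in their owning program; each sample's expression is the
#' weight-mixture of the three programs plus Gaussian noise, on the log2
#' scale. Reference centroids are the noise-free programs plus two derived
#' tissue anchors (normal bile duct, mostly cholangiocyte; normal liver,
#' mostly hepatocyte). Deterministic under the config seed.
#'
#' @param cfg `sim_config`.
#' @return list: `expr` (genes x samples), `centroids` (named list of named
#'   per-gene vectors: `hepatocyte`, `cholangiocyte`, `hepatoblast`, `NBD`,
#'   `Liver`), `truth` (`cohort_truth` with classes and mixing weights).
#' @export
simulate_expression <- function(cfg) {
  set.seed(cfg$seed)
  feats <- gene_features(cfg)
  n_genes <- cfg$n_genes
  baseline <- stats::rnorm(n_genes, 5, 1.2)
  marker_idx <- split(seq_len(3L * cfg$markers_per_program),
                      rep(1:3, each = cfg$markers_per_program))
  programs <- vapply(1:3, function(p) {
    v <- baseline
    v[marker_idx[[p]]] <- v[marker_idx[[p]]] + cfg$marker_effect
    v
  }, numeric(n_genes))
  dimnames(programs) <- list(feats$feature_id, program_names)
  classes <- sample_classes(cfg)
  W <- t(vapply(classes, function(cl)
    rdirichlet1(cfg$mixing_profiles[[cl]] * cfg$mixing_concentration[[cl]]),
    numeric(3)))
  dimnames(W) <- list(names(classes), program_names)
  X <- programs %*% t(W) +
    matrix(stats::rnorm(n_genes * length(classes), 0, cfg$noise_sd), n_genes)
  dimnames(X) <- list(feats$feature_id, names(classes))
  centroids <- list(
    hepatocyte = programs[, "hepatocyte"],
    cholangiocyte = programs[, "cholangiocyte"],
    hepatoblast = programs[, "hepatoblast"],
    NBD = 0.85 * programs[, "cholangiocyte"] + 0.15 * programs[, "hepatocyte"],
    Liver = 0.90 * programs[, "hepatocyte"] + 0.05 * programs[, "cholangiocyte"] +
      0.05 * programs[, "hepatoblast"])
  truth <- structure(list(sample_ids = names(classes), true_class = classes,
                          mixing_weights = W, exposures = NULL,
                          r249s = NULL, cn_events = cfg$cn_events,
                          hazard_ratios = cfg$hazard_ratios),
                     class = "cohort_truth")
  list(expr = expression_matrix(X), centroids = centroids, truth = truth)
}

parse_motif <- function(labels) {
  data.frame(f1 = substr(labels, 1L, 1L), ref = substr(labels, 3L, 3L),
             alt = substr(labels, 5L, 5L), f2 = substr(labels, 7L, 7L),
             stringsAsFactors = FALSE)
}

#' Simulate somatic mutation catalogs from planted signatures
#'
#' Per tumor sample: a lognormal mutation count, a Dirichlet-jittered
#' exposure over the planted signatures around its class profile, and
#' multinomial motif draws from the resulting mixture. Contexts are written
#' directly into the variant table (no reference genome needed); half of the
#' records are emitted in their purine-strand representation to exercise
#' strand collapse. A configurable fraction of Blast-Like samples carries a
#' TP53 p.R249S record and an exposure tilt toward the aflatoxin-like
#' signature.
#'
#' @param cfg `sim_config`.
#' @param truth `cohort_truth` from [simulate_expression()] (rebuilt from
#'   the config when omitted).
#' @return variant table; attributes `exposures` (samples x signatures) and
#'   `r249s` (named logical).
#' @export
simulate_mutations <- function(cfg, truth = NULL) {
  set.seed(cfg$seed + 10007L)
  classes <- if (is.null(truth)) sample_classes(cfg) else truth$true_class
  classes <- classes[classes != "Normal"]
  ids <- names(classes)
  S <- ncol(cfg$planted_signatures)
  sig_names <- colnames(cfg$planted_signatures)
  afl <- cfg$aflatoxin_signature
  r249s <- stats::setNames(classes == "Blast-Like" &
                             stats::runif(length(ids)) < cfg$r249s_rate, ids)
  exposures <- vapply(ids, function(s) {
    prof <- cfg$exposure_profiles[classes[[s]], ]
    if (r249s[[s]]) {
      prof[afl] <- prof[afl] + cfg$r249s_boost
      prof <- prof / sum(prof)
    }
    rdirichlet1(prof * cfg$exposure_concentration)
  }, numeric(S))
  exposures <- t(matrix(exposures, nrow = S,
                        dimnames = list(sig_names, ids)))
  n_mut <- pmax(1L, round(stats::rlnorm(length(ids), cfg$mutations_meanlog,
                                        cfg$mutations_sdlog)))
  labels <- motif_labels()
  motif_counts <- vapply(seq_along(ids), function(i) {
    p <- as.vector(cfg$planted_signatures %*% exposures[i, ])
    stats::rmultinom(1L, n_mut[i], p)[, 1L]
  }, integer(96))
  rec_sample <- rep(rep(ids, each = 96), as.vector(motif_counts))
  rec_motif <- rep(rep(labels, length(ids)), as.vector(motif_counts))
  pm <- parse_motif(rec_motif)
  ctx <- paste0(pm$f1, pm$ref, pm$f2)
  ref <- pm$ref; alt <- pm$alt
  flip <- stats::runif(length(ref)) < 0.5
  ref[flip] <- unname(.comp[ref[flip]])
  alt[flip] <- unname(.comp[alt[flip]])
  ctx[flip] <- revcomp3(ctx[flip])
  vt <- data.frame(
    sample_id = rec_sample,
    chrom = as.character(sample.int(22L, length(ref), replace = TRUE)),
    pos = sample.int(1e8L, length(ref), replace = TRUE),
    ref = ref, alt = alt,
    gene = NA_character_, protein_change = NA_character_,
    context = ctx, stringsAsFactors = FALSE)
  carriers <- ids[r249s]
  if (length(carriers)) {
    hotspot <- data.frame(
      sample_id = carriers, chrom = "17", pos = 7674220L,
      ref = "G", alt = "T", gene = "TP53", protein_change = "p.R249S",
      context = "AGG", stringsAsFactors = FALSE)
    vt <- rbind(vt, hotspot)
  }
  vt <- vt[order(match(vt$sample_id, ids)), , drop = FALSE]
  rownames(vt) <- NULL
  attr(vt, "exposures") <- exposures
  attr(vt, "r249s") <- r249s
  vt
}

#' Simulate segmented copy-number profiles with class-specific events
#'
#' Baseline 0 with Gaussian jitter per gene; each planted event adds its
#' step over the genes of its region for a Bernoulli(penetrance) subset of
#' each class. Calls discretize the continuous values at the configured
#' thresholds (defaults: |x| >= 0.3 gives +/-1, |x| >= 1.0 gives +/-2).
#'
#' @param cfg `sim_config`.
#' @param truth optional `cohort_truth` (rebuilt from the config when
#'   omitted).
#' @return `cn_table` over all cohort samples; attribute `event_carriers`
#'   (samples x events logical matrix).
#' @export
simulate_copy_number <- function(cfg, truth = NULL) {
  set.seed(cfg$seed + 20011L)
  classes <- if (is.null(truth)) sample_classes(cfg) else truth$true_class
  ids <- names(classes)
  feats <- gene_features(cfg)
  vals <- matrix(stats::rnorm(nrow(feats) * length(ids), 0, cfg$cn_jitter_sd),
                 nrow(feats), dimnames = list(feats$feature_id, ids))
  carriers <- matrix(FALSE, length(ids), length(cfg$cn_events),
                     dimnames = list(ids, vapply(cfg$cn_events, `[[`,
                                                 character(1), "name")))
  for (k in seq_along(cfg$cn_events)) {
    ev <- cfg$cn_events[[k]]
    rows <- feats$chrom == ev$chrom & feats$start >= ev$start &
      feats$end <= ev$end
    pen <- ev$penetrance[classes]
    pen[is.na(pen)] <- 0
    hit <- stats::runif(length(ids)) < pen
    carriers[, k] <- hit
    vals[rows, hit] <- vals[rows, hit] + ev$step
  }
  th <- cfg$call_thresholds
  calls <- sign(vals) * ((abs(vals) >= th[1L]) + (abs(vals) >= th[2L]))
  storage.mode(calls) <- "integer"
  cn <- cn_table(feats, vals, calls)
  attr(cn, "event_carriers") <- carriers
  cn
}

#' Simulate survival with class-specific hazards
#'
#' Exponential event times with per-class hazard `baseline x HR`; with
#' probability `censor_rate` an observation is censored at a uniform time
#' before its event. Stage and grade are drawn independently of class and
#' hazard (planted-null covariates). Normals carry no survival record.
#'
#' @param cfg `sim_config`.
#' @param truth optional `cohort_truth`.
#' @return clinical data.frame: `sample_id`, `time_days`, `event`, `class`,
#'   `stage`, `grade`.
#' @export
simulate_survival <- function(cfg, truth = NULL) {
  set.seed(cfg$seed + 30013L)
  classes <- if (is.null(truth)) sample_classes(cfg) else truth$true_class
  classes <- classes[classes != "Normal"]
  ids <- names(classes)
  hr <- cfg$hazard_ratios[classes]
  if (anyNA(hr)) stop("hazard ratio missing for some class")
  t_event <- stats::rexp(length(ids), rate = cfg$baseline_hazard * hr)
  censored <- stats::runif(length(ids)) < cfg$censor_rate
  time <- ifelse(censored, stats::runif(length(ids), 0, t_event), t_event)
  data.frame(
    sample_id = ids,
    time_days = round(time, 1),
    event = as.integer(!censored),
    class = unname(classes),
    stage = sample(c("I", "II", "III", "IV"), length(ids), replace = TRUE,
                   prob = c(0.30, 0.35, 0.20, 0.15)),
    grade = sample(c("G1", "G2", "G3", "G4"), length(ids), replace = TRUE,
                   prob = c(0.20, 0.40, 0.30, 0.10)),
    stringsAsFactors = FALSE)
}

#' Simulate the full multi-omic cohort
#'
#' Runs every generator under sub-seeds derived from the config seed and
#' couples copy number into expression for the configured dosage genes
#' (`expr[gene, ] += coef * cn[gene, ]`), so expression-copy-number
#' correlation is planted where the coefficient is nonzero.
#'
#' @param cfg `sim_config`.
#' @return list: `expr`, `centroids`, `variants`, `cn`, `clinical`, `truth`,
#'   `cfg`.
#' @export
simulate_cohort <- function(cfg = sim_config()) {
  ex <- simulate_expression(cfg)
  truth <- ex$truth
  variants <- simulate_mutations(cfg, truth)
  truth$exposures <- attr(variants, "exposures")
  truth$r249s <- attr(variants, "r249s")
  cn <- simulate_copy_number(cfg, truth)
  clinical <- simulate_survival(cfg, truth)
  expr <- ex$expr
  for (g in names(cfg$cn_dosage_coef)) {
    if (g %in% rownames(expr) && g %in% rownames(cn$values))
      expr[g, ] <- expr[g, ] + cfg$cn_dosage_coef[[g]] * cn$values[g, colnames(expr)]
  }
  list(expr = expression_matrix(unclass(expr)), centroids = ex$centroids,
       variants = variants, cn = cn, clinical = clinical, truth = truth,
       cfg = cfg)
}

#' Write a simulated cohort bundle to a directory
#'
#' Emits the expression TSV, MAF, copy-number values/calls/features TSVs,
#' clinical TSV, truth TSV and reference centroid TSV.
#'
#' @param cohort output of [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_expression(cohort$expr, p("expression.tsv"))
  write_variants(cohort$variants, p("variants.maf"))
  write_copy_number(cohort$cn, p("cn_values.tsv"), p("cn_calls.tsv"),
                    p("cn_features.tsv"))
  write_clinical(cohort$clinical, p("clinical.tsv"))
  truth_df <- data.frame(sample_id = cohort$truth$sample_ids,
                         true_class = unname(cohort$truth$true_class),
                         stringsAsFactors = FALSE)
  utils::write.table(truth_df, p("truth.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  cent <- do.call(cbind, cohort$centroids)
  write_expression(cent, p("centroids.tsv"))
  invisible(dir)
}
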