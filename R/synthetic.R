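#' Default synthetic-cohort configuration
#'
#' The generator emulates an intraoperative microdialysis study: ~15 cases
#' with 1-3 catheters each across enhancing tumour (E), non-enhancing tumour
#' (NE) and adjacent brain (B), plus a block of CSF samples with graded
#' blood contamination. Peak areas follow a multiplicative log-normal model:
#' `value = exp(mu_m + patient_(m,case) + class_effect_(m,location) + noise)`
#' with patient effects `Normal(0, tau^2)` per (metabolite, case) and noise
#' `Normal(0, sigma^2)`.
#'
#' Metabolite classes and their default multiplicative location effects:
#' \describe{
#'   \item{plasma_derived}{elevated where the blood-brain barrier is
#'     disrupted: x6 in E, x1.5 in NE (amino acids, carnitines).}
#'   \item{tumour_produced}{secreted by tumour regardless of enhancement:
#'     x8 in E, x3 in NE. One sentinel, `GAA_like`, gets x128 in E and x14
#'     in NE, emulating a creatine-precursor analogue that dominates the
#'     tumour end of ranked lists.}
#'   \item{brain_associated}{x5 in B (an `NAA_like` sentinel among them).}
#'   \item{idh_oncometabolite}{one sentinel `2HG_like`, elevated x20 in E
#'     and x25 in NE of IDH-mutant cases only.}
#'   \item{background}{no location effect.}
#' }
#'
#' Missingness is intensity-dependent by default (logistic in
#' log-abundance), emulating non-detects. CSF samples mix a plasma profile
#' into a clean CSF profile in proportion to a per-sample contamination
#' fraction; heme content is proportional to that fraction plus noise.
#'
#' @param seed integer seed; all randomness derives from it.
#' @return a `generator_config` list; override elements by passing
#'   modified copies to [generate_cohort()].
#' @export
default_generator_config <- function(seed) {
  if (missing(seed) || is.null(seed)) validation_error("a seed is required")
  structure(list(
    seed = as.integer(seed),
    # 7 full E/NE/B cases, 2 E/B, 5 NE/B, 1 all-tumour E/NE: 9 E/B pairs,
    # 8 E/NE pairs, 12 NE/B pairs, 37 catheters across 15 cases
    case_design = c(rep("E,NE,B", 7L), rep("E,B", 2L), rep("NE,B", 5L),
                    "E,NE"),
    idh_mutant_cases = c(1L, 3L, 5L, 10L, 12L),
    n_metabolites = 200L,
    class_proportions = c(plasma_derived = 0.20, tumour_produced = 0.05,
                          brain_associated = 0.10, idh_oncometabolite = 0.005,
                          background = 0.645),
    # multiplicative location effects per class (columns E, NE, B)
    effects = rbind(plasma_derived = c(E = 6, NE = 1.5, B = 1),
                    tumour_produced = c(E = 8, NE = 3, B = 1),
                    brain_associated = c(E = 1, NE = 1, B = 5),
                    idh_oncometabolite = c(E = 20, NE = 25, B = 1),
                    background = c(E = 1, NE = 1, B = 1)),
    gaa_like_effects = c(E = 128, NE = 14, B = 1),
    tau = 0.5,            # patient-effect sd, log scale
    sigma = 0.4,          # measurement-noise sd, log scale
    mu_log_mean = 10,     # baseline log-abundance location
    mu_log_sd = 1.5,      # spread of metabolite baselines
    missing_rate = 0.04,
    missing_mechanism = "intensity_dependent",
    n_csf = 26L,
    csf_plasma_carryover = 12,   # plasma-profile multiplier on plasma_derived
    csf_paired_contamination = c(bloody = 0.8, clean = 0.02),
    heme_scale = 100,
    heme_noise_sd = 0.05
  ), class = "generator_config")
}

#' Generate a synthetic microdialysis cohort with ground truth
#'
#' Draws a catheter peak-area matrix, its sample annotation, a CSF block
#' (pooled samples with graded contamination plus one bloody/clean pair from
#' a dedicated subject), and the full generative truth, under the model
#' described in [default_generator_config()].
#'
#' @param config a `generator_config`, typically
#'   [default_generator_config()] with elements overridden.
#' @return list with `matrix` (raw `peak_matrix` of catheter samples),
#'   `annotation` (`sample_annotation` covering catheters and CSF), `csf`
#'   (raw `peak_matrix` of CSF samples), `heme` (named vector), and `truth`
#'   (metabolite classes and realized effects, per-case IDH status, per-CSF
#'   contamination fraction).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  cfg <- config
  designs <- strsplit(cfg$case_design, ",", fixed = TRUE)
  if (!length(designs) || any(lengths(designs) == 0L))
    validation_error("case_design must give each case at least one catheter")
  if (abs(sum(cfg$class_proportions) - 1) > 1e-8)
    validation_error("class proportions must sum to 1")
  if (cfg$tau < 0 || cfg$sigma < 0)
    validation_error("sds must be non-negative")

  n_cases <- length(designs)
  m <- cfg$n_metabolites
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))

  # --- metabolite classes (deterministic layout, sentinels first)
  counts <- round(cfg$class_proportions * m)
  counts["idh_oncometabolite"] <- max(1L, counts[["idh_oncometabolite"]])
  counts["background"] <- m - sum(counts[setdiff(names(counts), "background")])
  classes <- rep(names(counts), times = counts)
  met_ids <- sprintf("met%03d", seq_len(m))
  met_ids[which(classes == "tumour_produced")[1L]] <- "GAA_like"
  met_ids[which(classes == "idh_oncometabolite")[1L]] <- "2HG_like"
  met_ids[which(classes == "brain_associated")[1L]] <- "NAA_like"

  set.seed(derive_seed(cfg$seed, 1L))
  mu <- stats::rnorm(m, cfg$mu_log_mean, cfg$mu_log_sd)
  names(mu) <- met_ids
  # sentinels emulate robustly detected compounds: fixed above-average
  # baseline so their planted effects are observable, not censored
  mu[c("GAA_like", "2HG_like", "NAA_like")] <- cfg$mu_log_mean + cfg$mu_log_sd

  # realized multiplicative effects per metabolite x location
  eff <- matrix(1, m, 3L, dimnames = list(met_ids, c("E", "NE", "B")))
  for (cl in rownames(cfg$effects))
    eff[classes == cl, ] <- rep(cfg$effects[cl, ], each = sum(classes == cl))
  eff["GAA_like", ] <- cfg$gaa_like_effects

  idh <- rep("wild_type", n_cases)
  idh[intersect(cfg$idh_mutant_cases, seq_len(n_cases))] <- "mutant"

  # --- catheter samples
  sample_id <- character(); case_id <- character(); location <- character()
  for (i in seq_len(n_cases)) {
    for (loc in designs[[i]]) {
      sample_id <- c(sample_id, sprintf("case%02d_%s", i, loc))
      case_id <- c(case_id, sprintf("case%02d", i))
      location <- c(location, loc)
    }
  }
  n_samp <- length(sample_id)
  vals <- matrix(NA_real_, m, n_samp, dimnames = list(met_ids, sample_id))
  onco <- classes == "idh_oncometabolite"
  for (i in seq_len(n_cases)) {
    set.seed(derive_seed(cfg$seed, 100L + i))
    patient <- stats::rnorm(m, 0, cfg$tau)
    cols <- which(case_id == sprintf("case%02d", i))
    for (j in cols) {
      loc <- location[j]
      e <- eff[, loc]
      if (idh[i] != "mutant") e[onco] <- 1
      vals[, j] <- exp(mu + patient + log(e) +
                         stats::rnorm(m, 0, cfg$sigma))
    }
  }

  # --- intensity-dependent missingness on catheter samples
  set.seed(derive_seed(cfg$seed, 2L))
  vals <- apply_missingness(vals, cfg)

  annotation <- data.frame(
    sample_id = sample_id, case_id = case_id,
    catheter = c(E = "X", NE = "Y", B = "Z")[location],
    location = location,
    idh_status = idh[match(case_id, sprintf("case%02d", seq_len(n_cases)))],
    recurrent = FALSE, batch = "batch1", heme = NA_real_,
    perfusate_excluded = "", stringsAsFactors = FALSE)

  # --- CSF block: pooled samples plus one paired bloody/clean subject
  set.seed(derive_seed(cfg$seed, 3L))
  contamination <- stats::rbeta(cfg$n_csf, 0.8, 2.5)
  csf_ids <- c(sprintf("csf%02d", seq_len(cfg$n_csf)),
               "csf_paired_bloody", "csf_paired_clean")
  contamination <- c(contamination, cfg$csf_paired_contamination)
  names(contamination) <- csf_ids
  plasma_boost <- rep(1, m)
  plasma_boost[classes == "plasma_derived"] <- cfg$csf_plasma_carryover
  csf_vals <- matrix(NA_real_, m, length(csf_ids),
                     dimnames = list(met_ids, csf_ids))
  clean_profile <- exp(mu) * ifelse(classes == "brain_associated", 2, 1)
  plasma_profile <- exp(mu) * plasma_boost
  for (j in seq_along(csf_ids)) {
    f <- contamination[j]
    base <- (1 - f) * clean_profile + f * plasma_profile
    csf_vals[, j] <- base * exp(stats::rnorm(m, 0, cfg$sigma))
  }
  set.seed(derive_seed(cfg$seed, 4L))
  csf_vals <- apply_missingness(csf_vals, cfg)
  heme <- contamination * cfg$heme_scale *
    exp(stats::rnorm(length(csf_ids), 0, cfg$heme_noise_sd))

  csf_annotation <- data.frame(
    sample_id = csf_ids,
    case_id = c(rep(sprintf("csf_subject%02d", seq_len(cfg$n_csf))),
                "csf_paired_subject", "csf_paired_subject"),
    catheter = "none", location = "CSF", idh_status = "unknown",
    recurrent = FALSE, batch = "batch1", heme = unname(heme),
    perfusate_excluded = "", stringsAsFactors = FALSE)

  truth <- list(
    metabolites = data.frame(metabolite = met_ids, class = classes,
                             effect_E = eff[, "E"], effect_NE = eff[, "NE"],
                             effect_B = eff[, "B"], mu = mu,
                             stringsAsFactors = FALSE),
    cases = data.frame(case_id = sprintf("case%02d", seq_len(n_cases)),
                       idh_status = idh, stringsAsFactors = FALSE),
    csf = data.frame(sample_id = csf_ids,
                     contamination = unname(contamination),
                     stringsAsFactors = FALSE),
    config = cfg)

  list(matrix = peak_matrix(vals, layer = "raw"),
       annotation = as_sample_annotation(rbind(annotation, csf_annotation)),
       csf = peak_matrix(csf_vals, layer = "raw"),
       heme = heme,
       truth = truth)
}

# Intensity-dependent (logistic in log-abundance) or uniform missingness,
# calibrated so the overall missing fraction matches cfg$missing_rate while
# preferentially hitting low values.
apply_missingness <- function(vals, cfg) {
  rate <- cfg$missing_rate
  if (rate <= 0) return(vals)
  lv <- log(vals)
  if (identical(cfg$missing_mechanism, "intensity_dependent")) {
    z <- (lv - mean(lv)) / stats::sd(lv)
    w <- stats::plogis(-2 * z)              # low abundance -> high weight
    prob <- pmin(1, w * rate / mean(w))
  } else {
    prob <- matrix(rate, nrow(vals), ncol(vals))
  }
  drop <- matrix(stats::runif(length(vals)) < prob, nrow(vals))
  # never blank out an entire metabolite
  for (i in which(rowSums(!drop) == 0L)) drop[i, 1L] <- FALSE
  vals[drop] <- NA_real_
  vals
}

#' Deterministic miniature test cohort
#'
#' A fixed-seed instance of [generate_cohort()] small enough to exercise
#' every pipeline stage quickly: 9 cases carrying an E catheter (7 of them
#' with all three locations), 200 metabolites, the standard CSF block.
#' Byte-stable across runs.
#'
#' @return the [generate_cohort()] result for the fixture configuration.
#' @export
fixture_small <- function() {
  cfg <- default_generator_config(seed = 20240101L)
  generate_cohort(cfg)
}
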