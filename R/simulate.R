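# Synthetic CyTOF cohort generator.
#
# Emulates the statistical structure the pipeline assumes: a whole-blood
# leukocyte mixture (neutrophils, T, B, NK, monocytes, cDC, pDC, basophils)
# with canonical marker signatures on the arcsinh scale, two planted
# disease-associated subpopulations with known per-sample ground truth
# (a CD11b-low CD16-high neutrophil subset whose within-neutrophil fraction
# rises with disease duration, and a CD11a-high Granzyme-B-high T-cell
# subset present in a random subset of patients and inversely linked to
# DAS28), per-sample batch shifts, marker zero inflation, and optional
# TLR-stimulated sample mates in which monocyte/cDC/pDC cytokine channels
# shift upward for a responder fraction of cells.

table1_fixture <- function() {
  tibble::tibble(
    patient = paste0("PAT-", 1:9),
    group = "RA",
    age_range = c("36-40", "80-85", "40-45", "71-75", "81-85", "56-60",
                  "56-60", "50-55", "56-70"),
    treatments = c("Prednisone", "Tocilizumab",
                   "Nonsteroidal anti-inflammatory drugs", "Tocilizumab",
                   "Etanercept, Methotrexate", "Methotrexate",
                   "Methotrexate Hydroxychloroquine, Salazopyrine, Prednisone",
                   "Rituximab, Methotrexate", "Rituximab, Methotrexate"),
    duration_months = c(28L, 172L, 124L, 76L, 136L, 76L, 148L, 244L, 304L),
    das28 = c(2.70, 6.85, 5.49, 3.49, 2.68, 1.89, 2.58, 2.97, 2.56),
    anti_ccp = c("Yes", "Yes", "Yes", "Yes", "Yes", NA, "Yes", "Yes", "Yes"),
    erosion = c("Yes", "Yes", "Yes", "Yes", "Yes", NA, "No", "Yes", "Yes"),
    rf = c("Yes", "Yes", "Yes", "No", NA, NA, "Yes", "Yes", "Yes")
  )
}

#' Simulate (or fix) the clinical covariate table of an RA cohort
#'
#' In fixture mode (the default when `n_ra = 9`) the verbatim reference
#' patient table is returned: disease durations 28-304 months, DAS28
#' 1.89-6.85, and treatment/serology flags. In sampled mode, durations are
#' drawn uniformly over \[28, 304\] months, DAS28 uniformly over
#' \[1.89, 6.85\], and categorical fields from the empirical frequencies of
#' the fixture.
#'
#' @param n_ra Number of RA patients (>= 1).
#' @param seed Integer seed used in sampled mode.
#' @param fixture Return the verbatim 9-patient table (requires `n_ra = 9`).
#' @return A tibble with columns `patient`, `group`, `age_range`,
#'   `treatments`, `duration_months`, `das28`, `anti_ccp`, `erosion`, `rf`.
#' @export
simulate_clinical <- function(n_ra = 9, seed = 1L, fixture = (n_ra == 9)) {
  if (n_ra < 1) abort("n_ra must be >= 1")
  fix <- table1_fixture()
  if (fixture) {
    if (n_ra != 9) abort("fixture mode provides exactly 9 RA patients")
    return(fix)
  }
  set.seed(derive_seed(seed, 17L))
  tibble::tibble(
    patient = sprintf("PAT-%02d", seq_len(n_ra)),
    group = "RA",
    age_range = sample(fix$age_range, n_ra, replace = TRUE),
    treatments = sample(fix$treatments, n_ra, replace = TRUE),
    duration_months = as.integer(round(runif(n_ra, 28, 304))),
    das28 = round(runif(n_ra, 1.89, 6.85), 2),
    anti_ccp = sample(fix$anti_ccp, n_ra, replace = TRUE),
    erosion = sample(fix$erosion, n_ra, replace = TRUE),
    rf = sample(fix$rf, n_ra, replace = TRUE)
  )
}

# Marker signatures on the arcsinh scale. Levels: negative ~0.2, background
# ~0.3, low 1.0, medium 2.5-3.5, high 4.0-4.5, very high 6.0. Any marker not
# listed for a population sits at the zero-inflated background mode.
default_population_signatures <- function() {
  sig <- function(population, ...) {
    v <- c(...)
    tibble::tibble(population = population, marker = names(v), mean = unname(v))
  }
  dplyr::bind_rows(
    sig("neutrophil", CD66 = 4.5, CD16 = 4.0, CD11b = 4.0, CD32 = 3.0,
        CD15 = 4.0, HLADR = 0.2),
    sig("neutrophil_cd11b_low", CD66 = 4.5, CD16 = 6.0, CD11b = 1.0,
        CD32 = 3.0, CD15 = 4.0, HLADR = 0.2),
    sig("t_cell", CD3 = 4.5, CD11a = 2.5, CD28 = 3.0, CD45 = 4.0),
    sig("tcell_cd11a_gzb", CD3 = 4.5, CD11a = 6.0, GranzymeB = 6.0,
        CCR5 = 3.5, CD28 = 3.0, CD45 = 4.0),
    sig("b_cell", CD19 = 4.5, CD20 = 4.0, HLADR = 3.5, CD45 = 4.0),
    sig("nk", CD16 = 4.2, GranzymeB = 3.5, Perforin = 3.5, CD56 = 4.0,
        CD3 = 0.2, CD66 = 0.2, CD45 = 4.0),
    sig("monocyte", CD14 = 4.5, HLADR = 4.0, CD11b = 3.5, CD11c = 3.0,
        CD64 = 3.5, CD86 = 2.5, CD36 = 3.5, CD45 = 4.0),
    sig("cdc", CD11c = 4.5, HLADR = 4.5, CD86 = 3.0, CD14 = 0.3,
        CD45 = 4.0),
    sig("pdc", CD123 = 4.5, HLADR = 4.0, CD45 = 4.0),
    sig("basophil", CD123 = 4.2, HLADR = 0.2, CD45 = 3.5)
  )
}

# Blood-norm baseline abundances; subpopulations are carved out of their
# parent at simulation time, so only major populations appear here.
default_base_fractions <- function() {
  c(neutrophil = 0.55, t_cell = 0.25, monocyte = 0.08, b_cell = 0.05,
    nk = 0.05, cdc = 0.01, pdc = 0.005, basophil = 0.005)
}

# Fine population label -> major cell-type label (subpopulations map to
# their parent for annotation-accuracy scoring).
population_celltype <- function(population) {
  map <- c(neutrophil = "neutrophil", neutrophil_cd11b_low = "neutrophil",
           t_cell = "t_cell", tcell_cd11a_gzb = "t_cell", b_cell = "b_cell",
           nk = "nk", monocyte = "monocyte", cdc = "cdc", pdc = "pdc",
           basophil = "basophil")
  unname(map[population])
}

#' Cohort simulation settings
#'
#' Bundles every parameter of the synthetic cohort: sample sizes (9 RA + 5
#' healthy by default), cells per sample, population signatures and
#' abundances, the logit-scale covariate links that plant the two
#' disease-associated subpopulations, noise and zero-inflation levels, batch
#' effects, and the stimulation-arm response model.
#'
#' @param n_ra,n_healthy Cohort sizes.
#' @param cells_per_sample Cells simulated per sample.
#' @param noise_sd Gaussian marker noise SD on the arcsinh scale.
#' @param zero_p_background,zero_p_signature Zero-inflation probabilities for
#'   background and signature markers.
#' @param background_mean Arcsinh-scale mode of unexpressed markers.
#' @param batch_sd SD of the per-sample batch shift added to every marker.
#' @param base_fractions Named major-population fractions (must sum to 1).
#' @param signatures Long tibble `population, marker, mean` of signature
#'   modes.
#' @param links Named list of subpopulation links; each link carves a
#'   subpopulation out of `parent` with within-parent fraction
#'   `plogis(intercept + slope * (covariate - center) / scale + noise)` for
#'   RA samples and `healthy_fraction` for healthy ones. `presence_prob`,
#'   when < 1, makes the subpopulation bimodally present across patients.
#' @param stimulated Also generate TLR-stimulated mates for every sample.
#' @param responder_fraction Fraction of monocyte/cDC/pDC cells whose
#'   cytokine channels respond under stimulation.
#' @param stim_shift_sds Upward cytokine shift for responders, in units of
#'   `noise_sd`.
#' @param cofactor Arcsinh cofactor the simulated scale corresponds to.
#' @param seed Master seed; all per-sample seeds derive from it.
#' @param fixture_clinical Use the verbatim 9-patient clinical table when
#'   `n_ra = 9`.
#' @return A list of settings (class `cohort_spec`).
#' @export
cohort_spec <- function(n_ra = 9, n_healthy = 5, cells_per_sample = 10000,
                        noise_sd = 0.35, zero_p_background = 0.4,
                        zero_p_signature = 0.02, background_mean = 0.3,
                        batch_sd = 0.05,
                        base_fractions = default_base_fractions(),
                        signatures = default_population_signatures(),
                        links = NULL, stimulated = FALSE,
                        responder_fraction = 0.4, stim_shift_sds = 4,
                        cofactor = 5, seed = 42L,
                        fixture_clinical = (n_ra == 9)) {
  if (abs(sum(base_fractions) - 1) > 1e-9) {
    abort("base population fractions must sum to 1")
  }
  if (noise_sd <= 0) abort("noise_sd must be positive")
  links <- links %||% list(
    neutrophil_cd11b_low = list(
      subpop = "neutrophil_cd11b_low", parent = "neutrophil",
      covariate = "duration_months", slope = 0.6, intercept = qlogis(0.30),
      center = 150, scale = 80, noise_sd = 0.2,
      healthy_fraction = 0.092, presence_prob = 1),
    tcell_cd11a_gzb = list(
      subpop = "tcell_cd11a_gzb", parent = "t_cell",
      covariate = "das28", slope = -0.5, intercept = qlogis(0.15),
      center = 3.5, scale = 1.5, noise_sd = 0.2,
      healthy_fraction = 0.03, presence_prob = 5 / 9)
  )
  for (lk in links) {
    if (!lk$parent %in% names(base_fractions)) {
      abort(paste0("link parent '", lk$parent, "' is not a population"))
    }
  }
  structure(list(
    n_ra = n_ra, n_healthy = n_healthy, cells_per_sample = cells_per_sample,
    noise_sd = noise_sd, zero_p_background = zero_p_background,
    zero_p_signature = zero_p_signature, background_mean = background_mean,
    batch_sd = batch_sd, base_fractions = base_fractions,
    signatures = signatures, links = links, stimulated = stimulated,
    responder_fraction = responder_fraction, stim_shift_sds = stim_shift_sds,
    responder_populations = c("monocyte", "cdc", "pdc"),
    cofactor = cofactor, seed = as.integer(seed),
    fixture_clinical = fixture_clinical
  ), class = "cohort_spec")
}

# Per-sample planted within-parent subpopulation fractions from the
# logit-scale covariate links.
planted_fractions <- function(spec, clinical, seed) {
  set.seed(derive_seed(seed, 29L))
  out <- list()
  for (nm in names(spec$links)) {
    lk <- spec$links[[nm]]
    frac <- numeric(nrow(clinical))
    present <- logical(nrow(clinical))
    for (i in seq_len(nrow(clinical))) {
      if (clinical$group[i] != "RA") {
        frac[i] <- lk$healthy_fraction
        present[i] <- lk$healthy_fraction > 0
      } else {
        present[i] <- runif(1) < lk$presence_prob
        if (!present[i]) { frac[i] <- 0; next }
        cov <- clinical[[lk$covariate]][i]
        if (is.null(cov) || is.na(cov)) {
          abort(paste0("unknown or missing covariate '", lk$covariate, "'"))
        }
        z <- (cov - lk$center) / lk$scale
        frac[i] <- plogis(lk$intercept + lk$slope * z +
                            rnorm(1, 0, lk$noise_sd))
      }
    }
    out[[nm]] <- tibble::tibble(
      patient = clinical$patient, subpopulation = nm, parent = lk$parent,
      present = present, planted_fraction = frac)
  }
  dplyr::bind_rows(out)
}

# Draw truncated-at-zero Gaussian marker values for one population block.
draw_population_block <- function(n, markers, spec, population, batch_shift,
                                  condition) {
  mu <- setNames(rep(spec$background_mean, length(markers)), markers)
  zp <- setNames(rep(spec$zero_p_background, length(markers)), markers)
  sig <- spec$signatures[spec$signatures$population == population, ]
  mu[sig$marker] <- sig$mean
  zp[sig$marker] <- spec$zero_p_signature
  stim_markers <- character(0)
  if (condition == "TLR_stimulated" &&
      population_celltype(population) %in% spec$responder_populations) {
    stim_markers <- intersect(c("MIP1b", "TNFa", "IL8"), markers)
  }
  mat <- matrix(0, nrow = n, ncol = length(markers),
                dimnames = list(NULL, markers))
  responder <- if (length(stim_markers) > 0) {
    runif(n) < spec$responder_fraction
  } else rep(FALSE, n)
  for (j in seq_along(markers)) {
    m <- markers[j]
    mean_j <- rep(mu[m] + batch_shift[j], n)
    if (m %in% stim_markers) {
      mean_j[responder] <- mean_j[responder] +
        spec$stim_shift_sds * spec$noise_sd
    }
    x <- rnorm(n, mean_j, spec$noise_sd)
    # truncate at zero by redrawing (keeps exact zeros reserved for the
    # zero-inflation mask)
    bad <- which(x < 0)
    tries <- 0
    while (length(bad) > 0 && tries < 50) {
      x[bad] <- rnorm(length(bad), mean_j[bad], spec$noise_sd)
      bad <- bad[x[bad] < 0]
      tries <- tries + 1
    }
    if (length(bad) > 0) x[bad] <- 0.001
    zeroed <- runif(n) < zp[m]
    # responder cytokine production overrides zero inflation
    if (m %in% stim_markers) zeroed <- zeroed & !responder
    x[zeroed] <- 0
    mat[, j] <- x
  }
  mat
}

#' Simulate one whole-blood sample
#'
#' Draws per-cell population labels multinomially from the base fractions
#' (with planted subpopulations carved out of their parent at the supplied
#' within-parent fraction), then marker values from truncated Gaussians on
#' the arcsinh scale with marker-level zero inflation and a per-sample batch
#' shift. Under TLR stimulation a responder fraction of monocyte/cDC/pDC
#' cells shifts its cytokine channels upward.
#'
#' @param spec A [cohort_spec()].
#' @param patient One row of the clinical table.
#' @param condition `"unstimulated"` or `"TLR_stimulated"`.
#' @param seed Integer seed.
#' @param planted Optional tibble from `planted_fractions()`; computed from
#'   the patient row when absent.
#' @return A list with `events` (tibble of cells x markers with
#'   `.sample_id`, `.condition`, `.group`, `.population` columns) and
#'   `truth` (per-subpopulation planted fractions used).
#' @export
simulate_sample <- function(spec, patient, condition = "unstimulated",
                            seed = 1L, planted = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  condition <- match.arg(condition, c("unstimulated", "TLR_stimulated"))
  if (is.null(planted)) planted <- planted_fractions(spec, patient, seed)
  planted <- planted[planted$patient == patient$patient, ]
  markers <- default_panel()$marker
  n <- spec$cells_per_sample
  set.seed(derive_seed(seed, 31L))
  labels <- sample(names(spec$base_fractions), n, replace = TRUE,
                   prob = spec$base_fractions)
  for (i in seq_len(nrow(planted))) {
    idx <- which(labels == planted$parent[i])
    carve <- idx[runif(length(idx)) < planted$planted_fraction[i]]
    labels[carve] <- planted$subpopulation[i]
  }
  batch_shift <- rnorm(length(markers), 0, spec$batch_sd)
  mat <- matrix(0, nrow = n, ncol = length(markers),
                dimnames = list(NULL, markers))
  for (pop in unique(labels)) {
    idx <- which(labels == pop)
    mat[idx, ] <- draw_population_block(length(idx), markers, spec, pop,
                                        batch_shift, condition)
  }
  events <- tibble::as_tibble(mat)
  events$.sample_id <- if (condition == "TLR_stimulated") {
    paste0(patient$patient, "_stim")
  } else patient$patient
  events$.patient <- patient$patient
  events$.condition <- condition
  events$.group <- patient$group
  events$.population <- labels
  events <- set_events_transform(events, "arcsinh", spec$cofactor)
  list(events = events, truth = planted)
}

#' Simulate a multi-sample cohort with planted ground truth
#'
#' Generates the full study layout: `n_ra` RA and `n_healthy` healthy
#' unstimulated samples (plus TLR-stimulated mates when
#' `spec$stimulated = TRUE`), a clinical covariate table, and per-sample
#' ground truth for the planted subpopulations. Deterministic under
#' `spec$seed`.
#'
#' @param spec A [cohort_spec()].
#' @return A `cytof_cohort` list: `samples` (named list of event tables),
#'   `clinical`, `truth` (per sample x subpopulation planted fractions),
#'   `panel`, and `spec`.
#' @export
simulate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  clin_ra <- simulate_clinical(spec$n_ra, seed = spec$seed,
                               fixture = spec$fixture_clinical)
  clin_hd <- tibble::tibble(
    patient = sprintf("HD-%d", seq_len(spec$n_healthy)), group = "healthy",
    age_range = NA_character_, treatments = NA_character_,
    duration_months = NA_integer_, das28 = NA_real_,
    anti_ccp = NA_character_, erosion = NA_character_, rf = NA_character_)
  clinical <- dplyr::bind_rows(clin_ra, clin_hd)
  planted <- planted_fractions(spec, clinical, spec$seed)
  conditions <- if (spec$stimulated) {
    c("unstimulated", "TLR_stimulated")
  } else "unstimulated"
  samples <- list()
  for (i in seq_len(nrow(clinical))) {
    for (cond in conditions) {
      s <- simulate_sample(spec, clinical[i, ], cond,
                           seed = derive_seed(spec$seed,
                                              100L * i + (cond == "TLR_stimulated")),
                           planted = planted)
      nm <- if (cond == "unstimulated") clinical$patient[i] else
        paste0(clinical$patient[i], "_stim")
      samples[[nm]] <- s$events
    }
  }
  truth <- dplyr::left_join(planted,
                            clinical[, c("patient", "group")], by = "patient")
  structure(list(samples = samples, clinical = clinical, truth = truth,
                 panel = default_panel(), spec = spec),
            class = "cytof_cohort")
}

#' @export
print.cytof_cohort <- function(x, ...) {
  cat("<cytof_cohort> ", length(x$samples), " samples (",
      sum(x$clinical$group == "RA"), " RA / ",
      sum(x$clinical$group == "healthy"), " healthy), ",
      nrow(x$samples[[1]]), " cells/sample, ",
      nrow(x$panel), " markers\n", sep = "")
  invisible(x)
}

#' Export a simulated cohort to disk
#'
#' Writes one file per sample (FCS or CSV), a ground-truth sidecar
#' (`<sample>_truth.csv`: cell index and population label), and the clinical
#' table (`clinical.csv`).
#'
#' @param cohort A `cytof_cohort`.
#' @param dir Output directory (created if needed).
#' @param format `"fcs"` or `"csv"`.
#' @return `dir`, invisibly.
#' @export
export_cohort <- function(cohort, dir, format = c("csv", "fcs")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(cohort$samples)) {
    ev <- cohort$samples[[nm]]
    write_events(ev, file.path(dir, paste0(nm, ".", format)), format)
    write.csv(data.frame(cell = seq_len(nrow(ev)),
                         population = ev$.population),
              file.path(dir, paste0(nm, "_truth.csv")), row.names = FALSE)
  }
  write.csv(cohort$clinical, file.path(dir, "clinical.csv"),
            row.names = FALSE)
  invisible(dir)
}
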