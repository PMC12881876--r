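# Deterministic 69-landmark template skull (left side digitized, arbitrary
# length unit ~ skull length). Fixed choices:
#   - landmarks 1..3  : midsagittal plane points (y = 0)
#   - landmarks 20/23/27: skull-roof triple defining the oblique coronal plane
#     z = roof_z - y * tan(tilt)  (plane normal in the y-z plane)
#   - remaining landmarks: fixed quasi-random points on the left hemi-dome
skull_template <- function(tilt = 0.3, roof_z = 0.6) {
  lm <- matrix(NA_real_, 69, 3)
  lm[1, ] <- c(0.05, 0, 0.25)
  lm[2, ] <- c(0.50, 0, 0.62)
  lm[3, ] <- c(0.95, 0, 0.30)
  lm[20, ] <- c(0.45, 0, roof_z)
  lm[23, ] <- c(0.30, -0.40, roof_z + 0.40 * tan(tilt))
  lm[27, ] <- c(0.55, -0.35, roof_z + 0.35 * tan(tilt))
  free <- setdiff(1:69, c(1:3, 20, 23, 27))
  # low-discrepancy angles spread points over the left hemi-dome
  i <- seq_along(free)
  u <- (i * 0.6180339887) %% 1
  v <- (i * 0.7548776662) %% 1
  phi <- pi * (0.15 + 0.7 * u) # polar angle from the x axis
  psi <- pi * (0.05 + 0.9 * v) # azimuth, left side only (y <= 0)
  lm[free, ] <- cbind(
    0.5 + 0.45 * cos(phi),
    -0.45 * sin(phi) * sin(psi),
    0.30 + 0.30 * sin(phi) * cos(psi)^2
  )
  lm
}

#' Synthetic study design
#'
#' The sampling frame of the synthetic ontogenetic dataset: number of species,
#' developmental stages with their target relative ages (percent of adult
#' centroid size), specimens per species-stage cell, and the generative
#' regimes for each suture.
#'
#' @param n_species number of species (default 22).
#' @param stages named vector of stage -> target relative-age fraction.
#' @param n_per_stage specimens per species and stage (default 1).
#' @param missing_fraction probability that a free landmark is recorded as
#'   missing (default 0).
#' @param coronal_tilt oblique-plane tilt in radians (default 0.3).
#' @param clade_effect multiplicative amplitude offset for marsupials
#'   (default 0: no clade difference, matching the null the pipeline is
#'   expected to recover).
#' @param regimes named list suture -> age-profile name.
#' @param adult_size_mean,adult_size_sdlog lognormal parameters of adult
#'   centroid size across species.
#' @return a `study_design` list.
#' @export
study_design <- function(n_species = 22L,
                         stages = c(foetal = 0.30, infant = 0.55, subadult = 0.80, adult = 1.00),
                         n_per_stage = 1L, missing_fraction = 0,
                         coronal_tilt = 0.3, clade_effect = 0,
                         regimes = list(
                           interfrontal = "decline", sagittal = "decline",
                           coronal = "late_rise"
                         ),
                         adult_size_mean = 10, adult_size_sdlog = 0.4) {
  structure(
    list(
      n_species = as.integer(n_species), stages = stages,
      n_per_stage = as.integer(n_per_stage),
      missing_fraction = missing_fraction, coronal_tilt = coronal_tilt,
      clade_effect = clade_effect, regimes = regimes,
      adult_size_mean = adult_size_mean, adult_size_sdlog = adult_size_sdlog
    ),
    class = "study_design"
  )
}

# Pure-birth tree over the species with unit depth: a monotreme-like outgroup
# attached at the root, the remaining species from a Yule process whose root
# split also defines the marsupial/placental clade labels.
simulate_tree <- function(species, seed) {
  n <- length(species)
  stopifnot(n >= 3)
  set.seed(derive_seed(seed, "tree"))
  core <- ape::rphylo(n - 1, birth = 1, death = 0)
  depth <- max(ape::node.depth.edgelength(core))
  core$edge.length <- core$edge.length / depth * 0.8
  core_txt <- sub(";$", "", ape::write.tree(core))
  tree <- ape::read.tree(text = paste0("(outgroup:1,", core_txt, ":0.2);"))
  # clade labels from the core root split: smaller side = marsupials
  core_root <- ape::Ntip(core) + 1L
  kids <- core$edge[core$edge[, 1] == core_root, 2]
  side_tips <- lapply(kids, function(k) {
    if (k <= ape::Ntip(core)) core$tip.label[k] else ape::extract.clade(core, k)$tip.label
  })
  marsupial_core <- side_tips[[which.min(lengths(side_tips))]]
  clade <- setNames(rep("Placentalia", n), c("outgroup", core$tip.label))
  clade["outgroup"] <- "Monotremata"
  clade[marsupial_core] <- "Marsupialia"
  # rename tips to the requested species names (outgroup first)
  old <- c("outgroup", core$tip.label)
  tree$tip.label <- species[match(tree$tip.label, old)]
  names(clade) <- species[match(names(clade), old)]
  list(tree = tree, clade = clade)
}

#' Generate one synthetic specimen
#'
#' One skull: the 69-landmark template with species-specific shape offsets,
#' mild ontogenetic (allometric) elongation, isotropic scaling to the
#' specimen's centroid-size target, plus the three suture curves placed on the
#' skull roof. Optionally masks free landmarks as missing.
#'
#' @param design a [study_design()].
#' @param species_idx species index (drives the species effects).
#' @param stage stage name (must be in `names(design$stages)`).
#' @param seed top-level study seed; all specimen randomness derives from it.
#' @param replicate replicate number within the species-stage cell.
#' @param clade clade label of the species (the design's `clade_effect`, when
#'   non-zero, scales marsupial coronal amplitude).
#' @return a list with `landmarks` (69 x 3), `curves` (named list of 3
#'   matrices) and `meta` (one-row tibble).
#' @export
generate_specimen <- function(design, species_idx, stage, seed = 1L, replicate = 1L,
                              clade = "Placentalia") {
  stopifnot(stage %in% names(design$stages))
  sp_name <- sprintf("species_%02d", species_idx)
  sp_seed <- derive_seed(seed, paste0("species", species_idx))
  set.seed(sp_seed)
  shape_offset <- matrix(rnorm(69 * 3, 0, 0.010), 69, 3)
  shape_offset[c(1, 2, 3), 2] <- 0 # keep midline points midsagittal
  adult_size <- design$adult_size_mean * exp(rnorm(1, 0, design$adult_size_sdlog))
  amp_factor <- exp(rnorm(3, 0, 0.22)) # per suture
  wav_factor <- exp(rnorm(3, 0, 0.10))
  names(amp_factor) <- names(wav_factor) <- SUTURE_NAMES

  spec_key <- paste("spec", species_idx, stage, replicate, sep = "_")
  spec_seed <- derive_seed(seed, spec_key)
  set.seed(spec_seed)
  age_target <- design$stages[[stage]]
  rel_age <- if (stage == "adult" && replicate == 1L) {
    100
  } else {
    100 * age_target * exp(rnorm(1, 0, 0.06))
  }
  scale <- adult_size * rel_age / 100

  lm <- skull_template(tilt = design$coronal_tilt) + shape_offset
  elong <- 1 + 0.12 * (rel_age / 100 - 1) # young skulls relatively shorter
  lm[, 1] <- 0.5 + (lm[, 1] - 0.5) * elong

  anchors <- list(
    interfrontal = list(origin = c(0.08, 0, 0.60), len = 0.36),
    sagittal = list(origin = c(0.56, 0, 0.60), len = 0.36),
    coronal = list(origin = c(0.48, 0, 0.62), len = 0.50)
  )
  curves <- lapply(SUTURE_NAMES, function(su) {
    pars <- suture_params(su,
      age_profile = design$regimes[[su]],
      tilt = design$coronal_tilt
    )
    af <- amp_factor[[su]]
    if (su == "coronal" && design$clade_effect != 0 && clade == "Marsupialia") {
      af <- af * (1 + design$clade_effect)
    }
    raw <- generate_suture_curve(pars,
      relative_age = rel_age,
      seed = derive_seed(spec_seed, su),
      amplitude_factor = af, waves_factor = wav_factor[[su]]
    )
    an <- anchors[[su]]
    pts <- sweep(raw * an$len, 2, an$origin, `+`)
    pts[, 1] <- 0.5 + (pts[, 1] - 0.5) * elong
    pts
  })
  names(curves) <- SUTURE_NAMES

  set.seed(derive_seed(spec_seed, "missing"))
  if (design$missing_fraction > 0) {
    free <- setdiff(1:69, c(1:3, 20, 23, 27))
    miss <- free[runif(length(free)) < design$missing_fraction]
    lm[miss, ] <- NA_real_
  }
  lm_scaled <- lm * scale
  curves <- lapply(curves, function(p) p * scale)
  list(
    landmarks = lm_scaled, curves = curves,
    meta = tibble::tibble(
      specimen_id = spec_key, species = sp_name, age_category = stage,
      replicate = replicate, true_relative_age = rel_age,
      true_adult_size = adult_size
    )
  )
}

#' Generate a full synthetic study
#'
#' The complete synthetic dataset the pipeline is tested on: landmark and
#' curve geometry for every specimen, metadata (clade from the simulated tree,
#' developmental mode, diet), a unit-depth pure-birth phylogeny over the
#' species, and a ground-truth table of the generative parameters for
#' recovery testing.
#'
#' @param design a [study_design()].
#' @param seed top-level seed; every random sub-artifact derives its own
#'   stream from it.
#' @return a list with `study` (a `suture_study` tibble), `tree`
#'   ([ape::phylo]) and `truth` (tibble of generative values per specimen).
#' @export
generate_study <- function(design = study_design(), seed = 1L) {
  species <- sprintf("species_%02d", seq_len(design$n_species))
  tr <- simulate_tree(species, seed)
  modes <- c("super_altricial", "altricial", "semi_altricial", "semi_precocial", "precocial")
  diets <- c("insectivore", "carnivore", "herbivore", "omnivore", "frugivore")
  specs <- list()
  for (i in seq_len(design$n_species)) {
    for (stage in names(design$stages)) {
      for (r in seq_len(design$n_per_stage)) {
        specs[[length(specs) + 1]] <- generate_specimen(
          design, i, stage, seed, r,
          clade = unname(tr$clade[species[i]])
        )
      }
    }
  }
  meta <- purrr::map_dfr(specs, "meta")
  meta$clade <- unname(tr$clade[meta$species])
  sp_idx <- as.integer(sub("species_", "", meta$species))
  meta$developmental_mode <- ifelse(
    meta$clade %in% c("Marsupialia", "Monotremata"), "super_altricial",
    modes[2 + (sp_idx %% 4)]
  )
  meta$diet <- diets[1 + (sp_idx %% length(diets))]
  study <- suture_study(
    meta = dplyr::select(meta, -"true_relative_age", -"true_adult_size"),
    landmarks = lapply(specs, `[[`, "landmarks"),
    curves = lapply(specs, `[[`, "curves"),
    midline = c(1L, 2L, 3L)
  )
  truth <- dplyr::select(
    meta, "specimen_id", "species", "clade", "age_category",
    "true_relative_age", "true_adult_size"
  )
  list(study = study, tree = tr$tree, truth = truth, design = design, seed = seed)
}
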