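# Synthetic single-cell Raman spectra with taxon- and growth-stage-specific
# structure. The generator emulates a pure-culture reference library: many
# strains nested in genera and phyla, four growth stages, >100 spectra per
# strain per stage, Gaussian band signatures, polynomial baseline drift and
# additive noise, plus an "environmental" perturbation mode emulating the
# signal degradation introduced by Raman-FISH processing.

#' Configuration for the synthetic SCRS generator
#'
#' Defaults emulate the full-scale reference library the package's analysis
#' pipeline is designed for: 36 strains in 16 genera and 4 phyla, four growth
#' stages (Exp, S1, S2, S3), 120 spectra per strain per stage (17,280 cells),
#' a 600-1800 cm^-1 fingerprint-region grid.
#'
#' @param n_strains Number of strains.
#' @param genus_partition Integer vector of strains per genus; must sum to
#'   `n_strains`.
#' @param n_phyla Number of phyla the genera are grouped into.
#' @param spectra_per_strain_per_stage Spectra simulated per strain per stage.
#' @param grid List with `start`, `stop` (cm^-1) and `n_channels`.
#' @param noise_sd Standard deviation of additive i.i.d. Gaussian noise (a.u.).
#' @param baseline List with `degree` (max polynomial order, <= 3) and
#'   `coef_range` (coefficients drawn uniformly from +/- this range). Set
#'   `coef_range = 0` for baseline-free spectra.
#' @param stage_separation Effect-size scalar for growth-stage signal
#'   (amplitude modulation of shared bands plus stage marker bands). 0 means
#'   stages are statistically indistinguishable.
#' @param taxon_separation Effect-size scalar for taxon signal (genus- and
#'   strain-specific bands). 0 means all strains share identical band sets.
#' @param amp_jitter_sd Baseline log-normal cell-to-cell amplitude jitter. The
#'   per-stage jitter is this value scaled by `stage_jitter_scale`.
#' @param stage_jitter_scale Named multipliers of `amp_jitter_sd` per stage.
#'   The default makes S1 the most internally consistent stage, mirroring the
#'   early-stationary-phase consistency the pipeline is designed to exploit.
#' @param environmental_mode Enable [generate_environmental_testset()].
#' @param env_strength Perturbation strength for environmental mode: scales an
#'   added broad fluorescence hump and extra amplitude jitter. 0 reproduces
#'   [generate_dataset()] output exactly.
#' @param seed Master seed; all substreams derive from it deterministically.
#'
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_strains = 36L,
                             genus_partition = c(4L, 3L, 3L, rep(2L, 13L)),
                             n_phyla = 4L,
                             spectra_per_strain_per_stage = 120L,
                             grid = list(start = 600, stop = 1800, n_channels = 900L),
                             noise_sd = 0.02,
                             baseline = list(degree = 3L, coef_range = 0.15),
                             stage_separation = 1,
                             taxon_separation = 1,
                             amp_jitter_sd = 0.08,
                             stage_jitter_scale = c(Exp = 1, S1 = 0.5, S2 = 1, S3 = 1.5),
                             environmental_mode = FALSE,
                             env_strength = 1,
                             seed = 1L) {
  cfg <- list(n_strains = as.integer(n_strains),
              genus_partition = as.integer(genus_partition),
              n_phyla = as.integer(n_phyla),
              spectra_per_strain_per_stage = as.integer(spectra_per_strain_per_stage),
              grid = grid, noise_sd = noise_sd, baseline = baseline,
              stage_separation = stage_separation,
              taxon_separation = taxon_separation,
              amp_jitter_sd = amp_jitter_sd,
              stage_jitter_scale = stage_jitter_scale,
              environmental_mode = isTRUE(environmental_mode),
              env_strength = env_strength,
              seed = as.integer(seed))
  if (cfg$n_strains < 1L) stop("n_strains must be >= 1")
  if (any(cfg$genus_partition < 1L)) stop("genus_partition entries must be >= 1")
  if (sum(cfg$genus_partition) != cfg$n_strains) {
    stop(sprintf("genus_partition sums to %d but n_strains is %d",
                 sum(cfg$genus_partition), cfg$n_strains))
  }
  if (cfg$n_phyla < 1L || cfg$n_phyla > length(cfg$genus_partition)) {
    stop("n_phyla must be between 1 and the number of genera")
  }
  if (cfg$spectra_per_strain_per_stage < 1L) stop("spectra_per_strain_per_stage must be >= 1")
  with(cfg$grid, {
    if (!(start < stop) || n_channels < 2) stop("invalid grid spec")
  })
  if (cfg$noise_sd < 0) stop("noise_sd must be >= 0")
  if (cfg$stage_separation < 0 || cfg$taxon_separation < 0) {
    stop("separation effect sizes must be >= 0")
  }
  if (!all(STAGE_LEVELS %in% names(cfg$stage_jitter_scale))) {
    stop("stage_jitter_scale must name all four stages")
  }
  class(cfg) <- "synthetic_config"
  cfg
}

config_grid <- function(config) {
  with(config$grid, seq(start, stop, length.out = n_channels))
}

# Evaluate RNG-consuming code under a derived seed, restoring global RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Bands every cell shares regardless of taxon: common biomolecule signatures
# (phenylalanine ring breathing ~1003, nucleic acids ~1095, amide III ~1250,
# CH2 deformation ~1450, amide I ~1660 cm^-1).
backbone_peaks <- function(grid_range) {
  centers <- c(1003, 1095, 1250, 1450, 1660)
  amps <- c(1.0, 0.6, 0.5, 0.8, 0.9)
  keep <- centers >= grid_range[1] & centers <= grid_range[2]
  if (!any(keep)) { # grid excludes fingerprint region: spread synthetic bands
    centers <- seq(grid_range[1], grid_range[2], length.out = 5)[1:5]
    amps <- c(1.0, 0.6, 0.5, 0.8, 0.9)
    keep <- rep(TRUE, 5)
  }
  data.frame(center = centers[keep], width = 12, amplitude = amps[keep])
}

# Stage marker bands (S1/S2/S3) at fixed positions within the grid range;
# exponential phase is the unmarked reference state.
stage_marker_peaks <- function(grid_range, stage_separation) {
  pos <- grid_range[1] + c(0.15, 0.45, 0.75) * diff(grid_range)
  list(
    Exp = data.frame(center = numeric(0), width = numeric(0), amplitude = numeric(0)),
    S1 = data.frame(center = pos[1], width = 15, amplitude = 0.5 * stage_separation),
    S2 = data.frame(center = pos[2], width = 15, amplitude = 0.5 * stage_separation),
    S3 = data.frame(center = pos[3], width = 15, amplitude = 0.5 * stage_separation)
  )
}

random_peaks <- function(n, grid_range, amp_lo, amp_hi, scale) {
  df <- data.frame(
    center = stats::runif(n, grid_range[1] + 0.02 * diff(grid_range),
                          grid_range[2] - 0.02 * diff(grid_range)),
    width = stats::runif(n, 8, 20),
    amplitude = stats::runif(n, amp_lo, amp_hi) * scale
  )
  df[df$amplitude > 0, , drop = FALSE]
}

#' Build the synthetic taxonomy: one band profile per strain
#'
#' Strains within a genus share genus-level bands, so genus structure exists
#' for downstream genus-level tasks; each strain adds strain-specific bands
#' whose amplitudes scale with `taxon_separation`. The first two strains of
#' the first multi-strain genus are built as a designated "overlapping pair"
#' (nearly identical band sets) emulating closely related strains that are
#' hard to distinguish; their ids are attached as `attr(, "overlap_pair")`.
#' Stage modulation (multiplier on shared bands plus stage marker bands) is
#' attached per stage for all four stages.
#'
#' @param config A [synthetic_config()].
#' @return List of `taxon_profile` objects, one per strain, with attribute
#'   `overlap_pair`.
#' @export
make_taxonomy <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  grid <- config_grid(config)
  grng <- range(grid)
  n_genera <- length(config$genus_partition)
  genus_ids <- sprintf("genus_%02d", seq_len(n_genera))
  # genera grouped into phyla in contiguous blocks
  phy_of_genus <- sprintf("phylum_%d",
                          sort(rep_len(seq_len(config$n_phyla), n_genera)))
  backbone <- backbone_peaks(grng)
  markers <- stage_marker_peaks(grng, config$stage_separation)

  with_seed(derive_seed(config$seed, 1L), {
    genus_peaks <- lapply(seq_len(n_genera), function(g) {
      random_peaks(5L, grng, 0.3, 0.9, config$taxon_separation)
    })
    # global per-stage multiplicative modulation of the backbone bands
    stage_mult <- lapply(STAGE_LEVELS, function(s) {
      if (s == "Exp") rep(1, nrow(backbone))
      else exp(config$stage_separation * stats::rnorm(nrow(backbone), 0, 0.25))
    })
    names(stage_mult) <- STAGE_LEVELS

    profiles <- list()
    overlap_pair <- character(0)
    first_multi <- which(config$genus_partition >= 2L)[1]  # NA if none
    k <- 0L
    for (g in seq_len(n_genera)) {
      n_in_genus <- config$genus_partition[g]
      shared_strain_peaks <- if (n_in_genus >= 2L) {
        random_peaks(3L, grng, 0.2, 0.6, config$taxon_separation)
      } else NULL
      for (j in seq_len(n_in_genus)) {
        k <- k + 1L
        strain_id <- sprintf("%s_s%d", genus_ids[g], j)
        is_overlap <- !is.na(first_multi) && g == first_multi && j <= 2L
        strain_peaks <- if (is_overlap) {
          # overlapping pair: shared bands plus one faint discriminating band
          overlap_pair <- c(overlap_pair, strain_id)
          rbind(shared_strain_peaks,
                random_peaks(1L, grng, 0.12, 0.18, config$taxon_separation))
        } else {
          random_peaks(3L, grng, 0.2, 0.6, config$taxon_separation)
        }
        base_peaks <- rbind(backbone, genus_peaks[[g]], strain_peaks)
        rownames(base_peaks) <- NULL
        n_mod <- nrow(base_peaks)
        stage_modulation <- lapply(STAGE_LEVELS, function(s) {
          mult <- rep(1, n_mod)
          mult[seq_len(nrow(backbone))] <- stage_mult[[s]]
          list(mult = mult, extra = markers[[s]])
        })
        names(stage_modulation) <- STAGE_LEVELS
        profiles[[k]] <- structure(
          list(strain_id = strain_id, genus = genus_ids[g],
               phylum = phy_of_genus[g], base_peaks = base_peaks,
               stage_modulation = stage_modulation),
          class = "taxon_profile")
      }
    }
    attr(profiles, "overlap_pair") <- overlap_pair
    profiles
  })
}

gaussian_bands <- function(grid, centers, widths, amplitudes) {
  if (length(centers) == 0L) return(numeric(length(grid)))
  out <- numeric(length(grid))
  for (i in seq_along(centers)) {
    out <- out + amplitudes[i] * exp(-0.5 * ((grid - centers[i]) / widths[i])^2)
  }
  out
}

# Clean (noise- and baseline-free) mean spectrum of a strain at a stage.
profile_spectrum <- function(profile, stage, grid) {
  bp <- profile$base_peaks
  mod <- profile$stage_modulation[[stage]]
  s <- gaussian_bands(grid, bp$center, bp$width, bp$amplitude * mod$mult)
  ex <- mod$extra
  s + gaussian_bands(grid, ex$center, ex$width, ex$amplitude)
}

random_baseline <- function(grid01, degree, coef_range) {
  if (coef_range <= 0 || degree < 0) return(numeric(length(grid01)))
  coefs <- stats::runif(degree + 1L, -coef_range, coef_range)
  if (degree == 0L) return(rep(coefs[1L], length(grid01)))
  drop(stats::poly(grid01, degree = degree, raw = TRUE,
                   simple = TRUE) %*% coefs[-1L]) + coefs[1L]
}

#' Simulate a labelled SCRS dataset from taxon profiles
#'
#' Each spectrum is the stage-modulated sum of Gaussian bands, multiplied by a
#' per-cell log-normal amplitude jitter, plus a random low-order polynomial
#' baseline and additive Gaussian noise. Sub-seeds are derived per strain x
#' stage, so the output is bit-identical for identical (profiles, config).
#'
#' @param profiles Output of [make_taxonomy()].
#' @param config The same [synthetic_config()].
#' @return An [scrs_dataset] with
#'   `n_strains * 4 * spectra_per_strain_per_stage` rows.
#' @export
generate_dataset <- function(profiles, config) {
  if (length(profiles) == 0L) stop("empty profile list")
  stopifnot(inherits(config, "synthetic_config"))
  grid <- config_grid(config)
  grid01 <- (grid - min(grid)) / diff(range(grid)) * 2 - 1
  m <- config$spectra_per_strain_per_stage
  blocks <- list(); lab <- list(); b <- 0L
  for (si in seq_along(profiles)) {
    pr <- profiles[[si]]
    for (st_i in seq_along(STAGE_LEVELS)) {
      stage <- STAGE_LEVELS[st_i]
      clean <- profile_spectrum(pr, stage, grid)
      jsd <- config$amp_jitter_sd * config$stage_jitter_scale[[stage]]
      b <- b + 1L
      blocks[[b]] <- with_seed(derive_seed(config$seed, 2L, si, st_i), {
        jit <- exp(stats::rnorm(m, 0, jsd))
        x <- outer(jit, clean)
        if (config$baseline$coef_range > 0) {
          for (r in seq_len(m)) {
            x[r, ] <- x[r, ] + random_baseline(grid01, config$baseline$degree,
                                               config$baseline$coef_range)
          }
        }
        if (config$noise_sd > 0) {
          x <- x + matrix(stats::rnorm(m * length(grid), 0, config$noise_sd),
                          nrow = m)
        }
        x
      })
      lab[[b]] <- data.frame(
        cell_id = sprintf("%s_%s_c%04d", pr$strain_id, stage, seq_len(m)),
        strain = pr$strain_id, genus = pr$genus, phylum = pr$phylum,
        stage = stage, stringsAsFactors = FALSE)
    }
  }
  scrs_dataset(grid, do.call(rbind, blocks), do.call(rbind, lab))
}

#' Simulate an environmental test set (Raman-FISH-like perturbation)
#'
#' Uses the same generative model as [generate_dataset()] and then perturbs
#' each spectrum with (i) a broad Gaussian fluorescence hump and (ii) extra
#' log-normal amplitude jitter, both scaled by `env_strength`. This emulates
#' the cellular-structure alteration and background fluorescence introduced
#' when taxonomy labels are acquired via FISH probing. Strength 0 returns the
#' unperturbed dataset bit-for-bit (same seed). Genus and strain labels are
#' retained; growth stage is kept for bookkeeping.
#'
#' @param profiles Output of [make_taxonomy()] (possibly a subset of strains).
#' @param config A [synthetic_config()] with `environmental_mode = TRUE`.
#' @return An [scrs_dataset].
#' @export
generate_environmental_testset <- function(profiles, config) {
  stopifnot(inherits(config, "synthetic_config"))
  if (!config$environmental_mode) {
    stop("environmental_mode is disabled in this config; enable it to ",
         "generate an environmental test set")
  }
  ds <- generate_dataset(profiles, config)
  s <- config$env_strength
  if (s == 0) return(ds)
  grid <- ds$grid
  grng <- range(grid)
  n <- nrow(ds$intensities)
  ints <- with_seed(derive_seed(config$seed, 3L), {
    hump_amp <- s * stats::runif(n, 0.3, 1.2)
    hump_ctr <- stats::runif(n, grng[1], grng[2])
    hump_wid <- stats::runif(n, 0.15, 0.35) * diff(grng)
    jit <- exp(stats::rnorm(n, 0, 0.15 * s))
    x <- ds$intensities
    for (r in seq_len(n)) {
      x[r, ] <- jit[r] * x[r, ] +
        hump_amp[r] * exp(-0.5 * ((grid - hump_ctr[r]) / hump_wid[r])^2)
    }
    x
  })
  scrs_dataset(grid, ints, ds$labels)
}
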