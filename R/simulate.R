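# Synthetic-study generator: annotated follicle sections with planted division
# angles, serial-section ovaries with planted stage counts, and fertility
# records — all seeded, with the ground truth recorded alongside.

#' Specify a division-angle model
#'
#' @param kind `"uniform"` (on \[0, 90\] degrees — the "random" null),
#'   `"folded_normal"` (|Normal(mode, sigma)| folded into \[0, 90\]; with mode
#'   0 and sigma 16.5 the median is ~11.1 degrees, the concentrated wild-type
#'   pattern), or `"point_mass"` (a constant angle).
#' @param mode_deg mode in degrees, in \[0, 90\].
#' @param sigma_deg spread in degrees (> 0; folded_normal only).
#' @return An object of class `angle_model`.
#' @export
angle_model <- function(kind = c("uniform", "folded_normal", "point_mass"),
                        mode_deg = 0, sigma_deg = 16.5) {
  kind <- match.arg(kind)
  if (mode_deg < 0 || mode_deg > 90) validation_error("mode_deg must lie in [0, 90]")
  if (kind == "folded_normal" && sigma_deg <= 0) {
    validation_error("sigma_deg must be > 0 for a folded normal")
  }
  structure(list(kind = kind, mode_deg = mode_deg, sigma_deg = sigma_deg),
            class = "angle_model")
}

#' Draw division angles from an angle model
#'
#' @param model an [angle_model()].
#' @param n number of angles (>= 1).
#' @param seed RNG seed.
#' @return Numeric vector of n angles in \[0, 90\] degrees.
#' @export
sample_angles <- function(model, n, seed = 1729L) {
  if (!inherits(model, "angle_model")) validation_error("model must be an angle_model")
  if (n < 1) validation_error("n must be >= 1")
  withr::with_seed(seed, {
    switch(model$kind,
      uniform = runif(n, 0, 90),
      point_mass = rep(model$mode_deg, n),
      folded_normal = fold_to_quadrant(rnorm(n, model$mode_deg, model$sigma_deg))
    )
  })
}

# fold an angle in degrees into [0, 90]: |a| mod 180, reflected above 90
#' @noRd
fold_to_quadrant <- function(a) {
  a <- abs(a) %% 180
  ifelse(a > 90, 180 - a, a)
}

#' Build a synthetic annotated follicle section with planted angles
#'
#' Places a circular oocyte and a circular basal lamina around it, then one
#' mitotic cell per planted angle at a random azimuth, halfway between oocyte
#' surface and lamina. Landmarks (a 2-point metaphase plate perpendicular to
#' the spindle, or two anaphase chromatid-group centroids placed symmetrically
#' about the cell centre) are constructed so the noiseless division angle
#' equals the planted angle exactly. Optional Gaussian jitter of scale
#' `noise_deg` (degrees-equivalent: landmark s.d. =
#' `separation * tan(noise) / sqrt(2)`, so the induced angular error has
#' roughly that s.d.) is applied to the landmark points — noise propagates
#' through the same geometry code real annotations would use.
#'
#' @param follicle_id identifier.
#' @param true_angles planted angles in degrees, each in \[0, 90\].
#' @param phase_mix probability a cell is annotated as metaphase (else anaphase).
#' @param noise_deg landmark jitter in degrees-equivalent (>= 0).
#' @param seed RNG seed.
#' @param oocyte_radius,lamina_radius section geometry (micrometres).
#' @param n_lamina_vertices polygon resolution of the basal lamina.
#' @return List with `section` (a `gc_section`) and `truth` (data frame
#'   `cell_id, phase, azimuth_deg, true_theta_deg`).
#' @export
build_section <- function(follicle_id, true_angles, phase_mix = 0.5,
                          noise_deg = 0, seed = 1729L,
                          oocyte_radius = 20, lamina_radius = 50,
                          n_lamina_vertices = 64L) {
  if (any(true_angles < 0 | true_angles > 90)) {
    validation_error("planted angles must lie in [0, 90] degrees")
  }
  if (noise_deg < 0) validation_error("noise_deg must be >= 0")
  n <- length(true_angles)
  withr::with_seed(seed, {
    azimuth <- runif(n, 0, 360)
    is_meta <- rbinom(n, 1L, phase_mix) == 1L
    lam_t <- seq(0, 2 * pi, length.out = n_lamina_vertices + 1L)[-(n_lamina_vertices + 1L)]
    lamina <- cbind(x = lamina_radius * cos(lam_t), y = lamina_radius * sin(lam_t))
    half_sep <- 4  # landmark half-separation, micrometres (chromatid masses / plate ends)
    cells <- vector("list", n)
    for (i in seq_len(n)) {
      az <- azimuth[i] * pi / 180
      radial <- c(cos(az), sin(az))
      centre <- radial * (oocyte_radius + lamina_radius) / 2
      sp_ang <- az + true_angles[i] * pi / 180   # spindle direction in the plane
      sp_dir <- c(cos(sp_ang), sin(sp_ang))
      jitter_sd <- if (noise_deg > 0) 2 * half_sep * tan(noise_deg * pi / 180) / sqrt(2) else 0
      jit <- function(p) p + rnorm(2L, 0, jitter_sd)
      cid <- sprintf("%s_c%02d", follicle_id, i)
      if (is_meta[i]) {
        plate_dir <- c(-sp_dir[2L], sp_dir[1L])
        p1 <- centre + half_sep * plate_dir
        p2 <- centre - half_sep * plate_dir
        if (jitter_sd > 0) { p1 <- jit(p1); p2 <- jit(p2) }
        cells[[i]] <- mitotic_cell(cid, centre, "metaphase", landmarks = rbind(p1, p2))
      } else {
        a <- centre - half_sep * sp_dir
        b <- centre + half_sep * sp_dir
        if (jitter_sd > 0) { a <- jit(a); b <- jit(b) }
        cells[[i]] <- mitotic_cell(cid, centre, "anaphase",
                                   landmarks_a = rbind(a), landmarks_b = rbind(b))
      }
    }
    section <- follicle_section(follicle_id, c(0, 0), lamina, cells,
                                oocyte_radius = oocyte_radius, layer_count = 1L)
    truth <- data.frame(
      cell_id = vapply(cells, `[[`, character(1), "cell_id"),
      phase = ifelse(is_meta, "metaphase", "anaphase"),
      azimuth_deg = azimuth,
      true_theta_deg = true_angles,
      stringsAsFactors = FALSE
    )
    list(section = section, truth = truth)
  })
}

#' Configure a synthetic study
#'
#' Defaults reproduce the design of the study this pipeline targets: a
#' wild-type-like group of 41 mitotic cells with concentrated angles (folded
#' normal, mode 0, sigma 16.5 degrees, sample median ~11 degrees) versus a
#' mutant-like group of 31 cells with uniform angles; ovaries of 100 4-um
#' serial sections censused one-in-five with a 5-fold planted reduction of
#' the mutant-like follicle rates; and 5 mating pairs per group with control
#' means 5.6 litters/pair and litter size 7.11 versus mutant-like 5.0 and 4.60.
#'
#' @param seed master seed; per-stage seeds are derived from it.
#' @param groups named list of per-group angle settings, each
#'   `list(model = angle_model(), n_cells =)`.
#' @param cells_per_follicle cells per synthetic follicle section.
#' @param phase_mix metaphase fraction.
#' @param noise_deg landmark jitter (degrees-equivalent).
#' @param census plan: `n_ovaries`, `sections_per_ovary`, `sampling_fraction`,
#'   and `stage_rates` — named list (per group) of per-section Poisson rates
#'   per stage.
#' @param fertility plan: `n_pairs`, named lists `mean_litters`,
#'   `mean_litter_size` per group, `sd_litter_size`, `control`.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed = 1729L,
                       groups = list(
                         wild_type_like = list(model = angle_model("folded_normal", 0, 16.5),
                                               n_cells = 41L),
                         mutant_like = list(model = angle_model("uniform"),
                                            n_cells = 31L)
                       ),
                       cells_per_follicle = 5L,
                       phase_mix = 0.5,
                       noise_deg = 0,
                       census = list(
                         n_ovaries = 4L,
                         sections_per_ovary = 100L,
                         sampling_fraction = 1 / 5,
                         stage_rates = list(
                           wild_type_like = c(primordial = 3.0, primary = 2.5,
                                              secondary = 1.5, antral = 0.75,
                                              preovulatory = 0.4),
                           mutant_like = c(primordial = 3.0, primary = 0.5,
                                           secondary = 0.3, antral = 0.15,
                                           preovulatory = 0.08)
                         )
                       ),
                       fertility = list(
                         n_pairs = 5L,
                         mean_litters = list(wild_type_like = 5.6, mutant_like = 5.0),
                         mean_litter_size = list(wild_type_like = 7.11, mutant_like = 4.60),
                         sd_litter_size = 1.0,
                         control = "wild_type_like"
                       )) {
  if (seed != round(seed)) validation_error("seed must be an integer")
  if (length(groups) < 1L) validation_error("at least one group is required")
  if (cells_per_follicle < 1L) validation_error("cells_per_follicle must be >= 1")
  if (phase_mix < 0 || phase_mix > 1) validation_error("phase_mix must lie in [0, 1]")
  if (noise_deg < 0) validation_error("noise_deg must be >= 0")
  structure(
    list(seed = as.integer(seed), groups = groups,
         cells_per_follicle = as.integer(cells_per_follicle),
         phase_mix = phase_mix, noise_deg = noise_deg,
         census = census, fertility = fertility),
    class = "sim_config"
  )
}

# small deterministic sub-seed derivation, kept below 2^31
#' @noRd
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + 1000003 * k) %% 2147483629)
}

#' Generate a complete synthetic study
#'
#' Emits every input the pipeline consumes: the annotation CSV (planted
#' division angles per group), the census CSV (serial-section follicle
#' observations with planted per-stage rates), the fertility CSV, and
#' `truth.json` recording every planted parameter, the per-cell true angles,
#' and the per-ovary stage counts on the sampled sections (generator
#' bookkeeping, so the census stage can be checked exactly).
#'
#' @param config a [sim_config()].
#' @param out_dir output directory (created if missing).
#' @return Invisibly, a list with the file paths and the truth object.
#' @export
build_study <- function(config = sim_config(), out_dir) {
  if (!inherits(config, "sim_config")) validation_error("config must be a sim_config")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  # --- angle annotations ---------------------------------------------------
  sections <- list()
  angle_truth <- list()
  gi <- 0L
  for (gname in names(config$groups)) {
    gi <- gi + 1L
    g <- config$groups[[gname]]
    angles <- sample_angles(g$model, g$n_cells, seed = derive_seed(config$seed, gi))
    split_idx <- split(seq_along(angles),
                       ceiling(seq_along(angles) / config$cells_per_follicle))
    for (fi in seq_along(split_idx)) {
      fid <- sprintf("%s_f%02d", gname, fi)
      bs <- build_section(fid, angles[split_idx[[fi]]],
                          phase_mix = config$phase_mix,
                          noise_deg = config$noise_deg,
                          seed = derive_seed(config$seed, 100L * gi + fi))
      sections[[fid]] <- bs$section
      tr <- bs$truth
      tr$follicle_id <- fid
      tr$group <- gname
      angle_truth[[fid]] <- tr
    }
  }
  angle_truth <- do.call(rbind, angle_truth)
  rownames(angle_truth) <- NULL
  annotations_path <- file.path(out_dir, "annotations.csv")
  write_annotations(sections, annotations_path)

  # --- census --------------------------------------------------------------
  cz <- config$census
  period <- as.integer(round(1 / cz$sampling_fraction))
  census_rows <- list()
  stage_feature <- list(
    primordial   = list(layer_count = 1L, gc_morphology = "flattened",
                        antral_cavities = "none", diam = 15),
    primary      = list(layer_count = 1L, gc_morphology = "cuboidal",
                        antral_cavities = "none", diam = 22),
    secondary    = list(layer_count = 3L, gc_morphology = "cuboidal",
                        antral_cavities = "none", diam = 40),
    antral       = list(layer_count = 6L, gc_morphology = "cuboidal",
                        antral_cavities = "multiple_small", diam = 60),
    preovulatory = list(layer_count = 8L, gc_morphology = "cuboidal",
                        antral_cavities = "single_large", diam = 70)
  )
  gi <- 0L
  for (gname in names(cz$stage_rates)) {
    gi <- gi + 1L
    rates <- cz$stage_rates[[gname]]
    for (ov in seq_len(cz$n_ovaries)) {
      ovid <- sprintf("%s_ov%d", gname, ov)
      rows <- withr::with_seed(derive_seed(config$seed, 10000L + 100L * gi + ov), {
        out <- list()
        for (sec in seq_len(cz$sections_per_ovary)) {
          for (st in names(rates)) {
            nf <- rpois(1L, rates[[st]])
            if (nf > 0L) {
              sf <- stage_feature[[st]]
              out[[length(out) + 1L]] <- data.frame(
                ovary_id = ovid, section_index = sec,
                follicle_id = sprintf("%s_s%03d_%s_%d", ovid, sec, st, seq_len(nf)),
                layer_count = sf$layer_count, gc_morphology = sf$gc_morphology,
                antral_cavities = sf$antral_cavities,
                oocyte_diameter_um = round(sf$diam * runif(nf, 0.9, 1.1), 2),
                stringsAsFactors = FALSE
              )
            }
          }
        }
        do.call(rbind, out)
      })
      census_rows[[ovid]] <- rows
    }
  }
  census_obs <- do.call(rbind, census_rows)
  rownames(census_obs) <- NULL
  census_path <- file.path(out_dir, "census.csv")
  write.csv(census_obs, census_path, row.names = FALSE, quote = FALSE)

  # planted sampled-section counts (bookkeeping on the generated records)
  sampled <- census_obs[census_obs$section_index %% period == 0, ]
  stage_of <- vapply(seq_len(nrow(sampled)), function(i) {
    classify_follicle(sampled$layer_count[i], sampled$gc_morphology[i],
                      sampled$antral_cavities[i], sampled$oocyte_diameter_um[i])
  }, character(1))
  planted_counts <- as.data.frame.matrix(
    table(sampled$ovary_id, factor(stage_of, levels = FOLLICLE_STAGES))
  )
  planted_counts <- cbind(ovary_id = rownames(planted_counts), planted_counts,
                          stringsAsFactors = FALSE)
  rownames(planted_counts) <- NULL

  # --- fertility -----------------------------------------------------------
  fz <- config$fertility
  fert_rows <- list()
  gi <- 0L
  for (gname in names(fz$mean_litters)) {
    gi <- gi + 1L
    fert_rows[[gname]] <- withr::with_seed(derive_seed(config$seed, 20000L + gi), {
      data.frame(
        group = gname,
        pair_id = sprintf("%s_p%d", gname, seq_len(fz$n_pairs)),
        litters = rpois(fz$n_pairs, fz$mean_litters[[gname]]),
        litter_size = round(pmax(1, rnorm(fz$n_pairs, fz$mean_litter_size[[gname]],
                                          fz$sd_litter_size)), 2),
        stringsAsFactors = FALSE
      )
    })
  }
  fert <- do.call(rbind, fert_rows)
  rownames(fert) <- NULL
  fertility_path <- file.path(out_dir, "fertility.csv")
  write.csv(fert, fertility_path, row.names = FALSE, quote = FALSE)

  # --- truth ---------------------------------------------------------------
  truth <- list(
    seed = config$seed,
    groups = lapply(config$groups, function(g) {
      list(kind = g$model$kind, mode_deg = g$model$mode_deg,
           sigma_deg = g$model$sigma_deg, n_cells = g$n_cells)
    }),
    phase_mix = config$phase_mix,
    noise_deg = config$noise_deg,
    angles = angle_truth,
    census = list(sampling_fraction = cz$sampling_fraction,
                  sections_per_ovary = cz$sections_per_ovary,
                  stage_rates = cz$stage_rates,
                  planted_sampled_counts = planted_counts),
    fertility = fz
  )
  truth_path <- file.path(out_dir, "truth.json")
  jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = 12,
                       dataframe = "columns", pretty = TRUE)

  invisible(list(
    annotations = annotations_path, census = census_path,
    fertility = fertility_path, truth_file = truth_path, truth = truth,
    sections = sections
  ))
}
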