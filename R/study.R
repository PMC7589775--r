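#' Default end-to-end study configuration
#'
#' A plain (YAML-serializable) list describing the full simulated study:
#' the acquisition grid, plate geometry, noise, the mixture designs for the
#' DD-SIMCA calibration (two plates of pure almond, one per variety), the
#' four DD-SIMCA validation sets (apricot/peanut x variety 1 at 0--50% in
#' 5% steps / variety 2 at 0, 7, 15, 22, 30%), the PLS calibration and two
#' validation sets per adulterant, and an external blind set
#' (0, 7, 15, 22, 30, 40, 45, 50% with the scatter-slope SD doubled to
#' emulate a re-imaged session).
#'
#' @param seed master integer seed; every random draw derives from it.
#' @return Nested list (`study_config`).
#' @export
default_study_config <- function(seed = 7L) {
  steps5 <- rep(seq(0, 50, by = 5), each = 5)             # 55 wells -> 110 halves
  steps5_v2 <- rep(c(0, 7, 15, 22, 30), each = 5)         # 25 wells -> 50 halves
  pls_cal <- rep(seq(0, 50, by = 5), each = 3)            # 33 wells -> 66 halves
  pls_val1 <- rep(seq(0, 50, by = 5), each = 2)           # 22 wells -> 44 halves
  pls_val2 <- c(rep(c(0, 7, 15, 22, 30), each = 4), 0, 0) # 22 wells -> 44 halves
  ext <- rep(c(0, 7, 15, 22, 30, 40, 45, 50), each = 5)   # 40 wells -> 80 halves
  list(
    seed = as.integer(seed),
    grid = list(start_nm = 900, stop_nm = 2494, n_bands = 275L),
    crop = list(low_nm = 935, high_nm = 1965),
    layout = list(rows = 5L, cols = 5L, well_diameter_px = 14L,
                  well_pitch_px = 22L, image_width_px = 118L),
    noise = list(additive_sd = 0.01, scatter_slope_sd = 0.02,
                 scatter_offset_sd = 0.005, baseline_tilt_sd = 0.005),
    external_scatter_slope_multiplier = 2,
    endmembers = list(baseline_level = 0.6, variety_shift = 0.04),
    ddsimca = list(alpha = 0.01, gamma = 0.01, factors = "auto",
                   max_factors = 5L, preprocess = "snv",
                   window = 11L, polyorder = 2L),
    plsr = list(max_factors = 12L,
                methods = c("mean_norm", "max_norm", "range_norm", "msc",
                            "snv", "sg_first", "sg_second", "raw")),
    designs = list(
      dds_cal_v1 = list(adulterant = "apricot", variety = 1L,
                        wells_pct = rep(0, 25), seed_offset = 1L),
      dds_cal_v2 = list(adulterant = "apricot", variety = 2L,
                        wells_pct = rep(0, 25), seed_offset = 2L),
      dds_val1_aa = list(adulterant = "apricot", variety = 1L,
                         wells_pct = steps5, seed_offset = 3L),
      dds_val2_aa = list(adulterant = "apricot", variety = 2L,
                         wells_pct = steps5_v2, seed_offset = 4L),
      dds_val1_ap = list(adulterant = "peanut", variety = 1L,
                         wells_pct = steps5, seed_offset = 5L),
      dds_val2_ap = list(adulterant = "peanut", variety = 2L,
                         wells_pct = steps5_v2, seed_offset = 6L),
      pls_cal_aa = list(adulterant = "apricot", variety = 1L,
                        wells_pct = pls_cal, seed_offset = 7L),
      pls_val1_aa = list(adulterant = "apricot", variety = 1L,
                         wells_pct = pls_val1, seed_offset = 8L),
      pls_val2_aa = list(adulterant = "apricot", variety = 2L,
                         wells_pct = pls_val2, seed_offset = 9L),
      pls_cal_ap = list(adulterant = "peanut", variety = 1L,
                        wells_pct = pls_cal, seed_offset = 10L),
      pls_val1_ap = list(adulterant = "peanut", variety = 1L,
                         wells_pct = pls_val1, seed_offset = 11L),
      pls_val2_ap = list(adulterant = "peanut", variety = 2L,
                         wells_pct = pls_val2, seed_offset = 12L),
      ext_aa = list(adulterant = "apricot", variety = 1L,
                    wells_pct = ext, seed_offset = 13L, external = TRUE),
      ext_ap = list(adulterant = "peanut", variety = 1L,
                    wells_pct = ext, seed_offset = 14L, external = TRUE)
    )
  )
}

# objects derived from a config
config_grid <- function(config) {
  make_wavelength_grid(config$grid$start_nm, config$grid$stop_nm,
                       config$grid$n_bands)
}
config_layout <- function(config) do.call(plate_layout, config$layout)
config_noise <- function(config, external = FALSE) {
  nm <- config$noise
  slope <- nm$scatter_slope_sd *
    if (external) config$external_scatter_slope_multiplier else 1
  noise_model(nm$additive_sd, slope, nm$scatter_offset_sd, nm$baseline_tilt_sd)
}
config_endmembers <- function(config) {
  do.call(default_endmembers, config$endmembers)
}

#' Simulate one configured design to a spectral set
#'
#' Splits the design's wells across plates of the configured capacity, and
#' for each plate renders the cube, calibrates it, segments the background,
#' crops to the analysis window and extracts the two averaged half-spectra
#' per well.
#'
#' @param config a [default_study_config()]-shaped list.
#' @param name design name in `config$designs`.
#' @return A `spectral_set` (2 spectra per well).
#' @export
simulate_design <- function(config, name) {
  dcfg <- config$designs[[name]]
  if (is.null(dcfg)) stop("unknown design: ", name)
  grid <- config_grid(config)
  layout <- config_layout(config)
  noise <- config_noise(config, isTRUE(dcfg$external))
  endmembers <- config_endmembers(config)
  wells <- dcfg$wells_pct
  capacity <- layout$rows * layout$cols
  n_plates <- ceiling(length(wells) / capacity)
  sets <- vector("list", n_plates)
  for (p in seq_len(n_plates)) {
    idx <- ((p - 1L) * capacity + 1L):min(p * capacity, length(wells))
    des <- mixture_design(dcfg$adulterant, dcfg$variety, wells[idx],
                          replicates_per_concentration = 1L,
                          seed = (config$seed + 7919L * dcfg$seed_offset +
                                    101L * p) %% 2147483647L)
    plate <- render_plate_cube(des, layout, endmembers, noise, grid,
                               plate_id = sprintf("%s_p%d", name, p))
    refl <- calibrate_reflectance(plate$raw,
                                  reference_pair(plate$dark, plate$white))
    mask <- segment_background(refl)
    refl <- crop_bands(refl, config$crop$low_nm, config$crop$high_nm)
    sets[[p]] <- extract_well_spectra(refl, mask, plate$truth, halves = TRUE)
  }
  bind_spectral_sets(sets)
}

# classification metrics for one validation set, plus the concentrations of
# any adulterated spectra accepted as pure
ddsimca_validation_row <- function(set_name, decisions, concentrations) {
  labels <- ifelse(concentrations == 0, "pure", "adulterated")
  cc <- confusion(decisions, labels)
  missed <- sort(unique(concentrations[labels == "adulterated" &
                                         decisions$decision == "accepted"]))
  data.frame(
    set = set_name, n = nrow(decisions),
    TP = cc$TP, FN = cc$FN, TN = cc$TN, FP = cc$FP,
    sensitivity = sensitivity(cc), specificity = specificity(cc),
    accuracy = accuracy(cc),
    missed_concentrations = paste(missed, collapse = ";"),
    stringsAsFactors = FALSE
  )
}

#' Run the full simulated study
#'
#' Simulates every configured set, fits the DD-SIMCA model on the pooled
#' pure-almond calibration spectra, validates it on the four mixture sets
#' and the two external blind sets, fits PLS1 models for every configured
#' pretreatment and both adulterants with leave-one-out factor selection,
#' and maps one apricot validation plate pixel-wise with the sg_second
#' apricot model. Deterministic given `config$seed`.
#'
#' @param config a [default_study_config()]-shaped list.
#' @param out_dir optional output directory; when given, the report JSON,
#'   model files, decision/prediction CSVs and the rendered concentration
#'   map PNG are written there.
#' @param verbose print one line per stage.
#' @return The study report (list): `ddsimca` metrics table, `plsr_grid`
#'   data.frame, `concentration_summaries`, `map_wells`, `meta`.
#' @export
run_study <- function(config = default_study_config(), out_dir = NULL,
                      verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }

  say("simulating %d designs", length(config$designs))
  sets <- stats::setNames(
    lapply(names(config$designs), function(nm) simulate_design(config, nm)),
    names(config$designs))

  # ---- DD-SIMCA --------------------------------------------------------
  dd <- config$ddsimca
  cal <- bind_spectral_sets(sets$dds_cal_v1, sets$dds_cal_v2)
  pp <- preprocess_spec(dd$preprocess, dd$window, dd$polyorder)
  A <- if (identical(dd$factors, "auto")) {
    ddsimca_select_factors(cal, dd$max_factors, dd$alpha, dd$gamma,
                           preprocess = pp)
  } else as.integer(dd$factors)
  say("DD-SIMCA: %d factors", A)
  dds_model <- ddsimca_fit(cal, A, dd$alpha, dd$gamma, preprocess = pp)

  dds_sets <- c("dds_val1_aa", "dds_val2_aa", "dds_val1_ap", "dds_val2_ap",
                "ext_aa", "ext_ap")
  dds_rows <- list()
  dds_decisions <- list()
  for (nm in dds_sets) {
    dec <- ddsimca_classify(dds_model, sets[[nm]])
    dds_decisions[[nm]] <- dec
    dds_rows[[nm]] <- ddsimca_validation_row(
      nm, dec, sets[[nm]]$meta$concentration_pct)
  }
  dds_table <- do.call(rbind, dds_rows)
  rownames(dds_table) <- NULL

  # ---- PLSR grid -------------------------------------------------------
  say("PLSR grid: %d methods x 2 adulterants", length(config$plsr$methods))
  plsr_rows <- list()
  plsr_models <- list()
  for (ad in c("aa", "ap")) {
    cal_s <- sets[[paste0("pls_cal_", ad)]]
    v1 <- sets[[paste0("pls_val1_", ad)]]
    v2 <- sets[[paste0("pls_val2_", ad)]]
    for (mth in config$plsr$methods) {
      spec <- preprocess_spec(mth, dd$window, dd$polyorder)
      spec <- fit_preprocess(spec, cal_s)
      cal_t <- apply_preprocess(spec, cal_s)
      cv <- pls1_loo(cal_t, A_max = config$plsr$max_factors)
      fit <- pls1_fit(cal_t, ncomp = cv$A_selected)
      fit$preprocess <- spec  # embed for prediction/mapping
      e1 <- evaluate_regression(v1$meta$concentration_pct, predict(fit, v1))
      e2 <- evaluate_regression(v2$meta$concentration_pct, predict(fit, v2))
      plsr_models[[paste(ad, mth, sep = ".")]] <- fit
      plsr_rows[[paste(ad, mth, sep = ".")]] <- data.frame(
        adulterant = if (ad == "aa") "apricot" else "peanut",
        method = mth, A = cv$A_selected,
        r2_cal = fit$fit_stats$r2_cal, sec = fit$fit_stats$sec,
        r2_val1 = e1$r2, sep_val1 = e1$se,
        r2_val2 = e2$r2, sep_val2 = e2$se,
        stringsAsFactors = FALSE)
    }
  }
  plsr_grid <- do.call(rbind, plsr_rows)
  rownames(plsr_grid) <- NULL

  # ---- chemical map of one apricot validation plate --------------------
  say("chemical map")
  map_model <- plsr_models[["aa.sg_second"]]
  dcfg <- config$designs$pls_val1_aa
  layout <- config_layout(config)
  capacity <- layout$rows * layout$cols
  des <- mixture_design(dcfg$adulterant, dcfg$variety,
                        dcfg$wells_pct[seq_len(min(capacity,
                                                   length(dcfg$wells_pct)))],
                        seed = (config$seed + 7919L * dcfg$seed_offset +
                                  101L) %% 2147483647L)
  plate <- render_plate_cube(des, layout, config_endmembers(config),
                             config_noise(config), config_grid(config),
                             plate_id = "map_plate")
  refl <- calibrate_reflectance(plate$raw,
                                reference_pair(plate$dark, plate$white))
  mask <- segment_background(refl)
  refl <- crop_bands(refl, config$crop$low_nm, config$crop$high_nm)
  cmap <- map_concentration(refl, mask, map_model, model_id = "aa.sg_second")
  map_wells <- summarize_wells(cmap, plate$truth)

  # ---- concentration-design summaries (Table-1 shape) ------------------
  summ_sets <- c(dds_cal = NA, dds_val1 = "dds_val1_aa",
                 dds_val2 = "dds_val2_aa", pls_cal = "pls_cal_aa",
                 pls_val1 = "pls_val1_aa", pls_val2 = "pls_val2_aa")
  conc_summaries <- lapply(names(summ_sets), function(nm) {
    conc <- if (nm == "dds_cal") rep(0, nrow(cal$spectra))
            else sets[[summ_sets[[nm]]]]$meta$concentration_pct
    c(list(set = nm), summarize_concentrations(conc))
  })
  conc_table <- do.call(rbind, lapply(conc_summaries, as.data.frame))

  report <- list(
    meta = list(seed = config$seed, ddsimca_factors = A,
                ddsimca_Nh = dds_model$Nh, ddsimca_Nv = dds_model$Nv,
                n_designs = length(config$designs)),
    ddsimca = dds_table,
    plsr_grid = plsr_grid,
    concentration_summaries = conc_table,
    map_wells = map_wells
  )

  if (!is.null(out_dir)) {
    save_ddsimca(dds_model, file.path(out_dir, "model.ddsimca"))
    save_plsr(map_model, file.path(out_dir, "apricot_sg2.plsr"))
    for (nm in names(dds_decisions)) {
      utils::write.csv(dds_decisions[[nm]],
                       file.path(out_dir, paste0("decisions_", nm, ".csv")),
                       row.names = FALSE)
    }
    map_path <- file.path(out_dir, "apricot_map.png")
    render_map(cmap, map_path)
    report$map_file <- "apricot_map.png"
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  report
}
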