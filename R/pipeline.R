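#' Pipeline configuration
#'
#' Nested configuration for [run_pipeline()]. Defaults give the toy-scale
#' study (20 subjects on a 400-vertex sphere); every stochastic stage draws
#' its seed from the master `seed`.
#'
#' @param seed Master seed (mandatory for every stochastic stage).
#' @param ... Named overrides merged into the defaults, e.g.
#'   `sim = list(n_subjects = 10)` or `decomp = list(n_boot = 20)`.
#' @return A named list of class `netdax_config`.
#' @export
netdax_config <- function(seed = 1L, ...) {
  base <- list(
    seed = as.integer(seed),
    sim = list(
      n_vertices = 400L, n_parcels = 20L, n_hp = 12L, n_patient = 8L,
      k_planted = 4L, overlap_frac = 0.3, t_frames = 150L, tr = 2,
      snr = 2, ar1 = 0.4,
      label_atlases = c(7L, 17L), component_atlases = 10L
    ),
    segment = list(min_frames = 120L, fd_threshold = 0.4),
    decomp = list(k_min = 4L, k_max = 4L, k_step = 2L, n_boot = 8L,
                  block_min_s = 20, block_max_s = 60, sparsity = 3L,
                  n_iter = 12L, min_explained = 0.2,
                  reproducibility_threshold = 0.5, epsilon = 1e-8),
    correspond = list(n_spins = 0L),
    # the toy cohort is small, so the default toy design is lean: one
    # spline covariate (age) with a single interior knot plus sex
    normative = list(heteroskedastic = FALSE, continuous = "age",
                     categorical = "sex", n_knots = 1L),
    infer = list(n_perm = 499L, alpha = 0.05),
    staging = list(enabled = TRUE, c_range = 1L, n_start = 2L, n_mcmc = 100L,
                   test_mode = TRUE, run_cvic = FALSE),
    scca = list(enabled = TRUE, n_perm = 99L, n_perm_select = 20L,
                test_mode = TRUE),
    write_nifti = FALSE
  )
  over <- list(...)
  for (nm in names(over)) {
    if (is.list(base[[nm]]) && is.list(over[[nm]])) {
      base[[nm]][names(over[[nm]])] <- over[[nm]]
    } else {
      base[[nm]] <- over[[nm]]
    }
  }
  structure(base, class = "netdax_config")
}

#' Simulate a full toy study
#'
#' Generates the geometry, canonical atlases, cohort table (with per-frame
#' motion traces) and per-subject BOLD with planted overlapping networks;
#' ground truth per subject is kept alongside.
#'
#' @param config A [netdax_config()].
#' @return A list: `geom`, `atlases`, `cohort`, `bold` (named list), `truth`
#'   (per-subject ground truth).
#' @export
simulate_study <- function(config) {
  s <- config$sim
  seeds <- derive_seeds(config$seed, 4L + s$n_hp + s$n_patient)
  geom <- make_geometry(s$n_vertices, s$n_parcels, seed = seeds[1])
  atlases <- make_atlases(geom, label_specs = s$label_atlases,
                          component_specs = s$component_atlases,
                          seed = seeds[2])
  n <- s$n_hp + s$n_patient
  cohort <- with_seed(seeds[3], tibble(
    subject_id = sprintf("sub-%04d", seq_len(n)),
    group = c(rep("HP", s$n_hp), rep("focal", s$n_patient)),
    age = runif(n, 18, 65),
    sex = sample(c("F", "M"), n, replace = TRUE),
    motion = exp(rnorm(n, log(0.12), 0.3))
  ))
  bold <- list()
  truth <- list()
  for (i in seq_len(n)) {
    sim_i <- plant_networks_and_bold(
      geom, K = s$k_planted, overlap_frac = s$overlap_frac,
      T_frames = s$t_frames, tr = s$tr, snr = s$snr, ar1 = s$ar1,
      seed = seeds[4L + i]
    )
    # per-frame motion trace around the subject's mean FD
    fd <- with_seed(seeds[4L + i] + 1L,
                    pmax(0.01, cohort$motion[i] + cumsum(rnorm(s$t_frames, 0, 0.01))))
    sim_i$ts$fd <- fd
    bold[[cohort$subject_id[i]]] <- sim_i$ts
    truth[[cohort$subject_id[i]]] <- sim_i$truth
  }
  list(geom = geom, atlases = atlases, cohort = cohort, bold = bold,
       truth = truth)
}

#' Per-subject correspondence feature table
#'
#' Computes, for one subject's networks against a set of canonical atlases:
#' the atlas-averaged normativity and non-normativity, the 17 network-level
#' consensus correspondence values (cross-atlas consensus map aggregated over
#' the geometry's 17-network partition), and the seven bilateral subcortical
#' CNR values — the 26-feature correspondence set used for staging.
#'
#' @param nets A `subject_networks`.
#' @param atlases List of `canonical_atlas` objects.
#' @param geom The shared geometry.
#' @return A one-row tibble with 26 feature columns.
#' @export
correspondence_features <- function(nets, atlases, geom) {
  profiles <- lapply(atlases, function(at) {
    correspondence_profile(dice_matrix(nets, at))
  })
  parcel_profiles <- map2(profiles, atlases, map_to_parcels, geom = geom)
  cm <- consensus_map(parcel_profiles, geom)
  net_vals <- rep(NA_real_, 17)
  net_vals[cm$networks$network] <- cm$networks$value
  sc <- subcortical_dice(nets, geom)
  out <- c(
    normativity = mean(vapply(profiles, `[[`, numeric(1), "normativity")),
    non_normativity = mean(vapply(profiles, `[[`, numeric(1), "non_normativity")),
    stats::setNames(net_vals, sprintf("cons_net%02d", 1:17)),
    stats::setNames(sc$cnr_bilateral, sprintf("subc_cnr%d", 1:7))
  )
  as_tibble(as.list(out))
}

#' Per-subject k-hubness feature table (wide)
#'
#' @param nets A `subject_networks`.
#' @param geom The shared geometry.
#' @return A one-row tibble, one column per region (34 cortical + 14
#'   subcortical).
#' @export
khubness_features <- function(nets, geom) {
  sm <- summarize_khubness(compute_khubness_map(nets), geom)
  out <- as.list(sm$mean_k)
  names(out) <- sm$region
  as_tibble(out)
}

write_result <- function(tbl, out_dir, name) {
  readr::write_tsv(tbl, file.path(out_dir, paste0(name, ".tsv")))
}

#' Run the full dual-axis pipeline
#'
#' Executes the stages in order — simulate/load, motion segment selection,
#' per-subject network decomposition, k-hubness, atlas correspondence,
#' normative w-scores, group inference, subtype/stage inference, sparse CCA —
#' writing each stage's result tables as TSV under `out_dir` plus a
#' provenance file (config and derived seeds). Subject decompositions are
#' cached under `out_dir/cache` and reused on re-runs with an identical
#' configuration, making re-runs byte-identical and cheap. Any stage failure
#' halts with an error naming the stage.
#'
#' @param config A [netdax_config()].
#' @param out_dir Output directory (created).
#' @param inputs Optional pre-built input bundle (as from [simulate_study()]
#'   or [load_inputs()]); `NULL` simulates from `config`.
#' @return Invisibly, a list of the in-memory stage results.
#' @export
run_pipeline <- function(config, out_dir, inputs = NULL) {
  stopifnot(inherits(config, "netdax_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cache_dir <- file.path(out_dir, "cache")
  dir.create(cache_dir, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("Pipeline stage `%s` failed: %s", name, conditionMessage(e)),
            class = "netdax_error_stage", parent = e)
    })
  }
  seeds <- derive_seeds(config$seed, 6L)

  if (is.null(inputs)) inputs <- stage("simulate", simulate_study(config))
  geom <- inputs$geom
  cohort <- inputs$cohort
  n <- nrow(cohort)

  # --- segment: minimum-motion window + exclusion flags -------------------
  segments <- stage("segment", {
    bind_rows(lapply(cohort$subject_id, function(id) {
      ts <- inputs$bold[[id]]
      if (is.null(ts$fd)) {
        return(tibble(subject_id = id, start = 1L, end = nrow(ts$data),
                      mean_fd = NA_real_, excluded = FALSE))
      }
      seg <- select_motion_segment(ts$fd, min(config$segment$min_frames, nrow(ts$data)),
                                   config$segment$fd_threshold)
      mutate(seg, subject_id = id, .before = 1)
    }))
  })
  write_result(segments, out_dir, "segments")
  keep_ids <- segments$subject_id[!segments$excluded]
  cohort <- filter(cohort, .data$subject_id %in% keep_ids)

  # --- decompose (cached per subject) -------------------------------------
  dconf <- do.call(decomp_config, config$decomp)
  nets <- stage("decompose", {
    out <- list()
    for (i in seq_along(cohort$subject_id)) {
      id <- cohort$subject_id[i]
      seg <- segments[segments$subject_id == id, ]
      ts <- inputs$bold[[id]]
      ts_use <- bold_ts(ts$data[seg$start:seg$end, , drop = FALSE], ts$tr, ts$mask)
      key <- rlang::hash(list(id, config$decomp, config$seed, seg$start, seg$end))
      cache_file <- file.path(cache_dir, paste0("decomp_", key, ".rds"))
      if (file.exists(cache_file)) {
        out[[id]] <- readRDS(cache_file)
      } else {
        out[[id]] <- estimate_networks(ts_use, dconf, seed = seeds[1] + i)
        saveRDS(out[[id]], cache_file)
      }
    }
    out
  })
  atoms_tbl <- tibble(
    subject_id = cohort$subject_id,
    n_atoms = vapply(nets[cohort$subject_id], function(x) nrow(x$loadings), integer(1)),
    mean_reproducibility = vapply(nets[cohort$subject_id],
                                  function(x) mean(x$reproducibility), numeric(1)),
    n_noise_flagged = vapply(nets[cohort$subject_id],
                             function(x) sum(flag_noise_atoms(x, geom)), integer(1))
  )
  write_result(atoms_tbl, out_dir, "atoms")
  cohort <- left_join(cohort, select(atoms_tbl, "subject_id", "n_atoms"),
                      by = "subject_id")

  # --- integrate: k-hubness -----------------------------------------------
  khub <- stage("khub", {
    bind_rows(lapply(cohort$subject_id, function(id) {
      mutate(khubness_features(nets[[id]], geom), subject_id = id, .before = 1)
    }))
  })
  write_result(khub, out_dir, "khubness_regions")

  # --- correspond -----------------------------------------------------------
  corr <- stage("correspond", {
    bind_rows(lapply(cohort$subject_id, function(id) {
      mutate(correspondence_features(nets[[id]], inputs$atlases, geom),
             subject_id = id, .before = 1)
    }))
  })
  write_result(corr, out_dir, "correspondence_features")
  if (config$correspond$n_spins > 0) {
    spin_p <- stage("correspond_spin", {
      bind_rows(lapply(cohort$subject_id, function(id) {
        p <- spin_significance(nets[[id]], inputs$atlases[[1]], geom,
                               n_perm = config$correspond$n_spins,
                               seed = seeds[2])
        tibble(subject_id = id, atom = rep(seq_len(nrow(p)), ncol(p)),
               network = rep(seq_len(ncol(p)), each = nrow(p)),
               p_spin = as.numeric(p))
      }))
    })
    write_result(spin_p, out_dir, "correspondence_spin")
  }

  # --- normative ------------------------------------------------------------
  normative <- stage("normative", {
    lapply(list(correspondence = corr, khubness = khub), function(tbl) {
      feats <- as.matrix(select(tbl, -"subject_id"))
      # a feature must vary within the healthy reference, or its residual
      # scale (hence every w-score) is undefined
      hp_rows <- cohort$group == "HP"
      keep <- apply(feats, 2, function(x) all(is.finite(x))) &
        apply(feats[hp_rows, , drop = FALSE], 2, sd) > 1e-10
      normative_wscores(feats[, keep, drop = FALSE], cohort,
                        continuous = config$normative$continuous,
                        categorical = config$normative$categorical,
                        heteroskedastic = config$normative$heteroskedastic,
                        n_knots = config$normative$n_knots)
    })
  })
  for (fam in names(normative)) {
    w_tbl <- as_tibble(normative[[fam]]$w) |>
      mutate(subject_id = cohort$subject_id, group = cohort$group, .before = 1)
    write_result(w_tbl, out_dir, paste0("wscores_", fam))
  }

  # --- infer ----------------------------------------------------------------
  patient <- cohort$group != "HP"
  infer <- stage("infer", {
    w_corr <- normative$correspondence$w
    glob_cols <- intersect(c("normativity", "non_normativity"), colnames(w_corr))
    glob <- test_global_metrics(w_corr[patient, glob_cols, drop = FALSE],
                                alpha = config$infer$alpha)
    reg_cols <- setdiff(colnames(w_corr), glob_cols)
    reg <- test_regional_maxT(w_corr[patient, reg_cols, drop = FALSE],
                              n_perm = config$infer$n_perm,
                              alpha = config$infer$alpha, seed = seeds[3])
    khub_reg <- test_regional_maxT(normative$khubness$w[patient, , drop = FALSE],
                                   n_perm = config$infer$n_perm,
                                   alpha = config$infer$alpha, seed = seeds[4])
    list(global = glob, correspondence = reg, khubness = khub_reg)
  })
  write_result(infer$global, out_dir, "stats_global")
  write_result(infer$correspondence, out_dir, "stats_correspondence_maxT")
  write_result(infer$khubness, out_dir, "stats_khubness_maxT")

  # --- stage ----------------------------------------------------------------
  staging <- NULL
  if (isTRUE(config$staging$enabled)) {
    staging <- stage("stage", {
      pf <- prepare_features(normative$correspondence$w,
                             patient = patient)
      zp <- pf$z[patient, , drop = FALSE]
      fit <- fit_sustain(zp, pf$event_model,
                         c_range = config$staging$c_range,
                         n_start = config$staging$n_start,
                         n_mcmc = config$staging$n_mcmc,
                         seed = seeds[5],
                         test_mode = config$staging$test_mode)
      C_use <- max(config$staging$c_range)
      cv <- NULL
      if (isTRUE(config$staging$run_cvic)) {
        cv <- select_model(zp, pf$event_model, c_range = config$staging$c_range,
                           n_start = config$staging$n_start,
                           n_mcmc = config$staging$n_mcmc, seed = seeds[5],
                           test_mode = config$staging$test_mode)
        C_use <- cv$c_star
      }
      assign <- assign_subtype_stage(fit$models[[as.character(C_use)]], zp,
                                     pf$event_model)
      assign$subject_id <- cohort$subject_id[patient]
      list(fit = fit, assign = assign, cvic = cv)
    })
    write_result(staging$assign, out_dir, "staging_assignments")
    if (!is.null(staging$cvic)) write_result(staging$cvic$cvic, out_dir, "staging_cvic")
  }

  # --- scca: system integrity vs system integration -------------------------
  scca <- NULL
  if (isTRUE(config$scca$enabled)) {
    scca <- stage("scca", {
      # toy cohorts are small: the integrity/integration association is
      # fit across all subjects' deviation profiles
      X <- normative$correspondence$w
      Y <- normative$khubness$w
      keepx <- apply(X, 2, sd) > 0
      keepy <- apply(Y, 2, sd) > 0
      X <- X[, keepx, drop = FALSE]
      Y <- Y[, keepy, drop = FALSE]
      sel <- select_penalties(X, Y, n_perm = config$scca$n_perm_select,
                              seed = seeds[6], test_mode = config$scca$test_mode)
      pt <- scca_permutation_test(X, Y, sel$c_x, sel$c_y,
                                  n_perm = config$scca$n_perm, seed = seeds[6])
      fit <- scca_fit(X, Y, sel$c_x, sel$c_y, n_dims = 1L, seed = seeds[6])
      list(fit = fit, test = pt, penalties = sel)
    })
    write_result(tibble(feature = rownames(scca$fit$u),
                        side = "X", weight = scca$fit$u[, 1]) |>
                   bind_rows(tibble(feature = rownames(scca$fit$v),
                                    side = "Y", weight = scca$fit$v[, 1])),
                 out_dir, "scca_weights")
    write_result(mutate(scca$test, c_x = scca$fit$penalties[1],
                        c_y = scca$fit$penalties[2]),
                 out_dir, "scca_test")
  }

  # --- provenance (no timestamps: re-runs must be byte-identical) ----------
  jsonlite::write_json(
    list(config = unclass(config), derived_seeds = seeds,
         package_version = as.character(utils::packageVersion("netdax"))),
    file.path(out_dir, "provenance.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(list(inputs = inputs, segments = segments, nets = nets,
                 khub = khub, corr = corr, normative = normative,
                 infer = infer, staging = staging, scca = scca))
}
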