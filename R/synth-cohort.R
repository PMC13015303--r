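#' Simulate a healthy/patient cohort with planted covariate and group effects
#'
#' Emulates the tabular inputs of the normative-modeling stage: per-subject
#' covariates (age, sex, head motion, number of decomposition atoms), features
#' built from linear/smooth covariate effects plus a planted patient-group
#' deviation and Gaussian noise. The noise can be made heteroskedastic in age
#' (standard deviation scaling geometrically across the age range) for
#' calibration tests of the heteroskedastic normative model.
#'
#' @param n_hp Number of healthy participants (at least 20).
#' @param n_patient Number of patients.
#' @param n_features Number of features; features are named `f1..fn`.
#' @param covariate_effects Named list of per-feature coefficient vectors for
#'   any of `age`, `sex`, `motion`, `n_atoms`, `age_quad` (a smooth quadratic
#'   age term). Each vector is recycled to `n_features`. `NULL` plants small
#'   random effects.
#' @param deviation_spec Named numeric vector of patient-group shifts keyed by
#'   feature name; unknown names are an error. `NULL` plants none.
#' @param noise_sd Residual standard deviation at the age-range midpoint.
#' @param hetero_ratio Ratio of residual sd at the oldest vs youngest age;
#'   1 (default) gives homoskedastic noise.
#' @param seed Integer seed.
#'
#' @return A list with `cohort` (tibble: subject_id, group, age, sex, motion,
#'   n_atoms), `features` (subjects x features matrix), and `truth`.
#' @export
simulate_cohort_features <- function(n_hp, n_patient, n_features,
                                     covariate_effects = NULL,
                                     deviation_spec = NULL,
                                     noise_sd = 1, hetero_ratio = 1,
                                     seed = 1L) {
  n_hp <- assert_positive_int(n_hp, "n_hp")
  if (n_hp < 20) abort("Need at least 20 healthy participants.",
                       class = "netdax_error_argument")
  n_patient <- max(0L, as.integer(n_patient))
  n_features <- assert_positive_int(n_features, "n_features")
  feat_names <- paste0("f", seq_len(n_features))
  if (!is.null(deviation_spec)) {
    bad <- setdiff(names(deviation_spec), feat_names)
    if (length(bad) > 0) {
      abort(sprintf("deviation_spec names unknown features: %s",
                    paste(bad, collapse = ", ")),
            class = "netdax_error_argument")
    }
  }
  with_seed(seed, {
    n <- n_hp + n_patient
    cohort <- tibble(
      subject_id = sprintf("sub-%04d", seq_len(n)),
      group = c(rep("HP", n_hp), rep("focal", n_patient)),
      age = runif(n, 18, 65),
      sex = sample(c("F", "M"), n, replace = TRUE),
      motion = exp(rnorm(n, log(0.12), 0.35)),
      n_atoms = sample(18:40, n, replace = TRUE)
    )
    if (is.null(covariate_effects)) {
      covariate_effects <- list(
        age = rnorm(n_features, 0, 0.02),
        sex = rnorm(n_features, 0, 0.2),
        motion = rnorm(n_features, 0, 0.5),
        n_atoms = rnorm(n_features, 0, 0.01)
      )
    }
    known <- c("age", "sex", "motion", "n_atoms", "age_quad")
    bad <- setdiff(names(covariate_effects), known)
    if (length(bad) > 0) {
      abort(sprintf("Unknown covariates in covariate_effects: %s",
                    paste(bad, collapse = ", ")),
            class = "netdax_error_argument")
    }
    design <- cbind(
      age = cohort$age,
      sex = as.numeric(cohort$sex == "M"),
      motion = cohort$motion,
      n_atoms = cohort$n_atoms,
      age_quad = ((cohort$age - 41.5) / 23.5)^2
    )
    beta <- matrix(0, 5, n_features, dimnames = list(known, feat_names))
    for (nm in names(covariate_effects)) {
      beta[nm, ] <- rep_len(covariate_effects[[nm]], n_features)
    }
    mu <- design %*% beta
    dev <- matrix(0, n, n_features, dimnames = list(NULL, feat_names))
    if (!is.null(deviation_spec)) {
      dev[cohort$group != "HP", names(deviation_spec)] <-
        matrix(deviation_spec, n_patient, length(deviation_spec), byrow = TRUE)
    }
    # heteroskedastic noise: sd scales geometrically across the age range
    age01 <- (cohort$age - 18) / (65 - 18)
    sds <- noise_sd * hetero_ratio^(age01 - 0.5)
    features <- mu + dev + matrix(rnorm(n * n_features), n) * sds
    colnames(features) <- feat_names
    truth <- structure(
      list(covariate_effects = beta, deviation_spec = deviation_spec,
           noise_sd = noise_sd, hetero_ratio = hetero_ratio),
      class = "ground_truth"
    )
    list(cohort = cohort, features = features, truth = truth)
  })
}

#' Stage-expected z-scores under a piecewise-linear event trajectory
#'
#' Each feature has z-score waypoints at 1, 2 and 3; its expected abnormality
#' at stage t is the piecewise-linear trajectory through (0, 0), the three
#' waypoint positions within the event ordering, and (N, z_max) at the end of
#' the sequence of N = 3F events.
#'
#' @param ordering Integer permutation of the N = 3F events; event
#'   `(f - 1) * 3 + w` is feature f reaching waypoint w.
#' @param n_features Number of features F.
#' @param z_max Trajectory endpoint abnormality (default 5).
#' @return An (N + 1) x F matrix of expected z at stages 0..N.
#' @export
stage_expected_z <- function(ordering, n_features, z_max = 5) {
  n_events <- 3L * n_features
  check_ordering(ordering, n_features)
  pos <- match(seq_len(n_events), ordering)  # stage at which each event completes
  stages <- 0:n_events
  out <- matrix(0, n_events + 1L, n_features)
  for (f in seq_len(n_features)) {
    p <- pos[(f - 1L) * 3L + 1:3]
    xs <- c(0, p, n_events)
    ys <- c(0, 1, 2, 3, max(z_max, 3))
    if (p[3] == n_events) {
      xs <- xs[1:4]
      ys <- ys[1:4]
    }
    out[, f] <- stats::approx(xs, ys, xout = stages, ties = "ordered")$y
  }
  out
}

check_ordering <- function(ordering, n_features) {
  n_events <- 3L * n_features
  if (length(ordering) != n_events || !setequal(ordering, seq_len(n_events))) {
    abort("Ordering must be a permutation of the 3*F events.",
          class = "netdax_error_ordering")
  }
  pos <- match(seq_len(n_events), ordering)
  for (f in seq_len(n_features)) {
    p <- pos[(f - 1L) * 3L + 1:3]
    if (is.unsorted(p, strictly = TRUE)) {
      abort(sprintf("Feature %d waypoints out of order (z=1 before z=2 before z=3).", f),
            class = "netdax_error_ordering")
    }
  }
  invisible(TRUE)
}

random_admissible_ordering <- function(n_features) {
  # random permutation, then sort each feature's three waypoints in place
  n_events <- 3L * n_features
  ord <- sample(n_events)
  for (f in seq_len(n_features)) {
    ev <- (f - 1L) * 3L + 1:3
    ord[sort(match(ev, ord))] <- ev
  }
  ord
}

#' Simulate a progression cohort following z-score event sequences
#'
#' Draws each subject a subtype and a stage, sets the expected feature
#' z-scores from the subtype's piecewise-linear event trajectory, and adds
#' Gaussian noise.
#'
#' @param n_subjects Number of subjects.
#' @param n_features Number of features.
#' @param n_subtypes 1 or 2 planted subtypes.
#' @param orderings Optional list of event orderings (one per subtype);
#'   `NULL` draws admissible orderings at random (reversed feature blocks for
#'   two subtypes, giving well-separated trajectories).
#' @param stage_distribution Optional probability vector over stages 0..N;
#'   `NULL` is uniform.
#' @param sigma Noise standard deviation (default 0.5).
#' @param z_max Trajectory endpoint (default 5).
#' @param seed Integer seed.
#'
#' @return A list with `z` (subjects x features), and `truth` carrying
#'   `subtype`, `stage`, and `orderings`.
#' @export
simulate_progression <- function(n_subjects, n_features, n_subtypes = 1,
                                 orderings = NULL, stage_distribution = NULL,
                                 sigma = 0.5, z_max = 5, seed = 1L) {
  n_subjects <- assert_positive_int(n_subjects, "n_subjects")
  n_features <- assert_positive_int(n_features, "n_features")
  if (!n_subtypes %in% 1:2) {
    abort("`n_subtypes` must be 1 or 2.", class = "netdax_error_argument")
  }
  n_events <- 3L * n_features
  with_seed(seed, {
    if (is.null(orderings)) {
      if (n_subtypes == 1) {
        orderings <- list(random_admissible_ordering(n_features))
      } else {
        # well-separated: feature blocks in opposite orders
        fwd <- as.vector(t(outer(seq_len(n_features), 1:3,
                                 function(f, w) (f - 1L) * 3L + w)))
        bwd <- as.vector(t(outer(rev(seq_len(n_features)), 1:3,
                                 function(f, w) (f - 1L) * 3L + w)))
        orderings <- list(fwd, bwd)
      }
    }
    if (length(orderings) != n_subtypes) {
      abort("Need one ordering per subtype.", class = "netdax_error_argument")
    }
    for (o in orderings) check_ordering(o, n_features)
    expected <- lapply(orderings, stage_expected_z,
                       n_features = n_features, z_max = z_max)
    if (is.null(stage_distribution)) {
      stage_distribution <- rep(1 / (n_events + 1), n_events + 1)
    }
    subtype <- sample.int(n_subtypes, n_subjects, replace = TRUE)
    stage <- sample(0:n_events, n_subjects, replace = TRUE,
                    prob = stage_distribution)
    z <- t(vapply(seq_len(n_subjects), function(i) {
      expected[[subtype[i]]][stage[i] + 1L, ] + rnorm(n_features, 0, sigma)
    }, numeric(n_features)))
    colnames(z) <- paste0("f", seq_len(n_features))
    truth <- structure(
      list(subtype = subtype, stage = stage, orderings = orderings,
           sigma = sigma, z_max = z_max),
      class = "ground_truth"
    )
    list(z = z, truth = truth)
  })
}

#' Simulate paired feature blocks with a planted sparse cross-block latent
#'
#' One shared latent variable loads on a sparse subset of columns in each
#' block with a controlled cross-block correlation; all remaining columns are
#' independent noise. This is the ground-truth substrate for sparse CCA
#' recovery and calibration tests.
#'
#' @param n Number of observations.
#' @param p,q Number of columns in blocks X and Y.
#' @param support_sizes Length-2 integer vector: planted support sizes in X
#'   and Y.
#' @param latent_r Cross-block latent correlation, in `[0, 1)`.
#' @param noise_sd Column noise sd around the latent (default 0.3).
#' @param seed Integer seed.
#'
#' @return A list with `X`, `Y` (standardizable matrices) and `truth` carrying
#'   the planted supports and latent variables.
#' @export
simulate_crossblock <- function(n, p, q, support_sizes = c(5, 5),
                                latent_r = 0.8, noise_sd = 0.3, seed = 1L) {
  n <- assert_positive_int(n, "n")
  if (latent_r < 0 || latent_r >= 1) {
    abort("`latent_r` must be in [0, 1).", class = "netdax_error_argument")
  }
  if (support_sizes[1] > p || support_sizes[2] > q) {
    abort("Support sizes cannot exceed block widths.",
          class = "netdax_error_argument")
  }
  with_seed(seed, {
    u <- rnorm(n)
    v <- latent_r * u + sqrt(1 - latent_r^2) * rnorm(n)
    X <- matrix(rnorm(n * p), n, p)
    Y <- matrix(rnorm(n * q), n, q)
    sx <- seq_len(support_sizes[1])
    sy <- seq_len(support_sizes[2])
    X[, sx] <- u + matrix(rnorm(n * length(sx)), n) * noise_sd
    Y[, sy] <- v + matrix(rnorm(n * length(sy)), n) * noise_sd
    colnames(X) <- paste0("x", seq_len(p))
    colnames(Y) <- paste0("y", seq_len(q))
    truth <- structure(
      list(support_x = sx, support_y = sy, u = u, v = v, latent_r = latent_r),
      class = "ground_truth"
    )
    list(X = X, Y = Y, truth = truth)
  })
}
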