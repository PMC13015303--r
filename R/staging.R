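#' Prepare w-score features for event-based staging
#'
#' Sign-aligns each feature on its patient-sample mean direction so that
#' larger values always mean increasing abnormality (the monotone-progression
#' assumption of the event model), and records the alignment vector for
#' inversion. Features with exactly zero patient mean are left unflipped and
#' flagged. Applying the alignment twice is idempotent on signs.
#'
#' @param w Subjects x features matrix of w-scores.
#' @param features Character vector of feature columns to use (default all).
#' @param patient Logical vector marking the rows whose mean direction
#'   defines the alignment (default all rows).
#' @param z_max Trajectory endpoint abnormality (default 5).
#' @param sigma Per-feature noise sd (scalar or vector; default 1, features
#'   being z-scaled).
#' @return A list with `z` (aligned matrix) and `event_model` (class
#'   `event_model`: features, n_events = 3F, waypoints 1/2/3, `alignment`,
#'   `z_max`, `sigma`, `flagged`).
#' @export
prepare_features <- function(w, features = colnames(w), patient = NULL,
                             z_max = 5, sigma = 1) {
  w <- as.matrix(w)
  if (is.null(colnames(w))) colnames(w) <- paste0("f", seq_len(ncol(w)))
  if (is.null(features)) features <- colnames(w)
  missing_f <- setdiff(features, colnames(w))
  if (length(missing_f) > 0) {
    abort(sprintf("Features not present: %s", paste(missing_f, collapse = ", ")),
          class = "netdax_error_argument")
  }
  z <- w[, features, drop = FALSE]
  if (is.null(patient)) patient <- rep(TRUE, nrow(z))
  m <- colMeans(z[patient, , drop = FALSE])
  alignment <- sign(m)
  flagged <- alignment == 0
  alignment[flagged] <- 1
  z_aligned <- sweep(z, 2, alignment, "*")
  em <- structure(
    list(features = features, n_features = length(features),
         n_events = 3L * length(features), waypoints = c(1, 2, 3),
         alignment = alignment, z_max = z_max,
         sigma = rep_len(sigma, length(features)), flagged = flagged),
    class = "event_model"
  )
  list(z = z_aligned, event_model = em)
}

#' @export
print.event_model <- function(x, ...) {
  cat(sprintf("<event_model> %d features, %d events (waypoints %s), z_max = %g\n",
              x$n_features, x$n_events, paste(x$waypoints, collapse = "/"), x$z_max))
  invisible(x)
}

# Fast piecewise-linear stage-expected z for all features given waypoint
# positions; equivalent to stage_expected_z() but avoids per-call validation.
expected_from_positions <- function(pos, n_events, z_max) {
  stages <- 0:n_events
  F <- nrow(pos)
  out <- matrix(0, n_events + 1L, F)
  for (f in seq_len(F)) {
    xs <- c(0, pos[f, ], n_events)
    ys <- c(0, 1, 2, 3, max(z_max, 3))
    if (pos[f, 3] == n_events) { xs <- xs[1:4]; ys <- ys[1:4] }
    seg <- findInterval(stages, xs, rightmost.closed = TRUE)
    seg[seg < 1] <- 1
    seg[seg >= length(xs)] <- length(xs) - 1L
    x0 <- xs[seg]; x1 <- xs[seg + 1L]
    y0 <- ys[seg]; y1 <- ys[seg + 1L]
    # xs is strictly increasing (waypoint positions are distinct stages)
    out[, f] <- y0 + (y1 - y0) * (stages - x0) / (x1 - x0)
  }
  out
}

ordering_positions <- function(ordering, n_features) {
  pos <- match(seq_len(3L * n_features), ordering)
  matrix(pos, n_features, 3L, byrow = TRUE)
}

# Precomputed context for repeated likelihood evaluations on one data set.
make_ll_ctx <- function(z, em) {
  zs <- sweep(as.matrix(z), 2, em$sigma, "/")
  list(zs = zs, rz2 = rowSums(zs^2),
       const = -sum(log(em$sigma)) - em$n_features / 2 * log(2 * pi),
       em = em)
}

stage_loglik_ctx <- function(ctx, ordering) {
  em <- ctx$em
  pos <- ordering_positions(ordering, em$n_features)
  E <- expected_from_positions(pos, em$n_events, em$z_max)
  Es <- E / rep(em$sigma, each = nrow(E))
  m <- tcrossprod(ctx$zs, Es)
  m <- m - 0.5 * rep(rowSums(Es^2), each = nrow(m))
  m - 0.5 * ctx$rz2 + ctx$const
}

# n x (N+1) log-likelihood of each subject at each stage under one ordering.
stage_loglik_matrix <- function(z, ordering, em) {
  stage_loglik_ctx(make_ll_ctx(z, em), ordering)
}

log_sum_exp_rows <- function(m) {
  mx <- m[cbind(seq_len(nrow(m)), max.col(m, ties.method = "first"))]
  mx + log(rowSums(exp(m - mx)))
}

#' Stage-marginalized sequence log-likelihood
#'
#' For one event ordering, computes each subject's log-likelihood averaged
#' over stages 0..N with a uniform stage prior; feature likelihoods are
#' Gaussian around the piecewise-linear waypoint trajectory. Computed in
#' log space for stability.
#'
#' @param z Aligned subjects x features matrix (see [prepare_features()]).
#' @param ordering Admissible event ordering.
#' @param em The `event_model`.
#' @return Numeric vector of per-subject log-likelihoods, with the full
#'   n x (N+1) per-stage log-likelihood matrix as attribute `stage_loglik`.
#' @export
sequence_likelihood <- function(z, ordering, em) {
  stopifnot(inherits(em, "event_model"))
  check_ordering(ordering, em$n_features)
  sl <- stage_loglik_matrix(as.matrix(z), ordering, em)
  ll <- log_sum_exp_rows(sl) - log(ncol(sl))
  attr(ll, "stage_loglik") <- sl
  ll
}

# Weighted total log-likelihood of an ordering (weights = responsibilities).
ordering_score <- function(z, ordering, em, weights = NULL) {
  ordering_score_ctx(make_ll_ctx(z, em), ordering, weights)
}

ordering_score_ctx <- function(ctx, ordering, weights = NULL) {
  sl <- stage_loglik_ctx(ctx, ordering)
  ll <- log_sum_exp_rows(sl) - log(ncol(sl))
  if (is.null(weights)) sum(ll) else sum(weights * ll)
}

# Greedy ascent: repeatedly remove one event and reinsert it at the best
# admissible position until no move improves the weighted log-likelihood.
greedy_ordering <- function(z, em, start, weights = NULL, max_pass = 4L,
                            ctx = NULL) {
  if (is.null(ctx)) ctx <- make_ll_ctx(z, em)
  ord <- start
  best <- ordering_score_ctx(ctx, ord, weights)
  trace <- best
  n_ev <- em$n_events
  for (pass in seq_len(max_pass)) {
    improved <- FALSE
    for (ev in sample(n_ev)) {
      cur_pos <- match(ev, ord)
      base <- ord[-cur_pos]
      f <- (ev - 1L) %/% 3L + 1L
      w_id <- (ev - 1L) %% 3L + 1L
      sibs <- (f - 1L) * 3L + 1:3
      lo <- if (w_id > 1) match(sibs[w_id - 1L], base) + 1L else 1L
      hi <- if (w_id < 3) match(sibs[w_id + 1L], base) else n_ev
      cand <- lo:hi
      scores <- vapply(cand, function(p) {
        ordering_score_ctx(ctx, append(base, ev, after = p - 1L), weights)
      }, numeric(1))
      top <- which.max(scores)
      if (scores[top] > best + 1e-9) {
        ord <- append(base, ev, after = cand[top] - 1L)
        best <- scores[top]
        improved <- TRUE
      }
      trace <- c(trace, best)
    }
    if (!improved) break
  }
  list(ordering = ord, loglik = best, trace = trace)
}

# Non-throwing admissibility check (hot path: called per MCMC proposal).
is_admissible <- function(ordering, n_features) {
  pos <- match(seq_len(3L * n_features), ordering)
  all(pos[seq(1, by = 3, length.out = n_features)] <
        pos[seq(2, by = 3, length.out = n_features)] &
      pos[seq(2, by = 3, length.out = n_features)] <
        pos[seq(3, by = 3, length.out = n_features)])
}

propose_swap <- function(ord, n_features) {
  n_ev <- length(ord)
  for (try in 1:20) {
    ij <- sample(n_ev, 2)
    new <- ord
    new[ij] <- new[ij[2:1]]
    if (is_admissible(new, n_features)) return(new)
  }
  ord
}

# Mixture log-likelihood and responsibilities for a set of orderings; `comp`
# columns (per-component marginal log-likelihoods) can be supplied/reused.
mixture_eval <- function(z, orderings, fractions, em, ctx = NULL, comp = NULL) {
  if (is.null(ctx)) ctx <- make_ll_ctx(z, em)
  n <- nrow(ctx$zs)
  C <- length(orderings)
  if (is.null(comp)) {
    comp <- vapply(orderings, function(o) {
      log_sum_exp_rows(stage_loglik_ctx(ctx, o)) - log(em$n_events + 1)
    }, numeric(n))
    comp <- matrix(comp, n, C)
  }
  lw <- sweep(comp, 2, log(fractions), "+")
  tot <- log_sum_exp_rows(matrix(lw, n))
  resp <- exp(lw - tot)
  list(loglik = sum(tot), resp = resp, comp = comp)
}

component_ll <- function(ctx, ordering) {
  log_sum_exp_rows(stage_loglik_ctx(ctx, ordering)) - log(ctx$em$n_events + 1)
}

fit_mixture <- function(z, em, orderings, n_mcmc, seed_stream, n_em = 4L,
                        ctx = NULL) {
  if (is.null(ctx)) ctx <- make_ll_ctx(z, em)
  C <- length(orderings)
  fractions <- rep(1 / C, C)
  for (round in seq_len(n_em)) {
    ev <- mixture_eval(z, orderings, fractions, em, ctx = ctx)
    fractions <- pmax(colMeans(ev$resp), 1e-6)
    fractions <- fractions / sum(fractions)
    if (C > 1) {
      for (c in seq_len(C)) {
        g <- greedy_ordering(z, em, orderings[[c]], weights = ev$resp[, c],
                             max_pass = 2L, ctx = ctx)
        orderings[[c]] <- g$ordering
      }
    }
  }
  # Metropolis MCMC over random admissible pairwise swaps, tracking the best;
  # only the proposed component's marginal likelihood is recomputed
  comp <- vapply(orderings, function(o) component_ll(ctx, o),
                 numeric(nrow(ctx$zs)))
  comp <- matrix(comp, ncol = C)
  ev <- mixture_eval(z, orderings, fractions, em, ctx = ctx, comp = comp)
  best <- list(orderings = orderings, fractions = fractions, loglik = ev$loglik)
  cur_ll <- ev$loglik
  mcmc_ll <- numeric(n_mcmc)
  with_seed(seed_stream, {
    for (it in seq_len(n_mcmc)) {
      c <- sample.int(C, 1)
      prop_ord <- propose_swap(orderings[[c]], em$n_features)
      comp_prop <- comp
      comp_prop[, c] <- component_ll(ctx, prop_ord)
      ev_p <- mixture_eval(z, orderings, fractions, em, ctx = ctx,
                           comp = comp_prop)
      if (log(runif(1)) < ev_p$loglik - cur_ll) {
        orderings[[c]] <- prop_ord
        comp <- comp_prop
        cur_ll <- ev_p$loglik
        if (cur_ll > best$loglik) {
          best <- list(orderings = orderings, fractions = fractions,
                       loglik = cur_ll)
        }
      }
      mcmc_ll[it] <- cur_ll
    }
  })
  ev <- mixture_eval(z, best$orderings, best$fractions, em, ctx = ctx)
  best$fractions <- pmax(colMeans(ev$resp), 1e-6)
  best$fractions <- best$fractions / sum(best$fractions)
  best$loglik <- mixture_eval(z, best$orderings, best$fractions, em,
                              ctx = ctx)$loglik
  best$mcmc_loglik <- mcmc_ll
  best
}

#' Fit the subtype-and-stage event model
#'
#' Hierarchical fit over candidate subtype counts: the one-subtype model is
#' optimized by greedy ascent from `n_start` random admissible orderings
#' followed by Metropolis MCMC over pairwise event swaps; each C-subtype
#' model is initialized by splitting the weakest subtype of the (C-1)-subtype
#' solution in two (2-cluster split of its subjects' MAP stages) and
#' re-optimized with responsibilities-weighted ascent and MCMC.
#'
#' @param z Aligned subjects x features matrix.
#' @param em The `event_model` from [prepare_features()].
#' @param c_range Candidate subtype counts (subset of 1..4).
#' @param n_start Greedy restarts for the one-subtype fit (default 25).
#' @param n_mcmc MCMC iterations per model (default 10000; values below 100
#'   are refused unless `test_mode = TRUE`).
#' @param seed Integer seed.
#' @param test_mode Allow tiny MCMC runs for unit tests.
#' @return An object of class `sustain_fit`: list of models indexed by C,
#'   each with `orderings`, `fractions`, `loglik`, `mcmc_loglik`,
#'   `greedy_trace`.
#' @export
fit_sustain <- function(z, em, c_range = 1:2, n_start = 25L, n_mcmc = 10000L,
                        seed = 1L, test_mode = FALSE) {
  stopifnot(inherits(em, "event_model"))
  z <- as.matrix(z)
  if (nrow(z) < 20 && !test_mode) {
    abort("Need at least 20 subjects.", class = "netdax_error_argument")
  }
  if (n_mcmc < 100 && !test_mode) {
    abort("Fewer than 100 MCMC iterations is only allowed in test mode.",
          class = "netdax_error_argument")
  }
  c_range <- sort(unique(as.integer(c_range)))
  if (any(c_range < 1 | c_range > 4)) {
    abort("Subtype counts must lie in 1..4.", class = "netdax_error_argument")
  }
  seeds <- derive_seeds(seed, n_start + 8L)
  models <- list()
  # one-subtype fit (always needed as the root of the hierarchy)
  starts <- lapply(seq_len(n_start), function(i) {
    with_seed(seeds[i], random_admissible_ordering(em$n_features))
  })
  ctx <- make_ll_ctx(z, em)
  fits1 <- with_seed(seeds[n_start + 1L], {
    lapply(starts, function(s) greedy_ordering(z, em, s, ctx = ctx))
  })
  best1 <- fits1[[which.max(vapply(fits1, `[[`, numeric(1), "loglik"))]]
  m1 <- fit_mixture(z, em, list(best1$ordering), n_mcmc, seeds[n_start + 2L],
                    ctx = ctx)
  m1$greedy_trace <- best1$trace
  models[["1"]] <- m1
  prev <- m1
  for (C in 2:4) {
    if (C > max(c_range)) break
    # split the weakest subtype: the one with the lowest mean responsibility-
    # weighted likelihood; initialize by a 2-cluster split of MAP stages
    ev <- mixture_eval(z, prev$orderings, prev$fractions, em)
    assign_c <- max.col(ev$resp, ties.method = "first")
    weakest <- which.min(vapply(seq_along(prev$orderings), function(c) {
      idx <- assign_c == c
      if (!any(idx)) return(Inf)
      mean(ev$comp[idx, c])
    }, numeric(1)))
    idx_w <- which(assign_c == weakest)
    stages <- apply(stage_loglik_matrix(z, prev$orderings[[weakest]], em), 1,
                    which.max) - 1L
    split_seed <- seeds[n_start + 2L + C]
    halves <- with_seed(split_seed, {
      if (length(idx_w) >= 4 && sd(stages[idx_w]) > 0) {
        km <- stats::kmeans(stages[idx_w], centers = 2, nstart = 5)
        split(idx_w, km$cluster)
      } else {
        split(idx_w, rep(1:2, length.out = length(idx_w)))
      }
    })
    new_orderings <- prev$orderings
    new_orderings[[weakest]] <- NULL
    for (h in halves) {
      init <- prev$orderings[[weakest]]
      g <- if (length(h) >= 3) {
        w <- numeric(nrow(z)); w[h] <- 1
        greedy_ordering(z, em, init, weights = w, max_pass = 2L, ctx = ctx)
      } else {
        list(ordering = init)
      }
      new_orderings[[length(new_orderings) + 1L]] <- g$ordering
    }
    mC <- fit_mixture(z, em, new_orderings, n_mcmc, split_seed + 1L,
                      ctx = ctx)
    models[[as.character(C)]] <- mC
    prev <- mC
  }
  structure(list(models = models[as.character(c_range)], em = em,
                 c_range = c_range),
            class = "sustain_fit")
}

#' @export
print.sustain_fit <- function(x, ...) {
  for (nm in names(x$models)) {
    m <- x$models[[nm]]
    cat(sprintf("  C = %s: loglik %.2f, fractions %s\n", nm, m$loglik,
                paste(sprintf("%.2f", m$fractions), collapse = "/")))
  }
  invisible(x)
}

#' Cross-validated subtype-count selection (CVIC)
#'
#' Splits subjects into folds, fits each candidate subtype count on the
#' training folds, evaluates held-out log-likelihood, and scores each C with
#' `CVIC(C) = -2 * sum(held-out log-likelihood)`. The C minimizing CVIC is
#' selected.
#'
#' @param z Aligned subjects x features matrix.
#' @param em The `event_model`.
#' @param c_range Candidate subtype counts.
#' @param folds Number of folds (default 5; every fold needs >= 3 subjects).
#' @param n_start,n_mcmc,seed,test_mode Passed to [fit_sustain()].
#' @return A list with `c_star` and `cvic` (tibble over candidates).
#' @export
select_model <- function(z, em, c_range = 1:2, folds = 5L, n_start = 5L,
                         n_mcmc = 1000L, seed = 1L, test_mode = FALSE) {
  z <- as.matrix(z)
  n <- nrow(z)
  folds <- assert_positive_int(folds, "folds")
  if (floor(n / folds) < 3) {
    abort("Every fold needs at least 3 subjects.", class = "netdax_error_argument")
  }
  fold_id <- with_seed(seed, sample(rep_len(seq_len(folds), n)))
  heldout <- matrix(0, folds, length(c_range),
                    dimnames = list(NULL, as.character(c_range)))
  for (f in seq_len(folds)) {
    train <- z[fold_id != f, , drop = FALSE]
    test <- z[fold_id == f, , drop = FALSE]
    fit <- fit_sustain(train, em, c_range = c_range, n_start = n_start,
                       n_mcmc = n_mcmc, seed = seed + f, test_mode = TRUE)
    for (cc in as.character(c_range)) {
      m <- fit$models[[cc]]
      ev <- mixture_eval(test, m$orderings, m$fractions, em)
      heldout[f, cc] <- ev$loglik
    }
  }
  cvic <- tibble(C = c_range, cvic = -2 * colSums(heldout))
  list(c_star = c_range[which.min(cvic$cvic)], cvic = cvic)
}

#' Assign maximum-a-posteriori subtype and stage
#'
#' Computes each subject's posterior over (subtype, stage) combinations under
#' a fitted model and returns the MAP assignment. Subjects whose aligned
#' z-scores are all below the first waypoint (z < 1) are classified Stage 0
#' ("network correspondence normal") by the explicit raw-threshold rule,
#' applied on top of the MAP stage.
#'
#' @param model A single model from a `sustain_fit` (e.g.
#'   `fit$models[["2"]]`) or the `sustain_fit` itself plus `C`.
#' @param z Aligned subjects x features matrix.
#' @param em The `event_model`.
#' @param C Subtype count to use when `model` is a `sustain_fit`.
#' @param stage0_rule Apply the all-z-below-1 Stage 0 filter (default TRUE).
#' @return A tibble: `subject`, `subtype`, `stage`, `posterior` (MAP
#'   posterior probability), `stage0_by_rule`.
#' @export
assign_subtype_stage <- function(model, z, em, C = NULL, stage0_rule = TRUE) {
  if (inherits(model, "sustain_fit")) {
    if (is.null(C)) C <- max(model$c_range)
    em <- model$em
    model <- model$models[[as.character(C)]]
  }
  z <- as.matrix(z)
  n <- nrow(z)
  Cn <- length(model$orderings)
  S <- em$n_events + 1L
  joint <- array(NA_real_, c(n, Cn, S))
  for (c in seq_len(Cn)) {
    sl <- stage_loglik_matrix(z, model$orderings[[c]], em)
    joint[, c, ] <- sl + log(model$fractions[c]) - log(S)
  }
  flat <- matrix(joint, n, Cn * S)
  norm <- log_sum_exp_rows(flat)
  post <- exp(flat - norm)
  map_idx <- max.col(post, ties.method = "first")
  subtype <- (map_idx - 1L) %% Cn + 1L
  stage <- (map_idx - 1L) %/% Cn
  map_post <- post[cbind(seq_len(n), map_idx)]
  rule <- apply(z < em$waypoints[1], 1, all)
  if (stage0_rule) stage[rule] <- 0L
  tibble(subject = seq_len(n), subtype = as.integer(subtype),
         stage = as.integer(stage), posterior = map_post,
         stage0_by_rule = rule)
}
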