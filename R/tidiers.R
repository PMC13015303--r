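#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @export
tidy.correspondence_profile <- function(x, ...) {
  tibble(network = seq_along(x$cnr), cnr = unname(x$cnr),
         best_atom = x$best_atom)
}

#' @export
glance.correspondence_profile <- function(x, ...) {
  tibble(normativity = x$normativity, non_normativity = x$non_normativity,
         n_networks = length(x$cnr))
}

#' @export
tidy.subject_networks <- function(x, ...) {
  tibble(atom = seq_len(nrow(x$loadings)),
         support_size = rowSums(x$supports),
         reproducibility = x$reproducibility)
}

#' @export
glance.subject_networks <- function(x, ...) {
  tibble(n_atoms = nrow(x$loadings), model_order = x$model_order,
         mean_reproducibility = mean(x$reproducibility))
}

#' @export
tidy.khubness_map <- function(x, ...) {
  tibble(vertex = seq_along(x$k), k = x$k)
}

#' @export
glance.khubness_map <- function(x, ...) {
  tibble(mean_k = mean(x$k), max_k = max(x$k),
         frac_connector = mean(x$k >= 2))
}

#' @export
tidy.consensus_map <- function(x, ...) x$parcels

#' @export
glance.consensus_map <- function(x, ...) {
  tibble(mean_value = mean(x$parcels$value, na.rm = TRUE),
         n_missing = sum(x$parcels$missing))
}

#' @export
tidy.normative_fit <- function(x, ...) {
  bind_rows(imap(x$models, function(m, nm) {
    tibble(feature = nm, term = seq_along(m$beta), estimate = m$beta,
           sigma = m$sigma, lambda = m$lambda)
  }))
}

#' @export
glance.normative_fit <- function(x, ...) {
  tibble(n_features = length(x$models),
         heteroskedastic = x$models[[1]]$heteroskedastic)
}

#' @export
tidy.sustain_fit <- function(x, ...) {
  bind_rows(imap(x$models, function(m, nm) {
    bind_rows(imap(m$orderings, function(o, c) {
      tibble(n_subtypes = as.integer(nm), subtype = as.integer(c),
             position = seq_along(o), event = o,
             feature = x$em$features[(o - 1L) %/% 3L + 1L],
             waypoint = (o - 1L) %% 3L + 1L)
    }))
  }))
}

#' @export
glance.sustain_fit <- function(x, ...) {
  bind_rows(imap(x$models, function(m, nm) {
    tibble(n_subtypes = as.integer(nm), loglik = m$loglik,
           fractions = paste(sprintf("%.3f", m$fractions), collapse = "/"))
  }))
}

#' @export
tidy.scca_model <- function(x, ...) {
  bind_rows(
    tibble(side = "X", feature = rownames(x$u) %||% paste0("x", seq_len(nrow(x$u))),
           dimension = rep(seq_len(ncol(x$u)), each = nrow(x$u)),
           weight = as.numeric(x$u)),
    tibble(side = "Y", feature = rownames(x$v) %||% paste0("y", seq_len(nrow(x$v))),
           dimension = rep(seq_len(ncol(x$v)), each = nrow(x$v)),
           weight = as.numeric(x$v))
  )
}

#' @export
glance.scca_model <- function(x, ...) {
  tibble(dimension = seq_along(x$cors), canonical_r = x$cors,
         c_x = x$penalties[1], c_y = x$penalties[2])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
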