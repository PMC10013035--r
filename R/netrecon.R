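# Causal-network reconstruction: per-patch conditional G-values,
# length-weighted averaging, bootstrap standard errors, surrogates.

#' Conditional G-values for all ordered pairs of a signal triple
#'
#' For each ordered pair (source -> target) among the three channels, the
#' conditional Granger test of source on target given the remaining channel
#' is computed.
#'
#' @param signals Named list of three equal-length numeric vectors or
#'   [pc_signal]s (typically one standardized stationary patch).
#' @param order AR model order.
#' @param test `"f"` or `"chi2"`.
#' @return A tibble with 6 rows: `source`, `target`, `cond`, `g_value`,
#'   `p_value`, `n` (patch length in samples), `order`. If the patch is too
#'   short for the conditional fit, an empty tibble is returned with a
#'   warning.
#' @export
patch_g_all_pairs <- function(signals, order = 5, test = "f") {
  if (length(signals) != 3 || is.null(names(signals)) ||
      any(names(signals) == "")) {
    stop("`signals` must be a named list of three series", call. = FALSE)
  }
  chans <- names(signals)
  vs <- lapply(signals, sig_values)
  n <- length(vs[[1]])
  # conditional fit needs n - order rows and 3 * order coefficients
  if (n - order < 3 * order + 1) {
    warning(sprintf("patch of %d samples too short for order %d; skipped",
                    n, order), call. = FALSE)
    return(tibble::tibble(source = character(), target = character(),
                          cond = character(), g_value = numeric(),
                          p_value = numeric(), n = integer(),
                          order = integer()))
  }
  rows <- list()
  for (tg in chans) {
    for (src in setdiff(chans, tg)) {
      cd <- setdiff(chans, c(tg, src))
      g <- g_conditional(pc_signal(vs[[tg]], label = tg),
                         pc_signal(vs[[src]], label = src),
                         cond = stats::setNames(list(vs[[cd]]), cd),
                         order = order, test = test)
      rows[[length(rows) + 1]] <- tibble::tibble(
        source = src, target = tg, cond = cd,
        g_value = g$g_value, p_value = g$p_value,
        n = n, order = as.integer(order)
      )
    }
  }
  dplyr::bind_rows(rows)
}

#' Length-weighted mean G-value
#'
#' @param g Numeric vector of per-patch G-values.
#' @param weights Patch lengths (samples) used as weights.
#' @return `sum(weights * g) / sum(weights)`.
#' @export
weighted_mean_g <- function(g, weights) {
  if (length(g) < 1) stop("need at least one record", call. = FALSE)
  if (length(weights) != length(g)) {
    stop("`weights` must match `g`", call. = FALSE)
  }
  sum(weights * g) / sum(weights)
}

#' Bootstrap standard error of a mean
#'
#' Resamples the records with replacement to their original count, takes
#' the unweighted mean of each resample, and returns the standard deviation
#' of the `n_boot` resample means.
#'
#' @param g Numeric vector of per-patch G-values.
#' @param n_boot Number of bootstrap resamples (default 100).
#' @param seed Optional seed.
#' @return The bootstrap standard error (0 for a single record).
#' @export
bootstrap_se <- function(g, n_boot = 100, seed = NULL) {
  k <- length(g)
  if (k < 1) stop("need at least one record", call. = FALSE)
  if (k == 1) return(0)
  means <- with_seed_if(seed, {
    vapply(seq_len(n_boot),
           function(b) mean(g[sample.int(k, k, replace = TRUE)]),
           numeric(1))
  })
  stats::sd(means)
}

#' Aggregate per-patch G records into network edges
#'
#' Groups patch records by directed pair, sleep stage and resolution, and
#' summarises each group with the patch-length-weighted mean G, the
#' bootstrap standard error of the (unweighted) mean, and the patch count.
#'
#' @param records A tibble of per-patch G records with columns `source`,
#'   `target`, `stage`, `resolution`, `g_value`, `n` (as produced by
#'   [reconstruct_network()]'s patch pass).
#' @param n_boot Bootstrap resamples for the standard error.
#' @param seed Optional seed.
#' @param weighted_bootstrap Use length-weighted means inside the bootstrap
#'   instead of unweighted means (default FALSE, matching the weighted
#'   point estimate / unweighted bootstrap convention).
#' @return A tibble with columns `source`, `target`, `stage`, `resolution`,
#'   `g_mean`, `g_se`, `n_patches`, `n_samples`. Pairs with no surviving
#'   patches are absent.
#' @export
network_edges <- function(records, n_boot = 100, seed = NULL,
                          weighted_bootstrap = FALSE) {
  if (nrow(records) == 0) {
    return(tibble::tibble(source = character(), target = character(),
                          stage = character(), resolution = numeric(),
                          g_mean = numeric(), g_se = numeric(),
                          n_patches = integer(), n_samples = integer()))
  }
  grp <- dplyr::group_by(records, .data$source, .data$target, .data$stage,
                         .data$resolution)
  idx <- 0L
  dplyr::ungroup(dplyr::summarise(
    grp,
    g_mean = weighted_mean_g(.data$g_value, .data$n),
    g_se = {
      idx <<- idx + 1L
      s <- if (is.null(seed)) NULL else child_seed(seed, "edge", idx)
      if (weighted_bootstrap) {
        k <- length(.data$g_value)
        if (k == 1) 0 else with_seed_if(s, stats::sd(vapply(
          seq_len(n_boot), function(b) {
            ii <- sample.int(k, k, replace = TRUE)
            weighted_mean_g(.data$g_value[ii], .data$n[ii])
          }, numeric(1))))
      } else {
        bootstrap_se(.data$g_value, n_boot = n_boot, seed = s)
      }
    },
    n_patches = dplyr::n(),
    n_samples = sum(.data$n),
    .groups = "drop"
  ))
}

# Run one subject through coarse-graining, stage partitioning, stationarity
# splitting and per-patch conditional G. Returns the patch-record tibble.
subject_patch_g <- function(subject, subject_id, resolutions, orders,
                            alpha, test) {
  chans <- c("H", "B", "E")
  if (!all(chans %in% names(subject))) {
    stop("subject needs channels H, B, E", call. = FALSE)
  }
  if (is.null(subject$hypnogram)) {
    stop("subject needs a hypnogram", call. = FALSE)
  }
  out <- list()
  for (res in resolutions) {
    coarse <- lapply(subject[chans], function(s) {
      if (res == 1) s else coarse_grain(s, res)
    })
    patches <- partition_by_stage(coarse, subject$hypnogram,
                                  resolution = res)
    for (i in seq_len(nrow(patches))) {
      seg <- patches$signals[[i]]
      sp <- split_patches(seg, resolution = res, orders = orders,
                          alpha = alpha)
      for (j in seq_len(nrow(sp))) {
        sub <- lapply(seg, function(v) v[sp$start[j]:sp$end[j]])
        # re-standardize the accepted sub-patch (the no-intercept AR models
        # assume zero-mean inputs)
        sds <- vapply(sub, stats::sd, numeric(1))
        if (any(sds == 0)) next
        sub <- lapply(sub, function(v) (v - mean(v)) / stats::sd(v))
        rec <- withCallingHandlers(
          patch_g_all_pairs(sub, order = sp$order[j], test = test),
          warning = function(w) invokeRestart("muffleWarning")
        )
        if (nrow(rec) == 0) next
        rec$subject <- subject_id
        rec$stage <- patches$stage[i]
        rec$resolution <- res
        out[[length(out) + 1]] <- rec
      }
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(source = character(), target = character(),
                          cond = character(), g_value = numeric(),
                          p_value = numeric(), n = integer(),
                          order = integer(), subject = character(),
                          stage = character(), resolution = numeric()))
  }
  dplyr::bind_rows(out)
}

#' Reconstruct a sleep-stage causal network from a cohort
#'
#' Full pipeline: for every subject and temporal resolution the three 1 Hz
#' channels are block-averaged, partitioned into same-stage patches
#' (standardized, wake excluded), recursively split until stationary
#' ([split_patches()]), and the six conditional G-values are computed per
#' accepted patch at its accepted model order. Patch records are pooled
#' across subjects and aggregated into directed edges per stage and
#' resolution with length-weighted means and bootstrap standard errors.
#'
#' @param cohort List of subjects; each subject is a list with 1 Hz
#'   [pc_signal]s `H`, `B`, `E` and a character `hypnogram` (one stage code
#'   per 30 s epoch). A single subject may be passed directly.
#' @param resolutions Temporal resolutions in seconds per sample (block
#'   sizes applied to the 1 Hz series).
#' @param orders Stationarity/AR model orders tried in sequence.
#' @param alpha ADF significance level.
#' @param test `"f"` or `"chi2"` for the per-patch G tests.
#' @param n_boot Bootstrap resamples for edge standard errors.
#' @param seed Optional seed (bootstrap only; the pipeline itself is
#'   deterministic).
#' @return An object of class `causal_network`: a list with `edges` (see
#'   [network_edges()]) and `patches` (all per-patch records).
#' @export
reconstruct_network <- function(cohort, resolutions = c(1, 2, 5, 10, 15),
                                orders = c(5, 4, 3), alpha = 0.05,
                                test = "f", n_boot = 100, seed = NULL) {
  if (!is.null(cohort$H)) cohort <- list(cohort)
  ids <- names(cohort)
  if (is.null(ids)) ids <- sprintf("s%02d", seq_along(cohort))
  recs <- dplyr::bind_rows(lapply(seq_along(cohort), function(i) {
    subject_patch_g(cohort[[i]], ids[i], resolutions, orders, alpha, test)
  }))
  edges <- network_edges(recs, n_boot = n_boot, seed = seed)
  structure(list(edges = edges, patches = recs), class = "causal_network")
}

#' @export
print.causal_network <- function(x, ...) {
  cat(sprintf("<causal_network> %d edges from %d patch records\n",
              nrow(x$edges), nrow(x$patches)))
  print(x$edges, n = 20)
  invisible(x)
}

#' Surrogate network from inter-subject channel recombination
#'
#' Destroys all genuine couplings by reassembling pseudo-subjects whose
#' three channels come from three different subjects (a fixed cyclic
#' derangement of the cohort indices: subject i donates H, subject i+1
#' donates B, subject i+2 donates E, modulo the cohort size). Channels are
#' truncated to the shortest donor; the hypnogram is taken from the
#' heart-rate donor. The standard pipeline is then applied, yielding the
#' no-causality baseline network.
#'
#' @inheritParams reconstruct_network
#' @return A `causal_network` of surrogate edges.
#' @export
surrogate_network <- function(cohort, resolutions = c(1, 2, 5, 10, 15),
                              orders = c(5, 4, 3), alpha = 0.05,
                              test = "f", n_boot = 100, seed = NULL) {
  ns <- length(cohort)
  if (ns < 3) {
    stop("surrogate recombination needs at least 3 subjects", call. = FALSE)
  }
  rot <- function(i, k) ((i - 1 + k) %% ns) + 1
  pseudo <- lapply(seq_len(ns), function(i) {
    donors <- list(H = cohort[[i]], B = cohort[[rot(i, 1)]],
                   E = cohort[[rot(i, 2)]])
    nmin <- min(length(donors$H$H$values), length(donors$B$B$values),
                length(donors$E$E$values))
    hyp <- donors$H$hypnogram
    nmin <- min(nmin, length(hyp) * 30L)
    list(
      H = pc_signal(donors$H$H$values[seq_len(nmin)], dt = 1, label = "H"),
      B = pc_signal(donors$B$B$values[seq_len(nmin)], dt = 1, label = "B"),
      E = pc_signal(donors$E$E$values[seq_len(nmin)], dt = 1, label = "E"),
      hypnogram = hyp[seq_len(ceiling(nmin / 30))]
    )
  })
  names(pseudo) <- sprintf("surrogate%02d", seq_len(ns))
  reconstruct_network(pseudo, resolutions = resolutions, orders = orders,
                      alpha = alpha, test = test, n_boot = n_boot,
                      seed = seed)
}

#' Write / read a network edge table
#'
#' Serializes the edge tibble of a [reconstruct_network()] result as TSV
#' (lossless round-trip of the numeric columns).
#'
#' @param network A `causal_network` or an edge tibble.
#' @param path Output file.
#' @return `write_network()` returns `path` invisibly; `read_network()`
#'   returns the edge tibble.
#' @export
write_network <- function(network, path) {
  edges <- if (inherits(network, "causal_network")) network$edges else network
  readr::write_tsv(edges, path)
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    source = readr::col_character(), target = readr::col_character(),
    stage = readr::col_character(), resolution = readr::col_double(),
    g_mean = readr::col_double(), g_se = readr::col_double(),
    n_patches = readr::col_integer(), n_samples = readr::col_integer()
  ))
}
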