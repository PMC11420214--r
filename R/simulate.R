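#' Synthetic genotype-activity landscape
#'
#' Stand-in for the unknown true genotype-to-activity map of a selection
#' experiment: a small set of high-activity centroid sequences whose activity
#' decays exponentially with Hamming distance, over a flat background — the
#' "isolated peaks separated by low-activity valleys" picture of rugged RNA
#' fitness landscapes.
#'
#' @param centroids data frame with columns `sequence`, `k_max` (per hour),
#'   `tau` (decay length in mutations, > 0) and optionally `chemistry`
#'   (default "PPP").
#' @param background background rate constant (per hour), below every k_max.
#' @return object of class `activity_landscape`.
#' @export
activity_landscape <- function(centroids, background = 1e-5) {
  stopifnot(is.data.frame(centroids),
            all(c("sequence", "k_max", "tau") %in% names(centroids)))
  if (is.null(centroids$chemistry)) centroids$chemistry <- "PPP"
  centroids$sequence <- normalize_rna(centroids$sequence)
  stopifnot(all(centroids$k_max > background), all(centroids$tau > 0))
  structure(list(centroids = centroids, background = background),
            class = "activity_landscape")
}

#' Activity of a sequence on a synthetic landscape
#'
#' `k = background + max_centroids (k_max - background) * exp(-d / tau)` with
#' `d` the Hamming distance to each centroid, per substrate chemistry.
#' Deterministic in its inputs.
#'
#' @param landscape an [activity_landscape()].
#' @param sequence RNA string matching the centroid length.
#' @param chemistry chemistry tag to evaluate (default the landscape's first).
#' @return rate constant (per hour).
#' @export
activity_of <- function(landscape, sequence, chemistry = NULL) {
  cen <- landscape$centroids
  if (is.null(chemistry)) chemistry <- cen$chemistry[1]
  cen <- cen[cen$chemistry == chemistry, , drop = FALSE]
  if (!nrow(cen)) return(landscape$background)
  d <- vapply(cen$sequence, hamming_distance, integer(1), b = sequence)
  landscape$background +
    max((cen$k_max - landscape$background) * exp(-d / cen$tau))
}

# Vectorized activity over many sequences (selection-round workhorse).
activities_of <- function(landscape, sequences, chemistry = NULL) {
  cen <- landscape$centroids
  if (is.null(chemistry)) chemistry <- cen$chemistry[1]
  cen <- cen[cen$chemistry == chemistry, , drop = FALSE]
  if (!nrow(cen)) return(rep(landscape$background, length(sequences)))
  contrib <- vapply(seq_len(nrow(cen)), function(i) {
    d <- hamming_to_reference(sequences, cen$sequence[i])
    (cen$k_max[i] - landscape$background) * exp(-d / cen$tau[i])
  }, numeric(length(sequences)))
  if (length(sequences) == 1L) contrib <- matrix(contrib, nrow = 1)
  landscape$background + apply(contrib, 1, max)
}

#' Sample a doped library
#'
#' Draws `n` independent library members: each position of the parent mutates
#' with probability `model$mutation_rate`, choosing uniformly among the three
#' non-parent bases. Reproducible given `seed`; the global RNG state is left
#' untouched.
#'
#' @param model a [doped_library_model()].
#' @param parent parent sequence, `nchar == model$length`.
#' @param n number of molecules to draw.
#' @param seed integer seed (mandatory).
#' @return character vector of length `n` (a multiset of sequences).
#' @export
sample_doped_library <- function(model, parent, n, seed) {
  parent <- normalize_rna(parent)
  if (nchar(parent) != model$length) {
    stop("parent length does not match model$length")
  }
  stopifnot(!missing(seed))
  pc <- strsplit(parent, "", fixed = TRUE)[[1]]
  L <- model$length
  withr::with_seed(as.integer(seed), {
    mut <- matrix(stats::runif(n * L) < model$mutation_rate, n, L)
    m <- matrix(pc, n, L, byrow = TRUE)
    if (any(mut)) {
      idx <- which(mut)
      orig <- m[idx]
      # uniform among the 3 non-parent bases: offset 1..3 in the alphabet
      pos <- match(orig, RNA_ALPHABET)
      off <- sample.int(3L, length(idx), replace = TRUE)
      m[idx] <- RNA_ALPHABET[((pos - 1L + off) %% 4L) + 1L]
    }
    apply(m, 1, paste, collapse = "")
  })
}

#' Selection-round configuration
#'
#' Per-round stringency of an activity-based selection: reaction time (h) and
#' a multiplicative Mg2+ scaling applied to every rate constant (a scaling
#' below 1 emulates lowering the Mg2+ concentration below saturation).
#'
#' @param model a [doped_library_model()].
#' @param parent parent sequence.
#' @param rounds number of selection rounds (>= 1).
#' @param times reaction time per round, hours (length `rounds` or 1).
#' @param mg_scale Mg2+ rate scaling per round (length `rounds` or 1).
#' @param seq_depth reads sequenced per round.
#' @param amp_depth molecules after amplification, per round.
#' @param spike optional named numeric vector of sequences to add to the
#'   round-0 pool at the given copy numbers. A simulated pool samples the
#'   library at far below its true complexity, so specific rare genotypes
#'   (e.g. the eventual selection winner, present among ~1e15 molecules but
#'   vanishingly unlikely in a tractable subsample) must be planted
#'   explicitly to be observable.
#' @param seed integer seed (mandatory).
#' @return list of class `selection_config`.
#' @export
selection_config <- function(model, parent, rounds = 6L,
                             times = c(15, 10, 5, 2, 1, 0.5),
                             mg_scale = c(1, 1, 0.75, 0.5, 0.33, 0.25),
                             seq_depth = 1e5, amp_depth = 1e6,
                             spike = NULL, seed) {
  stopifnot(rounds >= 1, seq_depth >= 1, amp_depth >= 1, !missing(seed))
  times <- rep_len(times, rounds)
  mg_scale <- rep_len(mg_scale, rounds)
  if (!is.null(spike)) {
    stopifnot(!is.null(names(spike)), all(spike >= 1))
    names(spike) <- normalize_rna(names(spike))
  }
  structure(list(model = model, parent = normalize_rna(parent),
                 rounds = as.integer(rounds), times = times,
                 mg_scale = mg_scale, seq_depth = seq_depth,
                 amp_depth = amp_depth, spike = spike,
                 seed = as.integer(seed)),
            class = "selection_config")
}

#' Simulate one round of activity-based selection
#'
#' Three seeded stages acting on a named count vector of molecules:
#' survival — each molecule ligates (and is captured) with probability
#' `p = 1 - exp(-k * time * mg_scale)`, applied as binomial thinning per
#' sequence; amplification — multinomial resampling of the survivors up to
#' `amp_depth` molecules; sequencing — multinomial subsampling down to
#' `seq_depth` reads. If no molecule survives, an error of class
#' `extinction_error` is signaled.
#'
#' @param pool named numeric vector: counts by sequence.
#' @param landscape an [activity_landscape()].
#' @param time reaction time (h).
#' @param mg_scale multiplicative Mg2+ rate scaling.
#' @param amp_depth,seq_depth amplification and sequencing depths.
#' @param seed integer seed (mandatory).
#' @param chemistry chemistry tag evaluated on the landscape.
#' @return named numeric vector of sequencing counts (zeros dropped).
#' @export
simulate_round <- function(pool, landscape, time, mg_scale = 1,
                           amp_depth = 1e6, seq_depth = 1e5, seed,
                           chemistry = NULL) {
  stopifnot(length(pool) > 0, !missing(seed))
  seqs <- names(pool)
  k <- activities_of(landscape, seqs, chemistry)
  p <- 1 - exp(-k * time * mg_scale)
  withr::with_seed(as.integer(seed), {
    survivors <- stats::rbinom(length(pool), size = round(pool), prob = p)
    if (sum(survivors) == 0) {
      stop(structure(class = c("extinction_error", "error", "condition"),
                     list(message = "pool went extinct: no molecule survived selection",
                          call = sys.call(-1))))
    }
    amplified <- stats::rmultinom(1, size = amp_depth,
                                  prob = survivors / sum(survivors))[, 1]
    sequenced <- stats::rmultinom(1, size = seq_depth,
                                  prob = amplified / sum(amplified))[, 1]
    out <- stats::setNames(as.numeric(sequenced), seqs)
    out[out > 0]
  })
}

#' Simulate a full selection experiment
#'
#' Samples a doped library from the configured parent, then chains
#' [simulate_round()] across rounds with the configured per-round stringency
#' (escalating by shortening reaction times and lowering the Mg2+ scaling).
#' Round 0 is the sequenced starting library. Per-round seeds are derived
#' deterministically from `config$seed`.
#'
#' @param config a [selection_config()].
#' @param landscape an [activity_landscape()].
#' @param chemistry chemistry tag evaluated on the landscape.
#' @return a [seq_count_table()] with rounds 0..`config$rounds`.
#' @export
simulate_selection <- function(config, landscape, chemistry = NULL) {
  stopifnot(inherits(config, "selection_config"))
  lib <- sample_doped_library(config$model, config$parent,
                              n = config$seq_depth, seed = config$seed)
  tab <- table(lib)
  pool <- stats::setNames(as.numeric(tab), names(tab))
  for (s in names(config$spike)) {
    pool[s] <- (if (is.na(pool[s])) 0 else pool[s]) + config$spike[s]
  }
  rows <- list(data.frame(round = 0L, sequence = names(pool),
                          count = unname(pool), stringsAsFactors = FALSE))
  for (r in seq_len(config$rounds)) {
    pool <- tryCatch(
      simulate_round(pool, landscape,
                     time = config$times[r], mg_scale = config$mg_scale[r],
                     amp_depth = config$amp_depth,
                     seq_depth = config$seq_depth,
                     seed = config$seed + 1000L * r,
                     chemistry = chemistry),
      extinction_error = function(e) {
        stop("selection went extinct at round ", r, call. = FALSE)
      })
    rows[[r + 1L]] <- data.frame(round = r, sequence = names(pool),
                                 count = unname(pool),
                                 stringsAsFactors = FALSE)
  }
  seq_count_table(do.call(rbind, rows))
}

#' Generate noisy synthetic kinetic data
#'
#' Evaluates a kinetic model on a design and applies multiplicative
#' log-normal noise (`value * exp(sigma * z)` with standard normal `z`) for
#' time courses and titrations; pH series instead receive Gaussian noise of
#' standard deviation `sigma` directly on `log10 k_obs`, the scale on which
#' pH-rate profiles are fitted. Reproducible given `seed`.
#'
#' @param type `"first_order"`, `"hill"` or `"ph"`.
#' @param design numeric vector: times (h), concentrations (mM) or pH values.
#' @param truth named list of true parameters — first_order: `k`, `A`;
#'   hill: `k_max`, `K_half`, `n`; ph: `slope`, `intercept` (log10 scale).
#' @param sigma noise level (0 gives exact model values).
#' @param seed integer seed (mandatory).
#' @return data frame with the design column (`time_h`, `conc_mM` or `pH`)
#'   and the response (`fraction` or `kobs_h`).
#' @export
generate_kinetics <- function(type = c("first_order", "hill", "ph"),
                              design, truth, sigma = 0, seed) {
  type <- match.arg(type)
  stopifnot(!missing(seed), sigma >= 0)
  withr::with_seed(as.integer(seed), {
    z <- stats::rnorm(length(design))
    switch(type,
      first_order = {
        stopifnot(truth$k > 0, truth$A > 0)
        f <- truth$A * (1 - exp(-truth$k * design)) * exp(sigma * z)
        data.frame(time_h = design, fraction = pmin(f, 1))
      },
      hill = {
        stopifnot(truth$k_max > 0, truth$K_half > 0, truth$n > 0)
        k <- truth$k_max * design^truth$n /
          (truth$K_half^truth$n + design^truth$n)
        data.frame(conc_mM = design, kobs_h = k * exp(sigma * z))
      },
      ph = {
        logk <- truth$slope * design + truth$intercept + sigma * z
        data.frame(pH = design, kobs_h = 10^logk)
      })
  })
}

#' Write a dataset with a JSON provenance record
#'
#' Writes `data` as TSV and a sibling `<path>.json` recording the generating
#' parameters and seed, so every synthetic dataset is self-describing.
#'
#' @param data data frame.
#' @param path output TSV path.
#' @param params list of generating parameters (must include the seed).
#' @return the path, invisibly.
#' @export
write_with_provenance <- function(data, path, params) {
  utils::write.table(data, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(params, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
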