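# Seeded synthetic-data generation. The generator emulates the two xylan
# populations the analysis targets: rigid twofold-screw xylan with a
# cellulose-like order parameter and long T1, and mobile threefold-screw
# xylan with a low order parameter and short T1. CP-like excitation weights
# rigid species, DP-like (long-recycle, quantitative) excitation weights by
# abundance. Every generator records its ground truth alongside the data.

#' Population and noise specification for synthetic datasets
#'
#' @param populations data frame with columns `name`, `conformation`
#'   (`"twofold"`/`"threefold"`), `s_ch` (truth, in \[0,1\]), `t1_s` (truth,
#'   s), `abundance` (>= 0), `mobility` (`"rigid"`/`"mobile"`).
#' @param noise_sigma Gaussian noise standard deviation on normalized curve
#'   intensities.
#' @param seed integer seed; identical (spec, seed) gives identical output.
#' @param config an [experiment_config()].
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(populations = default_populations("wild-type-like"),
                           noise_sigma = 0.02, seed = 1L,
                           config = experiment_config()) {
  need <- c("name", "conformation", "s_ch", "t1_s", "abundance", "mobility")
  if (!is.data.frame(populations) || !all(need %in% names(populations)))
    stop("populations needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (any(populations$abundance < 0))
    stop("abundances must be non-negative", call. = FALSE)
  if (any(populations$s_ch < 0 | populations$s_ch > 1))
    stop("s_ch truths must lie in [0, 1]", call. = FALSE)
  if (any(populations$t1_s <= 0))
    stop("t1 truths must be positive", call. = FALSE)
  if (!all(populations$mobility %in% c("rigid", "mobile")))
    stop("mobility must be 'rigid' or 'mobile'", call. = FALSE)
  structure(list(populations = populations,
                 noise_sigma = noise_sigma,
                 seed = as.integer(seed),
                 config = config),
            class = "synthetic_spec")
}

#' Default population mixtures per genotype
#'
#' Wild-type-like stems are dominated by rigid cellulose-bound twofold xylan;
#' the cellulose-deficient mutant is dominated by mobile threefold xylan. The
#' order-parameter truths (0.9 vs 0.4), T1 truths (4.0 s vs 0.8 s) and
#' abundances are illustrative values consistent with the qualitative
#' rigid/mobile contrast, not measured numbers.
#'
#' @param genotype `"wild-type-like"` or `"irx3-like"`.
#' @return data frame accepted by [synthetic_spec()].
#' @export
default_populations <- function(genotype = c("wild-type-like", "irx3-like")) {
  genotype <- match.arg(genotype)
  if (genotype == "wild-type-like") {
    data.frame(name = c("xylan-twofold", "xylan-threefold"),
               conformation = c("twofold", "threefold"),
               s_ch = c(0.9, 0.4), t1_s = c(4.0, 0.8),
               abundance = c(0.85, 0.15),
               mobility = c("rigid", "mobile"))
  } else {
    data.frame(name = c("xylan-twofold", "xylan-threefold"),
               conformation = c("twofold", "threefold"),
               s_ch = c(0.9, 0.4), t1_s = c(4.0, 0.8),
               abundance = c(0.05, 0.95),
               mobility = c("rigid", "mobile"))
  }
}

excitation_weights <- function(spec, excitation, mobile_cp_weight) {
  w <- spec$populations$abundance
  if (excitation == "cp-like")
    w <- w * ifelse(spec$populations$mobility == "rigid", 1, mobile_cp_weight)
  w
}

#' Generate a synthetic DIPSHIFT dataset
#'
#' Simulates one dephasing curve per population at its true order parameter,
#' scales it by the excitation weight (CP-like: rigid populations at full
#' weight, mobile populations down-weighted; DP-like: abundance-proportional)
#' and adds i.i.d. Gaussian noise. The ground truth travels with the result.
#'
#' @param spec a [synthetic_spec()].
#' @param excitation `"cp-like"` or `"dp-like"`.
#' @param mobile_cp_weight CP-like down-weighting factor for mobile
#'   populations (default 0.2).
#' @param powder optional powder scheme (defaults from the spec config).
#' @return named list of [dephasing_curve()]s (one per population), class
#'   `dipshift_dataset`, with attribute `truth` (data frame of truths and
#'   weights).
#' @export
generate_dipshift_dataset <- function(spec,
                                      excitation = c("cp-like", "dp-like"),
                                      mobile_cp_weight = 0.2,
                                      powder = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  excitation <- match.arg(excitation)
  w <- excitation_weights(spec, excitation, mobile_cp_weight)
  if (sum(w) <= 0)
    stop("empty dataset: all excitation weights are zero", call. = FALSE)
  if (is.null(powder)) powder <- default_powder(spec$config)
  set.seed(spec$seed)
  out <- vector("list", nrow(spec$populations))
  names(out) <- spec$populations$name
  for (i in seq_len(nrow(spec$populations))) {
    base <- simulate_dipshift(spec$populations$s_ch[i], spec$config,
                              powder = powder)
    noisy <- w[i] * base$intensity +
      stats::rnorm(nrow(base), sd = spec$noise_sigma)
    out[[i]] <- dephasing_curve(base$t1_us, noisy,
                                meta = list(truth_s_ch = spec$populations$s_ch[i],
                                            weight = w[i],
                                            excitation = excitation))
  }
  truth <- cbind(spec$populations, weight = w,
                 excitation = excitation, noise_sigma = spec$noise_sigma,
                 seed = spec$seed)
  structure(out, truth = truth, class = "dipshift_dataset")
}

#' Generate synthetic saturation-recovery series
#'
#' One exponential recovery per population,
#' \eqn{M(t) = M_{eq}(1 - e^{-t/T_1})} at the population's true T1, plus
#' Gaussian noise of standard deviation `noise_sigma * M_eq`.
#'
#' @param spec a [synthetic_spec()].
#' @param delays recovery delays in seconds (>= 3 values, non-negative).
#' @param m_eq equilibrium magnetization per population (default 1).
#' @return named list of [recovery_curve()]s, class `t1_dataset`, with
#'   attribute `truth`.
#' @export
generate_t1_series <- function(spec, delays, m_eq = 1) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (length(delays) < 3L)
    stop("at least 3 recovery delays are required", call. = FALSE)
  if (any(delays < 0))
    stop("range error: delays must be non-negative", call. = FALSE)
  delays <- sort(unique(delays))
  set.seed(spec$seed + 1L)
  out <- vector("list", nrow(spec$populations))
  names(out) <- spec$populations$name
  for (i in seq_len(nrow(spec$populations))) {
    m <- m_eq * (1 - exp(-delays / spec$populations$t1_s[i])) +
      stats::rnorm(length(delays), sd = spec$noise_sigma * m_eq)
    out[[i]] <- recovery_curve(delays, m)
  }
  truth <- cbind(spec$populations, m_eq = m_eq,
                 noise_sigma = spec$noise_sigma, seed = spec$seed)
  structure(out, truth = truth, class = "t1_dataset")
}

#' Generate a synthetic DQ-SQ peak list for a genotype
#'
#' Emits refocused-INADEQUATE peaks for the bonded xylan carbons in both
#' conformation contexts (and cellulose contexts when assignments are
#' supplied), with genotype-dependent intensities: wild-type-like spectra are
#' dominated by twofold xylan and cellulose, irx3-like spectra by threefold
#' xylan with cellulose suppressed. Gaussian jitter perturbs the SQ shifts;
#' the DQ shift is recomputed as the exact sum of the jittered SQ shifts.
#'
#' @param genotype `"wild-type-like"` or `"irx3-like"`.
#' @param table an [assignment_table()] containing both xylan cell-wall
#'   contexts (default the packaged reference plus synthetic cellulose set).
#' @param seed integer seed.
#' @param jitter_sd SQ shift jitter in p.p.m. (default 0.1).
#' @param intensities named intensity multipliers per context group
#'   (`twofold`, `threefold`, `cellulose`); defaults depend on genotype.
#' @return data frame of class `dq_peak_list` with columns `residue`,
#'   `carbon_a`, `carbon_b`, `context`, `sq_a`, `sq_b`, `dq`, `intensity`,
#'   plus attribute `truth`.
#' @export
generate_peak_list <- function(genotype = c("wild-type-like", "irx3-like"),
                               table = NULL, seed = 1L, jitter_sd = 0.1,
                               intensities = NULL) {
  genotype <- match.arg(genotype)
  if (is.null(table)) {
    xt <- xylan_shift_table()
    ct <- cellulose_shift_table()
    ct$source <- NULL
    table <- assignment_table(rbind(xt, ct))
  } else {
    table <- assignment_table(table)
  }
  for (ctx in c("twofold-cell-wall", "threefold-cell-wall"))
    if (!any(table$context == ctx))
      stop("insufficient data: assignment table lacks context ", ctx,
           call. = FALSE)
  if (is.null(intensities)) {
    intensities <- if (genotype == "wild-type-like")
      c(twofold = 1.0, threefold = 0.15, cellulose = 1.0)
    else
      c(twofold = 0.05, threefold = 1.0, cellulose = 0.05)
  }
  group_of <- function(ctx) {
    if (grepl("^twofold", ctx)) "twofold"
    else if (grepl("^threefold", ctx)) "threefold"
    else "cellulose"
  }
  set.seed(seed)
  pieces <- list()
  for (ctx in unique(table$context)) {
    resids <- unique(table$residue[table$context == ctx])
    for (res in resids) {
      ncarb <- max(table$carbon[table$context == ctx & table$residue == res])
      bonds <- default_bond_list(res, ncarb)
      pk <- suppressWarnings(predict_inadequate_peaks(table, bonds, ctx))
      if (nrow(pk) == 0L) next
      pk$context <- ctx
      pk$sq_a <- pk$sq_a + stats::rnorm(nrow(pk), sd = jitter_sd)
      pk$sq_b <- pk$sq_b + stats::rnorm(nrow(pk), sd = jitter_sd)
      pk$dq <- pk$sq_a + pk$sq_b
      pk$intensity <- intensities[[group_of(ctx)]]
      pieces[[paste(ctx, res)]] <- as.data.frame(pk)
    }
  }
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  attr(out, "truth") <- list(genotype = genotype, seed = seed,
                             jitter_sd = jitter_sd,
                             intensities = intensities)
  class(out) <- c("dq_peak_list", "data.frame")
  out
}

#' Strongest observed shift per xylan carbon from a peak list
#'
#' Collapses a (possibly multi-conformation) DQ-SQ peak list to one shift per
#' carbon of a residue by taking, for each carbon, the SQ shift of the
#' highest-intensity peak in which it participates. The result feeds
#' [classify_conformation()].
#'
#' @param peaks a peak list from [generate_peak_list()].
#' @param residue residue label (default `"Xn"`).
#' @return named numeric vector of shifts (names `"<residue><carbon>"`).
#' @export
dominant_shift_set <- function(peaks, residue = "Xn") {
  pk <- peaks[peaks$residue == residue, , drop = FALSE]
  if (nrow(pk) == 0L)
    stop("insufficient data: no peaks for residue ", residue, call. = FALSE)
  carbons <- sort(unique(c(pk$carbon_a, pk$carbon_b)))
  shifts <- vapply(carbons, function(cc) {
    ia <- which(pk$carbon_a == cc)
    ib <- which(pk$carbon_b == cc)
    cand <- rbind(data.frame(sq = pk$sq_a[ia], int = pk$intensity[ia]),
                  data.frame(sq = pk$sq_b[ib], int = pk$intensity[ib]))
    cand$sq[which.max(cand$int)]
  }, numeric(1))
  names(shifts) <- paste0(residue, carbons)
  shifts
}

#' Write a complete synthetic bundle to disk
#'
#' Generates a genotype's DIPSHIFT curves (CP-like), saturation-recovery
#' series, and DQ-SQ peak list, and writes them as CSV files plus a
#' `truth.json` sidecar holding every ground-truth value used.
#'
#' @param genotype `"wild-type-like"` or `"irx3-like"`.
#' @param dir output directory (created if missing).
#' @param seed integer seed.
#' @param config an [experiment_config()].
#' @param noise_sigma curve noise level (default 0.02).
#' @param delays saturation-recovery delays in seconds.
#' @return invisibly, the vector of file paths written.
#' @export
write_synthetic_bundle <- function(genotype = c("wild-type-like", "irx3-like"),
                                   dir, seed = 1L,
                                   config = experiment_config(),
                                   noise_sigma = 0.02,
                                   delays = c(0.1, 0.25, 0.5, 1, 2, 4, 8, 16)) {
  genotype <- match.arg(genotype)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  spec <- synthetic_spec(default_populations(genotype),
                         noise_sigma = noise_sigma, seed = seed,
                         config = config)
  curves <- generate_dipshift_dataset(spec, "cp-like")
  rec <- generate_t1_series(spec, delays)
  peaks <- generate_peak_list(genotype, seed = seed)
  paths <- character()
  for (nm in names(curves)) {
    p <- file.path(dir, paste0("dipshift_", nm, ".csv"))
    write_curve_csv(curves[[nm]], p)
    paths <- c(paths, p)
  }
  for (nm in names(rec)) {
    p <- file.path(dir, paste0("t1_", nm, ".csv"))
    write_curve_csv(rec[[nm]], p)
    paths <- c(paths, p)
  }
  ppk <- file.path(dir, "peaks.csv")
  utils::write.csv(as.data.frame(peaks), ppk, row.names = FALSE)
  paths <- c(paths, ppk)
  truth <- list(genotype = genotype, seed = seed,
                noise_sigma = noise_sigma,
                populations = spec$populations,
                dipshift = as.data.frame(attr(curves, "truth")),
                t1 = as.data.frame(attr(rec, "truth")),
                peaks = attr(peaks, "truth"))
  ptr <- file.path(dir, "truth.json")
  jsonlite::write_json(truth, ptr, auto_unbox = TRUE, digits = NA)
  paths <- c(paths, ptr)
  invisible(paths)
}
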