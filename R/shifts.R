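# 13C chemical-shift analysis: conformation-dependent shift differences,
# nearest-reference conformation classification, and double-quantum (DQ)
# peak-list prediction for refocused INADEQUATE spectra, where a bonded
# carbon pair shares a DQ shift equal to the sum of the two single-quantum
# (SQ) shifts.

#' Validate / construct a 13C assignment table
#'
#' An assignment table has one row per (residue, carbon, context) with the
#' isotropic 13C shift in p.p.m. Contexts are free labels (e.g.
#' `"twofold-cell-wall"`, `"threefold-solution"`, `"cellulose-domain-1"`).
#' An optional logical `uncertain` column flags tentative assignments, which
#' classification excludes by default.
#'
#' @param df data frame with columns `residue`, `carbon`, `context`,
#'   `shift_ppm` and optionally `uncertain`.
#' @return the validated data frame with class `assignment_table`.
#' @export
assignment_table <- function(df) {
  need <- c("residue", "carbon", "context", "shift_ppm")
  if (!is.data.frame(df) || !all(need %in% names(df)))
    stop("assignment table needs columns residue, carbon, context, shift_ppm",
         call. = FALSE)
  if (!"uncertain" %in% names(df)) df$uncertain <- FALSE
  df$uncertain <- as.logical(df$uncertain)
  df$carbon <- as.integer(df$carbon)
  if (any(!is.finite(df$shift_ppm)) || any(df$shift_ppm < 0) ||
      any(df$shift_ppm > 220))
    stop("shifts must lie within 0-220 p.p.m.", call. = FALSE)
  key <- paste(df$residue, df$carbon, df$context)
  if (anyDuplicated(key))
    stop("duplicate (residue, carbon, context) rows in assignment table",
         call. = FALSE)
  class(df) <- unique(c("assignment_table", class(df)))
  df
}

#' Read an assignment table from CSV
#'
#' @param path CSV file with columns `residue,carbon,context,shift_ppm`
#'   (optional `uncertain`).
#' @return an [assignment_table()].
#' @export
read_assignment_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  assignment_table(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Packaged xylan 13C shift reference table
#'
#' The packaged reference assignments for xylan xylose carbons 1-5 in three
#' contexts: twofold helical screw in the cell wall, threefold screw in the
#' cell wall, and threefold screw in solution. The twofold C3 shift is
#' flagged uncertain (it nearly coincides with cellulose C3).
#'
#' @return an [assignment_table()].
#' @export
xylan_shift_table <- function() {
  read_assignment_table(system.file("extdata", "table1.csv",
                                    package = "wallscrew", mustWork = TRUE))
}

#' Synthetic cellulose shift set (partially literature-backed)
#'
#' Cellulose glucan assignments for the two commonly resolved cellulose
#' domains. Rows with `source == "observed"` carry shifts reported for fresh
#' cell walls; the remaining ring carbons are synthetic stand-ins at typical
#' cellulose values, included so that bonded-pair peak prediction has a
#' complete ring (see the `source` column).
#'
#' @return an [assignment_table()] with an extra `source` column.
#' @export
cellulose_shift_table <- function() {
  read_assignment_table(system.file("extdata",
                                    "cellulose_shifts_synthetic.csv",
                                    package = "wallscrew", mustWork = TRUE))
}

#' Per-carbon shift difference between two contexts
#'
#' Computes delta(context_a) - delta(context_b) for each carbon of a residue.
#' Carbons missing from either context are reported as `NA`, never as zero.
#' Full precision is retained in `difference`; `display` carries the value
#' rounded to 0.1 p.p.m.
#'
#' @param table an [assignment_table()].
#' @param context_a,context_b context labels present in the table.
#' @param residue residue label (default `"Xn"`).
#' @return data frame with columns `residue`, `carbon`, `shift_a`, `shift_b`,
#'   `difference`, `display`, `uncertain`.
#' @examples
#' \dontrun{
#' shift_difference_table(xylan_shift_table(),
#'                        "twofold-cell-wall", "threefold-cell-wall")
#' }
#' @export
shift_difference_table <- function(table, context_a, context_b,
                                   residue = "Xn") {
  table <- assignment_table(table)
  for (ctx in c(context_a, context_b))
    if (!any(table$context == ctx & table$residue == residue))
      stop(sprintf("context '%s' not present for residue '%s'", ctx, residue),
           call. = FALSE)
  a <- table[table$context == context_a & table$residue == residue, ]
  b <- table[table$context == context_b & table$residue == residue, ]
  carbons <- sort(unique(c(a$carbon, b$carbon)))
  sa <- a$shift_ppm[match(carbons, a$carbon)]
  sb <- b$shift_ppm[match(carbons, b$carbon)]
  ua <- a$uncertain[match(carbons, a$carbon)]
  ub <- b$uncertain[match(carbons, b$carbon)]
  diff <- sa - sb
  data.frame(residue = residue, carbon = carbons,
             shift_a = sa, shift_b = sb,
             difference = diff,
             display = round(diff, 1),
             uncertain = (ua %in% TRUE) | (ub %in% TRUE))
}

#' Classify a conformation by nearest reference shift set
#'
#' Compares an observed carbon-to-shift map against two (or more) reference
#' contexts by root-mean-square shift distance over the shared carbons and
#' labels the observation with the closest context. Uncertain reference
#' assignments are excluded unless `use_uncertain = TRUE`.
#'
#' @param observed named numeric vector of shifts in p.p.m.; names are
#'   `"<residue><carbon>"` (e.g. `"Xn4"`) or bare carbon indices when
#'   `residue` is given.
#' @param references an [assignment_table()].
#' @param contexts character vector of candidate context labels (default the
#'   two cell-wall xylan conformations).
#' @param residue residue label for bare-numbered observed names.
#' @param carbons optional subset of carbon indices to use.
#' @param use_uncertain include reference rows flagged uncertain?
#' @param metric `"rms"` (default), `"l1"` or `"max"` distance.
#' @return object of class `conformation_call` with the winning `label`, the
#'   named vector `distances` (p.p.m.) and the carbons used. An exact tie or
#'   no overlapping carbons raises an error.
#' @export
classify_conformation <- function(observed, references,
                                  contexts = c("twofold-cell-wall",
                                               "threefold-cell-wall"),
                                  residue = "Xn", carbons = NULL,
                                  use_uncertain = FALSE,
                                  metric = c("rms", "l1", "max")) {
  metric <- match.arg(metric)
  references <- assignment_table(references)
  if (length(contexts) < 2L)
    stop("need at least two candidate contexts", call. = FALSE)
  nm <- names(observed)
  if (is.null(nm))
    stop("observed must be a named vector of shifts", call. = FALSE)
  obs_carbon <- ifelse(grepl("^[0-9]+$", nm), nm, sub("^.*?([0-9]+)$", "\\1", nm))
  obs_carbon <- as.integer(obs_carbon)
  if (!is.null(carbons)) {
    keep <- obs_carbon %in% carbons
    observed <- observed[keep]; obs_carbon <- obs_carbon[keep]
  }
  dist_fun <- switch(metric,
                     rms = function(x) sqrt(mean(x^2)),
                     l1 = function(x) mean(abs(x)),
                     max = function(x) max(abs(x)))
  used <- list()
  distances <- vapply(contexts, function(ctx) {
    ref <- references[references$context == ctx &
                        references$residue == residue, ]
    if (!use_uncertain) ref <- ref[!ref$uncertain, ]
    idx <- match(obs_carbon, ref$carbon)
    ok <- !is.na(idx)
    if (!any(ok)) return(NA_real_)
    used[[ctx]] <<- obs_carbon[ok]
    dist_fun(observed[ok] - ref$shift_ppm[idx[ok]])
  }, numeric(1))
  if (all(is.na(distances)))
    stop("insufficient data: no observed carbon overlaps the reference contexts",
         call. = FALSE)
  fin <- distances[!is.na(distances)]
  best <- names(fin)[which.min(fin)]
  runner <- sort(fin)[2L]
  if (length(fin) > 1L && isTRUE(min(fin) == runner))
    stop("ambiguous: reference contexts are exactly equidistant",
         call. = FALSE)
  structure(list(label = best, distances = distances,
                 carbons_used = used[[best]], metric = metric),
            class = "conformation_call")
}

#' @export
print.conformation_call <- function(x, ...) {
  cat(sprintf("<conformation_call: %s>\n", x$label))
  for (ctx in names(x$distances))
    cat(sprintf("  %s: %s p.p.m. (%s)\n", ctx,
                formatC(x$distances[[ctx]], digits = 3, format = "fg"),
                x$metric))
  cat("  carbons used:", paste(x$carbons_used, collapse = ", "), "\n")
  invisible(x)
}

#' Default xylose ring bond list
#'
#' Covalent ring connectivity C1-C2-C3-C4-C5 for a residue.
#'
#' @param residue residue label (default `"Xn"`).
#' @param n_carbons number of ring carbons (default 5 for xylose; use 6 for
#'   glucose).
#' @return data frame with columns `residue`, `carbon_i`, `carbon_j`.
#' @export
default_bond_list <- function(residue = "Xn", n_carbons = 5L) {
  data.frame(residue = residue,
             carbon_i = seq_len(n_carbons - 1L),
             carbon_j = seq_len(n_carbons - 1L) + 1L)
}

validate_bonds <- function(bonds) {
  need <- c("residue", "carbon_i", "carbon_j")
  if (!is.data.frame(bonds) || !all(need %in% names(bonds)))
    stop("bond list needs columns residue, carbon_i, carbon_j", call. = FALSE)
  if (any(bonds$carbon_i == bonds$carbon_j))
    stop("bond list contains a self-pair", call. = FALSE)
  lo <- pmin(bonds$carbon_i, bonds$carbon_j)
  hi <- pmax(bonds$carbon_i, bonds$carbon_j)
  if (anyDuplicated(paste(bonds$residue, lo, hi)))
    stop("bond list contains duplicate pairs", call. = FALSE)
  bonds
}

#' Predict refocused INADEQUATE DQ-SQ peaks
#'
#' For each covalently bonded carbon pair with assignments in the requested
#' context, emits one double-quantum peak whose DQ shift is exactly the sum
#' of the two single-quantum shifts. Bonds referencing a missing assignment
#' are skipped with a warning and counted in the `n_skipped` attribute.
#'
#' @param table an [assignment_table()].
#' @param bonds a bond list (see [default_bond_list()]).
#' @param context context label to predict for.
#' @return data frame of class `dq_peak_list` with columns `residue`,
#'   `carbon_a`, `carbon_b`, `sq_a`, `sq_b`, `dq`, ordered by
#'   (residue, carbon_a).
#' @examples
#' \dontrun{
#' predict_inadequate_peaks(xylan_shift_table(), default_bond_list(),
#'                          "twofold-cell-wall")
#' }
#' @export
predict_inadequate_peaks <- function(table, bonds, context) {
  table <- assignment_table(table)
  bonds <- validate_bonds(bonds)
  ref <- table[table$context == context, ]
  if (nrow(bonds) == 0L) {
    out <- data.frame(residue = character(), carbon_a = integer(),
                      carbon_b = integer(), sq_a = numeric(),
                      sq_b = numeric(), dq = numeric())
    attr(out, "n_skipped") <- 0L
    class(out) <- c("dq_peak_list", "data.frame")
    return(out)
  }
  ia <- match(paste(bonds$residue, bonds$carbon_i),
              paste(ref$residue, ref$carbon))
  ib <- match(paste(bonds$residue, bonds$carbon_j),
              paste(ref$residue, ref$carbon))
  ok <- !is.na(ia) & !is.na(ib)
  n_skipped <- sum(!ok)
  if (n_skipped > 0L)
    warning(sprintf("%d bond(s) skipped: missing assignment in context '%s'",
                    n_skipped, context))
  out <- data.frame(residue = bonds$residue[ok],
                    carbon_a = pmin(bonds$carbon_i, bonds$carbon_j)[ok],
                    carbon_b = pmax(bonds$carbon_i, bonds$carbon_j)[ok],
                    sq_a = ref$shift_ppm[ia[ok]],
                    sq_b = ref$shift_ppm[ib[ok]])
  out$dq <- out$sq_a + out$sq_b
  out <- out[order(out$residue, out$carbon_a), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_skipped") <- n_skipped
  class(out) <- c("dq_peak_list", "data.frame")
  out
}

#' Match predicted against observed DQ-SQ peaks
#'
#' Greedy nearest-neighbour matching in (SQ, DQ) space: a predicted and an
#' observed peak match when both SQ shifts and half the DQ difference are
#' within `tol` p.p.m. Unmatched peaks are listed both ways.
#'
#' @param predicted,observed data frames with columns `sq_a`, `sq_b`, `dq`.
#' @param tol matching tolerance in p.p.m. (> 0).
#' @return list of class `peak_match_report` with `matches` (indices and
#'   distances), `unmatched_predicted`, `unmatched_observed`.
#' @export
match_peaks <- function(predicted, observed, tol = 0.5) {
  if (!is.numeric(tol) || tol <= 0)
    stop("tol must be positive", call. = FALSE)
  canon <- function(df) {
    lo <- pmin(df$sq_a, df$sq_b); hi <- pmax(df$sq_a, df$sq_b)
    cbind(lo, hi, df$dq)
  }
  np <- if (is.null(predicted)) 0L else nrow(predicted)
  no <- if (is.null(observed)) 0L else nrow(observed)
  if (np == 0L || no == 0L) {
    return(structure(list(
      matches = data.frame(predicted = integer(), observed = integer(),
                           distance = numeric()),
      unmatched_predicted = seq_len(np),
      unmatched_observed = seq_len(no)), class = "peak_match_report"))
  }
  P <- canon(predicted); O <- canon(observed)
  d <- matrix(Inf, np, no)
  for (i in seq_len(np))
    d[i, ] <- pmax(abs(P[i, 1] - O[, 1]), abs(P[i, 2] - O[, 2]),
                   abs(P[i, 3] - O[, 3]) / 2)
  matches <- data.frame(predicted = integer(), observed = integer(),
                        distance = numeric())
  while (TRUE) {
    m <- which.min(d)
    if (!length(m) || !is.finite(d[m])) break
    i <- (m - 1L) %% np + 1L
    j <- (m - 1L) %/% np + 1L
    if (d[i, j] > tol) break
    matches <- rbind(matches,
                     data.frame(predicted = i, observed = j,
                                distance = d[i, j]))
    d[i, ] <- Inf
    d[, j] <- Inf
  }
  structure(list(matches = matches,
                 unmatched_predicted = setdiff(seq_len(np), matches$predicted),
                 unmatched_observed = setdiff(seq_len(no), matches$observed)),
            class = "peak_match_report")
}

#' @export
print.peak_match_report <- function(x, ...) {
  cat(sprintf("<peak_match_report: %d matched, %d predicted-only, %d observed-only>\n",
              nrow(x$matches), length(x$unmatched_predicted),
              length(x$unmatched_observed)))
  invisible(x)
}
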