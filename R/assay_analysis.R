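# EOP analysis from spot-titration plaque counts.
#
# A sample is titred by spotting 2 uL of each step of a 10-fold dilution
# series on a lawn; the titer comes from the least-diluted spot whose
# plaque count is in a countable range. Efficiency of plating (EOP) is the
# ratio of the titer on a lawn expressing a gene-targeting crRNA to the
# titer on a lawn expressing a nontargeting crRNA. Zero-plaque series give
# only an upper bound ("censored" values, rendered "<x").

#' Estimate a titer from a spot-titration series
#'
#' Uses the least-diluted spot (smallest dilution exponent) whose count
#' lies in the countable range. If every readable spot has zero plaques,
#' returns a censored detection-limit bound of one plaque at the least
#' dilute spot. Lawn-cleared spots (too many plaques to count) are skipped;
#' if every spot is lawn-cleared the sample is too concentrated and an
#' error asks for further dilution. If no spot is countable but some are
#' positive, the least-diluted positive spot is used and flagged.
#'
#' @param counts `data.frame` for one sample/replicate with columns
#'   `dilution_exponent` (integer k for a 10^-k dilution), `plaques`
#'   (non-negative integer; `NA` allowed for lawn-cleared spots),
#'   `volume_uL` (spot volume, default 2), and optionally `lawn_cleared`
#'   (logical).
#' @param countable_range inclusive plaque-count range considered reliable
#'   for a small spot (default `c(3, 30)`).
#' @return object of class `titer_estimate`: list with `value` (PFU/mL, or
#'   the upper bound when `censored`), `censored`, `dilution_used`,
#'   `plaques`, `note`.
#' @export
#' @examples
#' titer_from_spots(data.frame(dilution_exponent = 0, plaques = 10,
#'                             volume_uL = 2))  # 5000 PFU/mL
titer_from_spots <- function(counts, countable_range = c(3L, 30L)) {
  stopifnot(is.data.frame(counts), nrow(counts) >= 1L,
            all(c("dilution_exponent", "plaques") %in% names(counts)))
  if (!"volume_uL" %in% names(counts)) counts$volume_uL <- 2
  if (length(unique(counts$volume_uL)) != 1L)
    stop("all spots of one sample must share a spot volume", call. = FALSE)
  if (!"lawn_cleared" %in% names(counts)) counts$lawn_cleared <- FALSE
  counts$lawn_cleared <- counts$lawn_cleared | is.na(counts$plaques)
  if (any(!is.na(counts$plaques) & counts$plaques < 0))
    stop("plaque counts must be non-negative", call. = FALSE)
  vol_ml <- counts$volume_uL[1] / 1000
  counts <- counts[order(counts$dilution_exponent), , drop = FALSE]
  readable <- counts[!counts$lawn_cleared, , drop = FALSE]
  if (!nrow(readable))
    stop("all spots lawn-cleared: sample too concentrated, dilute further",
         call. = FALSE)
  titer_at <- function(n, k) n / (vol_ml * 10^-k)
  in_range <- readable$plaques >= countable_range[1] &
    readable$plaques <= countable_range[2]
  if (any(in_range)) {
    row <- readable[which(in_range)[1], ]
    return(structure(list(value = titer_at(row$plaques,
                                           row$dilution_exponent),
                          censored = FALSE,
                          dilution_used = row$dilution_exponent,
                          plaques = row$plaques, note = NA_character_),
                     class = "titer_estimate"))
  }
  positive <- readable$plaques > 0
  if (!any(positive)) {
    k_min <- min(readable$dilution_exponent)
    return(structure(list(value = titer_at(1, k_min), censored = TRUE,
                          dilution_used = k_min, plaques = 0L,
                          note = "no plaques at any dilution"),
                     class = "titer_estimate"))
  }
  row <- readable[which(positive)[1], ]
  structure(list(value = titer_at(row$plaques, row$dilution_exponent),
                 censored = FALSE, dilution_used = row$dilution_exponent,
                 plaques = row$plaques,
                 note = "count outside countable range"),
            class = "titer_estimate")
}

#' @export
print.titer_estimate <- function(x, ...) {
  cat(sprintf("<titer> %s%.3g PFU/mL (spot 10^-%d, %d plaques)\n",
              if (x$censored) "< " else "", x$value, x$dilution_used,
              x$plaques))
  invisible(x)
}

as_titer <- function(x) {
  if (inherits(x, "titer_estimate")) return(x)
  if (is.numeric(x) && length(x) == 1L)
    return(structure(list(value = x, censored = FALSE,
                          dilution_used = NA_integer_, plaques = NA_integer_,
                          note = NA_character_), class = "titer_estimate"))
  stop("expected a titer_estimate or a single number", call. = FALSE)
}

#' Efficiency of plating of a target sample versus the control
#'
#' EOP = target titer / control titer. If the target titer is a censored
#' bound, the EOP is a censored upper bound (bound / control). A censored
#' control invalidates the assay.
#'
#' @param target,control `titer_estimate` objects (or bare numbers,
#'   treated as uncensored titers in PFU/mL).
#' @return object of class `eop_value`: list with `value` and `censored`.
#' @export
compute_eop <- function(target, control) {
  target <- as_titer(target); control <- as_titer(control)
  if (control$censored)
    stop("control titer is censored: assay invalid", call. = FALSE)
  if (control$value <= 0) stop("control titer must be positive",
                               call. = FALSE)
  structure(list(value = target$value / control$value,
                 censored = target$censored), class = "eop_value")
}

#' @export
print.eop_value <- function(x, ...) {
  cat(sprintf("<EOP> %s%.3g\n", if (x$censored) "< " else "", x$value))
  invisible(x)
}

#' Aggregate EOP replicates and classify essentiality
#'
#' Uncensored replicates are summarised by their mean and sample standard
#' deviation (n-1 denominator); censored bounds are never averaged with
#' uncensored values. When every replicate is censored the mean of the
#' bounds is reported as a bound. The call uses a plating-defect threshold
#' of three orders of magnitude: `E` (essential phenotype) when the mean
#' (or bound) is at or below `threshold`, `NE` at or above `10 *
#' threshold`, and `intermediate` in between (a censored bound above the
#' threshold is also `intermediate`: it cannot exclude either call).
#'
#' @param replicates list of `eop_value` objects, or a numeric vector of
#'   uncensored EOPs.
#' @param threshold essentiality threshold on mean EOP (default `1e-3`).
#' @param locus_tag optional identifier carried into the result.
#' @return object of class `eop_result`: list with `locus_tag`,
#'   `eop_replicates`, `eop_mean`, `eop_sd`, `censored`, `n_uncensored`,
#'   `call`.
#' @export
aggregate_and_classify <- function(replicates, threshold = 1e-3,
                                   locus_tag = NA_character_) {
  if (is.numeric(replicates))
    replicates <- lapply(replicates, function(v)
      structure(list(value = v, censored = FALSE), class = "eop_value"))
  stopifnot(length(replicates) >= 1L)
  vals <- vapply(replicates, `[[`, numeric(1), "value")
  cens <- vapply(replicates, `[[`, logical(1), "censored")
  if (any(vals <= 0)) stop("EOP values must be positive", call. = FALSE)
  if (all(cens)) {
    m <- mean(vals); s <- NA_real_; censored <- TRUE
  } else {
    if (any(cens) && min(vals[cens]) < max(vals[!cens]))
      warning("censored bounds contradict uncensored replicates; ",
              "using uncensored values", call. = FALSE)
    m <- mean(vals[!cens])
    s <- if (sum(!cens) > 1L) stats::sd(vals[!cens]) else 0
    censored <- FALSE
  }
  call <- if (m <= threshold) "E"
          else if (censored) "intermediate"
          else if (m >= 10 * threshold) "NE"
          else "intermediate"
  structure(list(locus_tag = locus_tag, eop_replicates = replicates,
                 eop_mean = m, eop_sd = s, censored = censored,
                 n_uncensored = sum(!cens), call = call),
            class = "eop_result")
}

#' @export
print.eop_result <- function(x, ...) {
  cat(sprintf("<eop_result> %s: mean %s%.3g (sd %.3g, n=%d) -> %s\n",
              x$locus_tag, if (x$censored) "< " else "", x$eop_mean,
              if (is.na(x$eop_sd)) NA else x$eop_sd,
              length(x$eop_replicates), x$call))
  invisible(x)
}

#' Read a spot-count table (TSV)
#'
#' Expected columns: `sample_id, dilution_exponent, plaques, volume_uL,
#' replicate_id, control_flag`; optional `lawn_cleared`. Empty `plaques`
#' cells are read as lawn-cleared spots.
#'
#' @param path TSV path.
#' @return `data.frame`.
#' @export
read_spot_counts <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  needed <- c("sample_id", "dilution_exponent", "plaques", "replicate_id",
              "control_flag")
  if (!all(needed %in% names(tab)))
    stop("spot-count table must have columns ",
         paste(needed, collapse = ", "), call. = FALSE)
  if (!"volume_uL" %in% names(tab)) tab$volume_uL <- 2
  if (!"lawn_cleared" %in% names(tab)) tab$lawn_cleared <- FALSE
  tab$control_flag <- as.logical(tab$control_flag)
  tab
}

#' Full EOP analysis of a spot-count table
#'
#' The control (nontargeting-crRNA) lawn titer is a single property of
#' the phage stock, so it is estimated once as the mean of the per-replicate
#' control titrations; dividing each target replicate's single-spot titer
#' by one noisy control spot instead would bias the EOP upward (the ratio
#' of small Poisson counts inflates by roughly 1/control-count). Each
#' target replicate's titer is divided by that pooled control titer, and
#' the per-replicate EOPs are aggregated and classified per sample.
#'
#' @param counts spot-count `data.frame` (see [read_spot_counts()]).
#' @param control_id `sample_id` of the nontargeting-crRNA control; by
#'   default the samples with `control_flag = TRUE`.
#' @param threshold essentiality threshold (default `1e-3`).
#' @param countable_range passed to [titer_from_spots()].
#' @return `data.frame` with one row per target sample: `locus_tag,
#'   eop_mean, eop_sd, censored, n_replicates, call`.
#' @export
analyze_spot_table <- function(counts, control_id = NULL, threshold = 1e-3,
                               countable_range = c(3L, 30L)) {
  if (is.null(control_id)) {
    ctrl_ids <- unique(counts$sample_id[counts$control_flag])
    if (length(ctrl_ids) != 1L)
      stop("need exactly one control sample (or pass control_id)",
           call. = FALSE)
    control_id <- ctrl_ids
  }
  ctrl <- counts[counts$sample_id == control_id, , drop = FALSE]
  if (!nrow(ctrl)) stop("control sample '", control_id, "' not found",
                        call. = FALSE)
  ctrl_reps <- lapply(split(ctrl, ctrl$replicate_id), titer_from_spots,
                      countable_range = countable_range)
  ctrl_vals <- vapply(ctrl_reps, `[[`, numeric(1), "value")
  ctrl_cens <- vapply(ctrl_reps, `[[`, logical(1), "censored")
  if (all(ctrl_cens))
    stop("control titer is censored: assay invalid", call. = FALSE)
  control_titer <- mean(ctrl_vals[!ctrl_cens])
  targets <- setdiff(unique(counts$sample_id), control_id)
  rows <- lapply(targets, function(id) {
    sub <- counts[counts$sample_id == id, , drop = FALSE]
    reps <- lapply(split(sub, sub$replicate_id), function(r)
      compute_eop(titer_from_spots(r, countable_range), control_titer))
    res <- aggregate_and_classify(unname(reps), threshold, locus_tag = id)
    data.frame(locus_tag = id, eop_mean = res$eop_mean,
               eop_sd = res$eop_sd, censored = res$censored,
               n_replicates = length(reps), call = res$call,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write an EOP table (TSV), rendering censored means as "<x"
#' @param eop_table result of [analyze_spot_table()].
#' @param path output path.
#' @export
write_eop_table <- function(eop_table, path) {
  out <- eop_table
  out$EOP_average <- ifelse(out$censored,
                            sprintf("<%.1E", out$eop_mean),
                            sprintf("%.1E", out$eop_mean))
  out$SD <- ifelse(is.na(out$eop_sd), "", sprintf("%.1E", out$eop_sd))
  utils::write.table(
    out[, c("locus_tag", "EOP_average", "SD", "n_replicates", "call")],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Tally essentiality calls
#'
#' Counts calls (E / NE / NT / intermediate) in a character vector or in a
#' fixture/analysis table's call column. Blank or missing entries count as
#' `NT` (not tested).
#'
#' @param calls character vector of calls, or a `data.frame` with a column
#'   named by `column`.
#' @param column column to tally when `calls` is a `data.frame`.
#' @return named integer vector of counts.
#' @export
tally_calls <- function(calls, column = "call_this_work") {
  if (is.data.frame(calls)) calls <- calls[[column]]
  calls <- as.character(calls)
  calls[is.na(calls) | !nzchar(trimws(calls))] <- "NT"
  table(factor(trimws(calls)))
}
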