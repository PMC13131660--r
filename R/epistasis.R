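#' Single-mutation effect table
#'
#' Holds saturation-mutagenesis-style log2 effect sizes of single mutations,
#' each measured on a fixed background with activity `y0`. Note the standard
#' caveat: single effects are typically measured on the extant background
#' while reconstitution trajectories start from the ancestor; predictions
#' combining them inherit that mismatch (recorded in the object's
#' `background_note`).
#'
#' @param effects data.frame with `mutation_id`, `log2_effect` (optionally
#'   `position`, `from`, `to`).
#' @param y0 background activity (> 0).
#' @return object of class `single_effects`.
#' @export
single_effects <- function(effects, y0) {
  stopifnot(is.data.frame(effects),
            all(c("mutation_id", "log2_effect") %in% names(effects)))
  if (!all(is.finite(effects$log2_effect)))
    stop("effects must be finite", call. = FALSE)
  if (!is.numeric(y0) || y0 <= 0)
    stop("background activity y0 must be positive", call. = FALSE)
  if (anyDuplicated(effects$mutation_id))
    stop("duplicated mutation ids", call. = FALSE)
  structure(list(effects = effects, y0 = y0,
                 background_note = paste(
                   "single-mutation effects are measured on a fixed",
                   "background; combination predictions on other backgrounds",
                   "inherit this mismatch")),
            class = "single_effects")
}

#' @rdname single_effects
#' @param path TSV with columns mutation_id, position, from, to, log2_effect.
#' @export
read_single_effects <- function(path, y0) {
  single_effects(utils::read.table(path, sep = "\t", header = TRUE,
                                   stringsAsFactors = FALSE), y0)
}

#' Predict combined activity of a mutation subset
#'
#' Additive model (linear activity scale): `y0 + sum(y_i - y0)`, floored at
#' 0. Multiplicative model (additive in log2): `y0 * prod(y_i / y0)`, where
#' `y_i = y0 * 2^log2_effect` is the measured single-mutant activity. Both
#' models return `y_i` exactly for a single mutation and `y0` for the empty
#' subset.
#'
#' @param effects a [single_effects()] table.
#' @param subset character vector of mutation ids (empty allowed).
#' @param model `"additive"` or `"multiplicative"`.
#' @return predicted activity.
#' @export
predict_combination <- function(effects, subset,
                                model = c("additive", "multiplicative")) {
  model <- match.arg(model)
  stopifnot(inherits(effects, "single_effects"))
  missing <- setdiff(subset, effects$effects$mutation_id)
  if (length(missing) > 0L)
    stop("unknown mutation id(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  y0 <- effects$y0
  if (length(subset) == 0L) return(y0)
  le <- effects$effects$log2_effect[
    match(subset, effects$effects$mutation_id)]
  yi <- y0 * 2^le
  if (model == "additive") max(0, y0 + sum(yi - y0))
  else y0 * prod(yi / y0)
}

#' Compare additive and multiplicative predictions to a measured trajectory
#'
#' Predicts every intermediate's activity from the cumulative set of
#' introduced mutations under both models and reports the Spearman rank
#' correlation with the measured activities, plus a residual table.
#'
#' @param traj a `trajectory` with measured activities and mutation ids that
#'   appear in `effects`.
#' @param effects a [single_effects()] table.
#' @return list with `rho` (named: additive, multiplicative) and `residuals`
#'   (per-step data.frame with both predictions and measured values); rho is
#'   NA when measurements are constant or fewer than 3 steps are measured.
#' @export
model_comparison <- function(traj, effects) {
  d <- traj$steps
  preds_a <- numeric(nrow(d)); preds_m <- numeric(nrow(d))
  for (i in seq_len(nrow(d))) {
    ids <- d$mutation_id[seq_len(i)]
    ids <- ids[!is.na(ids)]
    preds_a[i] <- predict_combination(effects, ids, "additive")
    preds_m[i] <- predict_combination(effects, ids, "multiplicative")
  }
  meas <- d$measured
  ok <- !is.na(meas)
  rho <- c(additive = NA_real_, multiplicative = NA_real_)
  if (sum(ok) >= 3 && stats::sd(meas[ok]) > 0) {
    rho["additive"] <- if (stats::sd(preds_a[ok]) > 0)
      stats::cor(preds_a[ok], meas[ok], method = "spearman") else NA_real_
    rho["multiplicative"] <- if (stats::sd(preds_m[ok]) > 0)
      stats::cor(preds_m[ok], meas[ok], method = "spearman") else NA_real_
  }
  list(rho = rho,
       residuals = data.frame(step = d$step, measured = meas,
                              additive = preds_a, multiplicative = preds_m,
                              resid_additive = meas - preds_a,
                              resid_multiplicative = meas - preds_m,
                              stringsAsFactors = FALSE))
}

#' Order-dependence of mutational effects across trajectories
#'
#' For every mutation introduced in at least `min_contexts` trajectories, the
#' per-context effect is log2(activity after / activity before) at the step
#' where it is introduced. The spread of these effects across contexts
#' (`sd_across_contexts`) is compared with the replicate noise expected for a
#' step difference, obtained by propagating the two intermediates' standard
#' errors in log2 space (`sqrt(se_after^2 + se_before^2)`, with
#' `se_log2 = sigma / (mu * ln 2)`), pooled as a root mean square. A ratio
#' near 1 indicates effects as variable as noise alone; ratios well above 1
#' indicate genuine order dependence (epistasis).
#'
#' @param trajectories list of `trajectory` objects carrying `measured` (and
#'   ideally `measured_sigma`) per step.
#' @param min_contexts minimum number of trajectories a mutation must appear
#'   in (default 2); mutations below are excluded with a message.
#' @return data.frame per mutation: `mutation_id`, `n_contexts`,
#'   `mean_effect`, `sd_across_contexts`, `sd_replicate_noise`, `ratio`.
#' @export
order_dependence <- function(trajectories, min_contexts = 2) {
  recs <- list()
  for (ti in seq_along(trajectories)) {
    d <- trajectories[[ti]]$steps
    sig <- if ("measured_sigma" %in% names(d)) d$measured_sigma
           else rep(NA_real_, nrow(d))
    for (i in seq_len(nrow(d))[-1]) {
      if (is.na(d$mutation_id[i])) next
      a <- d$measured[i]; b <- d$measured[i - 1]
      if (is.na(a) || is.na(b) || a <= 0 || b <= 0) next
      se_a <- sig[i] / (a * log(2)); se_b <- sig[i - 1] / (b * log(2))
      recs[[length(recs) + 1L]] <- data.frame(
        mutation_id = d$mutation_id[i], trajectory = ti, step = d$step[i],
        effect = log2(a / b),
        noise_sd = sqrt(se_a^2 + se_b^2), stringsAsFactors = FALSE)
    }
  }
  recs <- do.call(rbind, recs)
  if (is.null(recs) || nrow(recs) == 0L)
    stop("no measurable steps in the supplied trajectories", call. = FALSE)
  counts <- table(recs$mutation_id)
  drop <- names(counts)[counts < min_contexts]
  if (length(drop) > 0L)
    message("excluding ", length(drop),
            " mutation(s) present in fewer than ", min_contexts,
            " trajectories")
  recs <- recs[!recs$mutation_id %in% drop, , drop = FALSE]
  rows <- lapply(split(recs, recs$mutation_id), function(g) {
    sdc <- stats::sd(g$effect)
    noise <- if (all(is.na(g$noise_sd))) NA_real_
             else sqrt(mean(g$noise_sd^2, na.rm = TRUE))
    data.frame(n_contexts = nrow(g), mean_effect = mean(g$effect),
               sd_across_contexts = sdc, sd_replicate_noise = noise,
               ratio = if (!is.na(noise) && noise > 0) sdc / noise
                       else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- cbind(mutation_id = names(rows), out, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Attribution of functional recovery to TFBS-overlapping mutations
#'
#' Splits the positive activity gains along a trajectory by whether the step's
#' mutation overlaps a reference functional TFBS interval. The observed share
#' is the fraction of the summed positive log2 gains contributed by
#' TFBS-overlapping steps; the expected share is the fraction of all
#' mutations that overlap a TFBS (count-based). Both reported as percent.
#'
#' @param traj a `trajectory` with measured (or predicted) activities and a
#'   `mutation_set` in `traj$events`.
#' @param sites data.frame with `start`, `end`: TFBS intervals in the
#'   alignment-column coordinates of the trajectory's mutation set.
#' @param use `"auto"`, `"measured"`, or `"predicted"`.
#' @return list with `observed_share`, `expected_share` (percent; observed NA
#'   when the trajectory has no positive gains).
#' @export
tfbs_attribution <- function(traj, sites,
                             use = c("auto", "measured", "predicted")) {
  use <- match.arg(use)
  d <- traj$steps
  v <- switch(use,
    auto = if (any(!is.na(d$measured))) d$measured else d$predicted,
    measured = d$measured, predicted = d$predicted)
  ev <- traj$events
  if (is.null(ev)) stop("trajectory carries no mutation set", call. = FALSE)
  ev_start <- ev$column_start
  ev_end <- ev$column_start + ev$n_columns
  overlaps_tfbs <- vapply(seq_len(nrow(ev)), function(i)
    any(ev_start[i] < sites$end & sites$start < ev_end[i]), logical(1))
  names(overlaps_tfbs) <- ev$id
  gains <- diff(log2(v))
  step_ids <- d$mutation_id[-1]
  pos <- !is.na(gains) & gains > 0
  total <- sum(gains[pos])
  observed <- if (total > 0)
    100 * sum(gains[pos & overlaps_tfbs[step_ids]]) / total else NA_real_
  expected <- 100 * mean(overlaps_tfbs)
  list(observed_share = observed, expected_share = expected)
}

#' Classify trajectory steps by their effect on reference TFBSs
#'
#' Each step is classified as: `"reconstituting"` if its mutation raises some
#' reference site's normalized affinity from at-or-below the call threshold
#' to above it for the first time; `"optimizing"` if it raises a site that is
#' already above threshold; `"background"` if it overlaps no reference site
#' (or overlaps but changes no site upward across the threshold structure).
#' Per-step site affinities are recomputed on every intermediate by mapping
#' the site windows through global alignment to the reference.
#'
#' @param traj a `trajectory` (reconstitution kind).
#' @param reference endogenous reference sequence.
#' @param sites data.frame `site_id`, `tf`, `start`, `end` on the reference
#'   (0-based half-open), plus `col_start`, `col_end` in the trajectory's
#'   alignment-column coordinates for overlap with mutation events.
#' @param motifs,normrefs named lists keyed by TF.
#' @param threshold call threshold (default 0.05).
#' @param params alignment parameters for window mapping.
#' @return data.frame `step`, `mutation_id`, `class`, `site_id` (the site
#'   acted upon, NA for background steps).
#' @export
classify_steps <- function(traj, reference, sites, motifs, normrefs,
                           threshold = 0.05,
                           params = preset_params("reconstitution")) {
  d <- traj$steps
  ev <- traj$events
  site_aff <- function(seq) {
    vapply(seq_len(nrow(sites)), function(r) {
      aln <- align_global(seq, reference, params)
      w <- map_interval(c(qry = aln$aligned_a, ref = aln$aligned_b),
                        "ref", "qry", sites$start[r], sites$end[r])
      if (is.null(w)) return(0)
      max_affinity_in_window(seq, motifs[[sites$tf[r]]],
                             normrefs[[sites$tf[r]]], w$start, w$end)
    }, numeric(1))
  }
  aff_prev <- site_aff(d$sequence[1])
  out <- list()
  for (i in seq_len(nrow(d))[-1]) {
    aff <- site_aff(d$sequence[i])
    mid <- d$mutation_id[i]
    e <- ev[ev$id == mid, , drop = FALSE]
    overlapped <- which(e$column_start[1] < sites$col_end &
                        sites$col_start < e$column_start[1] + e$n_columns[1])
    cls <- "background"; site <- NA_character_
    if (length(overlapped) > 0L) {
      crossed <- overlapped[aff_prev[overlapped] <= threshold &
                            aff[overlapped] > threshold]
      raised <- overlapped[aff_prev[overlapped] > threshold &
                           aff[overlapped] > aff_prev[overlapped]]
      if (length(crossed) > 0L) {
        cls <- "reconstituting"; site <- sites$site_id[crossed[1]]
      } else if (length(raised) > 0L) {
        cls <- "optimizing"; site <- sites$site_id[raised[1]]
      }
    }
    out[[length(out) + 1L]] <- data.frame(
      step = d$step[i], mutation_id = mid, class = cls, site_id = site,
      stringsAsFactors = FALSE)
    aff_prev <- aff
  }
  do.call(rbind, out)
}
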