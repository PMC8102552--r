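#' Effective counts of a junction count record
#'
#' Junction-count normalization: the inclusion isoform offers more
#' junction positions than the skipping isoform, so raw sums are divided
#' by the number of junctions on their side.  The normalized rates are
#' rounded to the nearest integer to serve as effective binomial counts
#' for the conjugate posterior and the Bayes factor.
#'
#' @param rec A [junction_count_record].
#' @return A list with `inc_rate`, `skip_rate` (length-normalized rates),
#'   `k` (effective inclusion count), `s` (effective skipping count) and
#'   `n` (`k + s`).
#' @export
effective_counts <- function(rec) {
  stopifnot(inherits(rec, "junction_count_record"))
  i <- sum(rec$inclusion) / length(rec$inclusion)
  s <- sum(rec$skipping) / length(rec$skipping)
  k_eff <- as.integer(round(i))
  s_eff <- as.integer(round(s))
  list(inc_rate = i, skip_rate = s, k = k_eff, s = s_eff, n = k_eff + s_eff)
}

#' Estimate percent spliced in (PSI) from junction counts
#'
#' The point estimate is the length-normalized junction-count ratio
#' `psi = i / (i + s)` with `i` and `s` the per-junction inclusion and
#' skipping read rates.  Uncertainty is carried by a conjugate
#' beta-binomial model on the effective counts: the posterior over PSI is
#' `Beta(prior_alpha + k, prior_beta + s)`.  With no informative reads at
#' all the estimate is undefined and the posterior equals the prior.
#'
#' @param rec A [junction_count_record].
#' @param prior_alpha,prior_beta Beta prior parameters (default 1, 1:
#'   uniform).
#' @param conf Central posterior interval mass (default 0.95).
#' @return An object of class `psi_estimate`: a list with `event_id`,
#'   `sample_id`, `psi` (`NA` when undefined), `defined`,
#'   `posterior_alpha`, `posterior_beta`, `ci_low`, `ci_high`, and the
#'   effective counts `k`, `s`.
#' @export
estimate_psi <- function(rec, prior_alpha = 1, prior_beta = 1, conf = 0.95) {
  if (prior_alpha <= 0 || prior_beta <= 0) stopf("prior parameters must be positive")
  eff <- effective_counts(rec)
  defined <- (eff$inc_rate + eff$skip_rate) > 0
  psi <- if (defined) eff$inc_rate / (eff$inc_rate + eff$skip_rate) else NA_real_
  a <- prior_alpha + eff$k
  b <- prior_beta + eff$s
  qs <- qbeta(c((1 - conf) / 2, 1 - (1 - conf) / 2), a, b)
  structure(
    list(event_id = rec$event_id, sample_id = rec$sample_id,
         psi = psi, defined = defined,
         posterior_alpha = a, posterior_beta = b,
         posterior_mean = a / (a + b),
         ci_low = qs[1L], ci_high = qs[2L],
         k = eff$k, s = eff$s),
    class = "psi_estimate")
}

#' @export
print.psi_estimate <- function(x, ...) {
  cat(sprintf("psi_estimate %s / %s: psi=%s  Beta(%g,%g)  95%% CI [%.3f, %.3f]\n",
              x$event_id, x$sample_id,
              if (x$defined) sprintf("%.3f", x$psi) else "undefined",
              x$posterior_alpha, x$posterior_beta, x$ci_low, x$ci_high))
  invisible(x)
}

#' PSI estimates for a set of records as a data frame
#'
#' @param records A list of [junction_count_record] objects.
#' @inheritParams estimate_psi
#' @return A data frame with one row per record.
#' @export
psi_table <- function(records, prior_alpha = 1, prior_beta = 1, conf = 0.95) {
  rows <- lapply(records, function(r) {
    p <- estimate_psi(r, prior_alpha, prior_beta, conf)
    data.frame(event_id = p$event_id, sample_id = p$sample_id, psi = p$psi,
               defined = p$defined, posterior_alpha = p$posterior_alpha,
               posterior_beta = p$posterior_beta, ci_low = p$ci_low,
               ci_high = p$ci_high, k = p$k, s = p$s, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

## log Bayes factor of the independent-PSI model over the shared-PSI
## model, both with Uniform(0,1) priors, for effective counts
## (ka successes of na) and (kb of nb); binomial coefficients cancel.
log_bf_independent <- function(ka, na, kb, nb) {
  lbeta(ka + 1, na - ka + 1) + lbeta(kb + 1, nb - kb + 1) -
    lbeta(ka + kb + 1, na + nb - ka - kb + 1)
}

#' Bayes-factor differential-splicing call between two samples
#'
#' Compares the marginal likelihood of an independent-PSI model (each
#' sample has its own inclusion probability) against a shared-PSI model
#' (one common probability), both under Uniform(0, 1) priors, using the
#' effective junction-normalized counts.  The Bayes factor has the closed
#' form `B(kA+1, nA-kA+1) B(kB+1, nB-kB+1) / B(kA+kB+1, nA+nB-kA-kB+1)`,
#' evaluated in log space.  An event is called differentially spliced
#' when the Bayes factor reaches `bf_threshold` (default 10).  With no
#' informative reads in either sample the data cannot discriminate the
#' models and the Bayes factor is exactly 1.
#'
#' @param rec_a,rec_b Two [junction_count_record]s for the same event.
#' @param bf_threshold Significance threshold on the Bayes factor
#'   (default 10).
#' @param prior_alpha,prior_beta Beta prior for the PSI point estimates
#'   reported alongside the call.
#' @return An object of class `diff_splice_result`: a list with
#'   `event_id`, `sample_a`, `sample_b`, `psi_a`, `psi_b`, `delta_psi`
#'   (`psi_b - psi_a`), `bayes_factor`, `log10_bf`, `significant`.
#' @export
bayes_factor_diff <- function(rec_a, rec_b, bf_threshold = 10,
                              prior_alpha = 1, prior_beta = 1) {
  if (rec_a$event_id != rec_b$event_id) {
    stopf("records describe different events ('%s' vs '%s')",
          rec_a$event_id, rec_b$event_id)
  }
  if (bf_threshold <= 0) stopf("bf_threshold must be positive")
  ea <- effective_counts(rec_a)
  eb <- effective_counts(rec_b)
  log_bf <- log_bf_independent(ea$k, ea$n, eb$k, eb$n)
  bf <- exp(log_bf)
  pa <- estimate_psi(rec_a, prior_alpha, prior_beta)
  pb <- estimate_psi(rec_b, prior_alpha, prior_beta)
  structure(
    list(event_id = rec_a$event_id,
         sample_a = rec_a$sample_id, sample_b = rec_b$sample_id,
         psi_a = pa$psi, psi_b = pb$psi,
         delta_psi = pb$psi - pa$psi,
         bayes_factor = bf, log10_bf = log_bf / log(10),
         significant = is.finite(bf) && bf >= bf_threshold),
    class = "diff_splice_result")
}

#' @export
print.diff_splice_result <- function(x, ...) {
  cat(sprintf("diff_splice %s: %s vs %s  dPSI=%s  BF=%.3g  %s\n",
              x$event_id, x$sample_a, x$sample_b,
              if (is.na(x$delta_psi)) "NA" else sprintf("%+.3f", x$delta_psi),
              x$bayes_factor,
              if (x$significant) "significant" else "not significant"))
  invisible(x)
}

#' Differential-splicing calls along an ordered stage series
#'
#' Runs [bayes_factor_diff] for every event between each pair of adjacent
#' stages.  `delta_psi` is always later stage minus earlier stage.
#'
#' @param records A list of [junction_count_record]s whose `sample_id`s
#'   are stage names.
#' @param stages Character vector giving the stage order.
#' @inheritParams bayes_factor_diff
#' @return A data frame with one row per event and adjacent-stage
#'   transition: `event_id`, `transition` (e.g. `"SG_diff->SC_preL"`),
#'   `stage_a`, `stage_b`, `psi_a`, `psi_b`, `delta_psi`, `bayes_factor`,
#'   `log10_bf`, `significant`.
#' @export
diff_splice_table <- function(records, stages, bf_threshold = 10,
                              prior_alpha = 1, prior_beta = 1) {
  if (length(stages) < 2L) stopf("need at least two ordered stages")
  ids <- vapply(records, `[[`, character(1), "event_id")
  samples <- vapply(records, `[[`, character(1), "sample_id")
  missing_stage <- setdiff(samples, stages)
  if (length(missing_stage) > 0L) {
    stopf("sample '%s' does not appear in the stage order", missing_stage[1L])
  }
  rows <- list()
  for (ev in unique(ids)) {
    sub <- records[ids == ev]
    sub_stage <- samples[ids == ev]
    for (i in seq_len(length(stages) - 1L)) {
      ia <- which(sub_stage == stages[i])
      ib <- which(sub_stage == stages[i + 1L])
      if (length(ia) != 1L || length(ib) != 1L) next
      d <- bayes_factor_diff(sub[[ia]], sub[[ib]], bf_threshold,
                             prior_alpha, prior_beta)
      rows[[length(rows) + 1L]] <- data.frame(
        event_id = ev,
        transition = paste0(stages[i], "->", stages[i + 1L]),
        stage_a = stages[i], stage_b = stages[i + 1L],
        psi_a = d$psi_a, psi_b = d$psi_b, delta_psi = d$delta_psi,
        bayes_factor = d$bayes_factor, log10_bf = d$log10_bf,
        significant = d$significant, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Does a splicing change persist through all later stages?
#'
#' A gain (or loss) called at the transition from stage `transition_index`
#' to `transition_index + 1` is maintained when the PSI of every later
#' stage stays on the post-transition side of the pre-transition baseline
#' by at least `margin`.  An undefined PSI at any later stage counts as
#' not maintained.
#'
#' @param psi Numeric vector of PSI estimates ordered by stage (`NA` =
#'   undefined).
#' @param transition_index Index of the pre-transition stage (the change
#'   happens between `transition_index` and `transition_index + 1`).
#' @param margin Maintenance margin on the PSI scale (default 0.05).
#' @return Logical; the attribute `"reason"` explains a `FALSE`.
#' @export
event_persists <- function(psi, transition_index, margin = 0.05) {
  n <- length(psi)
  if (transition_index < 1L || transition_index >= n) {
    stopf("transition_index must lie in [1, %d]", n - 1L)
  }
  base <- psi[transition_index]
  post <- psi[transition_index + 1L]
  if (is.na(base) || is.na(post)) {
    return(structure(FALSE, reason = "undefined PSI at the transition itself"))
  }
  dir <- sign(post - base)
  if (dir == 0) {
    return(structure(FALSE, reason = "no PSI change at the transition"))
  }
  for (j in (transition_index + 1L):n) {
    if (is.na(psi[j])) {
      return(structure(FALSE, reason = sprintf("undefined PSI at stage %d", j)))
    }
    if (dir * (psi[j] - base) < margin) {
      return(structure(FALSE,
                       reason = sprintf("stage %d PSI %.3f within margin of baseline %.3f",
                                        j, psi[j], base)))
    }
  }
  structure(TRUE, reason = NA_character_)
}

#' Exact Venn-style overlap counts for named gene sets
#'
#' @param gene_sets A named list (at least two elements) of character
#'   vectors of gene identifiers.
#' @return A data frame with one row per non-empty combination of set
#'   names: `sets` (names joined by `&`), `degree`, `n_intersection`
#'   (size of the plain intersection of the named sets) and
#'   `n_exclusive` (size of the Venn region: in all named sets and in no
#'   other).
#' @export
overlap_sets <- function(gene_sets) {
  if (is.null(names(gene_sets)) || length(gene_sets) < 2L ||
      anyNA(names(gene_sets)) || any(names(gene_sets) == "")) {
    stopf("gene_sets must be a named list of at least two sets")
  }
  sets <- lapply(gene_sets, unique)
  nm <- names(sets)
  combos <- unlist(lapply(seq_along(nm), function(k) {
    asplit(utils::combn(nm, k), 2L)
  }), recursive = FALSE)
  rows <- lapply(combos, function(cmb) {
    inter <- Reduce(intersect, sets[cmb])
    others <- setdiff(nm, cmb)
    excl <- inter
    for (o in others) excl <- setdiff(excl, sets[[o]])
    data.frame(sets = paste(cmb, collapse = "&"), degree = length(cmb),
               n_intersection = length(inter), n_exclusive = length(excl),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
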