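#' Enumerate alternative-splicing events between transcripts of one gene
#'
#' Pairwise comparison of exon chains yields typed events:
#' \describe{
#'   \item{SE}{an internal exon present in one transcript while the other
#'     joins the flanking exons directly (skipped/cassette exon);}
#'   \item{RI}{one transcript splits an exon of the other into two exons
#'     with identical outer boundaries (retained intron);}
#'   \item{A5SS / A3SS}{two introns share one boundary and differ at the
#'     other while the flanking exon on the differing side ends at the
#'     same position; whether the variable boundary is the donor (5')
#'     or acceptor (3') side is decided from the strand;}
#'   \item{MXE}{two non-overlapping internal exons, one per transcript,
#'     between shared flanking boundaries, neither present in the other
#'     transcript (mutually exclusive exons).}
#' }
#' Events found from several transcript pairs are deduplicated by
#' coordinates.
#'
#' @param transcripts A list of [transcript_model]s sharing one gene.
#' @return A data frame with columns `event_id`, `gene_id`, `event_type`,
#'   `contig`, `strand`, `var_start`, `var_end` (the variable exon for
#'   SE/MXE, the retained intron for RI, the extension for A5SS/A3SS),
#'   `var2_start`, `var2_end` (second exon of an MXE, otherwise `NA`) and
#'   `direction` (initialised to `"none"`).  Zero rows for a
#'   single-transcript gene.
#' @export
enumerate_as_events <- function(transcripts) {
  if (inherits(transcripts, "transcript_model")) transcripts <- list(transcripts)
  empty <- data.frame(event_id = character(0), gene_id = character(0),
                      event_type = character(0), contig = character(0),
                      strand = character(0), var_start = integer(0),
                      var_end = integer(0), var2_start = integer(0),
                      var2_end = integer(0), direction = character(0),
                      stringsAsFactors = FALSE)
  if (length(transcripts) < 2L) return(empty)
  gene <- unique(vapply(transcripts, `[[`, character(1), "gene_id"))
  if (length(gene) != 1L) stopf("transcripts must all belong to one gene")
  strand <- unique(vapply(transcripts, `[[`, character(1), "strand"))
  contig <- unique(vapply(transcripts, `[[`, character(1), "contig"))
  if (length(strand) != 1L || length(contig) != 1L) {
    stopf("transcripts of gene '%s' must share one contig and strand", gene)
  }

  rows <- list()
  emit <- function(type, vs, ve, v2s = NA_integer_, v2e = NA_integer_) {
    rows[[length(rows) + 1L]] <<- data.frame(
      event_id = paste(gene, type, vs, ve, sep = ":"),
      gene_id = gene, event_type = type, contig = contig, strand = strand,
      var_start = vs, var_end = ve, var2_start = v2s, var2_end = v2e,
      direction = "none", stringsAsFactors = FALSE)
  }
  has_exon <- function(tm, s, e) any(tm$exon_starts == s & tm$exon_ends == e)

  pair_scan <- function(x, y) {
    kx <- n_exons(x); ky <- n_exons(y)
    ## SE: internal exon of x, skipped by a direct junction in y
    if (kx >= 3L && ky >= 2L) {
      for (j in 2L:(kx - 1L)) {
        l_end <- x$exon_ends[j - 1L]; r_start <- x$exon_starts[j + 1L]
        adjacent <- any(y$exon_ends[-ky] == l_end & y$exon_starts[-1L] == r_start)
        if (adjacent && !has_exon(y, x$exon_starts[j], x$exon_ends[j])) {
          emit("SE", x$exon_starts[j], x$exon_ends[j])
        }
      }
    }
    ## RI: consecutive exon pair of x merged into one exon of y
    if (kx >= 2L) {
      for (j in seq_len(kx - 1L)) {
        if (any(y$exon_starts == x$exon_starts[j] & y$exon_ends == x$exon_ends[j + 1L])) {
          emit("RI", x$exon_ends[j] + 1L, x$exon_starts[j + 1L] - 1L)
        }
      }
    }
    ## MXE: internal exon of x vs non-overlapping internal exon of y
    ## between shared flanking boundaries
    if (kx >= 3L && ky >= 3L) {
      for (j in 2L:(kx - 1L)) {
        for (m in 2L:(ky - 1L)) {
          e1s <- x$exon_starts[j]; e1e <- x$exon_ends[j]
          e2s <- y$exon_starts[m]; e2e <- y$exon_ends[m]
          if (e1s == e2s && e1e == e2e) next
          if (!(e1e < e2s || e2e < e1s)) next
          if (x$exon_ends[j - 1L] != y$exon_ends[m - 1L]) next
          if (x$exon_starts[j + 1L] != y$exon_starts[m + 1L]) next
          if (has_exon(y, e1s, e1e) || has_exon(x, e2s, e2e)) next
          if (e1s <= e2s) emit("MXE", e1s, e1e, e2s, e2e)
          else emit("MXE", e2s, e2e, e1s, e1e)
        }
      }
    }
    ## A5SS/A3SS: intron pairs sharing exactly one boundary, with the
    ## flanking exon on the differing side otherwise identical
    ix <- transcript_introns(x); iy <- transcript_introns(y)
    if (nrow(ix) > 0L && nrow(iy) > 0L) {
      for (a in seq_len(nrow(ix))) {
        for (b in seq_len(nrow(iy))) {
          s1 <- ix$start[a]; e1 <- ix$end[a]
          s2 <- iy$start[b]; e2 <- iy$end[b]
          if (s1 == s2 && e1 != e2) {
            ## exon following each intron must share its far end
            fx <- x$exon_ends[match(e1 + 1L, x$exon_starts)]
            fy <- y$exon_ends[match(e2 + 1L, y$exon_starts)]
            if (!is.na(fx) && !is.na(fy) && fx == fy) {
              type <- if (strand == "+") "A3SS" else "A5SS"
              emit(type, min(e1, e2) + 1L, max(e1, e2))
            }
          } else if (e1 == e2 && s1 != s2) {
            ## exon preceding each intron must share its far start
            px <- x$exon_starts[match(s1 - 1L, x$exon_ends)]
            py <- y$exon_starts[match(s2 - 1L, y$exon_ends)]
            if (!is.na(px) && !is.na(py) && px == py) {
              type <- if (strand == "+") "A5SS" else "A3SS"
              emit(type, min(s1, s2), max(s1, s2) - 1L)
            }
          }
        }
      }
    }
  }

  n <- length(transcripts)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      pair_scan(transcripts[[i]], transcripts[[j]])
      pair_scan(transcripts[[j]], transcripts[[i]])
    }
  }
  if (length(rows) == 0L) return(empty)
  out <- do.call(rbind, rows)
  out <- out[!duplicated(out[c("event_type", "var_start", "var_end",
                               "var2_start", "var2_end")]), , drop = FALSE]
  out <- out[order(out$var_start, out$var_end, out$event_type), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assign gain/loss direction to skipped-exon differential calls
#'
#' Direction is defined by the sign of `delta_psi` across a stage
#' transition (later stage minus earlier stage): a significant positive
#' change is a `gain` of the variable exon, a significant negative change
#' a `loss`.  Only SE events receive a direction; calls that are not
#' significant stay `"none"`.
#'
#' @param events An event data frame from [enumerate_as_events] (needs
#'   `event_id`, `event_type`).
#' @param diffs A differential-splicing data frame from
#'   [diff_splice_table] (needs `event_id`, `delta_psi`, `significant`).
#' @return `diffs` augmented with `event_type` and `direction` columns.
#' @export
classify_gain_loss <- function(events, diffs) {
  out <- merge(diffs, events[c("event_id", "event_type")],
               by = "event_id", all.x = TRUE, sort = FALSE)
  if (all(out$event_type != "SE", na.rm = TRUE)) {
    warnf("gain/loss direction applies only to SE events; all directions stay 'none'")
  }
  out$direction <- ifelse(
    !is.na(out$event_type) & out$event_type == "SE" & out$significant &
      !is.na(out$delta_psi) & out$delta_psi != 0,
    ifelse(out$delta_psi > 0, "gain", "loss"),
    "none")
  out
}

#' Per-transition frequencies of significant splicing events
#'
#' @param classified A data frame from [classify_gain_loss] (needs
#'   `transition`, `event_type`, `significant`, `direction`).
#' @return A data frame with one row per transition: the number of
#'   significant events, the count and fraction of each event type among
#'   them (fractions sum to 1), the gain and loss counts among SE events
#'   and their ratio.  A transition with zero significant events is
#'   `flagged` and its fractions are `NA`.
#' @export
tally_frequencies <- function(classified) {
  need <- c("transition", "event_type", "significant", "direction")
  if (!all(need %in% names(classified))) {
    stopf("input must have columns: %s", paste(need, collapse = ", "))
  }
  types <- c("SE", "RI", "A5SS", "A3SS", "MXE")
  transitions <- unique(classified$transition)
  rows <- lapply(transitions, function(tr) {
    sub <- classified[classified$transition == tr & classified$significant, , drop = FALSE]
    n_sig <- nrow(sub)
    cnt <- vapply(types, function(t) sum(sub$event_type == t, na.rm = TRUE), integer(1))
    frac <- if (n_sig > 0L) cnt / n_sig else rep(NA_real_, length(types))
    n_gain <- sum(sub$direction == "gain")
    n_loss <- sum(sub$direction == "loss")
    row <- data.frame(transition = tr, n_significant = n_sig,
                      stringsAsFactors = FALSE)
    for (i in seq_along(types)) row[[paste0("n_", types[i])]] <- cnt[i]
    for (i in seq_along(types)) row[[paste0("frac_", types[i])]] <- frac[i]
    row$n_gain <- n_gain
    row$n_loss <- n_loss
    row$gain_loss_ratio <- if (n_loss > 0L) n_gain / n_loss else NA_real_
    row$flagged <- n_sig == 0L
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
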