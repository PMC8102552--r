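## Independent oracles used to cross-check the package implementations.
## These deliberately re-derive everything from first principles (numeric
## integration, codon-by-codon scanning, literal pattern definitions)
## rather than calling the code paths they verify.

## ---- Bayes factor: numerical integration of both marginal likelihoods

## \int_0^1 p^k (1-p)^(n-k) dp, evaluated numerically (binomial
## coefficients cancel in the Bayes-factor ratio)
marginal_integral <- function(k, n) {
  stats::integrate(function(p) p^k * (1 - p)^(n - k), 0, 1,
                   rel.tol = 1e-10, abs.tol = 0)$value
}

bf_numeric_oracle <- function(ka, na, kb, nb) {
  marginal_integral(ka, na) * marginal_integral(kb, nb) /
    marginal_integral(ka + kb, na + nb)
}

## ---- brute-force splice / translate / scan oracle for ORF consequences

oracle_revcomp <- function(x) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(x, "")[[1]]), collapse = ""))
}

oracle_splice <- function(tm, genome) {
  pieces <- character(0)
  for (i in seq_along(tm$exon_starts)) {
    pieces <- c(pieces, genome_subseq(genome, tm$contig,
                                      tm$exon_starts[i], tm$exon_ends[i]))
  }
  s <- paste(pieces, collapse = "")
  if (tm$strand == "-") s <- oracle_revcomp(s)
  s
}

## spliced position of a genomic base, recounted with an explicit loop
oracle_map <- function(tm, gpos) {
  order_idx <- if (tm$strand == "+") seq_along(tm$exon_starts) else
    rev(seq_along(tm$exon_starts))
  offset <- 0L
  for (i in order_idx) {
    w <- tm$exon_ends[i] - tm$exon_starts[i] + 1L
    if (tm$exon_starts[i] <= gpos && gpos <= tm$exon_ends[i]) {
      within <- if (tm$strand == "+") gpos - tm$exon_starts[i] else
        tm$exon_ends[i] - gpos
      return(offset + within + 1L)
    }
    offset <- offset + w
  }
  stop("position not exonic")
}

## categorize a novel-exon insertion by explicit codon walking
orf_oracle <- function(variant, canonical, genome) {
  stops <- c("TAA", "TAG", "TGA")
  S <- oracle_splice(variant, genome)
  start_g <- if (variant$strand == "+") variant$cds_start else variant$cds_end
  p0 <- oracle_map(variant, start_g)
  can_len <- 0L
  for (i in seq_along(canonical$exon_starts)) {
    can_len <- can_len + canonical$exon_ends[i] - canonical$exon_starts[i] + 1L
  }
  ## novel exon of the variant (the one absent from the canonical chain)
  nov <- NULL
  for (i in seq_along(variant$exon_starts)) {
    found <- FALSE
    for (j in seq_along(canonical$exon_starts)) {
      if (variant$exon_starts[i] == canonical$exon_starts[j] &&
          variant$exon_ends[i] == canonical$exon_ends[j]) found <- TRUE
    }
    if (!found) nov <- c(variant$exon_starts[i], variant$exon_ends[i])
  }
  exon_len <- nov[2] - nov[1] + 1L
  b1 <- oracle_map(variant, if (variant$strand == "+") nov[1] else nov[2])
  b2 <- b1 + exon_len - 1L

  ## canonical CDS length from the canonical transcript itself
  p0_can <- oracle_map(canonical, start_g)
  stop_g <- if (canonical$strand == "+") canonical$cds_end else canonical$cds_start
  cds_len <- oracle_map(canonical, stop_g) - p0_can + 1L
  q_can <- p0 + cds_len - 3L
  if (b2 < p0 || b1 > q_can + 2L) {
    return(list(category = "no_change", added = NA_integer_, nmd = FALSE))
  }

  pos <- p0
  added <- 0L
  q <- NA_integer_
  while (pos + 2L <= nchar(S)) {
    codon <- substr(S, pos, pos + 2L)
    if (codon %in% stops) { q <- pos; break }
    if ((pos + 2L) >= b1 && (pos + 2L) <= b2) added <- added + 1L
    pos <- pos + 3L
  }
  if (is.na(q)) {
    return(list(category = "frameshift_ptc", added = NA_integer_, nmd = FALSE))
  }
  ## last exon-exon junction position in spliced coordinates
  widths <- variant$exon_ends - variant$exon_starts + 1L
  last_exon_width <- if (variant$strand == "+") widths[length(widths)] else widths[1L]
  last_junction <- sum(widths) - last_exon_width
  nmd <- (last_junction - (q + 2L)) > 50L

  if (q <= b2 && q + 2L >= b1) {
    list(category = "ptc_in_novel_exon", added = added, nmd = nmd)
  } else if (exon_len %% 3L == 0L) {
    list(category = "in_frame_addition", added = NA_integer_, nmd = FALSE)
  } else {
    list(category = "frameshift_ptc", added = NA_integer_, nmd = nmd)
  }
}

## ---- exhaustive alternative-splicing event oracle (string-key based)

event_oracle <- function(tx, ty) {
  keys <- character(0)
  strand <- tx$strand
  exon_key <- function(tm) paste(tm$exon_starts, tm$exon_ends)
  junction_key <- function(tm) {
    k <- length(tm$exon_starts)
    if (k < 2L) return(character(0))
    paste(tm$exon_ends[-k], tm$exon_starts[-1L])
  }
  for (pair in list(list(tx, ty), list(ty, tx))) {
    a <- pair[[1L]]; b <- pair[[2L]]
    ka <- length(a$exon_starts)
    ex_b <- exon_key(b)
    jn_b <- junction_key(b)
    ## SE
    if (ka >= 3L) {
      for (j in 2:(ka - 1L)) {
        if (paste(a$exon_ends[j - 1L], a$exon_starts[j + 1L]) %in% jn_b &&
            !(paste(a$exon_starts[j], a$exon_ends[j]) %in% ex_b)) {
          keys <- c(keys, paste("SE", a$exon_starts[j], a$exon_ends[j]))
        }
      }
    }
    ## RI
    if (ka >= 2L) {
      for (j in 1:(ka - 1L)) {
        if (paste(a$exon_starts[j], a$exon_ends[j + 1L]) %in% ex_b) {
          keys <- c(keys, paste("RI", a$exon_ends[j] + 1L, a$exon_starts[j + 1L] - 1L))
        }
      }
    }
    ## MXE
    kb <- length(b$exon_starts)
    if (ka >= 3L && kb >= 3L) {
      for (j in 2:(ka - 1L)) {
        for (m in 2:(kb - 1L)) {
          e1 <- c(a$exon_starts[j], a$exon_ends[j])
          e2 <- c(b$exon_starts[m], b$exon_ends[m])
          if (identical(e1, e2)) next
          if (!(e1[2] < e2[1] || e2[2] < e1[1])) next
          if (a$exon_ends[j - 1L] != b$exon_ends[m - 1L]) next
          if (a$exon_starts[j + 1L] != b$exon_starts[m + 1L]) next
          if (paste(e1[1], e1[2]) %in% ex_b) next
          if (paste(e2[1], e2[2]) %in% exon_key(a)) next
          lo <- if (e1[1] <= e2[1]) e1 else e2
          hi <- if (e1[1] <= e2[1]) e2 else e1
          keys <- c(keys, paste("MXE", lo[1], lo[2], hi[1], hi[2]))
        }
      }
    }
    ## A5SS / A3SS via intron pairs
    ia <- cbind(a$exon_ends[-ka] + 1L, a$exon_starts[-1L] - 1L)
    ib <- cbind(b$exon_ends[-kb] + 1L, b$exon_starts[-1L] - 1L)
    if (ka >= 2L && kb >= 2L) {
      for (u in seq_len(nrow(ia))) {
        for (v in seq_len(nrow(ib))) {
          if (ia[u, 1] == ib[v, 1] && ia[u, 2] != ib[v, 2]) {
            fa <- a$exon_ends[which(a$exon_starts == ia[u, 2] + 1L)]
            fb <- b$exon_ends[which(b$exon_starts == ib[v, 2] + 1L)]
            if (length(fa) == 1L && length(fb) == 1L && fa == fb) {
              type <- if (strand == "+") "A3SS" else "A5SS"
              keys <- c(keys, paste(type, min(ia[u, 2], ib[v, 2]) + 1L,
                                    max(ia[u, 2], ib[v, 2])))
            }
          }
          if (ia[u, 2] == ib[v, 2] && ia[u, 1] != ib[v, 1]) {
            pa <- a$exon_starts[which(a$exon_ends == ia[u, 1] - 1L)]
            pb <- b$exon_starts[which(b$exon_ends == ib[v, 1] - 1L)]
            if (length(pa) == 1L && length(pb) == 1L && pa == pb) {
              type <- if (strand == "+") "A5SS" else "A3SS"
              keys <- c(keys, paste(type, min(ia[u, 1], ib[v, 1]),
                                    max(ia[u, 1], ib[v, 1]) - 1L))
            }
          }
        }
      }
    }
  }
  sort(unique(keys))
}

## implementation events rendered with the same keys for comparison
event_keys <- function(events) {
  if (nrow(events) == 0L) return(character(0))
  keys <- ifelse(events$event_type == "MXE",
                 paste(events$event_type, events$var_start, events$var_end,
                       events$var2_start, events$var2_end),
                 paste(events$event_type, events$var_start, events$var_end))
  sort(unique(keys))
}

## all exon chains with up to 4 exons drawn from a fixed boundary grid
all_exon_chains <- function(bounds = seq(10L, 80L, by = 10L)) {
  chains <- list()
  for (m in 1:4) {
    if (2L * m > length(bounds)) break
    cmb <- utils::combn(bounds, 2L * m)
    for (j in seq_len(ncol(cmb))) {
      v <- cmb[, j]
      chains[[length(chains) + 1L]] <- list(starts = v[seq(1L, 2L * m, 2L)],
                                            ends = v[seq(2L, 2L * m, 2L)])
    }
  }
  chains
}
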