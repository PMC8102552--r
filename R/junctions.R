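#' Construct a junction count record
#'
#' The informative-read substrate for PSI estimation: counts of reads
#' supporting each inclusion junction and each skipping junction of one
#' splicing event in one sample.  Both sides must define at least one
#' junction; counts are non-negative integers.
#'
#' @param event_id,sample_id Identifiers.
#' @param inclusion,skipping Non-negative integer vectors, one element per
#'   junction on the respective side.
#' @return An object of class `junction_count_record`.
#' @export
junction_count_record <- function(event_id, sample_id, inclusion, skipping) {
  check_counts <- function(x, side) {
    if (length(x) == 0L) {
      stopf("event '%s' sample '%s': %s junction list must be non-empty",
            event_id, sample_id, side)
    }
    if (anyNA(x) || any(x < 0) || any(x != floor(x))) {
      stopf("event '%s' sample '%s': %s counts must be non-negative integers",
            event_id, sample_id, side)
    }
    as.integer(x)
  }
  structure(
    list(event_id = as.character(event_id),
         sample_id = as.character(sample_id),
         inclusion = check_counts(inclusion, "inclusion"),
         skipping = check_counts(skipping, "skipping")),
    class = "junction_count_record")
}

#' @export
print.junction_count_record <- function(x, ...) {
  cat(sprintf("junction_count_record %s / %s: inc [%s], skip [%s]\n",
              x$event_id, x$sample_id,
              paste(x$inclusion, collapse = ","),
              paste(x$skipping, collapse = ",")))
  invisible(x)
}

#' Read junction count records from a long-format TSV
#'
#' Expected columns: `event_id`, `sample_id`, `junction_role`
#' (`inc`/`skip`), `junction_index`, `count`.
#'
#' @param path Path to a tab-separated file with header.
#' @return A list of [junction_count_record] objects, one per
#'   (event, sample) pair, in file order of first appearance.
#' @export
read_junction_counts <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("event_id", "sample_id", "junction_role", "junction_index", "count")
  if (!all(need %in% names(df))) {
    stopf("counts table '%s' must have columns: %s", path, paste(need, collapse = ", "))
  }
  if (!all(df$junction_role %in% c("inc", "skip"))) {
    stopf("junction_role must be 'inc' or 'skip'")
  }
  key <- paste(df$event_id, df$sample_id, sep = "\r")
  lapply(unique(key), function(k) {
    sub <- df[key == k, , drop = FALSE]
    inc <- sub[sub$junction_role == "inc", , drop = FALSE]
    skp <- sub[sub$junction_role == "skip", , drop = FALSE]
    junction_count_record(sub$event_id[1L], sub$sample_id[1L],
                          inc$count[order(inc$junction_index)],
                          skp$count[order(skp$junction_index)])
  })
}

#' Write junction count records to a long-format TSV
#'
#' @param records A list of [junction_count_record] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_junction_counts <- function(records, path) {
  rows <- lapply(records, function(r) {
    data.frame(
      event_id = r$event_id, sample_id = r$sample_id,
      junction_role = rep(c("inc", "skip"), c(length(r$inclusion), length(r$skipping))),
      junction_index = c(seq_along(r$inclusion), seq_along(r$skipping)),
      count = c(r$inclusion, r$skipping),
      stringsAsFactors = FALSE)
  })
  write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a protein-domain annotation table
#'
#' Expected columns: `gene_id`, `domain_name`, `aa_start`, `aa_end`
#' (1-based inclusive protein coordinates on the canonical protein).
#'
#' @param path Path to a tab-separated file with header.
#' @return A data frame with the validated columns.
#' @export
read_domain_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "domain_name", "aa_start", "aa_end")
  if (!all(need %in% names(df))) {
    stopf("domain table '%s' must have columns: %s", path, paste(need, collapse = ", "))
  }
  if (any(df$aa_start < 1L) || any(df$aa_end < df$aa_start)) {
    stopf("domain table '%s': require 1 <= aa_start <= aa_end", path)
  }
  df[need]
}
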