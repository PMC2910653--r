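#' Detect nested retroposon insertions (TinT events)
#'
#' Scans a coordinate-sorted repeat annotation for
#' transposition-in-transposition events: a guest element lying strictly
#' between two fragments of the same host family on the same strand, with no
#' other annotated hit intervening, where the two host fragments have
#' near-continuous consensus coordinates (the signature of a single host
#' copy split by the guest's insertion).
#'
#' Continuity is measured as the consensus gap between the two host
#' fragments: `consensus_start(right) - consensus_end(left) - 1` on the plus
#' strand (mirrored on the minus strand, where the genomically left fragment
#' carries the consensus 3' end). An event is emitted when the absolute gap
#' is at most `continuity_window`. Both host fragments must be at least
#' `min_fragment` bp long. When two candidate guests sit between the same
#' pair of host fragments the configuration is ambiguous and no event is
#' emitted for that host pair; each hit appears at most once as a guest.
#' Self-nesting (guest and host of the same family) is detected like any
#' other combination.
#'
#' @param annotation A [repeat_annotation()], typically already restricted
#'   with [filter_families()] to the families under study.
#' @param continuity_window Maximum absolute consensus gap (bp) between the
#'   host fragments. Default 30.
#' @param min_fragment Minimum host fragment length (bp). Default 30.
#'
#' @return A tibble with one row per event: guest and host hit identifiers,
#'   families, genomic location, and the consensus continuity gap.
#' @export
detect_nested_insertions <- function(annotation, continuity_window = 30,
                                     min_fragment = 30) {
  stopifnot(continuity_window >= 0, min_fragment >= 1)
  empty <- tibble(
    sequence_id = character(), guest_hit_id = character(),
    host_left_id = character(), host_right_id = character(),
    guest_family = character(), host_family = character(),
    guest_start = integer(), guest_end = integer(),
    continuity_gap = integer())
  if (nrow(annotation) < 3) return(empty)
  h <- as_tibble(annotation)
  h <- h %>%
    group_by(.data$sequence_id) %>%
    mutate(
      l_id = lag(.data$hit_id), r_id = lead(.data$hit_id),
      l_family = lag(.data$family), r_family = lead(.data$family),
      l_strand = lag(.data$strand), r_strand = lead(.data$strand),
      l_gs = lag(.data$genome_start), l_ge = lag(.data$genome_end),
      r_gs = lead(.data$genome_start), r_ge = lead(.data$genome_end),
      l_cs = lag(.data$consensus_start), l_ce = lag(.data$consensus_end),
      r_cs = lead(.data$consensus_start), r_ce = lead(.data$consensus_end)) %>%
    ungroup()
  h <- h %>%
    filter(!is.na(.data$l_id), !is.na(.data$r_id),
           .data$l_family == .data$r_family,
           .data$l_strand == .data$r_strand,
           .data$l_ge < .data$genome_start,
           .data$genome_end < .data$r_gs,
           .data$l_ge - .data$l_gs + 1 >= min_fragment,
           .data$r_ge - .data$r_gs + 1 >= min_fragment) %>%
    mutate(continuity_gap = ifelse(.data$l_strand == "+",
                                   .data$r_cs - .data$l_ce - 1L,
                                   .data$l_cs - .data$r_ce - 1L)) %>%
    filter(abs(.data$continuity_gap) <= continuity_window)
  if (nrow(h) == 0) return(empty)
  h %>%
    mutate(guest_hit_id = .data$hit_id, host_left_id = .data$l_id,
           host_right_id = .data$r_id, guest_family = .data$family,
           host_family = .data$l_family, guest_start = .data$genome_start,
           guest_end = .data$genome_end,
           continuity_gap = as.integer(.data$continuity_gap)) %>%
    select("sequence_id", "guest_hit_id", "host_left_id", "host_right_id",
           "guest_family", "host_family", "guest_start", "guest_end",
           "continuity_gap")
}

#' Build the guest-into-host TinT count matrix
#'
#' @param events Event tibble from [detect_nested_insertions()] (or a
#'   simulator truth ledger with `guest_family`/`host_family` columns).
#' @param families Ordered character vector of family names defining the
#'   matrix dimension. Defaults to the sorted union of families seen in the
#'   events. An event family missing from the list is an error.
#'
#' @return An integer matrix of class `tint_matrix` with `counts[i, j]` the
#'   number of events of guest family `i` nested inside host family `j`, and
#'   attribute `total_events`.
#' @export
build_tint_matrix <- function(events, families = NULL) {
  if (is.null(families)) {
    families <- sort(unique(c(events$guest_family, events$host_family)))
  }
  unknown <- setdiff(unique(c(events$guest_family, events$host_family)),
                     families)
  if (length(unknown) > 0) {
    abort(paste0("event families not in the family list: ",
                 paste(unknown, collapse = ", ")))
  }
  m <- matrix(0L, length(families), length(families),
              dimnames = list(guest = families, host = families))
  if (nrow(events) > 0) {
    tab <- table(factor(events$guest_family, levels = families),
                 factor(events$host_family, levels = families))
    m[] <- as.integer(tab)
  }
  attr(m, "total_events") <- if (is.null(events)) 0L else nrow(events)
  class(m) <- c("tint_matrix", "matrix", "array")
  m
}

#' @export
print.tint_matrix <- function(x, ...) {
  cat("<tint_matrix> ", nrow(x), " families, ",
      attr(x, "total_events"), " nested insertions (rows = guest, columns = host)\n",
      sep = "")
  print(unclass(x)[seq_len(nrow(x)), seq_len(ncol(x))])
  invisible(x)
}

#' @export
as_tibble.tint_matrix <- function(x, ...) {
  fam <- rownames(x)
  tibble(guest_family = rep(fam, times = length(fam)),
         host_family = rep(fam, each = length(fam)),
         n = as.integer(unclass(x)))
}

#' Write / read a TinT count matrix as delimited text
#'
#' Plain tab-separated table with a family header row and a family name
#' first column (rows = guest family, columns = host family).
#'
#' @param x A `tint_matrix`.
#' @param path File path.
#' @return `path` invisibly for the writer; a `tint_matrix` for the reader.
#' @export
write_tint_matrix <- function(x, path) {
  df <- cbind(data.frame(family = rownames(x)), as.data.frame(unclass(x)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tint_matrix
#' @export
read_tint_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  fam <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  dimnames(m) <- list(guest = fam, host = fam)
  attr(m, "total_events") <- sum(m)
  class(m) <- c("tint_matrix", "matrix", "array")
  m
}
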