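#' Construct a marker locus alignment
#'
#' A marker locus is a gapped multiple alignment of one orthologous genomic
#' site across taxa, with the candidate retroposon's alignment columns and
#' its annotation (subtype, orientation, target-site duplication) recorded
#' for the taxa where they are known. Per-taxon annotations default to the
#' locus-level values.
#'
#' @param alignment Named character vector of equal-length gapped sequences
#'   over `A C G T N -` (case-insensitive). Replicate sequences of one taxon
#'   may be given as `taxon|1`, `taxon|2`, ...
#' @param candidate_span Integer pair: first and last alignment column of
#'   the candidate element.
#' @param element_subtype Element subtype label (e.g. `"MIR3_Mars"`).
#' @param element_strand `"+"` or `"-"`.
#' @param tsd Optional target-site duplication sequence.
#' @param taxon_info Optional tibble with columns `taxon` and any of
#'   `subtype`, `strand`, `tsd` overriding the locus-level annotation for
#'   individual taxa.
#' @return An object of class `marker_locus`.
#' @export
marker_locus <- function(alignment, candidate_span, element_subtype = NA,
                         element_strand = "+", tsd = NULL,
                         taxon_info = NULL) {
  if (is.null(names(alignment))) abort("`alignment` must be named by taxon")
  lens <- nchar(alignment)
  if (length(unique(lens)) != 1) {
    abort("all aligned sequences must have equal length")
  }
  if (length(candidate_span) != 2 || candidate_span[1] < 1 ||
      candidate_span[2] > lens[1] || candidate_span[1] > candidate_span[2]) {
    abort("`candidate_span` must be an in-bounds column range")
  }
  structure(list(alignment = toupper(alignment),
                 candidate_span = as.integer(candidate_span),
                 element_subtype = element_subtype,
                 element_strand = element_strand, tsd = tsd,
                 taxon_info = taxon_info),
            class = "marker_locus")
}

locus_taxon_meta <- function(locus, taxon) {
  meta <- list(subtype = locus$element_subtype,
               strand = locus$element_strand, tsd = locus$tsd)
  ti <- locus$taxon_info
  if (!is.null(ti) && taxon %in% ti$taxon) {
    row <- ti[ti$taxon == taxon, ]
    for (f in intersect(c("subtype", "strand", "tsd"), names(row))) {
      if (!is.na(row[[f]][1])) meta[[f]] <- row[[f]][1]
    }
  }
  meta
}

#' Validate a candidate marker across taxa
#'
#' Scores each taxon of a locus alignment for the candidate element using
#' the orthology criteria: (1) identical genomic insertion points (the
#' element occupies the same alignment columns, within `slop`), (2)
#' identical element orientation, (3) identical element subtype, (4)
#' concurrent flanking target-site duplications where recorded, (5) shared
#' diagnostic indels (identical gap pattern inside the element span), and
#' (6) consistency across replicate sequences of the same taxon. A taxon is
#' called present only if every checkable criterion passes; absent requires
#' a clean empty site (aligned flanks, no residue in the span); anything
#' else -- a shifted, partial, reoriented or otherwise discordant element,
#' or an inconsistent replicate set -- is missing.
#'
#' @param locus A [marker_locus()].
#' @param reference_taxon Taxon carrying the element that the other taxa are
#'   compared against; must be present at the locus.
#' @param slop Allowed insertion-point shift in alignment columns
#'   (default 2).
#' @param flank_window Columns on each side of the span used to check that
#'   flanks align (default 10).
#'
#' @return A list with `states` (named character vector of calls) and
#'   `report` (a tibble with one row per taxon and a logical column per
#'   criterion; `NA` = not checkable).
#' @export
validate_marker <- function(locus, reference_taxon, slop = 2,
                            flank_window = 10) {
  aln <- locus$alignment
  base_taxon <- sub("\\|.*$", "", names(aln))
  if (!reference_taxon %in% base_taxon) {
    abort("alignment lacks the reference taxon")
  }
  span <- locus$candidate_span
  chars <- strsplit(aln, "")
  span_cols <- span[1]:span[2]
  occupancy <- function(i) {
    s <- chars[[i]][span_cols]
    which(s != "-")
  }
  ref_i <- which(base_taxon == reference_taxon)[1]
  ref_occ <- occupancy(ref_i)
  if (length(ref_occ) == 0) {
    abort("the reference taxon must carry the element (present)")
  }
  ref_meta <- locus_taxon_meta(locus, reference_taxon)
  ref_gaps <- setdiff(seq(min(ref_occ), max(ref_occ)), ref_occ)

  eval_seq <- function(i) {
    taxon <- base_taxon[i]
    occ <- occupancy(i)
    width <- nchar(aln[i])
    flank_cols <- c(
      if (span[1] > 1) seq(max(1, span[1] - flank_window), span[1] - 1),
      if (span[2] < width) seq(span[2] + 1, min(width, span[2] + flank_window)))
    flank_cov <- mean(chars[[i]][flank_cols] != "-")
    if (length(occ) == 0) {
      state <- if (flank_cov >= 0.5) "absent" else "missing"
      return(tibble(taxon = taxon, call = state,
                    insertion_point = NA, orientation = NA, subtype = NA,
                    tsd = NA, diagnostic_indels = NA, consistency = NA))
    }
    meta <- locus_taxon_meta(locus, taxon)
    c1 <- abs(min(occ) - min(ref_occ)) <= slop &&
      abs(max(occ) - max(ref_occ)) <= slop
    c2 <- if (is.na(meta$strand) || is.na(ref_meta$strand)) NA else
      meta$strand == ref_meta$strand
    c3 <- if (is.na(meta$subtype) || is.na(ref_meta$subtype)) NA else
      meta$subtype == ref_meta$subtype
    c4 <- if (is.null(meta$tsd) || is.null(ref_meta$tsd)) NA else
      toupper(meta$tsd) == toupper(ref_meta$tsd)
    gaps <- setdiff(seq(min(occ), max(occ)), occ)
    c5 <- if (!c1) NA else setequal(gaps, ref_gaps)
    ok <- all(unlist(Filter(Negate(is.na), list(c1, c2, c3, c4, c5))))
    tibble(taxon = taxon, call = if (ok) "present" else "missing",
           insertion_point = c1, orientation = c2, subtype = c3,
           tsd = if (is.null(c4)) NA else c4,
           diagnostic_indels = c5, consistency = NA)
  }
  per_seq <- bind_rows(lapply(seq_along(aln), eval_seq))
  # criterion 6: replicate sequences of one taxon must agree
  report <- per_seq %>%
    group_by(.data$taxon) %>%
    summarise(across(c("insertion_point", "orientation", "subtype", "tsd",
                       "diagnostic_indels"),
                     ~ if (all(is.na(.x))) NA else all(.x, na.rm = TRUE)),
              consistency = length(unique(.data$call)) == 1,
              call = if (length(unique(.data$call)) == 1) .data$call[1] else
                "missing",
              .groups = "drop")
  states <- setNames(report$call, report$taxon)
  list(states = states, report = report)
}

#' Build a schematic synthetic locus alignment
#'
#' Constructs a small gapped alignment with known truth for exercising
#' [validate_marker()]: shared random flanks, an element block inserted in
#' the taxa marked present, a clean empty site in the taxa marked absent,
#' a destroyed site (non-specific deletion spanning the locus) for taxa
#' marked deleted, and an option to shift one taxon's element. The
#' sequences are schematic (uniform random letters), not simulated
#' nucleotide evolution.
#'
#' @param true_states Named character vector over
#'   `c("present", "absent", "deleted")`.
#' @param element_len,flank Element and flank lengths in columns.
#' @param shift_taxon Optional taxon whose element is shifted by
#'   `shift_by` columns (a criterion-1 violation when beyond the slop).
#' @param shift_by Shift amount in columns.
#' @param subtype Element subtype label recorded on the locus.
#' @param seed Integer seed.
#' @return A [marker_locus()] whose names carry the truth in
#'   `attr(, "true_states")`.
#' @export
make_synthetic_locus <- function(true_states, element_len = 20, flank = 15,
                                 shift_taxon = NULL, shift_by = 0,
                                 subtype = "SINE_X1", seed = 1) {
  stopifnot(all(true_states %in% c("present", "absent", "deleted")))
  set.seed(seed)
  letters4 <- c("A", "C", "G", "T")
  fl <- function(n) paste(sample(letters4, n, replace = TRUE), collapse = "")
  left <- fl(flank); right <- fl(flank)
  elem <- fl(element_len)
  pad <- max(0, abs(shift_by))
  width_elem <- element_len + pad
  seqs <- vapply(names(true_states), function(tx) {
    st <- true_states[[tx]]
    if (st == "present") {
      sh <- if (!is.null(shift_taxon) && tx == shift_taxon) shift_by else 0
      body <- paste0(strrep("-", sh), elem, strrep("-", pad - sh))
      paste0(left, body, right)
    } else if (st == "absent") {
      paste0(left, strrep("-", width_elem), right)
    } else { # deleted: the site and part of the flanks are gone
      keep <- max(1, flank - 8)
      paste0(substr(left, 1, keep),
             strrep("-", flank - keep + width_elem + flank - keep),
             substr(right, nchar(right) - keep + 1, nchar(right)))
    }
  }, "")
  locus <- marker_locus(seqs,
                        candidate_span = c(flank + 1, flank + width_elem),
                        element_subtype = subtype)
  attr(locus, "true_states") <- true_states
  locus
}
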