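marker_symbols <- c(present = "+", absent = "-", missing = "?", deleted = "d")

#' Construct a presence/absence marker matrix
#'
#' A marker matrix records, for each taxon and each retroposon insertion
#' locus (marker), one of four states: present (`+`), absent (`-`), missing
#' data (`?`), or deleted (`d`, a non-specific deletion that destroyed the
#' site). Because a deletion makes presence unknowable, `d` is treated as
#' missing in every downstream computation (counting and parsimony), not as
#' absence.
#'
#' @param states Character matrix (taxa in rows, markers in columns) with
#'   entries in `+ - ? d`, or the equivalent `1 0 ?` coding.
#' @param taxa,markers Optional label vectors overriding the dimnames.
#' @param outgroup Optional outgroup taxon label (must be among the taxa).
#'
#' @return An object of class `marker_matrix`.
#' @export
marker_matrix <- function(states, taxa = rownames(states),
                          markers = colnames(states), outgroup = NULL) {
  states <- as.matrix(states)
  states[states == "1"] <- "+"
  states[states == "0"] <- "-"
  bad <- !states %in% c("+", "-", "?", "d")
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1, ]
    abort(sprintf("unknown marker state '%s' at row %d, column %d",
                  states[bad][1], idx[1], idx[2]))
  }
  if (is.null(taxa)) taxa <- sprintf("t%d", seq_len(nrow(states)))
  if (is.null(markers)) markers <- sprintf("m%d", seq_len(ncol(states)))
  if (anyDuplicated(taxa)) abort("taxon labels must be unique")
  if (anyDuplicated(markers)) abort("marker labels must be unique")
  if (!is.null(outgroup) && !outgroup %in% taxa) {
    abort("`outgroup` must be one of the taxa")
  }
  dimnames(states) <- list(taxa, markers)
  structure(list(states = states, taxa = taxa, markers = markers,
                 outgroup = outgroup),
            class = "marker_matrix")
}

#' @export
print.marker_matrix <- function(x, ...) {
  cat("<marker_matrix> ", length(x$taxa), " taxa x ", length(x$markers),
      " markers", if (!is.null(x$outgroup)) paste0(", outgroup ", x$outgroup),
      "\n", sep = "")
  tab <- table(factor(x$states, levels = c("+", "-", "?", "d")))
  cat("  states: ", paste(names(tab), tab, sep = "=", collapse = "  "), "\n",
      sep = "")
  invisible(x)
}

#' @export
as_tibble.marker_matrix <- function(x, ...) {
  tibble(taxon = rep(x$taxa, times = length(x$markers)),
         marker = rep(x$markers, each = length(x$taxa)),
         state = as.vector(x$states))
}

#' @export
autoplot.marker_matrix <- function(object, ...) {
  d <- as_tibble(object) %>%
    mutate(taxon = factor(.data$taxon, levels = rev(object$taxa)),
           marker = factor(.data$marker, levels = object$markers))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$marker, y = .data$taxon,
                                  fill = .data$state)) +
    ggplot2::geom_tile(colour = "grey80") +
    ggplot2::scale_fill_manual(values = c("+" = "grey15", "-" = "white",
                                          "?" = "grey70", "d" = "orange")) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Parse a delimited presence/absence marker table
#'
#' Accepts tab-, comma- or semicolon-delimited text with a header row and a
#' label first column. Symbols may be `+ - ? d` or `1 0 ?`. With
#' `orientation = "markers"` (the layout of the packaged marsupial table)
#' rows are markers and columns are taxa; with `"taxa"` rows are taxa.
#' Taxon order is preserved exactly as given.
#'
#' @param lines Character vector of file lines.
#' @param orientation `"markers"` (rows are markers) or `"taxa"`.
#' @param outgroup Optional outgroup taxon label.
#' @return A [marker_matrix()].
#' @export
parse_marker_matrix <- function(lines, orientation = c("markers", "taxa"),
                                outgroup = NULL) {
  orientation <- match.arg(orientation)
  lines <- lines[!grepl("^\\s*$", lines)]
  if (length(lines) < 2) abort("marker table needs a header and at least one row")
  sep <- if (grepl("\t", lines[1])) "\t" else if (grepl(",", lines[1])) "," else ";"
  cells <- strsplit(lines, sep, fixed = TRUE)
  width <- length(cells[[1]])
  for (i in seq_along(cells)) {
    if (length(cells[[i]]) != width) {
      abort(sprintf("ragged marker table: row %d has %d fields, expected %d",
                    i, length(cells[[i]]), width))
    }
  }
  header <- trimws(cells[[1]][-1])
  labels <- vapply(cells[-1], function(r) trimws(r[1]), "")
  body <- t(vapply(cells[-1], function(r) trimws(r[-1]), character(width - 1)))
  for (i in seq_len(nrow(body))) {
    bad <- which(!body[i, ] %in% c("+", "-", "?", "d", "1", "0"))
    if (length(bad) > 0) {
      abort(sprintf("unknown marker state '%s' at data row %d, column %d",
                    body[i, bad[1]], i, bad[1]))
    }
  }
  if (orientation == "markers") {
    marker_matrix(t(body), taxa = header, markers = labels,
                  outgroup = outgroup)
  } else {
    marker_matrix(body, taxa = labels, markers = header, outgroup = outgroup)
  }
}

#' Read / write marker matrices as delimited text
#'
#' @param path File path.
#' @param x A [marker_matrix()].
#' @param orientation Table layout, see [parse_marker_matrix()].
#' @param outgroup Optional outgroup taxon label.
#' @param symbols `"signs"` writes `+ - ? d`; `"binary"` writes `1 0 ?`
#'   (deleted collapses to `?`).
#' @return The reader returns a [marker_matrix()]; the writer returns
#'   `path` invisibly.
#' @export
read_marker_matrix <- function(path, orientation = c("markers", "taxa"),
                               outgroup = NULL) {
  parse_marker_matrix(readLines(path), orientation, outgroup)
}

#' @rdname read_marker_matrix
#' @export
write_marker_matrix <- function(x, path, orientation = c("markers", "taxa"),
                                symbols = c("signs", "binary")) {
  orientation <- match.arg(orientation)
  symbols <- match.arg(symbols)
  states <- x$states
  if (symbols == "binary") {
    states[states == "+"] <- "1"
    states[states == "-"] <- "0"
    states[states == "d"] <- "?"
  }
  if (orientation == "markers") {
    out <- rbind(c("marker", x$taxa), cbind(x$markers, t(states)))
  } else {
    out <- rbind(c("taxon", x$markers), cbind(x$taxa, states))
  }
  writeLines(apply(out, 1, paste, collapse = "\t"), path)
  invisible(path)
}

#' Write a marker matrix as a NEXUS data block
#'
#' Binary coding (`1` present, `0` absent, `?` missing or deleted), for
#' interoperability with parsimony software.
#'
#' @param x A [marker_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_nexus_matrix <- function(x, path) {
  states <- x$states
  states[states == "+"] <- "1"
  states[states == "-"] <- "0"
  states[states == "d"] <- "?"
  rows <- paste0("    ", format(x$taxa, width = max(nchar(x$taxa)) + 2),
                 apply(states, 1, paste, collapse = ""))
  writeLines(c(
    "#NEXUS", "BEGIN DATA;",
    sprintf("  DIMENSIONS NTAX=%d NCHAR=%d;", length(x$taxa),
            length(x$markers)),
    "  FORMAT DATATYPE=STANDARD SYMBOLS=\"01\" MISSING=?;",
    "  MATRIX", rows, "  ;", "END;"), path)
  invisible(path)
}

#' The packaged marsupial retroposon marker matrix
#'
#' The transcription of the published 21-taxon x 53-marker presence/absence
#' table of marsupial retroposon insertions (20 marsupials covering all
#' seven orders plus a human outgroup scored absent throughout). Taxa are
#' labelled with full species names because the original table abbreviates
#' two different taxa as "Pt"; column order follows the original exactly.
#'
#' @return A [marker_matrix()] with outgroup `Homo_sapiens`.
#' @export
marsupial_markers <- function() {
  path <- system.file("extdata", "marsupial_markers.tsv",
                      package = "retromark", mustWork = TRUE)
  read_marker_matrix(path, orientation = "markers", outgroup = "Homo_sapiens")
}

#' Marsupial taxon groups of the packaged marker matrix
#'
#' Named list of taxon labels by order, plus the composite clades used in
#' the analysis: Australidelphia (Microbiotheria + the four Australasian
#' orders), Euaustralidelphia (the four Australasian orders), and the full
#' marsupial ingroup.
#'
#' @return Named list of character vectors.
#' @export
marsupial_taxon_groups <- function() {
  g <- list(
    didelphimorphia = c("Monodelphis_domestica", "Didelphis_virginiana",
                        "Metachirus_nudicaudatus"),
    paucituberculata = c("Rhyncholestes_raphanurus", "Caenolestes_fuliginosus"),
    microbiotheria = "Dromiciops_gliroides",
    notoryctemorphia = "Notoryctes_typhlops",
    dasyuromorphia = c("Phascogale_tapoatafa", "Dasyurus_geoffroii",
                       "Sminthopsis_crassicaudata", "Myrmecobius_fasciatus"),
    peramelemorphia = c("Macrotis_lagotis", "Perameles_gunnii",
                        "Isoodon_obesulus"),
    diprotodontia = c("Tarsipes_rostratus", "Pseudocheirus_peregrinus",
                      "Trichosurus_vulpecula", "Macropus_robustus",
                      "Potorous_tridactylus", "Vombatus_ursinus"),
    outgroup = "Homo_sapiens")
  g$euaustralidelphia <- c(g$notoryctemorphia, g$dasyuromorphia,
                           g$peramelemorphia, g$diprotodontia)
  g$australidelphia <- c(g$microbiotheria, g$euaustralidelphia)
  g$marsupials <- c(g$didelphimorphia, g$paucituberculata, g$australidelphia)
  g
}

#' Count marker support for a clade hypothesis
#'
#' Counts the `[k l m]` support pattern of a marker matrix around one
#' internal edge. `k` is the number of markers present in every scored
#' focal taxon and absent in every scored taxon outside the clade; missing
#' and deleted states are compatible with either side and are skipped, and
#' a marker with no scored taxon on one side does not count. When `split`
#' divides the focal clade into its two daughter lineages `s1` and `s2`,
#' the conflicting counts are `l` (markers grouping `s1` with the outside
#' taxa to the exclusion of `s2`) and `m` (markers grouping `s2` with the
#' outside), the two alternative resolutions of the trichotomy at the edge.
#' Without a `split`, no alternative grouping is evaluated and `l = m = 0`.
#'
#' @param x A [marker_matrix()].
#' @param focal Character vector: taxa of the hypothesized clade.
#' @param outside Taxa outside the clade; defaults to all remaining taxa.
#' @param split Optional list of two character vectors partitioning
#'   `focal` into its daughter lineages.
#' @return An object of class `support_pattern` with fields `k`, `l`, `m`.
#' @export
support_pattern <- function(x, focal, outside = NULL, split = NULL) {
  if (length(focal) == 0) abort("`focal` must be non-empty")
  if (!all(focal %in% x$taxa)) {
    abort(paste0("focal taxa not in matrix: ",
                 paste(setdiff(focal, x$taxa), collapse = ", ")))
  }
  if (is.null(outside)) outside <- setdiff(x$taxa, focal)
  count_side <- function(inside, outside) {
    ins <- x$states[inside, , drop = FALSE]
    out <- x$states[outside, , drop = FALSE]
    ins_scored <- colSums(ins == "+" | ins == "-")
    out_scored <- colSums(out == "+" | out == "-")
    ins_ok <- colSums(ins == "-") == 0 & ins_scored > 0
    out_ok <- colSums(out == "+") == 0 & out_scored > 0
    sum(ins_ok & out_ok)
  }
  k <- count_side(focal, outside)
  l <- m <- 0L
  if (!is.null(split)) {
    stopifnot(length(split) == 2)
    s1 <- split[[1]]; s2 <- split[[2]]
    if (!setequal(c(s1, s2), focal) || length(intersect(s1, s2)) > 0) {
      abort("`split` must partition the focal clade into two disjoint sets")
    }
    # the alternative groupings are clades of the ingroup: the outgroup can
    # never sit inside them, so it is left out of the present-side; with no
    # in-frame outside lineage left there is no alternative to support
    out_in <- setdiff(outside, x$outgroup)
    if (length(out_in) > 0) {
      l <- count_side(c(s1, out_in), s2)
      m <- count_side(c(s2, out_in), s1)
    }
  }
  structure(list(k = as.integer(k), l = as.integer(l), m = as.integer(m),
                 focal = focal, outside = outside),
            class = "support_pattern")
}

#' @export
print.support_pattern <- function(x, ...) {
  cat(sprintf("<support_pattern> [%d %d %d] (clade of %d taxa vs %d outside)\n",
              x$k, x$l, x$m, length(x$focal), length(x$outside)))
  invisible(x)
}

#' Pairwise marker conflicts
#'
#' Two presence/absence markers conflict when, restricted to scored taxa,
#' their present-sets overlap but neither is nested in the other -- i.e.
#' some taxon is present for both, some taxon is present for the first and
#' scored absent for the second, and vice versa. On a homoplasy-free
#' matrix every pair is compatible (nested or disjoint).
#'
#' @param x A [marker_matrix()].
#' @return A tibble of conflicting marker pairs (zero rows when the matrix
#'   is conflict-free).
#' @export
marker_conflicts <- function(x) {
  p <- x$states == "+"
  a <- x$states == "-"
  nm <- length(x$markers)
  out <- list()
  for (i in seq_len(nm - 1)) {
    for (j in seq(i + 1, nm)) {
      if (any(p[, i] & p[, j]) && any(p[, i] & a[, j]) &&
          any(a[, i] & p[, j])) {
        out[[length(out) + 1]] <- tibble(marker_a = x$markers[i],
                                         marker_b = x$markers[j])
      }
    }
  }
  if (length(out) == 0) {
    tibble(marker_a = character(), marker_b = character())
  } else {
    bind_rows(out)
  }
}
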