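#' Construct a repeat annotation
#'
#' A repeat annotation is a tibble of repeat hits -- one row per annotated
#' repeat fragment -- in the RepeatMasker coordinate convention: 1-based,
#' fully closed intervals on both the genomic sequence and the family
#' consensus. Rows are sorted by `(sequence_id, genome_start)` on
#' construction and every hit receives an identifier unique within the
#' annotation.
#'
#' @param hits A data frame with columns `sequence_id`, `genome_start`,
#'   `genome_end`, `strand` (`"+"` or `"-"`), `family`, `repeat_class`,
#'   `consensus_start`, `consensus_end`, and optionally `divergence`,
#'   `score`, `starred` (logical overlap flag) and `rm_id`.
#' @param source_label Genome or species name the annotation describes.
#'
#' @return A tibble of class `repeat_annotation`, coordinate-sorted, with a
#'   `hit_id` column and a `source_label` attribute.
#' @export
repeat_annotation <- function(hits, source_label = "genome") {
  hits <- as_tibble(hits)
  required <- c("sequence_id", "genome_start", "genome_end", "strand",
                "family", "repeat_class", "consensus_start", "consensus_end")
  missing_cols <- setdiff(required, names(hits))
  if (length(missing_cols) > 0) {
    abort(paste0("repeat annotation is missing columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (!"divergence" %in% names(hits)) hits$divergence <- NA_real_
  if (!"score" %in% names(hits)) hits$score <- NA_real_
  if (!"starred" %in% names(hits)) hits$starred <- FALSE
  if (!"rm_id" %in% names(hits)) hits$rm_id <- NA_character_
  if (nrow(hits) > 0) {
    if (any(hits$genome_start >= hits$genome_end)) {
      abort("genome_start must be < genome_end for every hit")
    }
    if (any(hits$consensus_start >= hits$consensus_end)) {
      abort("consensus_start must be < consensus_end for every hit")
    }
    if (!all(hits$strand %in% c("+", "-"))) {
      abort("strand must be '+' or '-'")
    }
  }
  hits <- dplyr::arrange(hits, .data$sequence_id, .data$genome_start,
                         .data$genome_end)
  hits$hit_id <- if (nrow(hits) > 0) sprintf("h%06d", seq_len(nrow(hits))) else character()
  hits <- dplyr::select(
    hits, "hit_id", "sequence_id", "genome_start", "genome_end", "strand",
    "family", "repeat_class", "consensus_start", "consensus_end",
    "divergence", "score", "starred", "rm_id")
  attr(hits, "source_label") <- source_label
  class(hits) <- c("repeat_annotation", class(tibble()))
  hits
}

#' @export
print.repeat_annotation <- function(x, ...) {
  cat("<repeat_annotation> ", attr(x, "source_label"), ": ", nrow(x),
      " hits, ", length(family_catalog(x)), " families\n", sep = "")
  NextMethod()
}

#' Families present in a repeat annotation
#'
#' @param annotation A [repeat_annotation()].
#' @return Character vector of distinct family names.
#' @export
family_catalog <- function(annotation) {
  sort(unique(annotation$family))
}

#' Source label of a repeat annotation
#'
#' @param annotation A [repeat_annotation()].
#' @return The genome/species label the annotation was built with.
#' @export
source_label <- function(annotation) {
  attr(annotation, "source_label")
}

rm_header <- c(
  "   SW   perc perc perc  query     position in query            matching  repeat          position in repeat",
  "score   div. del. ins.  sequence  begin  end          (left)   repeat    class/family  begin  end    (left)   ID",
  "")

strip_parens <- function(x) as.numeric(gsub("[()]", "", x))

#' Parse RepeatMasker .out annotation lines
#'
#' Reads the standard RepeatMasker `.out` table (three header lines followed
#' by whitespace-delimited rows) or a headerless equivalent. Minus-strand
#' rows (printed with orientation `C` and consensus coordinates in
#' `(left) end begin` order) are normalized so that
#' `consensus_start < consensus_end` and the strand is recorded as `"-"`.
#' Rows carrying the trailing `*` higher-scoring-overlap flag are retained
#' and marked in the `starred` column. Columns beyond the ones used here are
#' tolerated and ignored.
#'
#' @param lines Character vector of file lines.
#' @param source_label Genome or species name for the annotation.
#'
#' @return A [repeat_annotation()] tibble; empty input yields an annotation
#'   with zero hits.
#' @export
parse_repeatmasker <- function(lines, source_label = "genome") {
  line_no <- seq_along(lines)
  keep <- !grepl("^\\s*$", lines)
  lines <- lines[keep]
  line_no <- line_no[keep]
  # drop header lines: anything before the first row starting with a number
  is_data <- grepl("^\\s*[0-9]", lines)
  first_data <- which(is_data)[1]
  if (!is.na(first_data)) {
    keep <- seq(first_data, length(lines))
    line_no <- line_no[keep]
    lines <- lines[keep]
  } else {
    lines <- character()
    line_no <- integer()
  }
  if (length(lines) == 0) {
    return(repeat_annotation(tibble(
      sequence_id = character(), genome_start = integer(),
      genome_end = integer(), strand = character(), family = character(),
      repeat_class = character(), consensus_start = integer(),
      consensus_end = integer()), source_label))
  }
  fields <- strsplit(trimws(lines), "\\s+")
  rows <- vector("list", length(fields))
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    if (length(f) < 14) {
      abort(sprintf("malformed RepeatMasker row at line %d: expected >= 14 fields, got %d",
                    line_no[i], length(f)))
    }
    strand <- f[9]
    if (!strand %in% c("+", "C", "-")) {
      abort(sprintf("malformed RepeatMasker row at line %d: unknown orientation '%s'",
                    line_no[i], strand))
    }
    if (strand == "+") {
      cs <- strip_parens(f[12]); ce <- strip_parens(f[13])
    } else {
      # C rows print consensus as (left) end begin
      cs <- strip_parens(f[14]); ce <- strip_parens(f[13])
      strand <- "-"
    }
    gs <- suppressWarnings(as.integer(f[6]))
    ge <- suppressWarnings(as.integer(f[7]))
    if (is.na(gs) || is.na(ge) || is.na(cs) || is.na(ce)) {
      abort(sprintf("malformed RepeatMasker row at line %d: non-numeric coordinates",
                    line_no[i]))
    }
    rows[[i]] <- tibble(
      sequence_id = f[5], genome_start = gs, genome_end = ge,
      strand = strand, family = f[10], repeat_class = f[11],
      consensus_start = as.integer(cs), consensus_end = as.integer(ce),
      divergence = suppressWarnings(as.numeric(f[2])),
      score = suppressWarnings(as.numeric(f[1])),
      starred = length(f) >= 16 && f[16] == "*" || length(f) >= 15 && f[15] == "*",
      rm_id = if (length(f) >= 15 && f[15] != "*") f[15] else NA_character_)
  }
  repeat_annotation(bind_rows(rows), source_label)
}

#' Read a RepeatMasker .out file
#'
#' @param path Path to a `.out` file.
#' @param source_label Genome label; defaults to the file name.
#' @return A [repeat_annotation()].
#' @export
read_repeatmasker <- function(path, source_label = basename(path)) {
  parse_repeatmasker(readLines(path), source_label)
}

#' Write a repeat annotation as a RepeatMasker .out table
#'
#' Emits the three-line header and one row per hit in the RepeatMasker
#' column layout, so that [parse_repeatmasker()] round-trips all fields.
#' Query-left and consensus-left counts, which require sequence lengths the
#' annotation does not carry, are written as `(0)`.
#'
#' @param annotation A [repeat_annotation()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_repeatmasker <- function(annotation, path) {
  fmt_row <- function(i) {
    h <- annotation[i, ]
    score <- if (is.na(h$score)) 0 else h$score
    div <- if (is.na(h$divergence)) 0 else h$divergence
    if (h$strand == "+") {
      cons <- sprintf("%d %d (0)", h$consensus_start, h$consensus_end)
      ori <- "+"
    } else {
      cons <- sprintf("(0) %d %d", h$consensus_end, h$consensus_start)
      ori <- "C"
    }
    id <- if (is.na(h$rm_id)) sub("^h0*", "", h$hit_id) else h$rm_id
    star <- if (isTRUE(h$starred)) " *" else ""
    sprintf("%6.0f %5.1f  0.0  0.0  %s %d %d (0) %s %s %s %s %s%s",
            score, div, h$sequence_id, h$genome_start, h$genome_end,
            ori, h$family, h$repeat_class, cons, id, star)
  }
  rows <- if (nrow(annotation) > 0) vapply(seq_len(nrow(annotation)), fmt_row, "") else character()
  writeLines(c(rm_header, rows), path)
  invisible(path)
}

#' Restrict a repeat annotation to selected families
#'
#' Keeps only hits whose family is in `families`, preserving coordinate
#' order. Families named but absent from the annotation's catalog trigger a
#' warning, not an error.
#'
#' @param annotation A [repeat_annotation()].
#' @param families Non-empty character vector of family names to keep.
#' @return A [repeat_annotation()] containing only the selected hits.
#' @export
filter_families <- function(annotation, families) {
  if (length(families) == 0) abort("`families` must be non-empty")
  absent <- setdiff(families, family_catalog(annotation))
  if (length(absent) > 0) {
    warn(paste0("families not present in annotation: ",
                paste(absent, collapse = ", ")))
  }
  out <- annotation[annotation$family %in% families, ]
  attr(out, "source_label") <- attr(annotation, "source_label")
  class(out) <- class(annotation)
  out
}
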