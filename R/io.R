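# File readers and writers. All formats are plain TSV/whitespace-separated
# text; lines starting with "#" and blank lines are skipped everywhere.

read_clean_lines <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  list(lines = lines[keep], lineno = which(keep))
}

split_fields <- function(lines) strsplit(trimws(lines), "[ \t]+")

#' Read a PPI network from an edge-list file
#'
#' Accepts a two-column whitespace/tab-separated edge list, or a three-column
#' SIF-style file whose middle (interaction type) column is ignored. An
#' optional identifier mapping is applied to both endpoints before cleaning,
#' so duplicates introduced by the mapping are collapsed too.
#'
#' @param path path to the edge-list file.
#' @param mapping optional identifier mapping from [read_id_mapping()], or a
#'   named character vector (`old -> new`). Unmapped identifiers pass through
#'   unchanged.
#' @return a [ppi_network].
#' @export
read_ppi_network <- function(path, mapping = NULL) {
  cl <- read_clean_lines(path)
  if (length(cl$lines) == 0L) stop("empty edge-list file: ", path)
  fields <- split_fields(cl$lines)
  nf <- lengths(fields)
  bad <- which(nf != 2L & nf != 3L)
  if (length(bad) > 0L) {
    stop("malformed edge line ", cl$lineno[bad[1L]], " in ", path,
         " (expected 2 or 3 fields, got ", nf[bad[1L]], ")")
  }
  a <- vapply(fields, `[[`, "", 1L)
  b <- vapply(fields, function(f) f[[length(f)]], "")
  if (!is.null(mapping)) {
    a <- apply_id_mapping(a, mapping)
    b <- apply_id_mapping(b, mapping)
  }
  ppi_network(data.frame(a, b, stringsAsFactors = FALSE))
}

#' Read a two-column annotation table
#'
#' Reads protein/label pairs (protein TAB label) into a label-set map. Used
#' both for subcellular localization annotations (label = location) and for
#' orthology tables (label = reference species with a seed-ortholog pair).
#' Duplicate pairs are collapsed. An empty file yields an empty, valid map:
#' every protein is then simply unannotated.
#'
#' @param path path to the two-column file.
#' @return an object of class `annotation_map`: a list with `entries` (named
#'   list, protein -> character vector of labels) and `labels` (sorted label
#'   universe).
#' @export
read_annotation_pairs <- function(path) {
  cl <- read_clean_lines(path)
  if (length(cl$lines) == 0L) return(annotation_map(list()))
  fields <- split_fields(cl$lines)
  nf <- lengths(fields)
  bad <- which(nf != 2L)
  if (length(bad) > 0L) {
    stop("malformed annotation line ", cl$lineno[bad[1L]], " in ", path,
         " (expected 2 fields, got ", nf[bad[1L]], ")")
  }
  prot <- vapply(fields, `[[`, "", 1L)
  lab <- vapply(fields, `[[`, "", 2L)
  annotation_map(split(lab, prot))
}

#' Construct an annotation map from a protein -> labels list
#'
#' @param entries named list mapping protein identifiers to character vectors
#'   of labels; duplicates within a protein are collapsed, empty sets dropped.
#' @return an `annotation_map` object.
#' @export
annotation_map <- function(entries) {
  entries <- lapply(entries, function(x) sort(unique(as.character(x))))
  entries <- entries[lengths(entries) > 0L]
  if (length(entries) > 0L) entries <- entries[order(names(entries))]
  structure(
    list(entries = entries,
         labels = sort(unique(unlist(entries, use.names = FALSE)))),
    class = "annotation_map"
  )
}

#' @export
print.annotation_map <- function(x, ...) {
  cat("Annotation map:", length(x$entries), "proteins,",
      length(x$labels), "distinct labels\n")
  invisible(x)
}

#' Read a gold-standard essential-protein list
#'
#' One identifier per line. The list may contain proteins absent from the
#' network; evaluation restricts to the intersection with network nodes.
#'
#' @param path path to the list file.
#' @param mapping optional identifier mapping applied to each entry.
#' @return character vector of unique identifiers.
#' @export
read_essential_list <- function(path, mapping = NULL) {
  cl <- read_clean_lines(path)
  ids <- trimws(cl$lines)
  if (!is.null(mapping)) ids <- apply_id_mapping(ids, mapping)
  unique(ids)
}

#' Read a two-column identifier mapping table
#'
#' Each line maps an old identifier to its canonical replacement
#' (UniProt-style conversion table reduced to two columns). A key mapped to
#' two different targets is ambiguous and rejected.
#'
#' @param path path to the two-column (old, new) file.
#' @return named character vector (`names` = old identifiers).
#' @export
read_id_mapping <- function(path) {
  cl <- read_clean_lines(path)
  if (length(cl$lines) == 0L) return(stats::setNames(character(0), character(0)))
  fields <- split_fields(cl$lines)
  nf <- lengths(fields)
  bad <- which(nf != 2L)
  if (length(bad) > 0L) {
    stop("malformed mapping line ", cl$lineno[bad[1L]], " in ", path)
  }
  old <- vapply(fields, `[[`, "", 1L)
  new <- vapply(fields, `[[`, "", 2L)
  dup <- duplicated(paste(old, new, sep = "\r"))
  old <- old[!dup]
  new <- new[!dup]
  amb <- unique(old[duplicated(old)])
  if (length(amb) > 0L) {
    stop("ambiguous identifier mapping for: ", paste(amb, collapse = ", "))
  }
  stats::setNames(new, old)
}

#' Apply an identifier mapping with pass-through
#'
#' Identifiers present in the mapping are replaced; all others are returned
#' unchanged, so proteins without a canonical identifier are kept rather than
#' dropped.
#'
#' @param ids character vector of identifiers.
#' @param mapping named character vector (`old -> new`).
#' @return character vector of the same length.
#' @examples
#' apply_id_mapping(c("YAL001C", "unknownX"), c(YAL001C = "P31384"))
#' @export
apply_id_mapping <- function(ids, mapping) {
  if (is.null(mapping) || length(mapping) == 0L) return(ids)
  amb <- unique(names(mapping)[duplicated(names(mapping))])
  if (length(amb) > 0L) {
    stop("ambiguous identifier mapping for: ", paste(amb, collapse = ", "))
  }
  hit <- match(ids, names(mapping))
  ifelse(is.na(hit), ids, unname(mapping[hit]))
}

score_table_columns <- c("protein", "degree", "NC", "NNC", "SL", "NSL",
                         "OS", "NOS", "pr", "rank")

#' Write a per-protein score table
#'
#' Writes a 10-column tab-separated file (protein, degree, NC, NNC, SL, NSL,
#' OS, NOS, pr, rank) with a header line, rows in rank order and real-valued
#' scores formatted to six decimal places.
#'
#' @param scores a score table data.frame (e.g. from [son()]) with the columns
#'   above, or a `son` object.
#' @param path output path.
#' @export
write_score_table <- function(scores, path) {
  if (inherits(scores, "son")) scores <- scores$scores
  stopifnot(all(score_table_columns %in% names(scores)))
  scores <- scores[order(scores$rank), score_table_columns]
  out <- scores
  for (col in c("NC", "NNC", "SL", "NSL", "NOS", "pr")) {
    out[[col]] <- sprintf("%.6f", scores[[col]])
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(score_table_columns, collapse = "\t"), con)
  if (nrow(out) > 0L) {
    writeLines(do.call(paste, c(unname(as.list(out)), sep = "\t")), con)
  }
  invisible(path)
}

#' Read back a score table written by [write_score_table()]
#'
#' @param path path to the TSV file.
#' @return data.frame with the ten score-table columns.
#' @export
read_score_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                          colClasses = c(protein = "character"))
  stopifnot(identical(names(df), score_table_columns))
  df
}

#' Write a centrality (or any per-protein score) map as two-column TSV
#'
#' @param scores named numeric vector.
#' @param path output path.
#' @export
write_centrality <- function(scores, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(names(scores), sprintf("%.6f", scores), sep = "\t"), con)
  invisible(path)
}
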