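#' Construct an association table
#'
#' An association table holds experimentally verified miRNA-disease pairs
#' (the positive class of the positive-unlabeled setting) together with the
#' ordered miRNA and disease indices that all downstream matrices inherit.
#' Indices are lexicographic so that every run, on every platform, lays out
#' the association matrix identically.
#'
#' @param records a data frame with character columns `mirna` and `disease`
#'   (extra columns are dropped).
#' @param mirna_index,disease_index optional character vectors fixing the
#'   entity order; defaults to the sorted unique ids found in `records`.
#'   Every record id must appear in the corresponding index.
#' @return a tibble of class `association_table` with columns `mirna` and
#'   `disease`, carrying the indices as attributes.
#' @export
association_table <- function(records, mirna_index = NULL, disease_index = NULL) {
  records <- tibble::as_tibble(records)
  if (!all(c("mirna", "disease") %in% names(records))) {
    rlang::abort("`records` needs columns `mirna` and `disease`")
  }
  records <- dplyr::transmute(
    records,
    mirna = trimws(as.character(.data$mirna)),
    disease = trimws(as.character(.data$disease))
  )
  if (nrow(records) == 0L) rlang::abort("association table has no records")
  if (any(records$mirna == "" | records$disease == "")) {
    rlang::abort("blank miRNA or disease id in records")
  }
  n_dup <- sum(duplicated(pair_key(records$mirna, records$disease)))
  if (n_dup > 0L) {
    rlang::inform(sprintf("dropping %d duplicate association record(s)", n_dup))
    records <- dplyr::distinct(records, .data$mirna, .data$disease)
  }
  mirna_index <- if (is.null(mirna_index)) {
    sort(unique(records$mirna), method = "radix")
  } else as.character(mirna_index)
  disease_index <- if (is.null(disease_index)) {
    sort(unique(records$disease), method = "radix")
  } else as.character(disease_index)
  if (!all(records$mirna %in% mirna_index) ||
      !all(records$disease %in% disease_index)) {
    rlang::abort("every record id must appear in its index")
  }
  structure(
    records,
    mirna_index = mirna_index,
    disease_index = disease_index,
    class = c("association_table", class(records))
  )
}

#' @export
print.association_table <- function(x, ...) {
  cat(sprintf(
    "# Association table: %d records, %d miRNAs x %d diseases\n",
    nrow(x), length(mirna_index(x)), length(disease_index(x))
  ))
  NextMethod()
}

#' Entity indices of an association table
#'
#' @param x an `association_table`.
#' @return character vector of ordered ids.
#' @export
mirna_index <- function(x) attr(x, "mirna_index")

#' @rdname mirna_index
#' @export
disease_index <- function(x) attr(x, "disease_index")

#' Read a miRNA-disease association table
#'
#' Reads a delimited file whose first two columns are a miRNA id and a
#' disease id (the layout of curated association databases such as HMDD).
#' A header row is auto-detected: a first row whose cells look like column
#' names (`mirna`, `mirna_id`, `disease`, ...) is skipped.
#'
#' @param path file path; tab-, comma- or whitespace-delimited.
#' @return an [association_table()].
#' @export
read_association_table <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[!grepl("^\\s*$", lines)]
  if (length(lines) == 0L) rlang::abort(sprintf("empty association file: %s", path))
  fields <- stringr::str_split(trimws(lines), "[\t,]|\\s+")
  bad <- which(vapply(fields, function(f) length(f) < 2L || any(f[1:2] == ""), logical(1)))
  header_names <- c(
    "mirna", "mirna_id", "mir", "mirnas",
    "disease", "disease_id", "diseases", "disease_name"
  )
  first <- tolower(fields[[1]][1:2])
  has_header <- all(first %in% header_names)
  if (has_header) bad <- setdiff(bad, 1L)
  if (length(bad) > 0L) {
    rlang::abort(sprintf(
      "malformed or blank id on line %d of %s", bad[1], path
    ))
  }
  if (has_header) fields <- fields[-1L]
  if (length(fields) == 0L) rlang::abort(sprintf("no records in %s", path))
  association_table(tibble::tibble(
    mirna = vapply(fields, `[[`, character(1), 1L),
    disease = vapply(fields, `[[`, character(1), 2L)
  ))
}

#' Write an association table as TSV
#'
#' @param x an `association_table` (or any tibble with `mirna`, `disease`).
#' @param path output path; UTF-8, tab-delimited, with header.
#' @return `path`, invisibly.
#' @export
write_association_table <- function(x, path) {
  readr::write_tsv(tibble::tibble(mirna = x$mirna, disease = x$disease), path)
  invisible(path)
}

#' Build the binary association matrix
#'
#' Converts an association table into the Nm x Nd 0/1 matrix whose entry
#' (i, j) is 1 exactly when miRNA i and disease j are verified to be
#' related. Rows are miRNA interaction profiles, columns disease
#' interaction profiles; both follow the table's lexicographic indices.
#'
#' @param table an [association_table()].
#' @return integer matrix with dimnames (miRNAs x diseases).
#' @export
build_association_matrix <- function(table) {
  mi <- mirna_index(table)
  di <- disease_index(table)
  if (is.null(mi) || is.null(di)) {
    table <- association_table(table)
    mi <- mirna_index(table)
    di <- disease_index(table)
  }
  md <- matrix(0L, length(mi), length(di), dimnames = list(mi, di))
  md[cbind(match(table$mirna, mi), match(table$disease, di))] <- 1L
  md
}
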