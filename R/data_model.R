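# Relation kinds accepted by edge-list readers; order matters nowhere.
RELATION_KINDS <- c("circ-mi", "circ-cancer", "mi-cancer")

#' Read a two-column edge list
#'
#' Reads a delimited text file of `(source_id, target_id)` pairs. The
#' delimiter is sniffed from the first line (tab preferred, comma accepted).
#' A header line is detected heuristically: if the first row's fields never
#' reappear as identifiers in the body it is treated as a header and
#' dropped. Duplicate pairs are collapsed, keeping first-seen order.
#'
#' @param path Path to a TSV/CSV file with at least two columns.
#' @param relation_kind One of `"circ-mi"`, `"circ-cancer"`, `"mi-cancer"`.
#' @return An object of class `edge_list`: a list with `pairs` (a
#'   two-column character matrix), `relation_kind`, and `n_dropped`
#'   (duplicates removed).
#' @export
read_edge_list <- function(path, relation_kind = c("circ-mi", "circ-cancer", "mi-cancer")) {
  relation_kind <- match.arg(relation_kind)
  if (!file.exists(path)) stop("edge list file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty edge list file: ", path)

  sep <- if (grepl("\t", lines[[1]], fixed = TRUE)) "\t" else ","
  fields <- strsplit(lines, sep, fixed = TRUE)
  fields <- lapply(fields, function(f) {
    f <- trimws(f)
    f[nzchar(f)]
  })

  bad <- which(vapply(fields, length, 0L) < 2L)
  if (length(bad) > 0L) {
    stop(sprintf("malformed edge list row at line %d of %s (need >= 2 fields)",
                 bad[[1]], path))
  }

  src <- vapply(fields, `[[`, "", 1L)
  dst <- vapply(fields, `[[`, "", 2L)

  # Header heuristic: drop the first row if neither of its fields recurs
  # anywhere in the remaining rows (typical of "circRNA<TAB>miRNA" headers).
  if (length(src) > 1L && !(src[[1]] %in% src[-1]) && !(dst[[1]] %in% dst[-1]) &&
      grepl("[A-Za-z]", src[[1]]) && !grepl("[0-9]", src[[1]])) {
    src <- src[-1]
    dst <- dst[-1]
  }

  key <- paste(src, dst, sep = "\r")
  keep <- !duplicated(key)
  n_dropped <- sum(!keep)
  if (n_dropped > 0L) {
    message(sprintf("read_edge_list: dropped %d duplicate pair(s) from %s",
                    n_dropped, basename(path)))
  }
  edge_list(cbind(src[keep], dst[keep]), relation_kind, n_dropped)
}

#' Construct an edge list from pairs already in memory
#'
#' @param pairs Two-column character matrix (or coercible data.frame) of
#'   `(source_id, target_id)` pairs.
#' @param relation_kind One of the three tripartite relation kinds.
#' @param n_dropped Count of duplicates removed upstream (bookkeeping only).
#' @return An `edge_list` object.
#' @export
edge_list <- function(pairs, relation_kind = c("circ-mi", "circ-cancer", "mi-cancer"),
                      n_dropped = 0L) {
  relation_kind <- match.arg(relation_kind)
  if (is.data.frame(pairs)) pairs <- as.matrix(pairs)
  if (is.null(pairs) || length(pairs) == 0L) {
    pairs <- matrix(character(0), ncol = 2L)
  }
  storage.mode(pairs) <- "character"
  if (ncol(pairs) != 2L) stop("pairs must have exactly two columns")
  pairs[] <- trimws(pairs)
  if (any(!nzchar(pairs))) stop("edge list contains empty identifiers")
  key <- paste(pairs[, 1L], pairs[, 2L], sep = "\r")
  pairs <- pairs[!duplicated(key), , drop = FALSE]
  structure(list(pairs = pairs, relation_kind = relation_kind,
                 n_dropped = as.integer(n_dropped)),
            class = "edge_list")
}

#' @export
print.edge_list <- function(x, ...) {
  cat(sprintf("<edge_list> %s: %d pairs\n", x$relation_kind, nrow(x$pairs)))
  invisible(x)
}

# Ordered unique identifiers -> entity index (names + 0-based positions).
entity_index <- function(names) {
  names <- unique(as.character(names))
  if (length(names) == 0L) stop("cannot build an index over zero identifiers")
  structure(list(names = names,
                 position = stats::setNames(seq_along(names) - 1L, names)),
            class = "entity_index")
}

#' @export
print.entity_index <- function(x, ...) {
  cat(sprintf("<entity_index> %d identifiers\n", length(x$names)))
  invisible(x)
}

fill_adjacency <- function(pairs, row_index, col_index) {
  M <- matrix(0, length(row_index$names), length(col_index$names),
              dimnames = list(row_index$names, col_index$names))
  if (nrow(pairs) > 0L) M[pairs] <- 1
  M
}

#' Assemble the tripartite interaction dataset
#'
#' Builds binary adjacency matrices CM (circRNA x miRNA), CC (circRNA x
#' cancer) and MC (miRNA x cancer) from three edge lists. Identifier
#' indices are the union of identifiers seen for each entity class, in
#' first-seen order (CM edges first, then CC, then MC), so an entity known
#' only from its cancer associations still receives an all-zero interaction
#' profile — such cold-start rows are exactly what the similarity fusion
#' rule is designed to handle.
#'
#' @param cm `edge_list` of kind `"circ-mi"`.
#' @param cc `edge_list` of kind `"circ-cancer"`.
#' @param mc `edge_list` of kind `"mi-cancer"`.
#' @return An `interaction_dataset`: list with binary matrices `CM`, `CC`,
#'   `MC` (dimnames carry the identifiers) and the three `entity_index`
#'   objects `circ_index`, `mi_index`, `cancer_index`.
#' @export
build_dataset <- function(cm, cc, mc) {
  stopifnot(inherits(cm, "edge_list"), inherits(cc, "edge_list"),
            inherits(mc, "edge_list"))
  if (cm$relation_kind != "circ-mi") stop("cm must have relation kind 'circ-mi'")
  if (cc$relation_kind != "circ-cancer") stop("cc must have relation kind 'circ-cancer'")
  if (mc$relation_kind != "mi-cancer") stop("mc must have relation kind 'mi-cancer'")

  circ_ids <- c(cm$pairs[, 1L], cc$pairs[, 1L])
  mi_ids <- c(cm$pairs[, 2L], mc$pairs[, 1L])
  cancer_ids <- c(cc$pairs[, 2L], mc$pairs[, 2L])
  if (length(circ_ids) == 0L) stop("no circRNA identifiers in any input")
  if (length(mi_ids) == 0L) stop("no miRNA identifiers in any input")
  if (length(cancer_ids) == 0L) stop("no cancer identifiers in any input")

  circ_index <- entity_index(circ_ids)
  mi_index <- entity_index(mi_ids)
  cancer_index <- entity_index(cancer_ids)

  ds <- structure(list(
    CM = fill_adjacency(cm$pairs, circ_index, mi_index),
    CC = fill_adjacency(cc$pairs, circ_index, cancer_index),
    MC = fill_adjacency(mc$pairs, mi_index, cancer_index),
    circ_index = circ_index,
    mi_index = mi_index,
    cancer_index = cancer_index
  ), class = "interaction_dataset")
  validate_dataset(ds)
}

validate_dataset <- function(ds) {
  stopifnot(inherits(ds, "interaction_dataset"))
  nc <- length(ds$circ_index$names)
  nm <- length(ds$mi_index$names)
  nd <- length(ds$cancer_index$names)
  if (!identical(dim(ds$CM), c(nc, nm)) ||
      !identical(dim(ds$CC), c(nc, nd)) ||
      !identical(dim(ds$MC), c(nm, nd))) {
    stop("adjacency matrix shapes inconsistent with entity indices")
  }
  for (nm_ in c("CM", "CC", "MC")) {
    if (!all(ds[[nm_]] %in% c(0, 1))) stop(nm_, " is not binary")
  }
  ds
}

#' @export
print.interaction_dataset <- function(x, ...) {
  cat(sprintf(paste0("<interaction_dataset> %d circRNAs, %d miRNAs, %d cancers\n",
                     "  CM: %d edges (density %.4g)  CC: %d edges  MC: %d edges\n"),
              nrow(x$CM), ncol(x$CM), ncol(x$CC),
              sum(x$CM), interaction_density(x$CM), sum(x$CC), sum(x$MC)))
  invisible(x)
}

#' Density of a binary interaction matrix
#'
#' The fraction of entries that are 1: `sum(M) / (nrow(M) * ncol(M))`.
#'
#' @param M A non-empty binary matrix.
#' @return A fraction in `[0, 1]`.
#' @export
interaction_density <- function(M) {
  if (length(M) == 0L) stop("cannot compute the density of an empty matrix")
  sum(M != 0) / length(M)
}

#' Write a matrix with identifier headers
#'
#' Writes a TSV whose first column holds the row identifiers and whose
#' header row holds the column identifiers. Values are written with enough
#' significant digits (15) to round-trip doubles through text.
#'
#' @param M Numeric matrix with dimnames (or supply via `row_ids`/`col_ids`).
#' @param path Output file path.
#' @param row_ids,col_ids Optional identifier vectors overriding dimnames.
#' @return `path`, invisibly.
#' @export
write_id_matrix <- function(M, path, row_ids = rownames(M), col_ids = colnames(M)) {
  if (is.null(row_ids) || is.null(col_ids)) {
    stop("matrix must carry identifiers (dimnames or row_ids/col_ids)")
  }
  stopifnot(length(row_ids) == nrow(M), length(col_ids) == ncol(M))
  body <- apply(M, 2L, format, digits = 15L, scientific = FALSE, trim = TRUE)
  if (nrow(M) == 1L) body <- matrix(body, nrow = 1L)
  out <- rbind(c("id", col_ids), cbind(row_ids, body))
  ok <- tryCatch({
    writeLines(apply(out, 1L, paste, collapse = "\t"), path)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("could not write matrix to ", path)
  invisible(path)
}

#' Read a matrix written by [write_id_matrix()]
#'
#' @param path TSV file with an `id` header column and identifier headers.
#' @return Numeric matrix with identifier dimnames.
#' @export
read_id_matrix <- function(path) {
  df <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  row_ids <- as.character(df[[1L]])
  M <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(M) <- "double"
  rownames(M) <- row_ids
  M
}

# Recover the positive pairs of a binary matrix as an identifier edge list.
matrix_to_edges <- function(M) {
  idx <- which(M != 0, arr.ind = TRUE)
  cbind(rownames(M)[idx[, 1L]], colnames(M)[idx[, 2L]])
}
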