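#' Aligned barcode locus container
#'
#' A `locus_alignment` holds equal-length gapped DNA sequences for one barcode
#' locus, each tied to an individual and a species label. Internally the
#' alignment is a character matrix (rows = individuals, columns = alignment
#' positions) over the uppercase IUPAC alphabet plus `"-"`.
#'
#' @param seqs Character vector of aligned sequences (equal length).
#' @param ids Character vector of individual identifiers, unique within the locus.
#' @param species Character vector of species labels (binomials; underscores
#'   and spaces are interchangeable and normalised to underscores).
#' @param locus Single locus name.
#' @param boundaries Optional named integer vector of cumulative end columns of
#'   member loci, kept when alignments are concatenated.
#' @return An object of class `locus_alignment`.
#' @export
locus_alignment <- function(seqs, ids, species, locus, boundaries = NULL) {
  stopifnot(length(seqs) == length(ids), length(ids) == length(species))
  if (length(seqs) < 1 || any(!nzchar(seqs)))
    stop("alignment must contain non-empty sequences")
  if (anyDuplicated(ids))
    stop("individual ids must be unique within a locus: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (any(!nzchar(species))) stop("species labels must be non-empty")
  seqs <- vapply(seqs, normalize_seq, character(1), USE.NAMES = FALSE)
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1) {
    bad <- ids[lens != lens[1]][1]
    stop("unequal aligned lengths: record '", bad, "' has ", nchar(seqs[ids == bad]),
         " columns, expected ", lens[1])
  }
  mat <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  ok <- matrix(mat %in% IUPAC_CODES, nrow(mat))
  if (!all(ok)) {
    idx <- which(!ok, arr.ind = TRUE)[1, ]
    stop("non-IUPAC character '", mat[idx[1], idx[2]], "' in record '",
         ids[idx[1]], "' at position ", idx[2])
  }
  rownames(mat) <- ids
  structure(
    list(locus = locus, ids = ids, species = gsub(" ", "_", species),
         mat = mat, boundaries = boundaries),
    class = "locus_alignment"
  )
}

#' @export
print.locus_alignment <- function(x, ...) {
  cat("<locus_alignment> ", x$locus, ": ", nrow(x$mat), " sequences x ",
      ncol(x$mat), " bp, ", length(unique(x$species)), " species\n", sep = "")
  invisible(x)
}

#' @export
length.locus_alignment <- function(x) ncol(x$mat)

#' Number of sequences in an alignment
#' @param aln A `locus_alignment`.
#' @return Integer count of sequences.
#' @export
n_seq <- function(aln) nrow(aln$mat)

#' @importFrom tibble as_tibble tibble
#' @export
as_tibble.locus_alignment <- function(x, ...) {
  tibble::tibble(
    individual_id = x$ids,
    species = x$species,
    locus = x$locus,
    seq = apply(x$mat, 1, paste, collapse = "")
  )
}

species_of <- function(aln) stats::setNames(aln$species, aln$ids)

#' Read a species-annotated aligned FASTA file
#'
#' Headers are parsed into `(individual_id, species)` using `header_scheme`;
#' the default scheme is `"id|species"`, i.e. `>Da1|Genus_species`.
#' Sequences are uppercased and `U` converted to `T` on read.
#'
#' @param path Path to an aligned (gapped) FASTA file.
#' @param locus Locus name to attach.
#' @param header_scheme Either `"id|species"` (split on the first `|`) or
#'   `"id species"` (split on first whitespace).
#' @return A [locus_alignment()].
#' @export
read_aligned_fasta <- function(path, locus, header_scheme = "id|species") {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  hdr_idx <- grep("^>", lines)
  if (length(hdr_idx) == 0) stop("no FASTA records in ", path)
  headers <- sub("^>", "", lines[hdr_idx])
  ends <- c(hdr_idx[-1] - 1L, length(lines))
  seqs <- vapply(seq_along(hdr_idx), function(i) {
    paste(lines[seq(hdr_idx[i] + 1L, ends[i])], collapse = "")
  }, character(1))
  parsed <- parse_headers(headers, header_scheme)
  locus_alignment(seqs, parsed$id, parsed$species, locus)
}

parse_headers <- function(headers, scheme) {
  headers <- trimws(headers)
  if (scheme == "id|species") {
    pieces <- regmatches(headers, regexpr("\\|", headers), invert = TRUE)
    bad <- lengths(pieces) != 2
    if (any(bad)) stop("header not in 'id|species' form: ", headers[bad][1])
    list(id = trimws(vapply(pieces, `[`, "", 1)),
         species = trimws(vapply(pieces, `[`, "", 2)))
  } else if (scheme == "id species") {
    id <- sub("\\s.*$", "", headers)
    sp <- trimws(sub("^\\S+\\s*", "", headers))
    if (any(!nzchar(sp))) stop("header lacks a species token: ",
                               headers[!nzchar(sp)][1])
    list(id = id, species = sp)
  } else stop("unknown header_scheme: ", scheme)
}

#' Write an alignment as FASTA
#'
#' Inverse of [read_aligned_fasta()]: headers are `id|species`.
#'
#' @param aln A `locus_alignment`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_aligned_fasta <- function(aln, path) {
  seqs <- apply(aln$mat, 1, paste, collapse = "")
  out <- character(2L * length(seqs))
  out[c(TRUE, FALSE)] <- paste0(">", aln$ids, "|", aln$species)
  out[c(FALSE, TRUE)] <- seqs
  writeLines(out, path)
  invisible(path)
}

#' Assemble a multi-locus barcode dataset
#'
#' Bundles per-locus alignments and checks that species assignments are
#' consistent for individuals shared across loci.
#'
#' @param ... `locus_alignment` objects (or a single list of them).
#' @return A `barcode_dataset`: list with elements `loci` (named list of
#'   alignments) and `species_map` (named character vector individual -> species).
#' @export
barcode_dataset <- function(...) {
  loci <- list(...)
  if (length(loci) == 1 && !inherits(loci[[1]], "locus_alignment"))
    loci <- loci[[1]]
  stopifnot(all(vapply(loci, inherits, logical(1), "locus_alignment")))
  names(loci) <- vapply(loci, function(a) a$locus, character(1))
  species_map <- character(0)
  for (a in loci) {
    sm <- species_of(a)
    shared <- intersect(names(sm), names(species_map))
    if (length(shared) && any(sm[shared] != species_map[shared])) {
      bad <- shared[sm[shared] != species_map[shared]][1]
      stop("inconsistent species for individual '", bad, "' across loci")
    }
    species_map[names(sm)] <- sm
  }
  structure(list(loci = loci, species_map = species_map),
            class = "barcode_dataset")
}

#' @export
print.barcode_dataset <- function(x, ...) {
  cat("<barcode_dataset> ", length(x$loci), " loci (",
      paste(names(x$loci), collapse = ", "), "), ",
      length(x$species_map), " individuals, ",
      length(unique(x$species_map)), " species\n", sep = "")
  invisible(x)
}

#' Read a barcode dataset from a JSON manifest
#'
#' The manifest maps locus names to FASTA paths:
#' `{"loci": {"matK": "matK.fasta", ...}, "header_scheme": "id|species"}`.
#' Relative paths are resolved against the manifest's directory.
#'
#' @param path Path to the JSON manifest.
#' @return A [barcode_dataset()].
#' @export
read_dataset_manifest <- function(path) {
  cfg <- jsonlite::read_json(path)
  scheme <- cfg$header_scheme %||% "id|species"
  base <- dirname(path)
  alns <- lapply(names(cfg$loci), function(lc) {
    f <- cfg$loci[[lc]]
    if (!file.exists(f)) f <- file.path(base, f)
    read_aligned_fasta(f, lc, scheme)
  })
  barcode_dataset(alns)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Concatenate loci of a dataset end-to-end
#'
#' Joins the chosen loci per individual in the given order; the combined
#' length is the sum of member lengths and locus boundaries are retained in
#' the result's `boundaries` field.
#'
#' @param dataset A `barcode_dataset`.
#' @param loci Character vector of locus names to join, in order.
#' @return A `locus_alignment` named after the joined loci (e.g. `"rbcL+matK"`).
#' @export
concat_loci <- function(dataset, loci = names(dataset$loci)) {
  missing_loci <- setdiff(loci, names(dataset$loci))
  if (length(missing_loci))
    stop("unknown loci: ", paste(missing_loci, collapse = ", "))
  alns <- dataset$loci[loci]
  if (length(alns) == 1) return(alns[[1]])
  ids <- alns[[1]]$ids
  for (a in alns[-1]) {
    absent <- setdiff(ids, a$ids)
    absent <- union(absent, setdiff(a$ids, ids))
    if (length(absent))
      stop("individuals missing from some requested loci: ",
           paste(sort(absent), collapse = ", "))
  }
  mats <- lapply(alns, function(a) a$mat[ids, , drop = FALSE])
  mat <- do.call(cbind, mats)
  lens <- vapply(alns, function(a) ncol(a$mat), integer(1))
  locus_alignment(
    seqs = apply(mat, 1, paste, collapse = ""),
    ids = ids,
    species = unname(dataset$species_map[ids]),
    locus = paste(loci, collapse = "+"),
    boundaries = stats::setNames(cumsum(lens), loci)
  )
}

#' Enumerate multi-locus combinations
#'
#' All subsets of size >= `min_size` of the given loci, ordered by size then
#' lexicographically; five loci yield the 26 possible multi-locus combinations.
#'
#' @param locus_names Character vector of at least two locus names.
#' @param min_size Smallest subset size to include (default 2).
#' @return List of character vectors (each keeps the input's locus order).
#' @export
locus_combinations <- function(locus_names, min_size = 2) {
  if (length(locus_names) < 2) stop("need at least two loci")
  out <- list()
  for (k in seq(min_size, length(locus_names))) {
    cmb <- utils::combn(seq_along(locus_names), k, simplify = FALSE)
    subs <- lapply(cmb, function(i) locus_names[i])
    keys <- vapply(subs, function(s) paste(sort(s), collapse = "\r"), character(1))
    out <- c(out, subs[order(keys)])
  }
  out
}
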